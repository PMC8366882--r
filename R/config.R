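#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the identification pipeline. The
#' defaults encode the standard barcoding decision rules: a species is
#' called when the query is *more than* 99% identical to its best match
#' (and the runner-up species is below that bar), a genus when identity
#' exceeds 95%, and queries below the 95% floor stay unidentified.
#'
#' @param species_identity_threshold fraction; a species-level call needs
#'   best-hit identity strictly above this (default 0.99, i.e. the 1%
#'   divergence species boundary).
#' @param genus_identity_floor fraction; identity strictly above this (but
#'   failing the species rules) yields a genus-level call (default 0.95).
#' @param top_n_primary number of top hits whose species consensus can
#'   rescue a species call in the primary rules (default 100).
#' @param top_n_fallback number of top hits consulted by the fallback
#'   rules (default 5).
#' @param bootstrap_reps bootstrap replicates for tree supports
#'   (default 1000).
#' @param lineage_cluster_threshold K2P distance below which barcodes are
#'   chained into one lineage (default 0.01).
#' @param rng_seed integer seed recorded with every run.
#' @param exclusion_taxa character vector of species binomials excluded on
#'   external (ecological) grounds; their hits are removed and the cascade
#'   re-run once when they would decide a verdict.
#' @param months ordered month axis for phenology (default May-September,
#'   the sampling season).
#' @param eggs_only logical; restrict occurrence summaries to eggs.
#' @param match,mismatch,gap_open,gap_extend alignment scoring (a gap run
#'   of length L costs `gap_open + L * gap_extend`).
#' @param min_overlap minimum number of comparable alignment columns for
#'   a hit to count (default 100); ends-free alignments of unrelated
#'   sequences can otherwise win on short spurious perfect overlaps. The
#'   floor shrinks to the shorter sequence when sequences are shorter
#'   than this.
#' @return an object of class `run_config` (a validated list).
#' @export
#' @examples
#' cfg <- run_config(exclusion_taxa = "Siniperca roulei")
#' cfg$species_identity_threshold
run_config <- function(species_identity_threshold = 0.99,
                       genus_identity_floor = 0.95,
                       top_n_primary = 100L,
                       top_n_fallback = 5L,
                       bootstrap_reps = 1000L,
                       lineage_cluster_threshold = 0.01,
                       rng_seed = 1L,
                       exclusion_taxa = character(),
                       months = MONTHS_DEFAULT,
                       eggs_only = FALSE,
                       match = 1, mismatch = -1,
                       gap_open = 5, gap_extend = 2,
                       min_overlap = 100L) {
  cfg <- list(species_identity_threshold = as.numeric(species_identity_threshold),
              genus_identity_floor = as.numeric(genus_identity_floor),
              top_n_primary = as.integer(top_n_primary),
              top_n_fallback = as.integer(top_n_fallback),
              bootstrap_reps = as.integer(bootstrap_reps),
              lineage_cluster_threshold = as.numeric(lineage_cluster_threshold),
              rng_seed = as.integer(rng_seed),
              exclusion_taxa = as.character(exclusion_taxa),
              months = as.character(months),
              eggs_only = isTRUE(eggs_only),
              match = as.numeric(match), mismatch = as.numeric(mismatch),
              gap_open = as.numeric(gap_open),
              gap_extend = as.numeric(gap_extend),
              min_overlap = as.integer(min_overlap))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (!(genus_identity_floor > 0 &&
          genus_identity_floor <= species_identity_threshold &&
          species_identity_threshold < 1))
      stop("need 0 < genus_identity_floor <= species_identity_threshold < 1")
    if (top_n_primary < 1L || top_n_fallback < 1L) stop("top_n must be >= 1")
    if (bootstrap_reps < 0L) stop("bootstrap_reps must be >= 0")
    if (lineage_cluster_threshold <= 0) stop("lineage threshold must be > 0")
    if (min_overlap < 1L) stop("min_overlap must be >= 1")
    if (length(months) < 1L) stop("months must be nonempty")
  })
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  species rule : identity > %.4g (top-%d consensus)\n",
              x$species_identity_threshold, x$top_n_primary))
  cat(sprintf("  genus floor  : identity > %.4g (top-%d fallback)\n",
              x$genus_identity_floor, x$top_n_fallback))
  cat(sprintf("  lineages     : single linkage, K2P <= %.4g\n",
              x$lineage_cluster_threshold))
  cat(sprintf("  bootstrap    : %d replicates, seed %d\n",
              x$bootstrap_reps, x$rng_seed))
  if (length(x$exclusion_taxa))
    cat("  excluded     :", paste(x$exclusion_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' @param path file path.
#' @rdname run_config_io
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @param cfg a `run_config` object.
#' @rdname run_config_io
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
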