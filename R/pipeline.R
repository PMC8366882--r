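## Stage runners behind the command-line interface. Each stage reads and
## writes only files, so stages compose with no hidden state; counts and
## seeds are logged through message() (stderr).

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the simulation stage
#'
#' Writes a simulated reference library and egg survey to `outdir`:
#' `reference.fasta`, `taxonomy.tsv`, `queries.fasta`, `metadata.tsv`,
#' `truth.tsv` and `windows.yaml`.
#'
#' @param outdir output directory (created if needed).
#' @param params a [simulation_params()].
#' @return named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(outdir, params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(params)
  survey <- simulate_survey(ref)
  paths <- c(reference = file.path(outdir, "reference.fasta"),
             taxonomy = file.path(outdir, "taxonomy.tsv"),
             queries = file.path(outdir, "queries.fasta"),
             metadata = file.path(outdir, "metadata.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             windows = file.path(outdir, "windows.yaml"))
  write_fasta(ref$library$sequences, paths[["reference"]])
  write.table(ref$library$taxonomy, paths[["taxonomy"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(survey$sequences, paths[["queries"]])
  write.table(survey$metadata, paths[["metadata"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(survey$truth, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(survey$windows, paths[["windows"]])
  log_stage("simulate", "seed %d: %d references, %d eggs (%d dropped)",
            params$seed, length(ref$library$sequences), nrow(survey$truth),
            sum(survey$truth$dropped))
  invisible(paths)
}

#' Run the assignment stage
#'
#' Reads query barcodes, the reference library and optional metadata,
#' runs the assignment cascade on every query, and writes
#' `assignments.tsv` plus `assignment_summary.json` to `outdir`.
#'
#' @param queries_path query FASTA.
#' @param reference_path reference FASTA.
#' @param taxonomy_path reference taxonomy TSV.
#' @param outdir output directory.
#' @param metadata_path optional metadata TSV.
#' @param cfg a [run_config()].
#' @return the `egg_assignments` object, invisibly.
#' @export
run_assign <- function(queries_path, reference_path, taxonomy_path, outdir,
                       metadata_path = NULL, cfg = run_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  queries <- read_fasta(queries_path)
  lib <- read_reference_library(reference_path, taxonomy_path)
  md <- if (!is.null(metadata_path)) read_metadata(metadata_path, cfg$months)
  res <- assign_batch(queries, lib, cfg, metadata = md)
  write_assignments(res, file.path(outdir, "assignments.tsv"))
  jsonlite::write_json(res$summary[c("n", "n_species", "n_genus",
                                     "n_unidentified")],
                       file.path(outdir, "assignment_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("assign", "%d queries: %d species, %d genus, %d unidentified",
            res$summary$n, res$summary$n_species, res$summary$n_genus,
            res$summary$n_unidentified)
  invisible(res)
}

#' Run the tree stage
#'
#' Projects the query barcodes onto a common coordinate frame (anchored
#' on the first, or given, sequence), computes the K2P distance matrix,
#' builds the neighbor-joining tree (with bootstrap supports when
#' `cfg$bootstrap_reps > 0`), delimits lineages by single linkage at the
#' configured threshold, and writes `tree.nwk`, `distances.tsv` and
#' `lineages.tsv` to `outdir`.
#'
#' @param queries_path FASTA of barcodes (3 or more usable sequences).
#' @param outdir output directory.
#' @param cfg a [run_config()].
#' @param anchor optional anchor sequence for the projection (default:
#'   the first query).
#' @return list with `tree`, `distances`, `lineages`, invisibly.
#' @export
run_tree <- function(queries_path, outdir, cfg = run_config(),
                     anchor = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_fasta(queries_path)
  if (length(seqs) < 3L) stop("need at least 3 sequences for a tree")
  anchor <- anchor %||% seqs[[1L]]
  aligned <- if (length(unique(nchar(seqs))) > 1L ||
                 nchar(seqs[[1L]]) != nchar(anchor))
    project_to_reference(seqs, anchor, cfg) else seqs
  dm <- k2p_matrix(aligned)
  tree <- if (cfg$bootstrap_reps > 0L)
    bootstrap_supports(aligned, cfg$bootstrap_reps, seed = cfg$rng_seed)
  else nj_tree(dm)
  part <- cluster_lineages(dm, cfg$lineage_cluster_threshold)
  write_newick(tree, file.path(outdir, "tree.nwk"))
  write_distance_matrix(dm, file.path(outdir, "distances.tsv"))
  write_lineages(part, file.path(outdir, "lineages.tsv"))
  log_stage("tree", "%d sequences, %d lineages at K2P <= %g (%d bootstrap reps, seed %d)",
            length(seqs), length(part$clusters),
            cfg$lineage_cluster_threshold, cfg$bootstrap_reps, cfg$rng_seed)
  invisible(list(tree = tree, distances = dm, lineages = part))
}

#' Read an assignment report back from TSV
#'
#' Inverse of [write_assignments()]; the genus of genus-level verdicts is
#' taken from the taxon field, and of species-level verdicts from the
#' generic epithet. Families are filled from `taxonomy` when given.
#'
#' @param path assignment report TSV.
#' @param taxonomy optional reference taxonomy data.frame (columns
#'   `family`, `genus`).
#' @return data.frame in the layout of `assign_batch()$results`.
#' @export
read_assignments <- function(path, taxonomy = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  out <- data.frame(id = df$id, level = df$level, taxon = df$taxon,
                    rule_id = df$rule_id,
                    best_identity = num(df$best_identity),
                    second_best_identity = num(df$second_best_identity),
                    n_supporting_hits = as.integer(df$n_supporting_hits),
                    stringsAsFactors = FALSE)
  out$genus <- ifelse(out$level == "genus", out$taxon,
                      ifelse(out$level == "species",
                             sub("\\s.*$", "", out$taxon), NA))
  out$family <- NA_character_
  if (!is.null(taxonomy))
    out$family <- taxonomy$family[match(out$genus, taxonomy$genus)]
  out
}

#' Run the phenology stage
#'
#' Joins assignments with specimen months, builds the occurrence matrix
#' (optionally splitting lineages with a `lineages.tsv` partition) and
#' writes `occurrence.tsv`, `spawning_periods.tsv` and
#' `phenology_summary.json` to `outdir`.
#'
#' @param assignments_path assignment report TSV (or an
#'   `egg_assignments` object).
#' @param metadata_path metadata TSV (or data.frame).
#' @param outdir output directory.
#' @param cfg a [run_config()].
#' @param lineages_path optional lineage TSV from [run_tree()].
#' @param taxonomy_path optional reference taxonomy TSV for family labels.
#' @return the `occurrence_matrix`, invisibly.
#' @export
run_phenology <- function(assignments_path, metadata_path, outdir,
                          cfg = run_config(), lineages_path = NULL,
                          taxonomy_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tax <- if (!is.null(taxonomy_path))
    read.delim(taxonomy_path, stringsAsFactors = FALSE)
  res <- if (inherits(assignments_path, "egg_assignments")) assignments_path
  else read_assignments(assignments_path, tax)
  md <- if (is.data.frame(metadata_path)) metadata_path
  else read_metadata(metadata_path, cfg$months)
  part <- NULL
  if (!is.null(lineages_path)) {
    ldf <- read.delim(lineages_path, stringsAsFactors = FALSE)
    part <- structure(list(labels = ldf$id,
                           membership = setNames(ldf$lineage, ldf$id),
                           clusters = split(ldf$id, ldf$lineage),
                           threshold = cfg$lineage_cluster_threshold),
                      class = "lineage_partition")
  }
  occ <- occurrence_matrix(res, md, months = cfg$months, lineages = part,
                           eggs_only = cfg$eggs_only)
  write_occurrence(occ, file.path(outdir, "occurrence.tsv"))
  write.table(spawning_periods(occ),
              file.path(outdir, "spawning_periods.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rich <- monthly_richness(occ)
  jsonlite::write_json(list(monthly_richness = as.list(rich),
                            n_taxa = length(occ$taxa),
                            n_species_level = sum(occ$level == "species")),
                       file.path(outdir, "phenology_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("phenology", "%d taxa over %d months; richness %s",
            length(occ$taxa), length(occ$months),
            paste(rich, collapse = "/"))
  invisible(occ)
}

#' Run the whole pipeline on a simulated survey
#'
#' simulate -> assign -> tree -> phenology, each stage reading only the
#' previous stage's files under `outdir`.
#'
#' @param outdir output directory.
#' @param params a [simulation_params()].
#' @param cfg a [run_config()].
#' @return list with the stage results, invisibly.
#' @export
run_all <- function(outdir, params = simulation_params(),
                    cfg = run_config()) {
  paths <- run_simulate(outdir, params)
  res <- run_assign(paths[["queries"]], paths[["reference"]],
                    paths[["taxonomy"]], outdir,
                    metadata_path = paths[["metadata"]], cfg = cfg)
  tree <- tryCatch(run_tree(paths[["queries"]], outdir, cfg),
                   error = function(e) {
                     message("[tree] skipped: ", conditionMessage(e))
                     NULL
                   })
  occ <- run_phenology(file.path(outdir, "assignments.tsv"),
                       paths[["metadata"]], outdir, cfg,
                       lineages_path = if (!is.null(tree))
                         file.path(outdir, "lineages.tsv"),
                       taxonomy_path = paths[["taxonomy"]])
  invisible(list(assignments = res, tree = tree, occurrence = occ))
}
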