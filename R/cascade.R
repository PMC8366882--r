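## Hierarchical assignment cascade.
##
## Primary rules (curated-database stage), in strict order:
##   P1  best species identity > threshold AND second-best species
##       identity < threshold (or absent)            -> species of best hit
##   P1g best AND second-best species both > threshold, same genus -> genus
##   P2  all of the top-100 hits one species AND best > threshold -> species
## Fallback rules (general-database stage):
##   F1  top-5 hits one species AND best > threshold -> species
##   F2  best identity > genus floor -> majority genus of top 5
##       (tie -> unidentified)
##   F3  otherwise unidentified
## All threshold comparisons are strict: identity exactly at a threshold
## falls through to the next rule.

new_assignment <- function(query_id, level, taxon, rule_id, hits,
                           n_support) {
  fam <- gen <- NA_character_
  if (level != "unidentified") {
    row <- match(TRUE, if (level == "species") hits$hits$species == taxon
                 else hits$hits$genus == taxon)
    fam <- hits$hits$family[row]
    gen <- hits$hits$genus[row]
  }
  if (level == "genus") gen <- taxon
  list(query_id = query_id, level = level,
       taxon = if (level == "unidentified") "" else taxon,
       family = fam, genus = gen, rule_id = rule_id,
       best_identity = hits$best_species_identity,
       second_best_identity = hits$second_best_species_identity,
       n_supporting_hits = as.integer(n_support),
       strand = hits$strand %||% "+")
}

#' Primary assignment rules (best/second-best and top-hit consensus)
#'
#' Applies the curated-database stage of the cascade to a ranked hit list:
#' an unambiguous species call when the best species exceeds the identity
#' threshold and the runner-up species does not; a genus call when both
#' exceed it within one genus; a species call when all of the top
#' `top_n_primary` hits agree on one species (still requiring the best hit
#' to clear the threshold). Anything else is unresolved.
#'
#' @param hits a `hit_list` from [search_library()].
#' @param cfg a [run_config()].
#' @return an assignment (list) or `NULL` when unresolved.
#' @export
assign_primary <- function(hits, cfg = run_config()) {
  stopifnot(inherits(hits, "hit_list"), nrow(hits$hits) >= 1L)
  thr <- cfg$species_identity_threshold
  h <- hits$hits
  best <- hits$best_species_identity
  second <- hits$second_best_species_identity
  if (best > thr && (is.na(second) || second < thr)) {
    sp <- h$species[1L]
    return(new_assignment(hits$query_id, "species", sp, "P1_best_second",
                          hits, sum(h$species == sp & h$identity > thr)))
  }
  if (best > thr && !is.na(second) && second > thr) {
    g2 <- h$genus[h$species != h$species[1L]][which.max(
      h$identity[h$species != h$species[1L]])]
    if (identical(h$genus[1L], g2))
      return(new_assignment(hits$query_id, "genus", h$genus[1L],
                            "P1_best_second",
                            hits, sum(h$genus == g2 & h$identity > thr)))
  }
  k <- min(cfg$top_n_primary, nrow(h))
  topk <- h$species[seq_len(k)]
  if (length(unique(topk)) == 1L && best > thr)
    return(new_assignment(hits$query_id, "species", topk[1L], "P2_top100",
                          hits, k))
  NULL
}

#' Fallback assignment rules (top-five consensus, genus floor)
#'
#' The general-database stage: a species call when the top
#' `top_n_fallback` hits agree on one species and the best identity clears
#' the species threshold; else a genus call (majority genus of the top
#' five, ties unresolved to unidentified) when the best identity clears
#' the genus floor; else unidentified.
#'
#' @inheritParams assign_primary
#' @return an assignment (list); never `NULL`.
#' @export
assign_fallback <- function(hits, cfg = run_config()) {
  stopifnot(inherits(hits, "hit_list"), nrow(hits$hits) >= 1L)
  h <- hits$hits
  best <- hits$best_species_identity
  k <- min(cfg$top_n_fallback, nrow(h))
  topk <- h[seq_len(k), , drop = FALSE]
  if (length(unique(topk$species)) == 1L &&
      best > cfg$species_identity_threshold)
    return(new_assignment(hits$query_id, "species", topk$species[1L],
                          "F1_top5_species", hits, k))
  if (best > cfg$genus_identity_floor) {
    tab <- sort(table(topk$genus), decreasing = TRUE)
    if (length(tab) == 1L || tab[1L] > tab[2L])
      return(new_assignment(hits$query_id, "genus", names(tab)[1L],
                            "F2_genus_floor", hits, unname(tab[1L])))
    return(new_assignment(hits$query_id, "unidentified", "", "F2_genus_floor",
                          hits, 0L))
  }
  new_assignment(hits$query_id, "unidentified", "", "F3_below_floor", hits, 0L)
}

run_cascade <- function(hits, cfg) {
  assign_primary(hits, cfg) %||% assign_fallback(hits, cfg)
}

## Drop every hit of the given species from a hit_list and recompute the
## best/second-best species identities.
drop_species_hits <- function(hits, species, top_n) {
  keep <- !(hits$hits$species %in% species)
  if (!any(keep)) return(NULL)
  h <- hits$hits[keep, , drop = FALSE]
  best_species <- h$species[1L]
  other <- h$identity[h$species != best_species]
  h <- utils::head(h, top_n)
  h$rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  structure(list(query_id = hits$query_id, hits = h,
                 best_species_identity = h$identity[1L],
                 second_best_species_identity =
                   if (length(other)) max(other) else NA_real_,
                 strand = hits$strand),
            class = "hit_list")
}

#' Assign one query barcode
#'
#' Runs the library search and the full decision cascade (primary rules,
#' then fallback rules). When an excluded species (e.g. one ruled out on
#' recent-survey evidence) either wins the verdict or blocks a species
#' call, its hits are removed and the cascade is re-run once; such results
#' carry the rule id `X_excluded_override` and record the underlying rule
#' in `override_rule`.
#'
#' @param query nucleotide string; `query_id` defaults to its name.
#' @param library a `reference_library`.
#' @param cfg a [run_config()]; `cfg$exclusion_taxa` drives the override.
#' @param query_id id recorded in the result.
#' @return an assignment: list with `query_id`, `level` (`species`,
#'   `genus` or `unidentified`), `taxon`, `family`, `genus`, `rule_id`,
#'   identities and supporting-hit count.
#' @export
assign_barcode <- function(query, library, cfg = run_config(),
                   query_id = names(query) %||% "query") {
  top_n <- max(cfg$top_n_primary, cfg$top_n_fallback)
  hits <- search_library(query, library, top_n = top_n, cfg = cfg,
                         query_id = query_id)
  res <- run_cascade(hits, cfg)
  excl <- cfg$exclusion_taxa
  if (length(excl)) {
    triggered <- (res$level == "species" && res$taxon %in% excl) ||
      (res$level != "species" && any(hits$hits$species %in% excl))
    if (triggered) {
      pruned <- drop_species_hits(hits, excl, top_n)
      if (!is.null(pruned)) {
        res2 <- run_cascade(pruned, cfg)
        res2$override_rule <- res2$rule_id
        res2$rule_id <- "X_excluded_override"
        return(res2)
      }
    }
  }
  res
}

#' Assign a batch of query barcodes
#'
#' Order-preserving batch assignment with summary counts per verdict level
#' and specimen type.
#'
#' @param queries named character vector of query sequences.
#' @param library a `reference_library`.
#' @param cfg a [run_config()].
#' @param metadata optional specimen metadata (from [read_metadata()] or
#'   [simulate_survey()]); supplies `specimen_type` and `month`.
#' @return an object of class `egg_assignments`: list with `results`
#'   (one data.frame row per query) and `summary` (counts of species /
#'   genus / unidentified verdicts, overall and per specimen type).
#' @export
assign_batch <- function(queries, library, cfg = run_config(),
                         metadata = NULL) {
  if (length(queries) == 0L) {
    res <- data.frame(id = character(), level = character(),
                      taxon = character(), family = character(),
                      genus = character(), rule_id = character(),
                      best_identity = numeric(),
                      second_best_identity = numeric(),
                      n_supporting_hits = integer(),
                      specimen_type = character(), month = character(),
                      stringsAsFactors = FALSE)
    return(new_egg_assignments(res))
  }
  stopifnot(!is.null(names(queries)), all(nzchar(names(queries))))
  rows <- lapply(names(queries), function(id)
    assign_barcode(queries[[id]], library, cfg, query_id = id))
  res <- data.frame(id = vapply(rows, `[[`, "", "query_id"),
                    level = vapply(rows, `[[`, "", "level"),
                    taxon = vapply(rows, `[[`, "", "taxon"),
                    family = vapply(rows, `[[`, "", "family"),
                    genus = vapply(rows, `[[`, "", "genus"),
                    rule_id = vapply(rows, `[[`, "", "rule_id"),
                    best_identity = vapply(rows, `[[`, 0, "best_identity"),
                    second_best_identity =
                      vapply(rows, `[[`, 0, "second_best_identity"),
                    n_supporting_hits =
                      vapply(rows, `[[`, 0L, "n_supporting_hits"),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    m <- match(res$id, metadata$id)
    res$specimen_type <- metadata$specimen_type[m]
    res$month <- metadata$month[m]
  } else {
    res$specimen_type <- NA_character_
    res$month <- NA_character_
  }
  new_egg_assignments(res)
}

new_egg_assignments <- function(res) {
  lev <- factor(res$level, levels = c("species", "genus", "unidentified"))
  by_type <- table(type = res$specimen_type, level = lev, useNA = "no")
  structure(list(results = res,
                 summary = list(n = nrow(res),
                                n_species = sum(res$level == "species"),
                                n_genus = sum(res$level == "genus"),
                                n_unidentified =
                                  sum(res$level == "unidentified"),
                                by_type = by_type)),
            class = "egg_assignments")
}

#' @export
print.egg_assignments <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Barcode assignments: %d queries (%d species-level, %d genus-level, %d unidentified)\n",
              s$n, s$n_species, s$n_genus, s$n_unidentified))
  invisible(x)
}

#' @export
summary.egg_assignments <- function(object, ...) {
  s <- object$summary
  print(object)
  if (nrow(s$by_type)) {
    cat("By specimen type:\n")
    print(s$by_type)
  }
  sp <- object$results$taxon[object$results$level == "species"]
  if (length(sp)) {
    cat("Species-level taxa:\n")
    print(sort(table(sp), decreasing = TRUE))
  }
  invisible(s)
}
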