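## Taxon label for one assignment row group. Genus-level verdicts of one
## genus are split into numbered "<Genus> spp<k>" lineages when a lineage
## partition separates them, else pooled as "<Genus> spp"; unidentified
## queries become "Unknown species <k>" per lineage (one pooled group
## when no partition is supplied).
phenology_labels <- function(results, lineages = NULL) {
  lab <- results$taxon
  fam <- results$family
  member <- function(ids) {
    if (is.null(lineages)) rep(1L, length(ids))
    else {
      m <- lineages$membership[ids]
      match(m, unique(m[!is.na(m)]))
    }
  }
  gen_rows <- which(results$level == "genus")
  for (g in unique(results$genus[gen_rows])) {
    rows <- gen_rows[results$genus[gen_rows] == g]
    k <- member(results$id[rows])
    lab[rows] <- if (length(unique(k[!is.na(k)])) > 1L)
      paste0(g, " spp", k) else paste0(g, " spp")
  }
  unk_rows <- which(results$level == "unidentified")
  if (length(unk_rows)) {
    k <- member(results$id[unk_rows])
    k[is.na(k)] <- max(c(k[!is.na(k)], 0L)) + seq_len(sum(is.na(k)))
    lab[unk_rows] <- paste("Unknown species", k)
    fam[unk_rows] <- ""
  }
  list(taxon = lab, family = ifelse(is.na(fam), "", fam))
}

new_occurrence_matrix <- function(taxa, family, level, months, counts) {
  stopifnot(nrow(counts) == length(taxa), ncol(counts) == length(months))
  dimnames(counts) <- list(taxa, months)
  structure(list(taxa = taxa, family = family, level = level,
                 months = months, counts = counts, present = counts >= 1L),
            class = "occurrence_matrix")
}

#' Taxon-by-month occurrence matrix
#'
#' Converts dated assignments into the presence/absence community table:
#' one row per taxon (species binomials; genus-level lineages as
#' `"Genus spp"`, numbered when a lineage partition separates them;
#' unidentified lineages as `"Unknown species k"`), one column per month,
#' a cell being present when at least one assigned specimen fell in that
#' month.
#'
#' @param results an `egg_assignments` object, or its `results` data.frame
#'   with `month` filled in.
#' @param metadata optional metadata to (re)attach months by specimen id.
#' @param months ordered month axis (default May-September).
#' @param lineages optional `lineage_partition` over query ids, used to
#'   split genus-level and unidentified queries into numbered lineages.
#' @param eggs_only drop larvae before tabulating.
#' @return an object of class `occurrence_matrix`: list with `taxa`,
#'   `family`, `level`, `months`, `counts` (integer matrix) and `present`
#'   (logical matrix).
#' @export
occurrence_matrix <- function(results, metadata = NULL,
                              months = MONTHS_DEFAULT, lineages = NULL,
                              eggs_only = FALSE) {
  df <- if (inherits(results, "egg_assignments")) results$results else results
  if (!is.null(metadata)) {
    m <- match(df$id, metadata$id)
    df$month <- metadata$month[m]
    df$specimen_type <- metadata$specimen_type[m]
  }
  if (eggs_only) df <- df[df$specimen_type %in% "egg", , drop = FALSE]
  nomonth <- is.na(df$month) | !(df$month %in% months)
  if (any(nomonth)) {
    warning(sum(nomonth), " specimen(s) without a usable month dropped ",
            "from the occurrence matrix")
    df <- df[!nomonth, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    return(new_occurrence_matrix(character(0), character(0), character(0),
                                 months,
                                 matrix(0L, 0L, length(months))))
  pl <- phenology_labels(df, lineages)
  df$taxon_label <- pl$taxon
  first <- !duplicated(df$taxon_label)
  taxa <- df$taxon_label[first]
  counts <- table(factor(df$taxon_label, levels = taxa),
                  factor(df$month, levels = months))
  counts <- matrix(as.integer(counts), nrow = length(taxa))
  new_occurrence_matrix(taxa, pl$family[first],
                        ifelse(df$level[first] == "unidentified", "unknown",
                               df$level[first]),
                        months, counts)
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("Occurrence matrix: %d taxa x %d months\n",
              length(x$taxa), length(x$months)))
  if (length(x$taxa)) {
    disp <- ifelse(x$present, "+", "")
    df <- data.frame(Family = x$family, Taxon = x$taxa, disp,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- x$months
    df <- rbind(df, c("", "Total", as.character(monthly_richness(x))))
    print(df, row.names = FALSE, right = FALSE)
  }
  invisible(x)
}

#' Monthly taxon richness
#'
#' Number of taxa present per month. All taxon rows count — species-level,
#' genus-level lineages and unknown lineages alike — matching the total
#' row of the community table; the species-only statistic is available via
#' `taxa_table()`.
#'
#' @param m an `occurrence_matrix`.
#' @return named integer vector, one element per month.
#' @export
monthly_richness <- function(m) {
  stopifnot(inherits(m, "occurrence_matrix"))
  if (length(m$taxa) == 0L)
    return(setNames(integer(length(m$months)), m$months))
  setNames(as.integer(colSums(m$present)), m$months)
}

#' Spawning periods per taxon
#'
#' Months of occurrence, the first and last month, and whether the period
#' is continuous (no gap months between first and last occurrence) under
#' the configured month ordering.
#'
#' @param m an `occurrence_matrix`.
#' @return data.frame with one row per taxon occurring in at least one
#'   month: `taxon`, `level`, `n_months`, `first`, `last`, `continuous`,
#'   `months_present` (comma-separated).
#' @export
spawning_periods <- function(m) {
  stopifnot(inherits(m, "occurrence_matrix"))
  rows <- which(rowSums(m$present) > 0L)
  out <- lapply(rows, function(i) {
    idx <- which(m$present[i, ])
    data.frame(taxon = m$taxa[i], level = m$level[i],
               n_months = length(idx),
               first = m$months[min(idx)], last = m$months[max(idx)],
               continuous = all(seq(min(idx), max(idx)) %in% idx),
               months_present = paste(m$months[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||%
    data.frame(taxon = character(), level = character(),
               n_months = integer(), first = character(),
               last = character(), continuous = logical(),
               months_present = character())
}

#' Taxon table of an occurrence matrix
#'
#' @param m an `occurrence_matrix`.
#' @return data.frame with columns `taxon`, `family`, `level`.
#' @export
taxa_table <- function(m) {
  stopifnot(inherits(m, "occurrence_matrix"))
  data.frame(taxon = m$taxa, family = m$family, level = m$level,
             stringsAsFactors = FALSE)
}

#' Survey composition and success/failure accounting
#'
#' Sequencing-success bookkeeping (selected vs high-quality specimens,
#' failure rate), the egg species-assignment rate, and the family
#' composition of the species-level taxa (genus-level and unknown
#' lineages are excluded from family proportions).
#'
#' @param taxa data.frame with columns `taxon`, `family`, `level` (from
#'   [taxa_table()] or the packaged community fixture).
#' @param counts list with elements `n_selected_eggs`, `n_hq_eggs`,
#'   `n_hq_larvae` and optionally `n_species_assigned_eggs`.
#' @return an object of class `composition_summary`: list with the input
#'   counts plus `n_failed`, `failure_rate`, `n_aligned`,
#'   `egg_assignment_rate` (NA when species-assigned egg counts are
#'   unknown), `n_species_level_taxa`, `family_counts` and
#'   `family_proportions`.
#' @export
composition_summary <- function(taxa, counts) {
  need <- c("n_selected_eggs", "n_hq_eggs", "n_hq_larvae")
  stopifnot(all(need %in% names(counts)))
  sel <- counts$n_selected_eggs; hq <- counts$n_hq_eggs
  if (sel < 1L) stop("no eggs selected: counts inconsistent")
  if (hq > sel) stop("high-quality eggs exceed selected eggs")
  sp <- taxa[taxa$level == "species", , drop = FALSE]
  if (nrow(sp) && any(!nzchar(sp$family)))
    stop("family unknown for species-level taxa: ",
         paste(sp$taxon[!nzchar(sp$family)], collapse = ", "))
  fam <- sort(table(sp$family), decreasing = TRUE)
  assigned <- counts$n_species_assigned_eggs %||% NA_integer_
  structure(list(n_selected_eggs = sel, n_hq_eggs = hq,
                 n_hq_larvae = counts$n_hq_larvae,
                 n_failed = sel - hq,
                 failure_rate = (sel - hq) / sel,
                 n_aligned = hq + counts$n_hq_larvae,
                 n_species_assigned_eggs = assigned,
                 egg_assignment_rate = assigned / hq,
                 n_species_level_taxa = nrow(sp),
                 family_counts = fam,
                 family_proportions = fam / max(nrow(sp), 1L)),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("Selected eggs %d; high quality %d eggs + %d larvae; failed %d (%.1f%%)\n",
              x$n_selected_eggs, x$n_hq_eggs, x$n_hq_larvae, x$n_failed,
              100 * x$failure_rate))
  if (!is.na(x$n_species_assigned_eggs))
    cat(sprintf("Eggs assigned to species: %d (%.1f%%)\n",
                x$n_species_assigned_eggs, 100 * x$egg_assignment_rate))
  cat(sprintf("Species-level taxa: %d\n", x$n_species_level_taxa))
  if (length(x$family_counts)) {
    cat("Family composition:\n")
    for (f in names(x$family_counts))
      cat(sprintf("  %-18s %2d (%.1f%%)\n", f, x$family_counts[[f]],
                  100 * x$family_proportions[[f]]))
  }
  invisible(x)
}

#' Write an occurrence matrix as a community-table TSV
#'
#' Mirrors the familiar community-table layout: family, taxon, one column
#' per month with `+` for presence, and a final Total row of monthly
#' richness.
#'
#' @param m an `occurrence_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(m, path) {
  stopifnot(inherits(m, "occurrence_matrix"))
  disp <- matrix(ifelse(m$present, "+", ""), nrow = length(m$taxa))
  df <- data.frame(family = m$family, taxon = m$taxa, disp,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("family", "taxon", m$months)
  df <- rbind(df, c("", "Total", as.character(monthly_richness(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence matrix from a community-table TSV
#'
#' Inverse of [write_occurrence()]; also understands an optional `level`
#' column (species / genus / unknown). Rows named `Total` are ignored.
#'
#' @param path TSV path.
#' @param months month columns expected in the file.
#' @return an `occurrence_matrix` (presence only: counts are 0/1).
#' @export
read_occurrence <- function(path, months = MONTHS_DEFAULT) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  stopifnot(all(c("family", "taxon") %in% names(df)),
            all(months %in% names(df)))
  df <- df[df$taxon != "Total", , drop = FALSE]
  counts <- matrix(as.integer(as.matrix(df[, months, drop = FALSE]) == "+"),
                   nrow = nrow(df))
  level <- if ("level" %in% names(df)) df$level else
    ifelse(grepl("^Unknown species", df$taxon), "unknown",
           ifelse(grepl(" spp\\d*$", df$taxon), "genus", "species"))
  new_occurrence_matrix(df$taxon, df$family, level, months, counts)
}
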