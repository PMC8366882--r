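#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased, alignment gap characters (`-`) are stripped
#' (any alignment used downstream is recomputed internally), and the id is
#' the first whitespace-delimited token of each header. Record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    if (all(!nzchar(trimws(raw)))) return(setNames(character(0), character(0)))
    stop("not FASTA (no '>' header): ", path)
  }
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty id")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- gsub("-", "", toupper(as.character(set)), fixed = TRUE)
  if (any(!nzchar(seqs)))
    stop("empty sequence for FASTA record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' Deterministic writer: 80-column line wrap, records in input order, so
#' identical inputs give byte-identical files.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Read a reference barcode library
#'
#' Couples reference sequences with a three-rank taxonomy (family, genus,
#' species). Genus-level placeholders such as `"Rhinogobius spp"` are
#' accepted in the species column. Every FASTA id must have a taxonomy row.
#'
#' @param fasta_path FASTA of reference sequences.
#' @param taxonomy_path tab-separated table with columns
#'   `id`, `family`, `genus`, `species`.
#' @return an object of class `reference_library`: a list with elements
#'   `sequences` (named character) and `taxonomy` (data.frame), plus an
#'   `index` mapping each species, genus and family to its record ids.
#' @export
read_reference_library <- function(fasta_path, taxonomy_path) {
  seqs <- read_fasta(fasta_path)
  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("id", "family", "genus", "species")
  if (!all(need %in% names(tax)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tax$id))
    stop("duplicate ids in taxonomy table: ",
         paste(unique(tax$id[duplicated(tax$id)]), collapse = ", "))
  missing <- setdiff(names(seqs), tax$id)
  if (length(missing))
    stop("FASTA ids missing from taxonomy table: ",
         paste(missing, collapse = ", "))
  tax <- tax[match(names(seqs), tax$id), , drop = FALSE]
  rownames(tax) <- NULL
  reference_library(seqs, tax)
}

#' Construct a reference library from in-memory pieces
#'
#' @param sequences named character vector of reference sequences.
#' @param taxonomy data.frame with columns `id`, `family`, `genus`,
#'   `species`, one row per sequence.
#' @return a `reference_library` object.
#' @export
reference_library <- function(sequences, taxonomy) {
  stopifnot(length(sequences) >= 1L, all(names(sequences) == taxonomy$id))
  blank <- !nzchar(taxonomy$family) | !nzchar(taxonomy$genus) |
    !nzchar(taxonomy$species)
  if (any(blank))
    stop("empty taxonomy rank(s) for: ",
         paste(taxonomy$id[blank], collapse = ", "))
  binom <- grepl("^\\S+\\s+\\S+", taxonomy$species) &
    !grepl("\\bspp?\\d*$", taxonomy$species)
  epithet_ok <- !binom | sub("\\s.*$", "", taxonomy$species) == taxonomy$genus
  if (any(!epithet_ok))
    stop("species binomial does not match genus for: ",
         paste(taxonomy$id[!epithet_ok], collapse = ", "))
  idx <- list(species = split(taxonomy$id, taxonomy$species),
              genus = split(taxonomy$id, taxonomy$genus),
              family = split(taxonomy$id, taxonomy$family))
  structure(list(sequences = toupper(sequences), taxonomy = taxonomy,
                 index = idx),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("Reference library: %d sequences, %d species, %d genera, %d families\n",
              length(x$sequences), length(x$index$species),
              length(x$index$genus), length(x$index$family)))
  invisible(x)
}

#' Read specimen metadata
#'
#' Tab-separated table with columns `id`, `specimen_type` (`egg` or
#' `larva`) and either `month` (name or abbreviation) or `date`
#' (`YYYY-MM-DD`); an optional `time_slot` column is carried through.
#' Months outside the configured sampling season are kept but flagged in
#' the `in_season` column with a warning.
#'
#' @param path metadata file path.
#' @param months month axis defining the sampling season.
#' @return data.frame with columns `id`, `specimen_type`, `month`,
#'   `time_slot`, `in_season`.
#' @export
read_metadata <- function(path, months = MONTHS_DEFAULT) {
  md <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "specimen_type") %in% names(md)))
    stop("metadata must have columns id and specimen_type")
  if (!("month" %in% names(md)) && !("date" %in% names(md)))
    stop("metadata must have a month or date column")
  raw <- if ("month" %in% names(md)) md$month else md$date
  month <- normalize_month(raw)
  if (anyNA(month))
    stop("unparseable month/date in metadata row(s): ",
         paste(which(is.na(month)), collapse = ", "))
  type <- tolower(trimws(md$specimen_type))
  if (!all(type %in% c("egg", "larva")))
    stop("specimen_type must be 'egg' or 'larva' (rows ",
         paste(which(!type %in% c("egg", "larva")), collapse = ", "), ")")
  in_season <- month %in% months
  if (!all(in_season))
    warning(sum(!in_season), " specimen(s) dated outside the configured season")
  data.frame(id = md$id, specimen_type = type, month = month,
             time_slot = if ("time_slot" %in% names(md)) md$time_slot
                         else NA_character_,
             in_season = in_season, stringsAsFactors = FALSE)
}

#' Write an assignment report
#'
#' One tab-separated row per query, in input order: id, level, taxon,
#' rule id, best-hit identity, second-best-species identity and the number
#' of supporting hits. Identities are fixed to six decimals so reruns on
#' identical inputs are byte-identical.
#'
#' @param results an `egg_assignments` object or its `results` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(results, path) {
  df <- if (inherits(results, "egg_assignments")) results$results else results
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  out <- data.frame(id = df$id, level = df$level,
                    taxon = ifelse(is.na(df$taxon), "", df$taxon),
                    rule_id = df$rule_id,
                    best_identity = fmt(df$best_identity),
                    second_best_identity = fmt(df$second_best_identity),
                    n_supporting_hits = df$n_supporting_hits,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write a tree to Newick
#'
#' Branch lengths are kept; integer bootstrap supports, when present as
#' node labels, are written as internal-node labels so the file round-trips
#' through standard Newick parsers.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param dm square numeric matrix with dimnames (e.g. from [k2p_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  df <- data.frame(id = rownames(dm), format(dm, digits = 8, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(dm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a lineage partition as TSV
#'
#' @param part a `lineage_partition` from [cluster_lineages()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(part, path) {
  stopifnot(inherits(part, "lineage_partition"))
  df <- data.frame(id = part$labels, lineage = part$membership,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
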