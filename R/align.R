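#' Semi-global pairwise alignment of two barcodes
#'
#' Exhaustive dynamic-programming alignment with affine gap costs and free
#' end gaps (overlap alignment), the appropriate model for two
#' variable-length fragments of one locus. Columns where either row
#' carries a gap or an IUPAC ambiguity code are excluded from the
#' comparison counts.
#'
#' @param a,b nonempty nucleotide strings (uppercased internally).
#' @param match,mismatch per-column scores for identical / differing
#'   characters (defaults +1 / -1).
#' @param gap_open,gap_extend affine gap penalties; a gap run of length L
#'   costs `gap_open + L * gap_extend` (defaults 5 and 2).
#' @param free_end_a,free_end_b whether terminal gap columns in `a`'s /
#'   `b`'s row are free (both `TRUE` by default).
#' @return an object of class `pairwise_alignment` with elements
#'   `aligned_a`, `aligned_b` (equal-length gapped strings), `score`,
#'   `n_columns`, `n_compared`, `n_matches`, `n_transitions`,
#'   `n_transversions`.
#' @seealso [percent_identity()], [k2p_distance()]
#' @export
#' @examples
#' aln <- align_pair("ACGT", "ACTT")
#' percent_identity(aln)
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = 5, gap_extend = 2,
                       free_end_a = TRUE, free_end_b = TRUE) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  raw <- .align_pair_cpp(a, b, match, mismatch, gap_open, gap_extend,
                         free_end_a, free_end_b)
  counts <- .count_columns_cpp(raw$aligned_a, raw$aligned_b)
  structure(c(raw, as.list(counts)), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment: %d columns, %d compared, %d matches (score %g)\n",
              x$n_columns, x$n_compared, x$n_matches, x$score))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Matches over compared columns; gap columns and columns with an IUPAC
#' ambiguity code in either row are excluded from the denominator, so the
#' usual 99%/95% thresholds do not depend on fragment overhangs.
#'
#' @param aln a `pairwise_alignment` from [align_pair()].
#' @return fraction in \[0, 1\].
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$n_compared < 1L)
    stop_fisheggs("identity undefined: no comparable columns",
                  "fisheggs_undefined_identity")
  aln$n_matches / aln$n_compared
}

## closed-form K2P from transition/transversion proportions; NA outside
## the domain (saturation). Vectorised.
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d <- rep(NA_real_, length(w1))
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  d
}

#' Kimura two-parameter distance of an alignment
#'
#' With `P` and `Q` the transition and transversion proportions over
#' compared columns, the distance is
#' `d = -(1/2) * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions per site.
#' Pairs outside the model's domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`)
#' are saturated and raise an error of class `fisheggs_saturated`.
#'
#' @param aln a `pairwise_alignment` from [align_pair()].
#' @return nonnegative numeric distance.
#' @export
#' @examples
#' k2p_distance(align_pair("ACGTACGTAC", "ACGTACGTAC"))  # 0
k2p_distance <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$n_compared < 1L)
    stop_fisheggs("K2P distance undefined: no comparable columns",
                  "fisheggs_undefined_identity")
  P <- aln$n_transitions / aln$n_compared
  Q <- aln$n_transversions / aln$n_compared
  d <- k2p_from_pq(P, Q)
  if (is.na(d))
    stop_fisheggs(sprintf("saturated distance (P = %.3f, Q = %.3f)", P, Q),
                  "fisheggs_saturated")
  d
}

## identity of one query (as given) against every library record.
## Ends-free alignment can return a short spurious perfect overlap between
## unrelated sequences (a dozen matching bases score better than a
## full-length 25%-identity alignment), so alignments whose comparable
## overlap falls below the configured floor are scored as non-matches
## (identity 0); the floor adapts to short sequences.
library_identities <- function(query, library, cfg) {
  vapply(library$sequences, function(ref) {
    aln <- align_pair(query, ref, match = cfg$match, mismatch = cfg$mismatch,
                      gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    floor_pair <- min(cfg$min_overlap, nchar(query), nchar(ref))
    if (aln$n_compared < max(floor_pair, 1L)) 0
    else aln$n_matches / aln$n_compared
  }, numeric(1))
}

#' Orient a query to the reference library's strand
#'
#' Evaluates the query and its reverse complement exhaustively against the
#' whole library and keeps whichever strand attains the higher best-hit
#' identity; ties keep the forward strand.
#'
#' @param query nucleotide string.
#' @param library a `reference_library`.
#' @param cfg a [run_config()] (alignment scoring).
#' @return the oriented sequence, with attribute `strand` (`"+"` or `"-"`).
#' @export
orient_query <- function(query, library, cfg = run_config()) {
  stopifnot(inherits(library, "reference_library"))
  query <- toupper(as.character(query))
  fwd <- max(library_identities(query, library, cfg))
  rc <- reverse_complement(query)
  rev <- max(library_identities(rc, library, cfg))
  if (rev > fwd) structure(rc, strand = "-") else structure(query, strand = "+")
}

#' Rank a query against the reference library
#'
#' The implemented stand-in for an online barcode-database search:
#' exhaustive percent-identity ranking of the (oriented) query against
#' every reference. Best and second-best *species* identities follow the
#' interspecific-match convention: the runner-up is the best hit among
#' species other than the top species.
#'
#' @param query nucleotide string (or single named element of a FASTA
#'   vector).
#' @param library a `reference_library`.
#' @param top_n number of hits to keep (default from `cfg`).
#' @param cfg a [run_config()].
#' @param orient orient the query to the library strand first
#'   (default `TRUE`).
#' @param query_id id recorded in the result.
#' @return an object of class `hit_list`: list with `query_id`, `hits`
#'   (data.frame: `reference_id`, `family`, `genus`, `species`,
#'   `identity`, `rank`), `best_species_identity`,
#'   `second_best_species_identity` (NA when the library holds a single
#'   species) and `strand`.
#' @export
search_library <- function(query, library, top_n = cfg$top_n_primary,
                           cfg = run_config(), orient = TRUE,
                           query_id = names(query) %||% "query") {
  stopifnot(inherits(library, "reference_library"))
  if (length(library$sequences) < 1L) stop("empty reference library")
  top_n <- as.integer(top_n)
  if (top_n < 1L) stop("top_n must be >= 1")
  strand <- "+"
  seq <- toupper(as.character(query))
  if (orient) {
    seq <- orient_query(seq, library, cfg)
    strand <- attr(seq, "strand")
  }
  ident <- library_identities(seq, library, cfg)
  tax <- library$taxonomy
  ord <- order(-ident, tax$id, method = "radix")
  hits_all <- data.frame(reference_id = tax$id[ord],
                         family = tax$family[ord], genus = tax$genus[ord],
                         species = tax$species[ord],
                         identity = unname(ident[ord]),
                         stringsAsFactors = FALSE)
  best_species <- hits_all$species[1L]
  best_id <- hits_all$identity[1L]
  other <- hits_all$identity[hits_all$species != best_species]
  second_id <- if (length(other)) max(other) else NA_real_
  hits <- utils::head(hits_all, top_n)
  hits$rank <- seq_len(nrow(hits))
  structure(list(query_id = query_id, hits = hits,
                 best_species_identity = best_id,
                 second_best_species_identity = second_id,
                 strand = strand),
            class = "hit_list")
}

#' @export
print.hit_list <- function(x, n = 5L, ...) {
  cat(sprintf("Hits for %s (best %.4f, second-best species %s)\n",
              x$query_id, x$best_species_identity,
              ifelse(is.na(x$second_best_species_identity), "absent",
                     sprintf("%.4f", x$second_best_species_identity))))
  print(utils::head(x$hits, n))
  invisible(x)
}
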