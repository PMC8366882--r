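#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## sampling season of the field survey: the default month axis everywhere
MONTHS_DEFAULT <- c("May", "June", "July", "August", "September")

## Evaluate expr with a temporarily seeded RNG, restoring the caller's
## RNG state afterwards so library code never clobbers user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorised over a character vector; IUPAC ambiguity codes are mapped to
#' their complements and gap characters are preserved.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

## Normalise a month spelling or an ISO date to a calendar month name.
## Returns NA_character_ when the value cannot be interpreted.
normalize_month <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  lower <- tolower(x)
  full <- match(lower, tolower(month.name))
  out[!is.na(full)] <- month.name[full[!is.na(full)]]
  abb <- match(lower, tolower(month.abb))
  fill <- is.na(out) & !is.na(abb)
  out[fill] <- month.name[abb[fill]]
  todo <- is.na(out) & nzchar(x)
  if (any(todo)) {
    d <- suppressWarnings(as.Date(x[todo], format = "%Y-%m-%d"))
    mon <- as.POSIXlt(d)$mon + 1L
    out[todo][!is.na(d)] <- month.name[mon[!is.na(d)]]
  }
  out
}

stop_fisheggs <- function(msg, class, ...) {
  stop(structure(class = c(class, "fisheggs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
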