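#' Packaged drifting-egg community fixture
#'
#' The taxon-by-month occurrence table and specimen accounting of a
#' published May-September drifting-egg barcoding survey, shipped with
#' the package as plain-text data. The table holds 19 taxon rows (14
#' species-level binomials, genus-level lineages and unknown lineages)
#' over five months; the counts record the selected, high-quality and
#' species-assigned specimen numbers used by [composition_summary()].
#'
#' @return list with `occurrence` (an `occurrence_matrix`), `taxa` (its
#'   [taxa_table()]) and `counts` (named list of specimen counts).
#' @export
#' @examples
#' fx <- egg_community_fixture()
#' monthly_richness(fx$occurrence)
egg_community_fixture <- function() {
  tsv <- system.file("extdata", "egg_community_table.tsv",
                     package = "fisheggs", mustWork = TRUE)
  yml <- system.file("extdata", "egg_survey_counts.yaml",
                     package = "fisheggs", mustWork = TRUE)
  occ <- read_occurrence(tsv)
  list(occurrence = occ, taxa = taxa_table(occ),
       counts = yaml::read_yaml(yml))
}
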