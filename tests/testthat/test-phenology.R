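toy_results <- function() {
  data.frame(
    id = sprintf("e%02d", 1:10),
    level = c(rep("species", 6), "genus", "genus", "unidentified",
              "unidentified"),
    taxon = c(rep("Zacco platypus", 3), rep("Garra orientalis", 3),
              "Rhinogobius", "Rhinogobius", "", ""),
    family = c(rep("Cyprinidae", 6), "Gobiidae", "Gobiidae", NA, NA),
    genus = c(rep("Zacco", 3), rep("Garra", 3), "Rhinogobius",
              "Rhinogobius", NA, NA),
    rule_id = "P1_best_second",
    month = c("May", "May", "June", "June", "July", "August",
              "June", "July", "July", "July"),
    specimen_type = c(rep("egg", 8), "egg", "larva"),
    stringsAsFactors = FALSE)
}

test_that("occurrence matrix tabulates presence with supporting counts", {
  occ <- occurrence_matrix(toy_results())
  expect_s3_class(occ, "occurrence_matrix")
  expect_setequal(occ$taxa, c("Zacco platypus", "Garra orientalis",
                              "Rhinogobius spp", "Unknown species 1"))
  expect_equal(occ$counts["Zacco platypus", "May"], 2L)
  expect_equal(occ$counts["Zacco platypus", "June"], 1L)
  expect_true(all(occ$present == (occ$counts >= 1)))
  # one species, one month, three eggs -> one present cell with count 3
  solo <- toy_results()[c(1, 2, 2), ]
  solo$month <- "May"
  occ1 <- occurrence_matrix(solo)
  expect_equal(sum(occ1$present), 1)
  expect_equal(occ1$counts["Zacco platypus", "May"], 3L)
  # empty input -> all-absent matrix
  empty <- occurrence_matrix(toy_results()[0, ])
  expect_length(empty$taxa, 0)
  expect_equal(monthly_richness(empty),
               setNames(integer(5), empty$months))
})

test_that("monthly richness equals the presence column sums", {
  occ <- occurrence_matrix(toy_results())
  rich <- monthly_richness(occ)
  expect_identical(unname(rich), as.integer(colSums(occ$present)))
  expect_equal(rich[["July"]], 3L)  # Garra, Rhinogobius spp, Unknown sp 1
  expect_equal(rich[["September"]], 0L)
})

test_that("specimens without a usable month are dropped with a warning", {
  res <- toy_results()
  res$month[1] <- NA
  expect_warning(occ <- occurrence_matrix(res), "dropped")
  expect_equal(occ$counts["Zacco platypus", "May"], 1L)
})

test_that("eggs-only filtering and metadata joining work", {
  res <- toy_results()
  md <- data.frame(id = res$id, specimen_type = res$specimen_type,
                   month = res$month, stringsAsFactors = FALSE)
  res$month <- NULL; res$specimen_type <- NULL
  occ <- occurrence_matrix(res, metadata = md, eggs_only = TRUE)
  expect_false("Unknown species 1" %in% rownames(occ$counts) &&
                 occ$counts["Unknown species 1", "July"] > 1)
  expect_equal(sum(occ$counts), 9)  # the larva is gone
})

test_that("a lineage partition splits pooled genus and unknown rows", {
  res <- toy_results()
  part <- structure(list(labels = res$id,
                         membership = setNames(c(1:6, 7, 8, 9, 9), res$id),
                         clusters = split(res$id, c(1:6, 7, 8, 9, 9)),
                         threshold = 0.01),
                    class = "lineage_partition")
  occ <- occurrence_matrix(res, lineages = part)
  expect_true(all(c("Rhinogobius spp1", "Rhinogobius spp2") %in% occ$taxa))
  expect_equal(sum(grepl("^Unknown species", occ$taxa)), 1)
})

test_that("removing a taxon's records removes exactly its row", {
  res <- toy_results()
  full <- occurrence_matrix(res)
  drop <- occurrence_matrix(res[res$taxon != "Garra orientalis", ])
  expect_setequal(setdiff(full$taxa, drop$taxa), "Garra orientalis")
  shared <- intersect(full$taxa, drop$taxa)
  expect_equal(full$counts[shared, , drop = FALSE],
               drop$counts[shared, , drop = FALSE])
})

test_that("spawning periods record span and continuity", {
  occ <- occurrence_matrix(toy_results())
  sp <- spawning_periods(occ)
  z <- sp[sp$taxon == "Zacco platypus", ]
  expect_equal(z$n_months, 2)
  expect_identical(z$first, "May")
  expect_identical(z$last, "June")
  expect_true(z$continuous)
  g <- sp[sp$taxon == "Garra orientalis", ]
  expect_identical(c(g$first, g$last), c("June", "August"))
  expect_true(g$continuous)
})

test_that("composition summary does the success/failure arithmetic", {
  taxa <- data.frame(taxon = c("A a", "B b", "C c", "D spp"),
                     family = c("F1", "F1", "F2", "F1"),
                     level = c("species", "species", "species", "genus"),
                     stringsAsFactors = FALSE)
  cs <- composition_summary(taxa, list(n_selected_eggs = 100,
                                       n_hq_eggs = 60, n_hq_larvae = 5,
                                       n_species_assigned_eggs = 58))
  expect_equal(cs$n_failed, 40)
  expect_equal(cs$failure_rate, 0.4)
  expect_equal(cs$n_aligned, 65)
  expect_equal(cs$egg_assignment_rate, 58 / 60)
  # genus-level rows stay out of the family proportions
  expect_equal(cs$n_species_level_taxa, 3)
  expect_equal(sum(cs$family_proportions), 1)
  expect_equal(unname(cs$family_counts["F1"]), 2L)

  expect_error(composition_summary(taxa, list(n_selected_eggs = 0,
                                              n_hq_eggs = 0,
                                              n_hq_larvae = 0)),
               "inconsistent")
  expect_error(composition_summary(taxa, list(n_selected_eggs = 10,
                                              n_hq_eggs = 20,
                                              n_hq_larvae = 0)),
               "exceed")
})

test_that("occurrence tables round-trip through the TSV layout", {
  occ <- occurrence_matrix(toy_results())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occurrence(occ, f)
  lines <- readLines(f)
  expect_match(lines[length(lines)], "^\\tTotal\\t")
  back <- read_occurrence(f)
  expect_setequal(back$taxa, occ$taxa)
  expect_equal(back$present[occ$taxa, ], occ$present)
  expect_identical(back$level[match(occ$taxa, back$taxa)], occ$level)
})
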