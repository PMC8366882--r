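test_that("sequence evolution is distance-consistent under the K2P model", {
  set.seed(91)
  anc <- rand_seq(10000)
  expect_identical(evolve_sequence(anc, 0), anc)

  child <- evolve_sequence(anc, 0.05, kappa = 4)
  aln <- align_pair(anc, child)
  d_hat <- k2p_distance(aln)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(d_hat - 0.05), 3 * se)

  # transition:transversion counts reflect kappa (about kappa/2 at this
  # divergence; the exact expectation is 1.94 for d = 0.05, kappa = 4)
  ratio <- aln$n_transitions / aln$n_transversions
  expect_lt(abs(ratio - 1.94), 0.5)

  expect_warning(evolve_sequence(anc, 1.5), "saturation")
})

test_that("simulated reference libraries are reproducible with a real barcoding gap", {
  p <- simulation_params(n_species = 5, individuals_per_species = 3,
                         barcode_length = 400, seed = 92)
  ref <- simulate_reference(p)
  expect_length(ref$library$sequences, 15)
  expect_length(ref$library$index$species, 5)
  expect_true(all(nchar(ref$library$sequences) == 400))

  ref2 <- simulate_reference(p)
  expect_identical(ref$library$sequences, ref2$library$sequences)
  ref3 <- simulate_reference(p, seed = 93)
  expect_false(identical(ref$library$sequences, ref3$library$sequences))

  # realised barcoding gap: max within-species < min between-species K2P
  d <- k2p_matrix(ref$library$sequences)
  sp <- ref$library$taxonomy$species
  same <- outer(sp, sp, `==`) & upper.tri(d)
  diff <- outer(sp, sp, `!=`) & upper.tri(d)
  expect_lt(max(d[same]), min(d[diff]))
  expect_gte(min(d[diff]), p$interspecific_divergence)
})

test_that("surveys respect spawning windows and keep exact books", {
  p <- simulation_params(n_species = 6, individuals_per_species = 2,
                         barcode_length = 300, monthly_sampling = 8,
                         dropout_rate = 0.3, unknown_species_fraction = 0,
                         seed = 94)
  ref <- simulate_reference(p)
  sv <- simulate_survey(ref)
  # window contract: no eggs outside a species' active months
  for (i in seq_len(nrow(sv$truth))) {
    tsp <- sv$truth$species[i]
    expect_true(sv$truth$month[i] %in% sv$windows[[tsp]])
  }
  # bookkeeping: surviving sequences + dropped set = all specimens
  expect_setequal(c(names(sv$sequences), sv$truth$id[sv$truth$dropped]),
                  sv$truth$id)
  expect_identical(sv$metadata$id, sv$truth$id)
  # reproducibility under the seed
  sv2 <- simulate_survey(ref)
  expect_identical(sv$sequences, sv2$sequences)
  expect_identical(sv$truth, sv2$truth)
})

test_that("dropout is Bernoulli at the configured rate", {
  p <- simulation_params(n_species = 5, individuals_per_species = 1,
                         barcode_length = 200,
                         interspecific_divergence = 0.1,
                         spawning_windows = setNames(
                           rep(list(MONTHS_DEFAULT), 5),
                           paste0("Genus", c(1, 1, 2, 2, 3), " sp",
                                  c(1, 2, 1, 2, 1))),
                         monthly_sampling = 140, dropout_rate = 0.38,
                         unknown_species_fraction = 0, seed = 95)
  ref <- simulate_reference(p)
  sv <- simulate_survey(ref)
  n <- nrow(sv$truth)
  expect_gt(n, 3000)
  frac <- mean(sv$truth$dropped)
  expect_lt(abs(frac - 0.38), 3 * sqrt(0.38 * 0.62 / n))
})

test_that("off-library eggs never receive a species name", {
  p <- simulation_params(n_species = 4, individuals_per_species = 2,
                         barcode_length = 400, monthly_sampling = 6,
                         dropout_rate = 0, unknown_species_fraction = 0.2,
                         seed = 96)
  ref <- simulate_reference(p)
  sv <- simulate_survey(ref)
  expect_gt(sum(!sv$truth$in_library), 0)
  res <- assign_batch(sv$sequences, ref$library, run_config(),
                      metadata = sv$metadata)
  tr <- res$results
  tt <- sv$truth[match(tr$id, sv$truth$id), ]
  # in-library eggs all end at their true species
  expect_true(all(tr$level[tt$in_library] == "species" &
                    tr$taxon[tt$in_library] == tt$species[tt$in_library]))
  # off-library eggs end at genus level or unidentified, never a species
  expect_true(all(tr$level[!tt$in_library] != "species"))
})
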