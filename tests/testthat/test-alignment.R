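test_that("identical sequences align without gaps at full identity", {
  set.seed(41)
  s <- rand_seq(569)
  aln <- align_pair(s, s)
  expect_equal(aln$n_compared, 569)
  expect_equal(aln$n_matches, 569)
  expect_equal(aln$n_columns, 569)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
  expect_equal(percent_identity(aln), 1)
})

test_that("a forced substitution costs exactly one mismatch column", {
  aln <- align_pair("ACGT", "ACTT")
  expect_equal(aln$n_compared, 4)
  expect_equal(aln$n_matches, 3)
  expect_equal(aln$score, 2)  # 3 matches - 1 mismatch
  expect_equal(percent_identity(aln), 0.75)
})

test_that("alignment scores equal the brute-force DP optimum on short pairs", {
  set.seed(7)
  for (k in 1:60) {
    a <- rand_seq(sample(6:16, 1))
    b <- rand_seq(sample(6:16, 1))
    aln <- align_pair(a, b)
    expect_equal(aln$score, oracle_overlap_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an established overlap aligner", {
  set.seed(8)
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  for (k in 1:25) {
    a <- rand_seq(sample(20:60, 1))
    b <- rand_seq(sample(20:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
      substitutionMatrix = m, gapOpening = 5, gapExtension = 2)
    expect_equal(align_pair(a, b)$score, Biostrings::score(ref),
                 info = paste(a, b))
  }
})

test_that("identity denominator excludes gap and ambiguity columns", {
  # 48-base reference; query carries a 2-base insertion and one
  # substitution: 50 alignment columns, 48 compared, 47 matching
  set.seed(12)
  b <- rand_seq(48)
  a <- mutate_at(paste0(substr(b, 1, 24), "GG", substr(b, 25, 48)), 5)
  aln <- align_pair(a, b)
  expect_equal(aln$n_columns, 50)
  expect_equal(aln$n_compared, 48)
  expect_equal(aln$n_matches, 47)
  expect_equal(percent_identity(aln), 47 / 48)

  # ambiguity codes drop out of the comparison
  aln2 <- align_pair("ACGTNNACGT", "ACGTTTACGT")
  expect_equal(aln2$n_compared, 8)
  expect_equal(aln2$n_matches, 8)

  # no comparable columns at all -> explicit error
  expect_error(percent_identity(align_pair("NNNN", "ACGT")),
               class = "fisheggs_undefined_identity")
})

test_that("K2P distance matches its closed form and flags saturation", {
  self <- align_pair("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(k2p_distance(self), 0)

  # P = 0.10, Q = 0.05 evaluates to the frozen closed-form value
  pa <- structure(list(n_compared = 100L, n_transitions = 10L,
                       n_transversions = 5L),
                  class = "pairwise_alignment")
  expect_equal(k2p_distance(pa), 0.1701812, tolerance = 1e-6)

  # domain boundary 1 - 2P - Q = 0
  sat <- structure(list(n_compared = 100L, n_transitions = 45L,
                        n_transversions = 10L),
                   class = "pairwise_alignment")
  expect_error(k2p_distance(sat), class = "fisheggs_saturated")
})

test_that("identity and K2P are symmetric in their arguments", {
  set.seed(21)
  for (k in 1:10) {
    a <- rand_seq(80)
    b <- mutate_at(a, sample(80, sample(1:15, 1)))
    ab <- align_pair(a, b); ba <- align_pair(b, a)
    expect_equal(percent_identity(ab), percent_identity(ba))
    expect_equal(k2p_distance(ab), k2p_distance(ba))
  }
})

test_that("accumulating mismatches never increases identity to the original", {
  set.seed(33)
  ref <- rand_seq(200)
  pos <- sample(200)
  prev <- 1
  q <- ref
  for (k in seq(5, 60, by = 5)) {
    q <- mutate_at(ref, pos[1:k])
    idt <- percent_identity(align_pair(q, ref))
    expect_lte(idt, prev)
    prev <- idt
  }
})

test_that("K2P dominates the raw substitution proportion on its domain", {
  grid <- expand.grid(P = seq(0, 0.3, by = 0.025), Q = seq(0, 0.3, by = 0.025))
  grid <- grid[1 - 2 * grid$P - grid$Q > 0 & 1 - 2 * grid$Q > 0, ]
  d <- fisheggs:::k2p_from_pq(grid$P, grid$Q)
  expect_true(all(d >= grid$P + grid$Q - 1e-12))
})

test_that("query orientation recovers the library strand", {
  set.seed(55)
  refs <- vapply(1:4, function(i) rand_seq(300), "")
  lib <- toy_library(refs, species = paste("Genus", c("a", "a", "b", "b")))
  q <- mutate_at(refs[2], sample(300, 4))

  fwd <- orient_query(q, lib)
  expect_identical(as.character(fwd), q)
  expect_identical(attr(fwd, "strand"), "+")

  flipped <- orient_query(reverse_complement(q), lib)
  expect_identical(as.character(flipped), q)
  expect_identical(attr(flipped, "strand"), "-")

  # decision agrees with exhaustive two-strand evaluation (no-indel
  # construction, so per-strand best identity is a plain base count)
  for (k in 1:8) {
    q2 <- mutate_at(refs[sample(4, 1)], sample(300, sample(1:30, 1)))
    if (runif(1) < 0.5) q2 <- reverse_complement(q2)
    best_ident <- function(x) max(vapply(refs, function(r) {
      mean(strsplit(x, "")[[1]] == strsplit(r, "")[[1]])
    }, numeric(1)))
    want <- if (best_ident(reverse_complement(q2)) > best_ident(q2))
      reverse_complement(q2) else q2
    expect_identical(as.character(orient_query(q2, lib)), want)
  }
})
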