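test_that("K2P matrix is symmetric, zero-diagonal and matches direct counting", {
  set.seed(81)
  base <- rand_seq(300)
  seqs <- c(a = base, b = mutate_at(base, 1:6), c = mutate_at(base, 50:80),
            d = mutate_at(base, c(1:20, 200:240)))
  d <- k2p_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 4), names(seqs)))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], oracle_k2p_pair(seqs[[i]], seqs[[j]]),
                 tolerance = 1e-12)
  }
  # identical sequences are at distance zero
  expect_equal(k2p_matrix(c(x = base, y = base))["x", "y"], 0)
})

test_that("K2P matrix agrees with an established implementation", {
  set.seed(82)
  base <- rand_seq(569)
  seqs <- vapply(1:6, function(i) mutate_at(base, sample(569, 8 * i)), "")
  names(seqs) <- letters[1:6]
  # inject some ambiguity codes to exercise pairwise deletion
  substr(seqs[2], 10, 12) <- "NNN"
  d <- k2p_matrix(seqs)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(ref[names(seqs), names(seqs)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("saturated pairs are flagged and capped at twice the finite maximum", {
  seqs <- c(a = strrep("A", 60), b = strrep("A", 60), c = strrep("C", 60))
  substr(seqs[["b"]], 1, 6) <- "GGGGGG"  # mild divergence from a
  d <- k2p_matrix(seqs)
  sat <- attr(d, "saturated")
  expect_true(sat["a", "c"] && sat["b", "c"])
  expect_false(sat["a", "b"])
  fin <- d["a", "b"]
  expect_equal(d["a", "c"], 2 * fin)
})

test_that("three-taxon neighbor joining matches the closed form", {
  dm <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["A"]], (5 + 9 - 8) / 2)
  expect_equal(lens[["B"]], (5 + 8 - 9) / 2)
  expect_equal(lens[["C"]], (9 + 8 - 5) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("four-taxon additive matrices are recovered exactly, matching the LS oracle", {
  set.seed(83)
  for (k in 1:25) {
    ra <- random_additive(4)
    tr <- nj_tree(ra$dm)
    expect_true(same_topology(tr, ra$tree))
    expect_identical(quartet_of_tree(tr), ls_best_quartet(ra$dm))
    # branch lengths reproduce the generating distances exactly
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$dm), colnames(ra$dm)],
                 ra$dm, tolerance = 1e-8)
  }
})

test_that("neighbor joining is consistent on additive matrices up to 12 taxa", {
  set.seed(84)
  for (k in 1:30) {
    n <- sample(4:12, 1)
    ra <- random_additive(n)
    tr <- nj_tree(ra$dm)
    expect_true(same_topology(tr, ra$tree), info = paste("n =", n))
    # cross-check against an independent NJ implementation
    expect_true(same_topology(tr, ape::nj(as.dist(ra$dm))))
  }
})

test_that("degenerate all-equal distances give a deterministic clamped tree", {
  dm <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(dm) <- 0
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and saturate on clean splits", {
  set.seed(85)
  base <- rand_seq(150)
  aln <- c(a = base, b = base,
           c = mutate_at(base, 1:22), d = mutate_at(base, 1:22))
  bt <- bootstrap_supports(aln, n_reps = 200, seed = 9)
  supp <- attr(bt, "supports")
  expect_equal(max(supp, na.rm = TRUE), 100)
  bt2 <- bootstrap_supports(aln, n_reps = 200, seed = 9)
  expect_identical(attr(bt2, "supports"), supp)
  # no supports requested -> plain tree
  bt0 <- bootstrap_supports(aln, n_reps = 0)
  expect_null(bt0$node.label)
})

test_that("bootstrap supports are stable under more replicates", {
  set.seed(86)
  base <- rand_seq(200)
  aln <- vapply(1:7, function(i) mutate_at(base, sample(200, 12)), "")
  names(aln) <- letters[1:7]
  s1 <- attr(bootstrap_supports(aln, n_reps = 150, seed = 1), "supports")
  s2 <- attr(bootstrap_supports(aln, n_reps = 1500, seed = 2), "supports")
  p <- s2 / 100
  se <- 100 * sqrt(pmax(p * (1 - p), 0.25 / 1500) / 150)
  ok <- is.na(s1) | abs(s1 - s2) <= 3 * se + 1
  expect_true(all(ok), info = paste(s1, s2, collapse = " | "))
})

test_that("single-linkage lineages chain through the threshold", {
  # two tight groups far apart -> two lineages
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(0.05, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.002
  d["b1", "b2"] <- d["b2", "b1"] <- 0.002
  part <- cluster_lineages(d, 0.01)
  expect_length(part$clusters, 2)
  expect_setequal(part$clusters[[1]], c("a1", "a2"))

  # chain: a-b 0.008, b-c 0.008, a-c 0.016 -> one lineage at 0.01
  labs <- c("a", "b", "c")
  d2 <- matrix(c(0, 0.008, 0.016, 0.008, 0, 0.008, 0.016, 0.008, 0), 3,
               dimnames = list(labs, labs))
  expect_length(cluster_lineages(d2, 0.01)$clusters, 1)

  # everything within threshold -> one lineage
  d3 <- matrix(0.005, 3, 3, dimnames = list(labs, labs)); diag(d3) <- 0
  expect_length(cluster_lineages(d3, 0.01)$clusters, 1)
})

test_that("lineage count is non-increasing in the threshold", {
  set.seed(87)
  base <- rand_seq(400)
  seqs <- vapply(1:12, function(i) mutate_at(base, sample(400, sample(2:60, 1))), "")
  names(seqs) <- sprintf("s%02d", 1:12)
  d <- k2p_matrix(seqs)
  ks <- vapply(c(0.001, 0.005, 0.01, 0.02, 0.05, 0.2),
               function(h) length(cluster_lineages(d, h)$clusters), 0L)
  expect_true(all(diff(ks) <= 0))
  expect_error(cluster_lineages(d, 0), "threshold")
})

test_that("reference-anchored projection returns a fixed-width matrix frame", {
  set.seed(88)
  anchor <- rand_seq(120)
  with_insert <- paste0(substr(anchor, 1, 60), "GGGG", substr(anchor, 61, 120))
  with_del <- paste0(substr(anchor, 1, 40), substr(anchor, 51, 120))
  seqs <- c(a = anchor, b = with_insert, c = with_del)
  proj <- project_to_reference(seqs, anchor)
  expect_true(all(nchar(proj) == 120))
  expect_identical(proj[["a"]], anchor)
  # insertion columns relative to the anchor are dropped
  expect_identical(proj[["b"]], anchor)
  # deleted anchor positions surface as gaps
  expect_equal(sum(strsplit(proj[["c"]], "")[[1]] == "-"), 10)
})
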