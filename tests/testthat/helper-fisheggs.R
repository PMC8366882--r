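# Shared fixtures and independent oracles for the test suite.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute the bases at `pos` with a different base (deterministic: next
# base in ACGT cyclic order, always a real change)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ch[pos] <- nxt[ch[pos]]
  paste(ch, collapse = "")
}

# Independent brute-force DP oracle for the ends-free affine-gap
# alignment score (both ends free; gap run of length L costs go + L*ge).
# O(nm) full matrices, intended for short sequences only.
oracle_overlap_score <- function(a, b, match = 1, mismatch = -1,
                                 go = 5, ge = 2) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b); NI <- -1e18
  M <- X <- Y <- matrix(NI, n + 1, m + 1)
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- 0
  Y[1, 2:(m + 1)] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge,
                     X[i, j - 1] - go - ge)
    }
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ], M[, m + 1], X[, m + 1], Y[, m + 1])
}

# toy reference library from parallel vectors
toy_library <- function(seqs, species,
                        genus = sub("\\s.*$", "", species),
                        family = paste0("Fam_", genus),
                        ids = sprintf("R%02d", seq_along(seqs))) {
  names(seqs) <- ids
  reference_library(seqs, data.frame(id = ids, family = family,
                                     genus = genus, species = species,
                                     stringsAsFactors = FALSE))
}

# construct a hit_list directly for cascade tests; identities must be
# given in descending order. Best/second-best species identities are
# re-derived here, independently of search_library.
make_hits <- function(species, identity,
                      genus = sub("\\s.*$", "", species),
                      family = paste0("Fam_", genus),
                      query_id = "q") {
  stopifnot(!is.unsorted(rev(identity)))
  df <- data.frame(reference_id = sprintf("R%03d", seq_along(species)),
                   family = family, genus = genus, species = species,
                   identity = identity, rank = seq_along(species),
                   stringsAsFactors = FALSE)
  best_sp <- species[1]
  other <- identity[species != best_sp]
  structure(list(query_id = query_id, hits = df,
                 best_species_identity = identity[1],
                 second_best_species_identity =
                   if (length(other)) max(other) else NA_real_,
                 strand = "+"),
            class = "hit_list")
}

# unrooted-topology equality through ape (independent of nj_tree)
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# random tree with positive branch lengths and its additive distance matrix
random_additive <- function(n_taxa, min_bl = 0.05, max_bl = 1) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, min_bl, max_bl))
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Brute-force 4-taxon oracle: least-squares fit of the 5 branch lengths
# under each of the 3 unrooted topologies; returns the sister pairing of
# the best-fitting topology, e.g. c("A","B") for ((A,B),(C,D)).
ls_best_quartet <- function(dm) {
  lab <- rownames(dm)
  stopifnot(length(lab) == 4)
  pairings <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- vapply(pairings, function(p) {
    s1 <- p; s2 <- setdiff(1:4, p)
    # unknowns: terminal a,b (sisters 1), c,d (sisters 2), internal e
    # rows: the 6 pairwise path equations
    pairs <- rbind(c(s1[1], s1[2]), c(s2[1], s2[2]),
                   c(s1[1], s2[1]), c(s1[1], s2[2]),
                   c(s1[2], s2[1]), c(s1[2], s2[2]))
    A <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 0),
               c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
               c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1))
    y <- apply(pairs, 1, function(ij) dm[ij[1], ij[2]])
    fit <- qr.solve(A, y)
    sum((A %*% fit - y)^2)
  }, numeric(1))
  side <- sort(lab[pairings[[which.min(rss)]]])
  ref <- sort(lab)[1]
  if (ref %in% side) side else sort(setdiff(lab, side))
}

# sister pairing of one 4-taxon phylo tree (from its single internal
# split), normalised to the side containing the alphabetically first tip
quartet_of_tree <- function(phy) {
  parts <- ape::prop.part(ape::unroot(phy))
  sizes <- vapply(parts, length, 0L)
  inner <- which(sizes == 2)[1]
  side <- sort(phy$tip.label[parts[[inner]]])
  ref <- sort(phy$tip.label)[1]
  if (ref %in% side) side else sort(setdiff(phy$tip.label, side))
}

# per-pair K2P recomputed by direct column counting (independent path)
oracle_k2p_pair <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  pur <- c("A", "G")
  ts <- sum(a != b & ((a %in% pur) == (b %in% pur)))
  tv <- sum(a != b) - ts
  P <- ts / length(a); Q <- tv / length(a)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}
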