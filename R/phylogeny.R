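## integer base codes: A=0, G=1 (purines), C=2, T=3 (pyrimidines);
## NA for gaps and IUPAC ambiguity codes (excluded pairwise).
seq_codes <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must be equal length (aligned); got lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "))
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  codes <- matrix(c(0L, 1L, 2L, 3L)[match(chars, c("A", "G", "C", "T"))],
                  nrow = length(seqs))
  rownames(codes) <- names(seqs)
  codes
}

## per-pair per-column comparison classes over an aligned set:
## 0 excluded, 1 match, 2 transition, 3 transversion.
## rows indexed by pair (i < j, row-major over i).
pair_class_matrix <- function(codes) {
  n <- nrow(codes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  a <- codes[pairs[, 1L], , drop = FALSE]
  b <- codes[pairs[, 2L], , drop = FALSE]
  cls <- matrix(0L, nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  same <- ok & a == b
  ts <- ok & !same & (a %/% 2L == b %/% 2L)
  cls[same] <- 1L
  cls[ts] <- 2L
  cls[ok & !same & !ts] <- 3L
  list(pairs = pairs, cls = cls)
}

k2p_from_classes <- function(cls_counts) {
  n_comp <- cls_counts[, 1L] + cls_counts[, 2L] + cls_counts[, 3L]
  P <- ifelse(n_comp > 0, cls_counts[, 2L] / n_comp, NA_real_)
  Q <- ifelse(n_comp > 0, cls_counts[, 3L] / n_comp, NA_real_)
  k2p_from_pq(P, Q)
}

fill_dist_matrix <- function(d_pairs, pairs, labels) {
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  d[pairs] <- d_pairs
  d[pairs[, c(2L, 1L)]] <- d_pairs
  if (anyNA(d)) {
    bad <- is.na(d)
    fin <- max(d[!bad], 0)
    if (fin == 0)
      stop_fisheggs("all pairwise distances saturated", "fisheggs_saturated")
    d[bad] <- 2 * fin  # documented fallback for saturated pairs
    sat[bad] <- TRUE
  }
  attr(d, "saturated") <- sat
  d
}

#' Kimura two-parameter distance matrix
#'
#' Pairwise K2P distances over a set of equal-length aligned barcodes,
#' with pairwise deletion of columns where either sequence has a gap or an
#' ambiguity code. Saturated pairs (outside the model's domain) are set to
#' twice the largest finite distance and flagged in the `"saturated"`
#' attribute.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (at least 2).
#' @return symmetric numeric matrix with zero diagonal, dimnames from
#'   `names(seqs)` and a logical `"saturated"` attribute.
#' @export
k2p_matrix <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  codes <- seq_codes(seqs)
  n <- nrow(codes)
  # row-blocked so memory stays O(n L), not O(n^2 L)
  d_pairs <- numeric(0)
  pairs <- matrix(0L, 0L, 2L)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    a <- codes[rep(i, length(rest)), , drop = FALSE]
    b <- codes[rest, , drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    same <- ok & a == b
    ts <- ok & !same & (a %/% 2L == b %/% 2L)
    counts <- cbind(rowSums(same), rowSums(ts),
                    rowSums(ok) - rowSums(same) - rowSums(ts))
    d_pairs <- c(d_pairs, k2p_from_classes(counts))
    pairs <- rbind(pairs, cbind(i, rest))
  }
  fill_dist_matrix(d_pairs, pairs, names(seqs))
}

#' Neighbor-joining tree
#'
#' Canonical agglomerative neighbor joining: at each step the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined; ties are broken deterministically by the lowest (row, column)
#' index pair, with newly created nodes appended after the existing ones.
#' Negative branch lengths are clamped to zero. The result is unrooted
#' (trifurcating root node).
#'
#' @param dm symmetric distance matrix with dimnames (e.g. from
#'   [k2p_matrix()]), or a [stats::dist].
#' @return an [ape::phylo] tree whose tips are the matrix labels.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' nj_tree(d)
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 labels for a tree")
  labels <- rownames(dm) %||% as.character(seq_len(n))
  D <- unname(dm)
  node <- seq_len(n)       # phylo node id of each active cluster
  joins <- list()          # records (child1, child2, len1, len2)
  n_join <- 0L
  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    n_join <- n_join + 1L
    joins[[n_join]] <- c(node[i], node[j], max(vi, 0), max(vj, 0))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], n + n_join)  # provisional internal id
  }
  dij <- c(D[1, 2], D[1, 3], D[2, 3])
  v <- c((dij[1] + dij[2] - dij[3]) / 2,
         (dij[1] + dij[3] - dij[2]) / 2,
         (dij[2] + dij[3] - dij[1]) / 2)
  # internal ids: the final (root) trifurcation must be n+1; the k-th
  # earlier join becomes n+1+k
  remap <- function(id) ifelse(id <= n, id, id + 1L)
  edge <- matrix(0L, 0L, 2L)
  len <- numeric(0)
  for (k in seq_along(joins)) {
    u <- n + 1L + k
    edge <- rbind(edge, c(u, remap(joins[[k]][1L])),
                  c(u, remap(joins[[k]][2L])))
    len <- c(len, joins[[k]][3L], joins[[k]][4L])
  }
  root <- n + 1L
  edge <- rbind(edge, cbind(root, remap(node)))
  len <- c(len, pmax(v, 0))
  # order edges cladewise (preorder from the root) for a canonical tree
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  ord <- integer(0)
  stack <- rev(children[[as.character(root)]])
  while (length(stack)) {
    e <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ord <- c(ord, e)
    kid <- edge[e, 2L]
    if (kid > n) stack <- c(stack, rev(children[[as.character(kid)]]))
  }
  structure(list(edge = edge[ord, , drop = FALSE], edge.length = len[ord],
                 tip.label = labels, Nnode = n - 2L),
            class = "phylo", order = "cladewise")
}

## nontrivial bipartitions of an unrooted tree as canonical string keys:
## each split is the tip-label set on one side, normalised to the side
## not containing the alphabetically first label.
tree_split_keys <- function(phy) {
  n <- length(phy$tip.label)
  parts <- ape::prop.part(phy)
  ref <- sort(phy$tip.label)[1L]
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    tips <- phy$tip.label[parts[[k]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) {
      if (length(tips) < n) { keys <- c(keys, NA); nodes <- c(nodes, n + k) }
      next
    }
    side <- if (ref %in% tips) setdiff(phy$tip.label, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, n + k)
  }
  # root (all tips) is parts[[1]]: give it an NA key so node labels align
  data.frame(node = c(n + 1L, nodes), key = c(NA, keys),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the K2P/NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree
#' for each replicate, and labels each internal edge of the original tree
#' with the percentage of replicates containing the same bipartition.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (3 or more).
#' @param n_reps number of bootstrap replicates; `0` returns the tree
#'   without supports.
#' @param seed RNG seed for column resampling.
#' @return an [ape::phylo] tree; `$node.label` carries integer supports
#'   in \[0, 100\] (empty at the root), also available as the numeric
#'   `"supports"` attribute.
#' @export
bootstrap_supports <- function(alignment, n_reps = 1000L, seed = 1L) {
  if (length(alignment) < 3L) stop("need at least 3 sequences")
  codes <- seq_codes(alignment)
  pc <- pair_class_matrix(codes)
  count3 <- function(cls) cbind(rowSums(cls == 1L), rowSums(cls == 2L),
                                rowSums(cls == 3L))
  full_d <- fill_dist_matrix(k2p_from_classes(count3(pc$cls)), pc$pairs,
                             names(alignment))
  phy <- nj_tree(full_d)
  if (n_reps < 1L) return(phy)
  orig <- tree_split_keys(phy)
  tally <- setNames(numeric(nrow(orig)), orig$node)
  L <- ncol(pc$cls)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      cls_r <- pc$cls[, idx, drop = FALSE]
      d_r <- fill_dist_matrix(k2p_from_classes(count3(cls_r)), pc$pairs,
                              names(alignment))
      keys_r <- tree_split_keys(nj_tree(d_r))$key
      hitk <- !is.na(orig$key) & orig$key %in% keys_r
      tally[hitk] <- tally[hitk] + 1
    }
  })
  supp <- round(100 * tally / n_reps)
  supp[is.na(orig$key)] <- NA
  lab <- rep(NA_real_, phy$Nnode)
  lab[orig$node - length(alignment)] <- supp
  phy$node.label <- ifelse(is.na(lab), "", as.character(lab))
  attr(phy, "supports") <- lab
  phy
}

#' Delimit lineages by single-linkage clustering at a distance threshold
#'
#' Two barcodes share a lineage exactly when a chain of pairwise distances
#' at or below the threshold connects them, the operational proxy for
#' counting independent lineages on a barcoding tree at the species-level
#' divergence boundary.
#'
#' @param dm symmetric distance matrix with dimnames (e.g. from
#'   [k2p_matrix()]).
#' @param threshold positive K2P distance (default the 1% species
#'   boundary).
#' @return an object of class `lineage_partition`: list with `labels`,
#'   `membership` (integer vector named by label, numbered by first
#'   appearance), `clusters` (list of label sets) and `threshold`.
#' @export
cluster_lineages <- function(dm, threshold = 0.01) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (!(threshold > 0)) stop("threshold must be > 0")
  labels <- rownames(dm) %||% as.character(seq_len(nrow(dm)))
  if (nrow(dm) == 1L) {
    membership <- setNames(1L, labels)
  } else {
    hc <- hclust(as.dist(dm), method = "single")
    membership <- cutree(hc, h = threshold)
    # renumber clusters by first appearance in input order
    first <- unique(membership)
    membership <- setNames(match(membership, first), labels)
  }
  structure(list(labels = labels, membership = membership,
                 clusters = split(labels, membership),
                 threshold = threshold),
            class = "lineage_partition")
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat(sprintf("Lineage partition: %d sequences in %d lineages (single linkage, d <= %g)\n",
              length(x$labels), length(x$clusters), x$threshold))
  invisible(x)
}

#' Project sequences onto a reference anchor's coordinate frame
#'
#' Aligns each sequence semi-globally to the anchor and keeps one column
#' per anchor position (columns inserted relative to the anchor are
#' dropped; anchor positions not covered by the sequence become gaps).
#' This produces the fixed-width barcode matrix used for distances, trees
#' and lineage clustering.
#'
#' @param seqs named character vector of sequences.
#' @param anchor the anchor sequence (e.g. a designated reference).
#' @param cfg a [run_config()] (alignment scoring).
#' @return named character vector, every element `nchar(anchor)` wide.
#' @export
project_to_reference <- function(seqs, anchor, cfg = run_config()) {
  anchor <- toupper(as.character(anchor))
  out <- vapply(seqs, function(s) {
    aln <- align_pair(s, anchor, match = cfg$match, mismatch = cfg$mismatch,
                      gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    qa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
    ra <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
    paste(qa[ra != "-"], collapse = "")
  }, character(1))
  stopifnot(all(nchar(out) == nchar(anchor)))
  out
}
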