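#' SNN modularity clustering of spots
#'
#' PCA on the normalized expression matrix, a k-nearest-neighbor graph on
#' the PC scores, shared-nearest-neighbor (SNN) edge weights (Jaccard overlap
#' of neighbor sets, self included), and modularity-based community detection
#' (Louvain). Spots are canonicalized by sorting on spot id before any
#' computation, so the labeling is invariant to input column order; cluster
#' ids are renumbered 1..K by first appearance in sorted spot order.
#' Singleton communities are merged into the cluster with the nearest
#' centroid in PC space.
#'
#' @param normalized gene x spot matrix (e.g. from [normalize_log()]).
#' @param n_pcs number of principal components (capped at what the data
#'   supports).
#' @param k neighbors for the kNN graph; must be < number of spots.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed for the community detection.
#' @param prune SNN edges with Jaccard weight below this are dropped
#'   (1/15, the conventional default).
#' @return named integer vector of cluster ids (contiguous from 1) with
#'   attributes `n_pcs`, `k`, `resolution`, `seed`.
#' @export
snn_cluster <- function(normalized, n_pcs = 30, k = 20, resolution = 1.0,
                        seed = 0, prune = 1 / 15) {
  m <- as.matrix(normalized)
  n <- ncol(m)
  if (k >= n) stop("k must be smaller than the number of spots",
                   call. = FALSE)
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  ids <- colnames(m)

  x <- t(m)
  rank_max <- min(n_pcs, n - 1L, nrow(m))
  pcs <- if (sum(apply(x, 2L, stats::var)) == 0) {
    matrix(0, nrow = n, ncol = 1L)  # identical spots: one degenerate PC
  } else {
    prcomp(x, center = TRUE, scale. = FALSE, rank. = rank_max)$x
  }

  d <- as.matrix(dist(pcs))
  diag(d) <- Inf
  # neighbor sets include self; ties broken by (sorted) spot order
  nn <- lapply(seq_len(n), function(i) {
    c(i, order(d[i, ])[seq_len(k)])
  })
  # candidate edges: i -- each of its kNN
  ei <- rep(seq_len(n), each = k)
  ej <- unlist(lapply(nn, function(s) s[-1L]))
  pair <- cbind(pmin(ei, ej), pmax(ei, ej))
  pair <- unique(pair)
  w <- vapply(seq_len(nrow(pair)), function(r) {
    a <- nn[[pair[r, 1L]]]; b <- nn[[pair[r, 2L]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[pair[keep, 1L]], to = ids[pair[keep, 2L]],
               weight = w[keep]),
    directed = FALSE, vertices = ids)

  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(comm)[ids]

  labels <- .merge_singletons(labels, pcs, ids)
  labels <- as.integer(factor(labels, levels = unique(labels)))
  names(labels) <- ids
  attr(labels, "n_pcs") <- rank_max
  attr(labels, "k") <- k
  attr(labels, "resolution") <- resolution
  attr(labels, "seed") <- seed
  labels
}

.merge_singletons <- function(labels, pcs, ids) {
  tab <- table(labels)
  singles <- names(tab)[tab == 1L]
  if (length(singles) == 0L || length(tab) == length(singles)) return(labels)
  cent <- do.call(rbind, lapply(setdiff(names(tab), singles), function(cl) {
    colMeans(pcs[labels == cl, , drop = FALSE])
  }))
  rownames(cent) <- setdiff(names(tab), singles)
  for (cl in singles) {
    i <- which(labels == cl)
    dd <- colSums((t(cent) - pcs[i, ])^2)
    labels[i] <- rownames(cent)[which.min(dd)]
  }
  labels
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same spots,
#' computed from the contingency table under the permutation model.
#' Invariant to label permutation; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param labels_a,labels_b vectors of cluster labels over the same spots.
#'   If both are named, they are matched by name (an error if the spot sets
#'   differ); otherwise they are compared positionally.
#' @return ARI in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("labelings cover different spot sets", call. = FALSE)
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stop("labelings must have the same length", call. = FALSE)
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 spots", call. = FALSE)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
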