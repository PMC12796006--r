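#' Rank-based gene-set activity score for one spot
#'
#' Area under the gene-set recovery curve within the top-ranked fraction of
#' genes (AUCell-style). Genes are ranked by decreasing expression; with
#' `k = ceiling(top_fraction * n_genes)`, the recovery curve R(i) counts set
#' genes among the top i ranks and the score is
#' `sum_{i=1..k} R(i) / sum_{i=1..k} min(i, m)` with m the number of set
#' genes present in the universe. Being rank-based, the score is invariant
#' under strictly monotone transforms of the expression vector.
#'
#' Ties in expression are broken by a seeded random permutation, then by
#' gene-name order, so scoring is deterministic for a given seed.
#'
#' @param x named numeric expression vector for one spot.
#' @param gene_set character vector of gene ids.
#' @param top_fraction fraction of top-ranked genes integrated over
#'   (default 0.05).
#' @param seed seed for the tie-breaking permutation.
#' @return score in \[0, 1\]; 0 with a warning when the set misses the
#'   universe entirely.
#' @export
#' @examples
#' x <- setNames(c(10, 9, 8, 0, 0, 0, 0, 0, 0, 0), paste0("g", 1:10))
#' auc_score(x, c("g1", "g2"), top_fraction = 0.2)
auc_score <- function(x, gene_set, top_fraction = 0.05, seed = 0) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  if (is.null(names(x))) stop("x must be a named vector", call. = FALSE)
  n <- length(x)
  present <- intersect(gene_set, names(x))
  if (length(present) == 0L) {
    warning("gene set has no genes in the expression universe; score 0")
    return(0)
  }
  k <- ceiling(top_fraction * n)
  ranks <- .expression_ranks(x, seed)
  .auc_from_ranks(ranks[present], k, length(present))
}

# rank 1 = highest expression; ties broken by seeded permutation then name
.expression_ranks <- function(x, seed) {
  n <- length(x)
  tie <- local({
    set.seed(seed)
    sample.int(n)
  })
  ord <- order(-x, tie, names(x))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- names(x)
  ranks
}

.auc_from_ranks <- function(set_ranks, k, m) {
  inside <- set_ranks[set_ranks <= k]
  num <- sum(k - inside + 1)
  den <- sum(pmin(seq_len(k), m))
  num / den
}

#' Score a gene-set collection across all spots
#'
#' Applies [auc_score()] to every spot (column) and every set of a
#' collection. Ranks are computed once per spot and reused across sets.
#'
#' @param normalized gene x spot expression matrix (any monotone scale;
#'   the score is rank-based).
#' @param gene_sets named list of gene-id vectors.
#' @param top_fraction,seed passed to the scoring (one tie-break
#'   permutation per spot, all derived from `seed`).
#' @return spot x set matrix of scores in \[0, 1\]; attribute
#'   `top_fraction`.
#' @export
score_pathways <- function(normalized, gene_sets, top_fraction = 0.05,
                           seed = 0) {
  m <- as.matrix(normalized)
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets)))
    stop("gene_sets must have unique names", call. = FALSE)
  if (any(lengths(gene_sets) == 0L))
    stop("gene sets must be non-empty", call. = FALSE)
  n <- nrow(m)
  k <- ceiling(top_fraction * n)
  present <- lapply(gene_sets, intersect, y = rownames(m))
  if (any(lengths(present) == 0L))
    warning("set(s) with no genes in the universe scored 0: ",
            paste(names(gene_sets)[lengths(present) == 0L], collapse = ", "))
  out <- matrix(0, ncol(m), length(gene_sets),
                dimnames = list(colnames(m), names(gene_sets)))
  for (s in seq_len(ncol(m))) {
    ranks <- .expression_ranks(m[, s], seed)
    for (j in seq_along(present)) {
      if (length(present[[j]]) == 0L) next
      out[s, j] <- .auc_from_ranks(ranks[present[[j]]], k,
                                   length(present[[j]]))
    }
  }
  attr(out, "top_fraction") <- top_fraction
  out
}

#' Composite inflammation score
#'
#' Min-max normalizes each pathway's scores to \[0, 1\] across spots and
#' averages them per spot. A constant pathway cannot be normalized and
#' contributes 0 for every spot, with a warning.
#'
#' @param scores spot x pathway score matrix (e.g. from
#'   [score_pathways()]).
#' @param sets pathway columns to combine (default: the seven
#'   inflammation-related sets present in `scores`, else all columns).
#' @return named numeric vector in \[0, 1\].
#' @export
composite_inflammation <- function(scores, sets = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L)
    stop("need >= 2 spots (min-max normalization undefined)", call. = FALSE)
  if (is.null(sets)) {
    sets <- intersect(inflammation_set_names(), colnames(scores))
    if (length(sets) == 0L) sets <- colnames(scores)
  }
  if (!all(sets %in% colnames(scores)))
    stop("sets missing from scores: ",
         paste(setdiff(sets, colnames(scores)), collapse = ", "),
         call. = FALSE)
  sub <- scores[, sets, drop = FALSE]
  rng <- apply(sub, 2L, range)
  const <- rng[1, ] == rng[2, ]
  if (any(const))
    warning("constant pathway(s) contribute 0: ",
            paste(sets[const], collapse = ", "))
  norm <- sapply(seq_along(sets), function(j) {
    if (const[j]) rep(0, nrow(sub))
    else (sub[, j] - rng[1, j]) / (rng[2, j] - rng[1, j])
  })
  out <- rowMeans(norm)
  names(out) <- rownames(scores)
  out
}

#' Jenks natural breaks (exact 1-D optimal partition)
#'
#' Fisher's dynamic program: partitions sorted values into `n_classes`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations. Deterministic and exactly optimal. Classes are ordered
#' low to high.
#'
#' @param values numeric vector; needs at least `n_classes` distinct values.
#' @param n_classes number of classes (default 4).
#' @return list: `classes` (integer class per input value, 1 = lowest),
#'   `breaks` (upper value bound of classes 1..n_classes-1), `ssd` (optimal
#'   total within-class SSD).
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)$classes
jenks_breaks <- function(values, n_classes = 4) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numerics", call. = FALSE)
  .check_number(n_classes, "n_classes", positive = TRUE, integer = TRUE)
  n_distinct <- length(unique(values))
  if (n_distinct < n_classes)
    stop(sprintf("need >= %d distinct values, have %d",
                 n_classes, n_distinct), call. = FALSE)
  n <- length(values)
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # SSD of x[i..j]
  ssd_ij <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  k <- n_classes
  D <- matrix(Inf, n, k)      # D[j, c]: best SSD for x[1..j] in c classes
  B <- matrix(0L, n, k)       # argmin split: last class starts at B[j, c]
  for (j in seq_len(n)) {
    D[j, 1L] <- ssd_ij(1L, j)
    B[j, 1L] <- 1L
  }
  for (cc in seq_len(k)[-1L]) {
    for (j in cc:n) {
      best <- Inf; arg <- cc
      for (i in cc:j) {
        v <- (if (i > 1L) D[i - 1L, cc - 1L] else 0) + ssd_ij(i, j)
        if (v < best) { best <- v; arg <- i }
      }
      D[j, cc] <- best
      B[j, cc] <- arg
    }
  }
  # backtrack class boundaries on the sorted vector
  bounds <- integer(k)  # end index of each class
  j <- n
  for (cc in k:1) {
    bounds[cc] <- j
    j <- B[j, cc] - 1L
  }
  cls_sorted <- rep(seq_len(k), times = diff(c(0L, bounds)))
  classes <- integer(n)
  classes[ord] <- cls_sorted
  breaks <- x[bounds[-k]]
  list(classes = classes, breaks = breaks, ssd = D[n, k])
}

#' Classify spots into inflammation niches
#'
#' Wraps [jenks_breaks()] on the composite inflammation score; with the
#' default four classes the niches are labeled Low, Medium-Low,
#' Medium-High, High.
#'
#' @param composite named numeric vector from [composite_inflammation()].
#' @param n_classes number of niches (default 4).
#' @return data frame: spot_id, composite, class (ordered factor);
#'   attributes `breaks` and `ssd`.
#' @export
assign_inflammation_classes <- function(composite, n_classes = 4) {
  jb <- jenks_breaks(composite, n_classes)
  labs <- if (n_classes == 4L)
    c("Low", "Medium-Low", "Medium-High", "High")
  else paste0("C", seq_len(n_classes))
  out <- data.frame(
    spot_id = if (!is.null(names(composite))) names(composite)
              else as.character(seq_along(composite)),
    composite = as.numeric(composite),
    class = factor(labs[jb$classes], levels = labs, ordered = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "breaks") <- jb$breaks
  attr(out, "ssd") <- jb$ssd
  out
}

#' Pairwise group comparison by rank-sum tests
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of groups,
#' Benjamini-Hochberg corrected across pairs, with group medians. Used for
#' pathway-by-region, inflammation-by-cluster, state-by-class and
#' intensity-by-cluster comparisons. A single group (or a group paired with
#' itself) yields p = 1 by convention.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data frame: group1, group2, n1, n2, median1, median2, p, q.
#' @export
#' @examples
#' group_compare(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
group_compare <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes == 0L))
    stop("empty group level(s): ",
         paste(names(sizes)[sizes == 0L], collapse = ", "), call. = FALSE)
  lev <- levels(groups)
  if (length(lev) == 1L) {
    return(data.frame(group1 = lev, group2 = lev,
                      n1 = sizes[[1]], n2 = sizes[[1]],
                      median1 = median(values), median2 = median(values),
                      p = 1, q = 1, stringsAsFactors = FALSE))
  }
  pairs <- combn(lev, 2)
  res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    a <- values[groups == g1]; b <- values[groups == g2]
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided")$p.value)
    if (!is.finite(p)) p <- 1  # all-tied values
    data.frame(group1 = g1, group2 = g2, n1 = length(a), n2 = length(b),
               median1 = median(a), median2 = median(b), p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Read a gene-set collection in GMT format
#'
#' Each GMT line is: set name, description, then member genes, tab
#' separated. Uses fgsea's reader when available, otherwise a minimal
#' parser with the same output.
#'
#' @param path path to a `.gmt` file.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param gene_sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  description <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
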