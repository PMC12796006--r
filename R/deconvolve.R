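#' Build reference signatures from labeled expression profiles
#'
#' Summarizes a labeled reference (e.g. pseudo-bulk profiles from annotated
#' single cells) into one mean profile per cell type, optionally restricted
#' to the top marker genes of each type by fold change against the mean of
#' the other types.
#'
#' @param profiles gene x profile matrix of normalized expression (>= 0).
#' @param types character vector assigning each profile column to a cell
#'   type; every type needs >= 1 profile.
#' @param n_markers if not `NULL`, keep only the union of the top
#'   `n_markers` genes per type ranked by fold change (pseudo-count 1e-8).
#' @return gene x cell-type signature matrix; when markers were selected,
#'   attribute `markers` holds the per-type marker lists.
#' @export
build_reference_signatures <- function(profiles, types, n_markers = NULL) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0))
    stop("reference profiles must be non-negative", call. = FALSE)
  if (length(types) != ncol(profiles))
    stop("'types' must label every profile column", call. = FALSE)
  u <- unique(types)
  if (length(u) < 2L) stop("need at least 2 cell types", call. = FALSE)
  sig <- vapply(u, function(t) {
    rowMeans(profiles[, types == t, drop = FALSE])
  }, numeric(nrow(profiles)))
  dimnames(sig) <- list(rownames(profiles), u)
  if (is.null(n_markers)) return(sig)

  eps <- 1e-8
  markers <- lapply(u, function(t) {
    other <- rowMeans(sig[, setdiff(u, t), drop = FALSE])
    fc <- (sig[, t] + eps) / (other + eps)
    rownames(sig)[order(-fc)][seq_len(min(n_markers, nrow(sig)))]
  })
  names(markers) <- u
  keep <- unique(unlist(markers))
  out <- sig[keep, , drop = FALSE]
  attr(out, "markers") <- markers
  out
}

#' Spot deconvolution by non-negative least squares
#'
#' Fits each spot's expression vector as a non-negative combination of the
#' reference signatures over the shared gene set, then normalizes the
#' coefficients to proportions. This is a deterministic, reference-based
#' stand-in for probabilistic label transfer: the output contract (per-spot
#' cell-type scores) is the same, and score tables produced by external
#' tools can be used anywhere a score matrix is expected. Fit in linear
#' (depth-normalized, not log) space, where mixing is additive.
#'
#' @param spot_matrix gene x spot matrix of depth-normalized expression.
#' @param ref gene x cell-type signature matrix
#'   (see [build_reference_signatures()]).
#' @param min_genes minimum required overlap between the two gene
#'   namespaces.
#' @param normalize if `TRUE` (default) rows are scaled to sum to 1; raw
#'   NNLS coefficients otherwise (recorded in attribute `normalized`).
#' @return spot x cell-type score matrix; attribute `flagged` names spots
#'   whose fit was all-zero (scored uniform, with a warning).
#' @export
nnls_deconvolve <- function(spot_matrix, ref, min_genes = 50,
                            normalize = TRUE) {
  spot_matrix <- as.matrix(spot_matrix)
  ref <- as.matrix(ref)
  shared <- intersect(rownames(spot_matrix), rownames(ref))
  if (length(shared) < min_genes)
    stop(sprintf(
      "only %d genes shared between spots (%d) and reference (%d); need >= %d",
      length(shared), nrow(spot_matrix), nrow(ref), min_genes),
      call. = FALSE)
  A <- ref[shared, , drop = FALSE]
  Y <- spot_matrix[shared, , drop = FALSE]
  k <- ncol(A)
  scores <- matrix(0, nrow = ncol(Y), ncol = k,
                   dimnames = list(colnames(Y), colnames(A)))
  for (s in seq_len(ncol(Y)))
    scores[s, ] <- pracma::lsqnonneg(A, Y[, s])$x
  sums <- rowSums(scores)
  flagged <- rownames(scores)[sums == 0]
  if (length(flagged) > 0) {
    warning(length(flagged),
            " spot(s) had an all-zero fit; scored uniform: ",
            paste(head(flagged, 5), collapse = ", "))
    scores[sums == 0, ] <- 1 / k
    sums[sums == 0] <- 1
  }
  if (normalize) scores <- scores / sums
  attr(scores, "normalized") <- normalize
  attr(scores, "flagged") <- flagged
  scores
}

#' Stratify spots into high/low leukemic score (HLS/LLS)
#'
#' The AML deconvolution score of a spot is the sum of its scores over the
#' leukemic cell-type columns. Spots strictly above the median score are
#' HLS; spots at or below it (including ties at the median) are LLS.
#'
#' @param scores spot x cell-type score matrix.
#' @param aml_columns names of the leukemic columns to sum.
#' @return data frame: spot_id, aml_score, label (factor HLS/LLS);
#'   attributes `threshold` (the median) and `aml_columns`.
#' @export
#' @examples
#' sc <- matrix(c(.1, .2, .3, .4), ncol = 1,
#'              dimnames = list(paste0("s", 1:4), "AML"))
#' classify_hls_lls(sc, "AML")
classify_hls_lls <- function(scores, aml_columns) {
  scores <- as.matrix(scores)
  if (length(aml_columns) == 0L)
    stop("aml_columns must name at least one column", call. = FALSE)
  if (!all(aml_columns %in% colnames(scores)))
    stop("aml_columns missing from scores: ",
         paste(setdiff(aml_columns, colnames(scores)), collapse = ", "),
         call. = FALSE)
  if (nrow(scores) < 2L) stop("need at least 2 spots", call. = FALSE)
  aml <- rowSums(scores[, aml_columns, drop = FALSE])
  thr <- median(aml)
  lab <- factor(ifelse(aml > thr, "HLS", "LLS"), levels = c("HLS", "LLS"))
  out <- data.frame(spot_id = rownames(scores), aml_score = aml,
                    label = lab, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- thr
  attr(out, "aml_columns") <- aml_columns
  out
}

#' Differential co-localization of cell types between HLS and LLS spots
#'
#' For every non-leukemic cell type, compares its deconvolution scores in
#' HLS versus LLS spots with a two-sided Wilcoxon rank-sum test,
#' Benjamini-Hochberg corrected across cell types. Returns a volcano-ready
#' table.
#'
#' @param scores spot x cell-type score matrix.
#' @param labels output of [classify_hls_lls()].
#' @param exclude cell types to leave out (defaults to the leukemic columns
#'   recorded in `labels`).
#' @return data frame: cell_type, mean_hls, mean_lls, effect
#'   (mean_hls - mean_lls), p, q, neg_log10_p.
#' @export
differential_colocalization <- function(scores, labels,
                                        exclude = attr(labels,
                                                       "aml_columns")) {
  scores <- as.matrix(scores)
  scores <- scores[labels$spot_id, , drop = FALSE]
  types <- setdiff(colnames(scores), exclude)
  if (length(types) == 0L)
    stop("no cell types left after exclusion", call. = FALSE)
  hls <- labels$label == "HLS"
  if (!any(hls) || !any(!hls))
    stop("both HLS and LLS groups must be non-empty", call. = FALSE)
  small <- sum(hls) < 3L || sum(!hls) < 3L
  if (small)
    warning("a group has fewer than 3 spots; p values set to 1")
  res <- do.call(rbind, lapply(types, function(t) {
    a <- scores[hls, t]; b <- scores[!hls, t]
    p <- if (small) 1 else
      suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
    if (!is.finite(p)) p <- 1  # all-tied scores
    data.frame(cell_type = t, mean_hls = mean(a), mean_lls = mean(b),
               effect = mean(a) - mean(b), p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res$neg_log10_p <- -log10(res$p)
  rownames(res) <- NULL
  res
}

#' Neighborhood enrichment around HLS versus LLS spots
#'
#' For each spot, the neighborhood score of a cell type is the mean of that
#' type's scores over the spot's k nearest tissue spots (self excluded).
#' Neighborhood scores around HLS spots are compared with those around LLS
#' spots by two-sided rank-sum tests, BH-corrected across types.
#'
#' @param scores spot x cell-type score matrix.
#' @param labels output of [classify_hls_lls()].
#' @param lattice lattice data frame covering all scored spots.
#' @param k neighbors per spot (default 6, the hexagonal first ring).
#' @param exclude cell types to leave out of the testing (leukemic columns
#'   by default); their neighborhood scores are still computed.
#' @return list: `neighborhood` (spot x type matrix of neighborhood means),
#'   `tests` (data frame cell_type, mean_hls, mean_lls, effect, p, q).
#' @export
neighborhood_enrichment <- function(scores, labels, lattice, k = 6,
                                    exclude = attr(labels, "aml_columns")) {
  scores <- as.matrix(scores)
  ids <- rownames(scores)
  if (!all(ids %in% lattice$spot_id))
    stop("lattice does not cover all scored spots", call. = FALSE)
  n <- length(ids)
  if (k >= n) stop("k must be smaller than the number of spots",
                   call. = FALSE)
  pos <- lattice[match(ids, lattice$spot_id), c("x", "y")]
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  nbscore <- matrix(0, n, ncol(scores), dimnames = dimnames(scores))
  for (i in seq_len(n))
    nbscore[i, ] <- colMeans(scores[nb[[i]], , drop = FALSE])

  lab <- labels$label[match(ids, labels$spot_id)]
  hls <- lab == "HLS"
  types <- setdiff(colnames(scores), exclude)
  tests <- do.call(rbind, lapply(types, function(t) {
    a <- nbscore[hls, t]; b <- nbscore[!hls, t]
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided")$p.value)
    if (!is.finite(p)) p <- 1  # all-tied scores
    data.frame(cell_type = t, mean_hls = mean(a), mean_lls = mean(b),
               effect = mean(a) - mean(b), p = p, stringsAsFactors = FALSE)
  }))
  tests$q <- p.adjust(tests$p, method = "BH")
  rownames(tests) <- NULL
  list(neighborhood = nbscore, tests = tests)
}

#' Pairwise co-localization correlation of cell-type scores
#'
#' Pearson correlation between all pairs of cell-type score vectors across
#' spots, annotated `"***"` when |r| > 0.7 and `"**"` when 0.5 < |r| <= 0.7.
#' Types with zero variance get `NA` correlations and no annotation.
#'
#' @param scores spot x cell-type score matrix (>= 3 spots).
#' @return list: `r` (correlation matrix), `stars` (character matrix).
#' @export
colocalization_correlation <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L) stop("need at least 3 spots", call. = FALSE)
  v <- apply(scores, 2L, stats::var)
  r <- suppressWarnings(cor(scores))
  r[v == 0, ] <- NA_real_
  r[, v == 0] <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(r) & abs(r) > 0.7] <- "***"
  stars[!is.na(r) & abs(r) > 0.5 & abs(r) <= 0.7] <- "**"
  list(r = r, stars = stars)
}
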