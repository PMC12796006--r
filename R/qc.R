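#' Per-spot quality-control metrics
#'
#' Total counts, detected genes, and mitochondrial fraction per spot.
#' Mitochondrial genes are identified by a configurable name prefix.
#'
#' @param counts gene x spot count matrix with dimnames.
#' @param mito_prefix prefix of mitochondrial gene names (default `"MT-"`).
#' @return data frame: spot_id, total_counts, n_genes_detected,
#'   mito_fraction.
#' @export
qc_metrics <- function(counts, mito_prefix = "MT-") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mito <- startsWith(rownames(counts), mito_prefix)
  total <- colSums(counts)
  data.frame(
    spot_id = colnames(counts),
    total_counts = total,
    n_genes_detected = colSums(counts > 0),
    mito_fraction = ifelse(total > 0,
                           colSums(counts[mito, , drop = FALSE]) / total, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter spots by median absolute deviation
#'
#' A spot is retained iff, for every metric, its value lies within
#' `n_mads` median absolute deviations of the metric's median across all
#' spots. Total counts and detected gene numbers are filtered on the log1p
#' scale (stabilizes their skew); mitochondrial fraction on the raw scale.
#' The MAD is unscaled (no 1.4826 consistency factor). Filtering is
#' single-pass: medians and MADs come from all input spots and are not
#' recomputed after removal, so re-applying the filter to its own output can
#' remove further spots.
#'
#' A metric with zero MAD (all spots identical on that metric) excludes
#' nothing, since every deviation is then 0 <= 0.
#'
#' @param metrics data frame from [qc_metrics()].
#' @param n_mads number of MADs; `Inf` retains everything.
#' @return list: `retained` (spot ids), `report` (data frame with one row
#'   per spot: spot_id, retained, and a logical fail flag per metric),
#'   `bounds` (per-metric median/MAD/interval, on the filtering scale).
#' @export
#' @examples
#' cts <- matrix(rpois(200, 50), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
#' mad_filter(qc_metrics(cts))$retained
mad_filter <- function(metrics, n_mads = 3) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("metrics must be a non-empty data frame", call. = FALSE)
  need <- c("spot_id", "total_counts", "n_genes_detected", "mito_fraction")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  vals <- list(total_counts = log1p(metrics$total_counts),
               n_genes_detected = log1p(metrics$n_genes_detected),
               mito_fraction = metrics$mito_fraction)
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1))))
    stop("QC metrics must be finite", call. = FALSE)

  bounds <- do.call(rbind, lapply(names(vals), function(m) {
    v <- vals[[m]]
    md <- median(v)
    dev <- mad(v, constant = 1)  # unscaled MAD
    data.frame(metric = m, center = md, mad = dev,
               lower = md - n_mads * dev, upper = md + n_mads * dev)
  }))
  fails <- vapply(names(vals), function(m) {
    b <- bounds[bounds$metric == m, ]
    thr <- n_mads * b$mad
    if (is.nan(thr)) thr <- Inf  # n_mads = Inf on a zero-MAD metric
    abs(vals[[m]] - b$center) > thr
  }, logical(nrow(metrics)))
  fails <- matrix(fails, nrow = nrow(metrics),
                  dimnames = list(NULL, paste0("fail_", names(vals))))
  keep <- rowSums(fails) == 0L
  if (!any(keep))
    stop("MAD filter removed every spot; check metric distributions ",
         "(medians: ", paste(signif(bounds$center, 3), collapse = ", "), ")",
         call. = FALSE)
  report <- cbind(data.frame(spot_id = metrics$spot_id, retained = keep,
                             stringsAsFactors = FALSE),
                  as.data.frame(fails))
  list(retained = metrics$spot_id[keep], report = report, bounds = bounds)
}

#' Depth-normalize counts and log-transform
#'
#' Scales each spot to the median total count across spots, then applies
#' log1p. A stand-in for variance-stabilizing normalization with the same
#' contract: depth-invariant, log-scale output. Spots with zero total counts
#' are left all-zero with a warning.
#'
#' @param counts gene x spot matrix of non-negative counts.
#' @param log whether to apply log1p after depth scaling (`FALSE` returns
#'   the linear depth-normalized matrix, used for linear deconvolution).
#' @return matrix of the same shape.
#' @export
normalize_log <- function(counts, log = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- colSums(counts)
  target <- median(totals)
  scale <- ifelse(totals > 0, target / totals, 0)
  if (any(totals == 0))
    warning("spot(s) with zero total counts left all-zero: ",
            paste(head(colnames(counts)[totals == 0], 5), collapse = ", "))
  out <- sweep(counts, 2L, scale, "*")
  if (log) log1p(out) else out
}
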