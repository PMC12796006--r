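#' Aggregate single-cell protein intensities to spots
#'
#' Assigns each segmented cell to a spot iff its centroid lies within the
#' spot capture disc (radius = spot diameter / 2; discs do not overlap at
#' the standard 100 um pitch). Per-cell intensities are arcsinh-transformed
#' (`asinh(intensity / cofactor)`) and averaged per spot. Cells falling in
#' the gaps between discs are reported as unassigned, not snapped. Spots
#' with no assigned cells carry `NA`, not zero.
#'
#' @param cells cell table: columns cell_id, x, y, then marker intensities.
#' @param lattice lattice data frame with `spot_diameter_um` attribute
#'   (55 um by default).
#' @param cofactor arcsinh cofactor (> 0, default 5).
#' @param markers marker columns to aggregate (default: every numeric
#'   column other than x/y).
#' @return list: `spot_protein` (data frame: spot_id, n_cells, one column
#'   per marker), `unassigned` (cell ids outside every disc).
#' @export
aggregate_cells_to_spots <- function(cells, lattice, cofactor = 5,
                                     markers = NULL) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be > 0", call. = FALSE)
  ts <- tissue_spots(lattice)
  radius <- attr(lattice, "spot_diameter_um")
  if (is.null(radius)) radius <- 55
  radius <- radius / 2
  if (is.null(markers))
    markers <- setdiff(names(cells)[vapply(cells, is.numeric, logical(1))],
                       c("x", "y"))
  if (length(markers) == 0L) stop("no marker columns found", call. = FALSE)
  if (any(!is.finite(as.matrix(cells[, markers, drop = FALSE]))) ||
      any(cells[, markers] < 0))
    stop("marker intensities must be finite and >= 0", call. = FALSE)

  n_cells_total <- nrow(cells)
  assigned <- rep(NA_integer_, n_cells_total)
  if (n_cells_total > 0L) {
    # chunked nearest-spot search keeps the distance block small
    chunk <- 2000L
    starts <- seq(1L, n_cells_total, by = chunk)
    for (s in starts) {
      idx <- s:min(s + chunk - 1L, n_cells_total)
      dx <- outer(cells$x[idx], ts$x, "-")
      dy <- outer(cells$y[idx], ts$y, "-")
      d2 <- dx * dx + dy * dy
      j <- max.col(-d2, ties.method = "first")
      ok <- d2[cbind(seq_along(idx), j)] <= radius^2
      assigned[idx[ok]] <- j[ok]
    }
  }
  unassigned <- cells$cell_id[is.na(assigned)]

  out <- data.frame(spot_id = ts$spot_id,
                    n_cells = 0L, stringsAsFactors = FALSE)
  for (m in markers) out[[m]] <- NA_real_
  hit <- !is.na(assigned)
  if (any(hit)) {
    tab <- table(factor(assigned[hit], levels = seq_len(nrow(ts))))
    out$n_cells <- as.integer(tab)
    for (m in markers) {
      v <- asinh(cells[[m]][hit] / cofactor)
      sums <- tapply(v, factor(assigned[hit], levels = seq_len(nrow(ts))),
                     sum)
      out[[m]] <- ifelse(out$n_cells > 0, as.numeric(sums) / out$n_cells,
                         NA_real_)
    }
  }
  list(spot_protein = out, unassigned = unassigned)
}

#' k-nearest-neighbor spatial weight matrix
#'
#' Binary kNN weights on Euclidean distance between tissue-spot centers
#' (self excluded; distance ties broken by spot-id order), optionally
#' row-standardized so each row sums to 1. kNN graphs are directed, so the
#' matrix need not be symmetric (a boundary spot can list an interior
#' neighbor that does not list it back).
#'
#' @param lattice lattice data frame (tissue spots are used).
#' @param k neighbors per spot (default 6, the hexagonal first ring).
#' @param row_standardize divide each row by its sum (default `TRUE`).
#' @return sparse `dgCMatrix` with spot-id dimnames; attributes `k` and
#'   `row_standardized`.
#' @export
knn_weights <- function(lattice, k = 6, row_standardize = TRUE) {
  .check_number(k, "k", positive = TRUE, integer = TRUE)
  ts <- tissue_spots(lattice)
  ts <- ts[order(ts$spot_id), ]
  n <- nrow(ts)
  if (n <= k) stop("need more spots than k", call. = FALSE)
  d <- as.matrix(dist(cbind(ts$x, ts$y)))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = unlist(nb),
    x = if (row_standardize) 1 / k else 1, dims = c(n, n),
    dimnames = list(ts$spot_id, ts$spot_id))
  attr(W, "k") <- k
  attr(W, "row_standardized") <- row_standardize
  W
}

# align x, y, W on complete common spots; re-standardize rows after subsetting
.align_lees <- function(x, y, W) {
  std <- isTRUE(attr(W, "row_standardized"))  # subsetting drops attributes
  if (is.null(names(x)) || is.null(names(y)) || is.null(rownames(W))) {
    if (length(x) != length(y) || length(x) != nrow(W))
      stop("x, y and W sizes disagree and no names to match on",
           call. = FALSE)
    ids <- seq_along(x)
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]; W <- W[keep, keep, drop = FALSE]
  } else {
    ids <- Reduce(intersect, list(names(x)[!is.na(x)], names(y)[!is.na(y)],
                                  rownames(W)))
    if (length(ids) < 3L)
      stop("fewer than 3 spots with complete x, y and weights",
           call. = FALSE)
    x <- x[ids]; y <- y[ids]; W <- W[ids, ids, drop = FALSE]
  }
  if (std) {
    rs <- Matrix::rowSums(W)
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  list(x = as.numeric(x), y = as.numeric(y), W = as.matrix(W))
}

#' Lee's L bivariate spatial association statistic
#'
#' Combines Pearson correlation with spatial smoothing by a weight matrix:
#' `L = n / sum_i (sum_j w_ij)^2 * sum_i [(W(x - xbar))_i (W(y - ybar))_i] /
#' (sqrt(sum (x - xbar)^2) * sqrt(sum (y - ybar)^2))`.
#' Symmetric in x and y and invariant to affine rescaling of either.
#' Spots with missing values are dropped pairwise (row weights are
#' re-standardized after subsetting when the matrix was row-standardized).
#'
#' @param x,y named numeric spot values.
#' @param W spatial weight matrix (see [knn_weights()]); the identity
#'   matrix makes L the ordinary Pearson correlation.
#' @return Lee's L (scalar).
#' @export
lees_l <- function(x, y, W) {
  a <- .align_lees(x, y, W)
  if (stats::var(a$x) == 0 || stats::var(a$y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  n <- length(a$x)
  xc <- a$x - mean(a$x); yc <- a$y - mean(a$y)
  wx <- as.numeric(a$W %*% xc); wy <- as.numeric(a$W %*% yc)
  s <- sum(rowSums(a$W)^2)
  (n / s) * sum(wx * wy) / (sqrt(sum(xc^2)) * sqrt(sum(yc^2)))
}

#' Permutation test for Lee's L
#'
#' Permutes `y` over spots `n_perm` times (seeded) and reports the
#' two-sided p value `(1 + #{|L_perm| >= |L_obs|}) / (n_perm + 1)`.
#'
#' @param x,y named numeric spot values.
#' @param W spatial weight matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list: `L`, `p`, `n_perm`, `null_mean`, `null_sd`.
#' @export
lees_l_permutation <- function(x, y, W, n_perm = 999, seed = 0) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("n_perm must be >= 1", call. = FALSE)
  n_perm <- as.integer(n_perm)
  a <- .align_lees(x, y, W)
  if (stats::var(a$x) == 0 || stats::var(a$y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  n <- length(a$x)
  xc <- a$x - mean(a$x); yc <- a$y - mean(a$y)
  wx <- as.numeric(a$W %*% xc)
  s <- sum(rowSums(a$W)^2)
  denom <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  L_obs <- (n / s) * sum(wx * as.numeric(a$W %*% yc)) / denom

  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) sample.int(n),
                  integer(n))
  Yc <- matrix(yc[perms], nrow = n)  # columns are permuted centered y
  WY <- a$W %*% Yc
  L_null <- (n / s) * colSums(wx * as.matrix(WY)) / denom
  p <- (1 + sum(abs(L_null) >= abs(L_obs))) / (n_perm + 1)
  list(L = L_obs, p = p, n_perm = n_perm,
       null_mean = mean(L_null), null_sd = sd(L_null))
}
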