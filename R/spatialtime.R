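#' Shortest distance from each tissue spot to the nearest bone surface
#'
#' Euclidean distance from each tissue spot center to the nearest point on
#' any trabecular polygon boundary. Spots flagged `is_bone` (centers inside
#' a polygon) are excluded from the output rather than given distance 0.
#' Distances are to the polygon boundary, not the filled interior, and the
#' computation is invariant under rigid transforms of lattice and bone
#' together.
#'
#' @param lattice lattice data frame (see [generate_lattice_and_bone()]).
#' @param bone a [bone_geometry()] with >= 1 polygon.
#' @return named numeric vector of distances (micrometers) over tissue
#'   spots.
#' @export
distance_to_bone <- function(lattice, bone) {
  stopifnot(inherits(bone, "bone_geometry"))
  if (n_polygons(bone) == 0L)
    stop("bone geometry has no polygons", call. = FALSE)
  ts <- tissue_spots(lattice)
  if (nrow(ts) == 0L) stop("no tissue spots", call. = FALSE)
  d <- rep(Inf, nrow(ts))
  for (p in bone$polygons) {
    for (i in seq_len(nrow(p) - 1L)) {
      d <- pmin(d, .dist_point_segment(ts$x, ts$y,
                                       p[i, 1], p[i, 2],
                                       p[i + 1L, 1], p[i + 1L, 2]))
    }
  }
  setNames(d, ts$spot_id)
}

# vectorized distance from points (px, py) to segment (ax,ay)-(bx,by)
.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' SpatialTime scaling and proximal/distal split
#'
#' Min-max scales bone distances to \[0, 1\] (0 = adjacent to bone,
#' 1 = furthest) and splits spots at the median distance: proximal iff
#' `d <= median(d)` (ties at the median are proximal), distal otherwise.
#'
#' @param d named vector of bone distances (micrometers), e.g. from
#'   [distance_to_bone()].
#' @return data frame: spot_id, d_um, st (scaled \[0, 1\]), side (factor
#'   proximal/distal); attribute `median_d`.
#' @export
#' @examples
#' spatialtime_scale(setNames(c(0, 50, 100), paste0("s", 1:3)))
spatialtime_scale <- function(d) {
  if (length(d) < 2L) stop("need >= 2 spots", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and >= 0", call. = FALSE)
  rng <- range(d)
  if (rng[1] == rng[2])
    stop("constant distances: SpatialTime scaling is degenerate",
         call. = FALSE)
  med <- median(d)
  out <- data.frame(
    spot_id = if (!is.null(names(d))) names(d)
              else as.character(seq_along(d)),
    d_um = as.numeric(d),
    st = (as.numeric(d) - rng[1]) / (rng[2] - rng[1]),
    side = factor(ifelse(d <= med, "proximal", "distal"),
                  levels = c("proximal", "distal")),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "median_d") <- med
  out
}

#' Bone-proximity trends of cell-state scores
#'
#' For each requested cell state: Spearman correlation of its score with
#' SpatialTime, a proximal-versus-distal two-sided rank-sum test
#' (BH-corrected across states), and mean scores over equal-count
#' SpatialTime bins (line-plot table).
#'
#' @param scores spot x cell-type score matrix.
#' @param st_annotation data frame from [spatialtime_scale()].
#' @param states score columns to analyze (default: all).
#' @param n_bins number of equal-count SpatialTime bins (default 10).
#' @return list: `trend` (state, rho, p_rho, median_proximal,
#'   median_distal, p, q), `bins` (state, bin, st_mid, mean_score, n).
#' @export
gradient_trend <- function(scores, st_annotation, states = NULL,
                           n_bins = 10) {
  scores <- as.matrix(scores)
  if (is.null(states)) states <- colnames(scores)
  if (!all(states %in% colnames(scores)))
    stop("states missing from scores: ",
         paste(setdiff(states, colnames(scores)), collapse = ", "),
         call. = FALSE)
  ids <- intersect(st_annotation$spot_id, rownames(scores))
  if (length(ids) == 0L)
    stop("no spots shared between scores and SpatialTime annotation",
         call. = FALSE)
  if (n_bins > length(ids))
    stop("n_bins exceeds the number of spots", call. = FALSE)
  st <- st_annotation[match(ids, st_annotation$spot_id), ]
  sc <- scores[ids, states, drop = FALSE]

  trend <- do.call(rbind, lapply(states, function(s) {
    ct <- suppressWarnings(cor.test(sc[, s], st$st, method = "spearman",
                                    exact = FALSE))
    prox <- st$side == "proximal"
    p <- suppressWarnings(
      wilcox.test(sc[prox, s], sc[!prox, s],
                  alternative = "two.sided")$p.value)
    if (!is.finite(p)) p <- 1  # all-tied scores
    data.frame(state = s, rho = unname(ct$estimate), p_rho = ct$p.value,
               median_proximal = median(sc[prox, s]),
               median_distal = median(sc[!prox, s]), p = p,
               stringsAsFactors = FALSE)
  }))
  trend$q <- p.adjust(trend$p, method = "BH")
  rownames(trend) <- NULL

  # equal-count bins on SpatialTime rank
  bin <- ceiling(n_bins * rank(st$st, ties.method = "first") / length(ids))
  bins <- do.call(rbind, lapply(states, function(s) {
    agg <- aggregate(list(mean_score = sc[, s], st_mid = st$st),
                     by = list(bin = bin), FUN = mean)
    agg$n <- as.integer(table(bin))
    agg$state <- s
    agg[, c("state", "bin", "st_mid", "mean_score", "n")]
  }))
  rownames(bins) <- NULL
  list(trend = trend, bins = bins)
}
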