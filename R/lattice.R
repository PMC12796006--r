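#' Trabecular bone geometry
#'
#' A set of closed polygon rings (micrometer coordinates, same frame as the
#' spot lattice) outlining trabecular bone. Rings are stored as two-column
#' matrices whose first and last vertex coincide.
#'
#' @param polygons list of numeric n x 2 matrices; each ring is closed
#'   automatically if its last vertex differs from the first.
#' @return object of class `bone_geometry`.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
#' bone_geometry(list(sq))
bone_geometry <- function(polygons) {
  if (!is.list(polygons))
    stop("polygons must be a list of n x 2 matrices", call. = FALSE)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p)))
      stop("each polygon must be a finite n x 2 matrix with >= 3 vertices",
           call. = FALSE)
    if (any(p[1L, ] != p[nrow(p), ])) p <- rbind(p, p[1L, ])
    if (.ring_self_intersects(p))
      stop("polygon ring is self-intersecting", call. = FALSE)
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
  structure(list(polygons = polygons), class = "bone_geometry")
}

#' @export
print.bone_geometry <- function(x, ...) {
  cat("bone_geometry:", length(x$polygons), "polygon(s)\n")
  invisible(x)
}

#' Number of polygons in a bone geometry
#' @param x a `bone_geometry`.
#' @export
n_polygons <- function(x) length(x$polygons)

# naive O(m^2) proper-crossing check; rings here are small (tens of vertices)
.ring_self_intersects <- function(ring) {
  m <- nrow(ring) - 1L
  if (m < 4L) return(FALSE)
  seg <- function(i) rbind(ring[i, ], ring[i + 1L, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(m - 2L)) {
    jmax <- if (i == 1L) m - 1L else m
    js <- setdiff(seq.int(i + 2L, jmax), i)
    for (j in js) {
      a <- seg(i); b <- seg(j)
      d1 <- cross(b[1, ], b[2, ], a[1, ]); d2 <- cross(b[1, ], b[2, ], a[2, ])
      d3 <- cross(a[1, ], a[2, ], b[1, ]); d4 <- cross(a[1, ], a[2, ], b[2, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Test which points fall inside bone
#'
#' Point-in-polygon test against every ring of a [bone_geometry()].
#'
#' @param bone a `bone_geometry`.
#' @param xy numeric n x 2 matrix of micrometer coordinates.
#' @return logical vector, `TRUE` where the point lies inside any polygon.
#' @export
points_in_bone <- function(bone, xy) {
  stopifnot(inherits(bone, "bone_geometry"))
  xy <- as.matrix(xy)
  inside <- rep(FALSE, nrow(xy))
  for (p in bone$polygons) {
    # mgcv::in.out expects an open or closed loop; keep the closed ring
    inside <- inside | mgcv::in.out(p, xy)
  }
  inside
}

#' Generate the hexagonal spot lattice and trabecular bone contours
#'
#' Builds a Visium-like hex-offset lattice (constant center-to-center pitch;
#' odd array rows shifted half a pitch; row spacing `pitch * sqrt(3)/2` so
#' that each interior spot has six equidistant first-ring neighbors) and
#' places seeded random trabecular blobs. Spots whose centers fall inside a
#' blob are flagged `is_bone` and are excluded from tissue analyses
#' downstream. Coordinates are micrometers, origin top-left, y increasing
#' downward.
#'
#' @param config a [sim_config()].
#' @return list with elements `lattice` (data frame: spot_id, array_row,
#'   array_col, x, y, in_tissue, is_bone; attributes `pitch_um` and
#'   `spot_diameter_um`) and `bone` (a [bone_geometry()], possibly with zero
#'   polygons when `n_bone_blobs = 0`).
#' @export
#' @examples
#' g <- generate_lattice_and_bone(sim_config(n_rows = 6, n_cols = 6, seed = 1,
#'                                           n_bone_blobs = 0))
#' nrow(g$lattice)
generate_lattice_and_bone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pitch <- config$pitch_um
  r <- rep(seq_len(config$n_rows) - 1L, each = config$n_cols)
  cc <- rep(seq_len(config$n_cols) - 1L, times = config$n_rows)
  x <- cc * pitch + (r %% 2L) * pitch / 2
  y <- r * pitch * sqrt(3) / 2
  lattice <- data.frame(
    spot_id = sprintf("spot_r%03d_c%03d", r, cc),
    array_row = r, array_col = cc, x = x, y = y,
    in_tissue = TRUE, is_bone = FALSE,
    stringsAsFactors = FALSE)

  bone <- bone_geometry(list())
  if (config$n_bone_blobs > 0L) {
    set.seed(.layer_seed(config, 11L))
    xr <- range(x); yr <- range(y)
    # trabeculae are scattered through marrow; jittered-grid placement keeps
    # blob spacing even so bone distances stay in the few-hundred-um range
    n <- config$n_bone_blobs
    gc_ <- ceiling(sqrt(n)); gr <- ceiling(n / gc_)
    cells <- head(expand.grid(gx = seq_len(gc_), gy = seq_len(gr)), n)
    wx <- (xr[2] - xr[1]) / gc_; wy <- (yr[2] - yr[1]) / gr
    polys <- vector("list", n)
    for (i in seq_len(n)) {
      cx <- xr[1] + (cells$gx[i] - runif(1, 0.25, 0.75)) * wx
      cy <- yr[1] + (cells$gy[i] - runif(1, 0.25, 0.75)) * wy
      polys[[i]] <- .random_blob(cx, cy, config$bone_radius_um)
    }
    bone <- bone_geometry(polys)
    lattice$is_bone <- points_in_bone(bone, cbind(x, y))
  }
  attr(lattice, "pitch_um") <- pitch
  attr(lattice, "spot_diameter_um") <- config$spot_diameter_um
  list(lattice = lattice, bone = bone)
}

# star-shaped blob: radial jitter around an ellipse; cannot self-intersect
.random_blob <- function(cx, cy, radius, n_vertices = 24L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  rr <- radius * runif(1, 0.7, 1.3) *
    (1 + 0.25 * sin(th * sample(2:4, 1)) + runif(n_vertices, -0.1, 0.1))
  ar <- runif(1, 0.6, 1)  # ellipse aspect
  ring <- cbind(cx + rr * cos(th), cy + ar * rr * sin(th))
  rbind(ring, ring[1L, ])
}

#' Tissue spots of a lattice
#'
#' Spots under tissue and not flagged as bone; the unit of analysis for every
#' downstream stage.
#'
#' @param lattice a lattice data frame from [generate_lattice_and_bone()].
#' @return subset of `lattice` rows.
#' @export
tissue_spots <- function(lattice) {
  lattice[lattice$in_tissue & !lattice$is_bone, , drop = FALSE]
}
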