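# Readers/writers for the standard on-disk layout: MTX counts,
# Visium-style tissue positions, GeoJSON bone contours, CSV cell tables,
# YAML configs.

#' Write counts as MatrixMarket with gene/barcode sidecars
#'
#' @param counts gene x spot matrix.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read counts written by [write_counts_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return gene x spot matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write a Visium-style tissue positions table
#'
#' Columns barcode, in_tissue, array_row, array_col, pxl_row, pxl_col, with
#' the micrometer scale, pitch and spot diameter recorded in a JSON sidecar
#' (`<path>.json`).
#'
#' @param lattice lattice data frame.
#' @param path output CSV path.
#' @param um_per_px micrometers per pixel unit used for pxl_row/pxl_col
#'   (default 1: pixels are micrometers).
#' @return `path`, invisibly.
#' @export
write_tissue_positions <- function(lattice, path, um_per_px = 1) {
  df <- data.frame(barcode = lattice$spot_id,
                   in_tissue = as.integer(lattice$in_tissue),
                   array_row = lattice$array_row,
                   array_col = lattice$array_col,
                   pxl_row = lattice$y / um_per_px,
                   pxl_col = lattice$x / um_per_px)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(um_per_px = um_per_px,
               pitch_um = attr(lattice, "pitch_um"),
               spot_diameter_um = attr(lattice, "spot_diameter_um"),
               is_bone = lattice$spot_id[lattice$is_bone])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a tissue positions table written by [write_tissue_positions()]
#'
#' @param path CSV path (expects the JSON sidecar next to it).
#' @return lattice data frame with `pitch_um`/`spot_diameter_um` attributes.
#' @export
read_tissue_positions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lattice <- data.frame(spot_id = df$barcode,
                        array_row = df$array_row,
                        array_col = df$array_col,
                        x = df$pxl_col * side$um_per_px,
                        y = df$pxl_row * side$um_per_px,
                        in_tissue = df$in_tissue == 1L,
                        is_bone = df$barcode %in% side$is_bone,
                        stringsAsFactors = FALSE)
  attr(lattice, "pitch_um") <- side$pitch_um
  attr(lattice, "spot_diameter_um") <- side$spot_diameter_um
  lattice
}

#' Write bone contours as GeoJSON polygon features
#'
#' @param bone a [bone_geometry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bone_geojson <- function(bone, path) {
  stopifnot(inherits(bone, "bone_geometry"))
  features <- lapply(bone$polygons, function(p) {
    list(type = "Feature", properties = list(kind = "trabecular_bone"),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(p, 1L, c,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read bone contours from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features (outer rings only).
#'
#' @param path GeoJSON path.
#' @return a [bone_geometry()].
#' @export
read_bone_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
  })
  bone_geometry(polys)
}

#' Write/read the cell table as CSV
#'
#' @param cells cell table data frame.
#' @param path CSV path.
#' @return `path` (write) or the cell table (read).
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write/read a simulation config as YAML
#'
#' The hotspot-center matrix and marker panel are flattened to lists; the
#' reader rebuilds a validated [sim_config()].
#'
#' @param config a [sim_config()].
#' @param path YAML path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  if (!is.null(x$hotspot_centers))
    x$hotspot_centers <- apply(x$hotspot_centers, 1L, c, simplify = FALSE)
  x$markers <- as.list(x$markers)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$hotspot_centers))
    x$hotspot_centers <- do.call(rbind, x$hotspot_centers)
  x$markers <- as.data.frame(x$markers, stringsAsFactors = FALSE)
  do.call(sim_config, x)
}
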