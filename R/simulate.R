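# Synthetic data layers: composition, counts, protein cells.
# Each layer draws from its own sub-seed so layers are independently
# reproducible under a fixed sim_config.

# Dirichlet draws with a per-row concentration matrix (n x k)
.rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  g / rowSums(g)
}

#' Inflammation field at given coordinates
#'
#' Sum of isotropic Gaussian bumps at the hotspot centers, clipped to
#' \[0, 1\]. This latent field drives committed-like leukemic enrichment and
#' inflammatory-pathway up-regulation in the generator.
#'
#' @param xy n x 2 micrometer coordinates.
#' @param centers m x 2 hotspot centers (micrometers); `NULL` or empty gives
#'   an all-zero field.
#' @param radius_um Gaussian sd of each bump.
#' @return numeric vector in \[0, 1\].
#' @export
inflammation_field <- function(xy, centers, radius_um) {
  xy <- as.matrix(xy)
  f <- numeric(nrow(xy))
  if (is.null(centers) || nrow(centers) == 0L) return(f)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xy[, 1] - centers[i, 1])^2 + (xy[, 2] - centers[i, 2])^2
    f <- f + exp(-d2 / (2 * radius_um^2))
  }
  pmin(f, 1)
}

#' Simulate per-spot cell-type composition and the inflammation field
#'
#' Draws a Dirichlet composition per tissue spot. The concentration of
#' `AML_primitive` is multiplied by `exp(-d_bone / lambda)` (bone-proximity
#' gradient; `lambda = gradient_lengthscale_um`) and that of `AML_committed`
#' by `1 + (hotspot_fold - 1) * field`, where `field` is the
#' [inflammation_field()] evaluated at the spot centers. Bone spots carry no
#' composition.
#'
#' @param lattice,bone output of [generate_lattice_and_bone()].
#' @param config a [sim_config()].
#' @return list: `composition` (tissue-spot x cell-type matrix, rows on the
#'   simplex), `field` (named vector in \[0, 1\]), `d_bone` (named distances
#'   in micrometers, `Inf` when no bone), `hotspot_centers` (matrix used).
#' @export
simulate_spot_composition <- function(lattice, bone, config) {
  stopifnot(inherits(config, "sim_config"))
  ts <- tissue_spots(lattice)
  if (nrow(ts) == 0L) stop("lattice has no tissue spots", call. = FALSE)
  lambda <- config$gradient_lengthscale_um
  if (lambda <= 0) stop("gradient length scale must be > 0", call. = FALSE)

  set.seed(.layer_seed(config, 23L))
  xy <- cbind(ts$x, ts$y)
  centers <- config$hotspot_centers
  if (is.null(centers) && config$n_hotspots > 0L) {
    centers <- cbind(runif(config$n_hotspots, min(ts$x), max(ts$x)),
                     runif(config$n_hotspots, min(ts$y), max(ts$y)))
  }
  field <- inflammation_field(xy, centers, config$hotspot_radius_um)
  names(field) <- ts$spot_id

  if (n_polygons(bone) > 0L) {
    d <- distance_to_bone(lattice, bone)
    d <- d[ts$spot_id]
  } else {
    d <- setNames(rep(Inf, nrow(ts)), ts$spot_id)
  }
  grad <- if (is.infinite(lambda)) rep(1, nrow(ts)) else {
    g <- exp(-d / lambda)
    if (all(is.infinite(d))) rep(1, nrow(ts)) else g
  }

  k <- length(config$cell_types)
  alpha <- matrix(config$dirichlet_conc, nrow = nrow(ts), ncol = k,
                  dimnames = list(ts$spot_id, config$cell_types))
  alpha[, "AML_primitive"] <- alpha[, "AML_primitive"] * grad
  alpha[, "AML_committed"] <- alpha[, "AML_committed"] *
    (1 + (config$hotspot_fold - 1) * field)
  # keep concentrations strictly positive even far from bone
  alpha <- pmax(alpha, 1e-6)
  comp <- .rdirichlet_rows(alpha)
  dimnames(comp) <- dimnames(alpha)
  list(composition = comp, field = field, d_bone = d,
       hotspot_centers = centers)
}

#' Simulate spot-level expression counts
#'
#' Counts follow a negative binomial whose mean at gene g, spot s is
#' `depth_mean * sum_t pi_st * mu_gt`, where each cell type's expression
#' profile `mu_.t` sums to one and marker genes of type t are elevated
#' `signature_fold`-fold. Genes in the seven inflammatory pathway sets are
#' further multiplied by `1 + (hotspot_fold - 1) * field_s`. An EMT set is
#' annotated but not field-driven. `nb_dispersion` is the NB size (theta);
#' `Inf` gives Poisson draws.
#'
#' @param comp tissue-spot x cell-type composition matrix (rows on simplex).
#' @param field named inflammation field over the same spots.
#' @param config a [sim_config()].
#' @return list: `counts` (gene x spot integer matrix), `gene_sets` (named
#'   list of gene-id vectors: one per cell-type signature, the seven
#'   inflammation sets, and `EMT`), `profiles` (gene x cell-type mean
#'   expression matrix, columns summing to 1).
#' @export
simulate_expression_counts <- function(comp, field, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(abs(rowSums(comp) - 1) > 1e-9))
    stop("composition rows must sum to 1", call. = FALSE)
  if (config$nb_dispersion <= 0)
    stop("nb_dispersion must be > 0", call. = FALSE)
  field <- field[rownames(comp)]

  set.seed(.layer_seed(config, 37L))
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  types <- config$cell_types
  k <- length(types)
  sig_size <- config$signature_size
  gene_sets <- list()
  idx <- 1L
  for (t in types) {
    gene_sets[[paste0("sig_", t)]] <- genes[idx:(idx + sig_size - 1L)]
    idx <- idx + sig_size
  }
  for (nm in c(inflammation_set_names(), "EMT")) {
    gene_sets[[nm]] <- genes[idx:(idx + config$pathway_set_size - 1L)]
    idx <- idx + config$pathway_set_size
  }

  mu <- matrix(1, nrow = config$n_genes, ncol = k,
               dimnames = list(genes, types))
  for (t in types)
    mu[gene_sets[[paste0("sig_", t)]], t] <- config$signature_fold
  mu <- sweep(mu, 2L, colSums(mu), "/")

  mean_mat <- config$depth_mean * (mu %*% t(comp))  # genes x spots
  inflam_genes <- unique(unlist(gene_sets[inflammation_set_names()]))
  mean_mat[inflam_genes, ] <- mean_mat[inflam_genes, ] *
    rep(1 + (config$hotspot_fold - 1) * field, each = length(inflam_genes))

  counts <- if (is.infinite(config$nb_dispersion)) {
    matrix(rpois(length(mean_mat), lambda = mean_mat), nrow = nrow(mean_mat))
  } else {
    matrix(rnbinom(length(mean_mat), mu = mean_mat,
                   size = config$nb_dispersion), nrow = nrow(mean_mat))
  }
  dimnames(counts) <- dimnames(mean_mat)
  list(counts = counts, gene_sets = gene_sets, profiles = mu)
}

#' Simulate the single-cell protein layer
#'
#' Emulates a segmented multiplex-IHC cell table matched to the spot lattice:
#' cell counts per tissue spot are Poisson, positions uniform within the spot
#' disc, and each marker's intensity is
#' `(base + loading * driver) * exp(N(0, noise_sd))` — multiplicative
#' lognormal noise around a linear response to the marker's driver (a
#' cell-type proportion, total leukemic proportion, or the inflammation
#' field).
#'
#' @param lattice lattice data frame.
#' @param comp tissue-spot x cell-type composition matrix.
#' @param field named inflammation field.
#' @param config a [sim_config()].
#' @return data frame (cell table): cell_id, spot_id (ground truth), x, y,
#'   then one column per marker.
#' @export
simulate_protein_cells <- function(lattice, comp, field, config) {
  stopifnot(inherits(config, "sim_config"))
  mk <- config$markers
  if (any(mk$base < 0))
    stop("marker base intensity must be >= 0", call. = FALSE)
  ts <- tissue_spots(lattice)
  ts <- ts[ts$spot_id %in% rownames(comp), , drop = FALSE]
  set.seed(.layer_seed(config, 53L))
  n_cells <- rpois(nrow(ts), config$cells_per_spot_mean)
  total <- sum(n_cells)
  empty <- data.frame(cell_id = character(0), spot_id = character(0),
                      x = numeric(0), y = numeric(0))
  if (total == 0L) {
    for (m in mk$name) empty[[m]] <- numeric(0)
    return(empty)
  }
  spot_idx <- rep(seq_len(nrow(ts)), n_cells)
  r <- (config$spot_diameter_um / 2) * sqrt(runif(total))
  th <- runif(total, 0, 2 * pi)
  cells <- data.frame(
    cell_id = sprintf("cell_%06d", seq_len(total)),
    spot_id = ts$spot_id[spot_idx],
    x = ts$x[spot_idx] + r * cos(th),
    y = ts$y[spot_idx] + r * sin(th),
    stringsAsFactors = FALSE)

  aml_cols <- grep("^AML_", colnames(comp), value = TRUE)
  driver_value <- function(driver) {
    if (driver == "AML_total") rowSums(comp[, aml_cols, drop = FALSE])
    else if (driver == "inflammation") field[rownames(comp)]
    else comp[, driver]
  }
  for (i in seq_len(nrow(mk))) {
    drv <- driver_value(mk$driver[i])[cells$spot_id]
    noise <- if (mk$noise_sd[i] > 0)
      exp(rnorm(total, 0, mk$noise_sd[i])) else rep(1, total)
    cells[[mk$name[i]]] <- (mk$base[i] + mk$loading[i] * drv) * noise
  }
  rownames(cells) <- NULL
  cells
}

#' Pathology-like region labels for a synthetic dataset
#'
#' Discretizes the generator's latent structure into the kind of regions a
#' pathologist would annotate: `inflamed` where the inflammation field
#' exceeds a threshold, `peri_bone` within a margin of the nearest
#' trabecular surface, `parenchyma` elsewhere. Used as the reference
#' annotation when scoring unsupervised clusters.
#'
#' @param sim output of [simulate_spot_dataset()].
#' @param field_threshold inflammation field level defining `inflamed`.
#' @param bone_margin_um bone distance (micrometers) defining `peri_bone`.
#' @return named factor over tissue spots.
#' @export
synthetic_region_labels <- function(sim, field_threshold = 0.5,
                                    bone_margin_um = 150) {
  lab <- ifelse(sim$field > field_threshold, "inflamed",
                ifelse(sim$d_bone <= bone_margin_um, "peri_bone",
                       "parenchyma"))
  factor(setNames(lab, names(sim$field)),
         levels = c("inflamed", "peri_bone", "parenchyma"))
}

#' Generate the full synthetic dataset
#'
#' Runs all generator layers in order: lattice and bone, composition and
#' inflammation field, expression counts with gene-set annotation, and the
#' protein cell table.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `lattice`, `bone`, `composition`, `field`,
#'   `d_bone`, `hotspot_centers`, `counts`, `gene_sets`, `profiles`, `cells`.
#' @export
#' @examples
#' sim <- simulate_spot_dataset(sim_config(n_rows = 8, n_cols = 8, seed = 1,
#'                                         depth_mean = 500, n_genes = 600))
#' dim(sim$counts)
simulate_spot_dataset <- function(config = sim_config()) {
  geo <- generate_lattice_and_bone(config)
  cf <- simulate_spot_composition(geo$lattice, geo$bone, config)
  expr <- simulate_expression_counts(cf$composition, cf$field, config)
  cells <- simulate_protein_cells(geo$lattice, cf$composition, cf$field,
                                  config)
  c(list(config = config), geo, cf, expr, list(cells = cells))
}
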