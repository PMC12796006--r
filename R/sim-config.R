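#' Simulation configuration for the synthetic spot dataset
#'
#' Bundles every parameter of the synthetic generator: lattice geometry,
#' cell-type panel, expression model, inflammation hotspots, bone-gradient
#' length scale and the single-cell protein layer. Defaults emulate a
#' trabecular bone-marrow section: scattered bone blobs so that most tissue
#' spots lie within a few hundred micrometers of a bone surface, a
#' bone-proximity gradient for primitive-like leukemic cells, and broad
#' inflammation hotspots enriching committed-like leukemic cells.
#'
#' @param n_rows,n_cols lattice dimensions (spots); both >= 2.
#' @param seed integer seed; the generator derives one sub-seed per layer so
#'   each layer is independently reproducible.
#' @param cell_types character vector of cell-type names. Must contain the
#'   six core types listed in the default.
#' @param n_genes total genes simulated.
#' @param signature_size marker genes per cell type (disjoint blocks).
#' @param signature_fold expression fold of a marker gene in its own type
#'   relative to baseline.
#' @param pathway_set_size genes per annotated pathway set (7 inflammatory
#'   hallmark-style sets plus one EMT set).
#' @param depth_mean expected total counts per spot.
#' @param nb_dispersion negative-binomial size parameter (theta); larger is
#'   closer to Poisson, `Inf` draws Poisson counts exactly.
#' @param pitch_um center-to-center spot pitch in micrometers.
#' @param spot_diameter_um capture-spot diameter in micrometers.
#' @param n_bone_blobs number of trabecular blobs placed in the section
#'   (0 disables bone).
#' @param bone_radius_um mean blob radius in micrometers.
#' @param hotspot_centers numeric matrix (n x 2, micrometers) of inflammation
#'   hotspot centers, or `NULL` to place `n_hotspots` at seeded random
#'   positions.
#' @param n_hotspots hotspots placed when `hotspot_centers` is `NULL`.
#' @param hotspot_radius_um Gaussian sd of each hotspot bump, micrometers.
#' @param hotspot_fold multiplicative enrichment (>= 1) at a fully
#'   inflamed spot (field = 1) for committed-like leukemic abundance and for
#'   inflammatory-pathway transcripts.
#' @param gradient_lengthscale_um decay length lambda (micrometers) of the
#'   bone-proximity factor `exp(-d/lambda)` applied to primitive-like
#'   leukemic abundance; `Inf` disables the gradient.
#' @param dirichlet_conc per-type Dirichlet concentration before spatial
#'   modulation; larger values give less spot-to-spot compositional noise.
#' @param cells_per_spot_mean Poisson mean of segmented cells per spot in the
#'   protein layer.
#' @param markers data frame describing the protein marker panel with columns
#'   `name`, `driver` (a cell-type name, `"AML_total"`, or `"inflammation"`),
#'   `loading`, `base`, `noise_sd`; `NULL` uses a six-marker default panel
#'   (CD33, CD68, CD71, IL6, CXCL12, CXCR4).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_rows = 10, n_cols = 10, seed = 1)
#' cfg$pitch_um
sim_config <- function(n_rows = 40, n_cols = 40, seed = 0,
                       cell_types = c("AML_primitive", "AML_GMP",
                                      "AML_committed", "Monocyte",
                                      "Erythroid_late", "T_CD8_naive"),
                       n_genes = 600,
                       signature_size = 25,
                       signature_fold = 8,
                       pathway_set_size = 20,
                       depth_mean = 20000,
                       nb_dispersion = 2,
                       pitch_um = 100,
                       spot_diameter_um = 55,
                       n_bone_blobs = 7,
                       bone_radius_um = 150,
                       hotspot_centers = NULL,
                       n_hotspots = 3,
                       hotspot_radius_um = 800,
                       hotspot_fold = 3,
                       gradient_lengthscale_um = 100,
                       dirichlet_conc = 8,
                       cells_per_spot_mean = 25,
                       markers = NULL) {
  .check_number(n_rows, "n_rows", positive = TRUE, integer = TRUE)
  .check_number(n_cols, "n_cols", positive = TRUE, integer = TRUE)
  if (n_rows < 2 || n_cols < 2)
    stop("lattice must be at least 2 x 2 spots", call. = FALSE)
  .check_number(seed, "seed", integer = TRUE)
  core <- c("AML_primitive", "AML_GMP", "AML_committed", "Monocyte",
            "Erythroid_late", "T_CD8_naive")
  if (!all(core %in% cell_types))
    stop("cell_types must include: ", paste(core, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cell_types))
    stop("cell_types must be unique", call. = FALSE)
  .check_number(n_genes, "n_genes", positive = TRUE, integer = TRUE)
  .check_number(signature_size, "signature_size", positive = TRUE,
                integer = TRUE)
  if (signature_fold < 1)
    stop("signature_fold must be >= 1", call. = FALSE)
  .check_number(pathway_set_size, "pathway_set_size", positive = TRUE,
                integer = TRUE)
  n_sets <- length(inflammation_set_names()) + 1L  # + EMT
  if (n_genes < length(cell_types) * signature_size +
        n_sets * pathway_set_size)
    stop("n_genes too small for the requested signature and pathway blocks",
         call. = FALSE)
  if (!is.numeric(depth_mean) || depth_mean < 0)
    stop("depth_mean must be >= 0", call. = FALSE)
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("nb_dispersion must be > 0 (use Inf for Poisson counts)",
         call. = FALSE)
  .check_number(pitch_um, "pitch_um", positive = TRUE)
  .check_number(spot_diameter_um, "spot_diameter_um", positive = TRUE)
  if (n_bone_blobs < 0)
    stop("n_bone_blobs must be >= 0", call. = FALSE)
  if (!is.null(hotspot_centers)) {
    hotspot_centers <- as.matrix(hotspot_centers)
    if (ncol(hotspot_centers) != 2L)
      stop("hotspot_centers must be an n x 2 matrix of micrometer coordinates",
           call. = FALSE)
  }
  .check_number(hotspot_radius_um, "hotspot_radius_um", positive = TRUE)
  if (hotspot_fold < 1)
    stop("hotspot_fold must be >= 1", call. = FALSE)
  if (!(is.numeric(gradient_lengthscale_um) &&
          length(gradient_lengthscale_um) == 1L &&
          gradient_lengthscale_um > 0))
    stop("gradient_lengthscale_um must be > 0 (Inf disables the gradient)",
         call. = FALSE)
  .check_number(dirichlet_conc, "dirichlet_conc", positive = TRUE)
  if (cells_per_spot_mean < 0)
    stop("cells_per_spot_mean must be >= 0", call. = FALSE)
  if (is.null(markers)) markers <- default_marker_panel()
  markers <- as.data.frame(markers)
  need <- c("name", "driver", "loading", "base", "noise_sd")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(markers$base < 0))
    stop("marker base intensity must be >= 0", call. = FALSE)
  ok_driver <- markers$driver %in% c(cell_types, "AML_total", "inflammation")
  if (!all(ok_driver))
    stop("unknown marker driver(s): ",
         paste(markers$driver[!ok_driver], collapse = ", "), call. = FALSE)

  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    seed = as.integer(seed), cell_types = cell_types,
    n_genes = as.integer(n_genes),
    signature_size = as.integer(signature_size),
    signature_fold = signature_fold,
    pathway_set_size = as.integer(pathway_set_size),
    depth_mean = depth_mean, nb_dispersion = nb_dispersion,
    pitch_um = pitch_um, spot_diameter_um = spot_diameter_um,
    n_bone_blobs = as.integer(n_bone_blobs),
    bone_radius_um = bone_radius_um,
    hotspot_centers = hotspot_centers, n_hotspots = as.integer(n_hotspots),
    hotspot_radius_um = hotspot_radius_um, hotspot_fold = hotspot_fold,
    gradient_lengthscale_um = gradient_lengthscale_um,
    dirichlet_conc = dirichlet_conc,
    cells_per_spot_mean = cells_per_spot_mean,
    markers = markers), class = "sim_config")
}

#' Names of the seven inflammation-related hallmark-style gene sets
#'
#' The default collection used for the composite inflammation score:
#' inflammatory response, IL6/JAK/STAT3 signaling, TNF-alpha/NF-kB signaling,
#' IFN-gamma response, IFN-alpha response, complement, and IL2/STAT5
#' signaling.
#'
#' @return character vector of length 7.
#' @export
inflammation_set_names <- function() {
  c("Inflammatory_response", "IL6_JAK_STAT3", "TNFa_NFkB",
    "IFN_gamma_response", "IFN_alpha_response", "Complement",
    "IL2_STAT5")
}

#' Default protein marker panel for the synthetic mfIHC layer
#'
#' Six markers mirroring a leukemia bone-marrow panel: CD33 and CXCR4 load on
#' total leukemic (AML) proportion, CD68 on monocytes, CD71 on late erythroid
#' cells, and IL6 and CXCL12 on the inflammation field.
#'
#' @return data frame with columns name, driver, loading, base, noise_sd.
#' @export
default_marker_panel <- function() {
  data.frame(
    name = c("CD33", "CD68", "CD71", "IL6", "CXCL12", "CXCR4"),
    driver = c("AML_total", "Monocyte", "Erythroid_late",
               "inflammation", "inflammation", "AML_total"),
    loading = c(1, 1, 1, 1, 0.8, 0.9),
    base = c(0.1, 0.1, 0.1, 0.05, 0.05, 0.1),
    noise_sd = 0.1,
    stringsAsFactors = FALSE)
}

# layer-specific sub-seeds, kept within 32-bit integer range
.layer_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) * 7L + offset) %% .Machine$integer.max)
}
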