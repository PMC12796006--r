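# Shared fixtures (computed once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# default synthetic dataset, seed 1
default_sim <- function() .memo("sim", function() {
  simulate_spot_dataset(sim_config(seed = 1))
})

# linear depth-normalized matrix of the default dataset
default_linear <- function() .memo("linear", function() {
  normalize_log(default_sim()$counts, log = FALSE)
})

# NNLS scores of the default dataset against the generator's true profiles
default_scores <- function() .memo("scores", function() {
  sim <- default_sim()
  nnls_deconvolve(default_linear(), sim$profiles * sim$config$depth_mean)
})

# SpatialTime annotation of the default dataset
default_stann <- function() .memo("stann", function() {
  sim <- default_sim()
  spatialtime_scale(distance_to_bone(sim$lattice, sim$bone))
})

# minimal hand-built lattice for geometry tests
toy_lattice <- function(x, y, is_bone = FALSE) {
  n <- length(x)
  df <- data.frame(spot_id = sprintf("s%02d", seq_len(n)),
                   array_row = 0L, array_col = seq_len(n) - 1L,
                   x = x, y = y, in_tissue = TRUE,
                   is_bone = rep_len(is_bone, n),
                   stringsAsFactors = FALSE)
  attr(df, "pitch_um") <- 100
  attr(df, "spot_diameter_um") <- 55
  df
}

# exhaustive Jenks oracle: minimum within-class SSD over all ways to cut the
# sorted vector into k contiguous non-empty blocks
jenks_oracle_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssd(x))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(i) ssd(x[(b[i] + 1):b[i + 1]]),
                      numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# literal double-sum Lee's L
lees_l_oracle <- function(x, y, W) {
  W <- as.matrix(W)
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  num <- 0; s <- 0
  for (i in seq_len(n)) {
    wx <- 0; wy <- 0; wsum <- 0
    for (j in seq_len(n)) {
      wx <- wx + W[i, j] * xc[j]
      wy <- wy + W[i, j] * yc[j]
      wsum <- wsum + W[i, j]
    }
    num <- num + wx * wy
    s <- s + wsum^2
  }
  unname((n / s) * num / (sqrt(sum(xc^2)) * sqrt(sum(yc^2))))
}

# two-type mixture fixture for deconvolution tests: NB counts at given
# depth/dispersion from known proportions
mixture_fixture <- function(n_spots, seed, depth = 20000, theta = 2) {
  set.seed(seed)
  n_genes <- 300
  genes <- sprintf("g%03d", seq_len(n_genes))
  types <- c("A", "B", "C")
  mu <- matrix(1, n_genes, 3, dimnames = list(genes, types))
  mu[1:30, 1] <- 8; mu[31:60, 2] <- 8; mu[61:90, 3] <- 8
  mu <- sweep(mu, 2, colSums(mu), "/")
  pi_true <- t(vapply(seq_len(n_spots), function(i) {
    g <- rgamma(3, shape = 4); g / sum(g)
  }, numeric(3)))
  colnames(pi_true) <- types
  rownames(pi_true) <- sprintf("sp%04d", seq_len(n_spots))
  mean_mat <- depth * (mu %*% t(pi_true))
  counts <- matrix(rnbinom(length(mean_mat), mu = mean_mat, size = theta),
                   nrow = n_genes, dimnames = dimnames(mean_mat))
  list(counts = counts, mu = mu, pi_true = pi_true, depth = depth)
}
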