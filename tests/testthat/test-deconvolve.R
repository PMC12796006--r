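test_that("reference signatures: means, duplication, marker selection", {
  set.seed(3)
  prof <- matrix(runif(40), nrow = 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  types <- c("A", "B", "A", "B")
  sig <- build_reference_signatures(prof, types)
  expect_equal(sig[, "A"], rowMeans(prof[, c(1, 3)]))
  # one profile per type: signatures equal the profiles
  sig1 <- build_reference_signatures(prof[, 1:2], c("A", "B"))
  expect_equal(unname(sig1), unname(prof[, 1:2]))
  # duplicated profiles change nothing
  sig2 <- build_reference_signatures(prof[, c(1, 1, 2, 2)],
                                     c("A", "A", "B", "B"))
  expect_equal(sig2, sig1)
  # marker selection keeps exactly N genes per type, the top by fold change
  sigm <- build_reference_signatures(prof[, 1:2], c("A", "B"), n_markers = 5)
  mk <- attr(sigm, "markers")
  expect_equal(lengths(mk), c(A = 5L, B = 5L))
  fcA <- (sig1[, "A"] + 1e-8) / (sig1[, "B"] + 1e-8)
  expect_setequal(mk$A, names(sort(fcA, decreasing = TRUE))[1:5])
  expect_error(build_reference_signatures(prof, rep("A", 4)), "2 cell types")
})

test_that("NNLS recovers noiseless mixtures exactly", {
  set.seed(5)
  ref <- matrix(runif(300, 0, 10), nrow = 100,
                dimnames = list(paste0("g", 1:100), c("A", "B", "C")))
  y <- cbind(pure = ref[, "A"],
             mix = 0.6 * ref[, "A"] + 0.4 * ref[, "B"])
  sc <- nnls_deconvolve(y, ref, min_genes = 50)
  expect_equal(unname(sc["pure", ]), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(unname(sc["mix", ]), c(0.6, 0.4, 0), tolerance = 1e-6)
  expect_error(nnls_deconvolve(y[1:30, ], ref, min_genes = 50), "30")
})

test_that("NNLS beats every single-signature and simplex-grid fit", {
  set.seed(6)
  ref <- matrix(runif(60, 0, 5), nrow = 30,
                dimnames = list(paste0("g", 1:30), c("A", "B")))
  y <- 0.3 * ref[, "A"] + 0.7 * ref[, "B"] + rnorm(30, 0, 0.3)
  y <- pmax(y, 0)
  ym <- matrix(y, ncol = 1, dimnames = list(rownames(ref), "s1"))
  raw <- nnls_deconvolve(ym, ref, min_genes = 10, normalize = FALSE)
  res_nnls <- sum((y - ref %*% raw[1, ])^2)
  # grid over the simplex at 0.01 resolution, each with its optimal scale
  res_grid <- vapply(seq(0, 1, by = 0.01), function(w) {
    v <- ref %*% c(w, 1 - w)
    cc <- max(0, sum(v * y) / sum(v * v))
    sum((y - cc * v)^2)
  }, numeric(1))
  expect_lte(res_nnls, min(res_grid) + 1e-9)
})

test_that("HLS/LLS stratification follows the strict median rule", {
  sc <- matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1,
               dimnames = list(paste0("s", 1:4), "AML"))
  lab <- classify_hls_lls(sc, "AML")
  expect_equal(attr(lab, "threshold"), 0.25)
  expect_equal(lab$spot_id[lab$label == "HLS"], c("s3", "s4"))
  # ties at the median go to LLS; all-equal scores are all LLS
  sc2 <- matrix(rep(0.5, 6), ncol = 1,
                dimnames = list(paste0("s", 1:6), "AML"))
  lab2 <- classify_hls_lls(sc2, "AML")
  expect_true(all(lab2$label == "LLS"))
  # partition properties on distinct scores
  sim_sc <- default_scores()
  aml_cols <- grep("^AML_", colnames(sim_sc), value = TRUE)
  lab3 <- classify_hls_lls(sim_sc, aml_cols)
  expect_lte(sum(lab3$label == "HLS"), ceiling(nrow(sim_sc) / 2))
  expect_equal(sort(lab3$spot_id), sort(rownames(sim_sc)))
  expect_error(classify_hls_lls(sc, character(0)), "at least one")
})

test_that("differential co-localization: exact p, planted enrichment, guards", {
  # [1,2,3] vs [101,102,103]: exact two-sided rank-sum p = 0.1
  sc <- matrix(c(1, 2, 3, 101, 102, 103, rep(1, 6)), ncol = 2,
               dimnames = list(paste0("s", 1:6), c("Mono", "AML")))
  lab <- classify_hls_lls(
    matrix(c(rep(1, 3), rep(0, 3)), ncol = 1,
           dimnames = list(paste0("s", 1:6), "AML")), "AML")
  res <- differential_colocalization(sc, lab, exclude = "AML")
  expect_equal(res$p[res$cell_type == "Mono"], 0.1)
  expect_lt(res$effect[res$cell_type == "Mono"], 0)  # HLS spots hold 1,2,3

  # planted monocyte enrichment in HLS spots is recovered
  set.seed(8)
  n <- 200
  aml <- runif(n)
  mono <- pmin(pmax(0.2 * aml + rnorm(n, 0, 0.05), 0), 1)
  tcell <- runif(n, 0, 0.3)
  scores <- cbind(AML = aml, Monocyte = mono, T_CD8 = tcell)
  rownames(scores) <- sprintf("s%03d", 1:n)
  labs <- classify_hls_lls(scores, "AML")
  res2 <- differential_colocalization(scores, labs)
  expect_lt(res2$q[res2$cell_type == "Monocyte"], 0.05)
  expect_gt(res2$effect[res2$cell_type == "Monocyte"], 0)
  expect_gt(res2$q[res2$cell_type == "T_CD8"], 0.05)

  # groups below 3 spots: warning and p = 1
  small <- scores[1:4, ]
  lab4 <- classify_hls_lls(small, "AML")
  expect_warning(res3 <- differential_colocalization(small, lab4),
                 "fewer than 3")
  expect_true(all(res3$p == 1))
})

test_that("neighborhood enrichment sees planted co-localization, not noise", {
  sim <- default_sim()
  sc <- default_scores()
  aml_cols <- grep("^AML_", colnames(sc), value = TRUE)
  labs <- classify_hls_lls(sc, aml_cols)

  # spatially constant scores: nothing significant
  const <- matrix(0.25, nrow(sc), 4,
                  dimnames = list(rownames(sc), c("a", "b", "c", "d")))
  ne0 <- neighborhood_enrichment(const, labs, sim$lattice, k = 6,
                                 exclude = character(0))
  expect_true(all(ne0$tests$q >= 0.05))

  # k = 1 on a 2-spot lattice: the neighborhood is the other spot
  lat2 <- toy_lattice(c(0, 100), c(0, 0))
  sc2 <- matrix(c(0.2, 0.8, 0.8, 0.2), 2,
                dimnames = list(lat2$spot_id, c("AML", "Mono")))
  lab2 <- classify_hls_lls(sc2, "AML")
  ne2 <- neighborhood_enrichment(sc2, lab2, lat2, k = 1,
                                 exclude = character(0))
  expect_equal(unname(ne2$neighborhood[1, ]), unname(sc2[2, ]))
  expect_equal(unname(ne2$neighborhood[2, ]), unname(sc2[1, ]))
  expect_error(neighborhood_enrichment(sc2, lab2, lat2, k = 2), "smaller")

  # committed-like leukemic spots cluster in hotspots together with the
  # inflammation-driven microenvironment: its neighborhood enrichment around
  # HLS spots must be detected on the default dataset
  ne <- neighborhood_enrichment(sc, labs, sim$lattice, k = 6,
                                exclude = setdiff(colnames(sc),
                                                  "AML_committed"))
  expect_lt(ne$tests$q[ne$tests$cell_type == "AML_committed"], 0.05)
})

test_that("co-localization correlation stars follow the |r| thresholds", {
  set.seed(10)
  n <- 1000
  x <- rnorm(n)
  z <- rnorm(n)
  # construct a pair with sample r exactly 0.6
  zx <- resid(lm(z ~ x))
  y <- 0.6 * scale(x)[, 1] + sqrt(1 - 0.36) * scale(zx)[, 1]
  indep <- rnorm(n)
  sc <- cbind(A = x, B = y, C = indep)
  rownames(sc) <- sprintf("s%04d", 1:n)
  cc <- colocalization_correlation(sc)
  expect_equal(diag(cc$r), c(A = 1, B = 1, C = 1))
  expect_equal(diag(cc$stars), c(A = "***", B = "***", C = "***"))
  expect_equal(cc$r["A", "B"], 0.6, tolerance = 1e-10)
  expect_equal(cc$stars["A", "B"], "**")
  expect_lt(abs(cc$r["A", "C"]), 0.1)
  expect_equal(cc$stars["A", "C"], "")
  # zero-variance type reported as missing
  sc2 <- cbind(sc, D = rep(1, n))
  cc2 <- colocalization_correlation(sc2)
  expect_true(all(is.na(cc2$r["D", ])))
  expect_error(colocalization_correlation(sc[1:2, ]), "3 spots")
})
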