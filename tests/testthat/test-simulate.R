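test_that("composition rows lie on the simplex and are seeded", {
  sim <- default_sim()
  expect_true(all(abs(rowSums(sim$composition) - 1) < 1e-9))
  expect_true(all(sim$composition >= 0))
  expect_true(all(sim$field >= 0 & sim$field <= 1))
  # full determinism of every layer
  sim2 <- simulate_spot_dataset(sim_config(seed = 1))
  expect_identical(sim$composition, sim2$composition)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$cells, sim2$cells)
})

test_that("disabled effects give compositions with no spatial trend", {
  cfg <- sim_config(n_rows = 33, n_cols = 33, seed = 5,
                    hotspot_fold = 1, gradient_lengthscale_um = Inf,
                    n_bone_blobs = 4)
  g <- generate_lattice_and_bone(cfg)
  cf <- simulate_spot_composition(g$lattice, g$bone, cfg)
  expect_gt(nrow(cf$composition), 900)
  rho <- cor(cf$composition[, "AML_primitive"], cf$d_bone,
             method = "spearman")
  expect_lt(abs(rho), 0.1)
  rho_c <- cor(cf$composition[, "AML_committed"], cf$field,
               method = "spearman")
  expect_lt(abs(rho_c), 0.1)
})

test_that("planted bone gradient is visible in the generated truth", {
  sim <- default_sim()  # lambda = 100 um
  rho <- cor(sim$composition[, "AML_primitive"], sim$d_bone,
             method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("region labels discretize the latent fields consistently", {
  sim <- default_sim()
  reg <- synthetic_region_labels(sim)
  expect_equal(length(reg), nrow(sim$composition))
  expect_true(all(sim$field[reg == "inflamed"] > 0.5))
  expect_true(all(sim$d_bone[reg == "peri_bone"] <= 150))
  expect_gt(min(table(reg)), 0)
})

test_that("expression counts: zero depth, Poisson limit, hotspot fold", {
  sim <- default_sim()
  cfg0 <- sim_config(seed = 1, depth_mean = 0)
  z <- simulate_expression_counts(sim$composition, sim$field, cfg0)
  expect_true(all(z$counts == 0))

  # Poisson limit: sample mean over 10,000 replicate spots vs analytic mean
  cfg <- sim_config(seed = 2, nb_dispersion = Inf, depth_mean = 1000)
  comp <- matrix(0, 10000, length(cfg$cell_types),
                 dimnames = list(sprintf("r%05d", 1:10000), cfg$cell_types))
  comp[, "AML_primitive"] <- 1
  field <- setNames(rep(0, 10000), rownames(comp))
  ex <- simulate_expression_counts(comp, field, cfg)
  expect_true(all(ex$counts == floor(ex$counts)) && all(ex$counts >= 0))
  marker <- ex$gene_sets[["sig_AML_primitive"]][1]
  analytic <- 1000 * ex$profiles[marker, "AML_primitive"]
  expect_lt(abs(mean(ex$counts[marker, ]) / analytic - 1), 0.02)

  # pathway genes at field = 1 have hotspot_fold times the field = 0 mean
  comp2 <- comp[1:2000, , drop = FALSE]
  field2 <- setNames(rep(c(0, 1), each = 1000), rownames(comp2))
  cfg2 <- sim_config(seed = 3, nb_dispersion = Inf, depth_mean = 5000,
                     hotspot_fold = 3)
  ex2 <- simulate_expression_counts(comp2, field2, cfg2)
  pg <- unique(unlist(ex2$gene_sets[inflammation_set_names()]))
  ratio <- mean(ex2$counts[pg, field2 == 1]) / mean(ex2$counts[pg, field2 == 0])
  expect_lt(abs(ratio / 3 - 1), 0.05)
})

test_that("count simulation validates its inputs", {
  sim <- default_sim()
  bad <- sim$composition
  bad[1, ] <- bad[1, ] * 2
  expect_error(simulate_expression_counts(bad, sim$field, sim$config),
               "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("protein layer: empty table, exact driver, planted correlation", {
  sim <- default_sim()
  cfg0 <- sim_config(seed = 1, cells_per_spot_mean = 0)
  empty <- simulate_protein_cells(sim$lattice, sim$composition, sim$field,
                                  cfg0)
  expect_equal(nrow(empty), 0)
  expect_true(all(sim$config$markers$name %in% names(empty)))

  # zero noise, loading 1, base 0: per-spot mean intensity == driver exactly
  mk <- data.frame(name = "M", driver = "AML_total", loading = 1, base = 0,
                   noise_sd = 0)
  cfg <- sim_config(seed = 4, n_rows = 8, n_cols = 8, n_bone_blobs = 0,
                    markers = mk, cells_per_spot_mean = 10)
  g <- generate_lattice_and_bone(cfg)
  cf <- simulate_spot_composition(g$lattice, g$bone, cfg)
  cells <- simulate_protein_cells(g$lattice, cf$composition, cf$field, cfg)
  driver <- rowSums(cf$composition[, grep("^AML_", colnames(cf$composition)),
                                   drop = FALSE])
  per_spot <- tapply(cells$M, cells$spot_id, mean)
  expect_equal(as.numeric(per_spot),
               unname(driver[names(per_spot)]), tolerance = 1e-12)

  # CD33-like marker tracks total AML proportion at noise sd 0.1
  agg <- tapply(sim$cells$CD33, sim$cells$spot_id, mean)
  aml <- rowSums(sim$composition[, grep("^AML_",
                                        colnames(sim$composition))])
  shared <- intersect(names(agg), names(aml))
  expect_gt(cor(agg[shared], aml[shared]), 0.8)

  expect_error(sim_config(markers = data.frame(
    name = "M", driver = "AML_total", loading = 1, base = -1,
    noise_sd = 0)), "base")
})
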