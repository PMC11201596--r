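# Synthetic-cohort generator: one-factor battery structure, planted edge
# recovery, positive-definite repair, receptor-atlas planting.

test_that("one-factor battery reproduces the closed-form PC1 variance", {
  # variance explained of a one-factor correlation model: (1 + (m-1) lambda^2) / m
  cfg <- sim_config(n_subjects = 2000, n_nodes = 10, factor_loading = 0.677,
                    planted_pos_edges = matrix(integer(0), 0, 2),
                    planted_neg_edges = matrix(integer(0), 0, 2), seed = 42)
  beh <- simulate_behavior(cfg)
  X <- as.matrix(beh$measures[drinking_measure_names()])
  ve <- 100 * eigen(cor(X), symmetric = TRUE)$values[1] / 15
  closed_form <- 100 * (1 + 14 * 0.677^2) / 15
  expect_equal(closed_form, 49.5, tolerance = 0.01)
  expect_gt(ve, 47.5)
  expect_lt(ve, 51.5)
})

test_that("degenerate factor loadings give the expected spectra", {
  cfg1 <- null_config(300, 10, seed = 7, factor_loading = 1)
  X1 <- as.matrix(simulate_behavior(cfg1)$measures[drinking_measure_names()])
  ve1 <- 100 * eigen(cor(X1), symmetric = TRUE)$values[1] / 15
  expect_equal(ve1, 100, tolerance = 1e-8)

  cfg0 <- null_config(2000, 10, seed = 8, factor_loading = 0)
  X0 <- as.matrix(simulate_behavior(cfg0)$measures[drinking_measure_names()])
  ve0 <- 100 * eigen(cor(X0), symmetric = TRUE)$values[1] / 15
  expect_lt(abs(ve0 - 100 / 15), 1.5)
})

test_that("invalid generator parameters are rejected", {
  expect_error(sim_config(factor_loading = 1.2), class = "netfp_parameter_error")
  expect_error(sim_config(frames_per_block = 0), class = "netfp_parameter_error")
  expect_error(sim_config(base_connectivity = 0.5, effect_size = 0.2),
               class = "netfp_parameter_error")  # 3-SD margin violated
  expect_error(
    sim_config(planted_pos_edges = cbind(1, 2), planted_neg_edges = cbind(1, 2)),
    class = "netfp_parameter_error")
  cfg <- sim_config(n_subjects = 10, n_nodes = 10,
                    planted_pos_edges = cbind(1, 2), planted_neg_edges = cbind(3, 4))
  expect_error(simulate_timeseries(cfg, rnorm(3)), class = "netfp_parameter_error")
})

test_that("generation is seed-deterministic", {
  cfg <- sim_config(n_subjects = 20, n_nodes = 12,
                    planted_pos_edges = cbind(1, 2), planted_neg_edges = cbind(3, 4),
                    seed = 5)
  a <- simulate_behavior(cfg)
  b <- simulate_behavior(cfg)
  expect_identical(a$measures, b$measures)
  expect_false(identical(
    simulate_behavior(cfg, seed = 6)$measures, a$measures))
  s1 <- simulate_timeseries(cfg, a$ground_truth$latent_severity)
  s2 <- simulate_timeseries(cfg, a$ground_truth$latent_severity)
  expect_identical(s1$series, s2$series)
})

test_that("without planted effects, edge-severity correlations are null", {
  cfg <- null_config(400, 20, seed = 21)
  coh <- simulate_cohort(cfg, conditions = "reward")
  stats <- edge_behavior_correlation(coh$connectivity$reward,
                                     coh$ground_truth$latent_severity)
  expect_gte(mean(abs(stats$r) < 3 / sqrt(400)), 0.99)
})

test_that("a planted edge's sample correlation tracks severity", {
  cfg <- sim_config(n_subjects = 500, n_nodes = 6, frames_per_block = 100,
                    n_blocks_per_condition = 4,
                    planted_pos_edges = cbind(1, 2),
                    planted_neg_edges = matrix(integer(0), 0, 2),
                    effect_size = 0.2, base_connectivity = 0.2,
                    coupling = 1, seed = 13)
  sev <- withr::with_seed(99, rnorm(500))
  ts <- simulate_timeseries(cfg, sev)
  edge_r <- vapply(ts$series, function(s) cor(s$reward[, 1], s$reward[, 2]),
                   numeric(1))
  expect_gte(cor(edge_r, sev), 0.25)
})

test_that("planted-edge recovery improves with scan length", {
  sev <- withr::with_seed(31, rnorm(300))
  recovered <- vapply(c(5, 15, 60), function(fpb) {
    cfg <- sim_config(n_subjects = 300, n_nodes = 4, frames_per_block = fpb,
                      n_blocks_per_condition = 4,
                      planted_pos_edges = cbind(1, 2),
                      planted_neg_edges = matrix(integer(0), 0, 2),
                      effect_size = 0.2, base_connectivity = 0.2,
                      coupling = 1, seed = 77)
    ts <- simulate_timeseries(cfg, sev)
    edge_r <- vapply(ts$series, function(s) cor(s$reward[, 1], s$reward[, 2]),
                     numeric(1))
    cor(edge_r, sev)
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
})

test_that("planted-edge recovery error shrinks with cohort size", {
  # attenuation oracle: expected cor(edge_r, severity) = e / sqrt(e^2 + sigma^2)
  mk_err <- function(n, seed) {
    cfg <- sim_config(n_subjects = n, n_nodes = 4, frames_per_block = 15,
                      n_blocks_per_condition = 4,
                      planted_pos_edges = cbind(1, 2),
                      planted_neg_edges = matrix(integer(0), 0, 2),
                      effect_size = 0.2, base_connectivity = 0.2,
                      coupling = 1, seed = seed)
    sev <- withr::with_seed(seed + 1000, rnorm(n))
    ts <- simulate_timeseries(cfg, sev)
    edge_r <- vapply(ts$series, function(s) cor(s$reward[, 1], s$reward[, 2]),
                     numeric(1))
    expected <- cfg$effect_size /
      sqrt(cfg$effect_size^2 + ((1 - cfg$base_connectivity^2) / sqrt(60 - 1))^2)
    abs(cor(edge_r, sev) - expected)
  }
  med_err <- vapply(c(100, 400, 1600), function(n) {
    stats::median(vapply(1:5, function(s) mk_err(n, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("positive-definite repair clips, renormalizes, and is idempotent", {
  C <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.3, 0.2, 0.3, 1), 3)
  expect_equal(make_positive_definite(C), C, tolerance = 1e-12)
  expect_equal(make_positive_definite(diag(4)), diag(4))

  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)  # one negative eigenvalue
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  fixed <- make_positive_definite(bad)
  expect_true(isSymmetric(fixed))
  expect_equal(diag(fixed), rep(1, 3))
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 1e-6 * (1 - 1e-8))
  # change bounded relative to the nearest-PD reference (independent oracle)
  ref <- as.matrix(Matrix::nearPD(bad, corr = TRUE)$mat)
  expect_lte(max(abs(fixed - bad)), 2 * max(abs(ref - bad)) + 1e-8)
  expect_error(make_positive_definite(matrix(1:9, 3)), class = "netfp_parameter_error")
})

test_that("receptor atlas plants spatial associations and rescales exactly", {
  rec <- simulate_receptor_atlas(n_regions = 119,
                                 planted = c("GABAa_2" = 0.9), seed = 3)
  gray <- rec$receptors[rec$receptors$tissue_class == "gray", ]
  expect_gte(cor(gray[["GABAa_2"]], rec$tmap$t), 0.8)
  for (nm in receptor_map_names()) {
    expect_equal(min(rec$receptors[[nm]]), 0)
    expect_equal(max(rec$receptors[[nm]]), 100)
  }
  expect_equal(nrow(rec$receptors), 119 + 6)
  expect_setequal(unique(rec$receptors$tissue_class), c("gray", "white", "csf"))
  expect_error(simulate_receptor_atlas(map_names = c("A", "A")),
               class = "netfp_parameter_error")
  expect_error(simulate_receptor_atlas(n_regions = 5),
               class = "netfp_parameter_error")
})

test_that("unplanted receptor maps are calibrated at the nominal false-positive rate", {
  hits <- vapply(1:200, function(s) {
    rec <- simulate_receptor_atlas(n_regions = 60, map_names = paste0("m", 1:27),
                                   planted = c(), n_white = 0, n_csf = 0, seed = s)
    sc <- spatial_correlation(rec$tmap, rec$receptors)
    sum(sc$flagged)
  }, numeric(1))
  frac <- sum(hits) / (200 * 27)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})
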