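# CPM: edge statistics, selection, strengths, cross-validation,
# permutation inference, leakage and monotonicity properties.

random_edge_cohort <- function(n_subjects, n_nodes, seed) {
  n_edges <- n_nodes * (n_nodes - 1) / 2
  E <- withr::with_seed(seed, matrix(rnorm(n_subjects * n_edges), n_subjects, n_edges))
  attr(E, "n_nodes") <- n_nodes
  E
}

test_that("behaviour equal to one edge gives that edge r = 1", {
  E <- random_edge_cohort(40, 8, seed = 1)
  stats <- edge_behavior_correlation(E, E[, 7])
  expect_equal(stats$r[7], 1, tolerance = 1e-10)
  expect_true(all(abs(stats$r[-7]) < 1))
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  n <- 50
  E <- random_edge_cohort(n, 20, seed = 2)
  withr::with_seed(3, {
    y <- rnorm(n)
    covs <- data.frame(age = rnorm(n, 28, 3), sex = rbinom(n, 1, 0.5))
  })
  stats <- edge_behavior_correlation(E, y, covs)
  # oracle: per edge, lm() residuals of both sides, then cor() + cor.test df
  yr <- stats::residuals(lm(y ~ age + sex, data = covs))
  for (e in sample(ncol(E), 25)) {
    er <- stats::residuals(lm(E[, e] ~ age + sex, data = covs))
    r_o <- cor(er, yr)
    expect_equal(stats$r[e], r_o, tolerance = 1e-10)
    t_o <- r_o * sqrt(n - 4) / sqrt(1 - r_o^2)
    expect_equal(stats$p[e], 2 * pt(-abs(t_o), n - 4), tolerance = 1e-10)
  }
})

test_that("covariates orthogonal to both sides leave the correlation unchanged", {
  n <- 60
  E <- random_edge_cohort(n, 5, seed = 4)
  y <- withr::with_seed(5, rnorm(n))
  raw_cov <- withr::with_seed(6, rnorm(n))
  # orthogonalize the covariate against intercept, behaviour and every edge
  cov_orth <- qr.resid(qr(cbind(1, y, E)), raw_cov)
  simple <- edge_behavior_correlation(E, y)
  partial <- edge_behavior_correlation(E, y, covariates = cbind(c1 = cov_orth))
  expect_equal(partial$r, simple$r, tolerance = 1e-10)
})

test_that("edge p-values are calibrated under permuted behaviour", {
  n <- 80
  E <- random_edge_cohort(n, 20, seed = 7)
  y <- withr::with_seed(8, rnorm(n))
  hits <- withr::with_seed(9, {
    vapply(1:200, function(i) {
      sum(edge_behavior_correlation(E, sample(y))$p < 0.01)
    }, numeric(1))
  })
  frac <- sum(hits) / (200 * ncol(E))
  expect_gt(frac, 0.006)
  expect_lt(frac, 0.015)
})

test_that("selection splits by sign and matches the null expectation", {
  E <- random_edge_cohort(30, 6, seed = 10)
  y <- withr::with_seed(11, rnorm(30))
  stats <- edge_behavior_correlation(E, y)
  mask <- select_edges(stats, p_threshold = 0.999999)
  expect_equal(nrow(mask$positive) + nrow(mask$negative), nrow(stats))
  expect_true(all(stats$r[match(mask_key(mask$positive),
                                paste(stats$node_i, stats$node_j))] > 0))

  # null cohort at the 268-node scale: expected alpha * 35,778 selections
  E_null <- random_edge_cohort(200, 268, seed = 12)
  y_null <- withr::with_seed(13, rnorm(200))
  m_null <- select_edges(edge_behavior_correlation(E_null, y_null), 0.01)
  n_sel <- nrow(m_null$positive) + nrow(m_null$negative)
  expect_gt(n_sel, 358 - 3.5 * sqrt(358))
  expect_lt(n_sel, 358 + 3.5 * sqrt(358))

  expect_error(select_edges(stats, 0), class = "netfp_parameter_error")
})

test_that("planted edges are recovered with their signs", {
  cfg <- sim_config(n_subjects = 200, n_nodes = 30, frames_per_block = 38,
                    planted_pos_edges = rbind(c(1, 2), c(3, 4), c(5, 6)),
                    planted_neg_edges = rbind(c(7, 8), c(9, 10), c(11, 12)),
                    coupling = 1, seed = 14)
  coh <- simulate_cohort(cfg, conditions = "reward")
  stats <- edge_behavior_correlation(coh$connectivity$reward,
                                     coh$ground_truth$latent_severity)
  mask <- select_edges(stats, 0.01)
  gt <- coh$ground_truth
  expect_gte(mask_sensitivity(mask, gt), 0.85)
  expect_equal(mask_sign_errors(mask, gt), 0)
})

test_that("network strengths sum selected edge values", {
  m <- withr::with_seed(15, {
    a <- matrix(rnorm(100), 10)
    (a + t(a)) / 2
  })
  diag(m) <- 1
  empty <- edge_mask()
  expect_equal(network_strength(m, empty),
               c(pos_strength = 0, neg_strength = 0))
  single <- edge_mask(positive = cbind(2, 5))
  m[2, 5] <- m[5, 2] <- 0.37
  expect_equal(network_strength(m, single)[["pos_strength"]], 0.37)

  mask <- edge_mask(positive = rbind(c(1, 2), c(3, 7)),
                    negative = rbind(c(2, 9), c(4, 5), c(6, 10)))
  got <- network_strength(m, mask)
  oracle_pos <- m[1, 2] + m[3, 7]
  oracle_neg <- m[2, 9] + m[4, 5] + m[6, 10]
  expect_equal(got[["pos_strength"]], oracle_pos, tolerance = 1e-12)
  expect_equal(got[["neg_strength"]], oracle_neg, tolerance = 1e-12)

  strengths <- network_strengths(random_edge_cohort(5, 10, 16), mask)
  expect_equal(nrow(strengths), 5)
})

test_that("a perfect single-edge signal is predicted almost exactly", {
  E <- random_edge_cohort(60, 10, seed = 17)
  y <- E[, 11]
  fit <- cpm_fit(E, y, scheme = "loocv", p_threshold = 0.01)
  expect_gte(fit$r, 0.99)
  expect_equal(nrow(fit$predictions), 60)
  expect_true(all(is.finite(fit$predictions$predicted)))
})

test_that("edge selection is strictly training-fold-internal", {
  n <- 60
  E <- random_edge_cohort(n, 12, seed = 18)
  y <- withr::with_seed(19, E[, 3] * 0.5 + rnorm(n))
  fit <- cpm_fit(E, y, scheme = "kfold", k = 5, repeats = 1, seed = 20,
                 p_threshold = 0.05)
  folds <- lapply(seq_len(5), function(f) {
    which(withr::with_seed(netfingerprint:::derive_seed(20, "folds1"),
                           sample(rep_len(1:5, n))) == f)
  })
  for (f in 1:5) {
    y_bad <- y
    y_bad[folds[[f]]] <- withr::with_seed(100 + f, rnorm(length(folds[[f]])))
    fit_bad <- cpm_fit(E, y_bad, scheme = "kfold", k = 5, repeats = 1,
                       seed = 20, p_threshold = 0.05)
    expect_identical(fit$fold_masks[[f]], fit_bad$fold_masks[[f]])
  }
})

test_that("cross-validation covers subjects exactly once and masks stay disjoint", {
  E <- random_edge_cohort(45, 10, seed = 21)
  y <- withr::with_seed(22, rnorm(45))
  loo <- cpm_fit(E, y, scheme = "loocv", p_threshold = 0.2)
  expect_equal(sum(!is.na(loo$predictions$predicted)), 45)
  kf <- cpm_fit(E, y, scheme = "kfold", k = 5, repeats = 3, seed = 23,
                p_threshold = 0.2)
  expect_equal(unique(kf$selection_counts$total_folds), 15)
  expect_equal(length(kf$r_per_repeat), 3)
  for (mk in c(loo$fold_masks, kf$fold_masks)) {
    expect_length(intersect(mask_key(mk$pos), mask_key(mk$neg)), 0)
  }
})

test_that("permutation p hits the formula floor and is deterministic", {
  E <- random_edge_cohort(50, 8, seed = 24)
  y <- E[, 5]  # perfect signal: observed r beats every permutation
  fit <- cpm_fit(E, y, scheme = "loocv", n_perm = 24, seed = 25)
  expect_equal(fit$p, 1 / 25)
  fit2 <- cpm_fit(E, y, scheme = "loocv", n_perm = 24, seed = 25)
  expect_identical(fit$p, fit2$p)
  expect_identical(fit$r, fit2$r)
  expect_length(fit$r_perm, 24)
})

test_that("degenerate training folds fall back to intercept-only predictions", {
  E <- random_edge_cohort(30, 6, seed = 26)
  y <- withr::with_seed(27, rnorm(30))
  # threshold so strict nothing is ever selected
  expect_warning(fit <- cpm_fit(E, y, scheme = "loocv", p_threshold = 1e-12),
                 regexp = "intercept-only")
  expect_equal(fit$degenerate_folds, 30)
  expect_true(all(is.finite(fit$predictions$predicted)))
})

test_that("median cross-validated r never decreases with planted effect size", {
  effects <- c(0, 0.1, 0.2)
  med_r <- vapply(effects, function(eff) {
    rs <- vapply(1:20, function(s) {
      cfg <- sim_config(n_subjects = 120, n_nodes = 16, frames_per_block = 10,
                        n_blocks_per_condition = 4,
                        planted_pos_edges = rbind(c(1, 2), c(3, 4), c(5, 6)),
                        planted_neg_edges = rbind(c(7, 8), c(9, 10), c(11, 12)),
                        effect_size = eff, base_connectivity = 0.2,
                        coupling = 1, seed = 1000 + s)
      coh <- simulate_cohort(cfg, conditions = "reward")
      fit <- cpm_fit(coh$connectivity$reward, coh$ground_truth$latent_severity,
                     scheme = "kfold", k = 4, repeats = 2, seed = s,
                     p_threshold = 0.05)
      fit$r
    }, numeric(1))
    stats::median(rs)
  }, numeric(1))
  expect_true(all(diff(med_r) >= 0))
})

test_that("edge masks round-trip through edge-list files", {
  mask <- edge_mask(positive = rbind(c(3, 9), c(1, 4)), negative = cbind(2, 7))
  pos <- withr::local_tempfile(fileext = ".edges")
  neg <- withr::local_tempfile(fileext = ".edges")
  write_edge_mask(mask, pos, neg)
  back <- read_edge_mask(pos, neg)
  expect_setequal(mask_key(back$positive), mask_key(mask$positive))
  expect_setequal(mask_key(back$negative), mask_key(mask$negative))
  expect_error(edge_mask(positive = cbind(1, 2), negative = cbind(2, 1)),
               class = "netfp_parameter_error")
  expect_error(edge_mask(positive = cbind(3, 3)), class = "netfp_parameter_error")
})
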