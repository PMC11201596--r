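# Node extraction, block concatenation, connectivity matrices.

test_that("node extraction averages voxels within each label", {
  dims <- c(4, 4, 2, 6)
  img <- withr::with_seed(1, array(rnorm(prod(dims)), dims))
  atlas <- array(0L, dims[1:3])
  atlas[1:2, 1, 1] <- 1L
  atlas[3:4, 2, 1] <- 3L           # non-contiguous labels allowed
  atlas[, , 2] <- 2L

  # parcel whose voxels share one time course reproduces it exactly
  course <- withr::with_seed(2, rnorm(6))
  for (f in 1:6) img[1:2, 1, 1, f] <- course[f]
  ts <- extract_node_timeseries(img, atlas)
  expect_identical(colnames(ts), c("node_1", "node_2", "node_3"))
  expect_equal(ts[, "node_1"], course, ignore_attr = TRUE)

  # brute-force per-voxel averaging oracle
  for (lab in c(1L, 2L, 3L)) {
    idx <- which(atlas == lab)
    oracle <- vapply(1:6, function(f) {
      frame <- img[, , , f]
      mean(frame[idx])
    }, numeric(1))
    expect_equal(ts[, paste0("node_", lab)], oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  expect_error(extract_node_timeseries(img, array(0L, dims[1:3])),
               class = "netfp_data_error")
  expect_error(extract_node_timeseries(img, array(1L, c(3, 3, 3))),
               class = "netfp_data_error")
})

test_that("condition blocks concatenate in order, with optional lag", {
  series <- matrix(seq_len(40 * 3), 40, 3)
  blocks <- tibble::tibble(condition = c("reward", "fixation", "reward"),
                           start = c(1L, 11L, 16L), end = c(10L, 15L, 25L))
  out <- concatenate_condition_blocks(series, blocks, "reward")
  expect_equal(nrow(out), 20)
  expect_equal(out, series[c(1:10, 16:25), ])

  # lag equal to block length: windows fall entirely after the blocks
  lagged <- concatenate_condition_blocks(series, blocks, "reward", lag_frames = 10)
  expect_equal(lagged, series[c(11:20, 26:35), ])

  expect_error(concatenate_condition_blocks(series, blocks, "punishment"),
               class = "netfp_data_error")
  expect_error(concatenate_condition_blocks(series, blocks, "reward", lag_frames = 30),
               class = "netfp_data_error")
  overlapping <- tibble::tibble(condition = "reward", start = c(1L, 5L), end = c(10L, 14L))
  expect_error(concatenate_condition_blocks(series, overlapping, "reward"),
               class = "netfp_data_error")
})

test_that("connectivity matches the textbook two-pass Pearson oracle", {
  series <- withr::with_seed(4, matrix(rnorm(50 * 10), 50, 10))
  R <- connectivity_matrix(series)
  # two-pass oracle: explicit centring and normalised cross-products
  oracle <- diag(10)
  for (a in 1:9) for (b in (a + 1):10) {
    x <- series[, a] - mean(series[, a])
    y <- series[, b] - mean(series[, b])
    r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    oracle[a, b] <- oracle[b, a] <- r
  }
  expect_equal(R, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(R - t(R))), 1e-12)
})

test_that("anti-correlated nodes, Fisher z, and constant columns behave", {
  x <- withr::with_seed(5, rnorm(30))
  series <- cbind(x, -x, rnorm(30))
  R <- connectivity_matrix(series)
  expect_equal(R[1, 2], -1, tolerance = 1e-12)

  Z <- connectivity_matrix(series[, c(1, 3)], fisher_z = TRUE)
  expect_equal(diag(Z), c(0, 0), ignore_attr = TRUE)
  expect_equal(Z[1, 2], atanh(cor(series[, 1], series[, 3])), tolerance = 1e-12)

  const <- cbind(rnorm(20), rep(1, 20))
  expect_error(connectivity_matrix(const), class = "netfp_data_error")
  expect_warning(Rna <- connectivity_matrix(const, on_constant = "na"))
  expect_true(is.na(Rna[1, 2]))
  expect_equal(diag(Rna), c(1, 1))
  expect_error(connectivity_matrix(series[1:2, ]), class = "netfp_data_error")
})

test_that("node permutation permutes the matrix consistently", {
  series <- withr::with_seed(6, matrix(rnorm(60 * 8), 60, 8))
  perm <- withr::with_seed(7, sample(8))
  R <- connectivity_matrix(series)
  Rp <- connectivity_matrix(series[, perm])
  expect_equal(Rp, R[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sample connectivity converges to the planted population matrix", {
  sev <- 0.5
  errs <- vapply(c(25, 100, 400), function(fpb) {
    cfg <- sim_config(n_subjects = 1, n_nodes = 6, frames_per_block = fpb,
                      n_blocks_per_condition = 4,
                      planted_pos_edges = cbind(1, 2), planted_neg_edges = cbind(3, 4),
                      effect_size = 0.2, base_connectivity = 0.2, coupling = 1,
                      seed = 88)
    ts <- simulate_timeseries(cfg, sev)
    u <- ts$ground_truth$edge_factor
    target <- diag(6)
    target[1, 2] <- target[2, 1] <- 0.2 + 0.2 * u
    target[3, 4] <- target[4, 3] <- 0.2 - 0.2 * u
    max(abs(connectivity_matrix(ts$series[[1]]$reward) - target))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("time-series files round-trip through the tsv writers", {
  m <- withr::with_seed(8, matrix(rnorm(20 * 4), 20, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_timeseries(path)
  expect_equal(back, m, tolerance = 1e-12, ignore_attr = TRUE)
})
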