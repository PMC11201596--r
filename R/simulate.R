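# Synthetic cohort generator: one-factor drinking battery, block-structured
# node time series with planted behaviour-correlated edges, and region-keyed
# receptor atlases with planted spatial associations. Every downstream stage
# of the pipeline can therefore be validated against known ground truth.

#' Names of the 15 synthetic drinking measures
#'
#' Measure names used by [simulate_behavior()]. The last three
#' (days since last drink, age at first drink, longest abstinence) are
#' generated sign-flipped: higher raw values mean *less* severe drinking,
#' mimicking battery items that must be inverted before index construction.
#'
#' @return Character vector of length 15.
#' @export
drinking_measure_names <- function() {
  c("total_drinks_week", "drinks_per_drinking_day", "max_drinks_24h",
    "drinking_days_week", "heavy_drinking_days_month", "freq_5plus_month",
    "times_drunk_year", "binge_episodes_year", "weekend_drinks",
    "weekday_drinks", "freq_any_alcohol", "largest_drinks_year",
    "days_since_last_drink", "age_first_drink", "longest_abstinence")
}

#' Default sign-flipped measures
#' @return Character vector: the measures whose raw sign is inverted.
#' @export
default_flip_measures <- function() {
  c("days_since_last_drink", "age_first_drink", "longest_abstinence")
}

#' Names of the 27 receptor/transporter density maps
#'
#' The serotonin (5-HT1a/1b/2a/4), cannabinoid (CB1), dopamine (D1/D2,
#' FDOPA), GABAa, mu-opioid (MOR), metabotropic glutamate (mGluR5) receptor
#' systems and the DAT, NAT, SERT and VAChT transporters, with numeric
#' suffixes distinguishing source tracer studies (treated as opaque
#' identifiers).
#'
#' @return Character vector of length 27.
#' @export
receptor_map_names <- function() {
  c("5-HT1a_1", "5-HT1a_2", "5-HT1b_1", "5-HT1b_2", "5-HT2a_1", "5-HT2a_2",
    "5-HT4", "CB1", "D1", "D2_1", "D2_2", "FDOPA", "GABAa_1", "GABAa_2",
    "MOR_1", "MOR_2", "mGluR5_1", "mGluR5_2", "mGluR5_3", "DAT", "NAT",
    "SERT_1", "SERT_2", "SERT_3", "VAChT_1", "VAChT_2", "VAChT_3")
}

#' Sample disjoint positive/negative planted edge sets
#'
#' Draws planted node pairs and splits them into the two signed sets. By
#' default (`share_nodes = FALSE`) the pairs are node-disjoint: each node
#' participates in at most one planted edge, so the planted correlation
#' structure decomposes into independent 2 x 2 blocks that stay positive
#' definite for any planted correlation in (-1, 1). With
#' `share_nodes = TRUE` pairs are drawn uniformly from the upper triangle
#' and may share nodes (the target matrix is then repaired to positive
#' definiteness when needed).
#'
#' @param n_nodes Number of atlas nodes.
#' @param n_pos,n_neg Number of positively / negatively coupled edges.
#' @param seed Integer seed.
#' @param share_nodes Allow planted edges to share nodes?
#' @return List with `pos` and `neg`, each a two-column matrix of node pairs.
#' @export
sample_edge_sets <- function(n_nodes, n_pos = 10, n_neg = 10, seed = 1,
                             share_nodes = FALSE) {
  n_edges <- n_pos + n_neg
  as_named <- function(m) {
    colnames(m) <- c("node_i", "node_j")
    m
  }
  if (share_nodes) {
    idx <- edge_index_table(n_nodes)
    if (n_edges > nrow(idx))
      stop_param("cannot plant %d edges among %d pairs", n_edges, nrow(idx))
    picked <- withr::with_seed(seed, sample.int(nrow(idx), n_edges))
    pairs <- as_named(cbind(idx$node_i[picked], idx$node_j[picked]))
  } else {
    if (2 * n_edges > n_nodes)
      stop_param("node-disjoint planting of %d edges needs >= %d nodes (got %d); use share_nodes = TRUE or fewer edges",
                 n_edges, 2 * n_edges, n_nodes)
    nodes <- withr::with_seed(seed, sample.int(n_nodes, 2 * n_edges))
    pairs <- as_named(normalize_pairs(matrix(nodes, ncol = 2)))
  }
  list(pos = pairs[seq_len(n_pos), , drop = FALSE],
       neg = pairs[n_pos + seq_len(n_neg), , drop = FALSE])
}

#' Simulation configuration
#'
#' Bundles and validates all generator settings. Defaults emulate the study
#' conditions: 981 subjects, a 268-node atlas, gambling-task block structure
#' (2 runs x 2 blocks per condition, ~38 frames per block at TR 0.72 s), a
#' 15-measure one-factor battery whose first component carries ~49% of the
#' variance (factor loading 0.677), tens of planted behaviour-coupled edges
#' of both signs, and a brain-behaviour coupling calibrated so the
#' population-level connectome prediction r is approximately 0.25 (see
#' [expected_prediction_r()]).
#'
#' @param n_subjects Cohort size.
#' @param n_nodes Atlas nodes.
#' @param frames_per_block Frames in each task block.
#' @param n_blocks_per_condition Blocks per condition (across runs).
#' @param n_measures Battery size (>= 2).
#' @param factor_loading Loading of every measure on the latent severity
#'   factor, in `[0, 1]`.
#' @param planted_pos_edges,planted_neg_edges Two-column matrices of node
#'   pairs whose connectivity increases / decreases with severity. `NULL`
#'   draws default sets of 10 each via [sample_edge_sets()].
#' @param effect_size Maximum correlation shift per unit standardized
#'   severity at a planted edge.
#' @param base_connectivity Baseline correlation at planted edges.
#' @param coupling Brain-behaviour coupling in `[0, 1]`: correlation between
#'   the latent severity and the subject-level factor that drives planted
#'   edges. Caps the attainable connectome prediction r; the remaining
#'   connectivity variance is severity-independent individual variation.
#' @param noise_sd Marginal SD of the simulated node signals.
#' @param conditions Task conditions to generate.
#' @param fixation_frames_per_block Frames per fixation block.
#' @param seed Integer seed (also used for default edge placement).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 981,
                       n_nodes = 268,
                       frames_per_block = 38,
                       n_blocks_per_condition = 4,
                       n_measures = 15,
                       factor_loading = 0.677,
                       planted_pos_edges = NULL,
                       planted_neg_edges = NULL,
                       effect_size = 0.2,
                       base_connectivity = 0.2,
                       coupling = 0.26,
                       noise_sd = 1,
                       conditions = c("reward", "punishment"),
                       fixation_frames_per_block = 20,
                       seed = 1L) {
  if (is.null(planted_pos_edges) || is.null(planted_neg_edges)) {
    sets <- sample_edge_sets(n_nodes, 10, 10, seed = derive_seed(seed, "edges"))
    if (is.null(planted_pos_edges)) planted_pos_edges <- sets$pos
    if (is.null(planted_neg_edges)) planted_neg_edges <- sets$neg
  }
  planted_pos_edges <- normalize_pairs(planted_pos_edges)
  planted_neg_edges <- normalize_pairs(planted_neg_edges)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    frames_per_block = as.integer(frames_per_block),
    n_blocks_per_condition = as.integer(n_blocks_per_condition),
    n_measures = as.integer(n_measures), factor_loading = factor_loading,
    planted_pos_edges = planted_pos_edges,
    planted_neg_edges = planted_neg_edges,
    effect_size = effect_size, base_connectivity = base_connectivity,
    coupling = coupling, noise_sd = noise_sd, conditions = conditions,
    fixation_frames_per_block = as.integer(fixation_frames_per_block),
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("node_i", "node_j"))))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop_param("edge lists must be two-column matrices")
  m <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  colnames(m) <- c("node_i", "node_j")
  m
}

pair_keys <- function(pairs, n_nodes) {
  (pairs[, 1] - 1) * n_nodes + pairs[, 2]
}

validate_sim_config <- function(cfg) {
  if (cfg$n_measures < 2) stop_param("n_measures must be >= 2")
  if (cfg$factor_loading < 0 || cfg$factor_loading > 1)
    stop_param("factor_loading must lie in [0, 1], got %s", cfg$factor_loading)
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop_param("coupling must lie in [0, 1], got %s", cfg$coupling)
  if (cfg$frames_per_block < 1) stop_param("frames_per_block must be >= 1")
  if (cfg$n_blocks_per_condition < 1) stop_param("n_blocks_per_condition must be >= 1")
  all_pairs <- rbind(cfg$planted_pos_edges, cfg$planted_neg_edges)
  if (nrow(all_pairs)) {
    if (any(all_pairs < 1) || any(all_pairs > cfg$n_nodes))
      stop_param("planted edge node indices must lie in 1..n_nodes")
    if (any(all_pairs[, 1] == all_pairs[, 2]))
      stop_param("planted edges must not be self-pairs")
    kp <- pair_keys(cfg$planted_pos_edges, cfg$n_nodes)
    kn <- pair_keys(cfg$planted_neg_edges, cfg$n_nodes)
    if (length(intersect(kp, kn)))
      stop_param("planted positive and negative edge sets must be disjoint")
  }
  # 3-SD safety margin on the planted correlation range
  if (abs(cfg$base_connectivity) + 3 * cfg$effect_size >= 1)
    stop_param("|base_connectivity| + 3*effect_size must be < 1 (got %.3f)",
               abs(cfg$base_connectivity) + 3 * cfg$effect_size)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects, %d nodes, %d x %d frames per condition\n",
              x$n_subjects, x$n_nodes, x$n_blocks_per_condition, x$frames_per_block))
  cat(sprintf("  battery: %d measures, loading %.3f\n", x$n_measures, x$factor_loading))
  cat(sprintf("  planted edges: %d positive, %d negative (effect %.2f, base %.2f, coupling %.2f)\n",
              nrow(x$planted_pos_edges), nrow(x$planted_neg_edges),
              x$effect_size, x$base_connectivity, x$coupling))
  invisible(x)
}

#' Simulate the drinking battery and demographic covariates
#'
#' Generates a one-factor battery: each measure is
#' `loading * latent + sqrt(1 - loading^2) * noise`, with the measures in
#' [default_flip_measures()] (or the trailing measures, when the battery is
#' not the standard 15) emitted sign-flipped. Age is drawn from normal
#' distributions with sex-shifted means (men 27.9 +/- 3.6 y, women
#' 29.6 +/- 3.6 y) and sex is Bernoulli(0.518 female), emulating the study
#' demographics.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to the config seed.
#' @return List of class `synth_behavior`: `measures` (tibble: subject +
#'   one column per measure), `covariates` (tibble: subject, age, sex with
#'   sex coded 0 = male, 1 = female), and `ground_truth` (latent severity,
#'   flip set, config echo).
#' @export
simulate_behavior <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_subjects
  m <- config$n_measures
  lambda <- config$factor_loading
  if (m == 15) {
    measure_names <- drinking_measure_names()
    flip <- default_flip_measures()
  } else {
    measure_names <- sprintf("measure_%02d", seq_len(m))
    flip <- measure_names[m - seq_len(min(3, m - 1)) + 1]
  }
  out <- withr::with_seed(derive_seed(seed, "behavior"), {
    latent <- rnorm(n)
    noise <- matrix(rnorm(n * m), n, m)
    X <- lambda * latent + sqrt(1 - lambda^2) * noise
    colnames(X) <- measure_names
    X[, flip] <- -X[, flip]
    sex <- rbinom(n, 1, 0.518)                      # 0 = male, 1 = female
    age <- rnorm(n, mean = ifelse(sex == 1, 29.6, 27.9), sd = 3.6)
    list(latent = latent, X = X, sex = sex, age = age)
  })
  subject <- sprintf("sub_%04d", seq_len(n))
  structure(list(
    measures = as_tibble(cbind(tibble(subject = subject), as_tibble(out$X))),
    covariates = tibble(subject = subject, age = out$age, sex = out$sex),
    ground_truth = list(latent_severity = out$latent, flip_measures = flip,
                        factor_loading = lambda, config = config)
  ), class = "synth_behavior")
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Clips eigenvalues at `floor`, reconstructs, and renormalizes to unit
#' diagonal; iterates until the smallest eigenvalue of the renormalized
#' matrix respects the floor. Already-PD correlation matrices pass through
#' unchanged (to numerical precision).
#'
#' @param m Square symmetric matrix.
#' @param floor Smallest admissible eigenvalue (default `1e-6`).
#' @return Symmetric unit-diagonal matrix with smallest eigenvalue
#'   `>= floor * (1 - 1e-8)`.
#' @export
make_positive_definite <- function(m, floor = 1e-6) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_param("input must be a square matrix")
  if (!isSymmetric(m, tol = 1e-8)) stop_param("input matrix must be symmetric")
  m <- (m + t(m)) / 2
  for (it in seq_len(100)) {
    e <- eigen(m, symmetric = TRUE)
    if (e$values[length(e$values)] >= floor * (1 - 1e-8) &&
        max(abs(diag(m) - 1)) < 1e-12) {
      return(m)
    }
    vals <- pmax(e$values, floor)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / (d %o% d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  stop_sim("positive-definite repair did not converge")
}

#' Simulate block-structured node time series with planted edges
#'
#' For each subject and task condition, draws frames x nodes observations
#' from a zero-mean multivariate normal whose correlation matrix is the
#' identity except at planted edges, where the correlation is
#' `base +/- effect * u_i` (sign per edge list). The subject-level edge
#' factor `u_i = coupling * severity_i + sqrt(1 - coupling^2) * eta_i`
#' mixes the latent severity with independent individual variation shared
#' across a subject's planted edges, so the population brain-behaviour
#' correlation equals `coupling`. Target matrices are repaired to positive
#' definiteness before sampling; a repair that moves a planted edge by more
#' than `repair_tol` aborts, naming the offending edges. A `fixation`
#' condition with identity correlation is generated alongside the task
#' conditions.
#'
#' @param config A [sim_config()].
#' @param latent_severity Standardized severity scores, length `n_subjects`.
#' @param seed Seed; defaults to the config seed.
#' @param repair_tol Maximum tolerated PD-repair shift at a planted edge.
#' @return List of class `synth_timeseries`: `series` (per subject, a named
#'   list of frames x nodes matrices, one per condition), `ground_truth`
#'   (per-subject edge factor, planted edge lists with effect sizes).
#' @export
simulate_timeseries <- function(config, latent_severity, seed = config$seed,
                                repair_tol = 0.05) {
  validate_sim_config(config)
  n <- config$n_subjects
  if (length(latent_severity) != n)
    stop_param("latent_severity must have length n_subjects (%d)", n)
  p <- config$n_nodes
  frames <- config$frames_per_block * config$n_blocks_per_condition
  if (frames < 3) stop_param("need at least 3 frames per condition")
  fix_frames <- config$fixation_frames_per_block * config$n_blocks_per_condition
  pos <- config$planted_pos_edges
  neg <- config$planted_neg_edges
  conditions <- config$conditions

  withr::with_seed(derive_seed(seed, "timeseries"), {
    eta <- rnorm(n)
    u <- config$coupling * latent_severity + sqrt(1 - config$coupling^2) * eta
    series <- vector("list", n)
    for (i in seq_len(n)) {
      C <- diag(p)
      set_edges <- function(C, pairs, val) {
        if (nrow(pairs)) {
          C[pairs] <- val
          C[pairs[, 2:1, drop = FALSE]] <- val
        }
        C
      }
      r_pos <- pmin(pmax(config$base_connectivity + config$effect_size * u[i], -0.97), 0.97)
      r_neg <- pmin(pmax(config$base_connectivity - config$effect_size * u[i], -0.97), 0.97)
      C <- set_edges(C, pos, r_pos)
      C <- set_edges(C, neg, r_neg)
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch)) {
        Cr <- make_positive_definite(C)
        shift <- abs(Cr - C)
        planted <- rbind(pos, neg)
        bad <- planted[shift[planted] > repair_tol, , drop = FALSE]
        if (nrow(bad))
          stop_sim("planted correlation target not repairable within %.3f at edges: %s",
                   repair_tol,
                   paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", "))
        ch <- chol(Cr)
      }
      subj <- list()
      for (cond in conditions) {
        subj[[cond]] <- (matrix(rnorm(frames * p), frames, p) %*% ch) * config$noise_sd
      }
      subj[["fixation"]] <- matrix(rnorm(fix_frames * p), fix_frames, p) * config$noise_sd
      series[[i]] <- subj
    }
    names(series) <- sprintf("sub_%04d", seq_len(n))
    structure(list(
      series = series,
      ground_truth = list(
        edge_factor = u,
        planted_pos_edges = pos, planted_neg_edges = neg,
        effect_size = config$effect_size,
        base_connectivity = config$base_connectivity,
        coupling = config$coupling)
    ), class = "synth_timeseries")
  })
}

#' Interleave one subject's condition series into a single run
#'
#' Builds a full-run frames x nodes matrix by alternating condition blocks
#' (in the order reward, fixation, punishment, fixation, ...) together with
#' the block table that [concatenate_condition_blocks()] consumes.
#'
#' @param subject_series Named list of condition matrices for one subject
#'   (one element of `simulate_timeseries()$series`).
#' @param config The [sim_config()] used to generate the series.
#' @return List: `series` (frames x nodes) and `blocks` (tibble with
#'   `condition`, `start`, `end`, 1-based inclusive frame indices).
#' @export
assemble_run <- function(subject_series, config) {
  fpb <- config$frames_per_block
  ffb <- config$fixation_frames_per_block
  conds <- config$conditions
  chunks <- list()
  rows <- list()
  cursor <- 0L
  fix_used <- 0L
  take <- function(mat, k, from) mat[from + seq_len(k), , drop = FALSE]
  for (b in seq_len(config$n_blocks_per_condition)) {
    for (cond in conds) {
      chunks[[length(chunks) + 1L]] <- take(subject_series[[cond]], fpb, (b - 1L) * fpb)
      rows[[length(rows) + 1L]] <- tibble(condition = cond, start = cursor + 1L,
                                          end = cursor + fpb)
      cursor <- cursor + fpb
      if (fix_used + ffb <= nrow(subject_series[["fixation"]])) {
        chunks[[length(chunks) + 1L]] <- take(subject_series[["fixation"]], ffb, fix_used)
        rows[[length(rows) + 1L]] <- tibble(condition = "fixation", start = cursor + 1L,
                                            end = cursor + ffb)
        cursor <- cursor + ffb
        fix_used <- fix_used + ffb
      }
    }
  }
  list(series = do.call(rbind, chunks), blocks = bind_rows(rows))
}

#' Simulate a receptor/transporter atlas with planted spatial associations
#'
#' Generates a latent regional target pattern and, for each named
#' receptor/transporter system, a regional density map whose population
#' spatial correlation with the target equals the planted value (0 for
#' unplanted maps). Maps are then linearly rescaled to `[0, 100]` (an
#' affine transform, so correlations are unaffected). A configurable number
#' of extra white-matter and CSF regions is appended; their map values are
#' pure noise and they are meant to be excluded from spatial correlation.
#'
#' @param n_regions Number of gray-matter regions (>= 10; default 119).
#' @param map_names Map identifiers (default the 27 systems of
#'   [receptor_map_names()]).
#' @param planted Named numeric vector: map name -> true spatial r
#'   (|r| < 1). Unnamed maps get population correlation 0.
#' @param n_white,n_csf Extra white-matter / CSF regions appended.
#' @param target Optional latent regional pattern (length `n_regions`);
#'   drawn standard normal when `NULL`.
#' @param seed Integer seed.
#' @return List of class `synth_receptors`: `receptors` (tibble: region,
#'   tissue_class, one column per map), `tmap` (tibble: region, t — the
#'   target pattern as a pseudo effect map over gray regions), and
#'   `ground_truth` (planted correlations and the target pattern).
#' @export
simulate_receptor_atlas <- function(n_regions = 119,
                                    map_names = receptor_map_names(),
                                    planted = c("5-HT1a_1" = 0.9, "GABAa_2" = 0.9),
                                    n_white = 4, n_csf = 2,
                                    target = NULL, seed = 1) {
  if (n_regions < 10) stop_param("n_regions must be >= 10")
  if (anyDuplicated(map_names)) stop_param("duplicate map names")
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% map_names))
      stop_param("planted names must be a subset of map_names")
    if (any(abs(planted) >= 1)) stop_param("|planted r| must be < 1")
  }
  total <- n_regions + n_white + n_csf
  tissue <- c(rep("gray", n_regions), rep("white", n_white), rep("csf", n_csf))
  region <- sprintf("region_%03d", seq_len(total))
  withr::with_seed(derive_seed(seed, "receptors"), {
    if (is.null(target)) target <- rnorm(n_regions)
    if (length(target) != n_regions) stop_param("target must have length n_regions")
    z <- as.numeric(scale(target))
    maps <- vapply(map_names, function(nm) {
      r <- if (nm %in% names(planted)) planted[[nm]] else 0
      gray <- r * z + sqrt(1 - r^2) * rnorm(n_regions)
      rescale_map(c(gray, rnorm(n_white + n_csf)))
    }, numeric(total))
    colnames(maps) <- map_names
    receptors <- as_tibble(cbind(tibble(region = region, tissue_class = tissue),
                                 as_tibble(maps)))
    structure(list(
      receptors = receptors,
      tmap = tibble(region = region[seq_len(n_regions)], t = target),
      ground_truth = list(planted = planted, target = target)
    ), class = "synth_receptors")
  })
}

#' Simulate per-subject regional task contrasts
#'
#' Regional contrast values with a severity effect whose spatial profile
#' follows a target pattern: the contrast of subject i in region j is
#' `beta * target_j * severity_i` plus Gaussian noise. Feeding the result
#' to [parcel_glm_tmap()] yields a T map whose
#' spatial layout recovers `target`, closing the loop for the molecular
#' stage.
#'
#' @param target Regional pattern (length = number of regions).
#' @param severity Per-subject severity scores.
#' @param regions Region labels (default `region_001`, ...).
#' @param beta Effect size per unit severity.
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return Subjects x regions numeric matrix with region column names.
#' @export
simulate_regional_contrasts <- function(target, severity,
                                        regions = sprintf("region_%03d", seq_along(target)),
                                        beta = 0.5, noise_sd = 1, seed = 1) {
  n <- length(severity)
  p <- length(target)
  withr::with_seed(derive_seed(seed, "contrasts"), {
    M <- beta * (severity %o% target) + matrix(rnorm(n * p, sd = noise_sd), n, p)
    colnames(M) <- regions
    rownames(M) <- sprintf("sub_%04d", seq_len(n))
    M
  })
}

#' Closed-form oracle for the attainable prediction correlation
#'
#' Maps generator settings to the expected population-level CPM prediction
#' correlation, the product of three attenuation factors:
#' the brain-behaviour coupling `rho`; the network-strength reliability
#' `A = sqrt(k e^2 / (k e^2 + sigma_e^2))` where `k` is the number of
#' planted edges, `e` the per-edge effect and `sigma_e ~ (1 - base^2) /
#' sqrt(F - 1)` the sampling SD of an edge correlation over `F` frames; and
#' the PC1 proxy factor `b = sqrt(m lambda^2 / (1 + (m - 1) lambda^2))`
#' relating the measured index to the latent severity. Also returns the
#' expected per-edge severity correlation `rho * a * b` with
#' `a = e / sqrt(e^2 + sigma_e^2)`.
#'
#' @param config A [sim_config()].
#' @return Tibble with `prediction_r`, `edge_r`, and the three factors.
#' @export
expected_prediction_r <- function(config) {
  k <- nrow(config$planted_pos_edges) + nrow(config$planted_neg_edges)
  e <- config$effect_size
  frames <- config$frames_per_block * config$n_blocks_per_condition
  sigma_e <- (1 - config$base_connectivity^2) / sqrt(frames - 1)
  a <- e / sqrt(e^2 + sigma_e^2)
  A <- if (k > 0) sqrt(k * e^2 / (k * e^2 + sigma_e^2)) else 0
  lam <- config$factor_loading
  m <- config$n_measures
  b <- sqrt(m * lam^2 / (1 + (m - 1) * lam^2))
  tibble(prediction_r = config$coupling * A * b,
         edge_r = config$coupling * a * b,
         coupling = config$coupling, strength_reliability = A, pc1_proxy = b)
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulate_behavior()] and
#' [simulate_timeseries()] and computing per-condition connectivity
#' matrices, so downstream stages can be exercised in one call.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to the config seed.
#' @param conditions Conditions for which to compute connectivity.
#' @return List of class `synth_cohort`: `behavior`, `timeseries`,
#'   `connectivity` (per condition, a named list of node x node matrices),
#'   and `ground_truth`.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            conditions = config$conditions) {
  beh <- simulate_behavior(config, seed = seed)
  ts <- simulate_timeseries(config, beh$ground_truth$latent_severity, seed = seed)
  conn <- lapply(conditions, function(cond) {
    lapply(ts$series, function(s) connectivity_matrix(s[[cond]]))
  })
  names(conn) <- conditions
  structure(list(
    behavior = beh, timeseries = ts, connectivity = conn,
    ground_truth = c(beh$ground_truth, ts$ground_truth)
  ), class = "synth_cohort")
}
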