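# Connectome-based predictive modelling: covariate-adjusted edge
# selection, signed network strengths, cross-validated prediction and
# permutation inference.
#
# The cross-validation engine works on a subjects x edges matrix and, for
# permutation testing, carries the observed behaviour and all permuted
# behaviours through every fold simultaneously (one crossprod per fold),
# so the full CV is genuinely re-run per permutation at matrix-algebra
# cost. Selection by p < threshold is applied as the exactly equivalent
# |r| > r_crit rule, with r_crit = sqrt(t^2 / (t^2 + df)) at
# t = qt(1 - threshold/2, df).

#' Signed edge mask
#'
#' Holds the positive and negative networks: sets of unordered node pairs
#' whose connectivity correlates positively / negatively with behaviour.
#' The two sets are disjoint by construction.
#'
#' @param positive,negative Data frames (or two-column matrices) of node
#'   pairs with columns `node_i`, `node_j`.
#' @param n_nodes Optional atlas size for index validation.
#' @return Object of class `edge_mask`.
#' @export
edge_mask <- function(positive = NULL, negative = NULL, n_nodes = NULL) {
  to_tbl <- function(x) {
    if (is.null(x)) return(tibble(node_i = integer(0), node_j = integer(0)))
    x <- normalize_pairs(as.matrix(as.data.frame(x)[, 1:2]))
    tibble(node_i = as.integer(x[, 1]), node_j = as.integer(x[, 2]))
  }
  pos <- to_tbl(positive)
  neg <- to_tbl(negative)
  if (nrow(pos) && any(pos$node_i == pos$node_j) ||
      nrow(neg) && any(neg$node_i == neg$node_j))
    stop_param("edge mask must not contain self-pairs")
  if (!is.null(n_nodes)) {
    all_n <- c(pos$node_i, pos$node_j, neg$node_i, neg$node_j)
    if (length(all_n) && max(all_n) > n_nodes)
      stop_param("edge mask node index exceeds atlas size %d", n_nodes)
  }
  key <- function(d) paste(d$node_i, d$node_j)
  if (length(intersect(key(pos), key(neg))))
    stop_param("positive and negative edge sets must be disjoint")
  structure(list(positive = pos, negative = neg, n_nodes = n_nodes),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %d positive, %d negative edges\n",
              nrow(x$positive), nrow(x$negative)))
  invisible(x)
}

#' @rdname edge_mask
#' @param x An `edge_mask`.
#' @param ... Unused.
#' @export
tidy.edge_mask <- function(x, ...) {
  bind_rows(mutate(x$positive, polarity = "positive"),
            mutate(x$negative, polarity = "negative"))
}

#' Mask size
#' @param mask An `edge_mask`.
#' @return Named integer vector `c(positive = , negative = )`.
#' @export
mask_sizes <- function(mask) {
  c(positive = nrow(mask$positive), negative = nrow(mask$negative))
}

# ---- edge statistics ------------------------------------------------------

# Correlations of every edge column of E with every column of Y, partialling
# out the covariate design X (which includes the intercept). Returns the
# n_edges x n_behaviors correlation matrix plus df and the indices of
# (near-)constant edges.
edge_cor_core <- function(E, Y, X) {
  qx <- qr(X)
  Er <- qr.resid(qx, E)
  Yr <- qr.resid(qx, Y)
  ssE <- colSums(Er^2)
  ssY <- colSums(Yr^2)
  if (any(ssY <= 1e-12)) stop_data("behaviour is constant (after covariate adjustment)")
  const <- which(ssE <= 1e-10)
  denom <- sqrt(ssE) %o% sqrt(ssY)
  R <- crossprod(Er, Yr) / denom
  if (length(const)) R[const, ] <- 0
  R[!is.finite(R)] <- 0
  list(R = R, df = nrow(E) - 2L - (ncol(X) - 1L), constant = const)
}

build_design <- function(covs, idx) {
  if (is.null(covs)) matrix(1, length(idx), 1)
  else cbind(1, covs[idx, , drop = FALSE])
}

#' Edge-wise behaviour correlation
#'
#' For every upper-triangle edge, the partial Pearson correlation between
#' the subjects' edge values and the behaviour, controlling for the
#' covariates (`method = "partial"`; both sides are residualized against
#' age/sex before correlating). `method = "residualized"` instead
#' residualizes the behaviour only and correlates it with the raw edge
#' values. Two-tailed p-values come from the t transform on
#' `n - 2 - n_covariates` degrees of freedom. Constant edges are flagged
#' and carry r = 0, p = 1.
#'
#' @param conn Connectivity input: a list of node x node matrices, a
#'   3-D array (nodes x nodes x subjects), or a subjects x edges matrix
#'   with an `n_nodes` attribute.
#' @param behavior Numeric vector, one value per subject (or a
#'   `severity_index`).
#' @param covariates Data frame / matrix of numeric covariates (e.g. age,
#'   sex coded 0/1), or `NULL`.
#' @param method `"partial"` (default) or `"residualized"`.
#' @return Tibble: `edge`, `node_i`, `node_j`, `r`, `statistic`, `df`,
#'   `p`, `constant`.
#' @export
edge_behavior_correlation <- function(conn, behavior, covariates = NULL,
                                      method = c("partial", "residualized")) {
  method <- match.arg(method)
  E <- as_edge_matrix(conn)
  y <- as_behavior_vector(behavior)
  n <- nrow(E)
  if (length(y) != n) stop_data("behaviour length %d != %d subjects", length(y), n)
  covs <- as_covariate_matrix(covariates, n)
  q <- if (is.null(covs)) 0L else ncol(covs)
  if (n < q + 3L) stop_data("need at least %d subjects for %d covariates", q + 3L, q)
  if (sd(y) == 0) stop_data("behaviour is constant")
  if (method == "residualized" && !is.null(covs)) {
    y <- qr.resid(qr(cbind(1, covs)), y)
    covs <- NULL
  }
  cc <- edge_cor_core(E, cbind(y), build_design(covs, seq_len(n)))
  r <- as.numeric(cc$R)
  tstat <- r * sqrt(cc$df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), cc$df)
  p[cc$constant] <- 1
  idx <- edge_index_table(attr(E, "n_nodes"))
  mutate(idx, r = r, statistic = tstat, df = cc$df, p = p,
         constant = .data$edge %in% cc$constant)
}

#' Threshold edge statistics into a signed mask
#'
#' @param edge_stats Output of [edge_behavior_correlation()].
#' @param p_threshold Selection threshold in (0, 1); edges with
#'   `p < p_threshold` enter the mask, split by correlation sign.
#' @return An [edge_mask()].
#' @export
select_edges <- function(edge_stats, p_threshold = 0.01) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop_param("p_threshold must lie strictly in (0, 1)")
  ok <- !edge_stats$constant & edge_stats$p < p_threshold
  edge_mask(positive = edge_stats[ok & edge_stats$r > 0, c("node_i", "node_j")],
            negative = edge_stats[ok & edge_stats$r < 0, c("node_i", "node_j")])
}

#' Network strength of one connectivity matrix
#'
#' Sums the subject's edge values over the positive and negative edge
#' sets; these sums are the predictors in the CPM regression.
#'
#' @param matrix Node x node connectivity matrix.
#' @param mask An [edge_mask()].
#' @return Named numeric vector `c(pos_strength = , neg_strength = )`.
#' @export
network_strength <- function(matrix, mask) {
  sum_over <- function(pairs) {
    if (!nrow(pairs)) return(0)
    sum(matrix[cbind(pairs$node_i, pairs$node_j)])
  }
  c(pos_strength = sum_over(mask$positive), neg_strength = sum_over(mask$negative))
}

#' Network strengths for a cohort
#'
#' @param conn Connectivity input (see [edge_behavior_correlation()]).
#' @param mask An [edge_mask()].
#' @return Tibble: `subject`, `pos_strength`, `neg_strength`.
#' @export
network_strengths <- function(conn, mask) {
  E <- as_edge_matrix(conn)
  n_nodes <- attr(E, "n_nodes")
  cols <- mask_edge_columns(mask, n_nodes)
  tibble(subject = rownames(E) %||% sprintf("sub_%04d", seq_len(nrow(E))),
         pos_strength = strength_of(E, cols$pos),
         neg_strength = strength_of(E, cols$neg))
}

mask_edge_columns <- function(mask, n_nodes) {
  idx <- edge_index_table(n_nodes)
  keys <- (idx$node_i - 1) * n_nodes + idx$node_j
  to_cols <- function(d) {
    if (!nrow(d)) return(integer(0))
    match((d$node_i - 1) * n_nodes + d$node_j, keys)
  }
  list(pos = to_cols(mask$positive), neg = to_cols(mask$negative))
}

strength_of <- function(E, cols) {
  if (!length(cols)) return(rep(0, nrow(E)))
  rowSums(E[, cols, drop = FALSE])
}

# ---- cross-validation engine ---------------------------------------------

# E: subjects x edges; Y: subjects x (1 + n_perm) behaviours (column 1 is
# observed); covs: covariate matrix or NULL; folds: list of test-index
# vectors partitioning 1..n. Returns predictions for every behaviour
# column plus the per-fold masks for the observed behaviour.
cpm_cv_pass <- function(E, Y, covs, folds, p_threshold, network) {
  n <- nrow(E)
  nb <- ncol(Y)
  pred <- matrix(NA_real_, n, nb)
  masks <- vector("list", length(folds))
  degenerate <- 0L
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    E_tr <- E[tr, , drop = FALSE]
    E_te <- E[te, , drop = FALSE]
    X <- build_design(covs, tr)
    cc <- edge_cor_core(E_tr, Y[tr, , drop = FALSE], X)
    tcrit <- qt(1 - p_threshold / 2, cc$df)
    rcrit <- sqrt(tcrit^2 / (tcrit^2 + cc$df))
    R <- cc$R
    for (j in seq_len(nb)) {
      pos <- which(R[, j] > rcrit)
      neg <- which(R[, j] < -rcrit)
      if (j == 1L) masks[[f]] <- list(pos = pos, neg = neg)
      preds_tr <- list()
      preds_te <- list()
      if (network %in% c("positive", "combined")) {
        preds_tr$pos <- strength_of(E_tr, pos)
        preds_te$pos <- strength_of(E_te, pos)
      }
      if (network %in% c("negative", "combined")) {
        preds_tr$neg <- strength_of(E_tr, neg)
        preds_te$neg <- strength_of(E_te, neg)
      }
      keep <- vapply(preds_tr, function(v) sd(v) > 1e-12, logical(1))
      y_tr <- Y[tr, j]
      if (!any(keep)) {
        if (j == 1L) degenerate <- degenerate + 1L
        pred[te, j] <- mean(y_tr)
      } else {
        D <- cbind(1, do.call(cbind, preds_tr[keep]))
        qd <- qr(D)
        beta <- qr.coef(qd, y_tr)
        beta[is.na(beta)] <- 0
        Dte <- cbind(1, do.call(cbind, preds_te[keep]))
        pred[te, j] <- as.numeric(Dte %*% beta)
      }
    }
  }
  list(pred = pred, masks = masks, degenerate = degenerate)
}

make_folds <- function(n, scheme, k, seed) {
  if (scheme == "loocv") return(as.list(seq_len(n)))
  assignment <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(f) which(assignment == f))
}

#' Fit and cross-validate a connectome-based predictive model
#'
#' The full CPM protocol. Per cross-validation fold: edges are selected on
#' the training subjects only (partial correlation with behaviour
#' controlling covariates, `p < p_threshold`, split by sign), training
#' network strengths are computed over the selected sets, an ordinary
#' least-squares model of behaviour on the strength predictors is fitted
#' (one predictor for a single network, two for `"combined"`), and the
#' held-out subjects are predicted. Model performance is the Pearson
#' correlation between predicted and observed behaviour over all subjects
#' (for repeated k-fold, the mean over repeats). With `n_perm > 0` the
#' whole cross-validation is re-run on permuted behaviour (covariates stay
#' bound to their subjects) and the permutation p-value is
#' `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' A training fold whose selected strengths are constant (e.g. empty masks)
#' falls back to an intercept-only model and is counted in
#' `degenerate_folds`.
#'
#' @inheritParams edge_behavior_correlation
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Folds for `"kfold"` (>= 2).
#' @param repeats Repetitions of the k-fold split (default 100 for kfold;
#'   ignored for LOOCV).
#' @param p_threshold Edge-selection threshold (default 0.01).
#' @param network `"positive"`, `"negative"` or `"combined"`.
#' @param n_perm Number of behaviour permutations (0 = no test).
#' @param seed Integer seed controlling fold splits and permutations.
#' @param consensus Fraction of folds (over all repeats) in which an edge
#'   must be selected to enter the consensus mask (default 0.9).
#' @return Object of class `cpm_result`; see [glance.cpm_result()].
#' @export
cpm_fit <- function(conn, behavior, covariates = NULL,
                    scheme = c("loocv", "kfold"), k = 5,
                    repeats = NULL, p_threshold = 0.01,
                    network = c("combined", "positive", "negative"),
                    n_perm = 0, seed = 1, consensus = 0.9,
                    method = c("partial", "residualized")) {
  scheme <- match.arg(scheme)
  network <- match.arg(network)
  method <- match.arg(method)
  if (scheme == "kfold" && k < 2) stop_param("k must be >= 2")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop_param("p_threshold must lie strictly in (0, 1)")
  repeats <- repeats %||% if (scheme == "kfold") 100L else 1L
  if (scheme == "loocv") repeats <- 1L

  E <- as_edge_matrix(conn)
  n_nodes <- attr(E, "n_nodes")
  y <- as_behavior_vector(behavior)
  n <- nrow(E)
  if (length(y) != n) stop_data("behaviour length %d != %d subjects", length(y), n)
  if (sd(y) == 0) stop_data("behaviour is constant")
  covs <- as_covariate_matrix(covariates, n)
  if (method == "residualized" && !is.null(covs)) {
    y <- qr.resid(qr(cbind(1, covs)), y)
    covs <- NULL
  }
  q <- if (is.null(covs)) 0L else ncol(covs)
  if (n < q + 10L) stop_data("need at least %d subjects", q + 10L)

  Y <- cbind(y)
  if (n_perm > 0) {
    perms <- withr::with_seed(derive_seed(seed, "perm"), {
      vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
    })
    Y <- cbind(y, perms)
  }

  r_mat <- matrix(NA_real_, repeats, ncol(Y))
  pos_counts <- numeric(ncol(E))
  neg_counts <- numeric(ncol(E))
  total_folds <- 0L
  degenerate <- 0L
  first_pred <- NULL
  first_masks <- NULL
  for (rep_i in seq_len(repeats)) {
    folds <- make_folds(n, scheme, k, derive_seed(seed, paste0("folds", rep_i)))
    pass <- cpm_cv_pass(E, Y, covs, folds, p_threshold, network)
    r_mat[rep_i, ] <- suppressWarnings(cor(pass$pred, Y))[cbind(seq_len(ncol(Y)), seq_len(ncol(Y)))]
    for (mk in pass$masks) {
      pos_counts[mk$pos] <- pos_counts[mk$pos] + 1
      neg_counts[mk$neg] <- neg_counts[mk$neg] + 1
    }
    total_folds <- total_folds + length(folds)
    degenerate <- degenerate + pass$degenerate
    if (rep_i == 1L) {
      first_pred <- pass$pred[, 1]
      first_masks <- pass$masks
    }
  }
  if (degenerate > 0)
    warn(sprintf("%d training fold(s) had constant network strength; used intercept-only model", degenerate))
  r_means <- colMeans(r_mat)
  r_means[is.na(r_means)] <- 0
  r_obs <- r_means[1]
  p_perm <- if (n_perm > 0) (1 + sum(r_means[-1] >= r_obs)) / (1 + n_perm) else NA_real_

  idx <- edge_index_table(n_nodes)
  consensus_mask <- edge_mask(
    positive = idx[pos_counts >= consensus * total_folds, c("node_i", "node_j")],
    negative = idx[neg_counts >= consensus * total_folds, c("node_i", "node_j")],
    n_nodes = n_nodes)

  structure(list(
    predictions = tibble(
      subject = rownames(E) %||% sprintf("sub_%04d", seq_len(n)),
      observed = Y[, 1], predicted = first_pred),
    r = r_obs, p = p_perm, r_per_repeat = r_mat[, 1],
    r_perm = if (n_perm > 0) r_means[-1] else numeric(0),
    fold_masks = lapply(first_masks, function(mk) list(
      pos = idx[mk$pos, c("node_i", "node_j")],
      neg = idx[mk$neg, c("node_i", "node_j")])),
    selection_counts = mutate(idx, pos_count = pos_counts, neg_count = neg_counts,
                              total_folds = total_folds),
    consensus_mask = consensus_mask, consensus = consensus,
    scheme = scheme, k = if (scheme == "kfold") k else NA_integer_,
    repeats = repeats, n_perm = n_perm, seed = seed,
    p_threshold = p_threshold, network = network, method = method,
    n_subjects = n, n_nodes = n_nodes, degenerate_folds = degenerate
  ), class = "cpm_result")
}

#' Permutation test for a CPM configuration
#'
#' Convenience wrapper: runs [cpm_fit()] with `n_perm` behaviour
#' permutations and returns the fitted result including the permutation
#' p-value.
#'
#' @inheritParams cpm_fit
#' @param ... Passed to [cpm_fit()].
#' @return A `cpm_result` with `p` filled in.
#' @export
cpm_permutation_test <- function(conn, behavior, covariates = NULL,
                                 n_perm = 999, seed = 1, ...) {
  cpm_fit(conn, behavior, covariates = covariates, n_perm = n_perm,
          seed = seed, ...)
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("<cpm_result>\n")
  cat(sprintf("  scheme: %s%s, network: %s, threshold p < %g\n",
              x$scheme, if (x$scheme == "kfold") sprintf(" (k = %d, %d repeats)", x$k, x$repeats) else "",
              x$network, x$p_threshold))
  cat(sprintf("  n = %d subjects, %d nodes\n", x$n_subjects, x$n_nodes))
  cat(sprintf("  r = %.3f", x$r))
  if (!is.na(x$p)) cat(sprintf(", permutation p = %.4g (%d permutations)", x$p, x$n_perm))
  cat("\n")
  cat(sprintf("  consensus mask: %d positive, %d negative edges\n",
              nrow(x$consensus_mask$positive), nrow(x$consensus_mask$negative)))
  invisible(x)
}

#' Tidy and summarise CPM results
#'
#' `tidy()` returns per-subject observed and predicted behaviour;
#' `glance()` a one-row model summary; `autoplot()` the predicted-versus-
#' observed scatter.
#'
#' @param x,object A `cpm_result`.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.cpm_result <- function(x, ...) x$predictions

#' @rdname tidy.cpm_result
#' @export
glance.cpm_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, scheme = x$scheme, k = x$k, repeats = x$repeats,
         n_perm = x$n_perm, network = x$network,
         p_threshold = x$p_threshold, n_subjects = x$n_subjects,
         n_pos_consensus = nrow(x$consensus_mask$positive),
         n_neg_consensus = nrow(x$consensus_mask$negative),
         degenerate_folds = x$degenerate_folds)
}

#' @rdname tidy.cpm_result
#' @export
autoplot.cpm_result <- function(object, ...) {
  lab <- sprintf("r = %.2f%s", object$r,
                 if (!is.na(object$p)) sprintf(", p = %.3g", object$p) else "")
  ggplot(object$predictions, aes(x = .data$observed, y = .data$predicted)) +
    geom_point(alpha = 0.5, colour = "steelblue") +
    geom_abline(linetype = "dashed") +
    labs(title = "Cross-validated prediction", subtitle = lab,
         x = "observed severity", y = "predicted severity") +
    theme_minimal()
}

#' Write / read edge-list mask files
#'
#' Edge lists are tab-delimited with a comment header documenting 1-based
#' node indices.
#'
#' @param mask An [edge_mask()].
#' @param pos_path,neg_path Output paths.
#' @return Paths, invisibly.
#' @export
write_edge_mask <- function(mask, pos_path, neg_path) {
  hdr <- "# node_i\tnode_j (1-based node indices, unordered pairs)"
  write_one <- function(d, path) {
    writeLines(c(hdr, sprintf("%d\t%d", d$node_i, d$node_j)), path)
  }
  write_one(mask$positive, pos_path)
  write_one(mask$negative, neg_path)
  invisible(c(pos_path, neg_path))
}

#' @rdname write_edge_mask
#' @return `read_edge_mask()`: an `edge_mask`.
#' @export
read_edge_mask <- function(pos_path, neg_path) {
  read_one <- function(path) {
    d <- readr::read_tsv(path, comment = "#", col_names = c("node_i", "node_j"),
                         show_col_types = FALSE)
    if (!nrow(d)) tibble(node_i = integer(0), node_j = integer(0)) else d
  }
  edge_mask(positive = read_one(pos_path), negative = read_one(neg_path))
}
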