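# Molecular profiling: parcel-level GLM effect (T) maps for severity and
# their spatial correlation with receptor/transporter density maps across
# gray-matter regions.

#' Parcel-level GLM T map for severity
#'
#' Per region, ordinary least squares of the regional contrast value on
#' severity, age and sex (plus intercept); the T statistic is the severity
#' coefficient divided by its standard error, on `n - p` degrees of
#' freedom (`p` = number of design columns). This is a parcel-level
#' analogue of a voxelwise regression followed by parcel averaging: the
#' downstream spatial correlation consumes only regional values, so the
#' regression is run directly at the regional level. The map is returned
#' unthresholded.
#'
#' @param regional_contrasts Subjects x regions numeric matrix (region
#'   column names) or data frame with a `subject` column and one numeric
#'   column per region.
#' @param severity Per-subject severity scores (or a `severity_index`).
#' @param covariates Data frame / matrix of numeric covariates, or `NULL`.
#' @param contrast Label stored with the map (e.g. `"punishment-baseline"`).
#' @return Tibble of class `regional_tmap`: `region`, `t`, `beta`, `se`,
#'   with attributes `df` and `contrast`. Zero-residual regions (perfect
#'   fit) are flagged via a `perfect_fit` column and carry the largest
#'   finite T of the map's sign.
#' @export
parcel_glm_tmap <- function(regional_contrasts, severity, covariates = NULL,
                            contrast = "contrast") {
  if (is.data.frame(regional_contrasts)) {
    keep <- names(regional_contrasts)[names(regional_contrasts) != "subject"]
    regional_contrasts <- as.matrix(regional_contrasts[keep])
  }
  Yc <- as.matrix(regional_contrasts)
  y_sev <- as_behavior_vector(severity)
  n <- nrow(Yc)
  if (length(y_sev) != n) stop_data("severity length %d != %d subjects", length(y_sev), n)
  covs <- as_covariate_matrix(covariates, n)
  X <- cbind(intercept = 1, severity = y_sev, covs)
  p <- ncol(X)
  if (n < p + 1L) stop_data("need at least %d subjects for %d design columns", p + 1L, p)
  qx <- qr(X)
  if (qx$rank < p) stop_data("rank-deficient design (collinear covariates)")
  B <- qr.coef(qx, Yc)                       # p x regions
  res <- qr.resid(qx, Yc)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtX_inv_sev <- chol2inv(qr.R(qx))[2, 2]    # variance factor of the severity column
  se <- sqrt(sigma2 * XtX_inv_sev)
  beta <- B[2, ]
  tstat <- beta / se
  perfect <- sigma2 < 1e-24
  if (any(perfect)) {
    finite_max <- max(abs(tstat[!perfect]), 1e6)
    tstat[perfect] <- sign(beta[perfect]) * finite_max
  }
  regions <- colnames(Yc) %||% sprintf("region_%03d", seq_len(ncol(Yc)))
  out <- tibble(region = regions, t = unname(tstat), beta = unname(beta),
                se = unname(se), perfect_fit = unname(perfect))
  attr(out, "df") <- df
  attr(out, "contrast") <- contrast
  class(out) <- c("regional_tmap", class(out))
  out
}

#' Linearly rescale a map to the 0-100 range
#'
#' Affine transform sending the minimum to 0 and the maximum to 100;
#' monotone, so value order — and any Pearson correlation with another
#' fixed map — is preserved exactly.
#'
#' @param map Numeric vector with at least 2 distinct values.
#' @return Rescaled numeric vector.
#' @export
rescale_map <- function(map) {
  if (!is.numeric(map)) stop_data("map must be numeric")
  rng <- range(map, na.rm = TRUE)
  if (diff(rng) == 0) stop_data("cannot rescale a constant map")
  100 * (map - rng[1]) / (rng[2] - rng[1])
}

#' Spatial correlation of an effect map with receptor maps
#'
#' Pearson correlation, across shared gray-matter regions, between a
#' regional T map and each receptor/transporter density map, with
#' two-tailed parametric p-values; maps with (adjusted) `p < alpha` are
#' flagged. Region matching is by label, so row order is irrelevant;
#' regions whose tissue class is in `exclude_classes` (white matter and
#' CSF by default) are dropped before correlating.
#'
#' @param tmap Data frame with `region` and `t` columns (e.g. from
#'   [parcel_glm_tmap()]).
#' @param receptors Data frame with `region`, `tissue_class` and one
#'   numeric column per map (e.g. from [simulate_receptor_atlas()] or
#'   [read_receptor_table()]).
#' @param exclude_classes Tissue classes to drop.
#' @param alpha Significance level (default 0.05, per-map — no correction
#'   across maps by default, matching common practice with these atlases).
#' @param p_adjust Multiple-comparison correction across maps
#'   (`stats::p.adjust` method; default `"none"`).
#' @return Tibble of class `spatial_corr`: `map`, `r`, `p`, `n`,
#'   `flagged`; attribute `alpha`.
#' @export
spatial_correlation <- function(tmap, receptors,
                                exclude_classes = c("white", "csf"),
                                alpha = 0.05, p_adjust = "none") {
  if (!all(c("region", "t") %in% names(tmap)))
    stop_data("tmap must have region and t columns")
  if (!"region" %in% names(receptors))
    stop_data("receptor table must have a region column")
  if ("tissue_class" %in% names(receptors)) {
    receptors <- receptors[!receptors$tissue_class %in% exclude_classes, , drop = FALSE]
  }
  map_cols <- names(receptors)[vapply(receptors, is.numeric, logical(1))]
  if (!length(map_cols)) stop_data("receptor table has no numeric map columns")
  shared <- intersect(tmap$region, receptors$region)
  tvals <- tmap$t[match(shared, tmap$region)]
  res <- map(map_cols, function(nm) {
    x <- receptors[[nm]][match(shared, receptors$region)]
    ok <- is.finite(x) & is.finite(tvals)
    n_use <- sum(ok)
    if (n_use < 10)
      stop_data("fewer than 10 shared usable regions for map '%s' (%d)", nm, n_use)
    r <- cor(tvals[ok], x[ok])
    tstat <- r * sqrt(n_use - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble(map = nm, r = r, p = 2 * pt(-abs(tstat), n_use - 2), n = n_use)
  })
  out <- bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out$flagged <- out$p_adjusted < alpha
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  class(out) <- c("spatial_corr", class(out))
  out
}

#' @rdname spatial_correlation
#' @param x A `spatial_corr`.
#' @param ... Unused.
#' @export
glance.spatial_corr <- function(x, ...) {
  tibble(n_maps = nrow(x), n_flagged = sum(x$flagged),
         alpha = attr(x, "alpha"), p_adjust = attr(x, "p_adjust"),
         strongest_map = x$map[which.max(abs(x$r))],
         strongest_r = x$r[which.max(abs(x$r))])
}

#' @rdname spatial_correlation
#' @param object A `spatial_corr`.
#' @export
autoplot.spatial_corr <- function(object, ...) {
  d <- mutate(object, map = factor(.data$map, levels = object$map[order(object$r)]))
  ggplot(d, aes(x = .data$r, y = .data$map, fill = .data$flagged)) +
    geom_col() +
    geom_hline(yintercept = 0, colour = "grey50") +
    scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    labs(title = "Spatial correlation with receptor/transporter maps",
         x = "Pearson r across gray-matter regions", y = NULL,
         fill = sprintf("p < %.2g", attr(object, "alpha"))) +
    theme_minimal()
}

#' Read / write region-keyed molecular tables
#'
#' `receptors.tsv` holds `region`, `tissue_class` and one column per map;
#' `tmap.tsv` holds `region` and `t`; `spatial_corr.tsv` the correlation
#' results.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_receptor_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_receptor_table
#' @param tbl Table to write.
#' @export
write_molecular_table <- function(tbl, path) {
  readr::write_tsv(as_tibble(tbl), path)
  invisible(path)
}
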