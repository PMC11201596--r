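# PC1 drinking-severity index: correlation-matrix PCA of the measure
# battery with sign flipping and orientation anchoring.

#' Compute the PC1 severity index
#'
#' Builds a composite severity score as the first principal component of a
#' multi-measure battery under correlation-matrix PCA: measures named in
#' `flip` are sign-inverted (items where larger raw values mean lighter
#' drinking), every measure is z-scored, the sample correlation matrix is
#' eigendecomposed, and subjects are scored by projection onto the leading
#' eigenvector. The component's sign is anchored so that its correlation
#' with `anchor` (after flipping) is non-negative, making higher scores
#' mean more severe drinking. Variance explained is
#' `100 * eigenvalue / n_measures`, the correlation-PCA identity.
#'
#' Subjects with any missing measure are excluded with a warning
#' (`na_action = "exclude"`, default) or raise an error naming them
#' (`na_action = "error"`). A constant measure column is always an error.
#'
#' @param measures Data frame with a `subject` column (or subject ids in
#'   the first non-numeric column) and one numeric column per measure; at
#'   least 3 subjects and 2 measures.
#' @param flip Character vector of measure names to sign-invert before PCA.
#' @param anchor Measure name used to orient PC1 (default: first measure).
#' @param na_action `"exclude"` or `"error"`.
#' @return Object of class `severity_index`: `scores` (tibble `subject`,
#'   `pc1`), `eigenvalue`, `variance_explained` (percent), `loadings`
#'   (tibble `measure`, `loading`), `anchor`, `flip`, `excluded` (subject
#'   ids dropped for missingness).
#' @export
#' @examples
#' cohort <- simulate_behavior(sim_config(n_subjects = 200, n_nodes = 10))
#' idx <- compute_severity_pc1(cohort$measures, flip = default_flip_measures(),
#'                             anchor = "total_drinks_week")
#' glance(idx)
compute_severity_pc1 <- function(measures, flip = character(),
                                 anchor = NULL,
                                 na_action = c("exclude", "error")) {
  na_action <- match.arg(na_action)
  if (!is.data.frame(measures)) stop_data("measures must be a data frame")
  num <- vapply(measures, is.numeric, logical(1))
  measure_names <- names(measures)[num]
  if ("subject" %in% names(measures)) {
    subject <- as.character(measures$subject)
    measure_names <- setdiff(measure_names, "subject")
  } else {
    id_col <- names(measures)[!num]
    subject <- if (length(id_col)) as.character(measures[[id_col[1]]])
               else sprintf("sub_%04d", seq_len(nrow(measures)))
  }
  if (length(measure_names) < 2) stop_data("need at least 2 measure columns")
  bad_flip <- setdiff(flip, measure_names)
  if (length(bad_flip))
    stop_param("flip names not in measures: %s", paste(bad_flip, collapse = ", "))
  anchor <- anchor %||% measure_names[1]
  if (!anchor %in% measure_names)
    stop_param("anchor '%s' is not a measure column", anchor)

  X <- as.matrix(measures[measure_names])
  excluded <- character(0)
  if (anyNA(X)) {
    bad <- rowSums(is.na(X)) > 0
    excluded <- subject[bad]
    if (na_action == "error")
      stop_data("missing measures for subjects: %s", paste(excluded, collapse = ", "))
    warn(sprintf("excluding %d subject(s) with missing measures: %s",
                 length(excluded), paste(head(excluded, 10), collapse = ", ")))
    X <- X[!bad, , drop = FALSE]
    subject <- subject[!bad]
  }
  if (nrow(X) < 3) stop_data("need at least 3 subjects after exclusions")
  X[, intersect(flip, colnames(X))] <- -X[, intersect(flip, colnames(X))]
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_data("constant measure column(s): %s",
              paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  C <- cor(X)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  scores <- as.numeric(Z %*% v)
  orient <- cor(scores, Z[, anchor])
  if (is.finite(orient) && orient < 0) {
    v <- -v
    scores <- -scores
  }
  m <- ncol(X)
  structure(list(
    scores = tibble(subject = subject, pc1 = scores),
    eigenvalue = e$values[1],
    variance_explained = 100 * e$values[1] / m,
    loadings = tibble(measure = colnames(X), loading = v),
    eigenvalues = e$values,
    anchor = anchor, flip = flip, n_measures = m,
    excluded = excluded
  ), class = "severity_index")
}

#' @export
print.severity_index <- function(x, ...) {
  cat("<severity_index>\n")
  cat(sprintf("  %d subjects, %d measures\n", nrow(x$scores), x$n_measures))
  cat(sprintf("  PC1 eigenvalue %.3f, variance explained %.2f%%\n",
              x$eigenvalue, x$variance_explained))
  if (length(x$excluded))
    cat(sprintf("  %d subject(s) excluded for missing measures\n", length(x$excluded)))
  invisible(x)
}

#' @rdname compute_severity_pc1
#' @param x A `severity_index`.
#' @param ... Unused.
#' @export
tidy.severity_index <- function(x, ...) x$loadings

#' @rdname compute_severity_pc1
#' @export
glance.severity_index <- function(x, ...) {
  tibble(eigenvalue = x$eigenvalue,
         variance_explained = x$variance_explained,
         n_subjects = nrow(x$scores), n_measures = x$n_measures,
         n_excluded = length(x$excluded))
}

#' @rdname compute_severity_pc1
#' @param object A `severity_index`.
#' @export
autoplot.severity_index <- function(object, ...) {
  dat <- mutate(object$loadings,
                measure = factor(.data$measure, levels = rev(object$loadings$measure)))
  ggplot(dat, aes(x = .data$loading, y = .data$measure)) +
    geom_col(fill = "steelblue") +
    labs(title = sprintf("PC1 loadings (%.1f%% of variance)",
                         object$variance_explained),
         x = "loading", y = NULL) +
    theme_minimal()
}

#' Read / write the behaviour table
#'
#' `read_behavior_table()` reads a tab-delimited table with `subject`,
#' measure columns and optional `age`/`sex` covariates;
#' `write_severity()` writes the per-subject index as `severity.tsv`.
#'
#' @param path File path.
#' @return `read_behavior_table()`: a tibble. `write_severity()`: the path,
#'   invisibly.
#' @export
read_behavior_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_behavior_table
#' @param index A `severity_index`.
#' @export
write_severity <- function(index, path) {
  readr::write_tsv(index$scores, path)
  invisible(path)
}
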