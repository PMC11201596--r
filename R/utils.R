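# Internal helpers: error classes, edge indexing, seed derivation.

stop_param <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "netfp_parameter_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "netfp_data_error")
}

stop_sim <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "netfp_simulation_error")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "netfp_config_error")
}

#' Upper-triangle edge index table
#'
#' Enumerates the unordered node pairs of an `n_nodes` atlas in the order
#' used throughout the package: column-major upper triangle, i.e. (1,2),
#' (1,3), (2,3), (1,4), ... This matches `upper.tri()` so that
#' `matrix[upper.tri(matrix)]` lines up with `edge` row order.
#'
#' @param n_nodes Number of atlas nodes (>= 2).
#' @return A tibble with columns `edge`, `node_i`, `node_j` (`node_i < node_j`).
#' @export
#' @examples
#' edge_index_table(4)
edge_index_table <- function(n_nodes) {
  if (n_nodes < 2) stop_param("n_nodes must be >= 2, got %s", n_nodes)
  j <- rep.int(2:n_nodes, times = seq_len(n_nodes - 1L))
  i <- unlist(lapply(2:n_nodes, function(col) seq_len(col - 1L)), use.names = FALSE)
  tibble(edge = seq_along(i), node_i = i, node_j = j)
}

n_edges_for <- function(n_nodes) n_nodes * (n_nodes - 1L) / 2L

# Convert connectivity input (list of square matrices, 3-D array nodes x
# nodes x subjects, or an already-flat subjects x edges matrix carrying an
# "n_nodes" attribute) into subjects x edges matrix with attr n_nodes.
as_edge_matrix <- function(conn) {
  if (is.matrix(conn) && !is.null(attr(conn, "n_nodes"))) return(conn)
  if (is.array(conn) && length(dim(conn)) == 3) {
    conn <- lapply(seq_len(dim(conn)[3]), function(s) conn[, , s])
  }
  if (is.list(conn)) {
    n_nodes <- nrow(conn[[1]])
    ut <- upper.tri(conn[[1]])
    E <- t(vapply(conn, function(m) {
      if (!is.matrix(m) || nrow(m) != n_nodes || ncol(m) != n_nodes)
        stop_data("all connectivity matrices must be %d x %d", n_nodes, n_nodes)
      m[ut]
    }, numeric(sum(ut))))
    if (!is.null(names(conn))) rownames(E) <- names(conn)
    attr(E, "n_nodes") <- n_nodes
    return(E)
  }
  stop_data("cannot interpret connectivity input of class '%s'", class(conn)[1])
}

# Deterministic 31-bit seed derived from a base seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- rlang::hash(list(as.integer(seed), as.character(tag)))
  strtoi(substr(h, 1, 7), base = 16L)
}

# Extract the numeric vector behind a behaviour argument: numeric vector,
# severity_index object, or a data frame with a single numeric column (plus
# optional subject column).
as_behavior_vector <- function(behavior) {
  if (inherits(behavior, "severity_index")) return(behavior$scores$pc1)
  if (is.data.frame(behavior)) {
    num <- vapply(behavior, is.numeric, logical(1))
    num_cols <- names(behavior)[num & names(behavior) != "subject"]
    if (length(num_cols) != 1)
      stop_data("behaviour data frame must have exactly one numeric value column")
    return(behavior[[num_cols]])
  }
  if (!is.numeric(behavior)) stop_data("behaviour must be numeric")
  as.numeric(behavior)
}

# Covariate design matrix (numeric columns, subject column dropped), or NULL.
as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    keep <- names(covariates)[names(covariates) != "subject"]
    covariates <- covariates[keep]
    if (!all(vapply(covariates, is.numeric, logical(1))))
      stop_data("covariate columns must be numeric (code sex as 0/1)")
    covariates <- as.matrix(covariates)
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop_data("covariates have %d rows but %d subjects expected", nrow(covariates), n)
  if (anyNA(covariates)) stop_data("covariates contain missing values")
  covariates
}
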