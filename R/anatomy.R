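# Network anatomy: node degrees, canonical-network edge-count matrices,
# and edge-fraction specificity of a selected mask.

#' Canonical network labels
#'
#' The ten macroscale functional networks used to summarize edge anatomy:
#' medial frontal (MF), fronto-parietal (FP), default mode (DMN),
#' motor/sensory (Mot), visual I/II (VI, VII), visual association (Vas),
#' salience (SAL), subcortical (SC), cerebellum/brainstem (CBL).
#'
#' @return Character vector of length 10.
#' @export
canonical_networks <- function() {
  c("MF", "FP", "DMN", "Mot", "VI", "VII", "Vas", "SAL", "SC", "CBL")
}

macro_regions <- function() {
  c("prefrontal", "motor", "insula", "parietal", "temporal", "occipital",
    "limbic", "cerebellar", "subcortical", "brainstem")
}

#' Synthetic node annotation table
#'
#' A stand-in annotation for a 268-node atlas, assigning each node a
#' macroscale region, one of the ten canonical networks and a hemisphere.
#' The assignment is random (deterministic under `seed`), serving tests
#' and demonstrations; it does not reproduce any published atlas. Loaders
#' accept user-supplied real annotation tables in the same format.
#'
#' @param n_nodes Atlas size (default 268).
#' @param seed Integer seed.
#' @return Tibble: `node`, `macro_region`, `network`, `hemisphere`.
#' @export
synthetic_shen_atlas <- function(n_nodes = 268, seed = 1) {
  withr::with_seed(derive_seed(seed, "atlas"), {
    tibble(
      node = seq_len(n_nodes),
      macro_region = sample(macro_regions(), n_nodes, replace = TRUE),
      network = sample(canonical_networks(), n_nodes, replace = TRUE),
      hemisphere = rep_len(c("L", "R"), n_nodes))
  })
}

#' Node degrees of an edge mask
#'
#' Per node, the number of incident mask edges, separately per polarity.
#'
#' @param mask An [edge_mask()].
#' @param n_nodes Atlas size; inferred from the mask when `NULL`.
#' @return Tibble: `node`, `degree_pos`, `degree_neg`, `degree_total`.
#' @export
node_degrees <- function(mask, n_nodes = NULL) {
  n_nodes <- n_nodes %||% mask$n_nodes %||%
    max(c(mask$positive$node_i, mask$positive$node_j,
          mask$negative$node_i, mask$negative$node_j, 1L))
  count_inc <- function(d) {
    tabulate(c(d$node_i, d$node_j), nbins = n_nodes)
  }
  dp <- count_inc(mask$positive)
  dn <- count_inc(mask$negative)
  tibble(node = seq_len(n_nodes), degree_pos = dp, degree_neg = dn,
         degree_total = dp + dn)
}

#' Highest-degree nodes
#'
#' The complete set of nodes attaining the maximum degree in each polarity
#' (ties reported together, no arbitrary tie-break).
#'
#' @param degrees Output of [node_degrees()].
#' @return List with `positive`, `negative`, `total`: integer node vectors
#'   (empty when the corresponding degrees are all zero).
#' @export
highest_degree_nodes <- function(degrees) {
  top <- function(v) if (max(v) == 0) integer(0) else degrees$node[v == max(v)]
  list(positive = top(degrees$degree_pos),
       negative = top(degrees$degree_neg),
       total = top(degrees$degree_total))
}

#' Canonical-network edge-count matrices
#'
#' Counts the mask edges connecting nodes within and between each pair of
#' canonical networks, per polarity and for their sum. Cell (a, b) of each
#' symmetric 10 x 10 matrix counts edges whose endpoint networks are
#' {a, b}; within-network edges sit on the diagonal. The upper triangle
#' plus diagonal of each matrix sums to the mask size of that polarity.
#'
#' @param mask An [edge_mask()].
#' @param atlas Annotation table with `node` and `network` columns (e.g.
#'   [synthetic_shen_atlas()]).
#' @return Object of class `network_matrix`: list with `positive`,
#'   `negative`, `sum` matrices and the network `levels`.
#' @export
summarize_by_network <- function(mask, atlas) {
  if (!all(c("node", "network") %in% names(atlas)))
    stop_data("atlas must have node and network columns")
  levels <- if (all(atlas$network %in% canonical_networks()))
    canonical_networks() else sort(unique(atlas$network))
  lookup <- atlas$network[order(atlas$node)]
  names(lookup) <- sort(atlas$node)
  count_matrix <- function(d) {
    M <- matrix(0L, length(levels), length(levels), dimnames = list(levels, levels))
    if (!nrow(d)) return(M)
    missing <- setdiff(unique(c(d$node_i, d$node_j)), atlas$node)
    if (length(missing))
      stop_data("mask node(s) missing from atlas: %s",
                paste(head(missing, 10), collapse = ", "))
    a <- lookup[as.character(d$node_i)]
    b <- lookup[as.character(d$node_j)]
    lo <- pmin(match(a, levels), match(b, levels))
    hi <- pmax(match(a, levels), match(b, levels))
    for (e in seq_along(lo)) {
      M[lo[e], hi[e]] <- M[lo[e], hi[e]] + 1L
      if (lo[e] != hi[e]) M[hi[e], lo[e]] <- M[hi[e], lo[e]] + 1L
    }
    M
  }
  structure(list(positive = count_matrix(mask$positive),
                 negative = count_matrix(mask$negative),
                 sum = count_matrix(tidy(mask)),
                 levels = levels),
            class = "network_matrix")
}

#' @export
print.network_matrix <- function(x, ...) {
  cat("<network_matrix> edge counts within/between canonical networks\n")
  cat(sprintf("  positive: %d edges, negative: %d edges\n",
              network_matrix_total(x$positive), network_matrix_total(x$negative)))
  invisible(x)
}

#' Total edges in a network count matrix
#' @param m One polarity matrix from [summarize_by_network()].
#' @return Integer: sum over the upper triangle plus diagonal.
#' @export
network_matrix_total <- function(m) {
  sum(m[upper.tri(m, diag = TRUE)])
}

#' @rdname summarize_by_network
#' @param object A `network_matrix`.
#' @param polarity Which matrix to draw.
#' @param ... Unused.
#' @export
autoplot.network_matrix <- function(object, polarity = c("sum", "positive", "negative"),
                                    ...) {
  polarity <- match.arg(polarity)
  m <- object[[polarity]]
  d <- as_tibble(as.data.frame.table(m, responseName = "edges"))
  names(d)[1:2] <- c("network_a", "network_b")
  d$network_a <- factor(d$network_a, levels = object$levels)
  d$network_b <- factor(d$network_b, levels = rev(object$levels))
  ggplot(d, aes(x = .data$network_a, y = .data$network_b, fill = .data$edges)) +
    geom_tile(colour = "grey80") +
    scale_fill_gradient2(low = "white", high = "firebrick") +
    labs(title = sprintf("Edge counts (%s network)", polarity),
         x = NULL, y = NULL, fill = "edges") +
    theme_minimal()
}

#' Edge fraction of all possible connections
#'
#' Percentage of the atlas's unordered node pairs occupied by a mask:
#' `100 * n_edges / (n_nodes * (n_nodes - 1) / 2)`. For a 268-node atlas
#' there are 35,778 possible connections, so e.g. 39 selected edges occupy
#' about 0.109 percent.
#'
#' @param n_edges Number of selected edges.
#' @param n_nodes Atlas size (>= 2).
#' @return Percentage (numeric scalar).
#' @export
edge_fraction <- function(n_edges, n_nodes) {
  if (n_nodes < 2) stop_param("n_nodes must be >= 2")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_edges)
    stop_param("n_edges must lie in [0, %d]", max_edges)
  100 * n_edges / max_edges
}

#' Read / write atlas annotation tables
#'
#' Tab-delimited with columns `node`, `macro_region`, `network`,
#' `hemisphere` (extra columns such as coordinates are preserved).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_atlas_table <- function(path) {
  atlas <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("node", "network") %in% names(atlas)))
    stop_data("atlas table must have node and network columns")
  atlas
}

#' @rdname read_atlas_table
#' @param atlas Annotation tibble.
#' @export
write_atlas_table <- function(atlas, path) {
  readr::write_tsv(atlas, path)
  invisible(path)
}
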