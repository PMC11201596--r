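# Shared builders for synthetic cohorts used across test files.

# A cohort with no planted edges: the null hypothesis holds exactly.
null_config <- function(n_subjects, n_nodes, seed, ...) {
  sim_config(n_subjects = n_subjects, n_nodes = n_nodes,
             planted_pos_edges = matrix(integer(0), 0, 2),
             planted_neg_edges = matrix(integer(0), 0, 2),
             seed = seed, ...)
}

edge_key <- function(pairs) paste(pairs[, 1], pairs[, 2])

mask_key <- function(d) paste(d$node_i, d$node_j)

# Sensitivity of a consensus mask against the planted ground truth:
# fraction of planted edges recovered with the correct sign.
mask_sensitivity <- function(mask, ground_truth) {
  hits <- sum(edge_key(ground_truth$planted_pos_edges) %in% mask_key(mask$positive)) +
    sum(edge_key(ground_truth$planted_neg_edges) %in% mask_key(mask$negative))
  hits / (nrow(ground_truth$planted_pos_edges) + nrow(ground_truth$planted_neg_edges))
}

# Wrong-sign recovery count (planted positive edges appearing negative, or
# vice versa).
mask_sign_errors <- function(mask, ground_truth) {
  sum(edge_key(ground_truth$planted_pos_edges) %in% mask_key(mask$negative)) +
    sum(edge_key(ground_truth$planted_neg_edges) %in% mask_key(mask$positive))
}
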