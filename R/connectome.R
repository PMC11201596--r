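# Condition-specific connectivity: node time-course extraction from
# labelled 4-D images, block concatenation, and Pearson connectivity
# matrices.

#' Extract node-average time courses from a labelled 4-D image
#'
#' For each atlas label (> 0), averages the image over the voxels carrying
#' that label, per frame. Nodes are ordered by increasing label value.
#' Inputs can be in-memory arrays or NIfTI file paths (read with the RNifti
#' package when installed).
#'
#' @param image4d 4-D numeric array (x, y, z, frames) or NIfTI path.
#' @param label_atlas 3-D integer array on the same grid (0 = background)
#'   or NIfTI path.
#' @return Frames x nodes matrix; columns named `node_<label>`. Labels
#'   present in the atlas but empty after masking give an all-`NA` column
#'   with a warning.
#' @export
extract_node_timeseries <- function(image4d, label_atlas) {
  image4d <- read_volume(image4d)
  label_atlas <- read_volume(label_atlas)
  if (length(dim(image4d)) != 4) stop_data("image must be 4-D (x, y, z, frames)")
  if (length(dim(label_atlas)) != 3) stop_data("label atlas must be 3-D")
  if (!identical(dim(image4d)[1:3], dim(label_atlas)[1:3]))
    stop_data("label atlas grid %s does not match image grid %s",
              paste(dim(label_atlas), collapse = "x"),
              paste(dim(image4d)[1:3], collapse = "x"))
  labels <- as.integer(label_atlas)
  if (any(labels < 0)) stop_data("labels must be non-negative integers")
  used <- sort(unique(labels[labels > 0]))
  if (!length(used)) stop_data("label atlas contains only background")
  n_frames <- dim(image4d)[4]
  vox <- matrix(image4d, ncol = n_frames)      # voxels x frames
  keep <- labels > 0
  sums <- rowsum(vox[keep, , drop = FALSE], group = labels[keep])
  counts <- as.numeric(table(labels[keep]))
  ts <- t(sums / counts)                        # frames x nodes
  colnames(ts) <- sprintf("node_%d", used)
  ts
}

read_volume <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop_data("reading NIfTI paths requires the RNifti package")
    x <- RNifti::asNifti(RNifti::readNifti(x))
    x <- unclass(as.array(x))
  }
  x
}

#' Concatenate frames of one condition's blocks
#'
#' Pulls the frames belonging to the named condition's blocks out of a run,
#' optionally shifting every block window forward by `lag_frames` (e.g. to
#' account for hemodynamic delay), and concatenates them in block order.
#'
#' @param series Frames x nodes matrix for a full run.
#' @param blocks Data frame with `condition`, `start`, `end` (1-based
#'   inclusive frame indices).
#' @param condition Condition to extract.
#' @param lag_frames Non-negative forward shift applied to every window.
#' @return Frames x nodes matrix restricted to the condition's (shifted)
#'   blocks.
#' @export
concatenate_condition_blocks <- function(series, blocks, condition,
                                         lag_frames = 0) {
  if (lag_frames < 0) stop_param("lag_frames must be >= 0")
  if (!all(c("condition", "start", "end") %in% names(blocks)))
    stop_data("blocks table must have condition, start, end columns")
  sel <- blocks[blocks$condition == condition, , drop = FALSE]
  if (!nrow(sel)) stop_data("condition '%s' not present in block table", condition)
  starts <- sel$start + lag_frames
  ends <- sel$end + lag_frames
  if (any(ends > nrow(series)) || any(starts < 1))
    stop_data("shifted block windows fall outside the run (%d frames)", nrow(series))
  o <- order(starts)
  if (any(starts[o][-1] <= ends[o][-length(o)]))
    stop_data("shifted block windows overlap")
  idx <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE), use.names = FALSE)
  if (!length(idx)) stop_data("zero frames selected for condition '%s'", condition)
  series[idx, , drop = FALSE]
}

#' Node-by-node Pearson connectivity matrix
#'
#' Pairwise Pearson correlations between node time courses, optionally
#' Fisher z-transformed (`atanh`, diagonal set to 0). Constant node columns
#' are an error by default, or can be set to missing edge values.
#'
#' @param series Frames x nodes matrix (>= 3 frames).
#' @param fisher_z Apply the Fisher z transform?
#' @param on_constant `"error"` (default) or `"na"`: what to do with a
#'   constant node column.
#' @return Nodes x nodes symmetric matrix; diagonal 1 (r) or 0 (z).
#' @export
connectivity_matrix <- function(series, fisher_z = FALSE,
                                on_constant = c("error", "na")) {
  on_constant <- match.arg(on_constant)
  series <- as.matrix(series)
  if (nrow(series) < 3) stop_data("need at least 3 frames, got %d", nrow(series))
  sds <- apply(series, 2, sd)
  const <- which(sds == 0 | is.na(sds))
  if (length(const)) {
    if (on_constant == "error")
      stop_data("constant node column(s): %s", paste(const, collapse = ", "))
    warn(sprintf("setting edges of %d constant node(s) to NA", length(const)))
  }
  R <- suppressWarnings(cor(series))
  if (length(const)) {
    R[const, ] <- NA_real_
    R[, const] <- NA_real_
  }
  diag(R) <- 1
  if (fisher_z) {
    R <- atanh(R)
    diag(R) <- 0
  }
  R
}

#' Read / write time-series and connectivity files
#'
#' Tab-delimited frames x nodes time-series files and node x node
#' connectivity files, following the `<subject>_<condition>` naming
#' convention used by [run_pipeline()].
#'
#' @param path File path.
#' @return `read_timeseries()` / `read_connectivity()`: a numeric matrix.
#' @export
read_timeseries <- function(path) {
  as.matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_timeseries
#' @param mat Matrix to write.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- as_tibble(as.data.frame(mat), .name_repair = "minimal")
  if (is.null(colnames(mat))) names(df) <- sprintf("node_%d", seq_len(ncol(mat)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname read_timeseries
#' @export
read_connectivity <- function(path) {
  m <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
  dimnames(m) <- NULL
  m
}
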