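# End-to-end orchestration: simulate -> severity -> connect -> predict ->
# anatomy -> molecular, with a manifest for bit-identical reproduction.

#' Pipeline run configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Every stochastic stage derives its seed deterministically from the
#' single `seed` field, so a config fully determines a run.
#'
#' @param label Free-text run label.
#' @param seed Master integer seed.
#' @param simulate Generate synthetic inputs? When `FALSE`, `inputs` must
#'   point at existing files.
#' @param n_subjects,n_nodes,frames_per_block,n_blocks_per_condition,
#'   factor_loading,effect_size,base_connectivity,coupling,n_pos_edges,
#'   n_neg_edges Generator settings (see [sim_config()]).
#' @param n_regions,planted_receptors Receptor-atlas settings (see
#'   [simulate_receptor_atlas()]).
#' @param condition Task condition analysed (`"punishment"` or `"reward"`).
#' @param scheme,k,repeats,p_threshold,network,n_perm,consensus CPM
#'   settings (see [cpm_fit()]).
#' @param alpha Significance level for the spatial correlation stage.
#' @param flip,anchor Severity-index settings (see
#'   [compute_severity_pc1()]).
#' @param inputs Named list of input paths (`behavior`, `timeseries_dir`,
#'   `atlas`, `receptors`, `contrasts`) used when `simulate = FALSE`.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(label = "demo",
                       seed = 1L,
                       simulate = TRUE,
                       n_subjects = 200, n_nodes = 60,
                       frames_per_block = 38, n_blocks_per_condition = 4,
                       factor_loading = 0.677,
                       effect_size = 0.2, base_connectivity = 0.2,
                       coupling = 0.26,
                       n_pos_edges = 10, n_neg_edges = 10,
                       n_regions = 119,
                       planted_receptors = list("5-HT1a_1" = 0.9, "GABAa_2" = 0.9),
                       condition = "punishment",
                       scheme = "loocv", k = 5, repeats = 10,
                       p_threshold = 0.01, network = "combined",
                       n_perm = 99, consensus = 0.9,
                       alpha = 0.05,
                       flip = default_flip_measures(),
                       anchor = "total_drinks_week",
                       inputs = list()) {
  cfg <- structure(list(
    label = label, seed = as.integer(seed), simulate = isTRUE(simulate),
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    frames_per_block = as.integer(frames_per_block),
    n_blocks_per_condition = as.integer(n_blocks_per_condition),
    factor_loading = factor_loading, effect_size = effect_size,
    base_connectivity = base_connectivity, coupling = coupling,
    n_pos_edges = as.integer(n_pos_edges), n_neg_edges = as.integer(n_neg_edges),
    n_regions = as.integer(n_regions), planted_receptors = planted_receptors,
    condition = condition,
    scheme = scheme, k = as.integer(k), repeats = as.integer(repeats),
    p_threshold = p_threshold, network = network,
    n_perm = as.integer(n_perm), consensus = consensus,
    alpha = alpha, flip = flip, anchor = anchor, inputs = inputs
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!cfg$scheme %in% c("loocv", "kfold")) stop_config("scheme must be loocv or kfold")
  if (!cfg$network %in% c("combined", "positive", "negative"))
    stop_config("network must be combined, positive or negative")
  if (cfg$p_threshold <= 0 || cfg$p_threshold >= 1)
    stop_config("p_threshold must lie in (0, 1)")
  if (!cfg$simulate) {
    if (is.null(cfg$inputs$behavior) || !file.exists(cfg$inputs$behavior))
      stop_config("simulate = FALSE but behaviour file is missing")
    if (is.null(cfg$inputs$timeseries_dir) || !dir.exists(cfg$inputs$timeseries_dir))
      stop_config("simulate = FALSE but time-series directory is missing")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> severity -> connect -> predict ->
#' anatomy -> molecular on a [run_config()], writing every stage's outputs
#' plus a `manifest.json` (config, config hash, derived seeds, package and
#' R versions, per-stage timings, output files) into `out_dir`. Re-running
#' the same config reproduces all stochastic outputs bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages?
#' @return Invisibly, a list with the main in-memory results (`severity`,
#'   `cpm`, `network_matrix`, `spatial`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "netfp_pipeline_error", parent = e)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say("stage %-9s done in %6.2f s", name, timings[[name]])
    res
  }

  # -- stage: simulate / load inputs ---------------------------------------
  sim <- stage("simulate", {
    if (config$simulate) {
      sets <- sample_edge_sets(config$n_nodes, config$n_pos_edges,
                               config$n_neg_edges,
                               seed = derive_seed(config$seed, "edges"))
      scfg <- sim_config(
        n_subjects = config$n_subjects, n_nodes = config$n_nodes,
        frames_per_block = config$frames_per_block,
        n_blocks_per_condition = config$n_blocks_per_condition,
        factor_loading = config$factor_loading,
        planted_pos_edges = sets$pos, planted_neg_edges = sets$neg,
        effect_size = config$effect_size,
        base_connectivity = config$base_connectivity,
        coupling = config$coupling,
        conditions = config$condition, seed = config$seed)
      beh <- simulate_behavior(scfg)
      ts <- simulate_timeseries(scfg, beh$ground_truth$latent_severity)
      atlas <- synthetic_shen_atlas(config$n_nodes, seed = config$seed)
      rec <- simulate_receptor_atlas(
        n_regions = config$n_regions,
        planted = unlist(config$planted_receptors),
        seed = derive_seed(config$seed, "rec"))
      contrasts <- simulate_regional_contrasts(
        rec$ground_truth$target, beh$ground_truth$latent_severity,
        regions = rec$tmap$region, beta = 0.5,
        seed = derive_seed(config$seed, "contrasts"))

      behavior_tbl <- left_join(beh$measures, beh$covariates, by = "subject")
      readr::write_tsv(behavior_tbl, file.path(out_dir, "behavior.tsv"))
      ts_dir <- file.path(out_dir, "timeseries")
      dir.create(ts_dir, showWarnings = FALSE)
      for (s in names(ts$series)) {
        write_matrix_tsv(ts$series[[s]][[config$condition]],
                         file.path(ts_dir, sprintf("%s_%s.tsv", s, config$condition)))
      }
      write_atlas_table(atlas, file.path(out_dir, "atlas.tsv"))
      readr::write_tsv(rec$receptors, file.path(out_dir, "receptors.tsv"))
      readr::write_tsv(as_tibble(as.data.frame(contrasts), rownames = "subject"),
                       file.path(out_dir, "contrasts.tsv"))
      gt <- list(
        latent_severity = beh$ground_truth$latent_severity,
        planted_pos_edges = apply(sets$pos, 1, paste, collapse = "-"),
        planted_neg_edges = apply(sets$neg, 1, paste, collapse = "-"),
        effect_size = config$effect_size, coupling = config$coupling,
        planted_receptors = config$planted_receptors)
      jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(behavior = behavior_tbl, ts_dir = ts_dir, atlas = atlas,
           receptors = rec$receptors, contrasts = contrasts)
    } else {
      list(behavior = read_behavior_table(config$inputs$behavior),
           ts_dir = config$inputs$timeseries_dir,
           atlas = read_atlas_table(config$inputs$atlas),
           receptors = read_receptor_table(config$inputs$receptors),
           contrasts = {
             d <- readr::read_tsv(config$inputs$contrasts, show_col_types = FALSE)
             m <- as.matrix(d[names(d) != "subject"])
             rownames(m) <- d$subject
             m
           })
    }
  })

  # -- stage: severity ------------------------------------------------------
  severity <- stage("severity", {
    measure_cols <- setdiff(names(sim$behavior), c("age", "sex"))
    idx <- compute_severity_pc1(sim$behavior[measure_cols],
                                flip = intersect(config$flip, measure_cols),
                                anchor = config$anchor)
    write_severity(idx, file.path(out_dir, "severity.tsv"))
    jsonlite::write_json(
      list(eigenvalue = idx$eigenvalue,
           variance_explained = idx$variance_explained,
           loadings = idx$loadings),
      file.path(out_dir, "severity_summary.json"), auto_unbox = TRUE, digits = NA)
    idx
  })

  # -- stage: connect -------------------------------------------------------
  conn <- stage("connect", {
    subjects <- severity$scores$subject
    files <- file.path(sim$ts_dir, sprintf("%s_%s.tsv", subjects, config$condition))
    missing <- !file.exists(files)
    if (any(missing))
      stop_data("missing time-series file(s): %s",
                paste(head(basename(files[missing]), 5), collapse = ", "))
    conn_dir <- file.path(out_dir, "connectivity")
    dir.create(conn_dir, showWarnings = FALSE)
    mats <- lapply(seq_along(subjects), function(i) {
      m <- connectivity_matrix(read_timeseries(files[i]))
      write_matrix_tsv(m, file.path(conn_dir, sprintf("%s_%s_conn.tsv",
                                                      subjects[i], config$condition)))
      m
    })
    names(mats) <- subjects
    mats
  })

  # -- stage: predict -------------------------------------------------------
  cpm <- stage("predict", {
    covs <- sim$behavior[match(severity$scores$subject, sim$behavior$subject),
                         c("age", "sex")]
    fit <- cpm_fit(conn, severity, covariates = covs,
                   scheme = config$scheme, k = config$k,
                   repeats = config$repeats, p_threshold = config$p_threshold,
                   network = config$network, n_perm = config$n_perm,
                   seed = derive_seed(config$seed, "cpm"),
                   consensus = config$consensus)
    write_edge_mask(fit$consensus_mask,
                    file.path(out_dir, "mask_pos.edges"),
                    file.path(out_dir, "mask_neg.edges"))
    readr::write_tsv(fit$predictions, file.path(out_dir, "predictions.tsv"))
    jsonlite::write_json(as.list(glance(fit)), file.path(out_dir, "cpm_result.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  # -- stage: anatomy -------------------------------------------------------
  anat <- stage("anatomy", {
    mask <- cpm$consensus_mask
    degrees <- node_degrees(mask, n_nodes = config$n_nodes)
    readr::write_tsv(degrees, file.path(out_dir, "degrees.tsv"))
    nm <- summarize_by_network(mask, sim$atlas)
    for (pol in c("positive", "negative", "sum")) {
      readr::write_tsv(as_tibble(as.data.frame(nm[[pol]]), rownames = "network"),
                       file.path(out_dir, sprintf("network_matrix_%s.tsv", pol)))
    }
    list(degrees = degrees, network_matrix = nm,
         edge_fraction = edge_fraction(sum(mask_sizes(mask)), config$n_nodes))
  })

  # -- stage: molecular -----------------------------------------------------
  molecular <- stage("molecular", {
    tmap <- parcel_glm_tmap(sim$contrasts, severity,
                            covariates = sim$behavior[match(severity$scores$subject,
                                                            sim$behavior$subject),
                                                      c("age", "sex")],
                            contrast = paste0(config$condition, "-baseline"))
    write_molecular_table(tmap, file.path(out_dir, "tmap.tsv"))
    sc <- spatial_correlation(tmap, sim$receptors, alpha = config$alpha)
    write_molecular_table(sc, file.path(out_dir, "spatial_corr.tsv"))
    sc
  })

  manifest <- list(
    label = config$label,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seeds = list(master = config$seed,
                 cpm = derive_seed(config$seed, "cpm"),
                 receptors = derive_seed(config$seed, "rec")),
    package_version = as.character(packageVersion("netfingerprint")),
    r_version = as.character(getRversion()),
    timings_s = timings,
    outputs = sort(list.files(out_dir, recursive = FALSE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: r = %.3f, p = %s", cpm$r, format(cpm$p))
  invisible(list(severity = severity, cpm = cpm,
                 anatomy = anat, spatial = molecular, manifest = manifest))
}
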