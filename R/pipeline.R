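#' Pipeline run configuration
#'
#' Validated bag of parameters for [run_pipeline()]. Unknown keys are
#' rejected; every numeric parameter is bounds-checked.
#'
#' @param atlas An `annotation_volume` (or path prefix readable by
#'   [read_atlas()]).
#' @param plan Synthetic cohort plan for [generate_cohort()]; alternatively
#'   supply `swc_dir` with existing SWC files and a `manifest` tibble.
#' @param out_dir Output directory.
#' @param swc_dir Directory of existing SWC inputs (ignored when `plan` is
#'   given).
#' @param manifest Ground-truth/metadata tibble for `swc_dir` inputs
#'   (columns `neuron_id`, `s_type`, `path`).
#' @param resample_step Resampling step, um (> 0). Default 10.
#' @param alpha Alpha-shape parameter, voxel units (> 0). Default 0.4.
#' @param k_range GMM component range.
#' @param subtype_k_range Candidate subtype counts.
#' @param compartment Barcode compartment ("axon" default).
#' @param qc Apply the dendritic QC filter stage. Default FALSE.
#' @param qc_limits A [qc_intervals()] object when `qc` is TRUE.
#' @param stages Character subset of
#'   `c("simulate","qc","domains","barcode","scores","subtype")`.
#' @param seed Global seed; per-stage seeds are derived from it by hashing
#'   the stage name.
#' @return A validated `run_config`.
#' @export
run_config <- function(atlas, plan = NULL, out_dir = tempfile("run"),
                       swc_dir = NULL, manifest = NULL,
                       resample_step = 10, alpha = 0.4,
                       k_range = 1:6, subtype_k_range = NULL,
                       compartment = "axon", qc = FALSE,
                       qc_limits = NULL,
                       stages = c("simulate", "domains", "barcode",
                                  "scores", "subtype"),
                       seed = 1) {
  known <- c("simulate", "qc", "domains", "barcode", "scores", "subtype")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ",
                                    paste(bad, collapse = ", ")))
  if (!is.numeric(resample_step) || resample_step <= 0) {
    abort("resample_step must be > 0")
  }
  if (!is.numeric(alpha) || alpha <= 0) abort("alpha must be > 0")
  if (!compartment %in% c("axon", "dendrite", "whole")) {
    abort("compartment must be axon/dendrite/whole")
  }
  if (is.null(plan) && is.null(swc_dir)) {
    abort("either a synthetic plan or an swc_dir must be supplied")
  }
  structure(
    list(atlas = atlas, plan = plan, out_dir = out_dir, swc_dir = swc_dir,
         manifest = manifest, resample_step = resample_step, alpha = alpha,
         k_range = k_range, subtype_k_range = subtype_k_range,
         compartment = compartment, qc = isTRUE(qc),
         qc_intervals = qc_limits %||% qc_intervals(),
         stages = stages, seed = as.integer(seed)),
    class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML carries scalar fields of [run_config()] (paths, step, alpha,
#' seed, stages); the atlas is read from `atlas_prefix` via [read_atlas()].
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("atlas_prefix", "mirror_axis", "swc_dir", "out_dir",
             "resample_step", "alpha", "k_range", "subtype_k_range",
             "compartment", "qc", "stages", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) abort(paste0("unknown config key(s): ",
                                    paste(bad, collapse = ", ")))
  atlas <- read_atlas(y$atlas_prefix, mirror_axis = y$mirror_axis %||% 3)
  run_config(atlas = atlas, swc_dir = y$swc_dir,
             out_dir = y$out_dir %||% tempfile("run"),
             resample_step = y$resample_step %||% 10,
             alpha = y$alpha %||% 0.4,
             k_range = if (!is.null(y$k_range)) seq_len(y$k_range) else 1:6,
             subtype_k_range = y$subtype_k_range,
             compartment = y$compartment %||% "axon",
             qc = y$qc %||% FALSE,
             stages = y$stages %||% c("simulate", "domains", "barcode",
                                      "scores", "subtype"),
             seed = y$seed %||% 1)
}

stage_seed <- function(seed, stage) {
  h <- as.double(digest::digest2int(paste0(stage, ":", seed)))
  as.integer(((h %% 2147483646) + 2147483646) %% 2147483646) + 1L
}

#' Run the potential-connectivity typing pipeline
#'
#' Executes the enabled stages in dependency order - simulate (or load) ->
#' optional QC -> resample -> dendritic domains + panel -> connectivity
#' barcodes -> m/c scores + soma-distance correlations -> spatially tuned
#' subtyping - writing CSV/JSON outputs under `out_dir` and returning a
#' machine-readable run manifest with per-output hashes. Re-running with an
#' identical config reproduces identical hashes.
#'
#' @param config A [run_config()].
#' @return A `pipeline_run`: list with `manifest` (config snapshot, stage
#'   seeds, output hashes, warnings) and `results` (in-memory stage
#'   outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  atlas <- config$atlas
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  warnings <- character(0)
  results <- list()
  note <- function(msg) warnings <<- c(warnings, msg)

  # --- simulate / load -------------------------------------------------
  if ("simulate" %in% config$stages && !is.null(config$plan)) {
    swc_dir <- file.path(config$out_dir, "swc")
    manifest <- generate_cohort(config$plan, atlas,
                                seed = stage_seed(config$seed, "simulate"),
                                dir = swc_dir)
    outputs <- c(outputs, file.path(swc_dir, "manifest.json"))
  } else {
    if (is.null(config$swc_dir) || !dir.exists(config$swc_dir)) {
      abort("swc_dir missing and no synthetic plan supplied")
    }
    swc_dir <- config$swc_dir
    manifest <- config$manifest
    if (is.null(manifest)) {
      files <- list.files(swc_dir, pattern = "\\.swc$", full.names = TRUE)
      if (length(files) == 0) abort("no SWC files found in swc_dir")
      manifest <- tibble::tibble(
        neuron_id = sub("\\.swc$", "", basename(files)),
        s_type = NA_integer_, path = files)
    }
  }
  neurons <- lapply(manifest$path, read_swc)
  names(neurons) <- manifest$neuron_id
  results$manifest <- manifest

  # --- qc --------------------------------------------------------------
  if ("qc" %in% config$stages && config$qc) {
    qcres <- lapply(neurons, function(n) qc_filter(list(n),
                                                   config$qc_intervals))
    kept <- !vapply(qcres, function(q) is.null(q$kept), logical(1))
    if (!all(kept)) note(paste0(sum(!kept), " neuron(s) discarded by QC"))
    neurons <- neurons[kept]
    manifest <- manifest[kept, ]
  }

  # --- resample --------------------------------------------------------
  neurons <- lapply(neurons, resample_morphology,
                    step = config$resample_step)
  results$neurons <- neurons

  # --- domains ---------------------------------------------------------
  if ("domains" %in% config$stages) {
    stypes <- sort(unique(manifest$s_type))
    stype_domains <- list()
    gmm_fits <- list()
    for (st in stypes) {
      nn <- neurons[manifest$neuron_id[manifest$s_type == st]]
      dd <- pooled_dendrite_domain(nn, atlas, s_type = st,
                                   alpha = config$alpha)
      stype_domains <- c(stype_domains, dd)
      fit <- detect_arbor_domains(nn, atlas, s_type = st,
                                  alpha = config$alpha,
                                  k_range = config$k_range,
                                  seed = stage_seed(config$seed, "domains"))
      gmm_fits[[as.character(st)]] <- fit
    }
    panel <- whole_brain_panel(list(), stype_domains, atlas)
    results$panel <- panel
    results$gmm <- gmm_fits
    pj <- file.path(config$out_dir, "panel.json")
    jsonlite::write_json(panel$table, pj, digits = NA)
    outputs <- c(outputs, pj)
  }

  # --- barcode ---------------------------------------------------------
  if ("barcode" %in% config$stages) {
    conn <- connectivity_matrix(neurons, results$panel, atlas,
                                alpha = config$alpha,
                                compartment = config$compartment)
    results$connectivity <- conn
    cf <- file.path(config$out_dir, "connectivity.csv")
    utils::write.csv(conn, cf, row.names = FALSE)
    outputs <- c(outputs, cf)
  }

  # --- scores ----------------------------------------------------------
  if ("scores" %in% config$stages) {
    feats <- feature_table(neurons, compartment = "whole")
    fcols <- c("tips", "total_length", "max_path_distance",
               "n_bifurcations", "max_branch_order",
               "avg_bifurcation_angle_remote", "max_euclidean_distance")
    groups_key <- if ("c_subtype" %in% names(manifest)) {
      paste0(manifest$s_type, "/", manifest$c_subtype)
    } else as.character(manifest$s_type)
    m_groups <- split_feature_rows(feats[, fcols], groups_key)
    cmat <- barcode_matrix(results$connectivity)
    c_groups <- split_feature_rows(as.data.frame(cmat), groups_key)
    msc <- score_matrix(m_groups)
    csc <- score_matrix(c_groups)
    rat <- ratio_matrix(csc, msc)
    results$scores <- list(m = msc, c = csc, ratio = rat)
    sf <- file.path(config$out_dir, "scores.json")
    jsonlite::write_json(list(frac_ratio_lt_1 = rat$frac_lt_1), sf,
                         digits = NA, auto_unbox = TRUE)
    outputs <- c(outputs, sf)
  }

  # --- subtype ---------------------------------------------------------
  if ("subtype" %in% config$stages) {
    sub_results <- list()
    for (st in sort(unique(manifest$s_type))) {
      sel <- manifest$s_type == st
      if (sum(sel) < 4) next
      ids <- manifest$neuron_id[sel]
      somas <- as.matrix(manifest[sel, c("soma_x", "soma_y", "soma_z")])
      rownames(somas) <- ids
      dmap <- soma_distance_map(somas, st, atlas)
      cmat <- barcode_matrix(results$connectivity)[ids, , drop = FALSE]
      keep <- rowSums(cmat != 0) > 0
      if (sum(keep) < 4) next
      bundle <- build_affinity(cmat[keep, , drop = FALSE],
                               dmap[keep, keep, drop = FALSE])
      sub_results[[as.character(st)]] <-
        subtype_clusters(bundle, k_range = config$subtype_k_range)
    }
    results$subtypes <- sub_results
    lf <- file.path(config$out_dir, "subtypes.csv")
    lab <- dplyr::bind_rows(lapply(names(sub_results), function(st) {
      dplyr::mutate(tidy(sub_results[[st]]), s_type = as.integer(st))
    }))
    utils::write.csv(lab, lf, row.names = FALSE)
    outputs <- c(outputs, lf)
  }

  hashes <- vapply(outputs, function(f) digest::digest(file = f),
                   character(1))
  manifest_out <- list(
    config = config_snapshot(config),
    stage_seeds = setNames(
      lapply(config$stages, function(s) stage_seed(config$seed, s)),
      config$stages),
    outputs = setNames(as.list(hashes), basename(outputs)),
    warnings = warnings)
  mf <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest_out, mf, digits = NA, auto_unbox = TRUE)
  structure(list(manifest = manifest_out, results = results,
                 out_dir = config$out_dir),
            class = "pipeline_run")
}

split_feature_rows <- function(df, key) {
  m <- as.matrix(df)
  lapply(split(seq_len(nrow(m)), key), function(i) m[i, , drop = FALSE])
}

config_snapshot <- function(config) {
  list(resample_step = config$resample_step, alpha = config$alpha,
       k_range = range(config$k_range), compartment = config$compartment,
       qc = config$qc, stages = config$stages, seed = config$seed)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages: ",
      paste(x$manifest$config$stages, collapse = " -> "), "\n  outputs: ",
      paste(names(x$manifest$outputs), collapse = ", "), "\n", sep = "")
  invisible(x)
}
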