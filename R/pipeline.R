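# End-to-end orchestration: simulate (or load) -> preprocess -> subject GLM
# -> group maps -> ROI correlation, with a reproducibility manifest and
# deterministic result tables.

#' Pipeline configuration
#'
#' Validates and normalises the full parameter set of [run_pipeline()].
#'
#' @param out_dir results directory.
#' @param seed integer seed driving every stochastic component.
#' @param simulate logical; generate a synthetic study (`TRUE`) or read
#'   recordings from `input_dirs` (one recording bundle per subject, with a
#'   `clinical` table path required).
#' @param sim a [sim_params()] used when simulating.
#' @param input_dirs,clinical_path,roi_path inputs when `simulate = FALSE`.
#' @param condition_map optional stimulus-label mapping for loaded data.
#' @param cutoff_hz,variance_fraction,iqr_factor,dpf preprocessing knobs.
#' @param peak_time,max_ar_order subject-GLM knobs (`NULL` = `round(4 fs)`).
#' @param alpha ROI-CA step-1 channel selection level.
#' @param sensitivity_threshold ROI sensitivity threshold.
#' @param write_recordings also persist simulated recordings as text
#'   bundles (large; default `FALSE`).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE,
                            sim = sim_params(),
                            input_dirs = NULL, clinical_path = NULL,
                            roi_path = NULL, condition_map = NULL,
                            cutoff_hz = 0.01, variance_fraction = 0.80,
                            iqr_factor = 1.5, dpf = c(6, 6),
                            peak_time = 6, max_ar_order = NULL,
                            alpha = 0.05, sensitivity_threshold = 0.20,
                            write_recordings = FALSE) {
  assert(is_scalar_num(cutoff_hz) && cutoff_hz > 0, "fp_config",
         "cutoff_hz must be > 0")
  assert(is_scalar_num(variance_fraction) && variance_fraction > 0 &&
           variance_fraction < 1, "fp_config",
         "variance_fraction must lie in (0, 1)")
  assert(is_scalar_num(iqr_factor) || identical(iqr_factor, Inf), "fp_config",
         "iqr_factor must be numeric")
  assert(iqr_factor > 0, "fp_config", "iqr_factor must be > 0")
  assert(all(dpf > 0) && length(dpf) == 2, "fp_config",
         "dpf must be two positive values")
  assert(is_scalar_num(peak_time) && peak_time > 0, "fp_config",
         "peak_time must be > 0")
  assert(is_scalar_num(alpha) && alpha > 0 && alpha < 1, "fp_config",
         "alpha must lie in (0, 1)")
  assert(is_scalar_num(sensitivity_threshold) && sensitivity_threshold > 0 &&
           sensitivity_threshold <= 1, "fp_config",
         "sensitivity_threshold must lie in (0, 1]")
  if (!simulate) {
    assert(length(input_dirs) >= 1 && !is.null(clinical_path), "fp_config",
           "non-simulated runs need input_dirs and clinical_path")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim, input_dirs = input_dirs,
                 clinical_path = clinical_path, roi_path = roi_path,
                 condition_map = condition_map, cutoff_hz = cutoff_hz,
                 variance_fraction = variance_fraction,
                 iqr_factor = iqr_factor, dpf = dpf, peak_time = peak_time,
                 max_ar_order = max_ar_order, alpha = alpha,
                 sensitivity_threshold = sensitivity_threshold,
                 write_recordings = write_recordings),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: study simulation (or loading), preprocessing,
#' subject-level GLM with task-vs-rest contrasts, group-level
#' mixed-effects activation and between-group contrast maps, ROI-based
#' correlation analysis, and group characterisation; writes one
#' tab-separated result table per stage plus a reproducibility manifest.
#' Identical configuration and seed reproduce every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return (invisibly) list with the in-memory results and the paths of
#'   the written tables.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  assert(inherits(config, "pipeline_config"), "fp_config",
         "config must come from pipeline_config()")
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  stage <- "simulate"
  result <- tryCatch({
    if (cfg$simulate) {
      say("simulating study (seed %d)", cfg$seed)
      study <- simulate_study(cfg$sim, seed = cfg$seed)
      subjects <- study$subjects
      clinical <- study$clinical
      roi_cfg <- study$roi_config
      if (cfg$write_recordings) {
        for (s in subjects) {
          write_recording(s$intensity, s$design,
                          file.path(cfg$out_dir, "recordings", s$id))
        }
      }
    } else {
      say("loading %d recordings", length(cfg$input_dirs))
      clinical <- read_clinical_table(cfg$clinical_path)
      subjects <- lapply(seq_along(cfg$input_dirs), function(i) {
        rec <- read_recording(cfg$input_dirs[i], cfg$condition_map)
        id <- as.character(clinical$subject[i])
        list(id = id, group = clinical$group[i],
             design = rec$design, intensity = rec$intensity)
      })
      roi_cfg <- if (!is.null(cfg$roi_path)) {
        load_roi_config(cfg$roi_path, subjects[[1]]$intensity$montage)
      } else NULL
    }
    write_clinical_table(clinical, file.path(cfg$out_dir, "clinical.tsv"))

    stage <- "preprocess+slsa"
    slsa_rows <- list()
    for (s in subjects) {
      say("subject %s: preprocess + GLM", s$id)
      hb <- preprocess_recording(s$intensity, cutoff_hz = cfg$cutoff_hz,
                                 variance_fraction = cfg$variance_fraction,
                                 iqr_factor = cfg$iqr_factor, dpf = cfg$dpf)
      glm <- fit_subject_glm(hb, s$design, max_ar_order = cfg$max_ar_order,
                             peak_time = cfg$peak_time)
      for (cond in glm$design_matrix$conditions) {
        cmap <- contrast_map(glm, cond)
        cmap$subject <- s$id
        cmap$group <- s$group
        slsa_rows[[length(slsa_rows) + 1]] <- cmap
      }
    }
    slsa <- do.call(rbind, slsa_rows)
    slsa <- slsa[, c("subject", "group", "channel", "chromophore",
                     "condition", "estimate", "se", "t", "p", "q",
                     "ar_order", "dof")]
    names(slsa)[names(slsa) == "estimate"] <- "beta"
    write_num_table(slsa, file.path(cfg$out_dir, "subject_glm.tsv"))

    stage <- "glsa"
    say("group-level mixed-effects maps")
    model <- fit_group_model(slsa)
    maps <- list()
    for (cond in unique(slsa$condition)) {
      for (g in unique(slsa$group)) {
        maps[[length(maps) + 1]] <- group_activation_map(model, g, cond)
      }
      if (length(unique(slsa$group)) == 2) {
        maps[[length(maps) + 1]] <- group_contrast_map(model, cond)
      }
    }
    group_maps <- do.call(rbind, maps)
    write_num_table(group_maps, file.path(cfg$out_dir, "group_maps.tsv"))

    stage <- "roica"
    roica <- NULL
    contrast_maps <- group_maps[grepl("^contrast:", group_maps$map), ]
    if (!is.null(roi_cfg) && nrow(contrast_maps)) {
      say("ROI-based correlation analysis")
      roica <- roi_ca(contrast_maps, slsa, roi_cfg, clinical,
                      alpha = cfg$alpha)
      write_num_table(roica, file.path(cfg$out_dir, "roica.tsv"))
    }

    stage <- "characterize"
    characterization <- tryCatch(
      characterize_groups(clinical),
      error = function(e) NULL)
    if (!is.null(characterization)) {
      write_num_table(characterization,
                      file.path(cfg$out_dir, "group_characterization.tsv"))
    }

    list(subject_glm = slsa, group_maps = group_maps, roica = roica,
         characterization = characterization, clinical = clinical)
  }, error = function(e) {
    fp_stop("fp_pipeline", "pipeline failed at stage '%s': %s", stage,
            conditionMessage(e))
  })

  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL
  cfg_file <- file.path(cfg$out_dir, "config.json")
  writeLines(jsonlite::serializeJSON(cfg_for_hash, pretty = TRUE), cfg_file)
  manifest <- list(
    package = "fnirspipe",
    version = as.character(utils::packageVersion("fnirspipe")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    tables = list(
      subject_glm = nrow(result$subject_glm),
      group_maps = nrow(result$group_maps),
      roica = if (is.null(result$roica)) 0L else nrow(result$roica),
      clinical = nrow(result$clinical)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(result, list(out_dir = cfg$out_dir)))
}
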