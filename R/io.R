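# On-disk formats: plain-text recording bundles, clinical tables, ROI and
# pipeline configuration, result tables.
#
# A recording is stored as a directory of tab-separated text files plus a
# small YAML header -- one intensity file per wavelength with channels as
# columns, montage tables for sources/detectors/channels, and an event
# table.  Numeric payloads are written with 17 significant digits so that a
# write/read cycle reproduces the doubles bit-for-bit.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_num_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an fNIRS recording to a plain-text bundle
#'
#' @param rec an [fnirs_intensity()] recording.
#' @param design optional [stim_design()] event table.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, design = NULL, path) {
  assert(inherits(rec, "fnirs_intensity"), "fp_validation",
         "rec must be an fnirs_intensity")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- rec$montage
  meta <- list(format = "fnirspipe-recording", version = 1L,
               sampling_frequency_hz = rec$fs,
               wavelengths_nm = as.numeric(m$wavelengths),
               n_channels = n_channels(m), n_samples = dim(rec$intensity)[3])
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  write_num_table(m$sources, file.path(path, "sources.tsv"))
  write_num_table(m$detectors, file.path(path, "detectors.tsv"))
  write_num_table(m$channels, file.path(path, "channels.tsv"))
  for (w in 1:2) {
    mat <- t(rec$intensity[, w, , drop = TRUE])
    if (n_channels(m) == 1L) mat <- matrix(rec$intensity[, w, ], ncol = 1)
    df <- as.data.frame(mat)
    names(df) <- channel_ids(m)
    write_num_table(df, file.path(path, sprintf("intensity_wl%g.tsv",
                                                m$wavelengths[w])))
  }
  if (!is.null(design)) {
    ev <- design$events
    write_num_table(ev, file.path(path, "events.tsv"))
    cat(fmt_num(design$duration), "\n", sep = "",
        file = file.path(path, "events_total_duration.txt"))
  }
  invisible(path)
}

#' Read an fNIRS recording from a plain-text bundle
#'
#' @param path directory written by [write_recording()].
#' @param condition_map optional named character vector mapping on-disk
#'   stimulus labels to canonical condition names (default: identity, with
#'   "LG"/"RG" expected).
#' @return list with elements `intensity` ([fnirs_intensity()]), `montage`,
#'   and `design` ([stim_design()] or `NULL`).
#' @export
read_recording <- function(path, condition_map = NULL) {
  need <- function(f) {
    fp <- file.path(path, f)
    assert(file.exists(fp), "fp_format", "recording is missing '%s'", f)
    fp
  }
  meta <- yaml::read_yaml(need("meta.yaml"))
  wl <- as.numeric(meta$wavelengths_nm)
  assert(length(wl) == 2L, "fp_unsupported_data",
         "recording has %d wavelengths; only dual-wavelength data supported",
         length(wl))
  as_num <- function(df, cols) {
    for (nm in intersect(cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
    df
  }
  sources <- as_num(utils::read.delim(need("sources.tsv")), c("x", "y", "z"))
  detectors <- as_num(utils::read.delim(need("detectors.tsv")),
                      c("x", "y", "z"))
  channels <- as_num(utils::read.delim(need("channels.tsv")), "distance")
  montage <- fnirs_montage(wl, sources, detectors, channels)
  n_ch <- n_channels(montage)
  arr <- NULL
  for (w in 1:2) {
    df <- utils::read.delim(need(sprintf("intensity_wl%g.tsv", wl[w])),
                            check.names = FALSE, colClasses = "numeric")
    assert(ncol(df) == n_ch, "fp_format",
           "intensity table has %d columns but montage %d channels",
           ncol(df), n_ch)
    if (is.null(arr)) arr <- array(NA_real_, c(n_ch, 2, nrow(df)))
    arr[, w, ] <- t(as.matrix(df))
  }
  rec <- fnirs_intensity(meta$sampling_frequency_hz, arr, montage)
  design <- NULL
  if (file.exists(file.path(path, "events.tsv"))) {
    ev <- as_num(utils::read.delim(file.path(path, "events.tsv")),
                 c("onset", "duration"))
    if (!is.null(condition_map)) {
      mapped <- condition_map[ev$condition]
      assert(!anyNA(mapped), "fp_config",
             "condition_map does not cover stimulus label '%s'",
             ev$condition[which(is.na(mapped))[1]])
      ev$condition <- unname(mapped)
    }
    total <- as.numeric(readLines(file.path(path, "events_total_duration.txt"))[1])
    design <- stim_design(ev, total)
  }
  list(intensity = rec, montage = montage, design = design)
}

#' Read a clinical covariate table
#'
#' Parses a comma- or tab-delimited table with one row per subject.  Column
#' names are matched case-insensitively; `subject` and `group` are required,
#' and the conventional clinical covariates (`age`, `criq`, `duration`,
#' `updrs`, `scwe`, `scwt`) are parsed as numerics when present.  Group
#' labels are normalised case-insensitively to `ePD` (early) / `mPD`
#' (moderate) Parkinson's disease.
#'
#' @param path file path (delimiter sniffed from the header line), or a
#'   data.frame to validate/normalise directly.
#' @return validated data.frame of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  assert(all(c("subject", "group") %in% names(df)), "fp_format",
         "clinical table needs 'subject' and 'group' columns")
  assert(!anyDuplicated(df$subject), "fp_validation",
         "duplicated subject id in clinical table")
  grp <- tolower(trimws(as.character(df$group)))
  known <- c(epd = "ePD", mpd = "mPD")
  assert(all(grp %in% names(known)), "fp_validation",
         "unknown group label '%s' (expected ePD or mPD)",
         df$group[which(!grp %in% names(known))[1]])
  df$group <- unname(known[grp])
  num_cols <- intersect(names(df), c("age", "criq", "duration", "updrs",
                                     "scwe", "scwt"))
  for (nm in num_cols) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      v <- trimws(as.character(v))
      v[v == ""] <- NA
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      assert(!length(bad), "fp_format",
             "unparseable numeric cell '%s' in column '%s', row %d",
             v[bad[1]], nm, bad[1])
      v <- parsed
    }
    df[[nm]] <- v
  }
  if ("age" %in% names(df)) {
    assert(all(is.na(df$age) | df$age > 0), "fp_validation", "age must be > 0")
  }
  if ("duration" %in% names(df)) {
    assert(all(is.na(df$duration) | df$duration >= 0), "fp_validation",
           "disease duration cannot be negative")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical covariate table
#' @param clinical data.frame as returned by [read_clinical_table()].
#' @param path output file (tab-separated).
#' @export
write_clinical_table <- function(clinical, path) {
  write_num_table(as.data.frame(clinical), path)
  invisible(path)
}

#' Load a region-of-interest configuration
#'
#' An ROI configuration assigns montage channels to labelled cortical
#' regions.  Membership is given either explicitly (channel ids, or
#' source/detector pairs) or implicitly through a sensitivity matrix (the
#' fraction of each region's signal collected by each channel), which is
#' thresholded with [select_roi_channels_by_sensitivity()].
#'
#' @param config path to a YAML/JSON file, or an equivalent list with
#'   elements `rois` (list of `label`, optional `hemisphere`/`area`, and
#'   `channels` or `pairs`) and/or `sensitivity` (named rows = ROI labels,
#'   columns = channels) plus optional `threshold`.
#' @param montage the montage the channel ids refer to.
#' @return object of class `roi_config`: data.frame `rois` plus named list
#'   `membership` and optional `sensitivity` matrix.
#' @export
load_roi_config <- function(config, montage) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  rois <- config$rois %||% list()
  labels <- vapply(rois, function(r) as.character(r$label), character(1))
  assert(!anyDuplicated(labels), "fp_config", "duplicate ROI label '%s'",
         labels[anyDuplicated(labels)])
  ch_ids <- channel_ids(montage)
  membership <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (!is.null(r$channels)) {
      chs <- as.character(unlist(r$channels))
    } else if (!is.null(r$pairs)) {
      prs <- r$pairs
      chs <- vapply(prs, function(p) {
        hit <- montage$channels$channel[
          montage$channels$source == p[[1]] & montage$channels$detector == p[[2]]]
        assert(length(hit) == 1L, "fp_config",
               "no channel for source-detector pair (%s, %s)", p[[1]], p[[2]])
        as.character(hit)
      }, character(1))
    } else {
      chs <- character(0)
    }
    bad <- setdiff(chs, ch_ids)
    assert(!length(bad), "fp_config", "ROI '%s' references unknown channel '%s'",
           labels[i], if (length(bad)) bad[1] else "")
    membership[[i]] <- chs
  }
  sens <- NULL
  if (!is.null(config$sensitivity)) {
    sens <- as.matrix(as.data.frame(config$sensitivity, check.names = FALSE))
    if (!is.null(config$sensitivity_rois)) {
      rownames(sens) <- config$sensitivity_rois
    }
    assert(all(sens >= 0 & sens <= 1), "fp_config",
           "sensitivity fractions must lie in [0, 1]")
    assert(all(colnames(sens) %in% ch_ids), "fp_config",
           "sensitivity matrix references unknown channels")
    thr <- config$threshold %||% 0.20
    sel <- select_roi_channels_by_sensitivity(sens, thr)
    for (lab in names(sel)) membership[[lab]] <- sel[[lab]]
    labels <- names(membership)
  }
  roi_df <- data.frame(
    roi = labels,
    hemisphere = vapply(labels, function(l) {
      h <- substr(l, 1, 1)
      if (h %in% c("L", "R")) h else NA_character_
    }, character(1)),
    area = sub("^[LR]-", "", labels),
    n_channels = vapply(membership, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(rois = roi_df, membership = membership, sensitivity = sens),
            class = "roi_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roi_config <- function(x, ...) {
  cat(sprintf("ROI configuration: %d regions (%s)\n", nrow(x$rois),
              paste(x$rois$roi, collapse = ", ")))
  invisible(x)
}

# roi_config from the synthetic montage's ROI table
roi_config_from_table <- function(roi_tab) {
  labels <- unique(roi_tab$roi)
  membership <- lapply(stats::setNames(labels, labels), function(l) {
    roi_tab$channel[roi_tab$roi == l]
  })
  roi_df <- data.frame(roi = labels,
                       hemisphere = substr(labels, 1, 1),
                       area = sub("^[LR]-", "", labels),
                       n_channels = lengths(membership),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(rois = roi_df, membership = membership, sensitivity = NULL),
            class = "roi_config")
}
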