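# Montage: optode geometry and channel (source-detector pair) definitions.

#' Construct an fNIRS montage
#'
#' A montage describes the optode layout of a continuous-wave fNIRS
#' recording: the two measurement wavelengths, source and detector optodes
#' (with optional 3D scalp positions in mm), and the measurement channels,
#' each a source-detector pairing with its geometric distance.
#'
#' @param wavelengths numeric length-2, wavelengths in nm (both in 600-1000).
#' @param sources data.frame with columns `id`, `label`, and optionally
#'   `x`, `y`, `z` (mm).
#' @param detectors data.frame, same layout as `sources`.
#' @param channels data.frame with columns `channel`, `source`, `detector`
#'   and optionally `distance` (mm).  When positions are present the distance
#'   is checked against (or filled from) the Euclidean source-detector
#'   distance.
#' @return an object of class `fnirs_montage`.
#' @export
fnirs_montage <- function(wavelengths, sources, detectors, channels) {
  assert(is.numeric(wavelengths) && length(wavelengths) == 2L,
         "fp_unsupported_data", "a montage needs exactly 2 wavelengths, got %d",
         length(wavelengths))
  assert(all(wavelengths > 600 & wavelengths < 1000), "fp_validation",
         "wavelengths must lie in (600, 1000) nm")
  sources <- as.data.frame(sources)
  detectors <- as.data.frame(detectors)
  channels <- as.data.frame(channels)
  for (nm in c("id", "label")) {
    if (is.null(sources[[nm]])) sources[[nm]] <- sources$id
    if (is.null(detectors[[nm]])) detectors[[nm]] <- detectors$id
  }
  assert(!anyDuplicated(sources$id) && !anyDuplicated(detectors$id),
         "fp_validation", "duplicate source or detector ids")
  assert(!anyDuplicated(channels$channel), "fp_validation",
         "channel ids must be unique")
  assert(all(channels$source %in% sources$id), "fp_validation",
         "channel references unknown source id")
  assert(all(channels$detector %in% detectors$id), "fp_validation",
         "channel references unknown detector id")

  has_pos <- all(c("x", "y", "z") %in% names(sources)) &&
    all(c("x", "y", "z") %in% names(detectors))
  if (has_pos) {
    sp <- sources[match(channels$source, sources$id), c("x", "y", "z")]
    dp <- detectors[match(channels$detector, detectors$id), c("x", "y", "z")]
    geo <- sqrt(rowSums((as.matrix(sp) - as.matrix(dp))^2))
    if (is.null(channels$distance)) {
      channels$distance <- geo
    } else {
      assert(all(abs(channels$distance - geo) <= 1e-6), "fp_validation",
             "channel distance disagrees with optode positions (> 1e-6 mm)")
    }
  }
  assert(!is.null(channels$distance) && all(channels$distance > 0),
         "fp_validation", "source-detector distances must be > 0")

  structure(list(wavelengths = as.numeric(wavelengths),
                 sources = sources, detectors = detectors,
                 channels = channels),
            class = "fnirs_montage")
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf("fNIRS montage: %d sources, %d detectors, %d channels @ %g/%g nm\n",
              nrow(x$sources), n_det <- nrow(x$detectors), nrow(x$channels),
              x$wavelengths[1], x$wavelengths[2]))
  invisible(x)
}

n_channels <- function(montage) nrow(montage$channels)
channel_ids <- function(montage) as.character(montage$channels$channel)

#' Stimulus design (block paradigm event table)
#'
#' @param events data.frame with columns `condition` (character, e.g. "LG"
#'   left grasp / "RG" right grasp), `onset` (s) and `duration` (s).
#' @param duration total recording duration in seconds.
#' @return object of class `stim_design`.
#' @export
stim_design <- function(events, duration) {
  events <- as.data.frame(events)
  assert(all(c("condition", "onset", "duration") %in% names(events)),
         "fp_validation", "events need condition, onset, duration columns")
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  assert(all(events$duration > 0), "fp_validation", "event durations must be > 0")
  assert(is_scalar_num(duration) && duration > 0, "fp_validation",
         "total duration must be a positive scalar")
  ends <- events$onset + events$duration
  assert(all(ends <= duration + 1e-9), "fp_validation",
         "events must end before the total duration")
  if (nrow(events) > 1) {
    # no overlap between any two events (conditions never run concurrently)
    assert(all(ends[-nrow(events)] <= events$onset[-1] + 1e-9),
           "fp_validation", "events overlap")
  }
  structure(list(events = events, duration = as.numeric(duration)),
            class = "stim_design")
}

#' @export
print.stim_design <- function(x, ...) {
  tab <- table(x$events$condition)
  cat(sprintf("Block design: %d events (%s), %.0f s total\n", nrow(x$events),
              paste(sprintf("%s x %d", names(tab), tab), collapse = ", "),
              x$duration))
  invisible(x)
}

#' Raw dual-wavelength intensity recording
#'
#' @param fs sampling frequency in Hz.
#' @param intensity numeric array `[channel, wavelength, time]` of strictly
#'   positive light intensities.
#' @param montage the [fnirs_montage()] the channels index into.
#' @return object of class `fnirs_intensity`.
#' @export
fnirs_intensity <- function(fs, intensity, montage) {
  assert(is_scalar_num(fs) && fs > 0, "fp_validation",
         "sampling frequency must be > 0")
  assert(is.array(intensity) && length(dim(intensity)) == 3L, "fp_validation",
         "intensity must be a [channel, wavelength, time] array")
  assert(dim(intensity)[2] == 2L, "fp_unsupported_data",
         "expected 2 wavelengths, got %d", dim(intensity)[2])
  assert(dim(intensity)[1] == n_channels(montage), "fp_validation",
         "intensity has %d channels but montage %d", dim(intensity)[1],
         n_channels(montage))
  bad <- which(!(is.finite(intensity) & intensity > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    fp_stop("fp_validation",
            "nonpositive intensity at channel %s, wavelength %d, sample %d",
            channel_ids(montage)[bad[1, 1]], bad[1, 2], bad[1, 3])
  }
  dimnames(intensity) <- list(channel_ids(montage),
                              paste0("wl", montage$wavelengths), NULL)
  structure(list(fs = fs, intensity = intensity, montage = montage),
            class = "fnirs_intensity")
}

#' Synthetic whole-head montage grouped into canonical ROIs
#'
#' Builds a schematic 102-channel whole-head layout in which channels are
#' grouped into the ten canonical regions of interest used for motor-task
#' mapping: left/right sensorimotor (SMN), primary and secondary visual
#' (VIS1, VIS2), and dorsolateral/ventrolateral prefrontal (PFC1, PFC2)
#' areas.  Each channel has its own source and detector placed 30 mm apart;
#' positions are schematic scalp coordinates, adequate for geometry checks
#' but not anatomically registered.
#'
#' @param channels_per_roi named integer vector, channels per ROI label.
#' @param wavelengths wavelengths in nm.
#' @param distance source-detector distance in mm.
#' @return list with `montage` ([fnirs_montage()]), `roi` (data.frame
#'   `roi`, `hemisphere`, `area`, `channel`), and `active` (named list of
#'   channel ids carrying the planted functional response in each ROI).
#' @export
synthetic_montage <- function(channels_per_roi = c(
                                "L-SMN" = 12, "R-SMN" = 12,
                                "L-VIS1" = 8, "R-VIS1" = 8,
                                "L-VIS2" = 10, "R-VIS2" = 10,
                                "L-PFC1" = 10, "R-PFC1" = 10,
                                "L-PFC2" = 11, "R-PFC2" = 11),
                              wavelengths = c(760, 850),
                              distance = 30) {
  rois <- names(channels_per_roi)
  assert(!is.null(rois) && !anyDuplicated(rois), "fp_config",
         "channels_per_roi must be a named vector with unique ROI labels")
  n_total <- sum(channels_per_roi)
  ch <- paste0("CH", seq_len(n_total))
  src <- paste0("S", seq_len(n_total))
  det <- paste0("D", seq_len(n_total))
  # schematic positions: ROIs on a coarse grid, channels spread along x
  roi_row <- rep(seq_along(rois), channels_per_roi)
  within <- unlist(lapply(channels_per_roi, seq_len), use.names = FALSE)
  sx <- within * 35
  sy <- roi_row * 40
  sources <- data.frame(id = src, label = src, x = sx, y = sy, z = 0)
  detectors <- data.frame(id = det, label = det, x = sx + distance, y = sy, z = 0)
  channels <- data.frame(channel = ch, source = src, detector = det,
                         distance = distance)
  montage <- fnirs_montage(wavelengths, sources, detectors, channels)
  roi_tab <- data.frame(
    roi = rep(rois, channels_per_roi),
    hemisphere = substr(rep(rois, channels_per_roi), 1, 1),
    area = sub("^[LR]-", "", rep(rois, channels_per_roi)),
    channel = ch, stringsAsFactors = FALSE)
  # the "focal" subset of each ROI that carries the planted response
  active <- lapply(split(roi_tab$channel, roi_tab$roi)[rois], function(v) {
    v[seq_len(max(1L, floor(length(v) / 2)))]
  })
  list(montage = montage, roi = roi_tab, active = active)
}
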