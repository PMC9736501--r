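# Preprocessing chain: intensity -> optical density -> wavelet motion
# correction -> zero-phase high-pass -> PCA removal of superficial
# components -> modified Beer-Lambert inversion to hemoglobin.

STEP_ORDER <- c(od = 1, wavelet = 2, highpass = 3, pca = 4, mbll = 5)

check_step_order <- function(steps, step) {
  done <- max(c(0, STEP_ORDER[steps]), na.rm = TRUE)
  assert(STEP_ORDER[[step]] > done, "fp_step_order",
         "preprocessing step '%s' cannot run after '%s' (chain order is %s)",
         step, steps[length(steps)], paste(names(STEP_ORDER), collapse = " -> "))
  invisible(TRUE)
}

#' Convert raw intensities to optical-density changes
#'
#' Computes `dOD(c, lambda, t) = -ln(I / I_ref)` per channel and wavelength,
#' with the reference taken as the geometric temporal mean of the trace, so
#' that a constant trace maps to exactly zero and the map is affine in the
#' underlying log-attenuation (continuous-wave recordings determine
#' concentration *changes* up to a per-channel baseline, which this
#' convention fixes at the temporal mean).
#'
#' @param raw an [fnirs_intensity()] recording.
#' @return object of class `fnirs_od` with fields `fs`, `od`
#'   (`[channel, wavelength, time]`), `montage`, `steps`.
#' @export
intensity_to_od <- function(raw) {
  assert(inherits(raw, "fnirs_intensity"), "fp_validation",
         "raw must be an fnirs_intensity")
  logI <- log(raw$intensity)
  ref <- apply(logI, c(1, 2), mean)
  od <- -sweep(logI, c(1, 2), ref, "-")
  structure(list(fs = raw$fs, od = od, montage = raw$montage, steps = "od"),
            class = "fnirs_od")
}

#' Zero-phase high-pass filter
#'
#' 3rd-order Butterworth high-pass applied forward and backward
#' (`signal::filtfilt`), removing drifts and DC without shifting event
#' timing.
#'
#' @param x an `fnirs_od` object, an `fnirs_hb` object, a numeric matrix
#'   (rows = traces), or a vector.
#' @param cutoff cutoff frequency in Hz (default 0.01).
#' @param fs sampling frequency; taken from `x` when it carries one.
#' @param order filter order.
#' @return filtered object of the same shape.
#' @export
highpass <- function(x, cutoff = 0.01, fs = NULL, order = 3) {
  if (inherits(x, c("fnirs_od", "fnirs_hb"))) fs <- x$fs
  assert(is_scalar_num(fs) && fs > 0, "fp_validation", "fs must be provided")
  assert(is_scalar_num(cutoff) && cutoff > 0 && cutoff < fs / 2,
         "fp_validation", "cutoff must lie in (0, Nyquist = %g) Hz", fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  # remove the mean first: filtfilt's edge handling is numerically poor for
  # a large DC offset at low normalised cutoffs
  ff <- function(v) signal::filtfilt(bf, v - mean(v))
  if (inherits(x, "fnirs_od")) {
    check_step_order(x$steps, "highpass")
    for (c_i in seq_len(dim(x$od)[1])) for (w in 1:2) {
      x$od[c_i, w, ] <- ff(x$od[c_i, w, ])
    }
    x$steps <- c(x$steps, "highpass")
    x$hp_cutoff <- cutoff
    x
  } else if (inherits(x, "fnirs_hb")) {
    x$hbo <- t(apply(x$hbo, 1, ff))
    x$hbr <- t(apply(x$hbr, 1, ff))
    x$steps <- c(x$steps, "highpass")
    x$hp_cutoff <- cutoff
    x
  } else if (is.matrix(x)) {
    t(apply(x, 1, ff))
  } else {
    ff(as.numeric(x))
  }
}

# Core PCA removal on a traces-by-time matrix: SVD of the uncentered data,
# subtract the smallest leading component set reaching >= variance_fraction
# cumulative variance.
pca_remove_matrix <- function(mat, variance_fraction) {
  assert(nrow(mat) >= 2, "fp_validation",
         "PCA removal needs >= 2 channels (rows)")
  assert(is_scalar_num(variance_fraction) && variance_fraction > 0 &&
           variance_fraction < 1, "fp_validation",
         "variance_fraction must lie in (0, 1)")
  sv <- svd(mat)
  ev <- sv$d^2
  if (sum(ev) == 0) return(list(mat = mat, removed = 0L, explained = numeric(0)))
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  approx_k <- sv$u[, 1:k, drop = FALSE] %*%
    (sv$d[1:k] * t(sv$v[, 1:k, drop = FALSE]))
  list(mat = mat - approx_k, removed = k, explained = cum[k])
}

#' Remove superficial/systemic components by PCA
#'
#' Pools all channel/wavelength traces of a subject into a traces-by-time
#' matrix, decomposes it over channels (uncentered SVD), and subtracts the
#' smallest leading set of principal components whose cumulative explained
#' variance reaches `variance_fraction`.  Scalp-borne systemic physiology
#' (superficial blood flow, Mayer waves, cardiac residue) is spatially
#' global and therefore concentrates in the leading components, while focal
#' task responses largely survive.
#'
#' @param x an `fnirs_od` object or numeric matrix (rows = traces).
#' @param variance_fraction target cumulative variance to remove,
#'   in (0, 1); default 0.80.
#' @return object of the same shape; for `fnirs_od` input, attributes
#'   `pca_removed` (number of components) and `pca_explained` are attached.
#' @export
pca_remove_superficial <- function(x, variance_fraction = 0.80) {
  if (inherits(x, "fnirs_od")) {
    check_step_order(x$steps, "pca")
    dm <- dim(x$od)
    mat <- rbind(x$od[, 1, , drop = TRUE], x$od[, 2, , drop = TRUE])
    if (dm[1] == 1L) fp_stop("fp_validation",
                             "PCA removal needs >= 2 channels")
    res <- pca_remove_matrix(mat, variance_fraction)
    x$od[, 1, ] <- res$mat[seq_len(dm[1]), ]
    x$od[, 2, ] <- res$mat[dm[1] + seq_len(dm[1]), ]
    x$steps <- c(x$steps, "pca")
    attr(x, "pca_removed") <- res$removed
    attr(x, "pca_explained") <- res$explained
    x
  } else {
    pca_remove_matrix(as.matrix(x), variance_fraction)$mat
  }
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves, per channel and time point, the 2x2 modified Beer-Lambert system
#' `dOD(lambda) = ln(10) * [eps_HbO2(lambda) dHbO2 + eps_HbR(lambda) dHbR]
#' * d * DPF(lambda)` for the two chromophores, with `d` the source-detector
#' distance from the montage and `DPF` the differential pathlength factor.
#'
#' @param od an `fnirs_od` object.
#' @param dpf length-2 differential pathlength factors (default 6 at both
#'   wavelengths, the conventional adult value).
#' @param default_distance source-detector distance in mm used when the
#'   montage lacks one (default 30).
#' @return object of class `fnirs_hb` with `hbo`/`hbr` matrices
#'   (`[channel, time]`, micromolar), `fs`, `montage`, `steps`.
#' @export
od_to_hb <- function(od, dpf = c(6, 6), default_distance = 30) {
  assert(inherits(od, "fnirs_od"), "fp_validation", "od must be an fnirs_od")
  check_step_order(od$steps, "mbll")
  assert(length(dpf) == 2 && all(dpf > 0), "fp_validation",
         "dpf must be two positive values")
  m <- od$montage
  dist <- m$channels$distance
  dist[is.na(dist)] <- default_distance
  n_ch <- n_channels(m)
  nt <- dim(od$od)[3]
  hbo <- matrix(NA_real_, n_ch, nt)
  hbr <- matrix(NA_real_, n_ch, nt)
  for (c_i in seq_len(n_ch)) {
    E <- mbll_matrix(m$wavelengths, dist[c_i], dpf)
    sol <- solve(E, rbind(od$od[c_i, 1, ], od$od[c_i, 2, ]))
    hbo[c_i, ] <- sol[1, ] * 1000  # mM -> uM
    hbr[c_i, ] <- sol[2, ] * 1000
  }
  rownames(hbo) <- rownames(hbr) <- channel_ids(m)
  structure(list(fs = od$fs, hbo = hbo, hbr = hbr, montage = m,
                 steps = c(od$steps, "mbll"), hp_cutoff = od$hp_cutoff),
            class = "fnirs_hb")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: optical-density conversion, wavelet motion-artifact
#' correction, zero-phase high-pass filtering, PCA removal of superficial
#' components, and the modified Beer-Lambert inversion.  The provenance of
#' applied steps is logged on the returned object.
#'
#' @param raw an [fnirs_intensity()] recording.
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param variance_fraction PCA removal target.
#' @param iqr_factor wavelet outlier threshold.
#' @param dpf differential pathlength factors.
#' @return an `fnirs_hb` object.
#' @export
preprocess_recording <- function(raw, cutoff_hz = 0.01,
                                 variance_fraction = 0.80,
                                 iqr_factor = 1.5, dpf = c(6, 6)) {
  od <- intensity_to_od(raw)
  od <- wavelet_motion_correct(od, iqr_factor = iqr_factor)
  od <- highpass(od, cutoff = cutoff_hz)
  od <- pca_remove_superficial(od, variance_fraction = variance_fraction)
  od_to_hb(od, dpf = dpf)
}
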