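# Synthetic-study generator: block designs, planted hemodynamic responses
# with physiological/serially-correlated noise, superficial components and
# motion artifacts, forward Beer-Lambert projection to dual-wavelength
# intensities, and clinical covariates rank-coupled to response amplitudes.
#
# Every stochastic draw goes through a named seed substream
# (substream_seed), so adding subjects or toggling components never
# perturbs other draws, and identical (params, seed) yield bit-identical
# studies.

#' Simulation parameters
#'
#' Collects every knob of the synthetic-study generator with defaults that
#' emulate a two-group whole-head motor-grasping block study: 10 s task /
#' 20 s rest blocks, 10 trials per side in randomized order, 1.9531 Hz
#' sampling, a 102-channel montage grouped into ten ROIs, canonical
#' responses with group-dependent amplitudes (contralateral sensorimotor
#' dominance, inverted prefrontal pattern), AR(1)-plus-oscillatory noise,
#' a shared superficial component, sporadic motion artifacts, and clinical
#' covariates matching the published two-group demographics.
#'
#' @param n_epd,n_mpd subjects per group (defaults 13 / 26).
#' @param fs sampling frequency in Hz (default 1.9531).
#' @param oversample integer internal oversampling factor; physiological
#'   noise is synthesised at `fs * oversample` and decimated *without*
#'   anti-aliasing so that cardiac power aliases into the recording as it
#'   does in real data.
#' @param trials_per_condition,task_duration,rest_duration,initial_rest
#'   block paradigm (s).
#' @param channels_per_roi named vector passed to [synthetic_montage()].
#' @param amplitudes data.frame `roi, condition, epd, mpd` of planted peak
#'   HbO2 response amplitudes in uM on each ROI's focal channels.
#' @param chromophore_ratio `r` with planted HbR amplitude `-r * HbO2`.
#' @param subject_amp_sd between-subject SD of the ROI response amplitude
#'   (uM), shared across the ROI's channels and conditions.
#' @param ar_coef,ar_sd AR(1) coefficient (at the emitted rate) and
#'   marginal SD (uM) of the serially correlated noise.
#' @param cardiac,mayer,resp,drift `c(amplitude uM, frequency Hz)` of the
#'   oscillatory confounds.
#' @param hbr_noise_factor scaling of all noise amplitudes on HbR.
#' @param superficial_sd,superficial_tau,superficial_load,superficial_hbr_factor
#'   marginal SD (uM), correlation time (s), per-channel positive loading
#'   range, and HbR scaling of the shared scalp component.
#' @param artifact_rate_per_min,spike_amp,shift_amp motion-artifact Poisson
#'   rate and amplitudes (multiples of each trace's SD).
#' @param beta_noise_sd subject-level estimation noise (uM) used by the
#'   fast beta-level generator [simulate_subject_betas()].
#' @param dpf,baseline_intensity forward-model constants.
#' @param covariates per-variable, per-group `mean`/`sd` (plus `missing`
#'   counts) of the clinical covariates.
#' @param target_correlation `list(variable, roi, rho)`: the designated
#'   covariate is rank-coupled (Gaussian copula) to the designated ROI's
#'   subject amplitudes with population Spearman correlation `rho`.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_epd = 13, n_mpd = 26,
                       fs = 1.9531, oversample = 4L,
                       trials_per_condition = 10, task_duration = 10,
                       rest_duration = 20, initial_rest = 15,
                       channels_per_roi = NULL,
                       amplitudes = NULL,
                       chromophore_ratio = 0.5,
                       subject_amp_sd = 0.08,
                       ar_coef = 0.8, ar_sd = 0.08,
                       cardiac = c(0.05, 1.1), mayer = c(0.04, 0.1),
                       resp = c(0.03, 0.25), drift = c(0.03, 0.005),
                       hbr_noise_factor = 0.5,
                       superficial_sd = 1.2, superficial_tau = 5,
                       superficial_load = c(0.7, 1.3),
                       superficial_hbr_factor = 0.4,
                       artifact_rate_per_min = 0.5,
                       spike_amp = 10, shift_amp = 3,
                       beta_noise_sd = 0.05,
                       dpf = c(6, 6), baseline_intensity = 100,
                       covariates = NULL,
                       target_correlation = list(variable = "updrs",
                                                 roi = "R-VIS2", rho = 0.5)) {
  if (is.null(channels_per_roi)) {
    channels_per_roi <- c("L-SMN" = 12, "R-SMN" = 12, "L-VIS1" = 8,
                          "R-VIS1" = 8, "L-VIS2" = 10, "R-VIS2" = 10,
                          "L-PFC1" = 10, "R-PFC1" = 10, "L-PFC2" = 11,
                          "R-PFC2" = 11)
  }
  if (is.null(amplitudes)) amplitudes <- default_amplitudes()
  if (is.null(covariates)) covariates <- default_covariates()
  p <- list(n_epd = n_epd, n_mpd = n_mpd, fs = fs,
            oversample = as.integer(oversample),
            trials_per_condition = trials_per_condition,
            task_duration = task_duration, rest_duration = rest_duration,
            initial_rest = initial_rest,
            channels_per_roi = channels_per_roi,
            amplitudes = as.data.frame(amplitudes),
            chromophore_ratio = chromophore_ratio,
            subject_amp_sd = subject_amp_sd,
            ar_coef = ar_coef, ar_sd = ar_sd,
            cardiac = cardiac, mayer = mayer, resp = resp, drift = drift,
            hbr_noise_factor = hbr_noise_factor,
            superficial_sd = superficial_sd, superficial_tau = superficial_tau,
            superficial_load = superficial_load,
            superficial_hbr_factor = superficial_hbr_factor,
            artifact_rate_per_min = artifact_rate_per_min,
            spike_amp = spike_amp, shift_amp = shift_amp,
            beta_noise_sd = beta_noise_sd,
            dpf = dpf, baseline_intensity = baseline_intensity,
            covariates = covariates, target_correlation = target_correlation)
  assert(p$n_epd >= 0 && p$n_mpd >= 0 && p$n_epd + p$n_mpd >= 1,
         "fp_validation", "need at least one subject")
  assert(p$fs > 0 && p$oversample >= 1, "fp_validation",
         "fs and oversample must be positive")
  assert(p$trials_per_condition >= 1, "fp_validation", "trials must be >= 1")
  assert(all(c(p$task_duration, p$rest_duration) > 0), "fp_validation",
         "task and rest durations must be > 0")
  assert(p$artifact_rate_per_min >= 0, "fp_validation",
         "artifact rate must be >= 0")
  for (nm in c("ar_sd", "superficial_sd", "subject_amp_sd", "beta_noise_sd")) {
    assert(p[[nm]] >= 0, "fp_validation", "%s must be >= 0", nm)
  }
  tc <- p$target_correlation
  if (!is.null(tc)) {
    assert(abs(tc$rho) < 1, "fp_validation",
           "target rank correlation must lie in (-1, 1)")
  }
  class(p) <- "sim_params"
  p
}

# Planted peak HbO2 amplitudes (uM) by ROI, condition and group: strong
# contralateral sensorimotor responses that are larger in the early group,
# an inverted (compensation-like) pattern in prefrontal areas, and a small
# early-dominant secondary-visual response.
default_amplitudes <- function() {
  rbind(
    data.frame(roi = "L-SMN", condition = "RG", epd = 0.3, mpd = 0.2),
    data.frame(roi = "R-SMN", condition = "LG", epd = 0.3, mpd = 0.2),
    expand.grid(roi = c("L-PFC1", "R-PFC1", "L-PFC2", "R-PFC2"),
                condition = c("LG", "RG"), stringsAsFactors = FALSE) |>
      transform(epd = 0.05, mpd = 0.1),
    expand.grid(roi = c("L-VIS1", "R-VIS1"), condition = c("LG", "RG"),
                stringsAsFactors = FALSE) |>
      transform(epd = 0.05, mpd = 0.05),
    expand.grid(roi = c("L-VIS2", "R-VIS2"), condition = c("LG", "RG"),
                stringsAsFactors = FALSE) |>
      transform(epd = 0.13, mpd = 0.05))
}

# Clinical covariate models: group means with SDs recovered from the
# published per-group standard errors (SD = SE * sqrt(N), N = 13 / 26);
# `missing` reproduces the reported incomplete Stroop administrations.
default_covariates <- function() {
  list(
    age = list(epd = c(63.519, 5.967), mpd = c(71.676, 6.961), min = 30),
    criq = list(epd = c(131.385, 22.318), mpd = c(122.577, 19.387), min = 40),
    duration = list(epd = c(2.903, 2.886), mpd = c(5.049, 2.394), min = 0),
    updrs = list(epd = c(16.077, 5.634), mpd = c(35.654, 12.235), min = 0),
    scwe = list(epd = c(9.083, 11.733), mpd = c(8.880, 8.504), min = 0,
                missing = 2),
    scwt = list(epd = c(12.693, 8.700), mpd = c(18.716, 15.808), min = 0,
                missing = 3))
}

#' Generate a randomized block design
#'
#' `trials_per_condition` left-grasp and right-grasp blocks of
#' `task_duration` seconds, each followed by `rest_duration` seconds of
#' rest, in a seeded random left/right order after an initial baseline.
#'
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return a [stim_design()].
#' @export
generate_design <- function(params, seed = 1) {
  p <- params
  local_seed(seed, "design")
  conds <- sample(rep(c("LG", "RG"), each = p$trials_per_condition))
  n_ev <- length(conds)
  onsets <- p$initial_rest +
    (seq_len(n_ev) - 1) * (p$task_duration + p$rest_duration)
  total <- p$initial_rest + n_ev * (p$task_duration + p$rest_duration)
  stim_design(data.frame(condition = conds, onset = onsets,
                         duration = p$task_duration), total)
}

# Marginal-SD-preserving AR(1) path at rate fs_hi whose decimated-by-k
# subsample is AR(1) with the requested coefficient at the emitted rate.
ar1_path <- function(n, coef_emitted, marginal_sd, k) {
  a <- coef_emitted^(1 / k)
  innov <- stats::rnorm(n, sd = marginal_sd * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = stats::rnorm(1, sd = marginal_sd)))
}

# Per-subject amplitude table: group-level planted amplitude plus a
# subject-specific ROI deviation shared across the ROI's channels and
# conditions.  Returns [channel x condition] HbO2 amplitude matrix plus the
# per-ROI deviations.
subject_amplitudes <- function(params, layout, group, seed, subject_id) {
  p <- params
  rois <- unique(layout$roi$roi)
  local_seed(seed, "amp", subject_id)
  dev <- stats::setNames(stats::rnorm(length(rois), sd = p$subject_amp_sd),
                         rois)
  chans <- channel_ids(layout$montage)
  conds <- c("LG", "RG")
  amp <- matrix(0, length(chans), length(conds),
                dimnames = list(chans, conds))
  gcol <- if (group == "ePD") "epd" else "mpd"
  for (i in seq_len(nrow(p$amplitudes))) {
    row <- p$amplitudes[i, ]
    act <- layout$active[[row$roi]]
    if (is.null(act) || !(row$condition %in% conds)) next
    amp[act, row$condition] <- amp[act, row$condition] +
      row[[gcol]] + dev[[row$roi]]
  }
  list(amp = amp, dev = dev)
}

#' Simulate one subject's hemoglobin time series
#'
#' Clean signal (planted amplitudes times the unit-peak cHRF-convolved
#' block regressors), AR(1) noise plus cardiac / Mayer / respiratory /
#' drift sinusoids with seeded random phases (synthesised at
#' `fs * oversample` and decimated without anti-aliasing), and a shared
#' superficial component with positive per-channel loadings.  HbR is the
#' anti-correlated companion of HbO2 (`-chromophore_ratio` times the
#' amplitude) with scaled-down noise.
#'
#' @param params a [sim_params()].
#' @param design a [stim_design()].
#' @param layout a [synthetic_montage()] result.
#' @param group `"ePD"` or `"mPD"`.
#' @param seed base seed.
#' @param subject_id label used for seed substreams.
#' @return list: `hb` (`fnirs_hb`), `truth` (amplitudes, ROI deviations,
#'   superficial loadings, and the clean/noise/superficial decomposition).
#' @export
simulate_subject_hb <- function(params, design, layout, group = "ePD",
                                seed = 1, subject_id = "S1") {
  p <- params
  m <- layout$montage
  n_ch <- n_channels(m)
  n <- floor(design$duration * p$fs)
  k <- p$oversample
  n_hi <- n * k
  fs_hi <- p$fs * k
  pick <- seq(1, n_hi, by = k)
  t_hi <- (seq_len(n_hi) - 1) / fs_hi

  sa <- subject_amplitudes(p, layout, group, seed, subject_id)
  regs <- lapply(stats::setNames(c("LG", "RG"), c("LG", "RG")), function(cn) {
    ev <- design$events[design$events$condition == cn, , drop = FALSE]
    if (!nrow(ev)) return(numeric(n))
    condition_regressor(ev, p$fs, n)
  })
  clean_hbo <- sa$amp[, "LG"] %o% regs$LG + sa$amp[, "RG"] %o% regs$RG
  clean_hbr <- -p$chromophore_ratio * clean_hbo

  noise_for <- function(chrom_factor, label) {
    out <- matrix(0, n_ch, n)
    for (c_i in seq_len(n_ch)) {
      local_seed(seed, "noise", subject_id, label, c_i)
      x <- ar1_path(n_hi, p$ar_coef, p$ar_sd, k)
      for (osc in list(p$cardiac, p$mayer, p$resp, p$drift)) {
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + osc[1] * sin(2 * pi * osc[2] * t_hi + phase)
      }
      out[c_i, ] <- chrom_factor * x[pick]
    }
    out
  }
  noise_hbo <- noise_for(1, "hbo")
  noise_hbr <- noise_for(p$hbr_noise_factor, "hbr")

  local_seed(seed, "superficial", subject_id)
  sup_t <- ar1_path(n_hi, exp(-k / (fs_hi * p$superficial_tau)),
                    p$superficial_sd, k)[pick]
  load <- stats::runif(n_ch, p$superficial_load[1], p$superficial_load[2])
  sup_hbo <- load %o% sup_t
  sup_hbr <- (load * p$superficial_hbr_factor) %o% sup_t

  hbo <- clean_hbo + noise_hbo + sup_hbo
  hbr <- clean_hbr + noise_hbr + sup_hbr
  rownames(hbo) <- rownames(hbr) <- channel_ids(m)
  hb <- structure(list(fs = p$fs, hbo = hbo, hbr = hbr, montage = m,
                       steps = "simulated"),
                  class = "fnirs_hb")
  truth <- list(amplitudes = sa$amp, roi_dev = sa$dev,
                superficial_loadings = load,
                components = list(
                  clean_hbo = clean_hbo, clean_hbr = clean_hbr,
                  noise_hbo = noise_hbo, noise_hbr = noise_hbr,
                  superficial_hbo = sup_hbo, superficial_hbr = sup_hbr))
  list(hb = hb, truth = truth)
}

#' Inject motion artifacts
#'
#' Adds spike (1-3 sample excursions) and step/baseline-shift artifacts at
#' Poisson-distributed times; amplitudes are multiples of each trace's
#' standard deviation with random sign.  For multi-channel (matrix) input
#' the default models head movements physically: every event hits all
#' traces at the same instant, with independent per-trace signs and
#' amplitude jitter (U(0.5, 1.5)); `shared_times = FALSE` draws an
#' independent Poisson event stream per trace instead.
#'
#' @param x numeric matrix (rows = traces) or vector.
#' @param fs sampling frequency (Hz).
#' @param rate_per_min expected artifact events per trace per minute.
#' @param spike_amp,shift_amp amplitudes, in multiples of the reference SD.
#' @param seed,label seed substream.
#' @param shared_times single event stream shared by all traces (matrix
#'   input only).
#' @param sd_reference per-trace reference scale for the artifact
#'   amplitudes; defaults to each trace's own SD.  The study generator
#'   passes the SD of the stochastic background noise so that artifact
#'   size tracks the hemodynamic scale rather than the (much larger)
#'   superficial component.
#' @return list: `data` (same shape as `x`), `log` (data.frame `trace`
#'   (`NA` for shared events), `sample`, `type`, `amplitude`).
#' @export
inject_artifacts <- function(x, fs, rate_per_min = 0.5, spike_amp = 10,
                             shift_amp = 3, seed = 1, label = "artifacts",
                             shared_times = TRUE, sd_reference = NULL) {
  assert(rate_per_min >= 0, "fp_validation", "artifact rate must be >= 0")
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  minutes <- n / fs / 60
  logs <- list()
  apply_event <- function(rows, at, type, amp_vec) {
    if (type == "spike") {
      width <- sample.int(3, 1)
      idx <- at:min(n, at + width - 1)
      x[rows, idx] <<- x[rows, idx] + amp_vec
    } else {
      x[rows, at:n] <<- sweep(x[rows, at:n, drop = FALSE], 1, amp_vec, "+")
    }
  }
  sd_rows <- if (is.null(sd_reference)) apply(x, 1, stats::sd)
             else rep(sd_reference, length.out = nrow(x))
  sd_rows[!is.finite(sd_rows) | sd_rows == 0] <- 1
  if (!vec_in && shared_times) {
    local_seed(seed, label, "shared")
    n_ev <- stats::rpois(1, rate_per_min * minutes)
    for (e in seq_len(n_ev)) {
      at <- sample.int(n, 1)
      type <- sample(c("spike", "shift"), 1)
      mult <- if (type == "spike") spike_amp else shift_amp
      amp <- mult * sd_rows * sample(c(-1, 1), nrow(x), replace = TRUE) *
        stats::runif(nrow(x), 0.5, 1.5)
      apply_event(seq_len(nrow(x)), at, type, amp)
      logs[[length(logs) + 1]] <- data.frame(trace = NA_integer_,
                                             sample = at, type = type,
                                             amplitude = mult)
    }
  } else {
    for (r in seq_len(nrow(x))) {
      local_seed(seed, label, r)
      n_ev <- stats::rpois(1, rate_per_min * minutes)
      for (e in seq_len(n_ev)) {
        at <- sample.int(n, 1)
        type <- sample(c("spike", "shift"), 1)
        mult <- if (type == "spike") spike_amp else shift_amp
        a <- sample(c(-1, 1), 1) * mult * sd_rows[r]
        apply_event(r, at, type, a)
        logs[[length(logs) + 1]] <- data.frame(trace = r, sample = at,
                                               type = type, amplitude = a)
      }
    }
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(trace = integer(0), sample = integer(0),
               type = character(0), amplitude = numeric(0))
  list(data = if (vec_in) drop(x) else x, log = log_df)
}

#' Forward modified Beer-Lambert projection
#'
#' Maps hemoglobin concentration changes to dual-wavelength intensities:
#' `dOD(lambda, t) = ln(10) [eps_HbO2 dHbO2 + eps_HbR dHbR] d DPF` and
#' `I = I0 exp(-dOD)`.  Exact inverse (up to the per-channel temporal-mean
#' baseline inherent to CW measurements) of
#' [intensity_to_od()] followed by [od_to_hb()].
#'
#' @param hb an `fnirs_hb` object.
#' @param dpf length-2 differential pathlength factors.
#' @param baseline_intensity `I0` per wavelength (scalar or length-2).
#' @param artifact_od optional `[2 * n_channels, time]` matrix of
#'   artifact optical density added before exponentiation (wavelength-1
#'   rows first).
#' @return an [fnirs_intensity()].
#' @export
forward_mbll <- function(hb, dpf = c(6, 6), baseline_intensity = 100,
                         artifact_od = NULL) {
  assert(inherits(hb, "fnirs_hb"), "fp_validation", "hb must be an fnirs_hb")
  m <- hb$montage
  n_ch <- n_channels(m)
  nt <- ncol(hb$hbo)
  I0 <- rep(baseline_intensity, length.out = 2)
  arr <- array(NA_real_, c(n_ch, 2, nt))
  for (c_i in seq_len(n_ch)) {
    E <- mbll_matrix(m$wavelengths, m$channels$distance[c_i], dpf)
    od <- E %*% rbind(hb$hbo[c_i, ], hb$hbr[c_i, ]) / 1000  # uM -> mM
    if (!is.null(artifact_od)) {
      od <- od + rbind(artifact_od[c_i, ], artifact_od[n_ch + c_i, ])
    }
    arr[c_i, 1, ] <- I0[1] * exp(-od[1, ])
    arr[c_i, 2, ] <- I0[2] * exp(-od[2, ])
  }
  fnirs_intensity(hb$fs, arr, m)
}

# Stack a subject's optical-density traces as a [2 * n_channels, time]
# matrix (wavelength-1 rows first), the layout inject_artifacts and
# forward_mbll share.
hb_to_od_matrix <- function(hb, dpf = c(6, 6)) {
  m <- hb$montage
  n_ch <- n_channels(m)
  out <- matrix(NA_real_, 2 * n_ch, ncol(hb$hbo))
  for (c_i in seq_len(n_ch)) {
    E <- mbll_matrix(m$wavelengths, m$channels$distance[c_i], dpf)
    od <- E %*% rbind(hb$hbo[c_i, ], hb$hbr[c_i, ]) / 1000
    out[c_i, ] <- od[1, ]
    out[n_ch + c_i, ] <- od[2, ]
  }
  out
}

#' Generate clinical covariates coupled to ground-truth amplitudes
#'
#' Draws each covariate from its per-group normal model (truncated below at
#' the configured minimum); the designated target covariate is instead
#' drawn through a Gaussian copula on the empirical normal scores of the
#' subjects' target-ROI amplitudes, with copula correlation
#' `2 sin(pi rho / 6)` so its population Spearman correlation with the
#' amplitude equals the requested `rho`.  Configured numbers of
#' Stroop scores are blanked at random to emulate incomplete
#' administration.
#'
#' @param params a [sim_params()].
#' @param subjects data.frame `subject`, `group`.
#' @param target_amplitude numeric vector (per subject) of the designated
#'   ROI's true response amplitude; required when a target correlation is
#'   configured.
#' @param seed base seed.
#' @return a `clinical_table` data.frame.
#' @export
generate_covariates <- function(params, subjects, target_amplitude = NULL,
                                seed = 1) {
  p <- params
  n <- nrow(subjects)
  tc <- p$target_correlation
  if (!is.null(tc) && !is.null(target_amplitude)) {
    assert(n >= 3, "fp_validation",
           "a target correlation needs >= 3 subjects")
  }
  out <- data.frame(subject = subjects$subject, group = subjects$group,
                    stringsAsFactors = FALSE)
  is_epd <- subjects$group == "ePD"
  for (v in names(p$covariates)) {
    cv <- p$covariates[[v]]
    local_seed(seed, "cov", v)
    if (!is.null(tc) && identical(v, tc$variable) &&
        !is.null(target_amplitude)) {
      # empirical-copula coupling to the realised amplitudes
      z_amp <- stats::qnorm((rank(target_amplitude,
                                  ties.method = "average") - 0.5) / n)
      rho_g <- 2 * sin(pi * tc$rho / 6)
      z <- rho_g * z_amp + sqrt(1 - rho_g^2) * stats::rnorm(n)
      w_epd <- sum(is_epd) / n
      mu <- w_epd * cv$epd[1] + (1 - w_epd) * cv$mpd[1]
      sdev <- sqrt(w_epd * cv$epd[2]^2 + (1 - w_epd) * cv$mpd[2]^2 +
                     w_epd * (1 - w_epd) * (cv$epd[1] - cv$mpd[1])^2)
      val <- mu + sdev * z
    } else {
      val <- numeric(n)
      val[is_epd] <- stats::rnorm(sum(is_epd), cv$epd[1], cv$epd[2])
      val[!is_epd] <- stats::rnorm(sum(!is_epd), cv$mpd[1], cv$mpd[2])
    }
    if (!is.null(cv$min)) val <- pmax(val, cv$min)
    miss <- cv$missing %||% 0
    if (miss > 0) {
      local_seed(seed, "covmiss", v)
      val[sample.int(n, min(miss, n))] <- NA
    }
    out[[v]] <- val
  }
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Simulate a complete synthetic study
#'
#' Generates the montage/ROI layout, a randomized block design per subject,
#' hemoglobin time series with planted group-dependent responses, the
#' forward-projected dual-wavelength intensities with motion artifacts, and
#' a clinical covariate table coupled to the planted amplitudes -- together
#' with a ground-truth sidecar for every planted quantity.
#'
#' @param params a [sim_params()].
#' @param seed integer seed; the single source of randomness.
#' @param keep_hb keep each subject's noise-free-of-artifacts hemoglobin
#'   series and component decomposition in the ground truth (memory-heavy;
#'   default `FALSE`).
#' @return object of class `fnirs_study`: `params`, `seed`, `layout`
#'   (montage + ROI table), `roi_config`, `subjects` (list of `id`,
#'   `group`, `design`, `intensity`, `artifact_log`), `clinical`, `truth`
#'   (per-subject amplitude matrices, ROI deviations, target-ROI amplitude
#'   vector).
#' @export
simulate_study <- function(params = sim_params(), seed = 1, keep_hb = FALSE) {
  p <- params
  layout <- synthetic_montage(p$channels_per_roi)
  groups <- c(rep("ePD", p$n_epd), rep("mPD", p$n_mpd))
  ids <- sprintf("sub%02d", seq_along(groups))
  subjects <- vector("list", length(ids))
  truth <- list(amplitudes = list(), roi_dev = list())
  target_amp <- numeric(length(ids))
  tc <- p$target_correlation
  for (i in seq_along(ids)) {
    design <- generate_design(p, substream_seed(seed, "design", ids[i]))
    sim <- simulate_subject_hb(p, design, layout, groups[i], seed, ids[i])
    od_mat <- hb_to_od_matrix(sim$hb, p$dpf)
    noise_od <- hb_to_od_matrix(
      structure(list(fs = p$fs, hbo = sim$truth$components$noise_hbo,
                     hbr = sim$truth$components$noise_hbr,
                     montage = layout$montage, steps = "sim"),
                class = "fnirs_hb"), p$dpf)
    art <- inject_artifacts(od_mat, p$fs, p$artifact_rate_per_min,
                            p$spike_amp, p$shift_amp, seed,
                            label = paste0("art/", ids[i]),
                            sd_reference = apply(noise_od, 1, stats::sd))
    rec <- forward_mbll(sim$hb, dpf = p$dpf,
                        baseline_intensity = p$baseline_intensity,
                        artifact_od = art$data - od_mat)
    subjects[[i]] <- list(id = ids[i], group = groups[i], design = design,
                          intensity = rec, artifact_log = art$log)
    if (keep_hb) subjects[[i]]$hb <- sim$hb
    truth$amplitudes[[ids[i]]] <- sim$truth$amplitudes
    truth$roi_dev[[ids[i]]] <- sim$truth$roi_dev
    if (keep_hb) truth$components[[ids[i]]] <- sim$truth$components
    if (!is.null(tc)) {
      act <- layout$active[[tc$roi]]
      target_amp[i] <- mean(sim$truth$amplitudes[act, ])
    }
  }
  clinical <- generate_covariates(
    p, data.frame(subject = ids, group = groups, stringsAsFactors = FALSE),
    target_amplitude = if (!is.null(tc)) target_amp else NULL, seed = seed)
  truth$target_amplitude <- stats::setNames(target_amp, ids)
  structure(list(params = p, seed = seed, layout = layout,
                 roi_config = roi_config_from_table(layout$roi),
                 subjects = subjects, clinical = clinical, truth = truth),
            class = "fnirs_study")
}

#' Fast beta-level study generator
#'
#' Bypasses time-series synthesis: draws each subject's channel-wise
#' task-vs-rest contrast coefficients directly as
#' `true amplitude + N(0, beta_noise_sd)`, with the same amplitude model,
#' covariate model and ground truth as [simulate_study()].  Used for
#' group-level and correlation calibration where thousands of replicates
#' are needed.
#'
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return list: `subject_betas` (data.frame `subject, group, condition,
#'   channel, chromophore, beta`), `clinical`, `layout`, `roi_config`,
#'   `truth`.
#' @export
simulate_subject_betas <- function(params = sim_params(), seed = 1) {
  p <- params
  layout <- synthetic_montage(p$channels_per_roi)
  groups <- c(rep("ePD", p$n_epd), rep("mPD", p$n_mpd))
  ids <- sprintf("sub%02d", seq_along(groups))
  chans <- channel_ids(layout$montage)
  tc <- p$target_correlation
  target_amp <- numeric(length(ids))
  rows <- vector("list", length(ids))
  amps <- list()
  for (i in seq_along(ids)) {
    sa <- subject_amplitudes(p, layout, groups[i], seed, ids[i])
    amps[[ids[i]]] <- sa$amp
    local_seed(seed, "betanoise", ids[i])
    beta_hbo <- sa$amp + matrix(stats::rnorm(length(sa$amp),
                                             sd = p$beta_noise_sd),
                                nrow(sa$amp))
    beta_hbr <- -p$chromophore_ratio * sa$amp +
      matrix(stats::rnorm(length(sa$amp),
                          sd = p$beta_noise_sd * p$hbr_noise_factor),
             nrow(sa$amp))
    rows[[i]] <- rbind(
      data.frame(subject = ids[i], group = groups[i],
                 condition = rep(colnames(sa$amp), each = length(chans)),
                 channel = rep(chans, 2), chromophore = "hbo",
                 beta = as.numeric(beta_hbo), stringsAsFactors = FALSE),
      data.frame(subject = ids[i], group = groups[i],
                 condition = rep(colnames(sa$amp), each = length(chans)),
                 channel = rep(chans, 2), chromophore = "hbr",
                 beta = as.numeric(beta_hbr), stringsAsFactors = FALSE))
    if (!is.null(tc)) {
      target_amp[i] <- mean(sa$amp[layout$active[[tc$roi]], ])
    }
  }
  clinical <- generate_covariates(
    p, data.frame(subject = ids, group = groups, stringsAsFactors = FALSE),
    target_amplitude = if (!is.null(tc)) target_amp else NULL, seed = seed)
  list(subject_betas = do.call(rbind, rows), clinical = clinical,
       layout = layout, roi_config = roi_config_from_table(layout$roi),
       truth = list(amplitudes = amps,
                    target_amplitude = stats::setNames(target_amp, ids)))
}
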