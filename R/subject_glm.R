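# Subject-level statistical analysis: canonical HRF design, AR-IRLS
# pre-whitened robust GLM per channel/chromophore, task-vs-rest contrasts,
# Benjamini-Hochberg FDR.

#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response: a positive gamma lobe peaking at
#' `peak_time` seconds minus a later undershoot lobe scaled by
#' `1/undershoot_ratio`, normalised to unit peak.  `undershoot_ratio = Inf`
#' yields the pure (nonnegative) gamma lobe.
#'
#' @param t nonnegative, increasing time grid in seconds.
#' @param peak_time time-to-peak in seconds (default 6).
#' @param undershoot_delay mode of the undershoot lobe (s).
#' @param undershoot_ratio peak-to-undershoot amplitude ratio (default 6).
#' @return numeric vector of responses, `canonical_hrf(0) == 0`, unit peak.
#' @export
canonical_hrf <- function(t, peak_time = 6, undershoot_delay = 16,
                          undershoot_ratio = 6) {
  assert(is_scalar_num(peak_time) && peak_time > 0, "fp_validation",
         "peak_time must be > 0")
  assert(all(t >= 0) && !is.unsorted(t), "fp_validation",
         "t must be nonnegative and increasing")
  shape1 <- peak_time + 1       # gamma(shape, rate = 1) has mode shape - 1
  shape2 <- undershoot_delay + 1
  f <- function(tt) {
    y <- stats::dgamma(tt, shape = shape1, rate = 1)
    if (is.finite(undershoot_ratio)) {
      y <- y - stats::dgamma(tt, shape = shape2, rate = 1) / undershoot_ratio
    }
    y
  }
  dense <- seq(0, max(40, peak_time * 4), by = 0.005)
  peak <- max(f(dense))
  f(t) / peak
}

# Condition regressor: boxcar of the condition's events convolved with the
# canonical HRF (or its time derivative), normalised so that the response to
# one isolated block of the condition's median duration has unit peak --
# i.e. the regression coefficient is the peak concentration change (uM) per
# block.  Shared by the design-matrix builder and the signal generator so
# that planted amplitudes are recovered as betas on the same scale.
condition_regressor <- function(events, fs, n, peak_time = 6,
                                derivative = FALSE) {
  dt <- 1 / fs
  hrf_t <- seq(0, 40, by = dt)
  hrf <- canonical_hrf(hrf_t, peak_time = peak_time)
  kern <- if (derivative) c(0, diff(hrf)) / dt else hrf
  box <- numeric(n)
  tgrid <- (seq_len(n) - 1) * dt
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    box[tgrid >= on - 1e-9 & tgrid < on + events$duration[i] - 1e-9] <- 1
  }
  conv_full <- function(b) {
    stats::convolve(b, rev(kern), type = "open")[seq_len(n)] * dt
  }
  # unit-peak normalisation from one isolated block
  med_dur <- stats::median(events$duration)
  box1 <- as.numeric(tgrid < med_dur)
  n1 <- min(n, length(hrf_t) + length(box1))
  ref <- stats::convolve(as.numeric(tgrid[seq_len(n1)] < med_dur), rev(hrf),
                         type = "open")[seq_len(n1)] * dt
  scale <- max(ref)
  conv_full(box) / scale
}

#' Build the GLM design matrix for a block paradigm
#'
#' One cHRF-convolved boxcar regressor per condition, its temporal
#' derivative companion, and a constant column.  Condition regressors are
#' scaled so a single task block elicits a unit-peak response; the
#' coefficient of a condition column is therefore the peak concentration
#' change attributable to one block.  The post-task rest is not modelled
#' explicitly: under the block design the task coefficient against the
#' implicit baseline is the task-vs-rest effect.
#'
#' @param design a [stim_design()].
#' @param fs sampling frequency (Hz).
#' @param n number of samples in the recording.
#' @param peak_time HRF time-to-peak (s).
#' @return list of class `fnirs_design_matrix`: `X` (n-by-p matrix),
#'   `labels`, `conditions`, `fs`.
#' @export
build_design <- function(design, fs, n, peak_time = 6) {
  assert(inherits(design, "stim_design"), "fp_validation",
         "design must be a stim_design")
  ends <- design$events$onset + design$events$duration
  assert(all(ends <= n / fs + 1e-9), "fp_validation",
         "event at %.1f s extends past the recording end (%.1f s)",
         max(ends), n / fs)
  conds <- intersect(c("LG", "RG"), unique(design$events$condition))
  if (!length(conds)) conds <- unique(design$events$condition)
  cols <- list()
  labels <- character(0)
  for (cn in conds) {
    ev <- design$events[design$events$condition == cn, , drop = FALSE]
    cols[[length(cols) + 1]] <- condition_regressor(ev, fs, n, peak_time)
    labels <- c(labels, cn)
  }
  for (cn in conds) {
    ev <- design$events[design$events$condition == cn, , drop = FALSE]
    cols[[length(cols) + 1]] <- condition_regressor(ev, fs, n, peak_time,
                                                    derivative = TRUE)
    labels <- c(labels, paste0("d", cn))
  }
  cols[[length(cols) + 1]] <- rep(1, n)
  labels <- c(labels, "const")
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  structure(list(X = X, labels = labels, conditions = conds, fs = fs,
                 peak_time = peak_time),
            class = "fnirs_design_matrix")
}

# Levinson-Durbin recursion on autocovariances; returns per-order phi and
# innovation variances for AR(0..p_max).
levinson <- function(x, p_max) {
  n <- length(x)
  r <- as.numeric(stats::acf(x, lag.max = p_max, type = "covariance",
                             plot = FALSE, demean = FALSE)$acf)
  v <- numeric(p_max + 1)
  phis <- vector("list", p_max + 1)
  v[1] <- r[1]
  phis[[1]] <- numeric(0)
  phi <- numeric(0)
  for (k in seq_len(p_max)) {
    if (v[k] <= 0) { v[(k + 1):(p_max + 1)] <- v[k]; phis[(k + 1):(p_max + 1)] <- phis[k]; break }
    lambda <- (r[k + 1] - sum(phi * r[k:2][seq_len(k - 1)])) / v[k]
    if (k > 1) phi <- c(phi - lambda * rev(phi), lambda) else phi <- lambda
    v[k + 1] <- v[k] * (1 - lambda^2)
    phis[[k + 1]] <- phi
  }
  list(phi = phis, v = v)
}

# Select AR order 0..p_max by BIC on the prediction-error variance.
select_ar <- function(x, p_max) {
  n <- length(x)
  p_max <- min(p_max, n - 2L)
  if (p_max < 1L) return(list(order = 0L, phi = numeric(0)))
  ld <- levinson(x, p_max)
  v <- pmax(ld$v, .Machine$double.xmin)
  bic <- n * log(v) + (0:p_max) * log(n)
  k <- which.min(bic) - 1L
  list(order = k, phi = if (k > 0) ld$phi[[k + 1]] else numeric(0))
}

ar_whiten <- function(v, phi) {
  p <- length(phi)
  if (p == 0) return(v)
  out <- stats::filter(v, c(1, -phi), method = "convolution", sides = 1)
  as.numeric(out[-seq_len(p)])
}

# Tukey bisquare IRLS on a whitened system; returns beta, covariance with
# the standard small-sample robustness correction, and the final weights.
bisquare_fit <- function(X, y, c_tune = 4.685, max_iter = 20, tol = 1e-6) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  n <- length(y); p <- ncol(X)
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-12 * (stats::median(abs(y)) + 1e-300)) {
      # (near-)exact fit: OLS solution, zero covariance
      return(list(beta = beta, cov = matrix(0, p, p), weights = rep(1, n),
                  scale = 0, iterations = it))
    }
    u <- as.numeric(r) / s
    w <- ifelse(abs(u) <= c_tune, (1 - (u / c_tune)^2)^2, 0)
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  r <- as.numeric(y - X %*% beta)
  s <- stats::median(abs(r)) / 0.6745
  u <- r / s
  in_rng <- abs(u) <= c_tune
  psi <- ifelse(in_rng, u * (1 - (u / c_tune)^2)^2, 0)
  psi_d <- ifelse(in_rng, (1 - (u / c_tune)^2) * (1 - 5 * (u / c_tune)^2), 0)
  m1 <- mean(psi_d)
  K <- 1 + p / n * stats::var(psi_d) / m1^2          # Huber correction
  sigma2 <- K^2 * s^2 * sum(psi^2) / (n - p) / m1^2
  XtX_inv <- chol2inv(chol(crossprod(X)))
  w <- ifelse(in_rng, (1 - (u / c_tune)^2)^2, 0)
  list(beta = beta, cov = sigma2 * XtX_inv, weights = w, scale = s,
       iterations = NA_integer_)
}

#' Fit a single-channel GLM by AR-IRLS
#'
#' Iterates: (robust) fit -> AR(p) model of the residual autocorrelation
#' (order chosen by BIC in `[0, max_ar_order]`) -> pre-whitening of both the
#' trace and the design by the estimated AR filter -> Tukey-bisquare
#' iteratively reweighted least squares on the whitened system; until the
#' coefficients stabilise.  Pre-whitening restores the nominal type-I level
#' of the channel-wise t-tests under the serially correlated noise typical
#' of fNIRS; the bisquare weights downweight residual motion outliers.
#'
#' @param y numeric trace (one channel, one chromophore).
#' @param design a design matrix from [build_design()] (or a plain matrix
#'   with column names).
#' @param max_ar_order maximum AR order (default `round(4 * fs)` when a
#'   design matrix carrying `fs` is given, else 8).
#' @param max_iter maximum outer whiten/refit iterations.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @return list: `beta`, `cov`, `dof`, `ar_order`, `ar_phi`, `converged`,
#'   `iterations`, `labels`.
#' @export
fit_ar_irls <- function(y, design, max_ar_order = NULL, max_iter = 10,
                        tol = 1e-4) {
  X <- if (inherits(design, "fnirs_design_matrix")) design$X else as.matrix(design)
  if (is.null(max_ar_order)) {
    max_ar_order <- if (inherits(design, "fnirs_design_matrix")) {
      as.integer(round(4 * design$fs))
    } else 8L
  }
  n <- length(y); p <- ncol(X)
  assert(n == nrow(X), "fp_validation", "length(y) != nrow(X)")
  assert(n > p + max_ar_order, "fp_validation",
         "trace too short for the design plus AR order")
  assert(qr(X)$rank == p, "fp_validation", "design matrix is rank deficient")

  ols <- stats::lm.fit(X, y)
  beta <- ols$coefficients
  resid <- as.numeric(ols$residuals)
  # exact-interpolation shortcut (noiseless data)
  if (sqrt(mean(resid^2)) < 1e-10 * (sqrt(mean(y^2)) + 1e-300)) {
    return(list(beta = beta, cov = matrix(0, p, p, dimnames = list(colnames(X), colnames(X))),
                dof = n - p, ar_order = 0L, ar_phi = numeric(0),
                converged = TRUE, iterations = 0L, labels = colnames(X)))
  }

  converged <- FALSE
  ar <- list(order = 0L, phi = numeric(0))
  rob <- NULL
  for (it in seq_len(max_iter)) {
    ar <- select_ar(resid, max_ar_order)
    yw <- ar_whiten(y, ar$phi)
    Xw <- apply(X, 2, ar_whiten, phi = ar$phi)
    rob <- bisquare_fit(Xw, yw)
    if (max(abs(rob$beta - beta)) < tol) {
      beta <- rob$beta
      converged <- TRUE
      break
    }
    beta <- rob$beta
    resid <- as.numeric(y - X %*% beta)
  }
  dof <- length(y) - ar$order - p
  dimnames(rob$cov) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(as.numeric(beta), colnames(X)), cov = rob$cov,
       dof = dof, ar_order = ar$order, ar_phi = ar$phi,
       converged = converged, iterations = it, labels = colnames(X))
}

#' Subject-level GLM over all channels and chromophores
#'
#' @param hb an `fnirs_hb` object from [preprocess_recording()].
#' @param design a [stim_design()] or prebuilt design matrix.
#' @param max_ar_order,max_iter,tol passed to [fit_ar_irls()].
#' @param peak_time HRF peak time used when building the design.
#' @return object of class `subject_glm`: list with `fits` (named list
#'   `"<channel>.<chromophore>"`), `design_matrix`, `channels`, `fs`.
#' @export
fit_subject_glm <- function(hb, design, max_ar_order = NULL, max_iter = 10,
                            tol = 1e-4, peak_time = 6) {
  assert(inherits(hb, "fnirs_hb"), "fp_validation", "hb must be an fnirs_hb")
  dm <- if (inherits(design, "stim_design")) {
    build_design(design, hb$fs, ncol(hb$hbo), peak_time = peak_time)
  } else design
  # when the data were high-pass filtered, apply the identical filter to the
  # task regressors (not the constant) so the fit is unbiased: the model of
  # H y is H X beta, and an unfiltered X would absorb the regressors' own
  # sub-cutoff power into the coefficient
  if (!is.null(hb$hp_cutoff)) {
    task_cols <- dm$labels != "const"
    dm$X[, task_cols] <- highpass(t(dm$X[, task_cols, drop = FALSE]),
                                  cutoff = hb$hp_cutoff, fs = hb$fs) |> t()
  }
  chans <- rownames(hb$hbo) %||% as.character(seq_len(nrow(hb$hbo)))
  fits <- list()
  for (c_i in seq_along(chans)) {
    for (chrom in c("hbo", "hbr")) {
      y <- hb[[chrom]][c_i, ]
      fits[[paste(chans[c_i], chrom, sep = ".")]] <-
        fit_ar_irls(y, dm, max_ar_order = max_ar_order,
                    max_iter = max_iter, tol = tol)
    }
  }
  structure(list(fits = fits, design_matrix = dm, channels = chans,
                 fs = hb$fs),
            class = "subject_glm")
}

#' Task-vs-rest contrast map for one condition
#'
#' Tests the condition's cHRF coefficient (the derivative companion absorbs
#' latency jitter and is not tested) against zero with a two-sided t-test at
#' the stored residual degrees of freedom.  Positive t encodes activation,
#' negative t inhibition; per chromophore, channel-wise p-values are
#' BH-adjusted into q-values.
#'
#' @param glm a `subject_glm` from [fit_subject_glm()].
#' @param condition condition label (`"LG"` or `"RG"`).
#' @return data.frame (class `contrast_result`) with columns `channel`,
#'   `chromophore`, `condition`, `estimate`, `se`, `t`, `p`, `q`,
#'   `ar_order`, `dof`.
#' @export
contrast_map <- function(glm, condition) {
  assert(inherits(glm, "subject_glm"), "fp_validation",
         "glm must be a subject_glm")
  assert(condition %in% glm$design_matrix$conditions, "fp_validation",
         "unknown condition '%s'", condition)
  rows <- lapply(names(glm$fits), function(key) {
    f <- glm$fits[[key]]
    est <- f$beta[[condition]]
    se <- sqrt(f$cov[condition, condition])
    t_val <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
    p <- if (is.infinite(t_val)) 0 else 2 * stats::pt(-abs(t_val), df = f$dof)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(channel = paste(parts[-length(parts)], collapse = "."),
               chromophore = parts[length(parts)],
               condition = condition, estimate = est, se = se,
               t = t_val, p = p, ar_order = f$ar_order, dof = f$dof,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (chrom in unique(out$chromophore)) {
    i <- out$chromophore == chrom
    out$q[i] <- fdr_bh(out$p[i])
  }
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' @param p numeric vector of p-values in `[0, 1]` (one family, e.g. all
#'   channels of one chromophore-by-condition map).
#' @return monotone step-up adjusted q-values, same length as `p`.
#' @export
fdr_bh <- function(p) {
  assert(is.numeric(p), "fp_validation", "p must be numeric")
  ok <- !is.na(p)
  assert(all(p[ok] >= 0 & p[ok] <= 1), "fp_validation",
         "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
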