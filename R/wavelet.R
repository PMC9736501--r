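# Periodized orthogonal discrete wavelet transform (Daubechies-2) and the
# IQR-based motion-artifact correction built on it.
#
# The filter bank is written out here because the correction operates on
# every channel/wavelength trace and needs exact perfect reconstruction:
# analysis/synthesis use the orthogonal db2 pair with circular (periodized)
# convolution, so idwt(dwt(x)) == x to machine precision for dyadic lengths.

# db2 scaling (low-pass reconstruction) filter; sums to sqrt(2)
DB2_H <- c(0.48296291314453416, 0.83651630373780790,
           0.22414386804201339, -0.12940952255126037)
# quadrature mirror: g[k] = (-1)^k h[L-1-k]
DB2_G <- rev(DB2_H) * c(1, -1, 1, -1)

dwt_step <- function(x) {
  n <- length(x)
  idx <- outer(seq(0, n - 2, by = 2), 0:3, "+") %% n + 1  # (2k + m) mod n
  xm <- matrix(x[idx], ncol = 4)
  list(a = drop(xm %*% DB2_H), d = drop(xm %*% DB2_G))
}

idwt_step <- function(a, d) {
  n <- 2L * length(a)
  x <- numeric(n)
  for (m in 0:3) {
    pos <- (2 * seq_along(a) - 2 + m) %% n + 1
    x[pos] <- x[pos] + DB2_H[m + 1] * a + DB2_G[m + 1] * d
  }
  x
}

# Full periodized db2 decomposition of a dyadic-length vector down to
# approximation length >= 4 (or `levels` if given).
dwt_db2 <- function(x, levels = NULL) {
  n <- length(x)
  assert(n >= 8 && bitwAnd(n, n - 1L) == 0L, "fp_validation",
         "dwt_db2 needs a dyadic length >= 8, got %d", n)
  max_levels <- as.integer(log2(n)) - 2L  # stop at approximation length 4
  levels <- if (is.null(levels)) max_levels else min(levels, max_levels)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_db2 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]])
  }
  a
}

# Reflect-pad a trace to the next power of two (recording lengths are not
# dyadic); the pad is stripped after reconstruction.
pad_dyadic <- function(x) {
  n <- length(x)
  n2 <- 2^ceiling(log2(max(n, 8)))
  if (n2 == n) return(list(x = x, n = n))
  pad <- n2 - n
  refl <- rev(x)[seq_len(min(pad, n))]
  while (length(refl) < pad) refl <- c(refl, rev(refl))[seq_len(pad)]
  list(x = c(x, refl[seq_len(pad)]), n = n)
}

wavelet_correct_trace <- function(x, iqr_factor, min_coefs = 16L) {
  p <- pad_dyadic(x)
  dec <- dwt_db2(p$x)
  if (is.finite(iqr_factor)) {
    # Pass 1 -- levels with enough coefficients for stable quartiles get
    # the IQR outlier rule (quartiles of the 8-16 samples at the deepest
    # levels are dominated by the very outliers they are meant to flag, so
    # those levels are skipped here).  Coefficients whose support lies in
    # the reflection pad are spared -- the pad crease is not an artifact
    # of the data.  The time positions of flagged coefficients are kept.
    cand_t <- numeric(0)
    cand_j <- integer(0)
    fences <- vector("list", length(dec$details))
    for (j in seq_along(dec$details)) {
      d <- dec$details[[j]]
      if (length(d) < min_coefs) next
      q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      fences[[j]] <- c(q[1], q[2], iqr)
      out <- (d < q[1] - iqr_factor * iqr | d > q[2] + iqr_factor * iqr) &
        (seq_along(d) - 1) * 2^j < p$n
      if (any(out)) {
        cand_t <- c(cand_t, (which(out) - 0.5) * 2^j)
        cand_j <- c(cand_j, rep(j, sum(out)))
      }
      d[out] <- 0
      dec$details[[j]] <- d
    }
    # Pass 2 -- a spike or step has coefficients aligned in time at every
    # level, but on strongly coloured backgrounds its mid- and deep-level
    # coefficients can sit inside that level's fences.  An artifact is
    # *confirmed* when outliers from at least two distinct levels align in
    # time (isolated single-level flags are ordinary noise tails); the
    # coefficients of every level whose support covers a confirmed
    # artifact time are zeroed.  Artifact-free traces confirm no events
    # and are untouched by this pass.
    events <- numeric(0)
    for (i in seq_along(cand_t)) {
      tol <- 2^pmax(cand_j[i], cand_j) + 2
      if (any(cand_j != cand_j[i] & abs(cand_t - cand_t[i]) <= tol)) {
        events <- c(events, cand_t[i])
      }
    }
    if (length(events)) {
      for (j in seq_along(dec$details)) {
        # an artifact's coefficient magnitude decays ~2^(-j/2) with depth
        # while the gate window grows as 2^j; past the 32-sample scale the
        # residual is negligible and gating would excise large stretches
        # of legitimate slow physiology
        if (2^j > 32 || is.null(fences[[j]])) next
        d <- dec$details[[j]]
        f <- fences[[j]]
        ctr <- (seq_along(d) - 0.5) * 2^j
        hw <- 1.5 * 2^j
        near <- vapply(ctr, function(cc) any(abs(events - cc) < hw),
                       logical(1))
        # near a confirmed artifact the evidence threshold drops to a
        # quarter of the global fence: surgical, so task-band content
        # away from (or small near) events is untouched
        loc <- 0.25 * iqr_factor * f[3]
        d[near & (d < f[1] - loc | d > f[2] + loc)] <- 0
        dec$details[[j]] <- d
      }
    }
  }
  idwt_db2(dec)[seq_len(p$n)]
}

#' Wavelet-based motion-artifact correction
#'
#' Decomposes each channel/wavelength trace with a Daubechies-2 discrete
#' wavelet transform and zeroes detail coefficients lying more than
#' `iqr_factor` interquartile ranges beyond the quartiles of their level --
#' the classic outlier rule for transient motion artifacts (spikes and
#' baseline shifts), which concentrate in few large coefficients while
#' hemodynamics and oscillatory physiology spread over many small ones.
#' A second pass time-gates: artifact times confirmed by outlier alignment
#' across two or more levels have their coefficients zeroed at every level
#' up to the 32-sample scale, which removes the artifact content that slips
#' inside the fences of physiology-dominated mid levels.
#'
#' @param od an optical-density object from [intensity_to_od()], or a plain
#'   numeric matrix (rows = traces) / vector.
#' @param iqr_factor positive outlier multiplier (default 1.5; `Inf`
#'   disables thresholding, returning the input to reconstruction
#'   precision).
#' @param min_coefs levels with fewer coefficients than this are left
#'   untouched (their quartiles are too unstable to define outliers, and
#'   they carry the slow physiology the high-pass stage handles anyway).
#' @return object of the same shape with corrected traces.
#' @export
wavelet_motion_correct <- function(od, iqr_factor = 1.5, min_coefs = 16L) {
  assert(is_scalar_num(iqr_factor) || identical(iqr_factor, Inf),
         "fp_validation", "iqr_factor must be a positive number")
  assert(iqr_factor > 0, "fp_validation", "iqr_factor must be > 0")
  if (inherits(od, "fnirs_od")) {
    check_step_order(od$steps, "wavelet")
    dm <- dim(od$od)
    for (c_i in seq_len(dm[1])) for (w in 1:2) {
      od$od[c_i, w, ] <- wavelet_correct_trace(od$od[c_i, w, ], iqr_factor, min_coefs)
    }
    od$steps <- c(od$steps, "wavelet")
    return(od)
  }
  if (is.matrix(od)) {
    t(apply(od, 1, wavelet_correct_trace, iqr_factor = iqr_factor, min_coefs = min_coefs))
  } else {
    wavelet_correct_trace(as.numeric(od), iqr_factor, min_coefs)
  }
}
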