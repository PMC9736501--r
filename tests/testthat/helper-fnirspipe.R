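# Shared fixtures: all built in code, kept deliberately tiny so the unit
# suite stays fast; the calibration/simulation studies live in
# test-acceptance.R at their full sizes.

tiny_montage <- function(n_ch = 4, wavelengths = c(760, 850), distance = 30) {
  ids <- paste0("CH", seq_len(n_ch))
  src <- paste0("S", seq_len(n_ch))
  det <- paste0("D", seq_len(n_ch))
  fnirs_montage(
    wavelengths,
    sources = data.frame(id = src, label = src, x = seq_len(n_ch) * 40,
                         y = 0, z = 0),
    detectors = data.frame(id = det, label = det,
                           x = seq_len(n_ch) * 40 + distance, y = 0, z = 0),
    channels = data.frame(channel = ids, source = src, detector = det,
                          distance = distance))
}

tiny_design <- function(n_per_cond = 2, task = 10, rest = 20, lead = 10) {
  n_ev <- 2 * n_per_cond
  stim_design(
    data.frame(condition = rep(c("LG", "RG"), n_per_cond),
               onset = lead + (seq_len(n_ev) - 1) * (task + rest),
               duration = task),
    lead + n_ev * (task + rest))
}

# smooth zero-mean hemoglobin series for inversion tests
smooth_hb <- function(montage, n = 200, fs = 1.9531, seed = 1) {
  set.seed(seed)
  n_ch <- nrow(montage$channels)
  tt <- (seq_len(n) - 1) / fs
  hbo <- t(sapply(seq_len(n_ch), function(i) {
    0.3 * sin(2 * pi * 0.05 * tt + i) + 0.1 * sin(2 * pi * 0.11 * tt + 2 * i)
  }))
  hbr <- -0.5 * hbo
  rownames(hbo) <- rownames(hbr) <- as.character(montage$channels$channel)
  structure(list(fs = fs, hbo = hbo, hbr = hbr, montage = montage,
                 steps = "sim"),
            class = "fnirs_hb")
}

# textbook Benjamini-Hochberg step-up, written independently of p.adjust:
# sort ascending, q_(i) = min_{j >= i} m p_(j) / j
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * p[o[i]] / i)
    q_sorted[i] <- min(run_min, 1)
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Pearson correlation from explicit sums (oracle helper)
pearson_sums <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  num / den
}

quick_params <- function(...) {
  sim_params(n_epd = 1, n_mpd = 1, target_correlation = NULL,
             channels_per_roi = c("L-SMN" = 2, "R-SMN" = 2),
             trials_per_condition = 2, ...)
}
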