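# Synthetic-study generator: block designs, planted responses, artifacts,
# covariate coupling, determinism and conservation.

fs <- 1.9531

test_that("generated designs follow the block paradigm", {
  p <- sim_params()
  d <- generate_design(p, seed = 3)
  expect_equal(nrow(d$events), 20)
  expect_equal(sort(unique(d$events$condition)), c("LG", "RG"))
  expect_equal(as.numeric(table(d$events$condition)), c(10, 10))
  expect_equal(unique(diff(d$events$onset)), 30)
  expect_true(all(d$events$duration == 10))
  expect_gte(d$duration, 600)

  p1 <- sim_params(trials_per_condition = 1)
  expect_equal(nrow(generate_design(p1, seed = 1)$events), 2)

  d2 <- generate_design(p, seed = 3)
  expect_identical(d$events, d2$events)
  orders <- vapply(1:30, function(s) {
    paste(generate_design(p, seed = s)$events$condition, collapse = "")
  }, character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("noiseless simulation reproduces the task regressor exactly", {
  p <- quick_params(ar_sd = 0, cardiac = c(0, 1.1), mayer = c(0, 0.1),
                    resp = c(0, 0.25), drift = c(0, 0.005),
                    superficial_sd = 0, subject_amp_sd = 0)
  layout <- synthetic_montage(p$channels_per_roi)
  d <- generate_design(p, seed = 1)
  sim <- simulate_subject_hb(p, d, layout, group = "ePD", seed = 1,
                             subject_id = "s1")
  n <- ncol(sim$hb$hbo)
  ev <- d$events[d$events$condition == "RG", ]
  reg <- fnirspipe:::condition_regressor(ev, p$fs, n)
  act <- layout$active[["L-SMN"]]  # carries the right-grasp response
  amp <- sim$truth$amplitudes[act[1], "RG"]
  expect_equal(amp, 0.3)
  expect_equal(sim$hb$hbo[act[1], ], amp * reg, tolerance = 1e-12,
               ignore_attr = TRUE)
  # anti-correlated chromophore at the configured ratio
  expect_equal(sim$hb$hbr[act[1], ], -0.5 * amp * reg, tolerance = 1e-12,
               ignore_attr = TRUE)
  # inactive channel stays silent
  inact <- setdiff(layout$roi$channel[layout$roi$roi == "L-SMN"], act)
  expect_equal(max(abs(sim$hb$hbo[inact[1], ])), 0)
})

test_that("chromophore ratio arithmetic propagates to ground truth", {
  p <- quick_params(chromophore_ratio = 0.5, subject_amp_sd = 0,
                    ar_sd = 0, cardiac = c(0, 1.1), mayer = c(0, 0.1),
                    resp = c(0, 0.25), drift = c(0, 0.005),
                    superficial_sd = 0)
  layout <- synthetic_montage(p$channels_per_roi)
  d <- generate_design(p, seed = 2)
  sim <- simulate_subject_hb(p, d, layout, "ePD", seed = 2, subject_id = "s1")
  act <- layout$active[["L-SMN"]][1]
  i <- match(act, rownames(sim$hb$hbo))
  peak_hbo <- sim$truth$amplitudes[act, "RG"]
  expect_equal(peak_hbo, 0.3)
  # the HbR companion is -r x the HbO2 response everywhere
  expect_equal(sim$hb$hbr[i, ], -0.5 * sim$hb$hbo[i, ], tolerance = 1e-12)
})

test_that("artifact injection: zero rate, logging, Poisson counts", {
  set.seed(1)
  y <- rnorm(500)
  out0 <- inject_artifacts(y, fs, rate_per_min = 0, seed = 1)
  expect_identical(out0$data, y)
  expect_equal(nrow(out0$log), 0)

  # a logged spike is where the series deviates most from the clean input
  clean <- sin(2 * pi * 0.02 * (1:1200) / fs)
  art <- inject_artifacts(clean, fs, rate_per_min = 0.3, spike_amp = 10,
                          shift_amp = 3, seed = 2, shared_times = FALSE)
  spikes <- art$log[art$log$type == "spike", ]
  expect_gt(nrow(spikes), 0)
  dev <- abs(art$data - clean)
  expect_true(any(abs(which.max(dev) - spikes$sample) <= 3))

  # Poisson counting oracle: rate 2/min on a 10-min recording, 40 seeds;
  # the total count is Poisson(40 * 20)
  n10 <- round(10 * 60 * fs)
  counts <- vapply(1:40, function(s) {
    nrow(inject_artifacts(numeric(n10), fs, rate_per_min = 2, seed = s,
                          shared_times = FALSE)$log)
  }, numeric(1))
  total <- sum(counts)
  expect_gte(total, qpois(0.005, 40 * 20))
  expect_lte(total, qpois(0.995, 40 * 20))
})

test_that("covariate generation matches its group means and copula target", {
  # large-n copula oracle: target rho recovered within +-0.05
  p <- sim_params(n_epd = 1000, n_mpd = 1000)
  subs <- data.frame(subject = sprintf("s%04d", 1:2000),
                     group = rep(c("ePD", "mPD"), each = 1000))
  amp <- rnorm(2000, 0.1, 0.05)
  clin <- generate_covariates(p, subs, target_amplitude = amp, seed = 5)
  got <- spearman_cor(clin$updrs, amp)
  expect_lt(abs(got$rho - 0.5), 0.05)

  # independence: target rho 0
  p0 <- sim_params(n_epd = 1000, n_mpd = 1000,
                   target_correlation = list(variable = "updrs",
                                             roi = "R-VIS2", rho = 0))
  clin0 <- generate_covariates(p0, subs, target_amplitude = amp, seed = 6)
  expect_lt(abs(spearman_cor(clin0$updrs, amp)$rho), 0.05)

  # other covariates independent of the amplitudes
  expect_lt(abs(spearman_cor(clin$criq, amp)$rho), 0.08)

  # published group demographics as generator defaults (13 / 26 subjects):
  # mean ages within 2 SE of 63.5 and 71.7 when averaged over seeds
  p2 <- sim_params()
  subs2 <- data.frame(subject = sprintf("s%02d", 1:39),
                      group = c(rep("ePD", 13), rep("mPD", 26)))
  ages <- t(vapply(1:25, function(s) {
    cl <- generate_covariates(p2, subs2, target_amplitude = rnorm(39), seed = s)
    c(mean(cl$age[cl$group == "ePD"]), mean(cl$age[cl$group == "mPD"]))
  }, numeric(2)))
  se <- c(5.967 / sqrt(13), 6.961 / sqrt(26)) / sqrt(25)
  expect_lt(abs(mean(ages[, 1]) - 63.519), 2 * se[1])
  expect_lt(abs(mean(ages[, 2]) - 71.676), 2 * se[2])

  # Stroop missingness reproduces the reported incomplete administrations
  cl <- generate_covariates(p2, subs2, target_amplitude = rnorm(39), seed = 2)
  expect_equal(sum(is.na(cl$scwe)), 2)
  expect_equal(sum(is.na(cl$scwt)), 3)

  # a target correlation with too few subjects is degenerate
  expect_error(
    generate_covariates(p2, subs2[1:2, ], target_amplitude = c(1, 2), seed = 1),
    class = "fp_validation")
})

test_that("identical (params, seed) reproduce the study bit for bit", {
  p <- quick_params()
  s1 <- simulate_study(p, seed = 17)
  s2 <- simulate_study(p, seed = 17)
  expect_identical(s1$subjects[[1]]$intensity$intensity,
                   s2$subjects[[1]]$intensity$intensity)
  expect_identical(s1$clinical, s2$clinical)
  s3 <- simulate_study(p, seed = 18)
  expect_false(identical(s1$subjects[[1]]$intensity$intensity,
                         s3$subjects[[1]]$intensity$intensity))
})

test_that("component decomposition sums exactly to the emitted series", {
  p <- quick_params()
  st <- simulate_study(p, seed = 23, keep_hb = TRUE)
  s <- st$subjects[[1]]
  comp <- st$truth$components[[s$id]]
  total <- comp$clean_hbo + comp$noise_hbo + comp$superficial_hbo
  expect_identical(total, s$hb$hbo, ignore_attr = TRUE)
  expect_identical(comp$clean_hbr + comp$noise_hbr + comp$superficial_hbr,
                   s$hb$hbr, ignore_attr = TRUE)
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(trials_per_condition = 0), class = "fp_validation")
  expect_error(sim_params(task_duration = -1), class = "fp_validation")
  expect_error(sim_params(artifact_rate_per_min = -0.1),
               class = "fp_validation")
  expect_error(sim_params(target_correlation = list(variable = "updrs",
                                                    roi = "R-VIS2", rho = 1)),
               class = "fp_validation")
})
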