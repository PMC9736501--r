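# ROI selection, averaging, Spearman machinery, ROI-based correlation
# analysis, group characterisation.

test_that("sensitivity thresholding is inclusive and matches brute force", {
  sens <- matrix(c(0.20, 0.19, 0.5, 0.0,
                   0.10, 0.25, 0.0, 1.0,
                   0.0,  0.0,  0.0, 0.0),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"),
                                 c("CH1", "CH2", "CH3", "CH4")))
  sel <- select_roi_channels_by_sensitivity(sens, 0.20)
  # brute force over all entries
  for (r in rownames(sens)) {
    expect_setequal(sel[[r]], colnames(sens)[sens[r, ] >= 0.20])
  }
  expect_identical(sel$A, c("CH1", "CH3"))  # 0.20 exactly is included
  expect_identical(sel$C, character(0))
  # a channel may serve several ROIs
  sens2 <- rbind(A = c(CH1 = 0.5), B = c(CH1 = 0.9))
  sel2 <- select_roi_channels_by_sensitivity(sens2, 0.2)
  expect_identical(sel2$A, sel2$B)
  expect_error(select_roi_channels_by_sensitivity(sens, 0),
               class = "fp_validation")
  expect_error(select_roi_channels_by_sensitivity(sens * 3, 0.2),
               class = "fp_validation")
})

test_that("ROI averaging is the unweighted mean over members", {
  vals <- c(CH1 = 2, CH2 = -2, CH3 = 1, CH4 = 5, CH5 = 0.5)
  out <- roi_average(vals, list(single = "CH3",
                                balanced = c("CH1", "CH2"),
                                five = names(vals)))
  expect_equal(out$mean[out$roi == "single"], 1)
  # balanced positive/negative channels cancel (the documented caveat of
  # averaging signed statistics)
  expect_equal(out$mean[out$roi == "balanced"], 0)
  expect_equal(out$mean[out$roi == "five"], sum(vals) / 5)
  expect_warning(res <- roi_average(vals, list(empty = character(0))),
                 "no member channels")
  expect_equal(nrow(res), 0)
})

test_that("spearman_cor matches mid-rank oracles and is monotone-invariant", {
  # hand oracle with a tie: x = 1..4, y = (1, 2, 2, 4)
  s <- spearman_cor(1:4, c(1, 2, 2, 4))
  expect_equal(s$rho, pearson_sums(1:4, c(1, 2.5, 2.5, 4)), tolerance = 1e-12)
  # against the established implementation
  set.seed(3)
  x <- rnorm(25); y <- x + rnorm(25)
  expect_equal(spearman_cor(x, y)$rho,
               unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  # strictly monotone transform changes nothing; reversal negates
  expect_equal(spearman_cor(exp(x), y^3 + 5 * y)$rho,
               spearman_cor(x, y^3 + 5 * y)$rho)
  expect_equal(spearman_cor(x, -y)$rho, -spearman_cor(x, y)$rho)
  # monotone dependence attains 1
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_error(spearman_cor(1:2, 2:1), class = "fp_validation")
  expect_warning(s0 <- spearman_cor(rep(1, 5), rnorm(5)), "zero rank")
  expect_true(is.na(s0$rho))
})

test_that("partial_spearman equals the first-order formula on mid-ranks", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  z <- c(1, 2, 3, 4, 5, 6)
  got <- partial_spearman(x, y, z)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- pearson_sums(rx, ry); r_xz <- pearson_sums(rx, rz)
  r_yz <- pearson_sums(ry, rz)
  expect_equal(got$rho,
               (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
               tolerance = 1e-12)
  # constant covariate falls back to the plain coefficient
  expect_warning(pc <- partial_spearman(x, y, rep(1, 6)), "zero rank")
  expect_equal(pc$rho, spearman_cor(x, y)$rho)
  # y identical to the covariate exercises the degenerate path
  expect_warning(partial_spearman(x, z, z), "undefined")
  # independent covariate leaves the coefficient essentially unchanged
  set.seed(5)
  n <- 2000
  a <- rnorm(n); b <- 0.6 * a + rnorm(n); cvt <- rnorm(n)
  expect_lt(abs(partial_spearman(a, b, cvt)$rho - spearman_cor(a, b)$rho),
            0.05)
})

test_that("roi_ca selects, averages and correlates as specified", {
  small <- c("L-SMN" = 6, "R-VIS2" = 6)
  p <- sim_params(channels_per_roi = small)
  sb <- simulate_subject_betas(p, seed = 73)
  model <- fit_group_model(sb$subject_betas)
  cms <- rbind(group_contrast_map(model, "LG"), group_contrast_map(model, "RG"))
  res <- roi_ca(cms, sb$subject_betas, sb$roi_config, sb$clinical)
  expect_s3_class(res, "roi_correlation")
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(all(res$n >= 3))
  # age rows carry no partial coefficient (age is the covariate)
  expect_true(all(is.na(res$partial_rho[res$variable == "age"])))
  # selected channel sets grow with alpha
  res_small <- roi_ca(cms, sb$subject_betas, sb$roi_config, sb$clinical,
                      alpha = 0.01)
  res_large <- roi_ca(cms, sb$subject_betas, sb$roi_config, sb$clinical,
                      alpha = 0.20)
  key <- function(d) paste(d$roi, d$chromophore, d$condition, d$variable)
  shared <- intersect(key(res_small), key(res_large))
  expect_true(all(res_large$n_channels[match(shared, key(res_large))] >=
                    res_small$n_channels[match(shared, key(res_small))]))

  # vacuous selection: no significant channel anywhere
  cms0 <- cms
  cms0$p <- 1
  expect_equal(nrow(roi_ca(cms0, sb$subject_betas, sb$roi_config,
                           sb$clinical)), 0)
})

test_that("group characterisation gates on Shapiro-Wilk and matches U oracle", {
  set.seed(2)
  # normal variable -> t branch; with two identical groups t = 0, p = 1
  x <- rnorm(12, 50, 5)
  clin <- data.frame(subject = paste0("s", 1:24),
                     group = rep(c("ePD", "mPD"), each = 12),
                     age = c(x, x), stringsAsFactors = FALSE)
  class(clin) <- c("clinical_table", "data.frame")
  out <- characterize_groups(clin, variables = "age")
  expect_identical(out$test, "t")
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)

  # the Mann-Whitney U statistic equals the brute-force count of pairwise
  # wins; a heavy-tailed variable trips the normality gate
  skewed <- c(exp(rnorm(12)), exp(rnorm(12) + 2))
  clin$updrs <- skewed
  out2 <- characterize_groups(clin, variables = "updrs")
  if (out2$test == "mann-whitney") {
    g1 <- skewed[1:12]; g2 <- skewed[13:24]
    u_brute <- sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
    expect_equal(out2$statistic, u_brute)
  }
  # tiny exhaustive oracle: x = (1,2,3) vs y = (4,5,6) -> U = 0
  expect_equal(unname(wilcox.test(c(1, 2, 3), c(4, 5, 6))$statistic), 0)

  # gate behaviour: normal data at n = 200/group passes Shapiro most times
  gate <- replicate(30, {
    cl <- data.frame(subject = paste0("s", 1:400),
                     group = rep(c("ePD", "mPD"), each = 200),
                     age = rnorm(400, 65, 7))
    class(cl) <- c("clinical_table", "data.frame")
    characterize_groups(cl, variables = "age")$test == "t"
  })
  expect_gte(mean(gate), 0.85)
})
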