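# ROI analysis: sensitivity-based channel selection, ROI averaging, the
# two-step ROI-based correlation analysis against clinical covariates
# (plain and age-partialled Spearman), and group characterisation tests.

#' Select ROI member channels from a sensitivity matrix
#'
#' A channel belongs to an ROI iff it collects at least `threshold` of the
#' region's signal (inclusive); a channel may belong to several ROIs.
#'
#' @param sensitivity numeric matrix, rows = ROIs (rownames = labels),
#'   columns = channels (colnames = ids), entries in `[0, 1]`.
#' @param threshold inclusion threshold in `(0, 1]` (default 0.20).
#' @return named list of channel-id vectors, one per ROI.
#' @export
select_roi_channels_by_sensitivity <- function(sensitivity, threshold = 0.20) {
  assert(is_scalar_num(threshold) && threshold > 0 && threshold <= 1,
         "fp_validation", "threshold must lie in (0, 1]")
  sens <- as.matrix(sensitivity)
  assert(all(sens >= 0 & sens <= 1), "fp_validation",
         "sensitivity fractions must lie in [0, 1]")
  chans <- colnames(sens) %||% as.character(seq_len(ncol(sens)))
  rois <- rownames(sens) %||% paste0("ROI", seq_len(nrow(sens)))
  out <- lapply(seq_len(nrow(sens)), function(i) {
    chans[sens[i, ] >= threshold]
  })
  stats::setNames(out, rois)
}

#' Average channel-wise values over ROI members
#'
#' Unweighted arithmetic mean of a channel-indexed statistic over each
#' ROI's member channels.  Note that averaging signed statistics can cancel
#' balanced positive/negative channels; member counts are reported so this
#' is visible.
#'
#' @param values named numeric vector (names = channel ids).
#' @param membership named list of channel-id vectors.
#' @return data.frame with `roi`, `mean`, `n_channels`; ROIs with no
#'   members are omitted with a warning.
#' @export
roi_average <- function(values, membership) {
  assert(!is.null(names(values)), "fp_validation", "values must be named")
  rows <- lapply(names(membership), function(lab) {
    chs <- intersect(membership[[lab]], names(values))
    if (!length(chs)) {
      fp_warn("ROI '%s' has no member channels with values; omitted", lab)
      return(NULL)
    }
    data.frame(roi = lab, mean = mean(values[chs]), n_channels = length(chs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(roi = character(0), mean = numeric(0),
                                      n_channels = integer(0))
  rownames(out) <- NULL
  out
}

mid_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties) with a
#' two-sided p-value from the t approximation at `n - 2` degrees of
#' freedom.  Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors.
#' @return list: `rho`, `p`, `n`; `rho` is `NA` (with a warning) when
#'   either variable has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert(n >= 3, "fp_validation",
         "Spearman correlation needs >= 3 complete pairs, got %d", n)
  rx <- mid_rank(x); ry <- mid_rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    fp_warn("zero rank variance; Spearman coefficient undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- spearman_p(rho, n, df = n - 2)
  list(rho = rho, p = p, n = n)
}

spearman_p <- function(rho, n, df) {
  if (abs(rho) >= 1) return(0)
  t_val <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(t_val), df = df)
}

#' Partial Spearman correlation given a covariate
#'
#' Mid-rank-transforms all three variables and applies the first-order
#' partial-correlation formula to the rank correlations; the two-sided p
#' uses `n - 3` degrees of freedom.  A covariate with zero rank variance
#' falls back to the plain Spearman coefficient with a warning.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector to partial out (conventionally age).
#' @return list: `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariate) {
  ok <- stats::complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; z <- covariate[ok]
  n <- length(x)
  assert(n >= 4, "fp_validation",
         "partial Spearman needs >= 4 complete triples, got %d", n)
  rx <- mid_rank(x); ry <- mid_rank(y); rz <- mid_rank(z)
  if (stats::sd(rz) == 0) {
    fp_warn("covariate has zero rank variance; falling back to plain Spearman")
    s <- spearman_cor(x, y)
    return(list(rho = s$rho, p = s$p, n = n))
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    fp_warn("zero rank variance; partial Spearman undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz); r_yz <- stats::cor(ry, rz)
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (den == 0) {
    fp_warn("degenerate rank dependence on covariate; partial Spearman undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- (r_xy - r_xz * r_yz) / den
  p <- spearman_p(rho, n, df = n - 3)
  list(rho = rho, p = p, n = n)
}

#' Two-step ROI-based correlation analysis
#'
#' Step 1: within each chromophore-by-condition between-group contrast map,
#' note the channels with uncorrected `p < alpha`, and intersect them with
#' each ROI's membership.  Step 2: average every subject's task-vs-rest
#' contrast coefficient over the selected channels.  Step 3: correlate the
#' per-subject ROI averages (all subjects pooled) with each clinical
#' variable by Spearman's rank correlation, and, since age is itself
#' related to both disease stage and cortical activity, by the
#' age-partialled Spearman correlation.  Missing clinical values are
#' handled pairwise-complete; BH-adjusted companions of the raw p-values
#' are emitted for transparency.
#'
#' @param contrast_maps `group_map` data.frame from [group_contrast_map()]
#'   (stacked over conditions).
#' @param subject_betas data.frame `subject, group, condition, channel,
#'   chromophore, beta`.
#' @param roi_config an `roi_config` (or named membership list).
#' @param clinical a `clinical_table`.
#' @param alpha step-1 channel selection level (uncorrected; default 0.05).
#' @param variables clinical variables to correlate.
#' @param age_covariate variable partialled out (default `"age"`).
#' @return data.frame (class `roi_correlation`) keyed by
#'   `(roi, chromophore, condition, variable)` with `rho`, `p`, `q`,
#'   `partial_rho`, `partial_p`, `n`, `n_channels`.
#' @export
roi_ca <- function(contrast_maps, subject_betas, roi_config, clinical,
                   alpha = 0.05,
                   variables = c("age", "criq", "duration", "updrs",
                                 "scwe", "scwt"),
                   age_covariate = "age") {
  membership <- if (inherits(roi_config, "roi_config")) roi_config$membership
                else roi_config
  cm <- as.data.frame(contrast_maps)
  sb <- as.data.frame(subject_betas)
  clin <- as.data.frame(clinical)
  variables <- intersect(variables, names(clin))
  rows <- list()
  for (chrom in unique(cm$chromophore)) {
    for (cond in unique(cm$condition)) {
      sel_map <- cm[cm$chromophore == chrom & cm$condition == cond, ]
      sig_channels <- sel_map$channel[sel_map$p < alpha]
      for (lab in names(membership)) {
        chs <- intersect(membership[[lab]], sig_channels)
        if (!length(chs)) next
        sub <- sb[sb$chromophore == chrom & sb$condition == cond &
                    sb$channel %in% chs, ]
        if (!nrow(sub)) next
        avg <- tapply(sub$beta, sub$subject, mean)
        dat <- clin[match(names(avg), as.character(clin$subject)), ]
        for (v in variables) {
          res <- tryCatch(spearman_cor(as.numeric(avg), dat[[v]]),
                          error = function(e) NULL)
          if (is.null(res)) {
            fp_warn("ROI %s / %s / %s / %s: < 3 complete pairs; omitted",
                    lab, chrom, cond, v)
            next
          }
          pres <- list(rho = NA_real_, p = NA_real_)
          if (v != age_covariate && age_covariate %in% names(dat)) {
            pres <- tryCatch(
              partial_spearman(as.numeric(avg), dat[[v]], dat[[age_covariate]]),
              error = function(e) list(rho = NA_real_, p = NA_real_))
          }
          rows[[length(rows) + 1]] <- data.frame(
            roi = lab, chromophore = chrom, condition = cond, variable = v,
            rho = res$rho, p = res$p,
            partial_rho = pres$rho, partial_p = pres$p,
            n = res$n, n_channels = length(chs), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi = character(0), chromophore = character(0),
               condition = character(0), variable = character(0),
               rho = numeric(0), p = numeric(0), partial_rho = numeric(0),
               partial_p = numeric(0), n = integer(0), n_channels = integer(0))
  out$q <- if (nrow(out)) fdr_bh(out$p) else numeric(0)
  rownames(out) <- NULL
  class(out) <- c("roi_correlation", "data.frame")
  out
}

#' Group characterisation tests for clinical variables
#'
#' For each variable: Shapiro-Wilk normality test on the pooled sample
#' gates the two-group comparison -- an equal-variance two-sample t-test
#' when normality is not rejected (`p >= 0.05`), otherwise the
#' Mann-Whitney U test.
#'
#' @param clinical a `clinical_table`.
#' @param variables variables to test (default: all numeric columns).
#' @param groups the two group labels.
#' @return data.frame: `variable`, `shapiro_w`, `shapiro_p`, `test`
#'   (`"t"` or `"mann-whitney"`), `statistic`, `dof` (t only), `p`,
#'   `n_epd`, `n_mpd`.
#' @export
characterize_groups <- function(clinical, variables = NULL,
                                groups = c("ePD", "mPD")) {
  clin <- as.data.frame(clinical)
  if (is.null(variables)) {
    variables <- setdiff(names(clin)[vapply(clin, is.numeric, logical(1))],
                         c("subject"))
  }
  g1 <- clin$group == groups[1]
  g2 <- clin$group == groups[2]
  assert(sum(g1) >= 3 && sum(g2) >= 3, "fp_validation",
         "both groups need >= 3 subjects")
  rows <- list()
  for (v in variables) {
    x1 <- clin[[v]][g1]; x2 <- clin[[v]][g2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 3 || length(x2) < 3) {
      fp_warn("variable '%s' has too few non-missing values; skipped", v)
      next
    }
    pooled <- c(x1, x2)
    sw <- if (stats::sd(pooled) == 0) list(statistic = NA_real_, p.value = 0)
          else stats::shapiro.test(pooled)
    if (!is.na(sw$p.value) && sw$p.value >= 0.05) {
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, shapiro_w = unname(sw$statistic),
        shapiro_p = sw$p.value, test = "t",
        statistic = unname(tt$statistic), dof = unname(tt$parameter),
        p = tt$p.value, n_epd = length(x1), n_mpd = length(x2),
        stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, shapiro_w = unname(sw$statistic),
        shapiro_p = sw$p.value, test = "mann-whitney",
        statistic = unname(wt$statistic), dof = NA_real_,
        p = wt$p.value, n_epd = length(x1), n_mpd = length(x2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
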