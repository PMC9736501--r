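# Group-level statistical analysis: per-channel linear mixed-effects model
# over subject-level contrast betas, group activation maps, and
# between-group interaction contrasts.

cell_name <- function(group, condition) paste(group, condition, sep = ":")

#' Fit the group-level mixed model for one channel/chromophore
#'
#' Cell-means linear mixed-effects model over the subject-level
#' task-vs-rest contrast coefficients:
#' `beta ~ -1 + group:condition + (1 | subject)` fitted by REML, i.e. one
#' fixed effect per group-by-condition cell and a random intercept per
#' subject.  Subject-level precisions are not used as weights.  When the
#' residual variance degenerates to (numerically) zero, or the mixed fit
#' fails, an exact ordinary-least-squares cell-means fit is substituted and
#' flagged.
#'
#' @param betas data.frame with columns `subject`, `group`, `condition`,
#'   `beta` (already restricted to one channel and chromophore).
#' @return list: `cells` (named estimates), `cov`, `dof`,
#'   `random_intercept_var`, `residual_var`, `n_obs`, `n_subjects`,
#'   `converged`, `engine`.
#' @export
fit_lmem <- function(betas) {
  betas <- as.data.frame(betas)
  assert(all(c("subject", "group", "condition", "beta") %in% names(betas)),
         "fp_validation", "betas needs subject, group, condition, beta")
  betas$cell <- factor(cell_name(betas$group, betas$condition))
  counts <- table(betas$cell)
  assert(all(counts > 0), "fp_validation", "empty group:condition cell '%s'",
         names(counts)[which(counts == 0)[1]])
  n_obs <- nrow(betas)
  n_sub <- length(unique(betas$subject))
  n_cell <- nlevels(betas$cell)

  ols <- function() {
    # exact cell-means fit, valid for any number of cells including one
    est <- tapply(betas$beta, betas$cell, mean)
    cnt <- tapply(betas$beta, betas$cell, length)
    rss <- sum((betas$beta - est[betas$cell])^2)
    s2 <- if (n_obs > n_cell) rss / (n_obs - n_cell) else 0
    if (!is.finite(s2)) s2 <- 0
    V <- diag(s2 / as.numeric(cnt), nrow = n_cell)
    est <- stats::setNames(as.numeric(est), paste0("cell", names(est)))
    list(est = est, V = V, s2 = s2, tau2 = 0, engine = "ols")
  }

  res <- NULL
  if (n_obs > n_cell) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(beta ~ 0 + cell + (1 | subject), data = betas, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      s2 <- vc$vcov[vc$grp == "Residual"]
      if (s2 > 1e-12 * (mean(betas$beta^2) + 1e-300)) {
        res <- list(est = lme4::fixef(fit),
                    V = as.matrix(stats::vcov(fit)),
                    s2 = s2, tau2 = sum(vc$vcov[vc$grp != "Residual"]),
                    engine = "lmem")
      }
    }
  }
  if (is.null(res)) res <- ols()

  # residual dof: conservative containment-style approximation; when every
  # subject contributes a single observation the random intercept is
  # unidentified and the OLS dof applies.
  dof <- if (n_obs > n_sub) max(1L, n_obs - n_cell - n_sub + 1L)
         else max(1L, n_obs - n_cell)
  names(res$est) <- sub("^cell", "", names(res$est))
  dimnames(res$V) <- list(names(res$est), names(res$est))
  list(cells = res$est, cov = res$V, dof = dof,
       random_intercept_var = res$tau2, residual_var = res$s2,
       n_obs = n_obs, n_subjects = n_sub,
       converged = TRUE, engine = res$engine)
}

#' Fit group-level models for every channel and chromophore
#'
#' @param subject_betas data.frame with columns `subject`, `group`,
#'   `condition`, `channel`, `chromophore`, `beta`.
#' @return object of class `group_model`: named list of [fit_lmem()]
#'   results keyed `"<channel>.<chromophore>"`, plus `channels`,
#'   `chromophores`, `groups`, `conditions`.
#' @export
fit_group_model <- function(subject_betas) {
  sb <- as.data.frame(subject_betas)
  need <- c("subject", "group", "condition", "channel", "chromophore", "beta")
  assert(all(need %in% names(sb)), "fp_validation",
         "subject_betas needs columns %s", paste(need, collapse = ", "))
  keys <- unique(sb[c("channel", "chromophore")])
  fits <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- sb$channel == keys$channel[i] & sb$chromophore == keys$chromophore[i]
    fits[[paste(keys$channel[i], keys$chromophore[i], sep = ".")]] <-
      fit_lmem(sb[sel, ])
  }
  structure(list(fits = fits,
                 channels = unique(sb$channel),
                 chromophores = unique(sb$chromophore),
                 groups = unique(sb$group),
                 conditions = unique(sb$condition)),
            class = "group_model")
}

map_from_contrast <- function(model, cvec_fun, map_type, condition) {
  rows <- lapply(names(model$fits), function(key) {
    f <- model$fits[[key]]
    cv <- cvec_fun(f)
    est <- sum(cv * f$cells)
    se <- sqrt(drop(t(cv) %*% f$cov %*% cv))
    t_val <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
    p <- if (is.infinite(t_val)) 0 else 2 * stats::pt(-abs(t_val), df = f$dof)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(channel = paste(parts[-length(parts)], collapse = "."),
               chromophore = parts[length(parts)], map = map_type,
               condition = condition, estimate = est, se = se, t = t_val,
               p = p, dof = f$dof, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (chrom in unique(out$chromophore)) {
    i <- out$chromophore == chrom
    out$q[i] <- fdr_bh(out$p[i])
  }
  rownames(out) <- NULL
  class(out) <- c("group_map", "data.frame")
  out
}

#' Group activation map
#'
#' Per-channel t/p/q for one group-by-condition cell against zero; positive
#' t encodes activation relative to baseline.  q-values are BH-adjusted
#' across channels within each chromophore map.
#'
#' @param model a `group_model` from [fit_group_model()].
#' @param group,condition cell selectors.
#' @return `group_map` data.frame.
#' @export
group_activation_map <- function(model, group, condition) {
  target <- cell_name(group, condition)
  f1 <- model$fits[[1]]
  assert(target %in% names(f1$cells), "fp_validation",
         "unknown group/condition cell '%s'", target)
  map_from_contrast(model, function(f) {
    as.numeric(names(f$cells) == target)
  }, map_type = paste0("activation:", group), condition = condition)
}

#' Group contrast map (ePD vs mPD)
#'
#' Per-channel t/p/q for the between-group difference of one condition's
#' cell means; positive t encodes a larger mean activation in the first
#' (early, `ePD`) group.  Both the uncorrected p and the BH-adjusted q are
#' reported.
#'
#' @param model a `group_model`.
#' @param condition condition label.
#' @param groups length-2 character, contrast is `groups[1] - groups[2]`.
#' @return `group_map` data.frame.
#' @export
group_contrast_map <- function(model, condition, groups = c("ePD", "mPD")) {
  f1 <- model$fits[[1]]
  cells <- cell_name(groups, condition)
  assert(all(cells %in% names(f1$cells)), "fp_validation",
         "missing group cell(s) %s",
         paste(setdiff(cells, names(f1$cells)), collapse = ", "))
  map_from_contrast(model, function(f) {
    as.numeric(names(f$cells) == cells[1]) - as.numeric(names(f$cells) == cells[2])
  }, map_type = paste0("contrast:", groups[1], "-", groups[2]),
  condition = condition)
}
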