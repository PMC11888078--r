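# Multiple imputation by chained equations with predictive mean matching
# (PMM), plus Rubin's-rules pooling. Imputation targets are the per-wave
# utilities and per-period direct and indirect costs with dropout
# missingness; structurally missing control waves are left to the
# extrapolation module.

impute_targets <- function(wide, max_wave = NULL) {
  k <- attr(wide, "n_waves")
  last <- min(k - 1L, max_wave %||% (k - 1L))
  fams <- c("u", "dc", "ic")
  targets <- list()
  for (t in seq_len(last)) {
    for (f in fams) {
      v <- paste0(f, t)
      st <- wide[[paste0("str", t)]]
      mis <- is.na(wide[[v]]) & !st
      obs <- !is.na(wide[[v]])
      if (all(mis | st)) {
        stop(sprintf("variable '%s' has no observed values to impute from", v),
             call. = FALSE)
      }
      if (any(mis)) {
        targets[[v]] <- list(var = v, family = f, wave = t,
                             mis = which(mis), obs = which(obs))
      }
    }
  }
  targets
}

impute_predictors <- function(family, wave, k) {
  base <- c("age", "gender_male", "antidepressant_use", "treatment",
            paste0(family, 0L))
  if (wave > 1L) base <- c(base, paste0(family, wave - 1L))
  if (wave < k - 1L) base <- c(base, paste0(family, wave + 1L))
  base
}

# One PMM draw for a single variable: Bayesian regression parameter draw,
# predicted means, and donor matching among the `donors` closest observed
# cases.
pmm_draw <- function(y, Z_obs, Z_mis, donors) {
  qz <- qr(Z_obs)
  r <- qz$rank
  if (r < ncol(Z_obs)) {
    keep <- qz$pivot[seq_len(r)]
    Z_obs <- Z_obs[, keep, drop = FALSE]
    Z_mis <- Z_mis[, keep, drop = FALSE]
    qz <- qr(Z_obs)
  }
  df <- nrow(Z_obs) - qz$rank
  if (df < 1L) stop("too few complete cases for the imputation model",
                    call. = FALSE)
  beta_hat <- qr.coef(qz, y)
  res <- y - as.numeric(Z_obs %*% beta_hat)
  sigma2_hat <- sum(res^2) / df
  sigma2_star <- sigma2_hat * df / stats::rchisq(1L, df)
  R <- qr.R(qz)
  beta_star <- beta_hat +
    backsolve(R, stats::rnorm(ncol(Z_obs))) * sqrt(sigma2_star)
  yhat_obs <- as.numeric(Z_obs %*% beta_hat)
  yhat_mis <- as.numeric(Z_mis %*% beta_star)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d)[seq_len(donors)]
    y[pool[sample.int(length(pool), 1L)]]
  }, numeric(1L))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills dropout-missing utilities and period costs by iterated
#' chained-equation regression with predictive mean matching: each missing
#' cell receives the observed value of a donor whose predicted mean is
#' closest to the (parameter-uncertainty-perturbed) prediction for the
#' missing case. Imputed values therefore always lie within the observed
#' support of the variable. Each variable is modelled on age, gender,
#' antidepressant use, treatment arm, its baseline value, and the adjacent
#' (previous/next) assessments; predictors that are structurally unavailable
#' for the cases involved are pruned from that model. Structurally missing
#' control waves are never imputed here.
#'
#' @param data A [trial_panel()] (with `wage` supplied) or a wide frame from
#'   the internal layout.
#' @param m Number of completed datasets (at least 2 for pooling).
#' @param donors Size of the PMM donor pool (k nearest predicted means).
#' @param cycles Number of chained-equation cycles.
#' @param seed Integer seed; the stack is deterministic given it.
#' @param wage [wage_model()], required when `data` is a `trial_panel`.
#' @param max_wave Impute only variables up to this wave (0-based); later
#'   waves are left untouched. Useful when the analysis horizon does not
#'   need them.
#' @return Object of class `imputed_stack`: list with `datasets` (m complete
#'   wide frames), and the settings used.
#' @export
mice_pmm <- function(data, m = 5L, donors = 5L, cycles = 10L, seed = 1L,
                     wage = NULL, max_wave = NULL) {
  if (inherits(data, "trial_panel")) {
    if (is.null(wage)) stop("`wage` is required to value productivity days",
                            call. = FALSE)
    wide <- panel_wide(data, wage)
  } else {
    wide <- data
  }
  if (m < 1L) stop("`m` must be at least 1", call. = FALSE)
  k <- attr(wide, "n_waves")
  for (f in c("u", "dc", "ic")) {
    if (anyNA(wide[[paste0(f, 0L)]])) {
      stop("baseline values must be complete before imputation",
           call. = FALSE)
    }
  }
  targets <- impute_targets(wide, max_wave)
  if (length(targets) == 0L) {
    datasets <- replicate(m, wide, simplify = FALSE)
    return(structure(list(datasets = datasets, m = m, donors = donors,
                          cycles = cycles, seed = seed,
                          variables = character(0)),
                     class = "imputed_stack"))
  }
  for (tg in targets) {
    if (length(tg$obs) < donors) {
      stop(sprintf("donor pool for '%s' (%d observed) smaller than requested (%d)",
                   tg$var, length(tg$obs), donors), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  datasets <- vector("list", m)
  for (im in seq_len(m)) {
    cur <- wide
    # initial fill: random draws from the observed values
    for (tg in targets) {
      cur[[tg$var]][tg$mis] <-
        sample(cur[[tg$var]][tg$obs], length(tg$mis), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (tg in targets) {
        preds <- impute_predictors(tg$family, tg$wave, k)
        rows <- c(tg$obs, tg$mis)
        Zfull <- cbind(`(Intercept)` = 1,
                       as.matrix(cur[preds]))
        # prune predictors structurally unavailable, or constant, over the
        # cases involved in this model
        Zsub <- Zfull[rows, , drop = FALSE]
        usable <- !apply(Zsub, 2, anyNA) &
          (colnames(Zfull) == "(Intercept)" |
             apply(Zsub, 2, function(col) stats::sd(col) > 0))
        usable[is.na(usable)] <- FALSE
        Z <- Zfull[, usable, drop = FALSE]
        cur[[tg$var]][tg$mis] <- pmm_draw(
          y = cur[[tg$var]][tg$obs],
          Z_obs = Z[tg$obs, , drop = FALSE],
          Z_mis = Z[tg$mis, , drop = FALSE],
          donors = donors)
      }
    }
    datasets[[im]] <- cur
  }
  structure(list(datasets = datasets, m = m, donors = donors,
                 cycles = cycles, seed = seed,
                 variables = vapply(targets, `[[`, "", "var")),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d datasets, %d variables imputed (PMM, %d donors, %d cycles)\n",
              x$m, length(x$variables), x$donors, x$cycles))
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-dataset estimates; the
#' total variance combines the mean within-imputation variance with the
#' between-imputation variance inflated by `(1 + 1/m)`. Degrees of freedom
#' follow the classic Rubin formula, and the 95% CI uses the t distribution
#' on those degrees of freedom.
#'
#' @param estimates Per-dataset point estimates (length m, m >= 2).
#' @param variances Per-dataset squared standard errors.
#' @param conf_level Confidence level for the interval.
#' @return Object of class `pooled_estimate` with `point`, `within`,
#'   `between`, `total`, `se`, `df`, `ci`, and `m`.
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1))  # total variance 1 + (4/3) * 1
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("Rubin pooling needs at least 2 imputed datasets",
                   call. = FALSE)
  if (length(variances) != m) {
    stop("`estimates` and `variances` must have equal length", call. = FALSE)
  }
  assert_nonneg(variances, "variances")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- stats::var(estimates)
  total <- wbar + (1 + 1 / m) * b
  se <- sqrt(total)
  df <- if (b == 0) Inf else (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2
  alpha <- 1 - conf_level
  half <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) * se
          else stats::qnorm(1 - alpha / 2) * se
  structure(list(point = qbar, within = wbar, between = b, total = total,
                 se = se, df = df, ci = c(qbar - half, qbar + half), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate: %.5g (SE %.5g, 95%% CI %.5g to %.5g, m = %d)\n",
              x$point, x$se, x$ci[1], x$ci[2], x$m))
  invisible(x)
}
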