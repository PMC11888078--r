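# Synthetic two-arm trial generator. Emulates the statistical structure the
# cost-utility pipeline assumes: 1:1 randomization, near-1 bounded utilities
# with small between-arm differences, zero-inflated right-skewed cost
# components, productivity-day counts, monotone MAR dropout heavier in the
# intervention arm, and structural truncation of control follow-up.

#' Default cost-component parameters for the synthetic generator
#'
#' Each cost component (drug, treatment, diagnostic) is generated as a
#' zero-inflated lognormal: a Bernoulli "resource user" indicator times a
#' lognormal amount. Defaults are calibrated so that arm-wise means and user
#' fractions in the pre- and post-treatment periods match the magnitudes
#' typical of a depression trial in an urban Chinese setting, with gently
#' declining use over follow-up.
#'
#' @param n_waves Number of assessment waves (costing periods).
#' @return Named list per component with matrices `p_use`, `meanlog`,
#'   `sdlog` (rows `intervention`, `control`; one column per period).
#' @export
default_cost_params <- function(n_waves = 5L) {
  mk <- function(int, ctl) {
    m <- rbind(intervention = rep_len(int, n_waves),
               control = rep_len(ctl, n_waves))
    colnames(m) <- paste0("p", seq_len(n_waves) - 1L)
    m
  }
  # conditional (user-only) means on the natural scale
  cm <- function(x, sdlog) log(x) - sdlog^2 / 2
  list(
    drug = list(
      p_use = mk(c(0.525, 0.131, 0.120, 0.110, 0.100),
                 c(0.533, 0.189, 0.180, 0.170, 0.160)),
      meanlog = mk(cm(c(11203, 17418, 15676, 14805, 13934), 1.5),
                   cm(c(9116, 7073, 6366, 6012, 5658), 1.5)),
      sdlog = mk(1.5, 1.5)
    ),
    treatment = list(
      p_use = mk(c(0.098, 0.016, 0.015, 0.015, 0.014),
                 c(0.074, 0.016, 0.015, 0.015, 0.014)),
      meanlog = mk(cm(c(1833, 5806, 5225, 4935, 4645), 1.2),
                   cm(c(3326, 1344, 1210, 1142, 1075), 1.2)),
      sdlog = mk(1.2, 1.2)
    ),
    diagnostic = list(
      p_use = mk(c(0.525, 0.082, 0.080, 0.078, 0.075),
                 c(0.574, 0.115, 0.110, 0.105, 0.100)),
      meanlog = mk(cm(c(1005, 568, 511, 483, 454), 1.0),
                   cm(c(1319, 508, 457, 432, 406), 1.0)),
      sdlog = mk(1.0, 1.0)
    )
  )
}

#' Configuration of the synthetic trial generator
#'
#' Defaults reproduce the design of the motivating trial: 244 participants
#' allocated 1:1, five assessment waves, arm-wise utility means around
#' 0.52-0.62 with SD 0.22, zero-inflated lognormal cost components,
#' productivity-day rates that dominate total costs, monotone dropout with a
#' heavier first-wave hazard in the intervention arm (completion about 73%
#' vs 94.3%), and control follow-up truncated after the post-treatment wave.
#'
#' @param n_total Number of participants (at least 2).
#' @param allocation_ratio Integer pair `(intervention, control)`.
#' @param times Assessment times in years (see [time_grid()]).
#' @param utility_means Matrix (rows `intervention`, `control`) of per-wave
#'   utility means, all at most 1.
#' @param utility_sd Common utility SD (noise clamped to
#'   `[utility_floor, 1]`).
#' @param utility_floor Lower clamp of the utility scale (worse than death
#'   allowed down to this value).
#' @param utility_person_share Share of utility variance attributed to a
#'   persistent person effect (drives within-person correlation over waves).
#' @param cost_params Per-component zero-inflated lognormal parameters, see
#'   [default_cost_params()].
#' @param cost_person_share Share of log-cost variance from a persistent
#'   person effect.
#' @param lost_rate,reduced_rate Matrices (rows `intervention`, `control`) of
#'   expected lost / reduced productivity days per week, per period.
#' @param productivity_person_sd SD of the person-level logit shift of the
#'   daily productivity-loss probability.
#' @param dropout_hazard Matrix (rows `intervention`, `control`) of per-wave
#'   dropout probabilities for waves 1..K-1, or `NULL` for no dropout.
#' @param dropout_coefficients Optional named numeric vector of logit
#'   coefficients on observed quantities (`age`, `gender_male`,
#'   `antidepressant_use`, `prev_utility`) making dropout covariate-dependent
#'   while remaining missing at random.
#' @param control_truncation_wave Last control-arm wave with data (0-based);
#'   later control waves are structurally missing. `NULL` disables
#'   truncation.
#' @param cost_utility_correlation Correlation between the person-level
#'   utility and cost factors (the trial does not report this; default 0).
#' @param seed Integer master seed; the panel is a deterministic function of
#'   the configuration including the seed.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_total = 244L,
                         allocation_ratio = c(1L, 1L),
                         times = c(0, 0.25, 0.50, 0.75, 1.25),
                         utility_means = rbind(
                           intervention = c(0.5190, 0.6002, 0.6057, 0.6240,
                                            0.6146),
                           control = c(0.5625, 0.6012, 0.6067, 0.6250,
                                       0.6156)),
                         utility_sd = 0.22,
                         utility_floor = -0.3,
                         utility_person_share = 0.6,
                         cost_params = default_cost_params(length(times)),
                         cost_person_share = 0.4,
                         lost_rate = rbind(
                           intervention = c(1.5, 1.0, 0.9, 0.8, 0.7),
                           control = c(1.3, 0.75, 0.70, 0.65, 0.60)),
                         reduced_rate = rbind(
                           intervention = c(5.0, 3.5, 3.2, 3.0, 2.8),
                           control = c(4.3, 2.6, 2.4, 2.2, 2.0)),
                         productivity_person_sd = 0.5,
                         dropout_hazard = rbind(
                           intervention = c(0.270, 0.0233, 0.0224, 0.0359),
                           control = c(0.057, 0.020, 0.020, 0.030)),
                         dropout_coefficients = NULL,
                         control_truncation_wave = 1L,
                         cost_utility_correlation = 0,
                         seed = 1L) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 2) {
    stop("`n_total` must be a single count of at least 2", call. = FALSE)
  }
  if (length(allocation_ratio) != 2L || any(allocation_ratio < 1) ||
      any(allocation_ratio != round(allocation_ratio))) {
    stop("`allocation_ratio` must be a pair of positive integers",
         call. = FALSE)
  }
  grid <- time_grid(times)
  k <- length(times)
  chk_mat <- function(m, name, ncols = k) {
    if (!is.matrix(m) || nrow(m) != 2L || ncol(m) != ncols ||
        !all(c("intervention", "control") %in% rownames(m))) {
      stop(sprintf(
        "`%s` must be a 2 x %d matrix with rows 'intervention' and 'control'",
        name, ncols), call. = FALSE)
    }
  }
  chk_mat(utility_means, "utility_means")
  if (any(utility_means > 1)) stop("utility means must not exceed 1",
                                   call. = FALSE)
  assert_nonneg(utility_sd, "utility_sd")
  assert_prob(utility_person_share, "utility_person_share")
  assert_prob(cost_person_share, "cost_person_share")
  for (comp in names(cost_params)) {
    for (f in c("p_use", "meanlog", "sdlog")) {
      chk_mat(cost_params[[comp]][[f]], paste0(comp, "$", f))
    }
    assert_prob(cost_params[[comp]]$p_use, paste0(comp, "$p_use"))
  }
  chk_mat(lost_rate, "lost_rate"); chk_mat(reduced_rate, "reduced_rate")
  assert_nonneg(lost_rate, "lost_rate")
  assert_nonneg(reduced_rate, "reduced_rate")
  if (!is.null(dropout_hazard)) {
    chk_mat(dropout_hazard, "dropout_hazard", ncols = k - 1L)
    assert_prob(dropout_hazard, "dropout_hazard")
  }
  if (!is.null(control_truncation_wave) &&
      (control_truncation_wave < 1L || control_truncation_wave > k - 1L)) {
    stop("`control_truncation_wave` must name a post-baseline wave",
         call. = FALSE)
  }
  assert_number(cost_utility_correlation, "cost_utility_correlation",
                lower = -1, upper = 1)
  structure(list(
    n_total = as.integer(n_total),
    allocation_ratio = as.integer(allocation_ratio),
    grid = grid,
    utility_means = utility_means,
    utility_sd = utility_sd,
    utility_floor = utility_floor,
    utility_person_share = utility_person_share,
    cost_params = cost_params,
    cost_person_share = cost_person_share,
    lost_rate = lost_rate,
    reduced_rate = reduced_rate,
    productivity_person_sd = productivity_person_sd,
    dropout_hazard = dropout_hazard,
    dropout_coefficients = dropout_coefficients,
    control_truncation_wave = control_truncation_wave,
    cost_utility_correlation = cost_utility_correlation,
    seed = as.integer(seed)
  ), class = "trial_config")
}

#' Randomize participants to trial arms
#'
#' Permuted-block randomization at the given allocation ratio: complete
#' blocks of size `sum(allocation_ratio)` realize the ratio exactly; a final
#' incomplete block assigns the remainder in seed-determined order, keeping
#' arm sizes within one of the exact ratio.
#'
#' @param n_total Number of participants (positive).
#' @param allocation_ratio Integer pair `(intervention, control)`.
#' @param seed Integer seed; the assignment is a deterministic function of
#'   it.
#' @return Character vector of `"intervention"` / `"control"` of length
#'   `n_total`.
#' @examples
#' table(randomize(244, c(1, 1), seed = 1))  # 122 / 122
#' @export
randomize <- function(n_total, allocation_ratio = c(1L, 1L), seed = 1L) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total <= 0 ||
      n_total != round(n_total)) {
    stop("`n_total` must be a positive integer", call. = FALSE)
  }
  if (any(allocation_ratio < 1) ||
      any(allocation_ratio != round(allocation_ratio))) {
    stop("allocation parts must be positive integers", call. = FALSE)
  }
  block <- rep(c("intervention", "control"), times = allocation_ratio)
  n_blocks <- ceiling(n_total / length(block))
  set.seed(as.integer(seed))
  arms <- unlist(lapply(seq_len(n_blocks), function(b) sample(block)))
  arms[seq_len(n_total)]
}

#' Simulate a synthetic two-arm trial panel
#'
#' Generates a complete [trial_panel()] under the configuration, then (by
#' default) applies the configured dropout process and structural control
#' truncation. Identical configurations (including the seed) yield identical
#' panels.
#'
#' @param config A [trial_config()].
#' @param apply_dropout Apply the configured dropout hazards (via
#'   [impose_missingness()]) before returning.
#' @return A [trial_panel()].
#' @export
simulate_trial <- function(config, apply_dropout = TRUE) {
  stopifnot(inherits(config, "trial_config"))
  n <- config$n_total
  k <- length(config$grid$times)
  period_weeks <- c(13, diff(config$grid$times) * 52)

  arm <- randomize(n, config$allocation_ratio, sub_seed(config$seed, 1L))

  set.seed(sub_seed(config$seed, 2L))
  age <- pmin(pmax(round(stats::rnorm(n, 28.3, 7.0)), 18), 60)
  gender <- ifelse(stats::runif(n) < 0.75, "female", "male")
  antidep <- stats::runif(n) < 0.48

  # person-level latent factors (utility, cost, productivity)
  set.seed(sub_seed(config$seed, 3L))
  z_u <- stats::rnorm(n)
  z_c_raw <- stats::rnorm(n)
  rho <- config$cost_utility_correlation
  z_c <- rho * z_u + sqrt(1 - rho^2) * z_c_raw
  z_d <- stats::rnorm(n)

  sd_b <- config$utility_sd * sqrt(config$utility_person_share)
  sd_e <- config$utility_sd * sqrt(1 - config$utility_person_share)
  util <- matrix(NA_real_, n, k)
  for (t in seq_len(k)) {
    mu <- config$utility_means[arm, t]
    util[, t] <- pmin(pmax(mu + sd_b * z_u + stats::rnorm(n, 0, sd_e),
                           config$utility_floor), 1)
  }

  set.seed(sub_seed(config$seed, 4L))
  comp_vals <- list()
  cshare <- config$cost_person_share
  for (comp in names(config$cost_params)) {
    pr <- config$cost_params[[comp]]
    m <- matrix(0, n, k)
    for (t in seq_len(k)) {
      use <- stats::runif(n) < pr$p_use[arm, t]
      eps <- sqrt(cshare) * z_c + sqrt(1 - cshare) * stats::rnorm(n)
      m[, t] <- ifelse(use,
                       exp(pr$meanlog[arm, t] + pr$sdlog[arm, t] * eps), 0)
    }
    comp_vals[[comp]] <- m
  }

  set.seed(sub_seed(config$seed, 5L))
  lost <- matrix(0, n, k); reduced <- matrix(0, n, k)
  shift <- config$productivity_person_sd * z_d
  for (t in seq_len(k)) {
    days_t <- round(7 * period_weeks[t])
    p_lost <- stats::plogis(stats::qlogis(
      pmin(pmax(config$lost_rate[arm, t] / 7, 1e-8), 1 - 1e-8)) + shift)
    p_red <- stats::plogis(stats::qlogis(
      pmin(pmax(config$reduced_rate[arm, t] / 7, 1e-8), 1 - 1e-8)) + shift)
    lost[, t] <- stats::rbinom(n, days_t, p_lost)
    reduced[, t] <- stats::rbinom(n, days_t, p_red)
  }

  participants <- data.frame(
    participant_id = seq_len(n), arm = arm, age = age, gender = gender,
    antidepressant_use = antidep, stringsAsFactors = FALSE)
  waves <- data.frame(
    participant_id = rep(seq_len(n), each = k),
    wave = rep(seq_len(k) - 1L, times = n),
    time = rep(config$grid$times, times = n),
    utility = as.vector(t(util)),
    drug = as.vector(t(comp_vals$drug)),
    treatment = as.vector(t(comp_vals$treatment)),
    diagnostic = as.vector(t(comp_vals$diagnostic)),
    lost_days = as.vector(t(lost)),
    reduced_days = as.vector(t(reduced)),
    observed = TRUE, structural = FALSE, stringsAsFactors = FALSE)

  tw <- config$control_truncation_wave
  if (!is.null(tw)) {
    ctl <- participants$participant_id[participants$arm == "control"]
    idx <- waves$participant_id %in% ctl & waves$wave > tw
    waves$structural[idx] <- TRUE
    waves$observed[idx] <- FALSE
    waves[idx, c("utility", "drug", "treatment", "diagnostic",
                 "lost_days", "reduced_days")] <- NA
  }

  panel <- trial_panel(participants, waves, config$grid)
  if (apply_dropout && !is.null(config$dropout_hazard)) {
    panel <- impose_missingness(panel, config$dropout_hazard,
                                config$dropout_coefficients,
                                seed = sub_seed(config$seed, 6L))
  }
  panel
}

#' Impose monotone missing-at-random dropout on a panel
#'
#' Applies a discrete-time dropout process: at each post-baseline wave, each
#' still-observed participant drops out with a probability given by the
#' arm- and wave-specific hazard, optionally shifted on the logit scale by
#' observed covariates and the previous wave's utility. Once a participant
#' drops out, all later waves are missing. Because the hazard depends only on
#' observed quantities, the mechanism is missing at random by construction.
#' Structurally missing control waves are unaffected.
#'
#' @param panel A [trial_panel()].
#' @param dropout_hazard Matrix (rows `intervention`, `control`) of hazards
#'   in `[0, 1]` for waves 1..K-1.
#' @param covariate_coefficients Optional named numeric vector (names among
#'   `age`, `gender_male`, `antidepressant_use`, `prev_utility`) of logit
#'   coefficients; covariates are centred so the marginal hazard stays near
#'   the configured value.
#' @param seed Integer seed.
#' @return The panel with dropout applied.
#' @export
impose_missingness <- function(panel, dropout_hazard,
                               covariate_coefficients = NULL, seed = 1L) {
  stopifnot(inherits(panel, "trial_panel"))
  assert_prob(dropout_hazard, "dropout_hazard")
  k <- length(panel$grid$times)
  if (!is.matrix(dropout_hazard) || ncol(dropout_hazard) != k - 1L) {
    stop("`dropout_hazard` needs one column per post-baseline wave",
         call. = FALSE)
  }
  p <- panel$participants
  w <- panel$waves
  n <- nrow(p)
  util <- matrix(w$utility[order(w$participant_id, w$wave)], n, k,
                 byrow = TRUE)
  covs <- cbind(age = p$age, gender_male = as.numeric(p$gender == "male"),
                antidepressant_use = as.numeric(p$antidepressant_use))
  covs <- sweep(covs, 2, colMeans(covs))
  set.seed(as.integer(seed))
  dropped <- rep(FALSE, n)
  miss <- matrix(FALSE, n, k)
  for (t in seq_len(k - 1L)) {
    h <- dropout_hazard[p$arm, t]
    eta <- stats::qlogis(pmin(pmax(h, 0), 1))
    if (!is.null(covariate_coefficients)) {
      cc <- covariate_coefficients
      for (nm in intersect(names(cc), colnames(covs))) {
        eta <- eta + cc[[nm]] * covs[, nm]
      }
      if ("prev_utility" %in% names(cc)) {
        prev <- util[, t]
        prev[is.na(prev)] <- mean(prev, na.rm = TRUE)
        eta <- eta + cc[["prev_utility"]] * (prev - mean(prev))
      }
    }
    drop_now <- !dropped & (stats::runif(n) < stats::plogis(eta))
    dropped <- dropped | drop_now
    miss[dropped, t + 1L] <- TRUE
  }
  ord_key <- (match(w$participant_id, p$participant_id) - 1L) * k + w$wave + 1L
  miss_long <- as.vector(t(miss))[ord_key]
  idx <- miss_long & !w$structural
  w$observed[idx] <- FALSE
  w[idx, c("utility", "drug", "treatment", "diagnostic", "lost_days",
           "reduced_days")] <- NA
  trial_panel(p, w, panel$grid)
}
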