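# Shared fixtures, all built in code.

fixture_wage <- wage_model(10000)

# A small, fast trial configuration on the default 5-wave grid.
small_config <- function(n = 60, seed = 1, ...) {
  trial_config(n_total = n, seed = seed, ...)
}

# Two-wave configuration used by recovery simulations: baseline and one
# post-treatment assessment, no structural truncation, moderate noise.
# `delta_u1` shifts the intervention arm's post-treatment utility mean and
# `cost_factor_int` scales the intervention arm's cost level.
twowave_config <- function(n = 244, seed = 1,
                           mu0 = 0.55, delta_u1 = 0, u1_gain = 0.05,
                           utility_sd = 0.2, person_share = 0.7,
                           cost_mean_ctl = 2000, cost_mean_int = NULL,
                           sdlog = 0.5,
                           dropout = 0, ...) {
  if (is.null(cost_mean_int)) cost_mean_int <- cost_mean_ctl
  mk <- function(int, ctl) rbind(intervention = int, control = ctl)
  cm <- function(x, s) log(x) - s^2 / 2
  cost_params <- list(
    drug = list(p_use = mk(c(1, 1), c(1, 1)),
                meanlog = mk(cm(c(cost_mean_ctl, cost_mean_int), sdlog),
                             cm(c(cost_mean_ctl, cost_mean_ctl), sdlog)),
                sdlog = mk(c(sdlog, sdlog), c(sdlog, sdlog))),
    treatment = list(p_use = mk(c(0, 0), c(0, 0)),
                     meanlog = mk(c(0, 0), c(0, 0)),
                     sdlog = mk(c(1, 1), c(1, 1))),
    diagnostic = list(p_use = mk(c(0, 0), c(0, 0)),
                      meanlog = mk(c(0, 0), c(0, 0)),
                      sdlog = mk(c(1, 1), c(1, 1)))
  )
  trial_config(
    n_total = n, times = c(0, 0.25),
    utility_means = mk(c(mu0, mu0 + u1_gain + delta_u1),
                       c(mu0, mu0 + u1_gain)),
    utility_sd = utility_sd, utility_person_share = person_share,
    cost_params = cost_params,
    lost_rate = mk(c(1, 1), c(1, 1)),
    reduced_rate = mk(c(2, 2), c(2, 2)),
    productivity_person_sd = 0.3,
    dropout_hazard = mk(dropout, dropout),
    control_truncation_wave = NULL,
    seed = seed, ...)
}

# Complete per-participant analysis data with known treatment effects, for
# exercising the SUR and bootstrap machinery directly.
make_analysis_data <- function(n = 244, delta_cost = 0, delta_qaly = 0,
                               sd_cost = 500, sd_qaly = 0.01, rho = 0.3,
                               seed = 1) {
  set.seed(seed)
  treatment <- rep(c(1, 0), length.out = n)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  baseline_cost <- rlnorm(n, log(2000), 0.5)
  baseline_utility <- pmin(rnorm(n, 0.55, 0.2), 1)
  data.frame(
    participant_id = seq_len(n),
    treatment = treatment,
    age = round(runif(n, 18, 60)),
    gender_male = rbinom(n, 1, 0.25),
    antidepressant_use = rbinom(n, 1, 0.5),
    baseline_cost = baseline_cost,
    baseline_utility = baseline_utility,
    total_cost = 2000 + 0.5 * baseline_cost + delta_cost * treatment +
      sd_cost * z1,
    qaly = 0.14 + 0.1 * baseline_utility + delta_qaly * treatment +
      sd_qaly * z2
  )
}

# Construct a draw set with the given counts per quadrant.
make_draws <- function(n_se, n_sw, n_ne, n_nw) {
  data.frame(
    delta_qaly = c(rep(1, n_se), rep(-1, n_sw), rep(1, n_ne), rep(-1, n_nw)),
    delta_cost = c(rep(-1, n_se), rep(-1, n_sw), rep(1, n_ne), rep(1, n_nw))
  )
}

# Wide-format frame builder for imputation/extrapolation unit tests.
make_wide <- function(df, times) {
  attr(df, "grid") <- time_grid(times)
  attr(df, "n_waves") <- length(times)
  df
}
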