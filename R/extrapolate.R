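# Scenario extrapolation: predict the control arm's post-truncation utility
# and cost trajectories from first-order autoregressive models fitted on the
# intervention arm only, so 3-, 6-, and 12-month scenario analyses are
# possible when control follow-up stops at the post-treatment wave.

traj_families <- c(utility = "u", direct = "dc", indirect = "ic")

#' Fit intervention-arm trajectory models
#'
#' For each outcome (utility, direct cost, indirect cost) and each
#' transition between consecutive waves from wave 2 onwards, fits a linear
#' model of the wave-t value on the wave-(t-1) value, the baseline value,
#' age, gender, and antidepressant use, using intervention-arm rows with
#' both waves available. These models encode the assumption that, absent
#' the truncation, control trajectories after the post-treatment wave would
#' follow the trend observed in the intervention arm.
#'
#' @param data A wide frame (internal layout) or [trial_panel()] with
#'   `wage`.
#' @param wage [wage_model()], required for a `trial_panel` input.
#' @param min_transitions Minimum complete transitions per model.
#' @return Object of class `trajectory_model`: per-outcome, per-wave
#'   coefficient vectors with residual SDs.
#' @export
fit_trajectory <- function(data, wage = NULL, min_transitions = 10L) {
  if (inherits(data, "trial_panel")) {
    if (is.null(wage)) stop("`wage` is required to value productivity days",
                            call. = FALSE)
    data <- panel_wide(data, wage)
  }
  k <- attr(data, "n_waves")
  if (is.null(k)) stop("`data` must be a wide panel frame", call. = FALSE)
  int <- data[data$treatment == 1, ]
  models <- list()
  for (out_name in names(traj_families)) {
    f <- traj_families[[out_name]]
    models[[out_name]] <- vector("list", k - 1L)
    for (t in 2:(k - 1L)) {
      y <- int[[paste0(f, t)]]
      X <- cbind(`(Intercept)` = 1,
                 prev = int[[paste0(f, t - 1L)]],
                 baseline = int[[paste0(f, 0L)]],
                 age = int$age,
                 gender_male = int$gender_male,
                 antidepressant_use = int$antidepressant_use)
      ok <- !is.na(y) & stats::complete.cases(X)
      if (sum(ok) < min_transitions) {
        stop(sprintf(
          "only %d complete %s transitions into wave %d (need >= %d)",
          sum(ok), out_name, t, min_transitions), call. = FALSE)
      }
      Xo <- X[ok, , drop = FALSE]
      qx <- qr(Xo)
      beta <- qr.coef(qx, y[ok])
      beta[is.na(beta)] <- 0  # aliased columns contribute nothing
      res <- y[ok] - as.numeric(Xo %*% beta)
      dfres <- max(sum(ok) - qx$rank, 1L)
      models[[out_name]][[t]] <- list(
        coef = beta, sigma = sqrt(sum(res^2) / dfres), n = sum(ok))
    }
  }
  structure(list(models = models, n_waves = k), class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf(
    "Trajectory model: %d outcomes x %d transitions (intervention-arm AR(1) regressions)\n",
    length(x$models), x$n_waves - 2L))
  invisible(x)
}

#' Extrapolate the control arm beyond its truncation wave
#'
#' Recursively fills structurally missing control-arm cells from wave 2 up
#' to the horizon with one-step mean predictions from the intervention-arm
#' trajectory models (individual-level recursion: each participant's own
#' previous value feeds the next prediction). Observed cells are never
#' overwritten, structurally flagged cells are always recomputed (so
#' whatever may sit in them is never read), predicted utilities are clamped
#' at 1, and predicted costs at 0. With `stochastic = TRUE` a residual draw
#' is added at each step.
#'
#' @param data Wide frame (internal layout) or [trial_panel()] with `wage`.
#' @param model A [fit_trajectory()] model.
#' @param horizon_wave Target wave index (0-based), at least 2.
#' @param stochastic Add residual noise to each prediction step.
#' @param seed Seed for the stochastic variant.
#' @param wage [wage_model()] for `trial_panel` input.
#' @param utility_cap Upper clamp for predicted utilities.
#' @return The wide frame with control cells filled; the per-cell provenance
#'   is recorded in the `provenance` attribute
#'   (`observed`/`imputed`/`extrapolated`/`missing`).
#' @export
extrapolate_control <- function(data, model, horizon_wave,
                                stochastic = FALSE, seed = NULL,
                                wage = NULL, utility_cap = 1) {
  if (inherits(data, "trial_panel")) {
    if (is.null(wage)) stop("`wage` is required to value productivity days",
                            call. = FALSE)
    data <- panel_wide(data, wage)
  }
  stopifnot(inherits(model, "trajectory_model"))
  k <- attr(data, "n_waves")
  if (horizon_wave < 2L || horizon_wave > k - 1L) {
    stop("`horizon_wave` must be a follow-up wave index (2 .. K-1)",
         call. = FALSE)
  }
  if (stochastic) {
    if (is.null(seed)) stop("stochastic extrapolation requires a seed",
                            call. = FALSE)
    set.seed(as.integer(seed))
  }
  ctl <- which(data$treatment != 1)
  for (t in 2:horizon_wave) {
    for (out_name in names(traj_families)) {
      f <- traj_families[[out_name]]
      col <- paste0(f, t)
      st <- data[[paste0("str", t)]]
      fill <- intersect(ctl, which(st))
      if (!length(fill)) next
      mt <- model$models[[out_name]][[t]]
      X <- cbind(1, data[[paste0(f, t - 1L)]][fill],
                 data[[paste0(f, 0L)]][fill], data$age[fill],
                 data$gender_male[fill], data$antidepressant_use[fill])
      pred <- as.numeric(X %*% mt$coef)
      if (stochastic) pred <- pred + stats::rnorm(length(pred), 0, mt$sigma)
      pred <- if (f == "u") pmin(pred, utility_cap) else pmax(pred, 0)
      vals <- data[[col]]
      vals[fill] <- pred
      data[[col]] <- vals
    }
  }
  # provenance flags per wave: observed / imputed-or-missing / extrapolated
  prov <- matrix("observed", nrow(data), k)
  for (t in seq_len(k) - 1L) {
    obs <- data[[paste0("obs", t)]]
    st <- data[[paste0("str", t)]]
    u <- data[[paste0("u", t)]]
    prov[!obs & !st & !is.na(u), t + 1L] <- "imputed"
    prov[!obs & !st & is.na(u), t + 1L] <- "missing"
    prov[st & !is.na(u), t + 1L] <- "extrapolated"
    prov[st & is.na(u), t + 1L] <- "missing"
  }
  colnames(prov) <- paste0("wave", seq_len(k) - 1L)
  attr(data, "provenance") <- prov
  data
}
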