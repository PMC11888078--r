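# Decision machinery: nonparametric stratified bootstrap of the incremental
# estimates, ICURs, cost-effectiveness plane classification, net monetary
# benefit, and cost-effectiveness acceptability curves.

#' Stratified nonparametric bootstrap of incremental cost and QALY
#'
#' Resamples participants with replacement within each arm (arm sizes are
#' preserved in every replicate), refits the joint cost/QALY model, and
#' records the incremental QALY and cost pair. Pairs are always kept
#' jointly. Replicates on which the model is inestimable are redrawn; if
#' more than `max_fail_frac` of the requested replicates fail, the bootstrap
#' aborts with a diagnostic.
#'
#' @param data Per-participant data frame containing a `treatment` column
#'   (1 = intervention) plus whatever `refit` needs.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; identical seeds give identical draw sets.
#' @param refit Function mapping a resampled data frame to
#'   `c(delta_qaly, delta_cost)`. Defaults to [fit_sur()] with `...` passed
#'   through.
#' @param identity If `TRUE`, the resample indices are forced to the
#'   original sample (exposes the seed/resampling contract for testing; with
#'   `B = 1` the single draw equals the point estimate).
#' @param max_fail_frac Maximum tolerated fraction of inestimable
#'   replicates.
#' @param ... Passed to [fit_sur()] when `refit` is `NULL`.
#' @return Object of class `bootstrap_draws`: data frame with columns
#'   `delta_qaly`, `delta_cost` and attributes `B`, `seed`, `n_failed`.
#' @export
bootstrap_ce <- function(data, B = 5000L, seed = 1L, refit = NULL,
                         identity = FALSE, max_fail_frac = 0.01, ...) {
  if (B < 1L) stop("`B` must be at least 1", call. = FALSE)
  if (!"treatment" %in% names(data)) {
    stop("`data` must contain a `treatment` column", call. = FALSE)
  }
  if (is.null(refit)) {
    refit <- function(d) {
      f <- fit_sur(d, ...)
      c(f$delta_qaly, f$delta_cost)
    }
  }
  idx_int <- which(data$treatment == 1)
  idx_ctl <- which(data$treatment != 1)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, B, 2L)
  n_failed <- 0L
  max_failed <- max(ceiling(max_fail_frac * B), 1L)
  b <- 1L
  while (b <= B) {
    rows <- if (identity) {
      seq_len(nrow(data))
    } else {
      c(sample(idx_int, length(idx_int), replace = TRUE),
        sample(idx_ctl, length(idx_ctl), replace = TRUE))
    }
    est <- tryCatch(refit(data[rows, , drop = FALSE]), error = function(e) e)
    if (inherits(est, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed > max_failed) {
        stop(sprintf(
          "bootstrap aborted: %d inestimable replicates (last error: %s)",
          n_failed, conditionMessage(est)), call. = FALSE)
      }
      next
    }
    draws[b, ] <- est
    b <- b + 1L
  }
  out <- data.frame(delta_qaly = draws[, 1L], delta_cost = draws[, 2L])
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "n_failed") <- n_failed
  class(out) <- c("bootstrap_draws", "data.frame")
  out
}

as_draws <- function(draws) {
  if (!all(c("delta_qaly", "delta_cost") %in% names(draws))) {
    stop("draws need `delta_qaly` and `delta_cost` columns", call. = FALSE)
  }
  draws
}

#' Incremental cost-utility ratio
#'
#' The ICUR is the incremental cost divided by the incremental QALY. The
#' ratio alone is ambiguous off the north-east quadrant, so the quadrant and
#' a dominance annotation are attached: south-east (cheaper, more effective)
#' is dominant, north-west (dearer, less effective) is dominated. A zero
#' incremental QALY yields a signed infinite sentinel with a warning.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALY
#'   (intervention minus control).
#' @return Object of class `icur` with `icur`, `quadrant`, `dominance`, and
#'   the inputs.
#' @examples
#' icur(-899.45, 0.0046)  # south-east: dominant
#' @export
icur <- function(delta_cost, delta_qaly) {
  quadrant <- plane_quadrant(delta_qaly, delta_cost)
  dominance <- switch(quadrant,
                      SE = "dominant", NW = "dominated", "none")
  ratio <- if (delta_qaly == 0) {
    warning("incremental QALY is zero: ICUR is a signed infinity",
            call. = FALSE)
    if (delta_cost == 0) 0 else sign(delta_cost) * Inf
  } else {
    delta_cost / delta_qaly
  }
  structure(list(icur = ratio, quadrant = quadrant, dominance = dominance,
                 delta_cost = delta_cost, delta_qaly = delta_qaly),
            class = "icur")
}

#' @export
print.icur <- function(x, ...) {
  cat(sprintf("ICUR: %.2f per QALY (quadrant %s%s)\n", x$icur, x$quadrant,
              if (x$dominance != "none") paste0(", ", x$dominance) else ""))
  invisible(x)
}

# Quadrant with the documented tie rule: boundary draws (delta = 0) are
# assigned to the positive side.
plane_quadrant <- function(delta_qaly, delta_cost) {
  east <- delta_qaly >= 0
  north <- delta_cost >= 0
  ifelse(east & north, "NE",
         ifelse(east & !north, "SE",
                ifelse(!east & north, "NW", "SW")))
}

#' Classify bootstrap draws on the cost-effectiveness plane
#'
#' Assigns each (incremental QALY, incremental cost) draw to a quadrant of
#' the cost-effectiveness plane and reports quadrant proportions as
#' percentages, with the south (cost-saving) and east (more effective)
#' aggregates as exact sums. Boundary draws are assigned to the positive
#' side.
#'
#' @param draws A [bootstrap_ce()] result or data frame with `delta_qaly`
#'   and `delta_cost`.
#' @return Object of class `plane_summary`: named list of percentages `ne`,
#'   `nw`, `se`, `sw`, `south`, `east`, plus the draw count `n`.
#' @export
classify_plane <- function(draws) {
  draws <- as_draws(draws)
  n <- nrow(draws)
  if (n == 0L) stop("`draws` must be nonempty", call. = FALSE)
  q <- plane_quadrant(draws$delta_qaly, draws$delta_cost)
  pct <- function(lbl) 100 * sum(q == lbl) / n
  out <- list(ne = pct("NE"), nw = pct("NW"), se = pct("SE"), sw = pct("SW"))
  out$south <- out$se + out$sw
  out$east <- out$se + out$ne
  out$n <- n
  class(out) <- "plane_summary"
  out
}

#' @export
print.plane_summary <- function(x, ...) {
  cat(sprintf(
    "CE plane (%d draws): SE %.2f%%, SW %.2f%%, NE %.2f%%, NW %.2f%% (south %.2f%%, east %.2f%%)\n",
    x$n, x$se, x$sw, x$ne, x$nw, x$south, x$east))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = threshold * delta_qaly - delta_cost`; the intervention is
#' cost-effective at the threshold iff the NMB is positive.
#'
#' @param delta_qaly,delta_cost Incremental QALY and cost.
#' @param threshold Willingness-to-pay per QALY (non-negative).
#' @return NMB in currency.
#' @export
nmb <- function(delta_qaly, delta_cost, threshold) {
  assert_nonneg(threshold, "threshold")
  threshold * delta_qaly - delta_cost
}

#' Willingness-to-pay grid
#'
#' Thresholds are multiples of the per-capita gross domestic product, the
#' anchoring recommended by the national costing guideline (base case 1.5x,
#' range 1-3x), plus a dense display grid for acceptability curves.
#'
#' @param gdp_per_capita Per-capita GDP in the analysis currency (positive).
#' @param multipliers Increasing positive multipliers.
#' @param display_points Number of evenly spaced display thresholds from 0
#'   to the largest multiple.
#' @return Object of class `wtp_grid` with `thresholds` (named by
#'   multiplier) and `display_thresholds`.
#' @examples
#' wtp_grid(80976)$thresholds  # 80976, 121464, 242928
#' @export
wtp_grid <- function(gdp_per_capita, multipliers = c(1, 1.5, 3),
                     display_points = 200L) {
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0) {
    stop("`gdp_per_capita` must be positive", call. = FALSE)
  }
  if (any(multipliers <= 0) || any(diff(multipliers) <= 0)) {
    stop("`multipliers` must be positive and increasing", call. = FALSE)
  }
  thresholds <- gdp_per_capita * multipliers
  structure(list(
    gdp_per_capita = gdp_per_capita,
    multipliers = multipliers,
    thresholds = stats::setNames(thresholds, paste0(multipliers, "x")),
    display_thresholds = seq(0, max(thresholds), length.out = display_points)
  ), class = "wtp_grid")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of bootstrap draws with a
#' positive net monetary benefit. At threshold 0 this equals the probability
#' of a cost saving; as the threshold grows it tends to the probability of a
#' QALY gain.
#'
#' @param draws Bootstrap draws (see [bootstrap_ce()]).
#' @param thresholds Numeric thresholds, or a [wtp_grid()] (its display grid
#'   is used).
#' @return Data frame with `threshold` and `probability`.
#' @export
ceac <- function(draws, thresholds) {
  draws <- as_draws(draws)
  if (nrow(draws) == 0L) stop("`draws` must be nonempty", call. = FALSE)
  if (inherits(thresholds, "wtp_grid")) {
    thresholds <- thresholds$display_thresholds
  }
  prob <- vapply(thresholds, function(lam) {
    mean(nmb(draws$delta_qaly, draws$delta_cost, lam) > 0)
  }, numeric(1L))
  data.frame(threshold = thresholds, probability = prob)
}

#' Percentile confidence interval for the ICUR
#'
#' Computes the draw-wise ICURs and their percentile interval (R's default
#' type-7 quantiles). Ratio intervals are only interpretable when all draws
#' fall in a single quadrant; when the draws mix quadrants (in particular
#' when the incremental QALY changes sign) a warning is raised and the
#' result is flagged, with net-monetary-benefit reporting preferred.
#'
#' @param draws Bootstrap draws.
#' @param level Confidence level.
#' @param method Currently `"percentile"`.
#' @return List with `lower`, `upper`, `level`, `method`, and
#'   `mixed_quadrants`.
#' @export
icur_ci <- function(draws, level = 0.95, method = "percentile") {
  method <- match.arg(method, "percentile")
  draws <- as_draws(draws)
  if (nrow(draws) == 0L) stop("`draws` must be nonempty", call. = FALSE)
  q <- plane_quadrant(draws$delta_qaly, draws$delta_cost)
  mixed <- length(unique(q)) > 1L
  if (mixed) {
    warning(paste("draws span multiple cost-effectiveness quadrants;",
                  "ratio confidence intervals are not interpretable -",
                  "prefer net-monetary-benefit reporting"), call. = FALSE)
  }
  if (any(draws$delta_qaly == 0)) {
    warning("draws with zero incremental QALY produce infinite ratios",
            call. = FALSE)
  }
  ratios <- draws$delta_cost / draws$delta_qaly
  alpha <- 1 - level
  qs <- stats::quantile(ratios, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  list(lower = qs[1L], upper = qs[2L], level = level, method = method,
       mixed_quadrants = mixed)
}
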