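# Health outcomes: SF-6D utilities and QALYs by the area-under-the-curve rule.

#' Assessment time grid
#'
#' Defines the assessment schedule of the trial in years since randomization.
#' The default grid places the baseline at 0 and subsequent assessments at the
#' boundaries of the costing periods (3, 6, 9 and 15 months are not used;
#' the default follows the four post-randomization periods of 3, 3, 3 and 6
#' months, i.e. 0.25, 0.50, 0.75 and 1.25 years). An alternative grid with the
#' first assessment at week 8 (`8/52` years) can be supplied for sensitivity
#' analyses.
#'
#' @param times Strictly increasing non-negative times in years; the first
#'   element must be 0 (baseline).
#' @param labels Labels for the assessment waves; defaults to `T0`, `T1`, ...
#' @return An object of class `cua_time_grid` with elements `times` and
#'   `labels`.
#' @examples
#' time_grid()
#' time_grid(times = c(0, 8 / 52, 0.5, 0.75, 1.25))
#' @export
time_grid <- function(times = c(0, 0.25, 0.50, 0.75, 1.25),
                      labels = paste0("T", seq_along(times) - 1L)) {
  if (!is.numeric(times) || length(times) < 2L) {
    stop("`times` must be a numeric vector with at least two assessments",
         call. = FALSE)
  }
  if (times[1L] != 0) stop("the first assessment time must be 0 (baseline)",
                           call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  if (length(labels) != length(times)) {
    stop("`labels` must have one entry per assessment time", call. = FALSE)
  }
  structure(list(times = as.numeric(times), labels = as.character(labels)),
            class = "cua_time_grid")
}

#' @export
print.cua_time_grid <- function(x, ...) {
  cat("Assessment grid (years):\n")
  print(stats::setNames(x$times, x$labels))
  invisible(x)
}

#' QALYs by the area-under-the-curve rule
#'
#' Integrates a piecewise-linear utility path over the assessment grid by the
#' trapezoidal rule. A constant utility `u` over a span of `T` years yields
#' exactly `u * T` QALYs, and the QALY accrued to an intermediate horizon
#' equals the integral over the corresponding grid prefix.
#'
#' @param utilities Numeric vector (one participant) or matrix (participants
#'   in rows) of utilities, one column per grid time. Missing utilities are an
#'   error: imputation or extrapolation must happen upstream.
#' @param grid A [time_grid()].
#' @param horizon Optional label (e.g. `"T1"`) or time in years; the
#'   integration is restricted to grid times `<= horizon`.
#' @return QALYs in years, one value per participant.
#' @examples
#' g <- time_grid()
#' qaly_auc(rep(1, 5), g)                      # 1.25 years in full health
#' qaly_auc(c(0.5190, 0.6002), time_grid(c(0, 0.25)))
#' @export
qaly_auc <- function(utilities, grid, horizon = NULL) {
  stopifnot(inherits(grid, "cua_time_grid"))
  u <- if (is.matrix(utilities)) utilities else matrix(utilities, nrow = 1L)
  times <- grid$times
  if (ncol(u) != length(times)) {
    stop("`utilities` must have one value per grid time", call. = FALSE)
  }
  if (!is.null(horizon)) {
    h <- if (is.character(horizon)) {
      idx <- match(horizon, grid$labels)
      if (is.na(idx)) stop("unknown horizon label: ", horizon, call. = FALSE)
      times[idx]
    } else {
      as.numeric(horizon)
    }
    keep <- times <= h + 1e-12
    if (sum(keep) < 2L) stop("horizon must include at least one interval",
                             call. = FALSE)
    u <- u[, keep, drop = FALSE]
    times <- times[keep]
  }
  if (anyNA(u)) {
    stop("missing utilities at grid points; impute or extrapolate upstream",
         call. = FALSE)
  }
  dt <- diff(times)
  mid <- (u[, -ncol(u), drop = FALSE] + u[, -1L, drop = FALSE]) / 2
  q <- as.numeric(mid %*% dt)
  if (!is.matrix(utilities)) q else stats::setNames(q, rownames(utilities))
}

sf6d_dimensions <- c("physical_functioning", "role_limitation",
                     "social_functioning", "pain", "mental_health", "vitality")

#' Toy additive SF-6D tariff
#'
#' A documented additive tariff for the six SF-6D dimensions (physical
#' functioning, role limitation, social functioning, pain, mental health,
#' vitality): full health (all dimensions at level 1) maps to utility 1 and
#' each step of severity subtracts a constant decrement. It anchors the scale
#' for testing and examples; a country-specific value set should be loaded
#' with [read_tariff()] for real analyses.
#'
#' @param n_levels Number of severity levels per dimension.
#' @param step Utility decrement per severity step.
#' @return A data frame with columns `dimension`, `level`, `decrement`.
#' @export
toy_tariff <- function(n_levels = 5L, step = 0.05) {
  assert_nonneg(step, "step")
  data.frame(
    dimension = rep(sf6d_dimensions, each = n_levels),
    level = rep(seq_len(n_levels), times = length(sf6d_dimensions)),
    decrement = rep(step * (seq_len(n_levels) - 1L),
                    times = length(sf6d_dimensions)),
    stringsAsFactors = FALSE
  )
}

#' Read a tariff coefficient file
#'
#' @param path Delimited file with columns `dimension`, `level`, `decrement`.
#' @param sep Field separator.
#' @return Tariff data frame as used by [utility_from_sf6d()].
#' @export
read_tariff <- function(path, sep = ",") {
  tf <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(tf))) {
    stop("tariff file must have columns dimension, level, decrement",
         call. = FALSE)
  }
  tf
}

#' Convert an SF-6D health state to a utility
#'
#' Applies an additive tariff: utility = 1 minus the sum of the per-dimension
#' decrements for the reported levels. The best health state maps to exactly
#' 1; severe states may map below 0 (worse than death).
#'
#' @param levels Named vector or list giving the level code for each of the
#'   six SF-6D dimensions.
#' @param tariff Tariff data frame (`dimension`, `level`, `decrement`), e.g.
#'   from [toy_tariff()] or [read_tariff()].
#' @return Utility value, at most 1.
#' @examples
#' best <- stats::setNames(rep(1, 6), unique(toy_tariff()$dimension))
#' utility_from_sf6d(best)  # 1
#' @export
utility_from_sf6d <- function(levels, tariff = toy_tariff()) {
  levels <- unlist(levels)
  dims <- unique(tariff$dimension)
  missing_dims <- setdiff(dims, names(levels))
  if (length(missing_dims)) {
    stop("missing level for dimension(s): ",
         paste(missing_dims, collapse = ", "), call. = FALSE)
  }
  dec <- 0
  for (d in dims) {
    lv <- levels[[d]]
    row <- tariff$dimension == d & tariff$level == lv
    if (!any(row)) {
      stop(sprintf("unknown level '%s' for dimension '%s'", lv, d),
           call. = FALSE)
    }
    dec <- dec + tariff$decrement[row][1L]
  }
  1 - dec
}

#' Compare an outcome between trial arms
#'
#' Reports the between-arm difference (intervention minus control) with the
#' test appropriate to the declared variable kind: Welch two-sample t test for
#' approximately normal outcomes, Mann-Whitney U for skewed outcomes such as
#' costs, chi-square for categorical variables.
#'
#' @param intervention,control Outcome values (numeric, or factor/character
#'   for `test = "chi-square"`) for each arm.
#' @param test One of `"t"`, `"mann-whitney"`, `"chi-square"`.
#' @return List with `difference` (intervention minus control, `NA` for the
#'   chi-square test), `statistic`, `p.value`, and `method`.
#' @export
group_compare <- function(intervention, control,
                          test = c("t", "mann-whitney", "chi-square")) {
  test <- match.arg(test)
  if (length(intervention) == 0L || length(control) == 0L) {
    stop("both arms must contain observations", call. = FALSE)
  }
  if (test == "chi-square") {
    arm <- rep(c("intervention", "control"),
               c(length(intervention), length(control)))
    tab <- table(arm, c(as.character(intervention), as.character(control)))
    ct <- suppressWarnings(stats::chisq.test(tab))
    return(list(difference = NA_real_, statistic = unname(ct$statistic),
                p.value = ct$p.value, method = ct$method))
  }
  if (length(intervention) < 2L || length(control) < 2L) {
    stop("variance-based tests need at least two observations per arm",
         call. = FALSE)
  }
  diff <- mean(intervention) - mean(control)
  if (test == "t") {
    if (stats::sd(intervention) == 0 && stats::sd(control) == 0) {
      # degenerate case: identical constants in both arms
      return(list(difference = diff, statistic = 0,
                  p.value = if (diff == 0) 1 else 0,
                  method = "Two-sample t test (degenerate)"))
    }
    tt <- stats::t.test(intervention, control)
    list(difference = diff, statistic = unname(tt$statistic),
         p.value = tt$p.value, method = tt$method)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(intervention, control, exact = FALSE)
    )
    list(difference = diff, statistic = unname(wt$statistic),
         p.value = wt$p.value, method = wt$method)
  }
}
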