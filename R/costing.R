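# Costing: bottom-up direct medical costs and human-capital productivity
# costs, aggregated to perspective-specific totals.

#' Wage model for human-capital productivity costing
#'
#' Productivity losses are valued by the human capital approach: a day of
#' absenteeism (lost productivity) costs one daily wage, and a day of
#' presenteeism (reduced productivity) costs a fraction of a daily wage. The
#' daily wage is the monthly wage divided by the number of working days per
#' month. The default presenteeism weight of 0.4298 follows the weighting
#' coefficient established for mental-health populations.
#'
#' There is deliberately no default monthly wage: it is a locale- and
#' year-specific input that the analyst must supply.
#'
#' @param monthly_wage Gross monthly wage in the analysis currency.
#' @param working_days_per_month Divisor converting the monthly to a daily
#'   wage (default 21.75).
#' @param presenteeism_weight Fraction of a daily wage lost per
#'   reduced-productivity day, in `[0, 1]`.
#' @return Object of class `wage_model`.
#' @examples
#' wage_model(10000)
#' @export
wage_model <- function(monthly_wage, working_days_per_month = 21.75,
                       presenteeism_weight = 0.4298) {
  assert_number(monthly_wage, "monthly_wage")
  if (monthly_wage <= 0) stop("`monthly_wage` must be positive", call. = FALSE)
  if (working_days_per_month <= 0) {
    stop("`working_days_per_month` must be positive", call. = FALSE)
  }
  assert_prob(presenteeism_weight, "presenteeism_weight")
  structure(list(monthly_wage = monthly_wage,
                 working_days_per_month = working_days_per_month,
                 presenteeism_weight = presenteeism_weight,
                 daily_wage = monthly_wage / working_days_per_month),
            class = "wage_model")
}

#' @export
print.wage_model <- function(x, ...) {
  cat(sprintf(
    "Wage model: %.2f/month over %.2f working days (daily %.2f), presenteeism weight %.4f\n",
    x$monthly_wage, x$working_days_per_month, x$daily_wage,
    x$presenteeism_weight))
  invisible(x)
}

#' Direct medical cost of a period (bottom-up)
#'
#' The direct medical cost is the exact sum of the drug, treatment, and
#' diagnostic/examination components for the period.
#'
#' @param drug,treatment,diagnostic Non-negative component costs; vectors are
#'   summed elementwise.
#' @return Direct medical cost per period.
#' @examples
#' direct_cost(5881.50, 179.60, 527.60)  # 6588.70
#' @export
direct_cost <- function(drug, treatment, diagnostic) {
  assert_nonneg(drug, "drug")
  assert_nonneg(treatment, "treatment")
  assert_nonneg(diagnostic, "diagnostic")
  drug + treatment + diagnostic
}

#' Indirect (productivity) cost of a period
#'
#' Values absenteeism and presenteeism by the human capital approach:
#' `lost_days * daily_wage + reduced_days * daily_wage * presenteeism_weight`.
#' The result is linear and homogeneous in the day counts.
#'
#' @param lost_days,reduced_days Non-negative day counts for the period.
#' @param wage A [wage_model()].
#' @return Indirect cost in currency.
#' @export
indirect_cost <- function(lost_days, reduced_days, wage) {
  stopifnot(inherits(wage, "wage_model"))
  assert_nonneg(lost_days, "lost_days")
  assert_nonneg(reduced_days, "reduced_days")
  wage$daily_wage * (lost_days + wage$presenteeism_weight * reduced_days)
}

#' Scale weekly disability-scale day counts to a costing period
#'
#' The disability scale asks for days of lost and reduced productivity "in
#' the last week"; period totals scale the weekly report by the period length
#' and cap at the period length in days.
#'
#' @param lost_per_week,reduced_per_week Weekly day counts in `[0, 7]`.
#' @param period_length_weeks Length of the costing period in weeks.
#' @param max_days_per_week Cap applied to the weekly counts before scaling;
#'   7 counts calendar days, 5 restricts to working days.
#' @return List with `lost_days` and `reduced_days` for the period.
#' @examples
#' sds_to_days(2, 0, 13)  # 26 lost days
#' @export
sds_to_days <- function(lost_per_week, reduced_per_week, period_length_weeks,
                        max_days_per_week = 7) {
  assert_number(lost_per_week, "lost_per_week", lower = 0, upper = 7)
  assert_number(reduced_per_week, "reduced_per_week", lower = 0, upper = 7)
  assert_nonneg(period_length_weeks, "period_length_weeks")
  cap <- max_days_per_week * period_length_weeks
  list(lost_days = pmin(lost_per_week * period_length_weeks, cap),
       reduced_days = pmin(reduced_per_week * period_length_weeks, cap))
}

#' Perspective-specific total cost
#'
#' The health-system perspective totals the intervention cost plus direct
#' medical costs; the societal perspective adds indirect (productivity)
#' costs. The intervention cost accrues to intervention-arm participants
#' only; the control arm's intervention cost is 0.
#'
#' @param direct,indirect Non-negative period (or cumulative) costs; vectors
#'   are combined elementwise.
#' @param arm `"intervention"` or `"control"` (recycled).
#' @param perspective `"society"` or `"health_system"`.
#' @param intervention_cost Per-participant cost of delivering the
#'   intervention (default CN Y545).
#' @return Total cost under the requested perspective.
#' @examples
#' total_cost(0, 0, "intervention", "health_system")  # 545
#' total_cost(100, 200, "intervention", "society")    # 845
#' @export
total_cost <- function(direct, indirect, arm,
                       perspective = c("society", "health_system"),
                       intervention_cost = 545) {
  perspective <- match.arg(perspective)
  assert_nonneg(direct, "direct")
  assert_nonneg(indirect, "indirect")
  arm <- as.character(arm)
  if (!all(arm %in% c("intervention", "control"))) {
    stop("`arm` must be 'intervention' or 'control'", call. = FALSE)
  }
  base <- ifelse(arm == "intervention", intervention_cost, 0) + direct
  if (perspective == "society") base + indirect else base
}
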