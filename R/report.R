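# Pipeline orchestration: from a trial panel and an analysis configuration
# to incremental cost-effectiveness summaries (point estimates, bootstrap
# uncertainty, planes, CEACs) per perspective, analysis sample, and horizon,
# plus descriptive tables.

#' Analysis configuration
#'
#' Collects every setting of a cost-utility run: perspectives, analysis
#' samples, horizons, imputation and bootstrap sizes, seeds, the
#' willingness-to-pay anchor, the wage model, the per-participant
#' intervention cost, and whether baseline values are adjusted for. The wage
#' model has no default: it is a locale-specific input.
#'
#' @param wage A [wage_model()] (required).
#' @param perspectives Subset of `"society"`, `"health_system"`.
#' @param samples Subset of `"intention_to_treat"`, `"complete_case"`.
#' @param horizons Wave labels (e.g. `"T1"`) at which to evaluate.
#' @param m Number of imputed datasets for the intention-to-treat sample.
#' @param B Bootstrap replicates.
#' @param donors,cycles PMM donor-pool size and chained cycles for the
#'   point-estimate imputation.
#' @param fast_cycles Chained cycles for the inner imputation refit inside
#'   each bootstrap replicate.
#' @param seed Master seed; all stage seeds derive from it.
#' @param gdp_per_capita,multipliers Willingness-to-pay anchor (see
#'   [wtp_grid()]).
#' @param intervention_cost Per-participant intervention delivery cost.
#' @param adjust_baseline Adjust for baseline cost/utility in the SUR
#'   equations.
#' @param stochastic_extrapolation Add residual noise to control-arm
#'   extrapolation steps.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(wage,
                            perspectives = c("society", "health_system"),
                            samples = "intention_to_treat",
                            horizons = "T1",
                            m = 5L, B = 5000L, donors = 5L, cycles = 10L,
                            fast_cycles = 2L, seed = 1L,
                            gdp_per_capita = 80976,
                            multipliers = c(1, 1.5, 3),
                            intervention_cost = 545,
                            adjust_baseline = TRUE,
                            stochastic_extrapolation = FALSE) {
  stopifnot(inherits(wage, "wage_model"))
  perspectives <- match.arg(perspectives, c("society", "health_system"),
                            several.ok = TRUE)
  samples <- match.arg(samples, c("intention_to_treat", "complete_case"),
                       several.ok = TRUE)
  assert_flag(adjust_baseline, "adjust_baseline")
  structure(list(
    wage = wage, perspectives = perspectives, samples = samples,
    horizons = horizons, m = as.integer(m), B = as.integer(B),
    donors = as.integer(donors), cycles = as.integer(cycles),
    fast_cycles = as.integer(fast_cycles), seed = as.integer(seed),
    wtp = wtp_grid(gdp_per_capita, multipliers),
    intervention_cost = intervention_cost,
    adjust_baseline = adjust_baseline,
    stochastic_extrapolation = stochastic_extrapolation
  ), class = "analysis_config")
}

# Row-wise trapezoidal QALY that propagates (rather than rejects) missing
# utilities; completeness is decided by the caller per analysis sample.
trapz_rows <- function(u, times) {
  dt <- diff(times)
  mid <- (u[, -ncol(u), drop = FALSE] + u[, -1L, drop = FALSE]) / 2
  as.numeric(mid %*% dt)
}

# Build the per-participant analysis frame at a horizon under a perspective.
build_analysis_data <- function(wide, horizon_wave, perspective, config) {
  k <- attr(wide, "n_waves")
  times <- attr(wide, "grid")$times
  h <- horizon_wave
  u <- as.matrix(wide[paste0("u", 0:h)])
  qaly <- trapz_rows(u, times[seq_len(h + 1L)])
  dcs <- as.matrix(wide[paste0("dc", seq_len(h))])
  ics <- as.matrix(wide[paste0("ic", seq_len(h))])
  direct <- rowSums(dcs)
  indirect <- rowSums(ics)
  interv <- ifelse(wide$treatment == 1, config$intervention_cost, 0)
  tc <- if (perspective == "society") interv + direct + indirect
        else interv + direct
  bc <- if (perspective == "society") wide$dc0 + wide$ic0 else wide$dc0
  data.frame(
    participant_id = wide$participant_id,
    treatment = wide$treatment,
    age = wide$age,
    gender_male = wide$gender_male,
    antidepressant_use = wide$antidepressant_use,
    baseline_utility = wide$u0,
    baseline_cost = bc,
    qaly = qaly,
    total_cost = tc
  )
}

sur_formulas <- function(adjust_baseline) {
  if (adjust_baseline) {
    list(cost = total_cost ~ treatment + baseline_cost + age + gender_male +
           antidepressant_use,
         qaly = qaly ~ treatment + baseline_utility + age + gender_male +
           antidepressant_use)
  } else {
    list(cost = total_cost ~ treatment + age + gender_male +
           antidepressant_use,
         qaly = qaly ~ treatment + age + gender_male + antidepressant_use)
  }
}

restore_wide_attrs <- function(d, template) {
  attr(d, "grid") <- attr(template, "grid")
  attr(d, "n_waves") <- attr(template, "n_waves")
  d
}

# Complete one working dataset: impute dropout cells (ITT only), then
# extrapolate structurally truncated control waves up to `max_wave`.
complete_datasets <- function(wide, sample, max_wave, config, seed) {
  datasets <- if (sample == "intention_to_treat") {
    mice_pmm(wide, m = config$m, donors = config$donors,
             cycles = config$cycles, seed = seed,
             max_wave = max_wave)$datasets
  } else {
    list(wide)
  }
  if (max_wave >= 2L) {
    datasets <- lapply(seq_along(datasets), function(i) {
      ds <- restore_wide_attrs(datasets[[i]], wide)
      if (!any(ds[[paste0("str", max_wave)]])) return(ds)
      model <- fit_trajectory(ds)
      extrapolate_control(ds, model, max_wave,
                          stochastic = config$stochastic_extrapolation,
                          seed = if (config$stochastic_extrapolation)
                            sub_seed(seed, 500L + i) else NULL)
    })
  }
  lapply(datasets, restore_wide_attrs, template = wide)
}

#' Run the full cost-utility pipeline
#'
#' For every requested perspective, analysis sample, and horizon, produces
#' the baseline-adjusted incremental cost and QALY (pooled over imputed
#' datasets for the intention-to-treat sample), the ICUR, bootstrapped
#' standard errors, the cost-effectiveness plane quadrant summary, the
#' acceptability curve, and the probability of cost-effectiveness at each
#' named willingness-to-pay multiple. The intention-to-treat sample imputes
#' dropout missingness; the complete-case sample drops participants without
#' the horizon's outcomes. Control waves beyond the truncation wave are
#' filled by intervention-arm trajectory extrapolation in either sample.
#' The bootstrap resamples participants stratified by arm and, for the
#' intention-to-treat sample, refits the imputation (with `fast_cycles`
#' chained cycles) inside every replicate.
#'
#' @param panel A [trial_panel()].
#' @param config An [analysis_config()].
#' @return Object of class `cua_results`: `summary` data frame (one row per
#'   perspective x sample x horizon), `results` (per-combination detail:
#'   point fit, draws, plane, CEAC, ICUR interval), and `manifest`.
#' @export
run_pipeline <- function(panel, config) {
  stopifnot(inherits(panel, "trial_panel"), inherits(config, "analysis_config"))
  t0 <- Sys.time()
  grid <- panel$grid
  wide <- panel_wide(panel, config$wage)
  fml <- sur_formulas(config$adjust_baseline)
  horizon_waves <- match(config$horizons, grid$labels) - 1L
  if (anyNA(horizon_waves) || any(horizon_waves < 1L)) {
    stop("`horizons` must name post-baseline waves of the panel grid",
         call. = FALSE)
  }
  max_wave <- max(horizon_waves)
  wtp <- config$wtp

  results <- list()
  rows <- list()
  combo <- 0L
  for (sample in config$samples) {
    seed_imp <- sub_seed(config$seed, 11L)
    datasets <- complete_datasets(wide, sample, max_wave, config, seed_imp)
    for (hw in horizon_waves) {
      for (persp in config$perspectives) {
        combo <- combo + 1L
        tic <- Sys.time()
        frames <- lapply(datasets, build_analysis_data, horizon_wave = hw,
                         perspective = persp, config = config)
        if (sample == "complete_case") {
          frames <- lapply(frames, function(f) f[stats::complete.cases(f), ])
        }
        point <- fit_sur_pooled(frames, cost_formula = fml$cost,
                                qaly_formula = fml$qaly)
        dc_pt <- point$delta_cost$point
        dq_pt <- point$delta_qaly$point

        refit <- make_refit(wide, sample, hw, max_wave, persp, config, fml)
        boot_data <- if (sample == "complete_case") {
          # resample within the analysed (complete) participants
          ids <- frames[[1L]]$participant_id
          restore_wide_attrs(wide[wide$participant_id %in% ids, ,
                                  drop = FALSE], wide)
        } else {
          wide
        }
        draws <- bootstrap_ce(boot_data, B = config$B,
                              seed = sub_seed(config$seed, 100L + combo),
                              refit = refit)
        plane <- classify_plane(draws)
        curve <- ceac(draws, wtp)
        probs <- vapply(wtp$thresholds, function(lam) {
          mean(nmb(draws$delta_qaly, draws$delta_cost, lam) > 0)
        }, numeric(1L))
        ratio <- suppressWarnings(icur(dc_pt, dq_pt))
        ci <- suppressWarnings(icur_ci(draws))
        res <- list(sample = sample, horizon = grid$labels[hw + 1L],
                    perspective = persp, point = point, icur = ratio,
                    draws = draws, plane = plane, ceac = curve,
                    icur_ci = ci,
                    prob_ce = stats::setNames(100 * probs,
                                              names(wtp$thresholds)),
                    seconds = as.numeric(difftime(Sys.time(), tic,
                                                  units = "secs")))
        key <- paste(sample, grid$labels[hw + 1L], persp, sep = ".")
        results[[key]] <- res
        rows[[key]] <- data.frame(
          sample = sample, horizon = grid$labels[hw + 1L],
          perspective = persp,
          delta_cost = dc_pt, delta_cost_bse = stats::sd(draws$delta_cost),
          delta_qaly = dq_pt, delta_qaly_bse = stats::sd(draws$delta_qaly),
          icur = ratio$icur,
          se_pct = plane$se, sw_pct = plane$sw, ne_pct = plane$ne,
          nw_pct = plane$nw, south_pct = plane$south, east_pct = plane$east,
          stringsAsFactors = FALSE)
        for (nm in names(wtp$thresholds)) {
          rows[[key]][[paste0("prob_ce_", nm)]] <- res$prob_ce[[nm]]
        }
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("cuatrial")),
    r_version = R.version.string,
    n_participants = nrow(panel$participants),
    seed = config$seed,
    m = config$m, B = config$B, donors = config$donors,
    cycles = config$cycles, fast_cycles = config$fast_cycles,
    adjust_baseline = config$adjust_baseline,
    gdp_per_capita = wtp$gdp_per_capita,
    multipliers = wtp$multipliers,
    intervention_cost = config$intervention_cost,
    wage = unclass(config$wage),
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(summary = summary, results = results, manifest = manifest),
            class = "cua_results")
}

# Closure refitting the full estimation path on one bootstrap resample.
make_refit <- function(wide, sample, hw, max_wave, persp, config, fml) {
  force(wide); force(sample); force(hw); force(max_wave); force(persp)
  function(d) {
    d <- restore_wide_attrs(d, wide)
    if (sample == "intention_to_treat") {
      inner_seed <- sample.int(2147483629L, 1L)
      datasets <- complete_datasets(d, sample, max_wave,
                                    fast_config(config), inner_seed)
      frames <- lapply(datasets, build_analysis_data, horizon_wave = hw,
                       perspective = persp, config = config)
      fits <- lapply(frames, fit_sur, cost_formula = fml$cost,
                     qaly_formula = fml$qaly)
      c(mean(vapply(fits, `[[`, 0, "delta_qaly")),
        mean(vapply(fits, `[[`, 0, "delta_cost")))
    } else {
      datasets <- complete_datasets(d, sample, max_wave, config, 0L)
      frame <- build_analysis_data(datasets[[1L]], hw, persp, config)
      frame <- frame[stats::complete.cases(frame), ]
      f <- fit_sur(frame, cost_formula = fml$cost, qaly_formula = fml$qaly)
      c(f$delta_qaly, f$delta_cost)
    }
  }
}

fast_config <- function(config) {
  config$cycles <- config$fast_cycles
  config
}

#' @export
print.cua_results <- function(x, ...) {
  cat("Cost-utility results\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Descriptive tables by trial arm
#'
#' Arm-wise summaries mirroring the usual reporting of a trial-based
#' economic evaluation: baseline characteristics, utility per wave with
#' completion counts and between-arm t tests, and per-period cost components
#' with resource-user counts and Mann-Whitney tests. Only observed values
#' enter these tables.
#'
#' @param panel A [trial_panel()].
#' @param wage A [wage_model()] to value productivity days.
#' @return List of data frames `baseline`, `utility`, and `costs`.
#' @export
descriptive_tables <- function(panel, wage) {
  stopifnot(inherits(panel, "trial_panel"), inherits(wage, "wage_model"))
  p <- panel$participants
  w <- panel$waves
  k <- length(panel$grid$times)
  arms <- c("intervention", "control")
  n_arm <- stats::setNames(vapply(arms, function(a) sum(p$arm == a), 0L),
                           arms)

  baseline <- do.call(rbind, lapply(arms, function(a) {
    pa <- p[p$arm == a, ]
    data.frame(arm = a, n = nrow(pa), age_mean = mean(pa$age),
               age_sd = stats::sd(pa$age),
               female_n = sum(pa$gender == "female"),
               female_pct = 100 * mean(pa$gender == "female"),
               antidepressant_n = sum(pa$antidepressant_use),
               antidepressant_pct = 100 * mean(pa$antidepressant_use),
               stringsAsFactors = FALSE)
  }))

  utility <- do.call(rbind, lapply(seq_len(k) - 1L, function(t) {
    do.call(rbind, lapply(arms, function(a) {
      ids <- p$participant_id[p$arm == a]
      wt <- w[w$wave == t & w$participant_id %in% ids, ]
      vals <- wt$utility[wt$observed]
      data.frame(wave = panel$grid$labels[t + 1L], arm = a,
                 n_observed = length(vals),
                 pct_observed = 100 * length(vals) / n_arm[[a]],
                 mean = if (length(vals)) mean(vals) else NA_real_,
                 sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  utility$p_value <- NA_real_
  for (t in seq_len(k) - 1L) {
    lbl <- panel$grid$labels[t + 1L]
    vi <- observed_values(panel, "utility", t, "intervention", wage)
    vc <- observed_values(panel, "utility", t, "control", wage)
    if (length(vi) >= 2 && length(vc) >= 2) {
      utility$p_value[utility$wave == lbl] <-
        group_compare(vi, vc, "t")$p.value
    }
  }

  comps <- c("drug", "treatment", "diagnostic", "direct", "indirect")
  costs <- do.call(rbind, lapply(seq_len(k) - 1L, function(t) {
    do.call(rbind, lapply(comps, function(cmp) {
      do.call(rbind, lapply(arms, function(a) {
        vals <- observed_values(panel, cmp, t, a, wage)
        data.frame(period = panel$grid$labels[t + 1L], component = cmp,
                   arm = a,
                   users_n = sum(vals > 0),
                   users_pct = 100 * sum(vals > 0) / n_arm[[a]],
                   mean = if (length(vals)) mean(vals) else NA_real_,
                   sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  costs$p_value <- NA_real_
  for (t in seq_len(k) - 1L) {
    for (cmp in comps) {
      vi <- observed_values(panel, cmp, t, "intervention", wage)
      vc <- observed_values(panel, cmp, t, "control", wage)
      if (length(vi) >= 2 && length(vc) >= 2) {
        sel <- costs$period == panel$grid$labels[t + 1L] &
          costs$component == cmp
        costs$p_value[sel] <- group_compare(vi, vc, "mann-whitney")$p.value
      }
    }
  }
  list(baseline = baseline, utility = utility, costs = costs)
}

observed_values <- function(panel, what, wave, arm, wage) {
  p <- panel$participants
  w <- panel$waves
  ids <- p$participant_id[p$arm == arm]
  wt <- w[w$wave == wave & w$participant_id %in% ids & w$observed, ]
  switch(what,
         utility = wt$utility,
         drug = wt$drug,
         treatment = wt$treatment,
         diagnostic = wt$diagnostic,
         direct = wt$drug + wt$treatment + wt$diagnostic,
         indirect = indirect_cost(wt$lost_days, wt$reduced_days, wage),
         stop("unknown summary: ", what, call. = FALSE))
}
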