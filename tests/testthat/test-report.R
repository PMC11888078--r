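test_that("the pipeline completes on a small fixture and is deterministic", {
  panel <- simulate_trial(small_config(n = 20, seed = 14))
  ac <- analysis_config(wage = fixture_wage, samples = "intention_to_treat",
                        horizons = "T1", m = 2, B = 5, cycles = 2,
                        fast_cycles = 1, donors = 3, seed = 3)
  res <- run_pipeline(panel, ac)
  expect_s3_class(res, "cua_results")
  expect_equal(nrow(res$summary), 2)  # both perspectives
  need <- c("delta_cost", "delta_cost_bse", "delta_qaly", "delta_qaly_bse",
            "icur", "se_pct", "sw_pct", "ne_pct", "nw_pct", "south_pct",
            "east_pct", "prob_ce_1x", "prob_ce_1.5x", "prob_ce_3x")
  expect_true(all(need %in% names(res$summary)))
  one <- res$results[["intention_to_treat.T1.society"]]
  expect_equal(nrow(one$draws), 5)
  expect_equal(nrow(one$ceac), 200)
  expect_true(all(one$ceac$probability >= 0 & one$ceac$probability <= 1))
  expect_true(is.list(res$manifest) && res$manifest$n_participants == 20)

  res2 <- run_pipeline(panel, ac)
  expect_identical(res$summary, res2$summary)
})

test_that("complete-case and multi-horizon runs emit every combination", {
  panel <- simulate_trial(small_config(n = 40, seed = 15))
  ac <- analysis_config(wage = fixture_wage, samples = "complete_case",
                        horizons = c("T1", "T4"), B = 5, seed = 9,
                        perspectives = "society")
  res <- run_pipeline(panel, ac)
  expect_equal(nrow(res$summary), 2)
  expect_setequal(res$summary$horizon, c("T1", "T4"))
})

test_that("baseline adjustment changes effects but not descriptives", {
  panel <- simulate_trial(small_config(n = 60, seed = 16))
  mk <- function(adj) {
    analysis_config(wage = fixture_wage, samples = "complete_case",
                    horizons = "T1", B = 3, seed = 5,
                    perspectives = "society", adjust_baseline = adj)
  }
  r_adj <- run_pipeline(panel, mk(TRUE))
  r_raw <- run_pipeline(panel, mk(FALSE))
  expect_false(isTRUE(all.equal(r_adj$summary$delta_cost,
                                r_raw$summary$delta_cost)))
  d1 <- descriptive_tables(panel, fixture_wage)
  expect_identical(d1, descriptive_tables(panel, fixture_wage))
})

test_that("societal minus health-system effect equals the indirect effect", {
  # fit the two perspective cost equations with a common covariate set: by
  # linearity of least squares the difference of the treatment coefficients
  # is exactly the indirect-cost treatment coefficient
  panel <- simulate_trial(small_config(n = 120, seed = 17,
                                       dropout_hazard = NULL,
                                       control_truncation_wave = NULL))
  wide <- cuatrial:::panel_wide(panel, fixture_wage)
  base <- data.frame(treatment = wide$treatment, age = wide$age,
                     gender_male = wide$gender_male,
                     antidepressant_use = wide$antidepressant_use,
                     baseline_cost = wide$dc0 + wide$ic0,
                     baseline_utility = wide$u0,
                     qaly = (wide$u0 + wide$u1) / 2 * 0.25)
  base$cost_soc <- 545 * wide$treatment + wide$dc1 + wide$ic1
  base$cost_hs <- 545 * wide$treatment + wide$dc1
  base$indirect <- wide$ic1
  fml <- function(y) stats::reformulate(
    c("treatment", "baseline_cost", "age", "gender_male",
      "antidepressant_use"), y)
  qf <- qaly ~ treatment + baseline_utility + age + gender_male +
    antidepressant_use
  f_soc <- fit_sur(base, fml("cost_soc"), qf, method = "ols")
  f_hs <- fit_sur(base, fml("cost_hs"), qf, method = "ols")
  f_ind <- fit_sur(base, fml("indirect"), qf, method = "ols")
  expect_equal(f_soc$delta_cost - f_hs$delta_cost, f_ind$delta_cost,
               tolerance = 1e-8)
})

test_that("descriptive tables are hand-checkable and internally consistent", {
  g <- time_grid(c(0, 0.25))
  participants <- data.frame(
    participant_id = 1:2, arm = c("intervention", "control"),
    age = c(30, 40), gender = c("female", "male"),
    antidepressant_use = c(TRUE, FALSE))
  waves <- data.frame(
    participant_id = rep(1:2, each = 2), wave = rep(0:1, 2),
    time = rep(c(0, 0.25), 2),
    utility = c(0.5, 0.6, 0.7, 0.8),
    drug = c(100, 50, 0, 0), treatment = c(10, 0, 0, 0),
    diagnostic = c(5, 0, 0, 0),
    lost_days = c(2, 1, 0, 0), reduced_days = c(4, 2, 0, 0),
    observed = TRUE, structural = FALSE)
  panel <- trial_panel(participants, waves, g)
  tabs <- descriptive_tables(panel, fixture_wage)

  ut <- tabs$utility
  expect_equal(ut$mean[ut$wave == "T0" & ut$arm == "intervention"], 0.5)
  expect_equal(ut$n_observed[ut$wave == "T1" & ut$arm == "control"], 1)

  ct <- tabs$costs
  dr <- ct[ct$component == "direct", ]
  expect_equal(dr$mean[dr$period == "T0" & dr$arm == "intervention"], 115)
  # direct equals the component sum in every cell
  for (per in unique(ct$period)) {
    for (a in unique(ct$arm)) {
      pick <- function(cmp) ct$mean[ct$period == per & ct$arm == a &
                                      ct$component == cmp]
      expect_equal(pick("direct"),
                   pick("drug") + pick("treatment") + pick("diagnostic"))
    }
  }
  ind <- ct[ct$component == "indirect" & ct$period == "T0" &
              ct$arm == "intervention", ]
  expect_equal(ind$mean, indirect_cost(2, 4, fixture_wage))
  # all-zero control costs summarize to zero users and zero means
  zero <- ct[ct$arm == "control" & ct$component == "drug" &
               ct$period == "T1", ]
  expect_equal(zero$users_n, 0)
  expect_equal(zero$mean, 0)
})
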