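test_that("permuted-block randomization realizes the allocation ratio", {
  expect_equal(as.integer(table(randomize(244, c(1, 1), seed = 1))),
               c(122L, 122L))
  expect_equal(as.integer(table(randomize(2, c(1, 1), seed = 4))), c(1L, 1L))
  counts <- table(randomize(245, c(1, 1), seed = 2))
  expect_setequal(as.integer(counts), c(122L, 123L))
  expect_equal(as.integer(table(randomize(30, c(2, 1), seed = 1))), c(10L, 20L))
  expect_identical(randomize(100, seed = 7), randomize(100, seed = 7))
  expect_error(randomize(0), "positive")
  expect_error(randomize(-3), "positive")
})

test_that("simulated panels are deterministic functions of the seed", {
  cfg <- small_config(n = 40, seed = 11)
  p1 <- simulate_trial(cfg)
  p2 <- simulate_trial(cfg)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_panel(p1, f1); write_panel(p2, f2)
  expect_identical(readLines(paste0(f1, "_waves.csv")),
                   readLines(paste0(f2, "_waves.csv")))
  p3 <- simulate_trial(small_config(n = 40, seed = 12))
  expect_false(identical(p1$waves, p3$waves))
})

test_that("panels round-trip through the delimited format", {
  p <- simulate_trial(small_config(n = 30, seed = 2))
  prefix <- withr::local_tempfile()
  write_panel(p, prefix)
  q <- read_panel(prefix)
  expect_equal(q$participants, p$participants)
  expect_equal(q$waves, p$waves, tolerance = 1e-12)
})

test_that("degenerate utility config yields exactly the configured value", {
  mk <- function(x) rbind(intervention = rep(x, 5), control = rep(x, 5))
  cfg <- small_config(n = 25, seed = 3, utility_means = mk(1),
                      utility_sd = 0, dropout_hazard = NULL)
  p <- simulate_trial(cfg)
  obs <- p$waves$utility[p$waves$observed]
  expect_true(all(obs == 1))
})

test_that("panel invariants hold on simulated data", {
  p <- simulate_trial(small_config(n = 80, seed = 5))
  w <- p$waves
  expect_true(all(w$utility <= 1, na.rm = TRUE))
  for (col in c("drug", "treatment", "diagnostic", "lost_days",
                "reduced_days")) {
    expect_true(all(w[[col]] >= 0, na.rm = TRUE))
  }
  # control waves beyond the truncation wave are structurally missing
  ctl <- p$participants$participant_id[p$participants$arm == "control"]
  late <- w[w$participant_id %in% ctl & w$wave > 1, ]
  expect_true(all(late$structural))
  expect_true(all(is.na(late$utility)))
  int <- w[!(w$participant_id %in% ctl), ]
  expect_false(any(int$structural))
})

test_that("arm-wise means recover the configured utility means", {
  cfg <- trial_config(n_total = 10000, seed = 21, dropout_hazard = NULL)
  p <- simulate_trial(cfg)
  ids <- p$participants$participant_id[p$participants$arm == "intervention"]
  base <- p$waves[p$waves$wave == 0 & p$waves$participant_id %in% ids, ]
  expect_equal(mean(base$utility), 0.5190, tolerance = 0.01 / 0.5190)
})

test_that("log-cost moments recover the configured parameters", {
  cfg <- twowave_config(n = 8000, seed = 31, cost_mean_ctl = 2000,
                        sdlog = 0.5)
  p <- simulate_trial(cfg)
  drugs <- p$waves$drug[p$waves$wave == 0]
  expect_equal(mean(log(drugs[drugs > 0])), log(2000) - 0.5^2 / 2,
               tolerance = 0.02)
  expect_equal(sd(log(drugs[drugs > 0])), 0.5, tolerance = 0.05)
})

test_that("dropout hazards control completion as configured", {
  mkh <- function(int, ctl) rbind(intervention = int, control = ctl)
  cfg0 <- small_config(n = 50, seed = 7,
                       dropout_hazard = mkh(rep(0, 4), rep(0, 4)))
  p0 <- simulate_trial(cfg0)
  int_ids <- p0$participants$participant_id[p0$participants$arm ==
                                              "intervention"]
  expect_true(all(p0$waves$observed[p0$waves$participant_id %in% int_ids]))

  # default hazards reproduce the trial's post-treatment completion rates
  cfg <- trial_config(n_total = 6000, seed = 8)
  p <- simulate_trial(cfg)
  w1 <- p$waves[p$waves$wave == 1, ]
  arm_of <- p$participants$arm[match(w1$participant_id,
                                     p$participants$participant_id)]
  comp_int <- mean(w1$observed[arm_of == "intervention"])
  comp_ctl <- mean(w1$observed[arm_of == "control"])
  expect_equal(comp_int, 0.73, tolerance = 0.03)
  expect_equal(comp_ctl, 0.943, tolerance = 0.02)

  # total dropout: hazard 1 at wave 1 leaves no post-baseline data and the
  # imputer refuses
  cfg1 <- small_config(n = 30, seed = 9, control_truncation_wave = NULL,
                       dropout_hazard = mkh(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  p1 <- simulate_trial(cfg1)
  expect_true(all(is.na(p1$waves$utility[p1$waves$wave == 1])))
  expect_error(mice_pmm(p1, m = 2, wage = fixture_wage), "no observed")
})

test_that("dropout is monotone: once missing, always missing", {
  p <- simulate_trial(small_config(n = 200, seed = 13))
  int_ids <- p$participants$participant_id[p$participants$arm ==
                                             "intervention"]
  for (id in int_ids) {
    obs <- p$waves$observed[p$waves$participant_id == id]
    # after the first FALSE, no TRUE may follow
    if (any(!obs)) expect_false(any(obs[which(!obs)[1]:length(obs)]))
  }
})

test_that("covariate-dependent dropout stays missing at random", {
  # regressing the missingness indicator on the withheld true value, given
  # the observed covariates, must show no association (MAR by construction)
  set.seed(404)
  zs <- replicate(30, {
    seed <- sample.int(1e6, 1)
    cfg <- twowave_config(n = 500, seed = seed, dropout = 0.3)
    cfg$dropout_coefficients <- c(prev_utility = -2, age = 0.02)
    complete <- simulate_trial(cfg, apply_dropout = FALSE)
    dropped <- impose_missingness(complete, cfg$dropout_hazard,
                                  cfg$dropout_coefficients, seed = seed + 1)
    wide_c <- cuatrial:::panel_wide(complete, fixture_wage)
    wide_d <- cuatrial:::panel_wide(dropped, fixture_wage)
    miss <- as.numeric(is.na(wide_d$u1))
    fit <- glm(miss ~ wide_c$u1 + wide_c$u0 + wide_c$age +
                 wide_c$gender_male, family = binomial)
    summary(fit)$coefficients["wide_c$u1", "z value"]
  })
  expect_lt(abs(mean(zs)), 0.6)
})

test_that("configuration invariants are enforced", {
  expect_error(trial_config(n_total = 1), "at least 2")
  expect_error(trial_config(allocation_ratio = c(0, 1)), "positive")
  mk <- function(x) rbind(intervention = rep(x, 5), control = rep(x, 5))
  expect_error(trial_config(utility_means = mk(1.2)), "exceed 1")
  expect_error(trial_config(dropout_hazard = rbind(intervention = rep(2, 4),
                                                   control = rep(0, 4))),
               "dropout_hazard")
})
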