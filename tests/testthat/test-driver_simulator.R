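# driver_simulator: population sampling, response model, lap kinematics,
# dataset bookkeeping, parameter/sign recovery.

test_that("sample_population reproduces the configured marginals", {
  pop <- sample_population(10000, seed = 3)
  expect_equal(mean(pop$BAS_Fun_Seeking), 11.704, tolerance = 0.1 / 11.704)
  expect_lt(abs(mean(pop$BAS_Fun_Seeking) - 11.704), 0.1)
  expect_lt(abs(sd(pop$BAS_Fun_Seeking) - 2.165), 0.1)
  expect_lt(abs(mean(pop$goRT_all) - 618.148), 0.02 * 618.148)
  expect_equal(nrow(sample_population(27, seed = 1)), 27L)
  # determinism
  expect_identical(sample_population(50, seed = 9),
                   sample_population(50, seed = 9))
  # configuration errors
  expect_error(factor_spec("x", 1, 0), "sd")
  expect_error(sample_population(1, seed = 1), "n_subjects")
})

test_that("sample_population honors a correlation matrix", {
  R <- diag(4)
  R[1, 4] <- R[4, 1] <- -0.8
  pop <- sample_population(5000, seed = 2, correlation = R)
  expect_lt(cor(pop$goRT_all, pop$BAS_Fun_Seeking), -0.7)
})

test_that("response_model_mean_speed matches hand arithmetic", {
  m <- default_response_models()$BAS_Fun_Seeking
  eff <- function(f, mod) {
    p <- stats::setNames(f, mod$factor)
    response_model_mean_speed(p, 1, mod) - response_model_mean_speed(p, 0, mod)
  }
  # HMI effect = beta_hmi + beta_interaction * f (hand-computed)
  expect_equal(eff(9.539, m), -2.5549, tolerance = 1e-10)
  expect_equal(eff(13.869, m), 1.3421, tolerance = 1e-10)
  pu <- default_response_models()$UPPS_P_Positive_Urgency
  expect_equal(eff(6.630, pu), -0.5551, tolerance = 1e-10)
  # without HMI, beta_hmi and beta_interaction contribute exactly nothing
  p <- c(BAS_Fun_Seeking = 20)
  expect_identical(response_model_mean_speed(p, 0, m),
                   m$intercept + m$beta_factor * 20)
  expect_error(response_model_mean_speed(c(other = 1), 1, m), "measure")
})

test_that("simulate_lap realizes the yellow-light statistics", {
  cfg <- single_factor_sim_config(seed = 5)
  subj <- sample_population(2, seed = 5)[1, , drop = FALSE]
  lap <- simulate_lap(subj, hmi_condition("road_markings", "distance"),
                      cfg$course, cfg, seed = 9)
  phase <- lap$light_phase
  transitions <- sum(phase == "Y" & c("", phase[-length(phase)]) == "G")
  expect_identical(transitions, 4L)
  expect_true(all(lap$speed_mps >= 0))
  # speed integrates acceleration (by construction of the finite difference)
  v_rebuilt <- lap$speed_mps[1] + cumsum(lap$accel_mps2) * 0.1 -
    lap$accel_mps2[1] * 0.1
  expect_equal(v_rebuilt, lap$speed_mps, tolerance = 1e-9)

  # noise-free limit: realized yellow mean equals the response model exactly
  cfg0 <- cfg
  cfg0$residual_sd <- 0
  cfg0$cruise_jitter_sd <- 0
  subj0 <- subj
  subj0$random_intercept <- 0
  lap0 <- simulate_lap(subj0, hmi_condition("road_markings", "distance"),
                       cfg$course, cfg0, seed = 9)
  tt0 <- build_trial_table(lap0)
  expected <- response_model_mean_speed(
    stats::setNames(subj0$BAS_Fun_Seeking, "BAS_Fun_Seeking"), 1,
    cfg$models[[1]])
  expect_equal(stats::na.omit(tt0$mean_yellow_speed),
               rep(expected, 4), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Monte-Carlo mean yellow speed matches the response model", {
  cfg <- single_factor_sim_config(seed = 2)
  cfg$course <- course_spec(n_lights_per_lap = 2L, n_yellow_per_lap = 2L,
                            lap_order = cfg$course$lap_order)
  subj <- sample_population(2, seed = 2)[1, , drop = FALSE]
  expected <- response_model_mean_speed(
    stats::setNames(subj$BAS_Fun_Seeking, "BAS_Fun_Seeking"), 0,
    cfg$models[[1]], random_intercept = subj$random_intercept)
  set.seed(42)
  vals <- unlist(lapply(1:400, function(i) {
    tt <- build_trial_table(simulate_lap(subj, hmi_condition("none"),
                                         cfg$course, cfg))
    tt$mean_yellow_speed[tt$had_yellow]
  }))
  se <- cfg$residual_sd / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("generate_dataset bookkeeping matches the study design", {
  b <- small_bundle()
  expect_identical(nrow(b$subjects), 5L)
  # trial table covers every subject x lap x approach
  expect_identical(nrow(b$trials), 5L * 4L * 4L)
  expect_identical(nrow(analysis_trials(b)),
                   5L * 3L * 4L)                    # practice lap excluded
  expect_setequal(unique(analysis_trials(b)$lap_id), 2:4)
  # cross-referenced ids
  expect_setequal(unique(b$log$subject_id), b$subjects$subject_id)
  # determinism: identical seed and config => identical bundle
  b2 <- generate_dataset(small_sim_config(seed = 3L))
  expect_identical(b$log, b2$log)
  expect_identical(b$subjects, b2$subjects)
})

test_that("OLS refit recovers the configured coefficients", {
  b <- generate_dataset(single_factor_sim_config("BAS_Fun_Seeking",
                                                 seed = 101))
  r <- refit_interaction(b, "BAS_Fun_Seeking")
  expect_lt(abs(r$beta_interaction - 0.9), 2 * r$se_interaction)
  expect_lt(abs(r$beta_hmi - (-11.14)), 2 * r$se_hmi)
  expect_identical(r$n_trials, 27L * 5L * 4L)
})

test_that("factor/yellow-speed correlations recover the configured signs", {
  cfg <- sim_config(n_subjects = 60L, seed = 12)
  b <- generate_dataset(cfg)
  tr <- analysis_trials(b)
  per_subj <- tapply(tr$mean_yellow_speed[tr$had_yellow],
                     tr$subject_id[tr$had_yellow], mean)
  s <- b$subjects[match(names(per_subj), b$subjects$subject_id), ]
  for (spec in default_factor_specs()) {
    r <- cor(s[[spec$name]], as.numeric(per_subj))
    expect_identical(sign(r), as.numeric(spec$sign_vs_yellow_speed),
                     label = paste("sign of", spec$name))
  }
})
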