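# evaluation_harness: counterfactual scoring, agreement metrics, KL
# separation, stepwise selection, LOOCV plumbing.

two_subject_trials <- function() {
  rbind(
    data.frame(subject_id = "S01", lap_id = 1:3, approach_idx = 1L,
               condition = c("hud_circle_distance", "hud_circle_distance",
                             "baseline"),
               hmi_present = c(TRUE, TRUE, FALSE), had_yellow = TRUE,
               mean_yellow_speed = c(14, 16, 18),
               max_yellow_speed = c(14, 16, 18)),
    data.frame(subject_id = "S02", lap_id = 1:2, approach_idx = 1L,
               condition = c("hud_circle_distance", "baseline"),
               hmi_present = c(TRUE, FALSE), had_yellow = TRUE,
               mean_yellow_speed = c(17, 19), max_yellow_speed = c(17, 19)))
}

test_that("counterfactual speed averages matching-condition trials", {
  tr <- two_subject_trials()
  # deploy for S01: HMI trials {14, 16} -> 15
  res <- counterfactual_yellow_speed(c(S01 = TRUE, S02 = TRUE), tr)
  expect_identical(unname(res$per_subject["S01"]), 15)
  # two subjects with values {15, 17}: mean 16, SE 1
  expect_identical(res$mean, 16)
  expect_identical(res$se, 1)
  # baseline identities: always-withhold equals the no-HMI average
  off <- counterfactual_yellow_speed(c(S01 = FALSE, S02 = FALSE), tr)
  no_hmi_avg <- mean(c(18, 19))
  expect_identical(off$mean, no_hmi_avg)
  on <- counterfactual_yellow_speed(c(S01 = TRUE, S02 = TRUE), tr)
  hmi_avg <- mean(c(mean(c(14, 16)), 17))
  expect_identical(on$mean, hmi_avg)
  # a subject with no matching trials is excluded with a warning
  tr2 <- tr[tr$subject_id != "S02" | !tr$hmi_present, ]
  expect_warning(res2 <- counterfactual_yellow_speed(
    c(S01 = TRUE, S02 = TRUE), tr2), "excluded")
  expect_identical(res2$n_excluded, 1L)
})

test_that("agreement metrics match their definitions", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- decision_agreement_metrics(lab, lab)
  expect_identical(perfect$kappa, 1)
  expect_identical(perfect$balanced_accuracy, 1)
  wrong <- decision_agreement_metrics(!lab, lab)
  expect_identical(wrong$balanced_accuracy, 0)
  expect_error(decision_agreement_metrics(lab, rep(TRUE, 4)),
               "single class")
  # uniform-random decisions against fixed balanced labels average 50%
  set.seed(60)
  ba <- replicate(1e4, decision_agreement_metrics(
    runif(10) < 0.5, rep(c(TRUE, FALSE), 5))$balanced_accuracy)
  expect_lt(abs(mean(ba) - 0.5), 0.01)
})

test_that("kl_separation is anchored, invariant, and consistent", {
  # identical groups: zero separation
  base <- exact_moment_points(40, c(0, 0), diag(2), seed = 2)
  lat <- rbind(base, base)
  fv <- rep(c(0, 1), each = 40)
  expect_lt(abs(kl_separation(lat, fv)), 1e-9)
  # exact N(0, I) vs N((1,0), I) moments: the normalization anchor, 1.0
  shifted <- sweep(exact_moment_points(40, c(0, 0), diag(2), seed = 3), 2,
                   c(1, 0), `+`)
  lat2 <- rbind(base, shifted)
  expect_equal(kl_separation(lat2, fv), 1, tolerance = 1e-9)
  # 500 random samples at separation 2: close to 4 (closed-form oracle)
  set.seed(4)
  lat3 <- rbind(matrix(rnorm(1000), 500, 2),
                cbind(rnorm(500, 2), rnorm(500)))
  v <- kl_separation(lat3, rep(c(0, 1), each = 500))
  expect_lt(abs(v - 4), 0.3)
  # rotation invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(kl_separation(lat2 %*% R, fv), kl_separation(lat2, fv),
               tolerance = 1e-8)
  # relabeling the two groups changes nothing
  expect_equal(kl_separation(lat2, -fv), kl_separation(lat2, fv),
               tolerance = 1e-9)
})

test_that("stepwise selection controls the null and finds real signal", {
  set.seed(70)
  # all-noise candidates: the Bonferroni entry rule keeps the empty set in
  # (1 - 0.05/5)^5 = 95.1% of populations; 500 replicates have a binomial
  # SE of ~1%, so assert the rate minus ~2 SE
  empties <- replicate(500, {
    X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
    y <- rnorm(200)
    length(stepwise_select(X, y)) == 0L
  })
  expect_gte(mean(empties), 0.93)
  # a single strong predictor is found
  set.seed(71)
  X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  y <- X$V3 + rnorm(200, 0, 0.1)
  expect_identical(stepwise_select(X, y), "V3")
  # exactly the four driving factors out of eight candidates
  set.seed(72)
  X8 <- as.data.frame(matrix(rnorm(300 * 8), 300, 8))
  names(X8) <- c(paste0("real", 1:4), paste0("noise", 1:4))
  y8 <- rowSums(X8[, 1:4]) + rnorm(300, 0, 0.5)
  expect_setequal(stepwise_select(X8, y8), paste0("real", 1:4))
})

test_that("loocv_evaluate runs one fold per subject without leakage", {
  b <- small_bundle()
  rep <- suppressWarnings(loocv_evaluate(
    b, enc_config = quick_encoder_config(epochs = 4L),
    n_seeds = 2L, seed_base = 1L, window_T = 15L,
    snippets_per_subject = 4L))
  expect_identical(rep$seeds, 1:2)
  folds <- rep$fold_subjects
  expect_identical(sort(names(folds)), sort(b$subjects$subject_id))
  for (s in names(folds))
    expect_false(s %in% folds[[s]])        # held-out subject never trains
  expect_identical(rep$policy_speeds$policy,
                   c("no_hmi", "always", "random", "window_averaged",
                     "instantaneous"))
  expect_true(all(is.finite(rep$policy_speeds$mean)))
  # baseline identities inside the report: no_hmi row equals the plain
  # no-HMI per-condition average
  tr <- analysis_trials(b)
  ids <- b$subjects$subject_id
  off <- counterfactual_yellow_speed(
    stats::setNames(rep(FALSE, length(ids)), ids), tr)
  expect_equal(rep$policy_speeds$mean[1], off$mean, tolerance = 1e-9)
  # default seed count follows the protocol (10 seeds)
  expect_identical(eval(formals(loocv_evaluate)$n_seeds), 10L)
})

test_that("null coupling gives the personalized policy no spurious edge", {
  # factors disconnected from behavior: interaction and gain both zero
  cfg <- sim_config(
    n_subjects = 8L,
    models = list(BAS_Fun_Seeking = response_coefficients(
      "BAS_Fun_Seeking", beta_hmi = 0, beta_interaction = 0)),
    weights = 1, cruise_factor_gain = 0,
    course = course_spec(n_lights_per_lap = 4L, n_yellow_per_lap = 2L,
                         lap_order = c("practice", "baseline", "hmi",
                                       "hmi")),
    seed = 21L)
  b <- generate_dataset(cfg)
  rep <- suppressWarnings(loocv_evaluate(
    b, enc_config = quick_encoder_config(epochs = 4L), n_seeds = 3L,
    seed_base = 1L, window_T = 15L, snippets_per_subject = 4L))
  ps <- rep$per_seed_speeds
  diffs <- ps$window_averaged[, 1] - ps$random[, 1]
  p <- tryCatch(stats::t.test(diffs)$p.value, error = function(e) 1)
  expect_gt(p, 0.05)
})
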