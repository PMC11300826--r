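#' Sample a synthetic subject population
#'
#' Draws per-subject cognitive scores from the configured Normal marginals
#' (independent by default, or with a given correlation matrix via Cholesky)
#' plus a Normal per-subject random intercept for the yellow-speed response.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param specs Named list of [factor_spec()].
#' @param seed Integer seed.
#' @param random_intercept_sd Between-subject SD of the random intercept, m/s.
#' @param correlation Optional correlation matrix across factors, in the
#'   order of `specs`.
#' @return data.frame: `subject_id`, one column per factor (raw score),
#'   `random_intercept`.
#' @export
sample_population <- function(n_subjects, specs = default_factor_specs(),
                              seed = 1L, random_intercept_sd = 2.69,
                              correlation = NULL) {
  if (n_subjects < 2L) stop("sample_population: need n_subjects >= 2")
  sds <- vapply(specs, `[[`, 0, "sd")
  if (any(sds <= 0)) stop("sample_population: all factor sds must be > 0")
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("sample_population: duplicate factor names")
  k <- length(specs)
  withr_seed(seed)
  zmat <- matrix(stats::rnorm(n_subjects * k), n_subjects, k)
  if (!is.null(correlation)) {
    ch <- chol(correlation)   # fails on non-PD input, intentionally
    zmat <- zmat %*% ch
  }
  scores <- sweep(sweep(zmat, 2, sds, `*`), 2,
                  vapply(specs, `[[`, 0, "mean"), `+`)
  colnames(scores) <- nms
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    scores,
    random_intercept = stats::rnorm(n_subjects, 0, random_intercept_sd),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Seed the global RNG stream (no-op for NULL). Every stochastic entry point
# takes an explicit seed so that results are reproducible end to end.
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Expected mean yellow-light speed under one response model
#'
#' The mixed-model mean structure: `intercept + beta_hmi * HMI +
#' beta_factor * f + beta_interaction * HMI * f + random_intercept`, with no
#' residual noise.
#'
#' @param profile Named numeric vector of raw cognitive scores (must contain
#'   the model's factor).
#' @param hmi_present 0/1 or logical flag.
#' @param coeffs A [response_coefficients()].
#' @param random_intercept Subject random intercept, m/s (default 0).
#' @return Expected mean yellow-phase speed, m/s.
#' @export
response_model_mean_speed <- function(profile, hmi_present, coeffs,
                                      random_intercept = 0) {
  if (!coeffs$factor %in% names(profile))
    stop("response_model_mean_speed: profile has no measure named '",
         coeffs$factor, "'")
  f <- as.numeric(profile[[coeffs$factor]])
  h <- as.numeric(hmi_present)
  coeffs$intercept + coeffs$beta_hmi * h + coeffs$beta_factor * f +
    coeffs$beta_interaction * h * f + random_intercept
}

# Weighted composite yellow-speed linear predictor for a subject row under
# a sim_config (shared intercept = weighted mean of model intercepts).
composite_yellow_predictor <- function(subject, hmi_present, config,
                                       include_random = TRUE) {
  w <- config$weights / sum(config$weights)
  h <- as.numeric(hmi_present)
  eta <- sum(w * vapply(config$models, `[[`, 0, "intercept"))
  for (j in seq_along(config$models)) {
    m <- config$models[[j]]
    f <- as.numeric(subject[[m$factor]])
    eta <- eta + w[j] * (m$beta_hmi * h + m$beta_factor * f +
                           m$beta_interaction * h * f)
  }
  if (include_random) eta <- eta + as.numeric(subject[["random_intercept"]])
  eta
}

# Sign-corrected standardized factor composite (unit variance under
# independent factors); drives the cruise-speed trait expression.
composite_factor_z <- function(subject, config) {
  w <- config$weights / sum(config$weights)
  z <- 0
  for (j in seq_along(config$models)) {
    fac <- config$models[[j]]$factor
    sp <- config$specs[[fac]]
    z <- z + w[j] * sp$sign_vs_yellow_speed * (as.numeric(subject[[fac]]) -
                                                 sp$mean) / sp$sd
  }
  z / sqrt(sum(w^2))
}

condition_label <- function(condition) {
  if (condition$interface_type == "none") "baseline"
  else paste(condition$interface_type, condition$trigger, sep = "_")
}

#' Simulate one lap for one subject
#'
#' Kinematic realization of the statistical target: the subject cruises at a
#' trait- and subject-specific speed; at each of the lap's yellow approaches
#' the light turns yellow at a random time-to-arrival inside the dilemma
#' window, a stop/go tendency (logistic in the same linear predictor) picks
#' the ramp direction, and the yellow-phase speed profile is shifted so its
#' mean equals the response-model mean plus Normal residual noise exactly.
#' Acceleration is the finite difference of speed, so speed integrates
#' acceleration by construction.
#'
#' @param subject One-row data.frame from [sample_population()].
#' @param condition An [hmi_condition()].
#' @param course A [course_spec()] (geometry; the lap schedule is ignored
#'   here).
#' @param config A [sim_config()] supplying response models and noise levels.
#' @param lap_id Integer lap index recorded in the log.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param practice Logical; recorded in the `condition` column as
#'   `"practice"` when the lap is the acclimation baseline.
#' @return Trajectory log data.frame with columns `time_s`, `speed_mps`,
#'   `accel_mps2`, `dist_to_light_m`, `light_phase` (G/Y/R), `hmi_active`,
#'   `approach_idx`, `lap_id`, `condition`, `subject_id`.
#' @export
simulate_lap <- function(subject, condition, course = course_spec(),
                         config = default_sim_config(), lap_id = 1L,
                         seed = NULL, practice = FALSE) {
  if (!is.null(seed)) withr_seed(seed)
  dt <- config$dt
  hmi_present <- condition$interface_type != "none"
  label <- if (practice) "practice" else condition_label(condition)

  yellow_set <- sort(sample.int(course$n_lights_per_lap,
                                course$n_yellow_per_lap))
  eta_yellow <- composite_yellow_predictor(subject, hmi_present, config)
  eta_base <- composite_yellow_predictor(subject, FALSE, config,
                                         include_random = FALSE) +
    as.numeric(subject[["random_intercept"]])
  v_cruise <- max(5, eta_base + config$cruise_factor_gain *
                    composite_factor_z(subject, config))
  shared_intercept <- sum((config$weights / sum(config$weights)) *
                            vapply(config$models, `[[`, 0, "intercept"))

  pieces <- vector("list", course$n_lights_per_lap)
  for (i in seq_len(course$n_lights_per_lap)) {
    is_yellow <- i %in% yellow_set
    if (is_yellow) {
      tta <- stats::runif(1, config$tta_range[1], config$tta_range[2])
      t_onset <- (course$light_spacing - v_cruise * tta) / v_cruise
      n_pre <- max(2L, as.integer(round(t_onset / dt)))
      n_y <- max(2L, as.integer(round(config$yellow_duration / dt)))
      n_post <- as.integer(round(1.0 / dt))

      # smooth AR(1) cruise jitter, stationary sd = cruise_jitter_sd
      rho <- 0.97
      innov <- stats::rnorm(n_pre, 0, config$cruise_jitter_sd *
                              sqrt(1 - rho^2))
      jit <- as.numeric(stats::filter(innov, rho, method = "recursive"))
      v_pre <- pmax(0, v_cruise + jit)

      v_y_mean <- eta_yellow + stats::rnorm(1, 0, config$residual_sd)
      p_go <- stats::plogis((eta_yellow - shared_intercept) / 2)
      go <- stats::runif(1) < p_go
      slope <- if (go) 0.3 else -1.5                    # m/s^2 ramp
      idx <- seq_len(n_y)
      v_yellow <- pmax(0, v_y_mean + slope * dt * (idx - mean(idx)))
      v_post <- v_yellow[n_y] + (v_cruise - v_yellow[n_y]) *
        seq_len(n_post) / n_post
      speed <- c(v_pre, v_yellow, v_post)
      phase <- c(rep("G", n_pre), rep("Y", n_y), rep("R", n_post))
    } else {
      n_app <- max(2L, as.integer(ceiling(course$light_spacing /
                                            (v_cruise * dt))))
      rho <- 0.97
      innov <- stats::rnorm(n_app, 0, config$cruise_jitter_sd *
                              sqrt(1 - rho^2))
      jit <- as.numeric(stats::filter(innov, rho, method = "recursive"))
      speed <- pmax(0, v_cruise + jit)
      phase <- rep("G", n_app)
    }
    dist <- course$light_spacing - cumsum(c(0, speed[-length(speed)])) * dt
    hmi <- rep(0L, length(speed))
    if (hmi_present) {
      if (condition$trigger == "distance") {
        hmi[dist <= course$trigger_distance] <- 1L
      } else if (is_yellow) {
        hmi[phase != "G"] <- 1L
      }
    }
    pieces[[i]] <- data.frame(
      speed_mps = speed, dist_to_light_m = dist, light_phase = phase,
      hmi_active = hmi, approach_idx = i, stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, pieces)
  n <- nrow(log)
  log$time_s <- (seq_len(n) - 1L) * dt
  log$accel_mps2 <- c(0, diff(log$speed_mps) / dt)
  log$lap_id <- as.integer(lap_id)
  log$condition <- label
  log$subject_id <- subject$subject_id
  log[, c("time_s", "speed_mps", "accel_mps2", "dist_to_light_m",
          "light_phase", "hmi_active", "approach_idx", "lap_id",
          "condition", "subject_id")]
}

#' Generate a full synthetic study dataset
#'
#' Samples a population, runs every subject through the configured lap
#' schedule (default: practice baseline, analysis baseline, then the four
#' HMI variants in randomized order per subject), and assembles trajectory
#' logs plus subject and trial tables, all cross-referenced by subject id
#' and fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return A `dataset_bundle`: list with `subjects`, `log` (all laps,
#'   row-bound), `trials` (one row per light approach, practice laps
#'   flagged), `lap_schedule`, and `config`.
#' @export
generate_dataset <- function(config = default_sim_config()) {
  lap_order <- config$course$lap_order
  n_hmi_laps <- sum(lap_order == "hmi")
  if (n_hmi_laps > 0 && n_hmi_laps %% length(hmi_variants()) != 0 &&
      n_hmi_laps > length(hmi_variants()))
    stop("generate_dataset: hmi lap count incompatible with the 4 variants")
  withr_seed(config$seed)
  subjects <- sample_population(config$n_subjects, config$specs,
                                seed = sample.int(2^31 - 2, 1),
                                random_intercept_sd =
                                  config$random_intercept_sd,
                                correlation = config$correlation)
  logs <- list()
  sched <- list()
  variants <- hmi_variants()
  for (s in seq_len(config$n_subjects)) {
    subj <- subjects[s, , drop = FALSE]
    order_hmi <- sample.int(length(variants))
    hmi_i <- 0L
    for (l in seq_along(lap_order)) {
      kind <- lap_order[l]
      if (kind == "hmi") {
        hmi_i <- hmi_i + 1L
        cond <- variants[[order_hmi[(hmi_i - 1L) %% length(variants) + 1L]]]
      } else {
        cond <- hmi_condition("none")
      }
      lap_log <- simulate_lap(subj, cond, config$course, config,
                              lap_id = l, seed = sample.int(2^31 - 2, 1),
                              practice = (kind == "practice"))
      logs[[length(logs) + 1L]] <- lap_log
      sched[[length(sched) + 1L]] <- data.frame(
        subject_id = subj$subject_id, lap_id = l,
        condition = lap_log$condition[1],
        is_practice = (kind == "practice"),
        hmi_present = cond$interface_type != "none",
        stringsAsFactors = FALSE)
    }
  }
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  lap_schedule <- do.call(rbind, sched)
  trials <- build_trial_table(log)
  trials$is_practice <- trials$condition == "practice"
  structure(list(subjects = subjects, log = log, trials = trials,
                 lap_schedule = lap_schedule, config = config),
            class = "dataset_bundle")
}

#' Analysis trials (practice lap excluded)
#'
#' @param bundle A `dataset_bundle` from [generate_dataset()].
#' @return The trial table without practice-lap rows.
#' @export
analysis_trials <- function(bundle) {
  bundle$trials[!bundle$trials$is_practice, , drop = FALSE]
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("Synthetic driving study:", nrow(x$subjects), "subjects,",
      length(unique(x$lap_schedule$lap_id)), "laps/subject,",
      nrow(x$trials), "light approaches\n")
  invisible(x)
}
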