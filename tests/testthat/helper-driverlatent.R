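# Shared fixtures, built in code. Expensive objects are cached per test run.

# Reduced encoder settings used throughout the suite: 2.5 s windows at
# 10 Hz, hidden size 8, 60 epochs at lr 3e-3 (the full-size exported
# defaults are too slow for a CPU test run; see the methods vignette).
quick_encoder_config <- function(seed = 1L, epochs = 60L) {
  encoder_config(hidden_size = 8L, epochs = epochs, learning_rate = 3e-3,
                 batch_size = 64L, seed = seed)
}

quick_window <- 25L

# Small study: 5 subjects, 1 practice + 1 baseline + 2 HMI laps, 4 lights.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_subjects = 5L,
             course = course_spec(n_lights_per_lap = 4L,
                                  n_yellow_per_lap = 2L,
                                  lap_order = c("practice", "baseline",
                                                "hmi", "hmi")),
             seed = seed, ...)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

strong_bundle <- function() {
  cached("strong_bundle", generate_dataset(strong_sim_config(seed = 1L)))
}

strong_snippets <- function() {
  cached("strong_snippets", {
    b <- strong_bundle()
    log <- b$log[b$log$condition != "practice", , drop = FALSE]
    extract_snippets(log, window_T = quick_window)
  })
}

small_bundle <- function() {
  cached("small_bundle", generate_dataset(small_sim_config(seed = 3L)))
}

# A tiny hand-built trajectory log (one subject, one lap, one yellow
# approach) for io unit tests.
toy_log <- function(n_pre = 30L, yellow_speeds = rep(15, 10), dt = 0.1) {
  speed <- c(rep(20, n_pre), yellow_speeds, rep(18, 5))
  n <- length(speed)
  phase <- c(rep("G", n_pre), rep("Y", length(yellow_speeds)), rep("R", 5))
  data.frame(
    time_s = (seq_len(n) - 1) * dt,
    speed_mps = speed,
    accel_mps2 = c(0, diff(speed) / dt),
    dist_to_light_m = 400 - cumsum(c(0, speed[-n])) * dt,
    light_phase = phase,
    hmi_active = 0L,
    approach_idx = 1L,
    lap_id = 1L,
    condition = "baseline",
    subject_id = "S01",
    stringsAsFactors = FALSE)
}

# Brute-force contrastive loss: explicit double loop over ordered pairs,
# independent of the vectorized implementation.
contrastive_brute <- function(z, y, epsilon) {
  B <- nrow(z)
  s <- matrix(0, B, B)
  for (i in 1:B) for (j in 1:B) s[i, j] <- sum((y[i, ] - y[j, ])^2)
  mx <- max(s)
  if (mx > 0) s <- s / mx
  s <- pmin(pmax(s, 0), 1)
  total <- 0
  for (i in 1:B) for (j in 1:B) {
    if (i == j) next
    d <- sqrt(sum((z[i, ] - z[j, ])^2))
    total <- total + (1 - s[i, j]) * d^2 + s[i, j] * max(0, epsilon - d)^2
  }
  total / (B * (B - 1))
}

# 1-D KL(q || N(0,1)) by quadrature; independent of the closed form.
kl_quadrature_1d <- function(mu, lv) {
  sd_q <- exp(lv / 2)
  f <- function(x) {
    q <- stats::dnorm(x, mu, sd_q)
    ifelse(q > 0, q * (stats::dnorm(x, mu, sd_q, log = TRUE) -
                         stats::dnorm(x, log = TRUE)), 0)
  }
  stats::integrate(f, mu - 12 * sd_q - 12, mu + 12 * sd_q + 12,
                   rel.tol = 1e-10)$value
}

# Points with exact sample moments: mean `m`, covariance `S`.
exact_moment_points <- function(n, m, S, seed = 1L) {
  set.seed(seed)
  d <- length(m)
  x <- matrix(stats::rnorm(n * d), n, d)
  x <- sweep(x, 2, colMeans(x))
  x <- x %*% solve(chol(stats::cov(x)))
  x <- x %*% chol(S)
  sweep(x, 2, m, `+`)
}
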