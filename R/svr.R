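#' Per-subject HMI speed-reduction target
#'
#' The decision model's regression target: the subject's mean yellow-phase
#' speed over HMI trials minus the mean over no-HMI trials. Negative means
#' the HMI slowed this subject down (beneficial).
#'
#' @param trials Trial table rows for one subject (practice laps should
#'   already be excluded); only `had_yellow` rows are used.
#' @return Speed delta, m/s.
#' @export
compute_speed_delta_target <- function(trials) {
  tr <- trials[trials$had_yellow, , drop = FALSE]
  subj <- unique(trials$subject_id)
  if (length(subj) != 1L)
    stop("compute_speed_delta_target: expected trials for one subject")
  hmi <- tr$mean_yellow_speed[tr$hmi_present]
  base <- tr$mean_yellow_speed[!tr$hmi_present]
  if (length(hmi) == 0L || length(base) == 0L)
    stop("compute_speed_delta_target: subject ", subj,
         " lacks yellow trials in ",
         if (length(hmi) == 0L) "the HMI condition" else "the no-HMI condition")
  mean(hmi) - mean(base)
}

# Polynomial kernel (gamma * <x, x'> + coef0)^degree.
poly_kernel <- function(X, Y = NULL, degree = 3, gamma = 1, coef0 = 1) {
  if (is.null(Y)) Y <- X
  (gamma * tcrossprod(as.matrix(X), as.matrix(Y)) + coef0)^degree
}

# Epsilon-insensitive SVR on the bias-free dual (targets centered, constant
# component carried by coef0): minimize 0.5 b'Kb - b'y + eps * sum|b| over
# b in [-C, C]^n by cyclic coordinate descent with closed-form updates.
svr_fit <- function(X, y, degree = 3, C = 1, epsilon = 0.1, gamma = 1,
                    coef0 = 1, tol = 1e-8, max_iter = 1000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("svr_fit: need at least 2 training points")
  y_center <- mean(y)
  y0 <- y - y_center
  K <- poly_kernel(X, degree = degree, gamma = gamma, coef0 = coef0)
  beta <- numeric(n)
  f <- numeric(n)                       # K %*% beta, kept incrementally
  soft <- function(r, e) sign(r) * max(0, abs(r) - e)
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      kii <- K[i, i]
      if (kii <= 0) next
      r <- y0[i] - f[i] + kii * beta[i]
      bi <- min(C, max(-C, soft(r, epsilon) / kii))
      d <- bi - beta[i]
      if (d != 0) {
        f <- f + d * K[, i]
        beta[i] <- bi
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  structure(
    list(X = X, beta = beta, y_center = y_center, degree = degree, C = C,
         epsilon = epsilon, gamma = gamma, coef0 = coef0,
         iterations = it, fitted = f + y_center),
    class = "svr_poly"
  )
}

svr_predict <- function(model, Xnew) {
  Kn <- poly_kernel(as.matrix(Xnew), model$X, degree = model$degree,
                    gamma = model$gamma, coef0 = model$coef0)
  as.numeric(Kn %*% model$beta + model$y_center)
}

#' Fit the HMI decision model
#'
#' Support-vector regression with a polynomial kernel mapping each snippet's
#' latent mean to its subject's single speed-delta target (a many-to-one
#' function). Deterministic: the solver is cyclic coordinate descent with no
#' randomness.
#'
#' @param latents Matrix of latent means (one row per snippet).
#' @param subject_ids Subject id per row of `latents`.
#' @param targets Named numeric vector: per-subject speed delta
#'   ([compute_speed_delta_target()]), m/s.
#' @param degree,C,epsilon,gamma,coef0 Kernel / SVR hyperparameters
#'   (defaults: cubic kernel, C = 1, epsilon-tube 0.1). `gamma = NULL`
#'   (default) uses the scale-invariant convention
#'   `1 / (latent_dim * mean latent variance)`, so the kernel resolves
#'   structure at whatever scale the KL-regularized embedding settled on.
#' @param threshold Deploy threshold on the predicted delta, m/s (default 0).
#' @return Object of class `decision_model`.
#' @export
fit_decision_model <- function(latents, subject_ids, targets, degree = 3,
                               C = 1, epsilon = 0.1, gamma = NULL, coef0 = 1,
                               threshold = 0) {
  latents <- as.matrix(latents)
  if (length(subject_ids) != nrow(latents))
    stop("fit_decision_model: one subject id per latent row required")
  if (length(unique(subject_ids)) < 2L)
    stop("fit_decision_model: need latents from at least 2 subjects")
  missing <- setdiff(unique(subject_ids), names(targets))
  if (length(missing))
    stop("fit_decision_model: no target for subject(s): ",
         paste(missing, collapse = ", "))
  y <- as.numeric(targets[subject_ids])
  if (is.null(gamma)) {
    v <- mean(apply(latents, 2, stats::var))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(latents) * v) else 1
  }
  svr <- svr_fit(latents, y, degree = degree, C = C, epsilon = epsilon,
                 gamma = gamma, coef0 = coef0)
  structure(list(svr = svr, threshold = threshold, fitted = TRUE),
            class = "decision_model")
}

#' Predict the speed delta for a latent
#'
#' @param model A `decision_model`.
#' @param z Latent vector, or matrix with one latent per row.
#' @return Predicted speed delta(s), m/s.
#' @export
predict_delta <- function(model, z) {
  if (!inherits(model, "decision_model") || !isTRUE(model$fitted))
    stop("predict_delta: model is not a fitted decision_model")
  zz <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  svr_predict(model$svr, zz)
}

#' Instantaneous deploy decision
#'
#' Deploy the HMI iff the predicted speed delta is strictly below the
#' threshold (ties withhold).
#'
#' @param model A `decision_model`.
#' @param z A single latent vector.
#' @return Logical: deploy?
#' @export
decide_instantaneous <- function(model, z) {
  predict_delta(model, z) < model$threshold
}

#' Window-averaged deploy decision
#'
#' Deploy iff the mean predicted delta over the subject's recent snippet
#' latents is strictly below the threshold. Invariant to snippet order.
#'
#' @param model A `decision_model`.
#' @param latents Matrix of the subject's snippet latent means (>= 1 row).
#' @return Logical: deploy?
#' @export
decide_window_averaged <- function(model, latents) {
  latents <- as.matrix(latents)
  if (nrow(latents) == 0L)
    stop("decide_window_averaged: empty latent window")
  mean(predict_delta(model, latents)) < model$threshold
}

#' Save / load a decision model as JSON
#'
#' @param model A `decision_model`.
#' @param path Output `.json` path.
#' @return `load_decision_model`: the restored model.
#' @export
save_decision_model <- function(model, path) {
  stopifnot(inherits(model, "decision_model"))
  s <- model$svr
  obj <- list(X = list(dim = dim(s$X), data = as.numeric(s$X)),
              beta = s$beta, y_center = s$y_center, degree = s$degree,
              C = s$C, epsilon = s$epsilon, gamma = s$gamma,
              coef0 = s$coef0, threshold = model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_decision_model
#' @export
load_decision_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  svr <- structure(
    list(X = matrix(o$X$data, o$X$dim[1], o$X$dim[2]),
         beta = as.numeric(o$beta), y_center = o$y_center,
         degree = o$degree, C = o$C, epsilon = o$epsilon, gamma = o$gamma,
         coef0 = o$coef0),
    class = "svr_poly")
  structure(list(svr = svr, threshold = o$threshold, fitted = TRUE),
            class = "decision_model")
}
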