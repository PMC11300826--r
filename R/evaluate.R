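#' Counterfactual mean yellow-light speed under a decision policy
#'
#' Treats the study as a within-subject randomized trial: each subject's
#' outcome is the average of `mean_yellow_speed` over the yellow trials whose
#' experimental condition (HMI present or not) matches the policy's
#' decision. Aggregates the per-subject values into a mean and standard
#' error across subjects. Subjects with no matching trials are excluded with
#' a warning and counted.
#'
#' @param decisions Either a named logical vector (one deploy decision per
#'   subject) or a data.frame with `subject_id`, `lap_id`, `approach_idx`,
#'   `deploy` for per-trial decisions.
#' @param trials Trial table (practice laps should already be excluded).
#' @return List with `mean`, `se`, `per_subject` (named vector) and
#'   `n_excluded`.
#' @export
counterfactual_yellow_speed <- function(decisions, trials) {
  tr <- trials[trials$had_yellow, , drop = FALSE]
  per_trial <- is.data.frame(decisions)
  if (per_trial) {
    key_t <- paste(tr$subject_id, tr$lap_id, tr$approach_idx)
    key_d <- paste(decisions$subject_id, decisions$lap_id,
                   decisions$approach_idx)
    tr$deploy <- decisions$deploy[match(key_t, key_d)]
    tr <- tr[!is.na(tr$deploy), , drop = FALSE]
    subjects <- unique(tr$subject_id)
  } else {
    subjects <- names(decisions)
    tr <- tr[tr$subject_id %in% subjects, , drop = FALSE]
    tr$deploy <- as.logical(decisions[tr$subject_id])
  }
  vals <- vapply(subjects, function(s) {
    g <- tr[tr$subject_id == s & tr$hmi_present == tr$deploy, , drop = FALSE]
    if (nrow(g) == 0L) NA_real_ else mean(g$mean_yellow_speed)
  }, 0)
  excluded <- sum(is.na(vals))
  if (excluded > 0L)
    warning("counterfactual_yellow_speed: ", excluded,
            " subject(s) had no trials matching their decision; excluded")
  vals <- vals[!is.na(vals)]
  list(mean = mean(vals),
       se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
       else NA_real_,
       per_subject = vals, n_excluded = excluded)
}

#' Agreement between deploy decisions and benefit labels
#'
#' Cohen's kappa (chance-corrected agreement) and balanced accuracy (mean of
#' the per-class recalls) of binary decisions against binary labels
#' (`TRUE` = the subject's measured speed delta is negative, i.e. the HMI
#' should be deployed).
#'
#' @param decisions Logical vector.
#' @param labels Logical vector of the same length, containing both classes.
#' @return List with `kappa` and `balanced_accuracy`.
#' @export
decision_agreement_metrics <- function(decisions, labels) {
  decisions <- as.logical(decisions); labels <- as.logical(labels)
  if (length(decisions) != length(labels))
    stop("decision_agreement_metrics: length mismatch")
  if (length(unique(labels)) < 2L)
    stop("decision_agreement_metrics: labels contain a single class; ",
         "balanced accuracy is undefined")
  po <- mean(decisions == labels)
  pe <- mean(decisions) * mean(labels) +
    (1 - mean(decisions)) * (1 - mean(labels))
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
  recall_pos <- mean(decisions[labels])
  recall_neg <- mean(!decisions[!labels])
  list(kappa = kappa, balanced_accuracy = (recall_pos + recall_neg) / 2)
}

# KL(N(m0,S0) || N(m1,S1)) in closed form.
gaussian_kl <- function(m0, S0, m1, S1) {
  d <- length(m0)
  S1i <- solve(S1)
  dm <- m1 - m0
  0.5 * (sum(diag(S1i %*% S0)) + as.numeric(t(dm) %*% S1i %*% dm) - d +
           determinant(S1)$modulus - determinant(S0)$modulus)
}

#' Normalized KL separation of an embedding by a cognitive factor
#'
#' Splits the rows at the factor median, fits a Gaussian (mean, covariance)
#' to each group's latents, and returns the symmetrized KL divergence
#' between the two fitted Gaussians divided by 0.5 — the KL of two
#' identity-covariance Gaussians at unit separation — so 1.0 means "as
#' separated as an ideal unit-distance clustering". Singular covariances are
#' ridge-regularized with a warning.
#'
#' @param latents Matrix of latent means (rows = snippets or subjects).
#' @param factor_values Numeric factor value per row.
#' @param ridge Ridge added to a singular covariance.
#' @return Normalized separation (>= 0).
#' @export
kl_separation <- function(latents, factor_values, ridge = 1e-6) {
  latents <- as.matrix(latents)
  if (nrow(latents) != length(factor_values))
    stop("kl_separation: one factor value per latent row required")
  med <- stats::median(factor_values)
  lo <- factor_values <= med
  if (sum(lo) < 2L || sum(!lo) < 2L)
    stop("kl_separation: need at least 2 rows per median-split group")
  fit_group <- function(x) {
    S <- stats::cov(x)
    if (!is.finite(determinant(S)$modulus) ||
        rcond(S) < .Machine$double.eps * 100) {
      warning("kl_separation: singular covariance; ridge-regularized")
      S <- S + diag(ridge, ncol(x))
    }
    list(m = colMeans(x), S = S)
  }
  a <- fit_group(latents[lo, , drop = FALSE])
  b <- fit_group(latents[!lo, , drop = FALSE])
  sym <- 0.5 * (gaussian_kl(a$m, a$S, b$m, b$S) +
                  gaussian_kl(b$m, b$S, a$m, a$S))
  as.numeric(sym / 0.5)
}

#' Stepwise selection of behavior-predictive measures
#'
#' Forward selection (add the candidate producing the largest fit gain) with
#' interleaved backward elimination on a linear model of the per-subject
#' behavior statistic. The default criterion controls the family-wise error
#' on a null population: a candidate enters only if its partial t-test
#' survives a Bonferroni-corrected threshold `alpha / n_candidates`, and an
#' included measure is dropped when it no longer does. Penalized-fit
#' criteria (`"adjr2"`, `"aic"`, `"bic"`) are available but admit noise
#' predictors at a non-trivial rate.
#'
#' @param candidates data.frame or matrix of candidate measures (columns).
#' @param behavior Numeric behavior statistic per row.
#' @param criterion `"bonferroni"` (default), `"adjr2"`, `"aic"` or
#'   `"bic"`.
#' @param alpha Family-wise level for `"bonferroni"`.
#' @return Character vector of selected measure names (possibly empty).
#' @export
stepwise_select <- function(candidates, behavior,
                            criterion = c("bonferroni", "adjr2", "aic",
                                          "bic"),
                            alpha = 0.05) {
  criterion <- match.arg(criterion)
  candidates <- as.data.frame(candidates)
  nms <- names(candidates)
  k <- length(nms)
  dat <- cbind(.y = behavior, candidates)
  fit_with <- function(vars) {
    form <- if (length(vars) == 0L) .y ~ 1
    else stats::reformulate(vars, response = ".y")
    stats::lm(form, data = dat)
  }
  score <- function(fit) switch(
    criterion,
    adjr2 = summary(fit)$adj.r.squared,
    aic = -stats::AIC(fit),
    bic = -stats::BIC(fit),
    bonferroni = NA_real_)
  pval_of <- function(fit, var) {
    tab <- summary(fit)$coefficients
    if (!var %in% rownames(tab)) return(1)
    tab[var, 4]
  }
  included <- character(0)
  repeat {
    changed <- FALSE
    # forward: best addition
    pool <- setdiff(nms, included)
    if (length(pool)) {
      if (criterion == "bonferroni") {
        ps <- vapply(pool, function(v)
          pval_of(fit_with(c(included, v)), v), 0)
        best <- pool[which.min(ps)]
        if (min(ps) < alpha / k) { included <- c(included, best)
          changed <- TRUE }
      } else {
        cur <- score(fit_with(included))
        sc <- vapply(pool, function(v) score(fit_with(c(included, v))), 0)
        if (max(sc) > cur + 1e-10) {
          included <- c(included, pool[which.max(sc)]); changed <- TRUE }
      }
    }
    # backward: worst removal
    if (length(included) > 1L || (length(included) == 1L &&
                                  criterion != "bonferroni")) {
      if (criterion == "bonferroni") {
        fit <- fit_with(included)
        ps <- vapply(included, function(v) pval_of(fit, v), 0)
        if (max(ps) >= alpha / k) {
          included <- setdiff(included, included[which.max(ps)])
          changed <- TRUE }
      } else {
        cur <- score(fit_with(included))
        sc <- vapply(included, function(v)
          score(fit_with(setdiff(included, v))), 0)
        if (max(sc) > cur + 1e-10) {
          included <- setdiff(included, included[which.max(sc)])
          changed <- TRUE }
      }
    }
    if (!changed) break
  }
  included
}

#' OLS refit of the HMI-by-factor interaction with subject indicators
#'
#' Calibration check for the simulator: regresses mean yellow-phase speed on
#' subject indicator variables, HMI presence, and the HMI-by-factor
#' interaction over the analysis yellow trials, and returns the estimated
#' HMI main effect and interaction with their standard errors.
#'
#' @param bundle A `dataset_bundle`.
#' @param factor Factor name.
#' @return List with `beta_hmi`, `se_hmi`, `beta_interaction`,
#'   `se_interaction`, `n_trials`.
#' @export
refit_interaction <- function(bundle, factor) {
  tr <- analysis_trials(bundle)
  tr <- tr[tr$had_yellow, , drop = FALSE]
  tr$f <- bundle$subjects[[factor]][match(tr$subject_id,
                                          bundle$subjects$subject_id)]
  tr$h <- as.numeric(tr$hmi_present)
  fit <- stats::lm(mean_yellow_speed ~ 0 + subject_id + h + h:f, data = tr)
  tab <- summary(fit)$coefficients
  list(beta_hmi = tab["h", 1], se_hmi = tab["h", 2],
       beta_interaction = tab["h:f", 1], se_interaction = tab["h:f", 2],
       n_trials = nrow(tr))
}

#' Mixed-model variance partition of a generated dataset
#'
#' Fits `mean_yellow_speed ~ HMI * factor + (1 | subject)` with lme4 on the
#' analysis yellow trials and returns the marginal and conditional variance
#' explained (fixed effects alone, and fixed plus random intercept).
#'
#' @param bundle A `dataset_bundle`.
#' @param factor Factor name.
#' @return List with `r2_marginal`, `r2_conditional`.
#' @export
refit_variance_partition <- function(bundle, factor) {
  tr <- analysis_trials(bundle)
  tr <- tr[tr$had_yellow, , drop = FALSE]
  tr$f <- bundle$subjects[[factor]][match(tr$subject_id,
                                          bundle$subjects$subject_id)]
  tr$h <- as.numeric(tr$hmi_present)
  fit <- lme4::lmer(mean_yellow_speed ~ h * f + (1 | subject_id), data = tr,
                    REML = TRUE)
  var_fixed <- stats::var(as.numeric(lme4::getME(fit, "X") %*%
                                       lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- vc$vcov[vc$grp == "subject_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  total <- var_fixed + var_rand + var_resid
  list(r2_marginal = var_fixed / total,
       r2_conditional = (var_fixed + var_rand) / total)
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For each seed and each held-out subject: trains the encoder on the other
#' subjects' pre-transition snippets (factor standardization refit on the
#' training subjects only), fits the SVR decision model on the training
#' subjects' latent means and speed-delta targets, encodes the held-out
#' subject's snippets, and records window-averaged and instantaneous deploy
#' decisions. Policies are scored counterfactually over matching-condition
#' trials and against the measured benefit labels; embedding separation is
#' computed per factor on each fold's training embedding (latent spaces are
#' fold-specific, so folds are never pooled) and averaged over folds.
#' Metrics are averaged over seeds.
#'
#' @param bundle A `dataset_bundle`.
#' @param enc_config An [encoder_config()].
#' @param decision_hyper Named list of [fit_decision_model()] hyperparameters.
#' @param n_seeds Number of seeds (the seed list is `seed_base + 0:(n-1)`).
#' @param seed_base First seed.
#' @param window_T Snippet window length (steps).
#' @param snippets_per_subject Optional cap on snippets per subject (random
#'   subsample, seeded) to bound training cost.
#' @return Object of class `eval_report`: `policy_speeds` (per-policy mean /
#'   SE of counterfactual yellow speed, averaged over seeds), `agreement`
#'   (kappa and balanced accuracy per policy), `kl` (per-factor normalized
#'   separation), `labels`, per-seed `decisions`, `fold_subjects`,
#'   `excluded_subjects`, and `seeds`.
#' @export
loocv_evaluate <- function(bundle, enc_config = encoder_config(),
                           decision_hyper = list(), n_seeds = 10L,
                           seed_base = 1L, window_T = 100L,
                           snippets_per_subject = NULL) {
  trials <- analysis_trials(bundle)
  subjects <- bundle$subjects$subject_id
  if (length(subjects) < 3L) stop("loocv_evaluate: need >= 3 subjects")

  targets <- numeric(0)
  excluded <- character(0)
  for (s in subjects) {
    tt <- trials[trials$subject_id == s, , drop = FALSE]
    val <- tryCatch(compute_speed_delta_target(tt), error = function(e) NA)
    if (is.na(val)) excluded <- c(excluded, s) else targets[s] <- val
  }
  if (length(excluded))
    warning("loocv_evaluate: excluded subject(s) without both conditions: ",
            paste(excluded, collapse = ", "))
  subjects <- setdiff(subjects, excluded)
  labels <- targets[subjects] < 0
  if (length(unique(labels)) < 2L)
    warning("loocv_evaluate: benefit labels are single-class; agreement ",
            "metrics will be unavailable")

  log <- bundle$log[bundle$log$condition != "practice" &
                      bundle$log$subject_id %in% subjects, , drop = FALSE]
  snips <- extract_snippets(log, window_T = window_T)
  if (!is.null(snippets_per_subject)) {
    withr_seed(seed_base * 7919L %% (2^31 - 2))
    keep <- unlist(lapply(split(seq_along(snips$snippets),
                                vapply(snips$snippets, `[[`, "",
                                       "subject_id")),
                          function(ix) if (length(ix) <= snippets_per_subject)
                            ix else sort(sample(ix, snippets_per_subject))))
    snips$snippets <- snips$snippets[sort(keep)]
  }
  snip_subj <- vapply(snips$snippets, `[[`, "", "subject_id")
  snip_lap <- vapply(snips$snippets, `[[`, 0L, "lap_id")
  snip_app <- vapply(snips$snippets, function(s) as.integer(s$approach_idx),
                     0L)

  seeds <- seed_base + seq_len(n_seeds) - 1L
  policies <- c("no_hmi", "always", "random", "window_averaged",
                "instantaneous")
  speed_acc <- stats::setNames(vector("list", length(policies)), policies)
  agree_acc <- list()
  kl_acc <- list()
  decisions_all <- list()
  fold_subjects <- stats::setNames(vector("list", length(subjects)),
                                   subjects)

  for (sd_i in seeds) {
    wa_dec <- stats::setNames(logical(length(subjects)), subjects)
    inst_dec <- data.frame(subject_id = character(), lap_id = integer(),
                           approach_idx = integer(), deploy = logical(),
                           stringsAsFactors = FALSE)
    pooled_lat <- matrix(numeric(0), 0, enc_config$latent_dim)
    pooled_subj <- character(0)
    for (s in subjects) {
      tr_idx <- which(snip_subj != s)
      te_idx <- which(snip_subj == s)
      if (length(te_idx) == 0L) { wa_dec[s] <- FALSE; next }
      train_snips <- snips
      train_snips$snippets <- snips$snippets[tr_idx]
      train_subj_tab <- bundle$subjects[
        bundle$subjects$subject_id %in% unique(snip_subj[tr_idx]), ,
        drop = FALSE]
      ft <- standardize_factors(train_subj_tab,
                                intersect(names(default_factor_specs()),
                                          names(train_subj_tab)))
      cfg <- enc_config
      cfg$seed <- as.integer((sd_i * 131071 + match(s, subjects)) %%
                               (2^31 - 2))
      ckpt <- train_encoder(train_snips, ft, cfg)
      fold_subjects[[s]] <- unique(snip_subj[tr_idx])

      enc_tr <- encode_set(train_snips, ckpt)
      model <- do.call(fit_decision_model,
                       c(list(latents = enc_tr$mean,
                              subject_ids = enc_tr$subject_id,
                              targets = targets[names(targets) != s]),
                         decision_hyper))
      test_snips <- snips
      test_snips$snippets <- snips$snippets[te_idx]
      enc_te <- encode_set(test_snips, ckpt)
      wa_dec[s] <- decide_window_averaged(model, enc_te$mean)
      preds <- predict_delta(model, enc_te$mean)
      inst_dec <- rbind(inst_dec, data.frame(
        subject_id = s, lap_id = snip_lap[te_idx],
        approach_idx = snip_app[te_idx],
        deploy = preds < model$threshold, stringsAsFactors = FALSE))
      # embedding separation on this fold's training latents (latent
      # spaces differ between folds, so they are never pooled)
      kl_fold <- vapply(names(default_factor_specs()), function(fac) {
        if (!fac %in% names(bundle$subjects)) return(NA_real_)
        fv <- bundle$subjects[[fac]][match(enc_tr$subject_id,
                                           bundle$subjects$subject_id)]
        tryCatch(suppressWarnings(kl_separation(enc_tr$mean, fv)),
                 error = function(e) NA_real_)
      }, 0)
      kl_acc[[length(kl_acc) + 1L]] <- kl_fold
      pooled_lat <- rbind(pooled_lat, enc_te$mean)
      pooled_subj <- c(pooled_subj, rep(s, length(te_idx)))
    }

    withr_seed((sd_i * 524287L + 17L) %% (2^31 - 2))
    rand_dec <- stats::setNames(stats::runif(length(subjects)) < 0.5,
                                subjects)
    dec_by_policy <- list(
      no_hmi = stats::setNames(rep(FALSE, length(subjects)), subjects),
      always = stats::setNames(rep(TRUE, length(subjects)), subjects),
      random = rand_dec,
      window_averaged = wa_dec,
      instantaneous = inst_dec)
    for (p in policies) {
      cf <- suppressWarnings(
        counterfactual_yellow_speed(dec_by_policy[[p]], trials))
      speed_acc[[p]] <- rbind(speed_acc[[p]], c(cf$mean, cf$se))
    }
    if (length(unique(labels)) == 2L) {
      ag <- list()
      for (p in c("random", "window_averaged")) {
        m <- decision_agreement_metrics(dec_by_policy[[p]][subjects],
                                        labels)
        ag[[p]] <- c(m$kappa, m$balanced_accuracy)
      }
      mi <- decision_agreement_metrics(
        inst_dec$deploy, labels[inst_dec$subject_id])
      ag[["instantaneous"]] <- c(mi$kappa, mi$balanced_accuracy)
      agree_acc[[length(agree_acc) + 1L]] <- ag
    }
    decisions_all[[as.character(sd_i)]] <-
      list(window_averaged = wa_dec, instantaneous = inst_dec,
           random = rand_dec)
  }

  policy_speeds <- data.frame(
    policy = policies,
    mean = vapply(policies, function(p) mean(speed_acc[[p]][, 1]), 0),
    se = vapply(policies, function(p) mean(speed_acc[[p]][, 2]), 0),
    row.names = NULL)
  agreement <- if (length(agree_acc)) {
    pols <- names(agree_acc[[1]])
    data.frame(
      policy = pols,
      kappa = vapply(pols, function(p)
        mean(vapply(agree_acc, function(a) a[[p]][1], 0)), 0),
      balanced_accuracy = vapply(pols, function(p)
        mean(vapply(agree_acc, function(a) a[[p]][2], 0)), 0),
      row.names = NULL)
  } else NULL
  kl <- colMeans(do.call(rbind, kl_acc), na.rm = TRUE)
  structure(
    list(policy_speeds = policy_speeds, agreement = agreement, kl = kl,
         labels = labels, targets = targets[subjects],
         decisions = decisions_all, fold_subjects = fold_subjects,
         excluded_subjects = excluded, seeds = seeds,
         per_seed_speeds = speed_acc),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("LOOCV evaluation over", length(x$labels), "subjects,",
      length(x$seeds), "seed(s)\n\nCounterfactual yellow-light speed:\n")
  print(transform(x$policy_speeds, mean = round(mean, 2),
                  se = round(se, 2)), row.names = FALSE)
  if (!is.null(x$agreement)) {
    cat("\nDecision agreement vs measured benefit:\n")
    print(transform(x$agreement, kappa = round(kappa, 3),
                    balanced_accuracy = round(balanced_accuracy, 3)),
          row.names = FALSE)
  }
  cat("\nNormalized KL separation (mean over folds):\n")
  print(round(x$kl, 3))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV tables
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$policy_speeds,
                   file.path(dir, "policy_speeds.csv"), row.names = FALSE)
  if (!is.null(report$agreement))
    utils::write.csv(report$agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
  utils::write.csv(data.frame(factor = names(report$kl),
                              normalized_kl = as.numeric(report$kl)),
                   file.path(dir, "kl_separation.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(policy_speeds = report$policy_speeds, agreement = report$agreement,
         kl = as.list(report$kl),
         labels = as.list(report$labels),
         targets = as.list(report$targets), seeds = report$seeds,
         excluded_subjects = report$excluded_subjects),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
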