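# latent_encoder: losses against independent oracles, gradients against
# finite differences, encoding/decoding contracts, training behavior.

test_that("reconstruction_loss matches the closed-form Gaussian NLL", {
  # 1-D action at the distribution mean with unit variance: 0.5 * ln(2*pi)
  dec <- list(mean = matrix(0), log_variance = matrix(0))
  expect_equal(reconstruction_loss(matrix(0), dec), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # one sd away adds exactly 0.5
  expect_equal(reconstruction_loss(matrix(1), dec) -
                 reconstruction_loss(matrix(0), dec), 0.5,
               tolerance = 1e-12)
  # numerical density oracle on random cases
  set.seed(11)
  for (i in 1:20) {
    a <- matrix(rnorm(6), 3, 2)
    m <- matrix(rnorm(6), 3, 2)
    lv <- matrix(rnorm(6, sd = 0.5), 3, 2)
    oracle <- mean(vapply(1:3, function(r)
      -sum(dnorm(a[r, ], m[r, ], exp(lv[r, ] / 2), log = TRUE)), 0))
    expect_equal(reconstruction_loss(a, list(mean = m, log_variance = lv)),
                 oracle, tolerance = 1e-9)
  }
})

test_that("contrastive_loss evaluates the printed formula", {
  # identical latents and targets: both terms vanish
  z <- rbind(c(1, 2), c(1, 2))
  y <- rbind(1, 1)
  expect_identical(contrastive_loss(z, y, epsilon = 1), 0)
  # similar targets (s = 0), latent distance 1: (1 - 0) * 1^2 = 1
  expect_equal(contrastive_loss(rbind(c(0, 0), c(1, 0)), rbind(1, 1),
                                epsilon = 1), 1, tolerance = 1e-12)
  # dissimilar targets (s = 1), identical latents: max(0, 1 - 0)^2 = 1
  expect_equal(contrastive_loss(rbind(c(0, 0), c(0, 0)), rbind(0, 1),
                                epsilon = 1, scale_y = FALSE), 1,
               tolerance = 1e-12)
  expect_error(contrastive_loss(matrix(0, 1, 2), matrix(0, 1, 1)), "batch")
})

test_that("contrastive_loss equals a brute-force double loop", {
  set.seed(5)
  for (i in 1:100) {
    B <- sample(2:16, 1)
    z <- matrix(rnorm(B * 2), B, 2)
    y <- matrix(rnorm(B * 4), B, 4)
    eps <- runif(1, 0.5, 2)
    expect_lt(abs(contrastive_loss(z, y, eps) -
                    contrastive_brute(z, y, eps)), 1e-9)
  }
})

test_that("kl_regularizer matches closed form and quadrature", {
  expect_identical(kl_regularizer(list(mean = c(0, 0),
                                       log_variance = c(0, 0))), 0)
  expect_equal(kl_regularizer(list(mean = c(1, 0),
                                   log_variance = c(0, 0))), 0.5,
               tolerance = 1e-12)
  expect_equal(kl_regularizer(list(mean = c(0, 0),
                                   log_variance = c(log(2), 0))),
               0.15343, tolerance = 1e-4)
  # 1-D quadrature oracle
  set.seed(21)
  for (i in 1:15) {
    mu <- rnorm(1)
    lv <- rnorm(1, sd = 0.7)
    expect_lt(abs(kl_regularizer(list(mean = mu, log_variance = lv)) -
                    kl_quadrature_1d(mu, lv)), 1e-6)
  }
  # additivity across dimensions holds exactly
  mu <- c(0.3, -1.2); lv <- c(0.4, -0.8)
  expect_equal(kl_regularizer(list(mean = mu, log_variance = lv)),
               kl_regularizer(list(mean = mu[1], log_variance = lv[1])) +
                 kl_regularizer(list(mean = mu[2], log_variance = lv[2])),
               tolerance = 1e-12)
})

test_that("total_loss is the linear combination of its parts", {
  parts <- list(L1 = 1.7, L2 = 0.3, L3 = 2.1)
  cfg <- encoder_config(alpha1 = 1, alpha2 = 0, alpha3 = 0)
  expect_identical(total_loss(parts, cfg), 1.7)
  cfg2 <- encoder_config(alpha1 = 2, alpha2 = 2, alpha3 = 0.2)
  expect_equal(total_loss(parts, cfg2),
               2 * total_loss(parts, encoder_config(alpha1 = 1, alpha2 = 1,
                                                    alpha3 = 0.1)),
               tolerance = 1e-12)
  expect_identical(total_loss(list(L1 = 0, L2 = 0, L3 = 0), cfg2), 0)
})

test_that("sample_latent is the reparameterized Gaussian", {
  enc <- structure(list(mean = c(2, -1), log_variance = c(log(4), 0)),
                   class = "latent_encoding")
  expect_identical(sample_latent(enc, seed = 4), sample_latent(enc, seed = 4))
  # degenerate-variance limit collapses to the mean
  enc0 <- structure(list(mean = c(2, -1), log_variance = c(-60, -60)),
                    class = "latent_encoding")
  expect_equal(sample_latent(enc0, seed = 1), c(2, -1), tolerance = 1e-10)
  # moments over many draws
  set.seed(31)
  draws <- t(replicate(1e5, sample_latent(enc)))
  expect_lt(abs(mean(draws[, 1]) - 2), 3 * 2 / sqrt(1e5))
  expect_lt(abs(var(draws[, 1]) - 4), 3 * 4 * sqrt(2 / 1e5))
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(42)
  cfg <- encoder_config(latent_dim = 2, hidden_size = 3, dec_hidden = 4)
  B <- 4L; Tn <- 3L; C <- 2L
  X <- lapply(1:Tn, function(t) matrix(rnorm(B * C), B, C))
  actions <- matrix(rnorm(B * 2), B, 2)
  Y <- matrix(rnorm(B * 3), B, 3)
  eps <- matrix(rnorm(B * 2), B, 2)
  params <- driverlatent:::init_encoder_params(C, 2L, cfg)
  out <- driverlatent:::encoder_loss_grads(params, X, actions, Y, eps, cfg)
  lossfun <- function(p)
    driverlatent:::encoder_loss_grads(p, X, actions, Y, eps, cfg)$loss
  h <- 1e-6
  for (nm in names(params)) {
    g_num <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g_num[i] <- (lossfun(pp) - lossfun(pm)) / (2 * h)
    }
    rel <- max(abs(g_num - out$grads[[nm]])) / max(1e-8, max(abs(g_num)))
    expect_lt(rel, 1e-4, label = paste("gradient of", nm))
  }
})

test_that("encode and decode_action satisfy their contracts", {
  sn <- strong_snippets()
  ft <- standardize_factors(strong_bundle()$subjects)
  cfg <- quick_encoder_config(epochs = 3L)
  sn40 <- sn
  sn40$snippets <- sn$snippets[1:40]
  ck <- train_encoder(sn40, ft, cfg)
  enc <- encode(sn$snippets[[1]], ck)
  expect_s3_class(enc, "latent_encoding")
  expect_length(enc$mean, 2L)
  expect_length(enc$log_variance, 2L)
  expect_identical(encode(sn$snippets[[1]], ck), enc)   # deterministic
  bad <- sn$snippets[[1]]
  bad$channels <- bad$channels[, 1:3]
  expect_error(encode(bad, ck), "channels")
  dec <- decode_action(enc$mean, ck)
  expect_identical(decode_action(enc$mean, ck), dec)
  expect_true(all(dec$variance > 0))
  expect_true(all(is.finite(dec$mean)))
  expect_error(decode_action(c(1, 2, 3), ck), "latent")
})

test_that("training descends and is reproducible; checkpoints roundtrip", {
  # two synthetic subjects at opposite factor extremes with distinct
  # behavior
  cfg_sim <- strong_sim_config(seed = 2, n_subjects = 6)
  b <- generate_dataset(cfg_sim)
  log <- b$log[b$log$condition != "practice", ]
  sn <- extract_snippets(log, window_T = quick_window)
  ft <- standardize_factors(b$subjects)
  cfg <- quick_encoder_config(seed = 5, epochs = 15L)
  ck <- train_encoder(sn, ft, cfg)
  hist <- ck$loss_history
  expect_lt(mean(tail(hist$total, 3)), hist$total[1])
  ck2 <- train_encoder(sn, ft, cfg)
  expect_equal(ck$params, ck2$params, tolerance = 1e-12)
  # serialization roundtrip preserves encodings
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_equal(encode(sn$snippets[[3]], back), encode(sn$snippets[[3]], ck),
               tolerance = 1e-12)
})

test_that("trained latents separate subjects by factor (permutation test)", {
  b <- strong_bundle()
  sn <- strong_snippets()
  ft <- standardize_factors(b$subjects)
  ck <- train_encoder(sn, ft, quick_encoder_config(seed = 1))
  enc <- encode_set(sn, ck)
  f <- b$subjects$BAS_Fun_Seeking[match(enc$subject_id,
                                        b$subjects$subject_id)]
  lo <- f <= median(f)
  stat <- function(grp) {
    m1 <- colMeans(enc$mean[grp, , drop = FALSE])
    m2 <- colMeans(enc$mean[!grp, , drop = FALSE])
    sqrt(sum((m1 - m2)^2))
  }
  obs <- stat(lo)
  # permute at the subject level to respect within-subject dependence
  subj <- unique(enc$subject_id)
  set.seed(99)
  perm <- replicate(200, {
    sh <- stats::setNames(sample(lo[match(subj, enc$subject_id)]), subj)
    stat(sh[enc$subject_id])
  })
  p <- (1 + sum(perm >= obs)) / 201
  expect_lt(p, 0.01)
})
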