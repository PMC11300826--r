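#' Encoder training configuration
#'
#' Hyperparameters of the variational recurrent context encoder and its
#' three-term loss `alpha1 * L1 + alpha2 * L2 + alpha3 * L3` (action
#' reconstruction, contrastive alignment with cognitive targets, KL
#' regularization toward N(0, I)).
#'
#' @param latent_dim Latent dimension (2 suffices to capture the factors and
#'   keeps the embedding directly interpretable).
#' @param hidden_size LSTM hidden units.
#' @param dec_hidden Hidden units of the action-decoder MLP.
#' @param alpha1,alpha2,alpha3 Non-negative loss weights (reconstruction,
#'   contrastive, KL).
#' @param epsilon Contrastive margin (> 0): how far apart dissimilar-target
#'   latents are pushed.
#' @param batch_size Minibatch size |Z| for the contrastive batch.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param logvar_clamp Log-variances are clamped to `[-c, c]` for stability.
#' @param distance_measure Latent distance; only `"euclidean"` is
#'   implemented.
#' @param seed Integer seed for initialization, batching and latent
#'   sampling.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(latent_dim = 2L, hidden_size = 64L,
                           dec_hidden = 16L, alpha1 = 1, alpha2 = 1,
                           alpha3 = 0.1, epsilon = 1, batch_size = 32L,
                           learning_rate = 1e-3, epochs = 200L,
                           logvar_clamp = 10, distance_measure = "euclidean",
                           seed = 1L) {
  if (any(c(alpha1, alpha2, alpha3) < 0))
    stop("encoder_config: loss weights must be >= 0")
  if (epsilon <= 0) stop("encoder_config: epsilon must be > 0")
  if (latent_dim < 1L) stop("encoder_config: latent_dim must be >= 1")
  if (distance_measure != "euclidean")
    stop("encoder_config: only the euclidean distance is implemented")
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_size = as.integer(hidden_size),
         dec_hidden = as.integer(dec_hidden),
         alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         epsilon = epsilon, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         logvar_clamp = logvar_clamp, distance_measure = distance_measure,
         seed = as.integer(seed)),
    class = "encoder_config"
  )
}

# Uniform fan-in initialization; LSTM forget-gate bias starts at +1.
init_encoder_params <- function(input_size, action_dim, config) {
  H <- config$hidden_size; C <- input_size; dz <- config$latent_dim
  Hd <- config$dec_hidden
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr),
                               nr, nc)
  b_lstm <- numeric(4L * H)
  b_lstm[(H + 1L):(2L * H)] <- 1
  list(
    Wx = u(C, 4L * H), Wh = u(H, 4L * H), b = b_lstm,
    Wm = u(H, dz), bm = numeric(dz),
    Wv = u(H, dz), bv = numeric(dz),
    W1 = u(dz, Hd), b1 = numeric(Hd),
    W2 = u(Hd, action_dim), b2 = numeric(action_dim),
    W3 = u(Hd, action_dim), b3 = numeric(action_dim)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM forward over a list of T input matrices (B x C). Returns the final
# hidden state and (optionally) per-step caches for BPTT.
lstm_forward <- function(X, params, keep_cache = FALSE) {
  H <- ncol(params$Wh) %/% 4L
  B <- nrow(X[[1]])
  Tn <- length(X)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    a <- X[[t]] %*% params$Wx + h %*% params$Wh +
      matrix(params$b, B, 4L * H, byrow = TRUE)
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(a[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(a[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cc,
                         tc = tc, h_prev = h)
    h <- h_new; cc <- c_new
  }
  list(h = h, cache = cache)
}

clamp <- function(x, c) pmin(pmax(x, -c), c)

# Encoder heads: final hidden state -> (mean, clamped log-variance).
encoder_heads <- function(h, params, config) {
  B <- nrow(h)
  mu <- h %*% params$Wm + matrix(params$bm, B, length(params$bm),
                                 byrow = TRUE)
  lv_raw <- h %*% params$Wv + matrix(params$bv, B, length(params$bv),
                                     byrow = TRUE)
  list(mu = mu, lv = clamp(lv_raw, config$logvar_clamp),
       lv_mask = abs(lv_raw) < config$logvar_clamp)
}

# Decoder MLP: latent -> Gaussian over the (standardized) action.
decoder_forward <- function(z, params, config) {
  B <- nrow(z)
  hd <- tanh(z %*% params$W1 + matrix(params$b1, B, length(params$b1),
                                      byrow = TRUE))
  am <- hd %*% params$W2 + matrix(params$b2, B, length(params$b2),
                                  byrow = TRUE)
  alv_raw <- hd %*% params$W3 + matrix(params$b3, B, length(params$b3),
                                       byrow = TRUE)
  list(hd = hd, am = am, alv = clamp(alv_raw, config$logvar_clamp),
       alv_mask = abs(alv_raw) < config$logvar_clamp)
}

standardize_channels <- function(mat, center, scale) {
  sweep(sweep(mat, 2, center), 2, scale, `/`)
}

as_snippet_matrix <- function(snippet) {
  if (is.matrix(snippet)) snippet else snippet$channels
}

#' Encode a trajectory snippet
#'
#' Runs the LSTM over the snippet's (standardized) channels and returns the
#' variational head's output. Deterministic given the parameters.
#'
#' @param snippet A snippet from [extract_snippets()] (or a bare T x C
#'   channel matrix).
#' @param params An `encoder_checkpoint` from [train_encoder()], or a bare
#'   parameter list for untrained use.
#' @param config An [encoder_config()]; taken from the checkpoint when
#'   omitted.
#' @return Object of class `latent_encoding`: list with `mean` and
#'   `log_variance`, each of length `latent_dim`.
#' @export
encode <- function(snippet, params, config = NULL) {
  ckpt <- NULL
  if (inherits(params, "encoder_checkpoint")) {
    ckpt <- params; params <- ckpt$params
    if (is.null(config)) config <- ckpt$config
  }
  if (is.null(config)) config <- encoder_config()
  x <- as_snippet_matrix(snippet)
  if (ncol(x) != nrow(params$Wx))
    stop("encode: snippet has ", ncol(x), " channels but the encoder ",
         "expects ", nrow(params$Wx))
  if (!is.null(ckpt))
    x <- standardize_channels(x, ckpt$input_center, ckpt$input_scale)
  X <- lapply(seq_len(nrow(x)), function(t) x[t, , drop = FALSE])
  h <- lstm_forward(X, params)$h
  heads <- encoder_heads(h, params, config)
  structure(list(mean = as.numeric(heads$mu),
                 log_variance = as.numeric(heads$lv)),
            class = "latent_encoding")
}

#' Encode every snippet in a set
#'
#' Batched version of [encode()]: all snippets are run through the LSTM
#' together.
#'
#' @param snips A `snippet_set`.
#' @param ckpt An `encoder_checkpoint`.
#' @return List with `mean` and `log_variance` matrices (one row per
#'   snippet) and `subject_id`.
#' @export
encode_set <- function(snips, ckpt) {
  stopifnot(inherits(ckpt, "encoder_checkpoint"))
  Tn <- nrow(as_snippet_matrix(snips$snippets[[1]]))
  X <- lapply(seq_len(Tn), function(t)
    do.call(rbind, lapply(snips$snippets, function(s)
      standardize_channels(s$channels[t, , drop = FALSE],
                           ckpt$input_center, ckpt$input_scale))))
  h <- lstm_forward(X, ckpt$params)$h
  heads <- encoder_heads(h, ckpt$params, ckpt$config)
  list(mean = heads$mu, log_variance = heads$lv,
       subject_id = vapply(snips$snippets, `[[`, "", "subject_id"))
}

#' Reparameterized latent sample
#'
#' `z = mean + exp(log_variance / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param enc A `latent_encoding`.
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @return Numeric latent vector.
#' @export
sample_latent <- function(enc, seed = NULL) {
  withr_seed(seed)
  d <- length(enc$mean)
  enc$mean + exp(enc$log_variance / 2) * stats::rnorm(d)
}

#' Decode an action distribution from a latent
#'
#' @param z Latent vector (length `latent_dim`).
#' @param params An `encoder_checkpoint` or bare parameter list.
#' @param config An [encoder_config()]; taken from the checkpoint when
#'   omitted.
#' @return List with `mean` and `variance` over the action channels
#'   (speed m/s, accel m/s^2), in raw action units when decoding from a
#'   checkpoint.
#' @export
decode_action <- function(z, params, config = NULL) {
  ckpt <- NULL
  if (inherits(params, "encoder_checkpoint")) {
    ckpt <- params; params <- ckpt$params
    if (is.null(config)) config <- ckpt$config
  }
  if (is.null(config)) config <- encoder_config()
  if (length(z) != nrow(params$W1))
    stop("decode_action: latent length ", length(z), " != latent_dim ",
         nrow(params$W1))
  dec <- decoder_forward(matrix(z, 1), params, config)
  m <- as.numeric(dec$am); v <- as.numeric(exp(dec$alv))
  if (!is.null(ckpt)) {
    m <- m * ckpt$action_scale + ckpt$action_center
    v <- v * ckpt$action_scale^2
  }
  names(m) <- names(v) <- ckpt$action_names %||% NULL
  list(mean = m, variance = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian action reconstruction loss
#'
#' Mean over samples of the negative log-likelihood of the observed action
#' under the decoded diagonal-Gaussian distribution (summed over action
#' dimensions).
#'
#' @param actions Matrix (B x D) or vector of observed actions.
#' @param decoded List with `mean` and `log_variance` matrices matching
#'   `actions`.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(actions, decoded) {
  a <- as.matrix(actions)
  m <- as.matrix(decoded$mean); lv <- as.matrix(decoded$log_variance)
  stopifnot(all(dim(a) == dim(m)), all(dim(a) == dim(lv)))
  nll <- 0.5 * (log(2 * pi) + lv + (a - m)^2 / exp(lv))
  mean(rowSums(nll))
}

# Pairwise squared target distances, rescaled to [0, 1] by the batch
# maximum (the similarity weight must be a convex-combination coefficient).
contrastive_similarity <- function(batch_y) {
  y <- as.matrix(batch_y)
  s <- as.matrix(stats::dist(y))^2
  mx <- max(s)
  if (mx > 0) s <- s / mx
  pmin(pmax(s, 0), 1)
}

#' Contrastive loss over a batch of latents with continuous targets
#'
#' Mean over ordered pairs of
#' `(1 - s) * l(z, z')^2 + s * max(0, epsilon - l(z, z'))^2`, where `s` is
#' the squared target distance rescaled to `[0, 1]` by the batch maximum and
#' `l` is the Euclidean latent distance: similar-target pairs are pulled
#' together, dissimilar-target pairs pushed beyond the margin.
#'
#' @param batch_z Latent matrix (B x latent_dim), B >= 2.
#' @param batch_y Standardized target matrix (B x K).
#' @param epsilon Margin (> 0).
#' @param distance_measure Only `"euclidean"`.
#' @param scale_y Rescale squared target distances by the batch maximum
#'   (default); set `FALSE` only when `batch_y` distances are already in
#'   `[0, 1]`.
#' @return Scalar loss (>= 0 under the `[0, 1]` scaling).
#' @export
contrastive_loss <- function(batch_z, batch_y, epsilon = 1,
                             distance_measure = "euclidean",
                             scale_y = TRUE) {
  if (distance_measure != "euclidean")
    stop("contrastive_loss: only the euclidean distance is implemented")
  z <- as.matrix(batch_z)
  B <- nrow(z)
  if (B < 2L) stop("contrastive_loss: need a batch of at least 2")
  y <- as.matrix(batch_y)
  if (nrow(y) != B) stop("contrastive_loss: z/y batch sizes differ")
  s <- if (scale_y) contrastive_similarity(y)
  else pmin(pmax(as.matrix(stats::dist(y))^2, 0), 1)
  d <- as.matrix(stats::dist(z))
  hinge <- pmax(0, epsilon - d)
  pair <- (1 - s) * d^2 + s * hinge^2
  diag(pair) <- 0
  sum(pair) / (B * (B - 1))
}

# Gradient of contrastive_loss w.r.t. the latent matrix (s held fixed).
contrastive_grad_z <- function(z, s, epsilon) {
  B <- nrow(z)
  d <- as.matrix(stats::dist(z))
  hinge <- pmax(0, epsilon - d)
  ratio <- matrix(0, B, B)
  pos <- d > 1e-12
  ratio[pos] <- hinge[pos] / d[pos]
  W <- (1 - s) - s * ratio
  diag(W) <- 0
  (4 / (B * (B - 1))) * (rowSums(W) * z - W %*% z)
}

#' KL regularizer toward the standard Normal
#'
#' `KL(N(mu, diag(exp(lv))) || N(0, I)) =
#' 0.5 * sum(exp(lv) + mu^2 - 1 - lv)`. For a batch (matrix input) the mean
#' over rows is returned.
#'
#' @param enc A `latent_encoding`, or a list with `mean` / `log_variance`
#'   vectors or matrices.
#' @return Scalar KL (>= 0).
#' @export
kl_regularizer <- function(enc) {
  mu <- enc$mean; lv <- enc$log_variance
  if (is.matrix(mu)) {
    mean(rowSums(0.5 * (exp(lv) + mu^2 - 1 - lv)))
  } else {
    0.5 * sum(exp(lv) + mu^2 - 1 - lv)
  }
}

#' Weighted total loss
#'
#' @param parts List with `L1`, `L2`, `L3`.
#' @param config An [encoder_config()] (only the alphas are used).
#' @return `alpha1 * L1 + alpha2 * L2 + alpha3 * L3`.
#' @export
total_loss <- function(parts, config) {
  config$alpha1 * parts$L1 + config$alpha2 * parts$L2 +
    config$alpha3 * parts$L3
}

# Forward + backward pass of the full three-term objective on one batch.
# X: list of T matrices (B x C), standardized; actions: B x D standardized;
# Y: B x K standardized targets; eps: B x dz reparameterization noise.
# Returns loss parts and gradients for every parameter.
encoder_loss_grads <- function(params, X, actions, Y, eps, config) {
  B <- nrow(X[[1]])
  H <- config$hidden_size
  fwd <- lstm_forward(X, params, keep_cache = TRUE)
  heads <- encoder_heads(fwd$h, params, config)
  mu <- heads$mu; lv <- heads$lv
  z <- mu + exp(lv / 2) * eps
  dec <- decoder_forward(z, params, config)

  s <- contrastive_similarity(Y)
  L1 <- reconstruction_loss(actions, list(mean = dec$am,
                                          log_variance = dec$alv))
  L2 <- contrastive_loss(z, Y, epsilon = config$epsilon)
  L3 <- kl_regularizer(list(mean = mu, log_variance = lv))
  parts <- list(L1 = L1, L2 = L2, L3 = L3)

  # --- backward: decoder / L1 ---
  dam <- config$alpha1 * (dec$am - actions) / exp(dec$alv) / B
  dalv <- config$alpha1 * 0.5 * (1 - (actions - dec$am)^2 / exp(dec$alv)) /
    B * dec$alv_mask
  dhd <- (dam %*% t(params$W2) + dalv %*% t(params$W3)) * (1 - dec$hd^2)
  gW2 <- t(dec$hd) %*% dam;  gb2 <- colSums(dam)
  gW3 <- t(dec$hd) %*% dalv; gb3 <- colSums(dalv)
  gW1 <- t(z) %*% dhd;       gb1 <- colSums(dhd)
  dz <- dhd %*% t(params$W1)

  # --- contrastive / L2 on z ---
  dz <- dz + config$alpha2 * contrastive_grad_z(z, s, config$epsilon)

  # --- heads: z = mu + exp(lv/2) * eps; L3 on (mu, lv) ---
  dmu <- dz + config$alpha3 * mu / B
  dlv <- (dz * eps * 0.5 * exp(lv / 2) +
            config$alpha3 * 0.5 * (exp(lv) - 1) / B) * heads$lv_mask
  gWm <- t(fwd$h) %*% dmu; gbm <- colSums(dmu)
  gWv <- t(fwd$h) %*% dlv; gbv <- colSums(dlv)
  dh <- dmu %*% t(params$Wm) + dlv %*% t(params$Wv)

  # --- BPTT through the LSTM ---
  gWx <- params$Wx * 0; gWh <- params$Wh * 0; gb <- params$b * 0
  dc <- matrix(0, B, H)
  for (t in rev(seq_along(X))) {
    cc <- fwd$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc <- dc * cc$f
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    gWx <- gWx + t(X[[t]]) %*% da
    gWh <- gWh + t(cc$h_prev) %*% da
    gb <- gb + colSums(da)
    dh <- da %*% t(params$Wh)
  }

  list(parts = parts, loss = total_loss(parts, config),
       grads = list(Wx = gWx, Wh = gWh, b = gb, Wm = gWm, bm = gbm,
                    Wv = gWv, bv = gbv, W1 = gW1, b1 = gb1, W2 = gW2,
                    b2 = gb2, W3 = gW3, b3 = gb3))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the variational recurrent context encoder
#'
#' Minimizes the weighted three-term loss with Adam over minibatches.
#' Trajectory channels and actions are standardized internally using
#' training-set statistics, which are stored in the checkpoint and re-applied
#' at encode time. Fully reproducible from the config seed.
#'
#' @param snips A `snippet_set` from [extract_snippets()].
#' @param profiles A `factor_transform` from [standardize_factors()], or a
#'   standardized matrix with subject ids as rownames; every snippet subject
#'   must be present.
#' @param config An [encoder_config()].
#' @return Object of class `encoder_checkpoint`: parameters, config, loss
#'   history (per-epoch mean of total loss and of the three parts), and the
#'   stored input/action standardization statistics.
#' @export
train_encoder <- function(snips, profiles, config = encoder_config()) {
  if (inherits(profiles, "factor_transform")) profiles <- profiles$profiles
  profiles <- as.matrix(profiles)
  subj <- vapply(snips$snippets, `[[`, "", "subject_id")
  if (length(unique(subj)) < 2L)
    stop("train_encoder: need snippets from at least 2 subjects")
  missing <- setdiff(unique(subj), rownames(profiles))
  if (length(missing))
    stop("train_encoder: no profile for subject(s): ",
         paste(missing, collapse = ", "))
  N <- length(snips$snippets)
  Tn <- nrow(as_snippet_matrix(snips$snippets[[1]]))
  Cn <- ncol(as_snippet_matrix(snips$snippets[[1]]))

  flat <- do.call(rbind, lapply(snips$snippets, `[[`, "channels"))
  input_center <- colMeans(flat)
  input_scale <- apply(flat, 2, stats::sd)
  input_scale[!is.finite(input_scale) | input_scale < 1e-8] <- 1
  X_all <- lapply(seq_len(Tn), function(t)
    standardize_channels(
      do.call(rbind, lapply(snips$snippets,
                            function(s) s$channels[t, , drop = FALSE])),
      input_center, input_scale))

  act_raw <- do.call(rbind, lapply(snips$snippets, `[[`, "action"))
  action_center <- colMeans(act_raw)
  action_scale <- apply(act_raw, 2, stats::sd)
  action_scale[!is.finite(action_scale) | action_scale < 1e-8] <- 1
  actions <- standardize_channels(act_raw, action_center, action_scale)
  Y <- profiles[subj, , drop = FALSE]

  withr_seed(config$seed)
  params <- init_encoder_params(Cn, ncol(actions), config)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), total = numeric(),
                        L1 = numeric(), L2 = numeric(), L3 = numeric())
  dz <- config$latent_dim
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    starts <- seq(1L, N, by = config$batch_size)
    ep_loss <- c(total = 0, L1 = 0, L2 = 0, L3 = 0)
    nb <- 0L
    for (st in starts) {
      idx <- ord[st:min(st + config$batch_size - 1L, N)]
      if (length(idx) < 2L) next          # contrastive needs pairs
      Xb <- lapply(X_all, function(m) m[idx, , drop = FALSE])
      eps <- matrix(stats::rnorm(length(idx) * dz), length(idx), dz)
      out <- encoder_loss_grads(params, Xb, actions[idx, , drop = FALSE],
                                Y[idx, , drop = FALSE], eps, config)
      if (!is.finite(out$loss))
        stop("train_encoder: non-finite loss at epoch ", ep,
             " (parts: ", paste(sprintf("%s=%.3g", names(out$parts),
                                        unlist(out$parts)),
                                collapse = ", "), ")")
      upd <- adam_step(params, out$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + c(out$loss, out$parts$L1, out$parts$L2,
                             out$parts$L3)
      nb <- nb + 1L
    }
    history[ep, ] <- c(ep, ep_loss / max(nb, 1L))
  }
  structure(
    list(params = params, config = config, loss_history = history,
         input_center = input_center, input_scale = input_scale,
         action_center = action_center, action_scale = action_scale,
         action_names = colnames(act_raw), channel_names = snips$channel_names,
         window_T = Tn, n_snippets = N),
    class = "encoder_checkpoint"
  )
}

#' @export
print.encoder_checkpoint <- function(x, ...) {
  hist <- x$loss_history
  cat("encoder_checkpoint: latent_dim", x$config$latent_dim, ", hidden",
      x$config$hidden_size, ", trained", nrow(hist), "epochs on",
      x$n_snippets, "snippets\n")
  if (nrow(hist) > 0)
    cat(sprintf("  loss %.4f -> %.4f\n", hist$total[1],
                hist$total[nrow(hist)]))
  invisible(x)
}

#' Save / load an encoder checkpoint as JSON
#'
#' Text-only serialization: matrices are stored with their dimensions and
#' restored exactly.
#'
#' @param ckpt An `encoder_checkpoint`.
#' @param path Output `.json` path.
#' @return `load_checkpoint`: the restored checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "encoder_checkpoint"))
  pack <- function(p) if (is.matrix(p))
    list(dim = dim(p), data = as.numeric(p)) else list(dim = NULL,
                                                       data = as.numeric(p))
  obj <- list(
    params = lapply(ckpt$params, pack),
    config = unclass(ckpt$config),
    loss_history = ckpt$loss_history,
    input_center = as.list(ckpt$input_center),
    input_scale = as.list(ckpt$input_scale),
    action_center = as.list(ckpt$action_center),
    action_scale = as.list(ckpt$action_scale),
    action_names = ckpt$action_names, channel_names = ckpt$channel_names,
    window_T = ckpt$window_T, n_snippets = ckpt$n_snippets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(p) if (!is.null(p$dim) && length(p$dim) == 2L)
    matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  params <- lapply(obj$params, unpack)
  config <- do.call(encoder_config, obj$config[names(formals(encoder_config))])
  structure(
    list(params = params, config = config,
         loss_history = as.data.frame(obj$loss_history),
         input_center = unlist(obj$input_center),
         input_scale = unlist(obj$input_scale),
         action_center = unlist(obj$action_center),
         action_scale = unlist(obj$action_scale),
         action_names = obj$action_names,
         channel_names = obj$channel_names,
         window_T = obj$window_T, n_snippets = obj$n_snippets),
    class = "encoder_checkpoint"
  )
}
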