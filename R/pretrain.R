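# Contrastive pretraining: NT-Xent loss over projected embeddings of
# augmented view pairs, optimized with LARS.

#' NT-Xent (normalized temperature-scaled cross-entropy) contrastive loss
#'
#' For each ordered positive pair (i, j),
#' `loss_ij = -log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`
#' with `sim` the cosine similarity and the sum running over the other
#' 2N - 1 views in the batch; the returned value is the mean over all 2N
#' ordered positive pairs.
#'
#' @param z Matrix with one row per view (2N rows).
#' @param pair_index Integer vector: `pair_index[i]` is the row of view i's
#'   positive partner. Must be an involution without fixed points.
#' @param tau Temperature (> 0).
#' @return Nonnegative scalar loss.
#' @export
nt_xent_loss <- function(z, pair_index, tau = 0.5) {
  nt_xent(z, pair_index, tau)$loss
}

# Loss plus analytic gradient d loss / d z (used by the training loop; the
# gradient is validated against finite differences in the tests).
nt_xent <- function(z, pair_index, tau = 0.5, want_grad = FALSE) {
  z <- as.matrix(z)
  n2 <- nrow(z)
  if (n2 < 2L) stop("need at least 2 views (one pair)", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  pi_ <- as.integer(pair_index)
  if (length(pi_) != n2 || any(pi_[pi_] != seq_len(n2)) || any(pi_ == seq_len(n2))) {
    stop("pair_index must be an involution without fixed points", call. = FALSE)
  }
  norms <- sqrt(rowSums(z^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    stop("zero-norm embedding row(s): ", paste(zero, collapse = ", "),
         " (cosine similarity undefined)", call. = FALSE)
  }
  zn <- z / norms
  s <- tcrossprod(zn) / tau
  # softmax over k != i within each row
  diag(s) <- -Inf
  smax <- apply(s, 1L, max)
  e <- exp(s - smax)
  rs <- rowSums(e)
  # loss_i = -s[i, p(i)] + log sum_{k != i} exp(s[i, k])
  li <- -(s[cbind(seq_len(n2), pi_)]) + smax + log(rs)
  loss <- mean(li)
  if (!want_grad) return(list(loss = loss))
  p <- e / rs
  p[cbind(seq_len(n2), pi_)] <- p[cbind(seq_len(n2), pi_)] - 1
  p <- p / n2
  # s = zn zn^T / tau appears through row i and column i
  dzn <- (p %*% zn + crossprod(p, zn)) / tau
  # through row normalization
  dz <- (dzn - zn * rowSums(dzn * zn)) / norms
  list(loss = loss, grad = dz)
}

#' One LARS (layer-wise adaptive rate scaling) update
#'
#' Per parameter tensor, the trust ratio
#' `local_lr = trust_coefficient * ||w|| / (||g|| + weight_decay * ||w||)`
#' rescales the update; momentum acts on the weight-decayed gradient scaled
#' by the local rate, and the step is `base_lr` times the momentum buffer.
#' Bias vectors (names ending in `.b`) are excluded from trust-ratio scaling
#' and weight decay, the standard practice for LARS.
#'
#' @param weights Named list of parameter arrays.
#' @param grads Named list of gradients (same names).
#' @param base_lr Base learning rate.
#' @param weight_decay L2 coefficient.
#' @param trust_coefficient LARS trust coefficient.
#' @param momentum_state Named list of momentum buffers, or `NULL` for a
#'   fresh (zero) state.
#' @param momentum Momentum coefficient.
#' @return List with updated `weights` and `momentum_state`.
#' @export
lars_step <- function(weights, grads, base_lr, weight_decay = 0,
                      trust_coefficient = 1e-3, momentum_state = NULL,
                      momentum = 0.9) {
  if (is.null(momentum_state)) {
    momentum_state <- lapply(weights, function(w) w * 0)
  }
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (any(!is.finite(g))) stop("non-finite gradient in ", nm, call. = FALSE)
    w <- weights[[nm]]
    if (endsWith(nm, ".b") || grepl("bn", nm, fixed = TRUE)) {
      # biases and normalization parameters: no trust scaling, no decay
      local_lr <- 1
    } else {
      g <- g + weight_decay * w
      wn <- sqrt(sum(w^2)); gn <- sqrt(sum(g^2))
      local_lr <- if (wn > 0 && gn > 0) {
        trust_coefficient * wn / (gn + weight_decay * wn)
      } else {
        1
      }
    }
    momentum_state[[nm]] <- momentum * momentum_state[[nm]] + local_lr * g
    weights[[nm]] <- w - base_lr * momentum_state[[nm]]
  }
  list(weights = weights, momentum_state = momentum_state)
}

#' Pretraining configuration
#'
#' Full-scale defaults follow the published recipe (batch size 2048, 100
#' epochs, learning rate 0.3, weight decay 1e-5, LARS, ResNet50 encoder,
#' 128-dim projection); [desk_pretrain_config()] is the CPU preset used by
#' the tests. The temperature `tau` is not part of the published recipe and
#' defaults to 0.5.
#'
#' @param batch_size N source images per step (2N views).
#' @param tau NT-Xent temperature.
#' @param epochs Maximum epochs; training also stops when the relative loss
#'   improvement over `saturation_window` epochs falls below
#'   `saturation_tol`.
#' @param learning_rate,weight_decay,momentum,trust_coefficient LARS settings.
#' @param encoder_name Encoder architecture (see [make_encoder()]).
#' @param projection_dim Dimension of the loss-facing embedding z.
#' @param projection_hidden Hidden width of the 2-layer projection head.
#' @param augmentation An [augmentation_policy()].
#' @param saturation_tol,saturation_window Loss-saturation stopping rule.
#' @return Object of class `pretrain_config`.
#' @export
pretrain_config <- function(batch_size = 2048L, tau = 0.5, epochs = 100L,
                            learning_rate = 0.3, weight_decay = 1e-5,
                            momentum = 0.9, trust_coefficient = 1e-3,
                            encoder_name = "resnet50",
                            projection_dim = 128L, projection_hidden = 64L,
                            augmentation = augmentation_policy(),
                            saturation_tol = 1e-3, saturation_window = 10L) {
  if (batch_size < 2L) stop("batch_size must be >= 2 (need negatives)", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size), tau = tau,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, momentum = momentum,
                 trust_coefficient = trust_coefficient,
                 encoder_name = encoder_name,
                 projection_dim = as.integer(projection_dim),
                 projection_hidden = as.integer(projection_hidden),
                 augmentation = augmentation,
                 saturation_tol = saturation_tol,
                 saturation_window = as.integer(saturation_window)),
            class = "pretrain_config")
}

#' Desk-profile pretraining configuration (small encoder, 32 px views)
#' @param ... Overrides passed to [pretrain_config()].
#' @export
desk_pretrain_config <- function(...) {
  # desk-scale optimization differs from the large-batch recipe: with only
  # a few hundred gradient steps the temperature is lowered to sharpen the
  # contrastive gradient and the trust coefficient raised so LARS takes
  # usefully sized relative steps
  args <- utils::modifyList(
    list(batch_size = 32L, epochs = 30L, encoder_name = "tiny",
         learning_rate = 0.3, trust_coefficient = 5e-3, tau = 0.2,
         saturation_tol = 1e-4,
         augmentation = augmentation_policy(output_size = 32L)),
    list(...))
  do.call(pretrain_config, args)
}

#' Embed a batch of views
#'
#' @param views (H, W, 3, 2N) array of augmented views, ordered so that rows
#'   2m-1 and 2m are the two views of source m.
#' @param encoder Encoder from [make_encoder()].
#' @param head Projection head network.
#' @param standardize Standardize each view per channel before encoding
#'   (the model's input normalization; on by default, matching training).
#' @return Object of class `embedding_batch`: `h` (2N x h_dim), `z`
#'   (2N x projection_dim), `pair_index`.
#' @export
embed <- function(views, encoder, head, standardize = TRUE) {
  if (standardize) {
    for (i in seq_len(dim(views)[4])) {
      views[, , , i] <- standardize_channels(views[, , , i, drop = TRUE])
    }
  }
  ef <- net_forward(encoder$net, views)
  hf <- net_forward(head, ef$out)
  n2 <- dim(views)[4]
  if (n2 %% 2L) stop("expected an even number of views", call. = FALSE)
  pair_index <- as.integer(seq_len(n2) + c(1L, -1L))
  structure(list(h = t(ef$out), z = t(hf$out), pair_index = pair_index),
            class = "embedding_batch")
}

#' Contrastive pretraining loop
#'
#' Runs epochs of view-pair construction, embedding, NT-Xent loss and LARS
#' updates over the manifest, stopping at `config$epochs` or when the mean
#' epoch loss saturates. Fully seeded: identical `(manifest, cache, config,
#' seed)` give identical loss traces and checkpoints under single-threaded
#' linear algebra.
#'
#' @param manifest A `fundus_manifest` (labels are not used).
#' @param cache A `stylized_cache`, required when the policy's
#'   `nst_probability > 0`.
#' @param config A [pretrain_config()].
#' @param seed Integer seed.
#' @return Object of class `cl_checkpoint`: named encoder arrays, named
#'   projection-head arrays, config snapshot, epochs run and loss trace.
#' @export
pretrain <- function(manifest, cache = NULL, config = desk_pretrain_config(),
                     seed = 1) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  if (config$batch_size > nrow(manifest)) {
    stop("batch_size exceeds dataset size", call. = FALSE)
  }
  encoder <- make_encoder(config$encoder_name, derive_seed(seed, "enc-init"))
  head <- make_projection_head(encoder$h_dim, config$projection_hidden,
                               config$projection_dim,
                               derive_seed(seed, "head-init"))
  if (!is.null(cache) && is.null(cache$store)) cache <- preload_cache(cache)

  enc_par <- net_params(encoder$net)
  head_par <- net_params(head)
  par <- c(enc_par, head_par)
  n_enc <- length(enc_par)
  mstate <- NULL
  trace <- numeric(0)
  n <- nrow(manifest)
  epochs_run <- 0L

  for (ep in seq_len(config$epochs)) {
    ep_seed <- derive_seed(seed, paste0("epoch-", ep))
    ep_loss <- with_seed(ep_seed, {
      order_ep <- sample(n)
      losses <- numeric(0)
      for (start in seq(1L, n - config$batch_size + 1L, by = config$batch_size)) {
        ids <- order_ep[start:(start + config$batch_size - 1L)]
        views <- vector("list", 2L * length(ids))
        for (m in seq_along(ids)) {
          vp <- withCallingHandlers(
            make_view_pair(manifest[ids[m], , drop = FALSE],
                           config$augmentation, cache),
            retinaCL_zero_sd = function(w) invokeRestart("muffleWarning"))
          views[[2L * m - 1L]] <- vp$view_i
          views[[2L * m]] <- vp$view_j
        }
        x <- prep_batch(views)
        encoder$net <- net_set_params(encoder$net, par[seq_len(n_enc)])
        head <- net_set_params(head, par[-seq_len(n_enc)])
        ef <- net_forward(encoder$net, x)
        hf <- net_forward(head, ef$out)
        pair_index <- as.integer(seq_len(2L * length(ids)) + c(1L, -1L))
        nx <- nt_xent(t(hf$out), pair_index, config$tau, want_grad = TRUE)
        if (!is.finite(nx$loss)) {
          stop("non-finite contrastive loss at epoch ", ep,
               " (trace: ", paste(signif(trace, 4), collapse = ", "), ")",
               call. = FALSE)
        }
        bh <- net_backward(head, hf$caches, t(nx$grad))
        be <- net_backward(encoder$net, ef$caches, bh$dx)
        upd <- lars_step(par, c(be$grads, bh$grads),
                         base_lr = config$learning_rate,
                         weight_decay = config$weight_decay,
                         trust_coefficient = config$trust_coefficient,
                         momentum_state = mstate,
                         momentum = config$momentum)
        par <- upd$weights
        mstate <- upd$momentum_state
        losses <- c(losses, nx$loss)
      }
      mean(losses)
    })
    trace <- c(trace, ep_loss)
    epochs_run <- ep
    w <- config$saturation_window
    if (ep > w) {
      prev <- trace[ep - w]
      if (is.finite(prev) && prev > 0 &&
          (prev - trace[ep]) / prev < config$saturation_tol) break
    }
  }

  encoder$net <- net_set_params(encoder$net, par[seq_len(n_enc)])
  head <- net_set_params(head, par[-seq_len(n_enc)])
  structure(list(
    encoder = net_params(encoder$net),
    projection = net_params(head),
    encoder_name = config$encoder_name,
    h_dim = encoder$h_dim,
    epoch = epochs_run,
    loss_trace = trace,
    config_snapshot = config[setdiff(names(config), "augmentation")]
  ), class = "cl_checkpoint")
}
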