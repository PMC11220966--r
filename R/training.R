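#' Training configuration
#'
#' Defaults follow the published fine-tuning recipe: sequence length 512
#' pieces, batch size 8, learning rate 2e-5, focal loss. The learning rate
#' is a fine-tuning rate for a large pretrained encoder; from-scratch
#' encoders declare an `lr_scale` multiplier on their contract (the tiny
#' encoder uses 500, i.e. an effective 1e-2) so the same config drives both.
#' Focal gamma/alpha and the smoothing mass are not given by the recipe and
#' default to the common conventions (gamma 2, alpha 0.25, eps 0.1).
#'
#' @param seq_len max encoded length in pieces.
#' @param batch_size examples per gradient step.
#' @param learning_rate base step size.
#' @param loss one of `"focal"`, `"cross_entropy"`, `"label_smoothing"`.
#' @param focal_gamma focusing exponent (>= 0).
#' @param focal_alpha positive-class weight in (0,1), or NULL for unweighted.
#' @param smoothing_eps label-smoothing mass in [0,1).
#' @param epochs training epochs.
#' @param seed RNG seed (initialization and shuffling).
#' @param runs repetition count for mean/std reporting.
#' @param warmup_frac fraction of steps with linear learning-rate warmup.
#' @param weight_decay decoupled weight decay.
#' @param stride window stride for long contexts.
#' @return list of class `train_config`.
#' @export
train_config <- function(seq_len = 512L, batch_size = 8L,
                         learning_rate = 2e-5,
                         loss = c("focal", "cross_entropy", "label_smoothing"),
                         focal_gamma = 2, focal_alpha = 0.25,
                         smoothing_eps = 0.1, epochs = 20L, seed = 42L,
                         runs = 3L, warmup_frac = 0.1, weight_decay = 0.01,
                         stride = 128L) {
  loss <- match.arg(loss)
  stopifnot(seq_len > 0, batch_size > 0, learning_rate > 0, focal_gamma >= 0,
            smoothing_eps >= 0, smoothing_eps < 1, epochs > 0, runs > 0)
  structure(list(seq_len = as.integer(seq_len),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 smoothing_eps = smoothing_eps, epochs = as.integer(epochs),
                 seed = as.integer(seed), runs = as.integer(runs),
                 warmup_frac = warmup_frac, weight_decay = weight_decay,
                 stride = as.integer(stride)),
            class = "train_config")
}

P_CLAMP <- 1e-12

# per-position weights and loss/grad wrt the probability matrix.
# probs: M x 2 (masked rows only), labels: binary vector (1 = positive class)
loss_core <- function(probs, labels, kind, gamma, alpha, eps,
                      want_grad = FALSE) {
  M <- nrow(probs)
  if (M == 0L) return(list(value = 0, grad = probs))
  tcol <- labels + 1L
  idx_t <- cbind(seq_len(M), tcol)
  idx_o <- cbind(seq_len(M), 3L - tcol)
  p_t <- pmax(probs[idx_t], P_CLAMP)
  p_o <- pmax(probs[idx_o], P_CLAMP)
  if (kind == "focal") {
    a_t <- if (is.null(alpha)) rep(1, M) else ifelse(labels == 1L, alpha,
                                                     1 - alpha)
    value <- mean(-a_t * (1 - p_t)^gamma * log(p_t))
    if (!want_grad) return(list(value = value))
    g_t <- a_t * (gamma * (1 - p_t)^(pmax(gamma - 1, 0)) * log(p_t) -
                    (1 - p_t)^gamma / p_t) / M
    if (gamma == 0) g_t <- a_t * (-1 / p_t) / M
    grad <- matrix(0, M, 2)
    grad[idx_t] <- g_t
    list(value = value, grad = grad)
  } else {
    # cross-entropy, optionally label-smoothed: targets (1-eps, eps)
    t1 <- 1 - eps; t0 <- eps
    value <- mean(-(t1 * log(p_t) + t0 * log(p_o)))
    if (!want_grad) return(list(value = value))
    grad <- matrix(0, M, 2)
    grad[idx_t] <- -t1 / p_t / M
    grad[idx_o] <- -t0 / p_o / M
    list(value = value, grad = grad)
  }
}

#' Focal loss over masked positions
#'
#' Mean over context positions of `-alpha_t (1 - p_t)^gamma log p_t`, where
#' `p_t` is the predicted probability of the true class. With `gamma = 0`
#' and `alpha = NULL` this reduces exactly to the unsmoothed cross-entropy.
#'
#' @param probs N x 2 row-stochastic matrix.
#' @param labels binary vector (1 marks the positive class) of length N.
#' @param mask binary context mask of length N.
#' @param gamma focusing exponent.
#' @param alpha positive-class weight (the negative class gets `1 - alpha`);
#'   `NULL` for unweighted.
#' @return scalar loss.
#' @export
focal_loss <- function(probs, labels, mask, gamma = 2, alpha = 0.25) {
  keep <- mask == 1L
  loss_core(probs[keep, , drop = FALSE], labels[keep], "focal",
            gamma, alpha, 0)$value
}

#' Cross-entropy loss with optional label smoothing
#'
#' Mean masked negative log-likelihood against targets softened to
#' `(1 - eps, eps)`; `smoothing_eps = 0` is plain cross-entropy.
#'
#' @inheritParams focal_loss
#' @param smoothing_eps smoothing mass in [0,1).
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, mask, smoothing_eps = 0) {
  keep <- mask == 1L
  loss_core(probs[keep, , drop = FALSE], labels[keep], "ce",
            0, NULL, smoothing_eps)$value
}

loss_by_config <- function(probs, labels, mask, cfg, want_grad = FALSE) {
  keep <- mask == 1L
  res <- switch(cfg$loss,
    focal = loss_core(probs[keep, , drop = FALSE], labels[keep], "focal",
                      cfg$focal_gamma, cfg$focal_alpha, 0, want_grad),
    cross_entropy = loss_core(probs[keep, , drop = FALSE], labels[keep],
                              "ce", 0, NULL, 0, want_grad),
    label_smoothing = loss_core(probs[keep, , drop = FALSE], labels[keep],
                                "ce", 0, NULL, cfg$smoothing_eps, want_grad))
  if (want_grad) {
    G <- matrix(0, length(labels), 2)
    G[keep, ] <- res$grad
    res$grad <- G
  }
  res
}

# softmax backward: dS from dK given K (row-stochastic)
softmax_backward <- function(dK, K) {
  K * (dK - rowSums(dK * K))
}

# forward + loss + full analytic gradients for one example under the tiny
# encoder. Returns loss parts and grads as a named list matching params.
example_grads <- function(example, encoder, head, cfg) {
  fw <- tiny_forward(example, encoder)
  L <- fw$L
  K_start <- predict_start(L, head)
  K_end <- predict_end(L, K_start, head)
  ls <- loss_by_config(K_start, example$start_labels, example$context_mask,
                       cfg, want_grad = TRUE)
  le <- loss_by_config(K_end, example$end_labels, example$context_mask,
                       cfg, want_grad = TRUE)

  dS_end <- softmax_backward(le$grad, K_end)

  d <- head$d
  A <- if (head$mode == "conditioned") cbind(L, K_start) else L
  gQ_end <- crossprod(A, dS_end)
  dA <- dS_end %*% t(head$Q_end)
  dL_end <- dA[, seq_len(d), drop = FALSE]

  # the end loss reaches K_start through the conditioning columns; gradient
  # flows through it (no detaching), matching the forward computation
  dK_start <- ls$grad
  if (head$mode == "conditioned")
    dK_start <- dK_start + dA[, d + 1:2, drop = FALSE]
  dS_start <- softmax_backward(dK_start, K_start)

  gQ_start <- crossprod(L, dS_start)
  dL <- dS_start %*% t(head$Q_start) + dL_end

  p <- encoder$params
  dZ <- dL * (1 - L^2)
  gb <- colSums(dZ)
  gW1 <- crossprod(fw$Xprev, dZ)
  gW2 <- crossprod(fw$X, dZ)
  gW3 <- crossprod(fw$Xnext, dZ)
  gWq <- outer(fw$qbar, colSums(dZ))
  gWm <- crossprod(fw$XQ, dZ)

  n <- nrow(L)
  dXQ <- dZ %*% t(p$Wm)
  dX <- dZ %*% t(p$W2) + dXQ * fw$Q
  if (n > 1L) {
    dX[-n, ] <- dX[-n, , drop = FALSE] +
      dZ[-1, , drop = FALSE] %*% t(p$W1)
    dX[-1, ] <- dX[-1, , drop = FALSE] +
      dZ[-n, , drop = FALSE] %*% t(p$W3)
  }
  if (length(fw$qpos) > 0L) {
    dqbar <- (as.numeric(colSums(dZ) %*% t(p$Wq)) +
                colSums(dXQ * fw$X)) / length(fw$qpos)
    dX[fw$qpos, ] <- dX[fw$qpos, , drop = FALSE] +
      matrix(dqbar, length(fw$qpos), d, byrow = TRUE)
  }
  gE <- list(ids = fw$ids, dX = dX)  # sparse embedding grad

  list(loss = list(total = ls$value + le$value, start_part = ls$value,
                   end_part = le$value),
       grads = list(Q_start = gQ_start, Q_end = gQ_end, W1 = gW1, W2 = gW2,
                    W3 = gW3, Wq = gWq, Wm = gWm, b = gb, E = gE),
       K_start = K_start, K_end = K_end)
}

adam_init <- function(shapes) {
  lapply(shapes, function(x) list(m = x * 0, v = x * 0))
}

adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, wd = 0) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  param <- param - lr * (mhat / (sqrt(vhat) + eps) + wd * param)
  list(param = param, state = state)
}

lr_at <- function(step, total, base, warmup_frac) {
  w <- max(1, floor(total * warmup_frac))
  if (step <= w) return(base * step / w)
  # linear decay to a 20% floor rather than zero: slow-to-escape
  # initializations keep a usable step size in late epochs
  frac <- (total - step) / max(1, total - w)
  base * max(0.2, frac)
}

#' Fine-tune the span model
#'
#' Minimizes the unweighted sum of start-head and end-head losses with
#' AdamW-style updates (decoupled weight decay, 10% linear warmup then
#' linear decay), shuffling examples each epoch. When a dev set is supplied,
#' micro-F1 is computed each epoch and the best-dev state is returned;
#' training stops early once dev F1 reaches 1 (it cannot improve further).
#' Deterministic given `cfg$seed` and the encoder implementation.
#'
#' @param dataset list of `encoded_example`s (training split).
#' @param encoder a trainable encoder contract (currently [tiny_encoder()]).
#' @param cfg a [train_config()].
#' @param dev optional list with `examples` (encoded dev set) and `corpus`
#'   (gold dev `mrc_corpus`) for per-epoch selection.
#' @param mode span head mode, `"conditioned"` or `"base"`.
#' @param quiet suppress per-epoch messages.
#' @return model `state`: encoder params, head params, vocab, plus `history`
#'   (per-epoch loss and dev F1) and `best_epoch`.
#' @export
train_model <- function(dataset, encoder, cfg = train_config(), dev = NULL,
                        mode = c("conditioned", "base"), quiet = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(dataset) > 0L)
  set.seed(cfg$seed)
  head <- head_params(encoder$d, mode = mode, init = "random")
  # pre-index pieces once
  dataset <- lapply(dataset, function(ex) {
    ex$piece_ids <- piece_ids(ex$pieces, encoder$vocab); ex })
  if (!is.null(dev))
    dev$examples <- lapply(dev$examples, function(ex) {
      ex$piece_ids <- piece_ids(ex$pieces, encoder$vocab); ex })

  lr_base <- cfg$learning_rate * (encoder$lr_scale %||% 1)
  n <- length(dataset)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$epochs
  dense <- c("Q_start", "Q_end", "W1", "W2", "W3", "Wq", "Wm", "b")
  params <- c(encoder$params,
              list(Q_start = head$Q_start, Q_end = head$Q_end))
  opt <- adam_init(params[c(dense, "E")])
  step <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_f1 = numeric())
  best <- list(f1 = -Inf, params = params, epoch = 0L)

  snapshot <- function(params) {
    encoder$params <- params[c("E", "W1", "W2", "W3", "Wq", "Wm", "b")]
    head$Q_start <- params$Q_start; head$Q_end <- params$Q_end
    list(encoder = encoder, head = head)
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      batch <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      acc <- NULL; accE <- NULL
      snap <- snapshot(params)
      for (j in batch) {
        eg <- example_grads(dataset[[j]], snap$encoder, snap$head, cfg)
        if (!is.finite(eg$loss$total))
          stop("training diverged: non-finite loss at epoch ", epoch)
        epoch_loss <- epoch_loss + eg$loss$total
        g <- eg$grads
        if (is.null(acc)) {
          acc <- g[dense]
          accE <- matrix(0, nrow(params$E), ncol(params$E))
        } else {
          for (nm in dense) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
        # scatter-add sparse embedding grads
        ids <- g$E$ids
        for (u in unique(ids)) {
          rows <- which(ids == u)
          accE[u, ] <- accE[u, ] +
            if (length(rows) == 1L) g$E$dX[rows, ] else
              colSums(g$E$dX[rows, , drop = FALSE])
        }
      }
      step <- step + 1L
      lr <- lr_at(step, total_steps, lr_base, cfg$warmup_frac)
      bs <- length(batch)
      for (nm in dense) {
        r <- adam_step(params[[nm]], acc[[nm]] / bs, opt[[nm]], lr, step,
                       wd = cfg$weight_decay)
        params[[nm]] <- r$param; opt[[nm]] <- r$state
      }
      r <- adam_step(params$E, accE / bs, opt$E, lr, step, wd = 0)
      params$E <- r$param; opt$E <- r$state
    }
    dev_f1 <- NA_real_
    if (!is.null(dev)) {
      snap <- snapshot(params)
      pred <- predict_examples(dev$examples, snap$encoder, snap$head)
      spans <- decode_to_corpus(pred, dev$examples, dev$corpus)
      rep <- evaluate_spans(spans, dev$corpus)
      dev_f1 <- rep$micro$f1
      if (dev_f1 > best$f1) best <- list(f1 = dev_f1, params = params,
                                         epoch = epoch)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = epoch_loss / n,
                                         dev_f1 = dev_f1))
    if (!quiet)
      message(sprintf("epoch %d  loss %.5f  dev F1 %s", epoch,
                      epoch_loss / n,
                      ifelse(is.na(dev_f1), "-", sprintf("%.4f", dev_f1))))
    if (!is.na(dev_f1) && dev_f1 >= 1) break
  }
  sel <- if (is.null(dev)) list(f1 = NA_real_, params = params,
                                epoch = cfg$epochs) else best
  snap <- snapshot(sel$params)
  list(encoder_params = snap$encoder$params, head = snap$head,
       vocab = encoder$vocab, d = encoder$d, encoder_name = encoder$name,
       lr_scale = encoder$lr_scale %||% 1,
       history = history, best_epoch = sel$epoch, cfg = cfg)
}

# run forward over examples with given encoder/head; returns piece-space
# span predictions per example
predict_examples <- function(examples, encoder, head) {
  lapply(examples, function(ex) forward(ex, encoder, head)$spans)
}

state_encoder <- function(state) {
  enc <- tiny_encoder(state$vocab, d = state$d, seed = 0L)
  enc$params <- state$encoder_params
  enc$lr_scale <- state$lr_scale %||% 500
  enc
}

#' Predict annotations for a corpus with a trained model
#'
#' Runs the forward pass over every (sentence, entity type) triple and
#' decodes the predictions back to word-space spans.
#'
#' @param corpus an `mrc_corpus` (gold spans, if any, are ignored).
#' @param qs the `query_set` used at training time.
#' @param state trained model state from [train_model()].
#' @param tok tokenizer (default [word_tokenizer()]).
#' @param max_len,stride encoding geometry (defaults from the state's config).
#' @return list of predicted span data.frames, one per sentence.
#' @export
predict_corpus <- function(corpus, qs, state, tok = word_tokenizer(),
                           max_len = NULL, stride = NULL) {
  if (n_sentences(corpus) == 0L) return(list())
  max_len <- max_len %||% state$cfg$seq_len %||% 512L
  stride <- stride %||% state$cfg$stride %||% 128L
  examples <- encode_corpus(corpus, qs, tok, max_len = max_len,
                            stride = stride)
  enc <- state_encoder(state)
  examples <- lapply(examples, function(ex) {
    ex$piece_ids <- piece_ids(ex$pieces, enc$vocab); ex })
  pred <- predict_examples(examples, enc, state$head)
  decode_to_corpus(pred, examples, corpus)
}
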