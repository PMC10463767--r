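#' Training configuration
#'
#' Contrastive training binds balanced text pairs, the shared (siamese)
#' encoder and one of the three objectives. Both sides of every pair go
#' through identical weights; the pooled embeddings feed the configured
#' loss and gradients flow back through the shared encoder.
#'
#' @param learning_rate AdamW learning rate. The default 1e-3 suits the
#'   small from-scratch encoder; when fine-tuning an external pretrained
#'   encoder the conventional 2e-5 applies.
#' @param batch_size Pairs per mini-batch (default 32; at least 2, since
#'   the CoSENT objective needs a positive and a negative in a batch to
#'   produce signal).
#' @param epochs Training epochs (default 15).
#' @param weight_decay Decoupled weight decay on weight matrices (not on
#'   biases, layer norms or embeddings); default 0.01.
#' @param clip_norm Global gradient-norm clip (default 1).
#' @param pooling Pooling strategy used during training and inference.
#' @param loss A [loss_config].
#' @param seed Seed controlling shuffling (re-drawn per epoch as
#'   `seed + epoch`) and head initialization.
#' @return List of class `pemr_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         epochs = 15L, weight_decay = 0.01, clip_norm = 1,
                         pooling = "cls", loss = loss_config("cosent"),
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 2L, epochs >= 1L,
            weight_decay >= 0, inherits(loss, "pemr_loss_config"))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 clip_norm = clip_norm, pooling = pooling, loss = loss,
                 seed = as.integer(seed)),
            class = "pemr_train_config")
}

# ---- AdamW over the nested parameter list -------------------------------

adam_zeros <- function(x) {
  if (is.list(x)) lapply(x, adam_zeros) else x * 0
}

# decoupled weight decay applies to weight matrices only
decayed_leaf <- function(name) {
  name %in% c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "W")
}

grad_sq_norm <- function(g) {
  if (is.list(g)) sum(vapply(g, grad_sq_norm, numeric(1))) else sum(g^2)
}

grad_scale <- function(g, s) {
  if (is.list(g)) lapply(g, grad_scale, s = s) else g * s
}

adamw_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step_one <- function(p, g, m, v, name) {
    if (is.list(p)) {
      nms <- names(p)
      out <- list(p = p, m = m, v = v)
      for (k in seq_along(p)) {
        r <- step_one(p[[k]], g[[k]], m[[k]], v[[k]],
                      if (is.null(nms)) name else nms[k])
        out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (wd > 0 && decayed_leaf(name)) upd <- upd + wd * p
    list(p = p - lr * upd, m = m, v = v)
  }
  step_one(params, grads, state$m, state$v, "")
}

# ---- training loop ------------------------------------------------------

#' Train an encoder on labeled text pairs
#'
#' Runs seeded mini-batch contrastive training: each batch encodes both
#' pair sides through the shared encoder, pools, evaluates the configured
#' objective, backpropagates through the compiled transformer and updates
#' every parameter with AdamW. A batch containing only one label class
#' under CoSENT contributes zero loss (counted, not an error). When
#' `dev_pairs` is given, held-out pair cosines are scored against the 0/1
#' labels after every epoch and the parameters with the best Spearman
#' correlation are retained as the best checkpoint.
#'
#' @param pairs A `pemr_pairs` data frame containing both labels overall.
#' @param encoder An initialized `pemr_encoder` with a vocabulary.
#' @param config A [train_config].
#' @param dev_pairs Optional held-out `pemr_pairs` for epoch evaluation.
#' @param checkpoint_dir Optional directory receiving `final.rds` and
#'   `best.rds` checkpoints plus `history.csv`.
#' @param verbose Print one line per epoch.
#' @return List with `encoder` (final), `best` (best-Spearman checkpoint,
#'   or final when no dev set), `history` (data frame: epoch, mean_loss,
#'   pearson, spearman) and `head` (the Sentence-BERT head when that loss
#'   is used).
#' @export
train_encoder <- function(pairs, encoder, config = train_config(),
                          dev_pairs = NULL, checkpoint_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(encoder, "pemr_encoder"), !is.null(encoder$vocab),
            nrow(pairs) >= 1L)
  labs <- as.integer(pairs$label)
  if (!all(c(0L, 1L) %in% unique(labs)))
    stop("training pairs must contain both labels")
  cfg <- encoder$config
  lk <- config$loss$kind
  emb_dim <- if (config$pooling == "pooler") cfg$pooler_dim else cfg$dim

  ta <- tokenize(pairs$text_a, encoder$vocab, cfg$max_len)
  tb <- tokenize(pairs$text_b, encoder$vocab, cfg$max_len)

  head_obj <- if (lk == "sbert_softmax")
    sbert_head(emb_dim, config$loss$num_labels, seed = config$seed)
  state <- list(m = adam_zeros(encoder$params), v = adam_zeros(encoder$params))
  hstate <- if (!is.null(head_obj))
    list(m = adam_zeros(head_obj["W"]), v = adam_zeros(head_obj["W"]))
  t_step <- 0L
  n <- nrow(pairs)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        pearson = numeric(0), spearman = numeric(0))
  best <- list(spearman = -Inf, params = encoder$params)

  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(config$seed + epoch, sample.int(n))
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(idx)
      if (B < 2L) next
      ids <- rbind(ta$ids[idx, , drop = FALSE], tb$ids[idx, , drop = FALSE])
      lens <- c(ta$lens[idx], tb$lens[idx])
      enc <- encode(encoder, ids, lens, keep_cache = TRUE)
      pf <- pool_forward(enc, config$pooling, encoder)
      U <- pf$emb[seq_len(B), , drop = FALSE]
      V <- pf$emb[B + seq_len(B), , drop = FALSE]
      y <- labs[idx]

      dU <- dV <- matrix(0, B, emb_dim)
      dW_head <- NULL
      if (lk == "cosent") {
        if (length(unique(y)) < 2L) { batch_losses <- c(batch_losses, 0); next }
        cr <- cosine_rows(U, V, grad = TRUE)
        cl <- cosent_loss(cr$cos, y, lambda = config$loss$lambda, grad = TRUE)
        loss <- cl$loss
        dU <- cl$dcos * cr$dU
        dV <- cl$dcos * cr$dV
      } else if (lk == "sbert_softmax") {
        so <- sbert_objective(U, V, head_obj, y, grad = TRUE)
        loss <- so$loss
        dU <- so$dU; dV <- so$dV; dW_head <- so$dW
      } else {  # simcse_sup: positives are anchor/positive, negatives hard
        pos <- which(y == 1L); neg <- which(y == 0L)
        if (length(pos) == 0L) { batch_losses <- c(batch_losses, 0); next }
        sl <- simcse_sup_loss(U[pos, , drop = FALSE], V[pos, , drop = FALSE],
                              hard_negatives = if (length(neg))
                                V[neg, , drop = FALSE],
                              tau = config$loss$tau, grad = TRUE)
        loss <- sl$loss
        dU[pos, ] <- sl$d_anchors
        dV[pos, ] <- sl$d_positives
        if (length(neg)) dV[neg, ] <- sl$d_hard_negatives
      }
      batch_losses <- c(batch_losses, loss)

      pb <- pool_backward(enc, pf$cache, rbind(dU, dV), encoder)
      grads <- cpp_enc_backward(enc$cache, encoder$params, pb$grad_outputs)
      grads$pooler <- pb$pooler %||%
        list(W = 0 * encoder$params$pooler$W, b = 0 * encoder$params$pooler$b)
      grads <- grads[names(encoder$params)]

      gn <- sqrt(grad_sq_norm(grads))
      if (is.finite(config$clip_norm) && gn > config$clip_norm)
        grads <- grad_scale(grads, config$clip_norm / gn)

      t_step <- t_step + 1L
      r <- adamw_step(encoder$params, grads, state, config$learning_rate,
                      config$weight_decay, t_step)
      encoder$params <- r$p; state$m <- r$m; state$v <- r$v
      if (!is.null(dW_head)) {
        rh <- adamw_step(head_obj["W"], list(W = dW_head), hstate,
                         config$learning_rate, config$weight_decay, t_step)
        head_obj$W <- rh$p$W; hstate$m <- rh$m; hstate$v <- rh$v
      }
    }

    pe <- sp <- NA_real_
    if (!is.null(dev_pairs) && nrow(dev_pairs) > 0L) {
      ev <- evaluate_pairs(encoder, dev_pairs, pooling = config$pooling)
      pe <- as.numeric(ev$pearson); sp <- as.numeric(ev$spearman)
      if (!is.na(sp) && sp > best$spearman)
        best <- list(spearman = sp, params = encoder$params)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, mean_loss = mean(batch_losses),
      pearson = pe, spearman = sp))
    if (verbose)
      message(sprintf("epoch %02d  loss %.5f  pearson %s  spearman %s",
                      epoch, mean(batch_losses),
                      formatC(pe, digits = 4), formatC(sp, digits = 4)))
  }

  best_encoder <- encoder
  if (is.finite(best$spearman)) best_encoder$params <- best$params
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_encoder(encoder, file.path(checkpoint_dir, "final.rds"))
    save_encoder(best_encoder, file.path(checkpoint_dir, "best.rds"))
    utils::write.csv(history, file.path(checkpoint_dir, "history.csv"),
                     row.names = FALSE)
  }
  list(encoder = encoder, best = best_encoder, history = history,
       head = head_obj)
}

#' Score held-out pairs with an encoder
#'
#' Cosine similarity of every pair against its 0/1 label, summarized by
#' Pearson and Spearman correlation (the semantic-matching metrics used
#' for model selection).
#'
#' @param encoder A `pemr_encoder` (or a plain `function(texts) -> matrix`).
#' @param pairs A `pemr_pairs` data frame.
#' @param pooling Pooling strategy when `encoder` is a `pemr_encoder`.
#' @return List with `pearson`, `spearman` (flagged `NA` when undefined,
#'   see [pearson_cor]) and the pair `cosines`.
#' @export
evaluate_pairs <- function(encoder, pairs, pooling = "cls") {
  stopifnot(nrow(pairs) >= 1L)
  fn <- if (inherits(encoder, "pemr_encoder"))
    as_encode_fn(encoder, pooling) else match.fun(encoder)
  U <- fn(pairs$text_a)
  V <- fn(pairs$text_b)
  cs <- cosine_rows(U, V)$cos
  list(pearson = pearson_cor(cs, pairs$label),
       spearman = spearman_cor(cs, pairs$label),
       cosines = cs)
}
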