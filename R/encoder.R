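#' Encoder configuration
#'
#' Architecture of the trainable bidirectional transformer encoder: token +
#' learned position embeddings feeding `n_layers` standard transformer
#' blocks (multi-head self-attention, residual connections, layer
#' normalization and a position-wise feed-forward sublayer). The default
#' size is deliberately small so the encoder trains from scratch on a CPU
#' in minutes; larger pretrained encoders plug in through the
#' `function(texts) -> matrix` contract instead (see [as_encode_fn]).
#'
#' @param vocab_size Vocabulary size (rows of the token-embedding table).
#' @param dim Model width `d`; must be divisible by `n_heads` (the per-head
#'   width is `d / n_heads`).
#' @param n_heads Number of attention heads.
#' @param n_layers Number of transformer blocks (>= 1).
#' @param max_len Maximum sequence length in tokens including `[CLS]`
#'   (default 80).
#' @param ff_dim Hidden width of the feed-forward sublayer (default
#'   `4 * dim`, the convention of the BERT family).
#' @param pooler_dim Output width of the pooler head (default `dim`).
#' @param seed Seed for parameter initialization.
#' @return List of class `pemr_encoder_config`.
#' @export
encoder_config <- function(vocab_size, dim = 64L, n_heads = 4L,
                           n_layers = 2L, max_len = 80L, ff_dim = 4L * dim,
                           pooler_dim = dim, seed = 1L) {
  stopifnot(vocab_size >= length(vocab_specials), dim >= 1L, n_heads >= 1L,
            n_layers >= 1L, max_len >= 2L, ff_dim >= 1L, pooler_dim >= 1L)
  if (dim %% n_heads != 0L) stop("dim must be divisible by n_heads")
  structure(list(vocab_size = as.integer(vocab_size), dim = as.integer(dim),
                 n_heads = as.integer(n_heads), d_k = as.integer(dim / n_heads),
                 n_layers = as.integer(n_layers), max_len = as.integer(max_len),
                 ff_dim = as.integer(ff_dim), pooler_dim = as.integer(pooler_dim),
                 seed = as.integer(seed)),
            class = "pemr_encoder_config")
}

#' Initialize an encoder with seeded random parameters
#'
#' Weights are drawn from `normal(0, 0.02)` (the convention of the BERT
#' model family); biases start at zero and layer-norm gains at one.
#'
#' @param config An [encoder_config].
#' @param vocab Optional `pemr_vocab` stored with the encoder so that
#'   [encode_texts] can tokenize.
#' @return Object of class `pemr_encoder`: list with `config`, `params` and
#'   `vocab`.
#' @export
init_encoder <- function(config, vocab = NULL) {
  stopifnot(inherits(config, "pemr_encoder_config"))
  if (!is.null(vocab)) stopifnot(length(vocab) == config$vocab_size)
  d <- config$dim; f <- config$ff_dim
  w <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  params <- withr::with_seed(config$seed, {
    p <- list(tok_emb = w(config$vocab_size, d),
              pos_emb = w(config$max_len, d),
              layers = lapply(seq_len(config$n_layers), function(l) {
                list(Wq = w(d, d), bq = numeric(d),
                     Wk = w(d, d), bk = numeric(d),
                     Wv = w(d, d), bv = numeric(d),
                     Wo = w(d, d), bo = numeric(d),
                     ln1_g = rep(1, d), ln1_b = numeric(d),
                     W1 = w(d, f), b1 = numeric(f),
                     W2 = w(f, d), b2 = numeric(d),
                     ln2_g = rep(1, d), ln2_b = numeric(d))
              }),
              pooler = list(W = w(d, config$pooler_dim),
                            b = numeric(config$pooler_dim)))
    p
  })
  structure(list(config = config, params = params, vocab = vocab),
            class = "pemr_encoder")
}

#' Scaled dot-product attention (reference implementation)
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` row-wise, excluding masked
#' (padding) key positions from the softmax. Every output row is a convex
#' combination of the rows of `V`. This plain-R version is the package's
#' reference definition; the compiled encoder is cross-checked against it.
#'
#' @param Q,K,V Numeric matrices; `Q` and `K` have `d_k` columns, `K` and
#'   `V` the same number of rows.
#' @param mask Optional binary vector over key positions; 1 keeps a key,
#'   0 removes it. All-zero masks are an error (nothing to attend to).
#' @return Matrix with `nrow(Q)` rows and `ncol(V)` columns.
#' @export
attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  if (is.null(mask)) mask <- rep(1L, nrow(K))
  stopifnot(length(mask) == nrow(K))
  if (all(mask == 0)) stop("attention mask excludes every key position")
  S <- Q %*% t(K) / sqrt(ncol(Q))
  S[, mask == 0] <- -Inf
  P <- exp(S - apply(S, 1L, max))
  P <- P / rowSums(P)
  P %*% V
}

#' Multi-head self-attention (reference implementation)
#'
#' Splits the per-head projections out of full-width parameter matrices,
#' runs [attention] per head with `Q = K = V = X`, concatenates the heads
#' and applies the output linear map. The residual/normalization and
#' feed-forward sublayers around this core live in the transformer block of
#' the compiled encoder.
#'
#' @param X Token representation matrix (`n x d`).
#' @param layer_params Named list with `Wq`, `Wk`, `Wv` (`d x d`), `Wo`
#'   (`d x d`) and bias vectors `bq`, `bk`, `bv`, `bo` (a `layers` element
#'   of an encoder's `params`).
#' @param n_heads Number of heads; `d` must be divisible by it.
#' @param mask Optional binary mask over positions.
#' @return `n x d` matrix.
#' @export
multi_head <- function(X, layer_params, n_heads, mask = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  stopifnot(d %% n_heads == 0L, all(dim(layer_params$Wq) == c(d, d)))
  dk <- d %/% n_heads
  Q <- sweep(X %*% layer_params$Wq, 2L, layer_params$bq, `+`)
  K <- sweep(X %*% layer_params$Wk, 2L, layer_params$bk, `+`)
  V <- sweep(X %*% layer_params$Wv, 2L, layer_params$bv, `+`)
  heads <- lapply(seq_len(n_heads), function(h) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
              V[, cols, drop = FALSE], mask)
  })
  sweep(do.call(cbind, heads) %*% layer_params$Wo, 2L, layer_params$bo, `+`)
}

# Plain-R forward pass through the full encoder stack for one sequence of
# 0-based token ids. Independent of the compiled path; used to cross-check
# it on tiny configurations.
encoder_forward_ref <- function(encoder, ids) {
  cfg <- encoder$config; p <- encoder$params
  n <- length(ids)
  stopifnot(n >= 1L, all(ids >= 0L), all(ids < cfg$vocab_size))
  X <- p$tok_emb[ids + 1L, , drop = FALSE] +
    p$pos_emb[seq_len(n), , drop = FALSE]
  outs <- list(X)
  ln <- function(x, g, b) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    sweep(sweep((x - mu) / sqrt(v + 1e-5), 2L, g, `*`), 2L, b, `+`)
  }
  gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    A <- multi_head(X, lp, cfg$n_heads)
    Y1 <- ln(X + A, lp$ln1_g, lp$ln1_b)
    H <- gelu(sweep(Y1 %*% lp$W1, 2L, lp$b1, `+`))
    FF <- sweep(H %*% lp$W2, 2L, lp$b2, `+`)
    X <- ln(Y1 + FF, lp$ln2_g, lp$ln2_b)
    outs[[l + 1L]] <- X
  }
  outs
}

#' Run the encoder over tokenized sequences
#'
#' Applies the transformer stack to each sequence (padding positions are
#' never attended to and never influence real positions). Returns the
#' per-layer token representations needed by the pooling strategies.
#'
#' @param encoder A `pemr_encoder`.
#' @param ids Integer matrix of 0-based token ids (one row per sequence) as
#'   produced by [tokenize].
#' @param lens Integer vector of true (unpadded) sequence lengths.
#' @param keep_cache Internal: retain activations for a backward pass.
#' @return List of class `pemr_encoding`: `outputs` (a list of
#'   `n_layers + 1` stacked matrices, index 1 being the embedding-layer
#'   output; rows of sequence `i` are `starts[i] .. starts[i]+lens[i]-1`),
#'   `starts`, `lens`, and optionally `cache`.
#' @export
encode <- function(encoder, ids, lens, keep_cache = FALSE) {
  stopifnot(inherits(encoder, "pemr_encoder"))
  cfg <- encoder$config
  ids <- as.matrix(ids)
  if (any(ids >= cfg$vocab_size)) stop("token id outside the vocabulary")
  if (any(lens < 1L) || any(lens > ncol(ids)) || any(lens > cfg$max_len))
    stop("invalid sequence lengths")
  res <- cpp_enc_forward(encoder$params, ids, as.integer(lens),
                         cfg$n_heads, isTRUE(keep_cache))
  structure(list(outputs = res$outputs,
                 starts = as.integer(res$starts), lens = as.integer(lens),
                 n = nrow(ids), dim = cfg$dim, cache = res$cache),
            class = "pemr_encoding")
}

#' Pool token representations into sentence embeddings
#'
#' The five supported strategies: `cls` takes the last-layer `[CLS]` row;
#' `mean` averages the last-layer rows of real tokens; `first_last_avg`
#' averages `(first encoder layer + last layer) / 2` over real tokens;
#' `pooler` passes the `[CLS]` row through a dense layer with Tanh; `max`
#' takes the element-wise maximum over real-token rows. Padding positions
#' never contribute.
#'
#' @param encoding A `pemr_encoding` from [encode].
#' @param strategy One of `"cls"`, `"mean"`, `"first_last_avg"`,
#'   `"pooler"`, `"max"`.
#' @param encoder The encoder (needed for the pooler head parameters).
#' @param first_last Which "first" layer `first_last_avg` uses: the first
#'   encoder block (`"layer1"`, default) or the embedding-layer output
#'   (`"embedding"`).
#' @return Numeric matrix, one embedding row per sequence.
#' @export
pool <- function(encoding, strategy = c("cls", "mean", "first_last_avg",
                                        "pooler", "max"),
                 encoder = NULL, first_last = c("layer1", "embedding")) {
  strategy <- match.arg(strategy)
  first_last <- match.arg(first_last)
  pool_forward(encoding, strategy, encoder, first_last)$emb
}

pool_forward <- function(encoding, strategy, encoder = NULL,
                         first_last = "layer1") {
  outs <- encoding$outputs
  last <- outs[[length(outs)]]
  n <- encoding$n; d <- ncol(last)
  starts <- encoding$starts; lens <- encoding$lens
  cache <- list(strategy = strategy, first_last = first_last)
  emb <- switch(
    strategy,
    cls = last[starts, , drop = FALSE],
    mean = {
      rows <- sequence(lens, from = starts)
      g <- rep.int(seq_len(n), lens)
      rowsum(last[rows, , drop = FALSE], g) / lens
    },
    first_last_avg = {
      first_idx <- if (first_last == "layer1") 2L else 1L
      cache$first_idx <- first_idx
      rows <- sequence(lens, from = starts)
      g <- rep.int(seq_len(n), lens)
      rowsum((outs[[first_idx]][rows, , drop = FALSE] +
                last[rows, , drop = FALSE]) / 2, g) / lens
    },
    pooler = {
      stopifnot(!is.null(encoder))
      cls <- last[starts, , drop = FALSE]
      z <- sweep(cls %*% encoder$params$pooler$W, 2L,
                 encoder$params$pooler$b, `+`)
      cache$cls <- cls
      cache$t <- tanh(z)
      cache$t
    },
    max = {
      idx <- matrix(0L, n, d)
      out <- matrix(0, n, d)
      for (i in seq_len(n)) {
        rows <- starts[i]:(starts[i] + lens[i] - 1L)
        block <- last[rows, , drop = FALSE]
        am <- max.col(t(block), ties.method = "first")
        idx[i, ] <- rows[am]
        out[i, ] <- block[cbind(am, seq_len(d))]
      }
      cache$argmax <- idx
      out
    })
  dimnames(emb) <- NULL
  list(emb = emb, cache = cache)
}

# Map a gradient on the pooled embeddings back to gradients on the stacked
# per-layer outputs (plus pooler-head gradients when applicable).
pool_backward <- function(encoding, pcache, demb, encoder = NULL) {
  outs <- encoding$outputs
  L1 <- length(outs)
  total <- nrow(outs[[1L]]); d <- ncol(outs[[1L]])
  n <- encoding$n; starts <- encoding$starts; lens <- encoding$lens
  grads <- vector("list", L1)
  zero <- function() matrix(0, total, d)
  pooler_grad <- NULL
  st <- pcache$strategy
  if (st == "cls") {
    g <- zero(); g[starts, ] <- demb
    grads[[L1]] <- g
  } else if (st == "mean") {
    g <- zero()
    rows <- sequence(lens, from = starts)
    g[rows, ] <- demb[rep.int(seq_len(n), lens), ] / rep.int(lens, lens)
    grads[[L1]] <- g
  } else if (st == "first_last_avg") {
    g <- zero()
    rows <- sequence(lens, from = starts)
    g[rows, ] <- demb[rep.int(seq_len(n), lens), ] / (2 * rep.int(lens, lens))
    grads[[L1]] <- g
    gf <- g
    if (pcache$first_idx == L1) {
      grads[[L1]] <- g + gf
    } else {
      grads[[pcache$first_idx]] <- gf
    }
  } else if (st == "pooler") {
    dz <- demb * (1 - pcache$t^2)
    pooler_grad <- list(W = crossprod(pcache$cls, dz), b = colSums(dz))
    dcls <- dz %*% t(encoder$params$pooler$W)
    g <- zero(); g[starts, ] <- dcls
    grads[[L1]] <- g
  } else if (st == "max") {
    g <- zero()
    for (i in seq_len(n)) {
      g[cbind(pcache$argmax[i, ], seq_len(d))] <-
        g[cbind(pcache$argmax[i, ], seq_len(d))] + demb[i, ]
    }
    grads[[L1]] <- g
  }
  for (k in seq_len(L1)) if (is.null(grads[[k]])) grads[[k]] <- matrix(0, 0, 0)
  list(grad_outputs = grads, pooler = pooler_grad)
}

#' Embed texts with an encoder
#'
#' Tokenizes with the encoder's stored vocabulary, runs the transformer and
#' pools. This is the package's realisation of the encoder plug-in
#' contract: everything downstream (indexing, retrieval, evaluation)
#' depends only on a `function(texts) -> embedding matrix`.
#'
#' @param encoder A `pemr_encoder` carrying a vocabulary.
#' @param texts Character vector.
#' @param pooling Pooling strategy, see [pool].
#' @param batch_size Sequences encoded per compiled call.
#' @return Numeric matrix with one embedding row per text.
#' @export
encode_texts <- function(encoder, texts, pooling = "cls", batch_size = 256L) {
  stopifnot(inherits(encoder, "pemr_encoder"), !is.null(encoder$vocab))
  out <- vector("list", ceiling(length(texts) / batch_size))
  bi <- 0L
  for (start in seq(1L, length(texts), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(texts))
    tk <- tokenize(texts[idx], encoder$vocab, encoder$config$max_len)
    enc <- encode(encoder, tk$ids, tk$lens)
    bi <- bi + 1L
    out[[bi]] <- pool(enc, pooling, encoder = encoder)
  }
  do.call(rbind, out)
}

#' Wrap an encoder as a plain embedding function
#'
#' @param encoder A `pemr_encoder`.
#' @param pooling Pooling strategy.
#' @return A `function(texts)` returning an embedding matrix; the interface
#'   any external pretrained encoder can implement to replace the built-in
#'   one.
#' @export
as_encode_fn <- function(encoder, pooling = "cls") {
  force(encoder); force(pooling)
  function(texts) encode_texts(encoder, texts, pooling = pooling)
}

#' Save or load an encoder checkpoint
#'
#' A single-file checkpoint holding the configuration, all named parameter
#' tensors and the vocabulary.
#'
#' @param encoder A `pemr_encoder`.
#' @param path File path.
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "pemr_encoder"))
  saveRDS(unclass(encoder), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- "pemr_encoder_config"
  if (!is.null(obj$vocab)) class(obj$vocab) <- "pemr_vocab"
  structure(obj, class = "pemr_encoder")
}

# Cheap deterministic fingerprint tying a reference index to the encoder
# that produced it.
encoder_fingerprint <- function(encoder) {
  s <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else s <<- s + sum(as.numeric(x)^2)
  }
  walk(encoder$params)
  sprintf("d%d-L%d-%s", encoder$config$dim, encoder$config$n_layers,
          formatC(s, digits = 12, format = "g"))
}
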