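#' Cosine similarity
#'
#' `u . v / (||u|| ||v||)`, the similarity used both at training time (the
#' CoSENT objective ranks pair cosines) and at inference time (retrieval
#' against the reference set).
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine of a zero-norm vector is undefined")
  sum(u * v) / (nu * nv)
}

# Row-wise cosine between two matrices of paired embeddings, with the
# gradients of each cosine w.r.t. both rows.
cosine_rows <- function(U, V, grad = FALSE) {
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  if (any(nu == 0) || any(nv == 0))
    stop("cosine of a zero-norm embedding is undefined")
  dot <- rowSums(U * V)
  cs <- dot / (nu * nv)
  if (!grad) return(list(cos = cs))
  # d cos / dU = V/(|u||v|) - cos * U/|u|^2   (row-wise)
  dU <- V / (nu * nv) - cs / nu^2 * U
  dV <- U / (nu * nv) - cs / nv^2 * V
  list(cos = cs, dU = dU, dV = dV)
}

#' Loss configuration
#'
#' @param kind One of `"cosent"`, `"simcse_sup"`, `"sbert_softmax"`.
#' @param lambda CoSENT scale hyperparameter (default 20, the published
#'   CoSENT default).
#' @param tau SimCSE temperature (default 0.05, the SimCSE convention).
#' @param num_labels Label count of the Sentence-BERT classification head
#'   (default 2: same/different prescription).
#' @return List of class `pemr_loss_config`.
#' @export
loss_config <- function(kind = c("cosent", "simcse_sup", "sbert_softmax"),
                        lambda = 20, tau = 0.05, num_labels = 2L) {
  kind <- match.arg(kind)
  stopifnot(lambda > 0, tau > 0, num_labels >= 2L)
  structure(list(kind = kind, lambda = lambda, tau = tau,
                 num_labels = as.integer(num_labels)),
            class = "pemr_loss_config")
}

#' CoSENT ranking loss over pair cosines
#'
#' `log(1 + sum over (pos, neg) cross pairs of exp(lambda * (cos_neg -
#' cos_pos)))`, computed with a numerically stable log-sum-exp. The sum runs
#' over every (positive pair, negative pair) combination in the batch; with
#' no positives or no negatives the cross set is empty and the loss is
#' exactly 0. Unlike the Sentence-BERT classification objective, this loss
#' directly orders cosines, so the training target matches the cosine used
#' at inference.
#'
#' @param cosines Numeric vector of pair cosine similarities.
#' @param labels Binary vector: 1 = same prescription, 0 = different.
#' @param lambda Positive scale (default 20).
#' @param grad If `TRUE`, also return the gradient w.r.t. `cosines`.
#' @return Loss scalar, or `list(loss, dcos)` when `grad = TRUE`.
#' @export
cosent_loss <- function(cosines, labels, lambda = 20, grad = FALSE) {
  stopifnot(length(cosines) == length(labels), lambda > 0,
            all(labels %in% c(0, 1)))
  cp <- cosines[labels == 1]
  cn <- cosines[labels == 0]
  if (length(cp) == 0L || length(cn) == 0L) {
    if (!grad) return(0)
    return(list(loss = 0, dcos = numeric(length(cosines))))
  }
  # terms x_{qp} = lambda * (cos_neg_q - cos_pos_p); loss = logsumexp(0, x)
  x <- lambda * outer(cn, cp, `-`)
  m <- max(0, x)
  loss <- m + log(exp(-m) + sum(exp(x - m)))
  if (!grad) return(loss)
  W <- exp(x - loss)  # d loss / d x_{qp}, all <= 1
  dcos <- numeric(length(cosines))
  dcos[labels == 0] <- lambda * rowSums(W)
  dcos[labels == 1] <- -lambda * colSums(W)
  list(loss = loss, dcos = dcos)
}

#' Supervised SimCSE contrastive loss
#'
#' Temperature-scaled cross-entropy over cosines: each anchor must place
#' its positive above all in-batch positives and hard negatives,
#' `-log( exp(cos(h_i, h_i+)/tau) / sum_j [exp(cos(h_i, h_j+)/tau) +
#' exp(cos(h_i, h_j-)/tau)] )`, averaged over anchors. Hard negatives are
#' optional (the plain in-batch form).
#'
#' @param anchors Matrix of anchor embeddings (one row each).
#' @param positives Matrix of the anchors' positives, row-aligned.
#' @param hard_negatives Optional matrix of hard negatives entering every
#'   anchor's denominator.
#' @param tau Positive temperature (default 0.05).
#' @param grad If `TRUE`, also return gradients w.r.t. all inputs.
#' @return Mean loss, or a list with `loss`, `d_anchors`, `d_positives`,
#'   `d_hard_negatives`.
#' @export
simcse_sup_loss <- function(anchors, positives, hard_negatives = NULL,
                            tau = 0.05, grad = FALSE) {
  anchors <- as.matrix(anchors); positives <- as.matrix(positives)
  stopifnot(nrow(anchors) == nrow(positives), tau > 0, nrow(anchors) >= 1L)
  B <- nrow(anchors)
  H <- if (is.null(hard_negatives)) 0L else nrow(as.matrix(hard_negatives))
  cand <- if (H > 0L) rbind(positives, as.matrix(hard_negatives)) else positives
  M <- B + H
  # cosines of every anchor against every candidate, with gradients
  CS <- matrix(0, B, M)
  gr <- if (grad) list() else NULL
  dA <- matrix(0, B, ncol(anchors))
  dC <- matrix(0, M, ncol(anchors))
  for (i in seq_len(B)) {
    cr <- cosine_rows(matrix(anchors[i, ], M, ncol(anchors), byrow = TRUE),
                      cand, grad = grad)
    CS[i, ] <- cr$cos
    if (grad) gr[[i]] <- cr
  }
  Z <- CS / tau
  m <- apply(Z, 1L, max)
  lse <- m + log(rowSums(exp(Z - m)))
  losses <- lse - Z[cbind(seq_len(B), seq_len(B))]
  loss <- mean(losses)
  if (!grad) return(loss)
  P <- exp(Z - lse)              # softmax rows
  D <- P
  D[cbind(seq_len(B), seq_len(B))] <- D[cbind(seq_len(B), seq_len(B))] - 1
  D <- D / (tau * B)             # d loss / d CS[i, j]
  for (i in seq_len(B)) {
    dA[i, ] <- colSums(D[i, ] * gr[[i]]$dU)
    dC <- dC + D[i, ] * gr[[i]]$dV
  }
  list(loss = loss,
       d_anchors = dA,
       d_positives = dC[seq_len(B), , drop = FALSE],
       d_hard_negatives = if (H > 0L) dC[B + seq_len(H), , drop = FALSE])
}

#' Initialize a Sentence-BERT classification head
#'
#' Trainable weight `W` of shape `3n x k` applied to the concatenation
#' `(u, v, |u - v|)` of two sentence embeddings.
#'
#' @param dim Embedding dimension `n`.
#' @param num_labels Number of target labels `k`.
#' @param seed Seed for the normal(0, 0.02) initialization.
#' @export
sbert_head <- function(dim, num_labels = 2L, seed = 1L) {
  stopifnot(num_labels >= 2L)
  W <- withr::with_seed(seed,
    matrix(stats::rnorm(3L * dim * num_labels, 0, 0.02), 3L * dim, num_labels))
  structure(list(W = W, dim = as.integer(dim),
                 num_labels = as.integer(num_labels)),
            class = "pemr_sbert_head")
}

#' Sentence-BERT softmax classification objective
#'
#' `softmax(W' (u, v, |u - v|))` with cross-entropy against the pair label.
#' Used only at training time; inference always ranks by cosine similarity
#' (the mismatch between this training objective and cosine inference is
#' exactly what the CoSENT loss removes).
#'
#' @param U,V Row-aligned matrices of pair embeddings (or single vectors).
#' @param head A [sbert_head].
#' @param labels Integer labels in `0 .. k-1`, one per pair.
#' @param grad If `TRUE`, also return gradients w.r.t. `U`, `V` and `W`.
#' @return List with `probs` (one row per pair) and `loss` (mean
#'   cross-entropy); with `grad`, also `dU`, `dV`, `dW`.
#' @export
sbert_objective <- function(U, V, head, labels, grad = FALSE) {
  if (is.null(dim(U))) U <- matrix(U, 1L)
  if (is.null(dim(V))) V <- matrix(V, 1L)
  stopifnot(inherits(head, "pemr_sbert_head"), nrow(U) == nrow(V),
            ncol(U) == head$dim, length(labels) == nrow(U),
            all(labels >= 0L), all(labels < head$num_labels))
  B <- nrow(U)
  Z <- cbind(U, V, abs(U - V))
  logits <- Z %*% head$W
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  probs <- exp(logits - lse)
  picked <- logits[cbind(seq_len(B), labels + 1L)]
  loss <- mean(lse - picked)
  if (!grad) return(list(probs = probs, loss = loss))
  D <- probs
  D[cbind(seq_len(B), labels + 1L)] <- D[cbind(seq_len(B), labels + 1L)] - 1
  D <- D / B
  dZ <- D %*% t(head$W)
  d <- head$dim
  s <- sign(U - V)
  dU <- dZ[, seq_len(d), drop = FALSE] +
    s * dZ[, 2L * d + seq_len(d), drop = FALSE]
  dV <- dZ[, d + seq_len(d), drop = FALSE] -
    s * dZ[, 2L * d + seq_len(d), drop = FALSE]
  list(probs = probs, loss = loss, dU = dU, dV = dV, dW = crossprod(Z, D))
}
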