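# Small, quickly trainable setting shared by the tests below.
train_fixture <- function(seed = 31L, n_classes = 2L, records = 10L) {
  corp <- quick_corpus(n_classes = n_classes, records_per_class = records,
                       seed = seed)
  pairs <- build_pairs(corp$records, seed = seed)
  vocab <- fit_vocab(serialize_records(corp$records))
  enc <- init_encoder(encoder_config(vocab_size = length(vocab), dim = 16L,
                                     n_heads = 2L, n_layers = 1L,
                                     max_len = 32L, ff_dim = 32L,
                                     seed = seed), vocab)
  list(corp = corp, pairs = pairs, enc = enc)
}

test_that("training configuration enforces its invariants", {
  expect_error(train_config(epochs = 0L))
  expect_error(train_config(batch_size = 1L))
  expect_error(train_config(learning_rate = 0))
  expect_error(loss_config("cosent", lambda = -1))
  cfg <- train_config()
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 15L)
  expect_equal(cfg$loss$kind, "cosent")
})

test_that("training twice with one seed yields identical histories", {
  fx <- train_fixture()
  cfg <- train_config(epochs = 2L, batch_size = 8L, seed = 9L)
  f1 <- train_encoder(fx$pairs, fx$enc, cfg, dev_pairs = fx$pairs[1:10, ])
  f2 <- train_encoder(fx$pairs, fx$enc, cfg, dev_pairs = fx$pairs[1:10, ])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$encoder$params, f2$encoder$params)
})

test_that("pairs with a single overall label class are rejected", {
  fx <- train_fixture()
  pos_only <- fx$pairs[fx$pairs$label == 1L, ]
  expect_error(train_encoder(pos_only, fx$enc, train_config(epochs = 1L)),
               "both labels")
})

test_that("a single-class CoSENT batch contributes zero loss, not an error", {
  fx <- train_fixture(records = 4L)
  # order pairs so at least one mini-batch is pure positive
  pairs <- fx$pairs[order(-fx$pairs$label), ]
  cfg <- train_config(epochs = 1L, batch_size = 2L, seed = 1L)
  fit <- train_encoder(pairs, fx$enc, cfg)
  expect_true(all(is.finite(fit$history$mean_loss)))
})

test_that("the CoSENT training loss improves on a separable two-class task", {
  corp <- generate_corpus(generator_config(
    n_classes = 2L, records_per_class = 15L, tokens_per_field = 2L,
    vocab_core = 8L, vocab_shared = 12L, noise_rate = 0.05, seed = 33L))
  pairs <- build_pairs(corp$records, seed = 33L, max_pairs = 200L)
  vocab <- fit_vocab(serialize_records(corp$records))
  enc <- init_encoder(encoder_config(vocab_size = length(vocab), dim = 32L,
                                     n_heads = 2L, n_layers = 1L,
                                     max_len = 32L, ff_dim = 64L, seed = 2L),
                      vocab)
  fit <- train_encoder(pairs, enc, train_config(epochs = 15L, seed = 3L))
  h <- fit$history$mean_loss
  expect_lt(h[15], h[1])
  # trained embeddings separate the classes in cosine space
  emb <- encode_texts(fit$encoder, serialize_records(corp$records))
  emb <- emb / sqrt(rowSums(emb^2))
  S <- emb %*% t(emb)
  same <- outer(corp$truth$class, corp$truth$class, `==`)
  diag(same) <- NA
  within <- mean(S[which(same)])
  between <- mean(S[which(!same)])
  expect_gte(within - between, 0.2)
})

test_that("all three objectives run end to end and update parameters", {
  fx <- train_fixture(records = 6L)
  for (lk in c("cosent", "simcse_sup", "sbert_softmax")) {
    cfg <- train_config(epochs = 1L, batch_size = 8L, seed = 5L,
                        loss = loss_config(lk))
    fit <- train_encoder(fx$pairs, fx$enc, cfg)
    expect_false(identical(fit$encoder$params$tok_emb, fx$enc$params$tok_emb))
    if (lk == "sbert_softmax") expect_s3_class(fit$head, "pemr_sbert_head")
  }
})

test_that("backpropagated embedding gradients match finite differences", {
  # a 4-pair batch at the loss level: d(cosent)/d(embedding coordinate)
  set.seed(41)
  U <- matrix(rnorm(12), 4); V <- matrix(rnorm(12), 4)
  lab <- c(1, 0, 1, 0)
  cr <- pemrec:::cosine_rows(U, V, grad = TRUE)
  cl <- cosent_loss(cr$cos, lab, 20, grad = TRUE)
  dU <- cl$dcos * cr$dU
  loss_at <- function(M) {
    cosent_loss(pemrec:::cosine_rows(M, V)$cos, lab, 20)
  }
  eps <- 1e-6
  for (i in c(1, 5, 9)) {
    up <- U; up[i] <- up[i] + eps
    dn <- U; dn[i] <- dn[i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(dU[i], num, tolerance = 1e-4)
  }
})

test_that("full-model gradients match finite differences through the stack", {
  fx <- train_fixture(records = 3L)
  enc <- fx$enc
  tk <- tokenize(c("a b", "c d e", "f", "g h"), enc$vocab, 8L)
  lab <- c(1, 0)
  loss_of <- function(params) {
    e2 <- enc; e2$params <- params
    fw <- encode(e2, tk$ids, tk$lens)
    pf <- pemrec:::pool_forward(fw, "mean", e2)
    cr <- pemrec:::cosine_rows(pf$emb[1:2, ], pf$emb[3:4, ])
    cosent_loss(cr$cos, lab, 10)
  }
  fw <- encode(enc, tk$ids, tk$lens, keep_cache = TRUE)
  pf <- pemrec:::pool_forward(fw, "mean", enc)
  cr <- pemrec:::cosine_rows(pf$emb[1:2, ], pf$emb[3:4, ], grad = TRUE)
  cl <- cosent_loss(cr$cos, lab, 10, grad = TRUE)
  demb <- rbind(cl$dcos * cr$dU, cl$dcos * cr$dV)
  pb <- pemrec:::pool_backward(fw, pf$cache, demb, enc)
  gr <- pemrec:::cpp_enc_backward(fw$cache, enc$params, pb$grad_outputs)
  eps <- 1e-6
  check <- function(analytic, get, set, idx) {
    for (i in idx) {
      p <- enc$params
      x <- get(p); x[i] <- x[i] + eps; fp <- loss_of(set(p, x))
      x <- get(enc$params); x[i] <- x[i] - eps; fm <- loss_of(set(enc$params, x))
      num <- (fp - fm) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-4,
                   label = sprintf("analytic grad [%d]", i))
    }
  }
  check(gr$layers[[1]]$W1, function(p) p$layers[[1]]$W1,
        function(p, x) { p$layers[[1]]$W1 <- x; p }, c(1, 17, 33))
  check(gr$layers[[1]]$ln1_g, function(p) p$layers[[1]]$ln1_g,
        function(p, x) { p$layers[[1]]$ln1_g <- x; p }, c(1, 8))
  check(gr$tok_emb, function(p) p$tok_emb,
        function(p, x) { p$tok_emb <- x; p }, c(3, 20))
  check(gr$layers[[1]]$Wv, function(p) p$layers[[1]]$Wv,
        function(p, x) { p$layers[[1]]$Wv <- x; p }, c(2, 10))
})

test_that("pair evaluation returns the documented closed forms and flags", {
  perfect <- function(texts) {
    # fake bi-encoder: identical texts embed identically
    key <- as.integer(factor(texts, levels = unique(texts)))
    cbind(cos(key), sin(key))
  }
  pairs <- data.frame(text_a = c("x", "y"), text_b = c("x", "z"),
                      label = c(1L, 0L), stringsAsFactors = FALSE)
  ev <- evaluate_pairs(perfect, pairs)
  expect_equal(ev$cosines[1], 1, tolerance = 1e-12)

  expect_equal(pearson_cor(c(.9, .8, .2, .1), c(1, 1, 0, 0)),
               0.7 / sqrt(0.5), tolerance = 1e-10)
  flagged <- pearson_cor(c(.9, .8, .2, .1), c(1, 1, 1, 1))
  expect_true(is.na(flagged))
  expect_match(attr(flagged, "reason"), "constant")
})

test_that("best-checkpoint selection tracks held-out Spearman", {
  fx <- train_fixture()
  cfg <- train_config(epochs = 3L, batch_size = 8L, seed = 13L)
  dev <- fx$pairs[1:16, ]
  dir <- withr::local_tempdir()
  fit <- train_encoder(fx$pairs, fx$enc, cfg, dev_pairs = dev,
                       checkpoint_dir = dir)
  expect_true(file.exists(file.path(dir, "final.rds")))
  expect_true(file.exists(file.path(dir, "best.rds")))
  expect_true(file.exists(file.path(dir, "history.csv")))
  best_sp <- max(fit$history$spearman, na.rm = TRUE)
  got <- evaluate_pairs(load_encoder(file.path(dir, "best.rds")), dev)
  expect_equal(as.numeric(got$spearman), best_sp, tolerance = 1e-10)
})
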