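test_that("attention reduces to V for a single position and normalizes rows", {
  V <- matrix(c(3, -1, 2), 1)
  expect_equal(attention(matrix(0.7), matrix(0.7), V), V)

  # with V = I the output rows are the softmax weights themselves
  set.seed(1)
  Q <- matrix(rnorm(20), 5); K <- matrix(rnorm(20), 5)
  P <- attention(Q, K, diag(5))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_true(all(P > 0))
  # masked keys get exactly zero weight
  Pm <- attention(Q, K, diag(5), mask = c(1, 1, 0, 1, 0))
  expect_true(all(Pm[, c(3, 5)] == 0))
  expect_equal(rowSums(Pm), rep(1, 5), tolerance = 1e-6)
  expect_error(attention(Q, K, diag(5), mask = rep(0, 5)), "mask")
})

test_that("the two-token attention value matches the hand-derived softmax", {
  X <- matrix(c(1, 0), 2, 1)
  out <- attention(X, X, X)
  # scores row 1 are (1, 0): softmax = (e/(e+1), 1/(e+1)); row 2 is uniform
  expect_equal(out, matrix(c(exp(1) / (exp(1) + 1), 0.5), 2, 1),
               tolerance = 1e-6)
  expect_equal(out[1, 1], 0.7311, tolerance = 1e-4)
})

test_that("multi_head with one identity head degenerates to plain attention", {
  set.seed(2)
  X <- matrix(rnorm(4 * 6), 4, 6)
  lp <- list(Wq = diag(6), Wk = diag(6), Wv = diag(6), Wo = diag(6),
             bq = numeric(6), bk = numeric(6), bv = numeric(6),
             bo = numeric(6))
  expect_equal(multi_head(X, lp, n_heads = 1L), attention(X, X, X))
})

test_that("multi_head matches an independent per-head recomputation", {
  set.seed(3)
  d <- 6L; h <- 2L; n <- 4L
  X <- matrix(rnorm(n * d), n, d)
  lp <- list(Wq = matrix(sample(-2:2, d * d, TRUE), d),
             Wk = matrix(sample(-2:2, d * d, TRUE), d),
             Wv = matrix(sample(-2:2, d * d, TRUE), d),
             Wo = matrix(sample(-2:2, d * d, TRUE), d),
             bq = rnorm(d), bk = rnorm(d), bv = rnorm(d), bo = rnorm(d))
  got <- multi_head(X, lp, n_heads = h)
  expect_equal(dim(got), c(n, d))
  # step-by-step oracle: project, slice heads, attend, concat, map
  Q <- sweep(X %*% lp$Wq, 2, lp$bq, `+`)
  K <- sweep(X %*% lp$Wk, 2, lp$bk, `+`)
  V <- sweep(X %*% lp$Wv, 2, lp$bv, `+`)
  heads <- list()
  for (hh in 1:h) {
    cols <- ((hh - 1) * 3 + 1):(hh * 3)
    S <- Q[, cols] %*% t(K[, cols]) / sqrt(3)
    P <- exp(S); P <- P / rowSums(P)
    heads[[hh]] <- P %*% V[, cols]
  }
  want <- sweep(cbind(heads[[1]], heads[[2]]) %*% lp$Wo, 2, lp$bo, `+`)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the compiled encoder matches the plain-R reference stack", {
  for (seed in c(4, 5)) {
    enc <- tiny_encoder(seed = seed)
    tk <- tokenize("w1 w2 w3 w4 w5", enc$vocab, enc$config$max_len)
    fw <- encode(enc, tk$ids, tk$lens)
    ref <- pemrec:::encoder_forward_ref(enc, tk$ids[1, seq_len(tk$lens[1])])
    expect_length(fw$outputs, enc$config$n_layers + 1L)
    for (l in seq_along(ref))
      expect_equal(fw$outputs[[l]][seq_len(tk$lens[1]), ], ref[[l]],
                   tolerance = 1e-12)
  }
})

test_that("encoding is deterministic and validates ids and layer counts", {
  enc <- tiny_encoder(n_layers = 1L)
  tk <- tokenize(c("w1 w2", "w3"), enc$vocab, enc$config$max_len)
  a <- encode(enc, tk$ids, tk$lens)
  b <- encode(enc, tk$ids, tk$lens)
  expect_identical(a$outputs, b$outputs)
  expect_length(a$outputs, 2L)  # embedding + one block
  bad <- tk$ids; bad[1, 2] <- length(enc$vocab)
  expect_error(encode(enc, bad, tk$lens), "vocabulary")
})

test_that("padding never changes embeddings under any pooling strategy", {
  enc <- tiny_encoder()
  txt <- "w1 w2 w3 w4"
  tk_short <- tokenize(txt, enc$vocab, max_len = 5)   # exactly fits
  tk_long <- tokenize(txt, enc$vocab, max_len = 12)   # heavily padded
  for (strat in c("cls", "mean", "first_last_avg", "pooler", "max")) {
    e1 <- pool(encode(enc, tk_short$ids, tk_short$lens), strat, enc)
    e2 <- pool(encode(enc, tk_long$ids, tk_long$lens), strat, enc)
    expect_equal(e1, e2, tolerance = 1e-6)
    expect_true(all(is.finite(e1)))
  }
})

test_that("pooling strategies implement their defining reductions", {
  # hand-built token outputs: two real rows and one padding row
  d <- 2L
  last <- rbind(c(1, 3), c(3, 1), c(9, 9))
  fake <- structure(list(outputs = list(last * 0.5, last),
                         starts = 1L, lens = 2L, n = 1L, dim = d),
                    class = "pemr_encoding")
  expect_equal(drop(pool(fake, "mean")), c(2, 2))       # padding row ignored
  expect_equal(drop(pool(fake, "cls")), c(1, 3))
  expect_equal(drop(pool(fake, "max")), c(3, 3))
  # (first + last)/2 averaged over real rows; here first = 0.5 * last
  expect_equal(drop(pool(fake, "first_last_avg", first_last = "embedding")),
               c(1.5, 1.5))
  # pooler with identity dense and zero bias is tanh of the [CLS] row
  enc <- list(params = list(pooler = list(W = diag(d), b = numeric(d))))
  expect_equal(drop(pool(fake, "pooler", encoder = enc)), tanh(c(1, 3)))
  # constant rows: mean equals cls
  const <- rbind(c(2, -1), c(2, -1))
  fake2 <- structure(list(outputs = list(const, const), starts = 1L,
                          lens = 2L, n = 1L, dim = d),
                     class = "pemr_encoding")
  expect_equal(pool(fake2, "mean"), pool(fake2, "cls"))
  expect_error(pool(fake2, "nope"))
})

test_that("first_last_avg can use the embedding layer instead of block 1", {
  enc <- tiny_encoder()
  tk <- tokenize("w1 w2 w3", enc$vocab, enc$config$max_len)
  fw <- encode(enc, tk$ids, tk$lens)
  a <- pool(fw, "first_last_avg", enc, first_last = "layer1")
  b <- pool(fw, "first_last_avg", enc, first_last = "embedding")
  expect_false(isTRUE(all.equal(a, b)))
  n <- tk$lens[1]
  want <- colMeans((fw$outputs[[1]][1:n, ] + fw$outputs[[3]][1:n, ]) / 2)
  expect_equal(drop(b), want)
})

test_that("encoder checkpoints round-trip and embed identically", {
  enc <- tiny_encoder()
  f <- withr::local_tempfile(fileext = ".rds")
  save_encoder(enc, f)
  back <- load_encoder(f)
  expect_equal(encode_texts(back, c("w1 w2", "w5 w9 w2")),
               encode_texts(enc, c("w1 w2", "w5 w9 w2")))
})

test_that("encode_texts is a pure function with stable batching", {
  enc <- tiny_encoder()
  texts <- c("w1 w2 w3", "w4", "w5 w6", "w7 w8 w9 w10")
  all_at_once <- encode_texts(enc, texts)
  in_batches <- encode_texts(enc, texts, batch_size = 2L)
  expect_identical(all_at_once, encode_texts(enc, texts))
  expect_equal(all_at_once, in_batches, tolerance = 1e-12)
  expect_equal(dim(all_at_once), c(4L, enc$config$dim))
})
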