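#' End-to-end training workflow
#'
#' Convenience wrapper binding the pipeline stages the way the
#' recommendation experiments use them: stratified 8:1:1 split of the
#' corpus into a training pool, a query set and a reference set; a further
#' stratified 7:3 split of the pool into pair-training and pair-test
#' records; balanced 1:1 pair construction within each side; vocabulary
#' fitting; and contrastive training with per-epoch evaluation on the
#' held-out pairs (best checkpoint by Spearman).
#'
#' @param records A [pemr_corpus].
#' @param extra_vocab_texts Optional additional texts included when fitting
#'   the tokenizer vocabulary (e.g. an open-set corpus, mirroring a
#'   pretrained tokenizer whose coverage exceeds the training data; unseen
#'   tokens keep their randomly initialized, never-updated embeddings).
#' @param loss A [loss_config].
#' @param pooling Pooling strategy.
#' @param dim,n_heads,n_layers,max_len Encoder architecture, see
#'   [encoder_config].
#' @param learning_rate,batch_size,epochs,weight_decay Training settings,
#'   see [train_config].
#' @param max_train_pairs,max_dev_pairs Caps on the balanced pair sets
#'   (seeded subsamples); keep training tractable on one CPU.
#' @param groups Field groups serialized into pair texts.
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @param verbose Print per-epoch progress.
#' @return List with `encoder` (best checkpoint), `final` (last epoch),
#'   `history`, `pairs`, `dev_pairs`, `splits` (named list `train_pool`,
#'   `pair_train`, `pair_test`, `queries`, `reference`) and
#'   `train_prescriptions` (the training manifest used to label
#'   closed/open protocols).
#' @export
train_pipeline <- function(records, extra_vocab_texts = NULL,
                           loss = loss_config("cosent"), pooling = "cls",
                           dim = 64L, n_heads = 4L, n_layers = 2L,
                           max_len = 80L, learning_rate = 1e-3,
                           batch_size = 32L, epochs = 15L,
                           weight_decay = 0.01,
                           max_train_pairs = 800L, max_dev_pairs = 200L,
                           groups = names(pemr_field_groups), seed = 1L,
                           verbose = FALSE) {
  seed <- as.integer(seed)
  parts <- split_dataset(records, c(0.8, 0.1, 0.1), seed = seed)
  pool <- parts[[1L]]; queries <- parts[[2L]]; reference <- parts[[3L]]
  pair_parts <- split_dataset(pool, c(0.7, 0.3), seed = seed + 1L)
  pair_train <- pair_parts[[1L]]; pair_test <- pair_parts[[2L]]

  pairs <- build_pairs(pair_train, groups = groups, balance_ratio = 1,
                       seed = seed + 2L, max_pairs = max_train_pairs)
  dev_pairs <- build_pairs(pair_test, groups = groups, balance_ratio = 1,
                           seed = seed + 3L, max_pairs = max_dev_pairs)

  vocab <- fit_vocab(c(serialize_records(records), extra_vocab_texts))
  ecfg <- encoder_config(vocab_size = length(vocab), dim = dim,
                         n_heads = n_heads, n_layers = n_layers,
                         max_len = max_len, seed = seed + 4L)
  tcfg <- train_config(learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs,
                       weight_decay = weight_decay, pooling = pooling,
                       loss = loss, seed = seed + 5L)
  fit <- train_encoder(pairs, init_encoder(ecfg, vocab), tcfg,
                       dev_pairs = dev_pairs, verbose = verbose)
  list(encoder = fit$best, final = fit$encoder, history = fit$history,
       pairs = pairs, dev_pairs = dev_pairs,
       splits = list(train_pool = pool, pair_train = pair_train,
                     pair_test = pair_test, queries = queries,
                     reference = reference),
       train_prescriptions = unique(pair_train$prescription),
       pooling = pooling)
}
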