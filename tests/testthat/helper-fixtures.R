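# Shared fixtures, built in code.

# A small hand-written corpus: three prescriptions over five records.
tiny_corpus <- function() {
  pemr_corpus(data.frame(
    record_id = paste0("r", 1:5),
    onset_date = paste("june", 1:5),
    location = c("north field", "north field", "south field", "river plot",
                 "river plot"),
    field_distribution = "patchy",
    species = c("tomato", "tomato", "cucumber", "eggplant", "eggplant"),
    growth_stage = "flowering",
    affected_part = c("leaf", "leaf", "stem", "fruit", "fruit"),
    severity = c("mild", "severe", "mild", "severe", "mild"),
    main_symptoms = c("yellow spots", "yellow spots", "white mold",
                      "soft rot", "soft rot"),
    detail = paste("note", 1:5),
    prescription = c("rx_a", "rx_a", "rx_b", "rx_c", "rx_c"),
    stringsAsFactors = FALSE))
}

# Minimal vocabulary + encoder for contract tests (fast to run).
tiny_vocab <- function(words = paste0("w", 1:12)) {
  structure(c("[PAD]", "[UNK]", "[CLS]", "[FSEP]", words),
            class = "pemr_vocab")
}

tiny_encoder <- function(dim = 16L, n_heads = 2L, n_layers = 2L,
                         max_len = 12L, ff_dim = 24L, seed = 42L,
                         vocab = tiny_vocab()) {
  init_encoder(encoder_config(vocab_size = length(vocab), dim = dim,
                              n_heads = n_heads, n_layers = n_layers,
                              max_len = max_len, ff_dim = ff_dim,
                              seed = seed), vocab)
}

# Small fast-to-embed synthetic corpus (short texts).
quick_corpus <- function(n_classes = 3L, records_per_class = 8L, seed = 5L,
                         noise_rate = 0.1, ...) {
  generate_corpus(generator_config(
    n_classes = n_classes, records_per_class = records_per_class,
    tokens_per_field = 2L, vocab_core = 6L, vocab_shared = 10L,
    noise_rate = noise_rate, seed = seed, ...))
}
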