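#' Whitespace tokenizer with a fitted vocabulary
#'
#' The synthetic corpus and the serialized PEMR texts are whitespace-token
#' streams, so the package's built-in tokenizer splits on whitespace and
#' maps tokens through a fitted vocabulary. External pretrained encoders
#' bring their own tokenizer through the plug-in contract (any function
#' mapping texts to an embedding matrix), so nothing downstream depends on
#' this choice.
#'
#' Token ids are 0-based: id 0 is the padding token, and the reserved
#' tokens `[PAD]`, `[UNK]`, `[CLS]`, `[FSEP]` occupy ids 0-3.
#'
#' @param texts Character vector to fit on.
#' @param min_count Minimum occurrence count for a token to enter the
#'   vocabulary (rarer tokens map to `[UNK]`).
#' @return Object of class `pemr_vocab`: a character vector of tokens whose
#'   position minus one is the token id.
#' @export
fit_vocab <- function(texts, min_count = 1L) {
  toks <- unlist(strsplit(texts, "[[:space:]]+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  tab <- table(toks)
  kept <- sort(names(tab)[tab >= min_count])
  kept <- setdiff(kept, vocab_specials)
  structure(c(vocab_specials, kept), class = "pemr_vocab")
}

vocab_specials <- c("[PAD]", "[UNK]", "[CLS]", "[FSEP]")

token_id <- function(vocab, tokens) {
  id <- match(tokens, vocab) - 1L
  id[is.na(id)] <- 1L  # [UNK]
  id
}

#' Tokenize texts to fixed-length id sequences
#'
#' Prepends `[CLS]`, truncates to `max_len` tokens, and right-pads with the
#' padding id 0. The attention mask is 1 on real tokens (including `[CLS]`)
#' and 0 on padding.
#'
#' @param texts Character vector.
#' @param vocab A `pemr_vocab`.
#' @param max_len Maximum sequence length in tokens, `[CLS]` included
#'   (default 80).
#' @return List with integer matrices `ids` and `mask` (one row per text,
#'   `max_len` columns) and integer vector `lens` of unpadded lengths. An
#'   empty text yields the valid length-1 sequence `[CLS]`.
#' @export
tokenize <- function(texts, vocab, max_len = 80L) {
  stopifnot(inherits(vocab, "pemr_vocab"), max_len >= 2L)
  n <- length(texts)
  ids <- matrix(0L, n, max_len)
  lens <- integer(n)
  cls <- token_id(vocab, "[CLS]")
  for (i in seq_len(n)) {
    toks <- strsplit(texts[i], "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    seq_ids <- c(cls, token_id(vocab, toks))
    if (length(seq_ids) > max_len) seq_ids <- seq_ids[seq_len(max_len)]
    lens[i] <- length(seq_ids)
    ids[i, seq_along(seq_ids)] <- seq_ids
  }
  mask <- matrix(0L, n, max_len)
  for (i in seq_len(n)) mask[i, seq_len(lens[i])] <- 1L
  list(ids = ids, mask = mask, lens = lens)
}

#' Read and write a vocabulary file
#'
#' One token per line; line number minus one is the token id.
#'
#' @param vocab A `pemr_vocab`.
#' @param path File path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(unclass(vocab), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  structure(readLines(path, encoding = "UTF-8", warn = FALSE),
            class = "pemr_vocab")
}
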