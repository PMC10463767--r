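# Independent oracles shared across test files. These deliberately use
# naive formulations (double loops, explicit enumeration) and no code from
# the implementation paths they check.

# CoSENT: enumerate every (positive, negative) cross term directly.
cosent_naive <- function(cosines, labels, lambda) {
  s <- 0
  for (i in seq_along(cosines)) for (j in seq_along(cosines)) {
    if (labels[i] == 1 && labels[j] == 0)
      s <- s + exp(lambda * (cosines[j] - cosines[i]))
  }
  log(1 + s)
}

# Retrieval: per-row cosine loop, stable sort, first-occurrence dedup.
recommend_oracle <- function(q, emb, rx, ids, n) {
  scores <- vapply(seq_len(nrow(emb)), function(i) {
    sum(q * emb[i, ]) / (sqrt(sum(q^2)) * sqrt(sum(emb[i, ]^2)))
  }, numeric(1))
  scores <- pmin(pmax(scores, -1), 1)
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  seen <- character(0)
  for (i in ord) {
    if (rx[i] %in% seen) next
    seen <- c(seen, rx[i])
    keep <- c(keep, i)
    if (length(keep) == n) break
  }
  data.frame(prescription = rx[keep], score = scores[keep],
             supporting_record_id = ids[keep], stringsAsFactors = FALSE)
}
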