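#' Construct a reference index from precomputed embeddings
#'
#' Rows are L2-normalized so cosine similarity against a query reduces to a
#' dot product; retrieval is exact exhaustive search (reference sets are at
#' most tens of thousands of records).
#'
#' @param embeddings Numeric matrix, one row per reference record.
#' @param prescriptions Character vector of prescriptions aligned by row.
#' @param record_ids Character vector of record ids aligned by row.
#' @param fingerprint Optional string identifying the encoder that produced
#'   the embeddings; [recommend] warns when it does not match.
#' @return Object of class `pemr_index`.
#' @export
reference_index <- function(embeddings, prescriptions, record_ids,
                            fingerprint = NULL) {
  embeddings <- as.matrix(embeddings)
  stopifnot(nrow(embeddings) >= 1L,
            nrow(embeddings) == length(prescriptions),
            nrow(embeddings) == length(record_ids))
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(nrm == 0)) stop("reference embedding with zero norm")
  structure(list(embeddings = embeddings / nrm,
                 prescriptions = as.character(prescriptions),
                 record_ids = as.character(record_ids),
                 fingerprint = fingerprint),
            class = "pemr_index")
}

#' Embed a reference record set into an index
#'
#' Serializes every reference record (all field groups by default), embeds
#' it with the encoder, L2-normalizes and stores it with its prescription.
#' This realizes the "standard reference set" of the recommendation
#' workflow: the embedded historical records whose prescriptions are the
#' candidates.
#'
#' @param records A [pemr_corpus] (non-empty).
#' @param encoder A `pemr_encoder` or a `function(texts) -> matrix`.
#' @param groups Field groups serialized into the reference texts.
#' @param pooling Pooling strategy when `encoder` is a `pemr_encoder`.
#' @return A `pemr_index`.
#' @export
build_index <- function(records, encoder, groups = names(pemr_field_groups),
                        pooling = "cls") {
  if (nrow(records) == 0L) stop("cannot build an index from zero records")
  fp <- NULL
  fn <- if (inherits(encoder, "pemr_encoder")) {
    fp <- encoder_fingerprint(encoder)
    as_encode_fn(encoder, pooling)
  } else match.fun(encoder)
  emb <- fn(serialize_records(records, groups))
  reference_index(emb, records$prescription, records$record_id,
                  fingerprint = fp)
}

#' Recommend prescriptions for a query
#'
#' Embeds the query text, scores it by cosine against every reference row,
#' ranks rows by score (ties broken by earlier reference row for
#' determinism), de-duplicates prescriptions keeping each prescription's
#' best-scoring supporting record, and returns the first `n` distinct
#' prescriptions. Top-N therefore counts distinct prescriptions, not
#' reference records.
#'
#' @param query_text Query string (a serialized PEMR).
#' @param index A `pemr_index`.
#' @param encoder A `pemr_encoder` or `function(texts) -> matrix`; must be
#'   the encoder the index was built with.
#' @param n Number of distinct prescriptions to return (>= 1). When fewer
#'   distinct prescriptions exist, all are returned and the result carries
#'   attribute `truncated = TRUE`.
#' @param query_id Identifier echoed into the result.
#' @param pooling Pooling strategy when `encoder` is a `pemr_encoder`.
#' @return Object of class `pemr_recommendation`: list with `query_id` and
#'   `ranked`, a data frame of `prescription`, `score`,
#'   `supporting_record_id` with non-increasing scores.
#' @export
recommend <- function(query_text, index, encoder, n = 5L,
                      query_id = "query", pooling = "cls") {
  stopifnot(inherits(index, "pemr_index"), n >= 1L, length(query_text) == 1L)
  fn <- if (inherits(encoder, "pemr_encoder")) {
    if (!is.null(index$fingerprint) &&
        !identical(index$fingerprint, encoder_fingerprint(encoder)))
      warning("index was built with a different encoder")
    as_encode_fn(encoder, pooling)
  } else match.fun(encoder)
  q <- drop(fn(query_text))
  ranked <- rank_prescriptions(q, index, n)
  structure(list(query_id = query_id, ranked = ranked$df),
            class = "pemr_recommendation",
            truncated = ranked$truncated)
}

# Core ranking shared by recommend() and the batch evaluation path:
# full cosine vector, stable sort, first-occurrence prescription dedup.
rank_prescriptions <- function(q, index, n) {
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("query embedding has zero norm")
  scores <- drop(index$embeddings %*% (q / nq))
  scores <- pmin(pmax(scores, -1), 1)  # guard float32 rounding past +/-1
  ord <- order(-scores, seq_along(scores))
  first <- !duplicated(index$prescriptions[ord])
  keep <- ord[first]
  truncated <- length(keep) < n
  keep <- keep[seq_len(min(n, length(keep)))]
  list(df = data.frame(prescription = index$prescriptions[keep],
                       score = scores[keep],
                       supporting_record_id = index$record_ids[keep],
                       stringsAsFactors = FALSE),
       truncated = truncated)
}

#' Save or load a reference index
#'
#' The on-disk form is a directory with a TSV metadata table
#' (`meta.tsv`: record_id, prescription), a JSON shape header
#' (`shape.json`) and the embedding matrix as row-major little-endian
#' float32 (`embeddings.f32`). Writing a loaded index reproduces the files
#' byte-for-byte.
#'
#' @param index A `pemr_index`.
#' @param path Directory path.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "pemr_index"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(record_id = index$record_ids,
               prescription = index$prescriptions),
    file.path(path, "meta.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  shape <- list(nrow = nrow(index$embeddings), ncol = ncol(index$embeddings),
                dtype = "float32", order = "row-major",
                fingerprint = index$fingerprint)
  writeLines(jsonlite::toJSON(shape, auto_unbox = TRUE, null = "null"),
             file.path(path, "shape.json"))
  con <- file(file.path(path, "embeddings.f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(index$embeddings)), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  shape <- jsonlite::fromJSON(file.path(path, "shape.json"))
  meta <- utils::read.delim(file.path(path, "meta.tsv"),
                            stringsAsFactors = FALSE, quote = "",
                            encoding = "UTF-8")
  con <- file(file.path(path, "embeddings.f32"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = shape$nrow * shape$ncol, size = 4L,
                  endian = "little")
  emb <- matrix(vals, nrow = shape$nrow, ncol = shape$ncol, byrow = TRUE)
  idx <- reference_index(emb, meta$prescription, meta$record_id,
                         fingerprint = shape$fingerprint)
  # rows were stored normalized in float32; keep the stored values exactly
  idx$embeddings <- emb
  idx
}

#' @export
print.pemr_recommendation <- function(x, ...) {
  cat(sprintf("Recommendation for '%s':\n", x$query_id))
  print(x$ranked, row.names = FALSE)
  invisible(x)
}
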