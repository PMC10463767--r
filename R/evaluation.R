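#' Correlation metrics with explicit undefined flagging
#'
#' Sample Pearson correlation, and Spearman as Pearson on mid-ranks
#' (average ranks for ties). With 0/1 pair labels, Pearson is the
#' point-biserial special case and is computed with the ordinary formula
#' (identical value). A constant input makes the correlation undefined;
#' rather than silently returning 0 (which would corrupt best-checkpoint
#' selection), the result is `NA` carrying a `reason` attribute.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`, or flagged `NA`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(x, y)
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(x, y, method = "spearman")
}

#' Top-N recommendation accuracy
#'
#' A query counts as a hit when its true prescription appears among the
#' first `n` distinct recommended prescriptions; the accuracy is hits over
#' the number of queries.
#'
#' @param recommendations List of `pemr_recommendation` objects (or data
#'   frames with a `prescription` column), one per query.
#' @param truths Character vector of true prescriptions, aligned.
#' @param n Cut-off (>= 1).
#' @return Accuracy in `[0, 1]`.
#' @export
topn_accuracy <- function(recommendations, truths, n) {
  stopifnot(length(recommendations) == length(truths), n >= 1L)
  if (length(truths) == 0L) stop("empty query set")
  hits <- vapply(seq_along(truths), function(i) {
    r <- recommendations[[i]]
    rx <- if (is.data.frame(r)) r$prescription else r$ranked$prescription
    truths[i] %in% utils::head(rx, n)
  }, logical(1))
  sum(hits) / length(truths)
}

#' Run a recommendation evaluation protocol
#'
#' Builds a reference index, serializes the queries with the chosen field
#' groups, retrieves for every query and computes Top-n accuracy at each
#' requested cut-off. The protocol label is decided by prescription-set
#' overlap with the training manifest: `open_set` when the query
#' prescriptions are disjoint from the prescriptions seen in training,
#' `closed_set` otherwise. A query whose true prescription is absent from
#' the reference set counts as an automatic miss (it cannot be retrieved);
#' the open-set protocol depends on this convention. By default both the
#' queries and the reference are serialized with the same `groups`, which
#' is how the field-ablation experiment presents incomplete inputs;
#' `reference_groups` overrides the reference side.
#'
#' @param encoder A `pemr_encoder` or `function(texts) -> matrix`.
#' @param query_records,reference_records Non-empty [pemr_corpus] objects.
#' @param groups Field groups for query serialization.
#' @param ns Integer cut-offs (default `c(1, 3, 5)`).
#' @param train_prescriptions Prescriptions present in the training data;
#'   used only to label the protocol.
#' @param reference_groups Field groups for the reference side (defaults
#'   to `groups`).
#' @param pooling Pooling strategy for `pemr_encoder` inputs.
#' @return Object of class `pemr_eval_report`: `topn_accuracy` (named by
#'   `n`), `n_queries`, `protocol`, `input_groups`, `missing_truth`, and
#'   `ranks`, the per-query data frame of truth ranks (`Inf` when the
#'   truth is not retrievable).
#' @export
run_protocol <- function(encoder, query_records, reference_records,
                         groups = names(pemr_field_groups), ns = c(1L, 3L, 5L),
                         train_prescriptions = NULL,
                         reference_groups = groups, pooling = "cls") {
  stopifnot(nrow(query_records) >= 1L, nrow(reference_records) >= 1L,
            all(ns >= 1L))
  fn <- if (inherits(encoder, "pemr_encoder"))
    as_encode_fn(encoder, pooling) else match.fun(encoder)
  index <- build_index(reference_records, fn, groups = reference_groups)
  qtexts <- serialize_records(query_records, groups)
  Q <- fn(qtexts)
  truths <- query_records$prescription

  ranks <- vapply(seq_len(nrow(query_records)), function(i) {
    r <- rank_prescriptions(Q[i, ], index, n = length(index$prescriptions))
    pos <- match(truths[i], r$df$prescription)
    if (is.na(pos)) Inf else as.numeric(pos)
  }, numeric(1))

  acc <- vapply(ns, function(n) mean(ranks <= n), numeric(1))
  names(acc) <- as.character(ns)

  protocol <- if (is.null(train_prescriptions)) "closed_set" else {
    if (length(intersect(unique(truths), unique(train_prescriptions))) == 0L)
      "open_set" else "closed_set"
  }
  structure(list(topn_accuracy = acc, n_queries = nrow(query_records),
                 protocol = protocol, input_groups = groups,
                 missing_truth = sum(!is.finite(ranks)),
                 ranks = data.frame(query_id = query_records$record_id,
                                    truth = truths, rank = ranks,
                                    stringsAsFactors = FALSE),
                 pearson = NA_real_, spearman = NA_real_),
            class = "pemr_eval_report")
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `pemr_eval_report`.
#' @param path Output path; `NULL` returns the JSON string.
#' @param ranks_csv Optional path for a per-query CSV of truth ranks
#'   (audit trail).
#' @export
write_eval_report <- function(report, path = NULL, ranks_csv = NULL) {
  stopifnot(inherits(report, "pemr_eval_report"))
  obj <- list(protocol = report$protocol,
              input_groups = report$input_groups,
              n_queries = report$n_queries,
              missing_truth = report$missing_truth,
              topn_accuracy = as.list(report$topn_accuracy),
              pearson = if (is.na(report$pearson)) NULL
                        else as.numeric(report$pearson),
              spearman = if (is.na(report$spearman)) NULL
                         else as.numeric(report$spearman))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(ranks_csv))
    utils::write.csv(report$ranks, ranks_csv, row.names = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.pemr_eval_report <- function(x, ...) {
  cat(sprintf("%s evaluation on %d queries (groups: %s)\n", x$protocol,
              x$n_queries, paste(x$input_groups, collapse = "+")))
  for (n in names(x$topn_accuracy))
    cat(sprintf("  Top-%s accuracy: %.4f\n", n, x$topn_accuracy[[n]]))
  if (x$missing_truth > 0)
    cat(sprintf("  %d query(ies) with truth absent from the reference\n",
                x$missing_truth))
  invisible(x)
}
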