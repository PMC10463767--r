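#' Field groups of a plant electronic medical record
#'
#' A PEMR is organised by the disease-triangle principle of plant pathology
#' (environment, host plant, pathogen manifestation): three groups of three
#' free-text fields each, plus the prescription label attached by the plant
#' doctor. This constant fixes the canonical field order used everywhere a
#' record is serialized to text.
#'
#' @format Named list mapping group name to a character vector of field names.
#' @export
pemr_field_groups <- list(
  environment = c("onset_date", "location", "field_distribution"),
  plant       = c("species", "growth_stage", "affected_part"),
  symptom     = c("severity", "main_symptoms", "detail")
)

pemr_fields <- function() unlist(pemr_field_groups, use.names = FALSE)

#' Construct a PEMR corpus data frame
#'
#' Validates and assembles a flat `data.frame` of plant records, one row per
#' record, with columns `record_id`, the nine group fields (see
#' [pemr_field_groups]) and `prescription`.
#'
#' @param df Data frame containing at least `record_id` and `prescription`;
#'   missing field columns are filled with empty strings.
#' @return A `data.frame` of class `pemr_corpus`.
#' @export
pemr_corpus <- function(df) {
  stopifnot(is.data.frame(df), "record_id" %in% names(df),
            "prescription" %in% names(df))
  for (f in pemr_fields()) {
    if (!f %in% names(df)) df[[f]] <- ""
    df[[f]] <- as.character(df[[f]])
    df[[f]][is.na(df[[f]])] <- ""
  }
  df$record_id <- as.character(df$record_id)
  df$prescription <- as.character(df$prescription)
  if (anyDuplicated(df$record_id))
    stop("record_id values must be unique within a corpus")
  df <- df[, c("record_id", pemr_fields(), "prescription")]
  rownames(df) <- NULL
  class(df) <- c("pemr_corpus", "data.frame")
  df
}

# Fold fullwidth ASCII forms (U+FF01..U+FF5E) and the ideographic space
# (U+3000) to their halfwidth equivalents; PEMR text entered on mobile IMEs
# mixes the two widths freely.
to_halfwidth <- function(x) {
  chartr(intToUtf8(c(0x3000L, 0xFF01:0xFF5E)),
         intToUtf8(c(0x20L, 0x21:0x7E)), x)
}

normalize_text <- function(x) {
  x <- to_halfwidth(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalize raw records and standardize prescription names
#'
#' Applies text normalization (whitespace trimming/collapsing and
#' fullwidth-to-halfwidth folding) to every field, maps each prescription to
#' its canonical name through an alias table, rejects invalid records, and
#' removes exact duplicates. A record is invalid when its prescription is
#' empty after aliasing or when all three symptom fields are empty. The
#' duplicate key is the full serialized text of all field groups plus the
#' prescription, so two records differing in any field are both kept.
#'
#' @param df Data frame of raw records (same columns as [pemr_corpus]).
#' @param alias_map Optional data frame with columns `variant` and
#'   `canonical`; variants are matched case-insensitively after
#'   normalization. Prescriptions without an alias entry are kept as their
#'   normalized, case-folded form.
#' @return List with `records` (a clean [pemr_corpus]) and `rejected`
#'   (data frame of `record_id`, `reason` for every dropped record).
#' @export
normalize_records <- function(df, alias_map = NULL) {
  stopifnot(is.data.frame(df), "prescription" %in% names(df))
  if (!"record_id" %in% names(df)) df$record_id <- as.character(seq_len(nrow(df)))
  for (f in c(pemr_fields(), "prescription")) {
    if (!f %in% names(df)) df[[f]] <- ""
    df[[f]][is.na(df[[f]])] <- ""
    df[[f]] <- normalize_text(df[[f]])
  }
  rx <- tolower(df$prescription)
  if (!is.null(alias_map)) {
    stopifnot(all(c("variant", "canonical") %in% names(alias_map)))
    key <- tolower(normalize_text(alias_map$variant))
    hit <- match(rx, key)
    rx[!is.na(hit)] <- normalize_text(alias_map$canonical)[hit[!is.na(hit)]]
  }
  df$prescription <- rx

  reasons <- rep(NA_character_, nrow(df))
  reasons[!nzchar(df$prescription)] <- "empty prescription"
  sym_empty <- Reduce(`&`, lapply(pemr_field_groups$symptom,
                                  function(f) !nzchar(df[[f]])))
  reasons[is.na(reasons) & sym_empty] <- "empty symptom group"

  keep <- is.na(reasons)
  kept <- df[keep, , drop = FALSE]
  dup_key <- paste(do.call(paste, c(kept[pemr_fields()], sep = "\x1f")),
                   kept$prescription, sep = "\x1f")
  dup <- duplicated(dup_key)
  rejected <- data.frame(
    record_id = c(df$record_id[!keep], kept$record_id[dup]),
    reason = c(reasons[!keep], rep("duplicate record", sum(dup))),
    stringsAsFactors = FALSE
  )
  list(records = pemr_corpus(kept[!dup, , drop = FALSE]), rejected = rejected)
}

#' Serialize records to encoder input text
#'
#' Concatenates the selected field groups of each record into one string, in
#' the fixed order environment, plant, symptom, with fields joined by a
#' reserved separator token. Omitted groups contribute nothing, which is how
#' the field-ablation experiments present incomplete inputs (for example a
#' farmer reporting symptoms only).
#'
#' @param records A [pemr_corpus] or compatible data frame.
#' @param groups Character subset of `c("environment","plant","symptom")`.
#' @param sep Separator token placed between fields (default `"[FSEP]"`;
#'   registered in the tokenizer vocabulary).
#' @return Character vector of serialized texts, one per record.
#' @export
serialize_records <- function(records, groups = names(pemr_field_groups),
                              sep = "[FSEP]") {
  groups <- match.arg(groups, names(pemr_field_groups), several.ok = TRUE)
  if (length(groups) == 0L) stop("at least one field group must be selected")
  fields <- unlist(pemr_field_groups[names(pemr_field_groups) %in% groups],
                   use.names = FALSE)
  cols <- lapply(fields, function(f) as.character(records[[f]]))
  do.call(paste, c(cols, sep = paste0(" ", sep, " ")))
}

#' Stratified dataset split with largest-remainder rounding
#'
#' Partitions a corpus into parts matching the requested ratios within every
#' stratum (by default the prescription label), so rare prescriptions appear
#' in each part roughly proportionally. Within a stratum, part sizes are the
#' largest-remainder rounding of `n * ratios`; a stratum with fewer records
#' than parts sends all its records to the largest-ratio part with a
#' warning, preserving rare prescriptions for training.
#'
#' @param records A [pemr_corpus].
#' @param ratios Positive numeric vector summing to 1 (e.g. `c(.8,.1,.1)`).
#' @param stratify_by Column used as the stratification key.
#' @param seed Integer seed controlling the within-stratum shuffle.
#' @return List of [pemr_corpus] parts, in ratio order. Disjoint, and their
#'   union is the input.
#' @export
split_dataset <- function(records, ratios, stratify_by = "prescription",
                          seed = 1L) {
  stopifnot(is.numeric(ratios), length(ratios) >= 2L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  key <- as.character(records[[stratify_by]])
  if (any(is.na(key) | !nzchar(key)))
    stop("every record needs a non-empty '", stratify_by, "' value")
  parts <- rep(list(integer(0)), length(ratios))
  withr::with_seed(seed, {
    for (s in sort(unique(key))) {
      idx <- which(key == s)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      if (n < length(ratios)) {
        warning(sprintf(
          "stratum '%s' has %d record(s), fewer than %d parts; all assigned to the largest part",
          s, n, length(ratios)))
        big <- which.max(ratios)
        parts[[big]] <- c(parts[[big]], idx)
        next
      }
      sizes <- largest_remainder(n, ratios)
      stop_at <- cumsum(sizes)
      start_at <- c(1L, head(stop_at, -1L) + 1L)
      for (p in seq_along(ratios)) {
        if (sizes[p] > 0L)
          parts[[p]] <- c(parts[[p]], idx[start_at[p]:stop_at[p]])
      }
    }
  })
  lapply(parts, function(i) pemr_corpus(records[sort(i), , drop = FALSE]))
}

# n * ratios rounded so the sizes sum to n: floor the quotas, then hand the
# remaining units to the largest fractional parts (ties to the earlier part).
largest_remainder <- function(n, ratios) {
  quota <- n * ratios
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    frac <- quota - sizes
    ord <- order(-frac, seq_along(ratios))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  as.integer(sizes)
}

#' Build balanced same-prescription text pairs
#'
#' Enumerates all unordered pairs of records, labels a pair 1 when the two
#' records share a normalized prescription and 0 otherwise, and down-samples
#' the (usually dominant) negatives to `round(balance_ratio * n_pos)`. This
#' turns disease-prescription records into the binary disease-disease pairs
#' that the contrastive objectives train on.
#'
#' @param records A [pemr_corpus] with at least two rows.
#' @param groups Field groups serialized into the pair texts.
#' @param balance_ratio Target ratio of negatives to positives (default 1).
#' @param seed Integer seed for negative down-sampling and output shuffling.
#' @param max_pairs Optional cap on the emitted pair count; when exceeded, a
#'   seeded subsample stratified by label (preserving the balance) is kept.
#' @param sep Field separator token, as in [serialize_records].
#' @return Data frame of class `pemr_pairs` with columns `text_a`, `text_b`,
#'   `label`, `id_a`, `id_b`; row order is a seeded shuffle.
#' @export
build_pairs <- function(records, groups = names(pemr_field_groups),
                        balance_ratio = 1, seed = 1L, max_pairs = Inf,
                        sep = "[FSEP]") {
  n <- nrow(records)
  if (n < 2L) {
    out <- data.frame(text_a = character(0), text_b = character(0),
                      label = integer(0), id_a = character(0),
                      id_b = character(0), stringsAsFactors = FALSE)
    class(out) <- c("pemr_pairs", "data.frame")
    return(out)
  }
  stopifnot(balance_ratio > 0)
  texts <- serialize_records(records, groups, sep = sep)
  ij <- utils::combn(n, 2L)
  i <- ij[1L, ]; j <- ij[2L, ]
  lab <- as.integer(records$prescription[i] == records$prescription[j])
  pos <- which(lab == 1L); neg <- which(lab == 0L)
  withr::with_seed(seed, {
    if (length(pos) == 0L) {
      warning("no positive pairs; returning all negatives unbalanced")
      keep <- neg
    } else {
      n_neg <- round(balance_ratio * length(pos))
      if (length(neg) > n_neg) neg <- sort(sample(neg, n_neg))
      keep <- c(pos, neg)
    }
    if (is.finite(max_pairs) && length(keep) > max_pairs) {
      kp <- keep[lab[keep] == 1L]; kn <- keep[lab[keep] == 0L]
      fr <- max_pairs / length(keep)
      if (length(kp)) kp <- sort(sample(kp, round(fr * length(kp))))
      if (length(kn)) kn <- sort(sample(kn, min(length(kn), max_pairs - length(kp))))
      keep <- c(kp, kn)
    }
    keep <- keep[sample.int(length(keep))]
  })
  out <- data.frame(text_a = texts[i[keep]], text_b = texts[j[keep]],
                    label = lab[keep],
                    id_a = records$record_id[i[keep]],
                    id_b = records$record_id[j[keep]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pemr_pairs", "data.frame")
  out
}

#' Read and write PEMR records as JSON Lines
#'
#' One record object per line, UTF-8, with the three field groups nested
#' under `environment`, `plant` and `symptom`.
#'
#' @param path File path.
#' @return `read_records` returns a [pemr_corpus]; `write_records` returns
#'   `path` invisibly.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    row <- list(record_id = x$record_id %||% NA_character_,
                prescription = x$prescription %||% "")
    for (g in names(pemr_field_groups)) {
      for (f in pemr_field_groups[[g]]) {
        row[[f]] <- as.character(x[[g]][[f]] %||% "")
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  pemr_corpus(do.call(rbind, rows))
}

#' @rdname read_records
#' @param records A [pemr_corpus].
#' @export
write_records <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(r) {
    obj <- list(record_id = records$record_id[r])
    for (g in names(pemr_field_groups)) {
      obj[[g]] <- as.list(records[r, pemr_field_groups[[g]], drop = FALSE])
    }
    obj$prescription <- records$prescription[r]
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write text-pair files
#'
#' Tab-separated with header `text_a  text_b  label`. Extra bookkeeping
#' columns (`id_a`, `id_b`) are written when present and restored on read.
#'
#' @param path File path.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          encoding = "UTF-8")
  stopifnot(all(c("text_a", "text_b", "label") %in% names(df)))
  df$label <- as.integer(df$label)
  class(df) <- c("pemr_pairs", "data.frame")
  df
}

#' @rdname read_pairs
#' @param pairs A `pemr_pairs` data frame.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a prescription alias table
#'
#' Two-column TSV `variant  canonical` used by [normalize_records] to
#' standardize pesticide names.
#'
#' @param path File path.
#' @export
read_alias_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          encoding = "UTF-8")
  stopifnot(all(c("variant", "canonical") %in% names(df)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
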