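#' Configuration for the synthetic PEMR corpus generator
#'
#' The generator emulates the structure of real plant electronic medical
#' records without any real data: a set of latent disease classes, each
#' mapped to one prescription, each owning a disjoint core vocabulary per
#' field group, plus a shared vocabulary common to all classes (generic
#' agronomic filler words). Field texts of a record are token draws from the
#' record's class vocabulary, with each token replaced by a shared token
#' with probability `noise_rate`; field groups outside `signal_groups` are
#' drawn entirely from the shared vocabulary and therefore carry no class
#' signal.
#'
#' @param n_classes Number of latent disease classes (>= 2).
#' @param records_per_class Records generated per class.
#' @param vocab_core Core vocabulary size per class per field group.
#' @param vocab_shared Size of the class-independent shared vocabulary.
#' @param tokens_per_field Tokens drawn for each of the nine fields.
#' @param noise_rate Probability in `[0,1)` that a signal token is replaced
#'   by a shared token.
#' @param signal_groups Field groups that carry class signal.
#' @param share_prescription If `TRUE`, the first two classes share one
#'   prescription (a many-diseases-one-prescription corpus, used to check
#'   that pair labels follow prescriptions, not diseases).
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   configuration.
#' @return A list of class `pemr_generator_config`.
#' @export
generator_config <- function(n_classes = 8L, records_per_class = 60L,
                             vocab_core = 20L, vocab_shared = 50L,
                             tokens_per_field = 6L, noise_rate = 0.1,
                             signal_groups = names(pemr_field_groups),
                             share_prescription = FALSE, seed = 1L) {
  stopifnot(n_classes >= 2L, records_per_class >= 1L, vocab_core >= 1L,
            vocab_shared >= 0L, tokens_per_field >= 1L,
            noise_rate >= 0, noise_rate < 1, length(signal_groups) >= 1L)
  signal_groups <- match.arg(signal_groups, names(pemr_field_groups),
                             several.ok = TRUE)
  if (noise_rate > 0 && vocab_shared == 0L)
    stop("noise_rate > 0 requires a non-empty shared vocabulary")
  structure(list(n_classes = as.integer(n_classes),
                 records_per_class = as.integer(records_per_class),
                 vocab_core = as.integer(vocab_core),
                 vocab_shared = as.integer(vocab_shared),
                 tokens_per_field = as.integer(tokens_per_field),
                 noise_rate = noise_rate, signal_groups = signal_groups,
                 share_prescription = isTRUE(share_prescription),
                 seed = as.integer(seed)),
            class = "pemr_generator_config")
}

group_tag <- c(environment = "env", plant = "plt", symptom = "sym")

core_vocab <- function(class_id, group, n) {
  sprintf("c%03d_%s_w%02d", class_id, group_tag[[group]], seq_len(n))
}

shared_vocab <- function(n) {
  if (n == 0L) character(0) else sprintf("shared_w%03d", seq_len(n))
}

#' Generate a synthetic PEMR corpus with known class structure
#'
#' @param config A [generator_config].
#' @param class_ids Internal: explicit class identifiers (defaults to
#'   `1:n_classes`); used by [generate_open_set] to allocate fresh classes.
#' @return List with `records` (a [pemr_corpus]) and `truth`, a data frame
#'   mapping `record_id` to its latent `class` and `prescription`, carrying
#'   the configuration as attribute `"config"`.
#' @export
generate_corpus <- function(config, class_ids = seq_len(config$n_classes)) {
  stopifnot(inherits(config, "pemr_generator_config"),
            length(class_ids) == config$n_classes)
  shared <- shared_vocab(config$vocab_shared)
  rx <- sprintf("rx_%03d", class_ids)
  if (config$share_prescription) rx[2L] <- rx[1L]

  draw_field <- function(class_id, group) {
    k <- config$tokens_per_field
    if (group %in% config$signal_groups) {
      toks <- sample(core_vocab(class_id, group, config$vocab_core), k,
                     replace = TRUE)
      if (config$noise_rate > 0) {
        flip <- stats::runif(k) < config$noise_rate
        if (any(flip)) toks[flip] <- sample(shared, sum(flip), replace = TRUE)
      }
    } else {
      if (length(shared) == 0L) return("")
      toks <- sample(shared, k, replace = TRUE)
    }
    paste(toks, collapse = " ")
  }

  rows <- withr::with_seed(config$seed, {
    out <- vector("list", config$n_classes * config$records_per_class)
    i <- 0L
    for (ci in seq_len(config$n_classes)) {
      for (r in seq_len(config$records_per_class)) {
        i <- i + 1L
        row <- list(record_id = sprintf("syn-%03d-%03d", class_ids[ci], r))
        for (g in names(pemr_field_groups)) {
          for (f in pemr_field_groups[[g]]) {
            row[[f]] <- draw_field(class_ids[ci], g)
          }
        }
        row$prescription <- rx[ci]
        row$class <- class_ids[ci]
        out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  truth <- data.frame(record_id = rows$record_id, class = rows$class,
                      prescription = rows$prescription,
                      stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  rows$class <- NULL
  list(records = pemr_corpus(rows), truth = truth)
}

#' Generate an open-set corpus of unseen classes
#'
#' Emulates the open-set evaluation setting: diseases and prescriptions that
#' never appeared in the base (training) corpus, while the shared filler
#' vocabulary is reused so the text style transfers but the labels do not.
#'
#' @param config A [generator_config] describing the open-set corpus (its
#'   `n_classes` is the number of new classes).
#' @param base_truth The `truth` data frame of the base corpus.
#' @return As [generate_corpus]; classes and prescriptions are guaranteed
#'   disjoint from the base corpus.
#' @export
generate_open_set <- function(config, base_truth) {
  stopifnot(is.data.frame(base_truth), "class" %in% names(base_truth))
  new_ids <- max(base_truth$class) + seq_len(config$n_classes)
  if (length(intersect(new_ids, unique(base_truth$class))) > 0L)
    stop("open-set class identifiers collide with the base corpus")
  open <- generate_corpus(config, class_ids = new_ids)
  if (length(intersect(unique(open$truth$prescription),
                       unique(base_truth$prescription))) > 0L)
    stop("open-set prescriptions collide with the base corpus")
  open
}
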