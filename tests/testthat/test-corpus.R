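test_that("normalization trims, folds width, and applies prescription aliases", {
  raw <- data.frame(
    record_id = "x1",
    severity = "  mild ", main_symptoms = "ｙellow　spots",
    detail = "ok",
    prescription = " Mancozeb  80%WP", stringsAsFactors = FALSE)
  alias <- data.frame(variant = "mancozeb 80%wp", canonical = "mancozeb",
                      stringsAsFactors = FALSE)
  res <- normalize_records(raw, alias)
  expect_equal(res$records$prescription, "mancozeb")
  expect_equal(res$records$severity, "mild")
  # fullwidth letter and ideographic space folded to ASCII
  expect_equal(res$records$main_symptoms, "yellow spots")
  expect_equal(nrow(res$rejected), 0L)
})

test_that("invalid and duplicate records are rejected with reasons", {
  raw <- data.frame(
    record_id = c("a", "b", "c", "d"),
    severity = c("mild", "mild", "mild", ""),
    main_symptoms = c("spots", "spots", "mold", ""),
    detail = c("", "", "", ""),
    prescription = c("rx1", "rx1", "", "rx2"),
    stringsAsFactors = FALSE)
  res <- normalize_records(raw)
  expect_equal(res$records$record_id, c("a", "c")[1])  # b dup, c no rx, d no symptom
  expect_setequal(res$rejected$record_id, c("b", "c", "d"))
  expect_equal(res$rejected$reason[res$rejected$record_id == "b"],
               "duplicate record")
  expect_equal(res$rejected$reason[res$rejected$record_id == "c"],
               "empty prescription")
  expect_equal(res$rejected$reason[res$rejected$record_id == "d"],
               "empty symptom group")
})

test_that("serialization is a deterministic ordered projection of field groups", {
  corp <- tiny_corpus()
  # symptom-only projection in declared field order
  s <- serialize_records(corp[1, ], groups = "symptom")
  expect_equal(s, "mild [FSEP] yellow spots [FSEP] note 1")
  # independently hand-built full concatenation for the same record
  r <- corp[1, ]
  hand <- paste(r$onset_date, r$location, r$field_distribution, r$species,
                r$growth_stage, r$affected_part, r$severity, r$main_symptoms,
                r$detail, sep = " [FSEP] ")
  expect_equal(serialize_records(corp[1, ]), hand)
  expect_identical(serialize_records(corp), serialize_records(corp))
  expect_error(serialize_records(corp, groups = character(0)))
})

test_that("stratified split matches largest-remainder ratios per stratum", {
  one <- quick_corpus(n_classes = 2L, records_per_class = 5L)$records
  one$prescription <- "same"
  one <- pemr_corpus(one)
  parts <- split_dataset(one, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(vapply(parts, nrow, integer(1)), c(8L, 1L, 1L))

  twenty <- quick_corpus(n_classes = 2L, records_per_class = 10L)$records
  twenty$prescription <- "same"
  halves <- split_dataset(pemr_corpus(twenty), c(0.5, 0.5), seed = 3)
  expect_equal(vapply(halves, nrow, integer(1)), c(10L, 10L))

  # strata of 7 and 3 with ratios .7/.3: largest remainder gives (5,2), (2,1)
  df <- quick_corpus(n_classes = 2L, records_per_class = 5L)$records
  df$prescription <- rep(c("p1", "p2"), c(7, 3))
  parts <- split_dataset(pemr_corpus(df), c(0.7, 0.3), seed = 1)
  tab1 <- table(parts[[1]]$prescription)
  tab2 <- table(parts[[2]]$prescription)
  expect_equal(as.integer(tab1[c("p1", "p2")]), c(5L, 2L))
  expect_equal(as.integer(tab2[c("p1", "p2")]), c(2L, 1L))
})

test_that("splits partition the corpus and are seed-deterministic", {
  corp <- quick_corpus(n_classes = 4L, records_per_class = 11L)$records
  parts <- split_dataset(corp, c(0.8, 0.1, 0.1), seed = 9)
  ids <- unlist(lapply(parts, `[[`, "record_id"))
  expect_equal(sort(ids), sort(corp$record_id))   # union, no loss
  expect_equal(anyDuplicated(ids), 0L)            # disjoint
  again <- split_dataset(corp, c(0.8, 0.1, 0.1), seed = 9)
  expect_identical(lapply(parts, as.data.frame), lapply(again, as.data.frame))
  other <- split_dataset(corp, c(0.8, 0.1, 0.1), seed = 10)
  expect_equal(vapply(other, nrow, integer(1)), vapply(parts, nrow, integer(1)))
})

test_that("a stratum smaller than the part count goes to the largest part", {
  df <- tiny_corpus()  # every prescription has fewer than 3 records
  w <- capture_warnings(parts <- split_dataset(df, c(0.6, 0.2, 0.2), seed = 1))
  expect_true(all(grepl("fewer than", w)))
  expect_length(w, 3L)
  expect_true("rx_b" %in% parts[[1]]$prescription)
  expect_equal(nrow(parts[[1]]), 5L)
})

test_that("pair construction enumerates, labels, and balances correctly", {
  expect_equal(nrow(build_pairs(tiny_corpus()[1, , drop = FALSE])), 0L)

  # labels A A B B: 6 unordered pairs, 2 positive; ratio 1 keeps 2 + 2
  df <- tiny_corpus()[c(1, 2, 4, 5), ]
  pairs <- build_pairs(df, seed = 4)
  expect_equal(nrow(pairs), 4L)
  expect_equal(sum(pairs$label == 1L), 2L)
  expect_equal(sum(pairs$label == 0L), 2L)

  # labels A A B: 1 positive + 1 of the 2 candidate negatives
  pairs3 <- build_pairs(tiny_corpus()[c(1, 2, 3), ], seed = 4)
  expect_equal(nrow(pairs3), 2L)
  expect_equal(sum(pairs3$label), 1L)
})

test_that("pair labels agree with an independent recomputation and counts bound", {
  corp <- quick_corpus(n_classes = 3L, records_per_class = 5L)$records
  pairs <- build_pairs(corp, balance_ratio = 2, seed = 7)
  n <- nrow(corp)
  expect_lte(nrow(pairs), n * (n - 1) / 2)
  rx <- setNames(corp$prescription, corp$record_id)
  relab <- as.integer(rx[pairs$id_a] == rx[pairs$id_b])  # oracle
  expect_identical(relab, pairs$label)
  expect_true(all(pairs$id_a != pairs$id_b))             # no self-pairs
  # positive count is exactly sum over labels of C(n_label, 2)
  all_pairs <- build_pairs(corp, balance_ratio = 1e9, seed = 7)
  expect_equal(sum(all_pairs$label == 1L),
               sum(choose(table(corp$prescription), 2)))
})

test_that("pair construction is seed-deterministic and warns without positives", {
  corp <- quick_corpus(n_classes = 3L, records_per_class = 4L)$records
  p1 <- build_pairs(corp, seed = 11)
  p2 <- build_pairs(corp, seed = 11)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- build_pairs(corp, seed = 12)
  expect_equal(table(p3$label), table(p1$label))

  singletons <- corp[!duplicated(corp$prescription), ]
  expect_warning(pn <- build_pairs(singletons, seed = 1), "no positive")
  expect_true(all(pn$label == 0L))
})

test_that("max_pairs caps the output with the balance preserved", {
  corp <- quick_corpus(n_classes = 3L, records_per_class = 8L)$records
  capped <- build_pairs(corp, seed = 2, max_pairs = 40)
  expect_lte(nrow(capped), 40L)
  expect_equal(sum(capped$label == 1L), sum(capped$label == 0L))
})

test_that("records and pairs round-trip through their file formats", {
  corp <- tiny_corpus()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_records(corp, f)
  back <- read_records(f)
  expect_equal(as.data.frame(back), as.data.frame(corp))

  pairs <- build_pairs(corp, seed = 1)
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, pf)
  expect_equal(as.data.frame(read_pairs(pf)), as.data.frame(pairs))
  expect_equal(readLines(pf, n = 1), "text_a\ttext_b\tlabel\tid_a\tid_b")

  af <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tcanonical", "bordeaux mix\tbordeaux mixture"), af)
  am <- read_alias_map(af)
  expect_equal(am$canonical, "bordeaux mixture")
})
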