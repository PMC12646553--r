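test_that("a JSONL cohort loads with visits, code sets and sizes intact", {
  path <- write_sample_cohort()
  ch <- read_cohort(path)
  expect_s3_class(ch, "csrec_cohort")
  expect_length(ch$patients, 1L)
  expect_length(ch$patients[[1]]$visits, 2L)
  v1 <- ch$patients[[1]]$visits[[1]]
  expect_length(v1$diagnoses, 10L)
  expect_length(v1$procedures, 3L)
  expect_length(v1$medications, 5L)
})

test_that("degenerate cohort files are handled explicitly", {
  empty <- tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_warning(ch <- read_cohort(empty), "empty")
  expect_length(ch$patients, 0L)

  bad <- tempfile(fileext = ".jsonl")
  writeLines('{"subject_id": "x", not json', bad)
  expect_error(read_cohort(bad), "line 1")

  nodiag <- tempfile(fileext = ".jsonl")
  writeLines(paste0('{"subject_id":"x","visits":[{"diagnoses":[],',
                    '"procedures":[],"medications":[]}]}'), nodiag)
  expect_error(read_cohort(nodiag), "diagnoses")

  expect_error(read_cohort(tempfile()), "no such file")
})

test_that("duplicate codes are deduplicated with a warning", {
  p <- list(list(subject_id = "s", visits = list(
    list(diagnoses = c("a", "a", "b"), procedures = character(),
         medications = character()))))
  expect_warning(ch <- as_cohort(p), "duplicate")
  expect_equal(ch$patients[[1]]$visits[[1]]$diagnoses, c("a", "b"))
})

test_that("write_cohort/read_cohort round-trips and is byte-stable", {
  set.seed(42)
  ch <- random_cohort(10)
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_cohort(ch, f1)
  ch2 <- read_cohort(f1)
  expect_equal(ch2, ch)
  write_cohort(ch2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("filter_cohort drops short patients and rare medications in order", {
  pats <- list(
    list(subject_id = "a", visits = list(
      list(diagnoses = "d1", procedures = character(), medications = c("X", "Y")))),
    list(subject_id = "b", visits = list(
      list(diagnoses = "d1", procedures = character(), medications = "X"),
      list(diagnoses = "d2", procedures = character(), medications = "Z"))),
    list(subject_id = "c", visits = list(
      list(diagnoses = "d1", procedures = character(), medications = "Z"),
      list(diagnoses = "d2", procedures = character(), medications = "Z"))))
  ch <- as_cohort(pats)

  # one-visit patient removed at min_visits = 2
  out <- filter_cohort(ch, min_visits = 2)
  expect_equal(vapply(out$patients, `[[`, "", "subject_id"), c("b", "c"))

  # identity filter
  expect_equal(filter_cohort(ch, min_visits = 1, min_med_freq = 0), ch)

  # brute-force frequency oracle: count visits containing each code
  all_visits <- unlist(lapply(ch$patients, `[[`, "visits"), recursive = FALSE)
  counts <- table(unlist(lapply(all_visits, function(v) unique(v$medications))))
  expect_equal(unname(counts[c("X", "Y", "Z")]), c(2, 1, 3),
               ignore_attr = TRUE)
  out3 <- filter_cohort(ch, min_visits = 1, min_med_freq = 3)
  meds_left <- unique(unlist(lapply(out3$patients, function(p)
    lapply(p$visits, `[[`, "medications"))))
  expect_equal(meds_left, "Z")

  # medication filter precedes the visit filter: removing X cannot revive "a"
  expect_error(filter_cohort(ch, min_visits = 3), "empty")
})

test_that("filter_cohort is idempotent", {
  set.seed(7)
  ch <- random_cohort(15)
  once <- filter_cohort(ch, min_visits = 2, min_med_freq = 2)
  twice <- filter_cohort(once, min_visits = 2, min_med_freq = 2)
  expect_equal(twice, once)
})

test_that("vocabulary indexes every distinct code exactly once", {
  path <- write_sample_cohort()
  ch <- read_cohort(path)
  vocab <- build_vocabulary(ch)
  expect_equal(vocab$n_diag, 12L)  # union of the two visits
  expect_equal(vocab$n_med, 6L)
  expect_equal(vocab$n_proc, 3L)
  expect_false(anyDuplicated(vocab$med) > 0)

  # adding an already-present code changes nothing (set semantics)
  ch2 <- ch
  ch2$patients[[1]]$visits[[1]]$medications <-
    ch2$patients[[1]]$visits[[1]]$medications[c(1:5, 1)]
  expect_warning(v <- as_cohort(ch2$patients), "duplicate")
  expect_equal(build_vocabulary(v), vocab)
})

test_that("a cohort without procedures builds a vocabulary with a warning", {
  p <- list(list(subject_id = "s", visits = list(
    list(diagnoses = c("496", "2449"), procedures = character(),
         medications = character()))))
  ch <- as_cohort(p)
  w <- capture_warnings(vocab <- build_vocabulary(ch))
  expect_match(w, "no procedure", all = FALSE)
  expect_equal(vocab$n_diag, 2L)
  expect_equal(vocab$n_proc, 0L)
})

test_that("encode_visit produces correct multi-hot vectors", {
  path <- write_sample_cohort()
  ch <- read_cohort(path)
  vocab <- build_vocabulary(ch)
  v <- ch$patients[[1]]$visits[[1]]
  enc <- encode_visit(v, vocab)
  expect_equal(sum(enc$v_d), 10L)
  expect_equal(sum(enc$v_p), 3L)
  expect_equal(which(enc$v_d == 1L), match(sort(v$diagnoses), vocab$diag),
               ignore_attr = TRUE)

  # empty medication set encodes to all zeros (first-visit history case)
  v$medications <- character()
  expect_equal(sum(encode_visit(v, vocab)$v_m), 0L)

  expect_error(encode_visit(list(diagnoses = "zzz", procedures = character(),
                                 medications = character()), vocab), "zzz")
})

test_that("encode_visit popcounts equal set cardinalities on random visits", {
  set.seed(11)
  codes <- sprintf("c%03d", 1:40)
  vocab <- structure(list(diag = codes, proc = codes, med = codes,
                          n_diag = 40L, n_proc = 40L, n_med = 40L),
                     class = "csrec_vocab")
  for (i in 1:1000) {
    v <- list(diagnoses = sample(codes, sample.int(10, 1)),
              procedures = sample(codes, sample.int(10, 1) - 1),
              medications = sample(codes, sample.int(10, 1) - 1))
    enc <- encode_visit(v, vocab)
    expect_identical(sum(enc$v_d), length(v$diagnoses))
    expect_identical(sum(enc$v_p), length(v$procedures))
    expect_identical(sum(enc$v_m), length(v$medications))
    # per-index membership oracle
    expect_identical(which(enc$v_m == 1L), sort(match(v$medications, codes)))
  }
})

test_that("split_cohort gives exact 23:16:16 sizes for 55 patients", {
  set.seed(3)
  ch <- random_cohort(55)
  parts <- split_cohort(ch, c(23, 16, 16), seed = 99)
  expect_equal(length(parts$train$patients), 23L)
  expect_equal(length(parts$val$patients), 16L)
  expect_equal(length(parts$test$patients), 16L)
  # determinism
  parts2 <- split_cohort(ch, c(23, 16, 16), seed = 99)
  expect_identical(parts, parts2)
})

test_that("split_cohort partitions are disjoint and exhaustive", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    ch <- random_cohort(n)
    parts <- split_cohort(ch, seed = i)
    ids <- lapply(parts, function(p) vapply(p$patients, `[[`, "", "subject_id"))
    expect_equal(sort(unname(unlist(ids))),
                 sort(vapply(ch$patients, `[[`, "", "subject_id")))
    expect_length(intersect(ids$train, ids$val), 0L)
    expect_length(intersect(ids$train, ids$test), 0L)
    expect_length(intersect(ids$val, ids$test), 0L)
  }
})
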