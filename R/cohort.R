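## Longitudinal EHR cohorts: one patient = an ordered sequence of visits, each
## visit a set of diagnosis codes, procedure codes and medication codes.
## Codes are opaque strings (ICD-9-like for diagnoses/procedures, ATC-like for
## medications); the ATC level is carried as a cohort-level flag only.

#' Construct a cohort object
#'
#' A cohort is an ordered list of patients, each an ordered list of visits;
#' every visit holds three code sets (diagnoses, procedures, medications).
#' Diagnosis sets must be non-empty; duplicate codes within a set are dropped
#' with a warning. Visit order is the order given.
#'
#' @param patients List of patients. Each patient is a list with elements
#'   `subject_id` (string) and `visits`, a list of visits; each visit is a list
#'   with `hadm_id` (string, optional), `diagnoses`, `procedures`,
#'   `medications` (character vectors; `diagnoses` non-empty).
#' @param level Medication code granularity flag, `"ATC04"` or `"ATC05"`.
#'   Codes are treated as opaque strings either way.
#' @return An object of class `csrec_cohort`.
#' @export
as_cohort <- function(patients, level = c("ATC05", "ATC04")) {
  level <- match.arg(level)
  ids <- vapply(patients, function(p) as.character(p$subject_id), "")
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  patients <- lapply(patients, function(p) {
    if (length(p$visits) < 1L)
      stop("patient ", p$subject_id, " has zero visits")
    p$visits <- lapply(seq_along(p$visits), function(i) {
      v <- p$visits[[i]]
      for (f in c("diagnoses", "procedures", "medications")) {
        codes <- as.character(if (is.null(v[[f]])) character() else v[[f]])
        if (any(!nzchar(codes)))
          stop("patient ", p$subject_id, " visit ", i, ": empty code string in ", f)
        if (anyDuplicated(codes)) {
          warning("patient ", p$subject_id, " visit ", i,
                  ": duplicate codes in ", f, " removed", call. = FALSE)
          codes <- unique(codes)
        }
        v[[f]] <- codes
      }
      if (length(v$diagnoses) == 0L)
        stop("patient ", p$subject_id, " visit ", i, ": diagnoses must be non-empty")
      if (is.null(v$hadm_id)) v$hadm_id <- sprintf("%s-%d", p$subject_id, i)
      v[c("hadm_id", "diagnoses", "procedures", "medications")]
    })
    list(subject_id = as.character(p$subject_id), visits = p$visits)
  })
  structure(list(patients = patients, level = level), class = "csrec_cohort")
}

#' Read a cohort from JSONL
#'
#' The interchange format is one patient per line:
#' `{"subject_id": "...", "visits": [{"hadm_id": "...", "diagnoses": [...],
#' "procedures": [...], "medications": [...]}, ...]}`. Files are UTF-8.
#' Visits are taken in file order. An empty file yields an empty cohort with a
#' warning; a malformed line raises an error naming the line.
#'
#' @param path Path to a JSONL file.
#' @inheritParams as_cohort
#' @return A `csrec_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, level = c("ATC05", "ATC04")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty cohort file: ", path, call. = FALSE)
    return(structure(list(patients = list(), level = level),
                     class = "csrec_cohort"))
  }
  patients <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop("parse error at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(rec$subject_id) || is.null(rec$visits))
      stop("parse error at line ", i, ": missing subject_id or visits",
           call. = FALSE)
    list(subject_id = rec$subject_id,
         visits = lapply(rec$visits, function(v)
           list(hadm_id = v$hadm_id,
                diagnoses = unlist(v$diagnoses),
                procedures = unlist(v$procedures),
                medications = unlist(v$medications))))
  })
  as_cohort(patients, level)
}

#' Write a cohort to JSONL
#'
#' Inverse of [read_cohort()]: one patient per line, UTF-8, stable field order,
#' so identical cohorts produce byte-identical files.
#'
#' @param cohort A `csrec_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "csrec_cohort"))
  lines <- vapply(cohort$patients, function(p) {
    jsonlite::toJSON(list(
      subject_id = jsonlite::unbox(p$subject_id),
      visits = lapply(p$visits, function(v) list(
        hadm_id = jsonlite::unbox(v$hadm_id),
        diagnoses = as.list(v$diagnoses),
        procedures = as.list(v$procedures),
        medications = as.list(v$medications)))), auto_unbox = FALSE)
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Filter a cohort by medication frequency and visit count
#'
#' Two-stage filter, applied in a fixed, documented order: first, medications
#' occurring in fewer than `min_med_freq` visits across the whole cohort are
#' removed from every visit; second, patients with fewer than `min_visits`
#' visits are dropped. Counting medication frequency before dropping patients
#' makes the medication vocabulary independent of the visit-count cut.
#'
#' @param cohort A `csrec_cohort`.
#' @param min_visits Minimum visits per retained patient (>= 1).
#' @param min_med_freq Minimum number of visits a medication must appear in to
#'   be retained (0 disables the filter).
#' @return The filtered `csrec_cohort`. Errors if nothing survives.
#' @export
filter_cohort <- function(cohort, min_visits = 2L, min_med_freq = 0L) {
  stopifnot(inherits(cohort, "csrec_cohort"), min_visits >= 1L, min_med_freq >= 0L)
  patients <- cohort$patients
  if (min_med_freq > 0L) {
    counts <- table(unlist(lapply(patients, function(p)
      unlist(lapply(p$visits, function(v) unique(v$medications))))))
    keep_meds <- names(counts)[counts >= min_med_freq]
    patients <- lapply(patients, function(p) {
      p$visits <- lapply(p$visits, function(v) {
        v$medications <- v$medications[v$medications %in% keep_meds]
        v
      })
      p
    })
  }
  patients <- Filter(function(p) length(p$visits) >= min_visits, patients)
  if (length(patients) == 0L)
    stop("cohort empty after filtering (min_visits=", min_visits,
         ", min_med_freq=", min_med_freq, ")")
  structure(list(patients = patients, level = cohort$level),
            class = "csrec_cohort")
}

#' Build code vocabularies for a cohort
#'
#' Assigns a contiguous 1-based integer index to every distinct diagnosis,
#' procedure and medication code in the cohort, in sorted code order so the
#' mapping is deterministic.
#'
#' @param cohort A non-empty `csrec_cohort`.
#' @return A list of class `csrec_vocab` with elements `diag`, `proc`, `med`
#'   (character vectors; position = index) and `n_diag`, `n_proc`, `n_med`.
#' @export
build_vocabulary <- function(cohort) {
  stopifnot(inherits(cohort, "csrec_cohort"))
  if (length(cohort$patients) == 0L) stop("cohort is empty")
  pull <- function(field) sort(unique(unlist(lapply(cohort$patients, function(p)
    unlist(lapply(p$visits, `[[`, field))))))
  diag <- pull("diagnoses"); proc <- pull("procedures"); med <- pull("medications")
  if (length(proc) == 0L) warning("cohort has no procedure codes", call. = FALSE)
  if (length(med) == 0L) warning("cohort has no medication codes", call. = FALSE)
  structure(list(diag = diag, proc = proc, med = med,
                 n_diag = length(diag), n_proc = length(proc),
                 n_med = length(med)),
            class = "csrec_vocab")
}

#' Multi-hot encode one visit
#'
#' Maps a visit's three code sets onto binary vectors over the vocabulary:
#' `v_d[i] = 1` iff the diagnosis with index `i` is present, likewise `v_p`
#' and `v_m`. Popcounts equal the code-set cardinalities.
#'
#' @param visit A visit (list with `diagnoses`, `procedures`, `medications`).
#' @param vocab A `csrec_vocab` from [build_vocabulary()].
#' @return A list of class `csrec_multihot` with integer 0/1 vectors
#'   `v_d`, `v_p`, `v_m`.
#' @export
encode_visit <- function(visit, vocab) {
  stopifnot(inherits(vocab, "csrec_vocab"))
  one_hot <- function(codes, universe, what) {
    v <- integer(length(universe))
    if (length(codes)) {
      idx <- match(codes, universe)
      if (anyNA(idx))
        stop("unknown ", what, " code: ",
             paste(codes[is.na(idx)], collapse = ", "))
      v[idx] <- 1L
    }
    v
  }
  structure(list(v_d = one_hot(visit$diagnoses, vocab$diag, "diagnosis"),
                 v_p = one_hot(visit$procedures, vocab$proc, "procedure"),
                 v_m = one_hot(visit$medications, vocab$med, "medication")),
            class = "csrec_multihot")
}

#' Split a cohort into train/validation/test sets
#'
#' Patient-level split (all visits of a patient land in the same part) with
#' sizes proportional to `ratio`; the remainder after flooring the validation
#' and test shares is assigned to training. With 55 patients and the default
#' 23:16:16 ratio the parts have exactly 23, 16 and 16 patients. Deterministic
#' under a fixed seed; the global RNG state is left untouched.
#'
#' @param cohort A `csrec_cohort` with at least 3 patients.
#' @param ratio Positive integer triple `(train, val, test)`.
#' @param seed Integer seed for the permutation.
#' @return A list with `csrec_cohort` elements `train`, `val`, `test`.
#' @export
split_cohort <- function(cohort, ratio = c(23L, 16L, 16L), seed = 1L) {
  stopifnot(inherits(cohort, "csrec_cohort"), length(ratio) == 3L, all(ratio > 0))
  n <- length(cohort$patients)
  if (n < 3L) stop("need at least 3 patients to split")
  n_val <- floor(n * ratio[2] / sum(ratio))
  n_test <- floor(n * ratio[3] / sum(ratio))
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  part <- function(idx) structure(
    list(patients = cohort$patients[sort(idx)], level = cohort$level),
    class = "csrec_cohort")
  list(train = part(perm[seq_len(n_train)]),
       val = part(perm[n_train + seq_len(n_val)]),
       test = part(perm[n_train + n_val + seq_len(n_test)]))
}

#' Per-visit summary statistics of a cohort
#'
#' @param cohort A `csrec_cohort`.
#' @return A list with the patient/visit counts and the mean visits per
#'   patient and mean diagnoses/procedures/medications per visit.
#' @export
cohort_stats <- function(cohort) {
  stopifnot(inherits(cohort, "csrec_cohort"))
  nv <- vapply(cohort$patients, function(p) length(p$visits), 0L)
  per_visit <- function(field) unlist(lapply(cohort$patients, function(p)
    vapply(p$visits, function(v) length(v[[field]]), 0L)))
  list(n_patients = length(cohort$patients),
       n_visits = sum(nv),
       mean_visits = if (length(nv)) mean(nv) else NA_real_,
       mean_diag = if (sum(nv)) mean(per_visit("diagnoses")) else NA_real_,
       mean_proc = if (sum(nv)) mean(per_visit("procedures")) else NA_real_,
       mean_med = if (sum(nv)) mean(per_visit("medications")) else NA_real_)
}

#' @export
print.csrec_cohort <- function(x, ...) {
  s <- cohort_stats(x)
  cat(sprintf("EHR cohort (%s): %d patients, %d visits\n", x$level,
              s$n_patients, s$n_visits))
  if (s$n_patients > 0)
    cat(sprintf("  mean visits/patient %.3f; per visit: %.2f diagnoses, %.2f procedures, %.2f medications\n",
                s$mean_visits, s$mean_diag, s$mean_proc, s$mean_med))
  invisible(x)
}

#' @export
print.csrec_vocab <- function(x, ...) {
  cat(sprintf("vocabulary: |D|=%d diagnoses, |P|=%d procedures, |M|=%d medications\n",
              x$n_diag, x$n_proc, x$n_med))
  invisible(x)
}

## Evaluate `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
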