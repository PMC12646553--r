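## Evaluation metrics for multilabel medication recommendation. All four are
## computed per visit and macro-averaged over the visits pooled across the
## test patients. A "batch" is a list of visits, each a list with
##   truth:  integer set of prescribed medication indices (1-based),
##   pred:   integer set of recommended medication indices,
##   scores: numeric vector of per-medication scores (needed for PRAUC only).

check_batch <- function(batch) {
  if (length(batch) == 0L) stop("empty evaluation batch")
  invisible(batch)
}

#' Mean Jaccard similarity of recommended vs prescribed sets
#'
#' Per visit, `|intersect(truth, pred)| / |union(truth, pred)|`, averaged over
#' visits.
#' A visit where both sets are empty scores 1 (the recommendation is exactly
#' right); this boundary case is undefined in the ratio itself and is fixed by
#' convention.
#'
#' @param batch List of visits; see Details in [evaluate_batch()].
#' @return Mean Jaccard in `[0, 1]`.
#' @export
jaccard <- function(batch) {
  check_batch(batch)
  mean(vapply(batch, function(v) {
    u <- length(union(v$truth, v$pred))
    if (u == 0L) 1 else length(intersect(v$truth, v$pred)) / u
  }, 0))
}

#' Mean per-visit F1 of recommended vs prescribed sets
#'
#' Per visit, precision `|intersect|/|pred|` and recall `|intersect|/|truth|`
#' combine into `2PR/(P+R)`; any 0/0 is taken as 0.
#'
#' @inheritParams jaccard
#' @return Mean F1 in `[0, 1]`.
#' @export
f1 <- function(batch) {
  check_batch(batch)
  mean(vapply(batch, function(v) {
    tp <- length(intersect(v$truth, v$pred))
    p <- if (length(v$pred)) tp / length(v$pred) else 0
    r <- if (length(v$truth)) tp / length(v$truth) else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, 0))
}

#' Mean per-visit area under the precision-recall curve
#'
#' Per visit, medications are ranked by descending score (ties broken by
#' ascending index for determinism) and the step-integrated area
#' `sum_i Precision(i) * DeltaRecall(i)` is accumulated over the full ranking
#' — the average-precision form, where `DeltaRecall` telescopes so only ranks
#' holding a true medication contribute. Visits with an empty truth set have
#' an undefined recall and are excluded with a warning.
#'
#' @inheritParams jaccard
#' @return Mean PRAUC in `[0, 1]`.
#' @export
prauc <- function(batch) {
  check_batch(batch)
  vals <- vapply(batch, function(v) {
    if (length(v$truth) == 0L) return(NA_real_)
    ord <- order(-v$scores, seq_along(v$scores))
    hit <- ord %in% v$truth
    prec <- cumsum(hit) / seq_along(ord)
    sum(prec[hit]) / length(v$truth)
  }, 0)
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " visit(s) with empty truth excluded from PRAUC",
            call. = FALSE)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) stop("no visit with a non-empty truth set")
  }
  mean(vals)
}

#' Mean drug-drug interaction rate of recommended sets
#'
#' Per visit, the fraction of unordered pairs of recommended medications that
#' are flagged in the interaction matrix. Visits recommending fewer than two
#' medications have no pairs and contribute 0 by convention.
#'
#' @inheritParams jaccard
#' @param ddi Symmetric 0/1 interaction matrix over the medication vocabulary.
#' @return Mean DDI rate in `[0, 1]`.
#' @export
ddi_rate <- function(batch, ddi) {
  check_batch(batch)
  stopifnot(is.matrix(ddi), nrow(ddi) == ncol(ddi))
  mean(vapply(batch, function(v) {
    r <- v$pred
    if (length(r) < 2L) return(0)
    sub <- ddi[r, r, drop = FALSE]
    sum(sub[upper.tri(sub)] != 0) / (length(r) * (length(r) - 1) / 2)
  }, 0))
}

#' Score a batch on all four metrics
#'
#' @inheritParams ddi_rate
#' @return Named numeric vector `jaccard`, `prauc`, `f1`, `ddi`.
#' @export
evaluate_batch <- function(batch, ddi) {
  c(jaccard = jaccard(batch), prauc = prauc(batch), f1 = f1(batch),
    ddi = ddi_rate(batch, ddi))
}
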