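## Experiment orchestration at desk scale: ablation grids, head-count and
## medication-frequency-threshold sweeps, with a frequency baseline as the
## sanity floor. Every cell is fully seeded: simulate -> filter -> split ->
## train -> evaluate on the test split.

#' k-most-frequent medication baseline
#'
#' Recommends the same set — the `k` medications occurring in the most
#' training visits — for every visit, with scores proportional to training
#' frequency. The floor any learned model must beat.
#'
#' @param train_cohort Training `csrec_cohort`.
#' @param k Number of medications to recommend (>= 1).
#' @param vocab Optional `csrec_vocab` (defaults to the training cohort's).
#' @return Object of class `csrec_freq_baseline` with a [predict()] method
#'   returning an evaluation batch.
#' @export
frequency_baseline <- function(train_cohort, k, vocab = NULL) {
  stopifnot(k >= 1L)
  if (is.null(vocab)) vocab <- build_vocabulary(train_cohort)
  counts <- numeric(vocab$n_med)
  for (p in train_cohort$patients)
    for (v in p$visits) {
      idx <- match(unique(v$medications), vocab$med)
      idx <- idx[!is.na(idx)]
      counts[idx] <- counts[idx] + 1
    }
  ord <- order(-counts, seq_along(counts))
  top <- sort(ord[seq_len(min(k, vocab$n_med))])
  scores <- if (max(counts) > 0) counts / max(counts) else counts
  structure(list(top = top, scores = scores, k = k, vocab = vocab),
            class = "csrec_freq_baseline")
}

#' @export
predict.csrec_freq_baseline <- function(object, cohort, ...) {
  cohort <- restrict_to_vocab(cohort, object$vocab)
  out <- list()
  for (p in cohort$patients)
    for (v in p$visits) {
      truth <- match(v$medications, object$vocab$med)
      out[[length(out) + 1L]] <- list(truth = sort(truth[!is.na(truth)]),
                                      pred = object$top,
                                      scores = object$scores)
    }
  out
}

#' @export
print.csrec_freq_baseline <- function(x, ...) {
  cat("frequency baseline: recommends",
      paste(x$vocab$med[x$top], collapse = ", "), "\n")
  invisible(x)
}

## One experiment cell: simulate (or reuse) a cohort, filter, split, train,
## evaluate on the test split. Returns the four metrics.
run_cell <- function(synth, model_cfg, seed, min_visits = 2L,
                     min_med_freq = 0L, cohort_cache = NULL) {
  sim <- if (is.null(cohort_cache)) {
    synth$seed <- seed
    generate_cohort(synth)
  } else cohort_cache
  cohort <- filter_cohort(sim$cohort, min_visits = min_visits,
                          min_med_freq = min_med_freq)
  vocab <- build_vocabulary(cohort)
  parts <- split_cohort(cohort, seed = seed)
  model_cfg$seed <- seed
  fit <- csrec(parts$train, sim$ddi_pairs, model_cfg, val = parts$val,
               vocab = vocab)
  ev <- evaluate_model(fit, parts$test)
  list(metrics = ev$metrics, fit = fit, parts = parts, sim = sim,
       vocab = vocab)
}

#' Run an experiment grid
#'
#' Evaluates the cross product of variants, head counts, medication-frequency
#' thresholds, DDI penalties and seeds on seeded synthetic cohorts. For every
#' cell: simulate, filter, split (23:16:16 by patient), train with early
#' stopping, and score the test split on the four metrics. A failing cell is
#' recorded with `NA` metrics and the grid continues. If `out_dir` is given,
#' per-cell CSV rows are written as they complete and existing rows are
#' reused on re-run (resumability).
#'
#' @param synth A `csrec_synth_config` (its seed is overridden per cell).
#' @param model A `csrec_config` used as the base configuration.
#' @param variants Character vector of model variants.
#' @param heads Integer vector of head counts.
#' @param med_freq_thresholds Integer vector of minimum medication
#'   frequencies (applied via [filter_cohort()]).
#' @param lambdas Numeric vector of DDI penalties.
#' @param seeds Integer vector of seeds.
#' @param out_dir Optional directory for resumable per-cell results.
#' @return A data frame of class `csrec_results`: one row per cell with the
#'   setting, seed and metrics.
#' @export
run_grid <- function(synth, model, variants = model$variant,
                     heads = model$heads, med_freq_thresholds = 0L,
                     lambdas = model$lambda, seeds = 1L, out_dir = NULL) {
  stopifnot(length(variants) > 0, length(heads) > 0, length(seeds) > 0)
  bad <- setdiff(variants, c("full", "WO_S", "WO_C", "GAT_GCN", "WO_DM",
                             "WO_PM", "WO_DP", "WO_MM"))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  grid <- expand.grid(variant = variants, heads = heads,
                      med_freq = med_freq_thresholds, lambda = lambdas,
                      seed = seeds, stringsAsFactors = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    tag <- sprintf("%s_h%d_f%d_l%g_s%d", cell$variant, cell$heads,
                   cell$med_freq, cell$lambda, cell$seed)
    cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
    if (!is.null(cache) && file.exists(cache))
      return(utils::read.csv(cache))
    cfg <- model
    cfg$variant <- cell$variant
    cfg$heads <- as.integer(cell$heads)
    cfg$d_head <- max(1L, as.integer(round(cfg$embed_dim / cfg$heads)))
    cfg$width <- as.integer(cfg$heads * cfg$d_head)
    cfg$lambda <- cell$lambda
    m <- tryCatch(
      run_cell(synth, cfg, cell$seed, min_med_freq = cell$med_freq)$metrics,
      error = function(e) {
        warning("cell ", tag, " failed: ", conditionMessage(e), call. = FALSE)
        c(jaccard = NA_real_, prauc = NA_real_, f1 = NA_real_, ddi = NA_real_)
      })
    row <- data.frame(variant = cell$variant, heads = cell$heads,
                      med_freq = cell$med_freq, lambda = cell$lambda,
                      seed = cell$seed, jaccard = m[["jaccard"]],
                      prauc = m[["prauc"]], f1 = m[["f1"]], ddi = m[["ddi"]])
    if (!is.null(cache)) utils::write.csv(row, cache, row.names = FALSE)
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("csrec_results", "data.frame")
  out
}

#' Aggregate grid results over seeds
#'
#' @param results A `csrec_results` data frame from [run_grid()].
#' @return Data frame with mean and standard deviation of each metric per
#'   setting.
#' @export
aggregate_results <- function(results) {
  key <- interaction(results$variant, results$heads, results$med_freq,
                     results$lambda, drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    data.frame(variant = g$variant[1L], heads = g$heads[1L],
               med_freq = g$med_freq[1L], lambda = g$lambda[1L],
               n_seeds = nrow(g),
               jaccard_mean = mean(g$jaccard), jaccard_sd = stats::sd(g$jaccard),
               prauc_mean = mean(g$prauc), prauc_sd = stats::sd(g$prauc),
               f1_mean = mean(g$f1), f1_sd = stats::sd(g$f1),
               ddi_mean = mean(g$ddi), ddi_sd = stats::sd(g$ddi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
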