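## Seeded synthetic longitudinal EHR cohorts. The generator emulates the
## marginal shape of ICU hypertension cohorts (visits per patient, code-set
## sizes per visit) and plants recoverable structure: diagnosis->medication
## prescription rules, medication co-prescription clusters, and contraindicated
## (DDI) pairs. Codes are synthetic strings ("D001", "P001", "M001").

#' Synthetic cohort configuration
#'
#' Visit counts are drawn as `1 + X` with `X ~ Poisson(mu)` conditioned on
#' `X >= 1` (every patient has at least two visits); `mu` is calibrated so the
#' realized mean matches `mean_visits`. Diagnosis-set sizes use the same
#' zero-truncated calibration against `mean_diag`; procedure counts are plain
#' Poisson. Diagnosis and procedure codes are drawn without replacement from a
#' Zipf-like popularity distribution (`weight ~ rank^-skew`), so low-rank codes
#' are common — in particular the rule-bearing diagnoses. A diagnosis carries
#' over to the next visit with probability `persistence` (chronic-condition
#' carryover). Medications are the union of rule-fired medications, cluster
#' co-prescriptions and Bernoulli noise; their per-visit mean is therefore
#' emergent, not a direct dial.
#'
#' @param n_patients Number of patients.
#' @param n_diag,n_proc,n_med Vocabulary sizes.
#' @param mean_visits Target mean visits per patient (>= 2).
#' @param mean_diag Target mean diagnoses per visit (>= 1).
#' @param mean_proc Target mean procedures per visit.
#' @param rules Data frame with columns `diag`, `med` (1-based indices) and
#'   `prob`: when the diagnosis is present, the medication is prescribed with
#'   probability `prob`.
#' @param copair_clusters List of integer vectors of medication indices; each
#'   visit, a cluster fires with probability `cluster_rate` and all its
#'   members are co-prescribed.
#' @param cluster_rate Per-visit firing probability of each cluster.
#' @param ddi_pairs Two-column integer matrix of contraindicated medication
#'   index pairs (exported alongside the cohort).
#' @param noise_rate Per-medication Bernoulli noise probability.
#' @param persistence Probability that a diagnosis recurs at the next visit.
#' @param skew Zipf exponent of the code popularity distribution.
#' @param seed Integer seed; the same seed yields a byte-identical cohort.
#' @return A list of class `csrec_synth_config`.
#' @seealso [synth_profile()], [generate_cohort()]
#' @export
synth_config <- function(n_patients,
                         n_diag = 200L, n_proc = 100L, n_med = 18L,
                         mean_visits = 2.8169, mean_diag = 9.3666,
                         mean_proc = 2.5492,
                         rules = default_rules(),
                         copair_clusters = list(c(13L, 14L), c(15L, 16L)),
                         cluster_rate = 0.06,
                         ddi_pairs = rbind(c(5L, 6L), c(13L, 14L)),
                         noise_rate = 0.005,
                         persistence = 0.6,
                         skew = 0.8,
                         seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_diag = as.integer(n_diag),
              n_proc = as.integer(n_proc), n_med = as.integer(n_med),
              mean_visits = mean_visits, mean_diag = mean_diag,
              mean_proc = mean_proc, rules = rules,
              copair_clusters = copair_clusters, cluster_rate = cluster_rate,
              ddi_pairs = ddi_pairs, noise_rate = noise_rate,
              persistence = persistence, skew = skew, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "csrec_synth_config")
}

default_rules <- function() {
  data.frame(diag = 4:7, med = 4:7, prob = 0.9)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0L, cfg$n_diag >= 1L, cfg$n_med >= 1L,
            cfg$mean_visits > 2, cfg$mean_diag > 1, cfg$mean_proc >= 0)
  probs <- c(cfg$cluster_rate, cfg$noise_rate, cfg$persistence, cfg$rules$prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (nrow(cfg$rules) &&
      (any(cfg$rules$diag < 1L | cfg$rules$diag > cfg$n_diag) ||
       any(cfg$rules$med < 1L | cfg$rules$med > cfg$n_med)))
    stop("rule indices out of vocabulary range")
  idx <- unlist(cfg$copair_clusters)
  if (length(idx) && any(idx < 1L | idx > cfg$n_med))
    stop("cluster medication indices out of range")
  if (length(cfg$ddi_pairs) && any(cfg$ddi_pairs < 1L | cfg$ddi_pairs > cfg$n_med))
    stop("DDI pair indices out of range")
  invisible(cfg)
}

#' Shipped cohort profiles
#'
#' Desk-scale configurations whose visit/diagnosis/procedure means match the
#' published ICU hypertension cohort summaries this package targets:
#' `mimic3_like` (mean visits 2.3361, diagnoses 10.9262, procedures 4.0609)
#' and `mimic4_like` (2.8169, 9.3666, 2.5492), both with small vocabularies
#' (|D| = 200, |P| = 100, |M| = 18) suitable for laptop runs.
#'
#' @param name `"mimic4_like"` or `"mimic3_like"`.
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `csrec_synth_config`.
#' @export
synth_profile <- function(name = c("mimic4_like", "mimic3_like"),
                          n_patients = 2000L, seed = 1L, ...) {
  name <- match.arg(name)
  means <- switch(name,
                  mimic4_like = c(visits = 2.8169, diag = 9.3666, proc = 2.5492),
                  mimic3_like = c(visits = 2.3361, diag = 10.9262, proc = 4.0609))
  cfg <- synth_config(n_patients = n_patients, mean_visits = means[["visits"]],
                      mean_diag = means[["diag"]], mean_proc = means[["proc"]],
                      seed = seed, ...)
  attr(cfg, "profile") <- name
  cfg
}

## Calibrate the Poisson rate of a zero-truncated Poisson so that
## E[X | X >= 1] = target (target > 1).
calibrate_ztpois <- function(target) {
  if (target <= 1) stop("zero-truncated Poisson mean must exceed 1")
  uniroot(function(mu) mu / (1 - exp(-mu)) - target,
          lower = 1e-8, upper = max(target * 2, 10), tol = 1e-10)$root
}

rztpois <- function(n, mu) {
  x <- rpois(n, mu)
  while (any(x == 0L)) x[x == 0L] <- rpois(sum(x == 0L), mu)
  x
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configured distributions and returns it together
#' with a report of the realized statistics (means, per-rule conditional
#' prescription frequencies, DDI co-prescription rate) computed exactly from
#' the emitted cohort. Fully deterministic under `config$seed`; the caller's
#' RNG state is untouched.
#'
#' @param config A `csrec_synth_config`.
#' @return A list with `cohort` (a `csrec_cohort`), `ddi_pairs` (two-column
#'   character matrix of contraindicated codes) and `report` (class
#'   `csrec_generator_report`).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  cfg <- config
  d_codes <- sprintf("D%03d", seq_len(cfg$n_diag))
  p_codes <- sprintf("P%03d", seq_len(cfg$n_proc))
  m_codes <- sprintf("M%03d", seq_len(cfg$n_med))
  w_d <- seq_len(cfg$n_diag)^(-cfg$skew)
  w_p <- seq_len(cfg$n_proc)^(-cfg$skew)

  patients <- with_seed(cfg$seed, {
    if (cfg$n_patients == 0L) list() else {
      mu_v <- calibrate_ztpois(cfg$mean_visits - 1)
      mu_d <- calibrate_ztpois(max(cfg$mean_diag, 1 + 1e-6))
      lapply(seq_len(cfg$n_patients), function(pid) {
        n_visits <- 1L + rztpois(1L, mu_v)
        prev_diag <- integer()
        visits <- vector("list", n_visits)
        for (t in seq_len(n_visits)) {
          size_d <- rztpois(1L, mu_d)
          kept <- prev_diag[runif(length(prev_diag)) < cfg$persistence]
          if (length(kept) > size_d)      # keep set sizes on calibration
            kept <- sort(sample(kept, size_d))
          need <- size_d - length(kept)
          if (need > 0L) {
            pool <- setdiff(seq_len(cfg$n_diag), kept)
            fresh <- pool[sample.int(length(pool), min(need, length(pool)),
                                     prob = w_d[pool])]
            diag_idx <- c(kept, fresh)
          } else diag_idx <- kept
          diag_idx <- sort(diag_idx)
          prev_diag <- diag_idx

          n_p <- rpois(1L, cfg$mean_proc)
          proc_idx <- if (n_p > 0L)
            sort(sample.int(cfg$n_proc, min(n_p, cfg$n_proc), prob = w_p))
          else integer()

          meds <- integer()
          if (nrow(cfg$rules)) for (r in seq_len(nrow(cfg$rules)))
            if (cfg$rules$diag[r] %in% diag_idx &&
                runif(1L) < cfg$rules$prob[r])
              meds <- c(meds, cfg$rules$med[r])
          for (cl in cfg$copair_clusters)
            if (runif(1L) < cfg$cluster_rate) meds <- c(meds, cl)
          noise <- which(runif(cfg$n_med) < cfg$noise_rate)
          meds <- sort(unique(c(meds, noise)))

          visits[[t]] <- list(hadm_id = sprintf("H%06d-%d", pid, t),
                              diagnoses = d_codes[diag_idx],
                              procedures = p_codes[proc_idx],
                              medications = m_codes[meds])
        }
        list(subject_id = sprintf("S%05d", pid), visits = visits)
      })
    }
  })
  cohort <- structure(list(patients = patients, level = "ATC05"),
                      class = "csrec_cohort")
  ddi_pairs <- if (length(cfg$ddi_pairs))
    cbind(m_codes[cfg$ddi_pairs[, 1L]], m_codes[cfg$ddi_pairs[, 2L]])
  else matrix(character(), 0L, 2L)
  report <- generator_report(cohort, cfg, d_codes, m_codes)
  list(cohort = cohort, ddi_pairs = ddi_pairs, report = report)
}

generator_report <- function(cohort, cfg, d_codes, m_codes) {
  s <- cohort_stats(cohort)
  all_visits <- unlist(lapply(cohort$patients, `[[`, "visits"),
                       recursive = FALSE)
  rule_freq <- if (nrow(cfg$rules) && length(all_visits)) {
    vapply(seq_len(nrow(cfg$rules)), function(r) {
      d <- d_codes[cfg$rules$diag[r]]; m <- m_codes[cfg$rules$med[r]]
      has_d <- vapply(all_visits, function(v) d %in% v$diagnoses, NA)
      if (!any(has_d)) return(NA_real_)
      mean(vapply(all_visits[has_d], function(v) m %in% v$medications, NA))
    }, 0)
  } else numeric()
  ddi_coprescribed <- if (length(cfg$ddi_pairs) && length(all_visits)) {
    mean(vapply(all_visits, function(v) {
      any(apply(cfg$ddi_pairs, 1L, function(pr)
        all(m_codes[pr] %in% v$medications)))
    }, NA))
  } else 0
  structure(list(n_patients = s$n_patients, n_visits = s$n_visits,
                 mean_visits = s$mean_visits, mean_diag = s$mean_diag,
                 mean_proc = s$mean_proc, mean_med = s$mean_med,
                 rule_conditional_freq = rule_freq,
                 ddi_coprescription_rate = ddi_coprescribed),
            class = "csrec_generator_report")
}

#' @export
print.csrec_generator_report <- function(x, ...) {
  cat(sprintf("generator report: %d patients, %d visits\n", x$n_patients, x$n_visits))
  cat(sprintf("  realized means: visits %.4f, diagnoses %.4f, procedures %.4f, medications %.4f\n",
              x$mean_visits, x$mean_diag, x$mean_proc, x$mean_med))
  if (length(x$rule_conditional_freq))
    cat("  rule P(med | diag):", paste(sprintf("%.3f", x$rule_conditional_freq),
                                       collapse = " "), "\n")
  cat(sprintf("  DDI co-prescription rate: %.4f\n", x$ddi_coprescription_rate))
  invisible(x)
}

#' Check a generator report against a target profile
#'
#' Compares the realized mean visits/diagnoses/procedures against the profile
#' targets at an absolute tolerance; returns a pass flag plus per-statistic
#' diagnostics naming any statistic out of band.
#'
#' @param report A `csrec_generator_report`.
#' @param profile Named numeric vector with elements `mean_visits`,
#'   `mean_diag`, `mean_proc` (targets), or a `csrec_synth_config`.
#' @param tol Absolute tolerance.
#' @return List with `pass` (logical) and `diagnostics` (data frame of
#'   statistic, target, realized, ok).
#' @export
validate_against_profile <- function(report, profile, tol = 0.15) {
  if (inherits(profile, "csrec_synth_config"))
    profile <- c(mean_visits = profile$mean_visits,
                 mean_diag = profile$mean_diag,
                 mean_proc = profile$mean_proc)
  stats <- intersect(names(profile), c("mean_visits", "mean_diag", "mean_proc"))
  if (length(stats) == 0L) stop("profile names no known statistic")
  realized <- unlist(report[stats])
  ok <- abs(realized - profile[stats]) <= tol
  list(pass = all(ok),
       diagnostics = data.frame(statistic = stats,
                                target = as.numeric(profile[stats]),
                                realized = as.numeric(realized),
                                ok = as.logical(ok)))
}
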