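# Shared fixture builders. Everything is generated in code; nothing binary.

# An ICU-style two-visit patient (10 diagnoses / 3 procedures at the first
# visit, overlapping medication sets) used across the cohort tests.
sample_patient_jsonl <- function() {
  paste0('{"subject_id":"10001217","visits":[',
         '{"hadm_id":"24597018",',
         '"diagnoses":["3240","3484","3485","5180","340","04109","3051","4019","V168","V161"],',
         '"procedures":["139","331","3897"],',
         '"medications":["HydrALAzine","LeVETiracetam","Vancomycin","Bisacodyl","Meropenem"]},',
         '{"hadm_id":"27703517",',
         '"diagnoses":["3240","3485","340","04102","04184","4019","3051"],',
         '"procedures":["139"],',
         '"medications":["HydrALAzine","Vancomycin","Meropenem","Bisacodyl","Lidocaine"]}]}')
}

write_sample_cohort <- function(path = tempfile(fileext = ".jsonl")) {
  writeLines(sample_patient_jsonl(), path)
  path
}

# small random cohort as plain lists
random_cohort <- function(n_patients, n_diag = 12, n_proc = 6, n_med = 8,
                          max_visits = 4) {
  pats <- lapply(seq_len(n_patients), function(i) {
    nv <- sample.int(max_visits, 1)
    list(subject_id = sprintf("p%03d", i),
         visits = lapply(seq_len(nv), function(t) list(
           diagnoses = sprintf("d%02d", sample.int(n_diag, sample.int(4, 1))),
           procedures = sprintf("q%02d", sample.int(n_proc,
                                                    sample.int(3, 1) - 1)),
           medications = sprintf("m%02d", sample.int(n_med,
                                                     sample.int(4, 1) - 1)))))
  })
  as_cohort(pats)
}

# random evaluation batch over n_med medications
random_batch <- function(n_visits, n_med, empty_truth_ok = FALSE) {
  lapply(seq_len(n_visits), function(i) {
    lo <- if (empty_truth_ok) 0L else 1L
    truth <- sort(sample.int(n_med, sample(lo:min(4L, n_med), 1)))
    pred <- sort(sample.int(n_med, sample(0:min(4L, n_med), 1)))
    list(truth = truth, pred = pred, scores = runif(n_med))
  })
}

random_ddi <- function(n_med, n_pairs = 3) {
  A <- matrix(0, n_med, n_med)
  for (k in seq_len(n_pairs)) {
    ij <- sample.int(n_med, 2)
    A[ij[1], ij[2]] <- 1; A[ij[2], ij[1]] <- 1
  }
  A
}

# single attention head with random parameters
random_head <- function(d_in, d_head) {
  list(linear_map = matrix(rnorm(d_in * d_head), d_in, d_head),
       attn_vector = rnorm(2 * d_head), negative_slope = 0.2)
}

# random GRU parameter set of width r
random_gru <- function(r, scale = 0.4) {
  m <- function() matrix(rnorm(r * r, sd = scale), r, r)
  list(Wz = m(), Uz = m(), bz = matrix(rnorm(r, sd = scale), 1),
       Wr = m(), Ur = m(), br = matrix(rnorm(r, sd = scale), 1),
       Wh = m(), Uh = m(), bh = matrix(rnorm(r, sd = scale), 1))
}

# tiny deterministic generator config for fast model tests
tiny_sim <- function(n_patients, seed = 1) {
  generate_cohort(synth_profile("mimic4_like", n_patients = n_patients,
                                seed = seed))
}

# quick model config for tests (defaults overridable)
tiny_config <- function(...) {
  args <- utils::modifyList(list(embed_dim = 8, heads = 2, max_epochs = 2,
                                 patience = 5, seed = 1), list(...))
  do.call(csrec_config, args)
}

# gradients via the R tape (reference engine), as a flat named list
tape_gradients <- function(params, enc, config, a_ddi) {
  tp <- csrec:::tape_new()
  leaves <- csrec:::make_leaves(tp, params)
  root <- csrec:::tp_patient_loss(tp, leaves, enc, params, config, a_ddi)
  g <- csrec:::tp_backward(tp, root)
  list(loss = csrec:::tp_val(tp, root)[1],
       grads = lapply(stats::setNames(nm = names(params)), function(nm) {
         gg <- g[[as.character(leaves[[nm]])]]
         if (is.null(gg)) params[[nm]] * 0 else gg
       }))
}

cpp_gradients <- function(params, enc, config, a_ddi) {
  s <- csrec:::enc_index_sets(enc)
  out <- csrec:::cpp_patient_loss_grad(params, s$D, s$P, s$M, ncol(a_ddi),
                                       unclass(config), a_ddi, NULL, TRUE)
  list(loss = out$loss, grads = out$grads)
}
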