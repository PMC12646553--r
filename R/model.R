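## The full recommender: embeddings -> graph collaboration -> bidirectional
## temporal selection -> multilabel prediction head. The numeric forward pass
## (used for prediction and as a cross-check) and the tape forward pass (used
## for training gradients) share the same structure; a test pins them equal.

#' Model configuration
#'
#' @param embed_dim Requested embedding dimension `d`. The effective internal
#'   width is `heads * round(d / heads)` so that per-head slices tile exactly;
#'   with the defaults (d = 64, 3 heads) the width is 63.
#' @param heads Number of attention heads H (>= 1); 3 by default.
#' @param lambda Non-negative DDI penalty when combining the medication
#'   co-occurrence graph with the interaction graph.
#' @param threshold Recommendation threshold on predicted probabilities,
#'   strictly in (0, 1); medications with probability strictly above it are
#'   recommended.
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param max_epochs,patience Training length and early-stopping patience (in
#'   epochs without validation improvement).
#' @param seed Integer seed controlling initialisation and data order.
#' @param variant Model variant: `"full"` or one of the ablations `"WO_S"`
#'   (no temporal selection; last visit only), `"WO_C"` (no graph
#'   collaboration; raw pooled embeddings), `"GAT_GCN"` (graph convolution
#'   instead of attention), `"WO_DM"`, `"WO_PM"`, `"WO_DP"`, `"WO_MM"`
#'   (drop the corresponding graph).
#' @param pooling Visit pooling, `"mean"` (default) or `"sum"`.
#' @param activation Aggregation activation, `"elu"` (default) or `"tanh"`.
#' @param tanhshrink_on Use tanhshrink for the backward coefficients (TRUE,
#'   default) or plain tanh.
#' @param negative_slope LeakyReLU slope in the attention logits.
#' @param self_loops Include each node in its own neighbourhood (standard-GAT
#'   behaviour; default FALSE, the neighbour-focused modification).
#' @param use_edge_weight_prior Multiply attention exponentials by the
#'   combined graph's edge weights (default FALSE: attention is computed from
#'   node features only).
#' @param cooccur_scope Build the medication co-occurrence graph from the
#'   patient's own history (`"patient"`, default) or globally from the
#'   training cohort (`"cohort"`).
#' @param loss_reduction `"sum"` (default) or `"mean"` over visit/medication
#'   terms.
#' @param grad_clip Global gradient-norm clip (Inf disables).
#' @param target_train_jaccard Optional early-exit target on training-set
#'   Jaccard, checked every `eval_every` epochs (used for capacity checks).
#' @param eval_every Epoch interval for the optional training-set metric.
#' @return A list of class `csrec_config`.
#' @export
csrec_config <- function(embed_dim = 64L, heads = 3L, lambda = 1,
                         threshold = 0.5, learning_rate = 1e-3,
                         weight_decay = 1e-5, max_epochs = 100L,
                         patience = 10L, seed = 1L,
                         variant = c("full", "WO_S", "WO_C", "GAT_GCN",
                                     "WO_DM", "WO_PM", "WO_DP", "WO_MM"),
                         pooling = "mean", activation = "elu",
                         tanhshrink_on = TRUE, negative_slope = 0.2,
                         self_loops = FALSE, use_edge_weight_prior = FALSE,
                         cooccur_scope = c("patient", "cohort"),
                         loss_reduction = c("sum", "mean"),
                         grad_clip = 5, target_train_jaccard = NULL,
                         eval_every = 5L) {
  variant <- match.arg(variant)
  cooccur_scope <- match.arg(cooccur_scope)
  loss_reduction <- match.arg(loss_reduction)
  stopifnot(heads >= 1L, threshold > 0, threshold < 1, patience >= 1L,
            lambda >= 0, max_epochs >= 1L, learning_rate > 0)
  d_head <- max(1L, as.integer(round(embed_dim / heads)))
  structure(list(embed_dim = as.integer(embed_dim), heads = as.integer(heads),
                 d_head = d_head, width = as.integer(heads * d_head),
                 lambda = lambda, threshold = threshold,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 variant = variant, pooling = pooling, activation = activation,
                 tanhshrink_on = tanhshrink_on,
                 negative_slope = negative_slope, self_loops = self_loops,
                 use_edge_weight_prior = use_edge_weight_prior,
                 cooccur_scope = cooccur_scope,
                 loss_reduction = loss_reduction, grad_clip = grad_clip,
                 target_train_jaccard = target_train_jaccard,
                 eval_every = as.integer(eval_every)),
            class = "csrec_config")
}

xavier <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

## Flat named list of parameter matrices (biases are 1 x k rows).
init_params <- function(vocab, config) {
  r <- config$width; dh <- config$d_head; H <- config$heads
  nm <- vocab$n_med
  with_seed(config$seed, {
    p <- list(E_d = xavier(max(vocab$n_diag, 1L), r),
              E_p = xavier(max(vocab$n_proc, 1L), r),
              E_m = xavier(max(nm, 1L), r))
    for (stage in c("m", "dp", "md", "mp")) {
      for (h in seq_len(H)) {
        p[[paste0("gat_", stage, "_W", h)]] <- xavier(r, dh)
        p[[paste0("gat_", stage, "_a", h)]] <- xavier(1L, 2L * dh)
      }
      p[[paste0("gcn_", stage)]] <- xavier(r, r)
    }
    for (ent in c("d", "p", "m")) {
      for (dir in c("f", "b")) {
        for (g in c("Wz", "Ur", "Wr", "Uz", "Wh", "Uh"))
          p[[paste0("gru_", dir, "_", ent, "_", g)]] <- xavier(r, r)
        for (g in c("bz", "br", "bh"))
          p[[paste0("gru_", dir, "_", ent, "_", g)]] <- matrix(0, 1L, r)
      }
      p[[paste0("W_alpha_", ent)]] <- xavier(r, r)
      p[[paste0("b_alpha_", ent)]] <- matrix(0, 1L, r)
      p[[paste0("W_beta_", ent)]] <- xavier(r, r)
      ## tanhshrink(x) = x - tanh(x) is ~cubically flat at the origin; a unit
      ## bias starts the backward gate in its responsive range instead of the
      ## dead zone (see the methods vignette, "Numerical choices")
      p[[paste0("b_beta_", ent)]] <- matrix(1, 1L, r)
    }
    p$W_out <- xavier(3L * r, nm)
    p$b_out <- matrix(0, 1L, nm)
    p
  })
}

gat_group <- function(params, stage, H) {
  list(W = lapply(seq_len(H), function(h) params[[paste0("gat_", stage, "_W", h)]]),
       a = lapply(seq_len(H), function(h)
         as.numeric(params[[paste0("gat_", stage, "_a", h)]])))
}

gru_group <- function(params, dir, ent) {
  g <- function(nm) params[[paste0("gru_", dir, "_", ent, "_", nm)]]
  list(Wz = g("Wz"), Uz = g("Uz"), bz = g("bz"),
       Wr = g("Wr"), Ur = g("Ur"), br = g("br"),
       Wh = g("Wh"), Uh = g("Uh"), bh = g("bh"))
}

## Grouped view used by build_patient_rep().
grouped_params <- function(params) {
  out <- list()
  for (ent in c("d", "p", "m")) {
    out[[paste0("gru_f_", ent)]] <- gru_group(params, "f", ent)
    out[[paste0("gru_b_", ent)]] <- gru_group(params, "b", ent)
    for (nm in c("W_alpha_", "b_alpha_", "W_beta_", "b_beta_"))
      out[[paste0(nm, ent)]] <- params[[paste0(nm, ent)]]
  }
  out
}

active_idx <- function(v) which(v != 0L)

bipartite_adj <- function(n_left, n_right) {
  n <- n_left + n_right
  A <- matrix(0, n, n)
  if (n_left > 0L && n_right > 0L) {
    A[seq_len(n_left), n_left + seq_len(n_right)] <- 1
    A[n_left + seq_len(n_right), seq_len(n_left)] <- 1
  }
  A
}

## Per-patient medication co-occurrence counts restricted to `idx`
## (the union of history medications), from index sets `med_sets`.
cooccur_counts <- function(med_sets, idx) {
  k <- length(idx)
  A <- matrix(0, k, k)
  for (ms in med_sets) {
    pos <- match(ms, idx)
    pos <- pos[!is.na(pos)]
    if (length(pos) >= 2L)
      A[pos, pos] <- A[pos, pos] + 1
  }
  diag(A) <- 0
  A
}

## ---- numeric forward -----------------------------------------------------

#' Entity-level node representations via staged graph propagation
#'
#' Runs the ordered three-stage collaborative update for one prediction step:
#' (1) medication nodes over the lambda-combined co-occurrence/DDI graph
#' built from visits `1..t-1`; (2) diagnosis and procedure nodes over each
#' visit's diagnosis-procedure graph; (3) cross-updates over the
#' medication-diagnosis and medication-procedure graphs using the stage-1/2
#' outputs. Variant flags reroute or skip stages (see [csrec_config()]).
#'
#' @param enc List of encoded visits (`csrec_multihot`) for one patient.
#' @param t Prediction step (1-based visit index).
#' @param params Flat model parameter list (as stored in a fitted `csrec`
#'   object's `$params`).
#' @param config A `csrec_config`.
#' @param a_ddi Binary interaction matrix over the medication vocabulary.
#' @param a_mm_global Optional cohort-global co-occurrence matrix (used when
#'   `config$cooccur_scope == "cohort"`).
#' @return List with `V_D`, `V_P` (per-visit node matrices, length `t`) and
#'   `V_M` (length `t-1`; empty when there is no medication history).
#' @export
entity_level_sets <- function(enc, t, params, config, a_ddi,
                              a_mm_global = NULL) {
  r <- ncol(params$E_d); H <- config$heads
  variant <- config$variant
  D <- lapply(enc[seq_len(t)], function(e) active_idx(e$v_d))
  P <- lapply(enc[seq_len(t)], function(e) active_idx(e$v_p))
  M <- if (t > 1L) lapply(enc[seq_len(t - 1L)], function(e) active_idx(e$v_m))
       else list()

  run_layer <- function(feats, adj, stage) {
    if (variant == "GAT_GCN")
      gcn_aggregate(feats, adj, params[[paste0("gcn_", stage)]],
                    config$activation)
    else
      gat_layer(feats, adj, gat_group(params, stage, H),
                negative_slope = config$negative_slope,
                activation = config$activation,
                self_loops = config$self_loops,
                edge_weight_prior = config$use_edge_weight_prior)
  }

  ## stage 1: medication nodes over the combined medication graph
  hist_meds <- sort(unique(unlist(M)))
  m1 <- if (length(hist_meds) == 0L) matrix(0, 0L, r)
  else if (variant %in% c("WO_C", "WO_MM"))
    params$E_m[hist_meds, , drop = FALSE]
  else {
    amm <- if (config$cooccur_scope == "cohort" && !is.null(a_mm_global))
      a_mm_global[hist_meds, hist_meds, drop = FALSE]
    else cooccur_counts(M, hist_meds)
    g <- pmax(amm - config$lambda * a_ddi[hist_meds, hist_meds, drop = FALSE], 0)
    run_layer(params$E_m[hist_meds, , drop = FALSE], g, "m")
  }

  ## stage 2: diagnosis & procedure nodes over the per-visit dp graph
  VD <- vector("list", t); VP <- vector("list", t)
  for (j in seq_len(t)) {
    dj <- params$E_d[D[[j]], , drop = FALSE]
    pj <- params$E_p[P[[j]], , drop = FALSE]
    if (variant %in% c("WO_C", "WO_DP") ||
        (length(D[[j]]) + length(P[[j]])) == 0L) {
      VD[[j]] <- dj; VP[[j]] <- pj
    } else {
      out <- run_layer(rbind(dj, pj),
                       bipartite_adj(length(D[[j]]), length(P[[j]])), "dp")
      VD[[j]] <- out[seq_along(D[[j]]), , drop = FALSE]
      VP[[j]] <- out[length(D[[j]]) + seq_along(P[[j]]), , drop = FALSE]
    }
  }

  ## stage 3: cross-updates over the md and mp graphs (med side = previous
  ## visit's medications, features from stage 1)
  VM <- if (t > 1L) vector("list", t - 1L) else list()
  for (j in seq_len(t)) {
    if (j < 2L) next
    mids <- M[[j - 1L]]
    mf <- m1[match(mids, hist_meds), , drop = FALSE]
    if (length(mids) > 0L && !(variant %in% c("WO_C", "WO_DM")) &&
        length(D[[j]]) > 0L) {
      out <- run_layer(rbind(mf, VD[[j]]),
                       bipartite_adj(length(mids), length(D[[j]])), "md")
      mf <- out[seq_along(mids), , drop = FALSE]
      VD[[j]] <- out[length(mids) + seq_along(D[[j]]), , drop = FALSE]
    }
    if (length(mids) > 0L && !(variant %in% c("WO_C", "WO_PM")) &&
        length(P[[j]]) > 0L) {
      out <- run_layer(rbind(mf, VP[[j]]),
                       bipartite_adj(length(mids), length(P[[j]])), "mp")
      mf <- out[seq_along(mids), , drop = FALSE]
      VP[[j]] <- out[length(mids) + seq_along(P[[j]]), , drop = FALSE]
    }
    VM[[j - 1L]] <- mf
  }
  list(V_D = VD, V_P = VP, V_M = VM)
}

## Numeric forward for one prediction step.
forward_patient <- function(enc, t, params, config, a_ddi,
                            a_mm_global = NULL) {
  els <- entity_level_sets(enc, t, params, config, a_ddi, a_mm_global)
  rep <- build_patient_rep(els$V_D, els$V_P, els$V_M,
                           grouped_params(params), config)
  x <- matrix(c(rep$d_t, rep$p_t, rep$m_prev), 1L)
  logits <- as.numeric(x %*% params$W_out + params$b_out)
  probs <- 1 / (1 + exp(-logits))
  list(probs = probs, logits = logits,
       recommended = recommend(probs, config$threshold))
}

#' Threshold probabilities into a recommended medication set
#'
#' Strict inequality: a probability exactly at the threshold is not
#' recommended; the empty set is allowed.
#'
#' @param probs Numeric probability vector over the medication vocabulary.
#' @param threshold Threshold in (0, 1).
#' @return Integer vector of recommended medication indices.
#' @export
recommend <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  which(probs > threshold)
}

#' Multilabel binary cross-entropy loss
#'
#' `L = -sum(y * log p + (1 - y) * log(1 - p))` over all visit/medication
#' terms (sum convention; `reduction = "mean"` divides by the number of
#' terms). Probabilities are clipped to `[eps, 1 - eps]` first.
#'
#' @param probs Numeric vector/matrix of predicted probabilities.
#' @param targets Binary vector/matrix of the same shape.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(probs, targets, reduction = c("sum", "mean"),
                     eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(probs) != length(targets))
    stop("shape mismatch: ", length(probs), " probs vs ",
         length(targets), " targets")
  p <- pmin(pmax(probs, eps), 1 - eps)
  l <- -sum(targets * log(p) + (1 - targets) * log(1 - p))
  if (reduction == "mean") l / length(probs) else l
}

## ---- tape forward --------------------------------------------------------

make_leaves <- function(tp, params) {
  lapply(params, function(v) tp_leaf(tp, v))
}

tp_run_layer <- function(tp, x, adj, stage, leaves, config) {
  force(x)
  if (config$variant == "GAT_GCN")
    tp_gcn_aggregate(tp, x, adj, leaves[[paste0("gcn_", stage)]],
                     config$activation)
  else
    tp_gat_layer(tp, x, adj,
                 lapply(seq_len(config$heads), function(h)
                   leaves[[paste0("gat_", stage, "_W", h)]]),
                 lapply(seq_len(config$heads), function(h)
                   leaves[[paste0("gat_", stage, "_a", h)]]),
                 negative_slope = config$negative_slope,
                 activation = config$activation,
                 self_loops = config$self_loops,
                 edge_weight_prior = config$use_edge_weight_prior)
}

## Tape forward for one prediction step; returns the clipped-probability node.
tp_forward_patient <- function(tp, leaves, enc, t, params, config, a_ddi,
                               a_mm_global = NULL) {
  r <- ncol(params$E_d)
  variant <- config$variant
  D <- lapply(enc[seq_len(t)], function(e) active_idx(e$v_d))
  P <- lapply(enc[seq_len(t)], function(e) active_idx(e$v_p))
  M <- if (t > 1L) lapply(enc[seq_len(t - 1L)], function(e) active_idx(e$v_m))
       else list()

  hist_meds <- sort(unique(unlist(M)))
  m1 <- if (length(hist_meds) == 0L) NULL
  else if (variant %in% c("WO_C", "WO_MM"))
    tp_rows(tp, leaves$E_m, hist_meds)
  else {
    amm <- if (config$cooccur_scope == "cohort" && !is.null(a_mm_global))
      a_mm_global[hist_meds, hist_meds, drop = FALSE]
    else cooccur_counts(M, hist_meds)
    g <- pmax(amm - config$lambda * a_ddi[hist_meds, hist_meds, drop = FALSE], 0)
    tp_run_layer(tp, tp_rows(tp, leaves$E_m, hist_meds), g, "m", leaves, config)
  }

  VD <- vector("list", t); VP <- vector("list", t)
  for (j in seq_len(t)) {
    dj <- if (length(D[[j]])) tp_rows(tp, leaves$E_d, D[[j]]) else NULL
    pj <- if (length(P[[j]])) tp_rows(tp, leaves$E_p, P[[j]]) else NULL
    if (variant %in% c("WO_C", "WO_DP") || is.null(dj) && is.null(pj)) {
      VD[j] <- list(dj); VP[j] <- list(pj)
    } else {
      stacked <- if (is.null(pj)) dj else if (is.null(dj)) pj
                 else tp_rbind2(tp, list(dj, pj))
      out <- tp_run_layer(tp, stacked,
                          bipartite_adj(length(D[[j]]), length(P[[j]])),
                          "dp", leaves, config)
      VD[j] <- list(if (length(D[[j]])) tp_rows(tp, out, seq_along(D[[j]]))
                    else NULL)
      VP[j] <- list(if (length(P[[j]]))
        tp_rows(tp, out, length(D[[j]]) + seq_along(P[[j]])) else NULL)
    }
  }

  VM <- if (t > 1L) vector("list", t - 1L) else list()
  for (j in seq_len(t)) {
    if (j < 2L) next
    mids <- M[[j - 1L]]
    if (length(mids) == 0L) next
    mf <- tp_rows(tp, m1, match(mids, hist_meds))
    if (!(variant %in% c("WO_C", "WO_DM")) && length(D[[j]]) > 0L) {
      out <- tp_run_layer(tp, tp_rbind2(tp, list(mf, VD[[j]])),
                          bipartite_adj(length(mids), length(D[[j]])),
                          "md", leaves, config)
      mf <- tp_rows(tp, out, seq_along(mids))
      VD[[j]] <- tp_rows(tp, out, length(mids) + seq_along(D[[j]]))
    }
    if (!(variant %in% c("WO_C", "WO_PM")) && length(P[[j]]) > 0L) {
      out <- tp_run_layer(tp, tp_rbind2(tp, list(mf, VP[[j]])),
                          bipartite_adj(length(mids), length(P[[j]])),
                          "mp", leaves, config)
      mf <- tp_rows(tp, out, seq_along(mids))
      VP[[j]] <- tp_rows(tp, out, length(mids) + seq_along(P[[j]]))
    }
    VM[[j - 1L]] <- mf
  }

  pool_seq <- function(nodes) lapply(nodes, function(nd)
    tp_pool_visit(tp, nd, width = r, pooling = config$pooling))
  sel <- function(nodes, ent) {
    seq_nodes <- pool_seq(nodes)
    Lf <- lapply(stats::setNames(nm = c("Wz", "Uz", "bz", "Wr", "Ur", "br",
                                        "Wh", "Uh", "bh")),
                 function(g) leaves[[paste0("gru_f_", ent, "_", g)]])
    Lb <- lapply(stats::setNames(nm = c("Wz", "Uz", "bz", "Wr", "Ur", "br",
                                        "Wh", "Uh", "bh")),
                 function(g) leaves[[paste0("gru_b_", ent, "_", g)]])
    tp_select_aggregate(tp, seq_nodes, Lf, Lb,
                        leaves[[paste0("W_alpha_", ent)]],
                        leaves[[paste0("b_alpha_", ent)]],
                        leaves[[paste0("W_beta_", ent)]],
                        leaves[[paste0("b_beta_", ent)]],
                        r, shrink = config$tanhshrink_on,
                        wo_s = variant == "WO_S")
  }
  d_t <- sel(VD, "d")
  p_t <- sel(VP, "p")
  m_prev <- sel(VM, "m")
  x <- tp_cbind2(tp, list(d_t, p_t, m_prev))
  logits <- tp_addbias(tp, tp_mm(tp, x, leaves$W_out), leaves$b_out)
  tp_clip(tp, tp_sigmoid(tp, logits), 1e-7, 1 - 1e-7)
}

## Tape loss over all prediction steps of one patient.
tp_patient_loss <- function(tp, leaves, enc, params, config, a_ddi,
                            a_mm_global = NULL) {
  total <- NULL
  n_terms <- 0L
  for (t in seq_along(enc)) {
    pc <- tp_forward_patient(tp, leaves, enc, t, params, config, a_ddi,
                             a_mm_global)
    y <- matrix(enc[[t]]$v_m, 1L)
    term <- tp_add(tp, tp_cmul(tp, tp_log(tp, pc), y),
                   tp_cmul(tp, tp_log(tp, tp_rsub(tp, 1, pc)), 1 - y))
    vloss <- tp_scale(tp, tp_sum(tp, term), -1)
    n_terms <- n_terms + length(y)
    total <- if (is.null(total)) vloss else tp_add(tp, total, vloss)
  }
  if (config$loss_reduction == "mean") total <- tp_scale(tp, total, 1 / n_terms)
  total
}

## ---- training ------------------------------------------------------------

## Adam over the flattened parameter vector: one vectorised update instead of
## ninety small per-matrix updates.
adam_new <- function(params) {
  n <- sum(lengths(params))
  ends <- cumsum(lengths(params))
  starts <- c(1L, head(ends, -1L) + 1L)
  list(m = numeric(n), v = numeric(n), t = 0L,
       starts = starts, ends = ends)
}

adam_step <- function(params, grads, state, lr, wd, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- unlist(grads, use.names = FALSE)
  if (is.finite(clip)) {
    nrm <- sqrt(sum(g * g))
    if (nrm > clip) g <- g * (clip / nrm)
  }
  p <- unlist(params, use.names = FALSE)
  g <- g + wd * p
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  p <- p - lr * (state$m / c1) / (sqrt(state$v / c2) + eps)
  for (k in seq_along(params))
    params[[k]][] <- p[state$starts[k]:state$ends[k]]
  list(params = params, state = state)
}

encode_cohort <- function(cohort, vocab) {
  lapply(cohort$patients, function(p)
    lapply(p$visits, encode_visit, vocab = vocab))
}

## Restrict every visit's code sets to the vocabulary (prediction on cohorts
## containing codes unseen at training time).
restrict_to_vocab <- function(cohort, vocab) {
  dropped <- 0L
  cohort$patients <- lapply(cohort$patients, function(p) {
    p$visits <- lapply(p$visits, function(v) {
      for (fv in list(c("diagnoses", "diag"), c("procedures", "proc"),
                      c("medications", "med"))) {
        keep <- v[[fv[1L]]] %in% vocab[[fv[2L]]]
        dropped <<- dropped + sum(!keep)
        v[[fv[1L]]] <- v[[fv[1L]]][keep]
      }
      v
    })
    p
  })
  if (dropped > 0L)
    warning(dropped, " code(s) outside the vocabulary dropped", call. = FALSE)
  cohort
}

#' Fit the medication recommender
#'
#' Trains the full model (or an ablation variant) on a cohort: per patient and
#' visit `t`, the diagnosis/procedure sets of visits `1..t` and the medication
#' sets of visits `1..t-1` predict the medications of visit `t`. Optimisation
#' is Adam on the summed binary cross-entropy, one patient per step, with L2
#' weight decay and early stopping on validation Jaccard (best parameters are
#' restored). Fully deterministic for a fixed `config$seed`.
#'
#' @param cohort Training `csrec_cohort`.
#' @param ddi_pairs Optional two-column character matrix of contraindicated
#'   medication code pairs (see [read_ddi_csv()]).
#' @param config A [csrec_config()].
#' @param val Optional validation `csrec_cohort` (disjoint from `cohort`);
#'   without it, early stopping monitors training Jaccard.
#' @param vocab Optional `csrec_vocab`; defaults to the vocabulary of
#'   `cohort` and `val` combined, so that validation codes are encodable.
#' @return An object of class `csrec`: list with `params`, `config`, `vocab`,
#'   `ddi` (matrix), `report` (per-epoch data frame), `best_epoch`,
#'   `stop_reason`.
#' @examples
#' \donttest{
#' sim <- generate_cohort(synth_profile("mimic4_like", n_patients = 60, seed = 1))
#' parts <- split_cohort(sim$cohort, seed = 1)
#' cfg <- csrec_config(embed_dim = 12, heads = 2, max_epochs = 3, seed = 1)
#' fit <- csrec(parts$train, sim$ddi_pairs, cfg, val = parts$val)
#' print(fit)
#' }
#' @export
csrec <- function(cohort, ddi_pairs = NULL, config = csrec_config(),
                  val = NULL, vocab = NULL, engine = c("cpp", "tape")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cohort, "csrec_cohort"), inherits(config, "csrec_config"))
  if (is.null(vocab)) {
    pool <- cohort
    if (!is.null(val))
      pool$patients <- c(pool$patients, val$patients)
    vocab <- build_vocabulary(pool)
  }
  a_ddi <- if (is.null(ddi_pairs) || length(ddi_pairs) == 0L)
    matrix(0, vocab$n_med, vocab$n_med)
  else build_ddi_matrix(ddi_pairs, vocab)

  a_mm_global <- if (config$cooccur_scope == "cohort") {
    build_cooccurrence(unlist(lapply(cohort$patients, function(p)
      lapply(p$visits, `[[`, "medications")), recursive = FALSE), vocab)
  } else NULL

  enc_train <- encode_cohort(cohort, vocab)
  enc_val <- if (!is.null(val)) encode_cohort(val, vocab) else NULL
  sets <- lapply(enc_train, enc_index_sets)

  params <- init_params(vocab, config)
  state <- adam_new(params)
  n <- length(enc_train)
  report <- data.frame(epoch = integer(), train_loss = numeric(),
                       monitor_jaccard = numeric())
  best_metric <- -Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  stop_reason <- "max_epochs"

  monitor_enc <- if (!is.null(enc_val)) enc_val else enc_train
  monitor_engine <- if (engine == "cpp") "cpp" else "r"
  monitor_jaccard <- function(p) {
    batch <- predict_batch_enc(monitor_enc, p, config, a_ddi, a_mm_global,
                               engine = monitor_engine)
    jaccard(batch)
  }

  for (epoch in seq_len(config$max_epochs)) {
    order <- with_seed(config$seed * 1009L + epoch, sample.int(n))
    epoch_loss <- 0
    for (i in order) {
      if (engine == "cpp") {
        s <- sets[[i]]
        res <- cpp_patient_loss_grad(params, s$D, s$P, s$M, vocab$n_med,
                                     unclass(config), a_ddi, a_mm_global,
                                     TRUE)
        l <- res$loss
        grads <- res$grads
      } else {
        tp <- tape_new()
        leaves <- make_leaves(tp, params)
        root <- tp_patient_loss(tp, leaves, enc_train[[i]], params, config,
                                a_ddi, a_mm_global)
        l <- tp_val(tp, root)[1L]
        g <- tp_backward(tp, root)
        grads <- lapply(stats::setNames(nm = names(params)), function(nm) {
          gg <- g[[as.character(leaves[[nm]])]]
          if (is.null(gg)) params[[nm]] * 0 else gg
        })
      }
      if (!is.finite(l))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", patient ", i)
      epoch_loss <- epoch_loss + l
      upd <- adam_step(params, grads, state, config$learning_rate,
                       config$weight_decay, config$grad_clip)
      params <- upd$params; state <- upd$state
    }
    mj <- monitor_jaccard(params)
    report <- rbind(report, data.frame(epoch = epoch, train_loss = epoch_loss,
                                       monitor_jaccard = mj))
    if (mj > best_metric + 1e-12) {
      best_metric <- mj; best_params <- params; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) { stop_reason <- "early_stopping"; break }
    }
    if (!is.null(config$target_train_jaccard) &&
        epoch %% config$eval_every == 0L) {
      tj <- jaccard(predict_batch_enc(enc_train, params, config, a_ddi,
                                      a_mm_global, engine = monitor_engine))
      if (tj >= config$target_train_jaccard) {
        stop_reason <- "target_reached"
        best_params <- params; best_epoch <- epoch
        break
      }
    }
  }

  structure(list(params = best_params, config = config, vocab = vocab,
                 ddi = a_ddi, a_mm_global = a_mm_global, report = report,
                 best_epoch = best_epoch, best_metric = best_metric,
                 stop_reason = stop_reason, call = match.call()),
            class = "csrec")
}

enc_index_sets <- function(enc) {
  list(D = lapply(enc, function(e) active_idx(e$v_d)),
       P = lapply(enc, function(e) active_idx(e$v_p)),
       M = lapply(enc, function(e) active_idx(e$v_m)))
}

## Prediction over pre-encoded patients -> evaluation batch. The compiled
## kernel and the plain-R forward implement the same computation; tests pin
## them equal, and `engine = "r"` exposes the reference path.
predict_batch_enc <- function(enc_list, params, config, a_ddi,
                              a_mm_global = NULL, engine = "cpp") {
  out <- list()
  for (enc in enc_list) {
    if (engine == "cpp") {
      s <- enc_index_sets(enc)
      probs <- cpp_patient_probs(params, s$D, s$P, s$M, ncol(a_ddi),
                                 unclass(config), a_ddi, a_mm_global)
      for (t in seq_along(enc))
        out[[length(out) + 1L]] <-
          list(truth = s$M[[t]],
               pred = recommend(probs[t, ], config$threshold),
               scores = probs[t, ])
    } else {
      for (t in seq_along(enc)) {
        fw <- forward_patient(enc, t, params, config, a_ddi, a_mm_global)
        out[[length(out) + 1L]] <-
          list(truth = active_idx(enc[[t]]$v_m),
               pred = fw$recommended, scores = fw$probs)
      }
    }
  }
  out
}

#' Predict medication recommendations
#'
#' Runs the fitted model over every visit of a cohort. For each visit `t` the
#' prediction uses that visit's diagnoses/procedures and the medication
#' history of earlier visits; the visit's own medications serve as the truth
#' in the returned batch. Codes absent from the training vocabulary are
#' dropped with a warning.
#'
#' @param object A fitted `csrec` object.
#' @param cohort A `csrec_cohort` to score.
#' @param type `"batch"` (default; list of per-visit truth/pred/scores,
#'   directly consumable by the metrics) or `"probs"` (matrix of
#'   probabilities, one row per visit).
#' @param threshold Recommendation threshold; defaults to the fitted config's.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (the plain-R
#'   reference forward); the two agree to near machine precision and are
#'   pinned together by the test suite.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.csrec <- function(object, cohort, type = c("batch", "probs"),
                          threshold = NULL, engine = c("cpp", "r"), ...) {
  type <- match.arg(type)
  engine <- match.arg(engine)
  if (is.null(threshold)) threshold <- object$config$threshold
  cfg <- object$config
  cfg$threshold <- threshold
  cohort <- restrict_to_vocab(cohort, object$vocab)
  enc_list <- encode_cohort(cohort, object$vocab)
  batch <- predict_batch_enc(enc_list, object$params, cfg, object$ddi,
                             object$a_mm_global, engine = engine)
  if (type == "probs")
    do.call(rbind, lapply(batch, `[[`, "scores"))
  else batch
}

#' Evaluate a fitted model on a cohort
#'
#' @param fit A fitted `csrec` object.
#' @param cohort Cohort to score.
#' @param ddi Optional interaction matrix (defaults to the one stored in the
#'   fit).
#' @return List with `metrics` (named vector: jaccard, prauc, f1, ddi) and
#'   `batch`.
#' @export
evaluate_model <- function(fit, cohort, ddi = NULL) {
  if (is.null(ddi)) ddi <- fit$ddi
  batch <- predict(fit, cohort)
  list(metrics = evaluate_batch(batch, ddi), batch = batch)
}

#' @export
print.csrec <- function(x, ...) {
  cat(sprintf("csrec fit: variant %s, width %d (H=%d), |D|=%d |P|=%d |M|=%d\n",
              x$config$variant, x$config$width, x$config$heads,
              x$vocab$n_diag, x$vocab$n_proc, x$vocab$n_med))
  cat(sprintf("  epochs run %d, best epoch %d (monitor Jaccard %.4f), stop: %s\n",
              nrow(x$report), x$best_epoch, x$best_metric, x$stop_reason))
  invisible(x)
}

#' @export
summary.csrec <- function(object, ...) {
  print(object)
  cat("training trajectory (last 5 epochs):\n")
  print(utils::tail(object$report, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.csrec <- function(object, ...) object$params

#' @export
plot.csrec <- function(x, ...) {
  r <- x$report
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(r$epoch, r$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "csrec training", ...)
  par(new = TRUE)
  plot(r$epoch, r$monitor_jaccard, type = "l", lty = 2, axes = FALSE,
       xlab = "", ylab = "")
  axis(4)
  abline(v = x$best_epoch, lty = 3)
  legend("topright", legend = c("train loss", "monitor Jaccard"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Save / load a fitted model as portable JSON
#'
#' The checkpoint is a single JSON file holding the configuration, all
#' parameter matrices at full precision, the vocabulary and the interaction
#' matrix's nonzero pairs.
#'
#' @param fit A `csrec` object.
#' @param path File path.
#' @return `load_csrec`: the restored `csrec` object.
#' @export
save_csrec <- function(fit, path) {
  obj <- list(config = unclass(fit$config),
              vocab = unclass(fit$vocab),
              params = lapply(fit$params, function(m)
                list(dim = dim(m), data = as.numeric(m))),
              ddi_nz = which(fit$ddi != 0),
              best_epoch = fit$best_epoch, stop_reason = fit$stop_reason)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_csrec
#' @param path File path.
#' @export
load_csrec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- obj$config
  config$target_train_jaccard <- obj$config$target_train_jaccard
  class(config) <- "csrec_config"
  vocab <- obj$vocab
  class(vocab) <- "csrec_vocab"
  params <- lapply(obj$params, function(m)
    matrix(m$data, m$dim[1L], m$dim[2L]))
  ddi <- matrix(0, vocab$n_med, vocab$n_med)
  if (length(obj$ddi_nz)) ddi[as.integer(obj$ddi_nz)] <- 1
  structure(list(params = params, config = config, vocab = vocab, ddi = ddi,
                 a_mm_global = NULL, report = NULL,
                 best_epoch = obj$best_epoch, best_metric = NA_real_,
                 stop_reason = obj$stop_reason, call = NULL),
            class = "csrec")
}
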