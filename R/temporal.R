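## Bidirectional gated-recurrent selection over the visit sequence.
##
## Per entity type, the per-visit node matrices are pooled to one vector per
## visit; a forward GRU produces states g_1..g_t and selection coefficients
## alpha_j = tanh(W_a g_j + b_a), a backward GRU (run over the reversed
## sequence) produces states whose coefficients beta_j = tanhshrink(W_b h_j +
## b_b), with tanhshrink(x) = x - tanh(x). The aggregated representation is
## sum_j alpha_j * beta_j * V_j (elementwise). Numeric functions are the
## public surface; tp_* twins run on the autodiff tape during training.

#' Pool a visit's node matrix to a single vector
#'
#' Arithmetic mean over rows (`pooling = "mean"`, the default) or sum; an
#' empty matrix (no active codes) pools to the zero vector.
#'
#' @param entity_nodes Numeric matrix, one row per active code (possibly 0
#'   rows).
#' @param width Vector length to return when `entity_nodes` has zero rows
#'   (defaults to its column count).
#' @param pooling `"mean"` or `"sum"`.
#' @return Numeric vector of length `ncol(entity_nodes)`.
#' @export
pool_visit <- function(entity_nodes, width = ncol(entity_nodes),
                       pooling = "mean") {
  if (is.null(dim(entity_nodes))) entity_nodes <- matrix(entity_nodes, 1L)
  if (nrow(entity_nodes) == 0L) return(numeric(width))
  switch(pooling,
         mean = colMeans(entity_nodes),
         sum = colSums(entity_nodes),
         stop("unknown pooling: ", pooling))
}

## One GRU step. P: list(Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh); x, h: 1 x r.
gru_cell <- function(x, h, P) {
  z <- plogis(x %*% P$Wz + h %*% P$Uz + rep(P$bz, each = nrow(x)))
  r <- plogis(x %*% P$Wr + h %*% P$Ur + rep(P$br, each = nrow(x)))
  hh <- tanh(x %*% P$Wh + (r * h) %*% P$Uh + rep(P$bh, each = nrow(x)))
  (1 - z) * h + z * hh
}

gru_run <- function(seq_list, P) {
  r <- length(P$bz)
  h <- matrix(0, 1L, r)
  lapply(seq_list, function(x) {
    h <<- gru_cell(matrix(x, 1L), h, P)
    h
  })
}

#' Forward selection coefficients
#'
#' Runs the forward GRU over the pooled visit sequence and maps each state to
#' a coefficient vector `alpha_j = tanh(W_alpha g_j + b_alpha)`; entries lie
#' strictly in (-1, 1).
#'
#' @param seq_list List of per-visit pooled vectors (oldest first), non-empty.
#' @param gru_params GRU parameter list (`Wz`,`Uz`,`bz`,`Wr`,`Ur`,`br`,
#'   `Wh`,`Uh`,`bh`).
#' @param W_alpha,b_alpha Output map (r x r matrix, length-r bias).
#' @return List with `alpha` (list of 1 x r matrices) and `states`.
#' @export
forward_coefficients <- function(seq_list, gru_params, W_alpha, b_alpha) {
  if (length(seq_list) == 0L) stop("no history: empty visit sequence")
  states <- gru_run(seq_list, gru_params)
  alpha <- lapply(states, function(g) tanh(g %*% W_alpha + rep(b_alpha, each = 1L)))
  list(alpha = alpha, states = states)
}

#' Backward selection coefficients
#'
#' Runs a GRU over the reversed sequence and maps each state through
#' `tanhshrink(W_beta h_j + b_beta)` with `tanhshrink(x) = x - tanh(x)`
#' (or `tanh` when `shrink = FALSE`). Coefficients are returned in forward
#' order, aligned with the input sequence.
#'
#' @inheritParams forward_coefficients
#' @param W_beta,b_beta Output map.
#' @param shrink Use tanhshrink (default) or plain tanh.
#' @return List with `beta` (forward order) and `states` (forward order).
#' @export
backward_coefficients <- function(seq_list, gru_params, W_beta, b_beta,
                                  shrink = TRUE) {
  if (length(seq_list) == 0L) stop("no history: empty visit sequence")
  states_rev <- gru_run(rev(seq_list), gru_params)
  states <- rev(states_rev)
  out <- function(x) if (shrink) x - tanh(x) else tanh(x)
  beta <- lapply(states, function(h) out(h %*% W_beta + rep(b_beta, each = 1L)))
  list(beta = beta, states = states)
}

#' Coefficient-gated aggregation over the visit sequence
#'
#' `sum_j alpha_j * beta_j * V_j`, all products elementwise; linear in the
#' sequence for fixed coefficients.
#'
#' @param seq_list List of per-visit pooled vectors.
#' @param alpha,beta Coefficient lists of the same length.
#' @return Numeric vector.
#' @export
aggregate_selected <- function(seq_list, alpha, beta) {
  if (length(seq_list) != length(alpha) || length(seq_list) != length(beta))
    stop("length mismatch between sequence and coefficients")
  out <- 0
  for (j in seq_along(seq_list))
    out <- out + as.numeric(alpha[[j]]) * as.numeric(beta[[j]]) *
      as.numeric(seq_list[[j]])
  out
}

#' Aggregated patient representation from entity-level sets
#'
#' Pools each visit's node matrix, then applies the bidirectional selection
#' independently per entity type (diagnoses and procedures over visits
#' 1..t, medications over 1..t-1). An empty medication history yields the
#' zero vector for `m_prev`.
#'
#' @param V_D,V_P Lists of per-visit node matrices, length t.
#' @param V_M List of per-visit medication node matrices, length t-1 (possibly
#'   empty).
#' @param params Model parameter list (GRU + coefficient maps per entity).
#' @param config A `csrec_config` (pooling and tanhshrink settings).
#' @return List with vectors `d_t`, `p_t`, `m_prev`.
#' @export
build_patient_rep <- function(V_D, V_P, V_M, params, config) {
  r <- ncol(params$W_alpha_d)
  one <- function(V_list, ent) {
    seq_list <- lapply(V_list, pool_visit, width = r,
                       pooling = config$pooling)
    if (length(seq_list) == 0L) return(numeric(r))
    if (config$variant == "WO_S") return(as.numeric(seq_list[[length(seq_list)]]))
    fw <- forward_coefficients(seq_list, params[[paste0("gru_f_", ent)]],
                               params[[paste0("W_alpha_", ent)]],
                               params[[paste0("b_alpha_", ent)]])
    bw <- backward_coefficients(seq_list, params[[paste0("gru_b_", ent)]],
                                params[[paste0("W_beta_", ent)]],
                                params[[paste0("b_beta_", ent)]],
                                shrink = config$tanhshrink_on)
    aggregate_selected(seq_list, fw$alpha, bw$beta)
  }
  list(d_t = one(V_D, "d"), p_t = one(V_P, "p"), m_prev = one(V_M, "m"))
}

## ---- tape twins ----------------------------------------------------------

tp_pool_visit <- function(tp, node, width, pooling = "mean") {
  force(node)
  if (is.null(node) || nrow(tp_val(tp, node)) == 0L)
    return(tp_const(tp, matrix(0, 1L, width)))
  switch(pooling,
         mean = tp_colmeans(tp, node),
         sum = tp_scale(tp, tp_colmeans(tp, node), nrow(tp_val(tp, node))),
         stop("unknown pooling: ", pooling))
}

tp_gru_cell <- function(tp, x, h, L) {
  force(x); force(h)
  z <- tp_sigmoid(tp, tp_addbias(tp, tp_add(tp, tp_mm(tp, x, L$Wz),
                                            tp_mm(tp, h, L$Uz)), L$bz))
  r <- tp_sigmoid(tp, tp_addbias(tp, tp_add(tp, tp_mm(tp, x, L$Wr),
                                            tp_mm(tp, h, L$Ur)), L$br))
  hh <- tp_tanh(tp, tp_addbias(tp, tp_add(tp, tp_mm(tp, x, L$Wh),
                                          tp_mm(tp, tp_mul(tp, r, h), L$Uh)),
                               L$bh))
  tp_add(tp, tp_mul(tp, tp_rsub(tp, 1, z), h), tp_mul(tp, z, hh))
}

tp_gru_run <- function(tp, seq_nodes, L, r) {
  h <- tp_const(tp, matrix(0, 1L, r))
  lapply(seq_nodes, function(x) {
    h <<- tp_gru_cell(tp, x, h, L)
    h
  })
}

## Selection + aggregation for one entity type on the tape.
tp_select_aggregate <- function(tp, seq_nodes, Lf, Lb, Wa, ba, Wb, bb, r,
                                shrink = TRUE, wo_s = FALSE) {
  if (length(seq_nodes) == 0L) return(tp_const(tp, matrix(0, 1L, r)))
  if (wo_s) return(seq_nodes[[length(seq_nodes)]])
  gs <- tp_gru_run(tp, seq_nodes, Lf, r)
  hs <- rev(tp_gru_run(tp, rev(seq_nodes), Lb, r))
  out <- NULL
  for (j in seq_along(seq_nodes)) {
    alpha <- tp_tanh(tp, tp_addbias(tp, tp_mm(tp, gs[[j]], Wa), ba))
    pre <- tp_addbias(tp, tp_mm(tp, hs[[j]], Wb), bb)
    beta <- if (shrink) tp_tanhshrink(tp, pre) else tp_tanh(tp, pre)
    term <- tp_mul(tp, tp_mul(tp, alpha, beta), seq_nodes[[j]])
    out <- if (is.null(out)) term else tp_add(tp, out, term)
  }
  out
}
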