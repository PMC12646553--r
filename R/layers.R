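## Neighbour-focused multi-head graph attention.
##
## Attention logits for an edge (i, j) are LeakyReLU(a . [h_i || h_j]) with
## h = X W the head's linearly mapped features; weights are softmax-normalised
## over the neighbour set N_i. The layer deliberately EXCLUDES the node's own
## feature from aggregation ("focus on neighbours"): N_i never contains i
## unless `self_loops = TRUE` (the standard-GAT alternative, kept behind a
## flag). Isolated nodes bypass aggregation and keep their linearly mapped
## feature. Heads are concatenated.
##
## Each exported function has a tape twin (tp_*) used during training; the two
## share the same algebra, and the test suite pins them together.

act_fun <- function(name) {
  switch(name,
         elu = function(x) ifelse(x > 0, x, exp(x) - 1),
         tanh = tanh,
         none = identity,
         stop("unknown activation: ", name))
}

#' Attention weights of one node over its neighbours
#'
#' Computes the softmax-normalised attention of node `i` over `neighbors`
#' for a single head: `w_j` proportional to
#' `exp(LeakyReLU(attn_vector . [h_i || h_j]))` with `h = features %*%
#' linear_map`.
#'
#' @param features Node-feature matrix (nodes x d_in).
#' @param i Index of the attending node.
#' @param neighbors Non-empty integer vector of neighbour indices.
#' @param params Head parameters: list with `linear_map` (d_in x d_head) and
#'   `attn_vector` (length 2*d_head), optional `negative_slope` (default 0.2).
#' @return Numeric vector over `neighbors`, positive, summing to 1.
#' @export
attention_weights <- function(features, i, neighbors, params) {
  if (length(neighbors) == 0L) stop("isolated node: empty neighbor list")
  slope <- if (is.null(params$negative_slope)) 0.2 else params$negative_slope
  h <- features %*% params$linear_map
  dh <- ncol(h)
  a1 <- params$attn_vector[seq_len(dh)]
  a2 <- params$attn_vector[dh + seq_len(dh)]
  logits <- as.numeric(h[i, , drop = FALSE] %*% a1) +
    as.vector(h[neighbors, , drop = FALSE] %*% a2)
  logits <- ifelse(logits > 0, logits, slope * logits)
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Attention-weighted aggregation over neighbours
#'
#' `e_i = activation(sum_j w_j h_j)` over the mapped neighbour features only
#' (the node's own feature is excluded). An empty neighbour list returns the
#' node's own linearly mapped feature without activation (isolated-node
#' bypass).
#'
#' @inheritParams attention_weights
#' @param weights Attention weights from [attention_weights()].
#' @param activation `"elu"`, `"tanh"` or `"none"`.
#' @return Numeric vector of length `d_head`.
#' @export
aggregate_neighbors <- function(features, i, neighbors, weights, params,
                                activation = "elu") {
  h <- features %*% params$linear_map
  if (length(neighbors) == 0L) return(as.numeric(h[i, ]))
  act_fun(activation)(as.numeric(crossprod(weights,
                                           h[neighbors, , drop = FALSE])))
}

#' Multi-head attention aggregation for one node
#'
#' Concatenates [aggregate_neighbors()] outputs over the heads; output length
#' is `H * d_head`.
#'
#' @inheritParams attention_weights
#' @param head_params List of per-head parameter lists.
#' @param activation Aggregation activation.
#' @return Numeric vector of length `H * d_head`.
#' @export
multi_head_aggregate <- function(features, i, neighbors, head_params,
                                 activation = "elu") {
  unlist(lapply(head_params, function(hp) {
    w <- if (length(neighbors)) attention_weights(features, i, neighbors, hp)
         else numeric()
    aggregate_neighbors(features, i, neighbors, w, hp, activation)
  }))
}

## Full-graph numeric layer over a weighted adjacency (zero = no edge).
## params: list(W = list of H d_in x d_head, a = list of H length-2*d_head).
gat_layer <- function(features, adj, params, negative_slope = 0.2,
                      activation = "elu", self_loops = FALSE,
                      edge_weight_prior = FALSE) {
  n <- nrow(features)
  mask <- (adj > 0) * 1
  if (self_loops) diag(mask) <- 1 else diag(mask) <- 0
  ## an entirely edgeless graph carries no collaborative signal: leave the
  ## features untouched (nodes merely isolated inside a connected graph still
  ## take the linearly mapped bypass below)
  if (all(mask == 0)) return(features)
  prior <- if (edge_weight_prior) {
    pm <- adj * mask
    if (self_loops) diag(pm)[diag(pm) == 0] <- 1
    pm
  } else mask
  deg <- rowSums(mask)
  iso <- deg == 0
  act <- act_fun(activation)
  heads <- lapply(seq_along(params$W), function(h) {
    Hl <- features %*% params$W[[h]]
    dh <- ncol(Hl)
    a1 <- params$a[[h]][seq_len(dh)]; a2 <- params$a[[h]][dh + seq_len(dh)]
    s1 <- as.vector(Hl %*% a1); s2 <- as.vector(Hl %*% a2)
    L <- outer(s1, rep(1, n)) + outer(rep(1, n), s2)
    E <- exp(ifelse(L > 0, L, negative_slope * L)) * prior
    rs <- rowSums(E) + iso            # isolated rows: denominator 1, P row 0
    P <- E / rs
    out <- act(P %*% Hl)
    out[iso, ] <- Hl[iso, ]
    out
  })
  do.call(cbind, heads)
}

## Tape twin of gat_layer. `x` is a tape node; W/a are tape leaf ids.
tp_gat_layer <- function(tp, x, adj, W_ids, a_ids, negative_slope = 0.2,
                         activation = "elu", self_loops = FALSE,
                         edge_weight_prior = FALSE) {
  force(x)
  n <- nrow(tp_val(tp, x))
  mask <- (adj > 0) * 1
  if (self_loops) diag(mask) <- 1 else diag(mask) <- 0
  if (all(mask == 0)) return(x)          # edgeless graph: no update
  prior <- if (edge_weight_prior) {
    pm <- adj * mask
    if (self_loops) diag(pm)[diag(pm) == 0] <- 1
    pm
  } else mask
  deg <- rowSums(mask)
  iso <- (deg == 0) * 1
  ones_row <- matrix(1, 1L, n)
  heads <- lapply(seq_along(W_ids), function(h) {
    Hl <- tp_mm(tp, x, W_ids[[h]])
    dh <- ncol(tp_val(tp, Hl))
    a1 <- tp_rows(tp, tp_t(tp, a_ids[[h]]), seq_len(dh))
    a2 <- tp_rows(tp, tp_t(tp, a_ids[[h]]), dh + seq_len(dh))
    s1 <- tp_mm(tp, Hl, a1)           # n x 1
    s2 <- tp_mm(tp, Hl, a2)
    L <- tp_add(tp, tp_mm(tp, s1, tp_const(tp, ones_row)),
                tp_mm(tp, tp_const(tp, t(ones_row)), tp_t(tp, s2)))
    E <- tp_cmul(tp, tp_exp(tp, tp_lrelu(tp, L, negative_slope)), prior)
    rs <- tp_push(tp, matrix(rowSums(tp_val(tp, E)) + iso, ncol = 1L),
                  "rowsum_iso", E, iso)
    P <- tp_rowdiv(tp, E, rs)
    agg <- tp_mm(tp, P, Hl)
    out <- switch(activation,
                  elu = tp_elu(tp, agg),
                  tanh = tp_tanh(tp, agg),
                  none = agg)
    if (any(iso > 0)) {               # bypass: isolated rows keep X W
      keep <- matrix(rep(1 - iso, dh), ncol = dh)
      out <- tp_add(tp, tp_cmul(tp, out, keep),
                    tp_cmul(tp, Hl, 1 - keep))
    }
    out
  })
  if (length(heads) == 1L) heads[[1L]] else tp_cbind2(tp, heads)
}

#' Degree-normalised graph convolution (GCN aggregation)
#'
#' The ablation alternative to graph attention: adds self-loops, normalises
#' the adjacency symmetrically by `1/sqrt(d_i d_j)` and applies
#' `activation(A_norm X W)`.
#'
#' @param features Node-feature matrix.
#' @param adjacency Square (weighted) adjacency matrix.
#' @param weight_matrix d_in x d_out weight matrix.
#' @param activation Activation name.
#' @return Updated node-feature matrix.
#' @export
gcn_aggregate <- function(features, adjacency, weight_matrix,
                          activation = "elu") {
  stopifnot(nrow(adjacency) == ncol(adjacency))
  A <- (adjacency > 0) * 1
  diag(A) <- 1
  d <- rowSums(A)
  norm <- A / sqrt(outer(d, d))
  act_fun(activation)(norm %*% features %*% weight_matrix)
}

gcn_norm <- function(adjacency) {
  A <- (adjacency > 0) * 1
  diag(A) <- 1
  d <- rowSums(A)
  A / sqrt(outer(d, d))
}

tp_gcn_aggregate <- function(tp, x, adjacency, W_id, activation = "elu") {
  force(x)
  norm <- gcn_norm(adjacency)
  agg <- tp_mm(tp, tp_push(tp, norm %*% tp_val(tp, x), "mm_constL", x, norm),
               W_id)
  switch(activation, elu = tp_elu(tp, agg), tanh = tp_tanh(tp, agg),
         none = agg)
}
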