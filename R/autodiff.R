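## Minimal reverse-mode automatic differentiation on a tape of matrix ops.
## Every value is a base-R matrix; a node is an integer id into the tape.
## This is the gradient engine behind model training; the public model
## functions never expose it. Ops are kept to exactly what the architecture
## needs; each op stores its parents and enough auxiliary state to run the
## chain rule in a single reverse sweep.

## Node slots live directly in environments keyed by the node id (as a
## string): environment writes are O(1), whereas writing into a list held in
## an environment copies the list once any reader has touched it.
tape_new <- function(capacity = NULL) {
  tp <- new.env(parent = emptyenv())
  tp$v <- new.env(parent = emptyenv())   # values
  tp$o <- new.env(parent = emptyenv())   # op names
  tp$p <- new.env(parent = emptyenv())   # parent ids
  tp$x <- new.env(parent = emptyenv())   # auxiliary state
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, op, par = NULL, aux = NULL) {
  n <- tp$n + 1L
  k <- as.character(n)
  tp$v[[k]] <- val
  tp$o[[k]] <- op
  if (!is.null(par)) tp$p[[k]] <- par
  if (!is.null(aux)) tp$x[[k]] <- aux
  tp$n <- n
  n
}

as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

tp_leaf <- function(tp, val) tp_push(tp, as_mat(val), "leaf")
tp_const <- function(tp, val) tp_push(tp, as_mat(val), "const")
tp_val <- function(tp, id) tp$v[[as.character(id)]]

tp_mm <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) %*% tp_val(tp, b), "mm", c(a, b))
}
tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) + tp_val(tp, b), "add", c(a, b))
}
tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) - tp_val(tp, b), "sub", c(a, b))
}
tp_mul <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) * tp_val(tp, b), "mul", c(a, b))
}
## matrix (n x k) plus a 1 x k bias row, broadcast over rows
tp_addbias <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, sweep(tp_val(tp, a), 2L, as.vector(tp_val(tp, b)), "+"),
          "addbias", c(a, b))
}
tp_scale <- function(tp, a, s) {
  force(a)
  tp_push(tp, tp_val(tp, a) * s, "scale", a, s)
}
## constant minus node (for 1 - z gates)
tp_rsub <- function(tp, s, a) {
  force(a)
  tp_push(tp, s - tp_val(tp, a), "rsub", a)
}
tp_cmul <- function(tp, a, C) {   # multiply by a constant matrix, elementwise
  force(a)
  tp_push(tp, tp_val(tp, a) * C, "cmul", a, C)
}
tp_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp_val(tp, a)))
  tp_push(tp, y, "sigmoid", a)
}
tp_tanh <- function(tp, a) {
  force(a)
  tp_push(tp, tanh(tp_val(tp, a)), "tanh", a)
}
tp_tanhshrink <- function(tp, a) {
  force(a)
  th <- tanh(tp_val(tp, a))
  tp_push(tp, tp_val(tp, a) - th, "tanhshrink", a, th)
}
tp_elu <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, ifelse(x > 0, x, exp(x) - 1), "elu", a)
}
tp_lrelu <- function(tp, a, slope = 0.2) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, ifelse(x > 0, x, slope * x), "lrelu", a, slope)
}
tp_exp <- function(tp, a) {
  force(a)
  tp_push(tp, exp(tp_val(tp, a)), "exp", a)
}
tp_log <- function(tp, a) {
  force(a)
  tp_push(tp, log(tp_val(tp, a)), "log", a)
}
tp_sum <- function(tp, a) {
  force(a)
  tp_push(tp, matrix(sum(tp_val(tp, a)), 1L, 1L), "sum", a)
}
tp_colmeans <- function(tp, a) {
  force(a)
  tp_push(tp, matrix(colMeans(tp_val(tp, a)), 1L), "colmeans", a)
}
tp_rows <- function(tp, a, idx) {
  force(a)
  tp_push(tp, tp_val(tp, a)[idx, , drop = FALSE], "rows", a, idx)
}
tp_t <- function(tp, a) {
  force(a)
  tp_push(tp, t(tp_val(tp, a)), "t", a)
}
tp_cbind2 <- function(tp, nodes) {
  vals <- lapply(nodes, function(i) tp_val(tp, i))
  tp_push(tp, do.call(cbind, vals), "cbind", as.integer(nodes),
          vapply(vals, ncol, 0L))
}
tp_rbind2 <- function(tp, nodes) {
  vals <- lapply(nodes, function(i) tp_val(tp, i))
  tp_push(tp, do.call(rbind, vals), "rbind", as.integer(nodes),
          vapply(vals, nrow, 0L))
}
## row-wise division of an n x m matrix by an n x 1 column
tp_rowdiv <- function(tp, a, r) {
  force(a); force(r)
  tp_push(tp, tp_val(tp, a) / as.vector(tp_val(tp, r)), "rowdiv", c(a, r))
}
tp_clip <- function(tp, a, lo, hi) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, pmin(pmax(x, lo), hi), "clip", a, c(lo, hi))
}

## Reverse sweep from `root` (scalar 1 x 1). Returns an environment `g`
## holding a gradient matrix for every reachable node.
tp_backward <- function(tp, root) {
  g <- new.env(parent = emptyenv())
  g[[as.character(root)]] <- matrix(1, 1L, 1L)
  acc <- function(p, gp) {
    k <- as.character(p)
    gk <- g[[k]]
    g[[k]] <- if (is.null(gk)) gp else gk + gp
  }
  val <- tp$v
  for (i in seq(root, 1L)) {
    ki <- as.character(i)
    gi <- g[[ki]]
    if (is.null(gi)) next
    op <- tp$o[[ki]]
    if (op == "leaf" || op == "const") next
    p <- tp$p[[ki]]
    switch(op,
      mm = { acc(p[1L], gi %*% t(val[[as.character(p[2L])]]))
             acc(p[2L], t(val[[as.character(p[1L])]]) %*% gi) },
      add = { acc(p[1L], gi); acc(p[2L], gi) },
      sub = { acc(p[1L], gi); acc(p[2L], -gi) },
      mul = { acc(p[1L], gi * val[[as.character(p[2L])]])
              acc(p[2L], gi * val[[as.character(p[1L])]]) },
      addbias = { acc(p[1L], gi)
                  acc(p[2L], matrix(colSums(gi), 1L)) },
      scale = acc(p, gi * tp$x[[ki]]),
      rsub = acc(p, -gi),
      cmul = acc(p, gi * tp$x[[ki]]),
      sigmoid = { y <- val[[ki]]; acc(p, gi * y * (1 - y)) },
      tanh = { y <- val[[ki]]; acc(p, gi * (1 - y * y)) },
      tanhshrink = { th <- tp$x[[ki]]; acc(p, gi * th * th) },
      elu = { x <- val[[as.character(p)]]; y <- val[[ki]]
              acc(p, gi * ifelse(x > 0, 1, y + 1)) },
      lrelu = { x <- val[[as.character(p)]]
                acc(p, gi * ifelse(x > 0, 1, tp$x[[ki]])) },
      exp = acc(p, gi * val[[ki]]),
      log = acc(p, gi / val[[as.character(p)]]),
      sum = acc(p, matrix(gi[1L], nrow(val[[as.character(p)]]), ncol(val[[as.character(p)]]))),
      colmeans = { v <- val[[as.character(p)]]
                   acc(p, matrix(rep(gi / nrow(v), each = nrow(v)),
                                 nrow(v), ncol(v))) },
      rows = { gp <- matrix(0, nrow(val[[as.character(p)]]), ncol(val[[as.character(p)]]))
               idx <- tp$x[[ki]]
               for (k in seq_along(idx))
                 gp[idx[k], ] <- gp[idx[k], ] + gi[k, ]
               acc(p, gp) },
      t = acc(p, t(gi)),
      cbind = { widths <- tp$x[[ki]]; off <- 0L
                for (k in seq_along(p)) {
                  acc(p[k], gi[, off + seq_len(widths[k]), drop = FALSE])
                  off <- off + widths[k]
                } },
      rbind = { heights <- tp$x[[ki]]; off <- 0L
                for (k in seq_along(p)) {
                  acc(p[k], gi[off + seq_len(heights[k]), , drop = FALSE])
                  off <- off + heights[k]
                } },
      rowdiv = { a <- val[[as.character(p[1L])]]; r <- as.vector(val[[as.character(p[2L])]])
                 acc(p[1L], gi / r)
                 acc(p[2L], matrix(-rowSums(gi * a / r^2), ncol = 1L)) },
      clip = { x <- val[[as.character(p)]]; b <- tp$x[[ki]]
               acc(p, gi * (x > b[1L] & x < b[2L])) },
      ## rowSums(parent) + const column, stored as n x 1
      rowsum_iso = acc(p, matrix(rep(gi, ncol(val[[as.character(p)]])),
                                 nrow(val[[as.character(p)]]), ncol(val[[as.character(p)]]))),
      ## constant-left matrix product C %*% parent (aux = C)
      mm_constL = acc(p, t(tp$x[[ki]]) %*% gi),
      stop("no backward rule for op ", op)
    )
  }
  g
}
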