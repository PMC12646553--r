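# Straight-line oracle for one attention head, written directly from the
# softmax-of-LeakyReLU definition.
oracle_attention <- function(features, i, neighbors, head) {
  h <- features %*% head$linear_map
  g <- sapply(neighbors, function(j) {
    x <- sum(head$attn_vector * c(h[i, ], h[j, ]))
    if (x > 0) x else 0.2 * x
  })
  exp(g) / sum(exp(g))
}

test_that("attention weights normalise correctly in degenerate cases", {
  set.seed(1)
  X <- matrix(rnorm(20), 5, 4)
  head <- random_head(4, 3)
  # single neighbour -> weight exactly 1
  expect_equal(attention_weights(X, 1, 2, head), 1)
  # identical neighbour features -> uniform weights
  Xu <- matrix(rep(rnorm(4), each = 5), 5, 4)
  Xu[1, ] <- rnorm(4)
  w <- attention_weights(Xu, 1, 2:5, head)
  expect_equal(w, rep(1 / 4, 4), tolerance = 1e-12)
  expect_error(attention_weights(X, 1, integer(), head), "isolated")
})

test_that("attention weights match the exponentiate-and-normalise oracle", {
  set.seed(2)
  for (i in 1:50) {
    X <- matrix(rnorm(5 * 4), 5, 4)
    head <- random_head(4, 3)
    nb <- sample(2:5, sample(1:4, 1))
    expect_equal(attention_weights(X, 1, nb, head),
                 oracle_attention(X, 1, nb, head), tolerance = 1e-10)
  }
})

test_that("attention rows are probability vectors on random graphs", {
  set.seed(3)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    head <- random_head(4, 2)
    nb <- sample(setdiff(seq_len(n), 1), sample(n - 1, 1))
    w <- attention_weights(X, 1, nb, head)
    expect_true(all(w > 0))
    expect_lt(abs(sum(w) - 1), 1e-6)
  }
})

test_that("neighbour aggregation is the weighted mean through the activation", {
  set.seed(4)
  head <- random_head(4, 3)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  # identical neighbour features: convex combination is the feature itself
  X <- matrix(rep(rnorm(4), each = 3), 3, 4)
  h <- X %*% head$linear_map
  out <- aggregate_neighbors(X, 1, 2:3, c(0.3, 0.7), head)
  expect_equal(out, elu(as.numeric(h[2, ])), tolerance = 1e-12)
  # uniform weights over two neighbours -> activation of the mean
  X2 <- matrix(rnorm(12), 3, 4)
  h2 <- X2 %*% head$linear_map
  out2 <- aggregate_neighbors(X2, 1, 2:3, c(0.5, 0.5), head)
  expect_equal(out2, elu(as.numeric((h2[2, ] + h2[3, ]) / 2)),
               tolerance = 1e-12)
  # dense row-stochastic matrix product oracle
  w <- runif(2); w <- w / sum(w)
  expect_equal(aggregate_neighbors(X2, 1, 2:3, w, head),
               elu(as.numeric(crossprod(w, h2[2:3, ]))), tolerance = 1e-10)
  # isolated node keeps its linearly mapped feature, no activation
  expect_equal(aggregate_neighbors(X2, 2, integer(), numeric(), head),
               as.numeric(h2[2, ]))
})

test_that("multi-head aggregation concatenates per-head outputs", {
  set.seed(5)
  X <- matrix(rnorm(16), 4, 4)
  head <- random_head(4, 3)
  # H = 1 reduces to a single head
  w <- attention_weights(X, 1, 2:4, head)
  expect_equal(multi_head_aggregate(X, 1, 2:4, list(head)),
               aggregate_neighbors(X, 1, 2:4, w, head))
  # equal head parameters tile the single-head output
  out3 <- multi_head_aggregate(X, 1, 2:4, list(head, head, head))
  expect_equal(out3, rep(aggregate_neighbors(X, 1, 2:4, w, head), 3))
})

test_that("gcn aggregation matches closed forms", {
  set.seed(6)
  X <- matrix(rnorm(8), 2, 4)
  W <- matrix(rnorm(12), 4, 3)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  # identity adjacency (after self-loops, nodes remain singletons)
  out <- gcn_aggregate(X, diag(2), W)
  expect_equal(out, elu(X %*% W), tolerance = 1e-12)
  # zero adjacency + self-loops reduces to the identity case
  expect_equal(gcn_aggregate(X, matrix(0, 2, 2), W), out)
  # two connected nodes: hand-computed 1/sqrt(d_i d_j) normalisation, d = 2
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  norm <- matrix(1 / 2, 2, 2)
  expect_equal(gcn_aggregate(X, A, W), elu(norm %*% X %*% W),
               tolerance = 1e-12)
})

test_that("the full attention layer is permutation-equivariant", {
  set.seed(7)
  n <- 6
  X <- matrix(rnorm(n * 4), n, 4)
  A <- matrix(rbinom(n * n, 1, 0.5), n, n)
  A <- pmax(A, t(A)); diag(A) <- 0
  params <- list(W = list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2)),
                 a = list(rnorm(4), rnorm(4)))
  out <- gat_layer(X, A, params)
  perm <- sample(n)
  out_p <- gat_layer(X[perm, ], A[perm, perm], params)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
})

test_that("an entirely edgeless graph leaves the features untouched", {
  set.seed(8)
  X <- matrix(rnorm(12), 3, 4)
  params <- list(W = list(matrix(rnorm(8), 4, 2)), a = list(rnorm(4)))
  expect_identical(gat_layer(X, matrix(0, 3, 3), params), X)
})

test_that("entity-level propagation handles first visits and symmetry", {
  sim <- tiny_sim(12, seed = 3)
  vocab <- build_vocabulary(sim$cohort)
  addi <- suppressWarnings(build_ddi_matrix(sim$ddi_pairs, vocab))
  cfg <- tiny_config()
  params <- csrec:::init_params(vocab, cfg)
  enc <- csrec:::encode_cohort(sim$cohort, vocab)[[1]]

  # t = 1: no medication history -> V_M empty, V_D / V_P still produced
  els <- entity_level_sets(enc, 1L, params, cfg, addi)
  expect_length(els$V_M, 0L)
  expect_equal(length(els$V_D), 1L)
  expect_equal(nrow(els$V_D[[1]]), sum(enc[[1]]$v_d))

  # constant embeddings: all nodes of one type become identical
  params2 <- params
  params2$E_d[] <- 0.1
  params2$E_p[] <- 0.1
  els2 <- entity_level_sets(enc, 1L, params2, cfg, addi)
  vd <- els2$V_D[[1]]
  if (nrow(vd) > 1)
    expect_lt(max(abs(sweep(vd, 2, vd[1, ]))), 1e-12)
})
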