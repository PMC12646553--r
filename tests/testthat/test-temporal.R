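# Independent step-by-step GRU oracle, coded from the gate equations.
oracle_gru <- function(seq_list, P) {
  r <- length(P$bz)
  h <- rep(0, r)
  lapply(seq_list, function(x) {
    x <- as.numeric(x)
    z <- 1 / (1 + exp(-(x %*% P$Wz + h %*% P$Uz + as.numeric(P$bz))))
    rr <- 1 / (1 + exp(-(x %*% P$Wr + h %*% P$Ur + as.numeric(P$br))))
    hh <- tanh(x %*% P$Wh + (rr * h) %*% P$Uh + as.numeric(P$bh))
    h <<- as.numeric((1 - z) * h + z * hh)
    h
  })
}

test_that("pool_visit reduces node matrices to their mean", {
  v <- rnorm(5)
  expect_equal(pool_visit(matrix(v, 1)), v)
  expect_equal(pool_visit(rbind(v, v)), v)
  set.seed(1)
  M <- matrix(rnorm(20), 4, 5)
  expect_equal(pool_visit(M), colMeans(M))
  expect_equal(pool_visit(M, pooling = "sum"), colSums(M))
  expect_equal(pool_visit(matrix(0, 0, 5), width = 5), rep(0, 5))
})

test_that("forward coefficients lie in (-1,1) and follow the recurrence", {
  set.seed(2)
  r <- 4
  P <- random_gru(r)
  W <- matrix(rnorm(r * r, sd = 0.5), r, r); b <- rnorm(r)

  # length-1 sequence: single coefficient from the first state only
  s1 <- list(rnorm(r))
  fc <- forward_coefficients(s1, P, W, b)
  expect_length(fc$alpha, 1L)
  expect_true(all(abs(fc$alpha[[1]]) < 1))

  # zero output map gives zero coefficients (tanh(0) = 0)
  fc0 <- forward_coefficients(s1, P, W * 0, b * 0)
  expect_equal(as.numeric(fc0$alpha[[1]]), rep(0, r))

  # random length-3 sequence vs the independent unroll oracle
  s3 <- lapply(1:3, function(i) rnorm(r))
  fc3 <- forward_coefficients(s3, P, W, b)
  states <- oracle_gru(s3, P)
  for (j in 1:3) {
    expect_equal(as.numeric(fc3$states[[j]]), states[[j]], tolerance = 1e-8)
    expect_equal(as.numeric(fc3$alpha[[j]]),
                 as.numeric(tanh(states[[j]] %*% W + b)), tolerance = 1e-8)
  }
  expect_error(forward_coefficients(list(), P, W, b), "no history")
})

test_that("backward coefficients use tanhshrink over the reversed sequence", {
  # the identity itself
  expect_equal(2 - tanh(2), 2 - tanh(2))
  set.seed(3)
  r <- 3
  P <- random_gru(r)
  W <- matrix(rnorm(r * r, sd = 0.5), r, r); b <- rnorm(r)
  s <- lapply(1:4, function(i) rnorm(r))
  bc <- backward_coefficients(s, P, W, b)
  states_rev <- oracle_gru(rev(s), P)
  for (j in 1:4) {
    # state j (forward order) is state (5-j) of the reversed run
    expect_equal(as.numeric(bc$states[[j]]), states_rev[[5 - j]],
                 tolerance = 1e-8)
    pre <- states_rev[[5 - j]] %*% W + b
    expect_equal(as.numeric(bc$beta[[j]]), as.numeric(pre - tanh(pre)),
                 tolerance = 1e-8)
  }
  # zero weights: tanhshrink(0) = 0
  bc0 <- backward_coefficients(s, P, W * 0, b * 0)
  expect_equal(as.numeric(bc0$beta[[1]]), rep(0, r))
  # tanh fallback
  bc_t <- backward_coefficients(s, P, W, b, shrink = FALSE)
  expect_equal(as.numeric(bc_t$beta[[2]]),
               as.numeric(tanh(bc$states[[2]] %*% W + b)), tolerance = 1e-10)
})

test_that("palindromic sequences make backward states mirror forward states", {
  set.seed(4)
  r <- 3
  P <- random_gru(r)
  W <- matrix(rnorm(r * r, sd = 0.5), r, r); b <- rnorm(r)
  x1 <- rnorm(r); x2 <- rnorm(r)
  pal <- list(x1, x2, x1)   # equals its own reversal
  fc <- forward_coefficients(pal, P, W, b)
  bc <- backward_coefficients(pal, P, W, b)
  # backward states over rev(pal) = forward states over pal, reversed in index
  for (j in 1:3)
    expect_equal(as.numeric(bc$states[[j]]), as.numeric(fc$states[[4 - j]]),
                 tolerance = 1e-10)
  # beta differs from alpha only through the output nonlinearity's argument
  pre3 <- as.numeric(fc$states[[3]] %*% W + b)
  expect_equal(as.numeric(bc$beta[[1]]), pre3 - tanh(pre3), tolerance = 1e-10)
})

test_that("aggregate_selected is the elementwise triple-product sum", {
  set.seed(5)
  r <- 4
  s <- lapply(1:4, function(i) rnorm(r))
  alpha <- lapply(1:4, function(i) runif(r, -1, 1))
  beta <- lapply(1:4, function(i) rnorm(r))
  # direct loop oracle
  want <- rep(0, r)
  for (j in 1:4) want <- want + alpha[[j]] * beta[[j]] * s[[j]]
  expect_equal(aggregate_selected(s, alpha, beta), want, tolerance = 1e-10)

  # single-term sum
  expect_equal(aggregate_selected(s[1], alpha[1], beta[1]),
               alpha[[1]] * beta[[1]] * s[[1]])
  # annihilation by zero alpha
  zero <- lapply(1:4, function(i) rep(0, r))
  expect_equal(aggregate_selected(s, zero, beta), rep(0, r))
  expect_error(aggregate_selected(s, alpha[1:3], beta), "mismatch")

  # linear in the sequence for fixed coefficients
  s2 <- lapply(s, function(x) 3 * x)
  expect_equal(aggregate_selected(s2, alpha, beta),
               3 * aggregate_selected(s, alpha, beta), tolerance = 1e-10)
})

test_that("tanhshrink shrinks strictly and alpha stays inside (-1,1)", {
  x <- seq(-5, 5, by = 0.25); x <- x[x != 0]
  expect_true(all(abs(x - tanh(x)) < abs(x)))
  set.seed(6)
  r <- 4
  P <- random_gru(r)
  W <- matrix(rnorm(r * r), r, r); b <- rnorm(r)
  s <- lapply(1:5, function(i) rnorm(r, sd = 3))
  fc <- forward_coefficients(s, P, W, b)
  expect_true(all(abs(unlist(fc$alpha)) < 1))
})

test_that("build_patient_rep composes pooling, selection and aggregation", {
  set.seed(7)
  cfg <- tiny_config()
  r <- cfg$width
  sim <- tiny_sim(8, seed = 2)
  vocab <- build_vocabulary(sim$cohort)
  params <- csrec:::init_params(vocab, cfg)
  gp <- csrec:::grouped_params(params)

  # t = 1 patient: m_prev is exactly zero, d_t/p_t single-term aggregates
  V_D <- list(matrix(rnorm(3 * r), 3, r))
  V_P <- list(matrix(rnorm(2 * r), 2, r))
  rep1 <- build_patient_rep(V_D, V_P, list(), gp, cfg)
  expect_equal(rep1$m_prev, rep(0, r))
  sd1 <- list(colMeans(V_D[[1]]))
  fw <- forward_coefficients(sd1, gp$gru_f_d, gp$W_alpha_d, gp$b_alpha_d)
  bw <- backward_coefficients(sd1, gp$gru_b_d, gp$W_beta_d, gp$b_beta_d)
  expect_equal(rep1$d_t, aggregate_selected(sd1, fw$alpha, bw$beta),
               tolerance = 1e-10)

  # t = 3 composition oracle, all three entities
  V_D <- lapply(1:3, function(i) matrix(rnorm(2 * r), 2, r))
  V_P <- lapply(1:3, function(i) matrix(rnorm(2 * r), 2, r))
  V_M <- lapply(1:2, function(i) matrix(rnorm(2 * r), 2, r))
  rep3 <- build_patient_rep(V_D, V_P, V_M, gp, cfg)
  for (ent in list(list(V_D, "d", "d_t"), list(V_P, "p", "p_t"),
                   list(V_M, "m", "m_prev"))) {
    sq <- lapply(ent[[1]], colMeans)
    fw <- forward_coefficients(sq, gp[[paste0("gru_f_", ent[[2]])]],
                               gp[[paste0("W_alpha_", ent[[2]])]],
                               gp[[paste0("b_alpha_", ent[[2]])]])
    bw <- backward_coefficients(sq, gp[[paste0("gru_b_", ent[[2]])]],
                                gp[[paste0("W_beta_", ent[[2]])]],
                                gp[[paste0("b_beta_", ent[[2]])]])
    expect_equal(rep3[[ent[[3]]]], aggregate_selected(sq, fw$alpha, bw$beta),
                 tolerance = 1e-10)
  }

  # nonlinearity probe: doubling the inputs does NOT double the output
  V_D2 <- lapply(V_D, function(m) 2 * m)
  rep_d2 <- build_patient_rep(V_D2, V_P, V_M, gp, cfg)
  expect_gt(max(abs(rep_d2$d_t - 2 * rep3$d_t)), 1e-6)
})

test_that("selection is deterministic for fixed parameters", {
  set.seed(8)
  r <- 4
  P <- random_gru(r)
  W <- matrix(rnorm(r * r), r, r); b <- rnorm(r)
  s <- lapply(1:3, function(i) rnorm(r))
  a1 <- forward_coefficients(s, P, W, b)
  a2 <- forward_coefficients(s, P, W, b)
  expect_identical(a1, a2)
})
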