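# Contrastive losses against brute-force oracles; training loop contracts.

test_that("pairwise squared distances match hand values and a loop oracle", {
  X <- rbind(c(0, 0), c(3, 4), c(3, 4))
  D2 <- pairwise_sq_euclidean(X)
  expect_equal(D2[1, 2], 25)
  expect_equal(D2[2, 3], 0)
  expect_true(isSymmetric(D2))
  expect_equal(diag(D2), rep(0, 3))

  set.seed(3)
  Y <- matrix(rnorm(24), 6, 4)
  D2y <- pairwise_sq_euclidean(Y)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D2y[i, j], sum((Y[i, ] - Y[j, ])^2), tolerance = 1e-12)
  }
})

test_that("NT-Xent closed forms hold", {
  # M = 1: the denominator's single term equals the numerator
  W <- rbind(c(0, 0), c(1, 1))
  D2 <- pairwise_sq_euclidean(W)
  expect_equal(nt_xent_euclid(1, 2, D2, tau = 5), 0)

  # M = 2 with all pairwise distances equal: uniform softmax over 3 terms
  # (vertices of a regular tetrahedron)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  D2t <- pairwise_sq_euclidean(tet)
  expect_equal(nt_xent_euclid(1, 3, D2t, tau = 7), log(3), tolerance = 1e-12)
})

test_that("NT-Xent and batch objective match brute-force oracles", {
  set.seed(17)
  for (rep in 1:5) {
    M <- sample(2:4, 1)
    p <- sample(2:5, 1)
    tau <- stats::runif(1, 0.5, 50)
    Z <- matrix(rnorm(M * p), M, p)
    Zhat <- matrix(rnorm(M * p), M, p)
    W <- rbind(Z, Zhat)
    D2 <- pairwise_sq_euclidean(W)
    for (i in seq_len(2 * M)) {
      j <- if (i <= M) M + i else i - M
      expect_equal(nt_xent_euclid(i, j, D2, tau),
                   oracle_nt_xent(i, j, W, tau), tolerance = 1e-6)
    }
    expect_equal(batch_objective(list(Z = Z, Zhat = Zhat), tau),
                 oracle_batch_J(Z, Zhat, tau), tolerance = 1e-6)
  }
})

test_that("J decreases when positive pairs shrink at fixed negatives", {
  set.seed(23)
  M <- 4; p <- 3
  Z <- matrix(rnorm(M * p), M, p)
  noise <- matrix(rnorm(M * p), M, p)
  J_far <- batch_objective(list(Z = Z, Zhat = Z + 1.0 * noise), tau = 10)
  J_near <- batch_objective(list(Z = Z, Zhat = Z + 0.1 * noise), tau = 10)
  expect_lt(J_near, J_far)
})

test_that("J is invariant to record order within a minibatch", {
  set.seed(29)
  M <- 5; p <- 4
  Z <- matrix(rnorm(M * p), M, p)
  Zhat <- matrix(rnorm(M * p), M, p)
  perm <- sample(M)
  expect_equal(batch_objective(list(Z = Z, Zhat = Zhat), 3),
               batch_objective(list(Z = Z[perm, ], Zhat = Zhat[perm, ]), 3),
               tolerance = 1e-10)
})

test_that("training reduces the validation objective on fixtures", {
  ts <- trained_small()
  hist <- ts$history
  expect_lte(nrow(hist), 6L)
  expect_lt(hist$val_J[nrow(hist)], hist$val_J[1])
  # contrastive goal: positive pairs closer than cross pairs on held-out data
  emb <- embed_records(ts$dat$val, ts$model)
  D <- pairwise_sq_euclidean(rbind(emb$Z, emb$Zhat))
  n <- length(ts$dat$val)
  pos <- mean(sqrt(D[cbind(seq_len(n), n + seq_len(n))]))
  cross <- sqrt(D[seq_len(n), n + seq_len(n), drop = FALSE])
  cross_mean <- mean(cross[row(cross) != col(cross)])
  expect_lt(pos, cross_mean)
})

test_that("early stopping and clamping contracts hold", {
  dat <- small_dataset()[1:40]
  # stopping contract: training ends at max_epochs or exactly patience
  # epochs after the best validation objective, whichever comes first
  fit <- train(dat[1:30], dat[31:40],
               train_config(M = 16L, learning_rate = 1e-3, max_epochs = 40L,
                            patience = 2L, seed = 4L),
               encoder = encoder_config(gnn_layers = 1L, gnn_hidden = 8L,
                                        projection_hidden = 8L, p = 8L,
                                        seed = 4L))
  n_ep <- nrow(fit$history)
  best <- which.min(fit$history$val_J)
  expect_true(n_ep == 40L || n_ep == best + 2L)
  # the returned checkpoint is the best-validation one
  expect_equal(min(fit$history$val_J), fit$history$val_J[best])

  expect_warning(
    train(dat[1:10], dat[31:35],
          train_config(M = 64L, max_epochs = 1L, seed = 1L),
          encoder = encoder_config(gnn_layers = 1L, gnn_hidden = 4L,
                                   projection_hidden = 4L, p = 4L, seed = 1L)),
    "clamped")
  expect_error(train(list(), dat[1:5], train_config()), "empty")
})
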