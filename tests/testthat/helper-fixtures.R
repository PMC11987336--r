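# Shared fixtures, memoized per test run.  Everything is generated in code;
# no data files.

.fx_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx_env[[key]])) .fx_env[[key]] <- force(expr)
  .fx_env[[key]]
}

# four hand-written records covering reagents/no-reagents, halogens, rings
tiny_records <- function() memo("tiny", list(
  reaction_record("t1", "CCOC(C)=O", c("CCO", "CC(=O)O"), c("O"),
                  list(yield = 85, temperature = 60)),
  reaction_record("t2", "CCNC(C)=O", c("CCN", "CC(=O)O"), character(0),
                  list(yield = 75)),
  reaction_record("t3", "c1ccccc1CO", c("c1ccccc1CBr"), c("O", "[Na+]"),
                  list(yield = 91, temperature = 100)),
  reaction_record("t4", "CCCOCC", c("CCCBr", "OCC"), character(0),
                  list(temperature = 40))))

small_dataset <- function() memo("small300",
  generate_reactions(fixture_config(n_reactions = 300, seed = 21)))

tiny_model <- function() memo("tiny_model",
  init_model(encoder_config(gnn_layers = 2L, gnn_hidden = 16L,
                            projection_hidden = 16L, p = 8L, seed = 42L)))

# a lightly trained small model + index shared by search/feedback tests
trained_small <- function() memo("trained_small", {
  dat <- generate_fixture_datasets(n_train = 160, n_val = 40, n_test = 40,
                                   seed = 31)
  fit <- train(dat$train, dat$val,
               train_config(M = 64L, max_epochs = 6L, seed = 2L),
               encoder = encoder_config(gnn_layers = 2L, gnn_hidden = 32L,
                                        projection_hidden = 32L, p = 32L,
                                        seed = 2L))
  emb <- embed_records(dat$train, fit$model)
  basis <- fit_basis(stack_embeddings(emb), evr_threshold = 0.95)
  db <- build_index(dat$train, fit$model, basis)
  list(dat = dat, model = fit$model, basis = basis, db = db,
       history = fit$history)
})

# independent brute-force oracles ------------------------------------------

# NT-Xent loss by direct summation of the definition
oracle_nt_xent <- function(i, j, W, tau) {
  n <- nrow(W)
  d2 <- function(a, b) sum((W[a, ] - W[b, ])^2)
  num <- exp(-d2(i, j) / tau)
  den <- 0
  for (k in seq_len(n)) if (k != i) den <- den + exp(-d2(i, k) / tau)
  -log(num / den)
}

oracle_batch_J <- function(Z, Zhat, tau) {
  M <- nrow(Z)
  W <- rbind(Z, Zhat)
  s <- 0
  for (i in seq_len(M)) {
    s <- s + oracle_nt_xent(i, M + i, W, tau) +
      oracle_nt_xent(M + i, i, W, tau)
  }
  s / (2 * M)
}

# margin ranking loss by explicit pair loop
oracle_margin <- function(x, H, r, delta) {
  K <- nrow(H)
  d <- apply(H, 1, function(h) sqrt(sum((h - x)^2)))
  s <- 0
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      s <- s + max(0, (r[i] - r[j]) * (d[i] - d[j]) + abs(r[i] - r[j]) * delta)
    }
  }
  2 / (K * (K - 1)) * s
}
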