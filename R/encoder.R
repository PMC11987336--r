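# Representation model: a shared GIN encoder f (edge-feature variant, sum
# pooling) and three bias-free projection heads g_P, g_R, g_A.
#
# The target vector of a record is z = g_P(f(G_P)); the prediction vector is
# zhat = g_R(f(G_R)) + g_A(f(G_A)), where an absent reagent graph contributes
# exactly a zero vector.  Both heads being bias-free makes g(0) = 0, so the
# skip-the-branch and encode-the-empty-graph paths agree bit-exactly.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

#' Encoder configuration
#'
#' @param gnn_layers number of GIN layers (default 5).
#' @param gnn_hidden GIN layer width (default 300).
#' @param projection_hidden projection-head hidden width (default 512).
#' @param p output dimensionality of target/prediction vectors (default 512).
#' @param seed initialization seed.
#' @return list of class `rxn_encoder_config`.
#' @export
encoder_config <- function(gnn_layers = 5L, gnn_hidden = 300L,
                           projection_hidden = 512L, p = 512L, seed = 1L) {
  stopifnot(gnn_layers >= 1L, gnn_hidden >= 1L, projection_hidden >= 1L,
            p >= 1L)
  structure(list(gnn_layers = as.integer(gnn_layers),
                 gnn_hidden = as.integer(gnn_hidden),
                 projection_hidden = as.integer(projection_hidden),
                 p = as.integer(p), readout = "sum", seed = as.integer(seed)),
            class = "rxn_encoder_config")
}

#' Initialize the representation model
#'
#' Seed-deterministic Glorot initialization of the GIN encoder (per-layer
#' MLPs with batch normalization) and the three projection heads (two
#' bias-free affine layers with ReLU after the first).
#'
#' @param config an [encoder_config()].
#' @return model state of class `rxn_model` (config, feature manifest,
#'   `params`, batch-norm `buffers`).
#' @export
init_model <- function(config = encoder_config()) {
  mf <- feature_manifest()
  h <- config$gnn_hidden
  set.seed(config$seed)
  params <- list(W_node = .glorot(mf$n_node_features, h))
  buffers <- list()
  for (l in seq_len(config$gnn_layers)) {
    params[[paste0("We_", l)]] <- .glorot(mf$n_edge_features, h)
    params[[paste0("eps_", l)]] <- 0
    params[[paste0("W1_", l)]] <- .glorot(h, 2L * h)
    params[[paste0("b1_", l)]] <- numeric(2L * h)
    params[[paste0("W2_", l)]] <- .glorot(2L * h, h)
    params[[paste0("b2_", l)]] <- numeric(h)
    params[[paste0("gamma_", l)]] <- rep(1, h)
    params[[paste0("beta_", l)]] <- numeric(h)
    buffers[[paste0("rm_", l)]] <- numeric(h)
    buffers[[paste0("rv_", l)]] <- rep(1, h)
  }
  for (role in c("P", "R", "A")) {
    params[[paste0("Wh1_", role)]] <- .glorot(h, config$projection_hidden)
    params[[paste0("Wh2_", role)]] <- .glorot(config$projection_hidden,
                                              config$p)
  }
  structure(list(config = config, manifest = mf, params = params,
                 buffers = buffers),
            class = "rxn_model")
}

#' Assemble a list of molecule graphs into one batched graph
#'
#' Graphs are concatenated into a single disconnected graph; zero-node graphs
#' occupy an all-zero pooling row so their readout is the empty-sum zero
#' vector.
#'
#' @param graphs list of `rxn_molgraph`.
#' @return batch structure (node matrix, doubled directed edges, sparse
#'   neighbor/incidence/pooling operators).
#' @keywords internal
build_graph_batch <- function(graphs) {
  g <- length(graphs)
  ns <- vapply(graphs, function(x) x$n_nodes, 0L)
  n <- sum(ns)
  offs <- cumsum(c(0L, ns))[seq_len(g)]
  Fn <- feature_manifest()$n_node_features
  Fe <- feature_manifest()$n_edge_features
  X <- matrix(0, n, Fn)
  src <- integer(0); dst <- integer(0)
  E2 <- list()
  gid <- integer(n)
  for (k in seq_len(g)) {
    gr <- graphs[[k]]
    if (gr$n_nodes > 0L) {
      rows <- offs[k] + seq_len(gr$n_nodes)
      X[rows, ] <- gr$node_features
      gid[rows] <- k
    }
    if (nrow(gr$edges) > 0L) {
      a <- gr$edges[, 1] + offs[k]; b <- gr$edges[, 2] + offs[k]
      src <- c(src, a, b); dst <- c(dst, b, a)
      E2[[length(E2) + 1L]] <- rbind(gr$edge_features, gr$edge_features)
    }
  }
  m2 <- length(src)
  E2 <- if (length(E2)) do.call(rbind, E2) else matrix(0, 0L, Fe)
  A <- Matrix::sparseMatrix(i = dst, j = src, x = 1, dims = c(n, n))
  Sdst <- Matrix::sparseMatrix(i = dst, j = seq_len(m2), x = 1,
                               dims = c(n, m2))
  Pool <- Matrix::sparseMatrix(i = gid[gid > 0L], j = which(gid > 0L), x = 1,
                               dims = c(g, n))
  list(X = X, E2 = E2, A = A, Sdst = Sdst, Pool = Pool, n = n, g = g)
}

.bcast <- function(v, nrow) matrix(v, nrow, length(v), byrow = TRUE)

# GIN forward over a batched graph.  Returns graph-level readouts (g x h),
# a cache for backprop, and (train mode) updated batch-norm buffers.
encode_batch_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config
  P <- model$params
  buf <- model$buffers
  g <- batch$g; n <- batch$n
  if (n == 0L) {
    return(list(G = matrix(0, g, cfg$gnn_hidden),
                cache = list(empty = TRUE, batch = batch), buffers = buf))
  }
  H <- batch$X %*% P$W_node
  layers <- vector("list", cfg$gnn_layers)
  for (l in seq_len(cfg$gnn_layers)) {
    eps <- P[[paste0("eps_", l)]]
    EW <- if (nrow(batch$E2) > 0L) batch$E2 %*% P[[paste0("We_", l)]]
          else matrix(0, 0L, cfg$gnn_hidden)
    nb <- as.matrix(batch$A %*% H)
    em <- if (nrow(EW) > 0L) as.matrix(batch$Sdst %*% EW)
          else matrix(0, n, cfg$gnn_hidden)
    agg <- (1 + eps) * H + nb + em
    Z1 <- agg %*% P[[paste0("W1_", l)]] + .bcast(P[[paste0("b1_", l)]], n)
    R1 <- pmax(Z1, 0)
    Z2 <- R1 %*% P[[paste0("W2_", l)]] + .bcast(P[[paste0("b2_", l)]], n)
    if (train) {
      mu <- colMeans(Z2)
      va <- colMeans(Z2 * Z2) - mu * mu
      va <- pmax(va, 0)
      xhat <- (Z2 - .bcast(mu, n)) / .bcast(sqrt(va + .BN_EPS), n)
      unb <- if (n > 1L) va * n / (n - 1L) else va
      buf[[paste0("rm_", l)]] <- (1 - .BN_MOMENTUM) * buf[[paste0("rm_", l)]] +
        .BN_MOMENTUM * mu
      buf[[paste0("rv_", l)]] <- (1 - .BN_MOMENTUM) * buf[[paste0("rv_", l)]] +
        .BN_MOMENTUM * unb
    } else {
      mu <- model$buffers[[paste0("rm_", l)]]
      va <- model$buffers[[paste0("rv_", l)]]
      xhat <- (Z2 - .bcast(mu, n)) / .bcast(sqrt(va + .BN_EPS), n)
    }
    BNout <- xhat * .bcast(P[[paste0("gamma_", l)]], n) +
      .bcast(P[[paste0("beta_", l)]], n)
    Hnext <- if (l < cfg$gnn_layers) pmax(BNout, 0) else BNout
    layers[[l]] <- list(H_in = H, agg = agg, Z1 = Z1, R1 = R1, xhat = xhat,
                        mu = mu, va = va, BNout = BNout, train = train)
    H <- Hnext
  }
  G <- as.matrix(batch$Pool %*% H)
  list(G = G,
       cache = list(empty = FALSE, batch = batch, layers = layers,
                    H_last = H),
       buffers = buf)
}

# reverse-mode gradients of encode_batch_forward; dG is g x h
encode_batch_backward <- function(model, cache, dG) {
  cfg <- model$config
  P <- model$params
  grads <- list()
  if (isTRUE(cache$empty)) return(grads)
  batch <- cache$batch
  n <- batch$n
  dH <- as.matrix(Matrix::crossprod(batch$Pool, dG))
  for (l in rev(seq_len(cfg$gnn_layers))) {
    lc <- cache$layers[[l]]
    dBN <- if (l < cfg$gnn_layers) dH * (lc$BNout > 0) else dH
    gam <- P[[paste0("gamma_", l)]]
    grads[[paste0("gamma_", l)]] <- colSums(dBN * lc$xhat)
    grads[[paste0("beta_", l)]] <- colSums(dBN)
    dxhat <- dBN * .bcast(gam, n)
    std <- sqrt(lc$va + .BN_EPS)
    if (isTRUE(lc$train)) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * lc$xhat)
      dZ2 <- (dxhat - .bcast(s1 / n, n) - lc$xhat * .bcast(s2 / n, n)) /
        .bcast(std, n)
    } else {
      dZ2 <- dxhat / .bcast(std, n)
    }
    grads[[paste0("W2_", l)]] <- crossprod(lc$R1, dZ2)
    grads[[paste0("b2_", l)]] <- colSums(dZ2)
    dR1 <- tcrossprod(dZ2, P[[paste0("W2_", l)]])
    dZ1 <- dR1 * (lc$Z1 > 0)
    grads[[paste0("W1_", l)]] <- crossprod(lc$agg, dZ1)
    grads[[paste0("b1_", l)]] <- colSums(dZ1)
    dagg <- tcrossprod(dZ1, P[[paste0("W1_", l)]])
    grads[[paste0("eps_", l)]] <- sum(dagg * lc$H_in)
    if (nrow(batch$E2) > 0L) {
      dEW <- as.matrix(Matrix::crossprod(batch$Sdst, dagg))
      grads[[paste0("We_", l)]] <- crossprod(batch$E2, dEW)
    } else {
      grads[[paste0("We_", l)]] <- matrix(0, nrow(P[[paste0("We_", l)]]),
                                          ncol(P[[paste0("We_", l)]]))
    }
    eps <- P[[paste0("eps_", l)]]
    dH <- (1 + eps) * dagg + as.matrix(Matrix::crossprod(batch$A, dagg))
  }
  grads$W_node <- crossprod(batch$X, dH)
  grads
}

# projection head forward/backward (two bias-free affine layers, ReLU between)
head_forward <- function(model, role, G) {
  W1 <- model$params[[paste0("Wh1_", role)]]
  W2 <- model$params[[paste0("Wh2_", role)]]
  A1 <- G %*% W1
  R <- pmax(A1, 0)
  list(Z = R %*% W2, cache = list(G = G, A1 = A1, R = R, role = role))
}

head_backward <- function(model, cache, dZ) {
  role <- cache$role
  W1 <- model$params[[paste0("Wh1_", role)]]
  W2 <- model$params[[paste0("Wh2_", role)]]
  grads <- list()
  grads[[paste0("Wh2_", role)]] <- crossprod(cache$R, dZ)
  dR <- tcrossprod(dZ, W2)
  dA1 <- dR * (cache$A1 > 0)
  grads[[paste0("Wh1_", role)]] <- crossprod(cache$G, dA1)
  list(grads = grads, dG = tcrossprod(dA1, W1))
}

#' Encode a molecule graph to its pooled GNN representation
#'
#' Sum-pooled node representations; a 0-node graph maps to the zero vector
#' (empty sum).  Uses evaluation-mode batch statistics.
#'
#' @param graph an `rxn_molgraph`.
#' @param model an `rxn_model`.
#' @return numeric vector of length `gnn_hidden`.
#' @export
encode <- function(graph, model) {
  stopifnot(inherits(graph, "rxn_molgraph"), inherits(model, "rxn_model"))
  if (ncol(graph$node_features) != model$manifest$n_node_features) {
    stop("feature dimensionality mismatch with the model manifest")
  }
  out <- encode_batch_forward(model, build_graph_batch(list(graph)),
                              train = FALSE)
  as.numeric(out$G[1, ])
}

# Forward pass producing target/prediction vectors for a list of featurized
# tuples.  Returns Z, Zhat (N x p), caches for backprop, and (train) updated
# batch-norm buffers (committed in order product, reactant, reagent).
model_forward_tuples <- function(model, tuples, train = FALSE) {
  N <- length(tuples)
  pg <- lapply(tuples, function(t) t$product_graph)
  rg <- lapply(tuples, function(t) t$reactant_graph)
  has_a <- which(vapply(tuples, function(t) !is.null(t$reagent_graph), TRUE))
  ag <- lapply(tuples[has_a], function(t) t$reagent_graph)

  fp <- encode_batch_forward(model, build_graph_batch(pg), train = train)
  model$buffers <- fp$buffers
  fr <- encode_batch_forward(model, build_graph_batch(rg), train = train)
  model$buffers <- fr$buffers
  fa <- NULL
  if (length(has_a)) {
    fa <- encode_batch_forward(model, build_graph_batch(ag), train = train)
    model$buffers <- fa$buffers
  }
  hp <- head_forward(model, "P", fp$G)
  hr <- head_forward(model, "R", fr$G)
  Zhat <- hr$Z
  ha <- NULL
  if (length(has_a)) {
    ha <- head_forward(model, "A", fa$G)
    Zhat[has_a, ] <- Zhat[has_a, , drop = FALSE] + ha$Z
  }
  list(Z = hp$Z, Zhat = Zhat, buffers = model$buffers,
       cache = list(fp = fp$cache, fr = fr$cache, fa = if (!is.null(fa)) fa$cache,
                    hp = hp$cache, hr = hr$cache, ha = if (!is.null(ha)) ha$cache,
                    has_a = has_a))
}

model_backward_tuples <- function(model, cache, dZ, dZhat) {
  grads <- list()
  bp <- head_backward(model, cache$hp, dZ)
  grads <- .acc_grads(grads, bp$grads)
  grads <- .acc_grads(grads, encode_batch_backward(model, cache$fp, bp$dG))
  br <- head_backward(model, cache$hr, dZhat)
  grads <- .acc_grads(grads, br$grads)
  grads <- .acc_grads(grads, encode_batch_backward(model, cache$fr, br$dG))
  if (length(cache$has_a)) {
    ba <- head_backward(model, cache$ha,
                        dZhat[cache$has_a, , drop = FALSE])
    grads <- .acc_grads(grads, ba$grads)
    grads <- .acc_grads(grads, encode_batch_backward(model, cache$fa, ba$dG))
  }
  # parameters untouched by this batch get zero gradients
  for (nm in names(model$params)) {
    if (is.null(grads[[nm]])) {
      p <- model$params[[nm]]
      grads[[nm]] <- if (is.null(dim(p))) numeric(length(p))
                     else matrix(0, nrow(p), ncol(p))
    }
  }
  grads
}

#' Embed one reaction record into its target/prediction vector pair
#'
#' z comes from the product path; zhat is the sum of the reactant-head and
#' reagent-head outputs, where an absent reagent graph contributes exactly
#' zero.
#'
#' @param tuple an `rxn_graph_tuple` (or an `rxn_record`, featurized on the
#'   fly).
#' @param model an `rxn_model`.
#' @return list of class `rxn_embedding_pair` with `z` and `z_hat` (length p).
#' @export
embed_record <- function(tuple, model) {
  if (inherits(tuple, "rxn_record")) tuple <- featurize_record(tuple)
  out <- model_forward_tuples(model, list(tuple), train = FALSE)
  structure(list(z = as.numeric(out$Z[1, ]), z_hat = as.numeric(out$Zhat[1, ])),
            class = "rxn_embedding_pair")
}

#' Embed many records as target/prediction matrices
#'
#' @param records list of `rxn_record` or `rxn_graph_tuple`.
#' @param model an `rxn_model`.
#' @param chunk number of records per forward pass.
#' @return list with matrices `Z` and `Zhat`, each N x p.
#' @export
embed_records <- function(records, model, chunk = 256L) {
  tuples <- lapply(records, function(r) {
    if (inherits(r, "rxn_record")) featurize_record(r) else r
  })
  N <- length(tuples)
  p <- model$config$p
  Z <- matrix(0, N, p); Zhat <- matrix(0, N, p)
  idx <- split(seq_len(N), ceiling(seq_len(N) / chunk))
  for (ii in idx) {
    out <- model_forward_tuples(model, tuples[ii], train = FALSE)
    Z[ii, ] <- out$Z
    Zhat[ii, ] <- out$Zhat
  }
  list(Z = Z, Zhat = Zhat)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles parameters, batch-norm buffers, the encoder config
#' and the feature-vocabulary manifest so embeddings are reproducible.
#'
#' @param model an `rxn_model`.
#' @param path file path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the `rxn_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "rxn_model"))
  m
}
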