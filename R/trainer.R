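# Contrastive representation learning with the Euclidean NT-Xent objective.
#
# A minibatch of M records yields 2M stacked vectors
# z_1..z_M, zhat_1..zhat_M (zhat_i is "z_{M+i}").  The per-pair loss is
#   l_c(i,j) = -log exp(-d2(i,j)/tau) / sum_{k != i} exp(-d2(i,k)/tau),
# and the batch objective J averages l_c(i, M+i) + l_c(M+i, i) over records:
# M positive pairs, 2M(M-1) negative pairs.  Log-sum-exp stabilization is
# applied before exponentiation.

#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam, learning rate 1e-4,
#' minibatch 4096, weight decay 1e-8, temperature 100, at most 200 epochs
#' with patience 20 on the validation objective.
#'
#' @param tau temperature (> 0).
#' @param M minibatch size (>= 2; clamped to the dataset size with a warning).
#' @param learning_rate,weight_decay Adam hyperparameters.
#' @param max_epochs,patience stopping rule.
#' @param seed shuffling/initialization seed.
#' @return list of class `rxn_train_config`.
#' @export
train_config <- function(tau = 100, M = 4096L, learning_rate = 1e-4,
                         weight_decay = 1e-8, max_epochs = 200L,
                         patience = 20L, seed = 1L) {
  stopifnot(tau > 0, M >= 2L, patience >= 1L, max_epochs >= 1L)
  structure(list(tau = tau, M = as.integer(M), learning_rate = learning_rate,
                 weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "rxn_train_config")
}

#' Pairwise squared Euclidean distances
#' @param vectors numeric matrix (rows are vectors).
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
pairwise_sq_euclidean <- function(vectors) {
  stopifnot(all(is.finite(vectors)))
  rs <- rowSums(vectors * vectors)
  D2 <- outer(rs, rs, "+") - 2 * tcrossprod(vectors)
  D2 <- pmax(D2, 0)
  diag(D2) <- 0
  D2
}

#' Euclidean NT-Xent loss for one ordered pair
#'
#' The denominator excludes only k == i (it includes k == j).
#'
#' @param i,j 1-based indices into the 2M stacked vectors, i != j.
#' @param D2 2M x 2M squared-distance matrix.
#' @param tau temperature.
#' @return non-negative loss scalar.
#' @export
nt_xent_euclid <- function(i, j, D2, tau) {
  stopifnot(i != j, tau > 0)
  a <- -D2[i, ] / tau
  a[i] <- -Inf
  m <- max(a)
  lse <- m + log(sum(exp(a - m)))
  -a[j] + lse
}

#' Contrastive batch objective J
#'
#' @param pairs list of `rxn_embedding_pair`, or a list with matrices
#'   `Z` and `Zhat` (M x p each).
#' @param tau temperature.
#' @return scalar J (0 when M = 1).
#' @export
batch_objective <- function(pairs, tau) {
  zz <- .pairs_to_matrices(pairs)
  .nt_xent_batch(zz$Z, zz$Zhat, tau, want_grad = FALSE)$J
}

.pairs_to_matrices <- function(pairs) {
  if (is.list(pairs) && !is.null(pairs$Z)) {
    return(list(Z = pairs$Z, Zhat = pairs$Zhat))
  }
  Z <- do.call(rbind, lapply(pairs, function(p) p$z))
  Zhat <- do.call(rbind, lapply(pairs, function(p) p$z_hat))
  list(Z = Z, Zhat = Zhat)
}

# J and (optionally) gradients with respect to Z and Zhat
.nt_xent_batch <- function(Z, Zhat, tau, want_grad = TRUE) {
  M <- nrow(Z)
  W <- rbind(Z, Zhat)
  n2 <- 2L * M
  D2 <- pairwise_sq_euclidean(W)
  A <- -D2 / tau
  diag(A) <- -Inf
  mx <- apply(A, 1, max)
  Pm <- exp(A - mx)              # row-wise shifted
  rs <- rowSums(Pm)
  Pm <- Pm / rs                  # row-softmax over k != i
  partner <- c((M + 1L):n2, 1L:M)
  losses <- vapply(seq_len(n2), function(i) {
    -A[i, partner[i]] + (mx[i] + log(rs[i]))
  }, 0)
  J <- sum(losses) / n2
  if (!want_grad) return(list(J = J))
  Cmat <- -Pm / (tau * n2)
  Cmat[cbind(seq_len(n2), partner)] <-
    Cmat[cbind(seq_len(n2), partner)] + 1 / (tau * n2)
  S <- Cmat + t(Cmat)
  gradW <- 2 * (rowSums(S) * W - S %*% W)
  list(J = J, dZ = gradW[seq_len(M), , drop = FALSE],
       dZhat = gradW[(M + 1L):n2, , drop = FALSE])
}

# J over a record set in evaluation mode, averaged over batches of size
# at most M (per-batch objectives weighted by batch size)
validation_objective <- function(model, tuples, tau, M) {
  N <- length(tuples)
  idx <- split(seq_len(N), ceiling(seq_len(N) / M))
  tot <- 0; wt <- 0
  for (ii in idx) {
    if (length(ii) < 2L) next
    out <- model_forward_tuples(model, tuples[ii], train = FALSE)
    tot <- tot + batch_objective(list(Z = out$Z, Zhat = out$Zhat), tau) *
      length(ii)
    wt <- wt + length(ii)
  }
  if (wt == 0) return(NA_real_)
  tot / wt
}

#' Train the representation model
#'
#' Adam on the Euclidean NT-Xent objective; per-epoch training/validation
#' objectives are logged; the checkpoint with the best validation objective is
#' returned.  Training stops at `max_epochs` or after `patience` epochs
#' without validation improvement.  Fully seed-deterministic in
#' single-threaded execution.
#'
#' @param train_records,val_records lists of `rxn_record` (non-empty).
#' @param config an [train_config()].
#' @param model optional pre-initialized `rxn_model` (default: a fresh
#'   [init_model()] with [encoder_config()] defaults seeded from `config`).
#' @param encoder optional [encoder_config()] used when `model` is NULL.
#' @param verbose print per-epoch objectives.
#' @return list with `model` (best checkpoint) and `history` (data.frame of
#'   epoch, train_J, val_J).
#' @export
train <- function(train_records, val_records, config = train_config(),
                  model = NULL, encoder = NULL, verbose = FALSE) {
  if (length(train_records) == 0L) stop("empty training dataset")
  if (length(val_records) == 0L) stop("empty validation dataset")
  if (is.null(model)) {
    if (is.null(encoder)) encoder <- encoder_config(seed = config$seed)
    model <- init_model(encoder)
  }
  M <- config$M
  if (M > length(train_records)) {
    warning("minibatch size ", M, " clamped to dataset size ",
            length(train_records))
    M <- length(train_records)
  }
  tuples <- lapply(train_records, featurize_record)
  vtuples <- lapply(val_records, featurize_record)

  opt <- adam_init(model$params, lr = config$learning_rate,
                   weight_decay = config$weight_decay)
  set.seed(config$seed)
  best_val <- Inf; best_model <- model; stall <- 0L
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  N <- length(tuples)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / M))
    ep_J <- 0; ep_w <- 0
    for (bi in batches) {
      if (length(bi) < 2L) next   # a lone record has no negatives
      fw <- model_forward_tuples(model, tuples[bi], train = TRUE)
      model$buffers <- fw$buffers
      ls <- .nt_xent_batch(fw$Z, fw$Zhat, config$tau)
      grads <- model_backward_tuples(model, fw$cache, ls$dZ, ls$dZhat)
      st <- optimizer_step(opt, model$params, grads)
      model$params <- st$params; opt <- st$opt
      ep_J <- ep_J + ls$J * length(bi); ep_w <- ep_w + length(bi)
    }
    val_J <- validation_objective(model, vtuples, config$tau, M)
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, ep_J / max(ep_w, 1))
    hist_val <- c(hist_val, val_J)
    if (verbose) {
      message(sprintf("epoch %3d  train J %.5f  val J %.5f", epoch,
                      ep_J / max(ep_w, 1), val_J))
    }
    if (is.finite(val_J) && val_J < best_val - 1e-12) {
      best_val <- val_J
      best_model <- model
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  list(model = best_model,
       history = data.frame(epoch = hist_epoch, train_J = hist_train,
                            val_J = hist_val))
}
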