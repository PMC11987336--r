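# Human-in-the-loop model updating.
#
# Rated search results enter a margin ranking loss over all hit pairs; the
# blended objective Jtilde = J + lambda * mean(l_r) is minimized for a fixed
# number of SGD-with-momentum iterations with batch normalization frozen
# (evaluation statistics).  Distances are computed in the reduced
# concatenated space R^{2q} with the basis V held fixed, so gradients flow
# through the representation model only; the database is then re-embedded
# with the same basis.

#' Feedback fine-tuning configuration
#'
#' Defaults follow the stated update protocol: SGD, 100 iterations, learning
#' rate 1e-4, momentum 0.9, weight decay 1e-8, margin delta = 100, trade-off
#' lambda = 0.01.  `minibatch` sizes the contrastive term's sample from the
#' training set (the full-scale protocol does not state it; 256 keeps the
#' term informative at desk scale).
#'
#' @param delta ranking margin (>= 0).
#' @param lambda trade-off between contrastive and ranking terms (>= 0).
#' @param iterations SGD iterations (>= 1).
#' @param learning_rate,momentum,weight_decay SGD hyperparameters.
#' @param minibatch contrastive minibatch size per iteration.
#' @param seed sampling seed.
#' @return list of class `rxn_feedback_config`.
#' @export
feedback_config <- function(delta = 100, lambda = 0.01, iterations = 100L,
                            learning_rate = 1e-4, momentum = 0.9,
                            weight_decay = 1e-8, minibatch = 256L,
                            seed = 1L) {
  stopifnot(delta >= 0, lambda >= 0, iterations >= 1L, minibatch >= 2L)
  structure(list(delta = delta, lambda = lambda,
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 minibatch = as.integer(minibatch), seed = as.integer(seed)),
            class = "rxn_feedback_config")
}

#' One rated search result
#'
#' @param query the `rxn_query` that produced the hits.
#' @param hit_records list of `rxn_record` in retrieved order.
#' @param ratings integer vector in {-1, 0, +1}, aligned with `hit_records`.
#' @param anchor_index_sets for substructure queries: list with `product`
#'   and/or `reactants` integer vectors of anchor record positions in the
#'   database (frozen at query time).
#' @return list of class `rxn_feedback_entry`.
#' @export
feedback_entry <- function(query, hit_records, ratings,
                           anchor_index_sets = NULL) {
  stopifnot(length(ratings) == length(hit_records),
            all(ratings %in% c(-1L, 0L, 1L)))
  structure(list(query = query, hit_records = hit_records,
                 ratings = as.integer(ratings),
                 anchor_index_sets = anchor_index_sets),
            class = "rxn_feedback_entry")
}

#' Margin ranking loss over one query's rated hits
#'
#' l_r = 2/(K(K-1)) * sum over pairs i<j of
#' max(0, (r_i - r_j)(d_i - d_j) + |r_i - r_j| * delta).  Pairs with equal
#' ratings contribute zero; K < 2 gives 0 with a warning.
#'
#' @param x query vector in R^{2q}.
#' @param hits_x K x 2q matrix of hit embeddings (retrieved order).
#' @param ratings integer vector in {-1, 0, +1}.
#' @param delta margin.
#' @return non-negative scalar.
#' @export
margin_ranking_loss <- function(x, hits_x, ratings, delta) {
  .margin_loss_grad(x, hits_x, ratings, delta, want_grad = FALSE)$loss
}

.margin_loss_grad <- function(x, hits_x, ratings, delta, want_grad = TRUE) {
  K <- nrow(hits_x)
  if (is.null(K) || K < 2L) {
    warning("fewer than 2 rated hits: margin ranking loss is 0")
    return(list(loss = 0,
                dd = numeric(if (is.null(K)) 0L else K)))
  }
  stopifnot(length(ratings) == K)
  diffs <- hits_x - matrix(x, K, length(x), byrow = TRUE)
  d <- sqrt(rowSums(diffs * diffs))
  w <- 2 / (K * (K - 1))
  loss <- 0
  dd <- numeric(K)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      dr <- ratings[i] - ratings[j]
      if (dr == 0L) next
      term <- dr * (d[i] - d[j]) + abs(dr) * delta
      if (term > 0) {
        loss <- loss + w * term
        if (want_grad) {
          dd[i] <- dd[i] + w * dr
          dd[j] <- dd[j] - w * dr
        }
      }
    }
  }
  if (!want_grad) return(list(loss = loss))
  # chain to hit vectors and the query vector; zero-distance hits get zero grad
  dH <- matrix(0, K, ncol(hits_x))
  dx <- numeric(ncol(hits_x))
  nz <- which(d > 0 & dd != 0)
  for (i in nz) {
    u <- diffs[i, ] / d[i]
    dH[i, ] <- dd[i] * u
    dx <- dx - dd[i] * u
  }
  list(loss = loss, dd = dd, dH = dH, dx = dx)
}

# Recompute the reduced-space embeddings of a feedback entry's query and hits
# with the current model (eval mode), optionally with gradient plumbing.
.entry_forward <- function(model, basis, entry, prep) {
  q <- basis$q
  V <- basis$V
  hits_fw <- model_forward_tuples(model, prep$hit_tuples, train = FALSE)
  Hx <- cbind(project(hits_fw$Z, basis), project(hits_fw$Zhat, basis))
  # query sides
  qry <- entry$query
  zs <- NULL; zh <- NULL
  q_fw <- list()
  if (qry$match_mode == "substructure") {
    stop("substructure-query fine-tuning requires anchor re-embedding; ",
         "freeze anchors into hit-style entries instead")
  }
  if (!is.null(prep$q_tuple)) {
    q_fw <- model_forward_tuples(model, list(prep$q_tuple), train = FALSE)
    if (!is.null(qry$product)) zs <- project(as.numeric(q_fw$Z[1, ]), basis)
    if (!is.null(qry$reactants)) zh <- project(as.numeric(q_fw$Zhat[1, ]), basis)
  }
  if (is.null(zh)) zh <- zs
  if (is.null(zs)) zs <- zh
  list(x = c(zs, zh), Hx = Hx, hits_fw = hits_fw, q_fw = q_fw)
}

# featurize an entry's query and hits once (model-independent)
.entry_prepare <- function(entry) {
  qry <- entry$query
  q_tuple <- NULL
  if (qry$match_mode != "substructure") {
    # synthesize a pseudo-record tuple carrying the query's graphs; the
    # product side is a single-molecule set, the reactant side the molecule
    # list (plus optional reagents on the reagent branch)
    q_tuple <- structure(list(
      product_graph = featurize_molecule_set(
        if (!is.null(qry$product)) qry$product else character(0)),
      reactant_graph = featurize_molecule_set(
        if (!is.null(qry$reactants)) qry$reactants else character(0)),
      reagent_graph = if (!is.null(qry$reagents) && length(qry$reagents)) {
        featurize_molecule_set(qry$reagents)
      } else NULL), class = "rxn_graph_tuple")
  }
  list(hit_tuples = lapply(entry$hit_records, featurize_record),
       q_tuple = q_tuple)
}

#' Blended objective Jtilde on a minibatch plus a feedback set
#'
#' Jtilde = J(S) + lambda * mean over entries of l_r, with hit and query
#' embeddings recomputed from the current model and projected with the fixed
#' basis.
#'
#' @param minibatch list of `rxn_record` (contrastive sample S).
#' @param feedback list of `rxn_feedback_entry` (non-empty).
#' @param lambda trade-off.
#' @param model an `rxn_model`.
#' @param basis an `rxn_basis`.
#' @param tau contrastive temperature.
#' @param delta ranking margin.
#' @return scalar Jtilde.
#' @export
combined_objective <- function(minibatch, feedback, lambda, model, basis,
                               tau = 100, delta = 100) {
  stopifnot(length(feedback) >= 1L)
  tuples <- lapply(minibatch, function(r) {
    if (inherits(r, "rxn_record")) featurize_record(r) else r
  })
  fw <- model_forward_tuples(model, tuples, train = FALSE)
  J <- batch_objective(list(Z = fw$Z, Zhat = fw$Zhat), tau)
  lr_sum <- 0
  for (entry in feedback) {
    prep <- .entry_prepare(entry)
    ef <- .entry_forward(model, basis, entry, prep)
    lr_sum <- lr_sum + margin_ranking_loss(ef$x, ef$Hx, entry$ratings, delta)
  }
  J + lambda * lr_sum / length(feedback)
}

#' Fine-tune the representation model on user feedback
#'
#' Minimizes Jtilde for `config$iterations` SGD-with-momentum steps.  The
#' contrastive minibatch is re-sampled from `train_records` each iteration;
#' rated hits and the query are re-embedded from the live model each
#' iteration; all batch-norm layers use frozen (evaluation) statistics
#' throughout.  Seed-deterministic.
#'
#' @param model an `rxn_model`.
#' @param train_records training dataset D (list of `rxn_record`).
#' @param feedback list of `rxn_feedback_entry` (non-empty).
#' @param config an [feedback_config()].
#' @param basis the fixed `rxn_basis`.
#' @return updated `rxn_model`.
#' @export
finetune <- function(model, train_records, feedback, config, basis) {
  stopifnot(inherits(config, "rxn_feedback_config"),
            length(feedback) >= 1L, length(train_records) >= 2L)
  tuples <- lapply(train_records, featurize_record)
  preps <- lapply(feedback, .entry_prepare)
  nQ <- length(feedback)
  opt <- sgd_init(model$params, lr = config$learning_rate,
                  momentum = config$momentum,
                  weight_decay = config$weight_decay)
  set.seed(config$seed)
  Mb <- min(config$minibatch, length(tuples))
  for (it in seq_len(config$iterations)) {
    bi <- sample.int(length(tuples), Mb)
    fw <- model_forward_tuples(model, tuples[bi], train = FALSE)
    ls <- .nt_xent_batch(fw$Z, fw$Zhat, tau = 100)
    grads <- model_backward_tuples(model, fw$cache, ls$dZ, ls$dZhat)
    if (config$lambda > 0) {
      for (e in seq_len(nQ)) {
        entry <- feedback[[e]]
        ef <- .entry_forward(model, basis, entry, preps[[e]])
        mg <- .margin_loss_grad(ef$x, ef$Hx, entry$ratings, config$delta)
        if (all(mg$dd == 0)) next
        scale <- config$lambda / nQ
        q <- basis$q
        V <- basis$V
        dZ <- (scale * mg$dH[, seq_len(q), drop = FALSE]) %*% t(V)
        dZh <- (scale * mg$dH[, q + seq_len(q), drop = FALSE]) %*% t(V)
        grads <- .acc_grads(grads, model_backward_tuples(
          model, ef$hits_fw$cache, dZ, dZh))
        # query-side gradients
        dx1 <- scale * mg$dx[seq_len(q)]
        dx2 <- scale * mg$dx[q + seq_len(q)]
        qry <- entry$query
        dqZ <- matrix(0, 1L, model$config$p)
        dqZh <- matrix(0, 1L, model$config$p)
        if (!is.null(qry$product) && !is.null(qry$reactants)) {
          dqZ[1, ] <- dx1 %*% t(V)
          dqZh[1, ] <- dx2 %*% t(V)
        } else if (!is.null(qry$product)) {
          dqZ[1, ] <- (dx1 + dx2) %*% t(V)
        } else {
          dqZh[1, ] <- (dx1 + dx2) %*% t(V)
        }
        grads <- .acc_grads(grads, model_backward_tuples(
          model, ef$q_fw$cache, dqZ, dqZh))
      }
    }
    st <- optimizer_step(opt, model$params, grads)
    model$params <- st$params; opt <- st$opt
  }
  model
}

#' Re-embed the database with an updated model and the same basis
#'
#' @param db an `rxn_index`.
#' @param model the updated `rxn_model`.
#' @param basis the (unchanged) `rxn_basis`; defaults to the index's own.
#' @return a fresh `rxn_index` with identical record order.
#' @export
refresh_index <- function(db, model, basis = NULL) {
  if (is.null(basis)) basis <- db$basis
  build_index(db$records, model, basis)
}
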