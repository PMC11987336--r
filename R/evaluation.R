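# Evaluation: reaction product prediction metrics (MRR, MR, Hit@k) and the
# simulated user-preference feedback experiment.

#' Product-prediction metrics over a test set
#'
#' For each test record, the prediction vector zhat (reactants side) is
#' ranked against the target vectors z of all candidate products (the unique
#' test-set products by default) by ascending Euclidean distance; the rank of
#' the ground-truth product yields MRR = mean(1/rank), MR = mean(rank) and
#' Hit@k = fraction of ranks <= k.  Rank ties are broken by candidate-pool
#' index.
#'
#' @param model an `rxn_model`.
#' @param test_records list of `rxn_record`.
#' @param candidate_products optional character vector of canonical product
#'   SMILES (default: unique products of `test_records`).
#' @param basis optional `rxn_basis`; when given, distances are computed on
#'   projected vectors.
#' @param hit_ks the k values reported (default 1, 3, 5, 10).
#' @return list of class `rxn_metrics`: `mrr`, `mr`, `hit_at` (named),
#'   `n_queries`, `n_candidates`, `ranks`.
#' @export
product_prediction_metrics <- function(model, test_records,
                                       candidate_products = NULL,
                                       basis = NULL,
                                       hit_ks = c(1L, 3L, 5L, 10L)) {
  prods <- vapply(test_records, function(r) r$product, "")
  if (is.null(candidate_products)) candidate_products <- unique(prods)
  truth_idx <- match(prods, candidate_products)
  if (any(is.na(truth_idx))) {
    stop("ground-truth product missing from the candidate pool")
  }
  # candidate target vectors: product-only pseudo-records through the P path
  cand_tuples <- lapply(candidate_products, function(p) {
    structure(list(product_graph = featurize_molecule_set(p),
                   reactant_graph = featurize_molecule_set(character(0)),
                   reagent_graph = NULL), class = "rxn_graph_tuple")
  })
  Zc <- embed_records(cand_tuples, model)$Z
  Zhat <- embed_records(test_records, model)$Zhat
  if (!is.null(basis)) {
    Zc <- project(Zc, basis)
    Zhat <- project(Zhat, basis)
  }
  cn <- rowSums(Zc * Zc)
  ranks <- vapply(seq_along(test_records), function(i) {
    d2 <- cn - 2 * as.numeric(Zc %*% Zhat[i, ])   # + const ||zhat||^2
    ord <- order(d2, seq_along(d2))
    which(ord == truth_idx[i])
  }, 0L)
  out <- metrics_from_ranks(ranks, hit_ks)
  out$n_candidates <- length(candidate_products)
  out
}

#' Summarize 1-based ranks into MRR, MR and Hit@k
#'
#' @param ranks integer vector of ground-truth ranks (>= 1).
#' @param hit_ks k values for Hit@k.
#' @return list of class `rxn_metrics`.
#' @export
metrics_from_ranks <- function(ranks, hit_ks = c(1L, 3L, 5L, 10L)) {
  stopifnot(all(ranks >= 1L))
  hit <- vapply(hit_ks, function(k) mean(ranks <= k), 0)
  names(hit) <- paste0("hit@", hit_ks)
  structure(list(mrr = mean(1 / ranks), mr = mean(ranks), hit_at = hit,
                 n_queries = length(ranks), ranks = ranks),
            class = "rxn_metrics")
}

#' Maximum Tanimoto similarity between a product and any reactant
#'
#' Circular fingerprints (radius 2, 2048 bits, frozen) with set arithmetic
#' |A&B| / |A|B|.
#'
#' @param product product SMILES.
#' @param reactants character vector of reactant SMILES (length >= 1).
#' @return similarity in [0, 1].
#' @export
max_tanimoto <- function(product, reactants) {
  stopifnot(length(reactants) >= 1L)
  fp <- circular_fingerprint(product)
  max(vapply(reactants, function(r) tanimoto(fp, circular_fingerprint(r)), 0))
}

#' User-preference scenario specification
#'
#' Five simulated-rater scenarios: (1) the hit's product carries the same set
#' of halogen element types {F, Cl, Br, I} as the query product (empty ==
#' empty counts as a match); (2) the hit's reactant count equals the query's
#' (or 2 when the query specifies no reactants); (3) the maximum Tanimoto
#' similarity between the hit's product and any of its reactants exceeds the
#' threshold; (4) = 1 and 2; (5) = 1 and 3.
#'
#' @param scenario_id integer 1-5.
#' @param tanimoto_threshold similarity threshold for scenarios 3/5
#'   (default 0.5).
#' @param default_reactant_count reactant count assumed for product-only
#'   queries in scenarios 2/4 (default 2).
#' @param halogen_semantics "set" (default) compares halogen element-type
#'   sets; "count" compares per-element halogen atom counts.
#' @return list of class `rxn_scenario`.
#' @export
scenario_spec <- function(scenario_id, tanimoto_threshold = 0.5,
                          default_reactant_count = 2L,
                          halogen_semantics = c("set", "count")) {
  stopifnot(scenario_id %in% 1:5, tanimoto_threshold > 0,
            tanimoto_threshold < 1)
  structure(list(scenario_id = as.integer(scenario_id),
                 tanimoto_threshold = tanimoto_threshold,
                 default_reactant_count = as.integer(default_reactant_count),
                 halogen_semantics = match.arg(halogen_semantics)),
            class = "rxn_scenario")
}

.halogen_signature <- function(smiles, semantics) {
  mol <- parse_smiles(smiles)
  if (semantics == "set") {
    paste(mol_halogen_set(mol), collapse = ",")
  } else {
    h <- mol$elem[mol$elem %in% .HALOGENS]
    paste(names(table(h)), as.integer(table(h)), sep = ":", collapse = ",")
  }
}

#' Rate one retrieved record under a preference scenario
#'
#' @param query the `rxn_query` that produced the hit.
#' @param record the retrieved `rxn_record`.
#' @param scenario an [scenario_spec()].
#' @return +1L if the scenario predicate holds, else -1L.
#' @export
rate_by_scenario <- function(query, record, scenario) {
  stopifnot(!is.null(record$product), length(record$reactants) >= 1L)
  cond1 <- function() {
    if (is.null(query$product)) return(FALSE)
    identical(.halogen_signature(query$product, scenario$halogen_semantics),
              .halogen_signature(record$product, scenario$halogen_semantics))
  }
  cond2 <- function() {
    nq <- if (is.null(query$reactants)) scenario$default_reactant_count
          else length(query$reactants)
    length(record$reactants) == nq
  }
  cond3 <- function() {
    max_tanimoto(record$product, record$reactants) >
      scenario$tanimoto_threshold
  }
  ok <- switch(scenario$scenario_id,
               cond1(), cond2(), cond3(),
               cond1() && cond2(), cond1() && cond3())
  if (ok) 1L else -1L
}

#' Simulated user-preference feedback loop
#'
#' For each round: retrieve top-K per query, rate every hit with the scenario
#' predicate, record the mean hit ratio (fraction of positive ratings),
#' fine-tune on all accumulated feedback and re-embed the database.  Round 0
#' is the pre-update state; the trajectory has `n_updates + 1` entries.
#'
#' @param queries list of `rxn_query`.
#' @param db an `rxn_index` (searched database).
#' @param model an `rxn_model`.
#' @param train_records training dataset for the contrastive term.
#' @param scenario an [scenario_spec()].
#' @param K retrieved records per query (default 30).
#' @param n_updates number of model updates (default 3).
#' @param config an [feedback_config()].
#' @param accumulate keep earlier rounds' feedback in the query set Q
#'   (default TRUE).
#' @return list of class `rxn_trajectory`: `hit_ratio` (length n_updates+1),
#'   `per_query` matrix (rounds x queries), final `model` and `db`.
#' @export
simulate_feedback_loop <- function(queries, db, model, train_records,
                                   scenario, K = 30L, n_updates = 3L,
                                   config = feedback_config(),
                                   accumulate = TRUE) {
  stopifnot(length(queries) >= 1L, n_updates >= 0L)
  traj <- numeric(n_updates + 1L)
  per_query <- matrix(0, n_updates + 1L, length(queries))
  Q <- list()
  for (round in 0:n_updates) {
    ratios <- numeric(length(queries))
    round_fb <- list()
    for (qi in seq_along(queries)) {
      qry <- queries[[qi]]
      qry$K <- as.integer(K)
      res <- search_reactions(qry, db, model)
      hit_records <- db$records[res$hits$index]
      ratings <- vapply(hit_records, function(r)
        rate_by_scenario(qry, r, scenario), 0L)
      ratios[qi] <- if (length(ratings)) mean(ratings == 1L) else 0
      round_fb[[length(round_fb) + 1L]] <-
        feedback_entry(qry, hit_records, ratings)
    }
    traj[round + 1L] <- mean(ratios)
    per_query[round + 1L, ] <- ratios
    if (round < n_updates) {
      Q <- if (accumulate) c(Q, round_fb) else round_fb
      cfg <- config
      cfg$seed <- config$seed + round   # fresh minibatch stream per round
      model <- finetune(model, train_records, Q, cfg, db$basis)
      db <- refresh_index(db, model)
    }
  }
  structure(list(hit_ratio = traj, per_query = per_query, model = model,
                 db = db, rounds = 0:n_updates),
            class = "rxn_trajectory")
}
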