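# Embedded database construction and top-K retrieval.
#
# Each record i is stored as x_i = [z'_i || zhat'_i] in R^{2q}; a query is
# embedded to x_* in the same space and the K nearest candidates by plain
# Euclidean distance (no reweighting between halves) are returned in
# ascending order, ties broken by record id.

#' Query specification
#'
#' At least one of `product` / `reactants` must be given.  In "exact" and
#' "similarity" modes the query molecules are embedded directly ("exact"
#' additionally post-filters hits to canonical equality on the queried
#' roles).  In "substructure" mode the molecules are patterns: database
#' records whose corresponding role contains every pattern are selected and
#' their stored embeddings averaged.
#'
#' @param product product SMILES or pattern, or NULL.
#' @param reactants character vector of reactant SMILES/patterns, or NULL.
#' @param reagents character vector of reagent SMILES, or NULL (only used
#'   alongside reactants for embedding the prediction side).
#' @param match_mode "similarity" (default), "exact" or "substructure".
#' @param attribute_ranges named list of c(lo, hi) ranges.
#' @param K number of records to retrieve (default 30).
#' @return list of class `rxn_query`.
#' @export
query_spec <- function(product = NULL, reactants = NULL, reagents = NULL,
                       match_mode = c("similarity", "exact", "substructure"),
                       attribute_ranges = list(), K = 30L) {
  match_mode <- match.arg(match_mode)
  if (is.null(product) && is.null(reactants)) {
    stop("at least one of product or reactants must be provided")
  }
  for (rg in attribute_ranges) {
    stopifnot(length(rg) == 2L, rg[1] <= rg[2])
  }
  structure(list(product = product, reactants = reactants,
                 reagents = reagents, match_mode = match_mode,
                 attribute_ranges = attribute_ranges, K = as.integer(K)),
            class = "rxn_query")
}

#' Build the embedded database
#'
#' Every record is embedded (target/prediction pair), projected with the
#' basis and stored as the concatenation [z' || zhat'].  Deterministic given
#' the checkpoint.
#'
#' @param records list of `rxn_record`.
#' @param model an `rxn_model`.
#' @param basis an `rxn_basis` fitted on embeddings from the same model.
#' @return object of class `rxn_index`: `records`, `X` (N x 2q), `q`.
#' @export
build_index <- function(records, model, basis) {
  stopifnot(model$config$p == basis$p)
  emb <- embed_records(records, model)
  Xz <- project(emb$Z, basis)
  Xh <- project(emb$Zhat, basis)
  structure(list(records = records, X = cbind(Xz, Xh), q = basis$q,
                 basis = basis),
            class = "rxn_index")
}

#' Embed a query into the reduced concatenated space
#'
#' Exact/similarity: z'_* from the product path, zhat'_* from the
#' reactant(+reagent) path.  Substructure: the missing side is the mean of
#' the stored z' (product pattern) or zhat' (reactant pattern) over matching
#' records.  Fallbacks: no reactants -> [z'_* || z'_*]; no product ->
#' [zhat'_* || zhat'_*].
#'
#' @param query an `rxn_query`.
#' @param model an `rxn_model`.
#' @param basis an `rxn_basis`.
#' @param db an `rxn_index` (required for substructure anchoring).
#' @return list with `x` (length 2q) and, for substructure queries,
#'   `anchor_ids` per role.
#' @export
embed_query <- function(query, model, basis, db = NULL) {
  q <- basis$q
  zs <- NULL; zh <- NULL
  anchors <- list()
  if (query$match_mode == "substructure") {
    if (is.null(db)) stop("substructure queries require a built index")
    if (!is.null(query$product)) {
      sel <- which(vapply(db$records, function(r)
        set_has_substructure(query$product, r$product), TRUE))
      if (!length(sel)) stop("no anchor records match the product pattern")
      zs <- colMeans(db$X[sel, seq_len(q), drop = FALSE])
      anchors$product <- vapply(db$records[sel], function(r) r$record_id, "")
    }
    if (!is.null(query$reactants)) {
      sel <- which(vapply(db$records, function(r) {
        all(vapply(query$reactants, function(pat) {
          any(vapply(r$reactants, function(s) set_has_substructure(pat, s),
                     TRUE))
        }, TRUE))
      }, TRUE))
      if (!length(sel)) stop("no anchor records match the reactant pattern(s)")
      zh <- colMeans(db$X[sel, q + seq_len(q), drop = FALSE])
      anchors$reactants <- vapply(db$records[sel], function(r) r$record_id, "")
    }
  } else {
    if (!is.null(query$product)) {
      g <- featurize_molecule_set(query$product)
      zp <- head_forward(model, "P",
                         matrix(encode(g, model), 1L))$Z
      zs <- project(as.numeric(zp), basis)
    }
    if (!is.null(query$reactants)) {
      g <- featurize_molecule_set(query$reactants)
      zr <- head_forward(model, "R", matrix(encode(g, model), 1L))$Z
      if (!is.null(query$reagents) && length(query$reagents)) {
        ga <- featurize_molecule_set(query$reagents)
        zr <- zr + head_forward(model, "A", matrix(encode(ga, model), 1L))$Z
      }
      zh <- project(as.numeric(zr), basis)
    }
  }
  if (is.null(zh)) zh <- zs
  if (is.null(zs)) zs <- zh
  list(x = c(as.numeric(zs), as.numeric(zh)), anchors = anchors)
}

#' Filter database records by attribute ranges
#'
#' A record is kept iff every specified attribute exists on the record and
#' lies inside its inclusive [lo, hi] range; records missing a specified
#' attribute are filtered out (set `keep_missing = TRUE` to invert that
#' choice).
#'
#' @param db an `rxn_index` (or plain list of records).
#' @param attribute_ranges named list of c(lo, hi).
#' @param keep_missing keep records lacking a specified attribute.
#' @return integer vector of candidate record indices.
#' @export
filter_by_ranges <- function(db, attribute_ranges, keep_missing = FALSE) {
  records <- if (inherits(db, "rxn_index")) db$records else db
  idx <- seq_along(records)
  if (length(attribute_ranges) == 0L) return(idx)
  known <- unique(unlist(lapply(records, function(r) names(r$attributes))))
  for (key in names(attribute_ranges)) {
    if (!key %in% known) {
      warning("unknown attribute '", key, "' in range filter")
    }
    rg <- attribute_ranges[[key]]
    keep <- vapply(records[idx], function(r) {
      v <- r$attributes[[key]]
      if (is.null(v)) return(keep_missing)
      v >= rg[1] && v <= rg[2]
    }, TRUE)
    idx <- idx[keep]
  }
  idx
}

#' Retrieve the top-K nearest records
#'
#' Euclidean distances over the candidate rows, ascending, ties broken by
#' record id (lexicographic).  Returns min(K, number of candidates) hits.
#'
#' @param x query vector in R^{2q}.
#' @param db an `rxn_index`.
#' @param candidates candidate row indices (default: all).
#' @param K number of hits.
#' @return object of class `rxn_search_result`: data.frame `hits`
#'   (record_id, index, distance) in ascending distance, plus `K`.
#' @export
retrieve_topk <- function(x, db, candidates = NULL, K = 30L) {
  stopifnot(K >= 1L)
  if (is.null(candidates)) candidates <- seq_along(db$records)
  if (!length(candidates)) {
    return(structure(list(hits = data.frame(record_id = character(0),
                                            index = integer(0),
                                            distance = numeric(0)),
                          K = as.integer(K)),
                     class = "rxn_search_result"))
  }
  diffs <- db$X[candidates, , drop = FALSE] -
    matrix(x, length(candidates), length(x), byrow = TRUE)
  d <- sqrt(rowSums(diffs * diffs))
  ids <- vapply(db$records[candidates], function(r) r$record_id, "")
  ord <- order(d, ids)
  take <- ord[seq_len(min(K, length(ord)))]
  structure(list(hits = data.frame(record_id = ids[take],
                                   index = candidates[take],
                                   distance = d[take],
                                   stringsAsFactors = FALSE),
                 K = as.integer(K)),
            class = "rxn_search_result")
}

#' Run a full search: embed the query, filter, retrieve
#'
#' @param query an `rxn_query`.
#' @param db an `rxn_index`.
#' @param model an `rxn_model`.
#' @return an `rxn_search_result` (exact mode post-filters hits to canonical
#'   equality on the queried roles).
#' @export
search_reactions <- function(query, db, model) {
  qe <- embed_query(query, model, db$basis, db)
  cand <- filter_by_ranges(db, query$attribute_ranges)
  res <- retrieve_topk(qe$x, db, cand, query$K)
  if (query$match_mode == "exact" && nrow(res$hits) > 0L) {
    keep <- vapply(res$hits$index, function(i) {
      r <- db$records[[i]]
      ok <- TRUE
      if (!is.null(query$product)) {
        ok <- ok && identical(canonical_smiles(query$product), r$product)
      }
      if (!is.null(query$reactants)) {
        ok <- ok && setequal(vapply(query$reactants, canonical_smiles, ""),
                             r$reactants)
      }
      ok
    }, TRUE)
    res$hits <- res$hits[keep, , drop = FALSE]
  }
  res
}
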