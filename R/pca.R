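# Principal-direction basis on stacked target/prediction vectors.
#
# The 2N x p matrix Z = [z_1; ...; z_N; zhat_1; ...; zhat_N] is factorized by
# SVD *without* mean-centering: the bias-free projection heads approximately
# zero-center the vectors over the database, and skipping centering keeps the
# projection a pure linear map z' = z V so reduced-space Euclidean distances
# relate to full-space ones through V'V alone (identity at q = p).

#' Stack embedding pairs into the 2N x p matrix Z
#'
#' Rows 1..N are target vectors, rows N+1..2N prediction vectors, order
#' preserved.
#'
#' @param pairs list of `rxn_embedding_pair`, or a list with `Z`/`Zhat`
#'   matrices.
#' @return 2N x p numeric matrix.
#' @export
stack_embeddings <- function(pairs) {
  zz <- .pairs_to_matrices(pairs)
  stopifnot(ncol(zz$Z) == ncol(zz$Zhat), nrow(zz$Z) == nrow(zz$Zhat))
  rbind(zz$Z, zz$Zhat)
}

#' Fit the principal-direction basis
#'
#' Uncentered SVD Z = U S V'.  With `evr_threshold`, q is the smallest
#' component count whose cumulative explained variance (squared-singular-value
#' energy fraction) reaches the threshold.  Column signs are fixed so the
#' largest-magnitude entry of each direction is positive.
#'
#' @param Z 2N x p matrix from [stack_embeddings()].
#' @param q reduced dimensionality (1 <= q <= min(2N, p)); ignored if
#'   `evr_threshold` is given.
#' @param evr_threshold explained-variance threshold in (0, 1]; default 0.95
#'   when `q` is NULL.
#' @return object of class `rxn_basis`: `V` (p x q), `singular_values`
#'   (all min(2N,p) values, non-increasing), `explained_variance_ratio`,
#'   `cum_explained_variance`, `q`, `p`, `evr_threshold`.
#' @export
fit_basis <- function(Z, q = NULL, evr_threshold = NULL) {
  stopifnot(is.matrix(Z), nrow(Z) >= 1L, all(is.finite(Z)))
  p <- ncol(Z)
  sv <- svd(Z)
  d <- sv$d
  energy <- d * d
  evr <- if (sum(energy) > 0) energy / sum(energy) else rep(0, length(d))
  cum <- cumsum(evr)
  if (is.null(q)) {
    if (is.null(evr_threshold)) evr_threshold <- 0.95
    stopifnot(evr_threshold > 0, evr_threshold <= 1)
    q <- which(cum >= evr_threshold - 1e-12)[1]
    if (is.na(q)) q <- length(d)
  } else {
    stopifnot(q >= 1L, q <= min(nrow(Z), p))
  }
  V <- sv$v[, seq_len(q), drop = FALSE]
  # reproducible sign convention
  for (j in seq_len(q)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(V = V, singular_values = d,
                 explained_variance_ratio = evr,
                 cum_explained_variance = cum,
                 q = as.integer(q), p = as.integer(p),
                 evr_threshold = evr_threshold),
            class = "rxn_basis")
}

#' Project vectors onto the principal directions
#'
#' @param vectors numeric vector of length p or an n x p matrix.
#' @param basis an `rxn_basis`.
#' @return length-q vector or n x q matrix.
#' @export
project <- function(vectors, basis) {
  if (is.null(dim(vectors))) {
    stopifnot(length(vectors) == basis$p)
    return(as.numeric(vectors %*% basis$V))
  }
  stopifnot(ncol(vectors) == basis$p)
  vectors %*% basis$V
}

#' Distance-preservation report for a reduced basis
#'
#' Relative errors |d_reduced - d_full| / d_full over all (or sampled) vector
#' pairs.  Errors are exactly zero at q = p and non-increasing in q on a fixed
#' sample (nested principal subspaces).
#'
#' @param vectors n x p matrix (n >= 2).
#' @param basis an `rxn_basis`.
#' @param max_pairs cap on the number of pairs evaluated (sampled
#'   deterministically by stride if exceeded).
#' @return list with `max_rel_error`, `mean_rel_error`, `n_pairs`.
#' @export
distance_preservation_report <- function(vectors, basis, max_pairs = 5000L) {
  stopifnot(nrow(vectors) >= 2L)
  n <- nrow(vectors)
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_pairs) {
    keep <- unique(round(seq(1L, ncol(pairs), length.out = max_pairs)))
    pairs <- pairs[, keep, drop = FALSE]
  }
  red <- project(vectors, basis)
  d_full <- sqrt(rowSums((vectors[pairs[1, ], , drop = FALSE] -
                          vectors[pairs[2, ], , drop = FALSE])^2))
  d_red <- sqrt(rowSums((red[pairs[1, ], , drop = FALSE] -
                         red[pairs[2, ], , drop = FALSE])^2))
  ok <- d_full > 0
  rel <- abs(d_red[ok] - d_full[ok]) / d_full[ok]
  if (!length(rel)) rel <- 0
  list(max_rel_error = max(rel), mean_rel_error = mean(rel),
       n_pairs = ncol(pairs))
}

#' Storage compression rate achieved by reducing p to q
#'
#' The fraction of stored dimensions removed, 1 - q/p, as a percentage.
#' With p = 512 and q = 26 this is 94.9%.
#'
#' @param p original dimensionality.
#' @param q reduced dimensionality.
#' @return percentage in [0, 100).
#' @export
compression_rate <- function(p, q) {
  stopifnot(p >= 1, q >= 1, q <= p)
  100 * (1 - q / p)
}

#' Save / load a projection basis
#' @param basis an `rxn_basis`.
#' @param path RDS path; a JSON sidecar manifest `<path>.json` records q, p,
#'   threshold and singular values.
#' @export
save_basis <- function(basis, path) {
  saveRDS(basis, path)
  jsonlite::write_json(
    list(q = basis$q, p = basis$p, evr_threshold = basis$evr_threshold,
         singular_values = basis$singular_values,
         centered = FALSE),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path) {
  b <- readRDS(path)
  stopifnot(inherits(b, "rxn_basis"))
  b
}
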