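# Molecule-set featurization: attributed graphs with frozen one-hot
# vocabularies.  Feature dimensions are constant across all molecules; every
# categorical feature has an explicit "other" bucket so rare inputs never
# change dimensionality or crash.

#' The frozen feature-vocabulary manifest
#'
#' Versioned with every model checkpoint so embeddings are reproducible.
#' Node features: atomic number, formal charge, heavy-atom degree,
#' hybridization, hydrogen count, chirality, aromatic flag, in-ring flag and
#' a ring-size multi-hot over sizes 3-7 and "8+".  Edge features: bond type,
#' bond direction, E/Z stereo, in-ring flag, conjugated flag.
#'
#' @return list with `node`, `edge` vocabulary definitions and dimensions
#'   `n_node_features`, `n_edge_features`.
#' @export
feature_manifest <- function() {
  node <- list(
    atomic_number = c(5, 6, 7, 8, 9, 15, 16, 17, 35, 53),  # B C N O F P S Cl Br I
    formal_charge = c(-2, -1, 0, 1, 2),
    degree = 0:6,
    hybridization = c("sp", "sp2", "sp3"),
    num_h = 0:4,
    chirality = c("none", "cw", "ccw"),   # exact categories, no "other"
    ring_sizes = c(3, 4, 5, 6, 7)          # plus an "8+" slot
  )
  edge <- list(
    bond_type = c("single", "double", "triple", "aromatic"),
    direction = c("none", "up", "down"),   # exact categories
    stereo = c("none", "Z", "E")           # exact categories
  )
  n_node <- (length(node$atomic_number) + 1L) + (length(node$formal_charge) + 1L) +
    (length(node$degree) + 1L) + (length(node$hybridization) + 1L) +
    (length(node$num_h) + 1L) + length(node$chirality) +
    2L +                                   # aromatic, in_ring flags
    (length(node$ring_sizes) + 1L)
  n_edge <- (length(edge$bond_type) + 1L) + length(edge$direction) +
    length(edge$stereo) + 2L               # in_ring, conjugated flags
  list(node = node, edge = edge, version = 1L,
       n_node_features = n_node, n_edge_features = n_edge)
}

.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
                Fe = 26, Cu = 29, Zn = 30, Br = 35, Pd = 46, I = 53, Pt = 78)

.onehot <- function(value, vocab) {
  v <- numeric(length(vocab) + 1L)
  idx <- match(value, vocab)
  v[if (is.na(idx)) length(vocab) + 1L else idx] <- 1
  v
}
.onehot_exact <- function(value, vocab) {
  v <- numeric(length(vocab))
  v[match(value, vocab)] <- 1
  v
}

#' Featurize a molecule set into one attributed graph
#'
#' Multiple molecules become one graph whose connected components are the
#' molecules; the empty set yields a valid 0-node graph.  Each bond is stored
#' once; the encoder treats messages as bidirectional.
#'
#' @param molecules character vector of SMILES, a "."-separated SMILES string,
#'   or a list of `rxn_mol`.
#' @return object of class `rxn_molgraph`: `node_features` (n x Fn matrix),
#'   `edges` (m x 2 matrix of 1-based node indices), `edge_features`
#'   (m x Fe matrix), `n_nodes`.
#' @export
featurize_molecule_set <- function(molecules) {
  mf <- feature_manifest()
  if (is.character(molecules)) {
    molecules <- parse_molecule_set(paste(molecules, collapse = "."))
  } else if (inherits(molecules, "rxn_mol")) {
    molecules <- list(molecules)
  }
  n_total <- sum(vapply(molecules, function(m) m$n_atoms, 0L))
  node_x <- matrix(0, nrow = n_total, ncol = mf$n_node_features)
  edges <- matrix(0L, nrow = 0L, ncol = 2L)
  edge_rows <- list()
  offset <- 0L
  for (mol in molecules) {
    for (v in seq_len(mol$n_atoms)) {
      node_x[offset + v, ] <- .node_row(mol, v, mf)
    }
    if (length(mol$a1)) {
      edges <- rbind(edges, cbind(mol$a1 + offset, mol$a2 + offset))
      for (b in seq_along(mol$a1)) {
        edge_rows[[length(edge_rows) + 1L]] <- .edge_row(mol, b, mf)
      }
    }
    offset <- offset + mol$n_atoms
  }
  edge_x <- if (length(edge_rows)) do.call(rbind, edge_rows)
            else matrix(0, nrow = 0L, ncol = mf$n_edge_features)
  structure(list(node_features = node_x, edges = edges,
                 edge_features = edge_x, n_nodes = n_total),
            class = "rxn_molgraph")
}

.node_row <- function(mol, v, mf) {
  z <- .ELEMENT_Z[[mol$elem[v]]]
  if (is.null(z)) z <- -1
  chir <- if (mol$chiral[v] == "@") "ccw" else if (mol$chiral[v] == "@@") "cw"
          else "none"
  rs <- mol$ring_sizes[[v]]
  ring_hot <- numeric(length(mf$node$ring_sizes) + 1L)
  if (length(rs)) {
    for (s in rs) {
      i <- match(s, mf$node$ring_sizes)
      ring_hot[if (is.na(i)) length(ring_hot) else i] <- 1
    }
  }
  c(.onehot(z, mf$node$atomic_number),
    .onehot(mol$charge[v], mf$node$formal_charge),
    .onehot(mol$degree[v], mf$node$degree),
    .onehot(mol$hybrid[v], mf$node$hybridization),
    .onehot(mol$nH[v], mf$node$num_h),
    .onehot_exact(chir, mf$node$chirality),
    as.numeric(mol$arom[v]), as.numeric(mol$in_ring[v]),
    ring_hot)
}

.edge_row <- function(mol, b, mf) {
  bt <- if (mol$barom[b]) "aromatic"
        else c("single", "double", "triple")[mol$order[b]]
  dir <- if (mol$bdir[b] == "/") "up" else if (mol$bdir[b] == "\\") "down"
         else "none"
  st <- if (nzchar(mol$bstereo[b])) mol$bstereo[b] else "none"
  c(.onehot(bt, mf$edge$bond_type),
    .onehot_exact(dir, mf$edge$direction),
    .onehot_exact(st, mf$edge$stereo),
    as.numeric(mol$b_in_ring[b]), as.numeric(mol$conj[b]))
}

#' Featurize a reaction record into its (product, reactants, reagents) graphs
#'
#' @param record an `rxn_record`.
#' @return object of class `rxn_graph_tuple` with `product_graph`,
#'   `reactant_graph` and `reagent_graph` (NULL iff the record has no
#'   reagents).
#' @export
featurize_record <- function(record) {
  stopifnot(inherits(record, "rxn_record"))
  structure(list(
    product_graph = featurize_molecule_set(record$product),
    reactant_graph = featurize_molecule_set(record$reactants),
    reagent_graph = if (length(record$reagents)) {
      featurize_molecule_set(record$reagents)
    } else NULL),
    class = "rxn_graph_tuple")
}
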