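# Substructure (subgraph monomorphism) matching and circular fingerprints.

#' Test whether a pattern molecule occurs as a substructure of a target
#'
#' Backtracking subgraph monomorphism (non-induced, as in chemical
#' substructure search). Atom compatibility requires equal element, aromatic
#' flag and formal charge; bond compatibility requires equal aromaticity and,
#' for non-aromatic bonds, equal order. Pattern hydrogen counts are ignored.
#'
#' @param pattern an `rxn_mol` or SMILES string (single molecule).
#' @param target an `rxn_mol` or SMILES string (single molecule).
#' @return TRUE if an embedding of `pattern` into `target` exists.
#' @export
has_substructure <- function(pattern, target) {
  p <- if (is.character(pattern)) parse_smiles(pattern) else pattern
  t <- if (is.character(target)) parse_smiles(target) else target
  np <- p$n_atoms; nt <- t$n_atoms
  if (np > nt) return(FALSE)
  padj <- .adjacency_list(p); tadj <- .adjacency_list(t)

  atom_ok <- function(pa, ta) {
    p$elem[pa] == t$elem[ta] && p$arom[pa] == t$arom[ta] &&
      p$charge[pa] == t$charge[ta] && p$degree[pa] <= t$degree[ta]
  }
  bond_ok <- function(pb, tb) {
    if (p$barom[pb] != t$barom[tb]) return(FALSE)
    p$barom[pb] || p$order[pb] == t$order[tb]
  }

  # order pattern atoms so each (after the first) touches an earlier one
  ord <- integer(0); placed <- logical(np)
  repeat {
    cand <- which(!placed)
    if (!length(cand)) break
    nxt <- NA_integer_
    if (length(ord)) {
      for (v in cand) {
        if (any(padj[[v]]$nbr %in% ord)) { nxt <- v; break }
      }
    }
    if (is.na(nxt)) nxt <- cand[1L]
    ord <- c(ord, nxt); placed[nxt] <- TRUE
  }

  map <- integer(np)  # pattern atom -> target atom (0 = unmapped)
  used <- logical(nt)
  match_rec <- function(k) {
    if (k > np) return(TRUE)
    pa <- ord[k]
    # candidate targets: neighbors of already-mapped neighbor if any
    nb <- padj[[pa]]
    anchor <- which(map[nb$nbr] > 0L)
    cands <- if (length(anchor)) {
      tadj[[map[nb$nbr[anchor[1L]]]]]$nbr
    } else seq_len(nt)
    for (ta in cands) {
      if (used[ta] || !atom_ok(pa, ta)) next
      ok <- TRUE
      for (j in seq_along(nb$nbr)) {
        q <- nb$nbr[j]
        if (map[q] == 0L) next
        tn <- tadj[[ta]]
        hit <- which(tn$nbr == map[q])
        if (!length(hit) || !bond_ok(nb$bond[j], tn$bond[hit[1L]])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      map[pa] <<- ta; used[ta] <<- TRUE
      if (match_rec(k + 1L)) return(TRUE)
      map[pa] <<- 0L; used[ta] <<- FALSE
    }
    FALSE
  }
  match_rec(1L)
}

#' Test whether any molecule in a set contains a pattern
#' @param pattern SMILES or `rxn_mol` pattern.
#' @param smiles_set "."-separated SMILES or list of `rxn_mol`.
#' @return logical.
#' @export
set_has_substructure <- function(pattern, smiles_set) {
  mols <- if (is.character(smiles_set)) parse_molecule_set(smiles_set)
          else smiles_set
  for (m in mols) if (has_substructure(pattern, m)) return(TRUE)
  FALSE
}

# deterministic 32-bit-ish string hash (FNV-1a folded into [0, 2^31))
.hash_str <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h)
}

#' Circular (Morgan-style) binary fingerprint of a molecule set
#'
#' Atom environments of radius 0..`radius` are hashed into `nbits` buckets.
#' The initial atom invariant is (element, charge, degree, H count, aromatic,
#' in-ring); each iteration hashes the atom identifier together with the
#' sorted (bond key, neighbor identifier) list.
#'
#' @param x SMILES (possibly "."-separated) or `rxn_mol` or list of `rxn_mol`.
#' @param radius environment radius (default 2, ECFP4-like).
#' @param nbits fingerprint length (default 2048).
#' @return sorted integer vector of set bit positions (1-based).
#' @export
circular_fingerprint <- function(x, radius = 2L, nbits = 2048L) {
  mols <- if (is.character(x)) parse_molecule_set(x)
          else if (inherits(x, "rxn_mol")) list(x) else x
  bits <- integer(0)
  for (mol in mols) {
    na <- mol$n_atoms
    adj <- .adjacency_list(mol)
    ids <- vapply(seq_len(na), function(v) {
      .hash_str(paste(mol$elem[v], mol$charge[v], mol$degree[v], mol$nH[v],
                      mol$arom[v], mol$in_ring[v], sep = "|"))
    }, 0L)
    bits <- c(bits, ids %% nbits)
    if (radius >= 1L) {
      for (r in seq_len(radius)) {
        new_ids <- vapply(seq_len(na), function(v) {
          nb <- adj[[v]]
          if (!length(nb$nbr)) return(.hash_str(paste("t", ids[v])))
          env <- sort(paste0(vapply(nb$bond, function(b) .bond_key(mol, b), ""),
                             ":", ids[nb$nbr]))
          .hash_str(paste(r, ids[v], paste(env, collapse = ",")))
        }, 0L)
        ids <- new_ids
        bits <- c(bits, ids %% nbits)
      }
    }
  }
  sort(unique(bits)) + 1L
}

#' Tanimoto similarity between two bit sets
#' @param a,b integer vectors of set bit positions.
#' @return |A intersect B| / |A union B| in [0, 1]; 0 if both empty.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
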