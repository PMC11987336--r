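# Canonical atom ranking (Morgan-style partition refinement with tie
# branching) and a canonical SMILES writer.  The canonical string drops
# stereo descriptors; it is used for constitution-level equality checks.

.bond_key <- function(mol, b) {
  if (mol$barom[b]) "a" else as.character(mol$order[b])
}

# iterative refinement of an initial invariant ranking; returns dense ranks
.refine_ranks <- function(mol, ranks) {
  na <- mol$n_atoms
  if (na <= 1L) return(rep(1L, na))
  adj <- .adjacency_list(mol)
  repeat {
    keys <- character(na)
    for (v in seq_len(na)) {
      nb <- adj[[v]]
      if (length(nb$nbr)) {
        lab <- sort(paste0(vapply(nb$bond, function(b) .bond_key(mol, b), ""),
                           ":", sprintf("%06d", ranks[nb$nbr])))
        keys[v] <- paste0(sprintf("%06d", ranks[v]), "|",
                          paste(lab, collapse = ","))
      } else {
        keys[v] <- sprintf("%06d", ranks[v])
      }
    }
    new_ranks <- match(keys, sort(unique(keys)))
    if (identical(new_ranks, ranks) || length(unique(new_ranks)) == na) {
      return(new_ranks)
    }
    ranks <- new_ranks
  }
}

.initial_ranks <- function(mol) {
  keys <- paste(mol$elem, mol$arom, mol$degree, mol$charge, mol$nH,
                sep = "_")
  match(keys, sort(unique(keys)))
}

# canonical SMILES for one molecule; branches over refinement ties and keeps
# the lexicographically smallest rendering, so the result does not depend on
# input atom order
.canonical_single <- function(mol, max_branch = 8L) {
  ranks <- .refine_ranks(mol, .initial_ranks(mol))
  .canon_rec(mol, ranks, max_branch)
}

.canon_rec <- function(mol, ranks, max_branch) {
  na <- mol$n_atoms
  if (length(unique(ranks)) == na) {
    return(.write_from_ranks(mol, ranks))
  }
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab > 1L])
  cell <- which(ranks == min(tied))
  if (length(cell) > max_branch) cell <- cell[1L]
  best <- NULL
  for (v in cell) {
    r2 <- ranks * 2L
    r2[v] <- r2[v] - 1L
    r2 <- match(r2, sort(unique(r2)))
    r2 <- .refine_ranks(mol, r2)
    s <- .canon_rec(mol, r2, max_branch)
    if (is.null(best) || s < best) best <- s
  }
  best
}

.write_from_ranks <- function(mol, ranks) {
  na <- mol$n_atoms
  adj <- .adjacency_list(mol)
  # per-component rendering, joined with "." after sorting
  comp <- integer(na); cur <- 0L
  for (root in order(ranks)) {
    if (comp[root] > 0L) next
    cur <- cur + 1L
    st <- root; comp[root] <- cur
    while (length(st)) {
      v <- st[length(st)]; st <- st[-length(st)]
      for (w in adj[[v]]$nbr) if (comp[w] == 0L) { comp[w] <- cur; st <- c(st, w) }
    }
  }
  out <- character(cur)
  for (ci in seq_len(cur)) {
    atoms <- which(comp == ci)
    root <- atoms[which.min(ranks[atoms])]
    out[ci] <- .render_component(mol, adj, ranks, root)
  }
  paste(sort(out), collapse = ".")
}

.render_component <- function(mol, adj, ranks, root) {
  order_nbrs <- function(v, excl_bond) {
    nb <- adj[[v]]
    keep <- which(nb$bond != excl_bond)
    keep[order(ranks[nb$nbr[keep]])]
  }
  # pass 1: mark tree edges under the deterministic visit order
  visited <- logical(mol$n_atoms)
  tree <- logical(length(mol$a1))
  walk <- function(v, in_bond) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (k in order_nbrs(v, if (is.na(in_bond)) -1L else in_bond)) {
      w <- nb$nbr[k]; b <- nb$bond[k]
      if (!visited[w]) {
        tree[b] <<- TRUE
        walk(w, b)
      }
    }
  }
  walk(root, NA_integer_)
  # pass 2: render; ring digits open at the first-rendered end of a back edge
  visited <- logical(mol$n_atoms)
  ring_no <- 0L
  ring_lbl <- rep(NA_character_, length(mol$a1))
  render <- function(v, in_bond) {
    visited[v] <<- TRUE
    tok <- .atom_token(mol, v)
    ring_toks <- ""
    children <- list()
    nb <- adj[[v]]
    for (k in order_nbrs(v, if (is.na(in_bond)) -1L else in_bond)) {
      w <- nb$nbr[k]; b <- nb$bond[k]
      if (tree[b]) {
        if (!visited[w]) children[[length(children) + 1L]] <- c(w, b)
      } else {
        if (is.na(ring_lbl[b])) {
          ring_no <<- ring_no + 1L
          ring_lbl[b] <<- if (ring_no < 10L) as.character(ring_no)
                          else paste0("%", sprintf("%02d", ring_no))
          # bond order printed at the opening end only
          ring_toks <- paste0(ring_toks, .bond_token(mol, b, v, w), ring_lbl[b])
        } else {
          ring_toks <- paste0(ring_toks, ring_lbl[b])
          ring_lbl[b] <<- NA_character_
        }
      }
    }
    body <- ""
    if (length(children)) {
      for (k in seq_along(children)) {
        w <- children[[k]][1]; b <- children[[k]][2]
        sub <- paste0(.bond_token(mol, b, v, w), render(w, b))
        if (k < length(children)) sub <- paste0("(", sub, ")")
        body <- paste0(body, sub)
      }
    }
    paste0(tok, ring_toks, body)
  }
  render(root, NA_integer_)
}

.bond_token <- function(mol, b, from, to) {
  if (mol$barom[b]) return("")
  o <- mol$order[b]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # single bond: explicit "-" needed only between two aromatic atoms
  if (mol$arom[from] && mol$arom[to]) "-" else ""
}

.atom_token <- function(mol, v) {
  e <- mol$elem[v]
  sym <- if (mol$arom[v]) tolower(e) else e
  needs_bracket <- mol$charge[v] != 0L || !(e %in% .ORGANIC_SUBSET)
  if (!needs_bracket && e %in% .ORGANIC_SUBSET) {
    # bracket needed if the stored H count differs from what a reader would
    # infer from the organic-subset valence rules
    defs <- .DEFAULT_VALENCE[[e]]
    used <- 0
    for (b in seq_along(mol$a1)) {
      if (mol$a1[b] == v || mol$a2[b] == v) {
        used <- used + (if (mol$barom[b]) 1L else mol$order[b])
      }
    }
    used <- used + (if (mol$arom[v]) 1L else 0L)
    d <- defs[defs >= used][1]
    implied <- if (is.na(d)) 0L else as.integer(d - used)
    needs_bracket <- implied != mol$nH[v]
  }
  if (!needs_bracket) return(sym)
  h <- if (mol$nH[v] == 0L) "" else if (mol$nH[v] == 1L) "H"
       else paste0("H", mol$nH[v])
  ch <- mol$charge[v]
  cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
        else if (ch > 1L) paste0("+", ch) else paste0("-", abs(ch))
  paste0("[", sym, h, cs, "]")
}

#' Canonical SMILES of a molecule
#'
#' Constitution-level canonicalization: two SMILES spellings of the same
#' molecular graph (same atoms, bonds, charges, aromaticity, H counts) map to
#' the same string regardless of atom order.  Stereo descriptors are not
#' emitted.
#'
#' @param x an `rxn_mol` or a SMILES string (may contain "." separators; each
#'   component is canonicalized and components are sorted).
#' @return canonical SMILES string.
#' @export
canonical_smiles <- function(x) {
  if (is.character(x)) {
    mols <- parse_molecule_set(x)
    return(paste(sort(vapply(mols, .canonical_single, "")), collapse = "."))
  }
  .canonical_single(x)
}
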