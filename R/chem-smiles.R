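# Minimal SMILES toolkit.
#
# Supports the organic subset (B C N O P S F Cl Br I, aromatic b c n o p s),
# bracket atoms with charge / explicit H / chirality / atom maps, branches,
# ring-closure digits (incl. %nn), bond orders - = # :, and directional bonds
# / \ around double bonds.  Hydrogens are implicit; atom maps are stripped on
# ingest.  This is deliberately not a full chemistry kernel: aromaticity is
# taken from the input notation (no kekulization), and ring perception uses a
# cycle basis from non-tree edges, which is sufficient for the ring-size
# feature vocabulary used here.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.DEFAULT_VALENCE <- list(B = 3L, C = 4L, N = c(3L, 5L), O = 2L,
                         P = c(3L, 5L), S = c(2L, 4L, 6L),
                         F = 1L, Cl = 1L, Br = 1L, I = 1L)
.HALOGENS <- c("F", "Cl", "Br", "I")

#' Parse a single (dot-free) SMILES string into a molecule object
#'
#' @param smiles SMILES of one molecule (no "." separator; see
#'   [parse_molecule_set()] for multi-molecule strings).
#' @return An object of class `rxn_mol`: a list with per-atom vectors
#'   (`elem`, `arom`, `charge`, `nH`, `chiral`, `degree`, `in_ring`,
#'   `ring_sizes`, `hybrid`) and per-bond vectors (`a1`, `a2`, `order`,
#'   `barom`, `bdir`, `bstereo`, `b_in_ring`, `conj`).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("empty or invalid SMILES input")
  }
  s <- chartr(" \t", "  ", smiles)
  if (grepl(" ", s, fixed = TRUE)) stop("SMILES contains whitespace: ", smiles)
  if (grepl(".", s, fixed = TRUE)) {
    stop("parse_smiles() handles a single molecule; got a '.'-separated set: ",
         smiles)
  }

  n_guess <- nchar(s)
  elem <- character(0); arom <- logical(0); charge <- integer(0)
  nH <- integer(0); bracket <- logical(0); chiral <- character(0)
  a1 <- integer(0); a2 <- integer(0); order <- integer(0)
  barom <- logical(0); bdir <- character(0)

  prev <- 0L                 # index of previous atom in chain
  stack <- integer(0)        # branch stack
  pend_order <- NA_integer_  # pending explicit bond token
  pend_arom <- FALSE
  pend_dir <- ""
  ring_open <- list()        # digit -> list(atom, order, arom, dir)

  add_atom <- function(e, ar, ch, h, br, chir) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    nH[length(nH) + 1L] <<- h
    bracket[length(bracket) + 1L] <<- br
    chiral[length(chiral) + 1L] <<- chir
    length(elem)
  }
  add_bond <- function(i, j, o, ar, dir) {
    if (i == j) stop("self-bond in SMILES: ", smiles)
    a1[length(a1) + 1L] <<- i; a2[length(a2) + 1L] <<- j
    order[length(order) + 1L] <<- o
    barom[length(barom) + 1L] <<- ar
    bdir[length(bdir) + 1L] <<- dir
  }
  connect <- function(idx) {
    if (prev > 0L) {
      o <- pend_order; ar <- pend_arom; dir <- pend_dir
      if (is.na(o)) {  # unspecified bond
        ar <- arom[prev] && arom[idx]
        o <- 1L
      }
      add_bond(prev, idx, o, ar, dir)
    }
    prev <<- idx
    pend_order <<- NA_integer_; pend_arom <<- FALSE; pend_dir <<- ""
  }

  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      if (prev == 0L) stop("branch before any atom in SMILES: ", smiles)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_order <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                           "/" = 1L, "\\" = 1L)
      pend_arom <- (ch == ":")
      pend_dir <- if (ch %in% c("/", "\\")) ch else ""
      i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        dig <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", dig)) stop("bad %nn ring closure in: ", smiles)
        i <- i + 3L
      } else {
        dig <- ch
        i <- i + 1L
      }
      if (prev == 0L) stop("ring closure before any atom in SMILES: ", smiles)
      key <- as.character(as.integer(dig))
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, order = pend_order,
                                 arom = pend_arom, dir = pend_dir)
      } else {
        op <- ring_open[[key]]
        o <- if (!is.na(pend_order)) pend_order else op$order
        ar <- pend_arom || op$arom
        if (is.na(o)) {
          ar <- arom[op$atom] && arom[prev]
          o <- 1L
        }
        dir <- if (nzchar(pend_dir)) pend_dir else op$dir
        add_bond(op$atom, prev, o, ar, dir)
        ring_open[[key]] <- NULL
      }
      pend_order <- NA_integer_; pend_arom <- FALSE; pend_dir <- ""
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close < 0L) stop("unclosed '[' in SMILES: ", smiles)
      body <- substr(s, i + 1L, i + close - 2L)
      at <- .parse_bracket_atom(body, smiles)
      idx <- add_atom(at$elem, at$arom, at$charge, at$nH, TRUE, at$chiral)
      connect(idx)
      i <- i + close
    } else {
      # organic-subset atom, possibly two letters
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE, 0L, NA_integer_, FALSE, "")
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE, 0L, NA_integer_, FALSE, "")
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE, "")
        i <- i + 1L
      } else {
        stop("unrecognized SMILES token '", ch, "' at position ", i,
             " in: ", smiles)
      }
      connect(idx)
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(elem) == 0L) stop("SMILES contains no atoms: ", smiles)

  mol <- list(elem = elem, arom = arom, charge = charge, nH = nH,
              bracket = bracket, chiral = chiral,
              a1 = a1, a2 = a2, order = order, barom = barom, bdir = bdir)
  class(mol) <- "rxn_mol"
  .perceive(mol)
}

.parse_bracket_atom <- function(body, smiles) {
  # [isotope][symbol][chiral][Hn][charge][:map]
  m <- regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
    body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L) stop("unparsable bracket atom [", body, "] in: ", smiles)
  sym <- g[3]
  ar <- grepl("^[a-z]", sym)
  e <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  chir <- if (nzchar(g[4])) g[4] else ""
  h <- 0L
  if (nzchar(g[5])) {
    h <- if (g[5] == "H") 1L else as.integer(substr(g[5], 2L, nchar(g[5])))
  }
  chg <- 0L
  if (nzchar(g[6])) {
    cs <- g[6]
    if (grepl("^[+-][0-9]+$", cs)) {
      chg <- as.integer(cs)
    } else {
      chg <- (nchar(cs)) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
    }
  }
  list(elem = e, arom = ar, charge = chg, nH = h, chiral = chir)
}

# ring perception, implicit hydrogens, derived atom/bond attributes
.perceive <- function(mol) {
  na <- length(mol$elem)
  nb <- length(mol$a1)

  # demote "aromatic" bonds that are not in any ring (e.g. biphenyl link)
  adj <- vector("list", na)
  for (b in seq_len(nb)) {
    adj[[mol$a1[b]]] <- c(adj[[mol$a1[b]]], b)
    adj[[mol$a2[b]]] <- c(adj[[mol$a2[b]]], b)
  }
  other_end <- function(b, v) if (mol$a1[b] == v) mol$a2[b] else mol$a1[b]

  # spanning forest -> non-tree (ring closure) bonds
  visited <- logical(na); tree <- logical(nb)
  closure <- integer(0)
  for (root in seq_len(na)) {
    if (visited[root]) next
    st <- root; visited[root] <- TRUE
    used <- logical(nb)
    while (length(st)) {
      v <- st[length(st)]; st <- st[-length(st)]
      for (b in adj[[v]]) {
        if (used[b]) next
        used[b] <- TRUE
        w <- other_end(b, v)
        if (!visited[w]) {
          visited[w] <- TRUE; tree[b] <- TRUE; st <- c(st, w)
        } else if (!tree[b]) closure <- c(closure, b)
      }
    }
  }
  closure <- unique(closure)

  ring_sizes <- vector("list", na)
  atom_in_ring <- logical(na)
  bond_in_ring <- logical(nb)
  for (b in closure) {
    u <- mol$a1[b]; v <- mol$a2[b]
    # BFS shortest path u -> v avoiding bond b
    par_atom <- integer(na); par_bond <- integer(na)
    seen <- logical(na); seen[u] <- TRUE
    q <- u
    while (length(q) && !seen[v]) {
      nxt <- integer(0)
      for (x in q) {
        for (bb in adj[[x]]) {
          if (bb == b) next
          w <- other_end(bb, x)
          if (!seen[w]) {
            seen[w] <- TRUE; par_atom[w] <- x; par_bond[w] <- bb
            nxt <- c(nxt, w)
          }
        }
      }
      q <- nxt
    }
    if (!seen[v]) next   # parallel edge guard; cannot happen for simple graphs
    path_atoms <- v; path_bonds <- integer(0)
    x <- v
    while (x != u) {
      path_bonds <- c(path_bonds, par_bond[x])
      x <- par_atom[x]
      path_atoms <- c(path_atoms, x)
    }
    cyc_atoms <- path_atoms
    cyc_bonds <- c(path_bonds, b)
    sz <- length(cyc_atoms)
    atom_in_ring[cyc_atoms] <- TRUE
    bond_in_ring[cyc_bonds] <- TRUE
    for (x in cyc_atoms) ring_sizes[[x]] <- unique(c(ring_sizes[[x]], sz))
  }
  for (b in seq_len(nb)) {
    if (mol$barom[b] && !bond_in_ring[b]) {
      mol$barom[b] <- FALSE
      mol$order[b] <- 1L
    }
  }

  degree <- integer(na)
  val_used <- numeric(na)
  for (b in seq_len(nb)) {
    o <- if (mol$barom[b]) 1L else mol$order[b]
    for (v in c(mol$a1[b], mol$a2[b])) {
      degree[v] <- degree[v] + 1L
      val_used[v] <- val_used[v] + o
    }
  }

  # implicit hydrogens for non-bracket organic-subset atoms
  for (v in seq_len(na)) {
    if (mol$bracket[v]) {
      if (is.na(mol$nH[v])) mol$nH[v] <- 0L
      next
    }
    defs <- .DEFAULT_VALENCE[[mol$elem[v]]]
    if (is.null(defs)) stop("no default valence for element ", mol$elem[v])
    used <- val_used[v] + (if (mol$arom[v]) 1L else 0L)
    d <- defs[defs >= used][1]
    mol$nH[v] <- if (is.na(d)) 0L else as.integer(d - used)
  }

  # hybridization: sp if triple bond or >=2 double bonds; sp2 if aromatic or
  # any double bond; else sp3 (coarse but standard for featurization)
  hyb <- character(na)
  ndouble <- integer(na); ntriple <- integer(na); nmulti_or_arom <- integer(na)
  for (b in seq_len(nb)) {
    for (v in c(mol$a1[b], mol$a2[b])) {
      if (!mol$barom[b] && mol$order[b] == 2L) ndouble[v] <- ndouble[v] + 1L
      if (!mol$barom[b] && mol$order[b] == 3L) ntriple[v] <- ntriple[v] + 1L
      if (mol$barom[b] || mol$order[b] >= 2L)
        nmulti_or_arom[v] <- nmulti_or_arom[v] + 1L
    }
  }
  for (v in seq_len(na)) {
    hyb[v] <- if (ntriple[v] > 0L || ndouble[v] >= 2L) "sp"
      else if (mol$arom[v] || ndouble[v] == 1L) "sp2"
      else "sp3"
  }

  # conjugation: aromatic bonds, multiple bonds adjacent to other multiple /
  # aromatic bonds, and single bonds joining two multiply-bonded atoms
  conj <- logical(nb)
  for (b in seq_len(nb)) {
    u <- mol$a1[b]; v <- mol$a2[b]
    if (mol$barom[b]) { conj[b] <- TRUE; next }
    if (mol$order[b] >= 2L) {
      conj[b] <- (nmulti_or_arom[u] >= 2L || nmulti_or_arom[v] >= 2L)
    } else {
      conj[b] <- (nmulti_or_arom[u] >= 1L && nmulti_or_arom[v] >= 1L)
    }
  }

  # E/Z assignment for double bonds flanked by directional single bonds
  bstereo <- rep("", nb)
  if (nb > 0L && any(nzchar(mol$bdir))) {
    for (b in seq_len(nb)) {
      if (mol$barom[b] || mol$order[b] != 2L) next
      u <- mol$a1[b]; v <- mol$a2[b]
      du <- .dir_at(mol, adj, u, b)
      dv <- .dir_at(mol, adj, v, b)
      if (is.na(du) || is.na(dv)) next
      # normalized outward from each double-bond atom: equal directions put
      # the reference substituents on the same side (Z), opposite ones E
      bstereo[b] <- if (du == dv) "Z" else "E"
    }
  }

  mol$degree <- degree
  mol$in_ring <- atom_in_ring
  mol$ring_sizes <- ring_sizes
  mol$hybrid <- hyb
  mol$b_in_ring <- bond_in_ring
  mol$conj <- conj
  mol$bstereo <- bstereo
  mol$n_atoms <- na
  mol
}

# normalized direction of a flanking directional bond, as seen walking away
# from double-bond atom v; NA if none
.dir_at <- function(mol, adj, v, dbond) {
  for (b in adj[[v]]) {
    if (b == dbond || !nzchar(mol$bdir[b])) next
    d <- mol$bdir[b]
    # bdir is recorded in written order a1 -> a2; flip if we traverse v -> other
    if (mol$a1[b] != v) d <- if (d == "/") "\\" else "/"
    return(d)
  }
  NA_character_
}

#' Parse a "."-separated SMILES string into a list of molecules
#'
#' Atom-map annotations (`:n` inside brackets) are stripped by the parser.
#'
#' @param smiles molecule-set notation, molecules separated by ".".
#' @return list of `rxn_mol`.
#' @export
parse_molecule_set <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  lapply(parts, parse_smiles)
}

#' Number of connected components of a molecule object
#' @param mol an `rxn_mol`.
#' @return integer component count.
#' @export
mol_components <- function(mol) {
  na <- mol$n_atoms
  if (na == 0L) return(0L)
  comp <- integer(na); cur <- 0L
  adj <- .adjacency_list(mol)
  for (root in seq_len(na)) {
    if (comp[root] > 0L) next
    cur <- cur + 1L
    st <- root; comp[root] <- cur
    while (length(st)) {
      v <- st[length(st)]; st <- st[-length(st)]
      for (w in adj[[v]]$nbr) if (comp[w] == 0L) { comp[w] <- cur; st <- c(st, w) }
    }
  }
  cur
}

.adjacency_list <- function(mol) {
  na <- mol$n_atoms
  adj <- replicate(na, list(nbr = integer(0), bond = integer(0)),
                   simplify = FALSE)
  for (b in seq_along(mol$a1)) {
    u <- mol$a1[b]; v <- mol$a2[b]
    adj[[u]]$nbr <- c(adj[[u]]$nbr, v); adj[[u]]$bond <- c(adj[[u]]$bond, b)
    adj[[v]]$nbr <- c(adj[[v]]$nbr, u); adj[[v]]$bond <- c(adj[[v]]$bond, b)
  }
  adj
}

#' Set of halogen element types present in a molecule
#' @param mol an `rxn_mol`.
#' @return character vector, subset of F, Cl, Br, I (sorted; may be empty).
#' @export
mol_halogen_set <- function(mol) {
  sort(intersect(unique(mol$elem), .HALOGENS))
}
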