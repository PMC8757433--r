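# Concrete molecules for template application. Same grammar as the pattern
# parser, but atoms are interpreted as structures: bracket atoms carry their
# explicit H count and charge, organic-subset atoms get implicit hydrogens
# from a fixed-valence model (B3 C4 N3 O2 P3 S2, halogens 1; aromatic atoms
# reserve one valence unit for the ring; positive charge on N/P adds one
# bonding slot, negative charge removes one).

.VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
              F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L)

.BOND_ORDER <- c("-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                 "/" = 1L, "\\" = 1L, "~" = 1L)

.fill_hydrogens <- function(symbol, aromatic, charge, bond_order_sum) {
  val <- .VALENCE[symbol]
  if (is.na(val)) return(0L)
  adj <- 0L
  if (charge > 0L && symbol %in% c("N", "P", "B")) adj <- charge
  if (charge < 0L) adj <- charge
  max(0L, val + adj - bond_order_sum - if (isTRUE(aromatic)) 1L else 0L)
}

.mol_bond_order_sums <- function(atoms, bonds) {
  n <- length(atoms)
  s <- integer(n)
  if (nrow(bonds) > 0L) {
    ord <- .BOND_ORDER[bonds$b]
    for (r in seq_len(nrow(bonds))) {
      s[bonds$i[r]] <- s[bonds$i[r]] + ord[r]
      s[bonds$j[r]] <- s[bonds$j[r]] + ord[r]
    }
  }
  s
}

# Resolve hydrogen counts on a parsed side graph: explicit counts from
# bracket atoms are kept, everything else is filled by valence.
.resolve_molecule <- function(side) {
  bos <- .mol_bond_order_sums(side$atoms, side$bonds)
  for (i in seq_along(side$atoms)) {
    a <- side$atoms[[i]]
    if (is.na(a$charge)) a$charge <- 0L
    if (is.na(a$hcount)) {
      a$hcount <- .fill_hydrogens(a$symbol, a$aromatic, a$charge, bos[i])
    }
    a$key <- .serialize_atom_query(a, with_map = FALSE)
    side$atoms[[i]] <- a
  }
  structure(side, class = "molecule")
}

#' Parse a molecule from SMILES
#'
#' Accepts the same restricted grammar as the template parser; bracket atoms
#' must be fully specified (their H count defaults to 0, SMILES semantics),
#' organic-subset atoms receive implicit hydrogens from the package's
#' fixed-valence model. Multi-fragment input (dots) is allowed.
#'
#' @param smiles a SMILES string
#' @return an object of class `molecule` (atoms with resolved `hcount` and
#'   `charge`, bonds, fragment ids)
#' @examples
#' m <- parse_molecule("CC(=O)OC")
#' vapply(m$atoms, function(a) a$hcount, integer(1))
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  # note: bracket atoms without an explicit H count are valence-filled like
  # bare atoms (so "[C:1]C" means methyl-CH3); an explicit Hn always wins
  .resolve_molecule(.parse_side(smiles))
}

# Structure properties of molecule atoms for the matcher.
.molecule_props <- function(mol) {
  n <- length(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0L)
    deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
  lapply(seq_len(n), function(i) {
    a <- mol$atoms[[i]]
    list(symbol = a$symbol, aromatic = isTRUE(a$aromatic),
         charge = a$charge, hcount = a$hcount,
         degree = as.integer(deg[i]), conn = as.integer(deg[i]),
         chiral = a$chiral, map = a$map)
  })
}

# View a molecule as a one-sided condensed graph so the WL/IR machinery can
# rank its atoms.
.mol_as_condensed <- function(mol) {
  n <- length(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0L)
    deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
  edges <- if (nrow(mol$bonds) > 0L) {
    data.frame(i = mol$bonds$i, j = mol$bonds$j, side = "l", b = mol$bonds$b)
  } else {
    data.frame(i = integer(0), j = integer(0), side = character(0), b = character(0))
  }
  structure(list(n = n, lq = mol$atoms, rq = vector("list", n),
                 ldeg = as.integer(deg), rdeg = integer(n),
                 map = integer(n), lidx = seq_len(n), ridx = rep(NA_integer_, n),
                 edges = edges),
            class = "condensed_graph")
}

# SMILES emission of one molecule component under a ranking. Bare-atom form
# is used when reparsing would reconstruct the same H count.
.write_molecule_atoms <- function(mol, rank, comp_atoms) {
  sub <- list(atoms = mol$atoms[comp_atoms],
              bonds = mol$bonds[mol$bonds$i %in% comp_atoms &
                                mol$bonds$j %in% comp_atoms, , drop = FALSE])
  sub$bonds$i <- match(sub$bonds$i, comp_atoms)
  sub$bonds$j <- match(sub$bonds$j, comp_atoms)
  bos <- .mol_bond_order_sums(sub$atoms, sub$bonds)
  token <- function(k) {
    a <- sub$atoms[[k]]
    bare_ok <- a$symbol %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I") &&
      a$charge == 0L && is.na(a$chiral) && !is.na(a$aromatic) &&
      a$hcount == .fill_hydrogens(a$symbol, a$aromatic, 0L, bos[k])
    if (bare_ok) {
      if (isTRUE(a$aromatic)) tolower(a$symbol) else a$symbol
    } else {
      parts <- if (isTRUE(a$aromatic)) tolower(a$symbol) else a$symbol
      if (!is.na(a$chiral)) parts <- paste0(parts, a$chiral)
      if (a$hcount > 0L) parts <- paste0(parts, "H", if (a$hcount > 1L) a$hcount else "")
      if (a$charge != 0L) {
        parts <- paste0(parts, if (a$charge > 0L) "+" else "-",
                        if (abs(a$charge) > 1L) abs(a$charge) else "")
      }
      paste0("[", parts, "]")
    }
  }
  .write_mol_dfs(sub, rank[comp_atoms], token)
}

.write_mol_dfs <- function(sub, rank, token) {
  n <- length(sub$atoms)
  adj <- vector("list", n)
  if (nrow(sub$bonds) > 0L) {
    for (r in seq_len(nrow(sub$bonds))) {
      i <- sub$bonds$i[r]; j <- sub$bonds$j[r]
      adj[[i]] <- rbind(adj[[i]], c(j, r))
      adj[[j]] <- rbind(adj[[j]], c(i, r))
    }
  }
  start <- which.min(rank)
  seen <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  closure_at <- vector("list", n)
  n_closures <- 0L
  edge_used <- rep(FALSE, max(1L, nrow(sub$bonds)))
  dfs1 <- function(v) {
    seen[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible(NULL))
    for (k in order(rank[nb[, 1L]])) {
      u <- nb[k, 1L]; er <- nb[k, 2L]
      if (edge_used[er]) next
      edge_used[er] <<- TRUE
      if (!seen[u]) {
        parent[u] <<- v
        children[[v]] <<- c(children[[v]], u)
        dfs1(u)
      } else {
        n_closures <<- n_closures + 1L
        d <- n_closures; bsym <- sub$bonds$b[er]
        closure_at[[v]] <<- rbind(closure_at[[v]], c(d, bsym))
        closure_at[[u]] <<- rbind(closure_at[[u]], c(d, bsym))
      }
    }
    invisible(NULL)
  }
  dfs1(start)
  bond_sym <- function(v, u) {
    nb <- adj[[v]]
    sub$bonds$b[nb[nb[, 1L] == u, 2L][1]]
  }
  emit <- function(v) {
    s <- token(v)
    cl <- closure_at[[v]]
    if (!is.null(cl)) {
      for (k in order(as.integer(cl[, 1L]))) {
        d <- as.integer(cl[k, 1L])
        tok <- if (d > 9L) sprintf("%%%02d", d) else as.character(d)
        s <- paste0(s, cl[k, 2L], tok)
      }
    }
    ch <- children[[v]]
    if (!is.null(ch)) {
      for (k in seq_along(ch)) {
        u <- ch[k]
        piece <- paste0(bond_sym(v, u), emit(u))
        s <- if (k < length(ch)) paste0(s, "(", piece, ")") else paste0(s, piece)
      }
    }
    s
  }
  emit(start)
}

.mol_components <- function(mol) {
  n <- length(mol$atoms)
  comp <- integer(n)
  adj <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      adj[[mol$bonds$i[r]]] <- c(adj[[mol$bonds$i[r]]], mol$bonds$j[r])
      adj[[mol$bonds$j[r]]] <- c(adj[[mol$bonds$j[r]]], mol$bonds$i[r])
    }
  }
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cid <- cid + 1L
    queue <- v
    while (length(queue) > 0L) {
      x <- queue[1]; queue <- queue[-1]
      if (comp[x] > 0L) next
      comp[x] <- cid
      queue <- c(queue, adj[[x]][comp[adj[[x]]] == 0L])
    }
  }
  comp
}

#' Canonical SMILES of a molecule
#'
#' Atoms are ranked by WL refinement plus individualization-refinement on the
#' molecular graph (features: element, aromaticity, charge, H count, degree)
#' and emitted deterministically; multi-fragment molecules emit their
#' fragments in sorted order. Used wherever outcome molecule sets are
#' compared.
#'
#' @param mol a `molecule` or SMILES string
#' @return a single canonical SMILES string (fragments dot-joined, sorted)
#' @examples
#' canonical_smiles("OC(C)=O") == canonical_smiles("CC(O)=O")
#' @export
canonical_smiles <- function(mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(mol, "molecule"))
  g <- .mol_as_condensed(mol)
  p <- wl_refine(initial_labels(g), g)
  bt <- break_ties(p, g)
  comp <- .mol_components(mol)
  pieces <- vapply(seq_len(max(comp)), function(ci) {
    .write_molecule_atoms(mol, bt$rank, which(comp == ci))
  }, character(1))
  paste(sort(pieces, method = "radix"), collapse = ".")
}
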