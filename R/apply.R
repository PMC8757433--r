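# Template application: match the template's pattern side (lhs) against a
# query molecule and rewrite the matched substructure according to the other
# side. Each distinct substructure embedding yields one candidate outcome
# molecule set; sets are deduplicated by canonical SMILES.

# Rewrite one embedding. Returns a molecule (possibly multi-fragment) or NULL
# when the edit degenerates (e.g. everything deleted).
.rewrite_embedding <- function(t, mol, emb) {
  lmap <- .side_maps(t$lhs); rmap <- .side_maps(t$rhs)
  n0 <- length(mol$atoms)
  atoms <- mol$atoms
  bonds <- mol$bonds
  # drop every molecule bond matched by an lhs bond (the transformation
  # rewrites bonding among matched atoms; unmatched ring bonds survive)
  if (nrow(t$lhs$bonds) > 0L) {
    for (r in seq_len(nrow(t$lhs$bonds))) {
      a <- emb[t$lhs$bonds$i[r]]; b <- emb[t$lhs$bonds$j[r]]
      hit <- (bonds$i == min(a, b)) & (bonds$j == max(a, b))
      bonds <- bonds[!hit, , drop = FALSE]
    }
  }
  # atom bookkeeping: lhs atoms whose map survives on rhs are edited in
  # place; lhs atoms without an rhs partner are deleted; rhs-only atoms are
  # created fresh
  rhs_target <- integer(length(t$rhs$atoms))   # rhs atom -> molecule atom id
  delete <- logical(n0)
  for (i in seq_along(t$lhs$atoms)) {
    m <- lmap[i]
    if (m == 0L || !(m %in% rmap)) delete[emb[i]] <- TRUE
  }
  for (j in seq_along(t$rhs$atoms)) {
    m <- rmap[j]
    if (m > 0L && m %in% lmap) {
      tgt <- emb[which(lmap == m)]
      q <- t$rhs$atoms[[j]]
      a <- atoms[[tgt]]
      if (!is.na(q$charge)) a$charge <- q$charge
      a$chiral <- q$chiral
      a$hcount <- NA_integer_  # refill by valence after the edit
      atoms[[tgt]] <- a
      rhs_target[j] <- tgt
    } else {
      q <- t$rhs$atoms[[j]]
      atoms[[length(atoms) + 1L]] <- .new_atom_query(
        q$symbol,
        aromatic = if (is.na(q$aromatic)) FALSE else q$aromatic,
        charge = if (is.na(q$charge)) 0L else q$charge,
        hcount = q$hcount, chiral = q$chiral)
      rhs_target[j] <- length(atoms)
    }
  }
  if (nrow(t$rhs$bonds) > 0L) {
    for (r in seq_len(nrow(t$rhs$bonds))) {
      a <- rhs_target[t$rhs$bonds$i[r]]; b <- rhs_target[t$rhs$bonds$j[r]]
      bsym <- t$rhs$bonds$b[r]
      if (bsym == "~") bsym <- "-"
      bonds <- rbind(bonds, data.frame(i = min(a, b), j = max(a, b), b = bsym))
    }
  }
  keep <- c(!delete, rep(TRUE, length(atoms) - n0))
  if (!any(keep)) return(NULL)
  newid <- cumsum(keep)
  atoms <- atoms[keep]
  if (nrow(bonds) > 0L) {
    ok <- keep[bonds$i] & keep[bonds$j]
    bonds <- bonds[ok, , drop = FALSE]
    bonds$i <- newid[bonds$i]; bonds$j <- newid[bonds$j]
  }
  for (i in seq_along(atoms)) atoms[[i]]$map <- 0L
  side <- list(atoms = atoms, bonds = bonds, frag = rep(1L, length(atoms)))
  # refill hydrogens on edited atoms (hcount NA) under the new bonding
  .resolve_molecule_after_edit(side)
}

.resolve_molecule_after_edit <- function(side) {
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

#' Apply a template to a query molecule
#'
#' Matches the template's pattern side against the molecule and rewrites each
#' substructure embedding, producing one outcome molecule set (the precursors
#' for a retro template, the products for a forward one) per embedding.
#' Outcome sets are deduplicated by canonical SMILES; a template that matches
#' nowhere is inapplicable. Engine errors on individual templates are caught
#' and reported as inapplicable with a warning, so batch evaluation is never
#' interrupted.
#'
#' @param t `rxn_template` or template string
#' @param mol `molecule` or SMILES string
#' @param max_embeddings cap on enumerated substructure embeddings
#' @return object of class `application_outcome`: `template` (raw string),
#'   `query` (canonical SMILES), `outcomes` (list of character vectors of
#'   canonical SMILES, each sorted), `applicable`
#' @examples
#' t <- "[C:1](=[O:2])[O:3][C:4]>>[O][C:1]=[O:2].[O:3][C:4]"
#' apply_template(t, "CC(=O)OC")$outcomes
#' @export
apply_template <- function(t, mol, max_embeddings = 64L) {
  if (is.character(t)) t <- parse_template(t)
  if (is.character(mol)) mol <- parse_molecule(mol)
  out <- tryCatch({
    embs <- .subgraph_embeddings(t$lhs, .molecule_props(mol),
                                 .side_adjacency(mol), limit = max_embeddings)
    sets <- list()
    seen <- character(0)
    for (emb in embs) {
      res <- .rewrite_embedding(t, mol, emb)
      if (is.null(res)) next
      comp <- .mol_components(res)
      smis <- vapply(seq_len(max(comp)), function(ci) {
        idx <- which(comp == ci)
        sub <- structure(list(atoms = res$atoms[idx],
                              bonds = {
                                bb <- res$bonds[res$bonds$i %in% idx &
                                                res$bonds$j %in% idx, , drop = FALSE]
                                bb$i <- match(bb$i, idx); bb$j <- match(bb$j, idx)
                                bb
                              },
                              frag = rep(1L, length(idx))), class = "molecule")
        canonical_smiles(sub)
      }, character(1))
      smis <- sort(smis, method = "radix")
      key <- paste(smis, collapse = ".")
      if (!key %in% seen) {
        seen <- c(seen, key)
        sets[[length(sets) + 1L]] <- smis
      }
    }
    sets
  }, error = function(e) {
    warning(sprintf("template application failed (%s); treated as inapplicable: %s",
                    conditionMessage(e), t$raw_string), call. = FALSE)
    list()
  })
  structure(list(template = t$raw_string,
                 query = canonical_smiles(mol),
                 outcomes = out,
                 applicable = length(out) > 0L),
            class = "application_outcome")
}
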