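# Query-into-structure subgraph matching (VF2-style backtracking). The query
# is one side of a template; the target is either another template's side
# treated as a structure, or a concrete molecule. Compatibility is the usual
# SMARTS semantics restricted to And-conjunctions.

# Structure-side view of a pattern atom: unspecified primitives fall back to
# the defaults a query-built structure would have (charge 0, no chirality);
# an unspecified degree is the pattern-graph degree.
.pattern_as_structure <- function(side) {
  n <- length(side$atoms)
  deg <- integer(n)
  if (nrow(side$bonds) > 0L) {
    tb <- tabulate(c(side$bonds$i, side$bonds$j), nbins = n)
    deg <- as.integer(tb)
  }
  lapply(seq_len(n), function(i) {
    q <- side$atoms[[i]]
    list(symbol = q$symbol,
         aromatic = isTRUE(q$aromatic),
         charge = if (is.na(q$charge)) 0L else q$charge,
         hcount = q$hcount,                      # NA = unspecified
         degree = if (is.na(q$degree)) deg[i] else q$degree,
         conn = if (is.na(q$conn)) deg[i] else q$conn,
         chiral = q$chiral,
         map = q$map)
  })
}

# Does atomic query q admit an atom with structure properties p?
.atom_compatible <- function(q, p) {
  if (q$symbol != "*") {
    if (q$symbol != p$symbol) return(FALSE)
    if (!is.na(q$aromatic) && q$aromatic != p$aromatic) return(FALSE)
  }
  if (!is.na(q$charge) && q$charge != p$charge) return(FALSE)
  if (!is.na(q$hcount)) {
    if (is.na(p$hcount) || q$hcount != p$hcount) return(FALSE)
  }
  if (!is.na(q$degree) && q$degree != p$degree) return(FALSE)
  if (!is.na(q$conn) && q$conn != p$conn) return(FALSE)
  if (!is.na(q$chiral)) {
    if (is.na(p$chiral) || q$chiral != p$chiral) return(FALSE)
  }
  TRUE
}

.bond_compatible <- function(qb, tb) {
  qb == "~" || qb == tb || (qb == "-" && (tb == "/" || tb == "\\"))
}

.side_adjacency <- function(side) {
  n <- length(side$atoms)
  adj <- vector("list", n)
  if (nrow(side$bonds) > 0L) {
    at <- c(side$bonds$i, side$bonds$j)
    other <- c(side$bonds$j, side$bonds$i)
    b <- c(side$bonds$b, side$bonds$b)
    o <- order(at)
    runs <- split(seq_along(at)[o], at[o])
    for (k in names(runs)) {
      idx <- runs[[k]]
      adj[[as.integer(k)]] <- data.frame(nbr = other[idx], b = b[idx])
    }
  }
  adj
}

# Visit order: per query fragment, start at the highest-degree atom and grow
# by adjacency so every non-initial atom has a matched neighbour to anchor on.
.match_order <- function(side) {
  n <- length(side$atoms)
  adj <- .side_adjacency(side)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  placed <- rep(FALSE, n)
  ord <- integer(0)
  while (!all(placed)) {
    cand <- which(!placed)
    start <- cand[which.max(deg[cand])]
    queue <- start
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (placed[v]) next
      placed[v] <- TRUE
      ord <- c(ord, v)
      if (!is.null(adj[[v]])) queue <- c(queue, adj[[v]]$nbr[!placed[adj[[v]]$nbr]])
    }
  }
  ord
}

# Enumerate injective embeddings of query side into target side (target given
# as structure properties + its own adjacency). Returns a list of integer
# vectors (query atom -> target atom), at most `limit` of them.
.subgraph_embeddings <- function(qside, tprops, tadj, limit = 1L) {
  nq <- length(qside$atoms)
  nt <- length(tprops)
  if (nq > nt) return(list())
  qadj <- .side_adjacency(qside)
  ord <- .match_order(qside)
  tdeg <- vapply(tadj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  qdeg <- vapply(qadj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  cand0 <- lapply(seq_len(nq), function(qi) {
    which(vapply(seq_len(nt), function(ti) {
      tdeg[ti] >= qdeg[qi] && .atom_compatible(qside$atoms[[qi]], tprops[[ti]])
    }, logical(1)))
  })
  out <- list()
  assign_ <- rep(NA_integer_, nq)
  used <- rep(FALSE, nt)
  rec <- function(pos) {
    if (length(out) >= limit) return(invisible(NULL))
    if (pos > nq) {
      out[[length(out) + 1L]] <<- assign_
      return(invisible(NULL))
    }
    qi <- ord[pos]
    for (ti in cand0[[qi]]) {
      if (used[ti]) next
      ok <- TRUE
      qa <- qadj[[qi]]
      if (!is.null(qa)) {
        for (r in seq_len(nrow(qa))) {
          qn <- qa$nbr[r]
          if (!is.na(assign_[qn])) {
            ta <- tadj[[ti]]
            hit <- FALSE
            if (!is.null(ta)) {
              rows <- which(ta$nbr == assign_[qn])
              if (length(rows) > 0L && .bond_compatible(qa$b[r], ta$b[rows[1]]))
                hit <- TRUE
            }
            if (!hit) { ok <- FALSE; break }
          }
        }
      }
      if (!ok) next
      assign_[qi] <<- ti; used[ti] <<- TRUE
      rec(pos + 1L)
      assign_[qi] <<- NA_integer_; used[ti] <<- FALSE
      if (length(out) >= limit) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L)
  out
}
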