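# Independent brute-force oracles. These deliberately avoid the package's
# WL/individualization and VF2 code paths: isomorphism and automorphisms are
# found by exhaustive feature-pruned permutation search on condensed graphs
# (tractable at <= 8 nodes), and cluster survivors by exhaustive all-pairs
# pruning.

oracle_node_keys <- function(g) {
  vapply(seq_len(g$n), function(v) {
    paste(g$ldeg[v], g$rdeg[v],
          if (is.null(g$lq[[v]])) "." else g$lq[[v]]$key,
          if (is.null(g$rq[[v]])) "." else g$rq[[v]]$key,
          sep = "|")
  }, character(1))
}

oracle_edge_env <- function(g) {
  e <- new.env(parent = emptyenv())
  if (nrow(g$edges) > 0L) {
    lo <- pmin(g$edges$i, g$edges$j); hi <- pmax(g$edges$i, g$edges$j)
    for (k in paste(lo, hi, g$edges$side, g$edges$b, sep = "|")) e[[k]] <- TRUE
  }
  e
}

# All bijections ga -> gb that preserve node keys and side-tagged edges.
oracle_isomorphisms <- function(ga, gb, find_all = FALSE) {
  if (ga$n != gb$n || nrow(ga$edges) != nrow(gb$edges)) return(list())
  ka <- oracle_node_keys(ga); kb <- oracle_node_keys(gb)
  if (!identical(sort(ka), sort(kb))) return(list())
  eb <- oracle_edge_env(gb)
  # ga adjacency with side/bond
  ea <- vector("list", ga$n)
  if (nrow(ga$edges) > 0L) {
    for (r in seq_len(nrow(ga$edges))) {
      i <- ga$edges$i[r]; j <- ga$edges$j[r]
      sb <- c(ga$edges$side[r], ga$edges$b[r])
      ea[[i]] <- c(ea[[i]], list(c(j, sb)))
      ea[[j]] <- c(ea[[j]], list(c(i, sb)))
    }
  }
  found <- list()
  perm <- rep(NA_integer_, ga$n)
  used <- rep(FALSE, gb$n)
  rec <- function(v) {
    if (!find_all && length(found) > 0L) return(invisible(NULL))
    if (v > ga$n) {
      found[[length(found) + 1L]] <<- perm
      return(invisible(NULL))
    }
    for (w in which(kb == ka[v] & !used)) {
      ok <- TRUE
      for (inc in ea[[v]]) {
        u <- as.integer(inc[1])
        if (!is.na(perm[u])) {
          key <- paste(min(w, perm[u]), max(w, perm[u]), inc[2], inc[3], sep = "|")
          if (is.null(eb[[key]])) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      perm[v] <<- w; used[w] <<- TRUE
      rec(v + 1L)
      perm[v] <<- NA_integer_; used[w] <<- FALSE
    }
    invisible(NULL)
  }
  rec(1L)
  found
}

oracle_isomorphic <- function(ga, gb) {
  length(oracle_isomorphisms(ga, gb)) > 0L
}

# Orbit partition of a condensed graph from its full automorphism group.
oracle_orbits <- function(g) {
  autos <- oracle_isomorphisms(g, g, find_all = TRUE)
  parent <- seq_len(g$n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in autos) {
    for (v in seq_len(g$n)) {
      a <- find(v); b <- find(p[v])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(g$n), find, integer(1))
}

# Partition the condensed graphs of templates into isomorphism classes by
# exhaustive pairwise comparison.
oracle_iso_classes <- function(graphs) {
  n <- length(graphs)
  cls <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (cls[i] > 0L) next
    nxt <- nxt + 1L
    cls[i] <- nxt
    if (i < n) {
      for (j in seq((i + 1L), n)) {
        if (cls[j] == 0L && oracle_isomorphic(graphs[[i]], graphs[[j]])) {
          cls[j] <- nxt
        }
      }
    }
  }
  cls
}

# Exhaustive all-pairs pruning of a canonical-deduplicated member list:
# survivors are the members not properly subsumed by any other member.
oracle_survivors <- function(members) {
  canon <- vapply(members, function(t) canonicalize(t)$canonical_string,
                  character(1))
  keep <- vapply(seq_along(members), function(i) {
    !any(vapply(seq_along(members), function(j) {
      j != i && canon[j] != canon[i] && subsumes(members[[j]], members[[i]])
    }, logical(1)))
  }, logical(1))
  sort(canon[keep])
}

same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
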