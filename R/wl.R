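# Weisfeiler-Lehman colour refinement and individualization-refinement
# tie-breaking on condensed graphs. Labels are small integers whose order is
# the cell order of the partition; all hashing is plain string ranking, so
# canonical forms are reproducible across sessions and machines.

.new_partition <- function(labels, iteration = 0L, stable = FALSE) {
  k <- max(labels)
  structure(list(labels = labels, n_cells = k, iteration = iteration,
                 discrete = k == length(labels), stable = stable),
            class = "wl_partition")
}

.compact_labels <- function(keys) {
  match(keys, sort(unique(keys), method = "radix"))
}

#' Initial WL node labels of a condensed graph
#'
#' Labels every node by its invariant tuple (left degree, right degree,
#' map-free left atomic SMARTS, map-free right atomic SMARTS); cells are
#' ordered by the radix order of those tuples, which fixes the initial
#' partition deterministically.
#'
#' @param g a `condensed_graph`
#' @return a `wl_partition`: integer `labels` (1..k, label order = cell
#'   order), `n_cells`, `iteration`, `discrete`, `stable`
#' @export
initial_labels <- function(g) {
  stopifnot(inherits(g, "condensed_graph"))
  .new_partition(.compact_labels(.cg_node_features(g)))
}

# One refinement sweep. The old label is the primary sort key, so cells can
# only split, never merge.
.refine_once <- function(labels, adj) {
  n <- length(labels)
  sig <- character(n)
  for (v in seq_len(n)) {
    nb <- adj$nbr[[v]]
    if (length(nb) == 0L) {
      sig[v] <- ""
    } else {
      parts <- paste0(adj$efeat[[v]], "#", formatC(labels[nb], width = 5, flag = "0"))
      sig[v] <- paste(sort(parts, method = "radix"), collapse = ",")
    }
  }
  keys <- paste0(formatC(labels, width = 5, flag = "0"), "/", sig)
  .compact_labels(keys)
}

#' Refine a WL partition to stability
#'
#' Iteratively relabels each node from its own label and the sorted multiset
#' of (side-tagged bond SMARTS, neighbour label) pairs until the partition is
#' stable, or at most |V| sweeps have run. Refinement is monotone: cells
#' split but never merge.
#'
#' @param p a `wl_partition` for `g`
#' @param g the `condensed_graph` the partition lives on
#' @return the refined, stable `wl_partition`
#' @export
wl_refine <- function(p, g) {
  stopifnot(inherits(p, "wl_partition"), inherits(g, "condensed_graph"))
  adj <- .cg_adjacency(g)
  labels <- p$labels
  iter <- p$iteration
  repeat {
    if (max(labels) == g$n) break
    if (iter >= g$n) break
    new_labels <- .refine_once(labels, adj)
    iter <- iter + 1L
    if (max(new_labels) == max(labels)) {  # refinement-only => unchanged
      labels <- new_labels
      return(.new_partition(labels, iter, stable = TRUE))
    }
    labels <- new_labels
  }
  .new_partition(labels, iter, stable = TRUE)
}

# Certificate of the condensed graph under a discrete labelling: node
# features in rank order plus the ranked, sorted edge list. Two discrete
# labellings yield equal certificates iff they differ by an automorphism, so
# minimizing the certificate makes the final ranking relabelling-invariant.
.cg_certificate <- function(g, feats, rank) {
  pos <- order(rank)
  node_part <- paste(feats[pos], collapse = ";")
  if (nrow(g$edges) > 0L) {
    ri <- rank[g$edges$i]; rj <- rank[g$edges$j]
    lo <- pmin(ri, rj); hi <- pmax(ri, rj)
    ek <- paste0(formatC(lo, width = 4, flag = "0"),
                 formatC(hi, width = 4, flag = "0"),
                 g$edges$side, g$edges$b)
    edge_part <- paste(sort(ek, method = "radix"), collapse = ";")
  } else {
    edge_part <- ""
  }
  paste0(node_part, ">>", edge_part)
}

.individualize <- function(labels, v) {
  l2 <- labels * 2L
  l2[v] <- l2[v] - 1L
  .compact_labels(formatC(l2, width = 6, flag = "0"))
}

#' Break remaining WL ties into a canonical node ranking
#'
#' Turns a stable (possibly non-discrete) WL partition into a bijective node
#' ranking by individualization-refinement: the first non-singleton cell in
#' cell order is split by individualizing each of its nodes in turn, the
#' partition is re-refined, and the branch whose discrete labelling yields
#' the lexicographically smallest graph certificate wins. Isomorphic inputs
#' therefore receive rankings that correspond under the isomorphism.
#'
#' If more than `budget` discrete branches would be explored (possible only
#' for highly symmetric graphs beyond the reach of 1-WL), the search stops
#' and a deterministic but not relabelling-invariant heuristic ranking is
#' returned with `nonunique_risk = TRUE`.
#'
#' @param p a stable `wl_partition`
#' @param g the `condensed_graph`
#' @param budget maximum number of discrete labellings to inspect
#' @return a list with `rank` (bijective integer ranking of nodes),
#'   `nonunique_risk` (logical), and `n_branches` explored
#' @export
break_ties <- function(p, g, budget = 64L) {
  stopifnot(inherits(p, "wl_partition"), inherits(g, "condensed_graph"))
  adj <- .cg_adjacency(g)
  feats <- .cg_node_features(g)
  labels <- p$labels
  if (max(labels) == g$n) {
    return(list(rank = labels, nonunique_risk = FALSE, n_branches = 1L))
  }
  best_cert <- NULL
  best_rank <- NULL
  leaves <- 0L
  overflow <- FALSE
  refine_to_stable <- function(lab) {
    repeat {
      if (max(lab) == length(lab)) return(lab)
      nl <- .refine_once(lab, adj)
      if (max(nl) == max(lab)) return(nl)
      lab <- nl
    }
  }
  recurse <- function(lab) {
    if (overflow) return(invisible(NULL))
    if (max(lab) == g$n) {
      leaves <<- leaves + 1L
      if (leaves > budget) { overflow <<- TRUE; return(invisible(NULL)) }
      cert <- .cg_certificate(g, feats, lab)
      if (is.null(best_cert) || cert < best_cert) {
        best_cert <<- cert
        best_rank <<- lab
      }
      return(invisible(NULL))
    }
    counts <- tabulate(lab)
    target <- which(counts > 1L)[1]
    for (v in which(lab == target)) {
      recurse(refine_to_stable(.individualize(lab, v)))
      if (overflow) break
    }
    invisible(NULL)
  }
  recurse(labels)
  if (overflow || is.null(best_rank)) {
    # graceful degradation: deterministic for a fixed input string, but not
    # guaranteed invariant under relabelling -- hence the flag
    o <- order(labels, seq_len(g$n))
    rank <- integer(g$n); rank[o] <- seq_len(g$n)
    return(list(rank = rank, nonunique_risk = TRUE, n_branches = leaves))
  }
  list(rank = best_rank, nonunique_risk = FALSE, n_branches = leaves)
}
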