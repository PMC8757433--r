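# Condensed graph: the two sides of a template merged into one graph by
# shared atom-map number. Mapped atoms present on both sides become a single
# node carrying both queries; unmapped (or one-sided) atoms stay singleton
# nodes on their side. Edges keep a side tag so broken/formed bonds remain
# distinguishable.

#' Build the condensed graph of a template
#'
#' Merges the left- and right-hand side pattern graphs of a template into one
#' graph in which atoms sharing a nonzero atom-map number are a single node.
#' The condensed graph is the substrate of canonicalization: node features
#' concatenate the (map-stripped) atomic SMARTS and pattern-graph degree of
#' both sides, and every bond carries its side of origin, so a bond broken by
#' the transformation appears as a left-tagged edge with no right counterpart.
#'
#' @param t an `rxn_template`
#' @return an object of class `condensed_graph`: a list with `n` (node
#'   count), `lq`/`rq` (per-node atom query or `NULL`), `ldeg`/`rdeg`
#'   (pattern-graph degrees), `map` (original map number, 0 for unmapped),
#'   `lidx`/`ridx` (per-node index of the atom within its side, `NA` when the
#'   node is absent from that side), and `edges` (data.frame `i`, `j`,
#'   `side` in `"l"`/`"r"`, `b` bond string)
#' @examples
#' t <- parse_template("[C:1][Br]>>[C:1][N:2]")
#' g <- build_condensed_graph(t)
#' g$n  # C1 merged; Br and N2 one-sided
#' @export
build_condensed_graph <- function(t) {
  stopifnot(inherits(t, "rxn_template"))
  lmap <- .side_maps(t$lhs); rmap <- .side_maps(t$rhs)
  shared <- intersect(lmap[lmap > 0L], rmap[rmap > 0L])
  nodes_map <- sort(shared)
  # one-sided atoms: unmapped, or mapped with no partner on the other side
  l_only <- which(!(lmap %in% nodes_map) | lmap == 0L)
  r_only <- which(!(rmap %in% nodes_map) | rmap == 0L)
  n <- length(nodes_map) + length(l_only) + length(r_only)
  lq <- vector("list", n); rq <- vector("list", n)
  lidx <- rep(NA_integer_, n); ridx <- rep(NA_integer_, n)
  map <- integer(n)
  k <- 0L
  for (m in nodes_map) {
    k <- k + 1L
    li <- which(lmap == m); ri <- which(rmap == m)
    lq[[k]] <- t$lhs$atoms[[li]]; rq[[k]] <- t$rhs$atoms[[ri]]
    lidx[k] <- li; ridx[k] <- ri; map[k] <- m
  }
  for (li in l_only) {
    k <- k + 1L
    lq[[k]] <- t$lhs$atoms[[li]]; lidx[k] <- li; map[k] <- lmap[li]
  }
  for (ri in r_only) {
    k <- k + 1L
    rq[[k]] <- t$rhs$atoms[[ri]]; ridx[k] <- ri; map[k] <- rmap[ri]
  }
  node_of_l <- match(seq_along(t$lhs$atoms), lidx)
  node_of_r <- match(seq_along(t$rhs$atoms), ridx)
  nl <- nrow(t$lhs$bonds); nr <- nrow(t$rhs$bonds)
  edges <- data.frame(
    i = c(node_of_l[t$lhs$bonds$i], node_of_r[t$rhs$bonds$i]),
    j = c(node_of_l[t$lhs$bonds$j], node_of_r[t$rhs$bonds$j]),
    side = rep(c("l", "r"), c(nl, nr)),
    b = c(t$lhs$bonds$b, t$rhs$bonds$b))
  sw <- edges$i > edges$j
  if (any(sw)) {
    tmp <- edges$i[sw]; edges$i[sw] <- edges$j[sw]; edges$j[sw] <- tmp
  }
  ldeg <- integer(n); rdeg <- integer(n)
  le <- edges$side == "l"
  if (any(le)) {
    tb <- table(factor(c(edges$i[le], edges$j[le]), levels = seq_len(n)))
    ldeg <- as.integer(tb)
  }
  if (any(!le)) {
    tb <- table(factor(c(edges$i[!le], edges$j[!le]), levels = seq_len(n)))
    rdeg <- as.integer(tb)
  }
  structure(list(n = n, lq = lq, rq = rq, ldeg = ldeg, rdeg = rdeg,
                 map = map, lidx = lidx, ridx = ridx, edges = edges),
            class = "condensed_graph")
}

# Per-node incidence list of (other endpoint, "side|bond") used by WL.
.cg_adjacency <- function(g) {
  nbr <- vector("list", g$n)
  efeat <- vector("list", g$n)
  if (nrow(g$edges) > 0L) {
    ef <- paste0(g$edges$side, g$edges$b)
    at <- c(g$edges$i, g$edges$j)
    other <- c(g$edges$j, g$edges$i)
    feat <- c(ef, ef)
    o <- order(at)
    runs <- split(seq_along(at)[o], at[o])
    for (k in names(runs)) {
      v <- as.integer(k)
      nbr[[v]] <- other[runs[[k]]]
      efeat[[v]] <- feat[runs[[k]]]
    }
  }
  list(nbr = nbr, efeat = efeat)
}

# Initial node feature string: both-side degrees + both-side map-free atomic
# SMARTS ("." marks an absent side).
.cg_node_features <- function(g) {
  vapply(seq_len(g$n), function(v) {
    lk <- if (is.null(g$lq[[v]])) "." else g$lq[[v]]$key
    rk <- if (is.null(g$rq[[v]])) "." else g$rq[[v]]$key
    paste(g$ldeg[v], g$rdeg[v], lk, rk, sep = "|")
  }, character(1))
}
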