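# Canonical template strings: renumber atom maps by canonical rank, emit each
# side by a rank-driven depth-first traversal with explicit bonds and
# deterministic ring-closure digits, sort fragments lexicographically.

# Emit one side of the template under a bijective node ranking.
# side: "l" or "r"; newmap: per-node replacement atom map (0 = none).
.write_side <- function(t, g, rank, newmap, side) {
  idx <- if (side == "l") g$lidx else g$ridx
  qs <- if (side == "l") g$lq else g$rq
  present <- which(!is.na(idx))
  if (length(present) == 0L) return("")
  es <- g$edges[g$edges$side == side, , drop = FALSE]
  adj <- vector("list", g$n)
  if (nrow(es) > 0L) {
    for (r in seq_len(nrow(es))) {
      i <- es$i[r]; j <- es$j[r]
      adj[[i]] <- rbind(adj[[i]], c(j, r))
      adj[[j]] <- rbind(adj[[j]], c(i, r))
    }
  }
  visited <- rep(FALSE, g$n)
  frag_strings <- character(0)
  atom_token <- function(v) {
    q <- qs[[v]]
    q$map <- newmap[v]
    .serialize_atom_query(q, with_map = TRUE)
  }
  for (root_pool in list(present)) {
    remaining <- root_pool
    while (length(remaining) > 0L) {
      start <- remaining[which.min(rank[remaining])]
      # pass 1: discover spanning tree (children by rank) and back edges
      parent <- rep(NA_integer_, g$n)
      children <- vector("list", g$n)
      closure_at <- vector("list", g$n)  # v -> rbind(digit, bond)
      n_closures <- 0L
      comp <- integer(0)
      seen <- rep(FALSE, g$n)
      edge_used <- rep(FALSE, max(1L, nrow(es)))
      dfs1 <- function(v) {
        seen[v] <<- TRUE
        comp <<- c(comp, v)
        nb <- adj[[v]]
        if (is.null(nb)) return(invisible(NULL))
        ord <- order(rank[nb[, 1L]])
        for (k in ord) {
          u <- nb[k, 1L]; er <- nb[k, 2L]
          if (edge_used[er]) next
          edge_used[er] <<- TRUE
          if (!seen[u]) {
            parent[u] <<- v
            children[[v]] <<- c(children[[v]], u)
            dfs1(u)
          } else {
            n_closures <<- n_closures + 1L
            d <- n_closures
            bsym <- es$b[er]
            closure_at[[v]] <<- rbind(closure_at[[v]], c(d, bsym))
            closure_at[[u]] <<- rbind(closure_at[[u]], c(d, bsym))
          }
        }
        invisible(NULL)
      }
      dfs1(start)
      bond_sym <- function(v, u) {
        nb <- adj[[v]]
        er <- nb[nb[, 1L] == u, 2L][1]
        es$b[er]
      }
      emit <- function(v) {
        s <- atom_token(v)
        cl <- closure_at[[v]]
        if (!is.null(cl)) {
          o <- order(as.integer(cl[, 1L]))
          for (k in o) {
            d <- as.integer(cl[k, 1L])
            tok <- if (d > 9L) sprintf("%%%02d", d) else as.character(d)
            s <- paste0(s, cl[k, 2L], tok)
          }
        }
        ch <- children[[v]]
        if (!is.null(ch) && length(ch) > 0L) {
          for (k in seq_along(ch)) {
            u <- ch[k]
            sub <- paste0(bond_sym(v, u), emit(u))
            s <- if (k < length(ch)) paste0(s, "(", sub, ")")
                 else paste0(s, sub)
          }
        }
        s
      }
      frag_strings <- c(frag_strings, emit(start))
      visited[comp] <- TRUE
      remaining <- setdiff(remaining, comp)
    }
  }
  paste(sort(frag_strings, method = "radix"), collapse = ".")
}

# Full template string under a ranking: maps renumbered 1..k in rank order.
.write_template <- function(t, g, rank) {
  mapped <- which(g$map > 0L)
  newmap <- integer(g$n)
  if (length(mapped) > 0L) {
    newmap[mapped[order(rank[mapped])]] <- seq_along(mapped)
  }
  paste0(.write_side(t, g, rank, newmap, "l"), ">>",
         .write_side(t, g, rank, newmap, "r"))
}

#' Canonicalize a reaction template
#'
#' Computes the unique string representation of the chemical transformation a
#' template encodes: the condensed graph is ranked by Weisfeiler-Lehman
#' refinement plus individualization-refinement tie-breaking, atom maps are
#' renumbered 1..k in rank order, atoms are emitted in a rank-driven
#' traversal and fragments sorted, so that any two strings describing the
#' same transformation (up to map renumbering and atom write order)
#' canonicalize identically.
#'
#' @param t an `rxn_template` (or a template string, parsed with defaults)
#' @param budget individualization budget handed to [break_ties()]
#' @return an object of class `canonical_form`: `canonical_string`, `rank`
#'   (per condensed-graph node), `nonunique_risk`
#' @examples
#' a <- canonicalize(parse_template("[C:1][O:2]>>[C:1][Br].[O:2]"))
#' b <- canonicalize(parse_template("[O:7][C:3]>>[O:7].[Br][C:3]"))
#' identical(a$canonical_string, b$canonical_string)
#' @export
canonicalize <- function(t, budget = 64L) {
  if (is.character(t)) t <- parse_template(t)
  stopifnot(inherits(t, "rxn_template"))
  g <- build_condensed_graph(t)
  p <- wl_refine(initial_labels(g), g)
  bt <- break_ties(p, g, budget = budget)
  structure(list(canonical_string = .write_template(t, g, bt$rank),
                 rank = bt$rank,
                 nonunique_risk = bt$nonunique_risk),
            class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("<canonical_form>", x$canonical_string,
      if (x$nonunique_risk) "(nonunique risk)" else "", "\n")
  invisible(x)
}

#' Merge duplicate templates by canonical form
#'
#' Groups templates whose canonical strings coincide (i.e. that encode the
#' same chemical transformation) and unions their provenance reaction ids.
#' The total multiset of reaction ids is conserved.
#'
#' @param ts list of `rxn_template`
#' @param budget tie-breaking budget, see [canonicalize()]
#' @return named list: canonical string -> merged `rxn_template` (reparsed
#'   from the canonical string, with unioned `reaction_ids`)
#' @export
deduplicate <- function(ts, budget = 64L) {
  stopifnot(is.list(ts))
  canon <- vapply(ts, function(t) canonicalize(t, budget)$canonical_string,
                  character(1))
  out <- list()
  for (cs in sort(unique(canon), method = "radix")) {
    members <- ts[canon == cs]
    ids <- unlist(lapply(members, function(t) t$reaction_ids))
    merged <- suppressWarnings(parse_template(
      cs,
      direction = members[[1]]$direction,
      radius_tag = members[[1]]$radius_tag,
      reaction_ids = ids))
    out[[cs]] <- merged
  }
  out
}

#' Canonicalize a template table
#'
#' Data-frame front end used by the command line: adds `canonical_template`,
#' `nonunique_risk` and `class_id` columns to a table with a template-string
#' column.
#'
#' @param df data.frame of template records
#' @param column name of the column holding template strings
#' @param budget tie-breaking budget
#' @return `df` with the three added columns; `class_id` numbers canonical
#'   classes in order of first appearance
#' @export
canonicalize_templates <- function(df, column = "template", budget = 64L) {
  stopifnot(is.data.frame(df), column %in% names(df))
  forms <- lapply(df[[column]], function(s) canonicalize(s, budget))
  df$canonical_template <- vapply(forms, `[[`, character(1), "canonical_string")
  df$nonunique_risk <- vapply(forms, `[[`, logical(1), "nonunique_risk")
  df$class_id <- match(df$canonical_template, unique(df$canonical_template))
  df
}
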