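# Hierarchical correction: cluster templates by their corrected lower-radius
# parent, detect subsumption by subgraph isomorphism within each cluster,
# keep only the most general (exclusive) templates and record a replacement
# map from every pruned template to its surviving root.

#' Does one template subsume another?
#'
#' `general` subsumes `specific` when the query graph of each side of
#' `general` embeds as a substructure into the corresponding side of
#' `specific` treated as a structure (query-built atoms with default charge 0
#' and pattern-graph degrees). Every molecule matched by `specific` is then
#' also matched by `general`, so the two templates are nonexclusive and only
#' the general one needs to be kept.
#'
#' Intended for same-cluster pairs, where the shared parent guarantees both
#' encode the same transformation core and an atom-map cross-check is
#' unnecessary; set `strict_maps = TRUE` (recommended for template sets from
#' a foreign extractor) to additionally require a pair of side embeddings
#' that are consistent on atom-map numbers.
#'
#' @param general,specific `rxn_template` objects (or template strings)
#' @param strict_maps verify map-consistent left/right embeddings?
#' @return `TRUE` iff `general` subsumes `specific` (reflexive)
#' @examples
#' lin <- parse_template("[C:1][O:2][C:3]>>[C:1][O:2].[C:3]")
#' bra <- parse_template("[C:1][O:2][C:3]C>>[C:1][O:2].[C:3]C")
#' subsumes(lin, bra)   # TRUE: linear context is the more general pattern
#' subsumes(bra, lin)   # FALSE
#' @export
subsumes <- function(general, specific, strict_maps = FALSE) {
  if (is.character(general)) general <- parse_template(general)
  if (is.character(specific)) specific <- parse_template(specific)
  stopifnot(inherits(general, "rxn_template"), inherits(specific, "rxn_template"))
  limit <- if (strict_maps) 256L else 1L
  embs <- list()
  for (side in c("lhs", "rhs")) {
    qs <- general[[side]]
    ts <- specific[[side]]
    if (length(qs$atoms) > length(ts$atoms)) return(FALSE)
    if (nrow(qs$bonds) > nrow(ts$bonds)) return(FALSE)
    e <- .subgraph_embeddings(qs, .pattern_as_structure(ts),
                              .side_adjacency(ts), limit = limit)
    if (length(e) == 0L) return(FALSE)
    embs[[side]] <- e
  }
  if (!strict_maps) return(TRUE)
  glm <- .side_maps(general$lhs); grm <- .side_maps(general$rhs)
  slm <- .side_maps(specific$lhs); srm <- .side_maps(specific$rhs)
  shared <- intersect(glm[glm > 0L], grm[grm > 0L])
  for (el in embs$lhs) {
    for (er in embs$rhs) {
      ok <- TRUE
      for (m in shared) {
        x <- slm[el[which(glm == m)]]
        y <- srm[er[which(grm == m)]]
        if (x == 0L || x != y) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

#' Cluster templates by their lower-specificity parent
#'
#' Groups templates at the working radius by the corrected canonical parent
#' template of their provenance reactions. A template whose reactions map to
#' more than one parent class is split into per-cluster copies with a
#' warning (extraction determinism normally prevents this).
#'
#' @param specific list of `rxn_template` at the radius being corrected
#' @param parent_of named character vector: reaction id -> corrected parent
#'   canonical template string
#' @return list of clusters, each `list(key = parent string, members = list
#'   of templates)`, ordered by parent string
#' @export
cluster_by_parent <- function(specific, parent_of) {
  stopifnot(is.list(specific), is.character(parent_of), !is.null(names(parent_of)))
  buckets <- list()
  for (t in specific) {
    if (length(t$reaction_ids) == 0L)
      stop("template without provenance reaction ids cannot be clustered")
    missing <- setdiff(t$reaction_ids, names(parent_of))
    if (length(missing) > 0L)
      stop(sprintf("no parent assignment for reaction id(s): %s",
                   paste(missing, collapse = ", ")))
    parents <- parent_of[t$reaction_ids]
    for (p in unique(parents)) {
      tp <- t
      tp$reaction_ids <- t$reaction_ids[parents == p]
      buckets[[p]] <- c(buckets[[p]], list(tp))
    }
    if (length(unique(parents)) > 1L)
      warning(sprintf("template straddles %d parent classes; split per cluster: %s",
                      length(unique(parents)), t$raw_string), call. = FALSE)
  }
  keys <- sort(names(buckets), method = "radix")
  lapply(keys, function(k) list(key = k, members = buckets[[k]]))
}

.template_size <- function(t) {
  length(t$lhs$atoms) + length(t$rhs$atoms)
}

#' Build the exclusivity tree of one cluster
#'
#' Iterative insertion in ascending template size (ties by canonical string):
#' each new template is compared only against the current roots. A root that
#' subsumes it adopts it as a child; if it subsumes one or more roots it
#' absorbs them (and their subtrees, path-compressed) and becomes a root
#' itself; otherwise it opens a new root. On exit the roots are pairwise
#' incomparable and every non-root maps to the unique root that subsumes it.
#'
#' @param cluster a cluster from [cluster_by_parent()] (members are assumed
#'   canonical-deduplicated)
#' @param strict_maps passed to [subsumes()]
#' @return `list(key, roots, children, replacement)`: `roots` is a list of
#'   surviving templates; `children` maps a root's canonical string to the
#'   templates it absorbed; `replacement` is a named character vector
#'   (pruned canonical string -> surviving canonical string)
#' @export
build_tree <- function(cluster, strict_maps = FALSE) {
  members <- cluster$members
  canon <- vapply(members, function(t) canonicalize(t)$canonical_string, character(1))
  sizes <- vapply(members, .template_size, integer(1))
  ord <- order(sizes, canon, method = "radix")
  roots <- list()       # list of list(t = template, cs = canonical string)
  children <- list()    # root cs -> list of templates
  replacement <- character(0)
  for (k in ord) {
    t <- members[[k]]; cs <- canon[k]
    placed <- FALSE
    for (r in roots) {
      if (subsumes(r$t, t, strict_maps = strict_maps)) {
        children[[r$cs]] <- c(children[[r$cs]], list(t))
        replacement[cs] <- r$cs
        placed <- TRUE
        break
      }
    }
    if (placed) next
    absorbed <- vapply(roots, function(r) subsumes(t, r$t, strict_maps = strict_maps),
                       logical(1))
    if (any(absorbed)) {
      for (r in roots[absorbed]) {
        children[[cs]] <- c(children[[cs]], list(r$t), children[[r$cs]])
        replacement[r$cs] <- cs
        if (!is.null(children[[r$cs]])) {
          sub_cs <- names(replacement)[replacement == r$cs]
          replacement[sub_cs] <- cs      # path compression to the final root
          children[[r$cs]] <- NULL
        }
      }
      roots <- roots[!absorbed]
    }
    roots <- c(roots, list(list(t = t, cs = cs)))
  }
  list(key = cluster$key,
       roots = lapply(roots, `[[`, "t"),
       children = children,
       replacement = replacement)
}

#' Correct one specificity level
#'
#' Clusters the given templates by their corrected parents, builds each
#' cluster's exclusivity tree, and returns the surviving templates (tree
#' roots, with the reactions of pruned templates reassigned to their root)
#' together with the full replacement map.
#'
#' @param specific list of `rxn_template` at the level being corrected
#' @param parent_of named character vector: reaction id -> corrected parent
#'   canonical string
#' @param strict_maps passed to [subsumes()]
#' @return `list(templates, replacement, trees, stats)`; `templates` is a
#'   named list canonical string -> surviving template, `replacement` a named
#'   character vector, `stats` counts before/after
#' @export
correct_level <- function(specific, parent_of, strict_maps = FALSE) {
  clusters <- cluster_by_parent(specific, parent_of)
  trees <- lapply(clusters, build_tree, strict_maps = strict_maps)
  replacement <- do.call(c, c(list(character(0)), lapply(trees, `[[`, "replacement")))
  survivors <- list()
  for (tr in trees) {
    for (root in tr$roots) {
      cs <- canonicalize(root)$canonical_string
      extra <- unlist(lapply(tr$children[[cs]], function(x) x$reaction_ids))
      merged <- root
      merged$reaction_ids <- unique(c(root$reaction_ids, extra))
      if (cs %in% names(survivors)) {
        merged$reaction_ids <- unique(c(survivors[[cs]]$reaction_ids,
                                        merged$reaction_ids))
      }
      survivors[[cs]] <- merged
    }
  }
  list(templates = survivors,
       replacement = replacement,
       trees = trees,
       stats = c(n_in = length(specific), n_out = length(survivors)))
}

#' Hierarchically correct a multi-radius template set
#'
#' Applies canonical deduplication at every level, then corrects the levels
#' in the fixed order: radius 1 is corrected with clustering at radius 0;
#' default (radius 1 plus special groups) and radius 2 are corrected with
#' clustering at corrected radius 1; radius 3 is corrected with clustering at
#' corrected radius 2. Radius 0 itself cannot be corrected (there is no lower
#' level), which is why canonicalization matters most there. Parent
#' assignments at each step use the corrected parent of each reaction, so
#' removals propagate up the radius hierarchy. A useful side effect at the
#' default level: special-group decorations not shared by all reactions of a
#' cluster are pruned automatically because the group-free member subsumes
#' the decorated ones.
#'
#' @param per_radius named list (`"r0"`, `"r1"`, `"r2"`, `"r3"`, `"default"`;
#'   any subset containing the levels needed as parents) of lists of
#'   `rxn_template`
#' @param strict_maps passed to [subsumes()]
#' @return `list(levels, replacement, stats)`: `levels` maps each input
#'   level to its corrected named template list, `replacement` maps each
#'   level to its replacement vector, `stats` is a data.frame with raw /
#'   deduplicated / corrected counts per level
#' @export
correct_hierarchically <- function(per_radius, strict_maps = FALSE) {
  stopifnot(is.list(per_radius), !is.null(names(per_radius)))
  order_steps <- list(c("r1", "r0"), c("default", "r1"), c("r2", "r1"), c("r3", "r2"))
  levels_out <- list()
  repl_out <- list()
  stats <- data.frame(level = character(0), n_raw = integer(0),
                      n_canonical = integer(0), n_corrected = integer(0))
  if (!"r0" %in% names(per_radius))
    stop("radius-0 templates are required as the base of the hierarchy")
  dedup <- lapply(per_radius, deduplicate)
  levels_out[["r0"]] <- dedup[["r0"]]
  stats <- rbind(stats, data.frame(level = "r0",
                                   n_raw = length(per_radius[["r0"]]),
                                   n_canonical = length(dedup[["r0"]]),
                                   n_corrected = length(dedup[["r0"]])))
  parent_map_of <- function(level_templates) {
    ids <- unlist(lapply(names(level_templates), function(cs)
      stats::setNames(rep(cs, length(level_templates[[cs]]$reaction_ids)),
                      level_templates[[cs]]$reaction_ids)))
    ids
  }
  for (step in order_steps) {
    lvl <- step[1]; parent_lvl <- step[2]
    if (!lvl %in% names(per_radius)) next
    if (!parent_lvl %in% names(levels_out))
      stop(sprintf("cannot correct level %s: corrected level %s missing",
                   lvl, parent_lvl))
    parent_of <- parent_map_of(levels_out[[parent_lvl]])
    res <- correct_level(unname(dedup[[lvl]]), parent_of, strict_maps = strict_maps)
    levels_out[[lvl]] <- res$templates
    repl_out[[lvl]] <- res$replacement
    stats <- rbind(stats, data.frame(level = lvl,
                                     n_raw = length(per_radius[[lvl]]),
                                     n_canonical = length(dedup[[lvl]]),
                                     n_corrected = length(res$templates)))
  }
  list(levels = levels_out, replacement = repl_out, stats = stats)
}
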