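# Synthetic template corpora with known ground truth. Classes are built from
# a small catalog of chemically sane retro transformations, decorated with
# random acyclic C/N/O context chains emulating extraction radii 0-3 plus a
# "default" level (radius 1 + special group). Planted defects: duplicates
# (map-renumbered, atom-reordered emissions of one class) and nonexclusive
# variants (a branched context chain subsumed by the linear one at radii
# 2-3; an optional special-group motif subsumed by the group-free template
# at the default level).

#' Catalog of core transformations
#'
#' Five retro templates (radius 0) used as the reaction cores of synthetic
#' corpora: ester cleavage, amide coupling, N-alkylation, reductive
#' amination, and sulfonamide formation. `attach` lists the map numbers of
#' atoms where context may grow.
#'
#' @return named list of cores (`template` string, `attach` map numbers)
#' @export
core_catalog <- function() {
  list(
    ester_cleavage = list(
      template = "[C:1](=[O:2])[O:3][C;H3:4]>>[O][C:1]=[O:2].[O:3][C;H3:4]",
      attach = 1L),
    amide_coupling = list(
      template = "[C:1](=[O:2])[N:3]>>[O][C:1]=[O:2].[N:3]",
      attach = c(1L, 3L)),
    n_alkylation = list(
      template = "[C:1][N:2]>>Br[C:1].[N:2]",
      attach = c(1L, 2L)),
    reductive_amination = list(
      template = "[C:1][N:2]>>O=[C:1].[N:2]",
      attach = c(1L, 2L)),
    sulfonamide = list(
      template = "[S:1](=[O:2])(=[O:3])[N:4]>>Cl[S:1](=[O:2])=[O:3].[N:4]",
      attach = c(1L, 4L))
  )
}

# Special-group motifs: atoms (element, charge), bonds among motif atoms
# (1-based, 0 = the anchor atom), bond orders.
.MOTIFS <- list(
  nitro = list(
    atoms = list(c("N", "1"), c("O", "0"), c("O", "-1")),
    bonds = list(c(0L, 1L, "-"), c(1L, 2L, "="), c(1L, 3L, "-"))),
  dioxolane = list(
    atoms = list(c("C", "0"), c("O", "0"), c("C", "0"), c("C", "0"), c("O", "0")),
    bonds = list(c(0L, 1L, "-"), c(1L, 2L, "-"), c(2L, 3L, "-"),
                 c(3L, 4L, "-"), c(4L, 5L, "-"), c(5L, 1L, "-")))
)

# Append one atom to both sides of a template under construction.
.add_ctx_atom <- function(tt, elem, map, anchor_l, anchor_r, bond = "-",
                          charge = NA_integer_) {
  q <- .new_atom_query(elem, aromatic = FALSE, charge = charge, map = map)
  for (side in c("lhs", "rhs")) {
    anchor <- if (side == "lhs") anchor_l else anchor_r
    tt[[side]]$atoms <- c(tt[[side]]$atoms, list(q))
    idx <- length(tt[[side]]$atoms)
    if (anchor > 0L) {
      tt[[side]]$bonds <- rbind(tt[[side]]$bonds,
                                data.frame(i = min(anchor, idx),
                                           j = max(anchor, idx), b = bond))
    }
    tt[[paste0(side, "_last")]] <- idx
  }
  tt
}

# Build the template of a fixture class at one level. `context` is a list
# keyed by attach map: list(elems = chain elements, branch_pos = 0 or chain
# position carrying a branch, branch_elem). `radius`: 0..3, "default"
# (radius 1 + motif), or "full" (radius 3 + branch + motif: the molecule
# scaffold).
.make_class_template <- function(core, context, radius, motif = NULL,
                                 reaction_ids = character(0)) {
  t0 <- parse_template(core$template)
  lhs <- t0$lhs; rhs <- t0$rhs
  lmap <- .side_maps(lhs); rmap <- .side_maps(rhs)
  next_map <- max(c(lmap, rmap)) + 1L
  rnum <- if (identical(radius, "default")) 1L
          else if (identical(radius, "full")) 3L
          else as.integer(radius)
  with_motif <- (identical(radius, "default") || identical(radius, "full")) &&
    !is.null(motif)
  with_branch <- identical(radius, "full") || (!identical(radius, "default") &&
                                               rnum >= 2L)
  tt <- list(lhs = lhs, rhs = rhs)
  motif_anchor_l <- NA_integer_; motif_anchor_r <- NA_integer_
  first_attach <- TRUE
  for (a in core$attach) {
    ctx <- context[[as.character(a)]]
    prev_l <- which(lmap == a); prev_r <- which(rmap == a)
    depth <- min(length(ctx$elems), rnum)
    for (p in seq_len(depth)) {
      tt <- .add_ctx_atom(tt, ctx$elems[p], next_map, prev_l, prev_r)
      next_map <- next_map + 1L
      prev_l <- tt$lhs_last; prev_r <- tt$rhs_last
      if (p == 1L && first_attach) {
        motif_anchor_l <- prev_l; motif_anchor_r <- prev_r
      }
      if (with_branch && !is.null(ctx$branch_pos) && ctx$branch_pos == p &&
          p + 1L <= rnum + if (identical(radius, "full")) 1L else 0L) {
        # branch atom sits at distance p+1; included at radius >= p+1
        if (p + 1L <= rnum || identical(radius, "full")) {
          tt <- .add_ctx_atom(tt, ctx$branch_elem, next_map, prev_l, prev_r)
          next_map <- next_map + 1L
          # chain continues from the backbone atom, not the branch
          tt$lhs_last <- prev_l; tt$rhs_last <- prev_r
        }
      }
    }
    first_attach <- FALSE
  }
  if (with_motif && !is.na(motif_anchor_l)) {
    spec <- .MOTIFS[[motif]]
    base_l <- length(tt$lhs$atoms); base_r <- length(tt$rhs$atoms)
    for (k in seq_along(spec$atoms)) {
      at <- spec$atoms[[k]]
      q <- .new_atom_query(at[1], aromatic = FALSE,
                           charge = as.integer(at[2]), map = next_map)
      next_map <- next_map + 1L
      tt$lhs$atoms <- c(tt$lhs$atoms, list(q))
      tt$rhs$atoms <- c(tt$rhs$atoms, list(q))
    }
    for (b in spec$bonds) {
      i <- as.integer(b[1]); j <- as.integer(b[2])
      il <- if (i == 0L) motif_anchor_l else base_l + i
      jl <- if (j == 0L) motif_anchor_l else base_l + j
      ir <- if (i == 0L) motif_anchor_r else base_r + i
      jr <- if (j == 0L) motif_anchor_r else base_r + j
      tt$lhs$bonds <- rbind(tt$lhs$bonds,
                            data.frame(i = min(il, jl), j = max(il, jl), b = b[3]))
      tt$rhs$bonds <- rbind(tt$rhs$bonds,
                            data.frame(i = min(ir, jr), j = max(ir, jr), b = b[3]))
    }
  }
  draft <- structure(list(lhs = tt$lhs, rhs = tt$rhs, direction = "retro",
                          radius_tag = NA_character_,
                          reaction_ids = reaction_ids,
                          raw_string = ""),
                     class = "rxn_template")
  g <- build_condensed_graph(draft)
  s <- .write_template(draft, g, seq_len(g$n))
  tag <- if (identical(radius, "default")) "default"
         else if (identical(radius, "full")) NA_character_
         else paste0("r", rnum)
  parse_template(s, direction = "retro", radius_tag = tag,
                 reaction_ids = reaction_ids)
}

#' Re-emit a template with shuffled atom order and map numbering
#'
#' Writes the same transformation as a different (but equivalent) string:
#' atoms are traversed in a random order and atom maps renumbered
#' accordingly. Used to plant duplicates in synthetic corpora; by
#' construction the canonical form is unchanged.
#'
#' @param t `rxn_template` or string
#' @return a template string encoding the same transformation
#' @export
scramble_template <- function(t) {
  if (is.character(t)) t <- parse_template(t)
  g <- build_condensed_graph(t)
  .write_template(t, g, sample(g$n))
}

#' Specification of a synthetic template corpus
#'
#' @param n_cores number of core transformations used (1-5)
#' @param classes_per_core distinct base transformation contexts per core
#'   (capped by the number of available radius-1 context combinations)
#' @param depth_range min/max context chain depth per attachment point
#'   (minimum must be >= 1 so radius-1 templates stay mutually exclusive)
#' @param multiplicities candidate duplicate multiplicities (reactions per
#'   class) and `mult_probs` their sampling weights
#' @param p_branch probability that a base class spawns a branched-context
#'   variant (nonexclusive at radii 2-3)
#' @param p_group probability that a base class spawns a special-group
#'   variant (nonexclusive at the default level)
#' @param seed RNG seed; the same seed reproduces the corpus byte for byte
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(n_cores = 5L, classes_per_core = 3L,
                         depth_range = c(1L, 3L),
                         multiplicities = 1:3, mult_probs = c(0.5, 0.3, 0.2),
                         p_branch = 0.25, p_group = 0.25, seed = 1L) {
  stopifnot(n_cores >= 1L, n_cores <= length(core_catalog()),
            classes_per_core >= 1L,
            depth_range[1] >= 1L, depth_range[2] >= depth_range[1],
            depth_range[2] <= 3L,
            length(multiplicities) == length(mult_probs),
            all(multiplicities >= 1L),
            p_branch >= 0, p_branch <= 1, p_group >= 0, p_group <= 1)
  structure(list(n_cores = as.integer(n_cores),
                 classes_per_core = as.integer(classes_per_core),
                 depth_range = as.integer(depth_range),
                 multiplicities = as.integer(multiplicities),
                 mult_probs = mult_probs,
                 p_branch = p_branch, p_group = p_group,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.CTX_ELEMS <- c("C", "N", "O")

# sample() that never falls into the scalar-x trap
.resample <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

#' Generate a synthetic template corpus with ground truth
#'
#' Emits per-reaction templates at radii 0-3 plus the default level, with
#' duplicates planted as scrambled re-emissions within a class and
#' nonexclusive variants planted as branched-context (radii 2-3) and
#' special-group (default level) siblings. Every planted subsumption is
#' verified with [subsumes()] at generation time.
#'
#' @param spec a [fixture_spec()]
#' @return list with `templates` (data.frame: `reaction_id`, `template_r0` ..
#'   `template_r3`, `template_default`), `truth` (see details), and `classes`
#'   (internal class records, used by [generate_recommendations()]).
#'   `truth$reactions` maps each reaction to its class and kind;
#'   `truth$class_key` / `truth$survivor_key` give, per level, each
#'   reaction's canonical-class and post-correction class assignment by
#'   construction; `truth$counts` tabulates expected deduplicated and
#'   exclusive class counts per level.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  cat_ <- core_catalog()[seq_len(spec$n_cores)]
  levels_ <- c("r0", "r1", "r2", "r3", "default")
  classes <- list()
  uid <- 0L
  for (core_name in names(cat_)) {
    core <- cat_[[core_name]]
    combos <- expand.grid(rep(list(.CTX_ELEMS), length(core$attach)),
                          stringsAsFactors = FALSE)
    combos <- combos[sample(nrow(combos)), , drop = FALSE]
    n_cls <- min(spec$classes_per_core, nrow(combos))
    for (ci in seq_len(n_cls)) {
      uid <- uid + 1L
      context <- list()
      for (ai in seq_along(core$attach)) {
        d <- .resample(seq(spec$depth_range[1], spec$depth_range[2]), 1L)
        elems <- c(combos[ci, ai],
                   if (d > 1L) sample(.CTX_ELEMS, d - 1L, replace = TRUE))
        context[[as.character(core$attach[ai])]] <-
          list(elems = elems, branch_pos = 0L, branch_elem = NA_character_)
      }
      base_uid <- uid
      classes[[uid]] <- list(uid = uid, core_name = core_name, core = core,
                             context = context, kind = "base",
                             base_uid = base_uid, motif = NULL)
      if (stats::runif(1) < spec$p_branch) {
        uid <- uid + 1L
        vctx <- context
        a1 <- as.character(core$attach[1])
        vctx[[a1]]$branch_pos <- 1L
        vctx[[a1]]$branch_elem <- sample(.CTX_ELEMS, 1L)
        classes[[uid]] <- list(uid = uid, core_name = core_name, core = core,
                               context = vctx, kind = "branch_variant",
                               base_uid = base_uid, motif = NULL)
      }
      if (stats::runif(1) < spec$p_group) {
        uid <- uid + 1L
        classes[[uid]] <- list(uid = uid, core_name = core_name, core = core,
                               context = context, kind = "group_variant",
                               base_uid = base_uid,
                               motif = sample(names(.MOTIFS), 1L))
      }
    }
  }
  # per-class templates at every level + generation-time verification of the
  # planted subsumption relations
  for (k in seq_along(classes)) {
    cl <- classes[[k]]
    tmpl <- list()
    for (lv in levels_) {
      r <- if (lv == "default") "default" else as.integer(sub("r", "", lv))
      tmpl[[lv]] <- .make_class_template(cl$core, cl$context, r, cl$motif)
    }
    classes[[k]]$templates <- tmpl
  }
  for (cl in classes) {
    if (cl$kind == "branch_variant") {
      base <- classes[[cl$base_uid]]
      for (lv in c("r2", "r3")) {
        if (!subsumes(base$templates[[lv]], cl$templates[[lv]]) ||
            subsumes(cl$templates[[lv]], base$templates[[lv]]))
          stop("fixture generator: planted branch subsumption failed verification")
      }
    }
    if (cl$kind == "group_variant") {
      base <- classes[[cl$base_uid]]
      if (!subsumes(base$templates[["default"]], cl$templates[["default"]]) ||
          subsumes(cl$templates[["default"]], base$templates[["default"]]))
        stop("fixture generator: planted special-group subsumption failed verification")
    }
  }
  # reactions + scrambled emissions
  rows <- list()
  rx <- list()
  rid <- 0L
  for (cl in classes) {
    # nonexclusive variants emulate rare decorations: one reaction each,
    # as with real special-group templates; duplicates multiply base classes
    m <- if (cl$kind == "base") {
      .resample(spec$multiplicities, 1L, prob = spec$mult_probs)
    } else 1L
    for (j in seq_len(m)) {
      rid <- rid + 1L
      id <- sprintf("RX%05d", rid)
      emitted <- vapply(levels_, function(lv) scramble_template(cl$templates[[lv]]),
                        character(1))
      rows[[rid]] <- data.frame(reaction_id = id,
                                template_r0 = emitted[["r0"]],
                                template_r1 = emitted[["r1"]],
                                template_r2 = emitted[["r2"]],
                                template_r3 = emitted[["r3"]],
                                template_default = emitted[["default"]])
      rx[[rid]] <- data.frame(reaction_id = id, core = cl$core_name,
                              class_uid = cl$uid, kind = cl$kind,
                              base_uid = cl$base_uid)
    }
  }
  templates <- do.call(rbind, rows)
  reactions <- do.call(rbind, rx)
  # construction ground truth: class key (canonical class) and survivor key
  # (post-correction class) per level
  key_of <- function(cl, lv) {
    switch(lv,
      r0 = cl$core_name,
      r1 = paste0("b", cl$base_uid),
      r2 = ,
      r3 = if (cl$kind == "branch_variant") paste0("c", cl$uid)
           else paste0("b", cl$base_uid),
      default = if (cl$kind == "group_variant") paste0("c", cl$uid)
                else paste0("b", cl$base_uid))
  }
  surv_of <- function(cl, lv) {
    switch(lv,
      r0 = cl$core_name,
      r1 = paste0("b", cl$base_uid),
      r2 = ,
      r3 = paste0("b", cl$base_uid),
      default = paste0("b", cl$base_uid))
  }
  class_key <- list(); survivor_key <- list()
  for (lv in levels_) {
    class_key[[lv]] <- vapply(reactions$class_uid,
                              function(u) key_of(classes[[u]], lv), character(1))
    survivor_key[[lv]] <- vapply(reactions$class_uid,
                                 function(u) surv_of(classes[[u]], lv), character(1))
  }
  counts <- do.call(rbind, lapply(levels_, function(lv) {
    data.frame(level = lv,
               n_raw = nrow(templates),
               n_classes = length(unique(class_key[[lv]])),
               n_exclusive = length(unique(survivor_key[[lv]])))
  }))
  list(templates = templates,
       truth = list(reactions = reactions, class_key = class_key,
                    survivor_key = survivor_key, counts = counts),
       classes = classes)
}

#' Instantiate the pattern side of a template as a molecule
#'
#' Strips atom maps and interprets each pattern atom as a concrete atom
#' (unspecified charge 0, hydrogens valence-filled, explicit H counts kept).
#' For fixture classes this yields a molecule that every template of the
#' class matches.
#'
#' @param t `rxn_template` or string
#' @return a `molecule`
#' @export
pattern_molecule <- function(t) {
  if (is.character(t)) t <- parse_template(t)
  side <- t$lhs
  for (i in seq_along(side$atoms)) side$atoms[[i]]$map <- 0L
  .resolve_molecule(side)
}

#' Generate planted ranked recommendations with a known T/P gap
#'
#' Builds query molecules and ranked template lists from a synthetic corpus
#' in which a controlled fraction of queries have a duplicate of the
#' ground-truth template (same class, different string) or a nonexclusive
#' sibling (the more general base of the truth's variant class) planted at
#' rank 1 while the truth itself sits at `truth_rank`. Before correction the
#' exact-template criterion misses those queries at cutoffs below
#' `truth_rank` while the exact-precursor criterion hits them, so the T/P
#' gap at such cutoffs equals `(n_dup + n_nonexcl) / n_queries` exactly;
#' after canonicalization plus hierarchical correction both criteria hit at
#' every cutoff.
#'
#' @param corpus result of [generate_corpus()]
#' @param n_queries number of queries
#' @param dup_rate,nonexcl_rate fractions of queries with a planted
#'   duplicate / nonexclusive sibling at rank 1
#' @param level template level used (`"default"` pairs with group variants;
#'   `"r2"`/`"r3"` pair with branch variants)
#' @param list_length ranked list length
#' @param truth_rank rank at which the truth is planted for defect queries
#' @param seed RNG seed
#' @return list of data.frames `recs` (`query_id`, `rank`, `template`,
#'   `score`), `truth` (`query_id`, `truth_template`, `truth_smiles`),
#'   `molecules` (`query_id`, `smiles`), `planted` (`query_id`, `kind`), and
#'   `planted_gap` (the exact T/P gap at cutoffs `< truth_rank`)
#' @export
generate_recommendations <- function(corpus, n_queries = 20L, dup_rate = 0.2,
                                     nonexcl_rate = 0.2, level = "default",
                                     list_length = 10L, truth_rank = 6L,
                                     seed = 1L) {
  stopifnot(truth_rank >= 2L, list_length >= truth_rank,
            dup_rate + nonexcl_rate <= 1)
  set.seed(seed)
  col <- paste0("template_", level)
  rxn <- corpus$truth$reactions
  variant_kind <- if (level == "default") "group_variant" else "branch_variant"
  n_dup <- round(dup_rate * n_queries)
  n_non <- round(nonexcl_rate * n_queries)
  variants <- which(rxn$kind == variant_kind)
  if (length(variants) < n_non)
    stop(sprintf("corpus has only %d %s reactions; raise p_%s or lower nonexcl_rate",
                 length(variants), variant_kind,
                 if (level == "default") "group" else "branch"))
  qs_non <- .resample(variants, n_non)
  rest <- setdiff(seq_len(nrow(rxn)), qs_non)
  qs_dup <- .resample(rest, n_dup)
  qs_norm <- .resample(setdiff(rest, qs_dup), n_queries - n_dup - n_non)
  queries <- data.frame(
    row = c(qs_dup, qs_non, qs_norm),
    kind = c(rep("dup", n_dup), rep("nonexcl", n_non),
             rep("none", length(qs_norm))))
  queries <- queries[sample(nrow(queries)), , drop = FALSE]
  recs <- list(); truths <- list(); mols <- list(); planted <- list()
  filler_pool <- function(core_name, n) {
    cand <- which(rxn$core != core_name)
    sel <- .resample(cand, n, replace = length(cand) < n)
    corpus$templates[[col]][sel]
  }
  for (qi in seq_len(nrow(queries))) {
    row <- queries$row[qi]; kind <- queries$kind[qi]
    cl <- corpus$classes[[rxn$class_uid[row]]]
    qid <- sprintf("Q%03d", qi)
    mol_t <- .make_class_template(cl$core, cl$context, "full", cl$motif)
    mol <- pattern_molecule(mol_t)
    smi <- canonical_smiles(mol)
    truth_string <- corpus$templates[[col]][row]
    ao <- apply_template(cl$templates[[level]], mol)
    if (!ao$applicable)
      stop("fixture generator: class template inapplicable to its own molecule")
    keys <- vapply(ao$outcomes, function(s) paste(s, collapse = "."), character(1))
    truth_smiles <- keys[order(keys, method = "radix")[1]]
    tl <- rep(NA_character_, list_length)
    if (kind == "none") {
      tl[1] <- truth_string
      tl[-1] <- filler_pool(cl$core_name, list_length - 1L)
    } else {
      plant <- if (kind == "dup") {
        s <- truth_string
        for (k in seq_len(50L)) {
          s <- scramble_template(cl$templates[[level]])
          if (s != truth_string) break
        }
        s
      } else {
        base <- corpus$classes[[cl$base_uid]]
        scramble_template(base$templates[[level]])
      }
      tl[1] <- plant
      tl[truth_rank] <- truth_string
      tl[is.na(tl)] <- filler_pool(cl$core_name, list_length - 2L)
    }
    recs[[qi]] <- data.frame(query_id = qid, rank = seq_len(list_length),
                             template = tl, score = 1 / seq_len(list_length))
    truths[[qi]] <- data.frame(query_id = qid, truth_template = truth_string,
                               truth_smiles = truth_smiles)
    mols[[qi]] <- data.frame(query_id = qid, smiles = smi)
    planted[[qi]] <- data.frame(query_id = qid, kind = kind)
  }
  list(recs = do.call(rbind, recs),
       truth = do.call(rbind, truths),
       molecules = do.call(rbind, mols),
       planted = do.call(rbind, planted),
       planted_gap = (n_dup + n_non) / n_queries)
}

#' Convert recommendation tables to ranked_recommendation objects
#'
#' @param rec_set result of [generate_recommendations()], or a list with
#'   `recs`, `truth`, `molecules` data.frames in that format
#' @return list of [ranked_recommendation()] objects
#' @export
as_recommendations <- function(rec_set) {
  ids <- unique(rec_set$recs$query_id)
  lapply(ids, function(qid) {
    rr <- rec_set$recs[rec_set$recs$query_id == qid, , drop = FALSE]
    rr <- rr[order(rr$rank), , drop = FALSE]
    tr <- rec_set$truth[rec_set$truth$query_id == qid, , drop = FALSE]
    mo <- rec_set$molecules[rec_set$molecules$query_id == qid, , drop = FALSE]
    ranked_recommendation(
      query_id = qid, query = mo$smiles[1],
      templates = rr$template, scores = rr$score,
      truth_template = tr$truth_template[1],
      truth_outcome = strsplit(tr$truth_smiles[1], ".", fixed = TRUE)[[1]])
  })
}
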