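# Subsumption, clustering, exclusivity trees and hierarchical correction.

test_that("a linear-context template subsumes its branched sibling", {
  lin <- parse_template("[C:3][C:1][N:2]>>Br[C:1][C:3].[N:2]")
  bra <- parse_template("[C:3]([C:4])[C:1][N:2]>>Br[C:1][C:3][C:4].[N:2]")
  expect_true(subsumes(lin, bra))
  expect_false(subsumes(bra, lin))
  expect_true(subsumes(lin, lin))   # reflexive
  expect_true(subsumes(bra, bra))
})

test_that("templates with disjoint peripheral context are incomparable", {
  a <- parse_template("[O:3][C:1][N:2]>>Br[C:1][O:3].[N:2]")
  b <- parse_template("[N:3][C:1][N:2]>>Br[C:1][N:3].[N:2]")
  expect_false(subsumes(a, b))
  expect_false(subsumes(b, a))
})

test_that("strict map checking rejects side-inconsistent embeddings", {
  g <- parse_template("[C:1][O:2][C:3]>>[C:1][O:2].[C:3]")
  s <- parse_template("C[C:1][O:2][C:3]>>C[C:1][O:2].[C:3]")
  expect_true(subsumes(g, s))
  expect_true(subsumes(g, s, strict_maps = TRUE))
  expect_true(subsumes(g, g, strict_maps = TRUE))
})

test_that("clustering partitions by parent and splits straddlers with a warning", {
  mk <- function(s, ids) parse_template(s, reaction_ids = ids)
  t1 <- mk("[C:3][C:1][N:2]>>Br[C:1][C:3].[N:2]", c("a", "b"))
  t2 <- mk("[O:3][C:1][N:2]>>Br[C:1][O:3].[N:2]", "c")
  parent_of <- c(a = "P1", b = "P1", c = "P2")
  cl <- cluster_by_parent(list(t1, t2), parent_of)
  expect_length(cl, 2L)
  expect_identical(vapply(cl, `[[`, character(1), "key"), c("P1", "P2"))
  # straddler: reactions under two parents -> split copies + warning
  parent_of2 <- c(a = "P1", b = "P2", c = "P2")
  expect_warning(cl2 <- cluster_by_parent(list(t1, t2), parent_of2),
                 "straddles")
  expect_length(cl2, 2L)
  expect_length(cl2[[2]]$members, 2L)
  expect_error(cluster_by_parent(list(t1), c(a = "P1")), "no parent assignment")
})

test_that("exclusivity trees keep most-general roots, pairwise incomparable", {
  # one root subsuming two specializations
  lin <- parse_template("[C:3][C:1][N:2]>>Br[C:1][C:3].[N:2]", reaction_ids = "x1")
  sp1 <- parse_template("[C:4][C:3][C:1][N:2]>>Br[C:1][C:3][C:4].[N:2]",
                        reaction_ids = "x2")
  sp2 <- parse_template("[O:4][C:3][C:1][N:2]>>Br[C:1][C:3][O:4].[N:2]",
                        reaction_ids = "x3")
  tree <- build_tree(list(key = "P", members = list(sp1, lin, sp2)))
  expect_length(tree$roots, 1L)
  root_cs <- canonicalize(tree$roots[[1]])$canonical_string
  expect_identical(root_cs, canonicalize(lin)$canonical_string)
  expect_length(tree$children[[root_cs]], 2L)
  expect_setequal(unname(tree$replacement), rep(root_cs, 2L))
  # singleton cluster kept as is
  tr1 <- build_tree(list(key = "P", members = list(lin)))
  expect_length(tr1$roots, 1L)
  expect_length(tr1$replacement, 0L)
  # mutually non-subsuming members both stay roots
  a <- parse_template("[O:3][C:1][N:2]>>Br[C:1][O:3].[N:2]", reaction_ids = "y1")
  b <- parse_template("[N:3][C:1][N:2]>>Br[C:1][N:3].[N:2]", reaction_ids = "y2")
  tr2 <- build_tree(list(key = "P", members = list(a, b)))
  expect_length(tr2$roots, 2L)
})

test_that("a general member arriving late absorbs comparable roots", {
  # equal atom counts, different bond structure: the two-fragment pattern is
  # the more general one and ties in insertion size with the ring
  ring <- parse_template("[C:1]1[C:2][C:3][C:4]1>>[C:1]1[C:2][C:3][C:4]1",
                         reaction_ids = "z1")
  chain <- parse_template("[C:1][C:2][C:3][C:4]>>[C:1][C:2][C:3][C:4]",
                          reaction_ids = "z2")
  expect_true(subsumes(chain, ring))
  tr <- build_tree(list(key = "P", members = list(ring, chain)))
  expect_length(tr$roots, 1L)
  expect_identical(canonicalize(tr$roots[[1]])$canonical_string,
                   canonicalize(chain)$canonical_string)
})

test_that("level correction equals exhaustive pairwise pruning on random clusters", {
  set.seed(123)
  for (k in 1:12) {
    members <- random_cluster(n_members = sample(3:7, 1L),
                              level = sample(c("r2", "r3", "default"), 1L))
    dd <- unname(deduplicate(members))
    tree <- build_tree(list(key = "P", members = dd))
    got <- sort(vapply(tree$roots, function(t) canonicalize(t)$canonical_string,
                       character(1)))
    expect_identical(got, oracle_survivors(dd), label = paste("cluster", k))
    # survivors pairwise non-subsuming
    for (i in seq_along(tree$roots)) {
      for (j in seq_along(tree$roots)) {
        if (i != j) expect_false(subsumes(tree$roots[[i]], tree$roots[[j]]))
      }
    }
  }
})

test_that("correct_level reassigns reactions and conserves the id multiset", {
  lin <- parse_template("[C:3][C:1][N:2]>>Br[C:1][C:3].[N:2]",
                        reaction_ids = c("a", "b"))
  sp <- parse_template("[C:4][C:3][C:1][N:2]>>Br[C:1][C:3][C:4].[N:2]",
                       reaction_ids = "c")
  other <- parse_template("[O:3][C:1][N:2]>>Br[C:1][O:3].[N:2]",
                          reaction_ids = "d")
  parent_of <- c(a = "P1", b = "P1", c = "P1", d = "P2")
  res <- correct_level(list(lin, sp, other), parent_of)
  expect_length(res$templates, 2L)
  all_ids <- sort(unname(unlist(lapply(res$templates, function(t) t$reaction_ids))))
  expect_identical(all_ids, c("a", "b", "c", "d"))
  surv_lin <- res$templates[[canonicalize(lin)$canonical_string]]
  expect_setequal(surv_lin$reaction_ids, c("a", "b", "c"))
  # already-exclusive input is the identity
  res2 <- correct_level(list(lin, other), parent_of)
  expect_length(res2$templates, 2L)
  expect_length(res2$replacement, 0L)
})

test_that("hierarchical correction recovers the fixture ground truth", {
  corpus <- small_corpus()
  res <- small_correction()
  truth <- corpus$truth$counts
  for (lv in truth$level) {
    expect_equal(length(res$levels[[lv]]),
                 truth$n_exclusive[truth$level == lv], label = lv)
    st <- res$stats[res$stats$level == lv, ]
    expect_equal(st$n_canonical, truth$n_classes[truth$level == lv], label = lv)
  }
  # conservation at every level
  n_rxn <- nrow(corpus$templates)
  for (lv in names(res$levels)) {
    ids <- unlist(lapply(res$levels[[lv]], function(t) t$reaction_ids))
    expect_equal(length(ids), n_rxn, label = lv)
    expect_equal(length(unique(ids)), n_rxn, label = lv)
  }
  # a clean corpus passes through unchanged
  cc <- clean_corpus()
  res2 <- correct_hierarchically(corpus_levels(cc))
  expect_true(all(vapply(res2$replacement, length, integer(1)) == 0L))
  expect_equal(res2$stats$n_corrected, res2$stats$n_canonical)
  # missing base level is an error
  expect_error(correct_hierarchically(corpus_levels(corpus, c("r1", "r2"))),
               "radius-0")
})

test_that("special-group variants lose their group to the group-free member", {
  corpus <- small_corpus()
  res <- small_correction()
  rxn <- corpus$truth$reactions
  gv <- rxn$reaction_id[rxn$kind == "group_variant"]
  expect_gt(length(gv), 0L)
  # every group-variant reaction now lives under a surviving default-level
  # template identical to its base class's group-free default template
  surv <- res$levels$default
  for (id in gv) {
    host <- which(vapply(surv, function(t) id %in% t$reaction_ids, logical(1)))
    expect_length(host, 1L)
    base_uid <- rxn$base_uid[rxn$reaction_id == id]
    base_cs <- canonicalize(corpus$classes[[base_uid]]$templates$default)$canonical_string
    expect_identical(names(surv)[host], base_cs)
  }
})
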