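# WL refinement, tie-breaking and canonical template strings.

test_that("initial labels partition by node features", {
  # three-node path, equal end queries, distinct middle -> 2 cells
  p <- initial_labels(build_condensed_graph(
    parse_template("[C:1][O:2][C:3]>>[C:1][O:2][C:3]")))
  expect_equal(p$n_cells, 2L)
  # all nodes identical features and degrees (triangle) -> 1 cell
  p2 <- initial_labels(build_condensed_graph(
    parse_template("[C:1]1[C:2][C:3]1>>[C:1]1[C:2][C:3]1")))
  expect_equal(p2$n_cells, 1L)
  # chirality tag is a node feature
  p3 <- initial_labels(build_condensed_graph(
    parse_template("[C@:1][C@@:2]>>[C@:1][C@@:2]")))
  expect_equal(p3$n_cells, 2L)
})

test_that("refinement splits by neighbourhood and never merges cells", {
  # path C-C-C with identical atom queries: degree feature separates the
  # middle node already at initialization; refinement keeps it stable
  g <- build_condensed_graph(parse_template("[C:1][C:2][C:3]>>[C:1][C:2][C:3]"))
  p0 <- initial_labels(g)
  p <- wl_refine(p0, g)
  expect_true(p$stable)
  expect_gte(p$n_cells, p0$n_cells)
  expect_equal(p$n_cells, 2L)
  expect_lte(p$iteration, g$n)
  # 6-cycle with alternating features: stabilizes at 2 cells, never discrete
  g6 <- build_condensed_graph(parse_template(
    "[C:1]1[O:2][C:3][O:4][C:5][O:6]1>>[C:1]1[O:2][C:3][O:4][C:5][O:6]1"))
  p6 <- wl_refine(initial_labels(g6), g6)
  expect_equal(p6$n_cells, 2L)
  expect_false(p6$discrete)
})

test_that("stable WL partition equals the automorphism orbit partition", {
  cases <- c(
    "[C:1][C:2][C:3]>>[C:1][C:2][C:3]",
    "[C:1]1[O:2][C:3][O:4][C:5][O:6]1>>[C:1]1[O:2][C:3][O:4][C:5][O:6]1",
    "[C:1]([C:2])([C:3])[C:4]>>[C:1]([C:2])([C:3])[C:4]",
    "[C:1](=[O:2])[O:3][C:4]>>[O][C:1]=[O:2].[O:3][C:4]")
  corpus <- small_corpus()
  seven <- vapply(corpus$classes[1:4], function(cl) cl$templates$r1$raw_string,
                  character(1))
  for (s in c(cases, seven)) {
    g <- build_condensed_graph(parse_template(s))
    p <- wl_refine(initial_labels(g), g)
    expect_true(same_partition(p$labels, oracle_orbits(g)), label = s)
  }
})

test_that("tie-breaking is deterministic and relabelling-invariant", {
  # discrete partition: no branching needed
  g <- build_condensed_graph(parse_template("[C:1][O:2]>>[C:1].[O:2]"))
  bt <- break_ties(wl_refine(initial_labels(g), g), g)
  expect_equal(bt$n_branches, 1L)
  expect_false(bt$nonunique_risk)
  # fully symmetric 6-ring: individualization explores branches but all
  # relabelings give the same string
  hex <- "[C:1]1[C:2][C:3][C:4][C:5][C:6]1>>[C:1]1[C:2][C:3][C:4][C:5][C:6]1"
  s1 <- canonicalize(hex)$canonical_string
  t <- parse_template(hex)
  set.seed(99)
  for (k in 1:6) {
    expect_identical(canonicalize(scramble_template(t))$canonical_string, s1)
  }
  # budget exhaustion degrades gracefully with the nonunique flag
  cf <- canonicalize(hex, budget = 2L)
  expect_true(cf$nonunique_risk)
})

test_that("canonical strings are invariant, idempotent and map-standardized", {
  a <- canonicalize("[C:1](=[O:2])[O:3][C:4]>>[O][C:1]=[O:2].[O:3][C:4]")
  b <- canonicalize("[C:9][O:5][C:7]=[O:2]>>[C:9][O:5].[O][C:7]=[O:2]")
  expect_identical(a$canonical_string, b$canonical_string)
  expect_identical(canonicalize(a$canonical_string)$canonical_string,
                   a$canonical_string)
  maps <- as.integer(sub(":", "", unlist(regmatches(
    a$canonical_string, gregexpr(":\\d+", a$canonical_string)))))
  expect_setequal(unique(maps), 1:4)
  expect_true(all(sort(unique(a$rank)) == seq_along(a$rank)))
})

test_that("canonical equality matches brute-force isomorphism on small graphs", {
  corpus <- small_corpus()
  set.seed(1)
  pool <- unlist(lapply(corpus$classes, function(cl) {
    c(cl$templates$r0$raw_string, cl$templates$r1$raw_string)
  }))
  ts <- lapply(pool, parse_template)
  graphs <- lapply(ts, build_condensed_graph)
  keep <- vapply(graphs, function(g) g$n <= 8L, logical(1))
  ts <- ts[keep]; graphs <- graphs[keep]
  expect_gte(length(ts), 10L)
  canon <- vapply(ts, function(t) canonicalize(t)$canonical_string, character(1))
  expect_true(same_partition(match(canon, unique(canon)),
                             oracle_iso_classes(graphs)))
})

test_that("deduplicate merges canonical classes and conserves reaction ids", {
  t <- parse_template("[C:1](=[O:2])[N:3]>>[O][C:1]=[O:2].[N:3]",
                      reaction_ids = "r1")
  set.seed(4)
  copies <- lapply(2:5, function(k) {
    parse_template(scramble_template(t), reaction_ids = sprintf("r%d", k))
  })
  other <- parse_template("[C:1][N:2]>>Br[C:1].[N:2]", reaction_ids = "r6")
  dd <- deduplicate(c(list(t), copies, list(other)))
  expect_length(dd, 2L)
  sizes <- sort(vapply(dd, function(x) length(x$reaction_ids), integer(1)))
  expect_equal(unname(sizes), c(1L, 5L))
  expect_setequal(unlist(lapply(dd, function(x) x$reaction_ids)),
                  sprintf("r%d", 1:6))
  # pairwise-distinct transformations stay distinct
  distinct <- lapply(names(core_catalog()), function(nm) {
    parse_template(core_catalog()[[nm]]$template, reaction_ids = nm)
  })
  expect_length(deduplicate(distinct), length(distinct))
})

test_that("canonicalize_templates adds class ids over a table", {
  corpus <- small_corpus()
  df <- canonicalize_templates(corpus$templates, column = "template_r0")
  expect_true(all(c("canonical_template", "nonunique_risk", "class_id") %in%
                  names(df)))
  expect_equal(length(unique(df$class_id)),
               corpus$truth$counts$n_classes[corpus$truth$counts$level == "r0"])
  expect_false(any(df$nonunique_risk))
})
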