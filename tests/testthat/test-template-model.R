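# Template parsing, validation and condensed-graph construction.

ESTER <- "[C:1](=[O:2])[O:3][C:4]>>[O][C:1]=[O:2].[O:3][C:4]"

test_that("a well-formed retro template parses with the expected shape", {
  t <- parse_template(ESTER, radius_tag = "r0", reaction_ids = "rx1")
  expect_s3_class(t, "rxn_template")
  expect_length(t$lhs$atoms, 4L)
  expect_equal(sum(vapply(t$lhs$atoms, function(a) a$map, integer(1)) > 0), 4L)
  expect_equal(max(t$rhs$frag), 2L)
  expect_identical(t$raw_string, ESTER)
  expect_identical(t$radius_tag, "r0")
})

test_that("unsupported query primitives are rejected, naming the token", {
  expect_error(parse_template("[C,N:1]>>[C:1]"),
               class = "retempl_unsupported_query")
  expect_error(parse_template("[C,N:1]>>[C:1]"), ",")
  expect_error(parse_template("[!C:1]>>[C:1]"),
               class = "retempl_unsupported_query")
  expect_error(parse_template("[$([C])[N:1]]>>[N:1]"),
               class = "retempl_parse_error")
})

test_that("structural validation catches malformed templates", {
  expect_error(parse_template("[C:1][C:1]>>[C:1]"), "duplicate atom map")
  expect_error(parse_template("[C:1]"), "side separator")
  expect_error(parse_template("[C:1]>>[C:1]>>[C:1]"), "side separator")
  expect_warning(parse_template("[C:1]>>[C:1][O:9]"), "rhs-only mapped")
})

test_that("serialization round-trips through the parser", {
  strings <- c(
    ESTER,
    "[C;H2;+0:1][N;H1:2]>>Br[C;H2;+0:1].[N;H1:2]",
    "[c:1]1[c:2][c:3][c:4][c:5][c:6]1>>[c:1]1[c:2][c:3][c:4][c:5][c:6]1",
    "[N+:1](=[O:2])[O-:3]>>[N+:1](=[O:2])[O-:3]")
  for (s in strings) {
    t <- suppressWarnings(parse_template(s))
    cs <- canonicalize(t)$canonical_string
    expect_identical(canonicalize(cs)$canonical_string, cs, label = s)
  }
})

test_that("atomic query serialization uses the frozen primitive order", {
  t <- parse_template("[H3;C;D1:1]>>[C;H3;D1:1]")
  expect_identical(t$lhs$atoms[[1]]$key, "[C;H3;D1]")
  expect_identical(t$lhs$atoms[[1]]$key, t$rhs$atoms[[1]]$key)
  t2 <- parse_template("[O-:1]>>[O;-1:1]")
  expect_identical(t2$lhs$atoms[[1]]$key, t2$rhs$atoms[[1]]$key)
})

test_that("condensed graph merges mapped atoms and keeps one-sided nodes", {
  # full overlap: every mapped atom on both sides -> one node each
  t <- parse_template("[C:1][C:2]([O:3])[N:4]>>[C:1][C:2]([O:3])[N:4]")
  g <- build_condensed_graph(t)
  expect_equal(g$n, 4L)
  expect_true(all(!is.na(g$lidx) & !is.na(g$ridx)))
  # unmapped leaving-group atom on rhs -> its own one-sided node
  t2 <- parse_template(ESTER)
  g2 <- build_condensed_graph(t2)
  expect_equal(g2$n, 5L)
  one_sided <- which(is.na(g2$lidx))
  expect_length(one_sided, 1L)
  expect_identical(g2$rq[[one_sided]]$symbol, "O")
  # broken bond: lhs-tagged edge with no rhs counterpart
  broken <- g2$edges[g2$edges$side == "l", ]
  formed <- g2$edges[g2$edges$side == "r", ]
  key <- function(e) paste(e$i, e$j)
  expect_true(any(!(key(broken) %in% key(formed))))  # the C-O ester bond
})

test_that("condensed graph is invariant under map permutation (isomorphism oracle)", {
  set.seed(42)
  templates <- c(ESTER,
                 "[C:1](=[O:2])[N:3]>>[O][C:1]=[O:2].[N:3]",
                 "[S:1](=[O:2])(=[O:3])[N:4]>>Cl[S:1](=[O:2])=[O:3].[N:4]")
  for (s in templates) {
    t <- parse_template(s)
    g <- build_condensed_graph(t)
    for (k in 1:5) {
      t2 <- parse_template(scramble_template(t))
      g2 <- build_condensed_graph(t2)
      expect_true(oracle_isomorphic(g, g2), label = paste(s, "perm", k))
    }
  }
})

test_that("template tables round-trip through CSV and JSON lines", {
  corpus <- clean_corpus()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(corpus$templates, path, row.names = FALSE)
  df <- read_templates(path)
  expect_identical(df$template_r1, corpus$templates$template_r1)
  ts <- template_records(df, "r1")
  expect_length(ts, nrow(df))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_templates_jsonl(ts, jl)
  back <- read_templates_jsonl(jl)
  expect_identical(vapply(back, function(t) t$raw_string, character(1)),
                   vapply(ts, function(t) t$raw_string, character(1)))
  expect_identical(back[[1]]$radius_tag, "r1")
})
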