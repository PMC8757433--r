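# Ranking metrics: T/P top-N accuracy, outcome averaging, applicability,
# popularity histograms.

ESTER_T <- "[C:1](=[O:2])[O:3][C:4]>>[O][C:1]=[O:2].[O:3][C:4]"
AMINE_T <- "[C:1][N:2]>>Br[C:1].[N:2]"
AMIDE_T <- "[C:1](=[O:2])[N:3]>>[O][C:1]=[O:2].[N:3]"

ester_rec <- function(templates, truth_template = ESTER_T) {
  ranked_recommendation("q1", "CC(=O)OC", templates,
                        truth_template = truth_template,
                        truth_outcome = c("CC(O)=O", "CO"))
}

test_that("truth at rank 1 gives full T and P accuracy at every N", {
  rec <- ester_rec(c(ESTER_T, AMINE_T, AMIDE_T))
  for (n in c(1, 3, 5)) {
    expect_equal(unname(topn_accuracy(list(rec), n, "T")), 1)
    expect_equal(unname(topn_accuracy(list(rec), n, "P")), 1)
  }
})

test_that("a duplicate at rank 1 is a P-hit and raw-string T-miss", {
  set.seed(8)
  dup <- scramble_template(ESTER_T)
  expect_false(dup == ESTER_T)
  rec <- ester_rec(c(dup, AMINE_T, AMIDE_T, ESTER_T))
  # raw comparison: truth string only at rank 4
  expect_equal(unname(topn_accuracy(list(rec), 1, "T", canonical = FALSE)), 0)
  expect_equal(unname(topn_accuracy(list(rec), 4, "T", canonical = FALSE)), 1)
  # the duplicate applies and yields the recorded precursors
  expect_equal(unname(topn_accuracy(list(rec), 1, "P")), 1)
  # canonical comparison resolves the discrepancy
  expect_equal(unname(topn_accuracy(list(rec), 1, "T", canonical = TRUE)), 1)
})

test_that("hand-placed truths over ten queries match the hand count", {
  set.seed(21)
  # truth planted at ranks 1..10 across ten otherwise-identical queries
  recs <- lapply(1:10, function(r) {
    fillers <- rep(AMINE_T, 10)
    tl <- append(fillers[-1], ESTER_T, after = r - 1L)
    ester_rec(tl)
  })
  expect_equal(unname(topn_accuracy(recs, 1, "T")), 0.1)
  expect_equal(unname(topn_accuracy(recs, 5, "T")), 0.5)
  expect_equal(unname(topn_accuracy(recs, 10, "T")), 1.0)
  p <- topn_accuracy(recs, c(1, 5, 10), "P")
  expect_equal(unname(p), c(0.1, 0.5, 1.0))
  # monotone in N, and T <= P throughout
  tt <- topn_accuracy(recs, 1:10, "T")
  expect_true(all(diff(tt) >= 0))
  expect_true(all(tt <= topn_accuracy(recs, 1:10, "P") + 1e-12))
})

test_that("one correct of three unranked outcomes credits one third at top-1", {
  rec <- ranked_recommendation(
    "q1", "CN(CC)CCC", AMINE_T,
    truth_template = AMINE_T,
    truth_outcome = c("CBr", "CCNCCC"))
  ao <- apply_template(AMINE_T, "CN(CC)CCC")
  expect_length(ao$outcomes, 3L)
  expect_equal(unname(outcome_averaged_topn(list(rec), 1)), 1 / 3)
  expect_equal(unname(outcome_averaged_topn(list(rec), 2)), 2 / 3)
  expect_equal(unname(outcome_averaged_topn(list(rec), 3)), 1)
})

test_that("outcome averaging equals plain P accuracy when k = 1 everywhere", {
  # both templates apply to methyl acetate with exactly one outcome each:
  # demethylation (wrong precursors) at rank 1, ester cleavage (truth) at 2
  demethyl <- "[C;H3:1][O:2]>>Br[C;H3:1].[O:2]"
  expect_length(apply_template(demethyl, "CC(=O)OC")$outcomes, 1L)
  rec <- ester_rec(c(demethyl, ESTER_T))
  for (n in 1:3) {
    expect_equal(unname(outcome_averaged_topn(list(rec), n)),
                 unname(topn_accuracy(list(rec), n, "P")))
  }
})

test_that("outcome averaging equals the Monte-Carlo permutation expectation", {
  # rank 1: amine template with 3 outcomes (one correct); the analytic
  # credit clamp(N-s+1,0,k)/k must equal the empirical expectation over
  # uniformly random within-template outcome orderings
  rec <- ranked_recommendation(
    "q1", "CN(CC)CCC", c(AMIDE_T, AMINE_T),
    truth_template = AMINE_T, truth_outcome = c("CBr", "CCNCCC"))
  got <- outcome_averaged_topn(list(rec), 1:4)
  k <- 3L; s <- 1L  # amide inapplicable: contributes no outcome slots
  set.seed(31)
  mc <- vapply(1:4, function(n) {
    mean(vapply(1:4000, function(i) {
      pos <- s - 1L + sample.int(k, 1L)
      as.numeric(pos <= n)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(got), mc, tolerance = 0.03)
  expect_equal(unname(got), pmin(pmax(1:4 - s + 1L, 0L), k) / k)
})

test_that("applicability is the applicable share of the top N", {
  all_app <- ester_rec(c(ESTER_T, ESTER_T, ESTER_T, ESTER_T, ESTER_T))
  expect_equal(as.numeric(applicability_at_n(list(all_app), 5)), 1)
  none <- ranked_recommendation("q2", "CCCC", c(ESTER_T, AMIDE_T),
                                truth_template = ESTER_T,
                                truth_outcome = "CCCC")
  expect_equal(as.numeric(applicability_at_n(list(none), 2)), 0)
  mixed <- ester_rec(c(ESTER_T, AMIDE_T, AMINE_T, ESTER_T, AMIDE_T))
  expect_equal(as.numeric(applicability_at_n(list(mixed), 5)), 2 / 5)
  # short lists: available count as denominator, flagged
  short <- applicability_at_n(list(none), 5)
  expect_equal(attr(short, "short_lists"), 1L)
})

test_that("popularity histogram bins reaction counts per template", {
  expect_equal(unname(popularity_histogram(rep(1L, 7))), c(7L, 0L, 0L, 0L))
  expect_equal(unname(popularity_histogram(c(150L))), c(0L, 0L, 0L, 1L))
  counts <- c(1L, 1L, 3L, 9L, 10L, 42L, 99L, 100L, 250L)
  h <- popularity_histogram(counts)
  expect_equal(unname(h), c(2L, 2L, 3L, 2L))
  expect_equal(sum(h), length(counts))
  expect_identical(names(h), c("1", "2-9", "10-99", ">=100"))
  ts <- list(parse_template(ESTER_T, reaction_ids = c("a", "b")),
             parse_template(AMINE_T, reaction_ids = "c"))
  expect_equal(unname(popularity_histogram(ts)), c(1L, 1L, 0L, 0L))
})

test_that("metrics are invariant to template relabelling under canonical compare", {
  set.seed(77)
  rec1 <- ester_rec(c(ESTER_T, AMINE_T, AMIDE_T))
  rec2 <- ester_rec(vapply(c(ESTER_T, AMINE_T, AMIDE_T), scramble_template,
                           character(1), USE.NAMES = FALSE),
                    truth_template = scramble_template(ESTER_T))
  for (n in 1:3) {
    expect_equal(topn_accuracy(list(rec1), n, "T"),
                 topn_accuracy(list(rec2), n, "T"))
    expect_equal(topn_accuracy(list(rec1), n, "P"),
                 topn_accuracy(list(rec2), n, "P"))
  }
})
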