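# Ranking metrics: top-N accuracy under the exact-template (T) and
# exact-precursor/product (P) success criteria, applicability, and
# outcome-averaged top-N accuracy (templates with k unranked outcomes give
# fractional credit). The T-P gap at fixed N measures nonexclusivity.

#' Construct a ranked recommendation
#'
#' One query molecule together with an ordered template suggestion list and
#' the recorded ground truth.
#'
#' @param query_id identifier
#' @param query query molecule SMILES
#' @param templates character vector of template strings, best first
#' @param scores numeric scores, non-increasing (defaults to `1/rank`)
#' @param truth_template the extracted ground-truth template string
#' @param truth_outcome character vector: the recorded outcome molecules
#'   (will be stored as sorted canonical SMILES)
#' @return object of class `ranked_recommendation`
#' @export
ranked_recommendation <- function(query_id, query, templates, scores = NULL,
                                  truth_template, truth_outcome) {
  if (is.null(scores)) scores <- 1 / seq_along(templates)
  stopifnot(length(scores) == length(templates),
            all(diff(scores) <= 1e-12))
  structure(list(query_id = query_id, query = query,
                 templates = as.character(templates),
                 scores = as.numeric(scores),
                 truth_template = truth_template,
                 truth_outcome = sort(vapply(truth_outcome, canonical_smiles,
                                             character(1), USE.NAMES = FALSE),
                                      method = "radix")),
            class = "ranked_recommendation")
}

.outcome_cache <- function() new.env(parent = emptyenv())

.cached_outcome <- function(template, query, cache) {
  key <- paste0(template, "\r", query)
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- suppressWarnings(apply_template(template, query))
  cache[[key]] <- res
  res
}

.truth_key <- function(rec) paste(rec$truth_outcome, collapse = ".")

.p_hit_rank <- function(rec, cache) {
  tk <- .truth_key(rec)
  for (r in seq_along(rec$templates)) {
    ao <- .cached_outcome(rec$templates[r], rec$query, cache)
    keys <- vapply(ao$outcomes, function(s) paste(s, collapse = "."), character(1))
    if (tk %in% keys) return(r)
  }
  Inf
}

.t_hit_rank <- function(rec, canonical, replacement) {
  xs <- rec$templates
  truth <- rec$truth_template
  if (canonical) {
    xs <- vapply(xs, function(s) canonicalize(s)$canonical_string, character(1),
                 USE.NAMES = FALSE)
    truth <- canonicalize(truth)$canonical_string
    if (!is.null(replacement)) {
      xs <- ifelse(xs %in% names(replacement), replacement[xs], xs)
      if (truth %in% names(replacement)) truth <- replacement[[truth]]
    }
  }
  hit <- which(xs == truth)
  if (length(hit) == 0L) Inf else hit[1]
}

#' Top-N accuracy of ranked recommendations
#'
#' Criterion `"T"` counts a query as a hit when the ground-truth template
#' itself appears among the top N suggestions (by canonical form when
#' `canonical = TRUE`, optionally routed through a correction `replacement`
#' map; by raw string otherwise). Criterion `"P"` counts a hit when any
#' top-N template, applied to the query, produces exactly the recorded
#' outcome molecules. With nonexclusive or duplicate templates T lags P; for
#' a mutually exclusive canonical template set the two coincide.
#'
#' @param recs list of `ranked_recommendation`
#' @param N integer vector of cutoffs
#' @param criterion `"T"` or `"P"`
#' @param canonical compare templates by canonical form? (T criterion only)
#' @param replacement optional named character vector mapping canonical
#'   strings of pruned templates to their surviving root (T criterion only)
#' @param cache optional outcome cache environment (reused across metrics)
#' @return named numeric vector of fractions, one per `N`
#' @export
topn_accuracy <- function(recs, N, criterion = c("T", "P"), canonical = TRUE,
                          replacement = NULL, cache = .outcome_cache()) {
  criterion <- match.arg(criterion)
  stopifnot(length(recs) > 0L, all(N >= 1L))
  ranks <- vapply(recs, function(rec) {
    if (criterion == "T") .t_hit_rank(rec, canonical, replacement)
    else .p_hit_rank(rec, cache)
  }, numeric(1))
  out <- vapply(N, function(n) mean(ranks <= n), numeric(1))
  names(out) <- paste0("top", N)
  out
}

#' Outcome-averaged top-N accuracy
#'
#' Lays the outcome sets of the ranked templates out in rank order: a
#' template producing k outcome sets occupies k consecutive outcome slots,
#' unranked among themselves. The query's credit at cutoff N is the
#' probability that the correct outcome falls into the first N slots under a
#' uniformly random within-template ordering: if the correct template's
#' window starts at slot s with k outcomes, credit is
#' `clamp(N - s + 1, 0, k) / k`. A top-ranked template with three outcomes,
#' one correct, therefore contributes 1/3 at N = 1.
#'
#' @inheritParams topn_accuracy
#' @return named numeric vector of fractions, one per `N`
#' @export
outcome_averaged_topn <- function(recs, N, cache = .outcome_cache()) {
  stopifnot(length(recs) > 0L, all(N >= 1L))
  per_query <- vapply(recs, function(rec) {
    tk <- .truth_key(rec)
    slot <- 0L
    window <- NULL
    for (r in seq_along(rec$templates)) {
      ao <- .cached_outcome(rec$templates[r], rec$query, cache)
      k <- length(ao$outcomes)
      keys <- vapply(ao$outcomes, function(s) paste(s, collapse = "."), character(1))
      if (tk %in% keys) {
        window <- c(start = slot + 1L, k = k)
        break
      }
      slot <- slot + k
    }
    if (is.null(window)) return(rep(0, length(N)))
    vapply(N, function(n) {
      min(max(n - window[["start"]] + 1L, 0L), window[["k"]]) / window[["k"]]
    }, numeric(1))
  }, numeric(length(N)))
  out <- if (length(N) == 1L) mean(per_query) else rowMeans(per_query)
  names(out) <- paste0("top", N)
  out
}

#' Fraction of applicable templates among the top N
#'
#' Mean over queries of the share of the N highest-ranked templates that
#' produce at least one outcome when applied to the query molecule. When a
#' query has fewer than N suggestions the available count is used as the
#' denominator and the result carries a `short_lists` attribute.
#'
#' @inheritParams topn_accuracy
#' @param N single cutoff
#' @return fraction in [0, 1]
#' @export
applicability_at_n <- function(recs, N, cache = .outcome_cache()) {
  stopifnot(length(recs) > 0L, N >= 1L)
  short <- 0L
  vals <- vapply(recs, function(rec) {
    avail <- min(N, length(rec$templates))
    if (avail < N) short <<- short + 1L
    app <- vapply(seq_len(avail), function(r) {
      .cached_outcome(rec$templates[r], rec$query, cache)$applicable
    }, logical(1))
    mean(app)
  }, numeric(1))
  structure(mean(vals), short_lists = short)
}

#' Template popularity histogram
#'
#' Counts templates per reactions-per-template bin; the default bins are
#' 1, 2-9, 10-99 and >=100 reactions.
#'
#' @param templates list of `rxn_template` (provenance in `reaction_ids`) or
#'   an integer vector of reaction counts
#' @param breaks increasing lower bin edges (first must be 1)
#' @return named integer vector of bin counts summing to the template count
#' @export
popularity_histogram <- function(templates, breaks = c(1, 2, 10, 100)) {
  counts <- if (is.numeric(templates)) as.integer(templates)
            else vapply(templates, function(t) length(t$reaction_ids), integer(1))
  stopifnot(all(counts >= 1L), breaks[1] == 1, !is.unsorted(breaks))
  edges <- c(breaks, Inf)
  labs <- vapply(seq_along(breaks), function(k) {
    lo <- breaks[k]; hi <- edges[k + 1] - 1
    if (is.infinite(edges[k + 1])) paste0(">=", lo)
    else if (lo == hi) as.character(lo)
    else paste0(lo, "-", hi)
  }, character(1))
  bin <- findInterval(counts, breaks)
  out <- tabulate(bin, nbins = length(breaks))
  names(out) <- labs
  out
}

#' Metric report over a recommendation set
#'
#' Convenience wrapper computing T and P top-N accuracy, the nonexclusivity
#' gap P - T, outcome-averaged accuracy, and applicability for a vector of
#' cutoffs.
#'
#' @inheritParams topn_accuracy
#' @param N integer vector of cutoffs
#' @return data.frame with one row per N: `T`, `P`, `gap`, `outcome_avg`,
#'   `applicability`
#' @export
evaluate_recommendations <- function(recs, N = c(1, 3, 5, 10),
                                     canonical = TRUE, replacement = NULL,
                                     cache = .outcome_cache()) {
  tacc <- topn_accuracy(recs, N, "T", canonical = canonical,
                        replacement = replacement, cache = cache)
  pacc <- topn_accuracy(recs, N, "P", cache = cache)
  oavg <- outcome_averaged_topn(recs, N, cache = cache)
  app <- vapply(N, function(n) as.numeric(applicability_at_n(recs, n, cache = cache)),
                numeric(1))
  data.frame(N = N, T = as.numeric(tacc), P = as.numeric(pacc),
             gap = as.numeric(pacc - tacc), outcome_avg = as.numeric(oavg),
             applicability = app)
}
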