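# Shared fixture corpora, built once per test run.

.corpus_memo <- new.env(parent = emptyenv())

memo_corpus <- function(name, spec) {
  if (is.null(.corpus_memo[[name]])) {
    .corpus_memo[[name]] <- generate_corpus(spec)
  }
  .corpus_memo[[name]]
}

# small corpus with every defect type planted
small_corpus <- function() {
  memo_corpus("small", fixture_spec(n_cores = 3L, classes_per_core = 2L,
                                    p_branch = 1, p_group = 1, seed = 7L))
}

# corpus with no planted defects and singleton classes
clean_corpus <- function() {
  memo_corpus("clean", fixture_spec(n_cores = 3L, classes_per_core = 2L,
                                    multiplicities = 1L, mult_probs = 1,
                                    p_branch = 0, p_group = 0, seed = 5L))
}

corpus_levels <- function(corpus, levels = c("r0", "r1", "r2", "r3", "default")) {
  template_records_all(corpus$templates)[levels]
}

# full hierarchical correction of the small corpus, computed once
small_correction <- function() {
  if (is.null(.corpus_memo$small_corr)) {
    .corpus_memo$small_corr <- correct_hierarchically(corpus_levels(small_corpus()))
  }
  .corpus_memo$small_corr
}

# Random same-parent cluster of templates for correction-oracle tests: all
# members share the core and first context atoms (the radius-1 parent),
# then specialize randomly in depth, branching and special groups.
random_cluster <- function(n_members = 5L, level = "r3") {
  cat_ <- core_catalog()
  core <- cat_[[sample.int(length(cat_), 1L)]]
  first <- lapply(core$attach, function(a) sample(c("C", "N", "O"), 1L))
  members <- lapply(seq_len(n_members), function(k) {
    context <- list()
    for (ai in seq_along(core$attach)) {
      d <- sample.int(3L, 1L)
      elems <- c(first[[ai]],
                 if (d > 1L) sample(c("C", "N", "O"), d - 1L, replace = TRUE))
      branch <- sample(c(0L, 1L), 1L, prob = c(0.7, 0.3))
      context[[as.character(core$attach[ai])]] <- list(
        elems = elems, branch_pos = branch,
        branch_elem = if (branch > 0L) sample(c("C", "N", "O"), 1L)
                      else NA_character_)
    }
    motif <- if (level == "default" && runif(1) < 0.4) {
      sample(c("nitro", "dioxolane"), 1L)
    } else NULL
    t <- retempl:::.make_class_template(core, context,
                                        if (level == "default") "default"
                                        else as.integer(sub("r", "", level)),
                                        motif,
                                        reaction_ids = sprintf("M%02d", k))
    t
  })
  members
}
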