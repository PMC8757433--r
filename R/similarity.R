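# Precedent-similarity baseline ranker: circular (Morgan-style) fingerprints
# from iterated WL atom environments, hashed to a fixed-width bit set with
# FNV-1a; templates are scored by the maximum Tanimoto similarity between
# the query and any precedent molecule carrying the template.

# 32-bit FNV-1a over a string, in double arithmetic (split multiply keeps
# every intermediate below 2^53).
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

#' Circular fingerprint of a molecule
#'
#' Computes Morgan-style atom environment identifiers: each atom's initial
#' invariant (element, aromaticity, charge, H count, degree) is iteratively
#' extended by its neighbours' identifiers and bond symbols up to the given
#' radius, and every (radius, identifier) pair is hashed to one of `nbits`
#' bits.
#'
#' @param mol `molecule` or SMILES string
#' @param radius environment radius (default 2, the conventional ECFP4-like
#'   setting)
#' @param nbits fingerprint width (default 2048)
#' @return sorted integer vector of on-bit positions (0-based)
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$atoms)
  adj <- .side_adjacency(mol)
  lab <- vapply(mol$atoms, function(a) {
    paste(a$symbol, isTRUE(a$aromatic), a$charge, a$hcount,
          sep = "|")
  }, character(1))
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  lab <- paste(lab, deg, sep = "|")
  idents <- paste0("0~", lab)
  for (r in seq_len(radius)) {
    lab <- vapply(seq_len(n), function(v) {
      nb <- adj[[v]]
      if (is.null(nb)) return(lab[v])
      ext <- sort(paste0(nb$b, lab[nb$nbr]), method = "radix")
      paste(lab[v], paste(ext, collapse = ","), sep = ">")
    }, character(1))
    idents <- c(idents, paste0(r, "~", lab))
  }
  bits <- vapply(unique(idents), function(s) .fnv1a(s) %% nbits, numeric(1))
  sort(unique(as.integer(bits)))
}

#' Tanimoto similarity of two bit sets
#'
#' @param a,b integer vectors of on-bit positions
#' @return `|a intersect b| / |a union b|` (0 when both are empty)
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Precedent-similarity template ranking
#'
#' Ranks the templates of a precedent corpus for a query molecule: each
#' template scores the maximum Tanimoto similarity between the query
#' fingerprint and the fingerprint of any precedent molecule associated with
#' that template. Ties are broken by canonical template string so rankings
#' are reproducible.
#'
#' @param query query molecule SMILES
#' @param corpus data.frame with columns `reaction_id`, `smiles` (precedent
#'   molecule: the product for retro templates), `template`
#' @param query_id identifier for the returned recommendation
#' @param truth_template,truth_outcome optional ground truth to attach
#' @param radius,nbits fingerprint parameters
#' @return a `ranked_recommendation` (with `NA` ground truth when not given)
#' @export
similarity_rank <- function(query, corpus, query_id = "q1",
                            truth_template = NA_character_,
                            truth_outcome = character(0),
                            radius = 2L, nbits = 2048L) {
  stopifnot(is.data.frame(corpus), nrow(corpus) > 0L,
            all(c("smiles", "template") %in% names(corpus)))
  qfp <- morgan_fingerprint(query, radius, nbits)
  sims <- vapply(corpus$smiles, function(s) {
    tanimoto(qfp, morgan_fingerprint(s, radius, nbits))
  }, numeric(1), USE.NAMES = FALSE)
  score <- tapply(sims, corpus$template, max)
  tmpl <- names(score)
  canon <- vapply(tmpl, function(s) canonicalize(s)$canonical_string,
                  character(1), USE.NAMES = FALSE)
  ord <- order(-as.numeric(score), canon, method = "radix")
  rec <- structure(list(query_id = query_id, query = query,
                        templates = tmpl[ord],
                        scores = as.numeric(score)[ord],
                        truth_template = truth_template,
                        truth_outcome = if (length(truth_outcome) > 0L) {
                          sort(vapply(truth_outcome, canonical_smiles,
                                      character(1), USE.NAMES = FALSE),
                               method = "radix")
                        } else character(0)),
                   class = "ranked_recommendation")
  rec
}
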