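---
title: "Curating reaction-template libraries: canonicalization, hierarchical correction, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating reaction-template libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retempl)
```

## The problem

Template-based retrosynthesis and forward-prediction models rank *reaction
templates* — generalized transformations written as a pair of SMARTS
patterns connected by atom mapping — for a query molecule. Template sets
extracted automatically from reaction databases suffer from two defects
that silently distort both training and evaluation:

* **duplicates** — the same transformation written as different strings
  (different atom-map numbering, different atom order);
* **nonexclusive templates** — distinct templates describing the same
  transformation on overlapping molecule sets, typically because one
  pattern embeds as a subgraph of the other (a linear context chain versus
  the same chain with a branch; a template with an appended special-group
  motif versus its group-free sibling).

With such defects, "recommend the exact extracted template" (criterion T)
and "reproduce the exact recorded precursors after application" (criterion
P) diverge: a model is punished for recommending a template that produces
precisely the right molecules. The T–P gap at fixed cutoff N is therefore a
direct measurement of nonexclusivity, and closing it is the goal of the two
algorithms this package implements.

## Canonicalization

A template is canonicalized on its **condensed graph**: the pattern graphs
of the two sides are merged so that atoms sharing a nonzero atom-map number
become a single node; unmapped or one-sided atoms stay singleton nodes, and
every edge keeps a side tag, so a bond broken by the transformation is
visible as a left-tagged edge without a right counterpart.

Node ranking uses **Weisfeiler–Lehman (WL) colour refinement**. The initial
label of a node is the tuple (left degree, right degree, map-free atomic
SMARTS of the left query, same for the right); each sweep relabels a node
by its own label plus the sorted multiset of (side-tagged bond SMARTS,
neighbour label) pairs, until the partition is stable or |V| sweeps have
run. Refinement is monotone — cells split, never merge. Labels are ranked
strings, never salted hashes, so results are identical across sessions and
machines.

1-WL cannot separate the orbits of certain highly symmetric graphs, so a
stable partition may leave ties. These are resolved by
**individualization–refinement**: each node of the first non-singleton cell
(in cell order) is individualized in turn, the partition re-refined, and
recursion continues until discrete; among all discrete branches the one
with the lexicographically smallest *graph certificate* (node features in
rank order plus the ranked edge list) wins. Two discrete labellings have
equal certificates exactly when they differ by an automorphism, which makes
the final ranking invariant under relabelling of the input. The branch
budget defaults to 64 discrete labellings — far above anything the
chemistry in scope produces (a fully symmetric six-ring explores 12). If a
pathological graph exceeds the budget, the template is emitted with a
deterministic heuristic ranking and a `nonunique_risk` flag rather than
failing; such strings are still stable for a fixed input, just not
guaranteed invariant.

The canonical string then renumbers atom maps 1..k in rank order, emits
atoms in a rank-driven depth-first traversal (start at the lowest-ranked
atom of each fragment, neighbours visited by rank, ring-closure digits in
visit order, every bond written explicitly), sorts fragments within a side
by their emitted strings, and joins the sides as `lhs>>rhs`. Atomic queries
serialize their primitives in a frozen order — symbol, charge, H count,
degree, connectivity, chirality — because that string doubles as a WL
feature; changing the order would change canonical forms.

Only And-conjunctions of simple atomic primitives are supported; the parser
rejects Or, negation, recursive SMARTS, and compound wildcards with an
error naming the offending token. That restriction matches what automated
template extractors emit, and it is what makes pattern-against-pattern
comparison decidable with a plain subgraph matcher. Equality of canonical
strings is verified against brute-force condensed-graph isomorphism on all
small fixtures in the test suite.

## Hierarchical correction

Template A **subsumes** B when each side of A's query graph embeds as a
substructure into the corresponding side of B *treated as a structure*
(query-built atoms with default charge 0 and pattern-graph degrees): every
molecule B matches, A matches too, so keeping both makes the set
nonexclusive and only the more general A should survive.

Pairwise subsumption over a whole library is quadratic in subgraph
isomorphism calls and can also produce spurious matches between templates
with different reaction centres. Both problems are avoided by working
**cluster-wise and level-wise**:

1. Templates at the level being corrected are clustered by the *corrected*
   canonical parent template of their reactions at the next-lower level.
   Within a cluster all members encode the same transformation core, which
   also makes an atom-map cross-check between matches unnecessary (a strict
   map-verified mode exists for template sets produced by a foreign
   extractor).
2. Within each cluster an **exclusivity tree** is built by iterative
   insertion in ascending template size (ties by canonical string): a new
   template is compared only against the current roots. A root that
   subsumes it adopts it; if it subsumes roots, it absorbs them (their
   subtrees are path-compressed onto the new root); otherwise it becomes a
   new root. On exit roots are pairwise incomparable, and every pruned
   template maps to its surviving root in a replacement table. Ascending
   size insertion makes general templates roots early; the test suite
   checks the tree against exhaustive all-pairs pruning on hundreds of
   randomized clusters.
3. Levels are corrected in the fixed order: radius 1 clustered at radius 0;
   then the default level (radius 1 plus special groups) and radius 2, both
   clustered at corrected radius 1; then radius 3 clustered at corrected
   radius 2. Radius 0 has no lower level and cannot be corrected, which is
   why canonical deduplication matters most there — errors at radius 0
   propagate up the scheme through wrong clustering.

The reactions of a pruned template are reassigned to its surviving root, so
the reaction-id multiset is conserved — the corrected set describes exactly
the same chemistry with fewer, mutually exclusive patterns. A welcome side
effect at the default level: special-group decorations that are not shared
by all reactions of a cluster are pruned automatically, because the
group-free member subsumes the decorated ones; groups that occur in every
reaction of their cluster, or in single-reaction templates, are kept. The
method never invents new, more general patterns — it only selects among the
extracted ones.

A template whose reactions straddle two parent classes (impossible with a
deterministic extractor) is split into per-cluster copies with a warning
rather than rejected.

## Evaluation metrics

`apply_template()` matches the pattern side against a query molecule and
rewrites each substructure embedding: bonds matched by pattern bonds are
replaced by the other side's bonds, pattern-only atoms are deleted,
other-side-only atoms created, charges updated, and hydrogens refilled by
valence; each embedding yields one outcome molecule set, deduplicated by
canonical SMILES.

* **Top-N accuracy (T)** — the ground-truth template appears among the top
  N suggestions; by raw string for uncorrected sets, by canonical form
  (optionally routed through the correction replacement map) otherwise.
* **Top-N accuracy (P)** — some top-N template applied to the query yields
  exactly the recorded outcome molecules (order-free set comparison of
  canonical SMILES). T ≤ P always; T = P for a mutually exclusive set.
* **Outcome-averaged top-N** — templates often produce several outcome sets
  that are unranked among themselves, so outcomes are laid out in rank
  order (a template with k outcomes fills k consecutive slots; an
  inapplicable template fills none) and a query whose correct outcome sits
  in a window starting at slot s with k slots is credited
  `clamp(N − s + 1, 0, k) / k` — the probability that a uniformly random
  within-template ordering places the correct outcome in the first N slots.
  The canonical worked example: a top-ranked template with three precursor
  sets, one correct, contributes 1/3 (33.3 %) at N = 1. This penalizes very
  general (small-radius) templates that fire everywhere.
* **Applicability at N** — mean fraction of the N highest-ranked templates
  that produce at least one outcome. When a query has fewer than N
  suggestions the available count is the denominator and the result is
  flagged; the alternative (dividing by N) would conflate short lists with
  inapplicability.
* **Similarity baseline** — precedent reactions are ranked by the maximum
  Tanimoto similarity of Morgan-style circular fingerprints (radius 2,
  2048 bits — the conventional ECFP4-like setting) between the query and
  any precedent molecule carrying the template; score ties break by
  canonical template string so rankings are reproducible.

## The synthetic corpus generator

Real template corpora require large reaction databases; the generator
instead builds template sets whose defects are *planted and therefore
known*. Five chemically sane retro cores (ester cleavage, amide coupling,
N-alkylation, reductive amination, sulfonamide formation) are decorated
with acyclic C/N/O context chains (depth 1–3 per attachment point,
emulating extraction radii; every class keeps ≥ 1 context atom per
attachment so radius-1 templates stay mutually exclusive by construction —
first-shell element combinations are assigned without repetition within a
core). All fixtures stay at ≤ ~15 heavy atoms so brute-force oracles remain
tractable.

* **Duplicates**: a class's reactions all share one context graph; each
  reaction's template strings are re-emitted with shuffled atom order and
  remapped atom numbers. Base-class multiplicities are sampled from
  {1, 2, 3} with weights 0.5/0.3/0.2 — a skew toward rare templates that
  mirrors the long-tailed popularity of real extracted sets.
* **Branched-context variants** (nonexclusive at radii 2–3): the base
  context plus one extra branch atom at distance 2, subsumed by the linear
  base.
* **Special-group variants** (nonexclusive at the default level): the base
  radius-1 context plus a motif — a nitro group (exercising charges) or a
  dioxolane ring (exercising ring closures) — subsumed by the group-free
  base. Variants carry one reaction each, as real rare decorated templates
  do; this also makes the singleton-template fraction provably
  non-increasing under correction.

Every planted subsumption is verified with `subsumes()` at generation time
and the generator aborts if a plant fails. Ground-truth class and survivor
assignments are derived from the construction, not from the algorithms
under test. `generate_recommendations()` additionally plants ranked lists
in which a duplicate or nonexclusive sibling of the truth occupies rank 1
while the truth sits outside the top 5, so the pre-correction T/P gap is an
exact arithmetic consequence of the plant and must vanish after correction.

What the generator does **not** emulate: aromatic ring context (aromatic
chemistry is exercised in unit tests, not in corpora), stereochemistry
beyond opaque tags, reagents/conditions, extraction noise, and the class
counts of patent-scale reaction databases. Passing tests therefore demonstrate the algorithms' contracts
(invariance, oracle equivalence, exact gap closure), not performance on any
real reaction dataset.

## Numerical and degenerate-input choices

* Implicit hydrogens use a fixed-valence model (B 3, C 4, N 3, O 2, P 3,
  S 2, halogens 1; aromatic atoms reserve one valence unit; positive charge
  on N/P/B adds a bonding slot, negative charge removes one). Bracket atoms
  without an explicit H count are valence-filled — a deliberate deviation
  from strict SMILES (which would give 0) so that pattern atoms instantiate
  to sensible molecules.
* Unmapped one-sided atoms participate in WL with an "absent" placeholder
  for the missing side; the left/right degrees are kept as separate
  features rather than summed.
* Bond symbols are always written explicitly (including `-` and `:`),
  removing any implicit-bond ambiguity between aromatic and aliphatic
  neighbours at the cost of slightly longer strings.
* Empty sides, duplicate maps within a side, and multiple `>>` separators
  are parse errors; mapped atoms appearing only on the right side are
  accepted with a warning (no known extractor emits them).
* Template-application failures on individual templates are caught and
  recorded as inapplicable with a warning, never failing a batch.

## Problem sizes

The test suite validates canonicalization invariance on 1000 corpus
templates × 10 random re-emissions each, canonical-vs-isomorphism oracle
equivalence on all fixtures with ≤ 8 condensed-graph nodes, and
tree-vs-exhaustive correction equivalence on 200 randomized clusters of
3–8 members — sizes at which the brute-force oracles are exact and the
whole suite runs in a few minutes on one CPU.

## Limitations

* 1-WL + individualization–refinement with a finite budget is not a
  guaranteed-unique canonical form for arbitrary graphs; flagged strings
  should be treated as potentially non-unique (the correction stage's
  subgraph tests are unaffected).
* The SMARTS subset excludes Or/negation/recursion; foreign template sets
  using them are rejected at parse time rather than mis-compared.
* The valence model is a simplification; exotic oxidation states or
  organometallics would need explicit H counts.
* Correction never introduces more general templates than were extracted;
  a library whose most general representative is missing stays nonexclusive
  at that site.
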