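---
title: "Quantifying birth-and-death dynamics of a gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying birth-and-death dynamics of a gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdfam)
```

## The model

Under the birth-and-death view of multigene-family evolution, member genes
evolve independently: some lineages ("stable" clades) persist as a single
copy in every genome of a sampled group, while others ("unstable" clades)
duplicate, get lost, or pseudogenize repeatedly. Stable members tend to
carry core physiological functions; unstable members track rapidly diverging
traits. `bdfam` operationalizes this contrast with four linked analyses.

**Clade branch-length statistics.** On a gene phylogram, the cumulative
branch length of a clade is the sum of all branch lengths within it:

> CBL(c) = sum of every terminal and internal edge strictly below the
> clade's most recent common ancestor (MRCA).

The MRCA's own subtending (stem) edge is *not* within the clade, so it is
excluded; a single-tip clade has CBL 0. Because CBL grows trivially with
clade size, the normalized CBL divides by the number of member sequences,
`nCBL = CBL / n`. The cumulative patristic distance adds the branches from
the tree root down to the node supporting the clade, `CPD = CBL +
path(root, MRCA)`. Whether the MRCA's stem edge belongs to that root path
is a genuine ambiguity of the verbal definition; we include it by default
(`include_stem = TRUE`), reading "the node supporting the clade" as the
MRCA reached through its stem, and expose the exclusive alternative as an
option. When the MRCA is the root the two conventions coincide and
`CPD = CBL`.

**Stability classification.** From a clade-by-species matrix of functional
copies and pseudogene copies, a clade is *stable* iff it has at least one
copy in every species. Pseudogenes do not count as presence by default: a
pseudogenized copy is a loss in progress, not a retained gene. Set
`count_pseudogenes = TRUE` to override. The call depends only on presence,
never on copy-number magnitude.

**Dollo gain/loss reconstruction.** Each clade is assumed to originate once
and never be regained. The origin is placed at the MRCA (on the species
tree) of the species that carry the clade — the most parsimonious single
origin — and losses are placed on the edges subtending the *maximal
all-absent subtrees* below the origin. A post-order pass computes, for each
node, whether every descendant tip lacks the clade; a loss edge is any
all-absent node whose parent is not all-absent. This decomposition is
unique, so no tie-breaking is ever needed, and the number of losses equals
the exhaustive-enumeration minimum (the test suite verifies this over all
presence patterns on small random trees, including polytomies). When
external evidence (e.g. outgroups) argues for a deeper origin than the
extant distribution implies, `origin_at_root` forces the named clades to
originate at the root, which converts their missing basal lineages into
explicit losses. Ancestral repertoire sizes then follow by counting clades
whose presence flag is true at a node, and
`repertoire_lower_bound(n_clades, n_lineage_specific_duplicates)` gives the
conservative ancestral count after removing clades that arose through
duplications confined to one species group.

**Selection-test post-processing.** Branch-site codon-model fits are
consumed as pairs of log-likelihoods; `lrt()` forms `2(lnL_alt − lnL_null)`
and its upper chi-squared tail. A negative statistic — possible when the
alternative fit converged to a local optimum — is clamped to 0 with a
warning rather than rejected, so real optimizer output can be processed in
bulk. The Holm step-down correction multiplies the i-th smallest p-value by
`(m − i + 1)` under a running maximum; the running maximum matters, as the
largest raw value can be lifted above its naive `1 × p`. Model parameters
(site-class proportions, dN/dS ratios) are validated for range and passed
through untouched: this package never estimates codon models.

**Group comparison.** The stable-vs-unstable contrast on a branch-length
metric is a two-sample t-test over clades. The default is the classical
pooled-variance two-sided form (`df = nA + nB − 2`), which matches the
degrees of freedom conventionally reported for such comparisons; Welch's
form is available via `flavor = "welch"`. Groups of fewer than two clades,
and all-identical data (zero pooled variance), are domain errors.

## The synthetic-data generator

`simulate_family()` plants one gene lineage per clade at the species-tree
root. Along each species-tree edge of duration *T*, every extant lineage
independently follows a linear birth–death process with duplication rate λ
and loss rate μ (events per lineage per unit time), simulated event by
event (Gillespie) so that the full event log is available for validating
the Dollo reconstruction. At each speciation node every surviving lineage
is copied into all daughter edges. Gene-tree branch lengths are elapsed
time multiplied by a per-class rate multiplier *r* (substitutions/site per
time unit), so a fast class can be simulated by `r > 1` without touching
the duplication process.

Defaults emulate a 12-genome fly-like study: 12 stable clades (λ = μ = 0,
r = 1) and 6 unstable clades (λ = μ = 0.05 per unit time, r = 2) on the
packaged 12-species tree (root at 60 time units, node heights from round
published divergence-time estimates), which yields on the order of 15–20
gene copies per genome. A loss occurring on a terminal edge leaves, with
probability `pseudogene_prob` (default 0.1, matching the rarity of
detectable pseudogenes relative to losses in real gene-family surveys), a
flagged pseudogene tip truncated at the loss time; losses on internal edges
are always silent, because a pseudogene can only be observed in a sequenced
extant genome. A single global seed drives one child stream per clade, so
enlarging the clade set never perturbs clades already simulated, and
identical configurations produce byte-identical output files.

What the generator deliberately does **not** emulate: sequence-level
evolution (no alignments, no codons, hence no selection acting on sites),
rate variation among lineages within a class, gene conversion between
clades (the birth-and-death model explicitly excludes concerted evolution),
and horizontal transfer or regain (a Dollo world). Passing tests on
simulated data therefore validate the bookkeeping and the statistics, not
the adequacy of the birth–death model for any particular real family.

## Numerical and design choices

* Missing Newick branch lengths become 0 with a warning (published trees
  often lack a root edge length); `missing_lengths = "error"` makes this
  strict. Negative branch lengths and duplicate tip labels are always
  errors.
* Non-monophyletic clade assignments are errors by default;
  `force_mrca = TRUE` computes over the full MRCA subtree and records
  `monophyletic = FALSE`.
* Single-tip clades are legal everywhere (a pseudogenized singleton is a
  clade), with CBL = 0.
* All internal computation is double precision; rounding (e.g. two
  significant figures for reported p-values) is applied only at the
  formatting layer, never before a comparison.
* Chi-squared tails are evaluated as upper-tail probabilities directly
  (`lower.tail = FALSE`), keeping full relative accuracy at magnitudes of
  1e-12 and beyond.
* Tables are UTF-8 TSV with a header row; `report.json` aggregates every
  stage's numbers and is byte-stable across re-runs on identical inputs.

## Validation strategy and problem sizes

The test suite checks every statistic against an independent route:
branch-length sums against brute-force edge enumeration (40 random trees of
5–12 tips, plus 1000 random trees for the additivity and scaling laws);
Dollo loss counts against exhaustive enumeration over all single-origin,
loss-subset placements on every presence pattern of 4–6-tip trees; the
Holm correction against a hand transcription of the step-down rule and a
published six-test table; the chi-squared tail against its `erfc` closed
form at one degree of freedom; and the simulator against the analytic
birth–death mean `E[N(T)] = e^{(λ−μ)T}` (10,000 replicates at λ = 0.3,
μ = 0.1, T = 1, asserted within three Monte-Carlo standard errors) and a
10,000-replicate type-I-error calibration of the t-test. These sizes keep
the full suite under about a minute while leaving the Monte-Carlo
assertions well resolved.

## Known limitations

* Dollo parsimony reports the *minimum* loss scenario; true histories with
  regain or with losses hidden by subsequent duplication are undercounted
  by construction.
* The ancestral lower bound is arithmetic on clade annotations; it is only
  as good as the lineage-specific-duplicate calls supplied with the data.
* Under extreme turnover the group comparison loses power: with the default
  generator settings (λ = μ = 0.05 over a depth-60 tree, i.e. λt = 3 per
  root-to-tip path) three quarters of gene lineages go extinct per path,
  surviving unstable clades are ragged (many near-singletons with nCBL near
  0), and the stable class has *zero* variance because its process is
  deterministic. The replicated power study in the test suite (200 seeded
  replicates) rejects in roughly 45% of replicates under these conditions —
  an honest ceiling of the pooled two-sided test in this corner of
  parameter space, driven by the simulation conditions rather than by the
  implementation (the same suite verifies the simulator's analytic mean and
  the test's type-I calibration). Real gene families, whose stable members
  do vary and whose unstable members lose only a few species, are an easier
  target than this stress test.
* The pipeline consumes codon-model log-likelihoods; it cannot detect a
  poorly converged upstream fit beyond clamping negative statistics.
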