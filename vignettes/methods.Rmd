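---
title: "Selecting the number of temporal clusters from kinase-substrate knowledge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of temporal clusters from kinase-substrate knowledge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosClue)
```

## The model

Time-course phosphoproteomics yields a matrix of phosphosite abundance
profiles over a handful of time points. Substrates of an active kinase tend
to move together, so clustering the (standardized) profiles groups sites by
putative upstream regulator. The open parameter is the number of clusters
`k`. phosClue treats curated kinase-substrate annotation as an external
information source and asks, for every candidate partitioning: *how
surprising is the way known substrate sets concentrate inside clusters?*

For cluster `i` and kinase `j`, the 2×2 contingency over all clustered
sites (`a` = substrates of `j` in `i`, `b` = its substrates elsewhere, `c`
= other sites in `i`, `d` = the rest) is tested one-sidedly with Fisher's
exact test — equivalently the hypergeometric upper tail `P(X >= a)` with
fixed margins, since with margins fixed a larger odds ratio is exactly a
larger `a`. Each cluster contributes its best kinase,
`p(cluster_i) = min_j p_ij`, and the `k` values are combined with Fisher's
combined probability test: `X = -2 * sum(log p(cluster_i))` referred to a
chi-squared distribution with `2k` degrees of freedom. The enrichment score
is `E_k = -log10(P_k)`. The sweep fits the data at each `k` in a range,
averages `E_k` over random restarts, and selects the maximizing `k`.

Two modelling caveats are worth stating plainly. First, the per-cluster
minimum is an extreme order statistic over `m` kinases, not a uniform
p-value; the combination treats it as if it were uniform, exactly as the
score is defined. `E_k` is therefore a relative ranking criterion across
`k`, not a calibrated significance level. Second, the per-cluster tests
share one dataset and are not independent; again this affects calibration,
not the ranking use. Both caveats motivated the permutation null described
below.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k_range` | 2–20 | cluster numbers evaluated; raise the ceiling for rich datasets (dense insulin-response-style courses can support 30+) |
| `repeats` | 10 | random restarts per `k`; the score averages over them |
| `method` | `cmeans` | fuzzy c-means; `kmeans` gives the classic hard variant |
| `fuzzifier` | 2 | c-means fuzziness exponent (dimensionless); values near 1 approach k-means |
| `min_substrates` | 2 | a kinase needs this many in-dataset substrates to enter the tests — one substrate cannot drive enrichment but would still compete in the per-cluster minimum |
| `standardize` | TRUE | row z-score (population SD) before clustering, so Euclidean distance compares shapes, not magnitudes |
| `select` | `modal` | how the optimum is chosen from the restarts (see below) |
| `alpha` (reporting) | 0.05 | raw Fisher p threshold for the per-cluster kinase report; Benjamini–Hochberg is available but off by default, matching the conventional raw-p report |

Initialization draws `k` distinct data rows uniformly under the seed — the
plain random-restart protocol. A k-means++-style start would converge more
reliably per restart, but the restart ensemble is the object the selection
is defined on, so the simple protocol is kept.

## Aggregating restarts: votes, not means

The score-vs-k *curve* reported and plotted is the restart mean of `E_k`.
The selected `k`, however, defaults to a vote: each restart index
contributes its own argmax-k, and the modal vote wins (`select = "modal"`;
`select = "mean"` gives the plain argmax of the mean curve). The reason is
robustness at the optimum itself. With `k` equal to the true cluster
number, most restarts reach the globally coherent partition, but
occasionally one or two land in a merge-and-split local optimum whose
score is far below — and because the scores at neighbouring `k` are
tightly clustered, a single bad restart at the true `k` can push its
*mean* below that of `k + 1`, which suffers no such outliers (the extra
centroid gives every restart enough freedom to find all true clusters). In
the 14-template simulation study this single mechanism accounted for
essentially all selection errors of the mean rule, while the vote — which
the bad restart cannot shift by more than one ballot — recovered the truth
in every replicate. The vote and the mean agree whenever restarts are
well-behaved.

## The enrichment universe

All clustered sites form the universe of every 2×2 table, annotated or
not, per the literal count definitions. The database is first intersected
with the dataset (`restrict_to_dataset()`); a site annotated to several
kinases counts once per kinase. Averaging across restarts is done on the
score `E_k`, not on `P_k`: the scores are the quantity compared across
`k`, and a mean of `P_k` would be dominated by single large values.
Ties in the argmax resolve to the smallest `k` (parsimony).

## The uninformative-fit flag

With no informative annotation the score curve does not develop an
interior peak — it creeps upward with `k`, because every extra cluster
contributes another minimum over `m` near-null p-values (expected around
`1/(m+1)`), which outweighs the two extra degrees of freedom. Rather than
hard-coding a shape heuristic, the fit calibrates itself: the per-`k` best
models are re-scored against the same database with site identities
randomly permuted, which preserves the set-size structure while destroying
any temporal association. If the real curve's peak does not exceed twice
the permutation-null peak, the fit is flagged `uninformative`. In the
simulation studies the real and null peaks differ by an order of magnitude
when informative groups exist (scores of hundreds vs. single digits), so
the factor 2 separates the regimes with a wide margin on both sides.

## What the simulator emulates

The generator reproduces the benchmark design used throughout the tests:

* **Templates.** Fourteen 7-point canonical patterns (`temporal_templates()`)
  — linear rise/fall, early/mid/late spikes, spike-and-decay, hump, valley,
  rise-to-plateau, plateau-to-late-fall, early fall, two oscillation phases,
  and a fall-recover-rise — shipped as a versioned fixture. The curves span
  a 6-unit dynamic range in arbitrary abundance units. After row
  standardization every pairwise template distance exceeds 2 (on profiles
  whose z-scored norm is `sqrt(7) ≈ 2.65`), i.e. the patterns are distinct
  but not caricatures: with unit noise the clusters genuinely overlap at
  their margins.
* **Sites.** Each simulated site is its template plus i.i.d. Gaussian noise,
  `sigma = 1` per time point, 500 sites per template by default. Relative
  to the 6-unit range this is moderate noise: strong enough that restarts
  disagree and extra centroids cannot carve stable "straggler" clusters out
  of the overlap regions, weak enough that the true structure is
  recoverable. This ratio is load-bearing — with much weaker noise the
  score develops a slow upward drift past the true `k`, because an extra
  near-empty cluster harvests stragglers, sharpens every informative test
  slightly, and adds a spurious minimum; the unit-noise regime suppresses
  exactly that pathology, and the recovery results should be read as
  conditional on it.
* **Annotations.** 100 kinase groups of 50 substrates; `g` informative
  groups sample their members from one template's sites each (distinct
  templates), the rest sample uniformly. Annotation noise `s` replaces
  `ceiling(s * 50)` members of every informative group with sites from
  other templates, drawn uniformly (neutral mis-assignment, not
  adversarially similar templates).
* **Degraded designs.** `time_subset` thins the time axis (three-point
  designs collapse several templates into near-identical shapes, so the
  selected `k` drops below the truth); `noisy_tail` replaces trailing
  columns with pure noise around a flat level, emulating non-functional
  late measurements.

What the simulation does **not** emulate: missing values, heteroscedastic
or correlated noise, unequal cluster sizes, peptide-level redundancy,
database bias toward well-studied kinases, and sites regulated by several
kinases with different kinetics. Passing the simulated benchmarks
therefore demonstrates the selection mechanism, not robustness to every
property of real SILAC data.

## Numerical choices

* Fisher tails come from the hypergeometric survival function and the
  combination from the chi-squared survival function in log space, so
  scores remain exact when `P_k` underflows (routine here: scores of
  several hundred).
* Degenerate margins (`a + b = 0` or `a + c = 0`) return p = 1; clusters
  with no eligible kinase contribute p = 1, neutral in the combination
  (`log 1 = 0`). Exact zeros (impossible from the tail formulas, possible
  from user input) are floored to the smallest positive double with a
  warning.
* c-means convergence: the e1071 Bezdek iteration with `iter.max = 200`;
  k-means: Lloyd with the same cap. An emptied k-means cluster (not
  observed in practice on standardized profiles) triggers a deterministic
  re-draw of the initial centers.
* The last few bits of the c-means memberships are not reproducible across
  calls (a quirk of the underlying C routine); hard assignments, scores and
  all selection results are exactly reproducible under a seed, and
  memberships are serialized at 8 significant digits.
* Constant rows are dropped before standardization (no shape); fold-change
  filtering works on ratio or log2 scale via an explicit flag, and the
  threshold is inclusive (`>=`).

## Benchmark scale

The simulation studies in `tests/` and `scripts/acceptance.R` run the full
published design — `sigma = 1`, 100 groups × 50 substrates, sweep 2–20,
10 restarts, fuzzy c-means, 10 replicate seeds per scenario — at 200 sites
per template (800–2800 sites per dataset). The noise-tolerance study uses
a 5-template dataset with `g = 5`, the cleanest reading of the published
`g = 5` design. At this scale one CPU completes the whole battery in tens
of minutes; recovery behaviour at 500 sites per template was verified to
be the same during development.

## Known limitations

* The score compares partitionings of *one* dataset at *one* granularity
  knob; it is not a significance test for "is there clustering at all" —
  use the permutation-null flag for that question.
* Databases whose informative coverage is very sparse (few informative
  kinases, each with a handful of in-dataset substrates) push the score
  toward the uninformative regime; `min_substrates` trims the hopeless
  kinases but cannot create signal.
* Motif scoring is the plain frequency-sum against a PSSM — no background
  correction, by construction — so scores are comparable across clusters
  for one PSSM, not across PSSMs.
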