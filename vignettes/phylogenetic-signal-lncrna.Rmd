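---
title: "Phylogenetic signal in lncRNA molecular traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal in lncRNA molecular traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncphylo)
```

# The question

Long non-coding RNAs evolve with little sequence conservation, so
cross-species comparisons work on their *molecular traits* instead: spliced
transcript length, exon count, GC content and maximal ORF length. If those
traits evolve along the species phylogeny, closely related species should
carry lncRNAs with similar trait values — detectable phylogenetic signal. If
lncRNAs arise and turn over largely independently in each lineage, their
traits should look phylogenetically unstructured even where the traits of
protein-coding transcripts are strongly structured. `lncphylo` implements the
full comparison: trait extraction, lncRNA/other class aggregation,
annotation-novelty accounting, three signal estimators, a local correlogram,
and Brownian-motion (BM) versus Ornstein-Uhlenbeck (OU) model comparison.

# Data model and preprocessing

Tip traits are **per-species class means**: every assembled transcript is
scored by an upstream lncRNA predictor (consumed here as a ranked score
table), flagged as lncRNA at a score threshold (default 0.5 — the predictor
emits probabilities and no canonical cutoff exists, so the threshold is a
config parameter), and the four traits are averaged per species within the
`lncRNA` and `other` classes. The `difference` series (lncRNA mean − other
mean) is computed as a third class and reported in its own table.

Trees enter as rooted newick with branch lengths in arbitrary units and are
rescaled to **relative ages** (`normalize_depth`): every branch length is
divided by the root-to-tip depth, so all patristic distances live on 0–2 and
results are comparable across trees. The tree must be ultrametric for this —
and for the λ transform and the OU covariance — within a relative tolerance
of 1e-6, which absorbs newick round-off. Tips are ordered lexicographically
in every matrix so repeated runs give identical output.

Traits are defined as:

* **length** — sum of exon lengths (spliced length, nt);
* **exons** — exon count;
* **gc** — (G+C)/(A+C+G+T) on the spliced sequence, case-insensitive,
  ambiguity codes excluded from numerator and denominator;
* **orf** — length in nt, *including* the stop codon, of the longest
  ATG-initiated, in-frame, stop-terminated reading frame scanned over the
  three forward frames of the sense strand only. Transcripts are directional,
  so the antisense strand is deliberately not scanned; a no-ORF transcript
  scores 0. Ties go to the 5'-most ORF, which cannot change the reported
  length.

# Novelty classification

Assembled transcripts are matched against the reference annotation with a
deliberately reduced version of gffcompare's vocabulary: three classes
suffice to count novel and intergenic lncRNAs.

* `annotated_match` — multi-exon: the ordered intron chain (donor/acceptor
  coordinates, same chromosome and strand) is exactly equal to a reference
  transcript's; single-exon: the exon interval is exactly equal. Intron-chain
  equality is gffcompare's "=" semantics; terminal exon ends may differ.
* `overlapping` — at least 1 bp of same-strand exonic overlap with any
  reference exon (containment and partial-splice-match cases collapse here).
* `intergenic` — everything else.

Strand-unknown transcripts are compared against both strands. One divergence
from gffcompare is documented rather than emulated: gffcompare tolerates
slight terminal differences for single-exon matches; we require exact
intervals. A "novel" lncRNA is any lncRNA-flagged transcript that is not an
`annotated_match`.

# Signal estimators

## Moran's I

With row-normalized weights `W` (zero diagonal) and centered trait `x`:

\[ I = \frac{n}{S_0} \frac{\sum_{i \ne j} w_{ij}(x_i-\bar x)(x_j-\bar x)}
          {\sum_i (x_i-\bar x)^2}, \qquad E[I] = -\frac{1}{n-1}. \]

The weighting scheme is not dictated by the statistic; we default to
`w_ij ∝ 1/d_ij` on patristic distances, row-normalized — the most common
distance-decay choice — and expose it behind the `method` argument of
`proximity_matrix()` so alternatives can be plugged in. For ten species the
null expectation is −1/9 = −0.111; values significantly above it mean
relatives resemble each other. Significance comes from random tip-label
permutations, two-sided around the null expectation, with the
`(hits + 1)/(B + 1)` convention and a default of 999 seeded permutations.
Zero patristic distances (identical tips) are rejected because 1/d is
undefined.

## Local correlogram and the phylogenetic patch

Global I compresses all distances into one number; the correlogram profiles
it. The distance axis is cut into `n_points = 100` grid values
`h_k = k · d_max / 100`. At each `h_k`, a binary window selects tip pairs
with `|d_ij − h_k| ≤ bandwidth` (default bandwidth: twice the grid spacing,
so neighboring windows overlap and the profile is smooth); the selected
weights are row-normalized and Moran's I computed. Windows holding fewer
than two pairs yield a missing value rather than an error. Confidence
intervals resample **tips** with replacement (cases bootstrap, 1000
replicates, percentile 95% CI); pairs formed by duplicate copies of the same
tip are excluded from the windows, and degenerate resamples (a single
distinct tip, or zero trait variance) are redrawn. A grid point is flagged
significant when its CI excludes −1/(n−1). The **phylogenetic patch** is the
smallest grid distance at which the flag drops from significant-positive to
not significant — a short patch is the correlogram's signature of an
adaptive (OU-like) process. The window construction and bootstrap unit are
documented parameters of this package, not claims of equivalence to any
other correlogram implementation.

## Blomberg's K

K compares the observed partitioning of trait variance to its Brownian
expectation using the phylogenetic GLS mean; K = 1 matches BM, larger K
means stronger resemblance among relatives. On an equal-depth star tree K is
exactly 1 for *any* trait vector — an algebraic identity the test suite
asserts to 1e-10. The permutation test shuffles tip labels and is one-sided
on the variance ratio.

## Pagel's λ

λ multiplies the off-diagonal of the BM covariance; the root state and rate
are profiled analytically and λ is found by scalar likelihood search on
`[0, λ_max]` (absolute tolerance 1e-8, endpoints checked explicitly because
`optimize()` never lands exactly on a boundary). `λ_max` is the
positive-definiteness safeguard `min_{i<j} C_ii C_jj / C_ij²` capped at 1.2:
empirical estimates can sit slightly above 1, so the bound must exceed 1,
but far above it the likelihood is undefined. The test against λ = 0 is a
likelihood-ratio test; the null lies on the boundary, so the statistic is
referred to the ½χ²₀ + ½χ²₁ mixture.

# BM and OU model comparison

BM has a closed-form ML solution. The OU model uses the non-stationary-root
parameterization with the root fixed at the single optimum (θ = z0) — the
common default of macroevolutionary fitting tools — because nothing in the
trait data identifies a separate root state on an ultrametric tree:

\[ V_{ij}(\alpha) = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
   \left(1 - e^{-2\alpha s_{ij}}\right). \]

σ² and z0 are profiled analytically; α is optimized on `[1e-8, 50/T]` —
beyond 50/T the covariance is numerically singular, and an estimate pinned
at the bound is flagged rather than silently truncated. The comparison
statistic is `LR = 2(lnL_OU − lnL_BM)` with one degree of freedom. BM is
nested at α = 0, a boundary, so the default p-value uses the ½χ²₀ + ½χ²₁
mixture; the plain χ²₁ tail is available via `boundary_correction = FALSE`.
BM is preferred unless the test rejects at 0.05 (the fewer-parameters rule).

Two numerical facts worth knowing. First, the OU likelihood at α → 0
approaches the BM likelihood (asserted to 1e-4 in the tests), so
`lnL_OU ≥ lnL_BM` always holds up to optimizer tolerance, and a violation is
reported as an optimizer failure rather than a result. Second, the boundary
LR test is **anti-conservative at small n**: on 16–64-tip trees under BM
truth the observed 95th percentile of LR is ≈ 4–5.5 against the asymptotic
mixture quantile of 2.71, and BM is preferred in ~80–90% of replicates
rather than the nominal 95%. The OU likelihood itself is exact (it matches
an independent OU implementation to seven digits at the same α); the
inflation is the well-known finite-sample behavior of this test. P-values
near 0.05 on small phylogenies should therefore be read cautiously.

# The synthetic study generator

The generator exists so every stage is testable without multi-gigabyte
downloads. It emulates the statistical structure of a real multi-species
study, not its biology:

* **Tree** — pure-birth (Yule, rate 1) with the requested tip count, scaled
  to depth 1.
* **Classes** — a configurable lncRNA fraction (default 0.064, matching the
  study-wide mean share of predicted lncRNAs) with class-specific
  distributions whose defaults encode the observed contrast: lncRNAs have
  lower GC (0.38 vs 0.44, SD 0.05), fewer exons (1 + Poisson(0.3) vs
  1 + Poisson(4)), shorter spliced lengths (log-normal, medians 500 vs 1500
  nt) and shorter planted ORFs (gamma, means 90 vs 900 nt).
* **Sequences** — each transcript's sense sequence carries a planted ORF of
  the drawn length (codons sampled with GC-biased base weights), with the
  remaining positions Bernoulli draws tuned so the whole transcript hits its
  GC target in expectation; realized class-mean GC lands within ±0.02 of the
  configured mean. Sequence composition is otherwise i.i.d.-like by design.
  Exon lengths are a random composition of the spliced length; introns are
  uniform 50–500 nt, intergenic spacers uniform 200–2000 nt on a single
  chromosome per species — the smallest genome that exercises coordinates.
* **Novelty** — a configurable fraction of transcripts (default 0.5) is
  withheld from the reference GFF3, so the novelty classifier has true
  positives to find.
* **Scores** — Beta-distributed around the class indicator (Beta(20, 4) for
  lncRNAs, Beta(4, 20) otherwise), so a 0.5 threshold misclassifies a small
  realistic fraction.
* **Signal** — `generate_study()` lets the class parameters drift across
  species under Brownian motion on the generated tree (additive on GC and
  log-length, multiplicative on exon rate and ORF mean), so the per-species
  class means genuinely carry the signal the estimators are asked to
  recover. All randomness flows from one master seed through per-species
  derived seeds.

What the generator does **not** emulate: UTR/alternative-splice structure,
codon usage, expression levels, assembly artifacts, or correlated traits.
Passing tests therefore demonstrate that the estimators and plumbing are
correct under the stated generative model, not that any biological
conclusion transfers to real transcriptomes.

# Problem sizes and calibration

The test suite and the acceptance script work at sizes chosen to give tight
Monte-Carlo error while staying interactive: Blomberg's K is averaged over
1000 BM simulations on a 32-tip tree (expected mean 1 within ±0.05), Pagel's
λ over 500 BM and 500 i.i.d. simulations on a 64-tip tree (expected means
near 1 and near 0), OU recovery over 60 simulations at αT = 5 (median within
a factor of 2), and the permutation mean of Moran's I over 20,000 shuffles
on a 10-tip tree (−1/9 within ±0.01). Pipeline round-trip tests use
10-species fixtures with tens to hundreds of transcripts per species.

# Known limitations

* Signal estimates on 10-species trees are intrinsically noisy; λ in
  particular has a flat likelihood at small n, and the correlogram's
  bootstrap CIs are approximate (coverage is not exactly nominal for a
  statistic computed on resampled distance submatrices).
* The ORF convention (sense strand, stop included) is one of several in use;
  compare absolute ORF lengths across tools with care.
* Single-exon matching is exact-interval, slightly stricter than
  gffcompare's; borderline single-exon transcripts can be "overlapping" here
  that gffcompare would call matched.
* The OU fit assumes an ultrametric tree and a single optimum; multi-regime
  OU and other models (early-burst, white noise) are out of scope.
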