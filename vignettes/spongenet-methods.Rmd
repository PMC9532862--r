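---
title: "Methods: ceRNA network inference with spongenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference with spongenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

## The model

A competing-endogenous-RNA (ceRNA) relationship is a triple
(circRNA, miRNA, mRNA) in which the circRNA carries binding sites for the
miRNA and titrates it away from the mRNA. Its observable signature in
expression data is a correlation pattern: the miRNA anticorrelated with
both the circRNA and the mRNA, and the circRNA positively correlated with
the mRNA. `spongenet` infers such triples for a two-group contrast
(normoxic vs hypoxic culture within a breed) through a fixed cascade of
filters, each with an explicit decision rule:

* differential expression per layer (the triple's members must respond
  to the contrast),
* physical plausibility (canonical seed sites of the miRNA on both the
  circRNA and the mRNA 3′UTR),
* the correlation signature (Spearman < −0.7 for both miRNA pairs,
  Pearson > 0.9 for the circRNA–mRNA pair, strict inequalities),
* a shared-miRNA sponge test: with N testable miRNAs, a circRNA
  targeting K of them and an mRNA targeted by n of them, an observed
  overlap of k shared miRNAs has upper-tail probability
  P(X ≥ k), X ~ Hypergeometric(N, K, n); the pair passes at p < 0.05.

All four conditions are conjunctive; a triple failing any one is not
emitted. This mirrors the common practice of ceRNA studies: the
correlation thresholds are screening heuristics, the hypergeometric
overlap is the only formal test, and no claim of mechanism is made
beyond consistency with the sponge hypothesis.

## Statistical components

**Differential expression.** Counts are first equalized to the geometric
mean library size (rounded half-to-even, so the procedure is
deterministic). Dispersion is estimated per feature by method of moments
on group-mean-centered counts, φ = max(0, (s² − m̄)/m̄²) under
Var = μ + φμ², and summarized by the median ("common") value; tagwise
empirical-Bayes shrinkage is deliberately out of scope. The two-group
test conditions on the combined total t of each feature: each group
total is negative binomial with size n_g/φ, and the two-sided p-value
sums the probabilities of all splits of t no more likely than the
observed one (ties included). At φ = 0 this reduces exactly to the
double-tailed conditional binomial Binomial(t, n_A/(n_A+n_B)) — a
property the test suite checks against full enumeration for every total
t ≤ 50. Decision rules are layer-specific: |log₂FC| ≥ 1 and p < 0.05
for circRNA and miRNA; |log₂FC| ≥ 1 and Benjamini–Hochberg FDR < 0.05
for mRNA. Fold changes use a pseudocount of 1 because a denominator
guard is otherwise unspecified; "FC ≥ 2" is read as absolute (both
directions), which is what up/down reporting implies.

**Normalization.** RPM (circRNA), TPM (miRNA) and FPKM (mRNA), with the
per-sample column sum as the mapped-read denominator — true mapped-read
totals would need alignments, and the column sum is internally
consistent — and effective length equal to the given feature length (no
fragment-length correction). RPM and TPM columns sum to 10⁶ (relative
tolerance 10⁻⁹); TPM equals column-renormalized FPKM, an identity the
tests assert numerically. The low-expression filter defaults to *off*
so no features disappear silently.

**Seed matching.** Canonical site classes only — 8mer, 7mer-m8,
7mer-A1, 6mer, defined from miRNA seed positions 2–8 with a literal
target adenosine opposite position 1, no G:U wobble — because they are
exactly reproducible and oracle-testable, whereas thermodynamic scores
(miRanda-style) depend on unpublished parameters. Each seed anchor
reports only its strongest class. Circular targets are scanned on the
sequence extended by its first 7 nt, positions folded modulo the length,
so back-splice-junction-spanning sites are found; the implementation is
checked against a brute-force scan of all rotations. The interaction
score 3·n(8mer) + 2·n(7mer-m8) + 2·n(7mer-A1) + 1·n(6mer) is a simple
additive summary used for ranking, not a binding-energy model. The
weakest class that qualifies a candidate pair defaults to 7mer-A1.

**Correlations.** Computed on log₂(normalized + 1) over the samples of
the two compared groups (n = 6 at the default three replicates): the
contrast being analysed should also be the one driving the coexpression,
and the log transform keeps high-abundance features from dominating
Pearson. Constant profiles yield an undefined correlation, which is
reported as missing, dropped with a warning, and can never pass a
filter.

**Sponge test universe.** All miRNAs with at least one predicted target
in the comparison — the test is conditioned on what was testable, not on
the full annotation, which would make every overlap look significant.
The sponge p-values are used raw at p < 0.05 (BH across pairs is
available behind `sponge_fdr = TRUE`) since a single decision threshold,
not an FDR, is the convention this pipeline reproduces. The analogous
over-representation analysis for annotation terms reuses the same
hypergeometric kernel with BH FDR ≤ 0.05.

**Network.** Nodes are typed; each triple contributes its
circRNA–miRNA and miRNA–mRNA edges (the circRNA–mRNA support edge is
optional). Hubs are ranked by degree with lexicographic tie-breaks —
"core nodes" in the descriptive, not centrality-theoretic, sense. The
top-k (default 50) sub-network ranks edges by sponge p ascending, then
|coefficient| descending, then ids; the ranking key is a documented
package choice, since "top relationship pairs" has no unique definition.

## The synthetic-data generator

The generator defines the conditions under which the pipeline's
guarantees are stated: four groups (TN, TL, LN, LL) × 3 replicates,
negative-binomial counts (Var = μ + φμ², Poisson at φ = 0), log-uniform
baseline means (default 20–2000), per-sample library-size factors drawn
once from [0.8, 1.2] × 10⁶, planted DE features with a ±2 log₂ mean
shift in the hypoxic groups, and 10 planted sponge pairs whose
orientation alternates (miRNA down in hypoxia for odd pairs, up for
even) so both signs are exercised.

Three generator choices deserve justification:

* **Two shared miRNAs per planted triple.** Under the sponge-test
  default universe (miRNAs with predicted targets, N ≈ 20–25), a pair
  sharing a single miRNA has k = K = n = 1 and p = 1/N > 0.05: a
  one-miRNA sponge is statistically indistinguishable from chance, and
  biologically a sponge is characterized by multiple shared miRNAs. Each
  planted circRNA–mRNA pair therefore shares two miRNAs, and ground
  truth lists one triple row per anchoring miRNA (20 rows at defaults).
* **A latent per-sample "sponge activity" factor.** With only
  group-mean shifts, within-group ranks are independent, and for 3 + 3
  samples the probability that a truly coupled pair exceeds |Spearman|
  > 0.7 is capped near 0.75 — planted triples would fail the printed
  thresholds for purely combinatorial reasons. Each triple therefore
  carries a per-sample log₂-normal factor (SD 1.2) loaded +1 on the
  circRNA and mRNA and −1 on its miRNAs: the within-group covariation
  that an actual titration mechanism would produce. The factor's
  multiplier is renormalized to arithmetic group mean 1 (per loading
  sign), so planted fold changes on count means remain exactly
  2^±effect and the DE stage is not perturbed.
* **A detectability floor for planted features.** Planted baselines are
  raised to ≥ 200 (log₂ floor), since an effect planted below
  quantifiable depth is invisible to any method and would measure
  sequencing depth, not pipeline behaviour.

Sequences are random RNA with the planted sites written in at recorded
positions; ~30% of circRNA sites span the back-splice junction. Every
canonical site contains the reverse complement of seed positions 2–7,
so rejection-scrubbing those 6-mers (outside planted spans, for all
planted miRNAs, on all targets) guarantees the emitted site table is the
complete scan truth — this is what makes exact site-recall and
triple-precision checks possible. Planted miRNAs get pairwise-distinct
seed cores for the same reason.

What the generator does *not* emulate: read-level sampling (no FASTQ),
batch effects, fragment-length bias, GC content, isoform structure,
correlated background coexpression, or chimeric back-splice reads.
Passing the planted-recovery tests therefore shows the inference chain
is correct and calibrated under its own assumptions — not that real
tissue data would yield comparable precision.

## Numerical choices and degenerate inputs

The hypergeometric tail is computed by summed log-binomials (stable for
any in-bound arguments); `stats::phyper` serves as an independent
cross-check in the tests, never as the implementation, so the kernel the
sponge test reports is the one that was verified by enumeration. The
exact test clamps p into (0, 1] and treats ties with a 1 + 10⁻¹²
relative guard. Undefined correlations never pass. Zero column sums,
missing lengths, negative values, out-of-range probabilities and
mismatched ids are rejected with explicit errors. All orderings
(candidates, triples, edges, hub ranks) are deterministic with
documented tie-breaks, and every stochastic step flows from a single
integer seed: identical configuration and seed reproduce every file
byte-for-byte.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen so the full suite completes
in minutes: 400/80/100 mRNA/miRNA/circRNA features for the default
fixture, 2,000 features for null calibration, 20 independent datasets
for the specificity bound, 500 random pairs for the rotation-oracle
comparison. At these sizes the end-to-end recovery on the default
fixture (seed 42) is precision 1.0 and recall 0.75 against 20 planted
miRNA-anchored triples; the stated test thresholds (recall ≥ 0.7,
precision ≥ 0.6) were fixed from a pre-build pilot at that seed.

## Known limitations

The DE stand-in uses a common dispersion and an exact conditional test;
it reproduces the published decision rules but not edgeR/DESeq output on
real data. Seed matching ignores 3′-supplementary pairing, conservation
and site accessibility. The correlation filters are threshold
heuristics inherited from the protocol being reproduced: at n = 6
samples a Pearson of 0.9 is not a calibrated significance statement.
Enrichment requires a user-supplied annotation; no GO/KEGG topology is
modelled. Hub ranking is degree-only by design.
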