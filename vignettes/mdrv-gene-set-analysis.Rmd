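---
title: "Rare damaging-variant gene-set analysis for 22q11.2DS conotruncal heart defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare damaging-variant gene-set analysis for 22q11.2DS conotruncal heart defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdmod)
```

## The problem and the model

About 40–50% of people with the 22q11.2 deletion syndrome develop a
conotruncal heart defect (CTD), a malformation of the cardiac outflow tract
or aortic arch. Everyone in such a cohort shares the same primary lesion —
hemizygosity of the ~3 Mb LCR22A–LCR22D interval, including one copy of
*TBX1* — so variation in cardiac outcome points to *modifiers*: rare
variants elsewhere in the genome that interact with the sensitized *TBX1*
network. The statistical setting is therefore a case-control comparison
within a syndrome: CTD cases vs deletion carriers with a normal heart.

Rare damaging variants are individually almost never recurrent, so the
package tests *aggregated* signals at two levels:

* **recurrently affected genes** — genes hit in two or more cases and no
  control (a deliberately stringent rule that suppresses sequencing
  artifacts, at the cost of sensitivity), screened for over-representation
  in curated gene sets by the hypergeometric tail; and
* **whole gene sets** — an expression-weighted quadratic form over all
  MDRV-bearing genes of a set, which uses every carrier rather than only
  recurrent genes.

### The MDRV definition

A most-damaging rare variant (MDRV) passes every stage of a cascade:

| stage | rule | default | rationale |
|---|---|---|---|
| rarity | gnomAD AAF < `aaf_max`, absent = novel = pass | 0.01 | modifiers of a rare syndrome must themselves be rare; novel variants are the rarest |
| class | LoF, or missense + MetaSVM "D", or splicing (spliceAI ≥ 0.5, or ada ≥ 0.6 and rf ≥ 0.6) | — | protein-damaging mechanisms only |
| conservation | phastCons ≥ `phastcons_min` | 0.5 | evolutionary constraint, probability scale [0,1] |
| deleteriousness | CADD ≥ `cadd_min` | 10 (phred) | top ~10% of genome-wide deleteriousness |
| regional constraint | CCRS ≥ `ccrs_min` | 80 (percentile) | variant sits in a constrained coding region |

Each stage is a pure predicate, so the retained set is invariant to stage
order; only the tally depends on it. Missing phastCons/CADD/CCRS values fail
their stage: a "high-confidence" set should not contain unscorable variants.
The spliceAI (0.5) and dbscSNV (0.6) operating points are the tools'
conventional defaults — the analysis design names the tools but no cutoffs —
and are exposed in `filter_config()`; the two splicing annotations are
combined disjunctively (either evidence source suffices), which is the
permissive reading and likewise configurable.

### Recurrence, expression filter and ORA

Carrier counts are *distinct subjects per gene* (a subject with two MDRVs in
one gene counts once; a homozygote counts once). The cardiac-progenitor
expression filter keeps genes with mean RPM ≥ 25 across the three E10.5
mouse tissue pools (pharyngeal arches 2–6, OFT + right ventricle, LV +
atria). The 25-RPM cutoff is the operational rule; on the reference data it
captures about the top 35% of protein-coding genes, and `expressed_genes()`
reports the fraction it actually achieves on whatever input it is given —
the two descriptions cannot both be enforced on arbitrary data, so the
printed cutoff wins.

ORA uses the upper-tail hypergeometric probability with the MDRV-affected
genes of the analyzed group as the background `N` — not the whole genome.
This matters: recurrent genes are a subset of affected genes by
construction, and using the genome as background would manufacture
enrichment. BH-FDR is applied over the full family of 19 sets × 4 scenarios
(cases/controls × expression filter on/off) = 76 tests.

### The weighted gene-set statistic

For each gene with at least one MDRV carrier, a 2×2 Fisher exact test
(carriers/non-carriers × cases/controls) gives a two-sided p, transformed to
a signed normal score

$$z = s\,\Phi^{-1}(1 - p/2), \qquad
  s = \operatorname{sign}\!\left(\tfrac{a}{a+b} - \tfrac{c}{c+d}\right),$$

with $z = 0$ when $p = 1$. The design description says only that the
gene-level (p, OR) pair is "transformed to z"; the signed inverse-normal is
the standard such transform and is recorded here as the package's choice.
For a set with gene scores $Z$ and weights $w$ (natural log of mean RPM + 1;
base and pseudocount are free choices, the pseudocount guards zero
expression),

$$T = Z^\mathsf{T} J Z, \qquad J = \frac{w w^\mathsf{T}}{w^\mathsf{T} w}
 \;=\; \frac{(\sum_i w_i z_i)^2}{\sum_i w_i^2}.$$

$J$ is a rank-one projection (idempotent, trace 1, invariant to positive
rescaling of $w$), so $T$ is the squared length of the projection of $Z$
onto the expression direction: genes expressed in cardiac progenitors
dominate the statistic, which is the point — genes in a set are not expected
to contribute to disease equally.

The null is simulated by shuffling case/control labels, recomputing every
per-gene Fisher z and then T, `n_perm` times (study default 2000). The
empirical p is $n/N$ with the observed statistic counted among the extremes,
so $p \ge 1/N$ and the smallest reportable value at 2000 permutations is
5.0e-4; this matches the convention under which the analysis reports its
minimum p, and it avoids zero p-values. One shared shuffle stream evaluates
every set — per-set marginals are unchanged, permutation effort is paid
once, and set statistics are comparable replicate by replicate. Because a
label shuffle preserves each gene's total carrier count $m$, the per-gene
Fisher p/z pair depends only on the number of case carriers $a$; the engine
therefore precomputes a lookup table over the hypergeometric support of $a$
per gene and scores all replicates by table lookup, which is what makes
2000 × 19 sets cheap. Full recomputation per replicate (rather than
permuting residual quantities) is the literal reading of the design and is
what is implemented.

## Numerical and degenerate-input choices

* **Exact HWE test.** The QC Hardy–Weinberg filter uses the exact
  conditional test (enumeration over heterozygote counts of the same parity,
  in log space), not the chi-square approximation — standard for
  rare-variant QC where expected cell counts are tiny. Monomorphic variants
  have a single attainable configuration and p = 1. X/Y variants are tested
  like autosomes and flagged, not special-cased.
* **Fisher two-sided rule.** Two-sided p sums point probabilities
  ≤ observed × (1 + 1e-7), the same tie rule as `stats::fisher.test`
  (verified against it in the tests); the oracle in the test suite instead
  enumerates tables from binomial coefficients.
* **Indel concordance.** "Base pairs overlapped" is implemented as the
  Jaccard fraction of the closed reference spans
  `[pos, pos + nchar(ref) - 1]`, threshold ≥ 0.10 — symmetric, so
  validation does not depend on which caller is "first".
* **Degenerate burden groups.** Welch's t is undefined when both groups are
  constant; equal constant groups report p = 1, different constant groups
  p = 0. Welch was chosen (over pooled t, Wilcoxon or Poisson regression)
  because only means and a p-value are specified upstream and Welch is the
  robust default for count means at these sample sizes.
* **Coordinates.** 1-based, fully closed, VCF convention throughout.
* **Ties in T.** Permuted statistics tying the observed one count as
  extreme (conservative).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the *statistical skeleton* of the cohort:
456/537 group sizes; ~1.8 expected MDRVs per subject; per-gene carriage
rates drawn from a Gamma(shape = 10) prior scaled to the target rate, which
reproduces the observed sparsity (~83% of affected genes with a single
MDRV); carrier clusters of at most two subjects per variant; a designated
274-gene set whose case rate is multiplied by `rho`; decoy variants built to
fail exactly one cascade stage each; ancestry strata at 74.4/15.6/10.0%;
and log-normal expression with `sdlog = 2` and `meanlog` placed so that
RPM ≥ 25 captures the top ~35% of genes. Defaults are the study conditions;
`rho` is the only knob meant to be moved in experiments.

It does **not** emulate: linkage or haplotype structure, gene length or
per-gene mutability differences, ancestry-correlated allele frequencies,
batch or caller artifacts, or relatedness. Passing tests on synthetic
cohorts therefore demonstrate the *statistical* correctness and calibration
of the machinery (type-I error, power ordering, determinism), not robustness
to those real-data complications — on real data the QC and concordance
stages exist precisely because those complications occur.

`simulate_table1_fixture()` is the deterministic worked-example bundle: 31
case-recurrent genes, of which the 12 published ones carry the printed
carrier counts (26 distinct carriers) and the expression flag, and the six
chromatin genes carry their published AAF/CADD/CCRS annotations. Its
conservation and splice scores are synthetic passes (the published table
prints PhyloP rather than phastCons and no splice ensemble scores), and the
duplicated EP400 row is encoded as one variant with two carriers.

## Problem sizes used by the test suite

The statistical acceptance checks run at reduced, stated sizes chosen to
estimate the relevant probabilities with useful Monte-Carlo precision while
keeping the suite quick: type-I calibration uses 400 null cohorts of
100 cases/100 controls over 1200 genes with 200 permutations (rejection
rate compared to 0.05 within 3 binomial SEs, ±0.033); power ordering uses
25 replicates per enrichment level ρ ∈ {1, 2, 4}; oracle equivalence grids
cover all HWE configurations with ≤ 30 subjects plus random instances to 50,
and hypergeometric/Fisher/BH instances with totals to 60. The
permutation-floor check runs at the full 456/537 × 2000-permutation scale
(a few seconds).

## Known limitations

* The recurrence rule conditions on *zero* carriers in the other group,
  which makes it sensitive to a single misclassified control.
* The WGST has no covariate adjustment (the upstream design relies on
  ancestry matching verified by a stratified burden test) and no
  variance-component alternative; a set whose genes pull in opposite
  directions can cancel in $w^\mathsf{T}Z$.
* Genes absent from the expression matrix receive weight 0 in the WGST and
  so are silently dropped from the statistic (they still count in ORA).
* Multi-transcript consequence conflicts must be resolved upstream: one
  gene symbol and one consequence per variant row.
* The exact HWE filter treats X/Y like autosomes (flagged in the QC
  output); sex-aware testing is out of scope.
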