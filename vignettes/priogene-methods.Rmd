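---
title: "Methods: integrative GWAS-eQTL prioritization of risk genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative GWAS-eQTL prioritization of risk genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priogene)
```

## The problem

Genome-wide association studies of complex diseases such as
moderate-to-severe asthma identify SNPs, not genes, and the strict
genome-wide significance threshold discards the many variants with small or
moderate effects. When a disease variant acts by changing the expression of
a nearby (or distant) gene, that mechanism is visible in expression
quantitative trait locus (eQTL) data: the same SNP associates both with the
disease and with the gene's expression. `priogene` implements a pipeline
that exploits this: it integrates GWAS summary statistics with eQTL
association tables to score genes, replicates the ranking with an LD-aware
gene-based association test, and validates the resulting gene set with
permutation overlap tests, gene-set enrichment, a random-phenotype negative
control, and group-wise differential/co-expression analysis. The final
product is a consensus table of genes significant in every line of
evidence.

## Bayesian GWAS-eQTL integration

For one eQTL dataset, the integration proceeds in four steps.

**eSNP discovery.** SNP-gene pairs with eQTL p-value at or below a
threshold (default $10^{-4}$, boundary inclusive) are declared eSNPs of
that gene. The inclusive boundary matters: a pair at exactly the threshold
counts.

**Per-SNP scoring.** Each eSNP is scored against the GWAS with a
Wakefield-style approximate Bayes factor on the z scale. Writing $z$ for
the GWAS z-score of the eSNP and $W$ for the prior variance of the
standardized effect (default $W = 0.1$),

$$
\ln \mathrm{BF}(z)
= \tfrac12 \ln\frac{1}{1+W} + \frac{z^2}{2}\,\frac{W}{1+W}.
$$

The function is strictly increasing in $z^2$ and negative at $z = 0$, which
reproduces the integration's three scenarios with a single continuous
formula: an eSNP with a strong GWAS signal contributes a positive score, an
eSNP with no GWAS signal a negative one, and a SNP that is not an eSNP is
never scored. The sign boundary at $W = 0.1$ sits at $|z| \approx 1.04$;
genome-wide significant eSNPs are comfortably positive. $W$ controls how
aggressively big $z^2$ is rewarded; $0.1$ (prior sd $\approx 0.32$ on the
standardized scale) is a conventional choice for complex-trait effect
sizes and is exposed as a parameter.

**LD pruning and aggregation.** eSNPs of one gene are greedily pruned by
panel $r^2$ (keep in eQTL-p order, drop anything with $r^2 > 0.8$ to a kept
eSNP) so that an LD block cannot pay into the gene score multiple times for
one underlying signal. The gene's log Bayes factor (LBF) is then the exact
sum of its retained eSNPs' scores. Genes without eSNPs are absent from the
output entirely.

**Simulated p-values.** The LBF null distribution is generated by
permutation: each replicate reassigns the genome-wide pool of GWAS z-scores
to SNPs uniformly at random while the eSNP structure stays fixed, and every
gene's LBF is recomputed. With $B$ replicates (default 1000 in
`run_bayes()`, smaller in desk-scale runs) the simulated p is the add-one
tail $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$, floored at
$1/(B+1)$ and never exactly 0. Permuting the observed pool rather than
re-simulating preserves the empirical z distribution, including whatever
signal and inflation it carries. Benjamini-Hochberg q-values are attached
across genes. Published analyses of this design report simulated p-values
as small as $10^{-6}$, implying far larger replicate counts than a desk
machine runs; that resolution limit is inherent to the empirical tail and
is why the floor is reported explicitly.

## The LD-aware gene-based test

The complementary gene-based test uses all SNPs assigned to a gene — same
chromosome, position within the gene span extended by 20 kb on both sides,
boundaries inclusive — not only eSNPs. With $z_i$ the SNP z-scores and $R$
their LD correlation estimated from a reference genotype panel, the
statistic is $T = \sum_i z_i^2$. Under the null $z \sim \mathcal N(0, R)$,
so $E[T] = m$ and $\operatorname{Var}[T] = 2\sum_{ij} r_{ij}^2$, and $T$ is
referred to a Satterthwaite scaled chi-square $c\,\chi^2_f$ matching both
moments. Two closed-form limits pin the construction down and are tested at
$10^{-9}$: a single-SNP gene returns exactly the SNP's two-sided normal p,
and a perfectly correlated duplicate of a single SNP collapses to the same
p. For larger SNP sets the scaled chi-square is an approximation matched in
its first two moments; adding a perfect LD copy of one SNP inside a
multi-SNP gene then perturbs the p slightly (the true null is invariant,
the two-moment fit is not) — a known, documented limitation. No ridge is
added when accumulating $\sum r_{ij}^2$: the moment match inverts nothing,
and a ridge would break the exact single-SNP limit. Genes are
Bonferroni-corrected over the number actually tested (those with at least
one assigned SNP).

## Resampling validation

**Overlap permutation test.** Whether two analyses' significant gene lists
overlap more than chance is assessed by drawing `|list_a|` genes uniformly
without replacement from an explicit background universe, $B$ times
(default $10^5$), counting each draw's overlap with `list_b`. The add-one
empirical p is conservative and never 0; when no replicate reaches the
observed overlap the print method reports `p < 1/(B+1)` rather than a bare
0. The background is always an explicit input because the testable gene
universe differs per dataset. As $B$ grows the empirical p converges to
the exact hypergeometric tail, which the test suite checks against
exhaustive enumeration.

**Random-phenotype negative control.** A null GWAS is built by assigning
case status to a seeded random subset of the panel samples and testing each
SNP's dosage against it with the 1-df score test of the case/control
dosage-mean contrast. The p-value uses the finite-sample $F(1, n-2)$
reference of the squared dosage-phenotype correlation rather than the
asymptotic chi-square: at panel-scale sample sizes the asymptotic reference
is measurably off, and only the null behaviour of this stage is ever
consumed. One irreducible discreteness remains: integer dosages put an atom
of a few percent at $p = 1$ (score exactly 0), so uniformity checks are run
at a scale (1000 SNPs) where that atom sits inside Kolmogorov-Smirnov
resolution, while type-I error and the genomic inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2)/0.455$ are checked at 5000 SNPs.

**Threshold profiles.** `threshold_overlap_profile()` reports, for a query
gene list and a result table, the fraction of query genes significant at
each of a strictly decreasing ladder of thresholds (default 0.05, 0.01,
0.001, $10^{-4}$); run against the real and the negative-control tables
side by side it shows the real-above-null pattern expected of genuine
signal.

## Enrichment and expression validation

Gene-set enrichment is the exact hypergeometric upper tail
$P(X \ge k)$ for $k$ query hits in a term of size $K$ (after intersecting
members with the background of $N$ genes, query size $n$), with both Holm
step-down and plain Bonferroni corrections reported — published analyses
of this kind are ambiguous about which correction applied where, so both
are emitted. Differential expression is one-way fixed-effects ANOVA with
Tukey HSD post hoc (Tukey-Kramer for unequal group sizes); two-group
comparisons use the classical pooled-variance Student t-test (Welch behind
a flag), and the two-group ANOVA p equals the squared-t p to $10^{-9}$.
Co-expression patterns are within-group Pearson correlation matrices;
constant genes yield flagged undefined entries. Inputs are assumed
normalized; no preprocessing is performed.

## Consensus

`build_consensus_table()` keeps genes with $p < \alpha$ (default 0.05,
uncorrected) in *every* real analysis — the operational choice of this
design, with corrected q-values carried in the per-stage outputs but not
filtered on — then attaches the negative-control p and a documented-gene
flag from a user-supplied catalog file without filtering on either.
`intersect_results()` supplies the intersection and exclusive Venn region
counts for up to four sets. The bundled
`published_consensus_pvalues()` worked example reconstructs a published
11-gene moderate-to-severe asthma consensus from its printed p-values:
all 11 genes survive the filter, 4 are flagged not-documented, and all 11
have non-significant negative-control p.

## The synthetic-data generator

Every input has a seeded synthetic counterpart so the pipeline can be
exercised end-to-end:

* **Genome layout.** `n_genes` loci on chromosomes 1-22, 2 Mb apart, each
  with `snps_per_gene` SNPs 1 kb apart — annotation windows never straddle
  loci, which keeps recovery accounting unambiguous.
* **LD panel.** Per-block latent Gaussian AR(1) with adjacent correlation
  `ld_decay` (default 0.5), thresholded to dosages 0/1/2 at Hardy-Weinberg
  quantiles of allele frequencies drawn Uniform(0.05, 0.5) — mirroring the
  MAF ≥ 5% filter conventional in array eQTL data. AR(1) blocks are a
  deliberate simplification of real LD: they admit closed-form expectations
  for the test oracles.
* **GWAS.** Per-block z-scores $\mathcal N(R\Lambda_0, R)$ with $R$
  estimated from the panel and $\Lambda_0$ nonzero only at planted SNPs
  ($\sqrt{n}\,\beta = 6$ by default, at the central SNP of each planted
  locus), i.e. a causal signal propagated through LD. Effects live directly
  on the z scale (`se = 1`) because the pipeline only ever consumes summary
  statistics. Default $n = 30{,}810$ matches the GWAS scale the pipeline
  targets.
* **eQTL datasets.** Cis pairs for every gene; planted genes' cis SNPs
  carry noncentrality $\sqrt{n_{eQTL}}\,\beta_{eQTL} = 6$ (default
  $n_{eQTL} = 1490$); different dataset labels share the skeleton and
  signal but redraw noise, emulating independent studies of the same
  biology. Optional trans eSNPs attach a distant locus to configured genes.
* **Expression.** Gaussian matrices over groups defaulting to 44 severe /
  72 mild-moderate / 38 control samples, with planted shifts for DEG genes.

What the generator does **not** emulate: realistic allele-frequency
spectra, arbitrary LD (only block AR(1)), genotype missingness and QC
artefacts, probe-level expression noise, confounding and population
structure. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under clean conditions, not that real-data
preprocessing issues are handled; that is the standard division of labour
between a method package and a QC pipeline.

The planted effect-size convention (noncentrality 6 on both sides) is a
deliberate default: strong enough that a correct implementation recovers
essentially all planted genes, weak enough that broken LD handling or
mis-calibrated nulls visibly degrade recovery. Real signal strengths are
unknowable from printed tables and this default is flagged as a convention
in the configuration documentation.

## Numerical and design choices

* p-values are clamped at $10^{-300}$ (real summary files print smaller
  values as 0, which the record invariant $(0,1]$ would reject).
* Near-singular panel block correlations in the GWAS simulator are
  ridge-regularized with $\epsilon = 10^{-6}$ and a warning.
* Every stage derives its RNG stream deterministically from the master
  seed and a stage tag, so a run is bit-reproducible from `(config, seed)`
  and changing the seed changes noise but never the (SNP, gene) skeleton.
* Greedy LD pruning (not optimal subset selection) is used for eSNPs: it
  is deterministic given the p-order, cheap, and the convention in
  practice.
* The cis/trans boundary is ±1 Mb around the gene span, the conventional
  bound, and configurable; trans eSNPs are scored identically to cis ones.
* Monomorphic SNPs: dropped with a warning from LD matrices (correlation
  undefined), reported with `p = 1` and a flag by the null GWAS.
* Internal coordinates are 1-based inclusive everywhere; BED on disk is
  the only 0-based half-open surface and the conversion happens at I/O.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the synthetic study at
1000 genes × 5 SNPs (20 planted), a 500-sample panel, $B = 300$-$500$
permutation replicates, 500-gene global-null calibration runs, and a
2000-gene expression null — sizes chosen so a complete check runs in about
a minute on a laptop while leaving every statistical property measurable.
The generator itself scales well beyond that.

## Known limitations

* The simulated-p resolution is $1/(B+1)$; ranking within the floor group
  falls back to the LBF itself.
* The Satterthwaite gene-based null is a two-moment approximation; its
  tails are approximate for heavily correlated multi-SNP genes (the
  calibration suite bounds the damage at the 0.05 level).
* The Bayesian score model is a single-SNP approximate Bayes factor summed
  over pruned eSNPs, not a joint multi-SNP posterior; it reproduces the
  sign scenarios and ranking behaviour of the published integration rather
  than any particular software's numeric output.
* Gene identifiers must be pre-harmonized across GWAS annotation, eQTL and
  expression inputs; no namespace mapping is attempted.
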