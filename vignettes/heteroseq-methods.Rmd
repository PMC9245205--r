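---
title: "heteroseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heteroseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteroseq)
```

`heteroseq` analyses gene expression inheritance in an F1 hybrid and its
two parents from gene-level RNA-seq counts. This vignette is the package's
own account of the statistics it implements: the models and their
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design decisions taken where more than
one reasonable convention exists.

## The count model

All expression statistics assume gene-level counts that are negative
binomial with a quadratic mean–variance relation,
$\mathrm{Var}(y) = \mu + \alpha\mu^2$, where the dispersion $\alpha$
captures biological replicate-to-replicate variability
($\sqrt{\alpha}$ is approximately the biological coefficient of
variation). Sequencing depth differences between samples are removed by
median-of-ratios size factors: for each sample, the median over reference
genes (nonzero in every sample) of the ratio of its count to the gene's
geometric mean. Size factors are defined only up to a common scale —
rescaling one sample rescales every normalized count by a common constant
— so all downstream statistics are built from normalized-count ratios and
are reported per contrast, not per sample.

**Dispersion.** Per gene, $\hat\alpha = \max\{0,(s^2-\bar\mu)/\bar\mu^2\}$
on normalized counts, pooled across replicate groups with weights
$n_g - 1$. Because a 3-replicate estimate has only 2 degrees of freedom,
the gene-wise value is shrunk 50/50 toward a mean–dispersion trend
$\alpha(\mu) = a_0/\mu + a_1$ fitted by least squares across genes (the
weight is exposed as `shrink_weight`; the trend needs at least 10 usable
genes, otherwise the mean gene-wise value stands in). Genes with no
nonzero replicate group have undefined dispersion and are excluded from
testing with `p = NA`.

**Two-group Wald test.** `nb_wald_test()` solves the NB score equations
with a log link on size-factor-normalized counts. For the two-group
design the solution is closed-form — each group mean is the mean of its
normalized counts — with
$\mathrm{Var}(\hat\beta) = \sum_g (1+\alpha\hat\mu_g)/(n_g\hat\mu_g)$,
which is the fixed point of the offset IRLS formulation whenever all size
factors are equal. Working on the normalized scale was a deliberate
choice: it makes fold changes and DEG calls exactly invariant to
rescaling any sample's counts, which the raw-count offset formulation
only achieves approximately (its NB weights are not scale-equivariant).
The price is that the Poisson part of the variance is evaluated at the
normalized rather than the raw mean; at the depths this package targets
(tens to hundreds of counts) the difference is far below the noise floor
of the test. Two-sided normal p-values are BH-adjusted per contrast, and
a gene is a DEG when `fdr <= 0.01` and `|log2fc| >= 1` (both exposed in
the configuration). No fold-change shrinkage, outlier filtering or
independent filtering is applied — those refinements of mature DE tools
are intentionally out of scope, so DEG counts from this package will not
match theirs exactly. A reporting-only fold change with a +0.5
pseudocount is available behind `pseudocount_lfc`; it never feeds the
test or the DEG flag.

At its stated operating point (3 vs 3 replicates, $\alpha = 0.1$, depth
200) the plug-in Wald test runs slightly hot: its measured type-I error
at nominal 0.05 sits around 0.06–0.08 depending on the realization,
the familiar behaviour of Wald tests with few-degrees-of-freedom
dispersion estimates. Power at a planted 4-fold change with
$\alpha = 0.05$ is essentially complete.

**Activity rule.** A gene is actively expressed in a replicate group when
at least 2 replicates have at least 2 reads (`active_min_reads`,
`active_min_reps`). Sample-correlation summaries use Pearson correlation
of $\log_2(\text{normalized count}+1)$ over the genes detected (count
$\ge 2$) in at least one of the two samples, reported as $R^2$.

## The Hp classifier

For every DEG between the hybrid and its parents (DGhp), with $p_1, p_2,
f_1$ the replicate means of normalized counts for the maternal parent,
paternal parent and hybrid, the additive effect is $a = |p_1-p_2|/2$, the
dominance effect $d = f_1 - (p_1+p_2)/2$, and $H_p = d/a$ classifies the
gene into additive $(-0.2, 0.2]$, partial dominance $(-0.8,-0.2] \cup
(0.2, 0.8]$, dominance $(-1.2,-0.8] \cup (0.8,1.2]$ or over-dominance
$(-\infty,-1.2] \cup (1.2,\infty)$. The intervals are half-open exactly
as written (the asymmetry between $\le -1.2$ and $> 1.2$ at the two
over-dominance boundaries is preserved, not symmetrized) and partition
the extended real line, which the test suite checks on a dense grid.

Conventions chosen where the formulas are silent:

* $p_1,p_2,f_1$ are arithmetic means of normalized counts across
  replicates — the natural summary consistent with the mid-parent
  formula.
* DGhp membership defaults to the **union** of the hybrid-vs-mother and
  hybrid-vs-father DEG sets (maximizes coverage); the intersection is
  available via `membership`/`dghp_union`.
* When the parents are equal ($a = 0$): a hybrid differing from them is
  the literal over-dominance situation, so $H_p = \pm\infty$ with the
  sign of $d$, classified over-dominant; when $d = 0$ too, $H_p = 0$
  (additive). Genes with $p_1 = p_2 = f_1 = 0$ are reported `degenerate`
  and excluded from category percentages.

$H_p$ is a ratio of differences of noisy means, so its sampling noise
grows with $|H_p|$ (errors scale roughly like
$\sqrt{\alpha/n}\,(1+H_p)$ for positive $H_p$). At $\alpha = 0.05$ with
3 replicates, genes whose expression tracks the *higher* parent
($H_p \approx +1$) are intrinsically hard to classify — no planting
margin fixes this — while genes tracking the lower parent are easy.
Misclassifications therefore concentrate in categories adjacent to the
planted one, and aggregate recovery under this noise level plateaus
around 80–85% even though noiseless recovery is exact. Users wanting
sharper mode calls should add replicates, not tighten thresholds.

## Allele-specific expression

Informative SNPs are sites where the two parents are homozygous for
different alleles, so each hybrid read covering one can be assigned to a
parental haplotype. `aggregate_haplotype_counts()` sums per-SNP allele
counts over each gene's exons; counts whose allele matches neither
parent go to a QC report, and SNPs shared by overlapping genes
contribute to each (flagged). The package starts from per-SNP allelic
counts — read-backed phasing, mapping-bias correction and alignment
filters happen upstream and are out of scope.

`ase_test()` fits, per gene and tissue, an NB GLM with log link on the
$2r$ maternal/paternal counts with a replicate factor and an allele
factor, and Wald-tests the allele coefficient; BH across the tested genes
of a tissue, ASEG when `p_adj <= 0.05`. Choices:

* The replicate factor is included so replicate-level depth differences
  cannot masquerade as imbalance.
* Per-gene dispersion is a method-of-moments estimate on within-allele
  replicate variation, floored at `1e-8`.
* Genes with fewer than `min_depth = 10` summed allelic reads are
  untested (`p = NA`): below that, the GLM is degenerate. The threshold
  is deliberately permissive; it exists to remove pathology, not to
  filter biology.
* A gene whose allele total is zero on one side has no finite MLE; it is
  reported `p = NA` via the non-convergence path rather than
  pseudocounted.
* The GLM is fitted by IRLS (tolerance `1e-10` on the coefficient change,
  100 iterations, linear predictor clamped to ±30 to keep divergent fits
  finite; initialization from `log(y + 0.5)` least squares).

Genes that are ASEGs in both tissues are classified `consistent_maternal`
/ `consistent_paternal` when biased to the same parent twice and
`shift_direction` otherwise; genes significant in one tissue only are not
classified.

## Set statistics

**Overlap resampling.** The overlap of two gene sets (e.g. parental DEGs
and ASEGs) is compared with 1,000 draws of same-sized random sets from
the expressed universe. Two p-values are reported: a one-sample Student
t of the null overlaps against the observed value (alternative: null
mean below observed), and the empirical permutation p
$(1+\#\{\text{null} \ge \text{obs}\})/(n_{\text{sim}}+1)$. The t-test
against a resampled null is fragile (it t-distributes a quantity that is
not a mean of the observed data), so the empirical p is the recommended
headline; the t version is retained as the conventional companion. The
universe is a configuration choice — here, the active genes of the
tissue.

**Over-representation.** Upper-tail hypergeometric p per term, BH across
terms. The test suite checks it against exhaustive enumeration of all
query draws for universes up to 12 genes.

**Variant density.** Per impact category, the count of variants on ASEGs
versus genome-wide, with significance from permuting gene sets of the
ASEG size (1,000 draws) — a choice that avoids parametric assumptions
about variant clustering along the genome.

## Variant filtering and annotation

Hard filters follow the standard short-variant thresholds: SNPs fail on
QUAL < 30, QD < 2, SOR > 3, FS > 60, MQ < 40, MQRankSum < −12.5 or
ReadPosRankSum < −8; indels on QUAL < 30, QD < 2, FS > 200, MQ < 40 or
ReadPosRankSum < −20. The rank-sum thresholds are applied as *negative*
values — rank-sum statistics are centred at zero, and positive cutoffs of
that size would discard nearly every variant; `rank_sum_sign_fix = FALSE`
restores the positive reading for comparison. A missing metric skips its
criterion; records with equal-length multi-base alleles are flagged
`complex` and passed through with a warning.

The consequence annotator is a minimal, documented subset of the
ontology used by standard effect predictors: coding SNVs are classified
by codon translation on the correct strand (synonymous / missense /
stop_gained / stop_lost / start_lost / stop_retained), CDS indels are
frameshift when the allele-length difference is not a multiple of 3 and
inframe otherwise, splice sites are the first and last two intronic
bases, UTR is a single term, and upstream/downstream windows span 5 kb.
One consequence per variant is reported: the most severe across
overlapping genes (HIGH > MODERATE > LOW > MODIFIER, ties broken by a
fixed consequence order), matching how variants are tallied per gene.
Genes whose CDS length is not a codon multiple are flagged at load and
skipped for coding calls. Indel gene-overlap uses the full REF span
including the anchor base; the strand-symmetry property of the
classifier is guaranteed (and tested) for SNVs, while left-anchored
indel representation is not closed under naive reverse-complement
mapping, so indel positions are conventions, not symmetric objects.

## The synthetic-data generator

`sim_config()` defines a trio study: by default 2,000 genes, two tissues,
three replicates, lognormal baseline means (location `log(200)`, spread
1), NB dispersion 0.05, per-sample depth factors with 10% lognormal
spread. The generator plants:

* **DE genes** (30% by default, exact counts): parents separated so the
  hybrid is at least $2^{\texttt{lfc\_magnitude}}$-fold (default 4-fold)
  from one parent, each DE gene assigned an inheritance-mode category
  whose noiseless $H_p$ lies inside the category interval with margin
  0.1 from every finite endpoint (unbounded tails truncated at
  $|H_p| = 3$). The parent separation is $2F$-fold for $H_p \ge 0$,
  $F^2$-fold for $-1 \le H_p < 0$ (the smallest separation for which a
  between-parents hybrid can still be $F$-fold from one parent) and
  4-fold in the deep negative tail (where the hybrid mean must stay
  non-negative; this caps `lfc_magnitude` at 2). The default category
  mixture (over-dominance 0.70, dominance 0.10, partial 0.12, additive
  0.08, over-dominance drawn positive with probability 0.75) mirrors the
  over-dominance-dominated pattern reported for hybrid-rice
  transcriptomes, which is also the study design this package emulates.
* **Allelic imbalance** (10% of genes): total allelic depth Poisson
  (mean 100), maternal count binomial with success probability
  $f/(1+f)$ for the biased parent at allelic fold $f = 4$; 5% of ASE
  genes flip direction in tissues after the first, exercising the
  shift-direction pattern.
* **A genome with gene models and variants**: chromosomes `chrSim1..k`
  of 100 genes each, genes of 60–180 codons with UTRs, half with one
  intron (nonzero CDS phase), either strand, gaps above 10.2 kb so
  intergenic placement is unambiguous; variants realized *by
  construction* per planted impact category (stop-creating, frameshift
  or splice SNVs/indels for HIGH; codon-changing SNVs for MODERATE;
  synonymous third-position SNVs for LOW; intronic/upstream/intergenic
  SNVs for MODIFIER), with REF always matching the emitted genome.
  Genes planted as ASE can carry a multiplied variant rate
  (`aseg_variant_multiplier`) to emulate variant enrichment on ASEGs;
  the default multiplier is 1, i.e. the default study plants **no**
  coupling between ASE, parental DE and variant load, so overlap and
  density tests on it are honest nulls.

The truth table (planted DE status, category, noiseless means, allelic
direction, variant impacts) is written separately and is never read by
the analysis pipeline — only by tests.

What the generator does **not** emulate: read-level artifacts (mapping
bias, positional coverage, duplicates), SNP linkage within genes (counts
are generated at gene level), correlated dispersion across genes, and
any coupling between DE and ASE. Passing tests on this generator
therefore demonstrate correctness of the statistics under their assumed
model, not robustness to alignment-level artifacts in real data.

Determinism: every operation seeds its own RNG stream from
`seed` + a fixed offset, so identical configurations yield byte-identical
fixtures and stage outputs regardless of which stages run.

## Pipeline and problem sizes

`run_pipeline()` executes simulate → DE → dominance → ASE → patterns →
overlap → enrichment → variant analysis behind one validated
configuration (YAML-loadable; all thresholds above are fields with the
defaults stated). Each stage writes a TSV; a MANIFEST records the files
and completion status, and rerunning with the same seed reproduces every
result table byte for byte (`run_report.tsv`, which carries wall times,
is the only exception).

The test suite and the acceptance script exercise the methods at the
sizes the statistics need and no more: 2,000-gene studies for planted
recovery, 5,000 genes for type-I calibration, 1,000-draw resamplings,
200 repetitions for permutation-p uniformity, 100 random gene models for
strand symmetry. These sizes were chosen so that each check has adequate
Monte-Carlo resolution while the whole suite stays in the minutes range
on one CPU.

## Known limitations

* The Wald DE test is mildly anticonservative at 3 replicates (see
  above); interpret borderline DEGs accordingly or add replicates.
* The dispersion trend is a two-parameter least-squares fit, not a
  robust regression; extreme dispersion outliers can tilt it.
* The annotator reports one consequence per variant and one transcript
  per gene; multi-isoform effects are out of scope.
* The overlap t-test is reported for continuity with common practice but
  the empirical p should be quoted.
* Hp classification quality is depth- and replicate-limited as described;
  category percentages from 3-replicate designs carry a few points of
  noise for the boundary-adjacent classes.
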