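# heteroseq

Inheritance-mode and allele-specific expression analysis for hybrid/parent
RNA-seq trios.

Hybrid crops often outperform both parents (heterosis). One window into the
phenomenon is the transcriptome of an F1 hybrid grown next to its two
parents: for every gene one can ask whether the hybrid's expression is
additive (at the mid-parent value), dominant (tracking one parent),
partially dominant, or over-dominant (outside the parental range), and —
when the parents differ at exonic SNPs — which parental allele the hybrid
actually transcribes. `heteroseq` implements this analysis for gene-level
read counts from a maternal line, a paternal line and their hybrid in one
or more tissues, with two or more biological replicates each, plus the
variant-level companion analyses (hard filtering, consequence/impact
annotation, variant density on allele-specifically expressed genes) and a
synthetic-data generator with a ground-truth table so every stage is
testable without sequencing data.

## The statistics at the core

* **Differential expression.** Genes with at least 2 reads in at least 2
  replicates are called active. Counts are normalized by median-of-ratios
  size factors; per-gene NB dispersion α (Var = μ + αμ²) is a
  method-of-moments estimate shrunk 50/50 toward a fitted mean-dispersion
  trend α(μ) = a₀/μ + a₁; each contrast is a negative-binomial Wald test
  with BH correction. A gene is a DEG when FDR ≤ 0.01 and |log₂FC| ≥ 1.
* **Inheritance mode.** For each DEG between the hybrid and its parents,
  with p₁, p₂, f₁ the mean normalized counts of the two parents and the
  hybrid, the additive effect is a = |p₁ − p₂|/2, the dominance effect
  d = f₁ − (p₁ + p₂)/2, and their ratio Hp = d/a classifies the gene:
  additive (−0.2 < Hp ≤ 0.2), partial dominance (−0.8 < Hp ≤ −0.2 or
  0.2 < Hp ≤ 0.8), dominance (−1.2 < Hp ≤ −0.8 or 0.8 < Hp ≤ 1.2),
  over-dominance (Hp ≤ −1.2 or Hp > 1.2).
* **Allele-specific expression.** Per-SNP parental-allele counts at
  homozygous-different sites are summed over each gene's exons; per gene
  and tissue a negative-binomial GLM with replicate and allele terms tests
  the allele coefficient (Wald, BH); genes with adjusted p ≤ 0.05 are
  ASEGs, classified across tissues as consistent maternal, consistent
  paternal, or shift direction.
* **Set statistics.** Overlap between gene sets is tested by 1,000 rounds
  of random resampling from the expressed universe (one-sample t against
  the observed overlap, plus the recommended empirical permutation p);
  term over-representation is the upper-tail hypergeometric test with BH;
  variant density on ASEGs is compared with the genomic background by
  gene-set permutation.
* **Variants.** GATK-style hard filters (QUAL < 30, QD < 2, SOR > 3,
  FS > 60 for SNPs / 200 for indels, MQ < 40, rank-sum rules) and a
  minimal consequence annotator (codon-aware on either strand) mapping to
  HIGH / MODERATE / LOW / MODIFIER impact categories.

## Worked example

```r
library(heteroseq)

# the Hp statistic on three toy genes: (p1, p2, f1)
hp_statistic(c(10, 10, 20), c(30, 30, 20), c(50, 20, 40))
#>   a_effect d_effect  hp
#> 1       10       30   3     # far above the high parent: over-dominance
#> 2       10        0   0     # at the mid-parent value: additive
#> 3        0       20 Inf     # above two equal parents: over-dominance

# a synthetic trio study: 500 genes, 2 tissues, 3 replicates
cfg  <- sim_config(seed = 1, n_genes = 500)
trio <- simulate_trio_counts(cfg)
se   <- trio$counts
cd   <- SummarizedExperiment::colData(se)
cols <- function(role) rownames(cd)[cd$role == role & cd$tissue == "leaf"]
sf   <- size_factors(se)
de_m <- nb_wald_test(se, cols("maternal"), cols("hybrid"), sf = sf)
de_f <- nb_wald_test(se, cols("paternal"), cols("hybrid"), sf = sf)
cl   <- classify_dghp(se, de_m, de_f, "leaf", sf = sf)
cl$summary
#>           category  n   percent
#>     over_dominance 97 64.666667
#>          dominance 14  9.333333
#>  partial_dominance 26 17.333333
#>           additive 13  8.666667

al  <- simulate_allelic_counts(cfg, trio$truth)
ase <- ase_test(al, "leaf")
sum(ase$is_aseg)
#> [1] 50
```

The 150 DEGs between this simulated hybrid and its parents are dominated
by over-dominant genes (64.7%), reproducing the planted mixture; 50 of the
500 genes are called allele-specifically expressed, matching the 10%
planted imbalance rate at depth 100 and 4-fold allelic bias.

The whole pipeline (simulate → DE → dominance → ASE → patterns → overlap →
enrichment → variants) runs behind one configuration:

```r
run_pipeline(pipeline_config(outdir = "demo", seed = 1,
                             sim = list(n_genes = 500)))
```

or from a shell via the thin wrapper
`inst/scripts/heteroseq-pipeline.R --config pipeline.yaml`. Every stage
writes a TSV; the same configuration and seed reproduce the result tables
byte for byte.

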