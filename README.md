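# cubtools

Codon usage bias (CUB) analysis for protein-coding sequences, nuclear or
organellar. `cubtools` is aimed at comparative-genomics work of the kind
routinely done on plant nuclear and chloroplast genomes: given CDS FASTA
files (one per genome) and, optionally, a gene × tissue RPKM expression
table, it computes the standard usage indices, diagnoses the sources of
bias, determines optimal codons, relates bias to expression, and clusters
genomes on their usage profiles.

## What it computes

- **QC** — sequences shorter than 300 bp removed (strictly; the threshold
  is configurable), out-of-frame tails trimmed and internal stops flagged.
- **Indices per gene** — relative synonymous codon usage
  RSCU<sub>ij</sub> = X<sub>ij</sub> / ((1/n<sub>i</sub>) Σ<sub>j</sub> X<sub>ij</sub>);
  Wright's effective number of codons
  ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ (range 20–61, capped at 61,
  F̂ = (nΣp² − 1)/(n − 1) per amino acid); GC, GC1/GC2/GC3, GC12; and
  A3/T3/G3/C3 with GC3s over the 59 synonymous codons.
- **Bias-source diagnostics** — ENC-plot against
  ENC<sub>exp</sub> = 2 + s + 29/(s² + (1 − s)²); PR2 plot
  (G3/(G3+C3) vs A3/(A3+T3), centre (0.5, 0.5)); neutrality regression of
  GC12 on GC3 with slope, Pearson r and p.
- **Optimal codons** — pooled RSCU of the lowest-ENC 5% of genes versus
  the highest-ENC 5%; a codon is optimal when RSCU (high-bias pool) > 1
  and ΔRSCU > 0.08, both strict; over/under-representation flagged at
  1.6/0.6.
- **Expression association** — Welch t-tests on log10(RPKM + 1) at the
  sequence level (tiers: RPKM > 10 high, 1 < RPKM ≤ 10 medium,
  0 < RPKM ≤ 1 low, 0 excluded; median-ENC split within tiers), the codon
  level (dominant third base), and the amino-acid level (per-family
  preferred codon, G/C- vs A/T-ending).
- **Clustering** — Euclidean distances between pooled 59-dimensional RSCU
  vectors, average-linkage dendrogram, Newick export, flat cuts, and a
  Robinson–Foulds comparison against any reference phylogeny.
- **Synthetic data** — a seeded generator with known ground truth
  (per-gene bias strength, preferred codons, expression coupling, planted
  genome groups) that exercises every stage.

See `vignettes/codon-usage-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(cubtools)

# a synthetic "nuclear-like" panel: 300 genes, per-gene bias strength
# 0.05-0.45, expression coupled to bias
cfg <- sim_preset("nuclear", n_genes = 300L, expression_coupling = 0.6, seed = 7L)
sim <- simulate_cds(cfg, genome = "demo")

qc <- qc_filter(sim$cds)
qc
#> CDS quality control (min length 300 bp)
#>   input: 300  kept: 300  removed (< 300 bp): 0
#>   frame-trimmed: 0  internal stop: 0

counts   <- codon_count_matrix(tokenize_cds(qc$kept))
profiles <- profile_genes(counts, genome = "demo")
round(sapply(profiles[c("ENC", "GC", "GC3", "GC3s")], mean), 3)
#>    ENC     GC    GC3   GC3s
#> 51.833  0.416  0.387  0.362

neutrality_fit(profiles)
#> Neutrality plot regression (GC12 ~ GC3), n = 300 genes
#>   slope = 0.01504 (se 0.02433)  intercept = 0.4253
#>   Pearson r = 0.03578  p = 0.5371
#>   GC12 in [ 0.3552, 0.5136 ]  GC3 in [ 0.2414, 0.5476 ]

find_optimal_codons(counts, profiles, fraction = 0.1)
#> Optimal codons: 18 (A:7, U:11, G:0, C:0)
#>  codon aa rscu_high rscu_low  delta
#>    AAA  K     1.365    1.035 0.3303
#>    AAT  N     1.457    1.051 0.4057
#>    ...
```

Reading the output: the panel shows moderate overall bias (mean ENC ≈ 52,
well above the strongly biased regime near 20) with A/U-rich third
positions (GC3s ≈ 0.36). The neutrality slope near 0 says GC12 does not
track GC3 — in this generator the two are uncoupled by construction, the
pattern read as selection-dominated in real data. The 18 optimal codons
are exactly the generator's A/T-ending preferred set: codons enriched in
the low-ENC tail with ΔRSCU far above the 0.08 threshold.

The same analysis runs from the shell:

```sh
Rscript inst/scripts/cub-pipeline.R simulate --out sim --n-genes 200 --bias 0.1,0.7 --seed 1
Rscript inst/scripts/cub-pipeline.R run --cds sim/synthetic_cds.fasta \
    --expression sim/expression.tsv --out results --tail-fraction 0.1
```

writing `profiles.tsv`, `pooled_rscu.tsv`, `enc_plot.tsv`, `pr2.tsv`,
`neutrality.tsv`, `optimal_codons.tsv`, `expression_tests.tsv`,
`rscu_distance.tsv`, `rscu_dendrogram.nwk` and a run log; re-running with
the same inputs is bitwise reproducible.

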