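---
title: "Codon usage bias analysis with cubtools: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Synonymous codons are not used uniformly: within a genome, and across genes
of one genome, some codons encoding a given amino acid are systematically
preferred. This codon usage bias (CUB) carries information about mutational
pressure (which shapes base composition, especially at the weakly
constrained third codon position), natural selection (notably translational
selection in highly expressed genes), and lineage history. cubtools
implements the standard analysis battery used in comparative CUB studies of
nuclear and organellar (typically chloroplast) protein-coding sequences:
usage indices per gene, three graphical diagnostics that separate mutation
from selection, data-driven determination of optimal codons, association of
bias with expression, and genome clustering on usage profiles.

The intended user supplies CDS FASTA files (one per genome) and optionally
a gene × tissue RPKM table. The package does not locate ORFs, parse
annotation, or compute expression from reads.

# Quantities computed

## Codon counting conventions

All statistics operate on the standard genetic code with a fixed,
alphabetical 64-codon order. Stop codons (TAA, TAG, TGA) never contribute
to any index; Met (ATG) and Trp (TGG) have no synonymous alternative and
are excluded from synonymous-usage statistics, leaving the 59 synonymous
codons of 18 degenerate amino acids. Six-fold families (Leu, Ser, Arg) are
treated as single families, not split 2+4. Sequences are tokenized from
position 1 in non-overlapping triplets; codons containing ambiguity symbols
are skipped and counted.

## RSCU

For amino acid $i$ with degeneracy $n_i$ and codon counts $X_{ij}$,

$$\mathrm{RSCU}_{ij} = \frac{X_{ij}}{\tfrac{1}{n_i}\sum_j X_{ij}},$$

the observed count over the count expected under equal synonymous usage.
Values sum to $n_i$ within each family; 1 means unbiased use. On pooled
usage, values above 1.6 are flagged over-represented and below 0.6
under-represented — conventional screening thresholds, configurable in
`pooled_rscu_table()` and `call_optimal()`.

## Wright's effective number of codons

`enc_wright()` follows Wright's (1990, Gene 87:23–29) estimator. For each
degenerate amino acid with occurrence count $n \ge 2$ the codon
homozygosity is estimated with the small-sample correction
$\hat F = (n\sum_j p_j^2 - 1)/(n-1)$; amino acids with $\hat F \le 0$ or
$n < 2$ are excluded from the class averages — the estimator is then
uninformative. Class means $\bar F_k$ are taken over the 2-, 3-, 4- and
6-fold classes (9, 1, 5 and 3 amino acids) and

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

When Ile is absent, $\bar F_3$ is imputed as $(\bar F_2 + \bar F_4)/2$;
when any other class is empty the gene's ENC is reported missing rather
than guessed. Estimates above 61 (possible in finite samples under
near-uniform usage) are capped at 61; the theoretical floor of 20 is a
mathematical consequence of $\hat F \le 1$ and is asserted in tests, not
clamped. ENC = 20 means one codon per amino acid; 61 means fully uniform
usage.

## Positional GC and third-base composition

`positional_gc()` reports the G+C fraction at each codon position over all
sense codons, GC as the mean of the three positions, and GC12 as the mean
of positions 1 and 2. (Whether "GC" should be sequence-wide or the mean
positional value is a genuinely open convention; the mean positional value
is used, and the two differ only through the stop codon.)
`synonymous_third_base()` counts A3/T3/G3/C3 over the 59 synonymous codons
only and reports GC3s = (G3+C3)/(A3+T3+G3+C3). Restricting to synonymous
codons avoids the fixed third bases of Met, Trp and the stops distorting
the skews; this matters for the PR2 plot below and is the documented
convention throughout. Raw counts are reported rather than
codonW-style "A3s" fractions, whose denominators differ per base; a
codonW-compatibility mode is out of scope.

# Bias-source diagnostics

**ENC-plot.** Observed ENC against GC3s, with the expected curve under
pure compositional drive, $\mathrm{ENC}_{exp} = 2 + s + 29/(s^2+(1-s)^2)$.
The curve runs from 31 at $s=0$ through its maximum 60.5 at $s=0.5$ to 32
at $s=1$. `enc_plot_table()` reports `deviation = ENC_exp - ENC_obs`, so a
positive deviation places the gene below the curve — usage more restricted
than composition alone explains, the signature read as selection.

**PR2 plot.** Per gene, $x = G3/(G3+C3)$ and $y = A3/(A3+T3)$ over
synonymous third bases. Under strand-symmetric, selection-free usage
(parity rule 2: A = T, G = C) genes sit at (0.5, 0.5); the direction of
displacement indicates which bases are favoured. Zero denominators yield
flagged missing coordinates rather than errors.

**Neutrality plot.** `neutrality_fit()` regresses GC12 on GC3 by ordinary
least squares and reports slope, intercept, Pearson r and its two-sided
p-value (t distribution, n−2 df). A slope near 1 means first/second
positions track third-position composition (mutation-dominated); near 0
means they are held steady against it (selection-dominated). The slope and
r are both reported explicitly because the two are routinely conflated in
the literature; when the correlation is numerically perfect the p-value is
set to 0 rather than evaluating a divergent t statistic.

# Optimal codons

Following the classical ENC-extremes design, `select_extreme_groups()`
sorts genes by ENC and takes the lowest 5% (strongest bias, the
"high-expression proxy") and highest 5% as the two reference groups. Group
size is `ceiling(fraction * n)`; ties at a cutoff are broken by gene id so
the selection is reproducible. Codon counts are pooled within each group —
pooling (rather than averaging per-gene RSCU) is the convention of
codonW-style workflows and weights genes by their codon content.
`delta_rscu()` differences the pooled RSCU as high-bias minus low-bias;
the orientation is stated prominently because it flips every call. A codon
is optimal when RSCU in the high-bias pool exceeds 1 *and* ΔRSCU exceeds
0.08, both strictly. The RSCU > 1 condition is evaluated on the high-bias
pool (the group the rule is about); a whole-dataset RSCU is used only for
the over/under-representation annotation.

A sampling-noise consideration governs when this procedure is meaningful:
for a 6-fold family the standard deviation of ΔRSCU under no true
difference is roughly $3.2/\sqrt{m}$ with $m$ codons of that amino acid
per pool, so pools below a few thousand codons per amino acid produce
spurious calls above the 0.08 threshold. Moreover, because the tails are
*selected on ENC*, under a null the high-bias pool consists of genes with
chance-concentrated usage, which inflates pooled-RSCU dispersion roughly
1.7× beyond iid multinomial noise. Genome-scale inputs (thousands of genes
per tail) absorb both effects comfortably; the package's own validation
panels are sized accordingly (30,000 genes for planted-recovery checks,
24,000 for null checks), and users applying the 5% rule to small gene sets
should widen the fraction or interpret calls cautiously.

# Expression association

Three levels, all tested with Welch's unequal-variance t-test (two-sided,
Satterthwaite degrees of freedom). RPKM is summarized as the mean across
tissues and transformed as log10(RPKM + 1) before testing to tame the
heavy right tail; a raw-scale mode exists. Benjamini–Hochberg adjusted
p-values are reported alongside raw ones, but significance flags use raw p
at 0.05 — the historical convention of these analyses, kept so results are
comparable; readers can consult `p_adj`.

1. **Sequence level.** Genes are tiered by summary RPKM — high (> 10),
   medium (1, 10], low (0, 1], excluded (= 0) — and split within each tier
   at the within-tier median ENC into strong/weak bias groups
   (`ENC <= median` is strong). A fixed ENC threshold (e.g. 50) is
   available where a dataset-independent cut is preferred; the median is
   the default because it guarantees balanced groups in every tier.
   Positive t means the strongly biased genes are more highly expressed.
2. **Codon level.** Each gene's dominant synonymous third base (argmax of
   A3/T3/G3/C3; ties resolved by the fixed order T > A > G > C, chosen to
   favour the most common third base in AT-rich plant genes and logged)
   defines four groups; all six pairwise tests plus combined G/C vs A/T
   are reported.
3. **Amino-acid level.** For each degenerate amino acid, genes are grouped
   by their maximal-RSCU codon for that amino acid (within one amino acid
   this is the count argmax; ties exclude the gene for that amino acid).
   The G/C-ending-preferring group is tested against the A/T-ending one.

Groups smaller than 3 make a comparison "untestable" — reported, not an
error — and degenerate variances are guarded (equal constant samples give
t = 0, p = 1).

# Genome clustering

Pooled per-genome RSCU vectors (59 coordinates, fixed alphabetical codon
order so outputs are byte-stable) are compared by Euclidean distance and
clustered agglomeratively. Linkage is average (UPGMA-style) by default —
the natural choice for a feature-vector dendrogram where no model of
evolutionary rates is claimed — with single, complete and Ward available.
Merge ties are resolved by `stats::hclust`'s deterministic rule. The
dendrogram exports as Newick with branch lengths equal to half the merge
heights (leaves of an average-linkage tree are then equidistant from the
root). `cut_clusters()` produces flat partitions at any k; no automatic
choice of k is attempted because cluster counts in published CUB analyses
are presentation choices, not estimands. `compare_topology()` reports the
Robinson–Foulds distance against a user-supplied reference phylogeny, as a
comparison aid only: RSCU dendrograms are feature clusterings, not
phylogenies, and routinely disagree with alignment-based trees.

# The synthetic-data generator

`sim_config()` + `simulate_codon_counts()`/`simulate_cds()` implement a
deliberately minimal generative model: per gene, amino acids are drawn iid
from a frequency vector, and each amino acid's codon from the mixture

$$(1-\beta)\,\times\,\text{background} \;+\; \beta\,\times\,
  \delta(\text{preferred codon}),$$

with per-gene bias strength β in [0, 1) and one preferred codon per amino
acid (A/T-ending by default, matching the third-base preference typical of
plant genomes). β = 0 gives uniform usage (mean ENC near 61 minus finite-
sample noise); β → 1 collapses every family onto one codon (ENC → 20).
This is *not* a mutation–selection–drift model: it has no phylogeny, no
indels, no within-gene autocorrelation, and base composition enters only
through which codons are preferred. Passing tests on this generator
demonstrate that the statistics recover planted structure of the kind they
estimate — not that real genomes satisfy the model.

Generator defaults: 200 genes of 100–400 sense codons (all CDS therefore
pass the 300-bp QC filter by construction, with ATG start and a sampled
stop appended); amino-acid frequencies flat over the 18 degenerate amino
acids with Met/Trp near proteome-typical 2.2%/1.2%. `sim_preset()` offers
a "nuclear"-like panel (per-gene β on 0.05–0.45, mean ENC near 52) and a
"chloroplast"-like one (β on 0.10–0.55, mean ENC near 50, lower GC) —
qualitative resemblances only.

Expression is simulated as log10-RPKM ~ Normal(μ_tier + γβ, σ_gene) with a
three-component tier mixture (defaults: means −0.7, 0.5, 1.6; σ_gene 0.3)
so all tiers are populated, tissues as noisy replicates (σ_tissue 0.1),
and 2% zero-RPKM genes for the excluded tier. γ = 0 is the null generator.
One structural subtlety, found while validating and worth knowing: with a
tier mixture, genes of the medium tier whose coupling pushes them just
over the RPKM = 10 boundary enter the realized high tier as
high-β/low-RPKM members and dilute the within-tier contrast. Planted
directional checks therefore generate a single-tier panel (tier
probabilities 0/0/1), which realizes the within-tier shifted-means design
directly; the mixture is retained for null calibration, where boundary
mixing cannot bias a test whose null is true.

Exact-slope ground truth for the neutrality regression is provided at
profile level by `simulate_neutrality_panel()` (GC12 = a + slope·GC3 +
noise). The sequence-level `gc3_coupling` parameter tilts amino-acid
composition with the gene's third-base propensity and produces a monotone
but uncalibrated slope; it exists to exercise the full sequence path, while
the profile-level panel is the oracle for slope recovery.

`simulate_genome_panel()` plants group structure by reassigning the
preferred codon of a `divergence` fraction of amino acids per group, so
between-group RSCU distance is controlled and flat-cut recovery can be
scored exactly.

# Numerical and validation choices

- All validation is seeded; problem sizes are chosen so each property is
  measured where its sampling noise is far from the decision threshold:
  1,000 random count tables for RSCU normalization (tolerance 1e-9);
  5 × 200 genes for the ENC–β monotonicity grid; 2,000 genes for slope
  recovery (tolerance band 0.27–0.33 around a true 0.3); 30,000-gene
  panels (1,500-gene 5% tails) for planted optimal-codon recovery and
  24,000-gene panels for null calls, per the ΔRSCU noise argument above;
  500 simulations of 600 genes for the 5%-level null calibration of the
  sequence-level test (acceptance band 3–7%).
- Brute-force oracles (loop-based RSCU and ENC, closed-form OLS, an O(n³)
  average-linkage agglomerator, textbook Welch formulas) live in the test
  helpers and are kept independent of the package's vectorized paths.
- QC policy: the 300-bp filter applies to raw length and removes strictly
  shorter sequences; non-multiple-of-3 sequences are trimmed (flagged) and
  internal-stop sequences retained (flagged) by default since stops never
  enter the statistics anyway — `strict = TRUE` rejects both, for users
  who want hard guarantees from their annotation.

# Known limitations

- No CAI, Fop, tAI or other optimality indices; no correspondence
  analysis; no codonW-identical "A3s" normalization.
- RSCU clustering is a similarity analysis, not phylogenetics; the package
  deliberately does not build alignment-based trees (use MAFFT/IQ-TREE/
  MEGA and feed the result to `compare_topology()`).
- The expression module assumes a supplied, already-normalized RPKM
  matrix.
- The generator's limitations are described above; in particular, real
  genes violate the iid-amino-acid assumption, and real ENC–expression
  coupling is confounded with length and composition in ways the mixture
  model does not emulate.
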