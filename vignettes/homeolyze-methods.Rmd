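---
title: "Methods and design of homeolyze"
author: "homeolyze authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of homeolyze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeolyze)
```

# The problem

In an allopolyploid, every gene exists as two homoeologous copies, one per
parental subgenome (here labelled A and D, as in cotton). Bulk RNA-seq reads
aligned to a single diploid reference cannot be attributed to a subgenome
unless they cover a *homoeo-SNP* — a fixed nucleotide difference between the
two parental genomes. `homeolyze` implements the full chain from aligned
reads to biological summaries:

1. partition reads into subgenome classes by diagnostic SNP alleles;
2. quantify expression (RPKM) and call which genes are expressed at all;
3. test homoeolog and between-accession expression differences with a
   negative binomial (NB) conditional exact test;
4. summarise homoeolog expression *bias* and its conservation across
   accessions;
5. classify each gene's *expression level dominance* (ELD) into the twelve
   standard categories;
6. cross-classify diploid versus polyploid expression changes; and
7. build neighbor-joining expression phylogenies.

Every stage can be exercised end to end on synthetic data with known ground
truth (`generate_truth()`, `generate_counts()`, `generate_reads()`).

# Read partitioning

`classify_reads()` scores, for each read, every index SNP covered by an
aligned base (CIGAR `M`/`=`/`X`; insertions and deletions never produce an
allele call) with base quality at or above the threshold (default 20,
matching the common phred-20 trimming convention). A base equal to the
A-allele votes A; equal to the D-allele votes D; anything else *abstains* —
we treat a third base as a sequencing error rather than a veto, which keeps
the classifier robust at realistic error rates. The read class is then

* **A** — at least one A vote and no D votes (resp. **D**),
* **X** — votes for both subgenomes (a chimeric molecule),
* **N** — no votes at all (uninformative).

`count_reads_by_gene()` assigns each primary alignment to the gene whose
exons it overlaps most (bp of aligned overlap); exact ties are discarded
rather than broken arbitrarily, so the rule is deterministic and testable.
Secondary and supplementary alignments are ignored; duplicates are kept.
Class totals are conserved: assigned plus unassigned tallies equal the
number of primary mapped reads, an invariant asserted throughout the suite.

# Quantification and presence calling

`rpkm()` implements reads per kilobase of exon model per million mapped
reads, `1e9 * count / (length * library_size)`. Analysis units are
`(accession, partition, replicate)` columns: the A- and D-partition units of
a polyploid use the assigned class counts, and `total` units use A + D + N.
Chimeric X reads are excluded from totals by default — they are flagged
artifacts of template switching — but `include_X = TRUE` restores them; the
library size of a unit is its column sum.

Whether a gene is expressed at all is decided by a two-component Gaussian
mixture on the per-accession mean of `log2(RPKM + 1)` across replicates
(`fit_presence_mixture()`): the lower-mean component is background, and the
posterior probability of the upper component is the per-gene probability of
expression. This plays the role of a microarray-era "probability of
expression" model while staying appropriate for RNA-seq counts. EM runs to a
relative log-likelihood change below 1e-8 (at most 500 iterations) from five
deterministic quantile-spread starts, keeping the best likelihood; component
variances are floored at 1e-6 so a tight background cannot collapse the fit.
Two operating points are used downstream: posterior > 0.5 defines *active*
genes (ELD universes, commonly expressed sets), and posterior >= 0.99
defines the *high-confidence* universe used for bias calling.

# Differential expression

The test chain mirrors the classic count-based DE recipe but is implemented
in-house and verified against independent oracles:

* **TMM normalization** (`tmm_factors()`): the reference sample is the one
  whose upper quartile of library-scaled counts is closest to the mean upper
  quartile; genewise log-ratios are doubly trimmed (30% of M tails, 5% of A
  tails) and combined by precision weights; factors are scaled to unit
  geometric mean.
* **Common dispersion** (`estimate_common_dispersion()`): counts are scaled
  to the geometric-mean effective library size and rounded ("pseudo
  counts"), and the NB dispersion maximizing the summed conditional
  log-likelihood (conditioning on each gene's within-group total) is found
  by golden-section search on [1e-6, 5]. Scaling-then-rounding is a
  deliberate simplification of quantile adjustment; the difference is second
  order at the replicate counts used here and is covered by
  parameter-recovery tests against the reference qCML implementation.
* **NB conditional exact test** (`nb_exact_test()`): conditioning on the
  total of the two group sums, each split follows the convolution of the two
  group-sum NB laws; the two-sided p-value is the probability mass of all
  splits no more probable than the observed one (ties included, with a 1e-10
  relative tie tolerance). At dispersion zero this reduces exactly to the
  binomial test. The unit suite compares it against a brute-force
  enumeration oracle to 1e-12 for totals up to 200.
* **FDR**: Benjamini–Hochberg per contrast (`bh_fdr()`, delegating to the
  standard step-up implementation), threshold 0.05 everywhere. Genes with
  fewer than 5 summed raw counts in a contrast are reported as `NA` — the
  exact test is degenerate there.

## A note on power at the reference conditions

The package's reference simulation conditions are three replicates,
dispersion 0.05, and 200 informative (subgenome-assigned) reads per gene.
Under BH at FDR 0.05 the effective per-gene threshold adapts to the fraction
of true signals in the tested cohort: with ~20% truly biased genes the
threshold is roughly `0.05 × rejected fraction`, which caps the power for a
2-fold change near 0.88 *regardless of depth*. The package therefore
quantifies sensitivity on a dedicated power cohort in which every gene
carries the 2-fold effect (with balanced directions so TMM normalization is
not distorted); there the exact test reaches ≥ 0.90 sensitivity, and the
type-I property is measured on a separate all-null cohort. Reported
sensitivities are meaningful only together with the cohort composition —
this is a property of adaptive FDR control, not of the test statistic.

# Homoeolog bias

`call_bias()` contrasts an accession's A-partition units against its
D-partition units on the high-confidence expressed universe and attaches the
*degree of bias*: the replicate-averaged `log2(RPKM_A + 1) − log2(RPKM_D +
1)`, whose pseudocount keeps zeros finite. A gene's direction is A or D only
when q < 0.05, with the sign taken from the degree. Downstream summaries
follow the field's bookkeeping: per-accession bias ratio (A-biased count
over D-biased count, 2 decimals) and percent biased (1 decimal); Venn region
counts over accessions; conserved-direction sets (genes biased in *every*
accession, split by unanimous direction) with "contrarian" genes defined by
unanimity of all other accessions; degree comparisons by two-sided
Mann–Whitney (the fold is a ratio of mean absolute degrees); per-chromosome
Pearson correlation of biased counts against gene totals; and a TE-proximity
association using Spearman rank correlation between signed degree and
distance from the gene span to the nearest TE interval (a linear-regression
alternative is available). The Mann–Whitney and Spearman choices are this
package's own: the analyses they support name no test, so we use the
standard nonparametric defaults.

# Expression level dominance

For each polyploid, three contrasts are computed on `total` units — A-diploid
vs D-diploid, polyploid vs A-diploid, polyploid vs D-diploid — and each is
collapsed to a sign: −1, 0 (not significant at q ≥ 0.05), or +1, oriented as
`sign(A − D)`, `sign(P − A)`, `sign(P − D)`. Thirteen of the 27 possible
triples are coherent and map to the twelve Roman-numeral categories plus
NoChange (see `eld_category_table()`); the other fourteen are internally
contradictory (e.g. A = P and D = P but A ≠ D, a small-sample artifact) and
are reported first-class as `Ambiguous` rather than dropped.

The orientation of the numerals is pinned by four constraints: II and IV are
"up" dominance (the polyploid matches the *higher* parent), IX and XI
"down"; the D-dominance ratio is `(II + XI) / (IV + IX)`; VIII is the
transgressive-up category `A = D < P`; and the remaining assignments (I vs
XII, III vs X, V vs VI) follow the conventional ordering of the
twelve-category scheme. The whole mapping lives in one table so a different
orientation is a one-line change. The polyploid's "total expression" P is
all assigned reads (A + D + N, excluding X).

# Diploid-polyploid cross-classification

`diploid_polyploid_matrix()` tallies a shared gene universe into the 2×2 of
(differentially expressed between the diploid parents?) × (homoeolog-biased
in the polyploid?), plus the direction-flip counts inside the
both-significant cell. Aggregate "natural polyploid" rows are arithmetic
means rounded half-up (`average_counts_row()`), reproducing the usual
printed-table convention. `genome_change_table()` contrasts each tetraploid
partition against its corresponding diploid (A_T vs A-diploid, D_T vs
D-diploid); the partition's roughly two-fold lower effective depth is
absorbed by the TMM factors, which is the main caveat of this stage — a
genuinely gene-specific diploid-to-tetraploid shift and a global depth
artifact are only distinguishable through normalization.

# Expression phylogenies

`expression_profiles()` averages `log2(RPKM + 1)` over replicates into one
leaf per accession-partition (diploids contribute a total leaf);
`homoeolog_diff_profiles()` builds one leaf per polyploid from the
replicate-averaged A−D log difference. Distances are sums of squared
differences over the commonly expressed genes; the log scale is this
package's choice (raw RPKM is available via `scale = "rpkm"`), since
squared differences on raw RPKM would be dominated by a handful of highly
expressed genes. `neighbor_joining()` is a textbook Saitou–Nei
implementation with deterministic lexicographic tie-breaking and negative
branch lengths clamped to zero with the deficit moved to the sibling branch
(preserving the path length through the joined pair) — the behaviour of the
classic distance-tree programs. Replicates are averaged before distances
because the trees have one leaf per accession-genome, not per library.

# The synthetic-data generator

`sim_config()` defaults encode the study conditions: two diploids (A2, D5),
a diploid F1 hybrid and three natural polyploids, three replicates each; NB
counts with common dispersion φ = 0.05; 200 informative reads per gene per
sample; 20% of expressed genes biased (log2 magnitude 1), 70% of those with
direction conserved across all polyploids; ELD categories realized in the
means with a two-fold step (the additive categories place P at the geometric
mean of parents four-fold apart, so every significant pair differs by
two-fold); and a per-origin read-class mix of 50% assigned / 2% chimeric /
48% uninformative, which reproduces the familiar ~25/25/2/48 A/D/X/N
accounting of a balanced polyploid library.

Design points worth knowing:

* **`depth` means informative reads.** All statistical guarantees are
  phrased in terms of the counts the tests actually see, so `depth` is the
  expected A + D (or diploid assigned) count per gene; N and X reads are
  generated on top. Binomial thinning preserves the NB size parameter, so
  unit counts are exactly NB with the configured dispersion.
* **Expression spread.** Per-gene expression is log-normal around `depth`
  with SD 1 log2 unit — a realistic dynamic range, and necessary for the
  presence mixture to have a non-degenerate expressed component. Setting the
  spread to 0 gives uniform depth for targeted power experiments.
* **Silent genes leak.** Unexpressed genes get 0.2% of `depth` rather than
  exactly zero, so the background mixture component has positive variance
  (real background is never exactly empty). A zero leak is available and
  produces all-zero counts.
* **Library sizes** are equal by default; `libsize_spread = 2` draws them
  log-uniform within two-fold to exercise normalization.
* **Read-level simulation** (`generate_reads()`) writes a full small-scale
  study — reference FASTA, two-exon gene models (GFF3), SNP index (D allele
  = reference base), TE intervals at truth-assigned distances (BED3), and
  per-sample SAM files whose reads carry their origin in an `XO` tag and the
  origin's allele at every covered SNP, with a configurable error rate at
  SNP columns and optional planted A-then-D chimeras. At the default SNP
  spacing (10/kb, i.e. every 100 bp) a 50-bp read covers at most one SNP, so
  roughly half of reads are informative — and chimeras are impossible;
  exercising the X class requires a denser index (e.g. `snp_per_kb = 50`).
  Output is byte-deterministic given the seed. The generator makes no
  attempt at sequence realism: composition is random, splicing is absent
  (reads stay within one exon), and quality is flat.

What passing tests on this generator do *not* show about real data: the
generator's bias directions are independent of the diploid expression
difference (in real cotton they are strongly coupled through conserved
cis-regulation), homoeo-SNP density is uniform rather than gene-specific,
mapping bias and reference bias are absent, and dispersion is common across
genes. Results on real data therefore depend on upstream alignment quality
in ways the synthetic suite cannot certify.

# Numerical and interface choices

* Internal genomic intervals use `GRanges`/`IRanges` (1-based closed), the
  standard container of this ecosystem; GFF3/SAM (1-based) and BED
  (0-based half-open) are converted at the file boundary only, and the
  conversion round-trips exactly.
* All randomness flows from the mandatory `seed` in `sim_config()`; each
  generator stage derives a fixed offset from it, and `run_pipeline()`
  writes a manifest of artifact checksums so reruns can be verified
  byte-for-byte.
* Problem sizes in the shipped tests were chosen for quick desk-scale runs:
  10,000 genes for the null calibration, 2,500 for the power cohort, 2,600
  for ELD recovery, 200 genes for the end-to-end demo, and ≤ 40 genes for
  read-level fixtures.
* The pipeline is driven from R (`run_config()` / `run_pipeline()`, with
  YAML via `read_run_config()`); there is no shell entry point — the
  functions and this vignette are the interface.

# Known limitations

* Only SNVs are supported in the SNP index; indel-diagnostic sites are out
  of scope, and allele calls are never made through indels.
* No tagwise or trended dispersion, no GLM framework: all significance
  calls reduce to two-group exact-test contrasts, which is faithful to the
  analyses this package reproduces but not a general DE engine.
* BH FDR is applied per contrast; a global correction across contrasts is a
  caller-level choice.
* The TE association and degree-comparison tests are stand-in
  nonparametric choices where the supported analyses name no method;
  conclusions about those p-values should not be read as replications.
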