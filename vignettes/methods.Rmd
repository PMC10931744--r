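---
title: "Methods: trio Hi-C and transcriptome integration for heterosis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio Hi-C and transcriptome integration for heterosis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hictrio)
```

# Scope and data model

`hictrio` analyses a parent/parent/hybrid (P1, P2, F1) trio for which each
sample has a genome-wide Hi-C contact matrix at a fixed bin resolution and a
replicated FPKM expression table. The question it addresses is how much of
the hybrid's expression change — and ultimately its heterosis — coincides
with changes in chromatin architecture: A/B compartment shifts and
topologically associating domain (TAD) reorganization.

All matrix-derived tracks live on a shared `BinTable` of fixed-resolution,
0-based, half-open genomic bins (`make_bins()`). Contact matrices are dense
symmetric count matrices coupled to their bin table; at the chromosome and
bin counts this package targets (a few hundred bins per chromosome), dense
storage is simpler and fast enough that a sparse backend would buy nothing.
Sparse triplet TSV plus a BED4 bin table is the on-disk interchange format.

# Matrix normalization

Raw matrices are standardized by iterative correction (`balance_matrix()`):
each round divides the matrix by the outer product of its row sums scaled
to mean one, iterating until all active row sums agree to a relative
tolerance of `1e-5` (at most 200 rounds, with a warning and the best
iterate on non-convergence). This is the standard matrix-balancing
normalization for Hi-C, which removes multiplicative per-bin biases under
the assumption of equal visibility. Bins with a zero raw marginal cannot be
corrected and are masked — excluded from the iteration and from every
downstream statistic — rather than imputed.

Cis/trans contact summaries (`contact_summary()`) are computed on **raw**
counts, each unordered pair counted once and diagonal counts contributing
once to the cis total. Normalization equalizes marginals and would distort
the trans/cis proportion, so the raw matrix is the right substrate for it.

# A/B compartment calling

Compartments are called per chromosome at 100 kb (`call_compartments()`):

1. The balanced cis block is converted to an observed/expected (O/E)
   matrix, dividing each entry by the mean of its diagonal
   (`expected_by_distance()`). This removes the distance-decay trend that
   would otherwise dominate the leading eigenvector.
2. The Pearson correlation matrix of the O/E profiles is computed over
   usable bins, and its leading eigenvector is the compartment score
   (`pc1`). Bins with no O/E variance are masked; a chromosome with fewer
   than 10 usable bins, or a degenerate (constant) correlation matrix, is
   fully masked with a warning rather than assigned arbitrary labels.
3. The eigenvector sign is arbitrary, so each chromosome is oriented by
   gene density: the positive (A) side must have the higher mean gene
   count per bin, reflecting that A compartments are gene-dense, active
   chromatin. An exact tie keeps the native sign and warns. Orientation is
   deterministic given the annotation, and idempotent.

Bins are labelled `A` when `pc1 > 0` and `B` otherwise. Genes are placed
into bins by midpoint; a midpoint exactly on a bin boundary goes to the
lower (left) bin, a convention applied uniformly everywhere genes meet
bins.

## Trio shift classification

`classify_shifts()` combines three tracks on an identical bin table into
per-bin trio states. State strings read **P1 → F1 → P2** (the hybrid in
the middle); this ordering is a package convention, fixed and documented
because three-letter shift notation is inherently ambiguous about sample
order. Percentages are computed over bins unmasked in all three samples
and reported to 2 decimal places; the unrounded eight-state vector always
sums to 100%.

Aggregates separate three biologically distinct situations: *unchanged*
bins (all three samples agree), *split-parent gains* (the parents disagree
and F1 resolves to one label), and *full flips* (both parents agree and F1
takes the opposite label — rare in stable genomes). The hybrid's net A
gain can be read either as the split-parent component alone or including
full flips; both are reported (`a_gain_split`, `a_gain_total`).

# TAD calling and comparison

TADs are called at 40 kb from the directionality index (DI), the classical
per-bin statistic contrasting upstream (`A`) and downstream (`B`) contact
sums within a window: with `E = (A+B)/2`,

`DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`

and `DI = 0` when `A == B` or `E == 0`. Bins whose window is cut by a
chromosome end use the truncated window and carry a flag.

The boundary caller (`call_tads()`) smooths the DI track with a 3-bin
running mean and places a boundary wherever a sustained-negative run
(length ≥ 3 bins) is followed by a sustained-positive run (length ≥ 3
bins). Two numerical details matter in practice and were added after
planted-structure validation: short flicker runs (below the persistence
length) between the two flanks are tolerated, since Poisson noise readily
breaks a genuine sign change into fragments; and the boundary is snapped
from the smoothed track back to the raw-DI sign change, because a centered
running mean lags the true transition by up to half its window. Domains
shorter than 5 bins are dropped. The caller is deterministic for fixed
parameters and invariant to positive scaling of the matrix.

**Choosing the DI window.** The window should be on the order of the
typical domain size: much larger windows average over several domains and
wash out small-domain boundaries. The function default (2 Mb) matches the
classical setting used for mammalian genomes with ~1 Mb TADs. The
synthetic genomes in this package plant 0.5–1 Mb domains (and hybrid
domains half that), so all synthetic-data analyses here use a 600 kb
window; planted-boundary recovery degrades substantially by 2 Mb on these
fixtures. The parameter is exposed everywhere.

`compare_tads()` marks a domain conserved when the other sample has a
domain with both boundaries within 1 bin (±40 kb), else specific; the
check is symmetric and brute-force verifiable. `boundary_specificity()`
correlates the two samples' DI tracks over ±12 bins (±480 kb) around each
boundary and calls the boundary shared at Pearson r ≥ 0.75; boundaries
whose window leaves the chromosome are excluded, and zero-variance windows
are flagged unclassifiable rather than silently dropped.

## Activated and repressed TADs

Conserved TADs containing at least one gene with a fold change are ranked
by the mean log2 fold change of their member genes, computed **parent
relative to F1** (F1 as the reference). The top 10% are *activated*, the
bottom 10% *repressed*, the remainder *other*; both tails take exactly
`floor(0.10 × n)` domains, ties broken by genomic order so the partition
is deterministic. With fewer than 10 rankable domains the tails would be
empty or unstable, so everything is classed *other* with a warning. The
fraction of member genes with fold change > 1 (`fc_fraction`) is reported
alongside for stacked-proportion summaries.

# Expression-side statistics

* **Active genes**: replicate-mean FPKM ≥ 1, boundary inclusive. The mean
  (rather than an any-replicate rule) is used because three-replicate
  means are the unit of every other expression comparison in the package.
* **Specifically expressed genes (SEGs)**: active in one sample and in
  neither of the other two; pairwise common/specific counts accompany the
  per-sample sets.
* **Sample correlation**: squared Pearson correlation of
  `log2(FPKM + 1)`, for all replicate pairs and for sample-level means.
* **DEG flag**: `padj < 0.05` and `|log2FC| > 1`, strict inequality on the
  fold-change boundary. The adjusted p-value (Benjamini–Hochberg FDR) is
  used as the significance criterion.
* **Trio categories**: genes that are DEGs in both F1-vs-parent contrasts
  are classed `Up` (F1 mean above both parents), `Down` (below both) or
  `B2P` (strictly between the parent means — the hybrid resolving between
  two diverged parental levels). Equal parent means leave no "between", so
  such genes fall to Up or Down by comparison with the common value. The
  three classes partition the trio set by construction.
* **Heterosis**: `MPH = 100 × (F1 − MP) / MP` with MP the mid-parent
  (average of the two parent means) and `HPH = 100 × (F1 − BP) / BP` with
  BP the better (larger) parent mean. Both are invariant under positive
  rescaling of the trait.
* **`simple_de_test()`** is a per-gene Welch t-test on `log2(FPKM + 1)`
  with BH adjustment, provided so synthetic data can flow end to end. It
  is *not* a substitute analysis for real experiments, where a
  count-based differential-expression table should be supplied as input.

# Integration into candidate genes

Two evidence tracks feed the candidate list. From compartments: DEGs
(F1 vs parent) whose midpoint bin shifted A↔B between that parent and F1;
a candidate is concordant when B-to-A comes with up-regulation in F1 and
A-to-B with down-regulation. From TADs: DEGs (parent vs F1) inside
activated or repressed conserved domains; concordance follows the ranking
convention — a repressed domain should hold genes down-regulated in the
parent relative to F1. Discordant genes are retained and flagged, since
discordance is itself informative about trans-acting regulation. DEGs in
"other" domains are not candidates. `final_candidates()` merges the
tracks, marking genes present in both with `source = "both"`, and its
set algebra (compartment-only + TAD-only + both = total) is brute-force
verifiable.

# The synthetic trio generator

`simulate_trio()` generates the full input bundle with recorded truth.
Cis contact intensity is
`base × (1 + d)^(-α) × compartment factor × TAD factor`, with a
multiplicative boost for bin pairs sharing a planted compartment label
(checkerboard blocks) or a planted TAD; trans intensity is uniform.
Counts are Poisson — the simplest noise model that exercises every
pipeline stage; real Hi-C is overdispersed, so recovery rates here bound
what matters for the method's logic, not what a sequencing experiment
would achieve.

Structural scales are genomic, not bin-denominated: compartment blocks
default to 2 Mb and TAD sizes to 0.5–1 Mb regardless of resolution,
because real compartment blocks do not shrink when one re-bins the same
genome more finely. Genes are placed with 3× density in A bins, and each
gene's FPKM is lognormal with a 6× boost when its bin is labelled A *in
that sample* — so planted compartment shifts automatically produce
concordant expression changes, and explicitly planted DEG effects
(default: 25 up and 15 down in F1 at |log2FC| = 2.5, 20 parental DEGs)
sit in unshifted bins to keep the two signals separable.

The default study conditions are 2 chromosomes × 200 bins at 100 kb with
compartment contrast 2.0 and decay exponent 1.0 for compartment analyses,
and 2 × 300 bins at 40 kb for TAD analyses; the paper-like preset
(`make_paper_like_trio()`) additionally boosts the hybrid's trans weight
(0.016 vs 0.01), splits half of the larger parental TADs in F1, and plants
a net B-to-A gain (~11% of bins shifted, ~89% stable). Phenotype means
are fixed so that the true fresh-weight heterosis is MPH 159.28% / HPH
150.11%, with 3% replicate CV. A fixed seed makes the bundle
byte-identical.

What the generator does **not** emulate: negative-binomial overdispersion,
restriction-fragment and mappability bias (so balancing is exercised but
not stressed), hierarchical/nested TADs, loops, allele-specific contacts
in the hybrid, and length-dependent FPKM effects. Passing recovery tests
therefore validates the pipeline's correctness and calibration on clean
planted structure, not its robustness to every artefact of real libraries.

# Numerical conventions and degenerate inputs

* Duplicate (i,j)/(j,i) triplet rows are rejected on read; unlisted pairs
  are zero.
* Masked bins propagate: they carry no compartment label, no DI value,
  and are excluded from percentages and correlations.
* All-zero diagonals get `expected = 0` and a flag; O/E entries with zero
  expected are `NA`.
* A Wilcoxon comparison where every value is tied reports p = 1.
* Ranking ties (TAD activity) break by genomic order; orientation ties
  (gene density) keep the PCA's native sign with a warning.
* Percentages are reported to 2 decimal places; sums are exact before
  rounding.

# Known limitations

The DI caller produces flat, non-hierarchical domains; nested structure
present in real data will be reported at whichever scale the window
emphasizes. Compartment calling uses PC1 only — chromosomes where the
leading eigenvector captures something other than compartments (e.g.
arm-level structure) are not rescued by a PC2 fallback and should be
inspected via the returned scores. The candidate-gene step inherits every
upstream threshold; its counts are bookkeeping over those calls, not a
statistical test of association.
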