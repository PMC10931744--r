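# hictrio

Integrative trio Hi-C × transcriptome analysis of hybrid heterosis.

Hybrid crops often outperform both parents (heterosis), and part of that
advantage appears to travel with reorganization of the three-dimensional
genome: shifts between active (A) and repressive (B) chromatin compartments
and rearrangement of topologically associating domains (TADs) in the hybrid.
`hictrio` implements, as a tested and reusable R pipeline, the joint
analysis of a parent/parent/hybrid (P1, P2, F1) trio for which each sample
has a genome-wide Hi-C contact matrix and a replicated RNA-seq FPKM table.
It is written for researchers doing 3D-genome work in plants (or any
diploid trio design) who want every stage of such an analysis — from matrix
balancing to the final candidate-gene list — scriptable, inspectable and
verifiable against planted ground truth.

## What it computes

* **Contact matrices** (`read_contact_matrix`, `balance_matrix`,
  `expected_by_distance`, `contact_summary`): sparse-triplet I/O, iterative
  correction (ICE-style row-marginal equalization), per-distance expected
  models, and raw cis/trans contact totals with the trans/cis ratio.
* **A/B compartments** (`call_compartments`, `classify_shifts`,
  `compartment_expression_contrast`): per chromosome, PC1 of the Pearson
  correlation of the observed/expected matrix at 100 kb, sign-oriented so
  compartment A is the gene-dense side; per-bin trio states
  (read P1 → F1 → P2) with eight-state percentages and A/B-gain
  aggregates; A-vs-B expression contrast with a rank-sum test.
* **TADs** (`directionality_index`, `call_tads`, `compare_tads`,
  `classify_tad_activity`, `boundary_specificity`, `tad_length_stats`):
  the classical directionality index
  `DI = sign(B−A)·((A−E)²/E + (B−E)²/E)`, `E = (A+B)/2`, over a
  configurable window at 40 kb; boundaries at sustained sign changes;
  conserved vs specific domains (boundaries within ±1 bin); activated /
  repressed / other classes as the top and bottom 10% of conserved domains
  ranked by mean log2 fold change (parent relative to F1); boundary
  sharing by DI-window correlation.
* **Expression & heterosis** (`active_genes`, `specific_genes`,
  `sample_correlation`, `classify_trio_degs`, `heterosis_stats`,
  `simple_de_test`): active genes (mean FPKM ≥ 1), sample-specific genes,
  replicate correlation (R²), trio DEG categories Up / Down / B2P
  (hybrid above both parents, below both, or strictly between), and
  mid-parent / high-parent heterosis
  `MPH = (F1 − MP)/MP × 100%`, `HPH = (F1 − BP)/BP × 100%`.
* **Integration** (`integrate_shifts`, `integrate_tads`,
  `final_candidates`): DEGs intersected with compartment shifts and TAD
  activity classes, each candidate flagged concordant when its expression
  direction matches the structural change (B-to-A ↔ up in F1, repressed
  TAD ↔ parent down vs F1), merged into a deduplicated candidate list.
* **Synthetic trios** (`sim_config`, `simulate_trio`,
  `make_paper_like_trio`, `write_sim_bundle`): Poisson contact matrices
  with planted distance decay, compartment checkerboard, TAD blocks and
  trio differences, plus compartment-coupled expression and phenotypes —
  with all truth recorded, so every stage has a ground-truth recovery test.

## Worked example

```r
library(hictrio)

sim <- make_paper_like_trio(seed = 1)   # hybrid-like synthetic trio, 100 kb

# 1. contact structure: the hybrid has relatively more trans contact
sapply(sim$matrices, function(m) contact_summary(m)$trans_cis_ratio)
#>     P1     P2     F1
#> 0.0869 0.0872 0.1400

# 2. compartments and trio shift states
bal    <- lapply(sim$matrices, balance_matrix)
tracks <- lapply(names(bal), function(s)
  call_compartments(bal[[s]], sim$genes, sample = s))
names(tracks) <- names(bal)
sh <- classify_shifts(tracks)
round(sh$aggregates, 2)
#>    unchanged a_gain_split b_gain_split       a_flip       b_flip
#>           89            6            2            3            0
#> a_gain_total b_gain_total
#>            9            2

# 3. candidate genes: DEGs sitting in P1->F1 compartment shifts
deg  <- simple_de_test(sim$expr, "F1", "P1")
sg   <- shift_gene_lists(sh, sim$genes, parent = "P1")
cand <- integrate_shifts(deg, sg, contrast = "F1_vs_P1")
table(shift = cand$structure_change, concordant = cand$concordant)
#>         concordant
#> shift    TRUE
#>   A-to-B    9
#>   B-to-A   13

# 4. heterosis of the simulated biomass phenotypes
heterosis_stats(sim$pheno)
#>          trait mph_percent hph_percent
#> 1 fresh_weight   153.06602   141.48402
#> 2   dry_weight    83.59738    77.79519
```

Reading the output: 89% of bins keep the same compartment in all three
samples; the hybrid gains A-compartment in 9% of bins (6% where the
parents disagreed, 3% full B→B→A flips) and loses it in 2%. All 22 DEGs
found inside P1→F1 shift bins change expression in the direction their
shift predicts (B-to-A genes up in F1, A-to-B genes down), and the
simulated hybrid shows strong biomass heterosis (fresh-weight mean 153%
above mid-parent for this seed).

The methods vignette (`vignettes/methods.Rmd`) documents the models,
parameter choices, numerical conventions and the generator's scope.

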