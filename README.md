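# orthoconserv

Cross-species conservation of tissue-level gene expression, measured
from gene-level TPM matrices and ortholog tables.

## The problem

During the mid-embryonic (phylotypic) period, some structures — the
notochord above all — are hypothesized to carry a *developmental
burden*: later development depends on their inductive signals, so their
transcriptomes should diverge more slowly between species. Testing this
requires comparing tissue transcriptomes across species (e.g. an avian
and a reptilian embryo) at three levels:

1. **Profile divergence** per structure: `d = 1 − ρ`, where `ρ` is the
   Spearman rank correlation of the two species' TPM vectors over
   expressed 1:1 orthologs (or orthoMCL-style ortholog groups, summing
   member TPM to absorb duplications and losses). Structures are
   compared against a reference structure with a two-tailed Dunnett
   many-to-one test over replicate pairs.
2. **Twofold conservation** per ortholog: with pseudocount `c`,
   `r = log2((a + c)/(b + c))`; conserved ⇔ `|r| ≤ log2 F` (default
   `F = 2`, boundary inclusive). A focal gene is tested against the
   genomic background by an exact two-sided Wilcoxon rank-sum over the
   nine cross-species replicate pairs; a gene set by a Student's t test
   on the per-pair within-twofold fractions (set vs background, n = 9).
3. **Structure-specific conservation**: genes conserved in all three
   structures, minus genes also within-twofold in a late-stage
   whole-embryo comparison (constitutive/housekeeping signal), tested
   for GO-term enrichment by two-sided Fisher's exact tests with Holm
   correction and fold enrichment `(k/n)/(K/N)`, keeping terms
   significant at both anterior and posterior axial levels.

A seeded synthetic-data generator (`simulate_dataset()`) emulates the
full sampling design — two species × three tissues × two axial levels ×
three replicates, plus late whole-embryo samples — with planted
conservation signal, so every stage is testable end to end without any
external download. See the vignette
(`vignettes/cross-species-conservation.Rmd`) for the model, parameter
and calibration details.

## Worked example

```r
library(orthoconserv)

sim <- simulate_dataset(sim_config(seed = 1))   # reference design, 12,000 genes
res <- analyze_dataset(sim, analysis_params())

res$distance_summary
#>        tissue  ap_level n mean_distance sd_distance
#>    notochord  posterior 3     0.188     ...
#>  neural_tube  posterior 3     0.238     ...
#>      somites  posterior 3     0.348     ...
```

The notochord shows the smallest expression distance, and the Dunnett
contrasts against it are strongly significant (adjusted p ≈ 4e-9 for
the neural tube, 3e-12 for the somites, posterior level). The planted
conserved gene set sits at a within-twofold fraction of 0.97 versus
0.73 for the genomic background (a 1.34× ratio; paired t, n = 9,
p ≈ 6e-13), and the planted late-divergent term is recovered by the
enrichment stage with ~3.7× fold enrichment at both axial levels
(Holm-adjusted p ≈ 7e-22):

```r
res$consistent_terms
#>      term_id term_name fold_anterior fold_posterior p_holm_anterior p_holm_posterior
#> 1 GO:0005814 centriole          3.70           3.71         ...e-22          ...e-22
```

The numbered scripts under `analysis/` run the same stages one at a
time against TSV files (`01_simulate.R` … `05_enrichment.R`), writing
their tables under `results/`; `run_pipeline()` does the whole thing in
one call and writes a manifest with input checksums.

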