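# TMEnet

Contamination-adjusted expression and signalling networks of the tumour
microenvironment.

## The problem

Sorted cell populations from high-grade serous ovarian carcinoma (HGSC)
lesions — tumour cells (TU), tumour-associated macrophages (TAM) and T cells
(TAT) from ascites and omentum, and the omental stroma (adipocytes ADI,
mesothelial cells MESO, fibroblasts CAF) — are never perfectly pure. A few
percent of a highly expressing contaminant is enough to create
false-positive "expression" of its signature genes in the sorted population,
which corrupts any downstream claim about which cell type produces which
cytokine or growth factor. TMEnet implements, as a tested and reusable R
package, the computational workflow for this setting:

1. **Marker-based contamination estimation.** For each (target,
   contaminant) pair, the 25 genes with the largest median fold change
   (contaminant over target, strict > 50-fold, computed with a symmetric
   0.001 offset so zero medians stay rankable) and median > 10 TPM in the
   contaminant form a contamination marker set. For marker gene *g*,

   ```
   pct_g = (TPM_sample,g − TPM_target-ref,g) / TPM_contaminant-ref,g × 100
   ```

   and the median of the 25 values estimates the contaminating percentage.
   Reference samples are the least-contaminated sample of each type.

2. **Sample exclusion.** TU/TAM/TAT samples with ≥ 4 % and ADI samples with
   ≥ 6 % estimated contamination by any cell type are excluded; MESO and
   CAF carry no threshold by default.

3. **Linear unmixing.** Kept samples are adjusted iteratively per
   contaminant, `(TPM − frac × TPM_contaminant) / (1 − frac)`, with the
   contaminant profile taken as the cohort median (or the patient-matched
   sample), negatives clamped to 0, and the matrix renormalised so every
   sample again sums to 10^6 (TPM).

4. **Downstream calls** on the adjusted matrix: expressed = median TPM > 2
   per cell type; cell-type/compartment selectivity at strict FC > 5
   against the best median outside the group; ligand→receptor target
   scores (per-receptor max-normalisation across cell types, summed over a
   ligand's receptor set, ligand-wise max-normalised to [0,1]);
   a metastasis signalling network gated on receptor median TPM > 2;
   patient-matched omentum-vs-ascites differential expression (paired
   t-test on log2(TPM+1), called at FC > 3, TPM > 3, nominal p < .05, BH
   q-values reported); secretome calls from timepoint LFQ proteomics and
   RNA–protein concordance; and a dual-significance survival filter
   (RFS p < .05 and |OS z| > 1.96) over a published 32-gene table shipped
   in `inst/extdata/`.

A fully seeded synthetic-data module generates cohorts with known ground
truth (planted markers, known mixing fractions, planted fold changes,
planted ligand→target structure, logistic protein detection), so the entire
pipeline is testable end to end without any data download.

## Worked example

```r
library(TMEnet)

cfg  <- simulationConfig(seed = 7)         # study-scale defaults
dir  <- tempfile()
pcfg <- simulateStudy(cfg, dir)            # writes matrix/meta/LR-map/LFQ TSVs
runPipeline(pcfg)                          # load -> adjust -> calls -> report
str(pipelineReport(file.path(dir, "run")))
```

Output from this exact run:

```
List of 11
 $ excluded_samples    : chr "TU_om_P04"
 $ selectivity_counts  :List of 7
  ..$ expressed  : int 12
  ..$ tumour     : int 2
  ..$ host       : int 10
  ...
 $ de_called           : int 0
 $ de_pairs            : int 3
 $ matched_spearman    : num 0.98
 $ secretome_size      : int 161
 $ rna_protein_spearman: num 0.874
 $ survival_kept       : int 32
 $ survival_short      : int 31
```

Reading: the one tumour sample simulated with 8 % macrophage contamination
was excluded at the 4 % threshold; all 12 planted ligands are recovered as
expressed with 2 tumour-selective (the two planted on TU producers); the
three surviving matched tumour pairs correlate at ρ = 0.98 with no planted
fold changes called; and the 32-gene survival table passes the dual filter
with 31 short-survival labels.

## Command line

A thin wrapper over the same functions ships in
`inst/scripts/netkit.R` (`simulate`, `run`, `report` subcommands); the R
functions are the primary interface.
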