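---
title: "TMEnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMEnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

TMEnet analyses TPM matrices of sorted cell populations from the ovarian
cancer tumour microenvironment: tumour cells (TU), macrophages (TAM), T
cells (TAT) from ascites and omentum, and omental stroma (ADI, MESO, CAF).
This vignette explains the models behind each step, the parameters that
matter, the numerical choices, and what the synthetic-data validation does
and does not establish.

## The data model

The central object is a `TpmExperiment`, a `SummarizedExperiment` whose
single `tpm` assay holds non-negative, finite TPM values with unique gene
symbols and sample identifiers, and whose `colData` records cell type,
compartment, patient and an optional pinned reference flag. The TPM
contract is that every sample column sums to 10^6; `renormalizeTpm()`
restores it after any row subset or adjustment and is idempotent. Gene
identity is the case-sensitive symbol string — no alias resolution is
attempted, because every annotation the workflow consumes (marker sets,
ligand–receptor tables, survival statistics) is symbol-keyed.

Before analysis, genes on the default exclusion list are removed and the
matrix renormalised: mitochondrial (`MT-*`), mitochondrial-ribosomal
(`MRPL*`/`MRPS*`), cytosolic ribosomal (`RPL*`/`RPS*`), non-coding
(`MIR*`/`LINC*`) families, a fixed set of genes known to quantify
discordantly between total-RNA and poly(A) library protocols, and histone
genes. Histones are included because their quantification is strongly
library-protocol dependent; users comparing within a single protocol can
supply their own list without them.

## Contamination model

A sorted sample is modelled as a convex mixture on the TPM simplex,

$$ s = \Big(1 - \sum_c f_c\Big)\, t + \sum_c f_c\, p_c , $$

with pure target profile $t$, contaminant profiles $p_c$ and fractions
$f_c \in [0, 1)$. Because TPM is within-sample normalised, a fraction $f$
of contaminating *RNA* — not of cells — is what the model sees; cell types
with more RNA per cell contribute proportionally more.

**Marker sets.** For each (target, contaminant) pair, candidate markers
need a median fold change (contaminant over target) strictly above 50 and
a contaminant median strictly above 10 TPM. Fold changes use a symmetric
additive offset of 0.001 on both medians: the offset's only published role
is avoiding division by zero, and applying it to both terms keeps ranking
stable when both medians are small. Candidates are ranked by fold change,
ties broken by gene symbol (a total order, so repeated runs are
byte-identical), and the top 25 kept.

**Estimation.** Per marker $g$,
$\mathrm{pct}_g = 100\,(s_g - t^{ref}_g)/p^{ref}_{c,g}$, where the
reference columns are the least-contaminated sample of each type
(minimal summed contaminating-marker TPM; a pinned `is_reference` flag
overrides). Each $\mathrm{pct}_g$ is clamped to $[0, 100]$ *before* the
median: with measurement noise, unclamped negative values would bias the
median downward. The estimate is the clamped median, floored at the
configurable assumed minimum contamination (default 0, because the
workflow's published floors are not printed as numbers; users replicating
a specific study must set them).

The estimator is exact on noise-free mixtures when markers are silent in
the target ($t^{ref}_g = 0$). When markers are merely *low* in the target,
$\mathrm{pct}_g = f\,(1 - t_g/p_{c,g})$, a deterministic downward bias of
order $f/\mathrm{FC}$ — about 2 % relative at the 50-fold selection
threshold. This is documented rather than corrected: correcting would
require trusting the target reference more than the workflow does.
A related practical point: the > 50-fold criterion compares *medians*, so
marker discovery should run on data where most samples of each type are
clean; if the majority of target samples carry the contaminant, the target
median is inflated and genuine markers fail the criterion.

**Exclusion.** A sample is excluded when any single contaminant's estimate
reaches its cell type's threshold: 4 % for TU/TAM/TAT, 6 % for ADI, none
for MESO/CAF. The comparison is `>=` (4.0 % exactly is out).

**Adjustment.** Kept samples are unmixed iteratively per contaminant,
$s \leftarrow (s - f_c\,p_c)/(1 - f_c)$, contaminant profiles taken as the
cohort median over kept samples of that type, or the patient-matched
sample when configured and available. The default removal order is
descending estimated fraction; order matters only through second-order
$f_i f_j$ cross terms, and single-contaminant mixtures invert exactly.
Negative corrected values are clamped to zero once, after all contaminants
are removed, and the matrix is renormalised once at the end — clamping
inside the loop would couple the contaminant order to the clamping
artefacts. The reference sample itself is adjusted like any other kept
sample; treating it as contamination-free would privilege one sample's
noise.

## Selectivity and the ligand–receptor network

Expression calls and selectivity work on per-cell-type medians (medians,
not means, throughout — consistent with the estimator and robust to single
outlier samples). For cell types present in both compartments, omentum
samples are preferred and ascites used as fallback; the preference is an
argument (`preferCompartment`) because the right choice depends on the
question asked.

A gene is *expressed* in a cell type when the median is strictly above
2 TPM. A gene is *selective* for a group (tumour; stroma/immune within
host) when the group's best median exceeds 5-fold the best median outside
the group. The baseline "max of medians outside the group" is the
strictest reading of a fold-change cut against all other cell types —
a mean-of-others baseline would let one silent cell type carry a gene to
selectivity. Within a selective group, member cell types are those whose
own median beats 5-fold the outside baseline, which yields the Venn-style
shared/single-type accounting and guarantees the partition counts sum to
the number of expressed genes.

Receptor target scores compress a ligand's receptor repertoire into one
row per ligand: (i) each receptor's median TPM is divided by its maximum
across cell types (making the score invariant to uniform rescaling of any
receptor, hence to gene-specific efficiency factors), (ii) the normalised
values are summed over the ligand's receptors, (iii) the sums are divided
by the ligand's maximum, so the top-receiving cell type scores 1. The
step-(iii) normalisation is ligand-wise max scaling; receptors absent from
the matrix are dropped with a warning, and a ligand with no expressed
receptor gets a zero row rather than an error. WNT-family ligands bind
receptor complexes with shared co-receptors, so their scores should be
read with caution; this is an annotation concern, not a computational one.

Network edges (producer cell type → ligand → target cell type) are emitted
for metastasis-flagged ligands only, require the target to express at
least one cognate receptor at median strictly above 2 TPM, and use the
ligand's selective cell types as producers (expressing cell types when the
ligand is not selective for anything).

## Matched differential expression

The paired test operates on $\log_2(\mathrm{TPM} + 1)$: the offset-1 log
stabilises multiplicative noise and matches the fold-change framing of the
calling rule; it is configurable. Per gene, a two-sided paired t-test
across patients (computed vectorised; equivalence with
`stats::t.test(paired = TRUE)` is asserted in the test suite), a
median-based fold change with additive offset 0.1 guarding zero medians,
and the call: fold change strictly above 3 in either direction, the larger
condition median strictly above 3 TPM, nominal p below .05. The nominal p
— not the BH q — drives the call, exactly as the workflow defines it;
q-values are reported alongside for transparency. Zero-variance genes get
p = 1 and a flag instead of NaN. The TPM > 3 filter applies to the larger
of the two condition medians ("either condition"); requiring both would
silently drop genes switched fully off in one compartment, which are the
most interesting calls. Profile-level correlation between conditions is
computed on median profiles over genes with median > 0 in either
condition, not as an average of per-pair correlations: the quantity of
interest is how similar the two compartment *profiles* are.

The survival filter keeps genes with RFS p < .05 and |OS z| > 1.96 and
labels direction from the agreement of hazard ratio and z sign. It is a
pure table filter over externally computed statistics; the packaged
32-gene table ships as data, and the package deliberately does not query
survival databases.

## Secretome concordance

Secretion signals are late-minus-baseline differences of LFQ values on a
single declared (log) scale; a missing baseline is treated as 0
(non-detection), configurable to dropping the pair. A protein is "in
secretome" when a peptide was detected anywhere and the late median
strictly exceeds the baseline median — a rank-based rule invariant under
any strictly increasing transform of all LFQ values. Detection rates are
binned by median TPM with empty bins reported as missing, and RNA–protein
concordance uses Spearman rank correlation over in-secretome proteins
(ties by average ranks; fewer than 3 points is an error).

## The synthetic-data generator

Every generator is a pure function of its configuration and mandatory
seed. The defaults emulate the study conditions the workflow targets: six
cell types; log-normal baseline expression (meanlog log 20, sdlog 1); 30
planted marker genes per type at 100-fold enrichment with baselines around
50 TPM (so contamination-marker criteria hold by construction); 12
strictly type-exclusive genes per type (zero off the owner — ideal
estimation markers and the carriers of the planted ligand→receptor
structure); multiplicative log-normal noise of σ = 0.2 on the natural-log
scale, consistent with replicate scatter of sorted-population RNA-Seq;
mixing on the TPM simplex followed by noise and renormalisation; six
matched patient pairs sharing a per-patient log-normal factor (σ = 0.5)
with residual noise σ = 0.3 and planted 8-fold shifts; and an LFQ model
lfq = log10(TPM + 1) + 3 (+ noise) with logistic detection in log10 TPM
(midpoint 10 TPM, slope 2).

What the generator does *not* emulate: count-level (Poisson) noise and
library-size effects below the TPM summary, gene-length/GC bias,
correlated gene modules, compositional competition between many
simultaneously changing genes, batch effects, and partial or doublet
contamination profiles. Passing tests therefore establish that the
implementation computes the intended quantities and that the estimators
behave as designed under the stated noise model — not that the thresholds
are optimal for any particular real cohort.

Problem sizes used by the test suite and the acceptance script — 500–3000
genes, 3–5 samples per type, 1000 genes × 6 pairs for calibration, 1000
estimator replicates per fraction — were chosen so every statistical check
has comfortable resolution while a full run stays in the tens of seconds.

## Numerical and degenerate-input conventions

* Renormalisation of an all-zero sample is an error naming the sample.
* Excluding every gene is an error; an empty exclusion list is a no-op on
  a normalised matrix.
* Marker selection returning nothing is a warning plus an empty set, not
  an error; estimation with an empty set is an error.
* A zero contaminant-reference value drops that marker with a warning;
  all markers dropped is an error.
* All published thresholds are strict inequalities exactly as printed
  (TPM > 2, FC > 5, FC > 3, TPM > 3, > 50-fold, > 10 TPM), while the
  exclusion rule is ≥ (4 %/6 %).
* Ranking ties break by gene symbol; reference-sample ties by sample
  identifier; contaminant-removal order by descending fraction then name.
  Every ordering is total, so reruns are byte-identical and the pipeline
  manifest hashes reproduce.

## Known limitations

* Iterative unmixing with fractions expressed relative to the whole
  sample leaves second-order residue for multi-contaminant samples; exact
  joint unmixing would require solving the full linear system, which the
  workflow intentionally does not do.
* The estimator's $f(1 - t/p)$ bias (above) means estimates from
  non-silent markers are conservative.
* Selectivity and network calls inherit any residual contamination left
  by imperfect estimates: small post-adjustment receptor residues can
  cross the 2-TPM edge threshold in heavily contaminated cohorts.
* The workflow assumes sorted populations with minor cross-contamination;
  it is not a deconvolution method for unsorted bulk.
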