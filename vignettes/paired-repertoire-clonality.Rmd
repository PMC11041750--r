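---
title: "Methods: clonality analysis of paired-tissue TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality analysis of paired-tissue TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpair)
```

## The model

`tcrpair` analyses matched blood/tissue single-cell TCR repertoires from
the same patients. The unit of analysis is the **clonotype**, defined
purely by CDR3 amino-acid identity: for each cell, the productive TRA and
TRB CDR3 sequences are collected, deduplicated within each chain, sorted,
and joined into a canonical key (TRA side, `|`, TRB side; `;` between
sequences of one chain; an empty side renders as `NA`). This makes the key
invariant to contig row order and robust to dual-TRA cells, and it
deliberately excludes V/J gene calls and nucleotide sequences: two clones
with identical CDR3 amino acids are treated as one, which is the right
resolution when the question is antigen-driven expansion. Gamma/delta
chains never enter the alpha/beta key.

The **clonotype abundance** of clone $c$ in tissue $t$ of patient $p$ is

$$f(c, t, p) = 100 \cdot \frac{n(c,t,p)}{N(t,p)},$$

with $N(t,p)$ the number of cells in which any TCR was detected in that
tissue of that patient. Denominators are always per patient and per
tissue: clonotypes are never pooled across patients, because CDR3 sharing
between individuals cannot be assumed for a matched design.

**Expansion levels** are assigned per tissue from $f$: Single (exactly one
occurrence), Small ($f \le 0.1$), Medium ($0.1 < f \le 1$), Large
($1 < f \le 10$), Hyperexpanded ($f > 10$), all boundaries inclusive on
the upper edge. A clone of one cell is Single even when $1/N$ exceeds
0.1% — occurrence takes precedence over frequency, which matters in small
repertoires. The same classifier is reused verbatim for bulk TCRβ clone
tables, with template counts in place of cell counts and per-sample
template totals as denominators.

**Tissue enrichment** compares a clone's two frequencies within one
patient. The qualitative notion of "higher in one tissue vs similar" is
made operational as a configurable frequency fold rule
(`enrichment_params()`): a clone is TissueEnriched when
$f_{tissue} \ge k \cdot f_{blood}$ (default $k = 2$), PBMCEnriched by the
mirrored rule, Unenriched otherwise, and Single when it occurs exactly
once across both tissues (the across-tissue reading of "one occurrence").
A clone absent from one tissue trivially satisfies any fold, so it
additionally needs at least `min_cells_expanded` (default 2) cells where
it is seen. These two defaults are package choices — the corresponding
published analyses parameterize "higher vs similar" in supplementary
material that is not machine-readable here — so every pipeline run writes
the values used into its manifest, and both are plain arguments. With
$k = 1$ a clone with exactly equal positive frequencies satisfies both
directions at once; that tie resolves to Unenriched.

## QC and gating

Cells enter the analysis only if they detect between 200 and 5,000 genes
(inclusive) and each of the flagged stress/lncRNA markers KCNQ1OT1,
UGDH-AS1 and GHET1 stays strictly below 2% of the cell's counts; a cell
with zero counts fails with an explicit reason. Readers never filter —
every QC decision happens in `qc_filter()` and is reported per cell, so
the surviving denominators are auditable. QC runs before clonotype
denominators are computed.

ADT counts are CLR-normalized per feature across cells
($\ln((x+1)/\text{geometric mean}(x+1))$), the feature-barcoding
convention; the transform is monotone per slice so gates respect raw
count order. T cells are CD3-positive and CD14-negative
(`cd3_min = 0.5`, `cd14_max = 0.5` on normalized units — artifact
defaults, since the published gate was cluster-based and printed no
values). CD4/CD8 single-positive labels use strict thresholds
CD4 > 0.75 and CD8 > 1.0 on normalized units; both gates firing gives
`double_positive`, neither `double_negative`, and both labels are
excluded from subset-scoped analyses. Scoped runs (`scope = "CD4"` or
`"CD8"`) restrict numerator *and* denominator to the gated subset, so
scoped frequencies are percentages of all CD4+ (or CD8+) TCRs.

## Differential expression

Contrasts between clonality-defined groups (Single vs expanded
Small–Large cells, PBMC-enriched vs tissue-enriched cells, or one cluster
split by tissue) use a two-sided Wilcoxon rank-sum test per gene on
log-normalized counts (library-size scaling to 10,000, `log1p`). Ranks
are invariant to monotone transforms, so the normalization affects only
the reported means. P values are Bonferroni-corrected by the **total**
number of genes in the dataset (not the number tested — this mirrors the
toolchain convention of correcting against the full gene universe), and a
gene is called significant at `p < 1e-6` with `|log2FC| ≥ 0.5`. The fold
change is `log2((mean_B + 1)/(mean_A + 1))`; the pseudocount avoids
division by zero, and the sign convention is that positive values mean
higher expression in group B. "Fold change of 0.5" is read as a log2
threshold, the modern convention; both cutoffs are arguments. Constant
genes get `p = 1` and zero fold change. For groups below 50 cells without
ties the exact rank-sum null is used; otherwise the tie-corrected normal
approximation (the behaviour of `stats::wilcox.test`).

## What the synthetic generator emulates

`simulation_config()` describes a study-like cohort; its defaults are the
study conditions the package is validated under:

| parameter | default | meaning |
|---|---|---|
| `n_patients`, `cells_per_tissue` | 3, 2000 | three matched pairs of 2,000 cells |
| `expanded_cell_fraction` | (0.23, 0.29) | expanded-cell share in blood / tissue, the published cohort-level percentages |
| `clone_size_law` | geometric(p = 0.5) | memoryless expansion; Zipf available |
| `shared_clone_fraction` | 0.5 | expanded clones present in both tissues |
| `enrichment_factor` | 4 | frequency multiplier on the enriched side |
| `enriched_tissue_probability` | 0.75 | enriched side is the tissue compartment |
| `dual_tra_rate`, `tra_dropout` | 0.1, 0.15 | dual-TRA clones and TRA capture dropout |
| `qc_violation_rates` | 2% + 2% | planted gene-count and flagged-gene violators |
| `myeloid_rate`, `doublet_rate` | 0.15, 0.02 | CD14+ admixture / CD4CD8 double-positive ADT phenotypes carrying spurious VDJ calls, removed by the gates |
| `cd4_fraction` | 0.7 | CD4:CD8 clone ratio, matching the ~3:1 subset sizes of such cohorts |

Expanded-clone sizes are drawn from the law **conditioned on size ≥ 2**
(for the geometric law this is exact by memorylessness,
$E[X \mid X \ge 2] = 2 + (1-p)/p$), so the planted expanded-cell fraction
is exactly the budget filled with multi-cell clones and is recoverable
from the emitted data; the last clone is trimmed so budgets are met
exactly. Shared clones get the count on their designated enriched side
scaled by `enrichment_factor` with stochastic rounding; clipping at the
tissue budget keeps totals exact. CDR3 strings are uniform random
amino-acid strings with C/F flanks (lengths 8–20), unique across clones —
there is no V(D)J recombination model, which suffices because the
analysis uses string identity only. ADT counts are negative binomial
(dispersion 50) with positive markers near 400–500 counts and negative
markers below 1, giving a CLR separation wide enough that the default
gates recover true types with ≥ 95% accuracy; an optional
`hyperexpanded_spike` forces one clone to 12% of blood and 5% of tissue
cells, reproducing the Hyperexpanded-in-blood / Large-in-tissue pattern
of a virus-specific clone.

What the generator does **not** emulate: transcriptome structure beyond
detected-gene counts (cluster labels are planted, not derived from
expression), biological CDR3 sequence statistics, ambient RNA, or
patient-level covariates. Passing recovery tests therefore demonstrates
the correctness of counting, classification and gating logic on data with
known truth — not robustness to the full noise spectrum of real 5′
libraries.

## Numerical and design choices

- "Between 200 and 5,000 genes" is read inclusively, "below 2%" strictly;
  both configurable.
- Frequencies per (patient, tissue, scope) sum to 100% by construction;
  tests assert it to 1e-9.
- Cluster-overlap rows sort by combined cell count, ties broken
  lexicographically on the key, so top-N reporting is deterministic.
- All written tables are sorted on their key columns; re-running a
  pipeline with the same configuration reproduces byte-identical outputs.
- Degenerate inputs fail loudly: empty contrast groups name the group,
  unknown cluster labels and missing ADT features are configuration
  errors, clones present in neither tissue are domain errors, and a
  degenerate clone-size law with a positive expanded fraction is rejected
  at config validation.
- Problem sizes in the test-suite and acceptance computations (2 patients
  × 300–1,000 cells for property tests; one 5,000-cell patient for
  recovery; 3 × 2,000 × 2 for the end-to-end run; 10 null replicates of
  2,000 genes for DE calibration) were chosen so each check has enough
  resolution for its tolerance — 3 binomial standard errors for recovery
  rates, exact equality for deterministic properties — while the whole
  suite stays comfortably runnable on a laptop.

## Known limitations

- Enrichment fold defaults are conventions, not published constants;
  conclusions sensitive to `fold_threshold` should be checked across a
  range.
- Exact CDR3 matching against annotation databases finds only literal
  hits; no fuzzy or motif matching (specificity-clustering approaches are
  deliberately out of scope).
- The Wilcoxon DE path tests one gene at a time with no covariate or
  batch adjustment; it mirrors the marker-test convention of single-cell
  toolchains rather than model-based DE.
- Barcode identity is scoped per (patient, tissue); identical barcode
  strings across tissues are distinct cells.
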