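---
title: "Gene fitness from pooled transposon competitions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene fitness from pooled transposon competitions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

A pooled transposon mutant competition starts from thousands of insertion
mutants mixed in one culture, grows them together under a condition of
interest, and asks which mutants changed in relative abundance. A strain's
fitness is

$$w_i = \log_2 \frac{x_i(\mathrm{END})}{x_i(\mathrm{START})},$$

the log2 ratio of its relative abundance after versus before the
competition: 0 for a neutral mutant, negative when the disrupted gene is
needed under the condition, positive when losing the gene is an advantage.
`tnfit` implements the two read-outs of this quantity used for
sulfate-reducing bacteria, where strongly *positive* fitness — mutants that
outgrow everything else under nitrate stress — is the signal of interest.

# Read-out 1: barcoded pools on a tag microarray

Each mutant carries a TagModule with two unique barcodes (an uptag and a
downtag). Two pools are competed separately; the uptags of pool 1 and the
downtags of pool 2 are amplified and hybridized to one array per
experiment, before (`START`) and after (`END`) growth. The pipeline is:

1. **Strain fitness** (`strain_fitness`): difference of the mean log2 tag
   intensities, END minus START. Because abundance enters the intensity
   through its logarithm, this difference estimates $w_i$ directly.
2. **Low-START exclusion** (`filter_low_start`): strains whose mean START
   intensity falls below `theta` are dropped. Their signal sits too close
   to the array background for the ratio to mean anything. Default
   `theta = log2(4 * background)`, i.e. two log2 units above the additive
   background level; override per experiment.
3. **Per-pool median centring** (`normalize_strain_median`): most strains
   are neutral in any one condition, so the per-pool median estimates the
   zero point; subtracting it removes pool-composition and labelling
   offsets. Done separately for the two pools.
4. **Gene fitness** (`gene_fitness`): unweighted mean over the included
   strain measurements in a gene, pools combined (a shared strain
   contributes one measurement per pool). Intergenic strains aggregate per
   intergenic label and are flagged, never mixed into genes.
5. **Position and mode correction** (`normalize_position_mode`): a running
   median over a centred window of 251 genes in chromosome order (truncated
   at edges) removes smooth positional trends such as replication-associated
   copy-number bias; a median is used so that a handful of strongly
   selected genes cannot drag their neighbourhood. The mode of the
   corrected distribution — the bulk of phenotypically silent genes,
   estimated as the argmax of a Gaussian kernel density on a 512-point grid
   with Silverman's bandwidth — is then subtracted, anchoring "no
   phenotype" at exactly one grid step of 0.
6. **Quality metrics** (`quality_metrics`): Pearson correlation of strain
   fitness between pools over shared strains, and Pearson correlation of
   gene fitness between adjacent same-operon genes. Co-operonic genes tend
   to share phenotypes, so both correlations proxy data quality; both
   collapse in "jackpot" cultures where a few mutants take over and
   everyone else's signal sinks into array background.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `theta` | `log2(4*background)` | log2 intensity | reliability floor for START signals |
| `window` | 251 | genes | positional trend scale; must be ≫ operon size and ≫ any selected cluster |
| `f_lo`, `f_hi` | 0.05, 0.85 | gene fraction | insertions in the first 5% may miss the promoter-proximal fold and the last 15% may leave a functional truncation |
| `pseudocount` | 1 | sites | keeps zero-insertion genes in tables, flagged |

# Read-out 2: insertion density (liquid-enrichment Tn-seq)

Here mutants are created en masse by conjugation, grown under selection,
and sequenced once at the end. A gene's fitness is the log2 ratio of its
unique-insertion density in the 5–85% coding window to the genome-wide
in-window density:

$$f_g = \log_2\!\left[\frac{n_g / \lambda_g}{N / \Lambda}\right],$$

with $n_g$ the unique insertion sites in the gene's window, $\lambda_g$ the
window length, and $N = \sum_g n_g$, $\Lambda = \sum_g \lambda_g$. Unique
sites, not read counts, are the measurement: each site is one surviving
lineage. Genes selected *for* keep all their sites detectable while the
bulk's sites fall below sequencing detection, which raises the selected
genes' relative density — this is how a gene can reach a large positive
$f_g$ even though site density cannot exceed its value at inoculation.

Window offsets are computed 5'→3' on the coding strand with floor
rounding, so `win_len = floor(0.85 L) - floor(0.05 L)` exactly and a
uniformly inserted gene keeps 80% of its sites. Both the numerator and the
normalizing density use window lengths, keeping units consistent; insertion
strand is ignored (a transposon on either strand disrupts the gene); a site
inside two overlapping genes' windows counts for both. Genes with zero
in-window sites would be $-\infty$; they get a pseudocount of 1 and a
`flagged_zero` mark, are excluded from positive-fitness sets, and break the
otherwise exact identity that the window-length-weighted mean of
$2^{f_g}$ equals 1.

The effective doublings of such a culture are estimated by treating the
unique insertions in positive-fitness genes (the only lineages contributing
appreciably to the final population) as the founding cell count:
`estimate_doublings(final_cells, start_pool)` returns
$\log_2(\mathrm{final}/\mathrm{start})$.

# Candidate selection across conditions

`select_candidates` applies an anion-consistency rule: fitness strictly
greater than `t_high` (default 2) in *both* salts of the stressor anion and
strictly less than `t_low` (default 0.25) in the osmotic controls, nitrite
and the no-stress condition. Requiring both salts separates the anion
effect from cation or osmotic effects. Candidates are ranked by their
minimum fitness across the high conditions — a conservative score that a
gene can only earn in both salts at once; ties break lexicographically.
Genes missing any rule cell are excluded (absence of evidence is not
resistance) and listed separately. Ranking on a single condition is
available through `rank_genes`. Cross-genome comparisons go through
`join_homologs`, which reports per-pair fitness side by side and the
fraction of pairs with concordant fitness sign; no orthology inference is
performed — the map is an input.

# The simulator: what it emulates, and what it does not

`simulate_competition` uses deterministic exponential competition,
$a_i = x_i(0)\,2^{(1+s_i)D}$ renormalized after $D$ reference doublings.
This is the simplest model with closed-form abundances; it reproduces the
jackpot phenomenon (with $s=3$ and $D=3.3$, ten strains out of 4000 exceed
half the final culture) and exposes exact per-strain truth
$w_i$ for oracle tests. Stationary phase is represented by fixing $D$ per
condition rather than by carrying-capacity dynamics, because the pipelines
only consume END/START ratios. Observation noise is log2-normal on
intensities (`sigma`) over an additive hybridization background, and
multinomial on sequencing reads; there are no spatial array artifacts, PCR
biases, or insertion-site preferences. Intergenic insertions are neutral.

The canonical study (`nitrate_scenario`) freezes the conditions once:

* 2400 genes, lognormal lengths (mean 900 bp, sdlog 0.3), 100 bp gaps;
* pools of 2200 + 2200 strains sharing 400 (4000 distinct), 5% intergenic,
  5% underrepresented at inoculation (100-fold down);
* per-strain idiosyncratic rate sd 0.45 — insertion-position and barcode
  effects make two mutants of the same gene grow slightly differently, and
  this continuous heterogeneity is what gives gene-level truth a full
  ranking for recovery tests (tier-only effects would leave most genes
  exactly tied);
* a contiguous 9-gene cluster with selection coefficients 2–4 plus a
  distant regulator at 3 under both nitrate salts, neutral in the four
  control conditions; 2% of genes sick ($s=-1$) everywhere; the middle
  cluster gene flagged as a pseudogene (it is scored like any gene);
* D = 3.3 in every barcode condition, intensity noise 0.3, array gain
  2×10⁶ with background 10;
* insertion library: 8×10⁵ unique sites and 4×10⁶ reads. At this depth a
  neutral site is sequenced with probability ≈ 0.4, so planted genes (all
  sites retained) sit ≈ 1.3 log2 units above the bulk while neutral genes
  stay within ±1 of zero; with an order of magnitude fewer sites the
  per-gene Poisson noise of site placement alone would push a handful of
  neutral genes outside that band regardless of read depth, which is why
  the generator works at the "hundreds of thousands of insertions" scale
  such libraries actually have.

Planted genes are guaranteed two shared strains each in the barcoded
library — a catalogued library only yields candidates for genes it covers.
Passing recovery tests on this scenario shows the estimators rank and
separate effects correctly under multiplicative growth, log-normal
intensity noise with a background floor, and multinomial sampling; it does
not show robustness to array spatial artifacts, PCR jackpotting of
individual junctions, insertion hot-spots, or condition-dependent
cross-contamination, none of which are modelled.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in files; window arithmetic uses
  0-based half-open offsets internally with a single conversion point.
* Running-median windows truncate at chromosome edges; fewer than three
  positioned genes skips the positional step with a warning.
* The KDE mode is deterministic given the data (fixed 512-point grid);
  after subtraction the recomputed mode lies within one grid step of 0.
* Empty pools after filtering, zero total in-window insertions, and rule
  conditions missing from a table are errors, not silent results.
* Infinite candidate thresholds form the degenerate select-all /
  select-none rules; finite thresholds must satisfy `t_high > t_low`.
* All randomness flows from one master seed through labelled sub-streams
  (`derive_seed`), so regenerating one read-out never perturbs another and
  identical configurations are byte-identical end to end.

# Problem sizes

The test-suite and reproduction runs use the canonical scenario exactly as
frozen above (4000 strains × 6 conditions, 8×10⁵ insertion sites); one full
study simulates and analyses in under a minute on a single core. The
smaller genomes appearing in unit tests (50–600 genes) are chosen per test
to make hand-computable oracles, not for speed of the method itself.

# Known limitations

* The barcode estimator is biased toward zero for strains whose END signal
  approaches array background (deliberately: that is also why jackpot
  cultures show degraded quality metrics, as observed in practice). Only
  ranks, not magnitudes, should be interpreted for such strains.
* Gene fitness is an unweighted mean over strain measurements; no
  tag-count or variance weighting is attempted.
* The insertion-density fitness of a gene with very few expected sites
  (short genes) is noisy; the pseudocount flag marks only the zero case.
* Real annotations may contain overlapping genes; mapping reports all
  containing genes, but the simulator never generates overlaps, so
  overlap handling is exercised only by constructed fixtures.
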