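---
title: "Quantifying promoter acetylation dynamics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter acetylation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`promacet` quantifies stranded single-end ChIP-seq of promoter histone
acetylation (H3K9ac), histone H3, RNA polymerase II (Rpb1) and
transcription-factor occupancy in a yeast-like genome with a
fixed-proportion spike-in, and classifies stress-repressed promoters from
treated/vehicle fold changes. This vignette explains the underlying model,
every convention the numbers depend on, and the choices made where the
design was genuinely open.

## From reads to signal

**Fragment-midpoint model.** Each sequenced read is reduced to its 5'
position (BED `start` on the plus strand, `end − 1` on the minus strand).
With sonicated chromatin of mean fragment length `2 × shift`, shifting the
plus- and minus-strand profiles towards each other by `shift` base pairs
places both reads of a fragment at (within 1 bp of) the fragment midpoint
— the position of the nucleosome or protein that was cross-linked.
Extending each shifted position into an `extend`-bp interval smooths the
point estimate. Defaults are `shift = 150`, `extend = 40`.

Two readings of "extend each read by 40 bp" are possible. The default
centers the 40 bp interval on the shifted position
(`[p − 20, p + 20)`), because towards-each-other shifting targets the
fragment midpoint and centering makes the two reads of one fragment
coincide; extension downstream of the shifted 5' end is available via
`extend_from = "shifted5p"`. Duplicate reads are kept: no deduplication is
applied anywhere.

**Windows.** All coordinates are 0-based, half-open. Quantification
geometries:

| kind | definition | default width | used for |
|---|---|---|---|
| `promoter_upstream` | `[tss − w, tss)` on +, `[tss + 1, tss + 1 + w)` on − | 400 bp (500 bp for TF occupancy) | promoter read counts, motif scanning |
| `plus1_centered` | `[d − floor(w/2), d − floor(w/2) + w)` around dyad `d` | 75 bp | H3K9ac / H3 |
| `gene_body` | TSS to TTS inclusive | — | Rpb1 |

The minus-strand promoter starts at `tss + 1` so the TSS base itself is
excluded from "upstream" symmetrically with the plus strand (whether the
original analysis included it is not determinable from its description;
the convention here is declared, not inferred). +1-dyad windows are
strand-independent on the reference axis; for even widths the extra base
falls 3' of the dyad on that axis. Orientation (5'→3' of the gene) is
applied only when building metagene profiles. Windows that run off the
chromosome are clipped and flagged; windows entirely off-chromosome are an
error.

**Counting modes.** "Total number of reads in a region" is read as the
number of shifted fragment midpoints falling in the window
(`midpoint_count`, the default for per-gene quantification); summed
per-base coverage (`coverage_mass`) is the alternative and is what feeds
profiles and heat maps, matching continuous track display. Both modes are
exposed everywhere and the choice is recorded in each `SignalTable`.

## Normalization

Order of operations: per-sample scaling first, then the optional mock-IP
ratio, then the contrast. The order is not uniquely determined by the
experimental description, so it is fixed here and written into every
table's provenance block.

* **Spike-in** (`norm = "spikein"`): samples receive a fixed proportion
  (default 5%) of foreign chromatin before immunoprecipitation, so
  spike-in reads track technical depth. Counts are multiplied by
  `reference_spikein / sample_spikein` (reference = first sample of the
  table). This is the only normalization that can reveal *global* signal
  shifts: under a planted uniform 2-fold acetylation loss the spike-in
  route reports a mean log2FC near −1 while per-million scaling reports
  near 0 (both measured by the test suite and `scripts/acceptance.R`).
* **Library size** (`norm = "library"`): per-million target reads, for
  tracks without spike-in.
* **Mock IP**: optional per-track ratio
  `(scaled + pc) / (mock_scaled + pc)` against a no-antibody control,
  isolating per-region enrichment. Applied to TF tracks; the
  H3K9ac/Rpb1 analyses are read-count based, so it defaults off. An
  H3-ratio (acetylation per nucleosome) can be requested the same way by
  passing the H3 sample as `mock`, and likewise defaults off.

**Pseudocount.** `pc = 1` raw count is added to both sides of every ratio
(`log2fc = log2((treated + pc)/(vehicle + pc))`). This prevents
infinities at promoters silenced by stress and biases low-coverage fold
changes towards 0; at the default depth (~200 midpoints per window) the
bias is negligible. `pc` must be strictly positive; NaN is never produced.

## Classification and statistics

A gene is **stress-repressed** when `Rpb1 log2FC < −1` and
`H3K9ac log2FC < −0.41` (strict inequalities, exactly these printed
values; `strict = FALSE` relaxes to ≤). Both contrasts must share a gene
universe; genes missing from either are excluded and counted. The
classifier is monotone in both thresholds, and the per-group member counts
always partition the member set — both are property-tested.

* **Pearson** correlation of per-gene fold changes via `cor.test`.
* **Mann–Whitney**: exact two-sided p by enumeration of all group
  assignments when both groups have ≤ 8 observations (correct under
  ties), otherwise a tie-corrected normal approximation with continuity
  correction. The two paths agree within 0.02 at n₁ = n₂ = 8 (tested).
* **ANOVA + Dunnett**: one-way `aov` followed by Dunnett contrasts of
  each group against "other" via `multcomp::glht`. The multivariate-t
  integration behind the adjusted p-values is randomized, so the call is
  wrapped in a local fixed RNG seed to make results reproducible
  run-to-run.
* **Motif enrichment**: a promoter *has* a motif if it contains ≥ 1 exact
  (IUPAC-aware, case-insensitive) occurrence on either strand —
  zero-or-one-per-sequence counting; total-occurrence counting is behind
  a flag. Enrichment is Fisher's exact test on the 2×2 presence table;
  the odds ratio is the sample cross-product with a Haldane 0.5
  correction when a cell is zero. The background excludes foreground
  genes by default (flag to include). No multiple-testing correction is
  applied across motifs or contrasts; raw p-values are reported.

## Metagene profiles and heat maps

Profiles average `coverage_mass` over `[anchor − flank, anchor + flank)`
(default flank 800 bp, anchored on the +1 dyad), reversing minus-strand
genes so positions run 5'→3' of the gene; genes whose window leaves the
chromosome are excluded and counted. Heat-map matrices order genes by
ascending Rpb1 log2FC with ties broken by `gene_id` (stable), bin columns
by averaging (`bin` must divide `2 × flank`), and apply no per-gene
scaling — display scaling belongs to plotting, which is deliberately left
outside the tested numeric artifact.

## The synthetic-data generator

The generator emulates the study design so that every stage has planted
ground truth: 5673 genes on 16 chromosomes in groups RP/RiBi/GR/other
(proportions 0.024/0.035/0.043/0.898, allocated exactly by largest
remainder), +1 dyads 60 bp downstream of the TSS, fragment lengths
Normal(300, 30) floored at 40 bp (consistent with `shift = 150`), 200
expected fragment midpoints per gene window per sample, uniform background
at 10⁻⁴ reads/bp, one spike-in chromosome at an expected 5% of total
reads, and a rapamycin-like treated/vehicle pair in which the repressed
groups carry planted per-gene (H3K9ac, Rpb1) log2 fold changes drawn from
per-group bivariate normals with between-track correlation ρ = 0.76
(clipped at 0 above for repressed groups). Promoters are i.i.d. uniform
ACGT with PAC/RRPE planted at per-group rates (high in RiBi/GR, low
elsewhere). Sequencing is single-end: one end of each fragment is emitted
with probability ½. The mock IP re-emits the library at background
geometry, so mock ratios isolate enrichment. Everything is reproducible
bit-for-bit from `(config, seed, condition, track)`.

Design notes, fixed once:

* **Spike-in rate.** The spike-in expectation is
  `f/(1 − f) × depth × baseline`, where `depth` is the sample's
  *technical* scale factor and `baseline` the expected target reads at
  unit biological signal — so the expected spike-in fraction equals `f`
  and, crucially, planted *biological* losses leave spike-in counts
  untouched (that is what makes spike-in normalization informative).
* **Correlation-recovery configuration.** The pooled planted correlation
  across genes equals ρ only when all groups share one untruncated
  distribution; with group-specific means the shared group structure
  inflates the pooled correlation above ρ. Correlation-recovery
  experiments therefore use `homogeneous_fc_specs()` (all groups
  mean −0.5, sd 1.0 per track — a spread of the magnitude real
  fold-change scatters show). With heterogeneous defaults the pooled
  planted correlation is by construction higher than ρ.
* **Classification-margin configuration.** Recovery of the repressed set
  is measured with `margin_fc_specs()`: repressed draws capped 0.5 log2
  units beyond both thresholds and background floored at −0.2, so the
  planted truth is unambiguous at the default sequencing depth.
* **Estimator noise floor.** At 200 expected midpoints per window the
  per-gene contrast is a log-ratio of two ~Poisson(200) counts, whose
  mean absolute error is ≈ `sqrt(2/200)/ln 2 × sqrt(2/π)` ≈ 0.115 even
  for genes with no true change; read-level midpoint jitter adds a little
  more. Mean absolute errors of ~0.12 reported by the test suite and the
  acceptance script are at this statistical floor, not implementation
  error; halving the error would require roughly 4× the depth.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: nucleosome arrays beyond the +1 window (no −1
nucleosome, no phasing), sequence-dependent immunoprecipitation or GC
bias, PCR duplicates, replicate structure and biological variance,
mappability, and annotation error in TSS/TTS/dyad positions. Tests
demonstrate that the *computational chain* is correct and well-calibrated
under its stated model, not that the model captures every property of
real chromatin.

## Problem sizes and runtime choices

Module tests run on toy genomes (3–1000 genes); end-to-end recovery
experiments use 5000 genes at 200 midpoints/promoter (one seed for
fold-change and correlation recovery, three seeds for set recovery), 2000
genes for the global-loss comparison, 1000 promoters for motif
enrichment, and 250–500 genes for byte-identity and integration runs.
These sizes give stable estimates (standard error of a mean log2FC at
n = 2000 is ~0.003) while keeping the full suite fast.

## Interfaces

The pipeline is driven either by the numbered scripts under `analysis/`
(simulate → quantify/contrast → classify/stats → metagene, each writing
TSVs under `results/`) or by `run_pipeline()` with a single declarative
YAML/list configuration (sample manifest, contrast list, parameters —
defaults: shift 150, extend 40, promoter 400, +1 window 75, TF window
500, pseudocount 1, thresholds −1/−0.41, flank 800). Every normalization
factor, threshold and exclusion count ends up in `summary.json`; reruns
with the same configuration and seed are byte-identical (tested). A
shell-level wrapper would add nothing over these two entry points, so
none is provided.

## Known limitations

* Peak calling, fragment-length estimation, input-DNA normalization,
  GC-bias correction and replicate variance modeling are out of scope.
* BAM support covers primary, mapped, single-end alignments only
  (optional MAPQ filter; requires Rsamtools).
* The Dunnett step requires the control group ("other") to be present;
  unbalanced group sizes are handled by `multcomp` but tiny groups make
  the multivariate-t adjustment conservative.
* Exact Mann–Whitney enumeration is combinatorial and is therefore capped
  at 8 observations per group; beyond that the tie-corrected
  approximation is used.
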