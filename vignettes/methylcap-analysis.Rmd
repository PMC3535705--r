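---
title: "Quality control, differential methylation and global methylation with methcapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control, differential methylation and global methylation with methcapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and the analysis model

MBD-capture sequencing (MethylCap-seq) enriches sonicated genomic DNA for
methylated fragments with the methyl-binding domain of MBD2 and sequences
the captured pool. Read density over a region is then a *relative* readout
of that region's methylation: relative to the rest of the same sample,
never absolute. Two consequences drive everything this package does:

1. **A failed capture invalidates a lane silently.** If enrichment fails,
   the lane still yields millions of well-aligned reads — drawn roughly
   uniformly (and irreproducibly) from the fragment pool instead of by
   methylation. Such lanes must be found and excluded before any
   between-group comparison.
2. **Global methylation is invisible to within-sample normalization.** Two
   samples with identically *distributed* but differently *scaled*
   methylation produce the same normalized profile, so a global indicator
   has to come from the shape of the signal across CpG density (the GMI),
   or from an external competitor (a methylated spike-in).

The analysis stack is: genome CpG index → per-lane loading, duplicate
removal, fragment extension, 500-bp bin counts, RPM → lane QC with
exclusion thresholds → replicate-lane averaging per sample → feature-level
Wilcoxon/Benjamini-Hochberg DMR calling, the CpG-density methylation
distribution and its AUC (GMI), and the spike-in regression.

## Coordinates, binning and normalization

All coordinates are 0-based, half-open; bin *i* covers
`[i*bin_size, (i+1)*bin_size)` (BED-compatible). A CpG belongs to the bin
containing its C. Soft-masked bases are ordinary bases; N never forms a
CpG.

Each aligned single-end read (36 bp by default) is extended in its strand
direction to the sonication fragment length (default 150 bp, per-lane
overridable) and assigned to **exactly one** bin — the bin containing the
fragment midpoint. The assay's input contract does not fix a rule for
fragments straddling a bin boundary; we chose single (midpoint) assignment
over counting a fragment in every overlapped bin because it makes bin
counts true fractions of reads: counts sum to the number of deduplicated
reads and RPM sums to exactly 10^6, which the noise statistic, the GMI and
the replicate-merging identities all rely on. Duplicate alignments (same
chromosome, leftmost position and strand) are removed as PCR artefacts
before any genomic analysis — but *retained* for spike-in counting, whose
purpose is to measure captured construct mass. Replicate lanes are
normalized individually and then averaged per sample, so a deep lane
cannot dominate a shallow replicate.

## The QC metrics and thresholds

* **CpG enrichment** — CpG frequency inside the extended fragments over
  CpG frequency of the reference genome (the relative-frequency
  formulation matching the metric's verbal definition; the upstream
  toolkit this emulates offers several variants and the source material
  does not name one, so absolute comparability of enrichment values
  across implementations is not asserted — only threshold and ordering
  behavior). ≈1 means no enrichment.
* **Saturation** — Pearson correlation of bin counts between two random
  halves of the lane's reads, a reproducibility proxy computed literally
  as "two random partitions" (a single seeded split, recorded in the QC
  report), not the extrapolated estimator some toolkits report.
* **5x CpG coverage** — fraction of all genomic CpG sites covered by ≥ 5
  extended, deduplicated fragments.
* **Noise** — percentage of assigned reads whose bin contains no CpG;
  methylation signal there is biologically implausible.

Exclusion uses the thresholds enrichment < 1.4, saturation < 0.5,
coverage < 0.05; a lane failing **any** one is excluded. The comparisons
are strict, so a metric exactly on its threshold passes — boundary
behavior is unstated in the metric definitions and had to be fixed
somewhere; strict reading of "<" is the documented choice. A
`force_include` escape hatch supports the manual borderline override a
sequencing core occasionally applies; it is never automatic.

## DMR calling

Per feature (CpG island, shore, promoter — supplied as BED4), RPM is
summed over every overlapping bin; a bin overlapping two features counts
fully toward both. Groups are compared feature-by-feature with a
two-sided Wilcoxon rank-sum test: midranks for ties; an exact p-value by
full enumeration of all `choose(m+n, m)` assignments when the combined
sample size is ≤ 12 (exactness matters most at small n, and 12 keeps
enumeration ≤ 924 assignments); otherwise the tie-corrected normal
approximation with a 0.5 continuity correction. Benjamini-Hochberg is
applied per feature class (islands, shores and promoters are corrected
separately, matching how such results are reported per class), with
significance at q ≤ 0.05. Features with zero signal in every sample are
tested anyway (p = 1) so the number of tests is reproducible from the
feature set alone.

## GMI and the spike-in

Bins with ≥ 1 CpG are classified by integer CpG count (≥ `c_max`, default
25, pools into the top class — the granularity is configurable because the
upstream class scheme is not fully specified); the mean RPM per class —
zero-RPM bins included — forms the methylation distribution, and its
unit-width sum (a left Riemann sum) is the GMI. Zero-CpG bins are
excluded: they are the noise domain, and including them would let
enrichment failures inflate the indicator. Class means are per-bin
averages (per-CpG averaging is a conceivable alternative; per-bin is
implemented and documented).

The spike-in construct (an in vitro fully methylated, CpG-dense plasmid
analogue at ~2.5 copies per genome) competes with genomic fragments for
capture, so its read share falls as the sample's global methylation
rises. Construct reads are counted without deduplication and normalized
by the lane's **raw** read total (not aligned reads — the construct
competes before alignment); both denominators are kept distinct in code.
GMI is regressed on 1/construct-RPM by ordinary least squares with the
standard two-sided t-test on the slope (df = n − 2).

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions: a 2 Mb single-contig
genome; 100 CpG islands of 1 kb at 0.1 CpG/bp on a 0.01 CpG/bp
background; 10% CpG-free bins; 100,000 reads per lane of 36 bp extended
to 150 bp; 5% injected PCR duplicates; a 5.3 kb fully methylated
construct at 2.5 copies per genome. Capture draws fragments with weight
`1 + k·(methylated CpGs in fragment)`; the linear form keeps expectations
analytically tractable (saturating alternatives are plausible but not
default). `k = 2` was calibrated so captured lanes score CpG enrichment
in the 2.3–3 range that good libraries of this assay typically show,
with noise a few percent — both checked by the acceptance suite, not
asserted from the calibration.

A sample's methylation is fractional: each region (an island, or a 2 kb
background segment) gets a methylation fraction drawn from a Beta around
its group mean (concentration 10, i.e. SD ≈ 0.15 at 0.5 — subclonal and
cellularity heterogeneity), and each CpG is methylated with that
fraction. CpG states belong to the sample's DNA and are shared by its
replicate lanes. Differentially methylated units are islands *plus the
regions overlapping their 500-bp shores* (differential methylation rarely
stops at an island edge), with a per-unit effect size drawn from
0.2–0.5 so true effects span borderline to strong — uniform effect sizes
would make every DMR survive or vanish together under FDR correction,
which is not how cohorts behave.

**Failed enrichment is not clean input.** An `input` lane samples
uniformly. A `failed` lane additionally carries a per-bin gamma
distortion field — part shared by all lanes of the library
(shape 1.6), part lane-specific (shape 2.8) — re-centered within each
bin CpG-density class so that failure stays CpG-neutral (enrichment ≈ 1).
This models residual, uncontrolled binding: failed libraries are noisy
and poorly reproducible across lanes, which is precisely why they damage
DMR detection when retained. The variance split between the shared and
lane components was set, before any acceptance measurement, by a forward
calculation targeting the replicate-lane correlation reported for
QC-failing libraries of this assay (~0.6).

Not modeled: sequencing errors and base qualities, GC/PCR amplification
bias, paired ends, mappability, repeat structure, chromosome-scale
genome organization, and MBD binding affinity as a function of CpG
spacing. Passing tests therefore demonstrate the *logic* of the stack
under a faithful capture-competition model at desk scale, not performance
on any particular human cohort.

## Numerical and degenerate-input choices

* RPM sums to 10^6 exactly (relative tolerance 10^-9 in the tests); a lane
  with zero assigned reads is an error, not a NaN.
* Saturation of a half with constant bin counts returns 1 when the two
  halves are proportional and is otherwise a "degenerate partition" error.
* A Wilcoxon test on two identical groups returns p = 1; BH caps q at 1
  and rejects p outside (0, 1].
* The spike-in regression refuses n < 3, non-positive RPM, and zero
  variance in 1/RPM.
* All randomness flows from explicit seeds: lane loading is
  deterministic; saturation records its seed; the simulator is a pure
  function of (config, seed).

## Problem sizes

The test suite and the acceptance script run the simulator at its 2 Mb /
100k-read defaults for lane-level properties, 5 × 10^4 reads per lane for
the 20-sample cohort experiments (10 seeds), 2 × 10^4 reads for null
cohorts, 5 × 10^6 reads once for the replicate-correlation depth check,
and 5,000 replicates for the Wilcoxon type-I calibration; these sizes
were chosen so each property has clear statistical resolution at desk
scale.

## Known limitations

* The enrichment score is one of several variants in circulation;
  thresholds were taken as published for the 1.4/0.5/0.05 rule and should
  be re-calibrated if a different variant is substituted.
* Per-class BH (rather than one global correction across all feature
  classes) changes which features reach significance when classes differ
  greatly in size; it is the reported convention here and a documented
  choice, not a statistical necessity.
* GMI is depth-invariant but not an absolute methylation calibration; its
  mapping to percent-mCpG depends on the capture chemistry.
* At 2 Mb, the spike-in's read share is far larger than in a mammalian
  genome at the same copy number; the competition *direction* is
  scale-free, absolute shares are not.

## A worked example

```{r, eval = FALSE}
library(methcapr)

cfg <- sim_config(seed = 7, reads_per_lane = 5e4)
cohort <- simulate_cohort(cfg, n_per_group = c(6, 6),
                          n_failed_per_group = c(1, 1),
                          dm_fraction = 0.2, seed = 7, dir = "sim")

idx <- build_genome_index("sim/genome.fa")   # or sim_index(cohort$genome)
res <- run_pipeline(list(
  manifest = "sim/manifest.tsv",
  fasta = "sim/genome.fa",
  features = list(islands = "sim/islands.bed", shores = "sim/shores.bed"),
  spikein = list(construct_name = "construct_mSssI"),
  out_dir = "run", seed = 7))

res$qc                      # per-lane metrics and verdicts
res$dmr$islands             # Wilcoxon/BH DMR table
res$gmi                     # per-sample global methylation indicator
```
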