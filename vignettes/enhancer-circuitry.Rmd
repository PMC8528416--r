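---
title: "Methods: super-enhancer landscapes and core regulatory circuitry"
author: "enhancerCircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer landscapes and core regulatory circuitry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

Cell identity in systems such as adrenergic neuroblastoma is enforced
by a core regulatory circuit (CRC): a handful of transcription factors,
each driven by a super-enhancer (SE), that bind their own and each
other's super-enhancers in an interconnected autoregulatory loop.
Perturbations that rewire this loop — retinoic acid treatment being the
motivating example — leave a characteristic multi-omic signature:
H3K27ac redistributes, some SEs are decommissioned and new ones form,
TF occupancy shifts within the same SEs, and the transcriptome shows
changes that only spike-in-normalized expression can quantify when the
shift is global.

`enhancerCircuits` implements that analysis chain end to end, from
binned coverage to CRC deltas:

1. **Coverage tracks.** Aligned read 5' positions are extended to
   200 bp in the strand direction and counted into 50-bp bins tiling
   each chromosome from coordinate 0 (`extendReads()`,
   `binCoverage()`). Tracks are depth-normalized to reads per million
   (`rpmNormalize()`); a region's signal is the bin-fraction-weighted
   sum (`regionSignal()`).
2. **Peaks.** A simple Poisson caller (`callPeaksSimple()`) marks bins
   above the upper-tail quantile of a background rate and keeps runs
   of at least 200 bp. It deliberately emulates only what the
   downstream stages need — two stringencies whose calls are merged
   (`collapsePeakSets()`) stand in for dual MACS parameter sets, and
   externally called peaks are accepted interchangeably. Peaks
   contacting a configured exclusion region (for example a high-copy
   amplicon, where enrichment reflects DNA copy number) are discarded
   (`excludeRegion()`).
3. **Super-enhancers.** Peaks wholly inside TSS ± 1 kb windows are
   removed (`tssExclude()`), survivors within 12.5 kb are stitched
   (`stitchPeaks()`), and stitched regions are ranked by integrated
   RPM signal. The SE cutoff is the ROSE hockey-stick tangent rule:
   with both the rank axis and the signal axis rescaled to [0, 1], the
   cutoff sits where the ascending curve's slope equals 1, found by
   maximizing the distance x − y below the diagonal (`rankAndCut()`,
   `hockeyStickCutoff()`).
4. **Gene assignment.** A gene is "expressed" when its promoter
   (TSS ± 500 bp) H3K27ac coverage is in the top two-thirds of genes
   (`promoterActivity()`); each enhancer goes to the expressed gene
   whose TSS is nearest the enhancer center (`assignEnhancer()`).
5. **Differential landscape.** Per-sample SE calls are merged into one
   collapsed union (`collapseSeUnion()`); each union region's
   per-million coverage is compared between conditions as
   log2((B + c)/(A + c)) and classified gained/lost/stable
   (`differentialCoverage()`).
6. **Occupancy and CRC.** Regions enriched (≥ 3-fold over floored IgG,
   `enrichmentCall()`) for at least one target enter a
   regions-by-targets matrix ordered by integrated H3K27ac
   (`buildOccupancyMatrix()`, a `SummarizedExperiment`). A candidate
   TF is admissible if expressed and assigned an SE; edges record
   binding enrichment at each other's SEs, and the CRC is the largest
   admissible set forming a complete directed subgraph with self-loops
   (`inferCRC()`, `selectCircuitMembers()`, `compareCRCs()`).
7. **Expression.** ERCC spike-in size factors (median-of-ratios
   restricted to spike-in rows, `spikeinSizeFactors()`) rescale counts
   to a per-cell-comparable scale, so a global transcriptome shift is
   measurable; `tpm()` and `foldChanges()` supply the base-mean
   TPM > 10 filter and log2 fold changes. `librarySizeFactors()` is
   the deliberate foil: it cancels global shifts, which is exactly the
   failure mode spike-ins exist to avoid.

`runPipeline()` chains all stages on a simulated study and writes
TSV/BED/JSON outputs plus a run log with resolved parameters and
output hashes; `inst/scripts/crcpipe.R` wraps the same functions as
shell subcommands.

# Coordinate conventions

Internally every interval is a `GRanges`, i.e. 1-based closed — the
native Bioconductor convention. All file formats convert at the
boundary: BED and bedGraph are 0-based half-open (handled by
`rtracklayer`), WIG is 1-based, and our documentation quotes 0-based
half-open spans where a convention matters. One deliberate choice:
region strings like `"chr2:14817188-17228298"` (the exclusion-list
syntax) are parsed as **0-based half-open**, matching the arithmetic of
the BED-based tooling such lists come from; under half-open overlap a
peak ending exactly at the region start does not contact it, while a
peak starting at the last base does. Sources that intend 1-based
inclusive coordinates differ by one base at the left edge —
`parseRegion()` documents the ambiguity.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `binWidth` | 50 | bp | track resolution |
| `extension` | 200 | bp | read-to-fragment extension |
| stitch distance `s` | 12500 | bp | max gap merged into one enhancer region |
| TSS exclusion `t` | 1000 | bp | half-width of promoter windows removed before stitching |
| promoter window | 500 | bp | half-width for promoter activity |
| expressed quantile | 1/3 | — | bottom fraction excluded (top two-thirds expressed, boundary ties in) |
| `pThresholds` | 1e-9, 1e-5 | — | strict/lenient Poisson peak thresholds, merged |
| `foldThreshold` | 2 | fold | gained/lost classification; the underlying scatter is threshold-free, so this is an explicit knob |
| diff pseudocount `c` | 1 | per-million signal | stabilizes ratios at empty regions |
| enrichment `minFold` | 3 | fold over IgG | occupancy/CRC edge calls |
| enrichment floor | 0.5 | integrated RPM | stops empty IgG regions inflating ratios |
| TPM filter | 10 | TPM | strict `>` base-mean filter for "highly expressed" |
| fc pseudocount | 0.5 | normalized counts | log2 fold changes |

The first six mirror the conventional values of the upstream tools
they emulate (MACS-style density tracks, ROSE stitching); the
enrichment and fold thresholds are not dictated by any published rule
and are therefore explicit, logged configuration.

# Numerical and degenerate-input choices

* **Tangent cutoff.** Signals are min–max rescaled; ties at the
  maximal x − y distance break toward the higher signal (fewer SEs —
  conservative). Curves with fewer than three distinct values warn and
  call zero SEs. The cutoff is invariant to multiplying all signals by
  a positive constant. Two behaviors of the tangent rule are worth
  knowing: it is **not monotone under adding low-signal regions**
  (appending regions shifts every higher point right on the rank axis
  and can move the tangent to a lower signal, calling more SEs), and
  with heavy-tailed "typical" signal distributions the extreme order
  statistics can place the rescaled tail slope above 1, admitting a
  few typicals above the cutoff. Both are properties of the rule, not
  of this implementation.
* **Bin occupancy.** A read contributes 1 to every bin it overlaps by
  ≥ 1 bp; region signal weights each bin by overlap/`binWidth`, so
  region signal is additive over partitions at bin boundaries.
* **Expressed threshold.** The cutoff value is the (⌊n/3⌋+1)-th
  smallest promoter coverage and the comparison is `>=`, so boundary
  ties are expressed and an all-equal input is all-expressed.
* **Assignment ties.** Equidistant TSSs resolve to the leftmost;
  enhancers on chromosomes without expressed genes are assigned `NA`
  and logged downstream rather than erroring.
* **CRC member selection.** A greedy lowest-degree-removal heuristic
  can miss the maximum complete subgraph, so membership is computed
  exactly: maximum cliques of the mutual-binding graph restricted to
  self-looped nodes (via igraph), with ties broken to the set that is
  lexicographically first in candidate order. Candidate lists are
  small (≤ ~20 TFs), so exact search is effectively free, and it
  provably agrees with brute-force subset enumeration — which the test
  suite asserts on hundreds of random graphs. A relaxed rule
  (`minIn`: bound by at least k members) is available.
* **Size factors.** Median-of-ratios restricted to spike-in rows, with
  the median taken on the log scale (geometric interpolation at even
  counts, matching DESeq2's estimator, against which the tests
  cross-check). Scaling one sample by k scales its factor *relative to
  the others* by k and leaves normalized counts invariant up to the
  predicted common k^(1/S) rescaling of the geometric-mean reference.
* **Spike-ins and TPM.** Spike-in rows are excluded from the TPM
  denominator so TPM reflects the biological transcriptome; samples
  with no shared nonzero spike-in are rejected rather than guessed.

# The synthetic study and what it does (not) show

`syntheticDesign()` lays out a deterministic two-condition study;
`simulateStudy()` draws from it: bin counts are Poisson around the
planted intensities, counts are Poisson around planted expression
levels, and everything is reproducible from one integer seed (an
exact-mean mode replaces draws by rounded means for oracle tests).

The default genome is intentionally small so a full end-to-end run
takes a few seconds and a 20-seed recovery study a couple of minutes
on one CPU: 2 chromosomes × 5 Mb, 60 genes (40 expressed per
condition — exactly the top two-thirds), 20 SE clusters of four 1.5-kb
constituents spaced 2.5 kb, and 44 typical enhancers. Per chromosome,
one TF gene loses its SE under treatment, one keeps it, and one gains
one de novo — the decommissioned / shared / de novo geometry of the
retinoid-treated adrenergic circuit (GATA3 and PHOX2B lost; HAND2 and
ISL1 shared; MEIS1 and SOX4 gained), with CRC members binding their
own and each other's SE constituents at 10× the flat IgG background.
Expression plants ten 4×-down and ten 4×-up genes, optional global
shifts that spare the spike-ins, and per-sample depth multipliers as
size-factor ground truth. Spike-in concentrations span 32–4096
expected counts, a realistic ERCC-mix depth at which the size-factor
estimate contributes negligible noise to per-gene fold changes.

What the generator emulates: planted enhancer geometry compatible with
the stitching parameters, condition-specific gain/loss, promoter
activity tied to the expressed-gene truth, occupancy wired to a known
CRC, Poisson counting noise, and spike-ins that report absolute scale.
What it does **not** emulate: mappability and GC bias, fragment-length
variation, copy-number structure, peak-shape asymmetries, overdispersed
(negative-binomial) expression noise, and genuinely ambiguous
enhancer–gene relationships (every planted SE has an unambiguous
nearest expressed gene). Passing recovery tests therefore demonstrates
that the pipeline's logic is correct under its own model assumptions —
not that those assumptions capture every property of real chromatin
data.

```{r, eval = FALSE}
library(enhancerCircuits)
design <- syntheticDesign()
metrics <- evaluateRecovery(design, seed = 1)
metrics$crcMembers
study <- recoveryStudy(design, nSeeds = 20)
```

# Known limitations

* The peak caller is a single global-rate Poisson scan — no local
  background, duplicate handling or shift model; for real data, import
  MACS output instead.
* Enrichment is integrated over whole regions, so a TF binding a small
  fraction of a very wide SE can fall below the fold threshold; the
  floor/fold knobs trade this against false edges.
* Differential classification uses a fixed fold threshold on a
  quantity the source analysis displays as a threshold-free scatter;
  the threshold is an explicit knob, not a recovered constant.
* CUT&RUN fragments are treated with single-end 5'-extension
  semantics; paired-end fragment reconstruction is upstream of this
  package.
* Statistical testing of differential enrichment/expression
  (dispersion modeling, p-values) is out of scope; the package reports
  normalized effect sizes.
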