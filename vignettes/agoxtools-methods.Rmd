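---
title: "Methods: readthrough conservation, dsRNA enrichment and nucleolar quantification"
author: "agoxtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: readthrough conservation, dsRNA enrichment and nucleolar quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agoxtools)
```

`agoxtools` packages four analyses around stop-codon readthrough and
double-stranded RNA, with a synthetic-data module that generates every
input with known ground truth. This vignette explains the models each
stage assumes, the parameters that matter, and the design choices made
where the procedures left them open.

## 1. Readthrough-region detection and conservation scoring

A putative translational-readthrough (TR) region is the mature-mRNA
interval between a transcript's annotated stop codon and the next
in-frame TAA/TAG/TGA downstream. Both stop codons are excluded from
the region. This exclusive convention is what makes the arithmetic of
the canonical AGO1 example self-consistent: a 99-nt region translating
to exactly 33 amino acids. Scanning proceeds codon by codon in the
annotated frame over the spliced mRNA, so multi-exon and minus-strand
transcripts are handled through an explicit transcript-to-genome
coordinate map (0-based, half-open, everywhere in the package).
Transcripts whose 3' end arrives before any downstream stop get status
`no_downstream_stop`, with the interval extended to the last complete
codon; they are reported but never scored, since their region is
truncated by annotation rather than biology.

Conservation scoring averages a per-base track (scores in [0, 1], as
for PhastCons) over the genome positions of the region. Positions
absent from the track are *excluded* from the mean rather than imputed
as zero — imputation would bias means downward exactly for the poorly
covered regions — and a region whose covered fraction falls below
`min_coverage` (default 0.8) is flagged `low_coverage` and left
unscored. "Highly conserved" is a report-time threshold (default 0.5)
on the mean score; it is a labelling convenience, not a calibrated
cutoff. TGA is always treated as terminating: selenoprotein-style
recoding is not modelled.

```{r ago1}
fa <- system.file("extdata", "ago1x_appended.fa", package = "agoxtools")
appended <- toupper(as.character(Biostrings::readDNAStringSet(fa)[[1]]))
m <- transcript_model("AGO1", chrom = "c", strand = "+",
                      exons = data.frame(start = 0, end = 9 + nchar(appended)),
                      cds_end_tx = 6, mrna = paste0("ATGAAATGA", appended))
reg <- find_readthrough_region(m)
c(reg$length_nt, nchar(translate_extension(reg$seq)))
```

The synthetic transcriptome plants a configurable fraction
(`frac_conserved_tr`, default 0.05) of transcripts whose TR region
draws scores from `conserved_score_range` (default [0.8, 1]) against a
background of [0.02, 0.4]. The ranges are disjoint by default so
planted-recovery is a sharp test: ranking by mean score must place
every planted region above every background region. Scores live on a
per-mille grid so that values written to bedGraph re-read bit-exactly;
the recorded truth means are recomputed from the emitted track, which
is why tests can demand agreement to 1e-12. A 5% per-base dropout
(`track_dropout`) exercises the coverage logic.

## 2. Frame analysis of readthrough-region alignments

Multi-species alignments of a TR region are analysed relative to a
reference species (by convention the first record, human in the
generated fixtures): the reference's gap-stripped sequence defines the
codon frame, and alignment columns where the reference is gapped
belong to no codon. A codon counts as nonsense in a species only when
all three of its columns are gap-free there and spell a stop —
partially gapped codons are skipped rather than guessed, since calling
alignment artifacts as stop codons is the error this analysis exists
to avoid. Indels are maximal runs of gap columns on one side of the
species/reference pair; an event is frame-preserving iff its length is
a multiple of 3. Adjacent runs separated by at least one aligned
column are separate events; no merging window is applied. The
`tarsier_like` generator preset reproduces the structure of the
classic vertebrate AGO1 alignment: one codon-aligned 3-nt deletion in
one species, zero nonsense codons, so every species' frame is intact.

Substitutions in generated alignments are drawn per site but resampled
whenever they would create an in-frame stop; nonsense codons and
indels therefore appear only where the configuration plants them,
which keeps the ground truth exact. Injections are applied deletions
first, then nonsense (validated against gaps), then insertions, so
that codon indices in the configuration always refer to reference
codons.

## 3. Residual-based dsRNA enrichment calling

The caller compares per-gene log2 fold changes (mutant vs control)
between a dsRNA pulldown and total RNA-seq. Because pulldown
composition tracks the transcriptome except where dsRNA content
changes, dsRNA fold changes are modelled as a linear function of total
fold changes; genes that deviate are the signal. The rule: fit
ordinary least squares (with intercept) of `lfc_dsrna` on
`lfc_total`, standardize raw residuals by their sample SD, and call
genes beyond ±2.5 standardized SDs enriched/depleted. Leverage-adjusted
studentization is available behind a flag but is not the default; with
thousands of genes the two are indistinguishable. Only genes called in
the same direction in both mutant comparisons enter the consistent
set, and the G/C composition of consistent sets is compared against
all genes with a two-sided Mann–Whitney U test (exact when both sides
have ≤25 values and no ties).

Fold changes are estimated simply: median-of-ratios size factors, then
`log2(mean normalized + 0.5)` differences. A shrunken
negative-binomial estimator would be better for low counts, but the
residual rule consumes fold changes from any estimator, and the
simple one keeps the stage self-contained; precomputed fold-change
tables can be supplied directly.

The count generator draws negative-binomial counts (variance
μ + μ²·φ, dispersion φ = 0.05) around log-normal baselines (median
200), with per-sample depth factors, a gene-level pulldown capture
efficiency that cancels in fold changes, and true fold changes shared
between assays except for the planted subset (default 1% enriched +
1% depleted, shifted ±2 log2 units identically in both mutants;
planted genes draw G/C near 0.6 against a 0.4 background). Under the
null (no planted genes) the flagged fraction matches the Gaussian
tail 2·(1−Φ(2.5)) ≈ 1.24% to within binomial error — slightly above
it in expectation, since residual variances are not perfectly
homogeneous across expression levels, which is worth remembering when
interpreting flag counts on real data.

## 4. Image quantification

The z-stack procedure has three steps. First, nuclei: the DAPI channel
is max-projected over z, thresholded (Otsu by default; a manual
threshold can be supplied), cleaned by morphological opening, labelled,
size-filtered (default ≥500 projected px) and stripped of
border-touching labels, whose truncated volumes would bias compartment
means. The projection mask then constrains per-slice segmentation: a
voxel belongs to a nucleus when its (y, x) is in that nucleus's
projection label and its DAPI intensity exceeds the threshold. Second,
nucleoli: the nucleolin channel is masked by the nuclei projection
(removing extranuclear signal) and segmented the same way at nucleolus
scale (default ≥20 px), and each nucleolus is assigned to the nucleus
whose footprint it overlaps most (ties: larger overlap, then lower
label, for determinism). Candidates larger than half their nucleus
footprint are rejected: nucleoli are substructures, and a "nucleolus"
the size of its nucleus means the channel had no nucleolar contrast.
Third, intensities: for each cell the signal channel is averaged over
nucleolar voxels and over the nucleoplasm (nucleus minus nucleoli);
the two compartments partition the nucleus voxel set by construction.
Compartment means are compared with a paired two-tailed t-test; when
the per-cell differences have zero variance the statistic is
undefined and the summary flags the degenerate case instead of
reporting a fabricated p-value.

Foci counting projects the stack to one plane (maximum, not sum — a
focus present in few slices should not be diluted), removes background
with a white top-hat (radius 4 px), and detects local maxima above a
prominence threshold; "non-overlapping" is realized as a minimum
separation between accepted maxima (default 3 px, brighter maxima
win). Counts are binned `<1` (exactly 0 — counts are integers), `1–5`,
`>5`.

The stack generator builds ellipsoidal nuclei on a jittered grid
(default 20 cells, 16×256×256 voxels), each with 1–3 ellipsoidal
nucleoli strictly contained and mutually disjoint. Channel intensities
are piecewise-constant before noise, with the signal channel exactly
`nucleolar_factor` (default 3, mirroring the observed nucleolar
enrichment at the observed sample size of 20 cells) times brighter in
nucleoli than nucleoplasm; additive Gaussian noise (SD 0.02 in [0, 1]
units) is applied, clipped at 0 and quantised to 16 bits. Real
confocal stacks differ in ways the generator deliberately omits —
Poisson photon statistics, PSF blur, intensity gradients, touching
nuclei — so passing tests demonstrate the correctness of the
measurement logic, not robustness to every imaging artifact; the
upstream segmentation parameters are the knobs to revisit on real
data.

## Determinism and problem sizes

All randomness flows from one integer seed; each generator draws from
its own fixed offset of it, so regenerating one data type never
perturbs another, and identical (seed, config) pairs produce
byte-identical files. The packaged tests and the acceptance script run
at desk scale by design: 100-transcript genomes, 20-species
alignments, 10,000-gene count matrices, 20-cell stacks (smaller
8-cell stacks inside the unit tests). These sizes put the Monte-Carlo
checks (null calibration within 3 binomial SDs, ≥95% planted
recovery, ratio recovery within 15%) comfortably inside their
tolerances while keeping a full run under a minute per stage.

## Known limitations

* The scanner assumes the annotation's stop codon is correct and never
  re-infers frames; GTF input must carry `stop_codon` features.
* The fold-change estimator is deliberately plain; strongly depleted
  low-count genes are shrunk by the pseudocount and are the main
  source of missed planted genes at default settings.
* Touching nuclei are not split (no watershed); the generator never
  produces them, but crowded real fields would need preprocessing.
* Mann–Whitney switches to the normal approximation with tie
  correction for all but small untied samples; exact p-values for
  large samples are out of scope.
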