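---
title: "Strand-resolved signal analysis at DNA double-strand breaks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved signal analysis at DNA double-strand breaks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbstrand)
```

## Scope and scientific background

`dsbstrand` implements the computational core of a strand-resolved analysis
of sequencing signal around sequence-specific DNA double-strand breaks
(DSBs), such as those induced by the AsiSI restriction enzyme in engineered
human cell lines. The biological questions it serves are: where do RNA:DNA
hybrids sit at a processed break (which strand, which side), how does
polymerase occupancy change under the global transcriptional repression that
follows damage, and does transcription elongation speed change after damage.

Three strand geometries organise everything:

* **Template strand.** The DNA strand complementary to the transcript: the
  Crick strand for a `+` gene, Watson for a `-` gene. A retained or nascent
  RNA can only hybridise with this strand.
* **Resected versus 3'-overhang strand.** End resection degrades the
  5'-terminated strand on each side of a break (5'→3'), leaving a 3'
  single-stranded overhang. Reading Watson 5'→3' left to right, on the
  right-hand fragment the Watson strand is 5'-terminated at the break
  (resected) and Crick is the overhang; mirrored on the left. This mapping
  follows directly from strand chemistry, but because most descriptions
  state it only pictorially, `split_by_resection()` encodes it explicitly:
  `resected(d) = crick_left(d) + watson_right(d)` and
  `overhang(d) = watson_left(d) + crick_right(d)`, with `d` the distance
  from the cut and both sides mirrored so `d = 0` abuts the break.
* **The coincidence that ties them together.** For a `+` gene, the template
  strand (Crick) is the 3' overhang on the gene-downstream (right) side of
  a cut; mirrored for `-` genes. One rule — *hybrids load on the template
  strand on the side where it is the overhang* — therefore simultaneously
  produces template-strand specificity, overhang-strand specificity and
  left/right asymmetry. The synthetic generator encodes exactly this rule,
  and the orientation module measures it back.

Coordinates are 0-based half-open throughout (BED convention); a cut at
`p` denotes the phosphodiester bond between `p - 1` and `p`, and the cut
bin belongs to the right-hand side of the break.

## DSB classification

`classify_dsb()` labels a break *transcription-coupled* (TC) when it lies
in the body of an expressed gene or within 1 kb upstream of its TSS
(`window` parameter, default 1000 bp). TC annotations subdivide into
`promoter` (within the window upstream, including the TSS bond),
`five_prime` (within the window downstream, inside the body) and
`gene_body`, with `exonic`/`intronic` labels for the intragenic classes.
Up to two annotations are kept per site — breaks near two expressed genes
are genuinely ambiguous — ranked by distance to the TSS. Published manual
annotations of this kind relied on *visible* nascent-transcription
coverage; the package abstracts that visual criterion into
`expression > threshold` (default 0), which is the only reasonable
machine-checkable substitute and is configurable.

One deliberate extension: when no expressed gene qualifies but the cut sits
inside a silent gene, the annotation reports that gene with `tc = FALSE`
rather than collapsing to `intergenic`. This keeps silent-gene breaks
distinguishable from true gene-desert breaks, and is what lets the
generator's `silent_gene` placement round-trip through the classifier.

The packaged annotation table (`load_dsb_annotation_fixture()`) is a
**synthetic stand-in** for a published manual annotation of 80 sites that
cannot be redistributed here: it reproduces every published category total
(80 sites; 65 TC / 15 silent; 31 promoter / 36 five-prime / 9 gene-body;
19 exonic / 26 intronic; 11 dual-annotated; 88% of TC annotations within
1 kb of a TSS) while identifiers and the site-to-label pairing are
invented. Counts computed from it are exact by construction; nothing about
individual sites should be read off it.

Control-gene selection (`select_control_genes()`) matches the damaged
genes' expression distribution by quantile binning (default quintiles,
edges from the damaged set's own empirical type-7 quantiles), excludes
genes within ±1 Mb of any cut and genes on an externally supplied
differential-expression list, and samples without replacement under a
fixed seed. The exclusion list is an *input*, not recomputed: such lists
derive from independent experiments.

## Coverage, strand routing and normalization

Tracks are per-chromosome binned vectors, one per strand, with bin values
holding signal mass (covered bases for fragment input), so binning
conserves totals exactly. Strand is derived from paired-end alignment
flags by bitmask containment — flags containing 80 or 160 are reverse
fragments, 96 or 144 forward, with reverse taking precedence for flags
containing both families — mirroring samtools-style flag filters. Because
library chemistry determines whether "forward" fragments report the Watson
or the Crick strand, `bin_fragments()` exposes an explicit `strand_invert`
switch instead of hard-coding either convention. bedGraph is the canonical
on-disk form (text, diffable); writing merges equal-value runs and omits
zeros, and reading reconstructs bins by overlap-weighted averaging, so a
write/load cycle is lossless at bin resolution.

Spike-in normalization is `1e6 / spike reads` per library. Damage-aware
normalization uses the TSS metagene: 40 upstream flank bins of 50 bp, 100
length-proportional body bins, 40 downstream flank bins (180 columns);
the scale factor is the mean over columns 30–50 (roughly −550 bp to +10%
of the body around the TSS, 1-based as metagene bins are conventionally
counted) in the damaged condition divided by the undamaged condition. The
factor is **applied by dividing the damaged track**: the published
procedure says only that factors were "applied", and division of the
numerator condition is the direction that equalizes genome-wide TSS
occupancy so that break-local changes remain visible. The choice is
recorded in the factor's provenance string and the track's `norm` tag.
Log2 fold-change tracks use a pseudocount (default 1 signal unit) to stay
bounded at zero-coverage bins.

## Profiles and statistics

Profile matrices are anchor-centred with per-output-bin mean track signal;
per-site quantification uses window *sums* (means differ only by the
constant window size; the choice is recorded in metadata). Averaged
profiles support the trimmed mean (the DRB/TT-seq metagene convention is
a 0.01 trim per tail). Paired comparisons use the two-sided Wilcoxon
signed-rank test with zero differences dropped, the exact null for
n ≤ 25 without ties, and the normal approximation with tie and continuity
corrections otherwise — the most widespread convention, chosen for
determinism. Boxplot summaries use type-7 (linear interpolation)
quartiles and the 1.5×IQR whisker/outlier rule; the quantile estimator is
stated explicitly because published boxplots rarely specify one and the
alternatives are visually indistinguishable.

## Elongation rates from DRB/TT-seq

After release from DRB inhibition, transcription restarts as a
synchronized wave whose front advances at the elongation rate. Per gene
and time point, coverage over −2 kb..+120 kb around the TSS in 100-bp
bins is smoothed with a cubic spline (`smooth.spline`, `spar = 0.3` — the
published metagene smoothing value; no per-gene value is published, so
the same stiffness is used per gene and exposed as a parameter). The
*wave peak* is the spline's maximum. Both the fit and the argmax are
restricted to bins downstream of the TSS: promoter-proximal signal is
often the tallest feature of a profile and, if included, its smoothed
shoulder can win or distort the argmax. Near-ties within a 1e-8 relative
tolerance resolve leftmost, for determinism.

Series are filtered out if any peak is missing, all peaks are identical
(static), or any peak fails to advance **strictly** past the previous time
point — the usual description of this filter (peaks must proceed past the
previous time point) is read here as requiring strict advance. Rates are the OLS slope of peak
distance (kb) on time (min); the cohort "average" is reported as the
median, with the mean alongside, since "average" is ambiguous and the
median is robust to the skewed per-gene rate distribution.

## The synthetic-data generator

`simulation_config()` fixes every study condition in one seeded object;
all stochastic stages derive independent RNG streams from the master seed
plus a stage name, so adding a track never changes another track's draws.
What each emulated assay contains, and what it deliberately omits:

* **qDRIP-seq**: uniform background; baseline R-loops on the template
  strand over each expressed gene's first 1.5 kb (amplitude ∝ expression);
  after damage, at TC breaks only, an exponential-decay hybrid
  (default decay length λ = 800 bp — profiles of this kind span ±1–2 kb,
  but no decay length is published, so λ is a free parameter, not a
  claim) on the template strand on the overhang side, amplitude ∝
  expression × cleavage. Hybrid amplitude several-fold the local baseline
  reflects the strong induced asymmetry these experiments show.
* **END-seq**: per side, the survival function `exp(-d/L)` of an
  exponential resection-length law on that side's overhang strand, with
  defaults L(4 h) = 1 kb and L(24 h) = 3 kb — order-of-magnitude values
  for early versus late resection, not published numbers. The polarity
  assignment is a generator convention sufficient for testing extent and
  bidirectionality; real END-seq chemistry is out of scope.
* **RPA ChIP-seq**: the same resection-span shape on the overhang strand,
  with a (1 + β) boost within 500 bp of the cut on the hybrid side of TC
  breaks (β = 1), emulating break-proximal ssDNA occupancy enhancement.
* **RNAPII ChIP-seq**: Gaussian TSS peaks (σ = 200 bp) plus body plateaus
  ∝ expression, split evenly across strands (ChIP is unstranded). After
  damage the *entire per-gene profile* is scaled by the global repression
  factor `g` (default 0.7), damaged genes additionally by the local
  eviction factor (0.5). Scaling the whole occupancy profile — rather
  than the TSS peak alone — is what makes the TSS-window scale-factor
  estimator a consistent estimator of `g`, which is the purpose of the
  recovery benchmark.
* **TT-seq**: sense-strand body coverage ∝ expression, attenuated
  downstream of the cut at damaged genes after damage.
* **DRB/TT-seq**: per long gene, a plateau from the TSS to the front at
  `rate × t` plus a Gaussian crest (σ = 1.5 kb) at the front, at time
  points 5, 10, 20, 30, 40 min; the shipped `default_drb.yaml` sets the
  true rate to 2 kb/min, 55 genes of 85–118 kb (all > 60 kb, the standard
  length filter; the lower bound of 85 kb keeps the 40-min front at 80 kb
  inside every gene body so no series is truncated).

All signal is Poisson-sampled per bin at a depth giving tens to hundreds
of counts in signal regions. The generator emulates the *statistical
structure* these analyses assume — strand routing, amplitudes, decay
scales, repression factors, counting noise. It does not emulate read-level
artefacts, mappability, sequence composition, replication timing,
antibody-efficiency variation or the correlated noise of real libraries.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated under the generative model, not that real
data meet that model.

## Numerical choices and degenerate inputs

* Windows must be multiples of the bin size; anchors too close to a
  chromosome edge are dropped with a warning in profile construction but
  are hard errors in single-window operations.
* The cut bin belongs to the right side of a break (half-open
  convention); orientation flips swap strand labels because reversing a
  genomic window reverses reading direction.
* Dominant-side orientation does not flip ties; site ranking breaks score
  ties by `dsb_id`; both for determinism.
* All-zero paired differences give p = 1 with a warning rather than an
  error, since downstream tabulation should not abort on a degenerate
  site set.
* The per-damaged-copy hybrid-frequency estimate divides the hybrid
  frequency range (default 5–10%, the single-molecule R-loop frequency of
  strongly R-loop-forming benchmark genes) by the cleaved-fraction range
  (default 10–20%): point estimate 50% from the midpoint ratio, with the
  cross-bound range 25–100% reported alongside and capped at 100%.

## Problem sizes used in validation

The shipped validation suite runs at desk scale: a 3-Mb single-chromosome
genome with 60 genes and 22 breaks for geometry checks; 200 genes on
10 Mb for scale-factor recovery at g ∈ {0.5, 0.7, 0.9}; 55 genes for the
elongation cohort; 2,000 null replicates at n = 65 for signed-rank
calibration. These sizes give stable recovery (the cohort median rate
lands within ±0.01 of truth; scale factors within ~1%) while keeping the
full suite around a minute of compute.

## Known limitations

* The classifier's `expression > 0` rule cannot reproduce borderline
  judgement calls of a by-eye annotation; the packaged fixture carries
  final labels precisely so that category accounting does not depend on
  re-deriving them.
* Resection is summarized by an exponential length law; real resection
  endpoints have structure (nucleosome phasing, CtIP/EXO1 kinetics) that
  the generator does not model.
* The elongation estimator assumes a single advancing front per gene;
  genes with internal TSSs or strong intronic signal can mislocalise the
  wave peak — the missing/static/non-advancing filters are the only
  guard.
* bigWig output is not produced; bedGraph is the interchange format, and
  conversion is a one-liner with standard genome-arithmetic tools.
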