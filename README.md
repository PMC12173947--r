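# dsbstrand

Strand-resolved analysis of sequencing signal around sequence-specific DNA
double-strand breaks (DSBs).

## The problem

At breaks induced inside or just upstream of actively transcribed genes
(transcription-coupled DSBs, TC-DSBs), RNA:DNA hybrids accumulate with two
striking geometric signatures: they sit on the **template strand** of the
damaged gene, and on the **3'-overhang strand** left by 5'→3' end
resection, asymmetrically on one side of the break. Meanwhile damage
triggers a genome-wide drop in RNA polymerase II occupancy that must be
normalized away before break-local changes can be quantified, and
DRB/TT-seq transcription-wave experiments ask whether elongation *speed*
changes after damage. `dsbstrand` provides the full computational tool
chain for these analyses, aimed at genomics analysts working with
strand-specific coverage around engineered break sites (AsiSI/Cas9
systems): qDRIP-seq, END-seq, RPA and RNAPII ChIP-seq, TT-seq and
DRB/TT-seq.

## What it computes

* **DSB classification** — TC vs silent; promoter / 5' region / gene body
  (1-kb windows around the TSS); exonic / intronic; up to two annotations
  per site; expression-matched control-gene selection with ±1 Mb
  exclusion.
* **Strand geometry** — with `d` the distance from the cut and the two
  sides folded together:
  `resected(d) = crick_left(d) + watson_right(d)`,
  `overhang(d) = watson_left(d) + crick_right(d)`;
  template-strand assignment (`+` → Crick); orientation of profile
  matrices by gene direction or hybrid dominant side; ranking of sites by
  induced signal gain.
* **Normalization** — spike-in factors (`1e6 / spike reads`); the
  TSS-metagene scale factor `mean(+DSB) / mean(−DSB)` over bins 30–50 of
  the 40 + 100 + 40 metagene layout, applied by dividing the damaged
  track; log2 fold-change ratio tracks.
* **Profiles & statistics** — anchor-centred matrices, trimmed-mean
  average profiles, windowed per-site quantification, paired two-sided
  Wilcoxon signed-rank tests, 1.5×IQR boxplot summaries.
* **Elongation rates** — per-gene DRB/TT-seq wave peaks by smoothing
  spline (`spar = 0.3`) on −2 kb..+120 kb coverage of genes > 60 kb,
  missing/static/non-advancing filters, OLS of peak distance (kb) on time
  (min): the slope is the rate in kb/min.
* **Synthetic data** — a seeded generator that emulates all of the above
  assays with known ground truth (hybrid side and amplitude, resection
  lengths, repression factor `g`, true elongation rate), used throughout
  the test suite for parameter-recovery validation.

## Worked example

```r
library(dsbstrand)

## 1. Category accounting on the packaged annotation table
str(summarize_categories(load_dsb_annotation_fixture()))
#> List of 11
#>  $ n_total           : int 80
#>  $ n_tc              : int 65
#>  $ n_silent          : int 15
#>  $ n_promoter        : int 31
#>  $ n_five_prime      : int 36
#>  $ n_gene_body       : int 9
#>  $ n_exonic          : int 19
#>  $ n_intronic        : int 26
#>  $ n_dual            : int 11
#>  $ n_within_gene     : int 45
#>  $ pct_within_1kb_tss: num 88
```

Of 80 break sites, 65 are transcription-coupled and 15 silent; 88% of TC
annotations lie within 1 kb of a transcription start site. (The packaged
table is a synthetic stand-in constructed to match the published totals —
see `?load_dsb_annotation_fixture`.)

```r
## 2. Overhang vs resected strand at simulated TC breaks
cfg  <- simulation_config(seed = 42)
gn   <- simulate_genome(cfg)
dsbs <- simulate_dsbs(cfg, gn)
tb   <- simulate_tracks(cfg, gn, dsbs)
tc   <- dsbs[dsbs$tc, ]
sp_p <- split_by_resection_sites(tb$tracks$qdrip_plus,  tc, 2000)
sp_m <- split_by_resection_sites(tb$tracks$qdrip_minus, tc, 2000)
ov <- rowSums(sp_p$overhang) - rowSums(sp_m$overhang)  # induced gain
rs <- rowSums(sp_p$resected) - rowSums(sp_m$resected)
round(c(mean_overhang = mean(ov), mean_resected = mean(rs)), 1)
#> mean_overhang mean_resected
#>        3366.8         155.9
signif(paired_wilcoxon(ov, rs), 3)
#> [1] 3.05e-05
```

The damage-induced hybrid signal lands overwhelmingly on the 3'-overhang
strand (here >20-fold the resected strand), and the paired signed-rank
test confirms the asymmetry across sites.

```r
## 3. Elongation-rate recovery from the default DRB/TT-seq simulation
cfg <- config_from_yaml(system.file("extdata", "default_drb.yaml",
                                    package = "dsbstrand"), seed = 42)
res <- cohort_rate(simulate_drb_timecourse(cfg)$timecourses)
c(median = res$summary$median_rate, n_pass = res$summary$n_pass)
#> median n_pass
#>      2     55
```

The wave-peak/regression estimator recovers the programmed elongation
rate of 2 kb/min across all 55 simulated genes.

A command-line wrapper for full runs (simulate → classify → strandsplit →
normalize → quantify → elongation, each writing a JSON run manifest) is
at `inst/scripts/dsb_pipeline.R`; see `?run_pipeline`.

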