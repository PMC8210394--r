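# hapmark

Histone-mark enrichment on disease-risk haplotypes, TAD gene mapping, and
differential-expression cross-referencing — as one tested, reproducible R
pipeline.

## The problem

GWAS tag SNPs index linkage-disequilibrium (LD) blocks, not causal
variants; for intracranial aneurysm, 16 replicated risk blocks (bundled
here with hg38 coordinates, sentinel rsIDs and nearest genes) are mostly
non-coding. The question is whether these blocks are unusually rich in
enhancer-associated chromatin (H3K4me1 / H3K27ac / H3K9ac ChIP-seq peaks)
in particular cell types, and if so, which genes — those sharing a
topologically associated domain (TAD) with the marked blocks — might be
the targets, and whether those genes are also differentially expressed in
diseased tissue.

For each (cell type, mark) peak set the package computes the observed
count *x* of blocks carrying ≥ 1 peak and scores it against an empirical
null: the same count measured on matched-length random regions sampled
uniformly from the genome over *N* iterations (default 1000), summarised
by mean μ and standard deviation σ, giving

    z = (x − μ) / σ

with a one-sided normal p-value, plus a rank-based empirical p-value
(1 + #{null ≥ x}) / (1 + N). Cell types with significant activating
marks are gated into the TAD stage (with an H3K9me3 closed-chromatin
check); their marked blocks are mapped to encompassing domains, domain
gene rosters are enumerated, and rosters are cross-referenced with
differential-expression tables.

A seeded synthetic-data module generates every input — toy genome, blocks
(published length multiset), peak sets with a controllable planted
per-block probability π over a uniform Poisson background, TAD
partitions, gene models, DEG tables — with recorded ground truth, so the
entire pipeline is exercisable and calibratable offline.

## Worked example

```r
library(hapmark)

blocks <- ia_ld_blocks()            # the 16 bundled risk LD blocks
head(interval_length(blocks))
#> [1]  7587 26269 74930 90316 49312 20830

dir <- tempfile("sim_")
cfg <- sim_config(planted_prob = 0.9)      # enrichment planted for HUVEC
sim <- simulate_dataset(cfg, dir, seed = 42)
report <- run_pipeline(run_config_from_dir(dir, iterations = 1000,
                                           seed = 43, gating = "all"))
print(report)
#> <run_report> 6 peak sets tested, gated cell types: HUVEC
#>   HUVEC_H3K27ac            x = 15  z =   4.52  p_z = 3.053e-06 †
#>   HUVEC_H3K4me1            x = 16  z =   5.04  p_z = 2.281e-07 †
#>   HUVEC_H3K9ac             x = 15  z =   4.46  p_z = 4.17e-06 †
#>   SMC_H3K27ac              x =  6  z =  -0.04  p_z = 0.5177
#>   SMC_H3K4me1              x =  3  z =  -1.45  p_z = 0.9262
#>   SMC_H3K9ac               x =  3  z =  -1.51  p_z = 0.9342
```

The planted cell type (HUVEC, π = 0.9) shows 15-16 of 16 blocks marked
against a null mean around 6, z-scores of 4.5-5 and p-values far below
0.05, so it alone passes the gate; the pure-background cell type (SMC)
sits at the null. Downstream, the gated cell type's marked blocks map to
TADs and genes:

```r
fr <- report$deg_fraction[["HUVEC"]]
sprintf("HUVEC DEG share: %d/%d = %.1f%%", fr$n_deg, fr$n_transcripts,
        fr$pct_exact)
#> [1] "HUVEC DEG share: 21/177 = 11.9%"
report$overlap[["HUVEC"]]$n_tads_with_deg   # 13 of 16 TADs contain a DEG
#> [1] 13
```

For the published study counts, `transcript_deg_percentage(20, 164)` and
`transcript_deg_percentage(19, 153)` both round to 12%. The published
tissue DEG records (8 studies, 25 genes) ship as `ia_deg_records()`.

## Analysis workflow

The `analysis/` scripts run the full study on synthetic data, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # dataset + ground truth
Rscript analysis/02_enrichment.R    # enrichment matrix, gating, H3K9me3
Rscript analysis/03_tads_degs.R     # TAD rosters, DEG overlap, recovery
Rscript analysis/04_calibration.R   # type-I error and power study
```

The calibration step compares the fixed mean-length null (conservative
for length sets this dispersed), the length-resampling null (nominal
type-I), and the rank-based empirical p (conservative at 16 discrete
regions) — see the methods vignette
(`vignettes/haplotype-enrichment-methods.Rmd`) for why.

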