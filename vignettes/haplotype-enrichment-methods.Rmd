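---
title: "Scoring histone-mark enrichment on risk haplotypes and mapping TAD genes"
author: "hapmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring histone-mark enrichment on risk haplotypes and mapping TAD genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapmark)
```

## The question the pipeline answers

Genome-wide association studies tag disease risk loci with sentinel SNPs,
but each tag indexes a whole linkage-disequilibrium (LD) block of
co-inherited variants, most of them non-coding. For intracranial aneurysm
(IA), 16 such blocks (mean length ~30.6 kb; bundled as `ia_ld_blocks()`)
carry the replicated risk signal. If risk operates through regulatory
elements rather than coding changes, the blocks should be unusually rich
in enhancer-associated chromatin — H3K4me1, H3K27ac and H3K9ac ChIP-seq
peaks — in the cell types where the risk is exerted, and the genes those
enhancers can reach (which, to a good approximation, are the genes in the
same topologically associated domain, TAD) should be over-represented
among genes differentially expressed in diseased tissue.

`hapmark` implements that chain as four testable stages:

1. **Enrichment**: per (cell type, histone mark) peak set, compare the
   number of LD blocks carrying at least one peak with the distribution
   of the same count over random genomic regions of matched length.
2. **Gating**: carry forward only cell types with significant
   activating-mark enrichment, and check those for closed-chromatin
   (H3K9me3) peaks on the blocks.
3. **TADs**: map each marked block to the domain(s) encompassing it and
   enumerate the genes in those domains.
4. **DEGs**: cross-reference the TAD gene rosters with published
   differential-expression tables.

## The enrichment statistic and its null

All coordinates are 0-based half-open (BED); an interval's length is
`end - start`, which reproduces the published block lengths exactly.
A block and a peak overlap when they share at least one base; abutting
intervals do not overlap. Strand is ignored everywhere.

The observed statistic is $x$, the number of query blocks overlapped by
one or more peaks (0-16 here). An optional pair-count mode (total
overlapping block-peak pairs) is provided because region-level and
pair-level readings of "number of intersections" are both defensible;
region-level is the default and matches counting "how many of the 16
regions overlapped".

The null repeats the measurement `iterations` times (default 1000) on
random regions sampled uniformly from the genome: a chromosome is chosen
with probability proportional to the number of valid placements
(`chrom_len - region_len + 1`), then a start position uniformly within
it. Regions within one draw may overlap each other; no exclusion is
applied. From the null counts the mean $\mu$ and population standard
deviation $\sigma$ (ddof = 0, fixed for determinism) give

$$z = \frac{x - \mu}{\sigma},$$

converted to a one-sided upper-tail normal p-value (`p_z`); enrichment is
the hypothesis, so the upper tail is the default and a two-sided option
is a flag. A rank-based empirical p-value

$$p_{\mathrm{emp}} = \frac{1 + \#\{\text{null counts} \ge x\}}{1 + \text{iterations}}$$

is always reported alongside. When $\sigma = 0$ (empty or saturated
null), the result carries an explicit degenerate flag, $z$ is reported as
a limit ($\pm\infty$ or 0) and `p_emp` is the value to trust.

Two null-length conventions are available:

* `"mean"` — every random region has the rounded mean block length
  (30,636 bp for the bundled set). This is the conventional
  matched-average-length construction.
* `"resample"` — each null draw reuses the actual 16 block lengths.

### What the calibration study shows

`analysis/04_calibration.R` measures the type-I error of both
conventions on pure-null synthetic data at the study operating point
(16 blocks with the bundled length multiset, 15 peaks/Mb background).
Two effects matter:

* The probability that a region is marked is concave in its length
  (approximately $1 - e^{-\lambda(L + \bar\ell)}$ for peak density
  $\lambda$ and mean peak length $\bar\ell$). With block lengths as
  dispersed as these (2.1-90.3 kb), a null built at the mean length
  overstates the background marking rate (Jensen's inequality), making
  the `"mean"` variant conservative (measured type-I ~0.01-0.02 at
  $\alpha = 0.05$).
* With only 16 regions the count statistic is heavily tied, so the
  add-one rank-based `p_emp` is super-uniform and likewise conservative
  (~0.01), whichever null is used. Uniformity of `p_emp` is recovered
  for large region counts (the test suite checks 1024 regions).

The `"resample"` null with the z-score p-value is well calibrated
(measured type-I ~0.04, inside the 95% binomial CI of 0.05 over 500
replicates), so the package's calibration and power studies use that
variant. Both conventions are available, neither is ever
anticonservative under the uniform background, and power against planted
per-block enrichment ($\pi = 0.9$ over a sparse background) is ~1 for
every variant.

## Gating, TADs and gene rosters

A cell type passes the gate when its activating marks are significant at
`alpha` (default 0.05) on `p_z`. Two policies exist: `"any"` (one
significant available mark suffices — the permissive reading, and the
default, since a cell type may have a single usable dataset) and
`"all"` (every available activating mark must be significant). The
ground-truth-recovery experiments on synthetic data use `"all"`: with
three independent activating marks per cell type, a pure-null cell type
passes an `"any"` gate with probability $1 - 0.95^3 \approx 14\%$ by
construction of a calibrated test, so the permissive gate cannot be
expected to reproduce the planted gate exactly on every seed; the
conjunctive gate has false-gating probability $\approx 10^{-4}$ at
essentially no cost in power. H3K9me3 (closed chromatin) never
participates in gating; for gated cell types with significant H3K27ac it
is checked for bare per-block presence.

Blocks marked by any significant mark are mapped to TADs with rule
`encompass`: all domains fully containing the block (nested and
overlapping domain calls are all returned, and the gene union is used).
A block spanning a domain boundary falls back to all overlapping domains
and is flagged `partial`. Genes are attached to domains by `overlap`
(>= 1 bp, the most inclusive reading of "encompassed"); `contained` and
`tss_within` are selectable, and under `tss_within` a gene maps to at
most one domain of a partition. Rosters are deduplicated, sorted gene
symbols — "transcripts" are counted at gene-symbol level.

DEG matching is exact after uppercasing and whitespace stripping; no
alias or HGNC resolution is attempted, a real limitation given the
heterogeneous nomenclature of published DEG lists. A TAD "contains a
DEG" if any roster gene matches any record passing the comparison
filter, regardless of direction, and conflicting directions across
studies are preserved as separate rows. The refinement figure
(`deg_fraction_of_transcripts()`) is
$100 \cdot |{\rm roster} \cap {\rm DEGs}| / |{\rm roster}|$, reported
with numerator and denominator; from the published counts, 20/164 and
19/153 both round to 12%.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 16 non-overlapping
blocks whose length multiset is the bundled published set; background
peaks as a homogeneous Poisson process (15 peaks/Mb, the density scale
of ENCODE-grade histone peak sets) with lognormal lengths (median 1 kb,
sdlog 0.5); a planted per-block peak probability $\pi$ (0 = exact null;
background peaks may still fall in blocks, keeping the null exactly the
uniform model the test assumes); TADs tiling a 4 x 25 Mb toy genome with
sizes uniform on 0.5-1.5 Mb, boundaries nudged off blocks so containment
is guaranteed by construction (a `boundary_spanning` switch disables the
nudge to exercise the partial-containment fallback); ~12 genes per TAD
(Poisson), matching the observed ~164 transcripts over 13 domains; and a
6% DEG fraction per comparison, whose union over the two comparisons
lands near the published ~12% combined share, plus decoy DEG symbols
absent from the annotation. Every planted item is recorded as ground
truth, and all emitted files are byte-identical under a fixed seed
(per-component sub-seeds are derived from the master seed;
per-iteration null seeds are prefix-stable, so extending the iteration
count does not reshuffle earlier draws).

The generator does not emulate: sequence context (GC, repeats, peak
clustering), which real ChIP-seq peaks have and the unconstrained
uniform null ignores; LD structure itself; read-level noise or peak
calling; hierarchical/nested real TAD calls; or gene-symbol aliasing.
Passing tests therefore certify the statistical machinery and the
interval bookkeeping under the stated model, not robustness to those
real-data features — in particular, a GC- or distance-matched null
(GREGOR/GoShifter-style) is out of scope by design, as the procedure
being implemented uses unconstrained uniform sampling.

## Numerical and engineering choices

* Overlap counting in the null loop uses a sorted per-chromosome index
  (`#\{peak starts < end\} - #\{peak ends <= start\}`), whose contract is
  equality with the all-pairs definition; property tests enforce this
  against a brute-force oracle, and the public `intersect_counts()` goes
  through IRanges overlap machinery.
* Degenerate inputs: empty peak sets give $x = 0$ and a degenerate null,
  never a significance claim; empty TAD sets warn and assign nothing;
  zero-length intervals are rejected at construction.
* Chromosome naming dialects are not normalized; a zero-overlap result
  with disjoint name sets raises a warning pointing at the likely
  `chr`-prefix mismatch.
* Peak files are consumed as published (no score filter) by default; a
  minimum-score option exists because published peak sets differ in
  post-processing.
* Problem sizes in the bundled studies (500 null replicates with
  200-iteration nulls for calibration, 200 for power, 1000 iterations
  for single runs) were chosen so each study completes in minutes on one
  core while leaving the measured properties unchanged at the full
  1000-iteration setting.

## Known limitations

The z-score p-value inherits a normality assumption that is visibly
coarse for 16 discrete regions; the empirical p-value is the safe,
slightly conservative companion and both are always reported. Gene-level
counting understates transcript-level multiplicity. Real TAD and DEG
inputs depend on the annotation and domain-calling choices of their
sources; counts such as "164 transcripts" are not reproducible from
coordinates alone and are not asserted anywhere. The multiple
(cell type x mark) tests are reported raw, matching the original
procedure; a Benjamini-Hochberg column can be added trivially by the
caller (`p.adjust`), and the absence of any correction should be kept in
mind when reading the significance daggers in the matrix output.
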