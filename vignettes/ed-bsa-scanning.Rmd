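---
title: "Euclidean-distance scanning for bulked-segregant QTL mapping"
author: "edscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euclidean-distance scanning for bulked-segregant QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscan)
```

## The method

Bulked-segregant analysis (BSA-seq) localizes quantitative trait loci by
sequencing two pools of individuals drawn from the opposite tails of a
trait distribution — here a HIGH and a LOW bulk — and comparing their
allele frequencies along the genome. At a SNP unlinked to the trait, both
bulks are random samples from the same panel and their allele-frequency
vectors agree up to sampling noise. Near a causal locus, tail selection
drives the bulks apart.

The per-SNP statistic is the Euclidean distance between the two pools'
allele-frequency vectors,

$$\mathrm{ED} = \sqrt{\sum_a (H_a - L_a)^2},$$

where $H_a$ and $L_a$ are the frequencies of allele $a$ in the high and
low pool. For a biallelic SNP, $\mathrm{ED} \in [0, \sqrt 2]$, reaching
$\sqrt 2$ when the pools are fixed for opposite alleles; it is symmetric
under pool swap. Raising ED to a power ($\mathrm{ED}^x$, default $x = 2$)
suppresses background noise relative to signal, since noise EDs are well
below 1 and signal EDs approach it.

The genome scan then proceeds in four steps, all exposed individually and
orchestrated by `ed_scan()`:

1. **Smoothing.** The per-SNP $\mathrm{ED}^x$ profile is noisy
   (binomial read sampling on top of binomial bulk sampling). We fit it
   with a tricube-kernel local weighted mean over physical distance:
   $w(d) = (1 - (|d|/b)^3)^3$ for $|d| < b$, with half-window $b$
   (`bandwidth`, default 2 Mb). This smoother preserves constants
   exactly, keeps every fitted value inside the data range of its window,
   and admits an exact brute-force oracle — the properties that drove its
   selection over heavier local-regression fits. Degree-1 loess was
   considered and rejected because it can overshoot the data range at
   peak shoulders, which interacts badly with a variance-based threshold.
2. **Thresholding.** Per chromosome, the significance threshold is the
   median plus three standard deviations of the fitted profile. The
   median (not the mean) resists inflation by the peak itself; the
   per-chromosome scope follows the practice of reporting one threshold
   per chromosome per replicate.
3. **Region calling.** Candidate regions are maximal runs of consecutive
   SNPs with fitted value *strictly above* the threshold (ties stay
   below); runs separated by less than `merge_gap` (default 100 kb) are
   merged. Region bounds are the first and last SNP positions of the run,
   not padded interval bounds.
4. **Replication.** Regions called independently in replicate years are
   intersected per chromosome (`intersect_regions()`); only overlaps
   `[max(starts), min(ends)]` survive. This is the step that removes
   single-year background excursions, which the per-chromosome
   median + 3 SD rule alone does not fully control.

Region sizes are reported as `end - start` in Mb, rounded
half-away-from-zero to 4 decimals; on the published replicated soybean
intervals this convention reproduces the printed sizes exactly
(e.g. 14333783..14628947 on Chr2 is 0.2952 Mb, and the four intervals
total 0.8636 Mb).

## Variant QC

`qc_filter()` applies the standard pooled-variant filters before
scanning, in this order:

* **Validity:** a pool's observation is a valid genotype only with at
  least `min_depth` (default 5) reads; below that it is treated as
  missing.
* **Site missingness:** sites missing in more than `max_site_missing`
  (default 0.5) of the pools are excluded. With two pools this drops
  exactly the sites missing in both.
* **MAF:** the pooled minor-allele frequency, computed from the combined
  ref/alt depths of the valid pools, must reach `min_maf` (default 0.2),
  boundary inclusive. Only biallelic SNPs enter the table at read time;
  indels and multiallelic records are dropped by `read_variant_vcf()`.

A site can survive QC with only one valid pool (the missingness rule
permits it), but the ED statistic needs both; `ed_scan()` excludes such
sites with a message rather than erroring, so the two rules compose.
The per-sample missingness and heterozygote-call parameters
(`max_sample_missing`, `het_min_reads`) belong to per-variety array
genotyping; they are carried in `qc_params()` for completeness but are
inert in two-pool mode, where a 30% sample filter over two samples is
meaningless. `marker_density()` summarizes the retained map in 500 kb
half-open windows plus adjacent-marker gaps.

## The simulator and what it does (and does not) emulate

No pooled sequencing data are deposited with the motivating study, so the
package ships a forward simulator (`sim_bsa_panel()`) that provides a
ground-truth surface for every downstream stage. It emulates:

* a multi-chromosome SNP panel with allele frequencies drawn uniformly
  from `maf_range` (default 0.1–0.9, a panel already screened for
  common variants);
* linkage via a Markov renewal ("copying") process along each haplotype:
  between adjacent SNPs separated by `d` bp the ancestral allele is
  redrawn with probability `r = min(0.5, d × 1e-8 × recomb_scale)`.
  Correlation with a causal locus decays roughly like
  `exp(-d × 1e-8 × recomb_scale)`; the default `recomb_scale = 50`
  makes association peaks a few Mb wide, matching the default 2 Mb
  smoothing bandwidth and the Mb-scale intervals reported in real
  soybean panels. One consequence of the renewal construction is that
  realized marginal frequencies are a local smoothing of the nominal
  per-SNP frequencies — acceptable for a scan test-bed, but not a
  population-genetic model;
* a quantitative trait: phenotype = Σ effect × dosage + Gaussian noise,
  with the noise variance set from the *realized* genetic variance so
  the genetic variance fraction equals `h2`. Replicate years share
  genotypes and redraw noise. `h2 = 0` produces a pure-noise (null)
  trait;
* extreme-bulk selection (`select_bulks()`): round-half-up of `q × n`
  individuals per tail, ties broken by individual id, so selection is
  deterministic and permutation-invariant. At 85 individuals and 15%
  tails this yields 13 + 13, the bulk scale of the motivating design;
* pooled sequencing (`sim_pool_reads()`): per site and pool, depth
  ~ Poisson(`depth`), alternate reads ~ Binomial with the pooled
  frequency folded through a symmetric error
  `p' = p(1-e) + (1-p)e` — the standard pooled-seq approximation.

It does **not** emulate coalescent or pedigree structure, population
stratification, linked selection, reference bias, mapping artifacts, or
read-level errors (no FASTQ). Passing tests on this generator therefore
demonstrate that the scan machinery recovers loci under idealized pooled
sampling — not that it is robust to the full error structure of real
resequencing data.

All randomness flows from one master seed expanded into stage-specific
substreams (`derive_seeds()`), and `run_pipeline()` records every
substream plus output checksums in its manifest; reruns are
bit-identical.

## Numerical and design choices

* **ED formula.** The source text names the statistic and describes H
  and L but does not print the formula; the Euclidean distance over the
  two pools' allele-frequency vectors is the single interpretive anchor
  of the package, consistent with "ED tends to zero when pools do not
  differ" and with the statistic's published use in pooled scans. The
  allele space is 2-dimensional (ref/alt) after QC.
* **Exponent.** `power = 2` by default (`ED²` is the associated value
  used in the motivating analysis); any `x ≥ 1` is accepted and the
  transform is rank-preserving.
* **Threshold scope.** Median + 3 SD is computed on the *fitted* values,
  per chromosome. Raw per-SNP values would inflate the SD with read
  noise; genome-wide pooling would let one long peak distort all
  chromosomes.
* **Boundary conventions.** Windows in `marker_density()` are half-open
  `[kw, (k+1)w)` (0-based internally, 1-based in I/O). Region membership
  uses strict `>` at the threshold. Gene-to-region overlap requires ≥ 1
  shared bp in 1-based inclusive coordinates (a containment-only mode is
  available). BED output is 0-based half-open; all TSVs are 1-based.
* **Rounding.** Mb sizes round half-away-from-zero (not banker's
  rounding) to 4 decimals, matching printed tables.
* **Degenerate inputs.** Thresholds require ≥ 2 sites (SD undefined
  below); phenotype summaries require n ≥ 4 and non-constant values;
  bulk selection refuses all-identical phenotypes; a smoothing bandwidth
  below the median marker gap triggers a warning (the fit degenerates
  toward the raw profile).

## Problem sizes used in the shipped validation

The package's tests exercise the full pipeline at the scale of the
motivating design: 200 individuals, five 50-Mb chromosomes at 20 SNPs/Mb
(~5000 SNPs), 15% tails, 50× pooled depth, two replicate years, twenty
replicate seeds, for both an `h2 = 0.8` single-QTL trait and an `h2 = 0`
null trait. Component-level checks (smoother oracle, interval algebra,
QC accounting) run on hand-sized fixtures where expected values are
enumerable by brute force. The same replicated-design simulation is what
`scripts/acceptance.R` reruns from scratch.

## Known limitations

* The median + 3 SD rule is a background-noise heuristic, not a
  calibrated genome-wide error rate; single-year scans regularly show
  background excursions, and replication across years is the intended
  control.
* On a chromosome where a broad peak occupies a large fraction of the
  map, the peak inflates its own chromosome's SD and can mask itself;
  this matters for short chromosomes or very wide linkage.
* Pool allele frequencies are treated as plug-in estimates; no shrinkage
  or coverage weighting is applied at low depth beyond the validity
  filter.
* The simulator's linkage process is a test-bed, not a demographic
  model; absolute recovery rates on it should not be read as field
  performance.

## A minimal worked example

```{r example, eval = FALSE}
truth <- sim_bsa_panel(200, c(Chr1 = 50e6, Chr2 = 50e6, Chr3 = 50e6),
                       snp_per_mb = 20,
                       qtls = list(qtl_spec("Chr2", 25e6, effect = 1)),
                       h2 = 0.8, n_years = 2, seed = 1)
regions <- lapply(1:2, function(y) {
  bulks <- select_bulks(truth$pheno[, y], 0.15, 0.15)
  sites <- sim_pool_reads(truth, bulks, depth = 50, seed = y)
  ed_scan(qc_filter(sites))$regions
})
intersect_regions(regions[[1]], regions[[2]], strict = FALSE)
```
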