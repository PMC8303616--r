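---
title: "Methods: window scans, ROH calling and the two-population simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window scans, ROH calling and the two-population simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

This vignette documents the statistical models behind `popgenscan`, the
parameters that matter, the numerical conventions, and what the synthetic
data generator does and does not emulate.

## The genotype model

Everything operates on a samples × variants matrix of diploid calls at
biallelic SNPs, coded by alternate-allele dosage (0 = hom ref, 1 = het,
2 = hom alt, `NA` = missing). Phase is never used: `0/1` and `1/0`, phased
or unphased, are the same heterozygote. Coordinates are 1-based inclusive
as in VCF; window arithmetic internally converts to 0-based half-open
intervals `[start, end)` and window tables report those 0-based bounds
(BED-compatible).

## Site filtering

`apply_site_filters()` applies four rules in a fixed order:

1. genotypes with depth below `min_genotype_depth` (default 10×) become
   missing;
2. sites with quality below `min_site_qual` (default 20) are removed;
3. sites with call rate below `min_call_rate` (default 0.9) are removed —
   computed over **all** samples, not per population;
4. monomorphic sites (all non-missing calls the same homozygote) are
   removed.

The order matters and is deliberate: depth masking happens first so that
low-depth genotypes can push a site below the call-rate threshold or make
it monomorphic — the conservative reading when no order is prescribed. The
call-rate threshold is exposed rather than fixed because reasonable
analyses use anything from 0.9 (combining heterogeneous cohorts) to 1.0
(a single dense cohort); the package takes no default position beyond 0.9.

Cohort sequencing summaries (`cohort_summary()`) report means and sample
standard deviations at 2 decimals. Exact half-way ties at the final decimal
round toward zero: summaries of inputs that are themselves printed at 2
decimals regularly land exactly on `x.xx5`, where IEEE half-even rounding
would let the reported digit depend on floating-point accumulation dust.
Breadth-of-coverage thresholds follow the convention that a threshold of 0
means *strictly greater than 0×* while any other threshold means *at least
t×*.

## Pooled heterozygosity (Hp, ZHp)

For each SNP, the major allele is whichever of ref/alt is more frequent
among non-missing calls (ties break to ref — Hp is tie-invariant, the rule
only fixes the reported count columns). Allele counts are
`2·homozygotes + heterozygotes`. Over the SNPs of a window,

$$ Hp = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
            {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2} \in [0, 0.5], $$

and windows are standardised genome-wide,
$ZHp = (Hp - \mu_{Hp}) / \sigma_{Hp}$, with `|ZHp| > 3` flagged as
outliers. Conventions:

- windows are genome-positioned: 0.5-Mb windows starting at offsets
  0, 250 kb, 500 kb, … of each chromosome (50% overlap), clipped at the
  chromosome end; a window exists whenever its start lies inside the
  chromosome;
- windows with fewer than `min_snps` SNPs (default 10) carry no Hp — ZHp on
  near-empty windows is noise; the floor is configurable and recorded in
  output;
- $\mu_{Hp}$ and $\sigma_{Hp}$ use the sample (n−1) standard deviation and
  are computed over windows with a defined Hp, i.e. after the floor. The
  alternative (including sub-floor windows) would mix undefined and defined
  statistics; excluding them keeps ZHp exactly mean-0/sd-1 over the windows
  that are actually reported.

## Fst

Per-SNP differentiation between two groups uses the Weir & Cockerham (1984)
two-population variance-component estimator $\hat\theta = a/(a+b+c)$
computed from sample sizes, allele frequencies and observed
heterozygosities. Negative estimates are reported as computed (never
clipped); sites where either group has fewer than two called samples are
skipped and counted; sites monomorphic across both groups have a zero
denominator and yield `NaN`. Hudson's estimator (Bhatia et al. 2013) is
available behind a flag for sensitivity analysis.

The window statistic mFst is the **arithmetic mean of per-SNP estimates**
in the window, the convention of window-scan pipelines built on plink's
per-SNP scores; a ratio-of-averages window statistic (summed variance
components) is available behind a flag. Windows with `mFst > 0.9` are
flagged as highly differentiated; complete fixation for opposite alleles
gives per-SNP Fst and mFst exactly 1.

Genome-wide, two summaries exist and they are not interchangeable:

- `overall_fst(fst, "mean")` — the mean of per-SNP ratios, consistent with
  mFst. Because $E[a/(a+b+c)] \neq E[a]/E[a+b+c]$, this statistic is
  biased downward; under a Balding–Nichols simulation with F = 0.25 and
  50+50 samples it sits near 0.18.
- `overall_fst(fst, "weighted")` — the multi-locus Weir–Cockerham
  estimator, the ratio of summed components. This is the estimator that
  recovers the differentiation parameter (0.247–0.262 across 20 simulation
  seeds at F = 0.25) and the one used in the parameter-recovery tests.

`fst_scan()` reports both.

## Runs of homozygosity and Froh

`detect_roh()` is a scanning-window caller in the plink `--homozyg` family.
Windows of `window_snps` consecutive SNPs slide one SNP at a time; a window
is homozygous-compatible iff it contains at most `max_het_per_window`
heterozygotes and at most `max_missing_per_window` (default 5) missing
calls. Each SNP scores the fraction of covering windows that are
compatible; SNPs at or above `hit_fraction` (default 0.05, plink's default)
are run-eligible. Maximal runs of eligible SNPs are split at inter-SNP gaps
above `max_gap` (default 500 kb) and reported when they span at least
`min_length` (default 1 Mb) and contain at least `min_snps_per_segment`
(default 25) SNPs. Segment coordinates are outermost SNP positions, so
length is SNP span, not window span. The stringency grid of interest
crosses window sizes {5, 10, 20} with heterozygote allowances {1, 2, 3}
(`roh_grid()`, nine cells); the (20, 3) cell is flagged as the headline
setting in `stringency_sweep()` output. Only window size, heterozygote
allowance, minimum length and maximum gap are externally prescribed
parameters; the remaining knobs are explicit configuration recorded in
output, because exact concordance with any particular plink build cannot
be promised.

Two behavioural notes, both verified against an exhaustive brute-force
scanner in the tests:

- with a permissive `hit_fraction`, segment boundaries can extend a few
  SNPs beyond a truly homozygous tract (a SNP just outside is eligible as
  long as one covering window tolerates the accumulated heterozygotes);
  at realistic densities this is tens of kilobases and well inside the
  Froh recovery tolerance;
- the caller is monotone in stringency: lowering the heterozygote
  allowance or enlarging the window never increases total ROH length.

`froh()` divides a sample's summed segment length by an **explicit,
required** denominator. The "genome length assessed" is genuinely
ambiguous in practice (assembly length? covered length? summed SNP span?)
and back-computing it from published per-sample tables gives inconsistent
values, so the package never silently chooses one. The bundled per-sample
ROH summary fixture is evaluated with 9.4 × 10⁸ bp, the approximate length
of the Northern Pike reference assembly against which such data are
aligned; the checked summary quantities (zero-segment samples, per-sample
mean segment length, cohort mean segment count) are denominator-free, and
the cohort mean Froh is stable at 0.03 for any denominator in the
admissible range.

## Sex-discordant marker screen

`find_sex_discordant()` formalises as an exact predicate what is often done
by eye: a marker is reported when every non-missing call of one sex is
heterozygous, every non-missing call of the other sex is the **same**
homozygote, and both sexes meet a per-sex call-rate threshold. The default
threshold 1 demands the perfect pattern with no missing calls; relaxing it
tolerates missingness without weakening the genotype predicate. The screen
is symmetric in the sexes (the pattern label flips). Heterozygote genotype
strings are printed alternate-allele-first, matching the convention of
published sex-marker tables.

## Genotype PCA

Dosages are mean-imputed per site, centered, optionally Patterson-scaled by
$\sqrt{p(1-p)}$, and decomposed by SVD. Monomorphic sites are dropped
(an all-identical matrix is an error, the documented degenerate contract).
Variance-explained fractions are singular values squared over the total
genotypic variance, hence non-negative, non-increasing and summing to at
most 1 for `k < n`. Component signs are fixed by forcing each component's
largest-magnitude loading positive, making output invariant to sample
order.

## The synthetic-data generator

`simulate_genotypes()` draws, per site, an ancestral frequency
$p_0 \sim U(a, b)$ and population frequencies
$p_i \sim \mathrm{Beta}$ with mean $p_0$ and variance $p_0(1-p_0)F$
(Balding–Nichols; $F = 0$ degenerates to a point mass), then binomial
diploid genotypes. On top of the neutral background it forces planted
features: homozygous tracts (each site set to the homozygote of the
population-major allele) and a sex-linked locus where every male is
heterozygous and every female homozygous reference — the XY-like pattern.
Missingness is uniform outside planted features; depth is negative
binomial; site qualities are uniform. Everything is reproducible from the
seed, down to byte-identical VCF output.

Default configuration (the emulated study structure): 5 chromosomes of
30 Mb, 5000 SNPs, cohorts of 12 (sexed, 6 female / 6 male) and 200
(unsexed), differentiation F = 0.24, ancestral frequencies in (0.05,
0.95), 5% missingness, depth mean 26× (dispersion 8), a 47-marker
sex-linked locus and three planted tracts of 2–3 Mb. Two deliberate
simplifications: positions are uniform with no recombination map, and
there is no linkage disequilibrium — ROH realism comes from planted
tracts, not genealogy. Consequently passing tests demonstrate correctness
of the estimators on exchangeable-site data, not robustness to LD,
RAD-locus dropout or sequencing-error structure, which real cohorts have.

Study sizes used by the test suite were chosen to make Monte-Carlo noise
small relative to the asserted tolerances while staying desk-scale: Fst
recovery uses 5000 SNPs and 50+50 samples over 20 seeds (±0.03 band); Froh
recovery uses 200 Mb of genome at 100 SNPs/Mb with planted fractions
0.01–0.05 (±0.01 band) on a panmictic, allele-frequency-rich background
(ancestral range 0.2–0.8) so that background heterozygosity, not
differentiation, dominates — the regime in which an ROH caller is actually
used. The ROH oracle-equivalence suite runs 200 random 100–300-SNP
instances against all nine grid cells with segment-level filters scaled to
instance size (minimum span 500 kb, 15 SNPs), since a 1-Mb floor on a
300-SNP toy chromosome would leave most instances trivially empty.

## Degenerate inputs and error contracts

- Ti/Tv with zero transversions raises a classed error
  (`popgenscan_undefined_ratio`) rather than returning a number.
- `normalize_hp()` on fewer than two defined windows, or on identical Hp
  everywhere ($\sigma_{Hp} = 0$), is an error.
- A chromosome with fewer SNPs than the scanning window yields no ROH
  segments and a warning.
- Group Fst requires two called samples per group per site; failing sites
  are skipped and counted, never silently dropped.
- VCF import validates structural shape first and reports the offending
  line number for malformed rows; excluded record classes (indel,
  multiallelic, other) are always counted.

## Known limitations

- No LD, recombination or genealogical ROH in the simulator (above).
- The ROH caller reproduces the plink algorithm family, not any specific
  plink build bit-for-bit; unprescribed parameters are explicit defaults.
- mFst inherits the per-SNP ratio bias discussed above; genome-wide claims
  should use the weighted estimator.
- Windowed statistics assume the filtered matrix; running scans on
  unfiltered data is possible but mixes QC failures into the statistics.
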