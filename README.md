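# surfbat

Case-only, stratification-robust association testing from genotype-imputation
reference panels, for statistical geneticists who have phased array data for
cases and a phased sequencing panel for controls — but no parents and no
individual-level control genotypes to merge.

## The idea

The transmission-disequilibrium test (TDT) is immune to population
stratification because it compares each transmitted parental allele with the
corresponding un-transmitted one. `surfbat` recreates this contrast without
families. Each phased case haplotype is modelled as a mosaic of a reference
panel under the Li–Stephens copying HMM; the reference individuals it copies
from act as *surrogate parents*. At any panel site, the copying posterior
P(s = k | o) over the 2N panel haplotypes yields two doses per case
haplotype:

- transmitted: ρ = Σₖ P(s = k | o) · 1{Hₖ = 1}
- pseudo-control: π = Σₖ P(s = k | o) · 1{H_r(k) = 1}

where r(k) is the *partner* haplotype of k within the same reference
individual — locally ancestry-matched to the copied haplotype whenever the
panel's individuals are not recently admixed. Summing discordance over case
haplotypes, NUM = Σ ρ(1−π) and DEN = NUM + Σ π(1−ρ) give the paired
statistic

  β̂ = logit(NUM/DEN),  var(β̂) = DEN/(NUM·(DEN−NUM)),  X = β̂²/var(β̂) ~ χ²₁,

the exact-form conditional-likelihood TDT (with hard doses it reduces to the
classical discordant-count test). An unpaired marginal-homogeneity χ²₁ test
on the expected 2×2 table (cells A–D) is also provided. Sites are filtered at
case MAF < 0.01 or INFO < 0.3 before testing; inflation is tracked as
λ = median(X)/0.4549 with optional genomic control.

The package also ships panel merging with Hudson's Fst outlier exclusion
(mean + 6 SD), genetic-map handling, and a mosaic-haplotype simulator
(structured synthetic panels, Poisson cM-scale tiles, local-ancestry and
allelic signal injection, array-like typed-site design) used to verify
calibration and power — see `vignette("surfbat-methods")`.

## Worked example

Simulate a null study — 200 admixed cases built as 10 cM mosaics of a
500-haplotype two-group panel, typed at an array-like subset — and scan it:

```r
library(surfbat)
library(dplyr)

b <- scenario("null", scale = 0.5, seed = 42)
b
#> <surfbat_scenario> null: panel 500 haplotypes x 2500 sites; 200 case haplotypes; 500 typed sites

scan <- run_surfbat(b$panel, b$targets)
scan
#> <surfbat_scan> 2500 sites: 2304 tested, 196 filtered; lambda = 1.069

glance(scan)
#> # A tibble: 1 × 5
#>   lambda_gc n_sites n_tested n_filtered n_degenerate
#>       <dbl>   <int>    <int>      <int>        <int>
#> 1      1.07    2500     2304        196            0

tidy(scan) |>
  filter(!filtered) |>
  select(pos, typed, maf_case, info, num, den, beta, x_paired, p_paired) |>
  head(5)
#> # A tibble: 5 × 9
#>     pos typed maf_case  info   num   den    beta x_paired p_paired
#>   <int> <lgl>    <dbl> <dbl> <dbl> <dbl>   <dbl>    <dbl>    <dbl>
#> 1  5261 FALSE   0.357  0.736  33.1  71.9 -0.162   0.468      0.494
#> 2 21010 TRUE    0.385  1.000  46.6  94.3 -0.0238  0.0133     0.908
#> 3 41724 TRUE    0.245  1.000  35.0  61.2  0.294   1.29       0.255
#> 4 46772 FALSE   0.0646 0.744  12.6  31.8 -0.420   1.34       0.247
#> 5 65062 FALSE   0.312  0.766  32.7  65.9 -0.0163  0.00437    0.947
```

Under the null the inflation factor sits near 1 and the per-site p-values are
uniform (`autoplot(scan)` draws the QQ plot; `plot_manhattan(scan)` the
genome scan). Each row is one panel site: `typed` says whether it was on the
simulated array or imputed, `num`/`den` are the expected discordant
transmission sums, and `beta` is the log transmission odds — all ~0 here, as
transmission is balanced when cases really are mosaics of the panel.

File-based workflows use the same engine: `surfbat_run()` reads phased
reference/target VCFs and a genetic map and writes a per-variant TSV plus a
JSON summary, and `inst/cli/surfbat.R` exposes `run`, `simulate` and
`panel-qc` subcommands for the shell.

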