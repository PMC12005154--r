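---
title: "Methods: pseudo-control association testing from imputation panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-control association testing from imputation panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfbat)
```

## The problem

Case-only association studies compare case allele frequencies against an
external reference panel. Done naively, any ancestry difference between cases
and panel masquerades as association. Family-based designs such as the
transmission-disequilibrium test (TDT) avoid this by conditioning on parental
genotypes, but parents are rarely available.

`surfbat` approximates the TDT without families. Each phased case haplotype is
modelled, under a Li–Stephens copying HMM, as an imperfect mosaic of a phased
reference panel. The reference individuals whose haplotypes a case haplotype
copies act as *surrogate parents*: the copied haplotype supplies the
"transmitted" allele dose, and the *partner* haplotype of the same reference
individual supplies an ancestry-matched "un-transmitted" (pseudo-control)
dose. Comparing transmitted against pseudo-control doses tests transmission
equilibrium locally, which is robust to population structure in the same way
the TDT is — provided the two haplotypes within each reference individual
share similar ancestry (true of panels recruited on local ancestry criteria;
violated by recently admixed reference individuals, a documented, not
enforced, assumption; `build_dosage_table()` warns when group labels reveal
cross-label posterior mass on partner pairs).

## The copying model

For a case haplotype observed at typed sites $j = 1, \dots, T$, the hidden
state $s_j \in \{1, \dots, H\}$ indicates which of the $H = 2N$ panel
haplotypes is being copied. We use the classic parameterization:

* uniform initial distribution $1/H$;
* per-interval switch probability
  $r_j = 1 - \exp(-0.04\, n_e\, d_j / H)$, with $d_j$ the genetic distance in
  cM between adjacent typed sites (the 0.04 converts cM into the $4 N_e g$
  scale in Morgans); switches land uniformly, so the transition kernel is
  $r_j/H + (1 - r_j)\,[k = l]$;
* symmetric emission: probability $1 - \varepsilon$ of observing the copied
  allele, $\varepsilon$ otherwise, absorbing mutation and genotyping error.

Posteriors $P(s_j = k \mid o)$ come from the forward–backward algorithm with
per-site rescaling (no log-space; the rescaled recursions are exact and do not
underflow even for $10^5$ sites — verified against a path-enumeration oracle
to $10^{-10}$). Zero genetic distance between adjacent typed sites yields an
identity transition. Defaults are $n_e = 20{,}000$ (the common imputation
default) and $\varepsilon = 10^{-4}$; both are exposed (`hmm_params()`, CLI
flags `--ne`, `--err`). No PBWT-style state compression is used: the exact
$O(TH)$ recursions are fast enough at the intended scale (up to $\sim 10^4$
reference haplotypes), and the compiled kernel keeps memory access contiguous.

## Dosages, tests, filters

With panel haplotypes stored in pairs per individual (0-based columns $2i$,
$2i+1$), the partner index is `partner_index()`, an involution. At any panel
site with alleles $H_k \in \{0,1\}$:

$$\rho = \sum_k P(s = k \mid o)\, [H_k = 1], \qquad
  \pi = \sum_k P(s = k \mid o)\, [H_{r(k)} = 1].$$

At untyped sites, $\rho$ and $\pi$ are linear interpolations (on the cM
scale) of the values obtained by applying the two flanking typed-site
posteriors to the untyped site's alleles. Interpolating the $(\rho, \pi)$
functionals rather than whole posterior rows is mathematically identical for
these linear functionals and far cheaper. Outside the typed range the nearest
typed posterior is used; a zero-cM span falls back to equal weights.

Per site, over all case haplotypes:

* paired test: $\mathrm{NUM} = \sum \rho(1-\pi)$,
  $\mathrm{DEN} = \mathrm{NUM} + \sum \pi(1-\rho)$,
  $\hat\beta = \mathrm{logit}(\mathrm{NUM}/\mathrm{DEN})$,
  $\mathrm{var}(\hat\beta) = \mathrm{DEN}/(\mathrm{NUM}(\mathrm{DEN}-\mathrm{NUM}))$,
  $X = \hat\beta^2/\mathrm{var}(\hat\beta) \sim \chi^2_1$ under transmission
  equilibrium. With hard doses this is the classical discordant-count TDT.
* unpaired test: marginal homogeneity of the expected 2×2 table
  $A = \sum(1-\rho)(1-\pi)$, $B = \sum(1-\rho)\pi$, $C = \sum\rho(1-\pi)$,
  $D = \sum\rho\pi$, margins $n_{1.} = A + C$, $n_{2.} = B + D$,
  $n_{.1} = A + B$, $n_{.2} = C + D$, and
  $X = \sum_{m=1,2} (n_{m.} - n_{.m})^2/(n_{m.} + n_{.m}) \sim \chi^2_1$.

Boundary sites ($\mathrm{NUM} \in \{0, \mathrm{DEN}\}$ or
$\mathrm{DEN} = 0$) are reported `NA` with a degenerate flag rather than
continuity-corrected; an optional Haldane-style correction (`haldane = TRUE`,
0.5 added to both discordant sums) is available but off by default, since the
boundary behaviour of the original software is unspecified.

Sites are filtered before testing when the **case** minor-allele frequency
(folded mean of $\rho$ over case haplotypes — the case group, not the panel,
is the stated reference population for this threshold) is below 0.01 or the
INFO score is below 0.3 — the defaults of the original implementation. INFO
is not defined by the original description, so we adopt the IMPUTE-style
variance-ratio measure on haploid doses:
$\mathrm{INFO} = 1 - \sum_h \rho_h (1 - \rho_h) / (H_t\, \hat\theta (1 -
\hat\theta))$ with $\hat\theta$ the mean dose, defined as 1 when
$\hat\theta \in \{0, 1\}$. It is 1 exactly when every dose is certain and 0
when all doses sit at a common interior value.

Genomic inflation is summarized as $\lambda = \mathrm{median}(X)/0.4549364$
over finite statistics of the paired test (the statistic the method leads
with); `genomic_control()` divides statistics by $\lambda$ and recomputes
p-values, with $\lambda < 1$ a no-op by convention. The 5e-8 and 1e-5
thresholds appear only as plot annotations, never as filters.

## Panel QC

When merging two sequencing panels, per-variant batch effects are screened by
Hudson's $F_{st}$. The original description cites the estimator but prints no
formula; we use the Bhatia-style ratio form

$$\hat F_{st} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
  \frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)},$$

computed per site (not as a ratio of averages) because the exclusion is
per-variant: sites above the mean + 6 SD of defined values are dropped.
Merging matches sites exactly on (chrom, pos, ref, alt); a site with swapped
or mismatched alleles at the same position is dropped and counted, never
flipped — a silent strand/allele flip is a worse failure mode than a lost
site.

## What the simulator emulates

`generate_panel()` builds a structured reference panel with no external data:
ancestral allele frequencies from a symmetric Beta(0.8, 0.8) clipped to
[0.05, 0.95], group frequencies from the Balding–Nichols model at divergence
$F = 0.15$ (continental-scale differentiation), and per group a set of 100
founder haplotypes from which panel haplotypes are drawn as fine-grained
mosaics (mean tile 1 cM), creating linkage disequilibrium that decays on the
cM scale. Haplotypes are paired into individuals within group, so partner
haplotypes are ancestry-matched by construction — the regime the test
assumes.

Case haplotypes are mosaics of the panel (`simulate_mosaic_haplotype()`):
breakpoints are a Poisson process on the cM axis with rate `1/tile_cm`, each
tile's source group is drawn from the configured weights and the source
haplotype uniformly within the group, and alleles are copied verbatim
(copying error belongs to the HMM's $\varepsilon$, not the simulator; tile
lengths are therefore exactly Exponential, which the tests verify by
Kolmogorov–Smirnov on unbiased per-haplotype gap samples — pooling all
interior gaps would length-bias the sample). Breakpoints-then-sources is a
Markov jump reading of the tile process; consecutive tiles may share a
group.

The named scenarios (`scenario()`) reproduce the study designs at desk scale:

* **null** — 200 cases as 10 cM mosaics of a 1,000-haplotype two-group panel
  with 50/50 tile-source weights, 5,000 panel sites, ~1,000 typed;
* **ancestry_signal** — 900 case haplotypes drawn from a 4,000-haplotype
  mosaic pool so that tiles overlapping a mid-chromosome focal position come
  650:250 from the two groups — local-ancestry excess with no allele
  constraint;
* **allelic_signal** — 900 case haplotypes with 500 carriers / 400
  non-carriers of a signal variant chosen mid-chromosome among variants with
  MAF ≥ 0.2 in both groups; carriers come from any group, so the signal is
  deliberately ancestry-confounded;
* **admixed_null** — three-way admixture with weights 1/6, 1/3, 1/2 and mean
  tile 100/12 cM, the expected segment length twelve generations after
  admixture (a mosaic stand-in for a coalescent admixture simulation, which
  is out of scope);
* **small_panel_inflation** — cases as 5 cM mosaics of a well-matched group,
  scanned against (a) the full 2,000 well-matched haplotypes and (b) 100
  well-matched plus 1,900 mismatched haplotypes, to contrast inflation.

Typed sites are designed array-style: MAF > 0.1, greedy left-to-right LD
thinning at $r^2 = 0.8$ within a 1 cM window, then uniform random selection.
A derived-allele-frequency window filter (0.05–0.95) and every-kth decimation
are available for panel thinning.

**Marker density.** The scenario chromosome is 25 cM / 25 Mb under a constant
1 cM/Mb map, giving ~1 panel site per 5 kb (sequencing-panel density) and
~1 typed site per 25 kb (array density). This matters: the switch rate
$r = 1 - \exp(-0.04\, n_e d/H)$ is calibrated for realistic marker spacing,
and stretching the same number of sites over a long chromosome would place
typed markers several tenths of a cM apart — a regime no genotyping array
occupies — where copying posteriors decohere between markers and the test
loses calibration for lack of imputation quality rather than any property of
the statistic. Problem sizes (1,000-haplotype panels, 200–450 cases,
2,000–5,000 sites) were chosen once as the package's desk-scale study
conditions.

**What passing tests do not show.** The simulator produces perfect panel
mosaics: real case haplotypes are not exact mosaics of any panel, real LD is
not a founder-mosaic process, allele frequencies are not Balding–Nichols, and
phasing/genotyping error enter only through $\varepsilon$. Calibration and
power here demonstrate the statistic's properties in its intended regime, not
performance on any particular real cohort.

## Numerical and design choices

* 1-based VCF positions externally, 0-based indices internally; the partner
  rule is the 0-based mirror of the 1-based odd/even statement.
* Posterior rows are renormalized after combining scaled forward and backward
  quantities; row sums are unit to $10^{-9}$ by construction.
* Adjacent typed sites at identical cM get an identity transition; positive
  distances floor the switch probability at $10^{-12}$.
* Ties in array design are resolved left-to-right (first-seen site wins);
  random selection is a single `sample()` under the scenario seed, and every
  scenario is a pure function of `(name, scale, seed)`.
* Degenerate inputs: monomorphic sites yield $\rho = \pi \in \{0, 1\}$ and
  fall to the MAF filter; an empty tested set warns rather than errors.
* Equivalence with the original software's output is expected to be
  approximate at best, since its exact transition/emission constants are not
  published; the path-enumeration oracle, not that software, defines
  correctness here.
* The command-line entry point (`inst/cli/surfbat.R`) is a thin wrapper over
  `surfbat_run()`, `surfbat_simulate()` and `surfbat_panel_qc()`; all logic
  lives in, and is tested through, the package functions.

## Limitations

Single-statistic per-site tests only: no PC-adjusted regression, no
local-ancestry regression comparators, no X chromosome, no quantitative
traits, no multiple-testing correction beyond annotation thresholds. Panels
with recently admixed individuals violate the partner-matching assumption and
inflate the statistics (the `small_panel_inflation` scenario reproduces this
deliberately); genomic control mitigates but does not repair a mismatched
panel.
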