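---
title: "Phenotyping diurnal preference and estimating its heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping diurnal preference and estimating its heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctura)
library(dplyr)
```

`noctura` analyses *Drosophila* locomotor recordings for diurnal
preference — whether a fly concentrates its activity in the light or the
dark phase — and estimates the genetic architecture of that preference.
This vignette explains the models behind each step, the parameters that
matter, and the design decisions taken where the methodology was genuinely
open.

## The phenotype: ND ratio

All phenotyping starts from a tidy activity table (`fly_id`, `time`,
`count`, `light`). The **ND ratio** of a complete 24 h day is the sum of
counts in dark (or subjective-dark) bins divided by the sum in light bins;
a fly's value is the mean of its daily ratios. The ratio form (rather than
a bounded fraction) is deliberate: strongly nocturnal flies have values
above 1, and selection operates on this scale. Days in which a fly is
active only in the dark have an infinite daily ratio; they are excluded
from the mean with a warning rather than silently clipped. Averaging daily
ratios is the default; pooling counts across days first
(`pool_days = TRUE`) is available and matters only for very unevenly
active days.

In constant darkness there is no light phase to compare against, so
*subjective* day and night are the prior LD schedule projected forward at
fixed clock times (`annotate_light()` with `dd_start`). The projection is
deliberately **not** adjusted for each fly's free-running period: masking
analyses compare regimes against a common, clock-time-defined reference
window.

## Rhythmicity: Fisher's exact g-test

A fly enters downstream analyses only if its activity is rhythmic. With
$I_1,\dots,I_m$ the periodogram ordinates at the Fourier frequencies,
Fisher's statistic is $g = \max_j I_j / \sum_j I_j$ and its exact null
tail probability is

$$p = \sum_{j=1}^{\lfloor 1/g \rfloor} (-1)^{j-1} \binom{m}{j} (1-jg)^{m-1},$$

computed in log space and clamped to $[0,1]$. The rhythmicity call uses
$p < 0.05$ on the series as recorded (30 min bins are typical). The test
suite checks the closed form against a Monte-Carlo permutation oracle at
small $m$ and verifies that p-values are uniform on white noise
(Kolmogorov–Smirnov against the uniform at 2,000 replicates).

## Free-running period: chi-square periodogram

`chi2_periodogram()` folds the series at each candidate period $P$ into
$K = \lfloor 60P/b \rfloor$ phase classes ($b$ = bin width in minutes) and
computes

$$Q_P = \frac{\sum_h n_h (\bar M_h - \bar x)^2}{\sum_i (x_i - \bar x)^2 / N},$$

which is $\chi^2_{K-1}$ under the null. The default grid is 18–30 h in
0.1 h steps, a range that brackets all plausible fly free-running periods.
Because the scan maximises over ~121 correlated candidates, comparing each
$Q_P$ with its raw 5% point would flag arrhythmic flies far too often; the
per-candidate threshold is therefore Bonferroni-adjusted
($\alpha/\text{grid size}$), which brings the scan-wise false-positive
rate back to about $\alpha$ and is verified by simulation in the test
suite. The reported period maximises $Q_P - \text{threshold}$. A
Lomb–Scargle scan over the same grid is provided purely as an independent
cross-check; with a different statistic it would otherwise be an easy way
to double-count evidence.

With the generator's default recording scale (six DD days at 30 min bins,
1,200 expected counts/day), the estimator recovers the generating period
to within ±0.25 h in at least 95% of replicates.

## Acrophase and circular statistics

Phases live on a 24 h circle at **15° per hour** (ZT0 = 0°, ZT12 = 180°).
Per cycle, the acrophase is the count-weighted circular mean of
bin-midpoint angles; across cycles the per-cycle phases are summarised by
their circular mean, resultant length $R$, and the standard 95% CI of a
mean direction (Zar's two-branch formula). Three numerical choices:

- the CI is reported as `NA` whenever $R \le \sqrt{\chi^2_{0.05,1}/2n}$,
  below which the formula is invalid;
- a cycle whose activity is numerically uniform has no defined phase
  (its within-cycle resultant is ~0); such cycles contribute a null vector
  rather than an arbitrary direction, so uniform flies come out with
  $R \approx 0$ and an undefined CI instead of a spurious $R = 1$;
- for strongly **bimodal** (crepuscular) patterns the full-day circular
  mean nearly cancels between the two bumps and is intrinsically
  unstable. That is a property of the statistic, not a bug; analyses that
  need a stable phase should use the morning/evening peak phases, which
  window the data to ZT21–ZT3 (MP) and ZT9–ZT15 (EP), 6 h windows
  flanking lights-on and lights-off where crepuscular peaks sit.

Light-pulse phase shifts are circular acrophase differences between a
pulsed and an unpulsed series, converted at 15°/h, with delays negative;
both series must pass the chi-square rhythmicity screen first.

## Sleep

Sleep uses the universal *Drosophila* convention: any run of ≥ 5
consecutive zero-count minutes is sleep, every minute inside the run
counting. Scoring is refused on re-binned data (a 30 min zero bin is not
five quiet minutes), and the per-hour profile averages across days. The
implementation is checked for exact equality against a brute-force
run-length scan.

## Masking

Masking — the clock-independent suppression of activity by light — is
quantified as the contrast between a fly's ND ratio under LD and under DD.
The first DD day is excluded as a transient. Group-level inference is a
two-way ANOVA (genotype, regime, genotype × regime) on per-fly ND values
with Tukey-adjusted post-hoc contrasts; a significant interaction is the
masking signature (nocturnal genotypes lose their nocturnality in DD,
diurnal ones do not).

## Realized heritability and the sib-mating correction

The realized-h² estimator regresses cumulative response on cumulative
selection differential through the origin (zero cumulative selection must
give zero expected response). The per-cycle differential charges both
parental sexes equally:
$S = \tfrac12(\bar P_{\text{sel males}} - \bar P) +
\tfrac12(\bar P_{\text{mated females}} - \bar P)$.

The design analysed here mates each selected male to an **unselected full
sister**, and that changes the estimator's properties. A sister shares the
family genetic effect with her selected brother, so conditional on his
selection her expected phenotypic deviation, $\tfrac{h^2}{2}S_m$, is
*entirely genetic* — she transmits it at full value, not at heritability
$h^2$. Charging her deviation into $S$ at face value therefore counts it
at the wrong rate, and the plain slope converges to
$3h^2/(2+h^2)$ rather than $h^2$ (≈ 0.39 at a true 0.30 — a 30% relative
overestimate, reproduced by simulation in the test suite).

The consistent bookkeeping moves the dam contribution to the response
side: with $S_m$, $S_f$ the per-sex mean deviations, regress
$\mathrm{cum}(R - S_f/2)$ on $\mathrm{cum}(S_m/2)$. A Gaussian
conditional-expectation calculation shows the per-cycle expectation of the
adjusted response is exactly $h^2$ times the adjusted differential, for
any $h^2$; simulation at the study design confirms near-unbiasedness.
`realized_h2()` applies this correction automatically when the per-sex
cycle means are available (`adjust = "auto"`), and `adjust = "none"` keeps
the plain slope for records that only carry S and R.

Two honest caveats. First, a small finite-design bias remains at low
heritability (about +0.02 at $h^2 \approx 0.1$ for 10 cycles with 25
families), driven by the autocorrelation of cumulative sums over few
cycles; it is well inside the calibration tolerances used here but would
matter for precision work. Second, the drift variance is a parametric
bootstrap — the same design re-simulated at the estimated h² — rather
than a closed-form approximation, trading a few seconds of computation for
freedom from distributional assumptions.

Parent–offspring regression is standard: the mid-parent slope estimates
h² directly, single-parent slopes estimate h²/2 and are doubled, and both
modes are always reported because published single-parent values are
sometimes left undoubled.

## The simulator

The generator is an infinitesimal additive model: breeding values are
Gaussian with variance $h^2 V_p$ (half shared within a full-sib family,
half individual Mendelian sampling), environmental deviations Gaussian
with variance $(1-h^2)V_p$, and offspring breeding values are midparent
plus a Mendelian deviation of variance $h^2 V_p / 2$. The ND phenotype
lives on the ratio scale with a positivity floor at 0.01.

Default conditions (chosen once, from the published population
trajectories, and not revisited): founder ND mean 0.75 and $V_p = 0.02$
(consistent with a per-cycle differential near 0.13 and ten-cycle
endpoints near 0.3 and 1.2); 300 males phenotyped per cycle, 25 selected,
10 cycles; 1,200 expected counts per fly per day; free-running period
24.2 ± 0.2 h; crepuscular activity bumps at ZT0 and ZT12 with von Mises
concentration 2.

Actograms are Poisson draws from an intensity built from the two-bump
template on the fly's circadian cycle (entrained at 24 h in LD,
free-running at its own $\tau$ in DD). Calibration is exact by
construction: with $x = \log(\text{ND}_{\text{true}}/\text{ND}_{\text{template}})$,
clock-night bins are scaled by $e^{(1-m)x}$ and lit bins by $e^{-mx}$, so
the expected LD ratio equals the fly's true ND for any masking coefficient
$m$, while the expected DD ratio relaxes to
$\text{ND}_{\text{template}}\,e^{(1-m)x}$ — equal to the LD ratio when
$m = 0$ and fully relaxed to the template's intrinsic (crepuscular,
$\approx 1$) ratio when $m = 1$. The default $m = 0.6$ makes nocturnal
genotypes lose most of their excess nocturnality in DD.

What the generator does *not* emulate: explicit loci and allele
frequencies (so the asymmetric selection response seen in real populations
arises here only if the two directions are given different h² values),
dominance and maternal effects, age or sex differences in activity level,
arousal-state autocorrelation within a day beyond the template shape, and
monitor artefacts other than status-flagged records. Passing
parameter-recovery tests therefore shows the estimators are correct for an
additive trait measured with Poisson noise — not that real data meet those
assumptions.

A fast phenotyping path (true ND plus optional Gaussian measurement
noise) and the full path (Poisson actogram scored by `nd_ratio()`) are
both available in `run_selection_experiment()`; replicated calibration
runs use the fast path, and the full path is exercised at reduced scale
(tens of flies, two cycles, two recording days) to confirm the two agree
in direction and magnitude.

## Complementation verdicts

`qct_test()` runs the Kruskal–Wallis omnibus across the three mutant
crosses (2 df) and all pairwise two-sample KS tests, exact for cells of
≤ 25 flies, with Benjamini–Hochberg-adjusted p-values reported alongside
the raw ones. The verdict rule is deliberately conservative:
`complemented` requires the full background ordering D* < C* < N* *and* a
significant N* vs D* KS contrast *and* a significant KW test; significant
heterogeneity in any other pattern is `failed_to_complement`; everything
else — including partial orderings — is `inconclusive` rather than being
forced into a binary call. Under the null, the simulated rate of spurious
`complemented` verdicts stays below the nominal 5%.

## Problem sizes and reproducibility

Every generator accepts a seed, and identical seeds give bit-identical
outputs. The calibration experiments shipped with the package use 200
replicate selection experiments per direction and 500 replicate family
sets (105 families for mid-parent, 85 mother–daughter pairs), sizes at
which the Monte-Carlo standard error of the recovered mean h² is a few
tenths of a percentage point. The end-to-end driver `run_end_to_end()`
replays the whole design at desk scale with a single seed and stamps every
output with the seed and a configuration hash.

## Known limitations

- The acrophase of strongly bimodal activity is unstable by construction;
  use MP/EP phases for crepuscular flies.
- Realized-h² estimates at low heritability carry a small upward
  finite-design bias even after the sib-mating correction.
- Sleep scoring requires 1-minute acquisition; recordings binned coarser
  at acquisition cannot be sleep-scored, only activity-scored.
- The DAM reader implements the 42-column single-beam layout only; no
  multi-beam dialects.
- Subjective day/night in DD follows clock time, not each fly's own
  free-running period, so long DD recordings of flies with extreme periods
  blur the subjective windows.
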