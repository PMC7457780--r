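# noctura

Diurnal-preference phenotyping and quantitative genetics for *Drosophila*
locomotor-activity data.

Flies, like people, differ in whether they are most active by day or by
night, and that preference is partly heritable. `noctura` implements the
full analysis chain used to study this trait: it turns raw activity-monitor
recordings into per-fly circadian phenotypes, and turns phenotyped
populations — real or simulated — into genetic conclusions.

## What it computes

**Phenotyping** (tibble in, tibble out; one row per fly):

- **ND ratio** — night/day activity ratio over complete 24 h days,
  `ND = Σ counts(dark) / Σ counts(light)`; > 1 nocturnal, < 1 diurnal.
  Works in LD and, via projected *subjective* day/night, in constant
  darkness (DD).
- **Rhythmicity** — Fisher's exact g-test on the activity periodogram:
  `g = max(I_j) / Σ I_j` over the m Fourier ordinates, with the exact null
  tail probability `p = Σ_{j≤1/g} (−1)^{j−1} C(m,j) (1−jg)^{m−1}`.
- **Free-running period** — Sokolove–Bushell chi-square periodogram over an
  18–30 h grid (Lomb–Scargle available as a cross-check).
- **Acrophase** — circular statistics of the daily peak phase at 15°/h
  (mean vector, resultant length R, 95% CI), plus morning/evening peak
  phases and light-pulse phase shifts.
- **Sleep** — the standard ≥ 5 min immobility rule on 1-minute bins.
- **Masking** — LD vs DD ND contrast with a genotype × regime ANOVA,
  quantifying the clock-independent suppression of activity by light.

**Genetics**:

- **Realized heritability** from truncation selection: the slope, through
  the origin, of cumulative response on cumulative selection differential
  (`R = h²S`), with a correction for sib-mating designs (selected males ×
  unselected sisters) in which the naive slope is inconsistent, and a
  parametric-bootstrap drift variance.
- **Parent–offspring regression** h² (mid-parent slope, or doubled
  single-parent slope).
- **Quantitative complementation tests**: Kruskal–Wallis across mutant
  crosses into the N*/D*/C* backgrounds, a pairwise KS matrix, and a
  complementation verdict based on the D* < C* < N* ordering rule.

**Simulation**: an infinitesimal-model generator of heritable ND
phenotypes, Poisson actograms with configurable masking and free-running
period, multi-cycle selection experiments (300 males phenotyped, 25
selected, 10 cycles by default), parent–offspring families, and QCT
tables — used throughout the tests to validate every estimator against its
generating truth.

## Worked example

```r
library(noctura)

# a full selection experiment at the study design, diurnal direction
cfg <- sim_config(h2 = 0.371, seed = 2024)
ex  <- run_selection_experiment(cfg, direction = "diurnal")
ex
#> <selection_experiment> diurnal selection, 10 cycles, cum S = -1.344,
#>   cum R = -0.640 (true h2 = 0.371)

realized_h2(ex$cycles, drift_reps = 100, config = cfg)
#> <h2_est> h2 = 0.371 (37.1%), se = 0.009, method = realized, drift var = 0.002082

head(ex$cycles[, c("cycle", "pop_mean", "S", "R", "cum_S", "cum_R")], 4)
#>   cycle pop_mean      S       R  cum_S   cum_R
#> 1     1    0.753 -0.119 -0.0643 -0.119 -0.0643
#> 2     2    0.689 -0.154 -0.0978 -0.273 -0.162
#> 3     3    0.591 -0.167 -0.0909 -0.440 -0.253
#> 4     4    0.500 -0.186 -0.0780 -0.626 -0.331

# parent-offspring regression on 105 simulated families
fams <- simulate_parent_offspring(sim_config(h2 = 0.14, seed = 2025), 105)
parent_offspring_h2(fams$midparent, "midparent")
#> <h2_est> h2 = 0.188 (18.8%), se = 0.078, method = midparent, p = 0.0174

# complementation test with a graded background effect
qct_test(simulate_qct(c(D = 0.4, C = 0.7, N = 1.1), seed = 2026))
#> <qct_result> KW chi2(2) = 49.05, p = 2.23e-11; verdict: complemented
```

Reading the output: the selection line's ND ratio drops from 0.75 towards
0.3 over ten cycles; the cumulative-response regression recovers the
generating h² of 0.371 exactly here, with a drift standard deviation of
about √0.0021 ≈ 0.046. A single 105-family regression is much noisier
(18.8% for a true 14%, standard error 7.8%), which is why replicated runs
are used for calibration. The complementation verdict is `complemented`
because the cross means order D* < C* < N*, and both the omnibus KW test
and the N* vs D* KS contrast are significant.

`run_end_to_end()` chains all of the above (actogram simulation →
phenotyping → masking ANOVA → selection analysis in both directions →
parent–offspring regressions → QCT) into a single seeded, reproducible
report; `inst/cli/noctura.R` is a thin command-line wrapper over the same
functions.

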