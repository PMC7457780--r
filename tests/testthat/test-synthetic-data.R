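# The infinitesimal-model simulator: populations, actograms, selection
# experiments, families and reproducibility.

test_that("populations are reproducible and partition variance as configured", {
  cfg <- sim_config(seed = 301)
  expect_identical(simulate_population(cfg, 50), simulate_population(cfg, 50))

  flat <- simulate_population(sim_config(h2 = 0, seed = 302), 2000)
  expect_lt(var(flat$g), 1e-12)

  herit <- simulate_population(sim_config(h2 = 1, Vp = 0.04, seed = 303), 5000)
  expect_lt(abs(var(herit$true_nd) - 0.04), 0.004)
  # e is degenerate at h2 = 1; only the positivity floor perturbs the ratio
  expect_lt(abs(var(herit$g) / var(herit$true_nd) - 1), 0.01)

  # full sibs share half the additive variance through the family effect
  fam_means <- tapply(herit$g, herit$family_id, mean)
  expect_lt(abs(var(fam_means) / var(herit$g) - 0.75), 0.05)

  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(n_pop = 10, n_selected = 25), "n_selected")
})

test_that("simulated actograms hit the configured ND ratio and daily total", {
  cfg <- sim_config(total_activity_per_day = 8000)
  fly <- tibble::tibble(id = "a1", true_nd = 1.2, tau = 24)
  nd <- withr::with_seed(311, vapply(1:12, function(i) {
    act <- simulate_activity(fly, cfg, ld_days = 3, bin_minutes = 30)
    nd_ratio(act)$nd_ratio
  }, numeric(1)))
  mc_se <- sd(nd) / sqrt(length(nd))
  expect_lt(abs(mean(nd) - 1.2), 3 * mc_se + 0.01)

  act <- withr::with_seed(312, simulate_activity(fly, cfg, ld_days = 4))
  expect_lt(abs(sum(act$count) / 4 - 8000), 3 * sqrt(4 * 8000))
  expect_equal(unique(act$light), c("L", "D"))
})

test_that("masking reshapes the DD ratio but leaves LD calibration alone", {
  fly_noct <- tibble::tibble(id = "n1", true_nd = 1.6, tau = 24)
  nd_both <- function(masking_m, seed) {
    cfg <- sim_config(total_activity_per_day = 8000, masking_m = masking_m)
    act <- withr::with_seed(seed, simulate_activity(
      fly_noct, cfg, ld_days = 3, dd_days = 5, bin_minutes = 30))
    suppressWarnings(masking_nd(act))
  }
  masked <- dplyr::bind_rows(purrr::map(1:6, function(i) nd_both(0.6, 320 + i)))
  unmasked <- dplyr::bind_rows(purrr::map(1:6, function(i) nd_both(0, 340 + i)))
  # with masking the nocturnal fly turns much more diurnal in DD
  expect_lt(mean(masked$nd_dd), mean(masked$nd_ld) - 0.2)
  # without masking the expected ratio carries over into DD
  expect_lt(abs(mean(unmasked$delta)), 0.1)
})

test_that("free-running period and entrained phase behave as configured", {
  cfg <- sim_config(total_activity_per_day = 4000)
  fly <- tibble::tibble(id = "t1", true_nd = 1, tau = 24.5)
  act <- withr::with_seed(331, simulate_activity(fly, cfg, ld_days = 0,
                                                 dd_days = 7, bin_minutes = 30))
  est <- chi2_periodogram(act)
  expect_lt(abs(est$period_hours - 24.5), 0.25)

  # entrained unimodal fly: acrophase is stable across LD days (the
  # crepuscular default is bimodal, where the circular mean nearly cancels)
  cfg_uni <- sim_config(total_activity_per_day = 4000,
                        bump_phases = c(12, 12), bump_concentration = 3)
  fly24 <- tibble::tibble(id = "t2", true_nd = 1, tau = 24)
  ld <- withr::with_seed(332, simulate_activity(fly24, cfg_uni, ld_days = 5,
                                                bin_minutes = 30))
  expect_gt(acrophase(ld, 24)$R, 0.95)
})

test_that("selection experiments respond as the breeder's equation predicts", {
  # no genetic variance, no systematic response
  r0 <- withr::with_seed(341, vapply(1:60, function(i) {
    dplyr::last(run_selection_experiment(sim_config(h2 = 0), "diurnal")$cycles$cum_R)
  }, numeric(1)))
  expect_lt(abs(mean(r0)), 0.02)

  # h2 = 1 and no environmental noise: response tracks the differential
  # (up to Mendelian sampling)
  ex1 <- run_selection_experiment(sim_config(h2 = 1, seed = 342), "diurnal")
  expect_lt(mean(abs(ex1$cycles$R - ex1$cycles$S)),
            0.25 * mean(abs(ex1$cycles$S)))

  # opposite selection directions produce responses of opposite sign
  cfg <- sim_config(h2 = 0.371, seed = 343)
  up <- run_selection_experiment(cfg, "nocturnal")
  down <- run_selection_experiment(cfg, "diurnal")
  expect_gt(dplyr::last(up$cycles$cum_R), 0)
  expect_lt(dplyr::last(down$cycles$cum_R), 0)
  # same seed, same founders: cycle-1 population means coincide
  expect_equal(up$cycles$pop_mean[1], down$cycles$pop_mean[1])

  expect_identical(run_selection_experiment(cfg, "diurnal")$cycles,
                   run_selection_experiment(cfg, "diurnal")$cycles)
  expect_equal(nrow(up$cycles), 10)
  expect_equal(up$cycles$cum_S, cumsum(up$cycles$S))
})

test_that("the full Poisson-actogram phenotyping path mirrors the fast path", {
  cfg <- sim_config(n_pop = 24, n_selected = 4, n_cycles = 2,
                    total_activity_per_day = 4000, seed = 351)
  ex <- run_selection_experiment(cfg, "diurnal", phenotype = "full",
                                 ld_days = 2, bin_minutes = 30)
  expect_equal(nrow(ex$cycles), 2)
  # a diurnal selection moves the population towards lower ND
  expect_lt(ex$cycles$selected_male_mean[1], ex$cycles$pop_mean[1])
  expect_true(all(is.finite(ex$cycles$S)))
})

test_that("measured phenotypic variance approaches Vp as counts grow", {
  cfg_hi <- sim_config(h2 = 0.4, total_activity_per_day = 60000, seed = 361)
  cfg_lo <- sim_config(h2 = 0.4, total_activity_per_day = 150, seed = 361)
  pop <- simulate_population(cfg_hi, 60)
  measure_var <- function(cfg) {
    acts <- simulate_actograms(pop, cfg, ld_days = 2, bin_minutes = 30,
                               seed = 362)
    var(suppressWarnings(nd_ratio(acts))$nd_ratio)
  }
  v_hi <- measure_var(cfg_hi)
  v_lo <- measure_var(cfg_lo)
  expect_lt(abs(v_hi - var(pop$true_nd)), 0.2 * var(pop$true_nd))
  expect_gt(v_lo, v_hi)
})

test_that("family tables regress as expected and are reproducible", {
  cfg <- sim_config(h2 = 0.14, seed = 371)
  a <- simulate_parent_offspring(cfg, 105)
  b <- simulate_parent_offspring(cfg, 105)
  expect_identical(a, b)
  expect_equal(nrow(a$midparent), 105)
  expect_equal(names(a), c("midparent", "mother_daughter", "father_son"))

  flat <- simulate_parent_offspring(sim_config(h2 = 0, seed = 372), 4000)
  expect_lt(abs(parent_offspring_h2(flat$midparent)$h2), 0.05)
})

test_that("simulate_qct draws the requested cells reproducibly", {
  q <- simulate_qct(c(N = 1.1, C = 0.7, D = 0.4), n_per_cell = 7, seed = 381)
  expect_equal(nrow(q), 21)
  expect_setequal(unique(q$background), c("N*", "C*", "D*"))
  expect_identical(q, simulate_qct(c(N = 1.1, C = 0.7, D = 0.4),
                                   n_per_cell = 7, seed = 381))
  withr::with_seed(382, {
    qc <- simulate_qct(c(N = 1.1, C = 0.7, D = 0.4),
                       control_means = c(N = 0.7, C = 0.7, D = 0.7))
    expect_setequal(unique(qc$allele), c("mutant", "control"))
  })
})
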