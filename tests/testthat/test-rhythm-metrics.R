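# Per-fly circadian phenotyping: ND ratio, rhythmicity, period, acrophase,
# sleep, masking and phase shifts.

test_that("ZT hours map onto the circle at 15 degrees per hour", {
  expect_identical(zt_to_angle(1), 15)
  expect_identical(zt_to_angle(12), 180)
  expect_identical(zt_to_angle(24), 0)
  expect_equal(zt_to_angle(-2), 330)
})

test_that("nd_ratio is the night/day count ratio with the expected symmetries", {
  counts <- c(rep(10L, 10), 0L, 0L, rep(10L, 12))  # day sum 100, night sum 120
  s <- make_activity(counts, light = ld_flags(24))
  expect_equal(nd_ratio(s)$nd_ratio, 1.2)

  eq <- make_activity(rep(5L, 24), light = ld_flags(24))
  expect_equal(nd_ratio(eq)$nd_ratio, 1)

  # scale invariance
  s7 <- s; s7$count <- s7$count * 7L
  expect_equal(nd_ratio(s7)$nd_ratio, nd_ratio(s)$nd_ratio)

  # swapping L and D labels inverts the ratio
  sw <- s; sw$light <- ifelse(s$light == "L", "D", "L")
  expect_equal(nd_ratio(sw)$nd_ratio, 1 / nd_ratio(s)$nd_ratio)

  # daily ratios average across complete days
  two <- make_activity(c(counts, rep(c(0L, 20L), each = 12)),
                       light = ld_flags(48))
  daily <- nd_ratio_daily(two)
  expect_equal(daily$nd_day, c(1.2, Inf))
  expect_warning(out <- nd_ratio(two), "infinite")
  expect_equal(out$nd_ratio, 1.2)
  expect_equal(out$n_days_inf, 1L)
})

test_that("nd_ratio rejects incomplete or silent recordings", {
  short <- make_activity(rep(1L, 10), light = ld_flags(10))
  expect_error(nd_ratio(short), "complete 24 h day")
  silent <- make_activity(rep(0L, 24), light = ld_flags(24))
  expect_error(nd_ratio(silent), "no activity")
  expect_error(nd_ratio(make_activity(rep(1L, 24))), "light-annotated")
})

test_that("Fisher's exact g p-value matches the closed form and a DFT peak", {
  # m = 5 ordinates, g = 0.9: only the j = 1 term survives, p = 5 * 0.1^4
  expect_equal(noctura:::fisher_g_pvalue(0.9, 5), 5e-4)
  # closed form against a Monte-Carlo permutation oracle at small m
  set.seed(21)
  m <- 6
  ords <- rexp(m)
  g_obs <- max(ords) / sum(ords)
  mc <- mean(replicate(4000, {
    o <- rexp(m); max(o) / sum(o) >= g_obs
  }))
  expect_equal(noctura:::fisher_g_pvalue(g_obs, m), mc, tolerance = 0.15)

  s <- make_activity(sine_counts(5, 30, 24), bin_minutes = 30)
  res <- fisher_g_test(s)
  expect_equal(res$peak_period_hours, 24)
  expect_lt(res$g_pvalue, 1e-6)

  expect_error(fisher_g_test(make_activity(rep(3L, 48), bin_minutes = 30)),
               "zero variance")
  expect_error(fisher_g_test(make_activity(c(1L, rep(0L, 9)))), ">= 16 bins")
})

test_that("chi-square periodogram recovers a known period and stays quiet on noise", {
  set.seed(31)
  s <- make_activity(sine_counts(7, 30, 23.5, poisson = TRUE), bin_minutes = 30)
  est <- chi2_periodogram(s)
  expect_true(est$significant)
  expect_lt(abs(est$period_hours - 23.5), 0.25)

  # white noise: false-positive rate near the nominal level
  hits <- vapply(1:200, function(i) {
    w <- make_activity(rpois(336, 20), bin_minutes = 30)
    chi2_periodogram(w)$significant
  }, logical(1))
  expect_lt(mean(hits), 0.12)

  expect_error(chi2_periodogram(make_activity(rpois(48, 5), bin_minutes = 30)),
               "shorter than 2 x p_max")
  # full scan exposes the whole periodogram
  scan <- chi2_periodogram(s, full = TRUE)
  expect_equal(nrow(scan), length(seq(18, 30, 0.1)))
})

test_that("Lomb-Scargle cross-check agrees with the chi-square estimate", {
  set.seed(32)
  s <- make_activity(sine_counts(7, 30, 25, poisson = TRUE), bin_minutes = 30)
  ls <- lomb_scargle_periodogram(s)
  x2 <- chi2_periodogram(s)
  expect_true(ls$significant)
  expect_lt(abs(ls$period_hours - x2$period_hours), 0.3)
})

test_that("acrophase has point-mass, shift-equivariance and uniform-case behaviour", {
  # all activity at ZT6 each day
  counts <- rep(0L, 72); counts[c(7, 31, 55)] <- 50L
  s <- make_activity(counts)
  a <- acrophase(s, 24)
  expect_equal(a$mean_deg, zt_to_angle(6.5))  # bin midpoint 6.5 h
  expect_equal(a$R, 1)
  expect_equal(a$n_cycles, 3L)

  # shifting activity 2 h later rotates the phase by +30 degrees
  s2 <- make_activity(c(rep(0L, 2), counts[1:70]))
  a2 <- acrophase(s2, 24)
  expect_equal((a2$mean_deg - a$mean_deg) %% 360, 30)
  expect_equal(a2$R, a$R)

  # uniform activity: no direction, CI undefined
  u <- acrophase(make_activity(rep(5L, 72)), 24)
  expect_lt(u$R, 1e-6)
  expect_true(is.na(u$ci95_deg))
})

test_that("circular 95% CI covers the true direction at about the nominal rate", {
  set.seed(41)
  mu <- 80
  cover <- vapply(1:300, function(i) {
    ang <- (mu + 25 * rnorm(8)) %% 360
    cm <- noctura:::circ_mean_deg(ang)
    ci <- noctura:::circ_ci95_deg(length(ang), cm$R)
    if (is.na(ci)) return(NA)
    diff <- abs(((cm$mean_deg - mu + 180) %% 360) - 180)
    diff <= ci
  }, logical(1))
  expect_gt(mean(cover, na.rm = TRUE), 0.88)
  expect_lt(mean(cover, na.rm = TRUE), 0.99)
})

test_that("morning and evening peaks land in their windows for crepuscular flies", {
  cfg <- sim_config(total_activity_per_day = 6000, seed = 51)
  fly <- tibble::tibble(id = "c1", true_nd = 1, tau = 24)
  act <- withr::with_seed(51, simulate_activity(fly, cfg, ld_days = 4,
                                                bin_minutes = 30))
  pk <- morning_evening_peaks(act)
  # circular distance to the template bump phases (ZT0, ZT12)
  expect_lt(abs(((pk$mp_deg + 180) %% 360) - 180), 20)
  expect_lt(abs(pk$ep_deg - 180), 20)

  # unimodal midday activity: MP window empty, EP defined
  counts <- rep(0L, 48); counts[23:26] <- 30L  # around ZT11-13
  uni <- make_activity(counts, bin_minutes = 30, light = ld_flags(48, 30))
  expect_warning(pk2 <- morning_evening_peaks(uni), "ZT21-ZT3")
  expect_true(is.na(pk2$mp_deg))
  expect_false(is.na(pk2$ep_deg))
})

test_that("sleep scoring counts minutes in immobile runs of five or more", {
  allzero <- make_activity(rep(0L, 1440), bin_minutes = 1)
  sp <- sleep_profile(allzero)
  expect_equal(sp$sleep_min, rep(60, 24))

  active <- make_activity(rep(c(1L, 0L, 0L, 0L), 360), bin_minutes = 1)
  expect_equal(sum(sleep_profile(active)$sleep_min), 0)

  counts <- rep(1L, 1440)
  counts[181:190] <- 0L  # a 10-minute run starting at minute 0 of hour 3
  one <- sleep_profile(make_activity(counts, bin_minutes = 1))
  expect_equal(one$sleep_min[one$hour == 3], 10)
  expect_equal(sum(one$sleep_min), 10)

  expect_error(sleep_profile(make_activity(rep(0L, 48), bin_minutes = 30)),
               "1-minute bins")
})

test_that("masking contrast is null for identical LD and DD behaviour", {
  set.seed(61)
  wide <- tibble::tibble(
    fly_id = sprintf("f%02d", 1:20),
    genotype = rep(c("N", "D"), each = 10),
    nd_ld = rnorm(20, rep(c(1.2, 0.4), each = 10), 0.1)
  )
  wide$nd_dd <- wide$nd_ld
  res <- masking_contrast(wide)
  g <- glance(res)
  expect_equal(res$groups$delta, c(0, 0))
  expect_gt(g$p_regime, 0.9)
  expect_lt(g$p_genotype, 1e-6)
})

test_that("phase shifts are zero for identical series and signed for delays", {
  # unimodal evening activity: a stable acrophase to compare against
  cfg <- sim_config(total_activity_per_day = 4000, bump_phases = c(12, 12),
                    bump_concentration = 3, seed = 71)
  fly <- tibble::tibble(id = "p1", true_nd = 1, tau = 24)
  act <- withr::with_seed(71, simulate_activity(fly, cfg, ld_days = 0,
                                                dd_days = 7, bin_minutes = 30))
  expect_equal(phase_shift(act, act)$shift_hours, 0)

  roll <- function(d, k) { d$count <- c(tail(d$count, k), head(d$count, -k)); d }
  delayed <- roll(act, 4)   # activity 2 h later
  ps <- phase_shift(act, delayed)
  expect_lt(abs(ps$shift_hours - (-2)), 0.5)
  advanced <- roll(act, -2) # 1 h earlier
  expect_lt(abs(phase_shift(act, advanced)$shift_hours - 1), 0.5)

  noise <- make_activity(withr::with_seed(72, rpois(336, 10)), bin_minutes = 30)
  expect_warning(ps0 <- phase_shift(noise, noise), "arrhythmic")
  expect_true(is.na(ps0$shift_hours))
})

test_that("phenotype_flies assembles one row per fly", {
  cfg <- sim_config(seed = 81)
  pop <- simulate_population(cfg, n_families = 3)
  acts <- simulate_actograms(pop[pop$sex == "M", ], cfg, ld_days = 3,
                             bin_minutes = 30)
  ph <- phenotype_flies(acts)
  expect_equal(nrow(ph), 3)
  expect_true(all(c("nd_ratio", "g_pvalue", "rhythmic", "acrophase_deg")
                  %in% names(ph)))
  expect_true(all(ph$rhythmic))
})
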