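# Selection differentials, realized heritability and parent-offspring
# regression.

test_that("selection differential weights both parental sexes equally", {
  pop <- c(rep(0.8, 8), 1.4, 0.9)
  expect_equal(selection_differential(pop, pop), 0)
  expect_equal(selection_differential(rep(0.8, 10), rep(1.4, 2), rep(0.9, 2)),
               0.35)
  # sisters at the population mean: half the male differential
  expect_equal(selection_differential(rep(0.8, 10), rep(1.4, 2), rep(0.8, 2)),
               0.3)
  expect_equal(selection_differential(rep(0.8, 10), rep(1.4, 2)), 0.3)
  expect_error(selection_differential(pop, numeric(0)), "empty")
})

test_that("realized h2 is the through-origin slope of cum R on cum S", {
  flat <- tibble::tibble(S = rep(0.2, 5), R = rep(0, 5))
  expect_equal(realized_h2(flat)$h2, 0)

  exact <- tibble::tibble(S = c(0.3, 0.2, 0.25), R = c(0.15, 0.1, 0.125))
  est <- realized_h2(exact)
  expect_equal(est$h2, 0.5)
  expect_equal(est$se, 0)
  expect_equal(est$method, "realized")

  # cum_S / cum_R columns are accepted too
  cums <- tibble::tibble(cum_S = cumsum(exact$S), cum_R = cumsum(exact$R))
  expect_equal(realized_h2(cums)$h2, 0.5)

  expect_error(realized_h2(tibble::tibble(S = c(0, 0), R = c(0, 0))),
               "no selection")
  expect_error(realized_h2(exact[1, ]), "at least 2")
})

test_that("realized h2 recovers the generator value; the naive slope overshoots", {
  reps <- withr::with_seed(101, {
    lapply(1:200, function(i) {
      ex <- run_selection_experiment(sim_config(h2 = 0.30), "diurnal")
      c(adj = realized_h2(ex$cycles)$h2,
        plain = realized_h2(ex$cycles, adjust = "none")$h2)
    })
  })
  adj <- vapply(reps, `[[`, numeric(1), "adj")
  plain <- vapply(reps, `[[`, numeric(1), "plain")
  expect_lt(abs(mean(adj) - 0.30), 0.03)
  # charging the sisters' (fully heritable) deviation into S biases the
  # plain slope towards 3 h2 / (2 + h2)
  expect_gt(mean(plain), mean(adj) + 0.05)
  expect_lt(abs(mean(plain) - 3 * 0.3 / (2 + 0.3)), 0.04)
})

test_that("realized h2 is noisier when fewer males are selected (drift)", {
  est_sd <- function(n_sel, seed) {
    cfg <- sim_config(h2 = 0.3, n_pop = 300, n_selected = n_sel, seed = NULL)
    withr::with_seed(seed, {
      sd(vapply(1:120, function(i) {
        realized_h2(run_selection_experiment(cfg, "diurnal")$cycles)$h2
      }, numeric(1)))
    })
  }
  expect_gt(est_sd(5, 102), est_sd(50, 103))
})

test_that("drift variance bootstrap returns a plausible slope variance", {
  cfg <- sim_config(h2 = 0.3, seed = 104)
  ex <- run_selection_experiment(cfg, "diurnal")
  est <- realized_h2(ex$cycles, drift_reps = 60, config = cfg)
  expect_true(is.finite(est$drift_var) && est$drift_var > 0)
  expect_lt(sqrt(est$drift_var), 0.2)
})

test_that("parent-offspring regression estimates h2 with the right scaling", {
  # offspring identical to midparent: slope and h2 are 1
  mp <- tibble::tibble(parent = seq(0.5, 1.1, by = 0.05))
  mp$offspring <- mp$parent
  expect_equal(parent_offspring_h2(mp, "midparent")$h2, 1)

  # independence: h2 near zero, non-significant
  set.seed(111)
  null <- tibble::tibble(parent = rnorm(600, 0.8, 0.15),
                         offspring = rnorm(600, 0.8, 0.15))
  est0 <- parent_offspring_h2(null, "midparent")
  expect_lt(abs(est0$h2), 0.12)
  expect_gt(est0$p.value, 0.05)

  # breeder's-equation oracle: midparent slope = h2, single-parent = h2/2
  fams <- simulate_parent_offspring(sim_config(h2 = 0.4, seed = 112),
                                    n_families = 10000, n_progeny = 2)
  est_mp <- parent_offspring_h2(fams$midparent, "midparent")
  est_mo <- parent_offspring_h2(fams$mother_daughter, "single_mother")
  expect_lt(abs(est_mp$h2 - 0.4), 0.03)
  expect_lt(abs(est_mo$h2 - 0.4), 0.06)
  expect_lt(abs(est_mo$slope - 0.2), 0.03)
  expect_lt(est_mp$p.value, 1e-6)

  degenerate <- tibble::tibble(parent = rep(1, 5), offspring = rnorm(5))
  expect_error(parent_offspring_h2(degenerate), "zero variance")
})

test_that("h2_est objects tidy and glance like broom fits", {
  est <- parent_offspring_h2(
    tibble::tibble(parent = c(0.6, 0.8, 1, 1.2), offspring = c(0.7, 0.8, 0.9, 1)),
    "midparent")
  td <- tidy(est)
  expect_equal(td$term, "h2")
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(est)
  expect_equal(gl$method, "midparent")
  expect_equal(gl$h2, td$estimate)
})
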