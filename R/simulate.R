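# Infinitesimal-model simulator of heritable diurnal preference: founder
# populations, Poisson actograms under LD/DD with light masking, multi-cycle
# truncation-selection experiments, parent-offspring families and QCT cross
# tables.

maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Simulation configuration
#'
#' Bundles the population and actogram parameters of the simulator. The
#' defaults describe the selection-experiment conditions emulated by the
#' package: 300 males phenotyped per cycle, the 25 most extreme selected and
#' crossed to unselected sisters, 10 cycles; a founder ND-ratio mean of 0.75
#' with phenotypic variance 0.02; crepuscular activity with morning and
#' evening bumps at ZT0 and ZT12; a free-running period near 24.2 h; and a
#' light-masking coefficient of 0.6 (most of a nocturnal fly's excess
#' nocturnality is light-driven and relaxes in DD).
#'
#' @param n_pop Males phenotyped per cycle.
#' @param n_selected Extreme males selected per cycle.
#' @param n_cycles Selection cycles.
#' @param h2 Narrow-sense heritability of the ND ratio, in `[0, 1]`.
#' @param nd_mean Founder population mean ND ratio.
#' @param Vp Phenotypic variance of the ND ratio.
#' @param total_activity_per_day Expected beam crossings per fly per day.
#' @param masking_m Light-masking coefficient (0 = none; 1 = all excess
#'   nocturnality is light-driven and disappears in DD).
#' @param tau_mean,tau_sd Mean and SD of the free-running period (hours).
#' @param bump_phases ZT hours of the morning and evening activity bumps.
#' @param bump_concentration von Mises concentration of the bumps.
#' @param measurement_sd Extra Gaussian measurement noise used by the fast
#'   phenotyping path (0 = phenotype equals true ND plus the environmental
#'   deviation already in Vp).
#' @param nd_floor Positivity floor for ND phenotypes on the ratio scale.
#' @param seed Optional integer seed making top-level generators
#'   reproducible.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_pop = 300, n_selected = 25, n_cycles = 10,
                       h2 = 0.371, nd_mean = 0.75, Vp = 0.02,
                       total_activity_per_day = 1200, masking_m = 0.6,
                       tau_mean = 24.2, tau_sd = 0.2,
                       bump_phases = c(0, 12), bump_concentration = 2,
                       measurement_sd = 0, nd_floor = 0.01, seed = NULL) {
  if (h2 < 0 || h2 > 1) abort("h2 must be in [0, 1]")
  if (n_selected > n_pop) abort("n_selected must be <= n_pop")
  if (Vp <= 0) abort("Vp must be positive")
  if (total_activity_per_day <= 0) abort("total_activity_per_day must be positive")
  if (masking_m < 0) abort("masking_m must be >= 0")
  if (bump_concentration <= 0) abort("bump_concentration must be positive")
  if (length(bump_phases) != 2) abort("bump_phases must give morning and evening ZT")
  structure(
    list(n_pop = as.integer(n_pop), n_selected = as.integer(n_selected),
         n_cycles = as.integer(n_cycles), h2 = h2, nd_mean = nd_mean,
         Vp = Vp, total_activity_per_day = total_activity_per_day,
         masking_m = masking_m, tau_mean = tau_mean, tau_sd = tau_sd,
         bump_phases = bump_phases, bump_concentration = bump_concentration,
         measurement_sd = measurement_sd, nd_floor = nd_floor, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d males/cycle, %d selected, %d cycles; ",
                     "h2 = %.3f, ND mean %.2f, Vp %.3f, masking %.2f, ",
                     "tau %.1f +/- %.1f h%s\n"),
              x$n_pop, x$n_selected, x$n_cycles, x$h2, x$nd_mean, x$Vp,
              x$masking_m, x$tau_mean, x$tau_sd,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}

# one full-sib family: shared effect a (var h2*Vp/2) + Mendelian deviation
# (var h2*Vp/2) per individual; environmental deviation var (1-h2)*Vp.
sim_family_members <- function(n_families, per_sex, config) {
  G <- config$h2 * config$Vp
  E <- (1 - config$h2) * config$Vp
  a <- rnorm(n_families, 0, sqrt(G / 2))
  purrr::map(c("M", "F"), function(sx) {
    tibble(
      family_id = rep(sprintf("F%04d", seq_len(n_families)), each = per_sex),
      sex = sx,
      g = rep(a, each = per_sex) + rnorm(n_families * per_sex, 0, sqrt(G / 2)),
      e = rnorm(n_families * per_sex, 0, sqrt(E))
    )
  }) %>%
    bind_rows() %>%
    mutate(true_nd = pmax(config$nd_mean + .data$g + .data$e, config$nd_floor),
           tau = rnorm(dplyr::n(), config$tau_mean, config$tau_sd),
           id = sprintf("%s%s%02d", .data$family_id, .data$sex,
                        stats::ave(seq_len(dplyr::n()),
                                   paste(.data$family_id, .data$sex),
                                   FUN = seq_along))) %>%
    select("id", "sex", "family_id", "g", "e", "true_nd", "tau")
}

#' Simulate a founder population
#'
#' Draws a population of full-sib male/female pairs under the infinitesimal
#' model: breeding values are Gaussian with variance `h2 * Vp` (half shared
#' within a family, half individual Mendelian sampling), environmental
#' deviations Gaussian with variance `(1 - h2) * Vp`, and the ND phenotype
#' is their sum around `nd_mean`, floored at `nd_floor`.
#'
#' @param config A [sim_config()].
#' @param n_families Number of full-sib families (one male and one female
#'   each); defaults to `config$n_pop`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A tibble with columns `id`, `sex`, `family_id`, `g`, `e`,
#'   `true_nd`, `tau`.
#' @export
simulate_population <- function(config, n_families = config$n_pop,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  maybe_with_seed(seed, sim_family_members(n_families, 1L, config))
}

# two von Mises bumps on the circadian cycle, phase in cycles [0, 1)
activity_template <- function(phase, config) {
  k <- config$bump_concentration
  pm <- config$bump_phases / 24
  exp(k * cos(2 * pi * (phase - pm[1]))) + exp(k * cos(2 * pi * (phase - pm[2])))
}

#' Simulate one fly's actogram
#'
#' Generates Poisson counts from a per-bin intensity built from a
#' crepuscular two-bump template on the fly's circadian cycle (entrained at
#' 24 h under LD, free-running at the fly's `tau` in DD). Counts are
#' allocated between clock-night and clock-day so that the expected
#' night/day ratio in LD equals the fly's `true_nd`; the light-driven share
#' of that nocturnality is a multiplicative suppression of activity during
#' the light phase, `exp(-masking_m * x)` with
#' `x = log(true_nd / template_nd)`, so in constant darkness the expected
#' ratio relaxes to `template_nd * exp((1 - masking_m) * x)` (equal to
#' `true_nd` when `masking_m = 0`). Expected total activity is
#' `total_activity_per_day` counts per day.
#'
#' @param ind A one-row tibble (or list) with `id`, `true_nd` and `tau`.
#' @param config A [sim_config()].
#' @param ld_days Days of 12:12 LD from lights-on.
#' @param dd_days Days of constant darkness appended after the LD block.
#' @param bin_minutes Bin width (must divide 1440).
#' @param t0 Timestamp of the first bin (lights-on).
#' @return A light-annotated activity tibble for one fly.
#' @export
simulate_activity <- function(ind, config, ld_days = 5, dd_days = 0,
                              bin_minutes = 1,
                              t0 = as.POSIXct("2024-01-01 08:00:00",
                                              tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  if (ld_days + dd_days < 1) abort("need at least one day")
  if (1440 %% bin_minutes != 0) abort("bin_minutes must divide 1440")
  b <- bin_minutes
  n_days <- ld_days + dd_days
  n <- n_days * 1440 / b
  t_mid <- (seq_len(n) - 0.5) * b
  in_dd <- t_mid > ld_days * 1440
  clock_min <- t_mid %% 1440
  is_light_phase <- clock_min < 720
  light <- ifelse(in_dd,
                  ifelse(is_light_phase, "subjL", "subjD"),
                  ifelse(is_light_phase, "L", "D"))
  # circadian phase: entrained at 24 h in LD, free-running at tau in DD
  phase <- ifelse(in_dd,
                  ((t_mid - ld_days * 1440) / 60 / ind$tau) %% 1,
                  (clock_min / 1440))
  tmpl <- activity_template(phase, config)
  # intrinsic night/day ratio of the template on an entrained day
  day_phase <- ((seq_len(1440 / b) - 0.5) * b) / 1440
  tmpl_day <- activity_template(day_phase, config)
  template_nd <- sum(tmpl_day[day_phase >= 0.5]) / sum(tmpl_day[day_phase < 0.5])
  x <- log(max(ind$true_nd, config$nd_floor) / template_nd)
  lam <- tmpl *
    exp((1 - config$masking_m) * x * (phase >= 0.5)) *   # clock-driven share
    exp(-config$masking_m * x * (light == "L"))          # light masking
  lam <- lam * config$total_activity_per_day * n_days / sum(lam)
  tibble(fly_id = as.character(ind$id),
         time = t0 + (seq_len(n) - 1) * b * 60,
         count = rpois(n, lam),
         light = light)
}

#' Simulate actograms for a whole population
#'
#' @param pop A population tibble from [simulate_population()].
#' @param config A [sim_config()].
#' @param ... Passed to [simulate_activity()] (`ld_days`, `dd_days`,
#'   `bin_minutes`, `t0`).
#' @param seed Seed (defaults to `config$seed`).
#' @return A light-annotated activity tibble for all flies.
#' @export
simulate_actograms <- function(pop, config, ..., seed = config$seed) {
  maybe_with_seed(seed, {
    pop %>%
      dplyr::rowwise() %>%
      dplyr::group_split() %>%
      purrr::map(function(ind) simulate_activity(ind, config, ...)) %>%
      bind_rows()
  })
}

# fast phenotype: true ND plus optional extra measurement noise
fast_phenotype <- function(true_nd, config) {
  if (config$measurement_sd > 0) {
    pmax(true_nd + rnorm(length(true_nd), 0, config$measurement_sd),
         config$nd_floor)
  } else {
    true_nd
  }
}

full_phenotype <- function(pop, config, ld_days, bin_minutes) {
  acts <- pop %>%
    dplyr::rowwise() %>%
    dplyr::group_split() %>%
    purrr::map(function(ind) {
      simulate_activity(ind, config, ld_days = ld_days, dd_days = 0,
                        bin_minutes = bin_minutes)
    }) %>%
    bind_rows()
  nd <- suppressWarnings(nd_ratio(acts))
  nd$nd_ratio[match(pop$id, nd$fly_id)]
}

#' Run a multi-cycle artificial-selection experiment in silico
#'
#' Emulates the selection design: each cycle, `n_pop` males are phenotyped
#' for their ND ratio, the `n_selected` most extreme in the chosen
#' direction are selected and each is crossed to a random unselected full
#' sister; offspring breeding values are midparent plus a Mendelian
#' sampling deviation of variance `h2 * Vp / 2`. Per cycle the population
#' mean and variance, the selected-male and mated-sister means, the
#' selection differential S (see [selection_differential()]) and the
#' response R (next-generation male mean minus current mean) are recorded,
#' with running sums `cum_S`, `cum_R`.
#'
#' @param config A [sim_config()].
#' @param direction `"diurnal"` (select smallest ND) or `"nocturnal"`
#'   (largest).
#' @param phenotype `"fast"` (analytic ND plus optional Gaussian measurement
#'   noise) or `"full"` (Poisson actogram via [simulate_activity()] scored
#'   with [nd_ratio()]).
#' @param ld_days,bin_minutes Recording length and bin width for the full
#'   phenotyping path.
#' @param seed Seed (defaults to `config$seed`).
#' @return A `selection_experiment` object: `$cycles` (one row per cycle)
#'   and `$truth` (the generating parameters).
#' @export
run_selection_experiment <- function(config,
                                     direction = c("diurnal", "nocturnal"),
                                     phenotype = c("fast", "full"),
                                     ld_days = 3, bin_minutes = 30,
                                     seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  direction <- match.arg(direction)
  phenotype <- match.arg(phenotype)
  maybe_with_seed(seed, {
    G <- config$h2 * config$Vp
    E <- (1 - config$h2) * config$Vp
    n_pop <- config$n_pop; n_sel <- config$n_selected
    pheno_of <- function(pop) {
      if (phenotype == "fast") fast_phenotype(pop$true_nd, config)
      else full_phenotype(pop, config, ld_days, bin_minutes)
    }
    pop <- sim_family_members(n_pop, 1L, config)
    males <- pop %>% filter(.data$sex == "M")
    females <- pop %>% filter(.data$sex == "F")
    recs <- vector("list", config$n_cycles)
    for (k in seq_len(config$n_cycles)) {
      pm <- pheno_of(males)
      sel <- order(pm, decreasing = (direction == "nocturnal"))[seq_len(n_sel)]
      # each selected male mates a random unselected sister from his family
      mates <- purrr::map_int(sel, function(i) {
        cand <- which(females$family_id == males$family_id[i])
        if (length(cand) == 0) {
          abort("fewer sisters than selected males (a family has no female)")
        }
        if (length(cand) == 1) cand else sample(cand, 1)
      })
      pf <- pheno_of(females[mates, ])
      S <- selection_differential(pm, pm[sel], pf)
      # progeny: families of equal expected size filling n_pop per sex
      base <- n_pop %/% n_sel
      sizes <- rep(base, n_sel) + rep(c(1L, 0L), c(n_pop - base * n_sel,
                                                   n_sel - (n_pop - base * n_sel)))
      mid <- (males$g[sel] + females$g[mates]) / 2
      make_sex <- function(sx) {
        tibble(
          family_id = rep(sprintf("C%02dF%03d", k, seq_len(n_sel)), sizes),
          sex = sx,
          g = rep(mid, sizes) + rnorm(n_pop, 0, sqrt(G / 2)),
          e = rnorm(n_pop, 0, sqrt(E))
        ) %>%
          mutate(true_nd = pmax(config$nd_mean + .data$g + .data$e,
                                config$nd_floor),
                 tau = rnorm(n_pop, config$tau_mean, config$tau_sd),
                 id = sprintf("%s%s%02d", .data$family_id, sx,
                              stats::ave(seq_len(n_pop), .data$family_id,
                                         FUN = seq_along)))
      }
      males_next <- make_sex("M")
      females_next <- make_sex("F")
      pm_next <- pheno_of(males_next)
      recs[[k]] <- tibble(
        cycle = k,
        pop_mean = mean(pm), pop_var = var(pm),
        selected_male_mean = mean(pm[sel]),
        sibling_female_mean = mean(pf),
        progeny_mean = mean(pm_next),
        S = S, R = mean(pm_next) - mean(pm),
        n_phenotyped = n_pop, n_selected = n_sel
      )
      males <- males_next; females <- females_next
    }
    cycles <- bind_rows(recs) %>%
      mutate(cum_S = cumsum(.data$S), cum_R = cumsum(.data$R))
    structure(
      list(cycles = cycles,
           truth = list(h2 = config$h2, Vp = config$Vp,
                        nd_mean = config$nd_mean, direction = direction,
                        seed = seed),
           config = config, direction = direction),
      class = "selection_experiment"
    )
  })
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat(sprintf("<selection_experiment> %s selection, %d cycles, cum S = %.3f, cum R = %.3f (true h2 = %.3f)\n",
              x$direction, nrow(x$cycles), last(x$cycles$cum_S),
              last(x$cycles$cum_R), x$truth$h2))
  invisible(x)
}

#' @export
tidy.selection_experiment <- function(x, ...) x$cycles

#' Simulate parent-offspring families
#'
#' Families of two unrelated measured parents and `n_progeny` measured
#' offspring (alternating sexes) under the infinitesimal model. Returns the
#' three regression tables used for heritability estimation.
#'
#' @param config A [sim_config()].
#' @param n_families Number of families.
#' @param n_progeny Offspring per family (at least 2 so both sexes appear).
#' @param seed Seed (defaults to `config$seed`).
#' @return A list of tibbles `midparent` (mid-parent vs mid-progeny),
#'   `mother_daughter` and `father_son` (single parent vs one offspring),
#'   each with columns `family_id`, `parent`, `offspring`.
#' @export
simulate_parent_offspring <- function(config, n_families = 105,
                                      n_progeny = 4, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_families < 3) abort("need at least 3 families")
  if (n_progeny < 2) abort("need at least 2 progeny per family")
  maybe_with_seed(seed, {
    G <- config$h2 * config$Vp
    E <- (1 - config$h2) * config$Vp
    measure <- function(g) {
      fast_phenotype(pmax(config$nd_mean + g + rnorm(length(g), 0, sqrt(E)),
                          config$nd_floor), config)
    }
    g_mo <- rnorm(n_families, 0, sqrt(G))
    g_fa <- rnorm(n_families, 0, sqrt(G))
    p_mo <- measure(g_mo); p_fa <- measure(g_fa)
    n_off <- n_families * n_progeny
    g_o <- rep((g_mo + g_fa) / 2, each = n_progeny) + rnorm(n_off, 0, sqrt(G / 2))
    p_o <- matrix(measure(g_o), nrow = n_progeny)   # one column per family
    fam <- sprintf("F%04d", seq_len(n_families))
    list(
      midparent = tibble(family_id = fam, parent = (p_mo + p_fa) / 2,
                         offspring = colMeans(p_o)),
      # within each family the first offspring is a daughter, the second a son
      mother_daughter = tibble(family_id = fam, parent = p_mo,
                               offspring = p_o[1, ]),
      father_son = tibble(family_id = fam, parent = p_fa,
                          offspring = p_o[2, ])
    )
  })
}

#' Simulate a quantitative-complementation cross table
#'
#' Draws per-fly ND values for the mutant-allele (and optionally
#' control-allele) crosses into the three backgrounds from normal
#' distributions with the given means. Background or allele-by-background
#' effects are expressed directly through the supplied means.
#'
#' @param means Named numeric vector of mutant-cross means for backgrounds
#'   `N*`, `D*`, `C*` (names may omit the star).
#' @param sd Common within-cell standard deviation.
#' @param n_per_cell Flies per cell.
#' @param control_means Optional named means for control-allele crosses.
#' @param gene Optional gene label.
#' @param nd_floor Positivity floor applied to drawn values.
#' @param seed Optional seed.
#' @return A tibble with columns `gene` (if given), `background`, `allele`,
#'   `fly_id`, `nd`, suitable for [qct_test()].
#' @export
simulate_qct <- function(means, sd = 0.15, n_per_cell = 20,
                         control_means = NULL, gene = NULL,
                         nd_floor = 0.01, seed = NULL) {
  draw <- function(mns, allele) {
    bg <- normalise_background(names(mns))
    purrr::map2(bg, as.numeric(mns), function(b, mu) {
      tibble(background = b, allele = allele,
             fly_id = sprintf("%s_%s_%02d", b, allele, seq_len(n_per_cell)),
             nd = pmax(rnorm(n_per_cell, mu, sd), nd_floor))
    }) %>% bind_rows()
  }
  maybe_with_seed(seed, {
    if (length(means) != 3) abort("means must name the three backgrounds")
    out <- draw(means, "mutant")
    if (!is.null(control_means)) out <- bind_rows(out, draw(control_means, "control"))
    if (!is.null(gene)) out <- mutate(out, gene = gene, .before = 1)
    out
  })
}
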