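# Quantitative genetics of diurnal preference: selection differentials,
# realized heritability from multi-cycle truncation selection (with a
# correction for sib-mating designs), and parent-offspring regression.

#' Selection differential with equal sex weighting
#'
#' For a design in which males are truncation-selected and each is mated to
#' a female (here, his unselected sister), the per-cycle differential is
#' \deqn{S = (\bar P_{males,sel} - \bar P_{pop})/2 +
#'           (\bar P_{females,mated} - \bar P_{pop})/2,}
#' i.e. both parental sexes are charged with their actual mean phenotypic
#' deviation from the phenotyped population. When `sibling_females` is
#' `NULL` the mated females are taken as a random population sample
#' (expected deviation zero) and S is half the male differential.
#'
#' Note that when the mated females are full sisters of the selected males
#' this S overstates the effectively selected deviation (the sisters'
#' deviation is itself almost entirely genetic); see
#' [realized_h2()]'s `adjust` argument.
#'
#' @param pop Phenotypes of the whole phenotyped population.
#' @param selected_males Phenotypes of the selected males.
#' @param sibling_females Phenotypes of the mated (sister) females, or
#'   `NULL`.
#' @return The selection differential S (phenotype units).
#' @examples
#' selection_differential(pop = rep(0.8, 10),
#'                        selected_males = rep(1.4, 2),
#'                        sibling_females = rep(0.9, 2))  # 0.35
#' @export
selection_differential <- function(pop, selected_males, sibling_females = NULL) {
  if (length(selected_males) == 0) abort("empty selected set")
  if (length(pop) == 0) abort("empty population")
  pm <- mean(pop)
  s_m <- mean(selected_males) - pm
  s_f <- if (is.null(sibling_females)) 0 else mean(sibling_females) - pm
  s_m / 2 + s_f / 2
}

new_h2_est <- function(h2, se, method, slope = NA_real_, p.value = NA_real_,
                       drift_var = NA_real_, n = NA_integer_) {
  structure(
    list(h2 = h2, se = se, method = method, slope = slope,
         p.value = p.value, drift_var = drift_var, n = n),
    class = "h2_est"
  )
}

#' @export
print.h2_est <- function(x, ...) {
  cat(sprintf("<h2_est> h2 = %.3f (%.1f%%), se = %.3f, method = %s",
              x$h2, 100 * x$h2, x$se, x$method))
  if (is.finite(x$p.value)) cat(sprintf(", p = %.3g", x$p.value))
  if (is.finite(x$drift_var)) cat(sprintf(", drift var = %.4g", x$drift_var))
  cat("\n")
  invisible(x)
}

#' @export
tidy.h2_est <- function(x, ...) {
  tibble(term = "h2", estimate = x$h2, std.error = x$se,
         p.value = x$p.value, method = x$method)
}

#' @export
glance.h2_est <- function(x, ...) {
  tibble(h2 = x$h2, se = x$se, method = x$method,
         drift_var = x$drift_var, p.value = x$p.value, n = x$n)
}

# through-origin least squares of y on x, returning slope and its se
origin_slope <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) abort("no selection applied (all cumulative differentials zero)")
  b <- sum(x * y) / sxx
  res <- y - b * x
  k <- length(x)
  se <- if (k > 1) sqrt(sum(res^2) / (k - 1) / sxx) else 0
  list(slope = b, se = se)
}

#' Realized heritability from a multi-cycle selection experiment
#'
#' Realized h2 is the least-squares slope, through the origin, of the
#' cumulative response to selection on the cumulative selection
#' differential across cycles.
#'
#' `adjust` controls the bookkeeping for sib-mating designs in which
#' selected males are crossed to their own unselected sisters. The sisters
#' are then indirectly selected through the shared family effect and their
#' phenotypic deviation is, in expectation, entirely genetic; charging it
#' into the differential at face value makes the plain slope converge to
#' about `3 h2 / (2 + h2)` rather than `h2`. With `adjust = "sib_dams"` the
#' dam contribution is instead moved to the response side: the slope of
#' `cum(R - S_f / 2)` on `cum(S_m / 2)` (with `S_m`, `S_f` the per-sex mean
#' deviations) is a consistent estimator of h2 for this design. The default
#' `"auto"` applies the correction when the per-sex columns
#' (`pop_mean`, `selected_male_mean`, `sibling_female_mean`) are available
#' and falls back to the plain slope otherwise; `"none"` always uses the
#' plain slope of `cum_R` on `cum_S`.
#'
#' The optional drift variance is a parametric bootstrap: the same design
#' (population size, selected number, cycles) is re-simulated at the
#' estimated h2 and the variance of the re-estimated slope across
#' replicates is reported.
#'
#' @param cycles A tibble of per-cycle records with columns `S` and `R` (or
#'   `cum_S`/`cum_R`), plus `pop_mean`, `selected_male_mean`,
#'   `sibling_female_mean` for the sib-dam correction.
#' @param adjust `"auto"`, `"sib_dams"` or `"none"`.
#' @param drift_reps Bootstrap replicates for the drift variance (0 to skip).
#' @param config A [sim_config()] describing the design, required when
#'   `drift_reps > 0`; its `h2` is overridden by the estimate.
#' @param direction Selection direction used in the drift bootstrap.
#' @return An `h2_est` object (`method = "realized"`); see [tidy.h2_est()].
#' @export
realized_h2 <- function(cycles, adjust = c("auto", "sib_dams", "none"),
                        drift_reps = 0, config = NULL,
                        direction = "diurnal") {
  adjust <- match.arg(adjust)
  cycles <- as_tibble(cycles)
  if (nrow(cycles) < 2) abort("need at least 2 selection cycles")
  if (!all(c("S", "R") %in% names(cycles))) {
    if (all(c("cum_S", "cum_R") %in% names(cycles))) {
      cycles$S <- diff(c(0, cycles$cum_S))
      cycles$R <- diff(c(0, cycles$cum_R))
    } else {
      abort("cycles need columns S and R (or cum_S and cum_R)")
    }
  }
  sex_cols <- c("pop_mean", "selected_male_mean", "sibling_female_mean")
  have_sex <- all(sex_cols %in% names(cycles)) &&
    !anyNA(cycles[sex_cols])
  if (adjust == "sib_dams" && !have_sex) {
    abort("sib-dam adjustment needs pop_mean, selected_male_mean and sibling_female_mean")
  }
  use_adjust <- adjust == "sib_dams" || (adjust == "auto" && have_sex)
  if (use_adjust) {
    s_m <- cycles$selected_male_mean - cycles$pop_mean
    s_f <- cycles$sibling_female_mean - cycles$pop_mean
    fit <- origin_slope(cumsum(s_m / 2), cumsum(cycles$R - s_f / 2))
  } else {
    fit <- origin_slope(cumsum(cycles$S), cumsum(cycles$R))
  }
  drift_var <- NA_real_
  if (drift_reps > 0) {
    if (is.null(config)) abort("drift bootstrap needs a sim_config")
    cfg <- config
    cfg$h2 <- min(max(fit$slope, 0), 1)
    cfg$seed <- NULL
    boots <- purrr::map_dbl(seq_len(drift_reps), function(i) {
      ex <- run_selection_experiment(cfg, direction = direction,
                                     phenotype = "fast")
      realized_h2(ex$cycles, adjust = if (use_adjust) "sib_dams" else "none")$h2
    })
    drift_var <- var(boots)
  }
  new_h2_est(h2 = fit$slope, se = fit$se, method = "realized",
             slope = fit$slope, drift_var = drift_var,
             n = nrow(cycles))
}

#' Heritability from parent-offspring regression
#'
#' Ordinary least-squares regression of offspring on parent phenotype.
#' With `mode = "midparent"` the slope estimates h2 directly; with a
#' single-parent predictor (`"single_mother"`, `"single_father"`) the slope
#' estimates h2/2 and is doubled. The p-value is the two-sided test of zero
#' slope.
#'
#' @param pairs A tibble with numeric columns `parent` and `offspring`, one
#'   row per family/pair.
#' @param mode `"midparent"`, `"single_mother"` or `"single_father"`.
#' @return An `h2_est` object.
#' @export
parent_offspring_h2 <- function(pairs,
                                mode = c("midparent", "single_mother",
                                         "single_father")) {
  mode <- match.arg(mode)
  pairs <- as_tibble(pairs)
  if (!all(c("parent", "offspring") %in% names(pairs))) {
    abort("pairs needs columns parent and offspring")
  }
  pairs <- pairs %>% filter(is.finite(.data$parent), is.finite(.data$offspring))
  if (nrow(pairs) < 3) abort("need at least 3 finite parent-offspring pairs")
  if (var(pairs$parent) == 0) abort("zero variance in parent predictor")
  fit <- lm(offspring ~ parent, data = pairs)
  sm <- summary(fit)$coefficients
  b <- sm["parent", "Estimate"]
  se <- sm["parent", "Std. Error"]
  p <- sm["parent", "Pr(>|t|)"]
  mult <- if (mode == "midparent") 1 else 2
  new_h2_est(h2 = mult * b, se = mult * se, method = mode,
             slope = b, p.value = p, n = nrow(pairs))
}
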