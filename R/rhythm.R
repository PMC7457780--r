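# Per-fly circadian phenotyping: ND ratio, Fisher's exact g-test, chi-square
# and Lomb-Scargle periodograms, acrophase circular statistics, sleep scoring,
# masking contrasts and light-pulse phase shifts.

NIGHT_FLAGS <- c("D", "subjD")
DAY_FLAGS <- c("L", "subjL")

# minutes since the fly's first bin
minutes_since_start <- function(time) {
  as.numeric(difftime(time, time[1], units = "mins"))
}

#' Convert Zeitgeber time to a circular angle
#'
#' Maps hours on the 24-h day onto the circle at 15 degrees per hour, so
#' ZT0 is 0 degrees and ZT12 (lights-off in LD 12:12) is 180 degrees.
#'
#' @param zt_hours Numeric vector of ZT hours.
#' @return Angles in degrees, in `[0, 360)`.
#' @examples
#' zt_to_angle(c(1, 12, 24))
#' @export
zt_to_angle <- function(zt_hours) {
  (zt_hours * 15) %% 360
}

#' Night/day activity ratio per fly
#'
#' The ND ratio compares activity during the 12 h dark (or subjective dark)
#' period with activity during the 12 h light (or subjective light) period.
#' For each complete 24 h day the daily ratio is the sum of counts in
#' `D`/`subjD` bins divided by the sum in `L`/`subjL` bins; the fly's value
#' is the mean of its daily ratios (or the pooled-count ratio with
#' `pool_days = TRUE`). Values above 1 indicate nocturnal, below 1 diurnal
#' preference. Days with zero light-phase activity but non-zero dark-phase
#' activity have an infinite ratio; they are excluded from the mean with a
#' warning and counted in `n_days_inf`.
#'
#' @param data Light-annotated activity tibble (see [annotate_light()]).
#' @param pool_days Pool counts across days instead of averaging daily
#'   ratios.
#' @return A tibble with one row per fly: `fly_id`, `nd_ratio`, `n_days`
#'   (complete days), `n_days_used`, `n_days_inf`.
#' @export
nd_ratio <- function(data, pool_days = FALSE) {
  check_activity(data, require_light = TRUE)
  daily <- nd_ratio_daily(data)
  n_inf_total <- sum(is.infinite(daily$nd_day))
  if (n_inf_total > 0) {
    warn(sprintf("%d day(s) with zero light-phase activity excluded (infinite ratio)",
                 n_inf_total))
  }
  daily %>%
    group_by(.data$fly_id) %>%
    summarise(
      nd_ratio = if (pool_days) {
        sum(.data$night_activity[is.finite(.data$nd_day)]) /
          sum(.data$day_activity[is.finite(.data$nd_day)])
      } else {
        mean(.data$nd_day[is.finite(.data$nd_day)])
      },
      n_days = dplyr::n(),
      n_days_used = sum(is.finite(.data$nd_day)),
      n_days_inf = sum(is.infinite(.data$nd_day)),
      .groups = "drop"
    )
}

#' Daily night/day ratios per fly
#'
#' @inheritParams nd_ratio
#' @return A tibble with one row per fly and complete 24 h day: `fly_id`,
#'   `day` (0-based), `night_activity`, `day_activity`, `nd_day`.
#' @export
nd_ratio_daily <- function(data) {
  check_activity(data, require_light = TRUE)
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      if (all(d$count == 0)) {
        abort(paste0("fly ", d$fly_id[1], ": no activity"))
      }
      day <- (seq_len(nrow(d)) - 1) %/% (1440 / b)
      complete <- names(which(table(day) == 1440 / b))
      d <- d[day %in% as.integer(complete), ]
      day <- day[day %in% as.integer(complete)]
      if (nrow(d) == 0) {
        abort(paste0("fly ", d$fly_id[1] %||% "?", ": no complete 24 h day"))
      }
      tibble(fly_id = d$fly_id[1], day = day, count = d$count,
             is_night = d$light %in% NIGHT_FLAGS)
    }) %>%
    bind_rows() %>%
    group_by(.data$fly_id, .data$day) %>%
    summarise(
      night_activity = sum(.data$count[.data$is_night]),
      day_activity = sum(.data$count[!.data$is_night]),
      .groups = "drop"
    ) %>%
    mutate(nd_day = .data$night_activity / .data$day_activity)
}

# Exact null distribution of Fisher's g (max periodogram ordinate over the
# sum of m ordinates): P(g > x) = sum_{j=1}^{floor(1/x)} (-1)^(j-1) C(m,j)
# (1 - j x)^(m-1), computed in log space and clamped to [0, 1].
fisher_g_pvalue <- function(g, m) {
  jmax <- floor(1 / g)
  j <- seq_len(min(jmax, m))
  terms <- exp(lchoose(m, j) + (m - 1) * log1p(-j * g))
  p <- sum(terms * rep_len(c(1, -1), length(j)))
  min(max(p, 0), 1)
}

#' Fisher's exact g-test for rhythmicity
#'
#' Screens each fly's activity series for a periodic component. The
#' periodogram is evaluated at the Fourier frequencies; the g statistic is
#' the largest ordinate divided by the sum of all `m` ordinates, and the
#' p-value is Fisher's exact null tail probability for g. The period at the
#' maximal ordinate is reported as `peak_period_hours`.
#'
#' @param data Activity tibble (light annotation not required).
#' @return A tibble with one row per fly: `fly_id`, `g_stat`, `g_pvalue`,
#'   `peak_period_hours`, `n_bins`.
#' @export
fisher_g_test <- function(data) {
  check_activity(data)
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      x <- as.numeric(d$count)
      n <- length(x)
      if (n < 16) abort(paste0("fly ", d$fly_id[1], ": need >= 16 bins"))
      if (var(x) == 0) abort(paste0("fly ", d$fly_id[1], ": zero variance"))
      m <- floor((n - 1) / 2)
      ords <- (Mod(fft(x - mean(x)))^2 / n)[2:(m + 1)]
      g <- max(ords) / sum(ords)
      jstar <- which.max(ords)
      tibble(fly_id = d$fly_id[1],
             g_stat = g,
             g_pvalue = fisher_g_pvalue(g, m),
             peak_period_hours = (n * b / 60) / jstar,
             n_bins = n)
    }) %>%
    bind_rows()
}

#' Chi-square (Sokolove-Bushell) periodogram period estimation
#'
#' For each candidate period the series is folded into phase classes and the
#' between-class concentration statistic
#' \deqn{Q_P = \sum_h n_h (\bar M_h - \bar x)^2 / (\sum_i (x_i - \bar x)^2 / N)}
#' is compared with its chi-square threshold (`K - 1` degrees of freedom).
#' Because the scan tries the whole period grid, the per-candidate threshold
#' is Bonferroni-adjusted (`alpha` divided by the grid size) so that the
#' scan-wise false-positive rate on arrhythmic data stays near `alpha`. The
#' reported period maximises the excess of the statistic over its threshold;
#' `significant` is `FALSE` when no candidate exceeds it.
#'
#' @param data Activity tibble; typically the constant-darkness portion of a
#'   recording, at least two times `p_max` long.
#' @param period_range Search range in hours, default 18-30 h.
#' @param step Search grid step in hours.
#' @param alpha Significance level for the threshold.
#' @param full Return the whole periodogram instead of the best candidate.
#' @return One row per fly (`fly_id`, `period_hours`, `statistic`,
#'   `threshold`, `significant`, `method`), or the full per-candidate scan
#'   when `full = TRUE`.
#' @export
chi2_periodogram <- function(data, period_range = c(18, 30), step = 0.1,
                             alpha = 0.05, full = FALSE) {
  check_activity(data)
  if (period_range[1] >= period_range[2]) abort("need p_min < p_max")
  periods <- seq(period_range[1], period_range[2], by = step)
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      x <- as.numeric(d$count)
      n <- length(x)
      if (n * b / 60 < 2 * period_range[2]) {
        abort(sprintf("fly %s: series (%.1f h) shorter than 2 x p_max (%.1f h)",
                      d$fly_id[1], n * b / 60, 2 * period_range[2]))
      }
      t_mid <- (seq_len(n) - 0.5) * b
      xbar <- mean(x)
      denom <- sum((x - xbar)^2) / n
      scan <- purrr::map(periods, function(P) {
        pm <- P * 60
        K <- floor(pm / b)
        cls <- pmin(floor(((t_mid %% pm) / pm) * K) + 1, K)
        nh <- tabulate(cls, K)
        Mh <- rowsum(x, cls)[, 1] / nh[nh > 0]
        Q <- sum(nh[nh > 0] * (Mh - xbar)^2) / denom
        tibble(period_hours = P, statistic = Q,
               threshold = qchisq(1 - alpha / length(periods),
                                  df = sum(nh > 0) - 1))
      }) %>% bind_rows() %>%
        mutate(fly_id = d$fly_id[1], significant = .data$statistic > .data$threshold,
               method = "chi2") %>%
        select("fly_id", "period_hours", "statistic", "threshold",
               "significant", "method")
      if (full) return(scan)
      scan[which.max(scan$statistic - scan$threshold), ]
    }) %>%
    bind_rows()
}

#' Lomb-Scargle periodogram (cross-check period estimator)
#'
#' Standard normalised Lomb-Scargle power evaluated on the same period grid
#' as [chi2_periodogram()]. The significance threshold uses the classical
#' `M`-independent-frequencies bound with `M` equal to the number of
#' candidates. Intended as an independent cross-check of the chi-square
#' estimator, not as the primary method.
#'
#' @inheritParams chi2_periodogram
#' @return Same shape as [chi2_periodogram()], `method = "lombscargle"`.
#' @export
lomb_scargle_periodogram <- function(data, period_range = c(18, 30), step = 0.1,
                                     alpha = 0.05, full = FALSE) {
  check_activity(data)
  periods <- seq(period_range[1], period_range[2], by = step)
  M <- length(periods)
  z_thr <- -log(1 - (1 - alpha)^(1 / M))
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      x <- as.numeric(d$count)
      x <- x - mean(x)
      s2 <- var(x)
      if (s2 == 0) abort(paste0("fly ", d$fly_id[1], ": zero variance"))
      t <- (seq_along(x) - 0.5) * b / 60   # hours
      scan <- purrr::map(periods, function(P) {
        w <- 2 * pi / P
        tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
        ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
        z <- 0.5 * ((sum(x * ct)^2 / sum(ct^2)) +
                      (sum(x * st)^2 / sum(st^2))) / s2
        tibble(period_hours = P, statistic = z, threshold = z_thr)
      }) %>% bind_rows() %>%
        mutate(fly_id = d$fly_id[1],
               significant = .data$statistic > .data$threshold,
               method = "lombscargle") %>%
        select("fly_id", "period_hours", "statistic", "threshold",
               "significant", "method")
      if (full) return(scan)
      scan[which.max(scan$statistic - scan$threshold), ]
    }) %>%
    bind_rows()
}

# Circular 95% CI half-width (degrees) for a mean direction from n angles
# with mean resultant length r (Zar's two-branch formula). NA when r is
# below the validity bound sqrt(chi2 / (2 n)).
circ_ci95_deg <- function(n, r) {
  if (n < 2 || !is.finite(r)) return(NA_real_)
  chi <- qchisq(0.95, df = 1)
  if (r <= sqrt(chi / (2 * n))) return(NA_real_)
  Rn <- n * r
  if (r <= 0.9) {
    arg <- sqrt((2 * n * (2 * Rn^2 - n * chi)) / (4 * n - chi)) / Rn
  } else {
    arg <- sqrt(n^2 - (n^2 - Rn^2) * exp(chi / n)) / Rn
  }
  if (!is.finite(arg) || arg > 1) return(NA_real_)
  acos(arg) * 180 / pi
}

circ_mean_deg <- function(theta_deg, w = NULL) {
  th <- theta_deg * pi / 180
  w <- w %||% rep(1, length(th))
  C <- sum(w * cos(th)) / sum(w)
  S <- sum(w * sin(th)) / sum(w)
  list(mean_deg = (atan2(S, C) * 180 / pi) %% 360, R = sqrt(C^2 + S^2))
}

#' Acrophase: circular phase of peak activity
#'
#' For each cycle of length `period_hours` the phase angle is the circular
#' mean of bin-midpoint angles weighted by counts (one hour = 15 degrees at
#' a 24 h period). Across cycles the per-cycle phases are summarised by
#' their circular mean, the mean resultant length `R`, and the 95% CI of the
#' mean direction (`NA` when `R` is below the CI validity bound). Cycles
#' with no activity are skipped with a warning. The series is assumed to
#' start at phase reference zero (ZT0 for entrained data).
#'
#' @param data Activity tibble.
#' @param period_hours Cycle length used to fold the data (e.g. 24 in LD,
#'   the free-running period in DD).
#' @return A tibble with one row per fly: `fly_id`, `mean_deg`, `R`,
#'   `ci95_deg`, `n_cycles`.
#' @export
acrophase <- function(data, period_hours = 24) {
  check_activity(data)
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      pm <- period_hours * 60
      t_mid <- minutes_since_start(d$time) + b / 2
      cyc <- floor(t_mid / pm)
      bins_per_cycle <- floor(pm / b)
      keep <- cyc %in% as.integer(names(which(table(cyc) >= bins_per_cycle)))
      d <- d[keep, ]; t_mid <- t_mid[keep]; cyc <- cyc[keep]
      if (nrow(d) == 0) abort(paste0("fly ", d$fly_id[1], ": no complete cycle"))
      per_cycle <- purrr::map(split(seq_len(nrow(d)), cyc), function(i) {
        if (sum(d$count[i]) == 0) return(NULL)   # all-zero cycle
        circ_mean_deg(((t_mid[i] %% pm) / pm) * 360, d$count[i])
      })
      n_zero <- sum(vapply(per_cycle, is.null, logical(1)))
      if (n_zero > 0) {
        warn(sprintf("fly %s: skipped %d all-zero cycle(s)", d$fly_id[1], n_zero))
      }
      per_cycle <- purrr::compact(per_cycle)
      if (length(per_cycle) == 0) {
        abort(paste0("fly ", d$fly_id[1], ": no usable cycle"))
      }
      # phaseless cycles (activity spread uniformly, within-cycle resultant
      # numerically zero) contribute a null vector rather than a spurious
      # direction
      angles <- vapply(per_cycle, `[[`, numeric(1), "mean_deg")
      ok <- vapply(per_cycle, `[[`, numeric(1), "R") > 1e-9
      if (any(!ok)) {
        warn(sprintf("fly %s: %d phaseless (uniform-activity) cycle(s)",
                     d$fly_id[1], sum(!ok)))
      }
      th <- angles[ok] * pi / 180
      n_cyc <- length(per_cycle)
      C <- sum(cos(th)) / n_cyc; S <- sum(sin(th)) / n_cyc
      R <- sqrt(C^2 + S^2)
      tibble(fly_id = d$fly_id[1],
             mean_deg = if (R > 0) (atan2(S, C) * 180 / pi) %% 360 else NA_real_,
             R = R,
             ci95_deg = circ_ci95_deg(n_cyc, R),
             n_cycles = n_cyc)
    }) %>%
    bind_rows()
}

# ZT hours for each bin: hours since series start modulo 24, assuming the
# series starts at lights-on. If light flags contradict that (first bin
# dark), the offset is inferred from the first D->L transition.
zt_hours_of <- function(d, b) {
  zt <- ((minutes_since_start(d$time) + b / 2) / 60) %% 24
  if ("light" %in% names(d) && nrow(d) > 1) {
    is_l <- d$light %in% DAY_FLAGS
    if (!is_l[1]) {
      trans <- which(!is_l[-nrow(d)] & is_l[-1])
      if (length(trans) == 0) {
        abort(paste0("fly ", d$fly_id[1],
                     ": cannot locate lights-on (no D->L transition)"))
      }
      zt <- zt - (minutes_since_start(d$time)[trans[1] + 1]) / 60
    }
  }
  zt %% 24
}

#' Morning and evening activity peak phases
#'
#' The morning peak (MP) is the count-weighted circular mean angle of bins
#' falling in the window ZT21-ZT3 (flanking lights-on); the evening peak
#' (EP) uses ZT9-ZT15 (flanking lights-off). Angles use 15 degrees per hour.
#' An empty window yields `NA` with a warning.
#'
#' @param data LD light-annotated activity tibble assumed to start at
#'   lights-on (otherwise lights-on is inferred from the first dark-to-light
#'   transition).
#' @return A tibble per fly: `fly_id`, `mp_deg`, `ep_deg`.
#' @export
morning_evening_peaks <- function(data) {
  check_activity(data, require_light = TRUE)
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      zt <- zt_hours_of(d, b)
      window_phase <- function(lo, hi) {
        inwin <- if (lo > hi) zt >= lo | zt < hi else zt >= lo & zt < hi
        if (!any(inwin) || sum(d$count[inwin]) == 0) {
          warn(sprintf("fly %s: no activity in ZT%g-ZT%g window",
                       d$fly_id[1], lo, hi))
          return(NA_real_)
        }
        circ_mean_deg(zt_to_angle(zt[inwin]), d$count[inwin])$mean_deg
      }
      tibble(fly_id = d$fly_id[1],
             mp_deg = window_phase(21, 3),
             ep_deg = window_phase(9, 15))
    }) %>%
    bind_rows()
}

#' Sleep profile from one-minute activity bins
#'
#' Scores sleep with the standard Drosophila convention: any run of five or
#' more consecutive zero-count minutes is sleep, and every minute inside
#' such a run counts as one sleep-minute. Output is minutes asleep per clock
#' hour (0-23, hours since the start of the series, which is assumed to be
#' lights-on), averaged across days.
#'
#' @param data Activity tibble with 1-minute bins.
#' @param min_run Minimum immobile run length in minutes (default 5).
#' @return A tibble per fly and hour: `fly_id`, `hour`, `sleep_min`.
#' @export
sleep_profile <- function(data, min_run = 5) {
  check_activity(data)
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      if (b != 1) {
        abort(paste0("fly ", d$fly_id[1], ": sleep scoring needs 1-minute bins; ",
                     "do not re-bin before sleep analysis"))
      }
      r <- rle(d$count == 0)
      asleep <- rep(r$values & r$lengths >= min_run, r$lengths)
      t0 <- minutes_since_start(d$time)
      hour <- (t0 %/% 60) %% 24
      day <- t0 %/% 1440
      cell <- tibble(hour = hour, day = day, asleep = asleep) %>%
        group_by(.data$hour, .data$day) %>%
        summarise(mins = sum(.data$asleep), n = dplyr::n(), .groups = "drop") %>%
        filter(.data$n == 60)   # only fully observed hour cells
      cell %>%
        group_by(.data$hour) %>%
        summarise(sleep_min = mean(.data$mins), .groups = "drop") %>%
        mutate(fly_id = d$fly_id[1]) %>%
        select("fly_id", "hour", "sleep_min")
    }) %>%
    bind_rows()
}

#' Per-fly ND ratios under LD and under constant darkness
#'
#' Splits a light-annotated recording that runs from an LD entrainment block
#' into constant darkness (flags `subjL`/`subjD`) and computes the ND ratio
#' in each regime. The first DD day is a transient and is excluded, so the
#' DD value uses days two onward.
#'
#' @param data Light-annotated activity tibble covering both LD and DD.
#' @return A tibble per fly: `fly_id`, `nd_ld`, `nd_dd`, `delta`
#'   (`nd_dd - nd_ld`).
#' @export
masking_nd <- function(data) {
  check_activity(data, require_light = TRUE)
  if (!any(data$light %in% c("subjL", "subjD"))) {
    abort("no subjective-darkness annotation (subjL/subjD); ",
          "annotate with a regime that sets dd_start")
  }
  data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      subj <- d$light %in% c("subjL", "subjD")
      ld <- d[!subj, ]
      dd <- d[subj, ]
      skip <- min(nrow(dd), 1440 / b)  # first DD day is a transient
      dd <- dd[-seq_len(skip), ]
      nd_of <- function(x) {
        if (nrow(x) < 1440 / b) return(NA_real_)
        suppressWarnings(nd_ratio(x)$nd_ratio)
      }
      tibble(fly_id = d$fly_id[1], nd_ld = nd_of(ld), nd_dd = nd_of(dd)) %>%
        mutate(delta = .data$nd_dd - .data$nd_ld)
    }) %>%
    bind_rows()
}

#' Light-masking contrast: genotype x light-regime analysis of ND ratios
#'
#' Tests whether diurnal preference differs between light regimes (LD vs
#' DD), between genotypes, and whether the regime effect depends on genotype
#' (the masking signature), using a two-way ANOVA on per-fly ND values with
#' Tukey-adjusted post-hoc comparisons.
#'
#' @param data A tibble with one row per fly carrying `fly_id`, `genotype`
#'   and either wide columns `nd_ld`/`nd_dd` (as from [masking_nd()] joined
#'   to genotype labels) or long columns `regime` (`"LD"`/`"DD"`) and `nd`.
#' @param alpha Significance level used in the printed summary.
#' @return A `masking_result` object: per-genotype means and deltas, the
#'   ANOVA table, and Tukey post-hoc contrasts. `tidy()` returns the ANOVA
#'   table, `glance()` a one-row summary.
#' @export
masking_contrast <- function(data, alpha = 0.05) {
  if (all(c("nd_ld", "nd_dd") %in% names(data))) {
    long <- data %>%
      tidyr::pivot_longer(c("nd_ld", "nd_dd"), names_to = "regime",
                          values_to = "nd") %>%
      mutate(regime = ifelse(.data$regime == "nd_ld", "LD", "DD"))
  } else if (all(c("regime", "nd") %in% names(data))) {
    long <- data
  } else {
    abort("need columns nd_ld/nd_dd or regime/nd, plus genotype")
  }
  if (!"genotype" %in% names(long)) abort("need a genotype column")
  long <- long %>%
    filter(is.finite(.data$nd)) %>%
    mutate(genotype = factor(.data$genotype),
           regime = factor(.data$regime, levels = c("LD", "DD")))
  fit <- aov(nd ~ genotype * regime, data = long)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble(
    term = trimws(rownames(an)),
    df = an$Df,
    statistic = an$`F value`,
    p.value = an$`Pr(>F)`
  ) %>% filter(.data$term != "Residuals")
  groups <- long %>%
    group_by(.data$genotype, .data$regime) %>%
    summarise(nd = mean(.data$nd), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "regime", values_from = "nd") %>%
    rename(nd_ld = "LD", nd_dd = "DD") %>%
    mutate(delta = .data$nd_dd - .data$nd_ld)
  tk <- TukeyHSD(fit, "genotype:regime")[[1]]
  tukey_tbl <- tibble(contrast = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"])
  structure(
    list(groups = groups, anova = anova_tbl, tukey = tukey_tbl,
         df_resid = an$Df[length(an$Df)], n = nrow(long), alpha = alpha),
    class = "masking_result"
  )
}

#' @export
print.masking_result <- function(x, ...) {
  cat("<masking_result> genotype x light-regime ANOVA on ND ratios\n")
  for (i in seq_len(nrow(x$anova))) {
    cat(sprintf("  %-16s F(%d,%d) = %.2f, p = %.3g\n",
                x$anova$term[i], x$anova$df[i], x$df_resid,
                x$anova$statistic[i], x$anova$p.value[i]))
  }
  print(x$groups)
  invisible(x)
}

#' @export
tidy.masking_result <- function(x, ...) x$anova

#' @export
glance.masking_result <- function(x, ...) {
  g <- function(term, col) x$anova[[col]][x$anova$term == term]
  tibble(F_regime = g("regime", "statistic"),
         p_regime = g("regime", "p.value"),
         F_genotype = g("genotype", "statistic"),
         p_genotype = g("genotype", "p.value"),
         F_interaction = g("genotype:regime", "statistic"),
         p_interaction = g("genotype:regime", "p.value"),
         df_resid = x$df_resid, n = x$n)
}

#' Phase shift between an unpulsed and a light-pulsed fly
#'
#' Compares post-pulse free-running acrophases of two single-fly DD series
#' (each spanning at least three cycles after the pulse). Both series are
#' first screened for rhythmicity with the chi-square periodogram; if either
#' is arrhythmic the shift is `NA`. The circular acrophase difference is
#' converted to hours at 15 degrees per hour; phase delays are negative,
#' advances positive.
#'
#' @param unpulsed,pulsed Single-fly activity tibbles (post-pulse portions).
#' @param period_range,step,alpha Passed to [chi2_periodogram()].
#' @return A one-row tibble: `shift_hours`, both acrophases (degrees), both
#'   period estimates and their significance.
#' @export
phase_shift <- function(unpulsed, pulsed, period_range = c(18, 30),
                        step = 0.1, alpha = 0.05) {
  for (d in list(unpulsed, pulsed)) {
    check_activity(d)
    if (length(unique(d$fly_id)) != 1) {
      abort("phase_shift() compares two single-fly series")
    }
  }
  pu <- chi2_periodogram(unpulsed, period_range, step, alpha)
  pp <- chi2_periodogram(pulsed, period_range, step, alpha)
  if (!pu$significant || !pp$significant) {
    warn("arrhythmic post-pulse series; phase shift undefined")
    shift <- NA_real_; au <- NA_real_; ap <- NA_real_
  } else {
    au <- acrophase(unpulsed, period_hours = pu$period_hours)$mean_deg
    ap <- acrophase(pulsed, period_hours = pu$period_hours)$mean_deg
    delta <- ((ap - au + 180) %% 360) - 180   # (-180, 180]
    shift <- -delta / 15                      # delay (later phase) -> negative
  }
  tibble(shift_hours = shift,
         acro_unpulsed_deg = au, acro_pulsed_deg = ap,
         period_unpulsed = pu$period_hours, period_pulsed = pp$period_hours,
         rhythmic = pu$significant && pp$significant)
}

#' One-stop per-fly rhythm phenotyping
#'
#' Combines the ND ratio, Fisher's exact g-test (with the rhythmicity call
#' at level `alpha`) and the entrained acrophase into one row per fly.
#'
#' @param data Light-annotated activity tibble.
#' @param alpha Rhythmicity threshold on the Fisher g p-value.
#' @param pool_days Passed to [nd_ratio()].
#' @return A tibble per fly: ND ratio, g statistics, `rhythmic`, acrophase.
#' @export
phenotype_flies <- function(data, alpha = 0.05, pool_days = FALSE) {
  nd <- nd_ratio(data, pool_days = pool_days)
  g <- fisher_g_test(data) %>%
    mutate(rhythmic = .data$g_pvalue < alpha)
  ac <- acrophase(data, period_hours = 24) %>%
    select("fly_id", acrophase_deg = "mean_deg", acrophase_R = "R")
  nd %>% left_join(g, by = "fly_id") %>% left_join(ac, by = "fly_id")
}
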