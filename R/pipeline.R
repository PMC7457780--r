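# Orchestration: configuration, the end-to-end desk-scale replay of the
# study design, and report writers.

#' Default end-to-end run configuration
#'
#' Returns the full configuration used by [run_end_to_end()], mirroring the
#' defaults of the analysis modules: rhythmicity and significance levels of
#' 0.05, an 18-30 h period search grid in 0.1 h steps, the selection design
#' of [sim_config()], heritabilities of 0.371 (diurnal direction), 0.084
#' (nocturnal) and 0.14 (parent-offspring), 105 families, and masking
#' genotype means of 1.2 (N), 0.75 (C) and 0.4 (D).
#'
#' @return A nested list; see `inst/extdata/default-config.yaml` for the
#'   same structure on disk.
#' @export
default_run_config <- function() {
  list(
    thresholds = list(alpha_rhythm = 0.05, alpha = 0.05,
                      period_min = 18, period_max = 30, period_step = 0.1),
    sim = list(n_pop = 300, n_selected = 25, n_cycles = 10,
               nd_mean = 0.75, Vp = 0.02, total_activity_per_day = 1200,
               masking_m = 0.6, tau_mean = 24.2, tau_sd = 0.2),
    selection = list(h2_diurnal = 0.371, h2_nocturnal = 0.084,
                     drift_reps = 100),
    parent_offspring = list(h2 = 0.14, n_families = 105, n_progeny = 4),
    masking = list(genotype_nd = list(N = 1.2, C = 0.75, D = 0.4),
                   n_per_genotype = 8, ld_days = 3, dd_days = 4,
                   bin_minutes = 30),
    qct = list(n_per_cell = 20, sd = 0.15,
               complemented_means = list(D = 0.4, C = 0.7, N = 1.1),
               null_mean = 0.75)
  )
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file with any subset of the fields of
#' [default_run_config()]; missing fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user)
}

sim_config_from_run <- function(config, h2) {
  do.call(sim_config, c(config$sim, list(h2 = h2)))
}

#' Replay the study design end to end at desk scale
#'
#' Runs the whole pipeline on simulated data: (1) a small cohort of flies
#' per genotype is given Poisson actograms over an LD block followed by
#' constant darkness and pushed through ND-ratio scoring and the masking
#' contrast; (2) full selection experiments are simulated in both
#' directions and realized heritability re-estimated (with a bootstrap
#' drift variance); (3) parent-offspring families are simulated and the
#' mid-parent and mother-daughter regressions re-estimated; (4) two
#' complementation scenarios (graded background effect, null) are tested.
#' The report carries every estimate next to its generating truth.
#'
#' @param config A configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param seed Integer seed controlling all randomness in the run.
#' @return A `noctura_report` object (a list of result tibbles plus the
#'   seed and a configuration hash).
#' @export
run_end_to_end <- function(config = default_run_config(), seed = 1) {
  withr::with_seed(seed, {
    alpha <- config$thresholds$alpha

    # 1. actogram cohort and masking contrast
    mk <- config$masking
    geno <- names(mk$genotype_nd)
    cohort <- purrr::map(geno, function(gn) {
      cfg_g <- sim_config_from_run(config, h2 = 0)
      tibble(
        id = sprintf("%s%02d", gn, seq_len(mk$n_per_genotype)),
        genotype = gn,
        true_nd = pmax(rnorm(mk$n_per_genotype, mk$genotype_nd[[gn]],
                             sqrt(cfg_g$Vp)), cfg_g$nd_floor),
        tau = rnorm(mk$n_per_genotype, cfg_g$tau_mean, cfg_g$tau_sd)
      )
    }) %>% bind_rows()
    cfg0 <- sim_config_from_run(config, h2 = 0)
    acts <- cohort %>%
      dplyr::rowwise() %>% dplyr::group_split() %>%
      purrr::map(function(ind) {
        simulate_activity(ind, cfg0, ld_days = mk$ld_days,
                          dd_days = mk$dd_days, bin_minutes = mk$bin_minutes)
      }) %>% bind_rows()
    pheno <- suppressWarnings(phenotype_flies(acts, alpha = config$thresholds$alpha_rhythm))
    mask <- suppressWarnings(masking_nd(acts)) %>%
      left_join(select(cohort, fly_id = "id", "genotype"), by = "fly_id")
    masking <- masking_contrast(mask, alpha = alpha)

    # 2. selection experiments, both directions
    sel <- purrr::map(c(diurnal = "diurnal", nocturnal = "nocturnal"),
                      function(dir) {
      h2 <- if (dir == "diurnal") config$selection$h2_diurnal
            else config$selection$h2_nocturnal
      cfg <- sim_config_from_run(config, h2 = h2)
      ex <- run_selection_experiment(cfg, direction = dir, phenotype = "fast")
      est <- realized_h2(ex$cycles, drift_reps = config$selection$drift_reps,
                         config = cfg, direction = dir)
      list(experiment = ex, estimate = est)
    })
    sel_tbl <- purrr::imap(sel, function(s, dir) {
      tibble(direction = dir, h2_true = s$experiment$truth$h2,
             h2_realized = s$estimate$h2, se = s$estimate$se,
             drift_var = s$estimate$drift_var,
             cum_S = last(s$experiment$cycles$cum_S),
             cum_R = last(s$experiment$cycles$cum_R))
    }) %>% bind_rows()

    # 3. parent-offspring regressions
    po_cfg <- sim_config_from_run(config, h2 = config$parent_offspring$h2)
    fams <- simulate_parent_offspring(po_cfg,
                                      n_families = config$parent_offspring$n_families,
                                      n_progeny = config$parent_offspring$n_progeny)
    po_tbl <- bind_rows(
      glance(parent_offspring_h2(fams$midparent, "midparent")),
      glance(parent_offspring_h2(fams$mother_daughter, "single_mother")),
      glance(parent_offspring_h2(fams$father_son, "single_father"))
    ) %>% mutate(h2_true = config$parent_offspring$h2)

    # 4. complementation scenarios
    qc <- config$qct
    qct_pos <- qct_test(simulate_qct(unlist(qc$complemented_means),
                                     sd = qc$sd, n_per_cell = qc$n_per_cell),
                        alpha = alpha)
    qct_null <- qct_test(simulate_qct(setNames(rep(qc$null_mean, 3),
                                               c("N", "C", "D")),
                                      sd = qc$sd, n_per_cell = qc$n_per_cell),
                         alpha = alpha)
    qct_tbl <- bind_rows(
      mutate(glance(qct_pos), scenario = "graded_background", .before = 1),
      mutate(glance(qct_null), scenario = "null", .before = 1)
    )

    structure(
      list(seed = seed, config_hash = rlang::hash(config), config = config,
           phenotypes = pheno, masking = masking, masking_nd = mask,
           selection = sel_tbl,
           selection_cycles = purrr::imap(sel, function(s, dir) {
             mutate(s$experiment$cycles, direction = dir, .before = 1)
           }) %>% bind_rows(),
           parent_offspring = po_tbl, qct = qct_tbl),
      class = "noctura_report"
    )
  })
}

#' @export
print.noctura_report <- function(x, ...) {
  cat(sprintf("<noctura_report> seed %d, config %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  cat("realized heritability:\n"); print(x$selection)
  cat("parent-offspring heritability:\n")
  print(select(x$parent_offspring, "method", "h2", "se", "p.value", "h2_true"))
  cat("complementation verdicts:\n")
  print(select(x$qct, "scenario", "kw_p", "verdict"))
  g <- glance(x$masking)
  cat(sprintf("masking: regime F = %.1f (p = %.2g), interaction F = %.1f (p = %.2g)\n",
              g$F_regime, g$p_regime, g$F_interaction, g$p_interaction))
  invisible(x)
}

#' Write an end-to-end report to disk
#'
#' Writes the report either as one JSON file (`report.json`) or as a set of
#' CSV tables, each stamped with the seed and configuration hash.
#'
#' @param report A `noctura_report` from [run_end_to_end()].
#' @param dir Output directory (created if needed).
#' @param format `"json"` or `"csv"`.
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, dir, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "noctura_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "json") {
    payload <- list(
      seed = report$seed, config_hash = report$config_hash,
      selection = report$selection,
      selection_cycles = report$selection_cycles,
      parent_offspring = report$parent_offspring,
      qct = report$qct,
      masking = glance(report$masking),
      phenotypes = report$phenotypes
    )
    jsonlite::write_json(payload, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stamp <- function(d) {
      mutate(d, seed = report$seed, config_hash = report$config_hash)
    }
    readr::write_csv(stamp(report$selection), file.path(dir, "selection.csv"))
    readr::write_csv(stamp(report$selection_cycles),
                     file.path(dir, "selection_cycles.csv"))
    readr::write_csv(stamp(report$parent_offspring),
                     file.path(dir, "parent_offspring.csv"))
    readr::write_csv(stamp(report$qct), file.path(dir, "qct.csv"))
    readr::write_csv(stamp(glance(report$masking)), file.path(dir, "masking.csv"))
    readr::write_csv(stamp(report$phenotypes), file.path(dir, "phenotypes.csv"))
  }
  invisible(dir)
}
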