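# Fixtures are built in code: small activity tables, DAM-dialect files and
# signal generators shared across the test files.

T0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")  # lights-on

# one fly's activity table from a count vector
make_activity <- function(counts, bin_minutes = 60, fly_id = "f1",
                          light = NULL, t0 = T0) {
  out <- tibble::tibble(
    fly_id = fly_id,
    time = t0 + (seq_along(counts) - 1) * bin_minutes * 60,
    count = as.integer(counts)
  )
  if (!is.null(light)) out$light <- light
  out
}

# LD 12:12 light labels for a series starting at lights-on
ld_flags <- function(n_bins, bin_minutes = 60, subjective = FALSE) {
  m <- (seq_len(n_bins) - 1) * bin_minutes %% 1440
  is_l <- (m %% 1440) < 720
  if (subjective) ifelse(is_l, "subjL", "subjD") else ifelse(is_l, "L", "D")
}

# sinusoidal counts (period in hours) with optional Poisson sampling
sine_counts <- function(days, bin_minutes, period_hours, mesor = 20,
                        amplitude = 15, poisson = FALSE) {
  n <- days * 1440 / bin_minutes
  t_h <- ((seq_len(n) - 0.5) * bin_minutes) / 60
  lam <- pmax(mesor + amplitude * cos(2 * pi * t_h / period_hours), 0)
  if (poisson) stats::rpois(n, lam) else as.integer(round(lam))
}

# write a DAM42 monitor file; `channels` is a matrix (rows = records,
# 32 columns), `status` a vector per record
write_dam_fixture <- function(path, channels, status = NULL,
                              t0 = T0, bin_minutes = 1) {
  n <- nrow(channels)
  status <- status %||% rep(1L, n)
  times <- t0 + (seq_len(n) - 1) * bin_minutes * 60
  lines <- vapply(seq_len(n), function(i) {
    paste(c(i, format(times[i], "%d %b %y"), format(times[i], "%H:%M:%S"),
            status[i], rep(0, 6), channels[i, ]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
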