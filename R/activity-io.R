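# Activity tables
#
# All locomotor data in noctura live in one tidy shape: a tibble with one row
# per fly per time bin and columns
#   fly_id : character
#   time   : POSIXct (UTC), start of the bin
#   count  : non-negative integer beam crossings in the bin
#   light  : optional, one of "L", "D", "subjL", "subjD"
# Bin width is inferred from consecutive timestamps and must be constant
# within a fly and divide 1440 minutes.

DAM_FIELDS <- 42L
DAM_CHANNELS <- 32L

check_activity <- function(data, require_light = FALSE, call = rlang::caller_env()) {
  need <- c("fly_id", "time", "count")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("activity data must have columns fly_id, time, count; missing: ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (require_light && !"light" %in% names(data)) {
    abort("activity data must be light-annotated (see annotate_light())", call = call)
  }
  if (any(data$count < 0) || any(data$count != round(data$count))) {
    abort("counts must be non-negative integers", call = call)
  }
  invisible(data)
}

# Inferred bin width in minutes for one fly's rows (assumed sorted).
# Errors on non-monotone or irregular spacing.
infer_bin_minutes <- function(time, fly_id = "?", call = rlang::caller_env()) {
  if (length(time) < 2) {
    abort(paste0("fly ", fly_id, ": need at least 2 bins to infer bin width"),
          call = call)
  }
  d <- as.numeric(diff(time), units = "mins")
  if (any(d <= 0)) {
    abort(paste0("fly ", fly_id, ": non-monotone timestamps"), call = call)
  }
  b <- min(d)
  if (any(abs(d - b) > 1e-6)) {
    abort(paste0("fly ", fly_id, ": gaps or irregular bin spacing; ",
                 "fill or split the series before analysis"), call = call)
  }
  if (1440 %% b != 0) {
    abort(paste0("fly ", fly_id, ": bin width ", b,
                 " min does not divide 1440"), call = call)
  }
  b
}

parse_dam_datetime <- function(date, time) {
  dt <- as.POSIXct(paste(date, time), format = "%d %b %y %H:%M:%S", tz = "UTC")
  iso <- is.na(dt)
  if (any(iso)) {
    dt[iso] <- as.POSIXct(paste(date[iso], time[iso]),
                          format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  dt
}

#' Read a DAM-style activity monitor file or a tidy activity CSV
#'
#' Reads either the 42-column tab-delimited DAMSystem3 monitor layout
#' (`dialect = "dam42"`: index, date, time, status, six metadata fields, then
#' 32 channel counts) or a tidy CSV with columns `fly_id`, `datetime`, `count`
#' and optionally `light_flag` (`dialect = "tidy_csv"`).
#'
#' For `dam42`, rows whose status field is not 1 are monitor error records;
#' they are dropped with a warning giving the count. Each channel becomes one
#' fly with id `<monitor>C<channel>`, where `<monitor>` is the file name
#' without extension (or the `monitor` argument). Gaps in the time base are
#' reported with a warning.
#'
#' @param path Path to the input file.
#' @param dialect `"dam42"` or `"tidy_csv"`.
#' @param monitor Monitor label used to build fly ids for `dam42`; defaults
#'   to the file name without extension.
#' @return A tidy activity tibble (`fly_id`, `time`, `count`, and `light` if
#'   the CSV carried a `light_flag` column), sorted by fly and time.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' cfg <- sim_config(seed = 1)
#' fly <- simulate_population(cfg, n_families = 1)[1, ]
#' act <- simulate_activity(fly, cfg, ld_days = 1, bin_minutes = 30)
#' write_activity_csv(act, tf)
#' head(read_dam_monitor(tf, "tidy_csv"))
#' @export
read_dam_monitor <- function(path, dialect = c("dam42", "tidy_csv"),
                             monitor = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "tidy_csv") {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("fly_id", "datetime", "count")
    if (!all(need %in% names(out))) {
      abort("tidy_csv needs header columns fly_id, datetime, count")
    }
    out <- out %>%
      mutate(time = as.POSIXct(.data$datetime, tz = "UTC"),
             count = as.integer(.data$count)) %>%
      select("fly_id", "time", "count",
             dplyr::any_of(c(light = "light_flag"))) %>%
      arrange(.data$fly_id, .data$time)
    if (nrow(out) == 0) abort("no records")
    check_activity(out)
    report_gaps(out)
    return(as_tibble(out))
  }

  monitor <- monitor %||% tools::file_path_sans_ext(basename(path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("no records")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != DAM_FIELDS)) {
    bad <- which(nf != DAM_FIELDS)[1]
    abort(sprintf("parse error at line %d: %d fields, expected %d",
                  bad, nf[bad], DAM_FIELDS))
  }
  m <- matrix(unlist(fields), ncol = DAM_FIELDS, byrow = TRUE)
  time <- parse_dam_datetime(m[, 2], m[, 3])
  if (anyNA(time)) {
    abort(sprintf("parse error at line %d: unparseable date/time",
                  which(is.na(time))[1]))
  }
  status <- suppressWarnings(as.integer(m[, 4]))
  ok <- !is.na(status) & status == 1L
  if (!any(ok)) abort("no records with status 1")
  if (any(!ok)) {
    warn(sprintf("dropped %d row(s) with status != 1", sum(!ok)))
  }
  time <- time[ok]
  if (is.unsorted(time, strictly = TRUE)) abort("non-monotone timestamps")
  counts <- matrix(suppressWarnings(as.numeric(m[ok, 10 + seq_len(DAM_CHANNELS)])),
                   ncol = DAM_CHANNELS)
  if (anyNA(counts)) abort("non-numeric channel count")
  out <- tibble(
    fly_id = rep(sprintf("%sC%02d", monitor, seq_len(DAM_CHANNELS)),
                 each = length(time)),
    time = rep(time, times = DAM_CHANNELS),
    count = as.integer(counts)
  ) %>% arrange(.data$fly_id, .data$time)
  check_activity(out)
  report_gaps(out)
  out
}

report_gaps <- function(data) {
  gaps <- data %>%
    group_by(.data$fly_id) %>%
    summarise(n_gap = {
      d <- as.numeric(diff(.data$time), units = "mins")
      if (length(d) < 2) 0L else sum(abs(d - min(d)) > 1e-6)
    }, .groups = "drop") %>%
    filter(.data$n_gap > 0)
  if (nrow(gaps) > 0) {
    warn(sprintf("time-base gaps detected in %d fly/flies (e.g. %s)",
                 nrow(gaps), gaps$fly_id[1]))
  }
  invisible(data)
}

#' Write an activity table as a tidy CSV
#'
#' The round-trip partner of `read_dam_monitor(dialect = "tidy_csv")`:
#' columns are written as `fly_id`, `datetime` (ISO-8601, UTC), `count` and,
#' when present, `light_flag`.
#'
#' @param data Activity tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(data, path) {
  check_activity(data)
  out <- tibble(
    fly_id = data$fly_id,
    datetime = format(data$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    count = data$count
  )
  if ("light" %in% names(data)) out$light_flag <- data$light
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Re-bin activity counts to a coarser time resolution
#'
#' Sums counts within consecutive non-overlapping windows of
#' `target_minutes`. Total activity is conserved except for a trailing
#' partial window, which is dropped with a warning. Light labels are kept
#' when constant within a window and set to `NA` otherwise.
#'
#' @param data Activity tibble.
#' @param target_minutes New bin width; must be a multiple of the current
#'   bin width.
#' @return Re-binned activity tibble.
#' @export
rebin <- function(data, target_minutes) {
  check_activity(data)
  has_light <- "light" %in% names(data)
  dropped <- 0L
  out <- data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      if (target_minutes %% b != 0) {
        abort(sprintf("target_minutes (%s) is not a multiple of bin width (%s)",
                      target_minutes, b))
      }
      k <- target_minutes / b
      if (k == 1) return(d)
      n_full <- nrow(d) %/% k
      rem <- nrow(d) - n_full * k
      if (rem > 0) dropped <<- dropped + as.integer(rem)
      if (n_full == 0) {
        abort(sprintf("fly %s: series shorter than one target bin", d$fly_id[1]))
      }
      idx <- rep(seq_len(n_full), each = k)
      d <- d[seq_len(n_full * k), ]
      res <- tibble(
        fly_id = d$fly_id[1],
        time = d$time[seq(1, by = k, length.out = n_full)],
        count = as.integer(tapply(d$count, idx, sum))
      )
      if (has_light) {
        lab <- tapply(d$light, idx, function(l) {
          if (length(unique(l)) == 1) l[1] else NA_character_
        })
        res$light <- as.character(lab)
      }
      res
    }) %>%
    bind_rows()
  if (dropped > 0) {
    warn(sprintf("rebin: dropped %d trailing bin(s) not filling a full window",
                 dropped))
  }
  out
}

#' Describe a light regime
#'
#' @param lights_on Clock time of lights-on, `"HH:MM"` or `"HH:MM:SS"`.
#' @param photoperiod_hours Hours of light per 24 h day (12 for LD 12:12).
#' @param dd_start Optional POSIXct after which lights stay off (release into
#'   constant darkness); must fall on a bin boundary of the series it is
#'   applied to.
#' @return A `light_regime` object.
#' @export
light_regime <- function(lights_on = "08:00:00", photoperiod_hours = 12,
                         dd_start = NULL) {
  if (photoperiod_hours < 0 || photoperiod_hours > 24) {
    abort("photoperiod_hours must be in [0, 24]")
  }
  parts <- as.numeric(strsplit(lights_on, ":", fixed = TRUE)[[1]])
  if (length(parts) == 2) parts <- c(parts, 0)
  if (length(parts) != 3 || anyNA(parts)) abort("lights_on must be HH:MM[:SS]")
  structure(
    list(lights_on = lights_on,
         lights_on_min = parts[1] * 60 + parts[2] + parts[3] / 60,
         photoperiod_hours = photoperiod_hours,
         dd_start = dd_start),
    class = "light_regime"
  )
}

#' @export
print.light_regime <- function(x, ...) {
  cat(sprintf("<light_regime> lights-on %s, LD %g:%g%s\n",
              x$lights_on, x$photoperiod_hours, 24 - x$photoperiod_hours,
              if (is.null(x$dd_start)) "" else
                paste0(", DD from ", format(x$dd_start, "%Y-%m-%d %H:%M"))))
  invisible(x)
}

# minutes since midnight (UTC) for a POSIXct vector
clock_minutes <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Annotate activity bins with light phase
#'
#' Labels each bin `"L"` or `"D"` from the regime's clock schedule. After
#' `dd_start` (release into constant darkness) the labels become `"subjL"` /
#' `"subjD"`: the prior LD schedule projected forward at the same clock
#' times, which is how subjective day and night are delineated in DD.
#'
#' @param data Activity tibble.
#' @param regime A [light_regime()].
#' @return `data` with a `light` column.
#' @export
annotate_light <- function(data, regime) {
  check_activity(data)
  stopifnot(inherits(regime, "light_regime"))
  if (regime$photoperiod_hours == 0) {
    abort("no subjective reference: photoperiod is 0 with no LD history; ",
          "describe the prior LD schedule and set dd_start instead")
  }
  p_min <- regime$photoperiod_hours * 60
  out <- data %>%
    arrange(.data$fly_id, .data$time) %>%
    group_by(.data$fly_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      b <- infer_bin_minutes(d$time, d$fly_id[1])
      m <- (clock_minutes(d$time) - regime$lights_on_min) %% 1440
      straddle <- (m < p_min & m + b > p_min) | (m >= p_min & m + b > 1440)
      if (any(straddle)) {
        abort(sprintf(paste0("fly %s: bin(s) straddle a light transition; ",
                             "re-bin to a width aligned with the schedule"),
                      d$fly_id[1]))
      }
      is_l <- m < p_min
      subj <- rep(FALSE, nrow(d))
      if (!is.null(regime$dd_start)) {
        off <- as.numeric(difftime(d$time, regime$dd_start, units = "mins"))
        if (any(off > 0 & off < b)) {
          abort("dd_start does not align to a bin boundary")
        }
        subj <- off >= 0
      }
      d$light <- ifelse(subj,
                        ifelse(is_l, "subjL", "subjD"),
                        ifelse(is_l, "L", "D"))
      d
    }) %>%
    bind_rows()
  out
}
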