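#' Bin a vitals stream into 1-minute blocks
#'
#' High-rate pressure samples are reduced to non-overlapping consecutive
#' 60-s bins starting at `t0`; each bin's value is the arithmetic mean of
#' the samples it contains.  A trailing partial bin is dropped.  Any sample
#' rate is accepted.
#'
#' @param time_s sample times, seconds, non-decreasing.
#' @param value sample values (typically MAP in mmHg).
#' @param t0 bin origin in seconds; defaults to the first sample time.
#' @param bin_s bin width in seconds (60).
#' @return numeric vector of per-bin means (possibly empty).
#' @export
#' @examples
#' bin_one_minute(seq(0.1, 120, by = 0.1), rep(c(59, 71), each = 600))
bin_one_minute <- function(time_s, value, t0 = NULL, bin_s = 60) {
  stopifnot(length(time_s) == length(value), bin_s > 0)
  if (length(time_s) == 0L) return(numeric())
  if (is.unsorted(time_s)) stop("time_s must be non-decreasing")
  if (is.null(t0)) {
    # samples are stamped at the end of their sampling interval, so the
    # stream origin sits one sample period before the first timestamp
    dt <- if (length(time_s) > 1L) stats::median(diff(time_s)) else 0
    t0 <- time_s[1] - dt
  }
  rel <- time_s - t0
  keep <- rel >= 0
  rel <- rel[keep]; value <- value[keep]
  if (length(rel) == 0L) return(numeric())
  # samples falling exactly on a bin's right edge belong to that bin;
  # a 1e-9 s tolerance absorbs floating-point jitter in sample clocks
  idx <- ceiling(rel / bin_s - 1e-9)
  idx[idx == 0L] <- 1L
  n_bins <- floor(max(rel) / bin_s + 1e-9)
  if (n_bins < 1) return(numeric())
  full <- idx <= n_bins
  as.numeric(tapply(value[full], factor(idx[full], levels = seq_len(n_bins)),
                    mean))
}

#' Time-in-range report from 1-minute MAP bins
#'
#' Proportion of 1-min bins in each pressure band: hypotension below
#' 60 mmHg, normotension 60--70 mmHg inclusive at both ends, hypertension
#' above 70 mmHg, with the hypertensive band split at 80 mmHg (70--80
#' exclusive at 70 -- which belongs to normotension -- and inclusive at 80).
#'
#' @param bins numeric vector of per-bin mean MAP, mmHg (>= 1 bin).
#' @param map_low,map_high normotension band bounds, mmHg.
#' @param map_very_high split point of the hypertensive band, mmHg.
#' @return a list of class `time_in_range_report` with percentage fields
#'   `pct_lt60`, `pct_60_70`, `pct_70_80`, `pct_gt80`, `pct_gt70` and the
#'   bin count `n_bins`.
#' @export
time_in_range <- function(bins, map_low = 60, map_high = 70,
                          map_very_high = 80) {
  if (length(bins) == 0L) stop("time_in_range() requires at least one bin")
  if (any(!is.finite(bins))) stop("bins must be finite")
  n <- length(bins)
  structure(list(
    pct_lt60 = 100 * sum(bins < map_low) / n,
    pct_60_70 = 100 * sum(bins >= map_low & bins <= map_high) / n,
    pct_70_80 = 100 * sum(bins > map_high & bins <= map_very_high) / n,
    pct_gt80 = 100 * sum(bins > map_very_high) / n,
    pct_gt70 = 100 * sum(bins > map_high) / n,
    n_bins = n
  ), class = "time_in_range_report")
}

#' Intervention rate and mix
#'
#' Interventions per hour over a phase window, and the bolus/titration
#' split: test boluses count as boluses, and every norepinephrine change
#' (increase or decrease) counts as one titration.
#'
#' @param interventions data.frame with columns `time_s` and `kind`
#'   (`fluid_bolus`, `test_bolus`, `ne_increase`, `ne_decrease`).
#' @param window_s numeric length-2, phase window `[start, end]` in seconds.
#' @return list with `interventions_per_hour`, `n_interventions`,
#'   `pct_boluses`, `pct_titrations` (the percentages are `NA` when no
#'   intervention falls in the window).
#' @export
intervention_stats <- function(interventions, window_s) {
  stopifnot(is.data.frame(interventions), length(window_s) == 2L,
            window_s[2] > window_s[1])
  inw <- interventions[interventions$time_s > window_s[1] &
                         interventions$time_s <= window_s[2], , drop = FALSE]
  hours <- (window_s[2] - window_s[1]) / 3600
  n <- nrow(inw)
  if (n == 0L)
    return(list(interventions_per_hour = 0, n_interventions = 0L,
                pct_boluses = NA_real_, pct_titrations = NA_real_))
  n_bolus <- sum(inw$kind %in% c("fluid_bolus", "test_bolus"))
  n_titr <- sum(inw$kind %in% c("ne_increase", "ne_decrease"))
  list(interventions_per_hour = n / hours,
       n_interventions = n,
       pct_boluses = 100 * n_bolus / n,
       pct_titrations = 100 * n_titr / n)
}

#' Cohort summary: median and interquartile range
#'
#' Summarises per-run reports across a cohort the way small-sample
#' physiology studies are reported: median with 25th/75th percentiles,
#' using linear-interpolation order statistics ([stats::quantile()]
#' type 7; for n = 5 these are the 2nd and 4th order statistics).
#'
#' @param reports a list of [time_in_range()] reports, or a data.frame of
#'   numeric per-run fields.
#' @return a data.frame with one row per field: `field`, `median`, `q1`,
#'   `q3`, `n`.
#' @export
#' @examples
#' cohort_summary(data.frame(pct_lt60 = c(16.9, 8.6, 5.1, 15.3, 26.3)))
cohort_summary <- function(reports) {
  if (is.data.frame(reports)) {
    df <- reports
  } else if (is.list(reports) && length(reports) > 0L) {
    df <- do.call(rbind, lapply(reports, function(r)
      as.data.frame(r[vapply(r, is.numeric, TRUE)])))
  } else {
    stop("reports must be a non-empty list of reports or a data.frame")
  }
  if (nrow(df) == 0L) stop("cohort_summary() requires at least one report")
  num <- vapply(df, is.numeric, TRUE)
  out <- lapply(names(df)[num], function(f) {
    x <- df[[f]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE,
                         na.rm = TRUE)
    data.frame(field = f, median = q[2], q1 = q[1], q3 = q[3],
               n = sum(!is.na(x)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hemodynamic exclusion screen
#'
#' Flags runs that would be excluded on hemodynamic grounds:
#'
#' * `expiration` -- any contiguous 5-min window with MAP below 20 mmHg at
#'   any time point;
#' * `setup_pressor` -- norepinephrine above 0.1 mcg/kg/min for more than
#'   10 min cumulative during the setup phase;
#' * `baseline_pressor` -- norepinephrine above 0.06 mcg/kg/min at time
#'   zero (start of the experiment).
#'
#' A white-cell-count criterion used alongside these requires laboratory
#' input and is intentionally not implemented.
#'
#' @param vitals data.frame with `time_s` and `pap_mmHg`.
#' @param ne_history data.frame with `time_s` and `ne_rate` (mcg/kg/min),
#'   step-wise constant between rows.
#' @param phases named list with `setup = c(start_s, end_s)` annotating the
#'   setup phase and `t0` the experiment start time.
#' @param map_floor expiration MAP threshold, mmHg.
#' @param expiration_s expiration window, s.
#' @param setup_ne_threshold,setup_ne_max_s setup-phase norepinephrine
#'   threshold (mcg/kg/min) and maximum cumulative duration (s).
#' @param baseline_ne_threshold time-zero norepinephrine threshold.
#' @return character vector of flags (empty when none apply).
#' @export
exclusion_screen <- function(vitals, ne_history, phases,
                             map_floor = 20, expiration_s = 300,
                             setup_ne_threshold = 0.1, setup_ne_max_s = 600,
                             baseline_ne_threshold = 0.06) {
  if (is.null(phases$setup) || is.null(phases$t0))
    stop("phases must annotate 'setup' (start, end) and 't0'")
  stopifnot(is.data.frame(vitals), is.data.frame(ne_history))
  flags <- character()

  # expiration: contiguous run of sub-threshold MAP spanning >= 5 min
  below <- vitals$pap_mmHg < map_floor
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      span <- vitals$time_s[ends[i]] - vitals$time_s[starts[i]]
      # a run of samples covering the full window (closed on both sides)
      if (span >= expiration_s) { flags <- c(flags, "expiration"); break }
    }
  }

  # setup pressor: cumulative time above threshold during setup
  su <- phases$setup
  nh <- ne_history[order(ne_history$time_s), , drop = FALSE]
  if (nrow(nh) > 0) {
    seg_start <- pmax(nh$time_s, su[1])
    seg_end <- pmin(c(nh$time_s[-1], su[2]), su[2])
    dur <- pmax(seg_end - seg_start, 0)
    cum <- sum(dur[nh$ne_rate > setup_ne_threshold])
    if (cum > setup_ne_max_s) flags <- c(flags, "setup_pressor")

    # baseline pressor: rate in force at time zero
    at0 <- nh$ne_rate[findInterval(phases$t0, nh$time_s)]
    if (length(at0) == 1L && !is.na(at0) && at0 > baseline_ne_threshold)
      flags <- c(flags, "baseline_pressor")
  }
  flags
}

#' Packaged cohort fixture: per-animal time at pressure ranges
#'
#' The published per-animal proportions of critical-care time at each blood
#' pressure range for the five-animal cohort, as printed (percent of 1-min
#' bins; ranges `<60`, `60--70`, `70--80`, `>80` mmHg).  Used as the fixture
#' for cohort median/IQR summaries.
#'
#' @return data.frame with columns `animal`, `pct_lt60`, `pct_60_70`,
#'   `pct_70_80`, `pct_gt80`.
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "swine_cohort_time_in_range.csv",
                      package = "hemocontrol", mustWork = TRUE)
  utils::read.csv(path)
}

# Display rounding used in range tables: one decimal, half away from zero.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
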