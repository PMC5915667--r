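#' Ordinary-least-squares slope of an HbA1c series
#'
#' Trend estimate in percent HbA1c per month, valid for two or more unevenly
#' spaced points.
#'
#' @param time numeric vector of months since the first measurement.
#' @param value HbA1c values in percent.
#' @return slope in %/month.
#' @export
series_slope <- function(time, value) {
  stopifnot(length(time) == length(value))
  if (length(time) < 2) stop("need at least 2 points for a slope")
  ct <- time - mean(time)
  if (all(ct == 0)) stop("all measurement times are equal")
  sum(ct * (value - mean(value))) / sum(ct^2)
}

#' Classify an HbA1c series into a clinical-evolution segment
#'
#' Rules evaluated in order (each later segment excludes the earlier ones):
#'
#' 1. **compensated** -- all values below 7%, or exactly one value in the
#'    7--9% band (inclusive) with no value above 9% and a mean below 7%;
#' 2. **improved** -- strictly negative OLS slope and a final value below 7%,
#'    regardless of the initial value;
#' 3. **highly decompensated** -- some value reaching or exceeding 9%;
#' 4. **moderately decompensated** -- everything else.
#'
#' The 9% boundary is assigned to the highly decompensated predicate so the
#' four predicates partition every series.
#'
#' @param time months since the first in-window measurement.
#' @param value HbA1c values in percent (at least 2).
#' @return object of class `outcome_segment`: list with `label` and the
#'   supporting statistics `slope`, `mean`, `max`, `final`, `n_in_band`
#'   (count of values in \[7, 9\]).
#' @export
classify_segment <- function(time, value) {
  stopifnot(length(time) == length(value))
  if (length(value) < 2) stop("need at least 2 measurements to classify")
  ord <- order(time)
  time <- time[ord]
  value <- value[ord]
  slope <- series_slope(time, value)
  final <- value[length(value)]
  n_band <- sum(value >= 7 & value <= 9)
  label <- if (all(value < 7) ||
               (n_band == 1 && !any(value > 9) && mean(value) < 7)) {
    "compensated"
  } else if (slope < 0 && final < 7) {
    "improved"
  } else if (any(value >= 9)) {
    "highly decompensated"
  } else {
    "moderately decompensated"
  }
  structure(list(label = label, slope = slope, mean = mean(value),
                 max = max(value), final = final, n_in_band = n_band),
            class = "outcome_segment")
}

#' @export
print.outcome_segment <- function(x, ...) {
  cat(sprintf("%s (slope %+.3f %%/month, mean %.1f, max %.1f, final %.1f)\n",
              x$label, x$slope, x$mean, x$max, x$final))
  invisible(x)
}

#' Segment every eligible patient of a cohort
#'
#' Restricts each patient's measurements to their study window (measurements
#' after `t_end` are dropped; everything from `t0` to `t_end` is kept) and
#' classifies the in-window series.
#'
#' @param measurements validated measurement table.
#' @param windows study-window data frame ([run_funnel()] output).
#' @return data frame with columns `patient_id`, `segment`, `slope`, `mean`,
#'   `max`, `final`.
#' @export
classify_segments <- function(measurements, windows) {
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    id <- windows$patient_id[i]
    sub <- measurements[measurements$patient_id == id &
                        measurements$date >= windows$t0[i] &
                        measurements$date <= windows$t_end[i], , drop = FALSE]
    sub <- sub[order(sub$date), , drop = FALSE]
    seg <- classify_segment(months_between(windows$t0[i], sub$date), sub$value)
    rows[[i]] <- data.frame(patient_id = id, segment = seg$label,
                            slope = seg$slope, mean = seg$mean, max = seg$max,
                            final = seg$final)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Tabulate outcome segments
#'
#' @param segments character vector of segment labels, or a data frame with a
#'   `segment` column.
#' @return data frame with columns `segment`, `n`, `pct` (percent of total,
#'   one decimal).
#' @export
segment_counts <- function(segments) {
  if (is.data.frame(segments)) segments <- segments$segment
  n <- as.integer(table(factor(segments, levels = SEGMENT_LEVELS)))
  total <- sum(n)
  data.frame(segment = SEGMENT_LEVELS, n = n,
             pct = if (total > 0) round(100 * n / total, 1) else rep(0, 4))
}
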