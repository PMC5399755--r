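#' Call turn events from an eccentricity time series
#'
#' A turn is called wherever the equivalent-ellipse eccentricity stays
#' below a threshold: maximal runs of sub-threshold frames lasting at
#' least `min_duration_s` become events, and events separated by less
#' than `merge_gap_s` are merged. Flagged (lost-worm) frames are
#' excluded from run membership but interrupt neither runs nor merging:
#' two sub-threshold stretches separated only by flagged frames belong
#' to the same run.
#'
#' @param eccentricity Numeric vector of per-frame eccentricities; `NA`
#'   marks flagged frames. Typically the `eccentricity` column of
#'   [compute_shape_metrics()].
#' @param frame_rate_hz Sampling rate of the series.
#' @param threshold Eccentricity threshold in (0, 1); frames with
#'   `eccentricity < threshold` are turn candidates. See
#'   [calibrate_threshold()].
#' @param min_duration_s Minimum event duration (s). The default 0.2 s
#'   is two frames at 10 Hz.
#' @param merge_gap_s Events separated by a gap strictly smaller than
#'   this are merged. The default 0.1 s (one frame interval at 10 Hz)
#'   bridges gaps created by flagged frames without fusing distinct
#'   turns; see the methods vignette.
#' @param median_filter Apply a 3-frame running median to the series
#'   before thresholding (off by default, keeping the event definition
#'   minimal).
#' @return An object of class `turn_events`: a list with `events`
#'   (tibble of `start_s`, `end_s`), `threshold_used`, and
#'   `per_minute_rates` (tibble of `minute`, `turns_per_min`; see
#'   [turns_per_minute()]).
#' @export
call_turns <- function(eccentricity, frame_rate_hz, threshold = 0.85,
                       min_duration_s = 0.2, merge_gap_s = 0.1,
                       median_filter = FALSE) {
  stopifnot(threshold > 0, threshold < 1, frame_rate_hz > 0)
  dt <- 1 / frame_rate_hz
  n <- length(eccentricity)
  time_s <- (seq_len(n) - 1) * dt
  e <- eccentricity
  if (median_filter) {
    e <- stats::runmed(e, 3, endrule = "keep")
  }
  valid <- !is.na(e)
  vt <- time_s[valid]
  below <- e[valid] < threshold
  events <- runs_to_events(vt, below, dt)
  ## minimum duration, then merging (in that order)
  keep <- (events$end_s - events$start_s) >= min_duration_s - 1e-9
  events <- events[keep, , drop = FALSE]
  events <- merge_events(events, merge_gap_s)
  duration_s <- n * dt
  rates <- turns_per_minute(events, duration_s)
  structure(list(events = tibble::as_tibble(events),
                 threshold_used = threshold,
                 per_minute_rates = rates),
            class = "turn_events")
}

#' @export
print.turn_events <- function(x, ...) {
  cat(sprintf("<turn_events> %d events (threshold %.2f)\n",
              nrow(x$events), x$threshold_used))
  if (nrow(x$per_minute_rates)) {
    cat("turns/min by minute:",
        paste(x$per_minute_rates$turns_per_min, collapse = " "), "\n")
  }
  invisible(x)
}

## Maximal TRUE-runs over (possibly irregular) sample times.
## An event spans [first frame time, last frame time + dt).
runs_to_events <- function(time_s, below, dt) {
  if (length(below) == 0 || !any(below)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- r$values
  data.frame(start_s = time_s[starts[sel]],
             end_s = time_s[ends[sel]] + dt)
}

## Merge events whose gap (next start minus previous end) is strictly
## below `merge_gap_s`. Idempotent.
merge_events <- function(events, merge_gap_s) {
  if (nrow(events) <= 1) return(events)
  events <- events[order(events$start_s), , drop = FALSE]
  s <- events$start_s; e <- events$end_s
  out_s <- s[1]; out_e <- e[1]
  for (i in 2:length(s)) {
    if (s[i] - out_e[length(out_e)] < merge_gap_s) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

#' Per-minute turn rates
#'
#' Counts event starts in each half-open whole-minute bin
#' \eqn{[60(m-1), 60m)} seconds; minute 5 is `[240, 300)` s, the
#' assay's primary comparison bin. Only complete minutes are reported.
#'
#' @param events `turn_events` object, or a data frame with `start_s`.
#' @param duration_s Recording length (s); a recording shorter than one
#'   minute yields an empty table with a warning.
#' @return A tibble of `minute` (1-based) and `turns_per_min`.
#' @export
turns_per_minute <- function(events, duration_s) {
  if (inherits(events, "turn_events")) events <- events$events
  n_min <- floor(duration_s / 60)
  if (n_min < 1) {
    warning("recording shorter than one minute: no complete minute bins")
    return(tibble::tibble(minute = integer(0), turns_per_min = numeric(0)))
  }
  counts <- vapply(seq_len(n_min), function(m) {
    sum(events$start_s >= 60 * (m - 1) & events$start_s < 60 * m)
  }, numeric(1))
  tibble::tibble(minute = seq_len(n_min), turns_per_min = counts)
}

#' Calibrate the eccentricity threshold against annotated turns
#'
#' Mirrors the original procedure of fixing the turn threshold from
#' manually detected turns: scans a grid of thresholds (default 0.5 to
#' 0.99 in steps of 0.01) and returns the one maximizing event-level F1
#' against the annotated turn intervals. A called event matches an
#' annotation when their intervals overlap. Ties are broken toward the
#' higher threshold.
#'
#' @inheritParams call_turns
#' @param annotations Data frame of annotated turn intervals
#'   (`start_s`, `end_s`), e.g. manual annotations or simulator ground
#'   truth. Must contain at least one interval.
#' @param grid Thresholds to scan.
#' @return The selected threshold (scalar), with attribute `"f1"`.
#' @export
calibrate_threshold <- function(eccentricity, frame_rate_hz, annotations,
                                grid = seq(0.5, 0.99, by = 0.01),
                                min_duration_s = 0.2, merge_gap_s = 0.1) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    stop("threshold calibration requires at least one annotated turn")
  }
  dur <- length(eccentricity) / frame_rate_hz
  if (max(annotations$start_s) > dur) {
    stop("annotations do not overlap the series time span")
  }
  f1s <- vapply(grid, function(th) {
    ev <- call_turns(eccentricity, frame_rate_hz, threshold = th,
                     min_duration_s = min_duration_s,
                     merge_gap_s = merge_gap_s)$events
    event_f1(ev, annotations)
  }, numeric(1))
  best <- max(f1s)
  th <- max(grid[f1s == best]) # ties toward the higher threshold
  structure(th, f1 = best)
}

## Event-level F1. Called events and annotations are matched one to
## one by interval overlap (greedy in time order), so a single called
## event spanning many annotations counts as one true positive, not
## several.
event_f1 <- function(called, annotated) {
  if (nrow(called) == 0) return(0)
  i <- 1L; j <- 1L; tp <- 0L
  nc <- nrow(called); na <- nrow(annotated)
  while (i <= nc && j <= na) {
    if (called$start_s[i] < annotated$end_s[j] &&
        annotated$start_s[j] < called$end_s[i]) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (called$end_s[i] <= annotated$start_s[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  prec <- tp / nc
  rec <- tp / na
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
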