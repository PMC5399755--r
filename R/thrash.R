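#' Signed body-bend signal from a swim video
#'
#' Operationalizes "curving of the worm body toward either side" as a
#' per-frame scalar: the mask is split at the centroid along the
#' equivalent-ellipse major axis, each half is ellipse-fitted, and the
#' bend is the signed angle between the two halves' major axes (0 for a
#' straight body, positive/negative for the two sides). The sign
#' convention is held consistent across frames by keeping the principal
#' axis direction continuous (no head/tail assignment is attempted).
#'
#' @param stack A [frame_stack()].
#' @param masks Optional precomputed masks from segmentation; computed
#'   with defaults otherwise. Flagged frames yield `NA` bend values.
#' @param metrics Optional precomputed [compute_shape_metrics()] table.
#' @return A tibble of `time_s` and `bend` (radians), one row per frame.
#' @export
bending_signal <- function(stack, masks = NULL, metrics = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(masks)) masks <- segment_stack(stack)
  if (is.null(metrics)) metrics <- compute_shape_metrics(stack, masks = masks)
  n <- length(stack)
  bend <- rep(NA_real_, n)
  prev_u <- NULL
  for (i in seq_len(n)) {
    m <- masks[[i]]
    if (is.null(m) || metrics$flagged[i]) next
    ori <- metrics$orientation[i]
    u <- c(sin(ori), cos(ori)) # (row, col) direction of the major axis
    if (!is.null(prev_u) && sum(u * prev_u) < 0) u <- -u
    prev_u <- u
    idx <- which(m, arr.ind = TRUE)
    d <- (idx[, 1] - metrics$centroid_r[i]) * u[1] +
      (idx[, 2] - metrics$centroid_c[i]) * u[2]
    b <- tryCatch({
      ang_a <- half_axis_angle(idx[d >= 0, , drop = FALSE])
      ang_p <- half_axis_angle(idx[d < 0, , drop = FALSE])
      wrap_half_angle(ang_a - ang_p)
    }, error = function(e) NA_real_)
    bend[i] <- b
  }
  tibble::tibble(time_s = frame_times(stack), bend = bend)
}

## Principal-axis angle of a pixel set (radians vs. the column axis).
half_axis_angle <- function(idx) {
  if (nrow(idx) < 3) stop("degenerate half-mask")
  r <- idx[, 1]; c <- idx[, 2]
  u20 <- mean((r - mean(r))^2)
  u02 <- mean((c - mean(c))^2)
  u11 <- mean((r - mean(r)) * (c - mean(c)))
  0.5 * atan2(2 * u11, u02 - u20)
}

wrap_half_angle <- function(a) {
  a <- ((a + pi / 2) %% pi) - pi / 2
  if (a <= -pi / 2) a + pi else a
}

#' Count body thrashes with a Schmitt trigger
#'
#' One thrash is one curving of the body toward either side: the count
#' increments at every alternation of the bend sign whose magnitude
#' exceeds the hysteresis band (half-cycle counting). A clean sinusoidal
#' bend at `f` Hz therefore yields `2 f` thrashes per second; noise
#' smaller than the band never triggers.
#'
#' @param bend Numeric bend series (radians); `NA` marks flagged frames,
#'   which are skipped without resetting the trigger state.
#' @param time_s Sample times (s), or supply `frame_rate_hz`.
#' @param frame_rate_hz Sampling rate used when `time_s` is missing.
#' @param hysteresis Half-width of the trigger band (radians, > 0).
#' @return A list with `total` (thrash count), `crossing_times_s`, and
#'   `per_minute` (tibble of `minute`, `thrashes_per_min` over complete
#'   minutes).
#' @export
count_thrashes <- function(bend, time_s = NULL, frame_rate_hz = NULL,
                           hysteresis = 0.2) {
  stopifnot(hysteresis > 0)
  if (is.null(time_s)) {
    stopifnot(!is.null(frame_rate_hz))
    time_s <- (seq_along(bend) - 1) / frame_rate_hz
  }
  state <- 0L
  crossings <- numeric(0)
  for (i in seq_along(bend)) {
    b <- bend[i]
    if (is.na(b)) next
    if (b > hysteresis && state != 1L) {
      crossings <- c(crossings, time_s[i])
      state <- 1L
    } else if (b < -hysteresis && state != -1L) {
      crossings <- c(crossings, time_s[i])
      state <- -1L
    }
  }
  duration_s <- max(time_s) + (time_s[2] - time_s[1])
  n_min <- floor(duration_s / 60)
  per_minute <- if (n_min >= 1) {
    tibble::tibble(
      minute = seq_len(n_min),
      thrashes_per_min = vapply(seq_len(n_min), function(m) {
        sum(crossings >= 60 * (m - 1) & crossings < 60 * m)
      }, numeric(1))
    )
  } else {
    tibble::tibble(minute = integer(0), thrashes_per_min = numeric(0))
  }
  list(total = length(crossings), crossing_times_s = crossings,
       per_minute = per_minute)
}
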