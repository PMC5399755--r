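#' Correct photobleaching by an exponential fit
#'
#' Fits the mono-exponential decay \eqn{\hat F(t) = a e^{-bt}} (with
#' \eqn{b \ge 0}) to the trace and divides it out ratiometrically,
#' renormalized to the fitted value at t = 0:
#' \deqn{F_{corr}(t) = F(t) \, \hat F(0) / \hat F(t).}
#' Division (rather than subtraction) preserves fractional responses,
#' which is what \eqn{\Delta F/F} measures. By default the decay is
#' fitted on the pre-stimulus baseline window only and extrapolated
#' over the whole trace, so a genuine response after the stimulus
#' cannot be absorbed into the decay estimate; set
#' `fit_window = "full"` to fit the entire trace instead. A flat trace
#' (fitted b of 0) passes through unchanged. If the nonlinear fit fails
#' to converge the function falls back to a linear detrend of the fit
#' window with a warning (never silently).
#'
#' @param trace A data frame with `time_s` and `F` (raw fluorescence,
#'   positive), as from [simulate_calcium_trace()] or an ROI-mean CSV.
#' @param fit_window `"baseline"` (default), `"full"`, or a numeric
#'   `c(from, to)` window in seconds over which to fit the decay.
#' @param baseline_window The baseline window (s) used when
#'   `fit_window = "baseline"`.
#' @return The trace tibble with an added `F_corrected` column;
#'   attribute `"bleach_fit"` records the method, coefficients `a` and
#'   `b`, and the fit window.
#' @export
bleach_correct <- function(trace, fit_window = "baseline",
                           baseline_window = c(0, 60)) {
  stopifnot(all(c("time_s", "F") %in% names(trace)))
  t <- trace$time_s
  F_raw <- trace$F
  if (length(F_raw) < 10) stop("trace too short to fit (need >= 10 samples)")
  if (any(F_raw <= 0)) stop("fluorescence must be positive")
  win <- if (identical(fit_window, "baseline")) {
    baseline_window
  } else if (identical(fit_window, "full")) {
    c(min(t), max(t) + 1e-9)
  } else {
    stopifnot(is.numeric(fit_window), length(fit_window) == 2)
    fit_window
  }
  sel <- t >= win[1] & t < win[2]
  if (sum(sel) < 10) stop("fit window holds fewer than 10 samples")
  ts <- t[sel]; Fs <- F_raw[sel]

  ## log-linear closed-form start, refined by Levenberg-Marquardt
  ll <- lm.fit(cbind(1, ts), log(Fs))$coefficients
  start <- c(a = exp(ll[[1]]), b = max(0, -ll[[2]]))
  fit <- tryCatch({
    out <- minpack.lm::nls.lm(
      par = start,
      fn = function(p) Fs - p[1] * exp(-p[2] * ts),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (out$info %in% c(0, 5)) stop("no convergence")
    list(method = "exponential_fit", a = out$par[[1]], b = out$par[[2]])
  }, error = function(e) NULL)

  if (is.null(fit)) {
    warning("exponential bleach fit did not converge; ",
            "falling back to a linear detrend")
    co <- lm.fit(cbind(1, ts), Fs)$coefficients
    Fhat <- co[[1]] + co[[2]] * t
    fit <- list(method = "linear_detrend", a = co[[1]], b = -co[[2]])
  } else {
    Fhat <- fit$a * exp(-fit$b * t)
  }
  if (any(Fhat <= 0)) {
    stop("fitted bleach curve is non-positive inside the trace")
  }
  out <- tibble::as_tibble(trace)
  out$F_corrected <- F_raw * Fhat[1] / Fhat
  attr(out, "bleach_fit") <- c(fit, list(window = win))
  out
}

#' Compute the percentage fluorescence change (delta-F/F)
#'
#' \eqn{\Delta F/F(t) = (F_{corr}(t) - F_{base}) / F_{base} \times
#' 100\%} with \eqn{F_{base}} the mean corrected fluorescence over the
#' baseline window (the first 60 s by default) and the series reported
#' over the analysis window (the first 120 s by default).
#'
#' @param trace Output of [bleach_correct()] (needs `F_corrected`), or
#'   any data frame with `time_s` and `F_corrected`.
#' @param baseline_window Half-open window (s) defining
#'   \eqn{F_{base}}.
#' @param analysis_window Half-open window (s) over which
#'   \eqn{\Delta F/F} is reported.
#' @return A tibble of `time_s` and `dff` (percent) over the analysis
#'   window; attribute `"F_base"` records the baseline.
#' @export
compute_dff <- function(trace, baseline_window = c(0, 60),
                        analysis_window = c(0, 120)) {
  stopifnot(all(c("time_s", "F_corrected") %in% names(trace)))
  t <- trace$time_s
  ## the last sample may sit one sampling interval short of the edge
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  if (max(t) + dt + 1e-9 < analysis_window[2]) {
    stop("trace does not cover the analysis window")
  }
  base_sel <- t >= baseline_window[1] & t < baseline_window[2]
  if (!any(base_sel)) stop("no samples in the baseline window")
  F_base <- mean(trace$F_corrected[base_sel])
  if (F_base <= 0) stop("baseline fluorescence F_base is not positive")
  sel <- t >= analysis_window[1] & t < analysis_window[2]
  out <- tibble::tibble(
    time_s = t[sel],
    dff = (trace$F_corrected[sel] - F_base) / F_base * 100
  )
  attr(out, "F_base") <- F_base
  out
}

#' Per-animal response summary
#'
#' Arithmetic mean of \eqn{\Delta F/F} over the response window (after
#' the solution switch; `[60, 120)` s by default).
#'
#' @param dff Output of [compute_dff()] (or data frame with `time_s`,
#'   `dff`).
#' @param response_window Half-open window (s).
#' @return Mean \eqn{\Delta F/F} in percent (scalar).
#' @export
response_summary <- function(dff, response_window = c(60, 120)) {
  sel <- dff$time_s >= response_window[1] & dff$time_s < response_window[2]
  vals <- dff$dff[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no usable samples in the response window")
  mean(vals)
}

#' Check normality of a sample
#'
#' Runs both tests used to justify parametric comparison of imaging
#' responses: a Kolmogorov-Smirnov test against a normal with the
#' sample's mean and SD, and the Shapiro-Wilk test.
#'
#' @param samples Numeric vector, n >= 3, non-constant.
#' @return A tibble of `test`, `statistic`, `p_value`.
#' @export
normality_check <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 3) stop("need at least 3 observations")
  if (sd(samples) == 0) stop("constant sample: normality is undefined")
  ks <- suppressWarnings(
    ks.test(samples, "pnorm", mean(samples), sd(samples))
  )
  sw <- shapiro.test(samples)
  tibble::tibble(
    test = c("Kolmogorov-Smirnov", "Shapiro-Wilk"),
    statistic = c(unname(ks$statistic), unname(sw$statistic)),
    p_value = c(ks$p.value, sw$p.value)
  )
}

#' Assemble and export a per-animal delta-F/F heat-map matrix
#'
#' Rows are animals, columns time points; the matrix round-trips
#' through CSV losslessly. `export_dff_heatmap()` additionally renders
#' a simple PNG image of the matrix.
#'
#' @param dff_list Named list of [compute_dff()] outputs (one per
#'   animal, on a common time grid).
#' @return A numeric matrix (animals x time), time in the column names.
#' @export
dff_matrix <- function(dff_list) {
  times <- dff_list[[1]]$time_s
  mat <- do.call(rbind, lapply(dff_list, function(d) {
    stopifnot(isTRUE(all.equal(d$time_s, times)))
    d$dff
  }))
  rownames(mat) <- names(dff_list)
  colnames(mat) <- format(times, trim = TRUE)
  mat
}

#' @rdname dff_matrix
#' @param mat Matrix from `dff_matrix()`.
#' @param csv_path,png_path Output paths (either may be `NULL`).
#' @export
export_dff_heatmap <- function(mat, csv_path = NULL, png_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(mat, csv_path, row.names = TRUE)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 80 + 24 * nrow(mat))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(t(mat)[, rev(seq_len(nrow(mat))), drop = FALSE],
                    axes = FALSE, xlab = "time", ylab = "animal",
                    main = "delta-F/F (%)")
  }
  invisible(mat)
}

#' Read a per-animal ROI-mean trace CSV
#'
#' Expects columns `time_s` and `F` (additional columns pass through).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "F") %in% names(df))) {
    stop("trace CSV '", path, "' must have columns time_s and F")
  }
  tibble::as_tibble(df)
}
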