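#' Parameters for the synthetic swim-video generator
#'
#' Bundles and validates every knob of the droplet swim simulator. The
#' defaults emulate the study conditions of the droplet assay: a single
#' adult worm per droplet recorded at 10 Hz, continuous ~2 Hz thrashing
#' interrupted by turn episodes whose rate may ramp over the 5 min
#' recording.
#'
#' @param duration_s Recording length in seconds.
#' @param frame_rate_hz Frames per second (camera rate; default 10).
#' @param worm_length_px Worm body arclength in pixels.
#' @param worm_halfwidth_px Half of the body width in pixels; the body is
#'   rendered as the midline dilated to this radius.
#' @param thrash_freq_hz Undulation cycles per second during swimming.
#' @param turn_rate_fn Function mapping time (s) to the expected turn
#'   rate in turns/min; must be non-negative. See [ramp_rate_fn()] and
#'   [constant_rate_fn()].
#' @param turn_duration_s Seconds a single turn posture is held.
#' @param turn_shape `"omega"` (near-closed >270 degree body arc) or
#'   `"reversal-bend"` (deep fold concentrated mid-body). Both depress
#'   the equivalent-ellipse eccentricity, matching the operational turn
#'   definition that pools reversals and big body bends.
#' @param area_scale Dimensionless body-area multiplier (1 = fully
#'   hydrated); linear dimensions are scaled by `sqrt(area_scale)`.
#' @param swim_amp_rad Peak swim curvature times body length (radians);
#'   controls how deeply "C-shaped" the swimming posture is.
#' @param wavelengths Number of undulation wavelengths along the body.
#' @param canvas_px Square canvas side in pixels; defaults to a
#'   single-droplet crop 1.75x the worm length.
#' @param fg_level,bg_level Foreground/background gray levels (0-255).
#' @param noise_sd Additive Gaussian pixel noise SD in gray levels.
#' @param seed Integer seed; identical seeds give bit-identical videos.
#'
#' @return A validated list of class `swim_sim_params`.
#' @export
#' @examples
#' p <- swim_sim_params(duration_s = 30, turn_rate_fn = constant_rate_fn(12))
swim_sim_params <- function(duration_s = 300,
                            frame_rate_hz = 10,
                            worm_length_px = 36,
                            worm_halfwidth_px = 2,
                            thrash_freq_hz = 2,
                            turn_rate_fn = constant_rate_fn(0),
                            turn_duration_s = 0.3,
                            turn_shape = c("omega", "reversal-bend"),
                            area_scale = 1,
                            swim_amp_rad = 9,
                            wavelengths = 1.5,
                            canvas_px = NULL,
                            fg_level = 200,
                            bg_level = 30,
                            noise_sd = 8,
                            seed = NULL) {
  turn_shape <- match.arg(turn_shape)
  stopifnot(duration_s > 0, frame_rate_hz > 0, worm_length_px > 0,
            worm_halfwidth_px > 0, thrash_freq_hz >= 0,
            turn_duration_s > 0, area_scale > 0, area_scale <= 1)
  if (!is.function(turn_rate_fn)) {
    stop("`turn_rate_fn` must be a function of time (s) returning turns/min")
  }
  tt <- seq(0, duration_s, length.out = 512)
  rates <- turn_rate_fn(tt)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("`turn_rate_fn` must be finite and >= 0 over [0, duration_s]")
  }
  canvas_px <- canvas_px %||% ceiling(worm_length_px * 1.75)
  if (worm_length_px > sqrt(2) * canvas_px) {
    stop("worm longer than the canvas diagonal; enlarge `canvas_px`")
  }
  lambda_max <- max(rates) / 60 # turns/s
  if (lambda_max > 0) {
    if (turn_duration_s >= 1 / lambda_max) {
      stop("unphysical parameters: `turn_duration_s` is not shorter than the ",
           "mean inter-turn gap implied by the maximum rate")
    }
    d_eff <- turn_duration_s + 1 / frame_rate_hz
    if (lambda_max * d_eff >= exp(-1)) {
      stop("unphysical parameters: turn rate too high to resolve episodes of ",
           "this duration at this frame rate")
    }
  }
  structure(list(
    duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    worm_length_px = worm_length_px, worm_halfwidth_px = worm_halfwidth_px,
    thrash_freq_hz = thrash_freq_hz, turn_rate_fn = turn_rate_fn,
    turn_duration_s = turn_duration_s, turn_shape = turn_shape,
    area_scale = area_scale, swim_amp_rad = swim_amp_rad,
    wavelengths = wavelengths, canvas_px = canvas_px,
    fg_level = fg_level, bg_level = bg_level, noise_sd = noise_sd,
    seed = seed
  ), class = "swim_sim_params")
}

#' Turn-rate profiles
#'
#' `constant_rate_fn(rate)` gives a flat expected turn rate, emulating
#' the stable turning of animals kept at their cultivation osmolarity.
#' `ramp_rate_fn(rate0, rate_end, ramp_end_s)` rises linearly from
#' `rate0` to `rate_end` over `[0, ramp_end_s]` and stays flat after,
#' emulating the gradual increase in turning after an osmotic upshift.
#' The default `ramp_end_s = 240` puts the plateau at the start of the
#' 5th minute, so the expected rate throughout the minute-5 bin
#' `[240, 300)` s equals `rate_end`.
#'
#' @param rate,rate0,rate_end Expected turn rates in turns/min.
#' @param ramp_end_s Time (s) at which the ramp reaches `rate_end`.
#' @return A vectorized function of time (s) returning turns/min.
#' @export
constant_rate_fn <- function(rate) {
  force(rate)
  function(t) rep_len(rate, length(t))
}

#' @rdname constant_rate_fn
#' @export
ramp_rate_fn <- function(rate0, rate_end, ramp_end_s = 240) {
  force(rate0); force(rate_end); force(ramp_end_s)
  function(t) rate0 + (rate_end - rate0) * pmin(t / ramp_end_s, 1)
}

#' Parameters for the synthetic GCaMP trace generator
#'
#' The generated trace follows
#' \deqn{F(t) = f_0 e^{-\beta t} (1 + A \cdot 1[t \ge t_{step}]) + \epsilon}
#' i.e. a mono-exponentially bleaching baseline with an optional
#' multiplicative step response at the solution switch, plus additive
#' Gaussian noise. Defaults mirror the imaging protocol: 120 s analyzed
#' per animal with the solution switched at 60 s.
#'
#' @param duration_s Trace length in seconds (default 120).
#' @param sample_rate_hz Samples per second (default 10).
#' @param f0 Baseline fluorescence at t = 0 (arbitrary units).
#' @param bleach_rate Photobleaching rate constant (1/s).
#' @param step_time_s Time of the solution switch (s).
#' @param step_amplitude_frac Fractional fluorescence step at the
#'   switch (0.2 = a 20% response).
#' @param noise_sd Additive noise SD (same units as `f0`).
#' @param seed Integer seed.
#' @return A validated list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(duration_s = 120,
                               sample_rate_hz = 10,
                               f0 = 100,
                               bleach_rate = 0.002,
                               step_time_s = 60,
                               step_amplitude_frac = 0,
                               noise_sd = 1,
                               seed = NULL) {
  stopifnot(duration_s > 0, sample_rate_hz > 0, f0 > 0, bleach_rate >= 0,
            step_time_s >= 0, step_time_s <= duration_s, noise_sd >= 0)
  structure(list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz, f0 = f0,
    bleach_rate = bleach_rate, step_time_s = step_time_s,
    step_amplitude_frac = step_amplitude_frac, noise_sd = noise_sd,
    seed = seed
  ), class = "calcium_sim_params")
}
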