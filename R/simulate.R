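#' Simulate a droplet swim video with known ground truth
#'
#' Renders a single worm swimming in a droplet crop. The midline
#' curvature is \eqn{\kappa(s,t) = A\sin(2\pi f t - k s)} during
#' swimming; during a turn episode it is replaced by a high uniform
#' curvature (`"omega"`, a >270 degree arc) or a deep mid-body fold
#' (`"reversal-bend"`). Turn episode starts follow an inhomogeneous
#' Poisson process at `turn_rate_fn`; arrivals closer than the episode
#' resolution (posture duration plus one frame interval) are merged into
#' a single episode, and the arrival intensity is calibrated so that the
#' merged episode rate equals `turn_rate_fn` (see the methods vignette).
#'
#' @param params A [swim_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{stack}{a [frame_stack()] of grayscale frames;}
#'     \item{truth}{ground truth: `turn_intervals` (data frame of
#'       `start_s`, `end_s`), `thrash_halfcycle_times` (seconds of each
#'       undulation half-cycle outside turns), `true_area_px` (rendered
#'       body area per frame), and the generating `params`.}
#'   }
#' @seealso [simulate_dehydration_pair()], [simulate_calcium_trace()]
#' @export
#' @examples
#' sim <- simulate_swim_video(swim_sim_params(
#'   duration_s = 10, turn_rate_fn = constant_rate_fn(12), seed = 1))
#' sim$stack
#' sim$truth$turn_intervals
simulate_swim_video <- function(params) {
  stopifnot(inherits(params, "swim_sim_params"))
  with_seed(params$seed, {
    p <- params
    n_frames <- round(p$duration_s * p$frame_rate_hz)
    scale <- sqrt(p$area_scale)
    L <- p$worm_length_px * scale
    hw <- p$worm_halfwidth_px * scale
    nr <- nc <- p$canvas_px
    n_mid <- max(24L, ceiling(L / 0.5))
    s_frac <- seq(0, 1, length.out = n_mid)

    intervals <- sample_turn_intervals(p$turn_rate_fn, p$duration_s,
                                       p$turn_duration_s, p$frame_rate_hz)
    handed <- if (nrow(intervals)) sample(c(-1, 1), nrow(intervals),
                                          replace = TRUE) else integer(0)
    base_angle <- runif(1, 0, 2 * pi)

    frames <- array(0L, dim = c(nr, nc, n_frames))
    true_area <- numeric(n_frames)
    times <- (seq_len(n_frames) - 1) / p$frame_rate_hz
    for (i in seq_len(n_frames)) {
      t <- times[i]
      ep <- if (nrow(intervals)) {
        which(intervals$start_s <= t & t < intervals$end_s)
      } else integer(0)
      kap <- if (length(ep)) {
        turn_curvature(s_frac, p$turn_shape, L, handed[ep[1]])
      } else {
        swim_curvature(s_frac, t, p, L)
      }
      mask <- render_worm_mask(worm_midline(kap, L, base_angle), hw, nr, nc)
      true_area[i] <- sum(mask)
      frames[, , i] <- grayscale_frame(mask, p$fg_level, p$bg_level,
                                       p$noise_sd)
    }

    half_times <- if (p$thrash_freq_hz > 0) {
      k <- seq_len(floor(2 * p$thrash_freq_hz * p$duration_s))
      k / (2 * p$thrash_freq_hz)
    } else numeric(0)
    if (nrow(intervals) && length(half_times)) {
      in_turn <- vapply(half_times, function(t) {
        any(intervals$start_s <= t & t < intervals$end_s)
      }, logical(1))
      half_times <- half_times[!in_turn]
    }

    list(
      stack = frame_stack(frames, p$frame_rate_hz),
      truth = list(turn_intervals = intervals,
                   thrash_halfcycle_times = half_times,
                   true_area_px = true_area,
                   params = p)
    )
  })
}

#' Simulate a pre/post dehydration micrograph pair
#'
#' Emulates the body-shrinkage measurement: a worm photographed before
#' and after soaking in a hyperosmotic solution. The post-soak worm has
#' its linear dimensions scaled by `sqrt(area_ratio)` so its rendered
#' body area is `area_ratio` times the pre-soak area. Pose (gentle body
#' curvature and orientation) varies between replicate images.
#'
#' @param area_ratio Target post/pre body-area ratio in (0, 1].
#' @param n_images Number of replicate pre/post image pairs.
#' @param seed Integer seed.
#' @param worm_length_px,worm_halfwidth_px,canvas_px,fg_level,bg_level,noise_sd
#'   Rendering parameters as in [swim_sim_params()]; the defaults give a
#'   well-resolved micrograph-like worm (>100 px long).
#' @return A list with `pre` and `post` (each a [frame_stack()] with
#'   `n_images` frames) and `truth`, a data frame of exact rendered
#'   pixel areas per image.
#' @export
#' @examples
#' dh <- simulate_dehydration_pair(0.776, n_images = 3, seed = 1)
#' with(dh$truth, post_area_px / pre_area_px)
simulate_dehydration_pair <- function(area_ratio, n_images = 3, seed = NULL,
                                      worm_length_px = 120,
                                      worm_halfwidth_px = 5,
                                      canvas_px = 200,
                                      fg_level = 200, bg_level = 30,
                                      noise_sd = 8) {
  stopifnot(area_ratio > 0, area_ratio <= 1, n_images >= 1)
  if (worm_length_px > sqrt(2) * canvas_px) {
    stop("worm longer than the canvas diagonal; enlarge `canvas_px`")
  }
  with_seed(seed, {
    render_one <- function(scale) {
      L <- worm_length_px * scale
      hw <- worm_halfwidth_px * scale
      n_mid <- ceiling(L / 0.4)
      s_frac <- seq(0, 1, length.out = n_mid)
      amp <- runif(1, 1, 3) / L        # gentle resting curvature
      phase <- runif(1, 0, 2 * pi)
      kap <- amp * sin(2 * pi * 1.2 * s_frac + phase)
      ang <- runif(1, 0, 2 * pi)
      mask <- render_worm_mask(worm_midline(kap, L, ang), hw,
                               canvas_px, canvas_px)
      list(mask = mask,
           frame = grayscale_frame(mask, fg_level, bg_level, noise_sd))
    }
    pre <- vector("list", n_images); post <- vector("list", n_images)
    pre_a <- numeric(n_images); post_a <- numeric(n_images)
    for (i in seq_len(n_images)) {
      a <- render_one(1)
      b <- render_one(sqrt(area_ratio))
      pre[[i]] <- a$frame; post[[i]] <- b$frame
      pre_a[i] <- sum(a$mask); post_a[i] <- sum(b$mask)
    }
    list(
      pre = frame_stack(pre, frame_rate_hz = 1),
      post = frame_stack(post, frame_rate_hz = 1),
      truth = data.frame(image = seq_len(n_images),
                         pre_area_px = pre_a, post_area_px = post_a,
                         area_ratio = area_ratio)
    )
  })
}

#' Simulate a GCaMP fluorescence trace
#'
#' Generates \eqn{F(t) = f_0 e^{-\beta t}(1 + A\,1[t \ge t_{step}]) +
#' \epsilon} with \eqn{\epsilon \sim N(0, \sigma^2)}: a bleaching
#' baseline, an optional multiplicative step response at the solution
#' switch, and additive noise.
#'
#' @param params A [calcium_sim_params()] object.
#' @return A list with `trace` (a tibble of `time_s` and raw `F`) and
#'   `truth` holding the noiseless components (`bleach`, `response`,
#'   `noiseless`) and the generating `params`.
#' @export
simulate_calcium_trace <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  with_seed(params$seed, {
    p <- params
    n <- round(p$duration_s * p$sample_rate_hz)
    t <- (seq_len(n) - 1) / p$sample_rate_hz
    bleach <- p$f0 * exp(-p$bleach_rate * t)
    response <- 1 + p$step_amplitude_frac * (t >= p$step_time_s)
    noiseless <- bleach * response
    F_raw <- noiseless + rnorm(n, 0, p$noise_sd)
    list(
      trace = tibble::tibble(time_s = t, F = F_raw),
      truth = list(bleach = bleach, response = response,
                   noiseless = noiseless, params = p)
    )
  })
}

#' Write generator ground truth as CSV
#'
#' Event log with columns `event_type` (`turn` or `thrash_halfcycle`),
#' `start_s`, `end_s` (equal to `start_s` for instantaneous events).
#'
#' @param truth The `truth` element returned by [simulate_swim_video()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  ti <- truth$turn_intervals
  df <- rbind(
    data.frame(event_type = rep("turn", nrow(ti)),
               start_s = ti$start_s, end_s = ti$end_s),
    data.frame(event_type = rep("thrash_halfcycle",
                                length(truth$thrash_halfcycle_times)),
               start_s = truth$thrash_halfcycle_times,
               end_s = truth$thrash_halfcycle_times)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
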