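## Worm body rendering: a midline of fixed arclength is built by
## integrating a curvature profile kappa(s), then dilated to the body
## half-width. All rendering is deterministic given the inputs.

## Integrate curvature into midline points, centered on the origin.
## kappa: curvature (rad/px) at `n` equally spaced arclength samples.
worm_midline <- function(kappa, length_px, base_angle = 0) {
  n <- length(kappa)
  ds <- length_px / n
  theta <- cumsum(kappa * ds)
  theta <- theta - mean(theta) + base_angle
  x <- cumsum(cos(theta)) * ds
  y <- cumsum(sin(theta)) * ds
  cbind(r = y - mean(y), c = x - mean(x))
}

## Rasterize the midline dilated to `halfwidth` on an nr x nc canvas.
## A pixel is foreground when its center lies within `halfwidth` of any
## midline sample (samples are dense relative to the pixel grid).
render_worm_mask <- function(pts, halfwidth, nr, nc,
                             center = c(nr / 2, nc / 2)) {
  y <- pts[, 1] + center[1]
  x <- pts[, 2] + center[2]
  R <- ceiling(halfwidth) + 1
  off <- as.matrix(expand.grid(di = -R:R, dj = -R:R))
  K <- nrow(off)
  iy <- rep(round(y), each = K) + off[, 1]
  ix <- rep(round(x), each = K) + off[, 2]
  d2 <- (iy - rep(y, each = K))^2 + (ix - rep(x, each = K))^2
  keep <- d2 <= halfwidth^2 & iy >= 1 & iy <= nr & ix >= 1 & ix <= nc
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(iy[keep], ix[keep])] <- TRUE
  mask
}

## Curvature profiles. `s_frac` is arclength as a fraction of body length.
swim_curvature <- function(s_frac, t, params, length_px) {
  amp <- params$swim_amp_rad / length_px
  amp * sin(2 * pi * params$thrash_freq_hz * t -
              2 * pi * params$wavelengths * s_frac)
}

turn_curvature <- function(s_frac, shape, length_px, handedness = 1) {
  if (shape == "omega") {
    ## near-closed arc: 306 degrees of total turning spread uniformly
    rep(handedness * 2 * pi * 0.85 / length_px, length(s_frac))
  } else {
    ## deep fold: 270 degrees concentrated in the middle third
    mid <- s_frac > 1 / 3 & s_frac < 2 / 3
    handedness * ifelse(mid, 1.5 * pi / (length_px / 3), 0)
  }
}

## Grayscale frame from a mask (uses current RNG state for noise).
grayscale_frame <- function(mask, fg, bg, noise_sd) {
  g <- matrix(bg, nrow(mask), ncol(mask))
  g[mask] <- fg
  if (noise_sd > 0) {
    g <- g + matrix(rnorm(length(g), 0, noise_sd), nrow(mask))
  }
  matrix(as.integer(pmin(pmax(round(g), 0L), 255L)), nrow(mask))
}
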