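# Fixtures are built in code: small masks with known closed-form
# moments, plus brute-force oracles used to cross-check the fast paths.

disk_mask <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  outer(1:n, 1:n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

rect_mask <- function(nr_fg, nc_fg, pad = 3) {
  m <- matrix(FALSE, nr_fg + 2 * pad, nc_fg + 2 * pad)
  m[pad + seq_len(nr_fg), pad + seq_len(nc_fg)] <- TRUE
  m
}

## Brute-force central moments by an explicit double loop; the
## reference the moment-based ellipse fit must agree with exactly.
brute_force_moments <- function(mask) {
  acc <- c(m00 = 0, m10 = 0, m01 = 0)
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        acc["m00"] <- acc["m00"] + 1
        acc["m10"] <- acc["m10"] + r
        acc["m01"] <- acc["m01"] + c
      }
    }
  }
  mr <- acc[["m10"]] / acc[["m00"]]
  mc <- acc[["m01"]] / acc[["m00"]]
  u <- c(u20 = 0, u02 = 0, u11 = 0)
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        u["u20"] <- u["u20"] + (r - mr)^2
        u["u02"] <- u["u02"] + (c - mc)^2
        u["u11"] <- u["u11"] + (r - mr) * (c - mc)
      }
    }
  }
  c(m00 = acc[["m00"]], centroid_r = mr, centroid_c = mc, u / acc[["m00"]])
}

ellipse_from_moments <- function(u20, u02, u11) {
  tr <- u20 + u02
  l1 <- tr / 2 + sqrt(tr^2 / 4 - (u20 * u02 - u11^2))
  l2 <- tr - l1
  c(a = 2 * sqrt(l1), b = 2 * sqrt(l2), ecc = sqrt(1 - l2 / l1))
}

## A single rendered swim-posture or turn-posture frame for shape tests.
posture_mask <- function(kind = c("straight", "swim", "omega", "reversal"),
                         length_px = 60, halfwidth = 3, canvas = 110,
                         phase = 0, angle = 0) {
  kind <- match.arg(kind)
  n <- ceiling(length_px / 0.5)
  s <- seq(0, 1, length.out = n)
  kap <- switch(kind,
    straight = rep(0, n),
    swim = (9 / length_px) * sin(2 * pi * phase - 2 * pi * 1.5 * s),
    omega = rep(2 * pi * 0.85 / length_px, n),
    reversal = ifelse(s > 1 / 3 & s < 2 / 3, 1.5 * pi / (length_px / 3), 0)
  )
  osmodrop:::render_worm_mask(
    osmodrop:::worm_midline(kap, length_px, angle),
    halfwidth, canvas, canvas
  )
}

## Assemble a tiny grayscale frame_stack from masks.
stack_from_masks <- function(masks, frame_rate_hz = 10, fg = 200, bg = 30) {
  frames <- lapply(masks, function(m) {
    g <- matrix(bg, nrow(m), ncol(m)); g[m] <- fg; g
  })
  frame_stack(frames, frame_rate_hz = frame_rate_hz)
}
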