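#' Fit the equivalent ellipse of a mask
#'
#' The core vision primitive of the droplet assay. From the central
#' second moments of the foreground pixels, builds the normalized
#' covariance
#' \deqn{C = \frac{1}{\mu_{00}}\begin{pmatrix}\mu_{20} & \mu_{11}\\
#'   \mu_{11} & \mu_{02}\end{pmatrix}}
#' with eigenvalues \eqn{\lambda_1 \ge \lambda_2}, and reports the
#' ellipse with the same mass distribution: semi-axes
#' \eqn{a = 2\sqrt{\lambda_1}}, \eqn{b = 2\sqrt{\lambda_2}},
#' eccentricity \eqn{e = \sqrt{1 - \lambda_2/\lambda_1}}. A disk gives
#' \eqn{e = 0}; an elongated swimming worm gives \eqn{e} near 1, and a
#' curled (turning) worm a markedly lower value.
#'
#' @param mask Logical matrix (or 0/1) from [segment_frame()], or a
#'   non-negative weight matrix when `weighted = TRUE` (grayscale-
#'   weighted moments).
#' @param weighted If `TRUE`, treat `mask` as pixel weights instead of a
#'   binary mask.
#' @return A one-row tibble: `centroid_r`, `centroid_c`, `a`, `b`,
#'   `orientation` (radians in (-pi/2, pi/2], major axis vs. the column
#'   axis), `eccentricity`, `area` (foreground pixel count, or total
#'   weight).
#' @export
#' @examples
#' disk <- outer(1:101, 1:101, function(r, c) (r - 51)^2 + (c - 51)^2 <= 50^2)
#' fit_equivalent_ellipse(disk)$eccentricity  # ~0
fit_equivalent_ellipse <- function(mask, weighted = FALSE) {
  v <- fit_ellipse_vec(mask, weighted = weighted)
  tibble::as_tibble(as.list(v))
}

## Fast path: the same computation returning a named numeric vector
## (used per frame inside compute_shape_metrics).
fit_ellipse_vec <- function(mask, weighted = FALSE) {
  w <- if (weighted) as.numeric(mask) else as.numeric(mask != 0)
  idx <- which(w > 0)
  if (length(idx) == 0) {
    stop_osmodrop("empty mask", "osmodrop_empty_mask")
  }
  nr <- nrow(mask)
  r <- ((idx - 1) %% nr) + 1
  c <- ((idx - 1) %/% nr) + 1
  wi <- w[idx]
  m00 <- sum(wi)
  mr <- sum(wi * r) / m00
  mc <- sum(wi * c) / m00
  u20 <- sum(wi * (r - mr)^2) / m00
  u02 <- sum(wi * (c - mc)^2) / m00
  u11 <- sum(wi * (r - mr) * (c - mc)) / m00
  tr <- u20 + u02
  dt <- u20 * u02 - u11^2
  disc <- max(tr^2 / 4 - dt, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr - l1
  if (l1 <= 0 || l2 <= 1e-12) {
    stop_osmodrop("degenerate mask (single pixel or collinear)",
                  "osmodrop_degenerate_shape")
  }
  ## principal eigenvector half-angle, major axis vs. the column axis
  ori <- 0.5 * atan2(2 * u11, u02 - u20)
  if (ori <= -pi / 2) ori <- ori + pi
  if (ori > pi / 2) ori <- ori - pi
  c(centroid_r = mr, centroid_c = mc,
    a = 2 * sqrt(l1), b = 2 * sqrt(l2),
    orientation = ori,
    eccentricity = sqrt(1 - l2 / l1),
    area = m00)
}

#' Per-frame shape metrics for a stack
#'
#' Segments each frame and fits the equivalent ellipse, producing the
#' per-frame metrics table that drives turn calling and thrash
#' counting. Frames where the worm cannot be segmented (or the shape is
#' degenerate) are flagged (`flagged = TRUE`, metrics `NA`) rather than
#' dropped.
#'
#' @param stack A [frame_stack()].
#' @param masks Optional precomputed list of masks (from an earlier
#'   segmentation pass); `NULL` entries mark flagged frames.
#' @inheritParams segment_frame
#' @param weighted Use grayscale-weighted moments (the frame itself as
#'   weights inside the mask) instead of binary-mask moments.
#' @return A tibble with one row per frame: `frame`, `time_s`, the
#'   [fit_equivalent_ellipse()] columns (area scaled by the stack's
#'   pixel size squared), and `flagged`.
#' @export
compute_shape_metrics <- function(stack, masks = NULL,
                                  policy = "otsu", threshold = NULL,
                                  min_area = 30, weighted = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(masks)) {
    masks <- segment_stack(stack, policy = policy, threshold = threshold,
                           min_area = min_area)
  }
  n <- length(stack)
  times <- frame_times(stack)
  empty <- c(centroid_r = NA_real_, centroid_c = NA_real_, a = NA_real_,
             b = NA_real_, orientation = NA_real_, eccentricity = NA_real_,
             area = NA_real_)
  rows <- vapply(seq_len(n), function(i) {
    m <- masks[[i]]
    if (is.null(m)) return(empty)
    inp <- if (weighted) get_frame(stack, i) * m else m
    tryCatch(fit_ellipse_vec(inp, weighted = weighted),
             osmodrop_degenerate_shape = function(e) empty)
  }, empty)
  out <- as.data.frame(t(rows))
  out$area <- out$area * stack$pixel_size^2
  res <- cbind(data.frame(frame = seq_len(n), time_s = times), out)
  res$flagged <- is.na(out$eccentricity)
  tibble::as_tibble(res)
}
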