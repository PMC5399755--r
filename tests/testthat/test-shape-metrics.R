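test_that("equivalent ellipse matches closed forms for disk and rectangle", {
  disk <- disk_mask(50)
  fd <- fit_equivalent_ellipse(disk)
  expect_lte(fd$eccentricity, 0.05)
  ## 200 x 50 rectangle: lambda ~ side^2, e = sqrt(1 - 1/16)
  rect <- rect_mask(50, 200)
  fr <- fit_equivalent_ellipse(rect)
  expect_equal(fr$eccentricity, sqrt(1 - 1 / 16), tolerance = 0.01)
  expect_equal(fr$a / fr$b, 4, tolerance = 0.01)
  expect_equal(abs(fr$orientation), 0, tolerance = 1e-9) # major axis = cols
})

test_that("moments agree exactly with a brute-force double loop", {
  masks <- list(
    disk_mask(8), rect_mask(5, 17),
    posture_mask("swim", length_px = 20, halfwidth = 1.5, canvas = 36),
    matrix(runif(40 * 40) > 0.6, 40, 40)
  )
  for (m in masks) {
    bf <- brute_force_moments(m)
    f <- fit_equivalent_ellipse(m)
    expect_identical(f$area, bf[["m00"]])
    expect_equal(f$centroid_r, bf[["centroid_r"]], tolerance = 1e-12)
    expect_equal(f$centroid_c, bf[["centroid_c"]], tolerance = 1e-12)
    ref <- ellipse_from_moments(bf[["u20"]], bf[["u02"]], bf[["u11"]])
    expect_equal(f$a, ref[["a"]], tolerance = 1e-12)
    expect_equal(f$b, ref[["b"]], tolerance = 1e-12)
    expect_equal(f$eccentricity, ref[["ecc"]], tolerance = 1e-12)
  }
})

test_that("eccentricity agrees with an independent image-moments oracle", {
  ## EBImage computes ellipse eccentricity from the same moment
  ## definition; the two implementations must agree on rendered worms.
  for (kind in c("swim", "omega")) {
    m <- posture_mask(kind)
    f <- fit_equivalent_ellipse(m)
    ref <- EBImage::computeFeatures.moment(m * 1)
    expect_equal(f$eccentricity, unname(ref[1, "m.eccentricity"]),
                 tolerance = 1e-6)
  }
})

test_that("eccentricity is invariant under rotation and translation", {
  eccs <- vapply(seq(0, pi, length.out = 8), function(ang) {
    fit_equivalent_ellipse(posture_mask("swim", angle = ang))$eccentricity
  }, numeric(1))
  expect_lt(max(eccs) - min(eccs), 0.01)
  ## translation: pad a mask asymmetrically
  m <- posture_mask("swim")
  shifted <- m[c(10:nrow(m), 1:9), c(5:ncol(m), 1:4)]
  expect_equal(fit_equivalent_ellipse(shifted)$eccentricity,
               fit_equivalent_ellipse(m)$eccentricity, tolerance = 1e-9)
})

test_that("axes scale linearly and area quadratically with mask scale", {
  small <- disk_mask(20)
  large <- disk_mask(40)
  fs <- fit_equivalent_ellipse(small)
  fl <- fit_equivalent_ellipse(large)
  expect_equal(fl$a / fs$a, 2, tolerance = 0.01)
  expect_equal(fl$b / fs$b, 2, tolerance = 0.01)
  expect_equal(fl$area / fs$area, 4, tolerance = 0.01)
})

test_that("turn postures depress eccentricity below swim postures", {
  swim_ecc <- vapply(seq(0, 0.45, by = 0.05), function(ph) {
    fit_equivalent_ellipse(posture_mask("swim", phase = ph))$eccentricity
  }, numeric(1))
  omega_ecc <- fit_equivalent_ellipse(posture_mask("omega"))$eccentricity
  rev_ecc <- fit_equivalent_ellipse(posture_mask("reversal"))$eccentricity
  expect_true(all(omega_ecc < swim_ecc))
  expect_true(all(rev_ecc < swim_ecc))
})

test_that("degenerate masks raise a degenerate-shape error", {
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_error(fit_equivalent_ellipse(single), class =
                 "osmodrop_degenerate_shape")
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_error(fit_equivalent_ellipse(line), class =
                 "osmodrop_degenerate_shape")
  empty <- matrix(FALSE, 9, 9)
  expect_error(fit_equivalent_ellipse(empty), class = "osmodrop_empty_mask")
})

test_that("segmentation recovers the rendered worm and ignores speckle", {
  sim <- simulate_swim_video(swim_sim_params(
    duration_s = 1, turn_rate_fn = constant_rate_fn(0), seed = 9))
  fr <- osmodrop:::get_frame(sim$stack, 1)
  mask <- segment_frame(fr)
  expect_lt(abs(sum(mask) - sim$truth$true_area_px[1]) /
              sim$truth$true_area_px[1], 0.02)
  ## speckle: bright dot away from the worm is excluded by the
  ## largest-component rule
  fr2 <- fr
  fr2[2:3, 2:3] <- 250
  mask2 <- segment_frame(fr2)
  expect_false(any(mask2[2:3, 2:3]))
  ## all-background frame
  flat <- matrix(30, 64, 64)
  expect_error(segment_frame(flat), class = "osmodrop_empty_mask")
  ## fixed-threshold policy on background noise: nothing crosses
  noise_only <- matrix(30 + rnorm(64 * 64, 0, 2), 64, 64)
  expect_error(segment_frame(noise_only, policy = "fixed", threshold = 120),
               class = "osmodrop_empty_mask")
})

test_that("flagged frames are reported, not dropped", {
  sim <- simulate_swim_video(swim_sim_params(
    duration_s = 1, turn_rate_fn = constant_rate_fn(0), seed = 10))
  frames <- sim$stack$frames
  frames[, , 4] <- 30L # lost worm in frame 4
  stack <- frame_stack(frames, 10)
  met <- compute_shape_metrics(stack)
  expect_equal(nrow(met), 10)
  expect_true(met$flagged[4])
  expect_true(is.na(met$eccentricity[4]))
  expect_false(any(met$flagged[-4]))
})

test_that("body area measurement matches pi r^2 and the truth ratio", {
  disk <- disk_mask(50)
  expect_equal(measure_body_area(disk), pi * 50^2, tolerance = 0.01)
  expect_equal(measure_body_area(disk, pixel_size = 2), 4 * pi * 50^2,
               tolerance = 0.01)
  expect_error(measure_body_area(matrix(FALSE, 5, 5)),
               class = "osmodrop_empty_mask")
  ## measured (segmented) pre/post ratio tracks the generating parameter
  dh <- simulate_dehydration_pair(0.776, n_images = 3, seed = 6)
  ratio <- vapply(1:3, function(i) {
    a_pre <- measure_body_area(segment_frame(osmodrop:::get_frame(dh$pre, i)))
    a_post <- measure_body_area(segment_frame(osmodrop:::get_frame(dh$post, i)))
    a_post / a_pre
  }, numeric(1))
  expect_equal(mean(ratio), 0.776, tolerance = 0.015 / 0.776)
})

test_that("blind renaming is seeded, reversible, and non-constant", {
  files <- sprintf("cond%s_worm%d.tif", rep(c("A", "B"), each = 3), 1:3)
  r1 <- blind_rename(files, seed = 42)
  r2 <- blind_rename(files, seed = 42)
  expect_identical(r1$blinded, r2$blinded)
  expect_identical(r1$mapping, r2$mapping)
  ## no condition information leaks into the blinded names
  expect_false(any(grepl("cond", basename(r1$blinded))))
  ## round trip
  expect_identical(unblind(r1$mapping, r1$mapping$blinded),
                   r1$mapping$original)
  expect_error(unblind(r1$mapping, "nope.tif"), "unknown")
  ## permutations vary across seeds
  perms <- vapply(1:100, function(s) {
    paste(blind_rename(files, seed = s)$mapping$original, collapse = "|")
  }, character(1))
  expect_gt(length(unique(perms)), 10)
  expect_error(blind_rename(c("a.tif", "a.tif"), 1), "unique")
})
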