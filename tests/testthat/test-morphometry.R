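# small helpers to build analytic masks directly
disk_mask <- function(r_mm, h, pad_px = 5) {
  R <- r_mm / h
  n <- 2 * (ceiling(R) + pad_px) + 1
  cx <- (n + 1) / 2 - 0.5
  xs <- matrix(seq_len(n) - 0.5 - cx, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5 - cx, n, n)
  xs^2 + ys^2 <= R^2
}

ellipse_mask <- function(a_mm, b_mm, h, angle_deg = 0, pad_px = 5) {
  A <- a_mm / h; B <- b_mm / h
  n <- 2 * (ceiling(A) + pad_px) + 1
  cx <- (n + 1) / 2 - 0.5
  xs <- matrix(seq_len(n) - 0.5 - cx, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5 - cx, n, n)
  th <- angle_deg * pi / 180
  u <- xs * sin(th) + ys * cos(th)
  v <- xs * cos(th) - ys * sin(th)
  (u / A)^2 + (v / B)^2 <= 1
}

test_that("calibration resolves explicit and two-point scales", {
  img <- matrix(0, 5, 5)
  cal <- calibrate(img, mm_per_pixel = 0.05)
  expect_equal(cal$mm_per_pixel, 0.05)
  cal2 <- calibrate(img, points = rbind(c(0, 0), c(100, 0)),
                    distance_mm = 5)
  expect_equal(cal2$mm_per_pixel, 0.05)
  expect_error(calibrate(img, points = rbind(c(3, 3), c(3, 3)),
                         distance_mm = 5), "coincide")
  expect_error(calibrate(img, mm_per_pixel = -1), "positive")
  expect_error(calibrate(img), "calibration error")
})

test_that("grayscale conversion uses Rec.601 weights and normalizes", {
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- c(255, 255, 255)
  rgb[2, 2, ] <- c(255, 0, 0)
  g_raw <- to_grayscale(rgb, normalize = FALSE)
  expect_equal(g_raw[1, 1], 255)
  expect_equal(g_raw[2, 2], 0.299 * 255)
  g <- to_grayscale(rgb)
  expect_equal(g[1, 1], 1)
  expect_equal(g[2, 2], 0.299)
  expect_equal(min(g), 0)
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("thresholding implements the 40%-of-white rule", {
  expect_warning(threshold_lesion(matrix(0.5, 4, 4), 0.40),
                 "all foreground")
  # linear rim ramp 0 -> 1 over 20 px: boundary at the 40% isoline +/- 1 px
  ramp <- matrix(rep(seq(0, 1, length.out = 20), each = 5), 5, 20,
                 byrow = FALSE)
  mask <- suppressWarnings(threshold_lesion(ramp, 0.40))
  first_fg <- min(which(mask[1, ]))
  analytic <- 0.40 * 19 + 1  # column where the ramp crosses 0.40
  expect_lt(abs(first_fg - analytic), 1)
  expect_error(threshold_lesion(ramp, 1.2), "in \\(0, 1\\)")
})

test_that("threshold monotonicity: higher cutoff never increases area", {
  set.seed(21)
  sp <- lesion_spec("oval", 4, 2.5, ovality = 0.4, center_mm = c(10, 10),
                    border_width_mm = 1)
  fr <- generate_top_view(list(sp), 0.05, noise_sd = 6, seed = 9,
                          width_px = 400, height_px = 400)
  gray <- to_grayscale(fr$image)
  areas <- vapply(seq(0.2, 0.8, by = 0.05), function(cc)
    sum(suppressWarnings(threshold_lesion(gray, cc))), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("hole filling matches a border flood-fill oracle and is
           idempotent", {
  # annulus -> solid disk (inner disk removed on the same pixel grid)
  outer <- disk_mask(3, 0.05)
  n <- nrow(outer)
  cx <- (n + 1) / 2 - 0.5
  xs <- matrix(seq_len(n) - 0.5 - cx, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5 - cx, n, n)
  ann <- outer & !(xs^2 + ys^2 <= (1.5 / 0.05)^2)
  filled <- fill_holes(ann)
  expect_equal(sum(filled), sum(outer))
  # solid ellipse unchanged
  ell <- ellipse_mask(4, 2, 0.1)
  expect_equal(fill_holes(ell), ell)
  # nested holes and random blobs against the flood-fill oracle
  set.seed(13)
  for (i in 1:10) {
    m <- random_blob_mask(60, 60)
    m[30:32, 30:32] <- FALSE
    m[10:11, 10] <- FALSE
    expect_equal(fill_holes(m), oracle_fill_holes(m))
  }
  # idempotence
  f1 <- fill_holes(ann)
  expect_equal(fill_holes(f1), f1)
})

test_that("region measurement matches closed forms for disks and
           ellipses", {
  reg <- measure_region(disk_mask(3, 0.05), 0.05)
  expect_equal(reg$area_mm2, pi * 9, tolerance = 0.01)
  expect_lt(reg$major_axis_mm / reg$minor_axis_mm, 1.02)
  reg2 <- measure_region(ellipse_mask(4, 2, 0.05), 0.05)
  expect_equal(reg2$major_axis_mm, 8, tolerance = 0.02)
  expect_equal(reg2$minor_axis_mm, 4, tolerance = 0.02)
  expect_equal(reg2$orientation_deg, 0, tolerance = 1)
  # single pixel
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  reg3 <- measure_region(one, 0.05)
  expect_equal(reg3$area_mm2, 0.0025)
  expect_gt(reg3$minor_axis_mm, 0)
  # component-count errors
  two <- matrix(FALSE, 8, 8); two[2, 2] <- TRUE; two[7, 7] <- TRUE
  expect_error(measure_region(two, 0.05), "found 2")
  expect_error(measure_region(matrix(FALSE, 4, 4), 0.05), "found 0")
})

test_that("region moments agree with the per-pixel brute-force oracle", {
  set.seed(17)
  sizes <- c(rep(60, 6), rep(120, 3), 200)
  for (n in sizes) {
    m <- fill_holes(random_blob_mask(n, n))
    h <- 0.05
    reg <- measure_region(m, h)
    o <- oracle_mask_moments(m, h)
    expect_equal(reg$area_mm2, o$area_mm2, tolerance = 1e-12)
    expect_equal(reg$centroid_mm, o$centroid_mm, tolerance = 1e-9)
    expect_equal(reg$major_axis_mm, o$major_mm, tolerance = 1e-9)
    expect_equal(reg$minor_axis_mm, o$minor_mm, tolerance = 1e-9)
  }
})

test_that("major-axis alignment verticalizes, preserves area and is
           idempotent", {
  reg <- measure_region(ellipse_mask(4, 2, 0.05, angle_deg = 37), 0.05)
  expect_equal(abs(reg$orientation_deg), 37, tolerance = 1)
  al <- align_major_axis(reg)
  expect_lt(abs(al$orientation_deg), 1)
  expect_lt(abs(al$area_mm2 - reg$area_mm2) / reg$area_mm2, 0.01)
  expect_lt(max(abs(al$centroid_mm / al$mm_per_pixel -
                    dim(al$mask) / 2)) , 2)
  # second application is a no-op within tolerance
  al2 <- align_major_axis(al)
  expect_lt(abs(al2$area_mm2 - al$area_mm2) / al$area_mm2, 0.01)
  expect_lt(abs(al2$orientation_deg), 1)
  # circles pass through essentially unchanged
  circ <- measure_region(disk_mask(3, 0.05), 0.05)
  alc <- align_major_axis(circ)
  expect_lt(abs(alc$area_mm2 - circ$area_mm2) / circ$area_mm2, 0.01)
})

test_that("segmentation finds, filters and orders lesions", {
  centers <- list(c(8, 8), c(24, 8), c(40, 8), c(8, 26), c(24, 26),
                  c(40, 26))
  specs <- lapply(centers, function(cc)
    lesion_spec("circle", 2.5, 2.5, center_mm = cc, border_width_mm = 0))
  fr <- generate_top_view(specs, 0.05, 0, 1, width_px = 960,
                          height_px = 680)
  subs <- segment_lesions(calibrate(fr))
  expect_length(subs, 6)
  # ordering: centroid row first, then column
  offs <- t(vapply(subs, function(s) attr(s, "offset_px"), c(row = 0,
                                                             col = 0)))
  expect_true(all(diff(offs[1:3, "col"]) > 0))
  expect_true(all(offs[4:6, "row"] > offs[1:3, "row"]))

  # a 0.2 mm^2 speck is filtered out at min_area 1 mm^2
  speck <- lesion_spec("circle", 0.25, 0.25, center_mm = c(30, 17),
                       border_width_mm = 0)
  fr2 <- generate_top_view(list(speck), 0.05, 0, 1, width_px = 960,
                           height_px = 680)
  expect_length(
    suppressMessages(segment_lesions(calibrate(fr2), min_area_mm2 = 1)), 0)

  # touching lesions merge into one sub-image (documented limitation)
  m1 <- disk_mask(2, 0.05, pad_px = 50)
  m2 <- matrix(FALSE, nrow(m1), ncol(m1))
  shift <- 79  # just under one diameter: overlapping disks
  m2[, seq_len(ncol(m1) - shift) + shift] <-
    m1[, seq_len(ncol(m1) - shift)]
  merged <- m1 | m2
  lab <- EBImage::bwlabel(matrix(as.numeric(merged), nrow(merged)))
  expect_equal(max(lab), 1)  # connected-component oracle on the composition
  img <- matrix(60, nrow(merged), ncol(merged))
  img[merged] <- 230
  cal <- calibrate(img, mm_per_pixel = 0.05)
  expect_length(segment_lesions(cal), 1)
})

test_that("depth measurement recovers ground truth on bisected views", {
  sp <- lesion_spec("circle", 3, 3, depth_mm = 5, border_width_mm = 0)
  fr <- generate_bisected_view(sp, 0.05, 0, 1, width_px = 400,
                               height_px = 400)
  d <- measure_depth(calibrate(fr))
  expect_equal(d$max_depth_mm, 5, tolerance = 0.1 / 5)
  expect_equal(d$surface_row_mm, 6, tolerance = 0.06 / 6)

  # deepest published condition as generator target
  sp2 <- lesion_spec("circle", 3, 3, depth_mm = 7.53, border_width_mm = 0)
  fr2 <- generate_bisected_view(sp2, 0.05, 0, 1, width_px = 400,
                                height_px = 400)
  expect_equal(measure_depth(calibrate(fr2))$max_depth_mm, 7.53,
               tolerance = 0.1 / 7.53)

  # lesion entirely above the detectable surface -> depth 0 with warning
  img <- matrix(5, 200, 200)
  img[150:199, ] <- 60            # tissue far below
  img[20:40, 90:110] <- 230       # bright blob above the surface
  cal <- calibrate(img, mm_per_pixel = 0.05, view = "bisected")
  expect_warning(d0 <- measure_depth(cal), "depth 0")
  expect_equal(d0$max_depth_mm, 0)
})

test_that("morphology classes recover the generator's shape families", {
  mk <- function(cls, a, b, ov) {
    sp <- lesion_spec(cls, a, b, ovality = ov, center_mm = c(10, 10),
                      border_width_mm = 0)
    fr <- generate_top_view(list(sp), 0.05, 0, 1, width_px = 400,
                            height_px = 400)
    measure_top_view(calibrate(fr))[[1]]
  }
  expect_identical(mk("circle", 3, 3, 0)$shape_class, "circle")
  expect_identical(mk("ellipse", 4, 2, 0)$shape_class, "ellipse")
  oval <- mk("oval", 4, 2.5, 0.4)
  expect_identical(oval$shape_class, "oval")
  # analytic half-area asymmetry of the egg curve is 2*ovality/(3*pi)
  asym <- lesionmorph:::.half_area_asymmetry(oval$mask)
  expect_equal(asym, 2 * 0.4 / (3 * pi), tolerance = 0.15)
})

test_that("replicate summaries give exact moments and a registered mean
           mask", {
  reg <- measure_region(disk_mask(2, 0.05), 0.05)
  s <- summarize_replicates(list(reg, reg, reg))
  expect_equal(s$sd_area_mm2, 0)
  expect_equal(s$mean_area_mm2, reg$area_mm2)
  expect_true(all(s$mean_mask %in% c(0, 1)))
  # areas {10, 20} -> mean 15, sd 7.071
  r10 <- measure_region(disk_mask(sqrt(10 / pi), 0.02), 0.02)
  r20 <- measure_region(disk_mask(sqrt(20 / pi), 0.02), 0.02)
  s2 <- summarize_replicates(list(r10, r20))
  expect_equal(s2$mean_area_mm2, 15, tolerance = 0.01)
  expect_equal(s2$sd_area_mm2, sqrt(50), tolerance = 0.05)
  expect_true(all(s2$mean_mask >= 0 & s2$mean_mask <= 1))
  expect_error(summarize_replicates(list()), "no regions")
})

test_that("measured mm-unit area is stable across rasterization scales", {
  sp <- lesion_spec("oval", 4, 2.5, ovality = 0.4, center_mm = c(10, 10),
                    border_width_mm = 0)
  a1 <- measure_top_view(calibrate(generate_top_view(
    list(sp), 0.05, 0, 1, width_px = 400, height_px = 400)))[[1]]$area_mm2
  a2 <- measure_top_view(calibrate(generate_top_view(
    list(sp), 0.025, 0, 1, width_px = 800, height_px = 800)))[[1]]$area_mm2
  expect_lt(abs(a1 - a2) / a2, 0.02)
})
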