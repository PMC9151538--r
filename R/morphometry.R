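# The lesion image-analysis pipeline: calibrate -> segment -> grayscale ->
# threshold at 40% of white -> fill holes -> region moments -> align the
# major axis vertical -> classify morphology; depth from bisected views.
#
# Coordinate convention: row 1 is the image top, y increases downward;
# pixel (r, c) has centre ((c - 0.5) h, (r - 0.5) h) in mm for scale h.
# A pixel belongs to the region whose membership test its centre passes.

#' Calibrate a raster image to millimetres
#'
#' Attaches a mm-per-pixel scale either explicitly or from two annotated
#' points a known distance apart. Pixel data are not modified.
#'
#' @param image 2-D intensity matrix (or HxWx3 array) in 0..255 or 0..1
#' @param mm_per_pixel explicit positive scale, or \code{NULL}
#' @param points 2x2 matrix of two (col, row) pixel positions, used with
#'   \code{distance_mm} when \code{mm_per_pixel} is \code{NULL}
#' @param distance_mm known separation of the two points in mm
#' @param view \code{"top"} or \code{"bisected"}
#' @return a \code{calibrated_image}: \code{pixels}, \code{mm_per_pixel},
#'   \code{view}
#' @examples
#' img <- matrix(0, 10, 10)
#' calibrate(img, points = rbind(c(0, 0), c(100, 0)), distance_mm = 5)
#' @export
calibrate <- function(image, mm_per_pixel = NULL, points = NULL,
                      distance_mm = NULL, view = c("top", "bisected")) {
  view <- match.arg(view)
  if (inherits(image, "synthetic_frame")) {
    return(structure(list(pixels = image$image,
                          mm_per_pixel = image$mm_per_pixel,
                          view = image$view),
                     class = "calibrated_image"))
  }
  if (is.null(mm_per_pixel)) {
    if (is.null(points) || is.null(distance_mm))
      stop("calibration error: supply mm_per_pixel or two points with a ",
           "known mm separation", call. = FALSE)
    stopifnot(is.matrix(points), nrow(points) == 2)
    px <- sqrt(sum((points[1, ] - points[2, ])^2))
    if (px == 0)
      stop("calibration error: the two annotated points coincide",
           call. = FALSE)
    if (!is.numeric(distance_mm) || distance_mm <= 0)
      stop("calibration error: distance_mm must be positive", call. = FALSE)
    mm_per_pixel <- distance_mm / px
  }
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1 ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("calibration error: mm_per_pixel must be a positive number",
         call. = FALSE)
  structure(list(pixels = image, mm_per_pixel = mm_per_pixel, view = view),
            class = "calibrated_image")
}

#' Convert an image to normalized grayscale
#'
#' 3-channel input is reduced with Rec.601 luminance weights
#' (0.299, 0.587, 0.114); the result is divided by its maximum so white
#' maps to 1. Normalization by the frame maximum makes the subsequent
#' 40\%-of-white threshold exposure-invariant.
#'
#' @param image 2-D matrix or HxWx3 array, any non-negative intensity scale
#' @param normalize divide by the maximum (default \code{TRUE})
#' @return matrix of intensities; in [0, 1] when normalized
#' @export
to_grayscale <- function(image, normalize = TRUE) {
  if (inherits(image, "calibrated_image")) image <- image$pixels
  if (is.null(dim(image)) || length(image) == 0)
    stop("empty image", call. = FALSE)
  if (length(dim(image)) == 3) {
    stopifnot(dim(image)[3] >= 3)
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
             0.114 * image[, , 3]
  }
  stopifnot(is.matrix(image))
  if (normalize) {
    mx <- max(image)
    if (mx <= 0) stop("cannot normalize an all-black image", call. = FALSE)
    image <- image / mx
  }
  image
}

#' Threshold a grayscale lesion image at a white-concentration cutoff
#'
#' Foreground (lesion) is every pixel whose normalized intensity is at
#' least \code{concentration} of the white level; the default 0.40
#' operationalizes the 40\%-of-white rule used to resolve the graded
#' reversible-injury rim into lesion vs normal tissue.
#'
#' @param gray intensity matrix in [0, 1] (see \code{\link{to_grayscale}})
#' @param concentration cutoff fraction in (0, 1)
#' @return logical matrix (TRUE = lesion); warns when the result is all
#'   foreground or all background
#' @export
threshold_lesion <- function(gray, concentration = 0.40) {
  stopifnot(is.matrix(gray), is.numeric(concentration),
            length(concentration) == 1)
  if (concentration <= 0 || concentration >= 1)
    stop("concentration must lie in (0, 1)", call. = FALSE)
  mask <- gray >= concentration
  if (all(mask) || !any(mask))
    warning("degenerate segmentation: mask is all ",
            if (all(mask)) "foreground" else "background", call. = FALSE)
  mask
}

#' Fill enclosed background holes in a binary mask
#'
#' Every background component not connected to the image border becomes
#' foreground; foreground never shrinks. Idempotent.
#'
#' @param mask logical (or 0/1) matrix
#' @return logical matrix
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::fillHull(m) > 0.5
}

#' Segment candidate lesions from a calibrated top-view frame
#'
#' Thresholds the whole frame, labels 8-connected components, drops
#' components smaller than \code{min_area_mm2}, and returns one padded
#' sub-image (original intensities) per surviving component, ordered by
#' centroid row then centroid column.
#'
#' @param frame a \code{calibrated_image} with \code{view = "top"}
#' @param concentration threshold fraction passed to
#'   \code{\link{threshold_lesion}}
#' @param min_area_mm2 minimum component area to keep (mm^2)
#' @param pad_px padding around each component crop (pixels)
#' @return list of \code{calibrated_image} sub-images (possibly empty),
#'   each with an \code{offset_px} attribute giving its (row, col) origin
#' @export
segment_lesions <- function(frame, concentration = 0.40, min_area_mm2 = 1,
                            pad_px = 10L) {
  stopifnot(inherits(frame, "calibrated_image"))
  if (frame$view != "top")
    stop("segment_lesions expects a top view", call. = FALSE)
  h <- frame$mm_per_pixel
  gray <- to_grayscale(frame$pixels)
  mask <- suppressWarnings(threshold_lesion(gray, concentration))
  if (!any(mask)) {
    message("segment_lesions: no candidate regions found")
    return(list())
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * h^2 >= min_area_mm2)
  if (length(keep) == 0) {
    message("segment_lesions: all candidate regions below min_area_mm2")
    return(list())
  }
  info <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    list(k = k,
         cr = mean(idx[, 1]), cc = mean(idx[, 2]),
         r1 = min(idx[, 1]), r2 = max(idx[, 1]),
         c1 = min(idx[, 2]), c2 = max(idx[, 2]))
  })
  ord <- order(vapply(info, `[[`, 0, "cr"), vapply(info, `[[`, 0, "cc"))
  lapply(info[ord], function(b) {
    r1 <- max(1L, b$r1 - pad_px); r2 <- min(nrow(gray), b$r2 + pad_px)
    c1 <- max(1L, b$c1 - pad_px); c2 <- min(ncol(gray), b$c2 + pad_px)
    sub <- structure(list(pixels = frame$pixels[r1:r2, c1:c2],
                          mm_per_pixel = h, view = "top"),
                     class = "calibrated_image")
    attr(sub, "offset_px") <- c(row = r1, col = c1)
    sub
  })
}

# central moments of a mask: returns list(n, centroid_px, cov_px)
# cov includes the 1/12 pixel-extent term so single pixels have finite axes
.mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  x <- idx[, 2] - 0.5
  y <- idx[, 1] - 0.5
  cx <- mean(x); cy <- mean(y)
  sxx <- mean((x - cx)^2) + 1 / 12
  syy <- mean((y - cy)^2) + 1 / 12
  sxy <- mean((x - cx) * (y - cy))
  list(n = n, centroid_px = c(x = cx, y = cy),
       cov_px = matrix(c(sxx, sxy, sxy, syy), 2, 2))
}

#' Measure a single-lesion binary mask
#'
#' Computes calibrated region descriptors from the mask's second central
#' moments: area (pixel count times scale squared), centroid, and the
#' ellipse-equivalent full major/minor axis lengths (4 times the square
#' roots of the covariance eigenvalues; the covariance includes the 1/12
#' per-pixel extent term). Orientation is the major-axis angle from
#' vertical in (-90, 90].
#'
#' @param mask logical matrix containing exactly one 8-connected foreground
#'   component
#' @param mm_per_pixel positive scale
#' @return a \code{lesion_region}: \code{mask}, \code{mm_per_pixel},
#'   \code{centroid_mm}, \code{major_axis_mm}, \code{minor_axis_mm},
#'   \code{orientation_deg}, \code{area_mm2}, \code{shape_class}
#' @export
measure_region <- function(mask, mm_per_pixel) {
  stopifnot(is.matrix(mask), mm_per_pixel > 0)
  mask <- mask > 0
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  ncomp <- max(lab)
  if (ncomp != 1)
    stop("measure_region expects exactly one connected component, found ",
         ncomp, call. = FALSE)
  mo <- .mask_moments(mask)
  e <- eigen(mo$cov_px, symmetric = TRUE)
  major <- 4 * sqrt(e$values[1]) * mm_per_pixel
  minor <- 4 * sqrt(e$values[2]) * mm_per_pixel
  v <- e$vectors[, 1]  # (x, y) components of the major axis
  ang <- atan2(v[1], v[2]) * 180 / pi  # from vertical (y, downward)
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  structure(list(mask = mask, mm_per_pixel = mm_per_pixel,
                 centroid_mm = unname(mo$centroid_px * mm_per_pixel),
                 major_axis_mm = major, minor_axis_mm = minor,
                 orientation_deg = ang,
                 area_mm2 = mo$n * mm_per_pixel^2,
                 shape_class = "unclassified"),
            class = "lesion_region")
}

#' @export
print.lesion_region <- function(x, ...) {
  cat(sprintf(paste0("<lesion_region> area %.2f mm^2, axes %.2f x %.2f mm, ",
                     "orientation %.1f deg, class %s\n"),
              x$area_mm2, x$major_axis_mm, x$minor_axis_mm,
              x$orientation_deg, x$shape_class))
  invisible(x)
}

# Rotate a binary mask by angle_deg (major-axis-from-vertical convention)
# about its centroid onto a square canvas large enough to hold any
# rotation; nearest-neighbour sampling keeps the mask binary.
.rotate_mask <- function(mask, angle_deg, centroid_px) {
  H <- nrow(mask); W <- ncol(mask)
  D <- as.integer(ceiling(sqrt(H^2 + W^2))) + 4L
  cc <- D / 2
  th <- angle_deg * pi / 180
  xo <- matrix(seq_len(D) - 0.5 - cc, D, D, byrow = TRUE)
  yo <- matrix(seq_len(D) - 0.5 - cc, D, D)
  # source position: the output vertical axis maps onto the original major
  # axis (at th from vertical), so rotate output offsets by +th
  xs <- centroid_px["x"] + xo * cos(th) + yo * sin(th)
  ys <- centroid_px["y"] - xo * sin(th) + yo * cos(th)
  ci <- as.integer(floor(xs)) + 1L
  ri <- as.integer(floor(ys)) + 1L
  ok <- ri >= 1L & ri <= H & ci >= 1L & ci <= W
  out <- matrix(FALSE, D, D)
  out[ok] <- mask[cbind(ri[ok], ci[ok])]
  out
}

#' Rotate a lesion region so its major axis is vertical
#'
#' Rotates the mask about its centroid by minus the measured orientation
#' (nearest-neighbour resampling, so the mask stays binary), fills any
#' resampling pinholes, and re-measures. Area is preserved to within the
#' interpolation tolerance (about 1\%).
#'
#' @param region a \code{lesion_region}
#' @return an aligned \code{lesion_region} with orientation near 0
#' @export
align_major_axis <- function(region) {
  stopifnot(inherits(region, "lesion_region"))
  if (abs(region$orientation_deg) < 1e-6) return(region)
  cen <- region$centroid_mm / region$mm_per_pixel
  names(cen) <- c("x", "y")
  rot <- .rotate_mask(region$mask, region$orientation_deg, cen)
  rot <- fill_holes(rot)
  # nearest-neighbour resampling can shed single-pixel fragments from a
  # ragged boundary; keep the dominant component
  lab <- EBImage::bwlabel(matrix(as.numeric(rot), nrow(rot)))
  if (max(lab) > 1) {
    counts <- tabulate(lab[lab > 0])
    rot <- matrix(lab == which.max(counts), nrow(rot))
  }
  out <- measure_region(rot, region$mm_per_pixel)
  out$shape_class <- region$shape_class
  out
}

#' Measure lesion depth on a calibrated bisected view
#'
#' The tissue surface row is the median, over columns in the lateral
#' window, of the first row whose normalized intensity reaches
#' \code{tissue_threshold} (tissue and lesion are both brighter than the
#' background above the cut surface). The lesion mask is the
#' \code{concentration} threshold of the same grayscale image, and maximum
#' depth is the full pixel extent from the surface row to the deepest
#' lesion row: \code{(max_row - surface_row + 1) * mm_per_pixel}.
#'
#' @param frame a \code{calibrated_image} with \code{view = "bisected"}
#' @param concentration lesion threshold fraction (default 0.40)
#' @param tissue_threshold tissue/background contrast threshold on
#'   normalized intensity (default 0.15)
#' @param lateral_window optional integer range of columns used for the
#'   surface estimate (default: all columns containing tissue)
#' @return a \code{depth_measurement}: \code{surface_row_mm},
#'   \code{max_depth_mm}; depth 0 with a warning when no lesion pixel lies
#'   below the surface
#' @export
measure_depth <- function(frame, concentration = 0.40,
                          tissue_threshold = 0.15, lateral_window = NULL) {
  stopifnot(inherits(frame, "calibrated_image"))
  if (frame$view != "bisected")
    stop("measure_depth expects a bisected view", call. = FALSE)
  h <- frame$mm_per_pixel
  gray <- to_grayscale(frame$pixels)
  tissue <- gray >= tissue_threshold
  cols <- if (is.null(lateral_window)) which(colSums(tissue) > 0)
          else intersect(lateral_window, seq_len(ncol(gray)))
  if (length(cols) == 0)
    stop("no tissue found in the lateral window", call. = FALSE)
  first_row <- vapply(cols, function(j) which(tissue[, j])[1], 0)
  surface_row <- stats::median(first_row, na.rm = TRUE)
  lesion <- fill_holes(suppressWarnings(
    threshold_lesion(gray, concentration)))
  rows <- which(rowSums(lesion) > 0)
  rows <- rows[rows >= surface_row]
  if (length(rows) == 0) {
    warning("no lesion foreground below the tissue surface; depth 0",
            call. = FALSE)
    depth <- 0
  } else {
    depth <- (max(rows) - surface_row + 1) * h
  }
  structure(list(surface_row_mm = (surface_row - 1) * h,
                 max_depth_mm = depth),
            class = "depth_measurement")
}

#' Classify lesion morphology from an aligned region
#'
#' Decision rule on the aligned (major-axis-vertical) mask: axis ratio at
#' most 1.15 is a \code{"circle"}; otherwise a relative area asymmetry of
#' at least 0.05 between the halves above and below the midpoint of the
#' region's vertical extent is an \code{"oval"} (egg shape); otherwise an
#' \code{"ellipse"}.
#'
#' @param region an aligned \code{lesion_region}
#' @return the region with \code{shape_class} set
#' @export
classify_morphology <- function(region) {
  stopifnot(inherits(region, "lesion_region"))
  ratio <- region$major_axis_mm / region$minor_axis_mm
  if (ratio <= 1.15) {
    region$shape_class <- "circle"
    return(region)
  }
  asym <- .half_area_asymmetry(region$mask)
  region$shape_class <- if (asym >= 0.05) "oval" else "ellipse"
  region
}

# |area above - area below| / total, split at the midpoint of the
# region's vertical extent (for the analytic egg curve with ovality o the
# value is 2 o / (3 pi); a symmetric ellipse gives 0). The split is at
# the extent midpoint rather than the centroid because the egg's centroid
# shifts toward its wide end, which would mask the asymmetry.
.half_area_asymmetry <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - 0.5
  mid <- (min(idx[, 1]) - 1 + max(idx[, 1])) / 2
  top <- sum(y < mid)
  bot <- sum(y > mid)
  abs(top - bot) / nrow(idx)
}

#' Summarize replicate lesion measurements
#'
#' Mean and sample SD (n - 1 denominator) of area and depth across
#' replicates, plus the average lesion morphology: the pixelwise mean of
#' the centroid-registered aligned masks on a common canvas.
#'
#' @param regions list of aligned \code{lesion_region}s (n >= 1)
#' @param depths optional list of \code{depth_measurement}s, same length
#' @return a \code{replicate_summary}: \code{n}, \code{mean_area_mm2},
#'   \code{sd_area_mm2}, \code{mean_depth_mm}, \code{sd_depth_mm},
#'   \code{mean_mask} (values in [0, 1])
#' @export
summarize_replicates <- function(regions, depths = NULL) {
  if (length(regions) == 0) stop("no regions to summarize", call. = FALSE)
  stopifnot(all(vapply(regions, inherits, TRUE, "lesion_region")))
  n <- length(regions)
  areas <- vapply(regions, `[[`, 0, "area_mm2")
  mean_depth <- sd_depth <- NA_real_
  if (!is.null(depths)) {
    stopifnot(length(depths) == n)
    dd <- vapply(depths, `[[`, 0, "max_depth_mm")
    mean_depth <- mean(dd)
    sd_depth <- if (n > 1) stats::sd(dd) else 0
  }
  # centroid-registered average morphology
  half_h <- max(vapply(regions, function(r) {
    cy <- r$centroid_mm[2] / r$mm_per_pixel
    max(cy, nrow(r$mask) - cy)
  }, 0))
  half_w <- max(vapply(regions, function(r) {
    cx <- r$centroid_mm[1] / r$mm_per_pixel
    max(cx, ncol(r$mask) - cx)
  }, 0))
  H <- 2L * as.integer(ceiling(half_h)) + 1L
  W <- 2L * as.integer(ceiling(half_w)) + 1L
  acc <- matrix(0, H, W)
  for (r in regions) {
    cy <- r$centroid_mm[2] / r$mm_per_pixel
    cx <- r$centroid_mm[1] / r$mm_per_pixel
    r0 <- as.integer(round((H + 1) / 2 - cy))
    c0 <- as.integer(round((W + 1) / 2 - cx))
    rows <- seq_len(nrow(r$mask)) + r0
    cols <- seq_len(ncol(r$mask)) + c0
    acc[rows, cols] <- acc[rows, cols] + r$mask
  }
  structure(list(n = n,
                 mean_area_mm2 = mean(areas),
                 sd_area_mm2 = if (n > 1) stats::sd(areas) else 0,
                 mean_depth_mm = mean_depth,
                 sd_depth_mm = sd_depth,
                 mean_mask = acc / n),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> n = %d: area %.2f +/- %.2f mm^2",
              x$n, x$mean_area_mm2, x$sd_area_mm2))
  if (is.finite(x$mean_depth_mm))
    cat(sprintf(", depth %.2f +/- %.2f mm", x$mean_depth_mm, x$sd_depth_mm))
  cat("\n")
  invisible(x)
}

#' Run the full top-view pipeline on one calibrated frame
#'
#' Segments the frame, then for each lesion: grayscale, threshold, hole
#' fill, region measurement, major-axis alignment and morphology
#' classification.
#'
#' @inheritParams segment_lesions
#' @return list of classified, aligned \code{lesion_region}s
#' @export
measure_top_view <- function(frame, concentration = 0.40,
                             min_area_mm2 = 1) {
  subs <- segment_lesions(frame, concentration, min_area_mm2)
  lapply(subs, function(s) {
    gray <- to_grayscale(s$pixels)
    mask <- fill_holes(suppressWarnings(
      threshold_lesion(gray, concentration)))
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
    # padding can admit fragments of neighbours; keep the largest component
    if (max(lab) > 1) {
      counts <- tabulate(lab[lab > 0])
      mask <- lab == which.max(counts)
    }
    classify_morphology(align_major_axis(
      measure_region(mask, s$mm_per_pixel)))
  })
}
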