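# Synthetic lesion photographs with known ground truth.
#
# Intensity model (8-bit): tissue background 60, lesion core 230, with a
# linear "reversible injury" ramp of width border_width_mm centred on the
# true lesion boundary; in bisected views the region above the tissue
# surface renders near-black (5). Additive Gaussian read noise, clamped.

.BG_TISSUE <- 60
.LESION_CORE <- 230
.BG_ABOVE_SURFACE <- 5

#' Ground-truth specification of one synthetic lesion
#'
#' Parameterizes a quasi-elliptical lesion footprint. Shape families:
#' \itemize{
#'   \item \code{"ellipse"}: standard ellipse, semi-axes \code{semi_major_mm}
#'     >= \code{semi_minor_mm}.
#'   \item \code{"oval"}: egg curve -- an ellipse whose transverse half-width
#'     varies linearly along the major axis, \eqn{b(u) = b (1 + o u / 2a)}
#'     for \eqn{u \in [-a, a]} with ovality \eqn{o}; its area is still
#'     \eqn{\pi a b} (the linear term integrates out).
#'   \item \code{"circle"}: axis ratio <= 1.05 and ovality 0.
#' }
#'
#' @param shape_class \code{"ellipse"}, \code{"oval"} or \code{"circle"}
#' @param semi_major_mm,semi_minor_mm half-axis lengths (mm), major >= minor
#' @param ovality asymmetry factor in [0, 0.6]; 0 for ellipse/circle
#' @param center_mm length-2 (x, y) position in the frame (mm; y downward)
#' @param orientation_deg major-axis angle from vertical (degrees)
#' @param border_width_mm width of the graded reversible-injury rim (mm)
#' @param depth_mm maximum lesion depth for the bisected view (mm), or NA
#' @return a \code{lesion_spec}
#' @export
lesion_spec <- function(shape_class = c("ellipse", "oval", "circle"),
                        semi_major_mm, semi_minor_mm,
                        ovality = 0, center_mm = c(0, 0),
                        orientation_deg = 0, border_width_mm = 0.3,
                        depth_mm = NA_real_) {
  shape_class <- match.arg(shape_class)
  stopifnot(is.numeric(semi_major_mm), is.numeric(semi_minor_mm),
            length(center_mm) == 2, ovality >= 0, ovality <= 0.6,
            border_width_mm >= 0)
  if (!(semi_major_mm >= semi_minor_mm && semi_minor_mm > 0))
    stop("require semi_major_mm >= semi_minor_mm > 0", call. = FALSE)
  if (shape_class == "circle" &&
      (semi_major_mm / semi_minor_mm > 1.05 || ovality != 0))
    stop("circle requires axis ratio <= 1.05 and ovality 0", call. = FALSE)
  if (shape_class %in% c("ellipse", "circle") && ovality != 0)
    stop("ovality must be 0 unless shape_class is 'oval'", call. = FALSE)
  structure(list(shape_class = shape_class,
                 semi_major_mm = semi_major_mm,
                 semi_minor_mm = semi_minor_mm,
                 ovality = ovality,
                 center_mm = as.numeric(center_mm),
                 orientation_deg = orientation_deg,
                 border_width_mm = border_width_mm,
                 depth_mm = depth_mm),
            class = "lesion_spec")
}

#' Analytic footprint area of a lesion spec
#'
#' \eqn{\pi a b} for all three shape families (the egg curve's linear width
#' modulation cancels over the full major axis).
#'
#' @param spec a \code{lesion_spec}
#' @return area in mm^2
#' @export
spec_area_mm2 <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  pi * spec$semi_major_mm * spec$semi_minor_mm
}

# Radial shape parameter rho for pixel offsets (dx, dy) in mm from the
# lesion centre: rho <= 1 is inside. Vectorized over dx, dy.
.spec_rho <- function(spec, dx, dy) {
  th <- spec$orientation_deg * pi / 180
  # major-axis unit vector (from vertical): (sin th, cos th) in (x, y-down)
  u <- dx * sin(th) + dy * cos(th)
  v <- dx * cos(th) - dy * sin(th)
  a <- spec$semi_major_mm
  b <- spec$semi_minor_mm * (1 + spec$ovality * u / (2 * a))
  bad <- b <= 0
  b[bad] <- NA_real_
  rho <- sqrt((u / a)^2 + (v / b)^2)
  rho[bad] <- Inf
  rho
}

# Approximate signed distance (mm) to the spec boundary: (rho - 1) times
# the centre-to-boundary distance along the pixel's ray.
.spec_signed_dist <- function(spec, dx, dy) {
  rho <- .spec_rho(spec, dx, dy)
  p <- sqrt(dx^2 + dy^2)
  d <- ifelse(rho > 1e-9, (rho - 1) / rho * p, -spec$semi_minor_mm)
  d[!is.finite(rho)] <- Inf
  d
}

# Rim-aware intensity of one lesion over pixel offsets (mm); background NA.
.spec_intensity <- function(spec, dx, dy) {
  w <- spec$border_width_mm
  d <- .spec_signed_dist(spec, dx, dy)
  if (w == 0) {
    out <- ifelse(d <= 0, .LESION_CORE, NA_real_)
  } else {
    out <- rep(NA_real_, length(d))
    out[d <= -w / 2] <- .LESION_CORE
    ramp <- d > -w / 2 & d < w / 2
    out[ramp] <- .LESION_CORE +
      (.BG_TISSUE - .LESION_CORE) * (d[ramp] + w / 2) / w
  }
  out
}

.new_frame <- function(image, mm_per_pixel, specs, view, seed) {
  structure(list(image = image, mm_per_pixel = mm_per_pixel,
                 specs = specs, view = view, seed = seed),
            class = "synthetic_frame")
}

#' @export
print.synthetic_frame <- function(x, ...) {
  cat(sprintf("<synthetic_frame> %s view, %d x %d px at %g mm/px, %d lesion(s), seed %s\n",
              x$view, nrow(x$image), ncol(x$image), x$mm_per_pixel,
              length(x$specs), format(x$seed)))
  invisible(x)
}

# bounding radius used for overlap / in-frame checks
.spec_radius <- function(spec) {
  spec$semi_major_mm * (1 + spec$ovality / 2) + spec$border_width_mm / 2
}

.check_layout <- function(specs, width_mm, height_mm) {
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    r <- .spec_radius(s)
    c <- s$center_mm
    if (c[1] - r < 0 || c[1] + r > width_mm ||
        c[2] - r < 0 || c[2] + r > height_mm)
      stop("lesion spec ", i, " does not fit inside the frame", call. = FALSE)
  }
  if (length(specs) > 1) {
    for (i in seq_len(length(specs) - 1)) {
      for (j in seq(i + 1, length(specs))) {
        d <- sqrt(sum((specs[[i]]$center_mm - specs[[j]]$center_mm)^2))
        if (d < .spec_radius(specs[[i]]) + .spec_radius(specs[[j]]))
          stop("lesion specs ", i, " and ", j, " overlap", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# pixel-centre coordinate grids (mm) for an H x W frame
.pixel_grid <- function(height_px, width_px, mm_per_pixel) {
  x <- (seq_len(width_px) - 0.5) * mm_per_pixel
  y <- (seq_len(height_px) - 0.5) * mm_per_pixel
  list(x = matrix(x, height_px, width_px, byrow = TRUE),
       y = matrix(y, height_px, width_px))
}

.add_noise_clamp <- function(img, noise_sd, seed) {
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed,
             stats::rnorm(length(img), sd = noise_sd))
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  matrix(img, nrow = nrow(img))
}

#' Render a synthetic top-view lesion photograph
#'
#' Lesion interiors are near-white on a darker tissue background, with a
#' linear intensity ramp of width \code{border_width_mm} (the reversible
#' injury rim) centred on the true boundary, plus additive Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param specs list of \code{lesion_spec}; footprints must lie inside the
#'   frame and must not overlap
#' @param mm_per_pixel scale (mm per pixel side)
#' @param noise_sd Gaussian noise SD in 8-bit intensity units
#' @param seed integer seed for the noise
#' @param width_px,height_px frame size in pixels
#' @return a \code{synthetic_frame} (8-bit grayscale matrix, rows = image
#'   rows top-down) carrying the specs as ground truth
#' @export
generate_top_view <- function(specs, mm_per_pixel = 0.05, noise_sd = 0,
                              seed = 1L, width_px = 1200L,
                              height_px = 800L) {
  if (inherits(specs, "lesion_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, mm_per_pixel > 0, noise_sd >= 0)
  .check_layout(specs, width_px * mm_per_pixel, height_px * mm_per_pixel)
  g <- .pixel_grid(height_px, width_px, mm_per_pixel)
  img <- matrix(.BG_TISSUE, height_px, width_px)
  for (s in specs) {
    v <- .spec_intensity(s, g$x - s$center_mm[1], g$y - s$center_mm[2])
    keep <- !is.na(v)
    img[keep] <- pmax(img[keep], v[keep])
  }
  img <- .add_noise_clamp(img, noise_sd, seed)
  .new_frame(img, mm_per_pixel, specs, "top", seed)
}

#' Render a synthetic bisected-view lesion photograph
#'
#' A horizontal tissue surface with near-black background above it and a
#' bright half-elliptical lesion cross-section extending
#' \code{spec$depth_mm} below the surface, half-width
#' \code{spec$semi_minor_mm} (the cut is through the lesion diameter).
#'
#' @param spec a \code{lesion_spec} with positive \code{depth_mm}
#' @param surface_frac vertical position of the tissue surface as a fraction
#'   of frame height
#' @inheritParams generate_top_view
#' @return a \code{synthetic_frame} with \code{view = "bisected"}
#' @export
generate_bisected_view <- function(spec, mm_per_pixel = 0.05, noise_sd = 0,
                                   seed = 1L, width_px = 1200L,
                                   height_px = 800L, surface_frac = 0.3) {
  stopifnot(inherits(spec, "lesion_spec"), mm_per_pixel > 0, noise_sd >= 0,
            surface_frac > 0, surface_frac < 1)
  if (!is.finite(spec$depth_mm) || spec$depth_mm <= 0)
    stop("bisected view requires a positive depth_mm", call. = FALSE)
  height_mm <- height_px * mm_per_pixel
  width_mm <- width_px * mm_per_pixel
  y_surf <- surface_frac * height_mm
  if (y_surf + spec$depth_mm + spec$border_width_mm / 2 >= height_mm)
    stop("lesion depth exceeds the frame below the surface", call. = FALSE)
  half_w <- spec$semi_minor_mm
  if (half_w + spec$border_width_mm / 2 >= width_mm / 2)
    stop("lesion cross-section exceeds the frame width", call. = FALSE)

  g <- .pixel_grid(height_px, width_px, mm_per_pixel)
  img <- matrix(.BG_ABOVE_SURFACE, height_px, width_px)
  below <- g$y >= y_surf
  img[below] <- .BG_TISSUE
  # half-ellipse cross-section as the lower half of an ellipse centred on
  # the surface line
  xs_spec <- lesion_spec("ellipse",
                         semi_major_mm = max(spec$depth_mm, half_w),
                         semi_minor_mm = min(spec$depth_mm, half_w),
                         orientation_deg = if (spec$depth_mm >= half_w) 0 else 90,
                         border_width_mm = spec$border_width_mm)
  v <- .spec_intensity(xs_spec, g$x - width_mm / 2, g$y - y_surf)
  keep <- !is.na(v) & below
  img[keep] <- pmax(img[keep], v[keep])
  img <- .add_noise_clamp(img, noise_sd, seed)
  gt <- spec
  gt$surface_mm <- y_surf
  .new_frame(img, mm_per_pixel, list(gt), "bisected", seed)
}

# shape family used at each contact angle: parallel contact smears the
# lesion into an ellipse, oblique contact gives an egg-shaped oval,
# perpendicular contact a circle
.angle_shape_class <- function(angle_deg) {
  if (angle_deg == 0) "ellipse" else if (angle_deg == 90) "circle" else "oval"
}

.SHAPE_DEFAULTS <- list(
  ellipse = list(axis_ratio = 2.0, ovality = 0),
  oval    = list(axis_ratio = 1.5, ovality = 0.4),
  circle  = list(axis_ratio = 1.0, ovality = 0)
)

# log-normal multiplicative factor with mean 1 and coefficient of
# variation cv
.lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a replicate panel of synthetic frames for one condition
#'
#' Draws \code{n} replicate lesions whose expected area and depth equal the
#' published cell means for the given (angle, force) condition, with
#' replicate-to-replicate scatter matching the cell coefficients of
#' variation (log-normal area/depth factors; both half-axes share the
#' square-root of the area factor). Shape family follows contact angle:
#' 0 degrees (parallel) gives ellipses, 30/45/60 (oblique) give ovals,
#' 90 (perpendicular) gives circles. Each replicate is rendered as one
#' top-view and one bisected-view frame.
#'
#' @param angle_deg,force_gf condition levels (members of
#'   \code{ANGLE_LEVELS} / \code{FORCE_LEVELS})
#' @param n replicate count (default 6, the study's design)
#' @param seed integer seed; all randomness in the panel derives from it
#' @param mm_per_pixel scale of the rendered frames
#' @param noise_sd Gaussian noise SD (8-bit units)
#' @param border_width_mm reversible-injury rim width
#' @param frame_px side length (pixels) of the square per-replicate frames
#' @param area_table,depth_table condition tables supplying the cell targets
#' @return a \code{condition_panel}: lists \code{top} and \code{bisected}
#'   of \code{synthetic_frame}s, plus the drawn \code{specs}
#' @export
make_condition_panel <- function(angle_deg, force_gf, n = 6L, seed = 1L,
                                 mm_per_pixel = 0.05, noise_sd = 4,
                                 border_width_mm = 0.3, frame_px = 360L,
                                 area_table = load_lesion_area_table(),
                                 depth_table = load_lesion_depth_table()) {
  stopifnot(angle_deg %in% ANGLE_LEVELS, force_gf %in% FORCE_LEVELS, n >= 1)
  acell <- area_table[area_table$angle_deg == angle_deg &
                      area_table$force_gf == force_gf, ]
  dcell <- depth_table[depth_table$angle_deg == angle_deg &
                       depth_table$force_gf == force_gf, ]
  stopifnot(nrow(acell) == 1L, nrow(dcell) == 1L)
  cls <- .angle_shape_class(angle_deg)
  par <- .SHAPE_DEFAULTS[[cls]]

  draws <- withr::with_seed(seed, {
    af <- .lognormal_factor(n, acell$sd / acell$mean)
    df <- .lognormal_factor(n, dcell$sd / dcell$mean)
    or <- stats::runif(n, -45, 45)
    list(area = acell$mean * af, depth = dcell$mean * df, orient = or)
  })

  centre <- rep(frame_px * mm_per_pixel / 2, 2)
  specs <- vector("list", n)
  top <- vector("list", n)
  bis <- vector("list", n)
  for (i in seq_len(n)) {
    a <- sqrt(draws$area[i] * par$axis_ratio / pi)
    b <- a / par$axis_ratio
    specs[[i]] <- lesion_spec(cls, semi_major_mm = a, semi_minor_mm = b,
                              ovality = par$ovality, center_mm = centre,
                              orientation_deg = if (cls == "circle") 0
                                                else draws$orient[i],
                              border_width_mm = border_width_mm,
                              depth_mm = draws$depth[i])
    top[[i]] <- generate_top_view(list(specs[[i]]), mm_per_pixel, noise_sd,
                                  seed = seed + 1000L + i,
                                  width_px = frame_px, height_px = frame_px)
    bis[[i]] <- generate_bisected_view(specs[[i]], mm_per_pixel, noise_sd,
                                       seed = seed + 2000L + i,
                                       width_px = frame_px,
                                       height_px = frame_px)
  }
  structure(list(angle_deg = angle_deg, force_gf = force_gf, n = n,
                 seed = seed, specs = specs, top = top, bisected = bis),
            class = "condition_panel")
}

#' Write / read a synthetic frame as PNG plus JSON sidecar
#'
#' \code{write_frame} stores the 8-bit image as \code{<prefix>.png} and the
#' calibration, seed, view and ground-truth specs as \code{<prefix>.json};
#' \code{read_frame} restores the pair.
#'
#' @param frame a \code{synthetic_frame}
#' @param prefix file path without extension
#' @return \code{write_frame}: the prefix, invisibly; \code{read_frame}: a
#'   \code{synthetic_frame}
#' @export
write_frame <- function(frame, prefix) {
  stopifnot(inherits(frame, "synthetic_frame"))
  png::writePNG(frame$image / 255, paste0(prefix, ".png"))
  side <- list(mm_per_pixel = frame$mm_per_pixel, view = frame$view,
               seed = frame$seed,
               specs = lapply(frame$specs, unclass))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_frame
#' @export
read_frame <- function(prefix) {
  img <- png::readPNG(paste0(prefix, ".png"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  specs <- lapply(side$specs, function(s) {
    s$center_mm <- as.numeric(unlist(s$center_mm))
    extra <- s[setdiff(names(s), c("shape_class", "semi_major_mm",
                                   "semi_minor_mm", "ovality", "center_mm",
                                   "orientation_deg", "border_width_mm",
                                   "depth_mm"))]
    sp <- lesion_spec(s$shape_class, s$semi_major_mm, s$semi_minor_mm,
                      ovality = s$ovality, center_mm = s$center_mm,
                      orientation_deg = s$orientation_deg,
                      border_width_mm = s$border_width_mm,
                      depth_mm = if (is.null(s$depth_mm)) NA_real_
                                 else s$depth_mm)
    sp[names(extra)] <- extra
    sp
  })
  .new_frame(round(img * 255), side$mm_per_pixel, specs, side$view,
             side$seed)
}
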