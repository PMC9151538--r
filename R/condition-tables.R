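# Condition tables: the published angle x force measurement grid.

#' Catheter contact-angle levels (degrees)
#' @export
ANGLE_LEVELS <- c(0, 30, 45, 60, 90)

#' Catheter contact-force levels (gram-force)
#' @export
FORCE_LEVELS <- c(2, 4, 6, 10, 15, 20, 30, 40)

# md5 sums of the shipped fixtures; guards against transcription drift.
.FIXTURE_MD5 <- c(
  lesion_area_mm2.csv = "263ca0d29891188d935c522f60581800",
  lesion_depth_mm.csv = "4c0a1f0cab39ecafb36e04f0eef4fda6",
  area_ratio.csv      = "bdf788688becac128045f9dd597bbf93"
)

.FIXTURE_UNITS <- c(
  lesion_area  = "mm^2",
  lesion_depth = "mm",
  ratio        = "",
  contact_area = "mm^2"
)

new_condition_table <- function(df, quantity_label) {
  stopifnot(is.data.frame(df),
            all(c("angle_deg", "force_gf", "mean") %in% names(df)))
  df <- df[order(df$angle_deg, df$force_gf), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            quantity_label = quantity_label,
            units = unname(.FIXTURE_UNITS[[quantity_label]]),
            class = c("condition_table", "data.frame"))
}

#' Quantity label of a condition table
#' @param x a \code{condition_table}
#' @return one of \code{"lesion_area"}, \code{"lesion_depth"}, \code{"ratio"},
#'   \code{"contact_area"}
#' @export
quantity_label <- function(x) attr(x, "quantity_label")

#' @export
print.condition_table <- function(x, ...) {
  cat(sprintf("<condition_table> %s [%s], %d cells\n",
              quantity_label(x), attr(x, "units"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

.validate_condition_table <- function(df, file, ratio = FALSE) {
  need <- c("angle_deg", "force_gf", "mean", "sd", "n")
  if (!all(need %in% names(df)))
    stop("fixture '", file, "' is corrupt: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  key <- paste(df$angle_deg, df$force_gf)
  full <- paste(rep(ANGLE_LEVELS, each = length(FORCE_LEVELS)),
                rep(FORCE_LEVELS, times = length(ANGLE_LEVELS)))
  if (nrow(df) != 40L || anyDuplicated(key) || !setequal(key, full))
    stop("fixture '", file, "' is corrupt: expected exactly one cell per ",
         "(angle, force) pair over 5 angles x 8 forces", call. = FALSE)
  if (any(!is.finite(df$mean)) || any(df$mean <= 0))
    stop("fixture '", file, "' is corrupt: non-positive or missing means",
         call. = FALSE)
  if (!ratio) {
    if (any(!is.finite(df$sd)) || any(df$sd < 0) || any(df$n < 2))
      stop("fixture '", file, "' is corrupt: invalid sd or n", call. = FALSE)
  }
  invisible(df)
}

.load_fixture <- function(file, quantity_label, ratio = FALSE,
                          verify_checksum = TRUE, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", file, package = "lesionmorph")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged fixture '", file, "' not found", call. = FALSE)
  if (verify_checksum) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.FIXTURE_MD5[[file]])))
      stop("fixture checksum mismatch for '", file,
           "': file content differs from the packaged transcription",
           call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c(
    angle_deg = "numeric", force_gf = "numeric",
    mean = "numeric", sd = "numeric", n = "integer"))
  .validate_condition_table(df, file, ratio = ratio)
  new_condition_table(df, quantity_label)
}

#' Load the published lesion-area grid
#'
#' Mean and standard deviation of ablated lesion area (mm^2) for each of the
#' 40 (contact angle, contact force) conditions, n = 6 replicate ablations per
#' cell.
#'
#' @param verify_checksum verify the fixture's md5 sum before parsing
#'   (default \code{TRUE}); a mismatch is a fatal error.
#' @return a \code{condition_table} with columns \code{angle_deg},
#'   \code{force_gf}, \code{mean}, \code{sd}, \code{n}
#' @export
load_lesion_area_table <- function(verify_checksum = TRUE) {
  .load_fixture("lesion_area_mm2.csv", "lesion_area",
                verify_checksum = verify_checksum)
}

#' Load the published lesion-depth grid
#'
#' Mean and standard deviation of maximum lesion depth (mm) for each of the
#' 40 conditions, n = 6.
#'
#' @inheritParams load_lesion_area_table
#' @return a \code{condition_table}
#' @export
load_lesion_depth_table <- function(verify_checksum = TRUE) {
  .load_fixture("lesion_depth_mm.csv", "lesion_depth",
                verify_checksum = verify_checksum)
}

#' Load the published lesion-area / contact-area ratio grid
#'
#' Dimensionless ratio of ablated lesion area to catheter contact area for
#' each of the 40 conditions (a single printed value per cell; no SD).
#'
#' @inheritParams load_lesion_area_table
#' @return a \code{condition_table}; \code{sd} and \code{n} are \code{NA}
#' @export
load_ratio_table <- function(verify_checksum = TRUE) {
  tbl <- .load_fixture("area_ratio.csv", "ratio", ratio = TRUE,
                       verify_checksum = verify_checksum)
  if (any(tbl$mean <= 0)) stop("ratio table contains non-positive ratios",
                               call. = FALSE)
  tbl
}

#' Recover the catheter contact-area grid
#'
#' The contact area is not published directly, but the lesion-area grid and
#' the lesion-area/contact-area ratio grid are; inverting the ratio gives the
#' contact area per condition:
#' \deqn{X = \bar{Y} / \mathrm{ratio}}
#' where \eqn{\bar{Y}} is the cell-mean lesion area (mm^2). Contact areas are
#' therefore mean-level quantities (ratio of means).
#'
#' @param area lesion-area \code{condition_table} (mm^2)
#' @param ratio ratio \code{condition_table} (dimensionless, all > 0)
#' @return a \code{condition_table} with \code{quantity_label}
#'   \code{"contact_area"} (mm^2); \code{sd}/\code{n} are \code{NA}
#' @examples
#' X <- recover_contact_area_table(load_lesion_area_table(), load_ratio_table())
#' subset(X, angle_deg == 0 & force_gf == 2)  # 16.67 / 1.46 = 11.42 mm^2
#' @export
recover_contact_area_table <- function(area = load_lesion_area_table(),
                                       ratio = load_ratio_table()) {
  stopifnot(inherits(area, "condition_table"),
            inherits(ratio, "condition_table"))
  if (!identical(paste(area$angle_deg, area$force_gf),
                 paste(ratio$angle_deg, ratio$force_gf)))
    stop("area and ratio tables do not cover the same conditions",
         call. = FALSE)
  if (any(!is.finite(ratio$mean)) || any(ratio$mean <= 0))
    stop("all ratios must be positive to invert them", call. = FALSE)
  out <- data.frame(angle_deg = area$angle_deg,
                    force_gf = area$force_gf,
                    mean = area$mean / ratio$mean,
                    sd = NA_real_, n = NA_integer_)
  new_condition_table(out, "contact_area")
}

# Canonical md5 of a parsed table (order-independent of file formatting);
# used by the reporting layer for provenance.
.table_md5 <- function(tbl) {
  s <- paste(tbl$angle_deg, tbl$force_gf, format(tbl$mean, digits = 15),
             format(tbl$sd, digits = 15), tbl$n, sep = ",", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
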