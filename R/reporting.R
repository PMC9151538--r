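# End-to-end runs: simulate panels to disk, measure them back, and
# reproduce the published statistics from the packaged tables.
# These functions are the package's entry points for scripted use.

#' Run configuration for simulation and measurement
#'
#' @param seed integer master seed; recorded in every output
#' @param mm_per_pixel raster scale
#' @param concentration_threshold lesion threshold fraction in (0, 1)
#' @param min_lesion_area_mm2 segmentation size filter
#' @param replicates lesions per condition (default 6)
#' @param noise_sd synthetic read-noise SD (8-bit units)
#' @param frame_px per-replicate frame side (pixels)
#' @param output_dir directory for written artifacts
#' @return a \code{run_config} list
#' @export
run_config <- function(seed = 1L, mm_per_pixel = 0.05,
                       concentration_threshold = 0.40,
                       min_lesion_area_mm2 = 1.0, replicates = 6L,
                       noise_sd = 4, frame_px = 360L,
                       output_dir = tempfile("lesionmorph_run_")) {
  stopifnot(concentration_threshold > 0, concentration_threshold < 1,
            replicates >= 1, mm_per_pixel > 0)
  structure(list(seed = as.integer(seed), mm_per_pixel = mm_per_pixel,
                 concentration_threshold = concentration_threshold,
                 min_lesion_area_mm2 = min_lesion_area_mm2,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 frame_px = as.integer(frame_px), output_dir = output_dir),
            class = "run_config")
}

# deterministic per-condition seed derived from the master seed
.condition_seed <- function(seed, angle_deg, force_gf) {
  as.integer((seed * 1009L + match(angle_deg, ANGLE_LEVELS) * 101L +
                match(force_gf, FORCE_LEVELS)) %% .Machine$integer.max)
}

#' Simulate replicate panels for a set of conditions and write them out
#'
#' For each requested (angle, force) condition, draws a replicate panel
#' (see \code{\link{make_condition_panel}}) and writes each frame as PNG
#' plus JSON sidecar, together with a manifest CSV listing every file with
#' its condition, view, replicate index and ground truth.
#'
#' @param config a \code{\link{run_config}}
#' @param conditions data frame with columns \code{angle_deg},
#'   \code{force_gf}; default all 40 study conditions
#' @return the manifest data frame, invisibly; written to
#'   \code{manifest.csv} in \code{config$output_dir}
#' @export
simulate_panels <- function(config = run_config(),
                            conditions = expand.grid(
                              angle_deg = ANGLE_LEVELS,
                              force_gf = FORCE_LEVELS)) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$output_dir))
    stop("cannot create output directory ", config$output_dir,
         call. = FALSE)
  area_tbl <- load_lesion_area_table()
  depth_tbl <- load_lesion_depth_table()
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    ang <- conditions$angle_deg[i]; frc <- conditions$force_gf[i]
    panel <- make_condition_panel(
      ang, frc, n = config$replicates,
      seed = .condition_seed(config$seed, ang, frc),
      mm_per_pixel = config$mm_per_pixel, noise_sd = config$noise_sd,
      frame_px = config$frame_px,
      area_table = area_tbl, depth_table = depth_tbl)
    for (j in seq_len(config$replicates)) {
      for (view in c("top", "bisected")) {
        fr <- if (view == "top") panel$top[[j]] else panel$bisected[[j]]
        prefix <- file.path(config$output_dir,
                            sprintf("a%02d_f%02d_r%d_%s", ang, frc, j, view))
        write_frame(fr, prefix)
        rows[[length(rows) + 1L]] <- data.frame(
          angle_deg = ang, force_gf = frc, replicate = j, view = view,
          file = paste0(basename(prefix), ".png"),
          seed = fr$seed,
          true_area_mm2 = spec_area_mm2(panel$specs[[j]]),
          true_depth_mm = panel$specs[[j]]$depth_mm)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Measure all simulated frames in a directory
#'
#' Reads every PNG/JSON frame pair named in \code{manifest.csv}, runs the
#' morphometry pipeline (top views: area, axes, class; bisected views:
#' depth), and writes per-lesion results plus per-condition replicate
#' summaries as CSV. Frames whose sidecar is missing are skipped with a
#' warning; if every frame is skipped the call fails.
#'
#' @param input_dir directory produced by \code{\link{simulate_panels}}
#' @param config a \code{\link{run_config}} (threshold and size filter used)
#' @return list with \code{lesions} (one row per lesion) and
#'   \code{summaries} (one row per condition) data frames, invisibly;
#'   written as \code{lesions.csv} / \code{condition_summaries.csv}
#' @export
measure_panels <- function(input_dir, config = run_config()) {
  man_path <- file.path(input_dir, "manifest.csv")
  if (!file.exists(man_path))
    stop("no manifest.csv in ", input_dir, call. = FALSE)
  manifest <- utils::read.csv(man_path)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    prefix <- sub("\\.png$", "", file.path(input_dir, manifest$file[i]))
    if (!file.exists(paste0(prefix, ".json")) ||
        !file.exists(paste0(prefix, ".png"))) {
      warning("skipping frame without calibration sidecar: ",
              manifest$file[i], call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    fr <- read_frame(prefix)
    cal <- calibrate(fr)
    if (fr$view == "top") {
      regs <- measure_top_view(cal, config$concentration_threshold,
                               config$min_lesion_area_mm2)
      for (rg in regs) {
        rows[[length(rows) + 1L]] <- data.frame(
          angle_deg = manifest$angle_deg[i],
          force_gf = manifest$force_gf[i],
          replicate = manifest$replicate[i],
          view = "top", area_mm2 = rg$area_mm2,
          major_mm = rg$major_axis_mm, minor_mm = rg$minor_axis_mm,
          depth_mm = NA_real_, shape_class = rg$shape_class)
      }
    } else {
      dm <- measure_depth(cal, config$concentration_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        angle_deg = manifest$angle_deg[i],
        force_gf = manifest$force_gf[i],
        replicate = manifest$replicate[i],
        view = "bisected", area_mm2 = NA_real_,
        major_mm = NA_real_, minor_mm = NA_real_,
        depth_mm = dm$max_depth_mm, shape_class = NA_character_)
    }
  }
  if (length(rows) == 0)
    stop("no measurable frames in ", input_dir,
         " (", skipped, " skipped)", call. = FALSE)
  lesions <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  key <- interaction(lesions$angle_deg, lesions$force_gf, drop = TRUE)
  summaries <- do.call(rbind, lapply(split(lesions, key), function(d) {
    a <- d$area_mm2[d$view == "top"]
    z <- d$depth_mm[d$view == "bisected"]
    data.frame(angle_deg = d$angle_deg[1], force_gf = d$force_gf[1],
               n = length(a),
               mean_area_mm2 = mean(a), sd_area_mm2 = stats::sd(a),
               mean_depth_mm = mean(z), sd_depth_mm = stats::sd(z))
  }))
  rownames(summaries) <- NULL
  utils::write.csv(lesions, file.path(input_dir, "lesions.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries,
                   file.path(input_dir, "condition_summaries.csv"),
                   row.names = FALSE)
  invisible(list(lesions = lesions, summaries = summaries))
}

.report_entry <- function(computed, reference, tol, extra = list()) {
  c(list(computed = computed, reference = reference, tolerance = tol,
         pass = is.finite(computed) && abs(computed - reference) <= tol),
    extra)
}

#' Reproduce the published statistics from the packaged tables
#'
#' Recomputes, from the fixtures alone (no images), the study's headline
#' statistics and flags each against its printed reference value and an
#' explicit tolerance:
#' \itemize{
#'   \item replicate-level Pearson r of force vs lesion area (0.7816) and
#'     force vs lesion depth (0.7807), via the balanced-design identity;
#'   \item condition-level Pearson r and P of angle vs area (-0.3688,
#'     0.0192) and angle vs depth (0.4550, 0.0032);
#'   \item Spearman r_s and P of force vs area ratio (0.1068, 0.5118) and
#'     angle vs area ratio (0.3737, 0.0175);
#'   \item Pearson r of recovered contact area vs lesion area (0.8507);
#'   \item the contact-area log fits X = a ln(Z) + b at 0 and 90 degrees
#'     (a = 2.685; a = 2.693, b = 0.892, R^2 = 0.893);
#'   \item the ratio round trip: recovered contact areas times the printed
#'     ratios reproduce the printed lesion-area means.
#' }
#' Logarithmic-vs-linear model comparisons per angle are included as
#' informational entries (no reference values are asserted for them).
#'
#' @param json_path optional path; when given, the report is also written
#'   as JSON
#' @return a \code{reproduction_report} list with \code{correlations},
#'   \code{fits}, \code{ratio_round_trip}, \code{model_comparisons} and
#'   \code{provenance}
#' @export
reproduce_tables <- function(json_path = NULL) {
  area <- load_lesion_area_table()
  depth <- load_lesion_depth_table()
  ratio <- load_ratio_table()
  contact <- recover_contact_area_table(area, ratio)

  cors <- list(
    force_vs_area = local({
      r <- pearson_balanced_raw(area, "force_gf")
      .report_entry(r$coefficient, 0.7816, 0.005,
                    list(method = "pearson_balanced_raw", n = r$n,
                         p = r$p_two_sided, evans = r$evans_label))
    }),
    force_vs_depth = local({
      r <- pearson_balanced_raw(depth, "force_gf")
      .report_entry(r$coefficient, 0.7807, 0.005,
                    list(method = "pearson_balanced_raw", n = r$n,
                         p = r$p_two_sided, evans = r$evans_label))
    }),
    angle_vs_area = local({
      r <- pearson_test(area$angle_deg, area$mean)
      .report_entry(r$coefficient, -0.3688, 0.001,
                    list(method = "pearson", n = r$n, p = r$p_two_sided,
                         p_reference = 0.0192, evans = r$evans_label))
    }),
    angle_vs_depth = local({
      r <- pearson_test(depth$angle_deg, depth$mean)
      .report_entry(r$coefficient, 0.4550, 0.001,
                    list(method = "pearson", n = r$n, p = r$p_two_sided,
                         p_reference = 0.0032, evans = r$evans_label))
    }),
    force_vs_ratio = local({
      r <- spearman_test(ratio$force_gf, ratio$mean)
      .report_entry(r$coefficient, 0.1068, 0.005,
                    list(method = "spearman", n = r$n, p = r$p_two_sided,
                         p_reference = 0.5118, evans = r$evans_label))
    }),
    angle_vs_ratio = local({
      r <- spearman_test(ratio$angle_deg, ratio$mean)
      .report_entry(r$coefficient, 0.3737, 0.005,
                    list(method = "spearman", n = r$n, p = r$p_two_sided,
                         p_reference = 0.0175, evans = r$evans_label))
    }),
    contact_vs_area = local({
      r <- pearson_test(contact$mean, area$mean)
      .report_entry(r$coefficient, 0.8507, 0.02,
                    list(method = "pearson", n = r$n, p = r$p_two_sided,
                         evans = r$evans_label))
    })
  )

  x0 <- contact[contact$angle_deg == 0, ]
  x90 <- contact[contact$angle_deg == 90, ]
  f0 <- fit_log(x0$force_gf, x0$mean)
  f90 <- fit_log(x90$force_gf, x90$mean)
  fits <- list(
    contact_logfit_0deg = .report_entry(f0$a, 2.685, 0.02,
      list(b = f0$b, r_squared = f0$r_squared, n = f0$n)),
    contact_logfit_90deg_a = .report_entry(f90$a, 2.693, 0.02,
      list(n = f90$n)),
    contact_logfit_90deg_b = .report_entry(f90$b, 0.892, 0.02, list()),
    contact_logfit_90deg_r2 = .report_entry(f90$r_squared, 0.893, 0.02,
                                            list())
  )

  rt <- lesion_contact_ratio(area$mean, contact$mean)
  ratio_rt <- list(max_abs_error = max(abs(rt - ratio$mean)),
                   pass = max(abs(rt - ratio$mean)) < 0.005)

  mc <- lapply(stats::setNames(ANGLE_LEVELS, paste0("deg", ANGLE_LEVELS)),
    function(a) {
      d <- area[area$angle_deg == a, ]
      cmpa <- compare_fits(d$force_gf, d$mean)
      d2 <- depth[depth$angle_deg == a, ]
      cmpd <- compare_fits(d2$force_gf, d2$mean)
      list(area = list(log_r2 = cmpa$log_r2, linear_r2 = cmpa$linear_r2,
                       behavior = cmpa$behavior),
           depth = list(log_r2 = cmpd$log_r2, linear_r2 = cmpd$linear_r2,
                        behavior = cmpd$behavior))
    })

  report <- structure(list(
    correlations = cors, fits = fits, ratio_round_trip = ratio_rt,
    model_comparisons = mc,
    provenance = list(
      package_version = as.character(utils::packageVersion("lesionmorph")),
      fixture_md5 = list(lesion_area = .table_md5(area),
                         lesion_depth = .table_md5(depth),
                         ratio = .table_md5(ratio)))),
    class = "reproduction_report")
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reproduction of the published lesion statistics\n")
  cat("-----------------------------------------------\n")
  for (nm in names(x$correlations)) {
    e <- x$correlations[[nm]]
    cat(sprintf("  %-16s %s: %8.4f (ref %8.4f, tol %.3g) %s\n", nm,
                e$method, e$computed, e$reference, e$tolerance,
                if (e$pass) "PASS" else "FAIL"))
  }
  for (nm in names(x$fits)) {
    e <- x$fits[[nm]]
    cat(sprintf("  %-24s %8.4f (ref %8.4f, tol %.3g) %s\n", nm,
                e$computed, e$reference, e$tolerance,
                if (e$pass) "PASS" else "FAIL"))
  }
  cat(sprintf("  ratio round-trip: max |error| = %.4f %s\n",
              x$ratio_round_trip$max_abs_error,
              if (x$ratio_round_trip$pass) "PASS" else "FAIL"))
  invisible(x)
}
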