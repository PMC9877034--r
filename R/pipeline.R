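#' Run the end-to-end screen analysis
#'
#' Executes the full pipeline on disk inputs: calibrate (alpha/beta from
#' single-fluorophore wells) -> quantify (cFRET correction, well
#' aggregation) -> primary scoring, exclusion filters and hit calling ->
#' secondary delta scoring -> Z'-factor QC per plate-replicate, writing
#' versioned CSV/JSON outputs and a run log with all parameters and the
#' exclusion funnel. Deterministic given inputs and config. Any stage
#' failure aborts with the stage name.
#'
#' Outputs written to \code{config$out_dir}: \code{coefficients.json},
#' \code{wells.csv}, \code{primary_screen.csv},
#' \code{secondary_screen.csv}, \code{qc.json} (Z' per plate-replicate
#' plus every threshold), \code{run_log.txt}.
#'
#' @param config a [pipeline_config()], or a path to one (YAML/JSON).
#' @param coeffs optional precomputed \code{spectral_coefficients};
#'   required when the config carries no calibration inputs.
#' @return invisibly, a list with \code{coeffs}, \code{wells},
#'   \code{primary}, \code{secondary}, \code{zprime} (data.frame per
#'   plate-replicate), \code{funnel}.
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' cfg <- sim_config(n_compounds = 160, seed = 9)
#' scr <- gen_screen_dataset(cfg)
#' cal <- gen_calibration_cells(cfg, n_rois = 60)
#' write_roi_table(scr$roi, file.path(dir, "roi.csv"))
#' write_plate_map(scr$platemap, file.path(dir, "platemap.csv"))
#' write_roi_table(cal$roi, file.path(dir, "cal_roi.csv"))
#' write_plate_map(cal$platemap, file.path(dir, "cal_platemap.csv"))
#' pc <- pipeline_config(file.path(dir, "roi.csv"),
#'                       file.path(dir, "platemap.csv"),
#'                       file.path(dir, "cal_roi.csv"),
#'                       file.path(dir, "cal_platemap.csv"),
#'                       out_dir = file.path(dir, "out"))
#' res <- run_screen_pipeline(pc)
#' res$funnel
#' }
#' @export
run_screen_pipeline <- function(config, coeffs = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  roi <- stage("read_inputs", read_roi_table(config$roi_csv))
  platemap <- stage("read_inputs", read_plate_map(config$platemap_csv))

  if (is.null(coeffs)) {
    if (is.null(config$calibration_roi_csv)) {
      stop("pipeline stage `calibrate` failed: no calibration inputs in ",
           "config and no precomputed coefficients supplied", call. = FALSE)
    }
    cal_roi <- stage("calibrate", read_roi_table(config$calibration_roi_csv))
    cal_pm <- stage("calibrate", read_plate_map(config$calibration_platemap_csv))
    coeffs <- stage("calibrate", estimate_spectral_coefficients(
      cal_roi, cal_pm, min_rois = config$min_calibration_rois))
  }
  write_coefficients(coeffs, file.path(config$out_dir, "coefficients.json"))

  wells <- stage("quantify", {
    co <- corrected_fret(roi, coeffs)
    aggregate_wells(co, platemap, min_rois = config$min_rois,
                    viability_fraction = config$viability_fraction)
  })
  write.csv(signif_cols(wells), file.path(config$out_dir, "wells.csv"),
            row.names = FALSE, quote = FALSE)

  primary <- stage("score_primary", score_primary(
    wells, hit_threshold = config$hit_threshold,
    diff_threshold = config$diff_threshold,
    viability_fraction = config$viability_fraction))
  write.csv(signif_cols(as.data.frame(primary)),
            file.path(config$out_dir, "primary_screen.csv"),
            row.names = FALSE, quote = FALSE)

  secondary <- stage("score_secondary", score_secondary(wells))
  write.csv(signif_cols(secondary),
            file.path(config$out_dir, "secondary_screen.csv"),
            row.names = FALSE, quote = FALSE)

  zp <- stage("qc_zprime", {
    ctrl <- wells[wells$role %in% c("dmso", "beta_lapachone") &
                    is.finite(wells$mean_cfret_per_donor), , drop = FALSE]
    grp <- split(ctrl, list(ctrl$plate_id, ctrl$replicate), drop = TRUE)
    rows <- lapply(grp, function(g) {
      pos <- g$mean_cfret_per_donor[g$role == "beta_lapachone"]
      neg <- g$mean_cfret_per_donor[g$role == "dmso"]
      z <- z_prime(pos, neg)
      data.frame(plate_id = g$plate_id[1], replicate = g$replicate[1],
                 mu_pos = z$mu_pos, sd_pos = z$sd_pos,
                 mu_neg = z$mu_neg, sd_neg = z$sd_neg,
                 z_prime = z$z_prime)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$replicate, out$plate_id), , drop = FALSE]
  })

  funnel <- attr(primary, "funnel")
  qc <- list(
    thresholds = list(hit_threshold = config$hit_threshold,
                      diff_threshold = config$diff_threshold,
                      viability_fraction = config$viability_fraction,
                      min_rois = config$min_rois,
                      min_calibration_rois = config$min_calibration_rois),
    coefficients = unclass(coeffs),
    z_prime = zp,
    funnel = as.list(funnel),
    seed = config$seed,
    version = config$version
  )
  jsonlite::write_json(qc, file.path(config$out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  log_lines <- c(
    paste0("fretscreen ", config$version, " screen analysis"),
    paste0("inputs: roi=", config$roi_csv, " platemap=", config$platemap_csv),
    sprintf("coefficients: alpha=%.6g beta=%.6g", coeffs$alpha, coeffs$beta),
    sprintf("thresholds: hit>%.6g, replicate diff>%.6g excluded, viability<%.6g excluded, min_rois=%d",
            config$hit_threshold, config$diff_threshold,
            config$viability_fraction, config$min_rois),
    sprintf("funnel: scored=%d above_threshold=%d excluded_replicate=%d excluded_cytotoxic=%d hits=%d",
            funnel[["scored"]], funnel[["above_threshold"]],
            funnel[["excluded_replicate"]], funnel[["excluded_cytotoxic"]],
            funnel[["hits"]]),
    sprintf("median plate Z' = %.4g", stats::median(zp$z_prime))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(coeffs = coeffs, wells = wells, primary = primary,
                 secondary = secondary, zprime = zp, funnel = funnel))
}
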