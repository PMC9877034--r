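#' @importFrom utils read.csv write.csv packageVersion
NULL

plate_roles <- c("dmso", "beta_lapachone", "test", "donor_only",
                 "acceptor_only")

# All floats in written tables carry 6 significant digits.
signif_cols <- function(df, digits = 6L) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Read and validate a ROI intensity table
#'
#' Long-format CSV with one row per quantified ROI: columns
#' \code{plate_id}, \code{well}, \code{roi}, \code{donor},
#' \code{acceptor}, \code{rawfret} and optionally \code{cell_count}.
#' Duplicate (plate_id, well, roi) keys and non-finite intensities are
#' rejected.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_roi_table <- function(path) {
  roi <- read.csv(path, stringsAsFactors = FALSE)
  check_roi_table(roi)
}

#' @rdname read_roi_table
#' @param roi ROI data.frame to write.
#' @export
write_roi_table <- function(roi, path) {
  check_roi_table(roi)
  write.csv(signif_cols(roi), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a plate map
#'
#' CSV with columns \code{plate_id}, \code{well}, \code{compound_id},
#' \code{role}, \code{concentration_um}, \code{replicate}. Roles must be
#' one of dmso, beta_lapachone, test, donor_only, acceptor_only; an
#' unknown role is reported with its row number.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_plate_map <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "compound_id", "role")
  miss <- setdiff(need, names(pm))
  if (length(miss)) {
    stop("plate map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!pm$role %in% plate_roles)
  if (length(bad)) {
    stop("plate map row ", bad[1], ": unknown role \"", pm$role[bad[1]],
         "\" (allowed: ", paste(plate_roles, collapse = ", "), ")",
         call. = FALSE)
  }
  dup <- which(duplicated(paste(pm$plate_id, pm$well)))
  if (length(dup)) {
    stop("plate map row ", dup[1], ": duplicate (plate_id, well) entry",
         call. = FALSE)
  }
  pm
}

#' @rdname read_plate_map
#' @param platemap plate-map data.frame to write.
#' @export
write_plate_map <- function(platemap, path) {
  write.csv(signif_cols(platemap), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read spectral coefficients as JSON
#'
#' @param coeffs a \code{spectral_coefficients} object (or compatible
#'   list).
#' @param path JSON path.
#' @return \code{path} invisibly (writer); a
#'   \code{spectral_coefficients} object (reader).
#' @export
write_coefficients <- function(coeffs, path) {
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "spectral_coefficients")
}

#' Pipeline configuration
#'
#' Bundles the file paths, thresholds and options of an end-to-end screen
#' analysis. Thresholds default to the assay's published rules (hit score
#' > 0.6, replicate difference > 0.15 excluded). The config
#' round-trips losslessly through YAML or JSON.
#'
#' @param roi_csv,platemap_csv screen ROI table and plate map paths.
#' @param calibration_roi_csv,calibration_platemap_csv single-fluorophore
#'   calibration inputs; omit (NULL) to pass precomputed coefficients to
#'   [run_screen_pipeline()].
#' @param out_dir output directory.
#' @param hit_threshold,diff_threshold,viability_fraction,min_rois,min_calibration_rois
#'   analysis thresholds (see [score_primary()], [aggregate_wells()],
#'   [estimate_alpha()]).
#' @param seed integer seed recorded in outputs.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(roi_csv, platemap_csv,
                            calibration_roi_csv = NULL,
                            calibration_platemap_csv = NULL,
                            out_dir = ".",
                            hit_threshold = 0.6,
                            diff_threshold = 0.15,
                            viability_fraction = 0.5,
                            min_rois = 6L,
                            min_calibration_rois = 20L,
                            seed = 1L) {
  structure(list(
    roi_csv = roi_csv, platemap_csv = platemap_csv,
    calibration_roi_csv = calibration_roi_csv,
    calibration_platemap_csv = calibration_platemap_csv,
    out_dir = out_dir,
    hit_threshold = hit_threshold, diff_threshold = diff_threshold,
    viability_fraction = viability_fraction,
    min_rois = as.integer(min_rois),
    min_calibration_rois = as.integer(min_calibration_rois),
    seed = as.integer(seed),
    version = as.character(packageVersion("fretscreen"))
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path destination; extension selects YAML (.yml/.yaml) or JSON.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$min_rois <- as.integer(x$min_rois)
  x$min_calibration_rois <- as.integer(x$min_calibration_rois)
  x$seed <- as.integer(x$seed)
  structure(x, class = "pipeline_config")
}
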