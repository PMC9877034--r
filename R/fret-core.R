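#' @importFrom stats lm coef sd t.test setNames residuals
NULL

# Least-squares slope through the origin of y on x, with residual SD.
# Chosen over mean-of-ratios because ROI intensities span orders of
# magnitude and the mixing model is proportional through zero.
origin_slope <- function(x, y) {
  fit <- lm(y ~ 0 + x)
  list(slope = unname(coef(fit)[1]),
       residual_sd = if (length(y) > 1) sqrt(sum(residuals(fit)^2) / (length(y) - 1)) else 0)
}

check_roi_table <- function(roi) {
  need <- c("plate_id", "well", "roi", "donor", "acceptor", "rawfret")
  miss <- setdiff(need, names(roi))
  if (length(miss)) {
    stop("ROI table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(roi[c("donor", "acceptor", "rawfret")], use.names = FALSE)
  if (any(!is.finite(vals))) {
    stop("ROI intensities must be finite", call. = FALSE)
  }
  key <- paste(roi$plate_id, roi$well, roi$roi)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well, roi) keys in ROI table", call. = FALSE)
  }
  invisible(roi)
}

#' Estimate the donor bleed-through coefficient alpha
#'
#' Fits the least-squares slope through the origin of the raw FRET-channel
#' intensity on the donor-channel intensity over ROIs from cells
#' expressing only the donor fluorophore. The slope is the fraction of
#' donor emission detected in the FRET channel (bleed-through).
#'
#' @param donor_only_rois data.frame of donor-only ROIs with columns
#'   \code{donor} and \code{rawfret} (a full ROI table works).
#' @param min_rois minimum calibration ROIs required (default 20).
#' @param background optional named numeric background to subtract from
#'   each channel before fitting (names \code{donor}, \code{fret});
#'   default none.
#' @return list with \code{alpha}, \code{n}, \code{residual_sd}.
#' @examples
#' rois <- data.frame(donor = 100 * (1:25), rawfret = 20 * (1:25))
#' estimate_alpha(rois)$alpha  # 0.2
#' @export
estimate_alpha <- function(donor_only_rois, min_rois = 20L, background = NULL) {
  d <- donor_only_rois$donor
  f <- donor_only_rois$rawfret
  if (!is.null(background)) {
    d <- d - background[["donor"]]
    f <- f - background[["fret"]]
  }
  if (length(d) < min_rois) {
    stop("alpha estimation needs at least ", min_rois,
         " donor-only ROIs (got ", length(d), ")", call. = FALSE)
  }
  if (all(d == 0)) {
    stop("alpha estimation failed: donor signal is identically zero",
         call. = FALSE)
  }
  res <- origin_slope(d, f)
  list(alpha = res$slope, n = length(d), residual_sd = res$residual_sd)
}

#' Estimate the acceptor cross-excitation coefficient beta
#'
#' Symmetric to [estimate_alpha()], with the acceptor channel as the
#' regressor over ROIs from cells expressing only the acceptor
#' fluorophore: the slope is the fraction of FRET-channel signal caused by
#' direct excitation of the acceptor at the donor wavelength.
#'
#' @param acceptor_only_rois data.frame with columns \code{acceptor} and
#'   \code{rawfret}.
#' @inheritParams estimate_alpha
#' @return list with \code{beta}, \code{n}, \code{residual_sd}.
#' @export
estimate_beta <- function(acceptor_only_rois, min_rois = 20L, background = NULL) {
  a <- acceptor_only_rois$acceptor
  f <- acceptor_only_rois$rawfret
  if (!is.null(background)) {
    a <- a - background[["acceptor"]]
    f <- f - background[["fret"]]
  }
  if (length(a) < min_rois) {
    stop("beta estimation needs at least ", min_rois,
         " acceptor-only ROIs (got ", length(a), ")", call. = FALSE)
  }
  if (all(a == 0)) {
    stop("beta estimation failed: acceptor signal is identically zero",
         call. = FALSE)
  }
  res <- origin_slope(a, f)
  list(beta = res$slope, n = length(a), residual_sd = res$residual_sd)
}

#' Estimate both spectral coefficients from a calibration plate
#'
#' Convenience wrapper that splits a ROI table by the plate map's
#' \code{donor_only} / \code{acceptor_only} roles and runs
#' [estimate_alpha()] and [estimate_beta()].
#'
#' @param roi ROI table (plate_id, well, roi, donor, acceptor, rawfret).
#' @param platemap plate map with columns plate_id, well, role.
#' @inheritParams estimate_alpha
#' @return object of class \code{spectral_coefficients}: list with
#'   \code{alpha}, \code{beta}, \code{n_donor_rois}, \code{n_acceptor_rois},
#'   \code{residual_sd_alpha}, \code{residual_sd_beta}.
#' @examples
#' cal <- gen_calibration_cells(sim_config(seed = 2), n_rois = 60)
#' estimate_spectral_coefficients(cal$roi, cal$platemap)
#' @export
estimate_spectral_coefficients <- function(roi, platemap, min_rois = 20L,
                                           background = NULL) {
  check_roi_table(roi)
  key <- paste(roi$plate_id, roi$well)
  pkey <- paste(platemap$plate_id, platemap$well)
  role <- platemap$role[match(key, pkey)]
  a <- estimate_alpha(roi[role %in% "donor_only", , drop = FALSE],
                      min_rois = min_rois, background = background)
  b <- estimate_beta(roi[role %in% "acceptor_only", , drop = FALSE],
                     min_rois = min_rois, background = background)
  structure(
    list(alpha = a$alpha, beta = b$beta,
         n_donor_rois = a$n, n_acceptor_rois = b$n,
         residual_sd_alpha = a$residual_sd, residual_sd_beta = b$residual_sd),
    class = "spectral_coefficients"
  )
}

#' @export
print.spectral_coefficients <- function(x, ...) {
  cat(sprintf("Spectral coefficients: alpha = %.4g (n = %d, resid SD %.3g), beta = %.4g (n = %d, resid SD %.3g)\n",
              x$alpha, x$n_donor_rois, x$residual_sd_alpha,
              x$beta, x$n_acceptor_rois, x$residual_sd_beta))
  invisible(x)
}

#' Corrected FRET per ROI
#'
#' Applies the spectral correction
#' \deqn{cFRET = rawFRET - \alpha \cdot donor - \beta \cdot acceptor}
#' and normalizes by the donor intensity (cFRET/donor). Negative cFRET
#' values are retained, not clipped, so null distributions stay centered.
#' ROIs with donor <= 0 or zero cell count get \code{valid = FALSE} and an
#' undefined ratio — they are excluded from well aggregation rather than
#' silently zeroed.
#'
#' @param roi ROI table; columns donor, acceptor, rawfret (and optionally
#'   plate_id, well, roi, cell_count, carried through).
#' @param coeffs a \code{spectral_coefficients} object, or any list with
#'   finite \code{alpha} and \code{beta}.
#' @param background optional named numeric per-channel constant
#'   background (names donor, acceptor, fret) subtracted before
#'   correction; default none.
#' @return the input data.frame with added columns \code{cfret},
#'   \code{cfret_per_donor} and logical \code{valid}.
#' @examples
#' r <- data.frame(donor = 1000, acceptor = 800, rawfret = 500)
#' corrected_fret(r, list(alpha = 0.2, beta = 0.1))$cfret  # 220
#' @export
corrected_fret <- function(roi, coeffs, background = NULL) {
  if (!is.finite(coeffs$alpha) || !is.finite(coeffs$beta)) {
    stop("spectral coefficients must be finite", call. = FALSE)
  }
  d <- roi$donor
  a <- roi$acceptor
  f <- roi$rawfret
  if (!is.null(background)) {
    d <- d - background[["donor"]]
    a <- a - background[["acceptor"]]
    f <- f - background[["fret"]]
  }
  out <- roi
  out$cfret <- f - coeffs$alpha * d - coeffs$beta * a
  out$valid <- d > 0
  if (!is.null(roi$cell_count)) out$valid <- out$valid & roi$cell_count > 0
  out$cfret_per_donor <- ifelse(d > 0, out$cfret / d, NA_real_)
  out
}

#' Aggregate corrected ROIs to well summaries
#'
#' Computes the mean and standard error of cFRET/donor over the valid
#' ROIs of each well (the assay quantifies 12 ROIs per well). Wells with
#' fewer valid ROIs than \code{min_rois} are flagged
#' \code{low_roi_count}; wells whose mean cell count falls below
#' \code{viability_fraction} of the same plate's DMSO mean cell count are
#' flagged \code{low_cell_count} (requires a plate map with DMSO roles and
#' a cell_count column). Wells with zero valid ROIs are returned with
#' \code{n_rois = 0}, an NA mean and the \code{no_valid_rois} flag.
#'
#' @param corrected output of [corrected_fret()].
#' @param platemap optional plate map (plate_id, well, role, compound_id,
#'   replicate); role/compound/replicate columns are joined onto the
#'   summaries and the DMSO cell-count reference is computed per plate.
#' @param min_rois minimum valid ROIs per well (default 6).
#' @param viability_fraction cell-count fraction of the plate DMSO mean
#'   below which a well is flagged (default 0.5).
#' @return data.frame: plate_id, well (+ platemap columns when given),
#'   mean_cfret_per_donor, se, n_rois, mean_cell_count, qc_flags
#'   (';'-separated, "" when clean).
#' @examples
#' cal <- corrected_fret(
#'   data.frame(plate_id = "P1", well = "A01", roi = 1:3,
#'              donor = c(1000, 1000, 1000), acceptor = 0,
#'              rawfret = c(500, 510, 490)),
#'   list(alpha = 0, beta = 0))
#' aggregate_wells(cal, min_rois = 2)
#' @export
aggregate_wells <- function(corrected, platemap = NULL, min_rois = 6L,
                            viability_fraction = 0.5) {
  stopifnot(all(c("plate_id", "well", "cfret_per_donor", "valid") %in%
                  names(corrected)))
  key <- interaction(corrected$plate_id, corrected$well, drop = TRUE,
                     lex.order = TRUE)
  has_counts <- !is.null(corrected$cell_count)
  rows <- split(seq_len(nrow(corrected)), key)
  res <- lapply(rows, function(idx) {
    sub <- corrected[idx, , drop = FALSE]
    ok <- sub$valid & is.finite(sub$cfret_per_donor)
    vals <- sub$cfret_per_donor[ok]
    n <- length(vals)
    data.frame(
      plate_id = sub$plate_id[1], well = sub$well[1],
      mean_cfret_per_donor = if (n) mean(vals) else NA_real_,
      se = if (n > 1) sd(vals) / sqrt(n) else if (n == 1) 0 else NA_real_,
      n_rois = n,
      mean_cell_count = if (has_counts) mean(sub$cell_count) else NA_real_
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL

  flags <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    fl <- character(0)
    if (out$n_rois[i] == 0) fl <- c(fl, "no_valid_rois")
    else if (out$n_rois[i] < min_rois) fl <- c(fl, "low_roi_count")
    flags[[i]] <- fl
  }

  if (!is.null(platemap)) {
    pkey <- paste(platemap$plate_id, platemap$well)
    m <- match(paste(out$plate_id, out$well), pkey)
    for (col in intersect(c("compound_id", "role", "concentration_um",
                            "replicate"), names(platemap))) {
      out[[col]] <- platemap[[col]][m]
    }
    if (has_counts && "role" %in% names(out)) {
      dmso_ref <- tapply(out$mean_cell_count[out$role %in% "dmso"],
                         out$plate_id[out$role %in% "dmso"], mean)
      ref <- dmso_ref[out$plate_id]
      low <- !is.na(ref) & out$mean_cell_count < viability_fraction * ref
      for (i in which(low)) flags[[i]] <- c(flags[[i]], "low_cell_count")
    }
  }
  out$qc_flags <- vapply(flags, paste, character(1), collapse = ";")
  out
}

#' FRET efficiency from acceptor photobleaching
#'
#' Acceptor photobleaching abolishes energy transfer, dequenching the
#' donor; the apparent FRET efficiency of a region is
#' \eqn{E = 1 - F_{pre} / F_{post}} computed from the donor intensity
#' before and after bleaching. Regions whose acceptor did not actually
#' decrease are flagged (\code{bleached = FALSE}). A paired two-sided
#' Student's t test compares pre- and post-bleach donor intensities.
#'
#' @param pairs data.frame with columns \code{pre_donor},
#'   \code{post_donor}, \code{pre_acceptor}, \code{post_acceptor} (one row
#'   per bleached region; a \code{region} id column is carried through).
#' @return list with \code{regions} (data.frame adding \code{efficiency}
#'   and \code{bleached}), \code{mean_efficiency} (over bleached regions),
#'   and \code{p_value} of the paired t test (NA when donor intensities
#'   are constant).
#' @examples
#' p <- data.frame(pre_donor = c(80, 82), post_donor = c(100, 101),
#'                 pre_acceptor = c(50, 55), post_acceptor = c(5, 6))
#' photobleach_fret_efficiency(p)$regions$efficiency
#' @export
photobleach_fret_efficiency <- function(pairs) {
  need <- c("pre_donor", "post_donor", "pre_acceptor", "post_acceptor")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("photobleach pairs need column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) < 2) {
    stop("need at least 2 paired regions", call. = FALSE)
  }
  if (any(pairs$post_donor <= 0)) {
    stop("post-bleach donor intensities must be > 0", call. = FALSE)
  }
  out <- pairs
  out$efficiency <- 1 - pairs$pre_donor / pairs$post_donor
  out$bleached <- pairs$post_acceptor < pairs$pre_acceptor
  p <- if (sd(pairs$post_donor - pairs$pre_donor) > 0) {
    t.test(pairs$post_donor, pairs$pre_donor, paired = TRUE)$p.value
  } else if (all(pairs$post_donor == pairs$pre_donor)) {
    1
  } else {
    NA_real_
  }
  list(regions = out,
       mean_efficiency = mean(out$efficiency[out$bleached]),
       p_value = p)
}
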