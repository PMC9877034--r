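check_multichannel <- function(image) {
  need <- c("donor", "acceptor", "rawfret")
  miss <- setdiff(need, names(image))
  if (length(miss)) {
    stop("multichannel image needs matrices: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dims <- lapply(image[need], dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("channel matrices must share the same dimensions", call. = FALSE)
  }
  if (any(vapply(image[need], function(m) any(m < 0), logical(1)))) {
    stop("input images must not contain negative pixels", call. = FALSE)
  }
  invisible(image)
}

#' Segment cells from the donor channel of a multichannel image
#'
#' Reference segmentation standing in for the commercial image-analysis
#' step of the assay: the donor channel (expressed constitutively by the
#' cells) is thresholded automatically (Otsu) or at a fixed value,
#' connected foreground components are labeled, components smaller than
#' \code{min_area} pixels are removed, and labels are re-indexed
#' contiguously from 1. Deterministic given the image and parameters. A
#' blank (constant) image yields an empty mask, not an error.
#'
#' @param image list with matrices \code{donor}, \code{acceptor},
#'   \code{rawfret} (as produced by [gen_images()]).
#' @param min_area minimum component area in pixels (default 50).
#' @param threshold_method \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold numeric threshold when \code{threshold_method =
#'   "fixed"}.
#' @return integer label matrix (0 = background, k >= 1 = ROI k).
#' @examples
#' img <- gen_images(sim_config(seed = 4), n_cells = 3)[[1]]
#' max(segment_rois(img))  # 3
#' @export
segment_rois <- function(image, min_area = 50L,
                         threshold_method = c("otsu", "fixed"),
                         threshold = NULL) {
  check_multichannel(image)
  threshold_method <- match.arg(threshold_method)
  donor <- image$donor
  if (threshold_method == "fixed") {
    if (is.null(threshold)) stop("fixed thresholding needs `threshold`",
                                 call. = FALSE)
    thr <- threshold
  } else {
    if (diff(range(donor)) == 0) {
      return(matrix(0L, nrow = nrow(donor), ncol = ncol(donor)))
    }
    thr <- EBImage::otsu(EBImage::Image(donor), range = range(donor),
                         levels = 256L)
  }
  fg <- donor > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  lab <- matrix(as.integer(lab), nrow = nrow(donor))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  relabel <- integer(max(lab, 1L))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow = nrow(lab), ncol = ncol(lab))
  nz <- lab > 0L
  out[nz] <- relabel[lab[nz]]
  out
}

#' Measure per-ROI channel intensities from a label mask
#'
#' Computes, for each label of the mask, the mean intensity of the three
#' channels and the pixel count (\code{cell_area}), yielding a ROI table
#' in the same schema the well-level pipeline consumes.
#'
#' @param mask integer label matrix (0 background).
#' @param image multichannel image, same dimensions as \code{mask}.
#' @param plate_id,well identifiers written into the table.
#' @return data.frame: plate_id, well, roi, donor, acceptor, rawfret,
#'   cell_area, ordered by label.
#' @examples
#' img <- gen_images(sim_config(seed = 4), n_cells = 3)[[1]]
#' measure_rois(img$mask, img)
#' @export
measure_rois <- function(mask, image, plate_id = "IMG01", well = "A01") {
  check_multichannel(image)
  if (!identical(dim(mask), dim(image$donor))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  labels <- sort(unique(mask[mask > 0]))
  if (!length(labels)) {
    return(data.frame(plate_id = character(0), well = character(0),
                      roi = integer(0), donor = numeric(0),
                      acceptor = numeric(0), rawfret = numeric(0),
                      cell_area = integer(0)))
  }
  rows <- lapply(labels, function(k) {
    px <- mask == k
    data.frame(plate_id = plate_id, well = well, roi = as.integer(k),
               donor = mean(image$donor[px]),
               acceptor = mean(image$acceptor[px]),
               rawfret = mean(image$rawfret[px]),
               cell_area = sum(px))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pixelwise corrected-FRET-per-donor map
#'
#' Renders the assay's ratio statistic per pixel:
#' \code{(rawfret - alpha * donor - beta * acceptor) / donor} inside the
#' foreground. Background pixels and pixels whose donor intensity is at
#' or below \code{donor_floor} are set to NA (masked, never divided).
#'
#' @param image multichannel image.
#' @param coeffs list with \code{alpha} and \code{beta}.
#' @param mask optional integer label mask defining the foreground; when
#'   absent the foreground is computed by [segment_rois()] with
#'   \code{min_area = 1}.
#' @param donor_floor minimum donor intensity for a defined ratio
#'   (default 0: any positive donor).
#' @return list with \code{map} (matrix, NA outside the defined
#'   foreground), \code{mean} (mean ratio inside), \code{n_pixels}.
#' @examples
#' img <- gen_images(sim_config(seed = 4, background_sd = 0,
#'                              shot_noise_factor = 0), n_cells = 3)[[1]]
#' fret_efficiency_map(img, list(alpha = 0.2, beta = 0.1), img$mask)$mean
#' @export
fret_efficiency_map <- function(image, coeffs, mask = NULL, donor_floor = 0) {
  check_multichannel(image)
  if (is.null(mask)) mask <- segment_rois(image, min_area = 1L)
  fg <- mask > 0 & image$donor > donor_floor
  map <- matrix(NA_real_, nrow = nrow(image$donor), ncol = ncol(image$donor))
  cf <- image$rawfret - coeffs$alpha * image$donor -
    coeffs$beta * image$acceptor
  map[fg] <- cf[fg] / image$donor[fg]
  vals <- map[fg]
  list(map = map,
       mean = if (length(vals)) mean(vals) else NA_real_,
       n_pixels = sum(fg))
}

# AU intensities are stored in 32-bit float TIFF pages divided by `scale`
# (default 2^16) so values stay inside the format's [0, 1] convention;
# readers multiply back.
tiff_scale_default <- 65536

#' Write / read a three-channel image as multi-page TIFF
#'
#' Pages are ordered donor, acceptor, rawFRET. Intensities (arbitrary
#' units) are stored as 32-bit floats divided by \code{scale}; the reader
#' multiplies back, so values up to \code{scale} AU round-trip at float
#' precision.
#'
#' @param image multichannel image (matrices donor, acceptor, rawfret).
#' @param path output .tif path.
#' @param scale intensity scale (default 2^16 AU).
#' @return \code{path}, invisibly.
#' @export
write_multichannel_tiff <- function(image, path, scale = tiff_scale_default) {
  check_multichannel(image)
  if (max(image$donor, image$acceptor, image$rawfret) > scale) {
    stop("pixel intensities exceed the TIFF storage scale (", scale, " AU)",
         call. = FALSE)
  }
  tiff::writeTIFF(list(image$donor / scale, image$acceptor / scale,
                       image$rawfret / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_multichannel_tiff
#' @export
read_multichannel_tiff <- function(path, scale = tiff_scale_default) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) {
    stop("expected a 3-page TIFF (donor, acceptor, rawFRET); got ",
         length(pages), " page(s)", call. = FALSE)
  }
  list(donor = pages[[1]] * scale, acceptor = pages[[2]] * scale,
       rawfret = pages[[3]] * scale)
}

#' Write / read a 16-bit label mask TIFF
#'
#' @param mask integer label matrix (labels <= 65535).
#' @param path output .tif path.
#' @return \code{path} invisibly (writer); integer matrix (reader).
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(m), nrow = nrow(m))
}
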