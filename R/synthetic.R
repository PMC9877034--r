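#' @importFrom stats rnorm rlnorm rpois runif
NULL

# Measured channel value = signal + constant background + Gaussian noise,
# SD = background_sd + shot_noise_factor * sqrt(signal). Exact in the
# noise-free limit.
measure_channel <- function(signal, offset, cfg) {
  if (noise_free(cfg)) {
    return(signal + offset)
  }
  sd <- cfg$background_sd + cfg$shot_noise_factor * sqrt(pmax(signal, 0))
  # Detected intensities are non-negative, as on a real camera; clipping
  # only ever acts on near-zero background pixels/cells.
  pmax(signal + offset + rnorm(length(signal), mean = 0, sd = sd), 0)
}

# Per-cell spectral mixing, averaged to ROI level. `theta` has one entry
# per ROI; each ROI averages cfg$cells_per_roi simulated cells.
simulate_roi_channels <- function(n_rois, theta, cfg,
                                  donor_present = TRUE,
                                  acceptor_present = TRUE) {
  m <- cfg$cells_per_roi
  n <- n_rois * m
  theta_cell <- rep(theta, each = m)
  D <- if (donor_present) rlnorm(n, cfg$donor_meanlog, cfg$donor_sdlog) else numeric(n)
  A <- if (acceptor_present) rlnorm(n, cfg$acceptor_meanlog, cfg$acceptor_sdlog) else numeric(n)
  # A donor can only be FRET-engaged when both fluorophores are present.
  fe <- if (donor_present && acceptor_present) {
    cfg$f0 * (1 + theta_cell) * cfg$E0
  } else {
    numeric(n)
  }
  if (any(fe > 1)) {
    stop("engaged-donor fraction f * E0 exceeds 1; reduce theta, f0 or E0",
         call. = FALSE)
  }
  donor_sig <- cfg$gain_donor * D * (1 - fe)
  acceptor_sig <- cfg$gain_acceptor * A
  raw_sig <- cfg$gain_fret * D * fe +
    cfg$alpha_true * donor_sig + cfg$beta_true * acceptor_sig
  off <- cfg$background_offset
  donor <- measure_channel(donor_sig, off[["donor"]], cfg)
  acceptor <- measure_channel(acceptor_sig, off[["acceptor"]], cfg)
  rawfret <- measure_channel(raw_sig, off[["fret"]], cfg)
  data.frame(
    donor = .colMeans(donor, m, n_rois),
    acceptor = .colMeans(acceptor, m, n_rois),
    rawfret = .colMeans(rawfret, m, n_rois)
  )
}

roi_cell_counts <- function(n_rois, viability, cfg) {
  lambda <- cfg$cells_per_roi * viability
  if (noise_free(cfg)) round(lambda) else rpois(n_rois, lambda)
}

# Row-major 96-well labels: "A01" .. "H12".
well_label <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Expected cFRET/donor ratio under the mixing model
#'
#' Closed-form, zero-background expectation of the corrected FRET per
#' donor ratio for a treatment with effect size \code{theta}:
#' \eqn{g_F f E_0 / (g_D (1 - f E_0))} with \eqn{f = f_0 (1 + \theta)}.
#' Used as the analytic oracle for simulated wells.
#'
#' @param cfg a [sim_config()] object.
#' @param theta treatment effect size (multiplicative uplift of the
#'   engaged fraction); vectorized.
#' @return numeric vector of expected cFRET/donor ratios.
#' @export
expected_cfret_per_donor <- function(cfg, theta = 0) {
  fe <- cfg$f0 * (1 + theta) * cfg$E0
  cfg$gain_fret * fe / (cfg$gain_donor * (1 - fe))
}

#' Generate single-fluorophore calibration ROIs
#'
#' Simulates donor-only and acceptor-only cell populations used to
#' estimate the bleed-through coefficient alpha (donor emission detected
#' in the FRET channel) and the cross-excitation coefficient beta
#' (acceptor signal excited directly at the donor wavelength). Donor-only
#' ROIs satisfy \code{rawfret = alpha_true * donor_signal + background +
#' noise} with the acceptor channel at background; acceptor-only ROIs are
#' symmetric.
#'
#' @param cfg a [sim_config()] object.
#' @param n_rois ROIs per calibration population (default 200).
#' @param seed random seed; defaults to \code{cfg$seed}.
#' @return list with elements \code{roi} (data.frame: plate_id, well, roi,
#'   donor, acceptor, rawfret, cell_count), \code{platemap} (data.frame:
#'   plate_id, well, compound_id, role, concentration_um, replicate) and
#'   \code{truth} (list with alpha, beta).
#' @examples
#' cal <- gen_calibration_cells(sim_config(), n_rois = 40)
#' table(cal$platemap$role)
#' @export
gen_calibration_cells <- function(cfg, n_rois = 200L, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  gen_pop <- function(role, well_offset) {
    ch <- simulate_roi_channels(
      n_rois, theta = rep(0, n_rois), cfg,
      donor_present = identical(role, "donor_only"),
      acceptor_present = identical(role, "acceptor_only")
    )
    widx <- (seq_len(n_rois) - 1L) %/% cfg$rois_per_well + 1L + well_offset
    if (max(widx) > 96L) {
      stop("calibration ROIs exceed one 96-well plate; lower n_rois",
           call. = FALSE)
    }
    data.frame(
      plate_id = "CAL01",
      well = well_label((widx - 1L) %/% 12L + 1L, (widx - 1L) %% 12L + 1L),
      roi = (seq_len(n_rois) - 1L) %% cfg$rois_per_well + 1L,
      ch,
      cell_count = roi_cell_counts(n_rois, 1, cfg)
    )
  }
  n_wells_d <- ceiling(n_rois / cfg$rois_per_well)
  roi_d <- gen_pop("donor_only", 0L)
  roi_a <- gen_pop("acceptor_only", n_wells_d)
  roi <- rbind(roi_d, roi_a)
  pm <- unique(roi[, c("plate_id", "well")])
  pm$compound_id <- "calibration"
  pm$role <- rep(c("donor_only", "acceptor_only"),
                 c(length(unique(roi_d$well)), length(unique(roi_a$well))))
  pm$concentration_um <- NA_real_
  pm$replicate <- 1L
  rownames(roi) <- rownames(pm) <- NULL
  list(roi = roi, platemap = pm,
       truth = list(alpha = cfg$alpha_true, beta = cfg$beta_true))
}

#' Generate a full replicate compound screen with ground truth
#'
#' Emulates the primary screen's design: \code{n_compounds} library
#' compounds at one concentration, arrayed 80 per 96-well plate
#' (columns 2-11), with column 1 as DMSO vehicle wells and column 12 as
#' beta-lapachone positive-control wells, repeated in
#' \code{n_replicate_screens} independent replicate screens. A configured
#' fraction of compounds are planted hits (effect theta drawn from
#' \code{hit_theta_range} times the positive-control effect) and a
#' disjoint fraction are cytotoxic (ROI cell counts reduced by
#' \code{viability_loss}; intensities unchanged, since the morphology
#' criterion is modeled purely through cell counts).
#'
#' @param cfg a [sim_config()] object.
#' @param seed random seed; defaults to \code{cfg$seed}.
#' @return list with elements \code{roi}, \code{platemap} (as in
#'   [gen_calibration_cells()]; roles here are \code{dmso},
#'   \code{beta_lapachone}, \code{test}) and \code{truth} (list:
#'   \code{compounds} data.frame with compound_id, theta, label in
#'   \{null, hit, cytotoxic\}; model parameters).
#' @examples
#' scr <- gen_screen_dataset(sim_config(n_compounds = 160, seed = 7))
#' table(scr$truth$compounds$label)
#' @export
gen_screen_dataset <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  n <- cfg$n_compounds
  n_plates <- ceiling(n / 80)
  compound_id <- sprintf("C%04d", seq_len(n))

  n_hits <- round(cfg$hit_fraction * n)
  n_cyto <- round(cfg$cytotoxic_fraction * n)
  if (n_hits + n_cyto > n) stop("hit + cytotoxic fractions exceed 1", call. = FALSE)
  special <- sample.int(n, n_hits + n_cyto)
  hit_idx <- special[seq_len(n_hits)]
  cyto_idx <- setdiff(special, hit_idx)
  theta <- numeric(n)
  theta[hit_idx] <- cfg$positive_control_theta *
    runif(n_hits, cfg$hit_theta_range[1], cfg$hit_theta_range[2])
  label <- rep("null", n)
  label[hit_idx] <- "hit"
  label[cyto_idx] <- "cytotoxic"

  # One plate's layout: column 1 DMSO, columns 2-11 test slots (row-major),
  # column 12 beta-lapachone.
  plate_rows <- rep(1:8, each = 12)
  plate_cols <- rep(1:12, times = 8)
  slot <- ifelse(plate_cols >= 2 & plate_cols <= 11,
                 (plate_rows - 1L) * 10L + (plate_cols - 1L), NA_integer_)

  pm_list <- vector("list", cfg$n_replicate_screens * n_plates)
  k <- 0L
  for (r in seq_len(cfg$n_replicate_screens)) {
    for (p in seq_len(n_plates)) {
      cidx <- (p - 1L) * 80L + slot
      cidx[!is.na(cidx) & cidx > n] <- NA_integer_
      role <- ifelse(plate_cols == 1L, "dmso",
                     ifelse(plate_cols == 12L, "beta_lapachone", "test"))
      keep <- role != "test" | !is.na(cidx)
      pm <- data.frame(
        plate_id = sprintf("R%dP%02d", r, p),
        well = well_label(plate_rows, plate_cols),
        compound_id = ifelse(role == "dmso", "DMSO",
                             ifelse(role == "beta_lapachone", "BLAP",
                                    compound_id[cidx])),
        role = role,
        concentration_um = 40,
        replicate = r
      )[keep, , drop = FALSE]
      k <- k + 1L
      pm_list[[k]] <- pm
    }
  }
  platemap <- do.call(rbind, pm_list)
  rownames(platemap) <- NULL

  theta_by_id <- c(DMSO = 0, BLAP = cfg$positive_control_theta,
                   stats::setNames(theta, compound_id))
  viab_by_id <- c(DMSO = 1, BLAP = 1,
                  stats::setNames(ifelse(label == "cytotoxic",
                                         1 - cfg$viability_loss, 1),
                                  compound_id))
  theta_well <- unname(theta_by_id[platemap$compound_id])
  viab_well <- unname(viab_by_id[platemap$compound_id])

  nr <- cfg$rois_per_well
  n_rois <- nrow(platemap) * nr
  ch <- simulate_roi_channels(n_rois, rep(theta_well, each = nr), cfg)
  roi <- data.frame(
    plate_id = rep(platemap$plate_id, each = nr),
    well = rep(platemap$well, each = nr),
    roi = rep(seq_len(nr), times = nrow(platemap)),
    ch,
    cell_count = roi_cell_counts(n_rois, rep(viab_well, each = nr), cfg)
  )

  truth <- list(
    compounds = data.frame(compound_id = compound_id, theta = theta,
                           label = label),
    alpha = cfg$alpha_true, beta = cfg$beta_true,
    f0 = cfg$f0, E0 = cfg$E0,
    positive_control_theta = cfg$positive_control_theta
  )
  list(roi = roi, platemap = platemap, truth = truth)
}

#' Generate a dose-response table from a four-parameter logistic truth
#'
#' Responses follow \eqn{y = d + (a - d) / (1 + (x/c)^b)} evaluated on
#' \code{cfg$dose_grid}, replicated \code{cfg$dose_replicates} times, with
#' multiplicative Gaussian noise of coefficient of variation
#' \code{cfg$dose_cv}.
#'
#' @param cfg a [sim_config()] object.
#' @param fourpl_truth named numeric (a, b, c, d); defaults to
#'   \code{cfg$fourpl_truth}.
#' @param seed random seed; defaults to \code{cfg$seed}.
#' @param compound_id label written into the table.
#' @return data.frame: compound_id, concentration_um, replicate, response.
#' @examples
#' head(gen_dose_response(sim_config(dose_cv = 0)))
#' @export
gen_dose_response <- function(cfg, fourpl_truth = cfg$fourpl_truth,
                              seed = cfg$seed, compound_id = "compound") {
  validate_sim_config(cfg)
  set.seed(seed)
  conc <- rep(cfg$dose_grid, each = cfg$dose_replicates)
  mu <- four_pl(conc, fourpl_truth[["a"]], fourpl_truth[["b"]],
                fourpl_truth[["c"]], fourpl_truth[["d"]])
  resp <- if (cfg$dose_cv > 0) mu + rnorm(length(mu), 0, cfg$dose_cv * abs(mu)) else mu
  data.frame(
    compound_id = compound_id,
    concentration_um = conc,
    replicate = rep(seq_len(cfg$dose_replicates), times = length(cfg$dose_grid)),
    response = resp
  )
}

#' Generate Mito Stress Test OCR traces
#'
#' Emulates an extracellular-flux Mito Stress run: oxygen consumption rate
#' measured in \code{cycles_per_phase} cycles at baseline and after each
#' sequential injection of oligomycin, FCCP, and rotenone/antimycin A,
#' with additive Gaussian noise per cycle. The injection column annotates
#' the first measurement following each injection; the phase column
#' carries the generator's ground-truth phase labels.
#'
#' @param cfg a [sim_config()] object.
#' @param n_wells number of wells (independent traces).
#' @param seed random seed; defaults to \code{cfg$seed}.
#' @param phase_means named numeric of true phase OCR means; defaults to
#'   \code{cfg$ocr_phase_means}. Means violating the canonical ordering
#'   FCCP >= baseline >= oligomycin >= rotenone/antimycin are generated
#'   anyway, with a warning (useful for probing metric edge cases).
#' @return data.frame: well, time_min, ocr, ecar, injection, phase.
#' @examples
#' tr <- gen_mito_stress(sim_config(ocr_sd = 0))
#' respiration_metrics(tr)
#' @export
gen_mito_stress <- function(cfg, n_wells = 1L, seed = cfg$seed,
                            phase_means = cfg$ocr_phase_means) {
  validate_sim_config(cfg)
  set.seed(seed)
  phases <- c("baseline", "oligomycin", "fccp", "rotenone_antimycin")
  pm <- phase_means[phases]
  if (!(pm[["fccp"]] >= pm[["baseline"]] &&
        pm[["baseline"]] >= pm[["oligomycin"]] &&
        pm[["oligomycin"]] >= pm[["rotenone_antimycin"]])) {
    warning("phase means violate the canonical ordering ",
            "FCCP >= baseline >= oligomycin >= rotenone/antimycin; ",
            "traces generated anyway", call. = FALSE)
  }
  k <- cfg$cycles_per_phase
  n_pts <- 4L * k
  time_min <- seq_len(n_pts) * 6.5
  injection <- rep("", n_pts)
  injection[k + 1L] <- "oligomycin"
  injection[2L * k + 1L] <- "fccp"
  injection[3L * k + 1L] <- "rotenone_antimycin"
  out <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    mu <- rep(unname(pm), each = k)
    ocr <- if (cfg$ocr_sd > 0) mu + rnorm(n_pts, 0, cfg$ocr_sd) else mu
    ecar <- if (cfg$ocr_sd > 0) 30 + rnorm(n_pts, 0, cfg$ocr_sd / 5) else rep(30, n_pts)
    out[[w]] <- data.frame(
      well = sprintf("W%02d", w), time_min = time_min, ocr = ocr,
      ecar = ecar, injection = injection, phase = rep(phases, each = k)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic three-channel fluorescence images with ground truth
#'
#' Renders cells as disjoint elliptical regions on a dark background, with
#' per-cell donor/acceptor abundances drawn from the configured lognormals
#' and pixel channel values following the same spectral mixing model as
#' the well-level generators. Emits the ground-truth label mask alongside
#' each image.
#'
#' @param cfg a [sim_config()] object.
#' @param n_images number of images.
#' @param theta treatment effect size applied to all cells.
#' @param n_cells cells per image; defaults to \code{cfg$cells_per_image}.
#' @param seed random seed; defaults to \code{cfg$seed}.
#' @param max_attempts placement attempts per cell before giving up
#'   (cells are required to be disjoint).
#' @return list of images; each a list with matrices \code{donor},
#'   \code{acceptor}, \code{rawfret}, integer \code{mask} (0 background,
#'   k >= 1 cell k), and \code{cells} data.frame (label, donor_abundance,
#'   acceptor_abundance, engaged_fraction).
#' @examples
#' img <- gen_images(sim_config(seed = 3), n_images = 1, n_cells = 3)[[1]]
#' max(img$mask)
#' @export
gen_images <- function(cfg, n_images = 1L, theta = 0,
                       n_cells = cfg$cells_per_image, seed = cfg$seed,
                       max_attempts = 200L) {
  validate_sim_config(cfg)
  set.seed(seed)
  h <- cfg$image_height
  w <- cfg$image_width
  fe <- cfg$f0 * (1 + theta) * cfg$E0
  if (fe > 1) stop("f * E0 exceeds 1 for this theta", call. = FALSE)
  lapply(seq_len(n_images), function(i) {
    cx <- cy <- rx <- ry <- numeric(0)
    for (k in seq_len(n_cells)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        rxk <- runif(1, 6, 12)
        ryk <- runif(1, 6, 12)
        cxk <- runif(1, rxk + 2, w - rxk - 1)
        cyk <- runif(1, ryk + 2, h - ryk - 1)
        rk <- max(rxk, ryk)
        if (all(sqrt((cx - cxk)^2 + (cy - cyk)^2) >
                pmax(rx, ry) + rk + 2)) {
          cx <- c(cx, cxk); cy <- c(cy, cyk)
          rx <- c(rx, rxk); ry <- c(ry, ryk)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_cells, " disjoint cells in a ",
             w, "x", h, " image; reduce n_cells or enlarge the image",
             call. = FALSE)
      }
    }
    D <- rlnorm(n_cells, cfg$donor_meanlog, cfg$donor_sdlog)
    A <- rlnorm(n_cells, cfg$acceptor_meanlog, cfg$acceptor_sdlog)
    mask <- matrix(0L, nrow = h, ncol = w)
    donor_sig <- acceptor_sig <- raw_sig <- matrix(0, nrow = h, ncol = w)
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    for (k in seq_len(n_cells)) {
      inside <- ((xs - cx[k]) / rx[k])^2 + ((ys - cy[k]) / ry[k])^2 <= 1
      mask[inside] <- k
      donor_sig[inside] <- cfg$gain_donor * D[k] * (1 - fe)
      acceptor_sig[inside] <- cfg$gain_acceptor * A[k]
      raw_sig[inside] <- cfg$gain_fret * D[k] * fe +
        cfg$alpha_true * donor_sig[inside] +
        cfg$beta_true * acceptor_sig[inside]
    }
    off <- cfg$background_offset
    list(
      donor = matrix(measure_channel(donor_sig, off[["donor"]], cfg), h, w),
      acceptor = matrix(measure_channel(acceptor_sig, off[["acceptor"]], cfg), h, w),
      rawfret = matrix(measure_channel(raw_sig, off[["fret"]], cfg), h, w),
      mask = mask,
      cells = data.frame(label = seq_len(n_cells), donor_abundance = D,
                         acceptor_abundance = A, engaged_fraction = fe)
    )
  })
}
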