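#' Simulation configuration for the synthetic FRET screen
#'
#' Builds and validates the parameter set that drives every synthetic-data
#' generator. Defaults emulate the study design: a 1280-compound library
#' screened at one concentration in two replicate experiments, DMSO
#' vehicle and beta-lapachone positive-control wells on every plate,
#' 12 regions of interest (ROIs) per well, single-fluorophore calibration
#' cells, a small set of planted hit and cytotoxic compounds, log-spaced
#' dose series, and three-measurement-cycle-per-phase Mito Stress traces.
#'
#' The spectral mixing model for a cell with donor abundance \eqn{D},
#' acceptor abundance \eqn{A} and FRET-engaged donor fraction \eqn{f}
#' (transfer efficiency \eqn{E_0} per engagement) is
#' \deqn{donor = g_D D (1 - f E_0) + bg + noise}
#' \deqn{acceptor = g_A A + bg + noise}
#' \deqn{rawFRET = g_F D f E_0 + \alpha \cdot donor_{sig} + \beta \cdot
#'   acceptor_{sig} + bg + noise}
#' with per-channel additive Gaussian noise of standard deviation
#' \code{background_sd + shot_noise_factor * sqrt(signal)}. Treatments act
#' multiplicatively on the engaged fraction, \eqn{f = f_0 (1 + \theta)}.
#' Donor quenching (the \eqn{1 - f E_0} factor) is included so acceptor
#' photobleaching recovers a positive transfer efficiency.
#'
#' @param seed integer; base random seed stored with the config.
#' @param n_compounds number of library compounds (default 1280).
#' @param n_replicate_screens number of replicate screens (default 2).
#' @param rois_per_well imaging fields quantified per well (default 12).
#' @param cells_per_roi simulated cells averaged into one ROI (default 50).
#' @param donor_meanlog,donor_sdlog lognormal parameters of per-cell donor
#'   abundance (arbitrary units).
#' @param acceptor_meanlog,acceptor_sdlog lognormal parameters of per-cell
#'   acceptor abundance.
#' @param f0 baseline FRET-engaged donor fraction, in \code{[0, 1]}.
#' @param E0 per-engagement transfer efficiency, in \code{(0, 1]}.
#' @param gain_donor,gain_acceptor,gain_fret channel gains (AU per
#'   abundance unit), all > 0.
#' @param alpha_true donor bleed-through coefficient into the FRET channel.
#' @param beta_true acceptor cross-excitation coefficient.
#' @param background_offset named numeric, per-channel constant background
#'   (AU), names \code{donor}, \code{acceptor}, \code{fret}.
#' @param background_sd additive (camera) noise SD, AU.
#' @param shot_noise_factor multiplier on \code{sqrt(signal)} noise.
#' @param hit_fraction fraction of compounds planted as hits.
#' @param hit_theta_range range of hit effect sizes as multiples of
#'   \code{positive_control_theta}.
#' @param positive_control_theta effect size theta of beta-lapachone wells
#'   (multiplicative uplift of the engaged fraction).
#' @param cytotoxic_fraction fraction of compounds planted as cytotoxic.
#' @param viability_loss fractional cell-count reduction in cytotoxic
#'   wells, in (0, 1).
#' @param dose_grid strictly increasing positive concentrations (uM).
#' @param dose_cv coefficient of variation of dose-response noise.
#' @param dose_replicates replicate wells per concentration.
#' @param fourpl_truth named numeric (a, b, c, d) of the true
#'   four-parameter logistic curve; \code{c} is the true EC50 in uM.
#' @param ocr_phase_means named numeric, true OCR (pmol O2/min) in the
#'   baseline, oligomycin, FCCP and rotenone/antimycin A phases.
#' @param ocr_sd per-cycle additive OCR noise SD.
#' @param cycles_per_phase measurement cycles per injection phase.
#' @param image_width,image_height synthetic image dimensions, pixels.
#' @param cells_per_image cells rendered per synthetic image.
#'
#' @return An object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$alpha_true
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 1280L,
                       n_replicate_screens = 2L,
                       rois_per_well = 12L,
                       cells_per_roi = 50L,
                       donor_meanlog = log(1000),
                       donor_sdlog = 0.3,
                       acceptor_meanlog = log(800),
                       acceptor_sdlog = 0.3,
                       f0 = 0.25,
                       E0 = 0.3,
                       gain_donor = 1,
                       gain_acceptor = 1,
                       gain_fret = 1,
                       alpha_true = 0.2,
                       beta_true = 0.1,
                       background_offset = c(donor = 0, acceptor = 0, fret = 0),
                       background_sd = 5,
                       shot_noise_factor = 1,
                       hit_fraction = 20 / 1280,
                       hit_theta_range = c(0.7, 1.3),
                       positive_control_theta = 1,
                       cytotoxic_fraction = 0.02,
                       viability_loss = 0.6,
                       dose_grid = exp(seq(log(0.025), log(5), length.out = 8)),
                       dose_cv = 0.05,
                       dose_replicates = 3L,
                       fourpl_truth = c(a = 1, b = 1.5, c = 0.6, d = 2),
                       ocr_phase_means = c(baseline = 100, oligomycin = 40,
                                           fccp = 150, rotenone_antimycin = 20),
                       ocr_sd = 5,
                       cycles_per_phase = 3L,
                       image_width = 128L,
                       image_height = 128L,
                       cells_per_image = 5L) {
  cfg <- list(
    seed = as.integer(seed),
    n_compounds = as.integer(n_compounds),
    n_replicate_screens = as.integer(n_replicate_screens),
    rois_per_well = as.integer(rois_per_well),
    cells_per_roi = as.integer(cells_per_roi),
    donor_meanlog = donor_meanlog, donor_sdlog = donor_sdlog,
    acceptor_meanlog = acceptor_meanlog, acceptor_sdlog = acceptor_sdlog,
    f0 = f0, E0 = E0,
    gain_donor = gain_donor, gain_acceptor = gain_acceptor,
    gain_fret = gain_fret,
    alpha_true = alpha_true, beta_true = beta_true,
    background_offset = background_offset,
    background_sd = background_sd,
    shot_noise_factor = shot_noise_factor,
    hit_fraction = hit_fraction,
    hit_theta_range = hit_theta_range,
    positive_control_theta = positive_control_theta,
    cytotoxic_fraction = cytotoxic_fraction,
    viability_loss = viability_loss,
    dose_grid = dose_grid, dose_cv = dose_cv,
    dose_replicates = as.integer(dose_replicates),
    fourpl_truth = fourpl_truth,
    ocr_phase_means = ocr_phase_means, ocr_sd = ocr_sd,
    cycles_per_phase = as.integer(cycles_per_phase),
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    cells_per_image = as.integer(cells_per_image)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x a \code{sim_config} object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  num_pos <- function(v, nm) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("sim_config: `", nm, "` must be positive and finite", call. = FALSE)
    }
  }
  num_pos(c(x$gain_donor, x$gain_acceptor, x$gain_fret), "gains")
  num_pos(x$n_compounds, "n_compounds")
  num_pos(x$rois_per_well, "rois_per_well")
  num_pos(x$cells_per_roi, "cells_per_roi")
  if (x$alpha_true < 0 || x$beta_true < 0) {
    stop("sim_config: alpha_true and beta_true must be >= 0", call. = FALSE)
  }
  if (x$f0 < 0 || x$f0 > 1) stop("sim_config: f0 must lie in [0, 1]", call. = FALSE)
  if (x$E0 <= 0 || x$E0 > 1) stop("sim_config: E0 must lie in (0, 1]", call. = FALSE)
  if (x$background_sd < 0 || x$shot_noise_factor < 0) {
    stop("sim_config: noise parameters must be >= 0", call. = FALSE)
  }
  if (any(x$background_offset < 0)) {
    stop("sim_config: background offsets must be >= 0", call. = FALSE)
  }
  theta_max <- max(x$positive_control_theta,
                   x$positive_control_theta * max(x$hit_theta_range))
  if (x$f0 * (1 + theta_max) * x$E0 > 1 + 1e-12) {
    stop("sim_config: f0 * (1 + theta) * E0 exceeds 1 for the largest ",
         "planted effect; engaged-donor fraction would be unphysical",
         call. = FALSE)
  }
  if (x$viability_loss <= 0 || x$viability_loss >= 1) {
    stop("sim_config: viability_loss must lie in (0, 1)", call. = FALSE)
  }
  dg <- x$dose_grid
  if (length(dg) < 1 || any(dg <= 0) || is.unsorted(dg, strictly = TRUE)) {
    stop("sim_config: dose_grid must be strictly positive and increasing",
         call. = FALSE)
  }
  if (!all(c("a", "b", "c", "d") %in% names(x$fourpl_truth))) {
    stop("sim_config: fourpl_truth needs named elements a, b, c, d",
         call. = FALSE)
  }
  if (x$fourpl_truth[["c"]] <= 0) {
    stop("sim_config: true EC50 (c) must be > 0", call. = FALSE)
  }
  phases <- c("baseline", "oligomycin", "fccp", "rotenone_antimycin")
  if (!all(phases %in% names(x$ocr_phase_means))) {
    stop("sim_config: ocr_phase_means needs phases ",
         paste(phases, collapse = ", "), call. = FALSE)
  }
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic FRET-screen configuration\n")
  cat(sprintf("  %d compounds x %d replicate screens, %d ROIs/well, %d cells/ROI\n",
              x$n_compounds, x$n_replicate_screens, x$rois_per_well,
              x$cells_per_roi))
  cat(sprintf("  f0 = %.3g, E0 = %.3g, positive-control theta = %.3g\n",
              x$f0, x$E0, x$positive_control_theta))
  cat(sprintf("  alpha_true = %.3g, beta_true = %.3g, background_sd = %.3g, shot factor = %.3g\n",
              x$alpha_true, x$beta_true, x$background_sd, x$shot_noise_factor))
  cat(sprintf("  planted hits: %d, cytotoxic: %d, seed = %d\n",
              round(x$hit_fraction * x$n_compounds),
              round(x$cytotoxic_fraction * x$n_compounds), x$seed))
  invisible(x)
}

# TRUE when the config produces exactly the deterministic mixing model
# (no stochastic measurement noise).
noise_free <- function(cfg) {
  cfg$background_sd == 0 && cfg$shot_noise_factor == 0
}
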