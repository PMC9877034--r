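mito_phases <- c("baseline", "oligomycin", "fccp", "rotenone_antimycin")

#' Assign Mito Stress trace timepoints to injection phases
#'
#' Splits an OCR trace into the four canonical phases using its injection
#' annotations: each timepoint belongs to the phase started by the most
#' recent injection (baseline before the first). Injections must appear
#' in the canonical order oligomycin, FCCP, rotenone/antimycin A, and
#' every phase must contain at least one measurement cycle.
#'
#' @param trace data.frame for a single well with columns \code{time_min}
#'   (strictly increasing), \code{ocr}, and \code{injection} ("" except on
#'   the first measurement after each injection).
#' @return \code{trace} with a \code{phase} factor column (levels
#'   baseline, oligomycin, fccp, rotenone_antimycin).
#' @examples
#' tr <- gen_mito_stress(sim_config())
#' table(segment_phases(tr)$phase)
#' @export
segment_phases <- function(trace) {
  need <- c("time_min", "ocr", "injection")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    stop("trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(trace$well) && length(unique(trace$well)) > 1) {
    stop("segment_phases expects a single well; split the table first",
         call. = FALSE)
  }
  if (is.unsorted(trace$time_min, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  inj <- trace$injection
  seen <- inj[nzchar(inj)]
  if (!identical(seen, mito_phases[-1])) {
    stop("injection annotations must be exactly oligomycin, fccp, ",
         "rotenone_antimycin in that order (got: ",
         if (length(seen)) paste(seen, collapse = ", ") else "none", ")",
         call. = FALSE)
  }
  phase_idx <- cumsum(nzchar(inj)) + 1L
  trace$phase <- factor(mito_phases[phase_idx], levels = mito_phases)
  counts <- table(trace$phase)
  if (any(counts == 0)) {
    stop("phase(s) without measurements: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  trace
}

#' Mito Stress Test respiration metrics
#'
#' Derives the standard respirometry quantities from a single-well OCR
#' trace. Each phase is summarized by the chosen statistic of its
#' measurement cycles (mean of the three cycles by default), then:
#' non-mitochondrial respiration = rotenone/antimycin phase summary;
#' basal = baseline - non-mitochondrial; ATP-linked = baseline -
#' oligomycin; proton leak = oligomycin - non-mitochondrial; maximal =
#' FCCP - non-mitochondrial; spare capacity = maximal - basal. The
#' identities basal = ATP-linked + proton leak and spare = maximal -
#' basal hold by construction.
#'
#' @param trace single-well trace as in [segment_phases()] (the phase
#'   column is recomputed from the injection annotations).
#' @param summary phase summary statistic: \code{"mean"} (default) or
#'   \code{"vendor"} (last baseline cycle, minimum oligomycin and
#'   rotenone/antimycin cycles, maximum FCCP cycle — a common flux-analyzer
#'   convention).
#' @return object of class \code{respiration_metrics}: list with
#'   \code{phase_summary} (named numeric), \code{non_mito}, \code{basal},
#'   \code{atp_linked}, \code{proton_leak}, \code{maximal},
#'   \code{spare_capacity} (all pmol O2/min).
#' @examples
#' cfg <- sim_config(ocr_sd = 0)
#' respiration_metrics(gen_mito_stress(cfg))$basal  # 80
#' @export
respiration_metrics <- function(trace, summary = c("mean", "vendor")) {
  summary <- match.arg(summary)
  trace <- segment_phases(trace)
  ph <- split(trace$ocr, trace$phase)
  ps <- if (summary == "mean") {
    vapply(ph, mean, numeric(1))
  } else {
    c(baseline = ph$baseline[length(ph$baseline)],
      oligomycin = min(ph$oligomycin),
      fccp = max(ph$fccp),
      rotenone_antimycin = min(ph$rotenone_antimycin))
  }
  if (any(ps < 0)) {
    warning("negative phase summaries (possible instrument anomaly): ",
            paste(names(ps)[ps < 0], collapse = ", "), call. = FALSE)
  }
  non_mito <- ps[["rotenone_antimycin"]]
  basal <- ps[["baseline"]] - non_mito
  atp_linked <- ps[["baseline"]] - ps[["oligomycin"]]
  proton_leak <- ps[["oligomycin"]] - non_mito
  maximal <- ps[["fccp"]] - non_mito
  structure(
    list(phase_summary = ps, non_mito = non_mito, basal = basal,
         atp_linked = atp_linked, proton_leak = proton_leak,
         maximal = maximal, spare_capacity = maximal - basal),
    class = "respiration_metrics"
  )
}

#' @export
print.respiration_metrics <- function(x, ...) {
  cat("Mito Stress respiration metrics (pmol O2/min):\n")
  cat(sprintf("  basal %.4g | ATP-linked %.4g | proton leak %.4g | maximal %.4g | spare %.4g | non-mito %.4g\n",
              x$basal, x$atp_linked, x$proton_leak, x$maximal,
              x$spare_capacity, x$non_mito))
  invisible(x)
}

#' Respiration metrics for every well of a trace table
#'
#' @param traces trace table with a \code{well} column.
#' @param ... passed to [respiration_metrics()].
#' @return data.frame with one row per well and the metric columns.
#' @export
respiration_metrics_by_well <- function(traces, ...) {
  out <- lapply(split(traces, traces$well), function(tr) {
    m <- respiration_metrics(tr, ...)
    data.frame(well = tr$well[1], non_mito = m$non_mito, basal = m$basal,
               atp_linked = m$atp_linked, proton_leak = m$proton_leak,
               maximal = m$maximal, spare_capacity = m$spare_capacity)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression fold change by the 2^-ddCT method
#'
#' Computes \eqn{2^{-\Delta\Delta C_T}} from the cycle-threshold values of
#' a target and a reference gene (e.g. Gapdh) in treated and control
#' samples: \eqn{\Delta C_T = C_T^{target} - C_T^{reference}} in each
#' condition, \eqn{\Delta\Delta C_T = \Delta C_T^{treated} -
#' \Delta C_T^{control}}, fold change \eqn{= 2^{-\Delta\Delta C_T}}.
#'
#' @param ct_target_treated,ct_reference_treated,ct_target_control,ct_reference_control
#'   finite PCR cycle-threshold values (vectorized).
#' @return fold change (dimensionless, > 0).
#' @examples
#' ddct_fold_change(24, 20, 26, 20)  # 4
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  if (any(!is.finite(cts))) {
    stop("all CT values must be finite", call. = FALSE)
  }
  dct_treated <- ct_target_treated - ct_reference_treated
  dct_control <- ct_target_control - ct_reference_control
  2^-(dct_treated - dct_control)
}
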