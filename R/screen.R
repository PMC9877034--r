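#' @importFrom stats aggregate dist
NULL

#' Control-normalized primary screen score
#'
#' The primary screen score of a compound is
#' \deqn{S = \frac{\overline{cFRET/donor}_{compound} -
#'   \overline{cFRET/donor}_{DMSO}}{\overline{cFRET/donor}_{\beta-lap} -
#'   \overline{cFRET/donor}_{DMSO}}}
#' so DMSO-like compounds score 0 and compounds matching the
#' beta-lapachone positive control score 1. This low-level helper takes
#' per-replicate means (compound, DMSO, beta-lapachone aligned by
#' replicate), averages each across replicates, and normalizes.
#'
#' @param compound_means per-replicate mean cFRET/donor of the compound.
#' @param dmso_means per-replicate DMSO control means (same length).
#' @param blap_means per-replicate beta-lapachone control means.
#' @param tolerance minimum control separation; below it the score is
#'   withheld with an error (plate fails QC).
#' @return list with \code{score}, \code{rep_means},
#'   \code{replicate_diff} (max absolute pairwise difference of the
#'   per-replicate compound means; 0 with one replicate).
#' @examples
#' primary_score(c(1.30, 1.30), c(1.00, 1.00), c(1.20, 1.20))$score  # 1.5
#' @export
primary_score <- function(compound_means, dmso_means, blap_means,
                          tolerance = 1e-9) {
  stopifnot(length(dmso_means) == length(compound_means),
            length(blap_means) == length(compound_means))
  denom <- mean(blap_means) - mean(dmso_means)
  if (abs(denom) <= tolerance) {
    stop("controls not separated: |beta-lapachone mean - DMSO mean| <= ",
         tolerance, "; plate fails QC", call. = FALSE)
  }
  s <- (mean(compound_means) - mean(dmso_means)) / denom
  rd <- if (length(compound_means) > 1) {
    max(dist(compound_means))
  } else {
    0
  }
  list(score = s, rep_means = compound_means, replicate_diff = rd)
}

# Per-(replicate, plate) control means and per-(compound, replicate)
# means from a well-summary table joined to roles.
compound_replicate_means <- function(wells) {
  need <- c("plate_id", "well", "mean_cfret_per_donor", "role",
            "compound_id", "replicate")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop("well summary is missing column(s): ", paste(miss, collapse = ", "),
         " (aggregate with a plate map)", call. = FALSE)
  }
  ok <- is.finite(wells$mean_cfret_per_donor)
  wells[ok, , drop = FALSE]
}

#' Score every compound of a primary screen
#'
#' Full primary-screen driver on a well-summary table (output of
#' [aggregate_wells()] with a plate map): computes per-replicate compound
#' means, normalizes against each compound's own plate's DMSO and
#' beta-lapachone control means (control means computed per
#' plate-replicate and averaged across replicates), applies the exclusion
#' filters, and calls hits.
#'
#' Exclusion filters follow the screen's published rules: a compound is
#' \code{replicate_inconsistent} when its raw per-replicate mean
#' cFRET/donor values differ by more than \code{diff_threshold} (strict
#' inequality; default 0.15), and \code{cytotoxic} when its mean well
#' cell count is below \code{viability_fraction} of its plates' DMSO mean
#' cell count (a computable proxy for the visual cell-death/morphology
#' criterion). A hit is an unflagged compound with score strictly above
#' \code{hit_threshold} (default 0.6).
#'
#' @param wells well-summary data.frame with columns plate_id, well,
#'   mean_cfret_per_donor, mean_cell_count, compound_id, role, replicate.
#' @param hit_threshold score above which (strictly) a clean compound is
#'   a hit.
#' @param diff_threshold replicate-difference exclusion threshold on raw
#'   mean cFRET/donor.
#' @param viability_fraction cytotoxicity threshold as a fraction of the
#'   plate DMSO mean cell count.
#' @param tolerance minimum control separation per plate.
#' @return object of class \code{primary_screen}: data.frame with one row
#'   per compound (compound_id, per-replicate means rep1/rep2/...,
#'   score, replicate_diff, flags, is_hit) plus attributes
#'   \code{thresholds} and \code{funnel} (scored / above-threshold /
#'   excluded counts).
#' @examples
#' scr <- gen_screen_dataset(sim_config(n_compounds = 160, seed = 11))
#' co <- corrected_fret(scr$roi, list(alpha = 0.2, beta = 0.1))
#' ws <- aggregate_wells(co, scr$platemap)
#' head(score_primary(ws))
#' @export
score_primary <- function(wells, hit_threshold = 0.6, diff_threshold = 0.15,
                          viability_fraction = 0.5, tolerance = 1e-9) {
  wells <- compound_replicate_means(wells)
  ctrl <- wells[wells$role %in% c("dmso", "beta_lapachone"), , drop = FALSE]
  # control means per (plate, replicate)
  ctrl_mean <- aggregate(mean_cfret_per_donor ~ plate_id + replicate + role,
                         data = ctrl, FUN = mean)
  ctrl_count <- aggregate(mean_cell_count ~ plate_id,
                          data = wells[wells$role %in% "dmso", , drop = FALSE],
                          FUN = mean)
  dmso_ref <- setNames(ctrl_count$mean_cell_count, ctrl_count$plate_id)

  test <- wells[wells$role %in% "test", , drop = FALSE]
  if (!nrow(test)) stop("no test wells in well summary", call. = FALSE)

  lookup_ctrl <- function(plate, rep, role) {
    v <- ctrl_mean$mean_cfret_per_donor[
      ctrl_mean$plate_id == plate & ctrl_mean$replicate == rep &
        ctrl_mean$role == role]
    if (!length(v)) {
      stop("plate ", plate, " replicate ", rep, " has no ", role,
           " control wells", call. = FALSE)
    }
    v
  }

  n_reps <- sort(unique(test$replicate))
  records <- lapply(split(test, test$compound_id), function(sub) {
    reps <- sort(unique(sub$replicate))
    rep_means <- vapply(reps, function(r) {
      mean(sub$mean_cfret_per_donor[sub$replicate == r])
    }, numeric(1))
    dmso <- vapply(reps, function(r) {
      lookup_ctrl(sub$plate_id[sub$replicate == r][1], r, "dmso")
    }, numeric(1))
    blap <- vapply(reps, function(r) {
      lookup_ctrl(sub$plate_id[sub$replicate == r][1], r, "beta_lapachone")
    }, numeric(1))
    ps <- primary_score(rep_means, dmso, blap, tolerance = tolerance)

    cell_frac <- if (all(is.finite(sub$mean_cell_count))) {
      mean(sub$mean_cell_count) / mean(dmso_ref[sub$plate_id])
    } else {
      NA_real_
    }
    out <- data.frame(compound_id = sub$compound_id[1],
                      score = ps$score, replicate_diff = ps$replicate_diff,
                      cell_count_fraction = cell_frac,
                      incomplete = !identical(as.integer(reps),
                                              as.integer(n_reps)))
    for (i in seq_along(reps)) out[[paste0("rep", reps[i])]] <- rep_means[i]
    out
  })
  rec <- do.call(rbind, records)
  rownames(rec) <- NULL

  rec <- apply_exclusion_filters(rec, diff_threshold = diff_threshold,
                                 viability_fraction = viability_fraction)
  rec <- select_primary_hits(rec, hit_threshold = hit_threshold)

  structure(rec, class = c("primary_screen", "data.frame"),
            thresholds = list(hit_threshold = hit_threshold,
                              diff_threshold = diff_threshold,
                              viability_fraction = viability_fraction),
            funnel = c(scored = nrow(rec),
                       above_threshold = sum(rec$score > hit_threshold),
                       excluded_replicate = sum(grepl("replicate_inconsistent", rec$flags)),
                       excluded_cytotoxic = sum(grepl("cytotoxic", rec$flags)),
                       hits = sum(rec$is_hit)))
}

#' Apply the screen's exclusion filters
#'
#' Flags \code{replicate_inconsistent} when per-replicate raw mean
#' cFRET/donor values differ by more than \code{diff_threshold} (strictly;
#' a difference of exactly 0.15 is retained), \code{cytotoxic} when the
#' compound's cell-count fraction of the plate DMSO reference is below
#' \code{viability_fraction}, and \code{incomplete} when a replicate
#' measurement is missing.
#'
#' @param records data.frame with columns \code{replicate_diff},
#'   \code{cell_count_fraction} and optionally \code{incomplete}.
#' @inheritParams score_primary
#' @return \code{records} with a \code{flags} column (';'-separated, ""
#'   when clean).
#' @examples
#' r <- data.frame(compound_id = c("a", "b"), replicate_diff = c(0.16, 0.15),
#'                 cell_count_fraction = 1)
#' apply_exclusion_filters(r)$flags
#' @export
apply_exclusion_filters <- function(records, diff_threshold = 0.15,
                                    viability_fraction = 0.5) {
  flags <- rep("", nrow(records))
  add <- function(flags, cond, label) {
    ifelse(cond, ifelse(nzchar(flags), paste(flags, label, sep = ";"), label),
           flags)
  }
  if (!is.null(records$incomplete)) {
    flags <- add(flags, records$incomplete, "incomplete")
  }
  flags <- add(flags, records$replicate_diff > diff_threshold,
               "replicate_inconsistent")
  if (!is.null(records$cell_count_fraction)) {
    flags <- add(flags, !is.na(records$cell_count_fraction) &
                   records$cell_count_fraction < viability_fraction,
                 "cytotoxic")
  }
  records$flags <- flags
  records
}

#' Select primary-screen hits
#'
#' A hit is an unflagged compound whose normalized score is strictly
#' greater than \code{hit_threshold}.
#'
#' @param records scored, flagged records (columns \code{score},
#'   \code{flags}).
#' @inheritParams score_primary
#' @return \code{records} with a logical \code{is_hit} column.
#' @export
select_primary_hits <- function(records, hit_threshold = 0.6) {
  records$is_hit <- records$score > hit_threshold & !nzchar(records$flags)
  records
}

#' Secondary screen delta score and ranking
#'
#' The secondary screen scores each compound as the unnormalized
#' difference \eqn{\Delta = \overline{cFRET/donor}_{compound} -
#' \overline{cFRET/donor}_{DMSO}} and ranks compounds by descending
#' delta (ties broken by compound id).
#'
#' @param wells well-summary data.frame as in [score_primary()]
#'   (beta-lapachone wells are not required).
#' @return data.frame: compound_id, delta, rank (sorted by rank).
#' @examples
#' scr <- gen_screen_dataset(sim_config(n_compounds = 80, seed = 5))
#' co <- corrected_fret(scr$roi, list(alpha = 0.2, beta = 0.1))
#' head(score_secondary(aggregate_wells(co, scr$platemap)))
#' @export
score_secondary <- function(wells) {
  wells <- compound_replicate_means(wells)
  dmso <- wells[wells$role %in% "dmso", , drop = FALSE]
  test <- wells[wells$role %in% "test", , drop = FALSE]
  if (!nrow(dmso)) stop("no DMSO wells in well summary", call. = FALSE)
  if (!nrow(test)) stop("no test wells in well summary", call. = FALSE)
  dmso_mean <- aggregate(mean_cfret_per_donor ~ plate_id + replicate,
                         data = dmso, FUN = mean)
  delta <- vapply(split(test, test$compound_id), function(sub) {
    reps <- sort(unique(sub$replicate))
    comp <- vapply(reps, function(r) {
      mean(sub$mean_cfret_per_donor[sub$replicate == r])
    }, numeric(1))
    ref <- vapply(reps, function(r) {
      p <- sub$plate_id[sub$replicate == r][1]
      v <- dmso_mean$mean_cfret_per_donor[dmso_mean$plate_id == p &
                                            dmso_mean$replicate == r]
      if (!length(v)) stop("plate ", p, " replicate ", r,
                           " has no DMSO wells", call. = FALSE)
      v
    }, numeric(1))
    mean(comp) - mean(ref)
  }, numeric(1))
  out <- data.frame(compound_id = names(delta), delta = unname(delta))
  out <- out[order(-out$delta, out$compound_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Z'-factor assay quality statistic
#'
#' Screening-window statistic
#' \deqn{Z' = 1 - \frac{3 (\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} -
#'   \mu_{neg}|}}
#' computed with sample means and standard deviations of the positive and
#' negative control wells. Values of 0.5 and above indicate an
#' industry-grade screening window; Z' is at most 1 (perfect separation,
#' zero variance).
#'
#' @param pos_values numeric, positive-control well values (>= 2).
#' @param neg_values numeric, negative-control well values (>= 2).
#' @return object of class \code{z_prime_result}: list with
#'   \code{mu_pos}, \code{sd_pos}, \code{mu_neg}, \code{sd_neg},
#'   \code{z_prime}.
#' @examples
#' z_prime(c(1.9, 2.0, 2.1), c(0.9, 1.0, 1.1))$z_prime
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2) {
    stop("z_prime needs at least 2 wells per control group", call. = FALSE)
  }
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n) {
    stop("controls not separated: positive and negative control means are equal",
         call. = FALSE)
  }
  sd_p <- sd(pos_values); sd_n <- sd(neg_values)
  structure(
    list(mu_pos = mu_p, sd_pos = sd_p, mu_neg = mu_n, sd_neg = sd_n,
         z_prime = 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)),
    class = "z_prime_result"
  )
}

#' @export
print.z_prime_result <- function(x, ...) {
  cat(sprintf("Z' = %.3f  (pos %.4g +/- %.3g, neg %.4g +/- %.3g)\n",
              x$z_prime, x$mu_pos, x$sd_pos, x$mu_neg, x$sd_neg))
  invisible(x)
}

#' Count compounds above the primary hit threshold
#'
#' Recount helper for published screen tables: number of compounds whose
#' normalized primary score exceeds (strictly) the threshold, before
#' exclusion filters.
#'
#' @param scores numeric vector of primary scores.
#' @param hit_threshold threshold (default 0.6).
#' @return integer count.
#' @export
count_primary_hits <- function(scores, hit_threshold = 0.6) {
  sum(scores > hit_threshold, na.rm = TRUE)
}
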