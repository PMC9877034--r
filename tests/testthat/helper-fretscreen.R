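# Noise-free configuration: deterministic mixing model, exact identities.
cfg_noise_free <- function(...) {
  sim_config(background_sd = 0, shot_noise_factor = 0, ocr_sd = 0,
             dose_cv = 0, ...)
}

# Small screen used across tests: 80 compounds on one plate pair.
small_screen <- function(seed = 42, ...) {
  gen_screen_dataset(sim_config(n_compounds = 80, seed = seed, ...))
}

# Well summaries straight from a generated screen, using the true
# spectral coefficients.
screen_wells <- function(scr, alpha = 0.2, beta = 0.1) {
  co <- corrected_fret(scr$roi, list(alpha = alpha, beta = beta))
  aggregate_wells(co, scr$platemap)
}

# Direct-transcription oracle for the primary screen on tiny instances:
# per-replicate means, plate-local control normalization, strict
# thresholds. Kept deliberately naive and separate from the package path.
naive_primary <- function(wells, hit_threshold = 0.6, diff_threshold = 0.15,
                          viability_fraction = 0.5) {
  test <- wells[wells$role == "test", ]
  out <- lapply(unique(test$compound_id), function(id) {
    sub <- test[test$compound_id == id, ]
    reps <- sort(unique(sub$replicate))
    rep_means <- dmso <- blap <- numeric(length(reps))
    for (i in seq_along(reps)) {
      r <- reps[i]
      s <- sub[sub$replicate == r, ]
      rep_means[i] <- mean(s$mean_cfret_per_donor)
      plate <- s$plate_id[1]
      ctl <- wells[wells$plate_id == plate & wells$replicate == r, ]
      dmso[i] <- mean(ctl$mean_cfret_per_donor[ctl$role == "dmso"])
      blap[i] <- mean(ctl$mean_cfret_per_donor[ctl$role == "beta_lapachone"])
    }
    S <- (mean(rep_means) - mean(dmso)) / (mean(blap) - mean(dmso))
    rd <- if (length(rep_means) > 1) max(abs(outer(rep_means, rep_means, "-"))) else 0
    # compound-well mean cell count vs its plates' DMSO mean cell count
    refs <- vapply(seq_len(nrow(sub)), function(j) {
      ctl <- wells[wells$plate_id == sub$plate_id[j] & wells$role == "dmso", ]
      mean(ctl$mean_cell_count)
    }, numeric(1))
    cyto <- mean(sub$mean_cell_count) / mean(refs) < viability_fraction
    data.frame(compound_id = id, score = S, replicate_diff = rd,
               cytotoxic = cyto,
               is_hit = S > hit_threshold & rd <= diff_threshold & !cyto)
  })
  do.call(rbind, out)
}
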