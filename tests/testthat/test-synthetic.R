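test_that("config validation rejects unphysical parameter sets", {
  expect_error(sim_config(gain_donor = 0), "positive")
  expect_error(sim_config(f0 = 0.8, E0 = 0.9, positive_control_theta = 1),
               "exceeds 1")
  expect_error(sim_config(dose_grid = c(1, 0.5)), "increasing")
  expect_error(sim_config(dose_grid = c(-1, 1)), "increasing")
  expect_error(sim_config(viability_loss = 1.2), "viability_loss")
  expect_error(sim_config(alpha_true = -0.1), "alpha_true")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_compounds = 40, seed = 5)
  expect_identical(gen_calibration_cells(cfg, n_rois = 24),
                   gen_calibration_cells(cfg, n_rois = 24))
  expect_identical(gen_screen_dataset(cfg), gen_screen_dataset(cfg))
  expect_identical(gen_mito_stress(cfg, n_wells = 2),
                   gen_mito_stress(cfg, n_wells = 2))
  expect_identical(gen_dose_response(cfg), gen_dose_response(cfg))
  expect_identical(gen_images(cfg, n_cells = 3), gen_images(cfg, n_cells = 3))
  # and different seeds give different draws
  expect_false(identical(gen_screen_dataset(cfg),
                         gen_screen_dataset(cfg, seed = 6)))
})

test_that("noise-free calibration populations obey the mixing model exactly", {
  cfg <- cfg_noise_free(alpha_true = 0.2, beta_true = 0.1)
  cal <- gen_calibration_cells(cfg, n_rois = 30)
  pm <- cal$platemap
  role <- pm$role[match(paste(cal$roi$plate_id, cal$roi$well),
                        paste(pm$plate_id, pm$well))]
  d <- cal$roi[role == "donor_only", ]
  a <- cal$roi[role == "acceptor_only", ]
  expect_equal(d$rawfret / d$donor, rep(0.2, nrow(d)))
  expect_equal(d$acceptor, rep(0, nrow(d)))
  expect_equal(a$rawfret / a$acceptor, rep(0.1, nrow(a)))
  expect_equal(a$donor, rep(0, nrow(a)))
})

test_that("null noise-free screen wells all equal the DMSO ratio", {
  cfg <- cfg_noise_free(n_compounds = 40, hit_fraction = 0,
                        cytotoxic_fraction = 0)
  scr <- gen_screen_dataset(cfg)
  ws <- screen_wells(scr)
  r0 <- expected_cfret_per_donor(cfg, 0)
  test_ratios <- ws$mean_cfret_per_donor[ws$role %in% c("test", "dmso")]
  expect_equal(test_ratios, rep(r0, length(test_ratios)), tolerance = 1e-12)
  rp <- expected_cfret_per_donor(cfg, cfg$positive_control_theta)
  blap <- ws$mean_cfret_per_donor[ws$role == "beta_lapachone"]
  expect_equal(blap, rep(rp, length(blap)), tolerance = 1e-12)
})

test_that("mean cFRET/donor increases strictly with theta", {
  cfg <- cfg_noise_free()
  thetas <- seq(0, 1, by = 0.25)
  expect_true(all(diff(expected_cfret_per_donor(cfg, thetas)) > 0))
  # simulated (noisy) well means follow the same ordering on average
  cfgn <- sim_config(n_compounds = 40, seed = 31, hit_fraction = 10 / 40,
                     cytotoxic_fraction = 0)
  scr <- gen_screen_dataset(cfgn)
  ws <- screen_wells(scr)
  tst <- ws[ws$role == "test", ]
  theta <- scr$truth$compounds$theta[match(tst$compound_id,
                                           scr$truth$compounds$compound_id)]
  by_comp <- tapply(tst$mean_cfret_per_donor, tst$compound_id, mean)
  th_comp <- tapply(theta, tst$compound_id, mean)
  # distinct planted effects rank correctly; tied theta = 0 compounds are
  # excluded (their relative order is noise)
  expect_gt(cor(by_comp[th_comp > 0], th_comp[th_comp > 0],
                method = "spearman"), 0.8)
  expect_gt(min(by_comp[th_comp > 0]), max(by_comp[th_comp == 0]))
})

test_that("cytotoxic compounds carry reduced cell counts", {
  cfg <- cfg_noise_free(n_compounds = 40, cytotoxic_fraction = 0.1,
                        hit_fraction = 0, viability_loss = 0.6)
  scr <- gen_screen_dataset(cfg)
  tr <- scr$truth$compounds
  pm <- scr$platemap
  roi <- scr$roi
  cid <- pm$compound_id[match(paste(roi$plate_id, roi$well),
                              paste(pm$plate_id, pm$well))]
  lab <- tr$label[match(cid, tr$compound_id)]
  expect_equal(unique(roi$cell_count[lab %in% "cytotoxic"]),
               round(cfg$cells_per_roi * 0.4))
  expect_equal(unique(roi$cell_count[lab %in% "null"]), cfg$cells_per_roi)
})

test_that("dose-response generator sits exactly on the curve when CV = 0", {
  cfg <- cfg_noise_free()
  dr <- gen_dose_response(cfg)
  tp <- cfg$fourpl_truth
  expect_equal(dr$response,
               four_pl(dr$concentration_um, tp[["a"]], tp[["b"]],
                       tp[["c"]], tp[["d"]]))
  expect_equal(nrow(dr), length(cfg$dose_grid) * cfg$dose_replicates)
})

test_that("mito stress generator annotates injections between phases", {
  cfg <- cfg_noise_free()
  tr <- gen_mito_stress(cfg)
  expect_equal(nrow(tr), 12)
  expect_equal(tr$injection[c(4, 7, 10)],
               c("oligomycin", "fccp", "rotenone_antimycin"))
  expect_equal(tr$ocr, rep(c(100, 40, 150, 20), each = 3))
  expect_warning(
    gen_mito_stress(cfg, phase_means = c(baseline = 100, oligomycin = 120,
                                         fccp = 150, rotenone_antimycin = 20)),
    "canonical ordering")
})

test_that("image generator emits disjoint labeled cells matching its masks", {
  cfg <- cfg_noise_free(seed = 8)
  img <- gen_images(cfg, n_cells = 5)[[1]]
  expect_equal(sort(unique(as.vector(img$mask))), 0:5)
  expect_equal(dim(img$donor), dim(img$mask))
  expect_true(all(img$donor >= 0))
  # pixel values inside a cell follow the mixing model exactly (no noise)
  k <- 3
  fe <- cfg$f0 * cfg$E0
  D <- img$cells$donor_abundance[k]
  expect_equal(unique(img$donor[img$mask == k]), D * (1 - fe))
  expect_error(gen_images(cfg, n_cells = 500), "disjoint")
})
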