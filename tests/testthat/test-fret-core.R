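test_that("corrected_fret implements the spectral correction exactly", {
  r <- data.frame(donor = 1000, acceptor = 800, rawfret = 500)
  out <- corrected_fret(r, list(alpha = 0.2, beta = 0.1))
  expect_equal(out$cfret, 220)
  expect_equal(out$cfret_per_donor, 0.22)
  # alpha = beta = 0 is the identity on the raw FRET channel
  out0 <- corrected_fret(r, list(alpha = 0, beta = 0))
  expect_equal(out0$cfret, 500)
  # negative values are preserved, not clipped
  neg <- corrected_fret(data.frame(donor = 1000, acceptor = 800, rawfret = 100),
                        list(alpha = 0.2, beta = 0.1))
  expect_equal(neg$cfret, -180)
  expect_error(corrected_fret(r, list(alpha = NA, beta = 0)), "finite")
})

test_that("corrected_fret is linear and scale-covariant", {
  set.seed(101)
  co <- list(alpha = 0.23, beta = 0.08)
  for (i in 1:25) {
    r <- data.frame(donor = runif(1, 10, 2000), acceptor = runif(1, 0, 2000),
                    rawfret = runif(1, 0, 2000))
    k <- runif(1, 0.1, 10)
    base <- corrected_fret(r, co)
    scaled <- corrected_fret(r * k, co)
    expect_equal(scaled$cfret, k * base$cfret)
    expect_equal(scaled$cfret_per_donor, base$cfret_per_donor)
    # additivity in each channel
    r2 <- r; r2$rawfret <- r2$rawfret + 100
    expect_equal(corrected_fret(r2, co)$cfret, base$cfret + 100)
  }
})

test_that("donor <= 0 ROIs are flagged invalid, never divided", {
  r <- data.frame(donor = c(1000, 0), acceptor = 0, rawfret = c(500, 50))
  out <- corrected_fret(r, list(alpha = 0.2, beta = 0))
  expect_equal(out$valid, c(TRUE, FALSE))
  expect_true(is.na(out$cfret_per_donor[2]))
})

test_that("alpha/beta estimators recover exact proportionality and fail loudly", {
  d <- data.frame(donor = 100 * (1:25), rawfret = 0.2 * 100 * (1:25))
  expect_equal(estimate_alpha(d)$alpha, 0.2)
  d$rawfret <- 0
  expect_equal(estimate_alpha(d)$alpha, 0)
  expect_error(estimate_alpha(d[1:5, ]), "at least 20")
  expect_error(estimate_alpha(data.frame(donor = rep(0, 25),
                                         rawfret = rep(0, 25))),
               "identically zero")
  a <- data.frame(acceptor = 50 * (1:30), rawfret = 0.1 * 50 * (1:30))
  expect_equal(estimate_beta(a)$beta, 0.1)
  expect_error(estimate_beta(a[1:3, ]), "at least 20")
})

test_that("coefficients recovered from noisy calibration cells within 2%", {
  cfg <- sim_config(alpha_true = 0.2, beta_true = 0.1, seed = 17)
  cal <- gen_calibration_cells(cfg, n_rois = 200)
  co <- estimate_spectral_coefficients(cal$roi, cal$platemap)
  expect_lt(abs(co$alpha - 0.2) / 0.2, 0.02)
  expect_lt(abs(co$beta - 0.1) / 0.1, 0.02)
  expect_equal(co$n_donor_rois, 200)
  expect_equal(co$n_acceptor_rois, 200)
})

test_that("correction with independently estimated coefficients nulls single-fluorophore ROIs", {
  cfg <- sim_config(seed = 23)
  cal_fit <- gen_calibration_cells(cfg, n_rois = 200, seed = 23)
  cal_new <- gen_calibration_cells(cfg, n_rois = 200, seed = 24)
  co <- estimate_spectral_coefficients(cal_fit$roi, cal_fit$platemap)
  pm <- cal_new$platemap
  role <- pm$role[match(paste(cal_new$roi$plate_id, cal_new$roi$well),
                        paste(pm$plate_id, pm$well))]
  fit_pm <- cal_fit$platemap
  fit_role <- fit_pm$role[match(paste(cal_fit$roi$plate_id, cal_fit$roi$well),
                                paste(fit_pm$plate_id, fit_pm$well))]
  for (rl in c("donor_only", "acceptor_only")) {
    sub <- corrected_fret(cal_new$roi[role == rl, ], co)
    chan <- if (rl == "donor_only") "donor" else "acceptor"
    # the SE of the mean residual includes the propagated uncertainty of
    # the estimated slope: se^2 = se_mean^2 + (se_slope * mean(channel))^2
    se_mean <- sd(sub$cfret) / sqrt(nrow(sub))
    x_fit <- cal_fit$roi[[chan]][fit_role == rl]
    resid_sd <- if (rl == "donor_only") co$residual_sd_alpha else co$residual_sd_beta
    se_slope <- resid_sd / sqrt(sum(x_fit^2))
    se <- sqrt(se_mean^2 + (se_slope * mean(sub[[chan]]))^2)
    expect_lt(abs(mean(sub$cfret)), 3 * se)
  }
})

test_that("aggregate_wells computes exact means, SEs and filter flags", {
  r <- data.frame(plate_id = "P1", well = "A01", roi = 1:12,
                  donor = 1000, acceptor = 0, rawfret = 500)
  out <- aggregate_wells(corrected_fret(r, list(alpha = 0, beta = 0)))
  expect_equal(out$mean_cfret_per_donor, 0.5)
  expect_equal(out$se, 0)
  expect_equal(out$n_rois, 12)
  expect_equal(out$qc_flags, "")
  # 8 of 12 ROIs with donor = 0 -> only 4 valid, low_roi_count at min 6
  r2 <- r; r2$donor[1:8] <- 0
  out2 <- aggregate_wells(corrected_fret(r2, list(alpha = 0, beta = 0)),
                          min_rois = 6)
  expect_equal(out2$n_rois, 4)
  expect_match(out2$qc_flags, "low_roi_count")
  # zero valid ROIs -> excluded with flag, NA mean
  r3 <- r; r3$donor <- 0
  out3 <- aggregate_wells(corrected_fret(r3, list(alpha = 0, beta = 0)))
  expect_equal(out3$n_rois, 0)
  expect_match(out3$qc_flags, "no_valid_rois")
  expect_true(is.na(out3$mean_cfret_per_donor))
})

test_that("well means equal direct recomputation and the analytic expectation", {
  scr <- small_screen(seed = 19)
  co <- corrected_fret(scr$roi, list(alpha = 0.2, beta = 0.1))
  ws <- aggregate_wells(co, scr$platemap)
  # oracle: arithmetic mean of included ROI ratios, recomputed directly
  w <- ws[7, ]
  ratios <- co$cfret_per_donor[co$plate_id == w$plate_id & co$well == w$well &
                                 co$valid]
  expect_equal(w$mean_cfret_per_donor, mean(ratios))
  expect_equal(w$se, sd(ratios) / sqrt(length(ratios)))
  # closed-form mixing-model limit for DMSO wells, noise on
  cfg <- sim_config(n_compounds = 80, seed = 19)
  dmso <- ws[ws$role == "dmso", ]
  r0 <- expected_cfret_per_donor(cfg, 0)
  pooled_se <- sd(dmso$mean_cfret_per_donor) / sqrt(nrow(dmso))
  expect_lt(abs(mean(dmso$mean_cfret_per_donor) - r0), 3 * pooled_se + 1e-3)
})

test_that("photobleach efficiency is donor dequenching with bleach checks", {
  p <- data.frame(pre_donor = c(80, 80), post_donor = c(100, 100),
                  pre_acceptor = c(60, 60), post_acceptor = c(5, 6))
  res <- photobleach_fret_efficiency(p)
  expect_equal(res$regions$efficiency, c(0.2, 0.2))
  expect_true(all(res$regions$bleached))
  # pre = post donor -> E = 0, non-significant
  q <- data.frame(pre_donor = c(90, 95, 100), post_donor = c(90, 95, 100),
                  pre_acceptor = 60, post_acceptor = 5)
  res_q <- photobleach_fret_efficiency(q)
  expect_equal(res_q$regions$efficiency, rep(0, 3))
  expect_gt(res_q$p_value, 0.05)
  # unbleached region flagged
  u <- data.frame(pre_donor = c(80, 80), post_donor = c(100, 100),
                  pre_acceptor = c(60, 60), post_acceptor = c(70, 5))
  expect_equal(photobleach_fret_efficiency(u)$regions$bleached, c(FALSE, TRUE))
  expect_error(photobleach_fret_efficiency(p[1, ]), "at least 2")
  expect_error(photobleach_fret_efficiency(transform(p, post_donor = 0)),
               "> 0")
})

test_that("noise-free full-bleach simulation returns E = f * E0 exactly", {
  cfg <- cfg_noise_free(seed = 4)
  fe <- cfg$f0 * cfg$E0
  set.seed(4)
  D <- rlnorm(9, cfg$donor_meanlog, cfg$donor_sdlog)
  A <- rlnorm(9, cfg$acceptor_meanlog, cfg$acceptor_sdlog)
  pairs <- data.frame(
    pre_donor = cfg$gain_donor * D * (1 - fe),   # quenched by transfer
    post_donor = cfg$gain_donor * D,             # fully dequenched
    pre_acceptor = cfg$gain_acceptor * A,
    post_acceptor = 0                            # complete bleach
  )
  res <- photobleach_fret_efficiency(pairs)
  expect_equal(res$regions$efficiency, rep(fe, 9))
  expect_equal(res$mean_efficiency, fe)
  expect_lt(res$p_value, 0.001)
})
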