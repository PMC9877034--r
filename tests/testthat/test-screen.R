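test_that("primary normalization hits its identity points", {
  expect_equal(primary_score(1.0, 1.0, 1.2)$score, 0)   # DMSO-like
  expect_equal(primary_score(1.2, 1.0, 1.2)$score, 1)   # positive-control-like
  expect_equal(primary_score(1.30, 1.00, 1.20)$score, 1.5)
  expect_equal(primary_score(c(1.3, 1.3), c(1.0, 1.0), c(1.2, 1.2))$score, 1.5)
  expect_error(primary_score(1.1, 1.0, 1.0 + 1e-12), "not separated")
})

test_that("exclusion filters use strict inequalities at the thresholds", {
  rec <- data.frame(compound_id = c("a", "b", "c"),
                    replicate_diff = c(0.16, 0.15, 0.14),
                    cell_count_fraction = 1)
  out <- apply_exclusion_filters(rec, diff_threshold = 0.15)
  expect_equal(grepl("replicate_inconsistent", out$flags),
               c(TRUE, FALSE, FALSE))
  # hit threshold strict at 0.6
  sc <- data.frame(compound_id = c("x", "y", "z"),
                   score = c(0.61, 0.60, 0.59), flags = "")
  hits <- select_primary_hits(sc, hit_threshold = 0.6)
  expect_equal(hits$is_hit, c(TRUE, FALSE, FALSE))
  # flagged compounds are never hits regardless of score
  sc2 <- data.frame(compound_id = "w", score = 0.9, flags = "cytotoxic")
  expect_false(select_primary_hits(sc2)$is_hit)
  # missing replicate -> incomplete flag
  inc <- apply_exclusion_filters(
    data.frame(compound_id = "v", replicate_diff = 0,
               cell_count_fraction = 1, incomplete = TRUE))
  expect_match(inc$flags, "incomplete")
})

test_that("simulator cytotoxic compounds get flagged and null screens score zero", {
  cfg <- cfg_noise_free(n_compounds = 80, cytotoxic_fraction = 0.1,
                        hit_fraction = 0.1, hit_theta_range = c(1, 1),
                        seed = 13)
  scr <- gen_screen_dataset(cfg)
  ws <- screen_wells(scr)
  pr <- score_primary(ws)
  tr <- scr$truth$compounds
  lab <- tr$label[match(pr$compound_id, tr$compound_id)]
  expect_true(all(grepl("cytotoxic", pr$flags[lab == "cytotoxic"])))
  expect_true(all(pr$flags[lab != "cytotoxic"] == ""))
  # noise-free identities: theta = 0 compounds score exactly 0,
  # theta = positive-control compounds exactly 1
  expect_equal(pr$score[lab == "null"], rep(0, sum(lab == "null")))
  expect_equal(pr$score[lab == "hit"], rep(1, sum(lab == "hit")))
})

test_that("primary screen matches a naive direct-transcription oracle", {
  scr <- small_screen(seed = 3, hit_fraction = 0.1, cytotoxic_fraction = 0.05)
  ws <- screen_wells(scr)
  pr <- score_primary(ws)
  oracle <- naive_primary(ws)
  m <- match(pr$compound_id, oracle$compound_id)
  expect_equal(pr$score, oracle$score[m])
  expect_equal(pr$replicate_diff, oracle$replicate_diff[m])
  expect_equal(grepl("cytotoxic", pr$flags), oracle$cytotoxic[m])
  expect_equal(pr$is_hit, oracle$is_hit[m])
})

test_that("primary score is affine-invariant and order-independent", {
  scr <- small_screen(seed = 29, hit_fraction = 0.1)
  ws <- screen_wells(scr)
  pr <- score_primary(ws)
  set.seed(77)
  for (i in 1:10) {
    off <- runif(1, -5, 5)
    k <- runif(1, 0.2, 5)
    ws_off <- ws; ws_off$mean_cfret_per_donor <- ws$mean_cfret_per_donor + off
    expect_equal(score_primary(ws_off)$score, pr$score, tolerance = 1e-9)
    ws_k <- ws; ws_k$mean_cfret_per_donor <- ws$mean_cfret_per_donor * k
    expect_equal(score_primary(ws_k)$score, pr$score, tolerance = 1e-9)
  }
  # permuting well rows changes nothing
  ws_perm <- ws[sample(nrow(ws)), ]
  pr_perm <- score_primary(ws_perm)
  expect_equal(pr_perm[order(pr_perm$compound_id), ],
               pr[order(pr$compound_id), ], ignore_attr = TRUE)
})

test_that("secondary deltas are raw differences, ranked with lexicographic ties", {
  # arithmetic on the published scale: 2.65 - 1.00 = 1.65
  wells <- data.frame(
    plate_id = "P1", well = c("A01", "A02", "B02", "C02"),
    mean_cfret_per_donor = c(1.00, 2.65, 1.00, 1.80),
    mean_cell_count = 50,
    compound_id = c("DMSO", "mns", "aaa", "bbb"),
    role = c("dmso", "test", "test", "test"), replicate = 1
  )
  sec <- score_secondary(wells)
  expect_equal(sec$delta[sec$compound_id == "mns"], 1.65)
  expect_equal(sec$delta[sec$compound_id == "aaa"], 0)
  expect_equal(sec$rank, 1:3)
  expect_equal(sec$compound_id[1], "mns")
  # exact ties resolved by compound id
  wells$mean_cfret_per_donor[wells$compound_id %in% c("aaa", "bbb")] <- 2
  sec2 <- score_secondary(wells)
  expect_equal(sec2$compound_id, c("mns", "aaa", "bbb"))
  expect_equal(sec2$delta, c(1.65, 1, 1))
  # scaling all values scales deltas proportionally
  ws <- wells; ws$mean_cfret_per_donor <- ws$mean_cfret_per_donor * 3
  expect_equal(score_secondary(ws)$delta, sec2$delta * 3)
})

test_that("secondary ranking recovers the planted effect-size order", {
  scr <- small_screen(seed = 41, hit_fraction = 0.25,
                      hit_theta_range = c(0.2, 1.3))
  ws <- screen_wells(scr)
  sec <- score_secondary(ws)
  theta <- scr$truth$compounds$theta[match(sec$compound_id,
                                           scr$truth$compounds$compound_id)]
  # among compounds with distinct planted effects, delta tracks theta;
  # zero-theta compounds are excluded because their rank order is pure
  # noise around delta = 0 (ties in truth)
  act <- theta > 0
  expect_gt(cor(sec$delta[act], theta[act], method = "spearman"), 0.9)
  expect_gt(min(sec$delta[act]), max(sec$delta[!act]))
})

test_that("z_prime matches the closed form and its limits", {
  # exact sample moments: two points at mu +/- sd/sqrt(2)
  mk <- function(mu, s) mu + c(-1, 1) * s / sqrt(2)
  z <- z_prime(mk(2, 0.1), mk(1, 0.1))
  expect_equal(z$z_prime, 0.4)
  expect_equal(z$mu_pos, 2)
  expect_equal(z$sd_pos, 0.1)
  # zero SDs -> perfect assay
  expect_equal(z_prime(c(2, 2, 2), c(1, 1, 1))$z_prime, 1)
  expect_error(z_prime(c(1, 1), c(1, 1)), "not separated")
  expect_error(z_prime(2, c(1, 1)), "at least 2")
  # z' <= 1 always; strictly decreasing in either SD
  set.seed(55)
  for (i in 1:20) {
    pos <- rnorm(8, 2, runif(1, 0.01, 0.5))
    neg <- rnorm(8, 1, runif(1, 0.01, 0.5))
    expect_lte(z_prime(pos, neg)$z_prime, 1)
  }
  z1 <- z_prime(mk(2, 0.1), mk(1, 0.1))$z_prime
  z2 <- z_prime(mk(2, 0.2), mk(1, 0.1))$z_prime
  z3 <- z_prime(mk(2, 0.1), mk(1, 0.2))$z_prime
  expect_true(z2 < z1 && z3 < z1)
})

test_that("count_primary_hits applies the strict threshold", {
  expect_equal(count_primary_hits(c(0.61, 0.60, 0.59, NA, 2)), 2)
})
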