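test_that("RBE weighting combines components as a weighted sum", {
  g <- build_grid(1, 1, 20)
  dc <- structure(list(alpha = matrix(0.5), li7 = matrix(0.3),
                       gamma = matrix(0.2), neutron_residual = matrix(0.1),
                       grid = g, run_id = 1L, seed = 1),
                  class = "dose_components")
  # hand arithmetic: 3.8*(0.5+0.3) + 1.0*0.2 + 3.2*0.1 = 3.56
  d <- weight_components(dc, rbe_weights(w_boron = 3.8, w_gamma = 1,
                                         w_neutron = 3.2))
  expect_equal(d[1, 1], 3.56)
  # identity weights give the plain sum; zero components give zero
  expect_equal(weight_components(dc, rbe_weights(1, 1, 1))[1, 1], 1.1)
  dz <- dc
  for (nm in c("alpha", "li7", "gamma", "neutron_residual")) dz[[nm]] <- matrix(0)
  expect_equal(weight_components(dz)[1, 1], 0)
})

test_that("prescription calibration rescales to the prescribed tumour maximum", {
  tumour <- matrix(TRUE, 3, 3)
  f <- matrix(seq(10, 36.7, length.out = 9), 3, 3)
  cal <- calibrate_prescription(f, tumour)
  expect_equal(cal$scale, 2)                       # 73.4 / 36.7
  expect_equal(max(cal$bio[tumour]), 73.4)
  # already calibrated -> scale 1 (idempotence)
  cal2 <- calibrate_prescription(cal$bio, tumour)
  expect_equal(cal2$scale, 1)
  expect_equal(cal2$bio, cal$bio)
  # ensemble: one scale from the mean, applied to every run
  runs <- list(f * 0.9, f * 1.1)
  cale <- calibrate_prescription(runs, tumour)
  expect_equal(max(Reduce(`+`, cale$bio) / 2), 73.4)
  expect_equal(cale$bio[[2]] / cale$bio[[1]],
               matrix(1.1 / 0.9, 3, 3))
  expect_error(calibrate_prescription(f * 0, tumour), "zero")
  expect_error(calibrate_prescription(f, tumour & FALSE), "no cells")
})

test_that("radiosensitivity sampling is truncated, seeded, with the right moments", {
  g <- toy_grid(20)
  rs <- sample_radiosensitivity(g, seed = 10)
  rs2 <- sample_radiosensitivity(g, seed = 10)
  expect_identical(rs$alpha, rs2$alpha)
  expect_identical(rs$beta, rs2$beta)
  expect_true(all(rs$alpha > 0))
  expect_true(all(rs$beta >= 0))

  # homogeneous limit
  h <- sample_radiosensitivity(g, alpha_mean = 0.3, alpha_sd = 0,
                               beta_mean = 0.03, beta_sd = 0, seed = 1)
  expect_true(all(h$alpha == 0.3) && all(h$beta == 0.03))

  # law of large numbers against the closed-form truncated-normal mean
  big <- build_grid(1000, 1000, 20)
  rb <- sample_radiosensitivity(big, alpha_mean = 0.3, alpha_sd = 0.12,
                                seed = 2)
  z <- 0.3 / 0.12
  trunc_mean <- 0.3 + 0.12 * stats::dnorm(z) / stats::pnorm(z)
  se <- 0.12 / sqrt(1e6)
  expect_lt(abs(mean(rb$alpha) - trunc_mean), 3 * se)
})

test_that("OER field is unity for BNCT and a monotone hypoxic core for EBRT", {
  g <- toy_grid(81)
  expect_equal(build_oer_field(g, "bnct"), matrix(1, 81, 81))
  expect_equal(build_oer_field(g, "ebrt", oer_max = 1), matrix(1, 81, 81))
  oer <- build_oer_field(g, "ebrt", oer_max = 3, core_radius_mm = 1)
  expect_equal(oer[41, 41], 3)
  expect_true(all(oer >= 1 & oer <= 3))
  # brute-force monotone non-increase along rays
  for (ray in list(oer[41, 41:81], oer[41:81, 41],
                   oer[cbind(41:81, 41:81)]))
    expect_true(all(diff(ray) <= 0))
  # ~1 at the ME boundary
  r <- radial_distance_field(g)
  expect_true(all(abs(oer[r > 40] - 1) < 1e-12))
  expect_error(build_oer_field(g, "ebrt", oer_max = 0.5), "oer_max")
})

test_that("single-fraction LQ survival follows the MEP-weighted closed form", {
  g <- build_grid(1, 1, 20)
  one <- bnctsf:::new_mep_field(matrix(1), g, "circular", list())
  rs <- homogeneous_rs(g, 0.3, 0.03)
  # alpha=0.3, beta=0.03, d=2 -> exp(-0.72)
  sp <- survival_bnct(one, matrix(2), rs)
  expect_equal(sp[1, 1], exp(-0.72))
  expect_equal(exp(-0.72), 0.48675, tolerance = 1e-4)
  # d = 0 -> SP == MEP; MEP = 0 -> SP == 0
  expect_equal(survival_bnct(one, matrix(0), rs)[1, 1], 1)
  zero <- bnctsf:::new_mep_field(matrix(0), g, "circular", list())
  expect_equal(survival_bnct(zero, matrix(50), rs)[1, 1], 0)
  expect_error(survival_bnct(one, matrix(-1), rs), "negative")
})

test_that("SP is bounded by MEP and monotone in dose and radiosensitivity", {
  g <- toy_grid(41)
  mep <- mep_circular(g)
  rs <- sample_radiosensitivity(g, seed = 3)
  for (scale in c(0.5, 1, 2, 10)) {
    d <- matrix(scale, 41, 41) * lateral_beam_profile(g, 15, 2) * 10
    sp <- survival_bnct(mep, d, rs)
    expect_true(all(sp >= 0 & sp <= mep$values + 1e-15))
  }
  d1 <- matrix(5, 41, 41); d2 <- matrix(10, 41, 41)
  expect_true(all(survival_bnct(mep, d2, rs) <= survival_bnct(mep, d1, rs)))
  rs_hot <- homogeneous_rs(g, 0.6, 0.06)
  rs_cold <- homogeneous_rs(g, 0.3, 0.03)
  expect_true(all(survival_bnct(mep, d1, rs_hot) <=
                    survival_bnct(mep, d1, rs_cold)))
})

test_that("fractionated EBRT survival reduces to the single-fraction form", {
  g <- toy_grid(81)
  mep <- mep_circular(g)
  masks <- make_roi_masks(g, 25)
  rs <- sample_radiosensitivity(g, seed = 5)
  oer1 <- build_oer_field(g, "bnct")  # all ones

  f1 <- generate_ebrt_field(g, 25, masks$gtv, fraction_dose_gy = 2,
                            n_fractions = 1, boost_gy = 0, noise_rel_sd = 0)
  expect_equal(survival_ebrt(mep, f1, rs, oer1),
               survival_bnct(mep, f1$fraction_dose, rs))

  # scalar oracle: 30 x 2 Gy, alpha=0.3, beta=0.03, OER=1 -> exp(-21.6)
  g1 <- build_grid(1, 1, 20)
  one <- bnctsf:::new_mep_field(matrix(1), g1, "circular", list())
  f30 <- structure(list(fraction_dose = matrix(2),
                        boost_fraction_dose = matrix(0),
                        n_fractions = 30L, n_boost_fractions = 0L,
                        grid = g1, run_id = 1L, seed = 1),
                   class = "ebrt_field")
  expect_equal(survival_ebrt(one, f30, homogeneous_rs(g1, 0.3, 0.03),
                             matrix(1))[1, 1],
               exp(-30 * 0.72))

  # raising OER in a cell strictly increases its survival
  sp1 <- survival_ebrt(one, f30, homogeneous_rs(g1, 0.3, 0.03), matrix(1))
  sp2 <- survival_ebrt(one, f30, homogeneous_rs(g1, 0.3, 0.03), matrix(2))
  expect_gt(sp2[1, 1], sp1[1, 1])
})

test_that("heterogeneous mean survival matches an independent Monte Carlo average", {
  g <- build_grid(300, 300, 20)
  one <- bnctsf:::new_mep_field(matrix(1, 300, 300), g, "circular", list())
  rs <- sample_radiosensitivity(g, alpha_mean = 0.3, alpha_sd = 0.1,
                                beta_mean = 0.03, beta_sd = 0.01, seed = 8)
  d <- 2
  sp <- survival_bnct(one, matrix(d, 300, 300), rs)
  # independent draw of the same expectation
  set.seed(987)
  a <- stats::rnorm(3e5, 0.3, 0.1); a <- a[a > 0][1:2e5]
  b <- stats::rnorm(3e5, 0.03, 0.01); b <- b[b >= 0][1:2e5]
  oracle <- exp(-(a * d + b * d^2))
  se <- stats::sd(oracle) / sqrt(length(oracle)) + stats::sd(sp) / sqrt(length(sp))
  expect_lt(abs(mean(sp) - mean(oracle)), 4 * se)
})
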