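test_that("survivor counts and initial cells match brute-force loop oracles", {
  g <- toy_grid(50)
  mep <- mep_circular(g)
  rs <- sample_radiosensitivity(g, seed = 2)
  d <- 40 * lateral_beam_profile(g, 15, 2)
  sp <- survival_bnct(mep, d, rs)
  masks <- make_roi_masks(g, 15)

  for (mask in list(masks$in_beam, masks$penumbra, masks$out_of_field)) {
    expect_equal(count_survivors(sp, mask), brute_masked_sum(sp, mask))
    expect_equal(initial_tumour_cells(mep, mask),
                 brute_masked_sum(mep$values, mask))
  }
  expect_equal(count_survivors(sp), sum(sp))
  expect_equal(count_survivors(sp * 0), 0)
  # linearity: uniform SP over a 10-cell ROI
  roi <- matrix(FALSE, 50, 50); roi[1, 1:10] <- TRUE
  expect_equal(count_survivors(matrix(0.5, 50, 50), roi), 5)
})

test_that("regional SFs are conserved and additive under the global denominator", {
  g <- toy_grid(50)
  mep <- mep_circular(g)
  rs <- sample_radiosensitivity(g, seed = 6)
  sp <- survival_bnct(mep, 30 * lateral_beam_profile(g, 15, 2), rs)
  masks <- make_roi_masks(g, 15)

  sf_beam <- region_sf(sp, mep, masks$in_beam)
  sf_pen <- region_sf(sp, mep, masks$penumbra)
  sf_out <- region_sf(sp, mep, masks$out_of_field)
  sf_tot <- region_sf(sp, mep, NULL)
  expect_equal(sf_beam + sf_pen + sf_out, sf_tot, tolerance = 1e-12)

  # zero dose: SP == MEP, total SF = 100%
  expect_equal(region_sf(survival_bnct(mep, mep$values * 0, rs), mep), 100)
  # SP = MEP / 2 -> 50%
  expect_equal(region_sf(mep$values / 2, mep), 50)
  # undefined SF errors out explicitly
  empty <- bnctsf:::new_mep_field(matrix(0, 50, 50), g, "circular", list())
  expect_error(region_sf(sp, empty), "undefined")
})

test_that("differential SF is a per-shell ratio that recombines to the total", {
  g <- toy_grid(101)  # wide enough to include empty (MEP = 0) outer shells
  mep <- mep_circular(g)
  rs <- sample_radiosensitivity(g, seed = 9)
  sp <- survival_bnct(mep, 30 * lateral_beam_profile(g, 15, 2), rs)
  shells <- shell_decomposition(g, 0.5)
  tab <- differential_sf(sp, mep, shells)

  # per-shell values match masked loop sums
  for (k in c(0L, 5L, 20L)) {
    mask <- shells$shell_index == k
    expect_equal(tab$sf[tab$shell == k],
                 100 * brute_masked_sum(sp, mask) /
                   brute_masked_sum(mep$values, mask))
  }
  # zero dose -> every defined shell reports 100%
  tab0 <- differential_sf(mep$values, mep, shells)
  expect_true(all(tab0$sf[!is.na(tab0$sf)] == 100))
  # shells with no tumour cells are undefined (NA), not zero
  expect_true(all(is.na(tab$sf[tab$initial_cells == 0])))
  # survivor-weighted recombination reproduces the global SF
  expect_equal(100 * sum(tab$survivors) / initial_tumour_cells(mep),
               region_sf(sp, mep), tolerance = 1e-12)
  # single-shell decomposition reduces to per-region SF
  wide <- shell_decomposition(g, shell_width_mm = 1000)
  tab1 <- differential_sf(sp, mep, wide)
  expect_equal(tab1$sf[1], region_sf(sp, mep, NULL, "per_region"))
})

test_that("run statistics reduce to the two-point mean and SD", {
  pr <- data.frame(run = 1:2, sf_total = c(2, 4))
  st <- run_statistics(pr)
  expect_equal(unname(st$mean["sf_total"]), 3)
  expect_equal(unname(st$sd["sf_total"]), sqrt(2))
  # identical runs -> SD 0
  st0 <- run_statistics(data.frame(run = 1:3, sf_total = c(5, 5, 5)))
  expect_equal(unname(st0$sd["sf_total"]), 0)
  # matches an independent statistics routine on 4 synthetic runs
  x <- c(3.97, 4.1, 3.8, 4.05)
  st4 <- run_statistics(data.frame(run = 1:4, sf_total = x))
  expect_equal(unname(st4$mean["sf_total"]), sum(x) / 4)
  expect_equal(unname(st4$sd["sf_total"]),
               sqrt(sum((x - mean(x))^2) / 3))
  expect_error(run_statistics(data.frame(run = 1, sf_total = 1)), ">= 2")
})

test_that("SF change is the relative reduction and handles signs and zeros", {
  expect_equal(sf_change(4, 1), 75)
  expect_equal(sf_change(7.43, 2.27), 100 * (7.43 - 2.27) / 7.43)
  expect_equal(sf_change(7.43, 2.27), 69.4482, tolerance = 1e-5)
  expect_equal(sf_change(3, 3), 0)
  expect_lt(sf_change(2, 3), 0)   # a larger margin may worsen SF
  expect_error(sf_change(0, 1), "zero baseline")
})

test_that("SF-change Monte Carlo has uniform-range moments and is seeded", {
  # all runs equal -> mean that value, SD exactly 0
  mc0 <- sfchange_mc(c(70, 70, 70), seed = 1)
  expect_equal(mc0$mean, 70)
  expect_identical(mc0$sd, 0)
  # determinism
  expect_identical(sfchange_mc(c(60, 80), seed = 5),
                   sfchange_mc(c(60, 80), seed = 5))
  # large-sample moments of U(60, 80): mean 70, SD 20 / sqrt(12)
  mc <- sfchange_mc(c(60, 80), n_samples = 2e5, seed = 3)
  expect_equal(mc$mean, 70, tolerance = 0.005)
  expect_equal(mc$sd, 20 / sqrt(12), tolerance = 0.02)
  expect_error(sfchange_mc(70), ">= 2")
})

test_that("modality comparison is a symmetric two-sided Welch test", {
  set.seed(31)
  a <- stats::rnorm(10, 70, 1)
  b <- stats::rnorm(10, 10, 1)
  expect_lt(compare_modalities(a, b), 0.001)
  expect_equal(compare_modalities(a, b), compare_modalities(b, a))
  # matches stats::t.test directly
  expect_equal(compare_modalities(a, b),
               stats::t.test(a, b, var.equal = FALSE)$p.value)
  # identical degenerate samples -> p = 1 by convention
  expect_equal(compare_modalities(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_error(compare_modalities(1, c(1, 2)), ">= 2")
})
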