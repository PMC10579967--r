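test_that("degenerate noise returns the latent counts and seeds reproduce", {
  kin <- preset_kinetics("CXCL10")
  ad <- preset_adaptation()
  tm <- gen_population(kin, ad, "constant:10", n_cells = 25,
                       noise = no_noise(), seed = 31)
  expect_equal(unname(tm$values), unname(tm$metadata$truth$protein),
               ignore_attr = TRUE)

  tm2 <- gen_population(kin, ad, "constant:10", n_cells = 25,
                        noise = no_noise(), seed = 31)
  expect_identical(tm$values, tm2$values)
  tm3 <- gen_population(kin, ad, "constant:10", n_cells = 25,
                        noise = no_noise(), seed = 32)
  expect_false(identical(tm$values, tm3$values))
})

test_that("the noiseless population mean converges on the mean-field solution", {
  kin <- preset_kinetics("IRF1")
  ad <- preset_adaptation()
  tm <- gen_population(kin, ad, "constant:10", n_cells = 1000,
                       noise = no_noise(), seed = 12)
  m <- colMeans(tm$values)
  sem <- apply(tm$values, 2, stats::sd) / sqrt(nrow(tm$values))
  sol <- integrate_model(kin, ad, "constant:10", tm$time)
  expect_lt(max(abs(m - sol$P) / pmax(sem, 1e-12)), 3)
})

test_that("the condition suite feeds the fitting layer consistently", {
  kin <- preset_kinetics("CXCL10")
  ad <- preset_adaptation()
  # unit gains: the generating parameters give (numerically) zero loss
  suite <- gen_condition_suite(kin, ad, mean_mode = "ode",
                               plate_gain = 1, chip_gain = 1)
  expect_length(suite$conditions, 9)
  expect_lt(model_loss(kin, ad, suite$conditions), 1e-6)

  # a 2x plate/chip gain difference is recovered by the bridging factor
  suite2 <- gen_condition_suite(kin, ad, mean_mode = "ode",
                                plate_gain = 2, chip_gain = 1)
  prep <- prepare_dataset(suite2$conditions, plate_ref = "plate_10",
                          chip_ref = "chip_const")
  expect_equal(prep$chip_factor, 2, tolerance = 1e-9)

  # the 12-h plate mask lands on plate conditions only
  suite3 <- gen_condition_suite(kin, ad, mean_mode = "ode",
                                mask_plate_12h = TRUE)
  for (cond in suite3$conditions) {
    if (cond$platform == "plate") expect_equal(cond$fit_mask[2], 12)
    else expect_null(cond$fit_mask)
  }
})

test_that("mean dose response is monotone in IFNg concentration", {
  kin <- preset_kinetics("CXCL9")
  ad <- preset_adaptation()
  suite <- gen_condition_suite(kin, ad, mean_mode = "ode")
  plate <- Filter(function(cd) cd$platform == "plate", suite$conditions)
  concs <- vapply(plate, function(cd) cd$protocol$segments$ifng, numeric(1))
  plate <- plate[order(concs)]
  for (i in seq_len(length(plate) - 1)) {
    expect_true(all(plate[[i + 1]]$value >= plate[[i]]$value - 1e-9))
  }
})

test_that("slow-opening synthetic populations keep a stable nonresponder fraction", {
  kin <- preset_kinetics("CXCL10")
  ad <- preset_adaptation()
  fracs <- vapply(c(51, 52, 53), function(s) {
    tm <- gen_population(kin, ad, "constant:10", n_cells = 300,
                         noise = no_noise(), seed = s)
    mean(apply(tm$values, 1, max) < 5)
  }, numeric(1))
  expect_true(all(fracs > 0.3))
  # binomial-scale fluctuation only across regenerated seeds
  expect_lt(max(fracs) - min(fracs), 4 * sqrt(0.25 / 300) * 2)
})
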