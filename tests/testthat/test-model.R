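test_that("TF input saturates, reduces without feedback, and halves at the regulator threshold", {
  kin <- toy_kinetics()
  ad <- toy_adaptation()

  expect_equal(tf_level(1e6, kin, no_adaptation()), 1, tolerance = 1e-12)
  expect_equal(tf_level(0, toy_kinetics(alpha = 1, Kd = 0), no_adaptation()), 0)

  # disabling the feedback reduces exactly to the open-loop input
  ifng <- c(0, 0.1, 1, 5, 20)
  expect_identical(tf_level(ifng, kin, no_adaptation(), regP = 123),
                   tanh(kin$alpha * (ifng + kin$Kd)))

  # regP at the half-suppression scale with unit exponent halves the input
  ad1 <- toy_adaptation(c1 = 1)
  expect_equal(tf_level(3, kin, ad1, regP = ad1$reg_thr),
               tanh(kin$alpha * (3 + kin$Kd)) / 2)

  expect_error(tf_level(-1, kin, ad), "ifng")
  expect_error(tf_level(1, kin, ad, regP = -5), "regP")
})

test_that("TF input is monotone in stimulus and in regulator level", {
  kin <- toy_kinetics()
  ad <- toy_adaptation()
  ifng <- seq(0, 30, length.out = 200)
  for (rp in c(0, 10, 100)) {
    v <- tf_level(ifng, kin, ad, regP = rp)
    expect_true(all(diff(v) >= 0))
  }
  for (cc in c(0.5, 5)) {
    v <- vapply(seq(0, 500, length.out = 150),
                function(rp) tf_level(cc, kin, ad, regP = rp), numeric(1))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("model derivatives match an independent hand evaluation and conserve loci", {
  kin <- toy_kinetics()
  ad <- toy_adaptation()
  st <- model_state(C = 0.8, OU = 0.7, OI = 0.5, M = 2, P = 10,
                    regM = 3, regP = 20)
  d <- ode_rhs(0, st, kin, ad, ifng = 5)
  # frozen term-by-term hand evaluation of the printed equations
  expect_equal(unname(d),
               c(-0.6625936510576989, -0.8758105159555305,
                 1.5384041670132294, 0, 1, 3.2993407674737458, 1),
               tolerance = 1e-12)

  # no active terms at zero TF from the all-closed resting state
  kin0 <- toy_kinetics(Kd = 0)
  d0 <- ode_rhs(0, model_state(2, 0, 0), kin0, no_adaptation(), ifng = 0)
  expect_true(all(d0 == 0))

  # chromatin derivatives cancel for arbitrary states
  set.seed(42)
  for (i in 1:25) {
    y <- model_state(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2),
                     runif(1, 0, 10), runif(1, 0, 50),
                     runif(1, 0, 20), runif(1, 0, 200))
    d <- ode_rhs(0, y, kin, ad, ifng = runif(1, 0, 20))
    expect_equal(unname(d[["C"]] + d[["OU"]] + d[["OI"]]), 0,
                 tolerance = 1e-12)
  }
})

test_that("stationary chromatin occupancies follow the closed form", {
  kin <- toy_kinetics()
  # opening requires TF
  expect_equal(unname(steady_state_chromatin(kin, 0)), c(2, 0, 0))

  # detailed-balance symmetry: equal one-step ratios give (2/3, 2/3, 2/3)
  kin_sym <- toy_kinetics(k1 = 1, k2 = 0.7, k3 = 1, k4 = 0.7)
  ss <- steady_state_chromatin(kin_sym, 0.7)
  expect_equal(unname(ss), rep(2 / 3, 3), tolerance = 1e-12)

  # agrees with the long-time limit of the dynamical system
  tf <- 0.6
  sol <- integrate_model(kin, no_adaptation(),
                         stimulus_protocol(
                           data.frame(t_start = 0, t_end = 400,
                                      ifng = atanh(tf) / kin$alpha - kin$Kd),
                           horizon = 400),
                         times = c(0, 400),
                         init = model_state(2, 0, 0))
  expect_equal(unname(unlist(sol[2, c("C", "OU", "OI")])),
               unname(steady_state_chromatin(kin, tf)), tolerance = 1e-6)

  # degenerate all-absorbing chain is flagged
  dg <- steady_state_chromatin(toy_kinetics(k2 = 0, k4 = 0), 0)
  expect_true(isTRUE(attr(dg, "degenerate")))
  expect_equal(unname(dg), c(2, 0, 0), ignore_attr = TRUE)
})

test_that("equilibration returns a fixed point of the dynamics", {
  # zero basal TF: everything rests at zero
  kin0 <- toy_kinetics(Kd = 0)
  eq0 <- equilibrate(kin0, no_adaptation(), 0)
  expect_equal(unname(eq0), c(2, 0, 0, 0, 0, 0, 0),
               ignore_attr = TRUE)

  # basal TF > 0 without adaptation: matches the closed-form chain
  kin <- toy_kinetics()
  eq <- equilibrate(kin, no_adaptation(), 0)
  tf <- tanh(kin$alpha * kin$Kd)
  expect_equal(unname(eq[c("C", "OU", "OI")]),
               unname(steady_state_chromatin(kin, tf)), tolerance = 1e-10)
  expect_equal(eq[["M"]], kin$k5 * eq[["OI"]] / kin$deltaM, tolerance = 1e-10)

  # with feedback: residual of the rhs vanishes at the returned state
  ad <- toy_adaptation()
  eqa <- equilibrate(kin, ad, 2)
  resid <- ode_rhs(0, eqa, kin, ad, ifng = 2)
  expect_lt(max(abs(resid)), 1e-7 * max(1, max(eqa)))

  # an equilibrated start stays put under integration
  sol <- integrate_model(kin, ad, "constant:0", 0:20, init = equilibrate(kin, ad, 0))
  expect_lt(max(abs(sweep(as.matrix(sol[, -1]), 2,
                          unlist(sol[1, -1])))), 1e-6)
})
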