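test_that("depletion half-life regression recovers known decay constants", {
  t <- c(0, 15, 30, 45)
  th <- fitDepletionHalfLife(t, exp(-0.022697 * t))
  expect_equal(as.numeric(th), 30.54, tolerance = 1e-3)
  expect_equal(attr(th, "k"), 0.022697, tolerance = 1e-6)

  # noisy decay, known k = 0.01/min, recovered within 5%
  set.seed(11)
  tt <- seq(0, 180, length.out = 10)
  conc <- exp(-0.01 * tt) * exp(rnorm(10, 0, 0.03))
  expect_equal(as.numeric(fitDepletionHalfLife(tt, conc)), log(2) / 0.01,
               tolerance = 0.05)

  expect_error(fitDepletionHalfLife(t, rep(1, 4)), "depletion")
  expect_error(fitDepletionHalfLife(c(0, 10), c(1, 0.5)), "3 time points")
  expect_error(fitDepletionHalfLife(c(0, 10, 5), c(1, .5, .7)), "increasing")
})

test_that("clearance scale-up chain reproduces the worked values", {
  cl <- intrinsicClearanceInVitro(30.54, 1, 0.5)
  expect_equal(cl, 0.04539, tolerance = 1e-3)
  expect_equal(intrinsicClearanceInVitro(log(2), 1, 1), 1.0)
  # doubling the half-life halves the clearance
  expect_equal(intrinsicClearanceInVitro(2 * 30.54), cl / 2)

  expect_equal(scaleClearanceToOrgan(cl, 34, 0.0309 * 89 * 1000),
               254.7, tolerance = 1e-3)
  expect_equal(scaleClearanceToOrgan(cl, 3.34, 0.015 * 89 * 1000),
               12.15, tolerance = 1e-2)
  expect_equal(scaleClearanceToOrgan(0, 34, 2750), 0)
  # linear in organ mass
  expect_equal(scaleClearanceToOrgan(cl, 34, 2 * 2750),
               2 * scaleClearanceToOrgan(cl, 34, 2750))
})

test_that("well-stirred clearance respects its limits and bounds", {
  expect_equal(hepaticPlasmaClearance(90, 0.14, 254.7, 1), 25.5,
               tolerance = 1e-2)
  # fu -> 0 kills clearance; small-CLint regime is unbound-limited
  expect_lt(hepaticPlasmaClearance(90, 1e-9, 254.7), 1e-6)
  expect_equal(hepaticPlasmaClearance(90, 0.1, 0.5), 0.1 * 0.5,
               tolerance = 1e-3)
  # flow-limited bound over a parameter sweep: under the printed operator
  # precedence the saturation limit is Q_H times the red-cell:plasma
  # ratio, equal to Q_H itself at ratio 1
  for (fu in c(0.01, 0.3, 1)) for (cli in c(1, 100, 1e5)) {
    expect_lt(hepaticPlasmaClearance(90, fu, cli, 1), 90)
    expect_lt(hepaticPlasmaClearance(90, fu, cli, 2), 180)
  }
})

test_that("fraction unbound follows the binding regression exactly", {
  expect_equal(signif(fractionUnbound(9.54), 3), 0.000158)
  expect_equal(signif(fractionUnbound(5.84), 4), 0.007175)
  expect_equal(fractionUnbound(0.4782 / 0.4485), 0.5)
  # strictly decreasing, inverse identity to machine precision
  lp <- seq(-2, 12, by = 0.25)
  fu <- fractionUnbound(lp)
  expect_true(all(diff(fu) < 0))
  x <- 0.4485 * lp - 0.4782
  expect_equal(fu * (10^x + 1), rep(1, length(lp)), tolerance = 1e-12)
})

test_that("metabolised fractions divide by the five-species molar total", {
  eq <- c(MEHTP = 1, "5OH" = 1, "2cx" = 1, "5cx" = 1, "5oxo" = 1)
  expect_equal(unname(fractionsMetabolised(eq)), rep(0.2, 3))
  only <- c(MEHTP = 2, "5OH" = 0, "2cx" = 0, "5cx" = 0, "5oxo" = 0)
  expect_equal(unname(fractionsMetabolised(only)), rep(0, 3))
  # constructed so the 5cx share is 0.204
  amt <- c(MEHTP = 0.5, "5OH" = 0.024, "2cx" = 0.004, "5cx" = 0.204,
           "5oxo" = 0.268)
  expect_equal(fractionsMetabolised(amt)[["5cx"]], 0.204)
  expect_error(fractionsMetabolised(eq * 0), "positive")
})

test_that("partition lookups resolve surrogates in exactly one hop", {
  ps <- defaultPartitionSet()
  st <- getPartition(ps, "DEHTP", "stomach")
  expect_equal(as.numeric(st), 7.4)
  expect_equal(attr(st, "via"), "gut")
  ad <- getPartition(ps, "DEHTP", "adipose")
  expect_equal(as.numeric(ad), 47.2)
  expect_equal(attr(ad, "via"), "direct")
  expect_equal(as.numeric(getPartition(ps, "MEHTP", "rapidly_perfused")),
               3.7)
  expect_error(getPartition(ps, "DEHTP", "brain"), "no partition")
  # a surrogate donor that itself needs a surrogate is rejected
  expect_error(partitionSet(ps$table,
                            c(stomach = "gut", gut = "spleen")),
               "one hop")
})

test_that("prior sampling matches closed-form quantiles", {
  set.seed(5)
  n <- 2e5
  u <- samplePrior(priorSpec("u", "uniform", 1, 30), n)
  expect_equal(unname(summarisePrior(u)), c(15.5, 1.725, 29.275),
               tolerance = 0.02)
  nn <- samplePrior(priorSpec("n", "normal", 30, 10), n)
  expect_equal(unname(summarisePrior(nn)),
               qnorm(c(0.5, 0.025, 0.975), 30, 10), tolerance = 0.02)
  h <- samplePrior(priorSpec("h", "halfnormal", 10), n)
  expect_equal(median(h), 10 * qnorm(0.75), tolerance = 0.05)
  expect_true(all(h >= 0))
  # truncation is exact and renormalised
  tn <- samplePrior(priorSpec("t", "normal", 0.05, 0.01,
                              lower = 0.0335515, upper = 0.0664485), n)
  expect_true(all(tn >= 0.0335515 & tn <= 0.0664485))
  expect_equal(median(tn), 0.05, tolerance = 1e-3)
  # density renormalisation integrates to one over the truncated support
  dens <- integrate(function(x)
    exp(logPriorDensity(priorSpec("t", "normal", 0.05, 0.01,
                                  lower = 0.0335515, upper = 0.0664485),
                        x)), 0.0335515, 0.0664485)$value
  expect_equal(dens, 1, tolerance = 1e-6)
})

test_that("prior configuration files load and cover the calibrated set", {
  pg <- defaultGlobalPriors()
  pl <- defaultLocalPriors()
  nm <- calibratedParameterNames()
  expect_setequal(names(pg), c(nm$globals, nm$sigmas))
  expect_setequal(names(pl), nm$locals)
  expect_equal(length(nm$globals) + length(nm$sigmas), 18)
  expect_equal(length(nm$locals), 19)
  # spot values: uniform plasma PC and half-normal error SD
  expect_equal(pg$Pbab$family, "uniform")
  expect_equal(c(pg$Pbab$p1, pg$Pbab$p2), c(1, 30))
  expect_equal(pg$sigma_5cx$family, "halfnormal")
  expect_equal(pg$sigma_5cx$p1, 1)
})
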