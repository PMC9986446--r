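test_that("buildModel derives volumes, flows and clearances correctly", {
  ctx <- buildModel()
  expect_equal(ctx$volumes[["liver"]], 0.0309 * 89, tolerance = 1e-8)
  expect_equal(ctx$clIntM, 254.7, tolerance = 1e-3)
  expect_equal(unname(ctx$flows[["total"]]), 14 * 89)
  # flow fractions renormalised to cardiac output
  expect_equal(sum(ctx$flows[setdiff(names(ctx$flows), "total")]),
               ctx$flows[["total"]], tolerance = 1e-10)

  loc <- defaultLocals(); loc$FracDOSEHep <- 0.8; loc$FracDoseLymph <- 0.3
  expect_error(buildModel(loc = loc), "exceeds 1")
  expect_error(buildModel(defaultPhysiology(0)), "positive")
  g <- defaultGlobals(); g$FB_DEHTP <- 1.2
  expect_error(buildModel(glob = g), "outside")
})

test_that("derivatives conserve molar mass and vanish at the origin", {
  ctx <- buildModel()
  y0 <- stats::setNames(numeric(40), stateNames())
  expect_equal(pbpkRhs(0, y0, ctx$parms)[[1]], numeric(40))

  set.seed(2)
  dNames <- grep("^A", stateNames(), value = TRUE)
  for (i in 1:10) {
    y <- stats::setNames(abs(rnorm(40)), stateNames())
    d <- pbpkRhs(0, y, ctx$parms)[[1]]
    names(d) <- stateNames()
    tot <- sum(d[dNames]) + sum(d[setdiff(stateNames(), dNames)]) /
      ctx$parms[["mwRatio"]]
    expect_lt(abs(tot), 1e-10)
  }
})

test_that("compiled derivatives agree with the R reference", {
  set.seed(3)
  for (i in 1:5) {
    tr <- drawKinetics(J = 1)
    glob <- defaultGlobals(); glob[names(tr$globals)] <- tr$globals
    loc <- defaultLocals(); loc[rownames(tr$locals)] <- tr$locals[, 1]
    ctx <- buildModel(glob = glob, loc = loc)
    simC <- simulatePBPK(ctx, data.frame(time = 0, amount = 50),
                         times = seq(0, 24, 2))
    simR <- simulatePBPK(ctx, data.frame(time = 0, amount = 50),
                         times = seq(0, 24, 2), useCompiled = FALSE)
    expect_equal(simC$states, simR$states, tolerance = 1e-6)
  }
})

test_that("simulation is linear in dose and mass-conserving", {
  ctx <- buildModel()
  s1 <- simulatePBPK(ctx, data.frame(time = 0, amount = 52.2),
                     times = seq(0, 48, 0.5))
  s2 <- simulatePBPK(ctx, data.frame(time = 0, amount = 104.4),
                     times = seq(0, 48, 0.5))
  expect_equal(s2$states, 2 * s1$states, tolerance = 1e-6)
  expect_lt(massBalance(s1) / 52.2, 1e-6)
  # cumulative urinary series are non-decreasing and positive by 48 h
  expect_true(all(diff(s1$output$u5cx) >= -1e-12))
  expect_gt(s1$output$u5cx[nrow(s1$output)], 0)
  # no dose, no residual
  s0 <- simulatePBPK(ctx, data.frame(time = 0, amount = 0),
                     times = seq(0, 10, 1))
  expect_equal(as.numeric(massBalance(s0)), 0)
})

test_that("loosening solver tolerances degrades the mass balance", {
  ctx <- buildModel()
  res <- vapply(c(1e-8, 1e-6, 1e-3), function(rt)
    massBalance(simulatePBPK(ctx, data.frame(time = 0, amount = 52.2),
                             times = seq(0, 48, 0.5), rtol = rt,
                             atol = rt * 1e-2)),
    numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("the lymph route is a pure transport delay with known arrival", {
  loc <- defaultLocals(); loc$FracDoseLymph <- 0.2; loc$Lymphlag <- 4
  ctx <- buildModel(loc = loc)
  sim <- simulatePBPK(ctx, data.frame(time = 0, amount = 50),
                      times = seq(0, 12, 0.05))
  aly <- sim$states[, "ALY"]
  expect_true(all(aly[sim$time < 4] == 0))
  # right after arrival the compartment holds the lymph-destined dose
  expect_equal(aly[sim$time == 4], 0.2 * 50, tolerance = 1e-8)
  # and decays at K1_Lymph thereafter (analytic single-bolus solution)
  t5 <- sim$time >= 4
  expect_equal(aly[t5], 10 * exp(-loc$K1_Lymph * (sim$time[t5] - 4)),
               tolerance = 1e-6)

  # ablation: no lymph fraction, compartment identically zero
  loc0 <- loc; loc0$FracDoseLymph <- 0
  sim0 <- simulatePBPK(buildModel(loc = loc0),
                       data.frame(time = 0, amount = 50),
                       times = seq(0, 12, 0.5))
  expect_true(all(sim0$states[, "ALY"] == 0))
})

test_that("each dose event produces its own deposition response", {
  ctx <- buildModel()
  sim <- simulatePBPK(ctx, data.frame(time = c(0, 9.5), amount = c(50, 10)),
                      times = seq(0, 30, 0.05))
  r <- sim$output$r5cx
  # rate rises after the second bolus from its pre-dose level
  i0 <- max(which(sim$time <= 9.5))
  expect_gt(max(r[sim$time > 9.5 & sim$time < 14]), r[i0] * 1.05)
  expect_lt(massBalance(sim) / 60, 1e-6)
})

test_that("interval-average deposition matches brute force on a fixture", {
  # piecewise-linear cumulative curve: rate 1 on [0,2], 3 on [2,4]
  tm <- seq(0, 4, 0.5)
  cum <- ifelse(tm <= 2, tm, 2 + 3 * (tm - 2))
  sim <- fakeSim(tm, cum)
  expect_equal(as.numeric(depositionRateInterval(sim, 0, 2, "5cx")), 1)
  expect_equal(as.numeric(depositionRateInterval(sim, 1, 3, "5cx")),
               (1 + 3) / 2)
  expect_equal(attr(depositionRateInterval(sim, 1, 3, "5cx"), "midpoint"),
               2)
  expect_error(depositionRateInterval(sim, 2, 2, "5cx"), "exceed")
  expect_error(depositionRateInterval(sim, 3, 5, "5cx"), "grid")
})

test_that("absorbed fraction adds the hepatic and lymphatic routes", {
  expect_equal(absorbedFraction(list(FracDOSEHep = 0.031,
                                     FracDoseLymph = 0.263)), 0.294)
  expect_equal(absorbedFraction(list(FracDOSEHep = 0,
                                     FracDoseLymph = 0)), 0)
  expect_equal(absorbedFraction(list(FracDOSEHep = 1,
                                     FracDoseLymph = 0)), 1)
})
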