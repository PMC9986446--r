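test_that("void schedules honour counts, totals and ordering", {
  des <- studyDesign()
  for (s in 1:8) {
    sched <- drawVoidSchedule(des, seed = s)
    expect_gte(nrow(sched), 20); expect_lte(nrow(sched), 23)
    expect_true(all(diff(sched$time_h) > 0))
    expect_equal(sched$time_h[nrow(sched)], 48)
    tot <- sum(sched$volume_L)
    expect_gte(tot, 3.62); expect_lte(tot, 5.59)
    expect_true(all(sched$volume_L > 0))
  }
})

test_that("kinetic draws respect supports and the dose-fraction cap", {
  for (s in 1:6) {
    tr <- drawKinetics(J = 3, seed = s)
    expect_true(tr$globals[["Pbab"]] > 1 && tr$globals[["Pbab"]] < 30)
    expect_true(all(tr$locals["FracDOSEHep", ] +
                      tr$locals["FracDoseLymph", ] <= 1))
    expect_true(all(tr$locals["Lymphlag", ] >= 0.99))
    expect_gte(attr(tr, "rejections"), 0)
  }
})

test_that("drawn body weights stay inside the truncation bounds", {
  des <- studyDesign(nVolunteers = 6, bodyWeights = NULL,
                     bwRange = c(60, 120))
  phys <- drawPhysiology(des, seed = 1)
  bw <- vapply(phys, `[[`, numeric(1), "BW")
  expect_true(all(bw > 49 & bw < 130))
  expect_true(all(bw >= 60 & bw <= 120))
  expect_identical(bw, vapply(drawPhysiology(des, seed = 1), `[[`,
                              numeric(1), "BW"))
})

test_that("zero-noise studies reproduce the model rates exactly", {
  gs <- generateStudy(smallDesign(), truthSlice(2), seed = 17)
  rates <- voidsToRates(gs$data$voids)
  pv <- list(globals = gs$truth$globals, sigmas = gs$truth$sigmas,
             locals = gs$truth$locals)
  mu <- dehtpk:::computeMu(pv, 1, gs$data)
  for (m in c("5OH", "2cx", "5cx")) {
    obs <- rates[rates$metabolite == m, "rate"]
    expect_equal(obs, unname(mu[[m]]), tolerance = 1e-7)
  }
})

test_that("generated studies survive a text round trip", {
  des <- smallDesign(noise = c("5OH" = 0.002, "2cx" = 0.0005,
                               "5cx" = 0.01))
  gs <- generateStudy(des, truthSlice(3), seed = 8)
  path <- tempfile(fileext = ".tsv")
  writeVoids(gs$data$voids, path)
  back <- readVoids(path)
  r1 <- voidsToRates(gs$data$voids)
  r2 <- voidsToRates(back)
  expect_equal(r2$rate, r1$rate, tolerance = 1e-9)
  expect_true(all(r1$rate >= 0))   # truncation: no negative noisy rates
})

test_that("lymph settings shape the deposition-curve morphology", {
  # near the strongly lymphatic volunteer: double peak
  trB <- truthSlice(2)
  desB <- smallDesign()
  gsB <- generateStudy(desB, trB, seed = 5)
  pv <- list(globals = trB$globals, sigmas = trB$sigmas,
             locals = trB$locals)
  ctx <- dehtpk:::ctxForVolunteer(pv, 1, gsB$data)
  sim <- simulatePBPK(ctx, data.frame(time = 0, amount = 52.2),
                      times = seq(0, 48, 0.05))
  expect_gte(countPeaks(sim$output$r5cx), 2)
  # without lymph uptake the late peak disappears
  pv0 <- pv; pv0$locals["FracDoseLymph", 1] <- 0
  ctx0 <- dehtpk:::ctxForVolunteer(pv0, 1, gsB$data)
  sim0 <- simulatePBPK(ctx0, data.frame(time = 0, amount = 52.2),
                       times = seq(0, 48, 0.05))
  expect_lt(countPeaks(sim0$output$r5cx), countPeaks(sim$output$r5cx))
})
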