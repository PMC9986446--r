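mkVoids <- function(times, vols, c5cx, volunteer = 1) {
  data.frame(volunteer = volunteer, time_h = times, volume_L = vols,
             conc_5OH = 0, conc_2cx = 0, conc_5cx = c5cx)
}

test_that("void-to-rate conversion does the interval arithmetic", {
  v <- data.frame(volunteer = 1, time_h = 2, volume_L = 0.25,
                  conc_5OH = 2, conc_2cx = 0, conc_5cx = 1)
  r <- voidsToRates(v)
  r5 <- r[r$metabolite == "5OH", ]
  expect_equal(r5$rate, 2 * 0.25 / 2)       # first interval from t = 0
  expect_equal(r5$midpoint, 1)
  expect_equal(r[r$metabolite == "2cx", "rate"], 0)
})

test_that("rates agree with a brute-force oracle on a five-void fixture", {
  set.seed(9)
  times <- cumsum(runif(5, 0.5, 4))
  vols <- runif(5, 0.1, 0.5)
  conc <- runif(5, 0, 2)
  v <- mkVoids(times, vols, conc)
  r <- voidsToRates(v)
  r5 <- r[r$metabolite == "5cx", ]
  t0 <- c(0, times[-5])
  for (i in 1:5) {
    expect_equal(r5$rate[i], conc[i] * vols[i] / (times[i] - t0[i]))
    expect_equal(r5$midpoint[i], (times[i] + t0[i]) / 2)
    expect_gt(r5$midpoint[i], t0[i]); expect_lt(r5$midpoint[i], times[i])
  }
  # mass conservation of the transformation
  expect_equal(sum(r5$rate * (r5$tEnd - r5$tStart)),
               cumulativeExcretion(v, 48)$m5cx)
  # unit-consistent rescaling leaves rates unchanged
  v2 <- v; v2$volume_L <- v$volume_L * 1000
  v2$conc_5cx <- v$conc_5cx / 1000
  expect_equal(voidsToRates(v2)$rate, r$rate)
})

test_that("cumulative excretion windows are additive", {
  v <- mkVoids(c(6, 20, 30, 40, 48), rep(0.3, 5), c(2, 1, .5, .2, .1))
  tot <- cumulativeExcretion(v, 48)$m5cx
  expect_equal(cumulativeExcretion(v, 24)$m5cx +
                 sum(v$conc_5cx[v$time_h > 24] * v$volume_L[v$time_h > 24]),
               tot)
  # scaled fixture reproduces a prescribed 48-h total
  v3 <- v; v3$conc_5cx <- v$conc_5cx * 2.88 / tot
  expect_equal(cumulativeExcretion(v3, 48)$m5cx, 2.88)
  empty <- cumulativeExcretion(v[0, ], 48)
  expect_equal(nrow(empty), 0)
})

test_that("invalid void records are rejected, valid ones round-trip", {
  v <- mkVoids(c(2, 1), c(0.2, 0.2), c(1, 1))
  expect_error(voidsToRates(v), "increasing")
  v2 <- mkVoids(c(1, 2), c(0.2, -0.1), c(1, 1))
  expect_error(voidsToRates(v2), "positive")
  v3 <- mkVoids(c(1, 2), c(0.2, 0.2), c(1, NA))
  expect_error(voidsToRates(v3), "missing")

  good <- mkVoids(c(1.25, 3.5, 7), c(0.21, 0.33, 0.4), c(0.9, 0.4, 0.2))
  path <- tempfile(fileext = ".tsv")
  writeVoids(good, path)
  back <- readVoids(path)
  expect_equal(back$conc_5cx, good$conc_5cx)
  expect_equal(voidsToRates(back)$rate, voidsToRates(good)$rate)
})
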