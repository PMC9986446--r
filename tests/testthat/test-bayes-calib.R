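test_that("zero-truncated normal log density has the right limits", {
  # truncation negligible far from zero
  expect_equal(truncNormLogDensity(50, 50, 1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # half-normal limit at mu = 0
  expect_equal(truncNormLogDensity(0.5, 0, 1),
               dnorm(0.5, log = TRUE) + log(2))
  expect_equal(truncNormLogDensity(-0.1, 1, 1), -Inf)
})

test_that("log prior rejects support violations and sums marginals", {
  tr <- defaultTruth()
  pv <- list(globals = tr$globals, sigmas = tr$sigmas, locals = tr$locals)
  lp <- logPrior(pv)
  expect_true(is.finite(lp))
  bad <- pv; bad$globals[["Pbab"]] <- 31
  expect_equal(logPrior(bad), -Inf)
  # dose-fraction constraint
  bad2 <- pv
  bad2$locals["FracDOSEHep", 1] <- 0.7
  bad2$locals["FracDoseLymph", 1] <- 0.301
  expect_equal(logPrior(bad2), -Inf)
  # the error SD contributes its half-normal(1) log density
  pv2 <- pv; pv2$sigmas[["sigma_OH"]] <- 0.5
  expect_equal(logPrior(pv2) - lp,
               (log(2) + dnorm(0.5, 0, 1, log = TRUE)) -
                 (log(2) + dnorm(tr$sigmas[["sigma_OH"]], 0, 1,
                                 log = TRUE)))
})

test_that("likelihood peaks at the generating parameters (zero noise)", {
  gs <- generateStudy(smallDesign(), truthSlice(2), seed = 21)
  pv <- list(globals = gs$truth$globals, sigmas = gs$truth$sigmas,
             locals = gs$truth$locals)
  ll0 <- logLikelihood(pv, gs$data)
  expect_true(is.finite(ll0))
  # perturbing an identified local parameter lowers the likelihood
  worse <- pv; worse$locals["FracDoseLymph", 1] <- 0.15
  expect_lt(logLikelihood(worse, gs$data), ll0)
  worse2 <- pv; worse2$locals["Lymphlag", 1] <- 2.5
  expect_lt(logLikelihood(worse2, gs$data), ll0)
})

test_that("prior-only MCMC reproduces closed-form prior quantiles", {
  ch <- runMCMC(NULL, iterations = 12000, thin = 2, seed = 4,
                nVolunteers = 1)
  s <- ch$samples
  # loose bounds: a random-walk chain on the prior is autocorrelated, so
  # the medians carry a few times the iid Monte-Carlo error
  expect_lt(abs(median(s[, "Pbab"]) - 15.5), 1.5)          # U(1, 30)
  expect_lt(abs(median(s[, "DEHTP_GUT_half_life"]) - 30), 1.0)
  expect_lt(abs(median(s[, "DEHTP_half_life"]) - 10 * qnorm(0.75)), 0.8)
  expect_true(all(s[, "escapeFracgu"] >= 0 & s[, "escapeFracgu"] <= 1))
  expect_true(all(s[, "FracDOSEHep.1"] + s[, "FracDoseLymph.1"] <= 1))
})

test_that("chains are reproducible under a fixed seed", {
  gs <- generateStudy(smallDesign(), truthSlice(2), seed = 21)
  c1 <- runMCMC(gs$data, iterations = 120, thin = 4, seed = 13)
  c2 <- runMCMC(gs$data, iterations = 120, thin = 4, seed = 13)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$logPost, c2$logPost)
})

test_that("posterior summaries order percentiles and locate the mode", {
  fake <- structure(list(
    samples = matrix(rep(c(2, 0.1, 0.2), each = 4), 4,
                     dimnames = list(NULL, c("K1_5cx", "FracDOSEHep.1",
                                             "FracDoseLymph.1"))),
    logPost = c(1, 5, 2, 0),
    config = list(J = 1)), class = "dehtpChain")
  ps <- posteriorSummary(fake)
  expect_equal(unname(ps$mode[["K1_5cx"]]), 2)
  expect_equal(ps$table$median, ps$table$q2.5)   # constant chain
  af <- ps$table[ps$table$parameter == "absorbedFraction.1", ]
  expect_equal(af$median, 0.3)

  two <- fake
  two$samples[, "K1_5cx"] <- c(1, 3, 1, 3)
  ps2 <- posteriorSummary(two)
  tab <- ps2$table[ps2$table$parameter == "K1_5cx", ]
  expect_equal(tab$median, 2)
  expect_true(tab$q2.5 <= tab$median && tab$median <= tab$q97.5)
})

test_that("predictive bands are ordered and collapse for one draw", {
  gs <- generateStudy(smallDesign(), truthSlice(2), seed = 21)
  ch <- runMCMC(gs$data, iterations = 80, thin = 8, seed = 2)
  grid <- seq(0, 24, 2)
  band <- predictiveBand(ch, gs$data, 1, "5cx", grid = grid, draws = 5)
  expect_true(all(band$lower <= band$upper + 1e-12))
  one <- ch; one$samples <- ch$samples[1, , drop = FALSE]
  one$logPost <- ch$logPost[1]
  b1 <- predictiveBand(one, gs$data, 1, "5cx", grid = grid, draws = 5)
  expect_equal(b1$lower, b1$upper)
  expect_equal(b1$lower, b1$mode)
})

test_that("chain text persistence round-trips samples and metadata", {
  gs <- generateStudy(smallDesign(), truthSlice(2), seed = 21)
  ch <- runMCMC(gs$data, iterations = 80, thin = 8, seed = 2)
  path <- tempfile(fileext = ".tsv")
  writeChain(ch, path)
  back <- readChain(path)
  expect_equal(back$samples, ch$samples, tolerance = 1e-12)
  expect_equal(back$logPost, ch$logPost, tolerance = 1e-12)
  expect_equal(back$config$seed, 2)
})
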