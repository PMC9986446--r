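## Shared fixtures built in code at test time.

## a small, fast study: fewer voids than the full design, zero or low noise
smallDesign <- function(noise = c("5OH" = 0, "2cx" = 0, "5cx" = 0),
                        n = 1) {
  studyDesign(nVolunteers = n, voidRange = c(8, 10), noiseSd = noise)
}

## a one-volunteer truth slice from the reference truth set
truthSlice <- function(j = 2) {
  tr <- defaultTruth()
  tr$locals <- tr$locals[, j, drop = FALSE]
  colnames(tr$locals) <- "1"
  tr
}

## hand-built minimal dehtpSim carrying a prescribed cumulative curve,
## for exercising the interval-average operator against brute force
fakeSim <- function(time, u5cx) {
  structure(list(time = time,
                 output = data.frame(time = time, u5cx = u5cx,
                                     u5OH = u5cx, u2cx = u5cx)),
            class = "dehtpSim")
}

## count strict local maxima of a rate curve (small threshold guards
## against solver-level wiggle)
countPeaks <- function(r, eps = 1e-9) {
  d <- diff(r)
  sum(d[-length(d)] > eps & d[-1] <= eps)
}
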