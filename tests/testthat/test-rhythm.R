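# Trace preprocessing, line/sine fits, AICc model comparison, and replicate
# summaries.

test_that("preprocessing drops the first day and removes slow trends", {
  t <- seq(0, 114, by = 1.5)
  const <- preprocessSeries(list(t = t, y = rep(5, length(t))))
  expect_true(all(const$t >= 24))
  expect_equal(const$y, rep(0, length(const$t)))

  ramp <- preprocessSeries(list(t = t, y = 2 * t + sin(2 * pi * t / 22)))
  slope <- unname(coef(lm(ramp$y ~ ramp$t))[2])
  expect_lt(abs(slope), 0.02)            # < 1% of the planted slope 2

  short <- list(t = seq(0, 20, by = 1.5), y = rnorm(14))
  expect_error(preprocessSeries(short), "fewer than 12")
})

test_that("line fits are exact on noiseless input and reject degenerate t", {
  t <- seq(24, 90, by = 1.5)
  lf <- fitLine(list(t = t, y = 2 * t + 1))
  expect_equal(lf$slope, 2, tolerance = 1e-10)
  expect_equal(lf$intercept, 1, tolerance = 1e-8)
  expect_lt(lf$rss, 1e-16)
  expect_equal(fitLine(list(t = t, y = rep(7, length(t))))$slope, 0)
  expect_error(fitLine(list(t = c(1, 2, 3), y = c(1, 2, 3))), "at least 4")
})

test_that("sine fits recover noiseless parameters to 1e-3", {
  t <- seq(24, 114, by = 1.5)
  sf <- fitSine(list(t = t, y = 3 + 2 * sin(2 * pi * t / 22)))
  expect_lt(abs(sf$period - 22), 1e-3)
  expect_lt(abs(sf$amplitude - 2), 1e-3)
  expect_lt(abs(sf$offset - 3), 1e-3)
  expect_true(sf$converged)
  expect_true(sf$phase >= 0 && sf$phase < sf$period)
})

test_that("a half-period phase shift moves phase by T/2, not T or A", {
  t <- seq(24, 114, by = 1.5)
  s1 <- fitSine(list(t = t, y = sin(2 * pi * t / 22)))
  s2 <- fitSine(list(t = t, y = sin(2 * pi * (t - 11) / 22)))
  expect_equal(s1$period, s2$period, tolerance = 1e-6)
  expect_equal(s1$amplitude, s2$amplitude, tolerance = 1e-6)
  dphi <- (s2$phase - s1$phase) %% 22
  expect_equal(dphi, 11, tolerance = 1e-3)
})

test_that("refitting the model's own predictions returns the same parameters", {
  t <- seq(24, 114, by = 1.5)
  sf <- fitSine(list(t = t, y = 1 + 4 * sin(2 * pi * (t - 3) / 20.3)))
  pred <- sf$offset + sf$amplitude *
    sin(2 * pi * (t - (sf$phase - sf$period / 4)) / sf$period)
  sf2 <- fitSine(list(t = t, y = pred))
  expect_equal(sf2$period, sf$period, tolerance = 1e-6)
  expect_equal(sf2$amplitude, sf$amplitude, tolerance = 1e-6)
  expect_equal(sf2$phase, sf$phase, tolerance = 1e-6)
})

test_that("AICc verdicts: sine wins on sinusoids, line wins on lines", {
  t <- seq(24, 114, by = 1.5)
  rc <- rhythmTest(list(t = t, y = 3 + 2 * sin(2 * pi * t / 22)))
  expect_gt(rc$pSineBetter, 0.9999)
  expect_true(rc$rhythmic)
  rl <- rhythmTest(list(t = t, y = 2 * t + 1))
  expect_lte(rl$pSineBetter, 0.5)
  expect_false(rl$rhythmic)
})

test_that("the Akaike weight is invariant under affine rescaling of y", {
  t <- seq(24, 114, by = 1.5)
  set.seed(33)
  y <- 2 * sin(2 * pi * t / 21) + rnorm(length(t), 0, 0.8)
  w1 <- rhythmTest(list(t = t, y = y))$pSineBetter
  w2 <- rhythmTest(list(t = t, y = 13.7 * y + 100))$pSineBetter
  expect_equal(w1, w2, tolerance = 1e-6)
})

test_that("AICc converges to AIC for large n", {
  # correction term 2k(k+1)/(n-k-1) at n = 1e4 is < 0.01 for both models
  for (k in c(3, 5))
    expect_lt(2 * k * (k + 1) / (1e4 - k - 1), 0.01)
  # and the fitted comparison at n = 1e4 uses rss-based AICc consistent with
  # the closed form
  t <- seq(0, 999.9, by = 0.1)
  set.seed(4)
  y <- sin(2 * pi * t / 24) + rnorm(length(t), 0, 0.5)
  lf <- fitLine(list(t = t, y = y))
  aic <- lf$n * log(lf$rss / lf$n) + 2 * lf$k
  aicc <- aic + 2 * lf$k * (lf$k + 1) / (lf$n - lf$k - 1)
  expect_lt(abs(aicc - aic), 0.01)
})

test_that("replicate summaries average periods and phases circularly", {
  mk_call <- function(period, phase) {
    structure(list(pSineBetter = 0.99, rhythmic = TRUE,
                   line = NULL,
                   sine = list(period = period, phase = phase)),
              class = "RhythmCall")
  }
  s <- summarizeReplicates(list(mk_call(20, 5), mk_call(20.3, 5),
                                mk_call(20.6, 5)))
  expect_equal(s$meanPeriod, 20.3)
  expect_equal(s$sdPeriod, 0.3, tolerance = 1e-10)
  expect_equal(s$nRhythmic, 3L)

  wrap <- summarizeReplicates(list(mk_call(22, 21.9), mk_call(22, 0.1)))
  expect_lt(min(wrap$meanPhase, 22 - wrap$meanPhase), 0.2)  # ~0 mod 22

  single <- summarizeReplicates(list(mk_call(20, 4)))
  expect_true(single$singleReplicate)
  expect_equal(single$sdPeriod, 0)

  none <- list(structure(list(rhythmic = FALSE), class = "RhythmCall"))
  expect_error(summarizeReplicates(none), "no rhythmic")
})
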