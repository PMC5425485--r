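test_that("motion summaries match hand-evaluated point-to-point formulas", {
  zero <- motionTrace(matrix(0, 5, 6))
  expect_true(all(motionSummary(zero) == 0))
  # +1 mm jump in x between two frames
  jump <- motionTrace(rbind(rep(0, 6), c(1, 0, 0, 0, 0, 0)))
  s <- motionSummary(jump)
  expect_equal(s[["mean_translation"]], 1)
  expect_equal(s[["mean_frame_displacement"]], 1)
  expect_equal(s[["mean_rotation"]], 0)
  # 1 degree rotation jump: FD contribution is 50 mm * pi / 180
  rot <- motionTrace(rbind(rep(0, 6), c(0, 0, 0, 1, 0, 0)))
  expect_equal(motionSummary(rot)[["mean_frame_displacement"]],
               50 * pi / 180)
  expect_equal(motionSummary(rot)[["mean_rotation"]], 1)
  expect_error(motionSummary(motionTrace(matrix(0, 1, 6))), "2 frames")
})

test_that("point-to-point summaries are invariant to a constant offset", {
  set.seed(5)
  p <- matrix(rnorm(10 * 6, sd = 0.05), 10, 6)
  s1 <- motionSummary(motionTrace(p))
  s2 <- motionSummary(motionTrace(sweep(p, 2, c(3, -2, 1, 0.5, -1, 2),
                                        "+")))
  keys <- c("mean_translation", "mean_rotation", "mean_frame_displacement")
  expect_equal(s1[keys], s2[keys])
})

test_that("motion QC applies the any-axis and point-to-point rules", {
  base <- c(mean_translation = 0, mean_rotation = 0,
            mean_frame_displacement = 0, max_abs_translation = 0,
            max_abs_rotation = 0)
  expect_true(qcExclude(base)$keep)
  s <- base; s["max_abs_translation"] <- 3.0
  d <- qcExclude(s)
  expect_false(d$keep)
  expect_match(d$reasons, "max abs translation")
  s <- base; s["mean_rotation"] <- 0.12
  d <- qcExclude(s)
  expect_false(d$keep)
  expect_match(d$reasons, "point-to-point rotation")
  # thresholds are configurable
  expect_true(qcExclude(s, meanRotationDeg = 0.2)$keep)
})

test_that("nuisance design has the expected columns and prunes rank loss", {
  set.seed(8)
  tr <- motionTrace(matrix(rnorm(102 * 6, sd = 0.05), 102, 6))
  d <- buildNuisanceDesign(102, tr, wmSeries = rnorm(102),
                           csfSeries = rnorm(102))
  expect_equal(dim(d$matrix), c(102L, 10L))
  expect_equal(d$labels[1:2], c("intercept", "drift"))
  expect_equal(qr(d$matrix)$rank, 10L)
  # all-zero motion collapses to intercept + drift + wm + csf
  expect_warning(
    d0 <- buildNuisanceDesign(102, motionTrace(matrix(0, 102, 6)),
                              wmSeries = rnorm(102),
                              csfSeries = rnorm(102)),
    "rank-deficient")
  expect_equal(dim(d0$matrix), c(102L, 4L))
  expect_error(buildNuisanceDesign(50, tr), "frames")
})

test_that("nuisance regression produces orthogonal residuals", {
  set.seed(9)
  nt <- 60
  wm <- rnorm(nt)
  d <- buildNuisanceDesign(nt, wmSeries = wm)
  # series inside the column space vanish
  p <- toyPanel(rbind(d$matrix[, "drift"], 5 + 2 * wm))
  r <- regressNuisance(p, d)
  expect_lt(max(abs(panelData(r))), 1e-10)
  # y = 2 wm + small noise: residual recovers the noise (OLS oracle)
  e <- rnorm(nt, sd = 0.01)
  p2 <- toyPanel(rbind(2 * wm + e))
  r2 <- regressNuisance(p2, d)
  expect_equal(unname(panelData(r2)[1, ]),
               unname(qr.resid(qr(d$matrix), e)), tolerance = 1e-12)
  # residuals orthogonal to every design column
  set.seed(10)
  p3 <- toyPanel(matrix(rnorm(4 * nt), 4, nt))
  r3 <- regressNuisance(p3, d)
  ip <- panelData(r3) %*% d$matrix
  expect_lt(max(abs(ip)) / max(abs(panelData(p3))), 1e-8)
  # residual variance never exceeds input variance
  expect_true(all(apply(panelData(r3), 1, var) <=
                  apply(panelData(p3), 1, var) + 1e-12))
  expect_error(regressNuisance(toyPanel(matrix(1, 2, 10)), d),
               "do not match")
})

test_that("ideal band-pass passes in-band, rejects out-of-band, removes DC", {
  tr <- 3; nt <- 300
  t <- (0:(nt - 1)) * tr
  inband <- sin(2 * pi * 0.04 * t)   # 0.04 Hz, bin-aligned
  outband <- sin(2 * pi * 0.12 * t)  # 0.12 Hz: in (0.08, Nyquist), bin-aligned
  p <- toyPanel(rbind(inband, outband, rep(2, nt)), tr = tr)
  f <- bandpassFilter(p)
  y <- panelData(f)
  expect_lt(sqrt(sum((y[1, ] - (inband - mean(inband)))^2)) /
            sqrt(sum(inband^2)), 1e-6)
  expect_lt(sum(y[2, ]^2) / sum(outband^2), 1e-10)
  expect_lt(max(abs(y[3, ])), 1e-12)   # DC bin zeroed; only fft roundoff
  expect_lt(max(abs(rowMeans(y))), 1e-12)
})

test_that("the ideal filter is idempotent and validates its band", {
  set.seed(12)
  p <- toyPanel(matrix(rnorm(3 * 120), 3, 120), tr = 3)
  f1 <- bandpassFilter(p)
  f2 <- bandpassFilter(f1)
  expect_equal(panelData(f2), panelData(f1), tolerance = 1e-12)
  expect_error(bandpassFilter(p, highHz = 0.2), "Nyquist.*3",
               perl = TRUE)
  expect_error(bandpassFilter(p, lowHz = 0.1, highHz = 0.05), "lowHz")
})
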