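test_that("group covariances assemble blocks and altered edges", {
  # no blocks, no alterations -> identity
  d0 <- syntheticDesign(nRegions = 5L, blocks = list(), seed = 1L)
  cv0 <- buildGroupCovariances(d0)
  expect_identical(cv0$control, diag(5))
  expect_identical(cv0$patient, diag(5))
  expect_equal(unname(cv0$repair_delta), c(0, 0))
  # one 3-region block at r = 0.5: compound symmetry, analytic eigenvalues
  d1 <- syntheticDesign(nRegions = 4L,
                        blocks = list(list(members = 1:3, r = 0.5)),
                        seed = 1L)
  cv1 <- buildGroupCovariances(d1)
  expect_equal(cv1$control[1, 2], 0.5)
  expect_equal(cv1$control[1, 4], 0)
  expect_equal(sort(eigen(cv1$control[1:3, 1:3])$values),
               c(0.5, 0.5, 2))
  expect_equal(unname(cv1$repair_delta), c(0, 0))
  # altered edge overwrites the two group matrices independently
  d2 <- syntheticDesign(nRegions = 4L, blocks = list(),
                        alteredEdges = data.frame(i = 1, j = 2,
                                                  r_control = 0.4,
                                                  r_patient = 0.1),
                        seed = 1L)
  cv2 <- buildGroupCovariances(d2)
  expect_equal(cv2$control[1, 2], 0.4)
  expect_equal(cv2$patient[1, 2], 0.1)
  expect_equal(cv2$patient[2, 1], 0.1)
  # requested |r| >= 1 is rejected
  expect_error(syntheticDesign(nRegions = 4L,
                               alteredEdges = data.frame(i = 1, j = 2,
                                                         r_control = 1,
                                                         r_patient = 0)),
               "\\|r\\| < 1")
})

test_that("positive-definite repair is applied and reported", {
  # force an indefinite matrix: a 3-clique at strongly negative r
  d <- syntheticDesign(nRegions = 3L,
                       blocks = list(list(members = 1:3, r = -0.6)),
                       seed = 1L)
  cv <- buildGroupCovariances(d)
  expect_gt(cv$repair_delta[["control"]], 0)
  expect_gte(min(eigen(cv$control)$values), 1e-7)
  expect_equal(diag(cv$control), rep(1, 3))
})

test_that("simulated series reproduce the target correlations", {
  d <- syntheticDesign(nRegions = 6L, nTimepoints = 10000L,
                       blocks = list(list(members = 1:3, r = 0.6)),
                       ar1 = 0, subjectVariabilitySd = 0, seed = 5L)
  cv <- buildGroupCovariances(d)
  set.seed(5)
  sub <- simulateSubject(cv$control, d, subjectId = "s", group = "control")
  r <- cor(t(panelData(sub$panel)))
  expect_lt(abs(r[1, 2] - 0.6), 0.03)
  expect_lt(abs(r[4, 5] - 0), 0.03)
  expect_lt(max(abs(edgeVector(r) - edgeVector(cv$control))), 0.05)
  # same seed gives bit-identical output
  s1 <- simulateSubject(cv$control, d, seed = 77L)
  s2 <- simulateSubject(cv$control, d, seed = 77L)
  expect_identical(panelData(s1$panel), panelData(s2$panel))
  expect_identical(motionParams(s1$motion), motionParams(s2$motion))
})

test_that("AR(1) coloring leaves the stationary cross-correlation intact", {
  base <- syntheticDesign(nRegions = 4L, nTimepoints = 8000L,
                          blocks = list(list(members = 1:2, r = 0.5)),
                          subjectVariabilitySd = 0, seed = 6L)
  cv <- buildGroupCovariances(base)
  for (phi in c(0, 0.4)) {
    d <- syntheticDesign(nRegions = 4L, nTimepoints = 8000L,
                         blocks = list(list(members = 1:2, r = 0.5)),
                         ar1 = phi, subjectVariabilitySd = 0, seed = 6L)
    sub <- simulateSubject(cv$control, d, seed = 8L)
    r <- cor(panelData(sub$panel)[1, ], panelData(sub$panel)[2, ])
    expect_lt(abs(r - 0.5), 0.05)
  }
  # AR(1) series are genuinely autocorrelated
  d4 <- syntheticDesign(nRegions = 4L, nTimepoints = 8000L, ar1 = 0.4,
                        subjectVariabilitySd = 0, seed = 6L,
                        blocks = list())
  sub <- simulateSubject(diag(4), d4, seed = 9L)
  y <- panelData(sub$panel)[1, ]
  expect_lt(abs(cor(y[-1], y[-length(y)]) - 0.4), 0.05)
})

test_that("cohorts carry ground truth, valid scores and determinism", {
  d <- syntheticDesign(nPatients = 8L, nControls = 6L, nRegions = 12L,
                       blocks = list(list(members = 1:4, r = 0.4)),
                       alteredEdges = data.frame(
                         i = c(1, 2), j = c(2, 3),
                         r_control = c(0.5, -0.15),
                         r_patient = c(0.05, -0.5)),
                       seed = 10L)
  ch <- simulateCohort(d)
  expect_length(ch$panels, 14L)
  expect_equal(vapply(ch$panels, groupLabel, ""),
               rep(c("patient", "control"), c(8, 6)))
  expect_equal(nrow(ch$truth$altered_edges), 2L)
  expect_equal(ch$truth$altered_edges$direction_class,
               c("decreased_positive", "increased_negative"))
  sc <- ch$scores
  expect_true(all(sc$MMSE >= 0 & sc$MMSE <= 30))
  expect_true(all(sc$PSQI >= 0 & sc$PSQI <= 21))
  expect_true(all(sc$ISI >= 0 & sc$ISI <= 28))
  expect_true(all(sc$sex %in% c("M", "F")))
  expect_false(any(is.na(sc[, c("MMSE", "MoCA", "PSQI", "ISI")])))
  # patients score in the clinical range, controls near the floor
  expect_gt(mean(sc$PSQI[sc$group == "patient"]),
            mean(sc$PSQI[sc$group == "control"]))
  ch2 <- simulateCohort(d)
  expect_identical(panelData(ch2$panels[[3]]), panelData(ch$panels[[3]]))
  expect_identical(ch2$scores, ch$scores)
})

test_that("score couplings induce the target correlation with edge z", {
  d <- syntheticDesign(nPatients = 39L, nControls = 4L, nRegions = 8L,
                       blocks = list(list(members = 1:4, r = 0.4)),
                       scoreCouplings = data.frame(i = 1, j = 2,
                                                   score = "MMSE",
                                                   target_r = 0.5),
                       seed = 11L)
  ch <- simulateCohort(d)
  pat <- ch$scores$group == "patient"
  z <- vapply(ch$panels[pat], function(p) {
    y <- panelData(p)
    atanh(cor(y[1, ], y[2, ]))
  }, 0)
  r <- cor(ch$scores$MMSE[pat], z)
  # exact empirical construction, blurred only by integer rounding
  expect_lt(abs(r - 0.5), 0.1)
})

test_that("generator defaults describe the intended study conditions", {
  d <- syntheticDesign()
  expect_equal(d@nPatients, 39L)
  expect_equal(d@nControls, 28L)
  expect_equal(d@nRegions, 116L)
  expect_equal(d@nTimepoints, 102L)
  expect_equal(d@trSeconds, 3)
  ae <- defaultAlteredEdges()
  expect_equal(nrow(ae), 10L)
  expect_equal(atanh(ae$r_control) - atanh(ae$r_patient), rep(0.5, 10),
               tolerance = 1e-12)
  expect_true(all(ae$i < ae$j))
})
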