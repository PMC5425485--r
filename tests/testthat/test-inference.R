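test_that("one-sample edge test matches the textbook formula", {
  out <- oneSampleEdgeTest(cbind(c(1, 2, 3), c(-1, 0, 1), c(0.5, 0.5, 0.5)))
  expect_equal(out$t[1], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$p[1], 2 * pt(-2 * sqrt(3), df = 2))
  expect_equal(out$t[2], 0)
  expect_equal(out$p[2], 1)
  expect_true(out$zero_variance[3])
  expect_true(is.nan(out$t[3]) && is.nan(out$p[3]))
  expect_error(oneSampleEdgeTest(matrix(1, 1, 2)), "2 subjects")
})

test_that("two-sample edge test matches hand and reference computations", {
  out <- twoSampleEdgeTest(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))
  expect_equal(out$t[1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(out$t[1], -3.6742, tolerance = 1e-4)
  expect_equal(out$p[1], 2 * pt(-3 / sqrt(2 / 3), df = 4))
  # identical groups
  same <- matrix(c(0.3, 0.1, 0.5), 3, 2)
  expect_equal(twoSampleEdgeTest(same, same)$t, c(0, 0))
  expect_equal(twoSampleEdgeTest(same, same)$p, c(1, 1))
  # per-edge independence: shifting one column leaves others unchanged
  a <- matrix(rnorm(3 * 2), 3, 2); b <- matrix(rnorm(3 * 2), 3, 2)
  b2 <- b; b2[, 2] <- b2[, 2] + 5
  expect_equal(twoSampleEdgeTest(a, b)$t[1], twoSampleEdgeTest(a, b2)$t[1])
  # zero pooled variance flagged
  expect_true(twoSampleEdgeTest(cbind(c(1, 1)), cbind(c(1, 1)))$zero_variance)
})

test_that("two-sample t agrees with stats::t.test and the oracle to 1e-10", {
  set.seed(31)
  for (k in 1:20) {
    a <- rnorm(sample(3:40, 1)); b <- rnorm(sample(3:40, 1))
    ours <- twoSampleEdgeTest(cbind(a), cbind(b))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_lt(abs(ours$t[1] - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p[1] - ref$p.value), 1e-10)
    expect_lt(abs(ours$t[1] - pooledTOracle(a, b)), 1e-10)
  }
})

test_that("BH rejection matches the brute-force step-up exactly", {
  expect_equal(bhFdr(c(0.001, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bhFdr(rep(1, 10), 0.05)))
  expect_true(bhFdr(0.04, 0.05))
  expect_equal(bhFdr(numeric(), 0.05), logical())
  expect_false(bhFdr(c(0.001, NaN), 0.05)[2])
  set.seed(32)
  for (k in 1:1000) {
    m <- sample(1:60, 1)
    p <- round(runif(m), sample(1:4, 1))
    p[p == 0] <- 1e-6
    if (k %% 7 == 0) p[sample(m, 1)] <- NA
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(bhFdr(p, q), bhBruteForce(p, q))
  }
})

test_that("split-permutation null is deterministic and sane at t = 0", {
  set.seed(33)
  Z <- matrix(rnorm(28 * 30), 28, 30)
  obs <- rnorm(30)
  obs[1] <- 0
  spec <- permutationSpec(nPermutations = 500L, seed = 99L)
  p1 <- splitPermutationNull(Z, spec, obs)
  p2 <- splitPermutationNull(Z, spec, obs)
  expect_identical(p1$perm_p, p2$perm_p)
  # chunking is a memory knob only
  p3 <- splitPermutationNull(Z, spec, obs, chunk = 64L)
  expect_identical(p1$perm_p, p3$perm_p)
  expect_identical(p1$perm_critical, p3$perm_critical)
  # zero observed statistic sits at the center of a symmetric null
  expect_gte(p1$perm_p[1], 0.5)
  expect_false(p1$significant[1])
  expect_true(all(p1$perm_p >= 1 / 501 & p1$perm_p <= 1))
  # splits must leave >= 2 subjects per part
  expect_error(splitPermutationNull(matrix(rnorm(9), 3, 3), spec,
                                    rnorm(3)), "fewer than 2")
})

test_that("permutation rejection rate is calibrated under the null", {
  # iid standard-normal z, observed comparison also null: the one-tailed
  # permutation decision at alpha = 0.01 should reject at a rate close
  # to the nominal level (within Monte-Carlo slack)
  rates <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    Z <- matrix(rnorm(28 * 200), 28, 200)
    obs <- twoSampleEdgeTest(matrix(rnorm(39 * 200), 39, 200),
                             matrix(rnorm(28 * 200), 28, 200))
    pn <- splitPermutationNull(Z, permutationSpec(2000L, seed = s), obs$t)
    mean(pn$significant)
  }, 0)
  expect_gte(mean(rates), 0.002)
  expect_lte(mean(rates), 0.03)
})

test_that("selection is a strict conjunction and classification follows means", {
  expect_equal(classifyEdgeDirection(0.4, 0.1, TRUE, TRUE),
               "decreased_positive")
  expect_equal(classifyEdgeDirection(-0.1, -0.35, TRUE, TRUE),
               "increased_negative")
  expect_equal(classifyEdgeDirection(-0.3, -0.1, TRUE, FALSE),
               "decreased_negative")
  expect_equal(classifyEdgeDirection(0.1, 0.4, FALSE, TRUE),
               "increased_positive")
  expect_equal(classifyEdgeDirection(0.2, -0.2, TRUE, TRUE),
               "unclassified")
  expect_equal(classifyEdgeDirection(0.2, -0.2, TRUE, TRUE,
                                     selected = FALSE), "not_selected")
})

test_that("group inference selects by both criteria and sorts by |t2|", {
  set.seed(34)
  nE <- 40
  # edges 1-3: strong positive connectivity in controls, collapsed in
  # patients (selected, decreased_positive); edge 4: strong in both
  # groups with no group difference (criterion 1 only)
  zC <- matrix(rnorm(20 * nE, 0, 0.1), 20, nE)
  zP <- matrix(rnorm(25 * nE, 0, 0.1), 25, nE)
  zC[, 1:3] <- zC[, 1:3] + 0.6
  zP[, 1:3] <- zP[, 1:3] + 0.1
  zC[, 4] <- zC[, 4] + 0.6
  zP[, 4] <- zP[, 4] + 0.6
  ce <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = t(rbind(zP, zC)), r = t(tanh(rbind(zP, zC)))),
    rowData = edgeIndex(ceiling((1 + sqrt(1 + 8 * nE)) / 2))[1:nE, ],
    colData = S4Vectors::DataFrame(
      group = rep(c("patient", "control"), c(25, 20)),
      row.names = paste0("s", 1:45)))
  ce <- methods::new("ConnectivityExperiment", ce)
  stats <- groupEdgeInference(ce, permutationSpec(600L, seed = 7L))
  expect_equal(nrow(stats), nE)
  expect_true(all(stats$selected[1:3]))
  expect_false(stats$selected[4])   # no group difference
  expect_true(stats$fdr_pass_patient[4] && stats$fdr_pass_control[4])
  expect_gte(stats$p2[4], 0.01)
  expect_true(all(stats$p2[1:3] < 0.01))
  # selection is exactly the conjunction of its three clauses
  expect_identical(stats$selected,
                   (stats$fdr_pass_patient | stats$fdr_pass_control) &
                     !is.na(stats$p2) & stats$p2 < 0.01 &
                     stats$perm_significant)
  expect_equal(stats$direction_class[1:3], rep("decreased_positive", 3))
  sel <- selectAlteredEdges(stats)
  expect_true(all(diff(abs(sel$t2)) <= 0))
  expect_true(all((stats$fdr_pass_patient | stats$fdr_pass_control)[
    stats$selected]))
  expect_true(all(stats$perm_significant[stats$selected]))
})

test_that("selection commutes with edge reordering", {
  set.seed(35)
  zC <- matrix(rnorm(15 * 12, 0.3, 0.15), 15, 12)
  zP <- matrix(rnorm(18 * 12, 0.3, 0.15), 18, 12)
  zP[, 2] <- zP[, 2] - 0.5
  spec <- permutationSpec(400L, seed = 11L)
  run <- function(zp, zc) {
    one_p <- oneSampleEdgeTest(zp); one_c <- oneSampleEdgeTest(zc)
    two <- twoSampleEdgeTest(zp, zc)
    perm <- splitPermutationNull(zc, spec, two$t)
    (bhFdr(one_p$p, 0.01) | bhFdr(one_c$p, 0.01)) &
      two$p < 0.01 & perm$significant
  }
  sel <- run(zP, zC)
  ord <- sample(12)
  selPerm <- run(zP[, ord], zC[, ord])
  expect_identical(selPerm, sel[ord])
})
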