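.colVars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x * x) - n * mu * mu) / (n - 1L)
}

#' Per-edge one-sample t test
#'
#' Tests, separately for every edge (column), whether the group's mean
#' Fisher-z value differs from zero: t = mean / (sd / sqrt(n)) with n - 1
#' degrees of freedom, two-tailed p. An edge with zero sample variance is
#' flagged (NaN statistics) rather than ever reported significant.
#'
#' @param z Subjects x edges numeric matrix of Fisher-z values.
#' @return A \link[S4Vectors]{DataFrame} with \code{t}, \code{p},
#'   \code{mean_z} and \code{zero_variance}.
#' @export
oneSampleEdgeTest <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 subjects")
  mu <- colMeans(z)
  v <- .colVars(z)
  bad <- v == 0
  t <- mu / sqrt(v / n)
  t[bad] <- NaN
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  S4Vectors::DataFrame(t = t, p = p, mean_z = mu, zero_variance = bad)
}

#' Per-edge pooled-variance two-sample t test
#'
#' Student's two-sample t with pooled variance, computed columnwise:
#' t = (mean(A) - mean(B)) / sqrt(s2p (1/nA + 1/nB)), df = nA + nB - 2,
#' two-tailed p. Edges with zero pooled variance are flagged NaN.
#'
#' @param zA,zB Subjects x edges matrices for the two groups (equal edge
#'   counts). In group inference A = patients, B = controls, so positive
#'   t means larger Fisher z in patients.
#' @return A \link[S4Vectors]{DataFrame} with \code{t}, \code{p},
#'   \code{mean_a}, \code{mean_b} and \code{zero_variance}.
#' @examples
#' twoSampleEdgeTest(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))$t  # -3.674
#' @export
twoSampleEdgeTest <- function(zA, zB) {
  zA <- as.matrix(zA); zB <- as.matrix(zB)
  if (ncol(zA) != ncol(zB)) stop("edge counts differ between groups")
  nA <- nrow(zA); nB <- nrow(zB)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  muA <- colMeans(zA); muB <- colMeans(zB)
  s2p <- ((nA - 1L) * .colVars(zA) + (nB - 1L) * .colVars(zB)) /
    (nA + nB - 2L)
  bad <- s2p == 0
  t <- (muA - muB) / sqrt(s2p * (1 / nA + 1 / nB))
  t[bad] <- NaN
  p <- 2 * stats::pt(-abs(t), df = nA + nB - 2L)
  S4Vectors::DataFrame(t = t, p = p, mean_a = muA, mean_b = muB,
                       zero_variance = bad)
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up false-discovery-rate control at level \code{q} over the
#' non-missing p-values; NaN/NA entries are never rejected.
#'
#' @param p Numeric vector of p-values (NA/NaN allowed).
#' @param q FDR level.
#' @return Logical rejection vector of the same length.
#' @export
bhFdr <- function(p, q) {
  if (!length(p)) return(logical())
  ok <- !is.na(p)
  rej <- logical(length(p))
  rej[ok] <- stats::p.adjust(p[ok], method = "BH") <= q
  rej
}

#' Configure the split-permutation null
#'
#' @param nPermutations Number of random splits (default 10000).
#' @param splitRule \code{"half_split"} or \code{"ratio_matched"}; see
#'   \linkS4class{PermutationSpec}.
#' @param alpha One-tailed type-I level (default 0.01).
#' @param seed Integer master seed.
#' @param groupSizes Observed group sizes (patients, controls), used only
#'   by \code{ratio_matched}.
#' @return A \linkS4class{PermutationSpec}.
#' @export
permutationSpec <- function(nPermutations = 10000L,
                            splitRule = "half_split", alpha = 0.01,
                            seed = 1L, groupSizes = c(39L, 28L)) {
  methods::new("PermutationSpec",
               nPermutations = as.integer(nPermutations),
               splitRule = splitRule, alpha = alpha,
               seed = as.integer(seed),
               groupSizes = as.integer(groupSizes))
}

.splitSizes <- function(n, spec) {
  n1 <- switch(spec@splitRule,
               half_split = n %/% 2L,
               ratio_matched = max(2L, min(n - 2L, round(
                 n * spec@groupSizes[1L] / sum(spec@groupSizes)))))
  if (n1 < 2L || n - n1 < 2L)
    stop("split rule leaves fewer than 2 subjects in a part (n = ", n, ")")
  n1
}

#' Within-control split-permutation null for the between-group test
#'
#' Builds an empirical null for each edge's between-group t statistic by
#' repeatedly partitioning the control subjects into two pseudo-groups at
#' random and recomputing the same pooled-variance t. The observed
#' statistic is then referred, one-tailed, to its own-sign tail: an edge
#' is significant when sign(t_obs) * t_null >= |t_obs| occurs in fewer
#' than alpha * N of the N repetitions. Reported quantities per edge:
#' \itemize{
#'   \item \code{perm_p}: add-one estimator
#'     (1 + #exceedances) / (1 + N), never exactly zero;
#'   \item \code{perm_critical}: empirical (1 - alpha) order-statistic
#'     quantile of the sign-aligned null;
#'   \item \code{significant}: the decision above.
#' }
#' Results are fully reproducible for a given \code{spec@seed}: the whole
#' sequence of splits is drawn from the master seed up front, so the
#' outcome does not depend on evaluation order.
#'
#' @param controls Subjects x edges Fisher-z matrix (controls only).
#' @param spec A \linkS4class{PermutationSpec}.
#' @param observedT Per-edge observed t statistics.
#' @param chunk Number of repetitions per vectorized block (memory
#'   knob only; the result is identical for any value).
#' @return A \link[S4Vectors]{DataFrame} with \code{perm_p},
#'   \code{perm_critical} and \code{significant}.
#' @export
splitPermutationNull <- function(controls, spec, observedT,
                                 chunk = 500L) {
  Z <- as.matrix(controls)
  nE <- ncol(Z)
  if (length(observedT) != nE)
    stop("observedT length does not match edge count")
  n <- nrow(Z)
  n1 <- .splitSizes(n, spec)
  N <- spec@nPermutations
  # draw all split assignments from the master seed up front
  perms <- local({
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(spec@seed)
    matrix(replicate(N, sample.int(n, n1)), nrow = n1)
  })
  Z2 <- Z * Z
  sgn <- sign(observedT)
  sgn[!is.finite(observedT)] <- 0
  absT <- abs(observedT)
  exceed <- numeric(nE)
  tnull <- matrix(NA_real_, N, nE)
  n2 <- n - n1
  totS <- colSums(Z)
  totS2 <- colSums(Z2)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    G <- matrix(0, length(idx), n)
    G[cbind(rep(seq_along(idx), each = n1), as.vector(perms[, idx]))] <- 1
    sA <- G %*% Z
    sA2 <- G %*% Z2
    vA <- (sA2 - sA * sA / n1) / (n1 - 1L)
    sB <- rep(1, length(idx)) %o% totS - sA
    vB <- (rep(1, length(idx)) %o% totS2 - sA2 - sB * sB / n2) / (n2 - 1L)
    s2p <- ((n1 - 1L) * vA + (n2 - 1L) * vB) / (n - 2L)
    tn <- (sA / n1 - sB / n2) / sqrt(s2p * (1 / n1 + 1 / n2))
    tnull[idx, ] <- tn
    aligned <- tn * rep(sgn, each = length(idx))
    exceed <- exceed + colSums(aligned >= rep(absT, each = length(idx)))
  }
  aligned_all <- tnull * rep(sgn, each = N)
  ord <- ceiling((1 - spec@alpha) * N)
  crit <- apply(aligned_all, 2L, function(x) sort(x)[ord])
  S4Vectors::DataFrame(perm_p = (1 + exceed) / (1 + N),
                       perm_critical = crit,
                       significant = exceed < spec@alpha * N &
                         is.finite(observedT))
}

#' Full two-criterion edge inference
#'
#' Runs the complete altered-edge statistical battery over an
#' edge-by-subject connectivity experiment:
#' \enumerate{
#'   \item criterion 1 - per-group two-tailed one-sample t tests of the
#'     Fisher-z values against zero, Benjamini-Hochberg corrected at
#'     level \code{q1} within each group across all edges (an edge
#'     qualifies if it passes in at least one group);
#'   \item criterion 2 - two-tailed pooled-variance two-sample t test
#'     (patients minus controls) with raw p < \code{p2}, additionally
#'     required to exceed the within-control split-permutation null at
#'     one-tailed level \code{spec@alpha}.
#' }
#' Edges passing all clauses are classified by direction
#' (\code{\link{classifyEdgeDirection}}).
#'
#' @param ce A \linkS4class{ConnectivityExperiment} with both groups.
#' @param spec A \linkS4class{PermutationSpec}.
#' @param q1 FDR level for criterion 1 (default 0.01).
#' @param p2 Raw two-sample threshold for criterion 2 (default 0.01).
#' @return An edge statistics \link[S4Vectors]{DataFrame} (one row per
#'   edge): group means, one-sample t/p and FDR flags, two-sample t/p,
#'   permutation p/critical/decision, \code{selected} and
#'   \code{direction_class}; the selection thresholds are stored in
#'   \code{metadata()}.
#' @export
groupEdgeInference <- function(ce, spec = permutationSpec(), q1 = 0.01,
                               p2 = 0.01) {
  zP <- groupZMatrix(ce, "patient")
  zC <- groupZMatrix(ce, "control")
  oneP <- oneSampleEdgeTest(zP)
  oneC <- oneSampleEdgeTest(zC)
  two <- twoSampleEdgeTest(zP, zC)
  spec@groupSizes <- c(nrow(zP), nrow(zC))
  perm <- splitPermutationNull(zC, spec, two$t)
  stats <- S4Vectors::DataFrame(
    SummarizedExperiment::rowData(ce)[, c("edge_id", "region_i",
                                          "region_j")],
    mean_z_patient = oneP$mean_z, mean_z_control = oneC$mean_z,
    t1_patient = oneP$t, p1_patient = oneP$p,
    t1_control = oneC$t, p1_control = oneC$p,
    fdr_pass_patient = bhFdr(oneP$p, q1),
    fdr_pass_control = bhFdr(oneC$p, q1),
    t2 = two$t, p2 = two$p,
    perm_p = perm$perm_p, perm_critical = perm$perm_critical,
    perm_significant = perm$significant)
  rd <- SummarizedExperiment::rowData(ce)
  if ("name_i" %in% colnames(rd)) {
    stats$name_i <- rd$name_i
    stats$name_j <- rd$name_j
    stats$abbrev_i <- rd$abbrev_i
    stats$abbrev_j <- rd$abbrev_j
  }
  stats$selected <- (stats$fdr_pass_patient | stats$fdr_pass_control) &
    !is.na(stats$p2) & stats$p2 < p2 & stats$perm_significant
  stats$direction_class <- classifyEdgeDirection(
    stats$mean_z_control, stats$mean_z_patient,
    stats$fdr_pass_control, stats$fdr_pass_patient, stats$selected)
  S4Vectors::metadata(stats) <- list(q1 = q1, p2 = p2,
                                     alpha_perm = spec@alpha,
                                     n_permutations = spec@nPermutations,
                                     split_rule = spec@splitRule,
                                     seed = spec@seed)
  stats
}

#' Select altered edges
#'
#' Applies the selection conjunction to a completed edge statistics
#' table and returns the selected rows sorted by |t2| descending.
#'
#' @param stats Edge statistics from \code{\link{groupEdgeInference}}.
#' @return The selected subset, sorted by absolute two-sample t.
#' @export
selectAlteredEdges <- function(stats) {
  sel <- stats[stats$selected, , drop = FALSE]
  sel[order(-abs(sel$t2)), , drop = FALSE]
}

#' Classify the direction of an altered edge
#'
#' Labels a selected edge by what happened to its connectivity in
#' patients relative to controls, anchored to the sign of the mean
#' Fisher z in the group(s) that established criterion 1 (control
#' preferred when both pass and their signs agree):
#' \itemize{
#'   \item reference sign positive: \code{decreased_positive} when the
#'     patient mean is below the control mean, else
#'     \code{increased_positive};
#'   \item reference sign negative: \code{increased_negative} when the
#'     patient mean is more negative than the control mean (a stronger
#'     anti-correlation), else \code{decreased_negative};
#'   \item both groups pass with opposite signs: \code{unclassified}.
#' }
#' Unselected edges are labelled \code{not_selected}.
#'
#' @param meanZControl,meanZPatient Per-edge group mean Fisher z.
#' @param fdrPassControl,fdrPassPatient Criterion-1 flags per group.
#' @param selected Logical selection vector (default all TRUE).
#' @return Character vector of direction classes.
#' @export
classifyEdgeDirection <- function(meanZControl, meanZPatient,
                                  fdrPassControl, fdrPassPatient,
                                  selected = NULL) {
  n <- length(meanZControl)
  if (is.null(selected)) selected <- rep(TRUE, n)
  out <- rep("not_selected", n)
  for (e in which(selected)) {
    sC <- sign(meanZControl[e]); sP <- sign(meanZPatient[e])
    s <- if (fdrPassControl[e] && fdrPassPatient[e]) {
      if (sC == sP) sC else NA_real_
    } else if (fdrPassControl[e]) {
      sC
    } else if (fdrPassPatient[e]) {
      sP
    } else {
      NA_real_
    }
    out[e] <- if (is.na(s)) {
      "unclassified"
    } else if (s > 0) {
      if (meanZPatient[e] < meanZControl[e]) "decreased_positive"
      else "increased_positive"
    } else {
      if (meanZPatient[e] < meanZControl[e]) "increased_negative"
      else "decreased_negative"
    }
  }
  out
}
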