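# Table-style anchors for behavioral score baselines. Clinical scales are
# anchored as mean + standard error (converted to sd via sqrt(n) at
# simulation time); age/education are mean + sd directly.
.scoreAnchors <- list(
  MMSE = list(control = c(28.55, 0.45), patient = c(26.91, 0.38),
              range = c(0, 30), se = TRUE),
  MoCA = list(control = c(26.37, 0.65), patient = c(22.56, 0.55),
              range = c(0, 30), se = TRUE),
  PSQI = list(control = c(0.37, 0.44), patient = c(13.19, 0.37),
              range = c(0, 21), se = TRUE),
  ISI  = list(control = c(0.59, 0.62), patient = c(15.52, 0.52),
              range = c(0, 28), se = TRUE),
  HAMA = list(control = c(0.19, 0.70), patient = c(9.61, 0.59),
              range = c(0, 56), se = TRUE),
  HAMD = list(control = c(0.36, 0.46), patient = c(8.53, 0.39),
              range = c(0, 52), se = TRUE),
  age  = list(control = c(51.25, 12.47), patient = c(52.21, 11.74),
              range = c(18, 90), se = FALSE),
  education = list(control = c(14.07, 2.69), patient = c(13.23, 3.38),
                   range = c(0, 25), se = FALSE))

.maleCounts <- c(control = 5L, patient = 6L)

#' Default network block structure
#'
#' Three covariance blocks emulating resting-state organisation on the
#' canonical 116-region ordering: a default-mode-like block (medial
#' prefrontal, posterior cingulate, precuneus, angular, middle temporal),
#' an anti-correlated task-positive block (middle frontal, opercular
#' inferior frontal, supplementary motor, postcentral, superior parietal,
#' inferior temporal) and a cerebellar block, with positive coupling
#' between the default-mode and cerebellar blocks.
#'
#' @return A list of block and between-block correlation entries.
#' @export
defaultBlocks <- function() {
  list(list(members = c(23:26, 35:36, 65:68, 85:86), r = 0.35),
       list(members = c(7:8, 11:12, 19:20, 57:60, 89:90), r = 0.35),
       list(members = c(91:94, 99:100, 105:106, 111:112), r = 0.25),
       list(between = c(1L, 2L), r = -0.15),
       list(between = c(1L, 3L), r = 0.10))
}

#' Default injected altered-edge set
#'
#' Ten group-difference edges with effect size \code{deltaZ} on the
#' Fisher-z scale: five decreased positive correlations inside the
#' default-mode-like block (control z 0.55 vs patient z 0.55 - deltaZ)
#' and five increased negative correlations between the default-mode and
#' task-positive blocks (control z -0.15 vs patient z -0.15 - deltaZ).
#'
#' @param deltaZ Group difference on the z scale (default 0.5).
#' @return data.frame(i, j, r_control, r_patient).
#' @export
defaultAlteredEdges <- function(deltaZ = 0.5) {
  dp <- rbind(c(23, 35), c(24, 68), c(25, 67), c(26, 86), c(36, 66))
  nn <- rbind(c(23, 59), c(24, 60), c(25, 89), c(35, 19), c(67, 20))
  nn <- t(apply(nn, 1L, sort))
  data.frame(i = c(dp[, 1], nn[, 1]), j = c(dp[, 2], nn[, 2]),
             r_control = c(rep(tanh(0.55), 5), rep(tanh(-0.15), 5)),
             r_patient = c(rep(tanh(0.55 - deltaZ), 5),
                           rep(tanh(-0.15 - deltaZ), 5)))
}

#' Construct a synthetic cohort design
#'
#' The defaults reproduce the study conditions the pipeline targets:
#' 39 patients and 28 controls, 116 regions, 102 frames at TR 3 s,
#' the block covariance of \code{\link{defaultBlocks}}, AR(1) temporal
#' autocorrelation 0.4, between-subject Fisher-z jitter 0.1 and no
#' injected alterations or couplings.
#'
#' @param nPatients,nControls,nRegions,nTimepoints,trSeconds Dimensions.
#' @param blocks Block covariance specification (see
#'   \code{\link{defaultBlocks}}).
#' @param baselineR Correlation outside all blocks.
#' @param alteredEdges data.frame(i, j, r_control, r_patient).
#' @param ar1 Temporal autocorrelation in [0, 0.9].
#' @param subjectVariabilitySd Between-subject jitter sd on the z scale.
#' @param scoreCouplings data.frame(i, j, score, target_r).
#' @param motionLevelMm Sd of per-frame simulated motion increments.
#' @param seed Integer master seed.
#' @return A \linkS4class{SyntheticDesign}.
#' @export
syntheticDesign <- function(nPatients = 39L, nControls = 28L,
                            nRegions = 116L, nTimepoints = 102L,
                            trSeconds = 3, blocks = defaultBlocks(),
                            baselineR = 0,
                            alteredEdges = data.frame(),
                            ar1 = 0.4, subjectVariabilitySd = 0.1,
                            scoreCouplings = data.frame(),
                            motionLevelMm = 0.02, seed = 1L) {
  methods::new("SyntheticDesign", nPatients = as.integer(nPatients),
               nControls = as.integer(nControls),
               nRegions = as.integer(nRegions),
               nTimepoints = as.integer(nTimepoints),
               trSeconds = trSeconds, blocks = blocks,
               baselineR = baselineR, alteredEdges = alteredEdges,
               ar1 = ar1, subjectVariabilitySd = subjectVariabilitySd,
               scoreCouplings = scoreCouplings,
               motionLevelMm = motionLevelMm, seed = as.integer(seed))
}

# Eigenvalue-floor positive-definite repair of a correlation matrix.
# Returns the repaired matrix (unit diagonal restored) and the largest
# absolute entry change.
.pdRepair <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor)
    return(list(matrix = m, delta = 0))
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / (d %o% d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  list(matrix = out, delta = max(abs(out - m)))
}

#' Assemble the two group correlation matrices
#'
#' Builds the control and patient inter-regional correlation matrices
#' from the design's block structure, overwrites the injected altered
#' edges with their group-specific values, and applies an
#' eigenvalue-floor positive-definite repair (minimum eigenvalue 1e-6)
#' where needed; the largest entry change introduced by the repair is
#' reported so callers can assert it is negligible.
#'
#' @param design A \linkS4class{SyntheticDesign}.
#' @return List with \code{control}, \code{patient} (correlation
#'   matrices) and \code{repair_delta} (named numeric, max abs change
#'   per group).
#' @export
buildGroupCovariances <- function(design) {
  n <- design@nRegions
  base <- matrix(design@baselineR, n, n)
  for (b in design@blocks) {
    if (!is.null(b$members)) {
      if (any(b$members > n)) stop("block member exceeds nRegions")
      base[b$members, b$members] <- b$r
    }
  }
  for (b in design@blocks) {
    if (!is.null(b$between)) {
      m1 <- design@blocks[[b$between[1L]]]$members
      m2 <- design@blocks[[b$between[2L]]]$members
      base[m1, m2] <- b$r
      base[m2, m1] <- b$r
    }
  }
  diag(base) <- 1
  if (any(abs(base[row(base) != col(base)]) >= 1))
    stop("block specification requires |r| < 1 off the diagonal")
  mk <- function(col) {
    m <- base
    ae <- design@alteredEdges
    if (nrow(ae)) {
      idx <- cbind(ae$i, ae$j)
      m[idx] <- ae[[col]]
      m[idx[, 2:1, drop = FALSE]] <- ae[[col]]
    }
    .pdRepair(m)
  }
  ctl <- mk("r_control")
  pat <- mk("r_patient")
  list(control = ctl$matrix, patient = pat$matrix,
       repair_delta = c(control = ctl$delta, patient = pat$delta))
}

#' Simulate one subject's panel and motion trace
#'
#' Draws a subject-specific correlation matrix by jittering the group
#' matrix on the Fisher-z scale (off-diagonal z + N(0, sd), tanh back,
#' PD-repaired), then generates AR(1) innovations with stationary unit
#' variance and colors them by the Cholesky factor, so the stationary
#' cross-correlation of the series equals the subject matrix regardless
#' of the AR coefficient. The motion trace is a cumulative sum of
#' Gaussian increments.
#'
#' @param cov Group correlation matrix (positive definite).
#' @param design A \linkS4class{SyntheticDesign}.
#' @param subjectId,group Panel metadata.
#' @param seed Optional integer; when given, output is bit-reproducible.
#' @return List with \code{panel} (a \linkS4class{RoiTimeSeriesPanel})
#'   and \code{motion} (a \linkS4class{MotionTrace}).
#' @export
simulateSubject <- function(cov, design, subjectId = "subj",
                            group = "unknown", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cov)
  nt <- design@nTimepoints
  R <- cov
  if (design@subjectVariabilitySd > 0) {
    up <- upper.tri(R)
    jit <- matrix(0, n, n)
    jit[up] <- stats::rnorm(sum(up), 0, design@subjectVariabilitySd)
    jit <- jit + t(jit)
    z <- atanh(pmin(pmax(R, -1 + 1e-9), 1 - 1e-9))
    diag(z) <- 0
    R <- tanh(z + jit)
    diag(R) <- 1
    R <- .pdRepair(R)$matrix
  }
  U <- chol(R)
  phi <- design@ar1
  eps <- matrix(stats::rnorm(nt * n), nt, n)
  X <- matrix(0, nt, n)
  X[1L, ] <- eps[1L, ]
  if (nt > 1L) {
    s <- sqrt(1 - phi^2)
    for (t in 2:nt) X[t, ] <- phi * X[t - 1L, ] + s * eps[t, ]
  }
  Y <- t(X %*% U)                      # regions x time, corr = R
  rownames(Y) <- rownames(cov)
  inc <- matrix(stats::rnorm(nt * 6L, 0, design@motionLevelMm), nt, 6L)
  trace <- motionTrace(apply(inc, 2L, cumsum))
  list(panel = roiTimeSeriesPanel(Y, subjectId = subjectId,
                                  group = group,
                                  trSeconds = design@trSeconds),
       motion = trace)
}

.sampleScores <- function(group, n) {
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(.scoreAnchors)) {
    a <- .scoreAnchors[[nm]]
    par <- a[[group]]
    sdv <- if (a$se) par[2L] * sqrt(n) else par[2L]
    out[[nm]] <- stats::rnorm(n, par[1L], sdv)
  }
  out
}

.coupleScore <- function(score, z, targetR) {
  u <- as.numeric(scale(z))
  eps <- stats::rnorm(length(z))
  er <- qr.resid(qr(cbind(1, u)), eps)
  er <- er / stats::sd(er)
  mu <- mean(score); sdv <- stats::sd(score)
  mu + sdv * (targetR * u + sqrt(1 - targetR^2) * er)
}

.truthDirection <- function(ae) {
  zc <- atanh(ae$r_control); zp <- atanh(ae$r_patient)
  ifelse(zc > 0,
         ifelse(zp < zc, "decreased_positive", "increased_positive"),
         ifelse(zp < zc, "increased_negative", "decreased_negative"))
}

#' Simulate a full two-group cohort
#'
#' Generates patient and control panels from their group correlation
#' matrices, per-subject motion traces, and a behavioral score table.
#' Scores are Gaussian baselines at realistic clinical anchors (means
#' and dispersions typical of an insomnia cohort vs healthy controls;
#' integer-rounded and clipped to each instrument's range). For every
#' score coupling in the design, the patient score is reconstructed as a
#' linear combination of the subjects' realized Fisher z at the coupled
#' edge and orthogonalized noise, so the induced sample correlation
#' equals the target (up to rounding/clipping). Everything is drawn from
#' the design seed, so identical designs give bit-identical cohorts.
#'
#' @param design A \linkS4class{SyntheticDesign}.
#' @return List with \code{panels} (patients then controls),
#'   \code{motion} (parallel list of \linkS4class{MotionTrace}),
#'   \code{scores} (data.frame: subject_id, group, sex, age, education
#'   and the six clinical scores) and \code{truth} (ground-truth record:
#'   altered edges with expected direction classes, couplings, repair
#'   deltas).
#' @export
simulateCohort <- function(design) {
  set.seed(design@seed)
  covs <- buildGroupCovariances(design)
  nP <- design@nPatients; nC <- design@nControls
  ids <- c(sprintf("patient_%02d", seq_len(nP)),
           sprintf("control_%02d", seq_len(nC)))
  groups <- rep(c("patient", "control"), c(nP, nC))
  sims <- lapply(seq_along(ids), function(k)
    simulateSubject(covs[[groups[k]]], design, subjectId = ids[k],
                    group = groups[k]))
  panels <- lapply(sims, `[[`, "panel")
  motion <- lapply(sims, `[[`, "motion")

  scores <- rbind(.sampleScores("patient", nP),
                  .sampleScores("control", nC))
  scores <- cbind(subject_id = ids, group = groups, scores)
  mP <- min(.maleCounts[["patient"]], nP)
  mC <- min(.maleCounts[["control"]], nC)
  sex <- c(rep(c("M", "F"), c(mP, nP - mP)),
           rep(c("M", "F"), c(mC, nC - mC)))
  scores$sex <- sex

  sc <- design@scoreCouplings
  if (nrow(sc)) {
    pat <- which(groups == "patient")
    for (k in seq_len(nrow(sc))) {
      z <- vapply(panels[pat], function(p) {
        y <- panelData(p)
        fisherZ(stats::cor(y[sc$i[k], ], y[sc$j[k], ]))
      }, 0)
      scores[[sc$score[k]]][pat] <-
        .coupleScore(scores[[sc$score[k]]][pat], z, sc$target_r[k])
    }
  }
  for (nm in names(.scoreAnchors)) {
    rg <- .scoreAnchors[[nm]]$range
    scores[[nm]] <- pmin(pmax(round(scores[[nm]]), rg[1L]), rg[2L])
  }

  truth <- list(altered_edges = if (nrow(design@alteredEdges)) {
    cbind(design@alteredEdges,
          direction_class = .truthDirection(design@alteredEdges))
  } else {
    design@alteredEdges
  },
  couplings = sc, repair_delta = covs$repair_delta, seed = design@seed)
  list(panels = panels, motion = motion, scores = scores, truth = truth)
}
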