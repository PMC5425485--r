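#' Construct a motion trace
#'
#' @param params Numeric n_frames x 6 matrix or data frame: columns 1-3
#'   translations (mm), columns 4-6 rotations (degrees).
#' @return A \linkS4class{MotionTrace}.
#' @export
motionTrace <- function(params) {
  params <- as.matrix(params)
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  methods::new("MotionTrace", params = params)
}

#' Read a 6-column realignment-parameter file
#'
#' @param path Whitespace- or tab-delimited text, one row per frame.
#' @return A \linkS4class{MotionTrace}.
#' @export
readMotionTrace <- function(path) {
  motionTrace(as.matrix(utils::read.table(path, header = FALSE)))
}

#' Summarise head motion
#'
#' Point-to-point motion summaries from a realignment trace:
#' \itemize{
#'   \item \code{mean_translation}: mean over frames t >= 2 of the
#'     Euclidean norm of the frame-to-frame translation difference (mm);
#'   \item \code{mean_rotation}: the analogue on the rotation columns
#'     (degrees);
#'   \item \code{mean_frame_displacement}: mean over frames t >= 2 of
#'     the sum of absolute translation differences plus 50 mm times the
#'     sum of absolute rotation differences in radians (the conventional
#'     50 mm head-radius framewise displacement);
#'   \item \code{max_abs_translation}, \code{max_abs_rotation}: largest
#'     absolute single-axis excursion over the whole run.
#' }
#' All summaries depend only on within-run motion, so they are invariant
#' to a constant offset of the whole trace (except the max-abs ones,
#' which measure absolute excursion and are used for the any-axis
#' exclusion rule).
#'
#' @param trace A \linkS4class{MotionTrace} with >= 2 frames.
#' @return Named numeric vector with the five summaries above.
#' @examples
#' tr <- motionTrace(rbind(rep(0, 6), c(1, 0, 0, 0, 0, 0)))
#' motionSummary(tr)["mean_frame_displacement"]  # 1 mm
#' @export
motionSummary <- function(trace) {
  p <- motionParams(trace)
  if (nrow(p) < 2L)
    stop("motion summaries need at least 2 frames, got ", nrow(p))
  dt <- diff(p[, 1:3, drop = FALSE])
  dr <- diff(p[, 4:6, drop = FALSE])
  c(mean_translation = mean(sqrt(rowSums(dt^2))),
    mean_rotation = mean(sqrt(rowSums(dr^2))),
    mean_frame_displacement =
      mean(rowSums(abs(dt)) + 50 * rowSums(abs(dr)) * pi / 180),
    max_abs_translation = max(abs(p[, 1:3])),
    max_abs_rotation = max(abs(p[, 4:6])))
}

#' Head-motion exclusion decision
#'
#' Applies the standard any-axis and point-to-point exclusion rules:
#' a subject is excluded when the maximum absolute translation exceeds
#' 2.5 mm or the maximum absolute rotation exceeds 2.5 degrees in any
#' axis, or when the mean point-to-point translation exceeds 0.15 mm or
#' the mean point-to-point rotation exceeds 0.1 degrees. All four
#' thresholds are configurable.
#'
#' @param summary Named vector from \code{\link{motionSummary}}.
#' @param maxTranslationMm,maxRotationDeg,meanTranslationMm,meanRotationDeg
#'   Exclusion thresholds.
#' @return A list with \code{keep} (logical) and \code{reasons}
#'   (character vector, empty when kept).
#' @export
qcExclude <- function(summary, maxTranslationMm = 2.5, maxRotationDeg = 2.5,
                      meanTranslationMm = 0.15, meanRotationDeg = 0.1) {
  reasons <- character()
  if (summary[["max_abs_translation"]] > maxTranslationMm)
    reasons <- c(reasons, sprintf("max abs translation %.3f mm > %.3f mm",
                                  summary[["max_abs_translation"]],
                                  maxTranslationMm))
  if (summary[["max_abs_rotation"]] > maxRotationDeg)
    reasons <- c(reasons, sprintf("max abs rotation %.3f deg > %.3f deg",
                                  summary[["max_abs_rotation"]],
                                  maxRotationDeg))
  if (summary[["mean_translation"]] > meanTranslationMm)
    reasons <- c(reasons,
                 sprintf("mean point-to-point translation %.3f mm > %.3f mm",
                         summary[["mean_translation"]], meanTranslationMm))
  if (summary[["mean_rotation"]] > meanRotationDeg)
    reasons <- c(reasons,
                 sprintf("mean point-to-point rotation %.3f deg > %.3f deg",
                         summary[["mean_rotation"]], meanRotationDeg))
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Build a nuisance regression design
#'
#' Assembles the time x k denoising design: intercept, linear drift, the
#' six motion parameters, and mean white-matter and cerebrospinal-fluid
#' signals (10 columns when all are supplied and non-degenerate).
#' Constant or collinear columns (e.g. an all-zero motion trace) are
#' dropped with a warning; the intercept always stays.
#'
#' @param nTimepoints Number of frames.
#' @param trace Optional \linkS4class{MotionTrace} with matching frames.
#' @param wmSeries,csfSeries Optional numeric vectors of matching length.
#' @return A list with \code{matrix} (time x k, full column rank) and
#'   \code{labels}.
#' @export
buildNuisanceDesign <- function(nTimepoints, trace = NULL, wmSeries = NULL,
                                csfSeries = NULL) {
  cols <- list(intercept = rep(1, nTimepoints),
               drift = seq_len(nTimepoints) - (nTimepoints + 1) / 2)
  if (!is.null(trace)) {
    p <- motionParams(trace)
    if (nrow(p) != nTimepoints)
      stop("motion trace has ", nrow(p), " frames but design needs ",
           nTimepoints)
    for (k in seq_len(6L)) cols[[colnames(p)[k]]] <- p[, k]
  }
  addSeries <- function(cols, x, label) {
    if (is.null(x)) return(cols)
    if (length(x) != nTimepoints)
      stop(label, " series length ", length(x),
           " does not match n_timepoints ", nTimepoints)
    cols[[label]] <- as.numeric(x)
    cols
  }
  cols <- addSeries(cols, wmSeries, "wm")
  cols <- addSeries(cols, csfSeries, "csf")
  X <- do.call(cbind, cols)
  if (any(!is.finite(X))) stop("non-finite values in nuisance regressors")
  # prune columns that add no rank (constant or collinear regressors)
  keep <- 1L
  for (k in seq_len(ncol(X))[-1L]) {
    cand <- c(keep, k)
    if (qr(X[, cand, drop = FALSE])$rank == length(cand)) keep <- cand
  }
  if (length(keep) < ncol(X))
    warning("dropping rank-deficient nuisance columns: ",
            paste(names(cols)[setdiff(seq_len(ncol(X)), keep)],
                  collapse = ", "))
  list(matrix = X[, keep, drop = FALSE], labels = names(cols)[keep])
}

#' Regress nuisance signals out of a panel
#'
#' Replaces every region's series by its ordinary-least-squares residual
#' against the nuisance design. Residuals are orthogonal to every design
#' column (to numerical precision), so motion, drift and global
#' compartment signals cannot drive downstream correlations.
#'
#' @param panel A \linkS4class{RoiTimeSeriesPanel}.
#' @param design A design from \code{\link{buildNuisanceDesign}}.
#' @return The residual panel (missing-region rows stay NA).
#' @export
regressNuisance <- function(panel, design) {
  X <- design$matrix
  Y <- panelData(panel)
  if (ncol(Y) != nrow(X))
    stop("design rows (", nrow(X), ") do not match panel frames (",
         ncol(Y), ")")
  ok <- setdiff(seq_len(nrow(Y)), missingRegions(panel))
  if (any(!is.finite(Y[ok, ])))
    stop("non-finite values in panel data")
  qrX <- qr(X)
  res <- Y
  res[ok, ] <- t(qr.resid(qrX, t(Y[ok, , drop = FALSE])))
  methods::initialize(panel, data = res)
}

#' Ideal band-pass filter for a panel
#'
#' Discrete-Fourier ideal band-pass: frequency bins with |f| strictly
#' outside [\code{lowHz}, \code{highHz}] are zeroed (pass-band edges
#' inclusive), as is the DC bin, and the series is reconstructed by the
#' inverse transform. The output is therefore exactly mean-zero, the
#' filter is idempotent, and pass/stop behavior is exact on bin-aligned
#' sinusoids. The conventional resting-state band 0.01-0.08 Hz is the
#' default.
#'
#' @param panel A \linkS4class{RoiTimeSeriesPanel} with known TR.
#' @param lowHz,highHz Pass-band edges in Hz; \code{highHz} must be below
#'   the Nyquist frequency 1/(2 TR).
#' @return The filtered panel.
#' @export
bandpassFilter <- function(panel, lowHz = 0.01, highHz = 0.08) {
  tr <- trSeconds(panel)
  nyquist <- 1 / (2 * tr)
  if (highHz >= nyquist)
    stop(sprintf(
      "highHz (%g Hz) must be below the Nyquist frequency %g Hz at TR %g s",
      highHz, nyquist, tr))
  if (lowHz < 0 || lowHz >= highHz)
    stop("need 0 <= lowHz < highHz")
  Y <- panelData(panel)
  nt <- ncol(Y)
  freq <- pmin(0:(nt - 1L), nt - (0:(nt - 1L))) / (nt * tr)
  keep <- freq >= lowHz & freq <= highHz
  keep[1L] <- FALSE                      # DC always removed
  ok <- setdiff(seq_len(nrow(Y)), missingRegions(panel))
  if (any(!is.finite(Y[ok, ])))
    stop("non-finite values in panel data")
  F <- stats::mvfft(t(Y[ok, , drop = FALSE]))
  F[!keep, ] <- 0
  out <- Y
  out[ok, ] <- t(Re(stats::mvfft(F, inverse = TRUE)) / nt)
  methods::initialize(panel, data = out)
}
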