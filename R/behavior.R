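#' Pearson correlation with a two-tailed p-value
#'
#' Sample Pearson r with the textbook t-based p-value:
#' t = r sqrt((n - 2) / (1 - r^2)), n - 2 degrees of freedom,
#' two-tailed. Degenerate inputs (a constant vector, or |r| = 1 which
#' makes the statistic infinite) are flagged.
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with missing
#'   values are dropped.
#' @return Named vector \code{c(r, p, n)}; \code{r} is NaN when a vector
#'   is constant, \code{p} is 0 when |r| = 1.
#' @export
pearsonWithP <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(c(r = NaN, p = NaN, n = n))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2L)
  c(r = r, p = p, n = n)
}

#' Partial Pearson correlation given covariates
#'
#' Correlation between the least-squares residuals of \code{x} and
#' \code{y} on an intercept plus the covariate columns; the p-value uses
#' t with n - k - 2 degrees of freedom, where k is the number of
#' (independent) covariate columns retained. Rank-deficient covariate
#' sets are reduced with a warning. With no covariates this reduces
#' exactly to \code{\link{pearsonWithP}}.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix or data.frame with one row per
#'   observation (factors must be pre-coded numerically; any affine
#'   coding of a binary covariate gives the same partial r).
#' @return Named vector \code{c(r, p, n, k)}.
#' @export
partialPearson <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      NROW(covariates) == 0L) {
    out <- pearsonWithP(x, y)
    return(c(out[c("r", "p")], n = out[["n"]], k = 0))
  }
  C <- as.matrix(covariates)
  if (!is.numeric(C)) stop("covariates must be numeric")
  ok <- is.finite(x) & is.finite(y) & apply(C, 1L, function(v)
    all(is.finite(v)))
  x <- x[ok]; y <- y[ok]; C <- C[ok, , drop = FALSE]
  X <- cbind(1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qrX$rank,
            " rank-deficient covariate column(s)")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  k <- ncol(X) - 1L
  n <- length(x)
  if (n <= k + 2L)
    stop("need n > k + 2 observations (n = ", n, ", k = ", k, ")")
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(c(r = NaN, p = NaN, n = n, k = k))
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r) * sqrt((n - k - 2) / (1 - r^2)), df = n - k - 2L)
  c(r = r, p = p, n = n, k = k)
}

#' Edge-strength vs behavioral-score correlations
#'
#' For each selected edge and each behavioral score, the Pearson
#' correlation of the patients' Fisher-z edge strengths with the score,
#' with both the uncorrected p < \code{level} verdict and a
#' Benjamini-Hochberg FDR verdict at the same level reported side by
#' side. The FDR family is the full edge x score grid by default
#' (\code{family = "grid"}); \code{family = "per_score"} corrects within
#' each score column instead.
#'
#' @param ce A \linkS4class{ConnectivityExperiment} whose \code{colData}
#'   carries the score columns.
#' @param edgeIds Integer edge ids (rows of \code{ce}) to test,
#'   typically the selected altered edges.
#' @param scoreNames Character vector of \code{colData} score columns.
#' @param level Significance level for both verdicts (default 0.05).
#' @param family \code{"grid"} or \code{"per_score"}.
#' @param covariates Optional matrix of per-patient covariates; when
#'   supplied, partial correlations are used instead of plain Pearson.
#' @return A \link[S4Vectors]{DataFrame}, one row per edge x score:
#'   \code{edge_id}, \code{score}, \code{r}, \code{p},
#'   \code{pass_uncorrected}, \code{fdr_pass}.
#' @export
edgeScoreCorrelations <- function(ce, edgeIds, scoreNames, level = 0.05,
                                  family = c("grid", "per_score"),
                                  covariates = NULL) {
  family <- match.arg(family)
  cd <- SummarizedExperiment::colData(ce)
  pat <- cd$group == "patient"
  if (sum(pat) < 3L) stop("need at least 3 patients")
  missing <- setdiff(scoreNames, colnames(cd))
  if (length(missing))
    stop("scores absent from colData: ", paste(missing, collapse = ", "))
  zP <- t(SummarizedExperiment::assay(ce, "z")[edgeIds, pat,
                                               drop = FALSE])
  rows <- expand.grid(score = scoreNames, edge_id = edgeIds,
                      stringsAsFactors = FALSE)[, 2:1]
  est <- t(mapply(function(e, s) {
    z <- zP[, match(e, edgeIds)]
    y <- as.numeric(cd[[s]][pat])
    if (stats::var(y, na.rm = TRUE) == 0 ||
        !is.finite(stats::var(y, na.rm = TRUE)))
      return(c(r = NaN, p = NaN))
    out <- if (is.null(covariates)) pearsonWithP(z, y) else
      partialPearson(z, y, covariates)
    out[c("r", "p")]
  }, rows$edge_id, rows$score))
  out <- S4Vectors::DataFrame(edge_id = rows$edge_id, score = rows$score,
                              r = est[, "r"], p = est[, "p"])
  out$pass_uncorrected <- !is.na(out$p) & out$p < level
  out$fdr_pass <- if (family == "grid") {
    bhFdr(out$p, level)
  } else {
    unsplit(lapply(split(out$p, out$score), bhFdr, q = level), out$score)
  }
  out
}
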