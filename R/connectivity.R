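#' Fisher r-to-z transformation
#'
#' The variance-stabilizing transform z = atanh(r) = log((1+r)/(1-r))/2
#' applied to correlation coefficients before t-testing. Correlations
#' with |r| >= 1 - 1e-7 (possible in degenerate inputs) are clipped to
#' +/-(1 - 1e-7) with a warning rather than propagated as infinities, so
#' downstream statistics stay finite while the event remains auditable.
#'
#' @param r Numeric vector or matrix of correlations.
#' @return z on the same shape; an odd, strictly increasing function of r.
#' @examples
#' fisherZ(0.5)            # 0.5493061
#' fisherZ(c(-0.5, 0, 0.5))
#' @export
fisherZ <- function(r) {
  lim <- 1 - 1e-7
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  clip <- abs(r) >= lim & !is.na(r)
  if (any(clip)) {
    warning(sum(clip), " correlation(s) with |r| >= 1 - 1e-7 clipped ",
            "before the z transform")
    r[clip] <- sign(r[clip]) * lim
  }
  atanh(r)
}

#' Canonical edge index of an atlas
#'
#' Enumerates the unordered region pairs (i, j), i < j, of a parcellation
#' in canonical upper-triangular order: (1,2), (1,3), ..., (1,n), (2,3),
#' ... For the bundled 116-region atlas this yields the full set of
#' 6,670 = 116 x 115 / 2 edges over which all group inference runs.
#'
#' @param atlas A \linkS4class{BrainAtlas}, or a single integer giving
#'   the number of regions.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{edge_id},
#'   \code{region_i}, \code{region_j} (canonical row positions) and,
#'   when an atlas is given, \code{name_i}, \code{name_j},
#'   \code{abbrev_i}, \code{abbrev_j}.
#' @examples
#' nrow(edgeIndex(116))  # 6670
#' edgeIndex(3)
#' @export
edgeIndex <- function(atlas) {
  n <- if (methods::is(atlas, "BrainAtlas")) nRegions(atlas) else
    as.integer(atlas)
  if (n < 2L) stop("need at least 2 regions")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  out <- S4Vectors::DataFrame(edge_id = seq_along(i),
                              region_i = i, region_j = j)
  if (methods::is(atlas, "BrainAtlas")) {
    lab <- atlasLabels(atlas)
    out$name_i <- lab$name[i]
    out$name_j <- lab$name[j]
    out$abbrev_i <- lab$abbreviation[i]
    out$abbrev_j <- lab$abbreviation[j]
  }
  out
}

#' Vectorize / devectorize symmetric edge values
#'
#' \code{edgeVector} extracts the upper triangle of a symmetric region x
#' region matrix in canonical edge order; \code{edgeMatrix} rebuilds the
#' symmetric matrix (with a chosen diagonal) from such a vector. The two
#' are exact inverses.
#'
#' @param m Symmetric numeric matrix.
#' @param v Numeric vector of length n(n-1)/2.
#' @param n Number of regions.
#' @param diagonal Value placed on the diagonal by \code{edgeMatrix}.
#' @return A vector, or a symmetric matrix.
#' @export
edgeVector <- function(m) t(m)[lower.tri(m)]

#' @rdname edgeVector
#' @export
edgeMatrix <- function(v, n, diagonal = 1) {
  if (length(v) != n * (n - 1L) / 2L)
    stop("edge vector length ", length(v), " does not match n = ", n)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  diag(m) <- diagonal
  m
}

#' Subject-level Pearson connectivity matrix
#'
#' Computes the sample Pearson correlation between every pair of region
#' time series (the textbook centered-dot-product formula, no bias
#' correction) and its Fisher r-to-z transform. The diagonal is stored as
#' 1 in r but never enters any edge vector. Correlation is invariant to
#' affine rescaling of any region's series with positive slope.
#'
#' @param panel A \linkS4class{RoiTimeSeriesPanel} with >= 3 frames, no
#'   missing regions, and nonzero variance in every region.
#' @return A list with symmetric matrices \code{r} and \code{z}
#'   (diagonal of z set to NA), plus \code{subjectId} and \code{group}.
#' @examples
#' p <- roiTimeSeriesPanel(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4)), "s1")
#' correlationMatrix(p)$r[1, 2]  # 0.8
#' @export
correlationMatrix <- function(panel) {
  Y <- panelData(panel)
  if (ncol(Y) < 3L) stop("need at least 3 timepoints")
  if (length(missingRegions(panel)))
    stop("panel has missing regions: ",
         paste(missingRegions(panel), collapse = ", "),
         "; resolve or subset the atlas explicitly before connectivity")
  v <- apply(Y, 1L, stats::var)
  if (any(v == 0)) {
    nm <- rownames(Y)
    bad <- which(v == 0)
    stop("zero-variance (constant) region series: ",
         paste(if (is.null(nm)) bad else nm[bad], collapse = ", "))
  }
  r <- stats::cor(t(Y))
  r <- (r + t(r)) / 2                  # enforce exact symmetry
  z <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  off <- row(r) != col(r)
  z[off] <- fisherZ(r[off])
  list(r = r, z = z, subjectId = subjectId(panel),
       group = groupLabel(panel))
}

#' Assemble an edge-by-subject connectivity experiment
#'
#' Computes each subject's Pearson/Fisher-z connectivity matrix and
#' stacks the canonical edge vectors into a
#' \linkS4class{ConnectivityExperiment} (rows = edges, columns =
#' subjects) carrying the atlas edge index as \code{rowData} and subject
#' metadata as \code{colData}.
#'
#' @param panels List of \linkS4class{RoiTimeSeriesPanel} objects with a
#'   common region count.
#' @param atlas A \linkS4class{BrainAtlas} matching the panels' rows.
#' @param scores Optional data.frame of per-subject behavioral scores
#'   with a \code{subject_id} column, merged into \code{colData}.
#' @return A \linkS4class{ConnectivityExperiment}.
#' @export
connectivityExperiment <- function(panels, atlas, scores = NULL) {
  if (!length(panels)) stop("no panels supplied")
  nr <- vapply(panels, function(p) nrow(panelData(p)), 0L)
  if (any(nr != nRegions(atlas)))
    stop("panel region counts do not all match the atlas (",
         nRegions(atlas), ")")
  mats <- lapply(panels, correlationMatrix)
  rmat <- vapply(mats, function(m) edgeVector(m$r),
                 numeric(nRegions(atlas) * (nRegions(atlas) - 1L) / 2L))
  zmat <- vapply(mats, function(m) edgeVector(m$z),
                 numeric(nrow(rmat)))
  ids <- vapply(mats, `[[`, "", "subjectId")
  colnames(rmat) <- colnames(zmat) <- ids
  cd <- S4Vectors::DataFrame(
    subject_id = ids,
    group = vapply(mats, `[[`, "", "group"),
    row.names = ids)
  if (!is.null(scores)) {
    m <- match(ids, scores$subject_id)
    if (anyNA(m))
      stop("scores table is missing subjects: ",
           paste(ids[is.na(m)], collapse = ", "))
    extra <- scores[m, setdiff(colnames(scores), "subject_id"),
                    drop = FALSE]
    rownames(extra) <- NULL
    for (cn in setdiff(colnames(extra), colnames(cd)))
      cd[[cn]] <- extra[[cn]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = zmat, r = rmat),
    rowData = edgeIndex(atlas), colData = cd)
  methods::new("ConnectivityExperiment", se)
}

#' Per-group Fisher-z edge matrices
#'
#' @param ce A \linkS4class{ConnectivityExperiment}.
#' @param group \code{"patient"} or \code{"control"}.
#' @return Subjects x edges matrix of Fisher-z values.
#' @export
groupZMatrix <- function(ce, group) {
  sel <- SummarizedExperiment::colData(ce)$group == group
  if (!any(sel)) stop("no subjects in group ", group)
  t(SummarizedExperiment::assay(ce, "z")[, sel, drop = FALSE])
}
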