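#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

#' BrainAtlas: a labelled whole-brain parcellation
#'
#' Holds the label table of a volumetric parcellation: one row per region,
#' in the canonical order used for all downstream edge indexing. The
#' bundled default is the 116-region whole-brain parcellation (90 cerebral
#' regions, 45 per hemisphere, plus 26 cerebellar regions) in its standard
#' numbering.
#'
#' @slot labels A \link[S4Vectors]{DataFrame} with columns \code{region_id}
#'   (positive integer label as used in a paired label volume), \code{name},
#'   \code{abbreviation}, \code{hemisphere} (\code{left}/\code{right}/
#'   \code{midline}), \code{compartment} (\code{cerebral}/\code{cerebellar})
#'   and an optional free-text \code{network_tag} annotation (no statistical
#'   role).
#'
#' @seealso \code{\link{loadAtlasLabels}}, \code{\link{defaultAtlas}},
#'   \code{\link{edgeIndex}}
#' @export
setClass("BrainAtlas", slots = c(labels = "DataFrame"))

setValidity("BrainAtlas", function(object) {
  lab <- object@labels
  need <- c("region_id", "name", "abbreviation", "hemisphere", "compartment")
  if (!all(need %in% colnames(lab)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(lab)), collapse = ", ")))
  if (anyDuplicated(lab$region_id))
    return("duplicate region_id values")
  if (any(lab$region_id <= 0) || any(lab$region_id != round(lab$region_id)))
    return("region_id values must be positive integers")
  if (!all(lab$hemisphere %in% c("left", "right", "midline")))
    return("hemisphere must be left, right or midline")
  if (!all(lab$compartment %in% c("cerebral", "cerebellar")))
    return("compartment must be cerebral or cerebellar")
  TRUE
})

#' RoiTimeSeriesPanel: one subject's region-by-time matrix
#'
#' Region-mean BOLD time series for a single subject, rows ordered by the
#' canonical atlas ordering. Rows of regions absent from the subject's label
#' volume are NA-filled and flagged in \code{missingRegions}.
#'
#' @slot subjectId Character scalar.
#' @slot group One of \code{"patient"}, \code{"control"}, \code{"unknown"}.
#' @slot data Numeric region x time matrix.
#' @slot trSeconds Positive numeric repetition time in seconds.
#' @slot missingRegions Integer vector of row indices with no voxels.
#'
#' @seealso \code{\link{extractRoiTimeseries}}, \code{\link{correlationMatrix}}
#' @export
setClass("RoiTimeSeriesPanel",
         slots = c(subjectId = "character", group = "character",
                   data = "matrix", trSeconds = "numeric",
                   missingRegions = "integer"))

setValidity("RoiTimeSeriesPanel", function(object) {
  if (length(object@subjectId) != 1L) return("subjectId must be length 1")
  if (!object@group %in% c("patient", "control", "unknown"))
    return("group must be patient, control or unknown")
  if (!is.numeric(object@data)) return("data must be numeric")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("trSeconds must be a positive scalar")
  bad <- setdiff(which(!apply(object@data, 1L, function(x) all(is.finite(x)))),
                 object@missingRegions)
  if (length(bad))
    return(paste("non-finite values in rows not flagged missing:",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  TRUE
})

#' MotionTrace: per-frame rigid-body head motion parameters
#'
#' Six realignment parameters per imaging frame: three translations in mm
#' and three rotations in degrees (the on-disk convention of realignment
#' tools; conversion to radians happens only inside the framewise
#' displacement computation).
#'
#' @slot params Numeric n_frames x 6 matrix, columns
#'   \code{trans_x, trans_y, trans_z, rot_x, rot_y, rot_z}.
#'
#' @seealso \code{\link{motionSummary}}, \code{\link{qcExclude}}
#' @export
setClass("MotionTrace", slots = c(params = "matrix"))

setValidity("MotionTrace", function(object) {
  if (!is.numeric(object@params) || ncol(object@params) != 6L)
    return("params must be a numeric matrix with 6 columns")
  if (any(!is.finite(object@params))) return("non-finite motion parameters")
  TRUE
})

#' ConnectivityExperiment: edge-by-subject Fisher-z connectivity
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose rows are the
#' n(n-1)/2 unordered region pairs (edges) of an atlas in canonical
#' upper-triangular order and whose columns are subjects. Assays \code{"z"}
#' (Fisher r-to-z transformed correlations) and \code{"r"} (raw Pearson
#' correlations) are always present; \code{rowData} carries
#' \code{region_i}/\code{region_j} (canonical row positions) and their
#' names; \code{colData} carries \code{group} and any behavioral scores.
#'
#' @seealso \code{\link{connectivityExperiment}},
#'   \code{\link{groupEdgeInference}}
#' @export
setClass("ConnectivityExperiment",
         contains = "SummarizedExperiment")

setValidity("ConnectivityExperiment", function(object) {
  if (!all(c("z", "r") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'z' and 'r' are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("region_i", "region_j") %in% colnames(rd)))
    return("rowData must carry region_i and region_j")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must carry a group column")
  TRUE
})

#' PermutationSpec: configuration of the split-permutation null
#'
#' Describes how the within-control permutation null for the between-group
#' edge test is built: how many random splits, how controls are divided,
#' the one-tailed type-I level, and the seed.
#'
#' @slot nPermutations Integer number of random splits (>= 100).
#' @slot splitRule \code{"half_split"} (floor(n/2) vs ceiling(n/2)) or
#'   \code{"ratio_matched"} (proportional to the observed group sizes).
#' @slot alpha One-tailed type-I error probability (default 0.01).
#' @slot seed Integer master seed.
#' @slot groupSizes Integer pair used by \code{ratio_matched}.
#'
#' @seealso \code{\link{splitPermutationNull}}
#' @export
setClass("PermutationSpec",
         slots = c(nPermutations = "integer", splitRule = "character",
                   alpha = "numeric", seed = "integer",
                   groupSizes = "integer"))

setValidity("PermutationSpec", function(object) {
  if (object@nPermutations < 100L)
    return("nPermutations must be >= 100")
  if (!object@splitRule %in% c("half_split", "ratio_matched"))
    return("splitRule must be half_split or ratio_matched")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  TRUE
})

#' SyntheticDesign: generative specification of a synthetic cohort
#'
#' Full description of a two-group synthetic resting-state cohort:
#' dimensions, block-structured inter-regional correlation, injected
#' group-difference edges, temporal autocorrelation, between-subject
#' variability, behavioral score couplings and simulated head motion.
#' The defaults reproduce the study conditions the pipeline targets:
#' 39 patients vs 28 controls, 116 regions, 102 frames at TR = 3 s
#' (a 5 min 6 s acquisition).
#'
#' @slot nPatients,nControls Group sizes.
#' @slot nRegions Number of atlas regions.
#' @slot nTimepoints Frames per subject.
#' @slot trSeconds Repetition time, seconds.
#' @slot blocks List of blocks, each \code{list(members=, r=)}; pairwise
#'   block coupling given as entries \code{list(between=c(b1,b2), r=)}.
#' @slot baselineR Correlation for region pairs in no block.
#' @slot alteredEdges data.frame(i, j, r_control, r_patient).
#' @slot ar1 AR(1) temporal autocorrelation coefficient in [0, 0.9].
#' @slot subjectVariabilitySd Between-subject jitter sd on the Fisher-z
#'   scale.
#' @slot scoreCouplings data.frame(i, j, score, target_r): the named score
#'   is constructed to correlate with the realized Fisher z of edge (i, j)
#'   across patients at target_r.
#' @slot motionLevelMm Sd of per-frame motion increments (mm and degrees).
#' @slot seed Integer master seed.
#'
#' @seealso \code{\link{syntheticDesign}}, \code{\link{simulateCohort}}
#' @export
setClass("SyntheticDesign",
         slots = c(nPatients = "integer", nControls = "integer",
                   nRegions = "integer", nTimepoints = "integer",
                   trSeconds = "numeric", blocks = "list",
                   baselineR = "numeric", alteredEdges = "data.frame",
                   ar1 = "numeric", subjectVariabilitySd = "numeric",
                   scoreCouplings = "data.frame", motionLevelMm = "numeric",
                   seed = "integer"))

setValidity("SyntheticDesign", function(object) {
  if (object@nPatients < 2L || object@nControls < 2L)
    return("at least 2 subjects per group")
  if (object@nRegions < 2L) return("need at least 2 regions")
  if (object@nTimepoints < 3L) return("need at least 3 timepoints")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  if (object@ar1 < 0 || object@ar1 > 0.9)
    return("ar1 must lie in [0, 0.9]")
  if (object@subjectVariabilitySd < 0)
    return("subjectVariabilitySd must be >= 0")
  ae <- object@alteredEdges
  if (nrow(ae)) {
    if (!all(c("i", "j", "r_control", "r_patient") %in% colnames(ae)))
      return("alteredEdges needs columns i, j, r_control, r_patient")
    if (any(abs(c(ae$r_control, ae$r_patient)) >= 1))
      return("altered-edge correlations must have |r| < 1")
    if (any(ae$i >= ae$j))
      return("altered edges must satisfy i < j")
    if (any(ae$j > object@nRegions))
      return("altered edge index exceeds nRegions")
  }
  sc <- object@scoreCouplings
  if (nrow(sc)) {
    if (!all(c("i", "j", "score", "target_r") %in% colnames(sc)))
      return("scoreCouplings needs columns i, j, score, target_r")
    if (any(abs(sc$target_r) >= 1))
      return("coupling target |r| must be < 1")
  }
  TRUE
})

setMethod("show", "BrainAtlas", function(object) {
  lab <- object@labels
  cat("BrainAtlas with", nrow(lab), "regions (",
      sum(lab$compartment == "cerebral"), "cerebral,",
      sum(lab$compartment == "cerebellar"), "cerebellar )\n")
  cat("  first:", paste(utils::head(lab$name, 3L), collapse = ", "), "...\n")
})

setMethod("show", "RoiTimeSeriesPanel", function(object) {
  cat("RoiTimeSeriesPanel", object@subjectId, "(", object@group, "):",
      nrow(object@data), "regions x", ncol(object@data), "frames, TR",
      object@trSeconds, "s\n")
  if (length(object@missingRegions))
    cat("  missing regions:",
        paste(object@missingRegions, collapse = ", "), "\n")
})

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", object@nPatients, "patients /", object@nControls,
      "controls,", object@nRegions, "regions,", object@nTimepoints,
      "frames @ TR", object@trSeconds, "s\n")
  cat("  blocks:", length(object@blocks),
      "| altered edges:", nrow(object@alteredEdges),
      "| score couplings:", nrow(object@scoreCouplings),
      "| ar1:", object@ar1, "| seed:", object@seed, "\n")
})
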