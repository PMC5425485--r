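#' Read a pipeline configuration file
#'
#' Configurations are YAML (or JSON, which YAML subsumes) mappings; see
#' \code{\link{runPipeline}} for the recognised keys. Defaults are
#' filled in for everything omitted.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  .fillConfig(yaml::read_yaml(path))
}

.fillConfig <- function(config) {
  def <- list(
    mode = "synthetic",
    synthetic = list(),
    files = list(),
    qc = list(enabled = TRUE, maxTranslationMm = 2.5, maxRotationDeg = 2.5,
              meanTranslationMm = 0.15, meanRotationDeg = 0.1),
    preprocess = list(nuisance = TRUE, bandpass = TRUE,
                      lowHz = 0.01, highHz = 0.08),
    inference = list(q1 = 0.01, p2 = 0.01, alphaPerm = 0.01,
                     nPermutations = 10000L, splitRule = "half_split"),
    behavior = list(scores = c("MMSE", "MoCA", "PSQI", "ISI"),
                    level = 0.05, family = "grid"),
    seed = 1L)
  for (k in names(def)) {
    if (is.null(config[[k]])) {
      config[[k]] <- def[[k]]
    } else if (is.list(def[[k]])) {
      for (kk in names(def[[k]]))
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- def[[k]][[kk]]
    }
  }
  if (!config$mode %in% c("synthetic", "files"))
    stop("mode must be 'synthetic' or 'files'")
  config
}

#' Placeholder atlas for non-standard region counts
#'
#' Builds a neutral \linkS4class{BrainAtlas} with generic region names,
#' for pipelines running on parcellations (or synthetic designs) whose
#' region count differs from the bundled 116-region table.
#'
#' @param n Number of regions.
#' @return A \linkS4class{BrainAtlas} with \code{n} generic regions.
#' @export
genericAtlas <- function(n) {
  methods::new("BrainAtlas", labels = S4Vectors::DataFrame(
    region_id = seq_len(n),
    name = sprintf("Region_%03d", seq_len(n)),
    abbreviation = sprintf("R%03d", seq_len(n)),
    hemisphere = rep("midline", n),
    compartment = rep("cerebral", n),
    network_tag = rep("", n)))
}

.designFromConfig <- function(syn, seed) {
  args <- syn
  if (isTRUE(args$defaultAltered)) {
    dz <- if (is.null(args$deltaZ)) 0.5 else args$deltaZ
    args$alteredEdges <- defaultAlteredEdges(dz)
  }
  args$defaultAltered <- NULL
  args$deltaZ <- NULL
  # YAML serializes a data.frame as a named list of columns; a config
  # written in R may instead give a list of per-edge rows
  asFrame <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    if (!is.null(names(x))) as.data.frame(x, stringsAsFactors = FALSE)
    else do.call(rbind.data.frame, x)
  }
  args$alteredEdges <- asFrame(args$alteredEdges)
  args$scoreCouplings <- asFrame(args$scoreCouplings)
  if (is.null(args$alteredEdges)) args["alteredEdges"] <- NULL
  if (is.null(args$scoreCouplings)) args["scoreCouplings"] <- NULL
  if (is.null(args$seed)) args$seed <- seed
  do.call(syntheticDesign, args)
}

.loadFilesCohort <- function(files) {
  panels <- lapply(files$panels, readRoiPanel)
  motion <- if (length(files$motion))
    lapply(files$motion, readMotionTrace) else NULL
  scores <- if (!is.null(files$subjects))
    utils::read.delim(files$subjects, stringsAsFactors = FALSE) else NULL
  if (!is.null(scores) && "group" %in% colnames(scores)) {
    m <- match(vapply(panels, subjectId, ""), scores$subject_id)
    panels <- lapply(seq_along(panels), function(k) {
      if (!is.na(m[k]))
        methods::initialize(panels[[k]], group = scores$group[m[k]])
      else panels[[k]]
    })
  }
  list(panels = panels, motion = motion, scores = scores, truth = NULL)
}

#' Run the full connectivity group-analysis pipeline
#'
#' Sequences quality control, time-series preprocessing, subject-level
#' connectivity, two-criterion group edge inference and edge-behavior
#' correlation as one reproducible run. Identical configuration and seed
#' give identical outputs.
#'
#' The configuration list (or YAML file via
#' \code{\link{readPipelineConfig}}) has blocks:
#' \describe{
#'   \item{mode}{\code{"synthetic"} (generate a cohort from a
#'     \code{synthetic} design block) or \code{"files"} (read panels,
#'     motion traces and a subject table from the \code{files} block).}
#'   \item{qc}{motion exclusion thresholds; excluded subjects are
#'     dropped with a logged reason.}
#'   \item{preprocess}{\code{nuisance} (motion + drift regression),
#'     \code{bandpass} with \code{lowHz}/\code{highHz}.}
#'   \item{inference}{\code{q1}, \code{p2}, \code{alphaPerm},
#'     \code{nPermutations}, \code{splitRule}.}
#'   \item{behavior}{score columns to correlate with selected edges,
#'     \code{level}, \code{family}.}
#' }
#'
#' @param config Configuration list or path to a YAML file.
#' @param outDir Optional output directory; when given, all tables
#'   (edge statistics, selected edges, behavior correlations, QC report,
#'   graph export), the serialized configuration and a machine-readable
#'   JSON summary are written there.
#' @return A run report list: \code{atlas}, \code{qc},
#'   \code{connectivity} (the \linkS4class{ConnectivityExperiment}),
#'   \code{edgeStats}, \code{selected}, \code{behavior}, \code{truth}
#'   (synthetic mode) and \code{summary} (counts per stage and per
#'   direction class, thresholds, seed).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- .fillConfig(config)
  seed <- as.integer(config$seed)

  cohort <- if (config$mode == "synthetic") {
    simulateCohort(.designFromConfig(config$synthetic, seed))
  } else {
    .loadFilesCohort(config$files)
  }
  panels <- cohort$panels
  atlas <- if (nrow(panelData(panels[[1L]])) == 116L) defaultAtlas() else
    genericAtlas(nrow(panelData(panels[[1L]])))

  # ---- QC -------------------------------------------------------------
  qcTab <- NULL
  if (isTRUE(config$qc$enabled) && !is.null(cohort$motion)) {
    sums <- t(vapply(cohort$motion, motionSummary, numeric(5L)))
    dec <- lapply(seq_len(nrow(sums)), function(k)
      qcExclude(sums[k, ],
                maxTranslationMm = config$qc$maxTranslationMm,
                maxRotationDeg = config$qc$maxRotationDeg,
                meanTranslationMm = config$qc$meanTranslationMm,
                meanRotationDeg = config$qc$meanRotationDeg))
    qcTab <- data.frame(subject_id = vapply(panels, subjectId, ""),
                        group = vapply(panels, groupLabel, ""),
                        sums,
                        keep = vapply(dec, `[[`, TRUE, "keep"),
                        reasons = vapply(dec, function(d)
                          paste(d$reasons, collapse = "; "), ""))
    if (any(!qcTab$keep)) {
      message("QC excludes ", sum(!qcTab$keep), " subject(s): ",
              paste(qcTab$subject_id[!qcTab$keep], collapse = ", "))
      panels <- panels[qcTab$keep]
    }
  }

  # ---- preprocessing --------------------------------------------------
  pp <- config$preprocess
  motion <- if (!is.null(cohort$motion) && !is.null(qcTab))
    cohort$motion[qcTab$keep] else cohort$motion
  panels <- lapply(seq_along(panels), function(k) {
    p <- panels[[k]]
    if (isTRUE(pp$nuisance)) {
      des <- buildNuisanceDesign(ncol(panelData(p)),
                                 trace = if (!is.null(motion))
                                   motion[[k]] else NULL)
      p <- regressNuisance(p, des)
    }
    if (isTRUE(pp$bandpass))
      p <- bandpassFilter(p, lowHz = pp$lowHz, highHz = pp$highHz)
    p
  })

  # ---- connectivity and inference ------------------------------------
  ce <- connectivityExperiment(panels, atlas, scores = cohort$scores)
  inf <- config$inference
  spec <- permutationSpec(nPermutations = inf$nPermutations,
                          splitRule = inf$splitRule,
                          alpha = inf$alphaPerm, seed = seed)
  stats <- groupEdgeInference(ce, spec, q1 = inf$q1, p2 = inf$p2)
  selected <- selectAlteredEdges(stats)

  # ---- behavior -------------------------------------------------------
  beh <- NULL
  scoresAvail <- intersect(config$behavior$scores,
                           colnames(SummarizedExperiment::colData(ce)))
  if (nrow(selected) && length(scoresAvail) &&
      sum(SummarizedExperiment::colData(ce)$group == "patient") >= 3L) {
    beh <- edgeScoreCorrelations(ce, selected$edge_id, scoresAvail,
                                 level = config$behavior$level,
                                 family = config$behavior$family)
  }

  dirCounts <- table(factor(selected$direction_class,
                            levels = c("decreased_positive",
                                       "increased_positive",
                                       "increased_negative",
                                       "decreased_negative",
                                       "unclassified")))
  summary <- list(
    seed = seed, n_subjects = ncol(ce),
    n_patients = sum(SummarizedExperiment::colData(ce)$group == "patient"),
    n_controls = sum(SummarizedExperiment::colData(ce)$group == "control"),
    n_regions = nRegions(atlas), n_edges = nrow(ce),
    n_excluded_qc = if (is.null(qcTab)) 0L else sum(!qcTab$keep),
    n_criterion1 = sum(stats$fdr_pass_patient | stats$fdr_pass_control),
    n_criterion2 = sum(stats$p2 < inf$p2 & stats$perm_significant,
                       na.rm = TRUE),
    n_selected = nrow(selected),
    selected_fraction = nrow(selected) / nrow(ce),
    direction_counts = as.list(dirCounts),
    thresholds = inf,
    package_version = as.character(utils::packageVersion("edgeFC")))
  message(sprintf(
    "pipeline: %d subjects | %d edges | criterion1 %d | criterion2 %d | selected %d",
    summary$n_subjects, summary$n_edges, summary$n_criterion1,
    summary$n_criterion2, summary$n_selected))

  report <- list(atlas = atlas, qc = qcTab, connectivity = ce,
                 edgeStats = stats, selected = selected, behavior = beh,
                 truth = cohort$truth, summary = summary)
  if (!is.null(outDir)) .writeRunOutputs(report, config, outDir)
  report
}

.writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.writeRunOutputs <- function(report, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(report$edgeStats, file.path(outDir, "edge_stats.tsv"))
  .writeTsv(report$selected, file.path(outDir, "selected_edges.tsv"))
  if (!is.null(report$behavior))
    .writeTsv(report$behavior, file.path(outDir, "behavior_correlations.tsv"))
  if (!is.null(report$qc))
    .writeTsv(report$qc, file.path(outDir, "qc_report.tsv"))
  renderEdgeGraph(report$selected, report$atlas,
                  file.path(outDir, "selected_edges_graph.tsv"))
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  jsonlite::write_json(report$summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Export selected edges for graph rendering
#'
#' Writes (and returns) an edge-list usable by standard graph / brain-net
#' viewers: region abbreviations, direction class and a color code
#' following the usual convention for group-difference connectograms -
#' red for decreased connectivity strength in patients
#' (\code{decreased_*} classes), blue for increased strength
#' (\code{increased_*}), grey for unclassified edges.
#'
#' @param selected Selected-edge table from
#'   \code{\link{selectAlteredEdges}}.
#' @param atlas The \linkS4class{BrainAtlas} the edges refer to.
#' @param path Optional output TSV path; an empty selection writes a
#'   header-only file.
#' @return A data.frame with columns \code{abbrev_i}, \code{abbrev_j},
#'   \code{name_i}, \code{name_j}, \code{t2}, \code{direction_class},
#'   \code{color}.
#' @export
renderEdgeGraph <- function(selected, atlas, path = NULL) {
  lab <- atlasLabels(atlas)
  n <- nrow(selected)
  out <- data.frame(
    abbrev_i = lab$abbreviation[selected$region_i],
    abbrev_j = lab$abbreviation[selected$region_j],
    name_i = lab$name[selected$region_i],
    name_j = lab$name[selected$region_j],
    t2 = selected$t2,
    direction_class = selected$direction_class,
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  out$color <- ifelse(startsWith(out$direction_class, "decreased"), "red",
                      ifelse(startsWith(out$direction_class, "increased"),
                             "blue", "grey"))
  if (!is.null(path)) .writeTsv(out, path)
  out
}
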