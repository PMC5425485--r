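#' Load an atlas label table
#'
#' Reads a tab-separated parcellation label table into a
#' \linkS4class{BrainAtlas}. Row order in the file defines the canonical
#' region ordering used by every downstream stage (time-series rows,
#' connectivity matrices and edge indexing), so a single table is the
#' single source of truth for edge identity.
#'
#' By default the table is required to describe the bundled whole-brain
#' parcellation: exactly 116 regions, of which 90 are cerebral (45 per
#' hemisphere) and 26 cerebellar. Alternative parcellations of any size
#' are accepted with \code{strict = FALSE}.
#'
#' @param path Path to a TSV file with header columns \code{region_id},
#'   \code{name}, \code{abbreviation}, \code{hemisphere},
#'   \code{compartment} and optionally \code{network_tag}.
#' @param strict Enforce the 116-region / 90 + 26 layout (default
#'   \code{TRUE}).
#' @return A \linkS4class{BrainAtlas}.
#' @examples
#' atlas <- defaultAtlas()
#' nRegions(atlas)
#' @export
loadAtlasLabels <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("atlas label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"network_tag" %in% colnames(tab)) tab$network_tag <- ""
  tab$network_tag[is.na(tab$network_tag)] <- ""
  if (anyDuplicated(tab$region_id))
    stop("duplicate region_id in atlas table: ",
         paste(unique(tab$region_id[duplicated(tab$region_id)]),
               collapse = ", "))
  if (strict) {
    if (nrow(tab) != 116L)
      stop("expected 116 regions in the bundled parcelllation layout, got ",
           nrow(tab), "; pass strict = FALSE for a custom atlas")
    if (sum(tab$compartment == "cerebral") != 90L ||
        sum(tab$compartment == "cerebellar") != 26L)
      stop("expected 90 cerebral + 26 cerebellar regions")
  }
  methods::new("BrainAtlas", labels = S4Vectors::DataFrame(tab))
}

#' The bundled 116-region whole-brain atlas
#'
#' Returns the package's default parcellation label table: 116 regions in
#' standard automated-anatomical-labelling order (90 cerebral regions, 45
#' per hemisphere, then 26 cerebellar regions including the vermis).
#'
#' @return A \linkS4class{BrainAtlas} with 116 regions.
#' @export
defaultAtlas <- function() {
  loadAtlasLabels(system.file("extdata", "aal116_labels.tsv",
                              package = "edgeFC"))
}

#' Construct a subject time-series panel
#'
#' @param data Numeric region x time matrix in canonical atlas row order.
#' @param subjectId Subject identifier.
#' @param group \code{"patient"}, \code{"control"} or \code{"unknown"}.
#' @param trSeconds Repetition time in seconds.
#' @param missingRegions Integer indices of atlas rows with no data
#'   (NA-filled).
#' @return A \linkS4class{RoiTimeSeriesPanel}.
#' @export
roiTimeSeriesPanel <- function(data, subjectId, group = "unknown",
                               trSeconds = 3, missingRegions = integer()) {
  methods::new("RoiTimeSeriesPanel", subjectId = as.character(subjectId),
               group = group, data = as.matrix(data),
               trSeconds = trSeconds,
               missingRegions = as.integer(missingRegions))
}

.readVolume <- function(x) {
  if (is.character(x)) as.array(RNifti::readNifti(x)) else as.array(x)
}

#' Extract region-mean time series from a labelled 4-D image
#'
#' Reduces a 4-D voxel image to one mean time series per atlas region: the
#' value of region r at frame t is the arithmetic mean over all voxels
#' whose label-volume value equals r's \code{region_id}. Regions present
#' in the atlas but absent from the label volume are kept as NA rows and
#' flagged (never silently dropped, since dropping regions would change
#' the downstream edge count).
#'
#' @param image 4-D numeric array (x, y, z, time) or path to a NIfTI file.
#' @param labels 3-D integer array of region labels (0 = background) or
#'   path to a NIfTI file; spatial shape must match \code{image}.
#' @param atlas A \linkS4class{BrainAtlas}; its row order defines the
#'   output row order.
#' @param subjectId,group,trSeconds Panel metadata.
#' @return A \linkS4class{RoiTimeSeriesPanel}; rows of missing regions are
#'   NA and listed in \code{missingRegions()}. A warning names them.
#' @examples
#' img <- array(c(1, 5, 2, 6, 3, 7), dim = c(2, 1, 1, 3))
#' lab <- array(c(1L, 2L), dim = c(2, 1, 1))
#' atlas <- loadAtlasLabels(system.file("extdata", "aal116_labels.tsv",
#'                                      package = "edgeFC"))
#' @export
extractRoiTimeseries <- function(image, labels, atlas, subjectId = "subj",
                                 group = "unknown", trSeconds = 3) {
  img <- .readVolume(image)
  lab <- .readVolume(labels)
  if (length(dim(img)) != 4L) stop("image must be 4-D (x, y, z, time)")
  if (length(dim(lab)) != 3L) stop("label volume must be 3-D")
  if (!identical(dim(img)[1:3], dim(lab)))
    stop("spatial shape mismatch: image ",
         paste(dim(img)[1:3], collapse = "x"), " vs labels ",
         paste(dim(lab), collapse = "x"))
  if (all(lab == 0)) stop("label volume contains no labelled voxels")
  ids <- atlasLabels(atlas)$region_id
  extra <- setdiff(unique(lab[lab != 0]), ids)
  if (length(extra))
    stop("label volume contains values absent from the atlas: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  nt <- dim(img)[4L]
  vox <- matrix(img, ncol = nt)       # voxels x time
  labv <- as.vector(lab)
  out <- matrix(NA_real_, nrow = length(ids), ncol = nt)
  missing <- integer()
  for (r in seq_along(ids)) {
    sel <- labv == ids[r]
    if (!any(sel)) {
      missing <- c(missing, r)
    } else {
      out[r, ] <- colMeans(vox[sel, , drop = FALSE])
    }
  }
  if (length(missing))
    warning("regions with no voxels in the label volume: ",
            paste(atlasLabels(atlas)$name[missing], collapse = ", "))
  rownames(out) <- atlasLabels(atlas)$name
  roiTimeSeriesPanel(out, subjectId = subjectId, group = group,
                     trSeconds = trSeconds, missingRegions = missing)
}

#' Write / read a time-series panel as delimited text
#'
#' Panels are persisted as TSV with regions in rows and frames in columns,
#' preceded by \code{#}-prefixed metadata comment lines (subject id, group,
#' TR, missing-region flags). \code{readRoiPanel} round-trips a written
#' panel to full double precision.
#'
#' @param panel A \linkS4class{RoiTimeSeriesPanel}.
#' @param path Output (input) file path.
#' @return \code{writeRoiPanel} returns \code{path} invisibly;
#'   \code{readRoiPanel} returns the panel.
#' @export
writeRoiPanel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# subject_id\t", subjectId(panel)),
               paste0("# group\t", groupLabel(panel)),
               paste0("# tr_seconds\t",
                      format(trSeconds(panel), digits = 17)),
               paste0("# missing_regions\t",
                      paste(missingRegions(panel), collapse = ","))), con)
  utils::write.table(format(panelData(panel), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(panelData(panel))),
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiPanel
#' @export
readRoiPanel <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ", "", lines[startsWith(lines, "# ")])
  keys <- sub("\t.*$", "", hdr)
  vals <- ifelse(grepl("\t", hdr), sub("^[^\t]*\t", "", hdr), "")
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) "" else vals[i]
  }
  body <- lines[!startsWith(lines, "# ")]
  parts <- strsplit(body, "\t")
  hasNames <- is.na(suppressWarnings(as.numeric(parts[[1L]][1L])))
  mat <- do.call(rbind, lapply(parts, function(p) {
    if (hasNames) as.numeric(p[-1L]) else as.numeric(p)
  }))
  if (hasNames) rownames(mat) <- vapply(parts, `[`, "", 1L)
  miss <- get("missing_regions")
  miss <- if (nzchar(miss)) {
    as.integer(strsplit(miss, ",")[[1L]])
  } else {
    integer()
  }
  mat[miss, ] <- NA_real_
  roiTimeSeriesPanel(mat, subjectId = get("subject_id"),
                     group = get("group"),
                     trSeconds = as.numeric(get("tr_seconds")),
                     missingRegions = miss)
}
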