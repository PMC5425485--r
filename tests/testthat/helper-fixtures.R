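# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk except the bundled atlas label table.

# A 4-row toy atlas written to a temporary TSV.
toyAtlasFile <- function(dir = tempdir(), dup = FALSE) {
  tab <- data.frame(region_id = c(1L, 2L, 3L, if (dup) 3L else 4L),
                    name = paste0("Toy_", 1:4),
                    abbreviation = paste0("T", 1:4),
                    hemisphere = c("left", "right", "left", "right"),
                    compartment = c("cerebral", "cerebral",
                                    "cerebellar", "cerebellar"),
                    network_tag = "")
  path <- tempfile("atlas", dir, ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyAtlas <- function() loadAtlasLabels(toyAtlasFile(), strict = FALSE)

# Panel with given data matrix and sensible defaults.
toyPanel <- function(data, tr = 3, group = "unknown", id = "s1")
  roiTimeSeriesPanel(data, subjectId = id, group = group, trSeconds = tr)

# A small two-group set of panels with iid Gaussian series.
gaussianPanels <- function(nA = 4, nB = 4, nRegions = 5, nt = 30,
                           seed = 1) {
  set.seed(seed)
  mk <- function(id, group)
    toyPanel(matrix(rnorm(nRegions * nt), nRegions, nt),
             group = group, id = id)
  c(lapply(seq_len(nA), function(k) mk(sprintf("pat%02d", k), "patient")),
    lapply(seq_len(nB), function(k) mk(sprintf("ctl%02d", k), "control")))
}

# Brute-force Benjamini-Hochberg step-up: the independent oracle used
# against bhFdr(). Sorts p, finds the largest k with p_(k) <= k q / m,
# rejects the k smallest.
bhBruteForce <- function(p, q) {
  ok <- which(!is.na(p))
  m <- length(ok)
  rej <- logical(length(p))
  if (!m) return(rej)
  ord <- ok[order(p[ok])]
  ks <- which(p[ord] <= q * seq_len(m) / m)
  if (length(ks)) rej[ord[seq_len(max(ks))]] <- TRUE
  rej
}

# Textbook pooled-variance two-sample t for a single edge.
pooledTOracle <- function(a, b) {
  s2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(s2 * (1 / length(a) + 1 / length(b)))
}
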