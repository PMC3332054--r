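# TSV dialect: first column probe_id, remaining columns sample ids.
writeMatrixTSV <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

readMatrixTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (colnames(dt)[1] != "probe_id")
    stop("expected first column 'probe_id' in ", path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$probe_id
  m
}

#' Read an expression matrix (and detection p-values) from TSV
#'
#' Both files use the dialect written by [writeFixture()]: first column
#' `probe_id`, then one float column per sample. Values in scientific notation
#' are parsed exactly.
#'
#' @param matrixPath intensity matrix TSV.
#' @param detectionPath optional detection p-value TSV of identical shape.
#' @param samples optional sample sheet (data.frame or path for
#'   [readSampleSheet()]).
#' @param scale intensity scale of the matrix file.
#' @return a [PBMCExperiment-class].
#' @export
readExpression <- function(matrixPath, detectionPath = NULL, samples = NULL,
                           scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  m <- readMatrixTSV(matrixPath)
  det <- NULL
  if (!is.null(detectionPath)) {
    det <- readMatrixTSV(detectionPath)
    if (!identical(dim(det), dim(m)))
      stop(sprintf(
        "dimension mismatch between matrix (%d x %d) and detection (%d x %d)",
        nrow(m), ncol(m), nrow(det), ncol(det)))
    if (!identical(colnames(det), colnames(m)))
      stop("sample ids differ between matrix and detection files")
    if (!identical(rownames(det), rownames(m)))
      stop("probe ids differ between matrix and detection files")
  }
  if (is.character(samples)) samples <- readSampleSheet(samples)
  PBMCExperiment(m, detection = det, samples = samples, scale = scale)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `group` (control, PTPN11, SOS1 or SHOC2),
#' `age`, `sex`, and the five leukocyte fractions
#' `neut_frac, lymph_frac, mono_frac, eos_frac, baso_frac`.
#'
#' @param path sample sheet TSV.
#' @return a data.frame keyed by `sample_id`.
#' @export
readSampleSheet <- function(path) {
  s <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "group")
  missing <- setdiff(need, colnames(s))
  if (length(missing))
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  if (!all(s$group %in% .GROUPS))
    stop("unknown group labels: ",
         paste(setdiff(unique(s$group), .GROUPS), collapse = ", "))
  if ("age" %in% colnames(s) && any(s$age < 0))
    stop("negative ages in sample sheet")
  rownames(s) <- s$sample_id
  s
}

#' Read a fixture directory written by [writeFixture()]
#'
#' @param dir directory containing `matrix.tsv`, `detection.tsv`,
#'   `samples.tsv` (and optionally `truth.json`).
#' @param scale intensity scale of the matrix file (fixtures from
#'   [simulatePBMC()] are log2).
#' @return a [PBMCExperiment-class]; truth, when present, is reattached to
#'   `metadata(x)$truth`.
#' @export
readFixture <- function(dir, scale = "log2") {
  x <- readExpression(file.path(dir, "matrix.tsv"),
                      detectionPath = file.path(dir, "detection.tsv"),
                      samples = file.path(dir, "samples.tsv"),
                      scale = scale)
  truthPath <- file.path(dir, "truth.json")
  if (file.exists(truthPath)) {
    tl <- jsonlite::read_json(truthPath)
    metadata(x)$truth <- data.frame(
      probe_id = names(tl),
      label = vapply(tl, `[[`, character(1), "label"),
      direction = vapply(tl, `[[`, character(1), "direction"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  x
}
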