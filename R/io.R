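#' Read a subject table
#'
#' Parses a delimited text file describing the scans of a longitudinal
#' study.  Required header columns: \code{subject_id}, \code{label} (+1 or
#' -1), \code{time} (acquisition time in years, any origin) and
#' \code{source} (path to a NIfTI volume, or 1-based row index into a
#' samples x D matrix file).  An optional \code{set} column
#' (\code{longitudinal} / \code{classification} / \code{both}) records set
#' membership.  The delimiter (tab, comma or semicolon) is detected from the
#' header line.
#'
#' Rows are grouped by subject and sorted by ascending time; times are
#' re-expressed relative to each subject's first scan.  The result is a
#' dataset skeleton: feature values are attached later by
#' [loadCohortMatrix()] or [loadCohortNifti()].
#'
#' @param path file path.
#' @return a data.frame with columns \code{subject_id}, \code{label},
#'   \code{time} (relative years), \code{source} and (if present)
#'   \code{set}, sorted by subject then time.
#' @export
readSubjectTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(";", hdr)) ";" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("subject_id", "label", "time", "source")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop(sprintf("subject table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  lab <- suppressWarnings(as.numeric(gsub("^\\+", "", as.character(tab$label))))
  if (any(is.na(lab)) || !all(lab %in% c(-1, 1)))
    stop("label must be +1 or -1")
  tab$label <- lab
  tab$time <- as.numeric(tab$time)
  if (any(!is.finite(tab$time))) stop("time must be numeric")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab[, c("subject_id", "time")]))
    stop("duplicate (subject_id, time) pair")
  if ("set" %in% colnames(tab)) {
    bad <- setdiff(unique(tab$set), c("longitudinal", "classification", "both"))
    if (length(bad))
      stop(sprintf("unknown set value(s): %s", paste(bad, collapse = ", ")))
  }
  o <- order(match(tab$subject_id, unique(tab$subject_id)), tab$time)
  tab <- tab[o, , drop = FALSE]
  tab$time <- stats::ave(tab$time, tab$subject_id, FUN = function(t) t - t[1])
  for (s in unique(tab$subject_id)) {
    l <- tab$label[tab$subject_id == s]
    if (length(unique(l)) != 1L)
      stop(sprintf("subject '%s' has inconsistent labels", s))
  }
  rownames(tab) <- NULL
  tab
}

#' Build a cohort from a subject table and a samples-by-features matrix
#'
#' \code{loadCohortMatrix} reads a delimited numeric matrix (samples x D, no
#' header) and assembles the \linkS4class{LongitudinalCohort}: the table's
#' \code{source} column gives the 1-based matrix row of each scan.
#' \code{buildCohort} does the same from an in-memory matrix.  Both routes
#' and the NIfTI route ([loadCohortNifti()]) produce identical cohort
#' objects for the same underlying values.
#'
#' @param table a subject table (data.frame from [readSubjectTable()]) or a
#'   path to one.
#' @param matrix a samples x D numeric matrix, or (for
#'   \code{loadCohortMatrix}) a path to a delimited file of one.
#' @param featureSpace feature-space tag, see [longitudinalCohort()].
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
buildCohort <- function(table, matrix, featureSpace = "generic") {
  if (is.character(table)) table <- readSubjectTable(table)
  .assertMatrix(matrix, "matrix")
  src <- suppressWarnings(as.integer(table$source))
  if (any(is.na(src)))
    stop("source column must hold matrix row indices for the matrix route")
  if (any(src < 1L | src > nrow(matrix)))
    stop("source row index out of range")
  longitudinalCohort(t(matrix[src, , drop = FALSE]),
                     subject = table$subject_id, label = table$label,
                     time = table$time, featureSpace = featureSpace)
}

#' @rdname buildCohort
#' @export
loadCohortMatrix <- function(table, matrix, featureSpace = "generic") {
  if (is.character(matrix)) {
    hdr <- readLines(matrix, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
    matrix <- as.matrix(utils::read.table(matrix, header = FALSE, sep = sep))
    dimnames(matrix) <- NULL
  }
  buildCohort(table, matrix, featureSpace = featureSpace)
}

#' Build a cohort from masked NIfTI volumes
#'
#' Reads one NIfTI volume per scan (paths in the table's \code{source}
#' column, resolved relative to the table's directory when not absolute),
#' applies the brain mask to each and assembles the cohort with
#' \code{featureSpace = "masked-voxels"}.
#'
#' @param table subject table (data.frame or path).
#' @param mask a \linkS4class{BrainMask} or path to a binary NIfTI mask.
#' @return a \linkS4class{LongitudinalCohort} with D = number of mask voxels.
#' @export
loadCohortNifti <- function(table, mask) {
  dir <- "."
  if (is.character(table)) {
    dir <- dirname(table)
    table <- readSubjectTable(table)
  }
  if (is.character(mask)) mask <- readBrainMask(mask)
  stopifnot(is(mask, "BrainMask"))
  paths <- as.character(table$source)
  paths <- ifelse(grepl("^(/|~)", paths), paths, file.path(dir, paths))
  feats <- vapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    applyMask(img, mask)
  }, numeric(mask@D))
  dimnames(feats) <- NULL
  longitudinalCohort(feats, subject = table$subject_id, label = table$label,
                     time = table$time, featureSpace = "masked-voxels")
}

#' Write / read a metrics report as JSON
#'
#' Serializes every field of a \linkS4class{MetricsReport} at full precision
#' together with table-style display renderings (percentages rounded
#' half-up to one decimal, AUC to three).  \code{readMetrics} restores an
#' identical report from such a file.
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path output/input file path.
#' @return \code{writeMetrics} returns \code{path} invisibly;
#'   \code{readMetrics} returns a \linkS4class{MetricsReport}.
#' @export
writeMetrics <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  if (report@nPos + report@nNeg == 0L)
    stop("empty report: no subjects")
  out <- list(
    counts = list(tp = report@tp, fp = report@fp, tn = report@tn,
                  fn = report@fn),
    n = list(pos = report@nPos, neg = report@nNeg),
    fractions = list(
      sensitivity = report@sensitivity, specificity = report@specificity,
      balanced_accuracy = report@balancedAccuracy,
      ppv = report@ppv, npv = report@npv, roc_auc = report@rocAuc),
    display = list(
      sensitivity_pct = .percent1(report@sensitivity),
      specificity_pct = .percent1(report@specificity),
      balanced_accuracy_pct = .percent1(report@balancedAccuracy),
      ppv_pct = .percent1(report@ppv), npv_pct = .percent1(report@npv),
      roc_auc = .roundHalfUp(report@rocAuc, 3)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("MetricsReport",
      tp = as.integer(x$counts$tp), fp = as.integer(x$counts$fp),
      tn = as.integer(x$counts$tn), fn = as.integer(x$counts$fn),
      sensitivity = num(x$fractions$sensitivity),
      specificity = num(x$fractions$specificity),
      balancedAccuracy = num(x$fractions$balanced_accuracy),
      ppv = num(x$fractions$ppv), npv = num(x$fractions$npv),
      rocAuc = num(x$fractions$roc_auc),
      nPos = as.integer(x$n$pos), nNeg = as.integer(x$n$neg))
}
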