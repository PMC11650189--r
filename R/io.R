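# Delimited-text readers/writers for every interchange format.
# All numeric output is written with full precision (%.15g) so that
# write -> read round-trips are value-faithful and runs are byte-stable.

fmtNum <- function(x) formatC(x, format = "g", digits = 15)

#' Write / read a numeric matrix as TSV
#'
#' Row names go into a leading `id` column; column names into the header.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `readMatrixTSV` returns the matrix with dimnames restored.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% paste0("r", seq_len(nrow(m))),
                   apply(unname(m), 2L, fmtNum), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(m) %||% paste0("c", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write / read the subject table as CSV
#'
#' @param subjects subject data.frame.
#' @param path file path.
#' @export
writeSubjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSubjects
#' @export
readSubjects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a node -> network partition as CSV
#'
#' @param partition data.frame with columns `node`, `network`.
#' @param path file path.
#' @export
writePartition <- function(partition, path) {
  utils::write.csv(partition, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write / read a parcel sphere as CSV
#'
#' Columns: parcel, x, y, z, hemisphere.
#'
#' @param sphere sphere data.frame.
#' @param path file path.
#' @export
writeSphere <- function(sphere, path) {
  out <- sphere
  for (cc in c("x", "y", "z")) out[[cc]] <- fmtNum(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSphere
#' @export
readSphere <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write / read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then members.
#'
#' @param collection a [GeneSetCollection-class] (descriptions optional via
#'   the `descriptions` argument).
#' @param path file path.
#' @param descriptions optional named character descriptions.
#' @return `readGMT` returns a [GeneSetCollection-class]; the background is
#'   the union of members unless `background` is supplied.
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
  sets <- geneSets(collection)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[nm] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @param background optional gene universe for the read collection.
#' @export
readGMT <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  GeneSetCollection(sets, background %||% unique(unlist(sets)))
}

#' Write a GradientSet as TSV plus a JSON sidecar
#'
#' The TSV holds node scores (`node`, `g1..gk`); the sidecar stores the
#' eigenvalues and explained ratios.
#'
#' @param g a [GradientSet-class].
#' @param path TSV path; the sidecar is `<path>.json`.
#' @export
writeGradientSet <- function(g, path) {
  writeMatrixTSV(gradientComponents(g), path)
  jsonlite::write_json(
    list(eigenvalues = g@eigenvalues, explainedRatio = g@explainedRatio),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeGradientSet
#' @export
readGradientSet <- function(path) {
  m <- readMatrixTSV(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("GradientSet", components = m, eigenvalues = meta$eigenvalues,
      explainedRatio = meta$explainedRatio, nodeIds = rownames(m))
}

#' Write a GroupStatMap as TSV
#'
#' Columns: node, t, z, p, d, plus any extra columns supplied (e.g.
#' `sig_fdr`, `cluster_id`).
#'
#' @param stat a [GroupStatMap-class].
#' @param path file path.
#' @param extra optional data.frame of additional per-node columns.
#' @export
writeStatMap <- function(stat, path, extra = NULL) {
  df <- statTable(stat)
  for (cc in c("t", "z", "p", "d")) df[[cc]] <- fmtNum(df[[cc]])
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-subject time series, one TSV per subject
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
writeTimeseries <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsl <- timeseriesList(cohort)
  paths <- vapply(names(tsl), function(id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    writeMatrixTSV(tsl[[id]], p)
    p
  }, "")
  invisible(paths)
}
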