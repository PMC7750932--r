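# CSV input/output for data matrices, kernel matrices and label vectors, plus
# a JSON run manifest. The dialect everywhere: comma-separated, header row,
# first column holds the observation IDs.

#' Read a data or kernel matrix from CSV
#'
#' Expects a header row and the observation IDs in the first column. Kernel
#' (similarity) matrices must be square with the header equal to the ID
#' column; data matrices may have any feature columns.
#'
#' @param path Path to the CSV file.
#' @param type `"auto"` (kernel when square with matching header and IDs),
#'   `"dataset"` or `"kernel"`.
#' @return Numeric matrix with observation IDs as row names (and, for
#'   kernels, column names).
#' @export
read_matrix_csv <- function(path, type = c("auto", "dataset", "kernel")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) parse_error(sprintf("%s: need an ID column plus data columns", path))
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    parse_error(sprintf("%s: duplicate observation ID '%s'", path, dup[1]))
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(values), nrow(values),
                                 dimnames = dimnames(values)))
  bad <- which(is.na(num) & !(values %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    parse_error(sprintf("%s: non-numeric value '%s' at row '%s', column '%s'",
                        path, values[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                        colnames(values)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    parse_error(sprintf("%s: missing value at row '%s', column '%s'",
                        path, ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  rownames(num) <- ids
  is_square_named <- nrow(num) == ncol(num) && identical(colnames(num), ids)
  if (type == "kernel" && !is_square_named) {
    parse_error(sprintf("%s: kernel CSV must be square with header equal to the ID column",
                        path))
  }
  num
}

#' Write a matrix to CSV
#'
#' Inverse of [read_matrix_csv()]: header row, observation IDs in the first
#' column, values formatted with 17 significant digits so a round trip
#' reproduces the doubles exactly.
#'
#' @param m Numeric matrix (row names used as IDs; generated if absent).
#' @param path Output path.
#' @param id_column Name of the first column (default `"obs_id"`).
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(m, path, id_column = "obs_id") {
  m <- as.matrix(m)
  ids <- rownames(m) %||% sprintf("obs_%03d", seq_len(nrow(m)))
  cn <- colnames(m) %||% sprintf("V%d", seq_len(ncol(m)))
  fm <- matrix(sprintf("%.17g", m), nrow(m))
  lines <- c(paste(c(id_column, cn), collapse = ","),
             paste(ids, apply(fm, 1, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read cluster labels from CSV
#'
#' Two columns: observation ID and integer cluster label.
#' @param path Path to the CSV file.
#' @return Named integer vector.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) parse_error(sprintf("%s: need columns obs_id, cluster", path))
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    parse_error(sprintf("%s: duplicate observation ID '%s'", path, dup[1]))
  }
  labels <- suppressWarnings(as.integer(df[[2]]))
  if (anyNA(labels) && !all(is.na(df[[2]][is.na(labels)]))) {
    parse_error(sprintf("%s: non-integer cluster label at row '%s'",
                        path, ids[which(is.na(labels))[1]]))
  }
  stats::setNames(labels, ids)
}

#' Write cluster labels to CSV
#' @param labels Named integer vector (names used as observation IDs).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels_csv <- function(labels, path) {
  ids <- names(labels) %||% sprintf("obs_%03d", seq_along(labels))
  utils::write.csv(data.frame(obs_id = ids, cluster = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records package version, R version, time stamp, seed and any run
#' parameters, so an analysis directory documents how it was produced.
#'
#' @param path Output path.
#' @param seed Seed used for the run.
#' @param parameters Named list of run parameters.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(path, seed = NULL, parameters = list()) {
  manifest <- list(
    package = "kliclust",
    version = as.character(utils::packageVersion("kliclust")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = parameters
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
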