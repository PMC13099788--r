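#' Read a participant metadata table
#'
#' Tab-separated, one header row, `participant_id` as first column.
#'
#' @param path file path.
#' @return data.frame with `participant_id` as character.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) == 0L || names(df)[1] != "participant_id")
    stop_schema("metadata table must have participant_id as its first column")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Write a participant metadata table
#'
#' @param meta data.frame with a `participant_id` column.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  if (!"participant_id" %in% names(meta))
    stop_schema("metadata table must have a participant_id column")
  meta <- meta[, c("participant_id", setdiff(names(meta), "participant_id"))]
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MetaPhlAn/HUMAnN-style merged abundance table
#'
#' Expects features in rows (first column the feature name) and samples in
#' columns, as written by `merge_metaphlan_tables.py` and
#' `humann_join_tables`. Returned in the package's internal orientation:
#' samples in rows, features in columns.
#'
#' @param path file path to a tab-separated merged table.
#' @return numeric matrix, samples x features.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop_schema("abundance table needs a feature column plus >=1 sample column")
  feat <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_schema("abundance table contains non-numeric or missing cells")
  rownames(m) <- feat
  t(m)
}

#' Write an abundance matrix as a MetaPhlAn-style merged table
#'
#' @param mat samples x features numeric matrix with dimnames.
#' @param path output path.
#' @param feature_col name for the first (feature) column.
#' @export
write_abundance <- function(mat, path, feature_col = "clade_name") {
  tm <- t(mat)
  df <- data.frame(feature = rownames(tm), tm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
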