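#' Read / write an abundance matrix TSV
#'
#' First column `protein_id`, remaining columns one per sample; empty cells
#' are missing values.
#'
#' @param path file path.
#' @param matrix proteins x samples numeric matrix.
#' @return `read_abundance()` returns the numeric matrix with protein row
#'   names.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "protein_id", "first column must be protein_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$protein_id
  check_matrix(m)
}

#' @rdname read_abundance
#' @export
write_abundance <- function(matrix, path) {
  check_matrix(matrix)
  df <- data.frame(protein_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' member ids. Reading is delegated to [fgsea::gmtPathways()].
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stop_if(is.null(names(sets)), "gene sets must be named")
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write generator ground truth as JSON
#'
#' @param truth ground-truth list from [simulate_abundance()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read / write a cell table TSV
#'
#' @param path file path.
#' @param cells per-cell data.frame from [simulate_cells()].
#' @return `read_cells()` returns the data.frame with logical marker columns.
#' @export
read_cells <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("BrdU", "Ki67", "pHH3", "Reelin"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
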