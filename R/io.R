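## File dialects shared by all stages: TSV for intensity matrices (first
## column `mirna_id`, one column per sample), CSV with header for record
## tables. UTF-8, '.' decimal. Writers format numerics at 12 significant
## digits so write(read(x)) round-trips to that precision.

#' @importFrom utils read.delim write.table count.fields
NULL

checkRectangular <- function(path, sep) {
  nf <- count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) stop("empty file: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
}

#' Read / write an intensity matrix (TSV dialect)
#'
#' `writeExpressionMatrix()` writes a tab-separated table whose first
#' column `mirna_id` holds the row labels and whose remaining columns are
#' samples. `readExpressionMatrix()` reads it back, checking for ragged
#' rows and non-numeric cells and reporting the offending line.
#'
#' @param path File path.
#' @return `readExpressionMatrix()` returns a numeric matrix with
#'   dimnames.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  checkRectangular(path, sep = "\t")
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "mirna_id")
    stop("malformed header in ", path, ": first column must be 'mirna_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    badRow <- which(apply(is.na(num) & !is.na(m), 1L, any))
    stop(sprintf("non-numeric cell in %s near line %d", path,
                 (if (length(badRow)) badRow[1L] else 1L) + 1L))
  }
  rownames(m) <- df$mirna_id
  m
}

#' @rdname readExpressionMatrix
#' @param m Numeric matrix with row and column names.
#' @export
writeExpressionMatrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(mirna_id = rownames(m),
                   signif(m, 12), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a record table (CSV dialect)
#'
#' Header-mandatory comma-separated tables used for designs, echo
#' records, survival records and truth tables. Ragged rows are reported
#' with their line number.
#'
#' @param path File path.
#' @return `readRecordTable()` returns a `data.frame`.
#' @export
readRecordTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  checkRectangular(path, sep = ",")
  read.delim(path, sep = ",", check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname readRecordTable
#' @param df A `data.frame`.
#' @export
writeRecordTable <- function(df, path) {
  stopifnot(is.data.frame(df))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 12)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
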