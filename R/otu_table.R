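#' Construct an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix of read counts with OTUs in
#' rows and samples in columns. Row names are OTU labels of the form
#' `<lowest taxonomic level>_<number>` (e.g. `"Corynebacterium_767"`); column
#' names are sample identifiers. Both must be unique.
#'
#' @param counts numeric matrix of counts (OTUs x samples). Values must be
#'   non-negative whole numbers.
#' @param otu_ids character vector of OTU labels; defaults to `rownames(counts)`.
#' @param sample_ids character vector of sample ids; defaults to
#'   `colnames(counts)`.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   `dimnames` set.
#' @examples
#' tab <- otu_table(matrix(0:5, nrow = 3,
#'                         dimnames = list(paste0("Taxon_", 1:3), c("s1", "s2"))))
#' dim(tab)
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids) || is.null(sample_ids)) {
    stop("otu_table requires OTU labels and sample ids (dimnames or arguments)")
  }
  if (length(otu_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop("dimension mismatch between counts and id vectors")
  }
  dup <- otu_ids[duplicated(otu_ids)]
  if (length(dup)) {
    stop("duplicated OTU id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be whole numbers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (total reads %s)\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' Expects a tab-separated file with one header row and the ids in the first
#' column. By default rows are OTUs and columns are samples
#' (`orientation = "otus_as_rows"`); use `"samples_as_rows"` for the transposed
#' layout. Orientation is never auto-detected.
#'
#' @param path path to a TSV file.
#' @param orientation either `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @return An [otu_table()].
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("format error: need a header row and at least one data row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (length(unique(nfield[-1])) != 1 ||
      !(nfield[1] %in% c(nfield[2], nfield[2] - 1L))) {
    stop("format error: ragged rows (inconsistent number of columns)")
  }
  header <- fields[[1]]
  # allow an R-style header that omits the id-column name
  col_ids <- if (nfield[1] == nfield[2]) header[-1] else header
  body <- fields[-1]
  row_ids <- vapply(body, `[[`, "", 1L)
  cells <- t(vapply(body, function(f) f[-1], character(length(col_ids))))
  if (length(col_ids) == 1L) cells <- matrix(cells, ncol = 1L)
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = length(row_ids)))
  if (anyNA(num)) stop("format error: non-numeric count cell(s)")
  m <- num
  dimnames(m) <- list(row_ids, col_ids)
  if (orientation == "samples_as_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU count table to TSV
#'
#' Writes the table with OTUs as rows, a header row of sample ids, and the OTU
#' labels in a first column named `otu_id`. `read_otu_table()` round-trips the
#' cell values exactly.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
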