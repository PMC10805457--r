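#' Read a delimited numeric data matrix
#'
#' Reads a rectangular delimited text file (CSV/TSV) of numbers into an
#' observations-by-features matrix, with cell-level error reporting: a
#' ragged row or a non-numeric cell fails with its line and column.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` picks `","` for `.csv` and
#'   whitespace/tab otherwise.
#' @param header Logical: skip a header line? Column names are kept.
#' @return A numeric matrix; row names are preserved if the first column is
#'   entirely non-numeric (treated as row identifiers).
#' @export
read_matrix <- function(path, delimiter = NULL, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  cn <- NULL
  first_data <- 1L
  if (header) {
    cn <- trimws(cells[[1L]])
    first_data <- 2L
  }
  cells <- cells[seq(first_data, length(cells))]
  if (length(cells) == 0L) stop("no data rows in ", path, call. = FALSE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged row at line ", bad + first_data - 1L, ": expected ",
         widths[1L], " fields, found ", widths[bad], call. = FALSE)
  }
  rown <- NULL
  first_col <- vapply(cells, `[[`, character(1), 1L)
  if (all(is.na(suppressWarnings(as.numeric(first_col)))) && widths[1L] > 1L) {
    rown <- trimws(first_col)
    cells <- lapply(cells, `[`, -1L)
    if (!is.null(cn) && length(cn) == widths[1L]) cn <- cn[-1L]
  }
  m <- matrix(NA_real_, length(cells), length(cells[[1L]]))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(trimws(cells[[i]])))
    bad <- which(is.na(v) & trimws(cells[[i]]) != "NA")
    if (length(bad))
      stop("non-numeric cell at line ", i + first_data - 1L, ", column ",
           bad[1L], ": '", cells[[i]][bad[1L]], "'", call. = FALSE)
    m[i, ] <- v
  }
  if (!is.null(rown)) rownames(m) <- rown
  if (!is.null(cn)) colnames(m) <- cn
  m
}
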