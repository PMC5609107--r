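#' Labeled matrices as TSV
#'
#' Matrices throughout the package are base numeric matrices with row/column
#' dimnames (similarity percent, ANI percent, or distances). These helpers
#' round-trip them through a TSV with a header row and a leading label column.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  gs_assert(is.matrix(m) && !is.null(rownames(m)) && !is.null(colnames(m)),
            "expected a matrix with row and column names")
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- apply(m, 2, parse_printed_number)
  if (!is.matrix(m)) m <- matrix(m, nrow = length(labels))
  rownames(m) <- labels
  colnames(m) <- colnames(df)[-1]
  m
}

#' Export a distance (or percent-similarity) matrix as a nexus DISTANCES block
#'
#' Writes `TAXA` and `DISTANCES` blocks (`TRIANGLE=BOTH`, labels, diagonal),
#' the format SplitsTree imports. A percent-similarity matrix is converted to
#' distances as `100 - similarity` when `from_similarity = TRUE`.
#'
#' @param m square numeric matrix with matching dimnames.
#' @param path output path.
#' @param from_similarity convert percent similarity to distance `100 - s`.
#' @param symmetrize average `m` with `t(m)` before export; without this flag
#'   an asymmetric input (beyond `tol`) is an error.
#' @param tol symmetry tolerance.
#' @return `path`, invisibly.
#' @export
export_nexus_distances <- function(m, path, from_similarity = FALSE,
                                   symmetrize = FALSE, tol = 1e-9) {
  gs_assert(is.matrix(m) && nrow(m) == ncol(m), "matrix must be square")
  gs_assert(identical(rownames(m), colnames(m)), "row/col labels must coincide")
  if (symmetrize) {
    m <- (m + t(m)) / 2
  } else {
    gs_assert(max(abs(m - t(m))) <= tol,
              "matrix asymmetric beyond tol=%g; pass symmetrize=TRUE", tol)
  }
  d <- if (from_similarity) 100 - m else m
  labels <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", nrow(d)),
    paste0("  TAXLABELS ", paste(sprintf("'%s'", labels), collapse = " "), ";"),
    "END;",
    "BEGIN DISTANCES;",
    sprintf("  DIMENSIONS NTAX=%d;", nrow(d)),
    "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
    "  MATRIX"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(sprintf("    '%s' %s", labels[i],
                       paste(format(d[i, ], digits = 10, trim = TRUE),
                             collapse = " ")), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Parse a nexus DISTANCES block written by [export_nexus_distances()]
#'
#' Round-trip reader (TRIANGLE=BOTH with labels and diagonal).
#'
#' @param path nexus file path.
#' @return square numeric matrix with dimnames.
#' @export
read_nexus_distances <- function(path) {
  lines <- readLines(path)
  gs_assert(toupper(trimws(lines[1])) == "#NEXUS", "not a nexus file: %s", path)
  i0 <- grep("MATRIX", lines, ignore.case = TRUE)[1]
  gs_assert(!is.na(i0), "no MATRIX in %s", path)
  rows <- list()
  for (ln in lines[(i0 + 1):length(lines)]) {
    ln <- trimws(ln)
    if (ln == ";" || toupper(ln) == "END;") break
    if (!nzchar(ln)) next
    lab <- sub("^'([^']*)'.*$", "\\1", ln)
    rest <- trimws(sub("^'[^']*'", "", ln))
    rows[[lab]] <- as.numeric(strsplit(rest, "\\s+")[[1]])
  }
  m <- do.call(rbind, rows)
  colnames(m) <- rownames(m)
  m
}
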