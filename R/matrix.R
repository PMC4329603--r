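# Construction and I/O of the information-weighted scoring matrix.

#' Information content of one alignment column
#'
#' Computes the sequence-logo information content of a column of aligned
#' residues: R = log2(20) - H - e(n), where H is the Shannon entropy (bits)
#' of the empirical residue frequencies and e(n) = 19 / (2 ln(2) n) is the
#' optional small-sample correction (n = number of canonical residues in the
#' column). Ambiguity letters ('X' and any other non-canonical letter) are
#' excluded before counting. Negative corrected values are clamped to 0.
#'
#' @param residues Character vector of single letters, or a single string.
#' @param applyCorrection Logical; subtract the small-sample correction
#'   (default `FALSE`).
#' @return Information content in bits, in `[0, log2(20)]`.
#' @examples
#' columnInformation("F")                     # log2(20) = 4.3219
#' columnInformation(c("F", "F", "F", "L"))   # 3.5106
#' @export
columnInformation <- function(residues, applyCorrection = FALSE) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- .seqToChars(residues)
  residues <- toupper(residues)
  residues <- residues[residues %in% AA20]
  n <- length(residues)
  if (n == 0L)
    stop("degenerate column: no canonical residues after removing ambiguity letters")
  p <- tabulate(factor(residues, levels = AA20), nbins = 20L) / n
  p <- p[p > 0]
  H <- -sum(p * log2(p))
  e <- if (isTRUE(applyCorrection)) 19 / (2 * log(2) * n) else 0
  max(0, MAX_BITS - H - e)
}

# Validate and coerce training windows to a character matrix of residues.
.windowMatrix <- function(windows) {
  windows <- .asWindows(windows)
  if (length(windows) == 0L)
    stop("empty training set: at least one 25-residue window is required")
  bad <- which(nchar(windows) != 25L)
  if (length(bad))
    stop("training windows must be exactly 25 residues long; offending window(s): ",
         paste(utils::head(names(windows)[bad], 5L), collapse = ", "))
  do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
}

# Coerce window input (AAStringSet / character / data.frame id,window).
.asWindows <- function(windows) {
  if (methods::is(windows, "XStringSet")) {
    out <- as.character(windows)
    names(out) <- sub("\\s.*$", "", names(windows))
    return(out)
  }
  if (is.data.frame(windows)) {
    if (!all(c("id", "window") %in% names(windows)))
      stop("window data frame must have columns 'id' and 'window'")
    return(stats::setNames(as.character(windows$window), windows$id))
  }
  if (!is.character(windows))
    stop("windows must be an AAStringSet, character vector or data frame")
  if (is.null(names(windows)))
    names(windows) <- sprintf("window_%04d", seq_along(windows))
  windows
}

#' Build a scoring matrix from aligned cleavage-site windows
#'
#' Builds the information-weighted scoring matrix from an alignment of
#' 25-residue windows spanning the signal-peptide cleavage site (positions
#' -5..-1 and +1..+20). Each entry is M(j, a) = f(j, a) * R(j): the
#' empirical frequency of residue `a` among the canonical residues of
#' column `j`, weighted by that column's information content (see
#' [columnInformation()]).
#'
#' @param windows 25-mer windows: an `AAStringSet`, a (preferably named)
#'   character vector, or a data frame with columns `id` and `window`.
#' @param applyCorrection Logical; apply the small-sample information
#'   correction per column (default `FALSE`).
#' @return A [ScoringMatrix-class] object.
#' @examples
#' m <- buildMatrix(c(a = strrep("A", 25), b = strrep("A", 25)))
#' columnInfo(m)[["-1"]]  # single-residue columns carry log2(20) bits
#' @export
buildMatrix <- function(windows, applyCorrection = FALSE) {
  chars <- .windowMatrix(windows)
  scores <- matrix(0, nrow = 20L, ncol = 25L,
                   dimnames = list(AA20, MATRIX_COLUMNS))
  for (j in seq_len(25L)) {
    col <- chars[, j]
    canon <- col[col %in% AA20]
    if (length(canon) == 0L)
      stop("degenerate column ", MATRIX_COLUMNS[j],
           ": only ambiguity letters in the training alignment")
    f <- tabulate(factor(canon, levels = AA20), nbins = 20L) / length(canon)
    R <- columnInformation(canon, applyCorrection = applyCorrection)
    scores[, j] <- f * R
  }
  .ScoringMatrix(scores, nSequences = nrow(chars),
                 correctionApplied = applyCorrection)
}

#' Read / write a scoring matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first header cell is
#' `residue` followed by the 25 integer column labels -5..-1, 1..20, with one
#' row per canonical residue (20 rows, any order) and non-negative decimal
#' values. Lines starting with `#` are ignored. `writeMatrix()` followed by
#' `readMatrix()` is the identity on values to 6 decimal places.
#'
#' @param path File path.
#' @param matrix A [ScoringMatrix-class].
#' @param nSequences,correctionApplied Metadata recorded in the returned
#'   object by `readMatrix()` (the TSV stores values only); defaults: 0 and
#'   `FALSE`.
#' @return `readMatrix()` returns a [ScoringMatrix-class]; `writeMatrix()`
#'   returns `path` invisibly.
#' @examples
#' m <- buildMatrix(c(a = strrep("A", 25)))
#' f <- tempfile(fileext = ".tsv")
#' writeMatrix(m, f)
#' m2 <- readMatrix(f)
#' all.equal(scoreValues(m), scoreValues(m2), tolerance = 1e-6)
#' @export
readMatrix <- function(path, nSequences = 0L, correctionApplied = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix format error: expected a header row and 20 residue rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (tolower(header[1L]) != "residue")
    stop("matrix format error: first header cell must be 'residue'")
  cols <- header[-1L]
  if (length(cols) != 25L || !identical(cols, MATRIX_COLUMNS))
    stop("matrix format error: expected 25 column labels -5..-1, 1..20; got ",
         length(cols), " column(s)")
  body <- fields[-1L]
  if (length(body) != 20L)
    stop("matrix format error: expected 20 residue rows, got ", length(body))
  scores <- matrix(0, 20L, 25L, dimnames = list(AA20, MATRIX_COLUMNS))
  seen <- character(0)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != 26L)
      stop("matrix format error at data row ", i, ": expected 26 fields, got ",
           length(row))
    aa <- toupper(row[1L])
    if (!aa %in% AA20)
      stop("matrix format error at data row ", i, ": unknown residue '", aa, "'")
    if (aa %in% seen)
      stop("matrix format error at data row ", i, ": duplicate residue row '",
           aa, "'")
    seen <- c(seen, aa)
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals))
      stop("matrix format error at data row ", i, " (residue ", aa,
           "): non-numeric value")
    if (any(vals < 0)) {
      j <- which(vals < 0)[1L]
      stop("matrix format error at data row ", i, ", column ", cols[j],
           ": negative value ", row[-1L][j])
    }
    scores[aa, ] <- vals
  }
  .ScoringMatrix(scores, nSequences = nSequences,
                 correctionApplied = correctionApplied)
}

#' @rdname readMatrix
#' @export
writeMatrix <- function(matrix, path) {
  stopifnot(methods::is(matrix, "ScoringMatrix"))
  m <- scoreValues(matrix)
  header <- paste(c("residue", MATRIX_COLUMNS), collapse = "\t")
  rows <- vapply(AA20, function(aa)
    paste(c(aa, sprintf("%.6f", m[aa, ])), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Export per-column frequencies and information
#'
#' Recovers the per-column residue frequencies f(j, a) = M(j, a) / R(j) and
#' the information content R(j) from a scoring matrix, in a long-format data
#' frame suitable for external sequence-logo tools.
#'
#' @param matrix A [ScoringMatrix-class].
#' @return A data frame with columns `column`, `residue`, `frequency`,
#'   `information_bits`. Columns with zero information have frequency `NA`.
#' @export
matrixProfile <- function(matrix) {
  stopifnot(methods::is(matrix, "ScoringMatrix"))
  m <- scoreValues(matrix)
  R <- columnInfo(matrix)
  freq <- sweep(m, 2L, ifelse(R > 0, R, NA_real_), "/")
  data.frame(
    column = rep(MATRIX_COLUMNS, each = 20L),
    residue = rep(AA20, times = 25L),
    frequency = as.vector(freq),
    information_bits = rep(unname(R), each = 20L),
    stringsAsFactors = FALSE)
}
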