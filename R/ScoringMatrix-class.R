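#' ScoringMatrix: information-weighted cleavage-site scoring matrix
#'
#' The central parameter object of the predictor: a 20-residue x 25-column
#' table of information-weighted frequencies describing the conserved motif
#' around the signal-peptide cleavage site. Columns are indexed -5..-1 (last
#' five signal-peptide residues) and +1..+20 (first twenty transit-peptide
#' residues); there is no position 0, the scissile bond lies between -1 and
#' +1. Each entry is M(j, a) = f(j, a) * R(j), the empirical frequency of
#' residue `a` in column `j` times the information content (bits) of that
#' column, so per-column entries sum to R(j) <= log2(20).
#'
#' @slot scores numeric matrix, 20 rows (canonical residues, alphabetical)
#'   by 25 columns (labels "-5".."-1", "1".."20"), all entries >= 0.
#' @slot nSequences integer, number of training windows.
#' @slot correctionApplied logical, whether the small-sample information
#'   correction was subtracted during construction.
#'
#' @seealso [buildMatrix()], [readMatrix()], [writeMatrix()],
#'   [columnInformation()]
#' @aliases ScoringMatrix-class
#' @exportClass ScoringMatrix
setClass("ScoringMatrix",
  representation(scores = "matrix",
                 nSequences = "integer",
                 correctionApplied = "logical"))

setValidity("ScoringMatrix", function(object) {
  m <- object@scores
  if (!is.numeric(m)) return("scores must be numeric")
  if (!identical(dim(m), c(20L, 25L)))
    return("scores must be a 20 x 25 matrix")
  if (!identical(rownames(m), AA20))
    return("rows must be the 20 canonical residues in alphabetical order")
  if (!identical(colnames(m), MATRIX_COLUMNS))
    return("columns must be labelled -5..-1, 1..20")
  if (any(!is.finite(m)) || any(m < 0))
    return("all scores must be finite and >= 0")
  cs <- colSums(m)
  if (any(cs > MAX_BITS + 1e-9))
    return("per-column sums must not exceed log2(20) bits")
  if (length(object@nSequences) != 1L || is.na(object@nSequences) ||
      object@nSequences < 0L)
    return("nSequences must be a single non-negative integer")
  if (length(object@correctionApplied) != 1L || is.na(object@correctionApplied))
    return("correctionApplied must be TRUE or FALSE")
  TRUE
})

#' @describeIn ScoringMatrix Display a compact summary: training size,
#'   correction flag, and the per-column information of the most informative
#'   columns.
#' @param object A `ScoringMatrix`.
#' @export
setMethod("show", "ScoringMatrix", function(object) {
  info <- columnInfo(object)
  cat("ScoringMatrix (cleavage-site motif, 25 columns x 20 residues)\n")
  cat("  training windows:", object@nSequences,
      "| small-sample correction:",
      if (object@correctionApplied) "on" else "off", "\n")
  top <- sort(info, decreasing = TRUE)[1:5]
  cat("  most informative columns (bits):",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  invisible(object)
})

#' @rdname scoreValues
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' Accessors for ScoringMatrix objects
#'
#' `scoreValues()` returns the 20 x 25 numeric score matrix;
#' `columnInfo()` the per-column information R(j) in bits (the column sums);
#' `nSequences()` the number of training windows; `correctionApplied()`
#' whether the small-sample correction was used.
#'
#' @param x A [ScoringMatrix-class] object.
#' @return See individual descriptions.
#' @examples
#' m <- buildMatrix(c(w1 = strrep("A", 25)))
#' scoreValues(m)["A", "1"]
#' columnInfo(m)[["1"]]
#' @export
setMethod("scoreValues", "ScoringMatrix", function(x) x@scores)

#' @rdname scoreValues
#' @export
setGeneric("columnInfo", function(x) standardGeneric("columnInfo"))

#' @rdname scoreValues
#' @export
setMethod("columnInfo", "ScoringMatrix", function(x) colSums(x@scores))

#' @rdname scoreValues
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname scoreValues
#' @export
setMethod("nSequences", "ScoringMatrix", function(x) x@nSequences)

#' @rdname scoreValues
#' @export
setGeneric("correctionApplied", function(x) standardGeneric("correctionApplied"))

#' @rdname scoreValues
#' @export
setMethod("correctionApplied", "ScoringMatrix", function(x) x@correctionApplied)

# Internal constructor.
.ScoringMatrix <- function(scores, nSequences, correctionApplied) {
  methods::new("ScoringMatrix",
               scores = scores,
               nSequences = as.integer(nSequences),
               correctionApplied = isTRUE(correctionApplied))
}
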