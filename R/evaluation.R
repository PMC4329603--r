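# Evaluation of predictions against labeled references: confusion counts,
# sensitivity / specificity / MCC, ROC points, transit-score histograms.

#' ConfusionCounts: binary confusion-matrix counts
#'
#' TP/FP/TN/FN counts of a hard binary classifier under a declared
#' positive-class definition: `"high_only"` counts only "plastid, high
#' confidence" predictions as positive; `"high_or_low"` counts both plastid
#' classes. Both "not plastid" classes are predicted-negative.
#'
#' @slot tp,fp,tn,fn Non-negative integer counts.
#' @slot positiveDefinition `"high_only"` or `"high_or_low"`.
#' @seealso [confusion()], [sensitivity()], [specificity()], [mcc()],
#'   [rocPoint()]
#' @aliases ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", positiveDefinition = "character"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || anyNA(v) || any(v < 0L))
    return("tp, fp, tn, fn must be single non-negative integers")
  if (length(object@positiveDefinition) != 1L ||
      !object@positiveDefinition %in% c("high_only", "high_or_low"))
    return("positiveDefinition must be 'high_only' or 'high_or_low'")
  TRUE
})

#' @describeIn ConfusionCounts Compact display.
#' @param object A `ConfusionCounts`.
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (positive =", object@positiveDefinition, ")\n")
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d (n=%d)\n", object@tp, object@fp,
              object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
  invisible(object)
})

#' Construct ConfusionCounts directly
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @param positiveDefinition `"high_only"` or `"high_or_low"`.
#' @return A [ConfusionCounts-class] object.
#' @examples
#' mcc(confusionCounts(2, 1, 2, 1))  # 1/3
#' @export
confusionCounts <- function(tp, fp, tn, fn,
                            positiveDefinition = "high_or_low") {
  methods::new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
               tn = as.integer(tn), fn = as.integer(fn),
               positiveDefinition = positiveDefinition)
}

#' @rdname counts
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Extract the four counts
#'
#' @param x A [ConfusionCounts-class].
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
setMethod("counts", "ConfusionCounts", function(x)
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn))

#' Tally predictions against a labeled reference
#'
#' @param predictions Data frame from [classifyProteins()] (columns `id`,
#'   `prediction`).
#' @param references Data frame with columns `id` and `plastid` (logical,
#'   or "Y"/"N"); optional `note`. Ids must be unique and every reference
#'   id must have a prediction.
#' @param positiveDefinition `"high_only"` or `"high_or_low"`.
#' @return A [ConfusionCounts-class] object over the reference ids.
#' @export
confusion <- function(predictions, references,
                      positiveDefinition = c("high_or_low", "high_only")) {
  positiveDefinition <- match.arg(positiveDefinition)
  stopifnot(is.data.frame(predictions),
            all(c("id", "prediction") %in% names(predictions)),
            is.data.frame(references),
            all(c("id", "plastid") %in% names(references)))
  if (anyDuplicated(references$id))
    stop("reference ids must be unique")
  missing <- setdiff(references$id, predictions$id)
  if (length(missing))
    stop("missing prediction for reference id(s): ",
         paste(missing, collapse = ", "))
  truth <- references$plastid
  if (!is.logical(truth)) truth <- toupper(as.character(truth)) == "Y"
  pred <- predictions$prediction[match(references$id, predictions$id)]
  positiveClasses <- if (positiveDefinition == "high_only") CLASS_HIGH
                     else c(CLASS_HIGH, CLASS_LOW)
  called <- pred %in% positiveClasses
  confusionCounts(tp = sum(called & truth), fp = sum(called & !truth),
                  tn = sum(!called & !truth), fn = sum(!called & truth),
                  positiveDefinition = positiveDefinition)
}

#' Classifier summary statistics
#'
#' Standard definitions: sensitivity = tp/(tp+fn) (true-positive rate),
#' specificity = tn/(tn+fp) (true-negative rate), and the Matthews
#' correlation coefficient MCC = (tp*tn - fp*fn) /
#' sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)). A zero denominator is an error for
#' sensitivity and specificity and yields 0 for MCC (the conventional
#' value for a degenerate table).
#'
#' @param c A [ConfusionCounts-class].
#' @return A single number; sensitivity and specificity in `[0, 1]`, MCC
#'   in `[-1, 1]`.
#' @examples
#' cc <- confusionCounts(2, 1, 2, 1)
#' sensitivity(cc); specificity(cc); mcc(cc)
#' @export
sensitivity <- function(c) {
  k <- counts(c)
  den <- k[["tp"]] + k[["fn"]]
  if (den == 0L) stop("sensitivity undefined: no true-positive-class records (tp+fn = 0)")
  k[["tp"]] / den
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  k <- counts(c)
  den <- k[["tn"]] + k[["fp"]]
  if (den == 0L) stop("specificity undefined: no true-negative-class records (tn+fp = 0)")
  k[["tn"]] / den
}

#' @rdname sensitivity
#' @export
mcc <- function(c) {
  k <- as.numeric(counts(c))
  tp <- k[1]; fp <- k[2]; tn <- k[3]; fn <- k[4]
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' ROC point of a hard classifier
#'
#' Maps confusion counts to the (false-positive rate, true-positive rate)
#' plane: the perfect predictor is at (0, 1), the perfect inverse at
#' (1, 0), and random guesses fall on the diagonal.
#'
#' @param c A [ConfusionCounts-class]; both denominators must be nonzero.
#' @return Named numeric vector `c(fpr = , tpr = )`.
#' @export
rocPoint <- function(c) {
  k <- counts(c)
  if (k[["fp"]] + k[["tn"]] == 0L || k[["tp"]] + k[["fn"]] == 0L)
    stop("ROC point undefined: a class is empty")
  c(fpr = k[["fp"]] / (k[["fp"]] + k[["tn"]]),
    tpr = k[["tp"]] / (k[["tp"]] + k[["fn"]]))
}

#' Transit-peptide score histogram and rank curve
#'
#' `transitScoreHistogram()` bins the transit-peptide scores of the
#' signal-peptide-positive predictions into half-open intervals
#' `[k*binWidth, (k+1)*binWidth)`. `transitScoreRankCurve()` returns the
#' same scores in descending order together with the +1 residue, the
#' rank-ordered view in which the score drop coinciding with loss of the
#' +1 phenylalanine is visible.
#'
#' @param predictions Data frame from [classifyProteins()].
#' @param binWidth Positive bin width (default 1).
#' @return `transitScoreHistogram()`: data frame `bin_start`, `bin_end`,
#'   `count`, ordered by bin, total count preserved;
#'   `transitScoreRankCurve()`: data frame `rank`, `transit_score`,
#'   `plus1_aa`, `prediction` in descending score order.
#' @export
transitScoreHistogram <- function(predictions, binWidth = 1) {
  if (!is.numeric(binWidth) || length(binWidth) != 1L || binWidth <= 0)
    stop("binWidth must be a single positive number")
  s <- predictions$transit_score[!is.na(predictions$signalp_pos) &
                                 !is.na(predictions$transit_score)]
  if (length(s) == 0L)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  lo <- floor(s / binWidth) * binWidth
  tab <- table(lo)
  start <- as.numeric(names(tab))
  o <- order(start)
  data.frame(bin_start = start[o], bin_end = start[o] + binWidth,
             count = as.integer(tab)[o])
}

#' @rdname transitScoreHistogram
#' @export
transitScoreRankCurve <- function(predictions) {
  keep <- !is.na(predictions$signalp_pos) & !is.na(predictions$transit_score)
  df <- predictions[keep, c("transit_score", "plus1_aa", "prediction")]
  df <- df[order(-df$transit_score), ]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Read a labeled reference TSV
#'
#' Columns: `id`, `plastid` (Y/N), optional `note`. `#` comments allowed.
#'
#' @param input File path or lines.
#' @return Data frame with `id`, `plastid` (logical), `note`.
#' @export
readReference <- function(input) {
  lines <- .inputLines(input)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("id", "plastid") %in% names(df)))
    stop("reference TSV must have columns 'id' and 'plastid'")
  df$plastid <- toupper(as.character(df$plastid)) == "Y"
  if (!"note" %in% names(df)) df$note <- ""
  df[c("id", "plastid", "note")]
}
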