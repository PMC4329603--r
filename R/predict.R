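# Core predictor: window scoring against the cleavage-site matrix, sliding
# window relocation of the cleavage site, transit-peptide score, and the
# four-class decision tree.

# Matrix column label j addresses sequence position m + j for j < 0 and
# m + j - 1 for j > 0, where m is the 1-based index of the first mature
# residue (+1 position). There is no position 0.
.addressedPositions <- function(matureStart, columns) {
  j <- as.integer(columns)
  matureStart + j - as.integer(j > 0L)
}

# Score a window without preconditions; returns score, completeness and the
# number of addressed positions inside the sequence (coverage). Positions
# outside the sequence and non-canonical residues contribute 0.
.scoreWindow <- function(chars, matureStart, scores, columns) {
  pos <- .addressedPositions(matureStart, columns)
  inside <- pos >= 1L & pos <= length(chars)
  total <- 0
  if (any(inside)) {
    res <- chars[pos[inside]]
    cols <- columns[inside]
    known <- res %in% AA20
    if (any(known))
      total <- sum(scores[cbind(res[known], cols[known])])
  }
  list(score = total, complete = all(inside), coverage = sum(inside))
}

#' Score a cleavage-site window
#'
#' Sums matrix entries over a 25-position (or user-chosen) window anchored
#' at a candidate cleavage site. Column j < 0 addresses sequence position
#' `matureStart + j` (signal-peptide side); column j > 0 addresses
#' `matureStart + j - 1` (transit-peptide side). Positions outside the
#' sequence and residues outside the canonical 20-letter alphabet
#' contribute 0.
#'
#' @param sequence A single protein sequence (string or `AAString`).
#' @param matureStart 1-based index of the first mature-protein residue
#'   (the +1 position); must be >= 2.
#' @param matrix A [ScoringMatrix-class].
#' @param columns Subset of matrix column labels to sum over (default: all
#'   25).
#' @return A list with `score` (numeric) and `complete` (`FALSE` if any
#'   addressed position fell outside the sequence).
#' @seealso [predictCleavageSite()], [transitPeptideScore()]
#' @export
windowScore <- function(sequence, matureStart, matrix,
                        columns = MATRIX_COLUMNS) {
  stopifnot(methods::is(matrix, "ScoringMatrix"))
  columns <- as.character(columns)
  if (length(columns) == 0L || !all(columns %in% MATRIX_COLUMNS))
    stop("columns must be a non-empty subset of the 25 matrix column labels")
  if (matureStart < 2L)
    stop("matureStart must be >= 2 (a signal peptide has at least one residue)")
  chars <- .seqToChars(sequence)
  res <- .scoreWindow(chars, as.integer(matureStart), scoreValues(matrix), columns)
  list(score = res$score, complete = res$complete)
}

# Candidate preference order for tie-breaking: offset 0 first, then smallest
# absolute offset with upstream (negative) before downstream.
.OFFSET_ORDER <- c(0L, -1L, 1L, -2L, 2L)

#' Relocate the cleavage site within a five-position sliding window
#'
#' Evaluates the five candidate cleavage sites at offsets -2..+2 around the
#' predictor-reported site, scoring each candidate window with the scoring
#' matrix, and returns the candidate with the highest score. Ties prefer
#' offset 0 (agreement with the external predictor), then the smallest
#' absolute offset, with upstream before downstream. Candidates whose
#' window lies entirely outside the sequence are never selected.
#'
#' @param sequence A single protein sequence.
#' @param signalpMatureStart 1-based first mature residue reported by the
#'   signal-peptide predictor (from a positive record).
#' @param matrix A [ScoringMatrix-class].
#' @param windowMode `"full25"` (default) scores each candidate with all 25
#'   matrix columns; `"core5"` restricts scoring to the five core columns
#'   -2, -1, +1, +2, +3 around the scissile bond.
#' @return A list with `matureStart` (the relocated +1 position), `offset`
#'   (in -2..+2), `candidateScores` (numeric length 5, named "-2".."2"),
#'   and `complete` (completeness flag of the selected window).
#' @export
predictCleavageSite <- function(sequence, signalpMatureStart, matrix,
                                windowMode = c("full25", "core5")) {
  stopifnot(methods::is(matrix, "ScoringMatrix"))
  windowMode <- match.arg(windowMode)
  if (signalpMatureStart < 2L)
    stop("signalpMatureStart must be >= 2")
  cols <- if (windowMode == "full25") MATRIX_COLUMNS else
    c("-2", "-1", "1", "2", "3")
  chars <- .seqToChars(sequence)
  sv <- scoreValues(matrix)
  offsets <- -2:2
  cand <- lapply(offsets, function(d) {
    m <- as.integer(signalpMatureStart) + d
    if (m < 2L) {
      # zero-length signal peptide: score with zero-fill but make the
      # candidate selectable only if some addressed position exists
      r <- .scoreWindow(chars, m, sv, cols)
      if (m < 1L) r$coverage <- 0L
      r
    } else .scoreWindow(chars, m, sv, cols)
  })
  scores <- vapply(cand, `[[`, numeric(1), "score")
  names(scores) <- as.character(offsets)
  eligible <- vapply(cand, `[[`, integer(1), "coverage") > 0L
  if (!any(eligible))
    stop("no candidate cleavage-site window overlaps the sequence")
  best <- max(scores[eligible])
  pick <- NA_integer_
  for (d in .OFFSET_ORDER) {
    i <- match(d, offsets)
    if (eligible[i] && scores[i] >= best - 0 && scores[i] == best) {
      pick <- i
      break
    }
  }
  list(matureStart = as.integer(signalpMatureStart) + offsets[pick],
       offset = offsets[pick],
       candidateScores = scores,
       complete = cand[[pick]]$complete)
}

#' Transit-peptide score
#'
#' Scores the 20 residues downstream of a cleavage site (matrix columns
#' +1..+20 only); the cleavage site itself and the signal-peptide side are
#' not evaluated. This is the quantity compared with the high-confidence
#' cutoff (default 2, strict).
#'
#' @inheritParams windowScore
#' @return A list with `score` and `complete` as in [windowScore()].
#' @export
transitPeptideScore <- function(sequence, matureStart, matrix) {
  windowScore(sequence, matureStart, matrix, columns = as.character(1:20))
}

# Truncate a sequence at the first stop character, with a warning.
.stripStops <- function(seq, id) {
  star <- regexpr("*", seq, fixed = TRUE)
  if (star > 0L) {
    warning("sequence ", id, " contains a stop character '*' at position ",
            star, "; it and everything after it are ignored", call. = FALSE)
    seq <- substr(seq, 1L, star - 1L)
  }
  seq
}

# Classify one sequence given its signal-peptide call. Returns a one-row
# data frame in the frozen output column order.
.classifyOne <- function(id, sequence, positive, matureStart, matrix,
                         cutoff, plus1Set, windowMode) {
  row <- data.frame(
    id = id, signalp_pos = NA_integer_, asafind_pos = NA_integer_,
    offset = NA_integer_, score_m2 = NA_real_, score_m1 = NA_real_,
    score_0 = NA_real_, score_p1 = NA_real_, score_p2 = NA_real_,
    cleavage_score = NA_real_, plus1_aa = NA_character_,
    transit_score = NA_real_, truncated = FALSE,
    prediction = CLASS_NP_NEG, stringsAsFactors = FALSE)
  if (!isTRUE(positive))
    return(row)
  sequence <- .stripStops(sequence, id)
  if (nchar(sequence) == 0L)
    stop("sequence ", id, " is empty after removing stop characters")
  site <- predictCleavageSite(sequence, matureStart, matrix,
                              windowMode = windowMode)
  chars <- .seqToChars(sequence)
  plus1 <- if (site$matureStart >= 1L && site$matureStart <= length(chars))
    chars[site$matureStart] else NA_character_
  ts <- windowScore(sequence, site$matureStart, matrix,
                    columns = as.character(1:20))
  # full 25-column window completeness at the relocated site, for the flag
  full <- windowScore(sequence, site$matureStart, matrix)
  cls <- if (!isTRUE(plus1 %in% plus1Set)) {
    CLASS_NP_POS
  } else if (site$offset == 0L && ts$score > cutoff) {
    CLASS_HIGH
  } else {
    CLASS_LOW
  }
  row$signalp_pos <- as.integer(matureStart)
  row$asafind_pos <- site$matureStart
  row$offset <- site$offset
  row[c("score_m2", "score_m1", "score_0", "score_p1", "score_p2")] <-
    as.list(unname(site$candidateScores))
  row$cleavage_score <- max(site$candidateScores)
  row$plus1_aa <- plus1
  row$transit_score <- ts$score
  row$truncated <- !(full$complete && ts$complete)
  row$prediction <- cls
  row
}

#' Classify proteins into the four plastid-targeting classes
#'
#' The full decision procedure for each input protein: (1) a
#' signal-peptide-negative record is "not plastid, SignalP negative";
#' (2) otherwise the cleavage site is relocated within +/-2 of the
#' predictor site ([predictCleavageSite()]); if the first residue of the
#' relocated transit peptide is not one of F, W, Y, L the protein is "not
#' plastid, SignalP positive" (a candidate for ER retention or other
#' secretory targeting); (3) otherwise it is "plastid, high confidence"
#' when the relocated site coincides with the predictor site (offset 0)
#' and the transit-peptide score exceeds the cutoff (strictly), else
#' "plastid, low confidence".
#'
#' @param sequences Proteins as an `AAStringSet` or named character vector.
#'   FASTA identifiers are the first whitespace-delimited header token.
#' @param signalp Data frame of signal-peptide calls ([readSignalP3Short()]
#'   or [readSignalPTab()]). Every sequence must have a record (error
#'   otherwise); predictor records without a sequence are dropped with a
#'   warning.
#' @param matrix A [ScoringMatrix-class].
#' @param cutoff High-confidence transit-score cutoff (default 2; strict
#'   comparison).
#' @param plus1Set Allowed first transit-peptide residues (default F, W,
#'   Y, L).
#' @param windowMode See [predictCleavageSite()].
#' @return A data frame, one row per input sequence in input order, with
#'   columns `id`, `signalp_pos`, `asafind_pos`, `offset`, `score_m2` ..
#'   `score_p2` (the five candidate scores), `cleavage_score`, `plus1_aa`,
#'   `transit_score`, `truncated`, `prediction`.
#' @examples
#' m <- buildMatrix(c(w = paste0("LLVSA", "FAP", strrep("S", 17))))
#' classifyProteins(
#'   c(p1 = paste0("MALLLLLVSA", "FAP", strrep("S", 30))),
#'   data.frame(id = "p1", positive = TRUE, mature_start = 11L),
#'   m)
#' @export
classifyProteins <- function(sequences, signalp, matrix,
                             cutoff = DEFAULT_CUTOFF,
                             plus1Set = DEFAULT_PLUS1_SET,
                             windowMode = c("full25", "core5")) {
  windowMode <- match.arg(windowMode)
  stopifnot(methods::is(matrix, "ScoringMatrix"), is.finite(cutoff))
  plus1Set <- toupper(plus1Set)
  if (length(plus1Set) == 0L || !all(plus1Set %in% AA20))
    stop("plus1Set must be a non-empty subset of the 20-letter alphabet")
  seqs <- .asSequences(sequences)
  .checkSignalPRecords(signalp)
  missing <- setdiff(names(seqs), signalp$id)
  if (length(missing))
    stop("no signal-peptide record for sequence id(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(signalp$id, names(seqs))
  if (length(extra))
    warning("signal-peptide record(s) without a matching sequence: ",
            paste(extra, collapse = ", "), call. = FALSE)
  rows <- lapply(names(seqs), function(id) {
    rec <- signalp[match(id, signalp$id), ]
    .classifyOne(id, seqs[[id]], rec$positive, rec$mature_start, matrix,
                 cutoff, plus1Set, windowMode)
  })
  do.call(rbind, rows)
}

#' Read / write prediction tables
#'
#' The prediction TSV has the frozen column order of [classifyProteins()]
#' output, with absent values serialized as `.` and the class label
#' verbatim. Lines starting with `#` are comments.
#'
#' @param predictions Data frame from [classifyProteins()].
#' @param path File path.
#' @param header Optional character vector of `#`-prefixed comment lines
#'   written before the table.
#' @return `writePredictions()` returns `path` invisibly;
#'   `readPredictions()` returns the data frame.
#' @export
writePredictions <- function(predictions, path, header = character(0)) {
  cols <- c("id", "signalp_pos", "asafind_pos", "offset", "score_m2",
            "score_m1", "score_0", "score_p1", "score_p2", "cleavage_score",
            "plus1_aa", "transit_score", "truncated", "prediction")
  stopifnot(all(cols %in% names(predictions)))
  fmt <- function(x, digits = FALSE) {
    out <- if (digits) ifelse(is.na(x), ".", sprintf("%.6f", x))
           else ifelse(is.na(x), ".", as.character(x))
    out
  }
  body <- predictions
  lines <- paste(
    fmt(body$id), fmt(body$signalp_pos), fmt(body$asafind_pos),
    fmt(body$offset), fmt(body$score_m2, TRUE), fmt(body$score_m1, TRUE),
    fmt(body$score_0, TRUE), fmt(body$score_p1, TRUE),
    fmt(body$score_p2, TRUE), fmt(body$cleavage_score, TRUE),
    fmt(body$plus1_aa), fmt(body$transit_score, TRUE),
    ifelse(body$truncated, "yes", "no"), body$prediction, sep = "\t")
  writeLines(c(header, paste(cols, collapse = "\t"), lines), path)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          na.strings = ".", stringsAsFactors = FALSE)
  df$truncated <- df$truncated == "yes"
  df
}
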