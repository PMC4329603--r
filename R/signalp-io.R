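# Parsers for external signal-peptide predictor output. The package consumes
# predictor calls; it never runs the predictor itself.

# Normalize path-or-lines input.
.inputLines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    readLines(x, warn = FALSE)
  else
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

.checkSignalPRecords <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "positive", "mature_start") %in% names(df)))
  df
}

#' Parse SignalP 3.0 neural-network short-format output
#'
#' Reads the 14-column whitespace-delimited short format of the SignalP 3.0
#' neural network (`name Cmax Cpos Cflag Ymax Ypos Yflag Smax Spos Sflag
#' Smean Smeanflag D Dflag`). A record is called signal-peptide positive
#' when its D-score flag is `Y` (the network's composite decision score);
#' the first mature-protein residue (the +1 position) is taken from the
#' Ymax position column, SignalP's predicted cleavage site. Lines starting
#' with `#` are comments.
#'
#' @param input File path, or a character vector of lines.
#' @return A data frame with columns `id`, `positive` (logical),
#'   `mature_start` (integer, `NA` for negative records), and raw scores
#'   `cmax`, `ymax`, `smax`, `smean`, `d`. Input order is preserved.
#' @examples
#' readSignalP3Short("seqA 0.83 18 Y 0.81 18 Y 0.95 10 Y 0.87 Y 0.84 Y")
#' @export
readSignalP3Short <- function(input) {
  lines <- .inputLines(input)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  out <- data.frame(id = character(n), positive = logical(n),
                    mature_start = NA_integer_,
                    cmax = NA_real_, ymax = NA_real_, smax = NA_real_,
                    smean = NA_real_, d = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) != 14L)
      stop("SignalP short-format parse error at line ", lineno[i],
           ": expected 14 columns, got ", length(f))
    num <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6, 8, 9, 11, 13)]))
    if (anyNA(num))
      stop("SignalP short-format parse error at line ", lineno[i],
           ": non-numeric score field")
    positive <- f[14L] == "Y"
    ypos <- as.integer(f[6L])
    if (positive && ypos < 2L)
      stop("SignalP short-format parse error at line ", lineno[i],
           ": positive record with cleavage position ", ypos,
           " implies a zero-length signal peptide")
    out$id[i] <- f[1L]
    out$positive[i] <- positive
    out$mature_start[i] <- if (positive) ypos else NA_integer_
    out$cmax[i] <- num[1L]; out$ymax[i] <- num[3L]; out$smax[i] <- num[5L]
    out$smean[i] <- num[7L]; out$d[i] <- num[8L]
  }
  out
}

#' Parse / write the generic signal-peptide call TSV
#'
#' A minimal 3-column dialect (`id`, `positive` as Y/N, `mature_start`)
#' that lets users supply calls converted from any predictor version.
#' `mature_start` is the 1-based index of the first mature-protein residue
#' and must be >= 2 for positive records (a signal peptide has at least one
#' residue); it is empty/ignored for negative records. Lines starting with
#' `#` are comments. Writing parsed records and re-parsing is the identity.
#'
#' @param input File path or character vector of lines (with header).
#' @param records Data frame as returned by a parser.
#' @param path Output file path.
#' @return `readSignalPTab()` returns a data frame with columns `id`,
#'   `positive`, `mature_start`; `writeSignalPTab()` returns `path`
#'   invisibly.
#' @examples
#' readSignalPTab(c("id\tpositive\tmature_start", "p1\tY\t20", "p2\tN\t"))
#' @export
readSignalPTab <- function(input) {
  lines <- .inputLines(input)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("signal-peptide TSV parse error: empty input")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || tolower(header[1L]) != "id" ||
      tolower(header[2L]) != "positive")
    stop("signal-peptide TSV parse error at line ", lineno[1L],
         ": expected header 'id<TAB>positive<TAB>mature_start'")
  body <- lines[-1L]
  lineno <- lineno[-1L]
  n <- length(body)
  out <- data.frame(id = character(n), positive = logical(n),
                    mature_start = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || length(f) > 3L)
      stop("signal-peptide TSV parse error at line ", lineno[i],
           ": expected 2-3 tab-separated fields, got ", length(f))
    if (!f[2L] %in% c("Y", "N"))
      stop("signal-peptide TSV parse error at line ", lineno[i],
           ": positive flag must be 'Y' or 'N', got '", f[2L], "'")
    positive <- f[2L] == "Y"
    ms <- if (length(f) == 3L && nzchar(trimws(f[3L]))) {
      v <- suppressWarnings(as.integer(f[3L]))
      if (is.na(v))
        stop("signal-peptide TSV parse error at line ", lineno[i],
             ": non-numeric mature_start '", f[3L], "'")
      v
    } else NA_integer_
    if (positive) {
      if (is.na(ms))
        stop("signal-peptide TSV parse error at line ", lineno[i],
             ": positive record without mature_start")
      if (ms < 2L)
        stop("signal-peptide TSV parse error at line ", lineno[i],
             ": mature_start ", ms, " implies a zero-length signal peptide")
    } else ms <- NA_integer_
    out$id[i] <- f[1L]; out$positive[i] <- positive; out$mature_start[i] <- ms
  }
  out
}

#' @rdname readSignalPTab
#' @export
writeSignalPTab <- function(records, path) {
  .checkSignalPRecords(records)
  lines <- c("id\tpositive\tmature_start",
             paste(records$id,
                   ifelse(records$positive, "Y", "N"),
                   ifelse(is.na(records$mature_start), "",
                          as.character(records$mature_start)),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Write mock records in the SignalP 3.0 NN short format (used by the
# synthetic-data generator so the short-format parser can be exercised
# end to end). Missing raw scores are filled with format-valid values.
writeSignalP3Short <- function(records, path) {
  .checkSignalPRecords(records)
  fill <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, nrow(records))
  }
  cmax <- fill("cmax", 0.5); ymax <- fill("ymax", 0.5)
  smax <- fill("smax", 0.5); smean <- fill("smean", 0.5); d <- fill("d", 0.5)
  flag <- ifelse(records$positive, "Y", "N")
  pos <- ifelse(is.na(records$mature_start), 1L, records$mature_start)
  lines <- sprintf("%s %.3f %d %s %.3f %d %s %.3f %d %s %.3f %s %.3f %s",
                   records$id, cmax, pos, flag, ymax, pos, flag,
                   smax, pmax(1L, pos - 5L), flag, smean, flag, d, flag)
  writeLines(c("# SignalP-NN euk predictions (mock)", lines), path)
  invisible(path)
}
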