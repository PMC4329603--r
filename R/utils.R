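# Shared constants and small helpers.

# Canonical 20-letter amino-acid alphabet, alphabetical order (stable TSV row
# order). Anything outside this set (X, B, Z, J, U, O, *) is excluded from
# frequency counts and scores 0 at lookup time.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column labels of the cleavage-site window: five signal-peptide positions
# upstream of the scissile bond and twenty transit-peptide positions
# downstream. There is no position 0; -1 is the last signal-peptide residue
# and +1 the first transit-peptide residue (the motif's phenylalanine).
MATRIX_COLUMNS <- as.character(c(-5:-1, 1:20))

# Maximum per-column information in bits for a 20-letter alphabet.
MAX_BITS <- log2(20)

# The four prediction classes, serialized verbatim.
CLASS_HIGH    <- "plastid, high confidence"
CLASS_LOW     <- "plastid, low confidence"
CLASS_NP_POS  <- "not plastid, SignalP positive"
CLASS_NP_NEG  <- "not plastid, SignalP negative"
PREDICTION_CLASSES <- c(CLASS_HIGH, CLASS_LOW, CLASS_NP_POS, CLASS_NP_NEG)

DEFAULT_PLUS1_SET <- c("F", "W", "Y", "L")
DEFAULT_CUTOFF <- 2

#' Prediction class labels
#'
#' The four class labels assigned by [classifyProteins()], in fixed order:
#' high-confidence plastid, low-confidence plastid, signal-peptide-positive
#' non-plastid (secretory/ER candidates), and signal-peptide-negative.
#'
#' @return Character vector of the four class labels.
#' @examples
#' predictionClasses()
#' @export
predictionClasses <- function() PREDICTION_CLASSES

# Split one or more sequences into character matrices / vectors of residues.
.seqToChars <- function(x) strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]

# Coerce protein input (AAStringSet, named character vector) to a named
# character vector of uppercase sequences.
.asSequences <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (!is.character(x))
    stop("sequences must be an AAStringSet or a character vector")
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("character sequences must be named by identifier")
  toupper(x)
}

# First whitespace-delimited token of a FASTA header.
.fastaId <- function(x) sub("\\s.*$", "", x)
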