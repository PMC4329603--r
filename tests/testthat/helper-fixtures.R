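# Shared test helpers: tiny hand-built matrices and sequences.

# A ScoringMatrix with all-zero entries.
zeroMatrix <- function() {
  buildMatrix(stats::setNames(strrep("A", 25), "w"))  # placeholder, overwritten
}

# A ScoringMatrix whose only nonzero entries are given as a named list
# "column|residue" = value (e.g. list(`1|F` = 2)).
toyMatrix <- function(entries = list()) {
  m <- matrix(0, 20, 25,
              dimnames = list(ASAFindR:::AA20, ASAFindR:::MATRIX_COLUMNS))
  for (key in names(entries)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    m[parts[2], parts[1]] <- entries[[key]]
  }
  ASAFindR:::.ScoringMatrix(m, nSequences = 0L, correctionApplied = FALSE)
}

# Independent brute-force oracle for window scoring: an explicit per-column
# loop with scalar lookups, no vectorization shared with the implementation.
bruteWindowScore <- function(sequence, matureStart, scores, columns) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  total <- 0
  complete <- TRUE
  for (col in columns) {
    j <- as.integer(col)
    pos <- if (j < 0) matureStart + j else matureStart + j - 1
    if (pos < 1 || pos > length(chars)) {
      complete <- FALSE
      next
    }
    aa <- chars[pos]
    if (aa %in% rownames(scores)) total <- total + scores[aa, col]
  }
  list(score = total, complete = complete)
}

# Brute-force relocation oracle: score all five candidates with the loop
# above and apply the documented tie-break order.
bruteRelocate <- function(sequence, signalpStart, scores) {
  offs <- -2:2
  sc <- sapply(offs, function(d)
    bruteWindowScore(sequence, signalpStart + d, scores,
                     ASAFindR:::MATRIX_COLUMNS)$score)
  cov <- sapply(offs, function(d) {
    chars <- strsplit(sequence, "")[[1]]
    m <- signalpStart + d
    if (m < 1) return(0L)
    pos <- sapply(ASAFindR:::MATRIX_COLUMNS, function(col) {
      j <- as.integer(col)
      if (j < 0) m + j else m + j - 1
    })
    sum(pos >= 1 & pos <= length(chars))
  })
  best <- max(sc[cov > 0])
  for (d in c(0L, -1L, 1L, -2L, 2L)) {
    i <- match(d, offs)
    if (cov[i] > 0 && sc[i] == best) return(list(offset = d, score = best))
  }
}

# Random sequence of canonical residues.
randomProtein <- function(n) {
  paste(sample(ASAFindR:::AA20, n, replace = TRUE), collapse = "")
}

# Random non-negative ScoringMatrix with valid column sums.
randomMatrix <- function() {
  m <- matrix(stats::runif(500), 20, 25,
              dimnames = list(ASAFindR:::AA20, ASAFindR:::MATRIX_COLUMNS))
  m <- sweep(m, 2, colSums(m), "/") * stats::runif(25, 0, log2(20))
  ASAFindR:::.ScoringMatrix(m, nSequences = 0L, correctionApplied = FALSE)
}
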