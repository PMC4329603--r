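# Seeded synthetic-data generator. Provides presequence-bearing proteins,
# secretory and non-secretory negatives, matched mock predictor output,
# training alignments of cleavage-site windows, and toy genomes with
# deliberately broken gene models, so every other module is testable
# without downloads or an external predictor binary.

# Background amino-acid composition (rough average proteome frequencies).
.backgroundComposition <- function() {
  p <- c(A = 0.080, C = 0.015, D = 0.050, E = 0.060, F = 0.040, G = 0.070,
         H = 0.022, I = 0.055, K = 0.060, L = 0.090, M = 0.022, N = 0.040,
         P = 0.050, Q = 0.040, R = 0.050, S = 0.070, T = 0.055, V = 0.090,
         W = 0.011, Y = 0.030)
  p / sum(p)
}

# Mix fixed residue probabilities into the background for one column.
.spike <- function(fixed, base = .backgroundComposition()) {
  stopifnot(sum(fixed) < 1)
  p <- base
  p[names(fixed)] <- 0
  p <- p / sum(p) * (1 - sum(fixed))
  p[names(fixed)] <- p[names(fixed)] + fixed
  p[AA20]
}

#' Transit-peptide residue composition
#'
#' The compositional model of the transit peptide the generator emulates:
#' enriched in hydroxylated residues (S, T) and positively charged
#' residues (R, K), depleted in negatively charged residues (D, E), and
#' alanine-rich, giving a net positive charge.
#'
#' @return Named probability vector over the 20 canonical residues.
#' @export
transitComposition <- function() {
  .spike(c(S = 0.20, T = 0.13, R = 0.11, K = 0.11, A = 0.12,
           D = 0.01, E = 0.01))
}

# Hydrophobic-biased composition of the signal-peptide core.
.hydrophobicComposition <- function() {
  .spike(c(L = 0.25, A = 0.16, V = 0.12, I = 0.10, F = 0.08, M = 0.04,
           W = 0.02, G = 0.05, S = 0.05, T = 0.04, P = 0.02))
}

#' Ground-truth cleavage-site probability matrix
#'
#' The default 20 x 25 column-wise probability matrix from which the
#' generator samples cleavage-site windows. It mimics the conserved
#' "ASAFAP" motif qualitatively at consensus strength: the hydrophobic
#' signal-peptide core still visible at -5/-4, strongly conserved
#' alanine at -3 and -1 with serine at -2 (the A-S-A signal-peptidase
#' pattern), a dominant phenylalanine at +1 (with W/Y/L minorities),
#' alanine at +2, proline enriched at +3, and a transit-peptide-like
#' S/T/R/K-rich composition at +4..+20. The -5/-4 columns are
#' deliberately unlike the A/S anchor columns so that the motif is not
#' self-similar under small shifts, as in the real logo. It is a
#' synthetic fixture constant, not a published matrix.
#'
#' @return Numeric matrix, rows the 20 residues, columns "-5".."-1",
#'   "1".."20"; each column sums to 1.
#' @export
defaultCleavagePWM <- function() {
  tc <- transitComposition()
  cols <- list(
    `-5` = .spike(c(L = 0.30, V = 0.15, A = 0.10)),
    `-4` = .spike(c(V = 0.20, L = 0.15, T = 0.10)),
    `-3` = .spike(c(A = 0.75)),
    `-2` = .spike(c(S = 0.70)),
    `-1` = .spike(c(A = 0.75)),
    `1`  = .spike(c(F = 0.85, Y = 0.04, L = 0.05, W = 0.015)),
    `2`  = .spike(c(A = 0.65)),
    `3`  = .spike(c(P = 0.55, A = 0.10)))
  for (j in 4:20) cols[[as.character(j)]] <- tc
  m <- do.call(cbind, cols)
  dimnames(m) <- list(AA20, MATRIX_COLUMNS)
  m
}

#' Specification of a synthetic benchmark
#'
#' Bundles the parameters of the generator: class sizes, length ranges
#' (in residues), the ground-truth cleavage-site probability matrix, the
#' transit-peptide composition, and the probability that a mock predictor
#' record misplaces the cleavage site by one position.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param nPositive,nSecretory,nNonsecretory Class sizes (default 200
#'   each).
#' @param signalLengthRange Signal-peptide core length range, residues
#'   between the initiator methionine and the -5..-1 window (default
#'   10-20).
#' @param transitTailRange Transit-peptide residues beyond the scored
#'   +1..+20 window (default 10-40).
#' @param matureLengthRange Mature-domain length range (default 80-250).
#' @param sitePerturbProb Probability that a mock predictor record shifts
#'   the true cleavage site by +/-1 (default 0.1, emulating predictor
#'   imprecision).
#' @param pwm Ground-truth probability matrix (default
#'   [defaultCleavagePWM()]).
#' @param transitComp,background Residue compositions for the transit tail
#'   and for background/mature regions.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(seed = 1L, nPositive = 200L, nSecretory = 200L,
                          nNonsecretory = 200L,
                          signalLengthRange = c(10L, 20L),
                          transitTailRange = c(10L, 40L),
                          matureLengthRange = c(80L, 250L),
                          sitePerturbProb = 0.1,
                          pwm = defaultCleavagePWM(),
                          transitComp = transitComposition(),
                          background = .backgroundComposition()) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            nPositive >= 0L, nSecretory >= 0L, nNonsecretory >= 0L,
            length(signalLengthRange) == 2L,
            signalLengthRange[1L] <= signalLengthRange[2L],
            length(transitTailRange) == 2L,
            transitTailRange[1L] <= transitTailRange[2L],
            length(matureLengthRange) == 2L,
            matureLengthRange[1L] <= matureLengthRange[2L],
            sitePerturbProb >= 0, sitePerturbProb <= 1,
            identical(dim(pwm), c(20L, 25L)))
  if (any(abs(colSums(pwm) - 1) > 1e-8))
    stop("spec error: pwm columns must each sum to 1")
  if (any(pwm < 0) || any(transitComp < 0) || any(background < 0))
    stop("spec error: probabilities must be non-negative")
  structure(list(seed = as.integer(seed), nPositive = as.integer(nPositive),
                 nSecretory = as.integer(nSecretory),
                 nNonsecretory = as.integer(nNonsecretory),
                 signalLengthRange = as.integer(signalLengthRange),
                 transitTailRange = as.integer(transitTailRange),
                 matureLengthRange = as.integer(matureLengthRange),
                 sitePerturbProb = sitePerturbProb, pwm = pwm,
                 transitComp = transitComp, background = background),
            class = "SyntheticSpec")
}

.sampleAA <- function(n, prob) {
  paste(sample(AA20, n, replace = TRUE, prob = prob), collapse = "")
}

.samplePWM <- function(pwm, columns) {
  paste(vapply(columns, function(j)
    sample(AA20, 1L, prob = pwm[, j]), character(1)), collapse = "")
}

.rint <- function(range) {
  if (range[1L] == range[2L]) range[1L]
  else sample(seq(range[1L], range[2L]), 1L)
}

#' Generate a labeled synthetic benchmark
#'
#' Emulates a reference set of known subcellular locations: plastid
#' positives carry a bipartite presequence (initiator methionine, a
#' hydrophobic signal-peptide core, the last five signal-peptide residues
#' and first twenty transit-peptide residues drawn from the ground-truth
#' probability matrix, a transit tail from the transit composition, then a
#' background mature domain); secretory negatives share the signal-peptide
#' architecture but draw +1..+20 from the background with a first
#' transit-peptide residue outside {F, W, Y, L}; non-secretory negatives
#' have no signal peptide. Mock predictor records carry the true cleavage
#' site, perturbed by +/-1 with probability `spec$sitePerturbProb`, and
#' are fully deterministic per seed.
#'
#' @param spec A [syntheticSpec()].
#' @return A list with `sequences` (named character vector), `signalp`
#'   (data frame in the generic-dialect layout, with mock raw scores),
#'   and `truth` (data frame `id`, `kind`, `plastid`, `true_mature_start`).
#' @export
generateBenchmark <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$pwm["F", "1"] == 0 && spec$nPositive > 0L)
    stop("spec error: ground-truth matrix assigns zero probability to the +1 phenylalanine")
  set.seed(spec$seed)
  ids <- character(0); seqs <- character(0); kind <- character(0)
  trueStart <- integer(0)
  for (i in seq_len(spec$nPositive)) {
    h <- .rint(spec$signalLengthRange)
    sp <- paste0("M", .sampleAA(h, .hydrophobicComposition()),
                 .samplePWM(spec$pwm, as.character(-5:-1)))
    down <- .samplePWM(spec$pwm, as.character(1:20))
    tail <- .sampleAA(.rint(spec$transitTailRange), spec$transitComp)
    mat <- .sampleAA(.rint(spec$matureLengthRange), spec$background)
    ids <- c(ids, sprintf("pos_%04d", i))
    seqs <- c(seqs, paste0(sp, down, tail, mat))
    kind <- c(kind, "plastid")
    trueStart <- c(trueStart, nchar(sp) + 1L)
  }
  for (i in seq_len(spec$nSecretory)) {
    h <- .rint(spec$signalLengthRange)
    sp <- paste0("M", .sampleAA(h, .hydrophobicComposition()),
                 .samplePWM(spec$pwm, as.character(-5:-1)))
    repeat {
      plus1 <- sample(AA20, 1L, prob = spec$background)
      if (!plus1 %in% DEFAULT_PLUS1_SET) break
    }
    down <- paste0(plus1, .sampleAA(19L, spec$background))
    mat <- .sampleAA(.rint(spec$matureLengthRange), spec$background)
    ids <- c(ids, sprintf("sec_%04d", i))
    seqs <- c(seqs, paste0(sp, down, mat))
    kind <- c(kind, "secretory")
    trueStart <- c(trueStart, nchar(sp) + 1L)
  }
  for (i in seq_len(spec$nNonsecretory)) {
    mat <- .sampleAA(.rint(spec$matureLengthRange) + 30L, spec$background)
    ids <- c(ids, sprintf("cyt_%04d", i))
    seqs <- c(seqs, paste0("M", mat))
    kind <- c(kind, "nonsecretory")
    trueStart <- c(trueStart, NA_integer_)
  }
  positive <- kind != "nonsecretory"
  reported <- trueStart
  if (any(positive)) {
    shift <- ifelse(stats::runif(length(reported)) < spec$sitePerturbProb,
                    sample(c(-1L, 1L), length(reported), replace = TRUE), 0L)
    reported <- ifelse(positive, pmax(2L, trueStart + shift), NA_integer_)
  }
  signalp <- data.frame(
    id = ids, positive = positive, mature_start = reported,
    cmax = round(ifelse(positive, stats::runif(length(ids), 0.5, 0.95),
                        stats::runif(length(ids), 0.02, 0.2)), 3),
    ymax = round(ifelse(positive, stats::runif(length(ids), 0.5, 0.95),
                        stats::runif(length(ids), 0.02, 0.2)), 3),
    smax = round(ifelse(positive, stats::runif(length(ids), 0.6, 0.99),
                        stats::runif(length(ids), 0.05, 0.3)), 3),
    smean = round(ifelse(positive, stats::runif(length(ids), 0.5, 0.95),
                         stats::runif(length(ids), 0.02, 0.2)), 3),
    d = round(ifelse(positive, stats::runif(length(ids), 0.5, 0.9),
                     stats::runif(length(ids), 0.02, 0.2)), 3),
    stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, kind = kind, plastid = kind == "plastid",
                      true_mature_start = trueStart,
                      stringsAsFactors = FALSE)
  list(sequences = stats::setNames(seqs, ids), signalp = signalp,
       truth = truth)
}

#' Generate a training alignment of cleavage-site windows
#'
#' Samples `n` 25-mer windows column-independently from the ground-truth
#' probability matrix; stands in for an alignment of manually curated
#' presequence windows.
#'
#' @param n Number of windows (>= 1).
#' @param spec A [syntheticSpec()] (its `pwm` and `seed` are used).
#' @return Named character vector of 25-mers.
#' @export
generateTrainingAlignment <- function(n, spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"), n >= 1L)
  set.seed(spec$seed)
  cols <- vapply(MATRIX_COLUMNS, function(j)
    sample(AA20, n, replace = TRUE, prob = spec$pwm[, j]), character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  stats::setNames(apply(cols, 1L, paste, collapse = ""),
                  sprintf("train_%05d", seq_len(n)))
}

# Random DNA with given base composition.
.sampleDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# n random "safe" codons: no ATG, no stop codon (so planted ORF interiors
# cannot divert the in-frame extension scan).
.safeCodons <- function(n) {
  all <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0)),
                         c("A", "C", "G", "T"), paste0))
  safe <- setdiff(all, c("ATG", STOP_CODONS))
  paste(sample(safe, n, replace = TRUE), collapse = "")
}

#' Generate a toy genome with deliberately broken gene models
#'
#' Plants full ORFs in random background DNA and emits gene models that
#' exercise every branch of the catalog optimizer: models truncated at
#' both ends (in frame) that must be extended back to their planted ORF,
#' an over-long (> 10 kb) model that must be dropped, an
#' identical-protein model pair of which the curated (`jgi_filtered`)
#' copy must win, a reverse-strand truncated model, and the literal
#' `CCATGAAATTTTAGGG` mini-scaffold whose CDS 6..11 must extend to 3..14
#' (protein MKF). Unmapped proteins comprise one exact copy of a planted
#' protein (to be excluded) and one paralog at 0.75 identity (to be
#' rescued).
#'
#' @param spec A [syntheticSpec()] (only `seed` is used).
#' @return A list with `genome` (named character vector of DNA),
#'   `models` (model data frame), `unmapped` (named character vector of
#'   proteins), and `truth` (data frame `id`, `fate`, `expected_start`,
#'   `expected_end`, `expected_protein`).
#' @export
generateToyGenome <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  plantORF <- function(nCodons) paste0("ATG", .safeCodons(nCodons - 2L), "TAA")
  orf1 <- plantORF(101L)            # 303 nt -> 100-aa protein
  orf2 <- plantORF(51L)             # 153 nt
  orf3 <- plantORF(61L)             # 183 nt, reverse strand
  seg <- function(n) .sampleDNA(n)
  # chr1 layout: [10500 bg][orf1][300 bg][orf2][400 bg][revcomp(orf3)][300 bg]
  p1 <- 10501L
  chr1 <- paste0(seg(10500L), orf1)
  p2 <- nchar(chr1) + 301L
  chr1 <- paste0(chr1, seg(300L), orf2)
  p3 <- nchar(chr1) + 401L
  orf3rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(orf3)))
  chr1 <- paste0(chr1, seg(400L), orf3rc, seg(300L))
  genome <- c(chr1 = chr1, chrEx = "CCATGAAATTTTAGGG")
  L3s <- p3; L3e <- p3 + nchar(orf3) - 1L
  models <- data.frame(
    id = c("m_trunc", "m_long", "m_dup_a", "m_dup_b", "m_rev", "m_ex"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chrEx"),
    strand = c("+", "+", "+", "+", "-", "+"),
    cds_start = c(p1 + 30L, 1L, p2, p2, L3s + 30L, 6L),
    cds_end = c(p1 + 302L - 30L, 10050L, p2 + 152L, p2 + 152L,
                L3e - 30L, 11L),
    est_support = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    jgi_filtered = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  protein1 <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(orf1))))
  protein3 <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(orf3))))
  # paralog at exactly 0.75 identity: mutate every 4th residue
  chars <- strsplit(protein1, "")[[1L]]
  idx <- seq(4L, length(chars), by = 4L)
  chars[idx] <- vapply(chars[idx], function(a)
    sample(setdiff(AA20, a), 1L), character(1))
  paralog <- paste(chars, collapse = "")
  unmapped <- c(u_identical = protein1, u_paralog = paralog)
  truth <- data.frame(
    id = c("m_trunc", "m_long", "m_dup_a", "m_dup_b", "m_rev", "m_ex",
           "u_identical", "u_paralog"),
    fate = c("extended", "dropped_length", "dropped_duplicate",
             "selected", "extended", "extended", "excluded_identity",
             "rescued"),
    expected_start = c(p1, NA, p2, p2, L3s, 3L, NA, NA),
    expected_end = c(p1 + 302L, NA, p2 + 152L, p2 + 152L, L3e, 14L, NA, NA),
    expected_protein = c(protein1, NA, NA, NA, protein3, "MKF", NA, paralog),
    stringsAsFactors = FALSE)
  list(genome = genome, models = models, unmapped = unmapped, truth = truth)
}
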