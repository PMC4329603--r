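# Toy-scale gene-catalog optimization: frame-preserving ORF extension,
# validity filters, per-locus selection, deduplication, and identity-based
# rescue of models from unknown chromosome locations.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.checkModels <- function(models) {
  need <- c("id", "chrom", "strand", "cds_start", "cds_end",
            "est_support", "jgi_filtered")
  stopifnot(is.data.frame(models), all(need %in% names(models)))
  if (!all(models$strand %in% c("+", "-")))
    stop("model strand must be '+' or '-'")
  if (any(models$cds_start > models$cds_end))
    stop("model cds_start must be <= cds_end")
  models
}

.asGenome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# Codons of a DNA string, 5'->3'.
.codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# Extend on the forward strand of `seq` (a plain character string).
# Returns list(start, end, unterminated).
.extendForward <- function(seq, s, e) {
  L <- nchar(seq)
  codon <- function(k) substr(seq, k, k + 2L)
  # upstream: stop immediately if the model already starts with ATG;
  # otherwise scan codon-by-codon in frame until the first ATG, aborting
  # (no change) if an in-frame stop codon or the sequence start intervenes
  if (codon(s) != "ATG") {
    k <- s - 3L
    while (k >= 1L) {
      cd <- codon(k)
      if (cd == "ATG") { s <- k; break }
      if (cd %in% STOP_CODONS) break
      k <- k - 3L
    }
  }
  # downstream: extend in frame to the first stop codon, which becomes the
  # model end; flag the model unterminated if none exists before seq end
  unterminated <- FALSE
  if (!codon(e - 2L) %in% STOP_CODONS) {
    k <- e + 1L
    found <- FALSE
    while (k + 2L <= L) {
      if (codon(k) %in% STOP_CODONS) { e <- k + 2L; found <- TRUE; break }
      k <- k + 3L
    }
    unterminated <- !found
  }
  list(start = s, end = e, unterminated = unterminated)
}

#' Extend a gene model in frame to ATG and stop
#'
#' Extends a CDS model upstream, codon by codon in its reading frame, to
#' the first ATG codon (leaving the start unchanged if an in-frame stop
#' codon or the sequence start intervenes, or if the model already starts
#' with ATG), and downstream to the first in-frame stop codon
#' (TAA/TAG/TGA), which becomes the model end. Strand-aware: a reverse
#' strand model behaves exactly like the forward case on the
#' reverse-complemented genome. The reading frame is anchored at the CDS
#' start, so the input span must be a codon multiple, and extension never
#' shrinks a model.
#'
#' @param genome A `DNAStringSet` (or named character vector of DNA).
#' @param model One-row data frame with columns `id`, `chrom`, `strand`,
#'   `cds_start`, `cds_end`, `est_support`, `jgi_filtered`.
#' @return The model row with updated `cds_start`/`cds_end` and an added
#'   logical column `unterminated` (no in-frame stop before the sequence
#'   end; coordinates left unchanged downstream in that case).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "CCATGAAATTTTAGGG"))
#' m <- data.frame(id = "m1", chrom = "chr1", strand = "+", cds_start = 6,
#'                 cds_end = 11, est_support = TRUE, jgi_filtered = FALSE)
#' extendModel(g, m)[, c("cds_start", "cds_end")]  # 3, 14 -> protein MKF
#' @export
extendModel <- function(genome, model) {
  genome <- .asGenome(genome)
  model <- .checkModels(model)
  stopifnot(nrow(model) == 1L)
  if (!model$chrom %in% names(genome))
    stop("model ", model$id, ": chromosome '", model$chrom,
         "' not in the genome")
  seq <- as.character(genome[[model$chrom]])
  L <- nchar(seq)
  s <- as.integer(model$cds_start); e <- as.integer(model$cds_end)
  if (s < 1L || e > L)
    stop("model ", model$id, ": coordinates outside the genome sequence")
  if ((e - s + 1L) %% 3L != 0L)
    stop("model ", model$id, ": CDS span is not a codon multiple")
  if (model$strand == "+") {
    r <- .extendForward(seq, s, e)
    model$cds_start <- r$start; model$cds_end <- r$end
  } else {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    r <- .extendForward(rc, L - e + 1L, L - s + 1L)
    model$cds_start <- L - r$end + 1L
    model$cds_end <- L - r$start + 1L
  }
  model$unterminated <- r$unterminated
  model
}

#' @rdname extendModel
#' @param models Data frame of models (several rows).
#' @export
extendModels <- function(genome, models) {
  models <- .checkModels(models)
  out <- lapply(seq_len(nrow(models)), function(i)
    extendModel(genome, models[i, , drop = FALSE]))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Length filter for gene models
#'
#' Models whose genomic span exceeds `maxNt` (default 10 kb) are assumed
#' to be incorrect and dropped; the comparison is strict, so a span of
#' exactly `maxNt` is kept.
#'
#' @param model Data frame of models (one or more rows).
#' @param maxNt Maximum allowed span in nucleotides (default 10000).
#' @return Logical vector, `TRUE` = keep.
#' @export
lengthFilter <- function(model, maxNt = 10000) {
  .checkModels(model)
  (model$cds_end - model$cds_start + 1) <= maxNt
}

# CDS nucleotide sequence of a model, 5'->3' (strand-aware).
.modelCDS <- function(genome, model) {
  genome <- .asGenome(genome)
  s <- substr(as.character(genome[[model$chrom]]),
              model$cds_start, model$cds_end)
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Protein translation of a gene model
#'
#' @param genome A `DNAStringSet`.
#' @param model One-row model data frame (codon-multiple span).
#' @return The protein sequence as a character string, without the
#'   terminal stop.
#' @export
modelProtein <- function(genome, model) {
  cds <- .modelCDS(genome, model)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(cds),
                          if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

#' Validate an extended gene model
#'
#' The four validity checks a model must pass to enter per-locus
#' selection: an N-terminal ATG (initiator methionine), no internal stop
#' codon, EST support (consumed as an input flag), and a C-terminal stop
#' codon.
#'
#' @param genome A `DNAStringSet`.
#' @param model One-row model data frame.
#' @return Named logical vector `starts_atg`, `no_internal_stop`,
#'   `est_support`, `terminal_stop`, plus `valid` (all four).
#' @export
validateModel <- function(genome, model) {
  model <- .checkModels(model)
  cds <- .modelCDS(genome, model)
  cod <- .codons(cds)
  n <- length(cod)
  startsATG <- cod[1L] == "ATG"
  terminalStop <- cod[n] %in% STOP_CODONS
  internal <- if (n > 2L) any(cod[2:(n - 1L)] %in% STOP_CODONS) else FALSE
  out <- c(starts_atg = startsATG,
           no_internal_stop = !internal,
           est_support = isTRUE(model$est_support),
           terminal_stop = terminalStop)
  c(out, valid = all(out))
}

# Locus ids by single-linkage clustering of overlapping same-chromosome,
# same-strand spans.
.locusIds <- function(models) {
  key <- paste(models$chrom, models$strand)
  locus <- integer(nrow(models))
  nextLocus <- 0L
  for (k in unique(key)) {
    i <- which(key == k)
    ir <- IRanges::IRanges(models$cds_start[i], models$cds_end[i])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, select = "first")
    locus[i] <- nextLocus + hit
    nextLocus <- nextLocus + length(red)
  }
  locus
}

#' Select one representative model per locus
#'
#' Loci are single-linkage clusters of same-chromosome, same-strand models
#' with overlapping spans. Within each locus the longest model passing all
#' of [validateModel()]'s checks wins; when tied models encode identical
#' proteins the curated (`jgi_filtered`) model is preferred. Exact
#' duplicate proteins among the chosen representatives are then removed
#' (again preferring the `jgi_filtered` copy).
#'
#' @param genome A `DNAStringSet`.
#' @param models Data frame of (extended) models.
#' @return The representative subset of `models`, with an added `protein`
#'   column; proteins are unique.
#' @export
selectPerLocus <- function(genome, models) {
  models <- .checkModels(models)
  if (nrow(models) == 0L) {
    models$protein <- character(0)
    return(models)
  }
  models$protein <- vapply(seq_len(nrow(models)), function(i)
    modelProtein(genome, models[i, , drop = FALSE]), character(1))
  valid <- vapply(seq_len(nrow(models)), function(i)
    validateModel(genome, models[i, , drop = FALSE])[["valid"]], logical(1))
  locus <- .locusIds(models)
  reps <- integer(0)
  for (l in unique(locus)) {
    i <- which(locus == l & valid)
    if (length(i) == 0L) next
    span <- models$cds_end[i] - models$cds_start[i] + 1L
    i <- i[span == max(span)]
    if (length(i) > 1L) {
      filt <- i[models$jgi_filtered[i]]
      i <- if (length(filt)) filt[1L] else i[1L]
    }
    reps <- c(reps, i)
  }
  out <- models[reps, , drop = FALSE]
  # deduplicate identical proteins across loci, preferring curated models
  if (nrow(out) > 1L) {
    pref <- order(!out$jgi_filtered)      # curated first, stable
    out <- out[pref, , drop = FALSE]
    out <- out[!duplicated(out$protein), , drop = FALSE]
    out <- out[order(match(out$id, models$id)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Global alignment identity (matches / alignment length) under match 1,
# mismatch 0, unit gap cost.
.aaSubst <- function() {
  letters <- c(AA20, "X", "B", "Z", "J", "U", "O", "*")
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  m
}

#' Pairwise global-alignment identity
#'
#' Identity = matches / alignment length under a global (Needleman-Wunsch)
#' alignment scoring match 1, mismatch 0, and unit gap cost.
#'
#' @param a,b Protein sequences (strings).
#' @return Identity in `[0, 1]`.
#' @examples
#' proteinIdentity("MKFA", "MKYA")  # 0.75
#' @export
proteinIdentity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .aaSubst(), gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(pa) / nchar(as.character(Biostrings::pattern(pa)))
}

#' Rescue proteins from unmapped gene models
#'
#' A protein from a model with unknown chromosome location is added to the
#' optimized set iff its maximum identity against every selected protein
#' is below `threshold` (default 0.95). With an empty selected set all
#' unmapped proteins are added.
#'
#' @param unmappedProteins Named character vector or `AAStringSet`.
#' @param selectedProteins Character vector of proteins already in the set.
#' @param threshold Identity threshold (strict `<`; default 0.95).
#' @return Data frame `id`, `protein`, `max_identity`, `rescued`.
#' @export
rescueUnmapped <- function(unmappedProteins, selectedProteins,
                           threshold = 0.95) {
  if (length(unmappedProteins) == 0L)
    return(data.frame(id = character(0), protein = character(0),
                      max_identity = numeric(0), rescued = logical(0)))
  prots <- .asSequences(unmappedProteins)
  maxId <- vapply(prots, function(p) {
    if (length(selectedProteins) == 0L) return(0)
    max(vapply(selectedProteins, proteinIdentity, numeric(1), a = p))
  }, numeric(1))
  data.frame(id = names(prots), protein = unname(prots),
             max_identity = unname(maxId),
             rescued = unname(maxId) < threshold,
             stringsAsFactors = FALSE)
}

#' Full gene-catalog optimization
#'
#' The complete pipeline: (1) in-frame extension of every model to ATG and
#' stop ([extendModel()]; can be disabled), (2) removal of models spanning
#' more than `maxNt`, (3) validity checks ([validateModel()]),
#' (4) per-locus selection and deduplication ([selectPerLocus()]), and
#' (5) rescue of unmapped proteins below the identity threshold
#' ([rescueUnmapped()]). Running the optimization on its own output
#' changes nothing.
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param models Data frame of models (see [extendModel()]).
#' @param unmapped Optional proteins from unmapped models (named character
#'   vector or `AAStringSet`).
#' @param maxNt Span filter in nucleotides (default 10000).
#' @param identityThreshold Rescue threshold (default 0.95).
#' @param extend Extend models before filtering (default `TRUE`).
#' @return A list with `proteins` (named character vector: representative
#'   and rescued proteins), `models` (the representative model rows with
#'   final coordinates and `protein`), and `provenance` (data frame
#'   `id`, `action`, `detail`, `cds_start`, `cds_end`).
#' @export
optimizeCatalog <- function(genome, models, unmapped = NULL, maxNt = 10000,
                            identityThreshold = 0.95, extend = TRUE) {
  genome <- .asGenome(genome)
  models <- .checkModels(models)
  prov <- data.frame(id = character(0), action = character(0),
                     detail = character(0), cds_start = integer(0),
                     cds_end = integer(0), stringsAsFactors = FALSE)
  note <- function(id, action, detail = "", s = NA_integer_, e = NA_integer_)
    rbind(prov, data.frame(id = id, action = action, detail = detail,
                           cds_start = s, cds_end = e,
                           stringsAsFactors = FALSE))
  work <- models
  if (isTRUE(extend) && nrow(work) > 0L) {
    ext <- extendModels(genome, work)
    for (i in seq_len(nrow(work))) {
      if (ext$cds_start[i] != work$cds_start[i] ||
          ext$cds_end[i] != work$cds_end[i])
        prov <- note(ext$id[i], "extended",
                     sprintf("%d..%d -> %d..%d", work$cds_start[i],
                             work$cds_end[i], ext$cds_start[i],
                             ext$cds_end[i]),
                     ext$cds_start[i], ext$cds_end[i])
    }
    work <- ext[names(ext) != "unterminated"]
  }
  keep <- lengthFilter(work, maxNt = maxNt)
  for (i in which(!keep))
    prov <- note(work$id[i], "dropped",
                 sprintf("span %d nt exceeds %d nt",
                         work$cds_end[i] - work$cds_start[i] + 1L,
                         as.integer(maxNt)))
  work <- work[keep, , drop = FALSE]
  reps <- selectPerLocus(genome, work)
  for (i in seq_len(nrow(work))) {
    if (work$id[i] %in% reps$id) {
      prov <- note(work$id[i], "kept", "locus representative",
                   work$cds_start[i], work$cds_end[i])
    } else {
      v <- validateModel(genome, work[i, , drop = FALSE])
      reason <- if (!v[["valid"]])
        paste("failed:", paste(names(v)[!v & names(v) != "valid"],
                               collapse = ","))
      else "superseded at locus or duplicate protein"
      prov <- note(work$id[i], "dropped", reason)
    }
  }
  proteins <- stats::setNames(reps$protein, reps$id)
  rescue <- rescueUnmapped(unmapped, unname(proteins),
                           threshold = identityThreshold)
  for (i in seq_len(nrow(rescue))) {
    prov <- note(rescue$id[i],
                 if (rescue$rescued[i]) "rescued" else "dropped",
                 sprintf("max identity %.3f vs threshold %.2f",
                         rescue$max_identity[i], identityThreshold))
  }
  if (any(rescue$rescued))
    proteins <- c(proteins, stats::setNames(
      rescue$protein[rescue$rescued], rescue$id[rescue$rescued]))
  list(proteins = proteins, models = reps, provenance = prov)
}

#' Read gene models from GFF3 or TSV
#'
#' GFF3 input must contain CDS features with attributes `ID`,
#' `est_support` (true/false) and `jgi_filtered` (true/false); TSV input
#' must have the model columns directly (`id`, `chrom`, `strand`,
#' `cds_start`, `cds_end`, `est_support`, `jgi_filtered`). The format is
#' chosen by file extension (`.gff`/`.gff3` vs anything else).
#'
#' @param path File path.
#' @return Model data frame.
#' @export
readModels <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path)
    g <- g[as.character(g$type) == "CDS"]
    df <- data.frame(
      id = as.character(g$ID),
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(BiocGenerics::strand(g)),
      cds_start = BiocGenerics::start(g),
      cds_end = BiocGenerics::end(g),
      est_support = tolower(as.character(g$est_support)) == "true",
      jgi_filtered = tolower(as.character(g$jgi_filtered)) == "true",
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines)]
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            stringsAsFactors = FALSE)
    df$est_support <- as.logical(df$est_support)
    df$jgi_filtered <- as.logical(df$jgi_filtered)
  }
  .checkModels(df)
}

#' Write gene models as GFF3
#'
#' @param models Model data frame.
#' @param path Output path.
#' @param header Optional extra `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
writeModelsGFF3 <- function(models, path, header = character(0)) {
  models <- .checkModels(models)
  lines <- sprintf("%s\tASAFindR\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;est_support=%s;jgi_filtered=%s",
                   models$chrom, models$cds_start, models$cds_end,
                   models$strand, models$id,
                   tolower(models$est_support),
                   tolower(models$jgi_filtered))
  writeLines(c("##gff-version 3", header, lines), path)
  invisible(path)
}
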