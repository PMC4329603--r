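# Gene-catalog optimization: in-frame extension, filters, per-locus
# selection, identity-based rescue, and the full pipeline on the toy genome.

toyModel <- function(id = "m1", chrom = "chr1", strand = "+", s, e,
                     est = TRUE, filt = FALSE) {
  data.frame(id = id, chrom = chrom, strand = strand, cds_start = s,
             cds_end = e, est_support = est, jgi_filtered = filt,
             stringsAsFactors = FALSE)
}

test_that("extension walks in frame to ATG and stop (worked example)", {
  g <- c(chr1 = "CCATGAAATTTTAGGG")
  e <- extendModel(g, toyModel(s = 6L, e = 11L))
  expect_identical(e$cds_start, 3L)
  expect_identical(e$cds_end, 14L)
  expect_identical(modelProtein(g, e), "MKF")
  expect_false(e$unterminated)
})

test_that("a complete ORF is a fixed point of extension", {
  g <- c(chr1 = "CCATGAAATTTTAGGG")
  m <- toyModel(s = 3L, e = 14L)
  e <- extendModel(g, m)
  expect_identical(e$cds_start, 3L)
  expect_identical(e$cds_end, 14L)
})

test_that("reverse-strand extension mirrors the forward case", {
  fwd <- "CCATGAAATTTTAGGG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  g <- c(chr1 = rc)
  L <- nchar(fwd)
  # model 6..11 on the forward sense = (L-11+1)..(L-6+1) on the minus strand
  e <- extendModel(g, toyModel(strand = "-", s = L - 11L + 1L, e = L - 6L + 1L))
  expect_identical(e$cds_start, L - 14L + 1L)
  expect_identical(e$cds_end, L - 3L + 1L)
  expect_identical(modelProtein(g, e), "MKF")
})

test_that("upstream extension aborts at an in-frame stop codon", {
  #        TAA GGG AAA TTT : stop two codons upstream, no ATG reachable
  g <- c(chr1 = "TAAGGGAAATTTTAGCC")
  e <- extendModel(g, toyModel(s = 7L, e = 12L))
  expect_identical(e$cds_start, 7L)     # unchanged upstream
  expect_identical(e$cds_end, 15L)      # still extends to the stop
})

test_that("models without a downstream stop are flagged unterminated", {
  g <- c(chr1 = "CCATGAAACCCGGGAAA")
  e <- extendModel(g, toyModel(s = 3L, e = 8L))
  expect_true(e$unterminated)
  expect_identical(e$cds_end, 8L)
  expect_error(extendModel(g, toyModel(s = 3L, e = 9L)), "codon multiple")
  expect_error(extendModel(g, toyModel(s = 3L, e = 99L)), "outside")
})

test_that("extension never shrinks a model and preserves frame", {
  spec <- syntheticSpec(seed = 701)
  toy <- generateToyGenome(spec)
  ext <- extendModels(toy$genome, toy$models)
  expect_true(all(ext$cds_start <= toy$models$cds_start))
  expect_true(all(ext$cds_end >= toy$models$cds_end))
  expect_true(all((toy$models$cds_start - ext$cds_start) %% 3L == 0L |
                  ext$strand == "-"))
  expect_true(all((ext$cds_end - ext$cds_start + 1L) %% 3L == 0L))
})

test_that("the 10 kb length filter is strict", {
  expect_true(lengthFilter(toyModel(s = 1L, e = 10000L)))
  expect_false(lengthFilter(toyModel(s = 1L, e = 10050L)))
  expect_true(lengthFilter(toyModel(s = 1L, e = 300L)))
})

test_that("validity checks name their four criteria", {
  g <- c(chr1 = "CCATGAAATTTTAGGG")
  v <- validateModel(g, toyModel(s = 3L, e = 14L, est = TRUE))
  expect_true(all(v))
  v2 <- validateModel(g, toyModel(s = 3L, e = 14L, est = FALSE))
  expect_false(v2[["est_support"]])
  expect_false(v2[["valid"]])
  # internal in-frame TAA
  g3 <- c(chr1 = "CCATGTAAAAATAGGG")
  v3 <- validateModel(g3, toyModel(s = 3L, e = 14L))
  expect_false(v3[["no_internal_stop"]])
  expect_true(v3[["starts_atg"]])
  expect_true(v3[["terminal_stop"]])
})

test_that("per-locus selection keeps the longest valid model", {
  #            1       9     15     21      29
  g <- c(chr1 = paste0("ATGAAATAG", "CCCCCC", "ATGAAACCCGGGTTTTGA",
                       strrep("G", 20)))
  short <- toyModel("short", s = 16L, e = 24L)   # inside the long ORF
  long <- toyModel("long", s = 16L, e = 33L)
  # distinct locus: the first ORF
  other <- toyModel("other", s = 1L, e = 9L)
  ext <- extendModels(g, rbind(short, long))
  ext$unterminated <- NULL
  sel <- selectPerLocus(g, rbind(ext, other))
  # short extends into long -> same coordinates -> deduplicated;
  # non-overlapping ORF retained
  expect_setequal(unique(sel$protein),
                  sel$protein)
  expect_true("other" %in% sel$id)
  expect_identical(sum(sel$chrom == "chr1" & sel$cds_start == 16L), 1L)
})

test_that("identical-protein ties resolve to the curated model", {
  g <- c(chr1 = paste0("ATGAAACCCTGA", strrep("C", 10)))
  a <- toyModel("a", s = 1L, e = 12L, filt = FALSE)
  b <- toyModel("b", s = 1L, e = 12L, filt = TRUE)
  sel <- selectPerLocus(g, rbind(a, b))
  expect_identical(sel$id, "b")
})

test_that("global-alignment identity follows match/alignment-length", {
  expect_equal(proteinIdentity("MKFA", "MKFA"), 1)
  expect_equal(proteinIdentity("MKFA", "MKYA"), 0.75)
  r <- rescueUnmapped(c(u1 = "MKFA", u2 = "MKYA"), c("MKFA"),
                      threshold = 0.95)
  expect_identical(r$rescued, c(FALSE, TRUE))
  # empty selected set: everything is rescued
  r2 <- rescueUnmapped(c(u = "MKFA"), character(0))
  expect_true(all(r2$rescued))
  r3 <- rescueUnmapped(character(0), c("MKFA"))
  expect_identical(nrow(r3), 0L)
})

test_that("the optimizer honors every planted fate in the toy genome", {
  toy <- generateToyGenome(syntheticSpec(seed = 702))
  res <- optimizeCatalog(toy$genome, toy$models, unmapped = toy$unmapped)
  tr <- toy$truth
  # truncated models are extended to their planted full ORFs
  for (id in c("m_trunc", "m_rev", "m_ex")) {
    row <- res$models[res$models$id == id, ]
    expect_identical(row$cds_start, tr$expected_start[tr$id == id])
    expect_identical(row$cds_end, tr$expected_end[tr$id == id])
    expect_identical(row$protein, tr$expected_protein[tr$id == id])
  }
  # the over-long model is dropped, the curated duplicate wins,
  # the identical unmapped protein is excluded, the 0.75 paralog rescued
  expect_false("m_long" %in% names(res$proteins))
  expect_false("m_dup_a" %in% names(res$proteins))
  expect_true("m_dup_b" %in% names(res$proteins))
  expect_false("u_identical" %in% names(res$proteins))
  expect_true("u_paralog" %in% names(res$proteins))
  expect_identical(unname(res$proteins[["u_paralog"]]),
                   tr$expected_protein[tr$id == "u_paralog"])
})

test_that("optimized catalogs satisfy the output invariants", {
  toy <- generateToyGenome(syntheticSpec(seed = 703))
  res <- optimizeCatalog(toy$genome, toy$models, unmapped = toy$unmapped)
  expect_true(all(startsWith(unname(res$proteins), "M")))
  expect_false(any(grepl("*", res$proteins, fixed = TRUE)))
  expect_identical(anyDuplicated(unname(res$proteins)), 0L)
  spans <- res$models$cds_end - res$models$cds_start + 1L
  expect_true(all(spans <= 10000L))
})

test_that("rerunning the optimizer on its own output changes nothing", {
  toy <- generateToyGenome(syntheticSpec(seed = 704))
  res <- optimizeCatalog(toy$genome, toy$models, unmapped = toy$unmapped)
  again <- optimizeCatalog(
    toy$genome, res$models[, names(res$models) != "protein"],
    unmapped = res$proteins[startsWith(names(res$proteins), "u_")])
  expect_identical(sort(names(again$proteins)), sort(names(res$proteins)))
  expect_identical(again$proteins[names(res$proteins)], res$proteins)
  expect_identical(
    again$models[order(again$models$id),
                 c("cds_start", "cds_end")],
    res$models[order(res$models$id), c("cds_start", "cds_end")])
})

test_that("models round-trip through GFF3", {
  toy <- generateToyGenome(syntheticSpec(seed = 705))
  f <- tempfile(fileext = ".gff3")
  writeModelsGFF3(toy$models, f)
  back <- readModels(f)
  back <- back[match(toy$models$id, back$id), ]
  rownames(back) <- NULL
  expect_identical(back$cds_start, toy$models$cds_start)
  expect_identical(back$cds_end, toy$models$cds_end)
  expect_identical(back$strand, toy$models$strand)
  expect_identical(back$est_support, toy$models$est_support)
  expect_identical(back$jgi_filtered, toy$models$jgi_filtered)
})
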