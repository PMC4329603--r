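# Predictor core: window scoring, cleavage-site relocation, transit score,
# and the four-class decision procedure.

test_that("windowScore handles unknowns, truncation and toy matrices", {
  m <- toyMatrix(list(`1|F` = 2.0))
  # all addressed residues unknown -> score 0, complete
  r <- windowScore(strrep("X", 40), 10, m)
  expect_equal(r$score, 0)
  expect_true(r$complete)
  # single-term sum: F at the mature start scores M(+1, F)
  seq <- paste0(strrep("G", 9), "F", strrep("G", 25))
  r2 <- windowScore(seq, 10, m)
  expect_equal(r2$score, 2.0)
  expect_true(r2$complete)
  # mature_start = 2 with upstream columns: only column -1 is in range
  m2 <- toyMatrix(list(`-1|A` = 1.5, `-5|A` = 1.0))
  r3 <- windowScore(strrep("A", 30), 2, m2, columns = as.character(-5:-1))
  expect_equal(r3$score, 1.5)
  expect_false(r3$complete)
  expect_error(windowScore("AAAA", 1, m), ">= 2")
  expect_error(windowScore("AAAA", 5, m, columns = character(0)), "non-empty")
})

test_that("window scoring agrees with a brute-force per-position loop", {
  set.seed(501)
  for (i in 1:60) {
    mat <- randomMatrix()
    seq <- randomProtein(sample(15:60, 1))
    ms <- sample(2:25, 1)
    cols <- sample(ASAFindR:::MATRIX_COLUMNS, sample(1:25, 1))
    got <- windowScore(seq, ms, mat, columns = cols)
    want <- bruteWindowScore(seq, ms, scoreValues(mat), cols)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_identical(got$complete, want$complete)
  }
})

test_that("cleavage-site relocation maximizes the window score", {
  # all-zero matrix: every candidate ties at 0, offset 0 wins
  r <- predictCleavageSite(strrep("A", 60), 20, toyMatrix())
  expect_identical(r$offset, 0L)
  expect_identical(r$matureStart, 20L)
  expect_identical(length(r$candidateScores), 5L)

  # sole F two positions before the reported site: offset -2 wins
  m <- toyMatrix(list(`1|F` = 4))
  seq <- paste0(strrep("G", 17), "F", strrep("G", 40))  # F at 18
  r2 <- predictCleavageSite(seq, 20, m)
  expect_identical(r2$offset, -2L)
  expect_equal(unname(r2$candidateScores[["-2"]]), 4)
  expect_equal(max(r2$candidateScores), 4)

  # canonical ASA|FAP spanning the reported site stays at offset 0
  train <- c(w = paste0("LLVSA", "FAP", strrep("S", 17)))
  mm <- buildMatrix(train)
  seq3 <- paste0("MKWLV", "LLVSA", "FAP", strrep("S", 25))
  r3 <- predictCleavageSite(seq3, 11, mm)
  expect_identical(r3$offset, 0L)
})

test_that("relocation matches the brute-force oracle on random instances", {
  set.seed(502)
  for (i in 1:40) {
    mat <- randomMatrix()
    seq <- randomProtein(sample(30:70, 1))
    ms <- sample(4:20, 1)
    got <- predictCleavageSite(seq, ms, mat)
    want <- bruteRelocate(seq, ms, scoreValues(mat))
    expect_identical(got$offset, want$offset)
    expect_equal(max(got$candidateScores), want$score, tolerance = 1e-9)
  }
})

test_that("ties prefer offset 0, then the smaller, upstream offset", {
  m <- toyMatrix(list(`-5|W` = 2))
  base <- strrep("G", 60)
  # W visible only to candidates -1 and +1 (positions m-6 and m-4), m = 20
  s <- base
  substr(s, 14, 14) <- "W"   # (20-1)-5
  substr(s, 16, 16) <- "W"   # (20+1)-5
  r <- predictCleavageSite(s, 20, m)
  expect_identical(r$offset, -1L)
  # tie including offset 0 resolves to 0
  s2 <- base
  substr(s2, 15, 15) <- "W"  # 20-5
  substr(s2, 13, 13) <- "W"  # (20-2)-5
  r2 <- predictCleavageSite(s2, 20, m)
  expect_identical(r2$offset, 0L)
})

test_that("transit score evaluates only the twenty downstream columns", {
  m <- toyMatrix(list(`1|F` = 3, `2|A` = 1, `-1|A` = 2))
  seq <- paste0(strrep("A", 9), "FA", strrep("G", 25))
  r <- transitPeptideScore(seq, 10, m)
  expect_equal(r$score, 4)        # upstream column -1 excluded
  expect_true(r$complete)
  # twenty unknown residues downstream
  r2 <- transitPeptideScore(paste0(strrep("A", 9), strrep("X", 20)), 10, m)
  expect_equal(r2$score, 0)
  expect_true(r2$complete)
  # only 12 residues downstream: zero-filled, flagged incomplete
  r3 <- transitPeptideScore(paste0(strrep("A", 9), "FA", strrep("G", 10)),
                            10, m)
  expect_equal(r3$score, 4)
  expect_false(r3$complete)
})

test_that("the sixteen decision-table branches map to the published classes", {
  # engineer each combination of {SignalP +/-} x {+1 in set} x {offset 0/!=0}
  # x {transit <= 2 / > 2} with a driver entry that forces the offset and a
  # +1-column entry that sets the transit score
  HIGH <- "plastid, high confidence"; LOW <- "plastid, low confidence"
  NPP <- "not plastid, SignalP positive"; NPN <- "not plastid, SignalP negative"
  mStart <- 10L
  for (sp in c(TRUE, FALSE)) for (dStar in c(0L, 1L))
    for (plus1 in c("F", "A")) for (t in c(1, 3)) {
      mat <- toyMatrix(stats::setNames(list(4, t),
                                       c("-5|W", paste0("1|", plus1))))
      s <- strrep("G", 60)
      substr(s, mStart + dStar - 5L, mStart + dStar - 5L) <- "W"
      substr(s, mStart + dStar, mStart + dStar) <- plus1
      rec <- data.frame(id = "p", positive = sp,
                        mature_start = if (sp) mStart else NA_integer_)
      out <- classifyProteins(c(p = s), rec, mat)
      expected <-
        if (!sp) NPN
        else if (plus1 == "A") NPP
        else if (dStar == 0L && t > 2) HIGH
        else LOW
      expect_identical(out$prediction, expected,
                       label = sprintf("sp=%s d=%d plus1=%s t=%g -> %s",
                                       sp, dStar, plus1, t, out$prediction))
      if (sp) {
        expect_identical(out$offset, dStar)
        expect_equal(out$transit_score, t)
        expect_identical(out$plus1_aa, plus1)
      } else {
        expect_true(is.na(out$offset) && is.na(out$transit_score))
      }
    }
})

test_that("the high-confidence cutoff is strictly greater than 2", {
  mkcase <- function(t) {
    mat <- toyMatrix(list(`-5|W` = 4, `1|F` = t))
    s <- strrep("G", 60)
    substr(s, 5, 5) <- "W"; substr(s, 10, 10) <- "F"
    classifyProteins(c(p = s),
                     data.frame(id = "p", positive = TRUE, mature_start = 10L),
                     mat)$prediction
  }
  expect_identical(mkcase(2.0), "plastid, low confidence")
  expect_identical(mkcase(2.01), "plastid, high confidence")
})

test_that("raising the transit score can only promote within plastid classes", {
  ranks <- c("not plastid, SignalP positive" = 0,
             "plastid, low confidence" = 1,
             "plastid, high confidence" = 2)
  prev <- -Inf
  for (t in c(0.5, 1.5, 2.0, 2.5, 3.5)) {
    mat <- toyMatrix(list(`-5|W` = 4, `1|F` = t))
    s <- strrep("G", 60)
    substr(s, 5, 5) <- "W"; substr(s, 10, 10) <- "F"
    cls <- classifyProteins(
      c(p = s), data.frame(id = "p", positive = TRUE, mature_start = 10L),
      mat)$prediction
    expect_gte(ranks[[cls]], min(prev, 1))
    expect_gte(ranks[[cls]], 1)  # never leaves the plastid classes
    prev <- ranks[[cls]]
  }
})

test_that("predictions are invariant under sequence translation", {
  set.seed(503)
  mat <- randomMatrix()
  seq <- randomProtein(45)
  ms <- 10L
  k <- 7L
  shifted <- paste0(randomProtein(k), seq)
  a <- classifyProteins(c(p = seq),
                        data.frame(id = "p", positive = TRUE,
                                   mature_start = ms), mat)
  b <- classifyProteins(c(p = shifted),
                        data.frame(id = "p", positive = TRUE,
                                   mature_start = ms + k), mat)
  expect_identical(b$asafind_pos, a$asafind_pos + k)
  expect_identical(b$offset, a$offset)
  expect_equal(b$transit_score, a$transit_score, tolerance = 1e-12)
  expect_equal(unlist(b[paste0("score_", c("m2", "m1", "0", "p1", "p2"))]),
               unlist(a[paste0("score_", c("m2", "m1", "0", "p1", "p2"))]),
               tolerance = 1e-12)
  expect_identical(b$prediction, a$prediction)
})

test_that("candidate scores always number five with cleavage_score their max", {
  set.seed(504)
  for (i in 1:10) {
    mat <- randomMatrix()
    seq <- randomProtein(50)
    out <- classifyProteins(
      c(p = seq), data.frame(id = "p", positive = TRUE,
                             mature_start = sample(3:20, 1)), mat)
    sc <- unlist(out[paste0("score_", c("m2", "m1", "0", "p1", "p2"))])
    expect_identical(length(sc), 5L)
    expect_equal(out$cleavage_score, max(sc), tolerance = 1e-12)
  }
})

test_that("stop characters are stripped with a warning", {
  mat <- toyMatrix(list(`1|F` = 3))
  s <- paste0(strrep("G", 9), "F", strrep("G", 30), "*", "GGGG")
  expect_warning(
    out <- classifyProteins(
      c(p = s), data.frame(id = "p", positive = TRUE, mature_start = 10L),
      mat),
    "stop character")
  expect_equal(out$transit_score, 3)
})

test_that("id matching errors on missing records and warns on extras", {
  mat <- toyMatrix()
  expect_error(
    classifyProteins(c(a = "MAAAA"),
                     data.frame(id = "b", positive = FALSE,
                                mature_start = NA_integer_), mat),
    "no signal-peptide record.*a")
  expect_warning(
    classifyProteins(c(a = "MAAAA"),
                     data.frame(id = c("a", "zzz"),
                                positive = c(FALSE, FALSE),
                                mature_start = NA_integer_), mat),
    "zzz")
})

test_that("prediction tables round-trip through the TSV writer", {
  set.seed(505)
  mat <- randomMatrix()
  b <- generateBenchmark(syntheticSpec(seed = 506, nPositive = 5L,
                                       nSecretory = 3L, nNonsecretory = 2L))
  pred <- classifyProteins(b$sequences, b$signalp, mat)
  f <- tempfile(fileext = ".tsv")
  writePredictions(pred, f, header = "# test")
  back <- readPredictions(f)
  expect_identical(back$id, pred$id)
  expect_identical(back$prediction, pred$prediction)
  expect_equal(back$transit_score, round(pred$transit_score, 6),
               tolerance = 1e-9)
  expect_identical(back$truncated, pred$truncated)
})
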