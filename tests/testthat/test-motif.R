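# Consensus construction, degenerate matching, PWM estimation,
# information content, and the PWM <-> consensus conversions.

test_that("buildConsensus returns the minimal covering code per column", {
  expect_identical(codeString(buildConsensus(c("GTTA", "GTTC"))), "GTTM")
  expect_identical(codeString(buildConsensus("ACGT")), "ACGT")
  expect_error(buildConsensus(c("ACG", "AC")), "ragged")

  # sampling every base of a chosen code at each column reconstructs it
  set.seed(13)
  sets <- list(A = "A", C = "C", G = "G", T = "T", M = c("A", "C"),
               R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
               Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
               H = c("A", "C", "T"), D = c("A", "G", "T"),
               B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  for (rep in 1:10) {
    code <- sample(names(sets), 8, replace = TRUE)
    sites <- vapply(1:20, function(i)
      paste(vapply(code, function(cd) sample(sets[[cd]], 1), character(1)),
            collapse = ""), character(1))
    # force every base of each set to appear so the minimal code is exact
    sites[1:4] <- vapply(1:4, function(k)
      paste(vapply(sets[code], function(s) s[min(k, length(s))],
                   character(1)), collapse = ""), character(1))
    expect_identical(codeString(buildConsensus(sites)),
                     paste(code, collapse = ""))
  }
})

test_that("every training site matches its own consensus with 0 mismatches", {
  set.seed(17)
  for (rep in 1:10) {
    sites <- vapply(1:12, function(i) random_dna(10), character(1))
    cons <- buildConsensus(sites)
    expect_true(all(vapply(sites, matchConsensus, consensus = cons,
                           FUN.VALUE = numeric(1)) == 0))
  }
})

test_that("matchConsensus counts set-membership failures", {
  expect_equal(matchConsensus("GTTYMMYMGTAAAC", "GTTCAACAGTAAAC"), 0)
  expect_equal(matchConsensus("GTTYMMYMGTAAAC", "GTTTACTGGGTAAT"), 4)
  expect_equal(matchConsensus("ACGT", "ACGT"), 0)
  expect_error(matchConsensus("ACGT", "ACG"), "length")
  # N in a window satisfies only the code N
  expect_equal(matchConsensus("NNNN", "ANCN"), 0)
  expect_equal(matchConsensus("AYGT", "ANGT"), 1)

  set.seed(19)
  codes <- strsplit("ACGTMRWSYKVHDBN", "")[[1]]
  for (rep in 1:40) {
    code <- paste(sample(codes, 9, replace = TRUE), collapse = "")
    win <- random_dna(9)
    expect_equal(matchConsensus(code, win), oracle_match(code, win))
  }
})

test_that("zero mismatches is equivalent to generability from the code", {
  # every window of width 5 over a consensus with mixed degeneracy
  code <- "AMSNT"
  sets <- list(A = "A", M = c("A", "C"), S = c("C", "G"),
               N = c("A", "C", "G", "T"), T = "T")
  gen <- do.call(expand.grid, c(sets[strsplit(code, "")[[1]]],
                                stringsAsFactors = FALSE))
  generable <- apply(gen, 1, paste, collapse = "")
  all5 <- apply(do.call(expand.grid,
                        rep(list(c("A", "C", "G", "T")), 5)), 1,
                paste, collapse = "")
  for (w in all5) {
    expect_equal(matchConsensus(code, w) == 0, w %in% generable)
  }
})

test_that("pwmFromSites applies the pseudocount rule and normalizes", {
  p <- probMatrix(pwmFromSites(c("A", "C", "G", "T"), alpha = 0))
  expect_equal(unname(p[1, ]), rep(0.25, 4))
  p1 <- probMatrix(pwmFromSites("G", alpha = 1))
  expect_equal(unname(p1[1, ]), c(0.2, 0.2, 0.4, 0.2))
  set.seed(29)
  sites <- vapply(1:9, function(i) random_dna(7), character(1))
  expect_equal(unname(rowSums(probMatrix(pwmFromSites(sites)))),
               rep(1, 7))
})

test_that("information content follows the closed form", {
  expect_equal(informationContent(pwmFromSites(c("A", "C", "G", "T"),
                                               alpha = 0))$ic, 0)
  expect_equal(informationContent(pwmFromSites("G", alpha = 0))$ic, 2)
  half <- pwmFromSites(c("A", "C"), alpha = 0)   # (0.5, 0.5, 0, 0)
  expect_equal(informationContent(half)$ic, 1)
  expect_true(informationContent(half)$conserved)     # at the 1-bit default
  expect_false(informationContent(half, threshold = 1.5)$conserved)
  expect_true(informationContent(pwmFromSites("G", alpha = 0))$conserved)
  expect_error(informationContent(half, background = c(0, 1, 1, 1)))
})

test_that("consensusFromPwm thresholds columns and agrees with buildConsensus", {
  m <- pwmFromSites(c("A", "C"), alpha = 0)
  expect_identical(codeString(consensusFromPwm(m, 0.25)), "M")
  onehot <- pwmFromSites("GATTACA", alpha = 0)
  expect_identical(codeString(consensusFromPwm(onehot)), "GATTACA")

  set.seed(43)
  for (rep in 1:10) {
    sites <- vapply(1:3, function(i) random_dna(6), character(1))
    # with alpha = 0 and threshold below 1/n, observed sets are recovered
    expect_identical(
      codeString(consensusFromPwm(pwmFromSites(sites, alpha = 0), 0.2)),
      codeString(buildConsensus(sites)))
  }
})

test_that("the operator-box consensus has the terminal inverted repeat", {
  cons <- "GTTYMMYMGTAAAC"
  rc <- revComp(cons)
  expect_identical(substr(rc, 1, 3), substr(cons, 1, 3))       # GTT
  expect_identical(substr(rc, 12, 14), substr(cons, 12, 14))   # AAC
})

test_that("motif reverse complement is consistent between forms", {
  set.seed(47)
  sites <- vapply(1:10, function(i) random_dna(8), character(1))
  pwm <- pwmFromSites(sites)
  rc_direct <- probMatrix(revCompMotif(pwm))
  rc_sites <- probMatrix(pwmFromSites(vapply(sites, revComp, character(1))))
  expect_equal(rc_direct, rc_sites, ignore_attr = TRUE)
  cons <- buildConsensus(sites)
  expect_identical(codeString(revCompMotif(cons)),
                   codeString(buildConsensus(vapply(sites, revComp,
                                                    character(1)))))
})

test_that("site files round-trip through FASTA and TSV", {
  sites <- c(s1 = "GTTCAACAGTAAAC", s2 = "GTTTAATCGTAAAC")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeGenomeFasta(sites, fa)
  expect_identical(readSites(fa), sites)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tGTTCAACAGTAAAC", "s2\tGTTTAATCGTAAAC"), tsv)
  expect_identical(readSites(tsv), sites)
})
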