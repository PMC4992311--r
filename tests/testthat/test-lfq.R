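# The label-free quantification stages, from identification filtering to
# the signed fold-change table.

genotypes8 <- setNames(rep(c("wt", "mutant"), each = 4),
                       c(paste0("wt_", 1:4), paste0("mut_", 1:4)))

# long peak table from a peptide x sample matrix (NA = missing cell)
peaks_from_matrix <- function(x, proteins, specific = TRUE) {
  cells <- which(!is.na(x), arr.ind = TRUE)
  data.frame(peptide = rownames(x)[cells[, 1]],
             protein = proteins[cells[, 1]],
             sample = colnames(x)[cells[, 2]],
             intensity = x[cells],
             peak_width = 50, rt_sd = 5,
             specific = rep_len(specific, nrow(x))[cells[, 1]],
             stringsAsFactors = FALSE)
}

idents_for <- function(peaks, prot_e = -5, pep_e = 0.001) {
  u <- unique(peaks[, c("protein", "peptide")])
  data.frame(protein = u$protein, peptide = u$peptide,
             peptide_evalue = pep_e, protein_log10_evalue = prot_e,
             stringsAsFactors = FALSE)
}

full_matrix <- function(values, peptides) {
  matrix(values, nrow = length(peptides), ncol = 8, byrow = TRUE,
         dimnames = list(peptides, names(genotypes8)))
}

test_that("identification filtering composes the three criteria", {
  idents <- data.frame(
    protein = c("A", "A", "A", "B", "C", "C"),
    peptide = c("a1", "a2", "a3", "b1", "c1", "c2"),
    peptide_evalue = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2),
    protein_log10_evalue = c(-3, -3, -3, -2, -4, -4))
  out <- filterIdentifications(idents)
  # A: all pass; B: protein E too high; C: one bad peptide leaves only one
  expect_setequal(out$protein, "A")
  expect_equal(nrow(out), 3L)

  # C survives if both its peptides pass
  idents$peptide_evalue[6] <- 0.04
  expect_setequal(filterIdentifications(idents)$protein, c("A", "C"))
})

test_that("peak filtering uses strict thresholds", {
  peaks <- data.frame(peptide = "p", protein = "P", sample = "wt_1",
                      intensity = 1,
                      peak_width = c(101, 100, 50, 50),
                      rt_sd = c(5, 20, 20.5, 5))
  out <- filterPeaks(peaks)
  expect_equal(out$peak_width, c(100, 50))   # width 101 and rt_sd 20.5 gone
  ok <- peaks[3:4, ]; ok$peak_width <- 90; ok$rt_sd <- 10
  expect_equal(filterPeaks(ok), ok, ignore_attr = TRUE)
})

test_that("peptide selection enforces specificity, 7-of-8 presence and 2 peptides", {
  x <- full_matrix(100, c("p1", "p2", "p3", "p4", "q1", "q2"))
  x["p3", 1:2] <- NA                          # 6 of 8 -> dropped
  x["p2", 1] <- NA                            # 7 of 8 -> kept
  x["q2", 1:3] <- NA                          # drops, leaving protein Q with 1
  prot <- c(rep("P", 4), rep("Q", 2))
  se <- peptideQuant(peaks_from_matrix(x, prot,
                                       specific = c(TRUE, TRUE, TRUE, FALSE,
                                                    TRUE, TRUE)),
                     genotypes8)
  out <- selectPeptides(se)
  expect_setequal(rownames(out), c("p1", "p2"))   # p4 non-specific, Q gone
})

test_that("a fully absent sample is reported by name", {
  x <- full_matrix(100, c("p1", "p2"))
  x[, "mut_3"] <- NA
  expect_error(peptideQuant(peaks_from_matrix(x, c("P", "P")), genotypes8),
               "mut_3")
})

test_that("imputation is exact for collinear peptides and flags dead ends", {
  a <- c(10, 12, 8, 11, 9, 10, 13, 10)
  x <- rbind(A = a, B = 2 * a)
  colnames(x) <- names(genotypes8)
  x["B", "mut_1"] <- NA
  se <- peptideQuant(peaks_from_matrix(x, c("P", "P")), genotypes8)
  done <- imputeMissing(se)
  expect_equal(SummarizedExperiment::assay(done, "intensity")["B", "mut_1"],
               2 * a[colnames(x) == "mut_1"])
  # observed cells are untouched
  expect_equal(SummarizedExperiment::assay(done, "intensity")["A", ],
               a, ignore_attr = TRUE)

  # complete data pass through unchanged
  x2 <- full_matrix(c(1:8, 11:18), c("m1", "m2"))
  se2 <- peptideQuant(peaks_from_matrix(x2, c("M", "M")), genotypes8)
  expect_equal(SummarizedExperiment::assay(imputeMissing(se2), "intensity"),
               SummarizedExperiment::assay(se2, "intensity"))

  # both peptides missing in the same sample: nothing to regress on
  x3 <- full_matrix(100, c("r1", "r2"))
  x3[, "wt_2"] <- NA
  x3["r1", "wt_3"] <- NA
  se3 <- suppressWarnings(peptideQuant(
    peaks_from_matrix(rbind(x3, full_matrix(50, c("s1", "s2"))),
                      c("R", "R", "S", "S")),
    genotypes8))
  expect_warning(imputeMissing(se3), "dropped")
})

test_that("median-ratio normalization uses the reference and resists outliers", {
  set.seed(73)
  base <- matrix(10^runif(40, 4, 6), nrow = 5,
                 dimnames = list(paste0("p", 1:5), names(genotypes8)))
  base[, "wt_2"] <- base[, "wt_1"] * 2          # a doubled run
  se <- peptideQuant(peaks_from_matrix(base, rep("P1", 5)), genotypes8)
  norm <- normalizeRuns(se, reference = "wt_1")
  xn <- SummarizedExperiment::assay(norm, "intensity")
  expect_equal(xn[, "wt_1"], base[, "wt_1"])    # reference untouched
  expect_equal(xn[, "wt_2"], base[, "wt_1"])    # factor 2 undone
  expect_equal(S4Vectors::metadata(norm)$norm_factors[["wt_2"]], 2)

  # one wild peptide does not move the median factor
  out <- base
  out[, "wt_3"] <- base[, "wt_1"]
  out["p2", "wt_3"] <- base["p2", "wt_1"] * 1000
  se2 <- peptideQuant(peaks_from_matrix(out, rep("P1", 5)), genotypes8)
  xn2 <- SummarizedExperiment::assay(normalizeRuns(se2, reference = "wt_1"),
                                     "intensity")
  expect_equal(xn2["p2", "wt_3"], base["p2", "wt_1"] * 1000)
  expect_equal(xn2["p1", "wt_3"], base["p1", "wt_1"])
})

test_that("protein roll-up sums peptides and ignores their order", {
  x <- full_matrix(c(rep(1, 8), rep(2, 8), rep(3, 8)),
                   c("a", "b", "c"))
  se <- peptideQuant(peaks_from_matrix(x, rep("P", 3)), genotypes8)
  up <- proteinRollup(se)
  expect_equal(unname(SummarizedExperiment::assay(up, "abundance")["P", ]),
               rep(6, 8))
  perm <- peptideQuant(peaks_from_matrix(x[c(3, 1, 2), ], rep("P", 3)),
                       genotypes8)
  expect_equal(SummarizedExperiment::assay(proteinRollup(perm), "abundance"),
               SummarizedExperiment::assay(up, "abundance"))
})

test_that("the peak-count rule needs both significance and a 5-peak difference", {
  counts <- rbind(same = rep(10, 8),
                  sep6 = c(10, 10, 10, 10, 16, 16, 16, 16),
                  sep4 = c(10, 10, 10, 10, 14, 14, 14, 14))
  colnames(counts) <- names(genotypes8)
  out <- peakCountTest(counts, genotypes8)
  expect_false(out$kw_pass[out$protein == "same"])
  expect_equal(out$peak_diff, c(0, 6, 4))
  sep6 <- out[out$protein == "sep6", ]
  expect_true(sep6$kw_pass == (sep6$kw_p < 0.05))
  expect_false(out$kw_pass[out$protein == "sep4"])   # diff 4 < 5
  expect_equal(out$kw_p[2], kruskal.test(
    counts["sep6", ], factor(rep(c("wt", "mutant"), each = 4)))$p.value)
})

test_that("two-group ANOVA equals the pooled t-test (F = t^2)", {
  set.seed(79)
  x <- matrix(rnorm(80, mean = 10), nrow = 10,
              dimnames = list(paste0("P", 1:10), names(genotypes8)))
  out <- anovaTest(x, genotypes8)
  grp <- rep(c("wt", "mutant"), each = 4)
  for (i in 1:10) {
    tt <- t.test(x[i, grp == "mutant"], x[i, grp == "wt"],
                 var.equal = TRUE)$p.value
    expect_equal(out$anova_p[i], tt, tolerance = 1e-12)
  }
  # degenerate rows: identical groups vs cleanly separated groups
  deg <- rbind(flat = rep(5, 8),
               split = rep(c(1, 2), each = 4))
  colnames(deg) <- names(genotypes8)
  dout <- anovaTest(deg, genotypes8)
  expect_false(dout$anova_sig[dout$protein == "flat"])
  expect_true(dout$anova_sig[dout$protein == "split"])
  jit <- deg["split", ] + rnorm(8, sd = 1e-4)
  expect_true(anovaTest(rbind(j = jit), genotypes8)$anova_sig)
})

test_that("signed fold changes follow the mutant-over-wild-type convention", {
  x <- rbind(up = rep(c(2, 49), each = 4),
             down = rep(c(27.5, 2), each = 4),
             flat = rep(3, 8))
  colnames(x) <- names(genotypes8)
  fc <- foldChange(x, genotypes8)
  expect_equal(fc$fold_change[fc$protein == "up"], 24.5)
  expect_equal(fc$fold_change[fc$protein == "down"], -13.75)
  expect_equal(fc$fold_change[fc$protein == "flat"], 1)
  expect_true(all(abs(fc$fold_change) >= 1))
})

test_that("a planted clean 10-fold protein comes out positive and significant", {
  sim <- simulateLfq(nProteins = 40, foldChanges = c(10, rep(1, 39)),
                     sigma = 0, missingRate = 0, nonSpecificRate = 0,
                     badPeptideRate = 0, badProteinRate = 0, seed = 83)
  res <- runLfqPipeline(sim$idents, sim$peaks, sim$genotypes)
  row <- res$table[res$table$protein == "P0001", ]
  expect_true(row$significant)
  expect_equal(row$fold_change, 10, tolerance = 1e-9)
  expect_equal(sum(res$table$significant), 1L)
})

test_that("scaling one run is absorbed by normalization", {
  sim <- simulateLfq(nProteins = 60, nDiff = 5, sigma = 0.15,
                     missingRate = 0, seed = 89)
  cfg <- lfqConfig(reference = "wt_1")
  base <- runLfqPipeline(sim$idents, sim$peaks, sim$genotypes, cfg)
  scaled_peaks <- sim$peaks
  i <- scaled_peaks$sample == "mut_2"
  scaled_peaks$intensity[i] <- scaled_peaks$intensity[i] * 7.3
  scaled <- runLfqPipeline(sim$idents, scaled_peaks, sim$genotypes, cfg)
  expect_equal(scaled$table$fold_change, base$table$fold_change,
               tolerance = 1e-9)
  # scaling the reference itself rescales all runs but not the ratios
  scaled_ref <- sim$peaks
  i <- scaled_ref$sample == "wt_1"
  scaled_ref$intensity[i] <- scaled_ref$intensity[i] * 0.2
  sref <- runLfqPipeline(sim$idents, scaled_ref, sim$genotypes, cfg)
  expect_equal(sref$table$fold_change, base$table$fold_change,
               tolerance = 1e-9)
})

test_that("fraction merging flags proteins significant in both fractions", {
  t1 <- data.frame(protein = c("A", "B"), fold_change = c(3, -2),
                   kw_p = 0.01, peak_diff = 6, anova_p = 0.01,
                   significant = c(TRUE, TRUE), n_peptides = 2)
  t2 <- data.frame(protein = c("A", "C"), fold_change = c(2.5, 4),
                   kw_p = 0.01, peak_diff = 6, anova_p = 0.01,
                   significant = c(TRUE, FALSE), n_peptides = 2)
  m <- mergeFractions(list(cytosol = t1, membrane = t2))
  expect_true(all(m$shared[m$protein == "A"]))
  expect_false(any(m$shared[m$protein %in% c("B", "C")]))
})

test_that("diff tables and comma-decimal inputs round-trip through TSV", {
  tab <- data.frame(protein = "P1", fold_change = 24.504, kw_p = 0.01,
                    peak_diff = 6, anova_p = 0.001, significant = TRUE,
                    n_peptides = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDiffTable(tab, f)
  line <- readLines(f)[2]
  expect_match(line, "24\\.50")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tpeptide\tpeptide_evalue\tprotein_log10_evalue",
               "P1\tpep\t0,01\t-3,5"), g)
  idents <- readIdentTsv(g, dec = ",")
  expect_equal(idents$peptide_evalue, 0.01)
  expect_equal(idents$protein_log10_evalue, -3.5)
})
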