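# Constrained upstream scanning: planted-site recovery, positional
# constraints, oracle equivalence, strand symmetry and hit table IO.

box <- iupacConsensus("GTTYMMYMGTAAAC")

test_that("a planted exact box is found at its planted offset only", {
  sim <- simulateGenome(box,
                        plants = data.frame(gene = 3, rel_offset = -100,
                                            strand = "+"),
                        nGenes = 5, seed = 101)
  hits <- scanUpstream(sim$genome, box)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene_id, "gene003")
  expect_equal(hits$rel_position, -100L)
  expect_equal(hits$mismatches, 0L)
  expect_identical(hits$matched_seq, sim$truth$matched_seq)
  # the genomic footprint has motif width
  expect_equal(hits$genome_end0 - hits$genome_start0, 14L)

  # a box planted beyond the search window is not reported
  sim600 <- simulateGenome(box,
                           plants = data.frame(gene = 3, rel_offset = -600,
                                               strand = "+"),
                           nGenes = 5, seed = 103)
  expect_equal(nrow(scanUpstream(sim600$genome, box, maxUpstream = 500)), 0L)
  expect_equal(nrow(scanUpstream(sim600$genome, box, maxUpstream = 700)), 1L)
})

test_that("scanRegion handles literal regions, multiple boxes and N runs", {
  h <- scanRegion("GTTCAACAGTAAAC", box)
  expect_equal(nrow(h), 1L)
  expect_equal(h$rel_position, -14L)

  two <- paste0("GTTCAACAGTAAAC", strrep("T", 7), "GTTTAATCGTAAAC")
  h2 <- scanRegion(two, box)
  expect_equal(h2$rel_position, c(-35L, -14L))

  expect_equal(nrow(scanRegion(strrep("N", 60), box)), 0L)
  expect_equal(nrow(scanRegion("ACGT", box)), 0L)   # shorter than motif
})

test_that("hits equal the naive oracle across mismatch settings", {
  set.seed(71)
  for (rep in 1:5) {
    sim <- simulateGenome(box,
                          plants = data.frame(gene = c(2, 4),
                                              rel_offset = c(-60, -210),
                                              strand = c("+", "-"),
                                              mismatches = c(0, 1)),
                          nGenes = 8, geneSpacing = 900,
                          seed = 200 + rep)
    for (mm in 0:2) {
      got <- scanUpstream(sim$genome, box, maxUpstream = 400,
                          maxMismatch = mm)
      want <- oracle_scan(sim$genome, codeString(box), max_up = 400,
                          max_mm = mm)
      cols <- c("gene_id", "rel_position", "strand", "mismatches")
      expect_equal(got[, cols], want[, cols], ignore_attr = TRUE,
                   label = sprintf("rep=%d mm=%d", rep, mm))
    }
  }
})

test_that("a genome and its reverse complement give mirrored hit sets", {
  sim <- simulateGenome(box,
                        plants = data.frame(gene = c(1, 4),
                                            rel_offset = c(-44, -130),
                                            strand = c("+", "-")),
                        nGenes = 6, seed = 301)
  g <- genes(sim$genome)
  L <- nchar(as.character(contigs(sim$genome)[[1]]))
  mirrored <- data.frame(
    gene_id = g$gene_id, contig = g$contig,
    strand = ifelse(g$strand == "+", "-", "+"),
    start0 = L - g$end0, end0 = L - g$start0)
  mirrored$tstart0 <- ifelse(mirrored$strand == "+", mirrored$start0,
                             mirrored$end0 - 1L)
  rc_genome <- annotatedGenome(
    c(contig1 = revComp(as.character(contigs(sim$genome)[[1]]))), mirrored)
  a <- scanUpstream(sim$genome, box)
  b <- scanUpstream(rc_genome, box)
  cols <- c("gene_id", "rel_position", "strand", "matched_seq", "mismatches")
  expect_equal(a[, cols], b[, cols], ignore_attr = TRUE)
})

test_that("palindromic consensus matches are deduplicated to one forward hit", {
  pal <- iupacConsensus("GTTTAAAC")      # self reverse-complementary
  region <- paste0(strrep("C", 20), "GTTTAAAC", strrep("C", 20))
  before <- scanRegion(region, pal, deduplicate = FALSE)
  after <- scanRegion(region, pal)
  expect_equal(nrow(before), 2L)
  expect_setequal(before$strand, c("+", "-"))
  expect_equal(length(unique(before$rel_position)), 1L)
  expect_equal(nrow(after), 1L)
  expect_equal(after$strand, "+")
})

test_that("promoter-interval restriction keeps only contained hits", {
  sim <- simulateGenome(box,
                        plants = data.frame(gene = c(2, 5),
                                            rel_offset = c(-50, -50),
                                            strand = "+"),
                        nGenes = 6, seed = 401)
  all_hits <- scanUpstream(sim$genome, box)
  expect_equal(nrow(all_hits), 2L)
  keep <- all_hits[1, ]
  prom <- GenomicRanges::GRanges(
    keep$contig,
    IRanges::IRanges(start = keep$genome_start0 - 10L,
                     end = keep$genome_end0 + 10L))
  restricted <- scanUpstream(sim$genome, box, promoters = prom)
  expect_equal(restricted$gene_id, keep$gene_id)
})

test_that("PWM-mode scanning thresholds on the log-odds score", {
  sites <- c("GTTCAACAGTAAAC", "GTTTAATCGTAAAC", "GTTCAATAGTAAAC",
             "GTTTACCCGTAAAC")
  pwm <- pwmFromSites(sites, alpha = 0.1)
  region <- paste0(strrep("A", 30), "GTTCAACAGTAAAC", strrep("G", 30))
  strong <- scanRegion(region, pwm, pwmScoreMin = 10)
  expect_equal(nrow(strong), 1L)
  expect_equal(strong$rel_position, -44L)
  expect_true(strong$pwm_score > 10)
  expect_error(scanRegion(region, pwm), "pwmScoreMin")
  # an absurd threshold removes everything
  expect_equal(nrow(scanRegion(region, pwm, pwmScoreMin = 1e6)), 0L)
})

test_that("hit tables survive a TSV round-trip and export valid BED", {
  sim <- simulateGenome(box,
                        plants = data.frame(gene = c(1, 2),
                                            rel_offset = c(-20, -313),
                                            strand = c("-", "+")),
                        nGenes = 4, seed = 501)
  hits <- scanUpstream(sim$genome, box)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeHits(hits, tsv, bed = bed)
  back <- readHits(tsv)
  expect_equal(back, hits, ignore_attr = TRUE)
  bedtab <- read.table(bed, sep = "\t")
  expect_equal(bedtab$V3 - bedtab$V2, rep(14L, nrow(bedtab)))

  empty <- scanUpstream(simulateGenome(box, nGenes = 2, seed = 7)$genome, box)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeHits(empty, tsv2)
  expect_equal(nrow(readHits(tsv2)), 0L)
})
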