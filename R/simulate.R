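# Simulators with known truth: planted-operator genomes for the scanning
# stack and peptide-intensity datasets for the LFQ stack. Every generator
# draws from its own seeded stream and leaves the caller's RNG untouched,
# so identical seeds give identical outputs.

# one random realization of a degenerate consensus, with exactly
# `mismatches` positions forced outside their code's base set
.realize_site <- function(motif, mismatches = 0L) {
  if (is(motif, "MotifPWM")) {
    if (mismatches > 0L)
      stop("mismatch planting is defined for consensus motifs only",
           call. = FALSE)
    p <- motif@probs
    return(paste(vapply(seq_len(nrow(p)), function(i)
      sample(DNA_BASES, 1L, prob = p[i, ]), character(1)), collapse = ""))
  }
  code <- .chars(codeString(motif))
  site <- vapply(code, function(cd) {
    s <- IUPAC_SETS[[cd]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1), USE.NAMES = FALSE)
  if (mismatches > 0L) {
    cand <- which(vapply(code, function(cd)
      length(IUPAC_SETS[[cd]]) < 4L, logical(1)))
    if (length(cand) < mismatches)
      stop("cannot introduce ", mismatches, " mismatch(es): only ",
           length(cand), " non-N position(s)", call. = FALSE)
    pos <- if (length(cand) == 1L) cand else sample(cand, mismatches)
    for (i in pos) {
      off <- setdiff(DNA_BASES, IUPAC_SETS[[code[i]]])
      site[i] <- if (length(off) == 1L) off else sample(off, 1L)
    }
  }
  paste(site, collapse = "")
}

#' Simulate a bacterial genome with operator boxes planted upstream of genes
#'
#' Generates one contig of iid background sequence at the requested GC
#' content, lays `nGenes` single-CDS gene models on alternating strands
#' (one per `geneSpacing` bp, CDS of `cdsLength` bp, leaving room for a
#' full upstream window), and writes one motif realization per row of
#' `plants` into the corresponding gene's upstream region.
#'
#' @param motif An [IUPACConsensus-class] (or [MotifPWM-class];
#'   mismatch planting then unavailable).
#' @param plants `data.frame` with columns `gene` (index into the gene
#'   list), `rel_offset` (start-relative offset of the site's 5' end on
#'   the coding strand; at most `-width(motif)`), `strand` (site strand
#'   relative to the coding strand) and optionally `mismatches`
#'   (default 0). May have zero rows.
#' @param nGenes Number of genes (default 20).
#' @param geneSpacing bp of contig per gene (default 1000; must leave
#'   >= 500 bp upstream of each CDS).
#' @param cdsLength CDS length in bp (default 300).
#' @param gcContent Background GC fraction (default 0.435, a typical
#'   Firmicute value).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A list: `genome` ([AnnotatedGenome-class]) and `truth`
#'   (`data.frame` of planted sites in scan-hit coordinates: `gene_id`,
#'   `rel_position`, `strand`, `matched_seq`, `mismatches`,
#'   `genome_start0`, `genome_end0`).
#' @export
simulateGenome <- function(motif, plants = data.frame(), nGenes = 20L,
                           geneSpacing = 1000L, cdsLength = 300L,
                           gcContent = 0.435, seed = 1L) {
  stopifnot(nGenes >= 1L, gcContent > 0, gcContent < 1)
  w <- width(motif)
  if (geneSpacing < cdsLength + w + 50L)
    stop("geneSpacing too small for cdsLength and motif", call. = FALSE)
  if (nrow(plants) > 0L) {
    if (!"mismatches" %in% names(plants)) plants$mismatches <- 0L
    stopifnot(all(c("gene", "rel_offset", "strand") %in% names(plants)),
              all(plants$strand %in% c("+", "-")),
              all(plants$gene %in% seq_len(nGenes)))
    if (any(plants$rel_offset > -w))
      stop("planted site must lie entirely upstream: rel_offset <= -width",
           call. = FALSE)
  }
  contigLength <- nGenes * geneSpacing + 100L

  with_seed(seed, {
    probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
               G = gcContent / 2, T = (1 - gcContent) / 2)
    chars <- sample(DNA_BASES, contigLength, replace = TRUE, prob = probs)

    strand <- rep(c("+", "-"), length.out = nGenes)
    a <- (seq_len(nGenes) - 1L) * geneSpacing + 50L       # slot starts, 0-based
    start0 <- ifelse(strand == "+", a + geneSpacing - cdsLength, a)
    end0 <- start0 + cdsLength
    genes <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(nGenes)),
      contig = "contig1", strand = strand,
      start0 = as.integer(start0), end0 = as.integer(end0),
      tstart0 = as.integer(ifelse(strand == "+", start0, end0 - 1L)),
      stringsAsFactors = FALSE)

    truth <- NULL
    if (nrow(plants) > 0L) {
      spans <- matrix(NA_integer_, nrow(plants), 2L)
      for (i in seq_len(nrow(plants))) {
        g <- genes[plants$gene[i], ]
        rel <- as.integer(plants$rel_offset[i])
        site <- .realize_site(motif, plants$mismatches[i])
        if (g$strand == "+") {
          g0 <- g$tstart0 + rel
          ins <- if (plants$strand[i] == "+") site else revComp(site)
        } else {
          g0 <- g$tstart0 - rel - w + 1L
          ins <- if (plants$strand[i] == "+") revComp(site) else site
        }
        if (g0 < 0L || g0 + w > contigLength)
          stop("planted site outside contig (gene ", g$gene_id, ")",
               call. = FALSE)
        if (any(!is.na(spans[, 1L]) & g0 < spans[, 2L] & g0 + w > spans[, 1L]))
          stop("overlapping planted sites", call. = FALSE)
        spans[i, ] <- c(g0, g0 + w)
        chars[(g0 + 1L):(g0 + w)] <- .chars(ins)
        truth <- rbind(truth, data.frame(
          gene_id = g$gene_id, rel_position = rel,
          strand = plants$strand[i], matched_seq = site,
          mismatches = as.integer(plants$mismatches[i]),
          genome_start0 = g0, genome_end0 = g0 + w,
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(truth))
      truth <- data.frame(gene_id = character(), rel_position = integer(),
                          strand = character(), matched_seq = character(),
                          mismatches = integer(), genome_start0 = integer(),
                          genome_end0 = integer(), stringsAsFactors = FALSE)
    genome <- annotatedGenome(c(contig1 = paste(chars, collapse = "")), genes)
    list(genome = genome, truth = truth)
  })
}

#' Write a simulated genome to FASTA + GFF3 + truth TSV
#'
#' @param sim Result of [simulateGenome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSimulatedGenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fasta"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth_sites.tsv"))
  writeGenomeFasta(contigs(sim$genome), paths[["fasta"]])
  writeGeneModels(genes(sim$genome), paths[["gff"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Simulate a peptide-quantification dataset with planted fold changes
#'
#' Emulates a 2-genotype x `nReplicates` label-free experiment. Each
#' protein gets a lognormal base intensity and 3-6 peptides with their own
#' multiplicative efficiencies; a planted signed fold change multiplies
#' the mutant samples (a fold of -x divides them by x); per-sample scale
#' factors mimic run-to-run global intensity drift; lognormal noise of
#' standard deviation `sigma` (natural-log scale) is applied per cell;
#' cells go missing independently at `missingRate`. Peak counts per
#' peptide x sample are 1 + Poisson(`peakBase` - 1); each present cell of a
#' planted-differential protein additionally receives `peakShift` extra
#' peaks in the higher-abundance genotype, so the protein-level count
#' difference clears the 5-peak rule even after peptide filtering. A small
#' fraction of peptides is non-specific, carries a failing E-value, or
#' belongs to a protein with a failing identification score, exercising
#' the pipeline's filters; a few junk peak rows with excessive width or
#' retention-time drift are added on top.
#'
#' @param nProteins Number of proteins (default 500).
#' @param nDiff Number of planted differential proteins (default 30),
#'   ignored when `foldChanges` is given.
#' @param foldRange Magnitude range of planted signed folds (default
#'   c(6, 25)); signs alternate.
#' @param foldChanges Optional full specification: numeric vector of
#'   signed folds, length `nProteins` (+1 for null proteins).
#' @param peptideRange Range of peptides per protein (default c(3, 6)).
#' @param nReplicates Replicates per genotype (default 4; 8 samples).
#' @param sigma Lognormal noise SD on the natural-log scale
#'   (default 0.2, i.e. ~20% CV).
#' @param missingRate Independent missingness per peptide x sample
#'   (default 0.1; must be < 1).
#' @param scaleRange Per-sample scale-factor range (default c(0.5, 2)).
#' @param nonSpecificRate Fraction of peptides flagged non-specific
#'   (default 0.05).
#' @param badPeptideRate Fraction of peptides with E-value >= 0.05
#'   (default 0.03).
#' @param badProteinRate Fraction of proteins with log10 E-value >= -2.6
#'   (default 0.02).
#' @param junkPeakRate Fraction of cells receiving an extra
#'   quality-failing peak row (default 0.05).
#' @param peakBase Mean peaks per peptide x sample (default 2).
#' @param peakShift Extra peaks per peptide cell in the higher genotype of
#'   a differential protein (default 4).
#' @param seed Integer seed.
#' @return A list: `idents`, `peaks` (long tables as consumed by
#'   [runLfqPipeline()]), `truth` (`protein`, `signed_fold`,
#'   `differential`) and `genotypes` (the named sample map).
#' @export
simulateLfq <- function(nProteins = 500L, nDiff = 30L, foldRange = c(6, 25),
                        foldChanges = NULL, peptideRange = c(3L, 6L),
                        nReplicates = 4L, sigma = 0.2, missingRate = 0.1,
                        scaleRange = c(0.5, 2), nonSpecificRate = 0.05,
                        badPeptideRate = 0.03, badProteinRate = 0.02,
                        junkPeakRate = 0.05, peakBase = 2L, peakShift = 4L,
                        seed = 1L) {
  if (missingRate >= 1 || missingRate < 0)
    stop("missingRate must be in [0, 1)", call. = FALSE)
  stopifnot(nReplicates >= 2L, sigma >= 0, all(scaleRange > 0))
  samples <- c(sprintf("wt_%d", seq_len(nReplicates)),
               sprintf("mut_%d", seq_len(nReplicates)))
  genotypes <- stats::setNames(rep(c("wt", "mutant"), each = nReplicates),
                               samples)
  ns <- length(samples)
  is_mut <- unname(genotypes) == "mutant"

  with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(nProteins))
    if (is.null(foldChanges)) {
      foldChanges <- rep(1, nProteins)
      if (nDiff > 0L) {
        idx <- sort(sample.int(nProteins, nDiff))
        mag <- stats::runif(nDiff, foldRange[1L], foldRange[2L])
        sgn <- rep(c(1, -1), length.out = nDiff)
        foldChanges[idx] <- sgn * mag
      }
    } else stopifnot(length(foldChanges) == nProteins)
    mult <- ifelse(foldChanges > 0, foldChanges, -1 / foldChanges)

    scale_s <- stats::runif(ns, scaleRange[1L], scaleRange[2L])
    npep <- if (peptideRange[1L] == peptideRange[2L])
      rep(peptideRange[1L], nProteins) else
      sample(peptideRange[1L]:peptideRange[2L], nProteins, replace = TRUE)
    base_p <- 10^stats::runif(nProteins, 5.5, 7)
    bad_prot <- stats::runif(nProteins) < badProteinRate

    peaks_list <- vector("list", nProteins)
    ident_list <- vector("list", nProteins)
    for (i in seq_len(nProteins)) {
      k <- npep[i]
      peps <- sprintf("%s_pep%02d", proteins[i], seq_len(k))
      eff <- 10^stats::runif(k, -0.5, 0.5)
      noise <- if (sigma > 0) exp(matrix(stats::rnorm(k * ns, 0, sigma),
                                         k, ns)) else matrix(1, k, ns)
      inten <- (base_p[i] * eff) %o% (scale_s * ifelse(is_mut, mult[i], 1)) *
        noise
      present <- matrix(stats::runif(k * ns) >= missingRate, k, ns)
      # per-cell peak counts; planted proteins gain peaks on their high side
      cnt <- matrix(1L + stats::rpois(k * ns, max(peakBase - 1L, 0L)), k, ns)
      cnt[!present] <- 0L
      if (abs(foldChanges[i]) > 1) {
        # every present cell of the higher-abundance genotype gains
        # peakShift peaks, so the protein-level difference survives even
        # if some peptides are later filtered out
        high <- if (foldChanges[i] > 0) is_mut else !is_mut
        cnt[, high] <- cnt[, high] + ifelse(present[, high], peakShift, 0L)
      }
      specific <- stats::runif(k) >= nonSpecificRate
      bad_pep <- stats::runif(k) < badPeptideRate
      pep_e <- 10^stats::runif(k, -4, -1.35)
      pep_e[bad_pep] <- stats::runif(sum(bad_pep), 0.06, 0.3)
      prot_log10e <- if (bad_prot[i]) stats::runif(1, -2.5, -1) else
        stats::runif(1, -8, -3)

      cells <- which(present, arr.ind = TRUE)
      if (nrow(cells) == 0L) next
      nrows <- cnt[cells]
      cell_int <- inten[cells]
      row_pe <- rep.int(cells[, 1L], nrows)
      row_s <- rep.int(cells[, 2L], nrows)
      row_int <- rep.int(cell_int / nrows, nrows)
      df <- data.frame(
        peptide = peps[row_pe], protein = proteins[i],
        sample = samples[row_s], intensity = row_int,
        peak_width = stats::runif(length(row_int), 30, 95),
        rt_sd = stats::runif(length(row_int), 0.5, 15),
        specific = specific[row_pe], stringsAsFactors = FALSE)
      junk <- which(stats::runif(nrow(cells)) < junkPeakRate)
      if (length(junk) > 0L) {
        jdf <- data.frame(
          peptide = peps[cells[junk, 1L]], protein = proteins[i],
          sample = samples[cells[junk, 2L]],
          intensity = 0.2 * cell_int[junk],
          peak_width = stats::runif(length(junk), 110, 250),
          rt_sd = stats::runif(length(junk), 25, 60),
          specific = specific[cells[junk, 1L]], stringsAsFactors = FALSE)
        df <- rbind(df, jdf)
      }
      peaks_list[[i]] <- df
      ident_list[[i]] <- data.frame(
        protein = proteins[i], peptide = peps,
        peptide_evalue = pep_e, protein_log10_evalue = prot_log10e,
        stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, peaks_list)
    idents <- do.call(rbind, ident_list)
    rownames(peaks) <- rownames(idents) <- NULL
    truth <- data.frame(protein = proteins, signed_fold = foldChanges,
                        differential = abs(foldChanges) > 1,
                        stringsAsFactors = FALSE)
    list(idents = idents, peaks = peaks, truth = truth,
         genotypes = genotypes)
  })
}

#' Write a simulated LFQ dataset to TSV files
#'
#' @param sim Result of [simulateLfq()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSimulatedLfq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(idents = file.path(dir, "identifications.tsv"),
             peaks = file.path(dir, "peaks.tsv"),
             truth = file.path(dir, "truth_folds.tsv"))
  for (nm in c("idents", "peaks", "truth"))
    utils::write.table(sim[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}
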