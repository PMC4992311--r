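# Label-free quantification workflow: identification filtering, peak
# quality filtering, selection of specific/repeatable peptides, imputation,
# median-ratio run normalisation, protein roll-up, Kruskal-Wallis
# peak-count and one-way ANOVA testing, and the signed fold-change table.
#
# Data model: a long "peaks" table carries one row per detected
# chromatographic peak (peptide x sample x peak); per peptide x sample the
# intensities are summed and the number of peak rows is the peak count.
# The quantification container is a SummarizedExperiment with peptides as
# rows, samples as columns and assays `intensity`, `observed`, `peaks`.

#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
NULL

.check_genotypes <- function(genotypes) {
  if (is.null(names(genotypes)) || any(names(genotypes) == ""))
    stop("genotypes must be a named vector (names = sample ids)",
         call. = FALSE)
  if (!all(genotypes %in% c("wt", "mutant")))
    stop("genotype values must be 'wt' or 'mutant'", call. = FALSE)
  if (min(table(factor(genotypes, levels = c("wt", "mutant")))) < 2L)
    stop("need >= 2 samples per genotype", call. = FALSE)
  genotypes
}

#' Filter protein identifications
#'
#' A peptide record is kept when its E-value is below `peptideEMax`; a
#' protein is kept when its log10 E-value is below `proteinLog10Max` and at
#' least `minPeptides` distinct peptide sequences survive the peptide-level
#' filter. Peptide filtering is applied first, so a protein supported only
#' by poor peptides is dropped.
#'
#' @param idents `data.frame` with columns `protein`, `peptide`,
#'   `peptide_evalue`, `protein_log10_evalue`.
#' @param proteinLog10Max Protein log10 E-value threshold (default -2.6,
#'   strict `<`).
#' @param minPeptides Minimum distinct surviving peptides per protein
#'   (default 2).
#' @param peptideEMax Peptide E-value threshold (default 0.05, strict `<`).
#' @return The retained records.
#' @export
filterIdentifications <- function(idents, proteinLog10Max = -2.6,
                                  minPeptides = 2L, peptideEMax = 0.05) {
  stopifnot(all(c("protein", "peptide", "peptide_evalue",
                  "protein_log10_evalue") %in% names(idents)))
  if (any(idents$peptide_evalue <= 0))
    stop("peptide E-values must be > 0", call. = FALSE)
  keep <- idents[idents$peptide_evalue < peptideEMax &
                 idents$protein_log10_evalue < proteinLog10Max, ,
                 drop = FALSE]
  npep <- tapply(keep$peptide, keep$protein,
                 function(p) length(unique(p)))
  ok <- names(npep)[npep >= minPeptides]
  out <- keep[keep$protein %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter chromatographic peaks on width and retention-time stability
#'
#' A peak is removed iff its width exceeds `widthMax` or its retention-time
#' standard deviation exceeds `rtSdMax` (strict inequalities: a peak at
#' exactly the threshold is kept).
#'
#' @param peaks Long peak table with columns `peak_width` and `rt_sd`
#'   (seconds).
#' @param widthMax Width cutoff in seconds (default 100).
#' @param rtSdMax RT standard-deviation cutoff in seconds (default 20).
#' @return The retained rows.
#' @export
filterPeaks <- function(peaks, widthMax = 100, rtSdMax = 20) {
  stopifnot(all(c("peak_width", "rt_sd") %in% names(peaks)))
  if (any(peaks$peak_width < 0) || any(peaks$rt_sd < 0))
    stop("peak_width and rt_sd must be >= 0", call. = FALSE)
  out <- peaks[!(peaks$peak_width > widthMax | peaks$rt_sd > rtSdMax), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a peptide-level quantification matrix
#'
#' Collapses a long peak table to one row per peptide and one column per
#' sample: intensities summed over a peptide's peaks in a sample, and the
#' number of peak rows kept as that cell's peak count.
#'
#' @param peaks Long table with columns `peptide`, `protein`, `sample`,
#'   `intensity`, `specific` (logical).
#' @param genotypes Named character vector mapping every sample id to
#'   `"wt"` or `"mutant"` (2 genotypes x >= 2 replicates; the default
#'   design is 2 x 4 = 8 samples).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `intensity` (NA where unobserved), `observed` and `peaks`; rowData
#'   `peptide`, `protein`, `specific`; colData `genotype`.
#' @export
peptideQuant <- function(peaks, genotypes) {
  genotypes <- .check_genotypes(genotypes)
  need <- c("peptide", "protein", "sample", "intensity", "specific")
  stopifnot(all(need %in% names(peaks)))
  samples <- names(genotypes)
  unknown <- setdiff(unique(peaks$sample), samples)
  if (length(unknown) > 0L)
    stop("sample(s) not in genotype map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(samples, unique(peaks$sample))
  if (length(absent) > 0L)
    stop("sample '", absent[1L], "' has no observations", call. = FALSE)
  if (any(peaks$intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0", call. = FALSE)

  pep_meta <- unique(peaks[, c("peptide", "protein", "specific")])
  if (anyDuplicated(pep_meta$peptide))
    stop("peptide mapped to more than one protein/specificity; ",
         "shared peptides must carry specific = FALSE under one id",
         call. = FALSE)
  pep_meta <- pep_meta[order(pep_meta$protein, pep_meta$peptide), ,
                       drop = FALSE]
  np <- nrow(pep_meta)
  ri <- match(peaks$peptide, pep_meta$peptide)
  ci <- match(peaks$sample, samples)
  intensity <- matrix(NA_real_, np, length(samples),
                      dimnames = list(pep_meta$peptide, samples))
  counts <- matrix(0L, np, length(samples),
                   dimnames = list(pep_meta$peptide, samples))
  agg_sum <- tapply(peaks$intensity, list(ri, ci), sum)
  agg_n <- tapply(peaks$intensity, list(ri, ci), length)
  rr <- as.integer(rownames(agg_sum)); cc <- as.integer(colnames(agg_sum))
  intensity[rr, cc] <- agg_sum
  cn <- agg_n; cn[is.na(cn)] <- 0L
  counts[rr, cc] <- as.integer(cn)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity, observed = !is.na(intensity),
                  peaks = counts),
    rowData = S4Vectors::DataFrame(peptide = pep_meta$peptide,
                                   protein = pep_meta$protein,
                                   specific = pep_meta$specific),
    colData = S4Vectors::DataFrame(sample = samples,
                                   genotype = unname(genotypes),
                                   row.names = samples))
}

#' Keep specific, repeatable peptides and quantifiable proteins
#'
#' Retains peptides that map to a single protein (`specific`) and were
#' observed in at least `minPresent` of the samples, then drops proteins
#' left with fewer than two such peptides.
#'
#' @param se Peptide-level [SummarizedExperiment::SummarizedExperiment]
#'   from [peptideQuant()].
#' @param requireSpecific Discard non-specific peptides (default TRUE).
#' @param minPresent Minimum samples with an observation (default 7, of
#'   the 8-sample design).
#' @return The filtered SummarizedExperiment.
#' @export
selectPeptides <- function(se, requireSpecific = TRUE, minPresent = 7L) {
  obs <- SummarizedExperiment::assay(se, "observed")
  rd <- SummarizedExperiment::rowData(se)
  keep <- rowSums(obs) >= minPresent
  if (requireSpecific) keep <- keep & rd$specific
  se <- se[keep, ]
  rd <- SummarizedExperiment::rowData(se)
  npep <- table(rd$protein)
  se[rd$protein %in% names(npep)[npep >= 2L], ]
}

#' Impute missing peptide intensities from sibling peptides
#'
#' For each peptide with missing cells, the covariate at sample `s` is the
#' mean intensity of the protein's other peptides observed at `s`. An
#' ordinary least-squares line of the peptide's observed intensities on
#' this covariate is fitted and evaluated at each missing sample. A
#' missing cell whose covariate is unavailable, or a peptide with fewer
#' than two usable fitting points, cannot be predicted: the peptide is
#' dropped with a warning. When the covariate is constant across the
#' fitted samples the peptide's observed mean is used instead.
#'
#' @param se Peptide-level SummarizedExperiment (after
#'   [selectPeptides()]).
#' @return The SummarizedExperiment with `intensity` completed; the
#'   `observed` assay still marks which cells were measured.
#' @export
imputeMissing <- function(se) {
  x <- SummarizedExperiment::assay(se, "intensity")
  obs <- SummarizedExperiment::assay(se, "observed")
  prot <- SummarizedExperiment::rowData(se)$protein
  drop <- logical(nrow(x))
  for (p in unique(prot[rowSums(!obs) > 0L])) {
    rows <- which(prot == p)
    for (r in rows[rowSums(!obs[rows, , drop = FALSE]) > 0L]) {
      others <- setdiff(rows, r)
      if (length(others) == 0L) { drop[r] <- TRUE; next }
      xo <- x[others, , drop = FALSE]
      oo <- obs[others, , drop = FALSE]
      cov <- colSums(xo * oo, na.rm = TRUE) / colSums(oo)   # NaN if none
      fit_s <- which(obs[r, ] & is.finite(cov))
      miss_s <- which(!obs[r, ])
      if (length(fit_s) < 2L || any(!is.finite(cov[miss_s]))) {
        drop[r] <- TRUE
        next
      }
      y <- x[r, fit_s]; cv <- cov[fit_s]
      if (stats::var(cv) == 0) {
        pred <- rep(mean(y), length(miss_s))
      } else {
        b <- stats::cov(cv, y) / stats::var(cv)
        a <- mean(y) - b * mean(cv)
        pred <- a + b * cov[miss_s]
      }
      # an extrapolated line can dip below zero; intensities cannot
      x[r, miss_s] <- pmax(pred, min(y) / 100)
    }
  }
  if (any(drop)) {
    warning(sum(drop), " peptide(s) dropped: missing cells not predictable ",
            "from sibling peptides (",
            paste(utils::head(rownames(x)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "", ")", call. = FALSE)
  }
  SummarizedExperiment::assay(se, "intensity") <- x
  se <- se[!drop, ]
  # dropping peptides can leave a protein below the 2-peptide floor
  rd <- SummarizedExperiment::rowData(se)
  npep <- table(rd$protein)
  se[rd$protein %in% names(npep)[npep >= 2L], ]
}

#' Median-ratio normalisation against a reference run
#'
#' Per sample `s` the factor is the median, over peptides measured (before
#' imputation) in both `s` and the reference run, of the intensity ratio
#' to the reference; every intensity in `s` (including imputed cells) is
#' divided by it. The reference's own factor is exactly 1.
#'
#' @param se Peptide-level SummarizedExperiment (complete intensities).
#' @param reference Reference sample id; by default the sample whose total
#'   observed intensity is closest to the median of sample totals (ties:
#'   first in column order).
#' @return The SummarizedExperiment with normalised intensities; the
#'   factors and reference are stored in `metadata(se)$norm_factors` /
#'   `$reference`.
#' @export
normalizeRuns <- function(se, reference = NULL) {
  x <- SummarizedExperiment::assay(se, "intensity")
  obs <- SummarizedExperiment::assay(se, "observed")
  if (is.null(reference)) {
    totals <- colSums(x * obs)
    reference <- colnames(x)[which.min(abs(totals - stats::median(totals)))]
  }
  if (!reference %in% colnames(x))
    stop("unknown reference sample: ", reference, call. = FALSE)
  f <- vapply(colnames(x), function(s) {
    if (s == reference) return(1)
    shared <- obs[, s] & obs[, reference]
    if (!any(shared))
      stop("no peptides shared between '", s, "' and the reference",
           call. = FALSE)
    stats::median(x[shared, s] / x[shared, reference])
  }, numeric(1))
  SummarizedExperiment::assay(se, "intensity") <-
    sweep(x, 2L, f, "/")
  S4Vectors::metadata(se)$norm_factors <- f
  S4Vectors::metadata(se)$reference <- reference
  se
}

#' Roll peptides up to protein abundances
#'
#' A protein's value in a sample is the sum of its retained peptides'
#' normalised intensities; peak counts are summed the same way.
#'
#' @param se Peptide-level SummarizedExperiment.
#' @return A protein-level SummarizedExperiment with assays `abundance`
#'   and `peaks`, rowData `protein` and `n_peptides`.
#' @export
proteinRollup <- function(se) {
  x <- SummarizedExperiment::assay(se, "intensity")
  pk <- SummarizedExperiment::assay(se, "peaks")
  prot <- SummarizedExperiment::rowData(se)$protein
  ab <- rowsum(x, prot)
  pks <- rowsum(pk, prot)
  npep <- as.integer(table(prot)[rownames(ab)])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab, peaks = pks),
    rowData = S4Vectors::DataFrame(protein = rownames(ab),
                                   n_peptides = npep,
                                   row.names = rownames(ab)),
    colData = SummarizedExperiment::colData(se),
    metadata = S4Vectors::metadata(se))
}

.kw_p <- function(values, grp) {
  if (length(unique(values)) == 1L) return(1)
  stats::kruskal.test(values, grp)$p.value
}

#' Kruskal-Wallis test on per-protein peak counts
#'
#' A protein passes when the Kruskal-Wallis p-value across the two
#' genotypes is below `alpha` and the absolute difference of per-genotype
#' mean peak counts is at least `minDiff`.
#'
#' @param counts Protein x sample peak-count matrix (or a protein-level
#'   SummarizedExperiment with a `peaks` assay).
#' @param genotypes Named genotype map (see [peptideQuant()]).
#' @param minDiff Minimum |mean mutant - mean wt| peak difference
#'   (default 5).
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `protein`, `kw_p`, `peak_diff` (mutant minus
#'   wt) and `kw_pass`.
#' @export
peakCountTest <- function(counts, genotypes, minDiff = 5, alpha = 0.05) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "peaks")
  genotypes <- .check_genotypes(genotypes)
  counts <- counts[, names(genotypes), drop = FALSE]
  grp <- factor(unname(genotypes), levels = c("wt", "mutant"))
  p <- apply(counts, 1L, .kw_p, grp = grp)
  d <- rowMeans(counts[, grp == "mutant", drop = FALSE]) -
       rowMeans(counts[, grp == "wt", drop = FALSE])
  data.frame(protein = rownames(counts), kw_p = p, peak_diff = d,
             kw_pass = p < alpha & abs(d) >= minDiff,
             row.names = NULL, stringsAsFactors = FALSE)
}

.anova_p <- function(values, grp) {
  if (any(!is.finite(values))) return(NA_real_)
  mw <- tapply(values, grp, mean)
  vw <- tapply(values, grp, stats::var)
  if (all(vw < .Machine$double.eps * max(abs(values), 1)^2)) {
    # no within-group variance: groups either coincide or separate exactly
    return(if (abs(diff(mw)) == 0) 1 else 0)
  }
  stats::oneway.test(values ~ grp, var.equal = TRUE)$p.value
}

#' One-way fixed-effect ANOVA on protein abundances
#'
#' Classical equal-variance one-way ANOVA with genotype as the single
#' fixed effect; with two groups this is equivalent to the pooled
#' two-sample t-test (F = t^2). Values are tested on the scale supplied —
#' the pipeline hands in log2 abundances by default.
#'
#' @param x Protein x sample abundance matrix (or SummarizedExperiment
#'   with an `abundance` assay).
#' @param genotypes Named genotype map.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `protein`, `anova_p`, `anova_sig`.
#' @export
anovaTest <- function(x, genotypes, alpha = 0.05) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "abundance")
  genotypes <- .check_genotypes(genotypes)
  x <- x[, names(genotypes), drop = FALSE]
  grp <- factor(unname(genotypes), levels = c("wt", "mutant"))
  p <- apply(x, 1L, .anova_p, grp = grp)
  data.frame(protein = rownames(x), anova_p = p,
             anova_sig = !is.na(p) & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed fold changes between mutant and wild type
#'
#' With `r = mean(mutant) / mean(wt)`, the signed fold change is `+r` when
#' `r >= 1` and `-1/r` otherwise, so a protein 13.75-fold lower in the
#' mutant is reported as -13.75. Magnitudes are always >= 1.
#'
#' @param x Protein x sample abundance matrix (or SummarizedExperiment
#'   with an `abundance` assay).
#' @param genotypes Named genotype map.
#' @return `data.frame` with `protein`, `mean_wt`, `mean_mutant` and
#'   `fold_change` (signed, unrounded; round to 2 decimals for reports).
#' @export
foldChange <- function(x, genotypes) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "abundance")
  genotypes <- .check_genotypes(genotypes)
  x <- x[, names(genotypes), drop = FALSE]
  grp <- factor(unname(genotypes), levels = c("wt", "mutant"))
  mw <- rowMeans(x[, grp == "wt", drop = FALSE])
  mm <- rowMeans(x[, grp == "mutant", drop = FALSE])
  r <- mm / mw
  data.frame(protein = rownames(x), mean_wt = mw, mean_mutant = mm,
             fold_change = ifelse(r >= 1, r, -1 / r),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Configuration for the LFQ pipeline
#'
#' Defaults are the workflow's standard thresholds: protein log10 E-value
#' < -2.6 with >= 2 peptides of E-value < 0.05; peak width <= 100 s and RT
#' standard deviation <= 20 s; specific peptides present in >= 7 of 8
#' samples; a minimum 5-peak difference with Kruskal-Wallis and one-way
#' ANOVA both at alpha = 0.05.
#'
#' @param proteinLog10Max,minPeptides,peptideEMax See
#'   [filterIdentifications()].
#' @param widthMax,rtSdMax See [filterPeaks()].
#' @param requireSpecific,minPresent See [selectPeptides()].
#' @param reference See [normalizeRuns()].
#' @param minPeakDiff,alpha See [peakCountTest()] / [anovaTest()].
#' @param peakRule Require the peak-count criterion in the final call
#'   (default TRUE); when FALSE the ANOVA alone decides.
#' @param logTransform Run the ANOVA on log2 abundances (default TRUE).
#' @return A named list of settings.
#' @export
lfqConfig <- function(proteinLog10Max = -2.6, minPeptides = 2L,
                      peptideEMax = 0.05, widthMax = 100, rtSdMax = 20,
                      requireSpecific = TRUE, minPresent = 7L,
                      reference = NULL, minPeakDiff = 5, alpha = 0.05,
                      peakRule = TRUE, logTransform = TRUE) {
  as.list(environment())
}

#' Run the full label-free differential-abundance pipeline
#'
#' Stages, in order: identification filtering, peak filtering, peptide
#' quantification, peptide selection, imputation, run normalisation,
#' protein roll-up, Kruskal-Wallis peak-count test and one-way ANOVA,
#' signed fold change. A protein is called differential when the ANOVA is
#' significant and (with `peakRule`) the peak-count criterion holds.
#'
#' @param idents Identification table (see [filterIdentifications()]).
#' @param peaks Long peak table (see [peptideQuant()]; also needs
#'   `peak_width` and `rt_sd`).
#' @param genotypes Named genotype map, e.g.
#'   `c(wt_1 = "wt", ..., mut_4 = "mutant")`.
#' @param config Settings from [lfqConfig()].
#' @return A list: `table` (per-protein results: `protein`, `fold_change`,
#'   `kw_p`, `peak_diff`, `anova_p`, `significant`, `n_peptides`), `se`
#'   (protein-level SummarizedExperiment) and `peptides` (the normalised
#'   peptide-level SummarizedExperiment).
#' @export
runLfqPipeline <- function(idents, peaks, genotypes, config = lfqConfig()) {
  genotypes <- .check_genotypes(genotypes)
  idents <- filterIdentifications(idents,
                                  proteinLog10Max = config$proteinLog10Max,
                                  minPeptides = config$minPeptides,
                                  peptideEMax = config$peptideEMax)
  keys <- paste(idents$protein, idents$peptide, sep = "\r")
  peaks <- peaks[paste(peaks$protein, peaks$peptide, sep = "\r") %in% keys, ,
                 drop = FALSE]
  peaks <- filterPeaks(peaks, widthMax = config$widthMax,
                       rtSdMax = config$rtSdMax)
  se <- peptideQuant(peaks, genotypes)
  se <- selectPeptides(se, requireSpecific = config$requireSpecific,
                       minPresent = config$minPresent)
  se <- imputeMissing(se)
  se <- normalizeRuns(se, reference = config$reference)
  pse <- proteinRollup(se)
  ab <- SummarizedExperiment::assay(pse, "abundance")
  kw <- peakCountTest(pse, genotypes, minDiff = config$minPeakDiff,
                      alpha = config$alpha)
  av <- anovaTest(if (config$logTransform) log2(ab) else ab, genotypes,
                  alpha = config$alpha)
  fc <- foldChange(pse, genotypes)
  tab <- data.frame(protein = fc$protein,
                    fold_change = fc$fold_change,
                    kw_p = kw$kw_p, peak_diff = kw$peak_diff,
                    anova_p = av$anova_p,
                    significant = av$anova_sig &
                      (if (config$peakRule) kw$kw_pass else TRUE),
                    n_peptides = SummarizedExperiment::rowData(pse)$n_peptides,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-sign(tab$fold_change), -abs(tab$fold_change)), ]
  rownames(tab) <- NULL
  list(table = tab, se = pse, peptides = se)
}

#' Merge the differential tables of two fractions
#'
#' Cytosolic and membrane fractions are analysed as two independent
#' pipeline runs; this joins their result tables and flags proteins found
#' (significant) in both.
#'
#' @param tables Named list of result tables (the `table` element of
#'   [runLfqPipeline()] output), e.g. `list(cytosol = ..., membrane = ...)`.
#' @return One table with extra columns `fraction` and `shared`
#'   (significant in more than one fraction).
#' @export
mergeFractions <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  out <- do.call(rbind, lapply(names(tables), function(nm)
    cbind(tables[[nm]], fraction = nm, stringsAsFactors = FALSE)))
  sig <- out[out$significant, , drop = FALSE]
  shared <- names(which(table(unique(sig[, c("protein", "fraction")])$protein) > 1L))
  out$shared <- out$protein %in% shared
  rownames(out) <- NULL
  out
}

#' Read identification and peak tables from TSV
#'
#' `dec = ","` accepts European comma-decimal numbers.
#'
#' @param path Input TSV with a header row.
#' @param dec Decimal separator (default `"."`).
#' @return A `data.frame`.
#' @export
readIdentTsv <- function(path, dec = ".") {
  utils::read.table(path, sep = "\t", header = TRUE, dec = dec,
                    stringsAsFactors = FALSE)
}

#' @rdname readIdentTsv
#' @export
readPeaksTsv <- function(path, dec = ".") {
  out <- utils::read.table(path, sep = "\t", header = TRUE, dec = dec,
                           stringsAsFactors = FALSE)
  if ("specific" %in% names(out)) out$specific <- as.logical(out$specific)
  out
}

#' Write the differential-protein table as TSV
#'
#' Fold changes and p-values are rounded for the report (2 decimals for
#' the signed fold change); the full-precision table is what
#' [runLfqPipeline()] returns.
#'
#' @param table Result table from [runLfqPipeline()] or
#'   [mergeFractions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDiffTable <- function(table, path) {
  table$fold_change <- sprintf("%.2f", table$fold_change)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
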