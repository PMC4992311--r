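# Constrained genome-wide scanning for operator boxes: every window of
# motif width inside each gene's upstream region is tested against a
# degenerate consensus (mismatch counting) or a PWM (log-odds score), on
# both strands, with hits reported in translational-start-relative
# coordinates.

# mismatch count of every width-w window of `chars` against consensus codes
.scan_mismatches <- function(chars, codechars) {
  w <- length(codechars)
  n <- length(chars)
  if (n < w) return(integer(0))
  nw <- n - w + 1L
  mm <- integer(nw)
  for (k in seq_len(w)) {
    mm <- mm + !IUPAC_MEMBER[cbind(codechars[k], chars[k:(k + nw - 1L)])]
  }
  mm
}

# log2-odds PWM score of every window (uniform background)
.scan_pwm <- function(chars, probs) {
  w <- nrow(probs)
  n <- length(chars)
  if (n < w) return(numeric(0))
  nw <- n - w + 1L
  lo <- log2(probs / 0.25)
  sc <- numeric(nw)
  b <- match(chars, DNA_BASES)           # NA for N
  for (k in seq_len(w)) {
    bi <- b[k:(k + nw - 1L)]
    v <- ifelse(is.na(bi), -Inf, lo[k, ifelse(is.na(bi), 1L, bi)])
    sc <- sc + v
  }
  sc
}

.empty_hits <- function() {
  data.frame(gene_id = character(), rel_position = integer(),
             strand = character(), matched_seq = character(),
             mismatches = integer(), pwm_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan one upstream region for motif matches
#'
#' Tests every window of motif width that lies entirely 5' of the
#' translational start (positions <= -1) on the coding strand and, if
#' requested, its reverse complement. With an [IUPACConsensus-class] motif
#' a window is a hit when its mismatch count is at most `maxMismatch`; with
#' a [MotifPWM-class], when its log2-odds score (uniform background)
#' reaches `pwmScoreMin`. A window matching identically on both strands
#' (palindromic match) is reported once, on the forward strand, unless
#' `deduplicate = FALSE`.
#'
#' @param region An [UpstreamRegion-class], or a plain character string
#'   taken to end immediately 5' of a start codon (its last base at -1).
#' @param motif An [IUPACConsensus-class] or [MotifPWM-class].
#' @param maxMismatch Mismatch tolerance for consensus scans (default 0).
#' @param bothStrands Scan the reverse strand too (default TRUE).
#' @param pwmScoreMin Score threshold in bits, required for PWM scans.
#' @param deduplicate Collapse identical two-strand palindromic matches
#'   (default TRUE).
#' @return A `data.frame` of hits: `gene_id`, `rel_position` (start-relative
#'   offset of the window's 5' end on the coding strand), `strand` of the
#'   match relative to the coding strand, `matched_seq` (motif orientation),
#'   `mismatches`, `pwm_score`; sorted by `rel_position`.
#' @export
scanRegion <- function(region, motif, maxMismatch = 0L, bothStrands = TRUE,
                       pwmScoreMin = NULL, deduplicate = TRUE) {
  if (is.character(region))
    region <- new("UpstreamRegion", gene_id = "region",
                  seq = .clean_genome_seq(region),
                  relOffset = if (nchar(region) > 0L) -nchar(region)
                              else NA_integer_,
                  downstreamExt = 0L)
  stopifnot(is(region, "UpstreamRegion"))
  n_up <- nchar(region@seq) - region@downstreamExt
  if (n_up == 0L) return(.empty_hits())
  seq <- substr(region@seq, 1L, n_up)    # hits must lie entirely at <= -1
  chars <- .chars(seq)

  is_pwm <- is(motif, "MotifPWM")
  w <- width(motif)
  if (length(chars) < w) return(.empty_hits())
  if (is_pwm && is.null(pwmScoreMin))
    stop("PWM scanning needs pwmScoreMin", call. = FALSE)

  hit_one_strand <- function(mchars_or_probs, strand) {
    if (is_pwm) {
      sc <- .scan_pwm(chars, mchars_or_probs)
      keep <- which(sc >= pwmScoreMin)
      mm <- rep(NA_integer_, length(keep))
      score <- sc[keep]
    } else {
      mmv <- .scan_mismatches(chars, mchars_or_probs)
      keep <- which(mmv <= maxMismatch)
      mm <- mmv[keep]
      score <- rep(NA_real_, length(keep))
    }
    if (length(keep) == 0L) return(NULL)
    win <- substring(seq, keep, keep + w - 1L)
    data.frame(gene_id = region@gene_id,
               rel_position = region@relOffset + keep - 1L,
               strand = strand,
               matched_seq = if (strand == "+") win else
                 vapply(win, revComp, character(1), USE.NAMES = FALSE),
               mismatches = mm, pwm_score = score,
               stringsAsFactors = FALSE)
  }

  if (is_pwm) {
    res <- hit_one_strand(motif@probs, "+")
    if (bothStrands)
      res <- rbind(res, hit_one_strand(revCompMotif(motif)@probs, "-"))
  } else {
    code <- .chars(codeString(motif))
    res <- hit_one_strand(code, "+")
    if (bothStrands)
      res <- rbind(res, hit_one_strand(.chars(revComp(codeString(motif))), "-"))
  }
  if (is.null(res)) return(.empty_hits())

  if (deduplicate && bothStrands && nrow(res) > 1L) {
    # a palindromic site matches the same window on both strands equally
    # well; keep the forward report
    fwd <- res[res$strand == "+", , drop = FALSE]
    idx <- match(res$rel_position, fwd$rel_position)
    same <- if (is_pwm) {
      !is.na(idx) & res$pwm_score == fwd$pwm_score[idx]
    } else {
      !is.na(idx) & res$mismatches == fwd$mismatches[idx]
    }
    same[is.na(same)] <- FALSE
    res <- res[!(res$strand == "-" & same), , drop = FALSE]
  }
  res <- res[order(res$rel_position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan every gene's upstream region of an annotated genome
#'
#' Applies [scanRegion()] to the `maxUpstream` bases 5' of each gene's
#' translational start (truncated at contig edges), optionally restricts
#' hits to a supplied promoter interval set, and reports hits with both
#' start-relative and absolute genomic coordinates.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param motif An [IUPACConsensus-class] or [MotifPWM-class].
#' @param maxUpstream Upstream window per gene in bp (default 500).
#' @param maxMismatch,bothStrands,pwmScoreMin,deduplicate Passed to
#'   [scanRegion()].
#' @param promoters Optional [GenomicRanges::GRanges] of promoter
#'   intervals; only hits fully contained in one are kept.
#' @return A `data.frame`: `gene_id`, `contig`, `gene_strand`,
#'   `rel_position`, `strand`, `matched_seq`, `mismatches`, `pwm_score`,
#'   `genome_start0`, `genome_end0` (0-based half-open genomic footprint),
#'   sorted by gene (annotation order) then `rel_position`.
#' @export
scanUpstream <- function(genome, motif, maxUpstream = 500L,
                         maxMismatch = 0L, bothStrands = TRUE,
                         pwmScoreMin = NULL, promoters = NULL,
                         deduplicate = TRUE) {
  stopifnot(is(genome, "AnnotatedGenome"))
  w <- width(motif)
  if (w > maxUpstream)
    stop("motif width exceeds maxUpstream window", call. = FALSE)
  g <- genome@genes
  if (nrow(g) == 0L) {
    out <- .empty_hits()
    out$contig <- character(0); out$gene_strand <- character(0)
    out$genome_start0 <- integer(0); out$genome_end0 <- integer(0)
    return(out)
  }
  res <- lapply(seq_len(nrow(g)), function(i) {
    reg <- extractUpstream(genome, g$gene_id[i], maxUpstream)
    h <- scanRegion(reg, motif, maxMismatch = maxMismatch,
                    bothStrands = bothStrands, pwmScoreMin = pwmScoreMin,
                    deduplicate = deduplicate)
    if (nrow(h) == 0L) return(NULL)
    h$contig <- g$contig[i]
    h$gene_strand <- g$strand[i]
    if (g$strand[i] == "+") {
      h$genome_start0 <- g$tstart0[i] + h$rel_position
    } else {
      h$genome_start0 <- g$tstart0[i] - h$rel_position - w + 1L
    }
    h$genome_end0 <- h$genome_start0 + w
    h
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    out <- .empty_hits()
    out$contig <- character(0); out$gene_strand <- character(0)
    out$genome_start0 <- integer(0); out$genome_end0 <- integer(0)
    return(out)
  }
  if (!is.null(promoters)) {
    hitsGr <- GenomicRanges::GRanges(
      seqnames = res$contig,
      ranges = IRanges::IRanges(start = res$genome_start0 + 1L,
                                end = res$genome_end0))
    within <- IRanges::overlapsAny(hitsGr, promoters, type = "within")
    res <- res[within, , drop = FALSE]
  }
  res <- res[order(match(res$gene_id, g$gene_id), res$rel_position), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("gene_id", "contig", "gene_strand", "rel_position", "strand",
          "matched_seq", "mismatches", "pwm_score", "genome_start0",
          "genome_end0")]
}

#' Write, and read back, a candidate-box table
#'
#' `writeHits()` writes the hit table as TSV (and optionally BED with the
#' absolute genomic footprint); `readHits()` restores it.
#'
#' @param hits A hit table from [scanUpstream()].
#' @param path TSV path.
#' @param bed Optional BED output path.
#' @return `path` invisibly for the writer; the hit `data.frame` for the
#'   reader.
#' @export
writeHits <- function(hits, path, bed = NULL) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(bed) && nrow(hits) > 0L) {
    bedtab <- data.frame(chrom = hits$contig, start = hits$genome_start0,
                         end = hits$genome_end0,
                         name = sprintf("%s@%d", hits$gene_id,
                                        hits$rel_position),
                         score = ifelse(is.na(hits$mismatches), 0L,
                                        hits$mismatches),
                         strand = hits$strand)
    utils::write.table(bedtab, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(gene_id = "character",
                                          matched_seq = "character"))
  if ("pwm_score" %in% names(out)) out$pwm_score <- as.numeric(out$pwm_score)
  if ("mismatches" %in% names(out))
    out$mismatches <- as.integer(out$mismatches)
  out
}
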