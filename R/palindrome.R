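# Detection of perfect and imperfect inverted repeats (DNA palindromes) with
# an optional central loop, as used to delimit operator palindromes in
# promoter regions.

#' Find inverted repeats in a DNA sequence
#'
#' Enumerates every candidate centre (loop placement) and extends the two
#' arms outwards base by base, counting a mismatch whenever the paired bases
#' are not Watson-Crick complementary (`N` never pairs). For each centre the
#' maximal arm is reported: the longest extension whose cumulative mismatch
#' count stays within `maxMismatch`. Hits shorter than `minArm` are
#' discarded. Since cumulative mismatches only grow with arm length, each
#' reported hit is not extendable without exceeding `maxMismatch` or running
#' off the sequence.
#'
#' @param seq DNA string (A/C/G/T/N; lowercase accepted).
#' @param minArm Minimum arm length in bp (>= 2).
#' @param maxLoop Maximum central loop length in bp (default 0).
#' @param maxMismatch Maximum non-complementary arm pairs allowed
#'   (default 0).
#' @return A `data.frame` with columns `start`, `end` (0-based half-open
#'   within `seq`), `arm_len`, `loop_len`, `mismatches` and `sequence`,
#'   sorted by `start` then descending `arm_len`. Zero rows when nothing is
#'   found.
#' @examples
#' findInvertedRepeats("GAATTC", minArm = 3)            # EcoRI site
#' findInvertedRepeats("GTTTAAAC", minArm = 4)
#' @export
findInvertedRepeats <- function(seq, minArm, maxLoop = 0L, maxMismatch = 0L) {
  stopifnot(minArm >= 2L, maxLoop >= 0L, maxMismatch >= 0L)
  empty <- data.frame(start = integer(), end = integer(),
                      arm_len = integer(), loop_len = integer(),
                      mismatches = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < 2L * minArm) return(empty)
  seq <- .clean_genome_seq(seq)
  ch <- .chars(seq)
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "*")  # N pairs with nothing
  compch <- unname(comp[ch])

  out <- vector("list", 64L); n_out <- 0L
  for (l in 0:maxLoop) {
    i_max <- n - l - minArm + 1L
    if (i_max < minArm + 1L) next
    for (i in (minArm + 1L):i_max) {           # loop occupies [i, i+l-1]
      kb <- min(i - 1L, n - i - l + 1L)        # arm-length bound at this centre
      mism <- compch[(i - 1L):(i - kb)] != ch[(i + l):(i + l + kb - 1L)]
      cum <- cumsum(mism)
      a <- sum(cum <= maxMismatch)
      if (a >= minArm) {
        s0 <- i - 1L - a                       # 0-based start
        e0 <- i - 1L + l + a
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- c(s0, e0, a, l, cum[a])
      }
    }
  }
  if (n_out == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(n_out)])
  res <- data.frame(start = m[, 1L], end = m[, 2L], arm_len = m[, 3L],
                    loop_len = m[, 4L], mismatches = m[, 5L],
                    stringsAsFactors = FALSE)
  res$sequence <- substring(seq, res$start + 1L, res$end)
  res <- res[order(res$start, -res$arm_len, res$loop_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write palindrome hits as TSV (and optionally BED)
#'
#' @param hits Result of [findInvertedRepeats()].
#' @param path Output TSV path.
#' @param seqId Sequence identifier recorded in the first column.
#' @param bed Optional BED output path.
#' @return `path`, invisibly.
#' @export
writePalindromeHits <- function(hits, path, seqId = "seq", bed = NULL) {
  tab <- cbind(seq_id = seqId, hits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    bedtab <- data.frame(chrom = seqId, start = hits$start, end = hits$end,
                         name = sprintf("pal_arm%d_loop%d_mm%d",
                                        hits$arm_len, hits$loop_len,
                                        hits$mismatches),
                         score = hits$arm_len, strand = "+")
    utils::write.table(bedtab, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
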