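# Degenerate-consensus and PWM motif models: construction from aligned
# operator sites, mismatch scoring, information content, and conversion
# between the two representations.

.check_alignment <- function(sites) {
  if (length(sites) < 1L) stop("need at least one site", call. = FALSE)
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L)
    stop("ragged alignment: site lengths ", paste(sort(w), collapse = ", "),
         call. = FALSE)
  ch <- unique(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE))
  bad <- setdiff(ch, DNA_BASES)
  if (length(bad) > 0L)
    stop("sites must be over A/C/G/T; found ", paste(bad, collapse = ", "),
         call. = FALSE)
  sites
}

.site_matrix <- function(sites) {
  do.call(rbind, strsplit(sites, "", fixed = TRUE))
}

#' Build the minimal degenerate consensus of aligned operator sites
#'
#' At every column the returned IUPAC code is the smallest code whose base
#' set equals the set of bases observed in that column, so each training
#' site matches the consensus with zero mismatches.
#'
#' @param sites Character vector of equal-length A/C/G/T site sequences.
#' @return An [IUPACConsensus-class].
#' @examples
#' buildConsensus(c("GTTA", "GTTC"))  # "GTTM"
#' @export
buildConsensus <- function(sites) {
  sites <- .check_alignment(sites)
  m <- .site_matrix(sites)
  code <- vapply(seq_len(ncol(m)), function(j)
    IUPAC_FROM_SET[[.set_key(m[, j])]], character(1))
  iupacConsensus(paste(code, collapse = ""))
}

#' Count mismatches between a degenerate consensus and a sequence window
#'
#' A position counts as a mismatch when the window base lies outside the
#' base set of the consensus code at that position. An `N` in the window
#' matches only the code `N`.
#'
#' @param consensus An [IUPACConsensus-class] or code string.
#' @param window Character string, same length as the consensus.
#' @return Integer mismatch count.
#' @examples
#' matchConsensus("GTTYMMYMGTAAAC", "GTTCAACAGTAAAC")  # 0
#' @export
matchConsensus <- function(consensus, window) {
  code <- if (is(consensus, "IUPACConsensus")) consensus@code else
    codeString(iupacConsensus(consensus))
  window <- toupper(window)
  if (nchar(window) != nchar(code))
    stop("window length ", nchar(window), " != consensus width ",
         nchar(code), call. = FALSE)
  cb <- .chars(code)
  wb <- .chars(window)
  bad <- setdiff(unique(wb), c(DNA_BASES, "N"))
  if (length(bad) > 0L)
    stop("window must be over A/C/G/T/N; found ",
         paste(bad, collapse = ", "), call. = FALSE)
  sum(!IUPAC_MEMBER[cbind(cb, wb)])
}

#' Estimate a PWM from aligned sites with a pseudocount
#'
#' `probs[i, b] = (count(i, b) + alpha) / (n + 4 alpha)`.
#'
#' @param sites Character vector of equal-length A/C/G/T sequences.
#' @param alpha Pseudocount per cell (default 0.5). Must be > 0 if any
#'   column lacks one of the four bases and log scoring is intended.
#' @return A [MotifPWM-class].
#' @export
pwmFromSites <- function(sites, alpha = 0.5) {
  stopifnot(alpha >= 0)
  sites <- .check_alignment(sites)
  m <- .site_matrix(sites)
  n <- nrow(m)
  probs <- t(vapply(seq_len(ncol(m)), function(j) {
    cnt <- table(factor(m[, j], levels = DNA_BASES))
    (as.numeric(cnt) + alpha) / (n + 4 * alpha)
  }, numeric(4)))
  colnames(probs) <- DNA_BASES
  new("MotifPWM", probs = probs, pseudocount = alpha)
}

#' Per-position information content of a PWM
#'
#' `IC_i = sum_b p_ib log2(p_ib / q_b)` against the background `q`
#' (uniform by default). Positions at or above `threshold` bits are flagged
#' conserved.
#'
#' @param pwm A [MotifPWM-class].
#' @param background Background base probabilities (length 4, A/C/G/T
#'   order); all entries must be positive.
#' @param threshold Conservation flag threshold in bits (default 1.0).
#' @return A `data.frame` with columns `position`, `ic` (bits) and
#'   `conserved`.
#' @export
informationContent <- function(pwm, background = rep(0.25, 4), threshold = 1.0) {
  stopifnot(is(pwm, "MotifPWM"), length(background) == 4L)
  if (any(background <= 0)) stop("background must be positive", call. = FALSE)
  background <- background / sum(background)
  p <- pwm@probs
  ic <- vapply(seq_len(nrow(p)), function(i) {
    pi <- p[i, ]
    nz <- pi > 0
    sum(pi[nz] * log2(pi[nz] / background[nz]))
  }, numeric(1))
  data.frame(position = seq_len(nrow(p)), ic = ic, conserved = ic >= threshold)
}

#' Collapse a PWM to a degenerate consensus
#'
#' Per column the code covers every base whose probability reaches
#' `threshold`; if no base does, the single most probable base is used
#' (ties broken alphabetically).
#'
#' @param pwm A [MotifPWM-class].
#' @param threshold Inclusion threshold in (0, 1] (default 0.25).
#' @return An [IUPACConsensus-class].
#' @export
consensusFromPwm <- function(pwm, threshold = 0.25) {
  stopifnot(is(pwm, "MotifPWM"), threshold > 0, threshold <= 1)
  p <- pwm@probs
  code <- vapply(seq_len(nrow(p)), function(i) {
    keep <- DNA_BASES[p[i, ] >= threshold]
    if (length(keep) == 0L) keep <- DNA_BASES[which.max(p[i, ])]
    IUPAC_FROM_SET[[.set_key(keep)]]
  }, character(1))
  iupacConsensus(paste(code, collapse = ""))
}

#' Reverse-complement a motif
#'
#' For a consensus, each code is complemented and the string reversed; for a
#' PWM the row order is reversed and the A/T and C/G columns swapped.
#'
#' @param motif An [IUPACConsensus-class] or [MotifPWM-class].
#' @return A motif of the same class.
#' @export
revCompMotif <- function(motif) {
  if (is(motif, "IUPACConsensus")) return(iupacConsensus(revComp(motif@code)))
  stopifnot(is(motif, "MotifPWM"))
  p <- motif@probs[rev(seq_len(nrow(motif@probs))), c("T", "G", "C", "A"),
                   drop = FALSE]
  colnames(p) <- DNA_BASES
  rownames(p) <- NULL
  new("MotifPWM", probs = p, pseudocount = motif@pseudocount)
}

#' Read aligned sites from FASTA or two-column TSV
#'
#' TSV input needs columns `id` and `sequence` (header optional when exactly
#' two columns).
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return Named character vector of site sequences.
#' @export
readSites <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    s <- Biostrings::readDNAStringSet(path)
    sites <- toupper(as.character(s))
    names(sites) <- sub("\\s.*$", "", names(s))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (identical(tolower(as.character(tab[1, ])), c("id", "sequence")))
      tab <- tab[-1, , drop = FALSE]
    sites <- toupper(tab[[2]])
    names(sites) <- tab[[1]]
  }
  sites
}

#' Write a motif in MEME minimal motif text format
#'
#' @param pwm A [MotifPWM-class].
#' @param path Output path.
#' @param name Motif name recorded in the file.
#' @param nsites Number of training sites to record (default 20).
#' @return `path`, invisibly.
#' @export
writeMemeMotif <- function(pwm, path, name = "motif1", nsites = 20L) {
  stopifnot(is(pwm, "MotifPWM"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(pwm@probs), nsites)), con)
  writeLines(apply(pwm@probs, 1L, function(r)
    paste(sprintf("%.6f", r), collapse = " ")), con)
  invisible(path)
}

#' Write a PWM as a TSV probability table
#'
#' @param pwm A [MotifPWM-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePwmTsv <- function(pwm, path) {
  tab <- data.frame(position = seq_len(nrow(pwm@probs)), pwm@probs,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
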