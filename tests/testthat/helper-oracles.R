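# Independent brute-force oracles and small fixture builders. The oracles
# deliberately re-derive everything from first principles (own IUPAC
# tables, naive enumeration) so they share no code with the package
# internals they check.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  if (nchar(s) == 0) return(s)
  paste(rev(strsplit(chartr("ACGTMKRYWSVBHDN", "TGCAKMYRWSBVDHN", s),
                     "")[[1]]), collapse = "")
}

# mismatches of a window against a degenerate code, by direct set lookup;
# an N in the window only satisfies the code N
oracle_match <- function(code, window) {
  cb <- strsplit(code, "")[[1]]
  wb <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(cb), function(i) {
    if (wb[i] == "N") return(cb[i] != "N")
    !(wb[i] %in% ORACLE_SETS[[cb[i]]])
  }, logical(1)))
}

# naive palindrome enumeration: every (centre, loop) pair, arms grown one
# pair at a time until the mismatch budget or the sequence edge is hit
oracle_palindromes <- function(seq, min_arm, max_loop, max_mismatch) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "*")
  rows <- list()
  for (l in 0:max_loop) {
    for (i in seq_len(n)) {            # loop occupies [i, i + l - 1]
      if (i + l - 1L > n) next
      k <- 0L; mm <- 0L; arm <- 0L; arm_mm <- 0L
      repeat {
        k <- k + 1L
        li <- i - k; ri <- i + l + k - 1L
        if (li < 1L || ri > n) break
        if (comp[[ch[li]]] != ch[ri]) mm <- mm + 1L
        if (mm > max_mismatch) break
        arm <- k; arm_mm <- mm
      }
      if (arm >= min_arm)
        rows[[length(rows) + 1L]] <-
          data.frame(start = i - 1L - arm, end = i - 1L + l + arm,
                     arm_len = arm, loop_len = l, mismatches = arm_mm)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      arm_len = integer(), loop_len = integer(),
                      mismatches = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, -out$arm_len, out$loop_len), ]
  rownames(out) <- NULL
  out
}

# naive upstream scan: every gene x offset x strand window, tested with
# oracle_match against the (manually reverse-complemented) code
oracle_scan <- function(genome, code, max_up, max_mm, both = TRUE) {
  g <- genes(genome)
  w <- nchar(code)
  rc_code <- oracle_revcomp(code)
  rows <- list()
  for (gi in seq_len(nrow(g))) {
    contig <- as.character(contigs(genome)[[g$contig[gi]]])
    clen <- nchar(contig)
    if (g$strand[gi] == "+") {
      from0 <- max(0, g$tstart0[gi] - max_up)
      up <- substr(contig, from0 + 1, g$tstart0[gi])
    } else {
      to0 <- min(clen, g$tstart0[gi] + 1 + max_up)
      up <- oracle_revcomp(substr(contig, g$tstart0[gi] + 2, to0))
    }
    L <- nchar(up)
    if (L < w) next
    for (j in seq_len(L - w + 1)) {
      win <- substr(up, j, j + w - 1)
      rel <- -L + j - 1L
      mmf <- oracle_match(code, win)
      if (mmf <= max_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$gene_id[gi], rel_position = rel, strand = "+",
          mismatches = mmf)
      if (both) {
        mmr <- oracle_match(rc_code, win)
        if (mmr <= max_mm && !(mmf <= max_mm && mmr == mmf))
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g$gene_id[gi], rel_position = rel, strand = "-",
            mismatches = mmr)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), rel_position = integer(),
                      strand = character(), mismatches = integer()))
  out <- do.call(rbind, rows)
  out[order(match(out$gene_id, g$gene_id), out$rel_position, out$strand), ]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# sequences of length len, each carrying one realization of `pwm` at a
# uniform random position (used by the EM recovery checks)
planted_sequences <- function(pwm, n_seq, len) {
  p <- probMatrix(pwm)
  w <- nrow(p)
  vapply(seq_len(n_seq), function(i) {
    bg <- random_dna(len)
    site <- paste(vapply(seq_len(w), function(k)
      sample(c("A", "C", "G", "T"), 1, prob = p[k, ]), character(1)),
      collapse = "")
    pos <- sample.int(len - w + 1L, 1L)
    paste0(substr(bg, 1, pos - 1), site, substr(bg, pos + w, len))
  }, character(1))
}

# a PWM whose per-column information content is roughly `bits`
# (one dominant base per consensus position)
conserved_pwm <- function(consensus_realization, p_major = 0.93) {
  p0 <- probMatrix(pwmFromSites(consensus_realization, alpha = 0))
  p <- p0 * p_major + (1 - p0) * ((1 - p_major) / 3)
  new("MotifPWM", probs = p / rowSums(p), pseudocount = 0)
}

# recovered-vs-planted column agreement, allowing the reverse-complement
# orientation of the recovered PWM
columns_recovered <- function(fit_pwm, planted_pwm) {
  r <- probMatrix(fit_pwm)
  p <- probMatrix(planted_pwm)
  maj <- apply(p, 1, which.max)
  rc <- r[rev(seq_len(nrow(r))), c(4, 3, 2, 1)]
  max(sum(apply(r, 1, which.max) == maj),
      sum(apply(rc, 1, which.max) == maj))
}
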