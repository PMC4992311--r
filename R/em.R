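# One-occurrence-per-sequence (OOPS) expectation-maximisation motif
# refinement: each input sequence is assumed to carry exactly one motif
# occurrence at an unknown position (and, optionally, strand) against a
# 0-order uniform background.

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# per-sequence placement tables: base indices (1..4) of every window of the
# given width, forward and (optionally) reverse-complement strand
.placements <- function(seq, w, bothStrands) {
  ch <- .chars(seq)
  b <- match(ch, DNA_BASES)
  L <- length(b)
  m <- L - w + 1L
  win <- function(bb) {
    idx <- outer(seq_len(w) - 1L, seq_len(m), "+")
    matrix(bb[idx], nrow = w)
  }
  fwd <- win(b)
  if (!bothStrands) return(list(fwd = fwd, rev = NULL, m = m, L = L))
  rb <- rev(5L - b)   # complement of A/C/G/T indices is 5 - index
  list(fwd = fwd, rev = win(rb), m = m, L = L)
}

# w x m matrix of per-window log-probabilities under logP (w x 4)
.window_logprob <- function(W, logP) {
  w <- nrow(W)
  lp <- matrix(as.vector(logP)[seq_len(w) + (as.vector(W) - 1L) * w],
               nrow = w)
  colSums(lp)
}

#' Refine a motif by OOPS expectation-maximisation
#'
#' Fits a PWM of fixed width to a set of sequences under the
#' one-occurrence-per-sequence model with a uniform position prior and a
#' 0-order uniform background. Restarts are initialised from actual
#' sequence windows chosen by a seeded recurrence heuristic (the
#' subsequence-seeding strategy of classic motif-discovery EM) and the
#' best-likelihood fit is kept. When `bothStrands` is `TRUE`
#' each sequence's reverse-complement placements compete alongside the
#' forward ones. The optimisation ascends the pseudocount-penalised
#' (Dirichlet-MAP) log likelihood, which is therefore non-decreasing across
#' iterations; the trace of the winning restart is returned.
#'
#' @param sequences Character vector (>= 2) of A/C/G/T sequences, each at
#'   least `width` long.
#' @param width Motif width in bp.
#' @param maxIter Maximum EM iterations per restart (default 200).
#' @param tol Stop when the objective improves by less than this
#'   (default 1e-6).
#' @param seed Integer seed; results are identical across runs with the
#'   same seed.
#' @param nRestarts Number of random restarts (default 5).
#' @param alpha Pseudocount added to expected counts in the M-step
#'   (default 0.5).
#' @param bothStrands Also consider reverse-complement placements
#'   (default TRUE).
#' @return A list with elements `pwm` ([MotifPWM-class]), `sites` (a
#'   `data.frame` with the best placement per sequence: `seq_index`,
#'   `position` 1-based on the input sequence, `strand`, `site`), `trace`
#'   (penalised log-likelihood per iteration of the winning restart) and
#'   `logLik` (its final value).
#' @export
emRefine <- function(sequences, width, maxIter = 200L, tol = 1e-6,
                     seed = 1L, nRestarts = 5L, alpha = 0.5,
                     bothStrands = TRUE) {
  if (length(sequences) < 2L) stop("need >= 2 sequences", call. = FALSE)
  sequences <- toupper(sequences)
  ch <- unique(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE))
  bad <- setdiff(ch, DNA_BASES)
  if (length(bad) > 0L)
    stop("sequences must be over A/C/G/T; found ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (width > min(nchar(sequences)))
    stop("width ", width, " exceeds shortest sequence (",
         min(nchar(sequences)), ")", call. = FALSE)
  width <- as.integer(width)
  pl <- lapply(sequences, .placements, w = width, bothStrands = bothStrands)
  ns <- 2L - !bothStrands   # strands per sequence
  bg_const <- sum(vapply(pl, function(p)
    (p$L - width) * log(0.25) - log(ns * p$m), numeric(1)))

  m_step <- function(zs) {
    cw <- matrix(0, nrow = width, ncol = 4L)
    for (i in seq_along(pl)) {
      z <- zs[[i]]
      mp <- pl[[i]]$m
      zf <- z[seq_len(mp)]
      W <- pl[[i]]$fwd
      for (b in 1:4) cw[, b] <- cw[, b] + (W == b) %*% zf
      if (bothStrands) {
        zr <- z[mp + seq_len(mp)]
        Wr <- pl[[i]]$rev
        for (b in 1:4) cw[, b] <- cw[, b] + (Wr == b) %*% zr
      }
    }
    cw <- cw + alpha
    cw / rowSums(cw)
  }

  # Seed selection, MEME-style: candidate seeds are actual sequence
  # windows; each is scored by how well it recurs across the sequence set
  # (sum over sequences of the best per-window match count against the
  # seed), and the top-scoring distinct candidates start the EM restarts.
  seed_score <- function(seed_w) {
    sum(vapply(pl, function(p) {
      best <- max(colSums(p$fwd == seed_w))
      if (bothStrands) best <- max(best, max(colSums(p$rev == seed_w)))
      best
    }, numeric(1)))
  }
  pick_seeds <- function(n_candidates = 100L) {
    tot <- vapply(pl, `[[`, integer(1), "m")
    idx <- sample.int(sum(tot), min(n_candidates, sum(tot)))
    si <- findInterval(idx - 1L, cumsum(c(0L, tot)), rightmost.closed = TRUE)
    ji <- idx - c(0L, cumsum(tot))[si]
    cand <- lapply(seq_along(idx), function(k) pl[[si[k]]]$fwd[, ji[k]])
    sc <- vapply(cand, seed_score, numeric(1))
    ord <- order(-sc)
    # a high-scoring candidate is often a site caught off-centre; slide it
    # within its sequence and keep the best-aligned window
    half_w <- max(width %/% 2L, 1L)
    refined <- lapply(utils::head(ord, 2L * nRestarts), function(k) {
      p <- pl[[si[k]]]
      js <- unique(pmin(pmax(ji[k] + (-half_w):half_w, 1L), p$m))
      scj <- vapply(js, function(j) seed_score(p$fwd[, j]), numeric(1))
      p$fwd[, js[which.max(scj)]]
    })
    unique(refined)
  }

  run_once <- function(seed_w) {
    # start from the seed window, softened towards uniform
    probs <- matrix(0.15 / 3, nrow = width, ncol = 4L)
    probs[cbind(seq_len(width), seed_w)] <- 0.85
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(maxIter)) {
      logP <- log(probs)
      obj <- bg_const + sum(alpha * logP)
      zs <- vector("list", length(pl))
      for (i in seq_along(pl)) {
        lp <- .window_logprob(pl[[i]]$fwd, logP)
        if (bothStrands) lp <- c(lp, .window_logprob(pl[[i]]$rev, logP))
        lse <- .logsumexp(lp)
        obj <- obj + lse
        zs[[i]] <- exp(lp - lse)
      }
      trace <- c(trace, obj)
      if (obj - prev < tol && it > 1L) break
      prev <- obj
      probs <- m_step(zs)
    }
    list(probs = probs, zs = zs, trace = trace,
         logLik = trace[length(trace)])
  }

  fits <- with_seed(seed, {
    seeds <- pick_seeds()
    lapply(seeds[seq_len(min(nRestarts, length(seeds)))], run_once)
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logLik"))]]

  sites <- do.call(rbind, lapply(seq_along(pl), function(i) {
    z <- best$zs[[i]]
    j <- which.max(z)            # ties -> lowest index: forward, low coord
    mp <- pl[[i]]$m
    if (j <= mp) {
      pos <- j; strand <- "+"
      site <- substr(sequences[i], pos, pos + width - 1L)
    } else {
      jr <- j - mp               # placement on the reverse-complement strand
      pos <- pl[[i]]$L - width + 2L - jr
      strand <- "-"
      site <- revComp(substr(sequences[i], pos, pos + width - 1L))
    }
    data.frame(seq_index = i, position = pos, strand = strand, site = site,
               stringsAsFactors = FALSE)
  }))

  probs <- best$probs
  colnames(probs) <- DNA_BASES
  list(pwm = new("MotifPWM", probs = probs, pseudocount = alpha),
       sites = sites, trace = best$trace, logLik = best$logLik)
}
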