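# IUPAC nucleotide code tables and small internal helpers shared across the
# motif, palindrome and scanning code.

# base sets of the 15 IUPAC codes (gap code '-' excluded on purpose)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# minimal code for each observed base set, keyed by the sorted set string
.set_key <- function(bases) paste(sort(unique(bases)), collapse = "")
IUPAC_FROM_SET <- local({
  m <- vapply(IUPAC_SETS, .set_key, character(1))
  stats::setNames(names(m), unname(m))
})

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", K = "M", R = "Y", Y = "R", W = "W", S = "S",
  V = "B", B = "V", H = "D", D = "H", N = "N"
)

# membership[code, base]: does a concrete genome base satisfy a consensus code?
# 'N' in a genome is treated as unknown: it satisfies only the code N.
IUPAC_MEMBER <- local({
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = length(bases),
              dimnames = list(IUPAC_CODES, bases))
  for (cd in IUPAC_CODES) m[cd, IUPAC_SETS[[cd]]] <- TRUE
  m[, "N"] <- FALSE
  m["N", "N"] <- TRUE
  m
})

DNA_BASES <- c("A", "C", "G", "T")

.check_iupac <- function(chars, what = "sequence") {
  bad <- setdiff(unique(chars), IUPAC_CODES)
  if (length(bad) > 0L)
    stop("non-IUPAC character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse-complement a DNA string over the full IUPAC alphabet
#'
#' Complements every IUPAC code (A<->T, C<->G, M<->K, R<->Y, W<->W, S<->S,
#' B<->V, D<->H, N<->N) and reverses the result. The empty string maps to
#' itself.
#'
#' @param seq A single character string over the IUPAC alphabet.
#' @return The reverse complement as a character string.
#' @examples
#' revComp("GAATTC")          # a perfect palindrome: "GAATTC"
#' revComp("GTTYMMYMGTAAAC")  # degenerate codes are complemented too
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) return(seq)
  ch <- .chars(toupper(seq))
  .check_iupac(ch)
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uppercase and validate a genome sequence (A/C/G/T/N only)
.clean_genome_seq <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  ch <- unique(.chars(seq))
  bad <- setdiff(ch, c(DNA_BASES, "N"))
  if (length(bad) > 0L)
    stop("invalid character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  seq
}
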