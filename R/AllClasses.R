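#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement readDNAStringSet writeXStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom BiocGenerics width
NULL

#' AnnotatedGenome: contig sequences plus gene models
#'
#' Container pairing a set of contig sequences with a table of bacterial gene
#' models. Coordinates are stored 0-based half-open internally; the
#' translational start of a gene is the genomic coordinate of the first base
#' of its start codon (`start0` on the plus strand, `end0 - 1` on the minus
#' strand). All user-facing offsets produced from this object use the
#' promoter convention in which -1 is the base immediately 5' of the start
#' codon and there is no position 0.
#'
#' @slot contigs A [Biostrings::DNAStringSet] of contig sequences
#'   (A/C/G/T/N).
#' @slot genes A `data.frame` with columns `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`), `start0`, `end0` (0-based half-open CDS span) and
#'   `tstart0` (0-based coordinate of the first base of the start codon).
#' @export
setClass("AnnotatedGenome",
  representation(contigs = "DNAStringSet", genes = "data.frame"))

setValidity("AnnotatedGenome", function(object) {
  g <- object@genes
  need <- c("gene_id", "contig", "strand", "start0", "end0", "tstart0")
  if (!all(need %in% names(g)))
    return(paste("genes table must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("duplicated gene_id")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (!all(g$contig %in% names(object@contigs)))
    return("gene on unknown contig")
  len <- Biostrings::width(object@contigs)[match(g$contig, names(object@contigs))]
  if (any(g$start0 < 0L) || any(g$end0 > len) || any(g$end0 <= g$start0))
    return("gene coordinates out of range")
  ts <- ifelse(g$strand == "+", g$start0, g$end0 - 1L)
  if (!all(g$tstart0 == ts))
    return("tstart0 inconsistent with strand and CDS span")
  TRUE
})

#' UpstreamRegion: promoter-proximal sequence in start-relative coordinates
#'
#' A stretch of coding-strand sequence 5' of a gene's translational start
#' (optionally extended a few bases into the coding sequence). The first base
#' of the upstream part sits at `relOffset` (a negative integer; -1 is the
#' base immediately 5' of the start codon).
#'
#' @slot gene_id Gene the region belongs to.
#' @slot seq Character string, 5'->3' on the coding strand.
#' @slot relOffset Start-relative offset of the first base (<= -1), or NA
#'   for an empty region.
#' @slot downstreamExt Number of trailing bases that lie at positions +1
#'   onward (inside the CDS).
#' @export
setClass("UpstreamRegion",
  representation(gene_id = "character", seq = "character",
                 relOffset = "integer", downstreamExt = "integer"))

setValidity("UpstreamRegion", function(object) {
  up_len <- nchar(object@seq) - object@downstreamExt
  if (object@downstreamExt < 0L) return("downstreamExt must be >= 0")
  if (up_len > 0L) {
    if (is.na(object@relOffset) || object@relOffset > -1L)
      return("relOffset must be <= -1 when upstream bases are present")
    if (-object@relOffset != up_len)
      return("relOffset inconsistent with upstream length")
  }
  TRUE
})

#' IUPACConsensus: a degenerate nucleotide motif
#'
#' A motif written as a string of IUPAC codes; each position stands for the
#' set of bases its code covers (M = \{A,C\}, Y = \{C,T\}, K = \{G,T\},
#' R = \{A,G\}, W = \{A,T\}, S = \{C,G\}, ...).
#'
#' @slot code Character string over the 15 IUPAC codes.
#' @export
setClass("IUPACConsensus", representation(code = "character"))

setValidity("IUPACConsensus", function(object) {
  if (length(object@code) != 1L || is.na(object@code) || nchar(object@code) == 0L)
    return("code must be a single non-empty string")
  bad <- setdiff(unique(.chars(object@code)), IUPAC_CODES)
  if (length(bad) > 0L)
    return(paste("non-IUPAC code(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct an IUPACConsensus from a code string
#'
#' @param code Character string over the IUPAC alphabet (lowercase accepted).
#' @return An [IUPACConsensus-class] object.
#' @examples
#' iupacConsensus("GTTYMMYMGTAAAC")
#' @export
iupacConsensus <- function(code) {
  new("IUPACConsensus", code = toupper(code))
}

#' MotifPWM: position weight matrix with pseudocount bookkeeping
#'
#' Per-position base probabilities of a fixed-width motif. Rows are motif
#' positions, columns the bases A, C, G, T; each row sums to 1.
#'
#' @slot probs Numeric matrix, width x 4, columns named A/C/G/T.
#' @slot pseudocount The per-cell pseudocount alpha used when the matrix was
#'   estimated from sites (0 if none).
#' @export
setClass("MotifPWM",
  representation(probs = "matrix", pseudocount = "numeric"))

setValidity("MotifPWM", function(object) {
  p <- object@probs
  if (!is.numeric(p) || ncol(p) != 4L || !identical(colnames(p), DNA_BASES))
    return("probs must be a numeric matrix with columns A, C, G, T")
  if (any(p < 0)) return("negative probabilities")
  if (any(abs(rowSums(p) - 1) > 1e-9)) return("rows must sum to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    return("pseudocount must be a single non-negative number")
  TRUE
})

#' @describeIn IUPACConsensus-class motif width (number of positions)
#' @param x An IUPACConsensus or MotifPWM.
#' @export
setMethod("width", "IUPACConsensus", function(x) nchar(x@code))

#' @describeIn MotifPWM-class motif width (number of positions)
#' @export
setMethod("width", "MotifPWM", function(x) nrow(x@probs))

#' Accessors for motif objects
#'
#' `codeString()` returns the degenerate code string of an
#' [IUPACConsensus-class]; `probMatrix()` the probability matrix of a
#' [MotifPWM-class]; `genes()` and `contigs()` the components of an
#' [AnnotatedGenome-class].
#'
#' @param x The object.
#' @return The underlying component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("codeString", function(x) standardGeneric("codeString"))
#' @rdname accessors
#' @export
setMethod("codeString", "IUPACConsensus", function(x) x@code)

#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))
#' @rdname accessors
#' @export
setMethod("probMatrix", "MotifPWM", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "AnnotatedGenome", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setMethod("contigs", "AnnotatedGenome", function(x) x@contigs)

#' @rdname accessors
#' @export
setGeneric("regionSeq", function(x) standardGeneric("regionSeq"))
#' @rdname accessors
#' @export
setMethod("regionSeq", "UpstreamRegion", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("relOffset", function(x) standardGeneric("relOffset"))
#' @rdname accessors
#' @export
setMethod("relOffset", "UpstreamRegion", function(x) x@relOffset)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome with", length(object@contigs), "contig(s) (",
      sum(Biostrings::width(object@contigs)), "bp ) and",
      nrow(object@genes), "gene model(s)\n")
})

setMethod("show", "IUPACConsensus", function(object) {
  cat("IUPACConsensus:", object@code, "(width", nchar(object@code), ")\n")
})

setMethod("show", "MotifPWM", function(object) {
  cat("MotifPWM, width", nrow(object@probs),
      ", pseudocount", object@pseudocount, "\n")
  print(round(object@probs, 3))
})

setMethod("show", "UpstreamRegion", function(object) {
  up_len <- nchar(object@seq) - object@downstreamExt
  cat("UpstreamRegion of", object@gene_id, ":", nchar(object@seq), "bp",
      if (up_len > 0L) paste0("[", object@relOffset, " .. -1]") else "(empty)",
      if (object@downstreamExt > 0L)
        paste0("+", object@downstreamExt, " downstream"), "\n")
})
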