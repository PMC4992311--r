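# Genome and annotation input/output, and extraction of upstream regions in
# translational-start-relative coordinates.

#' Read contig sequences from a FASTA file
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet; any
#' other letter (including U) is rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # read as raw strings first: DNAStringSet input would silently drop
  # letters outside its alphabet
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("FASTA parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  raw <- toupper(as.character(seqs))
  ok <- vapply(raw, function(s) !grepl("[^ACGTN]", s), logical(1))
  if (!all(ok)) {
    first <- names(seqs)[which(!ok)[1L]]
    bad <- setdiff(unique(.chars(raw[which(!ok)[1L]])), c(DNA_BASES, "N"))
    stop("FASTA parse error in '", path, "': disallowed character(s) ",
         paste(bad, collapse = ", "), " (record ", first, ")",
         call. = FALSE)
  }
  if (any(nchar(raw) == 0L))
    stop("FASTA parse error in '", path, "': empty sequence", call. = FALSE)
  out <- Biostrings::DNAStringSet(raw)
  names(out) <- names(seqs)
  out
}

#' Write contig sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports features of the requested type and converts their 1-based
#' inclusive coordinates to the package's internal 0-based half-open span.
#' The translational start of a minus-strand gene is the last genomic base
#' of the feature (GFF end - 1 after conversion).
#'
#' @param path Path to a GFF3 file.
#' @param featureType Feature type to keep (default `"CDS"`; `"gene"` also
#'   common).
#' @return A `data.frame` with columns `gene_id`, `contig`, `strand`,
#'   `start0`, `end0`, `tstart0` (the genes table of an
#'   [AnnotatedGenome-class]).
#' @export
readGeneModels <- function(path, featureType = "CDS") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == featureType]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), start0 = integer(),
                      end0 = integer(), tstart0 = integer(),
                      stringsAsFactors = FALSE))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("feature without strand in ", path, call. = FALSE)
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$locus_tag
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids))
    stop("features need an ID, locus_tag or Name attribute", call. = FALSE)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)         # 1-based inclusive end == 0-based exclusive
  data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start0 = start0,
    end0 = end0,
    tstart0 = ifelse(strand == "+", start0, end0 - 1L),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to GFF3
#'
#' Inverse of [readGeneModels()]: internal 0-based half-open spans go back to
#' 1-based inclusive GFF coordinates.
#'
#' @param genes Genes table (see [readGeneModels()]).
#' @param path Output path.
#' @param featureType Feature type to write (default `"CDS"`).
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path, featureType = "CDS") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start0 + 1L, end = genes$end0),
    strand = genes$strand)
  gr$type <- featureType
  gr$ID <- genes$gene_id
  if (featureType == "CDS") gr$phase <- 0L
  gr$source <- "regulonscan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Bundle contigs and gene models into an AnnotatedGenome
#'
#' @param contigs A [Biostrings::DNAStringSet] or named character vector of
#'   contig sequences.
#' @param genes Genes table as returned by [readGeneModels()].
#' @return An [AnnotatedGenome-class] object.
#' @examples
#' ag <- annotatedGenome(
#'   c(chr = "ACGTACGTACGTACGTACGT"),
#'   data.frame(gene_id = "g1", contig = "chr", strand = "+",
#'              start0 = 12L, end0 = 18L, tstart0 = 12L))
#' @export
annotatedGenome <- function(contigs, genes) {
  if (is.character(contigs)) {
    contigs <- vapply(contigs, .clean_genome_seq, character(1))
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  genes$start0 <- as.integer(genes$start0)
  genes$end0 <- as.integer(genes$end0)
  genes$tstart0 <- as.integer(genes$tstart0)
  new("AnnotatedGenome", contigs = contigs, genes = genes)
}

#' Load an AnnotatedGenome from FASTA + GFF3
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to the GFF3 annotation.
#' @param featureType GFF feature type holding the gene spans.
#' @return An [AnnotatedGenome-class].
#' @export
readAnnotatedGenome <- function(fasta, gff, featureType = "CDS") {
  annotatedGenome(readGenomeFasta(fasta), readGeneModels(gff, featureType))
}

#' Extract the sequence upstream of a gene's translational start
#'
#' Returns up to `maxLen` bases immediately 5' of the start codon, on the
#' coding strand (reverse-complemented for minus-strand genes), truncated at
#' the contig edge. Offsets use the promoter convention: -1 is the base
#' immediately 5' of the start codon; there is no position 0. An optional
#' `downstreamExt` appends bases from position +1 (the first base of the
#' start codon) onward.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param geneId Gene identifier.
#' @param maxLen Maximum upstream length in bp (>= 1).
#' @param downstreamExt Bases to append downstream of the start (default 0).
#' @return An [UpstreamRegion-class]; empty (zero-length upstream) when the
#'   gene sits at the contig edge.
#' @export
extractUpstream <- function(genome, geneId, maxLen, downstreamExt = 0L) {
  stopifnot(is(genome, "AnnotatedGenome"), maxLen >= 1L, downstreamExt >= 0L)
  g <- genome@genes[genome@genes$gene_id == geneId, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene: ", geneId, call. = FALSE)
  contig <- as.character(genome@contigs[[g$contig]])
  clen <- nchar(contig)
  maxLen <- as.integer(maxLen); downstreamExt <- as.integer(downstreamExt)
  if (g$strand == "+") {
    from0 <- max(0L, g$tstart0 - maxLen)       # 0-based half-open [from0, tstart0)
    up <- substr(contig, from0 + 1L, g$tstart0)
    dn <- if (downstreamExt > 0L)
      substr(contig, g$tstart0 + 1L, min(clen, g$tstart0 + downstreamExt))
      else ""
  } else {
    # upstream lies to the right of tstart0 on the genome
    to0 <- min(clen, g$tstart0 + 1L + maxLen)  # [tstart0+1, to0)
    up <- revComp(substr(contig, g$tstart0 + 2L, to0))
    dn <- if (downstreamExt > 0L)
      revComp(substr(contig, max(1L, g$tstart0 + 2L - downstreamExt),
                     g$tstart0 + 1L))
      else ""
  }
  n_up <- nchar(up)
  new("UpstreamRegion", gene_id = geneId, seq = paste0(up, dn),
      relOffset = if (n_up > 0L) -n_up else NA_integer_,
      downstreamExt = nchar(dn))
}

#' Export upstream regions as BED intervals
#'
#' Writes the genomic footprint of each gene's upstream window as a 0-based
#' half-open BED file (name = gene id, strand = coding strand).
#'
#' @param genome An [AnnotatedGenome-class].
#' @param maxLen Upstream window length in bp.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeUpstreamBed <- function(genome, maxLen, path) {
  g <- genome@genes
  clen <- Biostrings::width(genome@contigs)[match(g$contig, names(genome@contigs))]
  start0 <- ifelse(g$strand == "+", pmax(0L, g$tstart0 - maxLen), g$tstart0 + 1L)
  end0 <- ifelse(g$strand == "+", g$tstart0, pmin(clen, g$tstart0 + 1L + maxLen))
  bed <- data.frame(chrom = g$contig, start = start0, end = end0,
                    name = g$gene_id, score = 0L, strand = g$strand)
  bed <- bed[bed$end > bed$start, , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
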