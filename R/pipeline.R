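# Single entry point wiring the stages into complete workflows with a
# YAML/list configuration, an output directory and a run manifest.

.cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.load_motif <- function(config) {
  if (!is.null(config$motif)) return(iupacConsensus(config$motif))
  if (!is.null(config$sites)) return(buildConsensus(readSites(config$sites)))
  stop("config needs 'motif' (IUPAC string) or 'sites' (file)", call. = FALSE)
}

.need_file <- function(path, what) {
  if (is.null(path)) stop("config missing required input: ", what,
                          call. = FALSE)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  path
}

#' Run a complete workflow from a configuration
#'
#' Workflows: `"scan"` (genome-wide box search), `"consensus"` (build a
#' degenerate consensus and PWM from aligned sites, optionally EM-refined),
#' `"palindromes"` (inverted-repeat detection over FASTA records), `"lfq"`
#' (the differential-abundance pipeline) and `"simulate"` (either
#' synthetic generator). Outputs are written under `outdir` together with
#' a `manifest.yaml` recording the inputs, the effective parameter values,
#' the package version and the seed.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Must contain `workflow` and `outdir`; remaining keys are
#'   the stage parameters of the corresponding module functions (all
#'   thresholds default to the workflow's standard values: 500 bp
#'   upstream, 0 mismatches, protein log10 E-value -2.6, 2 peptides,
#'   peptide E-value 0.05, 100 s width, 20 s RT SD, 7-of-8 presence,
#'   5-peak difference, alpha 0.05).
#' @return The manifest list, invisibly; primary outputs are files under
#'   `outdir`.
#' @export
runWorkflow <- function(config) {
  if (is.character(config)) {
    .need_file(config, "config")
    config <- yaml::read_yaml(config)
  }
  wf <- .cfg_get(config, "workflow")
  outdir <- .cfg_get(config, "outdir")
  if (is.null(wf) || is.null(outdir))
    stop("config needs 'workflow' and 'outdir'", call. = FALSE)
  if (!wf %in% c("scan", "consensus", "palindromes", "lfq", "simulate"))
    stop("unknown workflow: ", wf, call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- .cfg_get(config, "seed", 1L)
  outputs <- character(0)
  params <- list()

  if (wf == "scan") {
    genome <- readAnnotatedGenome(
      .need_file(config$fasta, "fasta"), .need_file(config$gff, "gff"),
      featureType = .cfg_get(config, "feature_type", "CDS"))
    motif <- .load_motif(config)
    params <- list(motif = codeString(motif),
                   max_upstream = .cfg_get(config, "max_upstream", 500L),
                   max_mismatch = .cfg_get(config, "max_mismatch", 0L),
                   both_strands = .cfg_get(config, "both_strands", TRUE))
    promoters <- NULL
    if (!is.null(config$promoters)) {
      .need_file(config$promoters, "promoters")
      promoters <- rtracklayer::import(config$promoters, format = "bed")
      params$promoters <- config$promoters
    }
    hits <- scanUpstream(genome, motif,
                         maxUpstream = params$max_upstream,
                         maxMismatch = params$max_mismatch,
                         bothStrands = params$both_strands,
                         promoters = promoters)
    writeHits(hits, file.path(outdir, "hits.tsv"),
              bed = file.path(outdir, "hits.bed"))
    outputs <- c("hits.tsv", "hits.bed")

  } else if (wf == "consensus") {
    sites <- readSites(.need_file(config$sites, "sites"))
    cons <- buildConsensus(sites)
    alpha <- .cfg_get(config, "pseudocount", 0.5)
    pwm <- pwmFromSites(sites, alpha = alpha)
    params <- list(pseudocount = alpha, n_sites = length(sites))
    if (isTRUE(.cfg_get(config, "em_refine", FALSE))) {
      em_w <- .cfg_get(config, "em_width", nchar(sites[1L]))
      em_in <- if (!is.null(config$em_sequences))
        readSites(.need_file(config$em_sequences, "em_sequences")) else sites
      fit <- emRefine(unname(em_in), width = em_w, seed = seed,
                      alpha = alpha)
      pwm <- fit$pwm
      utils::write.table(fit$sites, file.path(outdir, "em_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "em_sites.tsv")
      params$em_width <- em_w
    }
    writeLines(codeString(cons), file.path(outdir, "consensus.txt"))
    writePwmTsv(pwm, file.path(outdir, "pwm.tsv"))
    writeMemeMotif(pwm, file.path(outdir, "motif.meme"),
                   nsites = length(sites))
    ic <- informationContent(pwm)
    utils::write.table(ic, file.path(outdir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "consensus.txt", "pwm.tsv", "motif.meme",
                 "conservation.tsv")

  } else if (wf == "palindromes") {
    seqs <- readGenomeFasta(.need_file(config$fasta, "fasta"))
    params <- list(min_arm = .cfg_get(config, "min_arm", 5L),
                   max_loop = .cfg_get(config, "max_loop", 10L),
                   max_mismatch = .cfg_get(config, "max_mismatch", 0L))
    all_hits <- do.call(rbind, lapply(names(seqs), function(id) {
      h <- findInvertedRepeats(as.character(seqs[[id]]),
                               minArm = params$min_arm,
                               maxLoop = params$max_loop,
                               maxMismatch = params$max_mismatch)
      if (nrow(h) > 0L) cbind(seq_id = id, h) else NULL
    }))
    if (is.null(all_hits))
      all_hits <- data.frame(seq_id = character(), start = integer(),
                             end = integer(), arm_len = integer(),
                             loop_len = integer(), mismatches = integer(),
                             sequence = character())
    utils::write.table(all_hits, file.path(outdir, "palindromes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- "palindromes.tsv"

  } else if (wf == "lfq") {
    dec <- .cfg_get(config, "decimal", ".")
    idents <- readIdentTsv(.need_file(config$idents, "idents"), dec = dec)
    peaks <- readPeaksTsv(.need_file(config$peaks, "peaks"), dec = dec)
    gt <- .cfg_get(config, "genotypes")
    if (is.null(gt)) stop("config needs 'genotypes' (sample: wt|mutant map)",
                          call. = FALSE)
    genotypes <- stats::setNames(unlist(gt), names(gt))
    cfg <- lfqConfig(
      proteinLog10Max = .cfg_get(config, "protein_log10_max", -2.6),
      minPeptides = .cfg_get(config, "min_peptides", 2L),
      peptideEMax = .cfg_get(config, "peptide_e_max", 0.05),
      widthMax = .cfg_get(config, "width_max", 100),
      rtSdMax = .cfg_get(config, "rt_sd_max", 20),
      minPresent = .cfg_get(config, "min_present", 7L),
      reference = .cfg_get(config, "reference"),
      minPeakDiff = .cfg_get(config, "min_peak_diff", 5),
      alpha = .cfg_get(config, "alpha", 0.05))
    params <- cfg
    res <- runLfqPipeline(idents, peaks, genotypes, config = cfg)
    writeDiffTable(res$table, file.path(outdir, "diff_proteins.tsv"))
    outputs <- "diff_proteins.tsv"

  } else if (wf == "simulate") {
    what <- .cfg_get(config, "what", "genome")
    params <- list(what = what)
    if (what == "genome") {
      motif <- .load_motif(config)
      plants <- if (!is.null(config$plants))
        do.call(rbind, lapply(config$plants, as.data.frame)) else
        data.frame()
      sim <- simulateGenome(motif, plants,
                            nGenes = .cfg_get(config, "n_genes", 20L),
                            gcContent = .cfg_get(config, "gc_content", 0.435),
                            seed = seed)
      writeSimulatedGenome(sim, outdir)
      outputs <- c("genome.fasta", "genes.gff3", "truth_sites.tsv")
    } else if (what == "lfq") {
      sim <- simulateLfq(
        nProteins = .cfg_get(config, "n_proteins", 500L),
        nDiff = .cfg_get(config, "n_diff", 30L),
        sigma = .cfg_get(config, "sigma", 0.2),
        missingRate = .cfg_get(config, "missing_rate", 0.1),
        seed = seed)
      writeSimulatedLfq(sim, outdir)
      outputs <- c("identifications.tsv", "peaks.tsv", "truth_folds.tsv")
    } else stop("simulate 'what' must be 'genome' or 'lfq'", call. = FALSE)
  }

  manifest <- list(
    workflow = wf,
    package_version = as.character(utils::packageVersion("regulonscan")),
    seed = seed,
    parameters = params,
    inputs = config[intersect(names(config),
                              c("fasta", "gff", "sites", "idents", "peaks",
                                "promoters", "motif", "em_sequences"))],
    outputs = as.list(outputs))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
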