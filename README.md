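# regulonscan

Tools for defining the regulon of a bacterial transcription factor that
binds a palindromic operator box, paired with the label-free proteomics
workflow used to measure the downstream effect of deleting the regulator.
The package is aimed at microbial regulatory genomics: given a handful of
experimentally mapped operator sites, it builds the degenerate consensus,
finds the operator palindromes in promoter regions, scans an annotated
genome for further candidate target genes, refines the motif by EM, and
turns peptide-level LC-MS quantifications into a signed fold-change table
of differentially abundant proteins.

## The models at the core

**Degenerate consensus.** For aligned operator sites, each column is
collapsed to the minimal IUPAC code whose base set equals the observed
bases (M = {A,C}, Y = {C,T}, ...), so every training site matches the
consensus with zero mismatches. Scanning counts, per window, the positions
whose base falls outside the code's set; genome-wide search is restricted
to at most 500 bp 5' of each translational start (coordinates use the
promoter convention: -1 is the base immediately 5' of the start codon),
on both strands, with palindromic double matches collapsed to one forward
report.

**Inverted repeats.** Palindrome detection grows complementary arms
around every centre and loop length (loop ≤ `maxLoop`, arm ≥ `minArm`),
counting non-complementary pairs, and reports maximal hits — one more
base pair would exceed the mismatch budget or the sequence edge.

**OOPS EM.** Motif refinement fits a PWM of fixed width `w` under the
one-occurrence-per-sequence model with uniform background: for sequence
`i` and placement `j`, responsibilities are
`z_ij ∝ Π_k p(k, base_ijk)`, and the M-step re-estimates
`p = (E-counts + α) / (n + 4α)`. The penalised log likelihood is
non-decreasing; restarts are seeded from recurrent sequence windows and
the best fit wins. Conservation is summarised as per-position information
content `IC_i = Σ_b p_ib log2(p_ib / q_b)`.

**LFQ differential abundance.** Identifications are kept when the protein
log10 E-value is below -2.6 with ≥ 2 distinct peptides of E-value < 0.05;
peaks wider than 100 s or with retention-time SD above 20 s are removed;
quantification uses specific peptides present in ≥ 7 of 8 runs (2
genotypes × 4 replicates), with missing cells imputed by regression on
sibling peptides, run scales removed by median-ratio normalisation to a
reference run, and protein values obtained by summation. A protein is
differential when a Kruskal-Wallis test on its peak counts (with a
minimum 5-peak mean difference) and a one-way ANOVA on log2 abundances
are both significant at α = 0.05. Fold changes are signed: `+r` means
`r`-fold higher in the mutant, `-r` means `r`-fold lower.

## Worked example

```r
library(regulonscan)

# consensus from five aligned operator sites
cons <- buildConsensus(c("GTTCAACAGTAAAC", "GTTTAATCGTAAAC",
                         "GTTCAATAGTAAAC", "GTTTCCCAGTAAAC",
                         "GTTCACTAGTAAAC"))
cons
#> IUPACConsensus: GTTYMMYMGTAAAC (width 14 )

# a synthetic 12-gene genome with three planted boxes, then rediscovered
sim <- simulateGenome(cons,
  plants = data.frame(gene = c(2, 5, 9), rel_offset = c(-41, -150, -288),
                      strand = c("+", "-", "+")),
  nGenes = 12, seed = 7)
scanUpstream(sim$genome, cons)[, c("gene_id", "rel_position", "strand",
                                   "matched_seq", "mismatches")]
#>   gene_id rel_position strand    matched_seq mismatches
#> 1 gene002          -41      + GTTCAACCGTAAAC          0
#> 2 gene005         -150      - GTTTACCAGTAAAC          0
#> 3 gene009         -288      + GTTTCCCAGTAAAC          0

# label-free proteomics with five planted fold changes
lf <- simulateLfq(nProteins = 100, nDiff = 5, seed = 7)
res <- runLfqPipeline(lf$idents, lf$peaks, lf$genotypes)
res$table[res$table$significant, ]
#>    protein fold_change   kw_p peak_diff  anova_p significant n_peptides
#> 1    P0031        13.1 0.0202      6.25 1.07e-06        TRUE          2
#> 2    P0092         9.1 0.0202      7.00 7.36e-07        TRUE          2
#> 47   P0042       -23.5 0.0209    -10.00 1.50e-08        TRUE          3
```

Each scan row is one candidate operator box: the gene whose upstream
region contains it, the start-relative offset of its 5' end, the strand
of the match relative to the coding strand, and the matched sequence. In
the proteomics table, `fold_change = 13.1` reads "13.1-fold more abundant
in the mutant", `-23.5` reads "23.5-fold less"; `peak_diff` is the
mutant-minus-wild-type mean peak-count difference backing the
Kruskal-Wallis criterion.

The same workflows are scriptable through YAML configs via
`runWorkflow()` (workflows `scan`, `consensus`, `palindromes`, `lfq`,
`simulate`), or from a shell through the thin wrapper in
`inst/scripts/regulonscan.R`.

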