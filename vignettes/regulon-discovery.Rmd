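---
title: "Operator-box discovery and label-free proteomics with regulonscan"
author: "regulonscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operator-box discovery and label-free proteomics with regulonscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

# Scope and model

`regulonscan` implements the computational half of a classic bacterial
regulon study: a MarR-family repressor binds a short palindromic operator
box upstream of the genes it controls, and its deletion reshapes the
proteome. The package covers two workflows.

**Motif workflow.** Aligned operator sites are collapsed into a degenerate
IUPAC consensus (per column, the minimal code whose base set equals the
observed bases, so every training site matches with zero mismatches), or
into a position weight matrix (PWM) with pseudocount
`p = (count + alpha) / (n + 4 alpha)`. The annotated genome is then scanned:
every window of motif width inside each gene's upstream region — at most
`maxUpstream` bp (default 500) 5' of the translational start, both strands —
is tested, and hits are reported in start-relative coordinates where -1 is
the base immediately 5' of the start codon (there is no position 0).
Inverted repeats ("palindromes") are detected by growing complementary
arms around every candidate centre and loop length; a hit is maximal when
one more base pair would exceed the mismatch budget or the sequence edge.
A one-occurrence-per-sequence (OOPS) EM refines a motif of fixed width
from unaligned promoter sequences.

**Proteomics workflow.** A label-free 2-genotype x 4-replicate
peptide-intensity experiment is reduced to a signed fold-change table:
identification filtering (protein log10 E-value < -2.6 with at least two
distinct peptides of E-value < 0.05), peak-quality filtering (width
<= 100 s, retention-time SD <= 20 s; strict inequalities, so boundary
peaks survive), selection of specific peptides present in at least 7 of
the 8 runs with at least two such peptides per protein, regression
imputation, median-ratio normalisation against a reference run, summation
roll-up to proteins, then a Kruskal-Wallis test on peak counts (requiring
at least a 5-peak mean difference between genotypes) and a one-way
fixed-effect ANOVA on abundances. A protein is called differential when
both criteria hold. Fold changes use the signed convention: `+r` when the
mutant mean is `r`-fold higher, `-r` when `r`-fold lower, so magnitudes
are always at least 1.

# Coordinate conventions

Internally all genomic coordinates are 0-based half-open; GFF3 input
(1-based inclusive) is converted on read, and the translational start of a
minus-strand gene is its feature's last base. All user-facing offsets use
the promoter convention above. A scan hit at `rel_position = -100` with a
14-bp motif occupies -100 .. -87; hits must lie entirely at positions
<= -1, so nothing overlapping the start codon is reported.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maxUpstream` | 500 bp | upstream window per gene |
| `maxMismatch` | 0 | consensus-scan mismatch tolerance |
| `alpha` | 0.5 | PWM/EM pseudocount per cell |
| `threshold` (consensus from PWM) | 0.25 | base-probability inclusion cutoff |
| IC `threshold` | 1.0 bit | conserved-position flag |
| `minArm`, `maxLoop`, `maxMismatch` | — | palindrome geometry bounds |
| `proteinLog10Max`, `minPeptides`, `peptideEMax` | -2.6, 2, 0.05 | identification filter |
| `widthMax`, `rtSdMax` | 100 s, 20 s | peak-quality filter |
| `minPresent` | 7 (of 8) | repeatable-peptide rule |
| `minPeakDiff`, `alpha` | 5, 0.05 | differential call |

Exact-consensus matching (0 mismatches) is the scanning default because
the consensus builder guarantees training sites match exactly; mismatch
tolerance and PWM log-odds scoring are explicit options. The
promoter-interval restriction (a BED/GRanges set) is off by default: such
annotations are an external resource.

# Numerical choices

* **EM objective.** The reported trace is the pseudocount-penalised
  (Dirichlet-MAP) log likelihood, which the EM iteration increases
  monotonically by construction; the plain likelihood could in principle
  dip by a rounding margin under MAP smoothing. Convergence is declared
  when the objective improves by less than `tol` (default 1e-6).
* **EM initialisation.** Restarts are seeded from actual sequence windows:
  random candidate windows are scored by how strongly they recur across
  the sequence set (sum over sequences of the best per-window match
  count), the top candidates are slide-refined within their sequence, and
  each surviving seed starts one EM run; the best final objective wins.
  Random-responsibility initialisation was evaluated and discarded — it
  stalls near the uniform saddle and converges to phase-shifted optima.
  Ties in site assignment resolve to the lowest coordinate, forward
  strand first.
* **Overfit floor.** A converged OOPS fit on pure iid noise still shows
  roughly 0.5 bits per column at these problem sizes (50 sequences of
  200 bp, width 14, both strands) — that is the maximum-likelihood
  alignment of noise, not a defect; genuinely conserved motifs sit near
  1.5 bits per column and are cleanly separated.
* **Palindromic double hits.** With a (near-)palindromic consensus the
  same genomic window can match on both strands with equal mismatch
  count; such pairs are collapsed to the forward report unless
  deduplication is turned off.
* **Imputation.** A missing peptide intensity is predicted by ordinary
  least squares of the peptide's observed values on the mean of its
  protein's other peptides, evaluated at the missing run. The fit needs
  two usable points; an unpredictable cell (no sibling observed in that
  run) drops the peptide with a warning. Predictions are floored at 1% of
  the peptide's smallest observed value, since an extrapolated line can
  dip below zero while intensities cannot. Because the regression carries
  an intercept on the raw scale, imputed cells are only approximately
  scale-equivariant; the run-scale invariance of the fold-change column
  is exact on complete data and holds to noise level otherwise.
* **Normalisation.** Per-run factors are medians of peptide ratios to the
  reference run, using only peptides measured (pre-imputation) in both
  runs; the default reference is the run whose total observed intensity
  is closest to the median of run totals. The reference's factor is
  exactly 1.
* **ANOVA scale.** The pipeline tests log2 abundances
  (`logTransform = TRUE`), which makes multiplicative lognormal noise
  exactly normal; `anovaTest()` itself is scale-agnostic, and with two
  groups equals the pooled t-test (F = t^2). Degenerate rows (no
  within-group variance) resolve to p = 1 when the group means coincide
  and p = 0 when they separate.
* **Peak-count rule.** Protein peak counts are the number of retained
  peak rows per protein and run; "minimum difference of 5 peaks" is
  applied to per-genotype mean counts. With `peakRule = FALSE` the ANOVA
  alone decides — this is the configuration under which the null
  type-I error of the pipeline sits at the nominal alpha, since two
  intersected independent tests would operate far below it.

# The synthetic-data generators

`simulateGenome()` lays single-CDS genes on alternating strands over an
iid background at 43.5% GC (a typical Firmicute value) and writes exact
motif realizations — optionally with a requested number of forced
mismatches — at chosen start-relative offsets. The truth table is in scan
coordinates, so recovery is a direct join. It deliberately omits
higher-order sequence composition, operons and overlapping genes:
oracle-equivalence testing and planted-site recovery need no
compositional realism.

`simulateLfq()` emulates the 2 x 4 design: lognormal protein base
intensities, per-peptide efficiencies, planted signed folds multiplying
the mutant runs, per-run scale factors (default range 0.5-2), lognormal
cell noise (`sigma` on the natural-log scale, default 0.2 ~ 20% CV), and
independent 10% missingness. Peak counts per peptide cell are
1 + Poisson(1); differential proteins gain 4 extra peaks per present cell
in their higher genotype, so the protein-level difference clears the
5-peak rule even after peptide filtering. Realistic nuisance processes
are layered on: 5% non-specific peptides, 3% peptides and 2% proteins
with failing identification scores, and 5% junk peak rows with excessive
width or retention-time drift. These exercise every filter, and they also
mean a planted protein can legitimately be lost before testing (a
corrupted identification, or a protein left with one repeatable peptide) —
measured pipeline sensitivity therefore sits near 0.9, not 1. What the
generator does not model: retention-time structure, intensity-dependent
missingness, correlated peptide noise, shared peptides between homologs.
Passing tests demonstrate the pipeline's arithmetic and its operating
characteristics under this model, not performance on real
chromatographic data.

# Validation design and problem sizes

The test suite checks every search engine against a naive enumeration
oracle written independently in the tests: the upstream scanner on
30 simulated 10-kb genomes cycling mismatch tolerances 0-2, and the
palindrome finder on 15 random 300-mers across the full parameter grid
(arm 3/5/7, loop 0/5/20, mismatch 0/2). These sizes keep the
brute-force oracles, which are quadratic and interpreted, to about a
minute while covering every parameter combination; the engines themselves
run two orders of magnitude faster. EM recovery is validated on 50
200-mers with one planted 14-wide motif at ~1.5 bits per column across 5
seeds (at least 12 of 14 consensus columns required in at least 4); the
LFQ pipeline on 500 proteins with 30 planted folds of magnitude 6-25
(sensitivity >= 0.8, FDR <= 0.1, all recovered signs correct) and on 2000
null proteins for type-I calibration. `scripts/acceptance.R` re-runs the
same experiments from scratch at any seed.

# Known limitations

* Gene models are single-CDS and bacterial; no splicing, no operon
  inference (transcription units are whatever gene list is supplied).
* The palindrome finder counts mismatched pairs only — no gaps or bulges,
  no thermodynamics.
* The EM is OOPS with a 0-order uniform background; no ZOOPS/TCM, no
  motif-width search, no E-value calibration.
* Upstream windows truncate at contig edges, not at neighbouring genes.
* Fractions (e.g. cytosolic and membrane) are analysed as independent
  pipeline runs and merged afterwards with a shared-protein flag.
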