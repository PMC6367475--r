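---
title: "Methods: simulated miRNA microarrays and hybridization-based target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated miRNA microarrays and hybridization-based target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gallmir)
```

# The problem

Selection experiments in the wax moth *Galleria mellonella* produce larval
lines that differ in resistance to the entomopathogenic fungus *Metarhizium
robertsii*. Two questions drive the computational side of such studies:

1. **Which miRNAs shift expression** between resistant (R) and susceptible
   (S) lines, infected (+) or uninfected (−), in the two tissues that matter
   for fungal infection (cuticle, fat body)? The measurement is a
   single-channel DNA oligonucleotide microarray with every probe printed in
   triplicate.
2. **What do those miRNAs target**, given that the *G. mellonella* genome is
   not fully annotated? Targets must be found de novo in an assembled
   transcriptome: find ORFs in contigs, treat the sequence downstream of the
   confirmed ORF as a putative 3'UTR, scan for seed complements, and confirm
   candidate sites by the thermodynamic stability (minimum free energy, MFE)
   of the miRNA:mRNA hybrid.

gallmir implements both arms as testable, reusable functions, plus a
synthetic-data generator that emulates every input with planted ground
truth, so the whole pipeline can be exercised and falsified without any
external data.

# The synthetic study

`sim_config()` fixes the study conditions. Defaults: 4 cohorts × 2 tissues ×
3 replicates; 300 miRNAs of 18–24 nt (unique seed heptamers by
construction); 80 contigs of 500–900 nt, each assembled as
5' pad + ORF (60–120 codons) + 3' tail; planted differential effects of
|log2FC| = 2 against replicate noise of SD 0.25 log2 units; a smooth
intensity-dependent bias of amplitude 0.8 log2 units; and a mean additive
background of 100 fluorescence units. Scale is emulated, not matched, to the
original arrays (thousands of miRNAs): 300 keeps every test fast while all
statistical structure (triplicate probes, planted density ≈ 13% per
comparison cell) is preserved; the calibration checks that need many tests
use 2,000 miRNAs explicitly.

Design choices a reader should know:

* **Coordinates** are 0-based, half-open everywhere.
* **Sites.** With probability `site_plant_prob` a contig's tail carries a
  site for one designated miRNA. By default the site is the reverse
  complement of the *whole* miRNA (`site_context = "full"`): the seed 7-mer
  is exact within it, and the surrounding complementarity gives the MFE
  filter true positives to find. `site_context = "seed"` plants bare
  7-mers. Tails are scrubbed of *accidental* seed complements for any miRNA
  in the set, and regenerated if a complete ORF of ≥ 30 codons would end
  downstream of the planted stop — so the truth tables are exhaustive and
  recovery tests can demand 100%.
* **Bias.** The intensity-dependent bias is
  `a · amplitude · sin(pi·(baseline − min)/range)` with `a = +1` for odd and
  `−1` for even replicate indices, emulating hybridization-batch effects.
  It cancels exactly in replicate-paired contrasts but appears as an MA
  trend of up to 2 × amplitude against the median pseudo-reference.
* **Background** is i.i.d. per probe, `N(mean, 0.1·mean)` clipped at zero,
  constant across samples; foreground = 2^signal + background, so
  subtraction recovers the signal exactly in the noiseless case.
* **Determinism.** Each generator stage seeds its own stream at
  `rng_seed + {0, 1, 2}` and draws in a documented order; identical configs
  give byte-identical FASTA/TSV artifacts.

What the generator does **not** emulate: probe thermodynamics, dye-swap
designs, spatial artifacts, correlated replicates, and imperfect
(non-Watson-Crick) seed sites. Passing tests therefore demonstrate the
correctness of the *computations*, not robustness to every artifact of real
arrays.

# Expression analysis

**Background subtraction** is `max(F − B, 1)` on the linear scale; the floor
of 1 fluorescence unit keeps log2 defined.

**Normalization.** Per sample, `M = log2(x) − log2(ref)` and
`A = (log2(x) + log2(ref))/2` against a median pseudo-reference (the arrays
are single-channel, so the two-channel M/A construction is formed against
the per-probe median across samples). The trend estimator is `stats::lowess`
(span 0.3, degree 1, 3 robustness iterations), fitted on the central 95% of
the A-range and extended as a constant beyond it: edge windows hold few
probes and — on arrays with strong effects — can be occupied exclusively by
differential probes, which a trend fit must not absorb.

A single fit-subtract pass leaves a residual of ~0.1 log2 units on a bias of
amplitude 0.8, so the pass is iterated. Numerically this is delicate: the
lowess smoother matrix has small negative eigenvalues, so naive unbounded
iteration is weakly expansive, and recomputing A from the moving values
introduces an irreducible M–A correlation through shared noise (regression
to the mean). `lowess_normalize()` therefore freezes the reference and A
within a *round*, repeats passes while the fitted trend shrinks, refreshes
the design between rounds, stops as soon as a fresh design fits a trend
below `tol = 1e-4` or stops improving, and returns the state with the
flattest observed trend. On a noise-free bias fixture this flattens a 1.6
log2-unit MA trend to < 1e-3 and makes the operation idempotent
(renormalizing the output reproduces it); on noise-dominated data a small
irreducible trend (~0.01–0.03) remains, which is a property of M-on-A
estimation itself, not of the implementation.

One interaction is worth quantifying: because the simulated bias alternates
sign with replicate index, it cancels exactly in replicate-paired tests
*before* normalization, while normalization replaces it with small
replicate-dependent residuals. Those residuals inflate the SD of paired
differences by ~18%, which matters at 2 degrees of freedom: planted-effect
recovery is ~95% without the bias nuisance and ~88% with it. The package
reports both figures (`scripts/acceptance.R`); power properties are asserted
on the fixture that isolates effect + noise, and normalization efficacy on
the fixture that isolates the bias.

**Testing.** Probe triplicates are collapsed by their mean per sample — the
mean keeps the full √3 noise reduction the triplicate printing buys, which
the paired test needs at n = 3 (the median of three would forfeit ~25% of
it and measurably drops recovery below acceptable power). The log2 fold
change is `mean(A) − mean(B)`; the p value is a paired Student's t across
replicate pairs (pairing by replicate index, the only pairing key the
design provides); one-way ANOVA (`anova_oneway`) is provided for contrasts
with more than two groups. Significance is gated on raw `p < 0.01` — the
threshold the headline counts use — with Benjamini–Hochberg adjusted values
reported alongside (`bh_adjust`, the classical step-up). Zero-variance
differences are flagged degenerate rather than given a p value.

**qPCR.** `qpcr_relative_expression()` implements the ΔΔCt (Livak) model
against a housekeeping reference (18S rRNA in the assays this mirrors),
retaining per-replicate ΔCt values for paired testing.

# Cohort set algebra

`run_all_comparisons()` produces the full comparison grid: 6 cohort pairs ×
2 tissues + 4 tissue contrasts = 16 comparisons (all contrasts are computed
uniformly, including any a report happens to omit). For the Venn view
relative to the uninfected susceptible baseline (S−), a miRNA is
"upregulated in X" iff significant *and* log2FC > 0 — no fold-change floor
is applied since none is defined for the original analysis. miRNAs
differential in both R+ and S+ (same tissue, same direction) are excluded
from both sets *before* partitioning (`exclude_shared_duplicates`), matching
the narrative order of the analysis this reproduces; the partition is the
standard 7-cell decomposition. Partition recovery is scored as the fraction
of (miRNA, set) membership indicators agreeing between the recovered and the
truth-derived partition, over miRNAs present in either.

# UTR annotation

`find_orfs()` scans the forward strand only — contigs are mRNA-sense
transcripts — walking every ATG codon-by-codon to the first in-frame stop
({TAA, TAG, TGA}); ATG-only starts; candidates containing N are skipped.
`min_len_codons` defaults to 30 (a common de-facto threshold; configurable —
the original analysis states none). The reference ORF bounding the 3'UTR is
the *complete ORF with the 3'-most stop* (ties: longer, then more upstream),
because the UTR is defined as sequence downstream of all confirmed coding
sequence; `rule = "longest"` is available. Contigs without a complete ORF
yield no UTR rather than being treated as all-UTR. UTRs shorter than 7 nt
(the seed length) are dropped.

# Target prediction

**Seeds.** The seed is miRNA positions 2–8 from the 5' end, matched in UTRs
as its DNA reverse complement. A protocol can also be phrased as "reverse
complement the whole miRNA and take positions 2–8 of that" — which selects
the miRNA's 3' end instead; both interpretations are implemented
(`interpretation = "mirna_seed"` default, `"literal_revcomp"` variant), and
the default follows the canonical seed definition. Matching is exact;
G:U wobbles do not count toward seed complementarity.

**Hybridization MFE.** `duplex_mfe()` minimizes, over all intermolecular
hybrid structures (antiparallel order-preserving matchings; no
intramolecular pairs, no pseudoknots), the nearest-neighbor energy

> initiation + Σ stack(doublet) over both-strand-adjacent consecutive pairs
> + Σ [loop_open + loop_extend · u] over bridged gaps (u = total unpaired
> nucleotides on both strands),

with allowed pairs {AU, UA, CG, GC, GU, UG}. Stack free energies are the
published Turner 2004 RNA/RNA values (including G:U), shipped as an
editable TSV (`extdata/stack_energies_turner2004.tsv`); initiation is the
Turner duplex initiation +4.09 kcal/mol; the affine loop penalties (open
3.0, extend 0.5 kcal/mol per nt) are package choices that keep the dynamic
program and its enumeration oracle tractable — asymmetric loops are
penalized by total unpaired count, with no tandem-mismatch tables. Absolute
MFEs are therefore model-dependent; every correctness claim about them is
oracle-based (exhaustive enumeration), not a comparison to any published
energy table output.

The DP state is "structure whose 3'-most miRNA pair is (i, j)". Loop
transitions use per-row suffix minima of `E + loop_extend·(j' − i')`, making
the whole computation O(M·L·M); adjacency is handled separately so that
stacked pairs always receive the stack term. With `require_seed = TRUE`
(the default in `predict_targets()`), only structures in which miRNA
positions 2–8 form a contiguous Watson–Crick helix are admissible —
"complete seed complementarity" — implemented as transition restrictions,
and windows admitting no such structure return `NA`. Reported structures
always re-sum to the reported MFE (`duplex_energy()`), and the optimum is
bounded above by the seed-helix-only energy.

**Windows and threshold.** Each seed match is evaluated on the match ± 30 nt
of UTR context (truncated at UTR bounds). Sites are retained at
`mfe ≤ −20 kcal/mol` by default — deliberately strict, prominently
configurable (`mfe_threshold`), and the retained set is monotone in it. The
original confirmation cutoff is unknown; do not interpret the default as
its reconstruction. `summarize_by_process()` replaces a database lookup
with a user-supplied contig → process table and counts distinct target
contigs per process, tallying unannotated contigs explicitly.

Whether the original analysis restricted matches to UTRs or scanned whole
contigs is not stated; this package scans UTRs only, per the stated
definition of candidate regions.

# Pipeline and reproducibility

`run_pipeline()` chains the stages (simulate → normalize → de / sets →
annotate-utr → targets → report) against one config (R list or YAML), with
every tabular artifact carrying a `#`-prefixed header (package version,
config hash, RNG seed — no timestamps), so a rerun with the same config is
byte-identical. A thin command-line wrapper ships at
`inst/scripts/gallmir`. Stage inputs are read back from the artifact
directory, so externally produced files in the same TSV/FASTA dialects can
replace the simulated ones at any stage boundary.

# Problem sizes used by the test suite

Oracle equivalence: 500 random (miRNA, site) pairs ≤ 10 nt against
exhaustive enumeration; 500 random 1-kb contigs against the brute-force
codon walk; 1,000 UTRs × 50 patterns against naive search; 1,000 random
p-vectors against the step-up definition. Calibration: one null array of
2,000 miRNAs (type-I band = 3 binomial SDs around 0.01) and 20 replicate
null arrays for the BH false-discovery bound. Power: the default study
(240 planted effects). These sizes were chosen so the full suite runs in a
few minutes while every Monte-Carlo bound retains comfortable margins.

# Known limitations

* The energy model is a compact stacking + affine-loop approximation; it
  ranks sites sensibly but its absolute MFEs are not comparable to
  full-featured folding tools.
* Normalization assumes most probes are not differential at any given
  intensity; fixtures with extreme differential density at the intensity
  edges will see partial effect absorption (mitigated, not eliminated, by
  trimmed fitting).
* The paired test at n = 3 has 2 degrees of freedom; detection at
  `p < 0.01` requires |t| > 9.9, so power claims are meaningful only for
  large effects, exactly as simulated.
* Replicates are modeled independent; the original platform's replicate
  correlation structure is unknown.
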