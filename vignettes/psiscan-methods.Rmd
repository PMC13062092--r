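---
title: "Methods: pseudouridine calling from bisulfite deletion signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudouridine calling from bisulfite deletion signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiscan)
```

## The measurement model

Bisulfite treatment converts pseudouridine (Ψ) into an adduct that reverse
transcriptase skips, producing a deletion in the cDNA at the modified
position. At a uridine carrying Ψ in a fraction *s* of transcripts, with
chemical/enzymatic conversion efficiency *c* and background indel rate ε,
the deletion count in a treated library of depth *n* is modelled as

> del ~ Binomial(n, s·c + ε),

and in the untreated control as Binomial(n, ε). The treated-minus-untreated
difference in deletion ratio therefore estimates **s·c**, not *s*:
incomplete conversion is confounded with stoichiometry. Everything the
package reports as a "Ψ level" is this product; we keep the convention
because it is what the assay measures.

Two practical complications shape the callers:

1. **Background indels.** Sequencing and alignment noise gives every
   position a small deletion rate in both conditions. The isolate filters
   bound it directly (untreated ratio < 1 %).
2. **Strain heterogeneity.** In a metatranscriptome, reads from related
   strains carry true genomic indels relative to the reference genome.
   These deletions appear **in both conditions at the same positions**, can
   exceed 1 % easily, and must not be called. The community mode therefore
   replaces the absolute untreated bound by a fold-change requirement plus
   Fisher's exact test on the 2×2 table (deletions / non-deletions ×
   treated / untreated).

## Filters and their comparison conventions

Isolate mode (defaults in `call_thresholds()`): depth ≥ 20 in both
conditions, treated deletion count ≥ 5, treated ratio ≥ 0.05, untreated
ratio **strictly** < 0.01; a site becomes high confidence with support in
≥ 2 samples. Community mode (`community_thresholds()`): depth ≥ 20 both,
treated deletions ≥ 5, treated ratio ≥ 0.02, treated ≥ 2 × untreated,
Fisher p < 0.01; genomes processed only above 20× mean coverage (strict >)
in both conditions. The inclusive/exclusive choices follow the filter
wording exactly and the tests pin each boundary (depth 19/20, deletions
4/5, ratios 4.9/5.0 %, untreated 0.9/1.0 %).

One consequence of the strict untreated rule is worth stating because it is
visible in every synthetic benchmark at fixed depth: with depth exactly
200 and background ε = 0.002, the untreated deletion count is ≤ 1 (ratio
0.5 % < 1 %) with probability
`pbinom(1, 200, 0.002)` ≈ 0.939, while 2 deletions land exactly on 1.0 %
and fail. A true site therefore passes the untreated filter in *both* of
two samples with probability ≈ 0.88, which is the high-confidence recall
the acceptance benchmark measures (≈ 88 %, with zero false positives). This
is a property of the published filter at that depth and background, not of
the implementation; raising depth off the 1 %-boundary multiples, relaxing
the bound, or adding samples all move recall toward 1.

The Fisher test defaults to the one-sided `greater` alternative because BS
chemistry can only add deletions; the two-sided variant is available since
the sidedness is a genuine modelling choice. An untreated ratio of exactly
0 passes the fold rule as written (no pseudocount is injected).

## Motifs and PUS preferences

Motifs are 5-mers on the transcribed strand with the Ψ centered (minus
strand: reverse complement of the mirrored window, rendered in ACGU). Only
sites with treated deletion ratio > 6 % enter the table — that figure is
the source dataset's median deletion ratio, a property of that data, so it
is a configurable constant here, not recomputed — and motifs seen fewer
than 6 times are dropped. Per motif, WT and PUS-mutant deletion ratios are
compared with a two-sided Wilcoxon rank sum test (exact null for combined
n ≤ 20 without ties, midrank normal approximation with continuity
correction otherwise; fully tied data return p = 1), with
Benjamini–Hochberg adjustment across the motif family of one mutant.
Consensus discovery is out of scope: `write_meme_fasta()` emits the gated
windows for external tools.

## Expression, Ψ-strength and PUS assignment

TPM uses a pseudocount of one on every gene (also in the decay module, so
a single TPM definition is used throughout). Ψ-strength is the sum of
deletion ratios over a transcript's called sites; a gene is assigned to a
PUS when the WT-minus-mutant strength difference is ≥ 0.05 in **every**
replicate pairing (a 1e-9 tolerance absorbs floating-point representation
at the printed boundary). The non-substrate control set requires TPM > 20
in all samples and zero calls anywhere, so absence of calls is unlikely to
be a coverage artifact.

## RIF-seq: spike-in normalization and decay fitting

After rifampicin arrest, libraries are normalized with ERCC spike-ins via
the per-spike constant k = (ERCC_n/ERCC_0)/(Total_n/Total_0), using the 25
spike-ins most abundant at timepoint 0 (ties broken lexicographically); the
per-timepoint factor is the geometric mean of k. Because both numerator and
denominator are ratios of library totals, a pure sequencing-depth change
cancels in k — the factor measures the drift of the mRNA pool **relative to
the constant spike-in input**. That dictates the simulator's two scaler
knobs: `pool_scalers` multiply gene expectations only (the quantity k
recovers, as its reciprocal), while `depth_scalers` multiply genes and
spikes alike and must leave k unchanged; the tests assert both behaviours.
For abundance trajectories we divide TPM by the factor, which removes the
TPM inflation a shrinking pool causes. This assumes spike-ins are a small
fraction of the library (~1 % in the simulations, as in practice); with a
large spike share the count-based k and the rate-based TPM no longer
cancel exactly.

Decay follows a delayed first-order exponential, A(t) = A0·e^(−λ(t−t0)₊):
constant during a lag t0, exponential afterwards. With five timepoints
(0, 3, 6, 12, 24 min) a continuous t0 is not identifiable, so fitting is a
deterministic grid search: t0 candidates are the observed timepoints up to
the second-largest plus their midpoints; each candidate gets a closed-form
least-squares fit of log A on (t − t0)₊; smallest residual sum of squares
wins, ties to the smaller t0. Half-life is ln 2/λ. Fits with λ ≤ 0 are
`no_decay`; fits with r² < 0.7 (log scale) are `poor_fit` — an automated
surrogate for the manual inspection the protocol calls for, chosen so a
clean two-phase series passes and a scrambled one does not. `rif_halflives`
censors timepoints whose raw count falls below 1 before fitting, because
at zero counts the log-abundance is the pseudocount floor, which would
flatten the tail of fast-decaying genes; zero abundances are otherwise
rejected rather than ε-padded.

## What the simulators emulate — and what they do not

`simulate_isolate` draws binomial deletions at fixed or negative-binomial
depth with conversion efficiency defaulting to 0.9. `simulate_community`
adds condition-shared indels: a fraction of positions (default 5 %)
receives a shared deletion probability η in both libraries, which is the
statistical signature of strain heterogeneity; genome depth scales with
relative abundance. `simulate_rifseq` draws Poisson counts from the decay
model with constant-input spike-ins; benchmarks add a stable background
pool (300 genes) so the spike share stays realistic and the aggregate pool
does not collapse — in real bacteria most of the library decays far slower
than the 1–20 min test genes.

Not emulated: alignment and realignment artifacts (left-alignment of
homopolymer deletions is handled only as a flag: runs ≥ 2 set
`homopolymer_flag`, since the exact site within a U-run is genuinely
ambiguous), sequence-dependent conversion efficiency, RNA structure
effects on BS accessibility, multi-mapping between related genomes, and
library-preparation biases. Passing the synthetic benchmarks therefore
shows the statistical machinery is correct under the stated model, not
that real-data artifacts are handled; the upstream realignment step the
pipeline expects is what keeps the model approximately true in practice.

Benchmark sizes (chosen to exercise the operating points, and stated here
as the package's own choices): 100 planted sites at depth 200 over 20 seed
replicates for isolate recovery; three 20-kb genomes at ~180–400× for
community specificity; 200 decaying genes plus 300 stable background genes
and 30 spike-ins for RIF-seq recovery.

## Known limitations

* Ψ level is s·c; absolute stoichiometry requires an external estimate of
  conversion efficiency.
* Positions inside U homopolymers are flagged, not resolved.
* rRNA/tRNA canonical numbering is not mapped; sites are reported in
  genome coordinates.
* The community caller treats the per-genome pileup as authoritative;
  read-assignment ambiguity between close genomes is upstream's problem.
* GC content is taken from the genome catalog (with a FASTA recompute
  fallback), matching how community genomes are usually described.
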