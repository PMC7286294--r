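---
title: "tadapipe: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadapipe: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

Targeted DamID (TaDa) reads out protein–DNA association through adenine
methylation of GATC motifs by an *E. coli* Dam fusion protein, digested with
DpnI and sequenced. The native resolution unit is therefore the **GATC
fragment**: the interval between two consecutive DpnI cut sites. `tadapipe`
tiles each chromosome into these fragments (cut midpoint at motif start + 2,
the blunt GA^TC cut; coordinates 0-based half-open throughout, converted
only at GFF3/BED/bedGraph boundaries) and resolves every downstream signal
onto them.

Per sample, fragment counts are scaled to reads per million (RPM) and the
central quantity is the per-fragment ratio

\[ r_f = \log_2\frac{\text{fusion}_f + \psi}{\text{Dam}_f + \psi}, \]

with a symmetric pseudocount \(\psi\) (default 1 RPM). The Dam-only channel
normalises for accessibility and copy number; with a Dam–Pol II fusion,
\(r_f\) over a gene body is a proxy for transcription. The ratio is computed
as a difference of logarithms so that swapping the channels negates it
exactly in floating point. \(\psi = 1\) RPM is a declared stand-in for the
upstream mapping pipeline's normalisation, which the source study delegates
to a previously published workflow; no claim of numerical equivalence with
that workflow is made.

# Transcribed-gene calling

A transcript's score is the mean \(r_f\) over the fragments intersecting its
span; a gene inherits the values of its transcript with the most significant
FDR, and is called **bound** when gene FDR < 0.01 (strict) and gene score
>= 0.2 log2 units (inclusive) — the published thresholds.

The FDR is an empirical permutation FDR. For each of \(P\) (default 100)
seeded permutations, fragment values are shuffled uniformly genome-wide and
all transcripts re-scored. For an observed score \(s\),

\[ \widehat{FDR}(s) = \frac{\mathbb{E}_{perm}\,\#\{\text{null scores} \ge s\}}
                          {\#\{\text{observed scores} \ge s\}}, \]

clipped to [0, 1]. Regularisation makes the FDR monotone non-increasing in
the score: each transcript receives the minimum raw FDR over all thresholds
at or below its score (the Benjamini–Hochberg-style direction — calling at a
more lenient threshold can only be adopted if it improves the estimated
FDR). The uniform value shuffle is the simplest exchangeability-based null.
The original Perl analysis scripts this pipeline emulates do not document
their FDR construction, and equivalence with them is not claimed.

**Why the calling pipeline scores transcripts unweighted.** The natural
per-bp score is the intersection-length-weighted mean, and
`transcript_score()` implements exactly that. For the permutation FDR,
however, length weighting is the wrong default: fragment lengths are roughly
exponential, so the weights within a transcript concentrate on a few long
fragments (effective sample size ~2–7 where 15–30 fragments are covered),
while the shuffle redistributes *values* irrespective of the *lengths* that
generated them. Long-fragment weights then amplify extreme values from
low-coverage fragments in the null, its tail fattens, and a 1% FDR becomes
unreachable — in seeded experiments literally zero genes could ever be
called. A permutation test requires the statistic to be exchangeable under
the null; the unweighted fragment mean restores that, so
`call_params(weighted = FALSE)` is the default and weighting remains a
configuration switch.

# Differential occupancy and unique sets

Cell types are compared by subtracting log2-ratio tracks replicate-by-
replicate. The replicate difference tracks are averaged (chosen over
intersection for power and determinism; intersection-style analyses can be
reproduced by running replicates separately) and analysed exactly like a
primary profile. Because DamID ratios can be negative, a significant gene is
only reported **enriched** if it is also bound in the numerator dataset.

Uniquely enriched in X: enriched in X vs Y *and* X vs Z. Uniquely depleted
in X: enriched in Y vs X *and* Z vs X, additionally requiring boundness in
both Y and Z (a factor present in both other types and absent from X). No
constraint is imposed between the two non-focal types. Transition tables
track every gene that ever enters a unique set through all stages, with
state `none` where absent.

# Peak calling

Candidate TF-binding peaks are maximal runs of >= 2 consecutive fragments
with \(r_f\) above an entry threshold \(\theta\) (default 0; the original
program's threshold is unpublished). The peak statistic defaults to the
**sum** of member values rather than the mean: under the value-shuffle null
a pair of high values re-assembles far more easily than an entire run, so
the mean statistic cannot separate a planted multi-fragment peak from
chance adjacency, while the sum demands that the null re-assemble
essentially the whole run. (The source study never names its statistic;
mean and min remain available.) Peak FDRs use the same empirical
construction as gene calling with S (default 1000) shuffles; significance
is FDR < 1e-4, the published 0.01% cutoff. Significant peaks present in
all replicates (>= 1 bp overlap, chained components merged, union span
kept) form the consensus; genes overlapping a peak, or the nearest
non-overlapping gene within 5 kb per side with no gene span in between,
are assigned.

A caveat the synthetic experiments make explicit: with only ~15 observed
peaks the empirical FDR has a floor of (null rate)/(observed count), and a
0.01% threshold is only attainable when the observed peak count is in the
hundreds-to-thousands, as in real genome-scale libraries. The package
asserts this honestly rather than relaxing the threshold.

# CATaDa accessibility

The Dam-only channel doubles as a chromatin accessibility readout.
Replicates are RPM-normalised then averaged (per-replicate analysis is
available by passing single-element lists). Robust between-condition changes
are maximal runs of >= 3 consecutive fragments whose RPM difference exceeds
10 RPM strictly, with a consistent sign — a difference "peak" of mixed signs
is not a coherent accessibility change. Gene loci are extended 5 kb upstream
and 2 kb downstream, strand-oriented (the standard reading; an unstranded
switch exists), clipped to the chromosome.

# scRNA-seq overlap mining

Gene rows are extracted from a MatrixMarket counts matrix; cells with fewer
than 3 transcripts for the gene are excluded everywhere (extraction, means,
overlaps) — the published filter applied consistently. Per-type means are
over *expressing* cells (the extraction-then-analyse order of the published
code; all-cell denominators are a switch) and ratio-normalised to
cholinergic. Overlap matrices count shared expressing cells among cells of
one type, with Jaccard fractions alongside.

# The synthetic world

The generator plants known truth and replays the full analysis over it. Its
defaults are the package's stated experimental world:

| parameter | default | rationale |
|---|---|---|
| genome | 1 chromosome, 3.5 Mb | smallest size that holds 200 genes of realistic span |
| GATC spacing | exponential, mean 250 bp (>= 8 bp) | fly-like motif density |
| genes | 200, 8–16 kb, 1–3 isoforms covering >= 80% of the span | gene-body Pol II scoring needs tens of fragments per transcript; TaDa-profiled neuronal genes are large |
| accessibility baseline \(a_f\) | log-normal, sdlog 0.5, shared across types | accessibility is broadly similar between neuron types |
| expressed effect | fusion weight \(a_f 2^{\beta x_f}\), \(\beta = 1\) | \(x_f\) = fraction of fragment covered by expressed genes |
| shared expressed genes | 40% of genes, all types | neurons express about half the genome |
| planted unique genes | 20 enriched + 10 depleted per type | recovery targets |
| counts | NB, dispersion 0.2, 1e5 reads/sample, 3 replicates | overdispersion is the norm for sequencing counts; Poisson as dispersion → 0 |
| TF peaks | 15 runs of 3–5 fragments, effect 2.0, 2 replicates, 2e5 reads | the TF experiments' ~10M reads scaled to the toy genome |
| scRNA | NB capture mean 0.5, planted TFs at 8x in disjoint 40-cell cholinergic subpopulations | "mostly non-overlapping" co-expression structure |

Background bases are drawn from {A, C, G} so a GATC can only occur where
planted — every cut site is known. All generators are byte-deterministic
under (config, seed); per-stream seeds derive from one master seed and a
label.

The genome geometry deviates deliberately from an earlier 1 Mb draft of
this generator: at 1 Mb, 200 genes are forced down to 1.5–4 kb
(6–16 fragments), and at the pinned depth and dispersion the permutation
FDR cannot separate a \(\beta = 1\) effect from its own null — zero genes
are ever called. A stated world in which the core analysis is degenerate
validates nothing, so the default world uses genes long enough to carry the
statistic the method actually relies on.

**What a green test does and does not establish.** The generator emulates
the *statistical shape* of TaDa data: fragment-level overdispersed counts,
a shared accessibility baseline, coherent gene-body enrichment, planted
peaks, sparse planted co-expression. It does not emulate mappability,
GC/copy-number artefacts, methylation spreading between adjacent GATCs,
isoform-specific transcription, or real genome sequence composition.
Recovery of planted truth shows the inference machinery is correct and
calibrated at desk scale — not that the biological conclusions of any real
dataset would be reproduced.

# Numerical choices and degenerate inputs

- FDR comparisons: strict `<` on thresholds (0.01, 1e-4); score threshold
  inclusive `>=` 0.2; accessibility strictly `>` 10 RPM. Ties in the
  gene reduction break by higher score, then lexicographic transcript id.
- All-zero count profiles are an error at RPM normalisation (no library
  size), not silently zero.
- Ambiguity codes never match GATC (conservative fragmentation).
- Genes without annotated transcripts receive a single transcript equal to
  the gene span so ncRNA entries flow through transcript-level scoring.
- Empty consensus/assignment results are empty tables with stable schemas,
  not errors.

# Known limitations

- The permutation null shuffles fragment values without preserving local
  autocorrelation; segment-preserving nulls would be stricter for broadly
  autocorrelated signals.
- Transcript scoring uses spans, not spliced structure, matching gene-body
  Pol II signal.
- At small observed peak counts the 0.01% empirical peak FDR is
  unattainable by construction (see above); interpret peak results at desk
  scale accordingly.
- Sensitivity of unique-set recovery at the default world is ~0.87 with
  precision 1.0: the depleted class pays the numerator-bound filter twice
  (once per non-focal type). This is a property of the stated thresholds at
  desk-scale depth, not a tunable of the implementation.
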