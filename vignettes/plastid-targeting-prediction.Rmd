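---
title: "Predicting plastid-targeted proteins from bipartite presequences"
author: "ASAFindR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plastid-targeted proteins from bipartite presequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ASAFindR)
```

## The biological problem

Diatoms and other algae whose plastids arose by secondary endosymbiosis of
a red alga surround those plastids with three or four membranes, the
outermost usually continuous with the endoplasmic reticulum. Nucleus-encoded
plastid proteins therefore travel through the secretory pathway first: their
N-terminal presequence is *bipartite*, an ER-type signal peptide followed
immediately by a transit peptide. The transit peptide almost always starts
with a phenylalanine — the "+1" position just downstream of the signal
peptidase cleavage site — embedded in the conserved "ASAFAP" motif, and is
rich in hydroxylated residues (S, T) with a net positive charge.

This package classifies protein sequences into four classes given (a) the
sequences, (b) an external signal-peptide predictor's calls (the package
parses predictor output; it never runs the predictor), and (c) an
information-weighted scoring matrix describing the cleavage-site motif.

## The scoring model

**Matrix construction.** Training data are aligned 25-residue windows
spanning the cleavage site, indexed −5..−1 (last signal-peptide residues)
and +1..+20 (first transit-peptide residues); there is no position 0. For
column $j$ with empirical residue frequencies $f(j,a)$ over the 20 canonical
residues, the information content in bits is

$$R(j) = \log_2 20 - H(j) - e(n), \qquad
  H(j) = -\sum_a f(j,a)\,\log_2 f(j,a),$$

with the optional small-sample correction $e(n) = 19/(2 \ln 2\, n)$
(Schneider–Stephens sequence-logo convention; $n$ is the per-column count of
canonical residues after removing ambiguity letters, the only well-defined
choice when columns differ in `X` content). The matrix entry is
$M(j,a) = f(j,a)\,R(j)$, so each column sums to $R(j) \le \log_2 20 \approx
4.32$ bits. Negative corrected information is clamped to zero: a score
contribution cannot be negative under the frequency-times-information
definition. The correction defaults to **off**, which preserves the clean
analytic identities used in the tests; it is exposed as a flag. Ambiguity
letters (X, B, Z, J, U, O, `*`) are excluded from counts and score 0 at
lookup — no penalty for unknowns can be justified.

**Window score.** A candidate cleavage site is described by the 1-based
index $m$ of the first mature residue. Column $j<0$ addresses sequence
position $m+j$, column $j>0$ addresses $m+j-1$. The window score is the sum
of matrix entries at the addressed residues; positions beyond either
sequence end contribute 0 and set a truncation flag.

**Cleavage-site relocation.** External predictors misplace the cleavage
site by a residue or two often enough to matter, so the five candidate
sites at offsets −2..+2 around the predictor's site are each scored with
the full 25-column matrix and the maximum wins. Ties prefer offset 0
(agreement with the predictor gates high confidence, so ties must not
spuriously demote records), then the smaller absolute offset, upstream
before downstream. A `core5` mode restricted to columns −2..+3 is available
for comparison; `full25` is the default because the whole motif, not just
the residues flanking the scissile bond, is informative.

**Transit-peptide score and decision.** The transit-peptide score is the
window score restricted to columns +1..+20 at the relocated site — the
cleavage site itself is shared by all secretory proteins and is therefore
not evaluated. Classification then follows a fixed decision tree:

1. predictor negative → *"not plastid, SignalP negative"*;
2. first residue of the relocated transit peptide not in {F, W, Y, L} →
   *"not plastid, SignalP positive"* (candidates for ER retention or other
   secretory targeting);
3. relocated site equals the predictor site (offset 0) **and** transit
   score strictly greater than the cutoff (default 2) →
   *"plastid, high confidence"*;
4. otherwise → *"plastid, low confidence"*.

The cutoff comparison is strict, so a transit score of exactly 2 is low
confidence. The +1-residue check uses the relocated site, not the
predictor's. Stop characters (`*`) truncate the sequence with a warning.

## Evaluation

Predictions are compared against labeled references under two
positive-class definitions — *high confidence only* and *high or low
confidence* (both "not plastid" classes count as predicted negative) —
using the standard sensitivity, specificity, and Matthews correlation
coefficient. A zero MCC denominator returns 0 by convention; zero
denominators for sensitivity or specificity are errors. ROC points are
(FPR, TPR); a perfect predictor maps to (0, 1). Transit-score histograms
and a descending rank curve expose the characteristic sharp score drop
where the +1 phenylalanine is lost.

## Gene-catalog optimization

Plastid-targeting prediction is only as good as the N-termini of the gene
models, so the package includes a toy-scale catalog optimizer: each CDS
model is extended in frame upstream to the first ATG (aborting, unchanged,
if an in-frame stop or the sequence start intervenes — the stop-guard
prevents biologically impossible extensions, which the bare "first ATG"
rule would allow) and downstream to the first stop codon; models spanning
more than 10 kb are assumed wrong and dropped (strict comparison, so
exactly 10 kb is kept); models must start with ATG, contain no internal
stop, end with a stop, and have EST support (consumed as an input flag —
EST alignment is out of scope); one representative per locus is kept.

Design choices where the procedure is genuinely underdetermined: a *locus*
is a single-linkage cluster of same-chromosome, same-strand models with
overlapping genomic spans (the simplest testable reading of "a given
position on the genome"); the longest valid model wins, identical-protein
ties resolve to the curated (`jgi_filtered`) model, and exact duplicate
proteins are removed; "length" for the 10 kb filter is genomic span.
Proteins from models without a chromosome assignment are rescued iff their
maximum identity to every selected protein is below 0.95, with identity =
matches / alignment length under global alignment scoring match 1,
mismatch 0, unit gap cost (no aligner or denominator is canonical here;
this is the simplest fully specified scheme). Extension applies to all
inputs by default and can be disabled. Input CDS spans must be codon
multiples since the reading frame is anchored at the model start. The whole
pipeline is idempotent: re-running it on its own output changes nothing.

## The synthetic-data generator

Real reference sets require curated localization data and a licensed
signal-peptide predictor, so the package ships a seeded generator that
emulates their structure:

* **positives**: Met + a hydrophobic signal-peptide core (10–20 residues)
  + a 25-position cleavage region sampled from a ground-truth probability
  matrix + a transit tail (10–40 residues, S/T/R/K-rich, D/E-poor, net
  positive) + a background mature domain (80–250 residues);
* **secretory negatives**: same signal-peptide architecture, but +1..+20
  drawn from background composition with the +1 residue forced outside
  {F, W, Y, L};
* **non-secretory negatives**: no signal peptide at all;
* matched mock predictor records carrying the true cleavage site,
  perturbed by ±1 with probability 0.1 by default (external predictors
  agree with manually curated motifs roughly 9 times in 10), plus
  format-valid mock scores so both parser dialects can be exercised.

The ground-truth matrix mimics the cleavage-site motif at consensus
strength: L/V-rich at −5/−4 (the hydrophobic core extends to there, which
also keeps the motif from being self-similar under small shifts), A .75 /
S .70 / A .75 at −3..−1, F .85 at +1 with W/Y/L minorities, A .65 at +2,
P .55 at +3, transit composition beyond. It is a synthetic fixture
constant, deliberately **not** any published matrix. With these defaults a
matrix learned from 500 generated windows classifies a 200+200+200
benchmark (exact mock sites) with high-or-low sensitivity and specificity
≥ 0.90 — verified across several disjoint seed pairs at design time.

What passing these tests does *not* show: real sequence sets have
phylogenetic correlation between training windows, motif strength varies
between lineages, real predictor errors are not independent ±1 shifts, and
real negatives include hard cases (ER-retained proteins with F at +1).
Accuracy numbers on the synthetic benchmark therefore characterize the
implementation, not expected field performance.

The toy-genome generator plants full ORFs (interiors free of in-frame ATG
and stop codons, so extension scans cannot be diverted) and emits models
truncated in frame at both ends, an over-long model, an identical-protein
duplicate pair, a reverse-strand truncated model, a 16-nt worked example
whose model must extend to the protein `MKF`, and unmapped paralogs at
identity 1.0 and exactly 0.75 — each with its intended fate recorded.

## Numerical choices and problem sizes

All scores are plain double sums of at most 25 matrix lookups; agreement
with an independent brute-force loop is asserted to 1e−9 on 1000 random
instances. The default test and validation scales — 500 training windows,
600-sequence benchmarks, 5000-window frequency checks, a ~12 kb toy
genome — were chosen so the whole suite completes in well under a minute
on one CPU while keeping binomial noise on the benchmark statistics around
one percentage point. Every stochastic step takes an explicit seed; the
command-line `simulate`/`predict` pipeline is byte-reproducible apart from
provenance comment headers. FASTA outputs carry `;`-prefixed provenance
comments (the only comment syntax FASTA parsers tolerate); tabular outputs
use `#`.

## Known limitations

* The shipped matrix is a synthetic stand-in; real use requires a matrix
  built from curated presequences of the organisms of interest
  (`buildMatrix()` accepts any 25-mer alignment).
* Only the neural-network-style short format and a generic TSV are parsed;
  calls from other predictor versions must be converted to the TSV dialect.
* The decision tree knows nothing about mitochondrial targeting or
  sub-compartments beyond the four classes.
* The catalog optimizer models single-CDS genes only — no splicing — and
  treats EST support as given.
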