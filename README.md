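# ASAFindR

Prediction of nucleus-encoded, plastid-targeted proteins in diatoms and
other algae with secondary plastids of the red lineage.

## The problem

Plastids acquired by secondary endosymbiosis of a red alga sit behind
three or four membranes, usually with the ER outermost. Nucleus-encoded
plastid proteins therefore carry a *bipartite* N-terminal presequence: an
ER-type signal peptide followed immediately by a transit peptide. The
transit peptide almost always begins with phenylalanine — the conserved
"ASAFAP" motif spans the signal-peptidase cleavage site — and is rich in
hydroxylated residues with a net positive charge. ASAFindR classifies
protein sequences into four classes from (a) the sequences, (b) an
external signal-peptide predictor's calls (SignalP 3.0 NN short format or
a generic TSV; the package parses output, it never runs the predictor),
and (c) an information-weighted cleavage-site scoring matrix.

It is intended for researchers annotating genomes or candidate gene lists
of diatoms, cryptophytes, haptophytes and related lineages.

## The method

A scoring matrix is built from aligned 25-residue windows spanning the
cleavage site (positions −5..−1 and +1..+20; no position 0). Each entry is

    M(j, a) = f(j, a) · R(j),     R(j) = log2(20) − H(j) − e(n)

the empirical residue frequency weighted by the sequence-logo information
content of the column (optional small-sample correction `e(n) = 19 / (2
ln2 n)`, off by default). For each predictor-positive sequence the five
candidate cleavage sites at offsets −2..+2 around the reported site are
scored with the full matrix; the maximum defines the relocated site. The
transit-peptide score sums columns +1..+20 only. Classes:

1. predictor negative → `not plastid, SignalP negative`
2. relocated +1 residue ∉ {F, W, Y, L} → `not plastid, SignalP positive`
3. offset 0 **and** transit score > 2 (strict) → `plastid, high confidence`
4. otherwise → `plastid, low confidence`

The package also provides evaluation statistics (sensitivity, specificity,
MCC, ROC points, transit-score histograms), a toy-scale gene-catalog
optimizer (in-frame ORF extension, 10 kb filter, validity checks,
per-locus selection, <95 %-identity rescue of unmapped models), and a
seeded synthetic-data generator for benchmarking without external data.

## Worked example

```r
library(ASAFindR)

# the packaged matrix is a synthetic stand-in built from generated
# training windows -- use a matrix from curated presequences in real work
mat <- readMatrix(system.file("extdata", "synthetic_default_matrix.tsv",
                              package = "ASAFindR"))

b <- generateBenchmark(syntheticSpec(seed = 7, nPositive = 2L,
                                     nSecretory = 1L, nNonsecretory = 1L,
                                     sitePerturbProb = 0))
pred <- classifyProteins(b$sequences, b$signalp, mat)
pred[, c("id", "signalp_pos", "asafind_pos", "offset", "cleavage_score",
         "plus1_aa", "transit_score", "prediction")]
```

```
        id signalp_pos asafind_pos offset cleavage_score plus1_aa transit_score
1 pos_0001          26          26      0          6.010        F        5.8313
2 pos_0002          19          19      0         11.668        F        6.2604
3 sec_0001          26          26      0          5.864        T        0.7235
4 cyt_0001          NA          NA     NA             NA     <NA>            NA
                     prediction
1      plastid, high confidence
2      plastid, high confidence
3 not plastid, SignalP positive
4 not plastid, SignalP negative
```

The two plastid-type sequences keep their reported cleavage site
(offset 0), show phenylalanine at +1 and transit scores well above the
cutoff of 2, so both are called high confidence. The secretory protein has
an equally good signal-peptide cleavage site but threonine at +1 and a
near-zero transit score; the cytosolic protein was predictor-negative.

The same analyses run from the shell via the bundled CLI
(`inst/scripts/asafind.R`):

```sh
Rscript inst/scripts/asafind.R predict \
  --fasta proteins.fasta --signalp signalp_short.txt \
  --matrix matrix.tsv --out predictions.tsv
```

with further subcommands `build-matrix`, `evaluate`, `optimize-catalog`
and `simulate`.

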