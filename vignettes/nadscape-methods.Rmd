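---
title: "Models and methods behind nadscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nadscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadscape)
```

# The measurement and its statistical structure

NAD captureSeq compares two sequencing libraries made from the same RNA.
In the **S** library (+ADPRC), the enzyme ADPRC marks the NAD moiety of
NAD-capped 5'-ends so they can be biotinylated and pulled down; the **N**
library omits the enzyme and measures unspecific background binding.  A
transcript species is NAD-capped when its reads are *enriched* in S over
N.  Because the protocol ligates the 5' adapter directly to the captured
end, read 5'-ends identify transcription start sites (TSSs) at
single-nucleotide resolution, which is what makes the downstream TSS,
promoter-motif and transcript-leader analyses possible.

`nadscape` implements the full downstream path: 5'-UTR-window counting,
enrichment calling, NAD-modification-ratio estimation, TSS cluster and
trend analysis, sharp-A calling and promoter matrices, per-read 5'/3'
geometry, and decapping-enzyme hierarchy inference — together with a
synthetic-data generator that plants known truth so every stage can be
validated quantitatively.

# Coordinate conventions

All internal coordinates are 0-based; single positions (TSS, TLS =
translation start site, TES = transcript end site) denote the base
itself.  File formats keep their native conventions (GFF3 1-based
inclusive, BED-like tables 0-based half-open) and are converted exactly
once at the I/O boundary.  "Upstream", "downstream" and transcript-leader
(TL) lengths are always computed in transcript orientation, so a single
code path serves both strands; the test suite checks that mirroring the
genome (reverse complement plus strand flip) leaves every statistic
unchanged.

# Counting and enrichment

Reads are assigned to a gene when their 5'-end falls inside the window
TLS − 120 to TLS + 65 (boundaries inclusive) on the matching strand;
rRNA/tRNA hits are tallied separately.  Enrichment is decided per feature
with the published thresholds: fold change FC > 1.414 (i.e. sqrt(2)),
normalised base mean NBM > 1, p < 0.05, all strict; FC < 0.707 with the
same gates marks depletion.

The test behind the p-value is a self-contained negative-binomial Wald
test:

* size factors by median-of-ratios against the geometric-mean
  pseudo-reference (cross-checked in the tests against DESeq2's
  implementation);
* FC as the ratio of group means of normalised counts with a pseudo-count
  of 0.5;
* Wald variance `sum_g (1/(n_g mu_g) + alpha/n_g)` with the NB dispersion
  `alpha` estimated by the method of moments within groups, **pooled
  across features by the median**, and floored at 0.01.

Pooling is deliberate: with three replicates the per-feature moments
estimator is mostly rectified noise, and keeping it per feature makes the
test conservative by roughly a factor of two.  With pooling, the type-I
error on Poisson-null matrices at background-level coverage sits at
0.05 ± 0.02 (checked in the suite).  At very deep coverage the 0.01
dispersion floor still dominates the Poisson term and the test becomes
mildly conservative; this is intentional protection against
anti-conservative calls on near-deterministic counts.  Median-of-ratios
normalisation assumes most features are *not* enriched; inputs where the
majority of species are NAD-capped would partially absorb the signal into
the size factors.

# NAD-modification ratios

Relative per-gene NAD-capping fractions are estimated by distributing an
externally supplied total NAD amount `k` (in practice a mass-spectrometric
measurement; here a config scalar) over genes:
`ratio = k * TPM_capture / TPM_transcriptome`, clipped to [0, 1].  The
estimator is invariant to library depth by construction (TPM on both
sides).  The qPCR-style estimator
`(S − background) / (S + non-NAD-cap)` is provided for targeted assays.

# TSS clusters and the trend test

Per gene, read 5'-ends are collected in the scan window from 50 nt
upstream of the canonical TSS down to the TLS.  Clusters are found
greedily: an 18-nt window is placed at the position maximising the
contained start count (S and N pooled), the modal position inside becomes
the cluster representative, those reads are removed, and the search
repeats while a window holds at least 2 starts (ties break towards the
shorter TL, deterministically).

Alternative TSS usage between S and N is tested with a weighted
linear-by-linear association test on the resulting 2 × n table.  The N
row is first scaled to the S row's total (rounded) so library depth
cannot masquerade as trend; the scaling constant is a package decision —
the row totals, not the raw proportions, are equalised.  Each table entry
then contributes its count as individual observations with row score 2
(S) or 1 (N) and column score equal to the cluster's TL length; the
weighted Pearson correlation r (population moments) yields
`M^2 = (n − 1) r^2` with `n` the total number of observations, referred
to a chi-squared distribution with one degree of freedom, gated at
`n >= 30`.  The implementation is verified against a brute-force
per-observation expansion to 1e-10, and its p-values are uniform under a
simulated null (KS < 0.05 over 2,000 genes).  The null simulation uses
4-6 clusters and 150 reads per group — enough distinct column scores and
mass for the chi-squared asymptotics the test relies on; with only two
clusters and a handful of reads the statistic is visibly discrete.

# Sharp-A TSSs and promoter matrices

A gene's observed TSS is the modal read 5'-end in the scan window, with
ties broken towards the candidate with the larger count one nucleotide
downstream (a deterministic stand-in for "one of the most abundant
positions").  The *sharp value* is the start count at the TSS divided by
the count one nucleotide upstream, floored at one read to avoid division
by zero; a *sharp A* requires an A at the TSS and a sharp value strictly
greater than `sharp_min` (default 4, configurable — a three-fold variant
of the rule is in circulation, so the threshold is exposed).

Promoter matrices are built from the −10..+10 window around the called
TSSs of a gene set (top-25 by fold change among sharp-A genes, or the
most abundant unenriched genes with 0.707 ≤ FC ≤ 1.414 as background):
position frequencies with a pseudo-count of 0.25 per base and information
content `IC = 2 − H` bits per position.  With 25 perfectly conserved
sites the pseudo-count caps IC at about 1.77 bits — the recovery check
uses 1.5 bits, not the theoretical 2.  The YAAG signature appears as a
pyrimidine at −1, A at +1 (the NAD incorporation site, always an
adenosine), A at +2 and G at +3.

# TSS shifts and the transcript-leader length index

Shifts of the NAD TSS against a reference are classified per gene from
the difference of modal TL lengths: more than 10 nt at FDR < 0.1 counts,
with the sign giving distal (longer leader) versus proximal.  Against a
read-level reference (N-group starts as an all-cap proxy) significance
comes from an unpaired two-sided rank-sum test; against a point reference
(a user-supplied canonical TSS) from a two-sided sign test.  Both choices
are package decisions, recorded here because the underlying test is not
uniquely determined by the decision rule.

Between two strains we define the transcript-leader length index as

TLI = (mu_B − mu_A) / W,

where mu is the read-count-weighted mean TL length of the strain's
S-group starts and W the scanned window length (UTR + 50 nt).  TLI is
antisymmetric in the strains and unitless; positive values mean the
second strain initiates at more distal positions.  Its FDR comes from the
trend test applied to the strain-A-vs-strain-B cluster table (mutant row
scored 2).  The formula itself is a package definition chosen to satisfy
the sign semantics of the index; only the thresholds (|TLI| > 0.1,
FDR < 0.1) are taken from the decision rule it implements.

# Read geometry and the truncation contrast

For each read the pair (5'-end, 3'-end) relative to the canonical TSS
forms a unit-bin 2D histogram per gene and group.  A read is
*full-length* when its 5'-end is within ±3 nt of the group's dominant TSS
and its 3'-end within ±3 nt of the annotated TES; the reported fraction
conditions on the dominant TSS (full-length / reads at the dominant TSS),
so 3' truncation is not confounded with TSS-usage differences between S
and N.  The truncation contrast R is the median of per-gene S/N
full-length-fraction ratios over enriched genes divided by the same
median over non-enriched genes; R < 1 indicates NAD-linked truncation.
Working per gene cancels transcript-length differences that a pooled
ratio would re-import through group-specific gene weighting.

# Decapping hierarchy

Starting from the strain with all three decapping enzymes (Rai1, Dxo1,
Npy1) deleted, enzymes are reintroduced one at a time.  An ordered path
(e1, e2) is supported by a species when reintroducing e1 shifts its TL
(|TLI| > 0.1, FDR < 0.1 — e1 removes some TL variants) and reintroducing
e2 then removes it from the enriched fraction or at least halves its fold
change (e2 removes the remainder).  The ≥2-fold drop quantifies
"significantly reduced"; no probabilistic model is fitted — the argument
is count-based, and paths are ranked by the number of resolved species.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analysis is designed for:

* **NAD fractions** uniform in 1-5% for capped genes — the regime where
  the modification percentage of transcripts is low — with 70% of genes
  uncapped, mirroring that only a minority of species are NAD-capped and
  keeping median-of-ratios normalisation valid.
* **Capture geometry**: NAD 5'-ends captured with probability c = 0.5 in
  S; any transcript with background b = 0.002 in both libraries.  The
  background is set so the attainable fold-change range (hundreds-fold
  for strongly capped genes) matches the large dynamic range this
  protocol achieves; a background of 2% would cap fold changes near 25
  and place weakly capped genes exactly on the 1.414 decision boundary.
* **TSS geometry**: each gene has a canonical TSS (TL 40-80 nt) and one
  NAD TSS offset 10-40 nt (distal or proximal); in two-variant mode
  (hierarchy studies) both a distal and a proximal NAD variant exist.
  NAD TSSs always initiate on A; a configurable fraction (default 0.8)
  carries the full YAAG context.
* **Read model**: 5'-ends at the originating TSS with one-nucleotide
  jitter (probability 0.2); 3'-ends from a per-nucleotide geometric stop
  process (stop probability 0.001, tripled for NAD transcripts), i.e.
  truncation is a memoryless elongation failure — a deliberately
  mechanism-free model.  Capture is per-transcript Bernoulli; there is no
  PCR-duplicate or base-error model.
* **Depth**: 4,000 transcript draws per gene per library (≈ 20-200
  captured reads per gene), three replicates per group.  Geometry
  analyses, which need per-gene 3'-end distributions, use 12,000 draws —
  the single-transcript regime of a highly expressed gene.
* **Strains**: per-enzyme survival probabilities by TL class plant the
  hierarchy: Rai1 is distal-specific (survival 0.05 distal / 1.0
  proximal), Npy1 broad (0.15 both), Dxo1 mild (0.6 both), so the true
  structure is "Rai1 first, Npy1 resolves the remainder".

What the generator does **not** emulate — fragmented libraries, PCR
amplification bias, sequencing errors, overlapping genes, mappability
artifacts — bounds what green tests mean: they demonstrate that the
statistics recover planted structure under the stated model, not that the
pipeline is robust to every artifact of real libraries.

# Validation scales and determinism

The validation suite uses: 200 random tables for the trend oracle, 2,000
genes for null calibration, 100 genes at ±30 nt for shift power, 200-gene
simulations for motif recovery, 300 genes for enrichment and ratio
recovery, 50 seeds per arm for the truncation contrast, 20 seeds for
hierarchy recovery and 10,000 inserts for the trimming inverse — sizes
chosen so each check is statistically meaningful while the whole suite
runs in about a minute.  All randomness flows from one global seed
through `stage_seed()`, an arithmetic hash of the stage name, so stages
are independently reproducible and `run_pipeline()` is byte-identical
under a fixed configuration.

The trimming inverse (`trim_reads(add_adapters(x)) == x`) holds on its
identifiability domain: inserts that do not begin with G (the leading
G-run is indistinguishable from the CTP-tailing artifact) and do not
contain the adapter motif internally.  `add_adapters()` additionally
resamples its random spacer so it never fabricates an earlier spurious
motif occurrence.

# Known limitations

* The enrichment test is a documented substitute for a shrinkage-based
  NB framework; it shares thresholds and normalisation but not shrinkage
  estimators, so p-values on real data will differ in the tails.
* Read classification places 18-nt reads in the "normal" class, making
  the small/normal partition gapless at 12-17 vs ≥18.
* Small-RNA cluster identity is ungapped best-offset (±3 nt) matches over
  the shorter length; clusters with an empty N side are reported as
  infinite enrichment and flagged rather than pseudo-counted.
* The mapper is an exhaustive mismatch scan for toy genomes; real data
  should arrive as pre-aligned BED-like tables.
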