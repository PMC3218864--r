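---
title: "Detecting split and permuted tRNA genes: models and methods"
author: "trnarr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting split and permuted tRNA genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnarr)
```

## Scope

`trnarr` re-implements, as a tested pipeline, the computational route by
which trans-spliced (split) and circularly permuted tRNA genes can be
discovered in archaeal genomes: structural tRNA detection, partner search
for orphan tRNA halves with bulge-helix-bulge (BHB) junction validation,
promoter identification against a Markov-chain null, and
promoter-to-gene spacing outlier analysis. Every stage can be exercised
on synthetic genomes with planted features and machine-readable ground
truth, so the pipeline is testable without any external data.

## The cloverleaf constraint model

Published discovery work of this kind scores candidates with covariance
models (Infernal). Covariance-model machinery is a large, existing tool;
this package instead uses a constraint-based cloverleaf model that keeps
the same decision semantics (a bit score with a default reporting cutoff
of 20 bits) on its own score scale. Scores are therefore *not*
comparable to tRNAscan-SE bit scores.

A mature tRNA is a fixed succession of segments: acceptor stem (7 bp),
positions 8-9, D stem (3-4 bp), D loop (4-12 nt), position 26, anticodon
stem (5 bp), anticodon loop (7 nt), variable loop (3-21 nt), T stem
(5 bp), T loop (7 nt), acceptor 3' strand, discriminator, and an
optional genomically encoded CCA. Folding enumerates every arm-length
combination compatible with the sequence length and scores:

* stem pairing, in bits per pair: G-C 2.0, A-U 1.5, G·U 0.8, non-pairing
  -2.0. A stem is accepted with at most one non-pairing position.
* conserved positions: U8, A14, G18/G19, A21, U33, the T-loop block
  G53-U54-U55-C56-R57-A58, C60/C61, and a CCA bonus; matches add the
  position weight, mismatches subtract half of it.

Ties are broken deterministically (most Watson-Crick pairs, then most
G-C pairs, then arm-length enumeration order). A consensus-built tRNA
scores in the 50-60 bit range, so the 20-bit cutoff leaves a wide margin
for the decoys that matter, while unpairable sequence cannot produce a
structure at all.

Sprinzl numbering is derived from the arm assignment: the anticodon is
always 34-36, the T loop 54-60, the discriminator 73; D-loop and
variable-loop insertions receive letter suffixes (17a, 20a, 47a, ...).

## Genome scanning

Scanning both strands anchors on the T-loop block (GTTCRA plus C61),
which doubles as the core of the internal B-box promoter. The 3' end of
the molecule sits at a fixed offset from this anchor, so each anchor is
expanded by enumerating arm-length combinations. Three secondary paths
handle molecules that do not fold in place:

* **canonical introns** (between Sprinzl 37 and 38, lengths 11-129 nt):
  the acceptor/D-arm block is searched upstream at the displacement that
  restores a full-length fold, and the intron boundaries must form a BHB;
* **candidate 3' halves**: a perfectly paired T stem with an intact
  T-loop block but no qualifying gene;
* **candidate permuted 5' parts**: an intact T-loop block whose T stem
  cannot pair downstream, evaluated under a 5'-part model (structure
  complete up to the T loop, with or without a canonical intron). These
  partial-structure calls require both local stems to pair perfectly and
  a partial score 6 bits above the gene cutoff, because arm-length
  enumeration on background sequence can otherwise assemble weak decoys.

Reported genes must additionally reach a conserved-core floor
(`consFloor`, default 12 bits of conserved-position score): the
T-loop anchor guarantees part of the conserved signal for every
candidate, so the floor is what separates genuine tRNAs (the designed
consensus core scores 17.8 bits) from structural decoys assembled by
free arm-length enumeration over background sequence (which plateau
around 6-8 bits). Overlapping hits resolve to the best score; the scan
is strand-symmetric by construction and is property-tested for it.

## BHB splice junctions and trans-pairing stems

The canonical junction (hBHBh') is modeled combinatorially: two strands
pair into helix / 3-nt bulge / 4-bp central helix / 3-nt bulge / helix,
with both splice sites strictly inside the bulges and flanking helices
of at least 3 bp (G·U allowed). Relaxed geometries (bulges 2-4 nt,
central helix 3-5 bp) are enumerated and reported but only canonical
matches satisfy the default candidate filters. `findBhb()` is checked
against an independently written exhaustive enumeration on thousands of
random contexts; `maxDuplex()` (the trans-pairing stem measure) is
checked the same way.

Split-partner search seeds on exact reverse-complement 12-mers between
the region upstream of an orphan 3' half and both genome strands, then
extends to the maximal duplex. A 12-mer seed is guaranteed for stems of
13 bp or more - the sizes observed for real split tRNAs - while the
default minimum reported stem is 10 bp. From the duplex geometry the 5'
half placement is reconstructed; the junction is *not* assumed but
recovered by enumerating arm-length combinations over Sprinzl 8-60 and
keeping the placement whose joined sequence folds best. Candidates must
fold above the cutoff *and* form a canonical BHB at the junction.

Split loci whose halves are adjacent on the same strand look exactly
like an intron-containing gene (the published archetype was originally
predicted as a pre-tRNA with a 121-nt intron). The pipeline therefore
re-classifies intron genes as split candidates when a quality promoter
hit lies inside the intron on the gene strand - evidence that the "3'
exon" has its own transcription unit.

## Promoter identification

Training windows are the 90 nt upstream of operon-leading genes
(no same-strand gene ends within 100 nt upstream) whose product
annotation is informative (not "putative"/"hypothetical"). A 16-mer
motif - wide enough for the TFB response element (a short A-run) plus
the TATA box - is fitted by EM under a zero-or-one-occurrence-per-
sequence model with 20 seeded restarts and a pseudocount of 0.1;
the in-package EM replaces an external motif-discovery binary.
Because window-seeded EM can converge to a solution displaced by a
column or two, the best restart is refined by re-running EM from
shifted versions of its PWM and keeping the highest-likelihood
alignment. The
motif scans the 150 nt upstream of every gene and tRNA locus (best
placement per window, most-upstream on ties; offsets are motif start
relative to the feature 5' end).

The score null is empirical: ten virtual genomes are sampled from a
fifth-order Markov chain trained on the target genome (pseudocount 0.25
per context cell, so no context is impossible in a small genome;
sampled genomes never contain N) and scanned with the same windowed
protocol. P-values use (r+1)/(n+1) smoothing and are monotone in the
score. Candidate hits are filtered by expected position and by a
P-value threshold equal to the worst training-gene promoter - so the
training set always passes its own filter.

A note on the "uninformative motif" calibration check: a PWM that is
*literally* uniform gives every window the same score, collapsing all
P-values to a single value, so uniformity is checked with a
random-column (no-signal) motif instead; its empirical P-values on
background windows are uniform by construction.

## Spacing outliers and permuted genes

Promoter-to-gene offsets of tRNA loci normally fall in a 30-49 nt band
(natural 5'-leader variation). An offset is an outlier when its
magnitude exceeds both the Tukey fence (Q3 + 1.5 IQR of the gene-derived
offset magnitudes) and the band edge; the fence is capped at the band
edge plus one motif width because with few tRNA hits the sample
quartiles are noisy enough to swallow genuine outliers. On the published
configuration (44 offsets in the band plus -72 and -65) the rule flags
exactly the two known outliers.

Each outlier locus is searched for a 3' part (T stem 3' strand,
acceptor 3' strand, discriminator, CCA) between its promoter and its
mature start, enumerating T-loop junctions; a candidate must fold above
the cutoff, form a canonical BHB across the precursor termini, and is
reported with its intervening length and any canonical intron in the 5'
part. Two practical details matter:

* a permuted precursor often folds into a *spurious low-quality
  full-gene call* spanning the intervening sequence; outlier-flagged
  genes are therefore re-examined under the 5'-part model, and genes
  superseded by a permuted candidate are re-assigned (dropped from the
  gene table), mirroring how the original low-scoring predictions were
  re-interpreted in the discovery setting;
* the residue at the junction is unpaired and unconserved, so junctions
  j/j+1 and (j-1)/j can tie exactly; ties are resolved toward the larger
  junction, assigning ambiguous residues to the mature gene rather than
  the intervening sequence.

## The synthetic-genome generator

`generateGenome()` plants, on a Markov background (uniform by default,
any trained `MarkovBackground` optionally):

* standard tRNA genes: consensus-derived sequences with stems sampled at
  a configurable G/C fraction (default 0.6, reflecting thermophile
  G-C-rich stems), conserved positions fixed, everything else random;
  optional canonical introns (>= 15 nt so the intron can carry its own
  BHB and internal helix);
* split pairs: a designed tRNA cut at the junction, with a canonical
  hBHBh' constructed at the splice sites and a G/C-rich trans-pairing
  stem (defaults 14 and 13 bp at junctions 37/38 and 30/31) between the
  5'-half trailer and 3'-half leader, laid out same-strand-adjacent
  (cis span 121 nt), convergent (3' half on the opposite strand) or
  distant (4.5 kb separation);
* permuted genes: 3' part, intervening sequence (1-7 nt), 5' part on one
  strand with a single promoter at an outlier spacing of 68-80 nt from
  the mature 5' end (around the observed -72/-65 spacings);
* decoy protein-coding genes with annotated products (a quarter
  "hypothetical", a third in two-gene operons) whose planted promoters
  train the motif stage.

Promoter instances are sampled from the package's TFB-RE+TATA template:
training (CDS) promoters at 0.85 consensus probability per core column,
tRNA-locus promoters at 0.95 - the discovery setting rests on strong
promoters at the candidate loci, and the noisier training set is what
the EM stage has to cope with. Feature blocks are placed in random
order and strand with at least 500 nt of background between blocks;
generation is deterministic per seed, and truth records are verified in
the tests by re-extracting every recorded locus.

What the generator does *not* emulate: real gene density and codon
structure (decoy CDS are background sequence with annotations), tRNA
sequence families and modification-driven identity elements, promoter
context effects, and genome-scale compositional heterogeneity. Passing
the planted-recovery suite therefore demonstrates the correctness of
the detection logic under the stated feature models, not sensitivity on
real genomes - where the conserved positions of real tRNAs are noisier
than consensus-derived plants.

## Problem sizes and numerical choices

The planted-recovery study design is 20 standard + 2 split + 1 permuted
gene per genome. The test suite and the acceptance script run this
design at a reduced per-genome size (about 220 kb with 12 standard
genes, across several seeds) chosen so the whole suite completes in a
few minutes on one CPU; per-genome scan plus discovery takes roughly
15-25 s at this size and scales linearly in genome length. Other fixed
choices: Markov pseudocount 0.25; EM convergence at an absolute
log-likelihood change below 1e-8 with at most 100 iterations; fragment
reporting thresholds of 10 bits (3' halves) and cutoff+6 bits (5'
parts); flanking-helix extension capped at 8 bp when enumerating BHBs.
Genomes are treated as linear; none of the modeled features spans a
replication origin.

## Known limitations

* The score scale is package-specific; published bit scores from
  covariance-model scanners cannot be compared numerically.
* Split junctions inside the D-loop or variable loop can be absorbed by
  the flexible arm lengths, making the junction position ambiguous by a
  nucleotide; the observed junctions (30/31, 37/38, 59/60) are all
  adjacent to fixed-length segments and are recovered exactly.
* Noncanonical introns are classified and BHB-validated when a gene
  carries them, but the genome scan only discovers canonical (37/38)
  introns.
* Promoter offsets can inherit a residual one-column alignment shift
  from EM motif training when the motif's flanks are uninformative;
  shift refinement removes this in practice, and the spacing analysis
  tolerates 1-2 nt of offset error by design.
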