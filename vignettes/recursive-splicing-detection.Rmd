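---
title: "Detecting recursive splicing from total RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recursive splicing from total RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recsplice)
library(dplyr)
```

## The biology and the two observable signals

Recursive splicing (RS) removes a long intron in successive segments
rather than as one lariat. The pivot of each step is an intronic
`AG|GT` element: the `AG` first serves as a 3' splice site, joining the
upstream exon to the intron's remainder, and the `GT` is immediately
reconstituted as a new 5' splice site (the "zero-length RS exon"). The
process is invisible in mature mRNA; what total RNA-seq of nuclear RNA
can capture are its transient intermediates and the nascent
transcription profile:

1. **Up-junction reads.** The upstream splicing intermediate joins the
   3' end of an annotated exon to the sequence beginning at the `GT` of
   an intronic `AGGT`. In aligned reads this is a splice junction whose
   acceptor boundary is the first base after the `AG` — the `G` of
   `GT` — and whose donor boundary is an annotated exon end.
2. **The saw-tooth coverage profile.** Coverage of intronic nascent RNA
   declines roughly linearly toward each splice point (positions near a
   splice point spend less time unspliced) and steps *up* just after an
   RS site, because the next segment persists longer. A long intron
   split once by RS therefore shows two descending teeth with a jump at
   the site.

Two companion observations complete the picture: *down-junction reads*
join a donor shortly downstream of the RS site (the 3' end of an RS
exon) to the next annotated exon, evidencing a downstream intermediate;
and *RS-like cryptic exons* are unannotated intronic segments with both
kinds of intermediates but an exon-like (flat-background, locally
elevated) rather than saw-tooth profile.

## The detection cascade

Candidate sites are every `AGGT` on a gene's sense strand (the span
from TSS to TES, scanned only in the transcription orientation;
intergenic sequence is never scanned). The cascade then applies, in
order:

| filter | default | rationale |
|---|---|---|
| host intron length | ≥ 1000 nt (RS), ≥ 50000 nt (cryptic) | RS is a long-intron phenomenon |
| mRNA enrichment | total RPM > 2 × mRNA RPM (RS); > 1 × (cryptic) | removes unannotated exons, which persist in mature mRNA |
| merged up-junction count | ≥ 10 reads | confidence floor; replicates are merged by summing raw counts |
| down-junction count | ≥ 2 (cryptic pipeline only) | requires the downstream intermediate |
| coverage pattern | saw-tooth (RS) / exon-like, not saw-tooth (cryptic) | the distinguishing nascent signature |

RPM is reads per million uniquely mapped reads per sample; pooled RPM
across replicates is `sum(counts) / sum(depths) × 1e6`. The enrichment
test uses a strict inequality on raw pooled RPMs, so a site with zero
mRNA junction reads passes at any positive total signal; the *reported*
fold change adds a 0.5-read pseudocount on the mRNA side only so the
display value stays finite. Enrichment is evaluated on pooled
replicates rather than per-replicate all-pass because pooling is the
more powerful test at the low counts this assay lives in, and matches
the merged-count spirit of the count filter.

The generalized `AGNN` scan is the identical code path with pattern
`AGNN` and a final pattern filter that discards `NN == GT`
(`exclude_nn = "GT"`), so canonical and non-canonical acceptors are
treated symmetrically up to that last step.

### Junction matching conventions

Junctions are parsed from the `N` operations of CIGAR strings by a
reference-coordinate walk (`M`, `D`, `=`, `X` consume reference; `I`,
`S` do not); each `N` yields one junction record. Matching to sites is
**exact**: aligners report junction boundaries exactly, so no
tolerance is applied. All boundary arithmetic is done in gene-sense
space: for a minus-strand gene the acceptor side of a junction is the
lower-coordinate gap edge. The up-junction donor must equal the 3' end
of a collapsed exon upstream of the site — a proper splice out of the
annotated donor — not merely fall inside an exon; a diagnostic column
(`up_count_anyexon`) reports the looser count so the effect of this
choice is visible per site. Down-junctions are scanned over the 350 nt
sense-downstream of the site's acceptor, and the modal donor position
(ties broken toward the smaller exon) is recorded as the RS-exon 3'
end.

## Automating the saw-tooth call

Visual inspection of coverage profiles does not scale and cannot be
tested, so the package replaces it with two statistics computed from
the sense-oriented per-base depth of the host intron:

* **Saw-tooth score** — `log2((mean depth over W nt downstream of the
  site + ε) / (mean depth over W nt upstream + ε))`, with `W = 5000`
  nt and `ε = 0.1` reads/base. The upstream window ends at the base
  before the site's `A`; the downstream window starts at the retained
  `G`. Additionally both flanks must *decline* along the sense
  direction: Spearman's ρ of 200-nt binned depth against position must
  be ≤ −0.3 in each flank (`trend_ok`). `W = 5000` suits RS-scale
  introns (tens of kb); when a flank is shorter, both windows shrink
  symmetrically and the row is flagged. `ε` guards against division
  blow-ups in sparse introns; Spearman is used for the trend because it
  is robust to isolated depth spikes.
* **Exon-likeness** — `log2` ratio of mean depth inside the putative
  exon (acceptor to observed down-donor, else 350 nt) against the
  average of the two flanking 5-kb windows. A cryptic exon with k-fold
  local coverage scores ≈ `log2 k`; a true saw-tooth site scores low
  because its downstream flank is as elevated as the "exon" region.

Candidates are then classified in a fixed hierarchy: **RS** when the
saw-tooth score reaches `τ_saw = 1` (one coverage doubling) with
declining flanks; else **unannotated exon** when exon-likeness reaches
`τ_exon = 2` (four-fold local elevation); else **nascent transcript**
when intron background coverage is at least `τ_bg = 0.05` reads/base;
else **unknown**. The thresholds were calibrated once on the simulator
(planted saw-tooth sites score ≈ 1.5–2.5 under the default geometry;
planted cryptic exons ≈ 3.3 on exon-likeness and < 0.5 on saw-tooth)
and are deliberately conservative mid-points between the two planted
classes; every call carries the underlying numbers so a human can
re-inspect any locus, mirroring the manual workflow the statistic
replaces.

## Splice-site strength models

The reconstituted 5'SS (r5'SS) after the first RS step is the last 30
nt of the upstream exon + `GT` + the 20 nt following `AGGT` (52-mer
logo form), scored via its 9-mer core (3 exonic nt + `GT` + 4 nt). The
downstream 5'SS is built the same way at the RS/cryptic exon's 3' end,
using the observed modal down-junction donor when present, else the
best-scoring `GT` in the 350-nt window (flagged
`best_window_donor` — needed because half of RS sites show no
down-junction reads, yet their donor strength is the interesting
contrast). 3'SS context is scored on 23-mers (18 nt + `AG` + 3 nt,
which for an `AGGT` site is 18 nt + `AGGT` + 1 nt).

Published analyses of these sequences used the external MaxEntScan
tables; this package does not re-derive the maximum-entropy inference
and does not reproduce absolute MaxEnt values. Instead it (a) loads
external parameter tables in a documented TSV format when provided,
and (b) otherwise trains a position weight matrix or a
position-specific first-order Markov model on the annotated `GT`
donors and `AG` acceptors implied by the supplied GTF + FASTA. Scores
are log2 odds against the genome-wide mononucleotide background. All
internal decisions are score *comparisons*, so any monotone transform
of the score scale preserves every classification; tests accordingly
assert orderings, not absolute values. Trained frequencies are shrunk
toward the uniform distribution with a fixed mixture weight of 0.05
rather than by an additive pseudocount: the mixture keeps scores
exactly invariant under duplication of the training set (a property the
scoring contract promises) while still bounding every frequency away
from zero; an additive pseudocount would violate that invariance.

## The simulator: what it emulates, and what it does not

`simulate_reference()` + `simulate_reads()` generate a toy study whose
defaults are the package's standing test conditions, chosen once:

* ~9 single-gene chromosomes (5 RS genes, 3 cryptic-exon hosts, 1
  plain gene), each `exon–long intron–exon–short intron–exon`.
* RS host introns 20–45 kb and cryptic hosts 52–60 kb — about ten-fold
  smaller than the real RS world (introns > 51 kb in genes > 294 kb)
  so the suite runs in minutes; every length threshold is configuration,
  so the scaled world stays coherent.
* RS sites carry the U1-pairing context `AGGTAAGT` and a 20-nt
  polypyrimidine tract; cryptic exons carry a weak reconstituted donor
  context but a strong `CAG|GTAAGT` downstream donor, reproducing the
  observed asymmetry between the two ends of cryptic exons.
* Intronic read starts are drawn with density proportional to
  `(distance to the segment's sense-downstream splice point + d)` with
  delay `d = 2000` nt — the minimal polymerase-position model that
  yields linear per-segment decline and the step at the RS site. The
  expected step height follows in closed form from this density, and
  the test suite checks the measured score against that expectation
  (within ±0.2 at 50× coverage).
* Planted junction reads are emitted in *exact* numbers (up: annotated
  donor → acceptor; down: RS-exon donor → next exon start), split
  across replicates so merged counts equal planted counts; the mRNA
  control contains mature-style exonic and annotated-junction reads
  only. Reads are single-end, error-free, emitted directly as
  coordinate-sorted SAM with CIGARs constructed from truth; the same
  seed yields byte-identical files.

What the simulator does **not** emulate — and therefore what a green
suite does *not* demonstrate about real data: sequencing errors and
quality variation, multi-mapping and alignment artefacts, PCR
duplicates, fragment-length effects, overlapping genes and antisense
transcription, expression heterogeneity across genes, partially spliced
canonical intermediates, and introns harbouring multiple RS sites.
Recovery of planted sites shows the machinery is correct, not that the
thresholds are optimal for any particular tissue; the saw-tooth
thresholds especially should be reported alongside any real-data claim.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (the R/Bioconductor
  convention), in memory and in every output table.
* Site enumeration requires the whole 4-mer strictly inside the host
  intron; overlapping genes yield one row per gene (deduplicate on
  `(chrom, a_pos, strand)` for coordinate-unique counts).
* `N` in a scan pattern matches any of A/C/G/T; ambiguity codes in the
  genome (including `N`) never match.
* Empty inputs: an empty alignment set is an error for read-category
  fractions (the proportions are undefined) but yields an all-zero
  coverage profile; a zero-gene simulation writes empty but valid
  FASTA/GTF.
* Ties in the modal down-donor go to the smaller exon span; the
  best-window donor without a model falls back to similarity with the
  `CAGGTAAGT` consensus.
* A junction-observed donor lacking `GT` (possible in principle with
  alignment noise) falls back to the window search and is flagged.

## Problem sizes

The default test and acceptance runs use the default simulated study
(~100k reads per total-RNA replicate, two replicates plus an mRNA
control, ~0.4 Mb genome), a 1000-CIGAR randomized junction oracle, and
1000 hill-climbing restarts for the score-model maximality check;
determinism is verified on a reduced two-gene configuration. These
sizes keep a full run within a few minutes on one CPU while leaving
every statistic well away from its decision boundary.

## Limitations

The pipeline detects RS only where splicing intermediates are captured
— lowly expressed genes or fast-turnover intermediates are invisible
at practical depths. The enrichment filter needs an mRNA-seq control
from comparable material. The saw-tooth statistic assumes a single RS
site per intron segment pair; closely spaced sites shorten the flanks
and shrink `W`. Absolute splice-site strengths are model-dependent;
only comparisons within one model are meaningful.
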