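---
title: "Methods: detecting and classifying subtelomeric Y' elements"
author: "yprimescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and classifying subtelomeric Y' elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `yprimescan`, and what the synthetic-data validation does
and does not establish about real assemblies.

## The annotation model

Y′ elements are treated as a family of structurally related repeats at
chromosome ends: a shared backbone carrying (i) an internal stretch of
tandem, degenerate ~36 bp units of variable copy number (0–36 observed),
or, in one family, a CA-rich repeat region of near-equal adenine/cytosine
composition; (ii) one or two conserved ORFs; and (iii) flanking telomeric
sequence — the terminal tract distally and, in about half the cases, an
interstitial telomeric sequence (ITS) on the centromere-proximal side or at
tandem-array junctions.  All coordinates are 0-based half-open internally;
GFF3 output converts to the 1-based inclusive convention.  "Left" and
"right" extremities of a contig are assigned by proximity to the contig
start/end, with the midpoint splitting short contigs.

## Telomere and ITS calling

The telomeric repeat is modelled as degenerate C~1–3~A on the CA strand
(TG~1–3~ on the G-rich strand), with unit probabilities giving ~62 % C —
clearly separated from the CA-rich element regions (~42 % C of A+C ≈ 87 %).
Per-position coverage by maximal runs of these units is computed on both
strands; runs shorter than 8 bp are ignored (isolated 2–4 bp unit matches
occur constantly in random sequence and carry no signal).  The score at
position *p* is the covered fraction of the window `[p, p+20)`, the better
strand taken, making calls exactly mirror under reverse complementation.
Runs of scores ≥ 0.8 are refined to their covered bases, merged across
base-space gaps ≤ 10 bp, then classified terminal (within 50 bp of a contig
edge) or interstitial; interstitial calls shorter than 20 bp — the smallest
ITS the pipeline reports — are discarded.  Window 20, threshold 0.8, merge
gap 10 and terminal margin 50 were fixed once by Monte-Carlo calibration on
random sequence: at these settings fewer than 1 % of random 10 kb fragments
produce any call, while terminal-tract recall on simulated genomes is 1.0
and ITS recall ≥ 0.95 with ≤ 10 bp boundary error.

## Alignment engine

Two primitives serve the whole pipeline, with scoring match +1,
mismatch −2, gap open −4, gap extend −1 (a gap of length *L* costs 4 + *L*):

* **Seeded gapped local alignment** — exact k-mer anchors (k = 15, or 11
  for short inputs), merged into maximal exact segments, collinearly
  chained under per-side gap bounds, assembled with exact affine-gap DP over
  inter-anchor rectangles, and extended outward with X-drop DP.  K-mers
  occurring more than 8 times in the target are skipped: they sit inside
  internal tandem repeats where anchors explode quadratically and the gap
  fill recovers the alignment anyway.  End extension follows the
  conventions of full Smith–Waterman tracebacks (first co-optimal cell at
  the high end, furthest at the low end), and the top hit agrees with an
  independent full-DP implementation (span ±2 bp, identity ±1 point) on
  planted-segment pairs.  In self-comparison mode anchors are restricted to
  the upper triangle and hits whose two spans overlap reciprocally by more
  than 50 % are discarded, which removes the trivial identity diagonal.
* **Spliced mapping** — the same engine with internal gaps allowed up to
  1 kb on either sequence, the slack needed when query and target carry
  different 36-mer stretch lengths (0–36 units span 0–1.3 kb).

Multiple sequence alignment is a pluggable contract: the default backend
shells out to MAFFT (`--auto`; deterministic for a given input) when it is
on the PATH, with a deterministic internal progressive aligner (UPGMA guide
tree from pairwise global-alignment identities, ties broken by input order,
profile–profile merges) as fallback and as the backend used in small exact
tests.  Gap removal from any MSA row must reproduce its input exactly; the
package enforces this invariant at run time.

## Detection funnel

Telomeres are masked before self-comparison.  Windows of 25 kb with a 5 kb
step over the 100 kb terminal span are self-aligned; off-diagonal hits of
aligned length 4.0–9.5 kb at ≥ 90 % identity are kept and deduplicated
across overlapping windows.  A repeat copy enters the high-confidence
database only when both edges lie within 50 bp of a telomeric call
("directly flanked"; the 50 bp bound is this package's quantification) and
the copy aligns to a reference Y′ over ≥ 500 bp at ≥ 80 % identity (the
quantification of "matched at least part of" a reference).  Reference
sequences are appended and duplicates collapsed.

Every entry is then mapped to every contig on both strands.  Extremal
alignment blocks shorter than 20 bp separated from the next block by more
than 100 bp are trimmed iteratively (spliced aligners over-extend across
non-matching stretches).  Hits from different entries competing for one
locus are merged: best score wins among hits overlapping reciprocally
> 50 %, with ties resolved by lower start then lexical database id; in
addition, a candidate mostly (> 50 %) covered by already-accepted hits is
suppressed — this removes partial-domain hits produced by the shared
proximal domain of different classes and by repeat matches spanning
tandem-array junctions, two cases the reciprocal rule alone cannot see.
Residual boundary overlaps are clipped so emitted elements never overlap.
Elements shorter than 1 kb are dropped; the secondary 3.5 kb core-length
count is reported in the funnel log but is not a filter.  Elements whose
interval touches a contig boundary are flagged edge-truncated and excluded
downstream.  Orientation is normalised to run from the centromere-proximal
end toward the telomere, using the strand of the database hit.

## Internal repeat profiling

The 36-mer scan computes, at every position, `(36 − d)/36` where *d* is the
minimum Levenshtein distance between the 36 bp window and any database
motif; IUPAC codes in motifs match their allowed sets, so one degenerate
consensus stands for its whole resolved family.  Distances above 8 are
clamped — the resulting floor (≈ 0.75) is far below the peak threshold and
saves most of the DP work.  Peaks are strict local maxima ≥ 0.85 (leftmost
index of a plateau), kept greedily from the highest score down under a
30-position minimum spacing.  The stretch spans the first peak through the
last peak's window — the trailing window is included, resolving the
ambiguity of "between the first and last peak" in favour of whole units —
and the unit count is the peak count.  Units are extracted at the peaks;
a unit whose best-motif alignment spans ≠ 36 bases (net indels, judged by a
semi-global alignment that prefers 36 bp spans among co-optimal solutions)
is excluded from the unit list used for position-frequency matrices and
database refinement, but still counts as a repeat.  One bootstrap round
pools all retained units, deduplicates them, caps them at the 64 most
frequent (ties lexicographic) and unions them with the seed database, so a
second pass can only gain recall.

CA-rich regions are detected compositionally: sliding 100 bp windows with
A+C ≥ 0.8 and min(A, C) ≥ 0.25, excluding telomere-like windows
(C/(C+A) ≥ 0.55 or high telomere-motif coverage), merged across ≤ 60
non-qualifying window starts, reported at ≥ 100 bp.  The merged region must
itself satisfy the same composition rules and show < 40 % telomere-motif
coverage; this whole-region check rejects windows straddling the boundary
of a genuine telomeric tract, which can otherwise slip through on local
composition alone (measured coverage: < 5 % for true CA regions, 100 % for
tracts).  These thresholds operationalise what was originally a manual
call; all are exposed in the configuration.  Pattern segmentation re-uses
the sliding edit-distance peak machinery with pattern-specific window
lengths and labels each base by the highest-scoring peak window covering
it.

Masking removes stretch intervals and records them for coordinate
lift-back; the removed lengths and the masked length always sum exactly to
the original length.

## Clustering and consensus

Percent similarity between two MSA rows is the fraction of identical
non-gap columns over all columns where not both rows are gaps — one-sided
gaps count as differences, so the measure is sensitive to structural
(indel) differences and comparatively tolerant of SNPs, which is what makes
the length classes separate cleanly.  Distances (100 − similarity) feed
average-linkage hierarchical clustering; the dendrogram is cut at every
k from 2 to min(100, n−1) and the cut maximising the mean silhouette is
returned, ties resolved to the smallest k for parsimony and determinism.
Elements are clustered on 36-mer-masked sequences; CA-containing elements
are re-clustered after additional CA-region removal, replacing only their
labels (fresh `CA*` namespace).  Clusters with fewer than five elements,
restricted to one strain, or with heterogeneity (100 − mean intra-cluster
similarity) above 15 points are not retained; the 15-point bound is this
package's concrete reading of "high intracluster heterogeneity".  Consensus
sequences are per-column majorities over the member MSA (ties in
A < C < G < T order, gap last), with majority-gap columns dropped.

## ORF profiling

ORFs are intervals ≥ 300 bases from an ATG to the next in-frame stop (TAA,
TAG, TGA), scanned over the three forward frames of orientation-normalised
elements; nested ATGs do not open separate ORFs, ORFs lacking a stop are
not reported, and codons containing ambiguity characters are treated as
sense codons.  Per cluster, each member's ORF mask (any frame) is lifted
through its MSA row (gaps contribute absence) and averaged per column;
profile values are exact multiples of 1/n.

## Association statistics

Each extremity's telomere length is normalised by its strain mean; groups
are formed by the class of the telomere-adjacent element (or "none") and
compared with a two-tailed two-sample t-test — Welch by default, with a
pooled-variance switch for the classical form.  Per-strain class copy
numbers are tested against per-strain mean telomere length by Spearman rank
correlation.  P-values are reported raw, with an optional
Benjamini–Hochberg column.  The chi-square contingency test uses no
continuity correction and warns when any expected count falls below 5.

## The synthetic-data generator

The generator emulates the structures the pipeline targets, at the reported
scales: contigs of 60 kb (large enough to host three-element arrays at both
ends plus a neutral core) with whole-unit telomeric tracts of ~300 ± 50 bp
at both ends; 0–3 elements per extremity oriented toward the nearer
telomere; class mix dominated by canonical long and short; 36-mer stretch
sizes 0–36 with median ~10 units; ITS lengths 20 to ~500 bp
(exponential excess over the 20 bp minimum), present at 62 % of tandem
junctions and 50 % of centromere-proximal positions; an inert X-element
placeholder centromere-proximal of each array; i.i.d. uniform background.
Templates obey the structural relations exactly: the short backbone is the
long backbone minus one 465 bp and one 600 bp block (both divisible by
three, so ORF frames survive the deletions), mid1/mid2 each lack one block,
and the CA classes replace the distal half with distinct 1.6–1.8 kb domains
nesting the CA repeats.  Backbones are scrubbed at construction so that the
only ORFs ≥ 300 bp are the two planted ones (one ~0.9 kb, one 1.8 kb),
making cluster-level ORF profiles interpretable.

Two divergence mechanisms are deliberately different.  Backbone
substitutions are i.i.d. per base at `substitution_rate`, so planted-element
edit distances follow a binomial law that tests can check.  Per-repeat
divergence of 36-mer and CA units is a fixed count `round(rate × length)`
of substitutions at random positions per unit: divergence is a property of
each repeat, every unit of a 10 %-divergent stretch carries exactly 4
substitutions, and unit-level detection behaves deterministically rather
than hinging on the binomial tail of each unit.  An optional per-strain
substitution layer applied to the class template before element-level
substitutions models within-strain homogenisation for the diversity
analyses.

Ground truth records every planted interval in contig coordinates including
the mutated element sequences, so truth re-extraction is an exact identity,
and the telomere-length table generator scales extremities by
`1 − effect(class)` and strains by `1 + Σ copy_effect × copies` to plant
class-specific shortening and strain-level copy-number associations.

What passing these tests shows — and does not.  The simulator plants exact
template copies with known divergence and clean flanks; it does not model
assembly errors (homopolymer indels, collapsed or over-assembled ends),
inter-class mosaicism, or genuinely novel element families.  Perfect
precision/recall on simulated genomes therefore validates the machinery and
its parameter defaults, not the real-strain catalog, whose reproduction
additionally depends on large external assemblies and manual end curation
that are out of scope here.

## Numerical choices and problem sizes

Degenerate inputs are defined everywhere: empty alignments are input
errors; all-identical similarity matrices make the silhouette undefined and
raise a degenerate-input error; a single consensus member passes through
with a warning; fewer than three CA elements skip re-clustering unchanged.
All tie-breaks (peak plateaus, silhouette ties, hit merging, consensus
residues) are fixed and documented above, so identical configuration and
seed give byte-identical outputs (the GFF3 writer also strips volatile
header lines).

The validation suite runs at the scales stated in its tests: 100 simulated
genomes (5 contigs each) for detection and telomere calling, 74 planted
stretches covering 0–36 units for unit-count recovery, 50 simulations of 60
elements from 4 templates for cluster recovery, 200 sequences or pairs for
the ORF and Smith–Waterman oracles, 500 and 1000 replicates for
association power and type-I calibration at 54 strains × 32 extremities,
and 1000 tracts per class for CA/telomere discrimination.  These sizes give
the binomial margins the asserted thresholds need while keeping a full run
in the tens of minutes on a single core; `scripts/acceptance.R` recomputes
the same quantities from scratch.

## Known limitations

* The internal seeded aligner is contract-equivalent, not bit-equivalent,
  to the external aligners a production run might use; an adapter accepting
  external tabular hits can replace it per locus.
* No algorithmic criterion exists for the manual assembly-end curation
  applied in real-data studies; none is attempted.
* The shipped 36-mer consensus and CA patterns are synthetic stand-ins; on
  real data users should supply the published motifs.
* Real-data headline numbers (catalog size, cluster count, consensus
  lengths, effect sizes) depend on external data and curation and are not
  asserted by this package's tests.
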