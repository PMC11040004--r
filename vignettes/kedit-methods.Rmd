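---
title: "Models and methods behind kedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`kedit` analyses the mitochondrial (kinetoplast) genomes of trypanosomatid
flagellates: networks of maxicircles, which carry rRNA genes, protein genes
and cryptogenes, and minicircles, which encode the guide RNAs (gRNAs) that
direct uridine insertion/deletion (U-indel) editing of cryptogene
transcripts.  The package covers structural annotation of minicircles,
gRNA gene discovery and expression calling, T-stripped read alignment and
edited-ORF reconstruction, 3'→5' editing-cascade reconstruction,
non-cognate guiding attribution, and codon-level analyses under the
protistan mitochondrial genetic code (NCBI table 4).  A ground-truthed
synthetic-data generator makes every step testable end to end.

# The duplex model

A gRNA recognises its mRNA by antiparallel base pairing in which both
Watson–Crick pairs (`A:U`, `U:A`, `G:C`, `C:G`) and `G:U` wobble pairs are
productive; anything else is a mismatch.  `align_duplex()` searches all
pairing registers of a gRNA against an mRNA for ungapped duplexes that

* contain a nucleation window of `seed_length` nt scoring at least
  `seed_score`,
* reach `min_length` nt and `min_score` overall,
* contain at most `max_gu` wobbles and `max_mismatch` mismatches, and
* end in `min_anchor` contiguous Watson–Crick pairs at the mRNA-3' side
  of the duplex — the gRNA 5' anchor, which must bind already-edited (or
  never-edited) sequence for the 3'→5' cascade to progress.

Duplexes are ungapped by design: guiding is pairing against the *edited*
mRNA, and U-indel differences are represented in the editing-site layer,
not by gapping the duplex.

Two parameter presets exist.  The *relaxed* preset (seed 16 nt / score 20,
length ≥ 21, score ≥ 25, ≤ 17 G:U, ≤ 4 mismatches, 2-nt anchor) is the
permissive setting used when asking whether any known gRNA could explain
an observed editing pattern.  The *canonical* preset (seed score 24,
length ≥ 25, score ≥ 35, ≤ 12 G:U, ≤ 2 mismatches, 4-nt anchor) is the
stricter discovery setting used to annotate gRNA genes.  The per-pair
scores default to WC +2, G:U +1, mismatch −1.  This scheme is chosen for
internal consistency — a minimal 21-nt all-WC duplex (score 42) and a
16-nt seed (32) clear the relaxed thresholds with headroom, while G:U-rich
duplexes score lower — and is configurable; published work using these
threshold names does not state the underlying per-pair scores, so the
scheme is an explicit interpretation.

**Reporting rule.**  Within one pairing register, every sub-window of a
pairing stretch may pass the thresholds.  `align_duplex()` reduces each
group of mutually overlapping passing windows on a register to the
best-scoring one (ties: longer, then leftmost), so a perfect duplex is
reported at exactly its full extent rather than padded with flanking
mismatches; remaining duplexes that overlap on the mRNA are optionally
pruned to the best-scoring one.  Whole-source scans
(`annotate_grna_genes()`) disable the second pruning step, because two
distinct gene loci may legitimately target overlapping mRNA intervals
(adjacent cascade positions); deduplication there happens on source
coordinates instead.

# The editing-site layer

U-indel editing changes only the number of uridines between non-U bases.
`build_site_table()` therefore decomposes a cryptogene into its non-T
*backbone* and one *editing site* per backbone base (the count of Ts
immediately 5' of it) plus a terminal site.  A read is aligned by
stripping its Ts and locating the residual backbone in the cryptogene
backbone (both strands, at most one substitution, unique best hit
required); observed per-site U counts are then read directly off the
read's T runs.  The first and last covered sites of a read are flagged
partial — their runs may be truncated by the read boundary — and are
excluded from edited-site and indel totals.

A read counts as *edited* when it differs from the reference at ≥ 5
fully observed sites, and as *hyper-edited* when it carries ≥ 10 U
insertions plus deletions in total; both thresholds follow the field's
use for expression profiles and non-cognate analyses.

# Edited-ORF reconstruction

`reconstruct_orf()` treats the per-site states `(site, U count)` as graph
nodes, connects states at adjacent sites co-observed within a read
(weights = supporting reads), and follows the maximum-bottleneck path
(maximising the minimum edge support; ties resolved by total support,
then fewer edits) 3'→5' from the majority state of the 3'-most interiorly
observed site.  The dynamic programme is restricted to the interiorly
observed site range: terminal sites are never observed interiorly (their
runs abut the read ends), so including them would zero the bottleneck of
every path and reduce the objective to total support alone.  Sites
outside the range fall back to the raw-observation majority, then to the
reference count — safe because truncation can only under-report a run, so
a zero reference count is exact.

The consensus states are rebuilt into the edited sequence and scanned in
all three frames for the longest ATG-initiated ORF terminating in
UAA/UAG under translation table 4 (UGA is tryptophan, never stop).
Reconstruction is reported as failed when no ORF reaches
`min_orf_fraction` (default 0.85) of the expected protein length; the
expectation defaults to the codon capacity of the reconstructed sequence
and should be supplied from cross-species homology when known.  This
failure mode is exactly what distinguishes stochastically edited
transcripts (no consistent editing pattern, hence no reconstructable ORF)
from canonically edited ones.

# Cascade reconstruction

Editing progresses 3'→5': each gRNA's anchor binds sequence edited by its
predecessor.  After aligning all gRNAs to an edited mRNA, three filters
are applied (`filter_alignments()`):

1. alignments using source loci outside the refined gRNA gene
   boundaries are discarded;
2. alignments with three or more *adjacent* mismatches are discarded —
   a G:U pair is not a mismatch and interrupts a mismatch run;
3. alignments with mismatch/length ratio strictly above 1/8 are
   discarded (exactly 1/8 is retained).

The filters are mutually independent, so their order is irrelevant.
Whether the ratio in (3) should count G:U pairs is not settled in the
literature that names the filter; `kedit` excludes them, consistent with
the notational separation of `:` (wobble) from `#` (mismatch).

`build_cascade()` then chains the best alignment per gRNA greedily from
the 3'-most end; each successor must start 5' of the current frontier and
is chosen to reach furthest 3' (ties to the higher score).  Anchor
overlaps, zero-length "adjacent but not overlapping" junctions, uncovered
gaps and the per-position redundancy profile are reported.

# Non-cognate attribution

For hyper-edited reads that fail to assemble into ORFs, the question is
how much of their editing the known gRNA repertoire could have guided
through off-target (non-cognate) anchoring.  Each read's observed
sequence is aligned against every gRNA under the relaxed preset; an
edited site is *explained* when some passing alignment covers the site's
U run together with both flanking backbone bases with no mismatched
column — then the gRNA's guiding nucleotides (A or G opposite U)
prescribe exactly the observed count.  A site covered by several
alignments is explained if at least one matches (existential semantics),
which makes the explained fraction monotone in the gRNA set.  "Editing
events" are counted as edited sites, not individual Us, consistent with
site-based edited-read counting; a per-U variant would require only a
different denominator.

Alignment features (length, G:U count, mismatch count) of cognate versus
non-cognate groups are compared with a two-sided rank-sum test
(`stats::wilcox.test`; exact for small samples, normal approximation with
continuity correction otherwise).  The underlying publications do not
name their test; the rank-sum test is the assumption-light default for
such shifted-distribution comparisons.

# Structural annotation choices

* **Motif scanning** is exact over IUPAC degenerate sets (no fuzzy
  matching): a position matches when each pattern symbol's set contains
  the sequence base.  Circular sequences are scanned across the origin.
  The canonical minicircle motifs are the universal CSB3 12-mer
  `ggggttggtgtg` and the CSB1 palindromic hairpin
  `yyryryrrrryyyyryryrr`; the GRAM (gRNA-associated motif) has no
  published machine-readable consensus and is accepted only as a
  user-supplied pattern.
* **Circularization** removes one copy of an exact terminal direct
  repeat of at least 20 bp (well above chance for ~2-kb circles; no
  published value exists).  A repeat longer than half the contig makes
  the circle length ambiguous and errors.
* **Inverted repeats** use einverted-style local alignment of the
  sequence against its own reverse complement with match +4, gap penalty
  14 and threshold 40 (published options) and mismatch −4 (the
  published options omit it; configurable).
* **Class deduplication** clusters greedily, longest first, under
  rotation- and strand-invariant ungapped identity (matches / longer
  length, anchored on exact seed words), at 0.97 by default — mirroring
  the small-RNA clustering identity, since no threshold is published for
  DNA classes.
* **Re-orientation** rotates a minicircle so the CSB nearest the
  functional gRNA gene sits at position 0, flipping strands if needed so
  the gene lies opposite the CSBs; ties go to the lower coordinate, and
  the operation is idempotent.

# Small-RNA processing choices

Adapter trimming removes exact internal adapter matches and terminal
partial matches of ≥ 8 nt; reads below 15 nt are dropped.  Completely
overlapping pairs (captured gRNAs shorter than the read length) merge
into a single insert, disagreements resolving to the higher base quality.
Tail stripping removes one trailing homopolymer run of T or A of ≥ 3 nt
(no published minimum; composite tails lose only the terminal run — a
documented limitation).  Clustering identity is matches/overlap of the
best-offset ungapped alignment, appropriate for near-identical copies;
consensus validation maps an exact 18-mer seed and tolerates one total
mismatch.  Where alignment-derived and expression-derived gene boundaries
conflict, expression wins, since read termini measure the processed gRNA
directly.

# The synthetic-data generator

`simulate_kdna()`/`simulate_reads()` plant everything downstream analyses
look for, and record it, so recovery can be asserted exactly:

* **Repertoire scale.**  Defaults emulate the study system: 41
  minicircle classes, one short 601-bp class, one class with two gRNA
  genes (42 minicircle gRNA genes), the rest 1920–2019 bp; three
  pan-edited cryptogenes; optional maxicircle gRNA loci; AT-rich
  backbone (GC 0.35).
* **Minicircle architecture.**  Two conserved regions, head-to-tail at
  opposite poles, each carrying a CSB1 instance and the CSB3 12-mer; one
  gRNA gene (two on the designated class) on the strand opposite the
  CSBs with a 12-nt GRAM nearby; one inverted repeat — GRAM and the
  repeat absent from the short class.
* **Cascades.**  Each edited mRNA is tiled 3'→5' with the configured
  anchor overlap; planted gRNAs are exact Watson–Crick complements of
  their interval, so the ground-truth invariant (zero mismatches) holds
  by construction.  Interval starts are nudged (≤ 6 nt) onto G/C mRNA
  bases so no gRNA ends in T or A, keeping genomically encoded sequence
  separable from added tails; where the mRNA is locally too AT-rich for
  a nudge, the tail base is chosen to differ from the terminal base —
  the generator guarantees tail separability one way or the other.
* **Guard columns.**  Three identical-base columns flank every planted
  gene, forcing duplex mismatches immediately outside it, so the
  discovery alignment ends exactly at the planted boundaries.
* **Rejection scanning.**  Any random sequence can by chance form a
  passing duplex with an edited mRNA.  Every built source (cryptogene
  pre-edited state, unedited gene, minicircle, maxicircle) is screened
  with the canonical discovery setting and rebuilt until only planted
  loci remain.  The planted repertoire is therefore the *complete*
  repertoire under the discovery preset — a property real genomes are
  not guaranteed to have, and one reason perfect recovery on synthetic
  data does not imply perfect recovery on real data.
* **Reads.**  mRNA reads are sampled from staged intermediates — a read
  is fully edited 3' of its breakpoint and pre-edited 5' of it,
  reflecting the anchor dependency of the cascade.  The stage
  distribution is not published for any real library; the default
  (pre 0.05 / intermediates 0.10 / fully edited 0.85) reflects a
  poly(A)-selected library dominated by mature mRNAs, at 30× coverage.
  Fragments are sampled with clipping at the molecule ends so per-base
  depth is flat across them.  Small-RNA pairs carry 3' poly(U)/poly(A)
  tails (lengths 3–8 nt by default) and a sequencing adapter.
  Sequencing noise is substitution-only, keeping U-indel ground truth
  unambiguous.
* **Decoys.**  Non-cognate decoy cryptogenes interleave windows copied
  from cognate cryptogene backbones (so donor gRNAs can pair there) with
  random spacers; per read, all window sites follow the donor-guided
  counts and enough spacer sites are randomly mis-edited to leave a
  configurable guided fraction (default 0.8) of editing events.  Decoy
  reads span the whole editing domain, so the planted fraction is exact
  per read.  Stochastic decoys are genuine cryptogenes (their pre-edited
  state encodes no ORF) whose reads are randomly mis-edited — they are
  transcribed, visibly edited, and unreconstructable, the phenotype of
  cryptogenes that have lost their gRNAs.

What the generator does **not** model: minicircle copy-number dynamics
and network replication, base-composition structure beyond global GC,
indel sequencing errors, partially processed gRNA 5' ends, branching or
alternative editing pathways, and chance gRNA-like loci (removed by
design, see above).  Passing the recovery tests therefore demonstrates
the correctness of the algorithms under the stated model, not their
robustness to every feature of real libraries.

# Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally; GFF3 output is 1-based
closed.  Editing sites are indexed 5'→3' internally with the 3'→5' number
(`n_sites + 1 - i`) reported alongside, since cascades progress 3'→5'.
Reads mapping with no hit or several equally good backbone hits are left
unassigned and counted.  An mRNA shorter than the minimum duplex length
yields an empty alignment set, not an error.  Problem sizes used
throughout the test-suite (a 12-class/240-nt configuration for unit
tests, the full 41-class configuration over 20 seeds for the end-to-end
recovery checks) were chosen as the smallest sizes at which every
planted structure is still non-trivially exercised.

# Known limitations

* The per-pair duplex scores and the seed-nucleation rule are
  interpretations; only the threshold names and values are published.
* The bottleneck-path objective for ORF reconstruction is likewise an
  interpretation of an unpublished objective, flagged as such.
* Circular gene loci spanning a minicircle origin are not searched for;
  re-oriented minicircles place genes away from the origin.
* Class deduplication identity is seed-anchored and heuristic; diverged
  circles sharing no exact seed word would not merge (irrelevant at the
  0.97 threshold it is used with).
* `stage_ucounts` assigns whole sites to a stage; a site exactly at a
  gRNA junction belongs to the later (5'-ward) gRNA.
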