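---
title: "Methods behind cladescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cladescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cladescan` is built around one biological situation: a transcription-factor
family has expanded by tandem duplication, its members share a conserved
spatial arrangement of amino-acid motifs, and the reference annotation has
missed some copies. This vignette describes the models and procedures the
package implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
more than one reasonable choice existed.

## Motif models and discovery

A motif is a position-frequency matrix (PFM) over the 20 standard residues
with a consensus string and a background composition. Discovery
(`discover_motifs()`) does not re-implement expectation–maximization
motif finding; it extracts conserved blocks from a seed alignment, which is
what the downstream stages actually need. Each alignment column `j` is
scored by its information content against the seed-set background
`q`: `IC(j) = sum_a p_aj log2(p_aj / q_a)` (pseudocount 0.01 per PFM cell).
A column is called conserved when three conditions hold:

* `IC >= 2` bits (default `ic_threshold`),
* gap fraction `<= 20%` (`max_gap_frac`),
* the most common residue covers `>= 50%` of rows (`min_dominance`).

The dominance condition exists because the plug-in IC estimate is inflated
at small sample sizes: with 5 sequences a column of five *different*
residues already scores `log2(4) = 2` bits, so IC alone cannot separate
conservation from sampling noise there. Requiring a majority residue is
cheap, scale-free, and leaves genuinely conserved columns (where the
dominant residue covers ~`1 - substitution rate` of rows) untouched.

Columns gapped in at least 80% of rows are masked before run-finding.
These are single-sequence insertions; without masking, one such column can
split a conserved block in two and push a short motif below the minimum
width. Masked columns never contribute to a PFM.

Maximal runs of conserved columns become motifs, bounded to widths 7–50
(the range observed for the seed family's conserved blocks); runs longer
than 50 are split into near-equal pieces, and motifs are numbered `M1,
M2, ...` by decreasing total IC, mirroring how discovery tools rank motifs
by significance. Scanning (`scan_protein()`) slides the PFM and scores
`sum_j log2(pfm[j, residue] / q[residue])`; unknown residues (X) score 0.
A hit is *present* when its identity to the consensus reaches 0.6 and its
log-odds is positive. The 0.6 default is deliberately permissive: diverged
but homologous motif copies in this kind of family retain roughly 70%
consensus identity, and clade membership additionally requires three
independent motifs, so single spurious presences are filtered downstream.

## The genome scan

`six_frame_translate()` produces all six translation tracks with exact
residue-to-genome coordinate maps (internally 0-based half-open intervals;
GFF3 I/O converts at the boundary, which eliminates off-by-one ambiguity in
the window arithmetic). `find_anchors()` locates every presence-called
occurrence of the spatially first and last motifs of the seed
architecture. `build_candidates()` turns anchors into candidate proteins:

* paired anchors (first then last, on one track, within `1.5 × target_len`
  residues) span a window from `first_start − offset_first` to
  `last_end + offset_last`;
* a lone anchor opens a window of exactly `target_len` residues (default
  280, the family's full-length protein size) positioned by the same
  offsets.

The offsets are not free parameters: `anchor_offsets()` measures them from
the seed family itself (mean residues before the first anchor, mean
residues after the last). Windows are clipped to the stop-free track
segment containing the anchor — truncation at a stop is preferred over
rejection because genuinely truncated members exist in real families —
and candidates shorter than 90 residues are dropped (the shortest real
members reported for this kind of clade are ~106 residues, so 90 keeps
every plausible member while removing stop-riddled junk).

Membership requires `>= 3` presence-called motifs of the full catalogue.
Overlapping same-strand candidates collapse to one call (most motifs,
then longest protein, then smallest start), and calls are reconciled
against the annotation at 50% reciprocal overlap into
`confirms-annotated` versus `novel`.

The scan is single-exon by construction: a member whose motifs span an
intron will be found only partially (its exonic anchor still seeds a
window) and may fail the motif-count filter. This matches the known
limitation that multi-exon members of the studied clade require
transcript evidence rather than frame translation.

## Alignments, identity, trees

Pairwise alignment is global Gotoh with affine gaps (gap of length L costs
`open + L·extend`): BLOSUM62 with 10/1 for protein, match +2 / mismatch −1
with 10/0.5 for DNA. The core DP is compiled (Rcpp) and is checked in the
test suite against both an independent explicit-gap-length recursion and
`Biostrings::pairwiseAlignment`. The multiple aligner is standard
progressive alignment: pairwise identities → UPGMA guide tree (leaves
pre-sorted lexicographically so equal-distance joins are deterministic) →
profile–profile Gotoh along the tree, where the column-pair score is the
expected substitution score under the two column profiles (gaps carry zero
weight, so heavily gapped profile columns score low).

Percent identity from an alignment counts identical ungapped columns over
columns where at least one partner is ungapped (columns gapped in both are
skipped); an alternative denominator (shorter ungapped sequence) is
available because published identity figures rarely state their
convention, and the two can differ by a few points on gappy alignments.

Trees are neighbor joining (via `ape`) on `1 − identity/100`, with support
from resampling alignment columns with replacement and counting each
internal bipartition's recurrence across replicates. This is deliberately
not a maximum-likelihood reconstruction: the claim the package needs to
test is monophyly of the family against outgroups, for which NJ with
bootstrap is sufficient and orders of magnitude cheaper.

## Promoter census

Promoters are the 3000 bases immediately upstream of the annotated gene
start, oriented in transcription direction (minus-strand regions
reverse-complemented), with the gene start standing in for the TSS — no
5′-evidence correction is attempted. Element patterns are IUPAC strings
matched exactly (via Biostrings, checked against a regex oracle);
overlapping occurrences count by default, since adjacent boxes genuinely
overlap in real promoters, and both strands are scanned by default with
palindromic patterns counted once per site. Forward-only and
non-overlapping modes exist because published occurrence totals rarely
state either convention; reproduction runs should report both.

## Co-expression consensus

Expression matrices are `log2(x+1)`-transformed, genes with zero variance
or mean below 0.1 are removed (correlation is undefined on constant rows;
the floor is a conventional low-expression cut on the log scale), and the
unsigned adjacency `|cor|^6` is condensed to the topological overlap
matrix. β = 6 is the customary unsigned default; it is a parameter, not a
fitted value — the package does not pick β by scale-free fit, which is
out of scope. Clade connectivity of a gene is its *mean* TOM to the clade
members: the mean is invariant to clade size and is the most conservative
reading of "most connected to the clade". Clade members themselves are
eligible neighborhood occupants (they are each other's strongest
neighbors), but the cross-series consensus report excludes them, since
the question is which outside genes track the family. Rankings break ties
lexicographically so top-k sets are deterministic.

## The synthetic generator

`generate_family_genome()` plants, on one chromosome: a tandem array of
single-exon genes whose translations carry the motif templates in order
(mutated per member at `substitution_rate`), 3000-nt promoters carrying
each cis-element at exactly its planted count on the forward strand and
nowhere else (the background is actively purged and re-verified; an
infeasible plant errors with advice rather than silently miscounting),
random intergenic spacers, a configurable strand pattern (minus-strand
members are emitted reverse-complemented so the scan's coordinate maps are
genuinely exercised), and an annotation covering only `n_annotated`
members. Defaults mirror the studied clade: 18 members of 280 residues, 9
templates with widths 50 down to 7, 12 annotated, one member missing its
4 N-terminal motifs and one missing its 2 C-terminal motifs.

One structural decision deserves emphasis. At `substitution_rate = 0` the
family is clonal — every full-length translation is identical, the
degenerate limit. At positive rates, motif blocks are mutated copies of
the shared templates while the inter-motif spacers are drawn independently
per member. This models spacers as effectively saturated relative to the
conserved blocks and is what makes the family's conservation structure
non-trivial: only the planted motifs are conserved across members, so
motif discovery has a real signal-from-noise task. A single uniform rate
applied to a wholly clonal ancestor could not produce both behaviors.

What the generator does *not* emulate: codon usage bias, introns, indel
evolution within motifs, promoter composition beyond uniform base
frequencies, and expression covariance structure beyond one planted
module. Passing tests therefore demonstrate correctness of the machinery
under a clean null, not performance on real genomes, where repeats,
pseudogenes and compositional bias add failure modes the tests cannot
see.

`generate_expression_series()` draws module genes as
`sqrt(ρ)·z + sqrt(1−ρ)·ε` around a shared per-series latent profile on the
log scale (so expected pairwise correlation is ρ), shifts/scales to a
TPM-like range and exponentiates; background genes are independent. The
same seed reproduces every matrix byte-for-byte.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path while completing in
minutes on one core: 20 random families of 5–20 members for the
planted-recovery study, 2000 genes × 12 samples × 5 series for the
consensus study (the TOM is a dense matrix product; 2000 genes is
comfortable for BLAS), 100-gene instances for exact TOM-oracle comparison
(agreement to 1e−10), 200 random 3-kb promoters for the IUPAC oracle
sweep, and 50 random pairs for alignment-score oracle equality.
Bootstrap support uses 50–100 replicates; support values are exact
fractions of replicates containing a bipartition. Matrix TSVs are written
with `%.17g` and parsed with `strtod` so values round-trip bit-exactly.

## Known limitations

* Discovery of very short motifs (width near 7) is sensitive to alignment
  quality around truncated members; a truncation that removes a terminal
  template can cost the catalogue that one block (detection is unaffected,
  since membership needs only 3 motifs).
* The progressive aligner does not iterate or refine; pathological input
  orders can produce suboptimal alignments, mitigated by the UPGMA guide
  tree and deterministic tie-breaking.
* The scan assumes single-exon members and does not integrate transcript
  evidence.
* PLACE-style catalogues are not bundled; users supply their own pattern
  tables (name + IUPAC string).
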