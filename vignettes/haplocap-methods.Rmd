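---
title: "haplocap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplocap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplocap)
```

## The problem

The killer-cell immunoglobulin-like receptor (KIR) region is a cluster of
roughly fifteen loci — a dozen protein-coding genes, two pseudogenes and one
recombination-hotspot intergenic region — packed into diploid haplotypes of
about 70–270 kb. Any two genes are over 85–98% identical, gene content and
order vary between haplotypes, and the region is dense with Alu and L1
repeats, including a stretch of inverted repeats in the hotspot between
*KIR3DP1* and *KIR2DL4*. Short reads cannot be placed uniquely there, so
the practical route to full haplotypes is hybridization capture of 2–8 kb
fragments, long-read circular-consensus sequencing, per-locus read binning,
per-bin assembly, and finally annotation of the assembled haplotigs.

haplocap implements the computational stages of that workflow — capture
panel design, read binning, haplotig annotation, and assembly evaluation —
together with a synthetic diploid simulator that carries complete ground
truth, so every stage is testable without access to cohort data. Error
correction and assembly themselves are consumed as external steps (the
workflow exposes a command hook and a bypass that accepts pre-made
haplotigs).

## Capture probe design

Probes are 120-base windows of the reference haplotypes. Candidates are
tiled at a fixed stride from position 0; a window is discarded if it
contains a non-ACGT base or overlaps an annotated repeat interval by even
one base (repeats would capture off-target DNA). A terminal window flush
with the reference end is added only when the end would otherwise lie more
than `max_gap / 2` beyond the last tiled window — candidate generation is
not prescribed by any published rule, so the simplest non-ragged tiling is
used and documented.

Each candidate is scored by the number of positions, on either strand of
every reference, where it matches within `allow_mismatches` substitutions,
excluding hits that touch a repeat interval. Selection is greedy by hit
count: probes are added in descending hit-count order (ties broken by probe
sequence, then first hit position) until the largest distance between
consecutive hit midpoints — including the distances to the reference ends —
falls below `max_gap` on every reference. The default `max_gap` of 5000
bases reflects the expected captured fragment length of roughly 4–5 kb: a
fragment overlapping any probe site is captured, so gaps smaller than a
fragment length imply contiguous capture coverage.

This strategy deliberately exploits homology: one probe sitting in a
conserved intron block recurs across all loci of the family, so a handful
of probes covers the whole cluster. `panel_size_experiment()` makes the
effect measurable — a panel for three homologous loci is consistently
smaller than for three unrelated loci of the same size. In that experiment
hits are counted with a 4-substitution tolerance: hybridization capture
(the physical process the hit count models) is robust to a few mismatches
over 120 bases, and homologous loci differ by exactly such small conserved-
block divergences. Exact matching (`allow_mismatches = 0`, the default
elsewhere) is kept for within-reference design, where every candidate
window trivially matches its source.

The greedy order is static: the paper's criterion ranks probes by total
hit count, not by marginal gap reduction, and the implementation follows
that. On small instances a greedy panel can therefore exceed the optimal
set cover; this is a property of the method, not a defect, and the test
suite documents rather than "fixes" it.

## Read binning

On/off-target classification and per-locus binning both reduce to k-mer
matching with `k = 25`, mirroring the short gene-probe matching of the
original workflow (`k=25`, reverse-complement aware, no masked middle
base, any hit counts). K-mers are canonicalized (a k-mer and its reverse
complement share one index entry), a read is on-target when it shares at
least `min_shared_kmers` (default 1) distinct indexed k-mers with the
capture panel, and it is binned to every locus whose catalog it matches.
Multi-assignment is intentional: a read spanning two loci belongs in both
bins, where it preserves junction evidence for per-bin assembly.

The published 25-mer gene-probe set is not distributed, so the locus
catalog is derived: all k-mers of each locus occurrence on the annotated
references, restricted to k-mers unique to exactly one locus. A
two-column TSV reader accepts externally supplied catalogs.

## Annotation

Annotation composes four steps.

1. **Probe signatures.** Every capture probe is aligned to the haplotig on
   both strands with a small substitution budget (default 3 over 120
   bases — assembled haplotigs carry real allelic variation). The ordered
   list of probe labels is the haplotig's signature.
2. **Orientation.** The loci of the family share one transcriptional
   orientation, so a haplotig whose hits are mostly reverse-strand is
   reverse-complemented before pattern matching; reported coordinates are
   mapped back to the input frame with strand `"-"`.
3. **Locus segmentation.** Per-locus probe patterns are learned from the
   annotated references (the ordered labels inside each truth locus
   interval; labels missing from some occurrence are flagged optional).
   The signature is tokenized greedily left to right, each token being the
   longest run of labels forming an ordered subsequence of some locus
   pattern — this tolerates absent probes, the situation seen in real data
   where a probe fails to align in one copy of a repeated pattern. Feature
   intervals extend between midpoints of adjacent tokens (haplotig ends
   for terminal features); the interval between two probe hits has no
   principled owner, and the midpoint is the symmetric, testable choice.
   Because homologous loci can share their entire probe pattern, the
   tokenization fixes only the boundaries; when a locus-specific k-mer
   catalog is available each feature's identity is confirmed by a k-mer
   vote over its interval — the same locus-specific short probes the
   binning stage uses, applied to the assembled sequence.
4. **Boundary placement.** For each junction between adjacent elements
   (UTRs, exons, introns) the references yield a 16-base marker: the last
   8 bases of the left element joined to the first 8 of the right. Within
   a feature, each expected junction is scanned at mismatch threshold 0,
   escalating through 1 and 2 to at most 3 only while no hit exists —
   minimal escalation, so a perfect site is never displaced by a fuzzier
   one. The junction position is the marker start plus 8. Among several
   hits at the accepted threshold the leftmost position strictly after the
   previous junction wins, which enforces element order by construction;
   junctions with no consistent hit are reported missing and the feature
   flagged incomplete.

Allele naming against a `locus*allele` FASTA library proceeds from exact
full-sequence identity (full-gene name), to identity of spliced exonic
sequence (cDNA-level name; library alleles are spliced by scanning the
same markers), to `NEW`. Outputs are GenBank feature-table (`.tbl`) and
GFF3, both 1-based inclusive, both round-tripping through bundled parsers.

## Evaluation

Alignments of haplotigs to reference haplotypes are read from PAF
(residue-match and block-length columns taken as-is) or SAM (matches and
aligned columns derived from CIGAR and the NM tag). Three statistics are
reported per reference:

- **coverage** — 100 × |union of aligned reference intervals| / length;
  overlapping haplotigs are never double-counted;
- **concordance** — 100 × Σ matches / Σ aligned columns, where aligned
  columns include insertion and deletion columns (indels are penalized;
  the published definition leaves this open, so the stricter convention
  is used and stated);
- **LG** — haplotigs are ranked by their aligned reference span
  (descending, ties by name) and their interval unions accumulated until
  `lg_fraction` (default 0.75, i.e. LG75) of the reference is covered.
  Span-ranking rather than raw-length ranking makes the metric
  alignment-aware; the ordering is a documented choice since the verbal
  definition ("the number of haplotigs it takes to phase 75%") fixes
  neither.

A deliberately trivial exact-substring aligner is bundled for fixture
tests only; real haplotigs should be aligned externally (e.g. minimap2)
and imported.

## The synthetic data generator

The simulator emulates the statistical structure the real workflow relies
on, not KIR sequence itself:

- a family of locus templates built from one set of master blocks; each
  template's variable blocks (UTRs and exons) diverge at a rate drawn
  uniformly from `1 - identity_range` (default identity 0.85–0.98, the
  published inter-gene identity band), conserved blocks (introns) and
  repeat elements at one tenth of that rate — conserved/variable
  alternation without committing to a finer mutation model;
- gene templates of ~3.9 kb with three exons, an Alu-like repeat inside
  intron 1; an exon-free intergenic hotspot template dominated by L1-like
  repeats carrying three Alu-like elements, two in opposite orientations
  (the inverted-repeat configuration of the real recombination hotspot);
- diploid haplotypes as ordered locus copies with fresh allelic variation
  (substitution rate 0.002 in variable blocks, a tenth elsewhere),
  random intergenic spacers and flanks; the default pair differs in gene
  content, like A- versus B-family haplotypes;
- reads as uniform fragments of 2000–8000 bases (the capture
  size-selection window) at a default substitution error rate of 0.001 —
  consensus long reads are accurate and no quantitative error profile is
  published, so the rate is a stated choice, with substitutions only
  (consensus indel rates are low and unstated);
- `fragment_haplotigs()` produces pre-broken "assemblies" with exact
  truth, so annotation and evaluation are testable without an assembler.

Real template lengths would be 5–16 kb; the defaults are scaled to desk
size (haplotypes of ~15–20 kb, four loci) so that a full
simulate–design–bin–annotate–evaluate cycle runs in seconds and the
acceptance suite completes in minutes. What passing tests show is that the
algorithms are correct under the generator's assumptions — i.i.d.
substitutions, no structural error within a haplotig, uniform fragment
lengths. They do not show robustness to assembly errors, PCR dropout (the
real workflow's known poly-AT gap), indel errors, or capture bias; those
require real data and are out of scope.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally; both writers
  emit 1-based inclusive coordinates, with start/end swapped on the minus
  strand in `.tbl`.
- All simulator entry points are deterministic under a fixed seed, and the
  RNG state of the calling session is restored afterwards.
- A reference shorter than `max_gap` is already covered by zero probes: an
  empty panel is valid. An empty candidate list is a design-infeasibility
  error; a fully masked reference yields an empty candidate list with a
  warning.
- Probe selection ties break by hit count, then probe sequence, then first
  hit position — fully deterministic.
- A strand tie in orientation keeps the input orientation and warns.
- Elements shorter than 8 bases cannot donate a marker half and are
  skipped with a warning; markers recurring at different junctions of the
  same locus are flagged ambiguous.
- Empty alignment input: coverage of no records is 0; concordance is
  undefined and reported as `NA`, never 0.

## Known limitations

- Thermodynamic probe QC (melting temperature, hairpins, genome-wide
  off-target screening) is out of scope, as in the original workflow it
  was delegated to vendor tooling.
- Allele naming resolves only exact full or spliced-sequence identity; no
  nearest-allele search, and fusion alleles are not called.
- The LG ranking and the concordance denominator are stated conventions;
  alternatives (length-ranked LG, indel-free concordance) would shift
  values slightly on imperfect data.
- The k-mer locus vote assumes the catalog's loci diverge somewhere; on
  loci that are literally identical no method can assign identity, and the
  tokenization label is kept.
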