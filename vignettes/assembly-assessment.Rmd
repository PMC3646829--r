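---
title: "Assessing de novo assemblies against a reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing de novo assemblies against a reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Short-read de novo assembly of fungal genomes is difficult for two reasons
that ordinary size statistics hide: secondary-metabolite biosynthesis (SMB)
genes such as polyketide synthases (PKS) and nonribosomal peptide synthetases
(NRPS) are built from similar repeating units that confuse graph assemblers,
and centromeres are long AT-rich tracts with little sequence complexity. When
a finished reference genome exists, an assembly can be judged much more
sharply than by N50 alone: align the scaffolds to the reference, and ask how
much of the genome is reconstructed *correctly*, in how large pieces, and
with which classes of error.

`asmrecon` implements that assessment for assemblies built from SOLiD
color-space mate-paired reads: the color-space codec and csfasta/.qual I/O,
the read-filtering regimes used for such data, a fragment aligner, the
assembly statistics (N50, NG50, R50), misarrangement classification,
small-indel accounting, per-gene reconstruction scoring and SMB-cluster
continuity testing — plus a seeded synthetic-data generator so every stage is
testable without real sequencing data.

# Statistics

**N50** is the largest length $L$ such that scaffolds of length $\ge L$
together contain at least half of all assembled bases. The statistic is
sometimes worded as "the length $N$ for which 50% of bases are in scaffolds
of length $L < N$"; that wording is internally inconsistent with the
cumulative-sum convention universally used in practice, so `n50()` implements
the standard convention and documents it. **NG50** replaces the half-assembly
threshold with half the *reference genome* size, so redundant assemblies are
not rewarded; `ng50()` returns 0 when the threshold is unreachable.

**R50** is the reconstruction-aware variant: the NG50 computed over the
*reference spans* of scaffold alignment fragments that pass the significance
score, with the reference size as the total. A scaffold with a large N50 but
many misjoins breaks into short aligned fragments, and R50 falls
accordingly — it is the single number that couples contiguity with
correctness. `r50()` counts each fragment's span as-is (matching a
per-fragment reading of the statistic); a `merge = TRUE` variant
union-merges overlapping spans first, for sensitivity analysis.

**Scaffolding ratio** is contig count over scaffold count (contigs are the
maximal N-free runs of scaffolds, `split_to_contigs()`), reported half-up to
two decimals as the conventional tables print it.

# Color space and filtering

SOLiD reads are di-base encoded: each symbol 0–3 is the XOR of the 2-bit
codes (A=0, C=1, G=2, T=3) of two adjacent bases, with the first base carried
as a primer. This reproduces the standard SOLiD encoding matrix: color 0 iff
the adjacent bases are equal, and `decode(encode(s)) == s` for every ACGT
string (property-tested). Undetermined calls are '.'.

Three filtering regimes are provided (`filter_policy()`):

* `nofilter` — keep everything;
* `nodot` — drop reads containing any '.' call;
* `qv` — keep a read only if *every* color has QV strictly above the
  threshold (default 10; QV 10 is 90% base-level accuracy under Phred
  scaling, `qv_to_accuracy()`). The inequality is strict because the
  convention for this filter is "all bases above QV 10", and a strict reading
  keeps the regimes unambiguous.

Two conventions make these regimes strictly nested: '.' positions always
carry QV 0 (enforced on file read even if the .qual file disagrees), so
`qv` survivors are a subset of `nodot` survivors, which are a subset of all
reads. The default pair rule is `both_pass` — a mate-pair with one bad mate
contributes no linkage signal to an assembler, so the pair is dropped whole;
an `independent` mode is kept for ablation since either behaviour is
defensible for this filter.

# The fragment aligner

`align_scaffolds()` is an anchor-and-chain local aligner in the style of
reference aligners used for assembly assessment:

1. exact k-mer anchors (k = 21, sampled every 25 bp of scaffold, plus the
   terminal k-mer) are matched against both reference strands via
   `Biostrings::matchPDict()`;
2. anchors are grouped into chains: split where the alignment diagonal jumps
   by more than `band` (200 bp, accommodating small-indel drift) or where
   more than `max_gap` (500 bp) of scaffold is unanchored;
3. chains are extended outward by exact matching, and the short inter-anchor
   pieces are resolved — by direct comparison when lengths agree, and by an
   affine-gap dynamic programme (Biostrings `pairwiseAlignment`, including
   terminal gaps) when they do not.

Scoring is unit-based: match +1, mismatch −1, a gap of length $L$ costs
$2 + L$. Fragments are kept when score > 40, the conventional cutoff for
significant homology under unit scoring. `local_align()` exposes the same
scoring as a full Smith–Waterman for short sequences and is checked against
an independent brute-force dynamic programme in the tests.

Three numerical choices matter:

* **`max_gap` = 500 bp** is deliberately below the 500 bp misarrangement
  counting threshold. An inversion replaces reference sequence *in place*, so
  the flanking forward anchors sit on the same diagonal; were `max_gap`
  larger than the smallest countable inversion, the chain would bridge
  straight across it and the event would be invisible. With `max_gap` at the
  threshold, every countable event breaks the chain and every sub-threshold
  event may legitimately be absorbed.
* **N never matches** (not even N–N): anchors containing N are discarded and
  the substitution matrix scores any N pairing −1, so assembler gap runs
  cannot contribute to fragment scores.
* **Determinism**: anchors, chains and output ordering are sorted (scaffold,
  scaffold coordinate, then reference coordinate), so repeated runs are
  byte-identical.

Alignments are *not* chained across events — each maximal local alignment is
one fragment — because the misarrangement classifier consumes exactly those
fragment boundaries. Precomputed alignments can be supplied as PAF
(`load_fragments()`; `AS:i` scores and `cg:Z` CIGARs are honoured, 0-based
half-open coordinates converted on read).

# Misarrangement classification

`classify_misarrangements()` walks consecutive fragment pairs of each
scaffold (fragments whose scaffold interval is contained in a longer
fragment's — repeat-induced secondary placements — are ignored):

* different chromosomes, or same-chromosome loci whose reference separation
  disagrees with the scaffold separation by more than `misjoin_bound`
  (default 100 kb, configurable; no principled value exists, so it is simply
  much larger than any indel we count) → **misjoin**;
* a maximal run of fragments whose strand opposes the majority strand of its
  locus block → **one inversion** (a flipped interior fragment is one event,
  not two junctions), counted only when the run spans more than `min_size`
  on the reference;
* reference gap exceeding scaffold gap by more than `min_size` (500 bp) →
  **deletion** of the difference; the reverse → **insertion**.

Counting is per-junction (a scaffold with two misjoins contributes two),
and events of size ≤ 500 bp are never reported. `count_small_indels()`
complements this with base-level insertion/deletion totals, optionally
restricted to gene regions via a mask over the per-indel reference
positions; the mask approach (rather than re-aligning genes to scaffolds)
keeps the genome-wide and gene-restricted counts on the same footing.

# Gene reconstruction and cluster continuity

`evaluate_genes()` aligns each gene's genomic sequence (introns included)
against the scaffolds and keeps segment pairs whose Karlin–Altschul E-value
$E = K m n e^{-\lambda S}$ falls below 1e-100. For unit match/mismatch
scoring on uniform-composition DNA the ungapped constants are
$\lambda = \ln 3$ (the root of $0.25 e^{\lambda} + 0.75 e^{-\lambda} = 1$)
and $K = 0.33$; both are configurable, but downstream logic depends only on
threshold behaviour, not absolute E-values. For each gene, only the scaffold
carrying the top-scoring HSP is used; all qualifying HSPs on that scaffold
contribute (using only the single best HSP would punish genes interrupted by
one small assembly gap, which is not what "reconstructed" means here). The
HSP fraction is the union of HSP intervals over the gene length; the
identity fraction counts identical bases within those intervals, overlaps
resolved in favour of the higher-scoring HSP, and is bounded above by the
HSP fraction by construction. Aggregates are base-weighted (genes weighted
by length), matching a "percentage of gene bases" reading rather than a
per-gene average.

`cluster_continuity()` declares an ordered gene cluster continuous when all
member genes have qualifying HSPs on one and the same scaffold, appear there
in reference order — whole-cluster reversal allowed, since scaffold
orientation is arbitrary — and no foreign gene's best placement falls
between them.

# The synthetic-data generator

The generator produces the statistical structure the assessment assumes,
not a sequencing-error model:

* **Genome** (`simulate_genome()`): 8 chromosomes of 125 kb (1 Mb total) by
  default — a deliberate scale-down from a typical 37 Mb fungal genome so
  the full pipeline runs in minutes, while every size threshold (500 bp
  events, 10/50 kb length classes, 95 bp scaffold floor) is kept at its
  real value so the classification logic is exercised unscaled. GC
  background 0.48 (typical for *Aspergillus*); one mid-chromosome AT-rich
  centromere per chromosome (8 kb, AT ≥ 0.85 enforced by composition);
  non-overlapping genes of 1–2 kb; and gene clusters modelling PKS/NRPS
  repeat structure — each cluster gene built from ~3 repeat units of 1.5 kb
  diverged ~10% from each other. Repeat-unit counts and divergence are this
  package's choices (no published repeat-family statistics exist to copy);
  10% divergence makes cross-unit alignments possible but distinguishable,
  which is the property that matters. Cluster spans are scaled to the small
  chromosomes (28/23/6 kb for 5/4/3 genes) rather than the ~75 kb of real
  SMB clusters.
* **Scaffolds** (`simulate_scaffolds()`): misjoins (cut-and-cross-join
  between chromosomes), in-place inversions, deletions, insertions of novel
  sequence, N-gap runs that replace an equal reference span (assembler gaps,
  deliberately *not* events), and 1–5 bp small indels. Event numbers are
  explicit counts rather than per-base rates so the truth table is fully
  determined by the seed; countable events draw sizes from 600–5000 bp, and
  a separate sub-threshold class (50–400 bp) exercises the 500 bp counting
  rule. Sites keep ≥ 2 kb of clean sequence between events (plus the
  maximum event size), sampled by the exact order-statistics construction so
  placement never fails when feasible. Every event is recorded with exact
  reference coordinates, and a segment table maps every scaffold interval
  back to the reference — the tests rebuild the scaffolds from it.
* **Reads** (`simulate_mate_pairs()`): SOLiD long mate-pair geometry — both
  mates from the same strand of a size-selected fragment, F3 from the 5'
  end, R3 from the 3' end — with Gaussian insert sizes truncated at twice
  the read length (defaults 2764 ± 500 bp, the 2.8 kb library; the 1.9 kb
  companion is 1875 ± 400), 50 bp reads, per-color undetermined-call dropout
  (default 0.01), and a per-position Gaussian QV model with linearly
  declining mean (33 → 20, SD 6, clipped to [0, 40]). The QV model produces
  realistic minimum-QV rejection without modelling the instrument; it is
  *not* a color-space error model, and reads carry no substitution errors.

What passing tests on this data do and do not show: they demonstrate that
the statistics, the classifier and the continuity test are *correct on data
matching their assumptions* — well-separated events, low base-level error,
moderate repeat divergence. They do not demonstrate robustness to densely
clustered rearrangements, high-identity segmental duplications, or
real color-space error structure; on real data the aligner's fragment
boundaries, and hence event coordinates, can shift by a few bases at
repeat-flanked breakpoints.

# Conventions and degenerate inputs

All internal coordinates are 1-based closed, the IRanges/GFF3 convention the
package's dependencies use end to end; PAF's 0-based half-open coordinates
are converted at the boundary. Empty inputs degrade explicitly: `n50()` of
nothing is an error, `ng50()`/`r50()` return the 0 sentinel when half the
genome is unreachable, a scaffold of pure N yields no contigs, and
`scaffolding_ratio()` rejects zero scaffolds. Ratios and table renderings
round half-up (away from zero), not banker's style, to match how such
tables are conventionally printed.

# Problem sizes used by the test suite

The shipped tests run the classifier's exactness check on a 1 Mb genome with
30 countable events (10 misjoins, 5 inversions, 8 deletions, 7 insertions)
plus 6 sub-threshold events, the identity pipeline on a 500 kb genome, the
oracle equivalences on 1,000 random length multisets and 200 random pairs
up to 200 bp, and the filter-nesting check on 10,000 simulated reads; these
sizes were chosen so the complete suite runs in about a minute while every
code path is exercised at the real thresholds.

# Known limitations

* The aligner assumes exact 21-mer anchors exist every ~25 bp of a true
  alignment; regions diverged beyond ~10% or shorter than ~40 bp may be
  missed entirely (they score below 40 anyway).
* Misjoin coordinates are junction estimates from fragment ends; with
  repeats at the junction the breakpoint can be placed anywhere in the
  repeat copy.
* E-values use ungapped Karlin–Altschul constants with a gapped scoring
  scheme; this is the standard pragmatic approximation and only threshold
  behaviour is relied on.
* `coverage_by_class()` materialises one integer per reference base per
  chromosome; fine at the megabase scale the package targets, wasteful for
  hundred-megabase genomes.
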