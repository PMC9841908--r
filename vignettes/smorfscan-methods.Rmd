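---
title: "smorfscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smorfscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`smorfscan` implements an evidence-integration pipeline for small open
reading frames (smORFs, 2–100 codons): discovery from assembled transcripts
and from multi-species conserved genomic regions, confidence tiering from
coding-potential and homology evidence, positional classification against a
gene annotation, union-mode expression quantification with parent-gene
inheritance, pairwise differential expression, and tissue-specificity
scoring. This vignette records the model, every tunable that matters, and
the design decisions taken where a published workflow leaves the behaviour
to external tools or unstated conventions. Nothing here reports an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# Coordinate and sequence conventions

Internally every genomic location is a `GRanges` (1-based, closed
intervals), the native Bioconductor convention; GFF3 input/output therefore
needs no coordinate shifting, and BED conversion is delegated to
`rtracklayer`. Transcript ("spliced") coordinates are 1-based with base 1
the first transcribed base. `txToGenome()` and `genomeToTx()` are exact
inverses on every transcribed base; this round-trip is asserted
property-style in the test suite.

Genome sequences are uppercased on input, so soft-masking is ignored.
Ambiguous bases (`N`) are legal in the genome: a codon containing `N` is
never accepted as a start or stop codon, and internal `N` codons translate
to `X`.

# The start-codon model

Initiation is allowed at ATG and at the nine near-cognate codons differing
from it at exactly one position (TTG/GTG/CTG, AAG/ACG/AGG, ATT/ATC/ATA) —
equivalently, the set of codons within Hamming distance 1 of ATG. A
property test enumerates all 64 codons against this closed form. Peptides
are translated with the initiator rendered as methionine regardless of the
codon's identity, matching initiator-tRNA biology; this matters only for
display and for peptide-level matching, never for coordinate arithmetic.

## The Kozak context window

The species-specific initiation context is summarised over a 14-nt window.
The window is defined here as positions −9…−1 (upstream), +1…+3 (the start
codon) and +4…+5 (2 nt downstream). Descriptions of this window sometimes
give "9 bp upstream and 3 bp downstream" alongside a 14-bp total and
discuss base preferences out to position +4; only a −9…+5 layout is
consistent with both the 14-bp total and a defined +4 position, so that
layout is used (and is configurable in `extractKozakContext()`).

Contexts for starts near the transcript 5′ end are padded with `N` rather
than discarded — discarding would silently bias the model against uORFs.
Profile columns ignore `N` and renormalise; a position observed only as `N`
falls back to uniform. The profile is built from the spliced transcript
sequence, not the genome, because the initiation context is an mRNA
property. "Reliable" genes feeding the profile are those with protein
alignment identity ≥ 30% and coverage ≥ 30% (boundary inclusive), both
configurable.

The profile supports log-odds scoring (`scoreKozakContext()`: per-position
`log2(f/0.25)`, zero frequencies floored at `1e-3`, `N` contributing 0),
but scoring is deliberately **not** a discovery filter: codon identity
decides admissibility, and the score is exposed for ranking only. This
keeps discovery reproducible and independent of profile composition.

# ORF discovery

`scanOrfs()` enumerates, per frame and strand, every stop codon and the
admissible starts since the previous in-frame stop. The default reports the
most-upstream admissible start per (strand, frame, stop) — the
longest-per-stop convention of standard ORF finders; `allStarts = TRUE`
reports every admissible start. Length bounds (default 9–303 nt, i.e.
2–100 codons plus the stop codon) are applied **after** start selection:
an over-long longest ORF is dropped, not silently replaced by a nested
shorter one. The scanner's contract is verified by exact set-equality
against a brute-force oracle (try every position as a start, walk to the
nearest stop) on random sequences in both modes and on both strands.

The upper bound interprets "at most 100 amino acids" as peptide ≤ 100 aa,
i.e. ORF length ≤ 303 nt including the stop; the lower bound comes from the
2-codon floor of the smORF definition. Both are parameters
(`minNt`/`maxNt`) of `smorfParams()`.

Transcript scanning is sense-strand only (assembled transcripts are already
stranded); conserved-region scanning covers both strands, since genomic
alignment intervals carry no reading orientation. Transcript hits are
projected to genomic blocks through the exon structure, so a junction-
spanning smORF has multiple CDS blocks; conserved-region hits are
single-block, because pairwise genome alignments are unspliced — no splice
inference is attempted inside conserved regions.

## Conserved regions

`conservedRegions()` computes maximal intervals where the per-base count of
*distinct species* with an alignment is at least `minSpecies` (default 2;
each species counts once per base however many of its intervals overlap).
Regions shorter than `minLen` (default 30 nt, roughly the smallest
interesting ORF with flanking context) are dropped; the recorded species
count is the maximum per-base coverage inside the region. The sweep is
order-invariant and split-invariant, and is checked against a per-base
counting oracle.

## Candidate identity and merging

A candidate's id is a pure function of its locus:
`smORF:<chrom>:<strand>:<blocks>`. Identical loci found by both routes
merge into one candidate with unioned evidence flags; identical peptides at
different loci stay distinct. Deduplication is by genomic position rather
than transcript position, so isoform-shared smORFs are counted once —
candidate counts depend on this choice, which is stated here deliberately.

# Evidence and confidence tiers

External evidence arrives as tables, not tool invocations: a
coding-potential call per candidate and homology hits with E-values.
Homology follows a peptide-length split: peptides > 15 aa need a hit with
E ≤ 0.15 (configurable `maxEvalue`); peptides ≤ 15 aa — too short for
meaningful alignment statistics — are matched by exact membership in a
short-peptide catalog.

Tiers combine the four flags:

| coding | homology | origin               | tier |
|--------|----------|----------------------|------|
| yes    | yes      | any                  | HC1  |
| no     | yes      | any                  | HC2  |
| yes    | no       | any                  | HC3  |
| no     | no       | transcript           | LC1  |
| no     | no       | conservation only    | LC2  |

`HC4` exists as a reserved enum value: tier schemes of this family
sometimes name a fourth high-confidence level, but no combination of the
four evidence flags maps to it under the logic above, so it receives no
candidates. Every candidate must carry at least one of the
transcript/conservation flags; tier assignment is total and exclusive, and
a partition property test asserts this over all synthetic candidates.

# Positional classification

Categories are assigned by the first matching rule in priority order
(InFrame > OutFrame > uORF > dORF > ncORF > intron > intergenic), the order
in which the categories are conventionally listed. A candidate matching
several rules through different transcripts receives the highest-priority
achievable category — multi-isoform conflicts are resolved by evaluating
against every transcript.

"Within" means every candidate base inside the feature's exonic footprint.
The in-frame test additionally requires the candidate to project to a
contiguous transcript interval whose start is in codon phase with the
annotated CDS — this makes the candidate's peptide a contiguous sub-peptide
of the annotated protein. Partial overlaps fall through: a candidate
overlapping CDS without containment/phase is OutFrameORF; one overlapping a
gene without satisfying any exonic rule is intronORF (this rule fires for
any gene-span overlap, covering both clean intron containment and straddling
cases); intergenicORF requires no gene overlap at all. ncORF containment is
required on the same strand as the non-coding transcript; an antisense ORF
inside a lncRNA exon falls through to intronORF. circRNA is treated as an
annotation biotype label only — no back-splice-aware placement.

# Quantification

`countUnion()` reimplements union-mode counting over exon features,
unstranded: a fragment is attributed to a gene only if every feature any of
its blocks touches belongs to that gene; fragments touching features of two
or more genes are *ambiguous*, fragments touching none are *no-feature*,
and `counted + ambiguous + no-feature = total` holds per sample by
construction and by test. Mapping-quality and duplicate handling are out of
scope because the input is interval fragments, not alignments.

smORF expression follows the parent-gene rule: a candidate overlapping a
gene's exons by ≥ 1 bp (either strand — counting is unstranded) inherits
that gene's count row verbatim; with several genes the largest overlap
wins, ties broken by lexicographic gene id for determinism. Orphan
candidates (no exon overlap — note this includes intronic candidates) are
quantified *independently* over their own region: each orphan's count is
the number of fragments overlapping its blocks, computed per orphan rather
than through the union rule, so overlapping orphan candidates do not
extinguish each other as "ambiguous". The effective length of an orphan for
FPKM is its ORF length; mapped smORFs use the parent gene's exonic length.
FPKM uses the gene-level library size `N` (total counted fragments), not
the column sum of the duplicated smORF matrix.

Sample correlation is computed on `log2(x+1)` (the pseudo-count is a
package convention, stated here because no standard exists); constant
samples get correlation 0 with a warning rather than NA.

# Differential expression

The DE stage is a normative, fully specified default rather than a wrapper
around an external engine: counts → CPM by library size; per tissue pair,
`log2FC = log2((mean1+0.5)/(mean2+0.5))` on tissue-mean CPM; two-sided
Welch t on `log2(CPM+1)` replicate values; Benjamini–Hochberg adjustment
within the pair; a feature is called when FDR ≤ 0.05 **and** |log2FC| ≥ 2.
The fold-change threshold is applied symmetrically in both directions,
which is what makes the tissue-pair count matrix symmetric. Degenerate
zero-variance rows get p = 1 when the group means agree and p = 0 otherwise.
The double gate is conservative: on pure-null simulations the call rate is
bounded at 1% in the acceptance suite, and planted 16-fold effects
(negative-binomial, mean 500, dispersion 0.05, 3 replicates, 200 true among
2,000) are recovered with recall ≥ 0.9 and empirical FDR ≤ 0.1. The test is
intentionally dependency-light and pluggable; reproducing the numerics of
edgeR/DESeq2/voom is a non-goal.

`summarizeDEMatrix()` reports per-tissue means over the n−1 off-diagonal
entries, the overall mean over the n(n−1)/2 unordered pairs, and the
extreme pairs; the overall mean equals the mean of per-tissue means by
algebra, asserted on random matrices and on the shipped silkworm table.

# Tissue specificity

Preprocessing before TSI follows the standard recipe: tissue-level FPKM
(replicate means) with values < 1 set to 0 (exactly 1 is retained), rows
with no remaining expression removed, and a log10 transform. Because log10
of zero is undefined, the transform is implemented as `log10(x+1)` after
the drop step — zeros stay zero — which is the one reading of
"log10-transform, removing zero-expression rows" that is defined
everywhere; the choice is flagged here as an interpretation.

`TSI = max(x)/Σx` per feature; the specific tissue is the argmax (first in
column order on ties). TSI is scale-invariant and its true range is
`[1/n, 1]` for n tissues — the floor is 1/n, not 0, a small divergence from
the loose "between 0 and 1" phrasing common in the literature. Threshold
counts at 0.8/0.85/0.9/0.95/1.0 are monotone non-increasing by
construction and by test.

# The synthetic generator

`generateSyntheticData()` is first-class, tested code that defines the
study conditions the pipeline is validated under: multi-exon genes with
UTRs and introns, lncRNA genes, intergenic space, planted smORFs of all
seven categories (starts cycled through the 10-codon set, in-frame stop, no
internal stop, ≤ 100 codons), ≥ 2-species conservation over the intronic,
intergenic and selected single-exon exonic plantings, and
negative-binomial fragment counts (variance `μ + φμ²`, default φ = 0.05)
over 3 tissues × 3 replicates with planted 16-fold changes and
tissue-exclusive features. All output is a deterministic function of the
seed, byte-for-byte.

Two generator conventions deserve explanation:

* **Guard stops.** Every planted ORF is preceded by an adjacent in-frame
  stop codon. Longest-per-stop reporting picks the most-upstream admissible
  start since the previous stop; the guard pins that choice to exactly the
  planted start whatever the surrounding random sequence contains. Without
  it, recovery would fail sporadically whenever an upstream in-frame
  near-cognate codon happened to occur — a sequence-composition accident,
  not a pipeline property.
* **InFrame plantings are whole short CDSs.** A nested in-frame smORF
  sharing an annotated stop cannot be emitted by longest-per-stop scanning
  when the host protein exceeds 100 codons (the longest ORF is filtered,
  and no shorter start is substituted). InFrame plantings are therefore
  complete CDSs of short protein-coding genes; the nested sub-peptide case
  (e.g. residues 10–40 of a longer protein) is still exercised by
  hand-built classification unit tests.

Planted decoys — a >100-codon ORF and a start-less codon stretch — verify
the length and start filters on real pipeline runs.

What the generator does **not** emulate: sequencing errors and base
qualities (fragments are clean intervals), alignment ambiguity and
multi-mapping, isoform diversity (one transcript per gene), biased fragment
placement, realistic conservation block structure (intervals are exact
envelopes plus decoys), and genome-scale repeat content. Passing the
recovery tests therefore demonstrates the pipeline's *logic* — coordinate
arithmetic, filters, tiering, classification, counting and the statistics —
under the stated noise model; it does not certify performance on real
libraries, where alignment and assembly artefacts dominate.

Problem sizes were chosen so the full suite and the acceptance script
complete comfortably on a laptop: a 2 × 40 kb genome with 54 genes and 56
planted smORFs for recovery runs, 9 fragment samples of roughly ten
thousand fragments each, and 2,000-feature count simulations for DE
calibration.

# Numerical conventions collected

* Kozak scoring pseudo-frequency: `1e-3`; uniform background 0.25; `N`
  scores 0.
* Consensus ties: alphabetical (A < C < G < T).
* Correlation transform: `log2(x+1)`; constant columns → 0 with warning.
* Welch degenerate rows: p = 1 if means equal, else 0.
* DE fold-change shrinkage: +0.5 on tissue-mean CPM before the ratio.
* Parent-gene ties: larger exon overlap, then lexicographic gene id.
* Orphan FPKM length: the ORF's own nt length.
* TSI argmax ties: first tissue in column order.
* Fragment files: BED6 rows grouped by the `name` column (one row per
  block), a deliberately simple on-disk form for multi-block fragments.

# Known limitations

* Tier criteria beyond the four evidence flags (e.g. distinguishing an
  HC4) are not modelled; the implemented logic is the normative behaviour.
* Conserved-region hits are unspliced; a genuinely spliced smORF supported
  only by conservation would be found as its largest exonic piece or
  missed.
* Union counting inherits the known blindness of union mode to
  gene-overlapping reads (they are discarded as ambiguous), and orphan
  independent counting can attribute one fragment to two overlapping
  orphan candidates.
* The DE default is a replicate-level t-test; with 2 replicates per tissue
  it is valid but underpowered, and no dispersion shrinkage across features
  is attempted.
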