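---
title: "Locus-resolution HML-2 transcription profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-resolution HML-2 transcription profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hml2profiler)
```

## The scientific setting

HERV-K(HML-2) proviruses are a family of ~70 highly similar paralogs, several
of which retain protein-coding capacity. Because short-read RNA-seq cannot
place reads confidently on the youngest (most similar, most biologically
interesting) loci, a Sanger-based strategy is used instead: long amplicon
cDNA clones from three diagnostic RT-PCR assays (a ~620-nt gag region, an env
5' region spanning the 292-bp indel that distinguishes type 1 from type 2
proviruses, and a rec/np9 amplicon spanning a spliced intron) are assigned to
individual loci through locus-specific nucleotide differences. The relative
cloning frequency of a locus — the fraction of a sample's clones assigned to
it — serves as a proxy for its relative transcript level.

This package implements that analysis as composable, tested stages. This
vignette records the models, the tunable parameters, the synthetic-data
design, and the choices made where the design was genuinely open.

## Assignment model

Each read is compared with every per-locus in-silico amplicon by a
*fit* edit distance: the read must align end-to-end while the amplicon's ends
are free. This treats a truncated Sanger read fairly (it is not charged for
amplicon sequence it never covered) while refusing to discard read sequence.
Unit costs (substitution 1, gap position 1) keep the distance an
interpretable count and make the decision rule checkable against an
independent dynamic-programming oracle, which the test suite does
exhaustively on 500 reads × 10 loci.

Decision parameters:

* `margin` (nt, default **0**): loci within `margin` of the minimal distance
  form the best set. A singleton is `unique`; two or more are `ambiguous` and
  are reported as a composite category (`"a|b"`) that stays one row in every
  frequency table — the convention the published per-sample tables use for
  locus pairs lacking discriminating positions within the amplicon. The
  default 0 means strict ties only: ambiguity arises from genuinely
  indistinguishable loci, not from read error. With `margin > 0` a locus at
  exactly `min + margin` is inside the set (the set-inclusion reading; at the
  boundary, set membership and the `second - best >= margin` reading differ
  and we use the former consistently).
* `max_distance` (fraction of amplicon length, default **0.05**): the error
  ceiling that absorbs Sanger/PCR error; above it a read is `unassigned` with
  reason `distance`. Reads outside 0.5–1.5× of the amplicon length range are
  `unassigned` with reason `length` before any alignment.

Orientation is decided per read (the cDNA strategy is unstranded): the
orientation minimising the distance to any amplicon wins, ties break toward
forward. Raising `margin` can only grow best sets; raising `max_distance` can
only shrink the unassigned count — both monotonicity properties are tested.

## Difference counting and diagnostic sites

Pairwise locus differences are counted from a global affine-gap alignment
(match +1, mismatch −1, gap open −5, gap extend −1) as substitutions plus
*indel events*: a contiguous gap run counts once, whatever its length.
Otherwise the 292-bp type indel would dominate every type-1-vs-type-2
distance and drown the substitution signal the assignment relies on. Whether
published difference counts included indels at all is not stated in the
literature this mirrors; counting each run once is recorded here as the
package's convention.

The implied multiple alignment for diagnostic sites is built progressively
against the longest amplicon as anchor rather than by joint multiple
alignment: pairwise alignments are reproducible, oracle-checkable and
sufficient for amplicons this similar. Sites where exactly one locus carries
a deviant base are flagged `private`; locus pairs with difference 0 are
reported as indistinguishable groups, and reads from them can never be
unique (a tested invariant).

## Provirus typing

Type calls come from a global alignment of the query's env 5' region to a
type-2 reference with cheap gap extension (open 5, extend 0.1), so length
differences surface as long gap runs rather than being absorbed as
mismatches. The segment "present" rule tolerates < 50 nt of gaps inside the
292-bp segment; the "absent" rule requires a single deletion of 292 ± 10 nt
overlapping it (an 8-nt flanking co-deletion still counts; a 28-nt one does
not and yields `unknown`). Queries shorter than 100 nt are rejected.

## Splice inference

Spliced alignment seeds the read onto its locus with near-free long gaps
(open 10, extend 0.05), so a multi-kb intron costs little more than opening
it; deletion runs ≥ `min_intron` (default **50 nt**) become introns, exon
blocks must reach `min_exon` (**20 nt**, shorter internal blocks dissolve
into a single merged intron). Boundaries are then refined: among all
mRNA-equivalent placements within ±10 nt (a placement is equivalent iff the
moved bases are identical, the classic splice-wobble criterion), a GT..AG
placement is preferred; among several, the acceptor closest to the annotated
SA2 wins. Defaults reflect the biology: the rec intron is kb-scale and the
interesting alternative acceptors sit hundreds of nt away, so a 50-nt floor
excludes alignment noise without risk.

Classification is junction-based against per-locus annotations (SD2, the
type-1 np9 donor, SA2, the 3' LTR start, the Env/Rec/Np9 start): SD2→SA2 on
type 2 = `rec`; np9-SD→anything = `np9` with the signed `acceptor_offset`
(the mutated-acceptor case surfaces as +7); SD2→non-canonical =
`np9_like_alternative` (+260 into the 3' LTR in the canonical example); no
introns = `unspliced`; everything else `unknown` with a reason. The
annotation schema carries an explicit `np9_sd` field: the type-1 np9 donor
is a distinct site and classification is impossible without it. A
length-based fallback (`classify_by_length`) exists for annotation-free loci
but is never preferred.

## Coding prediction

ORFs are maximal stop-to-stop open spans of ≥ 50 codons (the smallest
relevant product class, Np9, is well above that), so no reported ORF is
extendable in either direction — a tested invariant, along with exact
re-translation of every reported span. ORFs are mapped onto the 699-aa
canonical Env through an alignment of the canonical CDS to the locus, then
classed: `full_length_env` (aa 1–699, type 2 only), `type1_env` (starts
downstream of the indel, reaches TM), `pol_env_fusion` (≥ 30 codons
upstream of the env start), or a fragment class by domain content.

The domain map defaults to SP end = aa **96** and furin site = aa **463**.
The furin position is not printed anywhere authoritative; 463 is derived from
the approximate 41/26 kDa SU/TM mass split of the 699-aa precursor and is an
explicit, overridable parameter. Masses are sums of average residue masses
plus one water; published "approx." kDa values fold in gel mobility and
glycosylation, so the package treats them as ±15% bands and never as exact
targets (the SP's nominal ~13 kDa is not validated against sequence mass at
all, since its gel behaviour is known to be anomalous).

Spliced proteins are translated from the annotated start after in-silico
intron removal. A stop within the first 25 codons yields class `none` with
the stop position (the retrocopy's stop at Rec codon 19 is the canonical
case). Classification against the canonical references is exact for Rec/Np9
and prefix-based for `Rec_truncated`; chimeric products require each half to
reach ≥ 60% identity over ≥ 30 aa against its reference window (N-half vs a
Rec/Np9 prefix of its own length, C-half vs the Env C-terminus). The 60%/30
aa rule replaces dot-matrix window heuristics with a single reproducible
alignment criterion; identities use PID1 (gaps count against identity) so a
shared prefix alone cannot saturate a match.

## Quantification and statistics

Relative cloning frequency = 100 × count / column total, ambiguous composites
and the explicit `unassigned` row included in denominators by default
(configurable), so columns sum to 100. Two aggregation modes are first-class
because they answer different questions and both appear in practice:
`per_sample_mean` (unweighted mean of per-sample frequencies, with range) for
group comparisons, and `pooled` (share of all clones in the group) for
"fraction of the transcript pool" statements. They coincide exactly when all
samples have equal totals (tested).

`compare_groups` screens each group with Shapiro–Wilk at α = 0.05 and then
applies Welch's *t* (both normal) or a rank-based test. The rank default is
the two-sample rank-sum: a "signed-rank" test on unpaired disease/control
groups is statistically incoherent, so the signed-rank variant is available
only for genuinely paired designs, and the choice made is always reported in
the result object. No multiple-testing correction is applied by default
(matching field practice for these per-locus tables); `stats::p.adjust` is
the intended escape hatch. The test suite pins the rank branch to the exact
permutation null and the Welch branch to a 10,000-permutation oracle with
finite-sample slack.

ΔΔCt follows the standard model: ΔCt = mean Ct(target) − mean Ct(normalizer)
per sample, ΔΔCt relative to the designated high-expression reference sample
(fold ≡ 1 by construction), fold = 2^−ΔΔCt, with the replicate SD propagated
as √(s²target + s²normalizer) and reported as a fold range. Fold changes are
invariant to any constant Ct shift (tested). Amplification-efficiency
corrections (Pfaffl-type) are out of scope.

## The synthetic study

`simulation_config()` defaults *are* the study conditions and are not tuned
per test:

| parameter | default | rationale |
|---|---|---|
| `n_loci` | 20 | size of the observed transcribed gag panel |
| `reads_total` / `n_samples` | 820 / 28 | the gag panel's clone and sample counts |
| `mixing_proportions` | 0.53, 0.121, 0.104, 0.067, rest equal | the observed skew; top four ≈ 82% |
| `read_error_rate` | 0.002/nt | Sanger + PCR error scale |
| `type2_fraction` | 0.4 | roughly the panel's type composition |
| `identical_pair` | TRUE | forces one 0-difference pair (assignment ambiguity) |
| `retrocopy` | TRUE | a pre-spliced rec-mRNA locus, no gag amplicon, stop at Rec codon 19 |
| `mutated_acceptor` | TRUE | a non-reference type-1 locus whose canonical acceptor AG→GG with a new AG 7 nt downstream |
| `max_subs` | 20 | per-locus substitutions, giving 1–40 pairwise differences |

All loci descend from one synthetic ancestor provirus with a fixed layout
(`provirus_layout()`): a 699-codon env CDS preceded by an in-frame stop, the
292-bp segment containing SD2, the np9 donor upstream of it, SA2 near the CDS
end, and — planted in the 3' LTR — an alternative acceptor 260 nt downstream
of SA2 followed by a copy of the first 19 exon-3 codons and a stop, so the
alternatively spliced product is *by construction* the Rec protein lacking
its C-terminal 17 aa. Substitutions are planted only in the gag amplicon
interior, never in primer sites (fixture primer matching cannot silently
fail) and never in the env CDS (the canonical coding fixtures stay intact);
locus differences are therefore concentrated in the assignment amplicon,
which is the property under test.

What the generator deliberately does **not** emulate: phylogenetically
realistic HML-2 evolution (a star topology replaces the real tree),
chromatogram-level error profiles (substitutions only, no quality scores),
PCR chimeras and primer-mix amplification bias (ratios are carried as
metadata but default to unbiased), and real locus sequences. Passing tests
therefore demonstrate the correctness of the machinery under controlled
conditions, not concordance with any particular genome build; real use
requires a user-supplied locus FASTA + metadata table and splice
annotations.

Problem sizes in the tests and the acceptance script (500 × 10 oracle
comparison, one 820-read study, 10,000-permutation oracles) were chosen as
the smallest sizes at which the statistical checks are meaningful.

## Coordinates and I/O conventions

All internal coordinates are 1-based closed intervals, the R/Bioconductor
convention; anchor positions in metadata are single 1-based coordinates as
printed in locus tables. Sequence I/O is plain multi-FASTA plus tab-separated
metadata (CRLF and trailing whitespace tolerated); registries round-trip
byte-identically. The four degenerate forward primers of the published assays
are not part of the protocol text and must be supplied by the user; only the
six env600nt reverse primers ship verbatim
(`env600nt_reverse_primers()`). The synthetic assays generate their own
primers.

## Known limitations

* Assignment is hard-margin, not probabilistic: no EM reallocation of
  multi-mapping reads, no quality-score weighting (no chromatograms exist in
  this setting).
* Boundary refinement requires exact shift-equivalence; a read error exactly
  at an intron boundary can leave a non-canonical (unrefined) placement.
* `classify_provirus_type` assumes the query covers the indel region; heavily
  truncated windows return `unknown` rather than guessing.
* Chimeric-protein detection uses fixed half-splits; products whose breakpoint
  is far from the midpoint may be under-called.
* The per-sample statistics treat samples as independent; donors contributing
  several tissues are not modelled (no mixed effects).
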