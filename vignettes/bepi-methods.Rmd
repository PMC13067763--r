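---
title: "Scoring, quantification and screen analysis for base-editor engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, quantification and screen analysis for base-editor engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bepitools)
```

`bepitools` implements the computational layer of a cytosine base-editor
(CBE) engineering campaign: scoring editors on a composite
efficiency-vs-safety index, quantifying editing outcomes from amplicon
reads, designing balanced site-saturation libraries, analysing iterative
selection screens, and aggregating structure-derived geometry. This
vignette records the models, the conventions, and the design choices made
where the problem left them open.

## The BEPI scoring model

A CBE is characterized at a target site by two percentages: C-to-T
conversion (the desired outcome) and indel frequency (the principal
unwanted outcome, arising from double-strand-break processing). Ratios
like C-to-T/indel are misleading when indels are rare — a tiny denominator
inflates mediocre editors — so the package scores editors with the Base
Editor Performance Index. Fifteen candidate formulations across four
families (arithmetic, rational, logarithmic, exponential-decay) were
screened historically; the package ships the two printed in full:

* Formula 11: `c_to_t / exp(indel / 10)`
* Formula 14: `(c_to_t - indel) / exp(indel / 10)` — the selected form.

Both share the exponential penalty, which grows slowly below ~2% indels
and steeply above; Formula 14 adds a linear penalty in the numerator that
separates 0% from low indel frequencies, where Formula 11 is nearly flat.
The remaining thirteen formulation slots are registry placeholders
(`register_bepi_formula()`): their algebra is not published in the main
text, and inventing it would misrepresent the family, so users who have
the definitions can plug them in.

Formulations are compared on a fixed scenario grid of seven C-to-T levels
spanning 2.5–100% and eight indel levels spanning 0–10% — 56 cells. Only
the counts and endpoints are fixed by that design; the default interior
points (5, 10, 25, 50, 75 and 0.5, 1, 2.5, 5, 7.5, 9) are an even spread
over the ranges and are configurable. A formulation passes selection when
it is (i) strictly increasing in conversion at every grid indel level,
(ii) strictly decreasing in indel frequency at every conversion level, and
(iii) ranks a 75%-conversion / 7.5%-indel editor above a 50% / 5% one —
the "reward high efficiency under proportional indels" criterion.
`bepi_criteria()` also reports the low-indel discrimination margin
`score(c, 0) - score(c, 1)` at a reference conversion (default 50%),
the quantity on which Formula 14 beats Formula 11.

Scores are kept at full precision internally; display rounding is two
decimals, matching how such scores are reported. Negative scores (indel
exceeding conversion) are returned unclamped — clamping would hide exactly
the pathological editors the index exists to expose.

## Amplicon quantification conventions

**Coordinates.** Protospacer positions are PAM-relative: the PAM-proximal
base is position 1 and positions increase toward the 5' end, so 5' index
`i` in a 20-mer maps to position `21 - i`. This is the only convention
consistent with the annotated editable-cytosine positions of the three
packaged repeat-targeting spacers (13; 12 and 15; 12) under the window
12–17. Display coordinates on the full reference are 1-based inclusive.

**Reference construction.** `build_reference()` concatenates barcode,
the constant `GA` linker, the 20-nt protospacer, the PAM and a fixed 30-nt
suffix, recording component intervals. The default analysis window is
11–19 — deliberately broader than the empirical high-activity window
(12–17) so that window choice is an explicit, recorded parameter rather
than a guess; the two window statements in circulation cannot both be the
same convention, so the package exposes it as configuration.

**Alignment.** Reads are aligned globally (Needleman–Wunsch, affine gaps;
match +2, mismatch −3, gap open −5, gap extend −1 — conventional
parameters for short amplicons) via `Biostrings::pairwiseAlignment()`.
Reads below 60% alignment identity are flagged unaligned and excluded
from every denominator; they never raise errors. Deletion gaps are
normalized to their leftmost equivalent placement, the standard indel
normal form, so that gap-placement ambiguity in repeat context cannot
move an indel across the region boundary between runs or tools.

**Read accounting.** The indel frequency is the percentage of aligned
reads carrying an insertion or deletion overlapping the
protospacer∪PAM region, over all aligned reads. A deletion overlaps when
it removes at least one region base; an insertion overlaps when its
junction lies strictly between two region bases (an insertion after the
region's last base disrupts nothing inside it). Reads with such indels
are excluded from substitution numerators and denominators: their base
calls at deleted positions are undefined, and mixing outcome classes
would double-count. The remaining reads feed per-position C-to-T, C-to-A
and C-to-G counts (C-to-D is conversion to any of A/G/T, so window
C-to-T ≤ C-to-D holds by construction) and the three read-level window
classes: C-to-T inside the window, C-to-T outside it at the amplicon
level, and other substitutions inside the window.

**Window inference.** `infer_editing_window()` finds the maximal
contiguous run of positions whose C-to-T rate is at least a configurable
fraction (default 0.3) of the peak rate, breaking length ties toward the
PAM-proximal run. The threshold is a shape parameter, not a claim about
any particular editor; an all-zero profile is an error ("no editing
detected") rather than an arbitrary window.

## Balanced codon design

A degenerate codon (three IUPAC symbols) encodes the multiset of
translations of its Cartesian expansion. A site-saturation scheme is
*balanced* when every target amino acid is encoded by exactly one concrete
codon across the scheme and no expansion contains a stop. Mixing the
degenerate primers in molar proportion to their expansion sizes then
represents every amino acid equally — for the reference scheme
VAS/DGG/TNC/VYC/ATG (encoding HQNKDE / WRG / FSYC / LPITVA / M) the ratio
is 6:3:4:6:1 over 20 concrete codons.

`design_balanced_scheme()` searches for such schemes as an exact-cover
problem. Only codons whose expansion is stop-free and hits each amino acid
at most once can appear in a balanced scheme; of the 3375 degenerate
codons, 707 qualify, collapsing to 325 distinct amino-acid sets. The
search therefore enumerates set partitions of the target: a deterministic
depth-first search over blocks in canonical order (set size descending,
then lexicographic), which makes results independent of target-set
ordering. Because deduplication makes full enumeration cheap (the all-20
target has 662 partitions and runs in seconds), the default returns every
solution rather than a truncated list; each returned block carries all
degenerate codons realizing its set, and `as_scheme()` picks concrete
representatives. Rare codons (per an optional user-supplied list) down-rank
schemes without excluding them — no single usage table is canonical across
expression hosts. Stop codons always disqualify.

## Screen enrichment analysis

The bacterial selection applies three simultaneous pressures — base-editing
activity (rescue of a defective resistance-gene start codon ACG→ATG),
counter-selection of high double-strand-break variants (guides targeting
genomic repeats present 2, 7 or 12 times), and tolerance of continuous
expression — over four rounds. The analysis stages are:

* **Merging.** Read 2 is reverse-complemented and merged with read 1 by the
  best ungapped overlap of at least 15 nt with at most 10% mismatches;
  overlap disagreements resolve toward the higher base quality, ties to
  read 1. Amplicons are fixed-length, so no indel is allowed across the
  junction; unmergeable pairs are flagged and dropped from counting.
* **Counting.** Reconstructed sequences are counted exactly, per round,
  at the nucleotide level; `call_substitutions()` provides the
  protein-level view (and flags frameshifts — historically the signature
  of toxic-variant escape).
* **Fold enrichment.** Abundances are per-round frequencies. The fold
  change of a variant is its final-round frequency over its first-round
  frequency, with the denominator floored at half a read
  (`pseudocount = 0.5`) so variants absent from round 1 get large finite
  folds rather than infinities — standard enrichment practice, and
  configurable. A raw-count mode is provided since the original rule's
  scale is not stated; frequencies are the default because they are
  invariant to per-round sequencing depth.
* **Hits.** "More than a 1000-fold increase" is read literally: the
  comparison is strict (`>`), so a variant at exactly 1000 is not a hit.

Combinatorial libraries are enumerated as Cartesian products over
per-site residue sets; the packaged four-site specification (R14: R/D/W,
Q17: Q/P, V33: V/F/H/W/Y, K39: K/A/I, wild type first) yields the
90-member library including the all-wild-type combination.

## Structure geometry

Distances between residues use a side-chain reference atom by default —
NZ for lysine, OH for tyrosine, CB otherwise (CA for glycine) — because
the published pocket-entrance distances plausibly reflect side-chain
geometry; the atoms actually used upstream are not named, so a CA mode is
provided and the rule is recorded on every panel. Pocket surface areas
are consumed from tables (five replicate structure predictions per
scanned position in the reference protocol), never computed: alpha-shape
pocket computation is out of scope. Aggregation is the arithmetic mean
per position, ranked descending, ties to the lower residue number.
Trilateration solves the three-sphere intersection in closed form,
returns both mirror solutions when they exist, accepts solutions within
1e-6 Å residual, and reports residuals when the distances are
inconsistent. Collinear anchors are an error, not a warning.

## Synthetic data: what it does and does not emulate

`simulate_amplicon_reads()` draws, per read, either one indel (probability
`indel_prob`; length 1 + geometric(0.5); deletion starts uniform over the
protospacer∪PAM region, insertion junctions uniform over its interior) or
independent per-cytosine conversions at the specified PAM-relative
probabilities, then uniform sequencing errors. Two constraints keep the
generator's ground truth alignment-unambiguous, so that quantification can
be checked exactly at zero sequencing error: deletion positions whose
left-aligned gap placement would slide out of the region are rejected, and
the flanking bases of an insert are drawn different from their reference
neighbours. Every event is recorded in a ledger keyed by read.

`simulate_screen_rounds()` models selection as multinomial resampling
proportional to frequency × survival, with survival =
activity × exp(−dsb_hazard × copies) × viability. The exponential
double-strand-break term reflects independent per-copy lethality at a
repeat present `copies` times; the product form is a modeling choice made
to exercise the counting and enrichment machinery — the underlying biology
specifies only the qualitative logic of the three axes.

The simulators emulate the statistical structure the analyses assume
(position-dependent conversion, region-overlapping indels, sequencing
error, bottlenecked selection) but not instrument error profiles,
quality-score correlations, PCR jackpotting, or the lesion-processing
biochemistry behind indel formation. Passing parameter-recovery tests
therefore validates the bookkeeping — the estimators recover what the
generator put in — not the biological realism of any rate.

## Problem sizes and numerical choices

The test suite and acceptance checks run at deliberately desk-scale sizes:
2000 simulated reads for parameter recovery (binomial 3-standard-error
bands), 20 seeds for neutral-screen calibration at a 2 × 10⁴ bottleneck,
and the full 20-amino-acid design enumeration (seconds). Tolerances:
1e-12 for algebraic identities, 1e-6 Å for trilateration residuals,
3 binomial standard errors for rate recovery. Seeds are explicit
everywhere randomness exists; identical seed and specification give
byte-identical simulator output.

## Known limitations

* Only Formulas 11 and 14 ship with evaluators; the other thirteen are
  user-fillable placeholders.
* The quantifier is not a reimplementation of any external analyzer;
  parameter choices (alignment scores, 60% identity, window) are
  documented defaults, and agreement with other tools' output is not
  bit-for-bit.
* Quality scores are ignored in alignment and used only for overlap
  arbitration in merging; UMI handling and demultiplexing are out of
  scope.
* `read_structure()` reads PDB files (first model, altloc A); mmCIF
  support depends on the installed bio3d reader and atom tables can be
  supplied directly as data frames.
* The composite score for one published five-site variant (20.24) does
  not recompute from its printed mean activity and indel rate (the
  formula gives 19.90); the reference-editor value (10.34) does. The
  package asserts only the latter.
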