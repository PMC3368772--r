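---
title: "mirforge: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirforge: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirforge)
```

mirforge analyses plant small-RNA sequencing libraries end to end: read
cleanup and collapsing, categorization of unique small RNAs against an
annotated reference, assignment to conserved miRNA families, hairpin-based
discovery of novel miRNA precursors under structural rules, detection of
post-transcriptional modifications (RNA-editing-like substitutions and the
−1+UU isoform), and penalty-scored target prediction with cleavage-site
calling. This vignette explains the models behind each stage, the defaults
and their units, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## Coordinates and alphabets

All coordinates in mirforge are 1-based and inclusive, in both the API and
the report files. R's own containers are 1-based, every Bioconductor range
type is 1-based inclusive, and carrying a second convention through a
tibble-centric API invites off-by-one errors; the report headers state the
convention. Sequences are RNA internally (`A`, `C`, `G`, `U`); DNA input is
accepted everywhere and normalized silently, because transcript and EST
databases are customarily DNA while small-RNA tables are RNA.

## Read cleanup

A small-RNA read sequenced past its insert runs into the 3′ adapter, so the
adapter appears as a read suffix matching a prefix of the adapter sequence.
`trim_adapter()` removes the leftmost such suffix/prefix overlap of at least
`min_clip` nucleotides (default 6 nt, 0 mismatches; up to 1 configurable).
The leftmost qualifying overlap removes the longest adapter stretch, i.e.
the shortest insert consistent with the evidence. Reads with no adapter
evidence are dropped by default (`keep_untrimmed` retains them): whether
adapter-less reads should survive is a judgement call, and dropping them is
the conservative choice for libraries where the insert is shorter than the
read. Inserts are then kept in the 17–32 nt window — the observed length
range of plant small-RNA libraries — and collapsed into a unique-sequence
library with counts. Count conservation (Σ counts = surviving reads) is a
tested invariant. An optional mean-Phred filter exists but is off by
default, since no principled threshold is universal.

## Categorization

Short reads are categorized by exhaustive ungapped full-length matching
against an annotated reference set (both strands, ≤1 substitution by
default). At 17–32 nt, exhaustive scanning is exact and reproducible where
a heuristic aligner would introduce seed-dependent artefacts. The closed
category set is miRNA, tRNA, rRNA, sn/snoRNA, ncRNA, transposon, pseudo
mRNA, coding mRNA, plus *no hit* and *hit, unknown* (hits only to records
without a category label). Multi-category ties at equal mismatch count are
resolved by the fixed precedence just listed: structural RNA classes outrank
mRNA so that degradation fragments of structural RNAs are not absorbed into
the mRNA class. The precedence is a design choice — the field has no
standard — and is applied deterministically.

## Conserved family assignment

A read joins a family when it can be placed ungapped against a reference
mature with an overlap of at least 19 nt and at most one substitution, the
classical criterion for family-level conservation. The 19-nt bound is
interpreted as *alignment overlap*, not read length: this is the more
permissive reading and the one that admits 5′/3′ extensions, letting
23–27 nt long miRNA-like isoforms of a 21-nt mature stay with their family.
Best placement maximizes overlap, then minimizes mismatches; residual ties
between families are broken lexicographically (deterministic), and declared
synonym groups (e.g. families distinguishable only at one position) can be
merged by configuration. Family profiles are count-weighted and flag a
family *short* (dominant length 20–22 nt) or *long* (23–27 nt); dominant
length ties go to the shorter length.

## Folding model

Precursor discovery needs a secondary-structure model. mirforge ships a
simplified nearest-neighbour model: a 6×6 stacking table over the allowed
pairs (AU, UA, CG, GC, GU, UG) with standard Watson–Crick stacking free
energies and class-averaged wobble terms, size-dependent hairpin, bulge and
interior-loop penalties with logarithmic extrapolation, and an affine
multiloop term (a = 3.4, b = 0.4 per branch, c = 0 per unpaired nucleotide,
kcal/mol at 37 °C). Terminal mismatches, dangling ends, loop-asymmetry
penalties and special tetraloops are deliberately omitted; interior and
bulge loops larger than 30 unpaired nucleotides are disallowed. Pseudoknots
are excluded (nested structures only), and multibranch optima are allowed
by the folding engine but rejected later at the rule stage if the mature
does not sit in a stem arm.

`rna_fold()` computes the exact minimum-free-energy structure under this
model by dynamic programming over integer centi-kcal energies (exact ties,
no floating-point ambiguity), with deterministic tie-breaking that prefers
pairing the leftmost differing base. The test suite validates the DP
against exhaustive enumeration of *all* nested structures for hundreds of
short random sequences, and re-evaluates every reported structure with an
independent loop-decomposition scorer. Energies from this model are
comparable only within the model; the reports carry its version string
(`mirforge-nn-1.0`).

## Precursor rules and discovery

A candidate hairpin must satisfy, under `precursor_rules()` defaults: mature
length 20–22 nt; folding free energy ≤ −25 kcal/mol; at most 6 unpaired
nucleotides within the miR:miR\* duplex (3′ overhangs excluded); miR–miR\*
distance between 5 and 240 nt; and the mature wholly within one stem arm.
The energy ceiling is a rule *bound tied to the model in use* and is
configurable; the mature-length window can be widened (e.g. 20–27) to admit
long miRNA-like species, but stays narrow by default. The miR\* is predicted
from the pairing trace: star = positions pairing mature\[start .. end −
overhang\], extended by the 2-nt 3′ overhang characteristic of Dicer-like
processing, with bulged positions interpolated from the nearest paired
neighbour.

`find_precursors()` folds windows around each exact read locus (±250 nt by
default, plus shrinking sub-windows at ½, ¼ and 1/10 of the extent on each
side — a geometric grid that catches precursors much smaller than the full
window), keeps windows satisfying every rule, trims survivors to the
duplex-bearing stem (extending outward while the flanks still pair each
other, plus a 5-nt pad), refolds and re-checks the trimmed precursor, and
reduces overlapping survivors to the lowest-energy one. The two-stage check
matters: trimming removes chance complementarity in the flanks, so a weak
hairpin cannot borrow stability from unrelated flank structure.

One geometric fact discovered during design: under a minimum hairpin loop of
3 nt and the 2-nt overhang geometry, the smallest achievable miR–miR\*
distance is exactly 5 nt — the lower bound of the distance rule is the
geometric floor, so only the upper bound (240 nt) can actually reject a
candidate.

Read-mapped precursors are classified into the five-class taxonomy by how
reads distribute over the predicted miR/miR\* regions (a ±12 nt margin per
side around each region — the "around the duplex" window is ambiguous in the
field, and a symmetric per-side margin is the reading implemented, exposed
as `duplex_margin`): class 1, all reads within the miR/miR\* regions with
both strands supported; class 2, both strands supported plus weaker reads
outside; class 3a/3b, reads on the defining region only (≥2 reads / exactly
one); class 4, defining read plus weaker outside reads without star
support; class 5, an outside read more abundant than the defining read.
The classes partition: every candidate with at least one read gets exactly
one label.

## Modification detection

Within a family, reads whose best placement shows exactly one substitution
*inside the reference body* become editing candidates; each distinct
(position, reference base, observed base) combination is an event whose
frequency is 100 × supporting reads / all reads assigned to the family,
reported to 3 decimals. The denominator is the whole family (not just
reads of the affected length) — the natural reading when events are
reported per family. Substitutions in 5′/3′ extensions are not editing and
are excluded; indel-bearing reads are out of scope. Sequencing error is
not distinguished from editing (no error model is fitted); a minimum-support
option is exposed instead. The −1+UU isoform is exact string identity:
reference minus its first nucleotide plus `UU`, hence always one nucleotide
longer than the reference.

## Target prediction

Plant miRNA targets are found by penalty-scored complementarity: each
alignment column costs 0 (Watson–Crick), 0.5 (G:U wobble), 1 (other
mismatch) or 2 (gap), and a site is reported when the minimum total penalty
is ≤ 3, the alignment spans ≥ 20 columns (`"conserved"` preset; 18 for
`"novel"`), and miRNA positions 10–11 — numbered from the miRNA 5′ end, the
positions flanking the cleavage site — are perfectly Watson–Crick paired
with no insertion between them. Penalty semantics (lower is better,
threshold is a cap) follow the standard plant target-scoring convention.
The window search is exhaustive for reportable sites: an alignment with
more than ⌊threshold / gap⌋ gap columns already exceeds the threshold, so
scanning window widths |miRNA| ± that bound covers every optimum.
Overlapping windows reduce to the minimum-penalty site, ties to the lower
duplex energy. Seed-region weighting, bulge-asymmetry penalties and site
accessibility are intentionally not modelled.

Duplex energies are nearest-neighbour stacking sums over consecutive paired
columns under the shipped table — an estimate for ranking, version-stamped,
and not comparable with energies from other engines. The predicted cleavage
coordinate is the transcript position paired with the canonical 10th miRNA
nucleotide; it is read off the alignment columns, so the miRNA-relative
position is computed, not assumed.

## Synthetic data and what the tests show

`synthetic_config()` describes a synthetic study emulating the statistical
structure of a deeply sequenced, stress-pooled plant library: ~30 conserved
families with log-uniform abundances, 12 of them predominant (1,500–20,000
reads) and the rest minor (20–800); unique background degradation fragments
with the characteristic skew of 32% singletons and 53% doubletons; insert
lengths over 17–32 nt with modes at 24 and 21 nt and a long-species
shoulder at 27 nt; star strands at 5% of their mature; editing planted in
four families at 2–8% (one at exactly 1/13 ≈ 7.692%); −1+UU isoforms in
two families; 20 rule-satisfying hairpin loci and 20 single-rule decoys;
and planted target sites (perfect, one-wobble, shuffled decoy). Counts for
planted isoforms default to rounded expectations rather than binomial
draws, so recovered frequencies are deterministic. Everything is fixed by
one seed, and background fragments are substrings of the transcripts so
they legitimately categorize as mRNA degradation.

Decoys violate exactly one rule each: a clustered 7-nt duplex bulge
(unpaired rule), an A/U-only stem whose best-case stacking sum provably
stays above −25 kcal/mol (energy rule; C-only buffers prevent flanks from
extending the stem), a 300-nt spacer (distance rule), a 24-nt defining read
(mature length), and a read placed in the terminal loop (arm rule). A
distance-below-5 decoy is geometrically impossible, as noted above.

Passing these tests shows that the pipeline's logic is correct on data
matching its assumptions: exact adapter boundaries, substitution-only
variation, uniform random background, no sequencing-error model, no
paralogous precursor families, single-isoform matures. Real libraries
violate all of these to some degree, so recovery rates on synthetic data
are upper bounds, not forecasts.

## Validation suite sizes

The shipped test suite checks the folding DP against exhaustive structure
enumeration on 500 random sequences of 5–20 nt; the target aligner against
closed-form gap-placement enumeration on 200 random miRNA/window pairs; a
complete pipeline run on the default synthetic study (20/20 precursors
recovered, 0/20 decoys, exactly the 12 predominant families above 1,000
reads, every planted modification at its deterministic frequency); and
1,000 randomized property cases for the conservation and partition
invariants. These sizes were chosen so the whole suite completes in a few
minutes on a laptop while leaving the oracle comparisons statistically
meaningful.

## Known limitations

* The folding model is intentionally small; structures and energies differ
  from full Turner-model engines, and the −25 kcal/mol default should be
  recalibrated if the model is swapped out via `fold_params()`.
* Precursor search is transcriptome-based and plus-strand only; genomic
  (intergenic) precursors and antisense arrangements are out of scope.
* Editing detection cannot separate low-frequency editing from sequencing
  error without replicates; treat sub-percent events with caution.
* Target prediction reports complementarity, not repression: cleavage
  validation requires degradome or 5′-RACE style evidence.
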