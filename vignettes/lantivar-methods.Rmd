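---
title: "Methods: characterizing nisin-like lanthipeptide variants with lantivar"
author: "lantivar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing nisin-like lanthipeptide variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`lantivar` is a desk-scale toolkit for the in-silico side of describing a
new nisin variant: reconstructing and naming a mature core peptide
relative to nisin A, predicting its mass under the lanthipeptide
dehydration model, placing it among the known variants with an identity
matrix and a dendrogram, describing its biosynthetic gene-cluster
architecture, scanning the cluster for the promoter boxes, direct
repeats and intrinsic terminators that govern nisin expression, and
screening whole genomes for full or partial cluster content. A seeded
synthetic-data generator produces genomes, operons and regulatory
sequences with truth manifests so that every stage can be validated
end to end.

## Peptide variants, numbering and naming

Lanthipeptide precursors consist of an N-terminal leader and a mature
core peptide; all comparisons here are on mature cores
(`peptide_record`). Variants are expressed as *edit lists* —
substitutions, deletions and insertions — in 1-based coordinates of the
**original reference**, the convention used throughout the nisin
literature (nisin E's `Val32Phe` is numbered on nisin A even though the
residue sits at position 30 of nisin E). `apply_edits()` therefore
resolves all positions on the unedited reference, and `diff_variants()`
emits names in three-letter code (`Ile4Lys`, `ΔSer29`, `insAsn32`) that
`parse_edit_name()` inverts exactly. An insertion with `ref_pos = p`
sits immediately before reference position `p`, so a C-terminal
extension of an `n`-mer is named at position `n + 1`.

Alignments are global (Needleman–Wunsch with Gotoh's affine-gap
recurrences, in C++), scored with BLOSUM62, gap open 10 and gap extend
0.5 per position (a gap run of length `L` costs `10 + 0.5 L`). This
scoring reproduces the published placement of the nisin E deletion
block at nisin A positions 29–30. The traceback is deterministic: ties
prefer substitution columns over reference-consuming gaps over
query-consuming gaps, resolved from the alignment end so that equally
scoring gap runs settle as late as possible in the reference — the
orientation consistent with reference-numbered deletion names.

Percent identity is `100 × identities / compared columns`, counting
only columns with a residue in both rows. This convention reproduces
the published figure for nisin E against nisin A (24/32 = 75.0%)
independently of whether terminal or internal gaps are counted in the
alignment length. For nisin E against nisin U it gives 29/31 = 93.5%;
the value printed alongside the original description (93.6%) is not
reachable under any identities/columns convention on these sequences
and is treated as a rounding artefact; the package reports the
computed value.

The hinge region is defined positionally: the residues aligned to
nisin A positions 20–22 (NMK in nisin A, PIK in nisin E, PLK in
nisin U). `hinge_region()` errors if any hinge position is deleted
rather than guessing.

Dendrograms use the distance `100 − identity`. Neighbour joining is
implemented directly so that its tie-break is documented (the pair
whose lexicographically sorted labels come first is joined; internal
nodes inherit their smallest leaf label) and negative branch lengths —
an artefact NJ produces on non-additive inputs — are clamped to zero.
UPGMA (`upgma_tree()`) is offered as an alternative. On additive
inputs the implementation recovers the generating topology and agrees
topologically with `ape::nj`, which serves as an independent
cross-check in the test suite, never as the implementation.

## Mass model

Peptide masses are residue sums plus one water, with average and
monoisotopic residue masses shipped as a plain-text table
(`extdata/residue_masses.tsv`; water 18.0153 / 18.0106 Da). Headline
numbers use **average** masses, which reproduce the published 3245.9 Da
for the reconstructed nisin E core (monoisotopic gives 3243.5).
Each enzymatic dehydration of a Ser or Thr removes one water;
lanthionine/methyllanthionine ring formation is mass-neutral, so
`modified_mass(seq, n)` is the unmodified mass minus `n × 18.0153` and
`n` can never exceed the Ser+Thr count (nisin E has exactly 8).
`infer_dehydrations()` inverts this: it picks the count whose
prediction is nearest the observed mass, requires the residual to be
within a tolerance (default 1.5 Da, a linear-MALDI-scale figure; the
observed 3100.8 Da sits 0.95 Da from the 8-dehydration prediction),
and errors when nothing fits or two counts tie exactly. Adducts,
isotope envelopes and spectrum parsing are out of scope; observed
masses enter as numbers.

## Gene-cluster architecture

Clusters are ordered lists of genes labelled with the canonical role
alphabet `A B T C I P R K F E G`. `layout_string()` concatenates roles
in genomic order; the rearranged nisin E operon reads `PRKAFEGBTCI`
against nisin A's `ABTCIPRKFEG`. `compare_layouts()` reduces each
layout to its set of unordered adjacent role pairs; shared adjacencies
measure conserved synteny and *breakpoints* count adjacencies of the
first layout missing from the second. The comparison is deliberately
orientation-insensitive (a layout equals its reversal), because
cluster drawings are compared as drawn, without strand claims.

Classification is a pure function of the present role set:
`full_production` requires all eleven roles; `immunity_sensing_subset`
requires **exactly** `{R,K,F,E,G}` — the regulator/kinase plus
ABC-transporter immunity genes with no production machinery, the
configuration repeatedly observed without adjacent structural genes;
any other non-empty set is `partial` (including a hypothetical I+P
co-retention, which is not given its own category); the empty set is
`none`.

## Regulatory elements

Promoter models are pairs of hexamer boxes at a fixed spacer. The
packaged models are the streptococcal regulator promoter
(`TGCACA`/`TATTAC`, spacer 15), the core-peptide promoter
(`CTGAAC`/`TACAAT`, spacer 20), and the transport/immunity promoter
(`TGAACA`/`TATACT`, spacer 19). The peptidase-gene promoter boxes
(`CTGAAC`/`TAAAAT`) are packaged without a default spacer — no spacer
length is established for it — so `nisin_promoter_models()` includes
the P-type model only when the caller supplies one explicitly (the
generator and tests use 20, matching the closely related core-peptide
promoter). The lactococcal-type regulator promoter has no established
boxes here and can be built with `promoter_model()` when the user has
them. Scanning is Hamming matching per box (budget default 1 mismatch
per box, spacer slack default 1 nt, both settings reflecting the
near-exact boxes seen in cluster alignments); `N` never matches; both
strands are scanned; output coordinates are 1-based inclusive on the
forward strand (internal scanning is 0-based half-open).

The `TCT-N8-TCT` direct repeat conserved in NisRK-regulated promoters
is matched exactly with `find_direct_repeats()` (all overlapping
occurrences reported).

Intrinsic (Rho-independent) terminators are modelled as a stem–loop
followed by a U-tract. `hairpin_delta_g()` sums nearest-neighbour
stacking free energies over consecutive Watson–Crick stem pairs plus a
hairpin loop-initiation penalty, both read from plain-text parameter
tables shipped with the package (Turner-style Watson–Crick RNA stack
energies written in DNA letters; loop penalties for lengths 3–10 with
a logarithmic extrapolation beyond). Wobble G:U pairs are optionally
allowed with a single flat stack energy — a stated simplification, as
context-dependent wobble parameters add little at this scale.
`find_terminators()` enumerates, for every loop length 3–10 and every
innermost pair, the maximal outward stem extension; keeps stems of at
least 4 pairs whose energy is strictly below −5.0 kcal/mol ("stronger
than −5.0" is read as `ΔG < −5.0`, so boundary values are excluded)
and that are followed by at least 3 T within 8 nt downstream (the
U-tract criterion used by common predictors is unpublished, so this is
a stated, configurable default); resolves overlapping candidates to
the locally strongest; and classes hits stronger than −10.0 kcal/mol
as `strong`. This scanner is a documented re-implementation of the
terminator-prediction idea, not a reproduction of any specific
external tool's parameterisation, so published per-cluster terminator
counts obtained with such tools are qualitative guidance for it, not
targets. On sequences up to a few hundred nucleotides the scanner is
verified against a brute-force enumerator that tests every
(position, stem, loop) window.

## Pangenome screen

`find_orfs()` calls bacterial ORFs on both strands: start codons
`ATG/GTG/TTG` translated as Met (translation table 11), stops
`TAA/TAG/TGA`, one ORF per stop per frame (the first start after the
previous stop, i.e. the longest open frame), a stop codon required,
and ambiguous codons acting as frame breakers. `assign_homologs()`
aligns each candidate ORF protein globally to each reference role
protein and reports the best hit per role when it reaches the identity
threshold (default 90%, the published homolog criterion for the
immunity/sensing subset, adopted for all roles since no per-role
cut-offs are published). A length-ratio prefilter (0.6–1.67) skips
alignments that could not reach 90% identity; ties where one ORF best
serves two roles are flagged. `classify_genome()` composes
ORF calling, homolog assignment and role-set classification; it is
invariant to contig order and to the operon's position and strand.
Homology detection is deliberately ORF-plus-global-alignment rather
than a local-alignment seed-and-extend engine: it is fully
self-contained and adequate at desk scale, and equivalence with
BLAST-based screens of real genome databases is not claimed —
real-database screening is supported through the same interface but is
external, version-dependent, and not part of the validation suite.

The reference proteins (`nisin_cluster_references()`) are synthetic
stand-ins: role A is a synthetic leader fused to the reconstructed
nisin E core, and the other ten roles are fixed-seed random proteins
of rank-realistic, scaled-down lengths (110–320 residues). The true
nse gene products are not published as sequences, so screens against
this reference set exercise the machinery on planted truth; they say
nothing about real genomes.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of their parameters and an integer
seed (R's default Mersenne-Twister via `set.seed`, with the caller's
RNG state restored afterwards); retry loops derive attempt sub-seeds
as `seed + attempt × 10007`.

* `mutate_peptide()` plants a chosen number of non-overlapping
  substitutions and deletions and returns the true edit list — the
  round-trip oracle for `diff_variants()`.
* `make_regulatory_sequence()` builds a 200 nt (configurable) i.i.d.
  uniform background and plants one promoter site (exact boxes, exact
  spacer), one TCT-N8-TCT repeat and one designed hairpin cassette
  whose energy falls in a requested window: `strong` (below −10),
  `candidate` (−10 to −5) or `sub` (just above −5, hence designed to
  be *excluded*). The finished sequence is rejection-sampled until
  re-scanning recovers exactly the manifest — a clean-background
  guarantee that makes "100% recovery, zero false positives" a
  statement about scanner specificity on planted truth, not about
  random-sequence base rates.
* `make_cluster_sequence()` back-translates the reference proteins of
  a layout (flat synonymous-codon choice — downstream analysis is
  protein-level, so codon-usage realism is not modelled), separates
  them with random intergenic gaps, and plants regulatory features in
  named gaps. Coding sequence is *not* scrubbed: long ORFs legitimately
  contain chance motif matches, as real operons do, and only exact
  recovery of the planted features is guaranteed.
* `make_pangenome()` emulates a presence/absence screen at the
  published scale (default 44 genomes: 6 full operons, 20
  immunity/sensing subsets, the rest decoys-only), with coding genes
  mutated at the amino-acid level (default 2%, initiator Met kept so
  the start codon survives). Contigs are short (one operon plus
  flanks and two decoy genes, ~10–15 kb) — deliberate scaled-down
  problem sizes; there is no assembly gap, GC-content structure,
  transposase or SNP-level strain realism. Passing tests on this
  material demonstrates correct truth recovery of the screening
  machinery, not performance on real assemblies.

## Numerical and design choices

* Floats in reports are printed at one decimal (the precision the
  quantities are conventionally printed with); internal computation is
  double precision throughout.
* `infer_dehydrations` declares ambiguity only on exact residual ties;
  with water ≈ 18 Da, any tolerance below 9 Da makes ties impossible.
* Degenerate inputs fail loudly: empty sequences, unknown residues,
  edit/reference mismatches, non-symmetric matrices, fewer than three
  taxa for NJ, stems shorter than two pairs, and loops shorter than
  three nucleotides are all errors, not warnings.
* Validation problem sizes: alignment optimality is checked against
  exhaustive path enumeration for peptide pairs up to length 8 (500
  seeded trials); ORF calling against a six-frame brute force on 2 kb
  contigs; terminator scanning against the window enumerator on 200 nt
  sequences; the pangenome screen on the 44-genome fixture at 2%
  mutation. These sizes were chosen as the smallest that exercise
  every code path, including overlap resolution and both strands.

## Known limitations

* The scoring scheme fixes one optimal alignment; biologically
  equivalent tie alignments (and hence edit-list namings) other than
  the documented one are not enumerated.
* The hairpin model ignores bulges, internal loops, dangling ends and
  competing secondary structure; energies are only as good as the
  shipped nearest-neighbour tables.
* Promoter scanning is consensus matching, not a trained PWM; it will
  not find promoters that deviate by more than the mismatch budget.
* The leader/core split is supplied per record, never predicted.
* Real-genome screening inherits every caveat of the synthetic
  reference set described above.
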