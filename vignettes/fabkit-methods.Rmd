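---
title: "Methods: V+C antibody annotation, geometry and search in fabkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: V+C antibody annotation, geometry and search in fabkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabkit)
```

fabkit builds and queries collections of antibody structures that carry
both the variable (V) and constant (C) regions of their chains. Most
antibody informatics tooling stops at the V region; the constant region —
which fixes the isotype and with it the effector functions of the
antibody — is equally amenable to position-level analysis once it is
numbered in a consistent scheme. This vignette documents the models,
conventions and numerical choices behind each step, and what the
synthetic fixtures do and do not establish about behaviour on real data.

## Domain detection and IMGT-style numbering

A chain is decomposed into germline domains by iterated local alignment
against a reference set of IMGT-gapped alleles (`detect_domains()`). The
scoring family mirrors protein BLAST: BLOSUM62 with affine gap costs of
11 to open and 1 per gap position, so a gap of length $L$ costs $11+L$.
The decomposition is greedy: the best-scoring local hit is accepted,
its query span is masked, and the search repeats on the remaining
segments until no hit passes the thresholds. Ties are broken by higher
percent identity, then lexicographic allele id, making results
deterministic. Defaults of `min_identity = 50` (percent) and
`min_length = 50` (residues) separate genuine germline hits from noise
in fixture simulations; both are exposed in `pipeline_config()`.
Percent identity is `100 * identities / alignment length`, counting gap
columns in the length.

Numbering (`number_domain()`) is alignment transfer: the query span is
globally aligned to the hit allele's ungapped sequence, and every query
residue inherits the *gapped column index* of its aligned reference
residue. Because all alleles of one alignment set share a gapped width,
that column index is a position label comparable across chains and
entries — the property IMGT numbering provides, extended uniformly to C
domains. Insertions (query residues aligned to a reference gap) get the
preceding numeric label with lowercase suffixes `a, b, c, ...` in query
order; deletions simply leave holes, keeping the residue/label relation
bijective. Two caveats are deliberate: the hinge is representable as a
reference domain but never numbered (the IMGT C-domain scheme does not
cover it), and the symmetric center-out insertion conventions used by
canonical IMGT numbering inside long CDR loops are *not* reproduced —
alignment transfer is applied uniformly, so labels inside long
insertions may differ from canonical IMGT output.

## Chain- and structure-level annotation

Species are decided per domain and then consolidated. The deposition
metadata species is kept unless the best reference hit comes from
another species *and* beats the best same-species hit by strictly more
than `override_margin` percentage points of identity (default 8). When
the provided species has no reference hit at all, the best hit wins
unconditionally — the margin has nothing to compare against; this
fallback is a documented choice. The margin is read as an absolute
percentage-point difference, per domain.

Engineered formats follow from the per-domain species pattern: all
domains from one species is unflagged; V and C from different species is
chimeric; same species throughout but with the top two V hits split
between species within 2 identity points is reported as humanized —
a heuristic, always carrying a confidence note, never silently asserted.

Isotype (or light-chain type) is the gene prefix of the single
constant-region hit with the highest percent identity (ties: alignment
score, then allele id). Both the allele id and its gene prefix are
reported, since collapsing allele-level calls (`*01` vs `*02`) to gene
level loses information some users need.

Structural coverage is decided on the ATOM-resolved sequence, not the
deposited one: a structure with coordinates for any of CH2/CH3/CH4 is a
full antibody, otherwise V plus CH1/CL is a Fab, otherwise "other".
Consequently an unresolved span that wipes out every CH2-and-beyond
coordinate demotes a full-length construct to Fab, which is the correct
reading of what the crystal actually shows.

## Geometry

All geometry runs on labeled C-alpha sets. The Fab packing angles are
defined through pseudo-twofold (dyad) axes: superposing VL onto VH (and
CL onto CH1) over shared non-insertion labels by least squares (Kabsch)
yields a rotation close to a twofold; its axis is the module's
pseudo-dyad. The CH1–CL packing angle is the rotation angle of the
CL-onto-CH1 superposition, in (0, 180]. The elbow angle is the angle
between the two dyad axes. A twofold axis has no intrinsic sign — at a
rotation of exactly 180 degrees the eigenvector's direction is
arbitrary — so the two axes are compared as undirected lines:
`elbow_angle()` reports `acos(|a . b|)` in [0, 90] degrees by default,
with `convention = "obtuse"` giving the supplement for comparison with
literature elbow ranges (often quoted in (90, 225)). This is a
deliberate deviation from conventions that report a signed fold into
[0, 180]: with unsigned axes those conventions are not well defined, and
the acute-line angle is the quantity the fixtures can plant and recover
exactly. Degenerate cases are explicit: identity rotations (angle below
~6e-5 degrees) are reported as degenerate rather than given an arbitrary
axis, and collinear point sets are refused.

Contact matrices are all-against-all C-alpha distances between two
labeled domains with a boolean map under a cutoff of 8.0 Å — the common
contact-map convention; the source analyses specify C-alpha distances
but no cutoff, so it is exposed. Unresolved labels yield missing
entries, never zeros. Squared distances below 1e-10 are clamped to zero
to absorb floating-point cancellation for (near-)identical points.

Solvent accessibility is Shrake–Rupley with a deterministic Fibonacci
sphere lattice (default 960 points; the lattice depends only on the
count, so results are reproducible across platforms) and van der Waals
radii C 1.70, N 1.55, O 1.52, S 1.80 Å, probe 1.4 Å. Points exactly on
a neighbour's expanded sphere are resolved by a deterministic tie-break
(the lower-indexed atom keeps the shared surface), which gives the
physically sensible coincident-atom limit. The H–L interface is the
per-residue SASA lost on complex formation; residues burying more than
1.0 Å² are interface members (the threshold is exposed — the upstream
tool's exact value is not restated in its description), and the buried
area is the summed loss over both chains divided by two. Disulfides are
cysteine pairs with Sγ–Sγ distance at most 2.5 Å.

Inside `run_pipeline()` the interface SASA uses a coarser 240-point
lattice by default: at the 1 Å² membership threshold the per-residue
classification is insensitive to the lattice density, and batch
annotation stays fast. `sasa()` itself keeps the 960-point default.

## Search

The index stores four sequence views per H–L pair (heavy/light × V/V+C)
reconstructed from the numbering tables. Sequence search aligns each
present query chain locally against the matching view of every entry;
for paired queries the combined identity is the unweighted mean of the
chain identities (no combination rule is prescribed upstream; the
weights are an argument). Repertoire input is accepted as FASTA, AIRR
TSV, the same table as CSV, or 10x-style contig CSV, paired by cell
identifier where the dialect has one; more than 200 records per batch is
an error unless overridden, mirroring the interactive service's limit.
Nucleotide-only repertoires are rejected rather than silently
translated.

Interface similarity between two CH1–CL contact matrices is the Jaccard
index of their contact sets restricted to shared label pairs (both-empty
counts as identical, i.e. 1); a distance-correlation alternative sits
behind `method = "correlation"`. All CH1×CL label pairs participate —
the upstream definition of which pairs constitute "the interface" is not
public, so no sub-selection is imposed.

## Mutational-scan post-processing

Raw per-position × 20 score tables from external scorers are pivoted
into matrices with explicit missing values (never zero-filled). WT
scaling subtracts the wild-type residue's score per position, making WT
cells exactly 0. Multi-mutant scores are sums of scaled single-mutation
scores under an independence assumption that is echoed in the output
metadata; matrices tagged as Rosetta point scans are refused for
summation (their scores are not additive across positions) unless
forced.

The isotype-sensitivity statistic compares, per shared V-region
position, the same V region in two constant-region contexts against a
same-isotype replicate control. With substitution-level differences
$d_{iso}(m) = s_a(m) - s_b(m)$ and $d_{ctrl}(m) = s_{ctrl}(m) - s_b(m)$,
the default effect is

$$\mathrm{effect}(p) = \operatorname{sign}(\overline{d_{iso}})\;
\log_2\!\frac{\overline{|d_{iso}|}+\varepsilon}{\overline{|d_{ctrl}|}+\varepsilon},
\qquad \varepsilon = 10^{-6}.$$

Only the sign semantics of this "fold difference" are fixed upstream
(negative = first isotype favourable, for lower-is-better scores); the
aggregate is a design choice and is pluggable. Mean *absolute*
differences were chosen as the magnitude because the ratio of absolute
*means* of ~19 near-zero-mean noise differences is heavy-tailed
(Cauchy-like): a null position with an accidentally tiny control mean
would dominate any ranking. The absolute-means variant remains available
as `method = "mean_ratio"`. The sign is taken from the isotype contrast
alone so that swapping the two isotypes negates it exactly; the
magnitude is *not* swap-invariant, because the control is a b-versus-b
comparison and has no a-versus-a counterpart.

Significance is a two-sided Wilcoxon signed-rank test of $d_{iso}$
versus $d_{ctrl}$ paired over the ≤19 substitutions (no normality
assumption at that sample size), with Benjamini–Hochberg adjustment
across positions. Positions with fewer than 2 complete substitution
triples are skipped with a note.

## What the synthetic fixtures emulate — and what they do not

The generators exist so that every contract is testable offline with
known ground truth:

* **References** are random ancestor sequences diversified at a chosen
  substitution rate (default 0.15 between species, 0.25 between genes
  within a species), with gaps at fixed columns. They reproduce the
  *structure* of an IMGT-gapped release (alignment sets of constant
  width, species homologs, multiple isotypes), not real allele
  sequences or nomenclature.
* **Structures** are C-alpha traces (plus planted Sγ atoms) whose light
  domains are exact rigid images of their heavy partners under planted
  rotations, so packing angles have closed-form ground truth. They are
  not physically realistic folds; side-chain packing, real insertion
  patterns and author-numbering quirks of deposited files are absent.
  Coordinates are written with 3 decimals for byte-determinism, so
  recovery through files is exact only to ~1e-3 Å (~1e-3 degrees);
  machine-precision recovery is asserted on in-memory geometry.
* **Repertoires** are mutated copies of indexed V sequences (default 5%
  per-residue substitution) with a known pairing table.
* **Score fixtures** draw one shared landscape observed through three
  noisy scans (σ = 0.5), with per-position shifts of 2.0 planted in one
  pseudo-isotype — a size chosen to sit clearly above the noise yet far
  from trivial.

Passing tests on these fixtures establish the correctness of the
algorithms and conventions, *not* that real depositions parse cleanly
(legacy PDB files with author-specific numbering are explicitly assumed
to use polymer indices), nor that the detection thresholds are optimal
for distant homologs, nor that the heuristic humanization call matches
curated annotations.

Problem sizes in the shipped tests and acceptance script — reference
sets of ~22 alleles, 3–4 structures of ~190 residues per chain, 20-entry
search indexes, 50–200 score positions — were chosen as the smallest
sizes at which every property under test is non-trivial.

## Known limitations

* Alignment transfer can mislabel residues inside long CDR insertions
  relative to canonical center-out IMGT numbering.
* The elbow angle convention (acute angle between undirected dyad axes)
  differs from literature conventions by a deterministic mapping; use
  `convention = "obtuse"` when comparing against published ranges, and
  expect a constant offset against tools that define the axes from
  specific residue subsets.
* The pipeline pairs heavy and light chains by C-alpha contact count
  only when several candidates exist; co-crystals with many copies may
  need explicit pairing.
* `isotype_sensitivity()`'s effect magnitude depends on the chosen
  aggregate; ranking by |effect| is stable across the two provided
  methods in the planted-signal regime, but absolute values are not
  comparable between methods.
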