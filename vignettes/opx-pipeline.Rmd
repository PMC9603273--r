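---
title: "Classifying OPX proteins and measuring the periplasm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying OPX proteins and measuring the periplasm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opxtools)
```

## The biological problem

Gram-negative bacteria secrete high-molecular-weight polysaccharides
(capsules, exopolysaccharides, biosurfactants) across their cell envelope.
In Wzx/Wzy- and ABC-transporter-dependent pathways the last envelope-spanning
component is an outer-membrane polysaccharide export (OPX) protein of the
Wza family. Canonical Wza from *E. coli* caps the periplasmic machinery with
an OM-spanning amphipathic α-helix (the Wza_C domain), but many OPX
homologues — including WzaX/S/B of *Myxococcus xanthus* — are "truncated":
they keep the conserved periplasmic Poly_export (PF02563) and SLBB (PF10531)
domains but lack any OM-spanning element, raising the question of how their
polymers cross the outer membrane. Comparative genomics answers it in part:
truncated OPX genes are frequently encoded next to integral-OM β-barrel
porins (e.g. MXAN_7418/3226/1916 beside *wzaX/S/B*), suggesting an
OPX + β-barrel two-component architecture.

This package implements the full computational side of that analysis as
reusable, tested stages:

1. **Evidence parsing** (`read_domtbl()`, `read_fold_regions()`): HMMER3
   per-domain tables and pre-parsed fold-recognition homology regions.
2. **Architecture assembly** (`resolve_architecture()`): ordered,
   non-overlapping per-protein domain layouts.
3. **OPX classification** (`classify_opx()`): the three structural classes.
4. **Synteny scanning** (`pair_opx_barrels()`): β-barrel homologues within
   ±10 genes of each OPX gene.
5. **Phylogenetic marker extraction** (`extract_marker_sequences()`):
   Poly_export domains plus tree-annotation rings.
6. **Envelope geometry** (`distance_profile()`, `correlate_thickness()`):
   periplasm thickness from membrane traces and its correlation with OPX
   length.

A synthetic-data module generates every input with planted ground truth, so
the complete pipeline is testable without external databases or tomograms.

## Classification rules

Classification merges two evidence levels: sequence-level Pfam domain hits
(Poly_export, SLBB, Wza_C, GfcC) and fold-level homology regions against two
structural templates — Wza (PDB 2J58) and the stand-alone GfcC protein (PDB
3P42).

* **Membership gate.** Every OPX class begins with a Poly_export domain, so
  a protein is only considered OPX with Poly_export evidence: a domain hit,
  or a 2J58 region overlapping the template's Poly_export span. Stand-alone
  GfcC homologues and SLBB-only proteins return `NOT_OPX`.
* **Wza_C segment.** The OM-spanning helix corresponds to template residues
  326–359 of 2J58 (34 aa). A protein carries a true Wza_C segment when its
  2J58 regions cover at least 10 of those 34 template positions; we count
  template positions covered by the union of regions, so split alignments
  are not double-counted. The same segment found as a PF18412 domain hit is
  accepted as equivalent sequence-level evidence.
* **GfcC evidence.** A PF06251 domain hit, or a 3P42 region covering at
  least 30 query residues (the fold search frequently recovers GfcC modules
  that sequence search misses; the 30-aa floor suppresses spurious
  micro-regions).
* **Decision.** No GfcC evidence: Wza_C segment ⇒ Class 1 (Wza-like),
  otherwise Class 3 (truncated, Poly_export–SLBB only). With GfcC evidence
  the protein is Class 2, subdivided by whether the GfcC evidence precedes
  the Poly_export domain (compared by query-coordinate midpoints) and by
  Wza_C presence: 2A (after, no Wza_C), 2B (after, Wza_C — KpsD-like),
  2C (before, no Wza_C), 2D (before, Wza_C).

The decision depends only on Poly_export/GfcC/Wza_C evidence, so the SLBB
repeat count (1–14 in real architectures) never changes a class — a
property the test suite asserts directly.

The per-domain E-value cutoff is 1 × 10⁻⁵ and is applied to the HMMER
*i-Evalue* (per-domain independent E-value) rather than the full-sequence
E-value; parsers retain but flag rows above the cutoff so filtering remains
an explicit, auditable step.

**Overlap resolution.** Profile searches report overlapping hits; the
original analysis does not state a resolution rule, so we adopt standard
domain-calling practice: two hits conflict when their overlap exceeds 50%
of the shorter hit's span; the higher bit score wins, ties broken by lower
E-value, then lower start coordinate. Resolution is greedy in that priority
order, which makes it deterministic, idempotent and insensitive to input
row order.

**Summary statistics** use the lower median for even counts (the choice is
documented because the upstream analysis is silent) and report class
proportions over OPX hits only (`NOT_OPX` is excluded from the
denominator).

## Synteny scanning

For each classified OPX gene, all genes within ±10 positions on the same
replicon are scanned (strand is recorded but ignored; neighborhoods never
cross replicon boundaries). Each neighbor's protein is aligned locally
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1, via Biostrings) against
nine β-barrel query templates: MXAN_7418/3226/1916, the β-barrel modules of
PgaA (aa 511–807), GfcD (425–698), YjbH (423–698) and BcsC (785–1157),
AlgE (33–490), and Wzi without its plug domain (92–479).

Significance uses Karlin–Altschul statistics with the standard gapped
BLOSUM62 constants (λ = 0.267, K = 0.041) and per-pair search space m·n —
reproducible without an external search engine. A match is typed by query
coverage: ≥ 80% of the full-length query ⇒ `full_length`; otherwise ≥ 50%
of the porin module ⇒ `module_only`. The thresholds are package defaults
(the original description states only the intent of distinguishing lone
porin modules from multidomain homologues) and are configurable. Note that
for queries that are nearly all porin module (the MXAN templates, Wzi_bb at
81%), a module-only homologue still covers > 80% of the full-length
sequence and is therefore typed `full_length`; the distinction is only
meaningful for queries with substantial non-barrel regions, matching how
the published table reports separate module rows only for those queries.

The packaged query FASTA contains deterministic *synthetic stand-ins* (the
real sequences are not redistributable with the package) with the published
module coordinates; all synteny logic is sequence-agnostic, so supplying a
real query FASTA reproduces the analysis on real genomes.

## Phylogenetic marker

The Poly_export domain is present in all three classes and is used as the
phylogenetic marker. Extraction takes the N-terminal-most Poly_export span
per protein — all class definitions place Poly_export first, and
concatenating rare second copies would misalign the marker. Multiple
sequence alignment and maximum-likelihood inference are deliberately
external (`infer_marker_tree()` shells out to an aligner and FastTree when
present); the package ships an 8-sequence synthetic marker fixture with a
pre-computed newick so tests never invoke external tools. Annotation rings
carry class, phylum, nearby-β-barrel presence (true iff the protein anchors
at least one synteny hit) and protein length.

## Envelope geometry

Membrane traces are ordered polylines of model points in the plane of a
tomographic slice (image handling — slice selection, voxel averaging,
segmentation — belongs to upstream tools and is out of scope). The distance
profile resamples the source trace (by convention the OM) every 0.1 nm of
arc length and measures, at each sample, the minimum Euclidean distance to
the target polyline using point-to-segment projection. Point-to-segment is
strictly more accurate than nearest-model-point; a `mode = "point"` option
is retained for comparison with coarser scripts. Distances are reported in
Å (traces in nm), matching how envelope measurements are conventionally
quoted. Measurement is one-directional (OM → IM) by default; for parallel
membranes the two directions agree exactly, which the tests assert.

Correctness is anchored by a brute-force oracle: the target polyline is
densely sampled (5 × 10⁻⁴ nm) *with its vertices retained* — near a vertex
the nearest-point error of pure dense sampling is first-order in the step,
so keeping vertices is what makes the 10⁻⁶ Å agreement tolerance
attainable — and the minimum point-to-point distance is compared against
the implementation on randomized fixtures.

Per-species summaries average per-tomogram profile means (three tomograms
per species in the study design) and report SEM = sd/√n over tomogram
means; a single-tomogram species gets SEM 0 and a flag. Correlation of
thickness against OPX protein length reports Pearson's r and Spearman's ρ
(average ranks for ties). The hydrophobic thickness of the OM is estimated
as 40% of its total solvated thickness (a molecular-dynamics-derived rule
for asymmetric OM bilayers): 69.8 Å × 0.40 = 27.92 ≈ 28 Å.

## The synthetic-data generator

The generator's defaults encode the study conditions rather than free
dials:

* **Domain tables.** Planted E-values are drawn log-uniform in
  [10⁻⁵⁰, 10⁻⁶] (all below the 10⁻⁵ cutoff); decoy hits with E-values in
  [10⁻⁴, 10⁻²] are added at a 10% per-protein rate to exercise filtering.
  Domains are laid head-to-tail with 10-aa linkers (Poly_export 91 aa, SLBB
  50 aa, GfcC 151 aa, Wza_C 35 aa); a spec whose protein length cannot fit
  its planted architecture is rejected as contradictory.
* **Genomes.** Planted barrel genes carry the query template sequence
  (full-length or module subsequence per planted match type); filler genes
  carry uniform-random sequences *verified at generation time* to fall
  below the match threshold, so planted truth has no false positives by
  construction and synteny precision/recall on synthetic genomes is
  exactly 1.
* **Membrane traces.** Two dimensional, in the slice plane, emulating the
  per-slice measurement procedure. The backbone (optionally a gentle
  sinusoid; the offset is validated against the backbone's radius of
  curvature) defines the geometry; the IM is its exact normal offset at the
  true gap; tracing noise is applied to the *source* (OM) model points
  along the local normal, default spacing 1 nm. Measuring from the noisy
  trace to the smooth one makes each sampled distance equal to gap + noise
  with no nearest-point bias, so the profile mean recovers the planted gap
  within ~3·σ/√n over the n model points (~101 over the typical 100-nm
  stretch). Study-scale defaults mirror the real measurements: ~100 nm
  traces, gap 327 Å, three tomograms per species.
* **Correlated pairs.** Bivariate normal with the planted Pearson r;
  thickness centered at 327 ± 28.4 Å, lengths at 450 ± 120 aa. Lengths are
  rounded to whole residues except at |r| = 1, where rounding would break
  the exact linear relation. Recovery is within ~2/√n.

What the generator does *not* emulate: real HMM emission scores, realistic
protein folds or residue composition, operonic structure beyond gene order,
or membrane-segmentation artifacts. Passing tests therefore demonstrate the
correctness of the decision rules, bookkeeping and geometry — not the
sensitivity of profile search or fold recognition on real sequences.

## Problem sizes and numerical choices

The test suite and the acceptance script run planted studies at
1,000 proteins (classification recovery), 30–70-gene replicons (synteny),
100 randomized trace fixtures plus 100-nm trace pairs (geometry), and
n = 92 / 1,000 correlation samples — sizes chosen so each stage's
statistical bound is meaningfully exercised while the whole suite runs in
a few minutes on a laptop. All randomness flows through explicit seeds; a
given seed yields byte-identical outputs (the generators save and restore
the caller's RNG state).

Degenerate inputs are handled explicitly: empty spec lists produce empty
tables; an all-`NOT_OPX` summary reports zero proportions without division
errors; single-point traces, zero-length traces, negative noise and
out-of-range thresholds are rejected with messages; constant columns are a
correlation error rather than NaN.

## Known limitations

* The published database-scale counts (tens of thousands of OPX hits
  across NR/REP/MYXO snapshots) are not reproducible here: the snapshots
  are not redistributable, so validation is property-based on planted
  truth plus the small printed worked values.
* The synteny scan is limited to ±10 genes and to the nine query
  templates, mirroring the original design; barrels encoded farther away
  (large cluster insertions are documented in myxobacteria) or from
  unknown families are invisible to it.
* E-values for pairwise matches use fixed Karlin–Altschul constants, not
  query-specific fitted parameters; they are calibrated for thresholding,
  not for cross-database comparability.
* Membrane thickness (as opposed to intermembrane distance) is supported
  only as the distance between two leaflet traces of the same membrane.
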