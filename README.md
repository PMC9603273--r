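# opxtools

Tools for studying bacterial **outer-membrane polysaccharide export (OPX)
proteins** — the Wza-family components that cap Wzx/Wzy- and
ABC-transporter-dependent polysaccharide secretion systems — and their
relationship to the cell envelope.

Many OPX homologues (e.g. WzaX/S/B of *Myxococcus xanthus*) lack the
OM-spanning Wza_C α-helix of canonical *E. coli* Wza, yet their pathways
still secrete polymer across the outer membrane; such "truncated" OPX genes
are often encoded beside integral-OM β-barrel porins. This package
implements the computational pipeline behind that analysis:

* **Domain-evidence I/O** — parse HMMER3 per-domain tables (`hmmscan
  --domtblout` dialect) and fold-recognition homology regions; assemble
  ordered, non-overlapping per-protein domain architectures.
* **OPX classification** — assign each protein to one of three structural
  classes from merged sequence- and fold-level evidence:
  * **Class 1** (Wza-like): Poly_export–SLBB(1–14)–Wza_C;
  * **Class 2A–D** (KpsD/GfcC-like): architectures containing a GfcC
    domain, subdivided by Wza_C presence and whether GfcC precedes
    Poly_export;
  * **Class 3** (truncated): Poly_export–SLBB only.
  The Wza_C decision uses the 2J58 template segment aa 326–359: coverage of
  ≥ 10/34 template positions counts as a true Wza_C segment.
* **Synteny scanning** — find β-barrel porin homologues within ±10 genes of
  each OPX gene by local alignment against nine query templates
  (MXAN_7418/3226/1916, PgaA, GfcD, YjbH, BcsC barrel modules, AlgE, Wzi),
  typed as full-length vs module-only matches, and cross-tabulated by query
  and OPX class.
* **Phylogenetic marker extraction** — extract the conserved Poly_export
  domain per protein as the marker, with tree-annotation rings (class,
  phylum, nearby β-barrel, length) joinable onto any newick tree.
* **Envelope geometry** — measure periplasm thickness between IM/OM
  polyline traces from tomographic slices: the source trace is resampled
  every 0.1 nm of arc length and point-to-segment distances to the target
  are reported in Å; per-species summaries (3 tomograms each, mean ± SEM)
  and thickness-vs-OPX-length correlations (Pearson / Spearman).
* **Synthetic data** — generators for every input with planted ground
  truth (classes, adjacencies, gaps, correlations), so the whole pipeline
  is testable end-to-end without external databases or tomograms.

## Worked example

Generate a planted 200-protein proteome at reference-database-like class
proportions, classify it, and summarize:

```r
library(opxtools)

specs <- random_protein_specs(200,
  c(CLASS1 = 0.381, CLASS2A = 0.026, CLASS2B = 0.109, CLASS3 = 0.484),
  seed = 42)
tabs <- gen_domain_tables(specs, seed = 42)
cl <- classify_proteins(tabs$domain_hits, tabs$fold_regions, tabs$proteins)
summarize_classes(cl)
#> OPX classification summary: 200 OPX proteins of 200 classified
#>    class count proportion median_length_aa spii_fraction
#>   CLASS1    84      42.0%              365     0.6785714
#>  CLASS2A     3       1.5%              541     1.0000000
#>  CLASS2B    24      12.0%              466     0.7083333
#>  CLASS2C     0       0.0%               NA            NA
#>  CLASS2D     0       0.0%               NA            NA
#>   CLASS3    89      44.5%              380     0.6741573
```

Every planted class is recovered (compare `cl$class` against the specs);
proportions are over OPX hits and sum to 1; median lengths use the lower
median; `spii_fraction` is the lipoprotein (SPII signal) share per class.

Measure a synthetic membrane pair with a planted 327 Å gap, 10 Å tracing
noise and gentle curvature, then correlate thickness with OPX length on a
92-pair sample planted at r = 0.145:

```r
tp <- gen_membrane_pair(true_gap = 327, trace_length_nm = 100,
                        noise_sd = 10, curvature_amplitude = 20, seed = 7)
distance_profile(tp$om, tp$im)
#> periplasm_profile: synthetic_tomo, 1464 samples, mean 328.8 A (SEM 0.22)

correlate_thickness(gen_correlated_pairs(0.145, 92, seed = 7))
#> thickness-length correlation (all): Pearson 0.0642, Spearman 0.0747, n = 92

hydrophobic_thickness(69.8)   # 40% rule: 27.92, reported ~28 A
```

The recovered mean (328.8 Å) sits within the sampling bound
3·σ/√n ≈ 3 Å of the planted gap; at n = 92 the correlation estimate is
within its ~1/√n sampling noise of the planted value — the
same reason a weak correlation at that sample size is statistically
indistinguishable from none.

`run_all(opx_config(seed = 3))` runs every stage on a seeded synthetic
study and writes classification, synteny, marker, envelope and correlation
artifacts plus an md5 manifest; reruns with the same seed are
byte-identical.

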