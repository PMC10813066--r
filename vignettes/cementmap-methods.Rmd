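---
title: "Characterizing hypercementosis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing hypercementosis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cementmap)
```

# The problem

Cementum is the mineralized tissue covering the tooth root; it is
deposited throughout life and anchors the periodontal ligament. Under
mechanical overload, infection, impaction or loss of function its
apposition can exceed the physiological range — hypercementosis — and
the *pattern* of that excess (how thick, where on the root, and with
what surface texture) carries information about the tooth's history.
`cementmap` implements a complete quantitative characterization of such
patterns on single-rooted teeth and the classification of teeth into
five etiological groups: impacted (IMP), infected (INF), hypofunctional
(HYPO), hyperfunctional (HYPER) and mixed condition (MIX).

The package has four measurement layers and two statistical layers:

1. a per-vertex cementum **thickness map** on 3D surface meshes
   (micro-CT derived dentine core and cementum envelope), summarized as
   MAX THI (maximum thickness, µm), LOC MAX / LOC MIN (localization by
   root third and side), PREF (preferential apposition flag) and an
   atypical-shape category;
2. a confocal-style **surface topography** workflow (non-measured point
   filling, leveling, degree-2 form removal) summarized as MAX VE
   (maximum vertical elevation, µm) and a three-part surface-aspect
   score;
3. the **visual scoring systems** of dental anthropology (Molnar
   occlusal wear, Si/Sta caries, pulp exposure, impaction, the
   type.stage.form hypercementosis score, bone context);
4. a packaged, validated **reference dataset** of 35 hypercementotic
   teeth from 23 medieval-to-early-modern individuals;
5. an **etiology classifier**: a fixed published decision tree, a
   rule-based diagnostic-criteria classifier, and a from-scratch CART
   learner for refitting;
6. a from-scratch **Factor Analysis of Mixed Data** (FAMD) with
   iterative missing-data imputation and convex-hull group displays.

A synthetic tooth-root and height-map generator with analytic ground
truth stands in for raw scans; every measurement layer is validated by
parameter recovery against it.

# Thickness mapping

`compute_thickness()` defines the cementum thickness at each vertex of
the cementum envelope as the unsigned Euclidean distance to the nearest
point of the dentine surface — true point-to-triangle distance, not
vertex-to-vertex. For nested surfaces this matches a directional
pointwise surface-to-surface distance. The kernel is compiled (Eberly's
region-based closed form with a centroid-radius lower-bound prune) and
is tested against an independent pure-R implementation built on the
plane-foot/edge decomposition. Intersecting inputs yield zero thickness
at the affected vertices; these are flagged and warned about, never
silently accepted.

Two conventions are ours to fix because no standard exists:

* **Root thirds** (1 apical, 2 middle, 3 cervical) are equal
  axial-length intervals between the apex landmark and the
  cemento-enamel junction (CEJ) ring; on crownless roots without a
  preserved CEJ the preserved axial extent is used.
* **Sides** are 90° angular quadrants about the root axis centred on
  the four anatomical directions, with buccal (`<`) on the
  `buccal_reference` vector, mesial (`m`) at +90°, lingual (`>`)
  opposite and distal (`d`) at -90°.

`summarize_thickness()` reports LOC MAX as the third x side cell of the
maximal vertex plus any cell whose mean reaches 90% of that cell's mean
(`report_frac = 0.9`). The preferential-apposition flag quantifies
"not homogeneous around the long axis": PREF is true when the ratio of
the thickest to the thinnest side mean reaches `pref_ratio` (default
1.5), and LOC MIN is reported only in that case, otherwise `"No"`. The
1.5 default was chosen so that synthetic roots with zero angular
gradient but realistic smooth thickness texture (peak-to-valley up to
200 µm) score non-preferential, while gradients strong enough to be
anatomically meaningful (several hundred µm towards one side) score
preferential; it is a configuration key, not a constant.

## Atypical apposition shapes

`classify_shape()` extracts focal appositions as connected components
of vertices whose thickness exceeds the root baseline (the median
thickness) by `prominence_um` (default 300 µm), measures each
component, and applies the published size rules in a fixed precedence
order: atypical overgrowth (OG: wraps two or more sides, over 3 mm,
bulky), ridges (RID: at least three oblique elongated components under
1 mm wide, over 2 mm long, over 0.5 mm high), nodules (Nds: two or
more components each under 2 mm, collectively hemispherical), node
(NOD: a single component over 2 mm), spike-like projection (LSP: a
single component under 2 mm with multiple sharp internal maxima).

Measurements are made robust to mesh discretization by working in
local surface coordinates (axial position x circumferential arc),
which removes the component's own outward bulge from its in-surface
extents: the footprint diameter is the equivalent-circle diameter of
the component's convex-hull area; length and width are
principal-component extents corrected by one local edge length;
elongation is the scale-free ratio of the principal standard
deviations; obliquity is the angle of the first principal direction to
the root axis. Sub-resolution slivers (a few vertices straddling the
threshold) are discarded. These choices make the category assignment
invariant to mesh refinement, which the test suite checks by midpoint
subdivision.

# Surface topography

The processing chain is fixed: fill non-measured points, level,
optionally crop, remove the degree-2 form, then extract metrics.
Non-measured points are filled by harmonic interpolation (iterated
4-neighbour averaging to a fixed point), which is exact on locally
planar patches. Leveling subtracts the least-squares plane; form
removal subtracts the least-squares bivariate polynomial of total
degree 2, representing the curvature of the underlying root. Both are
idempotent projections, so the whole chain is invariant to adding any
degree-≤2 polynomial to the input.

**MAX VE** is defined as the peak-to-valley amplitude
(`max(z) - min(z)`) of the form-removed surface. The published usage of
"amplitude" does not distinguish peak-to-valley from robust
percentile-based amplitudes; peak-to-valley is the simplest reading and
is exact on the synthetic surfaces, whose generator scales the
detrended field to a prescribed amplitude.

The surface-aspect score has three parts:

| part | values | rule | default |
|------|--------|------|---------|
| elevation | `+` / `-` | MAX VE at or above the published amplitude threshold | 200 µm |
| texture | `S` / `R` | RMS of the Gaussian high-pass residual above a roughness threshold | cutoff 50 µm, RMS 5 µm |
| frequency | `1` / `2` | areal density of prominent relief maxima above a density threshold | 0.5 peaks per 100 µm x 100 µm, prominence 4 µm |

Elevation follows the published quantitative threshold directly.
Texture and frequency are qualitative guidelines in the source scoring
system; the package quantifies them with the proxies above, every
threshold being a configuration key. Relief maxima are counted on a
band-passed surface (Gaussian scales 12 µm to the texture cutoff):
the narrow band isolates individual relief peaks while broad
undulations cancel between the two blurs and short-correlation
micro-texture averages out, so neither form nor roughness masquerades
as relief frequency. The prominence default (4 µm) was calibrated on
the synthetic archetypes described below: it sits above the band-passed
residual of the roughest archetype noise and below the band-passed
height of the smallest archetype relief peak, with roughly twofold
margins on both sides.

# The synthetic generator

`make_root_pair()` builds the dentine core as a tapered superellipse
tube (circular by default) capped by a rounded apex — the simplest
closed shape with four distinguishable anatomical sides — and displaces
every vertex outward along its normal by an analytic apposition field:
a uniform base layer, an optional angular gradient (raised-cosine in
angle, Gaussian in axial position, centred on a chosen third), optional
shape primitives with compact-support bump profiles whose steep
shoulders make the thresholded footprint track the nominal diameter,
and an optional smooth seeded texture. The displacement *is* the
ground-truth thickness, so recovery can be asserted exactly: the
summary MAX THI is reproduced to machine precision when a vertex sits
at the field maximum, and within twice the mean edge length times the
local field slope otherwise. Primitives that cannot be represented
(footprints wrapping most of the circumference, or narrower than the
local mesh edge) fail loudly at generation time.

`make_height_map()` emulates processed confocal topographies from three
decoupled carriers plus an optional degree-2 form: broad undulations
carry the peak-to-valley amplitude; small relief peaks on a lightly
jittered lattice carry the relief frequency (the lattice keeps
neighbouring peaks resolvable as individual maxima at high densities);
and correlated noise carries the roughness (long correlation lengths
read as smooth, short ones as rough). After detrending, the combined
field is rescaled so its peak-to-valley equals the requested amplitude
exactly. `archetype_spec()` packages eight presets reproducing the
published aspect guideline categories; the generator parameters were
calibrated once so that each archetype sits well inside its category
under the default detector thresholds, and then frozen. The aspect
scorer recovers all eight archetypes in at least 95% of seeded draws
(100% in the shipped experiments).

What the generator deliberately does **not** emulate: voxel-level
micro-CT artifacts, segmentation errors at the cementum–dentine
junction, enamel crowns, instrument noise models of the confocal
scanner, or resorption lacunae. Passing recovery tests therefore
demonstrates the correctness of the measurement pipeline on clean
geometry, not robustness to acquisition pathology.

# Scoring systems

The composite hypercementosis score `type.stage.form` (e.g. `3.3.m`)
is reconstructed quantitatively from a thickness map by
`score_hypercementosis()`: the stage is the contiguous run of root
thirds from the apex whose mean thickness exceeds `baseline_um`
(default 500 µm), with stage 4 reserved for crownless roots whose whole
preserved surface exceeds the baseline; the type is diffuse (1) or
mixed (3) according to whether a focal shape component is present; the
form is marked (`M`) when MAX THI reaches `marked_um` (default
1500 µm). The full source scoring system is not published in
quantitative form, so both thresholds are explicit configuration keys;
the defaults reproduce the reference scores on synthetic analogues
(whole-root diffuse + node → `3.3.m`, crownless marked → `1.4.M`,
apical-only moderate → `1.1.m`). Type 2 (purely focal) exists in the
enumeration for fidelity to the source system but is never assigned by
this derivation; no reference tooth uses it. The derived score is
monotone: uniformly thicker fields never lower the stage or the form.

`validate_record()` enforces the cross-field consistency rules of the
visual systems (wear degree/direction/form coupling, caries site/stage
pairing, the impaction pattern, pulp exposure on infected teeth, and
the stage-4 CEJ rule) and returns violations as data rather than
throwing, so batch validation of user tables is cheap.

# The reference dataset

The packaged table transcribes the published per-tooth characterization
of 35 single-rooted teeth (23 individuals). Encoding decisions:

* Missing cells are explicit `NA`s, never zeroes. Two deliberate
  recodings keep the decision tree total: unscorable wear on crownless
  roots becomes degree 0 ("not applicable, crown not preserved"), and
  an unscorable antagonist becomes code 3, since the tree groups
  antagonist codes {0, 2, 3} against 1.
* Two teeth are flagged `excluded` (micro-CT revealed two coalescent
  roots); analyses default to the remaining 33.
* Composite localization codes (e.g. `"1>d +2m"`) are stored verbatim
  and parsed into third/side sets; parsing failures keep the verbatim
  text and flag the record.
* Reported statistics round half-away-from-zero to integer µm,
  matching the printed precision of the source. One printed group mean
  differs from the recomputation by 4 µm (1410 vs 1414 for the
  hypofunctional group); the fixture stores the raw values and the
  package reports the recomputed number, documenting rather than
  "correcting" the discrepancy.
* The printed table carries two anatomical-code artifacts
  (`ba_printed`); the canonical code from the individual-level table is
  exposed as `ba_code`, and both are preserved.

# Etiology classification

`published_tree()` encodes the fixed published tree: preferential
apposition at the root; on the preferential side, antagonist presence
isolates a pure HYPER leaf, the 1295 µm MAX THI threshold isolates a
pure MIX leaf, and wear degree 0–2 versus 3+ separates IMP from a
HYPER-majority leaf; on the non-preferential side, wear degree 0–1
gives the pure INF leaf and the 190 µm MAX VE threshold separates HYPO
from MIX. The verbal cut-point descriptions ("a score of 0, 1, or 2",
"0 or 1") are encoded as inclusive integer comparisons. A missing value
on the traversed path yields an explicit `"unroutable"` result; the
reference sample never needs imputation. On the 33 analysed teeth the
tree reproduces every published leaf composition: 8 HYPER pure, 5 MIX
pure, 2 IMP pure, 4 HYPER + 1 MIX, 4 INF pure, 5 HYPO pure, 4 MIX
pure — six of seven leaves pure, with exactly one tooth (a
mixed-condition premolar) classified as HYPER.

`classify_table3()` evaluates the published per-group diagnostic
criteria. The mixed-condition group is described in the source by
overlap percentages, not criteria, so MIX acts as the fallback when two
or more group profiles match fully and `"indeterminate"` is returned
when none does.

`fit_cart()` is a from-scratch CART: greedy binary recursive
partitioning maximizing Gini-impurity decrease, numeric splits at
midpoints between sorted distinct values, exhaustive categorical
subsets up to 8 observed levels, stopping at purity, `min_leaf`
(default 2) or `max_depth` (default 5). No cost-complexity pruning is
applied: the published tree is read as a final structure, and whether
the original fit used pruning or case weights is not stated, so a
refit may legitimately differ from the published structure — only the
application of the published tree is treated as a reproduction target.
Ties between splits break deterministically by column order and then by
the first candidate threshold. Every chosen split is tested against an
exhaustive enumeration oracle, and the first split is cross-checked
against an independent `rpart` fit.

# Factor analysis of mixed data

`fit_famd()` standardizes continuous columns to unit population
variance, divides each categorical level indicator by the square root
of its proportion before centring, and decomposes the combined
\(1/\sqrt{n}\)-weighted matrix by SVD. Three identities pin the
implementation down: the total inertia equals the number of continuous
columns plus \(\sum (\mathrm{levels}-1)\) over categorical columns and
the eigenvalues sum to it; with only continuous columns the
eigenvalues equal those of the correlation matrix (standardized PCA);
with only categorical columns they equal \(Q\) times the eigenvalues of
a correspondence analysis of the indicator matrix (\(Q\) = number of
variables), the scaling difference following from the inertia
convention. Row coordinates are invariant to level relabeling and to
affine rescaling of continuous columns, and their Gram matrix is
diagonal.

`impute_missing()` iterates a low-rank FAMD reconstruction. Missing
categorical cells stay *fuzzy* (indicator rows initialized at the
observed level proportions and updated continuously), because a
hard-label iteration can lock itself into a self-consistent wrong
level: the missing cell's own indicator then cancels the evidence of
the observed variables in the row's score. Cells are committed to their
highest-scoring level only at convergence. Regularization of the
reconstruction is deliberately omitted for determinism; with the small,
nearly complete tables this package targets, the unregularized iterate
is stable. Rank-1 structures are completed exactly.

The published axis percentages of the source analysis (14.4 / 11.6 /
8.1%) are *not* a reproduction target: the exact variable subset and
the ordinal-versus-nominal encoding of the wear scores used there are
not recoverable from the publication, and both encodings are supported
via the caller's choice of column types.

# Numerical choices and problem sizes

* Rounding of reported statistics: half-away-from-zero to integer µm.
* Harmonic fill tolerance 1e-8 µm; polynomial fits via QR on scaled
  coordinates; SVD rank cut at 1e-10.
* Degenerate inputs: flat surfaces score `-S2`; intersecting meshes
  flag zero-thickness vertices with a warning; single-class training
  data yield a single-leaf tree; empty classification tables yield an
  empty report with a zero exit.
* Default synthetic problem sizes were chosen to keep the full
  validation fast while staying comfortably inside asymptotic
  behaviour: roots use 48 rings x 40 sectors (≈1900 vertices), height
  maps 256 x 256 pixels at 8 µm (a 2 x 2 mm field), recovery
  experiments 50 seeded roots and 200 seeded height maps. At these
  sizes the complete test suite runs in about two minutes.

# Known limitations

* The thickness map is vertex-to-surface; no claim is made about the
  sub-triangle distribution on the cementum side.
* Shape categories follow a fixed precedence; fields mixing several
  archetypes report the highest-precedence match rather than a
  decomposition.
* The quantitative reconstructions of qualitative published systems
  (texture, frequency, hypercementosis type/stage/form) are calibrated
  on synthetic archetypes; applying them to real scans requires
  checking the configuration thresholds against instrument and sample.
* The CART refitter deliberately omits pruning and case weights.
* Synthetic validation covers clean geometry only (see the generator
  section).
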