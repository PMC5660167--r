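---
title: "Quantifying huntingtin aggregation and fibre morphometry in muscle sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying huntingtin aggregation and fibre morphometry in muscle sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Skeletal muscle of Huntington's disease (HD) mouse models such as R6/2
accumulates aggregated mutant huntingtin (HTT) in microscopically visible
inclusions, both inside myonuclei and in the cytoplasm. Two very different
readouts are used to follow this process:

* a **per-mass assay** (Seprion ligand-capture ELISA) reporting aggregate
  load per unit of tissue lysate, and
* **per-nucleus image statistics** from two-channel immunofluorescence:
  DAPI marks nuclei, the S830 antibody marks aggregated HTT.

The two can disagree for a purely geometric reason. A hypertrophic
intervention (here: inhibition of myostatin/activin A signalling with a
soluble ACVR2B/Fc receptor) enlarges fibres at an approximately constant
number of myonuclei per fibre. Nuclei - and the aggregates they carry - are
then spread over more tissue mass, so the per-mass signal falls even when
per-nucleus aggregation is unchanged. `myoquant` implements the image
quantification, the per-mass model, and the reconciliation logic needed to
distinguish genuine disease modification from this dilution artefact, and a
synthetic-section generator so the whole chain can be validated against
exact ground truth.

## ROI quantification

Each region of interest (ROI) is a 40x field exported as two 8-bit TIFFs.
The protocol is deliberately simple and fully deterministic:

1. **Fixed thresholds.** DAPI at intensity 90, S830 at 50; a pixel *below*
   the threshold is excluded, so a pixel exactly at the threshold is kept.
   The thresholds are protocol constants of the assay, not tuned per image
   (adaptive thresholding is explicitly out of scope).
2. **Objects** are maximal sets of adjacent above-threshold pixels.
   8-neighbour adjacency is the default, matching the common particle
   convention of ImageJ; 4-neighbour is available in `quant_config()`.
3. **Debris.** DAPI objects with fewer than 25 pixels are debris, not
   nuclei; a 25-pixel object is retained. No minimum is imposed on S830
   objects by default (`s830_min_pixels = 1`, configurable).
4. **Colocalization.** The debris-filtered DAPI mask partitions S830
   foreground pixels into intra- and extra-nuclear counts; these always sum
   to the total above-threshold S830 pixels.
5. **Object-level compartments.** The protocol is pixel-based, so an S830
   object straddling a nuclear boundary is ambiguous at the object level.
   The default `pixel-partition` rule splits such an object at the mask and
   re-labels each part, which keeps the pixel totals exact; the `majority`
   rule assigns the whole object to the compartment holding at least half
   its pixels (ties to nuclear, counted and reported). Neither convention
   is privileged by the assay description; both are provided and the
   choice is recorded in run metadata.
6. **Nine per-ROI statistics** (`summarize_roi()`): nucleus count and mean
   size, inclusion count and mean size, % S830 signal colocalized with
   DAPI, % inclusions nuclear, nuclear-inclusion count, % nuclei with an
   inclusion (a nucleus "contains" an inclusion when at least one
   nuclear-inclusion pixel falls in its pixel set - the automated
   equivalent of a manual count), and mean nuclear-inclusion size.
   Ratios with zero denominators are reported as `NA`, never 0, so empty
   ROIs cannot drag group means toward zero.

Whole-section images are gridded into nine equal ROIs centred in the tissue
bounding box (`grid_rois()`); two sections give 18 ROIs per mouse. The
**mouse**, not the ROI, is the unit of analysis: `aggregate_mouse()` takes
field-wise means (skipping `NA`s, with per-field n) before any group test.

## Fibre morphometry

Atrophy and hypertrophy are measured on laminin-stained sections as the
**lesser fibre diameter**: the minimum caliper (Feret) width of the fibre
cross-section, the standard myopathology measure because it is robust to
oblique sectioning. `min_feret()` scans the convex-hull edge normals
(rotating-calipers candidate set), which is exact for polygons; boundary
polygons are built over pixel *corners* so a w-pixel-wide block measures
exactly w.

Fibre segmentation in practice is often done with proprietary commercial
rule sets (e.g. Definiens) whose parameters cannot be recovered, so
absolute fibre counts per section are not comparable across pipelines -
distributional properties are. `segment_fibres()` standardises on
a conventional surrogate: Otsu (or fixed) threshold for the bright boundary
band, morphological opening (radius `smoothing_radius_px`, default 1 px)
as edge smoothing, distance-transform watershed (`watershed_tolerance`,
default 3 px) to split merged fibres - convex interiors have a concave
distance transform and are never split - and label growth of
`boundary_grow_px` (default 1 px, half the simulated band) to return each
fibre its share of the sarcolemmal outline. Acceptance rules: area in
[300, 30000] px, circularity >= 0.4, solidity >= 0.85, edge-touching
excluded. Rejected fibres are flagged with a reason, never dropped, so the
exclusion rate itself is auditable.

## The dilution model

`per_mass_signal()` formalises the per-mass readout of a tissue state as

    signal = nuclei_per_mg / h * (1 - satellite_fraction) * load_per_nucleus

with hypertrophy factor `h` and a satellite fraction of aggregate-free
(Pax7+) nuclei. The mapping from image statistics to `load_per_nucleus` is
`mean_nuclear_inclusion_px * pct_nuclei_with_inclusions / 100`, chosen
because it uses only the nuclear-inclusion panel quantities. Whether
ligand capture scales linearly with inclusion volume is an assumption of
the model, not something the imaging establishes.

`reconcile()` compares treated/vehicle ratios of the two readouts at a
relative tolerance `tol` (default 0.1; no published value exists, so it is
exposed in the interface): a per-mass drop with preserved per-nucleus load
is `"dilution"`; a drop in both is `"disease-modifying"`; anything else is
`"mixed"`.

## Group statistics

* `two_way_anova()` fits both main effects and the interaction and reports
  Type II sums of squares (via `car::Anova`). The source design is
  reported as a plain between-subject two-way ANOVA even for longitudinal
  measures; the package reproduces that stated design rather than
  correcting it to repeated measures. Type II is the common factorial
  convention when the interaction is not the focus; in balanced designs
  the SS partition is exact and verified to 1e-10 against the textbook
  closed form.
* `km_logrank()` uses the Mantel-Cox convention: hypergeometric variance,
  no continuity correction; verified against a hand-tabulated event table
  and calibrated (type-I error ~5% over 1000 null cohorts).
* `grubbs_test()` implements the iterative two-sided Grubbs screen with
  the exact t-quantile critical value. It is intended to be applied per
  genotype-by-treatment cell, not globally, so genotype effects cannot
  masquerade as outliers.
* `gene_filter()` is the RNA-seq retention rule (count >= 2 in >= 10 of 79
  samples; the boundary gene with count 2 in exactly 10 samples is kept).
  Downstream differential expression and network analysis are the province
  of established packages and out of scope here.
* `qpcr_fold_change()` normalizes to the geometric mean of three
  housekeeping genes before computing group fold changes.

## The synthetic generator

`simulate_roi()` emulates exactly the features the quantification relies
on, and nothing more:

* convex fibre cross-sections from a jittered-grid (Voronoi) tessellation
  with tunable mean diameter and approximate size dispersion;
* non-overlapping nuclei placed within 2 px of a fibre boundary
  (sarcolemmal myonuclei; interior placement is a switch);
* inclusion discs with lognormal radii, wholly nuclear or strictly
  extra-nuclear, mutually non-adjacent so each disc is one object;
* i.i.d. uniform background noise on [0, 40], strictly below both
  thresholds, with foreground at 200/180 - ground-truth masks are
  therefore *exactly* recoverable by thresholding, enabling pixel-set
  equality tests rather than approximate ones. An optional Gaussian blur
  (`blur_sigma`, default 0) trades this exactness for realism.

Two defaults encode the aggregation pattern of R6/2 muscle at 12 weeks:
55% of inclusions are nuclear, and the nuclear/cytoplasmic radius medians
(3.18 / 2.30 px at default scale) were calibrated once - numerically, from
the expected digital disc area under the lognormal radius law - so the
expected nuclear share of aggregate signal is 70%. Each nucleus hosts at
most one inclusion: at these sizes two non-overlapping discs cannot fit in
one nucleus footprint, and single nuclear inclusions match what is seen in
this tissue. Host nuclei are drawn without replacement; rare Poisson-tail
draws that exhaust the hosts are redrawn (bounded restarts), and genuinely
overcrowded configurations raise a dedicated condition.

`apply_hypertrophy(config, h)` multiplies the fibre diameter by `h` and
scales the per-ROI inclusion mean by the *realized* fibre-count ratio of
the tessellation grid (which quantizes to whole cells) rather than the
nominal 1/h^2, so inclusions per fibre - and hence every per-nucleus
statistic - are exactly invariant under hypertrophy. Nucleus size is
untouched: fibre hypertrophy does not enlarge nuclei.

Exported 40x fields vary in dimensions and pixel size between microscopes;
the defaults (1024 x 1024 at 0.31 um/px) are configurable placeholders. `demo_section_config()` (180 x 180 at 1 um/px, ~25 fibres,
~40 nuclei, ~30 inclusions per field) keeps every biological default while
simulating in tens of milliseconds; the test-suite problem sizes below use
it.

What the generator does **not** emulate - point-spread blurring, chromatic
shift, uneven illumination, tissue folds, staining gradients, 3D
sectioning artefacts - bounds what passing tests show: they validate the
measurement logic exactly, not robustness to microscopy artefacts.

## Numerical and design choices

* Threshold semantics "below is excluded" means `>=` is kept; covered by
  boundary tests at 89/90 and 24/25 px.
* `min_feret` is exact on hull-edge normals. The width function of a
  polygon has V-shaped minima there, so a fixed-step angle sweep converges
  only linearly; the independent test oracle therefore refines its 0.1
  degree grid by local optimisation before asserting 1e-6 agreement.
* The demonstration's "unchanged-or-larger nuclear inclusions" assertion
  is a non-inferiority check: a one-sided t-test for a treated *decrease*
  must fail to reject at alpha = 0.01. Under the simulated equality a raw
  sample-mean comparison would fail about half the time by chance; the
  package asserts a decrease only when the data clearly support one.
* Problem sizes: the demonstration uses 8 mice per group with 6 ROIs each
  per seed, giving roughly 1900 nuclei per group - enough that the
  per-nucleus load ratio estimate (sampling CV about 5%) stays inside the
  0.9 dilution boundary in well over 90% of cohorts. Calibration tests use
  50-seed batches of `demo_section_config()` fields.
* All simulators are deterministic given `(config, seed)` and leave the
  caller's RNG stream untouched; pipeline runs derive everything from one
  run seed and write it to the manifest.

## Known limitations

* The morphometry rule set is a reproducible surrogate for proprietary
  commercial pipelines; compare distributions, not counts.
* The dilution model treats ELISA capture as linear in aggregate pixel
  volume and ignores epitope accessibility and aggregate species.
* `fibre_diameter_cv` controls dispersion only approximately (grid-jitter
  amplitude), and the tessellation quantizes fibre counts to whole grid
  cells.
* The two-way ANOVA reproduces the stated between-subject design for
  longitudinal data; a repeated-measures analysis would be more efficient
  but is intentionally not substituted.
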