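---
title: "Quantifying DNA origami addressability from DNA-PAINT localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA origami addressability from DNA-PAINT localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paintability)
```

## The problem

DNA origami folds a long scaffold strand into a prescribed shape using ~200
short staple strands. Its practical value rests on *addressability*: a staple
extended with a single-stranded docking site can anchor a guest molecule at a
defined position with nanometer accuracy. Whether that works for a given
staple depends on two factors that bulk assays cannot separate: the staple
must be **incorporated** during folding, and its docking site must be
**accessible** for hybridization.

DNA-PAINT super-resolution microscopy probes both at the single-staple level.
Dye-labeled imager strands bind a docking site transiently and repeatedly;
each binding event produces localizations in consecutive camera frames. A
present, accessible site therefore accumulates hundreds of localizations over
an acquisition, while a missing or sequestered site accumulates essentially
none. This package implements the full quantification pipeline — and a kinetic
simulator that generates ground-truth data to validate it.

## The pipeline

1. **Picking** (`pick_structures()`): localizations are grouped into
   single-structure clusters by connected components over occupancy cells,
   replacing interactive selection. Clusters that are too small or too
   extended (merged neighbours) are dropped.
2. **Template alignment** (`align_to_template()`): each structure's
   localizations are histogrammed into 1–2 nm bins and the image is rotated
   stepwise through the full circle; at each step it is cross-correlated
   against a template image rendered from the designed site positions
   (unit-amplitude Gaussians, `render_template()`). The correlation is
   computed in the frequency domain, which searches every translation at
   once; scores are normalized by the image norms so they are comparable
   across templates. The best rotation/shift is applied to the localization
   list (`transform_locs()`).
3. **Per-site counting** (`count_sites()`): localizations within a closed
   disc around each designed site position are counted; where discs would
   overlap, the nearest site wins, so no localization is counted twice.
4. **Thresholding** (`fit_threshold()`, `determine_threshold()`): the pooled
   histogram of per-site counts is fitted with a single Gaussian on its
   detected-population peak; the detection threshold is the count value at
   the lower half-maximum of the fitted curve, $\mu - \sigma\sqrt{2\ln 2}$.
5. **Scoring** (`call_sites()`, `detection_efficiency()`,
   `false_positive_rate()`, `bootstrap_std()`): a site is detected iff its
   count reaches the threshold. Probed sites enter efficiency denominators;
   absent-by-design sites are scored identically but only for the
   false-positive rate; alignment sites are never scored.

Two higher-level analyses build on the per-site calls:

* **Two-color coincidence** (`coincidence_tally()`,
  `independence_estimate()`): staples carrying orthogonal docking sites on
  their 3′- and 5′-ends are imaged in two colors. Writing the per-instance
  category fractions as $(f_\mathrm{both}, f_{3'}, f_{5'}, f_\mathrm{none})$
  and assuming the two ends are detected independently given incorporation,
  the chance that an incorporated staple shows no signal at all is
  $(f_{5'}+f_\mathrm{none})(f_{3'}+f_\mathrm{none})$. When this is far below
  $f_\mathrm{none}$, the no-signal category measures failed incorporation, so
  the incorporated fraction is $1 - f_\mathrm{none}$ and the difference
  between it and the single-channel detection efficiency is an additive
  offset that translates any measured detection (accessibility) efficiency
  into an absolute incorporation efficiency
  (`detection_to_incorporation()`).
* **Saturation kinetics** (`fit_michaelis_menten()`): detection efficiency as
  a function of the molar staple excess over the scaffold follows a
  saturation curve $E(x) = v_\mathrm{max}\, x / (K_m + x)$, fitted by
  unweighted nonlinear least squares.

```{r twocolor}
est <- independence_estimate(two_color_tally(0.785, 0.050, 0.072, 0.093))
est
detection_to_incorporation(0.77, est$offset)
```

## Designs

Three design families ship with the package:

* `build_grid_20nm()` — 12 docking sites on a 4 × 3 lattice with 20 nm
  pitch, the standard benchmark structure. The row/column split is a design
  choice consistent with 12 sites at 20 nm spacing on the ~70 × 100 nm
  rectangle face.
* `build_bs_pair()` — two structures sharing an asymmetric arrowhead + line
  alignment pattern and six site positions; the 6 BS variant probes all six,
  the 3 BS variant probes three and keeps the other three as
  absent-by-design positions for false-positive scoring.
* `build_variant_library()` — 18 rectangle variants, each probing 12 staple
  positions of a 14 × 12 lattice (168 labels, 7 × 5 nm pitch), all sharing
  the alignment pattern so a structure can be assigned to its design by
  template correlation (`classify_template()`) and per-staple efficiencies
  merged into a heatmap (`build_heatmap()`).

The exact nm coordinates of the arrowhead + line pattern and the 18
probed-set assignments are not tabulated anywhere; the package defines fixed
programmatic fixtures. The alignment pattern is a five-site chevron plus a
four-site row placed outside the staple lattice — what matters for the method
is only that it is always present, breaks rotational and mirror symmetry, and
keeps all sites at least one counting-disc diameter apart. The 18 probed sets
follow wrapped lattice diagonals: variants 1–14 cover each of the 168
positions exactly once, variants 15–18 re-probe 48 of them (multiply probed
staples are averaged with structure-count weights in the heatmap), and
within-variant spacing stays above the 6 nm counting disc.

## The simulator

`simulate_field()` performs in-silico DNA-PAINT experiments with known
ground truth. Binding at each present site is an alternating renewal process:
exponential dark times (mean 12.5 s by default, corresponding to the imaging
conditions; derived as $1/(k_\mathrm{on} c)$ only when no explicit value is
given) and exponential bright times (mean 0.5 s). Each bright interval is cut
into camera frames (15,000 frames of 200 ms by default); every overlapped
frame emits one localization with photons proportional to the overlap time
(35 photons ms⁻¹ kW⁻¹ cm² × 1.5 kW cm⁻² × 200 ms = 10,500 photons for a full
frame, capped by a 1.5 × 10⁶ photon budget per event) and an isotropic
position error of $\sigma_\mathrm{PSF}/\sqrt{N_\mathrm{photons}}$ per axis
(PSF FWHM 309 nm, so ≈1.28 nm at full-frame photons), which is also the
recorded precision. Localizations below 100 photons are dropped, mimicking
the detection floor of spot-fitting software. Structures are placed uniformly
with uniform random orientation in a 128 × 128 px field of 160 nm pixels,
with a 400 nm minimum separation; adsorption is single-faced by default
(mirror simulation available by flag). Per-site presence is Bernoulli with a
configurable probability — this is the ground-truth dial the detection
pipeline is benchmarked against. One master seed derives per-structure child
streams, so fields are exactly reproducible.

What the simulator does *not* emulate: background or nonspecific
localizations (available only as zero by default), drift (tables represent
drift-corrected data), kinetic heterogeneity between sites, imager depletion,
and camera-level effects beyond photon-scaled precision. Passing tests on
simulated data therefore validate the geometry and statistics of the
pipeline, not its robustness to every experimental artifact; in particular,
simulated count histograms are much narrower than experimental ones (see
below).

## Numerical choices

* **Rotation step**: 1° by default — far below the angular scale of the
  smallest feature separation at the structure radius. Coarser steps (2–4°)
  are used in some validation runs where only classification, not angular
  precision, is at stake.
* **Binning**: alignment histograms and templates use 1 nm bins for
  single-site work (rendering σ 1 nm) and 2 nm bins for the 20-nm grid
  (σ 3 nm). Grid sizes are rounded to FFT-friendly lengths.
* **Correlation normalization**: plain (non-mean-subtracted) normalized
  cross-correlation; images are non-negative, so scores lie in [0, 1] and are
  comparable across templates.
* **Unassigned cut-off**: `min_correlation = 0.35`. Calibrated before the
  analyses were frozen: uniform-noise picks score below 0.08 against the
  single-site templates while correctly matched simulated structures score
  0.6–0.8; 0.35 sits well clear of both.
* **Counting boundary conventions**: closed disc (distance ≤ r) and
  inclusive threshold (count ≥ threshold).
* **Count-disc diameters**: presets `grid20` (20 nm), `excess` (18 nm),
  `bs3bs6` (5 nm), `variants18` (6 nm) reproduce the per-analysis
  parameters. A diameter larger than the minimum site spacing is rejected;
  a diameter equal to the spacing is allowed (the 20 nm disc on the 20 nm
  grid is the canonical configuration) because nearest-site assignment
  prevents double counting.
* **Histogram binning for the threshold fit**: Freedman–Diaconis on the
  pooled counts by default, overridable. The bin containing zero counts is
  excluded from peak selection and fitting (it is the undetected
  population), and the Gaussian is fitted over the contiguous bins above 10%
  of the peak, extended by one anchor bin per side so the tails constrain
  σ.

## The threshold on idealized data

The half-maximum rule is designed for experimental count histograms, whose
detected population is broad (site-to-site kinetic variability, structure
quality): there $\mu - \sigma\sqrt{2\ln 2}$ lands near the valley between
the undetected and detected populations. Idealized simulations are different:
with uniform kinetics the detected population is narrow (CV ≈ 8%), and a cut
at $\mu - 1.18\sigma$ would sit *inside* it, clipping its lower tail even
though every count is unambiguously far from zero. In that regime any analyst
looking at the histogram would put the cut in the wide empty range below the
peak — which is also how interactive threshold selection works in practice.

`determine_threshold()` automates exactly that judgement: it computes the
half-maximum threshold, then scans the counts below the fitted peak for the
widest empty interval. If that interval is wider than `gap_factor × σ` of
the fitted Gaussian (default factor 2), i.e. the populations are
cleanly separated, the cut moves to the midpoint of the interval; otherwise
the half-maximum value is used unchanged. On broad histograms reaching down
to zero the rule never fires and the estimator is the pure half-maximum fit;
on cleanly bimodal or all-detected data it places the cut in the gap, which
is what makes 0% false positives / 100% true positives attainable on
ground-truth simulations. For multi-condition experiments the recommended
workflow is to pool the counts of all conditions, fit one threshold, and pass
it to each `analyze_structures()` call — the threshold is a property of the
imaging conditions, not of any one sample.

## Validation scale

The shipped validation suite runs the full pipeline at the original
acquisition parameters (15,000 frames × 200 ms) with: 50 structures per
design for the 3 BS / 6 BS false-positive/true-positive experiment; 50
structures per presence level (30–100% in steps of 10) for the
identity-line calibration of detected versus simulated site fractions; 100
structures for rotation recovery; and two structures per variant for
18-template classification. These sizes were chosen to give binomial
uncertainties comfortably below the asserted tolerances while keeping the
suite quick to run; unit tests use shorter acquisitions (600–2,250 frames)
of the same model.

## Known limitations

* Thresholding assumes a single detected population; histograms with several
  well-separated positive modes (e.g. mixed designs analyzed jointly without
  classification) need a manual threshold.
* The independence assumption of the two-color analysis fails if 3′- and
  5′-end detection failures are correlated (e.g. partially synthesized
  staples); the estimate is then an upper bound on incorporation.
* Automated picking requires structures to be separated by more than the
  pick diameter; aggregates are discarded, which can bias efficiencies if
  aggregation correlates with structure quality.
* Structures whose alignment correlation falls below the cut are discarded;
  at very low presence probabilities this removes sparse structures and
  biases the mean detected fraction slightly upward.
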