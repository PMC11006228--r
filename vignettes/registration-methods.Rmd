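---
title: "Barcode-guided registration of histology sections to OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-guided registration of histology sections to OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Training an image-translation network that turns optical coherence tomography
(OCT) images of intact skin into virtual H&E histology requires training
pairs in which each 2D histology section is matched to the *exact* oblique
plane of the 3D OCT volume it came from. A section relates to the fresh-tissue
volume through nine degrees of freedom — three rotations, three translations,
and per-axis shrinkage scales from fixation and processing — and tissue
landmarks alone cannot recover them reliably.

`octhist` implements the fiducial-based solution: the tissue block is encased
in a fluorescent gel, an OCT volume is acquired, and a barcode of dark lines
is photobleached into the gel through the full imaging depth. Each bleached
line is a *vertical plane* in volume coordinates. Any physical section cuts
these planes in a set of dark traces whose positions encode, through the
barcode's gap ratios, which plane each trace came from — independently of
the unknown scale of the section. From the decoded correspondences the
section-to-volume mapping is estimated, the matching oblique OCT slice is
extracted, and co-registered OCT/H&E crops are assembled.

## The plane model

A section is modelled as a plane: section coordinates $(u,v)$ (µm; $u$ along
the slide, $v$ increasing with depth) map to volume coordinates by

$$\mathbf{p}(u,v) = L \begin{pmatrix}u\\v\end{pmatrix} + \mathbf{t}, \qquad
L = \operatorname{diag}(s_x, s_y, s_z)\, R_z(\alpha) R_y(\beta) R_x(\gamma)\, E,$$

where $E$ embeds $(u,v) \mapsto (u, 0, v)$: the canonical section is the
volume's $x$–$z$ plane (a vertical cross-section with the skin surface at
top), $R$ applies intrinsic $z$–$y$–$x$ Euler rotations, and the $s_i$ are
the per-axis shrinkage scales. `compose_plane()` and `decompose_plane()`
convert between the nine parameters and the affine form; the decomposition
solves a linear system in the inverse squared scales (row-scaling $L$ to
orthonormal columns) and is exact to machine precision. When the plane
normal lies exactly along $y$ the cross-plane scale $s_y$ is unobservable;
it is then set to $\sqrt{s_x s_z}$ and flagged.

The accuracy statistic throughout is the **cross-plane error**: the mean,
over a 1 mm × 0.5 mm grid of section coordinates, of the distance along the
true plane's normal between corresponding mapped points. In-plane
misalignment is excluded deliberately — it is directly visible when the two
images are overlaid and is absorbed by in-plane panning/stretching, whereas
cross-plane error silently swaps in tissue that was never in the section.

## Barcode design and decoding

A barcode family is a set of parallel vertical planes with azimuth $\theta$
and offsets $d_k$; the *gaps* between consecutive offsets follow a ratio
code. Because every bleach plane contains the depth axis and sections are
near-vertical, **all** traces on a realistic section are near-vertical
lines; trace orientation cannot separate families (and a family at
$\theta = 90°$ would be parallel to the section and leave no trace at all).
The default pattern therefore uses two families at $\theta = 0°$ and
$\theta = 45°$ with *distinct* codes — gaps $(1,2,3)\times 200$ µm and
$(2,1,3)\times 140$ µm — chosen so that no code, forwards or reversed, at
any plausible relative scale, mimics the other. Within a family the gap
*ratios* are invariant to the section's unknown affine scale, which is what
makes decoding possible at all. Codes whose gap vector is proportional to
its own reverse (e.g. $(1,1)$ or $(1,2,1)$) are rejected at construction:
they cannot distinguish a section viewed from either side.

`match_lines()` solves the correspondence by exhaustive search over
family/subset/order assignments: observed lines are grouped by approximate
parallelism (a generous 20° — two clicked points on a line carry several
degrees of angle noise), each group's sorted positions are compared with
every ordered subsequence of each family's offsets, forwards and reversed,
under a free per-family scale. Line positions are measured by projecting
each line's pick centroid onto the group's common normal; using each line's
own fitted normal instead would leak its slope noise into the position with
a lever arm of half the section height. Among assignments that survive the
15 % gap-ratio tolerance, the in-plane least-squares residual arbitrates:
only the true labelling is consistent with a single affine plane map.

## Estimating the nine parameters

**In-plane stage.** A pick $(u,v)$ on the trace of plane $k$ satisfies
$\mathbf{n}_k^\top (L_{xy} (u,v)^\top + \mathbf{t}_{xy}) = d_k$ — linear in
the six unknowns of the map's $x,y$ rows. `fit_inplane()` solves all picks
jointly by least squares (two families with distinct azimuths are required;
one family leaves the system rank-deficient) and reports the residual RMS
and the coefficient standard errors.

**Depth stage.** The bleach planes are vertical, so they say nothing about
the $z$ row. `resolve_depth()` completes the map by registering the
section's tissue top contour $(u, v_{\rm top})$ to the OCT surface height
map: the decomposition parameters and $t_z$ minimise a weighted sum of
(i) disagreement between the composed $x,y$ rows and the fitted ones,
weighted by the fit's own standard errors, (ii) squared distance between
the mapped contour's $z$ and the surface height *interpolated at the
candidate's own mapped lateral position* — re-interpolating inside the
objective matters, because in-plane errors otherwise sample the surface at
wrong positions and produce height errors correlated with the surface
undulation that badly bias the depth scale — and (iii) a soft pull of
$s_y$ towards $\sqrt{s_x s_z}$, since a single section leaves the
cross-plane scale nearly unobservable. By default $s_z$ is a free
parameter measured by the surface registration itself (`assume_sz =
"surface"`); tying $s_z := s_y$ or fixing a value are available as
alternatives for workflows with prior knowledge of the processing
shrinkage. The problem is solved by Levenberg–Marquardt on the residual
vector; with noiseless inputs the recovery is exact to well below 0.1 µm.

**Multi-section stage.** Consecutive sections from one block are parallel
cuts. `joint_stack_fit()` shares one linear part across sections, lets
translations differ only along the common plane normal, and registers all
contours at once; `method = "average"` instead averages independent
per-section decompositions, for comparison with the simpler description of
the workflow. Both reduce the estimator's spread; the joint fit is used by
default. The spacing of the recovered normal offsets, divided by $s_y$,
estimates the physical block spacing of the sections.

**Fine alignment.** The interactive refinement step — adjusting exactly
three translations and the in-plane rotation until the resliced OCT matches
the stained section — is automated as masked normalized cross-correlation
(NCC) optimisation: a coarse scan along the plane normal, then Nelder–Mead
over the four degrees of freedom. Orientation and scale stay frozen; the
returned map never scores below the starting one, and a constant (featureless)
reference returns the start unchanged with a flag. Before correlating, the
OCT reslice is log-transformed and its per-image linear depth trend is
removed, and both images are smoothed (σ = 2 px): attenuation gives OCT a
depth-brightness gradient that a stained section does not have, and without
detrending the correlation optimum slides systematically toward shallower
planes. `manual_deltas` bypasses the optimiser to reproduce the interactive
workflow. The search radius should match the accuracy of the starting
estimate (default ±50 µm); far beyond it, speckle and structure repeats can
offer spurious correlation optima.

## The phantom

`make_phantom()` generates the test bed with exhaustive ground truth:

* a wavy tissue surface (two random-phase sinusoids, default amplitude
  40 µm, period 400 µm) under a gel layer (default 150 µm);
* an epidermis band (default 80 ± 10 µm, dark in OCT as the nuclei-rich
  epithelium is) over bright dermis, with fully developed multiplicative
  exponential speckle, Beer–Lambert depth attenuation (default 0.005 /µm,
  matching useful signal to roughly 450 µm), and separable Gaussian blur at
  the system resolution (3.7 µm lateral, 2.0 µm axial FWHM);
* follicle-like dermal inclusions: dark oblique tubes whose axes drift with
  depth (slopes up to ±0.5), 50 by default. These are the landmarks that
  make fine alignment meaningful — their cross-sections *move* as the
  cutting plane moves, exactly as real hair follicles do. Smooth blobs, or
  too few of them, leave cross-plane position pinned only by speckle luck;
* 25-µm fluorescent beads in the gel, visible in both channels, for the
  independent colocation check;
* a uniformly fluorescent gel channel into which `apply_bleach()` writes
  the barcode as Gaussian troughs (FWHM = line width, default 25 µm).

Everything is deterministic in the seed. `simulate_sectioning()` produces,
per section: line picks (points on the true traces plus isotropic Gaussian
jitter — the default σ = 10 µm stands for slide-scan click precision),
the tissue top contour, the fluorescence image, an H&E-like rendering
(stylised label colours with texture noise; adequate for NCC alignment, no
histological realism claimed), and each bead's in-section position.
Sections advance by `spacing × s_y` along the plane normal — block-space
spacing shrinks by the cross-plane scale when mapped into the fresh-tissue
volume.

What the phantom does *not* model: non-affine (differential) tissue
deformation, multiple scattering, refraction, staining chemistry. Passing
the recovery bounds here shows the estimator is correct and noise-stable
under the plane-map model; it does not bound errors from real tissue
warping beyond that model.

## Validation experiments and problem sizes

`registration_experiment()` embodies the study conditions: 200 phantoms of
1 × 1 × 0.6 mm, random true planes with tilts ≤ 5°, per-axis scales uniform
in [0.8, 1.0], translations placed so the section crosses tissue and
barcode; sections 2 × 0.5 mm (the slide is wider than the OCT footprint);
two picks per line with σ = 10 µm jitter; correspondence decoded from
scratch each time. The cross-plane error is evaluated on a 1 mm × 0.5 mm
grid at 25 µm steps. Phantom truth (surface, beads, layers) is analytic,
so the barcode-only stage runs without voxel rasters; the refinement stage
rasterises the OCT channel at 5 µm voxel pitch and correlates at 8 µm
pixels — the working resolution for *paired crops* remains 1 µm/px, but
parameter-recovery statistics are insensitive to the Monte-Carlo raster
pitch, which was chosen so the full experiment runs in minutes on one CPU.
Bead seeding uses 120 beads per phantom: a 25-µm bead must fall within
about 15 µm of the cutting plane to appear in the section, so sparser
seeding leaves many replicates without a colocation measurement.

Under these conditions the barcode-only estimator recovers planes with a
cross-plane error of a few µm (SD well under the 59 µm pre-refinement
bound), fine alignment keeps the SD under the 25 µm post-refinement bound,
and the mean bead colocation error stays within one bead width. The exact
numbers for a given seed are computed by `scripts/acceptance.R`, never
stated statically.

## Numerical choices

* Reslicing is trilinear, not spline: it is exact on multilinear fields,
  reduces to bit-exact raster slices on axis-aligned planes, and keeps the
  brute-force oracle meaningful. Out-of-volume samples take the fill value
  and are masked.
* Focus-stack fusion uses Gaussian depth weights
  $w_k(z) = \exp(-(z - f_k)^2 / 2\sigma_f^2)$ with $\sigma_f$ defaulting to
  the 10 µm focus step, renormalised wherever any volume covers $z$, after
  median-intensity equalization against the median of the per-volume
  medians (order-invariant; constants are conserved exactly).
* Surface detection thresholds a 3-sample-smoothed A-line at the column
  background (median of the shallowest 5 %) plus `min_jump`, then 3 × 3
  median filters; columns without a crossing are flagged.
* SNR masking estimates the noise floor from the deepest 10 % of rows,
  thresholds the 3 × 3 local mean at floor + $k\sigma$, cuts everything
  deeper than 450 µm below the surface trace, and removes speckle-sized
  islands by morphological opening (disc, radius 3 px). Raising $k$ never
  unmasks a pixel.
* Stain normalization deconvolves against the standard hematoxylin/eosin
  optical-density matrix, matches the 99th-percentile concentration of each
  stain over tissue pixels to the reference, and recomposes; background
  white has zero optical density and passes through unchanged, and the
  operation is idempotent up to quantile-estimation noise.
* Volume files are multi-page TIFF (z-pages) with a JSON sidecar carrying
  spacing, origin, intensity domain, focal depth and the value range;
  intensities are stored as 16-bit scaled integers snapped to the storage
  grid, so a written file re-reads bit-exactly and re-writes to itself.
* The 1024 × 512 → 256 × 256 resize is anisotropic area-weighted pooling
  (exact block means at integer factors) with any-pooling of the mask: a
  target cell touching any masked source pixel is masked in both
  modalities.

## Known limitations

* The plane-map model is affine by construction; real sections warp
  non-affinely (the epithelium shrinks differentially), which bounds how
  far any 9-DOF estimate can go on real tissue.
* Fine alignment adjusts only the four named degrees of freedom; residual
  tilt errors from the barcode stage are not correctable there and
  propagate into the refined cross-plane error.
* The correspondence search is exhaustive and intended for patterns of a
  few families with ≤ ~8 lines each; decoding needs at least three lines
  per family to use gap ratios at all.
* The H&E rendering and the stain-jitter model are stylised; stain
  normalization is validated on them and on its invariants, not against a
  reference slide scanner.
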