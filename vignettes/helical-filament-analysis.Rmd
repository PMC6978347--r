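---
title: "Methods: helical lattice analysis of PB1-domain filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helical lattice analysis of PB1-domain filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixlattice)
```

This vignette documents the models, conventions and numerical choices
behind the package. It is the reference for why each default is what it
is; the README shows how the functions are used.

## The helical lattice model

A filament is modeled as a one-dimensional crystal: an asymmetric unit
repeated by the screw operation with rise $\Delta z$ (Å) and twist
$\Delta\varphi$ (degrees), possibly multiplied by an axial cyclic group
$C_c$ and, for antiparallel rungs, a dihedral two-fold perpendicular to
the axis. Derived descriptors are the units per turn
$U = 360/|\Delta\varphi|$ and the pitch $P = \Delta z \cdot U$.

Conventions adopted (the source data print signed twists without defining
handedness, so the package fixes one):

* the helix axis is $+z$ in a right-handed frame; **negative twist means a
  left-handed screw** viewed down $+z$;
* angles are wrapped into $(-180, 180]$, with ties at $-180$ mapped to
  $+180$;
* values are rounded half-up to printed precision only in the reporting
  layer (`report_round()`), never inside computations;
* the dihedral two-fold of `expand_symmetry()` passes through azimuth 0 of
  subunit 0. The phase of that axis is not observable from layer-line
  positions, so any fixed choice generates the same lattice up to a global
  rotation;
* `equivalent_description(sym, k, j)` regroups $k$ consecutive subunits
  (with point-group phase $j$) into one asymmetric unit. Together with the
  $C_c$ copies, every $(k, j)$ generates the identical point set, which the
  test suite verifies by brute-force expansion;
* `rationalize()` returns the best rational approximation $u/t$ with
  bounded $t$ (equivalent to a continued-fraction convergent or
  semiconvergent); ties break toward smaller $t$, then smaller $u$.

Layer lines sit at reciprocal heights $Z = n/P + m/p$ with $p$ the rise;
with $C_c$ symmetry only Bessel orders $n \equiv 0 \pmod c$ survive, and
on layer line $l$ of an integer helix ($u$ subunits in $t$ turns) the
allowed orders obey $l = tn + um$.

## Synthetic data: what is emulated, what is not

The generators produce exactly the inputs the analysis consumes, with
known ground truth:

* **Filaments** are rendered as isotropic Gaussian blobs (default
  $\sigma = 2.5$ Å) at the expanded subunit positions, projected along
  $y$. Blob rendering reproduces layer-line *geometry*, which depends only
  on positions; it does not emulate atomic scattering factors, the
  contrast transfer function, dose or ice gradients. Noise is white
  Gaussian at a variance-defined SNR. Default pixel sizes 1.386 and
  1.04 Å mirror the two imaging set-ups whose lattices are built in
  (`pb1_symmetry()`).
* **Tomograms** contain flat-capped solid tubes of unit density around
  curvature-limited persistent random walks (default direction change
  4°/2 nm step), convolved with a 1-voxel Gaussian as a resolution proxy,
  plus white noise. Defaults follow the reported morphology of filaments
  inside p62 bodies: diameter 15 ± 1 nm, log-normal lengths with mean
  30 nm (sdlog 0.3), 20 filaments in a 160 × 160 × 80 voxel volume at
  1 nm/voxel. Filaments are packed with a ≥ 4 nm surface gap so that
  neighbors remain resolvable at the rendered resolution; the SNR default
  of 2 is the package's choice (no calibration is published for such
  data). No missing wedge, tilt-series artifacts or membranes are
  simulated, so passing recovery tests demonstrates the measurement
  pipeline, not robustness to every cryo-ET artifact.
* **Titrations** come from the one-site isotherm below;
  **melt curves** are a logistic transition between two linear baselines.
  The default temperature schedule (15–90 °C in 0.5 °C steps, 151
  samples) matches standard dye-based thermal-shift protocols.

All generators are pure functions of their parameters and seed.

## Spectrum analysis choices

* Segments (350 Å boxes at a 60 Å mean step, the standard excision
  geometry for helical processing) are in-plane rotated so the local axis
  is vertical; a 10 % cosine taper suppresses box-edge ringing before the
  FFT.
* **Layer-line detection** scores each axial-frequency row by
  $(\max - \mathrm{median})/\mathrm{MAD}$ computed on *log* power. Raw
  power under noise is exponentially distributed, and on the log scale the
  row maximum of pure noise stays within a few MADs of the median: at the
  default thresholds pure-noise spectra yield no detections, which the
  suite checks over repeated seeds. The statistic is calibrated for data
  with a noise floor; on strictly noiseless spectra the "noise" estimate
  is the signal structure itself and the scores are not meaningful.
  Adjacent rows merge through local-maximum picking; heights are refined
  to sub-pixel by a parabola through the peak column.
* **Indexing** searches a (pitch, rise) grid per strand count, assigns
  each observed height to the nearest predicted $n/P + m/p$, and ranks
  candidates by an amplitude-weighted residual. When the filament radius
  is supplied, predicted radial peak positions (first maximum of $J_n$,
  at $x_n/2\pi r$) enter the score; this is what separates an $s$-start
  lattice from its 1-start alias, which have identical height combs.
  Radial errors are capped at 0.02 Å⁻¹ and meridional ($n = 0$) peaks are
  excluded from the radial term (their radial position sits inside the
  masked axial band). Peaks weaker than 0.2 % of the strongest are
  dropped: they sit near the noise floor and carry no indexing
  information. The winning assignment is refined by weighted linear least
  squares in $(1/P, 1/p)$, whose residual tolerance defaults to half a
  Fourier pixel in the recovery recipes.
* **Grid search** correlates gamma-compressed spectra
  ($\gamma = 0.25$) with the equator masked (2 Fourier pixels; the
  equator is dominated by the cylinder transform and carries no twist
  information). Compression lets the weaker high-order lines contribute
  instead of the few strongest lines dominating the correlation; without
  it the score surface is nearly flat along a (pitch, units/turn) valley.
* The recovery recipes use a 3000 Å filament (about 45 segments after
  excision) at SNR 2 — enough averaging for reliable sub-pixel heights at
  desk scale, far below the tens of thousands of segments of a real
  reconstruction, which is why map resolutions are out of scope here.

## Tomogram morphometry choices

* **Threshold**: Otsu on a 256-bin histogram, by default refined to the
  midpoint between the filament-interior plateau (median of voxels deeper
  than 3 voxels into the provisional mask) and the background median.
  The midpoint places the boundary of a blurred edge at half height,
  which is where the true surface of a smoothed step sits; plain Otsu on
  these unbalanced histograms lands below half height and inflates the
  mask. The volume is pre-smoothed (Gaussian, 1.5 voxels) to suppress
  single-voxel speckle before thresholding.
* **Skeletonization** deletes simple border points (Malandain–Bertrand
  characterization: one 26-connected foreground component in the
  neighborhood and one face-connected background component) in six
  directional subiterations, preserving endpoints. A sequential re-check
  keeps deletions topology-safe; a candidate whose neighborhood changed
  since collection is only deleted if the object is still two voxels
  thick along the peel direction — without that guard the sequential pass
  can unravel a thin slab end-first and collapse the skeleton of an
  even-width tube. A final cleanup removes residual simple points with
  three or more neighbors (curve interiors have exactly two and are
  untouched).
* **Tracing**: junction voxels (degree ≥ 3) split the skeleton into
  chains; side branches shorter than 3 × the mean mask radius are pruned
  iteratively, chains are spliced back across junction clusters that
  join exactly two survivors, and remaining multi-way junctions split
  the traces (conservative: crossings never produce a path through the
  junction, which biases lengths short in dense meshworks). Node
  coordinates are smoothed with a 5-node moving average before length
  measurement (the discrete skeleton zig-zags, inflating step sums by up
  to ~20 %). At free ends the path is extended to the mask boundary by
  the largest projection of near-axis mask voxels onto the end tangent
  (fitted over the last 5 smoothed nodes); the skeleton of a capped tube
  stops short of the true end by roughly one radius, and stubby
  components whose skeleton is shorter than the tube diameter fall back
  to the extent along the mask's principal axis.
* **Width** is measured per interior node by casting 8 ray pairs
  perpendicular to the local tangent and averaging the boundary-to-
  boundary distances, with a convexity correction $+2\sigma^2/w$ for the
  known smoothing $\sigma$ (a blurred convex surface recedes by
  $\sigma^2/w$ per side at the half-height threshold). Nodes within two
  radii of an end are excluded and the mean is 10 % trimmed. Ray
  averaging is unbiased under boundary quantization, unlike the distance
  transform, whose minimum statistic reads rough boundaries low.
* Directional thinning visits axes in a fixed order, so the pipeline is
  equivariant to axis permutation only at the level of summary statistics
  (the suite allows one trace of difference and a few percent on means),
  not voxel-exactly.

At the default study conditions (15 nm / 30 nm tubes, SNR 2) the full
pipeline recovers mean width within a few percent and mean length within
about 3 % of ground truth; the acceptance thresholds (10 % / 15 %) leave
room for seed-to-seed variation.

## Binding and stability fits

The one-site isotherm uses the standard perfusion-cell dilution
bookkeeping (displaced volume leaves the cell): after cumulative injected
volume $dV$, $M_t = M_0 (1 - dV/2V_0)/(1 + dV/2V_0)$ and
$X_t = X_0 (dV/V_0)/(1 + dV/2V_0)$. The bound fraction is the quadratic
root
$\Theta = \tfrac12\left(S - \sqrt{S^2 - 4X_t/NM_t}\right)$,
$S = 1 + X_t/NM_t + K_D/NM_t$, the cumulative heat is
$Q = N\Theta M_t \Delta H V_0$, and the per-injection heat adds the
displaced-volume correction $(dV_i/V_0)(Q_i + Q_{i-1})/2$. A conservation
check (total heat of a saturating titration $= N \Delta H M_0 V_0$ within
2 %) ties the convention down. Heats are in µcal, concentrations molar,
the default cell volume 1.4 ml.

`fit_one_site()` fits $\log K_D$, $\Delta H$, $N$ by Levenberg–Marquardt
with geometry-derived starts ($N$ from the molar ratio at half-height,
$\Delta H$ from the first injection) and a small multistart over binding
strength; standard errors come from the Jacobian, with the delta method
for $K_D$. Identifiability is guarded by the Wiseman $c$-value
($c = NM_0/K_D$, warning outside $[1, 10^4]$) and by an $R^2$/SE check
that flags fits to uninformative data instead of returning a silent
estimate. Default recovery experiments titrate a 10 µM cell with a
100 µM syringe over 28 × 10 µl injections, reaching molar ratio 2.

Melt curves are fitted per replicate: a linear pre-transition baseline
(region below the smoothed-derivative midpoint) is subtracted, the curve
normalized to maximum 1, and a four-parameter logistic fitted; $T_m$ is
the inflection. The four-parameter logistic is mathematically identical
to the Boltzmann sigmoid parameterization. A shared linear drift in both
baselines cancels in this procedure, which the tests verify to 0.1 °C.

## Degenerate inputs and error policy

Zero twist, non-positive rise, empty asymmetric units, constant volumes
under Otsu, fewer injections than the baseline window, melt curves
without a transition, and infeasible tomogram packing all raise immediate
errors naming the constraint. Layer-line detection returns an empty table
(not an error) when nothing exceeds threshold; salt-bridge search skips
unknown residue names with a single summary warning; alternate-location
atoms keep the highest occupancy with a message.

## Known limitations

* The printed pitch/units-per-turn values of some lattices are not
  arithmetically consistent with their refined rise/twist at the second
  decimal (e.g. a printed 135.9 Å pitch versus
  $9.574 \times 360/25.42 = 135.6$ Å). The package always reports values
  computed from rise and twist and does not attempt to reconcile rounded
  literature numbers.
* Detection thresholds assume a noise floor; strictly noiseless spectra
  should be analyzed with the indexing functions directly.
* No CTF, dose, missing wedge, or multi-model refinement: the spectrum
  module determines lattice parameters, it does not reconstruct maps.
* Interface analysis reports distances and contact counts only; no
  interface free energies.
* The tracer is tuned for loosely packed, non-touching tubes. Touching
  filaments merge into one component and are split at junctions, biasing
  lengths short.
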