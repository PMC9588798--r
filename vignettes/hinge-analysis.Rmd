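---
title: "Quantifying hinge motion and FRET dynamics in antibody assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hinge motion and FRET dynamics in antibody assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igmhinge)
```

## The scientific problem

Pentameric IgM presents ten Fab arms on a rigid disc-shaped core built
from the Cμ4 and Cμ3 constant domains and the J-chain. IgM has no
sequence-defined hinge; its hinge-equivalent is the Cμ2 domain, whose
C-terminal junction to Cμ3 lets each F(ab')₂ unit — the two Fabs plus the
Cμ2 dimer, which behave as one rigid body — pivot about a point at the
Cμ2/Cμ3 interface. Two angles describe an arm's orientation:

* **α (in-plane)**: the signed angle of the arm's projection onto the
  core platform, measured from the two-fold symmetry axis of the Cμ4
  dimer;
* **β (out-of-plane)**: the signed elevation of the arm above (+) or
  below (−) the Cμ4–Cμ3 platform plane.

In a cryo-EM reconstruction averaged over many particles, a mobile
F(ab')₂ contributes a blurred density cloud: the reconstructed map is the
convolution of the rigid-body density with the probability distribution
of its orientations. Two quantitative questions follow, and this package
implements the computations for both:

1. **Forward**: given an atomic model, a pivot and an assumed angular
   range, what does the motion-blurred density look like?
   (`simulate_pivot_ensemble`)
2. **Inverse**: given a density map, how far does the arm actually move?
   (`motion_range`, using the background-SNR boundary criterion)

A companion module analyses single-molecule FRET traces of the Fc
monomer, whose Cμ4 dimer interconverts between two conformations several
times per second, and predicts inter-dye distances from accessible-volume
dye models.

## The pivot frame and orientation measurements

`pivot_frame` holds the pivot point, the in-plane zero axis (α = 0), the
platform normal (β = 0) and a sign convention for β (the J-chain
hairpin-3 side is negative). `define_pivot_frame` derives these from a
core model: the zero axis is the axis of the two-fold rotation that best
superposes one Cμ4 chain onto the other (recovered from the Kabsch
rotation; a dimer whose best rotation deviates more than 20° from 180° is
rejected), the platform normal is the smallest principal axis of the core
selection, and the pivot is the midpoint of the hinge-terminal residue
pair. The two-fold axis is orthogonalised against the platform normal so
the frame invariant (zero axis ⊥ normal) holds exactly.

`measure_fab_orientation` takes the arm direction as the unit vector from
the Cα of the last Cμ2 residue to the centroid of the constant-domain Cα
atoms — backbone references, since no specific atoms are prescribed by
the conventions above. α is `atan2` of the in-plane projection, β is
`asin` of the normal component. When the arm is parallel to the normal
the projection is degenerate and α is reported as 0 by convention.
`rotate_about_pivot(model, frame, alpha, beta)` composes the elevation
about the transverse axis with the in-plane rotation about the normal so
that constructing an orientation and measuring it back is an exact round
trip — a property the test suite checks over a grid of angles.

## Rendering and the pivot ensemble

`render_density` gives every atom an isotropic unit-integral 3D Gaussian
(default σ = 2 Å) on an isotropic voxel grid (default 2 Å). All atoms are
weighted equally: the analysis operates on shape envelopes at low
threshold, not absolute scattering densities. Kernels are truncated at
5σ, which keeps the mass of an ensemble average equal to a single render
to better than 10⁻⁶ relative — the conservation property that makes
"motion blur" an exact reading of the ensemble average.

`simulate_pivot_ensemble` averages renders over an `orientation_grid`
(default uniform weights; a cosine taper is available). The default grid
mirrors the forward-modelling convention for the pentamer: ±50° on both
axes at 10° intervals, i.e. an 11 × 11 array of orientations.

## The arc quantifier

`motion_range` implements the measurement pipeline:

1. smooth the map with an isotropic 3D Gaussian, σ = 3 px (mirror
   boundary, so constants are preserved and interior mass conserved);
2. take six consecutive cross-sections at one-voxel spacing centred on
   the mid-plane for each axis (in-plane sections are parallel to the
   platform; out-of-plane sections contain the zero axis and the normal);
3. locate the arc radii (below), take grey-value profiles along the
   inner (Fab constant) and outer (Fab variable) arcs at 1° steps by
   bilinear interpolation;
4. estimate background statistics from section pixels farther than
   1.5 × the outer radius from the pivot;
5. bound the motion range per sign with the SNR criterion, and report the
   per-section boundaries and their mean per axis, arc and sign.

**Arc radii.** Every orientation of a pivoting rigid body keeps its
domains at a fixed distance from the pivot, so the domains appear at
their true radii in the radial profile of the ring-averaged grey value
(`detect_arc_radii`), no matter how widely the ensemble is spread.
Averaging along the ring suppresses voxel noise; maxima below a relative
floor or a robust noise floor (median + 5 MAD of the outermost rings) are
ignored. Radii can equally be supplied as configuration, matching the
practice of identifying the arcs by eye on the sections; circle fitting
of ridge points (`arc_ridge_points` + `fit_arc_circle`) confirms that the
arcs share a centre at the pivot.

**The boundary rule.** The criterion is that a profile point belongs to
the motion range while `(grey − mean(BKG))/sd(BKG)` is at least 2. Two
practical refinements were needed, and both are deliberate design
choices:

* *Peak tracking rather than support-edge crossing.* An ensemble
  generated at 10° orientation intervals produces a comb of arc blobs
  whose density genuinely extends about half a step plus the angular
  point-spread width beyond the outermost orientation. Any estimator that
  reports the angle where the profile *crosses* the threshold therefore
  carries an irreducible positive bias of several degrees. The boundary
  is instead the outermost resolvable arc peak (local profile maximum
  away from the centre) that passes the criterion — the angle of the last
  orientation at which the arm demonstrably dwells. Profiles with no
  off-centre local maxima (a plateau or a single smooth peak) fall back
  to the linearly interpolated threshold crossing, which is the correct
  reading for such shapes. A run still above threshold at the window edge
  is reported at the edge and flagged.
* *A relative floor for noise-free maps.* A simulated map without noise
  has background deviation ≈ 0 and the ratio is undefined. The working
  threshold is `mean(BKG) + max(2·sd(BKG), rel_floor·(peak − mean(BKG)))`
  with `rel_floor = 0.15` (and `peak_floor = 0.3` for counting a peak as
  present). On noisy maps the SNR term dominates; on clean maps the floor
  keeps the criterion defined. `snr_ratio` itself still refuses a
  zero-deviation background.

**Reported arc.** The outer (variable-domain) arc is the default for the
reported range: at fixed smoothing width the angular resolution of a ring
profile scales inversely with its radius, and at the constant-domain
radius the 10° orientation comb is at the edge of resolvability (angular
PSF ≈ 4.4° there versus ≈ 2.8° at the outer radius). Both arcs are always
measured and reported side by side.

**8-bit conversion.** The reference image workflow converts sections to
8-bit before measuring; `to_8bit` reproduces that (min–max rescale, round
half up), and `motion_range(use_8bit = TRUE)` mirrors it. The default is
to measure on float sections: the criterion is scale-free, and for widely
spread two-axis ensembles the arm blobs occupy only a few grey levels
after quantisation against the bright pivot region, which costs real
precision. On well-contrasted maps the 8-bit route changes boundaries by
less than 2°, which the suite asserts.

## Synthetic ground truth for the hinge

`make_toy_hinge_model` builds a deterministic two-arm rigid body: a core
slab disc in the platform plane behind the pivot, a shared stem cluster
at 0.23 L on the bisector, and two arms of line atoms with pseudo-domain
clusters at 0.59 L (constant) and 0.91 L (variable), splayed symmetrically
about the bisector in the out-of-plane plane. Defaults: arm length
L = 110 Å (a Cμ2-plus-Fab arm), splay 50°, pivot ranges ±50° at 10°
steps. The cluster offsets are mirror-symmetric about every coordinate
plane, so symmetric ensembles produce exactly mirror-symmetric maps.

`make_pivot_map` renders the ensemble at voxel 1.5 Å — chosen once so
that the angular PSF at the arc radii resolves the 10° orientation comb
(σ_spatial = √(2² + 4.5²) ≈ 4.9 Å after smoothing) — on a cube sized so
the background annulus beyond 1.5 × the outer radius is populated.
Optional i.i.d. Gaussian voxel noise is scaled to the noise-free map peak
(the boundary criterion only uses the background mean and deviation, so
uncoloured noise is the appropriate stress).

**Study conditions.** Range-recovery studies (clean, and with noise at
one fifth of the map peak) use single-axis ensembles: the in-plane-only
map is measured in-plane, the out-of-plane-only map out-of-plane. On a
full two-axis grid with that noise level, each cross-section sees its arm
blobs diluted 1/121 by the orientation count while the noise refers to
the global peak, leaving per-section signal at ~2–4σ after smoothing —
a regime where the criterion itself correctly reports no significant
signal. The splay-broadening study keeps the full two-axis ±50° grid,
noise-free. Problem sizes throughout (≈ 220³ voxel maps, 11 × 11
orientation grids, 100-molecule trace sets) were chosen as the smallest
that leave the measured quantities grid-converged.

**What the generator does not emulate**: structured (coloured)
reconstruction noise, CTF effects, per-particle alignment error,
inter-subunit overlap of neighbouring clouds, and the ~10° tilt of the
experimental cloud axes relative to the platform (available as a frame
configuration, not assumed). Passing the synthetic studies shows the
estimator recovers known angular ranges under the stated noise model; it
does not by itself validate performance on experimental reconstructions
with correlated noise.

## smFRET trace analysis

The trace model and its inversion: at state efficiency E and photon
budget I per frame, the donor channel is D = I(1−E) and the FRET channel
F = γIE + αD + βA, with A the directly-excited acceptor intensity
(constant per molecule while the acceptor is alive), α the donor
bleed-through, β the direct-excitation fraction and γ the detection
factor. State paths are two-state Markov chains with exponential dwells;
acceptor and donor bleach in single exponential steps; noise is Gaussian
with variance proportional to intensity (a seed-stable Poisson
surrogate). With zero noise, zero bleed and γ = 1 the efficiency formula
returns the state values exactly — the model-inversion consistency the
suite asserts.

Analysis (`analyze_fret_experiment`) proceeds: α from donor-only
molecules (mean F/D over pre-bleach frames), β from acceptor-only
molecules (mean F/A), then γ per molecule from donor recovery after
acceptor photobleaching with 10-frame windows either side of the step
(the step frame excluded), bleed-corrected so the generative bleed terms
do not bias the ratio, pooled as the mean after a 3-MAD outlier screen.
Efficiencies are computed on frames before the first bleach of
single-step molecules, masked outside [−0.2, 1.2], pooled, and fitted
with Gaussian mixtures (k = 1 and 2, unequal variances, BIC selection,
deterministic initialisation subset). Dwell analysis assigns frames with
hysteresis — a switch requires entering the target state's mean ± 1 sd
band — which suppresses noise-induced chatter that raw nearest-mean
assignment would count as transitions.

Two detection choices matter and are worth stating plainly:

* Acceptor bleaching is detected on the **A channel**, which is constant
  across FRET states; the F and D channels step at every state change and
  would misclassify dynamic molecules as multi-step.
* Donor bleaching is detected on the **recovered donor** D + F/γ, which
  is state-independent once γ is known.
* The step detector compares two-window means against a *local* pooled
  deviation (intensity-proportional noise is heteroscedastic: a long
  quiet post-bleach tail must not shrink the criterion), with windows
  that shrink near the trace edges; molecules whose acceptor is already
  dark in the first frames are excluded, as spots without a working
  acceptor.

## Accessible-volume dye distances

`accessible_volume` places candidate dye positions on a 1 Å grid within
the linker length (default 20 Å) of the labelled residue's Cβ (a
pseudo-Cβ is constructed for glycine), keeps positions whose dye sphere
(3.5 Å) does not clash with any model atom and whose straight path from
the attachment is unobstructed at the linker half-width (4.5 Å linker
diameter; straight-line reachability, no path search), and weights them
equally. These defaults are standard accessible-volume practice and are
stand-ins: they are all configurable, and the clash test treats atoms
with a single 1.7 Å radius rather than per-element van der Waals radii.
`mean_fret_distance` averages `1/(1+(r/R₀)⁶)` over donor–acceptor
position pairs (R₀ = 51 Å) and reports the FRET-weighted mean distance as
the single distance with that efficiency.

## Numerical choices, degenerate inputs, limitations

* Superposition uses the SVD (Kabsch) solution with a determinant guard
  against reflections; fewer than three pairs is refused as
  underdetermined, mismatched counts as a pairing error.
* Circle fits run the algebraic (Kåsa) solution, then Gauss–Newton
  refinement of radial residuals; collinear points are refused.
* Trilinear/bilinear interpolation treats lattice points outside the grid
  as missing; profiles refuse rings that leave the section.
* Ties in the boundary walk break toward smaller |angle| (the first
  crossing from the centre outward), giving a conservative range.
* The quantifier assumes one dominant arm system per map; separating
  overlapping clouds of neighbouring subunits is out of scope and should
  be handled with an exclusion mask or by cropping.
* The arc-radius auto-detector needs the arm density to stand above the
  ring-noise floor; at low contrast, pass `radii` explicitly.
* Boundaries are reported at the profile sampling resolution (1° default)
  for peak-type boundaries, interpolated for crossing-type boundaries.
* The FRET mixture fit reports at most two states; more complex
  heterogeneity shows up as inflated component widths, not extra states.
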