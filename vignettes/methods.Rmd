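---
title: "Simulating cine cardiac MR with exact functional ground truth"
author: "CardioPhantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cine cardiac MR with exact functional ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CardioPhantom produces short-axis balanced-SSFP cine images of a beating
left ventricle together with the exact ground truth behind every pixel:
label masks, dense displacement fields, strain curves, cavity volumes,
ejection fraction and mass. This vignette explains the models behind each
stage, the parameters that matter, the numerical choices, and what the
package's synthetic tests do and do not demonstrate about real data.

## The generative shape model

Anatomies are truncated thick-walled prolate spheroids described by a
handful of interpretable parameters (cavity length, base radius, wall
thickness at base and apex, sphericity, basal tilt, global scale). A
synthetic population sampled from preset-specific parameter distributions
(healthy, dilated thin-walled, hypertrophic thick-walled) stands in for a
clinical training set. The low-rank generative model is linear: principal
components of the flattened, pose-normalized endo/epicardial coordinate
grids, with the latent coordinates whitened so the training set is
standard normal per coordinate. A linear embedding is deterministic,
exactly invertible on its subspace, and satisfies the contract that
matters downstream — `decode(0)` is the population mean, `encode` after
`decode` is the identity, and shapes sampled within three standard
deviations stay anatomically valid. A nonlinear embedding could capture
curvature of the shape manifold but would add stochastic training for no
benefit at this population complexity. Principal-component extrapolation
can very occasionally pull the wall below the 0.5 mm validity floor at
single grid nodes; `sampleShape()` projects such shapes minimally back
into the valid set (0.6 mm floor) so that unconditional sampling always
yields usable anatomies.

Pose is normalized before fitting (apex at the origin, long axis along
+z, a reference circumferential node at azimuth zero) because rigid-body
variation is not anatomy. k-means on the training latents with three
clusters yields the NOR/DCM/HCM preset centers; centers are labelled by
decoded anatomy (largest cavity is DCM, thickest wall among the rest is
HCM).

## Reduced-order cardiac mechanics

One cardiac cycle is simulated with quasi-static continuum mechanics
projected onto a small library of smooth deformation modes (a Galerkin
reduced-order model). The full-order alternative — nonlinear finite
elements — costs hours per cycle; the reduced model keeps the constitutive
law, the loads and the conservation structure, and solves in tens of
seconds.

**Passive law.** The myocardium follows the four-term invariant
Holzapfel-Ogden strain energy: an isotropic `I1` exponential, fiber and
sheet stretch terms (`I4f`, `I4s`, active only in tension) and a
fiber-sheet shear term (`I8fs`), plus a volumetric penalty
`kappa/2 (J-1)^2`. The healthy baseline coefficients are the published
shear-data fit of the law (a = 0.496 kPa, b = 7.209, af = 15.193 kPa,
bf = 20.417, as = 3.283 kPa, bs = 11.176, afs = 0.662 kPa, bfs = 9.466);
`kappa` defaults to 2000 kPa, which keeps the wall-volume excursion over
the cycle below about 3.5% at preset operating pressures. Dilated and
hypertrophic presets multiply the stress-like coefficients by a
pathology factor of 5 (the physiologic range is 5-10).

**Fibers.** Helix angle linear in transmural depth, +60 degrees at the
endocardium to -45 at the epicardium by default; the fiber lies in the
circumferential-longitudinal plane and the sheet direction is radial.
The asymmetric range is deliberate: with symmetric +-60 fibers the
active torsional moments of the inner and outer wall cancel almost
exactly, leaving the twist direction as a symmetric double well through
which a quasi-static solver can snap unpredictably. An asymmetric helix
(well within the histologic range) gives the twist a definite sign.

**Activation.** A graph-geodesic (eikonal-style) front propagates from an
apical endocardial ring at an effective conduction velocity of 1.2 mm/ms;
the ring stimulus and the velocity jointly stand in for the fast
His-Purkinje system that is not modelled explicitly, giving an
activation-time spread of 60-90 ms. Active stress follows a smooth
two-sigmoid twitch (rise 90 ms, plateau 320 ms, relaxation 45 ms over a
1000 ms cycle), normalized so its peak equals `TaMax`, acting along the
deformed fiber direction.

**Pericardium and circulation.** The pericardial sac is a stiff quadratic
penalty on epicardial *radial* displacement (400 kPa/mm per epicardial
node by default) — longitudinal and circumferential motion stay free —
anchored at the end-diastolic configuration (the pericardium is taken to
conform to the heart at end diastole). Afterload is a three-element windkessel (Zc = 50,
Rp = 1100 mmHg ms/ml, C = 1.6 ml/mmHg) behind a diode aortic valve;
preload is a constant venous pressure with a diode mitral valve. Filling
is simulated by ramping the cavity pressure to the end-diastolic pressure
(10 mmHg); the resulting state defines EDV and the strain reference.

**Mode library.** Ten axisymmetric analytic displacement fields:
endocardial squeeze profiles (linear, quadratic and inverse-radius
transmural shapes — the 1/R profile is the volume-preserving radial
field of thick-wall contraction), a uniform squeeze, longitudinal
shortening (two transmural profiles), torsion, two transmural shears
and a thickening-gradient mode. Circumferential harmonics of the
squeeze are added only together with a scar, along with three
scar-localized modes (squeeze, bulge, shear weighted by the scar
blend): under symmetric activation the harmonics form symmetric double
wells (elliptical buckling) with no physical preference and would make
the quasi-static solution branch-dependent, whereas a scar both needs
them and fixes their orientation.

**Numerics.** Energies and virtual work are integrated by one-point
quadrature over a layered hexahedral mesh (default 16 x 8 x 3 elements
interpolated from the surface grids; element volumes use 2x2x2 Gauss),
with per-element stiffness, active-stress and conduction scalings for
the scar.
At fixed pressure the equilibrium is the minimum of a potential, found by
Levenberg-damped Newton with finite-difference modal Hessians, Hessian
reuse across warm starts, and an energy line search. Coupling to the
circulation is solved per 5 ms time step in *volume control*: windkessel
flows at a trial LV pressure (sub-stepped at 1 ms) set a target cavity
volume, the mechanics is solved with a stiff cavity-volume penalty, and
the conjugate pressure is driven to self-consistency by a safeguarded
secant iteration. Volume control removes the snap-through folds that
pressure-controlled quasi-statics exhibits around activation onset; a
small step-wise viscous regularization (eta = 30 kPa mm^3 per unit modal
amplitude) smooths what remains. The volume target is corrected for the
penalty bias so that cavity-volume changes match net valve flow to
better than 1% of stroke volume over the cycle — this conservation is a
tested invariant, not an assumption. Convergence tolerance is a maximal
modal virtual-work residual of 0.5 kPa mm^3 (about four orders below
peak systolic values).

Outputs are 50 uniformly spaced frames; frame 1 *is* the end-diastolic
reference, so strain curves start at zero and displacement fields vanish
at the reference by construction.

## Strain ground truth

Strains are reported per element as Green-Lagrange normal strains of the
end-diastolic local radial, circumferential and longitudinal directions
(orthonormal frames recomputed from the end-diastolic geometry) under
the incremental deformation `F(t) F(ED)^-1`. The Green convention was
chosen because the published functional targets this package calibrates
to are only mutually consistent under it: a healthy triplet like
(0.78, -0.14, -0.17) implies directional stretches (1.6, 0.85, 0.81)
whose product is near one-plus-shear, whereas stretch-minus-one strains
of that magnitude would require the wall to gain 27% volume at end
systole. Engineering strains remain available via
`computeStrain(type = "engineering")`.

A genuine tension in those published targets is worth stating plainly:
at EF near 50% and longitudinal shortening near 15-20%, volume
bookkeeping pins the myocardium-averaged radial stretch at about
1.4-1.5 for a near-incompressible wall, i.e. a Green radial strain near
0.55. Reaching 0.78 requires the wall to *gain* 10-15% volume at end
systole. This package keeps the tissue near-incompressible (wall-volume
excursion < 5% is one of its tested properties), so its healthy radial
strain settles near 0.47 rather than 0.78; the scar/remote ordering and
the scar-region magnitude of the infarct preset are unaffected. Users
who prefer the compressible regime can lower `kappa`.

## Phantom assembly and background warping

The moving ventricle is voxelized per slice: the deformed endo/epi
surface grids are intersected with each slice plane, giving sub-element
polygons that are rasterized (inside endo = blood pool, between = wall).
The torso background is procedural — body ellipse with a fat rim, two
lungs, an RV crescent with periodic contraction, atria in basal slices,
a descending aorta, a liver block — under a fixed 12-class dictionary.
The background's placeholder LV epicardial contour is warped onto the
simulated epicardial contour per slice: correspondences by matched
arc-length parameterization anchored at the RV-septal azimuth, Gaussian
radial-basis interpolation of the control displacements (kernel width
defaulting to half the contour radius, widened automatically if the
warped grid would fold), applied in backward convention. Composition
overwrites the LV classes from the foreground, so ground-truth masks are
bit-exact by construction. Warping is two-dimensional per slice;
mid-ventricular slices are the supported output, and apical/basal fidelity
is out of scope.

## Tissue properties and image formation

Per-class PD/T1/T2 come from a literature-regime table (1.5 T; YAML in
`inst/extdata`, overridable). Texture is a per-class mean-one log-normal
Gaussian random field (relative SD 8%, correlation length 6 mm by
default), excluded on the LV myocardium — the LV stays uniform so its
masks remain exact — and advected with the background deformation so
speckles stay on their tissue. The voxel-wise constraint T2 <= T1 is
re-imposed after every operation.

Images follow the closed-form on-resonance bSSFP steady state
`S = PD sin(a)(1-E1) / (1-(E1-E2)cos(a)-E1E2) exp(-TE/T2)` at TR 3.0 ms,
TE 1.5 ms, flip 60 degrees. Eight surface coils (Gaussian falloff from
positions on a circle around the torso, tangential phase ramps) multiply
a 0.5 mm in-plane phantom; Cartesian k-space is cropped symmetrically
about DC (at index floor(n/2)+1) to the 128 x 128 target — the low-pass
that produces partial voluming — and complex Gaussian noise is added
with the standard deviation calibrated so that mean LV blood-pool
magnitude over image-domain noise SD equals the target SNR of 30.
Reconstruction is inverse DFT and root-sum-of-squares. Off-resonance
banding, transient approach to steady state and undersampling are out of
scope. The per-pixel property *fit* inverts the same closed form by
bounded least squares and deliberately requires at least three
acquisitions: a single bSSFP image cannot identify three parameters.
Moreover, at a fixed short TR the steady-state signal depends on T2/T1
only (to first order in TR over the relaxation times), so varying the
flip angle alone leaves a flat T1 ridge; identifiable protocols must
vary the repetition time substantially, and the tests demonstrate
recovery with TRs spanning 3 to 2000 ms.

## Evaluation layer

Dice overlap (empty-vs-empty defined as 1), displacement error
statistics with optional in-plane projection, region-wise strain
summaries with peaks, and the standard network-evaluation preprocessing
(trilinear resampling to 1.25 mm in-plane and 16 slices, 128 x 128 x 16
crop about the LV centroid, robust 1st/99th percentile normalization).
The package evaluates externally produced masks and motions against its
ground truth; it does not bundle trained networks.

## Problem sizes and determinism

Default sizes were chosen so a full preset simulates in well under a
minute and a slice-frame images in seconds on a laptop core: surface
grids 64 x 64 for simulation (128 x 128 remains the default for
standalone anatomy generation), mechanics mesh 16 x 8 x 3, 10-17 modes,
5 ms mechanics steps with 1 ms circulation sub-steps, 50 output frames,
0.5 mm phantom resolution, 128 x 128 images. All stochastic stages
(population sampling, texture, noise) are seeded; given identical seeds
and BLAS, reruns are bit-identical, and the per-session cache keyed by
preset and solver settings means repeated imaging experiments do not
re-run the mechanics.

## Known limitations

Single ventricle only (no RV/atrial mechanics, no pulmonary loop); 2D
per-slice background warping; no breathing motion; eikonal activation
rather than reaction-diffusion electrophysiology; the synthetic
population spans smooth spheroid-family anatomies, so shape-model
reconstruction errors here (< 2 mm) say nothing about performance on
clinical segmentations with papillary muscles, trabeculation and
acquisition noise; and the radial-strain ceiling discussed above. Passing
the package's tests demonstrates internal consistency of the simulator
and its calibration, not equivalence to any clinical population.
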