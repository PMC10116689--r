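# CardioPhantom

Synthetic short-axis cine cardiac MR with exact functional ground truth.

Evaluating cardiac image analysis — segmentation, motion estimation,
strain mapping — needs images whose truth is known perfectly. Clinical
data never provides that: manual contours are noisy and the true
myocardial motion is unobservable. CardioPhantom simulates the whole
chain instead: a generative left-ventricular (LV) shape model produces
healthy (NOR), dilated (DCM), hypertrophic (HCM) and infarcted
anatomies; a reduced-order biophysical model contracts them for one
cardiac cycle; the moving ventricle is voxelized, embedded in a
procedural torso, given PD/T1/T2 tissue properties, and imaged with a
balanced-SSFP (bSSFP) signal model, surface coils, Cartesian k-space
encoding and noise. Every image comes with bit-exact label masks, dense
displacement fields, strain curves, volumes, mass and ejection fraction,
plus the metrics (Dice, displacement error, strain summaries) to score a
method against them. It is aimed at researchers developing or
benchmarking cardiac MR analysis tools.

## The models in brief

* **Shape**: principal components of pose-normalized endo/epicardial
  coordinate grids with a whitened latent space; z ~ N(0, I) samples
  valid anatomies, k-means on the latents yields the NOR/DCM/HCM preset
  centers.
* **Mechanics**: quasi-static Holzapfel–Ogden passive law
  (four invariant terms, a·(exp(b·x) − 1) type, volumetric penalty
  κ(J−1)²/2), active fiber stress along a ±helix-angle fiber field
  following an eikonal activation map, a pericardial penalty on
  epicardial radial displacement, coupled to a three-element windkessel
  with diode valves. Solved by Galerkin projection on 10-17 analytic
  deformation modes; cavity volume change matches net valve flow to
  < 1% of stroke volume.
* **Imaging**: closed-form on-resonance bSSFP steady state
  S = PD·sinα·(1−E1)/(1−(E1−E2)cosα−E1E2)·exp(−TE/T2), 8 coils,
  central k-space cropping of a 0.5 mm phantom (partial voluming),
  complex noise calibrated to SNR = blood magnitude / image-noise SD.
* **Ground truth**: Green–Lagrange strains of the end-diastolic local
  radial/circumferential/longitudinal directions, masks and displacement
  fields per frame.

See `vignettes/methods.Rmd` for assumptions, parameters and numerical
choices.

## Worked example

```r
library(CardioPhantom)

bm <- runBiomech(presetConfig("NOR"))   # anatomy -> mesh -> one cycle
bm$result
#> SimulationResult: 50 frames, EDV 150.2 ml, ESV 75.2 ml, EF 50.0%, mass 85.2 g

st <- computeStrain(bm$result)
max(colMeans(st@er))                    # peak mean radial strain (Green)
#> [1] 0.468

# full pipeline with images and ground truth written to disk
out <- runPreset(presetConfig("NOR"), outdir = "nor_out")
out$cine
#> CineImage: 128 x 128, 25 frames (TR 3.0 / TE 1.5 ms, flip 60 deg, SNR 30)
```

`runBiomech` simulates filling to an end-diastolic pressure of 10 mmHg
and one 1000 ms cycle; EDV/ESV are cavity volumes at end diastole and
end systole (divergence theorem on the deformed endocardial surface),
EF = 100·(EDV−ESV)/EDV, and mass is wall volume × 1.05 g/ml. The healthy
preset is calibrated to an EF of ~50% at ~150 ml EDV and ~85 g mass;
`nor_out/` contains the cine NIfTI, LV masks, strain curves (CSV),
hemodynamic traces and a JSON manifest of every parameter and seed.

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/cardiophantom", package="CardioPhantom"))') \
    run --preset INFARCT --outdir infarct_out --seed 7
```

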