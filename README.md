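# HistoMRIfuse

Co-registration of whole-mount histopathology with in vivo multiparametric
MRI (mpMRI) for soft-tissue sarcoma specimens.

Validating quantitative MRI biomarkers (DWI/ADC, IVIM, DCE pharmacokinetics)
against histology requires knowing *which* MRI voxels correspond to *which*
part of a stained section. For large, irregular soft-tissue specimens this is
solved by a two-step ex vivo bridge: the resected specimen is embedded in an
agarose block, scanned ex vivo, rigidly aligned to the in vivo scan, the
block is trimmed on an angle plate so its faces match the in vivo axial
planes, and a second ex vivo scan on a 4 mm localizer grid pins each
microtomy section to its MRI slice. The final histology-to-MRI mapping is a
2D nonrigid (thin-plate-spline) warp driven by paired anatomical landmarks.

`HistoMRIfuse` implements this workflow end to end for R, together with the
statistical machinery used to evaluate it and a synthetic specimen phantom
with known ground truth for every stage. It is aimed at imaging scientists
building MRI-histology validation pipelines.

## What is implemented

- **Rigid ex vivo → in vivo alignment** — closed-form least-squares
  (Kabsch/SVD) rotation + translation from paired 3D landmarks, no scaling,
  reflection-corrected (`estimateRigid`, `applyRigid`, `composeRigid`).
- **Cutting-angle derivation** — virtual back-rotation of the sectioning
  normal (Rodrigues' formula) into angle-plate settings: elevation,
  azimuth, and residual in-plane angle
  (`computePlateAngles`, `plateRotation`, `rodriguesRotate`); 4 mm slice
  planning and section-to-slice matching (`planSlices`,
  `matchSectionToSlice`).
- **Elastic registration** — 2D thin-plate spline with kernel
  U(r) = r² log r, exact landmark interpolation at λ = 0, affine
  reproduction, bending-energy regularization, and inverse-mapped image
  resampling (`fitTPS`, `warpPoints`, `warpImage`).
- **Accuracy protocol** — repeated random 50/50 landmark splits (default
  100 iterations): fit the warp on one half, measure Euclidean target
  registration error (TRE) on the held-out half, pool distances; median/IQR
  summaries, TRE per tumor volume, Kruskal–Wallis and Bonferroni-corrected
  Wilcoxon group comparisons (`runTREProtocol`, `summarizeTRE`,
  `trePerVolume`, `compareTREGroups`).
- **Habitat clustering** — voxel-wise k-means (k-means++ seeding, best of
  10 restarts) of the 8 z-scored parametric channels (ADC, D*, f, fD*,
  Ktrans, kep, ve, vp/iAUC) inside the tumor ROI, label back-mapping onto
  anatomy, per-region statistics, one-way ANOVA with Holm-adjusted pairwise
  t-tests (`clusterHabitats`, `regionStats`, `compareRegions`).
- **Phantom generator** — in vivo tumor volume, rigidly re-oriented ex vivo
  copy, deformed histology sections with noisy paired landmarks, and
  4-habitat parametric map stacks, all pure functions of a seed
  (`makeInvivoPhantom`, `makeExvivoPhantom`, `makeSectionPhantom`,
  `makeMapStack`).

File formats: NIfTI volumes (RNifti), TIFF/PNG sections, CSV landmark
tables, JSON rigid transforms (4×4 homogeneous matrix), TSV result tables.
A command-line front end (`exec/histomrifuse`, or `runCLI()` from R) chains
the steps: `simulate`, `register-rigid`, `plan-angles`, `register-elastic`,
`evaluate-tre`, `cluster`, `report`.

## Worked example

```r
library(HistoMRIfuse)

## synthetic specimen with known ground truth
inv <- makeInvivoPhantom(seed = 42)            # in vivo volume + ROI + landmarks
exv <- makeExvivoPhantom(inv, seed = 43)       # random rigid re-orientation

## 1. rigid alignment from the (noiseless) landmark pairs
fit <- estimateRigid(PairedLandmarks(inv$landmarks, exv$landmarks))
fit
#> RigidFitReport: 35 landmarks, rms residual 1.219e-14 mm
#> RigidTransform: rotation 20.373 deg, translation (11.651, -1.611, -6.152) mm

## 2. angle-plate settings that restore the in vivo orientation
computePlateAngles(fit@transform)
#> PlateAngles: elevation 19.4584 deg, azimuth 1.6677 deg, in-plane 6.0649 deg

## 3. deformed "histology" section with 1 mm landmark noise, TRE protocol
sl  <- extractSlice(inv$volume, 20)
sec <- makeSectionPhantom(sl$data, sl$pixelSize, amplitudeMm = 3,
                          noiseSigmaMm = 1, seed = 44)
res <- runTREProtocol(sec$pairs, nIter = 100, seed = 45)
summarizeTRE(res)
#>   median_mm   iqr_mm  mean_mm    sd_mm    n
#> 1  2.504614 1.799018 2.694732 1.409871 1700

## 4. habitat clustering of the 8-channel parametric map phantom
ms <- makeMapStack(inv$roi, seed = 46)
cr <- clusterHabitats(ms$stack, k = 4, seed = 47)
head(regionStats(ms$stack, cr), 4)
#>   region channel        mean         sd n_voxels flagged        unit
#> 1      A     ADC 2127.115538 262.332412     1825   FALSE 1e-3 mm^2/s
#> 2      A   Dstar   35.054343   2.804446     1825   FALSE 1e-3 mm^2/s
#> 3      A       f    4.714104   1.502424     1825   FALSE           %
#> 4      A  fDstar    1.355878   0.474844     1825   FALSE 1e-3 mm^2/s
```

The TRE summary reads as in a real study: with 1 mm annotation noise on
30–40 landmarks the pooled median TRE is ~2.5 mm — landmark noise enters
both the fitted warp and the held-out comparison, so the median tracks
σ·√(2 ln 4) ≈ 1.67·σ. The region table gives native-unit mean ± SD per
recovered habitat, one row per channel.

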