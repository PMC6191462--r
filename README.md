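# qvtools — quantitative vessel tortuosity of nodule-associated vasculature

Benign granulomas and malignant adenocarcinomas are frequent radiographic
mimics on chest CT, yet the vasculature feeding a malignant nodule tends to
be more tortuous and convoluted than that of a benign one. `qvtools`
quantifies that difference. It takes a Hounsfield-unit CT volume and a
nodule mask, isolates the lung fields, grows the nodule-associated
vasculature by seeded region growing, extracts sub-voxel vessel centerlines
with a fast-marching backtracking scheme, and summarizes the vessel
geometry in a 35-element quantitative vessel tortuosity (QVT) descriptor
used for feature selection, test–retest stability analysis, supervised
classification and unsupervised clustering.

The package is aimed at quantitative-imaging researchers who want a fully
inspectable, seedable implementation of this pipeline, together with a
synthetic vascular phantom generator that makes every stage testable
against analytic ground truth — no patient data required.

## The descriptor

For every vessel branch (an ordered centerline polyline between endpoints
or bifurcations):

* **torsion** — the chord-to-arc ratio `|p_end − p_start| / L`, 1 for a
  straight branch, approaching 0 for a convoluted one;
* **curvature** — at each interior centerline point, the Menger curvature
  `κ = 4·Area(p₁,p₂,p₃) / (|p₁p₂|·|p₂p₃|·|p₁p₃|)`, the inverse radius of
  the osculating circle through the point and its two neighbours (mm⁻¹).

The 35-vector collects first-order statistics (mean, sd, min, max, median)
of branch torsion, of per-branch mean curvature and per-branch maximum
curvature; branch and bifurcation counts; vasculature volume inside the
volume of interest (VOI), its ratio to the VOI volume and to the tight
bounding box; and normalized histograms of point curvature (8 bins) and
windowed point torsion (7 bins). See `qvt_feature_names()` and the
methods vignette (`vignettes/quantifying-vessel-tortuosity.Rmd`).

Downstream analysis mirrors the full study design: minimum-redundancy
maximum-relevance (mRMR) selection of the top 12 features, ICC(2,1)
test–retest stability, 3-fold cross-validated SVM/KNN/naive-Bayes
classification with rank AUC, k-means with a chi-squared association test,
and co-occurrence consensus clustering.

## Worked example

A self-contained phantom study — 20 synthetic cases, the adeno-like class
with markedly more tortuous vasculature than the granuloma-like class:

```r
library(qvtools)

coh <- make_cohort(10, seed = 42)          # 10 cases per class
rep <- run_study(coh, default_config(seed = 42))
print(rep)
#> <study_report>
#>   cases: 20   selected features: 12
#>   CV AUC: 0.963 +/- 0.064
#>   consensus purity: 1.000
#>   cluster/label chi2 p-value: 7.74e-06
```

The planted class effect is strong, so the cross-validated AUC (with
feature and hyperparameter selection nested inside the folds) is 0.96 and
the two consensus clusters coincide with the class labels (purity 1.0,
chi-squared p ≈ 8·10⁻⁶). A single case can be dissected stage by stage:

```r
cs  <- coh$cases[[1]]
res <- case_features(cs$volume, cs$nodule_mask, default_config(seed = 42))
res$tree
#> <vessel_tree> 5 branches, 2 bifurcations, total length 44.03 mm
round(res$features[c("qvt_torsion_mean", "qvt_curvMean_mean",
                     "qvt_nBranches", "qvt_vesselVolume", "qvt_volVoiRatio")], 4)
#>  qvt_torsion_mean qvt_curvMean_mean     qvt_nBranches  qvt_vesselVolume
#>            0.8067            0.4110            5.0000          251.3750
#>   qvt_volVoiRatio
#>            0.0186
```

This adeno-like case has mean branch torsion 0.81 (wiggly, well below the
straight-vessel value of 1) with 251 mm³ of vasculature filling 1.9% of
the VOI. Real data enter through `read_volume()` (NIfTI or a DICOM series
directory) and `run_case()`; `inst/cli/qvt.R` exposes the same steps as
shell subcommands (`segment`, `skeleton`, `features`, `phantom`, `study`).

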