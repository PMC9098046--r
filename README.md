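# dect — differential Euler characteristic transforms for protein ensembles

`dect` detects and localizes structural differences between two ensembles
of protein conformations — for example wild-type versus mutant
molecular-dynamics frames — **without atom-by-atom correspondence**.
Coordinate-based comparisons (RMSF differences, PCA, penalized linear
classifiers) need every atom paired across the two ensembles and are blind
to whole categories of change; `dect` instead compares the ensembles
through the topology of their shapes.

It is aimed at structural bioinformaticians and computational biophysicists
who have two sets of frames (multi-model PDB or XYZ) and want a per-atom /
per-residue map of where the ensembles differ, with a permutation-style
significance test for candidate regions.

## The method

1. **Mesh.** Each frame's atoms become vertices of a simplicial complex:
   edges join atoms closer than a cutoff `r`, triangles fill mutually
   connected triples. All meshes are normalized to the unit ball on one
   dataset-wide scale.
2. **Transform.** For directions `ν` grouped into `c` cones of `d`
   directions (cap radius `θ`), the sublevel filtration by atom height
   `h_ν(x) = xᵀν` over `l` thresholds yields Euler characteristic curves
   `χ_k = V_k − E_k + F_k`; their lag-`t` differences (the *differential*
   EC) over all directions give each frame a feature vector of length
   `J = c·d·l`.
3. **Classifier.** A Gaussian process probit model
   `y ~ Bernoulli(Φ(f))`, `f ~ N(0, K)` with RBF kernel
   `K_ii' = exp(−ϑ‖x_i−x_i'‖²)` (median-criterion bandwidth) is sampled by
   elliptical slice sampling.
4. **Attribution.** Latent draws are projected to effect sizes
   `β = X⁺f`; each feature gets the Kullback–Leibler divergence between
   the posterior of the remaining effects and the same posterior with that
   effect zeroed (in the working approximation `KLD_j ≈ α_j μ_j²/2`),
   normalized to `γ` on the simplex.
5. **Evidence.** Each atom's evidence is the minimum of its `m = c·d`
   associated `γ` values (closed form of the threshold-sweep
   reconstruction), averaged over frames and rank-scaled 0–100 per atom
   and per residue; a KNN null-region test converts region scores into
   P-values and calibrated Bayes factors `BF(P) = [−eP ln P]⁻¹`.

A controlled benchmark generator (globular self-avoiding chains + spatially
correlated thermal noise + constant or spherical ROI perturbations) and
three reference baselines (RMSF difference, PCA, elastic net) are included,
scored by ROC/AUC with the cone-wise detection rule.

## Worked example

```r
library(dect)

## two synthetic ensembles around one fold; class B has a perturbed loop
base <- synth_chain(120, seed = 7)
roi  <- compact_roi_window(base, width = 20)
fa   <- synth_ensemble(40, base = base, thermal_sigma = 0.4, seed = 1)
fb   <- perturb_roi(
  synth_ensemble(40, base = base, thermal_sigma = 0.4, seed = 2,
                 class_label = 1L),
  perturbation_spec("spherical", magnitude = 2, roi = roi, seed = 3))

fit <- dect(fa, fb, c = 6, d = 4, l = 40, n_iter = 4000, seed = 11)
fit
#> Topological ensemble comparison (differential EC transform)
#>   frames: 40 class A + 40 class B, 120 atoms each (class A)
#>   transform: r=7.64 A, c=6 cones x d=4 dirs, theta=0.80, l=40
#>   GP bandwidth (median criterion): 3.067e-06; 200 posterior draws
#>   top residues by evidence:  76, 13, 77, 79, 117

range(roi$atoms)
#> [1] 71 90

nt <- roi_null_test(fit$representative, fit$evidence$gamma_hat, roi,
                    n_regions = 500, seed = 12)
c(p = nt$p, bf = nt$bf)
#>    p   bf
#>    0  Inf
```

The fitted object prints the transform settings and the residues with the
highest evidence scores — three of the five top residues (76, 77, 79)
fall inside the perturbed window (atoms 71–90; each chain atom is one
residue here). Individual atom ranks are noisy at this small scale, but
the region-level test is unambiguous: the null-region test returns the
smallest representable P-value (`0` at granularity `1/(T+1)`), i.e. none
of the 500 random 20-atom regions outscored the perturbed one. `coef(fit)` returns the per-feature `γ`,
`fit$evidence` the atom/residue scores, `plot(fit)` the residue profile,
and `export_scored_pdb()` writes a structure with evidence in the B-factor
column for molecular viewers.

For file-based runs, `run_pipeline(pipeline_config(paths_a, paths_b, ...))`
reads PDB/XYZ frames, fits, and writes score CSVs, a scored PDB, and a JSON
manifest; `inst/scripts/run_pipeline.R` wraps it for the shell.

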