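# topoinfo

Tools for comparing two formalisms of *higher-order interaction* — beyond
pairwise dependence — in multivariate data: multivariate information theory
and topological data analysis. The package is aimed at researchers in
systems/network neuroscience and complex systems who want to ask, on point
clouds and multivariate time series, whether statistical synergy and
redundancy line up with topological features such as enclosed cavities.

## What it implements

**Information measures (nats), estimated nonparametrically.** For a
3-dimensional point cloud `X = (X1, X2, X3)`:

- total correlation `TC = Σ H(Xi) − H(X)` (deviation from independence),
- dual total correlation `DTC = H(X) − Σ H(Xi | X−i)` (shared information),
- O-information `O = TC − DTC` (`O > 0`: redundancy-dominated; `O < 0`:
  synergy-dominated),
- S-information `S = TC + DTC` and the normalized ratio `O/S ∈ [−1, 1]`.

All are entropy combinations, so they are estimated with a *single* k-th
nearest-neighbor search in the joint space (Chebyshev metric) plus digamma
range counts in the marginals — the Kraskov–Stögbauer–Grassberger scheme
generalized to entropy combinations. Closed-form Gaussian oracles validate
the estimators in the test suite.

**Topology.** Vietoris–Rips persistent homology over Z/2 on Chebyshev
distance matrices up to dimension 2 (boundary-matrix reduction with
clearing, truncated at the enclosing radius), with void-count and
persistence summaries of dimension-2 features ("3D cavities").

**Generators and screening.**

- `generate_shape()`: benchmark clouds with known topology — line, embedded
  plane, sphere, ball, hollow/filled torus, (p,q) torus knots — plus
  fixed-axis rotations and PCA rotation (`pca_rotate()`, a pure rotation).
- `generate_bold()`: synthetic multi-scan, autocorrelated (AR(1)) parcel
  time series with planted redundant (shared source) and synergistic
  (collider) triads.
- `screen_triads()`: the circular-shift significance screen — every triad's
  O-information tested against a pooled null built by rolling each channel
  into a different scan (autocorrelation preserved, cross-dependence
  destroyed), flagged at 3 SD.
- `compute_triad_features()` / `correlate_features()` / `ks_compare()`: join
  information, topology and PC1-compressibility per triad and rank-correlate
  them by significance class.

## Worked example

```r
library(topoinfo)

# A hollow sphere: synergy from an enclosed cavity, immune to rotation
sphere <- generate_shape("sphere", n = 10000, seed = 1)
set.seed(1)
estimate_all(sphere)
#> Higher-order information (k = 4, n = 10000, chebyshev metric)
#>   TC  =   2.5527 nat
#>   DTC =   3.9360 nat
#>   O   =  -1.3833 nat
#>   S   =   6.4887 nat
#>   O/S =  -0.2132

set.seed(2)
estimate_o_information(pca_rotate(sphere)$rotated)
#> [1] -1.375275

# The same cavity, seen topologically: a dominant dimension-2 void
sub <- subsample_rows(sphere, 150, seed = 3)
tda_summary(vr_diagram(chebyshev_distances(sub)))
#> $n_voids
#> [1] 2
#> $avg_persistence
#> [1] 0.2551827
#> $max_persistence
#> [1] 0.4702134
```

The sphere is strongly synergy-dominated (`O ≈ −1.38` nat) and — because a
sphere is rotationally symmetric — PCA rotation leaves that unchanged,
unlike a line or plane whose higher-order information is purely an artifact
of orientation and collapses to ~0 after PCA. The persistence summary finds
one long-lived dimension-2 bar (the cavity) plus one much shorter-lived
sampling artifact.

The two synthetic studies live under `analysis/` as numbered scripts:

```sh
Rscript analysis/01_shape_suite.R      # benchmark shapes, O before/after PCA
Rscript analysis/02_simulate_bold.R    # 30 parcels x 4 scans x 1100 frames
Rscript analysis/03_triad_screen.R     # all 4,060 triads vs circular-shift null
Rscript analysis/04_triad_features.R   # information vs topology correlations
```

Each writes its tables under `results/`. The methods vignette
(`vignettes/higher-order-topology.Rmd`) documents the estimator conventions,
the persistence algorithm, the generator's design choices and its
limitations.

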