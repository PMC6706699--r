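# ccptools

Quantitative analysis of clathrin-coated pit (CCP) dynamics from TIRF
microscopy, and of the binding biophysics of CCP regulators such as the
phospho-AP2 adaptor readers of the NECAP family.

Clathrin-mediated endocytosis proceeds through diffraction-limited coated
pits whose composition and fate are read out by multi-channel fluorescence
imaging: a *master* channel (typically clathrin light chain) defines where
pits are, and *slave* channels (AP2, phospho-AP2, NECAP, SNX9, cargo) are
quantified dependently at those positions. `ccptools` implements that whole
analysis chain as composable, pipe-friendly functions returning tibbles,
plus the binding-curve fits used to characterize the underlying
protein-protein interactions. Because real live-cell datasets of this kind
are rarely deposited, the package ships a first-class synthetic-data module
that generates movies, stills, track tables and titrations with complete
ground truth, so every stage is validated by parameter recovery.

## What it computes

**Spot detection** — candidate positions from a difference-of-Gaussians
band-pass, then least-squares fits of an isotropic 2D Gaussian PSF
`A·exp(−((x−x₀)² + (y−y₀)²)/(2σ²)) + c` per spot. The amplitude is tested
one-sided against the residual background noise at the location
(H₀: `A = k·σ_res`, `k = Φ⁻¹(1−α)`), with the statistic `(A − k·σ_res)/se(A)`
referred to a t distribution. Slave channels are fitted at master positions
with the fit position constrained within a search radius, giving a total,
order-preserving master/slave pairing.

**Normalization** — per-cell intensity distributions are expressed as
quantile tables; the reference is the across-cell median quantile table and
each cell gets the scale `s = ΣQ_ref·Q_cell / ΣQ_cell²` minimizing the MSE
to the reference.

**Colocalization** — Pearson correlation of paired master/slave intensities
and the proportion-versus-intensity curve: equal-count master-intensity
bins, per-bin proportion of detections with significant slave signal.
Condition pairs are compared with two-tailed unpaired Welch t-tests.

**Track statistics** — greedy mutual-nearest-neighbour linking with gap
closing; classification into *persistent* structures (present in every
frame of the acquisition), *bona fide* CCPs (trajectory intensity
thresholding) and *transient* assemblies; lifetime distributions with the
mean-of-top-5% ("95th percentile") statistic; persistent-structure density
per µm²; slave-positive subcategorization (≥30% of frames significant);
cohort-averaged intensity traces (mean ± SE on a common resampled axis);
and recruitment timing: Gaussian smoothing (SD 1.2 samples), sub-sample
peak localization by cubic interpolation, and maximum recruitment rate from
central differences.

**Binding fits** — single-site fluorescence anisotropy
`F = F_f + (F_b − F_f)·[L]/(K_d + [L])`; SPR biexponential dissociation
`R(t) = A_f·e^(−k_f t) + A_s·e^(−k_s t)` with a 1:1 amplitude isotherm
`A(C) = A_max·C/(K_D + C)`; an independent single-site ITC model with exact
per-injection mass balance and volume-displacement correction; and NMR
chemical-shift perturbations `Δδ = √(Δδ(¹H)² + (Δδ(¹⁵N)/5)²)`. Fit objects
support broom-style `tidy()`/`glance()` and `autoplot()`.

## Worked example

```r
library(ccptools)
library(dplyr)

# Simulate a dual-channel acquisition: 10 min at 0.5 frames/s, with 65%
# of CCPs carrying slave signal, then recover that fraction blind.
sim <- simulate_tracks(2000, slave_positive_fraction = 0.65, seed = 42)
tr  <- flag_slave_frames(sim$tracks, alpha = 0.05, noise_sd = 10)
cl  <- classify_tracks(rename(tr, amplitude = master),
                       n_frames = .Machine$integer.max,
                       frame_interval = 2, intensity_threshold = 50)
bona <- cl$track_id[cl$category == "bona_fide"]
pos  <- slave_positivity(filter(tr, track_id %in% bona))
100 * mean(pos$slave_positive)
#> [1] 63.78018
table(cl$category)
#> bona_fide transient
#>      1201       799
```

The recovered 63.8% sits within the binomial confidence interval of the
planted 65% (n = 1201 bona fide tracks); the lifetime mixture splits into
bona fide CCPs and short transient assemblies as planted. A full
image-based run (`run_movie_analysis()`) adds detection, linking,
persistent-structure density and cohort traces, e.g.:

```r
rep <- run_movie_analysis(list(
  seed = 5,
  conditions = list(
    list(name = "control", n_movies = 2,
         movie_spec = list(width = 96, height = 96, n_frames = 50,
                           persistent_count = 3, nucleation_rate = 0.4)),
    list(name = "treated", n_movies = 2,
         movie_spec = list(width = 96, height = 96, n_frames = 50,
                           persistent_count = 12, nucleation_rate = 0.4)))))
rep$per_cell |> select(cell_id, n_bona_fide, n_persistent,
                       persistent_density_um2, slave_positive_pct)
#> # A tibble: 4 × 5
#>   cell_id        n_bona_fide n_persistent persistent_density_um2 slave_positive_pct
#>   <chr>                <int>        <int>                  <dbl>              <dbl>
#> 1 control_cell01          16            3                 0.0782               68.8
#> 2 control_cell02          19            3                 0.0782               63.2
#> 3 treated_cell01          13           12                 0.313                46.2
#> 4 treated_cell02          15           12                 0.313                66.7
```

Binding data fit the same way:

```r
d <- simulate_titration("itc", list(K_D = 55e-6, n = 1, dH = -8),
                        design = list(cell_conc = 0.125e-3,
                                      syringe_conc = 2.5e-3))
fit <- fit_itc(d$heat_ucal, cell_conc = 0.125e-3, syringe_conc = 2.5e-3)
tidy(fit)
#> # A tibble: 3 × 3
#>   term   estimate std.error
#>   <chr>     <dbl>     <dbl>
#> 1 K_D   0.0000550  3.47e-19
#> 2 n     1.00       2.81e-15
#> 3 dH   -8.00       2.88e-14
```

## Command line

A thin CLI over the same functions lives at `inst/cli/ccptools.R`
(`simulate`, `coloc`, `fit`, `run-all`; each takes `--config <yaml>`,
`--out <dir>`, `--seed <int>`).
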