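# kkscascade

Progress-curve analysis of a minimal reconstituted kallikrein–kinin
system (KKS): activated Factor XII (FXIIa) converts prekallikrein (PK)
into plasma kallikrein (PKa), which cleaves native high-molecular-weight
kininogen (nHK) into cleaved kininogen (cHK), releasing bradykinin. The
package is written for enzymologists and systems biologists who want to
fit complete cleavage progress curves of this two-step proteolytic
cascade — measured on ice at high enzyme/substrate ratio with natural
protein substrates — rather than only initial velocities.

## The model

The cascade core is a pair of coupled Michaelis–Menten rate laws,

    d[PK]/dt  = −d[PKa]/dt = −kcat1 [F12a][PK] / ([PK] + KM1)
    d[nHK]/dt = −d[cHK]/dt = −kcat2 [PKa][nHK] / ([nHK] + KM2)

with FXIIa acting catalytically. Around this core the package models the
two systematic deviations seen in such progress curves:

* a **faster initial rate**, via a presteady-state initial burst —
  `[PKa](0) = inib·[F12a]₀` and `[cHK](0) = [cHK]₀ + inib2·inib·[F12a]₀`
  — and/or a stopping delay `Δt` (a sample nominally taken at time *t*
  keeps reacting for `Δt` seconds before the SDS stop buffer acts);
* a **slower late rate**, via product inhibition by cHK — competitive
  against FXIIa (apparent `KM1·(1+[cHK]/KI1)`) and uncompetitive
  against PKa (`kcat2` and `KM2` both divided by `1+[cHK]/KI2`) — or,
  alternatively, a zero-order FXIIa decay.

Trajectories are integrated with `lsoda` (36000 steps over 30 min by
default, compiled right-hand side). Model variants are scored against
assay collections by the sum of squared distances (SSD) between
predicted and observed cleavage fractions; free parameters are
optimised by deterministic cyclic coordinate descent that stops when
every free parameter is stable to two significant digits. Parameter
dispersion comes from bootstrap Monte Carlo over assays. Single-enzyme
constants (`kcat`, `KM`) are estimated from (S, v) velocity points by
Hanes–Woolf linearisation refined by nonlinear least squares, with the
gel and chromogenic-plate processing and QC rules built in.

## Worked example

```r
library(kkscascade)

# 32 synthetic assays at the documented concentration designs
# (ratio triples 1/6/6, 1/6/3, 0.5/1/12 of a 30 nM unit), 5% noise
assays <- generate_progress_assays(n_assays = 32,
                                   noise = noise_spec(0.05, seed = 1))

fit <- kks_fit(assays, variant = "chki_inib")
fit
#> Cascade fit ('chki_inib' variant): SSD = 0.2938 over 32 assays (448 observations)
#>   fitted (4 cycles): inib = 0.3186, KI1 = 256.7, KI2 = 12.39

cmp <- kks_compare(assays, variants = c("mm", "chki_inib"))
cmp
#> Cascade model comparison (ascending SSD):
#>     variant n_free    ssd iterations error
#> 1 chki_inib      3 0.2938          4  <NA>
#> 2        mm      0 8.2161          0  <NA>

bs <- kks_bootstrap(assays, template = fit, n_replicates = 100, seed = 2)
bs
#> Bootstrap Monte Carlo: 100 replicates (seed 2, 0 failed)
#>  parameter  median    p2.5   p97.5
#>       inib   0.319   0.311   0.328
#>        KI1 256.000 232.000 284.000
#>        KI2  12.400  11.800  13.000
#>        ssd   0.290   0.232   0.338
```

The fitted burst coefficient (`inib ≈ 0.32`) says that roughly a third
of the FXIIa pool activates one PK equivalent essentially instantly at
mixing; the inhibition constants say cHK binds the PKa reaction
(`KI2 ≈ 12 nM`) far more tightly than the FXIIa reaction
(`KI1 ≈ 260 nM`); the burst+inhibition model reduces the SSD roughly
28-fold relative to the plain Michaelis–Menten simulation on these
synthetic data. Single-enzyme estimation works the same way from
velocity points:

```r
pts <- generate_velocity_points(0.133, 672, enzyme = 1,
                                substrates = 112 * (1:5))
nonlinear_mm_fit(pts)
#> Michaelis-Menten fit (nonlinear, n = 5): kcat = 0.133 /s, KM = 672 nM
#>   Vmax = 0.133, enzyme = 1 nM, residual SS = 1.083e-34
```

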