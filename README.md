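# saxsdlvo

Colloidal interaction parameters from small-angle X-ray scattering
(SAXS) curves, for soft-matter and nanoparticle scientists who want to
fit structure factors outside the validity envelope of analytic models
such as the Hayter–Penfold RMSA.

For a suspension of monodisperse spheres, `I(q) = P(q) · S(q)`: the
sphere form factor `P(q)` is known, and the structure factor `S(q)`
encodes the pair interactions. Interactions follow DLVO theory — a
Hamaker van der Waals attraction plus a screened-Coulomb repulsion,

```
βU(d) = −H_A/(6 kBT) · [ 2r²/(d²−4r²) + 2r²/d² + ln(1 − 4r²/d²) ]
        + Z_eff² · L_B · (e^{κr}/(1+κr))² · e^{−κd}/d ,
```

parameterized by the effective macroion valency `Z_eff` and the Debye
length `κ⁻¹`. The package

1. **simulates** labelled SAXS curves by Metropolis Monte Carlo of DLVO
   spheres in a periodic box (radial distribution function → `S(q)` →
   `I(q)` on the 225-point grid 0.012–0.501 Å⁻¹),
2. **learns** the curve → `(Z_eff, κ⁻¹)` map with a dense forward
   network (8 hidden layers halving from 512), and the inverse
   parameters → curve map with a surrogate network (128, 512, 512, 512),
3. **infers** parameters for a measured curve by affine-invariant
   ensemble MCMC with a χ² likelihood evaluated through the surrogate,
   returning MAP estimates, credible intervals and the
   `Z_eff`–`κ⁻¹` correlation.

## Worked example

Simulate a suspension, train models on a small corpus, and invert a
noisy synthetic measurement (about ten minutes at these sizes):

```r
library(saxsdlvo)

## a labelled corpus at the reduced desk scale (200 particles/curve)
ds  <- build_dataset(200, desk_sim_config(), seed = 101)

## forward model at the optimized q cutoff
fm  <- train_forward_model(apply_q_cutoff(ds, 0.0677),
                           config = training_config(seed = 5,
                                                    early_stop_patience = 40))

## surrogate for the MCMC loop (model error calibrated on the val split)
noise <- estimate_mc_noise(dlvo_params(40, 5), desk_sim_config(seed = 880))
sm  <- train_surrogate_model(ds, mc_noise = noise,
                             config = training_config(seed = 7,
                                                      early_stop_patience = 40))

## a pseudo-measurement at known truth (35, 5 nm) with 2% noise
cfg   <- desk_sim_config(post_equil_steps = 3e5, n_snapshots = 3000,
                         seed = 2024)
clean <- generate_curve(dlvo_params(35, 5), cfg)
set.seed(2025)
data  <- saxs_curve(clean$q,
                    clean$intensity * (1 + 0.02 * rnorm(225)),
                    sigma = 0.02 * clean$intensity)

fit <- fit_saxs_dlvo(data, sm,
                     config = mcmc_config(n_walkers = 16, n_steps = 2500,
                                          seed = 314))
fit
#> DLVO parameter fit to a SAXS curve (surrogate + ensemble MCMC)
#> MAP estimate
#>   Z_eff    = 30.24  [95%: 26.43, 35.91]
#>   kappa^-1 = 5.641 nm  [95%: 4.951, 6.339]
#>   Z_eff/kappa^-1 correlation: -0.924
coef(fit)
plot(fit)        # marginal histograms, joint density, data/model overlay
```

The MAP lands within about 15% of the generating truth and the truth
sits inside both 95% intervals; the strong negative correlation is the
expected trade-off — raising either parameter strengthens the
interparticle repulsion, so the curve constrains a combination of the
two more tightly than either alone. On held-out test curves the forward
model reaches `r² ≈ 0.94` (`Z_eff`) and `0.92` (`κ⁻¹`) at a 350-curve
corpus, with over 90% of predictions within ±20%.

A thin command-line front end wraps the same functions
(`inst/cli/saxsdlvo`): `simulate`, `build-dataset`, `train-forward`,
`train-surrogate`, `select-qcutoff`, `predict`, `mcmc-fit`,
`make-fixtures`.

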