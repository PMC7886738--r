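# boundedwalk

Movement data are usually recorded inside a bounded arena — a cage, a
Petri dish, a home range — and the boundary biases every step statistic
in a geometry-specific way: steps that would leave the enclosure are
never observed, so the empirical step distribution is shortened and
reshaped even when the animal's intrinsic movement is a plain random
walk. Comparing field or laboratory histograms against the unbounded
step law therefore invites false conclusions (for instance, apparent
behavioural shortening of steps that is purely geometric).

`boundedwalk` implements the null model behind this effect and the
correction it licenses. An organism moving intermittently is reduced to
its stopping locations; the displacements between stops follow an
intrinsic density `f_i` (symmetric in 1D, rotationally symmetric in 2D),
confined to a bounded convex domain by one of three boundary conditions
(no-go, stop-go, reflecting). For **no-go** boundaries — steps ending
outside are simply redrawn — the observed ("transformed") step density
factorises,

```
f_t(l)  ∝  f_i(l) · h(l),        h(l) = measure( Ω ∩ (Ω − l) ),
```

where the *shaper function* `h` is the set covariance of the domain `Ω`:
the overlap measure between the domain and its translate by the step.
It equals the domain measure at `l = 0`, decreases monotonically along
every ray, and vanishes at the domain diameter. Since `h` depends only
on the known geometry, the intrinsic law can be reconstructed from the
observed histogram by bin-wise division, `f_i ∝ f_t / h`, up to the
diameter cutoff beyond which all information is lost.

The package provides:

* intrinsic step laws (parabolic, Gaussian, uniform, user-tabulated)
  with seeded samplers (`step_dist_1d()`, `step_dist_2d()`);
* bounded convex domains — interval, convex polygon, disk — with exact
  convex clipping, sampling, and the 1D reflection fold
  (`interval_domain()`, `polygon_domain()`, `disk_domain()`);
* shaper functions in closed form (interval, rectangle, disk) and by
  exact polygon clipping, plus the angle-averaged magnitude form
  (`shaper_function()`, `magnitude_shaper()`);
* ensemble simulation of stopping-location sequences under all three
  boundary conditions (`simulate_walk()`);
* steady-state stopping densities and a Nyström/power-iteration solver
  for the stationary Fredholm equation that independently verifies the
  no-go ansatz `g ∝ N` (`stopping_density_nogo()`,
  `fredholm_stationary()`), and analytic transformed step densities for
  all three boundary conditions (`transformed_pdf_*()`);
* histogram estimation with ensemble envelopes and the shaper inversion
  (`estimate_density()`, `reconstruct_intrinsic()`);
* a YAML/JSON-configured pipeline (`run_pipeline()`) and a thin CLI
  wrapper at `inst/cli/boundedwalk.R`.

## Worked example

Simulate the reference setup — unit square, parabolic intrinsic kernel
`f_i(l) = 3(a² − l²)₊ / (4a³)` with half-support `a = 0.75`, no-go
boundaries — then reconstruct the intrinsic magnitude density from the
biased observations:

```r
library(boundedwalk)

dom  <- square_domain()                          # unit square
kern <- step_dist_2d("parabolic", a = 0.75)
ens  <- simulate_walk(dom, kern, "no_go",
                      n_steps = 1e4, n_runs = 50, burn_in = 100, seed = 1)

mags <- step_magnitudes(ens)
dist_mean_square(kern)   # 0.1875  intrinsic mean-square step
mean(mags^2)             # 0.148   observed: confinement shortens steps

sh  <- shaper_function(dom)
est <- estimate_density(mags, default_bins(dom))
rec <- reconstruct_intrinsic(est, sh, shaper_floor = 0.01,
                             renormalise = TRUE)
rec
#> Intrinsic-step reconstruction: 60 bins, 12 excluded (floor 0.01 of h(0)), renormalised
head(as.data.frame(rec)[c(6, 12, 18, 24, 30), ])
#>    bin_center ft_mean shaper fi_mean  fi_sd
#> 6      0.1296  1.3642 5.2797  0.8936 0.0577
#> 12     0.2711  2.0948 4.2617  1.7000 0.0754
#> 18     0.4125  1.9684 3.3236  2.0483 0.1071
#> 24     0.5539  1.2721 2.4656  1.7844 0.0964
#> 30     0.6953  0.3452 1.6876  0.7075 0.0679
```

The observed mean-square step (0.148) is strictly below the intrinsic
one (0.1875): the boundary alone shortens steps. Each row divides the
observed magnitude density `ft_mean` by the angle-averaged shaper at the
bin centre, recovering the intrinsic magnitude density `fi_mean` (here
within 0.03 of the known truth on every retained bin) with the ensemble
envelope `fi_sd` scaled identically; the 12 bins nearest the diameter
`√2` are excluded because the shaper there is too small to invert
reliably. The same workflow runs from a config file:

```sh
Rscript inst/cli/boundedwalk.R demo --config inst/extdata/demo_config.yaml --out results/
```

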