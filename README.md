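# drgsd

Planning and evaluation of **two-stage group-sequential trial designs with
delayed (pipeline) responses**, for trial statisticians weighing whether the
extra machinery of delayed-response methods buys anything over a standard
group-sequential plan.

When a continuous endpoint is measured only some lag after enrolment, a
fraction of recruited patients is still "in the pipeline" at the interim
analysis.  Standard group-sequential designs (GSD) decide on the interim
statistic $Z_1$ alone and discard the pipeline data from decision-making.
The delayed-response design of Hampson & Jennison (2013, *JRSS-B* 75, 3–54)
(DR-GSD) instead uses the interim crossing of $(l_1, u_1)$ only to stop
*recruitment*, and takes the efficacy decision on the enlarged statistic
$\tilde Z_1 \ge d_1$ once the pipeline outcomes arrive; the repeated-rejection
variant (RR-GSD) additionally demands $Z_1 \ge u_1$ **and**
$\tilde Z_1 \ge d_1$, with $d_1 = \Phi^{-1}(1-\alpha)$, so a rejection can
never follow a low crossing.

The package

* solves error-spending boundary sets $\{l_1, u_1, d_1, d_2\}$ for all three
  designs with **nonbinding** lower boundaries, using Lan–DeMets
  Pocock-like and O'Brien–Fleming-like spending for both $\alpha$ and
  $\beta$, and calibrates the design alternative $\tilde\delta$ so each
  design attains power $1-\beta$ at its fixed maximum sample size;
* evaluates global operating characteristics analytically under the
  canonical multivariate normal model of $(Z_1, \tilde Z_1, Z_{1+2})$
  (correlations $\sqrt{I_a/I_b}$): stopping probabilities, power,
  conditional power, and expected sample size with pipeline patients always
  counted;
* validates everything by Monte-Carlo simulation, either of the test
  statistics directly or of synthetic patient-level trials with pooled-SD
  statistics.

## Worked example

A phase III schizophrenia trial (the Mehta & Pocock recruitment scenario):
effect 1.6 points on the negative-symptoms scale, SD 7.5, 345 patients per
arm, interim after 29% of the information with another 30% in the pipeline,
Pocock-like spending:

```r
library(drgsd)
fit <- drgsd("DR_GSD", alpha = 0.025, beta = 0.2, sigma = 7.5, n_max = 345,
             info_interim = 0.29, info_pipeline = 0.3)
summary(fit, delta = 1.6)
#> DR_GSD: two-stage error-spending design (pocock_like spending)
#>   continuation region (l1, u1) = (0.259, 2.322)
#>   interim decision value d1 = 1.584
#>   final critical value d2 = 2.119
#>   interim spends: alpha1 = 0.0101, beta1 = 0.0809
#>   calibrated design alternative delta~ = 1.7580 (power 0.80)
#>   per-arm sizes: n1 = 100.0, pipeline = 103.5, decision = 203.6, max = 345.0
#>   max |defining-equation residual| = 3.09e-13
#>
#> Operating characteristics:
#>  design delta p_futility p_reject_interim p_continue power expected_n_total
#>  DR_GSD   1.6      0.089            0.224      0.686 0.739          601.286
```

Reading this: recruitment stops at interim with probability 0.313; in 22.4%
of trials that stop ends in an immediate rejection on $\tilde Z_1 \ge 1.584$,
in 8.9% in a non-rejection.  Overall power at $\delta = 1.6$ is 0.739 and the
trial randomizes 601.3 patients on average, against 690 for the single-stage
design of the same significance level.  `design_comparison()` lines up all
three sequential designs and the fixed design:

```r
cmp <- design_comparison()
print(cbind(cmp[1], round(cmp[-1], 3)), row.names = FALSE)
#>  design     l1    u1    d1    d2 p_futility p_reject_interim power expected_n_total
#>   fixed     NA    NA    NA 1.960         NA               NA 0.800          690.000
#>     GSD  0.259 2.322    NA 2.119      0.106            0.208 0.722          601.286
#>  DR_GSD  0.259 2.322 1.584 2.119      0.089            0.224 0.739          601.286
#>  RR_GSD -0.164 1.815 1.960 2.043      0.098            0.329 0.737          569.222
```

GSD and DR-GSD share the continuation region (hence the expected sample
size); the DR-GSD converts part of the GSD's futility mass into interim
rejections.  The RR-GSD's laxer upper recruitment boundary (1.815 vs 2.322)
makes an interim rejection markedly more likely and its expected sample size
the smallest.

Other entry points: `performance(fit, delta)` for operating characteristics
over an effect grid, `design_grid()` for the full two-family comparison
grid, `simulate(fit, nsim, seed, mode = "patient_level")` for Monte-Carlo
validation, `read_design_config()`/`write_design_config()` for flat
YAML/JSON design files, and a thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/drgsd.R", package="drgsd"))')" \
  boundaries --design GSD --info-interim 0.29 --info-pipeline 0.3 --sigma 7.5 --n-max 345
```

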