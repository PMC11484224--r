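---
title: "Two-stage group-sequential designs with delayed responses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage group-sequential designs with delayed responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgsd)
```

## The problem

In a two-arm trial with a continuous endpoint, group-sequential designs test
the one-sided hypothesis $\mathcal H_0: \mu_I - \mu_C \le 0$ at an interim
analysis after $n_1$ of the planned $n_{max}$ patients per arm, and again at a
final analysis.  When the outcome is only observed some lag $\Delta_t$ after
enrolment, a fraction of patients has been recruited but not yet measured at
the interim look: the *pipeline*.  Standard designs ignore those patients for
decision-making (though they must still be counted in the trial's cost); the
delayed-response designs of Hampson and Jennison (2013) instead split the
interim decision into an irreversible *recruitment stop* on the interim
statistic $Z_1$, followed by the actual efficacy decision on the enlarged
statistic $\tilde Z_1$ once the pipeline outcomes have arrived.

This package plans and evaluates three such designs under a common
error-spending framework, all with *nonbinding* lower boundaries (the
regulatory-preferred convention: type-I error control holds even if a crossed
futility boundary is ignored):

* **GSD** — standard error-spending design: efficacy stop if $Z_1 \ge u_1$,
  futility if $Z_1 \le l_1$, final rejection if $Z_{1+2} \ge d_2$;
* **DR-GSD** — recruitment stops if $Z_1 \notin (l_1, u_1)$; the hypothesis
  is then tested as $\tilde Z_1 \ge d_1$.  Note that rejection is possible
  even after a *low* crossing;
* **RR-GSD** — interim rejection requires the "repeated" confirmation
  $Z_1 \ge u_1$ **and** $\tilde Z_1 \ge d_1$, with $d_1 = \Phi^{-1}(1-\alpha)$
  fixed, so a low crossing can never end in rejection.

## The canonical model

With information fractions $I_1 = n_1/n_{max}$ and
$\tilde I_1 = I_1 + I_{\Delta_t}$, the statistic vector
$(Z_1, \tilde Z_1, Z_{1+2})$ follows the canonical multivariate normal law:
unit variances, $\mathrm{corr}(Z_a, Z_b) = \sqrt{I_a/I_b}$ for
$I_a \le I_b$, and mean $(\delta/\sigma)\sqrt{I_k\, n_{max}/2}$ at level
$I_k$.  The final statistic is the inverse-normal combination
$Z_{1+2} = w_1 Z_1 + w_2 Z_2$ with planning weights $w_1 = \sqrt{n_1/n_{max}}$,
$w_2 = \sqrt{1 - n_1/n_{max}}$, which makes it the all-data z-statistic and
places it at information level 1.  The correlations obey the
independent-increments product rule
$\mathrm{corr}(Z_1, Z_{1+2}) = \mathrm{corr}(Z_1, \tilde Z_1)\,
\mathrm{corr}(\tilde Z_1, Z_{1+2})$, which the test suite asserts to
$10^{-12}$.

All rectangle probabilities go through `mvn_rect_prob()`, a thin wrapper
around the deterministic Miwa lattice algorithm of **mvtnorm** (4097 grid
points; well below $10^{-7}$ absolute error in dimensions 2–3).  A
deterministic quadrature was chosen over the quasi-random Genz–Bretz
algorithm so that solved boundaries are bit-reproducible across calls.

## Boundary determination

Interim error spends come from the Lan–DeMets spending functions that mimic
Pocock ($f(t) = \ell \log(1 + (e-1)t)$) and O'Brien–Fleming
($f(t) = 2 - 2\Phi(\Phi^{-1}(1-\ell/2)/\sqrt t)$) boundaries, evaluated at
$t = I_1$; the same families serve for $\alpha$- and $\beta$-spending, only
the level differs.

For the GSD (and, identically, the DR-GSD): $u_1 = \Phi^{-1}(1-\alpha_1)$;
$d_2$ solves $P_0(Z_1 < u_1, Z_{1+2} \ge d_2) = \alpha - \alpha_1$ — note the
continuation region used here is $(-\infty, u_1)$, which is what makes $l_1$
nonbinding.  The DR-GSD's extra decision value $d_1$ is the root of the
balance equation
$$P_0(Z_1 \ge u_1, \tilde Z_1 < d_1) = P_0(Z_1 \le l_1, \tilde Z_1 \ge d_1),$$
which exhausts the interim type-I error when the lower boundary is respected
and leaves the design conservative when it is not.  For the RR-GSD, $d_1$ is
fixed at $\Phi^{-1}(1-\alpha)$, $u_1$ solves
$P_0(Z_1 \ge u_1, \tilde Z_1 \ge d_1) = \alpha_1$, and $d_2$ is as above with
the RR-GSD's own $u_1$.  Root-finding order matters only for the RR-GSD and
is $u_1 \to d_2 \to (l_1, \tilde\delta)$, valid because the first two are
free of the design alternative.

**Calibration of the design alternative.**  The effect size
$\tilde\delta$ at which the $\beta$-spending is anchored is not a free input:
each design solves for the $\tilde\delta > 0$ at which its total type-II
error equals $\beta$ at the fixed $n_{max}$.  Concretely, the interim spend
equation defines $l_1(\tilde\delta)$ (for the GSD/DR-GSD,
$P_{\tilde\delta}(Z_1 \le l_1) = \beta_1$; for the RR-GSD the interim spend
also covers the high-crossing-then-fail path), and the remaining equation
$P_{\tilde\delta}(l_1 < Z_1 < u_1, Z_{1+2} < d_2) = \beta - \beta_1$ is
solved for $\tilde\delta$ by bracketed root-finding on the standardized
effect.  The RR-GSD therefore calibrates a *different* $\tilde\delta$ than
the GSD/DR-GSD pair — one reason grid-level power comparisons depend on which
design anchors the calibration.

One property deserves emphasis because it looks like a bug and is not: the
power identity "power at $\tilde\delta$ equals $1-\beta$" is exact for the
GSD and the RR-GSD, whose futility probability *is* the interim type-II
spend.  The DR-GSD inherits $\{l_1, u_1, d_2, \tilde\delta\}$ from the GSD,
but its futility event ($\tilde Z_1 < d_1$ after a recruitment stop on either
side) has probability slightly *below* $\beta_1$ under positive drift — the
balance equation converts part of the futility mass into interim rejections.
Its power at $\tilde\delta$ consequently sits one to two percentage points
*above* $1-\beta$ on the default comparison grid.  This is a feature of the
design (the same mechanism that gives it higher power than the GSD at equal
boundaries), not a solver tolerance, and the test suite asserts it as such.

Numerical conventions: z-scale roots are bracketed on $[-10, 10]$
(`uniroot`, tolerance $10^{-10}$; all realistic boundaries lie within
$[-0.5, 3]$); the standardized effect is bracketed so the final-analysis
drift stays below 10; every solver recomputes its defining-equation
residuals from the returned boundaries, and the suite requires them below
$10^{-6}$ in probability units.  Degenerate inputs are rejected up front:
$I_1 + I_{\Delta_t} \ge 1$ (the "wait for the pipeline" design is a
different design), zero pipeline for the delayed-response kinds (the balance
equation becomes vacuous), and spending splits that leave no error for a
stage.

## Operating characteristics

`performance()` evaluates, per design and effect, the futility and
interim-rejection probabilities, continuation probability
$P(l_1 < Z_1 < u_1)$ (identical across designs only for GSD/DR-GSD), global
power, and expected total sample size
$$\mathbb E[N] = 2\left(\tilde n_1 + P(\text{continue})\,(n_{max} -
\tilde n_1)\right),$$
in which pipeline patients are always counted — they are recruited whether or
not their data inform the decision — and, on continuation, count toward the
second stage so the final analysis always comprises $n_{max}$ per arm.
Conventions: `n_max`, `info_interim`, `info_pipeline` are per arm;
expected sample sizes are totals over both arms.  Information fractions are
treated as exact reals and patient counts kept real-valued internally;
rounding to whole patients happens only in reporting views and in the
patient-level simulator.  For the DR-GSD, "futility" means recruitment stop
followed by non-rejection regardless of which side was crossed; it is not
classical futility, and negative effects are included in evaluation grids
precisely to probe that behaviour.

## What the simulators emulate — and what they do not

Two Monte-Carlo routes validate every analytic probability:

* **canonical mode** draws $(Z_1, \tilde Z_1, Z_{1+2})$ directly from the
  canonical law (Cholesky factorization) and applies the decision logic —
  the standard protocol for validating operating characteristics;
* **patient-level mode** generates normal outcomes per patient
  ($\mu_C = 0$, $\mu_I = \delta$, common $\sigma$), computes stagewise
  pooled-SD statistics on rounded counts, and combines them with the fixed
  inverse-normal weights.  The simulated statistics are therefore t-type
  while the boundaries remain normal-quantile-based, mirroring how such a
  trial would actually be analysed at moderate $n_1$; the two modes agree
  within Monte-Carlo error for interim sizes of about 50 per arm and up.

The test suite's independent oracle constructs the statistics a third way —
from Brownian-motion score increments — so the analytic path, the package
simulator and the oracle share no code.

Neither simulator models recruitment calendars, arrival processes, random
response lags, dropout, unequal allocation, or non-normal endpoints.  Passing
tests show the decision machinery and the canonical-model arithmetic are
right; they do not show that a real trial's pipeline fraction is knowable in
advance, which is a planning assumption, not a statistical one.

Reproducibility: one seed governs a simulation call; replications consume
sequential substreams of the same generator, so a `(seed, nsim, n_reps)`
triple pins every downstream number bit-for-bit on a given platform.

## Validation problem sizes

The packaged checks use: the worked example (effect 1.6, SD 7.5, 345 per
arm, interim at 29% information, 30% pipeline, Pocock-like spending), whose
boundary sets and operating characteristics are reproduced to the 3 printed
decimals; a 2 spending families × 9 information-fraction pairs × 3 designs
constraint sweep; canonical-mode oracles at $10^6$ draws and patient-level
checks at $10^4$–$10^5$ trials; and a replicated experiment (O'Brien-Fleming
spending, $I_1 = 0.5$, $I_{\Delta_t} = 0.2$, $\delta = 0.3$, 10,000 trials ×
100 replications) confirming that replication means centre on the analytic
values.  These sizes keep every Monte-Carlo tolerance at three standard
errors while the whole suite runs in well under a minute of simulation time.

## A worked comparison

```{r example}
cmp <- design_comparison()
print(cbind(cmp[1], round(cmp[-1], 3)), row.names = FALSE)
```

The fixed design needs 690 patients for 80% power; all three sequential
designs trade a small power loss at the planning effect (they spread error
over two looks at the same maximal size) for an expected saving of roughly
90–120 patients.  The RR-GSD's laxer upper recruitment boundary makes interim
rejection markedly more likely and its expected sample size the smallest,
at the cost of a wider continuation region for unpromising effects.

## Known limitations

Two stages only; two equal arms; continuous endpoints; known-variance
normal theory for all analytic quantities (the t-refinement lives only in
the patient-level simulator); Pocock-like and O'Brien-Fleming-like spending
only; nonbinding lower boundaries only.  Expected trial *duration* is out of
scope — it depends on recruitment-pattern assumptions the package does not
model.  The conditional perspective is limited to `conditional_power()`:
once one conditions on continuation, GSD and DR-GSD are identical by
construction, so conditional scores cannot separate them.
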