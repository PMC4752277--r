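---
title: "Temperate phage–bacteria dynamics in the monoxenic mouse gut: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperate phage–bacteria dynamics in the monoxenic mouse gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagegut)
```

## The biological setting

A germ-free mouse colonized with two isogenic *E. coli* strains — one
carrying a λ prophage (the lysogen lineage L), one susceptible to the
phage (lineage S) — is a closed arena in which every process that
matters to a temperate phage can be measured: growth to the gut's
carrying capacity, washout by intestinal transit, spontaneous prophage
induction, phage adsorption, the lysis–lysogeny decision upon infection,
and burst of latent cells. This package implements a deterministic
mean-field model of that arena, the estimation pipeline that calibrates
it from fecal plate counts, the closed-form estimators for the
supporting in-vitro assays, and a synthetic-data generator that stands
in for the animal experiments.

## Model structure and assumptions

Five compartments per gram of feces: susceptibles $S$, resident lysogens
$L$, newly lysogenized susceptibles $S^L$, latent cells $Q$ and free
phage $V$. With $N = S + L + S^L$:

$$
\begin{aligned}
\dot S   &= rS(1 - N/k) - aSV - dS \\
\dot L   &= rL(1 - N/k) - xL - dL \\
\dot{S^L} &= rS^L(1 - N/k) + gaSV - xS^L - dS^L \\
\dot Q   &= (1-g)aSV + x(L + S^L) - lQ - dQ \\
\dot V   &= ylQ - aNV - dV
\end{aligned}
$$

The structural assumptions, each of which is a deliberate modelling
choice:

* **Shared growth.** Both lineages grow at the same maximal rate $r$
  toward the same capacity $k$: carrying the prophage is cost-free
  except through induction. (Receptor-deletion competitions with a
  non-inducible prophage support this: the lineages then drift
  neutrally.)
* **Latent cells neither grow nor count toward $N$.** A cell committed
  to lysis has handed its machinery to the phage; $Q$ appears in no
  logistic term.
* **Adsorption removes phage onto *all* bacteria** ($-aNV$ in $\dot V$):
  lysogens adsorb phage but are immune to superinfection, so only
  $-aSV$ appears in $\dot S$. This asymmetry matters: at calibrated
  densities the adsorption sink on ~$10^9$ immune cells dominates the
  free-phage balance.
* **Washout $d$ applies to all five compartments** — intestinal flux
  does not distinguish cell states.
* **Units.** Time is hours throughout; bacterial densities cfu/g of
  feces, phage pfu/g. The in-vitro adsorption assay yields a rate per
  ml of culture; it is reported in its own units and never silently
  converted to the in-vivo per-gram constant.

The packaged default parameters (`default_params()`) are the calibrated
in-vivo values: $d = 0.25$, $r = 1.1$ h⁻¹, $k = 4.6\times10^9$ cfu/g,
$x = 0.016$ h⁻¹, $l = 0.8$ h⁻¹, $y = 12.1$, $a = 2.6\times10^{-9}$
g h⁻¹, $g = 0.19$.

## Numerical choices

* Integration is in linear space with `deSolve::lsoda`, `rtol = 1e-8`,
  `atol = 1e-2` cfu/g (far below one countable cell). Components inside
  $(-\text{atol}, 0)$ are clamped to zero; anything more negative
  raises an error rather than being hidden — at these tolerances it
  would indicate a genuine solver failure.
* A fixed-step fourth-order run (`method = "rk4"`, $dt = 10^{-3}$ h)
  serves as an independent cross-check; the suite verifies agreement
  below 1% on every compartment at 48 h.
* `find_equilibrium()` integrates to a long horizon (2000 h by
  default) and then polishes the endpoint with a damped Newton
  iteration on the steady-state system using a central-difference
  Jacobian, to a scaled residual of $10^{-9}$. When $r \le d$ growth
  cannot offset washout and the washout state is returned explicitly
  rather than treated as a failure. At the calibrated parameters the
  coexistence equilibrium has $S^* = 0$: the susceptible *lineage*
  survives, but entirely as new lysogens.
* Two-phase simulations restart the integrator at the switch time from
  the phase-1 endpoint, so the state is continuous there by
  construction.

## The sequential calibration

Four stages, each consuming the dataset that isolates its parameters:

1. **Growth** ($r$, $k$): the monocolonization dynamics obey the 1-D
   logistic-with-washout model, which has the closed form of a logistic
   with effective rate $r - d$ and capacity $k(1 - d/r)$. Fitted by
   nonlinear least squares jointly over mice with shared $(r, k)$;
   $d = 0.25$ h⁻¹ is fixed (a property of gut transit, not of the
   strains).
2. **Induction and latency** ($x$, $l$): with the phage receptor
   deleted, $a = 0$ and only $L$, $S$, $Q$ move; $Q$ is fed purely by
   induction. Fitted on all three compartments.
3. **Adsorption** ($a$): the free-phage equilibrium balance
   $ylQ^* = (aN^* + d)V^*$ is linear in $a$ given the in-vitro burst
   size $y$; `solve_adsorption()` inverts it from observed late-time
   densities. Which experiment supplies those densities is an explicit
   input; the synthetic bundle reads them from the long-horizon state
   of the wild-type competition model.
4. **Lysogenization** ($g$): bounded scalar least squares on the
   log-ratio $L/(S+S^L)$ at 36 h — the time at which competition data
   resolve $g$ best — across mice and initial-ratio groups (an option
   fits all times up to 48 h instead).

Design decisions the data do not dictate, made once and used
throughout:

* **Residuals on log₁₀ densities.** Plate counts span seven decades and
  their error is multiplicative; least squares on the log scale weights
  decades equally.
* **Censoring.** Observations at the detection limit (default
  $10^2$ counts/g) are recorded at the limit, flagged, and excluded
  from residuals.
* **Initial conditions are data, not parameters.** Each mouse's
  observed time-0 densities seed its trajectory; they are not fitted.
* **Multi-start optimization.** Each nonlinear stage restarts from 5
  spread initializations (deterministic grid) and keeps the best
  optimum, guarding against local minima in the $(x, l)$ surface.
* **Equal weights** for the $L$, $S$, $Q$ residual blocks in stage 2.

## Bootstrap intervals

`bootstrap_ci()` resamples whole mice with replacement (cases, matching
the replication structure of the experiments — rates are shared, mice
differ in their counts), re-runs the estimator, and returns percentile
intervals; replicates where the estimator fails are dropped and counted,
with more than 20% failures aborting. Intervals are deterministic given
the seed.

With the small group sizes typical of gnotobiotic work (3–13 mice),
plain 2.5/97.5 percentile intervals are anti-conservative — a
well-documented small-sample property of the case bootstrap (Hesterberg
2015, *Am. Stat.* 69:371–386). The function therefore also offers
`type = "expanded"`, the expanded-percentile interval that widens the
quantile levels by the $t$-versus-normal and $(n-1)/n$ corrections; it
is the documented recommendation below ~15 cases and is what the
package's own nested-simulation coverage check uses (150 outer
replications of a 6-mouse design at count CV 0.2, 400 bootstrap
replicates each — sizes chosen to make the Monte-Carlo error on the
coverage estimate small relative to the 90–99% acceptance band).

## What the synthetic generator does and does not emulate

`generate_mouse_experiment()` draws per-mouse initial densities
lognormally around the gavage target (CV 0.3 by default — biological
variability in colonization take), integrates the deterministic model
(with $a$ forced to 0 in the receptor-deletion scenario), and reads
counts at the sampling times with multiplicative lognormal noise
(CV 0.2 by default, mean-1 so that noise does not bias densities) and
flooring at the detection limit. Latent cells are observable only in
the receptor-deletion scenario, where free phage can be spun out before
plating. Default sampling times $\{0, 6, 24, 30, 48, 72, 96, 144,
216\}$ h bracket daily sampling with extra early points where dynamics
are fast.

What it deliberately does **not** reproduce:

* **Resistant-mutant invasion.** In real mice, maltose-regulon mutants
  that no longer express the phage receptor sweep through both lineages
  from about day 2, independently of the phage. The model and generator
  are therefore faithful to wild-type infection dynamics only over the
  first ~48 h; receptor-deletion scenarios, which have no such
  selection pressure on the receptor, remain valid longer.
* **Demographic stochasticity.** Events at low copy number (the first
  induction events, rare recombinants) are not jump-simulated; the
  generator perturbs a mean-field trajectory.
* **The experimental free-phage peak.** In observed wild-type
  competitions the peak phage-to-lysogen ratio far exceeds the
  receptor-deletion one; in the calibrated mean-field model the $-aNV$
  sink (about 9 h⁻¹ at capacity) keeps wild-type $V$ low and the
  ordering is reversed. This mirrors the model's known tendency to
  misjudge the initial velocity of the dynamics, and tests assert the
  lysogenization shape (the $S^L$ fraction at 36 h) rather than the
  peak-ratio contrast.
* Rate parameters are shared across mice; only initial densities vary.
  Real inter-mouse variability in, e.g., transit rate is folded into
  count noise.

Passing the recovery tests on such data shows the pipeline is
*self-consistent* — it recovers the parameters that generated the data
at the study's design and noise level — not that the model is correct
for real mice.

## Sensitivity analysis

`parameter_sweep()` perturbs one parameter at a time over ×0.1–×10 of
its baseline (21 log-spaced points by default) and records the final
$L/(S+S^L)$ ratio at 100 h — by which the calibrated system is within
1% of its equilibrium value — for the three initial-ratio designs.
Notable behaviour at the calibrated baseline:

* The final lysogen gain falls monotonically as induction $x$ or
  lysogenization $g$ rise: both convert the lysogens' killing advantage
  into a cost (dead lysogens) or a gift (immune competitors).
* The gain is inversely proportional to $g$: the product
  (final ratio × $g$) is flat to a few percent over
  $g \in [0.05, 0.5]$, while $(ratio − 1) \times g$ is not — the
  proportionality includes the neutral offset. `gain_vs_g()` emits both
  diagnostics so the data decide.
* Adsorption $a$ barely moves the gain anywhere in its ten-fold range,
  and latency $l$ and burst size $y$ are likewise modest *upward*; a
  strongly *reduced* burst size, however, collapses the gain — with
  $y \approx 1$ the phage can barely amplify and the lysogens lose
  their weapon. "Phage-interaction parameters have modest impact" is
  therefore a statement about the calibrated neighbourhood, not a
  global one.

## Known limitations

* Validity window ≤ 48 h for wild-type scenarios (resistance invasion
  is out of scope by design, as are phage repressor mutants and
  recombinant gene capture).
* The latency rate $l$ is weakly identified from fecal counts alone —
  its calibration interval spans $[0, 1.5]$ h⁻¹ — and mostly matters
  through the product $yl$ in the equilibrium inversion.
* The model-independent induction estimate is *per generation* under
  its two-phase growth schedule, while the model's $x$ is per hour;
  the two are numerically close at the calibrated values but are
  reported in their native units and never converted into one another.
* Problem sizes in the test-suite checks (mice per group, bootstrap and
  outer-replication counts, lattice resolutions) are scaled to keep the
  full suite fast while leaving Monte-Carlo error well inside each
  asserted tolerance; the defaults in the package itself are the
  study-scale values.
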