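---
title: "Ranking drug-target candidates in ODE pathway models with aucsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug-target candidates in ODE pathway models with aucsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucsens)
library(ggplot2)
```

## The problem

Signaling-pathway models written as ordinary differential equations,
$dX/dt = F(X, P, u)$ with states $X$ (molecular concentrations), kinetic
parameters $P$ and an external excitation $u$, map each parameter to a single
biochemical process — a production, degradation, phosphorylation or transport
step. A drug that binds a molecule involved in one of those processes changes
the corresponding kinetic rate, usually reducing it. Finding promising
molecular drug targets can therefore be phrased as a sensitivity question:
*which single parameter, when substantially reduced, changes the system
output the most — and in which direction?*

Two features make standard sensitivity machinery a poor fit for this
question. First, local sensitivity functions and their usual unsigned
area-under-curve summaries cannot tell a parameter whose inhibition
*suppresses* the response from one whose inhibition *amplifies* it, yet that
direction is exactly what decides whether a target is useful for a given
therapeutic goal. Second, cells in a population respond heterogeneously to
the same drug — some are strongly affected, some partially or wholly
resistant — so a single fixed perturbation size misrepresents what a
treatment does to a population.

`aucsens` implements a randomized one-at-a-time (OAT) analysis that addresses
both: the perturbation is a *random multiplicative alteration factor* drawn
once per simulated cell, and the index is a *signed* AUC ratio.

## The index and the algorithm

One state variable $x_i$ is designated the system output (in the package:
`output_variable` of an `ode_model`). Writing $x_{i,\mathrm{nom}}(t)$ for the
output under nominal parameters $P_{\mathrm{nom}}$ and $x_i(p_j, t)$ for the
output with parameter $p_j$ altered to $\alpha\,p_{j,\mathrm{nom}}$, the
response difference is

$$\Delta x_i(p_j, t) = x_i(p_j, t) - x_{i,\mathrm{nom}}(t),$$

its integral $R_j = \int_0^T \Delta x_i(p_j, t)\,dt$ measures the effect over
the horizon $T$, and the normalised, dimensionless index is

$$S_j = \frac{\int_0^T \Delta x_i(p_j, t)\,dt}{\int_0^T x_{i,\mathrm{nom}}(t)\,dt}.$$

The integral is deliberately taken of the *signed* difference rather than of
$|\Delta x|$ or $(\Delta x)^2$: parameters that matter for drug targeting
produce a difference of consistent sign over the horizon, and keeping the
sign is what lets the ranking separate suppression from amplification. For a
non-negative output, $S = -1$ is the floor — the altered output is
identically zero (complete suppression) — while positive values are
unbounded.

The full analysis (`rank_parameters()`) is:

1. simulate once at nominal parameters and store the output AUC;
2. for each rankable parameter $p_j$, draw $n$ alteration factors $\alpha$
   from the chosen distribution (one per simulated cell);
3. for each draw, re-simulate with only $p_j$ changed to
   $\alpha\,p_{j,\mathrm{nom}}$ and compute $S_j$;
4. average: $A_j = \bar\mu(S_j)$;
5. rank the parameters by $A_j$.

For display, $A + 1$ is plotted on a log axis (`display_value()`,
`autoplot()`): the line at $1$ ($10^0$) is "no influence", points above it
are parameters whose alteration amplifies the output, points below are
suppressors. `classify_parameter()` applies the same split with a small
neutral band (default $\pm 0.01$ around $A = 0$; the band width is a display
convenience — the threshold itself is the meaningful quantity — and any
non-negative width can be supplied).

## The alteration-factor distribution

The default law (`alteration_dist()`) models an inhibitory drug:
$\alpha \sim \mathrm{LogNormal}(\mu = -2.08,\ \sigma = 0.61)$ on the
natural-log scale, giving mean $e^{\mu + \sigma^2/2} \approx 0.15$ — an
average 85% reduction of the targeted rate — with a right tail of weakly
affected cells standing in for partial or total drug resistance. A uniform
law would lack that resistant tail, which is why a log-normal is used. The
parameters are the location and scale of $\log\alpha$, **not** the mean and
standard deviation of $\alpha$; this classic confusion is worth a sentence
in any analysis report.

```{r dist}
d <- alteration_dist()
dist_mean(d)
summary(sample_alpha(d, 1e5, seed = 1))
```

Degenerate distributions (`kind = "degenerate"`) express deterministic
what-if runs, including `value = 0` for a complete knockout of a process.
For drugs that *increase* a rate (e.g. via blocking an inhibitor, or raising
a Michaelis constant), the same machinery runs with a user-supplied
distribution over $\alpha > 1$ (`mode = "amplification"`); no default
amplification law ships because a biologically plausible amplification range
is case-specific and needs expert input.

## Numerical choices

* **Solver.** `deSolve::lsoda` by default (`sim_config(stiff = TRUE)`): the
  method switches automatically between stiff and non-stiff integration,
  which matters because extreme alteration draws can stiffen an otherwise
  benign system. Tolerances default to `rtol = 1e-6`, `atol = 1e-9`.
* **Shared output grid.** Nominal and altered runs are evaluated on one
  fixed grid (default 1000 points on $[0, T]$), so $\Delta x$ is a pointwise
  difference with no interpolation. The AUCs are composite-trapezoid sums on
  that grid; for smooth ODE outputs at 1000 points the quadrature error is
  well below the solver error, and because numerator and denominator of $S$
  are computed on the same grid, grid error largely cancels in the ratio.
* **Failed integrations.** A run that errors, stops early or produces
  non-finite states is dropped and counted in `failed_runs`; a parameter
  losing more than 10% of its draws triggers a warning, and one losing all
  draws is flagged `unrankable` rather than omitted. Whether to drop or
  abort is a genuine design choice; dropping keeps a long ranking run alive
  and the counts make the data loss visible.
* **Undefined index.** If the nominal output AUC is at the numerical floor
  (the output never rises above zero), $S$ is undefined and the analysis
  errors out loudly rather than returning ratios of noise.
* **Zero nominal values.** The alteration is multiplicative, so a parameter
  with nominal value 0 cannot be ranked; it is reported as unrankable.
* **Reproducibility.** Every sampling function takes an explicit seed;
  `rank_parameters()` derives one independent substream per parameter from
  the master seed, so results are bit-reproducible and would not change if
  parameters were processed in parallel or in a different order.
* **Ranking order.** The mean index is reported per parameter; this package
  sorts by $|A|$ descending (ties broken alphabetically) so that strong
  suppressors and strong amplifiers both surface at the top, with
  `sort_by = "signed"` available when only one direction is of interest.

## The classical baseline

For comparison, `rank_classical()` implements the standard local ranking:
the sensitivity function $s_j(t) = \partial x_i(t)/\partial p_j$ along the
nominal trajectory, summarised by the area under its absolute curve. No
single canonical estimator or normalisation exists for this baseline; the
package uses central finite differences with relative step $10^{-3}$
(second-order accurate; forward sensitivity ODEs would be the higher-effort
alternative) and a *semi-relative* score
$R_{\mathrm{cl},j} = p_{j,\mathrm{nom}} \int_0^T |s_j(t)|\,dt$, which makes
scores comparable across parameters with different units without dividing by
$x_{\mathrm{nom}}(t)$ (a fully relative normalisation is undefined wherever
the output is near zero). The absolute value inside the integral follows the
usual convention — and is precisely why this baseline cannot discern
inhibiting from amplifying parameters. The package asserts nothing about
agreement between the two rankings; on nonlinear feedback systems they can
and do disagree.

## Demonstration models

Three executable models ship with the package, registered for configuration
files under the names below.

**`linear_chain`** — $dx/dt = k - d\,x$, $x(0) = 0$. The analytic oracle:
the solution is proportional to $k$, so $S = \alpha - 1$ *exactly* for the
production parameter, $A = E[\alpha] - 1 \approx -0.85$ under the default
law, and $\alpha = 0$ gives $S = -1$. Most of the test suite's frozen
expectations derive from this model's closed forms.

**`feedback_oscillator`** — a three-state surrogate with the loop topology
of the p53/Mdm2 regulatory module: output protein $P$, inhibitor mRNA $R$
(induced by $P$ through a Hill term), inhibitor protein $M$ (translated from
$R$, degrading $P$). The transcription/translation stages delay the negative
feedback enough to oscillate. These equations are *synthetic and
illustrative*: they are not any published p53 model, and no quantitative
reproduction of published case-study rankings is attempted — the published
systems' equations and nominal values live in their original papers and can
be plugged into `ode_model()` to run the identical pipeline. The surrogate
exists to exercise the method on an oscillatory output where reducing the
inhibitor's production (`s0`, `t0`) demonstrably amplifies the response.
Defaults were frozen after a one-off calibration
(`scripts/calibrate_demo_models.R`) confirming at least two output peaks
over a 100 h horizon and the documented effect directions; they have not
been revisited since.

**`cascade`** — a three-stage aperiodic surrogate of a cytokine-activated
cascade (kinase activation under a constant stimulus, saturable
phosphorylation, target transcript as output). Reducing the first activation
rate suppresses the output; reducing the transcript's degradation rate
amplifies it — the two directions a target ranking must separate, mirroring
the qualitative behavior of interferon-type signaling where stabilising the
target mRNA prolongs the response and throttling the first phosphorylation
step silences it.

Parameter inventories for the two case-study pathways (p53/Mdm2: 35 ranked
parameters plus the excluded constants `h0`, `NSAT`, `dDAM`; IFN-β JAK/STAT:
48 ranked plus the excluded saturation constants `ks1_phos_sat`,
`ks2_phos_sat`) ship as CSV fixtures via `load_parameter_inventory()`; they
document names, descriptions and ranked/excluded status, not equations or
nominal values.

## What the synthetic models do and do not show

The bundled models reproduce the *structural* features that matter to the
method — linearity (for exact oracles), delayed negative feedback with
oscillations, monotone cascade dynamics, saturation constants that must be
excluded from ranking — under clean, smooth, non-negative dynamics. They do
not emulate real pathway models' dimensionality (dozens of states), strong
stiffness, conservation cycles, or experimentally fitted parameter values.
A passing test suite therefore certifies the *method implementation* (index
algebra, sampling, bookkeeping, reproducibility), not the biological
conclusions one would draw on any particular published model; those depend
on that model's structure and fit, and the analysis inherits all the usual
OAT caveats (parameters assumed independent, one process altered at a time).

## A worked run

```{r rank, fig.width = 6, fig.height = 3.5}
model <- make_linear_chain(k = 1, d = 0.5)
cfg <- sim_config(horizon = 10, grid = 500)
ranking <- rank_parameters(model, cfg, n = 1000, seed = 1)
tidy(ranking)
glance(ranking)
autoplot(ranking)
```

The signs tell the drug-target story directly: reducing production starves
the output (`k` is suppressing, $A(k) = E[\alpha] - 1 \approx -0.85$,
display value $\approx 0.15$ below the threshold line), while reducing
degradation stabilises and raises it (`d` is amplifying, $A > 0$, point
above the line) — a distinction the unsigned classical baseline cannot make.
The ensemble view mirrors a treated cell population:

```{r ensemble, fig.width = 6, fig.height = 3.5}
ens <- population_ensemble(model, cfg, "k", n = 200, seed = 1)
autoplot(ens)
```

Problem sizes used in the package's own test and acceptance runs — grids of
100–1000 points, 20–5000 draws per parameter, toy models of one to three
states — were chosen as the smallest sizes at which the closed-form oracles
discriminate implementation errors from Monte-Carlo and solver noise.

## Known limitations

* Strictly one-at-a-time: joint perturbations are supported only as a manual
  multi-parameter `population_ensemble()`, never in the ranking.
* No variance-based global indices (Sobol/Morris), no frequency-domain or
  steady-state response characteristics — the AUC of the transient response
  is the single summary.
* No delay-differential, stochastic or event/discontinuity simulation; the
  excitation is a deterministic function of time.
* No SBML/CellML import; models are R functions, registered names, or
  expression-string configurations.
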