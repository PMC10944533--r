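---
title: "Models and methods: noise in ultrasensitive transcriptional switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: noise in ultrasensitive transcriptional switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchnoise)
```

# The four switch designs

A transcriptional switch turns a gene off as the copy number of a
repressor R rises past a threshold.  `switchnoise` implements four designs
of such a switch as explicit mass-action reaction networks over a single
gene copy and asks one question about each: how sharply does it switch
(ultrasensitivity), and how badly does molecular noise corrupt the on and
off states it is supposed to hold?

**Cooperative binding** (`cooperative_binding`). The repressor binds three
operator sites directly.  The first copy binds with dissociation constant
$K_r$, the second with $cK_r$ and the third with $c^2K_r$, so $c<1$ makes
binding cooperative; transcription (rate $\alpha$) proceeds unless all
three sites are occupied, and mRNA decays at rate $\beta$ per molecule.
Activity is the equilibrium probability that at least one site is free:
with $x = R_T/K_r$,
$$a(x) = 1 - \frac{x^3/c^3}{1 + 3x + 3x^2/c + x^3/c^3}.$$
The repressor pool is treated as an undepleted reservoir (at most three of
its $R_T$ copies are ever bound), so $R_T$ enters only as a continuous
load and activity and noise are smooth functions of $x$.

**Sequestration** (`sequestration`). The repressor never touches DNA.  A
transcriptional activator A binds the free promoter $E_F$ with
dissociation constant $K_a$, forming the transcribing state $E_A$; the
repressor instead titrates free activator into an inactive complex
$R\!A$ with dissociation constant $K_s$.  Copy numbers are conserved:
$A_T = A + R\!A + [\text{promoter-bound }A]$ and
$R_T = R + R\!A + [\text{promoter-bound }R]$.  The natural load is the
molar ratio $\tilde R_T = R_T/A_T$: below one, leftover activator keeps
the gene on; above one, essentially all activator is sequestered.  Tight
activator-DNA binding ($\tilde K_a = K_a/A_T \ll 1$) makes the transition
at $\tilde R_T = 1$ extremely sharp.

**Sequestration + blocking** (`sequestration_blocking`). The repressor can
additionally bind the DNA-bound activator ($E_A + R \rightleftharpoons
E_R$, dissociation constant $K_b$), silencing transcription without
removing the activator.

**Sequestration + blocking + displacement**
(`sequestration_blocking_displacement`). The repressed complex can leave
the DNA as a unit ($E_R \rightleftharpoons E_F + R\!A$, dissociation
constant $K_d$).  This closes a reaction cycle
$E_F \to E_A \to E_R \to E_F$; when $(K_aK_b)/(K_sK_d) \ne 1$
(`thermo_cycle_gap()`) the cycle is thermodynamically driven and the
promoter's stationary distribution depends on kinetics, not only on the
equilibrium constants.  This driving is what lets the triple switch beat
the equilibrium designs.

# Kinetic conventions

The literature on these switches specifies dissociation constants; a
stochastic model also needs a time scale.  We split every binding
equilibrium with one shared association rate constant `k_on` (per molecule
per unit time) and dissociation rate `k_on * K`, so all equilibrium
constants are honoured exactly and activity curves are independent of
`k_on` altogether.  Noise is not: the mRNA lifetime $1/\beta$ (our unit of
time, $\beta = 1$) must be compared with promoter dwell times.  The
package default is `k_on = 0.1` per molecule per unit time.  With the
figure presets this puts activator-DNA dwell times at tens of mRNA
lifetimes, the regime in which noise-induced promoter states persist long
enough to distort the mRNA distribution — the phenomenon these switch
designs are meant to suppress.  A fast-binding choice (`k_on` of order
10) averages the promoter over the mRNA lifetime and makes every design
look quiet and nearly Poisson; `k_on` is a first-class parameter for
exploring that regime.

All simulations use a single gene copy, as in the figure conditions the
presets reproduce.

# Figure presets and their calibration

Shipped in `inst/extdata/presets.yaml` and loaded by `preset_params()`:

| preset | constants (normalized) | sensitivity target |
|---|---|---|
| `cooperative_noncooperative` | $c=1$, $K_r=20$ | $n_{\mathrm{eff}} \approx 1.3$ |
| `cooperative` | $c=0.1$ ($c\to 0$: 3) | cooperativity raises $n_{\mathrm{eff}}$ |
| `sequestration_strong` | $\tilde K_a = 5\times10^{-3},\ \tilde K_s = 2.5\times10^{-5}$ | $\approx 50$ |
| `sequestration_weak` | $\tilde K_a = 10$ | $\approx 2$ |
| `sequestration_blocking` | strong + $\tilde K_b = 0.01$ | $\approx 50$ |
| `sequestration_blocking_displacement` | $\tilde K_a=5\times10^{-4},\ \tilde K_s=10^{-5},\ \tilde K_b=0.01,\ \tilde K_d=10$ | $\approx 200$ |

The published sensitivities are stated for each design, but the exact
constants behind them are not available here, so the presets were
calibrated once against those printed Hill coefficients using the
mean-field activity expressions below and then frozen; every analysis and
test in the package runs from these presets.  The defaults
$\alpha = 20$, $\beta = 1$, $A_T = 100$ put the fully-on mean at 20 mRNA
copies — large enough that bimodality is visible, small enough that exact
computation is cheap.

Two useful closed-form anchors for the sequestration switch (deep
titration, no blocking): activity falls to 90% of its plateau near
$\tilde R_T = 1 - 9\tilde K_a$ and to 10% near
$1 + 9\tilde K_s/\tilde K_a$, so
$n_{\mathrm{eff}} \approx \log 81 / \log\!\big[(1 + 9\tilde
K_s/\tilde K_a)/(1 - 9\tilde K_a)\big]$.  Sharpness therefore requires
$\tilde K_s \ll \tilde K_a \ll 1$ — the "strong activator" corner — and is
*not* monotone in $\tilde K_a$ at fixed $\tilde K_s$: pushing $\tilde K_a$
below the $\tilde K_s$ scale softens the off-transition again.  The
monotone "stronger activator = sharper switch" statement holds in the
sequestration-dominated regime $\tilde K_s \ll \tilde K_a$, which is where
the package asserts it.

# Activity curves and the effective Hill coefficient

`activity_curve()` computes steady-state activity against load with two
backends.

*Mean-field* (default): promoter occupancies from the stationary
distribution of the 2- or 3-state promoter chain with rates set by the
free A, R and $R\!A$ levels; free levels from deterministic titration
$R\!A = A\,R/K_s$ under the conservation laws, with the single promoter's
occupancy subtracted from the solution totals; iterated (damped) to a
fixed point with residual below $10^{-10}$.  For the driven displacement
cycle the 3-state stationary distribution comes from the Markov-chain
tree theorem; the shared `k_on` cancels.

*Exact CME*: the probability of a transcribing promoter state from the
stationary chemical master equation with integer copy numbers (the mRNA
dimension is dropped, `M_max = 0`, because the promoter marginal does not
depend on it).  Mean-field and exact activity agree to better than 2% at
$A_T = 100$ across the tested constant grid; the residual difference is a
genuine finite-copy-number effect.

`ec_thresholds()` locates EC90/EC10 — the loads where activity crosses
0.9 and 0.1 of its zero-load plateau — by grid bracketing plus bisection
on the continuous activity function (the piecewise-linear interpolant for
tabulated curves), and `effective_hill()` applies
$n_{\mathrm{eff}} = \log 81/\log(EC_{10}/EC_{90})$.  Thresholds are
*relative* to the zero-load plateau by default: a weak activator
($\tilde K_a = 10$) activates at most 9% of the time, so absolute
thresholds would be undefined for it, while its response *shape* is the
nearly linear titration profile with $n_{\mathrm{eff}} = 2$.  For strong
switches the plateau is ~1 and relative and absolute thresholds coincide.
Anchoring at the zero-load value (rather than the grid maximum) matters:
a log grid that misses the plateau would otherwise rescale silently.

Quantitative sensitivities for the titration designs are quoted at
$A_T = 1000$: the promoter-occupancy correction to the conservation laws
is $O(1/A_T)$, which is not negligible when the transition width is
itself ~1% of the load (the triple switch reads 136 at $A_T=100$ versus
176 at $A_T = 1000$, converging to its thermodynamic-limit value).

# The exact CME engine

`enumerate_states()` enumerates the reachable states under the
conservation laws — promoter state, complex count $n_{R\!A}$, free
repressor under turnover, and mRNA $m \le M_{\max}$ — and
`build_generator()` assembles the sparse generator with mass-action
propensities.  Transitions that would leave the truncated region are
dropped (reflecting truncation).  `steady_state()` solves $Qp = 0$ by
fixing the probability of the longest-dwell state and solving the
remaining sparse linear system by LU with iterative refinement (a
uniformized power iteration is the fallback), then verifies

* the residual $\lVert Qp\rVert_\infty < 10^{-10}$ relative to the
  largest exit rate (an absolute residual criterion is not scale
  invariant),
* non-negativity (entries above $-10^{-8}$ are clipped), and
* the truncation tail $P(m = M_{\max}) < 10^{-8}$ (and
  $P(r = R_{\max}) < 10^{-8}$ under turnover), doubling the truncation
  automatically until it holds.

$M_{\max}$ defaults to the constitutive Poisson bound
$\alpha/\beta + 10\sqrt{\alpha/\beta}$.  Doubling it changes means and
Fano factors by less than $10^{-6}$ at the operating points used in the
package, and the engine reproduces the Poisson and two-state telegraph
closed forms to $10^{-8}$ — those two models ship as
`constitutive_model()` and `telegraph_model()` precisely to pin the
engine against known answers.

`noise_summary()` reports mean, variance, Fano factor
($\sigma^2/\mu$; 1 for a Poisson gene), CV and the number of modes of the
mRNA marginal.  Modes are local maxima after merging equal-probability
plateaus, counted only when the peak carries at least $10^{-4}$
probability — below that floor, harmless ripples in a long tail would
register as modes.  Noise is compared across designs at each switch's own
EC90 (activation phase, "TAP") and EC10 (repression phase, "TRP"), and
summarized over whole phases by the trapezoidal area under the Fano
curve over $[0, EC_{90}]$ and $[EC_{10}, 2]$ (`fano_auc()`); the
integration range in load is a package convention, configurable through
`phase_windows()`.

# Stochastic simulation

`simulate()` is an exact direct-method Gillespie sampler (compiled;
R's RNG, so a seed fully determines the trajectory) returning the full
event log; `ssa_stationary()` streams the same simulation and returns
time-weighted stationary moments with batch-means standard errors (at
least 20 equal-time batches; the Fano standard error by the delta method
on the batch mean/second-moment pairs), plus dwell-time summaries per
promoter state.  Initial states are the free promoter with everything
unbound; the default 10% burn-in removes that transient rather than
attempting stationary-start sampling.  The package's standing
cross-validation is that SSA estimates agree with the exact CME within 3
standard errors at both operating points of all four presets.

Dwell times are the mechanistic story behind the noise rankings: at EC10
the strong sequestration switch holds a noise-induced $E_A$ state for
~17 mRNA lifetimes (hence bursts, a bimodal marginal and a large Fano
factor), blocking cuts that to ~2; at EC90 blocking's own failure mode —
a long-lived $E_R$ state, ~11 lifetimes — is cut to ~0.01 by
displacement.

# Matched-sensitivity comparisons

Raw noise comparisons between designs are confounded by their different
sensitivities.  `match_mean_curves()` removes the confound by tuning the
blocking constant $\tilde K_b$ of a target design (least squares on
$\log_{10}\tilde K_b \in [-4, 1]$) until its mean-mRNA curve
($\alpha/\beta$ times activity) matches a reference over the load grid.
Matching the blocking-only design to plain sequestration is degenerate —
$K_b \to \infty$ removes blocking entirely — and is flagged with a
boundary warning; matching the triple design is a genuine interior
optimum because displacement trades activation-phase gain against
repression-phase sharpness through $\tilde K_b$.  After matching, the
mean curves agree to within ~2% (over loads where the reference mean is
at least 10% of its maximum) and the triple switch shows the lowest
variance, Fano factor and CV across the transition region.

# Repressor turnover

Real repressor pools fluctuate.  The turnover variant replaces the fixed
pool with birth-death dynamics: production at `r_prod`, degradation at
`r_deg` per molecule, calibrated as `r_prod/r_deg = R_T` so the
stationary mean total matches the fixed pool it replaces.  Degradation
applies to the repressor wherever it sits — free, in $R\!A$, or on the
DNA — so the total pool is Poisson around $R_T$.  (Degrading only free
repressor, available as `deg_complex = FALSE`, pins the stationary mean of
the *free* pool at `r_prod/r_deg` instead, which saturates titration and
collapses every design to Michaelis-Menten sensitivity; it is kept as a
switchable variant, and the "fast cycling recovers the fixed pool" limit
is exercised with it on the cooperative reservoir model, the one case
where pool depletion by titration does not interfere.)

The default `r_deg = 1e-3` makes the repressor long-lived relative to
mRNA, the natural regime for a stable protein; pool fluctuations are then
quasi-static load noise.  Consequences at the presets
(`turnover_comparison()`, $A_T = 50$): sensitivity drops (e.g. 33 to 9
for strong sequestration — Poisson load spread $\sqrt{R_T}/A_T$ smears a
transition only a few molecules wide) and the mRNA *variance* rises at
both operating points.  The Fano factor at EC10 can fall, because
turnover raises the mean there faster than the variance; the package
therefore asserts the variance ordering, which is the robust statement.
Under turnover the activity/mean curves come from the exact promoter-level
CME with the extra free-repressor dimension; mRNA noise is estimated by
long-run SSA (the full CME with both repressor and mRNA dimensions is
larger than is worth solving here), and the matched-sensitivity
comparison re-matches $\tilde K_b$ on the turnover mean curves themselves
($A_T = 30$) before comparing noise — matching on the fixed-pool curves
and then switching turnover on leaves the designs with unequal means,
which would bias the mean-normalized measures.

# Deterministic ODE analysis

`ode_steady_state()` builds the mass-action ODE counterpart (promoter
occupancies as continuous fractions, conservation laws eliminated; 2-3
unknowns), finds all steady states by multi-start root solving, and
classifies each by the eigenvalues of the numerical Jacobian.  Across the
load grid the sequestration-family ODEs are monostable at the presets,
and the ODE mean agrees with the exact CME mean to better than 10% at
$A_T = 1000$.  The bimodal mRNA distribution of the strong-activator
switch during repression is therefore purely noise-induced — a mixture of
long-lived promoter states, not deterministic bistability.

# Problem sizes and numerical choices

Exact solves at the defaults involve 1e4-2e4 states (sparse LU,
about a second); scans (`scan_architectures()`, 4x4 grids of
$\tilde K_a \times \tilde K_s$ at $A_T = 40$) and the turnover analyses
($A_T = 30$-$50$) use reduced copy numbers chosen so the full analysis
suite runs in minutes while every qualitative conclusion is unchanged at
larger $A_T$.  SSA cross-checks use horizons of 3e4-3e5 time units
with fixed seeds.  Fixed-point iteration is damped 50/50 and converges
to $10^{-10}$; EC bisection stops at $10^{-6}$ in activity; scan cells
that fail (e.g. a switch too soft for the load window) are flagged
per-point, never fatal.

# What the synthetic conditions do and do not show

All results are model-based: a single gene copy, one shared association
rate constant, no translation or protein reporter layer, no feedback, no
cell division or extrinsic noise beyond the optional repressor turnover.
Passing tests demonstrate the mechanistic claims — which repression
mechanisms create or suppress noise, and why — under these controlled
conditions; they do not calibrate any real promoter.  Known limitations:
the displacement design's advantage depends on a thermodynamically driven
promoter cycle, so it costs free energy and its stationary state depends
on the kinetic splitting assumption; the cooperative model's repressor
reservoir ignores depletion (exact only when $R_T \gg 3$ or read as a
concentration); and mean-field activity is biased at small $A_T$, which
is why quantitative sensitivities are quoted in the large-copy limit.
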