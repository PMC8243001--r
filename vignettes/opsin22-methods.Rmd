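---
title: "The double two-state opsin model: simulation, fitting, and neuronal strength-duration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double two-state opsin model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(opsin22)
```

## The model and its assumptions

Channelrhodopsin photocurrents under sustained illumination show a fast
transient peak, decay onto a plateau as channels light-adapt, a
mono-exponential return to baseline after light-off, and slow (seconds)
recovery of the transient in the dark. `opsin22` represents this with two
independent first-order gates, in the spirit of the Hodgkin–Huxley sodium
channel: an open fraction $O \in [0,1]$ and a dark-adaptation conductance
factor $R \in [0,1]$,

$$ i \;=\; g\, G(V)\, O\, R\, (V - E), \qquad
   \frac{dO}{dt} = \frac{O_\infty(I) - O}{\tau_O(I,V)}, \qquad
   \frac{dR}{dt} = \frac{R_\infty(I) - R}{\tau_R(I,V)} . $$

$R$ is a linear transform of the physical dark/light-adapted populations
($R = 1$ fully dark-adapted, falling towards $1 - \mathrm{depth}$ under
light), which avoids introducing the light-adapted conductance as a separate
parameter. Key assumptions: the light response is **instantaneous** (no
activation intermediate, so responses to pulses shorter than the activation
constant are overestimated); no pH or ionic-concentration dependence (the
reversal potential must be adjusted by the user when ionic conditions
differ); the equilibria depend on irradiance only, voltage dependence being
carried by the rectification factor and the time constants.

### Dependency functions

All irradiance dependencies are logistics in $\log_{10} I$, bounded and
monotone as channel physics requires; $I = 0$ is defined by the limit of the
logistic (light-driven terms vanish):

* $\tau_O(I)$: falling logistic with dark limit `tauO_I[3]` (s);
* $\tau_R(I)$: biphasic falling logistic
  $p_1 (1 - p_2 L(p_3,p_4) - (1-p_2) L(p_5,p_6))$ — two light-dependent
  pathways, dark limit $p_1$;
* $O_\infty(I)$: rising logistic, 0 in the dark;
* $R_\infty(I)$: $1 - \mathrm{depth} \cdot$ rising logistic;
* $\tau_X(V)$: logistic in $V$; combined with the irradiance part by a
  product or a reciprocal sum (`combine_O`, `combine_R`). The reciprocal sum
  lets the voltage dependence dominate where the irradiance part is slow and
  vanish where it is fast, which matches the observed behaviour of the
  recovery versus inactivation constants for ChR2(H134R).
* $G(V)(V-E) = p_1(1 - p_2 e^{-(V-E)/p_3})$: the current is always computed
  in this algebraically cancelled form, so the removable singularity of
  $G$ at $V = E$ never arises numerically. $G$ itself is only evaluated for
  the sign constraint, and only on the experimental voltage grid — the
  published ChR2(H134R) rectification is slightly negative on a
  sub-interval of (0, 10) mV, so pointwise-continuous enforcement would
  reject a published fit.

Under voltage clamp and a rectangular pulse both gates are exact
mono-exponentials towards $(O_\infty, R_\infty)$ during the pulse and towards
$(0, 1)$ after it, giving the closed-form trace evaluated by
`photocurrent()`. The on-branch is closed at `t_off`, so the plateau
read-out equals the current at the pulse edge exactly. `simulate_clamp_ode()`
integrates the same equations with `deSolve::lsoda` (tolerances 1e-8/1e-10
by default) and serves as the closed form's independent cross-check and as
the route for non-rectangular light.

## Feature extraction

Seven features per stimulation condition drive the fitting: peak `i_peak`
(maximal deflection from the pre-pulse baseline), plateau `i_ss` (mean
magnitude over the last 5% of the on-phase — coincides with the edge sample
on noiseless data but is robust to noise), ratio `i_ratio`, and four time
constants from mono-exponential fits (`fit_monoexp`: bounded
Levenberg–Marquardt, analytic Jacobian, tolerances 1e-12, a deterministic
multistart of ten points plus a data-driven log-linear start). Segment
boundaries are onset-to-peak, peak-to-offset, and offset-to-end, each
dropping one guard sample after the edge; very short onset windows are
extended to four samples. The recovery constant is the dark interval at
which the second of two pulses reaches $1 - e^{-1}$ of the first peak,
interpolated monotonically (`monoH.FC`) across the interval grid.

These are approximations, not definitions: when $\tau_O \ll \tau_R$,
activation $\approx \tau_O(I,V)$, deactivation $\approx \tau_O(0,V)$,
inactivation $\approx \tau_R(I,V)$, and the recovery time rescaled by
$1/(1 - \ln\frac{1}{1 - I_{ratio}})$ approximates $\tau_R(0,V)$. The
relations degrade when the plateau is not reached within the pulse or the
time-to-peak is not large against $\tau_O$ — which the recovery-time
relation's validity conditions make explicit.

## The staged fitting procedure

1. **Targets.** `approximate_time_constant_targets()` maps the features to
   direct targets on the two $\tau$ surfaces using the relations above.
2. **Time constants.** `fit_time_constants()` fits each parametric surface
   by bounded multistart Levenberg–Marquardt on **relative** residuals —
   targets span ~0.2 ms to 10 s, and unweighted least squares would fit only
   the seconds-scale values. Starting points are the published initial
   vector, Latin-hypercube draws within the published bounds (2000 in paper
   mode, 50 in test mode), and a deterministic warm start that alternates
   between the intensity and voltage parts, each solved by a grid over the
   logistic shape parameters with the amplitude obtained linearly. The warm
   start matters at desk-scale budgets: the logistic surfaces have
   saturated, step-like local optima that trap generic starts.
3. **Equilibria and rectification.** `fit_equilibria()` minimizes the
   weighted RMS of peak/plateau/ratio residuals over conditions (weights
   10/20/50 for ChR2-class data, chosen to level feature magnitudes), with
   the model outputs computed from the closed form on the 0.15 ms evaluation
   grid. Constraints — the open-equilibrium saturation floor
   ($O_\infty > 0.6$ at 5500 W/m² for ChR2; a ceiling for non-saturating
   opsins), $G \ge 0$ on the experimental voltages, and the post-stimulus
   decay condition $R_\infty > 1 - \tau_R(0,V)/(\tau_R(0,V)+\tau_O(0,V))$ —
   enter as an exact quadratic penalty, and the returned point is verified
   feasible to 1e-6. A structured warm start pins $R_\infty$ from the ratio
   targets and separates $O_\infty$ from the rectification profile by a
   log-scale two-way decomposition over the irradiance-by-voltage grid.
4. **Target debiasing.** The extraction operators are multiplicatively
   biased estimators of the underlying constants (the activation window
   truncates at the peak; the plateau may not be reached). Fitting surfaces
   to raw targets applies that bias twice once the fitted model is itself
   measured by extraction. `debias_time_constants()` iterates to the fixed
   point of extraction-consistency: measure the current model with the same
   operators, divide the apparent-over-surface bias out of the targets,
   refit (two rounds by default; corrections outside a factor of 4 are
   distrusted and skipped). This stage is this package's own addition; it
   reduces the worst activation-constant recovery error on synthetic data
   from ~12% to under 5%.
5. **Swarm refinement.** `global_refine_pso()` optimizes all parameters in a
   box spanning 10% of the published bounds centered on the intermediate
   fit, clipped to those bounds. The cost extends the weighted RMS with the
   four time-constant terms, model features now **extracted from simulated
   traces by the same operations used on data** (single-pulse step 0.15 ms,
   two-pulse step 1 ms; a leaner single-start extraction with subsampled
   segments is used inside the swarm — identical operators, fewer starts,
   indistinguishable on noiseless traces). The swarm is a standard
   global-best PSO (inertia 0.7298, acceleration 1.49618/1.49618, reflecting
   walls, velocity clamped to half the box), seeded with the intermediate
   point and its coordinate-wise probes, so the refined fit can never be
   worse than the intermediate. Budgets: 1000 particles / 24 h in paper
   mode; 60 particles, 20 iterations, 2 minutes in test mode. The
   iteration cap is what makes seeded runs exactly reproducible; the
   wall-clock budget is checked at iteration boundaries and returns the best
   point so far with a flag.

Degeneracies are expected and accepted: the product of the conductance and
the rectification gain is identifiable but not its factors
(`normalize_conductance()` moves scale between them), and reciprocal-sum
time constants admit parameter trade-offs with identical surfaces. The
procedure's acceptance logic is therefore **feature recovery**: on noiseless
synthetic data from a known parameter set, the refitted model must reproduce
all seven features at every grid condition, not the generating parameters.

## Goodness of fit

`goodness_of_fit()` computes RMSE, RMSNE (1/target weights), RMSWE (the
fitting weights) and RMSZE (1/sd weights, only where target standard
deviations exist) per feature, and for grouped scopes (`all`, the four time
constants, the three current features) by summing the squared errors of the
grouped features per condition before the mean over conditions and the
root. The grouped mean is over conditions, not condition-feature pairs.

## The regular-spiking neuron and strength-duration analysis

The neuron is the classic regular-spiking cortical single-compartment
model: leak, transient Na and delayed-rectifier K with threshold-shifted
Traub kinetics, and the slow M-type K current that produces spike-frequency
adaptation (fixture: C = 1 µF/cm², g_leak = 0.0205, g_Na = 56, g_Kd = 6,
g_M = 0.075 mS/cm², E_leak = −70.3, E_Na = 50, E_K = −90 mV, V_T = −56.2 mV,
τ_max = 608 ms). Exactly which published fit of this cell the original
strength-duration numbers used is not recoverable, which is why the
package's comparisons to them carry a tolerance band. The opsin enters the
membrane equation with its model sign (negative = inward); simulations run
segment-wise between light edges with `deSolve::lsoda`, a 100 µs maximum
step and tolerances 1e-3/1e-6, through a compiled right-hand side (the
threshold searches below need hundreds of simulations). Spikes are upward
0 mV crossings with a 1 ms refractory rule; firing rates divide on-phase
spike counts by total on-time (a whole-window variant is exposed).

`build_sdc()` runs, for each of 15 log-spaced pulse durations over
1 ms – 1 s: a bisection on log-irradiance (bounds 0.1–1e6 W/m², 1% relative
tolerance) for the minimal irradiance producing a spike within one second
of the pulse, then a simulation at threshold whose opsin current is
integrated over the pulse-plus-one-second window and divided by the
duration (the temporal average current, TAC, reported as the inward
magnitude). The Hill–Lapicque curve
$TAC(PD) = I_{rheo}/(1 - e^{-PD \ln 2/\tau_{chron}})$ — the only form with
the correct limits, diverging at short durations and flattening to the
rheobase — and the empirical power mapping $I = a\,TAC^b + c$ are both fit
on **relative residuals**, because the thresholds span nearly two orders of
magnitude and absolute least squares lets the short-duration values pull
the fitted rheobase below the long-duration plateau that defines it.
Reported R² values are the ordinary adjusted ones (2 parameters for the
Hill–Lapicque fit, 3 for the mapping and for the composite
irradiance-versus-duration curve, whose parameter count is a convention the
source material leaves open — at 15 points the alternatives differ by
~0.02). The irradiance-domain rheobase and chronaxie follow in closed form
from the mapping and are exact inverses of the composition, which the test
suite verifies against a direct search.

## The synthetic-data generator

`generate_clamp_traces()` emulates the voltage-clamp study design the model
is meant for: single 0.5 s pulses (onset 50 ms, 0.3 s post window, 0.15 ms
sampling) over five log-spaced irradiances 1e2–1e4 W/m² by seven holding
potentials −80..+40 mV, plus two-pulse recovery series at the three highest
irradiances at −60 mV (conditioning and test pulses of 0.5 s, dark gaps
0.3–18 s, 1 ms sampling), with seeded additive white Gaussian noise at 1%
of the grid-maximal peak by default. Ground-truth features are measured
from the noiseless traces by the same extraction operators. What it does
*not* emulate: series-resistance and capacitive-transient artifacts,
coloured recording noise, cell-to-cell variability — so passing recovery
tests demonstrates correctness of the procedure under the model's own
assumptions, not robustness to every artifact of real recordings.

## Problem sizes and budgets used by the test suite

The shipped tests run the pipeline in test mode on the default noiseless
synthetic design (35 single-pulse conditions, 3 recovery series): 50/100
multistarts, 60 particles with a 20-iteration/2-minute swarm. The
closed-form/ODE agreement property uses 100 random parameter draws within
the published bounds (rejecting only draws whose time constants leave the
probe protocol numerically meaningless). The strength-duration analysis
always runs at full scale (15 durations) — with the compiled right-hand
side it takes seconds.

## Known limitations

* Instantaneous light response: sub-millisecond pulses overestimate the
  injected current; the strength-duration curve at the shortest durations
  inherits this.
* The empirical power mapping between average current and irradiance is an
  extrapolation-sensitive summary: its coefficients are strongly mutually
  correlated, and comparisons of individual coefficients across
  implementations are only meaningful when the exponent agrees.
* Equilibria carry no voltage dependence; opsins whose rectification does
  not absorb it will fit poorly.
* The fitting procedure assumes dark-adapted starts; paradigms with
  incomplete recovery between sweeps need explicit initial states
  (`photocurrent(init = ...)`).
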