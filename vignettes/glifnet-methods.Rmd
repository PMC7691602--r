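---
title: "Designing rate-coded spiking pathways: models, tuning rules, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing rate-coded spiking pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glifnet)
```

## The two models and why they are parallel

glifnet works with two neuron models that represent the same
computational object — a rate-coded node — at different levels of
abstraction.

The **non-spiking leaky integrator** holds a continuous depolarization
$\bar U$ (mV above rest) obeying
$$\bar C_{mem}\,\dot{\bar U} = -G_{mem}\bar U +
  \sum_i \bar G_{s,i}(E_{s,i}-\bar U) + I_{app} + I_{bias},$$
with graded synaptic conductance
$\bar G_s = \bar G_{max}\,\mathrm{clip}(\bar U_{pre}/R,0,1)$. Its
steady state is a conductance-weighted average of reversal potentials,
and a step input is followed with time constant
$\tau_{mem} = C_{mem}/(\sum_i G_{s,i} + G_{mem})$ — note that synaptic
conductance *loads* the membrane and enters the time constant.

The **GLIF spiking neuron** has the same membrane equation plus a
dynamic threshold $\theta$ that relaxes toward $\theta_0 + mU$ with
time constant $\tau_\theta$; when $U\ge\theta$ the membrane resets to 0
(the threshold is not reset). Spiking synapses jump to $G_{max}$ at
each pre-synaptic spike and decay with $\tau_s$.

Units everywhere: ms, mV above rest, nA, nF, $\mu$S, kHz. With these,
$C/G$ is in ms and $G\cdot V$ in nA, so no conversion constants appear.

The models are parallel in three ways, and each parallel is a closed
form in the package:

1. **Steady activation.** The GLIF steady frequency is
   $f_{sp} = -1/(\tau_{mem}\ln(1-\theta/U_\infty))$
   (`spiking_frequency()`), which is pinched between two lines of
   separation $1/\tau_{mem}$ (`frequency_bounds()`); with the bias rule
   below, frequency is nearly proportional to current, mirroring
   $\bar U_\infty \propto I_{app}$. Below threshold we define
   $f_{sp}=0$ rather than "undefined" so f–I curves are total
   functions usable in control loops.
2. **Transients.** With $m\ne 0$ the threshold value *at spike times*
   relaxes from $\theta_0$ to $\theta_\infty^*$ with effective constant
   $\tau_\theta^* = \tau_\theta/(1-m/2)$ (`threshold_transient()`), so
   the frequency transient mimics a non-spiking voltage transient of
   that time constant.
3. **Synaptic averaging.** Over one interspike period the spiking
   conductance averages to
   $G_{avg} = G_{max}\tau_s f(1-\delta)$ with
   $\delta = e^{-1/(f\tau_s)}$ (`average_conductance()`,
   `delta_nonlinearity()`): proportional to pre-synaptic frequency up
   to the controllable nonlinearity $\delta$.

## The spike-time threshold

For $m \ne 0$ the threshold at the moment of each steady-state spike,
$\theta_\infty^*$, solves an implicit equation with two printed
branches ($\tau_{mem}=\tau_\theta$ and the general case).
`solve_theta_star()` brackets the root in
$(10^{-9}U_\infty,\,(1-10^{-9})U_\infty)$ and uses Brent's method
(`uniroot`): the implicit function is positive near 0 (slope
$\propto\theta_0$) and equals $\theta_\infty - U_\infty$ at the upper
end, so a sign change exists exactly when steady spiking is possible;
absence of a bracket is reported as "cannot spike steadily". The
equal-$\tau$ branch is selected when
$|\tau_{mem}-\tau_\theta| < 10^{-6}\tau_\theta$: the general branch
contains the factor $\tau_{mem}/(\tau_\theta-\tau_{mem})$ multiplying a
difference of nearly equal powers, and in double precision it loses all
significant digits well before exact equality (we verified the two
branches agree to $10^{-3}$ at a relative $\tau$ separation of
$10^{-3}$, while at $10^{-7}$ separation the general branch's root is
numerically meaningless). The explicit approximation
$\theta_\infty^* \approx \theta_0/(1-m/2)$ (`theta_star_approx()`) is
the large-$U_\infty$ asymptote; the solver's root converges to it
monotonically as the drive grows, which the test suite checks on a
doubling grid.

## The design procedure

`design_pathway()` runs the tuning sequence for a two-node transmission
pathway with intended gain $k_{syn}$:

| step | parameter | rule | default result (flat / rising variant) |
|------|-----------|------|-----------------------|
| 1 | $F_{max}, R, \theta_0$ | network-wide constants | 0.1 kHz, 20 mV, 1 mV |
| 2 | $m$ | sign from desired transient | 0 / −5 |
| 3 | $\tau_\theta$ | $\bar\tau_{mem}(1-m/2)$ | — / 1750 ms |
| 4 | $I_{bias}$ | $G_{mem}\theta_0/(2-m)$ | 0.5 / 0.143 nA |
| 5 | $\tau_{mem}$ | $(R/F_{max})(1-m/2)/\theta_0$ | 200 / 700 ms |
| 6 | $\tau_s$ | $-1/(F_{max}\ln\delta)$, $\delta=1\%$ | 2.17 ms |
| 7 | $G_{max}$ | $k R/((E_s-kR)\tau_s F_{max})$ | 0.658 $\mu$S |

$\tau_s$ is set *equal to* its upper limit: the longest decay, hence
the smoothest post-synaptic drive, that stays inside the linearity
budget. Inhibitory pathways ($k_{syn}<0$ with $E_s<0$) use the same
algebra.

**Capacitance and conductance loading.** The design parameterizes
neurons by their time constant; capacitance is derived. Because
$\tau_{mem}$ is defined *with* synaptic loading, the pre-synaptic
(current-driven) neuron gets $C_{mem}=\tau_{mem}G_{mem}$ while the
post-synaptic neuron gets
$C_{mem}=\tau_{mem}(G_{mem}+\bar G_{max})$, where
$\bar G_{max} = kR/(E_s-kR)$ is its incoming average conductance at
the design point. This term is not cosmetic: the synaptic drive scales
with the driving force $E_s - U$, and a spiking membrane sits near
$\theta_0/2 \approx 0.5$ mV rather than at the non-spiking equivalent
voltage $kR = 20$ mV. Carrying the loading term through makes the two
effects cancel algebraically — per pre-synaptic spike the delivered
charge $G_{max}\tau_s(E_s - \langle U\rangle)$ equals the charge
$C_{mem}\theta_0$ needed for one post-synaptic spike — and the realized
gain lands on $k_{syn}$ exactly. Omitting it inflates the gain by
$E_s/(E_s-kR)\approx 1.13$ for the default design, which simulation
confirms.

```{r design}
d <- design_pathway(k_syn = 1, Es = 160, m = 0)
coef(d)
predict(d, Iapp = c(5, 10, 20))[, c("Iapp", "f_intended", "f_pre", "f_post")]
```

## Simulation scheme

`simulate_network()` (C++ core) integrates with forward Euler at
$\Delta t = \min_i(C_i/G_i)\times 10^{-4}$ ms by default — 0.02 ms for
the flat-transient design. Within a step: all membranes and thresholds
are updated from start-of-step state; spiking conductances decay by the
exact factor $e^{-\Delta t/\tau_s}$ (the linear decay has a closed-form
update, so it carries no truncation error); crossings $U\ge\theta$ are
detected at end of step; crossed membranes reset and outgoing
conductances jump to $G_{max}$. A conductance set at a spike first
affects its target on the next step — one $\Delta t$ of synaptic
latency, vanishing as $\Delta t \to 0$. One spike per neuron per step
is possible at most; an instability guard aborts if any $|U|$ exceeds
$10^4$ mV. Adaptive stepping is deliberately out of scope: threshold
crossings make the dynamics discontinuous, and fixed small steps keep
spike-time discretization error (first order in $\Delta t$, checked by
a halving test) below the tolerances of every comparison we make.

Initial conditions follow the convention $U(0)\sim\mathcal U[0,\theta_0]$
per spiking neuron (non-spiking neurons start at rest), which
desynchronizes identical neurons. **Reset noise** (optional, default
off) perturbs the post-spike potential with symmetric Gaussian noise.
We do not clip the noise at zero: clipping a centered Gaussian shifts
the mean reset by $+0.4\,\mathrm{sd}$, which biases the firing rate
(about $+4\%$ at sd $=0.1$ mV for the default design) and would corrupt
the very calibration the noise is meant to leave intact; a slightly
hyperpolarized reset is physiologically unremarkable.

All randomness flows from R's RNG, so a single `seed` makes any run —
including the C++ core's reset noise — bit-reproducible.

## Population pathways and what the scaling experiment shows

`build_population_pathway()` expands a design into two all-to-all
populations ($N^2$ synapses). Two rules distribute the designed
$G_{max}$ over each post-synaptic neuron's $N$ incoming synapses:

* `normalized` (constructor default): uniform weights rescaled so each
  neuron's total is exactly $G_{max}$. Every neuron then matches the
  analytic predictions individually; at $N=1$ this degenerates to the
  single designed synapse.
* `raw_uniform`: i.i.d. draws from $\mathcal U(0, 2G_{max}/N)$ — totals
  correct in expectation, varying per neuron, concentrating as
  $1/\sqrt N$.

`population_experiment()` uses `raw_uniform` by default, and this
choice deserves explanation. Under the normalized rule the
deterministic $N=1$ pathway is essentially *perfect*: the post-synaptic
neuron phase-locks 1:1 to its pre-synaptic partner, and we measured
steady encoding errors below $0.1\%$ — population averaging has nothing
left to improve, and the interesting claim "more neurons encode more
accurately" would be vacuous. Heterogeneous per-neuron totals are what
give the population something to average over; with them the experiment
shows strong, monotone improvement of both the population-mean encoding
error and the spread of single-neuron rates as $N$ grows, alongside the
(split-independent) smoothing of the instantaneous population rate.
Because the within-trial spread is identically zero at $N=1$ (one
neuron), the spread statistic pools single-neuron mean rates across the
trials at each $N$.

Experiment conditions (the package's defaults): $I_{app}=5$ nA — the
low-rate regime where single-neuron transmission artifacts are most
severe — 2000 ms per trial with a 500 ms burn-in, 10 trials per $N$,
$N\in\{1,5,10\}$. At 0.025 kHz this gives roughly 35 steady-state
interspike intervals per neuron per trial, enough to estimate a mean
rate to well under the effect sizes being compared.

**Transmission artifacts.** With marginal per-pulse charge (the
designed operating point) plus reset noise, a single post-synaptic
neuron occasionally fails to fire for a pre-synaptic spike; the
interspike interval then doubles, which `count_frequency_drops()`
detects as intervals $>1.5\times$ the median. The artifact is reliably
present at $N=1$ and vanishes for $N=10$, whose summed asynchronous
inputs drive the membrane smoothly.

## The transient-decay measurement

For the rising-transient design the theory says the smoothed frequency
transient decays with constant $\bar\tau_{mem}$ (500 ms by default).
The measured instantaneous-frequency residual is *not* a clean
exponential: frequency is a nonlinear function of the decaying
spike-time threshold, so early residuals (threshold still near
$\theta_0$, 3.5× its asymptote) decay with a shallower apparent slope.
The fitting procedure therefore uses the late phase, where the map is
locally linear: residuals between 2% and 50% of the transient
amplitude, log-linear least squares (`fit_decay_tau()`). On the default
design this yields ≈530 ms, and fitting the spike-time thresholds
themselves yields ≈492 ms.

## The reflex demonstration and its stand-in plant

`run_reflex_scenarios()` closes the loop around a deliberately simple
mechanical plant (all equations in `R/reflex.R`): a damped rotational
joint (inertia 63000, damping 1500) driven by an antagonist muscle pair
with moment arm 1; each muscle produces
$F = a\,F_{active} + k_{pas}\max(L-L_0,0)$ with first-order activation
dynamics ($\tau_{act}=20$ ms, $F_{active}=7$, $k_{pas}=10$). Flexor
stretch is encoded as $I_{app}=\mathrm{clip}(40\,s, 0, G_{mem}R)$ and
the pathway's output activation ($f/F_{max}$ or $\bar U/R$) drives the
flexor. Neural and mechanical dynamics are co-simulated with
zero-order-hold coupling at 1 ms.

The plant parameters were chosen once so that (a) the open-loop
extensor pulse deflects the joint by about 0.7 rad, and (b) the
fastest closed loop — the non-spiking pathway with a 10 ms time
constant — is stably damped: with substantially lighter damping the
activation lag ($\tau_{act}$) destabilizes the gain-1 reflex into a
limit cycle, which would confound the fluctuation comparison between
scenarios. Because the plant is a stand-in, only *ordinal* claims are
asserted anywhere: closed-loop peak extension below open-loop;
steady-hold force fluctuation ordered single-spiking > population >
non-spiking; slow-transient ($m=-5$) variants overshooting their
flat-transient twins. No absolute angle is a target. Steady-hold
fluctuation is measured over the final 500 ms of the (2250 ms) extensor
pulse, after the settling motion has died out.

For the $m=0$ variant the non-spiking comparison pathway uses a 10 ms
membrane time constant: the flat-transient spiking design has no
frequency transient to match, so the non-spiking analog is simply
"fast relative to the plant"; any value well below the plant's
~300 ms period gives indistinguishable trajectories.

## What the synthetic experiments do and do not show

Every quantitative statement in the tests is about this model class:
deterministic GLIF dynamics, conductance synapses with single-
exponential decay, identical neurons within a population, stationary
step inputs, and (where enabled) Gaussian reset noise as the only
stochasticity. Real neurons have refractory periods, channel noise,
heterogeneous parameters, and synaptic depression, none of which are
modeled; passing tests show that the *design algebra* is internally
consistent and that its predictions survive numerical integration, not
that a biological circuit tuned this way would hit the same numbers.
The frequency range (≤0.1 kHz), voltage convention (0 = rest) and the
interpretation of $E_s=160$ as mV above rest are fixed choices of the
design examples.

## Problem sizes

The test suite and validation battery use: single-pathway runs of
2–6 s simulated time at $\Delta t = 0.02$–0.07 ms; the population
experiment at $N\in\{1,5,10\}$ × 10 trials × 2 s; and eight reflex
scenarios of 3.5 s at 1 ms coupling. Each reflects a point of
diminishing returns: doubling any of them changes the measured
statistics by less than the assertion margins.
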