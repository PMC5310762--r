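---
title: "Modelling coupled calcium and IP3 oscillations in HSY cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coupled calcium and IP3 oscillations in HSY cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsycalcium)
```

## The system and the model

HSY cells, a human salivary duct cell line, respond to external agonists
(ATP, carbachol) with repetitive baseline spikes of cytosolic calcium,
accompanied by oscillations of IP3 in which each calcium peak slightly
precedes the following IP3 peak. The model implemented here treats those
oscillations as a *class I* mechanism: the oscillator proper is calcium
feedback on the IP3 receptor (IPR), while the IP3 oscillations are a
passive echo through calcium-activated phospholipase C that modulates —
but does not create — the rhythm.

The cell is divided into three well-mixed compartments: the cytosol
(calcium concentration $C$), the ER (concentration $C_{ER}$), and a small
*microdomain* around a cluster of IPR (concentration $C_b$) through which
all IPR flux transits before diffusing into the bulk cytosol. Total free
calcium in cytosolic-volume units is
$C_t = C + C_b/\gamma_1 + C_{ER}/\gamma_2$, with volume ratios
$\gamma_1 = 100$ and $\gamma_2 = 10$, so the ER concentration is recovered
algebraically as $C_{ER} = \gamma_2 (C_t - C - C_b/\gamma_1)$
(`compute_CER()`).

The state vector is $(C, C_t, C_b, P, m_{42}, h_{42}, P_s)$, where $P$ is
IP3, $m_{42}, h_{42}$ are the slow activation and inactivation gates of
the IPR, and $P_s$ is photoreleased IP3 present only in uncaging
protocols:

$$
\begin{aligned}
dC/dt &= J_{diff} + J_{leak} - J_{SERCA} + \epsilon\,(J_{in} - J_{pm}),\\
dC_t/dt &= \epsilon\,(J_{in} - J_{pm}),\\
dC_b/dt &= \gamma_1 (J_{IPR} - J_{diff}),\\
dP/dt &= V_{plc} - r_{deg} P,\\
dm_{42}/dt &= \lambda_{m42}(m_{42\infty} - m_{42}),\qquad
dh_{42}/dt = \lambda_{h42}(h_{42\infty} - h_{42}),\\
dP_s/dt &= V_{s\_plc}(t) - r_{s\_deg} P_s .
\end{aligned}
$$

$\epsilon \in \{0, 1\}$ switches between the closed-cell model (no plasma
membrane fluxes, $C_t$ constant) and the open cell. Fluxes are standard
forms: linear IPR release and microdomain drainage, a Hill-1.75 SERCA
pump, a Hill-2 PMCA pump, and plasma-membrane entry composed of a basal
leak, receptor-operated entry proportional to total IP3, and
store-operated entry falling off with the fourth power of $C_{ER}$
(`compute_fluxes()`).

### IPR gating

The IPR model has two modes: a *park* mode (essentially closed) and a
*drive* mode whose internal open/closed rates $q_{26} = 10500$,
$q_{62} = 4010\ \mathrm{s^{-1}}$ give a drive-mode open probability
$q_{26}/(q_{26}+q_{62}) \approx 0.72$. Mode switching rates
$q_{24}$ (drive to park) and $q_{42}$ (park to drive) depend on IP3
through eight coefficient functions (`gating_coefficients()`), on
microdomain calcium through the slow gates $m_{42}, h_{42}$, and on
*pore* calcium $C_p = C_{p0}\,(C_{ER}/C_{ER,ref})$ through
quasi-equilibrated closing gates (`gating_equilibria()`). With the mode
occupancy $D$ of the drive mode, the whole-cluster open probability is
$O_{IPR} = D\, q_{26}/(q_{26}+q_{62})$ (`open_probability()`). The slow
gate relaxation rates ($\lambda_{m42} = 1\ \mathrm{s^{-1}}$,
$\lambda_{h42}$ a $D$-weighted combination of $L = H = 0.1\
\mathrm{s^{-1}}$) set the tens-of-seconds period scale; the general
$(1-D)L + DH$ form is kept even though the defaults make it constant.

### IP3 dynamics and photorelease

IP3 is produced by agonist-stimulated PLC$\beta$ (saturating in the
agonist dose $\nu$, half-max $K_\nu = 45$ µM) and calcium-stimulated
PLC$\delta$ (Hill-4 in $C$, half-max $K_{plc} = 0.8$ µM), and degraded at
a constant rate $r_{deg} = 1.4\ \mathrm{s^{-1}}$ (`ip3_production()`).
Setting $\psi_2 = 0$ severs the calcium-to-IP3 coupling.

Photoreleased IP3 ($P_s$) behaves like IP3 everywhere it acts — the IPR
coefficient functions and receptor-operated entry use the total
$P + P_s$ — but is produced only by light: either a square pulse
($M$, onset $t_0$, duration $\Delta$, with the Heaviside convention that
the rate is exactly zero at both endpoints) or continuous low-level
uncaging at $k_{s\_plc}$ (`uncaging_rate()`). Its slow decay
($r_{s\_deg} = 0.006\ \mathrm{s^{-1}} \ll r_{deg}$) makes pulse effects
long-lived. Under constant uncaging $P_s$ has the exact solution
$\bar P_s (1 - e^{-r_{s\_deg} t})$ with
$\bar P_s = k_{s\_plc}/r_{s\_deg}$ (`ps_analytic()`), which the test
suite uses as an oracle against the integrator (agreement to
$10^{-6}$ µM).

## Protocols

Each virtual experiment is a contiguous schedule of parameter overrides
(`make_protocol()`), integrated segment by segment with the integrator
restarted at every boundary so that parameter switches and pulse edges
remain instantaneous (`simulate_protocol()`). Within a pulse window the
Heaviside product equals $M$ everywhere except at the two endpoints, so
the segment integrates a constant rate between exact restarts — identical
to integrating the discontinuous product. All runs start from the
unstimulated resting state, computed by relaxation plus damped Newton
refinement to $\max|{\rm rhs}| \le 10^{-10}$ (`find_resting_state()`);
closed-cell runs re-equilibrate under $\epsilon = 0$ at their fixed
$C_t$, a documented choice where either convention is defensible.

The seven protocols are: agonist steps (including stepwise
$\nu$ schedules), the closed cell, calcium-free medium ($J_{in} = 0$
after a cut time), a photoreleased-IP3 pulse, PLC inhibition during
continuous uncaging (stepwise reduction of $\psi_2$ and, to represent the
side effect of the inhibitor on SERCA, of $V_S$), uncaging after full
inhibition, and a long-run scan used to measure stable periods as a
function of $(\psi_2, V_S, k_{s\_plc})$.

```{r, eval = FALSE}
traj <- simulate_protocol(make_protocol("agonist_step", nu = 15))
m <- oscillation_metrics(trajectory_spikes(traj, "C"),
                         window = c(300, 600), last_n = 5)
m$mean_period  # about 62 s
```

## Trace analysis

`detect_spikes()` finds local maxima at least `min_prominence` above a
running baseline (10th percentile in a window of 1.5 median interpeak
spacings), separated by `min_separation`, and refines each peak time by
quadratic interpolation through the three samples around the maximum —
sub-sample accuracy that matters because the calcium-to-IP3 peak lag is
two orders of magnitude smaller than the period.

Estimator choices, where a definition had to be fixed:

* **Period** (`oscillation_metrics()`): mean of successive peak
  differences, by default over the last five complete cycles of the
  analysis window, which suppresses residual transient drift.
* **Peak delay** (`peak_delay()`): each calcium peak is matched to the
  nearest subsequent IP3 peak within half a period; with delays below a
  second and periods near a minute the pairing is unambiguous.
* **Transient frequency change** (`transient_frequency_change()`): the
  interspike interval immediately before the intervention versus the one
  immediately after it. The accelerations caused by a pulse or by a PLC
  inhibition step decay within two to three spikes, so any longer
  post-window averages the effect away; moreover the pulse protocol has
  only two pre-pulse intervals, ruling out longer symmetric windows. Both
  window lengths are arguments.
* **Termination** (`termination_time()`): the last peak time, accepted
  only if no further peak occurs within a 300 s horizon inside the
  simulated record.
* **Oscillatory classification** (`is_oscillatory()`): at least three
  spikes of amplitude 0.05 µM over baseline in the analysis window — far
  below the model's µM-scale spikes, so the call is threshold-insensitive.

## Numerical choices

The system is integrated with `deSolve`'s `lsoda` at `rtol = 1e-8`,
`atol = 1e-10`; `lsoda` switches to a stiff (BDF) method automatically,
which this system needs during spikes (the microdomain equation carries a
$\gamma_1 k_{diff} \sim 10^3\ \mathrm{s^{-1}}$ rate). A cross-check with
`radau` at `rtol = 1e-9` reproduces peak times to within the output
resolution. States are never clipped: the right-hand side signals an
error if $C$ or $C_{ER}$ falls below $-10^{-9}$, so parameter mistakes
surface instead of being hidden. Default output steps are 0.01 s for the
protocols used to measure sub-second peak delays and 0.05 s elsewhere.

Problem sizes: agonist-step and pulse runs use 600 s of simulated time
and measure steady cycles after t = 300 s; the calcium-free run uses
2500 s. The *stable* periods of the continuous-uncaging scan need far
longer runs: total calcium is the slowest variable, and its drift
re-shapes the orbit for roughly $10^4$ s, so stable-period measurements
integrate 15 000 s and average the last five cycles (the period at
2500 s is still ~15 % below its converged value — a transient, not a
different answer).

## The synthetic-trace generator

`generate_trace()` emulates the layout of frame-indexed fluorescence
recordings — frame number, time in minutes, signal, and a
piecewise-constant condition label — with a known ground truth: spikes
with instantaneous rise and exponential decay (time constant 0.15 of the
local period) are laid on a drifting baseline with Gaussian noise, under
a piecewise-constant period and amplitude schedule, deterministically
from a seed. It emulates what the analysis needs from real recordings
(baseline spikes, known peak times, condition switches) and deliberately
not what it does not: dye binding kinetics, photobleaching,
cell-to-cell variability, or sampling jitter. Passing recovery tests on
these traces therefore validates the estimators, not the realism of any
particular microscope.

## Known limitations

* The model is deterministic and whole-cell; stochastic channel gating
  and spatial calcium waves are out of scope.
* The calcium-to-IP3 peak delays the model produces at the default
  parameters (about 0.71 s at $\nu = 15$ µM, 0.78 s at $\nu = 20$ µM, as
  computed by `scripts/acceptance.R`) are robust to integrator choice and
  tolerance, and should be read as properties of the printed parameter
  set; sub-0.1 s features are sensitive to parameter precision beyond
  what the constants' significant digits pin down.
* Calcium-free depletion of total calcium is monotone but algebraically
  slow (PMCA extrusion falls off quadratically as $C$ declines), so
  complete store depletion lies far beyond the simulated horizons used
  here.
* The closed-cell oscillatory band in $C_t$ at $\nu = 15$ µM has a sharp
  lower edge near 67 µM but extends beyond 90 µM in simulation; the band
  edges depend on basin structure near the bifurcations and on the
  classification threshold.
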