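---
title: "Methods: a spiking basal ganglia model with action-selection benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking basal ganglia model with action-selection benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bgspike)
```

## The model

`bgspike` simulates the primate basal ganglia as a network of leaky
integrate-and-fire (LIF) neurons spanning five nuclei — striatal medium
spiny neurons (MSN) and fast-spiking interneurons (FSI), the subthalamic
nucleus (STN), and the external and internal globus pallidus (GPe, GPi) —
driven by three afferent populations modelled as Poisson generators:
cortico-striatal neurons (CSN, 2 Hz baseline), pyramidal-tract neurons
(PTN, 15 Hz) and the centromedian/parafascicular thalamus (CM/Pf, 4 Hz).

Resting potentials are shifted to zero, so each neuron follows

$$\tau_m \frac{dV}{dt} = -V + V_{in}(t), \qquad
V_{in}(t) = V_C + \sum_{j} \gamma_j \rho_j \sum_{n,s}
f_{\alpha_n}\!\left(t - (t_j^s + \delta_j)\right),$$

spiking when $V \ge \theta$, resetting to 0 and staying clamped for the
2-ms refractory period (synaptic kernel states keep evolving through
refractoriness).  Synapses are *voltage drives*: each presynaptic spike
adds an alpha-function post-synaptic potential

$$f_{\alpha_n}(t) = s_n A_n \frac{t}{\tau_n} e^{1 - t/\tau_n},$$

with amplitude $A_n$ (AMPA 1 mV, NMDA 0.025 mV, GABA$_A$ $-0.25$ mV) and a
time constant derived from the documented half-time $D_n$ (AMPA/GABA$_A$
5 ms, NMDA 100 ms).  Glutamatergic contacts trigger the AMPA and NMDA
kernels together; GABAergic contacts trigger GABA$_A$.

**Half-time interpretation.**  "Half-time" admits two readings.  The
package default reads $D_n$ as the decay time from the kernel
peak to half of the peak, giving $\tau_n = D_n/(u^*-1)$ where $u^*\approx
2.678$ solves $u\,e^{1-u} = 1/2$; the alternative reading $\tau_n =
D_n/\ln 2$ is selectable with `half_mode = "log2"` in `run_network()`.
The default is used everywhere in the tests.

**Dendritic attenuation.**  Dendrites are single-compartment finite cables
with sealed ends.  A dendrite of length $l$ (µm) and diameter $d$ (µm)
with intracellular resistivity $R_i = 200\ \Omega$cm and membrane
resistance $R_m = 20{,}000\ \Omega$cm$^2$ has electrotonic length
$L = l\sqrt{(4/d)(R_i/R_m)}$ (after µm→cm conversion), and a synapse at
fractional position $p$ is attenuated by
$\gamma = \cosh(L(1-p))/\cosh(L)$.  For the MSN dendrite ($l = 619$ µm,
$d = 1$ µm), $L \approx 1.238$ and a distal synapse at $p = 0.9$ has
$\gamma \approx 0.539$.

## From anatomy to a realized network

The wiring carries 12 internal projections (MSN→{MSN, GPe, GPi},
FSI→{MSN, FSI}, STN→{MSN, FSI, GPe, GPi}, GPe→{STN, GPe, GPi}) and 10
afferent ones (CSN→{MSN, FSI}, PTN→{MSN, FSI, STN}, CM/Pf→all five).  The
expected synapse count per target neuron is
$\nu_{Y\to X} = P_{Y\to X}\,(n_Y/n_X)\,\alpha_{Y\to X}$, from the bouton
count $\alpha$, the projecting fraction $P$ and the population sizes.  Each
target draws $\nu/\rho$ *distinct* presynaptic partners (the fractional
part is a probability of one more), where the redundancy $\rho = 3$ is the
number of contacts one axon makes on one dendritic field.  Redundancy is
implemented as a weight multiplier $w = \gamma\rho$ on a single synapse
row rather than $\rho$ duplicate rows — the PSP summation is linear, so
the dynamics are identical and the tables three times smaller.

Projections are *focused* (source pool restricted to the target's channel)
or *diffuse* (all channels).  Defaults: STN and CM/Pf efferents diffuse,
everything else focused, which realizes the off-centre/on-surround
MSN/STN→GPi motif.  CSN and PTN have one 12,000-generator pool per
channel; CM/Pf has a single shared 12,000-generator pool.  Where the
anatomical tables give only a location interval for $p$, the midpoint is
used; projections with no documented interval (FSI→FSI, STN→MSN, STN→FSI,
PTN→FSI, CM/Pf→{STN, GPe, GPi}) default to the full dendrite, midpoint
0.5, and the undocumented PTN→STN bouton count defaults to the 0–1 range
of the other sparse STN afferents.  All of these are configurable.
Self-connections are excluded in MSN→MSN, FSI→FSI and GPe→GPe (autapses
are undocumented; conservative default).  Per-projection delays default to
1 ms everywhere; distance-resolved delay tables are out of scope.

## Numerical scheme

The simulator is clock-driven at `dt = 0.1` ms (configurable).  Each alpha
kernel is integrated exactly as a pair of first-order states sharing
$\tau_n$, and the membrane uses the exact exponential propagator with
$V_{in}$ held constant over one step, so the only discretization errors
are the spike-time rounding to the step grid and the stepwise-constant
input assumption.  A deterministic neuron driven at constant $V_C$ fires
within 2% of the closed form
$\mathrm{ISI} = t_{ref} + \tau_m\ln(V_C/(V_C-\theta))$ at the default
resolution, and halving `dt` moves deterministic rates by well under 2%.
Poisson generators emit Bernoulli($r\,dt$) events per step, which for
$r\,dt \le 0.005$ is indistinguishable from a Poisson process at the
tested tolerances.  All randomness flows through R's RNG, so a build seed
plus a run seed reproduce a simulation exactly.

## Desk-scale populations

Reference populations (per channel: MSN 10,576, FSI 212, STN 32, GPe 100,
GPi 56; channels are 1/5000 of each nucleus) are too large for routine
testing, so `scale_populations()` shrinks every population and input pool
by a common factor while rescaling bouton counts so each neuron's
expected in-degree $\nu$ — and hence its mean synaptic drive — is
preserved exactly through the rounding.  The package test-suite uses
scale 0.02 for most dynamical checks (about 660 neurons, 180k synapses)
and 0.05 for the disruption benchmarks, where at least two STN neurons
per channel are needed for a *focused* subthalamic projection to be
meaningful; the command-line default is 0.05.  When a shrunken pool
cannot supply the requested number of distinct partners, sampling falls
back to with-replacement and warns — expected at these scales for the
FSI and pallidal pools.  Scaled networks preserve mean drives but not
finite-size fluctuation statistics: per-neuron input correlations are
stronger than at reference scale, so desk-scale tests establish
directions and invariants, not quantitative rate predictions at
reference scale.

## Tonic inputs and calibration

LIF neurons are silent without input, so each nucleus receives a constant
tonic potential $V_C$ — the degrees of freedom added by the translation
from a population-level model.  `hypersphere_calibrate()` implements the hypersphere-centre
procedure: evaluate the physiological score $F$ (the number of
satisfied firing-rate interval comparisons, 14 with the default battery:
5 rest rates plus 9 simulated antagonist injections in GPe/GPi) on a grid
of $V_C$ vectors, and return the feasible point furthest from its nearest
infeasible grid point — the centre of the largest ball inside the
feasible domain.  The ball is Euclidean in grid units by default; the
axis-aligned (Chebyshev) cube reading is also available.  Ties break
toward the feasible median, then lexicographically.  A caveat found while testing: a feasible region
touching the grid boundary has no infeasible neighbours beyond it, which
biases the recovered centre toward the edge — calibration grids should
extend at least one step beyond the plausible region on every axis.

The packaged default $V_C$ (MSN 21, FSI 2.5, STN 11, GPe 0, GPi 7 mV) was
fixed by one coarse calibration pass of this machinery against
physiological rest-rate ranges (MSN 0.05–1 Hz and FSI 7.8–14 Hz are the
two documented intervals; STN ≈ 15–25, GPe ≈ 50–70, GPi ≈ 60–80 Hz were
used as ballparks) and gives rest rates of roughly 0.2, 13, 22, 50 and
72 Hz at scale 0.02.  Only the MSN and FSI intervals are shipped as
constants; all other plausibility intervals must come from a user table,
and `make_fixture()` generates synthetic tables (±20% around a pilot
run's own rates) so that every calibration and scoring path is testable
without external data.

## Selection benchmarks

A two-channel competition maps each channel's salience $s \in [0,1]$
linearly onto its activated cortical subsets (500 CSN: $2 \to 20$ Hz;
500 PTN: $15 \to 46$ Hz; subset sizes are reference-scale counts and
shrink with the population scale), with a third channel at baseline and
CM/Pf constant.  Selection is read from the GPi:
$e_i = \max(0, 1 - y_i/y_{rest})$ per channel, winner efficiency
$e_w = \max_i e_i$, distortion $d_w = (\sum_i e_i - e_w)/\sum_i e_i$
(undefined, reported `NA`, when no channel is selected).  Grid sums
$e_\Sigma = \sum e_w$ and $d_\Sigma = \sum d_w$ summarize a model; on the
default 11×11 grid the best possible outcome is $e_\Sigma = 121$ (every
condition fully selecting its winner, $e_w = 1$) with $d_\Sigma = 0$ —
the bound `scripts/acceptance.R` re-derives.  $e_\Sigma$ sums the
*winner* efficiency per condition; summing all $e_i$ would make the
printed optimum unreachable on this grid, which settles the ambiguity in
favour of $e_w$-summation.  The winner label is "both" when
$|e_1-e_2| < 0.1$ (absolute rule; a 5%-relative variant is selectable).

Disruption benchmarks compare the intact circuit against: MSN→MSN and
FSI→MSN inhibition replaced by equal numbers of independent Poisson
processes at the population's measured rest rate (independence per
synapse is assumed; shared-rate generators are not modelled), and the
diffuse STN→GPi / STN→GPe projections rebuilt as focused.  The CM/Pf
sweep repeats the grid at 4–7 Hz thalamic drive.  Input-sensitivity
sweeps stimulate one population at several subset sizes and rates and
classify each nucleus's response as up/down/flat by a pooled linear
regression over ≥ 3 seeds: a trend is directional when the fitted change
across the span exceeds `max(0.1 Hz, 10% of baseline)` and every
per-seed slope agrees in sign.  The 0.1-Hz floor (rather than 0.5 Hz) is
deliberate: MSN rest rates are a few tenths of a hertz, so their entire
dynamic range under thalamic drive is below half a hertz, yet the pooled
estimates resolve it comfortably — a 0.5-Hz floor would classify the
striatal trends as flat by construction.

## Known limitations

* NMDA kernels have no voltage dependence, and synapses drive potentials,
  not conductances: the model is a voltage-drive formalism by design.
* All neurons of a nucleus share $\theta$, $V_C$, in-degree and dendrite
  geometry, so rate and CV distributions are narrower than in vivo.
* No specific optimized per-model parameter set is shipped;
  `sample_parameterization()` draws uniformly within the documented
  plausible ranges instead, and fixtures are labelled synthetic.
* Spectra are single-window FFTs of the summed population spike counts
  (1-ms bins, mean-subtracted, no taper) with band maxima for
  δ 2–4, α 8–12, β 12–35 and γ 35–128 Hz; per-neuron averaging and
  multitaper estimation are not implemented.
* Axonal delays are a single per-projection constant (default 1 ms), so
  delay-structured oscillation phenomena are only qualitatively present.
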