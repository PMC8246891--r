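# bgspike

A spiking (leaky integrate-and-fire) network model of the primate basal
ganglia with action-selection benchmarks.

## What it is for

The basal ganglia — striatum (medium spiny neurons, MSN, and fast-spiking
interneurons, FSI), subthalamic nucleus (STN) and the external/internal
globus pallidus (GPe, GPi) — are widely hypothesized to select among
competing actions by disinhibiting one "channel" of their tonically
active output nucleus, the GPi.  `bgspike` is for computational
neuroscientists who want to build such a circuit from *anatomical*
parameters (bouton counts, projecting fractions, dendritic synapse
locations), check it against *physiological* firing-rate constraints
(rest rates and simulated antagonist-injection experiments), and then
benchmark its selection behaviour without assuming the function in the
construction.

The core pieces:

* **Anatomy → network.** In-degrees follow
  `nu = P * (nY/nX) * alpha`; each target neuron draws `nu/rho` distinct
  presynaptic partners (redundancy `rho = 3` contacts per axon), from its
  own channel (focused projections) or all channels (diffuse: STN and
  CM/Pf efferents).
* **Synapses.** Voltage-drive alpha-function PSPs
  `f(t) = s A (t/tau) exp(1 - t/tau)` per receptor (AMPA, NMDA, GABA_A),
  attenuated by the passive-cable factor
  `gamma = cosh(L(1-p)) / cosh(L)`, `L = l sqrt((4/d)(Ri/Rm))`.
* **Dynamics.** LIF with `tau_m dV/dt = -V + V_C + sum(PSPs)`, exact
  exponential stepping at 0.1 ms, 2-ms refractoriness, Poisson cortical
  (CSN, PTN) and thalamic (CM/Pf) afferents.
* **Calibration.** Tonic inputs `V_C` are searched on a grid for the
  centre of the largest ball of settings that satisfy all 14
  physiological comparisons (5 rest rates + 9 receptor-block conditions).
* **Selection metrics.** Per-channel efficiency
  `e_i = max(0, 1 - y_i/y_rest)` of GPi suppression, winner efficiency
  `e_w`, distortion `d_w = (sum e - e_w)/sum e`, and grid sums
  `e_sum`/`d_sum` over an 11x11 salience grid, plus circuit-disruption
  and CM/Pf-sweep benchmarks.

## Worked example

Build a desk-scale (2%) network from the midpoint parameterization,
simulate rest, and run one two-channel competition:

```r
library(bgspike)

param <- scale_populations(bg_param(), 0.02)
net   <- build_network(param, seed = 1)
rest  <- run_network(net, duration = 1500, warmup = 500, seed = 1)
rate_summary(rest)
#>   nucleus    rate_hz
#> 1     MSN  0.2720126
#> 2     FSI 12.5833333
#> 3     STN 22.3333333
#> 4     GPe 46.8333333
#> 5     GPi 71.6666667
```

MSNs are near-silent (a few tenths of a hertz), FSIs fire around 13 Hz,
and STN/GPe/GPi show the tonic 20–70 Hz activity characteristic of awake
primate recordings — the pattern the tonic-input calibration targets.
Now compete two channels at saliences 0.2 and 0.8 (saliences map
linearly onto the firing rates of 500-neuron activated CSN/PTN subsets):

```r
sel <- run_selection_grid(param, saliences = c(0.2, 0.8), seeds = 1,
                          duration = 1500, warmup = 500)
sel$grid[, c("s1", "s2", "y1", "y2", "e1", "e2", "winner")]
#>    s1  s2 y1 y2         e1         e2 winner
#> 1 0.2 0.2 67 66 0.06511628 0.07906977   both
#> 2 0.8 0.2 32 67 0.55348837 0.06511628      1
#> 3 0.2 0.8 65 28 0.09302326 0.60930233      2
#> 4 0.8 0.8 34 25 0.52558140 0.65116279      2
```

The higher-salience channel's GPi output collapses from the ~72 Hz rest
rate (efficiency `e` is its fractional suppression), the losing channel
stays near rest, low equal saliences select nothing, and high saliences
on both channels disinhibit both at once (high distortion) — the
off-centre/on-surround selection phenomenology.  `disruption_comparison()`,
`cmpf_sweep()` and `input_sensitivity_sweep()` quantify how the
MSN/FSI inhibitions, the diffuse subthalamic projections and the
thalamic drive shape this behaviour.

A command-line front end wrapping these functions is installed at
`inst/cli/bgspike.R` (subcommands `validate`, `fixture`, `rest`,
`deactivate`, `calibrate`, `screen`, `select`, `disrupt`, `cmpf`,
`sweep`, `spectrum`).

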