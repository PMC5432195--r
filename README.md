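# balancedline

Continuous-parameter working memory in the balanced state: simulation and
theory of two reciprocally inhibiting balanced networks of binary neurons.

## The problem

Cortical neurons fire irregularly, which is well explained by the
*balanced state*: strong excitatory and inhibitory inputs, each of order
`sqrt(K)` for `K` synapses, cancel to leading order so that activity is
driven by input fluctuations and the network dynamics are chaotic. Working
memory for a continuous quantity (an angle, a position, an evidence level)
is usually modeled with a *continuous attractor* — a line of steady states
whose position encodes the remembered value. This package implements, for
modelers in computational neuroscience, a network that does both: two
balanced subnetworks (each an excitatory population E and an inhibitory
population I of `N` binary neurons, randomly connected with probability
`K/N` and weights `J/sqrt(K)`) coupled by mutual inhibition from each I
population to the opposite E population.

The mean activities `m = (m1, m2, m3, m4)` obey the mean-field dynamics

    tau_i dm_i/dt = -m_i + H(-u_i / sqrt(alpha_i)),

with `H` the Gaussian tail function, `u_i` the mean input and `alpha_i`
the input variance. For `K -> Inf` the steady-state system is linear and
becomes singular exactly at mutual inhibition `J_tilde = J_E - J_I`,
producing a **line of balanced states**

    m = (x, x/J_I, -x + J_I E0/(J_E - J_I), -x/J_I + E0/(J_E - J_I)),

a continuum of stable network states that stores a continuous value `x`
indefinitely. At finite `K` the line must be tuned: the package finds the
coupling at which the Jacobian of the linearized dynamics acquires a zero
eigenvalue. In finite networks the chaotic fluctuations drive
Ornstein-Uhlenbeck-like motion of the position `X` along the line —
drift `F(X, dt) ~ -lambda X dt` and diffusion `G(X, dt) ~ 2 D dt` with
`D ~ 1/N` — which is what ultimately limits the memory. The package
measures `(lambda, D)` from simulations and predicts the diffusion
semi-analytically from the noise correlations of a single balanced
subnetwork, with no fitted parameters.

## What is in the package

* `network_params()`, `build_connectivity()` — parameter container and the
  sparse random connectivity generator (mirrored or independent
  subnetworks, all-to-all or sparse cross-inhibition).
* `init_state()`, `run_network()`, `flip_neuron()` — event-driven
  asynchronous simulator (C++ core, R-seeded and bit-reproducible),
  population traces, spike records, state snapshots, perturbed-replica
  protocols, optional shared OU input noise.
* `solve_fixed_point()`, `jacobian()`, `tune_jtilde()`, `nullclines()`,
  `projection_basis()`, `integrate_mf()` — the mean-field theory.
* `project()`, `drift_diffusion()`, `fit_ou()`, `msd_curve()`,
  `autocorrelation_q()`, `short_time_G()`, `pair_cross_covariance()`,
  `population_cross_covariance()`, `ensemble_variance()` — trajectory and
  correlation statistics.
* `single_network_linearization()`, `noise_correlation_from_cm()`,
  `theory_cx()`, `semi_analytic_G()` — the semi-analytic diffusion theory.
* `run_experiment()` and a CLI (`inst/cli/balancedline.R`) — scripted
  study protocols at configurable scale.

## Worked example

Tune the line at `K = 1000`, then simulate a desk-scale network and
measure drift and diffusion along the attractor:

```r
library(balancedline)

p <- network_params(N = 4000, K = 100,
                    seeds = list(connectivity = 61, schedule = 62, init = 63))
tune_jtilde(p, K = Inf)   # 1.5 = J_E - J_I, the singular coupling
tune_jtilde(p, K = 1000)  # 1.702675, the finite-K tuned value

# run slightly on the stable side of tuning (see the methods vignette)
p$J_tilde <- detuned_jtilde(p, K = 100)
b <- projection_basis(p, K = 100)
sim <- simulate_network(p, duration = 40000, dt_rec = 0.5)
X <- project(sim$trace, b)

dd <- drift_diffusion(X, 0.5, X_grid = 0,
                      lags = c(5, 10, 20, 40, 80, 160, 320), delta = 5e-3)
g <- dd[!is.na(dd$G), ]
fit_ou(g$dt, g$G, lambda_init = 1/100, weights = 1/g$se_G^2)
```

```
OU fit (G): lambda = 0.01417 /ms (1/lambda = 70.5 ms), D = 4.222e-06 /ms
  D = 4.222e-05 per 10 ms; window 5 .. 320 ms
```

`lambda` is the restoring rate toward the symmetric state (the residual
drift of the slightly detuned line) and `D` the diffusion coefficient of
the memory coordinate; at `N = 4000` as here, `D * N ~ 0.017 /ms` and `D`
falls as `1/N` — doubling the network halves the diffusive degradation of
the stored value.

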