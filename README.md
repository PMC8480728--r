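# whiskstdp

Spike-timing-dependent plasticity (STDP) and the distribution of
whisking-phase tuning in a feed-forward thalamocortical circuit.

Rodent "whisking" neurons fire preferentially at a phase of the rhythmic
whisker sweep. Thalamic (VPM) preferred phases follow a von Mises
distribution with concentration κ ≈ 1, yet a cortical layer-4 inhibitory
(L4I) neuron pooling ~100 such inputs should inherit an extremely narrow
phase distribution centred on the delayed thalamic mean — which is not what
is observed. This package implements and analyzes the proposed resolution:
ongoing STDP keeps the thalamocortical weight profile perpetually
remodelling, so the downstream preferred phase **drifts** along a limit
cycle with phase-dependent speed, and the time it spends at each phase
induces a wide, non-trivially centred stationary distribution.

It is aimed at computational neuroscientists who want to simulate, fit and
dissect this mechanism: the deterministic slow-learning (mean-field) weight
dynamics, an event-level spiking simulator used as a validation oracle, a
self-consistent fixed-point solver, circular statistics for the drifting
phase, and the plasticity-free pooling baseline.

## The model

The N upstream neurons are independent inhomogeneous Poisson processes with
rates D(1 + γ cos(νt − φ_k)); the downstream neuron is linear-Poisson with
rate N⁻¹ Σ w_k ρ_k(t − d). With the weight profile's circular moments
w̄ = N⁻¹ Σ w_k and w̃ e^{iψ} = N⁻¹ Σ w_k e^{iφ_k}, the downstream cell is
tuned with mean D w̄, modulation γ w̃/w̄ and preferred phase ψ + νd.
Each pre/post spike pair changes its synapse by

    Δw = λ [ f₊(w) K₊(Δt) − f₋(w) K₋(Δt) ],   Δt = t_post − t_pre,

with soft bounds f₊ = (1−w)^μ, f₋ = α w^μ and normalized temporal kernels
(causal/anti-causal exponentials with τ₊, τ₋, or centred Gaussians). In the
slow-learning limit the weights obey, in rescaled time s = λt,

    dw(φ)/ds = F_d + w̄ F₀ + w̃ F₁,

where F_d is the O(1/N) contribution of a synapse's own delayed spikes, F₀
the phase-independent competition term and F₁ the rhythmic term carrying
the kernels' Fourier transforms at ν.

## Worked example

The canonical drifting-phase simulation (N = 150, κ_VPM = 1,
ψ_VPM = 5π/6, D = 10 spikes/s, γ = 1, 7 Hz whisking, d = 3 ms; asymmetric
kernels τ₊ = 22 ms, τ₋ = 50 ms, μ = 0.01, α = 1.1, λ = 0.01):

```r
library(whiskstdp)

model <- thalamic_model(n = 150, rate = 10, gamma = 1, freq_hz = 7,
                        delay = 0.003, input = von_mises_spec(1, 5 * pi / 6))
rule <- stdp_rule("asymmetric_exponential", tau_plus = 0.022,
                  tau_minus = 0.050, mu = 0.01, alpha = 1.1, lambda = 0.01)

traj <- euler_integrate(model, rule, n_steps = 1.5e5, seed = 1)
dist <- temporal_phase_distribution(traj)
dist
#> <phase distribution> 93 whole drift cycles, 7457 samples, 36 bins
#>   von Mises fit (ml): kappa = 0.990, psi = 0.809 rad
autoplot(dist)
```

The weights never settle (the trajectory ends at w̄ = 0.34, w̃ = 0.25 and
keeps moving), yet the time-resolved downstream preferred phase has a
stable, wide distribution: concentration κ_L4I ≈ 1 — comparable to the
upstream κ = 1 despite pooling 150 inputs — with mean ≈ 0.81 rad, far from
the delayed upstream mean ψ_VPM + νd ≈ 2.75 rad. The same histogram fitted
by nonlinear least squares (`fit_method = "nls"`) gives κ_L4I = 1.15,
ψ = 0.87 rad. Compare the plasticity-free baseline, where pooling alone
collapses the distribution:

```r
glance(quenched_ensemble(von_mises_spec(1, 0), n = 100, reps = 1e4, seed = 1))
# kappa_l4i = 45.5: two orders of magnitude narrower than observed tuning
```

Every result object is a tibble underneath (`tidy()`, `glance()`) and has
an `autoplot()` method; `whisk_presets()`, `whisk_run()` and
`whisk_sweep()` bundle the canonical parameter studies, and
`inst/scripts/whiskstdp.R` exposes them on the command line.

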