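# topoacq

Topology-driven closed-loop MR–PET acquisition, simulated end to end.

## The problem

In acute stroke imaging, what drives treatment decisions is the *topology*
of the cerebrovascular network — how many connected vascular territories
there are (β₀) and how many collateral loops (β₁) can re-route perfusion
around an occlusion — not pixel-wise image fidelity. Conventional
compressed-sensing MR and hybrid MR–PET protocols undersample with a mask
fixed before the scan, so acquisition cannot respond to what the evolving
reconstruction reveals about those structures.

`topoacq` simulates the alternative at desk scale: a closed loop in which
each batch of measurements (a bundle of k-space phase-encode lines, or a
block of PET projection angles) is chosen to most reduce the *topological
uncertainty* of the current reconstruction,

U_t = Σ_k w_k · W_p(D_t⁽ᵏ⁾, D*⁽ᵏ⁾),   k ∈ {0, 1},

the weighted degree-wise Wasserstein distance between the persistence
diagram D_t of the current image and a reference diagram D*. Both
modalities are reconstructed jointly by minimizing

‖Φ_MR F u − y_MR‖² + λ₁·TV(u) + [1ᵀ(Φ_PET x + r) − yᵀlog(Φ_PET x + r)]
 + λ₂·TV(x) + λ₃·Σᵢ exp(−|∇u|ᵢ/η)·|∇x|ᵢ,

i.e. least-squares k-space fidelity with total variation and an optional
structured Hankel low-rank projection on the MR side, and the Poisson
sinogram likelihood with TV plus an edge-weighted cross-modal coupling on
the PET side. Acquisition stops when the normalized Wasserstein-weighted
persistence deviation, 100·U(D_acc, D_ref)/U(D_ref, ∅), has stayed at or
below 3% for two consecutive steps.

The package is for methods researchers in computational imaging who want a
fully inspectable, seeded implementation of every stage: vascular phantoms
with analytically known Betti numbers, Fourier encoding with
variable-density Poisson-disc masks and partial-Fourier conjugate filling,
a parallel-beam PET projector with OS-EM, cubical persistent homology,
exact (linear-assignment) and sliced Wasserstein distances, a greedy
one-step look-ahead controller, and an actor–critic policy trained by
temporal-difference learning.

## A worked example

```r
library(topoacq)
ph <- rasterize_phantom(generate_vessel_tree(7002, 5, 0.5, 128, n_loops = 2),
                        seed = 7002)
print(ph)
trace <- run_closed_loop(ph, "greedy", stop_threshold = 3, seed = 7002)
print(trace)
trace$steps[, c("step", "action_type", "fraction", "U", "deviation")]
```

```
Phantom 128x128: 1187 vessel pixels, tree b1=2
Closed-loop trace (greedy): 8 steps, 41.5% sampled (reduction 58.5%),
  final deviation 1.66%, status: stopped
  step action_type fraction       U deviation
1    1        warm    0.117 0.57304    110.69
2    2          mr    0.160 0.43742     84.49
3    3          mr    0.202 0.15461     29.86
4    4          mr    0.245 0.05016      9.69
5    5          mr    0.287 0.03305      6.38
6    6          mr    0.330 0.02259      4.36
7    7          mr    0.372 0.00952      1.84
8    8          mr    0.415 0.00858      1.66
```

Read: starting from a warm start (central 8% of k-space rows plus every
5th projection angle, 11.7% of all measurement units), the greedy
controller adds seven bundles of 8 phase-encode lines. The uncertainty U_t
(intensity units: a persistence-weighted transport cost against the
phantom's ground-truth diagram) falls monotonically, and the normalized
deviation crosses the 3% stopping band at steps 7–8. The scan stops after
acquiring 41.5% of the measurements — a 58.5% sampling reduction — with the
two collateral loops intact.

`run_tier1_experiment()` repeats this over seeded phantom cohorts against
fully sampled reference reconstructions and reports retained sampling,
Betti deviations of the extracted centerline graphs, and the normalized
persistence deviation; `vignettes/topology-aware-acquisition.Rmd` documents
the models, parameter defaults, and design decisions. A thin CLI is at
`inst/cli/topoacq.R` (subcommands `run`, `benchmark-wasserstein`,
`reproduce-tier1`, `train-policy`).

## The acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the mean relative
error of the sliced-Wasserstein approximation against the exact
linear-assignment distance over 50 seeded random diagram pairs (t3); and,
from a 50-phantom greedy closed-loop experiment at 128², the mean
percentage of combined k-space + PET measurements omitted at the
topological stopping criterion (t4) and the mean normalized
Wasserstein-weighted persistence deviation of accelerated versus fully
sampled reconstructions (t5). Results are written as JSON to `--out`.
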