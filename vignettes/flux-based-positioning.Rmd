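---
title: "Flux-based midnucleoid positioning of the PomXY cluster: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-based midnucleoid positioning of the PomXY cluster: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomsim)
```

## The model

In *Myxococcus xanthus*, the PomX/PomY proteins form a single cargo cluster
on the nucleoid that moves to midnucleoid and marks the division site. PomZ,
a ParA/MinD-family ATPase, tethers the cluster to the nucleoid and drives
this motion. `pomsim` implements a one-dimensional lattice-gas description
of this system with three coupled layers.

**Stochastic lattice gas.** The nucleoid and the cluster are 1D lattices of
lengths $L$ and $L_c$ with spacing $a$; positions are continuous multiples
of $a$ (cell-centred sites). ATP-bound PomZ dimers attach from the cytosol
to any nucleoid site outside the cluster footprint with total rate
$k_\mathrm{on} N_\mathrm{cyto}(L-L_c)/L$, diffuse on the nucleoid
(hop rate $D_\mathrm{nuc}/a^2$ per direction), and bind a cluster site with
rate

$$k_a = k_a^0\, e^{-\tfrac{k}{2 k_B T}(x^\mathrm{clu}-x^\mathrm{nuc})^2},$$

the Boltzmann weight of the elastic tether (spring constant $k$) that
represents the combined compliance of the chromosome and the dimer. A
doubly-bound dimer hops with either binding site, each hop weighted by
$e^{-\tfrac{k}{4k_BT}(s_\mathrm{to}^2-s_\mathrm{from}^2)}$ where $s$ is the
tether stretch; the factor $1/2$ relative to the full energy difference
makes forward and backward hops satisfy detailed balance exactly, so a
frozen tether equilibrates to the lattice Boltzmann distribution (this is
asserted by a $\chi^2$ test against exact enumeration in the test suite).
Cluster edges reflect the cluster-binding site; nucleoid ends reflect the
nucleoid site. Cluster-bound dimers are released into the cytosol with the
hydrolysis rate $k_h$; optionally, nucleoid-only dimers detach with
$k_\mathrm{off}$ (default 0). There is no excluded volume.

The cluster moves overdamped under the summed tether forces,
$\gamma_c\,\dot x_c = -k\sum_i (x_i^\mathrm{clu}-x_i^\mathrm{nuc}) + F_\mathrm{ext}$,
with no thermal noise term; between Gillespie events the bound-site
assignments are frozen, so the position update is the exact exponential
relaxation of the total stretch (verified against fine-step Euler
integration). Event times follow the standard Gillespie prescription with
rates frozen at the event time; a configurable null-event rate
(`lambda_null`) can shorten steps to bound the error of that freezing — the
test suite confirms summary statistics are insensitive to it.

**Stationary reaction–diffusion model.** For a fixed cluster the PomZ
density obeys, in the adiabatic limit and neglecting tether elasticity,
a linear RD system: free density $c(x)$ with uniform cytosolic source
outside the footprint, absorption $k_a^\mathrm{tot}$ inside; doubly-bound
density $c_b(x)$ diffusing with $D_b = 0.5\,D_\mathrm{nuc}$, fed by
$k_a^\mathrm{tot} c$ and drained by $k_h c_b$; reflecting outer boundaries
and no-flux cluster edges; the cytosolic pool closed by particle-number
conservation. The aggregate binding rate is defined as the lattice sum of
the per-site spring-weighted rates,
$k_a^\mathrm{tot} = (k_a^0/a)\sqrt{2\pi k_B T/k}$ in the continuum limit,
so the stochastic and RD layers describe identical physics.
`solve_stationary()` evaluates the exact piecewise closed form (quadratic
or cosh outside, cosh/sinh inside, with all basis functions normalised at
the matching edges so the linear system stays conditioned for strong
absorption); `rd_time_march()` provides an independent finite-difference
route used as an oracle. The central outputs are the one-sided edge inflows
$j_R, j_L$, their difference $j_\mathrm{diff}=j_R-j_L$ (the position-sensing
signal: positive for a cluster left of midnucleoid), and the bound number
$N(x_c)=\int c_b$.

**Semi-analytic theory.** Treating dimer–cluster interactions as
independent, the mean force on the cluster is $F = C\, j_\mathrm{diff}$
with $C = f/k_h$, where $f$ is the duration-weighted ensemble mean of the
time-averaged single-dimer force, estimated from one-particle simulations
(`run_one_particle()` + `estimate_C()`; equivalently $C$ is the mean
time-integrated force per interaction). Tethers also add drag:
$\gamma(x_c) = \gamma_c + k_B T\, N(x_c)/(D_\mathrm{clu}+D_\mathrm{nuc})$.
The predicted mean velocity is $v(x_c) = C j_\mathrm{diff}(x_c)/\gamma(x_c)$
and `integrate_trajectory()` integrates it. Positioning is stable when PomZ
redistribution outpaces cluster motion; `timescale_criterion()` compares
$t_\mathrm{PomZ}=L^2/D_\mathrm{nuc}$ with
$t_\mathrm{cluster}=L\gamma(L/2)/(C j_R(L/2))$ and reports the margin
$t_\mathrm{PomZ}/t_\mathrm{cluster}$. The "$\ll$" in the stability condition
is operationalised as margin < $\rho$ with $\rho = 0.1$ by default; the
margin itself is always reported so the verdict is transparent. At the
package baseline the margin is $\sim 10^{-2}$; reducing $D_\mathrm{nuc}$
(and $D_\mathrm{clu}$) a hundredfold pushes it above 1, and the stochastic
trajectories then overshoot and oscillate around midnucleoid exactly as the
adiabatic theory ceases to apply.

## Parameters

All lengths are in µm, times in s, forces in pN. The baseline
(`pom_params()` defaults):

| parameter | default | meaning |
|---|---|---|
| `L` | 5 | nucleoid length |
| `L_c` | 0.7 | cluster length |
| `a` | 0.01 | lattice spacing |
| `k` | 25 pN/µm | tether spring constant |
| `kBT` | 4.1e-3 pN·µm | thermal energy (298 K) |
| `k_on` | 0.01 /s | cytosol→nucleoid attachment scale |
| `ka0` | 50 /s | per-site cluster binding scale |
| `k_h` | 1 /s | hydrolysis/release of cluster-bound dimers |
| `k_off` | 0 /s | optional nucleoid detachment |
| `D_nuc`, `D_clu` | 0.3 µm²/s | PomZ diffusivity on nucleoid / cluster |
| `gamma_c` | 1 pN·s/µm | cytosolic cluster drag |
| `N_total` | 100 | PomZ dimer count |
| `t_min` | 600 s | equilibration with frozen cluster |

The geometry, dimer count and equilibration time are the system's standard
values (cluster 0.7 µm on a 5 µm nucleoid, ≈100 dimers, 10 min
equilibration). The hydrolysis rate is fixed at 1/s by the published
single-dimer force observables: the force constant $C=0.0059$ pN·s equals
$f/k_h$ with $f=5.91\times10^{-3}$ pN, which is only consistent at
$k_h = 1$/s. The remaining rates are package choices made once, on physical
grounds: `k` of a few tens of pN/µm reproduces chromosomal-tether stiffness
with a thermal stretch ($\sqrt{k_BT/k}\approx 13$ nm) matching the
observation that dimers bind only slightly stretched; `k_on` of order
0.01/s encodes the tens-of-seconds nucleotide-exchange delay between
release and re-binding; `ka0` is large enough that the cluster is an
efficient absorber (penetration depth $\sqrt{D_\mathrm{nuc}/k_a^\mathrm{tot}}
\ll L_c$); `D_nuc` = 0.3 µm²/s is fast nucleoid diffusion, well inside the
stable regime, with oscillations appearing when it is reduced ~100×;
`gamma_c` = 1 pN·s/µm makes the bare cluster nearly immobile
($k_BT/\gamma_c \approx 4\times10^{-3}$ µm²/s). With these choices the
ensemble positioning time is tens of minutes and all qualitative regime
boundaries (optimal intermediate $k_h$, slowdown at small $D_\mathrm{clu}$,
oscillation onset at small $D_\mathrm{nuc}$) are reproduced. They were fixed
before the validation suite was frozen and are not tuned to it.

## What the simulations emulate — and what they do not

The generator reproduces the in-vivo situation the model idealises: a
single rigid cargo on a 1D nucleoid, uniform cytosolic re-attachment (fast
cytosolic mixing), a single combined hydrolysis-and-release step, no
dimer–dimer exclusion, no thermal noise on the cargo, and no cluster
assembly or splitting. Passing tests therefore demonstrate internal
consistency of the three layers and recovery of the published regime
structure — not 3D effects, crowding, explicit nucleotide exchange, or
cargo-size dynamics, which are outside the model.

## Numerical choices

* **Closed-form cluster advance.** Between events the total stretch relaxes
  exponentially; the update is exact, so no integration-step error enters
  the cluster dynamics.
* **Binding-site pruning.** Cluster sites with Boltzmann factor < 1e-12
  are excluded from binding sums (error bounded by the Gaussian tail); the
  aggregate binding propensity is tabulated on a fine grid (a/64) of the
  dimer–cluster offset and interpolated linearly.
* **Frozen rates.** Rates are held at their event-time values during each
  Gillespie step (the validated approximation); `lambda_null` exposes the
  null-event control.
* **Lattice commensurability of frozen clusters.** When the cluster is held
  fixed for profile/force protocols, its site grid should be commensurate
  with the nucleoid grid (cluster position a multiple of the lattice
  spacing). At quarter-phase offsets the time-averaged force acquires a
  small lattice-pinning artifact; a moving cluster averages over phases and
  is unaffected. Validation protocols snap frozen positions to the lattice.
* **Coarse-lattice caveat.** The tether-drag term of the friction formula
  is a continuum result; it holds on the fine default lattice
  ($k a^2/2k_BT \approx 0.3$ at $a=0.01$ µm) but acquires visible
  corrections on lattices coarse relative to the thermal stretch. The
  friction validation therefore runs at $a = 0.01$ µm.
* **RD conditioning.** All cosh/sinh bases are normalised at the matching
  edges, keeping the 4×4 matching system well conditioned for arbitrarily
  strong absorption or detachment; degenerate regimes ($k_h = 0$ with
  binding, no sink at all) are special-cased with explicit diagnostics or
  exact limits.
* **FD oracle grids.** The time-marching cross-check uses a conservative
  cell-centred discretisation whose source and sink terms share the
  grid-resolved footprint measure; comparisons at 1e-4 tolerance use grids
  whose faces align with the cluster edges, so that discretisation error,
  not the closed form, limits agreement.
* **Oscillation analysis defaults.** The histogram uses 100 bins over
  $[0,L]$ smoothed with a Gaussian kernel of 2 bins; the spectrum kernel is
  2 frequency bins; trajectories are resampled to a uniform 0.2-min grid by
  previous-value interpolation before the FFT. These widths are package
  decisions (no published values exist); they are recorded in every
  report, and the bimodality rule is stable under ±50% bin-count changes.
* **Flux-difference estimator orientation.** Profile extremes are summed
  and reported in the orientation of the inflow difference $j_R-j_L$, so
  the stochastic estimator and the RD `j_diff` agree in sign.
* **Attachment stretch sign.** For right-side arrivals the mean attachment
  stretch is reported as `mean(x_nuc - x_clu)`, positive when the dimer
  binds reaching over toward the cluster — the orientation in which both
  the mean stretch and the force constant are positive.

## Reduced problem sizes

The validation suite and the acceptance script use reduced conditions
chosen once: ensemble work runs on a half-length nucleoid (L = 2.5 µm,
L_c = 0.36 µm) with lattice a = 0.02 µm, shortened equilibration (300 s),
horizons of 15–50 simulated minutes and 8–20 replicates; one-particle force
estimation keeps the fine a = 0.01 µm lattice with 2–4×10^3 interactions
(bootstrap standard errors are reported alongside); the friction assay uses
a = 0.01 µm with a light cytosolic drag so the tether term dominates the
slope. Full-scale protocol settings (100+ replicates, hours-long horizons,
the 5 µm nucleoid) remain available through the presets at `scale = 1`.

## Known limitations

The model is strictly one-dimensional; the cargo is rigid and of fixed
size; nucleotide exchange is folded into the cytosolic re-attachment delay;
there is no excluded volume, so very high PomZ densities are outside the
model's validity; and the semi-analytic layer assumes the adiabatic regime
— its predictions are expected (and observed) to fail when PomZ diffusion
is slow relative to cluster motion.
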