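---
title: "Fractal chromatin domains from subdiffusive nucleosome movement"
author: "fracdomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal chromatin domains from subdiffusive nucleosome movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracdomain)
```

## The model

Interphase chromatin is partitioned into submegabase-sized domains, and
single-particle tracking of nucleosomes in live nuclei consistently shows
*subdiffusion*: the mean-squared displacement follows

$$\mathrm{MSD}(t) = D_\mathrm{sub}\, t^{\beta}, \qquad 0 < \beta < 1,$$

rather than the linear growth of free Brownian motion. `fracdomain`
implements a polymer-physics account of this observation. A domain is a
chain of $N$ monomers (nucleosomes) whose conformational state is summarized
by a single fractal dimension $d_f \in [1, 3]$ through the scaling law
$R \propto N^{1/d_f}$, where $R$ is the domain size (operationally, the
gyration radius $R_g$ — the choice of size measure is a convention we fix
and expose, since end-to-end distance or an enclosing radius would serve
too). $d_f = 1$ is a straight fiber, $d_f \simeq 5/3$ an excluded-volume
swollen coil, $d_f = 2$ the ideal chain, and $d_f = 3$ a maximally compact,
space-filling globule. The surrounding nucleoplasm is viscoelastic with
memory exponent $\alpha \in (0, 1]$ ($\alpha = 1$: purely viscous).

Balancing friction against the chain forces that maintain the fractal
structure and the (fractional) thermal noise yields the two relations the
whole package revolves around:

$$D_\mathrm{sub} \propto R^{\,2 d_f/(2+d_f)}, \qquad
  \beta = \frac{2\alpha}{2+d_f}.$$

Mobility is structure: a smaller, more compact domain ($R$ down, $d_f$ up)
makes both $D_\mathrm{sub}$ and $\beta$ smaller, so its nucleosomes jiggle
in a tighter cage. Read backwards, a fitted $(D_\mathrm{sub}, \beta)$ from
imaging data constrains $(R, d_f)$: that inversion is `infer_df()`,
`infer_relative_R()` and `compare_regions()`.

## The mode-space construction

The force balance above fixes only the scaling structure, so the dynamic
model is a design decision, made once and validated against the exponent
and size laws. We use a generalized Rouse (bead-spring) chain expressed in
its normal modes $X_p$, $p = 1..N-1$, with

$$\langle X_p^2\rangle = \frac{b^2 N^{2/d_f}}{2\pi^2}\, p^{-(1+2/d_f)},
  \qquad
  \tau_p = \tau_0 \left(N^{2/d_f} p^{-(1+2/d_f)}\right)^{1/\alpha},$$

and monomer positions reconstructed by the cosine transform
$r_n = X_0 + 2\sum_p X_p \cos(p\pi(n+\tfrac12)/N)$.

* The **variance law** makes equilibrium internal distances scale as
  $\langle (r_n - r_m)^2 \rangle \sim |n-m|^{2/d_f}$ — the chain *is* a
  fractal of dimension $d_f$. The prefactor $1/(2\pi^2)$ is calibrated so
  $d_f = 2$ reproduces the continuous-Rouse closed form and hence the Debye
  result $R_g^2 = N b^2/6$.
* The **relaxation law** ties $\tau_p^\alpha$ to the mode amplitude, i.e.
  each mode relaxes at the pace its own spring constant dictates under a
  common fractional friction. Two standard alternatives exist —
  $\tau_p = \tau_0 (N/p)^{(1+2/d_f)/\alpha}$ (elementary time set per
  monomer) and $\tau_p = \tau_0\, p^{-(1+2/d_f)/\alpha}$ (whole-domain time
  fixed) — but under the first the intermediate-time MSD is independent of
  $N$ and under the second it scales as $R^2$; *neither* reproduces
  $D_\mathrm{sub} \propto R^{2d_f/(2+d_f)}$. The form above gives the
  intermediate-regime MSD an $N^{2/(2+d_f)}$ prefactor, which equals
  $(R_a/R_b)^{2d_f/(2+d_f)}$ for same-$d_f$ domains — both halves of the
  mobility–structure relation then hold in one model, which is the reason
  this normalization was chosen. The slowest relaxation is
  $\tau_1 = \tau_0 N^{2/(d_f\alpha)}$ (`equilibration_time()`), and beyond
  a few $\tau_1$ the MSD saturates at $2 R_g^2$ because the center of mass
  is held statistically fixed by default (set `include_com = TRUE` to let
  the whole domain drift).

For $\alpha < 1$ the exact mode autocorrelation is a Mittag-Leffler decay
$E_\alpha(-(t/\tau_p)^\alpha)$. The default is the stretched exponential
$\exp(-(t/\tau_p)^\alpha)$ — same short- and long-time exponents, far
cheaper — and `decay = "mittag_leffler"` switches to the exact form,
evaluated by adaptive quadrature of its completely monotone spectral
representation, for verification.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `n_monomers` | nucleosomes per domain | 256 | submegabase domain at a few kb per nucleosome |
| `df` | fractal dimension | 2 | ideal chain, midpoint of the physical range |
| `alpha` | medium memory exponent | 1 | purely viscous baseline; held fixed, never co-fitted with $d_f$ (the two are not jointly identifiable from a single $\beta$) |
| `bond_scale` | bond length $b$ (µm) | 0.015 | gives $R_g \approx 0.1$ µm at the defaults, the observed domain scale |
| `base_time` | elementary time $\tau_0$ (s) | 0.01 | puts $\tau_1 \approx 2.6$ s at the defaults: equilibration within seconds, as observed |
| `frame_interval` | imaging frame time (s) | 0.05 | the 50 ms frame time of single-nucleosome imaging |
| fit window | lags used by `fit_subdiffusion()` | frames 2–10 | lag 1 is localization-noise dominated; long lags have few displacement pairs |

## What the generators emulate — and what they do not

`simulate_monomer_tracks()` produces 2D projections (the microscopy
convention) of exact stationary Gaussian mode processes, sampled by
circulant embedding on the frame grid; each track follows a fresh random
monomer, as in imaging, where every activated dot is an arbitrary
nucleosome of its domain. `generate_fbm_tracks()` is the phenomenological
counterpart: fractional Brownian paths with $H = \beta/2$ scaled so the 2D
ensemble MSD is exactly $D_\mathrm{sub} t^\beta$, plus optional static
localization noise (which adds $4\sigma^2$ to the 2D MSD at every lag).

Real single-nucleosome data differ in ways these generators deliberately do
not model: photobleaching-limited track lengths and detection gaps beyond
simple missing frames, dynamic localization error, drift, heterogeneous
domains within one field of view, crosslinking/tethering at the lamina, and
active (non-thermal) forces. Tests passing on synthetic data therefore
validate the estimators and the internal consistency of the model — not the
biological claim that nuclear-interior domains are larger and more open
than peripheral ones, which requires the imaging data themselves.

## Numerical choices

* **Exact sampling.** All Gaussian processes (fractional noise, mode
  autocovariances, fBm chains) are sampled by circulant embedding
  (Davies–Harte); there is no timestep discretization error. If an
  embedding is not nonnegative definite the operation fails with an
  explicit message to increase the number of frames, never silently.
* **$d_f$ estimation** uses internal-distance scaling
  $\log \langle (r_n - r_m)^2\rangle$ vs $\log |n-m|$ pooled over an
  ensemble, so one chain length suffices; the default window $[4, N/8]$
  avoids the bond scale at one end and finite-size saturation at the
  other. `df_hat = 2/slope`, with the standard error propagated from the
  slope. A straight chain gives exactly 1.
* **Exponent measurement.** `msd_mid_slope()` regresses the analytic MSD
  over the log-middle window (fractions 0.35–0.75) of
  $[\tau_0 N^{-1/\alpha}, \tau_1]$, clear of both the microscopic and the
  plateau crossovers; against $2\alpha/(2+d_f)$ the worst deviation on the
  $d_f \in \{1.5, 2, 2.5, 3\} \times \alpha \in \{0.5, 0.75, 1\}$ grid is
  about $+0.023$ (at $d_f = 3$, $\alpha = 1$, a slowly decaying crossover
  correction).
* **SAW equilibration.** The pivot sampler starts from a rod and uses
  $20N$ attempted pivots by default (twice the customary $10N$ heuristic,
  since the rod is an atypical start); zero accepted moves is an error.
  Octahedral symmetries exclude the identity; the occupancy set is
  persistent, so an attempt costs only the moving arm.
* **Degenerate inputs.** Zero internal distances, nonpositive MSD values
  in a log–log window, windows with fewer than 4 lags, and mixed
  dimensionality or frame intervals in an ensemble all raise typed errors
  (`fracdomain_invalid_argument`, `fracdomain_degenerate_input`) rather
  than propagating `NaN`.
* **Ties in region comparison** use a tolerance band (default: two pooled
  standard errors, separately for $D_\mathrm{sub}$ and $\beta$); a tied
  mobility ordering maps to `"undetermined"` structure, never to a
  spurious strict ordering.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at deliberately desk-scale
sizes, chosen once: 200 chains of $N = 512$ (ideal and fractional-Brownian
chains), 200 pivot-equilibrated SAWs of $N = 500$, the order-3
space-filling curve ($N = 512$), 500 simulated tracks of 100 frames per
dynamic grid point, and 300–800 equilibrium conformations for
gyration-radius averages. At these sizes the Monte-Carlo standard errors
are several times smaller than every tolerance asserted.

## Known limitations

* Only *ratios* of $D_\mathrm{sub}$ are structurally meaningful; the
  proportionality constant in the size law is unknown, and converting a
  ratio into $R_a/R_b$ is refused when the two regions' $d_f$ estimates
  differ (cross-$d_f$ prefactors are unknown).
* $\alpha$ is an assumption. A periphery/interior difference in medium
  viscoelasticity would masquerade as a $d_f$ difference; the package
  exposes $\alpha$ everywhere but never infers it.
* Absolute calibration of domain sizes in nanometers from in-vivo MSDs is
  out of scope; `plateau_R()` returns a size only when the curve itself
  saturates.
* The stretched-exponential decay slightly distorts the crossover shape
  relative to the exact Mittag-Leffler form (exponents are identical);
  use the verification flag where the crossover region matters.
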