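---
title: "Methods: from MD snapshots to vibrational observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MD snapshots to vibrational observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibsolv)
```

## The problem and the model

An IR-active local mode — the amide I C=O stretch of N-methylacetamide (NMA)
is the canonical case — reports on its molecular environment through three
observables:

1. the **central frequency** $\langle\omega\rangle$, whose solvent-to-solvent
   shift (solvatochromism) encodes the average environment;
2. the **frequency-fluctuation correlation function (FFCF)**
   $C(t) = \langle \delta\omega(t)\,\delta\omega(0)\rangle$ with
   $\delta\omega(t) = \omega(t) - \langle\omega\rangle$, whose decay times
   are the memory times of the environment; and
3. the **fluctuation amplitude** $\Delta$, the Gaussian width of the sampled
   frequency distribution, which measures the heterogeneity of environments.

The package computes all three from an instantaneous-frequency trajectory
$\omega(t)$ built by carving solvation-shell clusters out of MD snapshots and
evaluating a per-cluster vibrational frequency. The FFCF is modelled with the
Kubo stochastic picture — Gaussian fluctuations with exponential memory —

$$ c(t) = \sum_i \Delta_i^2 \, e^{-t/\tau_{ci}}, $$

fit with one or two components. The same parameters feed the forward
lineshape synthesis through
$g(t) = \sum_i \Delta\omega_i^2 \tau_i^2 (e^{-t/\tau_i} + t/\tau_i - 1)$ and
$A(\omega) \propto \mathrm{Re}\int_0^\infty e^{i(\omega-\omega_0)t} e^{-g(t)}
e^{-t/2T_1}\,dt$, which connects the fitted $(\Delta_i, \tau_i)$ to an
observable band shape and brackets the two classic limits (inhomogeneous
Gaussian, motionally narrowed Lorentzian).

## Pipeline assumptions

* **Snapshot cadence.** Snapshots are taken every 50 fs by default
  (`select_snapshots()`), a cadence that resolves sub-picosecond spectral
  diffusion while keeping cluster counts tractable; production runs of
  250 ps give 5001 snapshots.
* **Frozen environment.** Only the solute is relaxed in the frequency step;
  all solvent atoms are frozen (the cluster `frozen_mask`). Relaxing the
  solvent would collapse the very distribution of environments the FFCF is
  meant to sample.
* **Whole molecules.** Trajectories must store molecules intact (AMBER-style
  molecule-wise wrapping). Carving translates included solvent molecules by
  whole box vectors only — never atom-by-atom re-imaging — so internal
  geometries are preserved exactly; a molecule split across the boundary
  surfaces as a clash-guard error, signalling a broken trajectory.
* **Orthorhombic boxes.** Cubic/orthorhombic cells only; triclinic input is
  an explicit unsupported-feature error.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| shell cutoff, 2 shells | 7.5 | Å | radial distance from any solute atom that encloses two solvation layers of small-molecule solvents; the shell count itself is not a metric quantity, so the mapping is an explicit, loggable choice (`shells_to_cutoff()`, overridable) |
| shell cutoff, 1 shell | 4.0 | Å | first-minimum scale of typical solute–solvent radial distribution functions |
| assignment window | 1550–1850 | cm$^{-1}$ | brackets amide I across solvents with margin |
| candidate threshold | 0.5 × max score | — | a cluster has ~3N−6 modes; modes whose C/O-relative displacement projection on the C=O axis reaches half the best score are averaged, intensity-weighted |
| FFCF fit range | 0–10 | ps | FFCF decays in ~1–4 ps in the benchmark systems; longer lags of a 250 ps trajectory are noise-dominated |
| max FFCF lag | span/2 | — | longer lags have too few pairs to be meaningful |
| gap threshold | 20% | — | above this fraction of failed snapshots the trajectory is declared unusable rather than silently analysed |
| Stark slope (map engine) | −50 | cm$^{-1}$/(V/Å) | carbonyl-stretch scale tuning rate; sign: red shift for fields pointing C→O |

Inclusion in the shell is decided by *any-atom* distance (not center of
mass), which avoids orientation artifacts for elongated solvents, and the
distance test is half-open (`d < cutoff` includes) so membership is
deterministic under floating-point ties.

## Frequency assignment conventions

Engines return many modes per cluster; the probe mode is identified by the
magnitude of the projection of $(d_C - d_O)$ on the C→O unit vector, scores
normalized to the best in-window mode. The snapshot frequency is the
IR-intensity-weighted average over candidate modes, and the trajectory's
central frequency is the average over snapshots — i.e. intensity weighting
acts both within a snapshot and across the trajectory. Users comparing
against codes that weight only one of the two levels should note this
explicitly documented choice. Imaginary modes (negative frequencies) are
parsed and reported but never assigned; snapshots with no in-window real
mode, or whose optimization did not converge, become explicit gaps with a
logged count, and the FFCF estimator is gap-aware (a lag-$k$ pair
contributes only when both endpoints are valid, each lag normalized by its
own pair count). $\delta\omega$ is always taken against the single global
mean, matching the one-$\langle\omega\rangle$ definition of the FFCF.

## Numerical choices

* **Kubo fits** are multimodal in $(\tau_1, \tau_2)$, so `fit_kubo()` runs
  Levenberg–Marquardt from 6 starts with log-spaced $\tau$ pairs spanning
  0.05–10 ps, amplitudes splitting $C(0)$; bounds $\tau \in
  [\mathrm{d}t/2, \mathrm{span}]$. The best converged start wins; $\tau$
  pinned at a bound and near-degenerate component pairs ($\tau_2/\tau_1 <
  1.5$ or a vanishing amplitude share) raise diagnostic flags rather than
  silent acceptance. Near-equal true $\tau$ values are fundamentally
  unidentifiable from a bi-exponential; the degeneracy flag is the honest
  answer there.
* **$\tau_c$ reduction.** A two-component fit has no unique single
  correlation time. `correlation_time()` always computes three conventions —
  slowest component (default), amplitude-weighted mean
  $\sum\Delta_i^2\tau_i/\sum\Delta_i^2$, and the normalized FFCF integral —
  and reports all of them so downstream comparisons can state which one they
  use.
* **Amplitude.** $\Delta$ comes from a least-squares Gaussian fit to the
  Freedman–Diaconis-binned, density-normalized frequency histogram; the
  direct sample standard deviation is always reported alongside (the two
  agree for Gaussian statistics, and their disagreement is itself a
  non-Gaussianity diagnostic). A constant trajectory is a zero-width error.
* **Lineshapes.** $\Delta$ stays in cm$^{-1}$ everywhere user-facing and is
  converted to rad/ps only inside $g(t)$, through a single constant
  ($c = 0.0299792458$ cm/ps) — unit slips are the dominant failure mode in
  this corner. The half-sided transform uses trapezoidal end correction and
  4× zero padding; automatic grids resolve the fastest component
  ($\mathrm{d}t \le \tau_{\min}/12$) and extend to six response decay times,
  and user-supplied grids that violate the coarser $\tau_{\min}/10$ /
  5-decay-times floor raise errors instead of aliasing. `expm1()` keeps the
  small-$t$ limit of $g(t)$ accurate.
* **FWHM** is measured by linear interpolation at the half-maximum
  crossings; multiple disjoint above-half regions (structured bands) are an
  error, not a guess.
* **Determinism.** Cluster files, fixture trajectories and manifests write
  numbers with 17 significant digits, so the file-based pipeline reproduces
  in-memory results bit-for-bit; one user seed feeds separate derived
  streams for placement, orientations and walks.

## What the synthetic generators emulate — and what they do not

`simulate_ou()` uses the exact OU discretization
$\delta\omega_{k+1} = a\,\delta\omega_k + \Delta\sqrt{1-a^2}\,\xi_k$,
$a = e^{-\mathrm{d}t/\tau}$, which is distributionally exact at any step
size; an Euler scheme would bias the variance by $\sim\mathrm{d}t/2\tau$ and
contaminate parameter-recovery checks. Its FFCF and marginal are exactly the
Kubo model, so it validates the estimator and fitter under the model's own
assumptions.

`generate_fixture_trajectory()` builds a toy solute among charge dumbbells
(±0.25 e, 1 Å apart, 50 molecules in a 20 Å box, 0.2 Å per-frame reflected
Gaussian walks — a liquid-like RMS displacement for a 50 fs cadence) so the
whole carve → engine → FFCF chain runs without external software. Neither
generator reproduces real solvent structure: there are no hydrogen-bond
kinetics, no inertial librations, no force field. Passing tests on these
fixtures therefore demonstrates the *machinery* — estimator correctness,
assignment logic, file-format fidelity, parameter recovery at realistic
trajectory lengths — not the physical accuracy of any particular frequency
engine, which must be established against experiment as in the packaged
benchmark table.

The built-in map engine is a deliberately minimal one-parameter Stark map
(field of environment point charges at the C=O midpoint projected on the
bond axis, one mode, unit intensity). It is exactly linear in every charge,
which makes superposition a testable invariant, and it exists so the
pipeline is deterministic and engine-independent in tests; it is not a
production frequency model.

## Validation problem sizes

The shipped checks use: 200 random trajectories ($N \le 2000$, with and
without gaps) against a double-loop FFCF oracle; 50 random noiseless
bi-exponential curves recovered to $10^{-4}$ relative; 20 OU replicates at
$\Delta = 10$ cm$^{-1}$, $\tau = 1$ ps, 250 ps @ 50 fs — the production
trajectory length — where the replicate spread in fitted $\tau$ is itself a
reported result (sampling error at this trajectory length is material, about
±25% for single replicates, and medians are required to land within 5% in
$\Delta$ and 15% in $\tau$); lineshape limits within 2–3% of the closed
forms; and a 1000–2000-frame fixture pipeline required to be bit-identical
between its file-based and in-memory routes.

## Known limitations

* Two Kubo components at most; no stretched exponentials, no explicit
  inertial (Gaussian) early-time component.
* No 2DIR (third-order) synthesis or center-line-slope analysis; the
  lineshape module is linear absorption only.
* The external-engine adapter prepares and parses GFN2-xTB jobs but never
  executes them; full reproduction of the benchmark table requires running
  that engine on ~5000 clusters per solvent, hours of compute outside this
  package's scope.
* Molecule-intact input is assumed; no trajectory re-imaging service is
  provided beyond whole-molecule translation during carving.
* The benchmark regressions recompute statistics from the packaged table's
  rounded entries; values agree with the source analyses to table-rounding
  precision.
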