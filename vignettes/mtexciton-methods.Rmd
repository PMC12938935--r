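---
title: "Collective excitation dynamics in tryptophan networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective excitation dynamics in tryptophan networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtexciton)
```

## The physical model

`mtexciton` treats each tryptophan chromophore as a two-level point dipole:
a position $\mathbf r_n$ (Å), a unit transition-dipole direction
$\hat\mu_n$, and a site-energy offset $\epsilon_n$ (cm$^{-1}$).  Networks of
such dipoles — a tubulin dimer carries eight of them — interact through the
common electromagnetic vacuum, which produces two textbook kernels as a
function of the dimensionless separation $\alpha_{nm} = k_0 r_{nm}$ with
$k_0 = 2\pi/\lambda_0$ and $\lambda_0 = 280$ nm (the near-UV tryptophan
band):

* a coherent dipole–dipole coupling $\Delta_{nm}$, with the familiar
  $1/\alpha^3$ near-field divergence, and
* a collective radiative decay matrix $G_{nm}$, finite as $\alpha \to 0$
  with $G_{nn} = \gamma$, the single-emitter radiative rate.

Both are implemented exactly from their oscillatory brackets
(`coupling_delta()`, `decay_matrix()`).  For $\alpha < 0.05$ the decay
bracket suffers catastrophic cancellation in floating point, so it switches
to a truncated power series whose truncation error is below $10^{-14}$ at
the switchover; the two evaluation routes agree to $10^{-9}\gamma$ there
(tested).  Coincident sites are accepted only as explicit Dicke-limit
fixtures: $G_{nm}$ takes its analytic $\alpha\to 0$ limit
$\gamma\,\hat\mu_n\!\cdot\!\hat\mu_m$ while $\Delta$ diverges and must be
masked.

The effective non-Hermitian Hamiltonian

$$H_{\rm eff} = \mathrm{diag}(H_0) + \Delta - \tfrac{i}{2} G$$

is diagonalized by `eigenmodes()`.  Each complex eigenvalue
$E_j - \tfrac{i}{2}\Gamma_j$ gives a collective mode energy and radiative
rate; modes with $\Gamma_j/\gamma > 1$ are superradiant (bright), modes
with $\Gamma_j/\gamma < 1$ subradiant (dark).  The trace identity
$\sum_j \Gamma_j = N\gamma$ holds to $10^{-8}$ relative and is used as a
standing conservation check.

## Open-system dynamics

The trace-preserving dynamics run on the $(N{+}1)$-dimensional space
spanned by an explicit ground sink $|0\rangle$ and the $N$ single-site
excitations.  Collapse operators come from the eigendecomposition
$G = V \Lambda V^\top$, one per collective channel:
$L_j = \sqrt{g_j}\sum_n v^{(j)}_n |0\rangle\langle n|$
(`jump_operators()`; completeness $\sum_j L_j^\dagger L_j = G$ embedded in
the excited block is a tested invariant).  `lindblad_propagate()`
integrates the master equation with `deSolve::zvode` (adaptive Adams by
default, BDF for long smooth decays), with the right-hand side evaluated
in compiled code.

Because every jump empties into the sink and nothing re-excites, the
excited-sector block of the Lindblad solution coincides, for pure excited
initial states, with $\psi(t)\psi(t)^\dagger$ from the non-Hermitian
propagator $\psi(t) = e^{-iH_{\rm eff}t}\psi_0$ (`nonhermitian_propagate()`,
computed by an independent route: complex eigendecomposition rather than
ODE integration).  This equivalence is the central cross-validation of the
two formalisms and is enforced to $10^{-6}$ over random preparations in
the test suite.

### Numerical choices

* **Units.** Rates and energies live in a declared unit system: `"gamma"`
  (multiples of the single-site rate; the default for all fixture work,
  with time in units of $1/\gamma$) or `"cm-1"` (needed for lifetimes in
  seconds via $\tau = 1/(2\pi c \Gamma)$, $c = 2.99792458\times 10^{10}$
  cm/s).  The carrier energy $\hbar\omega_0$ is a global phase on the
  single-excitation manifold and is dropped (rotating frame); a
  `frame = "carrier"` option restores it for spectroscopic bookkeeping.
* **The single-site rate.** $\gamma$ is deliberately required
  configuration.  Physical examples use $1.2\times10^{-3}$ cm$^{-1}$,
  obtained from the vacuum spontaneous-emission formula
  $\gamma = \mu^2\omega_0^3/(3\pi\varepsilon_0\hbar c^3)$ with a 4 Debye
  transition dipole at 280 nm ($\approx 2.3\times10^8$ s$^{-1}$, a 4.4 ns
  radiative lifetime — the right order for the Trp $^1L_a$ transition).
* **Integrator tolerances.** Defaults are `rtol = 1e-12`,
  `atol = 1e-14`.  The near-field couplings of nm-spaced sites reach
  $\sim 5\times10^4\,\gamma$, so the density matrix carries fast
  oscillations and the global error grows with the
  integrated phase (roughly `rtol` $\times$ spectral radius $\times$
  window).  The positivity surrogate (most negative eigenvalue of $\rho$)
  is checked at exactly that scale, with a floor of $-10^{-8}$ reached for
  short windows at the default tolerances.  Trace preservation is checked
  at every output time at $10^{-8}$ unconditionally (the gain and loss
  terms cancel identically in exact arithmetic).
* **Degeneracies.** Mode ordering is by descending $\Gamma_j$, ties broken
  by ascending $E_j$ then index, so "the most superradiant mode" is
  reproducible.  Rates within $10^{-10}\gamma$ of zero are clamped to
  exactly zero and reported as perfectly dark ($\tau = \infty$); the
  smallest physical subradiant rates of interest are several orders above
  this clamp.
* **Mode projections.** $w_j(t) = \langle r_j|\rho|r_j\rangle$ with
  unit-normalized right eigenvectors by default.  Because $H_{\rm eff}$ is
  non-normal its eigenvectors are not orthogonal and the weights do not
  sum exactly to the excited population; a biorthogonal variant
  ($\langle l_j|\rho|l_j\rangle$) is available behind
  `method = "biorthogonal"`.  Neither convention is canonical; the right-
  vector one is the default because it keeps $w_j \ge 0$.

## Initial preparations and information metrics

`make_initial_state()` provides the five standard preparations:
superradiant and subradiant eigenmode states, the uniform coherent
superposition $N^{-1/2}\sum_n |n\rangle$, the maximally mixed single
excitation $N^{-1}\sum_n |n\rangle\langle n|$, and site-localized
injections.  `contrast_pair_states()` builds the orthogonal
tubulin-delocalized pairs — population contrast $(|10\rangle, |01\rangle)$
and phase contrast $(|10\rangle \pm |01\rangle)/\sqrt2$ — used in the
backflow protocol.

The metric layer adopts the standard definitions: the L1 norm of
coherence in the site basis (sink excluded by default — the ground state
carries no optical coherence in this model), correlated coherence
$C_{cc} = C(\rho_{AB}) - C(\rho_A) - C(\rho_B)$ with reductions by partial
trace onto vacuum-plus-subset, logarithmic negativity via an explicit
partial transpose on the two-qubit reduction of a site pair, von Neumann
mutual information (base 2 throughout), and the trace-distance measure of
non-Markovianity: $D(t) = \tfrac12\|\rho^{(1)}-\rho^{(2)}\|_1$ on the
reduced two-tubulin subsystem, with the scalar backflow
$N = \sum_i \max(0, D(t_{i+1})-D(t_i))$ accumulated directly on the output
grid (no smoothing or spline differentiation — the grid spacing is part of
the result's provenance).  For a pure single-excitation state the
correlated coherence has the closed form
$2(\sum_{a\in A}|\psi_a|)(\sum_{b\in B}|\psi_b|)$, which the tests use as
an independent oracle against the partial-trace implementation.  The
site-basis convention is the default; a local-eigenbasis-rotated variant
sits behind a flag since the basis-independent formulation is a
literature variant rather than a fixed convention.

## What the synthetic generator emulates — and what it does not

No structural coordinates ship with the package.  The eight-site
"pseudo-dimer" template is an explicitly synthetic stand-in: sites on a
short helix (radius 7 Å, rise 5.5 Å per site, 100° step) with dipoles
tilted 35° from the local tangent.  It reproduces the *regime* that
matters — nm-scale spacings, hence all pairwise $\alpha < 0.1$ and
near-field couplings up to $\sim 5\times10^4\gamma$, and mixed dipole
orientations, hence coexisting bright ($\Gamma_{\max}/\gamma \approx 3.0$)
and dark ($\Gamma_{\min}/\gamma \approx 3.7\times10^{-3}$) modes — but
makes no claim of fidelity to the tubulin fold.  Microtubule assemblies
tile this template over an idealized helical lattice (13 protofilaments,
11.2 nm cylinder radius, 8 nm axial rise per dimer, uniform angular step
$2\pi/13$; all overridable), ignoring the lattice seam and monomer rise.
Structural disorder is emulated by seeded Gaussian position jitter and
random dipole rotations in place of conformational sampling; static
energetic disorder adds uniform site-energy shifts on $[-W/2, W/2]$.
Consequences: passing tests demonstrate the collective radiative
mechanisms (superradiant export, subradiant retention, geometry-dependent
backflow) on a faithful *class* of geometries, not quantitative
predictions for real tubulin coordinates.

## Desk-scale study sizes

The original experiments run to tens of ns on HPC resources; this package
reproduces their structure at desk scale, with windows set by the
system's own rate scales rather than wall-clock targets:

* cross-validation and short-window dynamics on the 8-site dimer:
  $t \le 0.01/\gamma$ with 21 output points;
* half-decay comparisons: $t_{\max} = 3\ln 2/\Gamma$ of the prepared
  mode, so each preparation is followed to its own half-life;
* the single-spiral backflow protocol (104 sites, neighbor $k=2$, 11
  tubulins traced out): $t_{\max} = 0.015/\gamma \approx 2$ exchange
  periods of the strongest inter-tubulin coupling
  ($|\Delta|_{\max} \approx 8\times10^2\gamma$), 121 grid points;
* eigenmode-only scaling: one dimer up to 4 spirals (416 sites) with a
  20-seed disorder ensemble at $W = 200$ cm$^{-1}$; full Lindblad runs
  are capped at 2 spirals by default (`force` overrides).

## A physical caveat on the maximally mixed preparation

Under *collective* decay the maximally mixed excitation does not remain
exactly diagonal: the anticommutator part of the dissipator generates
inter-site coherence at first order, $\dot\rho_{nm}(0) = -G_{nm}/N$ for
$n \ne m$.  The Dicke pair makes this exact:
$\rho_{12}(t) = (e^{-2\gamma t}-1)/4$ starting from $I/2$.  The generated
coherence (and the accompanying sliver of negativity) is small on the
scale of coherent preparations but is *not* numerically zero, and the
package reports it honestly.  It vanishes identically only for
independent emitters ($G$ diagonal), which is how the diagonal-preserving
limit is exercised in the test suite.

## Known limitations

Single-excitation manifold only (no exciton–exciton interactions), zero
temperature (no thermal re-excitation), no non-radiative decay, dephasing
or vibronic coupling, no lattice seam, and no real structural input beyond
the optional PDB reader (whose dipole-axis convention for the $^1L_a$
moment is configurable because it is not standardized).
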