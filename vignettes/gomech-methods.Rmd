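---
title: "gomech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gomech: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomech)
```

This vignette is the package's own account of the science behind each
module: the models fitted, the parameters that matter, what the synthetic
generators do and do not emulate, and the choices made where the design
was genuinely open.

# AFM stiffness: the Hertz model

An AFM approach curve records cantilever force against piezo position
$z$. Before tip–sample contact at $z_0$ the force is a flat baseline;
beyond it, for a rigid spherical tip of radius $R$ indenting an elastic
half-space of Young's modulus $E$ and Poisson ratio $\gamma$ to depth
$\delta = z - z_0$, the Hertz model gives

$$F = \frac{4}{3}\,\frac{E}{1-\gamma^2}\,\sqrt{R}\,\delta^{3/2}.$$

The model assumes small strains, a homogeneous isotropic sample, no
adhesion, and indentation shallow relative to both cell thickness and tip
geometry — all the usual caveats of cell AFM. Within those assumptions
$F$ is linear in $E$, which the fit exploits.

**Fitting.** `estimate_contact_point()` performs an exhaustive grid
search: every sampled $z$ is tried as a candidate $z_0$, a two-parameter
piecewise model (constant baseline $b$, rise $b + c\,(z-z_0)^{3/2}$) is
solved in closed form, and the candidate with minimal residual sum of
squares wins. This is deterministic, free of optimiser tuning, and exact
on noiseless data whose grid contains the true contact sample. A curve
whose maximum force does not exceed the baseline by three times the noise
SD (estimated from successive baseline differences) is rejected as
no-contact; a best candidate at the first sample is flagged as a boundary
solution. `fit_hertz()` then subtracts the pre-contact baseline and fits
$F = c\,\delta^{3/2}$ by linear least squares over the depth window
$0 < \delta \le 500$ nm, converting
$E = 3c(1-\gamma^2)/(4\sqrt{R})$.

**Units.** All fitting happens in SI (Pa, m, N) — the Hertz equation is
unit-homogeneous only there — while curves are held in the
instrument-natural nm/nN and moduli reported in kPa.

**Defaults.** $\gamma = 0.4$ (the value appropriate for nearly
incompressible cells used throughout the study design this package
supports), $R = 10$ nm (a 20 nm-diameter probe), depth window 500 nm, and
a 0.02 N/m spring constant carried as metadata. Curves are assumed
force-versus-z with deflection already converted to force; for
deflection-mode files `fit_hertz(deflection_correction = TRUE)` applies
$\delta = (z-z_0) - F/k$. Only approach segments are modelled; retract
data, viscoelastic models (Ting, JKR, DMT) and adhesion analysis are out
of scope.

**Generator.** `gen_force_curve()` emits baseline + Hertzian rise with
i.i.d. Gaussian force noise and places $z_0$ exactly on the sample grid,
so noiseless recovery is exact to machine precision (the package's tests
assert $\le 10^{-6}$ relative error at 2.44, 1.32, 1.65 and 0.65 kPa). It
does not emulate hydrodynamic drag, baseline tilt, or adhesion hysteresis
— so passing recovery tests demonstrate the estimator, not robustness to
every instrumental artefact.

# Actin orientation and the nematic order parameter

Fluorescent F-actin images are analysed block-wise. Each overlapping
block (default 32 px window, 50% overlap) is mean-subtracted, Hann
tapered, and Fourier transformed; the DC bin is removed and the power
spectrum restricted to radii between 1 and the Nyquist circle. The
second-moment (structure-tensor-style) eigen-analysis of that spectrum
gives the spectral major axis; since a filament texture concentrates
spectral energy perpendicular to the filaments, the local director is the
orthogonal axis, reported in $[0, \pi)$. Coherence — the normalised
eigenvalue anisotropy — is 0 for isotropic or constant blocks and 1 for a
perfect grating; constant blocks are left unset.

The nematic order parameter of block $i$ is

$$q_i = \left\langle 2\left(\cos^2(\theta_i - \theta_j) - \tfrac12\right)\right\rangle_j
      = \langle \cos 2(\theta_i-\theta_j) \rangle_j$$

averaged over set neighbours $j$ within Chebyshev radius 1 (the
8-connected ring), the centre excluded. Directors are axial, so only
differences modulo $\pi$ matter; $q = 1$ for locally parallel directors
and $\langle q\rangle \to 0$ for i.i.d. uniform ones. The mask rule —
blocks with under 50% in-mask pixels are dropped — keeps the statistic
inside cells. Window size, overlap, neighbourhood radius and mask rule
are deliberate defaults exposed as arguments: published
$\langle q\rangle$ values depend on them, so cross-study comparisons
should fix them explicitly.

**Generator.** `gen_filament_image()` draws anti-aliased segments whose
orientations follow a $\pi$-periodic von Mises law — sampled on the
doubled angle and halved, the standard construction for axial data — with
concentration $\kappa$ ($\kappa = 0$ uniform, $\kappa \ge 10^6$ treated
as perfectly aligned) plus Gaussian background noise at a chosen peak
SNR. It emulates orientation statistics and contrast, not microscope
PSFs, out-of-focus light, or filament curvature; accordingly the tests
assert rotation equivariance, recovery of grating angles, and that
$\langle q\rangle$ increases with $\kappa$ (rank correlation across
$\kappa \in \{0.25, \dots, 8\}$; far above $\kappa \approx 30$ the drawn
angles are essentially identical and the estimate saturates, so that
range is where the property is informative).

Viability uses connected-component counts per channel
(`viability_from_channels()`): viable percentage
$= 100\,n_\text{green}/(n_\text{green}+n_\text{red})$. The disc-image
generator places non-overlapping cells, so counting is unambiguous; real
confluent images would need instance segmentation, which is out of scope.

# Single-cell migration

Velocity is defined as **net displacement projected on the channel
axis** between a track's first and last samples divided by elapsed time,
in µm/h. Microfluidic migration chips measure directed transit through
straight channels, making net axial motion the natural observable; a
path-length speed is available via `path_length = TRUE`. Cells moving
against the axis get negative velocities and are retained, so cohort
means can sit below mean speeds. Times are minutes in files, velocities
µm/h in reports.

Inhibition is plain arithmetic on cohort means,
$100\,(\bar v_\text{ctrl} - \bar v_\text{trt})/\bar v_\text{ctrl}$.
Note the package always reports the arithmetic value of whatever means it
is given — e.g. means of 18.4 and 11.2 µm/h give 39.1%, and 22.1 and
13.5 µm/h give 38.9% — rather than any independently rounded figure.

**Generator.** `gen_tracks()` draws per-cell speeds from a normal
truncated at zero (negative speeds are biologically meaningless),
advances cells along +x and adds isotropic positional jitter. It
reproduces speed heterogeneity and sampling cadence, not persistence,
turning, or channel-entry waiting times.

# Coarse-grained GO/actin observables

**Sheet construction.** `build_go_sheet()` places $2 n_x n_y$ beads on a
honeycomb lattice (nearest-neighbour spacing 0.24 nm by default — a 2:1
mapping of graphene's 0.142 nm C–C bond) and relabels exactly
$\mathrm{round}(f \cdot N)$ beads, drawn uniformly without replacement,
as oxidised SP1; the rest stay SG4. The default $f = 0.48$ matches the
GO composition the pipeline is built around. The bond list is the
nearest-neighbour graph, which is connected for any $n_x, n_y \ge 1$.

**Geometry.** All distances use the minimum-image convention in a cubic
box (default 25 nm). Group centres of mass unwrap each group relative to
its first bead before averaging (equal masses by default), so clusters
straddling the boundary get sensible centres; a group spanning more than
half the box is reported as ambiguous rather than silently averaged.

**Native contacts.** The reference contact list is every inter-group pair
below a cutoff in the reference frame; later frames count how many of
those pairs remain below the cutoff. The cutoff defaults to 0.6 nm for
both detection and counting (no tolerance factor) — a typical CG
bead-contact distance; it is exposed as an argument because published
contact counts are only comparable under an identical definition.

**Energies.** Lennard-Jones sums
$4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ over inter-group
minimum-image pairs within 1.2 nm, with three truncation modes: bare
(`plain`, for closed-form checks), potential-shifted (default), and the
standard force-switch polynomial on $[0.9, 1.2]$ nm. Electrostatics use
a screened Coulomb sum $f q_i q_j/(\epsilon_r r)$,
$f = 138.935$ kJ mol⁻¹ nm e⁻², with a conducting-boundary reaction-field
correction ($k_{rf} = 1/2r_c^3$) that vanishes at the cutoff and
$\epsilon_r = 15$, the Martini convention. Reaction field is the
deterministic desk-scale treatment of long-range electrostatics adopted
here; lattice-summation (PME) energies of a full MD engine are
reproducible only up to that convention choice, and this package performs
no MD propagation at all — no integrators, thermostats, barostats, or
bonded terms.

**Free-energy landscapes.** Samples of two collective variables are
binned on a regular grid (edges aligned to multiples of the bin width),
converted to probabilities and Boltzmann-inverted,
$F = -k_BT \ln(P/P_\text{max})$ with
$k_B = 0.0083145$ kJ mol⁻¹ K⁻¹ and $T = 300$ K by default, so the
occupied minimum is exactly zero; empty bins carry `NA` and are never
interpolated. `find_minima()` takes occupied bins that are ≤ all eight
occupied neighbours (ties at a well bottom are merged) and filters them
by **topographic prominence**: flood-filling below $F + 1$ kJ/mol from
each candidate in ascending $F$ order, a candidate reaching an accepted
deeper minimum is discarded. A plain strict-local-minimum rule would
report the shallow dips that multinomial counting noise carves into the
tails of any sampled basin; the prominence filter merges those into their
parent basin while keeping genuinely separated wells. The 1 kJ/mol
default ($\approx 0.4\,k_BT$) is the smallest barrier worth calling a
basin at 300 K; it is an argument, not a constant.

**Generators.** `gen_cv_samples()` draws bivariate-normal collective
variables (a harmonic-basin caricature of the true ensembles);
`gen_dimer_frames()` builds two rigid bead clusters at exact COM
separations with optional per-bead jitter. Neither emulates correlated
dynamics, multi-basin kinetics, or the actual actin/cofilin bead
chemistry — they provide the statistical structure the estimators assume,
with exactly known truth.

# Numerical choices and problem sizes

* Noiseless recovery tolerances are $10^{-6}$ relative (force curves,
  tracks, dimer separations); pairwise observables are checked against
  $O(N^2)$ double-loop and 27-image brute-force oracles to $10^{-10}$
  relative on frames of ≤ 100 beads.
* The test suite and acceptance script use desk-scale sizes chosen for
  statistical adequacy: 200-point curves, 200–500-cell cohorts,
  $10^5$-sample landscapes with 0.02 nm (or 10-contact) bins,
  128–160 px images with 3 replicates per concentration level, and
  10,000-bead sheets.
* All generators take an explicit integer seed, save and restore the
  caller's RNG state, and are bitwise reproducible for identical
  (parameters, seed).
* GRO files carry 3-decimal coordinates by format; the XYZ writer is used
  wherever tests need full precision.

# Known limitations

* Contact-point search is $O(n^2)$ in curve length — fine for typical
  AFM curves (hundreds of points), slow for very long ones.
* The orientation estimator reports one director per block; crossing
  filament populations within a block yield an intermediate axis with low
  coherence rather than two axes.
* Viability counting assumes non-touching cells per channel.
* Energies are pairwise nonbonded sums over explicit frames; no Ewald
  summation, no bonded terms, no dynamics.
* Printed $\langle q\rangle$ or contact-count values from any particular
  study depend on block geometry and contact definitions that are rarely
  fully specified; this package's defaults are documented above precisely
  so that its numbers are reproducible under its own conventions.
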