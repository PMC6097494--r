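---
title: "Bilayer observables, permeability and transfer energies with memphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilayer observables, permeability and transfer energies with memphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphys)
```

# What the package computes

Molecular-dynamics studies of phospholipid bilayers (DPPC, POPC and
relatives) are validated against a standard set of physical observables, and
used to predict quantities that are hard to measure directly.  `memphys`
implements that analysis chain for trajectories in PSF/PDB/DCD form, and —
because useful validation needs known ground truth — ships a synthetic-data
module that generates every input class from declared analytic models.

The observables, with their defining relations:

* **Area per lipid**: $A_L = \langle L_X L_Y\rangle / n_L$, the mean lateral
  box area over the lipids of one leaflet.  For a DPPC patch of 74 lipids
  ($n_L = 37$) in a $\sim\!47.5\times47.5$ Å box this is $\sim$61 Å².
* **Area compressibility modulus**:
  $K_A = k_B T \langle A_L\rangle / (n_L \langle \delta A_L^2\rangle)$,
  reported in dyn/cm.  The fluctuation $\langle\delta A_L^2\rangle$ is the
  biased ($1/N$) variance — the thermodynamic fluctuation formula, not a
  sample-variance estimate of it.
* **C–H order parameters**:
  $S_{\mathrm{CH}} = \langle (3\cos^2\theta - 1)/2 \rangle$ with $\theta$
  the angle between a C–H bond and the membrane normal.  The signed value is
  stored (headgroup sites are signed); the deuterium order parameter
  $|S_{CD}|$ per carbon is a view over its hydrogens.  Packaged tables map
  the CHARMM36 atom names of DPPC and POPC (sn-1/sn-2 acyl carbons and the
  $\alpha$, $\beta$, $g_1$, $g_2$, $g_3$ headgroup/glycerol sites).
* **Transmembrane density profiles**: histograms of per-atom weights along
  $z$ normalized by the slab volume — electron counts ($Z - q$ by default),
  partial charges, or neutron scattering lengths (lipid H $-3.74$ fm; water
  H replaced by the deuteron value $6.67$ fm under D$_2$O substitution;
  phosphatidylcholines have no exchangeable protons, so only water hydrogens
  are substituted).
* **Scattering form factors**:
  $|F(q)| = \left|\int [\rho(z) - \rho_w](\cos qz + i\sin qz)\,dz\right|$,
  by trapezoid quadrature of the contrast against the bulk solvent density.
* **Membrane dipole potential**:
  $\phi(z) - \phi(z_0) = -\varepsilon_0^{-1}\int_{z_0}^{z}\!\!\int_{z_0}^{z'}
  \zeta(z'')\,dz''dz'$, a double cumulative trapezoid of the charge density,
  zeroed at a reference position in bulk solution.
* **Permeability** (inhomogeneous solubility–diffusion):
  $1/P_m = \int_{-L/2}^{L/2} e^{w(z)/k_BT}/D(z)\,dz$, from an
  umbrella-sampling PMF $w(z)$ (WHAM) and a diffusivity profile $D(z)$
  estimated from harmonically restrained time series.
* **Solvation and transfer free energies**: staged TI/FEP bookkeeping with a
  Weeks–Chandler–Andersen split into electrostatic, dispersion and repulsive
  components; the water→alkane transfer energy is the component-wise
  difference of the two phases' solvation energies.

# Estimators and numerical choices

## WHAM

`wham_pmf()` solves the standard 1-D weighted-histogram equations
$$p_j = \frac{\sum_i n_{ij}}{\sum_i N_i\, e^{(f_i - b_i(z_j))/k_BT}},\qquad
  f_i = -k_BT \ln \sum_j p_j e^{-b_i(z_j)/k_BT}.$$
Plain fixed-point iteration can need $>10^5$ sweeps to reach the default
$10^{-8}$ kcal/mol tolerance, so the implementation instead minimizes the
equivalent convex unbinned-likelihood objective
$\mathcal{A}(g) = \sum_j n_j \ln \sum_i N_i e^{g_i - u_{ij}} - \sum_i N_i g_i$
with L-BFGS and an analytic gradient, then verifies the self-consistency
residual $\max_i |f_i' - f_i|$ against the tolerance.  All exponentials go
through log-sum-exp.  Interior bins left empty by every window are flagged
and carry `NA`; the PMF offset convention is bulk-mean zero over
$|z| \ge 35$ Å by default (minimum-zero and unshifted are available) — a PMF
is defined only up to a constant, so recovery tests align profiles by their
mean difference before computing errors.

A practical statistical caveat worth stating explicitly: WHAM can only align
window free energies through *overlap* of the biased distributions.  With
the restraint $k = 2.5$ kcal mol$^{-1}$ Å$^{-2}$ used for water permeation
the biased distributions are only $\sigma \approx 0.5$ Å wide, so umbrella
centers must be spaced $\lesssim 1$–$2\sigma$ apart (the package default is
1 Å).  A layout with 5 Å spacing has essentially zero inter-window overlap
($\sim\!10\sigma$), and no estimator can reconstruct the profile to
$\sim\!0.1$ kcal/mol from it at any realistic sample count; the test suite
demonstrates both regimes.

## Diffusivity from restrained series

`diffusivity_gle()` uses the generalized-Langevin relation for a
harmonically restrained coordinate,
$D = \langle\delta z^2\rangle^2 \big/ \int_0^\infty
\langle\delta z(0)\,\delta z(t)\rangle\,dt$.
The autocovariance is computed by FFT (unbiased normalization); the integral
is trapezoidal up to the first lag where the ACF falls below $e^{-2}$ of its
zero-time value, plus an exponential tail whose decay time is fitted over
the last $e$-fold of the kept portion.  A pure-exponential-fit alternative
is exposed for sensitivity analysis.  For an Ornstein–Uhlenbeck process with
$\sigma^2 = k_BT/k$ and $\tau = \sigma^2/D$ the estimator recovers
$D = \sigma^2/\tau$ within a few percent at $2\times10^5$ samples.  Series
whose ACF decays within a handful of samples trigger an "under-resolved"
warning rather than a silent bad estimate.

## Permeability integral

`permeability_sd()` evaluates the resistivity integrand
$e^{w(z)/k_BT}/D(z)$ on the PMF grid (the diffusivity profile is linearly
interpolated onto it) and integrates by trapezoid, converting Å to cm.  The
quadrature is exact for flat profiles ($P = D/L$) and matches piecewise
analytic barrier models to $<0.1\%$ at 0.01 Å resolution.  A warning is
raised when $w$ is visibly non-zero at both bounds (bulk not reached).

## TI and FEP

`ti_integrate()` is trapezoid quadrature of $\langle dU/d\lambda\rangle$
over the $\lambda$ grid (the conventional 11-window 0–1 layout is the
generator default), with window standard errors from block averaging
propagated through the quadrature weights.  `fep_stages()` uses exponential
averaging through log-sum-exp when only forward differences exist and the
binless two-state self-consistent estimator (Bennett's acceptance ratio) when
both directions are present — this is also the natural binless reading of
"free energies by WHAM" for two states.  Stage uncertainties come from a
block bootstrap (200 resamples, fixed seed).  The repulsive WCA component of
published workflows is a 9-stage FEP whose stage schedule is rarely printed;
stage boundaries are therefore user input here, and the ladder emitted by the
synthetic generator is a labeled convention.

## Density profiles and scattering

Profiles are accumulated per frame after wrapping into
$[-L_Z/2, L_Z/2)$ and normalized by the *mean* lateral area, which makes the
conservation identity
$\sum_j \rho_j\,\Delta z\,\langle L_XL_Y\rangle = $ (mean total weight per
frame) hold exactly even under box fluctuations; per-frame normalization
would satisfy it only approximately.  Profiles fed to form factors are
symmetrized by default (experimental curves assume a symmetric bilayer); raw
profiles keep both leaflets.  The bulk solvent density $\rho_w$ defaults to
the profile mean over $|z| \ge 30$ Å and is overridable — with a
$\sim$110 Å cell this region is bulk water.  For the dipole potential the
charge profile must be net neutral ($|Q| \le 10^{-6}$ e; the potential
diverges otherwise), and an optional linear detrend equalizing the two box
edges is off by default, since published profiles do not state whether such
a detrend was applied.

## Units and constants

Coordinates and boxes in Å; the membrane normal is $z$ with the bilayer
midplane at $z=0$; energies in kcal/mol with
$k_B = 1.987204259\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$; $K_A$ uses
$k_B = 1.380649\times10^{-16}$ erg/K to land in dyn/cm; diffusivities are
stored in Å²/ps (1 Å²/ps $= 10^{-4}$ cm²/s); potentials in volts via
$e/(\varepsilon_0\cdot\text{Å}) = 180.95$ V.  Default temperatures follow
the usual study conditions: DPPC at 323 K, POPC at 303 K, permeation at
298 K.

# The synthetic-data module

The generators replace multi-hundred-nanosecond MD trajectories with
desk-scale inputs whose ground truth is analytic:

* `gen_bilayer_trajectory()` draws atoms per frame from Gaussian $z$-slabs
  (mirrored at $-z$ for a symmetric bilayer), uniform in $x,y$, with
  Gaussian box-area fluctuations — so every density profile, area series and
  compressibility has a closed-form target.  Declared-order C–H pseudo-pairs
  sit on the cone $\theta = \arccos\sqrt{(2S+1)/3}$, making the order
  parameter exactly $S$.
* `gen_langevin_windows()` integrates overdamped Euler–Maruyama dynamics on
  a declared $w(z)$ plus the window bias, vectorized across windows, with
  the Itô spurious-drift term $\partial D/\partial z$ when $D$ depends on
  position.  The time step must resolve the fastest local relaxation
  ($dt \le \tau_{\min}/10$, enforced); a `thin` option records every
  $n$-th step so stored samples are less correlated at fixed storage.
  Euler–Maruyama inflates the stationary variance by
  $\approx (1 - \theta\,dt/2)^{-1}$ with $\theta = DK/k_BT$, so checks at
  the percent level use $\theta\,dt \lesssim 0.03$.
* `gen_lambda_dataset()` samples the $\lambda$-coupled harmonic oscillator
  exactly (Gaussian at every window), emitting $dU/d\lambda$ and
  neighbor-stage $\Delta U$ with the analytic
  $\Delta G = (k_BT/2)\ln(k_1/k_0)$.
* `gen_ou_series()` is the exact discretization of the Ornstein–Uhlenbeck
  process, the reference input for the diffusivity estimator.

All randomness flows through one seeded stream per generator call; identical
seeds give byte-identical output files.

What the generators deliberately do **not** emulate: molecular connectivity
and excluded volume, leaflet asymmetry, undulations and area–thickness
coupling, non-Markovian memory in the restrained dynamics, and anharmonic
tails of real window distributions.  Passing recovery tests therefore
demonstrate that the *estimators* are correct and well-conditioned at the
stated sampling sizes, not that any force field is accurate.

## Pipeline validation conditions

The end-to-end permeability check declares
$w(z) = 5\,e^{-z^2/112.5}$ kcal/mol (a 5 kcal/mol Gaussian barrier,
$\sigma = 7.5$ Å), constant $D = 0.3$ Å²/ps, $T = 298$ K, umbrella
restraints of 2.5 kcal mol$^{-1}$ Å$^{-2}$ every 0.5 Å across $\pm 40$ Å
with $2\times10^5$ stored samples per window (thinned 3× from
$dt = 0.02$ ps dynamics), and stiff 20 kcal mol$^{-1}$ Å$^{-2}$ restraints
at 5 Å intervals ($2\times10^5$ steps, $dt = 0.005$ ps) for the diffusivity
profile.  The spacing and sampling were chosen so that the window-alignment
random walk — the dominant error, which accumulates from the bulk reference
into the barrier region and enters $P_m$ exponentially — stays well below
$k_BT$; under these conditions the pipeline returns $P_m$ within a few
percent of the declared model's quadrature (the tolerance asserted is 20%).
Problem sizes in the test suite are scaled to keep each check in seconds
while leaving comfortable statistical margin.

# Known limitations

* Only orthorhombic cells and the $z$-normal convention are supported; no
  GRO/XTC/TRR formats, no triclinic wrap, no alignment beyond
  $z$-recentering.
* WHAM is 1-D; no MBAR generalization, no 2-D umbrella sampling.
* The GLE diffusivity estimator assumes a stationary restrained series; its
  ACF-truncation rule is a declared convention (the exact truncation used in
  published analyses is typically unstated).
* Whether published dipole-potential curves were detrended between the two
  bulk regions, and whether $\rho_w$ in form factors was simulation bulk or
  the experimental 0.333 e/Å³, is usually unstated; both choices are
  exposed as arguments.
* Energy evaluation from trajectories is out of scope for the free-energy
  module: $dU/d\lambda$ and $\Delta U$ series are inputs.
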