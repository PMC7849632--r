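---
title: "Two-constituent continuum mechanics of glioma spheroid growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-constituent continuum mechanics of glioma spheroid growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliosphere)
```

## The model

`gliosphere` simulates the avascular growth of a multicellular tumor
spheroid (MTS) embedded in a porous hydrogel, as a spherically symmetric
continuum of two compressible constituents:

* a **visco-elastic cell aggregate**, described by the concentrations of
  three phenotypes — proliferative $C_p$, hypoxic (motile) $C_m$ and
  necrotic $C_n$, with $C_{tot} = C_p + C_m + C_n$ — whose internal stress
  follows an adhesion-calibrated equation of state;
* a **linear elastic extracellular matrix (ECM)** that deforms
  quasi-statically in response to the expanding or contracting aggregate.

Oxygen is the only nutrient.  Its local concentration $n$ drives the
go-or-grow phenotype switch through two thresholds: cells turn hypoxic
below $\xi_h$ and hypoxic cells necrose below $\xi_n$.

### Intercellular stress

The aggregate stress is a function of total concentration alone,

$$\sigma_C = \gamma(C_{tot})\, K_{C0}\left(\frac{C_{tot}}{C_{eq}} - 1\right),$$

with $\gamma = 1$ above the equilibrium concentration $C_{eq}$ (linear
repulsion with bulk modulus $K_{C0}$), $\gamma \propto (C_{tot} -
C_\infty)^2$ between the detachment cut-off $C_\infty$ and $C_{eq}$
(adhesive traction), and $\gamma = 0$ below $C_\infty$ where cells no
longer interact.  The $27/4$ normalisation of the middle branch makes the
global traction minimum exactly $-\sigma_{att}$ at
$C_{tot} = (2C_{eq} + C_\infty)/3$; the unit tests verify this against a
brute-force scan.  $C_\infty$ and the maximum-attraction concentration
derive from the landmarks of a measured cell–cell force–distance curve via
$C = 1/r^3$, and $\sigma_{att}$ from the peak pair force spread over the
cell surface ($n_{nb} f_{max} / S_{cell} \approx 10$ Pa).

### Matrix elasticity and composite stress

The cell aggregate acts on the matrix as a volumetric strain source
$\delta_v = (1/K_{ECM})\, d\sigma_C/dr$, and the radial displacement $u$
solves

$$\frac{d}{dr}\!\left[\frac{1}{r^2}\frac{d}{dr}(r^2 u)\right]
  = \frac{1+\nu}{1-\nu}\,\delta_v, \qquad u(0) = 0,\; u(R_{dom}) = 0,$$

discretised by a symmetric second-order stencil and solved as a
tridiagonal system.  Strains are $\varepsilon_{rr} = du/dr$,
$\varepsilon_{\theta\theta} = \varepsilon_{\phi\phi} = u/r$, and the matrix
stress components use the model's constitutive prefactor
$K_{ECM}/(1+\nu)$:

$$\sigma_{rr} = \frac{K_{ECM}}{1+\nu}\left[(1-\nu)\varepsilon_{rr}
  + 2\nu\varepsilon_{\phi\phi}\right], \qquad
  \sigma_{\phi\phi} = \frac{K_{ECM}}{1+\nu}\left[\nu\varepsilon_{rr}
  + \varepsilon_{\phi\phi}\right],$$

with $\sigma_{ECM} = (2\sigma_{\phi\phi} + \sigma_{rr})/3$.  This
prefactor differs from the textbook Lamé form $E/((1+\nu)(1-2\nu))$; both
are available (`ecm_prefactor = "as_printed"` / `"standard"`), the printed
form being the default.

The composite total stress follows the iso-strain mixture rule,

$$\sigma_{tot} = \left(1 - \frac{C_{tot}}{C_{max}}\right)\sigma_{ECM}
  + \frac{C_{tot}}{C_{max}}\,\sigma_C,$$

and all phenotypes share the Darcy-type drift velocity
$v_D = -M\,\partial\sigma_{tot}/\partial r$ with
$M = M_0$ (constant permeability) or
$M = M_0\,\max(0,\,1-\varepsilon_v/3)^2$ (strain-dependent pore stretch,
$\varepsilon_v = \varepsilon_{rr} + 2\varepsilon_{\phi\phi}$).  The clamp
at zero reflects that fully collapsed pores cannot transmit cells;
behaviour under extreme compression is otherwise unspecified and this is
the conservative choice.

### A structural property: matrix stiffness cancels

Because the source term scales as $1/K_{ECM}$ while the stress scales as
$K_{ECM}\cdot\varepsilon$ and the displacement problem is linear, the
matrix stress — and with it $\sigma_{tot}$ and the entire trajectory — is
**independent of the ECM Young's modulus**; only the Poisson ratio enters.
A regression test asserts this: runs at 1.0 kPa and 2.5 kPa are
numerically identical.  Within this constitutive pair, stiffness-driven
selection of invasion regimes therefore cannot occur; changing `E_ECM`
only rescales $u$ and the strains.  Users probing stiffness effects should
treat this as a known property of the model equations, not a bug in their
configuration.

### Phenotype kinetics and oxygen

The balance of each phenotype couples advection (shared $v_D$), random
motility ($D_m$ for hypoxic cells, $D_p = D_m/10$ or $0$ for proliferative
cells, $D_n = 0$) and the sources

$$S_p = \frac{C_p}{\tau_p} \Lambda - h_{pm}\frac{C_p}{\tau_{pm}}
      + h_{mp}\frac{C_m}{\tau_{mp}}, \qquad
  S_n = h_{nec}\frac{C_m}{\tau_n},$$
$$S_m = h_m \frac{C_m}{\tau_m} \Lambda + h_{pm}\frac{C_p}{\tau_{pm}}
      - h_{mp}\frac{C_m}{\tau_{mp}} - h_{nec}\frac{C_m}{\tau_n},$$

where $\Lambda = (1 - C_{tot}/C_q)(n/n_{max})$ is logistic,
oxygen-modulated proliferation and the switch factors are smooth steps
$h_{pm} = \tfrac12\![1 - \tanh((n - \xi_h)/\lambda)]$,
$h_{mp} = 1 - h_{pm}$,
$h_{nec} = \tfrac12\![1 - \tanh((n - \xi_n)/\lambda)]$ with
$\lambda = 1$ mg/L.  Transitions cancel pairwise, so cells are conserved
up to proliferation and the necrotic pool is monotone non-decreasing
(there is no necrotic removal).  Note a practical consequence of the wide
smooth switch combined with the fast forward transition
($\tau_{pm} = 1$ h): at intermediate oxygen levels (2–3 mg/L) the leak
$h_{pm}/\tau_{pm}$ is already comparable to the proliferation rate, which
damps net growth well above the nominal threshold $\xi_h$.

Oxygen obeys spherical diffusion with uptake
$-(\alpha_p C_p + \alpha_m C_m)$, clamped at zero from below (the clamped
mass is logged in the run metadata).  Two boundary conditions are
supported: a closed domain (RBC, zero flux — total oxygen can only
decline) and permanent supply (PSBC, border pinned at $n_0$).

The logistic factor is clamped at zero on transient overshoot
($C_{tot} > C_q$ causes no crowding death); overshoot can only arise from
the explicit source step and is cosmetic at the default time step.

## Parameters

Defaults (all overridable via `sim_params()` or a YAML config):

| parameter | value | units | note |
|---|---|---|---|
| $V_{cell}$ | 1200 | µm³ | sets $C_{max} = 1/V_{cell} = 8.3\times10^5$ |
| $C_{eq}$ | $3.5\times10^5$ | cells/mm³ | equilibrium packing; an alternative $4\times10^5$ is a config override |
| $C_\infty$, $C_{att}$ | $2.8\times10^4$, $2.35\times10^5$ | cells/mm³ | from force–distance landmarks 33 / 16.2 µm |
| $\sigma_{att}$ | 10 | Pa | peak adhesion traction |
| $K_{C0}$ | 500 | Pa | aggregate bulk modulus ($E=300$ Pa, $\nu=0.4$) |
| $E_{ECM}$ | 1000 | Pa | baseline assumption inside the plausible 500–2500 Pa range (the value is dynamically inert, see above) |
| $\nu_{ECM}$ | 0.13 | — | acellular collagen |
| $M_0$ | $2.88\times10^{-4}$ | mm²/(Pa·day) | $k_0/\mu$ = 1e-12 m² / 300 Pa·s |
| $D_m$, $D_p$ | $2\times10^{-2}$, $D_m/10$ | mm²/day | hypoxic / proliferative motility |
| $D_{ox}$ | 86.4 | mm²/day | oxygen diffusivity |
| $\alpha_p$, $\alpha_m$ | $1.38\times10^{-2}$, $\alpha_p/5$ | (mm³/cell)·mg/(L·day) | uptake rates |
| $\xi_h$, $\xi_n$, $\lambda$ | 1.0, 0.8, 1.0 | mg/L | switch thresholds and width |
| $\tau_p$, $\tau_m$ | 1, 2 | day | doubling times |
| $\tau_{pm}$, $\tau_{mp}$, $\tau_n$ | 1/24, 4, 32/24 | day | transition times; $\tau_n$ follows the rate $0.74\,\mathrm{day}^{-1}$, the alternative 48 h is a config override |
| $R_0$, $C_{init}$, $n_0$ | 0.25 mm, $7\times10^4$, 4 mg/L | | initial sharp spheroid ($C_{init} = C_{eq}/5$), uniform oxygen |
| $R_{dom}$ | 1.5 | mm | domain border; accommodates the ~0.9 mm invasive-zone extent while keeping the closed-domain oxygen budget on a day scale |

The switch mode couples fields: `stiff` enforces the strict dichotomy
($D_p = 0$, $h_m = 0$); `overlap` permits reduced levels of both
($D_p = D_m/10$, $h_m = 1$ — the reduced hypoxic proliferation is already
carried by $\tau_m = 2\tau_p$, so no extra attenuation is applied).
$C_q = C_{max}$ and $n_{max} = n_0$.

## Numerics

* **Grid.** Uniform nodes at $r = 0, dr, \dots, R_{dom}$ with finite-volume
  weights that tile the ball exactly; default $dr = 5$ µm (301 nodes)
  resolves the ~50 µm transition layer with ≥10 nodes.
* **Diffusion.** Conservative finite-volume Crank–Nicolson; under zero-flux
  boundaries $\sum w f$ is conserved to round-off, and at the default
  $dt \le dr^2/D$ the update is bounds-preserving (M-matrix property).
  Verified against the radial heat kernel to <1% $L^2$ error.
* **Advection.** Flux-corrected transport: donor-cell low-order fluxes plus
  a Zalesak-limited centred antidiffusive correction on face areas
  $4\pi r^2$, with identically zero flux through the centre and the outer
  border.  Conservative to round-off, positivity-preserving, no new
  extrema.  The CFL bound $|v|\,dt/dr \le 0.5$ is enforced; the transport
  step sub-cycles automatically when the drift is fast.
* **Elasticity.** Symmetric second-order stencil for the displacement
  equation, Thomas tridiagonal solve.  The outer condition is $u(R_{dom}) =
  0$ only: prescribing both $u$ and $\varepsilon_{rr}$ at the border would
  over-determine a second-order boundary-value problem, so the border
  strain is exposed as a diagnostic instead.  Verified against the
  closed form $u = A(r^2 - R\,r)/4$ for a constant source and a quartic
  manufactured solution with observed order ≈ 2.
* **Splitting.** Per step: mechanics solve → FCT advection → diffusion →
  explicit Euler sources → oxygen step.  Default $dt = 2\times10^{-4}$ day
  (≈17 s) resolves the fastest kinetic process ($\tau_{pm} = 1$ h) with
  ≥200 steps.  $\delta_v$ uses direct differencing of the $\sigma_C$
  profile; the approximate form with $\gamma$ outside the derivative is a
  config toggle (`delta_v_form = "gamma_outside"`).
* **Degenerate inputs.** Negative concentrations from round-off are clamped
  at zero with the clamped mass accumulated in the run metadata;
  non-finite fields abort the run with the last valid snapshot.

Halving $dt$ changes the short-horizon density profile by <1% in $L^2$
(regression-tested); trajectories are bit-reproducible because the model
contains no randomness.

## Scenarios and observables

Five presets span the study conditions: `baseline` (soft matrix, closed
oxygen domain, overlapping switch, constant permeability),
`variable_permeability` (pore-stretch factor on), `stiff_switch` (strict
dichotomy), `subtumor` (stiff matrix with permanent oxygen supply) and
`rigid_rbc` (stiff matrix, closed domain).  All run 5 simulated days and
snapshot every 0.1 day plus the exact times 0.2, 0.3, 0.5, 1, 2, 3, 5.

Post-processing operationalises the headline observables:

* **invasive-zone growth** — displacement of the outermost
  $4\times10^2$ cells/mm³ total-density isoline beyond $R_0$ (the field
  has no formulaic invasive-zone width; the outermost plotted isoline is
  the operational definition);
* **hypoxia onset** — first time the centre-node oxygen falls below
  $\xi_h$, read from a per-step trace;
* **proliferative rims** — off-centre local maxima of $C_p$ above a
  prominence floor; the *main rim band* is frozen around the outermost
  in-core maximum at day 2 and re-used at day 3;
* **rim hypoxic fraction** — volume-weighted $C_m/(C_p + C_m)$ over the
  band.  Necrotic cells are excluded from the denominator because the
  quantity concerns the go/grow split of the live population; the
  necrotic-inclusive variant is available via `include_necrotic = TRUE`.

## What the simulations do and do not show

The synthetic scenarios emulate a 250 µm spheroid seeded at one fifth of
the equilibrium density in a collagen-like gel — sharp initial interface,
uniform initial oxygen, spherical symmetry.  They do not emulate azimuthal
fingering (a 3D instability outside a radial code), matrix fibre
alignment or plastic yield near the centre, necrotic clearance, or
interstitial fluid dynamics; conclusions about real spheroids are limited
accordingly.

Two quantitative cautions follow from the model's own magnitudes, both
load-bearing for interpretation:

1. With traction capped at $\sigma_{att} = 10$ Pa and
   $M_0 \approx 2.9\times10^{-4}$ mm²/(Pa·day), early drift speeds are of
   order $10^{-3}$–$10^{-2}$ mm/day.  Mechanical redistribution of the
   aggregate on sub-day time scales would require stresses two orders of
   magnitude larger than the adhesion cap permits, so early dynamics are
   dominated by proliferation and motility, not drift.
2. Under the closed-domain oxygen condition the total budget
   $n_0 \cdot \tfrac43\pi R_{dom}^3$ supports the initial cell population
   for roughly a day at the tabulated uptake rate, so closed-domain
   scenarios are oxygen-starved well before day 5; sustained growth
   requires the permanent-supply boundary.

The problem sizes used throughout the test-suite are the production ones:
301 grid nodes, $2\times10^{-4}$ day steps, 5-day horizons for scenario
tests (≈ 40 s per run) and shorter horizons (0.02–0.3 day) for behavioural
unit tests.

## Known limitations

* The stiffness cancellation (above) makes `E_ECM` dynamically inert; the
  `subtumor` and `rigid_rbc` presets therefore differ from their soft
  counterparts only through the oxygen boundary condition.
* The smooth switch with $\lambda = 1$ mg/L and $\tau_{pm} = 1$ h leaks
  proliferative cells into the hypoxic pool well above $\xi_h$; sharper
  switches can be emulated by reducing `lambda_switch`.
* Explicit Euler sources limit $dt$; no implicit kinetics are provided.
* No checkpoint/restart; parameter sweeps are expected to be scripted
  externally.
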