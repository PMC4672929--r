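---
title: "An ensemble model of chemoreceptor complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ensemble model of chemoreceptor complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwcens)
```

## The model

Chemoreceptor homodimers in *E. coli* cluster as trimers of dimers (TDs)
that are connected into larger signaling complexes by the adapter protein
CheW and the kinase CheA. `mwcens` models an equilibrium ensemble of such
complexes: each membrane site is either empty or holds one complex of
`x = 1 … x_max` TDs, and all receptors within a complex share a single
two-state (active/inactive) conformation in the Monod–Wyman–Changeux
sense. Ligand binding is integrated out, leaving per-dimer free energies

$$f_{\mathrm{on}} = \Delta\varepsilon(m) - \ln(1 + c/K_{\mathrm{on}}) + \mu,
\qquad
f_{\mathrm{off}} = -\ln(1 + c/K_{\mathrm{off}}) + \mu,$$

in units of $k_BT$. Because the inactive conformation binds attractant more
tightly ($K_{\mathrm{off}} \ll K_{\mathrm{on}}$), activity falls with
ligand concentration $c$; the modification offset
$\Delta\varepsilon(m) < 0$ (for the QEQE/QEQQ/QQQQ states studied here)
biases receptors active at $c = 0$.

A complex of size $x$ has $x-1$ internal linker slots and $x+2$ peripheral
rest-group sites. Under the base **bridged** architecture every linker is
–CheW–CheA₂–CheW– and contributes $\mu_{A_2} + 2\mu_W$ in either
conformational state, plus a coupling energy $J < 0$ when the complex is
active. Rest groups are developed symmetrically across all $x+2$ sites:
none, CheW only, or CheW + CheA₂. The partition function per site is

$$Z = 1 + \sum_S m_S\left(e^{-F_{\mathrm{on}}(S)} +
e^{-F_{\mathrm{off}}(S)}\right),$$

with $m_S$ the multiplicity of species $S$; the leading 1 is the empty
site. Kinase activity is the expectation of CheA₂ dimers in *active*
complexes, $A = \sum_S P_S P_S^{\mathrm{on}} n_{A_2}(S)$ — CheA in rest
groups contributes to $A$ (it autophosphorylates and is seen by FRET) even
though it does not couple TDs.

The defining constraint is a **constant receptor density**
$\rho = \sum_S 3x\,P_S$: at every concentration the chemical potential
$\mu$ is re-solved so that the mean number of receptor dimers per site
stays fixed, reflecting regulated receptor expression and membrane
insertion. This constraint — not receptor modification — is what pins the
average complex size, and with it the Hill coefficient, across conditions.

## Parameters

| parameter | units | meaning | typical fitted value |
|---|---|---|---|
| `delta_eps` | kT | active-state offset of one dimer at c = 0 | −1.1 … −3.0 |
| `kd_on`, `kd_off` | mM | active/inactive dissociation constants | 2.18, 0.001–0.003 |
| `j_coupling` | kT | per-linker active-active coupling J | ≈ −3.8 |
| `mu_w0`, `mu_a2_0` | kT | CheW / CheA₂ potentials at wild-type expression | −0.67, −1.68 |
| `mu_w2_0` | kT | CheW₂ core of a CheW-only linker (wonly schemes) | ≈ −5.0 |
| `rho` | dimers/site | target receptor density, 0 < ρ < 3·x_max | 3.1–10.3 |
| `x_max` | – | largest complex, in TDs | 4 |

`x_max = 4` bounds complexes at 12 dimers, consistent with observed Hill
coefficients; larger values mainly add numerically negligible species.
Expression conditions enter as multiples $(i, j)$ of wild-type CheW/CheA
with $\mu_W(i) = \mu_W^0 - \ln i$ and $\mu_{A_2}(j) = \mu_{A_2}^0 - \ln j$.

### Design choices on under-determined points

Several modeling details are not fixed by the biology alone; the package
resolves them as follows.

* **Sign of the expression scaling.** The chemical potential of an
  integrated protein must *decrease* as its free concentration rises
  (incorporation gets cheaper), so $\mu(i) = \mu^0 - \ln i$. This is also
  the only convention that yields the observed phenomenology — more CheW
  producing larger complexes and higher cooperativity. The wild-type
  potentials $\mu_W^0, \mu_{A_2}^0$ are treated as the fitted primitives;
  the underlying dissociation constants of CheW–receptor and CheW–CheA
  binding never need to be resolved individually.
* **CheW-only linker scaling.** The –CheW–CheW₂–CheW– linker's central
  CheW₂ unit contains two CheW monomers, so its potential scales twice as
  fast with CheW expression: $\mu_{W_2}(i) = \mu_{W_2}^0 - 2\ln i$. (The
  two flanking CheWs contribute $2\mu_W$ exactly as in the bridged
  linker.)
* **Mixed linkers.** When both linker types are enabled, a complex may mix
  them freely; the $\binom{x-1}{k}$ arrangements of $k$ CheA-containing
  linkers among $x-1$ slots are combined into one species with binomial
  multiplicity. Because linker slots are energetically independent, the
  resulting sums factorize exactly into a per-slot factor raised to
  $x - 1$ — an identity the test suite asserts against the enumeration.
* **Coupling energy.** $J$ is awarded per linker of *either* type in
  active complexes; CheW-only linkers couple TDs just as CheA-bridged ones
  do.
* **Symmetric variant.** In the alternative =CheW/CheA₂/CheW= architecture
  both CheA monomers contact trimers directly; linkers contribute
  $2\mu_W + 2\mu_A$ (CheW-only: $4\mu_W$) with $\mu_A(j) = \mu_A^0 - \ln j$
  per monomer. Rest groups are retained in the same three forms with
  $\mu_{A_2}$ replaced by $2\mu_A$, so that the variant differs from the
  base model only in linker stoichiometry, not in rest-group structure.

## Numerics

* **Density solve.** $\rho(\mu)$ is strictly decreasing (a grand-canonical
  ensemble loses occupancy monotonically as the per-particle cost rises),
  so the constraint has a unique root. It is found with Brent's method
  (`stats::uniroot`) inside a bracket expanded by doubling from
  $[-50, 50]$ kT up to $|\mu| = 500$ before failing with diagnostics; the
  achieved density is required to match the target to $10^{-10}$.
  Concentration sweeps warm-start each bracket at the previous solution.
* **Overflow safety.** All Boltzmann weights are handled in log space
  relative to the dominant weight, so bracketing at extreme $\mu$ cannot
  overflow. Since $\mu$ enters every species only through $e^{-3x\mu}$, the
  concentration-dependent part of the weights is computed once per
  concentration and cached through the root search.
* **Degenerate inputs.** $j = 0$ (no CheA) is supported via an infinite
  CheA potential: every CheA-containing species gets exactly zero weight
  and the activity vanishes. In that limit only single TDs survive, so
  density targets above 3 are correctly reported as unattainable.
* **Hill fits.** $A(c) = A_0/(1 + (c/c_H)^{n_H})$ is fitted by
  Levenberg–Marquardt least squares on the *raw* model activities
  (normalization is a plotting concern), initialized at
  $A_0 = \max A$, $c_H$ = grid point nearest half-maximum, $n_H = 2$, with
  all parameters bounded below by zero. The reference grid is 50
  log-spaced concentrations on $[10^{-3}, 1]$ mM; all published-value
  reproductions use exactly this grid.

## Parameter fitting

`fit_global()` minimizes
$\chi^2 = \sum (s_{\mathrm{family}} A_{\mathrm{model}}(c) - y)^2$ over a
bounded box. FRET signals are proportional to kinase activity with an
unknown gain, so one multiplicative scale per condition family (e.g. one
for a CheW series, one for a CheA series) is profiled analytically at every
evaluation ($s^* = \sum A y / \sum A^2$), keeping the nonlinear search
low-dimensional. Start points fill the box with a seeded Latin hypercube
and each is refined by bounded quasi-Newton (`L-BFGS-B`); the default of 50
starts is a desk-scale choice that reliably recovers three free parameters
in the test problems, and the whole procedure is deterministic given the
seed. $\mu_W^0$, $\mu_{A_2}^0$ and $\rho$ are mutually entangled (all three
shift complex-size statistics), so fits share one parameter set across
conditions and fix the concentration grid; confidence intervals are
deliberately not produced, as linear-theory intervals are unreliable for a
model this nonlinear.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of in-vivo FRET
dose-response data: per-condition sigmoids evaluated from the model itself
on a log-spaced grid, one unknown multiplicative signal scale, and additive
homoscedastic Gaussian noise (FRET ratio noise is approximately additive at
these amplitudes). Replicate measurements at a single concentration are
supported. It does **not** emulate photobleaching or other drifts,
concentration-dependent noise, adaptation kinetics, or cell-to-cell
variability — so a successful parameter recovery on synthetic data
demonstrates the identifiability and correctness of the inference
machinery under the model's own assumptions, not robustness to every
artifact of real FRET experiments.

Test problem sizes are deliberately modest: recovery tests use two
informative expression conditions (0.7× CheW and 8× CheA) on 12-point
grids with 2% additive noise and 50 starts, which recovers
$\Delta\varepsilon$, $J$ and $\rho$ to well within 10%.

## Known limitations

* Equilibrium only: assembly/insertion kinetics and adaptation dynamics
  (CheR/CheB, CheY/CheZ) are out of scope.
* No spatial lattice: hexagonal packing motivates the linker stoichiometry
  but geometry, membrane curvature and invagination effects at extreme
  overexpression are not modeled.
* Rest groups are symmetric (all $x+2$ sites identical), a combinatorial
  simplification.
* Experimentally printed Hill coefficients can exceed the model's
  (notably at high CheW under the base scheme); the CheW-only linker
  variant narrows but does not fully close that gap.
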