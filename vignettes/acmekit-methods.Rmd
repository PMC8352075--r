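---
title: "Hybrid master-equation models and the acmekit solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid master-equation models and the acmekit solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmekit)
```

## The model class

`acmekit` solves hybrid master equations for chemical reaction networks and
related population processes.  The state is split in two: continuum species
$x \in \mathbb{R}_+^d$ (scaled concentrations $x = X/\Omega$, where $\Omega$
is a typical molecule count) and a finite set of discrete states indexed by
$k$.  Per discrete state the density $p_k(x, t)$ obeys

$$
\partial_t p_k
= \sum_i \Big[ -e_i^{\mathsf T} \nabla (r_{ik}\, p_k)
 + \tfrac{1}{2\Omega}\, e_i^{\mathsf T} \mathrm{H}(r_{ik}\, p_k)\, e_i \Big]
+ \sum_j \Big[ -f_{jk}\, p_k + \lVert e_j\rVert \!\int\! f_{jk}\, p_k\,
   B_{jk}\, \mathrm{d}z \Big]
+ \sum_\ell \big[ -g_{k\ell}\, p_k + g_{\ell k}\, p_\ell \big],
$$

that is, drift and (optional) $1/2\Omega$-scaled diffusion along each
reaction direction $e_i$, non-local jump exchange with kernel $B_{jk}$ along
$e_j$, and pointwise transition fluxes between discrete states at rates
$g_{k\ell}(x, t)$.

Two deliberate departures from a classical probabilistic model make the
framework reach population-level processes:

* **Signed transition rates.**  A transition at rate $-G(x)$ into a
  *phantom* state adds $+G(x)\,p_k$ to the source state.  This linearises
  population growth: the source density then evolves as an unnormalised
  population density whose mass grows at the population growth rate, and
  the phantom state (which turns negative) is simply ignored.  Signed rates
  are opt-in (`allow_signed_rates`) so that physical models stay safe by
  default.
* **Non-probability kernels.**  A fragmentation kernel integrates to two —
  one division produces two cells — so the number density is deliberately
  non-conservative while the size-weighted (volume) density is conserved.

Absorbing discrete states accumulate mass without evaluating any outgoing
term; they implement first-passage problems (below).

## Spatial discretisation

The domain $[0, x_{\max}]^d$ carries a uniform cell-centred grid with a
single shared width $\Delta x$; cells are $[m\Delta x, (m+1)\Delta x)$ with
centres at $(m + \tfrac12)\Delta x$.  Because every $e_i$ is an integer
vector, each transport term acts along one-dimensional *rays* of cells, so
no transverse numerical diffusion arises in multi-species systems.

**Advection** uses a second-order semi-discrete central scheme of the
Kurganov–Tadmor family: limited linear reconstruction in each cell, a
central flux with local-speed dissipation at each interface, zero flux at
ray ends (no-flux boundaries), and exact discrete conservation by
telescoping.  The default limiter is minmod (most dissipative,
positivity-friendly); `vanleer` and `none` (unlimited central slopes, which
makes the operator exactly linear) are available.

**Flux fusion.**  Antiparallel reactions along the same direction line
(e.g. birth $\lambda(x)$ with $e = +1$ and death $\mu(x)$ with $e = -1$)
are fused into a single flux with net velocity $\lambda - \mu$ before
reconstruction.  This matters: treating them separately makes the scheme's
dissipation scale with the total activity $\lambda + \mu$ instead of the
net drift.  Near a flux-balance point (where $\lambda = \mu$) the
limiter-induced diffusion would then exceed the physical $1/2\Omega$
diffusion several-fold and visibly widen stationary peaks; with fusion the
numerical width of the selection-model profile matches the
Ornstein–Uhlenbeck prediction to a few percent at $\Delta x = 0.007$.
Diffusion coefficients of fused members still add with positive sign, as
the model demands.

**Diffusion** is the conservative central second difference of
$r_{ik} p_k$ along the ray, scaled by $1/(2\Omega\,\Delta x^2)$, with zero
end fluxes.

**Jump operators** are per-ray matrices mapping source-cell density to
destination-cell gain.  Where the kernel has a closed-form CDF (the
exponential burst kernel) each destination cell receives its exact kernel
mass; otherwise the midpoint rule is used.  In probability mode, columns
are renormalised to sum to one, folding mass that would land outside the
truncated domain back into the retained destinations — this preserves the
conservation law the mode owes.  In fragmentation mode the quadrature
covers the support $(0, \text{source})$ exactly, and the deposit that stays
inside the source cell is split 3:1 with the downstream neighbour so that
the first moment (volume) of every column is conserved to machine precision
at cell-centre accounting.  Only the ray-end cell, which cannot represent
sub-cell fragment sizes, is exempt; its contribution to the global volume
drift is below $10^{-4}$ in the benchmarks.

## Time integration

Explicit strong-stability-preserving RK3 (default; Heun and Euler
available) under a conservative CFL bound combining three limits:
$\Delta x / \max|r|$ (advection), $\Omega \Delta x^2 / \max(r\,\lVert e
\rVert^2)$ (diffusion), and $1/\max(\text{total local outgoing rate})$
(jump losses and transitions), multiplied by a safety factor (default 0.4).
Snapshots are hit exactly by step clipping, never by interpolation, and the
solver is fully deterministic — no randomness anywhere.

**Stiff absorption sinks.**  First-passage augmentation uses absorption
rates like $\alpha = 1000$, which would force $\mathrm{d}t \lesssim 4
\times 10^{-4}$.  With `split_sinks = TRUE`, transitions into absorbing
states are removed from the explicit operator and applied after each step
through their exact local exponential solution (Lie splitting, first order
in the coupling).  The absorbed mass is tracked exactly; against fully
explicit stepping the split agrees at the per-cent level while taking an
order of magnitude fewer steps.

**Steady states** can be computed two ways.  `method = "march"` integrates
until $\lVert \partial_t p \rVert_1 / \lVert p \rVert_1$ falls below
`steady_tol` (detection by right-hand-side norm, independent of snapshot
cadence).  `method = "direct"` (default) assembles the linearised operator
(unlimited slopes), replaces one row with the unit-mass constraint, and
solves the sparse system — the natural choice for the stationary
benchmarks, where time marching the 31-state gene-expression model at
$\gamma = 80$ would need millions of explicit steps.  Both paths are
cross-checked against each other and against a dense eigendecomposition on
small grids in the test suite.

## Domain truncation

Truncation bounds are numerical choices, set so that the truncated tail of
the relevant stationary or initial density is far below the comparison
tolerances:

* gene expression (bursty and finite-$\gamma$): $x \in [0, 6]$.  The
  canonical stationary density behaves like a Gamma tail with mean 2.4 and
  keeps 1.4% of its mass beyond $x = 4$, so a $[0,4]$ box would bias an
  $L^1$ comparison at the 0.02 level by the truncation alone; at
  $x_{\max} = 6$ the tail is $4 \times 10^{-5}$.
* selection: $x \in [0, 1.001]$ (143 cells of width 0.007; both drift
  roots are interior).
* fragmentation: $x \in [0, 3]$ for the pure case, whose initial profile
  $\propto e^{-2.5 x^3}$ is compactly concentrated, and $[0, 6]$ for the
  growth/decay case, whose early-time profile $\propto e^{-0.2 x^2}$ still
  carries $\sim 10^{-3}$ of its volume near $x = 3$.

The solver warns whenever more than $10^{-6}$ of the mass sits in the
outermost two cells.  Grids finer than one molecule ($\Delta x\,\Omega <
1$) draw a warning, not an error, so convergence studies remain possible.

## Case studies and their oracles

**Self-regulated gene expression.**  Transcription at a Hill rate
$H(x) = r_0 + r_1 x^n/(1+x^n)$, translation, and first-order decay of both
species; canonical parameters $r_0 = 2$, $r_1 = 10$, $n = 4$, $B = 40$,
$\gamma_0 = 1$, $\Omega = 200$ (`gene_expression_params()`).  Two model
forms are built: the finite-mRNA-lifetime form (mRNA count $0..K$ as
discrete states, per-state drift $k\gamma b - \gamma_0 x$ with
$b = B/\Omega$) and the bursty limit $\gamma \to \infty$ (exponential burst
kernel of mean $b$).  Oracles: the closed-form stationary density
$\propto e^{-x/b} x^{r_0/\gamma_0 - 1}(1+x^n)^{r_1/(n\gamma_0)}$, the
truncated discrete master equation solved as a sparse stationary problem
(`cme_reference`), and the $1/\gamma$ convergence of the finite-$\gamma$
steady states to the bursty limit (measured slope $-0.98$).

**First-passage times.**  An absorbing state is added with transition rate
$\alpha\,\mathbf{1}(x \text{ beyond } x_c)$; a cell is "inside" the region
iff its centre is, consistent with cell-average semantics.  The absorbed
mass is the switching-time CDF; `switching_summary()` derives the density,
mode (quadratic interpolation through the peak triple), median, tail rate
(log-linear fit over the last decade), and the mean with an exponential
tail correction $S(T)(T + 1/\lambda_{\text{tail}})$.  The quadrature oracle
evaluates the closed-form mean switching times via the integrating factor
$M(x) = \log(x/H) - x/b + \int^x H/(\gamma_0 y)\,\mathrm{d}y$ (the
divergent part is folded into its closed-form antiderivative; $M$ enters
only through differences, so its additive constant is immaterial) and the
inner integral $V$; the time to fall below $x_c$ integrates from $x_c$,
which is forced by the boundary condition $T(x_c) = 0$ and by
integrability of the integrand at the origin.  Simulated means at
$x_0 \in \{0.5, 1.5\}$ agree with the quadrature to 2.4% and 0.3%.

**Phenotypic selection.**  Birth $\lambda = \Lambda x(1-x)$, death
$\mu = x$, diffusion $(\lambda + \mu)/2\Omega$, growth field $G = gx$
realised as a $-G$ transition into a phantom state.  The default
$\Omega = 1000$ follows from the stated lumping of seven molecules per
cell at $\Delta x = 0.007$ — an inference, not a printed value.  The
large-time oracle is the Gaussian profile centred at $x_c = 1 - 1/\Lambda$
growing at $r_0 = G(x_c) = g(1 - 1/\Lambda)$.  The profile width is derived
here by a local Ornstein–Uhlenbeck expansion about the critical point:
variance $a/(2\Omega)$ with $a = (\lambda+\mu)(x_c)/|(\lambda-\mu)'(x_c)|
= 2/\Lambda$.  A moment-matched empirical fit (`fit_gaussian_profile()`)
is provided alongside; at $t = 5$ the fitted variance is within 10% of the
analytic value and the $L^1$ distance of the normalised profile to the
Gaussian is 0.035.

**Growth–fragmentation.**  Fragmentation at rate $a x^k$ with the uniform
binary-division kernel $2/y$ on $(0, y)$; optionally linear growth
($\dot x = x$) and uniform decay realised as a transition into an inert
absorbing state (the variant's fragmentation rate is $a k x^k$).  The
oracles are the self-similar pure-fragmentation solution, the explicit
growth/decay solution, and its limiting profile $c\,a^{2/k} e^{-a x^k}$.
One caveat is itself closed-form: at $t - t_0 = 2$ the exact solution still
sits at $L^1 = 0.028$ from its $t \to \infty$ limit, so convergence to the
limit can only be judged relative to that gap; the solver's own error
against the exact solution at that time is $1.5 \times 10^{-3}$.

## The synthetic-model generator

`generate_random_model()` produces seeded, reproducible, well-posed models
(bounded non-negative polynomial rates, probability-mode exponential
kernels, non-negative transitions, optional diffusion) used for
conservation and linearity fuzzing.  It emulates the *structure* of the
model class, not the stiffness, multimodality, strong non-locality or
signed rates of the real case studies — passing the fuzz suite therefore
certifies bookkeeping (conservation, linearity, determinism), while
quantitative accuracy is certified by the closed-form benchmarks above.

## Numerical choices and degenerate inputs

* Quadrature for the switching-time formulas: adaptive (`stats::integrate`)
  with relative tolerance $10^{-9}$; improper upper limits are cut where
  $e^{M}$ has fallen 40 log-units below its maximum ($x \approx 15$ for the
  canonical parameters), where the integrand is below $10^{-14}$ of its
  peak.
* Benchmark problem sizes: 120–240 cells for the gene-expression studies,
  143 for selection, 600–1200 for fragmentation; the CME reference
  truncates the protein at $x_{\max}\Omega$ counts and 30 mRNA states.
* Ties and flat peaks: the mode interpolation falls back to the grid
  argmax when the peak triple is not strictly concave.
* Empty models integrate exactly (zero tendency); models with all rates
  zero take a single step spanning the horizon.
* Reducible truncated chains make `cme_steady_state()` fail loudly with
  the closed classes listed; a single absorbing class is legitimate and
  returns the point mass.
* Time-dependent rates are supported by re-evaluating rates at each stage;
  the CFL step is recomputed per step only when `recompute_dt = TRUE`,
  since the bound is state-independent for autonomous models.

## Known limitations

* Explicit time stepping only; no IMEX or implicit integrators, so very
  stiff non-sink terms require small steps.
* The direct steady-state path linearises with unlimited slopes; for
  solutions with sharp fronts the march with minmod is the safer check.
* Binary and higher-order interactions (coalescence, aggregation) are out
  of scope; jump gains are linear in the density.
* Cell-average semantics cannot represent sub-cell fragment sizes at the
  smallest-size cell (see the jump-operator discussion above).
* Densities are exported as tidy CSV/JSON; no binary container format is
  provided.
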