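# acmekit

Deterministic solver for hybrid master equations: chemical reaction
networks whose abundant species live on a continuum (Fokker–Planck
drift–diffusion), coupled to discrete states (low-copy species or abstract
configurations), non-local jump processes (bursty production, cell
division), and — deliberately beyond the classical probabilistic setting —
*signed* discrete transition rates and non-probability jump kernels that
encode population-level processes such as phenotypic selection and
growth–fragmentation.

It is aimed at quantitative/systems biologists who need full transient and
stationary distributions (not moment closures or stochastic-simulation
samples) of models like self-regulated gene expression, first-passage-time
problems, selection-coupled birth–death dynamics, and size-structured
population balances.

## The model

Per discrete state `k`, the density `p_k(x, t)` over the scaled
concentration `x = X/Ω` obeys

    ∂t p_k = Σ_i [ −e_iᵀ∇(r_ik p_k) + (1/2Ω) e_iᵀ H(r_ik p_k) e_i ]      (reactions)
           + Σ_j [ −f_jk p_k + ‖e_j‖ ∫ f_jk p_k B_jk dz ]                 (jumps)
           + Σ_ℓ [ −g_kℓ p_k + g_ℓk p_ℓ ]                                 (transitions)

Rates `g_kℓ` may be negative (transitions into *phantom* states linearise
exponential population growth), and fragmentation kernels integrate to two
(one division, two cells), so the density is a population density rather
than a probability when these augmentations are used.

The solver is a conservative second-order central finite-volume scheme
(Kurganov–Tadmor family, minmod-limited, antiparallel fluxes fused into net
velocities) with SSP-RK3 time stepping under CFL control, exact-exponential
splitting for stiff absorption sinks, and both time-marched and direct
(sparse null-space) stationary solves. A truncated discrete
chemical-master-equation reference solver and a set of closed-form
benchmark densities and mean first-passage quadratures are included as
oracles.

## Worked example

Stationary density of bursty self-regulated gene expression (Hill-regulated
bursts of mean size `b = 0.2`, linear decay), compared with its closed form:

```r
library(acmekit)

m  <- build_gene_expression_bursty(dx = 0.05)   # domain [0, 6], 120 cells
ss <- steady_state(m)                           # direct sparse solve
x  <- drop(acme_grid(m)$centres)
L1 <- sum(abs(ss[, 1] - stationary_bursty_density(x))) * 0.05
peaks <- which(diff(sign(diff(ss[, 1]))) == -2) + 1L
c(L1 = L1, modes = length(peaks), low = x[peaks[1]], high = x[peaks[2]])
#>       L1    modes      low     high
#> 0.015859 2.000000 0.225000 2.075000
```

The solver reproduces the bimodal stationary law (low mode near `x = 0.23`,
high mode near `x = 2.1`) with an L1 error of 0.016 at `Δx = 0.05` — ten
protein molecules per cell at the canonical system size `Ω = 200`.

First-passage times across the boundary `x_c = 0.825` between the two
modes, via an absorbing-state augmentation:

```r
ma <- augment_first_passage(build_gene_expression_bursty(dx = 0.025),
                            x_c = 0.825, alpha = 1000, start_side = "low")
tr <- acme_integrate(ma, delta_initial(ma, 0.5),
                     solver_settings(t_final = 150, split_sinks = TRUE))
sw <- switching_summary(tr)
sw
#> <switching_summary> mode=0.02488 median=1.98 mean=3.45 lambda_tail=0.236 absorbed=1
mean_switching_times(switching_time_inputs(), 0.5)$T_low_high
#> [1] 3.535052
```

The simulated mean (3.45) agrees with the closed-form quadrature (3.54) to
2.4%, and the distribution is heavily skewed: the mean exceeds the mode by
two orders of magnitude.

Models can equally be described in YAML/JSON and driven from the shell
(`exec/acmekit`): `acmekit validate model.yaml`, `acmekit run model.yaml
--out results/`, `acmekit example selection`, `acmekit analytic
bursty-stationary --out table.csv`.

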