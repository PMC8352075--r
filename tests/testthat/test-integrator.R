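test_that("compute_dt applies the advective, rate and static branches", {
  # pure advection, |v| <= 1, dx = 0.05, safety 0.4 -> dt = 0.02
  m <- acme_model(continuum_species("x", 1, 20),
                  reactions = reaction(1L, function(x, t = 0) pmin(1, 1 + 0 * x)))
  st <- solver_settings(t_final = 100)
  expect_equal(compute_dt(m, NULL, 0, st), 0.02)

  # adding a stiff local absorption rate 1000 forces dt <= 0.4e-3
  ma <- acme_model(continuum_species("x", 1, 20),
                   states = list(discrete_state("a"),
                                 discrete_state("sink", absorbing = TRUE)),
                   reactions = reaction(1L, 1),
                   transitions = list(discrete_transition("a", "sink", 1000)))
  expect_lte(compute_dt(ma, NULL, 0, st), 0.4e-3)
  # ... unless the sink is split out of the explicit operator
  st_split <- solver_settings(t_final = 100, split_sinks = TRUE)
  expect_equal(compute_dt(ma, NULL, 0, st_split), 0.02)

  # static model: dt is the remaining time
  m0 <- acme_model(continuum_species("x", 1, 20))
  expect_equal(compute_dt(m0, NULL, 0, solver_settings(t_final = 7)), 7)
})

test_that("a zero-rhs model is integrated exactly and deterministically", {
  m0 <- acme_model(continuum_species("x", 1, 16))
  p0 <- uniform_density(m0)
  tr1 <- acme_integrate(m0, p0, solver_settings(t_final = 3))
  expect_identical(unclass(tr1$snapshots[[length(tr1$snapshots)]])[, 1],
                   unclass(p0)[, 1])
  # bit-identical repetition on a nontrivial model
  m <- generate_random_model(5, n_states = 2L)
  p <- uniform_density(m)
  a <- acme_integrate(m, p, solver_settings(t_final = 0.5))
  b <- acme_integrate(m, p, solver_settings(t_final = 0.5))
  expect_identical(a$snapshots[[length(a$snapshots)]],
                   b$snapshots[[length(b$snapshots)]])
  expect_identical(a$observables, b$observables)
})

test_that("phantom growth and two-state exchange match scalar closed forms", {
  sp <- continuum_species("x", 1, 8)
  mg <- acme_model(sp, states = list(discrete_state("k0"),
                                     discrete_state("ph", phantom = TRUE)),
                   transitions = list(discrete_transition("k0", "ph", -0.7)),
                   allow_signed_rates = TRUE)
  p0 <- uniform_density(mg, "k0")
  tr <- acme_integrate(mg, p0, solver_settings(t_final = 3, cfl_safety = 0.05))
  expect_equal(unname(tail(tr$observables$mass_k0, 1)), exp(0.7 * 3),
               tolerance = 1e-4)

  m2 <- acme_model(sp, states = list(discrete_state("a"), discrete_state("b")),
                   transitions = list(discrete_transition("a", "b", 1),
                                      discrete_transition("b", "a", 1)))
  p2 <- uniform_density(m2, "a")
  tr2 <- acme_integrate(m2, p2, solver_settings(t_final = 4, cfl_safety = 0.05))
  obs <- tr2$observables
  expect_equal(obs$mass_a, 0.5 + 0.5 * exp(-2 * obs$t), tolerance = 1e-4)
  expect_equal(unname(tail(obs$mass_a, 1)), 0.5, tolerance = 1e-3)
})

test_that("probability-mode models conserve mass through long integration", {
  m <- build_gene_expression_bursty(dx = 0.1)
  p0 <- uniform_density(m)
  tr <- acme_integrate(m, p0, solver_settings(t_final = 10))
  expect_lt(abs(tail(tr$observables$mass_k0, 1) - 1), 1e-8)
})

test_that("snapshots are taken exactly at the requested times", {
  m <- toy_birth_death(32L)
  p0 <- uniform_density(m)
  tr <- acme_integrate(m, p0,
                       solver_settings(t_final = 1,
                                       snapshot_times = c(0.25, 0.618, 1)))
  expect_equal(tr$times, c(0.25, 0.618, 1))
})

test_that("split-exponential sinks match the explicitly stepped operator", {
  sp <- continuum_species("x", 1, 16)
  mk <- function() acme_model(
    sp, states = list(discrete_state("a"),
                      discrete_state("sink", absorbing = TRUE)),
    reactions = reaction(-1L, function(x, t = 0) x),
    transitions = list(
      discrete_transition("a", "sink",
                          function(x, t = 0) 500 * as.numeric(x > 0.5))))
  m <- mk()
  p0 <- uniform_density(m, "a")
  expl <- acme_integrate(m, p0, solver_settings(t_final = 1))
  spl <- acme_integrate(m, p0, solver_settings(t_final = 1,
                                               split_sinks = TRUE))
  # total mass conserved in both treatments, absorbed fractions agree
  expect_lt(abs(sum(density_mass(expl$snapshots[[1]])) - 1), 1e-10)
  expect_lt(abs(sum(density_mass(spl$snapshots[[1]])) - 1), 1e-10)
  # Lie splitting of the sink is first order in dt, so the two treatments
  # agree at the few-per-cent level at the advective CFL step
  expect_equal(tail(spl$observables$mass_sink, 1),
               tail(expl$observables$mass_sink, 1), tolerance = 0.05)
  expect_lt(spl$steps, expl$steps / 5)  # the split removes the stiff limit
})

test_that("steady_state direct and march agree and preserve mass", {
  m <- build_gene_expression_bursty(dx = 0.1, x_max = 4)
  p0 <- uniform_density(m)
  direct <- steady_state(m, p0)
  expect_true(attr(direct, "converged"))
  expect_equal(unname(total_mass(direct)), 1, tolerance = 1e-10)
  march <- steady_state(m, p0, solver_settings(t_final = 400,
                                               steady_tol = 1e-9,
                                               limiter = "none"),
                        method = "march")
  expect_lt(sum(abs(march[, 1] - direct[, 1])) * 0.1, 1e-4)

  # already-stationary input returns immediately
  m0 <- acme_model(continuum_species("x", 1, 8))
  p <- uniform_density(m0)
  out <- steady_state(m0, p, method = "march")
  expect_true(attr(out, "converged"))
  expect_identical(unclass(out)[, 1], unclass(p)[, 1])
})

test_that("steady_state matches an eigen-solve oracle on a small model", {
  # 12-cell decay+jump model: stationary density from a dense null-space
  # eigendecomposition of the assembled operator
  m <- acme_model(continuum_species("x", 1, 12),
                  reactions = reaction(-1L, function(x, t = 0) x),
                  jumps = jump_process(1L, 1, jump_kernel_exponential(0.3),
                                       "probability"))
  A <- as.matrix(operator_matrix(m))
  eig <- eigen(A)
  i0 <- which.min(abs(eig$values))
  v <- Re(eig$vectors[, i0])
  v <- v / (sum(v) * (1 / 12))
  ss <- steady_state(m)
  expect_equal(unname(ss[, 1]), v, tolerance = 1e-8)
})

test_that("non-finite rates are rejected before integration", {
  mbad <- acme_model(continuum_species("x", 1, 16),
                     reactions = reaction(1L, function(x, t = 0)
                       ifelse(x > 0.5, NaN, 1)))
  p0 <- uniform_density(mbad)
  expect_error(acme_integrate(mbad, p0, solver_settings(t_final = 1)),
               "non-finite")
})
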