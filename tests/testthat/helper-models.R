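# Small fixture builders shared across test files.  Everything is generated
# in code; no stored data.

# minimal 1-species birth-death model (well-posed by construction)
toy_birth_death <- function(n_cells = 16L, lambda = 1, mu = 1) {
  acme_model(continuum_species("x", 1, n_cells),
             reactions = list(reaction(1L, lambda, name = "birth"),
                              reaction(-1L, function(x, t = 0) mu * x,
                                       name = "death")))
}

# uniform unit-mass density on a model's grid
uniform_density <- function(model, state = NULL) {
  grid <- acme_grid(model)
  labels <- state_labels_of(model)
  if (is.null(state)) state <- labels[1]
  project_density(function(x) rep.int(1, NROW(x)), grid, labels, state,
                  normalise = TRUE)
}

state_labels_of <- function(model)
  vapply(model$states, `[[`, character(1), "label")

random_density <- function(model, seed = 1) {
  grid <- acme_grid(model)
  labels <- state_labels_of(model)
  set.seed(seed)
  grid_density(grid, labels,
               matrix(runif(grid$n_total * length(labels)),
                      grid$n_total, length(labels)))
}

rhs_of <- function(model, p, t = 0, limiter = "minmod") {
  f <- make_rhs(model, limiter = limiter)
  f(unclass(p), t)
}
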