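# Prebuilt models for the three benchmark applications: self-regulated gene
# expression (finite mRNA lifetime and the bursty limit), first-passage
# absorption, phenotypic selection via a phantom state, and
# growth-fragmentation.  Plus a seeded random-model generator for property
# tests.

#' Gene expression with finite mRNA lifetime
#'
#' One continuum species (scaled protein level) and `K + 1` discrete states
#' holding the mRNA copy number `0..K`.  State `k` advects the protein with
#' drift `k * gamma * b - gamma0 * x` (translation minus decay, with
#' continuum-scaled per-mRNA production `gamma * b`), mRNA transcription
#' `k -> k+1` at the Hill rate of the protein level, and mRNA decay
#' `k -> k-1` at `gamma * k`.  Diffusion is off (noiseless limit).
#'
#' @param K mRNA truncation (`>= 1`).
#' @param gamma mRNA production/degradation rate scale (`> 0`).
#' @param params parameter list, see [gene_expression_params()].
#' @param dx cell width.
#' @param x_max protein domain truncation.
#' @param hill_fn optional override of the transcription rate function of
#'   `x` (defaults to the Hill rate with `params`).
#' @return an [acme_model()].
#' @export
build_gene_expression_finite_gamma <- function(K = 30L, gamma,
                                               params = gene_expression_params(),
                                               dx = 0.05, x_max = 6,
                                               hill_fn = NULL) {
  stopifnot(K >= 1L, gamma > 0)
  P <- params
  n_cells <- as.integer(round(x_max / dx))
  labels <- paste0("m", 0:K)
  states <- lapply(labels, discrete_state)
  if (is.null(hill_fn))
    hill_fn <- function(x, t = 0) hill_rate(x, P$r0, P$r1, P$n)
  production <- stats::setNames(lapply(0:K, function(k) {
    rate_k <- k * gamma * P$b
    function(x, t = 0) rep.int(rate_k, NROW(x))
  }), labels)
  decay <- function(x, t = 0) P$gamma0 * x
  transitions <- list()
  for (k in 0:(K - 1)) {
    transitions[[length(transitions) + 1L]] <-
      discrete_transition(labels[k + 1L], labels[k + 2L], hill_fn)
    rate_k <- gamma * (k + 1)
    transitions[[length(transitions) + 1L]] <-
      discrete_transition(labels[k + 2L], labels[k + 1L],
                          local({
                            r <- rate_k
                            function(x, t = 0) rep.int(r, NROW(x))
                          }))
  }
  acme_model(species = continuum_species("protein", x_max, n_cells),
             states = states,
             reactions = list(reaction(1L, production, name = "translation"),
                              reaction(-1L, decay, name = "protein decay")),
             transitions = transitions,
             omega = P$omega, diffusion = FALSE)
}

#' Bursty gene expression (instantaneous mRNA limit)
#'
#' One continuum species, one state: drift `-gamma0 * x` and a non-local
#' burst-production jump at the Hill rate with forward exponential kernel of
#' mean `b` (probability mode, mass conserving).
#'
#' @inheritParams build_gene_expression_finite_gamma
#' @return an [acme_model()].
#' @export
build_gene_expression_bursty <- function(params = gene_expression_params(),
                                         dx = 0.05, x_max = 6) {
  P <- params
  n_cells <- as.integer(round(x_max / dx))
  acme_model(species = continuum_species("protein", x_max, n_cells),
             states = discrete_state("k0"),
             reactions = reaction(-1L, function(x, t = 0) P$gamma0 * x,
                                  name = "protein decay"),
             jumps = jump_process(1L,
                                  function(x, t = 0) hill_rate(x, P$r0, P$r1, P$n),
                                  jump_kernel_exponential(P$b),
                                  mode = "probability", name = "burst"),
             omega = P$omega, diffusion = FALSE)
}

#' First-passage augmentation
#'
#' Adds an absorbing discrete state and, from every original non-phantom
#' state, a transition into it at rate `alpha * indicator(x beyond x_c)`:
#' for a start on the low side the absorbing region is `x > x_c`, for a
#' start on the high side `x < x_c`.  A cell counts as inside the region iff
#' its centre is.  The original dynamics are untouched; the absorbed mass as
#' a function of time is the switching-time CDF.
#'
#' @param model the model to augment.
#' @param x_c critical boundary.
#' @param alpha absorption rate (large = sharp absorption).
#' @param start_side `"low"` (initial condition below `x_c`) or `"high"`.
#' @param label label of the new absorbing state.
#' @return augmented [acme_model()].
#' @export
augment_first_passage <- function(model, x_c = 0.825, alpha = 1000,
                                  start_side = c("low", "high"),
                                  label = "absorbed") {
  start_side <- match.arg(start_side)
  stopifnot(alpha >= 0)
  region <- if (start_side == "low") {
    function(x, t = 0) alpha * as.numeric(x > x_c)
  } else {
    function(x, t = 0) alpha * as.numeric(x < x_c)
  }
  phantom <- state_flag(model, "phantom")
  absorbing <- state_flag(model, "absorbing")
  labels <- state_labels(model)
  new_transitions <- model$transitions
  for (k in labels[!phantom & !absorbing])
    new_transitions[[length(new_transitions) + 1L]] <-
      discrete_transition(k, label, region)
  acme_model(species = model$species,
             states = c(model$states, list(discrete_state(label, absorbing = TRUE))),
             reactions = restrict_rates(model$reactions, labels),
             jumps = restrict_rates(model$jumps, labels),
             transitions = new_transitions,
             omega = model$omega, diffusion = model$diffusion,
             allow_signed_rates = model$allow_signed_rates)
}

# keep normalised per-state rate lists pinned to the original states so the
# added state inherits no dynamics
restrict_rates <- function(items, labels) {
  lapply(items, function(it) {
    it$rate <- it$rate[intersect(names(it$rate), labels)]
    it$rate <- it$rate[!vapply(it$rate, is.null, logical(1))]
    it
  })
}

#' Point-mass initial condition
#'
#' All mass in the single cell containing `x0` (density `1/dx` there).
#'
#' @param model or grid.
#' @param x0 location.
#' @param state receiving state label.
#' @return a [grid_density()].
#' @export
delta_initial <- function(model, x0, state = NULL) {
  grid <- if (inherits(model, "acme_grid")) model else acme_grid(model)
  labels <- if (inherits(model, "acme_model")) state_labels(model) else "k0"
  if (is.null(state)) state <- labels[1]
  cell <- pmin(pmax(floor(x0 / grid$dx) + 1L, 1L), grid$n_cells[1])
  p <- grid_density(grid, labels)
  p[cell, state] <- 1 / grid$dx^grid$d
  p
}

#' Switching-time summary from an absorbed-mass record
#'
#' Computes the switching-time density (time derivative of the absorbed
#' mass), its CDF, the mode (quadratic interpolation through the peak
#' triple), median (linear CDF interpolation), mean with an exponential tail
#' correction, and the tail decay rate `lambda_tail` fitted log-linearly
#' over the last decade of the record.
#'
#' @param traj an [acme_integrate()] trajectory of an augmented model, or a
#'   data.frame with columns `t` and `cdf`.
#' @param absorbing label of the absorbing state (ignored for data.frame
#'   input).
#' @return list of class `switching_summary` with `t`, `density`, `cdf`,
#'   `mode`, `median`, `mean`, `lambda_tail`, `tail_r2`, `absorbed`;
#'   a `warning` element is set when less than 99% of the mass was absorbed
#'   by the horizon (tail correction dominates).
#' @export
switching_summary <- function(traj, absorbing = "absorbed") {
  if (inherits(traj, "acme_trajectory")) {
    t <- traj$observables$t
    cdf <- traj$observables[[paste0("mass_", absorbing)]]
    if (is.null(cdf)) stop("no absorbing state '", absorbing, "' in trajectory")
  } else {
    t <- traj$t
    cdf <- traj$cdf
  }
  keep <- !duplicated(t)
  t <- t[keep]
  cdf <- cdf[keep]
  tm <- 0.5 * (t[-1] + t[-length(t)])
  dens <- diff(cdf) / diff(t)
  dens[dens < 0] <- 0

  ipk <- which.max(dens)
  mode <- tm[ipk]
  if (ipk > 1 && ipk < length(dens)) {
    # quadratic through the peak triple to reduce grid bias
    t3 <- tm[(ipk - 1):(ipk + 1)]
    d3 <- dens[(ipk - 1):(ipk + 1)]
    den <- d3[1] - 2 * d3[2] + d3[3]
    if (den < 0) {
      h1 <- t3[2] - t3[1]
      mode <- t3[2] - 0.5 * h1 * (d3[3] - d3[1]) / den
    }
  }

  absorbed <- cdf[length(cdf)]
  med <- if (absorbed >= 0.5) {
    i <- which(cdf >= 0.5)[1]
    if (i == 1L) t[1] else
      t[i - 1] + (0.5 - cdf[i - 1]) / (cdf[i] - cdf[i - 1]) * (t[i] - t[i - 1])
  } else NA_real_

  horizon <- t[length(t)]
  tail_sel <- tm >= horizon / 10 & dens > 0
  lambda_tail <- NA_real_
  tail_r2 <- NA_real_
  if (sum(tail_sel) >= 5) {
    fit <- stats::lm(log(dens[tail_sel]) ~ tm[tail_sel])
    lambda_tail <- -unname(stats::coef(fit)[2])
    tail_r2 <- summary(fit)$r.squared
  }
  mean_body <- sum(tm * diff(cdf))
  remaining <- max(1 - absorbed, 0)
  mean_t <- if (is.finite(lambda_tail) && lambda_tail > 0) {
    mean_body + remaining * (horizon + 1 / lambda_tail)
  } else mean_body
  out <- list(t = tm, density = dens, cdf = cdf[-1], mode = mode,
              median = med, mean = mean_t, lambda_tail = lambda_tail,
              tail_r2 = tail_r2, absorbed = absorbed)
  if (absorbed < 0.99)
    out$warning <- sprintf(
      "only %.3f of the mass absorbed by the horizon; tail correction dominates",
      absorbed)
  structure(out, class = "switching_summary")
}

#' @export
print.switching_summary <- function(x, ...) {
  cat("<switching_summary> mode=", signif(x$mode, 4),
      " median=", signif(x$median, 4), " mean=", signif(x$mean, 4),
      " lambda_tail=", signif(x$lambda_tail, 4),
      " absorbed=", signif(x$absorbed, 4), "\n", sep = "")
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

#' Phenotypic selection model
#'
#' Logistic birth `lambda(x) = Lambda x (1 - x)` and linear death
#' `mu(x) = x` of a continuum species, with finite-system-size diffusion
#' `(lambda + mu)/(2 omega)`, coupled to a growth field `G(x) = g x` through
#' a phantom state: density flows from the physical state into the phantom
#' at rate `-G(x)`, which adds `+G(x) p` to the physical state and makes the
#' total physical mass grow at the population growth rate.
#'
#' @param Lambda birth factor.
#' @param g growth factor (`G(x) = g x`).
#' @param omega system size.
#' @param dx cell width (the domain is `ceiling(1/dx)` cells, slightly
#'   overshooting `x = 1` so that `dx` is exact).
#' @return an [acme_model()]; the growth field is attached as
#'   `attr(, "growth_field")`.
#' @export
build_selection_model <- function(Lambda = 3, g = 0.5, omega = 1000,
                                  dx = 0.007) {
  stopifnot(Lambda > 0, omega > 0)
  n_cells <- as.integer(ceiling(1 / dx - 1e-9))
  x_max <- n_cells * dx
  G <- function(x, t = 0) g * x
  m <- acme_model(
    species = continuum_species("x", x_max, n_cells),
    states = list(discrete_state("k0"),
                  discrete_state("phantom", phantom = TRUE)),
    reactions = list(
      reaction(1L, list(k0 = function(x, t = 0) Lambda * x * (1 - x)),
               name = "birth"),
      reaction(-1L, list(k0 = function(x, t = 0) x), name = "death")),
    transitions = list(
      discrete_transition("k0", "phantom", function(x, t = 0) -g * x)),
    omega = omega, diffusion = TRUE, allow_signed_rates = TRUE)
  attr(m, "growth_field") <- G
  attr(m, "Lambda") <- Lambda
  attr(m, "g") <- g
  m
}

#' Gaussian initial condition of the selection study
#'
#' `exp(-1000 (x - 0.1)^2) * sqrt(1000/pi)`, a narrow Gaussian at `x = 0.1`.
#'
#' @param model selection model (or grid).
#' @return a [grid_density()] with the mass in the physical state.
#' @export
selection_initial <- function(model) {
  grid <- acme_grid(model)
  p <- grid_density(grid, state_labels(model))
  x <- drop(grid$centres)
  p[, 1] <- exp(-1e3 * (x - 0.1)^2) * sqrt(1e3 / pi)
  p
}

#' Normalised densities and growth-rate series of a selection run
#'
#' Normalises each snapshot of the physical state by its mass `P0` and
#' returns two growth-rate estimators: the centred finite difference of
#' `log P0` along the recorded observable steps, and the instantaneous
#' identity `integral(G(x) p(x) dx)` evaluated on each snapshot.
#'
#' @param traj trajectory of a selection model.
#' @param model the model (for the growth field; defaults to
#'   `traj$model`).
#' @param state physical state label.
#' @return list with `normalised` (list of normalised snapshot densities),
#'   `growth` (data.frame `t`, `rate`) and `rate_integral` (data.frame
#'   `t`, `rate` at snapshot times).
#' @export
normalise_and_growth_rate <- function(traj, model = traj$model, state = "k0") {
  obs <- traj$observables
  P0 <- obs[[paste0("mass_", state)]]
  if (any(P0 <= 0)) stop("non-positive physical mass P0 in trajectory")
  t <- obs$t
  n <- length(t)
  rate <- rep(NA_real_, n)
  if (n >= 3) {
    rate[2:(n - 1)] <- (log(P0[3:n]) - log(P0[1:(n - 2)])) /
      (t[3:n] - t[1:(n - 2)])
  }
  G <- attr(model, "growth_field")
  grid <- acme_grid(model)
  x <- drop(grid$centres)
  norm_list <- vector("list", length(traj$snapshots))
  ri <- numeric(length(traj$snapshots))
  for (i in seq_along(traj$snapshots)) {
    p <- traj$snapshots[[i]]
    mass <- sum(p[, state]) * grid$dx
    q <- p[, state] / mass
    norm_list[[i]] <- data.frame(x = x, value = q)
    ri[i] <- if (!is.null(G)) sum(G(x) * q) * grid$dx else NA_real_
  }
  list(normalised = norm_list,
       growth = data.frame(t = t, rate = rate),
       rate_integral = data.frame(t = traj$times, rate = ri))
}

#' Growth-fragmentation model
#'
#' One continuum species (cell size).  Fragmentation is a non-local jump
#' towards smaller sizes at rate `a x^k` with the uniform binary-division
#' kernel (fragmentation mode: number doubles per event, volume conserved).
#' With `with_growth_decay = TRUE` the model adds linear growth in size
#' (drift `+x`) and uniform decay at rate 1 realised as a transition to an
#' inert absorbing state, matching the explicit benchmark
#' [fragmentation_growth_decay()] (whose fragmentation rate is `a k x^k`).
#'
#' @param a,k fragmentation rate parameters.
#' @param with_growth_decay logical.
#' @param dx cell width.
#' @param x_max size-domain truncation; the growth/decay variant needs the
#'   larger default because its early-time profile is wide.
#' @return an [acme_model()].
#' @export
build_fragmentation_model <- function(a = 5, k = 3, with_growth_decay = FALSE,
                                      dx = 0.005,
                                      x_max = if (with_growth_decay) 6 else 3) {
  stopifnot(a > 0, k >= 1)
  n_cells <- as.integer(round(x_max / dx))
  frag_rate_coef <- if (with_growth_decay) a * k else a
  jump <- jump_process(-1L,
                       function(x, t = 0) frag_rate_coef * x^k,
                       jump_kernel_uniform_fragmentation(),
                       mode = "fragmentation", name = "division")
  if (!with_growth_decay) {
    return(acme_model(species = continuum_species("size", x_max, n_cells),
                      states = discrete_state("k0"), jumps = jump))
  }
  acme_model(species = continuum_species("size", x_max, n_cells),
             states = list(discrete_state("k0"),
                           discrete_state("decayed", absorbing = TRUE)),
             reactions = reaction(1L, list(k0 = function(x, t = 0) x),
                                  name = "growth"),
             jumps = jump,
             transitions = list(discrete_transition("k0", "decayed", 1)))
}

#' Seeded random well-posed model
#'
#' Reproducible pseudo-random models for property testing: bounded
#' non-negative polynomial rates, probability-mode exponential jump kernels
#' and non-negative transition rates, so every generated model conserves
#' total mass.  The R random-number state is restored on exit.
#'
#' @param seed integer seed.
#' @param d number of continuum species (1 or 2).
#' @param n_states number of discrete states.
#' @param n_cells cells per dimension.
#' @param x_max domain truncation.
#' @return an [acme_model()] that passes [validate_model()] with no errors.
#' @export
generate_random_model <- function(seed, d = 1L, n_states = 2L,
                                  n_cells = 16L, x_max = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  species <- lapply(seq_len(d), function(j)
    continuum_species(paste0("x", j), x_max, n_cells))
  labels <- paste0("k", seq_len(n_states) - 1L)
  states <- lapply(labels, discrete_state)
  poly_rate <- function() {
    cf <- stats::runif(3, 0, 2)
    function(x, t = 0) {
      x1 <- if (is.matrix(x)) x[, 1] else x
      cf[1] + cf[2] * x1 + cf[3] * x1^2
    }
  }
  rand_dir <- function() {
    e <- integer(d)
    e[sample.int(d, 1)] <- sample(c(-1L, 1L), 1)
    e
  }
  n_rx <- sample(1:2, 1)
  reactions <- lapply(seq_len(n_rx), function(i)
    reaction(rand_dir(), poly_rate()))
  jumps <- list()
  if (stats::runif(1) < 0.7) {
    e <- integer(d)
    e[sample.int(d, 1)] <- 1L
    jumps <- list(jump_process(e, poly_rate(),
                               jump_kernel_exponential(stats::runif(1, 0.05, 0.3)),
                               mode = "probability"))
  }
  transitions <- list()
  if (n_states >= 2L) {
    for (i in seq_len(sample(1:2, 1))) {
      kk <- sample(n_states, 2)
      transitions[[length(transitions) + 1L]] <-
        discrete_transition(labels[kk[1]], labels[kk[2]], poly_rate())
    }
  }
  diffusion <- stats::runif(1) < 0.5
  acme_model(species = species, states = states, reactions = reactions,
             jumps = jumps, transitions = transitions,
             omega = if (diffusion) stats::runif(1, 50, 500) else NULL,
             diffusion = diffusion)
}
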