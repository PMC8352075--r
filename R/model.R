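#' Hill regulation rate
#'
#' Saturating Hill rate `r0 + r1 * x^n / (1 + x^n)` used to model
#' concentration-dependent regulation (e.g. transcription activated by its
#' downstream protein).  Monotone non-decreasing in `x` for `r1 >= 0`.
#'
#' @param x scaled concentration (non-negative, vectorised).
#' @param r0 basal rate at `x = 0`.
#' @param r1 maximal additional rate; the rate saturates at `r0 + r1`.
#' @param n Hill exponent (`n >= 1`); larger values sharpen the switch.
#' @return numeric vector of rates.
#' @examples
#' hill_rate(0, 2, 10, 4)   # basal rate 2
#' hill_rate(1, 2, 10, 4)   # half-saturation: 7
#' @export
hill_rate <- function(x, r0, r1, n) {
  xn <- x^n
  r0 + r1 * xn / (1 + xn)
}

#' Canonical self-regulated gene expression parameters
#'
#' The parameter set used throughout the gene-expression case studies:
#' Hill parameters `r0 = 2`, `r1 = 10`, `n = 4`, discrete burst size `B = 40`,
#' protein degradation rate `gamma0 = 1` and system size `omega = 200`.
#' The continuum-scaled mean burst size is `b = B / omega = 0.2`.
#'
#' @return named list with elements `r0`, `r1`, `n`, `B`, `gamma0`, `omega`, `b`.
#' @export
gene_expression_params <- function() {
  list(r0 = 2, r1 = 10, n = 4, B = 40, gamma0 = 1, omega = 200, b = 40 / 200)
}

#' Continuum species declaration
#'
#' @param name identifier of the species.
#' @param domain_max upper truncation of the scaled-concentration domain
#'   (the domain is `[0, domain_max]`).
#' @param n_cells number of uniform cells (`>= 4`).
#' @return object of class `continuum_species`.
#' @export
continuum_species <- function(name, domain_max, n_cells) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(domain_max) || domain_max <= 0)
    stop("domain_max must be positive")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 4L)
    stop("n_cells must be an integer >= 4")
  structure(list(name = name, domain_max = as.numeric(domain_max),
                 n_cells = n_cells),
            class = "continuum_species")
}

#' Discrete state declaration
#'
#' @param label identifier, unique within a model.
#' @param phantom logical; phantom states are bookkeeping states reached at
#'   (possibly negative) signed rates and carry no probability interpretation.
#' @param absorbing logical; absorbing states accumulate mass but no outgoing
#'   terms (reactions, jumps or transitions) are evaluated from them.
#' @return object of class `discrete_state`.
#' @export
discrete_state <- function(label, phantom = FALSE, absorbing = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, phantom = isTRUE(phantom),
                 absorbing = isTRUE(absorbing)),
            class = "discrete_state")
}

# Normalise a user-supplied rate into a per-state named list of functions
# of (x, t).  A bare function or scalar applies to every non-absorbing state.
normalise_rate <- function(rate, state_labels, dynamic_labels, what = "rate") {
  as_fn <- function(r) {
    if (is.function(r)) return(r)
    if (is.numeric(r) && length(r) == 1L) {
      force(r)
      f <- function(x, t = 0) rep.int(r, NROW(x))
      attr(f, "expr") <- format(r)
      return(f)
    }
    stop(what, " must be a function, a scalar, or a named list of these")
  }
  if (is.function(rate) || (is.numeric(rate) && length(rate) == 1L)) {
    out <- stats::setNames(vector("list", length(state_labels)), state_labels)
    for (k in dynamic_labels) out[[k]] <- as_fn(rate)
    return(out)
  }
  if (is.list(rate)) {
    if (is.null(names(rate)) || any(!nzchar(names(rate))))
      stop("per-state ", what, " list must be named by state label")
    out <- stats::setNames(vector("list", length(state_labels)), state_labels)
    for (k in names(rate)) out[[k]] <- as_fn(rate[[k]])
    return(out)
  }
  stop(what, " must be a function, a scalar, or a named list of these")
}

#' Local reaction (drift-diffusion term)
#'
#' A reaction displaces the continuum state by the integer stoichiometric
#' vector `displacement` at a state- and time-dependent rate.  On the
#' continuum it contributes an advection term along `displacement` and, when
#' diffusion is enabled, a diffusion term scaled by `1/(2 omega)`.
#'
#' @param displacement integer vector (length = number of continuum species),
#'   not all zero.
#' @param rate a function `f(x, t)`, a scalar, or a named list (by discrete
#'   state label) of these.  A single function/scalar applies to all
#'   non-absorbing states.
#' @param name optional label used in diagnostics.
#' @return object of class `acme_reaction`.
#' @export
reaction <- function(displacement, rate, name = NULL) {
  e <- as.integer(round(displacement))
  if (all(e == 0L)) stop("reaction displacement must be non-zero")
  structure(list(displacement = e, rate = rate,
                 name = if (is.null(name)) paste0("e=(", paste(e, collapse = ","), ")") else name),
            class = "acme_reaction")
}

#' Jump kernels
#'
#' Kernels describe the density of the jump length `u > 0` (physical distance
#' along the jump direction) for non-local state changes.
#'
#' `jump_kernel_exponential` is the standard burst-production kernel
#' `exp(-u/b)/b` with mean continuum-scaled burst size `b`, supported on
#' `(0, Inf)`.
#'
#' `jump_kernel_uniform_fragmentation` is the binary-division kernel: a parent
#' of size `y` splits uniformly, so the offspring-size density is `2/y` on
#' `(0, y)` -- twice a probability density, reflecting that one division event
#' produces two cells.
#'
#' `jump_kernel_custom` accepts `density(u, source)` where `source` is the
#' coordinate of the jumping cell along the jump axis, and a support
#' specification: `"halfline"` (support `(0, Inf)`) or `"source"` (support
#' `(0, source)`).
#'
#' @param b mean jump length of the exponential kernel (`b > 0`).
#' @param density function `(u, source) -> density value` (vectorised in `u`).
#' @param support `"halfline"` or `"source"`.
#' @return object of class `jump_kernel`.
#' @export
jump_kernel_exponential <- function(b) {
  stopifnot(is.numeric(b), b > 0)
  force(b)
  structure(list(type = "exponential",
                 density = function(u, source) exp(-u / b) / b,
                 cdf = function(u) -expm1(-u / b),
                 support = "halfline",
                 params = list(b = b)),
            class = "jump_kernel")
}

#' @rdname jump_kernel_exponential
#' @export
jump_kernel_uniform_fragmentation <- function() {
  structure(list(type = "uniform_fragmentation",
                 density = function(u, source) rep.int(2 / source, length(u)),
                 support = "source",
                 params = list()),
            class = "jump_kernel")
}

#' @rdname jump_kernel_exponential
#' @export
jump_kernel_custom <- function(density, support = c("halfline", "source")) {
  support <- match.arg(support)
  stopifnot(is.function(density))
  structure(list(type = "custom", density = density, support = support,
                 params = list()),
            class = "jump_kernel")
}

#' Non-local jump process
#'
#' A jump process moves density a finite distance along the integer direction
#' `direction` at rate `rate`, with jump lengths distributed by `kernel`.
#' In `"probability"` mode the discretised kernel columns are renormalised to
#' sum to one (each event moves one unit of density, conserving total mass).
#' In `"fragmentation"` mode the kernel integrates to two and the
#' discretisation conserves the first moment (volume) along the jump axis
#' exactly: one event nets one extra individual but no extra volume.
#'
#' @param direction integer displacement vector; jumps move along
#'   `+direction`.
#' @param rate as in [reaction()].
#' @param kernel a [jump_kernel_exponential()]-style kernel object.
#' @param mode `"probability"` or `"fragmentation"`.
#' @param name optional label.
#' @return object of class `acme_jump`.
#' @export
jump_process <- function(direction, rate, kernel,
                         mode = c("probability", "fragmentation"),
                         name = NULL) {
  e <- as.integer(round(direction))
  if (all(e == 0L)) stop("jump direction must be non-zero")
  mode <- match.arg(mode)
  if (!inherits(kernel, "jump_kernel")) stop("kernel must be a jump_kernel")
  if (mode == "fragmentation" && kernel$support != "source")
    stop("fragmentation mode requires a kernel supported on (0, source)")
  structure(list(direction = e, rate = rate, kernel = kernel, mode = mode,
                 name = if (is.null(name)) paste0("jump e=(", paste(e, collapse = ","), ")") else name),
            class = "acme_jump")
}

#' Discrete-state transition
#'
#' Pointwise flux of density from one discrete state to another at rate
#' `rate(x, t)`.  Rates may be negative (signed) when the model sets
#' `allow_signed_rates`; negative rates into phantom states encode
#' population-level growth terms.
#'
#' @param from,to state labels (`from != to`).
#' @param rate function `f(x, t)` or scalar.
#' @return object of class `acme_transition`.
#' @export
discrete_transition <- function(from, to, rate) {
  stopifnot(is.character(from), is.character(to), from != to)
  if (is.numeric(rate) && length(rate) == 1L) {
    r <- rate
    rate <- function(x, t = 0) rep.int(r, NROW(x))
    attr(rate, "expr") <- format(r)
  }
  if (!is.function(rate)) stop("transition rate must be a function or scalar")
  structure(list(from = from, to = to, rate = rate),
            class = "acme_transition")
}

#' Declarative hybrid model
#'
#' Assembles continuum species, discrete states, local reactions, non-local
#' jump processes and discrete transitions into a full model of the hybrid
#' master equation: per discrete state `k`, the density `p_k(x, t)` obeys
#' advection (and `1/(2 omega)`-scaled diffusion) along each reaction
#' direction, gain/loss from jump processes, and pointwise exchange between
#' states.
#'
#' @param species a `continuum_species` or list of them (dimension `d`).
#' @param states a `discrete_state` or list of them; defaults to a single
#'   state `"k0"`.
#' @param reactions list of [reaction()] objects.
#' @param jumps list of [jump_process()] objects.
#' @param transitions list of [discrete_transition()] objects.
#' @param omega system size (typical molecule count); required when
#'   `diffusion = TRUE`.
#' @param diffusion logical; `FALSE` gives the noiseless (infinite system
#'   size) limit.
#' @param allow_signed_rates logical opt-in for negative rates.
#' @return object of class `acme_model`.
#' @export
acme_model <- function(species, states = NULL, reactions = list(),
                       jumps = list(), transitions = list(),
                       omega = NULL, diffusion = FALSE,
                       allow_signed_rates = FALSE) {
  if (inherits(species, "continuum_species")) species <- list(species)
  stopifnot(length(species) >= 1L)
  if (is.null(states)) states <- list(discrete_state("k0"))
  if (inherits(states, "discrete_state")) states <- list(states)
  if (inherits(reactions, "acme_reaction")) reactions <- list(reactions)
  if (inherits(jumps, "acme_jump")) jumps <- list(jumps)
  if (inherits(transitions, "acme_transition")) transitions <- list(transitions)

  labels <- vapply(states, function(s) s$label, character(1))
  absorbing <- vapply(states, function(s) s$absorbing, logical(1))
  phantom <- vapply(states, function(s) s$phantom, logical(1))
  dynamic <- labels[!absorbing]

  for (i in seq_along(reactions))
    reactions[[i]]$rate <- normalise_rate(reactions[[i]]$rate, labels, dynamic,
                                          "reaction rate")
  for (i in seq_along(jumps))
    jumps[[i]]$rate <- normalise_rate(jumps[[i]]$rate, labels, dynamic,
                                      "jump rate")

  m <- structure(list(species = species, states = states,
                      reactions = reactions, jumps = jumps,
                      transitions = transitions,
                      omega = if (is.null(omega)) NULL else as.numeric(omega),
                      diffusion = isTRUE(diffusion),
                      allow_signed_rates = isTRUE(allow_signed_rates)),
                 class = "acme_model")
  m
}

#' @export
print.acme_model <- function(x, ...) {
  d <- length(x$species)
  cat("<acme_model> ", d, " continuum species, ",
      length(x$states), " discrete states\n", sep = "")
  cat("  species: ",
      paste(vapply(x$species, function(s)
        sprintf("%s [0,%g] x %d", s$name, s$domain_max, s$n_cells),
        character(1)), collapse = "; "), "\n", sep = "")
  cat("  states:  ",
      paste(vapply(x$states, function(s)
        paste0(s$label,
               if (s$phantom) " (phantom)" else "",
               if (s$absorbing) " (absorbing)" else ""),
        character(1)), collapse = ", "), "\n", sep = "")
  cat("  ", length(x$reactions), " reactions, ", length(x$jumps),
      " jumps, ", length(x$transitions), " transitions; diffusion ",
      if (x$diffusion) paste0("on (omega = ", x$omega, ")") else "off",
      "\n", sep = "")
  invisible(x)
}

state_labels <- function(model) vapply(model$states, `[[`, character(1), "label")
state_flag <- function(model, what) vapply(model$states, `[[`, logical(1), what)

#' Validate a model
#'
#' Pure structural and semantic checks.  Errors: dimension mismatches,
#' undefined state labels, missing system size with diffusion enabled.
#' Warnings: negative rates sampled on a probe grid without
#' `allow_signed_rates`, signed transitions into non-phantom states, jump
#' kernels materially truncated by the domain, grid resolution finer than a
#' single molecule (`dx * omega < 1`).
#'
#' @param model an [acme_model()].
#' @param strict if `TRUE`, raise an error when any error-level diagnostic is
#'   found.
#' @return data.frame with columns `level` (`"error"`/`"warning"`), `code`,
#'   `message`; zero rows for a well-posed model.
#' @export
validate_model <- function(model, strict = FALSE) {
  diags <- list()
  add <- function(level, code, message)
    diags[[length(diags) + 1L]] <<- data.frame(level = level, code = code,
                                               message = message)
  d <- length(model$species)
  labels <- state_labels(model)
  phantom <- state_flag(model, "phantom")
  absorbing <- state_flag(model, "absorbing")

  if (anyDuplicated(labels))
    add("error", "duplicate_state", "discrete state labels are not unique")

  dx <- vapply(model$species, function(s) s$domain_max / s$n_cells, numeric(1))
  if (d > 1 && diff(range(dx)) > 1e-12 * max(dx))
    add("error", "dx_mismatch",
        "cell width dx must be identical across species")
  if (!is.null(model$omega) && dx[1] * model$omega < 1)
    add("warning", "dx_subunit",
        sprintf("dx * omega = %.3g < 1: cells are finer than one molecule",
                dx[1] * model$omega))
  if (model$diffusion && (is.null(model$omega) || model$omega <= 0))
    add("error", "omega_missing",
        "diffusion is enabled but omega is missing or non-positive")

  probe <- probe_points(model)
  check_rate_signs <- function(rate_list, what, jump = NULL) {
    for (k in names(rate_list)) {
      if (!k %in% labels) {
        add("error", "unknown_state",
            sprintf("%s refers to undefined state '%s'", what, k))
        next
      }
      f <- rate_list[[k]]
      if (is.null(f)) next
      v <- f(probe, 0)
      if (any(!is.finite(v)))
        add("error", "nonfinite_rate",
            sprintf("%s rate is non-finite on the domain (state '%s')", what, k))
      else if (any(v < 0) && !model$allow_signed_rates)
        add("warning", "negative_rate",
            sprintf("%s rate is negative on the domain (state '%s') without allow_signed_rates",
                    what, k))
    }
  }

  for (rx in model$reactions) {
    if (length(rx$displacement) != d)
      add("error", "dimension_mismatch",
          sprintf("reaction %s displacement has length %d, expected %d",
                  rx$name, length(rx$displacement), d))
    else check_rate_signs(rx$rate, paste("reaction", rx$name))
  }
  for (jp in model$jumps) {
    if (length(jp$direction) != d) {
      add("error", "dimension_mismatch",
          sprintf("jump %s direction has length %d, expected %d",
                  jp$name, length(jp$direction), d))
      next
    }
    check_rate_signs(jp$rate, paste("jump", jp$name))
    if (jp$kernel$support == "halfline") {
      # truncated tail for a jump launched from the lower domain edge
      ax <- which(jp$direction != 0L)[1]
      span <- model$species[[ax]]$domain_max
      tail_mass <- kernel_tail_mass(jp$kernel, span)
      if (is.finite(tail_mass) && tail_mass > 1e-6)
        add("warning", "kernel_truncated",
            sprintf("jump %s kernel keeps %.2g of its mass beyond the domain; columns will be renormalised",
                    jp$name, tail_mass))
    }
  }
  for (tr in model$transitions) {
    for (lab in c(tr$from, tr$to))
      if (!lab %in% labels)
        add("error", "unknown_state",
            sprintf("transition %s->%s refers to undefined state '%s'",
                    tr$from, tr$to, lab))
    if (all(c(tr$from, tr$to) %in% labels)) {
      if (absorbing[match(tr$from, labels)])
        add("warning", "absorbing_outflow",
            sprintf("transition out of absorbing state '%s' is ignored", tr$from))
      v <- tr$rate(probe, 0)
      if (any(!is.finite(v)))
        add("error", "nonfinite_rate",
            sprintf("transition %s->%s rate is non-finite", tr$from, tr$to))
      else if (any(v < 0)) {
        if (!model$allow_signed_rates)
          add("warning", "negative_rate",
              sprintf("transition %s->%s has negative rate without allow_signed_rates",
                      tr$from, tr$to))
        else if (!phantom[match(tr$to, labels)])
          add("warning", "negative_rate_nonphantom",
              sprintf("negative-rate transition %s->%s targets a non-phantom state",
                      tr$from, tr$to))
      }
    }
  }

  out <- if (length(diags)) do.call(rbind, diags)
         else data.frame(level = character(), code = character(),
                         message = character())
  rownames(out) <- NULL
  if (strict && any(out$level == "error"))
    stop("model validation failed:\n  ",
         paste(out$message[out$level == "error"], collapse = "\n  "))
  out
}

# coarse probe grid used for sign/finiteness sampling
probe_points <- function(model, n = 9L) {
  d <- length(model$species)
  axes <- lapply(model$species, function(s)
    seq(s$domain_max / (2 * n), s$domain_max, length.out = n))
  pts <- as.matrix(expand.grid(axes))
  colnames(pts) <- NULL
  if (d == 1L) pts <- drop(pts)
  pts
}

kernel_tail_mass <- function(kernel, span) {
  if (kernel$type == "exponential") return(exp(-span / kernel$params$b))
  u <- seq(span, span * 50, length.out = 4096L)
  du <- u[2] - u[1]
  v <- tryCatch(kernel$density(u, span * 50), error = function(e) NA_real_)
  if (any(!is.finite(v))) return(NA_real_)
  sum(v) * du
}
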