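# Configuration parsing (YAML/JSON) and structured output.  The schema is
# deliberately strict: unknown keys are rejected with their path so typos
# cannot silently change a model.

check_keys <- function(obj, allowed, required = character(0), path) {
  if (!is.list(obj)) stop("config: ", path, " must be a mapping", call. = FALSE)
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop("config: unknown key ", path, "/", extra[1], call. = FALSE)
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("config: missing required key ", path, "/", missing[1], call. = FALSE)
  invisible(obj)
}

compile_rate_field <- function(rate, params, d, path, labels = NULL) {
  if (is.numeric(rate) && length(rate) == 1L) return(rate)
  if (is.character(rate) && length(rate) == 1L)
    return(rate_expression_compile(rate, params, d))
  if (is.list(rate)) {
    if (is.null(labels)) stop("config: ", path, " cannot be per-state here",
                              call. = FALSE)
    bad <- setdiff(names(rate), labels)
    if (length(bad))
      stop("config: ", path, " refers to unknown state '", bad[1], "'",
           call. = FALSE)
    return(lapply(rate, function(r) compile_rate_field(r, params, d, path)))
  }
  stop("config: ", path, " must be a number, an expression string, ",
       "or a per-state mapping", call. = FALSE)
}

parse_kernel <- function(kern, params, path) {
  check_keys(kern, c("type", "b", "expr", "support"), "type", path)
  switch(kern$type,
    exponential = {
      if (is.null(kern$b)) stop("config: ", path, " needs 'b'", call. = FALSE)
      jump_kernel_exponential(as.numeric(kern$b))
    },
    uniform_fragmentation = jump_kernel_uniform_fragmentation(),
    custom_expr = {
      if (is.null(kern$expr)) stop("config: ", path, " needs 'expr'",
                                   call. = FALSE)
      # whitelist check (u and source play the role of coordinates here)
      rate_expression_compile(kern$expr, c(params, list(u = 0, source = 0)), 1L)
      kk <- jump_kernel_custom(function(u, source)
        eval_kernel_expr(kern$expr, params, u, source),
        support = if (is.null(kern$support)) "halfline" else kern$support)
      kk$params <- list(expr = kern$expr, support = kk$support)
      kk
    },
    stop("config: ", path, " has unknown kernel type '", kern$type, "'",
         call. = FALSE))
}

eval_kernel_expr <- function(expr, params, u, source) {
  ast <- str2lang(expr)
  env <- new.env(parent = baseenv())
  for (nm in names(params)) assign(nm, as.numeric(params[[nm]]), envir = env)
  assign("u", u, envir = env)
  assign("source", source, envir = env)
  assign("min", base::pmin, envir = env)
  assign("max", base::pmax, envir = env)
  assign("pow", function(a, b) a^b, envir = env)
  assign("hill", hill_rate, envir = env)
  assign("indicator", function(cond) as.numeric(cond), envir = env)
  eval(ast, env)
}

#' Parse a model configuration file
#'
#' Reads a YAML or JSON model description (keys: `species`, `states`,
#' `params`, `reactions`, `jumps`, `transitions`, `omega`, `diffusion`,
#' `allow_signed_rates`, `solver`, `initial`) and builds the model, solver
#' settings and initial density.  All rate expressions are compiled with
#' [rate_expression_compile()]; unknown keys are rejected with the path of
#' the offending key.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return list with `model` ([acme_model()]), `settings`
#'   ([solver_settings()]), `initial` (a [grid_density()] or `NULL`) and the
#'   raw `config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    # YAML 1.2 boolean semantics: only true/false are logical, so parameter
    # names like `n` or `y` survive as keys
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x)
        if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
      "bool#no" = function(x)
        if (tolower(x) %in% c("false", "no", "off")) FALSE else x))
  }
  config_to_objects(cfg)
}

config_to_objects <- function(cfg) {
  check_keys(cfg, c("species", "states", "params", "reactions", "jumps",
                    "transitions", "omega", "diffusion", "allow_signed_rates",
                    "solver", "initial"),
             required = "species", path = "")
  params <- if (is.null(cfg$params)) list() else cfg$params
  species <- lapply(seq_along(cfg$species), function(i) {
    s <- check_keys(cfg$species[[i]], c("name", "domain_max", "n_cells"),
                    c("name", "domain_max", "n_cells"),
                    paste0("species[", i, "]"))
    continuum_species(s$name, s$domain_max, s$n_cells)
  })
  d <- length(species)
  states <- if (is.null(cfg$states)) NULL else
    lapply(seq_along(cfg$states), function(i) {
      s <- check_keys(cfg$states[[i]], c("label", "phantom", "absorbing"),
                      "label", paste0("states[", i, "]"))
      discrete_state(s$label, isTRUE(s$phantom), isTRUE(s$absorbing))
    })
  labels <- if (is.null(states)) "k0" else
    vapply(states, `[[`, character(1), "label")
  reactions <- lapply(seq_along(cfg$reactions), function(i) {
    r <- check_keys(cfg$reactions[[i]], c("displacement", "rate", "name"),
                    c("displacement", "rate"), paste0("reactions[", i, "]"))
    reaction(unlist(r$displacement),
             compile_rate_field(r$rate, params, d,
                                paste0("reactions[", i, "]/rate"), labels),
             name = r$name)
  })
  jumps <- lapply(seq_along(cfg$jumps), function(i) {
    j <- check_keys(cfg$jumps[[i]],
                    c("direction", "rate", "kernel", "mode", "name"),
                    c("direction", "rate", "kernel"), paste0("jumps[", i, "]"))
    jump_process(unlist(j$direction),
                 compile_rate_field(j$rate, params, d,
                                    paste0("jumps[", i, "]/rate"), labels),
                 parse_kernel(j$kernel, params, paste0("jumps[", i, "]/kernel")),
                 mode = if (is.null(j$mode)) "probability" else j$mode,
                 name = j$name)
  })
  transitions <- lapply(seq_along(cfg$transitions), function(i) {
    tr <- check_keys(cfg$transitions[[i]], c("from", "to", "rate"),
                     c("from", "to", "rate"), paste0("transitions[", i, "]"))
    discrete_transition(tr$from, tr$to,
                        compile_rate_field(tr$rate, params, d,
                                           paste0("transitions[", i, "]/rate")))
  })
  if (isTRUE(cfg$diffusion) && is.null(cfg$omega))
    stop("config: omega is required when diffusion is enabled", call. = FALSE)
  model <- acme_model(species = species, states = states,
                      reactions = reactions, jumps = jumps,
                      transitions = transitions,
                      omega = cfg$omega, diffusion = isTRUE(cfg$diffusion),
                      allow_signed_rates = isTRUE(cfg$allow_signed_rates))

  settings <- if (is.null(cfg$solver)) solver_settings() else {
    s <- check_keys(cfg$solver,
                    c("method", "cfl_safety", "t_final", "snapshot_times",
                      "steady_tol", "max_steps", "limiter", "theta",
                      "split_sinks", "record_every", "progress"),
                    character(0), "solver")
    do.call(solver_settings, s)
  }

  initial <- NULL
  if (!is.null(cfg$initial)) {
    ic <- check_keys(cfg$initial,
                     c("type", "state", "x0", "expr", "normalise"),
                     "type", "initial")
    grid <- acme_grid(model)
    st <- if (is.null(ic$state)) labels[1] else ic$state
    initial <- switch(ic$type,
      uniform = project_density(function(x) rep.int(1, NROW(x)), grid,
                                labels, st, normalise = TRUE),
      delta = delta_initial(model, ic$x0, state = st),
      expr = {
        f <- rate_expression_compile(ic$expr, params, length(species))
        project_density(function(x) f(x, 0), grid, labels, st,
                        normalise = !isFALSE(ic$normalise))
      },
      stop("config: unknown initial type '", ic$type, "'", call. = FALSE))
  }
  list(model = model, settings = settings, initial = initial, config = cfg)
}

#' Serialise a config-built model back to a configuration list
#'
#' Inverse of [parse_config()] for models whose rates were compiled from
#' expressions (the expression text is preserved in the compiled functions).
#' Models built programmatically from plain R closures cannot be serialised.
#'
#' @param model an [acme_model()] from [parse_config()].
#' @param settings optional [solver_settings()].
#' @return a config list; write it with [yaml::write_yaml()] or
#'   [jsonlite::write_json()].
#' @export
emit_config <- function(model, settings = NULL) {
  params <- list()
  rate_repr <- function(f) {
    if (is.numeric(f)) return(f)
    ex <- attr(f, "expr")
    if (is.null(ex)) stop("model rate has no expression text; ",
                          "only config-built models can be serialised")
    for (nm in names(attr(f, "params"))) params[[nm]] <<- attr(f, "params")[[nm]]
    ex
  }
  rate_list_repr <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    reprs <- lapply(lst, rate_repr)
    if (length(unique(unlist(reprs))) == 1L &&
        length(lst) == sum(!state_flag(model, "absorbing")))
      return(reprs[[1]])
    reprs
  }
  cfg <- list(
    species = lapply(model$species, function(s)
      list(name = s$name, domain_max = s$domain_max, n_cells = s$n_cells)),
    states = lapply(model$states, function(s)
      list(label = s$label, phantom = s$phantom, absorbing = s$absorbing)),
    reactions = lapply(model$reactions, function(r)
      list(displacement = as.list(r$displacement),
           rate = rate_list_repr(r$rate), name = r$name)),
    jumps = lapply(model$jumps, function(j)
      list(direction = as.list(j$direction), rate = rate_list_repr(j$rate),
           kernel = c(list(type = j$kernel$type), j$kernel$params),
           mode = j$mode, name = j$name)),
    transitions = lapply(model$transitions, function(tr)
      list(from = tr$from, to = tr$to, rate = rate_repr(tr$rate))),
    params = if (length(params)) params,
    omega = model$omega,
    diffusion = model$diffusion,
    allow_signed_rates = model$allow_signed_rates)
  if (!is.null(settings))
    cfg$solver <- settings[c("method", "cfl_safety", "t_final", "steady_tol",
                             "limiter", "split_sinks")]
  cfg[!vapply(cfg, is.null, logical(1))]
}

#' Write a trajectory to CSV files
#'
#' Writes `observables.csv` (step times and per-state masses) and one tidy
#' density CSV per snapshot (`density_t<time>.csv`).
#'
#' @param traj an [acme_integrate()] trajectory.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_trajectory_csv <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, "observables.csv")
  utils::write.csv(traj$observables, files[1], row.names = FALSE)
  for (i in seq_along(traj$snapshots)) {
    f <- file.path(dir, sprintf("density_t%g.csv", traj$times[i]))
    write_density_csv(traj$snapshots[[i]], f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Run manifest
#'
#' JSON record sufficient to re-execute a run: the config snapshot, solver
#' settings, package version, files written and warnings emitted.
#'
#' @param path output JSON path.
#' @param config raw config list (or NULL).
#' @param settings solver settings used.
#' @param files character vector of output files.
#' @param warnings character vector of warnings.
#' @export
write_manifest <- function(path, config, settings, files,
                           warnings = character(0)) {
  manifest <- list(
    package = "acmekit",
    version = as.character(utils::packageVersion("acmekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    settings = unclass(settings),
    outputs = as.list(files),
    warnings = as.list(warnings))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  file.rename(tmp, path)
  invisible(path)
}
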