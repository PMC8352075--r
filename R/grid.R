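#' Uniform cell-centred grid
#'
#' Tensor-product grid over the truncated domain `[0, domain_max]^d` with a
#' single shared cell width `dx`.  Cells are half-open `[m dx, (m+1) dx)` with
#' centres `x_m = (m + 1/2) dx`, zero-based index `m`.
#'
#' @param model an [acme_model()] (the grid is read off its species), or a
#'   list of `continuum_species`.
#' @return object of class `acme_grid` with fields `d`, `dx`, `n_cells`
#'   (per-dimension integer vector), `domain_max`, `n_total`, and the cell
#'   centre matrix `centres` (`n_total` x `d`, first axis fastest).
#' @export
acme_grid <- function(model) {
  species <- if (inherits(model, "acme_model")) model$species else model
  if (inherits(species, "continuum_species")) species <- list(species)
  n_cells <- vapply(species, `[[`, integer(1), "n_cells")
  dom <- vapply(species, `[[`, numeric(1), "domain_max")
  dx <- dom / n_cells
  if (diff(range(dx)) > 1e-12 * max(dx))
    stop("cell width dx must be identical across species")
  dx <- dx[1]
  axes <- lapply(seq_along(species), function(j)
    (seq_len(n_cells[j]) - 0.5) * dx)
  centres <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(centres) <- NULL
  structure(list(d = length(species), dx = dx, n_cells = n_cells,
                 domain_max = dom, n_total = prod(n_cells),
                 centres = centres,
                 species_names = vapply(species, `[[`, character(1), "name")),
            class = "acme_grid")
}

#' @export
print.acme_grid <- function(x, ...) {
  cat("<acme_grid> d=", x$d, ", dx=", format(x$dx),
      ", cells=", paste(x$n_cells, collapse = "x"), "\n", sep = "")
  invisible(x)
}

# coordinates as passed to rate functions: vector in 1-D, matrix otherwise
grid_coords <- function(grid) {
  if (grid$d == 1L) drop(grid$centres) else grid$centres
}

#' Per-state density on a grid
#'
#' Cell-average densities, one column per discrete state.  Mass of a state is
#' `sum(values) * dx^d`.
#'
#' @param grid an [acme_grid()].
#' @param states character vector of state labels (or a model).
#' @param values optional numeric matrix (`n_total` x `n_states`).
#' @return object of class `grid_density` (a numeric matrix with attributes).
#' @export
grid_density <- function(grid, states, values = NULL) {
  if (inherits(states, "acme_model")) states <- state_labels(states)
  n <- grid$n_total
  if (is.null(values)) values <- matrix(0, n, length(states))
  values <- as.matrix(values)
  stopifnot(nrow(values) == n, ncol(values) == length(states))
  dimnames(values) <- list(NULL, states)
  structure(values, grid = grid, class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  g <- attr(x, "grid")
  m <- density_mass(x)
  cat("<grid_density> ", ncol(x), " state(s) on ",
      paste(g$n_cells, collapse = "x"), " cells; mass: ",
      paste(sprintf("%s=%.6g", names(m), m), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project a density function onto a grid
#'
#' Cell averages via the midpoint rule (values of `f` at cell centres), with
#' optional renormalisation to unit total mass.  All mass is placed in one
#' discrete state.
#'
#' @param f density function of the coordinates (vector for `d = 1`, matrix
#'   rows otherwise).
#' @param grid an [acme_grid()].
#' @param states state labels of the resulting density (default single state
#'   `"k0"`).
#' @param state label receiving the projected mass.
#' @param normalise if `TRUE`, scale so total mass is exactly 1.
#' @return a [grid_density()].
#' @export
project_density <- function(f, grid, states = "k0", state = states[[1]],
                            normalise = FALSE) {
  if (inherits(states, "acme_model")) states <- state_labels(states)
  v <- f(grid_coords(grid))
  if (length(v) == 1L) v <- rep.int(v, grid$n_total)
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v))[1]
    stop(sprintf("density function is non-finite at cell %d (x = %s)",
                 bad, paste(signif(grid$centres[bad, ], 4), collapse = ", ")))
  }
  p <- grid_density(grid, states)
  p[, state] <- v
  if (normalise) {
    m <- sum(v) * grid$dx^grid$d
    if (m <= 0) stop("cannot normalise a density with non-positive mass")
    p[, state] <- v / m
  }
  p
}

#' Per-state mass
#'
#' @param p a [grid_density()].
#' @return named numeric vector, `sum(values) * dx^d` per state.
#' @export
density_mass <- function(p) {
  g <- attr(p, "grid")
  colSums(p) * g$dx^g$d
}

#' @rdname density_mass
#' @export
total_mass <- function(p) sum(density_mass(p))

#' One-dimensional marginal density
#'
#' Sums over discrete states and integrates out all continuum axes except
#' `axis`; total mass is preserved.
#'
#' @param p a [grid_density()].
#' @param axis continuum axis to keep (1-based).
#' @param states states to include (default all).
#' @return data.frame with columns `x` (cell centres of `axis`) and `value`.
#' @export
marginal <- function(p, axis = 1L, states = colnames(p)) {
  g <- attr(p, "grid")
  stopifnot(axis >= 1L, axis <= g$d)
  v <- rowSums(p[, states, drop = FALSE])
  if (g$d == 1L) {
    out <- data.frame(x = drop(g$centres), value = v)
  } else {
    idx_axis <- cell_axis_index(g, axis)
    dens <- vapply(seq_len(g$n_cells[axis]),
                   function(m) sum(v[idx_axis == m]), numeric(1))
    out <- data.frame(x = (seq_len(g$n_cells[axis]) - 0.5) * g$dx,
                      value = dens * g$dx^(g$d - 1L))
  }
  out
}

# per-cell index (1-based) along a given axis
cell_axis_index <- function(grid, axis) {
  stride <- c(1L, cumprod(grid$n_cells))[axis]
  ((seq_len(grid$n_total) - 1L) %/% stride) %% grid$n_cells[axis] + 1L
}

#' Per-state moments
#'
#' Raw moments of the coordinate along one axis: order 0 gives the mass,
#' order 1 gives `sum(x_m * p) * dx^d`, and so on.
#'
#' @param p a [grid_density()].
#' @param order non-negative integer moment order.
#' @param axis continuum axis (1-based).
#' @return named numeric vector, one entry per state.
#' @export
moments <- function(p, order = 1L, axis = 1L) {
  g <- attr(p, "grid")
  stopifnot(order >= 0L)
  if (order == 0L) return(density_mass(p))
  w <- g$centres[, axis]^order
  colSums(p * w) * g$dx^g$d
}

#' @export
as.data.frame.grid_density <- function(x, ...) {
  g <- attr(x, "grid")
  coords <- as.data.frame(g$centres)
  names(coords) <- if (g$d == 1L) "x" else paste0("x", seq_len(g$d))
  out <- do.call(rbind, lapply(colnames(x), function(k)
    cbind(data.frame(state = k), coords, data.frame(value = x[, k]))))
  rownames(out) <- NULL
  out
}

#' Write a density as tidy CSV
#'
#' Columns: `state`, cell-centre coordinates, `value`.
#'
#' @param p a [grid_density()].
#' @param path output file.
#' @export
write_density_csv <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = FALSE)
  invisible(path)
}
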