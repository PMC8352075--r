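# Truncated discrete chemical master equation: reference solver used to
# benchmark the continuum scheme against the exact (finite-state-projection
# style) stationary law of small networks.

#' Discrete reaction network on a truncated count lattice
#'
#' @param bounds named integer vector of per-species upper count bounds; the
#'   state space is the lattice `0:bounds[1] x 0:bounds[2] x ...`.
#' @param reactions list of reactions, each a list with `change` (integer
#'   count displacement vector) and `rate` (function of the count matrix `X`,
#'   one row per state, returning per-state propensities).
#' @return object of class `cme_network`.
#' @export
cme_network <- function(bounds, reactions) {
  stopifnot(length(bounds) >= 1L, all(bounds >= 0))
  structure(list(bounds = as.integer(bounds), reactions = reactions,
                 species = names(bounds)),
            class = "cme_network")
}

#' Truncated CME generator
#'
#' Sparse generator matrix of the master equation on the truncated lattice:
#' off-diagonal entries carry probability from state `X` to `X + change` at
#' the reaction propensity; diagonal entries are negative column sums, so
#' interior columns sum to zero exactly.  Reactions leaving the truncation
#' box are dropped.
#'
#' @param network a [cme_network()].
#' @return object of class `truncated_cme`: list with the generator `Q`
#'   (columns = source states), the count matrix `states` and `bounds`.
#' @export
build_generator <- function(network) {
  bounds <- network$bounds
  d <- length(bounds)
  n <- prod(bounds + 1L)
  axes <- lapply(bounds, function(b) 0:b)
  X <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(X) <- list(NULL, network$species)
  strides <- c(1L, cumprod(bounds + 1L)[-d])

  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (rx in network$reactions) {
    ch <- as.integer(rx$change)
    stopifnot(length(ch) == d)
    r <- rx$rate(X)
    if (length(r) == 1L) r <- rep.int(r, n)
    dest <- sweep(X, 2L, ch, `+`)
    ok <- rep(TRUE, n)
    for (j in seq_len(d)) ok <- ok & dest[, j] >= 0L & dest[, j] <= bounds[j]
    ok <- ok & r != 0
    if (!any(ok)) next
    src_idx <- which(ok)
    dest_idx <- as.integer(dest[ok, , drop = FALSE] %*% strides) + 1L
    ii <- c(ii, dest_idx, src_idx)
    jj <- c(jj, src_idx, src_idx)
    xx <- c(xx, r[ok], -r[ok])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  structure(list(Q = Q, states = X, bounds = bounds), class = "truncated_cme")
}

#' Stationary distribution of a truncated CME
#'
#' Null vector of the generator, normalised to unit probability, via a
#' sparse solve with one state pinned.  The chain must have a single closed
#' communicating class; with several closed classes the stationary law is
#' not unique and an error lists them.
#'
#' @param cme a `truncated_cme` from [build_generator()].
#' @return numeric probability vector over the lattice states (ordering as
#'   `cme$states`), with attribute `residual`.
#' @export
cme_steady_state <- function(cme) {
  Q <- cme$Q
  n <- nrow(Q)
  cls <- closed_classes(Q)
  if (length(cls) > 1L)
    stop("reducible chain: ", length(cls), " closed classes (sizes ",
         paste(lengths(cls), collapse = ", "), "); stationary law not unique")
  pin <- cls[[1]][1]
  A <- Q
  A[pin, ] <- 1
  b <- numeric(n)
  b[pin] <- 1
  q <- as.numeric(Matrix::solve(A, b))
  if (min(q) < -1e-9)
    warning("stationary solve produced negative entries down to ", min(q))
  q[q < 0] <- 0
  q <- q / sum(q)
  attr(q, "residual") <- max(abs(Q %*% q))
  q
}

# closed communicating classes of the jump chain: strongly connected
# components of the transition graph with no outgoing edge
closed_classes <- function(Q) {
  n <- nrow(Q)
  Qt <- methods::as(methods::as(Q, "generalMatrix"), "TsparseMatrix")
  keep <- Qt@x > 0 & Qt@i != Qt@j
  from <- Qt@j[keep] + 1L
  to <- Qt@i[keep] + 1L
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g, mode = "strong")$membership
  # a component is closed iff no edge leaves it
  leaving <- unique(comp[from][comp[from] != comp[to]])
  closed <- setdiff(unique(comp), leaving)
  lapply(closed, function(cc) which(comp == cc))
}

#' Lump a discrete count distribution onto a continuum grid
#'
#' Sums blocks of `dx * omega` consecutive molecule counts (cell `m` covers
#' counts `m*L .. (m+1)*L - 1`) and divides by `dx`, producing a density
#' directly comparable with continuum output.  Mass is preserved exactly for
#' counts within the grid range.
#'
#' @param prob probability vector over counts `0, 1, 2, ...` of a single
#'   species (e.g. a marginal of [cme_steady_state()]).
#' @param grid a one-dimensional [acme_grid()].
#' @param omega system size used in the continuum scaling `x = X / omega`.
#' @return data.frame with columns `x` (cell centres) and `value` (density).
#' @export
lump_to_grid <- function(prob, grid, omega) {
  stopifnot(grid$d == 1L)
  L <- grid$dx * omega
  if (abs(L - round(L)) > 1e-8)
    stop("dx * omega = ", L, " is not an integer lump size")
  L <- as.integer(round(L))
  nc <- grid$n_cells[1]
  counts <- seq_along(prob) - 1L
  cell <- counts %/% L + 1L
  v <- numeric(nc)
  inside <- cell <= nc
  agg <- tapply(prob[inside], cell[inside], sum)
  v[as.integer(names(agg))] <- as.numeric(agg)
  data.frame(x = drop(grid$centres), value = v / grid$dx)
}

#' Marginal of a lattice distribution
#'
#' @param prob probability vector from [cme_steady_state()].
#' @param cme the matching `truncated_cme`.
#' @param species species name or index to keep.
#' @return numeric vector over counts `0:bounds[species]`.
#' @export
cme_marginal <- function(prob, cme, species) {
  if (is.character(species)) species <- match(species, colnames(cme$states))
  counts <- cme$states[, species]
  out <- numeric(cme$bounds[species] + 1L)
  agg <- tapply(prob, counts, sum)
  out[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  out
}

#' Truncated CME of the self-regulated gene expression network
#'
#' The two-species network (mRNA, protein): transcription at a Hill rate of
#' the scaled protein level, translation at `gamma * B` per mRNA, mRNA decay
#' at `gamma`, protein decay at `gamma0`.
#'
#' @param K mRNA truncation (states `0..K`).
#' @param gamma mRNA production/degradation rate scale.
#' @param params parameter list as from [gene_expression_params()].
#' @param x_max protein truncation in scaled units (counts up to
#'   `x_max * omega`).
#' @return a [cme_network()].
#' @export
build_gene_expression_cme <- function(K = 30L, gamma,
                                      params = gene_expression_params(),
                                      x_max = 6) {
  P <- params
  Xmax <- as.integer(round(x_max * P$omega))
  cme_network(
    bounds = c(mRNA = as.integer(K), protein = Xmax),
    reactions = list(
      list(change = c(1L, 0L),
           rate = function(X) hill_rate(X[, "protein"] / P$omega, P$r0, P$r1, P$n)),
      list(change = c(-1L, 0L), rate = function(X) gamma * X[, "mRNA"]),
      list(change = c(0L, 1L), rate = function(X) gamma * P$B * X[, "mRNA"]),
      list(change = c(0L, -1L), rate = function(X) P$gamma0 * X[, "protein"])
    ))
}
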