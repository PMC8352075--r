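# Semi-discrete spatial operators: slope-limited central (Kurganov-Tadmor
# family) advection, conservative diffusion, non-local jump exchange and
# discrete-state coupling.  All operators act along 1-D rays of cells aligned
# with an integer direction vector, so no spurious transverse diffusion is
# introduced in multi-species systems.

#' Rays of cells along an integer direction
#'
#' Decomposes the grid into maximal ordered chains of cells whose indices
#' differ by `e`; every cell belongs to exactly one ray per direction.
#'
#' @param grid an [acme_grid()].
#' @param e integer direction vector of length `d`.
#' @return list of integer vectors of 1-based linear cell indices, ordered
#'   along `+e`.
#' @export
directional_rays <- function(grid, e) {
  d <- grid$d
  e <- as.integer(e)
  stopifnot(length(e) == d, any(e != 0L))
  n <- grid$n_cells
  if (d == 1L) {
    ray <- seq_len(n[1])
    if (e[1] < 0L) ray <- rev(ray)
    # |e| > 1 couples cells at stride |e|: one ray per residue class
    a <- abs(e[1])
    if (a == 1L) return(list(ray))
    return(lapply(seq_len(a), function(r) ray[seq(r, n[1], by = a)]))
  }
  strides <- c(1L, cumprod(n)[-d])
  idx0 <- seq_len(grid$n_total) - 1L
  multi <- sapply(seq_len(d), function(j) (idx0 %/% strides[j]) %% n[j])
  pred_out <- rep(FALSE, grid$n_total)
  for (j in seq_len(d)) {
    if (e[j] == 0L) next
    pj <- multi[, j] - e[j]
    pred_out <- pred_out | pj < 0L | pj >= n[j]
  }
  starts <- which(pred_out)
  lapply(starts, function(s) {
    m <- multi[s, ]
    out <- integer(0)
    repeat {
      out <- c(out, as.integer(sum(m * strides)) + 1L)
      m <- m + e
      if (any(m < 0L | m >= n)) break
    }
    out
  })
}

# generalised minmod of three slope candidates (theta = 1: classic minmod)
minmod3 <- function(a, b, c) {
  pos <- (a > 0) & (b > 0) & (c > 0)
  neg <- (a < 0) & (b < 0) & (c < 0)
  pos * pmin(a, b, c) + neg * pmax(a, b, c)
}

# limited cell slopes along one ray; boundary cells get zero slope
ray_slopes <- function(p, dx, limiter, theta) {
  n <- length(p)
  dminus <- c(0, diff(p)) / dx
  dplus <- c(diff(p), 0) / dx
  s <- switch(limiter,
    minmod = minmod3(theta * dminus, 0.5 * (dminus + dplus), theta * dplus),
    vanleer = {
      r <- dminus * dplus
      ifelse(r > 0, 2 * r / (dminus + dplus), 0)
    },
    none = 0.5 * (dminus + dplus),
    stop("unknown limiter '", limiter, "'"))
  s[1] <- 0
  s[n] <- 0
  s
}

# semi-discrete central-scheme divergence of the advective flux v*p along one
# ray; zero flux at ray ends.  Returns the tendency contribution.
kt_div <- function(p, v, dx, limiter = "minmod", theta = 1) {
  n <- length(p)
  if (n < 2L) return(numeric(n))
  s <- ray_slopes(p, dx, limiter, theta)
  i <- seq_len(n - 1L)
  vf <- 0.5 * (v[i] + v[i + 1L])
  pL <- p[i] + 0.5 * dx * s[i]
  pR <- p[i + 1L] - 0.5 * dx * s[i + 1L]
  H <- 0.5 * (vf * (pL + pR) - abs(vf) * (pR - pL))
  -(c(H, 0) - c(0, H)) / dx
}

# matrix-column version of kt_div with the linear ("none") reconstruction;
# used to assemble exact operator matrices.
kt_div_linear_mat <- function(P, v, dx) {
  n <- nrow(P)
  if (n < 2L) return(P * 0)
  D <- (P[-1L, , drop = FALSE] - P[-n, , drop = FALSE]) / dx
  zero <- matrix(0, 1L, ncol(P))
  S <- 0.5 * (rbind(zero, D) + rbind(D, zero))
  S[1L, ] <- 0
  S[n, ] <- 0
  i <- seq_len(n - 1L)
  vf <- 0.5 * (v[i] + v[i + 1L])
  PL <- P[i, , drop = FALSE] + 0.5 * dx * S[i, , drop = FALSE]
  PR <- P[i + 1L, , drop = FALSE] - 0.5 * dx * S[i + 1L, , drop = FALSE]
  H <- 0.5 * (vf * (PL + PR) - abs(vf) * (PR - PL))
  -(rbind(H, zero) - rbind(zero, H)) / dx
}

# conservative second difference of q = r*p along one ray, scaled by
# 1/(2 omega dx^2); zero flux at ray ends.
diff_div <- function(q, dx, omega) {
  n <- length(q)
  if (n < 2L) return(numeric(n))
  FF <- diff(q)
  (c(FF, 0) - c(0, FF)) / (2 * omega * dx^2)
}

diff_div_mat <- function(Q, dx, omega) {
  n <- nrow(Q)
  if (n < 2L) return(Q * 0)
  FF <- Q[-1L, , drop = FALSE] - Q[-n, , drop = FALSE]
  zero <- matrix(0, 1L, ncol(Q))
  (rbind(FF, zero) - rbind(zero, FF)) / (2 * omega * dx^2)
}

#' Advection tendency of one reaction
#'
#' Second-order semi-discrete central-scheme divergence of the flux
#' `rate * p` along the reaction direction, with limited slopes and zero flux
#' at ray ends.  Discretely conservative: interior fluxes telescope.
#'
#' @param p a [grid_density()].
#' @param rx an [reaction()] whose rates have been normalised by
#'   [acme_model()] (i.e. taken from `model$reactions`).
#' @param grid an [acme_grid()].
#' @param t evaluation time.
#' @param limiter `"minmod"` (default), `"vanleer"`, or `"none"` (unlimited
#'   central slopes; exactly linear in `p`).
#' @param theta dissipation parameter of the generalised minmod limiter
#'   (1 = most dissipative, 2 = sharpest).
#' @return tendency as a [grid_density()].
#' @export
advection_rhs <- function(p, rx, grid, t = 0, limiter = "minmod", theta = 1) {
  rays <- directional_rays(grid, rx$displacement)
  coords <- grid_coords(grid)
  out <- grid_density(grid, colnames(p))
  for (k in colnames(p)) {
    f <- rx$rate[[k]]
    if (is.null(f)) next
    v <- rate_values(f, coords, t, grid$n_total, rx$name)
    for (ray in rays)
      out[ray, k] <- out[ray, k] + kt_div(p[ray, k], v[ray], grid$dx,
                                          limiter, theta)
  }
  out
}

#' Diffusion tendency of one reaction
#'
#' Central second difference of `rate * p` along the reaction direction,
#' scaled by `1/(2 omega dx^2)`; conservative with zero-flux ends.  This is
#' the finite-system-size correction of the continuum limit and vanishes as
#' `omega` grows.
#'
#' @inheritParams advection_rhs
#' @param omega system size.
#' @return tendency as a [grid_density()].
#' @export
diffusion_rhs <- function(p, rx, grid, omega, t = 0) {
  stopifnot(is.numeric(omega), omega > 0)
  rays <- directional_rays(grid, rx$displacement)
  coords <- grid_coords(grid)
  out <- grid_density(grid, colnames(p))
  for (k in colnames(p)) {
    f <- rx$rate[[k]]
    if (is.null(f)) next
    v <- rate_values(f, coords, t, grid$n_total, rx$name)
    q <- v * p[, k]
    for (ray in rays)
      out[ray, k] <- out[ray, k] + diff_div(q[ray], grid$dx, omega)
  }
  out
}

rate_values <- function(f, coords, t, n, name) {
  v <- f(coords, t)
  if (length(v) == 1L) v <- rep.int(v, n)
  if (any(is.na(v)))
    stop("rate of ", name, " evaluated to NaN/NA")
  v
}

#' Discretised jump operator
#'
#' Builds, per ray, the sparse matrix mapping source-cell density to
#' destination-cell gain by midpoint quadrature of the kernel over the jump
#' length.  In probability mode every column is renormalised to sum to one
#' (mass that would land beyond the domain is folded back into the retained
#' destinations).  In fragmentation mode the quadrature covers the support
#' `(0, source)` exactly -- including the partial self-cell -- so each column
#' sums to (approximately) two while the first moment along the jump axis is
#' conserved to machine precision.
#'
#' @param jump an [jump_process()] from a model.
#' @param grid an [acme_grid()].
#' @return object of class `jump_operator`: list with `rays` (index vectors)
#'   and `matrices` (one `dgCMatrix` per ray, destination x source).
#' @export
build_jump_operator <- function(jump, grid) {
  e <- jump$direction
  rays <- directional_rays(grid, e)
  h <- grid$dx * sqrt(sum(e^2))
  kern <- jump$kernel
  mats <- lapply(rays, function(ray) {
    n <- length(ray)
    jump_matrix_ray(kern, jump$mode, n, h)
  })
  structure(list(rays = rays, matrices = mats, direction = e,
                 mode = jump$mode, kernel = kern),
            class = "jump_operator")
}

jump_matrix_ray <- function(kern, mode, n, h, drop_tol = 1e-15) {
  ii <- jj <- integer(0)
  xx <- numeric(0)
  if (kern$support == "halfline") {
    # offsets identical for every source; density may not depend on source
    if (!is.null(kern$cdf)) {
      # exact per-cell kernel mass when the CDF is available
      edges <- c(0, (seq_len(n) - 0.5) * h)
      w <- diff(kern$cdf(edges))
    } else {
      u <- c(h / 4, h * seq_len(n - 1L))
      w <- kern$density(u, Inf)
      w <- w * c(h / 2, rep.int(h, n - 1L))
    }
    if (any(w < 0)) stop("jump kernel is negative on its support")
    keep <- max(which(w > drop_tol * max(w, 1e-300)), 1L)
    w <- w[seq_len(keep)]
    for (i in seq_len(n)) {
      len <- min(keep, n - i + 1L)
      ii <- c(ii, i:(i + len - 1L))
      jj <- c(jj, rep.int(i, len))
      xx <- c(xx, w[seq_len(len)])
    }
  } else {
    for (i in seq_len(n)) {
      S <- (n - i) * h + h / 2
      u <- c(h / 4, h * seq_len(n - i))
      w <- kern$density(u, S)
      if (any(w < 0)) stop("jump kernel is negative on its support")
      w <- w * c(h / 2, rep.int(h, n - i))
      if (i < n) {
        # the self deposit covers jump lengths (0, h/2); its centroid sits a
        # quarter-cell downstream of the source centre.  Splitting it 3:1
        # between the source cell and its downstream neighbour preserves the
        # first moment (fragment volume) exactly at cell-centre accounting.
        w[2] <- w[2] + 0.25 * w[1]
        w[1] <- 0.75 * w[1]
      }
      ii <- c(ii, i:n)
      jj <- c(jj, rep.int(i, n - i + 1L))
      xx <- c(xx, w)
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  if (mode == "probability") {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M <- M %*% Matrix::Diagonal(n, 1 / cs)
  }
  M
}

# apply a jump operator to the weighted density f*p (single state)
apply_jump <- function(op, fp) {
  out <- -fp
  for (r in seq_along(op$rays)) {
    idx <- op$rays[[r]]
    out[idx] <- out[idx] + as.numeric(op$matrices[[r]] %*% fp[idx])
  }
  out
}

#' Discrete-transition tendency
#'
#' Pointwise per-cell exchange between discrete states: each loss from the
#' source state appears as a gain in the target state (cell-by-cell mass over
#' states is invariant), including for negative (signed) rates.  Transitions
#' out of absorbing states are skipped.
#'
#' @param p a [grid_density()].
#' @param model an [acme_model()] (its `transitions` are used).
#' @param t evaluation time.
#' @return tendency as a [grid_density()].
#' @export
transitions_rhs <- function(p, model, t = 0) {
  grid <- attr(p, "grid")
  coords <- grid_coords(grid)
  labels <- colnames(p)
  absorbing <- stats::setNames(state_flag(model, "absorbing"),
                               state_labels(model))
  out <- grid_density(grid, labels)
  for (tr in model$transitions) {
    if (absorbing[[tr$from]]) next
    g <- rate_values(tr$rate, coords, t, grid$n_total,
                     paste0("transition ", tr$from, "->", tr$to))
    flux <- g * p[, tr$from]
    out[, tr$from] <- out[, tr$from] - flux
    out[, tr$to] <- out[, tr$to] + flux
  }
  out
}

#' Compile the full semi-discrete right-hand side
#'
#' Precomputes rays and jump operators and returns a fast closure
#' `rhs(p, t)` summing all reaction advection(+diffusion), jump and
#' transition tendencies.  With `limiter = "none"` the returned operator is
#' exactly linear in `p`.
#'
#' @param model a validated [acme_model()].
#' @param limiter slope limiter passed to the advection scheme.
#' @param theta generalised minmod parameter.
#' @param exclude_transitions integer indices of `model$transitions` to leave
#'   out (used by the split treatment of stiff local sinks).
#' @return function `(p_matrix, t) -> tendency matrix` operating on the raw
#'   value matrix of a [grid_density()].
#' @export
make_rhs <- function(model, limiter = "minmod", theta = 1,
                     exclude_transitions = integer(0)) {
  grid <- acme_grid(model)
  coords <- grid_coords(grid)
  dx <- grid$dx
  N <- grid$n_total
  labels <- state_labels(model)
  absorbing <- stats::setNames(state_flag(model, "absorbing"), labels)
  omega <- model$omega
  diffusion <- model$diffusion

  rx_items <- fuse_reactions(model, grid)
  jp_items <- list()
  for (jp in model$jumps) {
    op <- build_jump_operator(jp, grid)
    for (k in labels) {
      f <- jp$rate[[k]]
      if (is.null(f) || absorbing[[k]]) next
      jp_items[[length(jp_items) + 1L]] <-
        list(k = k, f = f, op = op, name = jp$name)
    }
  }
  tr_items <- list()
  tr_idx <- setdiff(seq_along(model$transitions), exclude_transitions)
  for (i in tr_idx) {
    tr <- model$transitions[[i]]
    if (absorbing[[tr$from]]) next
    tr_items[[length(tr_items) + 1L]] <-
      list(from = tr$from, to = tr$to, rate = tr$rate,
           name = paste0("transition ", tr$from, "->", tr$to))
  }

  function(p, t) {
    dp <- matrix(0, N, length(labels), dimnames = list(NULL, labels))
    for (it in rx_items) {
      vd <- fused_rate_values(it, coords, t, N)
      pk <- p[, it$k]
      acc <- dp[, it$k]
      for (ray in it$rays) {
        acc[ray] <- acc[ray] + kt_div(pk[ray], vd$v[ray], dx, limiter, theta)
        if (diffusion)
          acc[ray] <- acc[ray] + diff_div(vd$D[ray] * pk[ray], dx, omega)
      }
      dp[, it$k] <- acc
    }
    for (it in jp_items) {
      f <- rate_values(it$f, coords, t, N, it$name)
      dp[, it$k] <- dp[, it$k] + apply_jump(it$op, f * p[, it$k])
    }
    for (it in tr_items) {
      g <- rate_values(it$rate, coords, t, N, it$name)
      flux <- g * p[, it$from]
      dp[, it$from] <- dp[, it$from] - flux
      dp[, it$to] <- dp[, it$to] + flux
    }
    dp
  }
}

# Group reactions by state and direction line: a reaction along -e is the
# same one-dimensional transport problem as one along +e with negated
# velocity.  Fusing antiparallel reactions into a single net-velocity flux
# keeps the scheme's dissipation proportional to the *net* drift |sum e r|
# rather than the total activity sum |r| -- essential near flux balance
# points (e.g. birth/death equilibria), where counter-flowing fluxes would
# otherwise add spurious diffusion far exceeding the physical 1/(2 omega)
# term.  Diffusion coefficients add with positive sign for every member.
fuse_reactions <- function(model, grid) {
  labels <- state_labels(model)
  absorbing <- stats::setNames(state_flag(model, "absorbing"), labels)
  groups <- list()
  for (rx in model$reactions) {
    e <- rx$displacement
    first <- which(e != 0L)[1]
    sgn <- if (e[first] > 0L) 1 else -1
    e_c <- as.integer(sgn * e)
    key <- paste(e_c, collapse = ",")
    for (k in labels) {
      f <- rx$rate[[k]]
      if (is.null(f) || absorbing[[k]]) next
      gk <- paste0(k, "|", key)
      if (is.null(groups[[gk]]))
        groups[[gk]] <- list(k = k, e = e_c, fns = list(), signs = numeric(0),
                             name = rx$name)
      groups[[gk]]$fns[[length(groups[[gk]]$fns) + 1L]] <- f
      groups[[gk]]$signs <- c(groups[[gk]]$signs, sgn)
      groups[[gk]]$name <- paste(groups[[gk]]$name, rx$name, sep = "+")
    }
  }
  ray_cache <- list()
  for (gk in names(groups)) {
    key <- paste(groups[[gk]]$e, collapse = ",")
    if (is.null(ray_cache[[key]]))
      ray_cache[[key]] <- directional_rays(grid, groups[[gk]]$e)
    groups[[gk]]$rays <- ray_cache[[key]]
  }
  unname(groups)
}

# net advective velocity and total diffusion rate of a fused group
fused_rate_values <- function(it, coords, t, N) {
  v <- numeric(N)
  D <- numeric(N)
  for (i in seq_along(it$fns)) {
    r <- rate_values(it$fns[[i]], coords, t, N, it$name)
    v <- v + it$signs[i] * r
    D <- D + r
  }
  list(v = v, D = D)
}

#' Full right-hand side of the hybrid system
#'
#' Sum of all reaction, jump and transition tendencies at time `t`.
#'
#' @param model an [acme_model()].
#' @param p a [grid_density()] on the model's grid.
#' @param t evaluation time.
#' @param limiter slope limiter (see [make_rhs()]).
#' @return tendency as a [grid_density()].
#' @export
assemble_rhs <- function(model, p, t = 0, limiter = "minmod") {
  rhs <- make_rhs(model, limiter = limiter)
  grid_density(attr(p, "grid"), colnames(p), rhs(unclass_density(p), t))
}

unclass_density <- function(p) {
  attr(p, "grid") <- NULL
  unclass(p)
}

#' Sparse matrix of the linearised semi-discrete operator
#'
#' Assembles the full operator at fixed time `t` with the unlimited central
#' reconstruction (`limiter = "none"`), for which the scheme is exactly
#' linear.  The state vector ordering is state-major: cells of the first
#' state, then cells of the second, and so on.  Used by the direct
#' steady-state solver and exportable for inspection.
#'
#' @param model an [acme_model()].
#' @param t evaluation time (rates are frozen at `t`).
#' @return a `dgCMatrix` of dimension `(n_cells * n_states)^2`.
#' @export
operator_matrix <- function(model, t = 0) {
  grid <- acme_grid(model)
  coords <- grid_coords(grid)
  dx <- grid$dx
  N <- grid$n_total
  labels <- state_labels(model)
  K <- length(labels)
  absorbing <- stats::setNames(state_flag(model, "absorbing"), labels)
  blocks <- stats::setNames(seq_along(labels) - 1L, labels) * N

  trip_i <- trip_j <- list()
  trip_x <- list()
  push <- function(M, roff, coff) {
    M <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    trip_i[[length(trip_i) + 1L]] <<- M@i + 1L + roff
    trip_j[[length(trip_j) + 1L]] <<- M@j + 1L + coff
    trip_x[[length(trip_x) + 1L]] <<- M@x
  }

  for (it in fuse_reactions(model, grid)) {
    vd <- fused_rate_values(it, coords, t, N)
    for (ray in it$rays) {
      n <- length(ray)
      A <- kt_div_linear_mat(diag(n), vd$v[ray], dx)
      if (model$diffusion)
        A <- A + diff_div_mat(diag(vd$D[ray]), dx, model$omega)
      push(Matrix::drop0(Matrix::Matrix(A, sparse = TRUE)),
           roff = 0L, coff = 0L)
      # remap ray-local indices to global cells within the state block
      last <- length(trip_i)
      trip_i[[last]] <- ray[trip_i[[last]]] + blocks[[it$k]]
      trip_j[[last]] <- ray[trip_j[[last]]] + blocks[[it$k]]
    }
  }
  for (jp in model$jumps) {
    op <- build_jump_operator(jp, grid)
    for (k in labels) {
      f <- jp$rate[[k]]
      if (is.null(f) || absorbing[[k]]) next
      fv <- rate_values(f, coords, t, N, jp$name)
      for (r in seq_along(op$rays)) {
        ray <- op$rays[[r]]
        M <- op$matrices[[r]] %*% Matrix::Diagonal(length(ray), fv[ray])
        push(M, 0L, 0L)
        last <- length(trip_i)
        trip_i[[last]] <- ray[trip_i[[last]]] + blocks[[k]]
        trip_j[[last]] <- ray[trip_j[[last]]] + blocks[[k]]
      }
      push(Matrix::Diagonal(N, -fv), blocks[[k]], blocks[[k]])
    }
  }
  for (tr in model$transitions) {
    if (absorbing[[tr$from]]) next
    g <- rate_values(tr$rate, coords, t, N,
                     paste0("transition ", tr$from, "->", tr$to))
    push(Matrix::Diagonal(N, -g), blocks[[tr$from]], blocks[[tr$from]])
    push(Matrix::Diagonal(N, g), blocks[[tr$to]], blocks[[tr$from]])
  }

  if (!length(trip_i))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(N * K, N * K)))
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(N * K, N * K))
}
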