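# Closed-form benchmark solutions: the stationary density of bursty
# self-regulated expression, mean switching-time quadratures, the limiting
# Gaussian of the selection model, and explicit growth-fragmentation
# solutions.  These serve both as user-facing references and as the oracles
# against which the finite-volume solver is tested.

#' Stationary density of bursty self-regulated gene expression
#'
#' Evaluates (up to normalisation) the closed-form stationary density of the
#' bursty production / linear decay model with Hill-regulated burst rate:
#' `exp(-x/b) * x^(r0/gamma0 - 1) * (1 + x^n)^(r1/(n*gamma0))`, normalised by
#' numerical quadrature on the truncated domain `[0, x_max]`.
#'
#' @param x evaluation points (scaled concentration).
#' @param r0,r1,n Hill parameters.
#' @param gamma0 protein decay rate.
#' @param b mean continuum-scaled burst size.
#' @param x_max upper truncation used for normalisation.
#' @return numeric density values at `x`.
#' @export
stationary_bursty_density <- function(x, r0 = 2, r1 = 10, n = 4,
                                      gamma0 = 1, b = 0.2, x_max = 6) {
  if (r0 <= 0)
    stop("r0 must be positive: the integrand x^(r0/gamma0 - 1) diverges")
  stopifnot(r1 >= 0, n >= 1, gamma0 > 0, b > 0)
  raw <- function(y)
    exp(-y / b + (r0 / gamma0 - 1) * log(pmax(y, .Machine$double.xmin)) +
        (r1 / (n * gamma0)) * log1p(y^n))
  z <- stats::integrate(raw, 0, x_max, rel.tol = 1e-10,
                        abs.tol = 0)$value
  v <- ifelse(x == 0 & r0 / gamma0 > 1, 0, raw(x) / z)
  v
}

#' Inputs of the mean switching-time formulas
#'
#' @param r0,r1,n Hill parameters of the burst rate.
#' @param gamma0 decay rate.
#' @param b mean burst size.
#' @param x_c critical boundary separating the low and high expression modes.
#' @return list of class `switching_time_inputs`.
#' @export
switching_time_inputs <- function(r0 = 2, r1 = 10, n = 4, gamma0 = 1,
                                  b = 0.2, x_c = 0.825) {
  stopifnot(r0 > 0, r1 >= 0, n >= 1, gamma0 > 0, b > 0, x_c > 0)
  structure(list(r0 = r0, r1 = r1, n = n, gamma0 = gamma0, b = b, x_c = x_c),
            class = "switching_time_inputs")
}

# Integrating-factor exponent of the first-passage backward equation:
# M(x) = log(x / H(x)) - x/b + int_0^x H(y)/(gamma0 y) dy, defined up to an
# additive constant (only differences enter the formulas); the
# logarithmically divergent integral of H(y)/(gamma0 y) is taken through its
# closed-form antiderivative (r0/gamma0) log x + (r1/(n gamma0)) log(1+x^n).
switching_M <- function(x, inp) {
  H <- hill_rate(x, inp$r0, inp$r1, inp$n)
  log(x / H) - x / inp$b + (inp$r0 / inp$gamma0) * log(x) +
    (inp$r1 / (inp$n * inp$gamma0)) * log1p(x^inp$n)
}

switching_V <- function(x, inp, rel.tol = 1e-10) {
  phi <- function(y) {
    H <- hill_rate(y, inp$r0, inp$r1, inp$n)
    dH <- inp$r1 * inp$n * y^(inp$n - 1) / (1 + y^inp$n)^2
    (1 / (inp$b * inp$gamma0 * y) + dH / (inp$gamma0 * y * H)) *
      exp(switching_M(y, inp))
  }
  vapply(x, function(xx) {
    if (xx <= 0) return(0)
    -stats::integrate(phi, 0, xx, rel.tol = rel.tol, abs.tol = 0,
                      stop.on.error = TRUE)$value
  }, numeric(1))
}

# upper cut standing in for infinity: beyond it exp(M) is negligible
switching_cut <- function(inp) {
  xs <- seq(inp$x_c, 60, by = 0.25)
  M <- switching_M(xs, inp)
  top <- max(M)
  xs[which(M < top - 40 & xs > inp$x_c + 1)[1]]
}

#' Mean switching times of the bimodal bursty model
#'
#' Quadrature evaluation of the closed-form mean first-passage times across
#' the critical boundary `x_c`: `T_low_high(x)` for initial conditions below
#' `x_c` (time to first exceed it) and `T_high_low(x)` for initial conditions
#' above it (time to first fall below).  All integrals are evaluated by
#' adaptive quadrature; results are deterministic to the stated tolerance.
#'
#' @param inp a [switching_time_inputs()].
#' @param x initial conditions (vectorised).
#' @param rel.tol quadrature relative tolerance.
#' @return data.frame with columns `x`, `T_low_high`, `T_high_low` (the
#'   column for the side `x` is on is the physically meaningful one).
#' @export
mean_switching_times <- function(inp, x, rel.tol = 1e-9) {
  xc <- inp$x_c
  Vxc <- switching_V(xc, inp)
  Mxc <- switching_M(xc, inp)
  Hxc <- hill_rate(xc, inp$r0, inp$r1, inp$n)
  cut <- switching_cut(inp)
  Vinf <- switching_V(cut, inp)
  boundary_term <- (1 - inp$gamma0 * xc * Vxc * exp(-Mxc)) / Hxc

  t_lh <- vapply(x, function(xx) {
    inner <- stats::integrate(function(y) exp(-switching_M(y, inp)) *
                                switching_V(y, inp),
                              xc, xx, rel.tol = rel.tol, abs.tol = 0)$value
    boundary_term + inner
  }, numeric(1))
  t_hl <- vapply(x, function(xx) {
    if (xx <= xc) return(0)
    stats::integrate(function(y) exp(-switching_M(y, inp)) *
                       (switching_V(y, inp) - Vinf),
                     xc, xx, rel.tol = rel.tol, abs.tol = 0)$value
  }, numeric(1))
  data.frame(x = x, T_low_high = t_lh, T_high_low = t_hl)
}

#' Asymptotics of the selection model
#'
#' For the logistic birth / linear death process (`lambda = Lambda x (1-x)`,
#' `mu = x`) under a growth field `G`, the large-time behaviour of the
#' growing population density is `exp(r0 t) Y(x)`: the critical point solves
#' `lambda(x_c) = mu(x_c)`, giving `x_c = 1 - 1/Lambda` for `Lambda > 1`;
#' the asymptotic growth rate is `r0 = G(x_c)`; and the limiting normalised
#' profile is a Gaussian centred at `x_c`.  The width parameter follows from
#' a local Ornstein-Uhlenbeck expansion about the critical point:
#' `a = (lambda + mu)(x_c) / |d(lambda - mu)/dx (x_c)| = 2 / Lambda`, and
#' the profile variance is `a / (2 omega)`.
#'
#' @param G growth field, a function of `x`.
#' @param Lambda birth factor (`> 1`).
#' @param omega system size.
#' @return list of class `selection_asymptotics` with `x_c`, `r0`, `a`,
#'   `sigma2` (profile variance) and `profile(x)` (normalised limiting
#'   Gaussian density).
#' @export
selection_asymptotics <- function(G, Lambda, omega) {
  if (Lambda <= 1) stop("Lambda must exceed 1 for an interior critical point")
  x_c <- 1 - 1 / Lambda
  r0 <- G(x_c)
  a <- 2 / Lambda
  sigma2 <- a / (2 * omega)
  profile <- function(x) stats::dnorm(x, mean = x_c, sd = sqrt(sigma2))
  structure(list(x_c = x_c, r0 = r0, a = a, sigma2 = sigma2,
                 profile = profile),
            class = "selection_asymptotics")
}

#' Fit a Gaussian width to a numerical profile
#'
#' Moment-matched Gaussian (mean and variance of the normalised tabulated
#' density); useful as an empirical alternative to the analytic width of
#' [selection_asymptotics()].
#'
#' @param x cell centres.
#' @param p density values (need not be normalised).
#' @return list with `mean`, `sigma2`.
#' @export
fit_gaussian_profile <- function(x, p) {
  w <- p / sum(p)
  m <- sum(w * x)
  list(mean = m, sigma2 = sum(w * (x - m)^2))
}

#' Self-similar solution of pure power-law fragmentation
#'
#' Density `c (a t)^(2/k) exp(-a t x^k)` solving the pure fragmentation
#' equation with fragmentation rate `a x^k` and uniform binary division.
#' The volume `integral(x rho dx)` is time-invariant (equal to
#' `c Gamma(2/k) / (k a^{2/k} a^{...})`; for `k = 2` it is `c/2`), while the
#' number density diverges at the origin as `t` grows.
#'
#' @param x sizes (vectorised).
#' @param t time (`> 0`).
#' @param a,k fragmentation rate parameters (`B(x) = a x^k`).
#' @param c arbitrary amplitude constant.
#' @return density values.
#' @export
fragmentation_selfsimilar <- function(x, t, a, k, c = 1) {
  stopifnot(t > 0, a > 0, k >= 1)
  c * (a * t)^(2 / k) * exp(-a * t * x^k)
}

#' Explicit solution of growth-fragmentation with linear growth and decay
#'
#' Density solving the growth-fragmentation equation with growth `g(x) = x`,
#' uniform decay at rate 1, fragmentation rate `a k x^k`:
#' `c exp(-2t) [a (exp(kt) - 1)]^(2/k) exp(-a (exp(kt)-1) (exp(-t) x)^k)`.
#' As `t -> Inf` it converges pointwise to the stationary profile
#' `c a^(2/k) exp(-a x^k)` returned by [limiting_fragmentation_profile()].
#'
#' @inheritParams fragmentation_selfsimilar
#' @export
fragmentation_growth_decay <- function(x, t, a, k, c = 1) {
  stopifnot(t >= 0, a > 0, k >= 1)
  s <- a * (exp(k * t) - 1)
  c * exp(-2 * t) * s^(2 / k) * exp(-s * (exp(-t) * x)^k)
}

#' @rdname fragmentation_growth_decay
#' @export
limiting_fragmentation_profile <- function(x, a, k, c = 1) {
  c * a^(2 / k) * exp(-a * x^k)
}
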