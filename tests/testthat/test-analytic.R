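test_that("stationary bursty density has the canonical shape and mass", {
  # with the canonical preset: exponent of x is r0/gamma0 - 1 = 1, the
  # composite power is r1/(n gamma0) = 2.5, and the kernel scale is b = 0.2
  x <- seq(0, 6, by = 0.001)
  v <- stationary_bursty_density(x)
  expect_equal(v[1], 0)                      # x-exponent 1 > 0
  expect_equal(sum(v) * 0.001, 1, tolerance = 1e-4)
  expect_equal(integrate(stationary_bursty_density, 0, 6,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  # exactly two interior local maxima (bimodality)
  peaks <- which(diff(sign(diff(v))) == -2)
  expect_equal(length(peaks), 2L)
  # ratio structure: log density + x/b - log x must equal 2.5*log(1+x^4)+const
  xs <- c(0.5, 1, 2, 3)
  lhs <- log(stationary_bursty_density(xs)) + xs / 0.2 - log(xs)
  expect_equal(diff(lhs), diff(2.5 * log1p(xs^4)), tolerance = 1e-10)
  expect_error(stationary_bursty_density(1, r0 = 0), "r0")
})

test_that("mean switching times agree with a fixed-grid Riemann oracle", {
  inp <- switching_time_inputs()
  # brute-force oracle on a 1e5-point fixed grid, trapezoid rule
  xc <- inp$x_c
  grid_to <- 15
  yg <- seq(1e-6, grid_to, length.out = 1e5)
  Hg <- hill_rate(yg, inp$r0, inp$r1, inp$n)
  dHg <- inp$r1 * inp$n * yg^(inp$n - 1) / (1 + yg^inp$n)^2
  Mg <- log(yg / Hg) - yg / inp$b + 2 * log(yg) + 2.5 * log1p(yg^inp$n)
  phig <- (1 / (inp$b * yg) + dHg / (yg * Hg)) * exp(Mg)
  dy <- yg[2] - yg[1]
  cum <- cumsum((phig + c(phig[1], phig[-length(phig)])) / 2 * dy)
  Vg <- -cum
  Vinf <- Vg[length(Vg)]
  V_at <- function(x) approx(yg, Vg, x)$y
  M_at <- function(x) approx(yg, Mg, x)$y
  bt <- (1 - xc * V_at(xc) * exp(-M_at(xc))) / hill_rate(xc, 2, 10, 4)
  integ_lh <- function(x) {
    sel <- yg >= min(x, xc) & yg <= max(x, xc)
    s <- sum(exp(-Mg[sel]) * Vg[sel]) * dy
    if (x >= xc) s else -s
  }
  integ_hl <- function(x) {
    sel <- yg >= xc & yg <= x
    sum(exp(-Mg[sel]) * (Vg[sel] - Vinf)) * dy
  }
  mst <- mean_switching_times(inp, c(0.5, 1.5))
  expect_equal(mst$T_low_high[1], bt + integ_lh(0.5), tolerance = 2e-3)
  expect_equal(mst$T_high_low[2], integ_hl(1.5), tolerance = 2e-3)
})

test_that("switching-time structure: boundary values and monotonicity", {
  inp <- switching_time_inputs()
  mst <- mean_switching_times(inp, c(0.2, inp$x_c, seq(0.9, 3, by = 0.3)))
  # below x_c the time to fall is zero by convention
  expect_equal(mst$T_high_low[1], 0)
  # at x = x_c the upward time is the boundary term only; it is positive
  # and smaller than at any lower initial condition
  expect_gt(mst$T_low_high[2], 0)
  expect_gt(mst$T_low_high[1], mst$T_low_high[2])
  # T_high_low is monotone increasing above x_c
  hl <- mst$T_high_low[-(1:2)]
  expect_true(all(diff(hl) > 0))
})

test_that("selection asymptotics solve the critical-point equations", {
  a2 <- selection_asymptotics(function(x) 0.5 * x, 2, 1000)
  expect_equal(a2$x_c, 0.5)                    # solve Lambda(1-x) = 1
  a3 <- selection_asymptotics(function(x) 0.5 * x, 3, 1000)
  expect_equal(a3$r0, 0.5 * (1 - 1 / 3))       # r0 = g (1 - 1/Lambda)
  expect_equal(selection_asymptotics(function(x) 0.5 * x, 3, 1)$r0, 1 / 3)
  # Lambda -> 1+ pushes the critical point to the origin
  eps <- selection_asymptotics(function(x) 0.5 * x, 1 + 1e-9, 1000)
  expect_lt(eps$x_c, 1e-8)
  expect_equal(eps$r0, 0.5 * eps$x_c)
  expect_error(selection_asymptotics(function(x) x, 1, 1000), "Lambda")
  # the profile is a unit-mass Gaussian at x_c
  expect_equal(integrate(a3$profile, 0, 1)$value, 1, tolerance = 1e-6)
  expect_equal(optimize(a3$profile, c(0, 1), maximum = TRUE)$maximum,
               2 / 3, tolerance = 1e-3)
})

test_that("fragmentation closed forms satisfy their equations in residual", {
  a <- 5
  # pure fragmentation: rho_t = -a x^k rho + int_x^Inf 2 a y^(k-1) rho dy
  for (k in c(2, 3)) {
    xs <- seq(0.01, 3, length.out = 100)
    ts <- seq(0.5, 2.5, length.out = 20)
    worst <- 0
    for (tt in ts) {
      dt <- 1e-6
      lhs <- (fragmentation_selfsimilar(xs, tt + dt, a, k) -
              fragmentation_selfsimilar(xs, tt - dt, a, k)) / (2 * dt)
      gain <- vapply(xs, function(x0)
        integrate(function(y) 2 * a * y^(k - 1) *
                    fragmentation_selfsimilar(y, tt, a, k),
                  x0, Inf, rel.tol = 1e-10)$value, numeric(1))
      rhs <- -a * xs^k * fragmentation_selfsimilar(xs, tt, a, k) + gain
      worst <- max(worst, max(abs(lhs - rhs)))
    }
    expect_lt(worst, 1e-3)
  }

  # growth/decay variant: rho_t = -(x rho)_x - (a k x^k + 1) rho
  #                              + int 2 a k y^(k-1) rho dy
  k <- 2
  xs <- seq(0.05, 2.5, length.out = 80)
  for (tt in c(0.1, 0.5, 1.5)) {
    dt <- 1e-6; dxn <- 1e-6
    f <- function(x, t) fragmentation_growth_decay(x, t, a, k)
    lhs <- (f(xs, tt + dt) - f(xs, tt - dt)) / (2 * dt)
    transport <- -((xs + dxn) * f(xs + dxn, tt) -
                   (xs - dxn) * f(xs - dxn, tt)) / (2 * dxn)
    gain <- vapply(xs, function(x0)
      integrate(function(y) 2 * a * k * y^(k - 1) * f(y, tt),
                x0, Inf, rel.tol = 1e-10)$value, numeric(1))
    rhs <- transport - (a * k * xs^k + 1) * f(xs, tt) + gain
    expect_lt(max(abs(lhs - rhs)), 1e-3)
  }
})

test_that("fragmentation invariants: volume, origin blow-up, limiting profile", {
  a <- 5
  # volume of the self-similar solution is time-invariant; c/2 for k = 2
  vol <- function(tt) integrate(function(x)
    x * fragmentation_selfsimilar(x, tt, a, 2), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(vol(0.5), 0.5, tolerance = 1e-8)
  expect_equal(vol(5), 0.5, tolerance = 1e-8)
  # origin value (a t)^(2/k) diverges with t
  expect_gt(fragmentation_selfsimilar(0, 100, a, 3),
            fragmentation_selfsimilar(0, 1, a, 3) * 10)
  # growth/decay solution converges pointwise to the limiting profile,
  # whose e-folding scale for a = 5, k = 2 is 1/sqrt(5)
  xs <- seq(0, 2, by = 0.05)
  expect_equal(fragmentation_growth_decay(xs, 30, a, 2),
               limiting_fragmentation_profile(xs, a, 2), tolerance = 1e-8)
  prof <- function(x) limiting_fragmentation_profile(x, 5, 2)
  expect_equal(prof(1 / sqrt(5)) / prof(0), exp(-1), tolerance = 1e-12)
})
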