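test_that("single-mode decay matches the heat-equation closed form", {
  g <- spatial_grid(128, 5, Lx = 2 * pi, Ly = 1)
  spec <- rd_system_spec(1, D = 1, lambdas = 0.2)
  u0 <- field_state(0, matrix(cos(g$x), g$ny, g$nx, byrow = TRUE), g)
  dt <- rd_stable_dt(spec, g)
  tr <- simulate_rd(spec, g, u0, t_end = 1, dt = dt, save_every = 1e6)
  uT <- tr$states[[length(tr$times)]]$values[[1]]
  k <- 2 * pi / g$Lx
  expected <- exp(-(1 * k^2 + 0.2) * tr$times[length(tr$times)]) * cos(g$x)
  expect_lt(max(abs(y_avg <- colMeans(uT) - expected)) / max(abs(expected)),
            1e-3)
})

test_that("constant source drives the state to c/lambda", {
  g <- spatial_grid(32, 5, Lx = 2 * pi, Ly = 1)
  spec <- rd_system_spec(1, D = 1, lambdas = 0.5, sources = list(0.8))
  u0 <- field_state(0, matrix(sin(g$x) + 1, g$ny, g$nx, byrow = TRUE), g)
  dt <- rd_stable_dt(spec, g)
  tr <- simulate_rd(spec, g, u0, t_end = 40, dt = dt, save_every = 1e7)
  uT <- tr$states[[length(tr$times)]]$values[[1]]
  expect_lt(max(abs(uT - 0.8 / 0.5)), 1e-6)
})

test_that("mass is conserved without reaction, degradation or sources", {
  g <- spatial_grid(24, 7, Lx = 3, Ly = 1)
  spec <- rd_system_spec(1, D = 0.7, lambdas = 0)
  set.seed(3)
  u0 <- field_state(0, matrix(runif(g$ny * g$nx), g$ny, g$nx), g)
  dt <- rd_stable_dt(spec, g)
  tr <- simulate_rd(spec, g, u0, t_end = 1, dt = dt, save_every = 500)
  # trapezoidal y-weights: interior rows count fully, boundary rows half
  wy <- rep(1, g$ny); wy[c(1, g$ny)] <- 0.5
  mass <- vapply(tr$states, function(st) sum(wy * st$values[[1]]), 0)
  expect_lt(max(abs(mass - mass[1])), 1e-10 * max(1, abs(mass[1])))
})

test_that("spatial discretization is second order", {
  err_at <- function(nx, ny) {
    g <- spatial_grid(nx, ny, Lx = 2 * pi, Ly = 1)
    spec <- rd_system_spec(1, D = 1, lambdas = 0)
    u0 <- field_state(0, matrix(cos(g$x), g$ny, g$nx, byrow = TRUE), g)
    tr <- simulate_rd(spec, g, u0, t_end = 0.5,
                      dt = rd_stable_dt(spec, g), save_every = 1e7)
    uT <- colMeans(tr$states[[length(tr$times)]]$values[[1]])
    tT <- tr$times[length(tr$times)]
    max(abs(uT - exp(-tT) * cos(g$x)))
  }
  e1 <- err_at(16, 5)
  e2 <- err_at(32, 9)
  expect_gt(e1 / e2, 3)   # ~4x for exact second order
  expect_lt(e1 / e2, 6)
})

test_that("dispersion relation handles the trivial cases", {
  spec <- rd_system_spec(1, D = 2, lambdas = 0.3)
  expect_equal(dispersion_growth_rates(spec, 0, 1), -2.3, tolerance = 1e-12)
  # at k = 0 the rate is the spectral abscissa of J - diag(lambda)
  spec2 <- rd_system_spec(2, D = c(1, 10), lambdas = c(0.2, 0.4),
                          reaction = reaction_brusselator(A = 2, B = 4))
  u0 <- c(2, 4 / 2)        # A, B/A with lambdas absorbed? not an equilibrium
  expect_error(dispersion_growth_rates(spec2, c(1, 1), 0), "equilibrium")
})

test_that("Brusselator shows a Turing band and simulate_rd grows at the predicted rate", {
  A <- 2; B <- 4.5
  spec <- rd_system_spec(2, D = c(0.05, 2), lambdas = c(0, 0),
                         reaction = reaction_brusselator(A, B))
  u0 <- c(A, B / A)
  ks <- seq(0, 4, by = 0.1)
  rates <- dispersion_growth_rates(spec, u0, ks)
  expect_lt(rates[1], 0)               # homogeneous state reaction-stable
  expect_gt(max(rates), 0)             # positive band at nonzero k
  # oracle: brute-force eigenvalue scan reproduces the same curve
  J <- matrix(c(B - 1, -B, A^2, -A^2), 2, 2, byrow = FALSE)
  oracle <- vapply(ks, function(k) {
    max(Re(eigen(J - diag(k^2 * c(0.05, 2)), only.values = TRUE)$values))
  }, 0)
  expect_equal(rates, oracle, tolerance = 1e-6)

  # early-time growth of an unstable mode matches the dispersion rate
  g <- spatial_grid(64, 5, Lx = 2 * pi, Ly = 1)
  k_star <- ks[which.max(rates)]
  k_star <- round(k_star)              # periodic admissible integer mode
  rate_star <- dispersion_growth_rates(spec, u0, k_star)
  ev <- eigen(J - diag(k_star^2 * c(0.05, 2)))
  vdir <- Re(ev$vectors[, which.max(Re(ev$values))])
  amp0 <- 1e-4
  init <- field_state(0, list(
    matrix(A + amp0 * vdir[1] * cos(k_star * g$x), g$ny, g$nx, byrow = TRUE),
    matrix(B / A + amp0 * vdir[2] * cos(k_star * g$x), g$ny, g$nx,
           byrow = TRUE)), g)
  dt <- rd_stable_dt(spec, g)
  t_end <- 1
  tr <- simulate_rd(spec, g, init, t_end = t_end, dt = dt, save_every = 1e7)
  uT <- colMeans(tr$states[[length(tr$times)]]$values[[1]]) - A
  modeamp <- 2 * mean(uT * cos(k_star * g$x))
  growth <- log(modeamp / (amp0 * vdir[1])) / tr$times[length(tr$times)]
  expect_lt(abs(growth - rate_star) / abs(rate_star), 0.05)
})

test_that("screened Poisson solver matches closed forms and a dense oracle", {
  g <- spatial_grid(32, 17, Lx = 2 * pi, Ly = 1)
  # constant source, b = 1: w = -S
  w <- solve_screened_poisson(2.5, d_w = 1, b = 1, grid = g)
  expect_lt(max(abs(w + 2.5)), 1e-8)
  # single Fourier mode, b = 0: w = -sin(kx)/k^2 to discretization accuracy
  gf <- spatial_grid(128, 5, Lx = 2 * pi, Ly = 1)
  src <- matrix(sin(gf$x), gf$ny, gf$nx, byrow = TRUE)
  w2 <- solve_screened_poisson(src, d_w = 1, b = 0, grid = gf)
  k <- 2 * pi / gf$Lx
  expect_lt(max(abs(w2 - (-src / k^2))), 1e-3)
  # random smooth source vs dense direct solve
  g3 <- spatial_grid(32, 17, Lx = 2, Ly = 1)
  set.seed(11)
  sm <- matrix(0, g3$ny, g3$nx)
  for (m in 1:3) {
    sm <- sm + matrix(rnorm(1) * cos(2 * pi * m * g3$x / g3$Lx +
                                       rnorm(1)), g3$ny, g3$nx,
                      byrow = TRUE) *
      matrix(cos((m - 1) * pi * g3$y / g3$Ly), g3$ny, g3$nx)
  }
  w3 <- solve_screened_poisson(sm, d_w = 1, b = 0.7, grid = g3)
  w3o <- dense_screened_solve(sm, 1, 0.7, g3)
  expect_lt(max(abs(w3 - w3o)), 1e-10)
  # Dirichlet boundary agrees with the oracle too
  w4 <- solve_screened_poisson(sm, 1, 0.7, g3, bc = c("dirichlet0",
                                                      "dirichlet0"))
  w4o <- dense_screened_solve(sm, 1, 0.7, g3, bc = c("dirichlet0",
                                                     "dirichlet0"))
  expect_lt(max(abs(w4 - w4o)), 1e-10)
  # singular case is refused
  expect_error(solve_screened_poisson(1, d_w = 1, b = 0, grid = g),
               "singular")
})

test_that("integration is deterministic and guarded", {
  g <- spatial_grid(16, 5, Lx = 1, Ly = 1)
  spec <- rd_system_spec(1, D = 1, lambdas = 0, noise_amplitude = 0.3)
  u0 <- field_state(0, matrix(0, g$ny, g$nx), g)
  dt <- rd_stable_dt(spec, g)
  t1 <- simulate_rd(spec, g, u0, t_end = 50 * dt, dt = dt, seed = 42)
  t2 <- simulate_rd(spec, g, u0, t_end = 50 * dt, dt = dt, seed = 42)
  expect_identical(t1$states[[length(t1$times)]]$values,
                   t2$states[[length(t2$times)]]$values)
  # dt above the stability bound is rejected before integration
  expect_error(simulate_rd(spec, g, u0, t_end = 1, dt = 10 * dt),
               "stability bound")
  # a blow-up aborts with the last finite time reported
  spec2 <- rd_system_spec(1, D = 1, lambdas = 0,
                          reaction = reaction_fn(function(u, x, y, t) {
                            list(u[[1]]^2 + 5)
                          }, m = 1))
  expect_error(simulate_rd(spec2, g, u0, t_end = 10,
                           dt = rd_stable_dt(spec2, g), save_every = 100),
               "last finite time")
})
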