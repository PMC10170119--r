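grid_seg <- spatial_grid(256, 5, Lx = 2 * pi, Ly = 1)

test_that("segment basis is unit-norm, localized, and warns on crowding", {
  bas <- build_segment_basis(c(1, 2, 4), 0.1, grid_seg)
  norms <- colSums(bas$profiles^2) * grid_seg$hx
  expect_equal(norms, rep(1, 3), tolerance = 1e-12)
  # two centers 10 eps apart: overlap below exp(-5)
  b2 <- build_segment_basis(c(1, 2), 0.1, grid_seg)
  ov <- sum(b2$profiles[, 1] * b2$profiles[, 2]) * grid_seg$hx
  expect_lt(abs(ov), exp(-5))
  expect_warning(build_segment_basis(c(1, 1.3), 0.1, grid_seg),
                 "overlap")
  expect_error(build_segment_basis(c(1, 2), -1, grid_seg), "positive")
  expect_error(build_segment_basis(c(2, 1), 0.1, grid_seg), "increasing")
})

test_that("amplitude projection solves the Gram system", {
  bas <- build_segment_basis(c(1, 2.5, 4, 5.5), 0.1, grid_seg)
  u <- bas$profiles[, 1] + 2 * bas$profiles[, 3]
  X <- project_to_amplitudes(u, bas)
  expect_equal(X, c(1, 0, 2, 0), tolerance = 1e-8)
  # field orthogonal to every profile projects to zero
  u_perp <- sin(7 * grid_seg$x)
  G <- crossprod(bas$profiles) * grid_seg$hx
  u_perp <- u_perp - bas$profiles %*%
    solve(G, crossprod(bas$profiles, u_perp) * grid_seg$hx)
  expect_lt(max(abs(project_to_amplitudes(as.numeric(u_perp), bas))), 1e-8)
  # L2 optimality: the Gram solution beats random coefficient vectors
  set.seed(5)
  u_r <- rnorm(grid_seg$nx)
  Xo <- project_to_amplitudes(u_r, bas)
  res_opt <- sum((u_r - bas$profiles %*% Xo)^2)
  worst <- min(vapply(1:100, function(i) {
    sum((u_r - bas$profiles %*% (Xo + rnorm(4, sd = 0.1)))^2)
  }, 0))
  expect_lte(res_opt, worst + 1e-12)
})

test_that("amplitude integration matches closed forms and stays bounded", {
  sys0 <- amplitude_system_quadratic(0, matrix(0, 2, 2))
  tr <- integrate_amplitudes(sys0, c(1.5, -2), t_end = 1, dt = 0.01)
  expect_equal(tr$X[nrow(tr$X), ], c(X1 = 1.5, X2 = -2))
  sys1 <- amplitude_system_quadratic(0, matrix(-1, 1, 1))
  tr1 <- integrate_amplitudes(sys1, 1, t_end = 1, dt = 0.001)
  expect_equal(unname(tr1$X[nrow(tr1$X), 1]), exp(-1), tolerance = 1e-8)
  ross <- amplitude_system_rossler()
  trr <- integrate_amplitudes(ross, c(1, 1, 1), t_end = 500, dt = 0.005,
                              save_every = 100L)
  expect_equal(trr$status, "ok")
  expect_lt(max(abs(trr$X)), 30)
  # interpreted fallback agrees with the compiled path
  rossf <- amplitude_system(ross$vfield, 3)
  tr_f <- integrate_amplitudes(rossf, c(1, 1, 1), t_end = 2, dt = 0.01)
  tr_c <- integrate_amplitudes(ross, c(1, 1, 1), t_end = 2, dt = 0.01)
  expect_equal(tr_f$X, tr_c$X, tolerance = 1e-10)
})

test_that("Lyapunov estimates recover linear spectral abscissas", {
  lin <- amplitude_system_quadratic(0, diag(c(0.3, -1)))
  ly <- estimate_largest_lyapunov(lin, c(1, 1), horizon = 50)
  expect_equal(ly$lambda_max, 0.3, tolerance = 0.01)
  stab <- amplitude_system_quadratic(0, diag(c(-1, -1)))
  ly2 <- estimate_largest_lyapunov(stab, c(1, 1), horizon = 100)
  expect_equal(ly2$lambda_max, -1, tolerance = 0.01)
})

test_that("Roessler Lyapunov exponent agrees with the two-orbit oracle", {
  ross <- amplitude_system_rossler()
  ly <- estimate_largest_lyapunov(ross, c(1, 1, 1), horizon = 1500,
                                  transient = 100)
  oracle <- two_orbit_lyapunov(rossler_vf(), c(1, 1, 1), horizon = 700)
  expect_gt(ly$lambda_max, 0)
  tol <- 2 * sqrt(ly$se^2 + oracle$se^2)
  expect_lt(abs(ly$lambda_max - oracle$lambda), max(tol, 0.02))
})

test_that("attractor enumeration counts bistable products", {
  one <- amplitude_system_groups("bistable")
  e1 <- enumerate_local_attractors(one, matrix(c(-2, 2), 2, 1),
                                   settle_time = 20)
  expect_length(e1$attractors, 2)
  two <- amplitude_system_groups(c("bistable", "bistable"), coupling = 0)
  corners <- as.matrix(expand.grid(c(-2, 2), c(-2, 2)))
  e2 <- enumerate_local_attractors(two, corners, settle_time = 20)
  expect_length(e2$attractors, 4)
  expect_equal(sort(vapply(e2$attractors, `[[`, 0, "basin_count")),
               rep(1, 4))
})

test_that("weak-coupling attractor counts factorize over groups", {
  for (Ma in 1:3) {
    for (gcpl in c(0, 1e-6)) {
      sys <- amplitude_system_groups(rep("bistable", Ma), coupling = gcpl)
      corners <- as.matrix(expand.grid(rep(list(c(-2, 2)), Ma)))
      enum <- enumerate_local_attractors(sys, corners, settle_time = 20)
      expect_length(enum$attractors, 2^Ma)
    }
  }
})

test_that("oscillatory groups contribute a fixed point and a limit cycle", {
  sys <- amplitude_system_groups("oscillatory")
  inits <- matrix(c(0.1, 0, 1.4, 0), 2, 2, byrow = TRUE)
  enum <- enumerate_local_attractors(sys, inits, settle_time = 60)
  expect_length(enum$attractors, 2)
  classes <- sort(vapply(enum$attractors, `[[`, "", "class"))
  expect_equal(classes, c("fixed-point", "periodic"))
})

test_that("embedding realizes a linear contraction on a small grid", {
  g <- spatial_grid(128, 9, Lx = 2 * pi, Ly = 0.5)
  bas <- build_segment_basis(pi + c(-0.75, 0, 0.75), 0.1, g)
  target <- amplitude_system_quadratic(0, -diag(3))
  emb <- embed_target_ode(target, bas, embedding_template(lambda1 = 200),
                          newton_linear = 2)
  expect_lt(emb$defect$rel, 0.1)
  X0 <- c(0.8, -0.5, 0.3)
  sim <- simulate_embedded(emb, X0, t_end = 3)
  ode <- X0 * exp(-sim$times[length(sim$times)])
  expect_lt(max(abs(sim$X[nrow(sim$X), ] - ode)) / max(abs(X0)), 0.05)
})

test_that("embedding realizes a harmonic oscillator with small energy drift", {
  g <- spatial_grid(128, 9, Lx = 2 * pi, Ly = 0.5)
  bas <- build_segment_basis(pi + c(-0.5, 0.5), 0.1, g)
  target <- amplitude_system_quadratic(0, matrix(c(0, -1, 1, 0), 2, 2))
  emb <- embed_target_ode(target, bas, embedding_template(lambda1 = 800),
                          newton_linear = 6)
  expect_lt(emb$defect$rel, 0.1)
  X0 <- c(0.5, 0)
  sim <- simulate_embedded(emb, X0, t_end = 2 * pi)
  energy <- rowSums(sim$X^2)
  expect_lt(abs(energy[length(energy)] - energy[1]) / energy[1], 0.02)
  # the loop closes: final state near the initial one
  expect_lt(sqrt(sum((sim$X[nrow(sim$X), ] - X0)^2)) / sqrt(sum(X0^2)), 0.1)
})

test_that("embedding rejects malformed targets", {
  g <- spatial_grid(64, 5, Lx = 2 * pi, Ly = 0.5)
  bas <- build_segment_basis(c(2, 4), 0.1, g)
  cubic <- amplitude_system_quadratic(0, -diag(2), cub = c(-1, 0))
  expect_error(embed_target_ode(cubic, bas), "bilinear targets")
  wrong_n <- amplitude_system_quadratic(0, -diag(3))
  expect_error(embed_target_ode(wrong_n, bas), "number of basis segments")
})
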