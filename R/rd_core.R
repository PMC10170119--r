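#' Integrate a reaction-diffusion system on the strip
#'
#' Method-of-lines integration of
#' `du_i/dt = d_i Lap(u_i) - lambda_i u_i + f_i(u) + eta_i(x, y)`
#' with second-order central differences, explicit RK4 for the deterministic
#' part and an additive Euler-Maruyama increment (scaled by `sqrt(dt)`) when
#' `noise_amplitude > 0`. Built-in reactions (`zero`, `brusselator`,
#' `fields`) run in compiled code; [reaction_fn()] reactions use an
#' interpreted fallback and are only suitable for small problems.
#'
#' @param spec An [rd_system_spec()].
#' @param grid A [spatial_grid()].
#' @param init A [field_state()] (or list of `ny x nx` matrices) at `t = 0`.
#' @param t_end Final time; the integrator takes `ceil(t_end/dt)` steps so the
#'   final snapshot time is within `dt` of `t_end`.
#' @param dt Time step; must satisfy the diffusion stability bound
#'   [rd_stable_dt()], otherwise the call is rejected before integration.
#' @param save_every Snapshot cadence in steps (the initial and final states
#'   are always included).
#' @param seed Integer seed for the noise stream (ignored when noise is off);
#'   identical spec + seed gives a bit-identical trajectory.
#' @return A `trajectory_record`: list with `times` (strictly increasing),
#'   `states` (list of [field_state()]), and `metadata` (integrator settings,
#'   seed, spec hash, status). On blow-up (non-finite value or `|u| > 1e8`)
#'   an error is raised naming the last finite time.
#' @examples
#' g <- spatial_grid(32, 5, Lx = 2 * pi, Ly = 1)
#' spec <- rd_system_spec(1, D = 1, lambdas = 0.2)
#' u0 <- field_state(0, matrix(cos(g$x), g$ny, g$nx, byrow = TRUE), g)
#' tr <- simulate_rd(spec, g, u0, t_end = 0.1, dt = rd_stable_dt(spec, g))
#' @export
simulate_rd <- function(spec, grid, init, t_end, dt, save_every = 1L,
                        seed = NULL) {
  stopifnot(inherits(spec, "rd_system_spec"), inherits(grid, "spatial_grid"))
  if (!inherits(init, "field_state")) init <- field_state(0, init, grid)
  if (length(init$values) != spec$m) stop("init does not match spec$m")
  dt_max <- rd_stable_dt(spec, grid)
  if (dt > dt_max * (1 + 1e-12)) {
    stop(sprintf("dt = %g violates the stability bound %g", dt, dt_max))
  }
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive")
  nsteps <- as.integer(ceiling(t_end / dt - 1e-9))
  save_every <- max(1L, as.integer(save_every))
  srcs <- lapply(spec$sources, resolve_source, grid = grid)
  bc0 <- vapply(spec$bc, function(b) as.integer(b[[1]] == "dirichlet0"), 1L)
  bc1 <- vapply(spec$bc, function(b) as.integer(b[[2]] == "dirichlet0"), 1L)
  rcode <- switch(spec$reaction$name, zero = 0L, brusselator = 1L,
                  fields = 2L, -1L)
  if (!is.null(seed)) set.seed(seed)
  if (rcode >= 0L) {
    res <- rd_integrate_cpp(init$values, grid$nx, grid$ny, grid$hx, grid$hy,
                            spec$D, spec$lambdas, bc0, bc1, srcs, rcode,
                            if (is.null(spec$reaction$params)) list()
                            else spec$reaction$params,
                            dt, nsteps, save_every, spec$noise_amplitude, 1e8)
  } else {
    res <- rd_integrate_r(init$values, grid, spec, srcs, bc0, bc1, dt, nsteps,
                          save_every)
  }
  if (res$status != "ok") {
    stop(sprintf("blow-up during integration; last finite time t = %g",
                 res$last_time))
  }
  states <- mapply(function(s, t) field_state(t, s, grid),
                   res$snapshots, res$times, SIMPLIFY = FALSE)
  structure(list(
    times = as.numeric(res$times),
    states = states,
    metadata = list(spec_hash = spec_hash(list(spec = spec[c("m", "D",
                      "lambdas", "bc", "noise_amplitude")],
                      reaction = spec$reaction$name,
                      grid = grid[c("nx", "ny", "Lx", "Ly")])),
                    seed = seed, dt = dt, t_end = t_end,
                    save_every = save_every, integrator = "rk4")),
    class = "trajectory_record")
}

#' @exportS3Method base::print
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record> %d snapshots, t in [%g, %g]\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# interpreted stepper for reaction_fn reactions (noise handled the same way)
rd_integrate_r <- function(values, grid, spec, srcs, bc0, bc1, dt, nsteps,
                           save_every) {
  m <- spec$m
  Ls <- lapply(seq_len(m), function(c) {
    laplacian_matrix(grid, spec$bc[[c]][1], spec$bc[[c]][2])
  })
  masks <- lapply(seq_len(m), function(c) {
    dirichlet_mask(grid, spec$bc[[c]][1], spec$bc[[c]][2])
  })
  X <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(grid$y, grid$ny, grid$nx)
  rfn <- spec$reaction$fn
  rhs <- function(u, t) {
    reac <- rfn(u, X, Y, t)
    lapply(seq_len(m), function(c) {
      r <- matrix(as.numeric(Ls[[c]] %*% as.vector(u[[c]])),
                  grid$ny, grid$nx) * spec$D[c] -
        spec$lambdas[c] * u[[c]] + reac[[c]] + srcs[[c]]
      r[matrix(masks[[c]], grid$ny, grid$nx)] <- 0
      r
    })
  }
  u <- values
  for (c in seq_len(m)) u[[c]][matrix(masks[[c]], grid$ny, grid$nx)] <- 0
  times <- 0
  snaps <- list(u)
  amp <- spec$noise_amplitude
  status <- "ok"; last_t <- 0
  for (s in seq_len(nsteps)) {
    t0 <- (s - 1) * dt
    k1 <- rhs(u, t0)
    k2 <- rhs(mapply(function(a, b) a + 0.5 * dt * b, u, k1,
                     SIMPLIFY = FALSE), t0 + dt / 2)
    k3 <- rhs(mapply(function(a, b) a + 0.5 * dt * b, u, k2,
                     SIMPLIFY = FALSE), t0 + dt / 2)
    k4 <- rhs(mapply(function(a, b) a + dt * b, u, k3, SIMPLIFY = FALSE),
              t0 + dt)
    u2 <- mapply(function(a, a1, a2, a3, a4) {
      a + dt / 6 * (a1 + 2 * a2 + 2 * a3 + a4)
    }, u, k1, k2, k3, k4, SIMPLIFY = FALSE)
    if (amp > 0) {
      u2 <- lapply(seq_len(m), function(c) {
        z <- u2[[c]] + amp * sqrt(dt) *
          matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx)
        z[matrix(masks[[c]], grid$ny, grid$nx)] <- 0
        z
      })
    }
    bad <- any(vapply(u2, function(z) {
      any(!is.finite(z)) || max(abs(z)) > 1e8
    }, TRUE))
    if (bad) { status <- "blowup"; last_t <- t0; break }
    u <- u2
    if (s %% save_every == 0 || s == nsteps) {
      times <- c(times, s * dt)
      snaps <- c(snaps, list(u))
    }
  }
  list(times = times, snapshots = snaps, status = status,
       last_time = if (status == "ok") nsteps * dt else last_t)
}

#' Linear growth rates of spatial modes about a homogeneous equilibrium
#'
#' For each wavenumber `k` returns the largest real part of the eigenvalues of
#' `J(u0) - k^2 D - diag(lambda)`, where `J` is the reaction Jacobian at the
#' homogeneous state `u0` (computed by central finite differences). This is
#' the dispersion relation whose positive band signals a Turing instability.
#'
#' @param spec An [rd_system_spec()] whose sources are spatially constant.
#' @param u0 Homogeneous state (length `m`); must be an equilibrium of the
#'   reaction + degradation + source terms (residual checked at 1e-8).
#' @param wavenumbers Numeric vector of wavenumbers `k`.
#' @return Numeric vector of growth rates, one per wavenumber.
#' @examples
#' spec <- rd_system_spec(1, D = 2, lambdas = 0.3)
#' dispersion_growth_rates(spec, 0, 1)  # -d k^2 - lambda = -2.3
#' @export
dispersion_growth_rates <- function(spec, u0, wavenumbers) {
  stopifnot(inherits(spec, "rd_system_spec"), length(u0) == spec$m)
  src <- vapply(spec$sources, function(s) {
    if (is.null(s)) return(0)
    if (is.numeric(s) && length(s) == 1L) return(as.numeric(s))
    if (is.function(s)) {
      v <- s(matrix(c(0, 0.5), 1), matrix(c(0.3, 0.7), 1))
      if (stats::sd(v) > 1e-12) stop("sources must be spatially constant")
      return(v[1])
    }
    if (is.matrix(s)) {
      if (stats::sd(s) > 1e-12) stop("sources must be spatially constant")
      return(s[1])
    }
    stop("unsupported source")
  }, 0)
  f0 <- reaction_point(spec$reaction, u0)
  resid <- f0 - spec$lambdas * u0 + src
  if (max(abs(resid)) > 1e-8) {
    stop(sprintf("u0 is not an equilibrium: residual %.3e", max(abs(resid))))
  }
  J <- reaction_jacobian(spec$reaction, u0)
  vapply(wavenumbers, function(k) {
    A <- J - diag(k^2 * spec$D + spec$lambdas, spec$m)
    max(Re(eigen(A, only.values = TRUE)$values))
  }, 0)
}

# evaluate the reaction at a single homogeneous state
reaction_point <- function(reaction, u0) {
  u <- lapply(u0, function(ui) matrix(ui, 1, 1))
  as.numeric(vapply(reaction$fn(u, matrix(0, 1, 1), matrix(0, 1, 1), 0),
                    function(z) z[1, 1], 0))
}

reaction_jacobian <- function(reaction, u0, h = NULL) {
  m <- length(u0)
  if (is.null(h)) h <- 1e-6 * (1 + abs(u0))
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    up <- u0; up[j] <- up[j] + h[j]
    dn <- u0; dn[j] <- dn[j] - h[j]
    J[, j] <- (reaction_point(reaction, up) -
                 reaction_point(reaction, dn)) / (2 * h[j])
  }
  J
}

#' Solve the screened Poisson equation on the strip
#'
#' Solves `d_w Lap(w) - b^2 w = source` with periodic x and the given y
#' boundary tags, using a sparse direct solve of the same discrete Laplacian
#' as the integrator. With `b = 0` and no Dirichlet side the operator is
#' singular: the source must have zero mean and the returned solution is the
#' zero-mean one.
#'
#' @param source `ny x nx` matrix (or function/scalar, resolved on the grid).
#' @param d_w Positive diffusion coefficient of the morphogen.
#' @param b Nonnegative decay parameter (`beta = b / sqrt(d_w)` is the inverse
#'   decay length).
#' @param grid A [spatial_grid()].
#' @param bc Character pair `c(bc_y0, bc_y1)`.
#' @return `ny x nx` matrix `w`, with attribute `residual` (the max-norm
#'   residual of the discrete equation).
#' @examples
#' g <- spatial_grid(32, 5, Lx = 2 * pi, Ly = 1)
#' w <- solve_screened_poisson(1, d_w = 1, b = 1, grid = g)
#' max(abs(w + 1)) < 1e-8  # w == -S/b^2
#' @export
solve_screened_poisson <- function(source, d_w, b, grid,
                                   bc = c("neumann0", "neumann0")) {
  stopifnot(d_w > 0, b >= 0)
  src <- resolve_source(source, grid)
  L <- laplacian_matrix(grid, bc[[1]], bc[[2]])
  mask <- dirichlet_mask(grid, bc[[1]], bc[[2]])
  n <- grid$ny * grid$nx
  A <- d_w * L - Matrix::Diagonal(n, b^2)
  rhs <- as.vector(src)
  if (any(mask)) {
    # pinned rows: w = 0
    idx <- which(mask)
    A[idx, ] <- 0
    A[cbind(idx, idx)] <- 1
    rhs[idx] <- 0
  } else if (b == 0) {
    if (abs(mean(src)) > 1e-10 * (max(abs(src)) + 1e-300)) {
      stop("singular system: b = 0 with nonzero-mean source and no Dirichlet side")
    }
    # deflate the constant null space: solve (A - P) w = rhs with
    # P = ones/n, which pins the solution mean to zero
    A <- A - Matrix::Matrix(1 / n, n, n)
  }
  w <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e) stop("linear solve failed: ",
                                         conditionMessage(e)))
  W <- matrix(w, grid$ny, grid$nx)
  res <- d_w * as.numeric(L %*% w) - b^2 * w - as.vector(src)
  res[mask] <- 0
  resid <- max(abs(res))
  scale <- max(abs(src))
  if (scale > 0 && resid > 1e-8 * scale) {
    stop(sprintf("screened Poisson solve did not converge: residual %.3e",
                 resid))
  }
  attr(W, "residual") <- resid
  W
}

# stable content hash for small R structures (canonical JSON -> md5)
spec_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
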