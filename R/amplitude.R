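#' Finite-dimensional amplitude systems
#'
#' An `amplitude_system` holds the reduced ODE `dX/dt = F(X)` for segment
#' amplitudes. Two structured families run in compiled code:
#' `"quadratic_cubic"`, `F_i = c0_i + (L X)_i + X_i (B X)_i + cub_i X_i^3`
#' (linear systems, the Roessler field, reduced Galerkin projections), and
#' `"segment_groups"`, weakly coupled groups of bistable or oscillatory units
#' (see [amplitude_system_groups()]). Arbitrary vector fields are supported
#' through `amplitude_system(vfield = ...)` with an interpreted integrator.
#'
#' @param vfield Function `F(X)` returning `dX/dt` (for the custom family).
#' @param n_vars Number of amplitudes.
#' @param group_index Optional integer vector assigning amplitudes to groups
#'   (must partition `1..n_vars`).
#' @return An object of class `amplitude_system`.
#' @export
amplitude_system <- function(vfield, n_vars, group_index = NULL) {
  stopifnot(is.function(vfield), n_vars >= 1)
  new_amplitude_system(family = "custom", n = as.integer(n_vars),
                       vfield = vfield, params = list(),
                       group_index = group_index)
}

new_amplitude_system <- function(family, n, vfield, params,
                                 group_index = NULL,
                                 coupling_matrix = NULL) {
  if (is.null(group_index)) group_index <- rep(1L, n)
  stopifnot(length(group_index) == n)
  if (!setequal(unique(group_index), seq_len(max(group_index)))) {
    stop("group_index must use consecutive group labels 1..M_a")
  }
  structure(list(family = family, n_vars = n, vfield = vfield,
                 params = params, group_index = as.integer(group_index),
                 coupling_matrix = coupling_matrix),
            class = "amplitude_system")
}

#' @exportS3Method base::print
print.amplitude_system <- function(x, ...) {
  cat(sprintf("<amplitude_system> n=%d, family=%s, M_a=%d\n",
              x$n_vars, x$family, max(x$group_index)))
  invisible(x)
}

#' Quadratic-bilinear amplitude system
#'
#' `F_i(X) = c0_i + sum_j L_ij X_j + X_i sum_j B_ij X_j + cub_i X_i^3`.
#'
#' @param c0 Constant term (length n, recycled from scalar).
#' @param L Linear coefficient matrix (n x n).
#' @param B Bilinear coefficient matrix (n x n); row i multiplies `X_i`.
#' @param cub Per-coordinate cubic coefficient (default 0).
#' @param group_index Optional group assignment.
#' @export
amplitude_system_quadratic <- function(c0, L, B = NULL, cub = 0,
                                       group_index = NULL) {
  L <- as.matrix(L)
  n <- nrow(L)
  stopifnot(ncol(L) == n)
  if (is.null(B)) B <- matrix(0, n, n)
  c0 <- rep_len(as.numeric(c0), n)
  cub <- rep_len(as.numeric(cub), n)
  params <- list(family_code = 1L, n = n, c0 = c0, L = L, B = as.matrix(B),
                 cub = cub)
  vf <- function(X) {
    as.numeric(c0 + L %*% X + X * (B %*% X) + cub * X^3)
  }
  cm <- abs(L) + abs(B)
  diag(cm) <- 0
  new_amplitude_system("quadratic_cubic", n, vf, params, group_index,
                       coupling_matrix = cm)
}

#' The Roessler vector field as an amplitude system
#'
#' `dX1 = -X2 - X3; dX2 = X1 + a X2; dX3 = b + X3 (X1 - c)` with the classic
#' chaotic parameters as defaults.
#'
#' @param a,b,c Roessler parameters.
#' @param scale Amplitude scale: the returned system governs `Y = scale * X`
#'   with `X` the classic Roessler coordinates. Linear terms are invariant;
#'   the bilinear coupling becomes `1/scale` and the constant `scale * b`.
#'   Rescaling leaves the Lyapunov spectrum and the attractor topology
#'   exactly unchanged (linear conjugacy) and keeps segment amplitudes O(1),
#'   which the reaction-diffusion embedding needs.
#' @param order Optional permutation: `order[i]` names which Roessler
#'   coordinate sits at position `i` (used to lay segments out along the
#'   strip axis in a different order than X1, X2, X3).
#' @export
amplitude_system_rossler <- function(a = 0.2, b = 0.2, c = 5.7, scale = 1,
                                     order = 1:3) {
  L <- matrix(0, 3, 3)
  L[1, 2] <- -1; L[1, 3] <- -1
  L[2, 1] <- 1; L[2, 2] <- a
  L[3, 3] <- -c
  B <- matrix(0, 3, 3)
  B[3, 1] <- 1 / scale
  c0 <- c(0, 0, scale * b)
  sys <- amplitude_system_quadratic(c0, L, B)
  if (!identical(order, 1:3)) sys <- reorder_amplitude_system(sys, order)
  sys
}

#' Permute the coordinates of a quadratic amplitude system
#'
#' @param system A `"quadratic_cubic"` family system.
#' @param order Integer permutation; position `i` of the new system carries
#'   coordinate `order[i]` of the old one.
#' @export
reorder_amplitude_system <- function(system, order) {
  stopifnot(system$family == "quadratic_cubic",
            setequal(order, seq_len(system$n_vars)))
  p <- system$params
  amplitude_system_quadratic(p$c0[order], p$L[order, order, drop = FALSE],
                             p$B[order, order, drop = FALSE], p$cub[order],
                             group_index = system$group_index[order])
}

#' Weakly coupled segment groups with two local attractors each
#'
#' Each group is either a bistable scalar unit `dX = X - X^3` (attracting
#' fixed points at -1 and +1) or a planar oscillatory unit with a stable
#' equilibrium at the origin and a stable unit-radius limit cycle
#' (`dr/dt = c r (r^2 - a)(1 - r^2)`, rotation `w`). Groups interact through
#' a linear coupling of strength `coupling` applied to every unit from the
#' first variables of the other groups; at `coupling = 0` the attractor count
#' factorizes as `2^M_a`.
#'
#' @param types Character vector over `{"bistable", "oscillatory"}`, one per
#'   group.
#' @param coupling Inter-group coupling strength (>= 0, typically tiny).
#' @param osc_a,osc_w,osc_c Oscillatory-unit parameters (unstable radius
#'   `sqrt(osc_a)`, angular speed, radial stiffness).
#' @return An `amplitude_system` of family `"segment_groups"`.
#' @export
amplitude_system_groups <- function(types, coupling = 0,
                                    osc_a = 0.25, osc_w = 1, osc_c = 1) {
  stopifnot(all(types %in% c("bistable", "oscillatory")), coupling >= 0)
  sizes <- ifelse(types == "bistable", 1L, 2L)
  n <- sum(sizes)
  gfirst <- cumsum(c(0L, sizes[-length(sizes)]))   # 0-based
  gtype <- as.integer(types == "oscillatory")
  group_index <- rep(seq_along(types), sizes)
  params <- list(family_code = 2L, n = n, gfirst = gfirst, gtype = gtype,
                 coupling = coupling, osc_a = osc_a, osc_w = osc_w,
                 osc_c = osc_c, types = types)
  vf <- function(X) {
    F <- numeric(n)
    firsts <- gfirst + 1L
    csum <- sum(X[firsts])
    for (k in seq_along(types)) {
      f <- firsts[k]
      other <- coupling * (csum - X[f])
      if (gtype[k] == 0L) {
        F[f] <- X[f] - X[f]^3 + other
      } else {
        p <- X[f]; q <- X[f + 1L]
        s <- p^2 + q^2
        gr <- osc_c * (s - osc_a) * (1 - s)
        F[f] <- gr * p - osc_w * q + other
        F[f + 1L] <- osc_w * p + gr * q + other
      }
    }
    F
  }
  cm <- matrix(coupling, n, n)
  diag(cm) <- 0
  new_amplitude_system("segment_groups", n, vf, params, group_index,
                       coupling_matrix = cm)
}

family_code <- function(system) {
  switch(system$family, quadratic_cubic = 1L, segment_groups = 2L, 0L)
}

#' Integrate an amplitude system with fixed-step RK4
#'
#' @param system An [amplitude_system()].
#' @param X0 Initial amplitudes.
#' @param t_end Final time.
#' @param dt Step size.
#' @param save_every Store every `save_every`-th step (initial and final
#'   states always included).
#' @param seed Optional seed (the built-in families are deterministic; the
#'   seed matters only for custom vector fields that draw random numbers).
#' @return List with `times` and `X` (matrix, one row per saved time), plus
#'   `status`/`last_time`; blow-up (`|X| > 1e8`) aborts with the last finite
#'   state retained in the record.
#' @export
integrate_amplitudes <- function(system, X0, t_end, dt, save_every = 1L,
                                 seed = NULL) {
  stopifnot(inherits(system, "amplitude_system"), dt > 0, t_end > 0,
            length(X0) == system$n_vars, all(is.finite(X0)))
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(ceiling(t_end / dt - 1e-9))
  save_every <- max(1L, as.integer(save_every))
  if (family_code(system) > 0L) {
    res <- ode_integrate_cpp(system$params, as.numeric(X0), dt, nsteps,
                             save_every)
  } else {
    res <- ode_integrate_r(system$vfield, as.numeric(X0), dt, nsteps,
                           save_every)
  }
  colnames(res$X) <- paste0("X", seq_len(system$n_vars))
  res
}

ode_integrate_r <- function(vf, X, dt, nsteps, save_every) {
  times <- 0
  out <- list(X)
  status <- "ok"; last <- 0
  for (s in seq_len(nsteps)) {
    k1 <- vf(X)
    k2 <- vf(X + 0.5 * dt * k1)
    k3 <- vf(X + 0.5 * dt * k2)
    k4 <- vf(X + dt * k3)
    X2 <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(X2)) || max(abs(X2)) > 1e8) {
      status <- "blowup"; last <- (s - 1) * dt; break
    }
    X <- X2
    if (s %% save_every == 0 || s == nsteps) {
      times <- c(times, s * dt)
      out <- c(out, list(X))
    }
  }
  list(times = times, X = do.call(rbind, out), status = status,
       last_time = if (status == "ok") nsteps * dt else last)
}

#' Largest Lyapunov exponent by the Benettin tangent method
#'
#' Integrates the variational equation alongside the flow (analytic Jacobian
#' for the built-in families, finite differences otherwise), renormalizes the
#' tangent vector every `renorm_interval`, discards the transient, and
#' averages the log growth. The standard error comes from splitting the
#' post-transient growth sequence into `n_blocks` contiguous blocks.
#'
#' @param system An [amplitude_system()].
#' @param X0 Initial state.
#' @param horizon Total integration time (must exceed `10 * transient`).
#' @param renorm_interval Renormalization interval (time units).
#' @param transient Discarded initial time (default 10% of the horizon).
#' @param dt Integration step (default `renorm_interval / 50`).
#' @param n_blocks Number of blocks for the standard error (>= 20 enforced).
#' @param seed Optional seed (only used by stochastic custom fields).
#' @return Object of class `lyapunov_estimate`: `lambda_max`, `se`,
#'   `horizon`, `renorm_interval`, `transient`, `n_samples`.
#' @export
estimate_largest_lyapunov <- function(system, X0, horizon,
                                      renorm_interval = 0.5,
                                      transient = 0.1 * horizon,
                                      dt = renorm_interval / 50,
                                      n_blocks = 20L, seed = NULL) {
  stopifnot(inherits(system, "amplitude_system"), horizon > transient,
            horizon >= 10 * transient - 1e-9)
  if (!is.null(seed)) set.seed(seed)
  renorm_steps <- max(1L, round(renorm_interval / dt))
  nsteps <- as.integer(ceiling(horizon / dt))
  if (family_code(system) > 0L) {
    res <- lyapunov_benettin_cpp(system$params, as.numeric(X0), dt, nsteps,
                                 renorm_steps)
  } else {
    res <- lyapunov_benettin_r(system$vfield, as.numeric(X0), dt, nsteps,
                               renorm_steps)
  }
  if (res$status != "ok") stop("trajectory blow-up during Lyapunov estimate")
  logs <- res$log_growth
  tau <- renorm_steps * dt
  drop <- floor(transient / tau)
  logs <- logs[(drop + 1L):length(logs)]
  rates <- logs / tau
  n_blocks <- max(20L, as.integer(n_blocks))
  blk <- split(rates, cut(seq_along(rates), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, 0)
  structure(list(lambda_max = mean(rates),
                 se = stats::sd(bm) / sqrt(length(bm)),
                 horizon = horizon, renorm_interval = tau,
                 transient = transient, n_samples = length(rates)),
            class = "lyapunov_estimate")
}

#' @exportS3Method base::print
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("lambda_max = %.4f +- %.4f (horizon %g, %d samples)\n",
              x$lambda_max, x$se, x$horizon, x$n_samples))
  invisible(x)
}

lyapunov_benettin_r <- function(vf, X, dt, nsteps, renorm_steps) {
  n <- length(X)
  w <- rep(1 / sqrt(n), n)
  logs <- numeric(0)
  numjac <- function(X) {
    h <- 1e-6 * (1 + abs(X))
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      up <- X; up[j] <- up[j] + h[j]
      dn <- X; dn[j] <- dn[j] - h[j]
      J[, j] <- (vf(up) - vf(dn)) / (2 * h[j])
    }
    J
  }
  for (s in seq_len(nsteps)) {
    J <- numjac(X)
    wk1 <- J %*% w
    wk2 <- J %*% (w + 0.5 * dt * wk1)
    wk3 <- J %*% (w + 0.5 * dt * wk2)
    wk4 <- J %*% (w + dt * wk3)
    w <- as.numeric(w + dt / 6 * (wk1 + 2 * wk2 + 2 * wk3 + wk4))
    k1 <- vf(X); k2 <- vf(X + 0.5 * dt * k1)
    k3 <- vf(X + 0.5 * dt * k2); k4 <- vf(X + dt * k3)
    X <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(X)) || max(abs(X)) > 1e8) {
      return(list(log_growth = logs, status = "blowup"))
    }
    if (s %% renorm_steps == 0) {
      nr <- sqrt(sum(w^2))
      logs <- c(logs, log(nr))
      w <- w / nr
    }
  }
  list(log_growth = logs, status = "ok", final_state = X)
}

#' Enumerate coexisting local attractors from a set of initial conditions
#'
#' Integrates every initial condition past a settling transient, fingerprints
#' the attractor by the per-coordinate time mean and amplitude range over the
#' post-transient window (rounded to `fingerprint_tol`), and merges
#' fingerprints that agree within `2 * fingerprint_tol` in the max norm.
#' Unbounded orbits are reported as escapes, not attractors.
#'
#' @param system An [amplitude_system()].
#' @param init_grid List (or matrix rows) of initial conditions.
#' @param settle_time Transient discarded before fingerprinting; the orbit is
#'   observed for an equally long window afterwards.
#' @param fingerprint_tol Rounding tolerance of the fingerprint (default
#'   1e-2).
#' @param dt Integration step.
#' @param classify Also label each attractor `fixed-point` / `periodic` /
#'   `aperiodic` (the latter two split by a short Lyapunov probe).
#' @return List with `attractors` (each: `fingerprint`, `basin_count`,
#'   `members`, `class`) and `escapes` (indices of unbounded orbits).
#' @export
enumerate_local_attractors <- function(system, init_grid, settle_time,
                                       fingerprint_tol = 1e-2, dt = 0.01,
                                       classify = TRUE) {
  stopifnot(settle_time > 0)
  if (is.matrix(init_grid)) {
    init_grid <- lapply(seq_len(nrow(init_grid)), function(i) init_grid[i, ])
  }
  fps <- list()
  escapes <- integer(0)
  reps <- list()
  for (i in seq_along(init_grid)) {
    res <- tryCatch(
      integrate_amplitudes(system, init_grid[[i]], t_end = 2 * settle_time,
                           dt = dt, save_every = max(1L, round(0.05 / dt))),
      error = function(e) NULL)
    if (is.null(res) || res$status != "ok") {
      escapes <- c(escapes, i)
      fps[[i]] <- NULL
      next
    }
    post <- res$X[res$times > settle_time, , drop = FALSE]
    fp <- round(c(colMeans(post), apply(post, 2, function(z) diff(range(z)))) /
                  fingerprint_tol) * fingerprint_tol
    fps[[i]] <- fp
    reps[[i]] <- post[nrow(post), ]
  }
  groups <- list()
  for (i in seq_along(init_grid)) {
    if (i %in% escapes) next
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (max(abs(fps[[i]] - groups[[gi]]$fingerprint)) <=
          2 * fingerprint_tol) {
        groups[[gi]]$members <- c(groups[[gi]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- list(fingerprint = fps[[i]],
                                            members = i, rep_state = reps[[i]])
    }
  }
  n <- system$n_vars
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    g$basin_count <- length(g$members)
    if (classify) {
      rng <- g$fingerprint[(n + 1L):(2L * n)]
      if (max(rng) < 10 * fingerprint_tol) {
        g$class <- "fixed-point"
      } else {
        ly <- tryCatch(
          estimate_largest_lyapunov(system, g$rep_state, horizon = 200,
                                    renorm_interval = 0.5, transient = 20),
          error = function(e) NULL)
        g$class <- if (!is.null(ly) && ly$lambda_max > 0.01) "aperiodic"
                   else "periodic"
      }
    }
    groups[[gi]] <- g
  }
  list(attractors = groups, escapes = escapes)
}
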