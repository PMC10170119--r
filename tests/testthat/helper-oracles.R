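# Independent oracles used by the test suite. These deliberately do not call
# the package implementations they are checking against.

# Two-orbit (trajectory-separation) largest-Lyapunov estimate with its own
# inline RK4; checks the Benettin tangent-method implementation.
two_orbit_lyapunov <- function(vf, X0, horizon = 600, dt = 0.01,
                               renorm = 0.5, d0 = 1e-8, transient = 60) {
  rk4 <- function(X) {
    k1 <- vf(X)
    k2 <- vf(X + 0.5 * dt * k1)
    k3 <- vf(X + 0.5 * dt * k2)
    k4 <- vf(X + dt * k3)
    X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n <- length(X0)
  X <- X0
  for (s in seq_len(round(transient / dt))) X <- rk4(X)
  Y <- X + d0 / sqrt(n)
  steps_per <- round(renorm / dt)
  nwin <- floor((horizon - transient) / renorm)
  logs <- numeric(nwin)
  for (w in seq_len(nwin)) {
    for (s in seq_len(steps_per)) {
      X <- rk4(X)
      Y <- rk4(Y)
    }
    d <- sqrt(sum((Y - X)^2))
    logs[w] <- log(d / d0)
    Y <- X + (Y - X) * d0 / d
  }
  rates <- logs / renorm
  blocks <- split(rates, cut(seq_along(rates), 20, labels = FALSE))
  bm <- vapply(blocks, mean, 0)
  list(lambda = mean(rates), se = sd(bm) / sqrt(length(bm)))
}

rossler_vf <- function(a = 0.2, b = 0.2, c = 5.7) {
  function(X) c(-X[2] - X[3], X[1] + a * X[2], b + X[3] * (X[1] - c))
}

# Dense direct screened-Poisson solve with an independently assembled
# stencil matrix (periodic x, Neumann/Dirichlet y).
dense_screened_solve <- function(source, d_w, b, grid,
                                 bc = c("neumann0", "neumann0")) {
  nx <- grid$nx; ny <- grid$ny
  n <- nx * ny
  A <- matrix(0, n, n)
  id <- function(i, j) (j - 1L) * ny + i     # column-major like the package
  for (j in seq_len(nx)) {
    jl <- if (j == 1) nx else j - 1
    jr <- if (j == nx) 1 else j + 1
    for (i in seq_len(ny)) {
      k <- id(i, j)
      if ((i == 1 && bc[1] == "dirichlet0") ||
          (i == ny && bc[2] == "dirichlet0")) {
        A[k, k] <- 1
        next
      }
      A[k, k] <- A[k, k] - 2 * d_w / grid$hx^2 - 2 * d_w / grid$hy^2 - b^2
      A[k, id(i, jl)] <- A[k, id(i, jl)] + d_w / grid$hx^2
      A[k, id(i, jr)] <- A[k, id(i, jr)] + d_w / grid$hx^2
      if (i == 1) {
        A[k, id(2, j)] <- A[k, id(2, j)] + 2 * d_w / grid$hy^2
      } else if (i == ny) {
        A[k, id(ny - 1, j)] <- A[k, id(ny - 1, j)] + 2 * d_w / grid$hy^2
      } else {
        A[k, id(i - 1, j)] <- A[k, id(i - 1, j)] + d_w / grid$hy^2
        A[k, id(i + 1, j)] <- A[k, id(i + 1, j)] + d_w / grid$hy^2
      }
    }
  }
  rhs <- as.vector(source)
  for (j in seq_len(nx)) {
    if (bc[1] == "dirichlet0") rhs[id(1, j)] <- 0
    if (bc[2] == "dirichlet0") rhs[id(ny, j)] <- 0
  }
  matrix(solve(A, rhs), ny, nx)
}

# Expected absorption time by forward propagation of the state distribution
# ("exhaustive path enumeration" truncated at probability mass 1 - tol).
propagate_absorption_mean <- function(kernel, target, start, tol = 1e-10) {
  n <- nrow(kernel)
  p <- numeric(n)
  p[start] <- 1
  if (start == target) return(0)
  mean_acc <- 0
  t <- 0
  repeat {
    t <- t + 1
    p <- as.numeric(p %*% kernel)
    newly <- p[target]
    mean_acc <- mean_acc + t * newly
    p[target] <- 0
    if (sum(p) < tol || t > 1e6) break
  }
  mean_acc
}

# Conway leading-number formula: expected first-occurrence *end* index of a
# binary word in an iid Bernoulli(1/2) stream is sum over self-overlap
# lengths i (prefix_i == suffix_i, including i = L) of 2^i. The expected
# 0-based *start* index is that minus the word length.
bernoulli_word_mean_start <- function(word) {
  L <- length(word)
  tot <- 0
  for (i in seq_len(L)) {
    if (identical(word[seq_len(i)], word[(L - i + 1):L])) tot <- tot + 2^i
  }
  tot - L
}

# reference config JSON used by the cli_io tests
write_test_config <- function(path, extra = NULL) {
  cfg <- list(experiment = "unit", seed = 7,
              grid = list(nx = 32, ny = 5, Lx = 6.283185307179586, Ly = 1),
              components = list(d = c(1), lambda = c(0.2)),
              integrate = list(dt = 1e-3, t_end = 0.01, save_every = 5))
  if (!is.null(extra)) cfg <- utils::modifyList(cfg, extra)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), path)
  path
}
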