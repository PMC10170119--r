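#' Absorbing Markov chains over gene-expression states
#'
#' The stochastic Turing machine of staged morphogenesis: a finite Markov
#' chain whose target state `s*` is absorbing ("the process stops when the
#' target pattern is reached"). Hitting times of the target are the
#' morphogenesis times tau; their dispersion statistics quantify how well
#' the process is canalized.
#'
#' @param kernel `n x n` row-stochastic transition matrix (rows sum to 1;
#'   row i holds the probabilities of moving from state i).
#' @param target Absorbing target state index (its row must be a point mass
#'   on itself; enforced).
#' @param environment Optional list of kernels indexed by an environment
#'   schedule `xi(t)`; see `xi_schedule`.
#' @param xi_schedule Optional integer vector: `xi_schedule[t]` names which
#'   kernel of `environment` drives step `t` (recycled); default uses
#'   `kernel` throughout.
#' @return Object of class `markov_chain_spec`.
#' @export
markov_chain_spec <- function(kernel, target, environment = NULL,
                              xi_schedule = NULL) {
  kernel <- as.matrix(kernel)
  n <- nrow(kernel)
  stopifnot(ncol(kernel) == n, target >= 1, target <= n)
  check_kernel <- function(K) {
    if (any(K < 0)) stop("negative transition probability")
    if (any(abs(rowSums(K) - 1) > 1e-12)) {
      stop("kernel rows must sum to 1 (tolerance 1e-12)")
    }
    K
  }
  kernel <- check_kernel(kernel)
  if (max(abs(kernel[target, ] - as.numeric(seq_len(n) == target))) > 1e-12) {
    stop("target row must be absorbing (point mass on itself)")
  }
  if (!is.null(environment)) {
    environment <- lapply(environment, function(K) {
      K <- check_kernel(as.matrix(K))
      stopifnot(nrow(K) == n)
      K
    })
  }
  # reachability of the target from every state (graph search on support)
  reach <- rep(FALSE, n)
  reach[target] <- TRUE
  repeat {
    new <- reach | apply(kernel[, reach, drop = FALSE] > 0, 1, any)
    if (all(new == reach)) break
    reach <- new
  }
  if (!all(reach)) {
    stop("target is not reachable from states: ",
         paste(which(!reach), collapse = ", "))
  }
  structure(list(n_states = n, kernel = kernel, target = as.integer(target),
                 environment = environment, xi_schedule = xi_schedule),
            class = "markov_chain_spec")
}

#' Random absorbing chain with flat-Dirichlet rows
#'
#' Draws each transient row from a flat Dirichlet distribution over all `n`
#' states (the canonical uninformative ensemble of "absorbing Markov chains
#' with constant transition probabilities") and makes the target row
#' absorbing.
#'
#' @param n Number of states.
#' @param target Absorbing state (default `n`).
#' @param seed Optional seed.
#' @return A [markov_chain_spec()].
#' @export
random_absorbing_chain <- function(n, target = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- matrix(stats::rexp(n * n), n, n)   # normalized exponentials ~ Dirichlet
  K <- K / rowSums(K)
  K[target, ] <- 0
  K[target, target] <- 1
  markov_chain_spec(K, target)
}

#' Simulate steps to absorption
#'
#' @param chain A [markov_chain_spec()].
#' @param start Start state (index) or `"uniform"` for a uniform random start.
#' @param seed Optional seed (identical seed gives an identical path).
#' @param max_steps Censoring threshold; default `1000 * n`.
#' @param n_rep Number of independent replicates.
#' @return Integer vector of hitting times tau (0 if the start is the
#'   target), with attribute `censored` (logical vector); censored entries
#'   are `NA`.
#' @export
simulate_absorption <- function(chain, start = "uniform", seed = NULL,
                                max_steps = 1000L * chain$n_states,
                                n_rep = 1L) {
  stopifnot(inherits(chain, "markov_chain_spec"), max_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- chain$n_states
  starts <- if (identical(start, "uniform")) {
    sample.int(n, n_rep, replace = TRUE)
  } else rep_len(as.integer(start), n_rep)
  if (is.null(chain$environment)) {
    cum <- t(apply(chain$kernel, 1, cumsum))
    taus <- markov_absorb_cpp(cum, chain$target - 1L, starts - 1L,
                              as.integer(max_steps))
  } else {
    sched <- chain$xi_schedule
    kernels <- chain$environment
    taus <- vapply(starts, function(s) {
      t <- 0L
      while (s != chain$target && t < max_steps) {
        K <- kernels[[sched[(t %% length(sched)) + 1L]]]
        s <- sample.int(n, 1L, prob = K[s, ])
        t <- t + 1L
      }
      if (s == chain$target) t else -1L
    }, 0L)
  }
  censored <- taus < 0L
  out <- ifelse(censored, NA_integer_, taus)
  attr(out, "censored") <- censored
  out
}

#' Exact expected absorption time and variance (fundamental matrix)
#'
#' Solves `(I - Q) t = 1` for the expected steps from each transient state
#' and the standard second-moment system for the variance, with `Q` the
#' transient-to-transient block of the kernel.
#'
#' @param chain A [markov_chain_spec()].
#' @param start Start state index, or a probability vector over all states,
#'   or `"uniform"`.
#' @return List with `mean` and `var` of tau for the given start.
#' @export
expected_absorption_exact <- function(chain, start = "uniform") {
  stopifnot(inherits(chain, "markov_chain_spec"))
  n <- chain$n_states
  tr <- setdiff(seq_len(n), chain$target)
  Q <- chain$kernel[tr, tr, drop = FALSE]
  IQ <- diag(length(tr)) - Q
  t1 <- tryCatch(solve(IQ, rep(1, length(tr))),
                 error = function(e) stop("target unreachable: singular I - Q"))
  # E[tau^2] = (2 N - I) t with N = (I - Q)^{-1}
  t2 <- solve(IQ, 2 * t1) - t1
  mean_all <- numeric(n)
  m2_all <- numeric(n)
  mean_all[tr] <- t1
  m2_all[tr] <- t2
  mu <- if (identical(start, "uniform")) {
    rep(1 / n, n)
  } else if (length(start) == 1L) {
    as.numeric(seq_len(n) == start)
  } else {
    stopifnot(length(start) == n, abs(sum(start) - 1) < 1e-8)
    as.numeric(start)
  }
  m1 <- sum(mu * mean_all)
  m2 <- sum(mu * m2_all)
  list(mean = m1, var = max(m2 - m1^2, 0))
}

#' Hitting-time dispersion statistics
#'
#' Computes both normalized dispersion statistics of the absorption time:
#' `sigma_paper = mean/sd` (the printed normalization of the source model)
#' and the coefficient of variation `cv = sd/mean`, with jackknife standard
#' errors. Censored samples (`NA`) are excluded and counted.
#'
#' @param samples Numeric vector of hitting times; `NA` marks censored runs.
#' @return Object of class `absorption_stats`: `n_samples`, `n_censored`,
#'   `mean`, `var`, `sigma_paper`, `cv`, `se_mean`, `se_sigma`, `se_cv`.
#'   When the variance is zero, `cv = 0` and `sigma_paper = Inf`.
#' @export
absorption_stats <- function(samples) {
  cens <- sum(is.na(samples))
  x <- samples[!is.na(samples)]
  if (length(x) < 2) stop("need at least 2 uncensored samples")
  m <- mean(x)
  v <- stats::var(x)
  jack <- function(f) {
    th <- vapply(seq_along(x), function(i) f(x[-i]), 0)
    sqrt((length(x) - 1) * mean((th - mean(th))^2))
  }
  if (v == 0) {
    return(structure(list(n_samples = length(x), n_censored = cens,
                          mean = m, var = 0, sigma_paper = Inf, cv = 0,
                          se_mean = 0, se_sigma = NA_real_, se_cv = 0),
                     class = "absorption_stats"))
  }
  structure(list(
    n_samples = length(x), n_censored = cens, mean = m, var = v,
    sigma_paper = m / sqrt(v), cv = sqrt(v) / m,
    se_mean = stats::sd(x) / sqrt(length(x)),
    se_sigma = jack(function(z) mean(z) / stats::sd(z)),
    se_cv = jack(function(z) stats::sd(z) / mean(z))),
    class = "absorption_stats")
}

#' @exportS3Method base::print
print.absorption_stats <- function(x, ...) {
  cat(sprintf(
    "<absorption_stats> n=%d (censored %d) Etau=%.3f sigma=%.3f cv=%.3f\n",
    x$n_samples, x$n_censored, x$mean, x$sigma_paper, x$cv))
  invisible(x)
}

#' Staged target-string plan
#'
#' Splits a target string over `{0,1}` into `k` consecutive substrings (the
#' staged decomposition of morphogenesis); stages have length `m/k`, with a
#' shorter last stage when `k` does not divide `m` (recorded).
#'
#' @param target_string Integer (0/1) vector or character string like
#'   `"0110"`.
#' @param k Number of stages.
#' @return Object of class `stage_plan` with `target`, `k`, `stage_lengths`,
#'   `substrings`.
#' @export
stage_plan <- function(target_string, k = 1L) {
  s <- parse_bits(target_string)
  m <- length(s)
  stopifnot(k >= 1, k <= m)
  base <- m %/% k
  lens <- rep(base, k)
  extra <- m - base * k
  if (extra > 0) lens[k] <- lens[k] + extra   # last stage absorbs remainder
  idx <- cumsum(c(0L, lens))
  subs <- lapply(seq_len(k), function(j) s[(idx[j] + 1L):idx[j + 1L]])
  stopifnot(identical(unlist(subs), s))
  structure(list(target = s, k = as.integer(k), stage_lengths = lens,
                 substrings = subs, uneven = extra > 0),
            class = "stage_plan")
}

parse_bits <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.integer(strsplit(x, "")[[1]])
  }
  x <- as.integer(x)
  stopifnot(all(x %in% c(0L, 1L)))
  x
}

#' Random search of a target string on the Boolean hypercube
#'
#' Single-stage: a nearest-neighbour random walk on the `m`-cube (one
#' uniformly chosen coordinate flips per step) that stops at the target
#' vertex. Staged: the walk runs on the subcube of each stage in turn; once a
#' stage's substring is matched those coordinates are frozen and the next
#' stage starts. The staged decomposition gives an exponential acceleration
#' (`O(k 2^{m/k})` versus the unstaged walk).
#'
#' @param m Hypercube dimension (1..24).
#' @param plan A [stage_plan()]; or `NULL` for a single stage with a random
#'   target.
#' @param start Start vertex (0/1 vector), or `NULL` for uniform random.
#' @param seed Optional seed.
#' @param max_steps Censoring threshold on total steps (default `1000 * 2^m`,
#'   capped at 1e8).
#' @return List with `tau` (total steps; `NA` if censored), `stage_taus`,
#'   `censored`, `target`, `start`.
#' @export
hypercube_search <- function(m, plan = NULL, start = NULL, seed = NULL,
                             max_steps = NULL) {
  stopifnot(m >= 1, m <= 24)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plan)) {
    plan <- stage_plan(stats::rbinom(m, 1L, 0.5), k = 1L)
  }
  stopifnot(inherits(plan, "stage_plan"), length(plan$target) == m)
  if (is.null(start)) start <- stats::rbinom(m, 1L, 0.5)
  start <- parse_bits(start)
  stopifnot(length(start) == m)
  if (is.null(max_steps)) max_steps <- min(1000 * 2^m, 1e8)
  res <- hypercube_walk_cpp(plan$target, start, plan$stage_lengths,
                            as.integer(max_steps))
  list(tau = if (res$censored) NA_integer_ else res$tau,
       stage_taus = res$stage_tau, censored = res$censored,
       target = plan$target, start = start)
}

#' Explicit kernel of the hypercube walk (oracle support)
#'
#' The `2^m`-state chain of the single-stage hypercube walk with an absorbing
#' target, for exact fundamental-matrix hitting times at small `m`.
#'
#' @param m Dimension (<= 12 kept small on purpose).
#' @param target Target vertex (0/1 vector); default all ones.
#' @return A [markov_chain_spec()].
#' @export
hypercube_chain <- function(m, target = rep(1L, m)) {
  stopifnot(m >= 1, m <= 12)
  target <- parse_bits(target)
  n <- 2^m
  K <- matrix(0, n, n)
  tidx <- sum(target * 2^(seq_len(m) - 1L)) + 1L
  for (s in seq_len(n)) {
    if (s == tidx) {
      K[s, s] <- 1
      next
    }
    for (j in seq_len(m)) {
      K[s, bitwXor(s - 1L, 2^(j - 1L)) + 1L] <- 1 / m
    }
  }
  markov_chain_spec(K, tidx)
}

#' Least-squares scaling of mean absorption time with state count
#'
#' Ordinary least squares of mean tau on the number of states `n`; the
#' ensemble-average hitting time of random constant-kernel absorbing chains
#' grows linearly in `n`.
#'
#' @param state_counts Numeric vector of `n` values (>= 4 distinct).
#' @param stats List of [absorption_stats()] (or numeric mean taus), one per
#'   state count.
#' @return List with `slope`, `intercept`, `r_squared`, and the `lm` fit.
#' @export
fit_tau_scaling <- function(state_counts, stats) {
  stopifnot(length(state_counts) == length(stats))
  if (length(unique(state_counts)) < 4) {
    stop("need at least 4 distinct state counts")
  }
  y <- vapply(stats, function(s) {
    if (inherits(s, "absorption_stats")) s$mean else as.numeric(s)
  }, 0)
  fit <- stats::lm(y ~ state_counts)
  ss <- suppressWarnings(summary(fit))  # flat/perfect fits are legitimate here
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = ss$r.squared, fit = fit)
}
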