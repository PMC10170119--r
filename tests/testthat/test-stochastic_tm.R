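geometric_chain <- function(p) {
  # state 1 transient, state 2 absorbing; per-step absorption probability p
  markov_chain_spec(matrix(c(1 - p, 0, p, 1), 2, 2), target = 2)
}

test_that("kernel validation enforces the chain invariants", {
  expect_error(markov_chain_spec(matrix(c(0.5, 0, 0.6, 1), 2, 2), 2),
               "sum to 1")
  expect_error(markov_chain_spec(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2), 2),
               "absorbing")
  K <- diag(2)                       # target unreachable from state 1
  expect_error(markov_chain_spec(K, 2), "not reachable")
})

test_that("exact absorption moments match the geometric closed form", {
  ch <- geometric_chain(0.25)
  ex <- expected_absorption_exact(ch, start = 1)
  expect_equal(ex$mean, 4, tolerance = 1e-12)
  expect_equal(ex$var, (1 - 0.25) / 0.25^2, tolerance = 1e-10)
  at_target <- expected_absorption_exact(ch, start = 2)
  expect_equal(at_target$mean, 0)
  expect_equal(at_target$var, 0)
})

test_that("exact moments match forward path enumeration on a random chain", {
  ch <- random_absorbing_chain(6, seed = 31)
  for (s in c(1, 3, 5)) {
    ex <- expected_absorption_exact(ch, start = s)
    pe <- propagate_absorption_mean(ch$kernel, ch$target, s)
    expect_equal(ex$mean, pe, tolerance = 1e-6)
  }
})

test_that("Monte Carlo absorption agrees with the fundamental matrix", {
  ch <- geometric_chain(0.25)
  taus <- simulate_absorption(ch, start = 1, seed = 2, n_rep = 10000)
  expect_false(any(is.na(taus)))
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 4), 3 * se)
  # starting at the target absorbs immediately
  expect_equal(unname(simulate_absorption(ch, start = 2, n_rep = 3)[1:3]),
               rep(0L, 3))
  # property: 50 random chains within 4 SE of the exact value
  for (i in 1:50) {
    n <- sample(4:32, 1)
    chn <- random_absorbing_chain(n, seed = 1000 + i)
    ex <- expected_absorption_exact(chn, start = 1)
    tt <- simulate_absorption(chn, start = 1, seed = 2000 + i, n_rep = 400)
    se <- max(sd(tt) / sqrt(length(tt)), 1e-9)
    expect_lt(abs(mean(tt) - ex$mean), 4 * se + 0.05 * ex$mean)
  }
})

test_that("absorption statistics report both dispersion normalizations", {
  st <- absorption_stats(rep(5, 10))
  expect_equal(st$cv, 0)
  expect_true(is.infinite(st$sigma_paper))
  set.seed(9)
  x <- rgeom(10000, 0.1) + 1
  st2 <- absorption_stats(x)
  expect_lt(abs(st2$cv - sqrt(1 - 0.1)), 3 * st2$se_cv)
  expect_equal(st2$sigma_paper * st2$cv, 1, tolerance = 1e-12)
  expect_error(absorption_stats(c(NA, NA, 3)), "at least 2")
  st3 <- absorption_stats(c(1, 2, NA, 4))
  expect_equal(st3$n_censored, 1)
})

test_that("hypercube search obeys the trivial and oracle cases", {
  # m = 1 from the wrong vertex always takes one step
  for (s in 1:5) {
    r <- hypercube_search(1, stage_plan(1L), start = 0L, seed = s)
    expect_equal(r$tau, 1L)
  }
  # m = 3 empirical mean within 3 SE of the exact walk-chain value
  plan <- stage_plan(c(1L, 0L, 1L))
  ch <- hypercube_chain(3, plan$target)
  ex <- expected_absorption_exact(ch, start = "uniform")
  set.seed(77)
  taus <- vapply(1:4000, function(i) hypercube_search(3, plan)$tau, 0L)
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - ex$mean), 3 * se)
})

test_that("staged decomposition accelerates the search and adds stage times", {
  set.seed(123)
  m <- 9
  total <- replicate(300, {
    plan <- stage_plan(rbinom(m, 1, 0.5), k = 3)
    res <- hypercube_search(m, plan)
    expect_identical(res$tau, as.integer(sum(res$stage_taus)))
    res$tau
  })
  single <- replicate(300, {
    plan <- stage_plan(rbinom(m, 1, 0.5), k = 1)
    hypercube_search(m, plan)$tau
  })
  expect_gt(mean(single) / mean(total), 2)
})

test_that("cv of staged totals scales as 1/sqrt(k)", {
  ch <- geometric_chain(1 / 16)
  draw_total <- function(k, nrep, seed) {
    taus <- matrix(simulate_absorption(ch, start = 1, seed = seed,
                                       n_rep = nrep * k), nrep, k)
    rowSums(taus)
  }
  cv1 <- absorption_stats(draw_total(1, 4000, 5))$cv
  for (k in c(4, 9)) {
    cvk <- absorption_stats(draw_total(k, 4000, 5 + k))$cv
    expect_lt(abs(cvk / (cv1 / sqrt(k)) - 1), 0.2)
  }
})

test_that("tau scaling fit recovers exact linear input", {
  ns <- c(8, 16, 32, 64)
  fit <- fit_tau_scaling(ns, as.list(3 * ns + 2))
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- fit_tau_scaling(ns, as.list(rep(5, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_tau_scaling(c(8, 8, 8, 8), as.list(1:4)), "distinct")
})

test_that("simulation paths are reproducible and censoring is flagged", {
  ch <- random_absorbing_chain(12, seed = 4)
  a <- simulate_absorption(ch, seed = 9, n_rep = 50)
  b <- simulate_absorption(ch, seed = 9, n_rep = 50)
  expect_identical(a, b)
  tight <- simulate_absorption(ch, start = 1, seed = 10, max_steps = 1,
                               n_rep = 200)
  expect_true(any(attr(tight, "censored")))
  expect_true(all(is.na(tight[attr(tight, "censored")])))
})

test_that("environment-dependent kernels follow the schedule", {
  # kernel A never absorbs, kernel B absorbs surely; schedule A,B,A,B...
  KA <- matrix(c(1, 0, 0, 1), 2, 2)
  KB <- matrix(c(0, 0, 1, 1), 2, 2)
  ch <- markov_chain_spec(KB, target = 2, environment = list(KA, KB),
                          xi_schedule = c(1L, 2L))
  taus <- simulate_absorption(ch, start = 1, seed = 1, n_rep = 20)
  expect_true(all(taus == 2))   # survives the A step, absorbed by the B step
})
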