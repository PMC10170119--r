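test_that("the four-type alphabet reproduces the worked encoding", {
  a <- cell_alphabet()
  pat <- c("gr", "wr", "wr", "wr", "wb", "gb", "gr", "wb", "wb")
  expect_equal(encode_pattern(pat, a), "000101011110001111")
  expect_equal(decode_pattern("000101011110001111", a), pat)
  expect_equal(encode_pattern(character(0), a), "")
  expect_equal(decode_pattern("", a), character(0))
  expect_error(encode_pattern("xx", a), "unknown")
  expect_error(decode_pattern("000", a), "multiple")
})

test_that("encode/decode roundtrip holds on random patterns", {
  a <- cell_alphabet()
  set.seed(14)
  for (i in 1:100) {
    pat <- sample(a$symbols, 50, replace = TRUE)
    expect_identical(decode_pattern(encode_pattern(pat, a), a), pat)
  }
})

test_that("classification follows the half-open convention", {
  ff <- partition_spec(c(0, 0.5, 1), c("r", "b"))
  expect_equal(as.character(classify_state(0.3, ff)), "r")
  expect_equal(as.character(classify_state(0.5, ff)), "b")  # tie goes up
  expect_equal(as.character(classify_state(1, ff)), "b")
  p3 <- partition_spec(c(0, 1/3, 2/3, 1), c("a", "b", "c"))
  expect_equal(as.character(classify_state(0.9, p3)), "c")
  expect_error(classify_state(1.5, ff, clip = FALSE), "outside")
  cl <- classify_state(1.5, ff)
  expect_true(attr(cl, "clipped"))
})

test_that("every in-box value maps to exactly one region", {
  set.seed(20)
  breaks <- sort(c(0, runif(4), 1))
  p <- partition_spec(breaks, letters[1:5])
  vals <- c(runif(1e4), breaks)          # interior points and all boundaries
  labs <- classify_state(vals, p)
  expect_true(all(labs %in% letters[1:5]))
  expect_length(labs, length(vals))
  # manual interval check on a subsample
  for (v in sample(vals, 50)) {
    k <- max(which(breaks <= v))
    k <- min(k, 5)
    expect_equal(as.character(classify_state(v, p)), letters[k])
  }
})

test_that("morphogen field obeys closed forms and the screening length", {
  g <- spatial_grid(128, 9, Lx = 8, Ly = 1)
  u <- matrix(1.3, g$ny, g$nx)
  w0 <- morphogen_field_from_u(u, u, d_w = 1, b = 1, grid = g)
  expect_lt(max(abs(w0)), 1e-10)
  wS <- morphogen_field_from_u(u + 0.7, u, d_w = 1, b = 1, grid = g)
  expect_lt(max(abs(wS + 0.7)), 1e-8)
  # a narrow source column decays by e over one screening length 1/beta
  b <- 2; d_w <- 1
  src <- matrix(rep(exp(-(g$x - 4)^2 / (2 * 0.02^2)), each = g$ny),
                g$ny, g$nx)
  w <- morphogen_field_from_u(src, 0, d_w = d_w, b = b, grid = g)
  expect_equal(attr(w, "decay_length"), 1 / b)
  prof <- abs(colMeans(w))
  x0 <- which.max(prof)
  x1 <- which.min(abs(g$x - (g$x[x0] + 1 / b)))
  # 1-D Green's function of (d_w d^2/dx^2 - b^2) is ~ exp(-beta |x|)
  expect_lt(abs(prof[x1] / prof[x0] - exp(-1)), 0.1 * exp(-1) + 0.02)
})

test_that("extract_cdp reads constant and monotone fields correctly", {
  ff <- partition_spec(c(0, 0.5, 1), c("r", "b"))
  xs <- seq(0, 1, length.out = 101)
  op <- morphogenetic_operator(ff, positions = seq(0.1, 0.9, by = 0.2),
                               delta_T = 1)
  const_traj <- list(times = 0:5,
                     profiles = matrix(0.4, 6, 101), x = xs)
  cdp <- extract_cdp(const_traj, op)
  expect_true(all(cdp$symbols == "r"))
  expect_true(all(apply(cdp$symbols, 2, function(cc) all(cc == cc[1]))))
  # monotone gradient crossing 1/2 once gives the French-flag form r...rb...b
  grad_traj <- list(times = 0:3,
                    profiles = matrix(rep(xs, each = 4), 4, 101), x = xs)
  cdp2 <- extract_cdp(grad_traj, op)
  for (k in seq_len(nrow(cdp2$symbols))) {
    s <- paste(cdp2$symbols[k, ], collapse = "")
    expect_match(s, "^r+b+$")
  }
  expect_error(extract_cdp(grad_traj, morphogenetic_operator(
    ff, positions = 0.5, delta_T = 10), n_times = 3), "beyond")
})

test_that("extract_cdp equals pointwise classification of window averages", {
  ff <- partition_spec(c(-3, 0.2, 3), c("lo", "hi"))
  xs <- seq(0, 2, length.out = 81)
  set.seed(33)
  times <- seq(0, 4, by = 0.5)
  profs <- t(vapply(times, function(t) {
    sin(2 * pi * xs + t) + 0.3 * rnorm(81)
  }, numeric(81)))
  op <- morphogenetic_operator(ff, positions = seq(0.2, 1.8, by = 0.4),
                               delta_T = 0.7, t_start = 0.7)
  cdp <- extract_cdp(list(times = times, profiles = profs, x = xs), op)
  for (probe in 1:200) {
    k <- sample(nrow(cdp$symbols), 1)
    j <- sample(ncol(cdp$symbols), 1)
    t_k <- op$t_start + (k - 1) * op$delta_T
    i <- findInterval(t_k, times)
    w <- (t_k - times[i]) / 0.5
    prof <- if (i >= length(times)) profs[i, ] else {
      (1 - w) * profs[i, ] + w * profs[i + 1, ]
    }
    win <- abs(xs - op$positions[j]) <= op$window_halfwidth + 1e-12
    expect_equal(cdp$symbols[k, j],
                 as.character(classify_state(mean(prof[win]), ff)))
  }
})

test_that("tent-map emission hits short strings at the Bernoulli rate", {
  ff <- partition_spec(c(0, 0.5, 1), c("r", "b"))
  # immediate hit when the first window already matches
  dyn0 <- function(n) rep(0.25, n)
  r0 <- run_until_string(dyn0, ff, "r", max_steps = 10)
  expect_equal(r0$hitting_time, 0L)
  # mean start index of "rb" matches the word-occurrence closed form
  hits <- vapply(1:800, function(s) {
    run_until_string(make_tent_dynamics(seed = s), ff, "rb",
                     max_steps = 1e4)$hitting_time
  }, 0L)
  expect_false(any(is.na(hits)))
  oracle <- bernoulli_word_mean_start(c("r", "b"))
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(mean(hits) - oracle), 3 * se)
  # symbol frequencies are unbiased
  dyn <- make_tent_dynamics(seed = 999)
  sym <- classify_state(dyn(20000), ff)
  expect_lt(abs(mean(sym == "r") - 0.5), 3 * 0.5 / sqrt(20000))
})

test_that("every length-6 binary target is reachable within budget", {
  ff <- partition_spec(c(0, 0.5, 1), c("r", "b"))
  set.seed(8)
  for (i in 1:12) {
    target <- sample(c("r", "b"), 6, replace = TRUE)
    res <- run_until_string(make_tent_dynamics(seed = 4000 + i), ff, target,
                            max_steps = 1e5)
    expect_false(res$censored)
    L <- length(res$emitted)
    expect_identical(res$emitted[(L - 5):L], target)
  }
  # censoring is graceful
  rc <- run_until_string(function(n) rep(0.25, n), ff, "b", max_steps = 50)
  expect_true(rc$censored)
  expect_true(is.na(rc$hitting_time))
})
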