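#' Cell-type alphabet with fixed-width binary codes
#'
#' Binary-tree encoding of differentiated cell types. The default four-type
#' alphabet encodes `gr, wr, gb, wb` as `00, 01, 10, 11`: the first bit
#' carries the r/b feature acquired at the first differentiation stage, the
#' second the g/w feature of the second stage.
#'
#' @param symbols Ordered character vector of cell-type names.
#' @param codes Character vector of equal-length binary codes (defaults to
#'   the binary expansion of the symbol index).
#' @return Object of class `cell_alphabet`.
#' @export
cell_alphabet <- function(symbols = c("gr", "wr", "gb", "wb"),
                          codes = NULL) {
  stopifnot(length(symbols) >= 1, !anyDuplicated(symbols))
  if (is.null(codes)) {
    bits <- max(1L, ceiling(log2(length(symbols))))
    codes <- vapply(seq_along(symbols) - 1L, function(i) {
      paste(rev(as.integer(intToBits(i))[seq_len(bits)]), collapse = "")
    }, "")
  }
  stopifnot(length(codes) == length(symbols), !anyDuplicated(codes),
            length(unique(nchar(codes))) == 1L,
            all(grepl("^[01]+$", codes)))
  structure(list(symbols = symbols, codes = codes,
                 bits_per_cell = nchar(codes[1])),
            class = "cell_alphabet")
}

#' Encode / decode cell patterns as binary strings
#'
#' `encode_pattern` concatenates the fixed-width code of each symbol;
#' `decode_pattern` is its exact inverse.
#'
#' @param symbols Character vector of cell types (encode).
#' @param bits Binary string (decode); its length must be a multiple of
#'   `bits_per_cell`.
#' @param alphabet A [cell_alphabet()].
#' @return `encode_pattern`: a single binary string; `decode_pattern`: a
#'   character vector of symbols.
#' @examples
#' a <- cell_alphabet()
#' encode_pattern(c("gr", "wr", "wb"), a)  # "000111"
#' @export
encode_pattern <- function(symbols, alphabet = cell_alphabet()) {
  if (length(symbols) == 0) return("")
  idx <- match(symbols, alphabet$symbols)
  if (anyNA(idx)) {
    stop("unknown symbols: ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  paste(alphabet$codes[idx], collapse = "")
}

#' @rdname encode_pattern
#' @export
decode_pattern <- function(bits, alphabet = cell_alphabet()) {
  if (nchar(bits) == 0) return(character(0))
  b <- alphabet$bits_per_cell
  if (nchar(bits) %% b != 0) {
    stop("binary string length is not a multiple of bits_per_cell")
  }
  chunks <- substring(bits, seq(1, nchar(bits), by = b),
                      seq(b, nchar(bits), by = b))
  idx <- match(chunks, alphabet$codes)
  if (anyNA(idx)) stop("invalid code chunk: ", chunks[which(is.na(idx))[1]])
  alphabet$symbols[idx]
}

#' Partition of morphogen-value space into labeled regions
#'
#' Scalar morphogen values are split into half-open intervals
#' `[breaks[i], breaks[i+1])`, the final interval closed at the top; a value
#' exactly at a threshold belongs to the upper region (the declared
#' tie-break closing the measure-zero gap left by open-interval
#' definitions).
#'
#' @param breaks Increasing numeric vector of interval endpoints (length
#'   `#regions + 1`); `breaks[1]`/`breaks[end]` bound the overall box U.
#' @param labels One label per region.
#' @return Object of class `partition_spec`.
#' @examples
#' french_flag <- partition_spec(c(0, 0.5, 1), c("r", "b"))
#' @export
partition_spec <- function(breaks, labels) {
  stopifnot(is.numeric(breaks), !is.unsorted(breaks, strictly = TRUE),
            length(labels) == length(breaks) - 1L)
  structure(list(breaks = as.numeric(breaks), labels = as.character(labels),
                 bounds = range(breaks)),
            class = "partition_spec")
}

#' Classify a morphogen value into its partition region
#'
#' @param value Numeric vector of morphogen values.
#' @param partition A [partition_spec()].
#' @param clip If `TRUE` (default), values outside the overall box are
#'   clipped to it and flagged in the `clipped` attribute; otherwise they
#'   raise an error.
#' @return Character vector of region labels (attribute `clipped`).
#' @export
classify_state <- function(value, partition, clip = TRUE) {
  stopifnot(inherits(partition, "partition_spec"))
  lo <- partition$bounds[1]; hi <- partition$bounds[2]
  out_of_box <- value < lo | value > hi
  if (any(out_of_box) && !clip) {
    stop("value outside the morphogen box and clipping disabled")
  }
  v <- pmin(pmax(value, lo), hi)
  # half-open [lo, hi): a value at an internal break goes to the upper
  # region; the top endpoint belongs to the last region
  idx <- findInterval(v, partition$breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), length(partition$labels))
  out <- partition$labels[idx]
  attr(out, "clipped") <- out_of_box
  out
}

#' Morphogen field sourced by the slow reagent
#'
#' Solves the screened Poisson equation `d_w Lap(w) - b^2 w = u - u0` for
#' the downstream morphogen `w`; `beta = b / sqrt(d_w)` sets the inverse
#' decay length of `w` around its source.
#'
#' @param u_field `ny x nx` concentration field of the source reagent.
#' @param u0_field Offset field (same shape), scalar, or `NULL` for the
#'   spatial mean of `u` (which keeps the `b = 0` problem solvable).
#' @param d_w,b Morphogen diffusion and decay parameters.
#' @param grid A [spatial_grid()].
#' @param bc y-boundary tags (periodic in x as always).
#' @return The field `w` with attributes `decay_length` (`1/beta`, `Inf`
#'   for `b = 0`) and `residual`.
#' @export
morphogen_field_from_u <- function(u_field, u0_field = NULL, d_w, b, grid,
                                   bc = c("neumann0", "neumann0")) {
  if (is.null(u0_field)) u0_field <- mean(u_field)
  src <- u_field - u0_field
  w <- solve_screened_poisson(src, d_w, b, grid, bc)
  attr(w, "decay_length") <- if (b > 0) sqrt(d_w) / b else Inf
  w
}

#' Morphogenetic operator: fields to symbol strings
#'
#' Holds the sampling layout of the operator `M` that converts a 1-D
#' morphogen profile into a string: the cell positions `xbar_j`, the sample
#' times `t_k = k * delta_T`, the per-cell averaging window, and the
#' partition of morphogen space.
#'
#' @param partition A [partition_spec()].
#' @param positions Strictly increasing cell positions along x.
#' @param delta_T Sampling interval (> 0).
#' @param window_halfwidth Half-width of the per-cell averaging window;
#'   default half the minimum position spacing.
#' @param t_start Time of the first sample (default `delta_T`).
#' @return Object of class `morphogenetic_operator`.
#' @export
morphogenetic_operator <- function(partition, positions, delta_T,
                                   window_halfwidth = NULL,
                                   t_start = delta_T) {
  stopifnot(inherits(partition, "partition_spec"), delta_T > 0,
            !is.unsorted(positions, strictly = TRUE))
  if (is.null(window_halfwidth)) {
    window_halfwidth <- if (length(positions) > 1L) {
      min(diff(positions)) / 2
    } else Inf
  }
  structure(list(partition = partition, positions = positions,
                 delta_T = delta_T, window_halfwidth = window_halfwidth,
                 t_start = t_start),
            class = "morphogenetic_operator")
}

#' Extract a cellular developmental program from a trajectory
#'
#' Applies the morphogenetic operator to a stored trajectory: for each cell
#' position and sample time, the morphogen is averaged over the cell window
#' (time interpolation between the bracketing snapshots, linear), classified
#' by the partition, and written into the positions x times symbol matrix
#' `a(j, t_k)` -- the cellular developmental program.
#'
#' @param trajectory Either a `trajectory_record` from [simulate_rd()]
#'   (fields are y-averaged before sampling) or a list with `times` and
#'   `profiles` (matrix, one row per time, columns = x-grid values) plus `x`
#'   (grid coordinates).
#' @param op A [morphogenetic_operator()].
#' @param alphabet Optional [cell_alphabet()] consistency check: operator
#'   labels must be alphabet symbols.
#' @param n_times Number of sample times `K` (default: as many as the
#'   trajectory spans).
#' @param component Which field component to read (default 1).
#' @return Object of class `cdp_record`: `symbols` is a `K x N_c` character
#'   matrix (rows = times, columns = positions), plus `times`, `positions`.
#' @export
extract_cdp <- function(trajectory, op, alphabet = NULL, n_times = NULL,
                        component = 1L) {
  stopifnot(inherits(op, "morphogenetic_operator"))
  if (inherits(trajectory, "trajectory_record")) {
    g <- NULL
    xs <- NULL
    profs <- t(vapply(trajectory$states, function(st) {
      val <- st$values[[component]]
      colMeans(val)
    }, numeric(ncol(trajectory$states[[1]]$values[[component]]))))
    times <- trajectory$times
    # grid coordinates are not stored in the record; reconstruct from the
    # snapshot width assuming the operator positions share its units
    xs <- attr(trajectory, "x")
    if (is.null(xs)) {
      stop("pass a list(times, profiles, x) or attach attr(trajectory, 'x')")
    }
  } else {
    times <- trajectory$times
    profs <- trajectory$profiles
    xs <- trajectory$x
  }
  stopifnot(nrow(profs) == length(times), length(xs) == ncol(profs))
  if (is.null(n_times)) {
    n_times <- max(1L, floor((max(times) - op$t_start) / op$delta_T) + 1L)
  }
  t_k <- op$t_start + (seq_len(n_times) - 1L) * op$delta_T
  missing <- t_k[t_k > max(times) + 1e-9 | t_k < min(times) - 1e-9]
  if (length(missing) > 0) {
    stop("sample times beyond trajectory span: ",
         paste(signif(missing, 6), collapse = ", "))
  }
  wins <- lapply(op$positions, function(p) {
    which(abs(xs - p) <= op$window_halfwidth + 1e-12)
  })
  if (any(vapply(wins, length, 0L) == 0)) {
    stop("a cell window contains no grid nodes")
  }
  sym <- matrix("", n_times, length(op$positions))
  for (k in seq_len(n_times)) {
    prof <- interp_profile(times, profs, t_k[k])
    vals <- vapply(wins, function(w) mean(prof[w]), 0)
    sym[k, ] <- as.character(classify_state(vals, op$partition))
  }
  if (!is.null(alphabet) && !all(sym %in% alphabet$symbols)) {
    stop("operator labels outside the alphabet")
  }
  structure(list(symbols = sym, times = t_k, positions = op$positions),
            class = "cdp_record")
}

# linear time interpolation between bracketing snapshots
interp_profile <- function(times, profs, t) {
  i <- findInterval(t, times, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(times))
  if (i == length(times) || abs(times[i] - t) < 1e-12) return(profs[i, ])
  w <- (t - times[i]) / (times[i + 1] - times[i])
  (1 - w) * profs[i, ] + w * profs[i + 1, ]
}

#' @exportS3Method base::print
print.cdp_record <- function(x, ...) {
  cat(sprintf("<cdp_record> %d times x %d positions\n", nrow(x$symbols),
              ncol(x$symbols)))
  invisible(x)
}

#' Iterated-map and ODE symbol sources
#'
#' `make_tent_dynamics` iterates the tent map `x -> 2 min(x, 1 - x)` with a
#' uniform jitter of width `1e-12` per step: exact floating-point iterates
#' collapse onto dyadic rationals within ~50 steps, and the jitter (far
#' below any partition resolution) restores the map's ergodic symbol
#' statistics, which for the dyadic partition are exactly Bernoulli(1/2).
#' `make_rossler_dynamics` samples one coordinate of the Roessler flow every
#' `delta_T` time units (a flow-based chaotic source); its long-run
#' median is a natural two-symbol threshold.
#'
#' @param seed Seed for the initial condition (and jitter stream).
#' @param coord Roessler coordinate to emit (default 1).
#' @param delta_T Flow time between samples.
#' @param dt Integration step of the flow sampler.
#' @return A function `f(n)` returning the next `n` values of the dynamics
#'   (stateful; successive calls continue the trajectory).
#' @export
make_tent_dynamics <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(1)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      x <<- 2 * min(x, 1 - x) + (stats::runif(1) - 0.5) * 1e-12
      x <<- min(max(x, 2^-40), 1 - 2^-40)
      out[i] <- x
    }
    out
  }
}

#' @rdname make_tent_dynamics
#' @export
make_rossler_dynamics <- function(seed = NULL, coord = 1L, delta_T = 1,
                                  dt = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  sys <- amplitude_system_rossler()
  X <- c(1, 1, 1) + stats::rnorm(3, sd = 0.1)
  # discard a transient so emission starts on the attractor
  tr <- integrate_amplitudes(sys, X, t_end = 50, dt = dt,
                             save_every = 1000L)
  X <- tr$X[nrow(tr$X), ]
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      tr <- integrate_amplitudes(sys, X, t_end = delta_T, dt = dt,
                                 save_every = 10000L)
      X <<- tr$X[nrow(tr$X), ]
      out[i] <- X[coord]
    }
    out
  }
}

#' Run a symbol-emitting dynamic until a target string appears
#'
#' Reads the dynamics every sampling step, classifies each value through the
#' partition, and slides a window of the target's length over the emitted
#' symbol sequence. The hitting time is the first start index (0-based, in
#' sampling steps) at which the window equals the target -- the stop signal
#' of the stochastic Turing machine. Ergodic chaotic sources emit any
#' prescribed string eventually; finite budgets censor gracefully.
#'
#' @param dynamics A sampler function `f(n)` (see [make_tent_dynamics()]),
#'   returning successive morphogen values.
#' @param partition A [partition_spec()].
#' @param target Character vector (or single string split into characters)
#'   of region labels.
#' @param max_steps Emission budget.
#' @param seed Optional seed applied before sampling starts.
#' @param chunk Internal batch size for the sampler.
#' @return List with `hitting_time` (`NA` if censored), `censored`,
#'   `emitted` (symbols up to and including the matched window).
#' @export
run_until_string <- function(dynamics, partition, target, max_steps = 1e6,
                             seed = NULL, chunk = 1024L) {
  stopifnot(is.function(dynamics), inherits(partition, "partition_spec"))
  if (length(target) == 1L && nchar(target[1]) > 1L) {
    target <- strsplit(target, "")[[1]]
  }
  if (!all(target %in% partition$labels)) {
    stop("target symbols outside the partition labels")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- length(target)
  emitted <- character(0)
  emitted_n <- 0L
  while (emitted_n < max_steps + L) {
    vals <- dynamics(min(chunk, max_steps + L - emitted_n))
    sym <- as.character(classify_state(vals, partition))
    emitted <- c(emitted, sym)
    emitted_n <- length(emitted)
    from <- max(1L, emitted_n - length(vals) - L + 1L)
    hit <- match_window(emitted, target, from)
    if (!is.na(hit)) {
      return(list(hitting_time = hit - 1L, censored = FALSE,
                  emitted = emitted[seq_len(hit + L - 1L)]))
    }
  }
  list(hitting_time = NA_integer_, censored = TRUE, emitted = emitted)
}

# first start index >= from at which target matches (NA if none)
match_window <- function(sym, target, from = 1L) {
  L <- length(target)
  n <- length(sym)
  if (n < L) return(NA_integer_)
  cand <- from:(n - L + 1L)
  for (off in seq_len(L)) {
    cand <- cand[sym[cand + off - 1L] == target[off]]
    if (length(cand) == 0L) return(NA_integer_)
  }
  cand[1]
}

#' Render a developmental program as a raster image
#'
#' Draws the positions x times symbol matrix as colored tiles (rows of cells
#' appearing bottom-to-top in time), optionally to a PNG file.
#'
#' @param x A `cdp_record`.
#' @param file Optional PNG path; `NULL` draws on the active device.
#' @param palette Named colors per symbol (defaults to a small built-in map).
#' @param ... Unused.
#' @exportS3Method base::plot
plot.cdp_record <- function(x, file = NULL, palette = NULL, ...) {
  syms <- sort(unique(as.vector(x$symbols)))
  if (is.null(palette)) {
    base_cols <- c(r = "#c0392b", b = "#2980b9", g = "#27ae60",
                   gr = "#7d3c98", wr = "#e67e22", gb = "#16a085",
                   wb = "#f1c40f")
    palette <- base_cols[syms]
    palette[is.na(palette)] <- grDevices::hcl.colors(sum(is.na(palette)),
                                                     "Dark 3")
    names(palette) <- syms
  }
  z <- matrix(match(x$symbols, syms), nrow(x$symbols), ncol(x$symbols))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::image(x = x$positions, y = x$times, z = t(z),
                  col = palette[seq_along(syms)], xlab = "position",
                  ylab = "time", main = "cellular developmental program",
                  useRaster = TRUE)
  invisible(x)
}
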