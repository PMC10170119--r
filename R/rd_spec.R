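#' Reaction-diffusion system specification
#'
#' Describes the m-component system
#' `du_i/dt = d_i Lap(u_i) - lambda_i u_i + f_i(u) + eta_i(x, y)`
#' on a strip with periodic x and mixed (Neumann/Dirichlet) y boundaries.
#' For the two-component case this is the slow/fast pair `u` (slow, diffusion
#' `d_u`) and `v` (fast, diffusion `D_v`) driven by maternal-gradient sources
#' `zeta`, `eta`.
#'
#' @param m Number of components.
#' @param D Numeric vector of `m` positive diffusion coefficients.
#' @param lambdas Numeric vector of `m` nonnegative linear degradation rates.
#' @param reaction A reaction object from [reaction_zero()],
#'   [reaction_brusselator()], [reaction_fields()] or [reaction_fn()].
#' @param sources List of `m` source terms; each either `NULL` (zero), a
#'   function `f(x, y)` vectorized over coordinate matrices, a single number,
#'   or an `ny x nx` matrix (resolved against a grid at integration time).
#' @param bc List of `m` character pairs `c(bc_y0, bc_y1)` with tags
#'   `"neumann0"` / `"dirichlet0"`; a single pair is recycled.
#' @param noise_amplitude Nonnegative additive white-noise amplitude, per unit
#'   sqrt(time) (Euler-Maruyama convention); 0 disables noise.
#' @return An object of class `rd_system_spec`.
#' @export
rd_system_spec <- function(m, D, lambdas, reaction = reaction_zero(m),
                           sources = NULL, bc = list(c("neumann0", "neumann0")),
                           noise_amplitude = 0) {
  m <- as.integer(m)
  stopifnot(m >= 1L, length(D) == m, length(lambdas) == m)
  if (any(D <= 0)) stop("all diffusion coefficients must be > 0")
  if (any(lambdas < 0)) stop("degradation rates must be >= 0")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  if (is.null(sources)) sources <- vector("list", m)
  stopifnot(length(sources) == m)
  if (length(bc) == 1L) bc <- rep(bc, m)
  stopifnot(length(bc) == m)
  for (b in bc) { check_bc(b[[1]]); check_bc(b[[2]]) }
  stopifnot(inherits(reaction, "rd_reaction"))
  if (!is.null(reaction$m) && reaction$m != m) {
    stop("reaction is for ", reaction$m, " components, spec has ", m)
  }
  structure(list(m = m, D = as.numeric(D), lambdas = as.numeric(lambdas),
                 reaction = reaction, sources = sources, bc = bc,
                 noise_amplitude = noise_amplitude),
            class = "rd_system_spec")
}

#' Built-in reaction terms
#'
#' `reaction_zero()` has no reaction part (linear dynamics only).
#' `reaction_brusselator()` is the classical Brusselator
#' `f = A - (B+1) u + u^2 v`, `g = B u - u^2 v` (any linear degradation is
#' carried by the spec's `lambdas`, not the reaction).
#' `reaction_fields()` is the segment-embedding reaction with spatially
#' varying coefficient fields:
#' `f = a u + b v + d u v + e u^2 + h v^2`, `g = cg u`
#' (all coefficients `ny x nx` fields; scalars are recycled).
#' `reaction_fn()` wraps an arbitrary R function
#' `fn(u, x, y, t)` returning a list of `m` arrays (slow path: integration
#' falls back to the interpreted stepper).
#'
#' @param m Number of components (for `reaction_zero`).
#' @param A,B Brusselator parameters.
#' @param a,b,d,e,h `ny x nx` coefficient matrices for the embedding
#'   reaction.
#' @param cg Gain field (or scalar) of the slow component in the fast
#'   equation.
#' @param fn Reaction function for `reaction_fn`.
#' @return An object of class `rd_reaction`.
#' @name reactions
NULL

#' @rdname reactions
#' @export
reaction_zero <- function(m = 1L) {
  structure(list(name = "zero", m = as.integer(m),
                 fn = function(u, x, y, t) lapply(u, function(ui) ui * 0)),
            class = "rd_reaction")
}

#' @rdname reactions
#' @export
reaction_brusselator <- function(A = 2, B = 4.5) {
  structure(list(
    name = "brusselator", m = 2L, params = list(A = A, B = B),
    fn = function(u, x, y, t) {
      list(A - (B + 1) * u[[1]] + u[[1]]^2 * u[[2]],
           B * u[[1]] - u[[1]]^2 * u[[2]])
    }), class = "rd_reaction")
}

#' @rdname reactions
#' @export
reaction_fields <- function(a, b, d = 0, e = 0, h = 0, cg = 1) {
  stopifnot(is.matrix(a))
  tomat <- function(z) if (is.matrix(z)) z else matrix(z, nrow(a), ncol(a))
  b <- tomat(b); d <- tomat(d); e <- tomat(e); h <- tomat(h); cg <- tomat(cg)
  for (z in list(b, d, e, h, cg)) stopifnot(all(dim(z) == dim(a)))
  structure(list(
    name = "fields", m = 2L,
    params = list(a = a, b = b, d = d, e = e, h = h, cg = cg),
    fn = function(u, x, y, t) {
      list(a * u[[1]] + b * u[[2]] + d * u[[1]] * u[[2]] + e * u[[1]]^2 +
             h * u[[2]]^2,
           cg * u[[1]])
    }), class = "rd_reaction")
}

#' @rdname reactions
#' @export
reaction_fn <- function(fn, m) {
  stopifnot(is.function(fn))
  structure(list(name = "custom", m = as.integer(m), fn = fn),
            class = "rd_reaction")
}

#' Concentration field state
#'
#' @param t Time stamp.
#' @param values Either an `m x ny x nx` array, or a list of `m` `ny x nx`
#'   matrices, or a single matrix (m = 1).
#' @param grid The [spatial_grid()] the values live on.
#' @return Object of class `field_state` with fields `t` and `values`
#'   (always a list of `ny x nx` matrices).
#' @export
field_state <- function(t, values, grid) {
  if (is.matrix(values)) values <- list(values)
  if (is.array(values) && length(dim(values)) == 3L) {
    values <- lapply(seq_len(dim(values)[1]), function(i) values[i, , ])
  }
  stopifnot(is.list(values))
  for (vi in values) {
    if (!all(dim(vi) == c(grid$ny, grid$nx))) {
      stop("field shape ", paste(dim(vi), collapse = "x"),
           " does not match grid ", grid$ny, "x", grid$nx)
    }
    if (!all(is.finite(vi))) stop("field values must be finite")
  }
  structure(list(t = t, values = values), class = "field_state")
}

# resolve a source entry to an ny x nx matrix
resolve_source <- function(src, grid) {
  X <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(grid$y, grid$ny, grid$nx)
  out <- if (is.null(src)) {
    matrix(0, grid$ny, grid$nx)
  } else if (is.function(src)) {
    val <- src(X, Y)
    if (length(val) == 1L) matrix(val, grid$ny, grid$nx) else val
  } else if (is.matrix(src)) {
    src
  } else if (is.numeric(src) && length(src) == 1L) {
    matrix(src, grid$ny, grid$nx)
  } else stop("unsupported source specification")
  if (!all(dim(out) == c(grid$ny, grid$nx))) stop("source has wrong shape")
  if (!all(is.finite(out))) stop("source must be evaluable (finite) on the grid")
  out
}

#' Explicit diffusion stability bound on the time step
#'
#' `dt <= 0.9 * min_i hx^2 hy^2 / (2 d_i (hx^2 + hy^2))`, the pure-diffusion
#' CFL limit with a 0.9 safety factor. Reaction stiffness is the caller's
#' responsibility.
#'
#' @param spec An [rd_system_spec()].
#' @param grid A [spatial_grid()].
#' @return The largest admissible `dt`.
#' @export
rd_stable_dt <- function(spec, grid) {
  0.9 * grid$hx^2 * grid$hy^2 /
    (2 * max(spec$D) * (grid$hx^2 + grid$hy^2))
}
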