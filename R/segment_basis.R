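#' Localized segment basis on the periodic x-axis
#'
#' Builds `N` periodized Gaussian profiles
#' `psi_i(x) ~ exp(-(x - xbar_i)^2 / (2 eps^2))`, each peaked at a segment
#' center `xbar_i` and normalized to unit discrete L2 norm
#' (`sum(psi^2) * hx = 1`). These are the localized segments whose amplitudes
#' `X_i(t)` carry the reduced dynamics of the slow component.
#'
#' @param centers Strictly increasing segment centers in `[0, Lx)`.
#' @param epsilon Width parameter `eps > 0`; must be smaller than the minimum
#'   center spacing. Centers closer than `4 eps` trigger a warning recorded in
#'   the basis metadata (overlaps are then not negligible).
#' @param grid A [spatial_grid()] providing the x discretization.
#' @return An object of class `segment_basis`: `centers`, `epsilon`,
#'   `profiles` (an `nx x N` matrix of profiles on `grid$x`), `grid`, and
#'   `metadata` (minimum spacing, warnings).
#' @examples
#' g <- spatial_grid(256, 3, Lx = 2 * pi, Ly = 1)
#' bas <- build_segment_basis(c(1, 3, 5), 0.1, g)
#' colSums(bas$profiles^2) * g$hx  # all 1
#' @export
build_segment_basis <- function(centers, epsilon, grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (epsilon <= 0) stop("epsilon must be positive")
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("centers must be strictly increasing")
  }
  if (any(centers < 0 | centers >= grid$Lx)) {
    stop("centers must lie in [0, Lx)")
  }
  n <- length(centers)
  spacing <- if (n > 1L) {
    d <- diff(c(centers, centers[1] + grid$Lx))  # periodic gaps
    min(d)
  } else grid$Lx
  if (epsilon >= spacing) stop("epsilon must be below the minimum center spacing")
  warnings <- character()
  if (n > 1L && spacing < 4 * epsilon) {
    warnings <- sprintf(
      "centers closer than 4*epsilon (min spacing %.3g): overlaps not negligible",
      spacing)
    warning(warnings)
  }
  profiles <- vapply(centers, function(cc) {
    p <- periodized_gaussian(grid$x, cc, epsilon, grid$Lx)
    p / sqrt(sum(p^2) * grid$hx)
  }, numeric(grid$nx))
  structure(list(centers = centers, epsilon = epsilon, profiles = profiles,
                 grid = grid,
                 metadata = list(min_spacing = spacing, warnings = warnings)),
            class = "segment_basis")
}

periodized_gaussian <- function(x, center, eps, L) {
  p <- 0
  for (k in -2:2) p <- p + exp(-(x - center + k * L)^2 / (2 * eps^2))
  p
}

#' @exportS3Method base::print
print.segment_basis <- function(x, ...) {
  cat(sprintf("<segment_basis> N=%d, epsilon=%g, min spacing %.3g\n",
              length(x$centers), x$epsilon, x$metadata$min_spacing))
  invisible(x)
}

#' Project a concentration field onto segment amplitudes
#'
#' Solves the Gram system `G X = <psi_i, u>` (discrete L2 inner products along
#' x) so that `sum(X_i psi_i)` is the L2-optimal representation of `u` in the
#' basis span. Two-dimensional fields are averaged over y first (the basis is
#' y-constant on the strip).
#'
#' @param field Numeric vector of length `nx`, or an `ny x nx` matrix.
#' @param basis A [build_segment_basis()] result on the same grid.
#' @return Numeric amplitude vector `X` of length `N`.
#' @export
project_to_amplitudes <- function(field, basis) {
  stopifnot(inherits(basis, "segment_basis"))
  g <- basis$grid
  if (is.matrix(field)) {
    if (!all(dim(field) == c(g$ny, g$nx))) stop("field does not match grid")
    field <- y_average(field, g)
  }
  if (length(field) != g$nx) stop("field does not match grid")
  if (!all(is.finite(field))) stop("field must be finite")
  P <- basis$profiles
  G <- crossprod(P) * g$hx
  if (kappa(G, exact = TRUE) > 1e12) {
    stop("Gram matrix condition number exceeds 1e12 (centers too close)")
  }
  as.numeric(solve(G, crossprod(P, field) * g$hx))
}

# reconstruct the field sum(X_i psi_i) as a length-nx profile
amplitudes_to_field <- function(X, basis) {
  as.numeric(basis$profiles %*% X)
}
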