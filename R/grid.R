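#' Rectangular strip grid with periodic x and bounded y
#'
#' The domain is the strip `[0, Lx) x [0, Ly]`: periodic in `x` (cell-sampled,
#' no duplicated endpoint, `hx = Lx/nx`) and bounded in `y` (vertex-sampled,
#' endpoints included, `hy = Ly/(ny-1)`).
#'
#' @param nx,ny Number of grid points along x (>= 4) and y (>= 3).
#' @param Lx,Ly Domain length along x and height along y (dimensionless).
#' @return An object of class `spatial_grid` with fields `nx`, `ny`, `Lx`,
#'   `Ly`, `hx`, `hy`, and node coordinate vectors `x` (length `nx`) and `y`
#'   (length `ny`).
#' @examples
#' g <- spatial_grid(64, 9, Lx = 2 * pi, Ly = 1)
#' g$hx * g$nx  # == Lx
#' @export
spatial_grid <- function(nx, ny, Lx, Ly) {
  stopifnot(is.numeric(nx), is.numeric(ny), is.numeric(Lx), is.numeric(Ly))
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4L) stop("nx must be >= 4")
  if (ny < 3L) stop("ny must be >= 3")
  if (Lx <= 0 || Ly <= 0) stop("Lx and Ly must be positive")
  structure(list(
    nx = nx, ny = ny, Lx = Lx, Ly = Ly,
    hx = Lx / nx, hy = Ly / (ny - 1L),
    x = seq(0, Lx, length.out = nx + 1L)[seq_len(nx)],
    y = seq(0, Ly, length.out = ny)
  ), class = "spatial_grid")
}

#' @exportS3Method base::print
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %d x %d on [0,%g) x [0,%g], hx=%.4g hy=%.4g\n",
              x$nx, x$ny, x$Lx, x$Ly, x$hx, x$hy))
  invisible(x)
}

# trapezoidal weights along the bounded y direction, normalized to mean weight
# (so that a y-constant field averages to itself)
y_weights <- function(grid) {
  w <- rep(1, grid$ny)
  w[c(1L, grid$ny)] <- 0.5
  w / sum(w)
}

# y-average of an ny x nx field -> length-nx profile
y_average <- function(field, grid) {
  as.numeric(crossprod(y_weights(grid), field))
}

#' Sparse discrete Laplacian for a strip grid
#'
#' Second-order central differences; periodic along x. Along y the boundary
#' rows are either reflected (zero-flux Neumann, via mirrored ghost rows) or
#' pinned (homogeneous Dirichlet: boundary rows carry the identity equation
#' `w = 0`).
#'
#' @param grid A [spatial_grid()].
#' @param bc_y0,bc_y1 `"neumann0"` or `"dirichlet0"` at `y = 0` / `y = Ly`.
#' @return A sparse `ny*nx` square matrix acting on fields flattened
#'   column-major from `ny x nx` matrices (y fastest).
#' @keywords internal
laplacian_matrix <- function(grid, bc_y0 = "neumann0", bc_y1 = "neumann0") {
  nx <- grid$nx; ny <- grid$ny
  ix2 <- 1 / grid$hx^2; iy2 <- 1 / grid$hy^2
  # x part: periodic circulant on nx, identity on y
  ex <- rep(1, nx)
  Dx <- Matrix::bandSparse(nx, nx, k = c(-1L, 0L, 1L),
                           diagonals = list(ex[-1], -2 * ex, ex[-1]))
  Dx[1L, nx] <- 1; Dx[nx, 1L] <- 1
  Dx <- Dx * ix2
  # y part with boundary treatment
  ey <- rep(1, ny)
  Dy <- Matrix::bandSparse(ny, ny, k = c(-1L, 0L, 1L),
                           diagonals = list(ey[-1], -2 * ey, ey[-1]))
  Dy <- as(Dy, "TsparseMatrix")
  Dy <- Dy * iy2
  Dy <- as(Dy, "CsparseMatrix")
  if (bc_y0 == "neumann0") {
    Dy[1L, 2L] <- 2 * iy2            # mirrored ghost: u_0 = u_2
  } else {
    Dy[1L, ] <- 0                     # pinned row, handled by caller
  }
  if (bc_y1 == "neumann0") {
    Dy[ny, ny - 1L] <- 2 * iy2
  } else {
    Dy[ny, ] <- 0
  }
  L <- Matrix::kronecker(Dx, Matrix::Diagonal(ny)) +
    Matrix::kronecker(Matrix::Diagonal(nx), Dy)
  methods::as(L, "CsparseMatrix")
}

# logical index of Dirichlet-pinned nodes in the flattened field
dirichlet_mask <- function(grid, bc_y0, bc_y1) {
  m <- matrix(FALSE, grid$ny, grid$nx)
  if (bc_y0 == "dirichlet0") m[1L, ] <- TRUE
  if (bc_y1 == "dirichlet0") m[grid$ny, ] <- TRUE
  as.vector(m)
}

check_bc <- function(bc) {
  if (!bc %in% c("neumann0", "dirichlet0")) {
    stop("boundary tag must be 'neumann0' or 'dirichlet0', got: ", bc)
  }
  bc
}
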