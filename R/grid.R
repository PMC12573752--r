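#' Periodic simulation cell
#'
#' @param lattice 3x3 matrix whose rows are the lattice vectors a1, a2, a3 in
#'   bohr, or a single number for a cubic cell edge (bohr).
#' @return object of class `dfq_cell` with elements `lattice`, `volume`,
#'   `reciprocal` (rows are the reciprocal vectors b_j, a_i . b_j = 2 pi d_ij).
#' @export
simulation_cell <- function(lattice) {
  if (length(lattice) == 1L) lattice <- diag(3) * lattice
  lattice <- as.matrix(lattice)
  stopifnot(all(dim(lattice) == c(3L, 3L)), all(is.finite(lattice)))
  vol <- det(lattice)
  if (!is.finite(vol) || abs(vol) < 1e-12)
    stop("invalid cell: lattice vectors are not linearly independent")
  if (vol < 0) stop("invalid cell: left-handed lattice (negative volume)")
  inv <- solve(lattice)
  structure(list(lattice = lattice, volume = vol,
                 reciprocal = 2 * pi * t(inv), inv_lattice = inv,
                 periodic = TRUE),
            class = "dfq_cell")
}

# smallest integer >= n whose prime factors are all in {2,3,5}
.next_fft_size <- function(n) {
  n <- max(1L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# signed FFT frequencies 0,1,...,floor((n-1)/2), -floor(n/2),...,-1
.fft_freq <- function(n) {
  m <- seq_len(n) - 1L
  m[m > n %/% 2] <- m[m > n %/% 2] - n
  m
}

# 3D array varying along the given dimension
.axis_array <- function(v, shape, dim) {
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  switch(dim,
         array(v, dim = shape),
         array(rep(v, each = n1), dim = shape),
         array(rep(v, each = n1 * n2), dim = shape))
}

#' Build a real-space grid from a plane-wave energy cutoff
#'
#' Chooses per-axis divisions so that the grid spacing h_i = |a_i|/n_i
#' satisfies h <= pi / sqrt(2 * cutoff), i.e. the grid resolves all plane
#' waves up to kinetic energy `cutoff`.  Sizes are rounded *up* to the next
#' 2,3,5-smooth integer (never coarser than the cutoff-implied spacing).
#'
#' @param cell a `dfq_cell`
#' @param cutoff plane-wave kinetic-energy cutoff in Hartree
#' @return object of class `dfq_grid`
#' @export
build_grid <- function(cell, cutoff) {
  stopifnot(inherits(cell, "dfq_cell"), cutoff > 0)
  alen <- sqrt(rowSums(cell$lattice^2))
  hmax <- pi / sqrt(2 * cutoff)
  shape <- vapply(alen / hmax, .next_fft_size, integer(1))
  spacing <- alen / shape
  B <- cell$reciprocal
  m1 <- .fft_freq(shape[1]); m2 <- .fft_freq(shape[2]); m3 <- .fft_freq(shape[3])
  gx <- .axis_array(m1 * B[1, 1], shape, 1) + .axis_array(m2 * B[2, 1], shape, 2) +
        .axis_array(m3 * B[3, 1], shape, 3)
  gy <- .axis_array(m1 * B[1, 2], shape, 1) + .axis_array(m2 * B[2, 2], shape, 2) +
        .axis_array(m3 * B[3, 2], shape, 3)
  gz <- .axis_array(m1 * B[1, 3], shape, 1) + .axis_array(m2 * B[2, 3], shape, 2) +
        .axis_array(m3 * B[3, 3], shape, 3)
  g2 <- gx^2 + gy^2 + gz^2
  coulG <- array(0, dim = shape)
  coulG[g2 > 0] <- 4 * pi / g2[g2 > 0]
  # derivative multipliers: zero the (unpaired) Nyquist component on even axes
  nyq <- function(m, n) if (n %% 2L == 0L) m != -(n %/% 2L) else rep(TRUE, n)
  d1 <- nyq(m1, shape[1]); d2 <- nyq(m2, shape[2]); d3 <- nyq(m3, shape[3])
  dmask <- .axis_array(as.numeric(d1), shape, 1) *
           .axis_array(as.numeric(d2), shape, 2) *
           .axis_array(as.numeric(d3), shape, 3)
  npts <- prod(shape)
  structure(list(cell = cell, shape = shape, spacing = spacing,
                 cutoff = cutoff, volume = cell$volume,
                 voxel = cell$volume / npts, npts = npts,
                 gx = gx, gy = gy, gz = gz, g2 = g2, coulG = coulG,
                 dmask = dmask),
            class = "dfq_grid")
}

#' @export
print.dfq_grid <- function(x, ...) {
  cat(sprintf("dfq_grid %d x %d x %d (cutoff %.4g Ha, spacing %.4g/%.4g/%.4g bohr)\n",
              x$shape[1], x$shape[2], x$shape[3], x$cutoff,
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Scalar field on a periodic grid
#'
#' @param grid a `dfq_grid`
#' @param values numeric 3D array matching `grid$shape`, or a single number
#' @return object of class `dfq_field`
#' @export
scalar_field <- function(grid, values = 0) {
  stopifnot(inherits(grid, "dfq_grid"))
  if (length(values) == 1L) values <- array(values, dim = grid$shape)
  stopifnot(all(dim(values) == grid$shape))
  structure(list(grid = grid, values = values), class = "dfq_field")
}

.same_grid <- function(a, b) {
  identical(a$grid$shape, b$grid$shape) &&
    isTRUE(all.equal(a$grid$cell$lattice, b$grid$cell$lattice))
}

.check_same_grid <- function(a, b) {
  if (!.same_grid(a, b)) stop("fields live on different grids")
}

#' Integrate a scalar field over the cell
#'
#' @param f a `dfq_field`
#' @return sum(values) * voxel volume
#' @export
integrate_field <- function(f) {
  stopifnot(inherits(f, "dfq_field"))
  sum(f$values) * f$grid$voxel
}

# forward / inverse FFT wrappers (continuous-coefficient convention handled
# by callers; these are plain DFTs)
.fftn <- function(values) stats::fft(values)
.ifftn_re <- function(coef) Re(stats::fft(coef, inverse = TRUE)) / length(coef)

#' Solve the periodic Poisson equation (Hartree potential)
#'
#' Returns phi with lap(phi) = -4 pi rho under periodic boundary conditions;
#' the G = 0 component is set to zero (uniform neutralizing-background
#' convention).  For an electron density rho (positive, in e/bohr^3) the
#' electron-electron Hartree energy is `0.5 * integrate_field(rho * phi)`.
#'
#' @param rho a `dfq_field`
#' @return a `dfq_field` with the potential (Hartree per unit charge)
#' @export
solve_hartree <- function(rho) {
  stopifnot(inherits(rho, "dfq_field"))
  g <- rho$grid
  phat <- .fftn(rho$values) * g$coulG
  scalar_field(g, .ifftn_re(phat))
}

#' Spectral gradient of a scalar field
#'
#' @param f a `dfq_field`
#' @return list of three `dfq_field`s (d/dx, d/dy, d/dz in bohr^-1 units)
#' @export
spectral_gradient <- function(f) {
  stopifnot(inherits(f, "dfq_field"))
  g <- f$grid
  fhat <- .fftn(f$values) * g$dmask
  list(scalar_field(g, .ifftn_re(1i * g$gx * fhat)),
       scalar_field(g, .ifftn_re(1i * g$gy * fhat)),
       scalar_field(g, .ifftn_re(1i * g$gz * fhat)))
}

# gradient returning plain arrays (hot path)
.grad_arrays <- function(grid, values) {
  fhat <- .fftn(values) * grid$dmask
  list(.ifftn_re(1i * grid$gx * fhat),
       .ifftn_re(1i * grid$gy * fhat),
       .ifftn_re(1i * grid$gz * fhat))
}

# spectral divergence of three arrays
.div_arrays <- function(grid, vx, vy, vz) {
  h <- 1i * grid$gx * .fftn(vx) + 1i * grid$gy * .fftn(vy) +
       1i * grid$gz * .fftn(vz)
  .ifftn_re(h * grid$dmask)
}

# spectral Laplacian of an array
.lap_array <- function(grid, values) {
  .ifftn_re(-grid$g2 * .fftn(values))
}

#' Spectral Laplacian of a scalar field
#' @param f a `dfq_field`
#' @return a `dfq_field`
#' @export
spectral_laplacian <- function(f) {
  scalar_field(f$grid, .lap_array(f$grid, f$values))
}

# fractional coordinates (0..1) of cartesian positions, rows = points
.frac_coords <- function(cell, pos) {
  pos <- matrix(pos, ncol = 3)
  f <- pos %*% cell$inv_lattice
  f - floor(f)
}

#' Minimum-image distance field to a point
#'
#' @param grid a `dfq_grid`
#' @param center cartesian position (bohr)
#' @return a `dfq_field` of |r - center| under the minimum-image convention
#' @export
distance_field <- function(grid, center) {
  sh <- grid$shape
  fr <- .frac_coords(grid$cell, center)
  f1 <- (seq_len(sh[1]) - 1) / sh[1] - fr[1]
  f2 <- (seq_len(sh[2]) - 1) / sh[2] - fr[2]
  f3 <- (seq_len(sh[3]) - 1) / sh[3] - fr[3]
  wrap <- function(x) x - round(x)
  f1 <- wrap(f1); f2 <- wrap(f2); f3 <- wrap(f3)
  A <- grid$cell$lattice
  dx <- .axis_array(f1 * A[1, 1], sh, 1) + .axis_array(f2 * A[2, 1], sh, 2) +
        .axis_array(f3 * A[3, 1], sh, 3)
  dy <- .axis_array(f1 * A[1, 2], sh, 1) + .axis_array(f2 * A[2, 2], sh, 2) +
        .axis_array(f3 * A[3, 2], sh, 3)
  dz <- .axis_array(f1 * A[1, 3], sh, 1) + .axis_array(f2 * A[2, 3], sh, 2) +
        .axis_array(f3 * A[3, 3], sh, 3)
  scalar_field(grid, sqrt(dx^2 + dy^2 + dz^2))
}

#' Index of the grid point nearest to a position
#'
#' Ties (positions exactly half-way between grid planes) are broken toward
#' the lower index, deterministically across platforms.
#'
#' @param grid a `dfq_grid`
#' @param pos cartesian position (bohr)
#' @return integer vector of three 1-based array indices
#' @export
nearest_grid_index <- function(grid, pos) {
  fr <- .frac_coords(grid$cell, pos)
  n <- grid$shape
  idx <- ceiling(fr * n - 0.5)        # tie at .5 falls to the lower index
  as.integer(idx %% n) + 1L
}

# reciprocal-space phase factors exp(-i G . R) for one position
.phase_factors <- function(grid, pos) {
  exp(-1i * (grid$gx * pos[1] + grid$gy * pos[2] + grid$gz * pos[3]))
}

# field from continuous Fourier coefficients c_G (array over the G grid):
# f(r_n) = sum_G c_G exp(i G r_n)
.field_from_coeff <- function(grid, cG) {
  scalar_field(grid, Re(stats::fft(cG, inverse = TRUE)))
}

# periodic normalized Gaussian of total weight `amount` and width sigma at pos:
# c_G = (amount / V) exp(-sigma^2 G^2 / 2) exp(-i G . R)
.gaussian_coeff <- function(grid, pos, sigma, amount) {
  (amount / grid$volume) * exp(-0.5 * sigma^2 * grid$g2) *
    .phase_factors(grid, pos)
}
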