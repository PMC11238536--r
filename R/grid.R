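#' Volumetric scalar fields on regular 3D grids
#'
#' A `volumetric_field` holds one scalar value per voxel of a regular,
#' axis-aligned 3D grid, together with the grid origin and spacing in bohr
#' and an optional list of atoms. It is the container for molecular orbitals
#' and electron densities throughout the package. The quadrature convention
#' is midpoint: the voxel with index `(i, j, k)` (1-based) is located at
#' `origin + (i-1, j-1, k-1) * spacing` and carries weight
#' `prod(spacing)`.
#'
#' @param values numeric 3D array of finite values; `dim(values)` is the grid
#'   shape.
#' @param origin numeric length-3, position of the first voxel (bohr).
#' @param spacing numeric length-3, strictly positive grid steps (bohr).
#' @param atoms optional `data.frame` with columns `number` (atomic number),
#'   `charge`, `x`, `y`, `z` (bohr).
#' @param orbital_ids optional integer vector of orbital identifiers, as
#'   carried by the orbital dialect of the cube format.
#' @return An object of class `volumetric_field`.
#' @export
volumetric_field <- function(values, origin, spacing, atoms = NULL,
                             orbital_ids = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L))
    stop("grid shape must have positive extent along every axis")
  if (!all(is.finite(values)))
    stop("field values must all be finite")
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("`origin` and `spacing` must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all grid spacings must be strictly positive")
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    need <- c("number", "charge", "x", "y", "z")
    if (!all(need %in% names(atoms)))
      stop("`atoms` must have columns number, charge, x, y, z")
  }
  structure(
    list(values = values, origin = origin, spacing = spacing,
         atoms = atoms, orbital_ids = orbital_ids),
    class = "volumetric_field")
}

#' @export
print.volumetric_field <- function(x, ...) {
  shp <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d grid, spacing (%.3g, %.3g, %.3g) bohr\n",
              class(x)[1L], shp[1L], shp[2L], shp[3L],
              x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) bohr; %d atom(s)\n",
              x$origin[1L], x$origin[2L], x$origin[3L],
              if (is.null(x$atoms)) 0L else nrow(x$atoms)))
  if (inherits(x, "density_field"))
    cat(sprintf("  mass %.8g%s\n", field_mass(x),
                if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Voxel volume of a field's grid
#' @param field a `volumetric_field`.
#' @return Voxel volume in bohr^3.
#' @export
voxel_volume <- function(field) prod(field$spacing)

#' Axis coordinate vectors of a field's grid
#' @param field a `volumetric_field`.
#' @return List with components `x`, `y`, `z`: voxel-center coordinates (bohr).
#' @export
grid_axes <- function(field) {
  shp <- dim(field$values)
  list(x = field$origin[1L] + (seq_len(shp[1L]) - 1) * field$spacing[1L],
       y = field$origin[2L] + (seq_len(shp[2L]) - 1) * field$spacing[2L],
       z = field$origin[3L] + (seq_len(shp[3L]) - 1) * field$spacing[3L])
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("fields are on different grids (origin, spacing and shape must match)")
  invisible(TRUE)
}

#' Convert an orbital to its probability density
#'
#' Squares the orbital voxelwise, `rho = |phi|^2`. The result is not yet
#' normalized; its quadrature mass equals 1 only if the orbital was
#' unit-normalized and the grid captures its full support.
#'
#' @param orb a `volumetric_field` holding a (real) orbital.
#' @return A `density_field` (subclass of `volumetric_field`) with
#'   `normalized = FALSE`.
#' @export
density_from_orbital <- function(orb) {
  stopifnot(inherits(orb, "volumetric_field"))
  d <- orb
  d$values <- orb$values^2
  d$normalized <- FALSE
  class(d) <- c("density_field", "volumetric_field")
  d
}

#' Mark a nonnegative field as a density
#'
#' @param field a `volumetric_field` with nonnegative values.
#' @param normalized logical; assert unit quadrature mass (checked to 1e-8).
#' @return A `density_field`.
#' @export
as_density <- function(field, normalized = FALSE) {
  stopifnot(inherits(field, "volumetric_field"))
  if (any(field$values < 0))
    stop("density values must be nonnegative everywhere")
  field$normalized <- normalized
  class(field) <- unique(c("density_field", class(field)))
  if (normalized && abs(field_mass(field) - 1) > 1e-8)
    stop("field declared normalized but quadrature mass differs from 1")
  field
}

#' Quadrature mass of a density
#' @param d a `density_field` (or any field; the raw quadrature sum is taken).
#' @return `sum(values) * voxel_volume`.
#' @export
field_mass <- function(d) sum(d$values) * voxel_volume(d)

#' Mass and grid-coverage check
#'
#' Computes the quadrature mass of a density and tests whether the grid
#' captures at least `threshold` of a reference total mass (1 for densities
#' of unit-normalized orbitals). Grids used for transport diagnostics should
#' cover at least 99% of the density, otherwise truncation biases the
#' divergence.
#'
#' @param d a `density_field`.
#' @param threshold coverage fraction, default 0.99.
#' @param reference reference total mass, default 1.
#' @return List with `mass` and logical `covered`.
#' @export
mass_and_coverage <- function(d, threshold = 0.99, reference = 1) {
  stopifnot(inherits(d, "density_field"))
  if (any(d$values < 0))
    stop("density invariant violated: negative values present")
  m <- field_mass(d)
  list(mass = m, covered = m >= threshold * reference)
}

#' Normalize a density to unit quadrature mass
#'
#' @param d a `density_field` with positive mass.
#' @return The rescaled `density_field` with `normalized = TRUE`.
#' @export
normalize_density <- function(d) {
  stopifnot(inherits(d, "density_field"))
  m <- field_mass(d)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize a density with zero (or non-finite) mass")
  d$values <- d$values / m
  d$normalized <- TRUE
  d
}

#' Barycenter and second moment of a density
#'
#' Midpoint-quadrature mean position and mean squared distance
#' `E[|r - center|^2]`. With `center = NULL` the second moment is taken about
#' the density's own barycenter, i.e. it is the total variance of the
#' electron position (the default normalizer of the dimensionless transport
#' diagnostic). The input must be normalized: moments of unnormalized
#' densities silently mix in the mass and are a classic source of bugs, so
#' they are refused.
#'
#' @param d a normalized `density_field`.
#' @param center optional length-3 numeric; if given, the second moment is
#'   about this fixed point (bohr).
#' @return List with `barycenter` (bohr) and `second_moment` (bohr^2).
#' @export
density_moments <- function(d, center = NULL) {
  stopifnot(inherits(d, "density_field"))
  if (!isTRUE(d$normalized))
    stop("`density_moments` requires a normalized density; call normalize_density()")
  ax <- grid_axes(d)
  w <- voxel_volume(d)
  # axis marginals: cheap exact reductions of the separable quadrature
  mx <- apply(d$values, 1L, sum) * w
  my <- apply(d$values, 2L, sum) * w
  mz <- apply(d$values, 3L, sum) * w
  bary <- c(sum(ax$x * mx), sum(ax$y * my), sum(ax$z * mz))
  ctr <- if (is.null(center)) bary else as.numeric(center)
  if (length(ctr) != 3L) stop("`center` must have length 3")
  second <- sum((ax$x - ctr[1L])^2 * mx) +
    sum((ax$y - ctr[2L])^2 * my) +
    sum((ax$z - ctr[3L])^2 * mz)
  list(barycenter = bary, second_moment = second)
}

#' Nuclear centroid of a field's atom list
#'
#' Default "center of the molecule": the unweighted centroid of the nuclear
#' positions carried in the cube header. Returns `NULL` when no atoms are
#' present.
#'
#' @param field a `volumetric_field`.
#' @return Length-3 numeric (bohr) or `NULL`.
#' @export
nuclear_centroid <- function(field) {
  a <- field$atoms
  if (is.null(a) || nrow(a) == 0L) return(NULL)
  c(mean(a$x), mean(a$y), mean(a$z))
}
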