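#' Attachment and detachment densities from state density matrices
#'
#' Diagonalizes the one-particle difference density matrix
#' `Delta = gamma_X - gamma_0` (both in one orthonormal orbital basis).
#' Eigenvectors with positive eigenvalues build the attachment density,
#' those with negative eigenvalues (absolute values as weights) the
#' detachment density; each eigenvector is assembled on the grid as a
#' linear combination of the basis orbital fields before squaring. For
#' states made of single excitations the two densities carry the same mass
#' (the number of promoted electrons).
#'
#' @param gamma0,gammaX symmetric occupation matrices (dimensionless) of the
#'   ground and excited state in one orthonormal orbital basis; equal
#'   traces required (1e-8).
#' @param orbitals list of basis orbital `volumetric_field`s, one per
#'   matrix row, all on one grid.
#' @param eig_tol eigenvalues with `|lambda| < eig_tol` are treated as zero,
#'   default 1e-10.
#' @return List with `rho_A` and `rho_D` (`density_field`s, not normalized;
#'   masses are the summed positive / negative eigenvalues) and the
#'   eigenvalues in `$eigenvalues`.
#' @export
attach_detach <- function(gamma0, gammaX, orbitals, eig_tol = 1e-10) {
  gamma0 <- as.matrix(gamma0); gammaX <- as.matrix(gammaX)
  n <- nrow(gamma0)
  if (!identical(dim(gamma0), dim(gammaX)) || n != ncol(gamma0))
    stop("`gamma0` and `gammaX` must be square matrices of equal size")
  if (max(abs(gamma0 - t(gamma0))) > 1e-8 ||
      max(abs(gammaX - t(gammaX))) > 1e-8)
    stop("density matrices must be symmetric")
  if (abs(sum(diag(gamma0)) - sum(diag(gammaX))) > 1e-8)
    stop("ground and excited state must hold the same electron number")
  if (length(orbitals) != n)
    stop("need one basis orbital field per density-matrix row")
  for (k in seq_len(n)[-1L]) check_same_grid(orbitals[[1L]], orbitals[[k]])

  delta <- gammaX - gamma0
  e <- eigen(delta, symmetric = TRUE)
  lam <- e$values
  if (abs(sum(lam)) > 1e-8 * max(1, sum(abs(lam))))
    warning("difference-matrix eigenvalues do not sum to zero; ",
            "inputs are not exactly idempotent-state differences")
  grid <- orbitals[[1L]]
  assemble <- function(idx, weights) {
    vals <- array(0, dim = dim(grid$values))
    for (k in idx) {
      psi <- array(0, dim = dim(grid$values))
      for (j in seq_len(n))
        if (abs(e$vectors[j, k]) > 0)
          psi <- psi + e$vectors[j, k] * orbitals[[j]]$values
      vals <- vals + weights[k] * psi^2
    }
    fld <- grid
    fld$values <- vals
    fld$orbital_ids <- NULL
    as_density(fld)
  }
  pos <- which(lam > eig_tol)
  neg <- which(lam < -eig_tol)
  if (!length(pos) && !length(neg))
    warning("difference matrix is numerically zero; ",
            "attachment and detachment densities are empty")
  rho_A <- assemble(pos, lam)
  rho_D <- assemble(neg, -lam)
  list(rho_A = rho_A, rho_D = rho_D, eigenvalues = lam)
}

#' Attachment/detachment density overlap
#'
#' `phi_S = integral sqrt(rho_A * rho_D) / ((mass_A + mass_D) / 2)`:
#' 1 when the density gained and the density lost occupy the same region,
#' 0 for disjoint supports.
#'
#' @param rho_A,rho_D `density_field`s on one grid with equal positive
#'   masses.
#' @return phi_S in `[0, 1]`.
#' @export
phi_s <- function(rho_A, rho_D) {
  stopifnot(inherits(rho_A, "density_field"), inherits(rho_D, "density_field"))
  check_same_grid(rho_A, rho_D)
  mA <- field_mass(rho_A); mD <- field_mass(rho_D)
  if (mA <= 0 || mD <= 0)
    stop("attachment/detachment densities must have positive mass")
  sum(sqrt(rho_A$values * rho_D$values)) * voxel_volume(rho_A) /
    (0.5 * (mA + mD))
}

#' Dimensionless transport diagnostic on attachment/detachment densities
#'
#' The Sinkhorn divergence between the (unit-normalized copies of the)
#' attachment and detachment densities, divided by the mean of their
#' second moments — the orbital-independent counterpart of [theta_prime()].
#' When the two densities share one shape and are merely displaced, the
#' divergence reduces to the squared centroid distance, so the value
#' approaches `D_CT^2 / variance`.
#'
#' @param rho_A,rho_D attachment / detachment `density_field`s with equal
#'   masses (1e-6).
#' @param cfg a [transport_config()].
#' @param center optional fixed center for the second moments (default:
#'   each density's own barycenter, i.e. the central variances).
#' @return Dimensionless value with attribute `converged`.
#' @export
theta_prime_ad <- function(rho_A, rho_D, cfg = transport_config(sigma = 4),
                           center = NULL) {
  stopifnot(inherits(rho_A, "density_field"), inherits(rho_D, "density_field"))
  check_same_grid(rho_A, rho_D)
  mA <- field_mass(rho_A); mD <- field_mass(rho_D)
  if (abs(mA - mD) > 1e-6)
    stop("attachment and detachment densities must hold the same mass")
  nA <- normalize_density(rho_A)
  nD <- normalize_density(rho_D)
  s <- sinkhorn_divergence(nA, nD, cfg)
  v <- 0.5 * (density_moments(nA, center)$second_moment +
                density_moments(nD, center)$second_moment)
  if (v <= 0) stop("degenerate geometry: zero electron-position variance")
  structure(as.numeric(s) / v, converged = attr(s, "converged"))
}

#' Full diagnostic record for one excitation
#'
#' Convenience wrapper computing the overlap diagnostic, the transport
#' diagnostic and its dimensionless form in one pass (sharing the
#' per-transition Sinkhorn solves), as a one-row data frame ready to be
#' stacked into a diagnostics table.
#'
#' @inheritParams theta_prime
#' @return One-row `data.frame` with columns `id`, `molecule`,
#'   `functional`, `energy`, `label`, `lambda`, `theta`, `theta_prime`,
#'   `variance`, `converged`.
#' @export
excitation_diagnostics <- function(exc, cfg = transport_config(sigma = 4),
                                   center = NULL, threshold = 0.05) {
  tab <- .transition_table(exc, cfg, threshold, center = center)
  csum <- sum(tab$c)
  data.frame(
    id = exc$id,
    molecule = exc$molecule %||% NA_character_,
    functional = exc$functional %||% NA_character_,
    energy = exc$energy,
    label = exc$label %||% NA_character_,
    lambda = sum(tab$c * tab$overlap) / csum,
    theta = sum(tab$c * tab$S) / csum,
    theta_prime = sum(tab$c * tab$S / tab$variance) / csum,
    variance = sum(tab$c * tab$variance) / csum,
    converged = all(tab$converged),
    stringsAsFactors = FALSE)
}
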