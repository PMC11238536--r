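#' Single-orbital transition
#'
#' One component `phi_i -> phi_a` of a linear-response excitation, with
#' excitation/de-excitation amplitudes `X`, `Y`. The weight of the
#' transition is `c = X^2 + Y^2`.
#'
#' @param i,a occupied / virtual orbital labels.
#' @param X,Y amplitudes (dimensionless); `Y` defaults to 0.
#' @param initial,final `volumetric_field` orbitals on one shared grid.
#' @return A `transition` object with the weight in `$c`.
#' @export
transition <- function(i, a, X, Y = 0, initial, final) {
  stopifnot(inherits(initial, "volumetric_field"),
            inherits(final, "volumetric_field"))
  check_same_grid(initial, final)
  structure(list(i = i, a = a, X = X, Y = Y, c = X^2 + Y^2,
                 initial = initial, final = final),
            class = "transition")
}

#' Electronic excitation
#'
#' A labeled collection of single-orbital transitions with an excitation
#' energy. Labels are restricted to the three canonical characters
#' (`"local"`, `"CT"`, `"Rydberg"`) or absent.
#'
#' @param id identifier (character).
#' @param transitions nonempty list of [transition()] objects.
#' @param label optional character label.
#' @param energy excitation energy (eV), optional.
#' @param molecule,functional optional tags.
#' @return An `excitation` object.
#' @export
excitation <- function(id, transitions, label = NULL, energy = NA_real_,
                       molecule = NA_character_, functional = NA_character_) {
  if (!length(transitions))
    stop("an excitation needs at least one transition")
  if (!all(vapply(transitions, inherits, logical(1L), "transition")))
    stop("`transitions` must be a list of transition objects")
  if (!is.null(label) && !label %in% c("local", "CT", "Rydberg"))
    stop("`label` must be one of \"local\", \"CT\", \"Rydberg\" (or NULL)")
  structure(list(id = id, transitions = transitions, label = label,
                 energy = energy, molecule = molecule,
                 functional = functional),
            class = "excitation")
}

#' @export
print.excitation <- function(x, ...) {
  cat(sprintf("<excitation> %s (%s): %d transition(s), energy %.3g eV\n",
              x$id, x$label %||% "unlabeled", length(x$transitions),
              x$energy))
  invisible(x)
}

.filter_transitions <- function(exc, threshold = 0.05) {
  keep <- Filter(function(tr) tr$c > threshold, exc$transitions)
  if (!length(keep))
    stop("no transition of ", exc$id, " has weight above the inclusion ",
         "threshold ", threshold)
  keep
}

#' Overlap of orbital moduli
#'
#' Quadrature of `|phi_a| * |phi_i|` on the shared grid. Both orbitals are
#' expected unit-normalized; deviations beyond 1e-6 are renormalized with a
#' warning. The overlap lies in `[0, 1]` up to quadrature tolerance: 1 for
#' identical moduli, 0 for disjoint supports.
#'
#' @param phi_a,phi_i orbital `volumetric_field`s on one grid.
#' @return Dimensionless overlap.
#' @export
overlap_moduli <- function(phi_a, phi_i) {
  check_same_grid(phi_a, phi_i)
  w <- voxel_volume(phi_a)
  na <- sum(phi_a$values^2) * w
  ni <- sum(phi_i$values^2) * w
  if (abs(na - 1) > 5e-3 || abs(ni - 1) > 5e-3)
    warning("orbitals are not unit-normalized on this grid; renormalizing")
  sum(abs(phi_a$values) * abs(phi_i$values)) * w / sqrt(na * ni)
}

#' Overlap diagnostic of an excitation
#'
#' Weighted average of the modulus overlaps of the included single-orbital
#' transitions: `Lambda = sum(c_ia * <|phi_a|, |phi_i|>) / sum(c_ia)` over
#' transitions with `c_ia` above the inclusion threshold. High values mean
#' local character, values near zero mean spatially separated (or very
#' diffuse) initial and final orbitals.
#'
#' @param exc an [excitation()].
#' @param threshold inclusion threshold on `c_ia`, default 0.05.
#' @return Lambda in `[0, 1]`.
#' @export
lambda_diagnostic <- function(exc, threshold = 0.05) {
  trs <- .filter_transitions(exc, threshold)
  cs <- vapply(trs, `[[`, numeric(1L), "c")
  ov <- vapply(trs, function(tr) overlap_moduli(tr$final, tr$initial),
               numeric(1L))
  sum(cs * ov) / sum(cs)
}

# per-transition working table: weights, densities, Sinkhorn divergence,
# variances. Everything downstream (theta, theta', records) reads this.
.transition_table <- function(exc, cfg, threshold = 0.05, center = NULL,
                              coverage_warn = TRUE) {
  trs <- .filter_transitions(exc, threshold)
  rows <- lapply(trs, function(tr) {
    ri <- density_from_orbital(tr$initial)
    ra <- density_from_orbital(tr$final)
    if (coverage_warn) {
      ci <- mass_and_coverage(ri); ca <- mass_and_coverage(ra)
      if (!ci$covered || !ca$covered)
        warning(sprintf(
          "%s (%s->%s): grid covers %.1f%% / %.1f%% of the densities",
          exc$id, format(tr$i), format(tr$a), 100 * ci$mass, 100 * ca$mass))
    }
    ri <- normalize_density(ri)
    ra <- normalize_density(ra)
    s <- sinkhorn_divergence(ri, ra, cfg)
    mi <- density_moments(ri, center)
    ma <- density_moments(ra, center)
    list(c = tr$c, S = as.numeric(s),
         converged = isTRUE(attr(s, "converged")),
         variance = 0.5 * (mi$second_moment + ma$second_moment),
         overlap = overlap_moduli(tr$final, tr$initial))
  })
  data.frame(c = vapply(rows, `[[`, numeric(1L), "c"),
             S = vapply(rows, `[[`, numeric(1L), "S"),
             variance = vapply(rows, `[[`, numeric(1L), "variance"),
             overlap = vapply(rows, `[[`, numeric(1L), "overlap"),
             converged = vapply(rows, `[[`, logical(1L), "converged"))
}

#' Transport diagnostic of an excitation
#'
#' Weighted average of the Sinkhorn divergences between the initial- and
#' final-orbital densities of the included transitions:
#' `Theta = sum(c_ia * S(rho_i, rho_a)) / sum(c_ia)`, in bohr^2. Grows
#' quadratically with the transfer distance where the overlap diagnostic
#' saturates at zero.
#'
#' @param exc an [excitation()].
#' @param cfg a [transport_config()]; the default operating point is
#'   `sigma = 4` on the grid ladder.
#' @param threshold inclusion threshold on `c_ia`.
#' @return Theta (bohr^2) with attribute `converged`.
#' @export
theta <- function(exc, cfg = transport_config(sigma = 4), threshold = 0.05) {
  tab <- .transition_table(exc, cfg, threshold)
  structure(sum(tab$c * tab$S) / sum(tab$c),
            converged = all(tab$converged))
}

#' Electron-position variance of an excitation
#'
#' Per transition, the mean of the second moments of the two transition
#' densities; by default each moment is taken about its own density's
#' barycenter (the variance of the electron position), which makes the
#' normalized diagnostic exactly scale-invariant. Passing `center` takes
#' all moments about that fixed point instead (e.g. the nuclear centroid).
#'
#' @param exc an [excitation()].
#' @param center optional fixed center (bohr).
#' @param threshold inclusion threshold on `c_ia`.
#' @return List with `per_transition` (bohr^2) and the c-weighted `mean`.
#' @export
electron_variance <- function(exc, center = NULL, threshold = 0.05) {
  trs <- .filter_transitions(exc, threshold)
  v <- vapply(trs, function(tr) {
    mi <- density_moments(normalize_density(density_from_orbital(tr$initial)),
                          center)
    ma <- density_moments(normalize_density(density_from_orbital(tr$final)),
                          center)
    0.5 * (mi$second_moment + ma$second_moment)
  }, numeric(1L))
  cs <- vapply(trs, `[[`, numeric(1L), "c")
  list(per_transition = v, mean = sum(cs * v) / sum(cs))
}

#' Dimensionless (variance-normalized) transport diagnostic
#'
#' Normalizes each transition's Sinkhorn divergence by that transition's
#' electron-position variance before c-weighting:
#' `Theta' = sum(c_ia * S_ia / v_ia) / sum(c_ia)`. Dimensionless and
#' invariant under uniform spatial rescaling of all inputs. For equal-width
#' Gaussian pairs it relates analytically to the overlap diagnostic:
#' `Theta' = (8/3) * (-log Lambda)` in the small-epsilon limit.
#'
#' @inheritParams theta
#' @param center optional fixed center for the variance (default: each
#'   density's own barycenter).
#' @return Theta' (dimensionless) with attribute `converged`.
#' @export
theta_prime <- function(exc, cfg = transport_config(sigma = 4),
                        center = NULL, threshold = 0.05) {
  tab <- .transition_table(exc, cfg, threshold, center = center)
  if (any(tab$variance <= 0))
    stop("degenerate geometry: a transition has zero electron-position variance")
  structure(sum(tab$c * tab$S / tab$variance) / sum(tab$c),
            converged = all(tab$converged))
}

#' Difference density and charge-transfer length
#'
#' `delta = rho_X - rho_0` between two equal-mass densities; the positive
#' and negative parts are separated voxelwise, each renormalized to unit
#' mass, and `D_CT` is the Euclidean distance between their barycenters.
#'
#' @param rho0,rhoX `density_field`s on one grid with equal masses (1e-6).
#' @return List with `delta` (signed `volumetric_field`), `d_ct` (bohr),
#'   and the two barycenters.
#' @export
delta_rho_dct <- function(rho0, rhoX) {
  stopifnot(inherits(rho0, "density_field"), inherits(rhoX, "density_field"))
  check_same_grid(rho0, rhoX)
  m0 <- field_mass(rho0); mX <- field_mass(rhoX)
  if (abs(m0 - mX) > 1e-6)
    stop(sprintf("densities have unequal masses (%.8g vs %.8g)", m0, mX))
  delta <- rho0
  delta$values <- rhoX$values - rho0$values
  delta$normalized <- NULL
  class(delta) <- "volumetric_field"
  pos <- delta; pos$values <- pmax(delta$values, 0)
  neg <- delta; neg$values <- pmax(-delta$values, 0)
  mp <- sum(pos$values) * voxel_volume(pos)
  if (mp <= 1e-14)
    return(list(delta = delta, d_ct = 0, barycenter_gain = NULL,
                barycenter_loss = NULL))
  bp <- density_moments(normalize_density(as_density(pos)))$barycenter
  bn <- density_moments(normalize_density(as_density(neg)))$barycenter
  list(delta = delta, d_ct = sqrt(sum((bp - bn)^2)),
       barycenter_gain = bp, barycenter_loss = bn)
}
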