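#' Symmetric grid template
#'
#' Builds an empty field on an axis-aligned grid of voxel centers
#' `center - halfwidth ... center + halfwidth` with the given spacing (the
#' grid is widened outward so the halfwidth is always reached).
#'
#' @param halfwidth scalar or length-3 half-extent (bohr).
#' @param spacing grid step (bohr), default 0.8 as used for all molecular
#'   grids in this package.
#' @param center grid center (bohr).
#' @param atoms optional atom table (see [volumetric_field()]).
#' @return A `volumetric_field` of zeros.
#' @export
grid_template <- function(halfwidth, spacing = 0.8, center = c(0, 0, 0),
                          atoms = NULL) {
  hw <- rep(as.numeric(halfwidth), length.out = 3L)
  sp <- rep(as.numeric(spacing), length.out = 3L)
  n_half <- ceiling(hw / sp)
  shape <- 2L * n_half + 1L
  origin <- center - n_half * sp
  volumetric_field(array(0, dim = shape), origin, sp, atoms = atoms)
}

# evaluate a separable Gaussian density on a grid template (analytic
# normalization; quadrature mass ~ 1 when the box covers the density)
.gaussian_on_grid <- function(grid, center, var3) {
  ax <- grid_axes(grid)
  g1 <- function(x, m, v) exp(-(x - m)^2 / (2 * v)) / sqrt(2 * pi * v)
  gx <- g1(ax$x, center[1L], var3[1L])
  gy <- g1(ax$y, center[2L], var3[2L])
  gz <- g1(ax$z, center[3L], var3[3L])
  outer(outer(gx, gy), gz)
}

#' Gaussian model orbital on a grid
#'
#' Returns the orbital whose squared modulus is the (diagonal-covariance)
#' Gaussian density `N(center, diag(var))`. The box must capture at least
#' 99% of the density, otherwise an error is raised: truncated marginals
#' bias every transport quantity downstream.
#'
#' @param center length-3 center (bohr).
#' @param var per-axis density variance (bohr^2), scalar or length-3.
#' @param grid a `volumetric_field` template (see [grid_template()]), or
#'   `NULL` to auto-build one spanning `3.5` standard deviations.
#' @param spacing grid step when auto-building, default 0.8 bohr.
#' @return A `volumetric_field` orbital (unit norm up to quadrature).
#' @export
gaussian_orbital <- function(center, var, grid = NULL, spacing = 0.8) {
  var3 <- .check_var3(var, "var")
  center <- as.numeric(center)
  if (is.null(grid))
    grid <- grid_template(abs(center) + 3.5 * sqrt(var3), spacing)
  rho <- .gaussian_on_grid(grid, center, var3)
  grid$values <- rho
  d <- as_density(grid)
  cov <- mass_and_coverage(d)
  if (!cov$covered)
    stop(sprintf(
      "grid covers only %.1f%% of the Gaussian density; enlarge the box",
      100 * cov$mass))
  orb <- grid
  orb$values <- sqrt(rho)
  orb
}

#' Mixture-of-Gaussians model orbital
#'
#' A normalized model orbital whose density is a weighted sum of
#' diagonal-covariance Gaussian lobes. This is the building block for
#' multi-lobe valence/antibonding orbital surrogates (pi systems, lone
#' pairs, sigma-star) in the synthetic molecule models.
#'
#' @param centers numeric matrix, one row per lobe (bohr).
#' @param vars per-lobe variance spec: numeric matrix (rows matching
#'   `centers`, length-3 per row), or a single scalar/length-3 used for all
#'   lobes.
#' @param weights positive lobe weights, normalized to sum 1.
#' @param grid grid template; required.
#' @param check_coverage error if the box captures < 99% of the density.
#' @return A `volumetric_field` orbital.
#' @export
gaussian_mixture_orbital <- function(centers, vars, weights = NULL, grid,
                                     check_coverage = TRUE) {
  centers <- rbind(centers)
  n <- nrow(centers)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("`weights` must be positive, one per lobe")
  weights <- weights / sum(weights)
  if (!is.matrix(vars)) vars <- matrix(.check_var3(vars, "vars"), n, 3L,
                                       byrow = TRUE)
  rho <- 0
  for (m in seq_len(n))
    rho <- rho + weights[m] * .gaussian_on_grid(grid, centers[m, ], vars[m, ])
  fld <- grid
  fld$values <- rho
  d <- as_density(fld)
  if (check_coverage && !mass_and_coverage(d)$covered)
    stop("grid covers less than 99% of the mixture density; enlarge the box")
  # renormalize to unit quadrature norm so downstream overlap checks are clean
  fld$values <- sqrt(rho / field_mass(d))
  fld
}

#' Equal-width Gaussian translation series
#'
#' The canonical charge-transfer toy model: pairs of equal-width Gaussian
#' orbitals whose centers are pulled apart along x by each displacement,
#' with the analytic overlap `exp(-d^2 / (8 s^2))` and the squared
#' Wasserstein distance `d^2` attached. The overlap decays to zero and then
#' stays flat, while the transport distance keeps growing quadratically -
#' the contrast that motivates the transport diagnostic.
#'
#' @param var equal per-axis density variance `s^2` (bohr^2), scalar.
#' @param displacements numeric vector of center separations (bohr).
#' @param halfwidth box half-extent (bohr); must fit the largest
#'   displacement plus 6 standard deviations.
#' @param spacing grid step, default 0.8 bohr.
#' @return List with one entry per displacement: `orb1`, `orb2`, `d`,
#'   `lambda_analytic`, `w2_analytic`.
#' @export
translation_series <- function(var, displacements, halfwidth = NULL,
                               spacing = 0.8) {
  s <- sqrt(var)
  need <- max(displacements) / 2 + 6 * s
  if (is.null(halfwidth)) halfwidth <- need
  if (halfwidth < need)
    stop("box too small for the largest displacement plus 6 standard deviations")
  grid <- grid_template(halfwidth, spacing)
  lapply(displacements, function(d) {
    list(orb1 = gaussian_orbital(c(-d / 2, 0, 0), var, grid),
         orb2 = gaussian_orbital(c(d / 2, 0, 0), var, grid),
         d = d,
         lambda_analytic = exp(-d^2 / (8 * var)),
         w2_analytic = d^2)
  })
}

#' Labeled synthetic excitation set
#'
#' Generates Gaussian model excitations of the three canonical characters:
#' \describe{
#'   \item{local}{concentric equal-width orbital pairs with a small center
#'     jitter (high overlap, near-zero transport);}
#'   \item{CT}{equal-width pairs with a center separation sampled from
#'     `ct_separation` (a genuinely charge-separated pair, vanishing overlap, quadratically growing transport);}
#'   \item{Rydberg}{concentric pairs whose final orbital is more diffuse by
#'     a width (standard-deviation) ratio sampled from `rydberg_ratio` -
#'     the final state is diffuse and delocalized rather than displaced,
#'     the failure mode that displacement-based diagnostics conflate
#'     with CT.}
#' }
#' All excitations share one grid sized from the most diffuse class member.
#' Every excitation carries 1-2 transitions with weights summing to 1.
#'
#' @param n_per_class excitations per class, default 20.
#' @param seed integer seed; the set is fully determined by it.
#' @param base_var initial-orbital density variance (bohr^2), default 1.
#' @param local_jitter max center jitter for the local class (bohr).
#' @param ct_separation length-2 range of CT center separations (bohr).
#' @param rydberg_ratio length-2 range (>= 1) of final/initial width ratios.
#' @param spacing grid step, default 0.8 bohr.
#' @param max_transitions maximum transitions per excitation (1-3).
#' @return List of `excitation` objects with `label` set.
#' @export
synthetic_excitation_set <- function(n_per_class = 20, seed = 1,
                                     base_var = 1,
                                     local_jitter = 0.3,
                                     ct_separation = c(5, 7),
                                     rydberg_ratio = c(3, 4),
                                     spacing = 0.8,
                                     max_transitions = 2) {
  if (local_jitter >= min(ct_separation))
    warning("local jitter range overlaps CT separations; classes are not ",
            "separable by construction")
  if (min(rydberg_ratio) < 1.5)
    warning("Rydberg width ratios close to 1 overlap the local class")
  s <- sqrt(base_var)
  widest <- max(rydberg_ratio) * s
  halfwidth <- max(ct_separation) / 2 + 3.5 * s
  halfwidth <- max(halfwidth, 3.5 * widest)
  grid <- grid_template(halfwidth, spacing)

  draw_pair <- function(class) {
    if (class == "local") {
      shift <- stats::runif(1, 0, local_jitter) * .unit_vector()
      list(c1 = c(0, 0, 0), v1 = base_var, c2 = shift, v2 = base_var)
    } else if (class == "CT") {
      d <- stats::runif(1, ct_separation[1L], ct_separation[2L])
      u <- .unit_vector()
      list(c1 = -d / 2 * u, v1 = base_var, c2 = d / 2 * u, v2 = base_var)
    } else {
      r <- stats::runif(1, rydberg_ratio[1L], rydberg_ratio[2L])
      list(c1 = c(0, 0, 0), v1 = base_var, c2 = c(0, 0, 0),
           v2 = r^2 * base_var)
    }
  }
  energy_range <- list(local = c(4, 6), CT = c(2.5, 4.5), Rydberg = c(7, 9))

  withr::with_seed(seed, {
    out <- list()
    for (class in c("local", "CT", "Rydberg")) {
      for (j in seq_len(n_per_class)) {
        n_tr <- sample.int(min(max_transitions, 3L), 1L)
        w <- stats::runif(n_tr, 0.3, 1)
        w <- w / sum(w)
        trans <- lapply(seq_len(n_tr), function(t) {
          p <- draw_pair(class)
          transition(i = t, a = t + 10L,
                     X = sqrt(w[t]), Y = 0,
                     initial = gaussian_orbital(p$c1, p$v1, grid),
                     final = gaussian_orbital(p$c2, p$v2, grid))
        })
        id <- sprintf("%s_%02d", tolower(class), j)
        out[[id]] <- excitation(id, trans, label = class,
                                energy = stats::runif(
                                  1, energy_range[[class]][1L],
                                  energy_range[[class]][2L]),
                                molecule = "synthetic")
      }
    }
    out
  })
}

.unit_vector <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

#' Write a synthetic excitation set as cube files plus a manifest
#'
#' Exercises the same I/O path as real data: each orbital goes to a cube
#' file and a JSON manifest references them with amplitudes and labels.
#'
#' @param excitations list of `excitation` objects.
#' @param dir output directory (created if needed).
#' @param settings optional list of global settings stored in the manifest
#'   (e.g. `sigma`, `spacing`, `c_threshold`).
#' @return Path to the manifest (invisibly).
#' @export
write_synthetic_manifest <- function(excitations, dir, settings = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(excitations, function(exc) {
    trs <- lapply(seq_along(exc$transitions), function(k) {
      tr <- exc$transitions[[k]]
      fi <- sprintf("%s_t%d_initial.cube", exc$id, k)
      fa <- sprintf("%s_t%d_final.cube", exc$id, k)
      write_cube(tr$initial, file.path(dir, fi))
      write_cube(tr$final, file.path(dir, fa))
      list(i = tr$i, a = tr$a, X = tr$X, Y = tr$Y,
           initial_cube = fi, final_cube = fa)
    })
    list(id = exc$id, molecule = exc$molecule, functional = exc$functional,
         energy = exc$energy, label = exc$label, transitions = trs)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(settings = settings, excitations = unname(entries)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
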