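#' Synthetic Gaussian-lobe model of the low-lying N2 excitations
#'
#' A synthetic stand-in for TDDFT output on the nitrogen molecule: the
#' valence orbitals involved in the three lowest singlet excitations are
#' modeled as mixtures of Gaussian lobes of one common 2p spatial scale
#' (Slater 2p extent of N, per-axis density variance 0.68 bohr^2) placed
#' according to their bonding/antibonding structure at the experimental
#' bond length 2.074 bohr. The three states are the valence
#' `sigma_g -> pi_g*` and the two `pi_u -> pi_g*` combinations; all
#' transitions are translation-dominated redistributions of valence
#' density, which is what makes the transport diagnostic converge quickly
#' on the regularization ladder for this molecule. No electronic-structure
#' calculation is involved: these are model densities for testing and
#' convergence studies only.
#'
#' @param spacing grid step (bohr), default 0.8.
#' @param halfwidth box half-extent (bohr), default 6.4 (covers > 99% of
#'   every model density).
#' @return Named list of three labeled [excitation()] objects.
#' @export
synthetic_n2_excitations <- function(spacing = 0.8, halfwidth = 6.4) {
  z_at <- 2.074 / 2           # experimental bond length 2.074 bohr
  v2p <- 0.68                  # Slater 2p <r^2>/3 for N
  off <- 0.7                   # p-lobe centroid offset from the nucleus
  atoms <- data.frame(number = c(7L, 7L), charge = c(7, 7),
                      x = 0, y = 0, z = c(-z_at, z_at))
  grid <- grid_template(halfwidth, spacing, atoms = atoms)
  lobes <- function(centers) gaussian_mixture_orbital(centers, v2p, grid = grid)
  # bonding sigma: density accumulated between the nuclei
  sigma_g <- lobes(rbind(c(0, 0, -0.5), c(0, 0, 0.5)))
  # bonding pi (x / y): perpendicular lobes spread over the bond region
  pi_u_x <- lobes(rbind(c(off, 0, -0.5), c(-off, 0, -0.5),
                        c(off, 0, 0.5), c(-off, 0, 0.5)))
  pi_u_y <- lobes(rbind(c(0, off, -0.5), c(0, -off, -0.5),
                        c(0, off, 0.5), c(0, -off, 0.5)))
  # antibonding pi*: lobes localized on the atoms
  pi_g_x <- lobes(rbind(c(off, 0, -z_at), c(-off, 0, -z_at),
                        c(off, 0, z_at), c(-off, 0, z_at)))
  pi_g_y <- lobes(rbind(c(0, off, -z_at), c(0, -off, -z_at),
                        c(0, off, z_at), c(0, -off, z_at)))
  amp <- sqrt(0.45)
  list(
    pi_g = excitation("n2_1pig",
      list(transition(3L, 6L, X = sqrt(0.9), initial = sigma_g,
                      final = pi_g_x)),
      label = "local", energy = 9.3, molecule = "N2 (synthetic model)"),
    sigma_u_minus = excitation("n2_1sigmau",
      list(transition(4L, 7L, X = amp, initial = pi_u_x, final = pi_g_y),
           transition(5L, 6L, X = amp, initial = pi_u_y, final = pi_g_x)),
      label = "local", energy = 9.9, molecule = "N2 (synthetic model)"),
    delta_u = excitation("n2_1deltau",
      list(transition(4L, 6L, X = amp, initial = pi_u_x, final = pi_g_x),
           transition(5L, 7L, X = amp, initial = pi_u_y, final = pi_g_y)),
      label = "local", energy = 10.3, molecule = "N2 (synthetic model)"))
}

#' Synthetic Gaussian-lobe model of the HCl charge-transfer excitations
#'
#' A synthetic stand-in for the low-lying singlet charge-transfer
#' excitations of hydrogen chloride, which move a chlorine lone-pair
#' electron into the sigma* orbital across the single H-Cl bond
#' (experimental bond length 2.409 bohr). The donor is a Cl 3p lone pair
#' perpendicular to the bond (Slater 3p extent, per-axis variance
#' 1.11 bohr^2); the acceptor sigma* is an antibonding two-center density
#' polarized toward hydrogen (weight 0.6 on H, slightly diffuse, and 0.4 on
#' the chlorine backside). Because donor and acceptor sit only one bond
#' apart, the transport diagnostic stays small — of the same size as local
#' excitations — despite the genuine charge-transfer character.
#'
#' @param spacing grid step (bohr), default 0.8.
#' @param halfwidth box half-extent (bohr), default 7.2.
#' @return Named list of two labeled [excitation()] objects (the two
#'   degenerate lone-pair components).
#' @export
synthetic_hcl_ct_excitations <- function(spacing = 0.8, halfwidth = 7.2) {
  r_hcl <- 2.409
  v3p <- 1.11                  # Slater 3p <r^2>/3 for Cl
  off <- 1.0
  atoms <- data.frame(number = c(17L, 1L), charge = c(17, 1),
                      x = 0, y = 0, z = c(0, r_hcl))
  grid <- grid_template(halfwidth, spacing, atoms = atoms)
  lp_x <- gaussian_mixture_orbital(rbind(c(off, 0, 0), c(-off, 0, 0)),
                                   v3p, grid = grid)
  lp_y <- gaussian_mixture_orbital(rbind(c(0, off, 0), c(0, -off, 0)),
                                   v3p, grid = grid)
  sigma_star <- gaussian_mixture_orbital(
    rbind(c(0, 0, r_hcl), c(0, 0, -off)),
    vars = rbind(rep(1.3, 3L), rep(v3p, 3L)),
    weights = c(0.6, 0.4), grid = grid)
  mk <- function(id, donor) excitation(
    id, list(transition(8L, 9L, X = sqrt(0.95), initial = donor,
                        final = sigma_star)),
    label = "CT", energy = 8.0, molecule = "HCl (synthetic model)",
    functional = "model")
  list(pi_x = mk("hcl_ct_x", lp_x), pi_y = mk("hcl_ct_y", lp_y))
}

#' Synthetic attachment/detachment model of the formaldehyde 1B1 state
#'
#' A synthetic stand-in for the formaldehyde `sigma(CH2) -> pi*(CO)`
#' excitation, built through the density-matrix route: a two-orbital basis
#' (donor sigma, acceptor pi*) with ground occupation `(1, 0)` and excited
#' occupation `(0, 1)` is fed through [attach_detach()], so the detachment
#' density is the donor density and the attachment density the acceptor
#' density. Geometry: C at the origin, O at 2.28 bohr along z, CH2 lobes on
#' the opposite side; the pi* acceptor is an out-of-plane two-center
#' density weighted toward carbon. The excitation shifts density from the
#' CH2 end to the CO bond — the partial charge-transfer character that
#' places this nominally local state in the CT region of the
#' attachment/detachment diagnostic plane.
#'
#' @param spacing grid step (bohr), default 0.8.
#' @param halfwidth box half-extent (bohr), default 6.4.
#' @return List with `rho_A`, `rho_D` (from [attach_detach()]),
#'   `orbitals`, `gamma0`, `gammaX`, and the grid `atoms`.
#' @export
synthetic_formaldehyde_ad <- function(spacing = 0.8, halfwidth = 6.4) {
  r_co <- 2.28
  atoms <- data.frame(number = c(6L, 8L, 1L, 1L), charge = c(6, 8, 1, 1),
                      x = 0, y = c(0, 0, 1.76, -1.76),
                      z = c(0, r_co, -1.11, -1.11))
  grid <- grid_template(halfwidth, spacing, atoms = atoms)
  sigma_ch2 <- gaussian_mixture_orbital(
    rbind(c(0, 0.9, -0.55), c(0, -0.9, -0.55)), 0.7, grid = grid)
  pi_star <- gaussian_mixture_orbital(
    rbind(c(0.75, 0, 0), c(-0.75, 0, 0),
          c(0.75, 0, r_co), c(-0.75, 0, r_co)),
    vars = rbind(rep(0.7, 3L), rep(0.7, 3L), rep(0.5, 3L), rep(0.5, 3L)),
    weights = c(0.3, 0.3, 0.2, 0.2), grid = grid)
  gamma0 <- diag(c(1, 0))
  gammaX <- diag(c(0, 1))
  ad <- attach_detach(gamma0, gammaX, list(sigma_ch2, pi_star))
  c(ad, list(orbitals = list(sigma_ch2, pi_star),
             gamma0 = gamma0, gammaX = gammaX, atoms = atoms))
}
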