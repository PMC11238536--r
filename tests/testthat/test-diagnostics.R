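test_that("transition weights follow the amplitude rule", {
  g <- grid_template(4, 1)
  o <- gaussian_orbital(c(0, 0, 0), 1, g)
  tr <- transition(1L, 2L, X = 0.9, Y = 0.1, initial = o, final = o)
  expect_equal(tr$c, 0.9^2 + 0.1^2)
  expect_error(transition(1L, 2L, X = 1, initial = o,
                          final = gaussian_orbital(c(0, 0, 0), 1,
                                                   grid_template(4, 0.5))),
               "different grids")
  expect_error(excitation("x", list()), "at least one")
  expect_error(excitation("x", list(tr), label = "bright"), "label")
})

test_that("overlap diagnostic behaves at its limits and analytic midpoint", {
  g <- grid_template(8, 0.5)
  o <- gaussian_orbital(c(0, 0, 0), 1, g)
  expect_equal(overlap_moduli(o, o), 1, tolerance = 1e-6)
  far1 <- gaussian_orbital(c(-6, 0, 0), 0.25, g)
  far2 <- gaussian_orbital(c(6, 0, 0), 0.25, g)
  expect_lt(overlap_moduli(far1, far2), 1e-10)
  o2 <- gaussian_orbital(c(3, 0, 0), 1, g)
  expect_equal(overlap_moduli(o2, o), exp(-9 / 8), tolerance = 0.01)
})

test_that("Lambda is the weighted mean of transition overlaps", {
  g <- grid_template(8, 0.8)
  conc <- gaussian_orbital(c(0, 0, 0), 1, g)      # overlap 1 with itself
  far <- gaussian_orbital(c(6, 0, 0), 0.4, g)     # ~0 with conc
  mk <- function(w1, w2, o2a, o2b) excitation("x", list(
    transition(1L, 2L, X = sqrt(w1), initial = conc, final = conc),
    transition(1L, 3L, X = sqrt(w2), initial = o2a, final = o2b)))
  # weights (0.9, 0.1), overlaps (1, ~0) -> 0.9 up to the residual tail
  # overlap the 0.8 bohr quadrature leaves behind
  expect_equal(lambda_diagnostic(mk(0.9, 0.1, conc, far)), 0.9,
               tolerance = 2e-3)
  # a below-threshold transition is excluded (and weights renormalized)
  expect_equal(lambda_diagnostic(mk(0.96, 0.04, conc, far)), 1,
               tolerance = 1e-4)
  expect_error(lambda_diagnostic(
    excitation("y", list(transition(1L, 2L, X = 0.1,
                                    initial = conc, final = conc)))),
    "threshold")
})

test_that("Theta reduces to the single-pair divergence and vanishes on identity", {
  g <- grid_template(8, 0.8)
  o1 <- gaussian_orbital(c(-1, 0, 0), 1, g)
  o2 <- gaussian_orbital(c(1, 0, 0), 1, g)
  cfg <- transport_config(sigma = 6)
  exc <- single_transition_excitation(o1, o2)
  r1 <- normalize_density(density_from_orbital(o1))
  r2 <- normalize_density(density_from_orbital(o2))
  expect_equal(as.numeric(theta(exc, cfg)),
               as.numeric(sinkhorn_divergence(r1, r2, cfg)),
               tolerance = 1e-10)
  same <- single_transition_excitation(o1, o1)
  expect_lt(abs(as.numeric(theta(same, cfg))), 1e-8)
})

test_that("Theta averages Gaussian pairs to the analytic value", {
  g <- grid_template(9, 0.8)
  mk <- function(d) list(gaussian_orbital(c(-d / 2, 0, 0), 1, g),
                         gaussian_orbital(c(d / 2, 0, 0), 1, g))
  p2 <- mk(2); p4 <- mk(4)
  exc <- excitation("x", list(
    transition(1L, 3L, X = sqrt(0.5), initial = p2[[1]], final = p2[[2]]),
    transition(2L, 4L, X = sqrt(0.5), initial = p4[[1]], final = p4[[2]])))
  # (2^2 + 4^2) / 2 = 10 bohr^2
  expect_equal(as.numeric(theta(exc, transport_config(sigma = 8))), 10,
               tolerance = 0.05)
})

test_that("electron variance is the mean central second moment", {
  g <- grid_template(8, 0.5)
  o1 <- gaussian_orbital(c(-1.5, 0, 0), 1.2, g)
  o2 <- gaussian_orbital(c(1.5, 0, 0), 1.2, g)
  exc <- single_transition_excitation(o1, o2)
  v <- electron_variance(exc)
  expect_equal(v$mean, 3 * 1.2, tolerance = 0.005)
  # about a fixed center the displacement contributes |c|^2
  v0 <- electron_variance(exc, center = c(0, 0, 0))
  expect_equal(v0$mean, 3 * 1.2 + 1.5^2, tolerance = 0.01)
})

test_that("Theta' matches the Gaussian overlap relation with slope 8/3", {
  ds <- c(0.7, 1.5, 2.5, 3.5)
  ser <- translation_series(1, ds, halfwidth = 8)
  cfg <- transport_config(sigma = 8)
  for (p in ser) {
    exc <- single_transition_excitation(p$orb1, p$orb2)
    tp <- as.numeric(theta_prime(exc, cfg))
    expect_equal(tp, (8 / 3) * (-log(lambda_diagnostic(exc))),
                 tolerance = 0.05)
  }
})

test_that("Theta' is dimensionless: invariant under uniform dilation", {
  # same physical problem at twice the length scale (d, s, grid all x2)
  cfg <- transport_config(sigma = 8)
  e1 <- {
    g <- grid_template(8, 0.8)
    single_transition_excitation(gaussian_orbital(c(-1, 0, 0), 1, g),
                                 gaussian_orbital(c(1, 0, 0), 1, g))
  }
  e2 <- {
    g <- grid_template(16, 1.6)
    single_transition_excitation(gaussian_orbital(c(-2, 0, 0), 4, g),
                                 gaussian_orbital(c(2, 0, 0), 4, g))
  }
  t1 <- as.numeric(theta_prime(e1, cfg))
  t2 <- as.numeric(theta_prime(e2, cfg))
  expect_equal(t1, t2, tolerance = 0.01)
  # while Theta itself scales by 4
  expect_equal(as.numeric(theta(e2, cfg)) / as.numeric(theta(e1, cfg)), 4,
               tolerance = 0.02)
})

test_that("zero-weight transitions change no diagnostic", {
  g <- grid_template(8, 0.8)
  o1 <- gaussian_orbital(c(-1, 0, 0), 1, g)
  o2 <- gaussian_orbital(c(1, 0, 0), 1, g)
  cfg <- transport_config(sigma = 6)
  base <- single_transition_excitation(o1, o2)
  padded <- excitation("x", c(base$transitions, list(
    transition(9L, 10L, X = 0, initial = o1, final = o1))))
  expect_equal(as.numeric(theta(padded, cfg)), as.numeric(theta(base, cfg)))
  expect_equal(lambda_diagnostic(padded), lambda_diagnostic(base))
  expect_equal(as.numeric(theta_prime(padded, cfg)),
               as.numeric(theta_prime(base, cfg)))
})

test_that("overlap and transport move in opposite directions on translation", {
  ser <- translation_series(1, c(0.5, 1.5, 2.5, 3.5, 4.5), halfwidth = 9)
  cfg <- transport_config(sigma = 6)
  lam <- th <- numeric(length(ser))
  for (i in seq_along(ser)) {
    exc <- single_transition_excitation(ser[[i]]$orb1, ser[[i]]$orb2)
    lam[i] <- lambda_diagnostic(exc)
    th[i] <- as.numeric(theta(exc, cfg))
  }
  expect_true(all(diff(lam) < 0))
  expect_true(all(diff(th) > 0))
})

test_that("difference density and D_CT behave under identity, shift and swap", {
  g <- grid_template(10, 0.8)
  r0 <- normalize_density(density_from_orbital(
    gaussian_orbital(c(0, 0, 0), 1, g)))
  expect_equal(delta_rho_dct(r0, r0)$d_ct, 0)
  rX <- normalize_density(density_from_orbital(
    gaussian_orbital(c(6, 0, 0), 1, g)))
  res <- delta_rho_dct(r0, rX)
  # disjoint supports: positive/negative parts are exactly the two Gaussians
  expect_equal(res$d_ct, 6, tolerance = 0.01)
  expect_lt(abs(sum(res$delta$values) * voxel_volume(res$delta)), 1e-6)
  swapped <- delta_rho_dct(rX, r0)
  expect_equal(swapped$d_ct, res$d_ct)
  expect_equal(swapped$delta$values, -res$delta$values)
  bad <- rX; bad$values <- bad$values * 2
  expect_error(delta_rho_dct(r0, bad), "unequal masses")
})
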