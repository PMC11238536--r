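cfg_tight <- function(eps = NULL, sigma = NULL)
  transport_config(epsilon = eps, sigma = sigma, tol = 1e-10,
                   max_iter = 20000)

test_that("the epsilon ladder follows the bounding-box diagonal", {
  # cubic box of side L: d_max = 3 L^2
  g <- grid_template(2, 0.5)         # 9 points per axis, L = 4
  expect_equal(epsilon_from_sigma(g, 0), 3 * 16)
  expect_equal(epsilon_from_sigma(g, 4), 3 * 16 / 16)
  for (s in 0:6)
    expect_equal(epsilon_from_sigma(g, s + 1), epsilon_from_sigma(g, s) / 2)
  expect_error(epsilon_from_sigma(g, -1), "nonnegative")
  expect_error(transport_config(epsilon = 1, sigma = 2), "exactly one")
  expect_error(transport_config(), "exactly one")
})

test_that("KL divergence matches direct evaluation and the Gibbs inequality", {
  # two-point masses: 0.5 log 2 + 0.5 log(2/3) = 0.143841...
  p <- array(c(0.5, 0.5), dim = c(2, 1, 1))
  q <- array(c(0.25, 0.75), dim = c(2, 1, 1))
  expect_equal(kl_divergence(p, q), 0.14384, tolerance = 1e-5)
  expect_equal(kl_divergence(p, p), 0)
  set.seed(1)
  for (i in 1:10) {
    a <- array(runif(8), dim = c(2, 2, 2)); a <- a / sum(a)
    b <- array(runif(8), dim = c(2, 2, 2)); b <- b / sum(b)
    expect_gte(kl_divergence(a, b), 0)
  }
  expect_equal(kl_divergence(array(c(1, 0), dim = c(2, 1, 1)),
                             array(c(0, 1), dim = c(2, 1, 1))), Inf)
})

test_that("entropic transport matches brute-force primal minimization", {
  # two-voxel densities: one free coupling parameter, minimized directly
  g1 <- volumetric_field(array(0, dim = c(2, 1, 1)), c(0, 0, 0), rep(1, 3))
  f1 <- g1; f1$values[] <- c(0.3, 0.7)
  f2 <- g1; f2$values[] <- c(0.6, 0.4)
  r1 <- normalize_density(as_density(f1))
  r2 <- normalize_density(as_density(f2))
  ot <- entropic_ot(r1, r2, cfg_tight(eps = 0.7))
  mp <- field_masses_points(r1)
  bf <- brute_force_ot(mp$a, as.vector(r2$values) * voxel_volume(r2),
                       mp$pts, 0.7)
  expect_equal(ot$value, bf, tolerance = 1e-6)

  # 27-voxel random densities at two regularization strengths
  set.seed(42)
  g <- grid_template(0.8, 0.8)
  r1 <- random_density(g); r2 <- random_density(g)
  a <- field_masses_points(r1); b <- field_masses_points(r2)
  for (eps in c(0.5, 2)) {
    ot <- entropic_ot(r1, r2, cfg_tight(eps = eps))
    bf <- brute_force_ot(a$a, b$a, a$pts, eps)
    expect_equal(ot$value, bf, tolerance = 1e-6)
  }
})

test_that("transport results satisfy the marginal and symmetry contracts", {
  set.seed(7)
  g <- grid_template(1.6, 0.8)
  r1 <- random_density(g); r2 <- random_density(g)
  cfg <- cfg_tight(sigma = 3)
  o12 <- entropic_ot(r1, r2, cfg)
  o21 <- entropic_ot(r2, r1, cfg)
  expect_true(o12$converged)
  expect_lte(o12$marginal_error, cfg$tol)
  expect_equal(o12$value, o21$value, tolerance = 1e-8)
  # regularized value is strictly positive even for identical densities
  oself <- entropic_ot(r1, r1, cfg)
  expect_gt(oself$value, 0)
  # mismatched grids are refused
  g2 <- grid_template(1.6, 0.4)
  expect_error(entropic_ot(r1, random_density(g2), cfg), "different grids")
  unnorm <- r2; unnorm$values <- 2 * unnorm$values; unnorm$normalized <- FALSE
  expect_error(entropic_ot(unnorm, r1, cfg), "normalized")
})

test_that("the divergence is debiased, symmetric and nonnegative", {
  set.seed(9)
  g <- grid_template(1.6, 0.8)
  cfg <- cfg_tight(sigma = 4)
  for (i in 1:5) {
    r1 <- random_density(g); r2 <- random_density(g)
    s12 <- sinkhorn_divergence(r1, r2, cfg)
    s21 <- sinkhorn_divergence(r2, r1, cfg)
    expect_equal(as.numeric(s12), as.numeric(s21), tolerance = 1e-8)
    expect_gte(as.numeric(s12), -1e-8)
    expect_lt(abs(as.numeric(sinkhorn_divergence(r1, r1, cfg))), 1e-8)
  }
})

test_that("grid transport reproduces the closed-form Gaussian values", {
  g <- grid_template(8, 0.8)
  eps <- epsilon_from_sigma(g, 8)
  cases <- list(list(m1 = c(-1, 0, 0), v1 = 1, m2 = c(1, 0, 0), v2 = 1),
                list(m1 = c(-1, 0, 0), v1 = 1, m2 = c(0, 0, 0), v2 = 4),
                list(m1 = c(0, 0, 0), v1 = c(1, 2, 0.8),
                     m2 = c(1, -1, 0), v2 = c(2, 1, 1.5)))
  for (cs in cases) {
    r1 <- normalize_density(density_from_orbital(
      gaussian_orbital(cs$m1, cs$v1, g)))
    r2 <- normalize_density(density_from_orbital(
      gaussian_orbital(cs$m2, cs$v2, g)))
    got <- entropic_ot(r1, r2, transport_config(epsilon = eps))$value
    want <- gaussian_ot_reference(cs$m1, cs$v1, cs$m2, cs$v2, eps)
    expect_equal(got, want, tolerance = 0.02)
    gots <- as.numeric(sinkhorn_divergence(r1, r2,
                                           transport_config(epsilon = eps)))
    wants <- gaussian_sinkhorn_reference(cs$m1, cs$v1, cs$m2, cs$v2, eps)
    expect_equal(gots, wants, tolerance = 0.02)
  }
})

test_that("sigma refinement converges on Gaussian pairs", {
  g <- grid_template(7, 0.8)
  r1 <- normalize_density(density_from_orbital(
    gaussian_orbital(c(-1, 0, 0), 1, g)))
  r2 <- normalize_density(density_from_orbital(
    gaussian_orbital(c(0.5, 0, 0), 2.5, g)))
  sigmas <- 2:10
  s <- vapply(sigmas, function(sg) as.numeric(
    sinkhorn_divergence(r1, r2, transport_config(sigma = sg, tol = 1e-9,
                                                 max_iter = 20000))),
    numeric(1))
  steps <- abs(diff(s))
  # past the point of maximal change the ladder contracts monotonically
  # (at very large epsilon everything is blurred and steps first grow)
  k <- which.max(steps)
  expect_true(all(diff(steps[k:length(steps)]) < 0))
  expect_lt(steps[length(steps)], steps[k] / 10)
  # and the refined value approaches the closed-form reference
  eps10 <- epsilon_from_sigma(g, 10)
  expect_equal(s[length(s)],
               gaussian_sinkhorn_reference(c(-1, 0, 0), 1,
                                           c(0.5, 0, 0), 2.5, eps10),
               tolerance = 0.02)
})

test_that("fixed and annealed schedules reach the same fixed point", {
  set.seed(5)
  g <- grid_template(1.6, 0.8)
  r1 <- random_density(g); r2 <- random_density(g)
  va <- entropic_ot(r1, r2, transport_config(sigma = 5, tol = 1e-10,
                                             max_iter = 50000,
                                             schedule = "anneal"))$value
  vf <- entropic_ot(r1, r2, transport_config(sigma = 5, tol = 1e-10,
                                             max_iter = 50000,
                                             schedule = "fixed"))$value
  expect_equal(va, vf, tolerance = 1e-8)
})
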