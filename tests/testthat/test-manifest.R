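write_demo_set <- function(dir, n = 1, seed = 2) {
  exc <- synthetic_excitation_set(n_per_class = n, seed = seed,
                                  max_transitions = 1, base_var = 0.8,
                                  rydberg_ratio = c(2, 2.5))
  write_synthetic_manifest(exc, dir, settings = list(sigma = 4))
}

test_that("JSON and CSV encodings parse to the same manifest", {
  dir <- withr::local_tempdir()
  path <- write_demo_set(dir)
  man <- parse_manifest(path)
  # re-encode as CSV
  rows <- do.call(rbind, lapply(man$entries, function(e)
    do.call(rbind, lapply(e$transitions, function(tr)
      data.frame(id = e$id, molecule = e$molecule, functional = "",
                 energy = e$energy, label = e$label, i = tr$i, a = tr$a,
                 X = tr$X, Y = tr$Y,
                 initial_cube = basename(tr$initial_cube),
                 final_cube = basename(tr$final_cube))))))
  csv <- file.path(dir, "manifest.csv")
  write.csv(rows, csv, row.names = FALSE)
  man2 <- parse_manifest(csv)
  expect_equal(length(man2$entries), length(man$entries))
  ids <- vapply(man$entries, `[[`, character(1), "id")
  ids2 <- vapply(man2$entries, `[[`, character(1), "id")
  expect_setequal(ids, ids2)
  e1 <- man$entries[[1]]; e2 <- man2$entries[[match(e1$id, ids2)]]
  expect_equal(e2$transitions[[1]]$X, e1$transitions[[1]]$X)
  expect_equal(e2$transitions[[1]]$c, e1$transitions[[1]]$c)
  expect_equal(e2$label, e1$label)
})

test_that("defaults are injected and weights computed, never read", {
  dir <- withr::local_tempdir()
  g <- grid_template(4, 1)
  write_cube(gaussian_orbital(c(0, 0, 0), 1, g), file.path(dir, "o1.cube"))
  write_cube(gaussian_orbital(c(1, 0, 0), 1, g), file.path(dir, "o2.cube"))
  jsonlite::write_json(list(excitations = list(list(
    id = "e1", transitions = list(list(
      i = 1, a = 2, X = 0.9, Y = 0.1,
      initial_cube = "o1.cube", final_cube = "o2.cube"))))),
    file.path(dir, "m.json"), auto_unbox = TRUE)
  man <- parse_manifest(file.path(dir, "m.json"))
  expect_equal(man$settings$spacing, 0.8)
  expect_equal(man$settings$sigma, 4)
  expect_equal(man$settings$c_threshold, 0.05)
  expect_equal(man$entries[[1]]$transitions[[1]]$c, 0.82)
})

test_that("broken manifests fail with precise messages", {
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(excitations = list(list(
    id = "ghost", transitions = list(list(
      i = 1, a = 2, X = 1, Y = 0,
      initial_cube = "missing.cube", final_cube = "missing.cube"))))),
    file.path(dir, "m.json"), auto_unbox = TRUE)
  expect_error(parse_manifest(file.path(dir, "m.json")),
               "ghost.*missing.cube")
  g <- grid_template(4, 1)
  write_cube(gaussian_orbital(c(0, 0, 0), 1, g), file.path(dir, "o.cube"))
  jsonlite::write_json(list(excitations = list(list(
    id = "e", label = "bright", transitions = list(list(
      i = 1, a = 2, X = 1, Y = 0,
      initial_cube = "o.cube", final_cube = "o.cube"))))),
    file.path(dir, "m2.json"), auto_unbox = TRUE)
  expect_error(parse_manifest(file.path(dir, "m2.json")), "bright")
})

test_that("the batch pipeline matches direct module calls and is deterministic", {
  dir <- withr::local_tempdir()
  path <- write_demo_set(dir)
  df <- run_diagnostics(path)
  expect_equal(nrow(df), 3)
  expect_true(all(is.na(df$error)))
  # composition: same numbers as calling the diagnostics directly
  man <- parse_manifest(path)
  exc <- load_excitations(man)
  direct <- excitation_diagnostics(exc[[df$id[1]]],
                                   transport_config(sigma = 4))
  expect_equal(df$theta[1], direct$theta, tolerance = 1e-12)
  expect_equal(df$lambda[1], direct$lambda, tolerance = 1e-12)
  # rerun: byte-identical CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f1, row.names = FALSE)
  write.csv(run_diagnostics(path), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("one unreadable cube flags its row and spares the batch", {
  dir <- withr::local_tempdir()
  path <- write_demo_set(dir)
  man <- parse_manifest(path)
  # corrupt the first excitation's final cube after parsing
  victim <- man$entries[[1]]$transitions[[1]]$final_cube
  writeLines("not a cube", victim)
  df <- run_diagnostics(man)
  expect_equal(sum(!is.na(df$error)), 1)
  expect_true(is.na(df$theta[1]))
  expect_true(all(is.finite(df$theta[-1])))
})

test_that("classification on separable diagnostics is perfect, overlap shows up", {
  # small separable set evaluated through the full pipeline
  exc <- synthetic_excitation_set(n_per_class = 6, seed = 13,
                                  max_transitions = 1)
  df <- run_diagnostics(exc)
  res <- run_classification(df, feature_sets = list(
    normalized = c("theta_prime", "log_lambda")), k = 5, folds = 3,
    seed = 1)
  expect_equal(res$normalized$accuracy, 1)
  expect_equal(unname(diag(res$normalized$confusion)), rep(6L, 3))
  # short-range CT overlaps the local class in Lambda by construction;
  # an overlap-only classifier then mislabels CT as local
  exc2 <- suppressWarnings(synthetic_excitation_set(
    n_per_class = 6, seed = 19, max_transitions = 1,
    local_jitter = 0.3, ct_separation = c(0.4, 0.9)))
  df2 <- run_diagnostics(exc2)
  res2 <- run_classification(df2, feature_sets = list(lam = "lambda"),
                             k = 5, folds = 3, seed = 1)
  expect_gt(res2$lam$confusion["CT", "local"], 0)
  expect_error(run_classification(df[0, ], feature_sets = list(l = "lambda"),
                                  k = 5), "not enough labeled rows")
})
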