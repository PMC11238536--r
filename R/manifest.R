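#' Parse an excitation manifest
#'
#' A manifest lists excitations, their single-orbital transitions with
#' amplitudes, and the cube files holding the orbitals. Two encodings are
#' accepted and yield identical manifests:
#' \describe{
#'   \item{JSON}{`{"settings": {...}, "excitations": [{"id", "molecule",
#'     "functional", "energy", "label", "transitions": [{"i", "a", "X",
#'     "Y", "initial_cube", "final_cube"}]}]}`.}
#'   \item{CSV}{one row per transition with columns `id, molecule,
#'     functional, energy, label, i, a, X, Y, initial_cube, final_cube`.}
#' }
#' Cube paths are resolved relative to the manifest's directory; transition
#' weights are always computed as `X^2 + Y^2`, never read from the file.
#' Global settings not present in the file get the package defaults
#' (`spacing` 0.8 bohr, `sigma` 4, `c_threshold` 0.05).
#'
#' @param path manifest file (`.json` or `.csv`).
#' @return A `manifest` object: `$settings` and `$entries` (each entry a
#'   list with resolved cube paths).
#' @export
parse_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  base <- dirname(normalizePath(path))
  ext <- tolower(tools::file_ext(path))
  defaults <- list(spacing = 0.8, sigma = 4, c_threshold = 0.05,
                   center = "auto")
  if (ext == "json") {
    doc <- jsonlite::read_json(path)
    settings <- utils::modifyList(defaults, doc$settings %||% list())
    entries <- doc$excitations %||% stop("manifest has no `excitations`")
    entries <- lapply(entries, function(e) {
      e$transitions <- lapply(e$transitions, as.list)
      e
    })
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "i", "a", "X", "Y", "initial_cube", "final_cube")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("manifest CSV lacks column(s): ", paste(miss, collapse = ", "))
    settings <- defaults
    entries <- lapply(split(df, factor(df$id, unique(df$id))), function(g) {
      list(id = g$id[1L],
           molecule = g$molecule[1L] %||% NA_character_,
           functional = g$functional[1L] %||% NA_character_,
           energy = if ("energy" %in% names(g)) g$energy[1L] else NA_real_,
           label = if ("label" %in% names(g) && nzchar(g$label[1L] %||% ""))
             g$label[1L] else NULL,
           transitions = lapply(seq_len(nrow(g)), function(r)
             list(i = g$i[r], a = g$a[r], X = g$X[r], Y = g$Y[r],
                  initial_cube = g$initial_cube[r],
                  final_cube = g$final_cube[r])))
    })
    entries <- unname(entries)
  } else stop("unsupported manifest format: .", ext, " (use .json or .csv)")

  entries <- lapply(entries, function(e) {
    if (is.null(e$id)) stop("manifest entry without an id")
    lab <- e$label
    if (!is.null(lab) && !is.na(lab) && !lab %in% c("local", "CT", "Rydberg"))
      stop("excitation ", e$id, " has unknown label \"", lab,
           "\"; allowed labels: local, CT, Rydberg")
    if (!length(e$transitions))
      stop("excitation ", e$id, " has no transitions")
    e$transitions <- lapply(e$transitions, function(tr) {
      for (f in c("initial_cube", "final_cube")) {
        p <- tr[[f]]
        if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
        if (!file.exists(p))
          stop("excitation ", e$id, ": cube file not found: ", tr[[f]])
        tr[[f]] <- p
      }
      tr$Y <- tr$Y %||% 0
      tr$c <- tr$X^2 + tr$Y^2
      tr
    })
    e
  })
  structure(list(settings = settings, entries = entries), class = "manifest")
}

#' Materialize manifest entries as excitation objects
#'
#' Reads every referenced cube exactly once (paths are cached) and builds
#' [excitation()] objects.
#'
#' @param manifest a `manifest` from [parse_manifest()].
#' @return Named list of `excitation` objects.
#' @export
load_excitations <- function(manifest) {
  stopifnot(inherits(manifest, "manifest"))
  cache <- new.env(parent = emptyenv())
  get_cube <- function(p) {
    key <- p
    if (is.null(cache[[key]])) cache[[key]] <- read_cube(p)
    cache[[key]]
  }
  out <- lapply(manifest$entries, function(e) {
    trs <- lapply(e$transitions, function(tr)
      transition(tr$i, tr$a, tr$X, tr$Y,
                 initial = get_cube(tr$initial_cube),
                 final = get_cube(tr$final_cube)))
    excitation(e$id, trs, label = e$label,
               energy = e$energy %||% NA_real_,
               molecule = e$molecule %||% NA_character_,
               functional = e$functional %||% NA_character_)
  })
  names(out) <- vapply(manifest$entries, `[[`, character(1L), "id")
  out
}

#' Run the diagnostics pipeline over a manifest
#'
#' Computes one diagnostic record per excitation. Failures are isolated:
#' an excitation whose cubes are unreadable or whose solve errors out is
#' reported in the `error` column and does not abort the batch. Output is
#' deterministic given inputs and settings.
#'
#' @param x a `manifest`, a manifest path, or a list of `excitation`s.
#' @param cfg optional [transport_config()]; by default built from the
#'   manifest settings (`sigma`).
#' @param threshold inclusion threshold on `c_ia`; default from settings.
#' @param center optional fixed center for the variance normalizer.
#' @return `data.frame`, one row per excitation (columns as in
#'   [excitation_diagnostics()] plus `error`).
#' @export
run_diagnostics <- function(x, cfg = NULL, threshold = NULL, center = NULL) {
  if (is.character(x)) x <- parse_manifest(x)
  if (inherits(x, "manifest")) {
    settings <- x$settings
    if (is.null(cfg)) cfg <- transport_config(sigma = settings$sigma)
    if (is.null(threshold)) threshold <- settings$c_threshold
    rows <- lapply(x$entries, function(e) {
      tryCatch({
        exc <- load_excitations(
          structure(list(settings = settings, entries = list(e)),
                    class = "manifest"))[[1L]]
        cbind(excitation_diagnostics(exc, cfg, center = center,
                                     threshold = threshold),
              error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(err)
        data.frame(id = e$id, molecule = e$molecule %||% NA_character_,
                   functional = e$functional %||% NA_character_,
                   energy = e$energy %||% NA_real_,
                   label = e$label %||% NA_character_,
                   lambda = NA_real_, theta = NA_real_,
                   theta_prime = NA_real_, variance = NA_real_,
                   converged = NA, error = conditionMessage(err),
                   stringsAsFactors = FALSE))
    })
  } else {
    if (is.null(cfg)) cfg <- transport_config(sigma = 4)
    if (is.null(threshold)) threshold <- 0.05
    if (!length(x)) stop("empty excitation list")
    rows <- lapply(x, function(exc) {
      tryCatch(
        cbind(excitation_diagnostics(exc, cfg, center = center,
                                     threshold = threshold),
              error = NA_character_, stringsAsFactors = FALSE),
        error = function(err)
          data.frame(id = exc$id, molecule = exc$molecule %||% NA_character_,
                     functional = exc$functional %||% NA_character_,
                     energy = exc$energy, label = exc$label %||% NA_character_,
                     lambda = NA_real_, theta = NA_real_,
                     theta_prime = NA_real_, variance = NA_real_,
                     converged = NA, error = conditionMessage(err),
                     stringsAsFactors = FALSE))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a diagnostics table
#'
#' Builds feature matrices from a diagnostics table (derived columns
#' `log_lambda = log(lambda)` and `log_phi_s` are added on demand) and
#' evaluates a k-NN classifier per requested feature set.
#'
#' @param diagnostics a `data.frame` from [run_diagnostics()] with a
#'   `label` column; rows with missing labels or features are dropped.
#' @param feature_sets list of character vectors of column names; default
#'   mirrors the standard diagnostic planes.
#' @param k neighbors, default 13.
#' @param folds cross-validation folds (0 = resubstitution), default 5.
#' @param seed fold seed.
#' @return Named list, one [knn_cv()] result per feature set, plus
#'   `$class_counts`.
#' @export
run_classification <- function(diagnostics,
                               feature_sets = list(
                                 lambda = "lambda",
                                 theta = "theta",
                                 joint = c("theta", "lambda"),
                                 normalized = c("theta_prime", "log_lambda")),
                               k = 13, folds = 5, seed = 1) {
  df <- diagnostics
  if (!"label" %in% names(df)) stop("diagnostics table has no `label` column")
  if ("lambda" %in% names(df))
    df$log_lambda <- log(pmax(df$lambda, .Machine$double.xmin))
  if ("phi_s" %in% names(df))
    df$log_phi_s <- log10(pmax(df$phi_s, .Machine$double.xmin))
  out <- lapply(feature_sets, function(fs) {
    miss <- setdiff(fs, names(df))
    if (length(miss))
      stop("feature column(s) not in table: ", paste(miss, collapse = ", "))
    keep <- !is.na(df$label) &
      apply(as.matrix(df[, fs, drop = FALSE]), 1L,
            function(r) all(is.finite(r)))
    sub <- df[keep, , drop = FALSE]
    if (nrow(sub) <= k)
      stop("not enough labeled rows (", nrow(sub), ") for k = ", k)
    knn_cv(as.matrix(sub[, fs, drop = FALSE]), sub$label, k = k,
           folds = folds, seed = seed)
  })
  out$class_counts <- table(df$label[!is.na(df$label)])
  out
}
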