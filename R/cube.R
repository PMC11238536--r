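#' Read a Gaussian cube file
#'
#' Parses the standard cube dialect: two comment lines; an atom-count/origin
#' record; three axis records (voxel count and step vector); the atom block;
#' then values in Z-fastest order. A negative atom count signals the orbital
#' dialect, in which one extra record lists the orbital IDs held in the file
#' (only single-orbital files are supported). Positive axis counts mean bohr
#' units; the negative (angstrom) convention is rejected rather than
#' converted silently.
#'
#' @param path path to a cube file.
#' @return A `volumetric_field`; orbital IDs, when present, are kept in
#'   `$orbital_ids`.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop("malformed cube header in ", path, ": fewer than 7 lines")
  toks <- function(i) {
    t <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    t[nzchar(t)]
  }
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(toks(i)))
    if (any(is.na(v)))
      stop("malformed cube header in ", path, " at line ", i, " (", what, ")")
    v
  }
  h3 <- num(3L, "atom count / origin")
  if (length(h3) < 4L)
    stop("malformed cube header in ", path, " at line 3 (atom count / origin)")
  natoms_raw <- as.integer(h3[1L])
  has_orbitals <- natoms_raw < 0L
  natoms <- abs(natoms_raw)
  origin <- h3[2:4]

  shape <- integer(3L)
  spacing <- numeric(3L)
  for (k in 1:3) {
    hk <- num(3L + k, "axis record")
    if (length(hk) < 4L)
      stop("malformed cube header in ", path, " at line ", 3L + k,
           " (axis record)")
    n_ax <- as.integer(hk[1L])
    if (n_ax < 0L)
      stop("cube file ", path, " uses the angstrom (negative axis count) ",
           "convention; convert to bohr before reading")
    if (n_ax == 0L)
      stop("malformed cube header in ", path, ": zero-size axis")
    step <- hk[1L + k]  # diagonal element of the axis matrix
    off <- hk[2:4][-k]
    if (any(abs(off) > 1e-10))
      stop("cube file ", path, " has a non-axis-aligned grid; only ",
           "rectangular grids are supported")
    shape[k] <- n_ax
    spacing[k] <- step
  }
  if (any(spacing <= 0))
    stop("malformed cube header in ", path, ": non-positive grid step")

  atoms <- NULL
  cursor <- 7L
  if (natoms > 0L) {
    if (length(lines) < 6L + natoms)
      stop("truncated cube file ", path, ": atom block incomplete")
    ab <- matrix(NA_real_, natoms, 5L)
    for (i in seq_len(natoms)) {
      v <- num(6L + i, "atom record")
      if (length(v) < 5L)
        stop("malformed atom record in ", path, " at line ", 6L + i)
      ab[i, ] <- v[1:5]
    }
    atoms <- data.frame(number = as.integer(ab[, 1L]), charge = ab[, 2L],
                        x = ab[, 3L], y = ab[, 4L], z = ab[, 5L])
    cursor <- 7L + natoms
  }

  rest <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[seq.int(cursor, length(lines))]), "\\s+"))))
  rest <- rest[!is.na(rest)]

  orbital_ids <- NULL
  if (has_orbitals) {
    if (length(rest) < 1L)
      stop("truncated cube file ", path, ": missing orbital ID record")
    n_orb <- as.integer(rest[1L])
    if (n_orb != 1L)
      stop("cube file ", path, " holds ", n_orb,
           " orbitals; only single-orbital cubes are supported")
    orbital_ids <- as.integer(rest[2L])
    rest <- rest[-(1:2)]
  }

  n_expect <- prod(shape)
  if (length(rest) < n_expect)
    stop("truncated cube file ", path, ": expected ", n_expect,
         " values, found ", length(rest))
  vals <- rest[seq_len(n_expect)]
  # file order is x slowest, z fastest; R arrays are first-index-fastest
  values <- aperm(array(vals, dim = rev(shape)), 3:1)
  volumetric_field(values, origin, spacing, atoms = atoms,
                   orbital_ids = orbital_ids)
}

#' Write a Gaussian cube file
#'
#' Inverse of [read_cube()]: metadata round-trips exactly and values are
#' written with 13 significant digits, so write-then-read reproduces a field
#' to better than 1e-12.
#'
#' @param field a `volumetric_field`.
#' @param path output path.
#' @param comment character scalar for the first comment line.
#' @export
write_cube <- function(field, path,
                       comment = "cube written by excitOT") {
  stopifnot(inherits(field, "volumetric_field"))
  shape <- dim(field$values)
  if (any(shape < 1L)) stop("cannot write a zero-size grid")
  atoms <- field$atoms
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  has_orb <- !is.null(field$orbital_ids)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(comment, "scalar field on a regular grid (bohr)"), con)
  fmt <- function(n, v) sprintf("%5d %19.12E %19.12E %19.12E", n, v[1], v[2], v[3])
  writeLines(fmt(if (has_orb) -max(natoms, 1L) else natoms, field$origin), con)
  for (k in 1:3) {
    step <- c(0, 0, 0)
    step[k] <- field$spacing[k]
    writeLines(fmt(shape[k], step), con)
  }
  if (natoms > 0L) {
    for (i in seq_len(natoms))
      writeLines(sprintf("%5d %19.12E %19.12E %19.12E %19.12E",
                         atoms$number[i], atoms$charge[i],
                         atoms$x[i], atoms$y[i], atoms$z[i]), con)
  } else if (has_orb) {
    # orbital dialect requires at least one atom record; emit a dummy
    writeLines(sprintf("%5d %19.12E %19.12E %19.12E %19.12E", 0L, 0, 0, 0, 0),
               con)
  }
  if (has_orb)
    writeLines(paste(c(length(field$orbital_ids),
                       field$orbital_ids), collapse = "  "), con)
  vals <- as.vector(aperm(field$values, 3:1))  # z fastest
  lines <- vapply(split(vals, ceiling(seq_along(vals) / 6)),
                  function(v) paste(sprintf("%20.12E", v), collapse = " "),
                  character(1L))
  writeLines(lines, con)
  invisible(path)
}
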