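# Molecular configuration container, extended-XYZ and array-archive I/O, and
# cutoff neighbor lists.  Units throughout the package: coordinates in
# Angstrom, energies in kcal/mol, forces in kcal/mol/A.  Unit conversion is
# the caller's responsibility.

ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
              "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
              "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
              "Ga", "Ge", "As", "Se", "Br", "Kr")

# standard atomic weights (amu), indexed by atomic number
ATOMIC_MASSES <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007,
                   15.999, 18.998, 20.180, 22.990, 24.305, 26.982, 28.085,
                   30.974, 32.06, 35.45, 39.948, 39.098, 40.078, 44.956,
                   47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693,
                   63.546, 65.38, 69.723, 72.630, 74.922, 78.971, 79.904,
                   83.798)

element_to_z <- function(sym) {
  z <- match(sym, ELEMENTS)
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  z
}

#' Atomic configuration
#'
#' A single molecular configuration: atomic numbers, Cartesian coordinates in
#' Angstrom, and optional energy (kcal/mol) and per-atom force
#' (kcal/mol/Angstrom) labels.
#'
#' @param atomic_numbers positive integer vector of length N.
#' @param coordinates N x 3 numeric matrix, Angstrom.
#' @param energy optional scalar energy, kcal/mol.
#' @param forces optional N x 3 force matrix, kcal/mol/Angstrom.
#' @param identifier optional text label.
#' @return an object of class `atomic_configuration`.
#' @export
atomic_configuration <- function(atomic_numbers, coordinates, energy = NULL,
                                 forces = NULL, identifier = NULL) {
  atomic_numbers <- as.integer(atomic_numbers)
  coordinates <- matrix(as.numeric(coordinates), ncol = 3L)
  n <- length(atomic_numbers)
  if (n < 1L) stop("configuration needs at least one atom")
  if (any(atomic_numbers < 1L)) stop("atomic numbers must be positive")
  if (nrow(coordinates) != n) stop("coordinates must be N x 3")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (!is.null(energy)) {
    energy <- as.numeric(energy)
    stopifnot(length(energy) == 1L, is.finite(energy))
  }
  if (!is.null(forces)) {
    forces <- matrix(as.numeric(forces), ncol = 3L)
    if (!identical(dim(forces), dim(coordinates)))
      stop("forces must have the same shape as coordinates")
  }
  structure(list(atomic_numbers = atomic_numbers, coordinates = coordinates,
                 energy = energy, forces = forces, identifier = identifier),
            class = "atomic_configuration")
}

#' @export
print.atomic_configuration <- function(x, ...) {
  cat(sprintf("<atomic_configuration: %d atoms%s%s>\n",
              length(x$atomic_numbers),
              if (!is.null(x$energy)) sprintf(", E = %.6g kcal/mol", x$energy)
              else "",
              if (!is.null(x$forces)) ", with forces" else ""))
  invisible(x)
}

n_atoms <- function(config) length(config$atomic_numbers)

#' Atomic masses of a configuration
#' @param config an `atomic_configuration`.
#' @return numeric vector of masses in amu.
#' @export
config_masses <- function(config) {
  z <- config$atomic_numbers
  if (any(z > length(ATOMIC_MASSES)))
    stop("no tabulated mass for atomic number > ", length(ATOMIC_MASSES))
  ATOMIC_MASSES[z]
}

## ---- extended XYZ --------------------------------------------------------

#' Read a multi-frame extended-XYZ file
#'
#' Layout per frame: atom-count line; comment line optionally carrying
#' `E=<energy>`; then one line per atom with element symbol, x, y, z and
#' optionally three trailing force columns.
#'
#' @param path input file path.
#' @return list of [atomic_configuration()] objects (empty list for an empty
#'   file).
#' @export
read_xyz <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  ## trailing blank lines are tolerated
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  configs <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop(sprintf("malformed atom-count line %d: '%s'", pos, lines[pos]))
    if (pos + 1L + n > length(lines))
      stop(sprintf("truncated frame starting at line %d", pos))
    comment <- lines[pos + 1L]
    energy <- NULL
    em <- regmatches(comment,
                     regexec("E\\s*=\\s*(-?[0-9.eE+-]+)", comment))[[1]]
    if (length(em) == 2L) energy <- as.numeric(em[2])
    atom_lines <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    nf <- lengths(toks)
    if (!all(nf %in% c(4L, 7L)))
      stop(sprintf("frame at line %d: atom lines must have 4 or 7 fields",
                   pos))
    sym <- vapply(toks, `[[`, "", 1L)
    nums <- t(vapply(toks, function(tk) as.numeric(tk[-1L]),
                     numeric(nf[1] - 1L)))
    coords <- nums[, 1:3, drop = FALSE]
    forces <- if (nf[1] == 7L) nums[, 4:6, drop = FALSE] else NULL
    configs[[length(configs) + 1L]] <-
      atomic_configuration(element_to_z(sym), coords, energy, forces)
    pos <- pos + 2L + n
  }
  configs
}

#' Write configurations to a multi-frame extended-XYZ file
#'
#' @param configs list of [atomic_configuration()] (a single configuration is
#'   accepted too).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(configs, path) {
  if (inherits(configs, "atomic_configuration")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    n <- n_atoms(cf)
    writeLines(as.character(n), con)
    comment <- if (!is.null(cf$energy))
      sprintf("E=%.12g", cf$energy) else "frame"
    writeLines(comment, con)
    sym <- ELEMENTS[cf$atomic_numbers]
    for (i in seq_len(n)) {
      if (is.null(cf$forces)) {
        writeLines(sprintf("%s %.12g %.12g %.12g", sym[i],
                           cf$coordinates[i, 1], cf$coordinates[i, 2],
                           cf$coordinates[i, 3]), con)
      } else {
        writeLines(sprintf("%s %.12g %.12g %.12g %.12g %.12g %.12g", sym[i],
                           cf$coordinates[i, 1], cf$coordinates[i, 2],
                           cf$coordinates[i, 3], cf$forces[i, 1],
                           cf$forces[i, 2], cf$forces[i, 3]), con)
      }
    }
  }
  invisible(path)
}

## ---- array archives ------------------------------------------------------

#' Read an MD17-style compressed array archive
#'
#' Keys: `z` (N atomic numbers), `R` (frames x N x 3 coordinates), optional
#' `E` (frames) and `F` (frames x N x 3).
#'
#' @param path .npz archive path.
#' @return list of [atomic_configuration()], one per frame.
#' @export
read_array_archive <- function(path) {
  arrs <- read_npz(path)
  if (is.null(arrs$z) || is.null(arrs$R))
    stop("archive must contain 'z' and 'R' arrays")
  z <- as.integer(arrs$z)
  R <- arrs$R
  if (length(dim(R)) == 2L) R <- array(R, c(1L, dim(R)))
  nf <- dim(R)[1]
  if (dim(R)[2] != length(z) || dim(R)[3] != 3L)
    stop("'R' must be frames x N x 3 matching 'z'")
  E <- arrs$E
  if (!is.null(E) && length(E) != nf)
    stop("frame-count mismatch between 'E' and 'R'")
  Fr <- arrs[["F"]]
  if (!is.null(Fr)) {
    if (length(dim(Fr)) == 2L) Fr <- array(Fr, c(1L, dim(Fr)))
    if (!identical(dim(Fr), dim(R)))
      stop("frame-count/shape mismatch between 'F' and 'R'")
  }
  lapply(seq_len(nf), function(k) {
    atomic_configuration(z, R[k, , ],
                         energy = if (!is.null(E)) E[k] else NULL,
                         forces = if (!is.null(Fr)) Fr[k, , ] else NULL)
  })
}

#' Write configurations to an MD17-style array archive
#'
#' All configurations must share the same atomic-number vector.  Energies and
#' forces are written when present on every frame.
#'
#' @param configs list of [atomic_configuration()].
#' @param path output .npz path.
#' @return `path`, invisibly.
#' @export
write_array_archive <- function(configs, path) {
  if (inherits(configs, "atomic_configuration")) configs <- list(configs)
  stopifnot(length(configs) >= 1L)
  z <- configs[[1]]$atomic_numbers
  for (cf in configs) {
    if (!identical(cf$atomic_numbers, z))
      stop("all frames must share the same atomic-number vector")
  }
  n <- length(z); nf <- length(configs)
  R <- array(0, c(nf, n, 3L))
  for (k in seq_len(nf)) R[k, , ] <- configs[[k]]$coordinates
  arrays <- list(z = as.integer(z), R = R)
  if (all(vapply(configs, function(cf) !is.null(cf$energy), TRUE)))
    arrays$E <- vapply(configs, function(cf) cf$energy, 0)
  if (all(vapply(configs, function(cf) !is.null(cf$forces), TRUE))) {
    Fr <- array(0, c(nf, n, 3L))
    for (k in seq_len(nf)) Fr[k, , ] <- configs[[k]]$forces
    arrays[["F"]] <- Fr
  }
  write_npz(arrays, path)
}

## ---- neighbor list -------------------------------------------------------

#' Build a cutoff neighbor list
#'
#' All directed pairs (i, j), i != j, with 0 < |r_ij| <= cutoff (inclusive
#' boundary; the cosine cutoff used by the network vanishes exactly at the
#' boundary, so membership there cannot change predictions).  No periodic
#' boundary conditions.
#'
#' @param config an [atomic_configuration()].
#' @param cutoff cutoff radius in Angstrom (> 0).
#' @return object of class `neighbor_list`: list with `pairs` (E x 2 integer
#'   matrix of directed (i, j)), `displacement` (E x 3, r_ij = R_j - R_i),
#'   `distance` (length E), `cutoff`, `n_atoms`.
#' @export
build_neighbor_list <- function(config, cutoff) {
  stopifnot(cutoff > 0)
  X <- config$coordinates
  n <- nrow(X)
  if (n == 1L) {
    return(structure(list(pairs = matrix(integer(0), 0L, 2L),
                          displacement = matrix(numeric(0), 0L, 3L),
                          distance = numeric(0), cutoff = cutoff,
                          n_atoms = n),
                     class = "neighbor_list"))
  }
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[ij$i != ij$j, , drop = FALSE]
  disp <- X[ij$j, , drop = FALSE] - X[ij$i, , drop = FALSE]
  dist <- sqrt(rowSums(disp^2))
  if (any(dist < 1e-12))
    stop("zero-distance pair: two atoms at identical coordinates")
  keep <- dist <= cutoff
  structure(list(pairs = cbind(i = ij$i[keep], j = ij$j[keep]),
                 displacement = disp[keep, , drop = FALSE],
                 distance = dist[keep], cutoff = cutoff, n_atoms = n),
            class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat(sprintf("<neighbor_list: %d directed pairs, %d atoms, cutoff %.3g A>\n",
              nrow(x$pairs), x$n_atoms, x$cutoff))
  invisible(x)
}

## ---- dataset splits ------------------------------------------------------

#' Random train/validation/test split
#'
#' @param n_total number of configurations.
#' @param n_train,n_val training and validation sizes; the remainder is test.
#' @param seed RNG seed.
#' @return object of class `dataset_split` with disjoint index vectors
#'   `train`, `val`, `test` and the `seed`.
#' @export
dataset_split <- function(n_total, n_train, n_val, seed = 1L) {
  stopifnot(n_train + n_val <= n_total, n_train >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n_total)
  structure(list(train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[setdiff(seq_len(n_total),
                                          seq_len(n_train + n_val))]),
                 seed = as.integer(seed)),
            class = "dataset_split")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a dataset-split YAML manifest
#' @param split a `dataset_split`.
#' @param path manifest path.
#' @return `path` / a `dataset_split`.
#' @export
write_split_manifest <- function(split, path) {
  write_simple_yaml(list(train = split$train, val = split$val,
                         test = split$test, seed = split$seed), path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  y <- read_simple_yaml(path)
  structure(list(train = as.integer(unlist(y$train)),
                 val = as.integer(unlist(y$val)),
                 test = as.integer(unlist(y$test)),
                 seed = as.integer(y$seed)),
            class = "dataset_split")
}
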