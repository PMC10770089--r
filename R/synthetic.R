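# Synthetic fixtures: random atom clusters, analytic bonded toy potentials
# (harmonic bonds/angles + cosine dihedrals) with exact gradients, labeled
# datasets, and random rigid transforms.  These power every oracle, symmetry
# and learnability test in the package without any external data.

#' Random atom cluster
#'
#' Atoms placed uniformly in a cubic box with a minimum pairwise separation
#' (rejection sampling), species drawn from the light elements H/C/N/O.
#'
#' @param n_atoms number of atoms.
#' @param box_scale cube edge length, Angstrom.
#' @param min_separation minimum pairwise distance, Angstrom.
#' @param seed RNG seed.
#' @return an [atomic_configuration()].
#' @export
random_cluster <- function(n_atoms, box_scale = 4, min_separation = 0.8,
                           seed = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(NA_real_, n_atoms, 3L)
  for (i in seq_len(n_atoms)) {
    placed <- FALSE
    for (try in 1:2000) {
      p <- stats::runif(3, 0, box_scale)
      if (i == 1L ||
          min(sqrt(rowSums((X[seq_len(i - 1L), , drop = FALSE] -
                              matrix(p, i - 1L, 3L, byrow = TRUE))^2))) >=
          min_separation) {
        X[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed) stop("packing failure: box too small for min_separation")
  }
  z <- sample(c(1L, 6L, 7L, 8L), n_atoms, replace = TRUE)
  atomic_configuration(z, X)
}

## ---- toy bonded potentials ----------------------------------------------

#' Toy bonded potential specification
#'
#' Classical bonded terms: harmonic bonds `k (r - r0)^2`, harmonic angles
#' `k_theta (theta - theta0)^2` and cosine dihedrals
#' `k_phi (1 + cos(n phi - phase))`.
#'
#' @param atomic_numbers species of the reference molecule.
#' @param coordinates reference (equilibrium-like) N x 3 geometry, Angstrom.
#' @param bonds data.frame with columns `i, j, k, r0` (k in kcal/mol/A^2).
#' @param angles optional data.frame `i, j, k, ktheta, theta0` (vertex `j`,
#'   ktheta in kcal/mol/rad^2, theta0 in radians, 0 < theta0 < pi).
#' @param dihedrals optional data.frame `i, j, k, l, kphi, n, phase`
#'   (kphi kcal/mol, integer periodicity n, phase in radians).
#' @return object of class `toy_potential_spec`.
#' @export
toy_potential_spec <- function(atomic_numbers, coordinates, bonds,
                               angles = NULL, dihedrals = NULL) {
  stopifnot(all(bonds$k >= 0))
  if (!is.null(angles))
    stopifnot(all(angles$ktheta >= 0), all(angles$theta0 > 0),
              all(angles$theta0 < pi))
  structure(list(atomic_numbers = as.integer(atomic_numbers),
                 coordinates = matrix(as.numeric(coordinates), ncol = 3L),
                 bonds = bonds, angles = angles, dihedrals = dihedrals),
            class = "toy_potential_spec")
}

#' Toy potential energy and analytic forces
#'
#' @param config an [atomic_configuration()].
#' @param spec a [toy_potential_spec()]; term indices refer to atoms of
#'   `config`.
#' @return list with `energy` (kcal/mol) and `forces` (N x 3, kcal/mol/A).
#' @export
toy_energy_forces <- function(config, spec) {
  X <- config$coordinates
  n <- nrow(X)
  E <- 0
  G <- matrix(0, n, 3L)   # gradient dE/dX
  b <- spec$bonds
  for (r in seq_len(NROW(b))) {
    i <- b$i[r]; j <- b$j[r]
    d <- X[j, ] - X[i, ]
    len <- sqrt(sum(d^2))
    if (len < 1e-10) stop("degenerate bond: coincident atoms")
    E <- E + b$k[r] * (len - b$r0[r])^2
    dEdr <- 2 * b$k[r] * (len - b$r0[r])
    u <- d / len
    G[j, ] <- G[j, ] + dEdr * u
    G[i, ] <- G[i, ] - dEdr * u
  }
  a <- spec$angles
  for (r in seq_len(NROW(a))) {
    ia <- a$i[r]; ib <- a$j[r]; ic <- a$k[r]    # vertex ib
    u <- X[ia, ] - X[ib, ]
    v <- X[ic, ] - X[ib, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    if (lu < 1e-10 || lv < 1e-10) stop("degenerate angle: zero-length arm")
    uh <- u / lu; vh <- v / lv
    ct <- max(-1, min(1, sum(uh * vh)))
    st <- sqrt(max(0, 1 - ct^2))
    if (st < 1e-8) stop("degenerate angle: collinear arms")
    th <- acos(ct)
    E <- E + a$ktheta[r] * (th - a$theta0[r])^2
    dEdth <- 2 * a$ktheta[r] * (th - a$theta0[r])
    ## d(theta)/d(cos theta) = -1/sin(theta)
    dct_da <- (vh - ct * uh) / lu
    dct_dc <- (uh - ct * vh) / lv
    ga <- dEdth * (-1 / st) * dct_da
    gc <- dEdth * (-1 / st) * dct_dc
    G[ia, ] <- G[ia, ] + ga
    G[ic, ] <- G[ic, ] + gc
    G[ib, ] <- G[ib, ] - ga - gc
  }
  d <- spec$dihedrals
  for (r in seq_len(NROW(d))) {
    ia <- d$i[r]; ib <- d$j[r]; ic <- d$k[r]; id <- d$l[r]
    b1 <- X[ib, ] - X[ia, ]
    b2 <- X[ic, ] - X[ib, ]
    b3 <- X[id, ] - X[ic, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    lb2 <- sqrt(sum(b2^2))
    n1sq <- sum(n1^2); n2sq <- sum(n2^2)
    if (n1sq < 1e-14 || n2sq < 1e-14)
      stop("degenerate dihedral: collinear atoms")
    phi <- atan2(sum(cross3(n1, n2) * b2) / lb2, sum(n1 * n2))
    E <- E + d$kphi[r] * (1 + cos(d$n[r] * phi - d$phase[r]))
    dEdphi <- -d$kphi[r] * d$n[r] * sin(d$n[r] * phi - d$phase[r])
    ## standard dihedral gradient (Blondel & Karplus form)
    dphi_da <- -lb2 / n1sq * n1
    dphi_dd <-  lb2 / n2sq * n2
    s <- sum(b1 * b2) / lb2^2
    t <- sum(b3 * b2) / lb2^2
    dphi_db <- -(1 + s) * dphi_da + t * dphi_dd
    dphi_dc <- s * dphi_da - (1 + t) * dphi_dd
    G[ia, ] <- G[ia, ] + dEdphi * dphi_da
    G[ib, ] <- G[ib, ] + dEdphi * dphi_db
    G[ic, ] <- G[ic, ] + dEdphi * dphi_dc
    G[id, ] <- G[id, ] + dEdphi * dphi_dd
  }
  list(energy = E, forces = -G)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Toy potential as a potential function
#'
#' Wraps a [toy_potential_spec()] into the `function(config) ->
#' list(energy, forces)` interface used by the MD driver.
#'
#' @param spec a [toy_potential_spec()].
#' @return a potential function.
#' @export
make_toy_potential <- function(spec) {
  force(spec)
  function(config) toy_energy_forces(config, spec)
}

#' Generate a labeled synthetic dataset
#'
#' Gaussian displacements around the spec's reference geometry, each frame
#' labeled with the exact toy energy and forces.
#'
#' @param spec a [toy_potential_spec()].
#' @param n_frames number of frames.
#' @param displacement_scale per-coordinate Gaussian sigma, Angstrom.
#' @param seed RNG seed.
#' @return list of labeled [atomic_configuration()]s.
#' @export
generate_dataset <- function(spec, n_frames, displacement_scale = 0.05,
                             seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X0 <- spec$coordinates
  lapply(seq_len(n_frames), function(k) {
    X <- X0 + matrix(stats::rnorm(length(X0), sd = displacement_scale),
                     nrow(X0), 3L)
    cf <- atomic_configuration(spec$atomic_numbers, X)
    ef <- toy_energy_forces(cf, spec)
    cf$energy <- ef$energy
    cf$forces <- ef$forces
    cf
  })
}

## ---- rigid transforms ----------------------------------------------------

#' Random rigid transform (rotation, translation, permutation)
#'
#' Rotation drawn uniformly from SO(3) via unit quaternions, translation
#' uniform in [-5, 5]^3 Angstrom, permutation uniform over atom orderings.
#'
#' @param n_atoms number of atoms (for the permutation).
#' @param seed RNG seed.
#' @param translate,permute set `FALSE` to disable those parts.
#' @return object of class `rigid_transform` with fields `rotation` (3 x 3,
#'   det +1), `translation` (length 3), `permutation` (length `n_atoms`).
#' @export
random_rigid_transform <- function(n_atoms, seed = NULL, translate = TRUE,
                                   permute = TRUE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3L, 3L, byrow = TRUE)
  structure(list(rotation = R,
                 translation = if (translate) stats::runif(3, -5, 5)
                 else c(0, 0, 0),
                 permutation = if (permute) sample.int(n_atoms)
                 else seq_len(n_atoms)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a configuration
#'
#' Coordinates are rotated and translated, forces rotated, and atoms
#' reordered by the permutation; the energy is unchanged.
#'
#' @param config an [atomic_configuration()].
#' @param tr a `rigid_transform`.
#' @return the transformed [atomic_configuration()].
#' @export
apply_transform <- function(config, tr) {
  p <- tr$permutation
  X <- config$coordinates %*% t(tr$rotation)
  X <- sweep(X, 2L, -tr$translation)
  Fm <- if (!is.null(config$forces)) config$forces %*% t(tr$rotation) else NULL
  atomic_configuration(config$atomic_numbers[p], X[p, , drop = FALSE],
                       energy = config$energy,
                       forces = if (!is.null(Fm)) Fm[p, , drop = FALSE]
                       else NULL,
                       identifier = config$identifier)
}

#' Inverse of a rigid transform
#' @param tr a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  inv_p <- order(tr$permutation)
  structure(list(rotation = t(tr$rotation),
                 translation = -drop(t(tr$rotation) %*% tr$translation),
                 permutation = inv_p),
            class = "rigid_transform")
}

## ---- the frozen recovery fixture ----------------------------------------

#' The frozen parameter-recovery fixture
#'
#' A 4-atom chain (C-C-C-C) with three harmonic bonds (k = 300 kcal/mol/A^2,
#' r0 = 1.5 A), two harmonic angles (k = 60 kcal/mol/rad^2, theta0 = 109.47
#' deg) and one 3-fold cosine dihedral (k = 3 kcal/mol, phase 0), plus the
#' dataset sizes used by the learnability acceptance test: 50 training and 10
#' validation frames of 0.05 A Gaussian displacements at seed 7, and a small
#' reference model (2 blocks, 64 channels).
#'
#' @return list with `spec` ([toy_potential_spec()]), `n_train`, `n_val`,
#'   `displacement_scale`, `seed`, `model_blocks`, `model_dim`.
#' @export
reference_fixture <- function() {
  r0 <- 1.5; th0 <- acos(-1 / 3)            # 109.47 deg tetrahedral
  ## chain built with bond length r0, both angles th0, dihedral ~60 deg
  x1 <- c(0, 0, 0)
  x2 <- c(r0, 0, 0)
  x3 <- x2 + r0 * c(-cos(th0), sin(th0), 0)
  ## place atom 4 at bond length from x3, angle th0 at x3, dihedral 60 deg
  phi <- pi / 3
  e1 <- (x3 - x2) / r0
  axis <- cross3(c(0, 0, 1), e1)            # in-plane normal reference
  b2h <- e1
  n_ref <- cross3(x2 - x1, x3 - x2); n_ref <- n_ref / sqrt(sum(n_ref^2))
  m_ref <- cross3(n_ref, b2h)
  d_dir <- -cos(th0) * b2h +
    sin(th0) * (cos(phi) * m_ref + sin(phi) * n_ref)
  x4 <- x3 + r0 * d_dir
  coords <- rbind(x1, x2, x3, x4)
  spec <- toy_potential_spec(
    atomic_numbers = c(6L, 6L, 6L, 6L),
    coordinates = coords,
    bonds = data.frame(i = 1:3, j = 2:4, k = 300, r0 = r0),
    angles = data.frame(i = c(1L, 2L), j = c(2L, 3L), k = c(3L, 4L),
                        ktheta = 60, theta0 = th0),
    dihedrals = data.frame(i = 1L, j = 2L, k = 3L, l = 4L,
                           kphi = 3, n = 3L, phase = 0))
  list(spec = spec, n_train = 50L, n_val = 10L, displacement_scale = 0.05,
       seed = 7L, model_blocks = 2L, model_dim = 64L)
}
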