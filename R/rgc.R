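# Runtime geometry calculation (RGC).
#
# Per-atom "direction units" v_i = sum_j u_ij (u_ij the unit vector from atom
# i to neighbor j) carry all neighborhood orientation information.  Inner
# products of v_i and of its vector rejections recover, in time linear in the
# edge count, the same angle / dihedral-torsion / improper cosine sums that a
# naive enumeration computes in O(N^2)-O(N^3):
#
#   <v_i, v_i>                         = sum_{j,k} cos(theta_jik)
#   <Rej_{u_ij} v_i, Rej_{u_ji} v_j>   = sum_{m,n} cos-weighted dihedral terms
#   <Rej_{u_ij} v_i, Rej_{u_ji} v_i>   = improper terms at vertex i
#
# The explicit enumeration oracles live alongside and are the module's core
# cross-check.  A real spherical-harmonics expansion extends the angle
# pathway to higher orders l through the addition theorem, without any
# Clebsch-Gordan products.

#' Direction units
#'
#' Sum of unit vectors from each atom to all its within-cutoff neighbors;
#' isolated atoms get the zero vector.
#'
#' @param nlist a `neighbor_list` from [build_neighbor_list()].
#' @param n_atoms number of atoms (defaults to the neighbor list's).
#' @return N x 3 matrix of direction units v_i.
#' @export
direction_units <- function(nlist, n_atoms = nlist$n_atoms) {
  v <- matrix(0, n_atoms, 3L)
  if (nrow(nlist$pairs) == 0L) return(v)
  u <- nlist$displacement / nlist$distance
  agg <- rowsum(u, group = nlist$pairs[, 1L], reorder = TRUE)
  v[as.integer(rownames(agg)), ] <- agg
  v
}

#' Per-node angle scalar
#'
#' `<v_i, v_i>`: the sum over all ordered neighbor pairs (j, k) of
#' cos(theta_jik), diagonal terms j = k included (each contributes 1).
#'
#' @param v N x 3 direction-unit matrix.
#' @return numeric vector of length N.
#' @export
angle_scalar <- function(v) rowSums(v^2)

#' Vector rejection
#'
#' Component of `a` perpendicular to `b`: `a - <a, b_hat> b_hat`.  Invariant
#' to positive scaling and to sign flips of the axis `b`.
#'
#' @param a numeric 3-vector (or n x 3 matrix of vectors).
#' @param b nonzero numeric 3-vector (axis).
#' @return same shape as `a`.
#' @export
vector_rejection <- function(a, b) {
  nb <- sqrt(sum(b^2))
  if (nb <= 0) stop("rejection axis must be nonzero")
  bh <- b / nb
  if (is.matrix(a)) {
    a - outer(drop(a %*% bh), bh)
  } else {
    a - sum(a * bh) * bh
  }
}

#' Per-edge dihedral scalar
#'
#' For each directed edge (i, j):
#' `<Rej_{u_ij}(v_i), Rej_{u_ji}(v_j)>`, which equals the double sum over
#' m in N(i), n in N(j) of the inner products of the individually rejected
#' unit vectors (terms with m = j or n = i vanish since their rejections are
#' zero).
#'
#' @param v N x 3 direction-unit matrix computed from `nlist`.
#' @param nlist the same `neighbor_list`.
#' @return numeric vector, one value per directed pair in `nlist$pairs`.
#' @export
dihedral_scalar <- function(v, nlist) {
  E <- nrow(nlist$pairs)
  if (E == 0L) return(numeric(0))
  u <- nlist$displacement / nlist$distance
  i <- nlist$pairs[, 1L]; j <- nlist$pairs[, 2L]
  vi <- v[i, , drop = FALSE]; vj <- v[j, , drop = FALSE]
  ## Rej against u and against -u coincide, so both rejections use u_ij
  wi <- vi - rowSums(vi * u) * u
  wj <- vj - rowSums(vj * u) * u
  rowSums(wi * wj)
}

#' Per-edge improper scalar
#'
#' For each directed edge (i, j): `<Rej_{u_ij}(v_i), Rej_{u_ji}(v_i)>`.
#' Both rejections act on the vertex's own direction unit v_i, and since
#' rejection is insensitive to the axis sign this equals
#' `|Rej_{u_ij}(v_i)|^2` — the vertex-centred improper-angle sum.
#'
#' @inheritParams dihedral_scalar
#' @return numeric vector, one value per directed pair.
#' @export
improper_scalar <- function(v, nlist) {
  E <- nrow(nlist$pairs)
  if (E == 0L) return(numeric(0))
  u <- nlist$displacement / nlist$distance
  i <- nlist$pairs[, 1L]
  vi <- v[i, , drop = FALSE]
  ti <- vi - rowSums(vi * u) * u
  rowSums(ti * ti)
}

#' Geometry scalars of a configuration
#'
#' Convenience wrapper computing direction units and all three RGC scalars.
#'
#' @param config an [atomic_configuration()].
#' @param cutoff neighbor cutoff, Angstrom.
#' @return list with `v`, `angle` (per node), `dihedral` and `improper` (per
#'   directed edge), and the `neighbor_list`.
#' @export
geometry_scalars <- function(config, cutoff) {
  nlist <- build_neighbor_list(config, cutoff)
  v <- direction_units(nlist)
  list(v = v, angle = angle_scalar(v),
       dihedral = dihedral_scalar(v, nlist),
       improper = improper_scalar(v, nlist),
       neighbor_list = nlist)
}

## ---- spherical harmonics -------------------------------------------------

#' Associated Legendre values P_l^m(x) for l = 0..l_max, m = 0..l
#'
#' Standard recurrences, WITHOUT the Condon-Shortley phase.
#'
#' @param x scalar in [-1, 1].
#' @param l_max maximum degree.
#' @return list indexed by l+1; element l+1 is the vector P_l^0..P_l^l.
#' @keywords internal
assoc_legendre <- function(x, l_max) {
  P <- vector("list", l_max + 1L)
  P[[1]] <- 1
  if (l_max == 0L) return(P)
  somx2 <- sqrt(max(0, 1 - x^2))
  for (l in 1:l_max) {
    P[[l + 1L]] <- numeric(l + 1L)
    for (m in 0:l) {
      if (m == l) {
        ## P_l^l = (2l-1)!! (1-x^2)^{l/2}   (no (-1)^l phase)
        P[[l + 1L]][m + 1L] <- prod(seq(1, 2 * l - 1, by = 2)) * somx2^l
      } else if (m == l - 1L) {
        P[[l + 1L]][m + 1L] <- x * (2 * m + 1) * P[[l]][m + 1L]
      } else {
        P[[l + 1L]][m + 1L] <-
          ((2 * l - 1) * x * P[[l]][m + 1L] -
             (l + m - 1) * P[[l - 1L]][m + 1L]) / (l - m)
      }
    }
  }
  P
}

#' Legendre polynomial P_l(x)
#'
#' Bonnet recurrence; used by the addition-theorem oracle and the enumeration
#' oracle for high-order angle scalars.
#'
#' @param x numeric vector in [-1, 1].
#' @param l degree (>= 0).
#' @return P_l evaluated at `x`.
#' @export
legendre_p <- function(x, l) {
  if (l == 0L) return(rep(1, length(x)))
  if (l == 1L) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:l) {
    p <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- p
  }
  pm1
}

#' Real spherical harmonics of a unit vector
#'
#' Orthonormal real spherical harmonics Y_{l,m}, l = 0..l_max, without the
#' Condon-Shortley phase.  They satisfy the addition theorem
#' `sum_m Y_{l,m}(a) Y_{l,m}(b) = (2l+1)/(4 pi) P_l(a . b)`.
#'
#' @param u unit 3-vector (|u| = 1 within 1e-8).
#' @param l_max maximum order, 1..4 supported.
#' @return list of class `spherical_expansion`: per order l (index l+1) a
#'   numeric vector of the 2l+1 values, m = -l..l.
#' @export
spherical_harmonics <- function(u, l_max) {
  stopifnot(l_max >= 0L, l_max <= 4L)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-8)
    stop("spherical_harmonics expects a unit vector")
  x <- u[1]; y <- u[2]; z <- u[3]
  ct <- z                                   # cos(theta)
  rho <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  P <- assoc_legendre(ct, l_max)
  out <- vector("list", l_max + 1L)
  for (l in 0:l_max) {
    vals <- numeric(2L * l + 1L)
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lfactorial(l - m) - lfactorial(l + m)))
      plm <- P[[l + 1L]][m + 1L]
      if (m == 0L) {
        vals[l + 1L] <- nrm * plm
      } else {
        vals[l + 1L + m] <- sqrt(2) * nrm * plm * cos(m * phi)
        vals[l + 1L - m] <- sqrt(2) * nrm * plm * sin(m * phi)
      }
    }
    out[[l + 1L]] <- vals
  }
  structure(out, class = "spherical_expansion", l_max = l_max)
}

#' Expanded (high-order) direction units
#'
#' Per order l = 1..l_max, the per-atom sum of real spherical harmonics of
#' the neighbor unit vectors: `V_i^{(l)} = sum_j Y_l(u_ij)`.  Order 1
#' reproduces the geometric direction units up to the fixed constant
#' sqrt(3 / (4 pi)).
#'
#' @inheritParams direction_units
#' @param l_max maximum order (1..4).
#' @return list per order l (index l) of N x (2l+1) matrices.
#' @export
expand_direction_units <- function(nlist, l_max, n_atoms = nlist$n_atoms) {
  stopifnot(l_max >= 1L, l_max <= 4L)
  out <- lapply(1:l_max, function(l) matrix(0, n_atoms, 2L * l + 1L))
  E <- nrow(nlist$pairs)
  if (E == 0L) return(out)
  u <- nlist$displacement / nlist$distance
  for (e in seq_len(E)) {
    Y <- spherical_harmonics(u[e, ], l_max)
    i <- nlist$pairs[e, 1L]
    for (l in 1:l_max) out[[l]][i, ] <- out[[l]][i, ] + Y[[l + 1L]]
  }
  out
}

#' High-order angle scalar
#'
#' Summed per-order inner products of the expanded direction units:
#' `sum_l <V_i^{(l)}, V_i^{(l)}>`.  By the addition theorem this equals
#' `sum_l (2l+1)/(4 pi) sum_{j,k} P_l(cos theta_jik)`.
#'
#' @param v_expanded output of [expand_direction_units()].
#' @return numeric vector of per-node scalars.
#' @export
high_order_angle_scalar <- function(v_expanded) {
  Reduce(`+`, lapply(v_expanded, function(V) rowSums(V^2)))
}

## ---- enumeration oracles -------------------------------------------------

oracle_guard <- function(config) {
  if (n_atoms(config) > 50L)
    stop("enumeration oracles are O(N^2)-O(N^3); use N <= 50")
}

neighbor_sets <- function(nlist) {
  n <- nlist$n_atoms
  u <- nlist$displacement / nlist$distance
  lapply(seq_len(n), function(i) {
    sel <- which(nlist$pairs[, 1L] == i)
    list(j = nlist$pairs[sel, 2L], u = u[sel, , drop = FALSE])
  })
}

#' Enumeration oracle for the angle scalar
#'
#' Explicit double loop over ordered neighbor pairs (j, k) of each node,
#' summing cos(theta_jik); never touches direction units.
#'
#' @param config an [atomic_configuration()] with N <= 50.
#' @param cutoff neighbor cutoff, Angstrom.
#' @return per-node numeric vector.
#' @export
oracle_angle_sum <- function(config, cutoff) {
  oracle_guard(config)
  nlist <- build_neighbor_list(config, cutoff)
  ns <- neighbor_sets(nlist)
  vapply(ns, function(s) {
    if (length(s$j) == 0L) return(0)
    total <- 0
    for (a in seq_along(s$j)) {
      total <- total + sum(drop(s$u %*% s$u[a, ]))  # cos theta over all k
    }
    total
  }, 0)
}

#' Enumeration oracle for the dihedral scalar
#'
#' For each directed edge (i, j), loops over m in N(i) and n in N(j),
#' rejecting each unit vector individually against the edge axis and summing
#' the pairwise inner products.
#'
#' @inheritParams oracle_angle_sum
#' @return per-directed-edge numeric vector (ordered as the neighbor list).
#' @export
oracle_dihedral_sum <- function(config, cutoff) {
  oracle_guard(config)
  nlist <- build_neighbor_list(config, cutoff)
  ns <- neighbor_sets(nlist)
  u <- nlist$displacement / nlist$distance
  E <- nrow(nlist$pairs)
  out <- numeric(E)
  for (e in seq_len(E)) {
    i <- nlist$pairs[e, 1L]; j <- nlist$pairs[e, 2L]
    axis <- u[e, ]
    Ri <- vector_rejection(ns[[i]]$u, axis)     # rejections of each u_im
    Rj <- vector_rejection(ns[[j]]$u, -axis)    # rejections of each u_jn
    total <- 0
    for (a in seq_len(nrow(Ri))) total <- total + sum(drop(Rj %*% Ri[a, ]))
    out[e] <- total
  }
  out
}

#' Enumeration oracle for the improper scalar
#'
#' For each directed edge (i, j), loops over pairs (m, n) of neighbors of the
#' vertex i, rejecting u_im against the edge axis and u_in against the
#' reversed axis.
#'
#' @inheritParams oracle_angle_sum
#' @return per-directed-edge numeric vector.
#' @export
oracle_improper_sum <- function(config, cutoff) {
  oracle_guard(config)
  nlist <- build_neighbor_list(config, cutoff)
  ns <- neighbor_sets(nlist)
  u <- nlist$displacement / nlist$distance
  E <- nrow(nlist$pairs)
  out <- numeric(E)
  for (e in seq_len(E)) {
    i <- nlist$pairs[e, 1L]
    axis <- u[e, ]
    Rm <- vector_rejection(ns[[i]]$u, axis)
    Rn <- vector_rejection(ns[[i]]$u, -axis)
    total <- 0
    for (a in seq_len(nrow(Rm))) total <- total + sum(drop(Rn %*% Rm[a, ]))
    out[e] <- total
  }
  out
}

#' Enumeration oracle for the high-order angle scalar
#'
#' Direct Legendre sum `sum_l (2l+1)/(4 pi) sum_{j,k} P_l(cos theta_jik)`
#' over explicit neighbor pairs, orders 1..l_max.
#'
#' @inheritParams oracle_angle_sum
#' @param l_max maximum order.
#' @return per-node numeric vector.
#' @export
oracle_high_order_angle_sum <- function(config, cutoff, l_max) {
  oracle_guard(config)
  nlist <- build_neighbor_list(config, cutoff)
  ns <- neighbor_sets(nlist)
  vapply(ns, function(s) {
    if (length(s$j) == 0L) return(0)
    total <- 0
    for (a in seq_along(s$j)) {
      ct <- pmin(1, pmax(-1, drop(s$u %*% s$u[a, ])))
      for (l in 1:l_max) {
        total <- total + (2 * l + 1) / (4 * pi) * sum(legendre_p(ct, l))
      }
    }
    total
  }, 0)
}
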