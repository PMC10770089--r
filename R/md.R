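# Minimal molecular-dynamics driver: velocity Verlet, optional Berendsen
# weak-coupling thermostat, Maxwell-Boltzmann initialization, and the
# interatomic distance distribution h(r) used to validate simulations.
#
# Unit system: Angstrom, femtosecond, amu, kcal/mol.  One kcal/mol equals
# KCAL_PER_AKMA amu A^2/fs^2 (4184 J/mol divided by 1e7 J/mol per
# amu A^2/fs^2), so accelerations are F * KCAL_PER_AKMA / m.

#' Unit conversion: kcal/mol per amu A^2/fs^2
#' @export
KCAL_PER_AKMA <- 4.184e-4

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCALMOL <- 1.987204259e-3

#' Molecular-dynamics state
#'
#' @param config an [atomic_configuration()] providing species and positions.
#' @param velocities N x 3 matrix, A/fs (default zero).
#' @param masses per-atom masses, amu (default from the species table).
#' @param timestep integration step, fs (default 0.5).
#' @param thermostat "none" (NVE) or "berendsen".
#' @param temperature_target target temperature, K.
#' @param coupling_time Berendsen coupling time, fs (default 100).
#' @return object of class `md_state`.
#' @export
md_state <- function(config, velocities = NULL, masses = NULL,
                     timestep = 0.5, thermostat = c("none", "berendsen"),
                     temperature_target = 300, coupling_time = 100) {
  thermostat <- match.arg(thermostat)
  n <- n_atoms(config)
  if (is.null(masses)) masses <- config_masses(config)
  stopifnot(all(masses > 0), timestep > 0, coupling_time > 0)
  if (is.null(velocities)) velocities <- matrix(0, n, 3L)
  velocities <- matrix(as.numeric(velocities), n, 3L)
  structure(list(config = config, velocities = velocities, masses = masses,
                 time = 0, timestep = timestep, thermostat = thermostat,
                 temperature_target = temperature_target,
                 coupling_time = coupling_time),
            class = "md_state")
}

#' Kinetic energy of an MD state, kcal/mol
#' @param state an `md_state`.
#' @return scalar kinetic energy.
#' @export
kinetic_energy <- function(state) {
  0.5 * sum(state$masses * rowSums(state$velocities^2)) / KCAL_PER_AKMA
}

#' Instantaneous temperature, K
#'
#' Uses 3N - 3 degrees of freedom (net momentum is removed at
#' initialization).
#'
#' @param state an `md_state`.
#' @return temperature in K.
#' @export
instantaneous_temperature <- function(state) {
  dof <- max(1L, 3L * length(state$masses) - 3L)
  2 * kinetic_energy(state) / (dof * KB_KCALMOL)
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Gaussian velocities at the target temperature with the net momentum
#' removed, then rescaled to hit the target exactly.
#'
#' @param state an `md_state`.
#' @param temperature target temperature, K.
#' @param seed RNG seed.
#' @return the `md_state` with velocities set.
#' @export
maxwell_boltzmann_velocities <- function(state, temperature, seed = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  n <- length(state$masses)
  sigma <- sqrt(KB_KCALMOL * temperature * KCAL_PER_AKMA / state$masses)
  v <- matrix(stats::rnorm(3L * n), n, 3L) * sigma
  ## remove net momentum
  p <- colSums(v * state$masses)
  v <- v - matrix(p / sum(state$masses), n, 3L, byrow = TRUE)
  state$velocities <- v
  t_now <- instantaneous_temperature(state)
  if (t_now > 0) state$velocities <- v * sqrt(temperature / t_now)
  state
}

#' One velocity-Verlet step
#'
#' @param state an `md_state`.
#' @param potential `function(config) -> list(energy, forces)` with forces
#'   the negative energy gradient.
#' @param forces optional pre-computed forces at the current positions
#'   (saves one evaluation inside loops).
#' @return the advanced `md_state`, with the end-of-step `forces` and
#'   `potential_energy` attached.
#' @export
velocity_verlet_step <- function(state, potential, forces = NULL) {
  dt <- state$timestep
  m <- state$masses
  if (is.null(forces)) forces <- potential(state$config)$forces
  acc <- sweep(forces * KCAL_PER_AKMA, 1L, m, "/")
  vh <- state$velocities + 0.5 * dt * acc
  state$config$coordinates <- state$config$coordinates + dt * vh
  ef <- potential(state$config)
  acc2 <- sweep(ef$forces * KCAL_PER_AKMA, 1L, m, "/")
  state$velocities <- vh + 0.5 * dt * acc2
  state$time <- state$time + dt
  state$forces <- ef$forces
  state$potential_energy <- ef$energy
  state
}

#' Berendsen weak-coupling velocity rescale
#'
#' `lambda = sqrt(1 + (dt/tau_c)(T_target/T_inst - 1))`; skipped with a
#' warning when the kinetic energy is zero.
#'
#' @param state an `md_state`.
#' @param target_T target temperature, K (default: the state's).
#' @param coupling_time coupling time tau_c, fs (default: the state's).
#' @return the rescaled `md_state`.
#' @export
berendsen_rescale <- function(state, target_T = state$temperature_target,
                              coupling_time = state$coupling_time) {
  t_inst <- instantaneous_temperature(state)
  if (t_inst <= 0) {
    warning("zero kinetic energy: Berendsen rescale skipped")
    return(state)
  }
  lambda <- sqrt(1 + (state$timestep / coupling_time) *
                   (target_T / t_inst - 1))
  state$velocities <- state$velocities * lambda
  state
}

#' Run a molecular-dynamics trajectory
#'
#' Velocity Verlet, optionally Berendsen-thermostatted; velocities are
#' Maxwell-Boltzmann initialized at the target temperature unless the state
#' already carries nonzero velocities.
#'
#' @param initial an [atomic_configuration()] or `md_state`.
#' @param potential `function(config) -> list(energy, forces)`.
#' @param steps number of integration steps.
#' @param timestep fs (default 0.5); ignored when `initial` is an
#'   `md_state`.
#' @param thermostat "none" or "berendsen".
#' @param temperature target temperature for initialization/thermostat, K.
#' @param coupling_time Berendsen coupling time, fs.
#' @param seed RNG seed for velocity initialization.
#' @param stride keep every `stride`-th frame (frame 0 always kept).
#' @return object of class `md_trajectory`: list with `frames` (list of
#'   [atomic_configuration()] with energies attached), `times`,
#'   `temperatures`, `total_energies` (kinetic + potential, kcal/mol), and
#'   the final `state`.
#' @export
run_md <- function(initial, potential, steps, timestep = 0.5,
                   thermostat = c("none", "berendsen"), temperature = 300,
                   coupling_time = 100, seed = 1L, stride = 1L) {
  thermostat <- match.arg(thermostat)
  state <- if (inherits(initial, "md_state")) initial else {
    md_state(initial, timestep = timestep, thermostat = thermostat,
             temperature_target = temperature, coupling_time = coupling_time)
  }
  if (all(state$velocities == 0) && temperature > 0)
    state <- maxwell_boltzmann_velocities(state, temperature, seed = seed)
  ef <- potential(state$config)
  frames <- list(); times <- numeric(0); temps <- numeric(0)
  etot <- numeric(0)
  snap <- function(state, e_pot) {
    cf <- state$config
    cf$energy <- e_pot
    frames[[length(frames) + 1L]] <<- cf
    times <<- c(times, state$time)
    temps <<- c(temps, instantaneous_temperature(state))
    etot <<- c(etot, e_pot + kinetic_energy(state))
  }
  snap(state, ef$energy)
  forces <- ef$forces
  for (k in seq_len(steps)) {
    state <- velocity_verlet_step(state, potential, forces = forces)
    if (!all(is.finite(state$config$coordinates)))
      stop("NaN coordinates at step ", k)
    if (thermostat == "berendsen") state <- berendsen_rescale(state)
    forces <- state$forces
    if (k %% stride == 0L) snap(state, state$potential_energy)
  }
  structure(list(frames = frames, times = times, temperatures = temps,
                 total_energies = etot, state = state),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d frames, %.4g fs>\n",
              length(x$frames), max(x$times)))
  invisible(x)
}

#' Interatomic distance distribution h(r)
#'
#' Histogram density of all interatomic pair distances, averaged over
#' trajectory frames: the ensemble average of atomic density at radius r.
#'
#' @param traj an `md_trajectory` or list of [atomic_configuration()]s.
#' @param grid strictly increasing bin-edge vector, Angstrom (default
#'   0..6 A in 0.05 A bins).
#' @return object of class `distance_distribution`: list with `r` (bin
#'   centers), `h` (density, normalized to unit integral), `ensemble_size`.
#' @export
distance_distribution <- function(traj, grid = seq(0, 6, by = 0.05)) {
  frames <- if (inherits(traj, "md_trajectory")) traj$frames else traj
  stopifnot(length(frames) >= 1L, all(diff(grid) > 0))
  counts <- numeric(length(grid) - 1L)
  for (cf in frames) {
    d <- as.vector(stats::dist(cf$coordinates))
    counts <- counts + graphics::hist(d[d >= grid[1] & d <= grid[length(grid)]],
                                      breaks = grid, plot = FALSE)$counts
  }
  widths <- diff(grid)
  dens <- counts / (sum(counts) * widths)
  structure(list(r = grid[-length(grid)] + widths / 2, h = dens,
                 ensemble_size = length(frames)),
            class = "distance_distribution")
}

#' Write an h(r) table
#' @param dd a `distance_distribution`.
#' @param path output path for the two-column (r, h) text table.
#' @return `path`, invisibly.
#' @export
write_distance_distribution <- function(dd, path) {
  utils::write.table(data.frame(r = dd$r, h = dd$h), path,
                     row.names = FALSE, col.names = c("r", "h"),
                     quote = FALSE)
  invisible(path)
}
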