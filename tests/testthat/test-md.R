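test_that("unit conversion constant matches the hand-computed value", {
  ## 1 kcal/mol = 4184 J/mol; 1 amu A^2/fs^2 = 1e-3 kg/mol * 1e10 m^2/s^2
  expect_equal(KCAL_PER_AKMA, 4184 / 1e7)
})

test_that("zero forces give uniform linear motion", {
  cf <- atomic_configuration(c(6L, 6L), rbind(c(0, 0, 0), c(10, 0, 0)))
  free <- function(config) list(energy = 0,
                                forces = matrix(0, 2L, 3L))
  st <- md_state(cf, velocities = rbind(c(0.01, 0, 0), c(0, 0.02, 0)),
                 timestep = 0.5)
  for (k in 1:10) st <- velocity_verlet_step(st, free)
  expect_equal(st$config$coordinates[1L, 1L], 0.01 * 5, tolerance = 1e-12)
  expect_equal(st$config$coordinates[2L, 2L], 0.02 * 5, tolerance = 1e-12)
})

test_that("harmonic diatomic matches the closed-form cosine", {
  k <- 100; r0 <- 1; m <- 12.011
  sp <- diatomic_spec(k = k, r0 = r0)
  pot <- make_toy_potential(sp)
  a0 <- 0.05
  cf <- atomic_configuration(c(6L, 6L),
                             rbind(c(0, 0, 0), c(r0 + a0, 0, 0)))
  st <- md_state(cf, timestep = 0.01)
  ## relative coordinate: reduced mass mu, spring constant 2k
  mu <- m / 2
  omega <- sqrt(2 * k * KCAL_PER_AKMA / mu)
  ts <- numeric(100); xs <- numeric(100)
  for (s in 1:100) {
    st <- velocity_verlet_step(st, pot)
    ts[s] <- st$time
    xs[s] <- st$config$coordinates[2L, 1L] - st$config$coordinates[1L, 1L]
  }
  expect_lt(max(abs(xs - (r0 + a0 * cos(omega * ts)))) / a0, 1e-4)
})

test_that("NVE conserves total energy on the toy potential", {
  fx <- reference_fixture()
  pot <- make_toy_potential(fx$spec)
  cf <- generate_dataset(fx$spec, 1L, 0.03, seed = 5L)[[1L]]
  traj <- run_md(cf, pot, steps = 1000L, timestep = 0.1,
                 thermostat = "none", temperature = 100, seed = 2L)
  drift <- max(traj$total_energies) - min(traj$total_energies)
  expect_lt(drift, 1e-3)
})

test_that("Berendsen rescale: fixed point, factor-2 case, zero-KE warning", {
  cf <- atomic_configuration(c(6L, 6L), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  st <- md_state(cf, timestep = 1, thermostat = "berendsen",
                 temperature_target = 300, coupling_time = 1)
  st <- maxwell_boltzmann_velocities(st, 300, seed = 3L)
  t0 <- instantaneous_temperature(st)
  expect_equal(t0, 300, tolerance = 1e-10)
  st1 <- berendsen_rescale(st, target_T = t0)
  expect_equal(st1$velocities, st$velocities)          # lambda = 1
  st2 <- berendsen_rescale(st, target_T = 4 * t0)      # tau = tau_c
  expect_equal(st2$velocities, 2 * st$velocities, tolerance = 1e-12)
  st$velocities[] <- 0
  expect_warning(berendsen_rescale(st), "skipped")
})

test_that("thermostatted run holds mean temperature near target", {
  fx <- reference_fixture()
  pot <- make_toy_potential(fx$spec)
  cf <- atomic_configuration(fx$spec$atomic_numbers, fx$spec$coordinates)
  traj <- run_md(cf, pot, steps = 4000L, timestep = 0.5,
                 thermostat = "berendsen", temperature = 300,
                 coupling_time = 50, seed = 4L, stride = 4L)
  mean_T <- mean(traj$temperatures[-(1:250)])   # discard equilibration
  expect_lt(abs(mean_T - 300) / 300, 0.05)
})

test_that("run_md: zero steps, determinism, NaN detection", {
  fx <- reference_fixture()
  pot <- make_toy_potential(fx$spec)
  cf <- generate_dataset(fx$spec, 1L, 0.02, seed = 6L)[[1L]]
  t0 <- run_md(cf, pot, steps = 0L, seed = 1L)
  expect_length(t0$frames, 1L)
  expect_equal(t0$frames[[1L]]$coordinates, cf$coordinates)
  t1 <- run_md(cf, pot, steps = 20L, timestep = 0.2, seed = 9L)
  t2 <- run_md(cf, pot, steps = 20L, timestep = 0.2, seed = 9L)
  expect_identical(t1$frames[[21L]]$coordinates,
                   t2$frames[[21L]]$coordinates)
  bad <- function(config) list(energy = NaN,
                               forces = matrix(NaN, 4L, 3L))
  expect_error(run_md(cf, bad, steps = 3L, seed = 1L), "NaN")
})

test_that("distance distribution: diatomic peak, rotation invariance, oracle", {
  cf <- atomic_configuration(c(6L, 6L), rbind(c(0, 0, 0), c(1, 0, 0)))
  dd <- distance_distribution(list(cf), grid = seq(0.5, 1.5, by = 0.05))
  expect_equal(dd$r[which.max(dd$h)], 0.975, tolerance = 0.05)
  expect_true(all(dd$h >= 0))
  ## rotation invariance frame-wise
  frames <- lapply(1:5, function(k) random_cluster(6L, seed = 1300L + k))
  dd1 <- distance_distribution(frames, grid = seq(0, 8, by = 0.1))
  rotated <- lapply(seq_along(frames), function(k) {
    apply_transform(frames[[k]],
                    random_rigid_transform(6L, seed = 1400L + k,
                                           permute = FALSE))
  })
  dd2 <- distance_distribution(rotated, grid = seq(0, 8, by = 0.1))
  expect_equal(dd1$h, dd2$h, tolerance = 1e-12)
  ## direct loop recomputation
  grid <- seq(0, 8, by = 0.1)
  counts <- numeric(length(grid) - 1L)
  for (cf2 in frames) {
    for (i in 1:5) for (j in (i + 1):6) {
      d <- sqrt(sum((cf2$coordinates[i, ] - cf2$coordinates[j, ])^2))
      bin <- findInterval(d, grid, left.open = TRUE)
      if (bin >= 1L && bin <= length(counts)) counts[bin] <- counts[bin] + 1L
    }
  }
  manual <- counts / (sum(counts) * diff(grid))
  expect_lt(max(abs(dd1$h - manual)), 1e-12)
})

test_that("a model potential drives stable NVE (energy conservation)", {
  ## trained or not, the network is an exact-gradient potential: NVE with a
  ## small step must conserve its total energy
  mod <- tiny_model(seed = 102L)
  cf <- random_cluster(4L, box_scale = 2.5, seed = 103L)
  traj <- run_md(cf, make_model_potential(mod), steps = 50L,
                 timestep = 0.2, temperature = 50, seed = 5L)
  drift <- max(traj$total_energies) - min(traj$total_energies)
  fluct <- max(abs(diff(traj$total_energies)))
  expect_lt(drift, 5e-3)
})
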