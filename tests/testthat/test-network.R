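# End-to-end symmetry, energy-force consistency, and the structural
# contracts of the network blocks.  Models here are random-initialized; all
# tolerances are float64-scale.

test_that("model config validates its invariants", {
  expect_error(model_config(hidden_dim = 30L, n_heads = 8L), "n_heads")
  expect_error(model_config(n_blocks = 0L))
  expect_s3_class(model_config(), "model_config")
  expect_equal(model_config()$n_blocks, 9L)
  expect_equal(model_config()$hidden_dim, 256L)
  expect_equal(model_config()$cutoff, 5)
})

test_that("cosine cutoff: boundary values and monotone decrease", {
  expect_equal(cosine_cutoff(0, 5), 1)
  expect_equal(cosine_cutoff(5, 5), 0)
  expect_equal(cosine_cutoff(7, 5), 0)
  grid <- cosine_cutoff(seq(0, 5, by = 0.01), 5)
  expect_true(all(diff(grid) <= 0))
  expect_true(all(grid >= 0 & grid <= 1))
})

test_that("single isolated atom: energy is its per-species scalar", {
  mod <- tiny_model()
  cf <- atomic_configuration(6L, matrix(c(0, 0, 0), 1L))
  e1 <- predict_energy(mod, cf)
  cf_moved <- atomic_configuration(6L, matrix(c(3, -2, 1), 1L))
  expect_identical(predict_energy(mod, cf_moved), e1)
  cf_other <- atomic_configuration(8L, matrix(c(0, 0, 0), 1L))
  expect_false(predict_energy(mod, cf_other) == e1)
  ## forces on an isolated atom vanish
  expect_equal(predict_forces(mod, cf), matrix(0, 1L, 3L))
})

test_that("atomic number outside the embedding table errors", {
  mod <- tiny_model()
  cf <- atomic_configuration(92L, matrix(0, 1L, 3L))
  expect_error(predict_energy(mod, cf), "embedding table")
})

test_that("embedding is distance sensitive through the RBF filter", {
  mod <- tiny_model()
  h2 <- function(r) atomic_configuration(c(1L, 1L),
                                         rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_false(isTRUE(all.equal(predict_energy(mod, h2(1)),
                                predict_energy(mod, h2(2)))))
})

test_that("energy is invariant, forces equivariant, under rigid motions and
           permutations (both spherical orders)", {
  set.seed(71)
  for (l_max in c(1L, 2L)) {
    mod <- tiny_model(seed = 70L + l_max, l_max = l_max)
    cf <- random_cluster(6L, seed = 72L)
    ef <- predict_energy_forces(mod, cf)
    for (k in 1:5) {
      tr <- random_rigid_transform(6L, seed = 1100L + k)
      ef2 <- predict_energy_forces(mod, apply_transform(cf, tr))
      expect_lt(abs(ef2$energy - ef$energy), 1e-10)
      Fexp <- (ef$forces %*% t(tr$rotation))[tr$permutation, , drop = FALSE]
      expect_lt(max(abs(ef2$forces - Fexp)), 1e-10)
    }
  }
})

test_that("analytic forces match finite differences and sum to zero", {
  set.seed(73)
  for (l_max in c(1L, 2L)) {
    mod <- tiny_model(seed = 74L, l_max = l_max)
    for (k in 1:3) {
      cf <- random_cluster(5L, box_scale = 3, seed = 1200L + k)
      ef <- predict_energy_forces(mod, cf)
      fd <- fd_forces(function(c2) predict_energy(mod, c2), cf, h = 1e-4)
      expect_lt(max(abs(ef$forces - fd)) / max(max(abs(fd)), 1e-8), 1e-5)
      expect_lt(max(abs(colSums(ef$forces))), 1e-8)
    }
  }
})

test_that("improper pathway preserves symmetry and changes predictions", {
  set.seed(75)
  mod_imp <- tiny_model(seed = 76L, use_improper = TRUE)
  mod_no <- tiny_model(seed = 76L, use_improper = FALSE)
  cf <- random_cluster(5L, seed = 77L)
  e_imp <- predict_energy(mod_imp, cf)
  expect_false(isTRUE(all.equal(e_imp, predict_energy(mod_no, cf))))
  tr <- random_rigid_transform(5L, seed = 78L)
  expect_lt(abs(predict_energy(mod_imp, apply_transform(cf, tr)) - e_imp),
            1e-10)
  fd <- fd_forces(function(c2) predict_energy(mod_imp, c2), cf, h = 1e-4)
  ef <- predict_energy_forces(mod_imp, cf)
  expect_lt(max(abs(ef$forces - fd)) / max(abs(fd)), 1e-5)
})

test_that("size extensivity: far-separated duplicate doubles the energy", {
  mod <- tiny_model()
  cf <- random_cluster(4L, box_scale = 2.5, seed = 79L)
  e1 <- predict_energy(mod, cf)
  cf2 <- atomic_configuration(
    rep(cf$atomic_numbers, 2L),
    rbind(cf$coordinates, cf$coordinates + 100))   # far beyond cutoff
  expect_equal(predict_energy(mod, cf2), 2 * e1, tolerance = 1e-10)
})

test_that("locality: atoms beyond the receptive field cannot matter", {
  ## with L blocks + embedding, information travels at most (L+1) hops
  mod <- tiny_model()   # L = 2, cutoff 5 -> receptive field 15 A
  cf <- atomic_configuration(c(6L, 6L, 8L),
                             rbind(c(0, 0, 0), c(2, 0, 0), c(50, 0, 0)))
  e_base <- predict_energy(mod, cf)
  cf$coordinates[3L, ] <- c(80, 5, -3)
  e_moved <- predict_energy(mod, cf)
  ## the far atom is isolated in both cases: energies identical
  expect_identical(e_base, e_moved)
})

test_that("energy is continuous as an atom crosses the cutoff", {
  mod <- tiny_model()
  rc <- mod$config$cutoff
  e_at <- function(r) predict_energy(
    mod, atomic_configuration(c(6L, 8L), rbind(c(0, 0, 0), c(r, 0, 0))))
  expect_lt(abs(e_at(rc - 1e-7) - e_at(rc + 1e-7)), 1e-6)
})

test_that("dipole head: zero/hand-computed cases and symmetries", {
  mod <- tiny_model()
  mod$config$head <- "dipole"
  cf <- atomic_configuration(c(6L, 6L, 1L, 8L),
                             random_cluster(4L, seed = 80L)$coordinates)
  mu <- predict_dipole(mod, cf)
  expect_gte(mu, 0)
  ## translation and rotation invariance of the magnitude
  tr <- random_rigid_transform(4L, seed = 81L, permute = FALSE)
  expect_lt(abs(predict_dipole(mod, apply_transform(cf, tr)) - mu), 1e-10)
})

test_that("spatial extent head: center-of-mass atom and invariance", {
  mod <- tiny_model()
  cf1 <- atomic_configuration(6L, matrix(0, 1L, 3L))
  expect_equal(predict_spatial_extent(mod, cf1), 0)
  ## translation invariance (r - r_c unchanged)
  cf <- random_cluster(4L, seed = 88L)
  r1 <- predict_spatial_extent(mod, cf)
  cf_shift <- cf
  cf_shift$coordinates <- cf$coordinates + 7
  expect_equal(predict_spatial_extent(mod, cf_shift), r1,
               tolerance = 1e-10)
})

test_that("scalar head shares the energy reduction path", {
  mod <- tiny_model()
  cf <- random_cluster(5L, seed = 82L)
  expect_identical(predict_scalar(mod, cf), predict_energy(mod, cf))
  ## permutation invariance
  tr <- random_rigid_transform(5L, seed = 83L, translate = FALSE)
  tr$rotation <- diag(3)
  expect_lt(abs(predict_scalar(mod, apply_transform(cf, tr)) -
                  predict_scalar(mod, cf)), 1e-10)
})

test_that("checkpoints round-trip parameters, config and calibration", {
  mod <- tiny_model(seed = 84L)
  mod$output_scale <- 2.5
  mod$output_shift <- -10
  tmp <- tempfile(fileext = ".npz")
  save_checkpoint(mod, tmp)
  back <- load_checkpoint(tmp)
  expect_equal(back$config, mod$config)
  expect_equal(back$output_scale, 2.5)
  expect_equal(back$output_shift, -10)
  for (nm in names(mod$params)) expect_equal(back$params[[nm]],
                                             mod$params[[nm]])
  cf <- random_cluster(4L, seed = 85L)
  expect_equal(predict_energy(back, cf), predict_energy(mod, cf))
})

test_that("deterministic mode: same seed gives bitwise-equal predictions", {
  m1 <- tiny_model(seed = 86L)
  m2 <- tiny_model(seed = 86L)
  cf <- random_cluster(5L, seed = 87L)
  expect_identical(predict_energy_forces(m1, cf),
                   predict_energy_forces(m2, cf))
})
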