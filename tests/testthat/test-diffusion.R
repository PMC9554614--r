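test_that("unit vectors have unit norm, isotropic mean and uniform z", {
  set.seed(1)
  u <- sample_unit_vectors(1e5)
  expect_equal(max(abs(sqrt(rowSums(u^2)) - 1)), 0, tolerance = 1e-12)
  expect_true(all(abs(colMeans(u)) < 3 / sqrt(1e5) * sqrt(1 / 3) * 3))
  # (runif's 32-bit resolution can produce a tie among 1e5 draws)
  expect_gt(suppressWarnings(stats::ks.test(u[, 3], "punif", -1, 1))$p.value,
            0.01)
  expect_equal(nrow(sample_unit_vectors(0)), 0)
})

test_that("the engine's direction sampler matches the same law", {
  u <- cleftsim:::cpp_sample_unit_vectors(1e5, 7)
  expect_equal(max(abs(sqrt(rowSums(u^2)) - 1)), 0, tolerance = 1e-12)
  expect_gt(stats::ks.test(u[, 3], "punif", -1, 1)$p.value, 0.01)
  expect_true(all(abs(colMeans(u)) < 0.01))
  # deterministic under the seed
  expect_identical(u, cleftsim:::cpp_sample_unit_vectors(1e5, 7))
})

test_that("released molecules start area-uniform on the vesicle disk", {
  p <- simulation_parameters(nnt = 20000, r_ves = 20)
  ens <- init_release(p, seed = 5)
  r2 <- ens$x^2 + ens$y^2
  expect_true(all(r2 <= 20^2))
  expect_true(all(ens$z == 0))
  # E[r^2] = r_ves^2 / 2 for an area-uniform disk
  expect_equal(mean(r2), 200, tolerance = 0.02)
  expect_true(all(ens$status == 0L) && all(ens$captures == 0L))

  po <- simulation_parameters(nnt = 1000, release_offset = 300)
  enso <- init_release(po, seed = 6)
  expect_equal(mean(enso$x), 300, tolerance = 0.05)
  expect_lt(max((enso$x - 300)^2 + enso$y^2), 20^2 + 1e-9)

  p0 <- simulation_parameters(nnt = 0)
  expect_length(init_release(p0, seed = 1)$x, 0)
})

test_that("step statistics follow the step rule", {
  p <- simulation_parameters(nnt = 1e5, ani = 0)
  nm <- numerics_config()
  ens <- init_release(p, seed = 2)
  set.seed(3)
  out <- step_positions(ens, p, nm)
  dx <- out$x - ens$x; dy <- out$y - ens$y; dz <- out$z - ens$z
  # every displacement has length sqrt(6 D dt) = 9.4868 nm
  expect_equal(range(sqrt(dx^2 + dy^2 + dz^2)), rep(sqrt(6 * 0.3 * 50), 2),
               tolerance = 1e-9)
  # per-axis variance of an isotropic step of length L is L^2/3 = 2 D dt
  expect_equal(stats::var(dx), 30, tolerance = 0.03)
  expect_equal(stats::var(dz), 30, tolerance = 0.03)
})

test_that("anisotropy scales in-column xy displacements by exactly 1 - ani", {
  nm <- numerics_config()
  u <- matrix(c(0.6, 0.48, 0.64), 1)  # a fixed unit vector
  mk <- function(ani) {
    p <- simulation_parameters(nnt = 1, ani = ani, D_ani = 100)
    ens <- init_release(p, seed = 1)
    ens$x <- 10; ens$y <- 0; ens$z <- 10   # inside the nanocolumn zone
    step_positions(ens, p, nm, u = u)
  }
  free <- mk(0); hind <- mk(0.9)
  expect_equal(hind$x - 10, 0.1 * (free$x - 10), tolerance = 1e-12)
  expect_equal(hind$y - 0, 0.1 * (free$y - 0), tolerance = 1e-12)
  expect_equal(hind$z, free$z)  # z motion unaffected
  # outside the zone the scaling does not apply
  p9 <- simulation_parameters(nnt = 1, ani = 0.9, D_ani = 100)
  ens <- init_release(p9, seed = 1)
  ens$x <- 200; ens$y <- 0; ens$z <- 10
  out <- step_positions(ens, p9, numerics_config(), u = u)
  expect_equal(out$x - 200, free$x - 10, tolerance = 1e-12)
})

test_that("a uniform field gradient produces the closed-form drift", {
  p <- simulation_parameters(nnt = 1000, ani = 0)
  nm <- numerics_config()
  g <- potential_grid(p, nm$grid_d)
  gr <- field_gradients(g)
  gr$gx[] <- 5 / 40   # mV per nm
  gr$gy[] <- 0
  ens <- init_release(p, seed = 4)
  u0 <- matrix(rep(c(0, 0, 1), each = 1000), ncol = 3)  # no xy randomness
  out <- step_positions(ens, p, nm, gradients = gr, u = u0)
  # dt * grad * D * F/(Rg T) = 0.0725 nm at these defaults
  expect_equal(unique(round(out$x - ens$x, 6)), 0.0725, tolerance = 1e-2)
  expect_equal(out$y, ens$y)
})

test_that("boundary handling reflects at the membranes and absorbs at the rim", {
  p <- simulation_parameters(nnt = 3, H_c = 20)
  ens <- init_release(p, seed = 1)
  ens$x <- c(0, 100, 999.9); ens$y <- c(0, 0, 40)
  ens$z <- c(-3, 21, 10)
  out <- apply_boundaries(ens, p)
  expect_equal(out$ensemble$z[1], 3)   # z = -e -> e
  expect_equal(out$ensemble$z[2], 19)  # H_c + e -> H_c - e
  expect_equal(out$absorbed, 1)        # x^2 + y^2 >= R^2 (boundary inclusive)
  expect_equal(out$ensemble$status, c(0L, 0L, 2L))

  ens$z <- c(-25, 10, 10)  # a reflected position still out of the cleft
  expect_error(apply_boundaries(ens, p), "decrease the time step")
})

test_that("molecule counts are conserved through composed stepping", {
  p <- simulation_parameters(nnt = 400, n_c = 0, n_r = 0, R = 300)
  nm <- numerics_config()
  ens <- init_release(p, seed = 9)
  set.seed(10)
  for (i in 1:300) {
    ens <- step_positions(ens, p, nm)
    ens <- apply_boundaries(ens, p)$ensemble
    expect_equal(sum(ens$status == 0L) + sum(ens$status == 1L) +
                   sum(ens$status == 2L), 400)
  }
  expect_gt(sum(ens$status == 2L), 0)  # some absorption by then
})

test_that("reflection preserves the uniform stationary density in z", {
  # closed box: absorption cannot occur because R is huge
  p <- simulation_parameters(nnt = 3000, R = 1e5, H_c = 20, n_c = 0, n_r = 0)
  nm <- numerics_config()
  ens <- init_release(p, seed = 11)
  set.seed(12)
  for (i in 1:120) {  # mixing time in z is ~ H_c^2 / 2D = 13 steps
    ens <- step_positions(ens, p, nm)
    ens <- apply_boundaries(ens, p)$ensemble
  }
  h <- table(cut(ens$z, seq(0, 20, by = 2)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})
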