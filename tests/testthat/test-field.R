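test_that("with no open channels the potential is identically zero", {
  p <- simulation_parameters()
  g <- potential_grid(p, 20)
  g <- solve_potential(g, p)
  expect_true(all(g$v == 0))
  tc <- total_current(g, p)
  expect_equal(tc$I_pA, 0)
  expect_equal(tc$g_pS, 0)
})

test_that("open channels hyperpolarize the cleft and reduce the driving force", {
  p <- simulation_parameters()  # E_intra = -65 mV
  g <- potential_grid(p, 20)
  g <- set_open_channels(g, x = c(0, 10, -15), y = c(0, 5, 0))
  expect_equal(sum(g$n), 3)
  g <- solve_potential(g, p)
  # v is between E_intra and the grounded rim: E_intra < v <= 0
  expect_true(all(g$v[g$mask] <= 0))
  expect_true(all(g$v[g$mask] > p$E_intra))
  expect_lt(min(g$v), 0)
  # discrete maximum principle: the extremum sits at a source element
  expect_true(g$n[which.min(g$v)] > 0)
  tc <- total_current(g, p)
  # one channel at nominal driving gives 25 pS x 65 mV = 1.625 pA
  expect_lt(tc$I_pA, 3 * 1.625)
  expect_gt(tc$I_pA, 0)
  expect_lt(tc$driving_force_mV, 65)

  g1 <- set_open_channels(potential_grid(p, 20), 0, 0)
  tc_off <- total_current(g1, p)           # field left at v = 0
  expect_equal(tc_off$I_pA, 1.625)
  tc_on <- total_current(solve_potential(g1, p), p)
  expect_lt(tc_on$I_pA, 1.625)
})

test_that("the sparse solve agrees with a dense oracle on a small grid", {
  p <- simulation_parameters(R = 55, H_c = 20)  # 5x5-ish in-disk core
  g <- potential_grid(p, 20)
  g <- set_open_channels(g, x = 5, y = -10)
  g <- solve_potential(g, p)
  # dense assembly of the same balance equations
  idx <- which(g$mask)
  n <- length(idx)
  kappa <- p$g_unit * 1e-12 * (p$Res * 1e-2) / (p$H_c * 1e-9)
  A <- matrix(0, n, n)
  b <- numeric(n)
  arr <- arrayInd(idx, dim(g$mask))
  for (k in seq_len(n)) {
    A[k, k] <- 4 + g$n[idx[k]] * kappa
    b[k] <- g$n[idx[k]] * kappa * p$E_intra
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- arr[k, 1] + d[1]; jj <- arr[k, 2] + d[2]
      if (ii >= 1 && ii <= g$nx && jj >= 1 && jj <= g$nx && g$mask[ii, jj]) {
        kk <- match((jj - 1) * g$nx + ii, idx)
        A[k, kk] <- -1
      }
    }
  }
  v_dense <- solve(A, b)
  expect_equal(g$v[idx], v_dense, tolerance = 1e-10)

  # the engine's cached-column Woodbury path solves the same system
  v_cpp <- cleftsim:::cpp_solve_field(g$n, p$R, 20, p$H_c, p$Res, p$g_unit,
                                      p$E_intra)
  expect_equal(v_cpp[idx], v_dense, tolerance = 1e-8)
})

test_that("the engine solver matches the direct solve on the full disk", {
  p <- simulation_parameters()
  g <- potential_grid(p, 20)
  set.seed(40)
  g <- set_open_channels(g, x = stats::rnorm(25, 0, 60),
                         y = stats::rnorm(25, 0, 60))
  g <- solve_potential(g, p)
  v_cpp <- cleftsim:::cpp_solve_field(g$n, p$R, 20, p$H_c, p$Res, p$g_unit,
                                      p$E_intra)
  expect_equal(max(abs(v_cpp - g$v)), 0, tolerance = 1e-8)
})

test_that("adding an open channel deepens the potential everywhere", {
  p <- simulation_parameters()
  g1 <- solve_potential(set_open_channels(potential_grid(p, 20), 0, 0), p)
  g2 <- solve_potential(set_open_channels(potential_grid(p, 20),
                                          c(0, 100), c(0, 0)), p)
  expect_true(all(g2$v[g2$mask] <= g1$v[g1$mask] + 1e-12))
  expect_lt(min(g2$v), min(g1$v))
})

test_that("transmembrane current balances the current leaving through the rim", {
  p <- simulation_parameters()
  g <- set_open_channels(potential_grid(p, 20), c(0, 20, -40), c(0, 0, 20))
  g <- solve_potential(g, p)
  kappa_S <- p$H_c * 1e-9 / (p$Res * 1e-2)   # siemens between neighbours
  # current into the Dirichlet ring: sum over in-disk cells of v * kappa per
  # missing neighbour (ring potential is 0)
  arr <- arrayInd(which(g$mask), dim(g$mask))
  ring_I <- 0
  for (k in seq_len(nrow(arr))) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- arr[k, 1] + d[1]; jj <- arr[k, 2] + d[2]
      outside <- ii < 1 || ii > g$nx || jj < 1 || jj > g$nx || !g$mask[ii, jj]
      if (outside)
        ring_I <- ring_I + g$v[arr[k, 1], arr[k, 2]] * 1e-3 * kappa_S
    }
  }
  tc <- total_current(g, p)
  expect_equal(-ring_I * 1e12, tc$I_pA, tolerance = 1e-8)
})

test_that("increasing cleft height shrinks the depolarization at fixed sources", {
  depth <- vapply(c(10, 20, 40), function(h) {
    p <- simulation_parameters(H_c = h)
    g <- set_open_channels(potential_grid(p, 20),
                           x = c(0, 15, -15, 0), y = c(0, 0, 10, -20))
    -min(solve_potential(g, p)$v)
  }, 0)
  expect_true(all(diff(depth) < 0))
})

test_that("gradients are exact on linear fields and point away from a source", {
  p <- simulation_parameters()
  g <- potential_grid(p, 20)
  # uniform v -> zero gradient
  g$v[g$mask] <- 3
  gr <- field_gradients(g)
  inner <- g$mask &
    rbind(FALSE, g$mask[-g$nx, ]) & rbind(g$mask[-1, ], FALSE) &
    cbind(FALSE, g$mask[, -g$nx]) & cbind(g$mask[, -1], FALSE)
  expect_true(all(gr$gx[inner] == 0) && all(gr$gy[inner] == 0))
  # v linear in x -> exact centred difference in the interior
  cx <- matrix(g$centers, g$nx, g$nx)
  g$v <- 0.01 * cx; g$v[!g$mask] <- 0
  gr <- field_gradients(g)
  expect_equal(unique(round(gr$gx[inner], 12)), 0.01)
  # single source: the potential well is deepest at the source, so the
  # gradient of v points radially away from it
  g2 <- solve_potential(set_open_channels(potential_grid(p, 20), 0, 0), p)
  gr2 <- field_gradients(g2)
  i0 <- which(g2$n > 0, arr.ind = TRUE)
  expect_gt(gr2$gx[i0[1] + 3, i0[2]], 0)
  expect_lt(gr2$gx[i0[1] - 3, i0[2]], 0)
})
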