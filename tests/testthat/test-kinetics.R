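test_that("equivalent concentration follows the half-sphere formula", {
  # Vol = (2/3) pi 5^3 = 261.8 nm^3 -> C = 1/(N_A Vol) ~ 6.34 mM
  expect_equal(equivalent_concentration(5), 6.343e-3, tolerance = 1e-3)
  expect_equal(equivalent_concentration(10) / equivalent_concentration(5),
               1 / 8)  # cubic scaling
  expect_lt(equivalent_concentration(1e4), 1e-12)
  expect_error(equivalent_concentration(0), "b_rad")
})

test_that("per-step binding and opening probabilities match rate x dt", {
  p <- simulation_parameters()
  nm <- numerics_config()
  tabs <- cleftsim:::.scheme_tables(ampar_kinetic_scheme(), p, nm)
  # C0 edge: K1 * C_eq * dt = 1.8412e7 * 6.343e-3 * 5e-8
  expect_equal(tabs$bind_p[1], 1.8412e7 * equivalent_concentration(5) * 5e-8,
               tolerance = 1e-12)
  expect_equal(tabs$bind_p[1], 5.8e-3, tolerance = 0.01)
  # C2 opening: beta * dt
  sch <- ampar_kinetic_scheme()
  beta <- sch$transitions$rate[sch$transitions$label == "beta"]
  expect_equal(beta * 5e-8, 2.58e-3, tolerance = 0.01)
})

test_that("capture requires proximity, an available binding edge and one event per step", {
  p <- simulation_parameters(nnt = 3, n_c = 0, n_r = 0, H_c = 20)
  nm <- numerics_config()
  sch <- ampar_kinetic_scheme()
  lay <- data.frame(id = 1L, x_nm = 0, y_nm = 0, group = "random")
  st <- init_receptor_states(1)
  ens <- init_release(p, seed = 1)
  ens$x <- c(0, 5.1, 0); ens$y <- rep(0, 3); ens$z <- c(19.9, 19.9, 1)
  # molecule 2 is outside the capture radius, molecule 3 far from the membrane
  set.seed(2)
  hits <- 0
  for (i in 1:2000) {
    st0 <- init_receptor_states(1)
    out <- attempt_binding(ens, st0, lay, sch, p, nm)
    if (out$states$state[1] != "C0") {
      hits <- hits + 1
      expect_equal(out$states$state[1], "C1")
      expect_equal(out$ensemble$status, c(1L, 0L, 0L))  # only molecule 1
      expect_equal(out$ensemble$captures[1], 1L)
    }
  }
  p_bind <- 1.8412e7 * equivalent_concentration(5) * 5e-8
  expect_gt(hits / 2000, p_bind - 3 * sqrt(p_bind / 2000))
  expect_lt(hits / 2000, p_bind + 3 * sqrt(p_bind / 2000))

  # a receptor in O2 has no binding edge: no capture no matter how close
  st$state <- "O2"; st$bound <- matrix(c(2L, 3L), 1)
  out <- attempt_binding(ens, st, lay, sch, p, nm)
  expect_equal(out$states$state[1], "O2")
  expect_equal(out$ensemble$status[1], 0L)
})

test_that("hemisphere geometry also rejects molecules beyond the 3-D radius", {
  p <- simulation_parameters(nnt = 1, n_c = 0, n_r = 0)
  nm <- numerics_config(capture_geometry = "hemisphere")
  sch <- ampar_kinetic_scheme()
  lay <- data.frame(id = 1L, x_nm = 0, y_nm = 0, group = "random")
  ens <- init_release(p, seed = 1)
  ens$x <- 4; ens$y <- rep(0, 1); ens$z <- 16  # xy ok, 3-D distance 5.7 > 5
  set.seed(1)
  for (i in 1:500) {
    out <- attempt_binding(ens, init_receptor_states(1), lay, sch, p, nm)
    expect_equal(out$states$state[1], "C0")
  }
})

test_that("sampled state dynamics match the matrix-exponential oracle", {
  # hold the glutamate concentration fixed and compare occupancies at 0.5 ms
  sch <- ampar_kinetic_scheme()
  conc <- 1e-3  # 1 mM
  dt_s <- 50e-9
  n <- 20000
  t_end <- 0.5e-3
  steps <- round(t_end / dt_s)
  # per-state transition table including binding at fixed concentration
  Q <- scheme_generator(sch, conc)
  Pstep <- diag(9) + Q * dt_s
  cum <- lapply(1:9, function(s) cumsum(Pstep[s, -s]))
  tos <- lapply(1:9, function(s) (1:9)[-s])
  set.seed(20)
  state <- rep(3L, n)  # start in C2
  for (k in seq_len(steps)) {
    u <- stats::runif(n)
    prev <- state   # freeze: one transition per receptor per step
    for (s in unique(prev)) {
      i <- which(prev == s)
      pick <- findInterval(u[i], c(0, cum[[s]]))
      moved <- pick <= 8
      state[i[moved]] <- tos[[s]][pick[moved]]
    }
  }
  emp <- tabulate(state, 9) / n
  theo <- as.numeric(Matrix::expm(Matrix::Matrix(Q * t_end))[3, ])
  se <- sqrt(pmax(theo * (1 - theo), 1e-12) / n)
  expect_true(all(abs(emp - theo) <= 3 * se + 2e-3),
              info = paste(round(emp, 4), round(theo, 4), collapse = " | "))
})

test_that("with no glutamate every receptor relaxes to C0", {
  sch <- ampar_kinetic_scheme()
  p <- simulation_parameters(nnt = 0)
  nm <- numerics_config(dt_ns = 500)
  lay <- data.frame(id = 1:3, x_nm = c(0, 20, 40), y_nm = 0,
                    group = "random")
  st <- init_receptor_states(3)
  st$state <- c("D2d", "O2", "D1")
  st$bound <- matrix(c(1L, 3L, 5L, 2L, 4L, NA), nrow = 3)
  ens <- new_ens <- list(x = numeric(5), y = numeric(5),
                         z = rep(10, 5), status = rep(1L, 5),
                         bound_to = c(1L, 1L, 2L, 2L, 3L),
                         captures = rep(1L, 5))
  class(ens) <- "molecule_ensemble"
  set.seed(21)
  for (i in 1:200000) {  # 100 ms at 500 ns
    out <- step_markov(st, ens, lay, sch, p, nm)
    st <- out$states; ens <- out$ensemble
    if (all(st$state == "C0")) break
  }
  expect_true(all(st$state == "C0"))
  expect_true(all(is.na(st$bound)))
  expect_true(all(ens$status == 0L))  # all five molecules released
})

test_that("binding bookkeeping is conserved through random bind/unbind sequences", {
  p <- simulation_parameters(nnt = 60, n_c = 0, n_r = 0, R = 150, H_c = 20)
  nm <- numerics_config()
  sch <- ampar_kinetic_scheme()
  set.seed(22)
  lay <- data.frame(id = 1:6, x_nm = c(0, 12, -12, 0, 24, -24),
                    y_nm = c(0, 0, 0, 12, 0, 0), group = "random")
  st <- init_receptor_states(6)
  ens <- init_release(p, seed = 23)
  ens$z <- rep(p$H_c - 1, 60)  # start near the receptors
  for (i in 1:1500) {
    ens <- step_positions(ens, p, nm)
    ens <- apply_boundaries(ens, p)$ensemble
    out <- attempt_binding(ens, st, lay, sch, p, nm)
    ens <- out$ensemble; st <- out$states
    out <- step_markov(st, ens, lay, sch, p, nm)
    st <- out$states; ens <- out$ensemble
    if (i %% 100 == 0) {
      cleftsim:::.check_receptor_states(st, sch)
      # every bound molecule id appears in exactly one receptor slot and
      # points back at that receptor
      bound_ids <- st$bound[!is.na(st$bound)]
      expect_equal(anyDuplicated(bound_ids), 0)
      expect_equal(sort(bound_ids), which(ens$status == 1L))
      holder <- rep(seq_len(6), 2)[!is.na(st$bound)]
      expect_equal(ens$bound_to[bound_ids], holder)
      expect_equal(sum(ens$status == 0L) + sum(ens$status == 1L) +
                     sum(ens$status == 2L), 60)
    }
  }
  expect_gt(sum(ens$captures), 0)
})

test_that("lateral diffusion follows the lattice law and preserves exclusion", {
  p <- simulation_parameters(D_r = 0.1)
  nm <- numerics_config()
  # p_move = 4 D_r dt / h^2 = 2e-4 at the defaults
  expect_equal(4 * 0.1 * 1e-3 * 50 / 100, 2e-4)

  # MSD of an unobstructed lattice walk: MSD/t -> 4 D_r (ensemble average;
  # a fast walker keeps the step count small, the law is the same)
  set.seed(30)
  Dr <- 100                                  # um^2/s -> p_move = 0.2
  pm <- 4 * Dr * 1e-3 * 50 / 100
  m <- 2000; nstep <- 2000
  dx <- dy <- matrix(0, m, 1)
  msd <- numeric(nstep)
  X <- Y <- numeric(m)
  for (k in seq_len(nstep)) {
    move <- stats::runif(m) < pm
    dir <- sample.int(4, m, replace = TRUE)
    X <- X + ifelse(move & dir == 1, -10, ifelse(move & dir == 2, 10, 0))
    Y <- Y + ifelse(move & dir == 3, -10, ifelse(move & dir == 4, 10, 0))
    msd[k] <- mean(X^2 + Y^2)
  }
  t_ns <- (1:nstep) * 50
  fit <- sum(t_ns * msd) / sum(t_ns^2)       # nm^2 per ns
  expect_equal(fit * 1e3, 4 * Dr, tolerance = 0.05)  # um^2/s

  # exclusion: two adjacent receptors can never share a cell
  p2 <- simulation_parameters(D_r = 100, n_c = 0, n_r = 2)
  nm2 <- numerics_config()
  lay <- data.frame(id = 1:2, x_nm = c(5, 15), y_nm = c(5, 5),
                    group = "random")
  st <- init_receptor_states(2)
  ens <- init_release(simulation_parameters(nnt = 0), seed = 1)
  set.seed(31)
  for (i in 1:400) {
    out <- lateral_diffusion_step(lay, st, ens, p2, nm2)
    lay <- out$layout; st <- out$states; ens <- out$ensemble
    cells <- paste(floor((lay$x_nm + p2$R) / 10),
                   floor((lay$y_nm + p2$R) / 10))
    expect_equal(anyDuplicated(cells), 0)
  }
  expect_equal(nrow(lay), 2)

  # D_r = 0 leaves the layout untouched
  p0 <- simulation_parameters(D_r = 0)
  out <- lateral_diffusion_step(lay, st, ens, p0, nm2)
  expect_identical(out$layout$x_nm, lay$x_nm)
})

test_that("receptor statistics summarize opening counts", {
  openings <- matrix(c(0, 0, 3, 12, 0, 15), nrow = 3)
  rs <- receptor_statistics(openings, thresholds = c(1, 12))
  expect_equal(rs$frac_never, 3 / 6)
  expect_equal(unname(rs$frac_at_least["ge1"]), 3 / 6)
  expect_equal(unname(rs$frac_at_least["ge12"]), 2 / 6)
  expect_error(receptor_statistics(matrix(numeric(0), 0, 0)), "repetition")
})
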