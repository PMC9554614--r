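test_that("no ligand or no receptors give a silent synapse", {
  nm <- fast_numerics()
  p0 <- tiny_params(nnt = 0)
  r0 <- run_single(p0, nm, seed = 1)
  expect_true(all(r0$I_mean == 0))

  pr <- simulation_parameters(nnt = 200, n_c = 0, n_r = 0, R = 300)
  rr <- run_ensemble(pr, numerics_config(duration_ms = 2), n_reps = 2, seed = 2)
  expect_true(all(rr$I_mean == 0))
  # with no receptors to hold them, molecules drain out of the cleft
  expect_true(all(rr$per_rep$absorbed > 0.9 * 200))
  expect_equal(rr$per_rep$absorbed + rr$per_rep$free + rr$per_rep$bound,
               rep(200L, 2))
})

test_that("a fixed seed reproduces the run bit for bit", {
  p <- tiny_params(nnt = 150)
  nm <- fast_numerics(0.3)
  a <- run_ensemble(p, nm, n_reps = 3, seed = 99)
  b <- run_ensemble(p, nm, n_reps = 3, seed = 99)
  expect_identical(a$I_mean, b$I_mean)
  expect_identical(a$per_rep, b$per_rep)
  expect_identical(a$openings, b$openings)
  c <- run_ensemble(p, nm, n_reps = 3, seed = 100)
  expect_false(identical(a$I_mean, c$I_mean))
})

test_that("molecule conservation holds in the aggregate outputs", {
  p <- tiny_params(nnt = 300)
  r <- run_ensemble(p, fast_numerics(0.5), n_reps = 4, seed = 5)
  expect_equal(r$per_rep$absorbed + r$per_rep$free + r$per_rep$bound,
               rep(300L, 4))
  expect_equal(sum(r$capture_hist), 300L * 4L)
})

test_that("the reference protocol produces a fast-rising, slower-decaying transient", {
  p <- fig3_params(1000)
  r <- run_ensemble(p, numerics_config(duration_ms = 2), n_reps = 4, seed = 6)
  ipk <- which.max(r$I_mean)
  expect_lt(r$time_ms[ipk], 0.3)            # peak within the first 0.3 ms
  expect_gt(max(r$I_mean), 5)
  expect_lt(mean(r$I_mean[r$time_ms > 1.8]), 0.35 * max(r$I_mean))
  expect_true(all(r$I_max >= r$I_mean - 1e-9 & r$I_mean >= r$I_min - 1e-9))
  # conductance trace is the open count times the unitary conductance
  expect_equal(r$g_mean, r$n_open_mean * 25)
})

test_that("a single repetition is its own ensemble mean", {
  p <- tiny_params(nnt = 200)
  r <- run_ensemble(p, fast_numerics(0.3), n_reps = 1, seed = 7)
  expect_equal(r$I_mean, r$I_min)
  expect_equal(r$I_mean, r$I_max)
})

test_that("disabling the field raises the current, more so for dense clusters", {
  nm <- numerics_config(duration_ms = 0.8)
  p <- simulation_parameters(nnt = 20000, n_c = 80, n_r = 0, ani = 0.5,
                             H_c = 10)
  on <- run_ensemble(p, nm, n_reps = 2, seed = 8)
  off <- run_ensemble(p, nm, n_reps = 2, seed = 8, field = FALSE)
  expect_gt(max(off$I_mean), max(on$I_mean))          # field on -> smaller
  expect_gt(max(off$I_mean) / max(on$I_mean), 1.01)   # and measurably so here
  expect_equal(max(on$per_rep$max_depol_mV) > 1, TRUE)
  expect_true(all(off$per_rep$max_depol_mV == 0))
})

test_that("the glutamate-charge drift term has a negligible effect at defaults", {
  # the two runs decorrelate after the first divergent binding event, so the
  # comparison is resolved only to the Monte Carlo error of the ensemble
  # mean; at 80 repetitions that floor is ~2-3% on the peak
  p <- fig3_params(1000)
  nm <- numerics_config(duration_ms = 0.8)
  on <- run_ensemble(p, nm, n_reps = 80, seed = 9, layout_policy = "fixed")
  off <- run_ensemble(p, nm, n_reps = 80, seed = 9, layout_policy = "fixed",
                      drift = FALSE)
  expect_lt(abs(max(on$I_mean) - max(off$I_mean)) / max(off$I_mean), 0.03)
})

test_that("a one-event train reduces to a single release", {
  p <- tiny_params(nnt = 200)
  tr <- run_train(p, fast_numerics(0.3), frequency = 1000, n_events = 1,
                  n_reps = 2, seed = 10, duration_ms = 0.3)
  sg <- run_ensemble(p, fast_numerics(0.3), n_reps = 2, seed = 10)
  expect_identical(tr$I_mean, sg$I_mean)
  expect_equal(dim(tr$event_peaks), c(1L, 2L))
})

test_that("repeated releases depress the response through desensitization", {
  p <- simulation_parameters(nnt = 10000, n_c = 0, n_r = 80, ani = 0,
                             D_r = 1)
  tr <- run_train(p, numerics_config(), frequency = 100, n_events = 3,
                  n_reps = 2, seed = 11, receptor_diffusion = "off")
  peaks <- rowMeans(tr$event_peaks)
  expect_lt(peaks[2], 0.9 * peaks[1])            # cumulative desensitization
  expect_gt(max(tr$desens_frac), 0.4)
  # the desensitized pool is still elevated when the later events arrive
  expect_gt(min(tr$desens_frac[tr$time_ms > 9 & tr$time_ms < 30]), 0.15)

  # freely diffusing receptors exchange with naive ones at the rim, easing
  # desensitization relative to anchored receptors (the replacement also
  # disperses the cluster, so the peak itself is geometry-confounded and is
  # not compared here)
  trd <- run_train(p, numerics_config(), frequency = 100, n_events = 3,
                   n_reps = 2, seed = 11, receptor_diffusion = "free")
  expect_lt(trd$desens_frac[length(trd$desens_frac)],
            tr$desens_frac[length(tr$desens_frac)])
})

test_that("grouped receptor diffusion keeps each group on its side of the column", {
  p <- simulation_parameters(nnt = 500, n_c = 10, n_r = 10, ani = 0.5,
                             D_r = 50)  # fast diffusion to stress the bounds
  tr <- run_train(p, numerics_config(), frequency = 200, n_events = 2,
                  n_reps = 2, seed = 12, receptor_diffusion = "grouped",
                  D_r_in = 10, D_r_out = 50)
  expect_s3_class(tr, "simulation_result")
  expect_equal(dim(tr$event_peaks), c(2L, 2L))
})
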