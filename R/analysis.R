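#' Biexponential fit of a synaptic current trace
#'
#' Fits \deqn{I(t) = \frac{Q}{\tau_{decay} - \tau_{rise}}
#' \left(e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}\right)}
#' to a current transient by nonlinear least squares. The two time constants
#' are interchangeable in this template, so the fit is parameterized with
#' `tau_decay = tau_rise + exp(theta)`, which smoothly enforces the ordering
#' `tau_rise < tau_decay` and removes the symmetry. Initialization uses half
#' the time-to-peak for the rise, a log-linear fit of the tail for the decay
#' and the trapezoidal charge for Q, followed by a small set of jittered
#' restarts (the objective is multimodal).
#'
#' Fits are intended for ensemble-mean traces; single stochastic
#' realizations are too noisy for stable time constants.
#'
#' @param time_ms time base, ms, or a `"simulation_result"` (in which case
#'   its mean trace is fitted and `current_pA` is ignored).
#' @param current_pA current trace, pA.
#' @return list of class `"biexp_fit"`: `Q_fC`, `tau_rise_us`,
#'   `tau_decay_ms`, `mse`, `converged`, and `fitted` (the model curve on
#'   the input time base).
#' @examples
#' t <- seq(0.005, 3, by = 0.005)
#' I <- 13 / (0.45 - 0.053) * (exp(-t / 0.45) - exp(-t / 0.053))
#' fit_biexponential(t, I)
#' @export
fit_biexponential <- function(time_ms, current_pA = NULL) {
  if (inherits(time_ms, "simulation_result")) {
    current_pA <- time_ms$I_mean
    time_ms <- time_ms$time_ms
  }
  t <- as.numeric(time_ms); I <- as.numeric(current_pA)
  stopifnot(length(t) == length(I), length(t) > 10)
  if (all(I == 0)) stop("no transient: the trace is identically zero")
  model <- function(par) {
    tr <- exp(par[2])
    td <- tr + exp(par[3])
    exp(par[1]) / (td - tr) * (exp(-t / td) - exp(-t / tr))
  }
  resid_fn <- function(par) model(par) - I

  ## initial values
  ipk <- which.max(I)
  tr0 <- max(t[ipk] / 2, t[2])
  Q0 <- max(sum(diff(t) * (I[-1] + I[-length(I)]) / 2), 1e-6)
  tail_idx <- which(t > t[ipk] & I > 0.05 * I[ipk])
  td0 <- if (length(tail_idx) > 5) {
    sl <- stats::coef(stats::lm(log(I[tail_idx]) ~ t[tail_idx]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 4 * tr0
  } else 4 * tr0
  td0 <- max(td0, tr0 * 1.5)
  start <- c(log(Q0), log(tr0), log(td0 - tr0))
  jitter_sets <- list(c(0, 0, 0), c(0, -1, 0.5), c(0, 0.7, -0.5),
                      c(0.3, -0.5, 1), c(-0.3, 0.5, -1))
  best <- NULL
  for (j in jitter_sets) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start + j, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse, info = fit$info)
  }
  if (is.null(best)) stop("biexponential fit failed from every start")
  par <- best$par
  tr <- exp(par[2]); td <- tr + exp(par[3])
  out <- list(Q_fC = exp(par[1]), tau_rise_us = tr * 1000,
              tau_decay_ms = td, mse = best$sse / length(t),
              converged = best$info %in% 1:3,
              fitted = model(par))
  class(out) <- "biexp_fit"
  out
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("Biexponential fit: Q = %.4g fC, tau_rise = %.4g us, tau_decay = %.4g ms (mse %.3g, %s)\n",
              x$Q_fC, x$tau_rise_us, x$tau_decay_ms, x$mse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summary metrics of a simulated synaptic event
#'
#' Peak current and conductance are read off the ensemble-mean traces; the
#' charge is the trapezoidal integral of the mean current; the effective
#' driving force is the ratio of peak current to peak conductance (it falls
#' below `E_syn - E_intra` when the cleft depolarizes); PNC is the
#' proportion of released neurotransmitter molecules captured at least once.
#'
#' @param result a `"simulation_result"`.
#' @return list: `peak_pA`, `peak_g_pS`, `Q_fC`, `driving_force_mV`,
#'   `pnc`, `frac_captured_ge2`, `capture_hist` (fractions by capture
#'   count), `max_depol_mV`.
#' @export
summary_metrics <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  I <- result$I_mean; t <- result$time_ms
  peak <- max(I)
  peak_g <- max(result$g_mean)
  Q <- sum(diff(t) * (I[-1] + I[-length(I)]) / 2)
  hist <- result$capture_hist
  total <- sum(hist)
  frac <- if (total > 0) hist / total else hist
  list(peak_pA = peak,
       peak_g_pS = peak_g,
       Q_fC = Q,
       driving_force_mV = if (peak_g > 0) peak / peak_g * 1e3 else NA_real_,
       pnc = if (total > 0) 1 - frac[1] else NA_real_,
       frac_captured_ge2 = if (total > 0) sum(frac[-(1:2)]) else NA_real_,
       capture_hist = frac,
       max_depol_mV = max(result$per_rep$max_depol_mV))
}

#' Mean-square-displacement validation of the diffusion step rule
#'
#' Simulates free 3-D Brownian motion with the engine's step rule (step
#' length `sqrt(6 D dt)` along a uniform random direction, no boundaries, no
#' field) and fits `MSD(t) = 6 D t` through the origin. Recovering the input
#' D validates the displacement statistics of the sampler.
#'
#' @param n_molecules number of walkers.
#' @param duration_ms simulated time, ms.
#' @param dt_ns time step, ns.
#' @param D input diffusion coefficient, um^2/ms.
#' @param seed integer seed.
#' @param sample_every record the MSD every this many steps.
#' @return list: `D_fit` (um^2/ms), `t_ms`, `msd_um2`.
#' @export
msd_validation <- function(n_molecules = 10000, duration_ms = 1, dt_ns = 50,
                           D = 0.3, seed = 1, sample_every = 20) {
  n_steps <- round(duration_ms * 1e6 / dt_ns)
  raw <- cpp_free_msd(as.integer(n_molecules), as.integer(n_steps),
                      as.integer(sample_every), dt_ns, D, as.integer(seed))
  msd_um2 <- raw$msd_nm2 * 1e-6
  slope <- sum(raw$t_ms * msd_um2) / sum(raw$t_ms^2)  # through-origin LS
  list(D_fit = slope / 6, t_ms = raw$t_ms, msd_um2 = msd_um2)
}

#' Correlation between release-site distance and charge transfer
#'
#' @param distance_nm per-event distance between release site and synapse
#'   centre.
#' @param charge_fC per-event total charge transfer.
#' @return list: `r` (Pearson correlation), `abs_r`, `n`.
#' @export
release_site_correlation <- function(distance_nm, charge_fC) {
  if (length(distance_nm) != length(charge_fC))
    stop("distance and charge must have equal length")
  if (length(distance_nm) < 3)
    stop("at least 3 events are needed to estimate a correlation")
  r <- stats::cor(distance_nm, charge_fC)
  list(r = r, abs_r = abs(r), n = length(distance_nm))
}

#' Simulate vesicle openings at random release sites
#'
#' Draws `n_events` release sites area-uniformly on the PSD disk, runs one
#' repetition per event with the release centred there, and returns the
#' per-event distance and charge (the input to
#' [release_site_correlation()]).
#'
#' @param params a `"cleft_params"` (its `release_offset` is overridden
#'   per event).
#' @param n_events number of events.
#' @param seed integer seed.
#' @param numerics a `"cleft_numerics"`; 2 ms per event by default.
#' @param layout optional fixed receptor layout shared by all events.
#' @return data.frame with `distance_nm` and `Q_fC`.
#' @export
simulate_release_sites <- function(params, n_events = 50, seed = 1,
                                   numerics = numerics_config(duration_ms = 2),
                                   layout = NULL) {
  set.seed(seed)
  d <- (params$D_dr / 2) * sqrt(stats::runif(n_events))
  if (is.null(layout)) layout <- place_receptors(params)
  Q <- vapply(seq_len(n_events), function(i) {
    p <- params
    p$release_offset <- d[i]
    r <- run_ensemble(p, numerics, n_reps = 1, seed = seed + i,
                      layout = layout)
    r$per_rep$Q_fC[1]
  }, 0)
  data.frame(distance_nm = d, Q_fC = Q)
}
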