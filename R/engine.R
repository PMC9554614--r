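## Orchestration of the coupled time loop. The per-step physics lives in the
## compiled engine (src/engine.cpp); these wrappers validate configurations,
## draw receptor layouts, translate the kinetic scheme into the flat tables
## the engine consumes, and package the results.

.scheme_tables <- function(scheme, params, numerics) {
  states <- scheme$states
  dt_s <- numerics$dt_ns * 1e-9
  ceq <- equivalent_concentration(numerics$b_rad, params$N_A)
  bind_to <- rep(-1L, length(states))
  bind_p <- rep(0, length(states))
  b <- scheme$transitions[scheme$transitions$kind == "binding", ]
  for (k in seq_len(nrow(b))) {
    s <- match(b$from[k], states)
    bind_to[s] <- match(b$to[k], states) - 1L
    bind_p[s] <- b$rate[k] * ceq * dt_s
  }
  eoff <- integer(length(states) + 1)
  eto <- integer(0); ecum <- numeric(0); erel <- integer(0)
  nb <- scheme$transitions[scheme$transitions$kind != "binding", ]
  for (s in seq_along(states)) {
    e <- nb[nb$from == states[s], ]
    eoff[s + 1] <- eoff[s] + nrow(e)
    if (nrow(e)) {
      eto <- c(eto, match(e$to, states) - 1L)
      ecum <- c(ecum, cumsum(e$rate * dt_s))
      erel <- c(erel, as.integer(e$kind == "unbinding"))
    }
  }
  list(n_states = length(states),
       open_state = match(scheme$open_states, states) - 1L,
       bind_to = bind_to, bind_p = bind_p,
       edge_offsets = eoff, edge_to = eto, edge_cum = ecum,
       edge_release = erel,
       is_desens = as.integer(states %in% scheme$desensitized_states))
}

.layout_matrix <- function(layouts) {
  do.call(rbind, lapply(layouts, function(l)
    cbind(l$x_nm, l$y_nm, ifelse(l$group == "nanocolumn", 1, 2))))
}

.assemble_result <- function(raw, params, numerics, n_steps, n_reps,
                             event_times_ms, layouts) {
  res <- list(
    time_ms = seq_len(n_steps) * numerics$dt_ns * 1e-6,
    I_mean = raw$I_mean, I_min = raw$I_min, I_max = raw$I_max,
    n_open_mean = raw$n_open_mean,
    g_mean = raw$n_open_mean * params$g_unit,
    desens_frac = raw$desens_frac,
    per_rep = data.frame(peak_I_pA = raw$peak_I, peak_g_pS = raw$peak_g,
                         Q_fC = raw$Q, max_depol_mV = raw$max_depol,
                         absorbed = raw$absorbed, free = raw$free,
                         bound = raw$bound),
    openings = raw$openings,
    capture_hist = raw$capture_hist,
    event_peaks = raw$event_peaks,
    event_times_ms = event_times_ms,
    n_reps = n_reps, nnt = params$nnt,
    params = params, numerics = numerics,
    layouts = layouts)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation result: %d repetition(s), nnt = %d, %d receptors, %g ms at dt = %g ns\n",
              x$n_reps, x$nnt, if (length(x$layouts)) nrow(x$layouts[[1]]) else 0,
              max(x$time_ms), x$numerics$dt_ns))
  cat(sprintf("  mean peak current %.3g pA, mean charge %.3g fC, max cleft depolarization %.3g mV\n",
              max(x$I_mean), mean(x$per_rep$Q_fC), max(x$per_rep$max_depol_mV)))
  invisible(x)
}

.run_core <- function(params, numerics, n_reps, seed, event_times_ms,
                      layout_policy, layout, field, drift, lateral,
                      D_r_in, D_r_out) {
  validate_parameters(params)
  scheme <- ampar_kinetic_scheme(params$affinity_scale)
  validate_scheme(scheme, numerics$dt_ns)
  if (is.null(n_reps)) n_reps <- numerics$n_reps
  if (is.null(n_reps)) n_reps <- default_reps(params$nnt)
  n_reps <- as.integer(n_reps)
  duration_ms <- numerics$duration_ms
  n_steps <- as.integer(round(duration_ms * 1e6 / numerics$dt_ns))
  event_steps <- as.integer(round(event_times_ms * 1e6 / numerics$dt_ns))
  if (any(diff(event_steps) < 1) && length(event_steps) > 1)
    stop("event interval shorter than one time step")
  if (any(event_steps >= n_steps)) stop("an event falls after the end of the simulation")

  if (layout_policy == "fixed") {
    if (is.null(layout)) {
      set.seed(seed)
      layout <- place_receptors(params)
    }
    layouts <- list(layout)
  } else {
    set.seed(seed)
    layouts <- lapply(seq_len(n_reps), function(i) place_receptors(params))
  }
  n_rec <- nrow(layouts[[1]])
  lay_m <- if (n_rec > 0) .layout_matrix(layouts) else matrix(0, 0, 3)

  conf <- c(
    list(R = params$R, H_c = params$H_c, D = params$D, ani = params$ani,
         D_ani = params$D_ani, r_ves = params$r_ves,
         release_offset = params$release_offset,
         dt_ns = numerics$dt_ns, n_steps = n_steps, nnt = params$nnt,
         event_steps = event_steps, b_rad = numerics$b_rad,
         g_unit = params$g_unit, E_intra = params$E_intra,
         Res = params$Res, grid_d = numerics$grid_d,
         F = params$F, Rg = params$Rg, T = params$T,
         field = field, drift = drift,
         capture_mode = if (identical(numerics$capture_geometry,
                                      "hemisphere")) 0L else 1L,
         lateral = switch(lateral, off = 0L, free = 1L, grouped = 2L),
         D_r_in = if (is.null(D_r_in)) params$D_r else D_r_in,
         D_r_out = if (is.null(D_r_out)) params$D_r else D_r_out,
         receptor_grid_h = numerics$receptor_grid_h,
         n_reps = n_reps, seed = seed,
         layouts = lay_m, n_layouts = length(layouts)),
    .scheme_tables(scheme, params, numerics))
  raw <- cpp_run(conf)
  .assemble_result(raw, params, numerics, n_steps, n_reps,
                   event_times_ms, layouts)
}

#' Run a Monte Carlo ensemble of single-release events
#'
#' Simulates `n_reps` independent repetitions of one vesicle opening: `nnt`
#' glutamate molecules released at t = 0 diffuse through the cleft, bind to
#' receptors, and the resulting open-channel configuration drives the
#' finite-volume cleft potential, which feeds back on the driving force and
#' on glutamate drift. Per step the engine executes: gradient lookup,
#' Brownian displacement, boundary conditions, capture, Markov transitions,
#' field solve (only when the open-channel configuration changed), and
#' recording.
#'
#' @param params a `"cleft_params"`.
#' @param numerics a `"cleft_numerics"`.
#' @param n_reps repetitions; default from `numerics` or [default_reps()].
#' @param seed integer root seed. Each repetition uses an independent
#'   substream derived from it; the same seed gives bit-identical results.
#' @param layout_policy `"redraw"` (a fresh receptor layout per repetition,
#'   the default) or `"fixed"` (one layout shared by all repetitions, as used
#'   when tracking identified receptors).
#' @param layout optional fixed layout (implies `layout_policy = "fixed"`).
#' @param field logical: solve the cleft potential (the electric feedback on
#'   the driving force).
#' @param drift logical: apply the electrophoretic drift of the charged
#'   glutamate in the solved field.
#' @return a `"simulation_result"`: mean/min/max current traces (pA), mean
#'   open-channel and desensitized-fraction traces, per-repetition summaries
#'   (peak current, peak conductance, charge, maximal cleft depolarization,
#'   final molecule counts), per-receptor opening counts, and the
#'   capture-count histogram.
#' @examples
#' \donttest{
#' p <- simulation_parameters(nnt = 500, n_c = 20, n_r = 20, ani = 0.5)
#' r <- run_ensemble(p, numerics_config(duration_ms = 1), n_reps = 3, seed = 1)
#' max(r$I_mean)
#' }
#' @export
run_ensemble <- function(params, numerics = numerics_config(), n_reps = NULL,
                         seed = 1, layout_policy = c("redraw", "fixed"),
                         layout = NULL, field = TRUE, drift = TRUE) {
  layout_policy <- match.arg(layout_policy)
  if (!is.null(layout)) layout_policy <- "fixed"
  .run_core(params, numerics, n_reps, seed, event_times_ms = 0,
            layout_policy, layout, field, drift, lateral = "off",
            D_r_in = NULL, D_r_out = NULL)
}

#' Run a single repetition
#'
#' Convenience wrapper: [run_ensemble()] with `n_reps = 1` (the mean trace
#' is then the single stochastic realization).
#'
#' @inheritParams run_ensemble
#' @return a `"simulation_result"`.
#' @export
run_single <- function(params, numerics = numerics_config(), seed = 1,
                       layout = NULL, field = TRUE, drift = TRUE) {
  run_ensemble(params, numerics, n_reps = 1, seed = seed,
               layout_policy = if (is.null(layout)) "redraw" else "fixed",
               layout = layout, field = field, drift = drift)
}

#' Run a train of vesicle releases
#'
#' Releases `nnt` molecules at each event time `k / frequency`
#' (k = 0, ..., n_events - 1). Receptor states, bound and free molecules and
#' the layout persist between events, so desensitization accumulates across
#' the train. Optionally the receptors themselves diffuse laterally on an
#' exclusion lattice: `"free"` receptors leaving the synapse are replaced by
#' naive (C0) receptors at the edge; in `"grouped"` mode nanocolumn
#' receptors stay inside the nanocolumn disk and the rest stay outside,
#' with per-group diffusion coefficients.
#'
#' @inheritParams run_ensemble
#' @param frequency stimulation frequency, Hz.
#' @param n_events number of releases.
#' @param receptor_diffusion `"off"`, `"free"` or `"grouped"`.
#' @param D_r_in,D_r_out per-group receptor diffusion coefficients, um^2/s
#'   (default `params$D_r` for both).
#' @param duration_ms total simulated time; default `n_events / frequency`
#'   seconds worth of events.
#' @return a `"simulation_result"`; `event_peaks` holds the per-event peak
#'   currents (events x repetitions).
#' @export
run_train <- function(params, numerics = numerics_config(), frequency = 100,
                      n_events = 5, n_reps = 20, seed = 1,
                      receptor_diffusion = c("off", "free", "grouped"),
                      D_r_in = NULL, D_r_out = NULL,
                      layout_policy = c("redraw", "fixed"), layout = NULL,
                      duration_ms = NULL, field = TRUE, drift = TRUE) {
  receptor_diffusion <- match.arg(receptor_diffusion)
  layout_policy <- match.arg(layout_policy)
  if (!is.null(layout)) layout_policy <- "fixed"
  interval_ms <- 1000 / frequency
  if (interval_ms < numerics$dt_ns * 1e-6)
    stop("event interval shorter than one time step")
  event_times_ms <- (seq_len(n_events) - 1) * interval_ms
  if (is.null(duration_ms)) duration_ms <- n_events * interval_ms
  numerics$duration_ms <- duration_ms
  .run_core(params, numerics, n_reps, seed, event_times_ms,
            layout_policy, layout, field, drift,
            lateral = receptor_diffusion, D_r_in = D_r_in,
            D_r_out = D_r_out)
}
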