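#' Physical and geometric parameters of the simulated synapse
#'
#' Builds the validated parameter set describing the synapse: the cylindrical
#' cleft, the presynaptic vesicle, the postsynaptic receptor population, the
#' nanocolumn (a zone of hindered lateral diffusion aligned with a dense
#' receptor cluster), and the electrical constants used by the finite-volume
#' field solve.
#'
#' All lengths are in nanometres. `D` is numerically identical in
#' \eqn{\mu m^2/ms} and \eqn{nm^2/ns}, which is the unit system the stepping
#' code works in.
#'
#' @param R cleft (synaptic space) radius, nm.
#' @param H_c cleft height, nm.
#' @param r_ves vesicle radius, nm.
#' @param nnt number of glutamate molecules released per vesicle opening.
#' @param ani anisotropy coefficient in `[0, 1)`: fraction by which lateral
#'   (xy) displacement is reduced inside the nanocolumn zone.
#' @param n_r number of receptors distributed uniformly over the PSD,
#'   outside the nanocolumn cluster.
#' @param n_c number of receptors in the nanocolumn cluster.
#' @param D_dr diameter of the postsynaptic density (PSD), nm.
#' @param R_std radial scale of the nanocolumn receptor distribution, nm.
#' @param D_ani diameter of the anisotropic-diffusion (nanocolumn) zone, nm.
#' @param D glutamate diffusion coefficient, \eqn{\mu m^2/ms}.
#' @param D_r receptor lateral diffusion coefficient, \eqn{\mu m^2/s}.
#' @param g_unit unitary conductance of one open channel, pS.
#' @param E_intra intracellular potential, mV (held fixed; resting value).
#' @param E_syn synaptic reversal potential, mV.
#' @param Res resistivity of the extracellular medium, Ohm cm.
#' @param N_A,F,Rg,T Avogadro number, Faraday constant, gas constant,
#'   absolute temperature.
#' @param affinity_scale multiplier applied to the two main binding rate
#'   constants (C0->C1 and C1->C2); models drugs changing receptor affinity.
#' @param release_offset distance of the release-site centre from the
#'   synapse centre, nm.
#'
#' @return A list of class `"cleft_params"`.
#' @examples
#' p <- simulation_parameters(nnt = 1000, ani = 0.5)
#' p$nnt
#' @export
simulation_parameters <- function(R = 1000, H_c = 20, r_ves = 20, nnt = 1000,
                                  ani = 0, n_r = 40, n_c = 40, D_dr = 400,
                                  R_std = 50, D_ani = 100, D = 0.3, D_r = 0.1,
                                  g_unit = 25, E_intra = -65, E_syn = 0,
                                  Res = 200, N_A = 6.022e23, F = 96485,
                                  Rg = 8.3144, T = 300,
                                  affinity_scale = 1, release_offset = 0) {
  p <- list(R = R, H_c = H_c, r_ves = r_ves, nnt = as.integer(nnt), ani = ani,
            n_r = as.integer(n_r), n_c = as.integer(n_c), D_dr = D_dr,
            R_std = R_std, D_ani = D_ani, D = D, D_r = D_r, g_unit = g_unit,
            E_intra = E_intra, E_syn = E_syn, Res = Res, N_A = N_A, F = F,
            Rg = Rg, T = T, affinity_scale = affinity_scale,
            release_offset = release_offset)
  class(p) <- "cleft_params"
  validate_parameters(p)
  p
}

#' @export
print.cleft_params <- function(x, ...) {
  cat("Synapse parameters (cleftsim)\n")
  cat(sprintf("  cleft: R = %g nm, H_c = %g nm; vesicle r_ves = %g nm, nnt = %d\n",
              x$R, x$H_c, x$r_ves, x$nnt))
  cat(sprintf("  nanocolumn: D_ani = %g nm, ani = %g, R_std = %g nm, n_c = %d; PSD D_dr = %g nm, n_r = %d\n",
              x$D_ani, x$ani, x$R_std, x$n_c, x$D_dr, x$n_r))
  cat(sprintf("  diffusion: D = %g um^2/ms, D_r = %g um^2/s; release offset = %g nm\n",
              x$D, x$D_r, x$release_offset))
  cat(sprintf("  electrics: g_unit = %g pS, E_intra = %g mV, E_syn = %g mV, Res = %g Ohm cm\n",
              x$g_unit, x$E_intra, x$E_syn, x$Res))
  if (x$affinity_scale != 1)
    cat(sprintf("  affinity scale on K1, K2: %g\n", x$affinity_scale))
  invisible(x)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "cleft_params"))
  lens <- c("R", "H_c", "r_ves", "D_dr", "R_std", "D_ani")
  for (f in lens)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("parameter '%s' must be a positive length (nm)", f))
  if (p$D <= 0) stop("diffusion coefficient D must be positive")
  if (p$ani < 0 || p$ani >= 1) stop("anisotropy coefficient must be in [0, 1)")
  if (p$nnt < 0) stop("nnt must be non-negative")
  if (p$n_r < 0 || p$n_c < 0) stop("receptor counts must be non-negative")
  if (p$r_ves > p$R) stop("vesicle radius exceeds cleft radius")
  if (p$D_ani > 2 * p$R) stop("nanocolumn diameter exceeds the cleft")
  if (p$release_offset < 0 || p$release_offset + p$r_ves > p$R)
    stop("release site (offset + r_ves) must lie inside the cleft")
  if (p$affinity_scale <= 0) stop("affinity_scale must be positive")
  if (p$D_r < 0) stop("receptor diffusion coefficient must be non-negative")
  invisible(TRUE)
}

#' Numerical settings for the stochastic engine
#'
#' @param dt_ns time step, ns. The default 50 ns gives a per-step displacement
#'   \eqn{\sqrt{6 D \Delta t} \approx 9.5} nm at D = 0.3 um^2/ms, i.e. of the
#'   order of the physical extent of a receptor.
#' @param duration_ms simulated time per release, ms.
#' @param n_reps number of Monte Carlo repetitions; `NULL` means the
#'   default `round(1e6 / nnt)` clipped to `[20, 1000]` (see [default_reps()]).
#' @param b_rad binding (capture) radius of a receptor, nm.
#' @param grid_d element size of the finite-volume field grid, nm.
#' @param receptor_grid_h lattice spacing for receptor lateral diffusion, nm.
#' @param capture_geometry shape of the region in which a glutamate molecule
#'   can be captured by a receptor. `"cylinder"` (default): the space
#'   occupied by the receptor protrusion — xy distance to the receptor
#'   within `b_rad` and z within `b_rad` of the postsynaptic membrane.
#'   `"hemisphere"`: 3-D distance to the receptor's membrane anchor point
#'   within `b_rad`. The equivalent concentration always uses the
#'   half-sphere volume.
#' @param seed optional RNG seed stored with the configuration.
#' @return A list of class `"cleft_numerics"`.
#' @export
numerics_config <- function(dt_ns = 50, duration_ms = 3, n_reps = NULL,
                            b_rad = 5, grid_d = 20, receptor_grid_h = 10,
                            capture_geometry = c("cylinder", "hemisphere"),
                            seed = NULL) {
  capture_geometry <- match.arg(capture_geometry)
  if (dt_ns <= 0) stop("dt_ns must be positive")
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (!is.null(n_reps) && n_reps < 1) stop("n_reps must be >= 1")
  if (b_rad <= 0) stop("b_rad must be positive")
  if (grid_d <= 0) stop("grid_d must be positive")
  if (receptor_grid_h <= 0) stop("receptor_grid_h must be positive")
  n <- list(dt_ns = dt_ns, duration_ms = duration_ms,
            n_reps = if (is.null(n_reps)) NULL else as.integer(n_reps),
            b_rad = b_rad, grid_d = grid_d,
            receptor_grid_h = receptor_grid_h,
            capture_geometry = capture_geometry, seed = seed)
  class(n) <- "cleft_numerics"
  n
}

#' @export
print.cleft_numerics <- function(x, ...) {
  cat(sprintf("Numerics: dt = %g ns, duration = %g ms, reps = %s, b_rad = %g nm, field grid = %g nm\n",
              x$dt_ns, x$duration_ms,
              if (is.null(x$n_reps)) "auto (1e6/nnt)" else x$n_reps,
              x$b_rad, x$grid_d))
  invisible(x)
}

#' Default repetition count for a given vesicle size
#'
#' `round(1e6 / nnt)` repetitions, clipped to `[20, 1000]`: smooth ensemble
#' means for small vesicles without an excessive cost for large ones.
#'
#' @param nnt number of released molecules.
#' @return integer repetition count.
#' @export
default_reps <- function(nnt) {
  if (nnt <= 0) return(20L)
  as.integer(min(1000, max(20, round(1e6 / nnt))))
}

#' Vesicle volume and transmitter content
#'
#' A spherical vesicle of radius `r_ves` holds
#' \eqn{V = \frac{4}{3}\pi r_{ves}^3} of transmitter solution; at
#' concentration `conc` that corresponds to `V[L] * conc[M] * N_A` molecules.
#'
#' @param r_ves vesicle radius, nm.
#' @param conc transmitter concentration in the vesicle, mM.
#' @param N_A Avogadro number.
#' @return list with `volume_m3` and `n_molecules` (nearest integer).
#' @examples
#' vesicle_content(20, 50)   # ~3.35e-23 m^3, ~1009 molecules
#' @export
vesicle_content <- function(r_ves = 20, conc = 50, N_A = 6.022e23) {
  if (r_ves <= 0) stop("r_ves must be positive")
  if (conc <= 0) stop("conc must be positive")
  vol_nm3 <- 4 / 3 * pi * r_ves^3
  vol_m3 <- vol_nm3 * 1e-27
  n <- round(vol_m3 * 1e3 * conc * 1e-3 * N_A)  # m^3 -> L, mM -> M
  list(volume_m3 = vol_m3, n_molecules = n)
}

## Effective-diffusion reduction by regularly spaced cylindrical obstacles.
## Two regimes in the filling fraction sigma: for small sigma the factor is
## 1 - sigma; for large sigma it is 2 sqrt(pi/4 - sigma) / (pi^(3/2) (1 - pi/4)).
## The two expressions intersect near sigma ~ 0.766; the "auto" branch switches
## there so that the returned factor is continuous in sigma.

.small_branch <- function(sigma) 1 - sigma
.large_branch <- function(sigma) {
  2 * sqrt(pi / 4 - sigma) / (pi^1.5 * (1 - pi / 4))
}

.branch_crossover <- function() {
  stats::uniroot(function(s) .large_branch(s) - .small_branch(s),
                 interval = c(0.3, pi / 4 - 1e-12), tol = 1e-12)$root
}

#' Diffusion reduction factor from the obstacle filling fraction
#'
#' Maps the fraction `sigma` of the cleft cross-section occupied by
#' trans-synaptic filaments (modelled as regularly spaced cylinders) to the
#' factor by which effective lateral diffusion is reduced.
#'
#' @param sigma filling fraction, `0 <= sigma < pi/4`.
#' @param branch `"auto"` (continuous crossover), `"small"` (`1 - sigma`) or
#'   `"large"` (the dense-packing expression, defined for `sigma < pi/4`).
#' @return reduction factor in (0, maximum of the chosen branch].
#' @seealso [filling_from_factor()] for the inverse.
#' @examples
#' anisotropy_from_filling(0.05)          # 0.95, dilute regime
#' filling_from_factor(0.1)               # ~0.78: a 90% reduction
#' @export
anisotropy_from_filling <- function(sigma, branch = c("auto", "small", "large")) {
  branch <- match.arg(branch)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (branch != "small" && any(sigma >= pi / 4))
    stop("the large-sigma expression requires sigma < pi/4")
  if (branch == "small" && any(sigma >= 1))
    stop("the small-sigma expression requires sigma < 1")
  switch(branch,
         small = .small_branch(sigma),
         large = .large_branch(sigma),
         auto = {
           cr <- .branch_crossover()
           ifelse(sigma < cr, .small_branch(sigma), .large_branch(sigma))
         })
}

#' Obstacle filling fraction from a diffusion reduction factor
#'
#' Inverse of [anisotropy_from_filling()]. Factors above the crossover value
#' invert the dilute branch in closed form; smaller factors (strong hindrance,
#' e.g. the factor 0.1 corresponding to an anisotropy coefficient of 0.9)
#' invert the dense branch by 1-D root finding to `tol`.
#'
#' @param factor diffusion reduction factor in (0, 1].
#' @param tol root-finding tolerance on sigma.
#' @return filling fraction sigma.
#' @export
filling_from_factor <- function(factor, tol = 1e-9) {
  if (length(factor) != 1 || !is.finite(factor))
    stop("factor must be a single finite number")
  if (factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]: outside the attainable range")
  cr <- .branch_crossover()
  if (factor >= .small_branch(cr)) return(1 - factor)
  stats::uniroot(function(s) .large_branch(s) - factor,
                 interval = c(cr, pi / 4 - 1e-12), tol = tol)$root
}

#' The two conventions for lateral hindrance
#'
#' The position update scales the xy *displacement* inside the nanocolumn by
#' `1 - ani`, which reduces the xy diffusion *coefficient* by `(1 - ani)^2`.
#' Narrative statements of the form "a reduction of xy diffusion by 90%" refer
#' to the displacement convention; this helper converts between the two.
#'
#' @param ani anisotropy coefficient in `[0, 1]`.
#' @return list with `displacement` (`1 - ani`) and `diffusivity`
#'   (`(1 - ani)^2`) reduction factors.
#' @export
anisotropy_factors <- function(ani) {
  stopifnot(all(ani >= 0), all(ani <= 1))
  list(displacement = 1 - ani, diffusivity = (1 - ani)^2)
}

#' Read / write flat key = value configuration files
#'
#' Scenario and user configurations are flat `key = value` text files whose
#' keys mirror the parameter symbols (plus the numerics keys `dt_ns`,
#' `duration_ms`, `n_reps`, `b_rad`, `grid_d`, `receptor_grid_h`, and the
#' optional flags `fixed_layout`, `frequency_hz`, `n_events`,
#' `description`). Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_config()`: a list with elements `params`
#'   (`"cleft_params"`), `numerics` (`"cleft_numerics"`) and `extra` (any
#'   remaining keys). `write_config()`: the path, invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line (expected key = value)")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  parsed <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- keys
  pf <- names(formals(simulation_parameters))
  nf <- setdiff(names(formals(numerics_config)), "seed")
  params <- do.call(simulation_parameters, parsed[intersect(keys, pf)])
  numerics <- do.call(numerics_config, parsed[intersect(keys, nf)])
  extra <- parsed[setdiff(keys, c(pf, nf))]
  list(params = params, numerics = numerics, extra = extra)
}

#' @rdname read_config
#' @param params a `"cleft_params"` object.
#' @param numerics a `"cleft_numerics"` object (optional).
#' @param extra named list of additional keys to store.
#' @export
write_config <- function(path, params, numerics = NULL, extra = list()) {
  fmt <- function(x) {
    if (is.logical(x)) tolower(as.character(x))
    else if (is.numeric(x)) format(x, digits = 15)
    else as.character(x)
  }
  items <- unclass(params)
  if (!is.null(numerics)) {
    nn <- unclass(numerics)
    nn$seed <- NULL
    nn <- nn[!vapply(nn, is.null, TRUE)]
    items <- c(items, nn)
  }
  items <- c(items, extra)
  writeLines(sprintf("%s = %s", names(items), vapply(items, fmt, "")), path)
  invisible(path)
}
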