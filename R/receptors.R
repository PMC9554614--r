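#' Equivalent concentration of one molecule in the capture half-sphere
#'
#' Binding rates are given per molar concentration; a single glutamate
#' molecule within the binding radius of a receptor is converted to a
#' concentration `C = 1 / (N_A * Vol)` with `Vol = (2/3) pi b_rad^3` the
#' half-sphere volume above the postsynaptic membrane (1 nm^3 = 1e-24 L).
#'
#' @param b_rad binding radius, nm.
#' @param N_A Avogadro number.
#' @return molar concentration.
#' @examples
#' equivalent_concentration(5)   # ~6.34 mM
#' @export
equivalent_concentration <- function(b_rad = 5, N_A = 6.022e23) {
  if (b_rad <= 0) stop("b_rad must be positive")
  vol_L <- (2 / 3) * pi * b_rad^3 * 1e-24
  1 / (N_A * vol_L)
}

#' Receptor state bookkeeping
#'
#' Creates the per-receptor state container used by the R-level stepping
#' operations: every receptor starts closed and unbound (C0).
#'
#' @param n number of receptors.
#' @return list of class `"receptor_states"` with `state` (labels),
#'   `bound` (n x 2 matrix of bound molecule ids), `openings` (cumulative
#'   entries into the open state).
#' @export
init_receptor_states <- function(n) {
  st <- list(state = rep("C0", n),
             bound = matrix(NA_integer_, nrow = n, ncol = 2),
             openings = rep(0L, n))
  class(st) <- "receptor_states"
  st
}

#' @export
print.receptor_states <- function(x, ...) {
  print(table(factor(x$state, levels = ampar_kinetic_scheme()$states)))
  invisible(x)
}

.check_receptor_states <- function(states, scheme) {
  nb <- rowSums(!is.na(states$bound))
  expected <- scheme$glu_count[states$state]
  if (any(nb != expected))
    stop("bound-molecule count inconsistent with receptor state labels")
  invisible(TRUE)
}

#' Glutamate capture by receptors
#'
#' A free molecule inside a receptor's capture region binds, provided the
#' receptor's state has an available binding transition, with per-step
#' probability `k_on * C_eq * dt`, where `C_eq` is the
#' [equivalent_concentration()]. The capture region is set by
#' `numerics$capture_geometry`: the space occupied by the receptor
#' protrusion (`"cylinder"`: xy distance and height above the postsynaptic
#' membrane both within `b_rad`; the default) or a half-sphere around the
#' membrane anchor point (`"hemisphere"`: 3-D distance to
#' `(x_r, y_r, H_c)` within `b_rad`). At most one binding event per
#' molecule and per receptor per step; when several molecules are eligible
#' for one receptor they are tried in randomized order.
#'
#' @param ensemble a `"molecule_ensemble"`.
#' @param states a `"receptor_states"`.
#' @param layout a `"receptor_layout"`.
#' @param scheme a `"kinetic_scheme"`.
#' @param params,numerics configuration objects.
#' @return list with updated `ensemble` and `states`.
#' @export
attempt_binding <- function(ensemble, states, layout, scheme, params,
                            numerics) {
  dt_s <- numerics$dt_ns * 1e-9
  ceq <- equivalent_concentration(numerics$b_rad, params$N_A)
  bedges <- .binding_edges(scheme)
  for (e in bedges)
    if (e$rate * ceq * dt_s >= 1)
      stop("binding probability k_on * C_eq * dt >= 1: decrease the time step")
  free <- which(ensemble$status == 0L &
                  ensemble$z >= params$H_c - numerics$b_rad)
  if (length(free) == 0) return(list(ensemble = ensemble, states = states))
  bound_mol <- logical(length(ensemble$x))
  for (r in sample.int(nrow(layout))) {
    st <- states$state[r]
    edge <- bedges[[st]]
    if (is.null(edge)) next
    d2 <- (ensemble$x[free] - layout$x_nm[r])^2 +
      (ensemble$y[free] - layout$y_nm[r])^2
    if (identical(numerics$capture_geometry, "hemisphere"))
      d2 <- d2 + (ensemble$z[free] - params$H_c)^2
    cand <- free[d2 <= numerics$b_rad^2]
    cand <- cand[!bound_mol[cand] & ensemble$status[cand] == 0L]
    if (length(cand) == 0) next
    if (length(cand) > 1) cand <- sample(cand)
    p <- edge$rate * ceq * dt_s
    for (m in cand) {
      if (stats::runif(1) < p) {
        ensemble$status[m] <- 1L
        ensemble$bound_to[m] <- r
        ensemble$captures[m] <- ensemble$captures[m] + 1L
        bound_mol[m] <- TRUE
        slot <- which(is.na(states$bound[r, ]))[1]
        states$bound[r, slot] <- m
        states$state[r] <- edge$to
        break   # one binding per receptor per step
      }
    }
  }
  list(ensemble = ensemble, states = states)
}

#' One Markov step for every receptor
#'
#' Handles unbinding and conformational transitions (binding is the job of
#' [attempt_binding()]). Each receptor takes at most one transition per step:
#' a single categorical draw over \{stay\} and the outgoing non-binding edges,
#' each edge with probability `rate * dt`. An unbinding edge releases one
#' bound molecule, which re-enters the free pool at its capture location
#' (the receptor centre, nudged 0.1 nm into the cleft). Entries into the
#' open state increment the per-receptor openings counter.
#'
#' @inheritParams attempt_binding
#' @return list with updated `states` and `ensemble`.
#' @export
step_markov <- function(states, ensemble, layout, scheme, params, numerics) {
  edges <- .nonbinding_edges(scheme, numerics$dt_ns)
  open_state <- scheme$open_states
  for (r in seq_along(states$state)) {
    e <- edges[[states$state[r]]]
    if (is.null(e)) next
    u <- stats::runif(1)
    k <- findInterval(u, c(0, e$cum), rightmost.closed = FALSE)
    if (k > length(e$to)) next   # stay
    if (e$release[k]) {
      slots <- which(!is.na(states$bound[r, ]))
      slot <- if (length(slots) > 1) sample(slots, 1) else slots
      m <- states$bound[r, slot]
      states$bound[r, slot] <- NA_integer_
      ensemble$status[m] <- 0L
      ensemble$bound_to[m] <- NA_integer_
      ensemble$x[m] <- layout$x_nm[r]
      ensemble$y[m] <- layout$y_nm[r]
      ensemble$z[m] <- params$H_c - 0.1
    }
    if (e$to[k] == open_state && states$state[r] != open_state)
      states$openings[r] <- states$openings[r] + 1L
    states$state[r] <- e$to[k]
  }
  list(states = states, ensemble = ensemble)
}

#' Lateral diffusion of receptors on an exclusion lattice
#'
#' Receptors hop on a square lattice of spacing `h` (one receptor per cell).
#' Per step a receptor attempts a move with probability
#' `p = 4 D_r dt / h^2`, in one of the four lattice directions chosen
#' uniformly; the move executes only if the target cell is free and allowed.
#' In `"free"` mode a receptor whose target cell centre leaves the cleft
#' (beyond the cleft radius) is replaced by a fresh receptor in state C0 at a uniformly
#' chosen edge cell, and any molecules it held are released at its last
#' position. In `"grouped"` mode nanocolumn receptors are confined to the
#' nanocolumn disk and the others are excluded from it (moves violating the
#' confinement are blocked), with optional per-group diffusion coefficients.
#'
#' @param layout a `"receptor_layout"` (coordinates are snapped to cell
#'   centres by the caller or by repeated application of this step).
#' @param states a `"receptor_states"`.
#' @param ensemble a `"molecule_ensemble"` (for releasing molecules held by
#'   replaced receptors).
#' @param params,numerics configuration objects.
#' @param mode `"free"` or `"grouped"`.
#' @param D_r_in,D_r_out per-group diffusion coefficients, um^2/s
#'   (default both `params$D_r`).
#' @return list with updated `layout`, `states`, `ensemble`.
#' @export
lateral_diffusion_step <- function(layout, states, ensemble, params, numerics,
                                   mode = c("free", "grouped"),
                                   D_r_in = NULL, D_r_out = NULL) {
  mode <- match.arg(mode)
  h <- numerics$receptor_grid_h
  if (is.null(D_r_in)) D_r_in <- params$D_r
  if (is.null(D_r_out)) D_r_out <- params$D_r
  ## D_r um^2/s -> nm^2/ns is a factor 1e-3
  p_move <- function(Dr) 4 * Dr * 1e-3 * numerics$dt_ns / h^2
  if (p_move(max(D_r_in, D_r_out)) >= 1)
    stop("lateral move probability >= 1: decrease the time step")
  cell <- function(v) floor((v + params$R) / h)
  center <- function(c) (c + 0.5) * h - params$R
  ci <- cell(layout$x_nm); cj <- cell(layout$y_nm)
  key <- function(i, j) paste(i, j)
  occ <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(layout))) {
    k <- key(ci[r], cj[r])
    if (!is.null(occ[[k]])) stop("two receptors occupy one lattice cell")
    occ[[k]] <- r
  }
  in_col <- function(x, y) x^2 + y^2 <= (params$D_ani / 2)^2
  edge_cells <- attr(layout, "edge_cells")
  dirs <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), ncol = 2, byrow = TRUE)
  for (r in seq_len(nrow(layout))) {
    Dr <- if (layout$group[r] == "nanocolumn") D_r_in else D_r_out
    if (Dr <= 0) next
    if (stats::runif(1) >= p_move(Dr)) next
    d <- dirs[sample.int(4, 1), ]
    ti <- ci[r] + d[1]; tj <- cj[r] + d[2]
    tx <- center(ti); ty <- center(tj)
    if (mode == "grouped") {
      keep <- if (layout$group[r] == "nanocolumn") in_col(tx, ty) else
        !in_col(tx, ty) && tx^2 + ty^2 <= params$R^2
      if (!keep) next
    }
    if (tx^2 + ty^2 > params$R^2) {
      ## leaves the synapse: replace by a naive receptor at the edge
      held <- which(!is.na(states$bound[r, ]))
      for (slot in held) {
        m <- states$bound[r, slot]
        ensemble$status[m] <- 0L
        ensemble$bound_to[m] <- NA_integer_
        ensemble$x[m] <- layout$x_nm[r]; ensemble$y[m] <- layout$y_nm[r]
        ensemble$z[m] <- params$H_c - 0.1
        states$bound[r, slot] <- NA_integer_
      }
      if (is.null(edge_cells)) {
        rng <- 0:(ceiling(2 * params$R / h) - 1)
        grid <- expand.grid(i = rng, j = rng)
        cx <- center(grid$i); cy <- center(grid$j)
        inside <- cx^2 + cy^2 <= params$R^2
        nbout <- (abs(cx) + h)^2 + cy^2 > params$R^2 |
          cx^2 + (abs(cy) + h)^2 > params$R^2
        edge_cells <- grid[inside & nbout, ]
      }
      repeat {
        pick <- edge_cells[sample.int(nrow(edge_cells), 1), ]
        if (is.null(occ[[key(pick$i, pick$j)]])) break
      }
      rm(list = key(ci[r], cj[r]), envir = occ)
      ci[r] <- pick$i; cj[r] <- pick$j
      occ[[key(ci[r], cj[r])]] <- r
      layout$x_nm[r] <- center(ci[r]); layout$y_nm[r] <- center(cj[r])
      states$state[r] <- "C0"
      next
    }
    if (!is.null(occ[[key(ti, tj)]])) next   # target occupied
    rm(list = key(ci[r], cj[r]), envir = occ)
    ci[r] <- ti; cj[r] <- tj
    occ[[key(ti, tj)]] <- r
    layout$x_nm[r] <- tx; layout$y_nm[r] <- ty
  }
  attr(layout, "edge_cells") <- edge_cells
  list(layout = layout, states = states, ensemble = ensemble)
}

#' Opening and desensitization summaries over repetitions
#'
#' @param openings matrix of per-receptor opening counts (receptors x
#'   repetitions), or a `"simulation_result"` holding one.
#' @param thresholds opening-count thresholds reported as
#'   "fraction opening at least k times".
#' @return list with `frac_never`, `frac_at_least` (named by threshold),
#'   `opening_distribution` (tabulated counts) and, when the input result
#'   carries one, the time course of the desensitized fraction.
#' @export
receptor_statistics <- function(openings, thresholds = c(1, 12)) {
  desens <- NULL
  if (inherits(openings, "simulation_result")) {
    desens <- openings$desens_frac
    openings <- openings$openings
  }
  if (length(openings) == 0)
    stop("receptor_statistics needs at least one completed repetition")
  counts <- as.vector(openings)
  out <- list(
    frac_never = mean(counts == 0),
    frac_at_least = stats::setNames(
      vapply(thresholds, function(k) mean(counts >= k), 0),
      paste0("ge", thresholds)),
    opening_distribution = table(counts))
  if (!is.null(desens)) out$desens_frac <- desens
  out
}
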