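## Molecule ensemble: a column-oriented container for glutamate molecules.
## status codes: 0 free, 1 bound, 2 absorbed.

new_molecule_ensemble <- function(x, y, z) {
  n <- length(x)
  ens <- list(x = x, y = y, z = z,
              status = rep(0L, n),
              bound_to = rep(NA_integer_, n),
              captures = rep(0L, n))
  class(ens) <- "molecule_ensemble"
  ens
}

#' @export
print.molecule_ensemble <- function(x, ...) {
  cat(sprintf("Glutamate ensemble: %d molecules (%d free, %d bound, %d absorbed)\n",
              length(x$x), sum(x$status == 0L), sum(x$status == 1L),
              sum(x$status == 2L)))
  invisible(x)
}

#' Initial glutamate positions at vesicle opening
#'
#' At t = 0 the vesicle releases `nnt` molecules at the presynaptic membrane
#' (z = 0), with (x, y) area-uniform on a disk of radius `r_ves` centred at
#' `(release_offset, 0)`.
#'
#' @param params a `"cleft_params"`.
#' @param seed optional seed.
#' @return a `"molecule_ensemble"` (fields `x`, `y`, `z`, `status`,
#'   `bound_to`, `captures`).
#' @export
init_release <- function(params, seed = NULL) {
  validate_parameters(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$nnt
  r <- params$r_ves * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  new_molecule_ensemble(params$release_offset + r * cos(th), r * sin(th),
                        rep(0, n))
}

#' Uniform random unit vectors
#'
#' Draws directions uniformly on the unit sphere by the inverse-CDF
#' construction: with a, b independent uniform on (0, 1), `theta = 2 pi a`,
#' `phi = arccos(1 - 2 b)`, and the vector is
#' `(sin phi cos theta, sin phi sin theta, cos phi)`. The z component is
#' uniform on `[-1, 1]`.
#'
#' @param n number of vectors.
#' @return an `n x 3` matrix of unit vectors.
#' @export
sample_unit_vectors <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  theta <- 2 * pi * stats::runif(n)
  phi <- acos(1 - 2 * stats::runif(n))
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## nm drift per unit gradient (mV/nm): dt[s] * grad[V/m] * D[m^2/s] * F/(Rg T)
.drift_coef <- function(params, numerics) {
  numerics$dt_ns * params$D * params$F / (params$Rg * params$T) * 1e-3
}

#' Advance free molecules by one Brownian step
#'
#' Each free molecule moves by `sqrt(6 D dt)` along a fresh uniform unit
#' vector; inside the nanocolumn zone (pre-step `x^2 + y^2 <= (D_ani/2)^2`)
#' the xy components of the displacement are scaled by `1 - ani`. When field
#' gradients are supplied, a deterministic drift
#' `dt * grad(v) * D F / (Rg T)` (xy only, scaled by the same anisotropy
#' factor) models the electrophoretic force on the -1 charged glutamate.
#' No boundary handling is performed here; see [apply_boundaries()].
#'
#' @param ensemble a `"molecule_ensemble"`.
#' @param params,numerics configuration objects.
#' @param gradients optional output of [field_gradients()]; `NULL` means no
#'   field. Molecules outside the gridded disk get zero drift.
#' @param u optional pre-drawn `n_free x 3` matrix of unit vectors (for
#'   deterministic tests); default draws fresh ones.
#' @return the updated ensemble.
#' @export
step_positions <- function(ensemble, params, numerics, gradients = NULL,
                           u = NULL) {
  free <- which(ensemble$status == 0L)
  n <- length(free)
  if (n == 0) return(ensemble)
  if (is.null(u)) u <- sample_unit_vectors(n)
  if (!is.matrix(u) || nrow(u) != n || ncol(u) != 3)
    stop("unit-vector matrix must be n_free x 3")
  x <- ensemble$x[free]; y <- ensemble$y[free]; z <- ensemble$z[free]
  s <- rep(1, n)
  if (params$ani > 0)
    s[x^2 + y^2 <= (params$D_ani / 2)^2] <- 1 - params$ani
  dr <- sqrt(6 * params$D * numerics$dt_ns)   # nm (D in nm^2/ns)
  nx <- x + dr * s * u[, 1]
  ny <- y + dr * s * u[, 2]
  nz <- z + dr * u[, 3]
  if (!is.null(gradients)) {
    if (!all(c("gx", "gy", "centers") %in% names(gradients)))
      stop("gradients must come from field_gradients()")
    ci <- findInterval(x, gradients$breaks, all.inside = TRUE)
    cj <- findInterval(y, gradients$breaks, all.inside = TRUE)
    idx <- cbind(ci, cj)
    gx <- gradients$gx[idx]; gy <- gradients$gy[idx]
    gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
    cf <- .drift_coef(params, numerics)
    nx <- nx + cf * s * gx
    ny <- ny + cf * s * gy
  }
  ensemble$x[free] <- nx; ensemble$y[free] <- ny; ensemble$z[free] <- nz
  ensemble
}

#' Enforce cleft boundary conditions
#'
#' Reflective (Neumann) conditions at both membranes: a post-step `z < 0`
#' becomes `|z|`, a `z > H_c` becomes `2 H_c - z`. Absorbing (Dirichlet)
#' condition at the lateral edge: molecules with `x^2 + y^2 >= R^2` are
#' removed from play, modelling clearance by perisynaptic astrocytes.
#'
#' @param ensemble a `"molecule_ensemble"` whose free molecules may violate
#'   the bounds by at most one step length.
#' @param params a `"cleft_params"`.
#' @return list with `ensemble` (updated) and `absorbed` (count of molecules
#'   absorbed by this call).
#' @export
apply_boundaries <- function(ensemble, params) {
  free <- which(ensemble$status == 0L)
  z <- ensemble$z[free]
  z <- ifelse(z < 0, -z, ifelse(z > params$H_c, 2 * params$H_c - z, z))
  if (any(z < 0 | z > params$H_c))
    stop("a reflected position is still outside the cleft: the displacement ",
         "exceeds the cleft height; decrease the time step")
  ensemble$z[free] <- z
  out <- ensemble$x[free]^2 + ensemble$y[free]^2 >= params$R^2
  ensemble$status[free[out]] <- 2L
  list(ensemble = ensemble, absorbed = sum(out))
}
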