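#' Finite-volume grid for the cleft potential
#'
#' The cleft disk (radius `R`) is covered by square elements of side
#' `grid_d`; an element belongs to the disk iff its centre does. The
#' extracellular potential `v` (mV) is defined per element, with a Dirichlet
#' ring `v = 0` on the out-of-disk neighbours, and `n` counts the open
#' channels whose (x, y) falls in each element.
#'
#' @param params a `"cleft_params"`.
#' @param grid_d element size, nm.
#' @return list of class `"potential_grid"` with `d`, `breaks`, `centers`,
#'   `nx`, `mask` (in-disk elements), `n` (open-channel counts) and `v`.
#' @export
potential_grid <- function(params, grid_d = 20) {
  nx <- ceiling(2 * params$R / grid_d)
  breaks <- -params$R + grid_d * (0:nx)
  centers <- -params$R + grid_d * (seq_len(nx) - 0.5)
  mask <- outer(centers^2, centers^2, `+`) < params$R^2
  g <- list(d = grid_d, breaks = breaks, centers = centers, nx = nx,
            mask = mask, n = matrix(0L, nx, nx), v = matrix(0, nx, nx),
            R = params$R)
  class(g) <- "potential_grid"
  g
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("Cleft potential grid: %d x %d elements of %g nm (%d in disk), %d open channels, v in [%g, %g] mV\n",
              x$nx, x$nx, x$d, sum(x$mask), sum(x$n), min(x$v), max(x$v)))
  invisible(x)
}

#' Count open channels into grid elements
#'
#' @param grid a `"potential_grid"`.
#' @param x,y coordinates (nm) of the currently open channels.
#' @return the grid with `n` replaced.
#' @export
set_open_channels <- function(grid, x, y) {
  n <- matrix(0L, grid$nx, grid$nx)
  if (length(x)) {
    ci <- findInterval(x, grid$breaks, all.inside = TRUE)
    cj <- findInterval(y, grid$breaks, all.inside = TRUE)
    for (k in seq_along(ci)) n[ci[k], cj[k]] <- n[ci[k], cj[k]] + 1L
  }
  if (any(n[!grid$mask] > 0)) stop("an open channel lies outside the gridded disk")
  grid$n <- n
  grid
}

#' Solve the cleft potential for the current open-channel configuration
#'
#' Neglecting capacitive currents, the net current through each element is
#' zero: the transmembrane current `n_ij g_unit (v_ij - E_intra)` balances
#' the lateral Ohmic currents to the four neighbours, each
#' `(v_ij - v_neighbour) H_c / Res`. With the Dirichlet ring this is a
#' symmetric positive-definite sparse system, solved directly. With the
#' intracellular potential at its (negative) resting value, open channels
#' drive `v` negative: the cleft hyperpolarizes by a few mV and the membrane
#' depolarization is `-v`.
#'
#' @param grid a `"potential_grid"` with `n` populated.
#' @param params a `"cleft_params"`.
#' @return the grid with `v` (mV) replaced.
#' @export
solve_potential <- function(grid, params) {
  idx <- which(grid$mask)
  if (length(idx) == 0) stop("empty grid")
  if (sum(grid$n) == 0) {
    grid$v[] <- 0
    return(grid)
  }
  nid <- matrix(NA_integer_, grid$nx, grid$nx)
  nid[idx] <- seq_along(idx)
  kappa <- params$g_unit * 1e-12 * (params$Res * 1e-2) / (params$H_c * 1e-9)
  ii <- jj <- integer(0); vv <- numeric(0)
  nvec <- grid$n[idx]
  arr <- arrayInd(idx, dim(grid$mask))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ni <- arr[, 1] + d[1]; nj <- arr[, 2] + d[2]
    ok <- ni >= 1 & ni <= grid$nx & nj >= 1 & nj <= grid$nx
    nb <- rep(NA_integer_, length(idx))
    nb[ok] <- nid[cbind(ni[ok], nj[ok])]
    has <- !is.na(nb)
    ii <- c(ii, which(has)); jj <- c(jj, nb[has]); vv <- c(vv, rep(-1, sum(has)))
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_along(idx), ii), j = c(seq_along(idx), jj),
    x = c(4 + nvec * kappa, vv), dims = c(length(idx), length(idx)))
  b <- nvec * kappa * params$E_intra
  v <- as.numeric(Matrix::solve(A, b))
  grid$v[] <- 0
  grid$v[idx] <- v
  grid
}

#' Electric gradients of the solved potential
#'
#' Centred differences `(v[i+1,j] - v[i-1,j]) / (2 d)` in the interior;
#' one-sided differences at elements adjacent to the Dirichlet ring;
#' `NA` outside the disk (treated as zero drift by [step_positions()]).
#'
#' @param grid a solved `"potential_grid"`.
#' @return list with `gx`, `gy` (mV/nm matrices), `breaks`, `centers`.
#' @export
field_gradients <- function(grid) {
  nx <- grid$nx; d <- grid$d
  gx <- gy <- matrix(NA_real_, nx, nx)
  m <- grid$mask; v <- grid$v
  at <- function(i, j) {
    ok <- i >= 1 & i <= nx & j >= 1 & j <= nx
    out <- rep(FALSE, length(i))
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  val <- function(i, j) {
    out <- rep(0, length(i))
    ok <- i >= 1 & i <= nx & j >= 1 & j <= nx
    out[ok] <- v[cbind(i[ok], j[ok])]
    out
  }
  arr <- arrayInd(which(m), dim(m))
  i <- arr[, 1]; j <- arr[, 2]
  lx <- at(i - 1, j); rx <- at(i + 1, j)
  ly <- at(i, j - 1); ry <- at(i, j + 1)
  cgx <- ifelse(lx & rx, (val(i + 1, j) - val(i - 1, j)) / (2 * d),
         ifelse(rx, (val(i + 1, j) - v[cbind(i, j)]) / d,
         ifelse(lx, (v[cbind(i, j)] - val(i - 1, j)) / d, 0)))
  cgy <- ifelse(ly & ry, (val(i, j + 1) - val(i, j - 1)) / (2 * d),
         ifelse(ry, (val(i, j + 1) - v[cbind(i, j)]) / d,
         ifelse(ly, (v[cbind(i, j)] - val(i, j - 1)) / d, 0)))
  gx[cbind(i, j)] <- cgx
  gy[cbind(i, j)] <- cgy
  list(gx = gx, gy = gy, breaks = grid$breaks, centers = grid$centers)
}

#' Total synaptic current and conductance
#'
#' `I = sum n_ij g_unit (v_ij - E_intra)` over the grid (pA, positive =
#' depolarizing) and `g = n_open g_unit` (pS). The effective driving force
#' `I / g` is reduced below `E_syn - E_intra` when the cleft potential is
#' non-zero.
#'
#' @param grid a solved `"potential_grid"`.
#' @param params a `"cleft_params"`.
#' @return list with `I_pA`, `g_pS`, `n_open`, `driving_force_mV`.
#' @export
total_current <- function(grid, params) {
  n_open <- sum(grid$n)
  I <- sum(grid$n * (grid$v - params$E_intra)) * params$g_unit * 1e-3
  g <- n_open * params$g_unit
  list(I_pA = I, g_pS = g, n_open = n_open,
       driving_force_mV = if (g > 0) I / g * 1e3 else NA_real_)
}
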