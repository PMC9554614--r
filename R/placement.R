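#' Draw a postsynaptic receptor layout
#'
#' Nanocolumn receptors are placed with radial distance from the synapse
#' centre drawn as `-R_std * log(1 - u)` (u uniform) and angle uniform on
#' `[0, 2*pi)`; receptors outside the nanocolumn cluster are placed
#' area-uniformly on the PSD disk (radius `D_dr / 2`). A hard-core exclusion
#' keeps every pair of receptor centres at least `min_dist` apart (the
#' physical receptor size); violating candidates are redrawn. Nanocolumn
#' draws falling outside the cleft radius `R` are redrawn (the exponential
#' radial law has an unbounded tail).
#'
#' @param params a `"cleft_params"` object.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param min_dist minimum centre-to-centre distance, nm. Zero disables the
#'   exclusion (useful when checking the radial law itself).
#' @param max_tries redraw budget per receptor before declaring the packing
#'   infeasible.
#' @return data.frame of class `"receptor_layout"` with columns
#'   `id`, `x_nm`, `y_nm`, `group` (`"nanocolumn"` or `"random"`).
#' @examples
#' lay <- place_receptors(simulation_parameters(n_c = 40, n_r = 40), seed = 1)
#' table(lay$group)
#' @export
place_receptors <- function(params, seed = NULL, min_dist = 10,
                            max_tries = 10000) {
  validate_parameters(params)
  if (!is.null(seed)) set.seed(seed)
  n_tot <- params$n_c + params$n_r
  x <- y <- numeric(n_tot)
  group <- character(n_tot)
  check_dist <- function(k, cx, cy) {
    if (min_dist <= 0 || k == 1) return(TRUE)
    i <- seq_len(k - 1)
    all((x[i] - cx)^2 + (y[i] - cy)^2 >= min_dist^2)
  }
  draw <- function(g) {
    if (g == "nanocolumn") {
      r <- -params$R_std * log(1 - stats::runif(1))
      if (r > params$R) return(NULL)   # tail outside the cleft: redraw
    } else {
      r <- (params$D_dr / 2) * sqrt(stats::runif(1))
    }
    th <- stats::runif(1, 0, 2 * pi)
    c(r * cos(th), r * sin(th))
  }
  groups <- c(rep("nanocolumn", params$n_c), rep("random", params$n_r))
  for (k in seq_len(n_tot)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      pt <- draw(groups[k])
      if (is.null(pt)) next
      if (check_dist(k, pt[1], pt[2])) {
        x[k] <- pt[1]; y[k] <- pt[2]; group[k] <- groups[k]
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "receptor packing infeasible: could not place %s receptor %d within %d redraws (min_dist = %g nm)",
        groups[k], k, max_tries, min_dist))
  }
  out <- data.frame(id = seq_len(n_tot), x_nm = x, y_nm = y, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("receptor_layout", "data.frame")
  out
}

#' @rdname read_layout
#' @param layout a `"receptor_layout"`.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write receptor layouts as CSV
#'
#' Columns `id, x_nm, y_nm, group`.
#'
#' @param path file path.
#' @return `read_layout()`: a `"receptor_layout"` data.frame.
#' @export
read_layout <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x_nm", "y_nm", "group") %in% names(out)))
  class(out) <- c("receptor_layout", "data.frame")
  out
}
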