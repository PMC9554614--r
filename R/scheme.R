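#' Nine-state AMPA receptor kinetic scheme
#'
#' The receptor model has three closed states (C0, C1, C2 with 0, 1, 2 bound
#' glutamate molecules), one open state (O2, two bound molecules) and five
#' desensitized states (D1 with one bound molecule, D2a-D2d with two).
#' Opening requires two bound molecules. Binding transitions (rates in
#' M^-1 s^-1, converted to per-step probabilities through the equivalent
#' concentration of one molecule in the capture half-sphere) are
#' C0 -> C1 (K1), C1 -> C2 (K2) and D1 -> D2a (K3); every other transition is
#' first order (s^-1). With no glutamate present, C0 is the unique absorbing
#' state of the chain. Three desensitized substates hang off C2 (and one off
#' the open state, capping sustained cycling at saturating glutamate);
#' recovery of the desensitized pool is dominated by the slow exits K-7,
#' K-9 and K-10, giving the tens-of-milliseconds recovery seen in train
#' simulations.
#'
#' @param affinity_scale multiplier applied to K1 and K2 only (the two main
#'   binding affinities); K3 is left untouched.
#' @return A list of class `"kinetic_scheme"` with elements `states`,
#'   `glu_count` (bound molecules per state), `transitions`
#'   (data.frame: `from`, `to`, `rate`, `kind`, `label`), `open_states`
#'   and `desensitized_states`.
#' @examples
#' sch <- ampar_kinetic_scheme()
#' subset(sch$transitions, kind == "binding")
#' @export
ampar_kinetic_scheme <- function(affinity_scale = 1) {
  if (affinity_scale <= 0) stop("affinity_scale must be positive")
  states <- c("C0", "C1", "C2", "O2", "D1", "D2a", "D2b", "D2c", "D2d")
  glu <- c(C0 = 0L, C1 = 1L, C2 = 2L, O2 = 2L, D1 = 1L,
           D2a = 2L, D2b = 2L, D2c = 2L, D2d = 2L)
  tr <- function(from, to, rate, kind, label)
    data.frame(from = from, to = to, rate = rate, kind = kind, label = label,
               stringsAsFactors = FALSE)
  transitions <- rbind(
    tr("C0", "C1", 1.8412e7 * affinity_scale, "binding", "K1"),
    tr("C1", "C0", 4.323e3, "unbinding", "K-1"),
    tr("C1", "C2", 4.000e6 * affinity_scale, "binding", "K2"),
    tr("C2", "C1", 1.7201e4, "unbinding", "K-2"),
    tr("C2", "O2", 5.1690e4, "conformational", "beta"),
    tr("O2", "C2", 1.0082e4, "conformational", "alpha"),
    tr("C1", "D1", 885.990, "conformational", "K4"),
    tr("D1", "C1", 280.350, "conformational", "K-4"),
    tr("D1", "D2a", 1.9863e7, "binding", "K3"),
    tr("D2a", "D1", 1.168e3, "unbinding", "K-3"),
    tr("C2", "D2a", 449.033, "conformational", "K5"),
    tr("D2a", "C2", 1.944, "conformational", "K-5"),
    tr("D2a", "D2b", 2.797, "conformational", "K6"),
    tr("D2b", "D2a", 3.9497e-2, "conformational", "K-6"),
    tr("C2", "D2c", 1.380e3, "conformational", "K7"),
    tr("D2c", "C2", 421.849, "conformational", "K-7"),
    tr("O2", "D2d", 848.141, "conformational", "K8"),
    tr("D2d", "O2", 538.920, "conformational", "K-8"),
    tr("D2c", "D2d", 51.700, "conformational", "K9"),
    tr("D2d", "D2c", 29.164, "conformational", "K-9"),
    tr("C2", "D2b", 939.000, "conformational", "K10"),
    tr("D2b", "C2", 24.463, "conformational", "K-10"))
  sch <- list(states = states, glu_count = glu, transitions = transitions,
              open_states = "O2",
              desensitized_states = c("D1", "D2a", "D2b", "D2c", "D2d"))
  class(sch) <- "kinetic_scheme"
  validate_scheme(sch)
  sch
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("AMPA receptor kinetic scheme: %d states, %d transitions (%d binding)\n",
              length(x$states), nrow(x$transitions),
              sum(x$transitions$kind == "binding")))
  cat("  states:", paste(x$states, collapse = " "), "\n")
  invisible(x)
}

validate_scheme <- function(scheme, dt_ns = 50) {
  tr <- scheme$transitions
  if (any(tr$rate < 0)) stop("negative rate in kinetic scheme")
  if (sum(tr$kind == "binding") != 3)
    stop("scheme must have exactly 3 binding transitions")
  if (length(scheme$open_states) != 1)
    stop("scheme must have exactly one open state")
  ## glutamate bookkeeping: binding/unbinding edges change the bound count
  ## by +1/-1, conformational edges keep it
  g <- scheme$glu_count
  dglu <- g[tr$to] - g[tr$from]
  expect <- c(binding = 1L, unbinding = -1L, conformational = 0L)
  if (any(dglu != expect[tr$kind]))
    stop("transition inconsistent with per-state glutamate counts")
  ## linearized per-step probabilities must be small at the default step
  if (any(tr$rate[tr$kind != "binding"] * dt_ns * 1e-9 >= 0.1))
    stop("a first-order rate violates rate * dt < 0.1 at dt = ", dt_ns, " ns")
  ## zero glutamate: restricted to non-binding edges, C0 must be the unique
  ## absorbing state and reachable from everywhere
  nb <- tr[tr$kind != "binding", ]
  if (any(nb$from == "C0"))
    stop("C0 must have no outgoing non-binding transition")
  reach <- "C0"
  repeat {
    grow <- unique(nb$from[nb$to %in% reach])
    if (all(grow %in% reach)) break
    reach <- union(reach, grow)
  }
  if (!setequal(reach, scheme$states))
    stop("C0 not reachable from every state without glutamate")
  invisible(TRUE)
}

#' Continuous-time generator of the scheme at fixed glutamate concentration
#'
#' Returns the 9x9 generator matrix Q (rows = from-state) in s^-1, with
#' binding edges entering at `rate * conc`. Used as the matrix-exponential
#' oracle for the sampled Markov dynamics.
#'
#' @param scheme a `"kinetic_scheme"`.
#' @param conc glutamate concentration, molar.
#' @return numeric matrix with state dimnames.
#' @export
scheme_generator <- function(scheme, conc = 0) {
  s <- scheme$states
  Q <- matrix(0, length(s), length(s), dimnames = list(s, s))
  tr <- scheme$transitions
  rate <- ifelse(tr$kind == "binding", tr$rate * conc, tr$rate)
  for (k in seq_len(nrow(tr))) Q[tr$from[k], tr$to[k]] <- Q[tr$from[k], tr$to[k]] + rate[k]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  utils::write.csv(scheme$transitions[c("from", "to", "rate", "kind")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize a kinetic scheme as CSV
#'
#' Columns `from,to,rate,kind`. Reading reconstructs state metadata (bound
#' glutamate counts, open and desensitized sets) from the state labels.
#'
#' @param scheme a `"kinetic_scheme"` (for writing).
#' @param path file path.
#' @return `read_scheme()`: a `"kinetic_scheme"`.
#' @export
read_scheme <- function(path) {
  ref <- ampar_kinetic_scheme()
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "rate", "kind") %in% names(tr)))
  states <- ref$states[ref$states %in% unique(c(tr$from, tr$to))]
  lab <- ref$transitions$label[match(paste(tr$from, tr$to),
                                     paste(ref$transitions$from, ref$transitions$to))]
  tr$label <- lab
  sch <- list(states = states, glu_count = ref$glu_count[states],
              transitions = tr, open_states = "O2",
              desensitized_states = intersect(ref$desensitized_states, states))
  class(sch) <- "kinetic_scheme"
  validate_scheme(sch)
  sch
}

## per-state transition tables used by the R-level stepping operations
.binding_edges <- function(scheme) {
  b <- scheme$transitions[scheme$transitions$kind == "binding", ]
  stats::setNames(lapply(seq_len(nrow(b)), function(i)
    list(to = b$to[i], rate = b$rate[i])), b$from)
}

.nonbinding_edges <- function(scheme, dt_ns) {
  dt_s <- dt_ns * 1e-9
  out <- lapply(scheme$states, function(s) {
    e <- scheme$transitions[scheme$transitions$from == s &
                              scheme$transitions$kind != "binding", ]
    if (nrow(e) == 0) return(NULL)
    p <- e$rate * dt_s
    if (sum(p) >= 1)
      stop("sum of outgoing rate * dt >= 1 for state ", s,
           ": decrease the time step")
    list(to = e$to, p = p, cum = cumsum(p), release = e$kind == "unbinding")
  })
  stats::setNames(out, scheme$states)
}
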