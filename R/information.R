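#' Binary concentration-discrimination problem
#'
#' The decision the cell faces: is the cognate concentration `c0` or `c1`?
#' Concentrations are in `c*` units with midpoint 1, so `c0 = 1 -
#' delta_c_rel/2` and `c1 = 1 + delta_c_rel/2`. The error tolerance `epsilon`
#' is the acceptable probability of deciding wrongly; the default 0.32
#' corresponds to a one-sigma error level.
#'
#' @param delta_c_rel Relative concentration difference `(c1 - c0)/c*`,
#'   default 0.1.
#' @param epsilon Error tolerance, in `(0, 1/2)`.
#' @return An object of class `decision_problem` with elements `c0`, `c1`,
#'   `delta_c_rel`, `epsilon`.
#' @export
decision_problem <- function(delta_c_rel = 0.1, epsilon = 0.32) {
  stopifnot(delta_c_rel > 0, delta_c_rel < 2, epsilon > 0, epsilon < 0.5)
  structure(list(c0 = 1 - delta_c_rel / 2, c1 = 1 + delta_c_rel / 2,
                 delta_c_rel = delta_c_rel, epsilon = epsilon),
            class = "decision_problem")
}

#' Information transmission rate
#'
#' Rate of accumulation of Kullback-Leibler divergence between the Gaussian
#' output distributions under the two hypothesis concentrations, decomposed
#' into an input term (the squared relative concentration difference) and an
#' output term (squared sharpness times squared precision):
#' `IR = (delta_c/c*)^2 * s^2 * p^2` nats per burst cycle, with
#' `p = (2v)^(-1/2)`. Equivalently `IR = (delta_c/c*)^2 (S P)^2` since the
#' occupancy normalizations of `S` and `P` cancel. A telegraph-limit circuit
#' (`S = 1, P = 1/2`) at `delta_c/c* = 0.1` transmits 0.0025 nats = 0.0036
#' bits per burst.
#'
#' @param s Sharpness (dimensionless), or normalized sharpness `S` if `p` is
#'   the normalized precision `P` (the product is all that enters).
#' @param p Precision in burst units.
#' @param delta_c_rel Relative concentration difference, default 0.1.
#' @return List with elements `nats` and `bits` (per burst cycle).
#' @examples
#' information_rate(1, 1/2)$bits   # ~0.0036, the equilibrium optimum
#' information_rate(2, 1/2)$bits   # ~0.0144, the nonequilibrium optimum
#' @export
information_rate <- function(s, p, delta_c_rel = 0.1) {
  nats <- delta_c_rel^2 * s^2 * p^2
  list(nats = nats, bits = nats / log(2))
}

#' Decision-time bound
#'
#' The sequential-probability-ratio-test lower bound on the mean time needed
#' to decide between the two hypothesis concentrations at error tolerance
#' `epsilon`: `T_bar = (1 - 2 epsilon) log((1 - epsilon)/epsilon) / IR`,
#' in burst cycles when `IR` is in nats per burst cycle.
#'
#' @param IR_nats Information rate in nats per burst cycle, `> 0`.
#' @param epsilon Error tolerance, in `(0, 1/2)`.
#' @return Mean decision time in burst cycles.
#' @examples
#' decision_time(0.0025)   # ~109 bursts for the equilibrium optimum
#' @export
decision_time <- function(IR_nats, epsilon = 0.32) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 1/2)")
  (1 - 2 * epsilon) * log((1 - epsilon) / epsilon) / IR_nats
}
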