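## Fast stationary solve on an irreducible generator (no structure checks).
## Replaces the last balance equation by the normalization constraint; one step
## of iterative refinement keeps the residual at machine level even for rate
## matrices spanning many decades.
.stationary <- function(Q) {
  n <- nrow(Q)
  sc <- max(abs(Q))
  Qs <- Q / sc
  A <- t(Qs)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- solve(A, b)
  r <- b - A %*% p
  p <- p + solve(A, r)
  p <- pmax(as.vector(p), 0)
  p / sum(p)
}

#' Stationary distribution of a circuit
#'
#' Solves `pi^T Q = 0`, `sum(pi) = 1` on the chain's single closed
#' communicating class; transient states (for instance noncognate-bound states
#' when `w = 0`) receive probability zero. Errors if the chain has more than
#' one closed class.
#'
#' @param m A `rate_matrix`.
#' @return Probability vector over the states of `m` (canonical order).
#' @examples
#' stationary_distribution(telegraph_matrix(1, 1))  # c(0.5, 0.5)
#' @export
stationary_distribution <- function(m) {
  stopifnot(inherits(m, "rate_matrix"))
  Q <- m$Q
  n <- nrow(Q)
  rec <- recurrent_class(Q)
  pi <- numeric(n)
  pi[rec] <- .stationary(Q[rec, rec, drop = FALSE])
  resid <- max(abs(pi %*% Q) / max(abs(Q)))
  if (resid > 1e-10)
    stop(sprintf("stationary solve failed to converge (residual %.2e)", resid))
  pi
}

#' Entropy production rate (Schnakenberg form)
#'
#' The mean free-energy dissipation rate of the stationary Markov process, in
#' kT per unit time:
#' `phi = sum over edge pairs i < j of (pi_i k_ij - pi_j k_ji) *
#' log(pi_i k_ij / (pi_j k_ji))`. Strictly nonnegative; zero iff the circuit
#' satisfies detailed balance. For the four-state circuit this equals the net
#' cycle flux `J` times the cycle affinity
#' `log(eta_ab * eta_ua / (eta_ib * eta_ba))`.
#'
#' @param m A `rate_matrix`.
#' @param pi Stationary distribution (computed if missing).
#' @return Scalar dissipation rate, kT per unit time.
#' @export
entropy_production <- function(m, pi = stationary_distribution(m)) {
  Q <- m$Q
  n <- nrow(Q)
  sup <- pi > 0
  tot <- 0
  for (i in seq_len(n - 1)) {
    if (!sup[i]) next
    for (j in seq((i + 1), n)) {
      if (!sup[j]) next
      fij <- Q[i, j]; fji <- Q[j, i]
      if (fij == 0 && fji == 0) next
      if (fij == 0 || fji == 0)
        stop("irreversible edge within the stationary support")
      a <- pi[i] * fij; b <- pi[j] * fji
      tot <- tot + (a - b) * log(a / b)
    }
  }
  tot
}

#' Mean burst cycle time
#'
#' The average time to complete one ON -> OFF -> ON fluctuation of the locus
#' conformation, the unit of time in which all performance metrics are
#' expressed. Computed as the reciprocal of the stationary one-way OFF -> ON
#' crossing frequency, `tau_b = 1 / sum over i in OFF, j in ON of pi_i k_ij`,
#' which equals the mean cycle time `1/k_on + 1/k_off` for the telegraph
#' circuit.
#'
#' @param m A `rate_matrix`.
#' @param pi Stationary distribution (computed if missing).
#' @param on_mask Logical ON-state indicator; defaults to the mask stored in
#'   `m`.
#' @return Scalar time (absolute units).
#' @export
burst_cycle_time <- function(m, pi = stationary_distribution(m),
                             on_mask = m$on_mask) {
  stopifnot(any(on_mask), !all(on_mask))
  off <- which(!on_mask)
  on <- which(on_mask)
  flux <- sum(pi[off] * rowSums(m$Q[off, on, drop = FALSE]))
  if (flux <= 0) stop("no OFF -> ON transitions with stationary weight")
  1 / flux
}

#' Full stationary solution of a circuit
#'
#' Bundles the stationary distribution with the derived thermodynamic and
#' timescale quantities: per-edge net fluxes, the scalar cycle flux `J` (when
#' the positive-rate graph is a single cycle, as in the four-state circuit),
#' the burst cycle time, and the entropy production rate both per unit time
#' and per burst cycle.
#'
#' @param m A `rate_matrix`.
#' @return An object of class `stationary_solution`: list with elements `pi`,
#'   `edge_flux` (data frame `from`, `to`, `flux` for each ordered edge),
#'   `J` (`NA` unless the topology is a single cycle), `tau_b`, `phi_rate`,
#'   `phi_per_burst`.
#' @export
steady_state <- function(m) {
  pi <- stationary_distribution(m)
  Q <- m$Q
  ed <- m$edges[m$edges$rate > 0, c("from", "to"), drop = FALSE]
  flux <- pi[ed$from] * Q[cbind(ed$from, ed$to)] -
    pi[ed$to] * Q[cbind(ed$to, ed$from)]
  tau_b <- burst_cycle_time(m, pi)
  phi <- entropy_production(m, pi)
  J <- NA_real_
  A <- Q > 0
  diag(A) <- FALSE
  if (all(rowSums(A) == 2) && all(colSums(A) == 2) && nrow(Q) >= 3) {
    ## single-cycle topology; orient along canonical edge 1 -> 2
    J <- pi[1] * Q[1, 2] - pi[2] * Q[2, 1]
  }
  structure(list(pi = pi,
                 edge_flux = data.frame(from = ed$from, to = ed$to, flux = flux),
                 J = J, tau_b = tau_b, phi_rate = phi,
                 phi_per_burst = phi * tau_b),
            class = "stationary_solution")
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat("<stationary_solution>\n")
  cat("  pi:", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  cat(sprintf("  tau_b = %.4g   phi = %.4g kT/time = %.4g kT/burst\n",
              x$tau_b, x$phi_rate, x$phi_per_burst))
  if (is.finite(x$J)) cat(sprintf("  cycle flux J = %.4g\n", x$J))
  invisible(x)
}
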