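## Restrict a rate_matrix to its recurrent class (identity for the usual
## all-positive-rate circuits). Keeps edges, ON mask and concentration
## dependence consistent so every downstream metric is computed on the chain
## that actually carries stationary weight.
reduce_recurrent <- function(m) {
  rec <- recurrent_class(m$Q)
  if (length(rec) == nrow(m$Q)) return(m)
  keep <- m$edges$from %in% rec & m$edges$to %in% rec & m$edges$rate > 0
  ed <- m$edges[keep, , drop = FALSE]
  remap <- match(seq_len(nrow(m$Q)), rec)
  ed$from <- remap[ed$from]
  ed$to <- remap[ed$to]
  structure(list(states = m$states[rec, , drop = FALSE],
                 Q = m$Q[rec, rec, drop = FALSE],
                 on_mask = m$on_mask[rec], edges = ed, spec = m$spec,
                 conc = m$conc, params = m$params),
            class = "rate_matrix")
}

## Derivative of the generator with respect to cognate concentration: only
## edges carrying a factor of c contribute, at rate/c each.
.dQ_dc <- function(m) {
  n <- nrow(m$Q)
  dQ <- matrix(0, n, n)
  e <- m$edges[m$edges$cexp > 0 & m$edges$rate > 0, , drop = FALSE]
  if (nrow(e)) dQ[cbind(e$from, e$to)] <- e$rate * e$cexp / m$conc$c
  diag(dQ) <- diag(dQ) - rowSums(dQ)
  dQ
}

## Core analytic metrics for an irreducible rate_matrix. Three linear solves:
## the stationary distribution, the concentration-derivative (sharpness) and
## the Poisson equation for the asymptotic variance of the ON indicator.
.metrics_core <- function(m, delta_c_rel = 0.1, epsilon = 0.32, r0 = 1) {
  Q <- m$Q
  n <- nrow(Q)
  on <- m$on_mask
  sc <- max(abs(Q))
  pi <- .stationary(Q)
  pi_a <- sum(pi[on])
  off <- !on
  tau_b <- 1 / sum(pi[off] * rowSums(Q[off, on, drop = FALSE]))

  ## entropy production (Schnakenberg, directed-edge form)
  e <- m$edges[m$edges$rate > 0, , drop = FALSE]
  a <- pi[e$from] * e$rate
  b <- pi[e$to] * Q[cbind(e$to, e$from)]
  phi_rate <- sum(a * log(a / b))

  ## sharpness: implicit differentiation of pi^T Q(c) = 0
  dQ <- .dQ_dc(m)
  Qs <- Q / sc
  A <- t(Qs)
  A[n, ] <- 1
  rhs <- -as.vector(pi %*% (dQ / sc))
  rhs[n] <- 0
  dpi <- solve(A, rhs)
  s <- m$conc$c * sum(dpi[on])

  ## asymptotic variance rate of the ON indicator (Poisson equation)
  bvec <- (pi_a - as.numeric(on)) / sc
  M <- Qs + matrix(1, n, 1) %*% matrix(pi, 1, n)
  g <- solve(M, bvec)
  v_abs <- 2 * sum(pi * (as.numeric(on) - pi_a) * g)
  v <- v_abs / tau_b              # burst-time units
  p <- if (v > 0) 1 / sqrt(2 * v) else NA_real_

  denom <- pi_a * (1 - pi_a)
  S <- s / denom
  P <- p * denom
  IR_nats <- delta_c_rel^2 * s^2 * p^2
  list(pi = pi, pi_a = pi_a, r_bar = r0 * pi_a, tau_b = tau_b,
       phi_rate = phi_rate, phi_per_burst = phi_rate * tau_b,
       s = s, v = v, p = p, S = S, P = P,
       IR_nats = IR_nats, IR_bits = IR_nats / log(2),
       T_bar = decision_time(IR_nats, epsilon))
}

#' Transcriptional sharpness
#'
#' Local sensitivity of the mean transcription rate to the cognate activator
#' concentration, `s = c* dpi_a/dc`, evaluated at the operating concentration
#' with the noncognate concentration held fixed. Computed analytically by
#' implicit differentiation of the stationary condition `pi^T Q(c) = 0`
#' (a bordered linear solve), not by finite differences. The production rate
#' `r0` is normalized out, so `s` is dimensionless.
#'
#' @param spec A [circuit_spec()], or a prebuilt `rate_matrix` (in which case
#'   `params`/`conc` are ignored).
#' @param params A [rate_params()].
#' @param conc A [concentrations()].
#' @return Scalar sharpness `s`.
#' @export
sharpness <- function(spec, params = NULL, conc = concentrations()) {
  m <- if (inherits(spec, "rate_matrix")) spec else
    build_rate_matrix(spec, params, conc)
  m <- reduce_recurrent(m)
  .metrics_core(m)$s
}

#' Output variance rate of the ON indicator
#'
#' Asymptotic variance rate `v` of the time-integrated ON indicator, in
#' burst-time units: the Poisson equation `Q g = pi_a 1 - 1_ON` (with
#' `pi^T g = 0`) gives the absolute rate `v_abs = 2 sum_i pi_i (1_ON,i -
#' pi_a) g_i`, and `v = v_abs / tau_b` converts to burst units. For the
#' telegraph circuit `v = 2 pi^2 (1-pi)^2` exactly, which anchors the
#' precision convention `p = (2 v)^(-1/2)` so that the telegraph attains
#' `P = p pi(1-pi) = 1/2`.
#'
#' @param m A `rate_matrix`.
#' @param pi Stationary distribution (computed if missing).
#' @param on_mask Logical ON-state indicator (defaults to the mask in `m`).
#' @return Scalar variance rate `v` (burst units), with the absolute-time rate
#'   attached as attribute `"v_abs"`.
#' @export
variance_rate <- function(m, pi = NULL, on_mask = m$on_mask) {
  m <- reduce_recurrent(m)
  res <- .metrics_core(m)
  structure(res$v, v_abs = res$v * res$tau_b)
}

#' Transcriptional specificity and cognate fraction
#'
#' Specificity is the concentration-normalized odds of cognate versus
#' noncognate occupancy, `f = (w/c) pi_c / pi_w`, with `pi_c = sum_i n_c,i
#' pi_i` and `pi_w = sum_i n_w,i pi_i` the mean cognate- and noncognate-bound
#' site numbers (for one binding site these are the bound-state
#' probabilities). At thermodynamic equilibrium `f` is pinned to the affinity
#' factor `alpha` for every topology. At `w = 0` the ratio is evaluated in the
#' `w -> 0` limit (`pi_w` vanishes linearly in `w`) and the result carries
#' attribute `"limit" = TRUE`.
#'
#' @param m A `rate_matrix` built from a noncognate-competitor spec.
#' @param pi Stationary distribution (recomputed internally when the limit is
#'   taken).
#' @return Scalar specificity `f`.
#' @export
specificity <- function(m, pi = NULL) {
  stopifnot(inherits(m, "rate_matrix"))
  spec <- m$spec
  if (is.null(spec) || !isTRUE(spec$include_noncognate))
    stop("specificity requires a circuit with the noncognate competitor")
  conc <- m$conc
  limit <- FALSE
  if (conc$w == 0) {
    ## f is analytic in w and pi_w ~ w: evaluate at a tiny w
    limit <- TRUE
    conc <- concentrations(c = conc$c, w = 1e-8, delta_c_rel = conc$delta_c_rel)
    m <- build_rate_matrix(spec, m$params, conc)
    pi <- NULL
  }
  if (is.null(pi)) pi <- stationary_distribution(m)
  pi_c <- sum(m$states$n_c * pi)
  pi_w <- sum(m$states$n_w * pi)
  f <- (conc$w / conc$c) * pi_c / pi_w
  if (limit) attr(f, "limit") <- TRUE
  f
}

#' @rdname specificity
#' @param f Specificity.
#' @param w_over_c Relative noncognate concentration `w/c`.
#' @return `cognate_fraction()`: the share `p_c = f / (f + w/c)` of binding
#'   interactions attributable to the cognate activator.
#' @export
cognate_fraction <- function(f, w_over_c) {
  as.numeric(f) / (as.numeric(f) + w_over_c)
}

#' Nonequilibrium sharpness envelope
#'
#' Upper bound on the observed normalized sharpness of a circuit facing
#' noncognate interference: `S <= f / (w/c + f) * S0`, where `S0` is the
#' intrinsic sharpness (the same circuit's normalized sharpness at `w = 0`)
#' and `f` its specificity. At equilibrium `f = alpha` and `S0 <= 1`, so for
#' `alpha = 100` and `w/c = 1000` the equilibrium limit is 0.09; spending
#' energy can trade `S0` (up to `N_A + 1`) against `f` (up to
#' `alpha^(N_A+1)`), raising the envelope to 0.91 at the `(S0 = 1,
#' f = alpha^2)` endpoint.
#'
#' @param S0 Intrinsic sharpness, `> 0`.
#' @param f Specificity, `> 0`.
#' @param w_over_c Relative noncognate concentration, `>= 0`.
#' @return Upper bound on `S`.
#' @examples
#' sharpness_envelope(1, 100, 1000)    # equilibrium limit ~ 0.09
#' sharpness_envelope(1, 1e4, 1000)    # nonequilibrium proofreading ~ 0.91
#' @export
sharpness_envelope <- function(S0, f, w_over_c) {
  stopifnot(S0 > 0, f > 0, w_over_c >= 0)
  f / (w_over_c + f) * S0
}

#' Intrinsic sharpness
#'
#' The normalized sharpness a circuit would show with zero noncognate
#' concentration: the noncognate-bound states then carry no stationary weight,
#' so `S0` equals the normalized sharpness of the cognate-only circuit with
#' identical parameters. For a circuit without the noncognate competitor,
#' `S0 = S`.
#'
#' @inheritParams sharpness
#' @return Scalar normalized intrinsic sharpness `S0`.
#' @export
intrinsic_sharpness <- function(spec, params, conc = concentrations()) {
  if (inherits(spec, "rate_matrix")) {
    params <- spec$params
    conc <- spec$conc
    spec <- spec$spec
  }
  spec0 <- circuit_spec(spec$n_binding_sites, spec$n_activation_steps,
                        include_noncognate = FALSE,
                        affinity_factor = spec$affinity_factor,
                        max_rate = spec$max_rate)
  conc0 <- concentrations(c = conc$c, w = 0, delta_c_rel = conc$delta_c_rel)
  m <- build_rate_matrix(spec0, params, conc0)
  .metrics_core(m, delta_c_rel = conc$delta_c_rel)$S
}

#' Full response summary of a circuit
#'
#' Computes every input-output metric of one circuit realization at its
#' operating concentrations: ON occupancy `pi_a`, mean rate `r_bar`, burst
#' cycle time `tau_b`, energy dissipation per burst `phi_per_burst`, sharpness
#' `s`, variance rate `v`, precision `p = (2v)^(-1/2)`, normalized sharpness
#' `S = s/(pi_a(1-pi_a))` and precision `P = p pi_a(1-pi_a)`, the information
#' rate in nats and bits per burst, the decision-time bound `T_bar`, and - for
#' circuits with the noncognate competitor - specificity `f`, cognate fraction
#' `p_c` and intrinsic sharpness `S0`.
#'
#' @inheritParams sharpness
#' @param epsilon Decision error tolerance for the reported `T_bar`.
#' @return A one-row data frame of class `response_summary`.
#' @examples
#' response_summary(circuit_spec(), rate_params(), concentrations())
#' @export
response_summary <- function(spec, params = NULL, conc = concentrations(),
                             epsilon = 0.32) {
  m <- if (inherits(spec, "rate_matrix")) spec else
    build_rate_matrix(spec, params, conc)
  mr <- reduce_recurrent(m)
  r0 <- if (!is.null(m$spec)) m$spec$max_rate else 1
  res <- .metrics_core(mr, delta_c_rel = m$conc$delta_c_rel, epsilon = epsilon,
                       r0 = r0)
  out <- data.frame(pi_a = res$pi_a, r_bar = res$r_bar, tau_b = res$tau_b,
                    phi_rate = res$phi_rate, phi_per_burst = res$phi_per_burst,
                    s = res$s, v = res$v, p = res$p, S = res$S, P = res$P,
                    IR_nats = res$IR_nats, IR_bits = res$IR_bits,
                    T_bar = res$T_bar)
  if (!is.null(m$spec) && isTRUE(m$spec$include_noncognate) &&
      !is.null(m$params)) {
    f <- specificity(m)
    out$f <- as.numeric(f)
    out$p_c <- cognate_fraction(f, m$conc$w / m$conc$c)
    out$S0 <- intrinsic_sharpness(m)
  }
  class(out) <- c("response_summary", class(out))
  out
}

#' @export
print.response_summary <- function(x, ...) {
  cat("<response_summary>\n")
  print.data.frame(signif(as.data.frame(x), 4), row.names = FALSE)
  invisible(x)
}
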