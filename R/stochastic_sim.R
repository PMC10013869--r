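#' Exact stochastic simulation of a circuit
#'
#' Gillespie simulation of the CTMC: exponential sojourn in each state at its
#' total exit rate, next state drawn with probability proportional to the
#' outgoing rates. The initial state is drawn from the stationary distribution
#' unless given. Deterministic given `seed`.
#'
#' @param m A `rate_matrix`.
#' @param duration Total simulated time (absolute units), `> 0`.
#' @param seed RNG seed.
#' @param init Optional initial state index.
#' @return An object of class `trajectory`: list with `times` (jump times,
#'   starting at 0), `states` (state index occupied from each jump time until
#'   the next), `on` (ON/OFF telegraph trace per sojourn), `duration`,
#'   `seed`, and the generating `spec`/`params`/`conc` as provenance.
#' @export
gillespie <- function(m, duration, seed = 1L, init = NULL) {
  stopifnot(inherits(m, "rate_matrix"), duration > 0)
  set.seed(seed)
  Q <- m$Q
  n <- nrow(Q)
  exit <- -diag(Q)
  P <- Q
  diag(P) <- 0
  cum <- lapply(seq_len(n), function(i)
    if (exit[i] > 0) cumsum(P[i, ] / exit[i]) else rep(1, n))
  if (is.null(init)) {
    pi <- stationary_distribution(m)
    init <- findInterval(stats::runif(1), cumsum(pi)) + 1L
  }
  cap <- max(256L, ceiling(duration * max(exit) * 1.3) + 64L)
  times <- numeric(cap)
  states <- integer(cap)
  k <- 1L
  states[1] <- init
  t <- 0
  repeat {
    s <- states[k]
    if (exit[s] <= 0) break
    dt <- stats::rexp(1, exit[s])
    t <- t + dt
    if (t >= duration) break
    nxt <- findInterval(stats::runif(1), cum[[s]]) + 1L
    if (k + 1L > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(states) <- cap
    }
    k <- k + 1L
    times[k] <- t
    states[k] <- nxt
  }
  structure(list(times = times[seq_len(k)], states = states[seq_len(k)],
                 on = m$on_mask[states[seq_len(k)]], duration = duration,
                 seed = seed, spec = m$spec, params = m$params, conc = m$conc),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d jumps over t = [0, %g], ON fraction %.3f (seed %d)\n",
              length(x$times) - 1L, x$duration, on_fraction(x), x$seed))
  invisible(x)
}

## Sojourn durations of a trajectory (last sojourn truncated at `duration`).
sojourns <- function(traj) {
  diff(c(traj$times, traj$duration))
}

on_fraction <- function(traj) {
  dt <- sojourns(traj)
  sum(dt[traj$on]) / traj$duration
}

#' Accumulated mRNA along a trajectory
#'
#' Integrates the production rate `r0 * 1_ON` over the trajectory. By default
#' mRNA accumulates deterministically while the locus is ON (synthesis shot
#' noise is excluded from the precision metric, and the same convention is
#' used here); with `poisson = TRUE`, each ON sojourn instead emits a Poisson
#' number of transcripts with the matching mean.
#'
#' @param traj A `trajectory`.
#' @param r0 Production rate while ON.
#' @param poisson Draw Poisson transcript counts per ON sojourn?
#' @param seed Seed for the Poisson draws.
#' @return Data frame with columns `time` and `mrna` (level at each jump
#'   time, ending at `duration`).
#' @export
accumulated_mrna <- function(traj, r0 = 1, poisson = FALSE, seed = 1L) {
  dt <- sojourns(traj)
  inc <- r0 * dt * as.numeric(traj$on)
  if (poisson) {
    set.seed(seed)
    inc <- stats::rpois(length(inc), inc)
  }
  data.frame(time = c(traj$times[-1], traj$duration), mrna = cumsum(inc))
}

## Count completed ON -> OFF -> ON cycles (number of OFF -> ON entries after
## the first).
count_cycles <- function(traj) {
  on <- traj$on
  max(0L, sum(diff(as.integer(on)) == 1L) - 0L)
}

#' Empirical metric estimates from trajectories
#'
#' Brute-force counterparts of the analytic stationary metrics, with
#' uncertainty: the ON occupancy `pi_a` (time fraction), the burst cycle time
#' `tau_b` (total time over completed OFF -> ON crossings), and the variance
#' rate `v` of the integrated ON indicator in burst units (batch-means over
#' windows of `batch_bursts` burst cycles). Standard errors come from a
#' nonparametric bootstrap over batches; very short trajectories yield wide
#' (flagged) errors rather than failures.
#'
#' @param trajs A `trajectory` or list of trajectories.
#' @param batch_bursts Batch length for the variance estimator, in estimated
#'   burst cycles.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List with elements `pi_a`, `tau_b`, `v`, each a `c(estimate, se)`
#'   vector, plus `n_batches` and `flagged` (TRUE when the data were too short
#'   for a stable variance estimate).
#' @export
estimate_metrics <- function(trajs, batch_bursts = 20, n_boot = 200,
                             seed = 1L) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  tot_t <- sum(vapply(trajs, `[[`, 0, "duration"))
  on_t <- sum(vapply(trajs, function(tr) on_fraction(tr) * tr$duration, 0))
  cycles <- sum(vapply(trajs, count_cycles, 0L))
  pi_a <- on_t / tot_t
  tau_b <- tot_t / max(cycles, 1L)
  ## batch means of the ON indicator over windows of batch_bursts * tau_b
  L <- batch_bursts * tau_b
  batch_means <- unlist(lapply(trajs, function(tr) {
    nb <- floor(tr$duration / L)
    if (nb < 1) return(numeric(0))
    edges <- seq(0, by = L, length.out = nb + 1)
    ends <- c(tr$times[-1], tr$duration)
    starts <- tr$times
    vapply(seq_len(nb), function(b) {
      lo <- edges[b]; hi <- edges[b + 1]
      ov <- pmin(ends, hi) - pmax(starts, lo)
      sum(ov[ov > 0 & tr$on]) / L
    }, 0)
  }))
  nb <- length(batch_means)
  flagged <- nb < 10
  v_abs <- if (nb >= 2) L * stats::var(batch_means) else NA_real_
  v <- v_abs / tau_b
  set.seed(seed)
  boot <- if (nb >= 2) {
    vapply(seq_len(n_boot), function(b) {
      idx <- 1L + floor(stats::runif(nb) * nb)
      bm <- batch_means[idx]
      c(mean(bm), L * stats::var(bm) / tau_b)
    }, c(0, 0))
  } else matrix(NA_real_, 2, 1)
  se_pi <- stats::sd(boot[1, ])
  se_v <- stats::sd(boot[2, ])
  se_tau <- tau_b / sqrt(max(cycles, 1L))
  list(pi_a = c(estimate = pi_a, se = se_pi),
       tau_b = c(estimate = tau_b, se = se_tau),
       v = c(estimate = v, se = se_v),
       n_batches = nb, flagged = flagged)
}

#' Simulated sequential decision times
#'
#' Monte-Carlo validation of the decision-time bound: each replicate simulates
#' the circuit under a true concentration (half the replicates at `c0`, half
#' at `c1`), accumulates the Gaussian drift-diffusion log-likelihood ratio of
#' the integrated transcriptional output, and stops at the symmetric Wald
#' thresholds `+/- log((1-epsilon)/epsilon)`. The log-likelihood ratio is
#' piecewise linear between jumps, so threshold crossings are located exactly.
#' Reports the mean stopping time in burst-cycle units, the realized error
#' fraction, and the fraction of replicates that hit the duration cap.
#'
#' @param spec A [circuit_spec()].
#' @param params A [rate_params()].
#' @param c0,c1 The two hypothesis concentrations (`c*` units), `c0 < c1`.
#' @param epsilon Error tolerance in `(0, 1/2)`.
#' @param n_rep Number of replicates.
#' @param seed RNG seed.
#' @param w Noncognate concentration held fixed across hypotheses.
#' @param max_bursts Duration cap per replicate, in burst cycles.
#' @return List with `mean_time` (bursts), `se_time`, `error_rate`,
#'   `cap_fraction`, `predicted` (the analytic bound), `times` and
#'   `decisions` per replicate.
#' @export
sprt_decision_times <- function(spec, params, c0 = 0.95, c1 = 1.05,
                                epsilon = 0.32, n_rep = 100, seed = 1L,
                                w = 0, max_bursts = 50 * decision_time(
                                  ir_star, epsilon)) {
  if (c0 >= c1) stop("need c0 < c1 (degenerate decision problem)")
  delta <- c1 - c0
  cmid <- (c0 + c1) / 2
  conc_star <- concentrations(c = cmid, w = w, delta_c_rel = delta / cmid)
  m_star <- build_rate_matrix(spec, params, conc_star)
  core <- .metrics_core(reduce_recurrent(m_star), delta_c_rel = delta / cmid,
                        epsilon = epsilon)
  ir_star <- core$IR_nats
  tau_b <- core$tau_b
  r0 <- spec$max_rate
  ## Gaussian LLR ingredients (absolute time units)
  occ_at <- function(cc) {
    mm <- build_rate_matrix(spec, params,
                            concentrations(c = cc, w = w,
                                           delta_c_rel = delta / cmid))
    mm <- reduce_recurrent(mm)
    pi <- .stationary(mm$Q)
    list(m = mm, mu = r0 * sum(pi[mm$on_mask]))
  }
  h0 <- occ_at(c0)
  h1 <- occ_at(c1)
  dmu <- h1$mu - h0$mu
  mubar <- (h1$mu + h0$mu) / 2
  v_abs <- core$v * tau_b * r0^2
  thresh <- log((1 - epsilon) / epsilon)
  cap_t <- max_bursts * tau_b
  set.seed(seed)
  times <- numeric(n_rep)
  decisions <- integer(n_rep)
  truth <- rep(c(0L, 1L), length.out = n_rep)
  capped <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    mm <- if (truth[r] == 0L) h0$m else h1$m
    tr <- gillespie(mm, cap_t, seed = seed + 7919L * r)
    t_grid <- c(tr$times, tr$duration)
    slope <- dmu * (r0 * as.numeric(tr$on) - mubar) / v_abs
    llr <- c(0, cumsum(slope * diff(t_grid)))
    hit_hi <- which(llr >= thresh)
    hit_lo <- which(llr <= -thresh)
    k_hi <- if (length(hit_hi)) hit_hi[1] else Inf
    k_lo <- if (length(hit_lo)) hit_lo[1] else Inf
    if (!is.finite(k_hi) && !is.finite(k_lo)) {
      capped[r] <- TRUE
      times[r] <- cap_t
      decisions[r] <- as.integer(llr[length(llr)] > 0)
      next
    }
    k <- min(k_hi, k_lo)
    lim <- if (k_hi < k_lo) thresh else -thresh
    ## crossing happened inside sojourn k-1: linear interpolation is exact
    t_cross <- t_grid[k - 1] + (lim - llr[k - 1]) / slope[k - 1]
    times[r] <- t_cross
    decisions[r] <- as.integer(lim > 0)
  }
  err <- mean(decisions != truth)
  list(mean_time = mean(times) / tau_b,
       se_time = stats::sd(times / tau_b) / sqrt(n_rep),
       error_rate = err, cap_fraction = mean(capped),
       predicted = decision_time(ir_star, epsilon),
       times = times / tau_b, decisions = decisions, truth = truth)
}

#' Write a synthetic trajectory dataset
#'
#' Generates an ensemble of Gillespie trajectories (the simulated burst
#' dynamics and accumulated-mRNA observables) and serializes them as plain
#' text: one CSV of jump records (`traj_id`, `time`, `state`, `on`) plus a
#' JSON sidecar with the generating circuit, concentrations, seeds and
#' durations. Regeneration with the same seed is bit-identical.
#'
#' @param spec A [circuit_spec()].
#' @param params A [rate_params()].
#' @param conc A [concentrations()].
#' @param durations Duration per trajectory (recycled to `n_traj`).
#' @param n_traj Number of trajectories (default 100, the ensemble size used
#'   for the accumulated-mRNA noise bands).
#' @param seed Base seed; trajectory `i` uses `seed + i`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
make_fixture <- function(spec, params, conc = concentrations(),
                         durations = 100, n_traj = 100, seed = 1L,
                         dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  durations <- rep_len(durations, n_traj)
  m <- build_rate_matrix(spec, params, conc)
  rows <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    tr <- gillespie(m, durations[i], seed = seed + i)
    rows[[i]] <- data.frame(traj_id = i, time = tr$times, state = tr$states,
                            on = as.integer(tr$on))
  }
  tab <- do.call(rbind, rows)
  csv <- file.path(dir, "trajectories.csv")
  meta <- file.path(dir, "metadata.json")
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec), params = unclass(params)[!vapply(params, is.null, TRUE)],
         conc = unclass(conc), durations = durations, n_traj = n_traj,
         seed = seed, states = "canonical (m, n_c, n_w) order"),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(trajectories = csv, metadata = meta))
}

#' Read back a synthetic trajectory dataset
#'
#' @param dir Directory written by [make_fixture()].
#' @return List with `trajectories` (list of `trajectory` objects) and
#'   `metadata`.
#' @export
read_fixture <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "trajectories.csv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  spec <- do.call(circuit_spec, meta$spec[c("n_binding_sites",
                                            "n_activation_steps",
                                            "include_noncognate",
                                            "affinity_factor", "max_rate")])
  st <- enumerate_states(spec)
  trajs <- lapply(split(tab, tab$traj_id), function(d) {
    i <- d$traj_id[1]
    structure(list(times = d$time, states = d$state,
                   on = st$on[d$state],
                   duration = meta$durations[i], seed = meta$seed + i,
                   spec = spec, params = NULL, conc = NULL),
              class = "trajectory")
  })
  list(trajectories = unname(trajs), metadata = meta)
}
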