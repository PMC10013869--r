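# Shared generators and independent oracles for the test suite.

# Log-uniform random rate parameters (uses the current RNG stream).
rand_params <- function(lo = -1.5, hi = 1.5, activator = FALSE) {
  r <- function(a = lo, b = hi) 10^runif(1, a, b)
  rate_params(k_b = r(), k_u = r(), k_a = r(), k_i = r(),
              eta_ab = if (activator) 10^runif(1, 0, hi) else r(),
              eta_ib = if (activator) 10^runif(1, lo, 0) else r(),
              eta_ua = r(), eta_ba = r(), eta_ub = r())
}

# Random equilibrium circuit from the energy/barrier construction.
rand_equilibrium <- function(spec, conc = concentrations(), spread = 3) {
  tpl <- burstinfo:::get_template(spec)
  ne <- length(unique(paste(pmin(tpl$edges$from, tpl$edges$to),
                            pmax(tpl$edges$from, tpl$edges$to))))
  equilibrium_sample(spec, runif(tpl$n, -spread, spread),
                     runif(ne, -spread, spread), conc)
}

# Brute-force cycle-affinity oracle: enumerate every simple cycle of the
# undirected support graph and take the maximum absolute log rate-product
# ratio. Independent of the spanning-tree implementation.
bruteforce_residual <- function(m) {
  Q <- m$Q
  n <- nrow(Q)
  adj <- Q > 0
  diag(adj) <- FALSE
  best <- 0
  paths <- lapply(seq_len(n), function(i) list(i))
  # depth-first enumeration of simple cycles anchored at their smallest vertex
  dfs <- function(path) {
    u <- path[length(path)]
    for (v in which(adj[u, ])) {
      if (v == path[1] && length(path) >= 3) {
        fwd <- sum(log(Q[cbind(path, c(path[-1], path[1]))]))
        rev <- sum(log(Q[cbind(c(path[-1], path[1]), path)]))
        best <<- max(best, abs(fwd - rev))
      } else if (v > path[1] && !(v %in% path)) {
        dfs(c(path, v))
      }
    }
  }
  for (i in seq_len(n)) dfs(i)
  best
}

# Central finite-difference sharpness oracle.
fd_sharpness <- function(spec, params, conc, h = 1e-6) {
  pa <- function(cc) {
    m <- build_rate_matrix(spec, params,
                           concentrations(cc, conc$w, conc$delta_c_rel))
    pi <- stationary_distribution(m)
    sum(pi[m$on_mask])
  }
  conc$c * (pa(conc$c + h) - pa(conc$c - h)) / (2 * h)
}

# Mean ON -> OFF -> ON cycle time counted directly on a trajectory.
cycle_time_oracle <- function(traj) {
  on <- traj$on
  entries <- traj$times[c(FALSE, diff(as.integer(on)) == 1L)]
  if (length(entries) < 2) return(NA_real_)
  mean(diff(entries))
}
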