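#' Configuration of a parameter sweep
#'
#' Controls the binned-archive evolutionary boundary search: log-uniform
#' random initialization, then rounds of Gaussian log10-space mutation of
#' archive members with an annealed scale and elitist replacement. All rate
#' and interaction magnitudes are drawn inside `10^log_bounds`; after each
#' evaluation the basal rates are additionally required to satisfy
#' `1e-5 <= k * tau_b <= 1e5` in burst-time units (the bound is expressed in
#' burst units, so it can only be checked once `tau_b` is known) and, when
#' `equilibrium_only = FALSE`, the activator constraint `eta_ab >= 1`,
#' `eta_ib <= 1` is enforced through the sampling box. Equilibrium sweeps draw
#' parameters directly on the detailed-balance manifold (see
#' [equilibrium_params()]), so every equilibrium circuit has zero cycle
#' affinity by construction.
#'
#' @param n_bins Number of x-axis bins for [pareto_boundary()].
#' @param n_init Random draws in the initialization round.
#' @param n_generations Refinement rounds.
#' @param n_elite Elite archive size for [maximize_metric()].
#' @param n_mutants Mutants evaluated per generation.
#' @param mutation_scale Length-2 numeric: initial and final log10-space
#'   mutation s.d. (geometric annealing).
#' @param seed RNG seed; reruns with the same seed are bit-identical.
#' @param log_bounds Length-2 numeric, log10 box for all rates and etas.
#' @param equilibrium_only Constrain sampling to detailed balance?
#' @param half_max_constraint Require `|r_bar/r0 - 0.5| <= half_max_tol`?
#' @param half_max_tol Tolerance of the half-maximum filter.
#' @param x_range Optional numeric(2) range for the boundary x-axis (otherwise
#'   taken from the initialization round).
#' @param x_log Bin the x-axis in log10 space?
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(n_bins = 50, n_init = 5000, n_generations = 200,
                         n_elite = 6, n_mutants = 24,
                         mutation_scale = c(0.6, 0.04), seed = 1,
                         log_bounds = c(-5, 5), equilibrium_only = FALSE,
                         half_max_constraint = FALSE, half_max_tol = 0.01,
                         x_range = NULL, x_log = TRUE) {
  stopifnot(n_bins >= 1, n_init >= 1, n_generations >= 0, n_elite >= 1,
            n_mutants >= 1, length(mutation_scale) == 2,
            all(mutation_scale > 0), length(log_bounds) == 2,
            log_bounds[1] < log_bounds[2], log_bounds[1] >= -5,
            log_bounds[2] <= 5)
  structure(list(n_bins = n_bins, n_init = n_init,
                 n_generations = n_generations, n_elite = n_elite,
                 n_mutants = n_mutants, mutation_scale = mutation_scale,
                 seed = seed, log_bounds = log_bounds,
                 equilibrium_only = equilibrium_only,
                 half_max_constraint = half_max_constraint,
                 half_max_tol = half_max_tol, x_range = x_range,
                 x_log = x_log),
            class = "sweep_config")
}

## ---- parameter-vector machinery -------------------------------------------

## Free log10 coordinates of one sweep mode. Equilibrium modes omit the
## coordinates fixed by the Kolmogorov criterion; eta_ba is derived.
sweep_coords <- function(spec, config) {
  lb <- config$log_bounds
  base <- list(k_b = lb, k_u = lb, k_a = lb, k_i = lb)
  etas <- if (config$equilibrium_only) {
    list(eta_ab = c(0, lb[2]), eta_ib = c(lb[1], 0), eta_ua = lb)
  } else {
    list(eta_ab = c(0, lb[2]), eta_ib = c(lb[1], 0), eta_ua = lb, eta_ba = lb)
  }
  co <- c(base, etas)
  if (spec$n_binding_sites > 1L) co$eta_ub <- lb
  lo <- vapply(co, `[`, 0, 1)
  hi <- vapply(co, `[`, 0, 2)
  list(names = names(co), lo = lo, hi = hi, d = length(co))
}

theta_to_params <- function(theta, coords, spec, config) {
  v <- as.list(10^theta)
  names(v) <- coords$names
  p <- rate_params(k_b = v$k_b, k_u = v$k_u, k_a = v$k_a, k_i = v$k_i,
                   eta_ab = if (is.null(v$eta_ab)) 1 else v$eta_ab,
                   eta_ib = if (is.null(v$eta_ib)) 1 else v$eta_ib,
                   eta_ua = v$eta_ua,
                   eta_ba = if (is.null(v$eta_ba)) 1 else v$eta_ba,
                   eta_ub = if (is.null(v$eta_ub)) 1 else v$eta_ub)
  if (config$equilibrium_only) p <- equilibrium_params(spec, p)
  p
}

reflect_box <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  lo + pmin(y, 2 * r - y)
}

## Evaluate one parameter vector; returns NULL when any constraint fails.
eval_theta <- function(theta, tpl, coords, spec, config, conc, want_S0 = FALSE,
                       augment = NULL) {
  p <- theta_to_params(theta, coords, spec, config)
  lim <- 10^config$log_bounds
  if (p$eta_ba < lim[1] || p$eta_ba > lim[2]) return(NULL)
  m <- fill_template(tpl, p, conc)
  met <- tryCatch(.metrics_core(m, delta_c_rel = conc$delta_c_rel),
                  error = function(e) NULL)
  if (is.null(met)) return(NULL)
  if (!all(is.finite(c(met$pi_a, met$tau_b, met$s, met$v))) || met$v <= 0)
    return(NULL)
  kt <- c(p$k_b * conc$c, p$k_u, p$k_a, p$k_i) * met$tau_b
  if (any(kt < 1e-5) || any(kt > 1e5)) return(NULL)
  if (config$half_max_constraint &&
      abs(met$pi_a - 0.5) > config$half_max_tol) return(NULL)
  met$pi <- NULL
  if (isTRUE(spec$include_noncognate) && conc$w > 0) {
    pi <- .stationary(m$Q)
    met$f <- (conc$w / conc$c) * sum(m$states$n_c * pi) / sum(m$states$n_w * pi)
  }
  if (want_S0) {
    spec0 <- circuit_spec(spec$n_binding_sites, spec$n_activation_steps,
                          FALSE, spec$affinity_factor, spec$max_rate)
    m0 <- fill_template(get_template(spec0), p,
                        concentrations(conc$c, 0, conc$delta_c_rel))
    met$S0 <- tryCatch(.metrics_core(m0)$S, error = function(e) NA_real_)
  }
  if (!is.null(augment)) {
    extra <- tryCatch(augment(p, met), error = function(e) NULL)
    if (is.null(extra) || any(!is.finite(unlist(extra)))) return(NULL)
    met <- c(met, as.list(extra))
  }
  list(theta = theta, params = p, metrics = met)
}

metric_value <- function(res, name) {
  v <- res$metrics[[name]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}

#' Maximize a response metric over circuit realizations
#'
#' Scalar specialization of the boundary sweep: log-uniform random
#' initialization followed by elitist mutate-evaluate-replace refinement with
#' an annealed log10-space mutation scale. Deterministic given
#' `config$seed`. Metrics available by name: `IR_bits`, `IR_nats`, `S`, `P`,
#' `s`, `p`, `pi_a`, `phi_per_burst`, `T_bar`, `f` (noncognate circuits), and
#' `S0` (set `want_S0 = TRUE`), plus any names produced by `augment`.
#'
#' @param spec A [circuit_spec()].
#' @param metric Metric name to maximize (see Details) or minimize.
#' @param config A [sweep_config()].
#' @param conc A [concentrations()].
#' @param maximize If `FALSE`, minimize the metric instead.
#' @param want_S0 Also compute intrinsic sharpness per candidate.
#' @param augment Optional `function(params, metrics)` returning extra named
#'   metric values (used e.g. for perturbation fold changes).
#' @return An object of class `sweep_result`: list with `value`, `metric`,
#'   `params` (the attaining [rate_params()]), `metrics` (all metrics of the
#'   best circuit), `history` (best value per generation, monotone),
#'   `n_eval`, `config`, `spec`, `conc`. If no feasible circuit is found,
#'   `value` is `NA` and `feasible` is `FALSE`.
#' @export
maximize_metric <- function(spec, metric = "IR_bits", config = sweep_config(),
                            conc = concentrations(), maximize = TRUE,
                            want_S0 = FALSE, augment = NULL) {
  set.seed(config$seed)
  tpl <- get_template(spec)
  coords <- sweep_coords(spec, config)
  sgn <- if (maximize) 1 else -1
  n_eval <- 0L
  score <- function(res) {
    if (is.null(res)) return(-Inf)
    v <- metric_value(res, metric)
    if (!is.finite(v)) -Inf else sgn * v
  }
  evaluate <- function(theta) {
    n_eval <<- n_eval + 1L
    eval_theta(theta, tpl, coords, spec, config, conc, want_S0, augment)
  }
  ## initialization
  pool <- vector("list", config$n_init)
  sc <- numeric(config$n_init)
  for (i in seq_len(config$n_init)) {
    th <- stats::runif(coords$d, coords$lo, coords$hi)
    pool[i] <- list(evaluate(th))
    sc[i] <- score(pool[[i]])
  }
  keep <- order(sc, decreasing = TRUE)[seq_len(min(config$n_elite, config$n_init))]
  elite <- pool[keep]
  esc <- sc[keep]
  ok <- is.finite(esc)
  elite <- elite[ok]
  esc <- esc[ok]
  history <- numeric(config$n_generations)
  if (length(elite)) {
    G <- max(config$n_generations, 1)
    s0 <- config$mutation_scale[1]
    s1 <- config$mutation_scale[2]
    per <- max(1L, ceiling(config$n_mutants / length(elite)))
    for (g in seq_len(config$n_generations)) {
      sig <- s0 * (s1 / s0)^((g - 1) / max(G - 1, 1))
      for (e in seq_along(elite)) {
        for (k in seq_len(per)) {
          th <- reflect_box(elite[[e]]$theta + stats::rnorm(coords$d, 0, sig),
                            coords$lo, coords$hi)
          cand <- evaluate(th)
          csc <- score(cand)
          if (is.finite(csc) && csc > min(esc)) {
            j <- which.min(esc)
            elite[[j]] <- cand
            esc[j] <- csc
          }
        }
      }
      history[g] <- sgn * max(esc)
    }
  }
  if (!length(elite)) {
    return(structure(list(value = NA_real_, metric = metric, feasible = FALSE,
                          params = NULL, metrics = NULL, history = history,
                          n_eval = n_eval, config = config, spec = spec,
                          conc = conc),
                     class = "sweep_result"))
  }
  best <- elite[[which.max(esc)]]
  structure(list(value = metric_value(best, metric), metric = metric,
                 feasible = TRUE, params = best$params,
                 metrics = best$metrics, theta = best$theta,
                 history = history, n_eval = n_eval, config = config,
                 spec = spec, conc = conc),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s = %.6g (%d evaluations%s)\n", x$metric,
              x$value, x$n_eval,
              if (isTRUE(x$feasible)) "" else "; NO feasible circuit"))
  invisible(x)
}

#' Trace the achievable-region boundary for a metric pair
#'
#' Maps the boundary of the region of `(x_metric, y_metric)` values reachable
#' by circuit realizations: random log-uniform initialization populates a
#' binned archive along the x-axis, then each refinement round mutates archive
#' members (annealed Gaussian log10-space proposals) and replaces a bin's
#' representative whenever the mutant improves the bin's extreme y value.
#' Per-bin maxima are monotone over generations and the whole procedure is
#' deterministic given `config$seed`.
#'
#' @inheritParams maximize_metric
#' @param x_metric,y_metric Metric names (see [maximize_metric()]).
#' @param track_min Also archive per-bin y minima?
#' @return An object of class `pareto_boundary`: list with `boundary` (data
#'   frame `x_lo`, `x_hi`, `x_center`, `x`, `y_max`, optionally `y_min`),
#'   `archive` (attaining [rate_params()] per bin), `n_eval`, `config`.
#'   Flagged via `feasible = FALSE` (empty boundary) when no draw satisfies
#'   the constraints.
#' @export
pareto_boundary <- function(spec, x_metric, y_metric, config = sweep_config(),
                            conc = concentrations(), track_min = FALSE,
                            want_S0 = FALSE, augment = NULL) {
  set.seed(config$seed)
  tpl <- get_template(spec)
  coords <- sweep_coords(spec, config)
  n_eval <- 0L
  evaluate <- function(theta) {
    n_eval <<- n_eval + 1L
    eval_theta(theta, tpl, coords, spec, config, conc, want_S0, augment)
  }
  init <- vector("list", config$n_init)
  for (i in seq_len(config$n_init)) {
    init[i] <- list(evaluate(stats::runif(coords$d, coords$lo, coords$hi)))
  }
  valid <- !vapply(init, is.null, TRUE)
  init <- init[valid]
  getxy <- function(res) c(metric_value(res, x_metric),
                           metric_value(res, y_metric))
  if (!length(init)) {
    return(structure(list(boundary = NULL, archive = NULL, feasible = FALSE,
                          n_eval = n_eval, config = config),
                     class = "pareto_boundary"))
  }
  xv <- vapply(init, function(r) getxy(r)[1], 0)
  xr <- config$x_range
  if (is.null(xr)) xr <- range(xv[is.finite(xv) & (xv > 0 | !config$x_log)])
  tx <- if (config$x_log) function(x) log10(pmax(x, 1e-300)) else identity
  edges <- seq(tx(xr[1]), tx(xr[2]), length.out = config$n_bins + 1)
  binof <- function(x) {
    b <- findInterval(tx(x), edges, rightmost.closed = TRUE)
    b[b < 1 | b > config$n_bins] <- NA_integer_
    b
  }
  arc_max <- vector("list", config$n_bins)
  ymax <- rep(-Inf, config$n_bins)
  arc_min <- vector("list", config$n_bins)
  ymin <- rep(Inf, config$n_bins)
  place <- function(res) {
    xy <- getxy(res)
    if (!all(is.finite(xy))) return(invisible())
    b <- binof(xy[1])
    if (is.na(b)) return(invisible())
    if (xy[2] > ymax[b]) { ymax[b] <<- xy[2]; arc_max[[b]] <<- res }
    if (track_min && xy[2] < ymin[b]) { ymin[b] <<- xy[2]; arc_min[[b]] <<- res }
    invisible()
  }
  for (r in init) place(r)
  G <- config$n_generations
  s0 <- config$mutation_scale[1]
  s1 <- config$mutation_scale[2]
  for (g in seq_len(G)) {
    sig <- s0 * (s1 / s0)^((g - 1) / max(G - 1, 1))
    occ <- which(!vapply(arc_max, is.null, TRUE))
    if (track_min) occ <- union(occ, which(!vapply(arc_min, is.null, TRUE)))
    if (!length(occ)) break
    for (k in seq_len(config$n_mutants)) {
      b <- occ[1 + (stats::runif(1) * length(occ)) %/% 1]
      src <- arc_max[[b]]
      if (is.null(src) || (track_min && !is.null(arc_min[[b]]) &&
                           stats::runif(1) < 0.5)) src <- arc_min[[b]]
      th <- reflect_box(src$theta + stats::rnorm(coords$d, 0, sig),
                        coords$lo, coords$hi)
      cand <- evaluate(th)
      if (!is.null(cand)) place(cand)
    }
  }
  occ <- !vapply(arc_max, is.null, TRUE)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  if (config$x_log) ctr <- 10^ctr
  bx <- if (config$x_log) 10^edges else edges
  bd <- data.frame(x_lo = bx[-length(bx)][occ], x_hi = bx[-1][occ],
                   x_center = ctr[occ],
                   x = vapply(arc_max[occ], function(r) getxy(r)[1], 0),
                   y_max = ymax[occ])
  if (track_min) {
    bd$y_min <- ifelse(is.finite(ymin[occ]), ymin[occ], NA_real_)
  }
  structure(list(boundary = bd, archive = lapply(arc_max[occ], `[[`, "params"),
                 archive_min = if (track_min) lapply(arc_min[occ], function(r)
                   if (is.null(r)) NULL else r$params),
                 x_metric = x_metric, y_metric = y_metric, feasible = TRUE,
                 n_eval = n_eval, config = config),
            class = "pareto_boundary")
}

#' @export
print.pareto_boundary <- function(x, ...) {
  if (!isTRUE(x$feasible)) {
    cat("<pareto_boundary> infeasible: no circuit satisfied the constraints\n")
    return(invisible(x))
  }
  cat(sprintf("<pareto_boundary> %s vs %s, %d occupied bins, %d evaluations\n",
              x$y_metric, x$x_metric, nrow(x$boundary), x$n_eval))
  invisible(x)
}

#' Maximum information rate versus noncognate concentration
#'
#' Runs paired equilibrium and nonequilibrium information-rate maximizations
#' at each relative noncognate concentration in `wc_grid`, holding the cognate
#' concentration at `c*`, and converts the optima to decision times. Each grid
#' point uses a sub-seed derived deterministically from `config$seed`.
#'
#' @param spec A [circuit_spec()] with `include_noncognate = TRUE`.
#' @param wc_grid Numeric vector of `w/c` values.
#' @param config A [sweep_config()] (its `equilibrium_only` flag is
#'   overridden per branch).
#' @param epsilon Error tolerance for the reported decision times.
#' @return A data frame with one row per (`w/c`, regime): columns `w_over_c`,
#'   `regime` (`"equilibrium"`/`"nonequilibrium"`), `IR_bits`, `T_bar`, `S`,
#'   `P`, `f`, `phi_per_burst`; the attaining parameter sets are attached as
#'   attribute `"params"`.
#' @export
scan_vs_wc <- function(spec, wc_grid, config = sweep_config(),
                       epsilon = 0.32) {
  stopifnot(isTRUE(spec$include_noncognate))
  rows <- list()
  params <- list()
  for (i in seq_along(wc_grid)) {
    conc <- concentrations(c = 1, w = wc_grid[i])
    for (regime in c("equilibrium", "nonequilibrium")) {
      cfg <- config
      cfg$equilibrium_only <- regime == "equilibrium"
      cfg$seed <- (config$seed + 997L * i +
                     as.integer(regime == "nonequilibrium")) %% .Machine$integer.max
      res <- maximize_metric(spec, "IR_nats", cfg, conc)
      rows[[length(rows) + 1L]] <- data.frame(
        w_over_c = wc_grid[i], regime = regime,
        IR_bits = if (isTRUE(res$feasible)) res$metrics$IR_bits else NA_real_,
        T_bar = if (isTRUE(res$feasible))
          decision_time(res$value, epsilon) else NA_real_,
        S = if (isTRUE(res$feasible)) res$metrics$S else NA_real_,
        P = if (isTRUE(res$feasible)) res$metrics$P else NA_real_,
        f = if (isTRUE(res$feasible) && !is.null(res$metrics$f))
          res$metrics$f else NA_real_,
        phi_per_burst = if (isTRUE(res$feasible))
          res$metrics$phi_per_burst else NA_real_)
      params[[length(params) + 1L]] <- res$params
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}
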