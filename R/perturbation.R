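#' Binding-site mutation response
#'
#' Models a point mutation of the activator binding site that weakens cognate
#' specificity: the cognate unbinding rate becomes `beta * k_u` (`beta >= 1`)
#' while noncognate unbinding keeps its wild-type value `alpha * k_u`. At
#' `beta = alpha` the site has fully lost cognate specificity. Reports the
#' experimental signatures: fold changes in the mean mRNA production rate and
#' in the normalized sharpness, plus the mutation-strength-normalized
#' sharpness fold `(S_mut/S) * beta` that puts different `beta` on a common
#' axis.
#'
#' @param spec A [circuit_spec()].
#' @param params Wild-type [rate_params()].
#' @param conc A [concentrations()].
#' @param beta Mutation strength `k_u_mut / k_u`, `>= 1`.
#' @return An object of class `perturbation_result`: one-row data frame with
#'   `beta`, `r_bar_wt`, `r_bar_mut`, `rate_fold`, `S_wt`, `S_mut`,
#'   `sharp_fold`, `sharp_fold_norm`, `w_over_c`, `equilibrium`.
#' @export
perturbation_response <- function(spec, params, conc = concentrations(),
                                  beta) {
  if (beta < 1) stop("beta < 1: only specificity-reducing mutations modeled")
  m_wt <- build_rate_matrix(spec, params, conc)
  core_wt <- .metrics_core(reduce_recurrent(m_wt),
                           delta_c_rel = conc$delta_c_rel)
  p_mut <- params
  p_mut$k_u_mut <- beta * params$k_u
  m_mut <- build_rate_matrix(spec, p_mut, conc)
  core_mut <- .metrics_core(reduce_recurrent(m_mut),
                            delta_c_rel = conc$delta_c_rel)
  eq <- detailed_balance_residual(m_wt) < 1e-8
  out <- data.frame(beta = beta,
                    r_bar_wt = spec$max_rate * core_wt$pi_a,
                    r_bar_mut = spec$max_rate * core_mut$pi_a,
                    rate_fold = core_mut$pi_a / core_wt$pi_a,
                    S_wt = core_wt$S, S_mut = core_mut$S,
                    sharp_fold = core_mut$S / core_wt$S,
                    sharp_fold_norm = core_mut$S / core_wt$S * beta,
                    w_over_c = conc$w / conc$c,
                    equilibrium = eq)
  class(out) <- c("perturbation_result", class(out))
  out
}

#' Equilibrium perturbation-response region and nonequilibrium signatures
#'
#' Traces the region of (rate fold change, normalized sharpness fold change)
#' reachable by equilibrium circuits whose wild type expresses at
#' half-maximum, and overlays the responses of information-rate-optimal
#' nonequilibrium circuits at the same mutation strength across a grid of
#' noncognate concentrations. Nonequilibrium optima falling outside the
#' equilibrium region are an experimentally accessible signature of energy
#' dissipation that does not require knowing `w/c`.
#'
#' @param spec A [circuit_spec()] (with the noncognate competitor for the
#'   `w/c` grid to matter).
#' @param beta Mutation strength, `>= 1`.
#' @param wc_grid Noncognate concentration ratios at which the nonequilibrium
#'   IR optima are computed.
#' @param config A [sweep_config()]; `equilibrium_only` and
#'   `half_max_constraint` are forced as required per branch.
#' @return List with `equilibrium_region` (a [pareto_boundary()] over
#'   `x = rate_fold`, `y = sharp_fold_norm`, tracking both the per-bin maxima
#'   and minima) and `nonequilibrium_points` (data frame of perturbation
#'   responses of the IR optima, one row per `w/c`).
#' @export
equilibrium_response_region <- function(spec, beta, wc_grid = c(1, 100, 1000),
                                        config = sweep_config()) {
  eq_cfg <- config
  eq_cfg$equilibrium_only <- TRUE
  eq_cfg$half_max_constraint <- TRUE
  eq_cfg$x_log <- FALSE
  if (is.null(eq_cfg$x_range)) eq_cfg$x_range <- c(0, 1.05)
  ## equilibrium region pooled over the w/c grid
  regions <- list()
  for (i in seq_along(wc_grid)) {
    cfg <- eq_cfg
    cfg$seed <- (eq_cfg$seed + 131L * i) %% .Machine$integer.max
    conc <- concentrations(c = 1, w = wc_grid[i])
    aug_i <- function(params, metrics) {
      p_mut <- params
      p_mut$k_u_mut <- beta * params$k_u
      unlist(perturbation_fold(spec, params, p_mut, conc))
    }
    regions[[i]] <- pareto_boundary(spec, "rate_fold", "sharp_fold_norm",
                                    cfg, conc, track_min = TRUE,
                                    augment = aug_i)
  }
  ## nonequilibrium IR optima and their responses
  ne_rows <- list()
  for (i in seq_along(wc_grid)) {
    cfg <- config
    cfg$equilibrium_only <- FALSE
    cfg$half_max_constraint <- TRUE
    cfg$seed <- (config$seed + 877L * i) %% .Machine$integer.max
    conc <- concentrations(c = 1, w = wc_grid[i])
    res <- maximize_metric(spec, "IR_nats", cfg, conc)
    if (!isTRUE(res$feasible)) next
    pr <- perturbation_response(spec, res$params, conc, beta)
    pr$IR_bits <- res$metrics$IR_bits
    ne_rows[[length(ne_rows) + 1L]] <- pr
  }
  list(equilibrium_region = regions,
       nonequilibrium_points = if (length(ne_rows)) do.call(rbind, ne_rows))
}

## Fold changes of one mutation without re-deriving wild-type metrics from
## scratch (used inside sweep augment hooks).
perturbation_fold <- function(spec, params, p_mut, conc) {
  m_wt <- fill_template(get_template(spec), params, conc)
  m_mut <- fill_template(get_template(spec), p_mut, conc)
  c_wt <- .metrics_core(reduce_recurrent(m_wt), delta_c_rel = conc$delta_c_rel)
  c_mut <- .metrics_core(reduce_recurrent(m_mut), delta_c_rel = conc$delta_c_rel)
  beta <- p_mut$k_u_mut / params$k_u
  list(rate_fold = c_mut$pi_a / c_wt$pi_a,
       sharp_fold = c_mut$S / c_wt$S,
       sharp_fold_norm = c_mut$S / c_wt$S * beta)
}
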