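#' Specify a gene-circuit topology
#'
#' A circuit is defined by the number of identical activator binding sites
#' (`n_binding_sites`), the number of molecular activation steps that must all
#' be engaged before the locus transcribes (`n_activation_steps`), and whether
#' an aggregate noncognate activator species competes for the binding sites.
#' The noncognate species is kinetically identical to the cognate activator
#' except that it unbinds `affinity_factor` times faster.
#'
#' @param n_binding_sites Integer `N_B >= 1`, number of activator binding sites.
#' @param n_activation_steps Integer `N_A >= 1`, number of molecular activation
#'   steps; the locus is ON (transcribing at `max_rate`) only when all are
#'   engaged.
#' @param include_noncognate Logical; include the competing noncognate species?
#' @param affinity_factor Dimensionless `alpha > 1`, ratio of noncognate to
#'   cognate unbinding rates. Default 100, the kinetic difference implied by
#'   short eukaryotic transcription-factor footprints (~4.6 kT).
#' @param max_rate mRNA production rate `r0` while ON (mRNA per unit time).
#' @return An object of class `circuit_spec`.
#' @examples
#' circuit_spec()                       # the minimal four-state circuit
#' circuit_spec(include_noncognate = TRUE)  # its six-state extension
#' @export
circuit_spec <- function(n_binding_sites = 1L, n_activation_steps = 1L,
                         include_noncognate = FALSE, affinity_factor = 100,
                         max_rate = 1) {
  stopifnot(length(n_binding_sites) == 1L, n_binding_sites >= 1,
            n_binding_sites == as.integer(n_binding_sites),
            length(n_activation_steps) == 1L, n_activation_steps >= 1,
            n_activation_steps == as.integer(n_activation_steps),
            is.logical(include_noncognate), length(include_noncognate) == 1L,
            affinity_factor >= 1, max_rate > 0)
  structure(list(n_binding_sites = as.integer(n_binding_sites),
                 n_activation_steps = as.integer(n_activation_steps),
                 include_noncognate = include_noncognate,
                 affinity_factor = affinity_factor,
                 max_rate = max_rate),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  n <- nrow(enumerate_states(x))
  cat(sprintf("<circuit_spec> N_B = %d, N_A = %d, %s, %d states\n",
              x$n_binding_sites, x$n_activation_steps,
              if (x$include_noncognate)
                sprintf("noncognate competitor (alpha = %g)", x$affinity_factor)
              else "cognate only", n))
  invisible(x)
}

#' Basal rates and interaction factors of one circuit realization
#'
#' The four basal rates are the activator binding rate per unit concentration
#' (`k_b`), the cognate unbinding rate (`k_u`), and the activation-step forward
#' and backward rates (`k_a`, `k_i`). The dimensionless `eta` factors encode
#' how one molecular component modifies another component's transitions: first
#' subscript = the reaction being modified (a = activation, i = inactivation,
#' u = unbinding, b = binding), second subscript = the modifier (b = bound
#' activator, a = active conformation). `eta_ub` is the pairwise
#' activator-activator cooperativity acting on unbinding (relevant when
#' `N_B > 1`). A circuit is at thermodynamic equilibrium iff every cycle's
#' forward and reverse rate products agree; for the four-state circuit this is
#' `eta_ab * eta_ua == eta_ib * eta_ba`.
#'
#' @param k_b,k_u,k_a,k_i Positive basal rates.
#' @param eta_ab,eta_ib,eta_ua,eta_ba,eta_ub Positive interaction factors.
#' @param k_u_mut Optional mutant cognate unbinding rate, used by the
#'   binding-site perturbation analysis. When set, cognate unbinding uses
#'   `k_u_mut` while noncognate unbinding keeps `alpha * k_u`.
#' @param check_activator If `TRUE`, require `eta_ab >= 1` and `eta_ib <= 1`
#'   (the transcription factor acts as an activator).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(k_b = 1, k_u = 1, k_a = 1, k_i = 1,
                        eta_ab = 1, eta_ib = 1, eta_ua = 1, eta_ba = 1,
                        eta_ub = 1, k_u_mut = NULL, check_activator = FALSE) {
  vals <- c(k_b = k_b, k_u = k_u, k_a = k_a, k_i = k_i, eta_ab = eta_ab,
            eta_ib = eta_ib, eta_ua = eta_ua, eta_ba = eta_ba, eta_ub = eta_ub)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rates and eta factors must be finite and > 0")
  if (!is.null(k_u_mut) && (!is.finite(k_u_mut) || k_u_mut <= 0))
    stop("k_u_mut must be finite and > 0")
  if (check_activator && (eta_ab < 1 || eta_ib > 1))
    stop("activator constraint violated: need eta_ab >= 1 and eta_ib <= 1")
  structure(list(k_b = k_b, k_u = k_u, k_a = k_a, k_i = k_i,
                 eta_ab = eta_ab, eta_ib = eta_ib, eta_ua = eta_ua,
                 eta_ba = eta_ba, eta_ub = eta_ub, k_u_mut = k_u_mut),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  cat(sprintf("  k_b = %.4g  k_u = %.4g  k_a = %.4g  k_i = %.4g\n",
              x$k_b, x$k_u, x$k_a, x$k_i))
  cat(sprintf("  eta_ab = %.4g  eta_ib = %.4g  eta_ua = %.4g  eta_ba = %.4g  eta_ub = %.4g\n",
              x$eta_ab, x$eta_ib, x$eta_ua, x$eta_ba, x$eta_ub))
  if (!is.null(x$k_u_mut)) cat(sprintf("  k_u_mut = %.4g\n", x$k_u_mut))
  invisible(x)
}

#' Activator concentrations
#'
#' All concentrations are in units of the midpoint concentration `c*`, so the
#' operating point of every analysis is `c = 1`. `w` is the aggregate
#' concentration of all noncognate activator species and is ignored unless the
#' circuit includes the noncognate competitor. `delta_c_rel` is the relative
#' difference `(c1 - c0)/c*` between the two hypothesis concentrations that the
#' cell must distinguish.
#'
#' @param c Cognate concentration (c* units), `> 0`.
#' @param w Aggregate noncognate concentration (c* units), `>= 0`.
#' @param delta_c_rel Relative concentration difference, default 0.1.
#' @return An object of class `concentrations`.
#' @export
concentrations <- function(c = 1, w = 0, delta_c_rel = 0.1) {
  stopifnot(is.finite(c), c > 0, is.finite(w), w >= 0,
            is.finite(delta_c_rel), delta_c_rel > 0)
  structure(list(c = c, w = w, delta_c_rel = delta_c_rel),
            class = "concentrations")
}

#' Enumerate the molecular states of a circuit
#'
#' States are labelled `(n_c, n_w, m)`: the numbers of cognate- and
#' noncognate-bound sites (`n_c + n_w <= N_B`) and the number of engaged
#' activation steps (`0 <= m <= N_A`). The canonical ordering is lexicographic
#' in `(m, n_c, n_w)` and is fixed so that serialized results are reproducible.
#' Without the noncognate species there are `(N_B+1)(N_A+1)` states; with it,
#' `(N_B+1)(N_B+2)/2 * (N_A+1)`.
#'
#' @param spec A [circuit_spec()].
#' @return A data frame with columns `n_c`, `n_w`, `m`, `on` (is the state
#'   transcriptionally active, i.e. `m == N_A`), and a character `label`.
#' @export
enumerate_states <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  NB <- spec$n_binding_sites
  NAct <- spec$n_activation_steps
  occ <- if (spec$include_noncognate) {
    g <- expand.grid(n_w = 0:NB, n_c = 0:NB)
    g <- g[g$n_c + g$n_w <= NB, c("n_c", "n_w")]
    g[order(g$n_c, g$n_w), , drop = FALSE]
  } else {
    data.frame(n_c = 0:NB, n_w = 0L)
  }
  st <- do.call(rbind, lapply(0:NAct, function(m) cbind(occ, m = m)))
  st <- st[order(st$m, st$n_c, st$n_w), , drop = FALSE]
  rownames(st) <- NULL
  st$on <- st$m == NAct
  st$label <- sprintf("c%dw%dm%d", st$n_c, st$n_w, st$m)
  st
}

## Internal edge-table "template" for a topology: every possible transition with
## its basal-rate type, combinatorial multiplicity, eta exponents and
## concentration dependence. Rates for any (params, conc) are then a vectorized
## fill; this is the hot path of the sweep engine.
circuit_template <- function(spec) {
  st <- enumerate_states(spec)
  n <- nrow(st)
  NB <- spec$n_binding_sites
  NAct <- spec$n_activation_steps
  key <- st$label
  idx <- function(nc, nw, m) match(sprintf("c%dw%dm%d", nc, nw, m), key)
  rows <- vector("list", 6L * n)
  k <- 0L
  for (i in seq_len(n)) {
    nc <- st$n_c[i]; nw <- st$n_w[i]; m <- st$m[i]
    ntot <- nc + nw
    free <- NB - ntot
    add <- function(to, type, mult, e_ab = 0, e_ib = 0, e_ua = 0, e_ba = 0,
                    e_ub = 0, cexp = 0, wexp = 0, kind) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(from = i, to = to, type = type, mult = mult,
                               e_ab = e_ab, e_ib = e_ib, e_ua = e_ua,
                               e_ba = e_ba, e_ub = e_ub, cexp = cexp,
                               wexp = wexp, kind = kind,
                               stringsAsFactors = FALSE)
    }
    if (free > 0)
      add(idx(nc + 1, nw, m), "k_b", free, e_ba = m, cexp = 1, kind = "bind_c")
    if (nc > 0)
      add(idx(nc - 1, nw, m), "k_u", nc, e_ua = m, e_ub = ntot - 1,
          kind = "unbind_c")
    if (spec$include_noncognate && free > 0)
      add(idx(nc, nw + 1, m), "k_b", free, e_ba = m, wexp = 1, kind = "bind_w")
    if (spec$include_noncognate && nw > 0)
      add(idx(nc, nw - 1, m), "k_u_w", nw, e_ua = m, e_ub = ntot - 1,
          kind = "unbind_w")
    if (m < NAct)
      add(idx(nc, nw, m + 1), "k_a", NAct - m, e_ab = ntot, kind = "activate")
    if (m > 0)
      add(idx(nc, nw, m - 1), "k_i", m, e_ib = ntot, kind = "deactivate")
  }
  edges <- do.call(rbind, rows[seq_len(k)])
  list(spec = spec, states = st, n = n, edges = edges,
       eta_mat = as.matrix(edges[, c("e_ab", "e_ib", "e_ua", "e_ba", "e_ub")]),
       type_id = match(edges$type, c("k_b", "k_u", "k_a", "k_i", "k_u_w")))
}

## Vectorized fill of edge rates and assembly of the generator.
fill_template <- function(tpl, params, conc) {
  ku_c <- if (is.null(params$k_u_mut)) params$k_u else params$k_u_mut
  logk <- c(log(params$k_b), log(ku_c), log(params$k_a), log(params$k_i),
            log(tpl$spec$affinity_factor * params$k_u))
  logeta <- log(c(params$eta_ab, params$eta_ib, params$eta_ua,
                  params$eta_ba, params$eta_ub))
  e <- tpl$edges
  lr <- log(e$mult) + logk[tpl$type_id] + drop(tpl$eta_mat %*% logeta) +
    e$cexp * log(conc$c)
  rate <- exp(lr)
  if (any(e$wexp > 0)) {
    wfac <- ifelse(e$wexp > 0, conc$w^e$wexp, 1)
    rate <- rate * wfac
  }
  Q <- matrix(0, tpl$n, tpl$n)
  Q[cbind(e$from, e$to)] <- rate
  diag(Q) <- -rowSums(Q)
  structure(list(states = tpl$states, Q = Q, on_mask = tpl$states$on,
                 edges = cbind(e, rate = rate), spec = tpl$spec, conc = conc,
                 params = params),
            class = "rate_matrix")
}

## Per-spec template cache (topology depends only on the spec).
.template_cache <- new.env(parent = emptyenv())
get_template <- function(spec) {
  keyname <- sprintf("NB%d_NA%d_%d", spec$n_binding_sites,
                     spec$n_activation_steps, as.integer(spec$include_noncognate))
  tpl <- .template_cache[[keyname]]
  if (is.null(tpl)) {
    tpl <- circuit_template(spec)
    .template_cache[[keyname]] <- tpl
  }
  ## affinity_factor / max_rate live in spec but not in the topology
  tpl$spec <- spec
  tpl
}

#' Assemble the CTMC generator of a circuit
#'
#' Builds the labeled transition-rate matrix at the given concentrations. Rate
#' laws follow exponent counting: each molecule of one component present
#' multiplies the other component's transitions by one factor of the
#' corresponding interaction term. For state `(n_c, n_w, m)` with
#' `n = n_c + n_w` bound sites: cognate binding `(N_B - n) k_b c eta_ba^m`;
#' cognate unbinding `n_c k_u eta_ua^m eta_ub^(n-1)`; noncognate
#' binding/unbinding identical with `w` and `alpha k_u`; activation
#' `m -> m+1` at `(N_A - m) k_a eta_ab^n`; deactivation `m -> m-1` at
#' `m k_i eta_ib^n`. For `N_B = N_A = 1` this reduces to the canonical
#' four-state (or, with the noncognate competitor, six-state) circuit with its
#' eight (twelve) rates.
#'
#' @param spec A [circuit_spec()].
#' @param params A [rate_params()].
#' @param conc A [concentrations()].
#' @return An object of class `rate_matrix`: a list with `states` (the state
#'   table from [enumerate_states()]), `Q` (the generator; off-diagonals are
#'   transition rates, rows sum to zero), `on_mask`, and `edges` (per-edge
#'   provenance: basal rate type, multiplicity, eta exponents, concentration
#'   dependence and the numeric rate).
#' @examples
#' m <- build_rate_matrix(circuit_spec(), rate_params(eta_ab = 2), concentrations())
#' m$edges[, c("from", "to", "kind", "rate")]
#' @export
build_rate_matrix <- function(spec, params, conc = concentrations()) {
  stopifnot(inherits(spec, "circuit_spec"), inherits(params, "rate_params"),
            inherits(conc, "concentrations"))
  m <- fill_template(get_template(spec), params, conc)
  if (any(!is.finite(m$edges$rate)) || any(m$edges$rate < 0))
    stop("nonpositive or nonfinite transition rate; check parameters")
  m
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d states, %d directed edges, %d ON state(s)\n",
              nrow(x$Q), sum(x$edges$rate > 0), sum(x$on_mask)))
  invisible(x)
}

#' Hand-coded four-state generator
#'
#' Explicit construction of the minimal circuit (one binding site, one
#' activation step) with its eight rates, used as an independent cross-check of
#' the general builder. States in canonical order: 1 = unbound/OFF,
#' 2 = bound/OFF, 3 = unbound/ON, 4 = bound/ON. The cycle
#' unbound/OFF -> bound/OFF -> bound/ON -> unbound/ON -> unbound/OFF carries
#' rates `k_b c`, `k_a eta_ab`, `k_u eta_ua`, `k_i` forward and `k_u`,
#' `k_i eta_ib`, `k_b c eta_ba`, `k_a` backward.
#'
#' @inheritParams build_rate_matrix
#' @return A `rate_matrix`.
#' @export
four_state_matrix <- function(params, conc = concentrations()) {
  stopifnot(inherits(params, "rate_params"), inherits(conc, "concentrations"))
  p <- params
  ku_c <- if (is.null(p$k_u_mut)) p$k_u else p$k_u_mut
  cc <- conc$c
  ## canonical order (m, n_c): 1:(0,0) 2:(0,1) 3:(1,0) 4:(1,1)
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- p$k_b * cc            # bind, OFF
  Q[2, 1] <- ku_c                  # unbind, OFF
  Q[2, 4] <- p$k_a * p$eta_ab      # activate, bound
  Q[4, 2] <- p$k_i * p$eta_ib      # deactivate, bound
  Q[4, 3] <- ku_c * p$eta_ua       # unbind, ON
  Q[3, 4] <- p$k_b * cc * p$eta_ba # bind, ON
  Q[1, 3] <- p$k_a                 # activate, unbound
  Q[3, 1] <- p$k_i                 # deactivate, unbound
  diag(Q) <- -rowSums(Q)
  spec <- circuit_spec()
  st <- enumerate_states(spec)
  ed <- data.frame(from = c(1, 2, 2, 4, 4, 3, 1, 3),
                   to   = c(2, 1, 4, 2, 3, 4, 3, 1),
                   kind = c("bind_c", "unbind_c", "activate", "deactivate",
                            "unbind_c", "bind_c", "activate", "deactivate"),
                   cexp = c(1, 0, 0, 0, 0, 1, 0, 0),
                   wexp = 0)
  ed$rate <- Q[cbind(ed$from, ed$to)]
  structure(list(states = st, Q = Q, on_mask = st$on, edges = ed, spec = spec,
                 conc = conc, params = params),
            class = "rate_matrix")
}

#' Two-state telegraph generator
#'
#' The minimal bursty locus: a single OFF <-> ON switch with rates `k_on` and
#' `k_off`. When `c_dependent = TRUE` the ON rate is proportional to the
#' cognate concentration (`k_on` is per unit concentration), which makes the
#' telegraph the closed-form anchor for the normalized sharpness (S = 1) and
#' precision (P = 1/2) bounds.
#'
#' @param k_on Switching rate OFF -> ON (per unit concentration if
#'   `c_dependent`).
#' @param k_off Switching rate ON -> OFF.
#' @param conc A [concentrations()].
#' @param c_dependent Does `k_on` scale with cognate concentration?
#' @return A `rate_matrix` with two states.
#' @export
telegraph_matrix <- function(k_on, k_off, conc = concentrations(),
                             c_dependent = TRUE) {
  stopifnot(k_on > 0, k_off > 0)
  cc <- if (c_dependent) conc$c else 1
  Q <- matrix(c(-k_on * cc, k_on * cc, k_off, -k_off), 2, 2, byrow = TRUE)
  st <- data.frame(n_c = c(0L, 1L), n_w = 0L, m = c(0L, 1L),
                   on = c(FALSE, TRUE), label = c("off", "on"))
  ed <- data.frame(from = c(1, 2), to = c(2, 1), kind = c("on", "off"),
                   cexp = c(as.integer(c_dependent), 0), wexp = 0,
                   rate = c(k_on * cc, k_off))
  structure(list(states = st, Q = Q, on_mask = st$on, edges = ed,
                 spec = NULL, conc = conc, params = NULL),
            class = "rate_matrix")
}

## States of the single terminal (recurrent) strongly-connected class.
recurrent_class <- function(Q) {
  if (nrow(Q) == 1L) return(1L)
  A <- Q > 0
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  nc <- comp$no
  leaves <- rep(TRUE, nc)
  ee <- which(A, arr.ind = TRUE)
  cross <- memb[ee[, 1]] != memb[ee[, 2]]
  leaves[unique(memb[ee[cross, 1]])] <- FALSE
  term <- which(leaves)
  if (length(term) != 1L)
    stop("reducible chain: more than one closed communicating class")
  which(memb == term)
}

#' Maximum cycle affinity of a rate matrix
#'
#' The thermodynamic distance from detailed balance: the maximum over an
#' independent cycle basis of `|log(product of forward rates / product of
#' reverse rates)|`. Zero (to numerical tolerance) iff the Kolmogorov criterion
#' holds, i.e. the circuit is at thermodynamic equilibrium. Transient states
#' (e.g. noncognate-bound states when `w = 0`) are excluded; a one-way edge
#' between recurrent states is a structural error since every physical
#' transition must be microscopically reversible.
#'
#' @param m A `rate_matrix`.
#' @return Dimensionless scalar `>= 0`.
#' @export
detailed_balance_residual <- function(m) {
  Q <- m$Q
  rec <- recurrent_class(Q)
  Q <- Q[rec, rec, drop = FALSE]
  n <- nrow(Q)
  if (n == 1L) return(0)
  fwd <- Q > 0
  diag(fwd) <- FALSE
  if (any(fwd != t(fwd)))
    stop("irreversible edge within the recurrent class")
  ## spanning-tree potentials: theta_j - theta_i = log(k_ij / k_ji) on tree
  ## edges; residual of a non-tree edge equals the affinity of its fundamental
  ## cycle.
  theta <- rep(NA_real_, n)
  theta[1] <- 0
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- which(fwd[i, ] & is.na(theta))
      theta[nb] <- theta[i] + log(Q[i, nb] / Q[nb, i])
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  ee <- which(fwd & upper.tri(fwd), arr.ind = TRUE)
  res <- abs(log(Q[ee] / Q[ee[, 2:1, drop = FALSE]]) -
               (theta[ee[, 2]] - theta[ee[, 1]]))
  max(res)
}

#' Construct an equilibrium circuit from energies and barriers
#'
#' Samples the equilibrium branch of the model family by construction: given
#' one free energy per state and one barrier per undirected edge of the
#' topology, each transition rate is `x_ij * exp(E_i - B_ij)` where `x_ij` is
#' the edge's concentration factor (`c` for cognate binding, `w` for
#' noncognate binding, 1 otherwise). The Kolmogorov criterion then holds
#' exactly and the stationary distribution is the Boltzmann weight
#' `pi_i ~ exp(-E_i) c^n_c w^n_w`. Where the topology is the four-state
#' circuit, the inverse mapping to basal rates and `eta` factors is attached
#' as attribute `"eta_params"`.
#'
#' @param spec A [circuit_spec()].
#' @param energies Numeric vector, one free energy (kT) per state in canonical
#'   order.
#' @param barriers Numeric vector, one barrier (kT) per undirected edge, in the
#'   order of unique undirected edges of the template (see the `edge_key`
#'   attribute of the result).
#' @param conc A [concentrations()].
#' @return A `rate_matrix` satisfying detailed balance to machine precision.
#' @export
equilibrium_sample <- function(spec, energies, barriers, conc = concentrations()) {
  tpl <- get_template(spec)
  e <- tpl$edges
  und <- paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "-")
  ukey <- unique(und)
  stopifnot(length(energies) == tpl$n, length(barriers) == length(ukey))
  B <- barriers[match(und, ukey)]
  lr <- energies[e$from] - B + e$cexp * log(conc$c)
  if (any(abs(lr) > 700)) stop("overflow in exponential rates; rescale energies")
  rate <- exp(lr)
  if (any(e$wexp > 0)) rate <- rate * ifelse(e$wexp > 0, conc$w^e$wexp, 1)
  Q <- matrix(0, tpl$n, tpl$n)
  Q[cbind(e$from, e$to)] <- rate
  diag(Q) <- -rowSums(Q)
  m <- structure(list(states = tpl$states, Q = Q, on_mask = tpl$states$on,
                      edges = cbind(e, rate = rate), spec = spec, conc = conc,
                      params = NULL),
                 class = "rate_matrix")
  attr(m, "edge_key") <- ukey
  if (spec$n_binding_sites == 1L && spec$n_activation_steps == 1L &&
      !spec$include_noncognate) {
    E <- energies
    Bm <- function(i, j) barriers[match(paste(min(i, j), max(i, j), sep = "-"), ukey)]
    k_b <- exp(E[1] - Bm(1, 2)); k_u <- exp(E[2] - Bm(1, 2))
    k_a <- exp(E[1] - Bm(1, 3)); k_i <- exp(E[3] - Bm(1, 3))
    attr(m, "eta_params") <- rate_params(
      k_b = k_b, k_u = k_u, k_a = k_a, k_i = k_i,
      eta_ab = exp(E[2] - Bm(2, 4)) / k_a,
      eta_ib = exp(E[4] - Bm(2, 4)) / k_i,
      eta_ua = exp(E[4] - Bm(3, 4)) / k_u,
      eta_ba = exp(E[3] - Bm(3, 4)) / k_b)
  }
  m
}

#' Project rate parameters onto the detailed-balance manifold
#'
#' Returns a copy of `params` whose interaction factors satisfy the Kolmogorov
#' criterion for the given topology. Under the exponent-counting rate laws
#' every fundamental square cycle of the occupancy-conformation lattice has
#' affinity `log(eta_ab * eta_ua / (eta_ib * eta_ba))`, so setting
#' `eta_ba := eta_ab * eta_ua / eta_ib` enforces detailed balance for all
#' `N_B` and `N_A`. Cooperativity (`eta_ub`) is an equilibrium interaction
#' and is untouched. Used by the sweep engine's equilibrium branch so that
#' equilibrium circuits are equilibrium by construction, not by rejection.
#'
#' @param spec A [circuit_spec()].
#' @param params A [rate_params()].
#' @return A `rate_params` on the equilibrium manifold.
#' @export
equilibrium_params <- function(spec, params) {
  p <- params
  p$eta_ba <- p$eta_ab * p$eta_ua / p$eta_ib
  p
}
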