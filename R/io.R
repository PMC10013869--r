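#' Serialize and restore circuit definitions
#'
#' Writes a circuit (spec, rate parameters, concentrations) to YAML or JSON,
#' chosen from the file extension, and reads it back.
#'
#' @param spec A [circuit_spec()].
#' @param params A [rate_params()].
#' @param conc A [concentrations()].
#' @param file Path ending in `.yaml`/`.yml` or `.json`.
#' @return `write_circuit()` returns `file` invisibly; `read_circuit()` a list
#'   with elements `spec`, `params`, `conc`.
#' @export
write_circuit <- function(spec, params, conc, file) {
  obj <- list(spec = unclass(spec),
              params = Filter(Negate(is.null), unclass(params)),
              conc = unclass(conc))
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(obj, file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported extension (use .yaml or .json)")
  invisible(file)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(file) {
  obj <- if (grepl("\\.ya?ml$", file)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else stop("unsupported extension (use .yaml or .json)")
  list(spec = do.call(circuit_spec, obj$spec),
       params = do.call(rate_params, obj$params),
       conc = do.call(concentrations, obj$conc))
}

#' Export a rate matrix as an edge list or GraphML
#'
#' `edge_list()` returns the directed edges of the generator with their rates
#' and provenance (which basal rate, multiplicity and concentration factors
#' built each rate); `write_edge_list()` saves it as CSV and
#' `write_graphml()` exports the labeled transition graph for inspection in
#' graph tools.
#'
#' @param m A `rate_matrix`.
#' @param file Output path.
#' @return `edge_list()`: a data frame with columns `from_state`, `to_state`,
#'   `rate`, `provenance`.
#' @export
edge_list <- function(m) {
  e <- m$edges[m$edges$rate > 0, , drop = FALSE]
  prov <- if (!is.null(e$type)) {
    sprintf("%s x%g%s%s", e$kind, e$mult,
            ifelse(e$cexp > 0, " *c", ""), ifelse(e$wexp > 0, " *w", ""))
  } else e$kind
  data.frame(from_state = m$states$label[e$from],
             to_state = m$states$label[e$to],
             rate = e$rate, provenance = prov)
}

#' @rdname edge_list
#' @export
write_edge_list <- function(m, file) {
  utils::write.csv(edge_list(m), file, row.names = FALSE)
  invisible(file)
}

#' @rdname edge_list
#' @export
write_graphml <- function(m, file) {
  el <- edge_list(m)
  g <- igraph::graph_from_data_frame(el, directed = TRUE)
  igraph::E(g)$rate <- el$rate
  igraph::V(g)$on <- m$states$on[match(igraph::V(g)$name, m$states$label)]
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Batch response summaries
#'
#' Evaluates [response_summary()] for a table of circuit parameter sets and
#' returns one row per circuit keyed by `circuit_id`, suitable for CSV
#' export.
#'
#' @param spec A [circuit_spec()] shared by all rows.
#' @param param_table Data frame with a `circuit_id` column plus columns named
#'   as [rate_params()] arguments; optional `c` and `w` columns override the
#'   concentrations per row.
#' @param conc Default [concentrations()].
#' @return A data frame of metric rows keyed by `circuit_id`.
#' @export
batch_response <- function(spec, param_table, conc = concentrations()) {
  stopifnot("circuit_id" %in% names(param_table))
  pnames <- intersect(names(param_table),
                      c("k_b", "k_u", "k_a", "k_i", "eta_ab", "eta_ib",
                        "eta_ua", "eta_ba", "eta_ub", "k_u_mut"))
  rows <- lapply(seq_len(nrow(param_table)), function(i) {
    p <- do.call(rate_params, as.list(param_table[i, pnames, drop = FALSE]))
    cc <- concentrations(
      c = if ("c" %in% names(param_table)) param_table$c[i] else conc$c,
      w = if ("w" %in% names(param_table)) param_table$w[i] else conc$w,
      delta_c_rel = conc$delta_c_rel)
    out <- response_summary(spec, p, cc)
    cbind(circuit_id = param_table$circuit_id[i], as.data.frame(out))
  })
  do.call(rbind, rows)
}
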