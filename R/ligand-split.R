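#' Ligand redistribution weights
#'
#' The receptor-level flow on an edge is split among the ligands expressed in
#' the source cell that can bind the receptor, in proportion to
#' `w_L = affinity^gamma * E_L(i)`: an affinity-weighting `phi(a) = a^gamma`
#' times ligand expression. With `gamma = 0` affinity is ignored; with the
#' default `gamma = 1` the weighting is the identity. Weights are returned
#' unnormalized.
#'
#' @param i Source cell id.
#' @param R Receptor gene symbol.
#' @param expr Expression matrix (cells x genes).
#' @param db An [lr_database()].
#' @param gamma Nonnegative affinity exponent.
#' @param tau Expression threshold (strict).
#' @return Named numeric vector of weights, one per expressed binder, in
#'   lexicographic ligand order.
#' @export
redistribution_weights <- function(i, R, expr, db, gamma = 1, tau = 0) {
  stopifnot(gamma >= 0)
  b <- binders(db, R)
  b <- b[b$ligand %in% colnames(expr), , drop = FALSE]
  e <- if (nrow(b) > 0) expr[i, b$ligand] else numeric()
  on <- e > tau
  if (!any(on)) {
    stop(sprintf("no expressed binder of '%s' in cell '%s' (violated upstream contract)",
                 R, i), call. = FALSE)
  }
  w <- b$affinity[on]^gamma * e[on]
  stats::setNames(as.numeric(w), b$ligand[on])
}

#' Split one edge flow across ligands
#'
#' Allocates `flow(L) = f_e * w_L / sum(w)`. The last ligand absorbs the
#' floating-point residual, so the allocations sum back to `f_e` to within
#' one unit in the last place (relative error below 1e-12).
#'
#' @param edge One-row data frame with at least `source`, `target`,
#'   `receptor` (a row of a flow graph's edge table).
#' @param f_e Nonnegative edge flow.
#' @param weights Named positive weight vector from
#'   [redistribution_weights()].
#' @return Data frame with columns `source,target,ligand,receptor,flow`, rows
#'   in lexicographic ligand order.
#' @export
split_edge_flow <- function(edge, f_e, weights) {
  stopifnot(f_e >= 0, length(weights) >= 1)
  total <- sum(weights)
  if (total <= 0) stop("redistribution weights sum to zero", call. = FALSE)
  weights <- weights[order(names(weights))]
  fl <- f_e * as.numeric(weights) / total
  n <- length(fl)
  if (n > 1) fl[n] <- f_e - sum(fl[-n])
  data.frame(source = edge$source, target = edge$target,
             ligand = names(weights), receptor = edge$receptor,
             flow = fl, stringsAsFactors = FALSE, row.names = NULL)
}

#' Redistribute all edge flows to single ligand-receptor resolution
#'
#' Applies [redistribution_weights()] and [split_edge_flow()] to every edge
#' of a feasible solution, producing the ligand-resolved flow table. The
#' redistribution is purely post hoc: it never feeds back into the flow
#' optimum.
#'
#' @param solution A feasible `flow_solution`.
#' @param expr Expression matrix used to build the graph.
#' @param db The [lr_database()] used to build the graph.
#' @param gamma Affinity exponent (see [redistribution_weights()]).
#' @param tau Expression threshold; defaults to the threshold used at graph
#'   build when available via `config`, else 0.
#' @param config Optional [flow_config()] supplying `tau`.
#' @return Data frame `source,target,ligand,receptor,flow`, ordered by
#'   (source, target, receptor, ligand).
#' @export
split_flows <- function(solution, expr, db, gamma = 1, tau = NULL,
                        config = NULL) {
  stopifnot(inherits(solution, "flow_solution"))
  if (!solution$feasible) {
    stop("cannot redistribute an infeasible solution", call. = FALSE)
  }
  if (is.null(tau)) {
    tau <- if (!is.null(config)) config$expr_threshold else 0
  }
  ed <- solution$flows
  if (nrow(ed) == 0) {
    return(data.frame(source = character(), target = character(),
                      ligand = character(), receptor = character(),
                      flow = numeric(), stringsAsFactors = FALSE))
  }
  parts <- lapply(seq_len(nrow(ed)), function(k) {
    w <- redistribution_weights(ed$source[k], ed$receptor[k], expr, db,
                                gamma = gamma, tau = tau)
    split_edge_flow(ed[k, , drop = FALSE], ed$flow[k], w)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$source, out$target, out$receptor, out$ligand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
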