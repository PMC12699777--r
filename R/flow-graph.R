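#' Spatial neighbor pairs under a distance cutoff
#'
#' All ordered pairs of distinct cells whose Euclidean distance is strictly
#' below `d_cutoff`; both directions are listed independently.
#'
#' @param coords Data frame with columns `cell`, `x`, `y`.
#' @param d_cutoff Positive distance cutoff (strict inequality).
#' @return Data frame with columns `source`, `target`, `distance`.
#' @export
pairwise_neighbors <- function(coords, d_cutoff) {
  validate_coords(coords)
  stopifnot(is.numeric(d_cutoff), length(d_cutoff) == 1, d_cutoff > 0)
  n <- nrow(coords)
  if (n < 2) {
    return(data.frame(source = character(), target = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  d <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  keep <- which(d < d_cutoff & row(d) != col(d), arr.ind = TRUE)
  out <- data.frame(source = coords$cell[keep[, 1]],
                    target = coords$cell[keep[, 2]],
                    distance = d[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Receptor-centric aggregate affinity
#'
#' The expression-weighted mean affinity of the ligands expressed in source
#' cell `i` (strictly above `tau`) that can bind receptor `R`:
#' `abar = sum(a_LR * E_L(i)) / sum(E_L(i))` over the expressed binders, or 0
#' when none is expressed.
#'
#' @param i Source cell id.
#' @param R Receptor gene symbol.
#' @param expr Expression matrix (cells in rows, genes in columns).
#' @param db An [lr_database()].
#' @param tau Expression threshold (strict).
#' @return A number in [0, 1].
#' @export
aggregate_affinity <- function(i, R, expr, db, tau = 0) {
  validate_expression(expr)
  b <- binders(db, R)
  b <- b[b$ligand %in% colnames(expr), , drop = FALSE]
  if (nrow(b) == 0) return(0)
  e <- expr[i, b$ligand]
  on <- e > tau
  if (!any(on)) return(0)
  sum(b$affinity[on] * e[on]) / sum(e[on])
}

#' Edge cost
#'
#' `c = d/d_cutoff + lambda * (1 - abar)`: normalized spatial distance plus a
#' penalty for weak aggregate binding affinity. Lies in [0, 1 + lambda].
#'
#' @param distance Spatial distance, in [0, d_cutoff).
#' @param affinity_aggregate Aggregate affinity in [0, 1].
#' @param config A [flow_config()].
#' @return Nonnegative edge cost (vectorized).
#' @export
edge_cost <- function(distance, affinity_aggregate, config) {
  stopifnot(all(distance >= 0), all(distance < config$d_cutoff),
            all(affinity_aggregate >= 0), all(affinity_aggregate <= 1))
  distance / config$d_cutoff +
    config$lambda_affinity * (1 - affinity_aggregate)
}

#' Edge capacity bounds
#'
#' The upper bound combines receptor abundance in the target cell with the
#' summed expression of the expressed binders in the source cell:
#' `u = kappa * combine(E_R(j), S_L(i))` with `combine` either `min` or
#' `product`. The lower bound is `epsilon * u` when at least one expressed
#' binder carries prior support, else 0.
#'
#' @param i,j Source and target cell ids.
#' @param R Receptor gene symbol.
#' @param expr Expression matrix (cells x genes).
#' @param db An [lr_database()].
#' @param config A [flow_config()].
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
edge_bounds <- function(i, j, R, expr, db, config) {
  validate_expression(expr)
  tau <- config$expr_threshold
  b <- binders(db, R)
  b <- b[b$ligand %in% colnames(expr), , drop = FALSE]
  e <- if (nrow(b) > 0) expr[i, b$ligand] else numeric()
  on <- e > tau
  S_L <- sum(e[on])
  E_R <- expr[j, R]
  if (E_R <= tau || S_L <= 0) {
    stop("edge_bounds called on an inadmissible (i, j, R) triple", call. = FALSE)
  }
  upper <- config$kappa_upper *
    switch(config$bound_combiner, min = min(E_R, S_L), product = E_R * S_L)
  if (upper <= 0) stop("internal error: zero upper bound on admissible edge")
  lower <- if (any(b$prior_confident[on])) config$epsilon_lower * upper else 0
  c(lower = lower, upper = upper)
}

#' Construct a receptor-centric flow graph
#'
#' One node per cell (net balance 0 unless overridden) and one directed edge
#' per (source i, target j, receptor R) triple passing all three gates:
#' distance strictly below the cutoff, receptor expressed in j above the
#' threshold, and at least one binder of R expressed in i above the threshold.
#' Each edge carries its distance, aggregate affinity, capacity bounds and
#' cost; edges are ordered lexicographically by (source, target, receptor).
#'
#' Positive lower bounds are restricted to the circulation core: nodes are
#' iteratively stripped while they lack admissible incoming or outgoing
#' capacity, because any edge touching such a node is forced to zero flow in
#' every circulation and a positive lower bound there would make the whole
#' problem infeasible regardless of epsilon. Edges outside the core are kept
#' (with lower bound 0) so the graph still reports the admissible topology.
#'
#' @param expr Expression matrix, cells in rows (rownames), genes in columns
#'   (colnames), nonnegative.
#' @param coords Data frame with columns `cell`, `x`, `y` covering exactly the
#'   cells of `expr`.
#' @param db An [lr_database()].
#' @param config A [flow_config()].
#' @param balances Optional data frame `cell,balance` of net supplies
#'   (positive = net source). Must sum to zero. Default: all zero.
#' @return A `flow_graph`: list with `nodes` (data frame `cell,balance`),
#'   `edges` (data frame `source,target,receptor,distance,affinity,lower,
#'   upper,cost`) and `config`.
#' @export
build_flow_graph <- function(expr, coords, db, config, balances = NULL) {
  validate_expression(expr)
  validate_coords(coords)
  stopifnot(inherits(db, "lr_database"), inherits(config, "flow_config"))
  cells <- rownames(expr)
  if (!setequal(cells, coords$cell) || nrow(coords) != length(cells)) {
    stop("expression matrix and coordinates cover different cells", call. = FALSE)
  }
  coords <- coords[match(cells, coords$cell), , drop = FALSE]
  tau <- config$expr_threshold

  nb <- pairwise_neighbors(coords, config$d_cutoff)
  receptors <- intersect(sort(unique(db$pairs$receptor)), colnames(expr))

  edge_list <- list()
  for (R in receptors) {
    b <- binders(db, R)
    b <- b[b$ligand %in% colnames(expr), , drop = FALSE]
    if (nrow(b) == 0) next
    EB <- expr[, b$ligand, drop = FALSE]
    on <- EB > tau
    S <- rowSums(EB * on)                       # per-source binder availability
    abar <- ifelse(S > 0, as.vector((EB * on) %*% b$affinity) / S, 0)
    prior <- as.vector(on %*% b$prior_confident) > 0
    ER <- expr[, R]
    names(S) <- names(abar) <- names(prior) <- names(ER) <- cells

    ok <- S[nb$source] > 0 & ER[nb$target] > tau
    if (!any(ok)) next
    sub <- nb[ok, , drop = FALSE]
    s_l <- S[sub$source]
    e_r <- ER[sub$target]
    upper <- config$kappa_upper *
      switch(config$bound_combiner, min = pmin(e_r, s_l), product = e_r * s_l)
    lower <- ifelse(prior[sub$source], config$epsilon_lower * upper, 0)
    aff <- abar[sub$source]
    edge_list[[R]] <- data.frame(
      source = sub$source, target = sub$target, receptor = R,
      distance = sub$distance, affinity = aff,
      lower = lower, upper = upper,
      cost = sub$distance / config$d_cutoff +
        config$lambda_affinity * (1 - aff),
      stringsAsFactors = FALSE)
  }

  edges <- if (length(edge_list) > 0) do.call(rbind, edge_list) else
    data.frame(source = character(), target = character(),
               receptor = character(), distance = numeric(),
               affinity = numeric(), lower = numeric(), upper = numeric(),
               cost = numeric(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target, edges$receptor), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  if (nrow(edges) == 0) {
    warning("flow graph has zero edges (distance cutoff or expression gates ",
            "exclude all cell pairs)", call. = FALSE)
  } else {
    core <- circulation_core(cells, edges)
    drop_lb <- !(edges$source %in% core & edges$target %in% core)
    edges$lower[drop_lb] <- 0
  }

  bal <- rep(0, length(cells))
  names(bal) <- cells
  if (!is.null(balances)) {
    stopifnot(is.data.frame(balances), all(c("cell", "balance") %in% names(balances)))
    if (!all(balances$cell %in% cells)) {
      stop("balance table names unknown cells", call. = FALSE)
    }
    bal[balances$cell] <- balances$balance
    if (abs(sum(bal)) > 1e-9 * max(1, max(abs(bal)))) {
      stop("node balances must sum to zero for a circulation to exist",
           call. = FALSE)
    }
  }

  flow_graph(edges,
             nodes = data.frame(cell = cells, balance = unname(bal),
                                stringsAsFactors = FALSE),
             config = config)
}

#' Assemble a flow graph from an explicit edge table
#'
#' Low-level constructor used by [build_flow_graph()] and handy for building
#' engineered instances (e.g. deliberately infeasible circulations) directly.
#'
#' @param edges Data frame with at least `source,target,lower,upper,cost`;
#'   `receptor`, `distance`, `affinity` are filled with placeholders when
#'   missing.
#' @param nodes Optional data frame `cell,balance`; defaults to the cells
#'   appearing in `edges` with balance 0.
#' @param config Optional [flow_config()] attached for downstream defaults.
#' @return A `flow_graph` object.
#' @export
flow_graph <- function(edges, nodes = NULL, config = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "lower", "upper", "cost") %in% names(edges)))
  if (!"receptor" %in% names(edges)) edges$receptor <- "R"
  if (!"distance" %in% names(edges)) edges$distance <- 0
  if (!"affinity" %in% names(edges)) edges$affinity <- 1
  if (any(edges$lower < 0) || any(edges$upper < edges$lower)) {
    stop("edge bounds must satisfy 0 <= lower <= upper", call. = FALSE)
  }
  if (any(edges$cost < 0)) {
    stop("edge costs must be nonnegative", call. = FALSE)
  }
  key <- paste(edges$source, edges$target, edges$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    stop("at most one edge per (source, target, receptor) triple", call. = FALSE)
  }
  if (is.null(nodes)) {
    cells <- sort(unique(c(edges$source, edges$target)))
    nodes <- data.frame(cell = cells, balance = 0, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("cell", "balance") %in% names(nodes)),
            !anyDuplicated(nodes$cell))
  edges <- edges[, c("source", "target", "receptor", "distance", "affinity",
                     "lower", "upper", "cost"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, config = config),
            class = "flow_graph")
}

#' @exportS3Method base::print
print.flow_graph <- function(x, ...) {
  cat(sprintf("<flow_graph> %d nodes, %d edges (%d with lower bound > 0)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$lower > 0)))
  invisible(x)
}

# Maximal node set on which a circulation can be supported: repeatedly drop
# nodes with no remaining outgoing or no remaining incoming edge.
circulation_core <- function(cells, edges) {
  keep <- cells
  repeat {
    e <- edges[edges$source %in% keep & edges$target %in% keep, , drop = FALSE]
    ok <- intersect(unique(e$source), unique(e$target))
    new_keep <- intersect(keep, ok)
    if (length(new_keep) == length(keep)) return(keep)
    keep <- new_keep
    if (length(keep) == 0) return(character())
  }
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (cells x genes)", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs cell rownames and gene colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop("duplicate gene symbols", call. = FALSE)
  if (any(expr < 0)) {
    bad <- which(expr < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at cell '%s', gene '%s'",
                 rownames(expr)[bad[1]], colnames(expr)[bad[2]]), call. = FALSE)
  }
  invisible(expr)
}

validate_coords <- function(coords) {
  if (!is.data.frame(coords) || !all(c("cell", "x", "y") %in% names(coords))) {
    stop("coordinates must be a data frame with columns cell, x, y",
         call. = FALSE)
  }
  if (anyDuplicated(coords$cell)) {
    stop("duplicate cell id in coordinate table", call. = FALSE)
  }
  if (!is.numeric(coords$x) || !is.numeric(coords$y) ||
      anyNA(coords$x) || anyNA(coords$y)) {
    stop("non-numeric coordinate", call. = FALSE)
  }
  invisible(coords)
}
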