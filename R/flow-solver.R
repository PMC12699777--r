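#' Quantize a flow graph to integer bounds
#'
#' The exact integral solver needs integer capacities. Bounds are scaled by
#' `s = quantum / max(upper)` and rounded conservatively -- lower bounds up,
#' upper bounds down -- so quantization never widens the feasible set. Costs
#' are scaled to integers with 1e6 steps over the cost range. Scale factors
#' are returned for back-conversion.
#'
#' @param graph A `flow_graph`.
#' @param quantum Positive integer; flow units assigned to the largest upper
#'   bound.
#' @return A list: `edges` (the edge table with integer `lower`, `upper`,
#'   `cost` columns replacing the originals), `flow_scale` (`s`),
#'   `cost_scale`, and `nodes` with integer balances.
#' @export
quantize_graph <- function(graph, quantum = 1000L) {
  stopifnot(inherits(graph, "flow_graph"), quantum >= 1)
  e <- graph$edges
  if (nrow(e) == 0) {
    return(list(edges = e, nodes = graph$nodes, flow_scale = 1, cost_scale = 1))
  }
  umax <- max(e$upper)
  if (umax <= 0) stop("empty capacity: all upper bounds are zero", call. = FALSE)
  s <- quantum / umax
  # an integer scale quantizes already-integral bounds exactly (keeps tight
  # l == u intervals solvable); only possible when umax <= quantum
  if (s >= 1) s <- floor(s)
  # tiny tolerance absorbs representation error in products like 0.05 * u * s
  li <- ceiling(e$lower * s - 1e-9)
  ui <- floor(e$upper * s + 1e-9)
  bad <- which(li > ui)
  if (length(bad) > 0) {
    stop(sprintf(paste0("quantization made lower > upper on %d edge(s) ",
                        "(first: %s -> %s / %s); raise `quantum`"),
                 length(bad), e$source[bad[1]], e$target[bad[1]],
                 e$receptor[bad[1]]), call. = FALSE)
  }
  cmax <- max(e$cost)
  cost_scale <- if (cmax > 0) 1e6 / cmax else 1
  ci <- round(e$cost * cost_scale)
  e$lower <- li
  e$upper <- ui
  e$cost <- ci
  nodes <- graph$nodes
  bi <- round(nodes$balance * s)
  if (sum(bi) != 0) {
    stop("node balances do not sum to zero after quantization", call. = FALSE)
  }
  nodes$balance <- bi
  list(edges = e, nodes = nodes, flow_scale = s, cost_scale = cost_scale)
}

#' Eliminate lower bounds: residual problem with super-source and super-sink
#'
#' Standard reduction of the bounded circulation: residual variables
#' `f' = f - l` with capacities `u - l`, node imbalances
#' `r_v = sum(l, into v) - sum(l, out of v) + b_v`, auxiliary zero-cost edges
#' super-source -> v of capacity `r_v` for `r_v > 0` and v -> super-sink of
#' capacity `-r_v` for `r_v < 0`, and fixed cost `sum(l_e * c_e)`. The
#' original problem is feasible iff a max flow saturates every auxiliary
#' edge, and its optimum is the fixed cost plus the residual optimum.
#'
#' @param qgraph Output of [quantize_graph()] (integer bounds/costs), or a
#'   `flow_graph` whose bounds and costs are already whole numbers.
#' @return A list: `edges` (residual capacities/costs), `imbalance` (named
#'   `r_v` vector), `aux` (data frame `from,to,capacity` of auxiliary edges),
#'   `super_source`, `super_sink`, `fixed_cost`, `nodes`.
#' @export
transform_lower_bounds <- function(qgraph) {
  if (inherits(qgraph, "flow_graph")) {
    qgraph <- list(edges = qgraph$edges, nodes = qgraph$nodes,
                   flow_scale = 1, cost_scale = 1)
  }
  e <- qgraph$edges
  nodes <- qgraph$nodes
  if (any(e$lower != round(e$lower)) || any(e$upper != round(e$upper)) ||
      any(e$cost != round(e$cost)) || any(nodes$balance != round(nodes$balance))) {
    stop("transform_lower_bounds needs integer bounds, costs and balances ",
         "(quantize first)", call. = FALSE)
  }
  if (sum(nodes$balance) != 0) {
    stop("node balances must sum to zero", call. = FALSE)
  }
  r <- nodes$balance
  names(r) <- nodes$cell
  if (nrow(e) > 0) {
    r <- r + tapply_sum(e$lower, e$target, nodes$cell) -
      tapply_sum(e$lower, e$source, nodes$cell)
  }
  pos <- names(r)[r > 0]
  neg <- names(r)[r < 0]
  aux <- rbind(
    data.frame(from = rep("..S", length(pos)), to = pos,
               capacity = unname(r[pos]), stringsAsFactors = FALSE),
    data.frame(from = neg, to = rep("..T", length(neg)),
               capacity = unname(-r[neg]), stringsAsFactors = FALSE))
  res_edges <- e
  res_edges$capacity <- e$upper - e$lower
  list(edges = res_edges, imbalance = r, aux = aux,
       super_source = "..S", super_sink = "..T",
       fixed_cost = sum(e$lower * e$cost), nodes = nodes)
}

tapply_sum <- function(values, keys, levels) {
  out <- rep(0, length(levels))
  names(out) <- levels
  agg <- rowsum(values, keys)
  out[rownames(agg)] <- agg[, 1]
  out
}

#' Solve the bounded minimum-cost circulation
#'
#' Quantizes the graph, eliminates lower bounds via the super-source /
#' super-sink transform, and solves the residual min-cost max-flow exactly by
#' successive shortest paths. If any auxiliary edge is left unsaturated the
#' circulation is infeasible: the solution reports `feasible = FALSE` with
#' per-node shortfall diagnostics and no flows. Otherwise the edge flows
#' `f = f' + l` are de-quantized and the objective is the fixed lower-bound
#' contribution plus the residual optimum.
#'
#' Prior-induced lower bounds can make a circulation infeasible;
#' `relax_lower = TRUE` halves every lower bound (equivalently the epsilon
#' fraction) up to `max_relax` times until a feasible circulation exists, and
#' records the final relaxation factor in the solution.
#'
#' @param graph A `flow_graph`.
#' @param quantum Integer flow quantum; defaults to the graph config's value.
#' @param relax_lower Halve lower bounds on infeasibility (up to `max_relax`
#'   times).
#' @param max_relax Maximum number of halvings.
#' @param verify Cross-check objective and feasibility against [lp_oracle()]
#'   (graphs up to 500 edges).
#' @return A `flow_solution`: list with `flows` (edge table plus `flow`
#'   column), `objective`, `feasible`, `diagnostics` (node shortfalls when
#'   infeasible), `epsilon_factor` (1 when no relaxation applied),
#'   `fixed_cost`, `residual_cost`, `flow_scale`, and integer-unit vectors
#'   `flow_int`, `lower_int`, `upper_int` for exact invariant checking.
#' @export
solve_flow <- function(graph, quantum = NULL, relax_lower = FALSE,
                       max_relax = 10L, verify = FALSE) {
  stopifnot(inherits(graph, "flow_graph"))
  if (is.null(quantum)) {
    quantum <- if (!is.null(graph$config)) graph$config$quantum else 1000L
  }
  attempt <- 0L
  g <- graph
  repeat {
    sol <- solve_flow_once(g, quantum)
    if (sol$feasible || !relax_lower || attempt >= max_relax ||
        all(g$edges$lower == 0)) break
    attempt <- attempt + 1L
    g$edges$lower <- g$edges$lower / 2
  }
  sol$epsilon_factor <- 2^(-attempt)
  if (attempt > 0) {
    message(sprintf("lower bounds relaxed %d time(s); final epsilon factor %g",
                    attempt, sol$epsilon_factor))
  }
  if (verify && nrow(graph$edges) <= 500) {
    oracle <- lp_oracle(g)
    if (oracle$feasible != sol$feasible) {
      warning("LP oracle disagrees with solver on feasibility", call. = FALSE)
    } else if (sol$feasible) {
      rel <- abs(oracle$objective - sol$objective) /
        max(1e-12, abs(oracle$objective))
      if (rel > 1e-3) {
        warning(sprintf("LP oracle objective differs by %.2g relative", rel),
                call. = FALSE)
      }
    }
    sol$verified <- oracle
  }
  sol
}

solve_flow_once <- function(graph, quantum) {
  e <- graph$edges
  empty_sol <- function(feasible, diagnostics = NULL) {
    structure(list(flows = cbind(e, flow = if (nrow(e)) 0 else numeric()),
                   objective = if (feasible) 0 else NA_real_,
                   feasible = feasible, diagnostics = diagnostics,
                   fixed_cost = 0, residual_cost = 0, flow_scale = 1,
                   flow_int = integer(), lower_int = integer(),
                   upper_int = integer(), epsilon_factor = 1),
              class = "flow_solution")
  }
  if (nrow(e) == 0 || max(e$upper) <= 0) {
    # no usable capacity: the zero circulation is the only candidate
    if (any(graph$nodes$balance != 0)) {
      return(empty_sol(FALSE, data.frame(cell = graph$nodes$cell,
                                         shortfall = abs(graph$nodes$balance))))
    }
    return(empty_sol(TRUE))
  }

  q <- quantize_graph(graph, quantum)
  rp <- transform_lower_bounds(q)

  node_ids <- c(rp$nodes$cell, rp$super_source, rp$super_sink)
  idx <- stats::setNames(seq_along(node_ids) - 1L, node_ids)
  m_real <- nrow(rp$edges)
  from <- c(idx[rp$edges$source], idx[rp$aux$from])
  to <- c(idx[rp$edges$target], idx[rp$aux$to])
  cap <- c(rp$edges$capacity, rp$aux$capacity)
  cost <- c(rp$edges$cost, rep(0, nrow(rp$aux)))

  res <- mcmf_cpp(length(node_ids), as.integer(from), as.integer(to),
                  as.numeric(cap), as.numeric(cost),
                  idx[[rp$super_source]], idx[[rp$super_sink]])

  required <- sum(rp$aux$capacity[rp$aux$from == rp$super_source])
  if (res$total_flow < required) {
    aux_flow <- res$flow[seq_len(nrow(rp$aux)) + m_real]
    short <- rp$aux$capacity - aux_flow
    is_src <- rp$aux$from == rp$super_source
    diag <- data.frame(
      cell = ifelse(is_src, rp$aux$to, rp$aux$from),
      side = ifelse(is_src, "undeliverable_inflow", "unrecoverable_outflow"),
      shortfall = short / q$flow_scale,
      stringsAsFactors = FALSE)
    diag <- diag[diag$shortfall > 0, , drop = FALSE]
    rownames(diag) <- NULL
    out <- empty_sol(FALSE, diag)
    out$flows$flow <- NA_real_
    return(out)
  }

  f_int <- q$edges$lower + res$flow[seq_len(m_real)]
  flows <- e
  flows$flow <- f_int / q$flow_scale
  objective_int <- rp$fixed_cost + res$total_cost
  structure(list(
    flows = flows,
    objective = objective_int / (q$flow_scale * q$cost_scale),
    feasible = TRUE,
    diagnostics = NULL,
    fixed_cost = rp$fixed_cost / (q$flow_scale * q$cost_scale),
    residual_cost = res$total_cost / (q$flow_scale * q$cost_scale),
    flow_scale = q$flow_scale,
    flow_int = f_int,
    lower_int = q$edges$lower,
    upper_int = q$edges$upper,
    epsilon_factor = 1), class = "flow_solution")
}

#' @exportS3Method base::print
print.flow_solution <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<flow_solution> feasible; %d edges, %d carrying flow; objective %.6g\n",
                nrow(x$flows), sum(x$flows$flow > 0), x$objective))
  } else {
    cat(sprintf("<flow_solution> infeasible; %d node shortfall(s)\n",
                if (is.null(x$diagnostics)) 0L else nrow(x$diagnostics)))
  }
  invisible(x)
}
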