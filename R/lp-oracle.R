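#' Linear-programming oracle for the bounded circulation
#'
#' Solves the bounded minimum-cost circulation directly as a linear program
#' over the node-arc incidence constraints, using the HiGHS solver via
#' `scipy.optimize.linprog` (invoked through the system `python`). This is a
#' verification oracle, deliberately independent of the integral
#' successive-shortest-paths solver in [solve_flow()]: the LP keeps the
#' native `l <= f <= u` variable bounds (no lower-bound elimination, no
#' quantization). Used in tests and `verify` mode; it never replaces the
#' solver.
#'
#' @param graph A `flow_graph` with at most `max_edges` edges.
#' @param max_edges Size guard (default 500).
#' @return A list with `feasible`, `objective`, and `flows` (edge table with
#'   `flow` column; `NULL` when infeasible).
#' @seealso [lp_oracle_batch()] to solve many small instances in one
#'   interpreter call.
#' @export
lp_oracle <- function(graph, max_edges = 500L) {
  lp_oracle_batch(list(graph), max_edges = max_edges)[[1]]
}

#' Batch form of the LP oracle
#'
#' Solves a list of bounded-circulation instances in a single Python
#' interpreter invocation (one process launch instead of one per instance).
#'
#' @param graphs List of `flow_graph` objects.
#' @inheritParams lp_oracle
#' @return List of results in the shape of [lp_oracle()].
#' @export
lp_oracle_batch <- function(graphs, max_edges = 500L) {
  stopifnot(is.list(graphs), all(vapply(graphs, inherits, logical(1), "flow_graph")))
  results <- vector("list", length(graphs))

  # trivial instances are answered R-side
  todo <- integer()
  problems <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    e <- g$edges
    if (nrow(e) > max_edges) {
      stop(sprintf("lp_oracle is guarded to <= %d edges", max_edges),
           call. = FALSE)
    }
    if (nrow(e) == 0) {
      feas <- all(g$nodes$balance == 0)
      results[[gi]] <- list(feasible = feas,
                            objective = if (feas) 0 else NA_real_,
                            flows = if (feas) cbind(e, flow = numeric()) else NULL)
      next
    }
    todo <- c(todo, gi)
    problems[[length(problems) + 1]] <- list(
      src = match(e$source, g$nodes$cell) - 1L,
      tgt = match(e$target, g$nodes$cell) - 1L,
      n_nodes = nrow(g$nodes),
      lower = e$lower, upper = e$upper, cost = e$cost,
      balance = g$nodes$balance)
  }

  if (length(todo) > 0) {
    infile <- tempfile(fileext = ".json")
    outfile <- tempfile(fileext = ".json")
    on.exit(unlink(c(infile, outfile)), add = TRUE)
    writeLines(jsonlite::toJSON(problems, digits = NA), infile)
    script <- system.file("python", "lp_oracle.py", package = "flowccc")
    if (!nzchar(script)) stop("bundled lp_oracle.py not found", call. = FALSE)
    status <- system2("python", c(shQuote(script), shQuote(infile),
                                  shQuote(outfile)),
                      stdout = NULL, stderr = "")
    if (status != 0 || !file.exists(outfile)) {
      stop("LP oracle subprocess failed (is python with scipy on the PATH?)",
           call. = FALSE)
    }
    ans <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
    for (k in seq_along(todo)) {
      gi <- todo[k]
      a <- ans[[k]]
      if (isTRUE(a$feasible)) {
        flows <- graphs[[gi]]$edges
        flows$flow <- as.numeric(unlist(a$flow))
        results[[gi]] <- list(feasible = TRUE,
                              objective = as.numeric(a$objective),
                              flows = flows)
      } else {
        results[[gi]] <- list(feasible = FALSE, objective = NA_real_,
                              flows = NULL)
      }
    }
  }
  results
}
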