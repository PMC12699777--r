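#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mean ranks).
#' Returns `NA` when either vector is constant (rank correlation is
#' undefined there).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A number in [-1, 1], or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Score inferred communication against ground truth
#'
#' For every ligand-receptor pair present in the ground truth, the inferred
#' and true amounts are vectorized over the ordered (source, target) grid
#' with source != target (the model is intercellular; autocrine entries are
#' excluded on both sides) and compared by Spearman correlation. Inferred
#' entries absent from `inferred` count as 0. Pairs whose truth or inferred
#' vector is constant are skipped and listed.
#'
#' @param inferred Ligand-flow table (`source,target,ligand,receptor,flow`).
#' @param truth Ground-truth table (`source,target,ligand,receptor,amount`)
#'   from [extract_ground_truth()].
#' @return A list of class `benchmark_result`: `per_pair` (data frame
#'   `ligand,receptor,rho,n`), `mean_rho`, `median_rho`, `skipped`.
#' @export
evaluate_inference <- function(inferred, truth) {
  stopifnot(all(c("source", "target", "ligand", "receptor", "amount") %in%
                  names(truth)),
            all(c("source", "target", "ligand", "receptor", "flow") %in%
                  names(inferred)))
  cells <- sort(unique(c(truth$source, truth$target)))
  grid <- expand.grid(source = cells, target = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  pair_key <- function(df) paste(df$source, df$target, sep = "\r")
  inf_key <- paste(inferred$source, inferred$target, inferred$ligand,
                   inferred$receptor, sep = "\r")
  inf_val <- stats::setNames(inferred$flow, inf_key)

  pairs <- unique(truth[, c("ligand", "receptor")])
  pairs <- pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
  rows <- list(); skipped <- list()
  for (k in seq_len(nrow(pairs))) {
    L <- pairs$ligand[k]; R <- pairs$receptor[k]
    tr <- truth[truth$ligand == L & truth$receptor == R, , drop = FALSE]
    tr_val <- stats::setNames(tr$amount, pair_key(tr))
    v_truth <- unname(tr_val[pair_key(grid)])
    v_truth[is.na(v_truth)] <- 0
    v_inf <- unname(inf_val[paste(grid$source, grid$target, L, R, sep = "\r")])
    v_inf[is.na(v_inf)] <- 0
    if (length(v_truth) < 3 || stats::var(v_truth) == 0 ||
        stats::var(v_inf) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(ligand = L, receptor = R,
                   reason = if (length(v_truth) < 3) "too_few_entries"
                            else "constant_vector",
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(ligand = L, receptor = R,
                 rho = spearman_rho(v_inf, v_truth),
                 n = length(v_truth), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop("no scorable ligand-receptor pair (all constant or too small)",
         call. = FALSE)
  }
  per_pair <- do.call(rbind, rows)
  structure(list(per_pair = per_pair,
                 mean_rho = mean(per_pair$rho),
                 median_rho = stats::median(per_pair$rho),
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL),
            class = "benchmark_result")
}

#' @exportS3Method base::print
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d pairs; mean rho %.3f, median rho %.3f\n",
              nrow(x$per_pair), x$mean_rho, x$median_rho))
  invisible(x)
}

#' Distance-weighted expression-product baseline
#'
#' A naive comparator: `flow(i,j,L,R) = E_L(i) * E_R(j) * exp(-d_ij / sigma)`
#' for every database pair and every ordered pair of distinct cells within
#' the distance cutoff.
#'
#' @param expr Expression matrix (cells x genes).
#' @param coords Coordinate table (`cell,x,y`).
#' @param db An [lr_database()].
#' @param sigma Positive kernel length scale.
#' @param d_cutoff Positive distance cutoff (strict).
#' @return Ligand-flow table `source,target,ligand,receptor,flow`.
#' @export
baseline_distance_product <- function(expr, coords, db, sigma, d_cutoff) {
  stopifnot(sigma > 0)
  validate_expression(expr)
  nb <- pairwise_neighbors(coords, d_cutoff)
  pairs <- db$pairs[db$pairs$ligand %in% colnames(expr) &
                      db$pairs$receptor %in% colnames(expr), , drop = FALSE]
  parts <- lapply(seq_len(nrow(pairs)), function(k) {
    L <- pairs$ligand[k]; R <- pairs$receptor[k]
    data.frame(source = nb$source, target = nb$target, ligand = L,
               receptor = R,
               flow = expr[nb$source, L] * expr[nb$target, R] *
                 exp(-nb$distance / sigma),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$source, out$target, out$receptor, out$ligand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the simulation benchmark suite
#'
#' For each (regime, seed) combination: generate a scenario, solve the
#' reaction-diffusion steady state for ground truth, run the flow-based
#' inference (graph build, bounded circulation with relax-on-infeasibility,
#' ligand redistribution) and the distance-product baseline on the converted
#' inputs, and score both against the ground truth.
#'
#' Defaults are chosen from the simulator's physics: with decay length
#' `sqrt(D / k_deg)` equal to one lattice spacing, the graph cutoff is
#' `2.5 h` and the baseline kernel scale is `d_cutoff / 2`.
#'
#' @param regimes Character vector of regimes.
#' @param seeds Integer vector of scenario seeds.
#' @param n_cells Lattice size (square number).
#' @param params A [kinetic_params()].
#' @param config Optional [flow_config()]; default as described above.
#' @param sigma Baseline kernel scale; default `d_cutoff / 2`.
#' @param gamma Affinity exponent for redistribution.
#' @return Data frame with one row per (regime, seed, method):
#'   `regime,seed,method,mean_rho,median_rho,n_pairs,feasible,epsilon_factor`.
#' @export
run_benchmark <- function(regimes = c("type1", "type2", "type3"),
                          seeds = 1:3, n_cells = 25,
                          params = kinetic_params(), config = NULL,
                          sigma = NULL, gamma = 1) {
  if (is.null(config)) config <- flow_config(d_cutoff = 2.5 * params$h)
  if (is.null(sigma)) sigma <- config$d_cutoff / 2
  rows <- list()
  for (regime in regimes) {
    for (seed in seeds) {
      sc <- make_scenario(regime, n_cells = n_cells, params = params,
                          seed = seed)
      sim <- simulate_steady_state(sc, params)
      truth <- extract_ground_truth(sim, sc, params)
      inputs <- scenario_to_inputs(sc)

      graph <- build_flow_graph(inputs$expression, inputs$coords, inputs$db,
                                config)
      sol <- suppressMessages(solve_flow(graph, relax_lower = TRUE))
      if (sol$feasible) {
        lig <- split_flows(sol, inputs$expression, inputs$db, gamma = gamma,
                           config = config)
        ev <- evaluate_inference(lig, truth)
        rows[[length(rows) + 1]] <- data.frame(
          regime = regime, seed = seed, method = "flow",
          mean_rho = ev$mean_rho, median_rho = ev$median_rho,
          n_pairs = nrow(ev$per_pair), feasible = TRUE,
          epsilon_factor = sol$epsilon_factor, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          regime = regime, seed = seed, method = "flow",
          mean_rho = NA_real_, median_rho = NA_real_, n_pairs = 0L,
          feasible = FALSE, epsilon_factor = sol$epsilon_factor,
          stringsAsFactors = FALSE)
      }

      base <- baseline_distance_product(inputs$expression, inputs$coords,
                                        inputs$db, sigma = sigma,
                                        d_cutoff = config$d_cutoff)
      evb <- evaluate_inference(base, truth)
      rows[[length(rows) + 1]] <- data.frame(
        regime = regime, seed = seed, method = "baseline",
        mean_rho = evb$mean_rho, median_rho = evb$median_rho,
        n_pairs = nrow(evb$per_pair), feasible = TRUE, epsilon_factor = 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
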