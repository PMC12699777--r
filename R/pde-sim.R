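#' Kinetic parameters of the reaction-diffusion simulator
#'
#' @param D Ligand diffusion coefficient (length^2 / time).
#' @param k_prod Reference per-cell per-ligand production rate (amount /
#'   time); actual rates are drawn log-uniformly over `[0.1, 1] * k_prod`.
#' @param k_deg First-order ligand degradation rate (1 / time); must be
#'   positive so a steady state exists.
#' @param k_on Binding rate constant (1 / (amount * time)). Receptor binding
#'   acts as a sink on the free-ligand field (internalization-style).
#' @param k_off Unbinding rate constant (1 / time); the equilibrium complex
#'   readout is `(k_on/k_off) * u * R_free`.
#' @param h Lattice spacing (length).
#' @param tol Relative convergence tolerance of the free-receptor fixed
#'   point.
#' @param max_outer Cap on outer fixed-point iterations.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(D = 1, k_prod = 1, k_deg = 1, k_on = 1, k_off = 1,
                           h = 1, tol = 1e-8, max_outer = 500L) {
  stopifnot(D > 0, k_prod >= 0, k_deg > 0, k_on >= 0, k_off > 0, h > 0,
            tol > 0, max_outer >= 1)
  structure(list(D = D, k_prod = k_prod, k_deg = k_deg, k_on = k_on,
                 k_off = k_off, h = h, tol = tol,
                 max_outer = as.integer(max_outer)),
            class = "kinetic_params")
}

#' Generate a benchmark scenario
#'
#' Places cells on a square lattice and draws, from a seeded generator, which
#' ligands each cell secretes (probability 0.5 per ligand, with every ligand
#' forced to have at least one producer), which receptors it displays
#' (probability 0.5, every receptor displayed somewhere), per-(cell, ligand)
#' production rates (log-uniform over `[0.1, 1] * k_prod`), per-(cell,
#' receptor) totals (log-uniform over `[0.1, 1]`), and a ligand-receptor
#' connectivity appropriate to the regime:
#' \describe{
#'   \item{type1}{more ligands than receptors; many-to-few wiring (each
#'     ligand binds a receptor, extra links with probability 0.3).}
#'   \item{type2}{more receptors than ligands; few-to-many wiring.}
#'   \item{type3}{at least 3 of each; random bipartite graph redrawn until
#'     density >= 0.4 with no isolated ligand or receptor.}
#' }
#'
#' @param regime `"type1"`, `"type2"` or `"type3"`.
#' @param n_cells A square number of lattice cells.
#' @param n_ligands,n_receptors Cardinalities; defaults per regime are
#'   4/2, 2/4 and 4/4.
#' @param params A [kinetic_params()].
#' @param seed Integer seed; the scenario is fully reproducible from it.
#' @return A list of class `scenario`.
#' @export
make_scenario <- function(regime = c("type1", "type2", "type3"),
                          n_cells = 25, n_ligands = NULL, n_receptors = NULL,
                          params = kinetic_params(), seed = 1) {
  regime <- match.arg(regime)
  side <- round(sqrt(n_cells))
  if (side * side != n_cells) stop("`n_cells` must be a square number", call. = FALSE)
  defaults <- switch(regime,
                     type1 = c(4, 2), type2 = c(2, 4), type3 = c(4, 4))
  if (is.null(n_ligands)) n_ligands <- defaults[1]
  if (is.null(n_receptors)) n_receptors <- defaults[2]
  if (regime == "type1" && !(n_ligands > n_receptors)) {
    stop("type1 requires n_ligands > n_receptors", call. = FALSE)
  }
  if (regime == "type2" && !(n_receptors > n_ligands)) {
    stop("type2 requires n_receptors > n_ligands", call. = FALSE)
  }
  if (regime == "type3" && (n_ligands < 3 || n_receptors < 3)) {
    stop("type3 requires at least 3 ligands and 3 receptors", call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  cells <- sprintf("c%03d", seq_len(n_cells))
  grid <- expand.grid(col = seq_len(side), row = seq_len(side))
  coords <- data.frame(cell = cells,
                       x = (grid$col - 1) * params$h,
                       y = (grid$row - 1) * params$h,
                       stringsAsFactors = FALSE)
  ligands <- sprintf("L%d", seq_len(n_ligands))
  receptors <- sprintf("R%d", seq_len(n_receptors))

  secretes <- matrix(stats::runif(n_cells * n_ligands) < 0.5,
                     n_cells, n_ligands, dimnames = list(cells, ligands))
  for (l in which(colSums(secretes) == 0)) {
    secretes[sample.int(n_cells, 1), l] <- TRUE
  }
  displays <- matrix(stats::runif(n_cells * n_receptors) < 0.5,
                     n_cells, n_receptors, dimnames = list(cells, receptors))
  for (r in which(colSums(displays) == 0)) {
    displays[sample.int(n_cells, 1), r] <- TRUE
  }

  log_unif <- function(n) 10^stats::runif(n, log10(0.1), log10(1))
  production <- matrix(0, n_cells, n_ligands, dimnames = list(cells, ligands))
  production[secretes] <- log_unif(sum(secretes)) * params$k_prod
  receptor_total <- matrix(0, n_cells, n_receptors,
                           dimnames = list(cells, receptors))
  receptor_total[displays] <- log_unif(sum(displays))

  conn <- switch(regime,
    type1 = wire_many_to_few(ligands, receptors),
    type2 = {
      flipped <- wire_many_to_few(receptors, ligands)
      data.frame(ligand = flipped$receptor, receptor = flipped$ligand,
                 stringsAsFactors = FALSE)
    },
    type3 = wire_dense_bipartite(ligands, receptors, min_density = 0.4))
  conn <- conn[order(conn$ligand, conn$receptor), , drop = FALSE]
  rownames(conn) <- NULL

  structure(list(regime = regime, cells = coords, ligands = ligands,
                 receptors = receptors, connectivity = conn,
                 production = production, receptor_total = receptor_total,
                 seed = seed, h = params$h),
            class = "scenario")
}

# each of the "many" side binds one uniformly drawn partner from the "few"
# side, plus extra links with probability 0.3; every partner gets >= 1 link
wire_many_to_few <- function(many, few, p_extra = 0.3) {
  pick <- few[sample.int(length(few), length(many), replace = TRUE)]
  extra <- matrix(stats::runif(length(many) * length(few)) < p_extra,
                  length(many), length(few))
  links <- matrix(FALSE, length(many), length(few),
                  dimnames = list(many, few))
  links[cbind(seq_along(many), match(pick, few))] <- TRUE
  links <- links | extra
  for (j in which(colSums(links) == 0)) {
    links[sample.int(length(many), 1), j] <- TRUE
  }
  idx <- which(links, arr.ind = TRUE)
  data.frame(ligand = many[idx[, 1]], receptor = few[idx[, 2]],
             stringsAsFactors = FALSE)
}

wire_dense_bipartite <- function(ligands, receptors, min_density = 0.4,
                                 max_tries = 100) {
  for (k in seq_len(max_tries)) {
    links <- matrix(stats::runif(length(ligands) * length(receptors)) < 0.5,
                    length(ligands), length(receptors),
                    dimnames = list(ligands, receptors))
    dens <- mean(links)
    if (dens >= min_density && all(rowSums(links) > 0) &&
        all(colSums(links) > 0)) {
      idx <- which(links, arr.ind = TRUE)
      return(data.frame(ligand = ligands[idx[, 1]],
                        receptor = receptors[idx[, 2]],
                        stringsAsFactors = FALSE))
    }
  }
  stop("could not draw a dense connected bipartite graph", call. = FALSE)
}

#' @exportS3Method base::print
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> %d cells, %d ligands, %d receptors, %d links (seed %d)\n",
              x$regime, nrow(x$cells), length(x$ligands), length(x$receptors),
              nrow(x$connectivity), x$seed))
  invisible(x)
}

#' Steady state of the reaction-diffusion model
#'
#' For each (source cell i, ligand L) with positive production, solves the
#' steady state of
#' `du/dt = D lap(u) - k_deg u - sum_R k_on R_free(x, R) u + p_iL delta_i`
#' on the cell lattice (5-point Laplacian, no-flux boundaries), where the sum
#' runs over receptors R bound by L. The free receptor field is shared across
#' all ligand fields and satisfies, at every cell,
#' `R_free = R_tot / (1 + sum_L (k_on/k_off) u_total_L)` with `u_total_L` the
#' superposition over sources; the coupled system is resolved by damped
#' (factor 0.5) fixed-point iteration on `R_free` with sparse linear solves
#' inside, to relative change below `tol`. After convergence the fields are
#' recomputed once at the final `R_free` so fields and receptors are mutually
#' consistent.
#'
#' @param scenario A [make_scenario()] object.
#' @param params A [kinetic_params()].
#' @return A list of class `sim_result`: `fields` (per-ligand matrix, sources
#'   in rows, lattice sites in columns), `u_total` (per-ligand totals),
#'   `R_free` (cells x receptors), `iterations`, `mass_balance` (per-ligand
#'   relative residual of production = degradation + binding flux).
#' @export
simulate_steady_state <- function(scenario, params = kinetic_params()) {
  stopifnot(inherits(scenario, "scenario"))
  cells <- scenario$cells$cell
  n <- length(cells)
  lap <- lattice_laplacian(scenario$cells, params$h)   # sparse, sums to zero rows
  kappa <- params$k_on / params$k_off

  binds <- split(scenario$connectivity$receptor, scenario$connectivity$ligand)
  R_free <- scenario$receptor_total

  solve_fields <- function(R_free) {
    lapply(stats::setNames(scenario$ligands, scenario$ligands), function(L) {
      rec <- binds[[L]]
      sink <- if (is.null(rec)) rep(0, n) else
        params$k_on * rowSums(R_free[, rec, drop = FALSE])
      p <- scenario$production[, L]
      U <- matrix(0, n, n, dimnames = list(cells, cells))
      src <- which(p > 0)
      if (length(src) > 0) {
        A <- -params$D * lap + Matrix::Diagonal(n, params$k_deg + sink)
        rhs <- matrix(0, n, length(src))
        rhs[cbind(src, seq_along(src))] <- p[src]
        U[src, ] <- t(as.matrix(Matrix::solve(A, rhs)))
      }
      U
    })
  }

  iterations <- 0L
  repeat {
    fields <- solve_fields(R_free)
    u_total <- matrix(vapply(fields, colSums, numeric(n)), nrow = n,
                      dimnames = list(cells, names(fields)))  # sites x ligands
    occ <- matrix(0, n, length(scenario$receptors),
                  dimnames = list(cells, scenario$receptors))
    for (R in scenario$receptors) {
      lig <- scenario$connectivity$ligand[scenario$connectivity$receptor == R]
      if (length(lig) > 0) {
        occ[, R] <- kappa * rowSums(u_total[, lig, drop = FALSE])
      }
    }
    R_new <- scenario$receptor_total / (1 + occ)
    delta <- max(abs(R_new - R_free) / pmax(abs(R_free), 1e-300))
    R_free <- 0.5 * R_free + 0.5 * R_new
    iterations <- iterations + 1L
    if (delta < params$tol) break
    if (iterations >= params$max_outer) {
      stop(sprintf("free-receptor fixed point did not converge in %d iterations (residual %.3g)",
                   params$max_outer, delta), call. = FALSE)
    }
  }
  fields <- solve_fields(R_free)
  u_total <- matrix(vapply(fields, colSums, numeric(n)), nrow = n,
                    dimnames = list(cells, names(fields)))

  mass_balance <- vapply(scenario$ligands, function(L) {
    prod_total <- sum(scenario$production[, L])
    if (prod_total == 0) return(0)
    rec <- binds[[L]]
    sink <- if (is.null(rec)) rep(0, n) else
      params$k_on * rowSums(R_free[, rec, drop = FALSE])
    out_total <- sum((params$k_deg + sink) * u_total[, L])
    abs(prod_total - out_total) / prod_total
  }, numeric(1))

  structure(list(fields = fields, u_total = u_total, R_free = R_free,
                 iterations = iterations, mass_balance = mass_balance),
            class = "sim_result")
}

# graph Laplacian of the 4-neighbor lattice, scaled by 1/h^2; no-flux
# boundaries arise from simply omitting outside neighbors
lattice_laplacian <- function(coords, h) {
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  adj <- abs(d2 - h) < 1e-9 * max(h, 1)
  A <- Matrix::Matrix(adj * 1, sparse = TRUE)
  (A - Matrix::Diagonal(n, Matrix::rowSums(A))) / h^2
}

#' Extract the ground-truth communication field
#'
#' The communication amount from source i to target j through the pair
#' (L, R) is the equilibrium bound complex at j attributable to i's ligand:
#' `G(i,j,L,R) = (k_on/k_off) * u_iL(x_j) * R_free(j, R)` for pairs in the
#' connectivity, 0 elsewhere. Emitted on the full ordered (source, target)
#' grid, including the autocrine diagonal; downstream evaluation may subset.
#'
#' @param sim A [simulate_steady_state()] result.
#' @param scenario The matching scenario.
#' @param params The matching [kinetic_params()].
#' @return Data frame `source,target,ligand,receptor,amount`.
#' @export
extract_ground_truth <- function(sim, scenario, params = kinetic_params()) {
  stopifnot(inherits(sim, "sim_result"), inherits(scenario, "scenario"))
  kappa <- params$k_on / params$k_off
  cells <- scenario$cells$cell
  n <- length(cells)
  parts <- lapply(seq_len(nrow(scenario$connectivity)), function(k) {
    L <- scenario$connectivity$ligand[k]
    R <- scenario$connectivity$receptor[k]
    G <- kappa * sim$fields[[L]] *
      matrix(sim$R_free[, R], n, n, byrow = TRUE)
    data.frame(source = rep(cells, times = n),
               target = rep(cells, each = n),
               ligand = L, receptor = R,
               amount = as.vector(G),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$ligand, out$receptor, out$source, out$target), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a scenario into inference inputs
#'
#' Ligand "expression" is the production rate, receptor "expression" the
#' total receptor amount; coordinates are the lattice positions; the prior
#' database is the scenario connectivity with affinity 1 and prior support on
#' every pair.
#'
#' @param scenario A [make_scenario()] object.
#' @return A list with `expression` (matrix), `coords` (data frame), `db`
#'   (an [lr_database()]).
#' @export
scenario_to_inputs <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  expr <- cbind(scenario$production, scenario$receptor_total)
  db <- lr_database(data.frame(ligand = scenario$connectivity$ligand,
                               receptor = scenario$connectivity$receptor,
                               affinity = 1, prior_confident = TRUE,
                               stringsAsFactors = FALSE))
  list(expression = expr, coords = scenario$cells, db = db)
}
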