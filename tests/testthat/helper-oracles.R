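# Independent oracles and fixture generators used across the suite.
# Everything here is deliberately naive (brute force, closed forms) and
# shares no code with the package internals it checks.

# random bounded-circulation instance: <= n_max nodes, <= m_max edges,
# integer bounds <= u_max, integer costs <= c_max, zero balances
rand_circulation <- function(n_max = 8, m_max = 16, u_max = 5, c_max = 10) {
  n <- sample(2:n_max, 1)
  m <- sample(1:m_max, 1)
  cells <- LETTERS[seq_len(n)]
  src <- sample(cells, m, replace = TRUE)
  tgt <- sample(cells, m, replace = TRUE)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  if (length(src) == 0) return(NULL)
  dup <- !duplicated(paste(src, tgt))
  src <- src[dup]; tgt <- tgt[dup]
  m <- length(src)
  u <- sample(0:u_max, m, replace = TRUE)
  l <- pmin(sample(0:u_max, m, replace = TRUE), u)
  flow_graph(data.frame(source = src, target = tgt, lower = l, upper = u,
                        cost = sample(0:c_max, m, replace = TRUE),
                        stringsAsFactors = FALSE),
             nodes = data.frame(cell = cells, balance = 0,
                                stringsAsFactors = FALSE))
}

# exhaustive enumeration over integer flows (instances with few edges only)
enum_circulation <- function(graph) {
  e <- graph$edges
  m <- nrow(e)
  stopifnot(m <= 6)
  grids <- lapply(seq_len(m), function(k) seq(e$lower[k], e$upper[k]))
  combos <- as.matrix(expand.grid(grids))
  cells <- graph$nodes$cell
  best <- Inf
  feasible <- FALSE
  for (r in seq_len(nrow(combos))) {
    f <- combos[r, ]
    ok <- TRUE
    for (v in cells) {
      net <- sum(f[e$source == v]) - sum(f[e$target == v])
      b <- graph$nodes$balance[graph$nodes$cell == v]
      if (net != b) { ok <- FALSE; break }
    }
    if (ok) {
      feasible <- TRUE
      best <- min(best, sum(f * e$cost))
    }
  }
  list(feasible = feasible, objective = if (feasible) best else NA_real_)
}

# Spearman via explicitly computed mean ranks and the Pearson formula
spearman_manual <- function(x, y) {
  mean_ranks <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- mean_ranks(x); ry <- mean_ranks(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force relay join: double loop over all row pairs
brute_relays <- function(table, min_flow = 0, link_table = NULL) {
  rows <- list()
  for (a in seq_len(nrow(table))) {
    for (b in seq_len(nrow(table))) {
      r1 <- table[a, ]; r2 <- table[b, ]
      if (r1$target != r2$source) next
      if (r1$source == r1$target || r2$source == r2$target) next
      if (r1$flow < min_flow || r2$flow < min_flow) next
      if (r1$flow <= 0 || r2$flow <= 0) next
      if (!is.null(link_table)) {
        lig <- link_table[[r1$receptor]]
        if (is.null(lig) || !(r2$ligand %in% lig)) next
      }
      rows[[length(rows) + 1]] <- data.frame(
        source = r1$source, ligand1 = r1$ligand, receptor1 = r1$receptor,
        via = r1$target, ligand2 = r2$ligand, receptor2 = r2$receptor,
        target = r2$target, flow1 = r1$flow, flow2 = r2$flow,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$source, out$ligand1, out$receptor1, out$via, out$ligand2,
            out$receptor2, out$target), , drop = FALSE]
}

# random ligand-flow table over a small cell/gene universe
rand_flow_table <- function(n_rows = 50, n_cells = 6) {
  cells <- sprintf("c%d", seq_len(n_cells))
  src <- sample(cells, n_rows, replace = TRUE)
  tgt <- sample(cells, n_rows, replace = TRUE)
  keep <- src != tgt
  data.frame(source = src[keep], target = tgt[keep],
             ligand = sample(sprintf("L%d", 1:4), sum(keep), replace = TRUE),
             receptor = sample(sprintf("R%d", 1:3), sum(keep), replace = TRUE),
             flow = round(stats::runif(sum(keep), 0, 1), 3),
             stringsAsFactors = FALSE)
}

# small deterministic expression/coords/database fixture: 3 cells in a row,
# 2 ligands, 2 receptors
toy_inputs <- function() {
  expr <- rbind(
    c1 = c(La = 2, Lb = 0, Ra = 0.5, Rb = 0),
    c2 = c(La = 1, Lb = 3, Ra = 2.0, Rb = 1),
    c3 = c(La = 0, Lb = 4, Ra = 1.0, Rb = 2))
  coords <- data.frame(cell = c("c1", "c2", "c3"),
                       x = c(0, 1, 2), y = c(0, 0, 0),
                       stringsAsFactors = FALSE)
  db <- lr_database(data.frame(
    ligand = c("La", "Lb", "Lb"),
    receptor = c("Ra", "Ra", "Rb"),
    affinity = c(1.0, 0.5, 0.8),
    prior_confident = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE))
  list(expr = expr, coords = coords, db = db)
}

# 1-site scenario built by hand (bypasses the lattice generator) for
# closed-form equilibrium checks
single_site_scenario <- function(production, receptor_total,
                                 connectivity = data.frame(ligand = "L1",
                                                           receptor = "R1")) {
  ligands <- sort(unique(c(colnames(production), connectivity$ligand)))
  receptors <- sort(unique(c(colnames(receptor_total), connectivity$receptor)))
  structure(list(
    regime = "type3",
    cells = data.frame(cell = "c001", x = 0, y = 0, stringsAsFactors = FALSE),
    ligands = ligands, receptors = receptors,
    connectivity = connectivity,
    production = production, receptor_total = receptor_total,
    seed = 0L, h = 1), class = "scenario")
}
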