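test_that("pairwise_neighbors is strict at the cutoff and lists both directions", {
  coords <- data.frame(cell = c("a", "b"), x = c(0, 5), y = c(0, 0))
  expect_equal(nrow(pairwise_neighbors(coords, 5)), 0)
  nb <- pairwise_neighbors(data.frame(cell = c("a", "b"), x = c(0, 3), y = 0), 5)
  expect_equal(nb$source, c("a", "b"))
  expect_equal(nb$target, c("b", "a"))
  expect_equal(nb$distance, c(3, 3))
})

test_that("pairwise_neighbors matches a brute-force double loop", {
  set.seed(11)
  coords <- data.frame(cell = sprintf("c%02d", 1:20),
                       x = runif(20), y = runif(20))
  nb <- pairwise_neighbors(coords, 0.3)
  brute <- list()
  for (i in 1:20) for (j in 1:20) {
    if (i == j) next
    d <- sqrt((coords$x[i] - coords$x[j])^2 + (coords$y[i] - coords$y[j])^2)
    if (d < 0.3) brute[[length(brute) + 1]] <-
        data.frame(source = coords$cell[i], target = coords$cell[j],
                   distance = d, stringsAsFactors = FALSE)
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$source, brute$target), ]
  rownames(brute) <- NULL
  expect_equal(nb, brute)
})

test_that("aggregate_affinity is the expression-weighted mean over expressed binders", {
  fix <- toy_inputs()
  # c1 expresses only La (affinity 1.0) above 0 for Ra
  expect_equal(aggregate_affinity("c1", "Ra", fix$expr, fix$db), 1.0)
  # c2 expresses La (E=1, a=1.0) and Lb (E=3, a=0.5) for Ra
  expect_equal(aggregate_affinity("c2", "Ra", fix$expr, fix$db),
               (1 * 1.0 + 3 * 0.5) / 4)
  # no expressed binder -> 0
  expect_equal(aggregate_affinity("c1", "Rb", fix$expr, fix$db), 0)

  # random binder sets match a direct recomputation
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    aff <- runif(k, 0.1, 1)
    db <- lr_database(data.frame(ligand = sprintf("L%d", 1:k), receptor = "R",
                                 affinity = aff))
    e <- round(runif(k, 0, 2), 2)
    expr <- matrix(c(e, 1), 1, k + 1,
                   dimnames = list("c", c(sprintf("L%d", 1:k), "R")))
    on <- e > 0
    expected <- if (any(on)) sum(aff[on] * e[on]) / sum(e[on]) else 0
    expect_equal(aggregate_affinity("c", "R", expr, db, tau = 0), expected)
  }
})

test_that("edge cost is the normalized distance plus affinity penalty", {
  cfg <- flow_config(d_cutoff = 10, lambda_affinity = 1)
  expect_equal(edge_cost(0, 1, cfg), 0)
  expect_equal(edge_cost(5, 0, cfg), 1.5)
  # strictly increasing in d, strictly decreasing in affinity
  d <- seq(0, 9.9, length.out = 25)
  expect_true(all(diff(edge_cost(d, 0.5, cfg)) > 0))
  a <- seq(0, 1, length.out = 25)
  expect_true(all(diff(edge_cost(3, a, cfg)) < 0))
})

test_that("edge bounds follow the min/product combiner and prior rule", {
  expr <- matrix(c(3, 2), 1, 2, dimnames = list("i", c("L", "R")))
  expr <- rbind(i = c(L = 3, R = 0), j = c(L = 0, R = 2))
  db_prior <- lr_database(data.frame(ligand = "L", receptor = "R",
                                     prior_confident = TRUE))
  cfg <- flow_config(d_cutoff = 1, epsilon_lower = 0.05)
  b <- edge_bounds("i", "j", "R", expr, db_prior, cfg)
  expect_equal(unname(b), c(0.05 * 2, 2))

  db_noprior <- lr_database(data.frame(ligand = "L", receptor = "R",
                                       prior_confident = FALSE))
  b2 <- edge_bounds("i", "j", "R", expr, db_noprior, cfg)
  expect_equal(unname(b2), c(0, 2))

  cfg_prod <- flow_config(d_cutoff = 1, bound_combiner = "product")
  b3 <- edge_bounds("i", "j", "R", expr, db_prior, cfg_prod)
  expect_equal(unname(b3[["upper"]]), 6)

  expect_error(edge_bounds("j", "i", "R", expr, db_prior, cfg), "inadmissible")
})

test_that("graph construction equals exhaustive enumeration of gated triples", {
  fix <- toy_inputs()
  cfg <- flow_config(d_cutoff = 1.5, epsilon_lower = 0.05)
  g <- build_flow_graph(fix$expr, fix$coords, fix$db, cfg)

  expected <- list()
  cells <- rownames(fix$expr)
  for (i in cells) for (j in cells) for (R in c("Ra", "Rb")) {
    if (i == j) next
    d <- abs(fix$coords$x[fix$coords$cell == i] -
               fix$coords$x[fix$coords$cell == j])
    if (d >= 1.5) next
    if (fix$expr[j, R] <= 0) next
    b <- binders(fix$db, R)
    e <- fix$expr[i, b$ligand]
    if (!any(e > 0)) next
    expected[[length(expected) + 1]] <- c(i, j, R)
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(g$edges), nrow(expected))
  expect_equal(g$edges$source, expected[order(expected[, 1], expected[, 2],
                                              expected[, 3]), 1])

  # spot-check one edge against scalar operations
  k <- which(g$edges$source == "c1" & g$edges$target == "c2" &
               g$edges$receptor == "Ra")
  expect_equal(g$edges$affinity[k],
               aggregate_affinity("c1", "Ra", fix$expr, fix$db))
  expect_equal(g$edges$cost[k],
               edge_cost(1, g$edges$affinity[k], cfg))
  bk <- edge_bounds("c1", "c2", "Ra", fix$expr, fix$db, cfg)
  expect_equal(g$edges$upper[k], bk[["upper"]])
})

test_that("graph respects distance and binding gates on degenerate inputs", {
  fix <- toy_inputs()
  cfg <- flow_config(d_cutoff = 0.5)
  expect_warning(g <- build_flow_graph(fix$expr, fix$coords, fix$db, cfg),
                 "zero edges")
  expect_equal(nrow(g$edges), 0)

  # receptor expressed in target but no binder expressed in source: no edge
  expr <- rbind(i = c(L = 0, R = 1), j = c(L = 0, R = 2))
  coords <- data.frame(cell = c("i", "j"), x = c(0, 1), y = 0)
  db <- lr_database(data.frame(ligand = "L", receptor = "R"))
  expect_warning(g2 <- build_flow_graph(expr, coords, db,
                                        flow_config(d_cutoff = 2)))
  expect_equal(nrow(g2$edges), 0)

  # cells mismatch errors
  expect_error(build_flow_graph(fix$expr, coords, fix$db,
                                flow_config(d_cutoff = 2)),
               "different cells")
})

test_that("edge sets are monotone in cutoff and threshold, and deterministic", {
  set.seed(21)
  n <- 12
  cells <- sprintf("c%02d", 1:n)
  genes <- c(sprintf("L%d", 1:3), sprintf("R%d", 1:2))
  expr <- matrix(round(runif(n * 5, 0, 2), 2) *
                   (runif(n * 5) < 0.7), n, 5,
                 dimnames = list(cells, genes))
  coords <- data.frame(cell = cells, x = runif(n, 0, 3), y = runif(n, 0, 3))
  db <- lr_database(data.frame(ligand = rep(sprintf("L%d", 1:3), 2),
                               receptor = rep(sprintf("R%d", 1:2), each = 3),
                               affinity = 0.5))
  key <- function(g) paste(g$edges$source, g$edges$target, g$edges$receptor)

  cut_seq <- c(0.8, 1.5, 2.5)
  keys <- lapply(cut_seq, function(dc) {
    suppressWarnings(key(build_flow_graph(expr, coords, db,
                                          flow_config(d_cutoff = dc))))
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))

  tau_keys <- lapply(c(0, 0.5, 1), function(tau) {
    suppressWarnings(key(build_flow_graph(expr, coords, db,
                                          flow_config(d_cutoff = 2,
                                                      expr_threshold = tau))))
  })
  expect_true(all(tau_keys[[2]] %in% tau_keys[[1]]))
  expect_true(all(tau_keys[[3]] %in% tau_keys[[2]]))

  g1 <- suppressWarnings(build_flow_graph(expr, coords, db,
                                          flow_config(d_cutoff = 2)))
  g2 <- suppressWarnings(build_flow_graph(expr, coords, db,
                                          flow_config(d_cutoff = 2)))
  expect_identical(g1$edges, g2$edges)

  # structural invariants on every edge
  cfg <- flow_config(d_cutoff = 2)
  e <- g1$edges
  expect_true(all(e$lower >= 0 & e$lower <= e$upper))
  expect_true(all(e$cost >= 0 & e$cost <= 1 + cfg$lambda_affinity))
  expect_true(all(e$distance < cfg$d_cutoff))
})

test_that("lower bounds are confined to the circulation core", {
  # c3 has no outgoing edge (expresses no ligand), so edges into it can carry
  # no circulation flow and must not carry a lower bound
  expr <- rbind(c1 = c(L = 1, R = 1),
                c2 = c(L = 1, R = 1),
                c3 = c(L = 0, R = 1))
  coords <- data.frame(cell = c("c1", "c2", "c3"), x = c(0, 1, 2), y = 0)
  db <- lr_database(data.frame(ligand = "L", receptor = "R",
                               prior_confident = TRUE))
  g <- build_flow_graph(expr, coords, db, flow_config(d_cutoff = 1.5))
  into_c3 <- g$edges$target == "c3"
  expect_true(any(into_c3))
  expect_true(all(g$edges$lower[into_c3] == 0))
  expect_true(all(g$edges$lower[!into_c3] > 0))
  # and the pruned graph is solvable as-is
  sol <- solve_flow(g)
  expect_true(sol$feasible)
})
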