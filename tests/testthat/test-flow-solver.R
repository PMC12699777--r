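test_that("quantization scales conservatively and reports impossible intervals", {
  g <- flow_graph(data.frame(source = "A", target = "B",
                             lower = 0.05, upper = 2.0, cost = 1))
  q <- quantize_graph(g, quantum = 1000L)
  expect_equal(q$edges$lower, 25)
  expect_equal(q$edges$upper, 1000)

  # conservative rounding can void tight intervals at coarse quanta
  g2 <- flow_graph(data.frame(source = "A", target = "B",
                              lower = 0.6, upper = 0.7, cost = 1))
  expect_error(quantize_graph(g2, quantum = 1L), "raise `quantum`")

  g3 <- flow_graph(data.frame(source = "A", target = "B",
                              lower = 0, upper = 0, cost = 1))
  expect_error(quantize_graph(g3, quantum = 10L), "empty capacity")
})

test_that("lower-bound elimination produces the standard residual problem", {
  # single edge A -> B with l=1, u=2: B carries excess inflow (needs to
  # re-export), A carries a deficit
  g <- flow_graph(data.frame(source = "A", target = "B",
                             lower = 1, upper = 2, cost = 3))
  rp <- transform_lower_bounds(g)
  expect_equal(rp$edges$capacity, 1)
  expect_equal(unname(rp$imbalance[c("A", "B")]), c(-1, 1))
  expect_equal(rp$fixed_cost, 3)
  expect_equal(rp$aux$from, c("..S", "A"))
  expect_equal(rp$aux$to, c("B", "..T"))
  expect_equal(rp$aux$capacity, c(1, 1))

  # zero lower bounds: identity residual, no aux edges
  g2 <- flow_graph(data.frame(source = c("A", "B"), target = c("B", "A"),
                              lower = 0, upper = c(2, 3), cost = 1))
  rp2 <- transform_lower_bounds(g2)
  expect_equal(nrow(rp2$aux), 0)
  expect_equal(rp2$fixed_cost, 0)
  expect_equal(rp2$edges$capacity, c(2, 3))

  expect_error(
    transform_lower_bounds(flow_graph(data.frame(source = "A", target = "B",
                                                 lower = 0, upper = 1.5,
                                                 cost = 1))),
    "integer")
})

test_that("solve handles canonical small circulations", {
  # zero lower bounds, zero balances, positive costs: empty circulation wins
  g <- flow_graph(data.frame(source = c("A", "B"), target = c("B", "A"),
                             lower = 0, upper = 2, cost = c(1, 2)))
  s <- solve_flow(g)
  expect_true(s$feasible)
  expect_equal(s$objective, 0)
  expect_equal(s$flows$flow, c(0, 0))

  # conservation forces equal flows around the 2-cycle; optimum at the bound
  g2 <- flow_graph(data.frame(source = c("A", "B"), target = c("B", "A"),
                              lower = c(1, 0), upper = c(2, 2),
                              cost = c(1, 2)))
  s2 <- solve_flow(g2)
  expect_true(s2$feasible)
  expect_equal(s2$flows$flow, c(1, 1))
  expect_equal(s2$objective, 3)
  expect_equal(s2$fixed_cost + s2$residual_cost, s2$objective)
})

test_that("infeasibility is a reported outcome with per-node shortfalls", {
  # forced lower-bound inflow into a node with no exit
  g <- flow_graph(data.frame(source = "A", target = "B",
                             lower = 1, upper = 2, cost = 1))
  s <- solve_flow(g)
  expect_false(s$feasible)
  expect_s3_class(s$diagnostics, "data.frame")
  expect_setequal(s$diagnostics$cell, c("A", "B"))
  expect_true(all(s$diagnostics$shortfall == 1))
  expect_true(all(is.na(s$flows$flow)))
})

test_that("relax_lower halves bounds until feasible and reports the factor", {
  # cycle capacity 2 cannot carry the lower bound 3; one halving fixes it
  g <- flow_graph(data.frame(source = c("A", "B"), target = c("B", "A"),
                             lower = c(3, 0), upper = c(4, 2), cost = 1))
  expect_false(solve_flow(g)$feasible)
  expect_message(s <- solve_flow(g, relax_lower = TRUE), "factor 0.5")
  expect_true(s$feasible)
  expect_equal(s$epsilon_factor, 0.5)
  expect_equal(s$flows$flow, c(1.5, 1.5))

  # structurally infeasible instances stay infeasible at every factor
  g2 <- flow_graph(data.frame(source = "A", target = "B",
                              lower = 1, upper = 2, cost = 1))
  s2 <- suppressMessages(solve_flow(g2, relax_lower = TRUE))
  expect_false(s2$feasible)
})

test_that("solver agrees with the LP oracle and exhaustive enumeration", {
  set.seed(101)
  graphs <- list()
  while (length(graphs) < 60) {
    g <- rand_circulation()
    if (!is.null(g)) graphs[[length(graphs) + 1]] <- g
  }
  oracles <- lp_oracle_batch(graphs)
  for (k in seq_along(graphs)) {
    s <- solve_flow(graphs[[k]])
    o <- oracles[[k]]
    expect_equal(s$feasible, o$feasible)
    if (s$feasible) {
      expect_lt(abs(s$objective - o$objective),
                1e-6 * max(1, abs(o$objective)))
    }
    if (nrow(graphs[[k]]$edges) <= 6) {
      en <- enum_circulation(graphs[[k]])
      expect_equal(s$feasible, en$feasible)
      if (en$feasible) {
        expect_lt(abs(s$objective - en$objective),
                  1e-5 * max(1, abs(en$objective)))
      }
    }
  }
})

test_that("feasible solutions satisfy conservation and bounds exactly in integer units", {
  set.seed(202)
  checked <- 0
  while (checked < 25) {
    g <- rand_circulation()
    if (is.null(g)) next
    s <- solve_flow(g)
    if (!s$feasible || length(s$flow_int) == 0) next
    checked <- checked + 1
    expect_true(all(s$flow_int >= s$lower_int))
    expect_true(all(s$flow_int <= s$upper_int))
    e <- s$flows
    for (v in g$nodes$cell) {
      net <- sum(s$flow_int[e$source == v]) - sum(s$flow_int[e$target == v])
      expect_identical(net, 0)
    }
    expect_equal(s$objective, s$fixed_cost + s$residual_cost)
  }
})

test_that("raising a single edge cost never decreases the optimal objective", {
  set.seed(303)
  tried <- 0
  while (tried < 10) {
    g <- rand_circulation()
    if (is.null(g)) next
    s <- solve_flow(g)
    if (!s$feasible) next
    tried <- tried + 1
    k <- sample(nrow(g$edges), 1)
    g2 <- g
    g2$edges$cost[k] <- g2$edges$cost[k] + 5
    s2 <- solve_flow(g2)
    expect_true(s2$feasible)
    expect_gte(s2$objective + 1e-9, s$objective)
  }
})

test_that("de-quantized objective converges to the continuous optimum", {
  set.seed(404)
  for (rep in 1:5) {
    n <- 5
    cells <- LETTERS[1:n]
    pairs <- expand.grid(source = cells, target = cells,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[sample(nrow(pairs), 10), ]
    u <- runif(10, 0.5, 2)
    g <- flow_graph(data.frame(source = pairs$source, target = pairs$target,
                               lower = 0.3 * u, upper = u,
                               cost = runif(10, 0.1, 2)),
                    nodes = data.frame(cell = cells, balance = 0))
    o <- lp_oracle(g)
    if (!o$feasible) next
    objs <- vapply(c(1e2, 1e3, 1e4), function(qt) {
      solve_flow(g, quantum = qt)$objective
    }, numeric(1))
    # conservative quantization restricts the feasible set, so the integral
    # optimum can only sit above the continuous one (modulo cost rounding)
    expect_true(all(objs >= o$objective - 1e-6 * max(1, abs(o$objective))))
    errs <- abs(objs - o$objective)
    expect_lt(errs[2], 1e-2 * max(1, abs(o$objective)))
    expect_lt(errs[3], 1e-3 * max(1, abs(o$objective)))
  }
})

test_that("verify mode cross-checks against the oracle without warnings", {
  g <- flow_graph(data.frame(source = c("A", "B", "B", "C"),
                             target = c("B", "C", "A", "A"),
                             lower = c(1, 0, 0, 0), upper = c(3, 3, 3, 3),
                             cost = c(1, 2, 1, 1)))
  expect_no_warning(s <- solve_flow(g, verify = TRUE))
  expect_true(s$feasible)
  expect_true(s$verified$feasible)
})
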