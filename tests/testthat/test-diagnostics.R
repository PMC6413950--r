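test_that("hysteresis is the forward-plus-reverse discrepancy", {
  # printed run values of the benchmark's problematic charged-batch edges
  h <- hysteresis(aggregate_repeats(c(-0.8, -1.6)),
                  aggregate_repeats(c(-2.2, -2.4)))
  expect_equal(h$value, -3.5)
  h2 <- hysteresis(aggregate_repeats(c(1.8, 1.5)),
                   aggregate_repeats(c(-2.0, -1.9)))
  expect_equal(h2$value, -0.3, tolerance = 1e-12)
  # perfect consistency
  expect_equal(hysteresis(fe_value(1.2, 0, "edge_mean"),
                          fe_value(-1.2, 0, "edge_mean"))$value, 0)
  # a missing direction is not-applicable, not zero
  expect_true(is.na(suppressWarnings(hysteresis(fe_value(1, 0, "edge_mean"),
                                                NULL))))
  # quadrature
  expect_equal(hysteresis(fe_value(1, 0.3, "edge_mean"),
                          fe_value(1, 0.4, "edge_mean"))$sigma, 0.5)
})

test_that("cycle enumeration finds exactly the simple cycles, canonically", {
  tri <- simple_network(edge_df(c("A", "B", "C"), c("B", "C", "A"), 1:3),
                        reference = "A", reference_dg = 0)
  cyc <- enumerate_cycles(tri)
  expect_length(cyc, 1)
  expect_identical(cyc[[1]], c("A", "B", "C"))
  # trees have no cycles
  tree <- simple_network(edge_df(c("A", "A", "B"), c("B", "C", "D"), 1:3),
                         reference = "A", reference_dg = 0)
  expect_length(enumerate_cycles(tree), 0)
  expect_error(enumerate_cycles(tri, max_length = 5), "3 or 4")
  # deterministic order
  expect_identical(enumerate_cycles(tri), enumerate_cycles(tri))
})

test_that("the packaged map contains all curated benchmark cycles", {
  topo <- ack1_topology()
  e <- edge_df(topo$edges$source, topo$edges$target, 0, sigma = 0.1)
  net <- perturbation_network(topo$ligands, e, "3", reference_dg = -6.86)
  found <- vapply(enumerate_cycles(net), paste, character(1), collapse = "-")
  for (cy in ack1_reference_cycles()) {
    expect_true(canonical_key(cy) %in% found, label = paste(cy, collapse = "-"))
  }
})

test_that("closures telescope to zero on potential-derived edges and negate on reversal", {
  set.seed(13)
  ids <- c("A", "B", "C", "D")
  truth <- setNames(rnorm(4, -9, 2), ids)
  pairs <- t(combn(ids, 2))
  e <- edge_df(pairs[, 1], pairs[, 2],
               truth[pairs[, 2]] - truth[pairs[, 1]], sigma = 0.1)
  net <- simple_network(e, reference = "A", reference_dg = truth["A"])
  for (cy in enumerate_cycles(net)) {
    expect_equal(cycle_closure(cy, net)$closure$value, 0, tolerance = 1e-12)
  }
  # antisymmetry under traversal reversal
  e2 <- edge_df(c("A", "B", "C"), c("B", "C", "A"), c(1.0, 0.5, 0.2))
  net2 <- simple_network(e2, reference = "A", reference_dg = 0)
  fwd <- cycle_closure(c("A", "B", "C"), net2)$closure$value
  rev <- cycle_closure(c("C", "B", "A"), net2)$closure$value
  expect_equal(fwd, 1.7)
  expect_equal(rev, -fwd)
})

test_that("an injected directed bias appears in the closure", {
  # consistent triangle, then +1 kcal/mol on one directed edge
  e <- edge_df(c("A", "B", "C"), c("B", "C", "A"), c(1.0 + 1.0, 0.5, -1.5))
  net <- simple_network(e, reference = "A", reference_dg = 0)
  expect_equal(cycle_closure(c("A", "B", "C"), net)$closure$value, 1.0)
  # unmeasured hop is a diagnostic error naming the edge
  expect_error(cycle_closure(c("A", "B", "D"), net), "B and D")
})

test_that("direction policies select measured values as documented", {
  e <- edge_df(c("A", "B", "C", "B"), c("B", "C", "A", "A"),
               c(1.0, 0.5, -1.5, -1.4), sigma = 0.1)
  net <- simple_network(e, reference = "A", reference_dg = 0)
  # hop A->B measured both ways: as_measured averages 1.0 and -(-1.4)
  as_m <- cycle_closure(c("A", "B", "C"), net, "as_measured")$closure$value
  expect_equal(as_m, (1.0 + 1.4) / 2 + 0.5 - 1.5)
  fwd <- cycle_closure(c("A", "B", "C"), net, "forward_only")$closure$value
  expect_equal(fwd, 1.0 + 0.5 - 1.5)
  rev <- cycle_closure(c("A", "B", "C"), net, "reverse_only")$closure$value
  expect_equal(rev, 1.4 + 0.5 - 1.5)
})

test_that("hysteresis equals the 2-cycle closure and flags identically", {
  e <- edge_df(c("A", "B"), c("B", "A"), c(1.3, -0.2), sigma = c(0.1, 0.2))
  net <- simple_network(e, reference = "A", reference_dg = 0)
  two <- cycle_closure(c("A", "B"), net)
  ht <- hysteresis_table(net, threshold = 0.8)
  expect_equal(two$closure$value, ht$h[1])
  expect_equal(two$closure$sigma, ht$sigma[1])
  expect_identical(ht$flagged[1], abs(ht$h[1]) >= 0.8)
})

test_that("closures of fitted per-ligand values vanish identically", {
  cfg <- scenario_config(samples_per_state = 0L, seed = 17)
  sc <- generate_scenario(cfg)
  an <- analyze_scenario(sc, n_boot = 1, boot_seed = 1)
  fitted <- setNames(an$dg$dg, an$dg$id)
  e <- an$network$edges
  e$value <- fitted[e$target] - fitted[e$source]
  refit <- an$network
  refit$edges <- e
  cl <- cycle_closure_table(refit)
  expect_lt(max(abs(cl$closure)), 1e-9)
})

test_that("threshold flagging counts and ranks ligands deterministically", {
  # boundary: a closure exactly at the threshold is flagged
  fl <- flag_cycles(data.frame(cycle = c("a-b-c", "b-c-d"),
                               closure = c(0.8, -0.79)), threshold = 0.8)
  expect_equal(fl$n_flagged, 1L)
  expect_true(fl$reports$flagged[1])
  expect_false(fl$reports$flagged[2])
  expect_identical(fl$ranking$id, c("a", "b", "c"))
  # all-zero closures flag nothing
  expect_equal(flag_cycles(rep(0, 5))$n_flagged, 0L)
  expect_error(flag_cycles(rep(0, 5), threshold = 0), "> 0")
  # ties broken by ligand id
  fl2 <- flag_cycles(data.frame(cycle = c("b-c-d", "a-c-d"),
                                closure = c(2, -2)))
  expect_identical(fl2$ranking$id[1:2], c("c", "d"))
  expect_equal(fl2$ranking$score[1:2], c(2L, 2L))
})

test_that("reported benchmark closures reproduce the published flag counts", {
  tab <- ack1_cycle_closures()
  counts <- vapply(c("A", "B", "C", "D", "E"), function(p) {
    flag_cycles(tab$closure[tab$protocol == p], threshold = 0.8)$n_flagged
  }, integer(1))
  expect_identical(unname(counts), c(6L, 1L, 4L, 1L, 1L))
})
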