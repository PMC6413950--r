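test_that("Ki to dG conversion uses RT ln(Ki/C0)", {
  expect_equal(ki_to_dg(1), 0)
  expect_equal(ki_to_dg(1e-5, 300), 0.0019872 * 300 * log(1e-5))
  expect_equal(ki_to_dg(1e-5, 300), -6.86, tolerance = 0.001)
  # monotone in Ki, inverse pair
  ki <- 10^seq(-10, -4, length.out = 7)
  expect_true(all(diff(ki_to_dg(ki)) > 0))
  expect_equal(dg_to_ki(ki_to_dg(ki)), ki)
  expect_error(ki_to_dg(0), "> 0")
  expect_error(ki_to_dg(-1e-6), "> 0")
})

test_that("relative binding free energy subtracts the two legs in quadrature", {
  d <- ddg_from_legs(fe_value(-5, 0.3, "leg"), fe_value(-3, 0.4, "leg"))
  expect_equal(d$value, -2)
  expect_equal(d$sigma, 0.5)
  expect_identical(d$kind, "edge_repeat")
  # identical legs cancel; sigma adds
  d2 <- ddg_from_legs(fe_value(1.3, 0.2, "leg"), fe_value(1.3, 0.2, "leg"))
  expect_equal(d2$value, 0)
  expect_equal(d2$sigma, 0.2 * sqrt(2))
  d3 <- ddg_from_legs(fe_value(-7.2, 0, "leg"), fe_value(-7.2, 0, "leg"))
  expect_equal(d3$value, 0)
  expect_equal(d3$sigma, 0)
  # antisymmetry under leg swap
  for (i in 1:20) {
    a <- fe_value(runif(1, -10, 10), runif(1, 0, 1), "leg")
    b <- fe_value(runif(1, -10, 10), runif(1, 0, 1), "leg")
    expect_equal(ddg_from_legs(a, b)$value, -ddg_from_legs(b, a)$value)
  }
  # identity guard
  expect_error(
    ddg_from_legs(fe_value(1, 0, "leg", edge = "a->b"),
                  fe_value(1, 0, "leg", edge = "a->c")),
    "different edges")
  expect_error(ddg_from_legs(fe_value(1, 0, "edge_mean"), fe_value(1, 0, "leg")),
               "leg")
})

test_that("repeat aggregation is mean +/- standard error", {
  a <- aggregate_repeats(c(1.8, 1.5))
  expect_equal(a$value, 1.65)
  expect_equal(a$sigma, 0.15)
  expect_identical(a$kind, "edge_mean")
  # n = 1 passes the propagated sigma through
  one <- aggregate_repeats(list(fe_value(2.2, 0.35, "edge_repeat")))
  expect_equal(one$value, 2.2)
  expect_equal(one$sigma, 0.35)
  expect_equal(aggregate_repeats(c(2, 2, 2))$sigma, 0)
  expect_error(aggregate_repeats(list()), "at least one")
})

test_that("racemate combination follows the Boltzmann mixture rule", {
  kt <- kT_kcal(300)
  expect_equal(combine_racemate(-1, -1)$value, -1)
  expect_equal(combine_racemate(0, 0)$value, 0)
  # one enantiomer effectively non-binding: value -> min + kT ln 2
  expect_equal(combine_racemate(0, 100)$value, kt * log(2), tolerance = 1e-10)
  expect_equal(combine_racemate(0, 100)$value, 0.413, tolerance = 0.001)
  # no overflow for inputs of hundreds of kT
  expect_equal(combine_racemate(-400, 250)$value, -400 + kt * log(2))
  expect_error(combine_racemate(0, 0, temperature = -5), "positive")
})

test_that("racemate combination is bounded by min and min + kT ln 2", {
  set.seed(42)
  kt <- kT_kcal(300)
  for (i in 1:2000) {
    a <- runif(1, -300, 300)
    b <- runif(1, -300, 300)
    v <- combine_racemate(a, b)$value
    expect_gte(v, min(a, b) - 1e-9)
    expect_lte(v, min(a, b) + kt * log(2) + 1e-9)
  }
})

test_that("network reconstruction anchors, telescopes and matches a brute-force fit", {
  # exact chain ref -> A -> B
  net <- simple_network(edge_df(c("ref", "A"), c("A", "B"), c(1, 2)),
                        reference = "ref", reference_dg = -6.86)
  est <- network_estimate(net)
  expect_equal(est$dg[est$id == "ref"], -6.86)
  expect_equal(est$dg[est$id == "A"], -5.86)
  expect_equal(est$dg[est$id == "B"], -3.86)
  expect_equal(est$sigma[est$id == "ref"], 0)

  # 4-node noisy network vs independent numeric minimiser
  set.seed(7)
  e <- edge_df(c("ref", "ref", "A", "B", "C", "A"),
               c("A", "B", "B", "C", "ref", "C"),
               rnorm(6, c(1, 2, 1, -1.5, -1.5, -0.5), 0.3),
               sigma = runif(6, 0.1, 0.5))
  net <- simple_network(e, reference = "ref", reference_dg = -7)
  est <- network_estimate(net)
  oracle <- wls_oracle(e, "ref", -7)
  for (id in names(oracle)) {
    expect_equal(est$dg[est$id == id], unname(oracle[id]), tolerance = 1e-6)
  }
})

test_that("noiseless cycle-consistent edges reproduce any ground truth exactly", {
  set.seed(11)
  topo <- ack1_topology()
  und <- topo$edges
  ids <- unique(c(und$source, und$target))
  truth <- setNames(runif(length(ids), -13, -6.8), ids)
  truth["3"] <- -6.86
  e <- edge_df(c(und$source, und$target), c(und$target, und$source),
               c(truth[und$target] - truth[und$source],
                 truth[und$source] - truth[und$target]), sigma = 0)
  net <- perturbation_network(ligand_table(ids), e, "3", reference_dg = -6.86)
  est <- network_estimate(net)
  expect_equal(setNames(est$dg, est$id)[ids], truth, tolerance = 1e-8)
})

test_that("duplicating an edge with the weight split in half leaves the fit unchanged", {
  set.seed(3)
  e <- edge_df(c("ref", "A", "ref"), c("A", "B", "B"),
               c(1.1, 2.2, 3.0), sigma = c(0.2, 0.3, 0.4))
  base <- network_estimate(simple_network(e, reference = "ref"))
  # split the first edge into two copies with sigma * sqrt(2) each
  e2 <- rbind(e[1, ], e[1, ], e[-1, ])
  e2$sigma[1:2] <- e$sigma[1] * sqrt(2)
  dup <- network_estimate(simple_network(e2, reference = "ref"))
  expect_equal(setNames(dup$dg, dup$id), setNames(base$dg, base$id),
               tolerance = 1e-10)
})

test_that("ligands with no path to the reference are reported, not dropped", {
  e <- edge_df(c("ref", "X"), c("A", "Y"), c(1, 2))
  net <- perturbation_network(ligand_table(c("ref", "A", "X", "Y")), e, "ref",
                              reference_dg = -6)
  expect_warning(est <- network_estimate(net), "unreachable")
  expect_true(all(c("X", "Y") %in% est$id))
  expect_false(any(est$resolvable[est$id %in% c("X", "Y")]))
  expect_true(all(is.na(est$dg[est$id %in% c("X", "Y")])))
})

test_that("network constructor validates its invariants", {
  expect_error(ligand_table(c("a", "a")), "unique")
  expect_error(ligand_table("r", is_racemate = TRUE), "enantiomer")
  expect_error(
    perturbation_network(ligand_table(c("a", "b")),
                         edge_df("a", "c", 1), "a", reference_dg = 0),
    "undeclared")
  expect_error(
    perturbation_network(ligand_table(c("a", "b")),
                         edge_df("a", "a", 1), "a", reference_dg = 0),
    "self-edges")
  expect_error(
    perturbation_network(ligand_table(c("a", "b")), edge_df("a", "b", 1), "z",
                         reference_dg = 0),
    "reference")
  # charged/neutral mismatch edges are flagged
  lig <- ligand_table(c("n", "c"), charge = c(0L, 1L), ki_molar = c(1e-6, NA))
  net <- perturbation_network(lig, edge_df("n", "c", 1), "n")
  expect_true(net$edges$charge_mismatch[1])
  expect_equal(net$reference_dg, ki_to_dg(1e-6))
})

test_that("enantiomer edges collapse onto the parent antisymmetrically", {
  lig <- rbind(
    ligand_table(c("X", "RR", "SS")),
    ligand_table("P", is_racemate = TRUE, enantiomer_r = "RR",
                 enantiomer_s = "SS"))
  e <- edge_df(c("RR", "SS", "X", "X"), c("X", "X", "RR", "SS"),
               c(1.0, 2.0, -1.0, -2.0), sigma = 0.1)
  net <- perturbation_network(lig, e, "X", reference_dg = 0)
  coll <- collapse_racemates(net)
  expect_setequal(unique(c(coll$edges$source, coll$edges$target)), c("P", "X"))
  fwd <- coll$edges$value[coll$edges$source == "P"]
  rev <- coll$edges$value[coll$edges$target == "P"]
  expect_equal(combine_racemate(1, 2)$value, fwd)
  # measurements into the parent combine to the exact negation here
  expect_equal(rev, -fwd, tolerance = 1e-12)
})
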