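# Shared fixtures: analytic Gaussian two-state systems and tiny networks,
# all built in code.

# Two Gaussian states u1 = x^2/2 (sd 1) and u2 = x^2/(2 s2^2) (sd s2).
# Exact dimensionless free-energy difference: Delta f = -ln(s2).
gaussian_pair <- function(n, seed, s2 = 2) {
  set.seed(seed)
  x <- c(rnorm(n, 0, 1), rnorm(n, 0, s2))
  reduced_potentials(rbind(x^2 / 2, x^2 / (2 * s2^2)), c(n, n))
}

# small directed-edge table helper
edge_df <- function(source, target, value, sigma = 0.1) {
  data.frame(source = as.character(source), target = as.character(target),
             value = value, sigma = sigma, stringsAsFactors = FALSE)
}

simple_network <- function(edges, ids = NULL, reference = "ref",
                           reference_dg = -6.86) {
  if (is.null(ids)) ids <- unique(c(edges$source, edges$target))
  perturbation_network(ligand_table(ids), edges, reference_id = reference,
                       reference_dg = reference_dg)
}

# independent WLS oracle: numeric minimisation of the weighted objective
wls_oracle <- function(edges, reference, reference_dg) {
  ids <- setdiff(unique(c(edges$source, edges$target)), reference)
  obj <- function(theta) {
    dg <- c(setNames(theta, ids), setNames(reference_dg, reference))
    sum((edges$value - (dg[edges$target] - dg[edges$source]))^2 /
          edges$sigma^2)
  }
  fit <- optim(rep(0, length(ids)), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  setNames(fit$par, ids)
}

canonical_key <- function(cycle) {
  paste(fepnet:::canonical_cycle(cycle), collapse = "-")
}
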