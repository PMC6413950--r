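#' ACK1-style two-batch perturbation map
#'
#' The packaged 15-ligand congeneric network: a neutral batch (ligands 2-8)
#' containing the reference ligand 3, a positively charged batch (15, 16,
#' 35, 36, 38, 39, 44, 45) with the racemic ligand 38 (enantiomers 38R and
#' 38S), and the 8-15 link joining the batches (flagged as a charged/neutral
#' mismatch edge; ligand 15 is treated as neutral there). The edge list
#' realises the benchmark cycle structure, including the 45-16-44 triangle
#' and the 38-39-35-36 ring.
#'
#' @return list with `ligands` (see [ligand_table()]) and `edges`
#'   (undirected pairs, columns `source`, `target`)
#' @export
ack1_topology <- function() {
  lig <- rbind(
    ligand_table(c("2", "3", "4", "5", "6", "7", "8"), batch = "batch1",
                 charge = 0L),
    ligand_table(c("15", "16", "35", "36", "39", "44", "45"), batch = "batch2",
                 charge = 1L),
    ligand_table("38", batch = "batch2", charge = 1L, is_racemate = TRUE,
                 enantiomer_r = "38R", enantiomer_s = "38S"),
    ligand_table(c("38R", "38S"), batch = "batch2", charge = 1L))
  lig$ki_molar[lig$id == "3"] <- 1e-5
  edges <- data.frame(
    source = c("3", "2", "5", "3", "2", "3", "3", "4", "7", "3", "4", "3",
               "8", "15", "16", "16", "44", "45", "35", "36", "38", "39"),
    target = c("2", "5", "6", "5", "6", "6", "4", "7", "6", "7", "6", "8",
               "15", "16", "45", "44", "45", "35", "36", "38", "39", "35"),
    stringsAsFactors = FALSE)
  list(ligands = lig, edges = edges)
}

#' Reference cycle set of the ACK1 benchmark
#'
#' The twelve curated cycles reported for the benchmark dataset: ten cycles
#' in batch 1, the 45-16-44 triangle and the 38-39-35-36 ring in batch 2.
#'
#' @return list of character vectors of ligand ids
#' @export
ack1_reference_cycles <- function() {
  lapply(strsplit(c("3-2-5-6", "3-2-5", "2-6-5", "3-5-6", "3-6-2",
                    "3-4-7-6", "3-7-6", "4-6-7", "3-4-7", "3-4-6",
                    "45-16-44", "38-39-35-36"), "-", fixed = TRUE), identity)
}

#' Scenario configuration for the synthetic-data generator
#'
#' The defaults are the study conditions the package is validated under:
#' the 15-ligand two-batch topology, 11 equidistant lambda windows, 2
#' independent repeats per direction, 2000 samples per window, 0.3 kcal/mol
#' repeat-level noise, and an assumed 0.4 kcal/mol experimental
#' uncertainty. Pose and water biases are direction-dependent: they are
#' added to the complex leg of any directed edge whose source (lambda = 0
#' endpoint) ligand is in the corresponding defect set, which is what
#' manufactures hysteresis and non-zero cycle closures.
#'
#' @param topology `"ack1"` (the packaged map) or `"random_connected"`
#' @param n_ligands number of ligands for random topologies
#' @param repeats independent repeats per edge direction
#' @param samples_per_state samples per lambda window; 0 selects the
#'   analytic leg mode in which leg values are the exact Gaussian-state
#'   free energies (no sampling, no estimator noise)
#' @param n_states number of lambda windows
#' @param sigma_repeat repeat-level Gaussian noise on each repeat's
#'   relative free energy, kcal/mol
#' @param pose_bias systematic bias (kcal/mol) on complex legs sourced at
#'   misposed ligands
#' @param water_bias same, for water-defect ligands
#' @param misposed,water_defect character vectors of ligand ids
#' @param enantiomer_gap true binding free-energy difference between the
#'   racemate's enantiomers, kcal/mol
#' @param exp_sigma experimental noise added to the emitted Ki table
#'   (kcal/mol equivalent)
#' @param temperature kelvin
#' @param reference_id reference ligand (anchored at Ki = 10 uM)
#' @param seed integer seed consumed by [generate_scenario()]
#' @return list of class `scenario_config`
#' @export
scenario_config <- function(topology = c("ack1", "random_connected"),
                            n_ligands = 15L, repeats = 2L,
                            samples_per_state = 2000L, n_states = 11L,
                            sigma_repeat = 0.3, pose_bias = 0, water_bias = 0,
                            misposed = c("2", "4", "7", "16", "44"),
                            water_defect = c("6", "7"),
                            enantiomer_gap = 0.5, exp_sigma = 0.4,
                            temperature = 300, reference_id = "3",
                            seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(repeats >= 1L, samples_per_state >= 0L, n_states >= 2L,
            sigma_repeat >= 0, pose_bias >= 0, water_bias >= 0,
            exp_sigma >= 0, temperature > 0)
  structure(as.list(environment()), class = "scenario_config")
}

#' Protocol-style scenario presets
#'
#' Maps the five set-up protocols of the benchmark narrative onto generator
#' knobs: A = misposed ligands and missing binding-site water (both biases
#' on), B = poses corrected (water bias only), C = water corrected (pose
#' bias only), D = both corrected (no bias), E = A with ten-fold sampling.
#'
#' @param protocol one of "A".."E"
#' @param pose_bias,water_bias bias magnitudes used when active, kcal/mol
#' @param ... further arguments to [scenario_config()]
#' @return `scenario_config`
#' @export
protocol_scenario <- function(protocol = c("A", "B", "C", "D", "E"),
                              pose_bias = 2.0, water_bias = 1.0, ...) {
  protocol <- match.arg(protocol)
  args <- switch(protocol,
    A = list(pose_bias = pose_bias, water_bias = water_bias),
    B = list(pose_bias = 0, water_bias = water_bias),
    C = list(pose_bias = pose_bias, water_bias = 0),
    D = list(pose_bias = 0, water_bias = 0),
    E = list(pose_bias = pose_bias, water_bias = water_bias))
  extra <- list(...)
  if (protocol == "E" && is.null(extra$samples_per_state)) {
    args$samples_per_state <- 20000L
  }
  cfg <- do.call(scenario_config, c(args, extra))
  cfg$protocol <- protocol
  cfg
}

#' Draw a ground truth for a scenario
#'
#' True binding free energies are uniform over [-13, -6.8] kcal/mol (the
#' Ki span 0.2 nM to 10 uM at 300 K); the reference ligand is pinned at
#' Ki = 10 uM exactly. The racemate parent's effective value is defined as
#' the value the Boltzmann edge combination recovers in the noiseless
#' limit, kT ln[ (exp(dG_R/kT) + exp(dG_S/kT)) / 2 ].
#'
#' @param config `scenario_config`
#' @param ligands ligand table (defaults to the configured topology's)
#' @return list of class `ground_truth`: `dg` (named vector incl.
#'   enantiomers and the effective parent value), `ki` (back-computed,
#'   mol/L), `misposed`, `water_defect`, `racemates`
#' @export
generate_ground_truth <- function(config, ligands = NULL) {
  if (is.null(ligands)) ligands <- scenario_ligands(config)
  kt <- kT_kcal(config$temperature)
  sub <- c(ligands$enantiomer_r, ligands$enantiomer_s)
  sub <- sub[!is.na(sub)]
  main <- setdiff(ligands$id, sub)
  dg <- setNames(runif(length(main), -13, -6.8), main)
  dg[config$reference_id] <- ki_to_dg(1e-5, config$temperature)
  for (p in ligands$id[ligands$is_racemate]) {
    r <- ligands$enantiomer_r[ligands$id == p]
    s <- ligands$enantiomer_s[ligands$id == p]
    dg[r] <- dg[p]
    dg[s] <- dg[p] + config$enantiomer_gap
    dg[p] <- kt * (logsumexp(dg[c(r, s)] / kt) - log(2))
  }
  structure(
    list(dg = dg, ki = dg_to_ki(dg[main], config$temperature),
         misposed = intersect(config$misposed, ligands$id),
         water_defect = intersect(config$water_defect, ligands$id),
         racemates = ligands$id[ligands$is_racemate]),
    class = "ground_truth")
}

scenario_ligands <- function(config) {
  if (config$topology == "ack1") return(ack1_topology()$ligands)
  ids <- as.character(seq_len(config$n_ligands))
  ligand_table(ids, batch = "batch1", charge = 0L)
}

scenario_edges <- function(config) {
  if (config$topology == "ack1") return(ack1_topology()$edges)
  ids <- as.character(seq_len(config$n_ligands))
  # random connected map: a spanning chain plus extra chords
  src <- ids[-length(ids)]; tgt <- ids[-1]
  extra <- max(0L, config$n_ligands - 3L)
  chords <- unique(t(replicate(extra, sort(sample(ids, 2L)))))
  e <- rbind(data.frame(source = src, target = tgt, stringsAsFactors = FALSE),
             data.frame(source = chords[, 1], target = chords[, 2],
                        stringsAsFactors = FALSE))
  e[e$source != e$target, , drop = FALSE]
}

#' Simulate one alchemical leg with exactly solvable Gaussian states
#'
#' Builds K one-dimensional Gaussian lambda states \eqn{u_k(x) = (x -
#' \mu_k)^2 / (2\sigma_k^2) + c_k} with means and widths interpolated
#' along the schedule and offsets chosen so the analytic dimensionless
#' free energy of state k is exactly \eqn{\lambda_k \, \Delta f}, i.e. the
#' end-to-end free energy equals `target_dg` by construction. Samples are
#' drawn i.i.d. from each state and the exact reduced-potential matrix is
#' returned.
#'
#' @param target_dg end-to-end leg free energy in kcal/mol
#' @param n_states number of lambda windows (>= 2)
#' @param samples_per_state samples drawn from every state (>= 1)
#' @param temperature kelvin
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used)
#' @return [reduced_potentials()] with attribute `analytic_f`, the exact
#'   dimensionless free energy of every state
#' @export
simulate_leg <- function(target_dg, n_states = 11L, samples_per_state = 2000L,
                         temperature = 300, seed = NULL) {
  if (samples_per_state < 1L) stop("`samples_per_state` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  kt <- kT_kcal(temperature)
  df <- target_dg / kt
  lam <- seq(0, 1, length.out = n_states)
  mu <- lam                      # unit displacement across the schedule
  sg <- 1 + 0.6 * lam            # widths 1.0 -> 1.6
  cc <- lam * df + log(sg * sqrt(2 * pi))   # f_k = c_k - ln(sigma_k sqrt(2 pi))
  x <- unlist(lapply(seq_len(n_states), function(k)
    rnorm(samples_per_state, mu[k], sg[k])))
  u <- outer(seq_len(n_states), seq_along(x), function(k, n)
    (x[n] - mu[k])^2 / (2 * sg[k]^2) + cc[k])
  out <- reduced_potentials(u, rep(samples_per_state, n_states), lam)
  attr(out, "analytic_f") <- lam * df
  out
}

#' Generate a complete synthetic scenario
#'
#' Emits, for every directed edge and repeat, a complex and a free leg
#' whose true leg free energies satisfy the thermodynamic identity
#' ddG = dG(complex) - dG(free) for the true relative binding free energy.
#' Repeat-level noise N(0, sigma_repeat^2) perturbs each repeat's complex
#' leg, and the configured pose/water biases are added to complex legs of
#' directed edges sourced at defect ligands. Edges of the racemate parent
#' are emitted per enantiomer. The experimental table carries lognormal Ki
#' noise equivalent to `exp_sigma` kcal/mol on every ligand except the
#' reference, whose Ki is an assumed (fixed) value.
#'
#' @param config `scenario_config`
#' @return object of class `fepnet_scenario`: list with `config`,
#'   `ground_truth`, `ligands`, `legs` (data.frame of leg metadata and
#'   target values, with a parallel list of [reduced_potentials()] in
#'   `u_matrices` unless `samples_per_state = 0`), `experimental`
#'   (data.frame `ligand_id`, `ki_molar`, `dg`)
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  ligands <- scenario_ligands(config)
  und <- scenario_edges(config)
  gt <- generate_ground_truth(config, ligands)

  # replace racemate parents by their enantiomers in the simulated edges
  sim <- und
  for (p in gt$racemates) {
    r <- ligands$enantiomer_r[ligands$id == p]
    s <- ligands$enantiomer_s[ligands$id == p]
    hit <- sim$source == p | sim$target == p
    dup <- sim[hit, , drop = FALSE]
    for (col in c("source", "target")) {
      sim[[col]][sim[[col]] == p] <- r
      dup[[col]][dup[[col]] == p] <- s
    }
    sim <- rbind(sim, dup)
  }

  bias_of <- function(id) {
    # enantiomers inherit the parent's defect status
    parent <- ligands$id[match(id, ligands$enantiomer_r)]
    parent2 <- ligands$id[match(id, ligands$enantiomer_s)]
    base <- if (!is.na(parent)) parent else if (!is.na(parent2)) parent2 else id
    config$pose_bias * (base %in% gt$misposed) +
      config$water_bias * (base %in% gt$water_defect)
  }

  legs <- list()
  for (i in seq_len(nrow(sim))) {
    for (dir in 1:2) {
      s <- if (dir == 1) sim$source[i] else sim$target[i]
      t <- if (dir == 1) sim$target[i] else sim$source[i]
      ddg_true <- gt$dg[t] - gt$dg[s]
      base_free <- runif(1, -1, 1)
      for (r in seq_len(config$repeats)) {
        eps <- rnorm(1, 0, config$sigma_repeat)
        legs[[length(legs) + 1L]] <- data.frame(
          source = s, target = t, repeat_id = r,
          environment = c("free", "complex"),
          target_value = c(base_free,
                           base_free + ddg_true + bias_of(s) + eps),
          stringsAsFactors = FALSE)
      }
    }
  }
  legs <- do.call(rbind, legs)
  legs$leg_id <- paste(legs$source, legs$target, legs$environment,
                       legs$repeat_id, sep = "|")

  u_matrices <- NULL
  if (config$samples_per_state > 0L) {
    u_matrices <- lapply(legs$target_value, simulate_leg,
                         n_states = config$n_states,
                         samples_per_state = config$samples_per_state,
                         temperature = config$temperature)
    names(u_matrices) <- legs$leg_id
  }

  sub <- c(ligands$enantiomer_r, ligands$enantiomer_s)
  main <- setdiff(ligands$id, sub[!is.na(sub)])
  dg_exp <- gt$dg[main] + rnorm(length(main), 0, config$exp_sigma)
  dg_exp[config$reference_id] <- ki_to_dg(1e-5, config$temperature)
  experimental <- data.frame(
    ligand_id = main,
    ki_molar = dg_to_ki(dg_exp, config$temperature),
    dg = unname(dg_exp), stringsAsFactors = FALSE)
  rownames(experimental) <- NULL

  structure(
    list(config = config, ground_truth = gt, ligands = ligands,
         legs = legs, u_matrices = u_matrices, experimental = experimental),
    class = "fepnet_scenario")
}

#' @export
print.fepnet_scenario <- function(x, ...) {
  cat(sprintf(
    "<fepnet_scenario %s> %d ligands, %d legs, %s\n",
    x$config$topology, nrow(x$ligands), nrow(x$legs),
    if (is.null(x$u_matrices)) "analytic legs"
    else sprintf("%d samples/state", x$config$samples_per_state)))
  invisible(x)
}
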