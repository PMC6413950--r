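#' Estimate per-leg free energies for a scenario
#'
#' Runs MBAR on every leg's reduced-potential matrix and converts the
#' end-state difference to kcal/mol. In analytic mode (scenario generated
#' with `samples_per_state = 0`) the exact leg free energies are passed
#' through with zero sigma.
#'
#' @param scenario `fepnet_scenario`
#' @param ... passed to [mbar()] via [leg_free_energy()]
#' @return data.frame: `leg_id`, `source`, `target`, `repeat_id`,
#'   `environment`, `value`, `sigma`, `converged`
#' @export
estimate_legs <- function(scenario, ...) {
  stopifnot(inherits(scenario, "fepnet_scenario"))
  legs <- scenario$legs
  out <- legs[, c("leg_id", "source", "target", "repeat_id", "environment")]
  if (is.null(scenario$u_matrices)) {
    out$value <- legs$target_value
    out$sigma <- 0
    out$converged <- TRUE
  } else {
    est <- lapply(scenario$u_matrices[legs$leg_id], leg_free_energy,
                  temperature = scenario$config$temperature, ...)
    out$value <- vapply(est, function(e) e$value, numeric(1))
    out$sigma <- vapply(est, function(e) e$sigma, numeric(1))
    out$converged <- vapply(est, function(e) isTRUE(attr(e, "converged")),
                            logical(1))
  }
  rownames(out) <- NULL
  out
}

#' Assemble directed edge values from leg estimates
#'
#' Pairs the complex and free leg of every (edge, repeat), applies the
#' relative-binding identity ddG = dG(complex) - dG(free), then aggregates
#' repeats into one mean +/- standard-error value per directed edge.
#'
#' @param leg_estimates data.frame from [estimate_legs()] or
#'   [read_edge_estimates()]
#' @return data.frame: `source`, `target`, `value`, `sigma`, `n_repeats`
#' @export
assemble_edges <- function(leg_estimates) {
  need <- c("source", "target", "repeat_id", "environment", "value", "sigma")
  stopifnot(all(need %in% names(leg_estimates)))
  key_rep <- paste(leg_estimates$source, leg_estimates$target,
                   leg_estimates$repeat_id, sep = "|")
  reps <- lapply(split(seq_len(nrow(leg_estimates)), key_rep), function(ix) {
    le <- leg_estimates[ix, ]
    ic <- which(le$environment == "complex")
    if_ <- which(le$environment == "free")
    if (length(ic) != 1L || length(if_) != 1L) {
      stop("each (edge, repeat) needs exactly one complex and one free leg: ",
           paste(unique(paste(le$source, le$target)), collapse = " "))
    }
    edge <- paste0(le$source[1], "->", le$target[1])
    ddg <- ddg_from_legs(
      fe_value(le$value[ic], le$sigma[ic], "leg", edge = edge,
               repeat_id = le$repeat_id[1]),
      fe_value(le$value[if_], le$sigma[if_], "leg", edge = edge,
               repeat_id = le$repeat_id[1]))
    data.frame(source = le$source[1], target = le$target[1],
               value = ddg$value, sigma = ddg$sigma, stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, reps)
  key_edge <- paste(reps$source, reps$target, sep = "|")
  rows <- lapply(split(seq_len(nrow(reps)), key_edge), function(ix) {
    agg <- aggregate_repeats(lapply(ix, function(i)
      fe_value(reps$value[i], reps$sigma[i], "edge_repeat")))
    data.frame(source = reps$source[ix[1]], target = reps$target[ix[1]],
               value = agg$value, sigma = agg$sigma,
               n_repeats = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$source, out$target), , drop = FALSE]
}

#' Build the perturbation network of a scenario
#'
#' @param scenario `fepnet_scenario`
#' @param edges directed edge table from [assemble_edges()]
#' @return `fepnet_network` with racemate edges collapsed
#' @export
scenario_network <- function(scenario, edges) {
  net <- perturbation_network(scenario$ligands, edges,
                              reference_id = scenario$config$reference_id,
                              temperature = scenario$config$temperature)
  collapse_racemates(net)
}

#' End-to-end analysis of a synthetic scenario
#'
#' simulate -> (MBAR) -> edge assembly -> racemate collapse -> network
#' reconstruction -> diagnostics -> benchmark metrics, in one call.
#'
#' @param scenario `fepnet_scenario` from [generate_scenario()]
#' @param threshold cycle-closure flagging threshold, kcal/mol
#' @param cycles explicit cycle list for the diagnostics (default: all
#'   simple cycles up to length 4 plus the 2-cycles)
#' @param n_boot bootstrap draws for the metrics report
#' @param boot_seed seed for the metrics bootstrap
#' @param sigma_floor passed to [network_estimate()]
#' @return list of class `fepnet_analysis`: `legs`, `edges`, `network`,
#'   `dg` (per-ligand reconstruction), `hysteresis`, `closures`, `flags`,
#'   `metrics`, `scenario`
#' @export
analyze_scenario <- function(scenario, threshold = 0.8, cycles = NULL,
                             n_boot = 1000L, boot_seed = NULL,
                             sigma_floor = 1e-6) {
  legs <- estimate_legs(scenario)
  edges <- assemble_edges(legs)
  net <- scenario_network(scenario, edges)
  dg <- network_estimate(net, sigma_floor = sigma_floor)
  ht <- hysteresis_table(net, threshold = threshold)
  cl <- cycle_closure_table(net, cycles = cycles)
  flags <- flag_cycles(cl, threshold = threshold)
  pred <- setNames(dg$dg, dg$id)
  pred_sigma <- setNames(dg$sigma, dg$id)
  expv <- setNames(scenario$experimental$dg, scenario$experimental$ligand_id)
  metrics <- bootstrap_metrics(pred[!is.na(pred)],
                               pred_sigma[!is.na(pred)], expv,
                               exp_sigma = scenario$config$exp_sigma,
                               n_boot = n_boot, seed = boot_seed,
                               protocol = scenario$config$protocol %||% NA_character_)
  structure(
    list(legs = legs, edges = edges, network = net, dg = dg,
         hysteresis = ht, closures = cl, flags = flags, metrics = metrics,
         scenario = scenario),
    class = "fepnet_analysis")
}

#' @export
print.fepnet_analysis <- function(x, ...) {
  cat("<fepnet_analysis>\n")
  print(x$network)
  print(x$flags)
  print(x$metrics)
  invisible(x)
}

#' Root-mean-square error of the reconstruction against ground truth
#'
#' @param analysis `fepnet_analysis` of a synthetic scenario
#' @return list with `rmse`, `rms_sigma` (root-mean-square propagated
#'   per-ligand sigma) and their ratio
#' @export
recovery_error <- function(analysis) {
  dg <- analysis$dg
  truth <- analysis$scenario$ground_truth$dg
  keep <- dg$resolvable & dg$id %in% names(truth) &
    dg$id != analysis$scenario$config$reference_id
  err <- dg$dg[keep] - truth[dg$id[keep]]
  rmse <- sqrt(mean(err^2))
  rms_sigma <- sqrt(mean(dg$sigma[keep]^2))
  list(rmse = rmse, rms_sigma = rms_sigma, ratio = rmse / rms_sigma)
}
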