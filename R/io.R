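#' Write reduced-potential samples to a tab-separated file
#'
#' One row per sample with columns `leg_id`, `repeat`, `origin_state`,
#' `sample_index`, `u_0` ... `u_(K-1)`. Numbers are serialized at full
#' precision so a round trip reproduces the in-memory values exactly.
#'
#' @param scenario `fepnet_scenario` generated with sampling enabled
#' @param path output file
#' @return `path`, invisibly
#' @export
write_reduced_potentials <- function(scenario, path) {
  if (is.null(scenario$u_matrices)) {
    stop("scenario has no sampled reduced potentials (analytic mode)")
  }
  rows <- lapply(scenario$legs$leg_id, function(id) {
    rp <- scenario$u_matrices[[id]]
    K <- nrow(rp$u)
    meta <- strsplit(id, "|", fixed = TRUE)[[1]]
    df <- data.frame(leg_id = id, repeat. = as.integer(meta[4]),
                     origin_state = rep(seq_len(K) - 1L, rp$counts),
                     sample_index = seq_len(ncol(rp$u)) - 1L,
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(t(rp$u)))
  })
  tab <- do.call(rbind, rows)
  K <- ncol(tab) - 4L
  names(tab) <- c("leg_id", "repeat", "origin_state", "sample_index",
                  paste0("u_", seq_len(K) - 1L))
  write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reduced-potential samples written by [write_reduced_potentials()]
#'
#' @param path TSV file
#' @param n_states expected number of lambda states (validated against the
#'   file's `u_*` columns when given)
#' @return named list of [reduced_potentials()] objects, one per leg; leg
#'   metadata (`source`, `target`, `environment`, `repeat_id`) is attached
#'   as the `legs` attribute
#' @export
read_reduced_potentials <- function(path, n_states = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ucols <- grep("^u_", names(tab), value = TRUE)
  if (!is.null(n_states) && length(ucols) != n_states) {
    stop(sprintf("file has %d states, expected %d", length(ucols), n_states))
  }
  out <- lapply(split(tab, tab$leg_id), function(d) {
    d <- d[order(d$sample_index), ]
    counts <- as.integer(table(factor(d$origin_state,
                                      levels = seq_along(ucols) - 1L)))
    if (sum(counts) != nrow(d)) stop("inconsistent per-state sample counts")
    reduced_potentials(t(as.matrix(d[, ucols])), counts)
  })
  meta <- do.call(rbind, strsplit(names(out), "|", fixed = TRUE))
  attr(out, "legs") <- data.frame(
    leg_id = names(out), source = meta[, 1], target = meta[, 2],
    environment = meta[, 3], repeat_id = as.integer(meta[, 4]),
    stringsAsFactors = FALSE)
  out
}

#' Write per-leg free-energy estimates to CSV
#'
#' Columns: `edge_id`, `source`, `target`, `environment`, `repeat`,
#' `value_kcal_mol`, `sigma_kcal_mol`.
#'
#' @param leg_estimates data.frame from [estimate_legs()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_edge_estimates <- function(leg_estimates, path) {
  out <- data.frame(
    edge_id = paste0(leg_estimates$source, "->", leg_estimates$target),
    source = leg_estimates$source, target = leg_estimates$target,
    environment = leg_estimates$environment,
    `repeat` = leg_estimates$repeat_id,
    value_kcal_mol = sprintf("%.17g", leg_estimates$value),
    sigma_kcal_mol = sprintf("%.17g", leg_estimates$sigma),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-leg estimates written by [write_edge_estimates()]
#'
#' @param path CSV file
#' @return data.frame with the columns of [estimate_legs()]
#' @export
read_edge_estimates <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("source", "target", "environment", "repeat",
            "value_kcal_mol", "sigma_kcal_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("malformed edge-estimate file, missing columns: ",
         paste(miss, collapse = ", "))
  }
  data.frame(leg_id = paste(tab$source, tab$target, tab$environment,
                            tab$`repeat`, sep = "|"),
             source = as.character(tab$source),
             target = as.character(tab$target),
             repeat_id = as.integer(tab$`repeat`),
             environment = tab$environment,
             value = as.numeric(tab$value_kcal_mol),
             sigma = as.numeric(tab$sigma_kcal_mol),
             stringsAsFactors = FALSE)
}

#' Write a perturbation network to JSON
#'
#' @param network `fepnet_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_network_json <- function(network, path) {
  payload <- list(
    ligands = network$ligands, edges = network$edges,
    reference_id = network$reference_id,
    reference_dg = network$reference_dg,
    temperature = network$temperature)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a perturbation network from JSON
#'
#' @param path JSON file written by [write_network_json()] or hand-authored
#'   with the same fields
#' @return `fepnet_network`
#' @export
read_network_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lig <- as.data.frame(p$ligands, stringsAsFactors = FALSE)
  for (col in c("ki_molar")) if (!col %in% names(lig)) lig[[col]] <- NA_real_
  if (!"is_racemate" %in% names(lig)) lig$is_racemate <- FALSE
  for (col in c("enantiomer_r", "enantiomer_s")) {
    if (!col %in% names(lig)) lig[[col]] <- NA_character_
  }
  lig$is_racemate[is.na(lig$is_racemate)] <- FALSE
  perturbation_network(lig, as.data.frame(p$edges, stringsAsFactors = FALSE),
                       reference_id = p$reference_id,
                       reference_dg = p$reference_dg,
                       temperature = p$temperature %||% 300)
}

#' Read an experimental affinity table
#'
#' Accepts either a `ki_molar` column (converted with [ki_to_dg()]) or a
#' `dg_kcal_mol` column.
#'
#' @param path CSV with column `ligand_id` plus `ki_molar` or `dg_kcal_mol`
#' @param temperature kelvin, for the Ki conversion
#' @return data.frame `ligand_id`, `dg`
#' @export
read_experimental_csv <- function(path, temperature = 300) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"ligand_id" %in% names(tab)) stop("missing `ligand_id` column")
  dg <- if ("dg_kcal_mol" %in% names(tab)) {
    as.numeric(tab$dg_kcal_mol)
  } else if ("ki_molar" %in% names(tab)) {
    ki_to_dg(as.numeric(tab$ki_molar), temperature)
  } else {
    stop("need a `ki_molar` or `dg_kcal_mol` column")
  }
  data.frame(ligand_id = as.character(tab$ligand_id), dg = dg,
             stringsAsFactors = FALSE)
}

#' Write an experimental affinity table
#'
#' @param experimental data.frame with `ligand_id` and `ki_molar` and/or
#'   `dg` columns (as produced by [generate_scenario()])
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_experimental_csv <- function(experimental, path) {
  out <- data.frame(ligand_id = experimental$ligand_id,
                    ki_molar = sprintf("%.17g", experimental$ki_molar),
                    dg_kcal_mol = sprintf("%.17g", experimental$dg),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published cycle closures of the ACK1 benchmark
#'
#' The packaged reference values: twelve thermodynamic cycles evaluated
#' under the five set-up protocols A-E, as mean +/- sigma in kcal/mol
#' (protocol E was not run for the charged batch, giving two missing
#' entries). Useful for demonstrating threshold flagging on real reported
#' numbers.
#'
#' @param path override the packaged fixture file (mainly for tests)
#' @return data.frame: `cycle`, `protocol`, `closure`, `sigma`
#' @export
ack1_cycle_closures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ack1_cycle_closures.json",
                        package = "fepnet", mustWork = TRUE)
  }
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(p$cycles, function(cy) {
    do.call(rbind, lapply(names(cy$closures), function(prot) {
      v <- cy$closures[[prot]]
      if (is.null(v$value)) return(NULL)
      data.frame(cycle = cy$cycle, protocol = prot,
                 closure = v$value, sigma = v$sigma,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
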