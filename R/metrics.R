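#' Benchmark metrics for predicted vs experimental binding free energies
#'
#' R-squared is the squared Pearson correlation of the two vectors, the
#' slope is the ordinary least-squares slope of predicted regressed on
#' experimental, and MUE is the mean unsigned error. All ligands present in
#' both tables enter, including the anchored reference ligand.
#'
#' @param predicted,experimental named numeric vectors of binding free
#'   energies (kcal/mol), names = ligand ids; or unnamed vectors of equal
#'   length in matched order
#' @return list with `r2`, `mue`, `slope`, `n`
#' @examples
#' compute_metrics(c(a = -7, b = -8, c = -9), c(a = -7, b = -8, c = -9))
#' @export
compute_metrics <- function(predicted, experimental) {
  if (!is.null(names(predicted)) && !is.null(names(experimental))) {
    common <- intersect(names(predicted), names(experimental))
    predicted <- predicted[common]
    experimental <- experimental[common]
  }
  keep <- is.finite(predicted) & is.finite(experimental)
  predicted <- predicted[keep]; experimental <- experimental[keep]
  n <- length(predicted)
  if (n < 3L || length(experimental) != n) {
    stop("need at least 3 ligands with both predicted and experimental values")
  }
  if (var(predicted) == 0 || var(experimental) == 0) {
    stop("R-squared undefined: zero variance in one of the vectors")
  }
  list(r2 = cor(predicted, experimental)^2,
       mue = mean(abs(predicted - experimental)),
       slope = unname(coef(lm(predicted ~ experimental))[2]),
       n = n)
}

#' Parametric bootstrap of benchmark metrics
#'
#' Each draw perturbs every predicted value by N(0, sigma_i^2) and every
#' experimental value by N(0, exp_sigma^2) and recomputes the metrics;
#' reported values are means +/- standard deviations over draws. The
#' experimental perturbation encodes the assumed uncertainty of the assay
#' (0.4 kcal/mol by default, since Ki uncertainties are typically not
#' reported).
#'
#' @param predicted named numeric vector of predicted dG (kcal/mol)
#' @param predicted_sigma uncertainties of the predictions (recycled)
#' @param experimental named numeric vector of experimental dG
#' @param exp_sigma assumed experimental uncertainty, kcal/mol
#' @param n_boot number of bootstrap draws (>= 100 recommended for
#'   reported uncertainties)
#' @param seed optional integer seed for reproducibility
#' @param protocol optional protocol label carried into the report
#' @return object of class `metrics_report`: list with `r2`, `r2_sigma`,
#'   `mue`, `mue_sigma`, `slope`, `slope_sigma`, `n_ligands`, `protocol`,
#'   and the bootstrap configuration
#' @export
bootstrap_metrics <- function(predicted, predicted_sigma = 0, experimental,
                              exp_sigma = 0.4, n_boot = 1000L, seed = NULL,
                              protocol = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  if (exp_sigma < 0) stop("`exp_sigma` must be >= 0")
  if (n_boot < 1L) stop("`n_boot` must be >= 1")
  common <- if (!is.null(names(predicted)) && !is.null(names(experimental))) {
    intersect(names(predicted), names(experimental))
  } else seq_along(predicted)
  p <- predicted[common]; e <- experimental[common]
  ps <- rep_len(predicted_sigma, length(predicted))
  if (!is.null(names(predicted))) names(ps) <- names(predicted)
  ps <- ps[common]
  draws <- vapply(seq_len(n_boot), function(i) {
    m <- compute_metrics(p + rnorm(length(p), 0, ps),
                         e + rnorm(length(e), 0, exp_sigma))
    c(m$r2, m$mue, m$slope)
  }, numeric(3))
  structure(
    list(r2 = mean(draws[1, ]), r2_sigma = sd(draws[1, ]),
         mue = mean(draws[2, ]), mue_sigma = sd(draws[2, ]),
         slope = mean(draws[3, ]), slope_sigma = sd(draws[3, ]),
         n_ligands = length(p), protocol = protocol,
         n_boot = n_boot, seed = seed, exp_sigma = exp_sigma),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report%s> n = %d\n  R2    %.2f +/- %.2f\n  MUE   %.2f +/- %.2f kcal/mol\n  slope %.2f +/- %.2f\n",
    if (is.na(x$protocol)) "" else paste0(" ", x$protocol),
    x$n_ligands, x$r2, x$r2_sigma, x$mue, x$mue_sigma, x$slope, x$slope_sigma))
  invisible(x)
}

#' Upper bound on achievable R-squared given experimental noise
#'
#' The best any predictor could score against noisy measurements: the mean
#' (+/- sd) over draws of the squared correlation between the experimental
#' vector and a copy perturbed by N(0, exp_sigma^2) per ligand. With
#' exp_sigma = 0 the bound is exactly 1.
#'
#' @param experimental numeric vector of experimental dG values (kcal/mol)
#' @param exp_sigma assumed experimental uncertainty, kcal/mol
#' @param n_boot number of draws
#' @param seed optional integer seed
#' @return list with `r2`, `sigma`
#' @export
r2_upper_bound <- function(experimental, exp_sigma = 0.4, n_boot = 1000L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (var(experimental) == 0) {
    stop("R-squared undefined: experimental vector has zero variance")
  }
  if (exp_sigma < 0) stop("`exp_sigma` must be >= 0")
  if (exp_sigma == 0) return(list(r2 = 1, sigma = 0))
  draws <- vapply(seq_len(n_boot), function(i) {
    cor(experimental, experimental + rnorm(length(experimental), 0, exp_sigma))^2
  }, numeric(1))
  list(r2 = mean(draws), sigma = sd(draws))
}

#' Side-by-side comparison of scenario metric reports
#'
#' @param reports named list of `metrics_report` objects (names = scenario
#'   or protocol labels)
#' @param flags optional named list of `flag_report` objects aligned with
#'   `reports`
#' @return data.frame with one row per scenario, sorted by MUE ascending
#' @export
compare_scenarios <- function(reports, flags = NULL) {
  if (length(reports) < 1L) stop("need at least one report")
  ns <- vapply(reports, function(r) r$n_ligands, numeric(1))
  if (length(unique(ns)) > 1L) {
    warning("scenario reports cover different ligand counts: ",
            paste(unique(ns), collapse = ", "))
  }
  labels <- names(reports) %||% as.character(seq_along(reports))
  out <- data.frame(
    scenario = labels,
    r2 = vapply(reports, function(r) r$r2, numeric(1)),
    r2_sigma = vapply(reports, function(r) r$r2_sigma, numeric(1)),
    mue = vapply(reports, function(r) r$mue, numeric(1)),
    mue_sigma = vapply(reports, function(r) r$mue_sigma, numeric(1)),
    slope = vapply(reports, function(r) r$slope, numeric(1)),
    n_flagged = if (is.null(flags)) NA_integer_ else
      vapply(flags, function(f) f$n_flagged, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$mue, out$scenario), , drop = FALSE]
}
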