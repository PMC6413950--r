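#' Free-energy value with uncertainty
#'
#' A scalar free energy in kcal/mol with a standard uncertainty and a
#' provenance kind: `"leg"` (one environment of one perturbation run),
#' `"edge_repeat"` (one repeat's relative binding free energy),
#' `"edge_mean"` (repeat-aggregated edge value) or `"ligand_dg"`
#' (network-reconstructed absolute binding free energy).
#'
#' @param value free energy in kcal/mol (finite scalar)
#' @param sigma standard uncertainty in kcal/mol (>= 0)
#' @param kind provenance tag
#' @param edge optional edge identity label (e.g. "16->45") used for
#'   consistency checks when combining legs
#' @param repeat_id optional repeat index
#' @return an object of class `fe_value`
#' @export
fe_value <- function(value, sigma = 0,
                     kind = c("leg", "edge_repeat", "edge_mean", "ligand_dg"),
                     edge = NULL, repeat_id = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(
    list(value = as.numeric(value), sigma = as.numeric(sigma), kind = kind,
         edge = edge, repeat_id = repeat_id),
    class = "fe_value")
}

#' @export
print.fe_value <- function(x, ...) {
  cat(sprintf("<fe_value %s> %.4f +/- %.4f kcal/mol", x$kind, x$value, x$sigma))
  if (!is.null(x$edge)) cat(sprintf("  [%s]", x$edge))
  cat("\n")
  invisible(x)
}

as_fe_value <- function(x, kind = "edge_mean") {
  if (inherits(x, "fe_value")) return(x)
  fe_value(x, 0, kind)
}

#' Relative binding free energy from the two legs of a perturbation
#'
#' Implements the double-decoupling identity for a single repeat:
#' \eqn{\Delta\Delta G_{X\to Y} = \Delta G^{complex}_{X\to Y} -
#' \Delta G^{free}_{X\to Y}}, with uncertainties combined in quadrature.
#'
#' @param dg_complex `fe_value` of kind `"leg"` for the bound (complex) leg
#' @param dg_free `fe_value` of kind `"leg"` for the solvent (free) leg
#' @return `fe_value` of kind `"edge_repeat"`
#' @examples
#' ddg_from_legs(fe_value(-5, 0.3, "leg"), fe_value(-3, 0.4, "leg"))
#' @export
ddg_from_legs <- function(dg_complex, dg_free) {
  stopifnot(inherits(dg_complex, "fe_value"), inherits(dg_free, "fe_value"))
  if (dg_complex$kind != "leg" || dg_free$kind != "leg") {
    stop("both inputs must be leg free energies (kind = \"leg\")")
  }
  if (!is.null(dg_complex$edge) && !is.null(dg_free$edge) &&
      !identical(dg_complex$edge, dg_free$edge)) {
    stop("legs belong to different edges: ",
         dg_complex$edge, " vs ", dg_free$edge)
  }
  if (!is.null(dg_complex$repeat_id) && !is.null(dg_free$repeat_id) &&
      !identical(dg_complex$repeat_id, dg_free$repeat_id)) {
    stop("legs belong to different repeats")
  }
  fe_value(dg_complex$value - dg_free$value,
           sqrt(dg_complex$sigma^2 + dg_free$sigma^2),
           kind = "edge_repeat",
           edge = dg_complex$edge %||% dg_free$edge,
           repeat_id = dg_complex$repeat_id %||% dg_free$repeat_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate independent repeats of an edge
#'
#' Mean of the repeat values; the uncertainty is the standard error of the
#' mean (sample sd / sqrt(n)) for n >= 2, or the single repeat's propagated
#' uncertainty for n = 1.
#'
#' @param repeats list of `fe_value` objects (kind `"edge_repeat"`), or a
#'   numeric vector of repeat values
#' @return `fe_value` of kind `"edge_mean"`
#' @examples
#' aggregate_repeats(c(1.8, 1.5))  # 1.65 +/- 0.15
#' @export
aggregate_repeats <- function(repeats) {
  if (is.numeric(repeats)) repeats <- lapply(repeats, fe_value, kind = "edge_repeat")
  if (length(repeats) == 0L) stop("at least one repeat is required")
  edges <- unique(unlist(lapply(repeats, function(r) r$edge %||% NA_character_)))
  if (length(edges) > 1L) stop("repeats belong to different edges")
  v <- vapply(repeats, function(r) r$value, numeric(1))
  n <- length(v)
  sigma <- if (n >= 2L) sd(v) / sqrt(n) else repeats[[1L]]$sigma
  fe_value(mean(v), sigma, kind = "edge_mean", edge = repeats[[1L]]$edge)
}

#' Boltzmann combination of enantiomer relative free energies
#'
#' A racemic ligand is a 1:1 mixture of two enantiomers; its effective
#' relative binding free energy to another ligand is
#' \deqn{\Delta\Delta G = -kT \ln\left[\tfrac12\left(
#'   e^{-\Delta\Delta G_R / kT} + e^{-\Delta\Delta G_S / kT}\right)\right].}
#' The result always lies between the more favourable enantiomer value and
#' that value plus \eqn{kT \ln 2}. Computed with log-sum-exp, so inputs of
#' hundreds of kT do not overflow. The uncertainty is propagated with
#' Boltzmann weights \eqn{w_i = e^{-\Delta\Delta G_i/kT} / \sum_j
#' e^{-\Delta\Delta G_j/kT}}: \eqn{\sigma^2 = \sum_i w_i^2 \sigma_i^2}.
#'
#' @param ddg_r,ddg_s `fe_value` (or bare numeric, kcal/mol) for the two
#'   enantiomers, in the same orientation
#' @param temperature temperature in kelvin
#' @return `fe_value` with the kind of the inputs (default `"edge_mean"`)
#' @examples
#' combine_racemate(0, 100)  # ~ +kT ln 2 = 0.413 kcal/mol at 300 K
#' @export
combine_racemate <- function(ddg_r, ddg_s, temperature = 300) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("`temperature` must be positive (kelvin)")
  }
  ddg_r <- as_fe_value(ddg_r)
  ddg_s <- as_fe_value(ddg_s)
  kt <- kT_kcal(temperature)
  a <- c(-ddg_r$value / kt, -ddg_s$value / kt)
  m <- max(a)
  val <- -kt * (m + log(0.5 * sum(exp(a - m))))
  w <- exp(a - m) / sum(exp(a - m))
  sigma <- sqrt(sum(w^2 * c(ddg_r$sigma, ddg_s$sigma)^2))
  fe_value(val, sigma, kind = ddg_r$kind, edge = ddg_r$edge)
}
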