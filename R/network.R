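#' Construct a ligand table for a perturbation network
#'
#' @param id character vector of ligand labels
#' @param batch batch membership, `"batch1"` or `"batch2"`
#' @param charge integer formal charge (0 or +1)
#' @param ki_molar experimental inhibition constant in mol/L (NA if unknown)
#' @param is_racemate logical; TRUE for a racemic ligand represented by two
#'   enantiomer sub-ligands
#' @param enantiomer_r,enantiomer_s ids of the enantiomer sub-ligands (NA
#'   unless `is_racemate`)
#' @return a `data.frame` with one row per ligand
#' @export
ligand_table <- function(id, batch = "batch1", charge = 0L, ki_molar = NA_real_,
                         is_racemate = FALSE, enantiomer_r = NA_character_,
                         enantiomer_s = NA_character_) {
  df <- data.frame(id = as.character(id), batch = batch,
                   charge = as.integer(charge), ki_molar = as.numeric(ki_molar),
                   is_racemate = is_racemate,
                   enantiomer_r = as.character(enantiomer_r),
                   enantiomer_s = as.character(enantiomer_s),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("ligand ids must be unique")
  if (any(df$ki_molar <= 0, na.rm = TRUE)) stop("ki_molar must be > 0")
  bad <- df$is_racemate & (is.na(df$enantiomer_r) | is.na(df$enantiomer_s))
  if (any(bad)) {
    stop("racemate ligands need both enantiomer ids: ",
         paste(df$id[bad], collapse = ", "))
  }
  df
}

#' Assemble a perturbation network
#'
#' A perturbation network holds the ligands of a congeneric series, the
#' directed repeat-aggregated \eqn{\Delta\Delta G} edges measured between
#' them, and the reference ligand against which absolute binding free
#' energies are reconstructed. Forward (X to Y) and reverse (Y to X)
#' measurements are stored as distinct directed edges.
#'
#' @param ligands data.frame from [ligand_table()]
#' @param edges data.frame with columns `source`, `target`, `value`
#'   (kcal/mol), `sigma` (kcal/mol); optional `n_repeats`, `protocol`,
#'   `charge_mismatch`
#' @param reference_id id of the reference ligand
#' @param reference_dg absolute binding free energy assigned to the
#'   reference (kcal/mol); defaults to `ki_to_dg()` of the reference
#'   ligand's Ki
#' @param temperature temperature in kelvin (used for the Ki conversion)
#' @return an object of class `fepnet_network`
#' @export
perturbation_network <- function(ligands, edges, reference_id,
                                 reference_dg = NULL, temperature = 300) {
  stopifnot(is.data.frame(ligands), is.data.frame(edges))
  need <- c("source", "target", "value", "sigma")
  if (!all(need %in% names(edges))) {
    stop("edges need columns: ", paste(need, collapse = ", "))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (!"n_repeats" %in% names(edges)) edges$n_repeats <- NA_integer_
  if (!"protocol" %in% names(edges)) edges$protocol <- NA_character_
  if (!"charge_mismatch" %in% names(edges)) edges$charge_mismatch <- FALSE
  known <- ligands$id
  unknown <- setdiff(c(edges$source, edges$target), known)
  if (length(unknown)) {
    stop("edges reference undeclared ligands: ", paste(unknown, collapse = ", "))
  }
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  if (!reference_id %in% known) stop("reference ligand not in ligand table")
  if (is.null(reference_dg)) {
    ki <- ligands$ki_molar[ligands$id == reference_id]
    if (is.na(ki)) stop("reference ligand has no Ki; supply `reference_dg`")
    reference_dg <- ki_to_dg(ki, temperature)
  }
  # flag edges that pair a charged with a neutral ligand (treated as neutral
  # in the simulation; no numerical correction applied)
  chg <- setNames(ligands$charge, ligands$id)
  mismatch <- chg[edges$source] != chg[edges$target]
  edges$charge_mismatch <- edges$charge_mismatch | unname(mismatch)
  structure(
    list(ligands = ligands, edges = edges,
         reference_id = reference_id,
         reference_dg = reference_dg,
         temperature = temperature),
    class = "fepnet_network")
}

#' @export
print.fepnet_network <- function(x, ...) {
  cat(sprintf("<fepnet_network> %d ligands, %d directed edges, reference %s (%.2f kcal/mol)\n",
              nrow(x$ligands), nrow(x$edges), x$reference_id, x$reference_dg))
  invisible(x)
}

#' Collapse enantiomer edges of racemic ligands
#'
#' Edges measured against the individual enantiomers of a racemic ligand
#' are combined into a single edge against the racemate parent with the
#' Boltzmann mixture rule of [combine_racemate()]. Both enantiomer values
#' are first oriented parent-to-other (measurements into the enantiomer are
#' sign-flipped), combined, then flipped back, which keeps the combination
#' antisymmetric under direction reversal.
#'
#' @param network `fepnet_network` whose edge table may reference
#'   enantiomer sub-ligand ids
#' @return the network with enantiomer edges replaced by parent edges
#' @export
collapse_racemates <- function(network) {
  lig <- network$ligands
  edges <- network$edges
  parents <- lig$id[lig$is_racemate]
  for (p in parents) {
    e1 <- lig$enantiomer_r[lig$id == p]
    e2 <- lig$enantiomer_s[lig$id == p]
    touches <- edges$source %in% c(e1, e2) | edges$target %in% c(e1, e2)
    if (!any(touches)) next
    sub <- edges[touches, , drop = FALSE]
    keep <- edges[!touches, , drop = FALSE]
    # orient every enantiomer measurement parent -> other
    other <- ifelse(sub$source %in% c(e1, e2), sub$target, sub$source)
    outgoing <- sub$source %in% c(e1, e2)
    orient_val <- ifelse(outgoing, sub$value, -sub$value)
    key <- paste(other, outgoing)   # one combined edge per (partner, direction)
    newrows <- lapply(split(seq_len(nrow(sub)), key), function(ix) {
      s <- sub[ix, , drop = FALSE]
      ov <- orient_val[ix]
      if (length(ix) == 2L) {
        comb <- combine_racemate(fe_value(ov[1], s$sigma[1], "edge_mean"),
                                 fe_value(ov[2], s$sigma[2], "edge_mean"),
                                 temperature = network$temperature)
        val <- comb$value; sg <- comb$sigma
      } else {  # only one enantiomer measured: relabel
        val <- ov[1]; sg <- s$sigma[1]
      }
      out <- s[1, , drop = FALSE]
      if (outgoing[ix][1]) {
        out$source <- p; out$target <- other[ix][1]; out$value <- val
      } else {
        out$source <- other[ix][1]; out$target <- p; out$value <- -val
      }
      out$sigma <- sg
      out
    })
    edges <- rbind(keep, do.call(rbind, newrows))
  }
  rownames(edges) <- NULL
  network$edges <- edges
  network
}

# ids reachable from the reference through the undirected edge skeleton
reachable_from_reference <- function(network) {
  adj <- split(c(network$edges$target, network$edges$source),
               c(network$edges$source, network$edges$target))
  seen <- network$reference_id
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Reconstruct absolute binding free energies over the network
#'
#' Solves the weighted least-squares problem in which every directed edge
#' contributes one observation \eqn{\Delta G_{target} - \Delta G_{source} =
#' \Delta\Delta G_{edge}} with weight \eqn{1/\sigma^2}, anchored by fixing
#' the reference ligand at `reference_dg`. Reverse edges enter with their
#' own sign as measured, so forward/reverse disagreement (hysteresis) is
#' averaged by the fit. Per-ligand uncertainties come from the diagonal of
#' the (pseudo-)inverse of the weighted normal matrix. Ligands with no path
#' to the reference are reported with `resolvable = FALSE` and `NA`
#' estimates rather than dropped.
#'
#' @param network `fepnet_network` (racemate edges already collapsed; see
#'   [collapse_racemates()])
#' @param sigma_floor smallest admissible edge sigma in kcal/mol; edge
#'   sigmas below it (e.g. noiseless synthetic data) are floored to keep
#'   weights finite
#' @return data.frame with columns `id`, `dg`, `sigma`, `resolvable`;
#'   the reference row has `sigma = 0`
#' @export
network_estimate <- function(network, sigma_floor = 1e-6) {
  stopifnot(inherits(network, "fepnet_network"))
  edges <- network$edges
  if (nrow(edges) == 0L) stop("network has no edges")
  if (sigma_floor <= 0) stop("`sigma_floor` must be > 0")
  ref <- network$reference_id
  conn <- reachable_from_reference(network)
  ids <- setdiff(intersect(network$ligands$id, conn), ref)
  # edges in components with no path to the reference cannot inform the fit
  edges <- edges[edges$source %in% conn & edges$target %in% conn, , drop = FALSE]
  p <- length(ids)
  m <- nrow(edges)
  X <- matrix(0, m, p, dimnames = list(NULL, ids))
  y <- edges$value
  for (i in seq_len(m)) {
    s <- edges$source[i]; t <- edges$target[i]
    if (t == ref) y[i] <- y[i] - network$reference_dg else X[i, t] <- 1
    if (s == ref) y[i] <- y[i] + network$reference_dg else X[i, s] <- -1
  }
  w <- 1 / pmax(edges$sigma, sigma_floor)^2
  A <- crossprod(X, X * w)
  b <- crossprod(X, y * w)
  cov <- tryCatch(solve(A), error = function(e) MASS::ginv(A))
  theta <- drop(cov %*% b)
  out <- data.frame(id = c(ref, ids),
                    dg = c(network$reference_dg, theta),
                    sigma = c(0, sqrt(pmax(diag(cov), 0))),
                    resolvable = TRUE, stringsAsFactors = FALSE)
  orphan <- setdiff(network$ligands$id, conn)
  # enantiomer sub-ligands are represented by their parent, not orphans
  sub <- c(network$ligands$enantiomer_r, network$ligands$enantiomer_s)
  orphan <- setdiff(orphan, sub[!is.na(sub)])
  if (length(orphan)) {
    out <- rbind(out, data.frame(id = orphan, dg = NA_real_, sigma = NA_real_,
                                 resolvable = FALSE, stringsAsFactors = FALSE))
    warning("ligands unreachable from the reference: ",
            paste(orphan, collapse = ", "))
  }
  rownames(out) <- NULL
  out[order(match(out$id, network$ligands$id)), , drop = FALSE]
}
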