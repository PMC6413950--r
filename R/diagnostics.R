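#' Hysteresis of a perturbation edge
#'
#' The discrepancy between independently computed forward (X to Y) and
#' reverse (Y to X) perturbations. With the sign convention used here the
#' hysteresis is the 2-cycle closure h = ddG(X to Y) + ddG(Y to X), which
#' is zero for perfectly consistent runs. Uncertainties add in quadrature.
#'
#' @param forward,reverse `fe_value` (or numeric, kcal/mol) edge means for
#'   the two directions; pass `NULL` for an unmeasured direction
#' @return `fe_value` of kind `"edge_mean"`, or `NA` (not-applicable, never
#'   silently zero) if either direction is missing
#' @examples
#' hysteresis(aggregate_repeats(c(-0.8, -1.6)), aggregate_repeats(c(-2.2, -2.4)))
#' @export
hysteresis <- function(forward, reverse) {
  if (is.null(forward) || is.null(reverse)) return(NA)
  forward <- as_fe_value(forward)
  reverse <- as_fe_value(reverse)
  fe_value(forward$value + reverse$value,
           sqrt(forward$sigma^2 + reverse$sigma^2),
           kind = "edge_mean")
}

#' Hysteresis table for all doubly measured edges
#'
#' @param network `fepnet_network`
#' @param threshold flagging threshold in kcal/mol
#' @return data.frame with one row per unordered ligand pair measured in
#'   both directions: `source`, `target` (forward orientation as stored),
#'   `h`, `sigma`, `flagged`
#' @export
hysteresis_table <- function(network, threshold = 0.8) {
  e <- network$edges
  key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
  rows <- lapply(split(seq_len(nrow(e)), key), function(ix) {
    if (length(ix) < 2L) return(NULL)
    f <- e[ix[1], ]; r <- e[ix[2], ]
    h <- hysteresis(fe_value(f$value, f$sigma, "edge_mean"),
                    fe_value(r$value, r$sigma, "edge_mean"))
    data.frame(source = f$source, target = f$target,
               h = h$value, sigma = h$sigma,
               flagged = abs(h$value) >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(source = character(), target = character(),
                      h = numeric(), sigma = numeric(), flagged = logical())
  }
  rownames(out) <- NULL
  out[order(out$source, out$target), , drop = FALSE]
}

#' Enumerate simple cycles of the perturbation map
#'
#' All simple undirected cycles of length 3 or 4 over edges with at least
#' one measured direction, in canonical form (smallest ligand id first,
#' smaller neighbour second) and deterministic order.
#'
#' @param network `fepnet_network`
#' @param max_length 3 or 4
#' @return list of character vectors of ligand ids (possibly empty)
#' @export
enumerate_cycles <- function(network, max_length = 4L) {
  if (!max_length %in% c(3L, 4L)) stop("`max_length` must be 3 or 4")
  e <- network$edges
  ids <- sort(unique(c(e$source, e$target)))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  adj[cbind(e$source, e$target)] <- TRUE
  adj <- adj | t(adj)
  cycles <- list()
  if (n >= 3L) {
    tri <- combn(ids, 3L, simplify = FALSE)
    for (v in tri) {
      if (adj[v[1], v[2]] && adj[v[2], v[3]] && adj[v[1], v[3]]) {
        cycles[[length(cycles) + 1L]] <- v
      }
    }
  }
  if (max_length == 4L && n >= 4L) {
    for (v in combn(ids, 4L, simplify = FALSE)) {
      # the three pairings of a 4-set; each order below is canonical
      for (ord in list(v[c(1, 2, 3, 4)], v[c(1, 2, 4, 3)], v[c(1, 3, 2, 4)])) {
        ok <- adj[ord[1], ord[2]] && adj[ord[2], ord[3]] &&
          adj[ord[3], ord[4]] && adj[ord[4], ord[1]]
        if (ok) cycles[[length(cycles) + 1L]] <- ord
      }
    }
  }
  lens <- lengths(cycles)
  keys <- vapply(cycles, paste, character(1), collapse = "-")
  cycles[order(lens, keys)]
}

# canonical form of a simple cycle: among all rotations and reflections,
# the sequence starting at the smallest id whose second element is the
# smaller of that id's two cycle neighbours
canonical_cycle <- function(cycle) {
  cycle <- as.character(cycle)
  n <- length(cycle)
  if (n < 3L) return(sort(cycle))
  i <- which.min(match(cycle, sort(cycle)))
  rot <- c(cycle[i:n], cycle[seq_len(i - 1L)])
  nb <- c(rot[2L], rot[n])
  if (sort(nb)[1L] == rot[2L]) rot else c(rot[1L], rev(rot[-1L]))
}

# closure contribution of one oriented hop x -> y under a direction policy
hop_value <- function(edges, x, y, direction_policy) {
  fwd <- which(edges$source == x & edges$target == y)
  rev <- which(edges$source == y & edges$target == x)
  has_f <- length(fwd) > 0L
  has_r <- length(rev) > 0L
  if (!has_f && !has_r) {
    stop(sprintf("no measured edge between %s and %s", x, y))
  }
  vf <- if (has_f) edges$value[fwd[1]] else NA_real_
  sf <- if (has_f) edges$sigma[fwd[1]] else NA_real_
  vr <- if (has_r) edges$value[rev[1]] else NA_real_
  sr <- if (has_r) edges$sigma[rev[1]] else NA_real_
  if (direction_policy == "as_measured" && has_f && has_r) {
    return(c((vf - vr) / 2, 0.5 * sqrt(sf^2 + sr^2)))
  }
  prefer_fwd <- switch(direction_policy,
                       as_measured = has_f,
                       forward_only = has_f,
                       reverse_only = !has_r)
  if (prefer_fwd) c(vf, sf) else c(-vr, sr)
}

#' Thermodynamic cycle closure
#'
#' Sum of oriented edge values along a cycle of ligands; zero for any set
#' of edges derived from a consistent underlying potential. When a hop is
#' traversed against its only measured direction the negated value is
#' used. The `direction_policy` controls how doubly measured hops enter:
#' `"as_measured"` (default) averages the traversal-direction value with
#' the negated opposite-direction value, `"forward_only"` prefers the
#' measurement oriented along the traversal, `"reverse_only"` prefers the
#' opposite one (negated).
#'
#' @param cycle character vector of ligand ids (length 3 or 4; 2 is
#'   admitted and equals the edge hysteresis)
#' @param network `fepnet_network`
#' @param direction_policy see above
#' @return a `cycle_report`: list with `cycle`, `closure` (`fe_value`),
#'   `flagged` (NA until thresholded)
#' @export
cycle_closure <- function(cycle, network,
                          direction_policy = c("as_measured", "forward_only",
                                               "reverse_only")) {
  direction_policy <- match.arg(direction_policy)
  cycle <- as.character(cycle)
  if (anyDuplicated(cycle)) stop("cycle has repeated ligand ids")
  if (length(cycle) < 2L) stop("cycle needs at least two ligands")
  edges <- network$edges
  hops <- cbind(cycle, c(cycle[-1], cycle[1]))
  if (length(cycle) == 2L) {
    # the 2-cycle: forward plus reverse, i.e. the hysteresis
    vf <- hop_value(edges, cycle[1], cycle[2], "forward_only")
    vr <- hop_value(edges, cycle[2], cycle[1], "forward_only")
    terms <- rbind(vf, vr)
  } else {
    terms <- t(apply(hops, 1, function(h)
      hop_value(edges, h[1], h[2], direction_policy)))
  }
  structure(
    list(cycle = cycle,
         closure = fe_value(sum(terms[, 1]), sqrt(sum(terms[, 2]^2)),
                            kind = "edge_mean"),
         flagged = NA),
    class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle %s> closure %.3f +/- %.3f kcal/mol\n",
              paste(x$cycle, collapse = "-"), x$closure$value, x$closure$sigma))
  invisible(x)
}

#' Closure table for a set of cycles
#'
#' @param network `fepnet_network`
#' @param cycles list of ligand-id vectors; default all simple cycles of
#'   length <= `max_length` plus, if `include_hysteresis`, the 2-cycles of
#'   all doubly measured edges
#' @param max_length passed to [enumerate_cycles()]
#' @param include_hysteresis include 2-cycles (edge hysteresis) in the table
#' @param direction_policy passed to [cycle_closure()]
#' @return data.frame with `cycle` (dash-joined ids), `length`, `closure`,
#'   `sigma`
#' @export
cycle_closure_table <- function(network, cycles = NULL, max_length = 4L,
                                include_hysteresis = TRUE,
                                direction_policy = "as_measured") {
  if (is.null(cycles)) {
    cycles <- enumerate_cycles(network, max_length)
    if (include_hysteresis) {
      ht <- hysteresis_table(network)
      two <- lapply(seq_len(nrow(ht)), function(i) c(ht$source[i], ht$target[i]))
      cycles <- c(two, cycles)
    }
  }
  rows <- lapply(cycles, function(cy) {
    rep <- cycle_closure(cy, network, direction_policy)
    data.frame(cycle = paste(cy, collapse = "-"), length = length(cy),
               closure = rep$closure$value, sigma = rep$closure$sigma,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cycle = character(), length = integer(),
                      closure = numeric(), sigma = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Flag cycles against a closure threshold and rank implicated ligands
#'
#' A cycle is flagged when the absolute mean closure meets or exceeds the
#' threshold (the uncertainty does not enter the comparison). Each ligand's
#' implication score is the number of flagged cycles containing it; ligands
#' are ranked by descending score with ties broken by ligand id.
#'
#' @param reports data.frame from [cycle_closure_table()] (columns `cycle`,
#'   `closure`), or a numeric vector of closure values
#' @param threshold flagging threshold in kcal/mol (> 0)
#' @return an object of class `flag_report`: list with `reports` (input
#'   plus `flagged` column), `n_flagged`, `ranking` (data.frame `id`,
#'   `score`), `threshold`
#' @export
flag_cycles <- function(reports, threshold = 0.8) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  if (is.numeric(reports)) {
    reports <- data.frame(cycle = as.character(seq_along(reports)),
                          closure = reports)
  }
  reports$flagged <- abs(reports$closure) >= threshold
  ids <- unlist(strsplit(reports$cycle[reports$flagged], "-", fixed = TRUE))
  if (length(ids)) {
    tab <- table(ids)
    ranking <- data.frame(id = names(tab), score = as.integer(tab),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$score, ranking$id), , drop = FALSE]
  } else {
    ranking <- data.frame(id = character(), score = integer())
  }
  rownames(ranking) <- NULL
  structure(list(reports = reports, n_flagged = sum(reports$flagged),
                 ranking = ranking, threshold = threshold),
            class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat(sprintf("<flag_report> %d of %d cycles flagged at |closure| >= %.2f kcal/mol\n",
              x$n_flagged, nrow(x$reports), x$threshold))
  if (nrow(x$ranking)) {
    top <- utils::head(x$ranking, 5L)
    cat("top implicated ligands:",
        paste(sprintf("%s (%d)", top$id, top$score), collapse = ", "), "\n")
  }
  invisible(x)
}
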