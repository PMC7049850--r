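# One-parameter bifurcation sweeps: track equilibrium branches and their
# stability over a parameter range, and refine bifurcation points
# (branch creation/destruction, stability switches) by bisection.

.branch_tags <- c("zero_tumor", "nonzero_tumor_zero_cytokine",
                  "nonzero_tumor_nonzero_cytokine")

# Signature of the equilibrium structure at one parameter value: per
# branch tag, the number of equilibria and the number with a negative
# stability margin.  Bifurcation events are exactly the points where
# this changes.  The margin sign (not the banded verdict) is used so
# that a stability switch bisects to the actual zero crossing of the
# leading eigenvalue rather than to the edge of the marginal band.
.equilibrium_signature <- function(reports) {
  sig <- integer(0L)
  for (tag in .branch_tags) {
    sel <- vapply(reports, function(r) r$point$branch == tag, logical(1L))
    sig <- c(sig, sum(sel),
             sum(vapply(reports[sel], function(r) r$margin < 0,
                        logical(1L))))
  }
  names(sig) <- as.vector(outer(c("n", "n_stable"), .branch_tags,
                                function(a, b) paste(a, b, sep = ".")))
  sig
}

#' Sweep one model parameter and track equilibrium branches
#'
#' At each grid value the parameter is substituted, all three equilibrium
#' branches are enumerated and classified, and points are linked across
#' adjacent grid values into curves by nearest-neighbour matching in
#' `log10(1 + T)`.  Curve ids are ordered by branch tag and then by tumor
#' size at first appearance (the tumor-free branch is always curve 1).
#'
#' @param params a [parameter_set].
#' @param name parameter to sweep (a [parameter_set()] field).
#' @param range length-2 numeric sweep range (lower end may be 0; only
#'   strictly positive values are sampled).
#' @param grid `"log"` (default) or `"linear"` sample spacing.
#' @param n number of samples.
#' @param n_extra_linear for log grids, additional linear samples filling
#'   the gap between the range's lower end and the smallest log sample.
#' @param n_scan scan resolution passed to the equilibrium solvers.
#' @return A `bifurcation_sweep`: list with `samples` (long data frame:
#'   value, branch, curve, the six state components, verdict, margin) and
#'   the sweep settings.
#' @export
bifurcation_sweep <- function(params, name, range, grid = c("log", "linear"),
                              n = 400L, n_extra_linear = 100L,
                              n_scan = 2000L) {
  stopifnot(inherits(params, "parameter_set"), length(range) == 2L,
            range[2L] > range[1L], range[1L] >= 0)
  grid <- match.arg(grid)
  if (grid == "log") {
    lo <- max(range[1L], range[2L] * 1e-9)
    vals <- 10^seq(log10(lo), log10(range[2L]), length.out = n)
    if (n_extra_linear > 0L && range[1L] < lo)
      vals <- c(seq(range[1L], lo, length.out = n_extra_linear + 1L)[-1L],
                vals)
  } else {
    vals <- seq(range[1L], range[2L], length.out = n)
  }
  vals <- sort(unique(vals[vals > 0]))
  rows <- vector("list", length(vals))
  sigs <- matrix(0L, length(vals), 6L)
  for (iv in seq_along(vals)) {
    reps <- enumerate_equilibria(set_param(params, name, vals[iv]),
                                 n_grid = n_scan)
    sigs[iv, ] <- .equilibrium_signature(reps)
    rows[[iv]] <- do.call(rbind, lapply(reps, function(rp)
      data.frame(value = vals[iv], branch = rp$point$branch,
                 t(rp$point$state), verdict = rp$verdict,
                 margin = rp$margin, row.names = NULL,
                 check.names = FALSE)))
  }
  samples <- do.call(rbind, rows)
  samples$curve <- .assign_curves(samples)
  samples <- samples[order(samples$curve, samples$value), ]
  rownames(samples) <- NULL
  structure(list(samples = samples, parameter = name, range = range,
                 grid_values = vals, signatures = sigs,
                 params = params, n_scan = n_scan),
            class = "bifurcation_sweep")
}

# Greedy curve tracking: within each branch tag, match points at each
# grid value to the open curve with the nearest log-tumor coordinate
# (jump threshold 0.3 decades in log10(1 + T)); unmatched points open a
# new curve.  Ids are then renumbered by tag and first-appearance order.
.assign_curves <- function(samples) {
  curve <- integer(nrow(samples))
  next_id <- 0L
  for (tag in .branch_tags) {
    idx <- which(samples$branch == tag)
    if (!length(idx)) next
    open <- list()   # id -> last log T
    for (v in unique(samples$value[idx])) {
      at <- idx[samples$value[idx] == v]
      lt <- log10(1 + samples$T[at])
      used <- character(0L)
      for (jj in order(lt)) {
        best <- NA_character_; bestd <- 0.3
        for (id in setdiff(names(open), used)) {
          dd <- abs(lt[jj] - open[[id]])
          if (dd < bestd) { best <- id; bestd <- dd }
        }
        if (is.na(best)) {
          next_id <- next_id + 1L
          best <- as.character(next_id)
        }
        open[[best]] <- lt[jj]
        used <- c(used, best)
        curve[at[jj]] <- as.integer(best)
      }
    }
  }
  # renumber by tag order then first appearance (value, then T)
  first <- stats::aggregate(seq_len(nrow(samples)),
                            by = list(curve = curve), FUN = min)
  ord <- order(match(samples$branch[first$x], .branch_tags),
               samples$value[first$x], samples$T[first$x])
  map <- integer(max(curve))
  map[first$curve[ord]] <- seq_along(ord)
  map[curve]
}

#' Locate bifurcation events by bisection
#'
#' Scans adjacent grid values of a sweep for changes in the equilibrium
#' signature (per-branch point counts and stable counts) and refines each
#' change by bisection on the parameter, re-running the equilibrium
#' enumeration at every probe, until the bracket is narrower than `tol`
#' (relative).  A change in a stable count with unchanged point count is
#' a `stability_switch`; a point-count increase/decrease is
#' `branch_created`/`branch_destroyed`.  For stability switches of the
#' tumor-free branch the closed-form critical value from
#' [tumor_free_stable()] is attached as a cross-check.
#'
#' @param sweep a [bifurcation_sweep()].
#' @param tol relative bracket tolerance.
#' @return Data frame of events: `parameter`, `value`, `type`, `branch`,
#'   `bracket_lo`, `bracket_hi`, `closed_form` (NA unless available).
#' @export
locate_bifurcations <- function(sweep, tol = 1e-4) {
  stopifnot(inherits(sweep, "bifurcation_sweep"))
  vals <- sweep$grid_values
  sigs <- sweep$signatures
  sig_at <- function(v)
    .equilibrium_signature(enumerate_equilibria(
      set_param(sweep$params, sweep$parameter, v), n_grid = sweep$n_scan))
  events <- list()
  for (i in seq_len(length(vals) - 1L)) {
    if (all(sigs[i, ] == sigs[i + 1L, ])) next
    lo <- vals[i]; hi <- vals[i + 1L]
    slo <- sigs[i, ]; shi <- sigs[i + 1L, ]
    while ((hi - lo) > tol * max(abs(hi), abs(lo))) {
      mid <- if (lo > 0 && hi / lo > 100) sqrt(lo * hi) else (lo + hi) / 2
      smid <- sig_at(mid)
      if (all(smid == slo)) lo <- mid else { hi <- mid; shi <- smid }
    }
    diffs <- which(slo != shi)
    for (dcomp in diffs) {
      tag <- .branch_tags[ceiling(dcomp / 2)]
      is_count <- dcomp %% 2L == 1L
      type <- if (!is_count) "stability_switch"
              else if (shi[dcomp] > slo[dcomp]) "branch_created"
              else "branch_destroyed"
      # a count change also changes the stable count trivially; keep the
      # stability_switch row only if the point count for the tag is flat
      if (!is_count && slo[dcomp - 1L] != shi[dcomp - 1L]) next
      cf <- NA_real_
      if (type == "stability_switch" && tag == "zero_tumor") {
        thr <- tumor_free_stable(sweep$params)
        cf <- switch(sweep$parameter, a = thr$a_crit, c = thr$c_crit,
                     NA_real_)
      }
      events[[length(events) + 1L]] <- data.frame(
        parameter = sweep$parameter, value = (lo + hi) / 2, type = type,
        branch = tag, bracket_lo = lo, bracket_hi = hi, closed_form = cf)
    }
  }
  if (!length(events))
    return(data.frame(parameter = character(0L), value = numeric(0L),
                      type = character(0L), branch = character(0L),
                      bracket_lo = numeric(0L), bracket_hi = numeric(0L),
                      closed_form = numeric(0L)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Refine a branch-existence boundary
#'
#' Bisects the largest (or smallest) parameter value at which a predicate
#' on the enumerated equilibria still holds, between two sweep samples
#' where it differs.  Used for branch-existence windows, e.g. the upper
#' boundary of the tumor-bearing zero-cytokine branch.
#'
#' @param params a [parameter_set].
#' @param name swept parameter name.
#' @param lo,hi bracketing parameter values; the predicate must differ
#'   between them.
#' @param predicate `function(reports)` returning `TRUE`/`FALSE` on the
#'   list from [enumerate_equilibria()].
#' @param tol relative bracket tolerance.
#' @param n_scan scan resolution.
#' @return The refined boundary value (bracket midpoint).
#' @export
refine_existence_boundary <- function(params, name, lo, hi, predicate,
                                      tol = 1e-4, n_scan = 2000L) {
  p_at <- function(v)
    isTRUE(predicate(enumerate_equilibria(set_param(params, name, v),
                                          n_grid = n_scan)))
  plo <- p_at(lo)
  if (plo == p_at(hi)) stop("predicate does not differ across the bracket")
  while ((hi - lo) > tol * max(abs(hi), abs(lo))) {
    mid <- (lo + hi) / 2
    if (p_at(mid) == plo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Export a sweep as plain tables
#'
#' @param sweep a [bifurcation_sweep()].
#' @param events optional events from [locate_bifurcations()].
#' @return List with `branches` (long table: value, curve, branch, T,
#'   verdict) and `events`.
#' @export
diagram_table <- function(sweep, events = NULL) {
  stopifnot(inherits(sweep, "bifurcation_sweep"))
  s <- sweep$samples
  branches <- data.frame(value = s$value, curve = s$curve,
                         branch = s$branch, T = s$T, verdict = s$verdict)
  if (is.null(events))
    events <- data.frame(parameter = character(0L), value = numeric(0L),
                         type = character(0L), branch = character(0L))
  list(branches = branches, events = events)
}

#' @export
print.bifurcation_sweep <- function(x, ...) {
  cat(sprintf("Bifurcation sweep of '%s' over [%g, %g]: %d samples, %d curves\n",
              x$parameter, x$range[1L], x$range[2L],
              length(x$grid_values), max(x$samples$curve)))
  invisible(x)
}
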