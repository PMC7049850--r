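# Independent oracles used by the tests.

# Adams weights by integrating Lagrange basis polynomials over the step.
# This is a different algorithm from the package's backward-difference
# recurrence: the weight of node t_i is the integral over [-1, 0] of the
# Lagrange polynomial on the node set, computed by expanding the
# polynomial coefficients and integrating term by term.
lagrange_adams_oracle <- function(nodes) {
  vapply(seq_along(nodes), function(i) {
    co <- 1   # polynomial coefficients, ascending powers
    for (j in seq_along(nodes)[-i]) {
      # multiply by (t - nodes[j]) / (nodes[i] - nodes[j])
      co <- (c(0, co) - nodes[j] * c(co, 0)) / (nodes[i] - nodes[j])
    }
    pw <- seq_along(co)
    sum(co * (0 - (-1)^pw) / pw)   # integral over [-1, 0]
  }, numeric(1L))
}

oracle_bashforth <- function(k) lagrange_adams_oracle(-(1:k))
oracle_moulton   <- function(k) lagrange_adams_oracle(-(0:k))

# 2-D sign-pattern root scan: locate simultaneous zeros of two residual
# surfaces on a log-log grid by flagging grid cells in which both
# surfaces change sign, then recursively subdividing each flagged cell
# (cells where the curves pass close without intersecting stop flagging
# under refinement).  Mirrors the intersection-of-curves construction
# for equilibria; independent of the package's 1-D
# reduction-and-bisection path.
flag_cells <- function(f1, f2, x_grid, y_grid) {
  F1 <- outer(x_grid, y_grid, f1)
  F2 <- outer(x_grid, y_grid, f2)
  s1 <- sign(F1); s2 <- sign(F2)
  hits <- NULL
  for (i in seq_len(length(x_grid) - 1L))
    for (j in seq_len(length(y_grid) - 1L)) {
      c1 <- s1[i:(i + 1L), j:(j + 1L)]
      c2 <- s2[i:(i + 1L), j:(j + 1L)]
      if (any(is.na(c1)) || any(is.na(c2))) next
      if (max(c1) >= 0 && min(c1) <= 0 && max(c2) >= 0 && min(c2) <= 0)
        hits <- rbind(hits, c(x_grid[i], x_grid[i + 1L],
                              y_grid[j], y_grid[j + 1L]))
    }
  hits
}

grid_intersections <- function(f1, f2, x_grid, y_grid, depth = 3L,
                               nsub = 9L) {
  cells <- flag_cells(f1, f2, x_grid, y_grid)
  for (lev in seq_len(depth)) {
    if (is.null(cells)) return(NULL)
    nxt <- NULL
    for (r in seq_len(nrow(cells))) {
      sub <- flag_cells(f1, f2,
                        10^seq(log10(cells[r, 1]), log10(cells[r, 2]),
                               length.out = nsub),
                        10^seq(log10(cells[r, 3]), log10(cells[r, 4]),
                               length.out = nsub))
      nxt <- rbind(nxt, sub)
    }
    cells <- nxt
  }
  if (is.null(cells)) return(NULL)
  cbind(sqrt(cells[, 1] * cells[, 2]), sqrt(cells[, 3] * cells[, 4]))
}

# cluster nearby grid hits (log-space tolerance) into distinct roots
cluster_hits <- function(hits, tol = 0.2) {
  if (is.null(hits)) return(NULL)
  lx <- log10(hits[, 1L])
  keep <- NULL
  for (i in seq_len(nrow(hits))) {
    if (is.null(keep) ||
        all(abs(log10(keep[, 1L]) - lx[i]) > tol))
      keep <- rbind(keep, hits[i, , drop = FALSE])
  }
  keep
}
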