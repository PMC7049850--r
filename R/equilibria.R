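# Equilibria of the unforced six-state system, along three branches:
#   zero_tumor                     : T = 0 (closed form)
#   nonzero_tumor_zero_cytokine    : T > 0, I = 0, Y = 0
#   nonzero_tumor_nonzero_cytokine : T > 0, I > 0 (tumor sizes are the
#                                    positive roots of a cubic)
# plus Jacobians, eigenvalues and stability classification.

.equilibrium_point <- function(branch, state, params) {
  state <- stats::setNames(as.numeric(state), .state_names)
  r <- rhs_untreated(pmax(state, 0), params)
  sc <- pmax(.equation_scales(pmax(state, 0), params), 1e-300)
  structure(list(branch = branch, state = state,
                 residual = max(abs(r) / sc)),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf("Equilibrium (%s): residual %.2e\n", x$branch, x$residual))
  print(signif(x$state, 6))
  invisible(x)
}

#' Tumor-free equilibrium (closed form)
#'
#' The unique equilibrium with `T = 0`:
#' `(0, e*alpha/(f*beta), 0, 0, alpha/beta, 0)`.
#'
#' @param params a [parameter_set].
#' @return An `equilibrium_point` with branch `"zero_tumor"`.
#' @export
zero_tumor_equilibrium <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  with(unclass(params), .equilibrium_point(
    "zero_tumor",
    c(0, e * alpha / (f * beta), 0, 0, alpha / beta, 0), params))
}

#' Closed-form eigenvalues at the tumor-free equilibrium
#'
#' The linearization at the tumor-free point has eigenvalues
#' `a - c*e*alpha/(f*beta)`, `-f`, `-m`, `-mu1`, `-beta`, `-mu_i`;
#' only the first can be positive.
#'
#' @param params a [parameter_set].
#' @return Named numeric vector of the six eigenvalues, in that order.
#' @export
zero_tumor_eigenvalues <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  with(unclass(params),
    c(lambda1 = a - c * e * alpha / (f * beta), lambda2 = -f,
      lambda3 = -m, lambda4 = -mu1, lambda5 = -beta, lambda6 = -mu_i))
}

#' Analytic Jacobian at the tumor-free equilibrium
#'
#' The exact linearization of the untreated system at the tumor-free
#' point.  Note the `(2,1)` entry `-p*N_eq` (NK inactivation by the
#' tumor), which is part of the true linearization; it does not affect
#' the eigenvalues because the matrix is lower triangular apart from the
#' lymphocyte coupling `(2,5) = e`, whose row `C` decouples.
#'
#' @param params a [parameter_set].
#' @return 6x6 numeric matrix (rows/columns ordered `T, N, L, Y, C, I`).
#' @export
zero_tumor_jacobian <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  with(unclass(params), {
    Neq <- e * alpha / (f * beta)
    Ceq <- alpha / beta
    J <- matrix(0, 6L, 6L, dimnames = list(.state_names, .state_names))
    J[1L, 1L] <- a - c * Neq
    J[2L, 1L] <- -p * Neq
    J[2L, 2L] <- -f
    J[2L, 5L] <- e
    J[3L, 1L] <- r1 * Neq + r2 * Ceq
    J[3L, 3L] <- -m
    J[4L, 4L] <- -mu1
    J[5L, 5L] <- -beta
    J[6L, 6L] <- -mu_i
    J
  })
}

#' Tumor-free stability and the recurrence thresholds
#'
#' The tumor-free state is stable (an eradicated tumor cannot recur from
#' an infinitesimal seed) exactly when `a < c*e*alpha/(f*beta)`.  The
#' function also returns the two critical parameter values implied by
#' that condition: `a_crit = c*e*alpha/(f*beta)` and its inverse
#' `c_crit = a*f*beta/(e*alpha)`, which the bifurcation sweeps cross.
#'
#' @param params a [parameter_set].
#' @return List with `stable` (logical), `a_crit`, `c_crit`.
#' @export
tumor_free_stable <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  with(unclass(params), {
    a_crit <- c * e * alpha / (f * beta)
    list(stable = a < a_crit, a_crit = a_crit,
         c_crit = a * f * beta / (e * alpha))
  })
}

#' NK population at a tumor equilibrium
#'
#' The NK balance (production from lymphocytes, recruitment, turnover,
#' exhaustion) solved at a given equilibrium tumor size:
#' `N(T) = e*alpha*(h + T^2) / (beta*(p*T^3 + (f - g)*T^2 + p*h*T + f*h))`.
#'
#' @param T tumor cells (vectorized, >= 0).
#' @param params a [parameter_set].
#' @return NK cells at equilibrium; error if the denominator is not
#'   positive (no physical equilibrium at that `T`).
#' @export
nk_at_tumor <- function(T, params) {
  stopifnot(inherits(params, "parameter_set"), all(T >= 0))
  with(unclass(params), {
    den <- beta * (p * T^3 + (f - g) * T^2 + p * h * T + f * h)
    if (any(den <= 0))
      stop("no physical NK equilibrium at this tumor size (denominator <= 0)")
    e * alpha * (h + T^2) / den
  })
}

# Required lysis fraction at a nonzero-tumor equilibrium, given T and the
# cytokine level I (tumor balance solved for D).
.required_lysis <- function(T, I, params) {
  with(unclass(params),
       a * (1 - b * T) - c * nk_at_tumor(T, params) -
         c1 / (a1 + T) * I)
}

# CD8+ T balance residual at a candidate (T, I): positive-definite form
#   u N L^2 + (m - j D^2 T^2/(k + D^2 T^2) + q T - p_i I/(g_i + I)) L
#     - (r1 N + r2 alpha/beta) T
# with N, D, L all functions of (T, I).  NA where the branch is invalid
# (required lysis outside [0, d)).
.cd8_residual <- function(T, I, params) {
  N <- nk_at_tumor(T, params)
  D <- .required_lysis(T, I, params)
  with(unclass(params), {
    valid <- is.finite(D) & D >= 0 & D < d
    L <- ifelse(valid, (s * pmax(D, 0) / (d - pmax(D, 0)))^(1 / l) * T, NA)
    DT2 <- D^2 * T^2
    ifelse(valid,
           u * N * L^2 +
             (m - j * DT2 / (k + DT2) + q * T - p_i * I / (g_i + I)) * L -
             (r1 * N + r2 * alpha / beta) * T,
           NA_real_)
  })
}

# Root scan of the CD8+ T balance residual along one axis (tumor size at
# fixed I, or IL-2 level at fixed T).  Handles interior sign changes on
# the valid grid and, crucially, roots squeezed between the last valid
# grid point and a branch-validity boundary: where the required lysis
# fraction D crosses 0 the residual limit is -(r1 N + r2 alpha/beta) T
# (negative), and where D crosses d the implied CD8+ level diverges and
# the residual limit is +Inf, so an edge point of opposite sign
# guarantees a bracketed root.  `axis` selects which coordinate varies.
.scan_cd8_roots <- function(grid_vals, other, params,
                            axis = c("T", "I")) {
  axis <- match.arg(axis)
  resid <- function(x)
    if (axis == "T") .cd8_residual(x, other, params)
    else .cd8_residual(other, x, params)
  lysis <- function(x)
    if (axis == "T") .required_lysis(x, other, params)
    else .required_lysis(other, x, params)
  r <- resid(grid_vals)
  fin <- is.finite(r)
  roots <- numeric(0L)
  # interior sign changes between adjacent valid points
  for (i1 in which(fin[-length(fin)] & fin[-1L])) {
    if (r[i1] == 0) { roots <- c(roots, grid_vals[i1]); next }
    if (r[i1] * r[i1 + 1L] < 0)
      roots <- c(roots, .bisect_log(resid, grid_vals[i1],
                                    grid_vals[i1 + 1L]))
  }
  # validity-boundary brackets
  edges <- which(fin[-length(fin)] != fin[-1L])
  for (i1 in edges) {
    iv <- if (fin[i1]) i1 else i1 + 1L        # valid side
    ii <- if (fin[i1]) i1 + 1L else i1        # invalid side
    Dbad <- lysis(grid_vals[ii])
    lim_pos <- is.finite(Dbad) && Dbad >= params$d   # D -> d: residual +Inf
    if (!is.finite(Dbad)) next
    if ((lim_pos && r[iv] < 0) || (!lim_pos && r[iv] > 0)) {
      bfun <- if (lim_pos) function(x) lysis(x) - params$d else lysis
      Tb <- .bisect_log(bfun, min(grid_vals[iv], grid_vals[ii]),
                        max(grid_vals[iv], grid_vals[ii]))
      # pull just inside the valid region before bisecting the residual
      inside <- function(frac)
        exp(log(Tb) + frac * (log(grid_vals[iv]) - log(Tb)))
      frac <- 1e-12
      while (frac < 1 && !is.finite(resid(inside(frac)))) frac <- frac * 10
      xin <- inside(frac)
      if (is.finite(resid(xin)) && resid(xin) * r[iv] < 0)
        roots <- c(roots, .bisect_log(resid, min(grid_vals[iv], xin),
                                      max(grid_vals[iv], xin)))
    }
  }
  sort(roots)
}

# Bisection on a log axis; fun values at lo/hi must bracket a sign change.
.bisect_log <- function(fun, lo, hi, rel_tol = 1e-14, maxit = 200L) {
  flo <- fun(lo)
  for (it in seq_len(maxit)) {
    mid <- sqrt(lo * hi)
    fmid <- fun(mid)
    if (!is.finite(fmid)) stop("bisection hit an invalid region")
    if (flo * fmid <= 0) hi <- mid else { lo <- mid; flo <- fmid }
    if ((hi - lo) <= rel_tol * hi) break
  }
  sqrt(lo * hi)
}

#' Nonzero-tumor, zero-cytokine equilibria
#'
#' Scans tumor sizes over `(T_min, 1/b)` on a log grid.  At each `T` the
#' NK level, the required lysis fraction (with `I = 0`) and the implied
#' CD8+ T level are closed forms; sign changes of the remaining CD8+ T
#' balance residual are refined by bisection.  Tumor sizes whose required
#' lysis fraction falls outside `[0, d)` are branch-invalid and skipped.
#' `Y = I = 0` and `C = alpha/beta` at every point on this branch.
#'
#' @param params a [parameter_set].
#' @param n_grid number of scan points.
#' @param T_min lower end of the scan (cells).
#' @return List of `equilibrium_point`s (possibly empty), in increasing
#'   tumor size.
#' @export
zero_cytokine_equilibria <- function(params, n_grid = 2000L, T_min = 1) {
  stopifnot(inherits(params, "parameter_set"), n_grid >= 10L, T_min > 0)
  Tmax <- (1 - 1e-12) / params$b
  Tg <- 10^seq(log10(T_min), log10(Tmax), length.out = n_grid)
  roots <- .scan_cd8_roots(Tg, 0, params)
  lapply(roots, function(Tr) {
    D <- .required_lysis(Tr, 0, params)
    .equilibrium_point(
      "nonzero_tumor_zero_cytokine",
      c(Tr, nk_at_tumor(Tr, params), cd8_from_lysis(Tr, D, params),
        0, params$alpha / params$beta, 0), params)
  })
}

#' Candidate tumor sizes on the nonzero-cytokine branch
#'
#' On the branch with active CD4+/IL-2 loop the equilibrium tumor size
#' satisfies a cubic whose coefficients involve only `alpha1`, `alpha2`,
#' `mu1`, `delta2`, `beta1`, `beta2` and `mu_i`:
#' `T^3 + (alpha1 + alpha2 + mu1/delta2 - beta1*beta2/(delta2*mu_i))*T^2
#'  + (alpha1*alpha2 + (mu1*alpha2 + mu1*alpha1)/delta2)*T
#'  + mu1*alpha1*alpha2/delta2 = 0`.
#' Roots are found from the polynomial companion matrix and polished by
#' one Newton step; only real positive roots are returned.
#'
#' @param params a [parameter_set].
#' @return Numeric vector of positive real roots (possibly empty),
#'   increasing.
#' @export
cytokine_tumor_candidates <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  co <- with(unclass(params), c(
    mu1 * alpha1 * alpha2 / delta2,
    alpha1 * alpha2 + (mu1 * alpha2 + mu1 * alpha1) / delta2,
    alpha1 + alpha2 + mu1 / delta2 - beta1 * beta2 / (delta2 * mu_i),
    1))
  rt <- polyroot(co)
  re <- Re(rt)[abs(Im(rt)) <= 1e-8 * pmax(Mod(rt), 1)]
  re <- re[re > 0]
  if (!length(re)) return(numeric(0L))
  poly  <- function(x) ((x + co[3L]) * x + co[2L]) * x + co[1L]
  dpoly <- function(x) (3 * x + 2 * co[3L]) * x + co[2L]
  sort(re - poly(re) / dpoly(re))
}

#' Nonzero-tumor, nonzero-cytokine equilibria
#'
#' For each candidate tumor size from [cytokine_tumor_candidates()],
#' scans the IL-2 concentration over `I_range` on a log grid; at each `I`
#' the required lysis fraction and CD8+ T level are closed forms, and
#' sign changes of the CD8+ T balance residual are refined by bisection.
#' The CD4+ T level then follows from the IL-2 balance,
#' `Y = mu_i * I * (alpha2 + T) / (beta2 * T)`.  Only fully nonnegative
#' points with a small full-system residual are kept.
#'
#' @param params a [parameter_set].
#' @param n_grid number of IL-2 scan points.
#' @param I_range scan range for the IL-2 concentration.
#' @return List of `equilibrium_point`s (possibly empty).
#' @export
nonzero_cytokine_equilibria <- function(params, n_grid = 2000L,
                                        I_range = c(1e-3, 1e12)) {
  stopifnot(inherits(params, "parameter_set"))
  Ig <- 10^seq(log10(I_range[1L]), log10(I_range[2L]), length.out = n_grid)
  out <- list()
  for (Tc in cytokine_tumor_candidates(params)) {
    for (Ir in .scan_cd8_roots(Ig, Tc, params, axis = "I")) {
      D <- .required_lysis(Tc, Ir, params)
      if (!(D >= 0 && D < params$d)) next
      Y <- with(unclass(params), mu_i * Ir * (alpha2 + Tc) / (beta2 * Tc))
      pt <- .equilibrium_point(
        "nonzero_tumor_nonzero_cytokine",
        c(Tc, nk_at_tumor(Tc, params), cd8_from_lysis(Tc, D, params),
          Y, params$alpha / params$beta, Ir), params)
      if (all(pt$state >= 0) && pt$residual < 1e-4)
        out[[length(out) + 1L]] <- pt
    }
  }
  out
}

#' Numerical Jacobian of the untreated system
#'
#' Central finite differences of [rhs_untreated()] with per-component
#' step `max(1e-6 |x_i|, 1e-3)`; one-sided differences are used for any
#' component (e.g. `T = 0`) where a central stencil would leave the
#' nonnegative domain.
#'
#' @param state numeric state `(T, N, L, Y, C, I)`, components >= 0.
#' @param params a [parameter_set].
#' @return 6x6 numeric matrix.
#' @export
jacobian_matrix <- function(state, params) {
  stopifnot(inherits(params, "parameter_set"))
  y <- .check_state(state, 6L)
  J <- matrix(0, 6L, 6L, dimnames = list(.state_names, .state_names))
  for (i in seq_len(6L)) {
    hstep <- max(1e-6 * abs(y[i]), 1e-3)
    if (y[i] - hstep >= 0) {
      yp <- y; yp[i] <- y[i] + hstep
      ym <- y; ym[i] <- y[i] - hstep
      J[, i] <- (rhs_untreated(yp, params) - rhs_untreated(ym, params)) /
        (2 * hstep)
    } else {
      yp <- y; yp[i] <- y[i] + hstep
      yq <- y; yq[i] <- y[i] + 2 * hstep
      f0 <- rhs_untreated(y, params)
      # second-order one-sided stencil
      J[, i] <- (-3 * f0 + 4 * rhs_untreated(yp, params) -
                   rhs_untreated(yq, params)) / (2 * hstep)
    }
  }
  J
}

#' Classify the stability of an equilibrium point
#'
#' Eigenvalues of the (numerical) Jacobian at the point; the verdict is
#' `"stable"` if the largest real part is negative, `"unstable"` if
#' positive, and `"marginal"` (verdict withheld) if it lies within
#' `marginal_tol * max(1, spectral radius)` of zero — bifurcation sweeps
#' pass through zero eigenvalues, where a sign verdict is meaningless.
#'
#' @param point an `equilibrium_point` (or a bare 6-state vector).
#' @param params a [parameter_set].
#' @param marginal_tol half-width of the marginal band, relative.
#' @return A `stability_report`: list with `point`, `eigenvalues`
#'   (complex), `margin` (max real part), `verdict`.
#' @export
classify_equilibrium <- function(point, params, marginal_tol = 1e-8) {
  if (inherits(point, "equilibrium_point")) {
    state <- point$state
  } else {
    state <- point
    point <- .equilibrium_point("unlabelled", state, params)
  }
  ev <- eigen(jacobian_matrix(state, params), only.values = TRUE)$values
  margin <- max(Re(ev))
  band <- marginal_tol * max(1, max(Mod(ev)))
  verdict <- if (abs(margin) < band) "marginal"
             else if (margin < 0) "stable" else "unstable"
  structure(list(point = point, eigenvalues = ev, margin = margin,
                 verdict = verdict),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s equilibrium: %s (max Re(lambda) = %.4g)\n",
              x$point$branch, x$verdict, x$margin))
  cat("eigenvalues:", paste(format(signif(x$eigenvalues, 4)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate and classify all equilibria
#'
#' Runs the three branch solvers and classifies every point.
#'
#' @param params a [parameter_set].
#' @param n_grid scan resolution passed to the branch solvers.
#' @return List of `stability_report`s.
#' @export
enumerate_equilibria <- function(params, n_grid = 2000L) {
  pts <- c(list(zero_tumor_equilibrium(params)),
           zero_cytokine_equilibria(params, n_grid = n_grid),
           nonzero_cytokine_equilibria(params, n_grid = n_grid))
  lapply(pts, classify_equilibrium, params = params)
}

#' Tabulate equilibria in the layout of a stability-results table
#'
#' @param params a [parameter_set].
#' @param n_grid scan resolution.
#' @return Data frame with branch, the six state components, verdict,
#'   stability margin and residual, one row per equilibrium.
#' @export
equilibria_table <- function(params, n_grid = 2000L) {
  reps <- enumerate_equilibria(params, n_grid = n_grid)
  do.call(rbind, lapply(reps, function(rp) {
    data.frame(branch = rp$point$branch,
               t(rp$point$state),
               verdict = rp$verdict,
               margin = rp$margin,
               residual = rp$point$residual,
               row.names = NULL, check.names = FALSE)
  }))
}
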