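# Right-hand sides of the untreated (6-state) and treated (7-state) systems.

.state_names   <- c("T", "N", "L", "Y", "C", "I")
.state_names7  <- c("T", "N", "L", "Y", "C", "I", "M")
.dose_names    <- c("v_M", "v_I", "v_L", "v_Y")

#' Fractional tumor lysis by CD8+ T cells
#'
#' Saturating kill fraction `D = d (L/T)^l / (s + (L/T)^l)`, evaluated in
#' the algebraically equivalent form `d L^l / (s T^l + L^l)` so that the
#' limits at vanishing populations are well defined: `D = 0` when `L = 0`
#' (including `T = L = 0`) and `D = d` when `T = 0` with `L > 0`.  This
#' preserves `D * T -> 0` as `T -> 0` and avoids a 0/0 at the origin.
#'
#' @param T tumor cells (vectorized, >= 0).
#' @param L CD8+ T cells (vectorized, >= 0).
#' @param params a [parameter_set].
#' @return Lysis fraction in day^-1, in `[0, d]`.
#' @export
lysis_fraction <- function(T, L, params) {
  stopifnot(inherits(params, "parameter_set"))
  if (any(!is.finite(T)) || any(!is.finite(L)))
    stop("non-finite populations")
  if (any(T < 0) || any(L < 0))
    stop("populations must be nonnegative")
  d <- params$d; s <- params$s; l <- params$l
  num <- L^l
  den <- s * T^l + num
  out <- ifelse(den > 0, d * num / den, 0)
  # T = 0, L > 0: den = num, ratio exactly 1
  out
}

#' Invert the lysis relation for the CD8+ T population
#'
#' Returns the unique `L >= 0` with `lysis_fraction(T, L) = D`, i.e.
#' `L = (s D / (d - D))^(1/l) * T`.
#'
#' @param T tumor cells (> 0, vectorized).
#' @param D target lysis fraction, `0 <= D < d`.
#' @param params a [parameter_set].
#' @return CD8+ T cells.
#' @export
cd8_from_lysis <- function(T, D, params) {
  stopifnot(inherits(params, "parameter_set"))
  if (any(D < 0) || any(D >= params$d))
    stop("lysis target must satisfy 0 <= D < d")
  (params$s * D / (params$d - D))^(1 / params$l) * T
}

.check_state <- function(state, n) {
  if (length(state) != n) stop("state must have length ", n)
  if (any(!is.finite(state))) stop("non-finite state")
  if (any(state < 0)) stop("state components must be nonnegative")
  unname(state)
}

#' Untreated model right-hand side
#'
#' Time derivatives of the six-state system (tumor `T`, natural killers
#' `N`, CD8+ T `L`, CD4+ T `Y`, circulating lymphocytes `C`, IL-2 `I`):
#' logistic tumor growth minus NK kill, CD8+ lysis and cytokine kill; NK
#' production from lymphocytes with tumor-induced recruitment and
#' exhaustion; CD8+ turnover, recruitment, stimulation, NK regulation and
#' IL-2 activation; CD4+ production by IL-2 with tumor-interaction loss;
#' constant lymphocyte source with linear turnover; IL-2 secretion by
#' CD4+ T cells with linear decay.
#'
#' @param state numeric vector `(T, N, L, Y, C, I)`, all components >= 0.
#' @param params a [parameter_set].
#' @return Named numeric vector of the six derivatives (per day).
#' @export
rhs_untreated <- function(state, params) {
  stopifnot(inherits(params, "parameter_set"))
  y <- .check_state(state, 6L)
  T <- y[1L]; N <- y[2L]; L <- y[3L]; Y <- y[4L]; C <- y[5L]; I <- y[6L]
  D <- lysis_fraction(T, L, params)
  with(unclass(params), {
    DT2 <- D^2 * T^2
    c(T = a * T * (1 - b * T) - c * N * T - D * T - c1 * T / (a1 + T) * I,
      N = e * C - f * N + g * T^2 / (h + T^2) * N - p * N * T,
      L = -m * L + j * DT2 / (k + DT2) * L - q * L * T +
          r1 * N * T + r2 * C * T - u * N * L^2 + p_i * I / (g_i + I) * L,
      Y = beta1 * T / (alpha1 + T) * I - mu1 * Y - delta2 * T * Y,
      C = alpha - beta * C,
      I = -mu_i * I + beta2 * T / (alpha2 + T) * Y)
  })
}

#' Treated model right-hand side
#'
#' Seven-state system: the untreated dynamics plus chemotherapy kill terms
#' `-K_X (1 - exp(-M)) X` on tumor, NK, CD8+ T and lymphocytes, additive
#' dose inputs on CD8+ T (`v_L`), CD4+ T (`v_Y`) and IL-2 (`v_I`), and the
#' drug compartment `dM/dt = -gamma M + v_M`.  With all doses zero and
#' `M = 0` the first six components reduce exactly to [rhs_untreated()].
#'
#' @param state numeric vector `(T, N, L, Y, C, I, M)`, components >= 0.
#' @param params a [parameter_set].
#' @param doses numeric vector `(v_M, v_I, v_L, v_Y)` of dose rates >= 0.
#' @return Named numeric vector of the seven derivatives.
#' @export
rhs_treated <- function(state, params, doses = c(0, 0, 0, 0)) {
  stopifnot(inherits(params, "parameter_set"))
  y <- .check_state(state, 7L)
  if (length(doses) != 4L || any(doses < 0) || any(!is.finite(doses)))
    stop("doses must be four nonnegative rates (v_M, v_I, v_L, v_Y)")
  doses <- unname(doses)
  base <- rhs_untreated(y[1:6], params)
  M <- y[7L]
  chemo <- 1 - exp(-M)
  with(unclass(params), {
    out <- c(base[1L] - K_T * chemo * y[1L],
             base[2L] - K_N * chemo * y[2L],
             base[3L] - K_L * chemo * y[3L] + doses[3L],
             base[4L] + doses[4L],
             base[5L] - K_C * chemo * y[5L],
             base[6L] + doses[2L],
             -gamma * M + doses[1L])
    names(out) <- .state_names7
    out
  })
}

# Per-equation magnitude scales: the largest absolute individual term of
# each untreated equation at `state`.  Used to judge equilibrium residuals
# relative to the sizes of the terms that cancel.
.equation_scales <- function(state, params) {
  y <- unname(state)
  T <- y[1L]; N <- y[2L]; L <- y[3L]; Y <- y[4L]; C <- y[5L]; I <- y[6L]
  D <- lysis_fraction(T, L, params)
  with(unclass(params), {
    DT2 <- D^2 * T^2
    c(max(abs(a * T * (1 - b * T)), c * N * T, D * T, c1 * T / (a1 + T) * I),
      max(e * C, f * N, g * T^2 / (h + T^2) * N, p * N * T),
      max(m * L, j * DT2 / (k + DT2) * L, q * L * T, r1 * N * T,
          r2 * C * T, u * N * L^2, p_i * I / (g_i + I) * L),
      max(beta1 * T / (alpha1 + T) * I, mu1 * Y, delta2 * T * Y),
      max(alpha, beta * C),
      max(mu_i * I, beta2 * T / (alpha2 + T) * Y))
  })
}

# Fast closure over one parameter set for the integrator: doses fixed per
# segment, no argument validation in the hot loop.  Negative components
# are clamped to zero before evaluation: the model is defined on the
# nonnegative orthant, but the explicit predictor can overshoot it
# transiently, and the non-integer powers in the lysis term would turn
# such excursions into NaN.
.make_rhs_treated <- function(params) {
  pp <- unclass(params)
  a <- pp$a; a1 <- pp$a1; b <- pp$b; cc <- pp$c; c1 <- pp$c1; d <- pp$d
  e <- pp$e; f <- pp$f; g <- pp$g; g_i <- pp$g_i; h <- pp$h; j <- pp$j
  k <- pp$k; K_T <- pp$K_T; K_N <- pp$K_N; K_L <- pp$K_L; K_C <- pp$K_C
  l <- pp$l; m <- pp$m; p <- pp$p; p_i <- pp$p_i; q <- pp$q; r1 <- pp$r1
  r2 <- pp$r2; s <- pp$s; u <- pp$u; alpha <- pp$alpha; alpha1 <- pp$alpha1
  alpha2 <- pp$alpha2; beta <- pp$beta; beta1 <- pp$beta1; beta2 <- pp$beta2
  gamma <- pp$gamma; mu1 <- pp$mu1; mu_i <- pp$mu_i; delta2 <- pp$delta2
  function(y, doses) {
    y[y < 0] <- 0
    T <- y[1L]; N <- y[2L]; L <- y[3L]; Y <- y[4L]; C <- y[5L]
    I <- y[6L]; M <- y[7L]
    Ll <- L^l
    den <- s * T^l + Ll
    D <- if (den > 0) d * Ll / den else 0
    DT2 <- D * D * T * T
    chemo <- 1 - exp(-M)
    tsat <- T / (alpha2 + T)
    c(a * T * (1 - b * T) - cc * N * T - D * T - c1 * T / (a1 + T) * I -
        K_T * chemo * T,
      e * C - f * N + g * T * T / (h + T * T) * N - p * N * T -
        K_N * chemo * N,
      -m * L + j * DT2 / (k + DT2) * L - q * L * T + r1 * N * T +
        r2 * C * T - u * N * L * L + p_i * I / (g_i + I) * L -
        K_L * chemo * L + doses[3L],
      beta1 * T / (alpha1 + T) * I - mu1 * Y - delta2 * T * Y + doses[4L],
      alpha - beta * C - K_C * chemo * C,
      -mu_i * I + beta2 * tsat * Y + doses[2L],
      -gamma * M + doses[1L])
  }
}
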