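# Adams-Bashforth / Adams-Moulton coefficients as exact rationals.
#
# The weights are generated from the backward-difference form of the Adams
# formulas: y_n = y_{n-1} + h * sum_j gamma_j grad^j f, where the gamma_j
# follow the classical rational recurrences
#   gamma_0 = 1,  gamma_m   = 1 - sum_{l<m} gamma_l / (m + 1 - l)   (explicit)
#   gamma*_0 = 1, gamma*_m  =   - sum_{l<m} gamma*_l / (m + 1 - l)  (implicit)
# and the nodal weights come from expanding the backward differences with
# binomial coefficients.  All arithmetic is exact: numerators and
# denominators stay below 2^53 for orders up to 12, which is checked at
# every operation, so the tables carry no transcription or roundoff error.
# Floats are derived once at the end.

.rat_check <- function(x) {
  if (any(abs(x) >= 2^53)) stop("rational overflow in Adams coefficients")
  x
}

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.rat <- function(num, den = 1) {
  num <- unname(num); den <- unname(den)
  if (den < 0) { num <- -num; den <- -den }
  g <- .rat_gcd(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num = .rat_check(num), den = den)
}

.rat_add <- function(x, y) {
  g <- .rat_gcd(x[2L], y[2L])
  dy <- y[2L] / g
  .rat(.rat_check(x[1L] * dy) + .rat_check(y[1L] * (x[2L] / g)),
       .rat_check(x[2L] * dy))
}

.rat_mul <- function(x, y) {
  g1 <- .rat_gcd(abs(x[1L]), y[2L])
  g2 <- .rat_gcd(abs(y[1L]), x[2L])
  .rat(.rat_check((x[1L] / g1) * (y[1L] / g2)),
       .rat_check((x[2L] / g2) * (y[2L] / g1)))
}

# gamma recurrence; explicit = TRUE gives the Adams-Bashforth gammas.
.adams_gamma <- function(n, explicit) {
  gam <- vector("list", n + 1L)
  gam[[1L]] <- .rat(1)
  for (m in seq_len(n)) {
    acc <- if (explicit) .rat(1) else .rat(0)
    for (l in 0:(m - 1L))
      acc <- .rat_add(acc, .rat_mul(gam[[l + 1L]], .rat(-1, m + 1L - l)))
    gam[[m + 1L]] <- acc
  }
  gam
}

.adams_table <- function(k, explicit) {
  # nodal weights: explicit uses gamma_0..gamma_{k-1} on f_{n-1}..f_{n-k};
  # implicit uses gamma*_0..gamma*_k on f_n..f_{n-k}.
  nj <- if (explicit) k - 1L else k
  gam <- .adams_gamma(nj, explicit)
  nw <- nj + 1L
  out <- vector("list", nw)
  for (r in 0:nj) {
    acc <- .rat(0)
    for (jj in r:nj)
      acc <- .rat_add(acc, .rat_mul(gam[[jj + 1L]],
                                    .rat((-1)^r * choose(jj, r))))
    out[[r + 1L]] <- acc
  }
  m <- do.call(rbind, out)
  list(num = unname(m[, "num"]), den = unname(m[, "den"]))
}

.adams_cache <- new.env(parent = emptyenv())

#' Adams multistep coefficients
#'
#' `adams_bashforth(k)` returns the `k` weights of the explicit `k`-step
#' Adams-Bashforth formula (applied to `f` at `t_{n-1}, ..., t_{n-k}`);
#' `adams_moulton(k)` returns the `k + 1` weights of the implicit
#' Adams-Moulton formula with history length `k` (applied at
#' `t_n, t_{n-1}, ..., t_{n-k}`).  Weights are interpolatory: exact for
#' polynomial integrands up to degree `k - 1` (Bashforth) or `k`
#' (Moulton), and in each case they sum to exactly 1.
#'
#' @param k number of history points; 1-12 for Bashforth, 0-12 for
#'   Moulton (`k = 0` is backward Euler, `k = 1` the trapezoidal rule).
#' @return An `adams_coefficients` object: list with integer-valued
#'   `num`, `den` (exact rationals) and their double quotient `value`,
#'   ordered from the most recent node.
#' @export
adams_bashforth <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 12L) stop("order k must be in 1..12")
  key <- paste0("ab", k)
  if (is.null(.adams_cache[[key]])) {
    tab <- .adams_table(k, explicit = TRUE)
    tab$value <- tab$num / tab$den
    .adams_cache[[key]] <- structure(tab, method = "bashforth", k = k,
                                     class = "adams_coefficients")
  }
  .adams_cache[[key]]
}

#' @rdname adams_bashforth
#' @export
adams_moulton <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > 12L) stop("history length k must be in 0..12")
  key <- paste0("am", k)
  if (is.null(.adams_cache[[key]])) {
    tab <- .adams_table(k, explicit = FALSE)
    tab$value <- tab$num / tab$den
    .adams_cache[[key]] <- structure(tab, method = "moulton", k = k,
                                     class = "adams_coefficients")
  }
  .adams_cache[[key]]
}

#' @export
print.adams_coefficients <- function(x, ...) {
  cat(sprintf("Adams-%s coefficients, k = %d:\n",
              attr(x, "method"), attr(x, "k")))
  cat(paste(sprintf("%.0f/%.0f", x$num, x$den), collapse = ", "), "\n")
  invisible(x)
}
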