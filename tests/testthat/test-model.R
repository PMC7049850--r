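test_that("lysis fraction has the right limits and saturation", {
  expect_equal(lysis_fraction(1e5, 0, p1), 0)
  expect_equal(lysis_fraction(0, 0, p1), 0)
  # T -> 0 with L > 0 saturates at d
  expect_equal(lysis_fraction(0, 10, p1), p1$d)
  expect_equal(lysis_fraction(1e-12, 10, p1), p1$d, tolerance = 1e-9)
  # half-saturation: L/T chosen so (L/T)^l = s gives d/2
  Tv <- 1e6
  Lv <- Tv * p1$s^(1 / p1$l)
  expect_equal(lysis_fraction(Tv, Lv, p1), p1$d / 2)
  expect_equal(p1$d / 2, 1.17)
  expect_error(lysis_fraction(-1, 1, p1), "nonnegative")
  expect_error(lysis_fraction(1, -1, p1), "nonnegative")
})

test_that("lysis fraction is monotone in L and bounded by d (grid)", {
  Ts <- 10^seq(0, 9, length.out = 50)
  Ls <- 10^seq(-2, 8, length.out = 50)
  for (Tv in Ts) {
    D <- lysis_fraction(rep(Tv, 50), Ls, p1)
    expect_true(all(diff(D) >= -1e-15))
    expect_true(all(D >= 0 & D <= p1$d))
  }
})

test_that("inverting the lysis relation round-trips", {
  expect_equal(cd8_from_lysis(1e6, 0, p1), 0)
  expect_equal(cd8_from_lysis(1e6, p1$d / 2, p1), p1$s^(1 / p1$l) * 1e6)
  Ts <- 10^seq(2, 8, length.out = 12)
  Ds <- seq(0.01, 0.99, length.out = 12) * p1$d
  for (Tv in Ts) for (Dv in Ds) {
    L <- cd8_from_lysis(Tv, Dv, p1)
    expect_equal(lysis_fraction(Tv, L, p1), Dv, tolerance = 1e-10)
  }
  expect_error(cd8_from_lysis(1e6, p1$d, p1), "0 <= D < d")
})

test_that("untreated RHS vanishes at the tumor-free equilibrium", {
  eq <- c(0, 315534, 0, 0, 6.25e10, 0)   # published values
  r <- rhs_untreated(eq, p1)
  expect_lt(max(abs(r)) / p1$alpha, 1e-4)   # rounded published N
  exact <- zero_tumor_equilibrium(p1)$state
  expect_lt(max(abs(rhs_untreated(exact, p1))) / p1$alpha, 1e-12)
})

test_that("untreated RHS matches hand evaluation on sparse states", {
  # tumor only: all other populations zero
  r <- rhs_untreated(c(1e6, 0, 0, 0, 0, 0), p1)
  expect_equal(unname(r[1]), p1$a * 1e6 * (1 - p1$b * 1e6))
  expect_equal(unname(r[2:4]), c(0, 0, 0))
  expect_equal(unname(r[5]), p1$alpha)
  expect_equal(unname(r[6]), 0)
  # lymphocyte fixed point C = alpha/beta
  r2 <- rhs_untreated(c(0, 0, 0, 0, p1$alpha / p1$beta, 0), p1)
  expect_equal(unname(r2[5]), 0)
})

test_that("tumor-free rates vanish for randomized parameter sets", {
  set.seed(42)
  for (rep in 1:20) {
    pp <- perturb_params(p1)
    eq <- zero_tumor_equilibrium(pp)$state
    r <- rhs_untreated(eq, pp)
    scales <- pmax(tumorimmune:::.equation_scales(eq, pp), 1e-300)
    expect_lt(max(abs(r) / scales), 1e-10)
  }
})

test_that("lymphocyte equation depends only on C", {
  st <- c(1e6, 1e3, 1e2, 1e5, 6e8, 1e4)
  base <- rhs_untreated(st, p1)[5]
  for (i in c(1:4, 6)) {
    st2 <- st; st2[i] <- st2[i] * 7 + 3
    expect_identical(rhs_untreated(st2, p1)[5], base)
  }
})

test_that("treated RHS reduces exactly to the untreated system", {
  states <- list(c(1e6, 1e3, 10, 1e6, 6e8, 0),
                 c(0, 315534, 0, 0, 6.25e10, 0),
                 c(1e7, 50, 1e5, 1e4, 1e9, 1e3))
  for (st in states) {
    tr <- rhs_treated(c(st, 0), p1, c(0, 0, 0, 0))
    expect_identical(unname(tr[1:6]), unname(rhs_untreated(st, p1)))
    expect_identical(unname(tr[7]), 0)
  }
})

test_that("treated RHS handles doses and chemotherapy saturation", {
  st <- c(1e6, 1e3, 10, 1e6, 6e8, 0, 0)
  r <- rhs_treated(st, p1, c(5, 0, 0, 0))
  expect_equal(unname(r[7]), 5)
  r2 <- rhs_treated(st, p1, c(0, 2, 3, 4))
  r0 <- rhs_treated(st, p1, c(0, 0, 0, 0))
  expect_equal(unname(r2[6] - r0[6]), 2)
  expect_equal(unname(r2[3] - r0[3]), 3)
  expect_equal(unname(r2[4] - r0[4]), 4)
  # saturation of the chemo kill at large drug concentration
  stM <- c(1e6, 1e3, 10, 1e6, 6e8, 0, 700)
  rM <- rhs_treated(stM, p1, c(0, 0, 0, 0))
  expect_equal(unname(rM[1]),
               unname(rhs_untreated(stM[1:6], p1)[1]) - p1$K_T * 1e6)
  expect_error(rhs_treated(st, p1, c(-1, 0, 0, 0)), "nonnegative")
  expect_error(rhs_untreated(c(-1, 0, 0, 0, 0, 0), p1), "nonnegative")
  expect_error(rhs_untreated(c(Inf, 0, 0, 0, 0, 0), p1), "non-finite")
})
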