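test_that("the tumor-free equilibrium matches its closed form", {
  for (pp in list(p1, p2)) {
    eq <- zero_tumor_equilibrium(pp)
    expect_equal(eq$branch, "zero_tumor")
    expect_equal(unname(eq$state[2]),
                 pp$e * pp$alpha / (pp$f * pp$beta))
    expect_equal(unname(eq$state[5]), pp$alpha / pp$beta)
    expect_equal(unname(eq$state[c(1, 3, 4, 6)]), rep(0, 4))
    expect_lt(eq$residual, 1e-12)
  }
  # both patients share the published values
  expect_equal(unname(zero_tumor_equilibrium(p1)$state[2]), 315534,
               tolerance = 1e-6)
  expect_equal(unname(zero_tumor_equilibrium(p2)$state[5]), 6.25e10)
  # parameter combination with e*alpha = f*beta gives N = 1
  pp <- parameter_set(utils::modifyList(ref_patient1,
    list(e = 0.2, alpha = 0.3, f = 0.6, beta = 0.1)))
  expect_equal(unname(zero_tumor_equilibrium(pp)$state[2]), 1)
})

test_that("tumor-free eigenvalues and stability threshold are closed form", {
  ev <- zero_tumor_eigenvalues(p1)
  expect_equal(unname(ev[2:6]), -c(0.0412, 0.204, 0.1, 0.012, 10))
  expect_gt(ev[1], 0)
  thr <- tumor_free_stable(p1)
  expect_false(thr$stable)
  expect_rel(thr$a_crit, 2.02257e-5, 2.5e-6)
  expect_rel(thr$c_crit, 1.365e-6, 2e-3)
  # lowering the growth rate below the threshold stabilizes the state
  lowa <- set_param(p1, "a", 1e-5)
  expect_true(tumor_free_stable(lowa)$stable)
  expect_lt(zero_tumor_eigenvalues(lowa)[1], 0)
  # the leading eigenvalue flips sign exactly at the threshold
  expect_lt(zero_tumor_eigenvalues(
    set_param(p1, "a", thr$a_crit * 0.999))[1], 0)
  expect_gt(zero_tumor_eigenvalues(
    set_param(p1, "a", thr$a_crit * 1.001))[1], 0)
})

test_that("NK balance reproduces published equilibrium values", {
  expect_equal(nk_at_tumor(1.90609e7, p1), 199.335, tolerance = 1e-4)
  expect_equal(nk_at_tumor(1.27423e6, p2), 2824.14, tolerance = 1e-4)
  # limit at T = 0 recovers the tumor-free value
  expect_equal(nk_at_tumor(0, p1), p1$e * p1$alpha / (p1$f * p1$beta))
})

test_that("zero-cytokine equilibria match the published table", {
  zc1 <- zero_cytokine_equilibria(p1)
  expect_gte(length(zc1), 1)
  st <- zc1[[1]]$state
  expect_equal(unname(st[1]), 1.90609e7, tolerance = 1e-5)
  expect_equal(unname(st[2]), 199.335, tolerance = 1e-4)
  expect_equal(unname(st[3]), 2.82461e6, tolerance = 1e-5)
  expect_equal(unname(st[4]), 0)
  expect_equal(unname(st[5]), 6.25e10)
  expect_equal(unname(st[6]), 0)
  zc2 <- zero_cytokine_equilibria(p2)
  st2 <- zc2[[1]]$state
  expect_equal(unname(st2[1]), 1.27423e6, tolerance = 1e-5)
  expect_equal(unname(st2[2]), 2824.14, tolerance = 1e-4)
  expect_equal(unname(st2[3]), 450073, tolerance = 1e-5)
  for (pt in c(zc1, zc2)) expect_lt(pt$residual, 1e-6)
})

test_that("the cytokine-branch cubic has the published tumor size", {
  for (pp in list(p1, p2)) {
    Tc <- cytokine_tumor_candidates(pp)
    expect_equal(length(Tc), 2L)
    expect_equal(max(Tc), 3.50643e6, tolerance = 1e-5)
    expect_true(min(Tc) > 1e2 && min(Tc) < 1e4)
  }
  # the cubic involves only shared parameters: identical roots
  expect_equal(cytokine_tumor_candidates(p1), cytokine_tumor_candidates(p2))
})

test_that("nonzero-cytokine equilibria match the published table", {
  nz2 <- nonzero_cytokine_equilibria(p2)
  expect_equal(length(nz2), 1L)
  st <- nz2[[1]]$state
  expect_equal(unname(st[1]), 3.50643e6, tolerance = 1e-5)
  expect_equal(unname(st[2]), 1030.37, tolerance = 1e-4)
  expect_equal(unname(st[3]), 952787, tolerance = 1e-5)
  expect_equal(unname(st[4]), 4.55393e6, tolerance = 1e-5)
  expect_equal(unname(st[6]), 2.45842e6, tolerance = 1e-5)
  # IL-2 balance identity used in the construction
  expect_equal(st[["Y"]] * p2$beta2 * st[["T"]] / (p2$alpha2 + st[["T"]]),
               p2$mu_i * st[["I"]], tolerance = 1e-8)
  # the first patient has no equilibrium on this branch
  expect_equal(length(nonzero_cytokine_equilibria(p1)), 0L)
})

test_that("a 2-D intersection scan reproduces the 1-D reduction roots", {
  # T-L plane: tumor balance and CD8+ balance as two residual surfaces
  for (pp in list(p1, p2)) {
    f1 <- function(T, L) pp$a * (1 - pp$b * T) - pp$c * nk_at_tumor(T, pp) -
      lysis_fraction(T, L, pp)
    f3 <- function(T, L) {
      N <- nk_at_tumor(T, pp)
      vapply(seq_along(T), function(i)
        rhs_untreated(c(T[i], N[i], L[i], 0, pp$alpha / pp$beta, 0), pp)[3],
        numeric(1))
    }
    hits <- cluster_hits(grid_intersections(
      f1, f3, 10^seq(3, log10((1 - 1e-5) / pp$b), length.out = 300),
      10^seq(2, 9, length.out = 300)), tol = 0.15)
    found <- sort(vapply(zero_cytokine_equilibria(pp),
                         function(e) e$state[["T"]], numeric(1)))
    expect_equal(nrow(hits), length(found))
    expect_equal(sort(hits[, 1]), found, tolerance = 0.05)
  }
  # I-L plane at the cubic tumor size for the second patient
  Tc <- max(cytokine_tumor_candidates(p2))
  g1 <- function(I, L) p2$a * (1 - p2$b * Tc) -
    p2$c * nk_at_tumor(Tc, p2) - p2$c1 * I / (p2$a1 + Tc) -
    lysis_fraction(rep(Tc, length(L)), L, p2)
  g3 <- function(I, L) {
    N <- nk_at_tumor(Tc, p2)
    vapply(seq_along(I), function(i)
      rhs_untreated(c(Tc, N, L[i], 0, p2$alpha / p2$beta, I[i]), p2)[3],
      numeric(1))
  }
  hits <- cluster_hits(grid_intersections(
    g1, g3, 10^seq(3, 9, length.out = 300), 10^seq(3, 8, length.out = 300)),
    tol = 0.15)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits[1, 1], 2.45842e6, tolerance = 0.05)
  expect_equal(hits[1, 2], 952787, tolerance = 0.05)
})

test_that("doubling the scan grid leaves equilibria unchanged to 1e-4", {
  for (pp in list(p1, p2)) {
    coarse <- zero_cytokine_equilibria(pp, n_grid = 2000)
    fine <- zero_cytokine_equilibria(pp, n_grid = 4000)
    expect_equal(length(coarse), length(fine))
    for (i in seq_along(coarse))
      expect_equal(coarse[[i]]$state, fine[[i]]$state, tolerance = 1e-4)
  }
  c2 <- nonzero_cytokine_equilibria(p2, n_grid = 2000)
  f2 <- nonzero_cytokine_equilibria(p2, n_grid = 4000)
  expect_equal(length(c2), length(f2))
  expect_equal(c2[[1]]$state, f2[[1]]$state, tolerance = 1e-4)
})

test_that("numerical Jacobian matches the analytic tumor-free linearization", {
  eq <- zero_tumor_equilibrium(p1)$state
  J <- jacobian_matrix(eq, p1)
  Ja <- zero_tumor_jacobian(p1)
  expect_equal(J, Ja, tolerance = 1e-6)
  expect_equal(J[1, 1], p1$a - p1$c * p1$e * p1$alpha / (p1$f * p1$beta),
               tolerance = 1e-6, ignore_attr = TRUE)
  # eigenvalues agree with the closed forms
  evn <- sort(Re(eigen(J, only.values = TRUE)$values))
  expect_equal(evn, sort(unname(zero_tumor_eigenvalues(p1))),
               tolerance = 1e-6)
})

test_that("classification agrees with the closed-form threshold (random sets)", {
  set.seed(7)
  n_checked <- 0
  for (rep in 1:200) {
    pp <- perturb_params(p1)
    rp <- classify_equilibrium(zero_tumor_equilibrium(pp), pp)
    if (rp$verdict == "marginal") next
    n_checked <- n_checked + 1
    expect_identical(rp$verdict == "stable", tumor_free_stable(pp)$stable)
  }
  expect_gt(n_checked, 190)
})

test_that("published equilibria are classified unstable; a stable case exists", {
  for (rp in enumerate_equilibria(p1)) expect_lt(rp$point$residual, 1e-6)
  et1 <- equilibria_table(p1)
  expect_identical(et1$verdict[et1$branch == "zero_tumor"], "unstable")
  expect_identical(et1$verdict[abs(et1$T - 1.90609e7) < 1e3], "unstable")
  et2 <- equilibria_table(p2)
  expect_identical(et2$verdict[et2$branch == "zero_tumor"], "unstable")
  expect_identical(et2$verdict[abs(et2$T - 1.27423e6) < 1e2], "unstable")
  expect_identical(et2$verdict[abs(et2$T - 3.50643e6) < 1e2], "unstable")
  # below the recurrence threshold the tumor-free state is stable
  rp <- classify_equilibrium(
    zero_tumor_equilibrium(set_param(p1, "a", 1e-5)),
    set_param(p1, "a", 1e-5))
  expect_identical(rp$verdict, "stable")
})
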