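# Reference parameter values for the two patients, hardcoded
# independently of the YAML fixtures so the fixtures themselves are under
# test, plus small helpers shared across test files.

ref_patient1 <- list(
  a = 4.31e-1, a1 = 1e5, b = 1.02e-9, c = 6.41e-11, c1 = 0.2, d = 2.34,
  e = 2.08e-7, f = 4.12e-2, g = 1.25e-2, g_i = 2e7, h = 2.02e7,
  j = 2.49e-2, k = 3.66e7, K_T = 0.9, K_N = 0.6, K_L = 0.6, K_C = 0.6,
  l = 2.09, m = 2.04e-1, p = 3.42e-6, p_i = 1.25e-1, q = 1.42e-6,
  r1 = 1.1e-7, r2 = 6.5e-11, s = 8.39e-2, u = 3e-10, alpha = 7.5e8,
  alpha1 = 1e3, alpha2 = 1e3, beta = 1.2e-2, beta1 = 0.835, beta2 = 5.4,
  gamma = 0.9, mu1 = 0.1, mu_i = 10, delta2 = 1e-7)

ref_patient2 <- utils::modifyList(ref_patient1, list(
  d = 1.88, k = 5.66e7, l = 1.81, m = 9.12, p = 3.59e-6, q = 1.59e-6,
  s = 5.12e-1, alpha = 5e8, beta = 8e-3))

p1 <- patient_params("patient1")
p2 <- patient_params("patient2")

# random positive perturbation of a parameter set (multiplicative,
# factor in [0.5, 2]); used by property tests under a fixed seed
perturb_params <- function(base) {
  vals <- unclass(base)
  vals <- lapply(vals, function(x) x * 2^stats::runif(1, -1, 1))
  parameter_set(vals, label = "perturbed")
}

# explicit relative-error expectation: all.equal() silently switches to
# absolute comparison when the target magnitude is below the tolerance,
# which would make checks on small thresholds (~1e-5) vacuous
expect_rel <- function(value, target, tol) {
  testthat::expect_lt(max(abs(value / target - 1)), tol)
}
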