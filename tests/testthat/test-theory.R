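test_that("panmictic establishment probability is 2 s_p / xi2, clipped", {
  expect_equal(panmictic_establishment_prob(0.05, 1), 0.1)
  expect_equal(panmictic_establishment_prob(0, 1), 0)
  expect_equal(panmictic_establishment_prob(0.01, 1), 0.02)
  expect_equal(panmictic_establishment_prob(3, 1), 1)  # clipped
  expect_error(panmictic_establishment_prob(0.05, 0), "xi2")
})

test_that("critical patch width has the arctangent form and limits", {
  s <- 0.07
  expect_equal(critical_patch_width(1, s, s), (1 / sqrt(2 * s)) * pi / 4)
  expect_equal(critical_patch_width(1, 0.1, 1e-12), 0, tolerance = 1e-5)
  expect_equal(critical_patch_width(1, 0.1, 0.02), 0.9403434,
               tolerance = 1e-6)
})

test_that("mutation rate is the mutational influx times p_e", {
  p <- pop_params(sigma = 0.95, s_m = 0.0046, s_p = 0.0023, mu = 1e-5,
                  rho = 1000, xi2 = 1)
  expect_equal(lambda_mut(p, A = 99), 2 * 0.0023 * 99000 * 1e-5)
  expect_equal(1 / lambda_mut(p, A = 99), 219.5872, tolerance = 1e-4)
  p0 <- theory_params(mu = 0)
  expect_equal(lambda_mut(p0, A = 5), 0)
  p2 <- theory_params(rho = 2)
  expect_equal(lambda_mut(p2, A = 5), 2 * lambda_mut(theory_params(), A = 5))
})

test_that("equilibrium frequency decays exponentially with the right scale", {
  p1 <- theory_params()
  ell <- characteristic_length(p1)
  expect_equal(equilibrium_frequency(ell, p1), exp(-1))
  p2 <- theory_params(d = 2)
  expect_equal(equilibrium_frequency(characteristic_length(p2), p2), exp(-1))
  expect_error(equilibrium_frequency(0, p2), "x = 0")
  # one characteristic length multiplies q by 1/e in d = 1
  x <- c(3, 7, 12)
  expect_equal(equilibrium_frequency(x + ell, p1) / equilibrium_frequency(x, p1),
               rep(exp(-1), 3))
  # log q + x/ell + ((d-1)/2) log(x/ell) is constant = log C
  p3 <- theory_params(d = 2, C = 2.5)
  x <- seq(2, 20, by = 0.5)
  z <- x / characteristic_length(p3)
  recovered <- log(equilibrium_frequency(x, p3)) + z + 0.5 * log(z)
  expect_equal(recovered, rep(log(2.5), length(x)))
})

test_that("effective area follows the strip construction", {
  p <- theory_params()          # ell = 1/sqrt(0.1) ~ 3.162
  ell <- characteristic_length(p)
  # small patch: full extent
  expect_equal(effective_area(list(w_lin = 1, w_perp = 1), p), 1)
  # 1D, w_lin = 2 ell -> ell
  expect_equal(effective_area(list(w_lin = 2 * ell, w_perp = 1), p), ell)
  # 2D long patch: strip of width ell times the transverse width
  p2 <- theory_params(d = 2)
  expect_equal(effective_area(list(w_lin = 50, w_perp = 7), p2), 7 * ell)
})

test_that("q over the patch matches quadrature and respects the A q(R) bound", {
  p <- theory_params(C = 1.7)
  patch <- list(w_lin = 4, w_perp = 1)
  R <- 8
  closed <- q_patch_integral(R, patch, p)
  quad <- integrate(function(x) equilibrium_frequency(x, p), R, R + patch$w_lin,
                    rel.tol = 1e-12)$value
  expect_equal(closed, quad, tolerance = 1e-10)
  # wide-patch limit C ell e^{-R/ell}
  ell <- characteristic_length(p)
  expect_equal(q_patch_integral(R, list(w_lin = 1e6, w_perp = 1), p),
               1.7 * ell * exp(-R / ell))
  # small patch ~ w q(R)
  tiny <- list(w_lin = 1e-4, w_perp = 1)
  expect_equal(q_patch_integral(R, tiny, p),
               1e-4 * equilibrium_frequency(R, p), tolerance = 1e-4)
  # bound q(S) <= A q(R), both dimensions
  for (d in 1:2) {
    pd <- theory_params(d = d)
    for (w_lin in c(0.5, 3, 20)) {
      patch <- list(w_lin = w_lin, w_perp = 2)
      A <- if (d == 1) w_lin else w_lin * 2
      expect_lte(q_patch_integral(5, patch, pd),
                 A * equilibrium_frequency(5, pd) + 1e-12)
    }
  }
})

test_that("migration rate has the tail form, branch structure and scalings", {
  p <- theory_params(s_m = 0.05, s_p = 0.1)  # p_e = 0.2 > s_m -> gamma < 1
  ell <- characteristic_length(p)
  r1 <- lambda_mig(20, p, A_prime = 1)
  # one characteristic length multiplies the rate by 1/e (d = 1)
  expect_equal(lambda_mig(20 + ell, p, A_prime = 1) / r1, exp(-1))
  # gamma branch: with p_e > s_m the rate is C rho A' s_m^2 e^{-z}
  expect_equal(r1, 0.05^2 * exp(-20 * sqrt(0.1)))
  expect_equal(r1, 4.479407e-06, tolerance = 1e-6)
  # with p_e < s_m the min term equals p_e
  p2 <- theory_params(s_m = 0.05, s_p = 0.01)  # p_e = 0.02 < s_m
  expect_equal(lambda_mig(20, p2, A_prime = 1),
               0.05 * 0.02 * exp(-20 * sqrt(0.1)))
  # linear in rho; decreasing in R
  expect_equal(lambda_mig(20, theory_params(s_m = 0.05, s_p = 0.1, rho = 3),
                          A_prime = 1), 3 * r1)
  Rs <- seq(5, 40, by = 1)
  expect_true(all(diff(lambda_mig(Rs, p, A_prime = 1)) < 0))
  # warns inside the characteristic length
  expect_warning(lambda_mig(0.5 * ell, p, A_prime = 1), "validity")
})

test_that("exact migration factor reduces to 2 s_m p_e and matches Monte Carlo", {
  expect_equal(exact_migration_factor(1, 1, p_e = 0.1, s_m = 0.05),
               2 * 0.05 * 0.1)
  # p_e -> 1: every arriving family (K >= 1) establishes -> 2 s_m / E[K]
  k <- 1:400
  pr <- dgeom(k - 1, prob = 1 / 20)  # shifted geometric, mean 20
  expect_equal(exact_migration_factor(k, pr, p_e = 1, s_m = 0.05),
               2 * 0.05 / sum(k * pr / sum(pr)), tolerance = 1e-10)
  expect_error(exact_migration_factor(0, 1, p_e = 0.1, s_m = 0.05),
               "degenerate")
  # Monte-Carlo oracle for (shifted) geometric K, mean 20, p_e = 0.1
  set.seed(42)
  draws <- rgeom(1e5, prob = 1 / 20) + 1
  est_num <- mean(1 - 0.9^draws)
  se <- sd(1 - 0.9^draws) / sqrt(1e5)
  mc <- est_num / (mean(draws) / (2 * 0.05))
  exact <- exact_migration_factor(k, pr, p_e = 0.1, s_m = 0.05)
  expect_lt(abs(mc - exact), 3 * se / (mean(draws) / (2 * 0.05)) + 1e-4)
})

test_that("critical gap distance matches the printed thresholds and flags", {
  expect_equal(as.numeric(critical_gap_distance(0.05, 1e-5, 10)), 21.84424,
               tolerance = 1e-5)
  expect_equal(as.numeric(critical_gap_distance(0.001, 1e-5, 10)), 66.98661,
               tolerance = 1e-5)
  expect_equal(as.numeric(critical_gap_distance(0.05, 1e-3, 10)), 7.281413,
               tolerance = 1e-5)
  # mutation always faster: flagged zero
  res <- critical_gap_distance(0.001, 1e-3, 10)
  expect_identical(as.numeric(res), 0)
  expect_true(attr(res, "mutation_always_faster"))
})

test_that("probability of parallel adaptation is logistic in R and consistent", {
  p <- theory_params(s_m = 0.05, s_p = 0.1, mu = 1e-5)
  Rs <- seq(5, 120, by = 1)
  pp <- prob_parallel(Rs, p, w = 10, gamma = 1)
  expect_true(all(pp > 0 & pp < 1))
  expect_true(all(diff(pp) > 0))
  expect_equal(prob_parallel(1e5, p, w = 10, gamma = 1), 1, tolerance = 1e-8)
  # equals 1/2 exactly at the critical gap (C = gamma = 1, d = 1)
  Rc <- as.numeric(critical_gap_distance(0.05, 1e-5, 10)) * p$sigma
  expect_equal(prob_parallel(Rc, p, w = 10, gamma = 1), 0.5)
  # invariant to rho, and to s_p rho rescaling within the gamma = 1 regime
  for (fac in c(0.5, 2, 10)) {
    p_r <- theory_params(s_m = 0.05, s_p = 0.1, mu = 1e-5, rho = fac)
    expect_equal(prob_parallel(30, p_r, w = 10), prob_parallel(30, p, w = 10))
  }
  for (fac in c(0.5, 2)) {  # s_p rho rescaling, staying in the gamma = 1 regime
    p_s <- theory_params(s_m = 0.5, s_p = 0.1 * fac, mu = 1e-5, rho = 1 / fac)
    p_b <- theory_params(s_m = 0.5, s_p = 0.1, mu = 1e-5)
    expect_equal(prob_parallel(30, p_s, w = 10), prob_parallel(30, p_b, w = 10))
  }
  # and prob_parallel = lambda_mut / (lambda_mut + 2 lambda_mig) exactly
  # (the competition uses the un-absorbed family-occupation rate)
  layoutA <- list(w_lin = 10 * characteristic_length(p), w_perp = 1)
  Ap <- effective_area(layoutA, p)
  A <- layoutA$w_lin
  lm_ <- lambda_mut(p, A)
  lg <- lambda_mig(30, p, Ap)
  expect_equal(prob_parallel(30, p, w = A / Ap), lm_ / (lm_ + 2 * lg))
})

test_that("cline fitting recovers the tail parameters", {
  # exact recovery from generated data
  p <- theory_params(s_m = 0.02, C = 0.7)
  x <- seq(2, 30, by = 2)
  q <- equilibrium_frequency(x, p)
  fit <- fit_cline(x, q, d = 1)
  expect_equal(fit$decay_length, characteristic_length(p), tolerance = 1e-10)
  expect_equal(fit$C_hat, 0.7, tolerance = 1e-10)
  # d = 2 with the square-root prefactor
  p2 <- theory_params(s_m = 0.02, C = 0.7, d = 2)
  q2 <- equilibrium_frequency(x, p2)
  fit2 <- fit_cline(x, q2, d = 2)
  expect_equal(fit2$decay_length, characteristic_length(p2), tolerance = 1e-4)
  # two-point fits are exact
  expect_equal(fit_cline(c(0, 12), c(0.5, 0.03))$decay_length,
               12 / log(0.5 / 0.03), tolerance = 1e-10)
  expect_equal(fit_cline(c(0, 10), c(0.5, 0.34))$decay_length,
               10 / log(0.5 / 0.34), tolerance = 1e-10)
  expect_error(fit_cline(c(1, 1), c(0.5, 0.3)), "distinct")
  expect_error(fit_cline(c(0, 5), c(0.5, 0)), "frequencies")
})

test_that("assumption checks flag the right violations", {
  # lattice-simulation parameters: no flags
  p <- sim_effective_params()
  p_fig1 <- pop_params(sigma = 0.95, s_m = 0.02, s_p = 0.1, rho = 1000)
  layout <- patch_layout(data.frame(area = 10, w_lin = 10, w_perp = 1))
  expect_length(check_assumptions(p_fig1, layout), 0)
  # distance flag
  lay2 <- patch_layout(data.frame(area = c(10, 10), w_lin = 10, w_perp = 1),
                       matrix(c(0, 3, 3, 0), 2))
  expect_true("interpatch_distance" %in% check_assumptions(p_fig1, lay2))
  # neighbourhood-size flag
  p_ok <- theory_params(s_m = 0.1, rho = 5)
  expect_false("neighborhood_size" %in% check_assumptions(p_ok))
  p_bad <- theory_params(s_m = 0.001, rho = 5)
  expect_true("neighborhood_size" %in% check_assumptions(p_bad))
  # narrow patch flag
  lay3 <- patch_layout(data.frame(area = 0.1, w_lin = 0.1, w_perp = 1))
  expect_true("patch_width" %in% check_assumptions(p_fig1, lay3))
})

test_that("parameter constructors validate their invariants", {
  expect_error(pop_params(sigma = -1, s_m = 0.05, s_p = 0.1), "sigma")
  expect_error(pop_params(sigma = 1, s_m = 0, s_p = 0.1), "s_m")
  expect_error(pop_params(sigma = 1, s_m = 0.05, s_p = 0.1, mu = 1), "mu")
  expect_error(patch_layout(data.frame(area = -1, w_lin = 1)), "widths")
  expect_error(
    patch_layout(data.frame(area = c(1, 1), w_lin = 1),
                 matrix(c(0, 1, 2, 0), 2)),
    "symmetric")
  # fig4 preset sets C = 5
  expect_equal(pop_params(sigma = 1, s_m = 0.05, s_p = 0.1,
                          preset = "fig4")$C, 5)
})
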