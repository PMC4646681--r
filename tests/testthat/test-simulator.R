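test_that("configuration validation and derived quantities", {
  expect_error(deme_grid_config(shape = 10, N = 100, s_map = 3, r = 0.3),
               "reproduction probabilities")
  expect_equal(effective_selection(0.3, 0), 0)
  expect_equal(effective_selection(0.3, 0.01), 0.002305034, tolerance = 1e-6)
  expect_equal(effective_selection(0.3, 0.1), log(1.33 / 1.3))
  expect_equal(dispersal_sigma(0.2), 0.9537701, tolerance = 1e-6)
  expect_equal(dispersal_sigma(0), 0)
  expect_equal(dispersal_sigma(0.2, kernel = 1), sqrt(0.2))  # single-step moves
  expect_equal(dispersal_sigma(0.2, d = 2), sqrt(0.2 * (4.40625 / 0.96875) * 0.75))
})

test_that("forward simulation conserves deme sizes and is reproducible", {
  n <- 41
  s_map <- ifelse(abs(seq_len(n) - 21) <= 5, 0.1, -0.02)
  cfg <- deme_grid_config(shape = n, N = 50, s_map = s_map, mu = 1e-4,
                          init = ifelse(abs(seq_len(n) - 21) <= 2, 50, 0),
                          t_max = 100, seed = 42)
  res <- run_forward(cfg)
  # counts bounded by N in every deme and generation
  expect_true(all(res$counts >= 0 & res$counts <= 50))
  # byte-identical reproduction from the same config/seed
  res2 <- run_forward(cfg)
  expect_identical(res, res2)
  # different seed gives a different trajectory
  cfg3 <- deme_grid_config(shape = n, N = 50, s_map = s_map, mu = 1e-4,
                           init = cfg$init, t_max = 100, seed = 43)
  expect_false(identical(run_forward(cfg3)$counts, res$counts))
})

test_that("no mutation and no initial alleles stays empty; 2d grids work", {
  cfg <- deme_grid_config(shape = 21, N = 20, s_map = 0.1, mu = 0,
                          t_max = 50, seed = 1)
  expect_true(all(run_forward(cfg)$counts == 0))
  cfg2 <- deme_grid_config(shape = c(9, 9), N = 30,
                           s_map = rep(0.05, 81), mu = 0,
                           init = c(rep(0, 40), 30, rep(0, 40)),
                           t_max = 30, seed = 3)
  res2 <- run_forward(cfg2)
  expect_true(all(res2$counts >= 0 & res2$counts <= 30))
  expect_equal(ncol(res2$counts), 81)
  # alleles spread beyond the initial deme
  expect_gt(sum(res2$counts[31, ] > 0), 1)
})

test_that("rare-allele growth matches the effective selection coefficient", {
  # single deme, no migration: log growth of the mean B count over
  # replicates approximates log((1 + r(1+s))/(1 + r))
  set.seed(21)
  n_rep <- 1500; tgen <- 20; N <- 1e5; b0 <- 200
  finals <- vapply(seq_len(n_rep), function(i) {
    cfg <- deme_grid_config(shape = 1, N = N, s_map = 0.01, m = 0,
                            init = b0, t_max = tgen, seed = 1e6 + i)
    run_forward(cfg)$counts[tgen + 1, 1]
  }, numeric(1))
  rate_hat <- log(mean(finals) / b0) / tgen
  se <- sd(finals) / sqrt(n_rep) / mean(finals) / tgen
  expect_lt(abs(rate_hat - effective_selection(0.3, 0.01)), 3 * se)
})

test_that("time to adaptation scans the count history monotonically", {
  n <- 31
  patch <- 14:18
  s_map <- ifelse(seq_len(n) %in% patch, 0.2, -0.05)
  cfg <- deme_grid_config(shape = n, N = 100, s_map = s_map, mu = 0,
                          init = ifelse(seq_len(n) == 16, 60, 0),
                          t_max = 60, focal_demes = patch, seed = 9)
  res <- run_forward(cfg)
  t_low <- time_to_adaptation(res, threshold = 1)
  t_mid <- time_to_adaptation(res, threshold = 50)
  expect_lte(t_low, t_mid)
  expect_equal(t_low, 0)  # initialized above threshold 1
  expect_true(is.na(time_to_adaptation(res, threshold = 1e6)))
})

test_that("lineages never move and always coalesce in a single deme", {
  cfg <- deme_grid_config(shape = 1, N = 10, s_map = 0.1, m = 0,
                          init = 10, t_max = 10, seed = 2)
  res <- run_forward(cfg)
  ls <- trace_lineages(res, n_lineages = 2, deme = 1)
  expect_true(all(ls$paths[!is.na(ls$paths)] == 1))
  # two lineages in a deme with n = 1 coalesce at once
  cfg1 <- deme_grid_config(shape = 1, N = 1, s_map = 0, m = 0,
                           init = 1, t_max = 3, seed = 2)
  res1 <- run_forward(cfg1)
  set.seed(1)
  ls1 <- trace_lineages(res1, n_lineages = 2, deme = 1)
  expect_equal(sum(ls1$events$type == "coalescence"), 1)
  expect_equal(ls1$events$generation[1], 2)  # first backward step
  expect_error(trace_lineages(res, n_lineages = 1, deme = 1, generation = 0),
               NA)
})

test_that("lineage locations only visit occupied demes and coalescence
           frequencies match exact enumeration on a fixed history", {
  # hand-built two-deme history (generations 0..3)
  cfg <- deme_grid_config(shape = 2, N = 2, s_map = 0, m = 0.4, kernel = 1,
                          init = c(2, 2), t_max = 3, seed = 5)
  res <- run_forward(cfg)
  res$counts <- matrix(c(2, 1,
                         2, 2,
                         1, 2,
                         2, 2), nrow = 4, byrow = TRUE)
  # exact coalescence probability of two lineages sampled in deme 1 at
  # generation 3, by dynamic programming over joint lineage states
  offs <- list(p = c(0.6, 0.4))  # stay, move (single-step kernel)
  back_prob <- function(y, counts_prev) {
    w <- c(ifelse(y == 1, 0.6, 0.4) * counts_prev[1],
           ifelse(y == 2, 0.6, 0.4) * counts_prev[2])
    w / sum(w)
  }
  # state: (deme1, deme2, coalesced?)
  states <- expand.grid(a = 1:2, b = 1:2)
  pr <- ifelse(states$a == 1 & states$b == 1, 1, 0)  # both start in deme 1
  p_coal <- 0
  for (g in 3:1) {
    prev <- res$counts[g, ]
    newpr <- numeric(nrow(states))
    for (i in seq_len(nrow(states))) {
      if (pr[i] == 0) next
      pa <- back_prob(states$a[i], prev)
      pb <- back_prob(states$b[i], prev)
      for (j in seq_len(nrow(states))) {
        move_p <- pa[states$a[j]] * pb[states$b[j]]
        if (move_p == 0) next
        if (states$a[j] == states$b[j]) {
          coal <- 1 / prev[states$a[j]]
          p_coal <- p_coal + pr[i] * move_p * coal
          newpr[j] <- newpr[j] + pr[i] * move_p * (1 - coal)
        } else {
          newpr[j] <- newpr[j] + pr[i] * move_p
        }
      }
    }
    pr <- newpr
  }
  # Monte Carlo with trace_lineages on the same frozen history
  set.seed(31)
  n_rep <- 4000
  coal <- vapply(seq_len(n_rep), function(i) {
    ls <- trace_lineages(res, n_lineages = 2, deme = 1)
    # occupied-deme invariant
    for (g in seq_len(nrow(ls$paths))) {
      demes <- ls$paths[g, !is.na(ls$paths[g, ])]
      if (length(demes)) stopifnot(all(res$counts[g, demes] > 0))
    }
    any(ls$events$type == "coalescence")
  }, logical(1))
  se <- sqrt(p_coal * (1 - p_coal) / n_rep)
  expect_lt(abs(mean(coal) - p_coal), 3 * se)
})

test_that("haplotype decay follows the minimum-of-exponentials law", {
  set.seed(17)
  tau <- 25
  # q_local = 0 throughout: L = min(L0, X_1, ..., X_tau), E[L] ~ 1/tau
  finals <- vapply(seq_len(4000), function(i) {
    traj <- shared_haplotype_decay(q_local = rep(0, tau), L0 = 50)
    traj$left[tau + 1]
  }, numeric(1))
  expect_lt(abs(mean(finals) - 1 / tau) / (1 / tau), 3 * 1 / sqrt(4000) + 0.05)
  # zero generations leave L untouched
  expect_equal(shared_haplotype_decay(q_local = numeric(0), L0 = 7)$left, 7)
  # q_local = 1: no background partners, L never shrinks
  traj1 <- shared_haplotype_decay(q_local = rep(1, 10), L0 = 3)
  expect_true(all(traj1$left == 3) && all(traj1$right == 3))
})

test_that("haplotype decay over conditioned transit times reproduces the
           killed-Brownian haplotype survival curve", {
  set.seed(23)
  m <- transit_model(R = 3, sigma = 1, s_m = 0.05, d = 1)
  mc <- simulate_killed_brownian(m, reps = 4000, dt = 0.01)
  taus <- round(mc$time[mc$hit])
  taus <- taus[taus >= 1]
  lens <- vapply(taus, function(tt) {
    shared_haplotype_decay(q_local = rep(0, tt), L0 = 100)$left[tt + 1]
  }, numeric(1))
  for (l in c(0.05, 0.2)) {
    est <- mean(lens > l)
    se <- sqrt(est * (1 - est) / length(lens))
    expect_lt(abs(est - haplotype_survival(l, m)), 3 * se + 0.02)
  }
})
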