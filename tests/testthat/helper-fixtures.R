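# shared fixtures: parameter sets and small helpers used across test files

# effective (growth-rate) parameters of the standard lattice simulations:
# raw multipliers s_p = 0.01, s_m = 0.02 on base reproduction r = 0.3
sim_effective_params <- function(C = 1) {
  pop_params(sigma = dispersal_sigma(0.2),
             s_m = -effective_selection(0.3, -0.02),
             s_p = effective_selection(0.3, 0.01),
             mu = 1e-5, rho = 1000, xi2 = offspring_variance(0.3),
             C = C, d = 1)
}

# generic theory parameter set used in closed-form checks
theory_params <- function(...) {
  defaults <- list(sigma = 1, s_m = 0.05, s_p = 0.1, mu = 1e-5, rho = 1,
                   xi2 = 1, C = 1, d = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(pop_params, args)
}

# independent oracle: lattice branching process with Poisson(1 + s(x))
# offspring and nearest-neighbour migration (stay 0.5, 0.25 per side);
# returns TRUE if the line survives to t_max (a proxy for establishment)
branching_establishes <- function(s, start, t_max = 400, stay = 0.5) {
  n <- length(s)
  counts <- integer(n)
  counts[start] <- 1L
  side <- (1 - stay) / 2
  for (t in seq_len(t_max)) {
    tot <- sum(counts)
    if (tot == 0L) return(FALSE)
    if (tot > 5000L) return(TRUE)  # escaped stochastic loss
    kids <- rpois(n, (1 + s) * counts)
    stayk <- rbinom(n, kids, stay)
    rest <- kids - stayk
    leftk <- rbinom(n, rest, 0.5)
    rightk <- rest - leftk
    counts <- stayk
    counts[seq_len(n - 1)] <- counts[seq_len(n - 1)] + leftk[-1]
    counts[2:n] <- counts[2:n] + rightk[-n]
  }
  sum(counts) > 0L
}
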