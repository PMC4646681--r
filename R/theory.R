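#' Panmictic establishment probability
#'
#' Probability that a single copy of a beneficial allele escapes loss by
#' demographic stochasticity in a well-mixed population: `2 s_p / xi2`,
#' clipped to `[0, 1]`.
#'
#' @param s_p Selective advantage (>= 0).
#' @param xi2 Variance in offspring number (> 0).
#' @return A probability.
#' @examples
#' panmictic_establishment_prob(0.05, 1) # 0.1
#' @export
panmictic_establishment_prob <- function(s_p, xi2) {
  if (!is.numeric(xi2) || any(xi2 <= 0)) {
    stop("'xi2' must be > 0", call. = FALSE)
  }
  if (any(s_p < 0)) stop("'s_p' must be >= 0", call. = FALSE)
  pmin(1, pmax(0, 2 * s_p / xi2))
}

#' Critical patch width for a stable polymorphism
#'
#' The minimum physical patch width below which migrational swamping prevents
#' any stable equilibrium carrying the locally adaptive allele:
#' `(sigma / sqrt(2 s_p)) * atan(sqrt(s_m / s_p))` (one dimension).
#'
#' @param sigma Dispersal distance (> 0).
#' @param s_p In-patch selective advantage (> 0).
#' @param s_m Between-patch selective disadvantage (> 0).
#' @return The critical width, in the units of `sigma`.
#' @examples
#' critical_patch_width(1, 0.1, 0.02) # ~0.940
#' @export
critical_patch_width <- function(sigma, s_p, s_m) {
  stopifnot(sigma > 0, s_p > 0, s_m >= 0)
  (sigma / sqrt(2 * s_p)) * atan(sqrt(s_m / s_p))
}

#' Rate of adaptation by new mutation
#'
#' The rate per generation at which mutations arise in a patch of area `A`
#' and become locally established: `2 s_p rho A mu / xi2`, i.e. the
#' mutational influx `rho A mu` times the establishment probability
#' `p_e = 2 s_p / xi2`. The expected waiting time is `1 / lambda_mut`.
#'
#' @param params A [pop_params] object.
#' @param A Patch area (> 0), in the unit implied by `rho`.
#' @return A rate per generation.
#' @examples
#' p <- pop_params(sigma = 0.95, s_m = 0.0046, s_p = 0.0023, mu = 1e-5,
#'                 rho = 1000)
#' lambda_mut(p, A = 99) # ~0.00455; waiting time ~220 generations
#' @export
lambda_mut <- function(params, A) {
  stopifnot(A > 0)
  panmictic_establishment_prob(params$s_p, params$xi2) * params$rho * A *
    params$mu
}

#' Equilibrium frequency of the allele at distance x from a patch
#'
#' The migration--selection-balance tail of the expected (time-averaged)
#' allele frequency at displacement `x` from an established patch:
#' `q(x) = C (|x| sqrt(2 s_m) / sigma)^(-(d-1)/2) exp(-|x| sqrt(2 s_m) / sigma)`.
#' The asymptotic form is intended for `|x|` beyond a few multiples of
#' `sigma`; this is documented, not enforced.
#'
#' @param x Displacement(s) from the patch edge (same unit as `sigma`).
#' @param params A [pop_params] object.
#' @return Expected frequency/frequencies.
#' @export
equilibrium_frequency <- function(x, params) {
  ax <- abs(x)
  if (params$d == 2L && any(ax == 0)) {
    stop("x = 0 is outside the domain of the two-dimensional tail", call. = FALSE)
  }
  z <- ax * sqrt(2 * params$s_m) / params$sigma
  params$C * z^(-(params$d - 1) / 2) * exp(-z)
}

#' Effective target area A' of a patch
#'
#' The area of the part of a patch that lies within one characteristic length
#' `sigma / sqrt(2 s_m)` of its near edge: in one dimension
#' `min(w_lin, sigma / sqrt(2 s_m))`, in two dimensions that strip times the
#' transverse width. If the patch is smaller than the strip the whole area is
#' used.
#'
#' @param patch One row of a [patch_layout] `patches` data frame (or any list
#'   with `area`, `w_lin`, `w_perp`).
#' @param params A [pop_params] object.
#' @return The effective area A'.
#' @export
effective_area <- function(patch, params) {
  ell <- characteristic_length(params)
  if (params$d == 1L) {
    min(patch$w_lin, ell)
  } else {
    patch$w_perp * min(patch$w_lin, ell)
  }
}

#' Integral of the equilibrium frequency over a patch
#'
#' `q(S) = integral of q(x) over the new patch`, for a patch whose near edge
#' is at distance `R`. In one dimension the exponential tail integrates in
#' closed form over `[R, R + w_lin]`; in two dimensions the enclosing
#' rectangle bound is used with the effective length `min(w_lin, ell)`
#' (the `sqrt(pi)` of the exact bound is absorbed into `C`). Always bounded
#' by `A * q(R)`.
#'
#' @param R Shortest distance to the patch (> 0).
#' @param patch Patch geometry (list with `w_lin`, `w_perp`).
#' @param params A [pop_params] object.
#' @return The integrated equilibrium frequency (units of area).
#' @export
q_patch_integral <- function(R, patch, params) {
  stopifnot(R > 0)
  ell <- characteristic_length(params)
  if (params$d == 1L) {
    params$C * exp(-R / ell) * ell * (1 - exp(-patch$w_lin / ell))
  } else {
    patch$w_perp * min(patch$w_lin, ell) * equilibrium_frequency(R, params)
  }
}

#' Rate of adaptation by migration from an established patch
#'
#' The effective rate per generation at which migrant families leaving a patch
#' where the allele is established reach and establish in a new patch at
#' shortest distance `R`:
#' \deqn{\lambda_{mig}(R) = C \rho A' s_m \min(s_m, p_e)
#'   (R \sqrt{2 s_m}/\sigma)^{-(d-1)/2} e^{-R \sqrt{2 s_m}/\sigma}.}
#' The underlying family-occupation argument produces twice this quantity
#' (an arriving family's mean occupation contribution is `K/(2 s_m)`); the
#' closed form above follows the convention in which that 2 is absorbed into
#' the empirically fitted `C`. The mutation-versus-migration competition
#' ([prob_parallel], [gillespie_colonization], [island_theta]) uses the
#' un-absorbed rate `2 * lambda_mig`, which makes [prob_parallel] equal
#' `lambda_mut / (lambda_mut + 2 lambda_mig)` identically.
#'
#' Valid for `R` beyond the characteristic length; a warning
#' is issued otherwise. The expression is non-monotonic in `s_m` outside its
#' validity region (`s_m < R^2 / (2 sigma^2)`); this is a property of the
#' approximation, documented rather than altered.
#'
#' @param R Shortest inter-patch distance (> 0).
#' @param params A [pop_params] object.
#' @param A_prime Effective area of the target patch (see [effective_area]).
#' @param gamma Optional override of the internal `min(1, s_m/p_e)`.
#' @return A rate per generation.
#' @export
lambda_mig <- function(R, params, A_prime, gamma = NULL) {
  stopifnot(all(R > 0), A_prime > 0)
  if (any(R <= characteristic_length(params))) {
    warning("lambda_mig is an asymptotic tail rate; R <= sigma/sqrt(2 s_m) is outside its validity region")
  }
  pe <- panmictic_establishment_prob(params$s_p, params$xi2)
  if (is.null(gamma)) gamma <- min(1, params$s_m / pe)
  z <- R * sqrt(2 * params$s_m) / params$sigma
  # gamma * p_e == min(s_m, p_e) when gamma is the internal default
  params$C * gamma * pe * params$rho * A_prime * params$s_m *
    z^(-(params$d - 1) / 2) * exp(-z)
}

#' Exact migrant-family rate multiplier for a general family-size distribution
#'
#' The establishment-versus-occupation ratio for arriving migrant families of
#' size `K`: `E[1 - (1 - p_e)^K] / (E[K] / (2 s_m))`. Multiplying the mean
#' occupation density `rho q(S)` by this factor gives the migration rate; it
#' reduces to `2 s_m p_e` when `p_e K` is small.
#'
#' @param k Support of the family-size distribution (nonnegative integers).
#' @param prob Probabilities for each value of `k` (will be normalized).
#' @param p_e Establishment probability of a single copy.
#' @param s_m Between-patch selective disadvantage.
#' @return The rate multiplier.
#' @examples
#' exact_migration_factor(1, 1, p_e = 0.1, s_m = 0.05) # 2 * 0.05 * 0.1
#' @export
exact_migration_factor <- function(k, prob, p_e, s_m) {
  stopifnot(length(k) == length(prob), all(k >= 0), all(k == floor(k)),
            all(prob >= 0))
  prob <- prob / sum(prob)
  EK <- sum(k * prob)
  if (EK == 0) {
    stop("degenerate family-size distribution: E[K] = 0", call. = FALSE)
  }
  sum((1 - (1 - p_e)^k) * prob) / (EK / (2 * s_m))
}

#' Critical inter-patch gap beyond which parallel adaptation dominates
#'
#' The distance (in units of the dispersal distance `sigma`) at which the
#' effective mutational and migrational influxes are equal:
#' `R/sigma = log(2 gamma s_m / (w mu)) / sqrt(2 s_m)`,
#' where `w = A / A'` is the patch width in characteristic lengths. Beyond
#' this gap, independent mutation is the more likely route to adaptation.
#' When the log argument is at most 1 (mutation always faster), 0 is returned
#' with attribute `mutation_always_faster = TRUE`.
#'
#' @param s_m Between-patch selective disadvantage.
#' @param mu Mutation rate per chromosome per generation.
#' @param w Patch width in units of `sigma / sqrt(2 s_m)`.
#' @param gamma Establishment cap `min(1, s_m / p_e)` (default 1).
#' @return `R / sigma`, with attribute `mutation_always_faster` (logical).
#' @examples
#' critical_gap_distance(0.05, 1e-5, 10) # ~21.8
#' @export
critical_gap_distance <- function(s_m, mu, w, gamma = 1) {
  stopifnot(s_m > 0, mu > 0, w > 0, gamma > 0)
  arg <- 2 * gamma * s_m / (w * mu)
  if (arg <= 1) {
    return(structure(0, mutation_always_faster = TRUE))
  }
  structure(log(arg) / sqrt(2 * s_m), mutation_always_faster = FALSE)
}

#' Probability that a second patch adapts by independent mutation
#'
#' The probability of parallel (convergent) adaptation for a patch at distance
#' `R` from an already adapted patch,
#' `lambda_mut / (lambda_mut + lambda_mig(R))`, in the width-scaled form
#' \deqn{P = \frac{w\mu/(2 s_m)}{w\mu/(2 s_m) + C \gamma
#'   (R\sqrt{2 s_m}/\sigma)^{-(d-1)/2} e^{-R\sqrt{2 s_m}/\sigma}},}
#' which increases approximately logistically with `R` on the scale
#' `sigma / sqrt(2 s_m)`. Invariant to `rho` and to rescalings that leave
#' `gamma` unchanged.
#'
#' @param R Inter-patch distance(s) (> 0).
#' @param params A [pop_params] object.
#' @param w Patch width in units of `sigma / sqrt(2 s_m)` (`A / A'`).
#' @param gamma Optional override of `min(1, s_m / p_e)`.
#' @return Probability/probabilities in `(0, 1)`.
#' @export
prob_parallel <- function(R, params, w, gamma = NULL) {
  stopifnot(all(R > 0), w > 0)
  if (is.null(gamma)) gamma <- gamma_factor(params)
  z <- R * sqrt(2 * params$s_m) / params$sigma
  mut <- w * params$mu / (2 * params$s_m)
  mig <- params$C * gamma * z^(-(params$d - 1) / 2) * exp(-z)
  mut / (mut + mig)
}

#' Fit the equilibrium-frequency tail to observed cline frequencies
#'
#' Ordinary least squares on log frequency against the tail functional form
#' `log q(x) = log C - ((d-1)/2) log(x sqrt(2 s_m)/sigma) - x sqrt(2 s_m)/sigma`,
#' estimating the constant `C` and the decay length `sigma / sqrt(2 s_m)`.
#' With exactly two points (d = 1) the fit is exact. Zero frequencies are
#' rejected rather than pseudo-counted.
#'
#' @param distances Distances from the patch edge (>= 0 for d = 1, > 0 for
#'   d = 2); at least two distinct values.
#' @param frequencies Observed allele frequencies in `(0, 1)`.
#' @param d Spatial dimension (1 or 2).
#' @return A list with elements `C_hat`, `decay_length`
#'   (`= sigma / sqrt(2 s_m)`), and `fitted`.
#' @examples
#' fit_cline(c(0, 12), c(0.5, 0.03))$decay_length # 12 / log(50/3) ~ 4.27
#' @export
fit_cline <- function(distances, frequencies, d = 1) {
  stopifnot(length(distances) == length(frequencies),
            length(distances) >= 2L, d %in% c(1, 2))
  if (anyDuplicated(distances)) {
    stop("'distances' must be distinct", call. = FALSE)
  }
  if (any(frequencies <= 0) || any(frequencies >= 1)) {
    stop("'frequencies' must lie strictly in (0, 1)", call. = FALSE)
  }
  y <- log(frequencies)
  if (d == 1) {
    fit <- stats::lm(y ~ distances)
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) stop("frequencies do not decay with distance", call. = FALSE)
    ell <- -1 / slope
    C_hat <- exp(stats::coef(fit)[[1]])
    fitted <- exp(stats::fitted(fit))
  } else {
    if (any(distances <= 0)) {
      stop("d = 2 requires strictly positive distances", call. = FALSE)
    }
    rss <- function(log_ell) {
      ell <- exp(log_ell)
      pred0 <- -0.5 * log(distances / ell) - distances / ell
      logC <- mean(y - pred0)
      sum((y - logC - pred0)^2)
    }
    opt <- stats::optimize(rss, c(log(min(diff(sort(distances)))) - 5,
                                  log(max(distances)) + 5))
    ell <- exp(opt$minimum)
    pred0 <- -0.5 * log(distances / ell) - distances / ell
    C_hat <- exp(mean(y - pred0))
    fitted <- C_hat * exp(pred0)
  }
  list(C_hat = C_hat, decay_length = ell, fitted = fitted)
}

#' Check the asymptotic-theory assumptions for a parameter set
#'
#' Flags parameter/layout combinations outside the validity region of the
#' tail approximations: inter-patch distances not large relative to
#' `sigma / sqrt(s_m)`; patch widths below the critical width for a stable
#' polymorphism; effective neighbourhood size too small
#' (`s_m <= 1 / (rho sigma^d)`, so local drift dominates); and a degenerate
#' establishment probability.
#'
#' @param params A [pop_params] object.
#' @param layout A [patch_layout] object (optional).
#' @return Character vector of flags (empty when all assumptions hold):
#'   subset of `"interpatch_distance"`, `"patch_width"`,
#'   `"neighborhood_size"`, `"establishment_prob"`.
#' @export
check_assumptions <- function(params, layout = NULL) {
  flags <- character(0)
  if (!is.null(layout)) {
    Rs <- layout$distances[upper.tri(layout$distances)]
    if (length(Rs) && any(Rs <= params$sigma / sqrt(params$s_m))) {
      flags <- c(flags, "interpatch_distance")
    }
    wcrit <- critical_patch_width(params$sigma, params$s_p, params$s_m)
    if (any(layout$patches$w_lin < wcrit)) {
      flags <- c(flags, "patch_width")
    }
  }
  # the theory needs s_m >> 1/(rho sigma^d) (Wright's neighbourhood size);
  # flag clear violations, i.e. s_m below half the drift scale's reciprocal
  if (params$s_m * params$rho * params$sigma^params$d < 0.5) {
    flags <- c(flags, "neighborhood_size")
  }
  pe <- panmictic_establishment_prob(params$s_p, params$xi2)
  if (pe <= 0 || pe >= 1) {
    flags <- c(flags, "establishment_prob")
  }
  flags
}
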