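#' Configuration for the forward deme-lattice simulator
#'
#' Individual-based (tracked at the level of counts) forward simulation of a
#' biallelic locus on a rectangular grid of demes of fixed size `N`. Each
#' generation: (1) every individual independently adds one offspring with
#' probability `r * (1 + s)` for its type and deme (`s = 0` for the ancestral
#' type b, the deme's `s_map` value for the adaptive type B); (2) every
#' individual stays put with probability `1 - m`, otherwise moves `k` steps
#' (`P(k)` proportional to `kernel`, default `2^-k` for `k = 1..5`) in a
#' uniformly chosen direction (cardinal in 1D; cardinal plus diagonal in 2D,
#' diagonals displacing `(k, k)`); migrants leaving the grid perish; (3) each
#' deme is uniformly resampled down to `N`; (4) each ancestral-type
#' individual mutates to B with probability `mu`.
#'
#' @param shape Integer vector: grid dimensions (length 1 for 1D, 2 for 2D).
#' @param N Individuals per deme.
#' @param s_map Per-deme selection multiplier for B (vector of length
#'   `prod(shape)` or matrix of dimension `shape`); B reproduces with
#'   probability `r * (1 + s)`.
#' @param r Base reproduction probability (default 0.3).
#' @param m Move probability per individual per generation (default 0.2).
#' @param kernel Unnormalized step-length masses for `k = 1, 2, ...`
#'   (default `2^-(1:5)`).
#' @param mu Per-individual b-to-B mutation probability per generation.
#' @param init Initial B counts per deme (default all zero).
#' @param t_max Number of generations to simulate.
#' @param focal_demes Deme indices (into the flattened grid) whose summed B
#'   count defines the adaptation time.
#' @param threshold B-allele count in the focal demes that defines
#'   "adapted" (default 100).
#' @param stop_when_adapted Stop the run at the first adapted generation.
#' @param seed Integer RNG seed (recorded in the result).
#' @return An object of class `deme_grid_config`.
#' @export
deme_grid_config <- function(shape, N, s_map, r = 0.3, m = 0.2,
                             kernel = 2^-(1:5), mu = 0, init = NULL,
                             t_max = 1000, focal_demes = NULL,
                             threshold = 100, stop_when_adapted = FALSE,
                             seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% 1:2, all(shape >= 1), N >= 1,
            r >= 0, m >= 0, m <= 1, mu >= 0, mu < 1, t_max >= 0)
  n_demes <- prod(shape)
  s_map <- as.numeric(s_map)
  if (length(s_map) == 1L) s_map <- rep(s_map, n_demes)
  stopifnot(length(s_map) == n_demes)
  if (any(r * (1 + s_map) < 0) || any(r * (1 + s_map) > 1)) {
    stop("reproduction probabilities r * (1 + s) must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(kernel < 0) || sum(kernel) <= 0) {
    stop("kernel masses must be nonnegative with positive sum", call. = FALSE)
  }
  if (is.null(init)) init <- integer(n_demes)
  init <- as.integer(init)
  stopifnot(length(init) == n_demes, all(init >= 0), all(init <= N))
  if (is.null(focal_demes)) focal_demes <- seq_len(n_demes)
  structure(list(shape = shape, N = as.integer(N), s_map = s_map, r = r,
                 m = m, kernel = kernel / sum(kernel), mu = mu, init = init,
                 t_max = as.integer(t_max),
                 focal_demes = as.integer(focal_demes),
                 threshold = threshold,
                 stop_when_adapted = isTRUE(stop_when_adapted),
                 seed = as.integer(seed)),
            class = "deme_grid_config")
}

# offsets of the migration model: list with per-offset probability and the
# destination index for every source deme (NA = off the grid)
build_offsets <- function(config) {
  shape <- config$shape
  ks <- seq_along(config$kernel)
  if (length(shape) == 1L) {
    dirs <- list(c(1), c(-1))
  } else {
    dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  probs <- c(1 - config$m,
             as.vector(outer(config$kernel, rep(1, length(dirs))) *
                         config$m / length(dirs)))
  deltas <- c(list(rep(0L, length(shape))),
              unlist(lapply(dirs, function(d) lapply(ks, function(k) k * d)),
                     recursive = FALSE))
  n <- prod(shape)
  dest <- matrix(NA_integer_, nrow = n, ncol = length(deltas))
  if (length(shape) == 1L) {
    pos <- seq_len(n)
    for (j in seq_along(deltas)) {
      to <- pos + deltas[[j]][1]
      to[to < 1 | to > n] <- NA_integer_
      dest[, j] <- to
    }
  } else {
    ix <- rep(seq_len(shape[1]), times = shape[2])
    iy <- rep(seq_len(shape[2]), each = shape[1])
    for (j in seq_along(deltas)) {
      tx <- ix + deltas[[j]][1]
      ty <- iy + deltas[[j]][2]
      ok <- tx >= 1 & tx <= shape[1] & ty >= 1 & ty <= shape[2]
      to <- ifelse(ok, (ty - 1L) * shape[1] + tx, NA_integer_)
      dest[, j] <- to
    }
  }
  list(probs = probs, dest = dest, deltas = deltas)
}

# allocate counts over offsets by sequential binomial peeling, then scatter
# to destinations; off-grid mass perishes
migrate_counts <- function(counts, offsets) {
  n <- length(counts)
  out <- numeric(n)
  remaining <- counts
  prem <- 1
  for (j in seq_along(offsets$probs)) {
    pj <- offsets$probs[j]
    if (pj <= 0) next
    take <- if (prem - pj < 1e-12) {
      remaining
    } else {
      stats::rbinom(n, remaining, pj / prem)
    }
    remaining <- remaining - take
    prem <- prem - pj
    to <- offsets$dest[, j]
    ok <- !is.na(to) & take > 0
    if (any(ok)) {
      out[to[ok]] <- out[to[ok]] + take[ok]
    }
    if (prem <= 1e-12) break
  }
  out
}

#' Run the forward deme-lattice simulation
#'
#' @param config A [deme_grid_config].
#' @return An object of class `sim_result`: list with `counts` (matrix of B
#'   counts, one row per recorded generation starting at generation 0, one
#'   column per deme in flattened order), `adaptation_time` (first generation
#'   with at least `threshold` B copies summed over the focal demes, or `NA`),
#'   and the `config` (with its seed) for exact reproduction.
#' @examples
#' cfg <- deme_grid_config(shape = 31, N = 100,
#'                         s_map = ifelse(abs(seq_len(31) - 16) <= 5, 0.1, -0.02),
#'                         init = ifelse(abs(seq_len(31) - 16) <= 5, 100, 0),
#'                         t_max = 50, seed = 7)
#' res <- run_forward(cfg)
#' @export
run_forward <- function(config) {
  stopifnot(inherits(config, "deme_grid_config"))
  set.seed(config$seed)
  offsets <- build_offsets(config)
  n <- prod(config$shape)
  N <- config$N
  pB <- config$r * (1 + config$s_map)
  pb <- config$r
  nB <- as.numeric(config$init)
  counts <- matrix(0, nrow = config$t_max + 1L, ncol = n)
  counts[1L, ] <- nB
  adapted_at <- NA_integer_
  if (sum(nB[config$focal_demes]) >= config$threshold) adapted_at <- 0L
  t_end <- config$t_max
  if (config$t_max > 0) {
    for (t in seq_len(config$t_max)) {
      nb <- N - nB
      # reproduction: each individual adds one offspring with prob r (1 + s)
      totB <- nB + stats::rbinom(n, nB, pB)
      totb <- nb + stats::rbinom(n, nb, pb)
      # migration
      totB <- migrate_counts(totB, offsets)
      totb <- migrate_counts(totb, offsets)
      # resample each deme down to N (if a deme ends up with fewer than N
      # individuals, the ancestral type fills it back up)
      pool <- totB + totb
      full <- pool >= N
      if (any(full)) {
        nB[full] <- stats::rhyper(sum(full), totB[full], totb[full], N)
      }
      if (any(!full)) {
        nB[!full] <- pmin(totB[!full], N)
      }
      # mutation b -> B
      if (config$mu > 0) {
        nB <- nB + stats::rbinom(n, N - nB, config$mu)
      }
      counts[t + 1L, ] <- nB
      if (is.na(adapted_at) &&
          sum(nB[config$focal_demes]) >= config$threshold) {
        adapted_at <- t
        if (config$stop_when_adapted) {
          t_end <- t
          break
        }
      }
    }
  }
  counts <- counts[seq_len(t_end + 1L), , drop = FALSE]
  structure(list(counts = counts, adaptation_time = adapted_at,
                 config = config, seed = config$seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Forward simulation:", paste(x$config$shape, collapse = " x "),
      "demes,", nrow(x$counts) - 1L, "generations recorded\n")
  cat("  adaptation time:",
      if (is.na(x$adaptation_time)) "not reached" else x$adaptation_time, "\n")
  invisible(x)
}

#' Intrinsic growth rate implied by the reproduction scheme
#'
#' The per-generation log growth rate of the adaptive allele when rare, for
#' base reproduction probability `r` and selection multiplier `s`:
#' `log((1 + r (1 + s)) / (1 + r))`. This is the selection coefficient to use
#' when comparing lattice simulations with the continuum theory.
#'
#' @param r Base reproduction probability.
#' @param s Selection multiplier (signed).
#' @return The effective selection coefficient per generation.
#' @examples
#' effective_selection(0.3, 0.01) # ~0.0023
#' @export
effective_selection <- function(r, s) {
  stopifnot(r * (1 + s) >= 0, r * (1 + s) <= 1)
  log((1 + r * (1 + s)) / (1 + r))
}

#' Offspring variance implied by the reproduction scheme
#'
#' Variance in the number of copies an individual leaves after one full
#' generation cycle (reproduce, then uniform resampling back down to `N`),
#' for a deme at carrying capacity: the individual has `W = 1 + Bernoulli(
#' r (1 + s))` copies entering the pool of expected size `N (1 + r)`, each
#' kept with probability `1/(1 + r)`, giving
#' `Var = E[W] p (1 - p) + p^2 Var[W]` with `p = 1/(1 + r)`. This is the
#' `xi^2` to use when comparing the lattice simulations with the continuum
#' theory (about 0.355 at `r = 0.3`, not 1).
#'
#' @param r Base reproduction probability.
#' @param s Selection multiplier (default 0; the dependence is weak).
#' @return The per-generation offspring variance.
#' @examples
#' offspring_variance(0.3) # ~0.355
#' @export
offspring_variance <- function(r, s = 0) {
  p <- 1 / (1 + r)
  EW <- 1 + r * (1 + s)
  VW <- r * (1 + s) * (1 - r * (1 + s))
  EW * p * (1 - p) + p^2 * VW
}

#' Dispersal distance implied by the migration model
#'
#' Per-axis root-mean-square parent--offspring displacement for move
#' probability `m` and step-length masses `kernel`: `sqrt(m E[k^2] c_d)`,
#' where `c_1 = 1` and `c_2 = 3/4` for the eight-direction 2D model (four
#' cardinal moves displace one axis by `k`, four diagonal moves displace both
#' axes by `k`).
#'
#' @param m Move probability.
#' @param kernel Unnormalized step-length masses for `k = 1, 2, ...`
#'   (default `2^-(1:5)`).
#' @param d Spatial dimension (1 or 2).
#' @return Sigma, in deme spacings.
#' @examples
#' dispersal_sigma(0.2) # ~0.95
#' @export
dispersal_sigma <- function(m, kernel = 2^-(1:5), d = 1) {
  stopifnot(m >= 0, m <= 1, d %in% c(1, 2))
  w <- kernel / sum(kernel)
  Ek2 <- sum(seq_along(w)^2 * w)
  cd <- if (d == 1) 1 else 3 / 4
  sqrt(m * Ek2 * cd)
}

#' Time until a patch is adapted
#'
#' The first recorded generation at which the summed B count over the focal
#' demes reaches `threshold`; `NA` if never within the simulated horizon.
#'
#' @param result A [run_forward] result.
#' @param threshold Allele-count threshold (default 100).
#' @param focal_demes Deme indices (default: the config's focal demes).
#' @return Generation number (0-based) or `NA`.
#' @export
time_to_adaptation <- function(result, threshold = 100, focal_demes = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(focal_demes)) focal_demes <- result$config$focal_demes
  tot <- rowSums(result$counts[, focal_demes, drop = FALSE])
  hit <- which(tot >= threshold)
  if (!length(hit)) return(NA_integer_)
  hit[1L] - 1L
}
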