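#' Network of habitat patches for the colonization Markov chain
#'
#' Combines a [patch_layout] with [pop_params] and precomputes, for every
#' patch, its mutation rate `lambda_mut` and, for every ordered pair, the
#' migration rate `lambda_mig` from an adapted patch into an unadapted one.
#'
#' @param layout A [patch_layout] with at least one patch.
#' @param params A [pop_params] object.
#' @return An object of class `patch_network`.
#' @export
patch_network <- function(layout, params) {
  stopifnot(inherits(layout, "patch_layout"), inherits(params, "pop_params"))
  k <- nrow(layout$patches)
  mut <- vapply(seq_len(k), function(i) {
    lambda_mut(params, layout$patches$area[i])
  }, numeric(1))
  mig <- matrix(0, k, k)
  if (k > 1L) {
    for (i in seq_len(k)) {         # source
      for (j in seq_len(k)) {       # target
        if (i == j) next
        Ap <- effective_area(layout$patches[j, ], params)
        # the chain competes mutation against the un-absorbed
        # family-occupation rate, twice the lambda_mig closed form;
        # this keeps the two-patch chain consistent with prob_parallel
        mig[i, j] <- 2 * suppressWarnings(
          lambda_mig(layout$distances[i, j], params, Ap))
      }
    }
  }
  structure(list(layout = layout, params = params,
                 lambda_mut = mut, lambda_mig = mig),
            class = "patch_network")
}

#' @export
print.patch_network <- function(x, ...) {
  cat("Patch network:", length(x$lambda_mut), "patch(es)\n")
  cat("  mutation rates:", paste(signif(x$lambda_mut, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exact stochastic simulation of patch colonization
#'
#' Continuous-time Markov chain over patch states: each unadapted patch
#' acquires the adaptation by new mutation at its `lambda_mut`, and by
#' migration at the sum of `lambda_mig` over currently adapted patches
#' (patches are assumed not to interfere with each other). Event times are
#' exponential; the simulation ends when every patch is adapted.
#'
#' @param network A [patch_network].
#' @return An object of class `partition_state`: list with `origin` (integer
#'   label of the founding mutation per patch), `events` (data frame with
#'   `time`, `patch`, `source` = `"mutation"` or the source patch index) and
#'   `n_origins`.
#' @export
gillespie_colonization <- function(network) {
  k <- length(network$lambda_mut)
  origin <- rep(NA_integer_, k)
  next_label <- 1L
  t_now <- 0
  events <- vector("list", k)
  for (step in seq_len(k)) {
    un <- which(is.na(origin))
    ad <- which(!is.na(origin))
    rate_mut <- network$lambda_mut[un]
    rate_mig <- if (length(ad)) {
      colSums(network$lambda_mig[ad, un, drop = FALSE])
    } else {
      numeric(length(un))
    }
    total <- sum(rate_mut) + sum(rate_mig)
    if (total <= 0) {
      stop("all colonization rates are zero (mu = 0 and no adapted patches)",
           call. = FALSE)
    }
    t_now <- t_now + stats::rexp(1, total)
    # pick the patch, then mutation vs migration, then the source patch
    patch_idx <- sample.int(length(un), 1L, prob = rate_mut + rate_mig)
    patch <- un[patch_idx]
    if (stats::runif(1) < rate_mut[patch_idx] /
        (rate_mut[patch_idx] + rate_mig[patch_idx])) {
      origin[patch] <- next_label
      next_label <- next_label + 1L
      src <- "mutation"
    } else {
      srcs <- network$lambda_mig[ad, patch]
      from <- ad[sample.int(length(ad), 1L, prob = srcs)]
      origin[patch] <- origin[from]
      src <- as.character(from)
    }
    events[[step]] <- data.frame(time = t_now, patch = patch, source = src)
  }
  structure(list(origin = origin, events = do.call(rbind, events),
                 n_origins = length(unique(origin))),
            class = "partition_state")
}

#' @export
print.partition_state <- function(x, ...) {
  cat("Colonization outcome:", length(x$origin), "patches,",
      x$n_origins, "independent origin(s)\n")
  cat("  origin labels:", paste(x$origin, collapse = " "), "\n")
  invisible(x)
}

#' Probability that a migrant adaptation came from each source patch
#'
#' Given that a focal patch adapts through migration, the probability the
#' allele came from adapted patch `i` at distance `R_i` is proportional to
#' `R_i^(-(d-1)/2) exp(-R_i sqrt(2 s_m)/sigma)`.
#'
#' @param distances Distances from the focal patch to each adapted patch.
#' @param params A [pop_params] object.
#' @return Normalized probabilities (sum to 1).
#' @export
origin_probabilities <- function(distances, params) {
  stopifnot(length(distances) >= 1, all(distances > 0))
  w <- distances^(-(params$d - 1) / 2) *
    exp(-distances * sqrt(2 * params$s_m) / params$sigma)
  w / sum(w)
}

#' Ewens concentration parameter of the island-model limit
#'
#' For many equal patches all at distance `R` from each other, the final
#' partition of patches by mutational origin follows the Ewens sampling
#' distribution. The concentration parameter is the mutation-to-migration
#' rate ratio
#' `theta = w mu exp(R sqrt(2 s_m)/sigma) / (2 C gamma s_m)`,
#' consistent with the mutation and migration rates used throughout (and
#' verified against the colonization chain on small networks).
#'
#' @param w Patch width in characteristic lengths (`A / A'`).
#' @param mu Mutation rate.
#' @param s_m Between-patch selective disadvantage.
#' @param R Common inter-patch distance.
#' @param sigma Dispersal distance.
#' @param C Cline constant (default 1).
#' @param gamma Establishment cap (default 1).
#' @return `theta`.
#' @export
island_theta <- function(w, mu, s_m, R, sigma, C = 1, gamma = 1) {
  stopifnot(w > 0, mu > 0, s_m > 0, R >= 0, sigma > 0)
  w * mu * exp(R * sqrt(2 * s_m) / sigma) / (2 * C * gamma * s_m)
}

#' Ewens sampling formula
#'
#' Probability of an unordered partition of `n` items into classes of the
#' given sizes under the Ewens sampling distribution with parameter `theta`:
#' `P = n! / theta_(n) * prod_j (theta / j)^(a_j) / a_j!`,
#' where `a_j` is the number of classes of size `j` and `theta_(n)` is the
#' rising factorial.
#'
#' @param sizes Integer class sizes (a partition of `n`).
#' @param theta Concentration parameter (> 0).
#' @return The partition probability.
#' @examples
#' ewens_partition_prob(c(2, 1, 1), theta = 1)
#' @export
ewens_partition_prob <- function(sizes, theta) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("class sizes must be positive integers", call. = FALSE)
  stopifnot(theta > 0)
  n <- sum(sizes)
  a <- tabulate(sizes, nbins = n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  exp(lfactorial(n) - log_rising +
        sum(a * (log(theta) - log(seq_len(n))) - lfactorial(a)))
}

#' Expected number of distinct origins in the island model
#'
#' `sum_{i=0}^{n-1} theta / (theta + i)`; grows logarithmically in the
#' number of patches `n`.
#'
#' @param theta Ewens concentration parameter.
#' @param n Number of patches.
#' @return Expected number of distinct mutational origins.
#' @export
expected_num_origins <- function(theta, n) {
  stopifnot(theta > 0, n >= 1)
  sum(theta / (theta + 0:(n - 1)))
}

#' All partitions of an integer
#'
#' Utility enumerating the integer partitions of `n` (used to normalize and
#' test the Ewens sampling formula on small cases).
#'
#' @param n Positive integer.
#' @return List of integer vectors in nonincreasing order.
#' @export
integer_partitions <- function(n) {
  rec <- function(n, max_part) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (p in seq_len(min(n, max_part))) {
      for (rest in rec(n - p, p)) {
        out[[length(out) + 1L]] <- c(p, rest)
      }
    }
    out
  }
  rec(n, n)
}
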