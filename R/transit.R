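#' Killed-Brownian transit model between two patches
#'
#' The trunk lineage of a rare migrant family is modelled as Brownian motion
#' with per-generation variance `sigma^2`, killed at rate `s_m` (the family's
#' asymptotic extinction rate). The model carries the shortest inter-patch
#' distance `R`, the target patch radius/width `w` (used for d = 2 and for
#' the within-patch occupation time), and the dimension `d`.
#'
#' @param R Shortest inter-patch distance (> 0).
#' @param sigma Dispersal distance (> 0).
#' @param s_m Killing (selection) rate per generation (> 0).
#' @param w Target patch radius/width (> 0).
#' @param d Spatial dimension (1 or 2).
#' @return An object of class `transit_model`.
#' @export
transit_model <- function(R, sigma, s_m, w = sigma, d = 1) {
  stopifnot(R > 0, sigma > 0, s_m > 0, w > 0, d %in% c(1, 2))
  structure(list(R = R, sigma = sigma, s_m = s_m, w = w, d = as.integer(d)),
            class = "transit_model")
}

#' @export
print.transit_model <- function(x, ...) {
  cat(sprintf("Killed-Brownian transit model (d = %d): R = %g, sigma = %g, s_m = %g, w = %g\n",
              x$d, x$R, x$sigma, x$s_m, x$w))
  cat(sprintf("  hit probability %g, R in characteristic lengths %g\n",
              transit_laplace(0, x), x$R * sqrt(2 * x$s_m) / x$sigma))
  invisible(x)
}

#' Mean migrant family size conditioned on survival
#'
#' The limiting mean size of a subcritical migrant family conditioned on
#' nonextinction, `E[K] = E[W(W-1)] / (E[W] s_m)`, for offspring number `W`.
#'
#' @param offspring Either the string `"poisson"` (with `mean`), or a list
#'   `list(k = ..., prob = ...)` giving an arbitrary offspring distribution
#'   with finite second moment.
#' @param s_m Selective disadvantage (> 0).
#' @param mean Offspring mean for the Poisson case (default `exp(-s_m)`).
#' @return `E[K]`.
#' @examples
#' family_size_mean("poisson", s_m = 0.05) # ~20
#' @export
family_size_mean <- function(offspring = "poisson", s_m, mean = exp(-s_m)) {
  if (s_m <= 0) stop("E[K] diverges for s_m <= 0", call. = FALSE)
  if (identical(offspring, "poisson")) {
    # E[W(W-1)] = mean^2 for Poisson
    EW <- mean; EWW1 <- mean^2
  } else {
    k <- offspring$k; pr <- offspring$prob / sum(offspring$prob)
    EW <- sum(k * pr); EWW1 <- sum(k * (k - 1) * pr)
  }
  EWW1 / (EW * s_m)
}

#' Simulate subcritical migrant-family size trajectories
#'
#' Branching-process realizations with Poisson offspring of mean
#' `exp(-s_m)`, started from a single individual. Useful as a Monte-Carlo
#' check of the survival identity
#' `exp(-s_m t) = (1 - k_e(t)) E[Z_t | Z_t > 0]`.
#'
#' @param s_m Selective disadvantage per generation.
#' @param t_max Number of generations to simulate.
#' @param reps Number of independent families.
#' @param mean Offspring mean (default `exp(-s_m)`).
#' @return Integer matrix of family sizes, `reps` rows by `t_max + 1` columns
#'   (column 1 is generation 0).
#' @export
simulate_family <- function(s_m, t_max, reps = 1, mean = exp(-s_m)) {
  stopifnot(is.finite(t_max), t_max >= 0, reps >= 1)
  Z <- matrix(0L, nrow = reps, ncol = t_max + 1L)
  Z[, 1L] <- 1L
  z <- rep(1L, reps)
  for (t in seq_len(t_max)) {
    alive <- z > 0L
    if (any(alive)) {
      z[alive] <- stats::rpois(sum(alive), mean * z[alive])
    }
    Z[, t + 1L] <- z
  }
  Z
}

#' Laplace transform of the transit time
#'
#' `E[exp(-l tau)]` for the first hitting time `tau` of the target patch by
#' the killed Brownian trunk (`tau = infinity` if killed first):
#' one dimension `exp(-R sqrt(2 (s_m + l)) / sigma)`; two dimensions
#' `K_0((R + w) sqrt(2 (s_m + l)) / sigma) / K_0(w sqrt(2 (s_m + l)) / sigma)`.
#' At `l = 0` this is the probability the family ever reaches the patch.
#'
#' @param l Nonnegative rate(s) at which the transform is evaluated.
#' @param model A [transit_model].
#' @return The transform value(s), decreasing in `l` and in `R`.
#' @export
transit_laplace <- function(l, model) {
  stopifnot(all(l >= 0))
  a <- sqrt(2 * (model$s_m + l)) / model$sigma
  if (model$d == 1L) {
    exp(-model$R * a)
  } else {
    besselK((model$R + model$w) * a, 0) / besselK(model$w * a, 0)
  }
}

#' Mean and variance of the transit time (one dimension)
#'
#' Conditioned on reaching the patch, the trunk's transit time has
#' `E[tau] = (R sqrt(2 s_m)/sigma) / (2 s_m)` and
#' `Var[tau] = (R sqrt(2 s_m)/sigma) / (2 s_m)^2`: successful migrants
#' effectively move at speed `sigma sqrt(2 s_m)`.
#'
#' @param model A [transit_model] with `d = 1`.
#' @return List with `mean` and `variance`, in generations.
#' @export
transit_time_moments <- function(model) {
  if (model$d != 1L) {
    stop("conditioned transit-time moments are only available for d = 1",
         call. = FALSE)
  }
  z <- model$R * sqrt(2 * model$s_m) / model$sigma
  list(mean = z / (2 * model$s_m), variance = z / (2 * model$s_m)^2)
}

#' Survival function of the hitchhiking haplotype length
#'
#' The genetic length `L` (Morgans, one side of the selected site) of the
#' ancestral haplotype still linked to the allele when it founds the new
#' patch satisfies `P{L > l} = E[exp(-l tau) | tau < infinity]`, which in one
#' dimension is
#' `exp(-(R/sigma) (sqrt(2 (l + s_m)) - sqrt(2 s_m)))`.
#'
#' @param l Genetic distance(s) in Morgans (>= 0).
#' @param model A [transit_model] with `d = 1`.
#' @return `P{L > l}`.
#' @export
haplotype_survival <- function(l, model) {
  stopifnot(all(l >= 0))
  if (model$d != 1L) {
    stop("the closed-form haplotype survival is only available for d = 1",
         call. = FALSE)
  }
  exp(-(model$R / model$sigma) * (sqrt(2 * (l + model$s_m)) - sqrt(2 * model$s_m)))
}

#' Mean and variance of the hitchhiking haplotype length (one dimension)
#'
#' `E[L] = sigma sqrt(2 s_m)/R + sigma^2/R^2` and
#' `Var[L] = 2 s_m sigma^2/R^2 + 4 sigma^3 sqrt(2 s_m)/R^3 + 5 sigma^4/R^4`,
#' both in Morgans. Equivalently `L` is distributed as
#' `(Y + sqrt(s_m))^2 - s_m` with `Y ~ Exp(rate R sqrt(2)/sigma)`; the
#' printed variance agrees exactly with that representation.
#'
#' @param model A [transit_model] with `d = 1`.
#' @return List with `mean` and `variance` (Morgans, Morgans^2).
#' @export
haplotype_moments <- function(model) {
  if (model$d != 1L) {
    stop("haplotype-length moments are only available for d = 1", call. = FALSE)
  }
  R <- model$R; sig <- model$sigma; s <- model$s_m
  list(mean = sig * sqrt(2 * s) / R + sig^2 / R^2,
       variance = 2 * s * sig^2 / R^2 + 4 * sig^3 * sqrt(2 * s) / R^3 +
         5 * sig^4 / R^4)
}

#' Sample hitchhiking haplotype lengths via the exponential representation
#'
#' Draws from the distribution of `L` using
#' `L = (Y + sqrt(s_m))^2 - s_m`, `Y ~ Exp(rate R sqrt(2)/sigma)`.
#'
#' @param n Number of draws.
#' @param model A [transit_model] with `d = 1`.
#' @return Numeric vector of lengths in Morgans.
#' @export
sample_haplotype_length <- function(n, model) {
  if (model$d != 1L) stop("d = 1 only", call. = FALSE)
  y <- stats::rexp(n, rate = model$R * sqrt(2) / model$sigma)
  (y + sqrt(model$s_m))^2 - model$s_m
}

#' Expected within-patch occupation time of a killed Brownian motion
#'
#' The expected time a migrant trunk entering at the patch edge spends inside
#' the patch before being killed: one dimension
#' `(1 - exp(-2 w sqrt(2 s_m)/sigma)) / (2 s_m)`; two dimensions
#' `(1/(2 s_m)) (1 - (2 w sqrt(2 s_m)/sigma) K_1(2 w sqrt(2 s_m)/sigma))`.
#' Both tend to `1/(2 s_m)` for wide patches.
#'
#' @param w Patch half-width/radius (> 0).
#' @param s_m Killing rate.
#' @param sigma Dispersal distance.
#' @param d Spatial dimension (1 or 2).
#' @return Expected occupation time in generations.
#' @export
patch_occupancy_g <- function(w, s_m, sigma, d = 1) {
  stopifnot(w > 0, s_m > 0, sigma > 0, d %in% c(1, 2))
  z <- 2 * w * sqrt(2 * s_m) / sigma
  if (d == 1) {
    (1 - exp(-z)) / (2 * s_m)
  } else {
    (1 - z * besselK(z, 1)) / (2 * s_m)
  }
}

#' Monte-Carlo killed Brownian transit (oracle simulator)
#'
#' Euler--Maruyama simulation of the trunk lineage: per-axis steps
#' `N(0, sigma^2 dt)`, killing applied per step with probability
#' `1 - exp(-s_m dt)`, absorption at the first crossing of distance `R`
#' (d = 1: level `R`; d = 2: entry into the disc of radius `w` centred at
#' distance `R + w`). The discretization bias is `O(sqrt(dt))`.
#'
#' @param model A [transit_model].
#' @param reps Number of independent paths.
#' @param dt Time step in generations (default 0.01).
#' @param t_max Time horizon in generations (default `50 / s_m`).
#' @param occupancy_halfwidth If non-`NULL` (d = 1), also accumulate the time
#'   each path spends in `[0, 2 * occupancy_halfwidth]` before being killed
#'   (no absorption in that case).
#' @return A data frame with columns `hit` (logical) and `time` (hitting time
#'   for hits, `NA` otherwise); when `occupancy_halfwidth` is set, a column
#'   `occupation` instead.
#' @export
simulate_killed_brownian <- function(model, reps, dt = 0.01,
                                     t_max = 50 / model$s_m,
                                     occupancy_halfwidth = NULL) {
  stopifnot(reps >= 1, dt > 0)
  n_steps <- ceiling(t_max / dt)
  kill_p <- 1 - exp(-model$s_m * dt)
  sd_step <- model$sigma * sqrt(dt)

  if (!is.null(occupancy_halfwidth)) {
    if (model$d != 1L) stop("occupancy mode is d = 1 only", call. = FALSE)
    x <- numeric(reps)
    occ <- numeric(reps)
    alive <- rep(TRUE, reps)
    for (i in seq_len(n_steps)) {
      idx <- which(alive)
      if (!length(idx)) break
      killed <- stats::runif(length(idx)) < kill_p
      alive[idx[killed]] <- FALSE
      idx <- idx[!killed]
      if (!length(idx)) next
      occ[idx] <- occ[idx] +
        dt * (x[idx] >= 0 & x[idx] <= 2 * occupancy_halfwidth)
      x[idx] <- x[idx] + stats::rnorm(length(idx), sd = sd_step)
    }
    return(data.frame(hit = NA, occupation = occ))
  }

  hit <- rep(FALSE, reps)
  time <- rep(NA_real_, reps)
  if (model$d == 1L) {
    x <- numeric(reps)
    active <- rep(TRUE, reps)
    for (i in seq_len(n_steps)) {
      idx <- which(active)
      if (!length(idx)) break
      killed <- stats::runif(length(idx)) < kill_p
      active[idx[killed]] <- FALSE
      idx <- idx[!killed]
      if (!length(idx)) next
      x[idx] <- x[idx] + stats::rnorm(length(idx), sd = sd_step)
      arrived <- idx[x[idx] >= model$R]
      if (length(arrived)) {
        hit[arrived] <- TRUE
        time[arrived] <- i * dt
        active[arrived] <- FALSE
      }
    }
  } else {
    cx <- model$R + model$w  # target disc centre on the x-axis
    x <- numeric(reps); y <- numeric(reps)
    active <- rep(TRUE, reps)
    for (i in seq_len(n_steps)) {
      idx <- which(active)
      if (!length(idx)) break
      killed <- stats::runif(length(idx)) < kill_p
      active[idx[killed]] <- FALSE
      idx <- idx[!killed]
      if (!length(idx)) next
      x[idx] <- x[idx] + stats::rnorm(length(idx), sd = sd_step)
      y[idx] <- y[idx] + stats::rnorm(length(idx), sd = sd_step)
      d2 <- (x[idx] - cx)^2 + y[idx]^2
      arrived <- idx[d2 <= model$w^2]
      if (length(arrived)) {
        hit[arrived] <- TRUE
        time[arrived] <- i * dt
        active[arrived] <- FALSE
      }
    }
  }
  data.frame(hit = hit, time = time)
}
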