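#' Per-deme selection profile on a one-dimensional lattice
#'
#' Builds the signed selection coefficient `s(x)` for each deme of a
#' one-dimensional lattice: `s_in` inside a central patch, `s_out`
#' (typically negative) outside, with an optional linear transition over
#' `transition_width` demes straddling each patch edge.
#'
#' @param n_demes Number of demes (>= 3).
#' @param patch Integer vector of deme indices forming the patch (contiguous).
#' @param s_in Selection coefficient inside the patch.
#' @param s_out Selection coefficient outside the patch (negative for a
#'   deleterious allele).
#' @param transition_width Number of demes over which `s` interpolates
#'   linearly between `s_out` and `s_in` (0 = abrupt step).
#' @return An object of class `selection_profile` (list with `n_demes`, `s`,
#'   `transition_width`).
#' @export
selection_profile <- function(n_demes, patch, s_in, s_out,
                              transition_width = 0) {
  stopifnot(n_demes >= 3, all(patch >= 1), all(patch <= n_demes),
            transition_width >= 0)
  s <- rep(s_out, n_demes)
  s[patch] <- s_in
  if (transition_width > 0) {
    lo <- min(patch); hi <- max(patch)
    ramp <- seq(s_out, s_in, length.out = transition_width + 2L)
    ramp <- ramp[-c(1L, length(ramp))]
    # ramp only edges interior to the lattice (a patch touching the
    # boundary has no transition on that side)
    if (lo > 1L) {
      left <- seq(lo - ceiling(transition_width / 2),
                  length.out = transition_width)
      keep <- left >= 1 & left <= n_demes
      s[left[keep]] <- ramp[keep]
    }
    if (hi < n_demes) {
      right <- seq(hi - floor(transition_width / 2) + 1L,
                   length.out = transition_width)
      keep <- right >= 1 & right <= n_demes
      s[right[keep]] <- rev(ramp)[keep]
    }
  }
  if (any(!is.finite(s))) stop("selection profile must be finite everywhere")
  structure(list(n_demes = as.integer(n_demes), s = s,
                 transition_width = transition_width),
            class = "selection_profile")
}

#' Nearest-neighbour migration kernel on a one-dimensional lattice
#'
#' Row-stochastic (up to boundary loss) migration matrix: each offspring
#' stays in its deme with probability `1 - m` and otherwise moves one step to
#' a uniformly chosen neighbour (`m/2` per side). Offspring stepping off the
#' lattice perish, so edge rows sum to less than one.
#'
#' @param n_demes Number of demes.
#' @param m Total per-offspring move probability (default 0.5, i.e. 0.25 per
#'   side).
#' @return An `n_demes` x `n_demes` matrix.
#' @export
migration_kernel_1d <- function(n_demes, m = 0.5) {
  stopifnot(n_demes >= 2, m >= 0, m <= 1)
  M <- diag(1 - m, n_demes)
  side <- m / 2
  idx <- seq_len(n_demes - 1L)
  M[cbind(idx, idx + 1L)] <- side
  M[cbind(idx + 1L, idx)] <- side
  M
}

#' Establishment-probability profile by generating-function fixed point
#'
#' Computes `p(x)`, the probability that a single new copy of the allele
#' appearing in deme `x` escapes demographic stochasticity, for a spatial
#' branching process on a one-dimensional deme lattice with Poisson offspring
#' of mean `1 + s(x)` and migration given by `kernel`. The extinction
#' probability `q = 1 - p` is the minimal fixed point of the per-deme
#' generating map
#' `q_x <- exp(-(1 + s(x)) * sum_y m_xy (1 - q_y))`
#' (offspring leaving the lattice perish, i.e. their lines are extinct).
#' The iteration starts from `q = 0`, is monotonically increasing, and stops
#' when the sup-norm change drops below `tol`.
#'
#' @param profile A [selection_profile].
#' @param kernel Migration matrix (rows may sum to < 1; the deficit is
#'   off-lattice loss), e.g. from [migration_kernel_1d].
#' @param tol Convergence tolerance on the sup-norm change (default 1e-12).
#' @param max_iter Maximum number of sweeps (default 1e6).
#' @return Numeric vector `p(x)` of establishment probabilities, one per
#'   deme, with attribute `iterations`.
#' @examples
#' prof <- selection_profile(41, 21:41, s_in = 0.05, s_out = -0.05)
#' p <- extinction_fixed_point(prof, migration_kernel_1d(41))
#' @export
extinction_fixed_point <- function(profile, kernel, tol = 1e-12,
                                   max_iter = 1e6) {
  stopifnot(inherits(profile, "selection_profile"), tol > 0)
  s <- profile$s
  n <- profile$n_demes
  stopifnot(nrow(kernel) == n, ncol(kernel) == n)
  rs <- rowSums(kernel)
  if (any(rs > 1 + 1e-12)) {
    stop("migration kernel rows must sum to at most 1", call. = FALSE)
  }
  lam <- 1 + s
  if (any(lam <= 0)) stop("offspring mean 1 + s must be > 0", call. = FALSE)
  q <- numeric(n)
  it <- 0L
  repeat {
    it <- it + 1L
    # survival mass seen by a parent in deme x: sum_y m_xy * p_y
    qn <- exp(-lam * drop(kernel %*% (1 - q)))
    delta <- max(abs(qn - q))
    q <- qn
    if (delta < tol) break
    if (it >= max_iter) {
      stop(sprintf("fixed-point iteration did not converge in %d sweeps (last sup-norm change %.3e)",
                   as.integer(max_iter), delta), call. = FALSE)
    }
  }
  p <- 1 - q
  # a deleterious boundary deme with appreciable p means the lattice is too
  # narrow for the tail to die out before the edge
  edge <- c(1L, n)
  if (any(s[edge] < 0 & p[edge] > max(sqrt(tol), 1e-6))) {
    warning("establishment probability is nonzero at a deleterious lattice boundary; widen the lattice")
  }
  structure(p, iterations = it)
}

#' Establishment probability in a homogeneous environment
#'
#' The scalar fixed point `p = 1 - exp(-(1 + s) p)` for a branching process
#' with Poisson(1 + s) offspring: the panmictic limit of
#' [extinction_fixed_point]. Zero for `s <= 0`.
#'
#' @param s Selection coefficient.
#' @return The establishment probability.
#' @examples
#' homogeneous_establishment(0.05) # ~0.0937
#' @export
homogeneous_establishment <- function(s) {
  if (s <= 0) return(0)
  f <- function(p) p - 1 + exp(-(1 + s) * p)
  # f(0) = 0 is the trivial root; bracket the positive one from above 0
  lower <- s / 10
  while (f(lower) >= 0) lower <- lower / 10
  stats::uniroot(f, c(lower, 1), tol = 1e-14)$root
}
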