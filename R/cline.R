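#' Define a migration--selection cline problem
#'
#' Discretization of the deterministic reaction--diffusion equation for the
#' allele frequency field,
#' `0 = (sigma^2/2) xi'' + s(x) xi (1 - xi)`
#' (plus the radial drift term `(sigma^2 (d-1) / (2 r)) xi'` for radially
#' symmetric problems). The grid spacing should be well below the
#' characteristic length `sigma / sqrt(2 max|s|)` and the outer boundary
#' several characteristic lengths beyond the patch.
#'
#' @param x Strictly increasing uniform grid (positions for d = 1, radii
#'   starting at 0 for radial problems).
#' @param s Signed selection coefficient at each grid point (positive inside
#'   the patch, negative outside).
#' @param sigma Dispersal distance.
#' @param d Spatial dimension (1, or 2 for the radial solver).
#' @return An object of class `cline_problem`.
#' @export
cline_problem <- function(x, s, sigma, d = 1) {
  stopifnot(length(x) == length(s), length(x) >= 5, sigma > 0, d %in% c(1, 2))
  h <- diff(x)
  if (any(abs(h - h[1]) > 1e-8 * h[1])) {
    stop("'x' must be a uniform grid", call. = FALSE)
  }
  ell_min <- sigma / sqrt(2 * max(abs(s)))
  if (h[1] > ell_min / 2) {
    warning("grid spacing is coarse relative to the characteristic length sigma/sqrt(2 max|s|)")
  }
  structure(list(x = x, s = s, sigma = sigma, d = as.integer(d), h = h[1]),
            class = "cline_problem")
}

# damped Newton on the discrete steady-state residual with zero-flux ends;
# radial = TRUE adds the (d-1)/r first-derivative term with the L'Hopital
# correction at r = 0 (the operator becomes d * (sigma^2/2) xi'' there)
solve_cline <- function(problem, tol, max_iter, radial) {
  x <- problem$x; s <- problem$s; h <- problem$h; sig2 <- problem$sigma^2
  n <- length(x)
  a <- sig2 / (2 * h^2)

  # second-difference operator with reflecting (zero-flux) boundaries
  main <- rep(-2 * a, n)
  up <- rep(a, n - 1)
  lo <- rep(a, n - 1)
  # ghost-point reflection: xi_0 = xi_2, xi_{n+1} = xi_{n-1}
  up[1] <- 2 * a
  lo[n - 1] <- 2 * a
  if (radial && problem$d == 2L) {
    b <- sig2 / (2 * 2 * h)  # coefficient of (1/r) * central first difference
    r <- x
    # interior rows get (d-1)/r * first-derivative term
    for (i in 2:(n - 1)) {
      up[i] <- up[i] + b / r[i]
      lo[i - 1] <- lo[i - 1] - b / r[i]
    }
    if (r[1] == 0) {
      # L'Hopital at r = 0: operator is d * (sigma^2/2) xi''
      main[1] <- -2 * a * problem$d
      up[1] <- 2 * a * problem$d
    }
    # outer boundary: keep reflection (domain chosen large enough)
  }
  L <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(lo, main, up))

  resid <- function(xi) drop(L %*% xi) + s * xi * (1 - xi)

  # initial guess: logistic limits by sign of s
  xi <- ifelse(s > 0, 0.95, 1e-3)
  r0 <- resid(xi)
  nrm <- max(abs(r0))
  hist <- nrm
  for (it in seq_len(max_iter)) {
    if (nrm < tol) break
    J <- L + Matrix::Diagonal(n, s * (1 - 2 * xi))
    step <- tryCatch(as.numeric(Matrix::solve(J, -r0)),
                     error = function(e) NULL)
    if (is.null(step)) step <- 0.1 * r0  # pseudo-timestep fallback
    lambda <- 1
    repeat {
      xi_new <- pmin(1 - 1e-12, pmax(0, xi + lambda * step))
      r_new <- resid(xi_new)
      if (max(abs(r_new)) < nrm || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    xi <- xi_new; r0 <- r_new; nrm <- max(abs(r_new))
    hist <- c(hist, nrm)
    if (it == max_iter && nrm >= tol) {
      stop(paste0("cline solver did not converge; residual history: ",
                  paste(signif(utils::tail(hist, 5), 3), collapse = " ")),
           call. = FALSE)
    }
  }
  if (xi[n] > 10 * tol && s[n] < 0) {
    warning("equilibrium frequency at the outer boundary exceeds 10 * tol; enlarge the domain")
  }
  structure(list(x = x, s = s, xi = xi, residual = nrm, problem = problem),
            class = "cline_solution")
}

#' Steady-state allele-frequency cline in one dimension
#'
#' Solves `(sigma^2/2) xi'' + s(x) xi (1 - xi) = 0` on the problem grid with
#' zero-flux boundaries, by damped Newton iteration (second-order central
#' differences) with a pseudo-timestepping fallback. The solution stays in
#' `[0, 1]` and its far-field log-slope approaches `-sqrt(2 s_m)/sigma`.
#'
#' @param problem A [cline_problem] with `d = 1`.
#' @param tol Sup-norm residual tolerance (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return A `cline_solution`: list with `x`, `s`, `xi`, `residual`.
#' @export
solve_equilibrium_1d <- function(problem, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(problem, "cline_problem"))
  solve_cline(problem, tol, max_iter, radial = FALSE)
}

#' Steady-state radial cline around a circular patch
#'
#' Solves the radially symmetric steady state
#' `(sigma^2/2)(xi'' + ((d-1)/r) xi') + s(r) xi (1 - xi) = 0`
#' with the symmetry condition at `r = 0` handled by an L'Hopital-corrected
#' stencil. With `d = 1` the drift term vanishes and the solution matches
#' [solve_equilibrium_1d].
#'
#' @param problem A [cline_problem] whose `x` is the radial grid from 0.
#' @param tol Sup-norm residual tolerance (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return A `cline_solution`.
#' @export
solve_equilibrium_radial <- function(problem, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(problem, "cline_problem"))
  solve_cline(problem, tol, max_iter, radial = TRUE)
}

#' @export
print.cline_solution <- function(x, ...) {
  cat("Cline steady state on", length(x$x), "grid points; sup-norm residual",
      format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Linearized far-field tail of the equilibrium frequency
#'
#' The decaying solution of the linearized steady-state equation
#' `u'' + ((d-1)/r) u' - (2 s_m / sigma^2) u = 0`,
#' in modified-Bessel form
#' `u(r) = C' c_d z^((2-d)/2) K_((2-d)/2)(z)` with
#' `z = (r - r1) sqrt(2 s_m)/sigma`, normalized (`c_1 = sqrt(2/pi)`,
#' `c_2 = 1`) so that for d = 1 it reduces exactly to
#' `C' exp(-(r - r1) sqrt(2 s_m)/sigma)`. At large `r` it behaves as
#' `r^((1-d)/2) exp(-r sqrt(2 s_m)/sigma)` up to a constant.
#'
#' @param r Radii (> `r1`).
#' @param s_m Between-patch selective disadvantage.
#' @param sigma Dispersal distance.
#' @param d Spatial dimension (1 or 2). For d = 2 the form solves the radial
#'   equation only with `r1 = 0`.
#' @param C_prime Multiplicative constant.
#' @param r1 Offset matching the inner boundary condition.
#' @return `u(r)`.
#' @export
linearized_tail <- function(r, s_m, sigma, d = 1, C_prime = 1, r1 = 0) {
  stopifnot(all(r > r1), s_m > 0, sigma > 0, d %in% c(1, 2))
  z <- (r - r1) * sqrt(2 * s_m) / sigma
  nu <- (2 - d) / 2
  cd <- if (d == 1) sqrt(2 / pi) else 1
  C_prime * cd * z^nu * besselK(z, nu)
}
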