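#' Global population parameters
#'
#' Bundles the scalar parameters of the patchy-landscape model: a single
#' biallelic locus whose derived allele B is favoured (selection `s_p`) inside
#' discrete habitat patches and disfavoured (selection `s_m`) everywhere else,
#' in a population of constant density `rho` dispersing with RMS per-axis
#' parent--offspring distance `sigma`.
#'
#' @param sigma Dispersal distance: root-mean-squared parent--offspring
#'   displacement per axis, in the distance unit used throughout (> 0).
#' @param s_m Selective disadvantage of the allele between patches, per
#'   generation. Supplied as a positive number; it is applied as a
#'   disadvantage.
#' @param s_p Selective advantage of the allele inside a patch, per
#'   generation (> 0).
#' @param mu Mutation rate towards the adaptive allele, per chromosome per
#'   generation (in `[0, 1)`).
#' @param rho Population density, per unit area (d = 2) or per unit length /
#'   per deme (d = 1) (> 0).
#' @param xi2 Variance in offspring number (> 0); enters the establishment
#'   probability `p_e = 2 s_p / xi2`.
#' @param C Dimensionless cline constant multiplying the equilibrium-frequency
#'   tail; 1 by default, fitted to data in applications.
#' @param d Spatial dimension, 1 or 2.
#' @param preset Optional named preset: `"fig4"` sets `C = 5`, the value that
#'   matches the deme-lattice simulations.
#'
#' @return An object of class `pop_params`.
#' @examples
#' p <- pop_params(sigma = 1, s_m = 0.05, s_p = 0.1, mu = 1e-5, rho = 10)
#' characteristic_length(p)
#' @export
pop_params <- function(sigma, s_m, s_p, mu = 0, rho = 1, xi2 = 1, C = 1,
                       d = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("theory", "fig4"))
    if (preset == "fig4") C <- 5
  }
  p <- structure(
    list(sigma = as.numeric(sigma), s_m = as.numeric(s_m),
         s_p = as.numeric(s_p), mu = as.numeric(mu), rho = as.numeric(rho),
         xi2 = as.numeric(xi2), C = as.numeric(C), d = as.integer(d)),
    class = "pop_params"
  )
  validate_pop_params(p)
  p
}

validate_pop_params <- function(p) {
  stop_param <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("sigma", "s_m", "s_p", "mu", "rho", "xi2", "C")) {
    stop_param(!num1(p[[f]]), sprintf("'%s' must be a single finite number", f))
  }
  stop_param(p$sigma <= 0, "'sigma' must be > 0")
  stop_param(p$s_m <= 0, "'s_m' must be > 0 (the s_m = 0 case needs a different model)")
  stop_param(p$s_p <= 0, "'s_p' must be > 0")
  stop_param(p$mu < 0 || p$mu >= 1, "'mu' must be in [0, 1)")
  stop_param(p$rho <= 0, "'rho' must be > 0")
  stop_param(p$xi2 <= 0, "'xi2' must be > 0")
  stop_param(p$C <= 0, "'C' must be > 0")
  stop_param(!(p$d %in% c(1L, 2L)), "'d' must be 1 or 2")
  invisible(p)
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population parameters (d =", x$d, ")\n")
  cat(sprintf("  sigma = %g, s_m = %g, s_p = %g, mu = %g\n",
              x$sigma, x$s_m, x$s_p, x$mu))
  cat(sprintf("  rho = %g, xi2 = %g, C = %g\n", x$rho, x$xi2, x$C))
  cat(sprintf("  characteristic length sigma/sqrt(2 s_m) = %g\n",
              characteristic_length(x)))
  invisible(x)
}

#' Characteristic length of the equilibrium cline
#'
#' `sigma / sqrt(2 s_m)`: the spatial scale of exponential decay of the
#' allele's equilibrium frequency away from a patch. All inter-patch
#' distances are naturally measured in these units.
#'
#' @param params A [pop_params] object.
#' @return The characteristic length, in the units of `sigma`.
#' @export
characteristic_length <- function(params) {
  params$sigma / sqrt(2 * params$s_m)
}

#' Establishment-vs-swamping factor gamma
#'
#' `gamma = min(1, s_m / p_e)` with `p_e = 2 s_p / xi2`; caps the migrant
#' establishment term so that a family arriving at a patch establishes with
#' probability at most one.
#'
#' @param params A [pop_params] object.
#' @return A number in `(0, 1]`.
#' @export
gamma_factor <- function(params) {
  pe <- panmictic_establishment_prob(params$s_p, params$xi2)
  min(1, params$s_m / pe)
}

#' Patch geometries and inter-patch distances
#'
#' @param patches A data frame with one row per patch and columns `area`,
#'   `w_lin` (linear extent towards other patches) and `w_perp` (transverse
#'   extent; ignored for d = 1).
#' @param distances Symmetric matrix of shortest inter-patch distances, in the
#'   same unit as `sigma`; `NULL` for a single patch.
#' @return An object of class `patch_layout`.
#' @examples
#' patch_layout(data.frame(area = c(10, 10), w_lin = 10, w_perp = 1),
#'              distances = matrix(c(0, 50, 50, 0), 2))
#' @export
patch_layout <- function(patches, distances = NULL) {
  stopifnot(is.data.frame(patches), nrow(patches) >= 1L)
  if (!all(c("area", "w_lin") %in% names(patches))) {
    stop("'patches' needs columns 'area' and 'w_lin'", call. = FALSE)
  }
  if (is.null(patches$w_perp)) patches$w_perp <- patches$area / patches$w_lin
  if (any(patches$area <= 0) || any(patches$w_lin <= 0) ||
      any(patches$w_perp <= 0)) {
    stop("patch areas and widths must be > 0", call. = FALSE)
  }
  if (is.null(distances)) {
    distances <- matrix(0, nrow(patches), nrow(patches))
  }
  distances <- as.matrix(distances)
  if (!isTRUE(all.equal(distances, t(distances))) ||
      any(diag(distances) != 0) || any(distances < 0)) {
    stop("'distances' must be a symmetric nonnegative matrix with zero diagonal",
         call. = FALSE)
  }
  if (nrow(distances) != nrow(patches)) {
    stop("'distances' dimension must match the number of patches", call. = FALSE)
  }
  structure(list(patches = patches, distances = distances),
            class = "patch_layout")
}

#' @export
print.patch_layout <- function(x, ...) {
  cat("Patch layout with", nrow(x$patches), "patch(es)\n")
  print(x$patches)
  if (nrow(x$patches) > 1L) {
    cat("shortest distances:\n")
    print(x$distances)
  }
  invisible(x)
}
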