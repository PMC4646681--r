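#' Load a parameter configuration from JSON
#'
#' Reads a JSON object with keys `sigma`, `s_m`, `s_p`, `mu`, `rho`, `xi2`,
#' `C`, `d` and optionally `patches` (list of objects with `area`, `w_lin`,
#' `w_perp`) and `distances` (matrix), validates every invariant, and returns
#' the corresponding parameter objects.
#'
#' @param path Path to a JSON file.
#' @return List with `params` ([pop_params]) and `layout` ([patch_layout] or
#'   `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("sigma", "s_m", "s_p")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing required keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- tryCatch(
    pop_params(sigma = cfg$sigma, s_m = cfg$s_m, s_p = cfg$s_p,
               mu = cfg$mu %||% 0, rho = cfg$rho %||% 1,
               xi2 = cfg$xi2 %||% 1, C = cfg$C %||% 1, d = cfg$d %||% 1),
    error = function(e) stop("invalid config: ", conditionMessage(e),
                             call. = FALSE)
  )
  layout <- NULL
  if (!is.null(cfg$patches)) {
    patches <- as.data.frame(cfg$patches)
    layout <- tryCatch(
      patch_layout(patches, cfg$distances),
      error = function(e) stop("invalid config ('patches'/'distances'): ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  list(params = params, layout = layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter configuration to JSON
#'
#' Inverse of [load_config]; a written config loads back identically.
#'
#' @param params A [pop_params] object.
#' @param layout Optional [patch_layout].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, layout = NULL, path) {
  cfg <- unclass(params)
  if (!is.null(layout)) {
    cfg$patches <- layout$patches
    cfg$distances <- layout$distances
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run records a manifest: a hash of the configuration,
#' the seed(s), the package version, wall-clock start/end, and the list of
#' output files, so that any stochastic output can be reproduced exactly.
#'
#' @param config_path Path of the configuration file used (hashed with md5),
#'   or `NULL`.
#' @param seed Seed(s) used.
#' @param outputs Character vector of output file paths.
#' @param started POSIXct start time.
#' @param path Manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config_path, seed, outputs, started,
                           path) {
  manifest <- list(
    config_hash = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else NA_character_,
    seed = seed,
    package = "patchadapt",
    version = as.character(utils::packageVersion("patchadapt")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    ended = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a headered, locale-independent TSV
#'
#' @param df Data frame.
#' @param path Output path ("-" for stdout).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- if (identical(path, "-")) stdout() else path
  utils::write.table(format(df, scientific = FALSE, trim = TRUE,
                            digits = 10),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulator configuration matching the migration--selection-balance run
#'
#' One- or two-dimensional grid with a central patch of 10 demes (1D) or a
#' 10-deme-wide block (2D) where the allele is favoured (`s_p = 0.1`) and
#' deleterious elsewhere (`s_m = 0.02`), 1000 individuals per deme, the
#' standard migration model (`m = 0.2`, step masses `2^-k`, `k <= 5`), run
#' for 1000 generations from a fully adapted patch.
#'
#' @param d Dimension (1 or 2).
#' @param n_demes Grid side length (default 201 for 1D, 101 for 2D).
#' @param N Individuals per deme (default 1000).
#' @param t_max Generations (default 1000).
#' @param seed RNG seed.
#' @return A [deme_grid_config].
#' @export
fig1_config <- function(d = 1, n_demes = if (d == 1) 201 else 101, N = 1000,
                        t_max = 1000, seed = 1) {
  if (d == 1) {
    centre <- (n_demes + 1) %/% 2
    patch <- which(abs(seq_len(n_demes) - centre) <= 4)
    s_map <- ifelse(seq_len(n_demes) %in% patch, 0.1, -0.02)
    init <- ifelse(seq_len(n_demes) %in% patch, N, 0)
    deme_grid_config(shape = n_demes, N = N, s_map = s_map, mu = 0,
                     init = init, t_max = t_max, focal_demes = patch,
                     seed = seed)
  } else {
    centre <- (n_demes + 1) %/% 2
    ix <- rep(seq_len(n_demes), times = n_demes)
    iy <- rep(seq_len(n_demes), each = n_demes)
    inpatch <- abs(ix - centre) <= 4 & abs(iy - centre) <= 4
    s_map <- ifelse(inpatch, 0.1, -0.02)
    init <- ifelse(inpatch, N, 0)
    deme_grid_config(shape = c(n_demes, n_demes), N = N, s_map = s_map,
                     mu = 0, init = init, t_max = t_max,
                     focal_demes = which(inpatch), seed = seed)
  }
}

#' Simulator configuration for the mutation-rate experiment
#'
#' Linear grid of 501 demes with one central 99-deme patch (`s_p = 0.01`,
#' `s_m` elsewhere), `mu = 1e-5`, starting with no adaptive alleles;
#' adaptation is reached when 100 B copies are present in the patch.
#'
#' @param rho Individuals per deme (default 1000).
#' @param s_m_raw Raw selection multiplier against the allele outside the
#'   patch (default 0.02).
#' @param s_p_raw Raw selection multiplier inside the patch (default 0.01).
#' @param n_demes Number of demes (default 501).
#' @param patch_width Patch width in demes (default 99).
#' @param mu Mutation rate (default 1e-5).
#' @param t_max Generations (default 5000).
#' @param seed RNG seed.
#' @return A [deme_grid_config] (with `stop_when_adapted = TRUE`).
#' @export
fig4_mutation_config <- function(rho = 1000, s_m_raw = 0.02, s_p_raw = 0.01,
                                 n_demes = 501, patch_width = 99, mu = 1e-5,
                                 t_max = 5000, seed = 1) {
  centre <- (n_demes + 1) %/% 2
  half <- (patch_width - 1) %/% 2
  patch <- which(abs(seq_len(n_demes) - centre) <= half)
  s_map <- ifelse(seq_len(n_demes) %in% patch, s_p_raw, -s_m_raw)
  deme_grid_config(shape = n_demes, N = rho, s_map = s_map, mu = mu,
                   t_max = t_max, focal_demes = patch, threshold = 100,
                   stop_when_adapted = TRUE, seed = seed)
}

#' Simulator configuration for the migration experiment
#'
#' Linear grid with two equal patches separated by `R` demes; the left patch
#' starts with the adaptive allele at frequency 0.8, the rest of the range
#' is empty. The mutation rate is zero so that the time to adaptation of the
#' right patch measures the migration channel alone.
#'
#' @param R Gap between the patches, in demes (default 70).
#' @param rho Individuals per deme (default 1000).
#' @param s_m_raw Raw selection multiplier between patches (default 0.02).
#' @param s_p_raw Raw selection multiplier inside patches (default 0.1,
#'   the strong in-patch selection used throughout the occupancy and lineage
#'   illustrations; strong in-patch selection keeps arriving families in the
#'   establishment-saturated regime the closed-form migration rate assumes).
#' @param patch_width Patch width in demes (default 99).
#' @param n_demes Total demes (default 501).
#' @param t_max Generations (default 15000).
#' @param seed RNG seed.
#' @return A [deme_grid_config] (focal demes = the initially unadapted
#'   patch; `stop_when_adapted = TRUE`).
#' @export
fig4_migration_config <- function(R = 70, rho = 1000, s_m_raw = 0.02,
                                  s_p_raw = 0.1, patch_width = 99,
                                  n_demes = 501, t_max = 15000, seed = 1) {
  stopifnot(2 * patch_width + R <= n_demes)
  centre <- (n_demes + 1) %/% 2
  left_hi <- centre - ceiling(R / 2)
  left <- seq(left_hi - patch_width + 1L, left_hi)
  right_lo <- centre + floor(R / 2) + 1L
  right <- seq(right_lo, right_lo + patch_width - 1L)
  s_map <- rep(-s_m_raw, n_demes)
  s_map[c(left, right)] <- s_p_raw
  init <- integer(n_demes)
  init[left] <- round(0.8 * rho)
  deme_grid_config(shape = n_demes, N = rho, s_map = s_map, mu = 0,
                   init = init, t_max = t_max, focal_demes = right,
                   threshold = 100, stop_when_adapted = TRUE, seed = seed)
}

#' Parallel-adaptation and haplotype-length curves for the rock pocket mouse
#'
#' Evaluates the probability of parallel adaptation and the expected shared
#' haplotype length over a grid of inter-patch distances for the
#' *Chaetodipus intermedius* parameter ranges: dispersal `sigma = 1` km,
#' cline widths `sigma/sqrt(s_m)` of 3 km and 30 km (`s_m = 1/9` and
#' `1/900`), mutational target sizes `mu = 1e-8` and `1e-5`, patch area
#' `A = 100` km^2 (10 km x 10 km).
#'
#' @param R_km Inter-patch distances in km (default `seq(10, 500, by = 10)`).
#' @param s_m Selection coefficients against the dark allele off-patch
#'   (default `c(1/9, 1/900)`).
#' @param mu Mutation rates (default `c(1e-8, 1e-5)`).
#' @param sigma Dispersal distance in km (default 1).
#' @param A Patch area in km^2 (default 100).
#' @return Data frame with columns `R_km`, `s_m`, `mu`, `prob_parallel`,
#'   `expected_haplotype_cM`.
#' @export
reproduce_fig7 <- function(R_km = seq(10, 500, by = 10),
                           s_m = c(1 / 9, 1 / 900), mu = c(1e-8, 1e-5),
                           sigma = 1, A = 100) {
  w_side <- sqrt(A)
  grid <- expand.grid(R_km = R_km, s_m = s_m, mu = mu)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    params <- pop_params(sigma = sigma, s_m = g$s_m, s_p = 0.5, mu = g$mu,
                         rho = 1, xi2 = 1, d = 1)
    ell <- characteristic_length(params)
    A_prime <- w_side * min(w_side, ell)
    w <- A / A_prime
    pp <- prob_parallel(g$R_km, params, w = w, gamma = 1)
    tm <- transit_model(R = g$R_km, sigma = sigma, s_m = g$s_m, d = 1)
    EL <- haplotype_moments(tm)$mean
    data.frame(R_km = g$R_km, s_m = g$s_m, mu = g$mu, prob_parallel = pp,
               expected_haplotype_cM = 100 * EL)
  })
  do.call(rbind, rows)
}
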