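#' Trace lineages of sampled alleles backwards through a simulation
#'
#' Backward-in-time random walk over the recorded per-deme B counts: in each
#' generation a lineage currently in deme `y` moves to deme `x` with
#' probability proportional to the forward migration probability from `x` to
#' `y` weighted by the B count in `x` in the previous generation. Two
#' lineages landing in the same deme with `n` copies each pick a label
#' uniformly on `1..n` and coalesce if the labels agree. A lineage with no
#' occupied source deme (the allele was just created there by mutation)
#' terminates with an origin event.
#'
#' @param result A [run_forward] result (with full counts history).
#' @param n_lineages Number of lineages to sample.
#' @param deme Deme index (flattened) to sample from; must hold at least one
#'   B copy at the sampling generation.
#' @param generation Sampling generation (0-based; default: last recorded).
#' @return An object of class `lineage_sample`: list with `paths` (matrix,
#'   one row per recorded generation from the sampling generation back to 0,
#'   one column per lineage; `NA` after coalescence into another lineage or
#'   after the origin) and `events` (data frame with columns `generation`,
#'   `deme`, `lineage`, `type` in `c("coalescence", "origin")`, `into`).
#' @export
trace_lineages <- function(result, n_lineages, deme,
                           generation = nrow(result$counts) - 1L) {
  stopifnot(inherits(result, "sim_result"), n_lineages >= 1)
  counts <- result$counts
  stopifnot(generation >= 0, generation <= nrow(counts) - 1L)
  if (counts[generation + 1L, deme] < 1) {
    stop("cannot sample lineages from a deme with no copies of the allele",
         call. = FALSE)
  }
  offsets <- build_offsets(result$config)
  n_demes <- ncol(counts)
  # forward probability x -> y for offset j means dest[x, j] == y;
  # precompute, for each destination y, its candidate sources and probs
  n_off <- length(offsets$probs)
  src <- matrix(NA_integer_, nrow = n_demes, ncol = n_off)
  for (j in seq_len(n_off)) {
    to <- offsets$dest[, j]
    ok <- !is.na(to)
    src[to[ok], j] <- which(ok)
  }

  cur <- rep.int(as.integer(deme), n_lineages)
  alive <- rep(TRUE, n_lineages)
  paths <- matrix(NA_integer_, nrow = generation + 1L, ncol = n_lineages)
  paths[generation + 1L, ] <- cur
  events <- list()
  if (generation > 0) {
    for (g in seq(generation, 1L)) {
      prev_counts <- counts[g, ]
      for (i in which(alive)) {
        cands <- src[cur[i], ]
        ok <- !is.na(cands)
        wts <- numeric(sum(ok))
        wts <- offsets$probs[ok] * prev_counts[cands[ok]]
        if (sum(wts) <= 0) {
          # no occupied source: the allele arose here by mutation
          events[[length(events) + 1L]] <-
            data.frame(generation = g - 1L, deme = cur[i], lineage = i,
                       type = "origin", into = NA_integer_)
          alive[i] <- FALSE
          cur[i] <- NA_integer_
          next
        }
        cur[i] <- cands[ok][sample.int(length(wts), 1L, prob = wts)]
      }
      # coalescence within demes
      live <- which(alive)
      if (length(live) > 1L) {
        for (dm in unique(cur[live])) {
          here <- live[cur[live] == dm]
          if (length(here) < 2L) next
          nball <- max(1, counts[g, dm])
          labels <- sample.int(nball, length(here), replace = TRUE)
          keepers <- !duplicated(labels)
          for (k in which(!keepers)) {
            into <- here[keepers][match(labels[k], labels[keepers])]
            events[[length(events) + 1L]] <-
              data.frame(generation = g - 1L, deme = dm, lineage = here[k],
                         type = "coalescence", into = into)
            alive[here[k]] <- FALSE
            cur[here[k]] <- NA_integer_
          }
        }
      }
      paths[g, ] <- cur
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(generation = integer(0), deme = integer(0),
               lineage = integer(0), type = character(0), into = integer(0))
  structure(list(paths = paths, events = events,
                 generation = generation),
            class = "lineage_sample")
}

#' @export
print.lineage_sample <- function(x, ...) {
  cat("Lineage sample:", ncol(x$paths), "lineage(s) traced back",
      nrow(x$paths) - 1L, "generations;",
      sum(x$events$type == "coalescence"), "coalescence event(s)\n")
  invisible(x)
}

#' Decay of the shared hitchhiking haplotype along a lineage path
#'
#' Tracks the genetic length of ancestral haplotype (per side of the selected
#' locus, in Morgans) still carried by a lineage as it moves through the
#' population. Each generation a crossover position `X ~ Exp(1)` Morgans is
#' drawn; with probability `1 - q_local` (the local frequency of carriers at
#' the lineage's deme) the recombination partner carries an unrelated
#' background and the shared length is cut to `min(L, X)`.
#'
#' @param lineage_path Vector of deme indices visited by the lineage
#'   (oldest first), or `NULL` to use `q_local` directly.
#' @param result A [run_forward] result supplying local frequencies (its
#'   rows must align with `lineage_path`); ignored when `q_local` is given.
#' @param q_local Optional vector of local carrier frequencies, one per
#'   generation (overrides `lineage_path`/`result`).
#' @param L0 Initial shared length per side, in Morgans (a configured
#'   chromosome half-length; default 10).
#' @return Data frame with columns `generation`, `left`, `right`: the shared
#'   lengths after each generation (row 1 = initial state).
#' @export
shared_haplotype_decay <- function(lineage_path = NULL, result = NULL,
                                   q_local = NULL, L0 = 10) {
  if (is.null(q_local)) {
    stopifnot(!is.null(lineage_path), inherits(result, "sim_result"))
    N <- result$config$N
    gens <- seq_along(lineage_path)
    q_local <- result$counts[cbind(gens, lineage_path)] / N
  }
  tsteps <- length(q_local)
  left <- right <- numeric(tsteps + 1L)
  left[1L] <- right[1L] <- L0
  L <- c(L0, L0)
  for (t in seq_len(tsteps)) {
    for (side in 1:2) {
      x <- stats::rexp(1)
      if (stats::runif(1) < 1 - q_local[t]) {
        L[side] <- min(L[side], x)
      }
    }
    left[t + 1L] <- L[1L]
    right[t + 1L] <- L[2L]
  }
  data.frame(generation = 0:tsteps, left = left, right = right)
}
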