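#' Forward-in-time simulation of a crypt cell population
#'
#' Simulates crypt morphogenesis followed by homeostatic renewal with
#' complete ancestry recording. Morphogenesis expands a single founder to
#' `N1` stem cells by symmetric divisions, then fills the transit pool by
#' rounds of asymmetric stem divisions in which existing transit cells also
#' divide, trimming randomly to `N2` (8 generations in total at the default
#' sizes). Each homeostatic generation assigns stem cells to division types
#' I/II/III with expected proportions `(alpha, alpha, beta)` under the exact
#' constant-size law (see [division_type_law()]), sends differentiated
#' daughters to deme 2, lets the dividing fraction `gamma` of deme-2 cells
#' produce two offspring and extrudes the rest.
#'
#' @param params A [division_params()] object, a single `beta`, or a
#'   [beta_schedule()] for time-varying asymmetric fractions.
#' @param config A [crypt_config()].
#' @param total_generations Total generations to simulate, including
#'   morphogenesis.
#' @param seed Integer seed; identical seeds give identical histories.
#' @return A `crypt_history` object: per-generation integer vectors
#'   `parent` (1-based index into the previous generation, 0 for the
#'   founder), `deme` (1 stem, 2 transit) and `dtype` (1/2/3 stem division
#'   types, 4 transit division, 5 extruded), plus `morph_gens`, the config
#'   and the realized division-type counts.
#' @examples
#' h <- simulate_crypt_history(division_params(0.6), crypt_config(),
#'                             total_generations = 20, seed = 1)
#' h
#' @export
simulate_crypt_history <- function(params, config = crypt_config(),
                                   total_generations, seed = NULL) {
  total_generations <- as.integer(total_generations)
  if (total_generations < config$morphogenesis_generations)
    stop("`total_generations` must cover morphogenesis (",
         config$morphogenesis_generations, " generations)")
  n_h <- total_generations - config$morphogenesis_generations
  bh <- beta_by_generation(params, max(n_h, 1L))[seq_len(n_h)]
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_forward_sim(config$N1, config$N2, as.numeric(bh))
  if (raw$morph_gens != config$morphogenesis_generations)
    warning("morphogenesis took ", raw$morph_gens, " generations (config says ",
            config$morphogenesis_generations, ")")
  counts <- t(vapply(raw$dtype, function(t) {
    c(typeI = sum(t == 1L), typeII = sum(t == 2L), typeIII = sum(t == 3L))
  }, integer(3)))
  structure(list(parent = raw$parent, deme = raw$deme, dtype = raw$dtype,
                 morph_gens = raw$morph_gens, config = config,
                 beta_by_gen = bh, type_counts = counts, seed = seed),
            class = "crypt_history")
}

#' @export
print.crypt_history <- function(x, ...) {
  G <- length(x$parent) - 1L
  last <- x$deme[[length(x$deme)]]
  cat(sprintf("crypt history: %d generations (%d morphogenesis), final deme sizes (%d, %d)\n",
              G, x$morph_gens, sum(last == 1L), sum(last == 2L)))
  invisible(x)
}

n_generations <- function(history) length(history$parent) - 1L

#' Extract the genealogy of a random cell sample
#'
#' Samples `sample_size` cells uniformly from all living cells of the final
#' generation (which realizes the hypergeometric split between demes) and
#' returns their timed ancestral tree, traced back through the recorded
#' ancestry to the most recent common ancestor.
#'
#' @param history A `crypt_history`.
#' @param sample_size Number of cells to sample (at most `N1 + N2`).
#' @param seed Optional integer seed.
#' @param cells Optional explicit 1-based indices into the final-generation
#'   roster (deme-1 cells first); overrides random sampling.
#' @return A `crypt_genealogy`: an [ape][ape::read.tree] `phylo` tree with
#'   branch lengths in generations, plus `node_time` (generations before
#'   sampling) and `node_deme` attributes.
#' @export
extract_genealogy <- function(history, sample_size, seed = NULL, cells = NULL) {
  roster <- history$deme[[length(history$deme)]]
  N <- length(roster)
  if (is.null(cells)) {
    if (sample_size < 1L || sample_size > N)
      stop("`sample_size` must be between 1 and the population size (", N, ")")
    if (!is.null(seed)) set.seed(seed)
    cells <- sample.int(N, sample_size)
  }
  if (length(cells) == 1L)
    return(structure(list(ntip = 1L, node_time = 0L,
                          node_deme = roster[cells], cells = cells),
                     class = "crypt_genealogy"))
  g <- cpp_extract_genealogy(history$config$N1, history$config$N2,
                             history$parent, history$deme, as.integer(cells))
  as_crypt_genealogy(g, cells = cells)
}

# wrap the C++ genealogy list into an ape phylo with annotations
as_crypt_genealogy <- function(g, cells = NULL) {
  ntip <- g$ntip
  phy <- structure(list(edge = g$edge,
                        edge.length = as.numeric(g$edge_length),
                        tip.label = paste0("cell", seq_len(ntip)),
                        Nnode = nrow(g$edge) / 2L),
                   class = c("crypt_genealogy", "phylo"), order = "cladewise")
  attr(phy, "node_time") <- g$node_time
  attr(phy, "node_deme") <- g$node_deme
  attr(phy, "cells") <- cells
  phy
}

#' @export
print.crypt_genealogy <- function(x, ...) {
  if (!is.null(x$ntip) && identical(x$ntip, 1L)) {
    cat("crypt genealogy: single sampled cell (trivial tree at time 0)\n")
    return(invisible(x))
  }
  nt <- attr(x, "node_time")
  cat(sprintf("crypt genealogy: %d cells, TMRCA %d generations, %d deme-1 tips\n",
              length(x$tip.label), max(nt),
              sum(attr(x, "node_deme")[seq_along(x$tip.label)] == 1L)))
  invisible(x)
}

# TMRCA (generations back) of two cells alive at generation `gen`
# (1-based indices into the roster of that generation); NA if distinct
# lineages persist to the founder (cannot happen with a single founder).
trace_pair_tmrca <- function(history, gen, i, j) {
  a <- i; b <- j
  if (gen < 1L) return(if (a == b) 0L else NA_integer_)
  for (g in seq(gen + 1L, 2L, by = -1L)) { # parent list index g = generation g-1
    if (a == b) return(gen - (g - 1L))
    a <- history$parent[[g]][a]
    b <- history$parent[[g]][b]
  }
  if (a == b) return(gen)
  NA_integer_
}

#' Mean pairwise divergence along a crypt history
#'
#' For each probed generation, estimates the mean pairwise divergence
#' (twice the coalescence time, in generations of separation) between two
#' randomly picked living cells, averaged over replicate simulated crypt
#' histories. The trajectory rises from zero at founding towards a
#' stationary plateau whose level increases with the asymmetric fraction.
#'
#' @param params [division_params()], single beta, or [beta_schedule()].
#' @param config A [crypt_config()].
#' @param generations_to_probe Generations (from founding) at which to
#'   measure; values beyond morphogenesis probe the homeostatic phase.
#' @param replicates Number of independent crypt histories.
#' @param pairs_per_probe Random cell pairs scored per probe per replicate.
#' @param seed Integer seed.
#' @return A data frame with columns `generation`, `mean_divergence` and
#'   `se` (standard error over replicates).
#' @export
pairwise_divergence_trajectory <- function(params, config = crypt_config(),
                                           generations_to_probe,
                                           replicates = 20L,
                                           pairs_per_probe = 20L,
                                           seed = NULL) {
  probes <- sort(unique(as.integer(generations_to_probe)))
  if (!is.null(seed)) set.seed(seed)
  maxg <- max(probes)
  res <- matrix(NA_real_, nrow = replicates, ncol = length(probes))
  for (r in seq_len(replicates)) {
    h <- simulate_crypt_history(params, config, total_generations = maxg)
    for (pi in seq_along(probes)) {
      g <- probes[pi]
      n <- length(h$deme[[g + 1L]])
      if (n < 2L) { res[r, pi] <- 0; next }
      np <- min(pairs_per_probe, choose(n, 2))
      d <- numeric(np)
      for (q in seq_len(np)) {
        ij <- sample.int(n, 2L)
        d[q] <- 2L * trace_pair_tmrca(h, g, ij[1], ij[2])
      }
      res[r, pi] <- mean(d)
    }
  }
  data.frame(generation = probes,
             mean_divergence = colMeans(res),
             se = apply(res, 2, stats::sd) / sqrt(replicates))
}

#' Stationary mean pairwise divergence
#'
#' The plateau of the divergence trajectory, estimated directly from the
#' stationary backward process: random pairs are split between demes
#' hypergeometrically and their coalescence time is simulated exactly.
#'
#' @param params [division_params()] or single beta (`beta = 1` has no
#'   stationary distribution and is rejected).
#' @param config A [crypt_config()].
#' @param draws Number of random pairs.
#' @param seed Integer seed.
#' @param max_generations Cap on the backward simulation.
#' @return A list with `mean_divergence` and its standard error.
#' @export
stationary_pairwise_divergence <- function(params, config = crypt_config(),
                                           draws = 2000L, seed = NULL,
                                           max_generations = 20000L) {
  params <- as_division_params(params)
  if (params$beta >= 1)
    stop("beta = 1 has no stationary pairwise divergence (lineages never coalesce)")
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rhyper(draws, config$N1, config$N2 - config$N1, 2L)
  t2 <- numeric(draws)
  for (s in 0:2) {
    idx <- which(m == s)
    if (!length(idx)) next
    t2[idx] <- cpp_bwd_tmrca(s, 2L - s, params$beta, config$N1, config$N2,
                             max_generations, length(idx))
  }
  list(mean_divergence = 2 * mean(t2), se = 2 * stats::sd(t2) / sqrt(draws))
}
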