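#' Single-generation coalescence probability for two stem lineages
#'
#' Probability that two randomly picked stem cells find a common ancestor
#' one generation back: the first must be the daughter of a symmetric
#' renewing (type I) division, probability `2 alpha / (2 alpha + beta)`,
#' and the second must be its sister, probability `1 / (N - 1)`. Under the
#' constant-size constraint `2 alpha + beta = 1` this is `2 alpha / (N - 1)`.
#'
#' @param params A [division_params()] object or single beta.
#' @param N Stem deme size (`>= 2`).
#' @return The per-generation coalescence probability.
#' @examples
#' single_step_coalescence_prob(division_params(0), 15) # 1/14
#' @export
single_step_coalescence_prob <- function(params, N) {
  params <- as_division_params(params)
  if (N < 2) stop("`N` must be at least 2")
  2 * params$alpha / (N - 1)
}

# effective backward event rates implied by the forward process
# law = "exact": moments of the parity-fixed binomial type counts
# law = "nominal": the idealized continuous fractions (alpha N1, beta N1)
backward_rates <- function(params, config, law = c("exact", "nominal")) {
  law <- match.arg(law)
  params <- as_division_params(params)
  N1 <- config$N1; N2 <- config$N2
  if (law == "exact") {
    mom <- division_type_law(params$beta, N1)
    e3 <- mom$e_niii; eni <- mom$e_ni; eni2 <- mom$e_ni_ni1
  } else {
    e3 <- params$beta * N1; eni <- params$alpha * N1
    eni2 <- eni * (eni - 1)
  }
  list(
    q1 = N1 / N2,                                  # lineage migration
    q2 = N1 * (N1 - 1) / (N2 * (N2 - 1)),          # two specific migrations
    c1 = 2 * eni / (N1 * (N1 - 1)),                # deme-1 pair coalescence
    c1c1 = 4 * eni2 / prod(N1 - 0:3),              # two disjoint deme-1 pairs
    c2 = (N2 - N1) / (N2 * (N2 - 1)),              # deme-2 pair coalescence
    c2c2 = (N2 - N1) * (N2 - N1 - 2) / prod(N2 - 0:3),
    c2m = 2 * eni / (N2 * (N2 - 1)),               # migrant pair, same type-II parent
    c12 = e3 / (N1 * N2),                          # stem + migrant, type-III parent
    mc1 = (N1 / N2) * 2 * eni / (N1 * (N1 - 1)),   # one migration + one C1
    mc2 = N1 * (N2 - N1) / (N2 * (N2 - 1) * (N2 - 2)), # one migration + one C2
    e_niii = e3, e_ni = eni)
}

ch2 <- function(x) ifelse(x >= 2, choose(x, 2), 0)
ch4p <- function(x) ifelse(x >= 4, 3 * choose(x, 4), 0) # pairs of disjoint pairs

#' One-generation backward transition row of the (m, n) lineage chain
#'
#' Enumerates the predecessor states of a lineage configuration `(m, n)`
#' (ancestral lineage counts in the stem and transit demes) reachable by at
#' most two backward events per generation: coalescence in deme 1,
#' coalescence in deme 2, migration (a deme-2 lineage whose parent is a stem
#' cell), a migrant pair coalescing directly onto a shared type-II parent,
#' and a stem lineage absorbing a migrant onto a shared type-III parent.
#' Probabilities use second-order inclusion-exclusion with exact joint event
#' probabilities; the mass of combinations with three or more events is
#' reported as `neglected`, not redistributed (an optional renormalized mode
#' is provided for sensitivity checks). Rows for states with `m + n <= 2`
#' are exact.
#'
#' @param state A list or vector with elements `m` and `n`.
#' @param params [division_params()] or single beta.
#' @param config A [crypt_config()].
#' @param law `"exact"` uses the effective division-type rates of the
#'   implemented forward process; `"nominal"` uses the idealized fractions.
#' @param renormalize If `TRUE`, scale the enumerated probabilities to sum
#'   to one.
#' @return A list with `state`, `entries` (data frame `m`, `n`, `prob` of
#'   predecessor states one generation back) and `neglected`.
#' @export
build_transition_table <- function(state, params, config = crypt_config(),
                                   law = c("exact", "nominal"),
                                   renormalize = FALSE) {
  m <- as.integer(state[["m"]]); n <- as.integer(state[["n"]])
  if (m < 0 || n < 0 || m + n < 1) stop("invalid lineage state")
  if (m + n == 1L) {
    return(list(state = c(m = m, n = n),
                entries = data.frame(m = m, n = n, prob = 1),
                neglected = 0))
  }
  r <- backward_rates(params, config, law)
  add <- function(acc, m2, n2, p) {
    if (p <= 0) return(acc)
    key <- paste(m2, n2)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
    acc
  }
  acc <- list()
  # no event
  p0 <- 1 - (n * r$q1 + ch2(m) * r$c1 + ch2(n) * r$c2) +
    (ch2(n) * r$q2 + n * ch2(m) * r$mc1 + n * ch2(n - 1) * r$mc2 +
     ch4p(m) * r$c1c1 + ch2(m) * ch2(n) * r$c1 * r$c2 + ch4p(n) * r$c2c2)
  acc <- add(acc, m, n, p0)
  # single coalescence in deme 1
  acc <- add(acc, m - 1, n,
             ch2(m) * (r$c1 - ch2(m - 2) * r$c1c1 - ch2(n) * r$c1 * r$c2 -
                       n * r$mc1))
  # single coalescence in deme 2
  acc <- add(acc, m, n - 1,
             ch2(n) * (r$c2 - ch2(n - 2) * r$c2c2 - ch2(m) * r$c1 * r$c2 -
                       (n - 2) * r$mc2))
  # single migration (no coalescence anywhere)
  acc <- add(acc, m + 1, n - 1,
             n * (r$q1 - (n - 1) * r$q2 - ch2(m) * r$mc1 -
                  ch2(n - 1) * r$mc2 - m * r$c12))
  # migrant absorbed by a stem lineage (shared type-III parent)
  acc <- add(acc, m, n - 1, m * n * r$c12)
  # migrant pair coalescing onto a shared type-II parent
  acc <- add(acc, m + 1, n - 2, ch2(n) * r$c2m)
  # two-event combinations
  acc <- add(acc, m + 2, n - 2, ch2(n) * (r$q2 - r$c2m)) # two migrations
  acc <- add(acc, m, n - 1, n * ch2(m) * r$mc1)          # migration + C1
  acc <- add(acc, m + 1, n - 2, n * ch2(n - 1) * r$mc2)  # migration + C2
  acc <- add(acc, m - 2, n, ch4p(m) * r$c1c1)            # C1 + C1
  acc <- add(acc, m - 1, n - 1, ch2(m) * ch2(n) * r$c1 * r$c2) # C1 + C2
  acc <- add(acc, m, n - 2, ch4p(n) * r$c2c2)            # C2 + C2
  # leading mass of >= 3-event combinations (three migrations, two
  # migrations + a coalescence, a composite two-event plus a third event);
  # it is removed from the no-event entry and reported, not redistributed
  N1 <- config$N1; N2 <- config$N2
  q3 <- if (n >= 3) N1 * (N1 - 1) * (N1 - 2) / (N2 * (N2 - 1) * (N2 - 2)) else 0
  neglected <- choose(max(n, 0), 3) * q3 +
    ch2(n) * ch2(n - 2) * r$q2 * r$c2 +
    ch2(n) * ch2(m) * r$q2 * r$c1 +
    ch2(n) * max(n - 2, 0) * r$c2m * r$q1 +
    m * n * max(n - 1, 0) * r$c12 * r$q1 +
    ch2(n) * ch2(m) * r$c2m * r$c1
  key0 <- paste(m, n)
  acc[[key0]] <- max(acc[[key0]] - neglected, 0)
  keys <- do.call(rbind, lapply(strsplit(names(acc), " "), as.integer))
  entries <- data.frame(m = keys[, 1], n = keys[, 2],
                        prob = unlist(acc, use.names = FALSE))
  entries <- entries[order(-entries$prob), , drop = FALSE]
  rownames(entries) <- NULL
  if (renormalize) entries$prob <- entries$prob / sum(entries$prob)
  list(state = c(m = m, n = n), entries = entries, neglected = neglected)
}

#' Expected time to the most recent common ancestor of two lineages
#'
#' First-step analysis of the backward chain over the two-lineage states
#' `(2,0)`, `(1,1)` and `(0,2)` (stem/stem, stem/transit, transit/transit),
#' using the exact one-generation transition law. For `beta = 1` two stem
#' lineages never coalesce and the expectation is infinite.
#'
#' @param params [division_params()] or single beta.
#' @param config A [crypt_config()].
#' @param initial_state List or vector with `m`, `n` and `m + n = 2`.
#' @param law `"exact"` matches the simulators (integer-constrained
#'   division-type counts); `"nominal"` uses the idealized rates, e.g.
#'   `1 / p` with `p = 2 alpha / (N1 - 1)` for two stem lineages.
#' @return Expected TMRCA in generations (possibly `Inf`).
#' @examples
#' expected_tmrca(division_params(0), crypt_config(), c(m = 2, n = 0),
#'                law = "nominal") # 14
#' @export
expected_tmrca <- function(params, config = crypt_config(), initial_state,
                           law = c("exact", "nominal")) {
  law <- match.arg(law)
  m <- as.integer(initial_state[["m"]]); n <- as.integer(initial_state[["n"]])
  if (m + n != 2L || m < 0 || n < 0)
    stop("`initial_state` must hold exactly two lineages")
  r <- backward_rates(params, config, law)
  if (r$c1 <= 0) {
    warning("beta = 1: two stem lineages never coalesce; expected TMRCA is infinite")
    return(Inf)
  }
  e20 <- 1 / r$c1
  e11 <- (1 + (r$q1 - r$c12) * e20) / r$q1
  stay02 <- 1 - 2 * r$q1 - r$c2 + r$q2
  e02 <- (1 + 2 * (r$q1 - r$q2) * e11 + (r$q2 - r$c2m) * e20) / (1 - stay02)
  if (m == 2L) e20 else if (m == 1L) e11 else e02
}

#' Hypergeometric deme split of a random cell sample
#'
#' A uniform sample of `sample_size` cells from the whole crypt contains
#' `m ~ Hypergeometric(N1, N2, sample_size)` stem cells.
#'
#' @param N1,N2 Deme sizes.
#' @param sample_size Cells sampled (1 to `N1 + N2`).
#' @param seed Optional integer seed.
#' @return A list with `m` (deme-1 lineages) and `n` (deme-2 lineages).
#' @export
sample_deme_counts <- function(N1, N2, sample_size, seed = NULL) {
  sample_size <- as.integer(sample_size)
  if (is.na(sample_size) || sample_size < 1L || sample_size > N1 + N2)
    stop("`sample_size` must be between 1 and N1 + N2")
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rhyper(1, N1, N2, sample_size)
  list(m = as.integer(m), n = sample_size - as.integer(m))
}

#' Sample a stationary genealogy from the backward process
#'
#' Simulates the two-deme coalescent generation by generation backward from
#' a lineage configuration `(m, n)` until a single ancestral lineage
#' remains. Each generation the parents' child-slot structure is drawn from
#' the exact division-type law and the lineages are assigned to distinct
#' slots without replacement, so the sampler is the exact time-reversal of
#' the homeostatic forward simulator (no transition truncation is involved).
#'
#' @param params [division_params()] or single beta (`beta = 1` with two or
#'   more stem lineages does not terminate and is caught by the cap).
#' @param config A [crypt_config()].
#' @param state List or vector with `m` and `n`.
#' @param seed Optional integer seed.
#' @param max_generations Cap on the backward simulation (error if hit).
#' @return A `crypt_genealogy` (see [extract_genealogy()]); node times are
#'   generations before sampling.
#' @export
sample_genealogy_stationary <- function(params, config = crypt_config(), state,
                                        seed = NULL, max_generations = 20000L) {
  params <- as_division_params(params)
  m <- as.integer(state[["m"]]); n <- as.integer(state[["n"]])
  if (m < 0 || n < 0 || m + n < 1L) stop("invalid lineage state")
  if (m > config$N1 || n > config$N2) stop("more lineages than cells in a deme")
  if (!is.null(seed)) set.seed(seed)
  if (m + n == 1L)
    return(structure(list(ntip = 1L, node_time = 0L,
                          node_deme = if (m == 1L) 1L else 2L, cells = NULL),
                     class = "crypt_genealogy"))
  g <- cpp_sample_genealogy_bwd(m, n, params$beta, config$N1, config$N2,
                                as.integer(max_generations))
  as_crypt_genealogy(g)
}
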