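#' Monte-Carlo likelihood settings
#'
#' @param k Number of Monte-Carlo genealogies (paper-scale default 20000;
#'   tests and examples use far fewer).
#' @param source Genealogy source: `"chain"` samples the stationary
#'   backward process (valid once the crypt has reached equilibrium, e.g.
#'   day 340); `"forward"` simulates crypt histories forward
#'   (morphogenesis + homeostasis) and is valid at any age, e.g. day 52.
#' @param generations For the forward source: either a single number of
#'   homeostatic generations, or a list with `mean`, `sd`, `lower`, `upper`
#'   describing a truncated-normal distribution over the generation number
#'   (one value is drawn per genealogy).
#' @param seed Integer root seed; all genealogy sampling derives from it.
#' @param max_generations Backward-simulation cap for the chain source.
#' @return A `likelihood_settings` object.
#' @export
likelihood_settings <- function(k = 20000L, source = c("chain", "forward"),
                                generations = NULL, seed = 1L,
                                max_generations = 20000L) {
  source <- match.arg(source)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer")
  if (source == "forward" && is.null(generations))
    stop("the forward source needs `generations`")
  structure(list(k = k, source = source, generations = generations,
                 seed = as.integer(seed),
                 max_generations = as.integer(max_generations)),
            class = "likelihood_settings")
}

draw_generation_numbers <- function(generations, k) {
  if (is.numeric(generations) && length(generations) == 1L)
    return(rep(as.integer(generations), k))
  g <- generations
  lo <- stats::pnorm(g$lower, g$mean, g$sd)
  hi <- stats::pnorm(g$upper, g$mean, g$sd)
  as.integer(round(stats::qnorm(stats::runif(k, lo, hi), g$mean, g$sd)))
}

# re-reference each marker to its modal allele within the crypt (ties
# resolved to the value closest to zero, then the smaller value); this
# removes the per-crypt offset accrued between the zygote and the crypt
# founder, matching the fixed root state of 0 in the pruning recursion
center_offsets <- function(genotypes) {
  for (j in seq_len(ncol(genotypes))) {
    v <- genotypes[, j]
    obs <- v[!is.na(v)]
    if (!length(obs)) next
    tab <- table(obs)
    cand <- as.integer(names(tab)[tab == max(tab)])
    ref <- cand[order(abs(cand), cand)][1]
    genotypes[, j] <- v - ref
  }
  genotypes
}

# collapse marker columns to unique patterns; returns patterns (cells x
# npat), and for each marker the index of its pattern
dedup_patterns <- function(genotypes) {
  key <- apply(genotypes, 2, paste, collapse = ",")
  uk <- unique(key)
  pid <- match(key, uk)
  patterns <- genotypes[, match(uk, key), drop = FALSE]
  list(patterns = matrix(as.integer(patterns), nrow = nrow(genotypes)),
       pattern_id = pid)
}

logmeanexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(mean(exp(x - mx)))
}

# Monte-Carlo SE of log mean exp via the delta method
logmeanexp_se <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(NA_real_)
  w <- exp(x - mx)
  stats::sd(w) / (mean(w) * sqrt(length(x)))
}

# k x nmarker -> k x npat tables for one crypt at one beta, one table per
# mutation model in `models` (the same k genealogies serve every model)
loglik_tables <- function(genotypes, beta, config, settings, models) {
  dd <- dedup_patterns(center_offsets(genotypes))
  caches <- lapply(models, power_cache)
  window <- models[[1]]$window
  if (settings$source == "chain") {
    if (beta >= 1)
      stop("beta = 1 has no stationary genealogy distribution")
    raw <- cpp_loglik_table_stationary(dd$patterns, beta, settings$k,
                                       config$N1, config$N2, caches, window,
                                       FALSE, settings$max_generations)
  } else {
    gh <- draw_generation_numbers(settings$generations, settings$k)
    raw <- cpp_loglik_table_forward(dd$patterns, rep(beta, max(gh)), gh,
                                    config$N1, config$N2, caches, window,
                                    FALSE)
  }
  list(tables = raw$tables, pattern_id = dd$pattern_id, tmrca = raw$tmrca)
}

# per-genealogy total log-likelihood given per-pattern tables and marker
# weights (markers are multiplied *before* averaging over genealogies: all
# markers of a crypt share one cell genealogy)
genealogy_logliks <- function(table, pattern_id, weights = NULL) {
  w <- tabulate(pattern_id, nbins = ncol(table))
  if (!is.null(weights)) {
    w <- numeric(ncol(table))
    for (i in seq_along(pattern_id)) w[pattern_id[i]] <- w[pattern_id[i]] + weights[i]
  }
  drop(table %*% w)
}

#' Monte-Carlo log-likelihood of one crypt's genotypes
#'
#' Estimates `Pr(D | theta) = E_G[ prod_markers Pr(D_marker | G) ]` by
#' averaging over `k` genealogies sampled from the coalescent (stationary
#' chain or forward simulation), evaluating each marker by Felsenstein
#' pruning on the shared genealogy. Markers are multiplied within a
#' genealogy before averaging: all markers of a crypt descend through one
#' cell genealogy.
#'
#' @param data Integer genotype matrix (cells x markers, offsets, `NA`
#'   missing) or a [crypt_genotypes()] object.
#' @param params [division_params()] or single beta.
#' @param config A [crypt_config()].
#' @param settings A [likelihood_settings()].
#' @param model A [mutation_model()].
#' @param genealogy Optional fixed genealogy; if given, no sampling is done
#'   and the result is the exact `sum over markers of log Pr(D_marker | G)`.
#' @return The log-likelihood, with attributes `mc_se` (Monte-Carlo
#'   standard error) and `k`.
#' @export
monte_carlo_loglik <- function(data, params, config = crypt_config(),
                               settings = likelihood_settings(k = 1000L),
                               model = mutation_model(), genealogy = NULL) {
  geno <- genotype_data(data)
  params <- as_division_params(params)
  if (!is.null(genealogy)) {
    ll <- sum(pruning_likelihood(genealogy, geno, model, log = TRUE))
    attr(ll, "k") <- 1L
    return(ll)
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  tl <- loglik_tables(geno, params$beta, config, settings, list(model))
  gl <- genealogy_logliks(tl$tables[[1]], tl$pattern_id)
  out <- logmeanexp(gl)
  if (!is.finite(out)) warning("all sampled genealogies gave zero likelihood")
  attr(out, "mc_se") <- logmeanexp_se(gl)
  attr(out, "k") <- settings$k
  out
}

#' Mutation-rate uncertainty as a discretized beta distribution
#'
#' @param shape1,shape2 Beta-distribution shape parameters.
#' @param bins Number of equal-probability bins; each bin is represented by
#'   the rate at its probability midpoint (quantile discretization).
#' @param support Range the beta distribution is transformed onto
#'   (default 0.0075 to 0.0125 mutations/site/generation).
#' @return A `rate_uncertainty` object with `rates` and `weights`.
#' @export
rate_uncertainty <- function(shape1 = 2, shape2 = 2, bins = 8L,
                             support = c(0.0075, 0.0125)) {
  bins <- as.integer(bins)
  if (bins < 1L) stop("`bins` must be at least 1")
  if (diff(support) <= 0) stop("degenerate support")
  q <- stats::qbeta((seq_len(bins) - 0.5) / bins, shape1, shape2)
  structure(list(rates = support[1] + q * diff(support),
                 weights = rep(1 / bins, bins),
                 shape1 = shape1, shape2 = shape2, support = support),
            class = "rate_uncertainty")
}

#' Monte-Carlo log-likelihood integrated over mutation-rate uncertainty
#'
#' Evaluates the likelihood at each discretized rate (the same sampled
#' genealogies serve every rate) and returns the log of the weighted
#' average.
#'
#' @inheritParams monte_carlo_loglik
#' @param uncertainty A [rate_uncertainty()].
#' @param step2_ratio,window Passed to the per-bin mutation models.
#' @return Log-likelihood with attribute `per_rate` (per-bin log-likelihoods).
#' @export
loglik_with_rate_uncertainty <- function(data, params, config = crypt_config(),
                                         settings = likelihood_settings(k = 1000L),
                                         uncertainty = rate_uncertainty(),
                                         step2_ratio = 1 / 7, window = 20L) {
  geno <- genotype_data(data)
  params <- as_division_params(params)
  models <- lapply(uncertainty$rates, mutation_model,
                   step2_ratio = step2_ratio, window = window)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  tl <- loglik_tables(geno, params$beta, config, settings, models)
  per_rate <- vapply(tl$tables, function(tab)
    logmeanexp(genealogy_logliks(tab, tl$pattern_id)), numeric(1))
  mx <- max(per_rate)
  out <- mx + log(sum(uncertainty$weights * exp(per_rate - mx)))
  attr(out, "per_rate") <- per_rate
  out
}
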