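#' Default beta grid
#'
#' 0 to 1 in steps of 0.04 (26 points), matching the resolution at which
#' Monte-Carlo noise still separates neighbouring grid points at practical
#' genealogy counts.
#'
#' @export
default_beta_grid <- function() seq(0, 1, by = 0.04)

# one sub-seed per crypt from the root seed (kept below 2^31); the first
# crypt uses the root seed itself, so a single-crypt fit reproduces
# monte_carlo_loglik at the same seed
crypt_seeds <- function(seed, n) {
  if (n == 1L) return(seed)
  set.seed(seed)
  c(seed, sample.int(.Machine$integer.max - 1L, n - 1L))
}

#' Likelihood surface over the asymmetric-division fraction
#'
#' Computes per-crypt log-likelihood curves over a grid of beta values via
#' [monte_carlo_loglik()], with common random numbers across grid points
#' (each crypt re-seeds the same sub-stream at every beta). Crypts of one
#' mouse are independent given beta, so mouse-level (pooled) surfaces are
#' the sums of the crypt surfaces. Under the stationary source `beta = 1`
#' is degenerate (stem lineages never coalesce) and is reported as `-Inf`.
#'
#' @param study A [crypt_genotypes()] object or a list of them.
#' @param config A [crypt_config()].
#' @param settings A [likelihood_settings()]; its `source` is overridden
#'   per crypt by the crypt's `regime` unless `honor_regime = FALSE`.
#' @param grid Beta grid (strictly increasing, within `[0, 1]`).
#' @param model A [mutation_model()].
#' @param honor_regime Use each crypt's stored regime?
#' @return A `likelihood_surface`: `grid`, `loglik` (grid x crypts),
#'   `se`, `pooled` (grid x mice), crypt metadata, and the per-beta
#'   likelihood tables needed by [bootstrap_beta()].
#' @export
profile_beta <- function(study, config = crypt_config(),
                         settings = likelihood_settings(k = 1000L),
                         grid = default_beta_grid(),
                         model = mutation_model(), honor_regime = TRUE) {
  study <- as_crypt_study(study)
  if (!length(study)) stop("empty study")
  if (any(diff(grid) <= 0) || any(grid < 0 | grid > 1))
    stop("`grid` must be strictly increasing within [0, 1]")
  nc <- length(study)
  seeds <- crypt_seeds(settings$seed, nc)
  ll <- se <- matrix(NA_real_, length(grid), nc)
  tables <- vector("list", nc)
  pattern_id <- vector("list", nc)
  warned <- FALSE
  for (ci in seq_len(nc)) {
    cg <- study[[ci]]
    st <- settings
    if (honor_regime && !is.null(cg$regime)) st$source <- cg$regime
    if (st$source == "forward" && is.null(st$generations)) {
      gm <- day_to_generations(cg$age_days, config) - config$morphogenesis_generations
      st$generations <- list(mean = gm, sd = 5, lower = gm - 10, upper = gm + 10)
    }
    tables[[ci]] <- vector("list", length(grid))
    for (bi in seq_along(grid)) {
      beta <- grid[bi]
      if (st$source == "chain" && beta >= 1) {
        if (!warned) {
          warning("beta = 1 has no stationary distribution; logLik set to -Inf")
          warned <- TRUE
        }
        ll[bi, ci] <- -Inf
        next
      }
      set.seed(seeds[ci]) # common random numbers across the grid
      tl <- loglik_tables(cg$genotypes, beta, config, st, list(model))
      pattern_id[[ci]] <- tl$pattern_id
      gl <- genealogy_logliks(tl$tables[[1]], tl$pattern_id)
      ll[bi, ci] <- logmeanexp(gl)
      se[bi, ci] <- logmeanexp_se(gl)
      tables[[ci]][[bi]] <- tl$tables[[1]]
    }
  }
  info <- data.frame(crypt = vapply(study, `[[`, "", "crypt"),
                     mouse = vapply(study, `[[`, "", "mouse"),
                     age_days = vapply(study, function(x) as.numeric(x$age_days), 0),
                     markers = vapply(study, function(x) ncol(x$genotypes), 0L))
  colnames(ll) <- colnames(se) <- paste(info$mouse, info$crypt, sep = ".")
  mice <- unique(info$mouse)
  pooled <- vapply(mice, function(mo)
    rowSums(ll[, info$mouse == mo, drop = FALSE]), numeric(length(grid)))
  structure(list(grid = grid, loglik = ll, se = se,
                 pooled = matrix(pooled, ncol = length(mice),
                                 dimnames = list(NULL, mice)),
                 info = info, tables = tables, pattern_id = pattern_id,
                 settings = settings, config = config, model = model,
                 seeds = seeds),
            class = "likelihood_surface")
}

#' @export
print.likelihood_surface <- function(x, ...) {
  cat(sprintf("likelihood surface: %d grid points x %d crypt(s), %d mouse/mice\n",
              length(x$grid), ncol(x$loglik), ncol(x$pooled)))
  est <- mle_beta(x)
  for (i in seq_along(est))
    cat(sprintf("  %s: beta-hat = %.3g (lnL %.2f)\n", names(est)[i], est[i],
                max(x$pooled[, i])))
  invisible(x)
}

argmax_low_tie <- function(grid, lnl) {
  mx <- max(lnl)
  if (!is.finite(mx)) stop("all log-likelihoods are -Inf")
  hits <- which(lnl == mx)
  if (length(hits) > 1L)
    warning("likelihood ties on the grid; reporting the smallest beta")
  grid[hits[1]]
}

#' Grid maximum-likelihood estimate of beta
#'
#' @param surface A `likelihood_surface`.
#' @param level `"mouse"` (pooled across crypts) or `"crypt"`.
#' @return Named numeric vector of estimates (ties resolved to the
#'   smaller beta with a warning).
#' @export
mle_beta <- function(surface, level = c("mouse", "crypt")) {
  level <- match.arg(level)
  L <- if (level == "mouse") surface$pooled else surface$loglik
  vapply(colnames(L), function(cn) argmax_low_tie(surface$grid, L[, cn]),
         numeric(1))
}

#' Profile-likelihood confidence interval for beta
#'
#' The connected grid span on which the log-likelihood stays within `drop`
#' units of its maximum; the default drop of `1.92 = 0.5 * qchisq(0.95, 1)`
#' gives an asymptotic 95% interval. Intervals touching 0 or 1 are
#' boundary intervals.
#'
#' @param surface A `likelihood_surface`.
#' @param drop Log-likelihood drop defining the interval.
#' @param level `"mouse"` or `"crypt"`.
#' @return Data frame with `group`, `beta_hat`, `lower`, `upper`.
#' @export
profile_ci <- function(surface, drop = 1.92, level = c("mouse", "crypt")) {
  level <- match.arg(level)
  L <- if (level == "mouse") surface$pooled else surface$loglik
  out <- lapply(colnames(L), function(cn) {
    lnl <- L[, cn]
    mx <- max(lnl)
    hit <- which(lnl == mx)[1]
    inside <- lnl >= mx - drop
    lo <- hit; while (lo > 1L && inside[lo - 1L]) lo <- lo - 1L
    hi <- hit; while (hi < length(lnl) && inside[hi + 1L]) hi <- hi + 1L
    data.frame(group = cn, beta_hat = surface$grid[hit],
               lower = surface$grid[lo], upper = surface$grid[hi])
  })
  do.call(rbind, out)
}

# per-mouse resampled marker weights -> pooled log-likelihood curve
reweighted_pooled <- function(surface, weights_by_crypt) {
  G <- length(surface$grid)
  ll <- matrix(0, G, ncol(surface$pooled), dimnames = dimnames(surface$pooled))
  for (ci in seq_len(ncol(surface$loglik))) {
    mo <- surface$info$mouse[ci]
    w <- weights_by_crypt[[ci]]
    for (bi in seq_len(G)) {
      tab <- surface$tables[[ci]][[bi]]
      ll[bi, mo] <- ll[bi, mo] + if (is.null(tab)) -Inf else
        logmeanexp(genealogy_logliks(tab, surface$pattern_id[[ci]], w))
    }
  }
  ll
}

#' Marker-resampling bootstrap for beta
#'
#' Resamples marker columns with replacement (jointly across the crypts of
#' one mouse: the same resampled marker multiset is applied to each of its
#' crypts) and re-estimates beta from the re-weighted likelihood surface,
#' reusing the fitted per-genealogy likelihood tables — this is exactly a
#' re-run of the analysis under the common-random-number seed protocol.
#' Cells are never resampled: they are the genealogy's leaves. With two
#' age groups the per-replicate difference `beta_young - beta_old` is also
#' reported, along with the count of replicates in which it is `<= 0`.
#'
#' @param study,config,settings,grid,model As in [profile_beta()]; a
#'   fitted `likelihood_surface` can be supplied as `surface` to skip the
#'   refit.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Seed for the resampling.
#' @param surface Optional pre-computed surface.
#' @return A `bootstrap_result`: replicate estimates, percentile 95%
#'   intervals (order statistics), and for paired ages the difference
#'   distribution.
#' @export
bootstrap_beta <- function(study, config = crypt_config(),
                           settings = likelihood_settings(k = 1000L),
                           B = 100L, seed = 1L, grid = default_beta_grid(),
                           model = mutation_model(), surface = NULL) {
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be at least 1")
  if (is.null(surface))
    surface <- profile_beta(study, config, settings, grid, model)
  info <- surface$info
  mice <- colnames(surface$pooled)
  # marker counts must match within a mouse for joint resampling
  set.seed(seed)
  est <- matrix(NA_real_, B, length(mice), dimnames = list(NULL, mice))
  for (b in seq_len(B)) {
    weights <- vector("list", nrow(info))
    for (mo in mice) {
      idx <- which(info$mouse == mo)
      M <- info$markers[idx[1]]
      if (!all(info$markers[idx] == M))
        stop("crypts of one mouse must share a marker panel for the joint bootstrap")
      draw <- sample.int(M, M, replace = TRUE)
      w <- tabulate(draw, nbins = M)
      for (ci in idx) weights[[ci]] <- w
    }
    ll <- reweighted_pooled(surface, weights)
    for (mi in seq_along(mice))
      est[b, mi] <- argmax_low_tie(surface$grid, ll[, mi])
  }
  ci <- apply(est, 2, stats::quantile, probs = c(0.025, 0.975), type = 1)
  out <- list(estimates = est, ci = ci, B = B,
              point = mle_beta(surface), surface_grid = surface$grid)
  ages <- tapply(info$age_days, info$mouse, function(a) a[1])[mice]
  if (length(mice) == 2L && all(is.finite(ages)) && ages[1] != ages[2]) {
    young <- mice[which.min(ages)]; old <- mice[which.max(ages)]
    d <- est[, young] - est[, old]
    out$diff <- d
    out$diff_ci <- stats::quantile(d, c(0.025, 0.975), type = 1)
    out$n_diff_nonpositive <- sum(d <= 0)
    out$diff_groups <- c(young = young, old = old)
  }
  structure(out, class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %d replicates\n", x$B))
  for (mo in colnames(x$estimates))
    cat(sprintf("  %s: beta-hat = %.3g, 95%% CI (%.3g, %.3g)\n", mo,
                x$point[mo], x$ci[1, mo], x$ci[2, mo]))
  if (!is.null(x$diff))
    cat(sprintf("  difference (%s - %s): CI (%.3g, %.3g); %d/%d replicates <= 0\n",
                x$diff_groups["young"], x$diff_groups["old"],
                x$diff_ci[1], x$diff_ci[2], x$n_diff_nonpositive, x$B))
  invisible(x)
}

#' Likelihood-ratio test for age-dependent division mode
#'
#' Tests H0: the two age groups share one asymmetric fraction, against
#' Ha: each age has its own. Per-crypt surfaces are computed once with
#' common random numbers, so both hypotheses are maximized over the same
#' Monte-Carlo surfaces; the statistic `-2 (lnL0 - lnLa)` is compared to a
#' chi-square distribution with one degree of freedom. Small negative
#' statistics (Monte-Carlo noise) are clipped to zero with a warning.
#'
#' @param data_age1,data_age2 Studies (lists of [crypt_genotypes()]) for
#'   the two age groups.
#' @param config A [crypt_config()] (shared; differing configs between
#'   ages are an error by construction).
#' @param settings A [likelihood_settings()] or a list of two (one per
#'   age group).
#' @param grid,model As in [profile_beta()].
#' @return An `lrt_result` with `lnl0`, `lnla`, `statistic`, `p_value`,
#'   the shared and per-age estimates, and the two fitted surfaces.
#' @export
lrt_equal_beta <- function(data_age1, data_age2, config = crypt_config(),
                           settings = likelihood_settings(k = 1000L),
                           grid = default_beta_grid(),
                           model = mutation_model()) {
  st <- if (inherits(settings, "likelihood_settings")) list(settings, settings)
        else settings
  if (length(st) != 2L) stop("`settings` must be one object or a list of two")
  # both ages run under the same seed protocol: common random numbers
  # across hypotheses (and identical data then give a statistic of 0)
  st[[2]]$seed <- st[[1]]$seed
  s1 <- profile_beta(as_crypt_study(data_age1), config, st[[1]], grid, model)
  s2 <- profile_beta(as_crypt_study(data_age2), config, st[[2]], grid, model)
  l1 <- rowSums(s1$pooled); l2 <- rowSums(s2$pooled)
  b1 <- argmax_low_tie(grid, l1); b2 <- argmax_low_tie(grid, l2)
  lnla <- max(l1) + max(l2)
  pooled <- l1 + l2
  b0 <- argmax_low_tie(grid, pooled)
  lnl0 <- max(pooled)
  stat <- -2 * (lnl0 - lnla)
  if (stat < 0) {
    warning("negative LRT statistic clipped to 0 (Monte-Carlo noise)")
    stat <- 0
  }
  structure(list(lnl0 = lnl0, lnla = lnla, statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 beta_shared = b0, beta_age1 = b1, beta_age2 = b2,
                 surface_age1 = s1, surface_age2 = s2),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT for equal asymmetric fractions:\n  lnL(H0) = %.2f at shared beta = %.3g\n  lnL(Ha) = %.2f at beta = (%.3g, %.3g)\n  -2 dlnL = %.3g, p = %.3g (chi-square, 1 df)\n",
              x$lnl0, x$beta_shared, x$lnla, x$beta_age1, x$beta_age2,
              x$statistic, x$p_value))
  invisible(x)
}
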