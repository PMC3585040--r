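#' Division-mode parameters
#'
#' The crypt model classifies stem-cell divisions into three types:
#' type I (symmetric renewal, two stem daughters), type II (symmetric
#' differentiation, two transit-amplifying daughters) and type III
#' (asymmetric, one of each). Holding the stem pool constant forces the
#' type I and type II fractions to be equal, so the model has a single
#' free parameter `beta`, the asymmetric fraction, with
#' `alpha = (1 - beta) / 2` for each symmetric type.
#'
#' @param beta Fraction of stem divisions that are asymmetric, in `[0, 1]`.
#' @return An object of class `division_params` with fields `beta` and
#'   `alpha`.
#' @examples
#' division_params(0.6)
#' @export
division_params <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1)
    stop("`beta` must be a single value in [0, 1]")
  structure(list(beta = beta, alpha = (1 - beta) / 2),
            class = "division_params")
}

#' @export
print.division_params <- function(x, ...) {
  cat(sprintf("division parameters: beta = %.4g (asymmetric), alpha = %.4g (each symmetric type)\n",
              x$beta, x$alpha))
  invisible(x)
}

#' Crypt population configuration
#'
#' Two-deme crypt model: deme 1 is the stem niche (`N1` cells), deme 2 the
#' transit-amplifying pool (`N2` cells). Each generation `N1` differentiated
#' daughters migrate into deme 2, a fraction `gamma = (N2 - N1) / (2 N2)` of
#' deme-2 cells divides once, and the remaining deme-2 cells are extruded
#' towards the villus, keeping both deme sizes constant.
#'
#' The wall clock maps to generations through the stem-cell cycle length
#' (`division_hours`, default 22 h) starting at crypt morphogenesis
#' (`morphogenesis_start_day`, postnatal day 7).
#'
#' @param N1,N2 Deme sizes (defaults 15 and 185 cells). `N2 - N1` must be
#'   even so that the dividing fraction of deme 2 is a whole number of cells.
#' @param morphogenesis_generations Nominal length of the morphogenesis
#'   phase in generations (default 8: founder expansion to `N1` stem cells
#'   followed by asymmetric filling of deme 2).
#' @param division_hours Stem-cell cycle length in hours.
#' @param morphogenesis_start_day Postnatal day at which crypt morphogenesis
#'   begins.
#' @return An object of class `crypt_config`.
#' @examples
#' cfg <- crypt_config()
#' cfg$gamma # (185 - 15) / (2 * 185)
#' @export
crypt_config <- function(N1 = 15L, N2 = 185L, morphogenesis_generations = 8L,
                         division_hours = 22, morphogenesis_start_day = 7) {
  N1 <- as.integer(N1); N2 <- as.integer(N2)
  if (is.na(N1) || N1 < 2L) stop("`N1` must be an integer >= 2")
  if (is.na(N2) || N2 <= N1) stop("`N2` must exceed `N1`")
  if ((N2 - N1) %% 2L != 0L)
    stop("`N2 - N1` must be even (the dividing half of the deme-2 turnover ",
         "must be a whole number of cells)")
  structure(list(N1 = N1, N2 = N2, gamma = (N2 - N1) / (2 * N2),
                 morphogenesis_generations = as.integer(morphogenesis_generations),
                 division_hours = division_hours,
                 morphogenesis_start_day = morphogenesis_start_day),
            class = "crypt_config")
}

#' @export
print.crypt_config <- function(x, ...) {
  cat(sprintf("crypt config: N1 = %d, N2 = %d, gamma = %.4g, %d morphogenesis generations, %g h cycle from day %g\n",
              x$N1, x$N2, x$gamma, x$morphogenesis_generations,
              x$division_hours, x$morphogenesis_start_day))
  invisible(x)
}

#' Map a postnatal age in days to a generation count
#'
#' Generations elapse at one stem-cell cycle (`division_hours`) per
#' generation, counted from the start of crypt morphogenesis. With the
#' defaults, day 52 maps to about 49 generations and day 340 to about 363.
#'
#' @param day Postnatal age in days.
#' @param config A [crypt_config()].
#' @return Integer number of generations (including morphogenesis).
#' @export
day_to_generations <- function(day, config = crypt_config()) {
  as.integer(round((day - config$morphogenesis_start_day) * 24 /
                   config$division_hours))
}

#' Piecewise-constant schedule for the asymmetric fraction
#'
#' Describes a time-varying asymmetric division fraction as a step function
#' of the homeostatic generation: `beta[i]` applies from `generation[i]`
#' (1-based, strictly increasing, first must be 1) until the next breakpoint.
#'
#' @param generation Integer breakpoints (first must be 1).
#' @param beta Asymmetric fractions at the breakpoints, all in `[0, 1]`.
#' @return An object of class `beta_schedule`.
#' @examples
#' # asymmetric early life, symmetric later
#' beta_schedule(c(1, 50), c(0.8, 0))
#' @export
beta_schedule <- function(generation, beta) {
  generation <- as.integer(generation)
  if (length(generation) != length(beta) || length(beta) < 1L)
    stop("`generation` and `beta` must be equal-length, non-empty")
  if (generation[1] != 1L || any(diff(generation) <= 0L))
    stop("`generation` must start at 1 and be strictly increasing")
  if (any(beta < 0 | beta > 1)) stop("all `beta` must lie in [0, 1]")
  structure(list(generation = generation, beta = beta),
            class = "beta_schedule")
}

# beta value per homeostatic generation 1..n
beta_by_generation <- function(params, n) {
  if (inherits(params, "division_params")) return(rep(params$beta, n))
  if (inherits(params, "beta_schedule")) {
    idx <- findInterval(seq_len(n), params$generation)
    return(params$beta[pmax(idx, 1L)])
  }
  if (is.numeric(params) && length(params) == 1L)
    return(rep(division_params(params)$beta, n))
  stop("`params` must be a division_params, beta_schedule or single beta value")
}

as_division_params <- function(params) {
  if (inherits(params, "division_params")) params
  else if (is.numeric(params) && length(params) == 1L) division_params(params)
  else stop("expected a division_params object or a single beta value")
}

#' Exact law of the per-generation division-type counts
#'
#' Keeping the stem deme at exactly `N1` cells forces the type I and II
#' counts to be equal, so the type III count must share the parity of `N1`.
#' The simulators draw `nIII ~ Binomial(N1, beta)` and, when `N1 - nIII` is
#' odd, adjust it by one in a fair-coin direction (clamped to `[0, N1]`).
#' This function returns the exact probability mass function of the adjusted
#' count and its first two moments, which the backward chain uses as
#' *effective* division-type rates. Away from the boundaries the adjustment
#' is unbiased (`E[nIII] = beta * N1`); at `beta = 0` with odd `N1` the
#' integer constraint forces one asymmetric division per generation, so the
#' effective asymmetric fraction is `1 / N1` rather than 0.
#'
#' @param beta Asymmetric division fraction.
#' @param N1 Stem deme size.
#' @return A list with `pmf` (over counts `0:N1`), `e_niii`, `e_ni`
#'   (`= E[nI] = E[nII]`), and `e_ni_ni1` (`= E[nI (nI - 1)]`).
#' @export
division_type_law <- function(beta, N1) {
  x0 <- 0:N1
  w <- stats::dbinom(x0, N1, beta)
  pmf <- numeric(N1 + 1L)
  for (i in seq_along(x0)) {
    x <- x0[i]
    if ((N1 - x) %% 2L == 0L) pmf[x + 1L] <- pmf[x + 1L] + w[i]
    else {
      up <- x + 1L; dn <- x - 1L
      if (dn < 0L) dn <- 1L
      if (up > N1) up <- N1 - 1L
      pmf[up + 1L] <- pmf[up + 1L] + w[i] / 2
      pmf[dn + 1L] <- pmf[dn + 1L] + w[i] / 2
    }
  }
  ni <- (N1 - x0) / 2 # nI given nIII (only parity-consistent entries weigh)
  list(pmf = pmf,
       e_niii = sum(pmf * x0),
       e_ni = sum(pmf * ni),
       e_ni_ni1 = sum(pmf * ni * (ni - 1)))
}
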