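#' Continuous-time crypt simulation configuration
#'
#' @param lambda Per-cell event rate (events per hour; the default is one
#'   division per 22-hour stem cycle).
#' @param stem_min,stem_max,stem_mean Bounds and target mean for the
#'   fluctuating stem pool; events that would push the stem count outside
#'   the bounds are rejected and redrawn.
#' @param p_divide Probability that a picked transit cell divides (rather
#'   than being extruded).
#' @param transit_max Soft cap on the transit pool (divisions beyond it
#'   are rejected).
#' @param max_rejections Per-event redraw cap before erroring.
#' @return A `continuous_config` object.
#' @export
continuous_config <- function(lambda = 1 / 22, stem_min = 10L, stem_max = 20L,
                              stem_mean = 15L, p_divide = 0.5,
                              transit_max = 400L, max_rejections = 1000L) {
  if (!(stem_min <= stem_mean && stem_mean <= stem_max))
    stop("need stem_min <= stem_mean <= stem_max")
  structure(list(lambda = lambda, stem_min = as.integer(stem_min),
                 stem_max = as.integer(stem_max),
                 stem_mean = as.integer(stem_mean), p_divide = p_divide,
                 transit_max = as.integer(transit_max),
                 max_rejections = as.integer(max_rejections)),
            class = "continuous_config")
}

#' Continuous-time crypt simulation
#'
#' Event-driven variant: with `n` living cells the time to the next event
#' is exponential with rate `n * lambda`; the affected cell is uniform
#' among cells. A picked stem cell divides as type I/II/III with
#' probabilities `(alpha, alpha, beta)`; a picked transit cell divides or
#' is extruded. The stem pool fluctuates within `[stem_min, stem_max]`:
#' an event that would leave the bounds is rejected and redrawn, which
#' keeps the retained trajectory inside the bounds with mean near
#' `stem_mean`.
#'
#' @param params [division_params()] or single beta.
#' @param config A [crypt_config()] (used for the initial deme sizes).
#' @param ct A [continuous_config()].
#' @param total_hours Simulated time span in hours.
#' @param seed Optional integer seed.
#' @return A `continuous_history`: per-cell `parent`, `deme`, `birth`
#'   (hours), the ids alive at the end, and the event acceptance rate.
#' @export
simulate_continuous <- function(params, config = crypt_config(),
                                ct = continuous_config(), total_hours,
                                seed = NULL) {
  params <- as_division_params(params)
  if (!is.null(seed)) set.seed(seed)
  n_tr0 <- min(config$N2, ct$transit_max)
  n0 <- ct$stem_mean + n_tr0
  cap <- 4096L
  parent <- rep(NA_integer_, cap); deme <- integer(cap); birth <- numeric(cap)
  deme[seq_len(n0)] <- c(rep(1L, ct$stem_mean), rep(2L, n_tr0))
  ncell <- n0
  alive <- integer(cap); alive[seq_len(n0)] <- seq_len(n0); nalive <- n0
  nstem <- ct$stem_mean; ntrans <- n_tr0
  time <- 0; accepted <- 0L; rejected <- 0L
  tcap <- 1024L; stem_traj <- integer(tcap); event_times <- numeric(tcap)
  grow <- function(x, need) { length(x) <- max(2L * length(x), need); x }
  while (TRUE) {
    time <- time + stats::rexp(1, nalive * ct$lambda)
    if (time > total_hours) break
    if (ncell + 2L > length(parent)) {
      parent <- grow(parent, ncell + 2L); deme <- grow(deme, ncell + 2L)
      birth <- grow(birth, ncell + 2L); alive <- grow(alive, ncell + 2L)
    }
    ok <- FALSE
    for (try in seq_len(ct$max_rejections)) {
      slot <- sample.int(nalive, 1L)
      i <- alive[slot]
      kids <- if (deme[i] == 1L) {
        u <- stats::runif(1)
        type <- if (u < params$alpha) 1L else if (u < 2 * params$alpha) 2L else 3L
        if (type == 1L && nstem + 1L > ct$stem_max) { rejected <- rejected + 1L; next }
        if (type == 2L && nstem - 1L < ct$stem_min) { rejected <- rejected + 1L; next }
        switch(type, c(1L, 1L), c(2L, 2L), c(1L, 2L))
      } else if (stats::runif(1) < ct$p_divide) {
        if (ntrans + 1L > ct$transit_max) { rejected <- rejected + 1L; next }
        c(2L, 2L)
      } else {
        if (ntrans <= 1L) { rejected <- rejected + 1L; next }
        integer(0) # extruded
      }
      if (deme[i] == 1L) nstem <- nstem - 1L else ntrans <- ntrans - 1L
      alive[slot] <- alive[nalive]; nalive <- nalive - 1L
      for (d in kids) {
        ncell <- ncell + 1L
        parent[ncell] <- i; deme[ncell] <- d; birth[ncell] <- time
        nalive <- nalive + 1L; alive[nalive] <- ncell
        if (d == 1L) nstem <- nstem + 1L else ntrans <- ntrans + 1L
      }
      ok <- TRUE; break
    }
    if (!ok)
      stop(sprintf("continuous-time rejection cap hit (acceptance rate %.3f)",
                   accepted / max(accepted + rejected, 1)))
    accepted <- accepted + 1L
    if (accepted > tcap) {
      tcap <- 2L * tcap
      length(stem_traj) <- tcap; length(event_times) <- tcap
    }
    stem_traj[accepted] <- nstem; event_times[accepted] <- time
  }
  structure(list(parent = parent[seq_len(ncell)], deme = deme[seq_len(ncell)],
                 birth = birth[seq_len(ncell)], alive = alive[seq_len(nalive)],
                 stem_trajectory = stem_traj[seq_len(accepted)],
                 event_times = event_times[seq_len(accepted)],
                 hours = total_hours, lambda = ct$lambda,
                 acceptance_rate = accepted / max(accepted + rejected, 1),
                 config = config, ct = ct, params = params),
            class = "continuous_history")
}

#' @export
print.continuous_history <- function(x, ...) {
  cat(sprintf("continuous-time history: %.0f h, %d living cells (%d stem), acceptance %.3f\n",
              x$hours, length(x$alive), sum(x$deme[x$alive] == 1L),
              x$acceptance_rate))
  invisible(x)
}

# coalescence time (hours before `at`) of two living cells
continuous_pair_tmrca <- function(sim, i, j, at = sim$hours) {
  anc <- function(i) {
    out <- i
    while (!is.na(sim$parent[i])) { i <- sim$parent[i]; out <- c(out, i) }
    out
  }
  ai <- anc(i); aj <- anc(j)
  common <- intersect(ai, aj)
  if (!length(common)) return(NA_real_)
  at - max(sim$birth[common])
}

#' Age-structured transit-pool configuration
#'
#' The transit pool is partitioned by age (divisions since leaving the stem
#' deme). Migrants enter age 1; each generation, `sizes[i + 1] / 2` cells
#' of age `i` divide into age `i + 1` and the rest are extruded; cells of
#' age `K` are always extruded the next generation.
#'
#' @param sizes Per-age deme sizes (length `K`); `sizes[1]` must equal the
#'   per-generation migrant count `N1`, and `sizes[i + 1] <= 2 sizes[i]`
#'   and even.
#' @return An `age_structure_config`.
#' @export
age_structure_config <- function(sizes = c(15L, 30L, 60L, 80L)) {
  sizes <- as.integer(sizes)
  K <- length(sizes)
  if (K < 1L) stop("need at least one age class")
  if (K > 1L) {
    if (any(sizes[-1] %% 2L != 0L))
      stop("sizes beyond age 1 must be even (each comes from dividing pairs)")
    if (any(sizes[-1] > 2L * sizes[-K]))
      stop("an age class cannot exceed twice the previous one")
  }
  structure(list(K = K, sizes = sizes), class = "age_structure_config")
}

#' Age-structured crypt simulation
#'
#' As [simulate_crypt_history()] but with the transit pool partitioned by
#' age; demes are coded 1 (stem) and `1 + age`. The age pools fill over
#' the first `K` homeostatic generations and are exactly conserved
#' afterwards.
#'
#' @param params [division_params()] or single beta.
#' @param config A [crypt_config()] (supplies `N1`; the transit structure
#'   comes from `age_config`).
#' @param age_config An [age_structure_config()] with
#'   `sizes[1] == config$N1`.
#' @param total_generations Homeostatic generations to simulate (after a
#'   founder expansion to `N1` stem cells).
#' @param seed Optional integer seed.
#' @return A `crypt_history`-shaped object (per-generation `parent` and
#'   `deme` lists) usable with [extract_genealogy()].
#' @export
simulate_age_structured <- function(params, config = crypt_config(),
                                    age_config = age_structure_config(),
                                    total_generations, seed = NULL) {
  if (age_config$sizes[1] != config$N1)
    stop("`sizes[1]` must equal N1 (every migrant enters age 1)")
  if (!is.null(seed)) set.seed(seed)
  N1 <- config$N1; K <- age_config$K; sz <- age_config$sizes
  # founder expansion to N1 stem cells
  parent <- list(0L); deme <- list(1L)
  while (sum(deme[[length(deme)]] == 1L) < N1) {
    ns <- sum(deme[[length(deme)]] == 1L)
    kids <- rep(seq_len(ns), each = 2L)
    if (length(kids) > N1) kids <- sort(sample(kids, N1))
    parent[[length(parent) + 1L]] <- kids
    deme[[length(deme) + 1L]] <- rep(1L, length(kids))
  }
  for (g in seq_len(total_generations)) {
    dm <- deme[[length(deme)]]
    stems <- which(dm == 1L)
    nIII <- draw_niii_r(N1, as_division_params(params)$beta)
    nI <- (N1 - nIII) %/% 2L
    perm <- sample(stems)
    cp <- integer(0); cd <- integer(0)
    for (s in perm[seq_len(nI)]) { cp <- c(cp, s, s); cd <- c(cd, 1L, 1L) }
    if (nIII > 0L) for (s in perm[(2L * nI + 1L):(2L * nI + nIII)]) {
      cp <- c(cp, s); cd <- c(cd, 1L)
    }
    # differentiated daughters enter age 1
    if (nI > 0L) for (s in perm[(nI + 1L):(2L * nI)]) { cp <- c(cp, s, s); cd <- c(cd, 2L, 2L) }
    if (nIII > 0L) for (s in perm[(2L * nI + 1L):(2L * nI + nIII)]) {
      cp <- c(cp, s); cd <- c(cd, 2L)
    }
    # age classes: sizes[a + 1] / 2 cells of age a divide into age a + 1
    for (a in seq_len(K - 1L)) {
      pool <- which(dm == 1L + a)
      nd <- min(length(pool), sz[a + 1L] %/% 2L)
      if (nd > 0L) for (s in sample(pool, nd)) {
        cp <- c(cp, s, s); cd <- c(cd, 2L + a, 2L + a)
      }
    }
    parent[[length(parent) + 1L]] <- cp
    deme[[length(deme) + 1L]] <- cd
  }
  structure(list(parent = parent, deme = deme,
                 morph_gens = length(parent) - 1L - total_generations,
                 config = config, age_config = age_config),
            class = c("age_structured_history", "crypt_history"))
}

#' Spatially structured transit-pool configuration
#'
#' Transit demes ordered from the crypt base towards the villus; migrants
#' enter deme 1 and offspring either stay or advance to the next deme,
#' with per-deme extrusion absorbing the remainder. The counts are exact:
#' each generation deme `d` holds `sizes[d]` cells, of which
#' `(stay_d + advance[d]) / 2` divide; `stay_1 = sizes[1] - N1` and
#' `stay_d = sizes[d] - advance[d - 1]`.
#'
#' @param sizes Per-deme sizes (sum is the transit-pool size).
#' @param advance Number of offspring advancing from deme `d` to `d + 1`
#'   (last entry must be 0).
#' @param N1 Stem deme size (migrant inflow into deme 1).
#' @return A `spatial_config`.
#' @export
spatial_config <- function(sizes = c(85L, 100L), advance = c(50L, 0L),
                           N1 = 15L) {
  sizes <- as.integer(sizes); advance <- as.integer(advance)
  S <- length(sizes)
  if (length(advance) != S || advance[S] != 0L)
    stop("`advance` must match `sizes` and end in 0")
  stay <- sizes - c(N1, advance[-S])
  if (any(stay < 0L)) stop("inflow exceeds a deme size")
  off <- stay + advance
  if (any(off %% 2L != 0L)) stop("stay + advance must be even in every deme")
  divide <- off %/% 2L
  if (any(divide > sizes)) stop("more dividers than cells in a deme")
  structure(list(S = S, sizes = sizes, advance = advance, stay = stay,
                 divide = divide, extrude = sizes - divide, N1 = N1),
            class = "spatial_config")
}

#' Spatially structured crypt simulation
#'
#' As [simulate_crypt_history()] but with the transit pool split into
#' ordered spatial demes (coded 1 + position); total cell numbers are
#' exactly conserved each generation once the demes have filled.
#'
#' @inheritParams simulate_age_structured
#' @param sp_config A [spatial_config()] with `N1` matching the config.
#' @export
simulate_spatial <- function(params, config = crypt_config(),
                             sp_config = spatial_config(N1 = config$N1),
                             total_generations, seed = NULL) {
  if (sp_config$N1 != config$N1) stop("spatial config N1 mismatch")
  if (!is.null(seed)) set.seed(seed)
  N1 <- config$N1; S <- sp_config$S
  parent <- list(0L); deme <- list(1L)
  while (sum(deme[[length(deme)]] == 1L) < N1) {
    ns <- sum(deme[[length(deme)]] == 1L)
    kids <- rep(seq_len(ns), each = 2L)
    if (length(kids) > N1) kids <- sort(sample(kids, N1))
    parent[[length(parent) + 1L]] <- kids
    deme[[length(deme) + 1L]] <- rep(1L, length(kids))
  }
  for (g in seq_len(total_generations)) {
    dm <- deme[[length(deme)]]
    stems <- which(dm == 1L)
    nIII <- draw_niii_r(N1, as_division_params(params)$beta)
    nI <- (N1 - nIII) %/% 2L
    perm <- sample(stems)
    cp <- integer(0); cd <- integer(0)
    for (s in perm[seq_len(nI)]) { cp <- c(cp, s, s); cd <- c(cd, 1L, 1L) }
    if (nIII > 0L) for (s in perm[(2L * nI + 1L):(2L * nI + nIII)]) {
      cp <- c(cp, s); cd <- c(cd, 1L)
    }
    if (nI > 0L) for (s in perm[(nI + 1L):(2L * nI)]) { cp <- c(cp, s, s); cd <- c(cd, 2L, 2L) }
    if (nIII > 0L) for (s in perm[(2L * nI + 1L):(2L * nI + nIII)]) {
      cp <- c(cp, s); cd <- c(cd, 2L)
    }
    for (d in seq_len(S)) {
      pool <- which(dm == 1L + d)
      ndiv <- min(length(pool), sp_config$divide[d])
      if (ndiv == 0L) next
      divs <- sample(pool, ndiv)
      off_d <- rep(divs, each = 2L)
      # advance in proportion to the configured flow (exact once filled)
      flow <- sp_config$advance[d] + sp_config$stay[d]
      nadv <- min(length(off_d),
                  round(length(off_d) * sp_config$advance[d] / max(flow, 1L)))
      adv_idx <- if (nadv > 0L) sample(seq_along(off_d), nadv) else integer(0)
      dd <- rep(1L + d, length(off_d))
      dd[adv_idx] <- 2L + d
      cp <- c(cp, off_d); cd <- c(cd, dd)
    }
    parent[[length(parent) + 1L]] <- cp
    deme[[length(deme) + 1L]] <- cd
  }
  structure(list(parent = parent, deme = deme,
                 morph_gens = length(parent) - 1L - total_generations,
                 config = config, sp_config = sp_config),
            class = c("spatial_history", "crypt_history"))
}

# R mirror of the C++ parity-fixed binomial draw
draw_niii_r <- function(N1, beta) {
  x <- stats::rbinom(1L, N1, beta)
  if ((N1 - x) %% 2L != 0L) {
    x <- x + if (stats::runif(1) < 0.5) 1L else -1L
    if (x < 0L) x <- 1L
    if (x > N1) x <- N1 - 1L
  }
  x
}
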