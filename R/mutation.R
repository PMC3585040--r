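#' Two-step stepwise microsatellite mutation model
#'
#' Per site and generation a repeat of length `j` mutates to `j +/- 1` or
#' `j +/- 2`, with total mutation probability `mu` and two-step changes at
#' `step2_ratio` times the frequency of one-step changes. States are repeat
#' offsets from the reference allele truncated to `[-window, +window]`;
#' probability mass that would step outside the window is added to the stay
#' probability, so every row remains stochastic.
#'
#' The defaults follow measurements in Mlh1-deficient mice: `mu = 0.01` per
#' site per generation and two-step mutations at 1/7 the one-step
#' frequency, giving per-step probabilities `p1 = 0.004375` and
#' `p2 = 0.000625`.
#'
#' @param mu Total mutation probability per site per generation (`< 1`).
#' @param step2_ratio Frequency of `+/-2` steps relative to `+/-1` steps.
#' @param window Half-width of the truncated offset state space.
#' @return An object of class `mutation_model` with fields `mu`,
#'   `step2_ratio`, `window`, `p1`, `p2`.
#' @examples
#' m <- mutation_model()
#' c(m$p1, m$p2)
#' @export
mutation_model <- function(mu = 0.01, step2_ratio = 1 / 7, window = 20L) {
  if (mu < 0 || mu >= 1) stop("`mu` must be in [0, 1)")
  if (step2_ratio < 0) stop("`step2_ratio` must be non-negative")
  window <- as.integer(window)
  if (window < 2L) stop("`window` must be at least 2")
  p1 <- mu / (2 * (1 + step2_ratio))
  structure(list(mu = mu, step2_ratio = step2_ratio, window = window,
                 p1 = p1, p2 = p1 * step2_ratio, cache = new.env(parent = emptyenv())),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("two-step mutation model: mu = %g/site/generation, p1 = %g, p2 = %g, window +/-%d\n",
              x$mu, x$p1, x$p2, x$window))
  invisible(x)
}

#' One-generation mutation transition matrix
#'
#' @param model A [mutation_model()].
#' @return A `(2 window + 1)` square stochastic matrix over offsets
#'   `-window..window`; rows index the parent state.
#' @export
one_generation_matrix <- function(model) {
  S <- 2L * model$window + 1L
  M <- diag(1 - model$mu, S)
  step <- function(M, d, p) {
    for (i in seq_len(S)) {
      j <- i + d
      if (j >= 1L && j <= S) M[i, j] <- M[i, j] + p
      else M[i, i] <- M[i, i] + p # reflected into the stay probability
    }
    M
  }
  M <- step(M, 1L, model$p1); M <- step(M, -1L, model$p1)
  M <- step(M, 2L, model$p2); M <- step(M, -2L, model$p2)
  dimnames(M) <- rep(list(as.character(-model$window:model$window)), 2)
  M
}

# external-pointer power cache for this model (built lazily, reused across
# likelihood calls: branch lengths are integer generation counts)
power_cache <- function(model) {
  if (is.null(model$cache$ptr))
    model$cache$ptr <- cpp_powcache(unname(one_generation_matrix(model)))
  model$cache$ptr
}

#' Mutation matrix along a branch of `t` generations
#'
#' The `t`-th power of the one-generation matrix, cached.
#'
#' @param model A [mutation_model()].
#' @param t Branch length in generations (non-negative integer).
#' @return The transition matrix over offsets after `t` generations.
#' @export
branch_matrix <- function(model, t) {
  t <- as.integer(t)
  if (is.na(t) || t < 0L) stop("`t` must be a non-negative integer")
  M <- cpp_branch_matrix(power_cache(model), t)
  dimnames(M) <- rep(list(as.character(-model$window:model$window)), 2)
  M
}

# decompose a phylo genealogy into time-ordered merge records (children
# created before parents); returns 0-based node ids for the C++ pruning
gtree_records <- function(genealogy) {
  phy <- genealogy
  ntip <- length(phy$tip.label)
  nt <- attr(phy, "node_time")
  if (is.null(nt)) { # fall back to branch lengths (tips contemporaneous)
    nt <- ape::node.depth.edgelength(phy)
    nt <- max(nt) - nt
  }
  internals <- (ntip + 1L):(ntip + phy$Nnode)
  ord <- internals[order(nt[internals])]
  id <- integer(ntip + phy$Nnode) # ape id -> creation order (0-based)
  id[seq_len(ntip)] <- seq_len(ntip) - 1L
  id[ord] <- ntip + seq_along(ord) - 1L
  ma <- mb <- mt <- integer(length(ord))
  for (i in seq_along(ord)) {
    kids <- phy$edge[phy$edge[, 1] == ord[i], 2]
    if (length(kids) != 2L) stop("genealogy must be a strictly binary merge tree")
    ma[i] <- id[kids[1]]; mb[i] <- id[kids[2]]
  }
  node_time <- integer(ntip + phy$Nnode)
  node_time[id + 1L] <- as.integer(round(nt))
  list(ntip = ntip, ma = ma, mb = mb, node_time = node_time,
       tip_label = phy$tip.label)
}

#' Felsenstein pruning likelihood of marker states on a genealogy
#'
#' Post-order conditional-likelihood recursion over the truncated offset
#' space. Missing leaves contribute all-ones partials. The root state is
#' fixed at offset 0 (the germline reference; mutations in the
#' mismatch-repair-deficient system accrue from conception along the
#' recorded branches) or, optionally, marginalized over a uniform prior.
#'
#' @param genealogy A `crypt_genealogy` (or any binary `phylo` whose branch
#'   lengths are integer generations and whose tips are contemporaneous).
#' @param marker_states Named vector of integer offsets (names matching tip
#'   labels; `NA` = missing), or a matrix with one column per marker and
#'   one row per cell.
#' @param model A [mutation_model()].
#' @param root `"fixed"` (offset 0) or `"uniform"`.
#' @param log Return log-likelihoods?
#' @return Per-marker likelihood `Pr(D_marker | G)` (vector).
#' @export
pruning_likelihood <- function(genealogy, marker_states, model = mutation_model(),
                               root = c("fixed", "uniform"), log = FALSE) {
  root <- match.arg(root)
  if (!is.null(genealogy$ntip) && identical(genealogy$ntip, 1L)) {
    # single-cell genealogy: the likelihood is the one-cell state probability
    st <- as.matrix(marker_states)
    ll <- ifelse(is.na(st[1, ]), 0, ifelse(st[1, ] == 0, 0, -Inf))
    return(if (log) ll else exp(ll))
  }
  rec <- gtree_records(genealogy)
  st <- marker_states
  if (is.null(dim(st))) st <- matrix(st, ncol = 1, dimnames = list(names(st), NULL))
  if (!is.null(rownames(st))) {
    if (!all(rec$tip_label %in% rownames(st)))
      stop("marker states must cover every genealogy tip")
    st <- st[rec$tip_label, , drop = FALSE]
  } else if (nrow(st) != rec$ntip) {
    stop("marker states do not match the genealogy tips")
  }
  if (any(abs(st) > model$window, na.rm = TRUE))
    stop("offsets outside the model window")
  ll <- cpp_prune_fixed(rec$ntip, rec$ma, rec$mb, rec$node_time,
                        matrix(as.integer(st), nrow = nrow(st)),
                        power_cache(model), model$window, root == "uniform")
  if (log) ll else exp(ll)
}
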