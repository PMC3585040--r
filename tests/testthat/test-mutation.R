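test_that("the two-step model resolves the default step probabilities", {
  m <- mutation_model()
  expect_equal(m$p1, 0.004375)
  expect_equal(m$p2, 0.000625)
  expect_equal(2 * m$p1 + 2 * m$p2, m$mu)
  expect_error(mutation_model(mu = 1), "mu")
})

test_that("one-generation matrices are stochastic for arbitrary models and mu = 0 is the identity", {
  set.seed(6)
  for (i in 1:10) {
    m <- mutation_model(mu = runif(1, 0, 0.5), step2_ratio = runif(1, 0, 1),
                        window = sample(2:12, 1))
    M <- one_generation_matrix(m)
    expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(one_generation_matrix(mutation_model(mu = 0))),
               diag(41))
})

test_that("branch matrices are cached powers of the one-generation matrix", {
  m <- mutation_model()
  expect_equal(unname(branch_matrix(m, 0)), diag(41))
  expect_equal(branch_matrix(m, 1)["0", "1"], 0.004375)
  # two-generation (0 -> +2) entry by explicit path enumeration
  M <- one_generation_matrix(m)
  paths <- M["0", "0"] * M["0", "2"] + M["0", "2"] * M["2", "2"] +
    M["0", "1"] * M["1", "2"] + M["0", "-1"] * M["-1", "2"] +
    M["0", "2"] * 0 # no other two-step routes contribute at this precision
  two <- sum(M["0", ] * M[, "2"])
  expect_equal(branch_matrix(m, 2)["0", "2"], two, tolerance = 1e-15)
  expect_equal(two, paths, tolerance = 1e-12)
  expect_error(branch_matrix(m, -1), "non-negative")
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(12)
  model <- mutation_model(mu = 0.08, window = 3)
  M <- one_generation_matrix(model)
  for (i in 1:25) {
    rec <- random_merge_tree(sample(2:4, 1))
    states <- sample(c(-2:2, NA), rec$ntip, replace = TRUE)
    g <- rec_to_genealogy(rec)
    names(states) <- g$tip.label
    lik <- pruning_likelihood(g, states, model)
    expect_equal(lik, brute_force_likelihood(rec, unname(states), M),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pruning degenerate cases: no data and a zero-length tree", {
  model <- mutation_model(window = 3)
  rec <- list(ntip = 2L, ma = 0L, mb = 1L, node_time = c(0L, 0L, 0L))
  g <- rec_to_genealogy(rec)
  expect_equal(pruning_likelihood(g, c(cell1 = NA, cell2 = NA), model), 1,
               ignore_attr = TRUE)
  expect_equal(pruning_likelihood(g, c(cell1 = 0, cell2 = 0), model), 1,
               ignore_attr = TRUE)
  expect_equal(pruning_likelihood(g, c(cell1 = 1, cell2 = 0), model), 0,
               ignore_attr = TRUE)
})

test_that("deleting an observation never decreases a marker likelihood", {
  set.seed(19)
  model <- mutation_model(window = 5)
  for (i in 1:10) {
    rec <- random_merge_tree(4)
    g <- rec_to_genealogy(rec)
    states <- sample(-2:2, 4, replace = TRUE)
    names(states) <- g$tip.label
    full <- pruning_likelihood(g, states, model)
    drop1 <- states; drop1[sample(4, 1)] <- NA
    expect_gte(pruning_likelihood(g, drop1, model) + 1e-15, full)
  }
})

test_that("a single injected genealogy gives the exact product over markers", {
  set.seed(23)
  model <- mutation_model()
  rec <- random_merge_tree(5, max_branch = 20L)
  g <- rec_to_genealogy(rec)
  geno <- matrix(sample(c(-1:1, NA), 5 * 12, replace = TRUE), 5, 12,
                 dimnames = list(g$tip.label, NULL))
  ll <- monte_carlo_loglik(geno, 0.4, genealogy = g, model = model)
  expect_equal(as.numeric(ll),
               sum(pruning_likelihood(g, geno, model, log = TRUE)))
})

test_that("Monte-Carlo error shrinks roughly as 1/sqrt(k)", {
  set.seed(33)
  des <- study_design(ages = 340, beta = 0.4, markers = 15, missingness = 0,
                      cells_per_crypt = 4L, crypts_per_mouse = 1L, seed = 3)
  ds <- generate_dataset(des, regime = "chain")
  ll_at <- function(k, seeds) vapply(seeds, function(s)
    as.numeric(monte_carlo_loglik(ds$study[[1]], 0.4,
      settings = likelihood_settings(k = k, source = "chain", seed = s))),
    numeric(1))
  sd_small <- stats::sd(ll_at(150, 1:14))
  sd_big <- stats::sd(ll_at(600, 1:14))
  expect_gt(sd_small / sd_big, 1.2)
  expect_lt(sd_small / sd_big, 3.5)
})

test_that("the likelihood is invariant to marker and cell relabelling under a fixed seed", {
  set.seed(41)
  des <- study_design(ages = 340, beta = 0.4, markers = 12, missingness = 0.2,
                      cells_per_crypt = 5L, crypts_per_mouse = 1L, seed = 8)
  ds <- generate_dataset(des, regime = "chain")
  geno <- ds$study[[1]]$genotypes
  st <- likelihood_settings(k = 200, source = "chain", seed = 6)
  base <- monte_carlo_loglik(geno, 0.3, settings = st)
  perm_mk <- geno[, sample(ncol(geno))]
  expect_equal(as.numeric(monte_carlo_loglik(perm_mk, 0.3, settings = st)),
               as.numeric(base))
})

test_that("the likelihood prefers the generating beta on stationary data", {
  set.seed(55)
  wins <- 0L
  for (r in 1:6) {
    des <- study_design(ages = 340, beta = 0, markers = 200, missingness = 0,
                        cells_per_crypt = 5L, crypts_per_mouse = 1L,
                        seed = 100 + r)
    ds <- generate_dataset(des, regime = "chain")
    st <- likelihood_settings(k = 300, source = "chain", seed = 200 + r)
    l0 <- monte_carlo_loglik(ds$study[[1]], 0, settings = st)
    l8 <- monte_carlo_loglik(ds$study[[1]], 0.8, settings = st)
    if (l0 > l8) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("rate-uncertainty mixtures behave as convex combinations", {
  des <- study_design(ages = 340, beta = 0.4, markers = 10, missingness = 0,
                      cells_per_crypt = 4L, crypts_per_mouse = 1L, seed = 5)
  ds <- generate_dataset(des, regime = "chain")
  st <- likelihood_settings(k = 150, source = "chain", seed = 9)
  one_bin <- rate_uncertainty(bins = 1, support = c(0.01 - 1e-9, 0.01 + 1e-9))
  lu <- loglik_with_rate_uncertainty(ds$study[[1]], 0.4, settings = st,
                                     uncertainty = one_bin)
  lm <- monte_carlo_loglik(ds$study[[1]], 0.4, settings = st)
  expect_equal(as.numeric(lu), as.numeric(lm), tolerance = 1e-6)
  u8 <- rate_uncertainty(bins = 8)
  l8 <- loglik_with_rate_uncertainty(ds$study[[1]], 0.4, settings = st,
                                     uncertainty = u8)
  per <- attr(l8, "per_rate")
  expect_gte(as.numeric(l8), min(per))
  expect_lte(as.numeric(l8), max(per))
  l4 <- loglik_with_rate_uncertainty(ds$study[[1]], 0.4, settings = st,
                                     uncertainty = rate_uncertainty(bins = 4))
  expect_lt(abs(as.numeric(l8) - as.numeric(l4)), 0.5)
  expect_error(rate_uncertainty(bins = 0), "at least 1")
  expect_error(rate_uncertainty(support = c(0.01, 0.01)), "degenerate")
})
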