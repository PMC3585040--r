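cfg <- crypt_config()

test_that("the single-step coalescence probability follows 2 alpha / (N - 1)", {
  expect_equal(single_step_coalescence_prob(1, 100), 0)
  expect_equal(single_step_coalescence_prob(0, 15), 1 / 14)
  expect_equal(single_step_coalescence_prob(0.6, 15), 0.4 / 14)
  expect_error(single_step_coalescence_prob(0.5, 1), "at least 2")
})

test_that("transition rows are stochastic up to the reported neglected mass", {
  states <- list(c(2, 0), c(1, 1), c(0, 2), c(3, 0), c(2, 1), c(1, 2), c(0, 3))
  for (b in c(0, 0.3, 0.6, 0.9)) for (st in states) {
    tt <- build_transition_table(list(m = st[1], n = st[2]), b, cfg)
    expect_equal(sum(tt$entries$prob) + tt$neglected, 1, tolerance = 1e-9)
    expect_true(all(tt$entries$prob >= 0))
    rn <- build_transition_table(list(m = st[1], n = st[2]), b, cfg,
                                 renormalize = TRUE)
    expect_equal(sum(rn$entries$prob), 1, tolerance = 1e-12)
  }
})

test_that("an absorbing state has an identity row and (2,0) coalesces at the single-step rate", {
  tt <- build_transition_table(list(m = 1, n = 0), 0.5, cfg)
  expect_equal(tt$entries, data.frame(m = 1, n = 0, prob = 1))
  row <- build_transition_table(list(m = 2, n = 0), 0.6, cfg)$entries
  p10 <- row$prob[row$m == 1 & row$n == 0]
  expect_equal(p10, 0.4 / 14, tolerance = 1e-6) # 0.02857
})

test_that("the (0,2) row matches one-generation frequencies from forward simulation", {
  b <- 0.3
  set.seed(14)
  h <- simulate_crypt_history(b, cfg, total_generations = 120)
  G <- length(h$parent)
  trials <- 4e4
  keys <- character(trials)
  for (i in seq_len(trials)) {
    g <- sample(15:G, 1)
    cells <- sample(which(h$deme[[g]] == 2L), 2)
    pars <- unique(h$parent[[g]][cells])
    pm <- h$deme[[g - 1L]]
    keys[i] <- paste(sum(pm[pars] == 1L), sum(pm[pars] == 2L))
  }
  emp <- table(keys) / trials
  tt <- build_transition_table(list(m = 0, n = 2), b, cfg)
  for (r in seq_len(nrow(tt$entries))) {
    k <- paste(tt$entries$m[r], tt$entries$n[r])
    p <- tt$entries$prob[r]
    e <- if (k %in% names(emp)) as.numeric(emp[[k]]) else 0
    se <- sqrt(max(p * (1 - p), 1e-10) / trials)
    expect_lt(abs(e - p), 3 * se + 2e-4)
  }
})

test_that("expected TMRCA: idealized limit, exact law, monotonicity and divergence at beta = 1", {
  expect_equal(expected_tmrca(0, cfg, c(m = 2, n = 0), law = "nominal"), 14)
  expect_equal(expected_tmrca(0, cfg, c(m = 2, n = 0)), 15) # integer-constrained law
  e <- vapply(c(0, 0.25, 0.5, 0.75, 0.95), function(b)
    expected_tmrca(b, cfg, c(m = 0, n = 2)), numeric(1))
  expect_true(all(diff(e) > 0))
  expect_warning(ei <- expected_tmrca(1, cfg, c(m = 2, n = 0)), "infinite")
  expect_equal(ei, Inf)
  expect_error(expected_tmrca(0.5, cfg, c(m = 2, n = 1)), "two lineages")
})

test_that("the stationary sampler reproduces the first-step expectations", {
  for (b in c(0.2, 0.7)) {
    set.seed(100 + round(10 * b))
    tm <- cryptcoal:::cpp_bwd_tmrca(1, 1, b, 15, 185, 20000, 3000)
    se <- stats::sd(tm) / sqrt(length(tm))
    expect_lt(abs(mean(tm) - expected_tmrca(b, cfg, c(m = 1, n = 1))), 3 * se)
  }
})

test_that("hypergeometric deme sampling behaves at the boundaries and on average", {
  expect_equal(sample_deme_counts(15, 185, 200, seed = 1),
               list(m = 15L, n = 185L))
  expect_error(sample_deme_counts(15, 185, 0), "between 1")
  expect_error(sample_deme_counts(15, 185, 201), "between 1")
  set.seed(8)
  m <- replicate(2000, sample_deme_counts(15, 185, 5)$m)
  se <- sqrt(5 * 0.075 * 0.925 * (195 / 199) / 2000)
  expect_lt(abs(mean(m) - 0.375), 3 * se)
})

test_that("sampled stationary genealogies are structurally valid", {
  set.seed(77)
  for (i in 1:40) {
    st <- list(m = sample(0:3, 1), n = sample(1:5, 1))
    g <- sample_genealogy_stationary(runif(1, 0, 0.9), cfg, st)
    if (st$m + st$n == 1L) {
      expect_identical(g$ntip, 1L)
      next
    }
    ntip <- length(g$tip.label)
    nt <- attr(g, "node_time")
    expect_equal(g$Nnode, ntip - 1L)              # binary merges only
    expect_true(all(nt[seq_len(ntip)] == 0))      # leaves at time 0
    for (e in seq_len(nrow(g$edge)))              # times increase root-ward
      expect_gt(nt[g$edge[e, 1]], nt[g$edge[e, 2]] - 1e-9)
    expect_true(all(g$edge.length >= 0))
  }
})

test_that("a single lineage yields the trivial genealogy and beta = 1 hits the cap", {
  g <- sample_genealogy_stationary(0.5, cfg, list(m = 1, n = 0))
  expect_identical(g$ntip, 1L)
  expect_identical(g$node_time, 0L)
  expect_error(sample_genealogy_stationary(1, cfg, list(m = 2, n = 0),
                                           seed = 1, max_generations = 500),
               "cap")
})

test_that("genealogies export to newick with deme annotations", {
  g <- sample_genealogy_stationary(0.4, cfg, list(m = 1, n = 3), seed = 5)
  nwk <- write_genealogy(g)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "_d1")
  reread <- ape::read.tree(text = nwk)
  expect_equal(length(reread$tip.label), 4L)
})
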