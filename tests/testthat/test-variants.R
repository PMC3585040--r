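cfg_small <- crypt_config(N1 = 15L, N2 = 35L)

test_that("continuous-time stem counts stay within bounds and lambda rescales time exactly", {
  ct <- continuous_config()
  sim <- simulate_continuous(0.4, cfg_small, ct, total_hours = 600, seed = 5)
  expect_true(all(sim$stem_trajectory >= 10 & sim$stem_trajectory <= 20))
  ct2 <- continuous_config(lambda = 2 / 22)
  sim2 <- simulate_continuous(0.4, cfg_small, ct2, total_hours = 300, seed = 5)
  expect_identical(sim$parent, sim2$parent)
  expect_identical(sim$deme, sim2$deme)
  expect_equal(sim2$birth, sim$birth / 2, tolerance = 1e-12)
})

test_that("continuous-time stem coalescence agrees with the discrete-generation model", {
  ct <- continuous_config(lambda = 1 / 22, stem_min = 13L, stem_max = 17L)
  beta <- 0.3
  hours <- 250 * 22
  set.seed(8)
  per_run <- replicate(60, {
    sim <- simulate_continuous(beta, cfg_small, ct, total_hours = hours)
    stems <- sim$alive[sim$deme[sim$alive] == 1L]
    pairs <- utils::combn(stems, 2)
    keep <- sample(ncol(pairs), min(25, ncol(pairs)))
    tm <- vapply(keep, function(p)
      cryptcoal:::continuous_pair_tmrca(sim, pairs[1, p], pairs[2, p]),
      numeric(1))
    mean(tm, na.rm = TRUE) / 22 # hours -> generation equivalents
  })
  set.seed(9)
  disc <- replicate(60, {
    h <- suppressWarnings(
      simulate_crypt_history(beta, cfg_small, total_generations = 250))
    G <- length(h$parent) - 1L
    stems <- which(h$deme[[G + 1L]] == 1L)
    pairs <- utils::combn(stems, 2)
    keep <- sample(ncol(pairs), 25)
    mean(vapply(keep, function(p)
      cryptcoal:::trace_pair_tmrca(h, G, pairs[1, p], pairs[2, p]),
      numeric(1)))
  })
  per_run <- per_run[is.finite(per_run)]
  se <- sqrt(stats::var(per_run) / length(per_run) + stats::var(disc) / 60)
  expect_lt(abs(mean(per_run) - mean(disc)), 3 * se)
})

test_that("age structure: age-1 cells always descend from stem cells and pools are conserved", {
  ac <- age_structure_config(c(15L, 30L, 60L, 80L))
  h <- simulate_age_structured(0.3, crypt_config(), ac,
                               total_generations = 30, seed = 3)
  G <- length(h$parent)
  for (g in (G - 10):G) {
    dm <- h$deme[[g]]; pm <- h$deme[[g - 1L]]
    age1 <- which(dm == 2L)
    expect_true(all(pm[h$parent[[g]][age1]] == 1L))
    # exact per-age sizes once filled
    expect_equal(unname(table(factor(dm, levels = 1:5))),
                 array(c(15L, 15L, 30L, 60L, 80L)))
  }
})

test_that("a maximum age of one empties the transit pool after a single generation", {
  ac <- age_structure_config(15L)
  h <- simulate_age_structured(0.3, crypt_config(), ac,
                               total_generations = 12, seed = 4)
  G <- length(h$parent)
  dm <- h$deme[[G]]
  expect_equal(sum(dm == 2L), 15L) # transit pool = this generation's migrants
  expect_true(all(dm %in% c(1L, 2L)))
})

test_that("age-structured stem dynamics match the base first-step analysis", {
  set.seed(6)
  tm <- replicate(150, {
    h <- simulate_age_structured(0.3, crypt_config(), age_structure_config(),
                                 total_generations = 160)
    G <- length(h$parent) - 1L
    stems <- sample(which(h$deme[[G + 1L]] == 1L), 2)
    cryptcoal:::trace_pair_tmrca(h, G, stems[1], stems[2])
  })
  e <- expected_tmrca(0.3, crypt_config(), c(m = 2, n = 0))
  expect_lt(abs(mean(tm) - e), 3 * stats::sd(tm) / sqrt(length(tm)))
})

test_that("spatial config validates and a single deme reduces to the base turnover", {
  expect_error(spatial_config(c(85L, 100L), c(50L, 1L)), "end in 0")
  expect_error(spatial_config(c(10L, 100L), c(50L, 0L), N1 = 15L), "exceeds")
  one <- spatial_config(185L, 0L, N1 = 15L)
  expect_equal(one$divide, 85L) # = gamma * N2 of the base model
  h <- simulate_spatial(0.3, crypt_config(), one, total_generations = 140,
                        seed = 7)
  G <- length(h$parent)
  for (g in (G - 5):G) {
    dm <- h$deme[[g]]
    expect_equal(c(sum(dm == 1L), sum(dm == 2L)), c(15L, 185L))
  }
  set.seed(10)
  tm <- replicate(120, {
    h <- simulate_spatial(0.3, crypt_config(), one, total_generations = 140)
    G <- length(h$parent) - 1L
    stems <- sample(which(h$deme[[G + 1L]] == 1L), 2)
    cryptcoal:::trace_pair_tmrca(h, G, stems[1], stems[2])
  })
  e <- expected_tmrca(0.3, crypt_config(), c(m = 2, n = 0))
  expect_lt(abs(mean(tm) - e), 3 * stats::sd(tm) / sqrt(length(tm)))
})

test_that("total cell counts are conserved in the two-deme spatial default", {
  sp <- spatial_config()
  h <- simulate_spatial(0.4, crypt_config(), sp, total_generations = 25,
                        seed = 9)
  G <- length(h$parent)
  for (g in (G - 5):G)
    expect_equal(length(h$deme[[g]]), 15L + sum(sp$sizes))
})

test_that("the extrusion location shifts within-crypt coalescence times reproducibly", {
  # With exact per-deme counts, concentrating extrusion in the distal deme
  # removes proximal self-renewal (every proximal offspring advances), so
  # lineages return to the stem pool faster and within-crypt coalescence
  # times SHORTEN relative to uniform extrusion; see the methods vignette.
  uniform <- spatial_config(c(85L, 100L), c(50L, 0L))
  distal <- spatial_config(c(85L, 100L), c(100L, 0L)) # no proximal extrusion
  mean_tmrca <- function(sp, seed) {
    set.seed(seed)
    replicate(80, {
      h <- simulate_spatial(0.3, crypt_config(), sp, total_generations = 150)
      G <- length(h$parent) - 1L
      ij <- sample(length(h$deme[[G + 1L]]), 2)
      cryptcoal:::trace_pair_tmrca(h, G, ij[1], ij[2])
    })
  }
  u <- mean_tmrca(uniform, 11); d <- mean_tmrca(distal, 11)
  se <- sqrt(stats::var(u) / 80 + stats::var(d) / 80)
  expect_gt(mean(u) - mean(d), 2 * se) # paired designs, same seeds
})
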