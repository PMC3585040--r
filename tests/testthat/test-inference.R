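cfg <- crypt_config()
model <- mutation_model()

make_stationary_study <- function(beta, markers, cells, crypts, seed,
                                  ages = 340) {
  ds <- generate_dataset(study_design(ages = ages, beta = beta,
                                      markers = markers, missingness = 0,
                                      cells_per_crypt = cells,
                                      crypts_per_mouse = crypts,
                                      model = model, config = cfg,
                                      seed = seed),
                         regime = "chain")
  ds$study
}

test_that("a one-crypt, one-point surface reproduces monte_carlo_loglik and pooling sums crypts", {
  study <- make_stationary_study(0.4, 15, 5, 2, seed = 21)
  st <- likelihood_settings(k = 150, source = "chain", seed = 17)
  surf <- profile_beta(study[1], cfg, st, grid = 0.4, model = model)
  direct <- monte_carlo_loglik(study[[1]], 0.4, cfg, st, model)
  expect_equal(unname(surf$loglik[1, 1]), as.numeric(direct))
  surf2 <- profile_beta(study, cfg, st, grid = c(0.2, 0.4), model = model)
  expect_equal(surf2$pooled[, 1], rowSums(surf2$loglik), ignore_attr = TRUE)
})

test_that("grid MLE takes the argmax and resolves ties to the smaller beta", {
  grid <- seq(0, 1, 0.25)
  expect_equal(cryptcoal:::argmax_low_tie(grid, c(-5, -2, -3, -4, -6)), 0.25)
  expect_warning(tie <- cryptcoal:::argmax_low_tie(grid, c(-2, -2, -3, -4, -6)),
                 "smallest")
  expect_equal(tie, 0)
  expect_error(cryptcoal:::argmax_low_tie(grid, rep(-Inf, 5)), "-Inf")
})

test_that("profile intervals: flat surfaces span the grid, zero drop degenerates, quadratic width matches the closed form", {
  grid <- seq(0, 1, 0.02)
  fake <- structure(list(grid = grid,
                         pooled = matrix(rep(-10, length(grid)),
                                         dimnames = list(NULL, "m1")),
                         loglik = NULL),
                    class = "likelihood_surface")
  ci <- suppressWarnings(profile_ci(fake))
  expect_equal(c(ci$lower, ci$upper), c(0, 1))
  curv <- 400 # lnl = -c/2 (b - 0.5)^2
  fake$pooled[, 1] <- -curv / 2 * (grid - 0.5)^2
  ci0 <- profile_ci(fake, drop = 0)
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$lower, 0.5)
  ciq <- profile_ci(fake)
  width <- ciq$upper - ciq$lower
  expect_lt(abs(width - 2 * sqrt(2 * 1.92 / curv)), 2 * 0.02)
  expect_equal(0.5 * stats::qchisq(0.95, 1), 1.92, tolerance = 5e-4)
})

test_that("surfaces recover the generating beta from stationary data", {
  study <- make_stationary_study(0.8, 150, 6, 1, seed = 77)
  st <- likelihood_settings(k = 400, source = "chain", seed = 13)
  surf <- suppressWarnings(profile_beta(study, cfg, st, model = model))
  expect_lt(abs(unname(mle_beta(surf)) - 0.8), 0.1 + 1e-9)
})

test_that("bootstrap on constant marker panels is degenerate and its CI endpoints are order statistics", {
  study <- make_stationary_study(0.4, 12, 5, 2, seed = 31)
  # make all markers identical copies of one column
  study <- lapply(study, function(cg) {
    cg$genotypes <- cg$genotypes[, rep(1, 10), drop = FALSE]
    colnames(cg$genotypes) <- paste0("mk", 1:10)
    cg
  })
  st <- likelihood_settings(k = 120, source = "chain", seed = 3)
  bs <- suppressWarnings(bootstrap_beta(study, cfg, st, B = 12, seed = 5,
                                        grid = seq(0, 0.9, 0.1), model = model))
  expect_equal(stats::sd(bs$estimates[, 1]), 0)
  expect_equal(unname(bs$ci[1, 1]), unname(bs$ci[2, 1]))
  expect_true(all(bs$ci %in% bs$estimates))
  expect_error(bootstrap_beta(study, cfg, st, B = 0), "at least 1")
})

test_that("identical age groups give a zero LRT statistic and p = 1", {
  study <- make_stationary_study(0.4, 15, 5, 2, seed = 41)
  st <- likelihood_settings(k = 100, source = "chain", seed = 7)
  res <- suppressWarnings(
    lrt_equal_beta(study, study, cfg, st, grid = seq(0, 0.9, 0.1),
                   model = model))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$beta_age1, res$beta_age2)
})

test_that("the LRT detects a strong division-mode contrast and never reports lnLa < lnL0", {
  rejections <- 0L
  for (r in 1:6) {
    young <- make_stationary_study(0.8, 60, 6, 2, seed = 500 + r)
    old <- make_stationary_study(0, 60, 6, 2, seed = 600 + r)
    st <- likelihood_settings(k = 300, source = "chain", seed = 700 + r)
    res <- suppressWarnings(
      lrt_equal_beta(young, old, cfg, st, grid = seq(0, 0.96, 0.04),
                     model = model))
    expect_gte(res$lnla, res$lnl0 - 1e-9)
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 5L)
})

test_that("marker information sharpens the estimate (20 vs 160 markers)", {
  errs <- sapply(c(20, 160), function(M) {
    e <- sapply(1:4, function(r) {
      study <- make_stationary_study(0.4, M, 6, 1, seed = 800 + 10 * M + r)
      st <- likelihood_settings(k = 250, source = "chain", seed = 900 + r)
      surf <- suppressWarnings(profile_beta(study, cfg, st, model = model))
      abs(unname(mle_beta(surf)) - 0.4)
    })
    mean(e)
  })
  expect_lte(errs[2], errs[1] + 0.04)
})
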