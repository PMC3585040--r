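test_that("the inclusion filter drops markers with fewer than two genotyped cells", {
  m <- matrix(c(0L, 1L, NA, NA,
                0L, NA, NA, NA,
                2L, 0L, 1L, NA), nrow = 4)
  colnames(m) <- c("a", "b", "c")
  expect_message(cg <- crypt_genotypes(m), "dropping 1")
  expect_equal(colnames(cg$genotypes), c("a", "c"))
  expect_error(suppressMessages(crypt_genotypes(m[, 2, drop = FALSE])),
               "no markers")
})

test_that("genotype tables round-trip through CSV and TSV", {
  des <- study_design(ages = c(52, 340), beta = c(0.6, 0), markers = 10,
                      cells_per_crypt = 4L, seed = 2)
  ds <- generate_dataset(des)
  for (ext in c("csv", "tsv")) {
    path <- file.path(tempdir(), paste0("geno.", ext))
    write_genotypes(ds$study, path)
    back <- read_genotypes(path)
    expect_equal(length(back), length(ds$study))
    orig <- ds$study[[2]]
    match_id <- which(vapply(back, function(x)
      x$mouse == orig$mouse && x$crypt == orig$crypt, logical(1)))
    expect_equal(unname(back[[match_id]]$genotypes[rownames(orig$genotypes),
                                                   colnames(orig$genotypes)]),
                 unname(orig$genotypes))
  }
})

test_that("model distances: zero for identical cells, symmetric, and the ML scan matches a direct scan", {
  model <- mutation_model()
  geno <- rbind(cellA = c(0L, 0L, 1L, -2L),
                cellB = c(0L, 0L, 1L, -2L),
                cellC = c(0L, 1L, 1L, NA))
  d <- pairwise_distance(geno, model)
  expect_equal(unname(d$distance["cellA", "cellB"]), 0)
  expect_true(isSymmetric(d$distance))
  expect_equal(unname(d$n_shared["cellA", "cellC"]), 3L)
  # two cells, one marker, offsets 0 and +1: independent scan over t
  single <- rbind(c1 = 0L, c2 = 1L)
  colnames(single) <- "mk1"
  dml <- pairwise_distance(single, model, t_max = 600)$distance[1, 2]
  scan <- vapply(0:600, function(t) branch_matrix(model, t)["0", "1"],
                 numeric(1))
  expect_equal(unname(dml), which.max(scan) - 1)
  dst <- pairwise_distance(single, model, method = "steps")$distance[1, 2]
  expect_equal(unname(dst), 1 / (2 * model$p1 + 4 * model$p2))
})

test_that("UPGMA reproduces hand agglomeration and is ultrametric", {
  D <- matrix(c(0, 2, 6,
                2, 0, 6,
                6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- upgma_tree(D)
  coph <- ape::cophenetic.phylo(phy)[rownames(D), colnames(D)]
  expect_equal(coph, D) # ultrametric input is recovered exactly
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_along(phy$tip.label)]
  expect_equal(max(tip_depth) - min(tip_depth), 0, tolerance = 1e-12)
  # two taxa at distance d -> both branches d/2
  D2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(sort(upgma_tree(D2)$edge.length), c(2.5, 2.5))
  D[1, 2] <- NA; D[2, 1] <- NA
  expect_error(upgma_tree(D), "missing")
})

test_that("crypts are monophyletic at stationary divergence and between-crypt distance grows with age", {
  model <- mutation_model()
  mono <- 0L
  for (r in 1:4) {
    des <- study_design(ages = 340, beta = 0.2, markers = 60,
                        cells_per_crypt = 5L, missingness = 0.1,
                        model = model, seed = 40 + r)
    ds <- generate_dataset(des, regime = "chain")
    geno <- combine_crypts(ds$study)
    phy <- upgma_tree(pairwise_distance(geno, model))
    tips1 <- grep("^crypt1", phy$tip.label, value = TRUE)
    if (ape::is.monophyletic(phy, tips1)) mono <- mono + 1L
  }
  expect_gte(mono, 3L)
  between <- sapply(c(52, 340), function(age) {
    des <- study_design(ages = age, beta = 0.4, markers = 60,
                        cells_per_crypt = 5L, missingness = 0,
                        model = model, seed = 91)
    ds <- generate_dataset(des, regime = if (age > 300) "chain" else "forward")
    geno <- combine_crypts(ds$study)
    d <- pairwise_distance(geno, model)$distance
    cr <- sub("\\..*$", "", rownames(d))
    mean(d[cr[row(d)] != cr[col(d)]])
  })
  expect_gt(between[2], between[1])
})
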