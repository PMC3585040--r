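#' Single-crypt genotype container
#'
#' Holds the cells x markers integer offset matrix for one crypt together
#' with its study metadata. Offsets are repeat-length differences from the
#' per-marker reference allele; `NA` marks failed genotyping.
#'
#' @param genotypes Integer matrix, rows = cells, columns = markers.
#' @param crypt,mouse Identifiers.
#' @param age_days Age at sampling (postnatal days).
#' @param regime Genealogy regime for likelihood fits: `"chain"`
#'   (stationary) or `"forward"` (non-stationary).
#' @param min_cells Markers genotyped in fewer cells are dropped (the
#'   study inclusion filter; default 2).
#' @return A `crypt_genotypes` object.
#' @export
crypt_genotypes <- function(genotypes, crypt = "crypt1", mouse = "mouse1",
                            age_days = NA_real_, regime = c("chain", "forward"),
                            min_cells = 2L) {
  regime <- match.arg(regime)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("cell", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("mk", seq_len(ncol(genotypes)))
  keep <- colSums(!is.na(genotypes)) >= min_cells
  if (!all(keep)) {
    message("dropping ", sum(!keep), " marker(s) genotyped in fewer than ",
            min_cells, " cells")
    genotypes <- genotypes[, keep, drop = FALSE]
  }
  if (ncol(genotypes) == 0L) stop("no markers pass the inclusion filter")
  structure(list(genotypes = genotypes, crypt = crypt, mouse = mouse,
                 age_days = age_days, regime = regime),
            class = "crypt_genotypes")
}

#' @export
print.crypt_genotypes <- function(x, ...) {
  cat(sprintf("crypt genotypes: %s / %s (day %s), %d cells x %d markers, %.1f%% missing\n",
              x$mouse, x$crypt, format(x$age_days), nrow(x$genotypes),
              ncol(x$genotypes), 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

genotype_data <- function(x) {
  if (inherits(x, "crypt_genotypes")) return(x$genotypes)
  if (is.matrix(x)) {
    m <- x; storage.mode(m) <- "integer"
    if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
    return(m)
  }
  stop("expected a genotype matrix or crypt_genotypes object")
}

as_crypt_study <- function(x) {
  if (inherits(x, "crypt_genotypes")) return(list(x))
  if (is.matrix(x)) return(list(crypt_genotypes(x)))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "crypt_genotypes")))
    return(x)
  stop("expected a crypt_genotypes object or a list of them")
}

#' Read genotype tables
#'
#' Reads a CSV/TSV table whose first column is the cell identifier,
#' followed by one integer offset column per marker (`NA` = missing). An
#' optional `crypt` column (and optional `mouse`, `age_days` columns)
#' splits the table into per-crypt objects.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated.
#' @param ... Passed to [crypt_genotypes()].
#' @return A `crypt_genotypes` object, or a list of them if a `crypt`
#'   column is present.
#' @export
read_genotypes <- function(path, ...) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("crypt", "mouse", "age_days"), names(df))
  cells <- df[[1]]
  mk <- as.matrix(df[, setdiff(names(df)[-1], meta), drop = FALSE])
  rownames(mk) <- cells
  if (!"crypt" %in% meta) return(crypt_genotypes(mk, ...))
  grp <- if ("mouse" %in% meta) paste(df$mouse, df$crypt) else df$crypt
  lapply(split(seq_len(nrow(df)), grp), function(idx) {
    crypt_genotypes(mk[idx, , drop = FALSE],
                    crypt = df$crypt[idx[1]],
                    mouse = if ("mouse" %in% meta) df$mouse[idx[1]] else "mouse1",
                    age_days = if ("age_days" %in% meta) df$age_days[idx[1]] else NA_real_,
                    ...)
  })
}

#' Write genotype tables
#'
#' @param x A `crypt_genotypes` object or list of them.
#' @param path Output file; `.tsv` writes tab-separated.
#' @export
write_genotypes <- function(x, path) {
  study <- as_crypt_study(x)
  rows <- lapply(study, function(cg)
    data.frame(cell = rownames(cg$genotypes), crypt = cg$crypt,
               mouse = cg$mouse, age_days = cg$age_days,
               cg$genotypes, check.names = FALSE))
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model-based pairwise distances between cells
#'
#' For each cell pair, `method = "ml"` reports the maximum-likelihood
#' number of generations separating the two cells under the two-step
#' model: the `t` maximizing the product over shared markers of the
#' `t`-generation transition probability between their offsets (found by
#' scanning `t`). `method = "steps"` reports the mean absolute offset
#' difference divided by the expected absolute change per generation, a
#' simple moment-based alternative. Only markers genotyped in both cells
#' are compared.
#'
#' @param data Genotype matrix or [crypt_genotypes()]; multiple objects
#'   may be combined with [combine_crypts()].
#' @param model A [mutation_model()].
#' @param method `"ml"` or `"steps"`.
#' @param t_max Largest separation scanned for `"ml"`.
#' @return A `dist_matrix` list: `distance` (symmetric matrix),
#'   `n_shared` (markers compared per pair).
#' @export
pairwise_distance <- function(data, model = mutation_model(),
                              method = c("ml", "steps"), t_max = 2000L) {
  method <- match.arg(method)
  geno <- center_offsets(genotype_data(data)) # distances are shift-invariant
  n <- nrow(geno)
  if (n < 2L) stop("need at least two cells")
  D <- matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno)))
  NS <- matrix(0L, n, n, dimnames = dimnames(D))
  pairs <- utils::combn(n, 2)
  shared <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ok <- !is.na(geno[i, ]) & !is.na(geno[j, ])
    cbind(geno[i, ok], geno[j, ok])
  })
  ns <- vapply(shared, nrow, integer(1))
  if (all(ns == 0L)) stop("no cell pair shares a genotyped marker")
  if (any(ns == 0L)) warning(sum(ns == 0L), " cell pair(s) share no markers (NA distance)")
  if (method == "steps") {
    rate <- 2 * model$p1 + 4 * model$p2
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      d <- if (ns[p] == 0L) NA_real_ else mean(abs(shared[[p]][, 1] - shared[[p]][, 2])) / rate
      D[i, j] <- D[j, i] <- d
      NS[i, j] <- NS[j, i] <- ns[p]
    }
    return(structure(list(distance = D, n_shared = NS, method = method),
                     class = "dist_matrix"))
  }
  # ML separation: one sweep over t, scoring all pairs at once; duplicate
  # offset pairs within a pair of cells are collapsed to counts
  w <- model$window
  combos <- lapply(shared, function(s) {
    if (nrow(s) == 0L) return(NULL)
    key <- paste(pmin(s[, 1], s[, 2]), pmax(s[, 1], s[, 2])) # P^t is symmetric
    tab <- table(key)
    ab <- do.call(rbind, strsplit(names(tab), " "))
    cbind(as.integer(ab[, 1]) + w + 1L, as.integer(ab[, 2]) + w + 1L,
          as.integer(tab))
  })
  best_t <- integer(ncol(pairs)); best_ll <- rep(-Inf, ncol(pairs))
  for (t in 0:t_max) {
    M <- cpp_branch_matrix(power_cache(model), t)
    for (p in seq_len(ncol(pairs))) {
      cb <- combos[[p]]
      if (is.null(cb)) next
      ll <- sum(cb[, 3] * log(M[cb[, 1:2, drop = FALSE]]))
      if (ll > best_ll[p]) { best_ll[p] <- ll; best_t[p] <- t }
    }
  }
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    D[i, j] <- D[j, i] <- if (ns[p] == 0L) NA_real_ else best_t[p]
    NS[i, j] <- NS[j, i] <- ns[p]
  }
  structure(list(distance = D, n_shared = NS, method = method),
            class = "dist_matrix")
}

#' Combine crypts into one genotype matrix
#'
#' Stacks the cells of several crypts over the union of their markers
#' (cells are prefixed with the crypt id), e.g. for a joint UPGMA tree.
#'
#' @param study A list of [crypt_genotypes()] objects.
#' @return An integer genotype matrix.
#' @export
combine_crypts <- function(study) {
  study <- as_crypt_study(study)
  markers <- Reduce(union, lapply(study, function(x) colnames(x$genotypes)))
  rows <- lapply(study, function(x) {
    m <- matrix(NA_integer_, nrow(x$genotypes), length(markers),
                dimnames = list(paste(x$crypt, rownames(x$genotypes), sep = "."),
                                markers))
    m[, colnames(x$genotypes)] <- x$genotypes
    m
  })
  do.call(rbind, rows)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merging
#' distance, so the tree is ultrametric. Agglomeration ties are broken
#' deterministically (first pair in label order).
#'
#' @param dist A `dist_matrix` from [pairwise_distance()] or a symmetric
#'   numeric matrix (no missing entries).
#' @return An ultrametric [ape][ape::read.tree] `phylo` tree.
#' @export
upgma_tree <- function(dist) {
  D <- if (inherits(dist, "dist_matrix")) dist$distance else as.matrix(dist)
  if (any(is.na(D))) stop("distance matrix has missing entries")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # as.phylo.hclust places tips at half the merge height, which is exactly
  # the UPGMA convention, so the heights are used as-is
  ape::as.phylo(hc)
}
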