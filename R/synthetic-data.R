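#' Synthetic study design
#'
#' Describes a complete synthetic single-cell microsatellite study with the
#' structure of the motivating experiment: a small number of mice sampled
#' at different ages, two colon crypts per mouse, 4-6 cells per crypt and a
#' shared per-mouse marker panel (70-90 usable markers by default, the
#' usable yield of a ~150-marker screen), with missing-completely-at-random
#' genotype dropout and the inclusion filter that every marker must be
#' genotyped in at least two cells.
#'
#' @param ages Postnatal age (days) of each mouse.
#' @param beta True asymmetric fraction per mouse (recycled); a list of
#'   [beta_schedule()] objects is accepted for time-varying truths.
#' @param crypts_per_mouse Crypts sampled per mouse.
#' @param cells_per_crypt `NULL` (drawn uniformly from `cell_range`), a
#'   single count, or a vector/matrix giving counts per crypt.
#' @param cell_range Range cells are drawn from when `cells_per_crypt` is
#'   `NULL`.
#' @param markers `NULL` (drawn uniformly from `marker_range` per mouse)
#'   or a fixed per-mouse marker count.
#' @param marker_range Range of usable marker counts.
#' @param missingness Per-entry dropout probability (columns violating the
#'   two-cell filter get their dropout mask redrawn).
#' @param model A [mutation_model()].
#' @param config A [crypt_config()].
#' @param stationary_generations Ages mapping to at least this many
#'   generations are treated as stationary (likelihoods use the backward
#'   chain); younger ages use forward simulation.
#' @param founder_divergence Add the mutations accumulated between the
#'   zygote and each crypt's most recent common ancestor (a per-marker
#'   offset shared by all cells of the crypt)? This is what separates
#'   crypts from each other; within-crypt analyses re-reference offsets to
#'   the per-marker modal allele, which removes the shared shift.
#' @param prenatal_days Days of prenatal lineage history charged to the
#'   zygote-to-founder branch.
#' @param seed Integer seed.
#' @return A `study_design` object.
#' @export
study_design <- function(ages = c(52, 340), beta = c(0.76, 0),
                         crypts_per_mouse = 2L, cells_per_crypt = NULL,
                         cell_range = c(4L, 6L), markers = NULL,
                         marker_range = c(70L, 90L), missingness = 0.3,
                         model = mutation_model(), config = crypt_config(),
                         stationary_generations = 300L,
                         founder_divergence = TRUE, prenatal_days = 20,
                         seed = 1L) {
  n_mice <- length(ages)
  if (!is.list(beta)) beta <- as.list(rep_len(beta, n_mice))
  if (missingness < 0 || missingness >= 1) stop("`missingness` must be in [0, 1)")
  structure(list(ages = ages, beta = beta, n_mice = n_mice,
                 crypts_per_mouse = as.integer(crypts_per_mouse),
                 cells_per_crypt = cells_per_crypt,
                 cell_range = as.integer(cell_range),
                 markers = markers, marker_range = as.integer(marker_range),
                 missingness = missingness, model = model, config = config,
                 stationary_generations = as.integer(stationary_generations),
                 founder_divergence = isTRUE(founder_divergence),
                 prenatal_days = prenatal_days,
                 seed = as.integer(seed)),
            class = "study_design")
}

# simulate offsets for each marker down a genealogy (root at offset 0)
drop_mutations <- function(genealogy, n_markers, model) {
  if (!is.null(genealogy$ntip) && identical(genealogy$ntip, 1L))
    return(matrix(0L, 1L, n_markers,
                  dimnames = list("cell1", paste0("mk", seq_len(n_markers)))))
  rec <- gtree_records(genealogy)
  nnode <- length(rec$node_time)
  states <- matrix(NA_integer_, nnode, n_markers)
  root <- nnode
  states[root, ] <- 0L
  w <- model$window
  offs <- -w:w
  draw_children <- function(parent_states, t) {
    if (t == 0L) return(parent_states)
    M <- branch_matrix(model, t)
    out <- integer(length(parent_states))
    for (s in unique(parent_states)) {
      idx <- which(parent_states == s)
      out[idx] <- sample(offs, length(idx), replace = TRUE, prob = M[s + w + 1L, ])
    }
    out
  }
  for (c in rev(seq_along(rec$ma))) { # root-ward merges first
    id <- rec$ntip + c
    for (kid in c(rec$ma[c] + 1L, rec$mb[c] + 1L)) {
      t <- rec$node_time[id] - rec$node_time[kid]
      states[kid, ] <- draw_children(states[id, ], t)
    }
  }
  tips <- states[seq_len(rec$ntip), , drop = FALSE]
  dimnames(tips) <- list(rec$tip_label, paste0("mk", seq_len(n_markers)))
  tips
}

apply_missingness <- function(geno, rate, max_tries = 200L) {
  if (rate <= 0) return(geno)
  n <- nrow(geno)
  for (j in seq_len(ncol(geno))) {
    for (try in seq_len(max_tries)) {
      drop <- stats::runif(n) < rate
      if (sum(!drop) >= 2L) { geno[drop, j] <- NA_integer_; break }
    }
  }
  geno
}

#' Generate a synthetic study dataset
#'
#' For each crypt: simulate the crypt to the age's generation count
#' (forward simulation with full ancestry, or an exact stationary backward
#' draw for ages past the stationarity threshold), sample the cells,
#' extract their genealogy, drop mutations independently per marker along
#' every branch under the two-step model starting from offset 0, and apply
#' missingness. The truth record keeps every true beta, genealogy and seed
#' so that parameter recovery can be scored.
#'
#' @param design A [study_design()].
#' @param regime `"auto"` (by age), or force `"chain"`/`"forward"` for
#'   every crypt.
#' @return A list with `study` (list of [crypt_genotypes()]) and `truth`
#'   (per-crypt list of `beta`, `genealogy`, `regime`, `seed`).
#' @export
generate_dataset <- function(design, regime = c("auto", "chain", "forward")) {
  regime <- match.arg(regime)
  set.seed(design$seed)
  cfg <- design$config
  study <- list()
  truth <- list()
  for (mi in seq_len(design$n_mice)) {
    age <- design$ages[mi]
    gens <- day_to_generations(age, cfg)
    reg <- if (regime != "auto") regime
           else if (gens >= design$stationary_generations) "chain" else "forward"
    M <- if (!is.null(design$markers)) rep_len(design$markers, design$n_mice)[mi]
         else sample(design$marker_range[1]:design$marker_range[2], 1L)
    for (ci in seq_len(design$crypts_per_mouse)) {
      ncell <- if (is.null(design$cells_per_crypt))
        sample(design$cell_range[1]:design$cell_range[2], 1L)
      else {
        cc <- design$cells_per_crypt
        if (is.matrix(cc)) cc[mi, ci] else rep_len(cc, design$crypts_per_mouse)[ci]
      }
      if (reg == "forward") {
        bh <- if (inherits(design$beta[[mi]], "beta_schedule")) design$beta[[mi]]
              else division_params(design$beta[[mi]])
        h <- simulate_crypt_history(bh, cfg, total_generations = gens)
        gtree <- extract_genealogy(h, ncell)
      } else {
        if (inherits(design$beta[[mi]], "beta_schedule"))
          stop("a time-varying beta needs the forward regime")
        mn <- sample_deme_counts(cfg$N1, cfg$N2, ncell)
        gtree <- sample_genealogy_stationary(division_params(design$beta[[mi]]),
                                             cfg, mn)
      }
      geno <- drop_mutations(gtree, M, design$model)
      if (design$founder_divergence) {
        # mutations on the zygote -> crypt-MRCA branch shift every cell of
        # the crypt by a shared per-marker offset
        root_t <- if (identical(gtree$ntip, 1L)) 0L
                  else max(attr(gtree, "node_time"))
        t_root <- as.integer(round(design$prenatal_days * 24 /
                                   cfg$division_hours)) +
          max(gens - root_t, 0L)
        w <- design$model$window
        p0 <- branch_matrix(design$model, t_root)[w + 1L, ]
        shift <- sample(-w:w, M, replace = TRUE, prob = p0)
        geno <- sweep(geno, 2L, shift, "+")
        storage.mode(geno) <- "integer"
      }
      geno <- apply_missingness(geno, design$missingness)
      id <- paste0("crypt", ci)
      mo <- paste0("mouse", mi, "_day", age)
      study[[length(study) + 1L]] <-
        crypt_genotypes(geno, crypt = id, mouse = mo, age_days = age,
                        regime = reg)
      truth[[length(truth) + 1L]] <-
        list(mouse = mo, crypt = id,
             beta = design$beta[[mi]], age_days = age,
             genealogy = gtree, regime = reg)
    }
  }
  list(study = study, truth = truth, design = design)
}

#' Generate the reference two-age study bundle
#'
#' A ready-made synthetic twin of the motivating experiment: two mice
#' sampled at days 52 and 340, two colon crypts each with (6, 5) and
#' (5, 4) cells, per-mouse marker panels of 70-90 usable markers, and
#' generator truths beta = 0.76 (young, non-stationary regime) and
#' beta = 0 (old, stationary regime).
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return As [generate_dataset()].
#' @export
generate_two_age_study <- function(seed = 1L) {
  design <- study_design(ages = c(52, 340), beta = c(0.76, 0),
                         cells_per_crypt = matrix(c(6L, 5L, 5L, 4L),
                                                  nrow = 2, byrow = TRUE),
                         seed = seed)
  generate_dataset(design)
}
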