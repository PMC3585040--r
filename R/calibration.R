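#' Type-I calibration of the equal-beta likelihood-ratio test
#'
#' Simulates replicate two-age study pairs under the null (both age groups
#' share one true asymmetric fraction, stationary regime), runs
#' [lrt_equal_beta()] on each pair and reports the empirical rejection
#' rate at the nominal chi-square (1 df) level. With a correctly calibrated
#' test the rejection percentage matches the nominal level up to binomial
#' noise.
#'
#' @param replicates Number of simulated study pairs.
#' @param beta Shared true asymmetric fraction.
#' @param markers Usable markers per mouse panel.
#' @param cells Cells per crypt.
#' @param crypts_per_mouse Crypts per mouse.
#' @param k Monte-Carlo genealogies per likelihood evaluation.
#' @param grid Beta grid for the fits.
#' @param config A [crypt_config()].
#' @param model A [mutation_model()].
#' @param level Nominal test level.
#' @param seed Root seed (fans out one generation seed and one analysis
#'   seed per replicate).
#' @return A list with `rejection_percent`, `p_values`, `statistics` and
#'   `replicates`.
#' @export
lrt_type1_calibration <- function(replicates = 200L, beta = 0.4,
                                  markers = 20L, cells = 5L,
                                  crypts_per_mouse = 2L, k = 500L,
                                  grid = default_beta_grid(),
                                  config = crypt_config(),
                                  model = mutation_model(),
                                  level = 0.05, seed = 1L) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * replicates),
                  nrow = 2L)
  pv <- stat <- numeric(replicates)
  for (r in seq_len(replicates)) {
    design <- study_design(ages = c(52, 340), beta = beta,
                           crypts_per_mouse = crypts_per_mouse,
                           cells_per_crypt = cells, markers = markers,
                           missingness = 0, model = model, config = config,
                           seed = seeds[1L, r])
    ds <- generate_dataset(design, regime = "chain")
    mice <- vapply(ds$study, `[[`, "", "mouse")
    st <- likelihood_settings(k = k, source = "chain", seed = seeds[2L, r])
    res <- suppressWarnings(
      lrt_equal_beta(ds$study[mice == unique(mice)[1]],
                     ds$study[mice == unique(mice)[2]],
                     config, st, grid, model))
    pv[r] <- res$p_value
    stat[r] <- res$statistic
  }
  list(rejection_percent = 100 * mean(pv < level), p_values = pv,
       statistics = stat, replicates = replicates, level = level)
}
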