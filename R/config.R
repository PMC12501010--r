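#' Pipeline configuration
#'
#' Collects the tunable thresholds of the analysis in one validated list.
#' Defaults follow the published analysis conventions for hexaploid wheat:
#' 51-mer gene coverage, tau >= 0.8 for tissue specificity, a 0.8 maximal
#' expression share for calling a tandem array unbalanced, a normalized-count
#' total below 0.5 for calling an n-let not expressed, a module-divergence
#' threshold at 85% of the median of per-module maximum distances, and
#' co-expression edges at r > 0.8 with BH-adjusted p < 0.01.
#'
#' @param k k-mer length for coverage scans (odd, >= 11).
#' @param tau_threshold tau at or above which a gene is tissue-specific.
#' @param tandem_balance_cutoff maximal member share at or above which a
#'   tandem array is unbalanced.
#' @param not_expressed_cutoff normalized-count total below which a triad
#'   is NotExpressed.
#' @param divergence_fraction fraction of the median of per-module maximum
#'   distances defining the module-divergence threshold.
#' @param metamodule_k_range integer range of candidate metamodule counts.
#' @param coexpr_r_cutoff Pearson r cutoff for co-expression edges.
#' @param coexpr_p_cutoff BH-adjusted p cutoff for co-expression edges.
#' @param max_gap maximal number of intervening other-family genes inside
#'   a tandem array.
#' @param window,step coverage-track window and step sizes in bp.
#' @param coverage_threshold windowed mean coverage below which windows are
#'   introgression candidates.
#' @param rng_seed integer seed used by `run_pipeline()`.
#' @return A list of class `pantriad_config`.
#' @examples
#' cfg <- pipeline_config(tau_threshold = 0.8)
#' cfg$k
#' @export
pipeline_config <- function(k = 51L,
                            tau_threshold = 0.8,
                            tandem_balance_cutoff = 0.8,
                            not_expressed_cutoff = 0.5,
                            divergence_fraction = 0.85,
                            metamodule_k_range = 2:10,
                            coexpr_r_cutoff = 0.8,
                            coexpr_p_cutoff = 0.01,
                            max_gap = 1L,
                            window = 2e6,
                            step = 5e3,
                            coverage_threshold = 0.5,
                            rng_seed = 1L) {
  assert_that(is_count(k) && k >= 11 && k %% 2 == 1,
              "`k` must be an odd integer >= 11")
  check_fraction(tau_threshold, "tau_threshold")
  check_fraction(tandem_balance_cutoff, "tandem_balance_cutoff")
  check_fraction(divergence_fraction, "divergence_fraction")
  check_fraction(coexpr_r_cutoff, "coexpr_r_cutoff")
  check_fraction(coexpr_p_cutoff, "coexpr_p_cutoff")
  check_fraction(coverage_threshold, "coverage_threshold")
  assert_that(is.numeric(not_expressed_cutoff) && not_expressed_cutoff >= 0,
              "`not_expressed_cutoff` must be non-negative")
  assert_that(all(metamodule_k_range == as.integer(metamodule_k_range)) &&
                all(metamodule_k_range >= 2),
              "`metamodule_k_range` must be integers >= 2")
  assert_that(is_count(max_gap) && max_gap >= 0, "`max_gap` must be >= 0")
  assert_that(window > 0 && step > 0, "`window` and `step` must be positive")
  structure(list(k = as.integer(k),
                 tau_threshold = tau_threshold,
                 tandem_balance_cutoff = tandem_balance_cutoff,
                 not_expressed_cutoff = not_expressed_cutoff,
                 divergence_fraction = divergence_fraction,
                 metamodule_k_range = as.integer(metamodule_k_range),
                 coexpr_r_cutoff = coexpr_r_cutoff,
                 coexpr_p_cutoff = coexpr_p_cutoff,
                 max_gap = as.integer(max_gap),
                 window = window,
                 step = step,
                 coverage_threshold = coverage_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "pantriad_config")
}

#' @export
print.pantriad_config <- function(x, ...) {
  cat("<pantriad_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
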