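#' Reference primer-combination characteristics
#'
#' Marker counts and replicate scoring error rates for the seven
#' EcoRI/HpaII--MspI primer combinations of the reference MS-AFLP study of 60
#' clonal poplars, as shipped in `inst/extdata/primer_combo_summary.csv`.
#' Used as the default layout of the fragment-profile simulator and by the
#' summary arithmetic checks.
#'
#' @return A data frame with columns `combo` (1..7), `n_markers` (fragments in
#'   the 150--600 bp range), `error_rate` (replicate mismatch rate),
#'   `n_susceptible` and `n_polymorphic` (methylation-susceptible marker
#'   counts).
#' @export
primer_combo_reference <- function() {
  path <- system.file("extdata", "primer_combo_summary.csv",
                      package = "epiclonal")
  read.csv(path, stringsAsFactors = FALSE)
}

## invert a replicate mismatch rate m = 2e(1-e) to the per-band flip rate e
flip_from_mismatch <- function(m) {
  if (any(m < 0 | m > 0.5)) .stopf("mismatch rate must lie in [0, 0.5]")
  (1 - sqrt(1 - 2 * m)) / 2
}

#' Default cumulative link mixed model parameters for the bud-set simulator
#'
#' Thresholds and slopes on the latent logit scale for the 7-level bud-set
#' score (3, 2.5, ..., 0; six thresholds between consecutive levels). The
#' defaults place the D50% of an average donor near day-of-year 235 with a
#' transition width of a few weeks, a positive day slope (bud set progresses),
#' a mild carbon:nitrogen effect, donor and ramet random-intercept standard
#' deviations of realistic magnitude, and a site effect linear in January
#' temperature chosen so that warmer home sites set bud later.
#'
#' @param alpha six strictly increasing thresholds.
#' @param beta_day slope per day of year.
#' @param beta_cn slope per C:N unit.
#' @param site_tjan_slope latent-scale site coefficient per degree Celsius of
#'   mean January temperature (negative: warm origin delays bud set).
#' @param sigma_tree,sigma_ramet random-intercept standard deviations.
#' @return A named list of class `clmm_params`.
#' @export
clmm_params <- function(alpha = 36.45 + c(-4.5, -3, -1.5, 0, 1.5, 3),
                        beta_day = 0.15,
                        beta_cn = 0.1,
                        site_tjan_slope = -0.154,
                        sigma_tree = 0.8,
                        sigma_ramet = 0.5) {
  if (length(alpha) != 6L || any(diff(alpha) <= 0))
    .stopf("alpha must be six strictly increasing thresholds")
  if (sigma_tree < 0 || sigma_ramet < 0)
    .stopf("random-effect standard deviations must be non-negative")
  structure(list(alpha = alpha, beta_day = beta_day, beta_cn = beta_cn,
                 site_tjan_slope = site_tjan_slope,
                 sigma_tree = sigma_tree, sigma_ramet = sigma_ramet),
            class = "clmm_params")
}

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module. Defaults emulate the
#' reference study: 60 donor trees (20 sites x 3 trees) from climatically
#' contrasting European sites, seven MS-AFLP primer combinations with the
#' reference per-combination marker counts and replicate error rates, 14
#' replicated samples, 13 ramets per donor scored on six weekly late-summer
#' dates, and a ramet C:N ratio negatively correlated with cutting weight
#' (r = -0.504).
#'
#' @param n_sites number of home sites (>= 2).
#' @param trees_per_site donor trees sampled per site.
#' @param n_primer_combos number of EcoRI/HpaII--MspI primer combinations.
#' @param loci_per_combo integer vector (recycled to `n_primer_combos`) of
#'   fragment loci per combination.
#' @param error_rate_per_combo per-band flip probability e per combination
#'   (recycled). Two independent scorings of one band then mismatch with
#'   probability 2e(1-e). Defaults invert the reference replicate mismatch
#'   rates so simulated replicate error rates reproduce them in expectation.
#' @param meth_freq_range range of per-locus methylation frequencies for
#'   methylation-variable loci.
#' @param frac_low_meth fraction of loci that are essentially unmethylated
#'   (frequency drawn in \[0, 0.02\]), emulating the share of markers that do
#'   not pass the methylation-susceptibility threshold.
#' @param hemi_fraction fraction of methylated states that are hemimethylated
#'   (HpaII cuts, MspI does not) rather than internal-CG methylated.
#' @param double_absence_rate probability of the somatic double-absence latent
#'   state (restriction-site loss).
#' @param n_replicate_pairs number of replicated samples.
#' @param climate_effect logit shift of the methylation probability per degree
#'   Celsius of site January temperature (0 = climate-neutral methylation).
#' @param clmm_params parameters of the bud-set model, see [clmm_params()].
#' @param ramets_per_donor cuttings per donor tree in the common garden.
#' @param obs_days strictly increasing day-of-year observation dates.
#' @param cn_weight_corr correlation between ramet C:N ratio and cutting
#'   weight.
#' @param cn_mean,cn_sd,weight_mean,weight_sd marginal moments of the ramet
#'   C:N ratio and cutting weight (g).
#' @param ssr_n_loci number of SSR loci (two alleles scored per locus).
#' @param ssr_n_mutants samples carrying a single-allele somatic variant (one
#'   repeat unit off at one locus).
#' @param ssr_n_offspring samples with a distinct half-sib multilocus genotype
#'   sharing at least one allele per locus with the clone.
#' @param ssr_allele_error per-allele mis-scoring probability for replicates.
#' @param ssr_repeat_unit repeat-unit length in bp (dinucleotide default).
#' @param seed integer seed; all generator randomness flows from it through
#'   per-table sub-streams.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 20L,
                       trees_per_site = 3L,
                       n_primer_combos = 7L,
                       loci_per_combo = c(29L, 22L, 25L, 28L, 20L, 51L, 41L),
                       error_rate_per_combo =
                         flip_from_mismatch(c(0.029, 0, 0.024, 0.033,
                                              0.038, 0.044, 0.028)),
                       meth_freq_range = c(0.05, 0.40),
                       frac_low_meth = 0.55,
                       hemi_fraction = 0.3,
                       double_absence_rate = 0.003,
                       n_replicate_pairs = 14L,
                       climate_effect = 0,
                       clmm_params = epiclonal::clmm_params(),
                       ramets_per_donor = 13L,
                       obs_days = c(218L, 225L, 232L, 239L, 246L, 253L),
                       cn_weight_corr = -0.504,
                       cn_mean = 12, cn_sd = 2,
                       weight_mean = 15, weight_sd = 5,
                       ssr_n_loci = 11L,
                       ssr_n_mutants = 5L,
                       ssr_n_offspring = 0L,
                       ssr_allele_error = 0.0015,
                       ssr_repeat_unit = 2L,
                       seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              trees_per_site = as.integer(trees_per_site),
              n_primer_combos = as.integer(n_primer_combos),
              loci_per_combo =
                rep_len(as.integer(loci_per_combo), n_primer_combos),
              error_rate_per_combo =
                rep_len(error_rate_per_combo, n_primer_combos),
              meth_freq_range = meth_freq_range,
              frac_low_meth = frac_low_meth,
              hemi_fraction = hemi_fraction,
              double_absence_rate = double_absence_rate,
              n_replicate_pairs = as.integer(n_replicate_pairs),
              climate_effect = climate_effect,
              clmm_params = clmm_params,
              ramets_per_donor = as.integer(ramets_per_donor),
              obs_days = as.integer(obs_days),
              cn_weight_corr = cn_weight_corr,
              cn_mean = cn_mean, cn_sd = cn_sd,
              weight_mean = weight_mean, weight_sd = weight_sd,
              ssr_n_loci = as.integer(ssr_n_loci),
              ssr_n_mutants = as.integer(ssr_n_mutants),
              ssr_n_offspring = as.integer(ssr_n_offspring),
              ssr_allele_error = ssr_allele_error,
              ssr_repeat_unit = as.integer(ssr_repeat_unit),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$error_rate_per_combo, cfg$meth_freq_range,
             cfg$double_absence_rate, cfg$hemi_fraction, cfg$frac_low_meth,
             cfg$ssr_allele_error)
  if (any(probs < 0 | probs > 1))
    .stopf("all probabilities must lie in [0, 1]")
  counts <- c(cfg$n_sites, cfg$trees_per_site, cfg$n_primer_combos,
              cfg$loci_per_combo, cfg$ramets_per_donor, cfg$ssr_n_loci)
  if (any(counts < 1L)) .stopf("counts must be >= 1")
  if (cfg$n_sites < 2L) .stopf("n_sites must be >= 2")
  if (any(diff(cfg$obs_days) <= 0))
    .stopf("obs_days must be strictly increasing")
  if (abs(cfg$cn_weight_corr) > 1)
    .stopf("cn_weight_corr must lie in [-1, 1]")
  if (is.na(cfg$seed)) .stopf("seed must be a finite integer")
  invisible(cfg)
}
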