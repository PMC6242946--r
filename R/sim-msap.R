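#' Donor-tree layout implied by a configuration
#'
#' Deterministically assigns `trees_per_site` donor trees to each simulated
#' site.
#'
#' @param config a [sim_config()].
#' @param sites a climate table from [simulate_sites()].
#' @return data frame with `donor_id`, `site_id`, `country`.
#' @export
donor_table <- function(config, sites) {
  n_donors <- config$n_sites * config$trees_per_site
  site_ix <- rep(seq_len(config$n_sites), each = config$trees_per_site)
  data.frame(donor_id = sprintf("T%03d", seq_len(n_donors)),
             site_id = sites$site_id[site_ix],
             country = if ("country" %in% names(sites))
               sites$country[site_ix] else NA_character_,
             stringsAsFactors = FALSE)
}

## latent methylation state -> (HpaII, MspI) presence bits
## U unmethylated (1,1); I internal-CG methylated (0,1);
## H hemimethylated (1,0); A double absence (0,0)
state_to_bands <- function(state) {
  hpa <- ifelse(state %in% c("U", "H"), 1L, 0L)
  msp <- ifelse(state %in% c("U", "I"), 1L, 0L)
  cbind(hpaii = hpa, mspi = msp)
}

#' Simulate dual-enzyme MS-AFLP fragment profiles
#'
#' Draws, for every sample and locus, a latent methylation state
#' (unmethylated / internal-CG methylated / hemimethylated / double absence),
#' optionally with the methylation probability shifted on the logit scale by
#' the site's January temperature, maps states to HpaII/MspI presence
#' patterns, and applies independent per-band scoring flips with the
#' per-combination error rate. Designated replicate pairs re-score the same
#' latent states with independent flips. The latent truth is returned
#' alongside for validation.
#'
#' @param config a [sim_config()].
#' @param sites a climate table from [simulate_sites()].
#' @return A list of class `fragment_profile_set` with elements
#'   `profiles` (long data frame: `primer_combo_id`, `enzyme`, `sample_id`,
#'   `locus_id`, `size`, `present`, `replicate_of`), `truth` (long data
#'   frame of latent states per sample x locus), `loci` (locus metadata) and
#'   `donors` (donor layout).
#' @export
simulate_msap <- function(config, sites) {
  validate_sim_config(config)
  donors <- donor_table(config, sites)
  n_donors <- nrow(donors)
  if (config$n_replicate_pairs > n_donors)
    .stopf("n_replicate_pairs (%d) exceeds the number of samples (%d)",
           config$n_replicate_pairs, n_donors)
  set.seed(.substream(config$seed, "msap"))

  combo_id <- rep(seq_len(config$n_primer_combos), config$loci_per_combo)
  n_loci <- length(combo_id)
  loci <- data.frame(locus_id = sprintf("c%d_L%03d", combo_id,
                                        unlist(lapply(config$loci_per_combo,
                                                      seq_len))),
                     primer_combo_id = combo_id,
                     size = round(runif(n_loci, 150, 600), 2),
                     meth_freq = ifelse(
                       runif(n_loci) < config$frac_low_meth,
                       runif(n_loci, 0, 0.02),
                       runif(n_loci, config$meth_freq_range[1],
                             config$meth_freq_range[2])),
                     stringsAsFactors = FALSE)

  t_jan <- sites$t_jan[match(donors$site_id, sites$site_id)]
  dt_jan <- t_jan - mean(t_jan)

  ## latent states on the donor x locus grid
  grid <- expand.grid(donor = seq_len(n_donors), locus = seq_len(n_loci))
  p_meth <- plogis(qlogis(loci$meth_freq[grid$locus]) +
                     config$climate_effect * dt_jan[grid$donor])
  u <- runif(nrow(grid))
  state <- ifelse(u < config$double_absence_rate, "A",
                  ifelse(runif(nrow(grid)) < p_meth,
                         ifelse(runif(nrow(grid)) < config$hemi_fraction,
                                "H", "I"),
                         "U"))
  truth <- data.frame(sample_id = donors$donor_id[grid$donor],
                      locus_id = loci$locus_id[grid$locus],
                      state = state, stringsAsFactors = FALSE)

  rep_ix <- seq_len(config$n_replicate_pairs)
  score <- function(sample_ids, donor_ix, replicate_of) {
    g <- expand.grid(s = seq_along(sample_ids), locus = seq_len(n_loci))
    st <- state[(g$locus - 1L) * n_donors + donor_ix[g$s]]
    bands <- state_to_bands(st)
    e <- config$error_rate_per_combo[loci$primer_combo_id[g$locus]]
    flip <- function(b) ifelse(runif(length(b)) < e, 1L - b, b)
    data.frame(primer_combo_id = rep(loci$primer_combo_id[g$locus], 2L),
               enzyme = rep(c("HpaII", "MspI"), each = nrow(g)),
               sample_id = rep(sample_ids[g$s], 2L),
               locus_id = rep(loci$locus_id[g$locus], 2L),
               size = rep(loci$size[g$locus], 2L),
               present = c(flip(bands[, "hpaii"]), flip(bands[, "mspi"])),
               replicate_of = rep(replicate_of[g$s], 2L),
               stringsAsFactors = FALSE)
  }
  profiles <- rbind(
    score(donors$donor_id, seq_len(n_donors), rep(NA_character_, n_donors)),
    if (config$n_replicate_pairs > 0L)
      score(paste0(donors$donor_id[rep_ix], "rep"), rep_ix,
            donors$donor_id[rep_ix]))

  structure(list(profiles = profiles, truth = truth, loci = loci,
                 donors = donors),
            class = "fragment_profile_set")
}
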