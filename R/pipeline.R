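read_input <- function(x) {
  if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
}

#' Write all synthetic study tables as CSV
#'
#' Writes the four analysis inputs (fragment profiles, SSR genotypes,
#' climate/site table, bud-set observations) plus a truth CSV per simulated
#' table; missing values are encoded "NA", files are UTF-8
#' comma-separated with a header row.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_csvs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write.csv(sim$climate, p("climate.csv"), row.names = FALSE)
  write.csv(sim$msap$profiles, p("fragments.csv"), row.names = FALSE)
  write.csv(sim$msap$truth, p("fragments_truth.csv"), row.names = FALSE)
  write.csv(sim$ssr, p("ssr.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$budset), p("budset.csv"), row.names = FALSE)
  tr <- attr(sim$budset, "truth")
  write.csv(data.frame(donor_id = names(tr$u_tree), u_tree = tr$u_tree),
            p("budset_truth_donor.csv"), row.names = FALSE)
  invisible(vapply(c("climate.csv", "fragments.csv", "fragments_truth.csv",
                     "ssr.csv", "budset.csv", "budset_truth_donor.csv"),
                   p, character(1)))
}

#' Generate every input table of a synthetic study
#'
#' @param config a [sim_config()].
#' @return List with `climate`, `donors`, `msap` (fragment profile set with
#'   truth), `ssr`, `budset`.
#' @export
simulate_study <- function(config = sim_config()) {
  climate <- simulate_sites(config)
  list(climate = climate,
       donors = donor_table(config, climate),
       msap = simulate_msap(config, climate),
       ssr = simulate_ssr(config),
       budset = simulate_budset(config, climate))
}

#' Run the full analysis pipeline
#'
#' Chains SSR clone identification, MS-AFLP scoring (both double-absence
#' modes), epigenetic diversity and structure statistics, the bud-set
#' cumulative link mixed model with D50% derivation and climate
#' correlations, and per-epilocus association tests with FDR control.
#' Samples not identified as clone members are excluded after the SSR
#' stage. Deterministic given `seed`.
#'
#' @param fragments fragment profile CSV path or long data frame.
#' @param ssr SSR genotype CSV path or data frame.
#' @param climate climate/site CSV path or data frame (needs `country` when
#'   `groups = "country"`).
#' @param budset bud-set observation CSV path or long data frame.
#' @param donors data frame mapping `donor_id` to `site_id` (and `country`);
#'   defaults to the map implied by the bud-set table plus the climate
#'   table.
#' @param groups grouping column for the AMOVA (default `"country"`).
#' @param n_perm permutations for AMOVA and Mantel tests.
#' @param seed integer seed for all permutation streams.
#' @param q FDR level.
#' @param cn_ref reference C:N ratio for D50%.
#' @param output_dir optional directory; when given, stage outputs (CSV) and
#'   the report (JSON) are written there.
#' @return A `run_report` list with per-stage summaries.
#' @export
run_full <- function(fragments, ssr, climate, budset, donors = NULL,
                     groups = "country", n_perm = 999, seed = 1, q = 0.05,
                     cn_ref = 12, output_dir = NULL) {
  climate <- read_input(climate)
  budset_df <- read_input(budset)
  frag <- if (inherits(fragments, "fragment_profile_set")) fragments$profiles
  else read_input(fragments)
  ssr_df <- read_input(ssr)

  if (is.null(donors)) {
    donors <- unique(budset_df[c("donor_id", "site_id")])
    donors$country <- climate$country[match(donors$site_id,
                                            climate$site_id)]
  }

  ## --- SSR: clone membership and genotyping error ---
  mlg <- classify_clonemates(identify_mlgs(ssr_df))
  ssr_err <- genotyping_error_rate(ssr_df)
  clone_members <- mlg$sample_id[mlg$is_clone]

  ## --- MS-AFLP scoring, clone members only (plus their replicates) ---
  keep <- frag$sample_id %in% clone_members |
    (!is.na(frag$replicate_of) & frag$replicate_of %in% clone_members)
  scored <- msap_score(frag[keep, , drop = FALSE])

  ## --- diversity on polymorphic complete loci, double absence missing ---
  epi_div <- polymorphic_loci(drop_missing_loci(scored$epi_missing))
  shan <- shannon_index(epi_div)
  matches <- match_epigenotypes(epi_div)
  d_eu <- epi_distance(epi_div, squared = FALSE)
  d_sq <- epi_distance(epi_div, squared = TRUE)
  pc <- pcoa(d_eu)
  grp <- donors[[groups]][match(rownames(epi_div$states), donors$donor_id)]
  am <- amova(d_sq, grp, n_perm = n_perm, seed = .substream(seed, "perm"))
  geo <- geo_distance(data.frame(
    sample_id = rownames(epi_div$states),
    latitude = climate$latitude[match(
      donors$site_id[match(rownames(epi_div$states), donors$donor_id)],
      climate$site_id)],
    longitude = climate$longitude[match(
      donors$site_id[match(rownames(epi_div$states), donors$donor_id)],
      climate$site_id)]))
  mt <- mantel(d_eu, geo, n_perm = n_perm, seed = .substream(seed, "perm"))

  ## --- bud-set phenology ---
  bud <- budset_df[budset_df$donor_id %in% clone_members, , drop = FALSE]
  fit <- budset_clmm(bud)
  d50_tab <- d50(fit, cn_ref = cn_ref)
  clim_cor <- pearson_climate(d50_tab, climate)

  ## --- per-epilocus association tests ---
  epi0 <- polymorphic_loci(scored$epi_zero)
  glm_res <- adjust_associations(epilocus_glm(epi0, climate, donors), q = q)
  welch_res <- adjust_associations(welch_test(d50_tab, epi0), q = q)

  report <- list(
    config = list(groups = groups, n_perm = n_perm, seed = seed, q = q,
                  cn_ref = cn_ref),
    version = as.character(utils::packageVersion("epiclonal")),
    ssr = list(n_samples = nrow(mlg), n_mlgs = length(unique(mlg$mlg_id)),
               n_clone_members = length(clone_members),
               error_rate_pct = ssr_err$rate_pct),
    msap = list(summary = scored$summary,
                mean_error_rate = scored$error_rates$mean_rate,
                n_loci_total = sum(scored$summary$n_markers, na.rm = TRUE) / 2,
                n_susceptible = nrow(scored$epi_missing$loci),
                n_polymorphic = sum(scored$epi_missing$loci$is_polymorphic),
                n_polymorphic_zero_mode =
                  sum(scored$epi_zero$loci$is_polymorphic),
                n_missing_loci = sum(scored$epi_missing$loci$has_missing)),
    diversity = list(shannon_mean = shan$mean, shannon_sd = shan$sd,
                     n_epigenotype_groups = length(unique(matches$group)),
                     phi_st = am$phi_st, amova_p = am$p_value,
                     mantel_r = mt$r, mantel_r2 = mt$r_squared,
                     mantel_p = mt$p_value,
                     pcoa_pct_axis1 = pc$pct_variance[1]),
    phenology = list(alpha = fit$alpha, beta = fit$beta,
                     sigma_tree = fit$sigma_tree,
                     sigma_ramet = fit$sigma_ramet,
                     loglik = fit$loglik, converged = fit$converged,
                     d50 = d50_tab, climate_correlations = clim_cor),
    associations = list(
      glm = glm_res, welch = welch_res,
      n_glm_tests = sum(glm_res$estimable),
      n_glm_significant_raw = sum(glm_res$p_value <= 0.05, na.rm = TRUE),
      n_glm_loci_significant_raw =
        length(unique(glm_res$locus_id[!is.na(glm_res$p_value) &
                                         glm_res$p_value <= 0.05])),
      n_glm_significant_fdr = sum(glm_res$significant_at_q),
      n_welch_tests = nrow(welch_res),
      n_welch_significant_raw = sum(welch_res$p_value <= 0.05,
                                    na.rm = TRUE),
      n_welch_significant_fdr = sum(welch_res$significant_at_q)))
  class(report) <- c("run_report", "list")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(mlg, file.path(output_dir, "mlg.csv"), row.names = FALSE)
    write.csv(cbind(sample_id = rownames(epi_div$states),
                    as.data.frame(epi_div$states)),
              file.path(output_dir, "epigenotypes.csv"), row.names = FALSE)
    write.csv(as.data.frame(pc$coordinates),
              file.path(output_dir, "pcoa.csv"))
    write.csv(d50_tab, file.path(output_dir, "d50.csv"), row.names = FALSE)
    write.csv(glm_res, file.path(output_dir, "associations_glm.csv"),
              row.names = FALSE)
    write.csv(welch_res, file.path(output_dir, "associations_welch.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## flatten data frames so the report serializes cleanly
report_to_json <- function(report) {
  rapply(unclass(report), function(x)
    if (is.data.frame(x)) as.list(x) else x,
    classes = "ANY", how = "replace")
}

#' Simulate a study and run the full pipeline with truth diagnostics
#'
#' Generates every input with [simulate_study()], runs [run_full()], and
#' appends truth-versus-estimate diagnostics: methylation-state recovery of
#' the scored epilocus matrix, bud-set model parameter recovery, and the
#' realized C:N--weight correlation.
#'
#' @param config a [sim_config()].
#' @param ... passed to [run_full()].
#' @return A `run_report` with an extra `truth` element.
#' @export
run_synthetic <- function(config = sim_config(), ...) {
  sim <- simulate_study(config)
  report <- run_full(fragments = sim$msap, ssr = sim$ssr,
                     climate = sim$climate, budset = sim$budset,
                     donors = sim$donors, seed = config$seed, ...)

  report$truth <- list(
    state_recovery = state_recovery(sim$msap, config),
    clmm = clmm_recovery(sim, report),
    cn_weight_corr = cor(unique(as.data.frame(
      sim$budset)[c("ramet_id", "cn", "weight")])$cn,
      unique(as.data.frame(sim$budset)[c("ramet_id", "cn", "weight")])$weight))
  report
}

## fraction of scored epilocus states equal to the latent truth
## (double-absence truth entries are excluded: their binary state is
## undefined under the missing-data scoring rule)
state_recovery <- function(msap_sim, config, epi = NULL) {
  if (is.null(epi)) {
    scored <- msap_score(msap_sim)
    epi <- scored$epi_missing
  }
  truth <- msap_sim$truth
  true_bin <- c(U = 0, I = 1, H = 1, A = NA)[truth$state]
  ix_s <- match(truth$sample_id, rownames(epi$states))
  ix_l <- match(truth$locus_id, colnames(epi$states))
  ok <- !is.na(ix_s) & !is.na(ix_l) & !is.na(true_bin)
  est <- epi$states[cbind(ix_s[ok], ix_l[ok])]
  list(rate = mean(est == true_bin[ok], na.rm = TRUE),
       n_compared = sum(!is.na(est)))
}

clmm_recovery <- function(sim, report) {
  pars <- attr(sim$budset, "truth")$params
  est_beta <- report$phenology$beta
  list(beta_day = c(true = pars$beta_day, est = unname(est_beta[["day"]])),
       beta_cn = c(true = pars$beta_cn, est = unname(est_beta[["cn"]])),
       sigma_tree = c(true = pars$sigma_tree,
                      est = report$phenology$sigma_tree),
       sigma_ramet = c(true = pars$sigma_ramet,
                       est = report$phenology$sigma_ramet))
}

#' @export
print.run_report <- function(x, ...) {
  cat("epiclonal pipeline report\n")
  cat(sprintf("  SSR: %d samples, %d MLGs, %d clone members, error %.3f%%\n",
              x$ssr$n_samples, x$ssr$n_mlgs, x$ssr$n_clone_members,
              x$ssr$error_rate_pct))
  cat(sprintf("  MSAP: %d loci, %d susceptible, %d polymorphic, mean error %.3f\n",
              x$msap$n_loci_total, x$msap$n_susceptible,
              x$msap$n_polymorphic, x$msap$mean_error_rate))
  cat(sprintf("  Diversity: Shannon %.3f (SD %.3f); Phi_ST %.3f (p %.3f); Mantel r2 %.3f (p %.3f)\n",
              x$diversity$shannon_mean, x$diversity$shannon_sd,
              x$diversity$phi_st, x$diversity$amova_p,
              x$diversity$mantel_r2, x$diversity$mantel_p))
  cc <- x$phenology$climate_correlations
  cat(sprintf("  Phenology: beta_day %.3f, sigma_tree %.3f, sigma_ramet %.3f; D50-t_jan r %.3f (p %.3g)\n",
              x$phenology$beta["day"], x$phenology$sigma_tree,
              x$phenology$sigma_ramet,
              cc$r[cc$variable == "t_jan"], cc$p_value[cc$variable == "t_jan"]))
  cat(sprintf("  Associations: %d/%d glm tests significant raw, %d after FDR; %d/%d Welch, %d after FDR\n",
              x$associations$n_glm_significant_raw,
              x$associations$n_glm_tests,
              x$associations$n_glm_significant_fdr,
              x$associations$n_welch_significant_raw,
              x$associations$n_welch_tests,
              x$associations$n_welch_significant_fdr))
  invisible(x)
}
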