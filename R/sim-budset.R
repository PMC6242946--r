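## ordered bud-set score labels, most advanced growth first
budset_levels <- function() c(3, 2.5, 2, 1.5, 1, 0.5, 0)

## per-category probabilities of the cumulative logit model:
## P(Y in first j categories) = plogis(alpha_j - lp)
cumlogit_cat_probs <- function(alpha, lp) {
  cum <- plogis(outer(lp, alpha, function(l, a) a - l))
  cbind(cum, 1)[, seq_len(length(alpha) + 1L), drop = FALSE] -
    cbind(0, cum)
}

## site fixed effects on the latent scale, linear in January temperature
site_effects <- function(config, sites) {
  b <- config$clmm_params$site_tjan_slope * (sites$t_jan - mean(sites$t_jan))
  setNames(b, sites$site_id)
}

#' Simulate longitudinal ordinal bud-set observations
#'
#' Draws, per ramet and observation day, a 7-level ordinal bud-set score
#' (3 = growing apical meristem down to 0 = fully developed bud, 0.5 steps)
#' from a cumulative logit model with a day slope, a site fixed effect linear
#' in the site's mean January temperature, a ramet-level carbon:nitrogen
#' covariate, and donor and ramet random intercepts. C:N is drawn jointly
#' with cutting weight at the configured correlation.
#'
#' @param config a [sim_config()]; `config$clmm_params` holds thresholds,
#'   slopes and random-effect standard deviations.
#' @param sites a climate table from [simulate_sites()].
#' @return A long data frame of class `budset_observations` with columns
#'   `ramet_id`, `donor_id`, `site_id`, `day`, `cn`, `weight`, `score`, and a
#'   `"truth"` attribute (donor and ramet random intercepts and per-site
#'   effects used in the draw).
#' @export
simulate_budset <- function(config, sites) {
  validate_sim_config(config)
  pars <- config$clmm_params
  if (any(diff(pars$alpha) <= 0))
    .stopf("clmm thresholds must be strictly increasing")
  set.seed(.substream(config$seed, "budset"))

  donors <- donor_table(config, sites)
  n_donors <- nrow(donors)
  n_ramets <- n_donors * config$ramets_per_donor
  ramet_donor <- rep(seq_len(n_donors), each = config$ramets_per_donor)
  ramet_id <- sprintf("%s_R%02d", donors$donor_id[ramet_donor],
                      rep(seq_len(config$ramets_per_donor), times = n_donors))

  ## C:N jointly normal with cutting weight at the configured correlation
  z1 <- rnorm(n_ramets); z2 <- rnorm(n_ramets)
  rho <- config$cn_weight_corr
  cn <- config$cn_mean + config$cn_sd * z1
  weight <- config$weight_mean +
    config$weight_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

  u_tree <- rnorm(n_donors, 0, pars$sigma_tree)
  u_ramet <- rnorm(n_ramets, 0, pars$sigma_ramet)
  beta_s <- site_effects(config, sites)

  days <- config$obs_days
  obs <- data.frame(
    ramet_id = rep(ramet_id, each = length(days)),
    donor_id = rep(donors$donor_id[ramet_donor], each = length(days)),
    site_id = rep(donors$site_id[ramet_donor], each = length(days)),
    day = rep(days, times = n_ramets),
    cn = rep(cn, each = length(days)),
    weight = rep(weight, each = length(days)),
    stringsAsFactors = FALSE)

  lp <- pars$beta_day * obs$day + beta_s[obs$site_id] +
    pars$beta_cn * obs$cn +
    rep(u_tree[ramet_donor] + u_ramet, each = length(days))
  cum <- plogis(outer(lp, pars$alpha, function(l, a) a - l))
  k <- 1L + rowSums(runif(nrow(obs)) > cum)
  obs$score <- budset_levels()[k]

  attr(obs, "truth") <- list(u_tree = setNames(u_tree, donors$donor_id),
                             u_ramet = setNames(u_ramet, ramet_id),
                             beta_site = beta_s, params = pars)
  class(obs) <- c("budset_observations", "data.frame")
  obs
}
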