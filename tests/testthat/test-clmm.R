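small_budset <- function(seed = 19, pars = clmm_params(),
                         n_sites = 2, trees = 5, ramets = 4) {
  cfg <- sim_config(seed = seed, n_sites = n_sites, trees_per_site = trees,
                    ramets_per_donor = ramets, clmm_params = pars,
                    ssr_n_mutants = 1)
  simulate_budset(cfg, simulate_sites(cfg))
}

test_that("without random effects the fit matches direct likelihood maximization", {
  obs <- small_budset(seed = 19,
                      pars = clmm_params(sigma_tree = 0, sigma_ramet = 0),
                      trees = 8, ramets = 5)
  fit <- budset_clmm(obs, sigma_tree = 0, sigma_ramet = 0)
  oracle <- polr_oracle(obs)
  expect_equal(unname(fit$alpha), oracle$alpha, tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-4)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  ## and the established proportional-odds fitter agrees
  skip_if_not_installed("MASS")
  lv <- c(3, 2.5, 2, 1.5, 1, 0.5, 0)
  pf <- MASS::polr(factor(score, levels = lv[lv %in% unique(obs$score)]) ~
                     day + cn + site_id, data = obs, method = "logistic")
  expect_equal(unname(fit$beta[c("day", "cn")]),
               unname(coef(pf)[c("day", "cn")]), tolerance = 1e-2)
})

test_that("Laplace log-likelihood matches exhaustive quadrature on a toy", {
  obs <- toy_budset(n_donors = 3, n_ramets = 2, days = c(230, 244),
                    seed = 42)
  fit <- budset_clmm(obs, sigma_tree = 0.8, sigma_ramet = 0.5)
  ll_quad <- quad_loglik(unname(fit$alpha), fit$beta[["day"]],
                         fit$beta[["cn"]], fit$beta_site,
                         sigma_t = 0.8, sigma_r = 0.5, data = obs,
                         n_nodes = 25)
  expect_lt(abs(fit$loglik - ll_quad), 0.1)
})

test_that("binary single-day data reduce to mixed logistic regression", {
  skip_if_not_installed("lme4")
  ## two categories only: scores 3 and 0, one observation day
  set.seed(77)
  n_d <- 40; n_r <- 8
  donor <- rep(sprintf("T%02d", 1:n_d), each = n_r)
  u <- rep(rnorm(n_d, 0, 0.9), each = n_r)
  cn <- rnorm(n_d * n_r, 12, 2)
  lp <- 0.25 * (cn - 12) + u
  y <- rbinom(n_d * n_r, 1, plogis(-lp))   # P(first category {3}) = plogis(-lp)
  obs <- data.frame(ramet_id = sprintf("R%03d", seq_along(y)),
                    donor_id = donor, site_id = "S01", day = 230,
                    cn = cn, score = ifelse(y == 1, 3, 0))
  fit <- budset_clmm(obs, sigma_ramet = 0)
  gl <- lme4::glmer(y ~ cn + (1 | donor), family = binomial,
                    data = data.frame(y = y, cn = cn, donor = donor))
  ## logit P(score = 3) = alpha_1 - beta_cn * cn - u, so the logistic slope
  ## is -beta_cn and its intercept is alpha_1
  expect_equal(fit$beta[["cn"]], -unname(lme4::fixef(gl)["cn"]),
               tolerance = 2e-2)
  expect_equal(fit$sigma_tree,
               sqrt(unname(lme4::VarCorr(gl)$donor[1])), tolerance = 2e-2)
  expect_equal(unname(fit$alpha[1]), unname(lme4::fixef(gl)[1]),
               tolerance = 5e-2)
})

test_that("the likelihood is invariant to row order and relabeling", {
  obs <- small_budset(seed = 23, trees = 4, ramets = 3)
  fit1 <- budset_clmm(obs)
  shuffled <- obs[sample(nrow(obs)), ]
  fit2 <- budset_clmm(shuffled)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
  expect_equal(fit2$beta, fit1$beta, tolerance = 5e-4)
  relab <- obs
  relab$donor_id <- chartr("T", "Z", relab$donor_id)
  relab$ramet_id <- chartr("T", "Z", relab$ramet_id)
  fit3 <- budset_clmm(relab)
  expect_equal(fit3$loglik, fit1$loglik, tolerance = 1e-6)
})

test_that("category probabilities are coherent and collapse to the closed form", {
  obs <- small_budset(seed = 29, trees = 4, ramets = 3)
  fit <- budset_clmm(obs)
  pr <- category_probabilities(fit, day = c(220, 240), site = "S01",
                               cn = 12)
  expect_equal(rowSums(pr), c(1, 1))
  expect_true(all(pr >= 0))
  ## cumulative probability over {3, 2.5, 2, 1.5} equals the threshold logit
  j <- sum(fit$labels >= 1.5)
  lp <- fit$beta[["day"]] * 220 + fit$beta[["cn"]] * 12
  expect_equal(sum(pr[1, 1:4]), plogis(unname(fit$alpha[j]) - lp),
               tolerance = 1e-10)
  ## day slope sign convention: later days move mass to later phenophases
  expect_lt(sum(pr[2, 1:4]), sum(pr[1, 1:4]))
})

test_that("degenerate inputs are rejected or collapsed with a warning", {
  obs <- small_budset(seed = 31, trees = 3, ramets = 2)
  one_cat <- obs; one_cat$score <- 2
  expect_error(budset_clmm(one_cat), "two observed categories")
  few <- obs; few$score <- ifelse(few$score >= 1.5, 2, 0)
  expect_warning(fit <- budset_clmm(few, sigma_tree = 0, sigma_ramet = 0),
                 "collapsing")
  expect_equal(length(fit$alpha), 1L)
})
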