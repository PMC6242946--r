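# Independent oracles used to check package computations.

## Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2))
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ]^2 * sqrt(pi))[ord])
}

## marginal log-likelihood of the bud-set model by exhaustive nested
## quadrature (donor integral outer, ramet integrals inner)
quad_loglik <- function(alpha, beta_day, beta_cn, beta_site, sigma_t,
                        sigma_r, data, n_nodes = 25) {
  lv <- c(3, 2.5, 2, 1.5, 1, 0.5, 0)
  labels <- lv[lv %in% unique(data$score)]
  k <- match(data$score, labels)
  alpha_ext <- c(-Inf, alpha, Inf)
  lpf <- beta_day * data$day + beta_cn * data$cn +
    beta_site[as.character(data$site_id)]
  p_obs <- function(shift) {
    plogis(alpha_ext[k + 1L] - (lpf + shift)) -
      plogis(alpha_ext[k] - (lpf + shift))
  }
  gh <- gauss_hermite(n_nodes)
  tn <- if (sigma_t > 0) sqrt(2) * sigma_t * gh$nodes else 0
  tw <- if (sigma_t > 0) gh$weights / sqrt(pi) else 1
  rn <- if (sigma_r > 0) sqrt(2) * sigma_r * gh$nodes else 0
  rw <- if (sigma_r > 0) gh$weights / sqrt(pi) else 1
  ll <- 0
  for (d in unique(data$donor_id)) {
    rows_d <- which(data$donor_id == d)
    Ld <- 0
    for (i in seq_along(tn)) {
      prod_r <- 1
      for (r in unique(data$ramet_id[rows_d])) {
        rows_r <- rows_d[data$ramet_id[rows_d] == r]
        Ir <- 0
        for (j in seq_along(rn)) {
          pv <- p_obs(tn[i] + rn[j])[rows_r]
          Ir <- Ir + rw[j] * prod(pv)
        }
        prod_r <- prod_r * Ir
      }
      Ld <- Ld + tw[i] * prod_r
    }
    ll <- ll + log(Ld)
  }
  ll
}

## fixed-effects cumulative logit log-likelihood, coded independently of the
## package (direct likelihood maximization oracle)
polr_oracle <- function(data) {
  lv <- c(3, 2.5, 2, 1.5, 1, 0.5, 0)
  labels <- lv[lv %in% unique(data$score)]
  k <- match(data$score, labels)
  K <- length(labels)
  site_lv <- sort(unique(as.character(data$site_id)))
  Xs <- outer(as.character(data$site_id), site_lv[-1], "==") * 1
  X <- cbind(data$day - mean(data$day), data$cn - mean(data$cn), Xs)
  nb <- ncol(X)
  nll <- function(th) {
    alpha <- th[1] + c(0, cumsum(exp(th[2:(K - 1)])))
    if (K == 2) alpha <- th[1]
    lp <- as.vector(X %*% th[(K - 1) + seq_len(nb)])
    ae <- c(-Inf, alpha, Inf)
    p <- plogis(ae[k + 1L] - lp) - plogis(ae[k] - lp)
    -sum(log(pmax(p, 1e-300)))
  }
  cum <- cumsum(tabulate(k, K) / length(k))[seq_len(K - 1)]
  a0 <- qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  th0 <- c(a0[1], if (K > 2) log(pmax(diff(a0), 1e-3)), rep(0, nb))
  o <- optim(th0, nll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  alpha <- o$par[1] + c(0, cumsum(exp(o$par[2:(K - 1)])))
  if (K == 2) alpha <- o$par[1]
  beta <- o$par[(K - 1) + seq_len(nb)]
  list(alpha = alpha + beta[1] * mean(data$day) + beta[2] * mean(data$cn),
       beta = beta, loglik = -o$value)
}

## Newton-Raphson simple logistic regression slope oracle
nr_logistic_slope <- function(y, x) {
  b <- c(0, 0)
  X <- cbind(1, x)
  for (i in 1:50) {
    p <- plogis(as.vector(X %*% b))
    w <- p * (1 - p)
    g <- crossprod(X, y - p)
    H <- crossprod(X * w, X)
    step <- solve(H, g)
    b <- b + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  b[2]
}

## AMOVA variance components from raw coordinates (centroid-based ANOVA),
## independent of the pairwise-distance formulation
amova_from_coords <- function(coords, groups) {
  n <- nrow(coords)
  gs <- split(seq_len(n), groups)
  centr <- colMeans(coords)
  ss_total <- sum(sweep(coords, 2, centr)^2)
  ss_within <- sum(vapply(gs, function(ix) {
    cg <- colMeans(coords[ix, , drop = FALSE])
    sum(sweep(coords[ix, , drop = FALSE], 2, cg)^2)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  g <- length(gs)
  sizes <- lengths(gs)
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  s2w <- ss_within / (n - g)
  s2a <- (ss_among / (g - 1) - s2w) / n0
  list(phi_st = s2a / (s2a + s2w), sigma2_among = s2a, sigma2_within = s2w,
       ss_among = ss_among, ss_within = ss_within)
}

## tiny deterministic bud-set data set built by hand
toy_budset <- function(n_donors = 3, n_ramets = 2, days = c(230, 244),
                       seed = 42, params = clmm_params()) {
  cfg <- sim_config(n_sites = n_donors, trees_per_site = 1,
                    ramets_per_donor = n_ramets, obs_days = days,
                    clmm_params = params, ssr_n_mutants = 0, seed = seed)
  sites <- simulate_sites(cfg)
  sites$site_id[] <- "S01"   # one site: no site fixed effects
  simulate_budset(cfg, sites)
}
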