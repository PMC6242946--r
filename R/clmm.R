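## segment sums: x summed over contiguous groups whose last indices are
## `ends` (observations must be pre-sorted by group)
.segsum <- function(x, ends) {
  s <- cumsum(x)[ends]
  c(s[1L], diff(s))
}

## inlined logistic; exp overflow maps cleanly to 0/1 in the tails
.ilogis <- function(x) 1 / (1 + exp(-x))

## per-observation ingredients of the cumulative logit likelihood and its
## first two derivatives with respect to the linear predictor
.cumlogit_terms <- function(alpha_ext, k, lp) {
  f_hi <- .ilogis(alpha_ext[k + 1L] - lp)
  f_lo <- .ilogis(alpha_ext[k] - lp)
  p <- pmax(f_hi - f_lo, 1e-12)
  d_hi <- f_hi * (1 - f_hi); d_lo <- f_lo * (1 - f_lo)
  g1 <- -(d_hi - d_lo) / p
  dp_hi <- d_hi * (1 - 2 * f_hi); dp_lo <- d_lo * (1 - 2 * f_lo)
  g2 <- (dp_hi - dp_lo) / p - g1^2
  list(logp = log(p), g1 = g1, g2 = g2)
}

## Laplace-approximated marginal log-likelihood for one parameter vector.
## env caches the random-effect modes between calls (warm starts).
.laplace_loglik <- function(alpha, lp_fixed, sigma_t, sigma_r, dat, env,
                            tol = 1e-9, max_iter = 60L) {
  k <- dat$k
  alpha_ext <- c(-Inf, alpha, Inf)
  has_t <- sigma_t > 0; has_r <- sigma_r > 0
  nT <- dat$n_tree; nR <- dat$n_ramet
  uT <- if (has_t) env$uT else numeric(nT)
  uR <- if (has_r) env$uR else numeric(nR)

  pen <- function(uT, uR) {
    lp <- lp_fixed + uT[dat$tree] + uR[dat$ramet]
    ct <- .cumlogit_terms(alpha_ext, k, lp)
    h <- sum(ct$logp) -
      (if (has_t) sum(uT^2) / (2 * sigma_t^2) else 0) -
      (if (has_r) sum(uR^2) / (2 * sigma_r^2) else 0)
    list(h = h, ct = ct)
  }

  cur <- pen(uT, uR)
  if (has_t || has_r) {
    for (it in seq_len(max_iter)) {
      g1 <- cur$ct$g1; g2 <- cur$ct$g2
      gT <- if (has_t) .segsum(g1, dat$tree_ends) - uT / sigma_t^2 else NULL
      gR <- if (has_r) .segsum(g1, dat$ramet_ends) - uR / sigma_r^2 else NULL
      gmax <- max(abs(c(gT, gR)), 0)
      if (gmax < tol) break
      if (has_t && has_r) {
        sum_r <- .segsum(g2, dat$ramet_ends)
        Arr <- -(sum_r - 1 / sigma_r^2)
        Atr <- -sum_r
        Att <- -( .segsum(g2, dat$tree_ends) - 1 / sigma_t^2)
        w <- Atr / Arr
        s <- Att - .segsum(Atr * w, dat$rtree_ends)
        rhs <- gT - .segsum(w * gR, dat$rtree_ends)
        dT <- rhs / s
        dR <- (gR - Atr * dT[dat$tree_of_ramet]) / Arr
      } else if (has_t) {
        Att <- -( .segsum(g2, dat$tree_ends) - 1 / sigma_t^2)
        dT <- gT / Att; dR <- numeric(0)
      } else {
        Arr <- -( .segsum(g2, dat$ramet_ends) - 1 / sigma_r^2)
        dR <- gR / Arr; dT <- numeric(0)
      }
      step <- 1
      repeat {
        uT_new <- if (has_t) uT + step * dT else uT
        uR_new <- if (has_r) uR + step * dR else uR
        cand <- pen(uT_new, uR_new)
        if (is.finite(cand$h) && cand$h >= cur$h - 1e-12) break
        step <- step / 2
        if (step < 1e-10) { cand <- cur; uT_new <- uT; uR_new <- uR; break }
      }
      uT <- uT_new; uR <- uR_new; cur <- cand
    }
  }

  ## log-determinant of minus the penalized Hessian at the mode
  g2 <- cur$ct$g2
  logdet <- 0
  if (has_t && has_r) {
    sum_r <- .segsum(g2, dat$ramet_ends)
    Arr <- -(sum_r - 1 / sigma_r^2)
    Atr <- -sum_r
    Att <- -( .segsum(g2, dat$tree_ends) - 1 / sigma_t^2)
    s <- Att - .segsum(Atr^2 / Arr, dat$rtree_ends)
    if (any(s <= 0) || any(Arr <= 0)) return(list(ll = -Inf))
    logdet <- sum(log(s)) + sum(log(Arr))
  } else if (has_t) {
    Att <- -( .segsum(g2, dat$tree_ends) - 1 / sigma_t^2)
    if (any(Att <= 0)) return(list(ll = -Inf))
    logdet <- sum(log(Att))
  } else if (has_r) {
    Arr <- -( .segsum(g2, dat$ramet_ends) - 1 / sigma_r^2)
    if (any(Arr <= 0)) return(list(ll = -Inf))
    logdet <- sum(log(Arr))
  }

  ll <- cur$h -
    (if (has_t) nT * log(sigma_t) else 0) -
    (if (has_r) nR * log(sigma_r) else 0) -
    0.5 * logdet
  if (has_t) env$uT <- uT
  if (has_r) env$uR <- uR
  list(ll = ll, uT = uT, uR = uR)
}

#' Fit a cumulative link mixed model to ordinal bud-set scores
#'
#' Proportional-odds model on the 7-level bud-set score ordered from 3
#' (growing apical meristem) to 0 (fully developed bud):
#' \deqn{\mathrm{logit}\, P(Bs \le_j) = \alpha_j - \beta_D D - \beta_S S -
#'   \beta_{CN} CN - u_{TID} - u_{RID}}
#' where the "first j categories" are the least-advanced scores, D is day of
#' year, S the home site of the donor (fixed, reference = alphabetically
#' first site), CN the ramet carbon:nitrogen ratio, and donor (TID) and
#' ramet (RID) random intercepts are normal with standard deviations
#' `sigma_tree` and `sigma_ramet`, ramets nested in donors. The marginal
#' likelihood is maximized with a Laplace approximation that exploits the
#' nested block structure (one arrowhead system per donor); thresholds are
#' parameterized as alpha_1 plus cumulated exponentials so they stay
#' strictly increasing, and standard deviations on the log scale. Gradients
#' are central finite differences (step 1e-5); convergence requires a
#' gradient max-norm below 1e-4.
#'
#' @param data long data frame with columns `ramet_id`, `donor_id`,
#'   `site_id`, `day`, `cn`, `score` (see [simulate_budset()]).
#' @param sigma_tree,sigma_ramet `NULL` to estimate (default) or a fixed
#'   non-negative value (0 removes the random term; with both 0 the model
#'   collapses to a plain cumulative logit regression).
#' @param control list: `grad_step` (1e-5), `grad_tol` (1e-4), `iter_max`
#'   (400).
#' @return Object of class `budset_clmm` with components `alpha`
#'   (thresholds, one per boundary between observed categories),
#'   `beta` (named: `day`, `cn`, site contrasts), `sigma_tree`,
#'   `sigma_ramet`, `ranef_tree`, `ranef_ramet` (predicted modes), `loglik`,
#'   `converged`, `method`, plus bookkeeping used by [d50()] and
#'   [category_probabilities()].
#' @seealso [d50()], [category_probabilities()], [simulate_budset()]
#' @export
budset_clmm <- function(data, sigma_tree = NULL, sigma_ramet = NULL,
                        control = list()) {
  ctl <- modifyList(list(grad_step = 1e-5, grad_tol = 1e-4, iter_max = 400L),
                    control)
  need <- c("ramet_id", "donor_id", "site_id", "day", "cn", "score")
  miss <- setdiff(need, names(data))
  if (length(miss)) .stopf("data lacks columns: %s",
                           paste(miss, collapse = ", "))
  ## observations sorted by (donor, ramet) so random-effect sums are
  ## contiguous segment sums; likelihood is invariant to the original order
  data <- as.data.frame(data)[order(as.character(data$donor_id),
                                    as.character(data$ramet_id)), ,
                              drop = FALSE]
  map <- unique(data[c("ramet_id", "donor_id", "site_id")])
  if (anyDuplicated(map$ramet_id))
    .stopf("each ramet must map to exactly one donor and site")

  lv_all <- budset_levels()
  labels <- lv_all[lv_all %in% unique(data$score)]
  if (length(labels) < 2L) .stopf("need at least two observed categories")
  if (length(labels) < length(lv_all))
    .warnf("collapsing %d empty score categories",
           length(lv_all) - length(labels))
  k <- match(data$score, labels)
  K <- length(labels)

  donor_site <- unique(data[c("donor_id", "site_id")])
  single <- names(which(table(donor_site$site_id) == 1))
  if (length(single))
    .warnf("site(s) with a single donor (site effect confounded): %s",
           paste(single, collapse = ", "))

  site_lv <- sort(unique(as.character(data$site_id)))
  Xs <- outer(as.character(data$site_id), site_lv[-1], "==") * 1
  ## day and cn are centered internally for optimizer conditioning; the
  ## reported thresholds are shifted back to the raw day-of-year scale
  day_bar <- mean(data$day); cn_bar <- mean(data$cn)
  X <- cbind(day = data$day - day_bar, cn = data$cn - cn_bar, Xs)
  site_names <- if (length(site_lv) > 1L) paste0("site", site_lv[-1])
  else character(0)
  colnames(X) <- c("day", "cn", site_names)

  tree_lv <- unique(as.character(data$donor_id))    # sorted by construction
  ramet_lv <- unique(as.character(data$ramet_id))   # grouped by donor
  dat <- list(k = k,
              tree = match(as.character(data$donor_id), tree_lv),
              ramet = match(as.character(data$ramet_id), ramet_lv),
              n_tree = length(tree_lv), n_ramet = length(ramet_lv))
  dat$tree_of_ramet <- dat$tree[match(ramet_lv, as.character(data$ramet_id))]
  dat$tree_ends <- cumsum(tabulate(dat$tree, dat$n_tree))
  dat$ramet_ends <- cumsum(tabulate(dat$ramet, dat$n_ramet))
  dat$rtree_ends <- cumsum(tabulate(dat$tree_of_ramet, dat$n_tree))

  est_t <- is.null(sigma_tree); est_r <- is.null(sigma_ramet)
  fix_t <- if (est_t) NA_real_ else sigma_tree
  fix_r <- if (est_r) NA_real_ else sigma_ramet
  np_beta <- ncol(X)

  env <- new.env()
  env$uT <- numeric(dat$n_tree); env$uR <- numeric(dat$n_ramet)

  unpack <- function(theta) {
    alpha <- theta[1] + c(0, cumsum(exp(theta[2:(K - 1)])))
    if (K == 2L) alpha <- theta[1]
    beta <- theta[(K - 1) + seq_len(np_beta)]
    i <- K - 1 + np_beta
    clamp <- function(x) exp(pmin(pmax(x, log(1e-4)), log(20)))
    st <- if (est_t) clamp(theta[i + 1]) else fix_t
    sr <- if (est_r) clamp(theta[i + est_t + 1]) else fix_r
    list(alpha = alpha, beta = beta, sigma_t = st, sigma_r = sr)
  }
  negll <- function(theta) {
    p <- unpack(theta)
    ll <- .laplace_loglik(p$alpha, as.vector(X %*% p$beta),
                          p$sigma_t, p$sigma_r, dat, env)$ll
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  numgrad <- function(theta) {
    h <- ctl$grad_step
    vapply(seq_along(theta), function(j) {
      tp <- tm <- theta; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (negll(tp) - negll(tm)) / (2 * h)
    }, numeric(1))
  }

  ## starting values: empirical cumulative logits, slopes 0, sigma 0.5
  cum <- cumsum(tabulate(k, K) / length(k))[seq_len(K - 1)]
  alpha0 <- qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  theta0 <- c(alpha0[1], if (K > 2) log(pmax(diff(alpha0), 1e-3)),
              rep(0, np_beta),
              if (est_t) log(0.5), if (est_r) log(0.5))

  ## pre-optimize fixed effects without random terms for stable starts
  env0 <- new.env(); env0$uT <- numeric(dat$n_tree)
  env0$uR <- numeric(dat$n_ramet)
  neg0 <- function(th) {
    p <- unpack(c(th, if (est_t) log(1e-4), if (est_r) log(1e-4)))
    ll <- .laplace_loglik(p$alpha, as.vector(X %*% p$beta), 0, 0, dat, env0)$ll
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  th_fix <- nlminb(theta0[seq_len(K - 1 + np_beta)], neg0,
                   control = list(iter.max = 300, eval.max = 600))$par
  theta0[seq_len(K - 1 + np_beta)] <- th_fix

  lo <- rep(-Inf, length(theta0)); hi <- rep(Inf, length(theta0))
  if (est_t) lo[K - 1 + np_beta + 1] <- log(1e-4)
  if (est_r) lo[K - 1 + np_beta + est_t + 1] <- log(1e-4)
  if (est_t) hi[K - 1 + np_beta + 1] <- log(20)
  if (est_r) hi[K - 1 + np_beta + est_t + 1] <- log(20)

  opt <- nlminb(theta0, negll, gradient = numgrad, lower = lo, upper = hi,
                control = list(iter.max = ctl$iter_max,
                               eval.max = 2 * ctl$iter_max,
                               rel.tol = 1e-8))
  ## Newton polish on the finite-difference gradient: nlminb stops on step
  ## size while the gradient can still be reduced; a few Newton steps with
  ## one FD Hessian drive the max-norm to the convergence tolerance.
  ## Parameters sitting on a box bound are held fixed during polishing.
  theta <- opt$par
  free <- which(theta > lo + 1e-8 & theta < hi - 1e-8)
  g <- numgrad(theta)
  if (max(abs(g[free])) > ctl$grad_tol && length(free)) {
    h <- 1e-4
    H <- matrix(0, length(theta), length(theta))
    for (j in free) {
      tp <- tm <- theta; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      H[, j] <- (numgrad(tp) - numgrad(tm)) / (2 * h)
    }
    Hf <- (H[free, free] + t(H[free, free])) / 2
    f_cur <- negll(theta)
    for (it in 1:5) {
      step <- tryCatch(solve(Hf, g[free]), error = function(e) NULL)
      if (is.null(step)) break
      scl <- 1
      repeat {
        cand <- theta; cand[free] <- cand[free] - scl * step
        f_new <- negll(cand)
        if (is.finite(f_new) && f_new <= f_cur + 1e-8 * abs(f_cur)) break
        scl <- scl / 2
        if (scl < 1e-4) { cand <- theta; f_new <- f_cur; break }
      }
      if (identical(cand, theta)) break
      theta <- cand; f_cur <- f_new
      g <- numgrad(theta)
      if (max(abs(g[free])) < ctl$grad_tol) break
    }
    opt <- list(par = theta, objective = f_cur, convergence = 0L)
  }
  p <- unpack(opt$par)
  final <- .laplace_loglik(p$alpha, as.vector(X %*% p$beta),
                           p$sigma_t, p$sigma_r, dat, env)
  gfin <- numgrad(opt$par)
  free_fin <- opt$par > lo + 1e-8 & opt$par < hi - 1e-8
  grad_norm <- if (any(free_fin)) max(abs(gfin[free_fin])) else 0

  beta_site <- setNames(c(0, p$beta[-(1:2)]), site_lv)
  alpha_raw <- p$alpha + p$beta[1] * day_bar + p$beta[2] * cn_bar
  ## threshold j bounds the cumulative set of the j least-advanced
  ## categories; named after the last score it includes ("max1.5" is the
  ## boundary used by the D50% statistic)
  fit <- list(alpha = setNames(alpha_raw,
                               paste0("max", labels[seq_len(K - 1)])),
              beta = setNames(p$beta, colnames(X)),
              beta_site = beta_site,
              sigma_tree = if (p$sigma_t <= 1e-4 + 1e-8 && est_t) 0
              else p$sigma_t,
              sigma_ramet = if (p$sigma_r <= 1e-4 + 1e-8 && est_r) 0
              else p$sigma_r,
              ranef_tree = setNames(final$uT, tree_lv),
              ranef_ramet = setNames(final$uR, ramet_lv),
              labels = labels,
              loglik = final$ll,
              converged = opt$convergence == 0 && grad_norm < ctl$grad_tol,
              grad_norm = grad_norm,
              method = "laplace",
              donors = donor_site[order(donor_site$donor_id), ],
              site_levels = site_lv,
              n_obs = length(k))
  class(fit) <- "budset_clmm"
  fit
}

#' @export
print.budset_clmm <- function(x, ...) {
  cat("Cumulative link mixed model (logit link, Laplace approximation)\n")
  cat(sprintf("  %d observations, %d donors, %d ramets; categories %s\n",
              x$n_obs, length(x$ranef_tree), length(x$ranef_ramet),
              paste(x$labels, collapse = " > ")))
  cat("Thresholds:\n"); print(round(x$alpha, 4))
  cat("Fixed effects:\n"); print(round(x$beta, 4))
  cat(sprintf("Random intercepts: sigma_tree = %.4f, sigma_ramet = %.4f\n",
              x$sigma_tree, x$sigma_ramet))
  cat(sprintf("log-likelihood %.3f (%sconverged)\n", x$loglik,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.budset_clmm <- function(object, ...) {
  object
}

#' @export
coef.budset_clmm <- function(object, ...) {
  c(object$alpha, object$beta)
}

#' @export
logLik.budset_clmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$alpha) + length(object$beta) +
              (object$sigma_tree > 0) + (object$sigma_ramet > 0),
            class = "logLik")
}

#' Random-effect modes of a fitted bud-set model
#'
#' @param fit a `budset_clmm`.
#' @return List with `tree` and `ramet` named vectors.
#' @export
ranef_budset <- function(fit) {
  list(tree = fit$ranef_tree, ramet = fit$ranef_ramet)
}

#' Category probabilities from a fitted bud-set model
#'
#' Differences the cumulative logits into per-category probabilities on the
#' full 7-level score scale (collapsed categories get probability 0).
#'
#' @param fit a `budset_clmm`.
#' @param day,site,cn covariate values (vectors are recycled to a common
#'   length).
#' @param ranef_tree,ranef_ramet random-intercept values (default 0, the
#'   population level).
#' @return Matrix with one row per input and one column per score level
#'   (3 down to 0); rows sum to 1.
#' @export
category_probabilities <- function(fit, day, site, cn,
                                   ranef_tree = 0, ranef_ramet = 0) {
  n <- max(length(day), length(site), length(cn))
  day <- rep_len(day, n); site <- rep_len(as.character(site), n)
  cn <- rep_len(cn, n)
  bad <- setdiff(site, fit$site_levels)
  if (length(bad)) .stopf("unknown site(s): %s", paste(bad, collapse = ", "))
  lp <- fit$beta[["day"]] * day + fit$beta[["cn"]] * cn +
    fit$beta_site[site] + rep_len(ranef_tree, n) + rep_len(ranef_ramet, n)
  probs <- cumlogit_cat_probs(fit$alpha, lp)
  out <- matrix(0, n, length(budset_levels()),
                dimnames = list(NULL, paste0("Bs", budset_levels())))
  out[, match(fit$labels, budset_levels())] <- probs
  out
}

#' @export
predict.budset_clmm <- function(object, newdata, ...) {
  rt <- if ("donor_id" %in% names(newdata))
    ifelse(is.na(match(newdata$donor_id, names(object$ranef_tree))), 0,
           object$ranef_tree[as.character(newdata$donor_id)]) else 0
  rr <- if ("ramet_id" %in% names(newdata))
    ifelse(is.na(match(newdata$ramet_id, names(object$ranef_ramet))), 0,
           object$ranef_ramet[as.character(newdata$ramet_id)]) else 0
  category_probabilities(object, newdata$day, newdata$site_id, newdata$cn,
                         rt, rr)
}
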