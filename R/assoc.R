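#' Per-epilocus binomial-logit regressions on climate covariates
#'
#' Simple logistic regressions (one covariate per model) of the binary
#' methylation state of each polymorphic epilocus on home-site climate.
#' Uses `glm()` with a binomial error distribution and a logit link. Fits
#' with complete separation (standardized |slope| > 15 or non-convergence)
#' are flagged non-estimable and excluded from FDR correction downstream.
#'
#' @param epi an `epilocus_matrix` scored with absence as unmethylated
#'   (mode `absence_as_unmethylated`), rows named by donor.
#' @param climate climate table with `site_id` and the covariates.
#' @param donors data frame mapping `donor_id` to `site_id`.
#' @param covariates climate covariates to test.
#' @return Data frame: `locus_id`, `covariate`, `estimate`, `statistic`
#'   (Wald z), `p_value`, `estimable`.
#' @export
epilocus_glm <- function(epi, climate, donors,
                         covariates = c("t_jan", "t_jul", "t_mar", "precip",
                                        "frost_days", "pet", "cn_topsoil")) {
  ep <- if (inherits(epi, "epilocus_matrix")) polymorphic_loci(epi)
  else list(states = as.matrix(epi))
  m <- ep$states
  site <- donors$site_id[match(rownames(m), donors$donor_id)]
  if (anyNA(site)) .stopf("donor-site map missing for some samples")
  ci <- match(site, climate$site_id)
  res <- list()
  for (v in covariates) {
    x <- climate[[v]][ci]
    if (is.null(x)) .stopf("unknown covariate %s", v)
    if (sd(x) == 0) .stopf("covariate %s is constant", v)
    for (l in colnames(m)) {
      y <- m[, l]
      ok <- !is.na(y)
      fit <- suppressWarnings(glm(y[ok] ~ x[ok], family = binomial()))
      sl <- summary(fit)$coefficients
      est <- unname(coef(fit)[2])
      sep <- !fit$converged || !is.finite(est) ||
        abs(est) * sd(x[ok]) > 15
      if (sep)
        .warnf("complete separation at locus %s / %s: excluded from FDR",
               l, v)
      res[[length(res) + 1L]] <-
        data.frame(locus_id = l, covariate = v,
                   estimate = est,
                   statistic = if (sep) NA_real_ else sl[2, "z value"],
                   p_value = if (sep) NA_real_ else sl[2, "Pr(>|z|)"],
                   estimable = !sep, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Welch's t-test of D50% timing by epilocus methylation state
#'
#' For each epilocus the donors' D50% values are split by methylation state
#' (fragment absence scored as unmethylated) and compared with Welch's
#' unequal-variance t-test (Welch--Satterthwaite degrees of freedom,
#' two-sided). Loci scored 1 in only one tested unit, or in all but one,
#' are discarded before testing.
#'
#' @param d50_table output of [d50()].
#' @param epi an `epilocus_matrix` in `absence_as_unmethylated` mode, rows
#'   named by donor.
#' @return Data frame: `locus_id`, `estimate` (mean difference, methylated
#'   minus unmethylated, days), `statistic` (t), `df`, `p_value`,
#'   `degenerate` (TRUE when a zero-variance group forced an exact 0/1 p).
#' @export
welch_test <- function(d50_table, epi) {
  m <- epi_states(epi)
  common <- intersect(rownames(m), d50_table$donor_id)
  if (length(common) < 4L) .stopf("too few donors with both D50 and epilocus data")
  m <- m[common, , drop = FALSE]
  dd <- d50_table$d50[match(common, d50_table$donor_id)]
  res <- list()
  for (l in colnames(m)) {
    y <- m[, l]
    ok <- !is.na(y)
    n1 <- sum(y[ok] == 1); n0 <- sum(y[ok] == 0)
    if (n1 <= 1L || n0 <= 1L) next  # discard rule
    g1 <- dd[ok][y[ok] == 1]; g0 <- dd[ok][y[ok] == 0]
    tt <- tryCatch(t.test(g1, g0), error = function(e) NULL)
    if (is.null(tt)) {
      ## both groups essentially constant: exact rule
      delta <- mean(g1) - mean(g0)
      res[[length(res) + 1L]] <-
        data.frame(locus_id = l, estimate = delta,
                   statistic = if (delta == 0) 0 else sign(delta) * Inf,
                   df = NA_real_,
                   p_value = if (delta == 0) 1 else .Machine$double.xmin,
                   degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1L]] <-
        data.frame(locus_id = l, estimate = mean(g1) - mean(g0),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(locus_id = character(), estimate = numeric(),
               statistic = numeric(), df = numeric(), p_value = numeric(),
               degenerate = logical())
  rownames(out) <- NULL
  out
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: after sorting ascending, adjusted p_i is the minimum
#' over j >= i of p_j * m / j, capped at 1; a test is significant when its
#' adjusted p is at most `q`.
#'
#' @param p_values raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values))
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    .stopf("p-values must lie in (0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Pool association results and apply FDR correction
#'
#' Adds `p_adjusted` and `significant_at_q` columns. The FDR family is all
#' estimable tests in `results` pooled (`family = "pooled"`), or each
#' covariate separately (`family = "per_covariate"`).
#'
#' @param results output of [epilocus_glm()] or [welch_test()].
#' @param q FDR level.
#' @param family `"pooled"` or `"per_covariate"`.
#' @return `results` with adjustment columns added.
#' @export
adjust_associations <- function(results, q = 0.05,
                                family = c("pooled", "per_covariate")) {
  family <- match.arg(family)
  results$p_adjusted <- NA_real_
  results$significant_at_q <- FALSE
  ok <- !is.na(results$p_value)
  grp <- if (family == "per_covariate" && "covariate" %in% names(results))
    results$covariate[ok] else rep("all", sum(ok))
  for (g in unique(grp)) {
    sel <- which(ok)[grp == g]
    bh <- bh_fdr(results$p_value[sel], q)
    results$p_adjusted[sel] <- bh$p_adjusted
    results$significant_at_q[sel] <- bh$significant
  }
  results
}
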