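#' Per-donor D50% bud-set timing
#'
#' The day of year at which a donor's ramets have 50% probability of having
#' at most reached bud-set score `score_ref` (default 1.5), at a reference
#' carbon:nitrogen ratio:
#' \deqn{D_{50\%} = (\alpha_{1.5} - \beta_{CN} \cdot CN_{ref} - \beta_S -
#'   u_{TID}) / \beta_D}
#' with \eqn{\alpha_{1.5}} the threshold whose lower cumulative set is
#' {3, 2.5, 2, 1.5}, \eqn{\beta_S} the donor's site effect (0 at the
#' reference site) and \eqn{u_{TID}} the donor's predicted random intercept.
#'
#' @param fit a [budset_clmm()] fit.
#' @param cn_ref reference C:N ratio (default 12).
#' @param score_ref score defining the cumulative set (default 1.5).
#' @return Data frame of class `d50_table`: `donor_id`, `site_id`, `d50`;
#'   `cn_reference` attribute records `cn_ref`.
#' @export
d50 <- function(fit, cn_ref = 12, score_ref = 1.5) {
  if (!inherits(fit, "budset_clmm")) .stopf("fit must be a budset_clmm")
  beta_d <- fit$beta[["day"]]
  if (beta_d == 0) .stopf("beta_day is zero: D50%% undefined")
  j <- sum(fit$labels >= score_ref)
  if (j < 1L || j > length(fit$alpha))
    .stopf("no threshold bounds the cumulative set up to score %s", score_ref)
  alpha_t <- fit$alpha[[j]]
  donors <- fit$donors
  out <- data.frame(
    donor_id = donors$donor_id,
    site_id = donors$site_id,
    d50 = (alpha_t - fit$beta[["cn"]] * cn_ref -
             fit$beta_site[donors$site_id] -
             fit$ranef_tree[donors$donor_id]) / beta_d,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cn_reference") <- cn_ref
  class(out) <- c("d50_table", "data.frame")
  out
}

#' Pearson correlations of D50% timing with home-site climate
#'
#' @param d50_table output of [d50()].
#' @param climate climate table with `site_id` and the requested variables.
#' @param variables climate variables to test.
#' @return Data frame `variable`, `r`, `p_value`, `n` (two-sided t-based p).
#' @export
pearson_climate <- function(d50_table, climate,
                            variables = c("t_jan", "t_jul", "pet")) {
  ix <- match(d50_table$site_id, climate$site_id)
  if (anyNA(ix)) .stopf("climate missing for site(s) %s",
                        paste(unique(d50_table$site_id[is.na(ix)]),
                              collapse = ", "))
  if (nrow(d50_table) < 3L) .stopf("need at least 3 donors")
  res <- lapply(variables, function(v) {
    x <- climate[[v]][ix]
    if (sd(x) == 0 || sd(d50_table$d50) == 0)
      .stopf("zero variance for %s", v)
    ct <- stats::cor.test(d50_table$d50, x)
    data.frame(variable = v, r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d50_table),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
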