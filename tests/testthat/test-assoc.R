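test_that("logistic slope matches a Newton-Raphson oracle", {
  set.seed(41)
  donors <- data.frame(donor_id = sprintf("T%02d", 1:25),
                       site_id = sprintf("S%02d", 1:25))
  for (rep in 1:20) {
    x <- rnorm(25)
    y <- rbinom(25, 1, plogis(0.8 * x))
    if (length(unique(y)) < 2) next
    m <- matrix(y, 25, 1, dimnames = list(donors$donor_id, "L1"))
    climate <- data.frame(site_id = donors$site_id, t_jan = x)
    res <- epilocus_glm(m, climate, donors, covariates = "t_jan")
    expect_equal(res$estimate, nr_logistic_slope(y, x), tolerance = 1e-6)
  }
})

test_that("complete separation is flagged non-estimable", {
  donors <- data.frame(donor_id = sprintf("T%02d", 1:20),
                       site_id = sprintf("S%02d", 1:20))
  x <- seq(-1, 1, length.out = 20)
  y <- as.integer(x > 0)
  m <- matrix(y, 20, 1, dimnames = list(donors$donor_id, "L1"))
  climate <- data.frame(site_id = donors$site_id, t_jan = x)
  expect_warning(res <- epilocus_glm(m, climate, donors,
                                     covariates = "t_jan"), "separation")
  expect_false(res$estimable)
  expect_true(is.na(res$p_value))
  expect_error(epilocus_glm(m, transform(climate, t_jan = 1), donors,
                            covariates = "t_jan"), "constant")
})

test_that("Welch test matches the textbook computation and discard rule", {
  d50_tab <- structure(data.frame(donor_id = sprintf("T%d", 1:8),
                                  site_id = "S01",
                                  d50 = c(1, 2, 3, 4, 10, 11, 12, 13)),
                       class = c("d50_table", "data.frame"))
  m <- matrix(c(rep(0, 4), rep(1, 4),    # clean split
                rep(0, 7), 1,            # singleton: discarded
                rep(1, 7), 0),           # n-1 rule: discarded
              8, 3, dimnames = list(d50_tab$donor_id, c("L1", "L2", "L3")))
  res <- welch_test(d50_tab, m)
  expect_equal(res$locus_id, "L1")
  tt <- t.test(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$df, unname(tt$parameter))
  expect_lt(res$p_value, 0.01)
  expect_equal(res$estimate, 9)

  ## identical groups give t = 0, p = 1
  m2 <- matrix(rep(c(0, 1), 4), 8, 1,
               dimnames = list(d50_tab$donor_id, "L1"))
  d50_eq <- d50_tab; d50_eq$d50 <- c(5, 5, 6, 6, 7, 7, 8, 8)
  res2 <- welch_test(d50_eq, m2)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  ## zero variance in both groups with different means: exact degenerate rule
  d50_z <- d50_tab; d50_z$d50 <- rep(c(5, 7), 4)
  res3 <- welch_test(d50_z, m2)
  expect_true(res3$degenerate)
  expect_equal(res3$statistic, Inf)
  expect_lt(res3$p_value, 1e-300)
})

test_that("BH adjustment reproduces step-up arithmetic", {
  b1 <- bh_fdr(0.04)
  expect_equal(b1$p_adjusted, 0.04)
  expect_true(b1$significant)

  b2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(b2$p_adjusted, rep(0.04, 4))
  expect_true(all(b2$significant))

  b3 <- bh_fdr(c(0.009, 0.9))
  expect_equal(b3$p_adjusted, c(0.018, 0.9))
  expect_equal(b3$significant, c(TRUE, FALSE))

  expect_error(bh_fdr(c(0, 0.5)), "p-values")
  expect_length(bh_fdr(numeric(0))$p_adjusted, 0)

  ## order invariance and rank monotonicity
  set.seed(2)
  p <- runif(12)
  perm <- sample(12)
  expect_equal(bh_fdr(p)$p_adjusted[perm], bh_fdr(p[perm])$p_adjusted)
  expect_true(all(diff(bh_fdr(sort(p))$p_adjusted) >= 0))
  expect_true(all(bh_fdr(p)$p_adjusted >= p))
})

test_that("pooled FDR family spans all covariates", {
  set.seed(9)
  res <- data.frame(locus_id = rep(sprintf("L%d", 1:5), 2),
                    covariate = rep(c("t_jan", "pet"), each = 5),
                    p_value = runif(10))
  adj <- adjust_associations(res, q = 0.05)
  expect_equal(adj$p_adjusted, p.adjust(res$p_value, "BH"))
  adj2 <- adjust_associations(res, q = 0.05, family = "per_covariate")
  expect_equal(adj2$p_adjusted[1:5],
               p.adjust(res$p_value[1:5], "BH"))
})
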