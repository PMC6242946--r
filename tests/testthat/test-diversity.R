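epi_from_matrix <- function(m) m  # diversity functions accept bare matrices

test_that("Shannon index matches hand arithmetic", {
  m <- cbind(L1 = c(1, 1, 0, 0),           # p = 0.5
             L2 = c(0, 0, 0, 0),           # monomorphic
             L3 = c(1, 0, 0, 0))           # p = 0.25
  rownames(m) <- sprintf("S%d", 1:4)
  sh <- shannon_index(m)
  expect_equal(unname(sh$per_locus["L1"]), log(2))
  expect_equal(unname(sh$per_locus["L2"]), 0)
  expect_equal(unname(sh$per_locus["L3"]),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(sh$mean, mean(sh$per_locus))
  ## invariant to sample and locus order
  sh2 <- shannon_index(m[c(3, 1, 4, 2), c(2, 3, 1)])
  expect_equal(sh2$mean, sh$mean)
})

test_that("epigenotype matching treats missing entries as wildcards", {
  m <- rbind(A = c(0, 1, NA),
             B = c(0, 1, 0),
             C = c(1, 1, 0))
  g <- match_epigenotypes(m)
  grp <- setNames(g$group, g$sample_id)
  expect_equal(grp[["A"]], grp[["B"]])
  expect_false(grp[["C"]] == grp[["A"]])
})

test_that("epigenetic distances follow the missing-data scaling rule", {
  m <- rbind(A = c(0, 0, 0, 0), B = c(1, 1, 0, 0))
  d2 <- epi_distance(m, squared = TRUE)
  expect_equal(d2$values["A", "B"], 2)
  expect_equal(epi_distance(m)$values["A", "B"], sqrt(2))

  m2 <- rbind(A = c(0, 1, NA), B = c(1, 1, 0))
  expect_equal(epi_distance(m2, squared = TRUE)$values["A", "B"], 1 * 3 / 2)
  expect_equal(epi_distance(m2, squared = TRUE)$values["A", "A"], 0)

  m3 <- rbind(A = c(0, NA), B = c(NA, 1))
  expect_error(epi_distance(m3), "share no scored locus")
})

test_that("geographic distances are haversine kilometres", {
  s <- data.frame(site_id = c("a", "b", "c"),
                  latitude = c(0, 0, 45), longitude = c(0, 1, 9))
  d <- geo_distance(s)
  expect_equal(d$values["a", "a"], 0)
  expect_equal(d$values["a", "b"], 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(d$values, t(d$values))
  expect_error(geo_distance(data.frame(site_id = "x", latitude = 99,
                                       longitude = 0)), "range")
})

test_that("PCoA reproduces Euclidean configurations and fixes signs", {
  set.seed(1)
  xy <- matrix(rnorm(20), 10, 2)
  rownames(xy) <- sprintf("S%d", 1:10)
  d <- as.matrix(dist(xy))
  pc <- pcoa(structure(list(values = d, ids = rownames(xy),
                            metric_tag = "euclidean_epi"),
                       class = "dist_matrix"))
  expect_equal(as.matrix(dist(pc$coordinates[, 1:2])), d,
               tolerance = 1e-8, ignore_attr = TRUE)
  ## agreement with classical MDS (up to sign)
  cm <- cmdscale(d, k = 2)
  expect_equal(abs(pc$coordinates[, 1]), abs(cm[, 1]), ignore_attr = TRUE)
  ## deterministic sign: largest loading positive
  expect_gt(max(pc$coordinates[, 1]), 0)
  expect_equal(pc$coordinates[which.max(abs(pc$coordinates[, 1])), 1],
               max(abs(pc$coordinates[, 1])))
  ## equidistant points: n-1 equal eigenvalues
  deq <- matrix(1, 4, 4) - diag(4)
  pceq <- pcoa(deq)
  expect_equal(pceq$eigenvalues[1:3], rep(pceq$eigenvalues[1], 3),
               tolerance = 1e-10)
  ## three collinear points: second positive eigenvalue vanishes
  dc <- as.matrix(dist(cbind(c(0, 1, 2), 0)))
  expect_lt(pcoa(dc)$eigenvalues[2], 1e-10)
})

test_that("AMOVA matches the centroid-based variance-component oracle", {
  set.seed(7)
  coords <- matrix(rnorm(18, sd = 1.5), 6, 3)
  coords[1:3, 1] <- coords[1:3, 1] + 2      # group shift
  groups <- rep(c("g1", "g2"), each = 3)
  d2 <- as.matrix(dist(coords))^2
  am <- amova(d2, groups, n_perm = 99, seed = 1)
  oracle <- amova_from_coords(coords, groups)
  expect_equal(am$phi_st, oracle$phi_st, tolerance = 1e-10)
  expect_equal(am$sigma2_among, oracle$sigma2_among, tolerance = 1e-10)
  expect_equal(am$ss_within, oracle$ss_within, tolerance = 1e-10)
  expect_equal(am$df_among, 1)
  expect_equal(am$df_within, 4)
  expect_gte(am$p_value, 1 / 100)
})

test_that("fully separated groups give Phi_ST of 1", {
  d2 <- rbind(c(0, 0, 9, 9), c(0, 0, 9, 9), c(9, 9, 0, 0), c(9, 9, 0, 0))
  am <- amova(d2, c("a", "a", "b", "b"), n_perm = 99, seed = 2)
  expect_equal(am$phi_st, 1)
})

test_that("AMOVA drops singleton groups and needs two eligible ones", {
  d2 <- as.matrix(dist(matrix(rnorm(10), 5)))^2
  expect_message(am <- amova(d2, c("a", "a", "b", "b", "c"), n_perm = 49,
                             seed = 1), "size 1")
  expect_equal(am$df_among + am$df_within, 3)  # 4 samples kept
  expect_error(suppressMessages(amova(d2, c("a", "a", "a", "a", "c"),
                                      n_perm = 9, seed = 1)), "two eligible")
})

test_that("Mantel statistic equals the direct lower-triangle correlation", {
  set.seed(3)
  xy <- matrix(rnorm(8), 4, 2)
  d1 <- as.matrix(dist(xy))
  d2 <- as.matrix(dist(xy + rnorm(8, sd = 0.3)))
  mt <- mantel(d1, d2, n_perm = 199, seed = 1)
  lt <- lower.tri(d1)
  expect_equal(mt$r, cor(d1[lt], d2[lt]))
  expect_equal(mt$r_squared, mt$r^2)
  expect_equal(mantel(d1, d1, n_perm = 9, seed = 1)$r, 1)
  ## independent implementation agrees on the statistic
  skip_if_not_installed("vegan")
  expect_equal(mt$r, unname(vegan::mantel(d1, d2, permutations = 5)$statistic))
})

test_that("permutation p-values respect the (count+1)/(n+1) floor", {
  set.seed(5)
  m <- matrix(rbinom(60, 1, 0.5), 6)
  rownames(m) <- sprintf("S%d", 1:6)
  d2 <- epi_distance(m, squared = TRUE)
  am <- amova(d2, rep(c("a", "b"), 3), n_perm = 19, seed = 1)
  expect_gte(am$p_value, 1 / 20)
  expect_lte(am$p_value, 1)
})
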