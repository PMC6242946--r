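## build a long dual-enzyme profile table from presence matrices
build_profiles <- function(hpa, msp, sizes = NULL, combo = 1,
                           replicate_of = NULL) {
  samples <- rownames(hpa); loci <- colnames(hpa)
  if (is.null(sizes)) sizes <- seq(200, 200 + 10 * (ncol(hpa) - 1), by = 10)
  if (is.null(replicate_of)) replicate_of <- rep(NA_character_,
                                                 length(samples))
  g <- expand.grid(s = seq_along(samples), l = seq_along(loci))
  data.frame(primer_combo_id = combo,
             enzyme = rep(c("HpaII", "MspI"), each = nrow(g)),
             sample_id = rep(samples[g$s], 2),
             locus_id = rep(loci[g$l], 2),
             size = rep(sizes[g$l], 2),
             present = c(hpa[cbind(g$s, g$l)], msp[cbind(g$s, g$l)]),
             replicate_of = rep(replicate_of[g$s], 2),
             stringsAsFactors = FALSE)
}

mat <- function(v, nr, samples = sprintf("S%d", seq_len(nr))) {
  m <- matrix(v, nr, byrow = TRUE)
  dimnames(m) <- list(samples, sprintf("L%d", seq_len(ncol(m))))
  m
}

test_that("replicate error rate is mismatches over compared band scores", {
  hpa <- mat(c(1, 1, 1,
               1, 1, 1), 2, samples = c("A", "Arep"))
  msp <- mat(c(1, 0, 1,
               1, 1, 1), 2, samples = c("A", "Arep"))  # 1 mismatch of 6
  pr <- build_profiles(hpa, msp, replicate_of = c(NA, "A"))
  er <- replicate_error_rate(pr)
  expect_equal(er$per_combo$rate, 1 / 6)
  expect_equal(er$per_combo$n_compared, 6)

  ## identical replicates give zero
  pr0 <- build_profiles(hpa, hpa, replicate_of = c(NA, "A"))
  expect_equal(replicate_error_rate(pr0)$per_combo$rate, 0)
})

test_that("the combined summary reproduces per-combination arithmetic", {
  s <- summarize_primer_combos(primer_combo_reference())
  comb <- s[nrow(s), ]
  expect_equal(comb$n_markers, 216)
  expect_equal(comb$n_susceptible, 94)
  expect_equal(comb$n_polymorphic, 65)
  expect_equal(comb$error_rate, 0.028, tolerance = 1e-12)
  expect_equal(s$pct_polymorphic[2], 100 * 16 / 21, tolerance = 1e-12)
  expect_equal(s$pct_polymorphic[3], 100)
})

test_that("size filter and singleton removal drop the right loci", {
  samples <- sprintf("S%d", 1:6)
  hpa <- matrix(1, 6, 4, dimnames = list(samples, paste0("L", 1:4)))
  msp <- hpa
  ## L2: singleton presence; L3: absent in exactly one sample
  hpa[, "L2"] <- c(1, 0, 0, 0, 0, 0); msp[, "L2"] <- 0
  hpa[, "L3"] <- c(0, 1, 1, 1, 1, 1); msp[, "L3"] <- 0
  ## L4 polymorphic, kept
  hpa[, "L4"] <- c(1, 1, 0, 0, 1, 1); msp[, "L4"] <- c(1, 1, 0, 0, 1, 1)
  pr <- build_profiles(hpa, msp, sizes = c(120, 300, 300, 300))
  out <- filter_fragments(pr)
  log <- attr(out, "removal_log")
  expect_setequal(log$locus_id, c("L1", "L2", "L3"))
  expect_equal(log$reason[log$locus_id == "L1"], "size_out_of_range")
  expect_setequal(unique(out$locus_id), "L4")
  ## in-range, non-singleton data pass through unchanged
  pr4 <- build_profiles(hpa[, 4, drop = FALSE], msp[, 4, drop = FALSE],
                        sizes = 300)
  expect_equal(nrow(filter_fragments(pr4)), nrow(pr4))
})

test_that("presence patterns classify to U/I/H/A", {
  hpa <- mat(c(1, 0, 1, 0), 1, samples = "S1")
  msp <- mat(c(1, 1, 0, 0), 1, samples = "S1")
  pat <- classify_patterns(build_profiles(hpa, msp))
  expect_equal(unname(pat$patterns["S1", ]), c("U", "I", "H", "A"))
})

test_that("susceptibility threshold is 2e(1-e) with strict exceedance", {
  expect_equal(2 * 0.028 * (1 - 0.028), 0.054432)
  samples <- sprintf("S%d", 1:60)
  hpa <- matrix(1, 60, 2, dimnames = list(samples, c("L1", "L2")))
  msp <- hpa
  msp[1:2, "L1"] <- 0          # 2/60 = 0.033 discordant
  msp[1:10, "L2"] <- 0         # 10/60 = 0.167 discordant
  pat <- classify_patterns(build_profiles(hpa, msp))
  fl <- select_methylation_susceptible(pat, c("1" = 0.028))
  expect_equal(fl$threshold, rep(0.054432, 2))
  expect_false(fl$is_susceptible[fl$locus_id == "L1"])
  expect_true(fl$is_susceptible[fl$locus_id == "L2"])
  ## e = 0: any discordance is evidence
  fl0 <- select_methylation_susceptible(pat, c("1" = 0))
  expect_true(all(fl0$is_susceptible))
  expect_error(select_methylation_susceptible(pat, c("1" = 0.6)), "0.5")
})

test_that("binarize maps patterns by scoring mode and flags polymorphism", {
  samples <- c("S1", "S2", "S3")
  hpa <- mat(c(1, 0, 0,
               0, 1, 0,
               0, 0, 1), 3, samples = samples)
  ## column L1: (U, I, A) via msp settings
  hpa[, 1] <- c(1, 0, 0); hpa[, 2] <- c(1, 1, 1); hpa[, 3] <- c(1, 1, 1)
  msp <- hpa; msp[, 1] <- c(1, 1, 0)
  pat <- classify_patterns(build_profiles(hpa, msp))
  fl <- select_methylation_susceptible(pat, c("1" = 0))
  em <- binarize(pat, fl, "missing_on_double_absence")
  expect_equal(unname(em$states[, "L1"]), c(0, 1, NA))
  ez <- binarize(pat, fl, "absence_as_unmethylated")
  expect_equal(unname(ez$states[, "L1"]), c(0, 1, 0))
  expect_true(em$loci$is_polymorphic[em$loci$locus_id == "L1"])
  expect_true(em$loci$has_missing[em$loci$locus_id == "L1"])
  ## an all-U locus is excluded by the threshold (not susceptible)
  expect_false("L2" %in% em$loci$locus_id)
})

test_that("zero-noise pipeline recovers every latent methylation state", {
  cfg <- sim_config(seed = 33, n_sites = 6, trees_per_site = 3,
                    n_primer_combos = 3, loci_per_combo = 40,
                    error_rate_per_combo = 0, n_replicate_pairs = 5)
  fp <- simulate_msap(cfg, simulate_sites(cfg))
  scored <- msap_score(fp)
  rec <- epiclonal:::state_recovery(fp, cfg, epi = scored$epi_missing)
  expect_equal(rec$rate, 1)
  expect_gt(rec$n_compared, 0)
  ## every methylation-variable locus that survived filtering is in the matrix
  tr <- fp$truth
  var_loci <- unique(tr$locus_id[tr$state %in% c("I", "H")])
  kept <- unique(scored$flags$locus_id)
  expect_true(all(intersect(var_loci, kept) %in%
                    colnames(scored$epi_missing$states)))
})

test_that("scoring counts are internally consistent", {
  cfg <- sim_config(seed = 15, n_sites = 6, trees_per_site = 3,
                    n_primer_combos = 3, loci_per_combo = 30,
                    n_replicate_pairs = 5)
  scored <- msap_score(simulate_msap(cfg, simulate_sites(cfg)))
  fl <- scored$flags
  expect_equal(nrow(fl), sum(fl$is_susceptible) + sum(!fl$is_susceptible))
  expect_true(all(scored$epi_missing$loci$locus_id %in%
                    fl$locus_id[fl$is_susceptible]))
  expect_lte(sum(scored$epi_missing$loci$is_polymorphic),
             nrow(scored$epi_missing$loci))
  ## binarize is invariant to sample order
  pat <- classify_patterns(
    filter_fragments(simulate_msap(cfg, simulate_sites(cfg))$profiles))
  fl2 <- select_methylation_susceptible(pat, scored$error_rates)
  em <- binarize(pat, fl2, "missing_on_double_absence")
  pat_rev <- pat
  pat_rev$patterns <- pat$patterns[rev(seq_len(nrow(pat$patterns))), ]
  em_rev <- binarize(pat_rev, fl2, "missing_on_double_absence")
  expect_equal(em_rev$states[rownames(em$states), ], em$states)
  expect_equal(em_rev$loci$is_polymorphic, em$loci$is_polymorphic)
})
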