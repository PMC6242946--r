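#' Simulate a multilocus SSR genotype table for a clonal collection
#'
#' Builds a dominant clone multilocus genotype (MLG) over `ssr_n_loci`
#' diploid loci, then derives the configured number of single-allele somatic
#' variants (one repeat unit off at one locus) and, optionally, half-sib
#' offspring genotypes that keep one clone allele per locus. Replicated
#' samples re-score their genotype with an independent per-allele error.
#'
#' @param config a [sim_config()].
#' @return A long data frame of class `ssr_genotype_table` with columns
#'   `sample_id`, `locus_id`, `allele_a`, `allele_b` (fragment sizes, bp,
#'   `allele_a <= allele_b`), `replicate_of`, plus a `"truth"` attribute with
#'   the clone MLG and the class (`clone`, `mutant`, `offspring`) of every
#'   sample.
#' @export
simulate_ssr <- function(config) {
  validate_sim_config(config)
  set.seed(.substream(config$seed, "ssr"))
  n_loci <- config$ssr_n_loci
  n_samples <- config$n_sites * config$trees_per_site
  n_mut <- config$ssr_n_mutants
  n_off <- config$ssr_n_offspring
  if (n_mut + n_off >= n_samples / 2)
    .stopf("mutants + offspring must stay a minority of samples")
  ru <- config$ssr_repeat_unit

  locus_id <- sprintf("SSR%02d", seq_len(n_loci))
  base <- 120 + 15 * seq_len(n_loci)
  clone <- t(vapply(seq_len(n_loci), function(l)
    sort(base[l] + ru * sample(0:12, 2, replace = TRUE)), numeric(2)))

  sample_id <- sprintf("T%03d", seq_len(n_samples))
  cls <- rep("clone", n_samples)
  if (n_mut > 0) cls[n_samples - n_off - seq_len(n_mut) + 1L] <- "mutant"
  if (n_off > 0) cls[n_samples - seq_len(n_off) + 1L] <- "offspring"

  geno <- lapply(seq_len(n_samples), function(i) {
    g <- clone
    if (cls[i] == "mutant") {
      l <- sample.int(n_loci, 1L); a <- sample.int(2L, 1L)
      g[l, a] <- g[l, a] + ru * sample(c(-1L, 1L), 1L)
    } else if (cls[i] == "offspring") {
      keep <- sample.int(2L, n_loci, replace = TRUE)
      for (l in seq_len(n_loci)) {
        other <- base[l] + ru * sample(setdiff(0:12, (clone[l, ] - base[l]) / ru),
                                       1L)
        g[l, ] <- c(clone[l, keep[l]], other)
      }
    }
    t(apply(g, 1, sort))
  })

  rows <- function(id, g, rep_of) {
    data.frame(sample_id = id, locus_id = locus_id,
               allele_a = g[, 1], allele_b = g[, 2],
               replicate_of = rep_of, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_samples), function(i)
    rows(sample_id[i], geno[[i]], NA_character_)))

  n_rep <- min(config$n_replicate_pairs, n_samples)
  if (n_rep > 0) {
    reps <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
      g <- geno[[i]]
      err <- matrix(runif(length(g)) < config$ssr_allele_error, nrow(g))
      g[err] <- g[err] + ru * sample(c(-1, 1), sum(err), replace = TRUE)
      rows(paste0(sample_id[i], "rep"), t(apply(g, 1, sort)), sample_id[i])
    }))
    out <- rbind(out, reps)
  }

  attr(out, "truth") <- list(clone_mlg = clone, class = setNames(cls, sample_id))
  class(out) <- c("ssr_genotype_table", "data.frame")
  out
}
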