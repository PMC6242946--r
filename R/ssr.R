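## wide list of per-sample genotypes: for each sample a loci x 2 matrix of
## sorted allele sizes; replicated samples are kept apart from originals
ssr_wide <- function(genotypes, include_replicates = FALSE) {
  g <- genotypes
  if (!all(c("sample_id", "locus_id", "allele_a", "allele_b") %in% names(g)))
    .stopf("genotype table lacks required columns")
  if (!include_replicates && "replicate_of" %in% names(g))
    g <- g[is.na(g$replicate_of), , drop = FALSE]
  if (anyDuplicated(g[c("sample_id", "locus_id")]))
    .stopf("each (sample, locus) must appear once")
  loci <- sort(unique(g$locus_id))
  samples <- unique(g$sample_id)
  per_sample <- lapply(samples, function(s) {
    gs <- g[g$sample_id == s, , drop = FALSE]
    if (!setequal(gs$locus_id, loci))
      .stopf("locus sets differ across samples (sample %s)", s)
    gs <- gs[match(loci, gs$locus_id), ]
    m <- cbind(pmin(gs$allele_a, gs$allele_b), pmax(gs$allele_a, gs$allele_b))
    rownames(m) <- loci
    m
  })
  names(per_sample) <- samples
  per_sample
}

## allele mismatch between two genotypes: per locus the alleles are compared
## as multisets (2 slots per locus), so heterozygote phase is irrelevant
allele_mismatch <- function(g1, g2) {
  sum(vapply(seq_len(nrow(g1)), function(l) {
    a <- g1[l, ]; b <- g2[l, ]
    2L - length(.multiset_intersect(a, b))
  }, integer(1)))
}

.multiset_intersect <- function(a, b) {
  out <- c()
  for (x in a) {
    i <- match(x, b)
    if (!is.na(i)) { out <- c(out, x); b <- b[-i] }
  }
  out
}

#' Group samples into multilocus genotypes (MLGs)
#'
#' Samples with identical allele sets at every locus share an MLG. MLG ids
#' are assigned by decreasing frequency (`G01` = modal MLG, the putative true
#' clone); ties are broken by first occurrence with a warning. Each sample's
#' allele-mismatch count to the modal MLG is reported (2 slots per locus,
#' compared as multisets). Samples with missing alleles are excluded with a
#' warning; replicated samples are ignored.
#'
#' @param genotypes long SSR table with columns `sample_id`, `locus_id`,
#'   `allele_a`, `allele_b` and optionally `replicate_of`.
#' @return A data frame of class `mlg_assignment` with `sample_id`, `mlg_id`,
#'   `mismatch_to_reference`, `is_clone` (NA until
#'   [classify_clonemates()] is run); genotypes and the reference MLG are
#'   carried in attributes.
#' @export
identify_mlgs <- function(genotypes) {
  g <- genotypes
  bad <- !complete.cases(g[c("allele_a", "allele_b")])
  if (any(bad)) {
    .warnf("excluding %d samples with missing alleles",
           length(unique(g$sample_id[bad])))
    g <- g[!g$sample_id %in% unique(g$sample_id[bad]), , drop = FALSE]
  }
  wide <- ssr_wide(g)
  if (!length(wide)) .stopf("no complete samples")
  key <- vapply(wide, function(m) paste(t(m), collapse = "/"), character(1))
  tab <- table(key)
  ord <- order(-as.vector(tab), match(names(tab), key))
  if (sum(tab == max(tab)) > 1L)
    .warnf("modal MLG is tied; ties broken by first occurrence")
  mlg_of_key <- setNames(sprintf("G%02d", seq_along(ord)), names(tab)[ord])
  ref_key <- names(tab)[ord][1L]
  ref <- wide[[match(ref_key, key)]]
  out <- data.frame(sample_id = names(wide),
                    mlg_id = unname(mlg_of_key[key]),
                    mismatch_to_reference = vapply(wide, allele_mismatch,
                                                   integer(1), g2 = ref),
                    is_clone = NA,
                    stringsAsFactors = FALSE)
  attr(out, "genotypes") <- wide
  attr(out, "reference") <- ref
  class(out) <- c("mlg_assignment", "data.frame")
  out
}

#' Flag clone members, allowing a possible somatic mutation
#'
#' A sample is a clone member when its allele mismatch to the reference
#' (modal) MLG is at most `max_mismatch` and every differing allele differs
#' from the reference allele by exactly one repeat unit, the signature of a
#' somatic stepwise mutation.
#'
#' @param assignment output of [identify_mlgs()].
#' @param max_mismatch maximum tolerated allele mismatches (default 1).
#' @param repeat_units repeat-unit length in bp, a single value or a named
#'   vector per locus; loci missing from a named vector are compared on
#'   mismatch count only, with a warning.
#' @return The assignment with `is_clone` filled in.
#' @export
classify_clonemates <- function(assignment, max_mismatch = 1L,
                                repeat_units = 2L) {
  wide <- attr(assignment, "genotypes")
  ref <- attr(assignment, "reference")
  if (is.null(wide)) .stopf("run identify_mlgs() first")
  loci <- rownames(ref)
  ru <- if (length(repeat_units) == 1L && is.null(names(repeat_units)))
    setNames(rep(repeat_units, length(loci)), loci) else repeat_units
  assignment$is_clone <- vapply(assignment$sample_id, function(s) {
    g <- wide[[s]]
    mm <- allele_mismatch(g, ref)
    if (mm == 0L) return(TRUE)
    if (mm > max_mismatch) return(FALSE)
    for (l in loci) {
      extra_g <- .multiset_diff(g[l, ], ref[l, ])
      extra_r <- .multiset_diff(ref[l, ], g[l, ])
      if (!length(extra_g)) next
      if (is.na(ru[l])) {
        .warnf("repeat unit unknown for locus %s; size test skipped", l)
        next
      }
      if (any(abs(sort(extra_g) - sort(extra_r)) != ru[l])) return(FALSE)
    }
    TRUE
  }, logical(1))
  assignment
}

.multiset_diff <- function(a, b) {
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i]
  }
  a
}

#' SSR genotyping error rate from replicated samples
#'
#' Percentage rate: 100 x (number of discordant scores in two independent
#' analyses) / (number of scored markers x number of individuals analysed).
#' A discordant score is a (sample, locus) whose allele multiset differs
#' between the original and the replicate.
#'
#' @param genotypes long SSR table including replicated samples
#'   (`replicate_of` set).
#' @return A list with `rate_pct`, `n_discordant`, `n_compared`.
#' @export
genotyping_error_rate <- function(genotypes) {
  reps <- unique(genotypes[!is.na(genotypes$replicate_of),
                           c("sample_id", "replicate_of")])
  if (!nrow(reps)) .stopf("no replicate pairs: error rate undefined")
  wide <- ssr_wide(genotypes, include_replicates = TRUE)
  n_loci <- nrow(wide[[1L]])
  disc <- 0L
  for (i in seq_len(nrow(reps))) {
    g1 <- wide[[reps$sample_id[i]]]
    g2 <- wide[[reps$replicate_of[i]]]
    disc <- disc + sum(vapply(seq_len(n_loci), function(l)
      !identical(sort(g1[l, ]), sort(g2[l, ])), logical(1)))
  }
  n_comp <- n_loci * nrow(reps)
  list(rate_pct = 100 * disc / n_comp, n_discordant = disc,
       n_compared = n_comp)
}
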