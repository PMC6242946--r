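as_profile_df <- function(x) {
  if (inherits(x, "fragment_profile_set")) x <- x$profiles
  need <- c("primer_combo_id", "enzyme", "sample_id", "locus_id", "size",
            "present")
  miss <- setdiff(need, names(x))
  if (length(miss)) .stopf("fragment profiles lack columns: %s",
                           paste(miss, collapse = ", "))
  if (!all(x$enzyme %in% c("HpaII", "MspI")))
    .stopf("enzyme must be HpaII or MspI")
  x
}

## samples x (enzyme:locus) presence matrix plus locus metadata
profile_wide <- function(df) {
  key <- paste(df$enzyme, df$locus_id, sep = ":")
  samples <- unique(df$sample_id); keys <- unique(key)
  m <- matrix(NA_integer_, length(samples), length(keys),
              dimnames = list(samples, keys))
  ix <- cbind(match(df$sample_id, samples), match(key, keys))
  if (anyDuplicated(ix)) .stopf("duplicate (combo, enzyme, sample, locus) rows")
  m[ix] <- df$present
  first <- !duplicated(key)
  list(m = m,
       key_meta = data.frame(key = key[first],
                             enzyme = df$enzyme[first],
                             locus_id = df$locus_id[first],
                             primer_combo_id = df$primer_combo_id[first],
                             size = df$size[first],
                             stringsAsFactors = FALSE))
}

#' Replicate scoring error rate per primer combination
#'
#' For every replicated sample, presence/absence scores of the original and
#' the replicate are compared band by band, pooled over both enzymes. The
#' per-combination rate is mismatches / compared band scores; the mean over
#' combinations is returned alongside.
#'
#' @param profiles a fragment profile set ([simulate_msap()] output or a long
#'   data frame) containing replicated samples (`replicate_of` set).
#' @return List with `per_combo` (data frame: `primer_combo_id`,
#'   `n_mismatch`, `n_compared`, `rate`) and `mean_rate`.
#' @export
replicate_error_rate <- function(profiles) {
  df <- as_profile_df(profiles)
  if (!"replicate_of" %in% names(df) || all(is.na(df$replicate_of)))
    .stopf("no replicate pairs: error rate undefined")
  pairs <- unique(df[!is.na(df$replicate_of),
                     c("sample_id", "replicate_of")])
  w <- profile_wide(df)
  combos <- sort(unique(w$key_meta$primer_combo_id))
  combo_of_key <- w$key_meta$primer_combo_id[match(colnames(w$m),
                                                   w$key_meta$key)]
  mism <- comp <- setNames(numeric(length(combos)), combos)
  for (i in seq_len(nrow(pairs))) {
    a <- w$m[pairs$sample_id[i], ]; b <- w$m[pairs$replicate_of[i], ]
    ok <- !is.na(a) & !is.na(b)
    mism <- mism + tapply(as.numeric(a[ok] != b[ok]), combo_of_key[ok], sum,
                          default = 0)[as.character(combos)]
    comp <- comp + tapply(rep(1, sum(ok)), combo_of_key[ok], sum,
                          default = 0)[as.character(combos)]
  }
  undefined <- comp == 0
  if (any(undefined))
    .warnf("no replicate comparisons for combo(s) %s",
           paste(combos[undefined], collapse = ", "))
  rate <- ifelse(comp > 0, mism / comp, NA_real_)
  list(per_combo = data.frame(primer_combo_id = combos,
                              n_mismatch = as.vector(mism),
                              n_compared = as.vector(comp),
                              rate = as.vector(rate)),
       mean_rate = mean(rate, na.rm = TRUE))
}

#' Filter fragments on size range and remove singleton loci
#'
#' Drops loci whose fragment size falls outside `[min_size, max_size]`, then
#' drops singleton loci: loci present (in either enzyme) in exactly one
#' sample, or absent in exactly one sample, which are likely scoring
#' artefacts.
#'
#' @param profiles fragment profile set or long data frame.
#' @param min_size,max_size retained fragment size range in bp.
#' @return The filtered long data frame with a `"removal_log"` attribute
#'   listing each removed locus and the reason.
#' @export
filter_fragments <- function(profiles, min_size = 150, max_size = 600) {
  df <- as_profile_df(profiles)
  loci <- unique(df[c("locus_id", "size")])
  bad_size <- loci$locus_id[loci$size < min_size | loci$size > max_size]

  keep <- !df$locus_id %in% bad_size
  d2 <- df[keep, , drop = FALSE]
  ## presence per (sample, locus): present in either enzyme
  pres <- aggregate(present ~ locus_id + sample_id, d2, max)
  n_samples <- length(unique(pres$sample_id))
  n_pres <- tapply(pres$present, pres$locus_id, sum)
  singleton <- names(n_pres)[n_pres == 1 | n_pres == n_samples - 1]

  out <- d2[!d2$locus_id %in% singleton, , drop = FALSE]
  if (!nrow(out)) .stopf("no loci left after filtering")
  attr(out, "removal_log") <-
    data.frame(locus_id = c(bad_size, singleton),
               reason = rep(c("size_out_of_range", "singleton"),
                            c(length(bad_size), length(singleton))),
               stringsAsFactors = FALSE)
  out
}

#' Classify dual-enzyme presence patterns into methylation states
#'
#' HpaII and MspI recognise the same CCGG motif but differ in methylation
#' sensitivity, so the joint presence pattern encodes the methylation state:
#' (1,1) U unmethylated; (0,1) I internal-CG methylation; (1,0) H
#' hemimethylation; (0,0) A ambiguous (full methylation or loss of the
#' restriction site).
#'
#' @param profiles fragment profile set or long data frame with both enzymes
#'   scored for every (sample, locus).
#' @return Object of class `methylation_patterns`: list with `patterns`
#'   (samples x loci character matrix of U/I/H/A) and `loci` metadata.
#' @export
classify_patterns <- function(profiles) {
  df <- as_profile_df(profiles)
  hpa <- df[df$enzyme == "HpaII", ]
  msp <- df[df$enzyme == "MspI", ]
  key <- function(d) paste(d$sample_id, d$locus_id)
  if (!setequal(key(hpa), key(msp)))
    .stopf("HpaII and MspI tables are not aligned on (sample, locus)")
  msp <- msp[match(key(hpa), key(msp)), ]
  pat <- c("00" = "A", "01" = "I", "10" = "H", "11" = "U")[
    paste0(hpa$present, msp$present)]
  samples <- unique(hpa$sample_id); loci <- unique(hpa$locus_id)
  m <- matrix(NA_character_, length(samples), length(loci),
              dimnames = list(samples, loci))
  m[cbind(match(hpa$sample_id, samples), match(hpa$locus_id, loci))] <- pat
  first <- !duplicated(hpa$locus_id)
  structure(list(patterns = m,
                 loci = data.frame(locus_id = hpa$locus_id[first],
                                   primer_combo_id =
                                     hpa$primer_combo_id[first],
                                   size = hpa$size[first],
                                   stringsAsFactors = FALSE)),
            class = "methylation_patterns")
}

#' Flag methylation-susceptible loci with per-combination error thresholds
#'
#' A locus is methylation-susceptible when the fraction of samples showing a
#' HpaII/MspI discordance (pattern I, H or A) strictly exceeds the
#' per-combination threshold tau = 2e(1-e): the expected per-individual
#' probability that two independent scorings of one band mismatch when each
#' is flipped with the combination's error rate e.
#'
#' @param patterns output of [classify_patterns()].
#' @param error_rates output of [replicate_error_rate()], or a named vector
#'   of per-combination rates.
#' @param threshold optional named vector of per-combination threshold
#'   overrides (on the discordance-fraction scale).
#' @return Data frame: `locus_id`, `primer_combo_id`, `frac_discordant`,
#'   `threshold`, `is_susceptible`.
#' @export
select_methylation_susceptible <- function(patterns, error_rates,
                                           threshold = NULL) {
  e <- if (is.list(error_rates) && !is.null(error_rates$per_combo))
    setNames(error_rates$per_combo$rate,
             error_rates$per_combo$primer_combo_id)
  else error_rates
  combos <- as.character(patterns$loci$primer_combo_id)
  if (!all(combos %in% names(e)))
    .stopf("error rate missing for combo(s) %s",
           paste(setdiff(combos, names(e)), collapse = ", "))
  if (any(e[combos] >= 0.5)) .stopf("error rate >= 0.5: threshold invalid")
  tau <- 2 * e[combos] * (1 - e[combos])
  if (!is.null(threshold)) {
    ov <- intersect(names(threshold), combos)
    tau[match(ov, combos)] <- threshold[ov]
  }
  ## fraction of discordant patterns among non-missing samples per locus
  disc <- matrix(patterns$patterns %in% c("I", "H", "A"),
                 nrow(patterns$patterns))
  frac <- colSums(disc) / colSums(!is.na(patterns$patterns))
  data.frame(locus_id = patterns$loci$locus_id,
             primer_combo_id = patterns$loci$primer_combo_id,
             frac_discordant = frac,
             threshold = as.vector(tau),
             is_susceptible = frac > as.vector(tau),
             stringsAsFactors = FALSE)
}

#' Binarize methylation patterns into an epilocus matrix
#'
#' Restricted to methylation-susceptible loci: U scores 0 (unmethylated), I
#' and H score 1 (methylated). The ambiguous double absence A scores missing
#' under `missing_on_double_absence` (somatic mutation cannot be excluded) or
#' 0 under `absence_as_unmethylated` (somatic mutations ignored). A locus is
#' polymorphic when both states occur among its non-missing entries; loci
#' containing missing values are flagged so they can be removed before
#' diversity analyses.
#'
#' @param patterns output of [classify_patterns()].
#' @param flags output of [select_methylation_susceptible()].
#' @param mode `"missing_on_double_absence"` or `"absence_as_unmethylated"`.
#' @return Object of class `epilocus_matrix`: list with `states` (samples x
#'   loci 0/1/NA matrix), `loci` metadata (`is_methylation_susceptible`,
#'   `is_polymorphic`, `has_missing`) and `mode`.
#' @export
binarize <- function(patterns,
                     flags,
                     mode = c("missing_on_double_absence",
                              "absence_as_unmethylated")) {
  mode <- match.arg(mode)
  keep <- flags$locus_id[flags$is_susceptible]
  p <- patterns$patterns[, colnames(patterns$patterns) %in% keep,
                         drop = FALSE]
  map <- c(U = 0, I = 1, H = 1,
           A = if (mode == "missing_on_double_absence") NA else 0)
  states <- matrix(map[p], nrow(p), ncol(p), dimnames = dimnames(p))
  poly <- apply(states, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1
  })
  loci <- patterns$loci[match(colnames(states), patterns$loci$locus_id), ]
  loci$is_methylation_susceptible <- TRUE
  loci$is_polymorphic <- as.vector(poly)
  loci$has_missing <- as.vector(colSums(is.na(states)) > 0)
  rownames(loci) <- NULL
  structure(list(states = states, loci = loci, mode = mode),
            class = "epilocus_matrix")
}

#' Drop epiloci containing missing values
#'
#' @param epi an `epilocus_matrix`.
#' @return The matrix restricted to loci without missing entries.
#' @export
drop_missing_loci <- function(epi) {
  keep <- !epi$loci$has_missing
  structure(list(states = epi$states[, keep, drop = FALSE],
                 loci = epi$loci[keep, , drop = FALSE], mode = epi$mode),
            class = "epilocus_matrix")
}

#' Restrict an epilocus matrix to polymorphic loci
#'
#' @param epi an `epilocus_matrix`.
#' @return The matrix restricted to polymorphic loci.
#' @export
polymorphic_loci <- function(epi) {
  keep <- epi$loci$is_polymorphic
  structure(list(states = epi$states[, keep, drop = FALSE],
                 loci = epi$loci[keep, , drop = FALSE], mode = epi$mode),
            class = "epilocus_matrix")
}

#' Per-primer-combination summary with combined totals
#'
#' Mirrors the standard reporting table of an MS-AFLP study: per combination
#' the marker count, replicate scoring error rate, methylation-susceptible
#' marker count and polymorphic count with percentage, plus an "All
#' combined" row holding column sums and the mean error rate.
#'
#' @param per_combo data frame with columns `n_markers`, `error_rate`,
#'   `n_susceptible`, `n_polymorphic` (one row per combination; extra
#'   columns are preserved).
#' @return The table with a `pct_polymorphic` column and a final combined
#'   row.
#' @export
summarize_primer_combos <- function(per_combo) {
  df <- as.data.frame(per_combo)
  need <- c("n_markers", "error_rate", "n_susceptible", "n_polymorphic")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("summary lacks columns: %s",
                           paste(miss, collapse = ", "))
  df$pct_polymorphic <- 100 * df$n_polymorphic / df$n_susceptible
  total <- df[1, , drop = FALSE]
  total[1, ] <- NA
  if ("combo" %in% names(df)) total$combo <- NA
  if ("primer" %in% names(df)) total$primer <- "All combined"
  total$n_markers <- sum(df$n_markers)
  total$error_rate <- mean(df$error_rate)
  total$n_susceptible <- sum(df$n_susceptible)
  total$n_polymorphic <- sum(df$n_polymorphic)
  total$pct_polymorphic <- 100 * total$n_polymorphic / total$n_susceptible
  out <- rbind(df, total)
  rownames(out) <- NULL
  out
}

#' Run the full MS-AFLP scoring pipeline on fragment profiles
#'
#' Chains [replicate_error_rate()], [filter_fragments()],
#' [classify_patterns()], [select_methylation_susceptible()] and
#' [binarize()] (both scoring modes). Replicated samples enter the error
#' rates only and are excluded from the epilocus matrices.
#'
#' @param profiles fragment profile set or long data frame.
#' @param min_size,max_size fragment size window in bp.
#' @param threshold optional per-combination threshold overrides.
#' @return List with `error_rates`, `flags`, `epi_missing` (double absence
#'   as missing), `epi_zero` (double absence as unmethylated), `summary`
#'   (per-combination table with combined row) and `removal_log`.
#' @export
msap_score <- function(profiles, min_size = 150, max_size = 600,
                       threshold = NULL) {
  df <- as_profile_df(profiles)
  er <- replicate_error_rate(df)
  filt <- filter_fragments(df, min_size, max_size)
  removal_log <- attr(filt, "removal_log")
  if ("replicate_of" %in% names(filt))
    filt <- filt[is.na(filt$replicate_of), , drop = FALSE]
  pat <- classify_patterns(filt)
  flags <- select_methylation_susceptible(pat, er, threshold = threshold)
  epi_missing <- binarize(pat, flags, "missing_on_double_absence")
  epi_zero <- binarize(pat, flags, "absence_as_unmethylated")
  per_combo <- do.call(rbind, lapply(split(flags, flags$primer_combo_id),
    function(f) data.frame(combo = f$primer_combo_id[1],
                           n_markers = nrow(f),
                           error_rate =
                             er$per_combo$rate[match(f$primer_combo_id[1],
                               er$per_combo$primer_combo_id)],
                           n_susceptible = sum(f$is_susceptible))))
  per_combo$n_polymorphic <- vapply(per_combo$combo, function(cb)
    sum(epi_missing$loci$is_polymorphic[epi_missing$loci$primer_combo_id == cb]),
    numeric(1))
  list(error_rates = er, flags = flags, epi_missing = epi_missing,
       epi_zero = epi_zero,
       summary = summarize_primer_combos(per_combo),
       removal_log = removal_log)
}
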