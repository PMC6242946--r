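epi_states <- function(epi) {
  if (inherits(epi, "epilocus_matrix")) epi$states
  else as.matrix(epi)
}

#' Shannon diversity index over binary epiloci
#'
#' Per locus, with p the frequency of the methylated state among non-missing
#' samples, I = -(p log p + (1-p) log(1-p)) with 0 log 0 = 0. The mean and
#' standard deviation over loci summarise epigenetic diversity.
#'
#' @param epi an `epilocus_matrix` or binary samples x loci matrix (NA
#'   allowed).
#' @return List with `per_locus` (named vector), `mean`, `sd`.
#' @export
shannon_index <- function(epi) {
  m <- epi_states(epi)
  if (!ncol(m)) .stopf("no loci")
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na)) {
    .warnf("skipping %d all-missing loci", sum(all_na))
    m <- m[, !all_na, drop = FALSE]
  }
  p <- colMeans(m, na.rm = TRUE)
  h <- function(q) ifelse(q %in% c(0, 1), 0, -(q * log(q) + (1 - q) * log(1 - q)))
  per_locus <- setNames(h(p), colnames(m))
  list(per_locus = per_locus, mean = mean(per_locus), sd = sd(per_locus))
}

#' Group samples sharing an epigenotype, treating missing data as wildcards
#'
#' Two samples match when, at every locus, both are non-missing and equal or
#' at least one is missing. The relation is not transitive; groups are built
#' greedily in sample order (each sample joins the first existing group
#' whose every member it matches).
#'
#' @param epi an `epilocus_matrix` or binary matrix.
#' @return Data frame `sample_id`, `group`.
#' @export
match_epigenotypes <- function(epi) {
  m <- epi_states(epi)
  n <- nrow(m)
  matches <- function(i, j) {
    a <- m[i, ]; b <- m[j, ]
    ok <- !is.na(a) & !is.na(b)
    all(a[ok] == b[ok])
  }
  group <- integer(n)
  members <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (g in seq_along(members)) {
      if (all(vapply(members[[g]], matches, logical(1), i = i))) {
        members[[g]] <- c(members[[g]], i); group[i] <- g
        placed <- TRUE; break
      }
    }
    if (!placed) { members[[length(members) + 1L]] <- i
      group[i] <- length(members) }
  }
  data.frame(sample_id = rownames(m), group = group,
             stringsAsFactors = FALSE)
}

#' Pairwise epigenetic distances on binary epiloci
#'
#' Squared Euclidean distance on a binary matrix is the mismatch count over
#' loci where both samples are scored, rescaled by L / L_complete(pair)
#' (L = total loci) so pairs with missing data stay comparable.
#'
#' @param epi an `epilocus_matrix` or binary matrix.
#' @param squared return squared distances (AMOVA input) instead of
#'   Euclidean (PCoA/Mantel input).
#' @return A `dist_matrix`: list with `values` (symmetric matrix), `ids`,
#'   `metric_tag`.
#' @export
epi_distance <- function(epi, squared = FALSE) {
  m <- epi_states(epi)
  if (nrow(m) < 2L) .stopf("need at least two samples")
  obs <- !is.na(m)
  m0 <- m; m0[!obs] <- 0
  ## mismatches over jointly scored loci: x(1-y) + y(1-x), computed with
  ## missing entries zeroed and masked by the joint-observation counts
  cross <- m0 %*% t(m0)
  ones <- obs * 1
  tot1 <- m0 %*% t(ones)              # methylated in i and scored in j
  mism <- (tot1 - cross) + t(tot1 - cross)
  complete <- ones %*% t(ones)
  if (any(complete[upper.tri(complete)] == 0)) {
    bad <- which(complete == 0 & upper.tri(complete), arr.ind = TRUE)[1, ]
    .stopf("samples %s and %s share no scored locus",
           rownames(m)[bad[1]], rownames(m)[bad[2]])
  }
  d2 <- mism * ncol(m) / complete
  diag(d2) <- 0
  structure(list(values = if (squared) d2 else sqrt(d2),
                 ids = rownames(m),
                 metric_tag = if (squared) "squared_euclidean_epi"
                 else "euclidean_epi"),
            class = "dist_matrix")
}

#' Great-circle distances between home sites
#'
#' Haversine distances (Earth radius 6371.0088 km) between coordinates.
#'
#' @param sites data frame with `latitude`, `longitude` and an id column
#'   (`site_id`, or `sample_id`/`donor_id` if distances between trees are
#'   wanted).
#' @return A `dist_matrix` in kilometres.
#' @export
geo_distance <- function(sites) {
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    .stopf("coordinates out of range")
  idcol <- intersect(c("sample_id", "donor_id", "site_id"), names(sites))[1]
  if (is.na(idcol)) .stopf("no id column found")
  km <- geosphere::distm(cbind(sites$longitude, sites$latitude),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371008.8)) /
    1000
  dimnames(km) <- list(sites[[idcol]], sites[[idcol]])
  structure(list(values = km, ids = sites[[idcol]], metric_tag = "geo_km"),
            class = "dist_matrix")
}

as_dist_values <- function(d) {
  v <- if (inherits(d, "dist_matrix")) d$values else as.matrix(d)
  if (nrow(v) != ncol(v) || any(abs(v - t(v)) > 1e-8))
    .stopf("distance matrix must be square and symmetric")
  v
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of -D^2/2, eigendecomposition, and axes scaled by
#' the square root of each positive eigenvalue. Axis signs are fixed by
#' making the largest-magnitude loading of each axis positive, so results
#' are deterministic across linear-algebra backends.
#'
#' @param d a `dist_matrix` (Euclidean, not squared) or symmetric matrix.
#' @return List of class `pcoa_result` with `coordinates`, `eigenvalues`
#'   (all, descending) and `pct_variance` over positive eigenvalues.
#' @export
pcoa <- function(d) {
  v <- as_dist_values(d)
  n <- nrow(v)
  a <- -0.5 * v^2
  centered <- a - outer(rowMeans(a), rep(1, n)) -
    outer(rep(1, n), colMeans(a)) + mean(a)
  e <- eigen(centered, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(v)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 pct_variance = 100 * e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

amova_components <- function(d2, groups) {
  n <- length(groups)
  gs <- split(seq_len(n), groups)
  ss_pairs <- function(ix) {
    if (length(ix) < 2L) return(0)
    sum(d2[ix, ix][upper.tri(d2[ix, ix])])
  }
  ss_total <- ss_pairs(seq_len(n)) / n
  ss_within <- sum(vapply(gs, function(ix) ss_pairs(ix) / length(ix),
                          numeric(1)))
  ss_among <- ss_total - ss_within
  g <- length(gs)
  df_among <- g - 1L
  df_within <- n - g
  sizes <- lengths(gs)
  n0 <- (n - sum(sizes^2) / n) / df_among
  sigma2_within <- ss_within / df_within
  sigma2_among <- (ss_among / df_among - sigma2_within) / n0
  phi <- sigma2_among / (sigma2_among + sigma2_within)
  list(df_among = df_among, df_within = df_within,
       ss_among = ss_among, ss_within = ss_within,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       phi_st = phi)
}

#' One-level AMOVA with permutation test of Phi-ST
#'
#' Analysis of molecular variance on squared pairwise distances with samples
#' in groups (e.g. countries). Variance components use the standard
#' unequal-sample-size coefficient n0; Phi-ST is the among-group share of
#' the total molecular variance. Significance is assessed by permuting
#' individuals among groups; p = (#(perm Phi >= observed) + 1) /
#' (n_perm + 1). Groups of size 1 are dropped with a message.
#'
#' @param d a squared-distance `dist_matrix` (or symmetric matrix of squared
#'   distances).
#' @param groups factor or character vector of group labels, aligned with
#'   the distance ids.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return List of class `amova_result` with the degrees of freedom, sums of
#'   squares, variance components, `phi_st`, `p_value` and `n_permutations`.
#' @export
amova <- function(d, groups, n_perm = 999, seed = 1) {
  d2 <- as_dist_values(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d2))
    .stopf("groups must align with the distance matrix")
  sizes <- table(groups)
  drop <- names(sizes)[sizes < 2]
  if (length(drop)) {
    message("dropping ", length(drop), " group(s) of size 1: ",
            paste(drop, collapse = ", "))
    keep <- !groups %in% drop
    d2 <- d2[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L) .stopf("need at least two eligible groups")
  obs <- amova_components(d2, groups)
  set.seed(seed)
  n <- length(groups)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    phi_b <- amova_components(d2, groups[sample.int(n)])$phi_st
    if (phi_b >= obs$phi_st) exceed <- exceed + 1L
  }
  structure(c(obs, list(p_value = (exceed + 1) / (n_perm + 1),
                        n_permutations = n_perm)),
            class = "amova_result")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-tailed
#' permutation test (rows and columns of the second matrix permuted
#' jointly); p = (#(perm r >= observed) + 1) / (n_perm + 1).
#'
#' @param d1,d2 `dist_matrix` objects (or symmetric matrices) on the same
#'   ids in the same order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List of class `mantel_result`: `r`, `r_squared`, `p_value`,
#'   `n_permutations`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1) {
  if (inherits(d1, "dist_matrix") && inherits(d2, "dist_matrix") &&
      !identical(d1$ids, d2$ids))
    .stopf("distance matrices must share ids in the same order")
  v1 <- as_dist_values(d1); v2 <- as_dist_values(d2)
  if (!all(dim(v1) == dim(v2))) .stopf("dimension mismatch")
  lt <- lower.tri(v1)
  r_obs <- cor(v1[lt], v2[lt])
  set.seed(seed)
  n <- nrow(v1)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(v1[lt], v2[p, p][lt]) >= r_obs) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, r_squared = r_obs^2,
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "mantel_result")
}
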