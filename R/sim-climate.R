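## Table of admissible climate ranges for the simulated home sites
## (min, max) per variable; values outside are clipped.
climate_ranges <- function() {
  list(latitude   = c(40.752, 55.890),
       longitude  = c(-4.593, 25.457),
       t_jan      = c(-1.400, 8.024),
       t_mar      = c(3.87, 10.83),
       t_jul      = c(14.93, 26.20),
       precip     = c(23.274, 101.065),
       frost_days = c(8.497, 26.436),
       pet        = c(22.746, 43.879),
       cn_topsoil = c(8, 16))
}

#' Simulate home sites with mutually correlated climate covariates
#'
#' Generates one row per home site with geography and climate covariates.
#' Winter-related variables (January and March temperature, frost-day
#' frequency, potential evapotranspiration) share a latent winter-mildness
#' factor with loadings of 0.96, so each of those pairs has squared
#' correlation above 0.8 in expectation; July temperature loads weakly and
#' precipitation and topsoil C:N are essentially independent. Values are
#' drawn around the midpoint of the admissible range with standard deviation
#' `sd_frac` times the range width, then clipped to the range.
#'
#' @param config a [sim_config()].
#' @param sd_frac spread of each covariate as a fraction of its admissible
#'   range; 0 gives identical (degenerate) rows.
#' @return A `climate_table` data frame with columns `site_id`, `country`,
#'   `latitude`, `longitude`, `t_jan`, `t_mar`, `t_jul`, `precip`,
#'   `frost_days`, `pet`, `cn_topsoil`.
#' @export
simulate_sites <- function(config, sd_frac = 0.2) {
  validate_sim_config(config)
  n <- config$n_sites
  set.seed(.substream(config$seed, "sites"))

  z <- rnorm(n)                      # latent winter mildness (standardized)
  load1 <- function(l) l * z + sqrt(1 - l^2) * rnorm(n)
  std <- list(t_jan      = load1(0.96),
              t_mar      = load1(0.96),
              frost_days = -load1(0.96),
              pet        = load1(0.96),
              t_jul      = load1(0.5),
              precip     = load1(0.2),
              cn_topsoil = rnorm(n),
              latitude   = -load1(0.7),
              longitude  = rnorm(n))
  rng <- climate_ranges()
  cols <- lapply(names(std), function(v) {
    r <- rng[[v]]
    mid <- mean(r); sdv <- sd_frac * diff(r)
    pmin(pmax(mid + sdv * std[[v]], r[1]), r[2])
  })
  names(cols) <- names(std)

  n_countries <- max(2L, ceiling(n / 2))
  out <- data.frame(site_id = sprintf("S%02d", seq_len(n)),
                    country = sprintf("C%02d",
                                      ((seq_len(n) - 1L) %% n_countries) + 1L),
                    cols[c("latitude", "longitude", "t_jan", "t_mar", "t_jul",
                           "precip", "frost_days", "pet", "cn_topsoil")],
                    stringsAsFactors = FALSE)
  class(out) <- c("climate_table", "data.frame")
  out
}

validate_climate_table <- function(sites) {
  need <- c("site_id", "latitude", "longitude", "t_jan", "t_jul", "pet")
  miss <- setdiff(need, names(sites))
  if (length(miss)) .stopf("climate table lacks columns: %s",
                           paste(miss, collapse = ", "))
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    .stopf("coordinates out of range")
  invisible(sites)
}
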