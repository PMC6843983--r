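#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the simulated study: a network of weather stations
#' recording daily maximum/minimum temperature with a seasonal cycle, a
#' linear multi-year trend and spatially correlated station baselines; a
#' regular lattice of cells with topographic, proximity and land-use
#' covariates; and per-cell species counts drawn from the log-linear Poisson
#' model with a Matern spatial field and an iid heterogeneity effect.
#'
#' Defaults emulate the study conditions: 190 stations, daily series for
#' 2007-2011, 5-year trends of 0.159 (maximum) and 0.332 (minimum) degrees C,
#' a 10 km lattice, field sd 0.5 and iid sd 0.2 on the log-count scale.
#'
#' @param n_stations number of weather stations.
#' @param lattice_nx,lattice_ny lattice dimensions (>= 2 each).
#' @param spacing cell spacing in metres.
#' @param date_start,date_end first and last day of the daily series.
#' @param trend named vector `c(tmax=, tmin=)`: linear increase in degrees C
#'   per 5 years injected into each variable.
#' @param seasonal_amplitude amplitude (degrees C) of the annual harmonic.
#' @param station_mean named vector `c(tmax=, tmin=)` of baseline means.
#' @param matern_temp [matern_spec()] of the spatially correlated station
#'   baseline effect (shared by both variables).
#' @param nugget_sd sd (degrees C) of independent day-to-day noise.
#' @param beta named coefficient vector on the log-count scale; names must
#'   match design columns of [build_design()] (e.g. `"(Intercept)"`,
#'   `"landuse8:dense_forest"`, `"dist_urban:Q2"`); unnamed columns get 0.
#' @param matern_count [matern_spec()] of the spatial field in the count
#'   model (set `sd = 0` to disable).
#' @param iid_sd sd of the unstructured per-cell effect (log scale).
#' @param landuse_probs category probabilities for the 8 land-use levels.
#' @param mu_log_bound generation aborts if any `|log mu|` exceeds this.
#' @param seed integer master seed; per-stage substreams are derived from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_stations = 190L,
                             lattice_nx = 10L, lattice_ny = 10L,
                             spacing = 10000,
                             date_start = as.Date("2007-01-01"),
                             date_end = as.Date("2011-12-31"),
                             trend = c(tmax = 0.159, tmin = 0.332),
                             seasonal_amplitude = 8,
                             station_mean = c(tmax = 20, tmin = 10),
                             matern_temp = matern_spec(range = 50000, sd = 1.5),
                             nugget_sd = 2,
                             beta = c("(Intercept)" = log(150)),
                             matern_count = matern_spec(range = 30000, sd = 0.5),
                             iid_sd = 0.2,
                             landuse_probs = c(other = 0.25, coniferous_forest = 0.15,
                                               dense_forest = 0.20, fruit_trees = 0.10,
                                               artificial_vegetated = 0.05,
                                               transitional_scrub = 0.10,
                                               natural_grassland = 0.07,
                                               mixed_forest = 0.08),
                             mu_log_bound = 30,
                             seed = 1L) {
  cfg <- list(n_stations = as.integer(n_stations),
              lattice_nx = as.integer(lattice_nx), lattice_ny = as.integer(lattice_ny),
              spacing = spacing,
              date_start = as.Date(date_start), date_end = as.Date(date_end),
              trend = trend, seasonal_amplitude = seasonal_amplitude,
              station_mean = station_mean,
              matern_temp = matern_temp, nugget_sd = nugget_sd,
              beta = beta, matern_count = matern_count, iid_sd = iid_sd,
              landuse_probs = landuse_probs, mu_log_bound = mu_log_bound,
              seed = as.integer(seed))
  if (cfg$lattice_nx < 2 || cfg$lattice_ny < 2 || cfg$lattice_nx * cfg$lattice_ny < 4)
    stop("generator_config: lattice must have at least 4 cells", call. = FALSE)
  if (cfg$spacing <= 0) stop("generator_config: spacing must be > 0", call. = FALSE)
  if (cfg$date_end <= cfg$date_start)
    stop("generator_config: date_end must be after date_start", call. = FALSE)
  if (cfg$nugget_sd < 0 || cfg$iid_sd < 0 || cfg$seasonal_amplitude < 0)
    stop("generator_config: standard deviations and amplitude must be >= 0", call. = FALSE)
  if (!all(c("tmax", "tmin") %in% names(cfg$trend)))
    stop("generator_config: trend must be named c(tmax=, tmin=)", call. = FALSE)
  if (!setequal(names(cfg$landuse_probs), landuse_levels()))
    stop("generator_config: landuse_probs must name all 8 land-use levels", call. = FALSE)
  structure(cfg, class = "generator_config")
}

# deterministic per-stage substream of the master seed
stage_seed <- function(config, stage) {
  offs <- c(lattice = 11L, stations = 23L, counts = 37L)
  (config$seed * 1009L + offs[[stage]]) %% 2147483647L
}

#' Generate a regular lattice of cells with covariates
#'
#' Centroids form an `nx * ny` grid with the configured spacing.  Covariates
#' are drawn from fixed realistic families: half-normal slope, uniform aspect
#' and hillshade on `[0, 360)`, gamma elevation, lognormal distances to urban
#' areas / roads / railways, and a categorical 8-level land use.
#'
#' @param config a [generator_config()].
#' @param seed optional override of the lattice substream seed.
#' @return data.frame with one row per cell: `cell_id`, centroid `x`, `y`
#'   (metres), `slope`, `aspect`, `hillshade` (degrees), `elevation` (m),
#'   `dist_urban`, `dist_road`, `dist_rail` (m), `landuse8` (factor) and an
#'   `species_count` column initialised to NA.
#' @export
generate_lattice <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(if (is.null(seed)) stage_seed(config, "lattice") else seed)
  nx <- config$lattice_nx; ny <- config$lattice_ny; h <- config$spacing
  n <- nx * ny
  ix <- (seq_len(n) - 1L) %% nx
  iy <- (seq_len(n) - 1L) %/% nx
  lev <- landuse_levels()
  data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    x = ix * h, y = iy * h,
    slope = abs(stats::rnorm(n, 0, 8)),
    aspect = stats::runif(n, 0, 360),
    hillshade = stats::runif(n, 0, 360),
    elevation = stats::rgamma(n, shape = 2, scale = 300),
    dist_urban = stats::rlnorm(n, log(2000), 1),
    dist_road = stats::rlnorm(n, log(1000), 1),
    dist_rail = stats::rlnorm(n, log(5000), 1),
    landuse8 = factor(sample(lev, n, replace = TRUE,
                             prob = config$landuse_probs[lev]), levels = lev),
    species_count = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Generate daily station temperature series
#'
#' Each record is `station mean + annual harmonic + linear trend + spatially
#' correlated station baseline + independent noise`, per variable.  Station
#' locations are uniform over the lattice bounding box; the station baseline
#' effect is one draw of a smoothness-1 Matern field (dense covariance,
#' shared between tmax and tmin).  In the rare event that independent noise
#' makes tmax fall below tmin on a given day, tmax is raised to tmin.
#'
#' @param config a [generator_config()].
#' @param seed optional override of the station substream seed.
#' @return data.frame with columns `station_id`, `x`, `y`, `date`, `tmax`,
#'   `tmin`; one row per station per day.
#' @export
generate_station_series <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(if (is.null(seed)) stage_seed(config, "stations") else seed)
  ns <- config$n_stations
  width <- config$lattice_nx * config$spacing
  height <- config$lattice_ny * config$spacing
  sx <- stats::runif(ns, 0, width)
  sy <- stats::runif(ns, 0, height)

  # spatially correlated baseline via dense Matern covariance
  if (config$matern_temp$sd > 0 && ns > 1) {
    D <- as.matrix(stats::dist(cbind(sx, sy)))
    S <- config$matern_temp$sd^2 * matern1_correlation(D, config$matern_temp$range)
    diag(S) <- config$matern_temp$sd^2
    L <- chol(S + diag(1e-8 * config$matern_temp$sd^2, ns))
    baseline <- drop(crossprod(L, stats::rnorm(ns)))
  } else baseline <- rep(0, ns)

  dates <- seq(config$date_start, config$date_end, by = "day")
  nd <- length(dates)
  t_years <- as.numeric(dates - config$date_start) / 365.25
  t_years <- t_years - mean(t_years)
  doy <- as.numeric(format(dates, "%j"))
  # annual harmonic peaking in late July (day ~205)
  seas <- config$seasonal_amplitude * cos(2 * pi * (doy - 205) / 365.25)

  station_id <- rep(sprintf("s%03d", seq_len(ns)), each = nd)
  base <- rep(baseline, each = nd)
  seas_all <- rep(seas, times = ns)
  t_all <- rep(t_years, times = ns)
  nrec <- ns * nd
  tmax <- config$station_mean[["tmax"]] + base + seas_all +
    (config$trend[["tmax"]] / 5) * t_all + stats::rnorm(nrec, 0, config$nugget_sd)
  tmin <- config$station_mean[["tmin"]] + base + seas_all +
    (config$trend[["tmin"]] / 5) * t_all + stats::rnorm(nrec, 0, config$nugget_sd)
  tmax <- pmax(tmax, tmin)
  data.frame(station_id = station_id,
             x = rep(sx, each = nd), y = rep(sy, each = nd),
             date = rep(dates, times = ns),
             tmax = tmax, tmin = tmin, stringsAsFactors = FALSE)
}

# expand a named coefficient vector onto the design columns (missing -> 0)
expand_beta <- function(beta, design_cols) {
  unknown <- setdiff(names(beta), design_cols)
  if (length(unknown))
    stop("beta names not in the design: ", paste(unknown, collapse = ", "), call. = FALSE)
  full <- stats::setNames(rep(0, length(design_cols)), design_cols)
  full[names(beta)] <- beta
  full
}

#' Generate species counts on a lattice from the log-linear Poisson model
#'
#' Draws `O_i ~ Poisson(mu_i)` with
#' `log mu_i = x_i' beta + u_i + v_i`, where `x_i` is the categorised design
#' row of cell `i`, `u` one draw of the SPDE Matern field and `v` iid
#' Gaussian heterogeneity.  The realised truth is recorded for parameter
#' recovery studies.
#'
#' @param lattice cell data.frame from [generate_lattice()].
#' @param config a [generator_config()]; `config$beta`, `config$matern_count`
#'   and `config$iid_sd` define the generative model.
#' @param schemes design schemes (default [default_design_schemes()]).
#' @param seed optional override of the counts substream seed.
#' @return list with `lattice` (input with `species_count` filled in) and
#'   `truth` (class `synthetic_truth`): `beta` on design columns, per-cell
#'   `u`, `v`, `mu`, the hyperparameters used, and fitted design `schemes`.
#' @export
generate_species_counts <- function(lattice, config,
                                    schemes = default_design_schemes(),
                                    seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(if (is.null(seed)) stage_seed(config, "counts") else seed)
  des <- build_design(lattice, schemes)
  beta <- expand_beta(config$beta, colnames(des$X))
  eta <- drop(des$X %*% beta)
  n <- nrow(lattice)

  if (config$matern_count$sd > 0) {
    prec <- build_precision(config$lattice_nx, config$lattice_ny,
                            config$spacing, config$matern_count)
    u <- sample_field(prec, seed = NULL, real_only = TRUE)
    # order of sample_field output follows mesh node order = row-major grid,
    # matching generate_lattice cell order
  } else u <- rep(0, n)
  v <- if (config$iid_sd > 0) stats::rnorm(n, 0, config$iid_sd) else rep(0, n)

  log_mu <- eta + u + v
  if (any(abs(log_mu) > config$mu_log_bound))
    stop("generate_species_counts: |log mu| exceeds bound (pathological coefficients)",
         call. = FALSE)
  mu <- exp(log_mu)
  counts <- stats::rpois(n, mu)
  lattice$species_count <- counts
  truth <- structure(list(beta = beta, u = u, v = v, mu = mu,
                          range = config$matern_count$range,
                          sigma_u = config$matern_count$sd,
                          sigma_v = config$iid_sd,
                          schemes = des$schemes, seed = config$seed),
                     class = "synthetic_truth")
  list(lattice = lattice, truth = truth)
}

#' Write the realised synthetic truth as a tidy CSV
#'
#' @param truth a `synthetic_truth`.
#' @param path output CSV path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(truth$mu)
  df <- rbind(
    data.frame(unit = names(truth$beta), parameter = "beta", value = unname(truth$beta)),
    data.frame(unit = sprintf("c%04d", seq_len(n)), parameter = "u", value = truth$u),
    data.frame(unit = sprintf("c%04d", seq_len(n)), parameter = "v", value = truth$v),
    data.frame(unit = sprintf("c%04d", seq_len(n)), parameter = "mu", value = truth$mu),
    data.frame(unit = c("range", "sigma_u", "sigma_v", "seed"), parameter = "hyper",
               value = c(truth$range, truth$sigma_u, truth$sigma_v, truth$seed))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
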