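#' Meteorological season of a date
#'
#' Month-based seasons: Mar-May spring, Jun-Aug summer, Sep-Nov autumn,
#' Dec-Feb winter.
#'
#' @param date a `Date` vector.
#' @return factor with levels spring, summer, autumn, winter.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  factor(s, levels = c("spring", "summer", "autumn", "winter"))
}

#' Year-over-year daily temperature differences for one station
#'
#' For every calendar day present in both year `t` and year `t - 1`, the
#' difference `value(t) - value(t - 1)` of the chosen variable.  Feb 29 is
#' excluded (it has no same-day counterpart); missing values are skipped.
#'
#' @param series data.frame with columns `date` plus the variable column
#'   (`tmax` or `tmin`) for a single station.
#' @param variable `"tmax"` or `"tmin"`.
#' @return data.frame with `date` (the later day of each pair) and `diff`.
#' @export
yoy_differences <- function(series, variable = c("tmax", "tmin")) {
  variable <- match.arg(variable)
  d <- as.Date(series$date)
  yrs <- as.integer(format(d, "%Y"))
  if (length(unique(yrs)) < 2)
    stop("yoy_differences: series must span at least 2 calendar years", call. = FALSE)
  md <- format(d, "%m-%d")
  keep <- md != "02-29" & !is.na(series[[variable]])
  d <- d[keep]; yrs <- yrs[keep]; md <- md[keep]
  val <- series[[variable]][keep]
  cur <- paste(yrs, md)
  prev <- paste(yrs - 1L, md)
  idx <- match(prev, cur)
  ok <- !is.na(idx)
  out <- data.frame(date = d[ok], diff = val[ok] - val[idx[ok]])
  out[order(out$date), , drop = FALSE]
}

#' Year-over-year differences for a multi-station table
#'
#' @param stations data.frame with `station_id`, `date` and the variable.
#' @param variable `"tmax"` or `"tmin"`.
#' @return data.frame with `station_id`, `date`, `diff`.
#' @export
yoy_differences_all <- function(stations, variable = c("tmax", "tmin")) {
  variable <- match.arg(variable)
  parts <- lapply(split(stations, stations$station_id), function(s) {
    d <- yoy_differences(s, variable)
    if (nrow(d)) d$station_id <- s$station_id[1]
    d
  })
  out <- do.call(rbind, parts[vapply(parts, nrow, 0L) > 0])
  rownames(out) <- NULL
  out[, c("station_id", "date", "diff")]
}

#' Seasonal and annual summaries of year-over-year differences
#'
#' @param differences data.frame with `date` and `diff` (e.g. from
#'   [yoy_differences()]).
#' @param stratify if TRUE (default) report the four seasons plus the annual
#'   row; if FALSE only the annual row.
#' @return data.frame with `season`, `mean_variation` and `n_pairs`; strata
#'   with no pairs carry `n_pairs = 0` and `NA` mean.
#' @export
summarize_variation <- function(differences, stratify = TRUE) {
  if (nrow(differences) == 0)
    stop("summarize_variation: no differences supplied", call. = FALSE)
  seas_levels <- c("spring", "summer", "autumn", "winter")
  out <- data.frame(season = character(0), mean_variation = numeric(0),
                    n_pairs = integer(0), stringsAsFactors = FALSE)
  if (stratify) {
    s <- season_of(differences$date)
    for (lev in seas_levels) {
      d <- differences$diff[s == lev]
      out <- rbind(out, data.frame(
        season = lev,
        mean_variation = if (length(d)) mean(d) else NA_real_,
        n_pairs = length(d)))
    }
  }
  rbind(out, data.frame(season = "annual",
                        mean_variation = mean(differences$diff),
                        n_pairs = nrow(differences)))
}

#' Fit the multi-year temperature trend
#'
#' Gaussian model `temperature = station intercept + annual harmonic(s) +
#' linear trend * time + noise`.  With station effects enabled the station
#' intercepts are a random effect fitted by REML (lme4); under flat priors
#' the REML fixed-effect distribution is the approximate posterior, so the
#' summaries reported (mean, sd, 2.5/97.5% quantiles) are approximate
#' Bayesian posterior summaries.  With `station_effects = FALSE` and
#' `harmonics = 0` the fit reduces to ordinary least squares on time alone.
#'
#' @param stations data.frame with `station_id`, `date` and the variable.
#' @param variable `"tmax"` or `"tmin"`.
#' @param harmonics number of annual harmonic pairs (default 1).
#' @param station_effects include a per-station random intercept.
#' @return object of class `trend_fit`: `trend` (per year: mean, sd, q2.5,
#'   q97.5), `trend_5yr` (same, times 5), `harmonics` (coefficients),
#'   `station_sd`, `residual_sd`, `n_obs`.
#' @export
fit_trend <- function(stations, variable = c("tmax", "tmin"),
                      harmonics = 1L, station_effects = TRUE) {
  variable <- match.arg(variable)
  d <- as.Date(stations$date)
  if (length(unique(d)) < 2)
    stop("fit_trend: need at least 2 distinct days (rank-deficient design)", call. = FALSE)
  if (station_effects && length(unique(stations$station_id)) < 2)
    stop("fit_trend: need >= 2 stations for station effects", call. = FALSE)
  y <- stations[[variable]]
  keep <- !is.na(y)
  y <- y[keep]; d <- d[keep]
  t_years <- as.numeric(d - min(d)) / 365.25
  t_years <- t_years - mean(t_years)
  df <- data.frame(y = y, t = t_years)
  if (harmonics > 0) {
    doy <- as.numeric(format(d, "%j")) / 365.25
    for (h in seq_len(harmonics)) {
      df[[paste0("s", h)]] <- sin(2 * pi * h * doy)
      df[[paste0("c", h)]] <- cos(2 * pi * h * doy)
    }
  }
  harm_terms <- setdiff(names(df), c("y", "t"))
  rhs <- paste(c("t", harm_terms), collapse = " + ")
  if (station_effects) {
    df$station <- factor(stations$station_id[keep])
    fm <- stats::as.formula(paste("y ~", rhs, "+ (1 | station)"))
    fit <- lme4::lmer(fm, data = df, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    est <- lme4::fixef(fit)[["t"]]
    se <- sqrt(Matrix::diag(as.matrix(stats::vcov(fit)))[
      which(names(lme4::fixef(fit)) == "t")])
    vc <- as.data.frame(lme4::VarCorr(fit))
    station_sd <- vc$sdcor[vc$grp == "station"][1]
    residual_sd <- vc$sdcor[vc$grp == "Residual"][1]
    harm_coef <- lme4::fixef(fit)[harm_terms]
  } else {
    fm <- stats::as.formula(paste("y ~", rhs))
    fit <- stats::lm(fm, data = df)
    est <- stats::coef(fit)[["t"]]
    se <- summary(fit)$coefficients["t", "Std. Error"]
    station_sd <- 0
    residual_sd <- summary(fit)$sigma
    harm_coef <- stats::coef(fit)[harm_terms]
  }
  est <- unname(est); se <- unname(se)
  q <- stats::qnorm(c(0.025, 0.975))
  tr <- c(mean = est, sd = se, q2.5 = est + q[1] * se, q97.5 = est + q[2] * se)
  structure(list(variable = variable,
                 trend = tr,
                 trend_5yr = tr * c(5, 5, 5, 5),
                 harmonics = harm_coef,
                 station_sd = station_sd,
                 residual_sd = residual_sd,
                 n_obs = length(y)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Temperature trend (%s): %.4f degC/yr (95%% CrI %.4f, %.4f)\n",
              x$variable, x$trend[["mean"]], x$trend[["q2.5"]], x$trend[["q97.5"]]))
  cat(sprintf("  per 5 years: %.4f (95%% CrI %.4f, %.4f); station sd %.3f, residual sd %.3f, n = %d\n",
              x$trend_5yr[["mean"]], x$trend_5yr[["q2.5"]], x$trend_5yr[["q97.5"]],
              x$station_sd, x$residual_sd, x$n_obs))
  invisible(x)
}

#' Krige station values onto lattice cell centroids
#'
#' Gaussian-process prediction with a smoothness-1 Matern covariance plus a
#' nugget: the constant mean is estimated by generalised least squares and
#' each centroid gets the GP conditional mean and conditional sd given the
#' station values.
#'
#' @param stations data.frame with `x`, `y`, `value` (one row per station,
#'   e.g. a station-level mean year-over-year variation).
#' @param lattice data.frame of cells with centroid `x`, `y`.
#' @param matern_spec a [matern_spec()] with positive range and sd.
#' @param nugget_sd measurement-error sd added to the station covariance
#'   diagonal.
#' @param estimate if TRUE, (range, sd, nugget) are re-estimated by maximum
#'   likelihood starting from the supplied values.
#' @return data.frame with `cell_id` (if present on `lattice`), `pred` and
#'   `pred_sd`.
#' @export
krige_to_cells <- function(stations, lattice, matern_spec, nugget_sd = 0,
                           estimate = FALSE) {
  stopifnot(inherits(matern_spec, "matern_spec"))
  ns <- nrow(stations)
  if (ns < 3) stop("krige_to_cells: need at least 3 stations", call. = FALSE)
  if (matern_spec$range <= 0 || matern_spec$sd <= 0)
    stop("krige_to_cells: range and sd must be positive", call. = FALSE)
  z <- stations$value
  if (anyNA(z)) stop("krige_to_cells: NA station values", call. = FALSE)

  if (estimate) {
    nll <- function(par) {
      rng <- exp(par[1]); sdv <- exp(par[2]); ng <- exp(par[3])
      K <- sdv^2 * matern1_correlation(as.matrix(stats::dist(stations[, c("x", "y")])), rng) +
        diag(ng^2 + 1e-10 * sdv^2, ns)
      L <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(L)) return(1e10)
      one <- rep(1, ns)
      Kz <- backsolve(L, forwardsolve(t(L), z))
      K1 <- backsolve(L, forwardsolve(t(L), one))
      mhat <- sum(K1 * z) / sum(K1 * one)
      r <- z - mhat
      Kr <- backsolve(L, forwardsolve(t(L), r))
      sum(log(diag(L))) + 0.5 * sum(r * Kr)
    }
    op <- stats::optim(log(c(matern_spec$range, matern_spec$sd,
                             max(nugget_sd, 1e-3 * matern_spec$sd))),
                       nll, method = "Nelder-Mead",
                       control = list(maxit = 400))
    matern_spec <- matern_spec(exp(op$par[1]), exp(op$par[2]))
    nugget_sd <- exp(op$par[3])
  }

  D <- as.matrix(stats::dist(stations[, c("x", "y")]))
  K <- matern_spec$sd^2 * matern1_correlation(D, matern_spec$range) +
    diag(nugget_sd^2, ns)
  L <- tryCatch(chol(K), error = function(e)
    stop("krige_to_cells: station covariance is ill-conditioned ",
         "(duplicate coordinates with zero nugget?)", call. = FALSE))
  Kinv_solve <- function(b) backsolve(L, forwardsolve(t(L), b))
  one <- rep(1, ns)
  K1 <- Kinv_solve(one)
  mhat <- sum(K1 * z) / sum(K1 * one)
  alpha <- Kinv_solve(z - mhat)

  dx <- outer(lattice$x, stations$x, "-")
  dy <- outer(lattice$y, stations$y, "-")
  Kc <- matern_spec$sd^2 *
    matern1_correlation(sqrt(dx^2 + dy^2), matern_spec$range)
  pred <- mhat + drop(Kc %*% alpha)
  KiKc <- Kinv_solve(t(Kc))
  cvar <- matern_spec$sd^2 - colSums(t(Kc) * KiKc)
  out <- data.frame(pred = pred, pred_sd = sqrt(pmax(cvar, 0)))
  if ("cell_id" %in% names(lattice)) out <- cbind(cell_id = lattice$cell_id, out)
  out
}

#' Station-level mean year-over-year variation for a station table
#'
#' Convenience wrapper: per-station [yoy_differences()] then the mean over
#' the requested season stratum.
#'
#' @param stations station data.frame (`station_id`, `x`, `y`, `date`,
#'   variable columns).
#' @param variable `"tmax"` or `"tmin"`.
#' @param season one of `"annual"`, `"spring"`, `"summer"`, `"autumn"`,
#'   `"winter"`.
#' @return data.frame with `station_id`, `x`, `y`, `value`, `n_pairs`.
#' @export
station_variation <- function(stations, variable = c("tmax", "tmin"),
                              season = "annual") {
  variable <- match.arg(variable)
  parts <- lapply(split(stations, stations$station_id), function(s) {
    d <- yoy_differences(s, variable)
    if (season != "annual") d <- d[season_of(d$date) == season, , drop = FALSE]
    data.frame(station_id = s$station_id[1], x = s$x[1], y = s$y[1],
               value = if (nrow(d)) mean(d$diff) else NA_real_,
               n_pairs = nrow(d))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
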