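# shared fixtures and independent brute-force oracles

# a single-station series over the given dates with supplied values
make_series <- function(dates, tmax, tmin = tmax - 8) {
  data.frame(station_id = "s1", x = 0, y = 0, date = as.Date(dates),
             tmax = tmax, tmin = tmin, stringsAsFactors = FALSE)
}

# explicit double-loop oracle for year-over-year differences: for every
# (month, day) pair present in consecutive years, value(t) - value(t-1)
oracle_yoy <- function(series, variable) {
  d <- as.Date(series$date)
  val <- series[[variable]]
  yrs <- as.integer(format(d, "%Y"))
  mds <- format(d, "%m-%d")
  out <- data.frame(date = as.Date(character(0)), diff = numeric(0))
  for (i in seq_along(d)) {
    if (mds[i] == "02-29" || is.na(val[i])) next
    j <- which(yrs == yrs[i] - 1L & mds == mds[i] & mds != "02-29")
    if (length(j) == 1L && !is.na(val[j])) {
      out <- rbind(out, data.frame(date = d[i], diff = val[i] - val[j]))
    }
  }
  out[order(out$date), , drop = FALSE]
}

# sort-and-slice oracle for quantile group sizes
oracle_quantile_counts <- function(values, k) {
  n <- length(values)
  br <- unname(stats::quantile(values, probs = seq(0, 1, length.out = k + 1), type = 7))
  cat <- cut(values, br, labels = FALSE, right = TRUE, include.lowest = TRUE)
  tabulate(cat, nbins = k)
}

# reduced design for small lattices: 2 quintile variables + land use
small_schemes <- function() {
  c(lapply(c("slope", "dist_urban"),
           function(v) list(variable = v, type = "quantile", k = 5L)),
    list(list(variable = "landuse8", type = "categorical",
              levels = landuse_levels())))
}

# dense multivariate-normal log density from a precision matrix
mvtnorm_logdens <- function(u, Q) {
  m <- length(u)
  -0.5 * m * log(2 * pi) + 0.5 * determinant(Q, logarithm = TRUE)$modulus -
    0.5 * drop(u %*% Q %*% u)
}

# independent evaluation of K_1 by quadrature of its integral representation,
# K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt
bessel_k1_quadrature <- function(x) {
  vapply(x, function(xi)
    stats::integrate(function(t) exp(-xi * cosh(t)) * cosh(t),
                     0, 30, rel.tol = 1e-10)$value, 0)
}
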