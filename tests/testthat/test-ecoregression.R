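test_that("log joint density matches hand computation and brute force", {
  # single cell, count 3, log mu = 0, flat priors: 3*0 - 1 - log(3!)
  lp <- eco_log_joint(beta = 0, y = 3, X = matrix(1, 1, 1))
  expect_equal(lp, -1 - log(6))

  # intercept/field confounding leaves the likelihood term unchanged
  prec <- build_precision(3, 3, 1, matern_spec(2, 1), ghost = 1)
  m <- nrow(prec$Q)
  set.seed(2)
  u <- stats::rnorm(m, 0, 0.1)
  y <- c(4, 6, 5, 7, 3, 5, 6, 4, 5)
  X <- matrix(1, 9, 1)
  ll_only <- function(beta, u) {
    eta <- drop(X %*% beta) + u[prec$real]
    sum(y * eta - exp(eta) - lgamma(y + 1))
  }
  cshift <- 0.37
  u_shift <- u - cshift
  expect_equal(ll_only(1 + cshift, u_shift), ll_only(1, u))
})

test_that("log joint equals an independent term-by-term evaluation", {
  prec <- build_precision(2, 2, 1, matern_spec(2, 0.8), ghost = 0)
  m <- nrow(prec$Q)
  set.seed(9)
  u <- stats::rnorm(m, 0, 0.3)
  v <- stats::rnorm(4, 0, 0.2)
  beta <- c(1.2, -0.4)
  X <- cbind(1, c(0, 1, 0, 1))
  y <- c(3, 5, 2, 7)
  got <- eco_log_joint(beta, y, X, u = u, v = v, precision = prec,
                       sigma_v = 0.25, beta_prior_sd = 5)
  eta <- drop(X %*% beta) + u[prec$real] + v
  want <- sum(stats::dpois(y, exp(eta), log = TRUE))
  Qd <- as.matrix(prec$Q)
  want <- want + as.numeric(mvtnorm_logdens(u, Qd))
  want <- want + sum(stats::dnorm(v, 0, 0.25, log = TRUE))
  want <- want + sum(stats::dnorm(beta, 0, 5, log = TRUE))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("intercept-only fit recovers the log mean count", {
  cells <- generate_lattice(generator_config(lattice_nx = 5, lattice_ny = 5, seed = 2))
  cells$species_count <- 50L
  fit <- fit_species_model(cells, schemes = list(),
                           spec = model_spec(draws = 400, seed = 3,
                                             fix_hyper = list(range = 20000,
                                                              sigma_u = 1e-6,
                                                              sigma_v = 1e-6)))
  b0 <- fit$summary$beta
  expect_lt(abs(b0$mean[1] - log(50)) / b0$sd[1], 3)
})

test_that("with random effects pinned the fit matches the Poisson GLM oracle", {
  cfg <- generator_config(lattice_nx = 12, lattice_ny = 12,
                          beta = c("(Intercept)" = log(50),
                                   "landuse8:mixed_forest" = 0.4,
                                   "slope:Q3" = 0.3),
                          matern_count = matern_spec(30000, 0), iid_sd = 0,
                          seed = 9)
  gen <- generate_species_counts(generate_lattice(cfg), cfg)
  fit <- fit_species_model(gen$lattice,
                           spec = model_spec(draws = 500, seed = 2,
                                             fix_hyper = list(range = 30000,
                                                              sigma_u = 1e-6,
                                                              sigma_v = 1e-6)))
  des <- build_design(gen$lattice)
  glm_fit <- stats::glm.fit(des$X, gen$lattice$species_count,
                            family = stats::poisson())
  # relative risks agree within 1% relative (coefficients within log(1.01))
  expect_lt(max(abs(fit$summary$beta$mean - stats::coef(glm_fit))), log(1.01))
})

test_that("the spatial model recovers generating coefficients on a 20x20 lattice", {
  cfg <- generator_config(lattice_nx = 20, lattice_ny = 20,
                          beta = c("(Intercept)" = log(150),
                                   "landuse8:dense_forest" = log(1.384),
                                   "landuse8:mixed_forest" = log(1.552),
                                   "slope:Q4" = 0.12, "dist_urban:Q2" = -0.043,
                                   "elevation:Q5" = 0.2, "aspect:Q4" = -0.066),
                          seed = 3)
  gen <- generate_species_counts(generate_lattice(cfg), cfg)
  fit <- fit_species_model(gen$lattice,
                           spec = model_spec(draws = 1000, hyper_draws = 25, seed = 1))
  truth <- richlattice:::expand_beta(cfg$beta, fit$summary$beta$parameter)
  # the field is recentred into the intercept, so the generating value for
  # the intercept is beta0 plus the realised field mean
  truth[["(Intercept)"]] <- truth[["(Intercept)"]] + mean(gen$truth$u)
  for (nm in names(cfg$beta)) {
    row <- fit$summary$beta[fit$summary$beta$parameter == nm, ]
    expect_lt(abs(row$mean - truth[nm]) / row$sd, 3)
  }
  # field range recovered within a factor of 2 of the generating 30 km
  rng <- fit$summary$hyper$mean[fit$summary$hyper$parameter == "range"]
  expect_gt(rng, 30000 / 2.5)
  expect_lt(rng, 30000 * 2.5)

  # relative risks are draw-wise transforms: mean(exp(draws)), not exp(mean)
  rr <- relative_risks(fit)
  d_mf <- fit$draws$beta[, "landuse8:mixed_forest"]
  row <- rr[rr$variable == "landuse8" & rr$category == "mixed_forest", ]
  expect_equal(row$rr_mean, mean(exp(d_mf)), tolerance = 1e-12)
  expect_equal(row$rr_q2.5, unname(stats::quantile(exp(d_mf), 0.025)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(row$rr_mean, exp(mean(d_mf)))))
  expect_equal(row$excess_pct, (row$rr_mean - 1) * 100)
  # reference rows pinned at 1
  expect_true(all(rr$rr_mean[rr$reference] == 1))
  expect_true(all(rr$rr_q2.5 <= rr$rr_q50 & rr$rr_q50 <= rr$rr_q97.5))
  # quantile ordering in summaries
  b <- fit$summary$beta
  expect_true(all(b$q2.5 <= b$q5 & b$q5 <= b$q50 & b$q50 <= b$q95 & b$q95 <= b$q97.5))
})

test_that("excess surface is the draw-wise exp of the latent effects", {
  cfg <- generator_config(lattice_nx = 6, lattice_ny = 6,
                          beta = c("(Intercept)" = log(80)), seed = 12)
  gen <- generate_species_counts(generate_lattice(cfg), cfg)
  fit <- fit_species_model(gen$lattice, schemes = small_schemes(),
                           spec = model_spec(draws = 300, hyper_draws = 8, seed = 5))
  es <- excess_surface(fit)
  expect_equal(nrow(es), 36)
  expect_equal(es$excess_mean, unname(colMeans(exp(fit$draws$u + fit$draws$v))),
               tolerance = 1e-12)
  expect_true(all(es$excess_q2.5 <= es$excess_mean & es$excess_mean <= es$excess_q97.5))
  expect_equal(es$cell_id, gen$lattice$cell_id)
})

test_that("MCMC and Laplace inferences agree on the coefficients", {
  cfg <- generator_config(lattice_nx = 7, lattice_ny = 7,
                          beta = c("(Intercept)" = log(100),
                                   "landuse8:mixed_forest" = 0.4),
                          seed = 5)
  gen <- generate_species_counts(generate_lattice(cfg), cfg)
  fl <- fit_species_model(gen$lattice, schemes = small_schemes(),
                          spec = model_spec(draws = 1000, hyper_draws = 20, seed = 1))
  fm <- fit_species_model(gen$lattice, schemes = small_schemes(),
                          spec = model_spec(method = "mcmc", draws = 2000,
                                            warmup = 400, chains = 4, seed = 2,
                                            check_convergence = FALSE))
  expect_equal(fm$diagnostics$method, "mcmc")
  expect_gt(fm$diagnostics$accept_latent, 0.2)
  # coefficient posteriors agree within Monte-Carlo error
  for (nm in c("(Intercept)", "landuse8:mixed_forest", "slope:Q3")) {
    ml <- fl$summary$beta[fl$summary$beta$parameter == nm, ]
    mm <- fm$summary$beta[fm$summary$beta$parameter == nm, ]
    expect_lt(abs(ml$mean - mm$mean), 0.3 * ml$sd + 0.05)
    expect_lt(abs(ml$sd - mm$sd) / ml$sd, 0.5)
  }
})
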