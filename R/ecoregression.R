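#' Model specification for the spatial Poisson regression
#'
#' Settings for fitting `O_i ~ Poisson(mu_i)` with
#' `log mu_i = x_i' beta + u_i + v_i`: a Matern structured field `u` (SPDE
#' GMRF, PC prior on range and sd), iid heterogeneity `v` (PC exponential
#' prior on its sd) and zero-mean Gaussian priors on `beta`.
#'
#' @param method `"laplace"` (nested Gaussian approximation with
#'   hyperparameter-uncertainty propagation; default) or `"mcmc"`
#'   (preconditioned MALA on the latent field with Metropolis updates of the
#'   hyperparameters).
#' @param beta_prior_sd sd of the zero-mean Gaussian coefficient priors.
#' @param pc_field [pc_prior_spec()] for the field; `NULL` uses
#'   `P(range < domain diameter / 5) = 0.5`, `P(sd > 1) = 0.01`.
#' @param pc_iid list `(sigma0, alpha)` of the PC exponential prior
#'   `P(sd_iid > sigma0) = alpha` on the heterogeneity sd.
#' @param draws total posterior draws to return.
#' @param hyper_draws number of hyperparameter samples across which the
#'   Laplace path propagates hyperparameter uncertainty.
#' @param chains,warmup MCMC chains and per-chain warmup iterations.
#' @param fix_hyper optional named list pinning `range`, `sigma_u` and/or
#'   `sigma_v` to fixed values instead of estimating them.
#' @param offset optional per-cell log offset (e.g. log sampling effort).
#' @param ghost ghost-ring padding of the SPDE mesh.
#' @param seed RNG seed for posterior sampling.
#' @param check_convergence error (rather than warn) when MCMC split-chain
#'   scale reduction exceeds 1.05 on a headline parameter.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(method = c("laplace", "mcmc"),
                       beta_prior_sd = 5,
                       pc_field = NULL,
                       pc_iid = list(sigma0 = 1, alpha = 0.01),
                       draws = 1000L,
                       hyper_draws = 30L,
                       chains = 4L,
                       warmup = 300L,
                       fix_hyper = NULL,
                       offset = NULL,
                       ghost = 2L,
                       seed = 1L,
                       check_convergence = TRUE) {
  method <- match.arg(method)
  if (draws < 1 || chains < 1) stop("model_spec: draws and chains must be >= 1", call. = FALSE)
  if (beta_prior_sd <= 0) stop("model_spec: beta_prior_sd must be > 0", call. = FALSE)
  if (!is.null(pc_field)) stopifnot(inherits(pc_field, "pc_prior_spec"))
  structure(list(method = method, beta_prior_sd = beta_prior_sd,
                 pc_field = pc_field, pc_iid = pc_iid,
                 draws = as.integer(draws), hyper_draws = as.integer(hyper_draws),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 fix_hyper = fix_hyper, offset = offset, ghost = as.integer(ghost),
                 seed = as.integer(seed), check_convergence = isTRUE(check_convergence)),
            class = "model_spec")
}

#' Unnormalised log joint density of the spatial Poisson model
#'
#' Sum of the Poisson log likelihood at `eta = X beta + A u + v + offset`,
#' the GMRF log density of `u` (when `u` and `precision` are supplied), the
#' iid Gaussian log density of `v` (when `v` and `sigma_v` are supplied) and
#' the Gaussian prior on `beta` (skipped when `beta_prior_sd = Inf`).
#'
#' @param beta coefficient vector.
#' @param y counts.
#' @param X design matrix.
#' @param u optional field values over the mesh nodes of `precision`.
#' @param v optional iid effects, one per cell.
#' @param precision `precision_operator` defining the GMRF prior of `u`.
#' @param A sparse projector from mesh nodes to cells; defaults to selecting
#'   the real (non-ghost) nodes of `precision` in order.
#' @param sigma_v sd of the iid effect.
#' @param beta_prior_sd Gaussian prior sd for `beta` (`Inf` = flat).
#' @param offset optional per-cell log offset.
#' @return scalar log density (unnormalised in the flat-prior parts).
#' @export
eco_log_joint <- function(beta, y, X, u = NULL, v = NULL, precision = NULL,
                          A = NULL, sigma_v = NULL, beta_prior_sd = Inf,
                          offset = NULL) {
  eta <- drop(X %*% beta)
  if (!is.null(u)) {
    if (is.null(precision)) stop("eco_log_joint: `u` given without `precision`", call. = FALSE)
    if (is.null(A)) {
      eta <- eta + u[precision$real]
    } else eta <- eta + as.numeric(A %*% u)
  }
  if (!is.null(v)) eta <- eta + v
  if (!is.null(offset)) eta <- eta + offset
  if (length(eta) != length(y)) stop("eco_log_joint: dimension mismatch", call. = FALSE)
  lp <- sum(y * eta - exp(eta) - lgamma(y + 1))
  if (!is.null(u)) {
    m <- length(u)
    lp <- lp + 0.5 * precision$logdet - 0.5 * m * log(2 * pi) -
      0.5 * drop(crossprod(u, as.numeric(precision$Q %*% u)))
  }
  if (!is.null(v)) {
    if (is.null(sigma_v)) stop("eco_log_joint: `v` given without `sigma_v`", call. = FALSE)
    lp <- lp + sum(stats::dnorm(v, 0, sigma_v, log = TRUE))
  }
  if (is.finite(beta_prior_sd))
    lp <- lp + sum(stats::dnorm(beta, 0, beta_prior_sd, log = TRUE))
  if (!is.finite(lp)) stop("eco_log_joint: non-finite log density (invalid parameter region)",
                           call. = FALSE)
  lp
}

## ---------------------------------------------------------------------------
## internal machinery
## ---------------------------------------------------------------------------

# infer regular-grid geometry from cell centroids
lattice_geometry <- function(cells) {
  xs <- sort(unique(cells$x)); ys <- sort(unique(cells$y))
  nx <- length(xs); ny <- length(ys)
  if (nx < 2 || ny < 2 || nx * ny != nrow(cells))
    stop("cells do not form a complete regular lattice", call. = FALSE)
  hx <- diff(xs); hy <- diff(ys)
  if (max(abs(hx - hx[1])) > 1e-6 * hx[1] || max(abs(hy - hy[1])) > 1e-6 * hy[1] ||
      abs(hx[1] - hy[1]) > 1e-6 * hx[1])
    stop("cells are not on a square regular grid", call. = FALSE)
  list(nx = nx, ny = ny, spacing = hx[1], x0 = xs[1], y0 = ys[1])
}

# sparse projector: cell rows -> mesh node columns
cell_projector <- function(cells, geom, ghost) {
  meshnx <- geom$nx + 2L * ghost
  ix <- as.integer(round((cells$x - geom$x0) / geom$spacing)) + ghost
  iy <- as.integer(round((cells$y - geom$y0) / geom$spacing)) + ghost
  node <- iy * meshnx + ix + 1L
  Matrix::sparseMatrix(i = seq_len(nrow(cells)), j = node, x = 1,
                       dims = c(nrow(cells), meshnx * (geom$ny + 2L * ghost)))
}

# model context shared by all inference paths
eco_context <- function(cells, schemes, spec) {
  y <- cells$species_count
  if (anyNA(y) || any(y < 0) || any(y != round(y)))
    stop("fit: species_count must be non-negative integers without NA", call. = FALSE)
  des <- build_design(cells, schemes)
  geom <- lattice_geometry(cells)
  fem <- mesh_fem(geom$nx + 2L * spec$ghost, geom$ny + 2L * spec$ghost, geom$spacing)
  A <- cell_projector(cells, geom, spec$ghost)
  n <- nrow(cells); m <- fem$m; p <- ncol(des$X)
  B <- cbind(Matrix::Matrix(des$X, sparse = TRUE), A, Matrix::Diagonal(n))
  pc_field <- spec$pc_field
  if (is.null(pc_field)) {
    diam <- sqrt((geom$nx^2 + geom$ny^2)) * geom$spacing
    pc_field <- pc_prior_spec(rho0 = diam / 5, alpha_rho = 0.5,
                              sigma0 = 1, alpha_sigma = 0.01)
  }
  offset <- if (is.null(spec$offset)) rep(0, n) else spec$offset
  list(y = y, X = des$X, labels = des$labels, schemes = des$schemes,
       geom = geom, fem = fem, A = A, B = B, n = n, m = m, p = p,
       pc_field = pc_field, offset = offset, cells = cells)
}

# theta is the log of the free hyperparameters, in this fixed order
hyper_names <- c("range", "sigma_u", "sigma_v")

theta_to_hyper <- function(theta, spec) {
  fixed <- spec$fix_hyper
  out <- numeric(3); names(out) <- hyper_names
  k <- 0L
  for (h in hyper_names) {
    if (!is.null(fixed[[h]])) out[h] <- fixed[[h]]
    else { k <- k + 1L; out[h] <- exp(theta[k]) }
  }
  out
}

free_hyper <- function(spec) hyper_names[!hyper_names %in% names(spec$fix_hyper)]

# prior precision of (beta, u, v) and the log-determinant pieces
prior_precision <- function(ctx, spec, hyper) {
  Qu <- precision_from_fem(ctx$fem, matern_spec(hyper[["range"]], hyper[["sigma_u"]]))
  chQ <- Matrix::Cholesky(Qu, LDL = FALSE, perm = TRUE)
  ld_Qu <- as.numeric(Matrix::determinant(chQ, logarithm = TRUE, sqrt = FALSE)$modulus)
  P <- Matrix::bdiag(Matrix::Diagonal(ctx$p, 1 / spec$beta_prior_sd^2),
                     Qu,
                     Matrix::Diagonal(ctx$n, 1 / hyper[["sigma_v"]]^2))
  logdetP <- -2 * ctx$p * log(spec$beta_prior_sd) + ld_Qu -
    2 * ctx$n * log(hyper[["sigma_v"]])
  list(P = Matrix::forceSymmetric(P), logdetP = logdetP, Qu = Qu, ld_Qu = ld_Qu)
}

ETA_CAP <- 35

# log p(z | theta) up to theta-free constants: Poisson ll - 0.5 z'Pz
inner_obj <- function(z, ctx, P) {
  eta <- pmin(as.numeric(ctx$B %*% z) + ctx$offset, ETA_CAP)
  sum(ctx$y * eta - exp(eta)) - 0.5 * drop(crossprod(z, as.numeric(P %*% z)))
}

# Newton ascent to the conditional mode of z given theta
inner_mode <- function(ctx, P, z0 = NULL, tol = 1e-9, maxit = 60L) {
  z <- if (is.null(z0)) rep(0, ctx$p + ctx$m + ctx$n) else z0
  f <- inner_obj(z, ctx, P)
  H <- NULL
  for (it in seq_len(maxit)) {
    eta <- pmin(as.numeric(ctx$B %*% z) + ctx$offset, ETA_CAP)
    mu <- exp(eta)
    g <- as.numeric(Matrix::crossprod(ctx$B, ctx$y - mu)) - as.numeric(P %*% z)
    H <- Matrix::forceSymmetric(Matrix::crossprod(ctx$B, ctx$B * mu) + P)
    chH <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
    step <- as.numeric(Matrix::solve(chH, g, system = "A"))
    alpha <- 1
    repeat {
      z_new <- z + alpha * step
      f_new <- inner_obj(z_new, ctx, P)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { z_new <- z; f_new <- f; break }
    }
    conv <- abs(f_new - f) < tol * (abs(f) + 1)
    z <- z_new; f <- f_new
    if (conv) break
  }
  eta <- pmin(as.numeric(ctx$B %*% z) + ctx$offset, ETA_CAP)
  mu <- exp(eta)
  H <- Matrix::forceSymmetric(Matrix::crossprod(ctx$B, ctx$B * mu) + P)
  chH <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
  ldH <- as.numeric(Matrix::determinant(chH, logarithm = TRUE, sqrt = FALSE)$modulus)
  list(z = z, f = f, H = H, chH = chH, logdetH = ldH, iterations = it)
}

# log prior of theta (free hyperparameters only), including log-scale Jacobians
hyper_log_prior <- function(hyper, ctx, spec) {
  lp <- 0
  free <- free_hyper(spec)
  if (any(c("range", "sigma_u") %in% free))
    lp <- lp + pc_prior_logdensity(hyper[["range"]], hyper[["sigma_u"]], ctx$pc_field)
  if ("sigma_v" %in% free) {
    lam <- -log(spec$pc_iid$alpha) / spec$pc_iid$sigma0
    lp <- lp + log(lam) - lam * hyper[["sigma_v"]]
  }
  for (h in free) lp <- lp + log(hyper[[h]])  # d(hyper)/d(log hyper)
  lp
}

# Laplace approximation to log p(theta | y), up to a constant
laplace_marginal <- function(theta, ctx, spec, z_warm = NULL) {
  hyper <- theta_to_hyper(theta, spec)
  pp <- prior_precision(ctx, spec, hyper)
  md <- inner_mode(ctx, pp$P, z0 = z_warm)
  lp <- md$f + 0.5 * pp$logdetP - 0.5 * md$logdetH + hyper_log_prior(hyper, ctx, spec)
  attr(lp, "mode") <- md
  lp
}

# central-difference Hessian of a scalar function
fd_hessian <- function(fn, x, h = NULL) {
  d <- length(x)
  if (is.null(h)) h <- 1e-3 * (1 + abs(x))
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- h[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i < d) for (j in seq((i + 1), d)) {
      ej <- rep(0, d); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# draw `n` samples from N(mode, H^{-1}) through the sparse Cholesky of H
gaussian_draws <- function(md, n) {
  dim_z <- length(md$z)
  zmat <- matrix(stats::rnorm(dim_z * n), dim_z, n)
  pert <- Matrix::solve(md$chH, Matrix::solve(md$chH, zmat, system = "Lt"),
                        system = "Pt")
  md$z + as.matrix(pert)
}

## ---------------------------------------------------------------------------
## fitting
## ---------------------------------------------------------------------------

#' Fit the Bayesian spatial Poisson species-count model
#'
#' Fits `O_i ~ Poisson(mu_i)` with
#' `log mu_i = x_i' beta + u_i + v_i` on a regular lattice of cells, where
#' the design is built by [build_design()], `u` is a smoothness-1 Matern
#' field constructed as an SPDE GMRF over the (ghost-padded) lattice mesh and
#' `v` is iid Gaussian heterogeneity.  PC priors govern the three
#' hyperparameters.
#'
#' The default `"laplace"` method maximises the Laplace-approximated
#' hyperparameter posterior, then propagates hyperparameter uncertainty by
#' sampling hyperparameters from the Gaussian approximation on the log scale
#' and, for each, drawing the latent field from its conditional Gaussian
#' approximation.  The `"mcmc"` method runs preconditioned MALA over the
#' latent field with Metropolis updates of the hyperparameters.
#'
#' For identifiability the structured field is recentred draw-wise: its mean
#' over real cells is moved into the intercept.
#'
#' @param cells lattice cell data.frame (must contain `x`, `y`,
#'   `species_count` and the scheme variables).
#' @param schemes design schemes (default [default_design_schemes()]).
#' @param spec a [model_spec()].
#' @return object of class `eco_fit` with elements `draws` (matrices `beta`,
#'   `u`, `v`, `hyper` on natural scale), `summary` (data.frames for `beta`
#'   and `hyper` with mean, sd and 2.5/5/50/95/97.5% quantiles),
#'   `labels`, `schemes`, `diagnostics`, `cell_id`, and the spec.
#' @export
fit_species_model <- function(cells, schemes = default_design_schemes(),
                              spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  ctx <- eco_context(cells, schemes, spec)
  free <- free_hyper(spec)
  d <- length(free)

  set.seed(spec$seed)
  if (d > 0) {
    init <- log(c(range = ctx$pc_field$rho0, sigma_u = 0.5, sigma_v = 0.3))[
      match(free, hyper_names)]
    warm <- new.env(); warm$z <- NULL
    negmarg <- function(th) {
      lp <- tryCatch(laplace_marginal(th, ctx, spec, z_warm = warm$z),
                     error = function(e) -Inf)
      if (is.finite(lp)) warm$z <- attr(lp, "mode")$z
      -as.numeric(lp)
    }
    opt <- stats::optim(init, negmarg, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-7))
    theta_hat <- opt$par
    Hm <- fd_hessian(function(th) -negmarg(th), theta_hat)
    Sigma_theta <- tryCatch(solve(-Hm), error = function(e) NULL)
    ok <- !is.null(Sigma_theta) && all(eigen(Sigma_theta, symmetric = TRUE,
                                             only.values = TRUE)$values > 0)
    if (!ok) Sigma_theta <- diag(1e-4, d)
    opt_conv <- opt$convergence
  } else {
    theta_hat <- numeric(0); Sigma_theta <- matrix(0, 0, 0); opt_conv <- 0L
  }

  if (spec$method == "laplace") {
    fit <- laplace_draws(ctx, spec, theta_hat, Sigma_theta)
    diagnostics <- list(method = "laplace", optim_convergence = opt_conv,
                        newton_iterations = fit$newton_iterations,
                        hyper_draws = fit$K, n_draws = nrow(fit$z_draws))
  } else {
    fit <- mcmc_draws(ctx, spec, theta_hat, Sigma_theta)
    diagnostics <- fit$diagnostics
  }

  assemble_fit(ctx, spec, fit$z_draws, fit$hyper_draws_nat, diagnostics)
}

laplace_draws <- function(ctx, spec, theta_hat, Sigma_theta) {
  d <- length(theta_hat)
  K <- if (d == 0) 1L else max(1L, spec$hyper_draws)
  per <- ceiling(spec$draws / K)
  Lth <- if (d > 0) chol(Sigma_theta) else NULL
  z_list <- vector("list", K)
  hyper_list <- vector("list", K)
  md0 <- NULL
  newton_it <- 0L
  for (k in seq_len(K)) {
    theta_k <- if (d == 0) theta_hat
      else if (k == 1L) theta_hat
      else theta_hat + drop(crossprod(Lth, stats::rnorm(d)))
    hyper_k <- theta_to_hyper(theta_k, spec)
    pp <- prior_precision(ctx, spec, hyper_k)
    md <- inner_mode(ctx, pp$P, z0 = if (is.null(md0)) NULL else md0$z)
    if (k == 1L) md0 <- md
    newton_it <- max(newton_it, md$iterations)
    z_list[[k]] <- t(gaussian_draws(md, per))
    hyper_list[[k]] <- matrix(hyper_k, per, 3, byrow = TRUE)
  }
  z_draws <- do.call(rbind, z_list)[seq_len(max(spec$draws, 1L)), , drop = FALSE]
  hyper_nat <- do.call(rbind, hyper_list)[seq_len(max(spec$draws, 1L)), , drop = FALSE]
  colnames(hyper_nat) <- hyper_names
  list(z_draws = z_draws, hyper_draws_nat = hyper_nat, K = K,
       newton_iterations = newton_it)
}

mcmc_draws <- function(ctx, spec, theta_hat, Sigma_theta) {
  d <- length(theta_hat)
  free <- free_hyper(spec)
  chains <- spec$chains
  iter_keep <- ceiling(spec$draws / chains)
  n_iter <- spec$warmup + iter_keep
  dim_z <- ctx$p + ctx$m + ctx$n

  prop_L <- if (d > 0) chol(Sigma_theta * (1.4^2 / max(d, 1)) + diag(1e-6, d)) else NULL

  # per-theta state: prior precision, conditional mode and the Gaussian
  # approximation N(mode, H^{-1}) used as independence / joint proposal
  make_state <- function(theta, z_warm = NULL) {
    hyper <- theta_to_hyper(theta, spec)
    pp <- prior_precision(ctx, spec, hyper)
    md <- inner_mode(ctx, pp$P, z0 = z_warm)
    lp_theta <- 0.5 * pp$logdetP + hyper_log_prior(hyper, ctx, spec)
    list(theta = theta, hyper = hyper, pp = pp, md = md, lp_theta = lp_theta)
  }
  # log proposal density at z (dimension constant cancels in all ratios)
  logq <- function(st, z) {
    r <- z - st$md$z
    0.5 * st$md$logdetH - 0.5 * drop(crossprod(r, as.numeric(st$md$H %*% r)))
  }
  draw_q <- function(st) drop(gaussian_draws(st$md, 1L))
  grad_z <- function(z, P) {
    eta <- pmin(as.numeric(ctx$B %*% z) + ctx$offset, ETA_CAP)
    as.numeric(Matrix::crossprod(ctx$B, ctx$y - exp(eta))) - as.numeric(P %*% z)
  }

  z_keep <- vector("list", chains)
  th_keep <- vector("list", chains)
  accept_z <- accept_t <- 0; tot_z <- tot_t <- 0

  for (ch in seq_len(chains)) {
    st <- make_state(theta_hat + if (d > 0) 0.5 * stats::rnorm(d) else numeric(0))
    z <- draw_q(st)
    f <- inner_obj(z, ctx, st$pp$P)
    eps <- 0.8
    s_theta <- 1
    keep_z <- matrix(NA_real_, iter_keep, dim_z)
    keep_t <- matrix(NA_real_, iter_keep, 3)
    for (it in seq_len(n_iter)) {
      ## (a) preconditioned MALA refinement of the latent field at fixed theta
      g <- grad_z(z, st$pp$P)
      mz <- z + (eps^2 / 2) * as.numeric(Matrix::solve(st$md$chH, g, system = "A"))
      zp <- mz + eps * (draw_q(st) - st$md$z)
      fp <- inner_obj(zp, ctx, st$pp$P)
      gp <- grad_z(zp, st$pp$P)
      mzp <- zp + (eps^2 / 2) * as.numeric(Matrix::solve(st$md$chH, gp, system = "A"))
      qM <- function(r) drop(crossprod(r, as.numeric(st$md$H %*% r)))
      log_alpha <- (fp - f) + (qM(zp - mz) - qM(z - mzp)) / (2 * eps^2)
      if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
        z <- zp; f <- fp; acc <- 1
      } else acc <- 0
      if (it <= spec$warmup) eps <- min(1.5, eps * exp(0.02 * (acc - 0.574)))

      ## (b) independence refresh of z from the Gaussian approximation
      zp <- draw_q(st)
      fp <- inner_obj(zp, ctx, st$pp$P)
      log_alpha <- (fp - f) - logq(st, zp) + logq(st, z)
      tot_z <- tot_z + 1
      if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
        z <- zp; f <- fp; accept_z <- accept_z + 1
      }

      ## (c) joint (theta, z) move: random-walk theta proposal with z drawn
      ## from the Gaussian approximation at the proposed theta; the joint
      ## accept ratio sidesteps the slow field/hyperparameter coupling
      if (d > 0) {
        thp <- st$theta + s_theta * drop(crossprod(prop_L, stats::rnorm(d)))
        stp <- tryCatch(make_state(thp, z_warm = st$md$z), error = function(e) NULL)
        acc_t <- 0
        if (!is.null(stp)) {
          zp <- draw_q(stp)
          fp <- inner_obj(zp, ctx, stp$pp$P)
          log_alpha <- (fp + stp$lp_theta - logq(stp, zp)) -
                       (f + st$lp_theta - logq(st, z))
          tot_t <- tot_t + 1
          if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
            st <- stp; z <- zp; f <- fp
            accept_t <- accept_t + 1
            acc_t <- 1
          }
        }
        if (it <= spec$warmup)
          s_theta <- min(3, max(0.2, s_theta * exp(0.05 * (acc_t - 0.3))))
      }
      if (it > spec$warmup) {
        keep_z[it - spec$warmup, ] <- z
        keep_t[it - spec$warmup, ] <- st$hyper
      }
    }
    z_keep[[ch]] <- keep_z
    th_keep[[ch]] <- keep_t
  }

  ## convergence diagnostics on headline parameters (beta columns + hypers)
  head_idx <- seq_len(ctx$p)
  rhat_beta <- vapply(head_idx, function(j)
    split_rhat(lapply(z_keep, function(m) m[, j])), 0)
  rhat_hyp <- if (d > 0) vapply(match(free, hyper_names), function(j)
    split_rhat(lapply(th_keep, function(m) log(m[, j]))), 0) else numeric(0)
  names(rhat_beta) <- colnames(ctx$X)
  names(rhat_hyp) <- free
  rhat_all <- c(rhat_beta, rhat_hyp)
  ess <- vapply(head_idx, function(j)
    ess_basic(unlist(lapply(z_keep, function(m) m[, j]))), 0)
  # the convergence gate covers the coefficients whose relative risks are
  # reported; hyperparameter Rhats are returned for inspection
  bad <- names(rhat_beta)[rhat_beta > 1.05]
  if (length(bad)) {
    msg <- paste0("MCMC did not converge (split-chain Rhat > 1.05) for: ",
                  paste(bad, collapse = ", "))
    if (spec$check_convergence) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  z_draws <- do.call(rbind, z_keep)
  hyper_nat <- do.call(rbind, th_keep)
  colnames(hyper_nat) <- hyper_names
  list(z_draws = z_draws, hyper_draws_nat = hyper_nat,
       diagnostics = list(method = "mcmc", rhat = rhat_all, ess = ess,
                          accept_latent = accept_z / max(tot_z, 1),
                          accept_hyper = if (tot_t) accept_t / tot_t else NA,
                          chains = chains, n_draws = nrow(z_draws)))
}

# split-chain potential scale reduction factor
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from the initial positive autocorrelations
ess_basic <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

summary_quantiles <- c(0.025, 0.05, 0.5, 0.95, 0.975)

assemble_fit <- function(ctx, spec, z_draws, hyper_nat, diagnostics) {
  p <- ctx$p; m <- ctx$m; n <- ctx$n
  beta_d <- z_draws[, seq_len(p), drop = FALSE]
  u_mesh <- z_draws[, p + seq_len(m), drop = FALSE]
  v_d <- z_draws[, p + m + seq_len(n), drop = FALSE]
  u_cells <- u_mesh %*% Matrix::t(ctx$A)
  u_cells <- as.matrix(u_cells)
  ## recentre the field; its mean goes into the intercept
  ubar <- rowMeans(u_cells)
  u_cells <- u_cells - ubar
  beta_d[, 1] <- beta_d[, 1] + ubar
  colnames(beta_d) <- colnames(ctx$X)

  summarize <- function(mat) {
    qs <- t(apply(mat, 2, stats::quantile, probs = summary_quantiles, names = FALSE))
    data.frame(parameter = colnames(mat), mean = colMeans(mat),
               sd = apply(mat, 2, stats::sd),
               q2.5 = qs[, 1], q5 = qs[, 2], q50 = qs[, 3],
               q95 = qs[, 4], q97.5 = qs[, 5], row.names = NULL)
  }
  structure(list(draws = list(beta = beta_d, u = u_cells, v = v_d, hyper = hyper_nat),
                 summary = list(beta = summarize(beta_d),
                                hyper = summarize(hyper_nat)),
                 labels = ctx$labels, schemes = ctx$schemes,
                 cell_id = if ("cell_id" %in% names(ctx$cells)) ctx$cells$cell_id
                           else as.character(seq_len(n)),
                 y = ctx$y, diagnostics = diagnostics, spec = spec),
            class = "eco_fit")
}

#' @export
print.eco_fit <- function(x, ...) {
  cat(sprintf("Spatial Poisson fit (%s): %d cells, %d coefficients, %d draws\n",
              x$diagnostics$method, length(x$y), ncol(x$draws$beta),
              nrow(x$draws$beta)))
  hy <- x$summary$hyper
  cat(sprintf("  field range %.0f, field sd %.3f, iid sd %.3f (posterior means)\n",
              hy$mean[hy$parameter == "range"], hy$mean[hy$parameter == "sigma_u"],
              hy$mean[hy$parameter == "sigma_v"]))
  invisible(x)
}

#' Relative risks with credible intervals
#'
#' Applies `exp` draw-wise to each non-reference category coefficient and
#' summarises; reference categories are fixed at 1.  `excess_pct` is
#' `(rr - 1) * 100`.
#'
#' @param fitted an `eco_fit`.
#' @return data.frame with `variable`, `category`, `reference`, `rr_mean`,
#'   `rr_sd`, `rr_q2.5`, `rr_q5`, `rr_q50`, `rr_q95`, `rr_q97.5`,
#'   `excess_pct`.
#' @export
relative_risks <- function(fitted) {
  stopifnot(inherits(fitted, "eco_fit"))
  lab <- fitted$labels
  rows <- list()
  for (sc in fitted$schemes) {
    v <- sc$variable
    if (sc$type == "quantile") {
      cats <- paste0("Q", seq_len(if (!is.null(sc$fitted)) sc$fitted$k else sc$k))
      ref <- "Q1"
    } else if (sc$type == "categorical") {
      cats <- sc$levels; ref <- sc$levels[1]
    } else next
    for (g in cats) {
      if (g == ref) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, category = g, reference = TRUE, rr_mean = 1, rr_sd = 0,
          rr_q2.5 = 1, rr_q5 = 1, rr_q50 = 1, rr_q95 = 1, rr_q97.5 = 1,
          excess_pct = 0)
      } else {
        col <- paste0(v, ":", g)
        if (!col %in% colnames(fitted$draws$beta))
          stop("relative_risks: no draws for category ", col, call. = FALSE)
        rr <- exp(fitted$draws$beta[, col])
        q <- stats::quantile(rr, summary_quantiles, names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, category = g, reference = FALSE,
          rr_mean = mean(rr), rr_sd = stats::sd(rr),
          rr_q2.5 = q[1], rr_q5 = q[2], rr_q50 = q[3], rr_q95 = q[4],
          rr_q97.5 = q[5], excess_pct = (mean(rr) - 1) * 100)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell excess surface
#'
#' Posterior mean and interval of `exp(u_i + v_i)`: the multiplicative
#' departure of each cell from its covariate-predicted count (1 = as
#' expected).
#'
#' @param fitted an `eco_fit`.
#' @return data.frame with `cell_id`, `excess_mean`, `excess_q2.5`,
#'   `excess_q97.5`.
#' @export
excess_surface <- function(fitted) {
  stopifnot(inherits(fitted, "eco_fit"))
  E <- exp(fitted$draws$u + fitted$draws$v)
  q <- apply(E, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(cell_id = fitted$cell_id,
             excess_mean = colMeans(E),
             excess_q2.5 = q[1, ], excess_q97.5 = q[2, ],
             row.names = NULL)
}
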