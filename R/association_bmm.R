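#' Association model configuration
#'
#' Controls the per-site binomial mixed model fit. The model for site i is
#' \deqn{y_j \sim Binomial(r_j, \pi_j), \quad
#'       logit(\pi_j) = \mu + age_j\gamma + x_j\beta + g_j + e_j}
#' with \eqn{g \sim N(0, \sigma_g^2 K)} over individuals (K the additive
#' relationship matrix) and independent \eqn{e_j \sim N(0, \sigma_e^2)}.
#' Fitting is by penalized quasi-likelihood (PQL) with restricted-likelihood
#' variance component estimation on a bounded log scale.
#'
#' @param predictor Phenotype name (`avg_litter_size`, `sperm_count_per_ml`
#'   or `testes_firmness`).
#' @param covariates Covariate column names; default age at sampling.
#' @param max_iterations PQL iteration cap.
#' @param tol Convergence tolerance on the fixed-effect max change.
#' @param clip Probability clip bound in (0, 0.5); working weights use
#'   probabilities clamped to `[clip, 1 - clip]`.
#' @param var_bounds Bounds for each variance component (logit scale).
#' @param grid_points Points per component in the coarse log-spaced REML
#'   grid that seeds the bounded quasi-Newton refinement.
#' @return A `bmm_config` list.
#' @export
bmm_config <- function(predictor = "avg_litter_size",
                       covariates = "age_at_sampling",
                       max_iterations = 50,
                       tol = 1e-5,
                       clip = 1e-6,
                       var_bounds = c(1e-8, 10),
                       grid_points = 5) {
  stopifnot(tol > 0, clip > 0, clip < 0.5, var_bounds[1] > 0,
            var_bounds[2] > var_bounds[1])
  structure(list(predictor = predictor, covariates = covariates,
                 max_iterations = max_iterations, tol = tol, clip = clip,
                 var_bounds = var_bounds, grid_points = grid_points),
            class = "bmm_config")
}

# negative restricted log-likelihood of the working linear mixed model
# z = X b + u,  Var(u) = sg2*K + se2*I + diag(1/w)
neg_reml <- function(log_theta, z, X, K, winv) {
  theta <- exp(log_theta)
  V <- theta[1] * K + diag(theta[2] + winv, nrow(K))
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(1e10)
  logdetV <- 2 * sum(log(diag(cv)))
  Vi_z <- backsolve(cv, forwardsolve(t(cv), z))
  Vi_X <- backsolve(cv, forwardsolve(t(cv), X))
  XtViX <- crossprod(X, Vi_X)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(1e10)
  b <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Vi_z)))
  resid <- z - X %*% b
  Vi_r <- backsolve(cv, forwardsolve(t(cv), resid))
  as.numeric(0.5 * (logdetV + 2 * sum(log(diag(cx))) +
                      crossprod(resid, Vi_r)))
}

# REML estimate of (sigma_g2, sigma_e2): coarse log grid then L-BFGS-B
estimate_vc <- function(z, X, K, winv, config, start = NULL) {
  lb <- log(config$var_bounds[1])
  ub <- log(config$var_bounds[2])
  if (is.null(start)) {
    grid <- seq(lb, ub, length.out = config$grid_points)
    cand <- as.matrix(expand.grid(grid, grid))
    vals <- apply(cand, 1, function(lt) neg_reml(lt, z, X, K, winv))
    start <- cand[which.min(vals), ]
  }
  opt <- stats::optim(start, neg_reml, z = z, X = X, K = K, winv = winv,
                      method = "L-BFGS-B", lower = lb, upper = ub,
                      control = list(maxit = 100))
  exp(opt$par)
}

# GLS solve returning coefficients, covariance, and BLUP of random effects
gls_step <- function(z, X, K, winv, theta) {
  n <- length(z)
  Sigma_u <- theta[1] * K + diag(theta[2], n)
  V <- Sigma_u + diag(winv, n)
  cv <- chol(V)
  Vi_z <- backsolve(cv, forwardsolve(t(cv), z))
  Vi_X <- backsolve(cv, forwardsolve(t(cv), X))
  XtViX <- crossprod(X, Vi_X)
  XtViX_inv <- solve(XtViX)
  b <- XtViX_inv %*% crossprod(X, Vi_z)
  resid <- z - X %*% b
  u <- Sigma_u %*% backsolve(cv, forwardsolve(t(cv), resid))
  list(b = drop(b), cov_b = XtViX_inv, u = drop(u))
}

skipped_result <- function(reason) {
  list(beta = NA_real_, se = NA_real_, wald_p = NA_real_,
       beta_raw = NA_real_, se_raw = NA_real_,
       sigma_g2 = NA_real_, sigma_e2 = NA_real_,
       converged = FALSE, n_iter = 0L, skip_reason = reason)
}

#' Fit the binomial mixed model at one site
#'
#' Penalized quasi-likelihood fit of methylated counts against a predictor
#' with covariates and a kinship random effect (see [bmm_config()] for the
#' model). Each iteration forms the working response
#' \eqn{z = \eta + (y/r - \pi)/(\pi(1-\pi))} with weights
#' \eqn{w = r\pi(1-\pi)}, re-estimates the variance components by REML of
#' the working linear mixed model, and updates fixed effects and random
#' effect predictions by generalized least squares.
#'
#' The predictor is standardized internally (mean 0, SD 1); `beta`/`se` are
#' on that scale for comparability across phenotypes and `beta_raw`/`se_raw`
#' undo the scaling.
#'
#' @param y Methylated counts per sample.
#' @param r Total counts per sample (all >= 1).
#' @param x Predictor values per sample.
#' @param covars Optional numeric matrix of covariates (columns), or `NULL`.
#' @param K Relationship matrix aligned to samples.
#' @param config A [bmm_config()].
#' @param fix_sigma Optional `c(sigma_g2, sigma_e2)` to pin the variance
#'   components instead of estimating them (0 allowed: with both pinned at
#'   0 the fit reduces to ordinary iteratively reweighted binomial
#'   regression).
#' @return A list: `beta`, `se`, `wald_p` (two-sided normal), `beta_raw`,
#'   `se_raw`, `sigma_g2`, `sigma_e2`, `converged`, `n_iter`,
#'   `skip_reason` (`"none"`, `"monomorphic"`, `"constant-predictor"` or
#'   `"non-converged"`).
#' @export
fit_site_bmm <- function(y, r, x, covars = NULL, K, config = bmm_config(),
                         fix_sigma = NULL) {
  n <- length(y)
  stopifnot(length(r) == n, length(x) == n, nrow(K) == n, ncol(K) == n)
  if (any(r < 1)) stop("all totals must be >= 1")
  if (all(y == 0) || all(y == r)) return(skipped_result("monomorphic"))
  if (stats::sd(x) == 0) return(skipped_result("constant-predictor"))

  x_center <- mean(x)
  x_scale <- stats::sd(x)
  xs <- (x - x_center) / x_scale
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    keep <- apply(covars, 2, stats::sd) > 0
    if (any(keep)) X <- cbind(X, scale(covars[, keep, drop = FALSE],
                                       scale = FALSE))
  }
  X <- cbind(X, predictor = xs)
  bi <- ncol(X)

  pinned <- !is.null(fix_sigma)
  theta <- if (pinned) pmax(fix_sigma, 0) else c(0.1, 0.1)
  p_hat <- (y + 0.5) / (r + 1)
  eta <- stats::qlogis(p_hat)
  b <- rep(0, bi)
  converged <- FALSE
  vc_start <- NULL
  iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    pi_hat <- stats::plogis(eta)
    pi_hat <- pmin(pmax(pi_hat, config$clip), 1 - config$clip)
    w <- r * pi_hat * (1 - pi_hat)
    z <- eta + (y / r - pi_hat) / (pi_hat * (1 - pi_hat))
    if (!pinned) {
      theta <- estimate_vc(z, X, K, 1 / w, config, start = vc_start)
      vc_start <- log(theta)
    }
    fit <- gls_step(z, X, K, 1 / w, theta)
    delta <- max(abs(fit$b - b))
    b <- fit$b
    eta <- drop(X %*% b + fit$u)
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  se <- sqrt(diag(fit$cov_b))[bi]
  beta <- b[bi]
  # Wald test on a t reference with residual df: the normal reference is
  # anti-conservative for PQL at the sample sizes this pipeline targets
  p <- 2 * stats::pt(-abs(beta / se), df = max(n - bi, 1))
  p <- max(p, .Machine$double.xmin)
  list(beta = beta, se = se, wald_p = p,
       beta_raw = beta / x_scale, se_raw = se / x_scale,
       sigma_g2 = unname(theta[1]), sigma_e2 = unname(theta[2]),
       converged = converged, n_iter = iter,
       skip_reason = if (converged) "none" else "non-converged")
}

#' Fit the binomial mixed model across all sites
#'
#' Runs [fit_site_bmm()] per site of a united count matrix. Skipped sites
#' (monomorphic or constant predictor) are retained with their skip flag so
#' downstream percentile selection sees the full site list.
#'
#' @param matrix A `CountMatrix`.
#' @param phenotypes Sample table covering every matrix sample (matched by
#'   `sample_id`).
#' @param K Relationship matrix over individuals (IDs = `studbook_no`), or
#'   already aligned to samples.
#' @param config A [bmm_config()].
#' @param fix_sigma Optional pinned variance components (see
#'   [fit_site_bmm()]).
#' @return A list with `results` (data.frame: site key columns, `beta`,
#'   `se`, `p`, `beta_raw`, `sigma_g2`, `sigma_e2`, `converged`,
#'   `skip_reason`) and `inflation` (genomic inflation factor: median
#'   observed 1-df chi-square over its theoretical median).
#' @export
fit_all_sites <- function(matrix, phenotypes, K, config = bmm_config(),
                          fix_sigma = NULL) {
  stopifnot(inherits(matrix, "CountMatrix"))
  idx <- match(matrix$samples, phenotypes$sample_id)
  if (anyNA(idx)) {
    stop("phenotype missing for sample(s): ",
         paste(matrix$samples[is.na(idx)], collapse = ", "))
  }
  pheno <- phenotypes[idx, , drop = FALSE]
  x <- predictor_vector(pheno, config$predictor)
  if (anyNA(x)) {
    stop("predictor '", config$predictor, "' undefined for sample(s): ",
         paste(pheno$sample_id[is.na(x)], collapse = ", "))
  }
  covars <- NULL
  if (length(config$covariates)) {
    have <- intersect(config$covariates, names(pheno))
    if (length(have)) {
      covars <- as.matrix(pheno[, have, drop = FALSE])
      storage.mode(covars) <- "double"
    }
  }
  if (all(as.character(pheno$studbook_no) %in% rownames(K))) {
    Ks <- K[as.character(pheno$studbook_no), as.character(pheno$studbook_no),
            drop = FALSE]
  } else if (all(matrix$samples %in% rownames(K))) {
    Ks <- K[matrix$samples, matrix$samples, drop = FALSE]
  } else {
    stop("kinship matrix IDs match neither individuals nor samples")
  }
  m <- nrow(matrix$sites)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    fit <- fit_site_bmm(matrix$m[i, ], matrix$total[i, ], x,
                        covars = covars, K = Ks, config = config,
                        fix_sigma = fix_sigma)
    rows[[i]] <- data.frame(
      beta = fit$beta, se = fit$se, p = fit$wald_p,
      beta_raw = fit$beta_raw, sigma_g2 = fit$sigma_g2,
      sigma_e2 = fit$sigma_e2, converged = fit$converged,
      skip_reason = fit$skip_reason, stringsAsFactors = FALSE)
  }
  res <- cbind(matrix$sites, do.call(rbind, rows))
  rownames(res) <- NULL
  p_ok <- res$p[!is.na(res$p)]
  inflation <- if (length(p_ok)) {
    stats::median(stats::qchisq(1 - p_ok, df = 1)) /
      stats::qchisq(0.5, df = 1)
  } else {
    NA_real_
  }
  list(results = res, inflation = inflation)
}

#' Quantile-quantile diagnostics for association p-values
#'
#' Pairs sorted observed p-values with uniform order-statistic expectations
#' on the -log10 scale and summarises inflation/deflation.
#'
#' @param p_values Numeric p-values (NAs dropped).
#' @return A list: `expected` and `observed` (-log10 scale, ascending),
#'   `slope` (least-squares through the origin), `direction`
#'   (`"inflated"`, `"deflated"` or `"uniform"` by a 10% slope band).
#' @export
qq_diagnostics <- function(p_values) {
  p <- sort(p_values[!is.na(p_values)])
  if (length(p) < 1L) stop("no finite p-values")
  m <- length(p)
  expected <- -log10(seq_len(m) / (m + 1))
  observed <- -log10(rev(p))  # both descending-significance order
  expected <- sort(expected)
  observed <- sort(observed)
  slope <- sum(expected * observed) / sum(expected^2)
  direction <- if (slope > 1.1) "inflated" else if (slope < 0.9) "deflated"
  else "uniform"
  list(expected = expected, observed = observed, slope = slope,
       direction = direction)
}

#' Write an association table as TSV
#'
#' @param assoc Result of [fit_all_sites()] (or its `results` element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  res <- if (is.data.frame(assoc)) assoc else assoc$results
  data.table::fwrite(res, path, sep = "\t", quote = FALSE)
  invisible(path)
}
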