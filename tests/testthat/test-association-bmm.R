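test_that("degenerate sites are skipped with the right flags", {
  K <- diag(4)
  r <- rep(10, 4)
  mono <- fit_site_bmm(rep(0, 4), r, c(0, 1, 0, 1), K = K)
  expect_equal(mono$skip_reason, "monomorphic")
  expect_true(is.na(mono$beta))
  full <- fit_site_bmm(r, r, c(0, 1, 0, 1), K = K)
  expect_equal(full$skip_reason, "monomorphic")
  const <- fit_site_bmm(c(1, 2, 3, 4), r, rep(2, 4), K = K)
  expect_equal(const$skip_reason, "constant-predictor")
  expect_error(fit_site_bmm(c(1, 1), c(0, 10), c(0, 1), K = diag(2)),
               ">= 1")
})

test_that("identical proportions give a zero effect", {
  f <- fit_site_bmm(c(3, 3), c(10, 10), c(0, 1), K = diag(2),
                    fix_sigma = c(0, 0))
  expect_equal(f$beta, 0, tolerance = 1e-8)
})

test_that("saturated two-group fit recovers the closed-form logit difference", {
  f <- fit_site_bmm(c(2, 8), c(10, 10), c(0, 1), K = diag(2),
                    fix_sigma = c(0, 0))
  expect_equal(f$beta_raw, qlogis(0.8) - qlogis(0.2), tolerance = 1e-4)
})

test_that("no-random-effect limit agrees with IRLS binomial regression", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(8:16, 1)
    x <- rnorm(n)
    r <- sample(10:30, n, replace = TRUE)
    y <- rbinom(n, r, plogis(rnorm(1) + 0.5 * x))
    if (all(y == 0) || all(y == r)) next
    f <- fit_site_bmm(y, r, x, K = diag(n), fix_sigma = c(0, 0))
    g <- glm(cbind(y, r - y) ~ I((x - mean(x)) / sd(x)), family = binomial)
    expect_equal(f$beta, unname(coef(g)[2]), tolerance = 1e-4)
    expect_equal(f$se, unname(sqrt(diag(vcov(g)))[2]), tolerance = 1e-3)
  }
})

test_that("PQL tracks full maximum likelihood on a kinship toy", {
  # 6 half/full sibs from a parent-offspring pedigree; variance components
  # pinned so the oracle integrates over the same random-effect law
  ped <- data.frame(id = c("s", "d", "k1", "k2", "k3", "k4"),
                    sire = c(NA, NA, "s", "s", "s", "s"),
                    dam = c(NA, NA, "d", "d", "d", "d"),
                    stringsAsFactors = FALSE)
  A <- additive_relationship(ped)
  sg2 <- 0.5; se2 <- 0.25
  set.seed(6)
  x <- c(-1, -0.5, 0, 0.3, 0.8, 1.2)
  r <- rep(30, 6)
  g <- drop(crossprod(chol(sg2 * A), rnorm(6)))
  y <- rbinom(6, r, plogis(0.2 + 1.0 * x + g + rnorm(6, sd = sqrt(se2))))
  f <- fit_site_bmm(y, r, x, K = A, fix_sigma = c(sg2, se2))
  Sigma <- sg2 * A + se2 * diag(6)
  ml <- oracle_bmm_ml(y, r, x, Sigma)
  # both on the raw predictor scale
  expect_lt(abs(f$beta_raw - ml$beta), 0.2)
})

test_that("beta is antisymmetric in x and stable under affine shifts", {
  set.seed(17)
  n <- 10
  x <- rnorm(n)
  r <- rep(20, n)
  y <- rbinom(n, r, plogis(0.3 * x))
  K <- diag(n)
  f1 <- fit_site_bmm(y, r, x, K = K, fix_sigma = c(0, 0))
  f2 <- fit_site_bmm(y, r, -x, K = K, fix_sigma = c(0, 0))
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-6)
  # affine shift: standardized beta unchanged; raw beta rescaled by slope
  f3 <- fit_site_bmm(y, r, 3 * x + 7, K = K, fix_sigma = c(0, 0))
  expect_equal(f1$beta, f3$beta, tolerance = 1e-6)
  expect_equal(f1$beta_raw, 3 * f3$beta_raw, tolerance = 1e-6)
})

test_that("proportional count doubling cannot increase the standard error", {
  set.seed(23)
  n <- 12
  x <- rnorm(n)
  r <- sample(10:20, n, replace = TRUE)
  y <- rbinom(n, r, plogis(0.5 * x))
  y[y == 0] <- 1  # keep polymorphic under doubling
  f1 <- fit_site_bmm(y, r, x, K = diag(n), fix_sigma = c(0.1, 0.1))
  f2 <- fit_site_bmm(2 * y, 2 * r, x, K = diag(n), fix_sigma = c(0.1, 0.1))
  expect_lte(f2$se, f1$se + 1e-10)
})

test_that("fit_all_sites flags bad sites, aligns kinship, reports inflation", {
  ds <- small_dataset()
  ms <- lapply(ds$methylomes, filter_cg)
  blood <- ds$phenotypes$sample_id[ds$phenotypes$tissue == "Blood"]
  u <- unite(ms[blood])
  u <- subset_matrix(u, sites = 1:25)
  # plant a monomorphic site
  u$m[1, ] <- 0L
  res <- fit_all_sites(u, ds$phenotypes, ds$kinship,
                       bmm_config(predictor = "avg_litter_size"))
  expect_equal(nrow(res$results), 25L)
  expect_equal(res$results$skip_reason[1], "monomorphic")
  expect_true(all(res$results$skip_reason[-1] %in%
                    c("none", "non-converged")))
  expect_true(is.finite(res$inflation))
  bad <- ds$phenotypes[ds$phenotypes$sample_id != blood[1], ]
  expect_error(fit_all_sites(u, bad, ds$kinship, bmm_config()),
               "phenotype missing")
})

test_that("QQ diagnostics report slope and direction", {
  m <- 200
  grid <- (1:m) / (m + 1)
  q <- qq_diagnostics(grid)
  expect_equal(q$slope, 1, tolerance = 0.02)
  expect_equal(q$direction, "uniform")
  expect_lt(max(abs(q$expected - q$observed)), 0.01)

  deflated <- qq_diagnostics(rep(1, 50))
  expect_equal(deflated$direction, "deflated")
  expect_error(qq_diagnostics(NA_real_), "no finite")
})
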