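test_that("profile optimum matches a fine grid search of the restricted likelihood", {
  fx <- make_fixture(20, 40, sigma_b2 = 0.05, seed = 1)
  fit <- gblup(fx$y, fx$grm)
  d <- fit$eigen$d; yt <- fit$rotated$y; ot <- fit$rotated$one; n <- fit$n
  prof <- function(lam) {
    w <- lam * d + 1
    sxx <- sum(ot^2 / w); mu <- sum(ot * yt / w) / sxx
    s2 <- sum((yt - mu * ot)^2 / w) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) + sum(log(w)) +
              log(sxx) + (n - 1))
  }
  lgrid <- exp(seq(log(1e-6), log(1e6), length.out = 10000))
  ll <- vapply(lgrid, prof, 0)
  lam_grid <- lgrid[which.max(ll)]
  # the grid resolves log-lambda to ~2.8e-3; agreement within one cell
  expect_equal(fit$vc$lambda, lam_grid, tolerance = 3e-3)
  # the optimizer's maximum is at least as good as the grid's
  expect_gte(prof(fit$vc$lambda), max(ll) - 1e-8)
})

test_that("eigen-profile REML equals dense explicit-V REML on small n", {
  for (seed in c(2, 3)) {
    fx <- make_fixture(30, 25, sigma_b2 = 0.03, seed = seed)
    fit <- gblup(fx$y, fx$grm)
    # same restricted log-likelihood surface, independently computed
    for (lam in c(0.1, fit$vc$lambda, 5)) {
      w <- lam * fit$eigen$d + 1
      ot <- fit$rotated$one; yt <- fit$rotated$y; n <- fit$n
      sxx <- sum(ot^2 / w); mu <- sum(ot * yt / w) / sxx
      s2 <- sum((yt - mu * ot)^2 / w) / (n - 1)
      ll_eigen <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) +
                            sum(log(w)) + log(sxx) + (n - 1))
      expect_equal(ll_eigen, dense_profile_ll(fx$y, fx$grm$G, lam),
                   tolerance = 1e-6)
    }
    # dense grid maximum agrees with the fitted ratio
    lg <- exp(seq(log(1e-4), log(1e4), length.out = 2000))
    lld <- vapply(lg, function(l) dense_profile_ll(fx$y, fx$grm$G, l), 0)
    expect_equal(log(fit$vc$lambda), log(lg[which.max(lld)]), tolerance = 1e-2)
  }
})

test_that("zero G gives the null-model limit, constant y errors", {
  set.seed(4)
  y <- rnorm(15)
  fit <- gblup(y, matrix(0, 15, 15))
  expect_equal(fit$vc$sigma_g2, 0)
  expect_equal(fit$mu_g, rep(0, 15))
  expect_equal(fit$vc$sigma_e2, var(y))       # REML n-1 denominator
  expect_true(fit$boundary)
  expect_error(gblup(rep(1, 10), diag(10)), "constant")
})

test_that("scale equivariance: fitting 2y quadruples both variance components", {
  fx <- make_fixture(40, 30, seed = 5)
  f1 <- gblup(fx$y, fx$grm)
  f2 <- gblup(2 * fx$y, fx$grm)
  expect_equal(f2$vc$sigma_g2, 4 * f1$vc$sigma_g2, tolerance = 1e-6)
  expect_equal(f2$vc$sigma_e2, 4 * f1$vc$sigma_e2, tolerance = 1e-6)
})

test_that("with G = I the total variance is recovered even though the split is not identified", {
  set.seed(6)
  y <- rnorm(60)
  fit <- gblup(y, diag(60))
  expect_equal(fit$vc$sigma_g2 + fit$vc$sigma_e2, var(y), tolerance = 1e-6)
})

test_that("BLUPs satisfy the jointly-normal identities", {
  fx <- make_fixture(30, 8, sigma_b2 = 0.08, seed = 7)
  fit <- gblup(fx$y, fx$grm)
  # BLUPs inherit the null space of G
  expect_lt(abs(sum(fit$mu_g)), 1e-8)
  cc <- conditional_cov(fit)
  # conditional-variance decomposition
  expect_lt(max(abs(cc$cov_mu_g + cc$cov_g_given_y -
                      fit$vc$sigma_g2 * fx$grm$G)),
            1e-6 * max(abs(fit$vc$sigma_g2 * fx$grm$G)))
  # Sigma_{g|y} positive semidefinite
  ev <- eigen(cc$cov_g_given_y, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))

  mb <- marker_blups(fit, covariances = TRUE)
  p <- ncol(fx$grm$centered)
  # Sigma_{beta|y} + Cov(mu_beta) = sigma_b2 I, entrywise
  expect_lt(max(abs(mb$cov_beta_given_y + mb$cov_mu_beta -
                      diag(fit$vc$sigma_b2, p))), 1e-8)
  # PX mu_beta = mu_g
  expect_lt(max(abs(fx$grm$centered %*% mb$mu_beta - fit$mu_g)), 1e-8)
})

test_that("marker BLUPs equal the ridge-regression solution", {
  fx <- make_fixture(25, 6, sigma_b2 = 0.1, seed = 8)
  fit <- gblup(fx$y, fx$grm)
  Z <- fx$grm$centered
  k <- fit$vc$sigma_e2 / fit$vc$sigma_b2
  ridge <- solve(crossprod(Z) + diag(k, ncol(Z)),
                 crossprod(Z, fx$y - fit$vc$mu))
  expect_lt(max(abs(marker_blups(fit)$mu_beta - drop(ridge))), 1e-8)
})

test_that("parameter recovery at moderate scale is unbiased within Monte-Carlo error", {
  # small-scale recovery check; the full study-size run lives in the
  # acceptance suite
  X <- simulate_genotypes(200, 300, seed = 9)
  b <- build_grm(X)
  s2b <- 0.5 / b$c
  set.seed(10)
  est <- replicate(60, {
    beta <- rnorm(ncol(b$centered), 0, sqrt(s2b))
    y <- drop(b$centered %*% beta) + rnorm(200, 0, sqrt(0.5))
    gblup(y, b)$vc$sigma_g2
  })
  z <- (mean(est) - 0.5) / (sd(est) / sqrt(length(est)))
  expect_lt(abs(z), 4)
})

test_that("fit methods behave like standard modelling objects", {
  fx <- make_fixture(30, 10, seed = 11)
  fit <- gblup(fx$y, fx$grm)
  expect_output(print(fit), "sigma_g\\^2")
  expect_output(print(summary(fit)), "phenotypic sample variance")
  expect_named(coef(fit), "(Intercept)")
  expect_equal(fitted(fit) + residuals(fit), unname(fx$y), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(logLik(fit)), fit$loglik_restricted)
  expect_equal(predict(fit), fit$mu_g)
  expect_equal(predict(fit, newdata = fx$X, type = "response"),
               fitted(fit), tolerance = 1e-10, ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30L, 3L))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
})

test_that("phenotype scaling flag rescales to unit sample variance", {
  fx <- make_fixture(40, 20, seed = 12)
  fit <- gblup(fx$y, fx$grm, scale_phenotype = TRUE)
  expect_equal(var(fit$y), 1, tolerance = 1e-12)
  f0 <- gblup(fx$y, fx$grm)
  expect_equal(fit$vc$sigma_g2, f0$vc$sigma_g2 / var(fx$y), tolerance = 1e-6)
})
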