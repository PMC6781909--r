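test_that("the two algebraic routes to V and W agree", {
  fx <- make_fixture(40, 60, sigma_b2 = 0.02, seed = 1)
  fit <- gblup(fx$y, fx$grm)
  # equivalent-model form sigma_g2 tr(G)/(n-1) vs marker form
  # sigma_b2 tr(SigmaHat_X)
  V_eq <- unconditional_expectation(fit)
  mc <- marker_covariance(fx$grm$centered)
  expect_equal(V_eq, fit$vc$sigma_b2 * mc_trace(mc), tolerance = 1e-10)
  expect_equal(V_eq, v_marker_form(fit), tolerance = 1e-10)

  fx2 <- make_fixture(30, 10, sigma_b2 = 0.05, seed = 2)
  fit2 <- gblup(fx2$y, fx2$grm)
  expect_equal(best_predictor(fit2), w_marker_form(fit2), tolerance = 1e-9)
  # cross_check flag exercises the same dual route internally
  expect_silent(genomic_variance(fit2, c("V", "W"), cross_check = TRUE))
})

test_that("W decomposes exactly as V plus the LD contribution", {
  fx <- make_fixture(35, 20, sigma_b2 = 0.03, seed = 3,
                     ld_model = "ar1_haplotype", rho = 0.6)
  fit <- gblup(fx$y, fx$grm)
  gv <- genomic_variance(fit, c("V", "W"))
  W <- gv$value[gv$estimator == "W"]; V <- gv$value[gv$estimator == "V"]
  L <- gv$ld_component[gv$estimator == "W"]
  expect_identical(W, V + L)                       # exact by construction
  expect_equal(ld_contribution(fit), L, tolerance = 1e-12)
  # explicit printed double sum agrees with the difference route
  expect_equal(ld_contribution(fit, method = "explicit"), L,
               tolerance = 1e-9)
  # base population too, through a supplied R
  R <- make_relationship("block_family", 35, 5, 0.3, ids = rownames(fx$X))
  gvb <- genomic_variance(fit, c("Vstar", "Wstar"), R = R)
  expect_identical(gvb$value[gvb$estimator == "Wstar"],
                   gvb$value[gvb$estimator == "Vstar"] +
                     gvb$ld_component[gvb$estimator == "Wstar"])
  expect_equal(ld_contribution(fit, "base", R = R, method = "explicit"),
               gvb$ld_component[gvb$estimator == "Wstar"], tolerance = 1e-9)
})

test_that("explicit LD sum matches a naive double loop and splits by diagonal", {
  fx <- make_fixture(30, 10, sigma_b2 = 0.05, seed = 4,
                     ld_model = "ar1_haplotype", rho = 0.8)
  fit <- gblup(fx$y, fx$grm)
  mb <- marker_blups(fit, covariances = TRUE)
  M <- tcrossprod(mb$mu_beta) - mb$cov_mu_beta
  S <- crossprod(fx$grm$centered) / (fit$n - 1)
  p <- ncol(S)
  diag_sum <- 0; off_sum <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) diag_sum <- diag_sum + M[i, i] * S[i, i]
    else off_sum <- off_sum + M[i, j] * S[i, j]
  }
  br <- ld_contribution(fit, method = "explicit", breakdown = TRUE)
  expect_equal(br$diagonal, diag_sum, tolerance = 1e-10)
  expect_equal(br$off_diagonal, off_sum, tolerance = 1e-10)
  expect_equal(br$total, diag_sum + off_sum, tolerance = 1e-10)
  expect_identical(sign(br$off_diagonal), sign(off_sum))
})

test_that("orthogonal marker columns give a zero off-diagonal LD part", {
  X <- matrix(c(0, 0, 2, 2,
                0, 2, 0, 2), 4, 2,
              dimnames = list(paste0("s", 1:4), c("m1", "m2")))
  b <- build_grm(X)
  expect_equal(crossprod(b$centered)[1, 2], 0)     # SigmaHat_X diagonal
  set.seed(5)
  y <- rnorm(4, sd = 1)
  names(y) <- rownames(X)
  fit <- gblup(y, b)
  br <- ld_contribution(fit, method = "explicit", breakdown = TRUE)
  expect_equal(br$off_diagonal, 0, tolerance = 1e-12)
})

test_that("known-effects limit: with beta fixed the quadratic form is the realized s_g^2", {
  fx <- make_fixture(20, 6, sigma_b2 = 0.1, seed = 6)
  mc <- marker_covariance(fx$grm$centered, cap = 100L)
  beta <- fx$ds$true_beta[colnames(fx$grm$centered)]
  # E[beta beta' | y] degenerates to beta beta' when beta is known:
  # tr(SigmaHat_X beta beta') = beta' SigmaHat_X beta = s_g^2
  expect_equal(sum(mc$matrix * tcrossprod(beta)),
               fx$ds$realized_sg2, tolerance = 1e-12)
  expect_equal(mc_quad(mc, beta), fx$ds$realized_sg2, tolerance = 1e-12)
})

test_that("estimator table carries provenance and validates populations", {
  fx <- make_fixture(25, 15, seed = 7)
  fit <- gblup(fx$y, fx$grm)
  expect_error(genomic_variance(fit, c("Vstar", "Wstar")), "relationship matrix")
  gv <- genomic_variance(fit, c("V", "W", "Vsstar", "Wsstar"))
  expect_true(all(gv$value >= 0))                 # PSD quadratic forms
  expect_output(print(gv), "estimator")
})

test_that("heritability summaries follow both conventions and refuse the base population", {
  fx <- make_fixture(60, 40, sigma_b2 = 0.02, seed = 8)
  fit <- gblup(fx$y, fx$grm, scale_phenotype = TRUE)
  gv <- genomic_variance(fit, c("V", "W"))
  h <- heritability(fit, gv)
  V <- gv$value[gv$estimator == "V"]; W <- gv$value[gv$estimator == "W"]
  expect_equal(h$h2_V, V / var(fit$y), tolerance = 1e-12)
  expect_equal(h$h2_W, W, tolerance = 1e-10)       # scaled y: h2_W = W
  expect_equal(h$h2_tilde_W, W / (W + fit$vc$sigma_e2), tolerance = 1e-12)
  expect_true(h$h2_tilde_V >= 0 && h$h2_tilde_V <= 1)
  expect_true(h$h2_tilde_W >= 0 && h$h2_tilde_W <= 1)
  expect_output(print(h), "h2_W")

  R <- diag(60); dimnames(R) <- list(rownames(fx$X), rownames(fx$X))
  gvb <- genomic_variance(fit, c("Vstar", "Wstar"), R = R)
  expect_error(heritability(fit, gvb), "current population")
})

test_that("estimators are invariant to sample reordering", {
  fx <- make_fixture(30, 20, seed = 9)
  fit1 <- gblup(fx$y, fx$grm)
  set.seed(10)
  perm <- sample(30)
  fit2 <- gblup(fx$y[perm], build_grm(fx$X[perm, ]))
  # equal up to the optimizer's tolerance (row order perturbs the
  # eigendecomposition in the last floating-point digits)
  expect_equal(best_predictor(fit2), best_predictor(fit1), tolerance = 1e-6)
  expect_equal(ld_contribution(fit2), ld_contribution(fit1), tolerance = 1e-6)
})
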