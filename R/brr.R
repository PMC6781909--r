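#' Bayesian ridge regression by Gibbs sampling
#'
#' Samples the posterior of the marker-effect model
#' y = mu 1 + Z beta + e, beta_j ~ N(0, sigma_b2), e ~ N(0, sigma_e2 I),
#' Z = PX the centred genotypes, with weakly informative scaled-inverse-
#' chi-square priors on both variance components (flat prior on mu).  One
#' full Gibbs sweep updates mu, each beta_j from its scalar normal full
#' conditional, then sigma_b2 and sigma_e2 (unless held fixed).  The
#' posterior mean of the quadratic form beta' SigmaHat_X beta — the M2
#' estimator, see [m2()] — is the Bayesian counterpart of the closed-form
#' best predictor W, which makes the sampler an independent numerical
#' cross-check of the gBLUP route.
#'
#' @param y numeric phenotype vector.
#' @param grm a `"grm"` object carrying the centred genotypes.
#' @param chain total Gibbs iterations (default 12000).
#' @param burnin discarded leading iterations (default 2000).
#' @param thin keep every `thin`-th draw (default 10).
#' @param seed integer seed; same seed and config reproduce the chain
#'   bit-exactly.
#' @param fix_vc `NULL`, or `list(sigma_b2 =, sigma_e2 =)` to hold the
#'   variance components fixed (turns the sampler into draws from the exact
#'   conjugate conditional posterior of beta, whose mean is the BLUP).
#' @param prior_df degrees of freedom of both scaled-inv-chi-square priors
#'   (default 5).
#' @param prior_split fraction of var(y) assigned to the genomic side when
#'   deriving the prior scales (default 0.5; the residual prior scale gets
#'   the complement).
#' @return object of class `"brr"`: `beta` (M x p retained draws), `vc`
#'   (M x 2, columns sigma_b2/sigma_e2), `mu` (M draws), `config`.
#' @export
brr <- function(y, grm, chain = 12000L, burnin = 2000L, thin = 10L,
                seed = 1L, fix_vc = NULL, prior_df = 5,
                prior_split = 0.5) {
  stopifnot(inherits(grm, "grm"))
  Z <- grm$centered
  if (is.null(Z)) stop("brr needs centred genotypes in the grm object")
  if (chain <= burnin) stop("chain length must exceed burn-in")
  if ((chain - burnin) %% thin != 0)
    stop("(chain - burnin) must be a multiple of thin")
  if (!is.null(names(y)) && !is.null(rownames(Z))) y <- y[rownames(Z)]
  y <- as.numeric(y)
  n <- length(y); p <- ncol(Z)
  set.seed(seed)

  zz <- colSums(Z^2)
  vy <- stats::var(y)
  # prior scales: split var(y) between the two components; the marker-level
  # scale spreads the genomic share over c = 2 sum p(1-p)
  S_e <- (1 - prior_split) * vy
  S_b <- prior_split * vy / grm$c
  fixed <- !is.null(fix_vc)
  s2b <- if (fixed) fix_vc$sigma_b2 else S_b
  s2e <- if (fixed) fix_vc$sigma_e2 else S_e

  M <- (chain - burnin) %/% thin
  beta_out <- matrix(NA_real_, M, p, dimnames = list(NULL, colnames(Z)))
  vc_out <- matrix(NA_real_, M, 2, dimnames = list(NULL, c("sigma_b2", "sigma_e2")))
  mu_out <- numeric(M)

  beta <- numeric(p)
  mu <- mean(y)
  e <- y - mu                       # current residual y - mu - Z beta
  k <- 0L
  for (it in seq_len(chain)) {
    # intercept (flat prior): mu | rest ~ N(mean(e + mu), s2e/n)
    e <- e + mu
    mu <- mean(e) + stats::rnorm(1L, sd = sqrt(s2e / n))
    e <- e - mu
    # marker effects, scalar sweep
    for (j in seq_len(p)) {
      e <- e + Z[, j] * beta[j]
      cj <- zz[j] + s2e / s2b
      mj <- sum(Z[, j] * e) / cj
      beta[j] <- stats::rnorm(1L, mj, sqrt(s2e / cj))
      e <- e - Z[, j] * beta[j]
    }
    if (!is.finite(sum(beta)))
      stop("divergent chain at iteration ", it)
    if (!fixed) {
      s2b <- (sum(beta^2) + prior_df * S_b) /
        stats::rchisq(1L, df = p + prior_df)
      s2e <- (sum(e^2) + prior_df * S_e) /
        stats::rchisq(1L, df = n + prior_df)
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      k <- k + 1L
      beta_out[k, ] <- beta
      vc_out[k, ] <- c(s2b, s2e)
      mu_out[k] <- mu
    }
  }
  structure(list(beta = beta_out, vc = vc_out, mu = mu_out,
                 config = list(chain = chain, burnin = burnin, thin = thin,
                               seed = seed, fix_vc = fix_vc,
                               prior_df = prior_df, prior_split = prior_split),
                 grm = grm),
            class = "brr")
}

#' @export
print.brr <- function(x, ...) {
  cat(sprintf("Bayesian ridge regression posterior: %d draws x %d markers\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  chain %d, burn-in %d, thin %d, seed %d%s\n",
              x$config$chain, x$config$burnin, x$config$thin, x$config$seed,
              if (!is.null(x$config$fix_vc)) " (variance components fixed)" else ""))
  invisible(x)
}

#' Posterior-mean genomic variance (M2 / M2*)
#'
#' Monte-Carlo average over retained draws of the quadratic form
#' beta' SigmaHat_X beta (current population) or beta' SigmaHat_X* beta
#' (base population, SigmaHat_X* = Z' B Z/(n-1) for the base-selecting B),
#' each draw evaluated implicitly as ||Z beta||^2/(n-1).  The Monte-Carlo
#' standard error is estimated by batch means (20 batches), which is robust
#' to residual autocorrelation in the chain.
#'
#' @param posterior a `"brr"` object.
#' @param b a `"b_matrix"`; default identity (current population, M2).
#' @return list with `estimate`, `mc_se`, and the per-draw values `draws`.
#' @export
m2 <- function(posterior, b = make_b_matrix("current")) {
  stopifnot(inherits(posterior, "brr"), inherits(b, "b_matrix"))
  Z <- posterior$grm$centered
  n <- nrow(Z)
  Gb <- Z %*% t(posterior$beta)           # n x M matrix of genomic values
  draws <- if (b$identity) colSums(Gb^2) / (n - 1)
           else colSums(Gb * (b$B %*% Gb)) / (n - 1)
  M <- length(draws)
  nb <- min(20L, M)
  bsz <- M %/% nb
  bm <- vapply(seq_len(nb),
               function(i) mean(draws[((i - 1L) * bsz + 1L):(i * bsz)]), 0)
  se <- stats::sd(bm) / sqrt(nb)
  list(estimate = mean(draws), mc_se = se, draws = draws)
}
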