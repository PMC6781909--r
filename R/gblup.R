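#' Fit the gBLUP model by spectral profile REML
#'
#' Fits the linear mixed model
#' \deqn{y = \mu 1 + g + \varepsilon, \quad g \sim N(0, \sigma_g^2 G),
#'       \quad \varepsilon \sim N(0, \sigma_\varepsilon^2 I)}
#' with an intercept-only fixed effect.  Because there are exactly two
#' variance components the restricted likelihood can be profiled down to one
#' dimension: G is eigendecomposed once, y and 1 are rotated into the
#' eigenbasis, and the variance ratio \eqn{\lambda = \sigma_g^2 /
#' \sigma_\varepsilon^2} is optimised on the log scale (coarse log-grid
#' bracket followed by derivative-free refinement).  This is exact for this
#' model class, not an approximation.
#'
#' @param y numeric phenotype vector (named if alignment with `grm` is
#'   wanted); its sample variance must be positive.
#' @param grm a `"grm"` object from [build_grm()], or a plain symmetric
#'   n x n covariance-structure matrix.
#' @param lambda_range search interval for the variance ratio
#'   \eqn{\lambda} (default `c(1e-8, 1e8)`).
#' @param tol convergence tolerance in \eqn{\log\lambda} (default 1e-10).
#' @param ngrid number of coarse log-grid points used to bracket the
#'   optimum before refinement.
#' @param scale_phenotype if `TRUE`, y is divided by its sample standard
#'   deviation before fitting, so the phenotypic sample variance is 1 (the
#'   convention under which estimated genomic variances read directly as
#'   heritabilities).
#' @return object of class `"gblup"`.  Components include `vc` (list with
#'   `sigma_g2`, `sigma_e2`, `sigma_b2` = sigma_g2/c, `mu`, `lambda`),
#'   `mu_g` (BLUP of the genomic values, E\[g|y\]), `loglik_restricted`,
#'   `converged`, `boundary`, `n_iter`, the eigendecomposition cache
#'   `eigen`, and the data (`y`, `grm`).
#' @seealso [marker_blups()], [genomic_variance()], [conditional_cov()]
#' @export
gblup <- function(y, grm, lambda_range = c(1e-8, 1e8), tol = 1e-10,
                  ngrid = 200L, scale_phenotype = FALSE) {
  if (is.matrix(grm)) {
    if (nrow(grm) != ncol(grm)) stop("G must be square")
    grm <- structure(list(G = grm, centered = NULL, c = NA_real_,
                          n = nrow(grm), p = NA_integer_,
                          allele_freqs = NULL, dropped_markers = character()),
                     class = "grm")
  }
  stopifnot(inherits(grm, "grm"))
  G <- grm$G
  if (!is.null(names(y)) && !is.null(rownames(G))) {
    if (!all(rownames(G) %in% names(y)))
      stop("phenotype vector does not cover all GRM samples")
    y <- y[rownames(G)]
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(G)) stop("length(y) does not match the GRM dimension")
  if (stats::var(y) <= 0) stop("phenotype vector is constant")
  if (scale_phenotype) y <- y / stats::sd(y)

  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-8 * max(d, 1e-300))
    stop("G is not positive semidefinite beyond tolerance")
  d <- pmax(d, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, n)))

  # restricted log-likelihood profiled over (mu, sigma_e2) at fixed lambda
  prof <- function(loglam) {
    w <- exp(loglam) * d + 1
    sxx <- sum(ot^2 / w)
    mu <- sum(ot * yt / w) / sxx
    r <- yt - mu * ot
    s2 <- sum(r^2 / w) / (n - 1)
    ll <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) +
                    sum(log(w)) + log(sxx) + (n - 1))
    list(ll = ll, mu = mu, sigma_e2 = s2)
  }

  if (max(d) <= 1e-12 * n) {          # G numerically zero: null-model limit
    at <- prof(log(lambda_range[1]))
    lambda <- 0
    opt <- list(maximum = log(lambda_range[1]), objective = at$ll)
    n_eval <- 1L
    boundary <- TRUE
  } else {
    lgrid <- seq(log(lambda_range[1]), log(lambda_range[2]),
                 length.out = ngrid)
    llg <- vapply(lgrid, function(l) prof(l)$ll, 0)
    i <- which.max(llg)
    lo <- lgrid[max(i - 1L, 1L)]
    hi <- lgrid[min(i + 1L, ngrid)]
    opt <- stats::optimize(function(l) prof(l)$ll, c(lo, hi),
                           maximum = TRUE, tol = tol)
    n_eval <- ngrid + 1L   # grid passes + refinement (optimize is internal)
    boundary <- i == 1L && opt$maximum <= lgrid[1] + 1e-6
    lambda <- if (boundary) 0 else exp(opt$maximum)
  }

  at <- prof(if (lambda > 0) log(lambda) else log(lambda_range[1]))
  if (lambda == 0) {                  # exact boundary values
    mu <- mean(y)
    sigma_e2 <- sum((y - mu)^2) / (n - 1)
    at$mu <- mu; at$sigma_e2 <- sigma_e2
  }
  sigma_e2 <- at$sigma_e2
  sigma_g2 <- lambda * sigma_e2
  w <- lambda * d + 1
  r <- yt - at$mu * ot
  qt <- r / (sigma_e2 * w)            # rotated Q y (REML projection of y)
  mu_g <- drop(U %*% (sigma_g2 * d * qt))
  names(mu_g) <- rownames(G)

  structure(list(
    vc = list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
              sigma_b2 = sigma_g2 / grm$c, mu = at$mu, lambda = lambda),
    mu_g = mu_g,
    loglik_restricted = opt$objective,
    converged = TRUE, boundary = boundary, n_iter = n_eval,
    eigen = list(U = U, d = d),
    rotated = list(y = yt, one = ot, q = qt, resid = r),
    y = y, n = n, grm = grm,
    scaled = scale_phenotype), class = "gblup")
}

# rotated representation of the REML projection Q = Vinv - Vinv 1 s^-1 1' Vinv
# returns per-fit scalars used all over the variance predictors
.gblup_scalars <- function(fit) {
  d <- fit$eigen$d
  lam <- fit$vc$lambda
  s2e <- fit$vc$sigma_e2
  w <- lam * d + 1
  ot <- fit$rotated$one
  s <- sum(ot^2 / (s2e * w))                       # 1' Vinv 1
  list(d = d, w = w, s2e = s2e, s = s,
       trG = sum(d),
       trGVinvG = sum(d^2 / (s2e * w)),
       aa = sum((d * ot / (s2e * w))^2))           # ||G Vinv 1||^2
}

# tr(G Q G) with the REML (intercept-adjusted) projection
.tr_GQG <- function(fit) {
  sc <- .gblup_scalars(fit)
  sc$trGVinvG - sc$aa / sc$s
}

#' Apply the REML projection operator Q to a vector or matrix
#'
#' Q = Vinv - Vinv 1 (1' Vinv 1)^-1 1' Vinv with V = sigma_g2 G + sigma_e2 I
#' at the fitted components.  Q y is cached from the fit; general products
#' are computed in the eigenbasis.
#'
#' @param fit a `"gblup"` object.
#' @param M n-vector or n x k matrix.
#' @return Q \%*\% M.
#' @export
gblup_project <- function(fit, M) {
  U <- fit$eigen$U
  sc <- .gblup_scalars(fit)
  Mt <- crossprod(U, M)
  VinvM <- Mt / (sc$s2e * sc$w)
  ot <- fit$rotated$one
  Vinv1 <- ot / (sc$s2e * sc$w)
  QMt <- VinvM - Vinv1 %*% (crossprod(Vinv1, Mt) / sc$s)
  U %*% QMt
}

#' Conditional covariance matrices of the genomic values
#'
#' For the jointly normal pair (g, y) at the fitted components:
#' Cov of the BLUP, \eqn{Cov(\mu_{g|y}) = \hat\sigma_g^4 G Q G}, and the
#' conditional covariance \eqn{\Sigma_{g|y} = \hat\sigma_g^2 G -
#' Cov(\mu_{g|y})}; the two add back to \eqn{\hat\sigma_g^2 G}.  Dense
#' n x n matrices; intended for moderate n.
#'
#' @param fit a `"gblup"` object.
#' @return list with `cov_mu_g` and `cov_g_given_y`.
#' @export
conditional_cov <- function(fit) {
  G <- fit$grm$G
  QG <- gblup_project(fit, G)
  cov_mu <- fit$vc$sigma_g2^2 * (G %*% QG)
  cov_mu <- (cov_mu + t(cov_mu)) / 2
  list(cov_mu_g = cov_mu,
       cov_g_given_y = fit$vc$sigma_g2 * G - cov_mu)
}

#' BLUPs of the marker effects and their covariances
#'
#' In the marker parameterisation beta ~ N(0, sigma_b2 I), the BLUP is
#' \eqn{\mu_{\beta|y} = \hat\sigma_\beta^2 Z' Q y} with Z = PX the centred
#' genotypes; \eqn{Cov(\mu_{\beta|y}) = \hat\sigma_\beta^4 Z' Q Z} and
#' \eqn{\Sigma_{\beta|y} = \hat\sigma_\beta^2 I - Cov(\mu_{\beta|y})}.
#' The genomic-value BLUP is recovered exactly as Z mu_beta = mu_g.
#'
#' @param fit a `"gblup"` fitted on a `"grm"` carrying centred genotypes.
#' @param covariances also return the two p x p covariance matrices
#'   (requires p <= `cap`).
#' @param cap largest p for which p x p matrices are materialised.
#' @return list with `mu_beta` and, if requested, `cov_mu_beta` and
#'   `cov_beta_given_y`.
#' @export
marker_blups <- function(fit, covariances = FALSE, cap = 20000L) {
  Z <- fit$grm$centered
  if (is.null(Z))
    stop("fit was built from a bare relationship matrix; no centred genotypes available")
  s2b <- fit$vc$sigma_b2
  Qy <- drop(fit$eigen$U %*% fit$rotated$q)
  out <- list(mu_beta = drop(s2b * crossprod(Z, Qy)))
  if (covariances) {
    if (ncol(Z) > cap)
      stop("p exceeds the materialisation cap; use the implicit n-dimensional forms")
    QZ <- gblup_project(fit, Z)
    cov_mu <- s2b^2 * crossprod(Z, QZ)
    cov_mu <- (cov_mu + t(cov_mu)) / 2
    out$cov_mu_beta <- cov_mu
    out$cov_beta_given_y <- diag(s2b, ncol(Z)) - cov_mu
  }
  out
}

#' @export
print.gblup <- function(x, ...) {
  cat("gBLUP fit (spectral profile REML)\n")
  cat(sprintf("  n = %d samples", x$n))
  if (!is.na(x$grm$p)) cat(sprintf(", p = %d markers", x$grm$p))
  cat("\n")
  cat(sprintf("  sigma_g^2 = %.6g   sigma_e^2 = %.6g   mu = %.6g\n",
              x$vc$sigma_g2, x$vc$sigma_e2, x$vc$mu))
  if (!is.na(x$vc$sigma_b2))
    cat(sprintf("  sigma_beta^2 = sigma_g^2 / c = %.6g\n", x$vc$sigma_b2))
  cat(sprintf("  restricted log-likelihood = %.6f%s\n", x$loglik_restricted,
              if (x$boundary) "  (variance ratio at boundary, sigma_g^2 = 0)" else ""))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  h2 <- object$vc$sigma_g2 / (object$vc$sigma_g2 + object$vc$sigma_e2)
  out <- list(fit = object, h2_ratio = h2,
              var_y = stats::var(object$y))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  sigma_g^2 / (sigma_g^2 + sigma_e^2) = %.4f\n", x$h2_ratio))
  cat(sprintf("  phenotypic sample variance = %.6g\n", x$var_y))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(`(Intercept)` = object$vc$mu)

#' @export
fitted.gblup <- function(object, ...) object$vc$mu + object$mu_g

#' @export
residuals.gblup <- function(object, ...) object$y - fitted(object)

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$loglik_restricted, df = 3L, class = "logLik")
}

#' Predict genomic values
#'
#' Without `newdata`, returns the BLUP of the genomic values for the
#' training samples (plus the intercept when `type = "response"`).  With
#' `newdata` (a genotype matrix over the same markers), predicts genomic
#' values for new individuals from the marker-effect BLUPs, centring the
#' new genotypes at the training column means.
#'
#' @param object a `"gblup"` fit.
#' @param newdata optional genotype matrix (samples x markers).
#' @param type `"genomic"` (g only) or `"response"` (mu + g).
#' @param ... unused.
#' @export
predict.gblup <- function(object, newdata = NULL,
                          type = c("genomic", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    g <- object$mu_g
  } else {
    Z <- object$grm$centered
    if (is.null(Z)) stop("marker-level prediction needs centred genotypes in the fit")
    keep <- colnames(Z)
    if (!all(keep %in% colnames(newdata)))
      stop("newdata lacks markers used in the fit")
    Znew <- sweep(newdata[, keep, drop = FALSE], 2L, object$grm$col_means, `-`)
    g <- drop(Znew %*% marker_blups(object)$mu_beta)
  }
  if (type == "response") object$vc$mu + g else g
}

#' Simulate phenotype vectors from a fitted gBLUP model
#'
#' Draws `nsim` new phenotype vectors y* = mu + g* + e* with
#' g* ~ N(0, sigma_g2 G) and e* ~ N(0, sigma_e2 I) at the fitted components
#' (parametric simulation from the fitted generative model).
#'
#' @param object a `"gblup"` fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns, `n` rows.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  U <- object$eigen$U; d <- object$eigen$d
  n <- object$n
  out <- replicate(nsim, {
    g <- drop(U %*% (sqrt(object$vc$sigma_g2 * d) * stats::rnorm(n)))
    object$vc$mu + g + stats::rnorm(n, sd = sqrt(object$vc$sigma_e2))
  })
  as.data.frame(out)
}

#' Diagnostic plot of a gBLUP fit
#'
#' Left: profile restricted log-likelihood over the variance ratio; right:
#' observed phenotypes against fitted values mu + BLUP(g).
#'
#' @param x a `"gblup"` fit.
#' @param ... passed to [plot()].
#' @export
plot.gblup <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lg <- seq(log(1e-6), log(1e6), length.out = 120)
  d <- x$eigen$d; yt <- x$rotated$y; ot <- x$rotated$one; n <- x$n
  ll <- vapply(lg, function(l) {
    w <- exp(l) * d + 1
    sxx <- sum(ot^2 / w); mu <- sum(ot * yt / w) / sxx
    s2 <- sum((yt - mu * ot)^2 / w) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) + sum(log(w)) +
              log(sxx) + (n - 1))
  }, 0)
  plot(exp(lg), ll, type = "l", log = "x", xlab = expression(lambda),
       ylab = "restricted log-likelihood", main = "profile REML", ...)
  if (x$vc$lambda > 0) graphics::abline(v = x$vc$lambda, lty = 2)
  plot(fitted(x), x$y, xlab = "fitted  mu + BLUP(g)", ylab = "observed y",
       main = "fit", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
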