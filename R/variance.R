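#' Predictors of the random additive genomic variance
#'
#' In the random-effects marker model the additive genomic variance
#' \deqn{s_{g,B}^2 = \frac{1}{n-1} g' B g}
#' is itself a random variable (the marker effects are random).  Two ways of
#' resolving that randomness are computed here, for the current population
#' (B = I) and the base population (B = R^{-1/2} P R^{-1/2}, or the
#' GRM-based transform):
#' \describe{
#'   \item{V family (unconditional expectation)}{
#'     \eqn{V_B = E[s_{g,B}^2] = \hat\sigma_g^2\, tr(B G)/(n-1)};
#'     for B = I this equals \eqn{\hat\sigma_\beta^2 tr(\hat\Sigma_X)} —
#'     the GREML-style estimator, which uses only the marker variances
#'     (diagonal of \eqn{\hat\Sigma_X}) and so ignores LD.}
#'   \item{W family (best predictor)}{
#'     \eqn{W_B = E[s_{g,B}^2 | y] = tr(B[\mu_{g|y}\mu_{g|y}' +
#'     \Sigma_{g|y}])/(n-1)}, the conditional expectation given the
#'     phenotypes — the minimum-MSE predictor of the random target.  It
#'     weights every entry of \eqn{\hat\Sigma_X}, so LD enters explicitly.}
#' }
#' The difference is the LD contribution, L(y) = W - V (exact).
#'
#' Estimators:
#' `V`, `W` (current population); `Vstar`, `Wstar` (base population through
#' a supplied relationship matrix); `Vsstar` (the fitted \eqn{\hat\sigma_g^2}
#' itself — the usual "genomic variance" reported by GREML software),
#' `Wsstar` (base population through the GRM pseudo-inverse transform).
#'
#' @param fit a `"gblup"` object.
#' @param estimators character vector from
#'   `c("V","W","Vstar","Wstar","Vsstar","Wsstar")`.
#' @param R relationship matrix, required for `Vstar`/`Wstar`.
#' @param rank_tol relative eigenvalue threshold for pseudo-inverses.
#' @param cross_check when the marker panel is materialisable (p below
#'   `cap`), also evaluate the marker-parameterisation forms
#'   \eqn{tr(\hat\Sigma_X[\mu_\beta\mu_\beta' + \Sigma_{\beta|y}])} and stop
#'   if the two routes disagree beyond 1e-8 relative.
#' @param cap p x p materialisation cap for the cross-check.
#' @return object of class `"genomic_variance"`: a data.frame with columns
#'   `estimator`, `population`, `value`, `ld_component` (the matching
#'   L(y) = W - V, `NA` for V-family rows).
#' @export
genomic_variance <- function(fit,
                             estimators = c("V", "W"),
                             R = NULL, rank_tol = NULL,
                             cross_check = FALSE, cap = 20000L) {
  all_est <- c("V", "W", "Vstar", "Wstar", "Vsstar", "Wsstar")
  estimators <- match.arg(estimators, all_est, several.ok = TRUE)
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  n <- fit$n
  need_R <- any(estimators %in% c("Vstar", "Wstar"))
  if (need_R && is.null(R))
    stop("Vstar/Wstar require a relationship matrix R")

  rows <- list()
  add <- function(est, pop, val, ld = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      estimator = est, population = pop, value = val, ld_component = ld,
      stringsAsFactors = FALSE)

  Vcur <- Wcur <- NULL
  if (any(estimators %in% c("V", "W"))) {
    Vcur <- unconditional_expectation(fit)
    Wcur <- best_predictor(fit)
    if ("V" %in% estimators) add("V", "current", Vcur)
    if ("W" %in% estimators) add("W", "current", Wcur, Wcur - Vcur)
  }
  if (need_R) {
    bm <- make_b_matrix("base", R = R, rank_tol = rank_tol)
    Vb <- unconditional_expectation(fit, bm)
    Wb <- best_predictor(fit, bm)
    if ("Vstar" %in% estimators) add("Vstar", "base", Vb)
    if ("Wstar" %in% estimators) add("Wstar", "base", Wb, Wb - Vb)
  }
  if (any(estimators %in% c("Vsstar", "Wsstar"))) {
    Vs <- fit$vc$sigma_g2                      # sigma_g2 tr(P)/(n-1)
    if ("Vsstar" %in% estimators) add("Vsstar", "base", Vs)
    if ("Wsstar" %in% estimators) {
      bm <- make_b_matrix("base", grm = fit$grm, use_grm = TRUE,
                          rank_tol = rank_tol)
      Ws <- best_predictor(fit, bm)
      add("Wsstar", "base", Ws, Ws - Vs)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("genomic_variance", "data.frame")

  if (cross_check && !is.null(fit$grm$centered) &&
      ncol(fit$grm$centered) <= cap) {
    for (i in seq_len(nrow(out))) {
      est <- out$estimator[i]
      if (est == "Vsstar") next      # printed simplification, no B-form twin
      bm <- switch(est,
        V = , W = make_b_matrix("current"),
        Vstar = , Wstar = make_b_matrix("base", R = R, rank_tol = rank_tol),
        Wsstar = make_b_matrix("base", grm = fit$grm, use_grm = TRUE,
                               rank_tol = rank_tol))
      mf <- if (est %in% c("V", "Vstar"))
        v_marker_form(fit, bm) else w_marker_form(fit, bm)
      sc <- max(abs(out$value[i]), 1e-12)
      if (abs(mf - out$value[i]) > 1e-8 * sc)
        stop(sprintf("marker-form cross-check failed for %s: %.12g vs %.12g",
                     est, out$value[i], mf))
    }
  }
  out
}

#' Unconditional expectation of the genomic variance for one B-matrix
#'
#' \eqn{\hat\sigma_g^2 tr(B G)/(n-1)} in the equivalent-model form; for the
#' identity B this coincides with the marker form
#' \eqn{\hat\sigma_\beta^2 tr(\hat\Sigma_X)}.
#'
#' @param fit a `"gblup"` object.
#' @param b a `"b_matrix"` (default: identity, current population).
#' @return scalar estimate.
#' @export
unconditional_expectation <- function(fit, b = make_b_matrix("current")) {
  stopifnot(inherits(b, "b_matrix"))
  n <- fit$n
  if (b$identity)
    return(fit$vc$sigma_g2 * sum(fit$eigen$d) / (n - 1))
  fit$vc$sigma_g2 * sum(b$B * fit$grm$G) / (n - 1)
}

#' Best predictor of the genomic variance for one B-matrix
#'
#' \eqn{tr(B[\mu_{g|y}\mu_{g|y}' + \Sigma_{g|y}])/(n-1)} with
#' \eqn{\Sigma_{g|y} = \hat\sigma_g^2 G - \hat\sigma_g^4 G Q G} (REML
#' projection Q).  For the identity B everything reduces to O(n) scalar
#' work in the eigenbasis of G; for an explicit B dense n x n products are
#' used.
#'
#' @inheritParams unconditional_expectation
#' @return scalar estimate.
#' @export
best_predictor <- function(fit, b = make_b_matrix("current")) {
  stopifnot(inherits(b, "b_matrix"))
  n <- fit$n
  s2g <- fit$vc$sigma_g2
  if (b$identity) {
    trSig <- s2g * sum(fit$eigen$d) - s2g^2 * .tr_GQG(fit)
    return((sum(fit$mu_g^2) + trSig) / (n - 1))
  }
  G <- fit$grm$G
  GQG <- G %*% gblup_project(fit, G)
  trBSig <- s2g * sum(b$B * G) - s2g^2 * sum(b$B * GQG)
  (drop(crossprod(fit$mu_g, b$B %*% fit$mu_g)) + trBSig) / (n - 1)
}

# marker-parameterisation forms (the p-dimensional route), used to
# cross-check the equivalent-model forms above
#' @rdname genomic_variance
#' @param b a `"b_matrix"` selecting the population.
#' @export
v_marker_form <- function(fit, b = make_b_matrix("current")) {
  Z <- fit$grm$centered
  if (is.null(Z)) stop("marker form needs centred genotypes")
  n <- fit$n
  S <- if (b$identity) crossprod(Z) / (n - 1)
       else crossprod(Z, b$B %*% Z) / (n - 1)
  fit$vc$sigma_b2 * sum(diag(S))
}

#' @rdname genomic_variance
#' @export
w_marker_form <- function(fit, b = make_b_matrix("current")) {
  Z <- fit$grm$centered
  if (is.null(Z)) stop("marker form needs centred genotypes")
  n <- fit$n
  mb <- marker_blups(fit, covariances = TRUE)
  M <- tcrossprod(mb$mu_beta) + mb$cov_beta_given_y   # E[beta beta' | y]
  S <- if (b$identity) crossprod(Z) / (n - 1)
       else crossprod(Z, b$B %*% Z) / (n - 1)
  sum(S * M)
}

#' Contribution of linkage disequilibrium to the genomic variance
#'
#' The best predictor decomposes exactly as W_B = V_B + L(y).  The default
#' route evaluates L(y) as that difference (O(n^2), valid at any p).  The
#' explicit route evaluates the printed double sum
#' \deqn{L(y) = \sum_j M_{jj} (\hat\Sigma_X)_{jj} + \sum_{i \ne j} M_{ij}
#'   (\hat\Sigma_X)_{ij}, \quad M = \mu_{\beta|y}\mu_{\beta|y}' -
#'   Cov(\mu_{\beta|y}),}
#' optionally splitting it into the variance-weighted diagonal part and the
#' LD-weighted off-diagonal part.
#'
#' @param fit a `"gblup"` object.
#' @param population `"current"` or `"base"`.
#' @param R relationship matrix (base population with a supplied R).
#' @param use_grm use the GRM pseudo-inverse transform for the base
#'   population.
#' @param method `"difference"` (default) or `"explicit"`.
#' @param breakdown with the explicit method, also return the diagonal and
#'   off-diagonal partial sums.
#' @param cap p x p materialisation cap for the explicit method.
#' @param rank_tol pseudo-inverse threshold.
#' @return scalar L(y), or (with `breakdown`) a list with `total`,
#'   `diagonal`, `off_diagonal`.
#' @export
ld_contribution <- function(fit, population = c("current", "base"),
                            R = NULL, use_grm = FALSE,
                            method = c("difference", "explicit"),
                            breakdown = FALSE, cap = 20000L,
                            rank_tol = NULL) {
  population <- match.arg(population)
  method <- match.arg(method)
  bm <- if (population == "current") make_b_matrix("current")
        else make_b_matrix("base", R = R, grm = fit$grm, use_grm = use_grm,
                           rank_tol = rank_tol)
  if (method == "difference" && !breakdown) {
    if (population == "base" && use_grm)
      return(best_predictor(fit, bm) - fit$vc$sigma_g2)
    return(best_predictor(fit, bm) - unconditional_expectation(fit, bm))
  }
  Z <- fit$grm$centered
  if (is.null(Z)) stop("explicit LD sum needs centred genotypes")
  if (ncol(Z) > cap)
    stop("p exceeds the materialisation cap; use method = \"difference\" without breakdown")
  n <- fit$n
  mb <- marker_blups(fit, covariances = TRUE)
  M <- tcrossprod(mb$mu_beta) - mb$cov_mu_beta
  S <- if (bm$identity) crossprod(Z) / (n - 1)
       else crossprod(Z, bm$B %*% Z) / (n - 1)
  dg <- sum(diag(M) * diag(S))
  total <- sum(M * S)
  if (!breakdown) return(total)
  list(total = total, diagonal = dg, off_diagonal = total - dg)
}

#' Heritability summaries in the current population
#'
#' Two conventions: relative to the phenotypic sample variance
#' (h2 = estimate / var(y); when the phenotypes were pre-scaled to unit
#' variance the estimates read directly as heritabilities), and relative to
#' the model-implied phenotypic variance (h2~ = estimate / (estimate +
#' residual variance)).  Heritability is defined only in the current
#' population: the residual variance refers to the observed individuals, so
#' base-population inputs are rejected.
#'
#' @param fit a `"gblup"` object.
#' @param predictions optional `"genomic_variance"` table holding current-
#'   population `V` and `W` rows (computed from `fit` if omitted).
#' @return object of class `"heritability"`: list with `h2_V`, `h2_W`,
#'   `h2_tilde_V`, `h2_tilde_W`, `phenotypic_variance`.
#' @export
heritability <- function(fit, predictions = NULL) {
  if (is.null(predictions)) {
    predictions <- genomic_variance(fit, c("V", "W"))
  }
  if (any(predictions$population != "current"))
    stop("heritability is defined only in the current population (the residual variance refers to the observed individuals)")
  V <- predictions$value[predictions$estimator == "V"]
  W <- predictions$value[predictions$estimator == "W"]
  if (!length(V) || !length(W)) stop("predictions must contain V and W rows")
  s2y <- stats::var(fit$y)
  s2e <- fit$vc$sigma_e2
  structure(list(h2_V = V / s2y, h2_W = W / s2y,
                 h2_tilde_V = V / (V + s2e), h2_tilde_W = W / (W + s2e),
                 phenotypic_variance = s2y),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat("Genomic heritability (current population)\n")
  cat(sprintf("  h2_V       = V / var(y)       = %.6f\n", x$h2_V))
  cat(sprintf("  h2_W       = W / var(y)       = %.6f\n", x$h2_W))
  cat(sprintf("  h2~_V      = V / (V + s2_e)   = %.6f\n", x$h2_tilde_V))
  cat(sprintf("  h2~_W      = W / (W + s2_e)   = %.6f\n", x$h2_tilde_W))
  cat(sprintf("  var(y)     = %.6g\n", x$phenotypic_variance))
  invisible(x)
}

#' @export
print.genomic_variance <- function(x, ...) {
  cat("Predicted additive genomic variance\n")
  df <- as.data.frame(x)
  df$value <- signif(df$value, 7)
  df$ld_component <- signif(df$ld_component, 7)
  print(df, row.names = FALSE)
  invisible(x)
}
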