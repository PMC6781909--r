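#' Validate a marker genotype matrix
#'
#' Checks an n x p matrix of allele dosages coded 0/1/2 (minor-allele counts
#' or reference-allele counts; the coding direction is irrelevant downstream
#' because centering removes it).  Row names are sample IDs, column names are
#' marker IDs; both must be present and unique.
#'
#' @param X numeric matrix, samples in rows, markers in columns.
#' @param allow_missing logical; if `FALSE` any `NA` entry is an error.
#' @return `X`, invisibly, after validation.
#' @export
validate_genotypes <- function(X, allow_missing = FALSE) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("genotypes must be a numeric matrix")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("genotype matrix needs sample IDs (rownames) and marker IDs (colnames)")
  if (anyDuplicated(rownames(X)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (anyDuplicated(colnames(X)))
    stop("duplicate marker IDs: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  na <- is.na(X)
  if (any(na) && !allow_missing) {
    idx <- which(na, arr.ind = TRUE)[1, ]
    stop(sprintf("missing genotype at sample '%s', marker '%s'",
                 rownames(X)[idx[1]], colnames(X)[idx[2]]))
  }
  bad <- !na & !(X %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid allele dosage %s at sample '%s', marker '%s' (must be 0, 1 or 2)",
      format(X[idx[1], idx[2]]), rownames(X)[idx[1]], colnames(X)[idx[2]]))
  }
  invisible(X)
}

#' Mean-centre genotype columns
#'
#' Applies the centering projector P = I - 11'/n columnwise: column j of the
#' result is x_j - xbar_j, where xbar_j = 2 p_j estimates twice the allele
#' frequency of the counted allele.
#'
#' @param X numeric genotype matrix (n x p), n >= 2.
#' @return list with `centered` (n x p, columns sum to zero) and
#'   `col_means` (the per-marker means xbar_j = 2 p_j).
#' @export
center_genotypes <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2)
    stop("centering needs at least 2 samples (the projector P is degenerate for n < 2)")
  m <- colMeans(X)
  list(centered = sweep(X, 2L, m, `-`), col_means = m)
}

#' VanRaden scaling constant
#'
#' c = 2 * sum_j p_j (1 - p_j), the total binomial dosage variance under
#' Hardy-Weinberg, computed from minor-allele frequencies.  Monomorphic
#' markers (p_j = 0) contribute nothing.
#'
#' @param allele_freqs minor-allele frequencies, each in \[0, 0.5\].
#' @return the positive scalar c.
#' @export
scaling_constant <- function(allele_freqs) {
  if (any(allele_freqs < 0 | allele_freqs > 0.5 + 1e-12))
    stop("allele frequencies must be minor-allele frequencies in [0, 0.5]")
  cc <- 2 * sum(allele_freqs * (1 - allele_freqs))
  if (cc <= 0)
    stop("all markers are monomorphic: scaling constant c = 0")
  cc
}

#' Build the genomic relationship matrix
#'
#' G = P X X' P / c with the VanRaden scaling c = 2 sum p_j(1-p_j), where
#' allele frequencies are estimated from the sample (p_hat = column mean / 2)
#' and folded to the minor allele.  Monomorphic markers are dropped with a
#' warning; their IDs are recorded.
#'
#' @param X validated genotype matrix (n x p dosages in 0/1/2).
#' @param drop_monomorphic drop zero-variance columns (default `TRUE`).
#' @return an object of class `"grm"`: list with `G` (n x n), `centered`
#'   (n x p_kept matrix PX), `c` (scaling constant), `allele_freqs` (folded,
#'   kept markers), `col_means`, `dropped_markers`, `n`, `p`.
#' @export
build_grm <- function(X, drop_monomorphic = TRUE) {
  validate_genotypes(X)
  cen <- center_genotypes(X)
  m <- cen$col_means
  p_hat <- pmin(m / 2, 1 - m / 2)           # fold to minor allele
  mono <- p_hat <= 0 | apply(cen$centered, 2L, function(z) all(z == 0))
  dropped <- colnames(X)[mono]
  if (any(mono)) {
    if (all(mono)) stop("all markers are monomorphic: scaling constant c = 0")
    warning(sprintf("dropping %d monomorphic marker(s)", sum(mono)))
  }
  Z <- cen$centered[, !mono, drop = FALSE]
  pf <- p_hat[!mono]
  cc <- scaling_constant(pf)
  G <- tcrossprod(Z) / cc
  G <- (G + t(G)) / 2                       # enforce exact symmetry
  dimnames(G) <- list(rownames(X), rownames(X))
  structure(list(G = G, centered = Z, c = cc, allele_freqs = pf,
                 col_means = m[!mono], dropped_markers = dropped,
                 n = nrow(X), p = ncol(Z)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d samples, %d markers (c = %.6g)\n",
              x$n, x$p, x$c))
  if (length(x$dropped_markers))
    cat(sprintf("  %d monomorphic marker(s) dropped\n", length(x$dropped_markers)))
  invisible(x)
}

#' Sample variance-covariance matrix of the marker genotypes
#'
#' SigmaHat_X = X'PX/(n-1) = Z'Z/(n-1) for centred genotypes Z = PX.  For
#' large marker panels the p x p matrix is never materialised: the object
#' keeps Z and evaluates traces and quadratic forms in the n-dimensional
#' representation (beta' SigmaHat_X beta = ||Z beta||^2/(n-1)).
#'
#' @param Z centred genotype matrix (columns mean zero), n x p.
#' @param population `"current"` or `"base"` provenance tag.
#' @param cap materialise the explicit p x p matrix only when p <= cap.
#' @return object of class `"marker_cov"`, with `$matrix` either the dense
#'   p x p matrix or `NULL` (implicit representation).
#' @export
marker_covariance <- function(Z, population = c("current", "base"),
                              cap = 20000L) {
  population <- match.arg(population)
  n <- nrow(Z); p <- ncol(Z)
  mat <- if (p <= cap) crossprod(Z) / (n - 1) else NULL
  structure(list(matrix = mat, Z = Z, n = n, p = p,
                 population = population, materialized = !is.null(mat)),
            class = "marker_cov")
}

#' Trace of a marker covariance (sum of per-marker sample variances)
#' @param mc a `"marker_cov"` object.
#' @return scalar trace of SigmaHat_X.
#' @export
mc_trace <- function(mc) {
  if (mc$materialized) sum(diag(mc$matrix))
  else sum(mc$Z^2) / (mc$n - 1)
}

#' Quadratic form beta' SigmaHat_X beta
#'
#' Evaluated implicitly as ||Z beta||^2/(n-1); exact by the algebraic
#' identity, independent of whether the p x p matrix was materialised.
#'
#' @param mc a `"marker_cov"` object.
#' @param beta p-vector of marker effects.
#' @return scalar value of the quadratic form.
#' @export
mc_quad <- function(mc, beta) {
  sum((mc$Z %*% beta)^2) / (mc$n - 1)
}
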