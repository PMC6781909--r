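#' Simulate marker genotypes
#'
#' Two data-generating processes for 0/1/2 allele dosages:
#' \describe{
#'   \item{`independent`}{each marker an independent Binomial(2, p_j) draw,
#'     p_j uniform over `maf_range` (Hardy-Weinberg, linkage equilibrium).}
#'   \item{`ar1_haplotype`}{two haplotypes per individual, each a
#'     first-order Markov chain of 0/1 alleles along the markers whose
#'     stationary marginal at marker j is p_j and whose adjacent-locus
#'     correlation is `rho`; dosage = sum of the haplotypes.  Because the
#'     haplotypes are independent, the adjacent-marker genotype correlation
#'     is also `rho` — the analytic target the generator is tested
#'     against.  Transition probabilities are
#'     P(1|1) = p_{j+1} + rho sqrt(q_j p_{j+1} q_{j+1} / p_j) and
#'     P(1|0) = p_{j+1} - rho sqrt(p_j p_{j+1} q_{j+1} / q_j), clipped to
#'     \[0, 1\] (clipping is inactive when successive MAFs are similar, as
#'     under the default narrow `maf_range`).}
#' }
#'
#' @param n number of individuals (>= 2).
#' @param p number of markers (>= 1).
#' @param maf_range minor-allele-frequency interval, inside (0, 0.5\].
#' @param ld_model `"independent"` or `"ar1_haplotype"`.
#' @param rho adjacent-marker correlation of the haplotype chain, in
#'   \[0, 1).
#' @param seed integer seed; identical arguments reproduce the matrix
#'   bit-exactly.
#' @return genotype matrix with sample IDs `s1..sn`, marker IDs `m1..mp`.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.1, 0.5),
                               ld_model = c("independent", "ar1_haplotype"),
                               rho = 0, seed = 1L) {
  ld_model <- match.arg(ld_model)
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie inside (0, 0.5]")
  set.seed(seed)
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  if (ld_model == "independent" || rho == 0) {
    X <- sapply(maf, function(pj) stats::rbinom(n, 2L, pj))
    X <- matrix(as.double(X), n, p)
  } else {
    q <- 1 - maf
    hap <- function() {
      H <- matrix(0L, n, p)
      H[, 1] <- stats::rbinom(n, 1L, maf[1])
      for (j in seq_len(p - 1L)) {
        r <- sqrt(maf[j] * q[j] * maf[j + 1] * q[j + 1])
        p11 <- min(1, max(0, maf[j + 1] + rho * r / maf[j]))
        p01 <- min(1, max(0, maf[j + 1] - rho * r / q[j]))
        pr <- ifelse(H[, j] == 1L, p11, p01)
        H[, j + 1] <- stats::rbinom(n, 1L, pr)
      }
      H
    }
    X <- hap() + hap()
    storage.mode(X) <- "double"
  }
  dimnames(X) <- list(paste0("s", seq_len(n)), paste0("m", seq_len(p)))
  X
}

#' Simulate phenotypes under the random-effects marker model
#'
#' Draws marker effects beta_j ~ N(0, sigma_b2) and residuals
#' e ~ N(0, sigma_e2 I), and forms y = mu 1 + P X beta + e with the centred
#' genotypes.  The realised value of the random additive genomic variance,
#' s_g^2 = beta' SigmaHat_X beta = ||PX beta||^2/(n-1), is stored — it is
#' the target quantity the V/W predictors are judged against.  If a
#' relationship matrix is attached, the realised base-population variance
#' s_g*^2 = (g*)' P g* / (n-1) with g* = R^{-1/2} g is stored as well.
#'
#' @param X genotype matrix (dosages 0/1/2).
#' @param sigma_b2 marker-effect variance (>= 0).
#' @param sigma_e2 residual variance (> 0).
#' @param mu intercept (default 0).
#' @param seed integer seed.
#' @param R optional relationship matrix for the base-population target.
#' @return object of class `"synthetic_dataset"`: list with `genotypes`,
#'   `phenotypes` (named vector), `true_beta`, `true_sigma_b2`,
#'   `true_sigma_e2`, `mu`, `realized_sg2`, optionally `realized_sg2_star`
#'   and `relationship`, and the generation provenance (`seed`).
#' @export
simulate_phenotypes <- function(X, sigma_b2, sigma_e2, mu = 0, seed = 1L,
                                R = NULL) {
  if (sigma_b2 < 0 || sigma_e2 <= 0)
    stop("need sigma_b2 >= 0 and sigma_e2 > 0")
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  beta <- stats::rnorm(p, 0, sqrt(sigma_b2))
  names(beta) <- colnames(X)
  eps <- stats::rnorm(n, 0, sqrt(sigma_e2))
  Z <- center_genotypes(X)$centered
  g <- drop(Z %*% beta)
  y <- mu + g + eps
  names(y) <- rownames(X)
  out <- list(genotypes = X, phenotypes = y, true_beta = beta,
              true_sigma_b2 = sigma_b2, true_sigma_e2 = sigma_e2, mu = mu,
              realized_sg2 = sum(g^2) / (n - 1), seed = seed)
  if (!is.null(R)) {
    gs <- drop(matrix_inv_sqrt(R) %*% g)
    out$realized_sg2_star <- sum((gs - mean(gs))^2) / (n - 1)
    out$relationship <- R
  }
  structure(out, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: n = %d, p = %d (seed %d)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$seed))
  cat(sprintf("  sigma_b2 = %.4g, sigma_e2 = %.4g, realised s_g^2 = %.4g\n",
              x$true_sigma_b2, x$true_sigma_e2, x$realized_sg2))
  invisible(x)
}

#' Construct a relationship matrix
#'
#' `identity` gives unrelated individuals; `block_family` gives
#' block-diagonal compound-symmetry families (1 on the diagonal,
#' `relatedness` off-diagonal within a family), which is PSD whenever
#' `relatedness` is in \[-1/(k-1), 1\] for family size k.
#'
#' @param kind `"identity"` or `"block_family"`.
#' @param n number of individuals.
#' @param family_size family block size (must divide n).
#' @param relatedness within-family off-diagonal value.
#' @param ids optional sample IDs (default `s1..sn`).
#' @return symmetric PSD matrix with sample dimnames.
#' @export
make_relationship <- function(kind = c("identity", "block_family"), n,
                              family_size = 2L, relatedness = 0.5,
                              ids = paste0("s", seq_len(n))) {
  kind <- match.arg(kind)
  if (kind == "identity") {
    R <- diag(n)
  } else {
    if (n %% family_size != 0) stop("family_size must divide n")
    if (relatedness > 1 || relatedness < -1 / (family_size - 1))
      stop("relatedness outside the PSD range for this family size")
    blk <- matrix(relatedness, family_size, family_size)
    diag(blk) <- 1
    R <- kronecker(diag(n %/% family_size), blk)
  }
  dimnames(R) <- list(ids, ids)
  R
}

#' Write a synthetic dataset as the delimited fixtures the readers consume
#'
#' @param ds a `"synthetic_dataset"`.
#' @param dir output directory (created if absent).
#' @return named list of the file paths written.
#' @export
write_synthetic <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  X <- ds$genotypes
  utils::write.table(data.frame(sample_id = rownames(X), X,
                                check.names = FALSE),
                     gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ppath <- file.path(dir, "phenotypes.tsv")
  utils::write.table(data.frame(sample_id = names(ds$phenotypes),
                                value = unname(ds$phenotypes)),
                     ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(genotypes = gpath, phenotypes = ppath)
  if (!is.null(ds$relationship)) {
    rpath <- file.path(dir, "relationship.tsv")
    R <- ds$relationship
    utils::write.table(data.frame(sample_id = rownames(R), R,
                                  check.names = FALSE),
                       rpath, sep = "\t", quote = FALSE, row.names = FALSE)
    out$relationship <- rpath
  }
  out
}
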