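#' Pseudo-inverse square root of a relationship matrix
#'
#' Computes R^{-1/2} from the eigendecomposition R = U L U'; eigenvalues
#' below `rank_tol` times the largest are treated as exactly zero and
#' inverted to zero (Moore-Penrose).  For a full-rank R the result satisfies
#' R^{-1/2} R R^{-1/2} = I; for a singular R the product is the orthogonal
#' projector onto range(R).
#'
#' @param R symmetric positive-semidefinite matrix.
#' @param rank_tol relative eigenvalue threshold; default
#'   `nrow(R) * .Machine$double.eps`.
#' @return symmetric matrix with attribute `"rank"` (the numerical rank
#'   used).
#' @export
matrix_inv_sqrt <- function(R, rank_tol = NULL) {
  n <- nrow(R)
  if (is.null(rank_tol)) rank_tol <- n * .Machine$double.eps
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lmax <- max(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(lmax, 1e-300))
    stop("matrix has a negative eigenvalue beyond tolerance; not PSD")
  keep <- eg$values > rank_tol * lmax
  inv <- ifelse(keep, 1 / sqrt(pmax(eg$values, 0)), 0)
  out <- eg$vectors %*% (inv * t(eg$vectors))
  out <- (out + t(out)) / 2
  attr(out, "rank") <- sum(keep)
  out
}

#' Quadratic-form matrix selecting the target population
#'
#' The random additive genomic variance in its general form is the quadratic
#' form s_{g,B}^2 = g' B g / (n-1).  B = I selects the current population
#' (ordinary sample variance of the genomic values); B = R^{-1/2} P R^{-1/2}
#' selects the base population reached by decorrelating the genomic values
#' with a relationship matrix R.  When no pedigree/external R is available
#' the GRM itself can stand in for R; since G 1 = 0 and P acts as the
#' identity on range(G), the GRM transform collapses to the Moore-Penrose
#' pseudo-inverse, B = G^+.
#'
#' @param population `"current"` or `"base"`.
#' @param R relationship matrix (required for the base population unless
#'   `use_grm`).
#' @param grm a `"grm"` object (required when `use_grm = TRUE`).
#' @param use_grm use the GRM transform for the base population.
#' @param rank_tol passed to [matrix_inv_sqrt()].
#' @return object of class `"b_matrix"`: list with `B` (matrix, or `NULL`
#'   for the identity tag), `population`, `identity`, `transform_source`.
#' @export
make_b_matrix <- function(population = c("current", "base"), R = NULL,
                          grm = NULL, use_grm = FALSE, rank_tol = NULL) {
  population <- match.arg(population)
  if (population == "current") {
    return(structure(list(B = NULL, population = "current", identity = TRUE,
                          transform_source = "none"), class = "b_matrix"))
  }
  if (use_grm) {
    if (is.null(grm)) stop("use_grm = TRUE needs a grm object")
    G <- grm$G
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    n <- nrow(G)
    if (is.null(rank_tol)) rank_tol <- n * .Machine$double.eps
    keep <- eg$values > rank_tol * max(eg$values, 0)
    inv <- ifelse(keep, 1 / pmax(eg$values, .Machine$double.xmin), 0)
    B <- eg$vectors %*% (inv * t(eg$vectors))      # G^+ (pseudo-inverse)
    B <- (B + t(B)) / 2
    src <- "grm"
  } else {
    if (is.null(R))
      stop("base population requires a relationship matrix R or use_grm = TRUE")
    Rh <- matrix_inv_sqrt(R, rank_tol)
    n <- nrow(R)
    P <- diag(n) - matrix(1 / n, n, n)
    B <- Rh %*% P %*% Rh
    B <- (B + t(B)) / 2
    src <- "supplied_R"
  }
  structure(list(B = B, population = "base", identity = FALSE,
                 transform_source = src), class = "b_matrix")
}

#' @export
print.b_matrix <- function(x, ...) {
  cat(sprintf("B-matrix: population = %s, transform = %s%s\n",
              x$population, x$transform_source,
              if (x$identity) " (identity tag)" else
                sprintf(" (%d x %d)", nrow(x$B), ncol(x$B))))
  invisible(x)
}
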