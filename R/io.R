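#' Read a marker genotype matrix
#'
#' Supported layouts:
#' \describe{
#'   \item{`tsv` / `csv`}{samples x markers; first row marker IDs, first
#'     column sample IDs.}
#'   \item{`plink_raw`}{whitespace-delimited PLINK `--recode A` export with
#'     the six leading metadata columns `FID IID PAT MAT SEX PHENOTYPE`;
#'     the counted-allele suffix (e.g. `_A` in `m1_A`) is stripped from
#'     marker IDs and `IID` becomes the sample ID.}
#' }
#' Dosages must be 0, 1 or 2.  Missing entries (`NA`) are an error unless
#' `missing` says otherwise; `"impute"` replaces them by the column mean of
#' the observed dosages, which leaves the centred column sum at zero.
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"plink_raw"`.
#' @param missing `"error"` (default), `"impute"` or `"keep"`.
#' @return numeric genotype matrix with sample/marker dimnames.
#' @export
read_genotypes <- function(path, format = c("tsv", "csv", "plink_raw"),
                           missing = c("error", "impute", "keep")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)[1:6]))
      stop("not a PLINK .raw file: expected leading columns ",
           paste(meta, collapse = " "))
    ids <- as.character(df$IID)
    X <- as.matrix(df[, -(1:6), drop = FALSE])
    colnames(X) <- sub("_[^_]+$", "", colnames(X))   # strip allele suffix
    rownames(X) <- ids
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    X <- as.matrix(df)
    if (!is.numeric(X)) stop("non-numeric genotype entries in ", path)
  }
  storage.mode(X) <- "double"
  validate_genotypes(X, allow_missing = missing != "error")
  if (anyNA(X) && missing == "impute") {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- mean(X[!na, j])
    }
  }
  X
}

#' Read a phenotype vector
#'
#' Two-column delimited file: sample ID, trait value.  A header line is
#' detected (and skipped) when the second field of the first line is not
#' numeric.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return named numeric vector of phenotypes.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype file needs two columns (id, value)")
  y <- as.numeric(df[[2]])
  if (anyNA(y)) stop("non-numeric phenotype value in ", path)
  names(y) <- as.character(df[[1]])
  if (anyDuplicated(names(y))) stop("duplicate sample IDs in phenotype file")
  y
}

#' Read a relationship matrix
#'
#' Square delimited matrix with sample IDs as header row and first column.
#' The matrix must be symmetric (relative tolerance 1e-10), free of missing
#' values, and positive semidefinite up to numerical noise (smallest
#' eigenvalue >= -1e-8 times the largest).
#'
#' @param path file path.
#' @param source `"pedigree"` or `"genomic"` provenance tag.
#' @param sep field separator (default tab).
#' @return numeric matrix with a `"source"` attribute.
#' @export
read_relationship <- function(path, source = c("pedigree", "genomic"),
                              sep = "\t") {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  R <- as.matrix(df)
  if (nrow(R) != ncol(R)) stop("relationship matrix is not square")
  if (anyNA(R)) stop("missing value in relationship matrix")
  validate_relationship(R)
  attr(R, "source") <- source
  R
}

#' @rdname read_relationship
#' @param R numeric square matrix to validate in place.
#' @export
validate_relationship <- function(R) {
  sc <- max(abs(R), 1e-300)
  if (max(abs(R - t(R))) > 1e-10 * sc)
    stop("relationship matrix is not symmetric (beyond 1e-10 relative tolerance)")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev, 0))
    stop("relationship matrix is not positive semidefinite")
  invisible(R)
}

#' Align genotypes, phenotypes and an optional relationship matrix by sample ID
#'
#' Restricts all inputs to the common set of sample IDs, in the genotype
#' matrix's order.  Samples present in one input but not another are dropped
#' with a warning.  Ordering of the inputs is irrelevant: all downstream
#' quantities depend only on the aligned set.
#'
#' @param X genotype matrix with sample rownames.
#' @param y named phenotype vector.
#' @param R optional relationship matrix with sample dimnames.
#' @return list with aligned `X`, `y` and (if given) `R`.
#' @export
align_samples <- function(X, y, R = NULL) {
  ids <- intersect(rownames(X), names(y))
  if (!is.null(R)) ids <- intersect(ids, rownames(R))
  if (length(ids) < 2) stop("fewer than 2 samples shared across inputs")
  dropped <- setdiff(union(rownames(X), names(y)), ids)
  if (length(dropped))
    warning(sprintf("dropping %d sample(s) absent from some input: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  ids <- rownames(X)[rownames(X) %in% ids]      # keep genotype order
  out <- list(X = X[ids, , drop = FALSE], y = y[ids])
  if (!is.null(R)) out$R <- R[ids, ids]
  out
}

#' Write an analysis report
#'
#' Serialises a set of genomic-variance predictions together with the fitted
#' variance components, convergence diagnostics and a provenance block.  JSON
#' keeps full double precision (round-trips bit-exactly); TSV is a flat table
#' with one row per estimator.
#'
#' @param predictions a `"genomic_variance"` table (see [genomic_variance()]).
#' @param fit the `"gblup"` fit the predictions came from.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @param provenance optional named list (seed, config, ...) copied verbatim.
#' @return `path`, invisibly.
#' @export
write_report <- function(predictions, fit, path, format = c("json", "tsv"),
                         provenance = list()) {
  format <- match.arg(format)
  if (!isTRUE(fit$converged)) stop("refusing to report an unconverged fit")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (format == "tsv") {
    utils::write.table(as.data.frame(predictions), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  rep <- list(
    predictions = lapply(seq_len(nrow(predictions)), function(i) {
      r <- predictions[i, ]
      list(estimator = r$estimator, population = r$population,
           value = r$value, ld_component = r$ld_component)
    }),
    variance_components = list(sigma_g2 = fit$vc$sigma_g2,
                               sigma_e2 = fit$vc$sigma_e2,
                               sigma_b2 = fit$vc$sigma_b2,
                               mu = fit$vc$mu),
    convergence = list(converged = fit$converged, boundary = fit$boundary,
                       n_iter = fit$n_iter,
                       loglik_restricted = fit$loglik_restricted),
    provenance = provenance)
  # 17 significant digits: decimal round-trips bit-exactly to double
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#' @param path report path.
#' @return the deserialised list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
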