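#' Marker quality control: missingness and minor allele frequency filter
#'
#' Removes markers with a missing-call fraction above `max_missing` or a
#' minor allele frequency below `min_maf`. Both comparisons are strict on the
#' removal side, so a marker at exactly 50% missing or exactly MAF 0.03 is
#' retained under the defaults. MAF is computed on non-missing dosages only,
#' as `min(f, 1 - f)` with `f = mean(dosage) / 2`. Marker order is preserved.
#'
#' @param m Dosage matrix (genotypes x markers), values in \{0, 1, 2\} or `NA`.
#' @param max_missing Maximum tolerated missing fraction (default 0.5).
#' @param min_maf Minimum tolerated minor allele frequency (default 0.03).
#' @return The filtered dosage matrix.
#' @export
filter_markers <- function(m, max_missing = 0.5, min_maf = 0.03) {
  validate_markers(m)
  miss <- colMeans(is.na(m))
  f <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- miss <= max_missing & !is.na(maf) & maf >= min_maf
  if (!any(keep)) {
    stop("empty panel: no marker passed the missingness/MAF filter", call. = FALSE)
  }
  m[, keep, drop = FALSE]
}

#' Impute missing marker calls by the column mean
#'
#' Each missing dosage is replaced by the mean of the marker's non-missing
#' dosages (real values allowed after imputation, which preserves the allele
#' frequency). Non-missing cells are untouched.
#'
#' @param m Dosage matrix with at least one non-missing call per marker.
#' @return Numeric matrix without missing values.
#' @export
impute_markers <- function(m) {
  validate_markers(m)
  full <- colSums(!is.na(m))
  if (any(full == 0)) {
    stop("fully missing marker column(s): run filter_markers() first", call. = FALSE)
  }
  if (!anyNA(m)) return(m)
  mu <- colMeans(m, na.rm = TRUE)
  out <- m
  storage.mode(out) <- "double"
  idx <- which(is.na(out), arr.ind = TRUE)
  out[idx] <- mu[idx[, 2]]
  out
}

#' Center and scale a marker matrix by columns
#'
#' Subtracts each column mean and divides by the column sample standard
#' deviation (denominator n - 1). This scaling makes the genomic relationship
#' matrix satisfy trace(G) = n - 1.
#'
#' @param m Complete dosage matrix; every column must be polymorphic.
#' @return Numeric matrix with column means 0 and sample variances 1.
#' @export
center_scale <- function(m) {
  if (anyNA(m)) stop("center_scale requires a complete matrix: impute first", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0] %||% which(sds == 0)
    stop("monomorphic marker column(s) with zero variance: ",
         paste(utils::head(bad, 5), collapse = ", "),
         " - filter before scaling", call. = FALSE)
  }
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Genomic relationship matrix G = XX'/p
#'
#' @param x Centered-and-scaled marker matrix from [center_scale()].
#' @return Symmetric positive semidefinite matrix labeled by genotype ids,
#'   with `attr(, "kind") == "genomic"` and trace n - 1.
#' @export
genomic_relationship <- function(x) {
  if (anyNA(x)) stop("scaled marker matrix must be complete", call. = FALSE)
  G <- tcrossprod(x) / ncol(x)
  attr(G, "kind") <- "genomic"
  attr(G, "n_markers_used") <- ncol(x)
  G
}

#' Marker pipeline: filter, impute, scale, relate
#'
#' Deterministic composition of [filter_markers()], [impute_markers()],
#' [center_scale()] and [genomic_relationship()].
#'
#' @inheritParams filter_markers
#' @return The genomic kinship matrix.
#' @export
genomic_kinship <- function(m, max_missing = 0.5, min_maf = 0.03) {
  x <- filter_markers(m, max_missing = max_missing, min_maf = min_maf)
  x <- impute_markers(x)
  # mean imputation can leave a column constant even when its MAF passed
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0) stop("empty panel: no polymorphic marker left", call. = FALSE)
  genomic_relationship(center_scale(x))
}

validate_markers <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0) {
    stop("marker matrix must be a non-empty genotypes x markers matrix", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate genotype ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate marker ids", call. = FALSE)
  v <- m[!is.na(m)]
  if (length(v) && !all(v %in% c(0, 1, 2))) {
    stop("marker dosages must be 0, 1 or 2 (or missing)", call. = FALSE)
  }
  invisible(m)
}
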