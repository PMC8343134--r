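#' Read and write the package's plain-text interchange formats
#'
#' Marker tables are CSV with genotypes in rows (first column `genotype`),
#' markers in columns, missing dosages as empty cells. Phenotypes are long
#' CSV `genotype,environment,yield`. Daily covariates are long CSV
#' `environment,day,variable,value`. Kinships are square CSV with an id
#' header row and column.
#'
#' @param m,pheno,ec,K Objects to write.
#' @param path File path.
#' @return Readers return the package's native containers; writers return
#'   the path invisibly.
#' @name envgblup-io
NULL

#' @rdname envgblup-io
#' @export
write_marker_csv <- function(m, path) {
  df <- data.frame(genotype = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname envgblup-io
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  validate_markers(m)
  m
}

#' @rdname envgblup-io
#' @export
write_pheno_csv <- function(pheno, path) {
  utils::write.csv(pheno[, c("genotype", "environment", "yield")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname envgblup-io
#' @export
read_pheno_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname envgblup-io
#' @export
write_ec_csv <- function(ec, path) {
  utils::write.csv(ec[, c("environment", "day", "variable", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname envgblup-io
#' @export
read_ec_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname envgblup-io
#' @export
write_kinship_csv <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname envgblup-io
#' @export
read_kinship_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  check_symmetric(K, tol = 1e-8, label = "kinship")
  K
}

#' Read diploid VCF genotypes as a dosage matrix
#'
#' Maps `GT` calls to alternate-allele dosages (0/0 -> 0, 0/1 or 1/0 -> 1,
#' 1/1 -> 2, `./.` -> missing). Requires the suggested `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Genotypes x markers dosage matrix.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- matrix(map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  m <- t(dos)  # genotypes in rows
  validate_markers(m)
  m
}
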