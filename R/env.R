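#' Impute single-day gaps in daily weather series
#'
#' Each missing day in an (environment, variable) series is replaced by the
#' mean of the previous and the following day's values within the same
#' environment. A missing first or last day takes its single available
#' neighbor. Two consecutive missing days are not supported and raise an
#' error, as does a fully missing series.
#'
#' @param ec Long EC table `(environment, day, variable, value)`.
#' @return The table with gaps filled, original row order preserved.
#' @export
impute_daily_gaps <- function(ec) {
  stopifnot(all(c("environment", "day", "variable", "value") %in% names(ec)))
  grp <- interaction(ec$environment, ec$variable, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(ec$day[idx])]
    v <- ec$value[idx]
    if (length(v) < 3) stop("series shorter than 3 days: ", g, call. = FALSE)
    na <- which(is.na(v))
    if (length(na) == 0) next
    if (length(na) == length(v)) stop("fully missing series: ", g, call. = FALSE)
    if (any(diff(na) == 1)) {
      stop("unsupported pattern: consecutive missing days in series ", g, call. = FALSE)
    }
    for (i in na) {
      v[i] <- if (i == 1) v[2] else if (i == length(v)) v[length(v) - 1]
              else mean(c(v[i - 1], v[i + 1]))
    }
    ec$value[idx] <- v
  }
  ec
}

#' Reshape a long EC table to the environment x covariate grid
#'
#' Columns are ordered variable-major then day (`tmin_tenthsC_d001`, ...),
#' giving q = n_variables x n_days covariates per environment.
#'
#' @param ec Long EC table.
#' @return Numeric matrix, environments in rows.
#' @export
ec_wide <- function(ec) {
  stopifnot(all(c("environment", "day", "variable", "value") %in% names(ec)))
  envs <- unique(ec$environment)
  vars <- unique(ec$variable)
  days <- sort(unique(ec$day))
  if (!identical(as.integer(days), seq_along(days))) {
    stop("day indices must be contiguous from 1", call. = FALSE)
  }
  W <- matrix(NA_real_, length(envs), length(vars) * length(days),
              dimnames = list(envs, paste0(rep(vars, each = length(days)), "_d",
                                           sprintf("%03d", rep(days, length(vars))))))
  col <- match(paste0(ec$variable, "_d", sprintf("%03d", ec$day)), colnames(W))
  row <- match(ec$environment, envs)
  W[cbind(row, col)] <- ec$value
  W
}

# Column-standardized EC grid; zero-variance columns dropped (count messaged).
standardize_ec <- function(ec) {
  W <- if (is.matrix(ec)) ec else ec_wide(ec)
  if (anyNA(W)) stop("EC grid has missing values: run impute_daily_gaps() first", call. = FALSE)
  if (nrow(W) < 2) stop("need at least 2 environments", call. = FALSE)
  sds <- apply(W, 2, stats::sd)
  drop <- sds == 0
  if (any(drop)) {
    message("Dropping ", sum(drop), " zero-variance EC column(s); q reduced to ",
            sum(!drop))
    W <- W[, !drop, drop = FALSE]
    sds <- sds[!drop]
    if (ncol(W) == 0) stop("all EC columns are constant across environments", call. = FALSE)
  }
  out <- scale(W, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Environmental kinship matrix Omega = WW'/q
#'
#' W is the column-standardized environment x covariate grid (sample s.d.,
#' denominator m - 1), so trace(Omega) = m - 1 for m environments. Constant
#' covariate columns are dropped before standardization with q reduced
#' accordingly.
#'
#' @param ec Long EC table or a pre-built wide grid.
#' @return Symmetric PSD m x m matrix with `attr(, "kind") == "environmental"`.
#' @export
env_kinship <- function(ec) {
  W <- standardize_ec(ec)
  Om <- tcrossprod(W) / ncol(W)
  attr(Om, "kind") <- "environmental"
  attr(Om, "q") <- ncol(W)
  Om
}

#' Principal component analysis of the environmental covariates
#'
#' PCA of the same column-standardized environment x covariate grid that
#' defines the Omega kernel, so the full score cross-product divided by q
#' reconstructs Omega. The sign of each component is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param ec Long EC table or wide grid.
#' @return List: `scores` (environments x 2), `pct_var` (percent variance per
#'   component, sums to 100), `all_scores`, `rotation`.
#' @export
ec_pca <- function(ec) {
  W <- standardize_ec(ec)
  pr <- stats::prcomp(W, center = FALSE, scale. = FALSE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  pct <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  names(pct) <- colnames(pr$x)
  list(scores = pr$x[, 1:2, drop = FALSE], pct_var = pct,
       all_scores = pr$x, rotation = pr$rotation)
}

#' Distance of each environment from the EC centroid
#'
#' Euclidean distance of each environment's standardized covariate vector
#' from the across-environment centroid (the origin after centering); a
#' simple outlier score used to cross-check divergent environments.
#'
#' @param ec Long EC table or wide grid.
#' @return Named numeric vector of distances.
#' @export
ec_centroid_distance <- function(ec) {
  W <- standardize_ec(ec)
  sqrt(rowSums(W^2))
}

# genotype x environment yield grid; errors if the grid is incomplete
pheno_wide <- function(pheno) {
  stopifnot(all(c("genotype", "environment", "yield") %in% names(pheno)))
  g <- sort(unique(pheno$genotype))
  e <- unique(pheno$environment)
  Y <- matrix(NA_real_, length(g), length(e), dimnames = list(g, e))
  idx <- cbind(match(pheno$genotype, g), match(pheno$environment, e))
  if (anyDuplicated(idx)) stop("duplicate (genotype, environment) records", call. = FALSE)
  Y[idx] <- pheno$yield
  if (anyNA(Y)) stop("incomplete grid: every genotype must be observed in every environment",
                     call. = FALSE)
  Y
}

#' Mean phenotypic correlation of each environment with the others
#'
#' For each environment, the mean Pearson correlation between its yield
#' vector and the yield vectors of all remaining environments, aligned on
#' genotypes (complete-grid data required).
#'
#' @param pheno Long phenotype table `(genotype, environment, yield)`.
#' @return Named numeric vector (one entry per environment, values in
#'   `[-1, 1]`).
#' @export
mean_phenotypic_correlation <- function(pheno) {
  Y <- pheno_wide(pheno)
  if (nrow(Y) < 3) stop("need at least 3 genotypes", call. = FALSE)
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant yield in environment ", colnames(Y)[which(sds == 0)[1]],
         ": correlation undefined", call. = FALSE)
  }
  C <- stats::cor(Y)
  diag(C) <- NA
  colMeans(C, na.rm = TRUE)
}

#' Identify the most and least extreme environments
#'
#' The most extreme environment has the lowest mean phenotypic correlation
#' with the remaining environments; the least extreme has the highest. Ties
#' are broken by label sort order with a warning.
#'
#' @param mean_corr Named vector from [mean_phenotypic_correlation()].
#' @return List with `most_extreme` and `least_extreme` labels.
#' @export
select_extreme_envs <- function(mean_corr) {
  stopifnot(!is.null(names(mean_corr)), length(mean_corr) >= 2)
  o_lo <- order(mean_corr, names(mean_corr))
  o_hi <- order(-mean_corr, names(mean_corr))
  if (sum(mean_corr == min(mean_corr)) > 1 || sum(mean_corr == max(mean_corr)) > 1) {
    warning("tied mean correlations: breaking ties by label order", call. = FALSE)
  }
  list(most_extreme = names(mean_corr)[o_lo[1]],
       least_extreme = names(mean_corr)[o_hi[1]])
}

#' Environment similarity report
#'
#' Combines the phenotype-based similarity (mean cross-environment Pearson
#' correlation of yield) with the EC-based one (PCA of the standardized
#' covariate grid) into one report; the extreme-environment designation uses
#' the phenotypic criterion.
#'
#' @param pheno Long phenotype table on a complete grid.
#' @param ec Long EC table (complete; impute gaps first).
#' @return Object of class `env_similarity_report`: `mean_corr`, `pc_scores`,
#'   `pct_var` (PC1 and PC2), `most_extreme`, `least_extreme`.
#' @export
env_similarity_report <- function(pheno, ec) {
  mc <- mean_phenotypic_correlation(pheno)
  pca <- ec_pca(ec)
  ext <- select_extreme_envs(mc)
  structure(list(mean_corr = mc, pc_scores = pca$scores,
                 pct_var = pca$pct_var[1:2],
                 most_extreme = ext$most_extreme,
                 least_extreme = ext$least_extreme),
            class = "env_similarity_report")
}

#' @export
print.env_similarity_report <- function(x, ...) {
  cat("Environment similarity report\n")
  cat("  most extreme (lowest mean r): ", x$most_extreme,
      sprintf(" (%.3f)\n", x$mean_corr[x$most_extreme]))
  cat("  least extreme (highest mean r):", x$least_extreme,
      sprintf(" (%.3f)\n", x$mean_corr[x$least_extreme]))
  cat(sprintf("  EC PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$pct_var[1], x$pct_var[2]))
  invisible(x)
}

#' Resample genotypes until phenotypic and EC extremes agree
#'
#' Draws random subsets of `n` genotypes and recomputes the mean phenotypic
#' correlations until the phenotype-based (most, least) extreme environments
#' match the covariate-based ranking supplied in `ec_ranking`.
#'
#' @param pheno Long phenotype table on a complete grid.
#' @param ec_ranking List with `most_extreme` and `least_extreme` labels
#'   (e.g. from EC-space distances).
#' @param n Subset size (the study design uses 500).
#' @param max_attempts Give up after this many draws.
#' @param seed RNG seed.
#' @return List: `genotypes` (the accepted sample), `attempts`, `mean_corr`
#'   of the accepted sample.
#' @export
sample_until_concordant <- function(pheno, ec_ranking, n = 500L,
                                    max_attempts = 100L, seed = 1L) {
  genos <- sort(unique(pheno$genotype))
  if (length(genos) < n) {
    stop("fewer than n = ", n, " genotypes available", call. = FALSE)
  }
  best <- list(score = -1L, extremes = NULL)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  for (attempt in seq_len(max_attempts)) {
    s <- sample(genos, n)
    mc <- mean_phenotypic_correlation(pheno[pheno$genotype %in% s, , drop = FALSE])
    ext <- suppressWarnings(select_extreme_envs(mc))
    score <- (ext$most_extreme == ec_ranking$most_extreme) +
             (ext$least_extreme == ec_ranking$least_extreme)
    if (score == 2L) {
      message("concordant sample accepted on attempt ", attempt)
      return(list(genotypes = sort(s), attempts = attempt, mean_corr = mc))
    }
    if (score > best$score) best <- list(score = score, extremes = ext)
  }
  stop("no concordant sample in ", max_attempts,
       " attempts; best attempt found (most = ", best$extremes$most_extreme,
       ", least = ", best$extremes$least_extreme, ")", call. = FALSE)
}

#' Within-environment heritability from a variance-component model
#'
#' Fits `y = mu + L + e` to the records of one environment with the line
#' effect random, using the package's Gibbs sampler on a single-kernel stack.
#' With replicated records the line covariance is the identity expanded to
#' records (`Z Z'`); with one record per line a genomic kinship must be
#' supplied (`Z G Z'`), otherwise the two variances are not identifiable.
#' Heritability is the ratio of the posterior-mean line variance to the
#' posterior-mean total variance.
#'
#' @param pheno Long phenotype table (may hold several environments).
#' @param environment Which environment to analyse.
#' @param G Optional genomic kinship (required without replicates).
#' @param n_iter,burn_in,thin Chain settings passed to [fit_gibbs()].
#' @param seed RNG seed for the chain.
#' @return One-row data.frame `(environment, sigma2_L, sigma2_resid, H2)` of
#'   class `heritability_estimate`.
#' @export
per_env_heritability <- function(pheno, environment, G = NULL,
                                 n_iter = 3000L, burn_in = 500L, thin = 5L,
                                 seed = NULL) {
  sub <- pheno[pheno$environment == environment, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for environment ", environment, call. = FALSE)
  lines <- sort(unique(sub$genotype))
  Zg <- matrix(0, nrow(sub), length(lines), dimnames = list(NULL, lines))
  Zg[cbind(seq_len(nrow(sub)), match(sub$genotype, lines))] <- 1
  if (any(duplicated(sub$genotype))) {
    K <- tcrossprod(Zg)
  } else if (!is.null(G)) {
    if (!all(lines %in% rownames(G))) stop("kinship does not cover all lines", call. = FALSE)
    K <- Zg %*% G[lines, lines] %*% t(Zg)
  } else {
    stop("one record per line and no kinship: line and residual variances ",
         "are not identifiable", call. = FALSE)
  }
  stack <- kernel_stack(response = sub$yield,
                        record_index = sub[, c("genotype", "environment")],
                        kernels = list(line = K))
  fit <- fit_gibbs(stack, n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
  s_L <- fit$vc$post_mean[fit$vc$term == "line"]
  s_R <- fit$vc$post_mean[fit$vc$term == "residual"]
  structure(data.frame(environment = environment, sigma2_L = s_L,
                       sigma2_resid = s_R, H2 = s_L / (s_L + s_R),
                       stringsAsFactors = FALSE),
            class = c("heritability_estimate", "data.frame"))
}
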