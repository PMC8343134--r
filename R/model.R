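#' Model specification for the multi-kernel mixed models
#'
#' The four standard multi-environment genomic prediction models:
#' \describe{
#'   \item{M0}{`y = mu + E + L + e` — environment main effect plus an IID
#'     line effect (no markers).}
#'   \item{M1}{`y = mu + E + g + e` — main genomic effect with covariance
#'     `G sigma2_g`.}
#'   \item{M2}{M1 plus a naive genotype-by-environment interaction with
#'     record-level covariance `Z_E Z_E' # Z_g G Z_g' sigma2_gE` (`#` =
#'     Hadamard product).}
#'   \item{M3}{M1 plus a covariate-informed reaction-norm interaction with
#'     covariance `Z_E Omega Z_E' # Z_g G Z_g' sigma2_gOmega`.}
#' }
#'
#' @param model_id One of `"M0"`, `"M1"`, `"M2"`, `"M3"`.
#' @return Object of class `model_spec` with the ordered term list.
#' @export
model_spec <- function(model_id = c("M1", "M0", "M2", "M3")) {
  model_id <- match.arg(model_id)
  terms <- switch(model_id,
                  M0 = c("env_main", "line_iid"),
                  M1 = c("env_main", "genomic_main"),
                  M2 = c("env_main", "genomic_main", "gxe_naive"),
                  M3 = c("env_main", "genomic_main", "gxw_informed"))
  structure(list(model_id = model_id, terms = terms), class = "model_spec")
}

#' Build environment and genotype incidence matrices
#'
#' One-hot 0/1 matrices connecting phenotypic records to environments
#' (`Z_E`) and genotypes (`Z_g`); column orders follow the sorted label
#' lists (or the supplied level vectors).
#'
#' @param pheno Long phenotype table `(genotype, environment, yield)`;
#'   `yield` may be `NA` for prediction cells.
#' @param genotypes,environments Optional explicit level sets; records with
#'   labels outside them raise a lookup error.
#' @return List: `Z_E`, `Z_g`, `record_index` (data.frame of the record
#'   labels in input order).
#' @export
build_incidence <- function(pheno, genotypes = NULL, environments = NULL) {
  stopifnot(nrow(pheno) > 0)
  glev <- genotypes %||% sort(unique(pheno$genotype))
  elev <- environments %||% sort(unique(pheno$environment))
  gi <- match(pheno$genotype, glev)
  ei <- match(pheno$environment, elev)
  if (anyNA(gi)) stop("unknown genotype label(s): ",
                      paste(utils::head(unique(pheno$genotype[is.na(gi)]), 3), collapse = ", "),
                      call. = FALSE)
  if (anyNA(ei)) stop("unknown environment label(s): ",
                      paste(utils::head(unique(pheno$environment[is.na(ei)]), 3), collapse = ", "),
                      call. = FALSE)
  n <- nrow(pheno)
  Z_E <- matrix(0, n, length(elev), dimnames = list(NULL, elev))
  Z_g <- matrix(0, n, length(glev), dimnames = list(NULL, glev))
  Z_E[cbind(seq_len(n), ei)] <- 1
  Z_g[cbind(seq_len(n), gi)] <- 1
  list(Z_E = Z_E, Z_g = Z_g,
       record_index = data.frame(genotype = pheno$genotype,
                                 environment = pheno$environment,
                                 stringsAsFactors = FALSE))
}

#' Low-level kernel stack constructor
#'
#' A kernel stack holds the response (with `NA` marking prediction cells),
#' the record labels, and one record-level covariance matrix per random
#' term. Kernels must be symmetric; positive semidefiniteness is checked at
#' fitting time through the eigendecomposition.
#'
#' @param response Numeric vector, `NA` allowed (at least one observed).
#' @param record_index Data.frame with `genotype` and `environment` columns.
#' @param kernels Named list of record x record matrices.
#' @param model_id Optional tag carried through to fits.
#' @return Object of class `kernel_stack`.
#' @export
kernel_stack <- function(response, record_index, kernels, model_id = NA_character_) {
  n <- length(response)
  stopifnot(nrow(record_index) == n, length(kernels) >= 1, !is.null(names(kernels)))
  if (!any(!is.na(response))) stop("at least one observed response required", call. = FALSE)
  for (nm in names(kernels)) {
    if (!all(dim(kernels[[nm]]) == n)) {
      stop("kernel '", nm, "' does not match the record count", call. = FALSE)
    }
    check_symmetric(kernels[[nm]], label = paste0("kernel '", nm, "'"))
  }
  structure(list(response = as.numeric(response),
                 record_index = record_index, kernels = kernels,
                 model_id = model_id),
            class = "kernel_stack")
}

#' Assemble the record-level covariance structures of a model
#'
#' Builds the per-term kernels from the kinships and incidence matrices:
#' `env_main = Z_E Z_E'`, `line_iid = Z_g Z_g'`,
#' `genomic_main = Z_g G Z_g'`, `gxe_naive = env_main # genomic_main`, and
#' `gxw_informed = Z_E Omega Z_E' # genomic_main` (Hadamard products; PSD by
#' the Schur product theorem).
#'
#' @param spec A [model_spec()].
#' @param G Genomic kinship (required for genomic terms), labeled by
#'   genotype ids covering `colnames(Z_g)`.
#' @param Omega Environmental kinship (required for M3), labeled by
#'   environment ids covering `colnames(Z_E)`.
#' @param Z_E,Z_g Incidence matrices from [build_incidence()].
#' @param response Record-level yields, `NA` for cells to predict.
#' @param record_index Record labels from [build_incidence()].
#' @return A [kernel_stack()].
#' @export
assemble_kernels <- function(spec, G = NULL, Omega = NULL, Z_E, Z_g,
                             response, record_index) {
  stopifnot(inherits(spec, "model_spec"))
  kernels <- list()
  Kg <- NULL
  if (any(c("genomic_main", "gxe_naive", "gxw_informed") %in% spec$terms)) {
    if (is.null(G)) stop("configuration error: genomic terms require G", call. = FALSE)
    ids <- colnames(Z_g)
    if (!all(ids %in% rownames(G))) {
      stop("G does not cover all genotypes in the records", call. = FALSE)
    }
    Kg <- Z_g %*% G[ids, ids] %*% t(Z_g)
  }
  for (term in spec$terms) {
    kernels[[term]] <- switch(term,
      env_main = tcrossprod(Z_E),
      line_iid = tcrossprod(Z_g),
      genomic_main = Kg,
      gxe_naive = tcrossprod(Z_E) * Kg,
      gxw_informed = {
        if (is.null(Omega)) {
          stop("configuration error: gxw_informed requires Omega", call. = FALSE)
        }
        envs <- colnames(Z_E)
        if (!all(envs %in% rownames(Omega))) {
          stop("Omega does not cover all environments in the records", call. = FALSE)
        }
        (Z_E %*% Omega[envs, envs] %*% t(Z_E)) * Kg
      },
      stop("unknown term: ", term, call. = FALSE))
  }
  kernel_stack(response, record_index, kernels, model_id = spec$model_id)
}

# Eigendecompose each term kernel once; eigenvalues below tol are truncated,
# eigenvalues materially negative raise a numerical error.
eigen_stack <- function(stack, tol = 1e-8) {
  lapply(stack$kernels, function(K) {
    e <- eigen(K, symmetric = TRUE)
    scale <- max(abs(e$values), 1)
    if (min(e$values) < -1e-6 * scale) {
      stop("numerical error: kernel is not positive semidefinite ",
           "(min eigenvalue ", signif(min(e$values), 3), ")", call. = FALSE)
    }
    keep <- e$values > tol
    if (!any(keep)) keep[1] <- TRUE
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
}

#' Fit a multi-kernel mixed model by Gibbs sampling
#'
#' Bayesian fit of `y = mu 1 + sum_t u_t + e`, `u_t ~ N(0, K_t sigma2_t)`,
#' `e ~ N(0, I sigma2)`, with a flat prior on `mu` and scaled-inverse
#' chi-square priors (`df0` degrees of freedom) on every variance; the prior
#' scales are set so each term's prior mode explains an equal share of half
#' the observed response variance (`R2`). Each term's effects are sampled in
#' the eigenbasis of its kernel (eigenvalues below 1e-8 truncated), which
#' makes the conditional updates independent across eigencomponents. Records
#' with a missing response contribute no information: they are refreshed
#' from the Gaussian predictive each sweep (data augmentation), so their
#' fitted values are genuine posterior predictions.
#'
#' With `fixed_vc` supplied, variance sampling is disabled and the fit is
#' computed exactly by the deterministic BLUP path ([fit_blup()]).
#'
#' @param stack A [kernel_stack()].
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning.
#' @param df0 Prior degrees of freedom for every variance component.
#' @param R2 Share of the response variance the prior attributes to the
#'   model (split equally among terms).
#' @param seed Chain seed; same seed, same stack gives bit-identical fits.
#' @param fixed_vc Optional named variances (`terms` plus `"residual"`)
#'   switching to the exact fixed-variance BLUP solution.
#' @return Object of class `gp_fit`: posterior mean `mu`, `vc` (data.frame
#'   term/post_mean/post_sd/ess), `gebv` (per-record observed and predicted
#'   values), `draws`, `n_saved`, `method`, `seed`.
#' @references The eigenbasis update is the standard trick for
#'   kernel-parameterized GBLUP samplers; see e.g. the RKHS literature on
#'   Bayesian genomic prediction.
#' @export
fit_gibbs <- function(stack, n_iter = 6000L, burn_in = 1000L, thin = 5L,
                      df0 = 5, R2 = 0.5, seed = NULL, fixed_vc = NULL) {
  stopifnot(inherits(stack, "kernel_stack"))
  if (!is.null(fixed_vc)) return(fit_blup(stack, fixed_vc))
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  y <- stack$response
  obs <- !is.na(y)
  n <- length(y)
  n_mis <- sum(!obs)
  terms <- names(stack$kernels)
  nt <- length(terms)
  eig <- eigen_stack(stack)
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6  # constant response: prior-driven variances
  S_t <- (R2 * vy / nt) * (df0 + 2) / df0    # prior scale from the prior-mode target
  S_e <- ((1 - R2) * vy) * (df0 + 2) / df0

  mu <- mean(y[obs])
  sig2 <- vy / 2
  sig2_t <- rep(R2 * vy / nt, nt)
  names(sig2_t) <- terms
  u <- matrix(0, n, nt, dimnames = list(NULL, terms))
  e <- ifelse(obs, y - mu, 0)

  n_save <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, n_save, nt + 2,
                  dimnames = list(NULL, c("mu", terms, "residual")))
  eta_sum <- numeric(n)
  k <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      if (n_mis > 0) e[!obs] <- stats::rnorm(n_mis, 0, sqrt(sig2))
      mu_new <- stats::rnorm(1, mu + mean(e), sqrt(sig2 / n))
      e <- e - (mu_new - mu)
      mu <- mu_new
      for (t in seq_len(nt)) {
        U <- eig[[t]]$U
        d <- eig[[t]]$d
        et <- e + u[, t]
        b <- crossprod(U, et)
        cv <- 1 / (1 / sig2 + 1 / (d * sig2_t[t]))
        a <- stats::rnorm(length(d), cv * b / sig2, sqrt(cv))
        u_new <- drop(U %*% a)
        e <- et - u_new
        u[, t] <- u_new
        sig2_t[t] <- (sum(a^2 / d) + df0 * S_t) / stats::rchisq(1, df0 + length(d))
      }
      sig2 <- (sum(e^2) + df0 * S_e) / stats::rchisq(1, df0 + n)
      if (!all(is.finite(c(mu, sig2, sig2_t)))) {
        stop("divergent chain: non-finite draw at iteration ", it, call. = FALSE)
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        k <- k + 1L
        draws[k, ] <- c(mu, sig2_t, sig2)
        eta_sum <- eta_sum + mu + rowSums(u)
      }
    }
  })
  vc_mean <- colMeans(draws)
  vc_sd <- apply(draws, 2, stats::sd)
  ess <- apply(draws, 2, function(x) {
    r1 <- if (stats::sd(x) == 0) 0 else stats::cor(x[-1], x[-length(x)])
    if (!is.finite(r1)) r1 <- 0
    max(1, min(length(x), length(x) * (1 - r1) / (1 + r1)))
  })
  vc <- data.frame(term = c(terms, "residual"),
                   post_mean = vc_mean[c(terms, "residual")],
                   post_sd = vc_sd[c(terms, "residual")],
                   ess = ess[c(terms, "residual")],
                   row.names = NULL, stringsAsFactors = FALSE)
  gebv <- data.frame(stack$record_index,
                     observed = y, predicted = eta_sum / k,
                     stringsAsFactors = FALSE)
  structure(list(model_id = stack$model_id, method = "gibbs",
                 mu = vc_mean[["mu"]], vc = vc, gebv = gebv, draws = draws,
                 n_saved = k, seed = seed,
                 chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                              df0 = df0, R2 = R2)),
            class = "gp_fit")
}

#' Exact fixed-variance BLUP fit
#'
#' With all variance components held fixed, the posterior of the Gaussian
#' model is available in closed form: `mu` is the GLS mean under
#' `V = sum_t sigma2_t K_t + sigma2 I` on the observed records, and each
#' term's effects are their conditional means
#' `sigma2_t K_t[, obs] V^{-1} (y - mu)`, evaluated for every record
#' including prediction cells. This is the deterministic path used for
#' oracle checks and fast cross-validation sweeps.
#'
#' @param stack A [kernel_stack()].
#' @param vc Named variances: one per term of the stack plus `"residual"`,
#'   all >= 0, residual > 0.
#' @return A `gp_fit` with `method = "blup"` and exact predictions.
#' @export
fit_blup <- function(stack, vc) {
  stopifnot(inherits(stack, "kernel_stack"))
  terms <- names(stack$kernels)
  need <- c(terms, "residual")
  if (!all(need %in% names(vc))) {
    stop("vc must name every term plus 'residual': ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  vc <- vc[need]
  if (any(vc < 0) || vc[["residual"]] <= 0) {
    stop("variances must be >= 0 with residual > 0", call. = FALSE)
  }
  y <- stack$response
  obs <- which(!is.na(y))
  V <- diag(vc[["residual"]], length(obs))
  for (t in terms) V <- V + vc[[t]] * stack$kernels[[t]][obs, obs, drop = FALSE]
  ch <- chol(V)
  yo <- y[obs]
  one <- rep(1, length(obs))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), yo))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  alpha <- backsolve(ch, forwardsolve(t(ch), yo - mu))
  eta <- rep(mu, length(y))
  u <- matrix(0, length(y), length(terms), dimnames = list(NULL, terms))
  for (t in terms) {
    u[, t] <- vc[[t]] * drop(stack$kernels[[t]][, obs, drop = FALSE] %*% alpha)
    eta <- eta + u[, t]
  }
  vc_df <- data.frame(term = need, post_mean = as.numeric(vc),
                      post_sd = NA_real_, ess = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
  gebv <- data.frame(stack$record_index, observed = y, predicted = eta,
                     stringsAsFactors = FALSE)
  structure(list(model_id = stack$model_id, method = "blup", mu = mu,
                 vc = vc_df, gebv = gebv, effects = u, draws = NULL,
                 n_saved = 0L, seed = NULL, chain = NULL),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Multi-kernel mixed model fit",
      if (!is.na(x$model_id)) paste0("(", x$model_id, ")"), "-", x$method, "\n")
  cat(sprintf("  mu = %.4g over %d records (%d observed)\n", x$mu,
              nrow(x$gebv), sum(!is.na(x$gebv$observed))))
  print(x$vc, digits = 4)
  invisible(x)
}

#' Extract genomic estimated breeding values for chosen cells
#'
#' Looks up the posterior-mean linear predictor for the requested
#' (genotype, environment) cells. Cells must have been part of the record
#' set at assembly time (prediction cells are declared with `NA` responses
#' before fitting).
#'
#' @param fit A `gp_fit`.
#' @param cells Data.frame with `genotype` and `environment` columns.
#' @return `cells` with a `predicted` column appended, in input order.
#' @export
predict_gebv <- function(fit, cells) {
  stopifnot(inherits(fit, "gp_fit"),
            all(c("genotype", "environment") %in% names(cells)))
  key_fit <- paste(fit$gebv$genotype, fit$gebv$environment, sep = "\r")
  key <- paste(cells$genotype, cells$environment, sep = "\r")
  i <- match(key, key_fit)
  if (anyNA(i)) {
    stop("cell(s) absent from the fitted record set: ",
         paste(utils::head(gsub("\r", " @ ", key[is.na(i)]), 3), collapse = "; "),
         " - declare prediction cells before fitting", call. = FALSE)
  }
  cells$predicted <- fit$gebv$predicted[i]
  cells
}
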