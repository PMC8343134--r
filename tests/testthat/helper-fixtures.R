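# Shared fixture builders. Everything is generated in code at test time.

# Small trial configuration on an arbitrary yield scale.
small_config <- function(n_families = 3L, family_size = 20L, n_markers = 200L,
                         n_environments = 4L, n_days = 20L,
                         vc = c(sigma2_E = 1, sigma2_g = 1, sigma2_gE = 0.25,
                                sigma2_gW = 0.25, sigma2_resid = 1),
                         mu = 10, n_divergent_envs = 0L, seed = 1L, ...) {
  sim_config(n_families = n_families, family_size = family_size,
             n_markers = n_markers, n_environments = n_environments,
             n_days = n_days, variance_components = vc, mu = mu,
             n_divergent_envs = n_divergent_envs, seed = seed, ...)
}

# Random labeled PSD kinship over the given ids (marker-derived, full rank
# when p >> n).
random_grm <- function(ids, p = 5 * length(ids), seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(0:2, length(ids) * p, replace = TRUE), length(ids), p,
              dimnames = list(ids, sprintf("M%04d", seq_len(p))))
  keep <- apply(m, 2, stats::sd) > 0
  G <- genomic_relationship(center_scale(m[, keep, drop = FALSE]))
  G
}

# Random multi-environment records with some prediction cells.
random_records <- function(n = 50L, n_geno = 12L, n_env = 4L, seed = 1L,
                           n_missing = 0L) {
  set.seed(seed)
  pheno <- data.frame(
    genotype = sample(sprintf("g%02d", seq_len(n_geno)), n, replace = TRUE),
    environment = sample(sprintf("e%d", seq_len(n_env)), n, replace = TRUE),
    yield = rnorm(n), stringsAsFactors = FALSE)
  if (n_missing > 0) pheno$yield[sample(n, n_missing)] <- NA
  pheno
}

# Independent mixed-model-equation oracle: Henderson's equations built from
# raw design matrices, solved densely. Deliberately a different algebraic
# route than fit_blup()'s V-inverse path.
mme_oracle <- function(pheno, kernels_geno, vc) {
  obs <- !is.na(pheno$yield)
  y <- pheno$yield[obs]
  inc <- build_incidence(pheno)
  terms <- names(kernels_geno)
  W <- matrix(1, sum(obs), 1)
  Ks <- list()
  blocks <- list()
  for (t in terms) {
    K <- kernels_geno[[t]]           # record-level kernel over all records
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > 1e-10
    Tt <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                   sum(keep))
    blocks[[t]] <- Tt                # u_t = Tt a_t with a_t ~ N(0, I sigma2_t)
    W <- cbind(W, Tt[obs, , drop = FALSE])
    Ks[[t]] <- ncol(Tt)
  }
  C <- crossprod(W)
  pos <- 1
  for (t in terms) {
    idx <- pos + seq_len(Ks[[t]])
    C[idx, idx] <- C[idx, idx] + diag(vc[["residual"]] / vc[[t]], Ks[[t]])
    pos <- pos + Ks[[t]]
  }
  sol <- solve(C, crossprod(W, y))
  mu <- sol[1]
  eta <- rep(mu, nrow(pheno))
  pos <- 1
  for (t in terms) {
    idx <- pos + seq_len(Ks[[t]])
    eta <- eta + drop(blocks[[t]] %*% sol[idx])
    pos <- pos + Ks[[t]]
  }
  list(mu = mu, eta = eta)
}
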