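test_that("model specifications carry the canonical term sets", {
  expect_equal(model_spec("M0")$terms, c("env_main", "line_iid"))
  expect_equal(model_spec("M1")$terms, c("env_main", "genomic_main"))
  expect_equal(model_spec("M2")$terms, c("env_main", "genomic_main", "gxe_naive"))
  expect_equal(model_spec("M3")$terms, c("env_main", "genomic_main", "gxw_informed"))
})

test_that("incidence matrices are one-hot with sorted columns", {
  pheno <- data.frame(genotype = c("g2", "g1", "g2", "g1"),
                      environment = c("eB", "eB", "eA", "eA"),
                      yield = 1:4, stringsAsFactors = FALSE)
  inc <- build_incidence(pheno)
  expect_equal(dim(inc$Z_E), c(4L, 2L))
  expect_equal(colnames(inc$Z_E), c("eA", "eB"))
  expect_true(all(rowSums(inc$Z_E) == 1) && all(rowSums(inc$Z_g) == 1))
  expect_equal(unname(colSums(inc$Z_E)), c(2, 2))
  # Z_E Z_E' flags records sharing an environment
  S <- tcrossprod(inc$Z_E)
  expect_equal(unname(S), outer(pheno$environment, pheno$environment, `==`) * 1)
  expect_error(build_incidence(pheno, genotypes = "g1"), "unknown genotype")
})

test_that("kernel assembly matches its algebraic identities", {
  # single environment with G = I: the naive interaction kernel collapses
  # onto the genomic kernel
  ids <- paste0("g", 1:3)
  pheno1 <- data.frame(genotype = ids, environment = "e1", yield = rnorm(3),
                       stringsAsFactors = FALSE)
  inc1 <- build_incidence(pheno1)
  I3 <- diag(3); dimnames(I3) <- list(ids, ids)
  st1 <- assemble_kernels(model_spec("M2"), G = I3, Z_E = inc1$Z_E,
                          Z_g = inc1$Z_g, response = pheno1$yield,
                          record_index = inc1$record_index)
  expect_equal(st1$kernels$gxe_naive, st1$kernels$genomic_main)

  # with Omega = I the reaction-norm kernel equals the naive one
  pheno <- random_records(30, 8, 3, seed = 2)
  inc <- build_incidence(pheno)
  G <- random_grm(sort(unique(pheno$genotype)), seed = 3)
  IO <- diag(3); dimnames(IO) <- list(colnames(inc$Z_E), colnames(inc$Z_E))
  st2 <- assemble_kernels(model_spec("M2"), G = G, Z_E = inc$Z_E,
                          Z_g = inc$Z_g, response = pheno$yield,
                          record_index = inc$record_index)
  st3 <- assemble_kernels(model_spec("M3"), G = G, Omega = IO, Z_E = inc$Z_E,
                          Z_g = inc$Z_g, response = pheno$yield,
                          record_index = inc$record_index)
  expect_equal(st3$kernels$gxw_informed, st2$kernels$gxe_naive)

  expect_error(assemble_kernels(model_spec("M3"), G = G, Z_E = inc$Z_E,
                                Z_g = inc$Z_g, response = pheno$yield,
                                record_index = inc$record_index),
               "requires Omega")
  expect_error(assemble_kernels(model_spec("M1"), Z_E = inc$Z_E,
                                Z_g = inc$Z_g, response = pheno$yield,
                                record_index = inc$record_index),
               "require G")
})

test_that("Hadamard products of PSD kernels stay PSD", {
  set.seed(5)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(100), 10))
    B <- crossprod(matrix(rnorm(100), 10))
    ev <- eigen(A * B, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("the fixed-variance path equals the mixed-model-equation oracle", {
  for (seed in 1:3) {
    pheno <- random_records(50, 12, 4, seed = seed)
    G <- random_grm(sort(unique(pheno$genotype)), seed = seed + 10)
    inc <- build_incidence(pheno)
    stack <- assemble_kernels(model_spec("M2"), G = G, Z_E = inc$Z_E,
                              Z_g = inc$Z_g, response = pheno$yield,
                              record_index = inc$record_index)
    vc <- c(env_main = 0.7, genomic_main = 1.3, gxe_naive = 0.4,
            residual = 0.9)
    fit <- fit_gibbs(stack, fixed_vc = vc)  # dispatches to the exact path
    expect_equal(fit$method, "blup")
    oracle <- mme_oracle(pheno, stack$kernels, vc)
    expect_equal(fit$mu, oracle$mu, tolerance = 1e-6)
    expect_equal(fit$gebv$predicted, oracle$eta, tolerance = 1e-6)
  }
})

test_that("a constant response returns its value as mu with vanishing
          variances", {
  pheno <- data.frame(genotype = rep(paste0("g", 1:5), 2),
                      environment = rep(c("e1", "e2"), each = 5),
                      yield = 7, stringsAsFactors = FALSE)
  inc <- build_incidence(pheno)
  stack <- assemble_kernels(model_spec("M0"), Z_E = inc$Z_E, Z_g = inc$Z_g,
                            response = pheno$yield,
                            record_index = inc$record_index)
  fit <- fit_gibbs(stack, n_iter = 600, burn_in = 100, thin = 2, seed = 1)
  expect_equal(fit$mu, 7, tolerance = 1e-2)
  expect_true(all(fit$vc$post_mean < 1e-3))
})

test_that("a zero interaction variance makes M2 collapse onto M1 exactly", {
  pheno <- random_records(60, 15, 4, seed = 6, n_missing = 10)
  G <- random_grm(sort(unique(pheno$genotype)), seed = 7)
  inc <- build_incidence(pheno)
  mk <- function(id) assemble_kernels(model_spec(id), G = G, Z_E = inc$Z_E,
                                      Z_g = inc$Z_g, response = pheno$yield,
                                      record_index = inc$record_index)
  vc1 <- c(env_main = 0.5, genomic_main = 1, residual = 1)
  f1 <- fit_blup(mk("M1"), vc1)
  f2 <- fit_blup(mk("M2"), c(vc1, gxe_naive = 0))
  expect_equal(f2$gebv$predicted, f1$gebv$predicted, tolerance = 1e-12)
})

test_that("chains are bit-reproducible and record-order exchangeable", {
  pheno <- random_records(40, 10, 3, seed = 8, n_missing = 5)
  G <- random_grm(sort(unique(pheno$genotype)), seed = 9)
  inc <- build_incidence(pheno)
  stack <- assemble_kernels(model_spec("M1"), G = G, Z_E = inc$Z_E,
                            Z_g = inc$Z_g, response = pheno$yield,
                            record_index = inc$record_index)
  fa <- fit_gibbs(stack, n_iter = 500, burn_in = 100, thin = 2, seed = 42)
  fb <- fit_gibbs(stack, n_iter = 500, burn_in = 100, thin = 2, seed = 42)
  expect_identical(fa$draws, fb$draws)
  expect_identical(fa$gebv, fb$gebv)

  # fixed-variance path: permuting records permutes predictions exactly
  vc <- c(env_main = 0.5, genomic_main = 1, residual = 1)
  f0 <- fit_blup(stack, vc)
  perm <- sample(nrow(pheno))
  incp <- build_incidence(pheno[perm, ])
  stackp <- assemble_kernels(model_spec("M1"), G = G, Z_E = incp$Z_E,
                             Z_g = incp$Z_g, response = pheno$yield[perm],
                             record_index = incp$record_index)
  fp <- fit_blup(stackp, vc)
  expect_equal(fp$gebv$predicted, f0$gebv$predicted[perm], tolerance = 1e-10)
})

test_that("predictions into unseen environments follow the kernel algebra", {
  ids <- paste0("g", 1:6)
  G <- random_grm(ids, seed = 10)
  train <- data.frame(genotype = rep(ids, 2),
                      environment = rep(c("eA", "eB"), each = 6),
                      yield = rnorm(12), stringsAsFactors = FALSE)
  cells <- data.frame(genotype = ids, environment = "eNew",
                      yield = NA_real_, stringsAsFactors = FALSE)
  records <- rbind(train, cells)
  inc <- build_incidence(records)
  vc <- c(env_main = 0.8, genomic_main = 1.2, residual = 1)
  stack <- assemble_kernels(model_spec("M1"), G = G, Z_E = inc$Z_E,
                            Z_g = inc$Z_g, response = records$yield,
                            record_index = inc$record_index)
  fit <- fit_blup(stack, vc)
  # unseen environment: no shrinkage target, prediction = mu + g_i exactly
  new_rows <- which(records$environment == "eNew")
  expect_equal(fit$gebv$predicted[new_rows],
               fit$mu + fit$effects[new_rows, "genomic_main"],
               tolerance = 1e-12)
  expect_equal(unname(fit$effects[new_rows, "env_main"]), rep(0, 6),
               tolerance = 1e-12)

  # M2 with a genotype unrelated to training: prediction collapses to mu
  ids2 <- c(ids, "gx")
  G2 <- diag(7) * 1.0
  dimnames(G2) <- list(ids2, ids2)
  G2[ids, ids] <- G
  rec2 <- rbind(train, data.frame(genotype = "gx", environment = "eNew",
                                  yield = NA_real_, stringsAsFactors = FALSE))
  inc2 <- build_incidence(rec2)
  st2 <- assemble_kernels(model_spec("M2"), G = G2, Z_E = inc2$Z_E,
                          Z_g = inc2$Z_g, response = rec2$yield,
                          record_index = inc2$record_index)
  f2 <- fit_blup(st2, c(env_main = 0.8, genomic_main = 1.2, gxe_naive = 0.5,
                        residual = 1))
  expect_equal(f2$gebv$predicted[nrow(rec2)], f2$mu, tolerance = 1e-10)

  # undeclared cells are refused
  expect_error(predict_gebv(fit, data.frame(genotype = "g1",
                                            environment = "nowhere")),
               "absent")
})

test_that("Omega coupling channels interaction signal into an unseen
          environment", {
  # two training environments; the target is strongly coupled to eA only
  ids <- sprintf("g%02d", 1:40)
  G <- random_grm(ids, p = 300, seed = 11)
  Om <- matrix(c(1, 0, 0.95,
                 0, 1, 0,
                 0.95, 0, 1), 3, 3,
               dimnames = list(c("eA", "eB", "eT"), c("eA", "eB", "eT")))
  set.seed(12)
  gwA <- drop(t(chol(G + diag(1e-8, 40))) %*% rnorm(40))
  train <- data.frame(genotype = rep(ids, 2),
                      environment = rep(c("eA", "eB"), each = 40),
                      yield = c(gwA, rnorm(40, sd = 0.1)),
                      stringsAsFactors = FALSE)
  rec <- rbind(train, data.frame(genotype = ids, environment = "eT",
                                 yield = NA_real_, stringsAsFactors = FALSE))
  inc <- build_incidence(rec)
  st <- assemble_kernels(model_spec("M3"), G = G, Omega = Om, Z_E = inc$Z_E,
                         Z_g = inc$Z_g, response = rec$yield,
                         record_index = inc$record_index)
  f <- fit_blup(st, c(env_main = 0.1, genomic_main = 0.1, gxw_informed = 1,
                      residual = 0.2))
  pred_T <- f$effects[rec$environment == "eT", "gxw_informed"]
  fitted_A <- f$effects[rec$environment == "eA", "gxw_informed"]
  expect_gt(cor(pred_T, fitted_A), 0.9)
})

test_that("Gibbs posteriors recover generative variances on a small study", {
  cfg <- small_config(n_families = 4, family_size = 25, n_environments = 4,
                      vc = c(sigma2_E = 1, sigma2_g = 1, sigma2_gE = 0,
                             sigma2_gW = 0, sigma2_resid = 1), seed = 16)
  st <- simulate_study(cfg)
  inc <- build_incidence(st$pheno)
  stack <- assemble_kernels(model_spec("M1"), G = st$G, Z_E = inc$Z_E,
                            Z_g = inc$Z_g, response = st$pheno$yield,
                            record_index = inc$record_index)
  fit <- fit_gibbs(stack, n_iter = 1500, burn_in = 300, thin = 3, seed = 17)
  for (term in c("genomic_main", "residual")) {
    row <- fit$vc[fit$vc$term == term, ]
    expect_lt(abs(row$post_mean - 1), 3 * row$post_sd)
  }
  expect_true(all(fit$vc$post_mean >= 0))
  expect_false(anyNA(fit$gebv$predicted))
})

test_that("degenerate stacks are rejected with informative errors", {
  pheno <- random_records(10, 4, 2, seed = 20)
  inc <- build_incidence(pheno)
  K <- tcrossprod(inc$Z_E)
  expect_error(kernel_stack(rep(NA_real_, 10), inc$record_index,
                            list(env = K)), "observed")
  expect_error(kernel_stack(pheno$yield, inc$record_index,
                            list(env = K[1:9, 1:9])), "record count")
  Kbad <- K; Kbad[1, 2] <- 5
  expect_error(kernel_stack(pheno$yield, inc$record_index, list(env = Kbad)),
               "symmetric")
  stack <- kernel_stack(pheno$yield, inc$record_index, list(env = K))
  expect_error(fit_gibbs(stack, n_iter = 100, burn_in = 100), "burn_in")
  expect_error(fit_blup(stack, c(env = 1, residual = 0)), "residual")
  expect_error(fit_blup(stack, c(residual = 1)), "must name")
})
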