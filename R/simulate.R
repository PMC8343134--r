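#' Configuration for the synthetic NAM-style trial generator
#'
#' Bundles every knob of the simulator: population structure (biparental RIL
#' families sharing a common parent), marker panel size, the multi-environment
#' trial layout, the daily weather grid, and the generative variance
#' components of the reaction-norm model
#' \deqn{y_{ij} = \mu + E_j + g_i + gE_{ij} + gw_{ij} + e_{ij}.}
#'
#' Defaults emulate the SoyNAM-scale study the package is designed around:
#' 40 families of 140 recombinant inbred lines (5,600 genotypes), 4,450
#' biallelic markers, 9 environments with 3 daily weather covariates over a
#' 125-day season, one weather-divergent environment, and variance components
#' giving a within-environment heritability near 0.5 on a grain-yield scale
#' (kg/ha): line s.d. 300, residual s.d. 300, environment s.d. 500, and
#' interaction variances at a quarter of the genomic variance.
#'
#' @param n_families Number of biparental RIL families.
#' @param family_size RILs per family.
#' @param n_markers Biallelic markers on one synthetic linear map.
#' @param n_environments Number of LOC_YEAR environments (>= 2).
#' @param n_days Days of daily weather after planting (>= 3).
#' @param variance_components Named vector with `sigma2_E`, `sigma2_g`,
#'   `sigma2_gE`, `sigma2_gW`, `sigma2_resid`, all >= 0 (yield units squared);
#'   the all-zero setting gives the noiseless limit `y = mu` everywhere.
#' @param mu Grand mean yield (kg/ha).
#' @param n_divergent_envs How many environments receive a +3 s.d. shift on
#'   all weather series, making them covariate-space outliers.
#' @param recomb Per-adjacent-marker recombination (switch) probability.
#' @param ec_noise,ec_shift Multipliers on the daily weather noise and the
#'   per-environment mean shifts (0 gives identical environments).
#' @param seed Master seed; all generator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_study()] for one-call generation of a full trial.
#' @export
sim_config <- function(n_families = 40L, family_size = 140L, n_markers = 4450L,
                       n_environments = 9L, n_days = 125L,
                       variance_components = c(sigma2_E = 250000, sigma2_g = 90000,
                                               sigma2_gE = 22500, sigma2_gW = 22500,
                                               sigma2_resid = 90000),
                       mu = 2500, n_divergent_envs = 1L, recomb = 0.05,
                       ec_noise = 1, ec_shift = 1, seed = 1L) {
  counts <- c(n_families = n_families, family_size = family_size,
              n_markers = n_markers)
  if (any(counts < 1)) {
    stop("configuration error: n_families, family_size and n_markers must be positive",
         call. = FALSE)
  }
  if (n_families * family_size < 2) {
    stop("configuration error: need at least 2 genotypes", call. = FALSE)
  }
  if (n_environments < 2) stop("configuration error: n_environments must be >= 2", call. = FALSE)
  if (n_days < 3) stop("configuration error: n_days must be >= 3", call. = FALSE)
  need <- c("sigma2_E", "sigma2_g", "sigma2_gE", "sigma2_gW", "sigma2_resid")
  if (!all(need %in% names(variance_components))) {
    stop("variance_components must be named: ", paste(need, collapse = ", "), call. = FALSE)
  }
  vc <- variance_components[need]
  if (any(vc < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  if (n_divergent_envs < 0 || n_divergent_envs > n_environments) {
    stop("configuration error: n_divergent_envs out of range", call. = FALSE)
  }
  if (recomb < 0 || recomb > 1) stop("configuration error: recomb must be in [0, 1]", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 n_markers = as.integer(n_markers),
                 n_environments = as.integer(n_environments),
                 n_days = as.integer(n_days),
                 variance_components = vc, mu = mu,
                 n_divergent_envs = as.integer(n_divergent_envs),
                 recomb = recomb, ec_noise = ec_noise, ec_shift = ec_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' Key-value (possibly nested) configs drive the generators; any key absent
#' from the file keeps its [sim_config()] default. `variance_components` may
#' be given as a nested mapping.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$variance_components)) {
    raw$variance_components <- unlist(raw$variance_components)
  }
  do.call(sim_config, raw)
}

env_labels <- function(m) {
  locs <- c("IA", "IL", "IN", "NE", "KS", "MO", "OH", "MI", "WI", "MN")
  i <- seq_len(m) - 1L
  paste0(locs[i %% length(locs) + 1L], "_", 2011L + i %/% length(locs))
}

#' Simulate NAM-style RIL genotypes
#'
#' Generates fully inbred recombinant inbred lines in `n_families` biparental
#' families that share one common-parent haplotype. Markers live on a single
#' synthetic linear map; each RIL's parental origin follows a first-order
#' Markov chain along the map with switch probability `config$recomb` between
#' adjacent markers. Dosages are coded 0/2 (homozygous only — RILs carry no
#' residual heterozygosity here).
#'
#' @param config A [sim_config()].
#' @return Integer matrix (genotypes x markers) with dosages in \{0, 2\},
#'   rownames `F.._R...`, colnames `M....`.
#' @export
simulate_nam_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_markers
  fs <- config$family_size
  with_seed(derive_seed(config$seed, "genotypes"), {
    common <- stats::rbinom(p, 1L, 0.5)
    blocks <- vector("list", config$n_families)
    for (f in seq_len(config$n_families)) {
      diverse <- stats::rbinom(p, 1L, 0.5)
      # parental origin per RIL: start 50/50, switch between adjacent markers
      start <- stats::rbinom(fs, 1L, 0.5)
      if (p > 1) {
        switches <- matrix(stats::runif(fs * (p - 1)) < config$recomb, fs, p - 1)
        origin <- (start + cbind(0L, t(apply(switches, 1, cumsum)))) %% 2L
      } else {
        origin <- matrix(start, fs, 1L)
      }
      allele <- matrix(common, fs, p, byrow = TRUE)
      allele[origin == 1L] <- matrix(diverse, fs, p, byrow = TRUE)[origin == 1L]
      blocks[[f]] <- 2L * allele
    }
    m <- do.call(rbind, blocks)
    dimnames(m) <- list(
      sprintf("F%02d_R%03d", rep(seq_len(config$n_families), each = fs),
              rep(seq_len(fs), config$n_families)),
      sprintf("M%04d", seq_len(p)))
    storage.mode(m) <- "integer"
    m
  })
}

#' Simulate daily environmental covariates
#'
#' For each environment, three daily series over the growing season: minimum
#' temperature and maximum temperature in tenths of degrees Celsius and
#' precipitation in inches (units kept as weather archives report them).
#' Each series is a smooth seasonal trend plus an environment-level mean
#' shift plus daily noise; maximum temperature is the minimum plus a strictly
#' positive diurnal gap, and precipitation is truncated at zero. The last
#' `n_divergent_envs` environments additionally get a +3 within-environment
#' s.d. shift on all three series, making them covariate-space outliers.
#'
#' @param config A [sim_config()].
#' @return Long data.frame `(environment, day, variable, value)` with
#'   variables `tmin_tenthsC`, `tmax_tenthsC`, `precip_inches`.
#' @export
simulate_env_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_environments
  nd <- config$n_days
  labs <- env_labels(m)
  d <- seq_len(nd)
  tmin_trend <- 100 + 80 * sin(pi * d / nd)          # tenths of deg C
  precip_trend <- 0.15 + 0.05 * sin(2 * pi * d / nd) # inches
  divergent <- labs[seq_len(m) > m - config$n_divergent_envs]
  with_seed(derive_seed(config$seed, "weather"), {
    out <- vector("list", m)
    for (j in seq_len(m)) {
      shift_T <- stats::rnorm(1, 0, 15 * config$ec_shift)
      shift_P <- stats::rnorm(1, 0, 0.04 * config$ec_shift)
      tmin <- tmin_trend + shift_T + stats::rnorm(nd, 0, 25 * config$ec_noise)
      gap <- pmax(5, 95 + stats::rnorm(nd, 0, 20 * config$ec_noise))
      tmax <- tmin + gap
      precip <- pmax(0, precip_trend + shift_P + stats::rnorm(nd, 0, 0.08 * config$ec_noise))
      if (labs[j] %in% divergent) {
        delta_T <- 3 * max(stats::sd(tmin), stats::sd(tmax))
        tmin <- tmin + delta_T
        tmax <- tmax + delta_T
        precip <- precip + 3 * stats::sd(precip)
      }
      out[[j]] <- data.frame(
        environment = labs[j],
        day = rep(d, 3),
        variable = rep(c("tmin_tenthsC", "tmax_tenthsC", "precip_inches"), each = nd),
        value = c(tmin, tmax, precip),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate phenotypes under the reaction-norm generative model
#'
#' Draws grain yield on the complete genotype x environment grid as
#' \eqn{y_{ij} = \mu + E_j + g_i + gE_{ij} + gw_{ij} + e_{ij}} with
#' \eqn{E_j \sim N(0, \sigma^2_E)}, genomic values \eqn{g_i = \sum_k x_{ik} b_k}
#' rescaled so their sample variance equals `sigma2_g` exactly, naive
#' interaction deviations independent across environments with covariance
#' \eqn{G\sigma^2_{gE}} within each environment, covariate-informed deviations
#' with covariance \eqn{(\Omega \otimes G)\sigma^2_{g\Omega}} where
#' \eqn{\Omega} is the environmental kinship built from `ecs`, and IID normal
#' residuals. Interaction terms are sampled exactly through eigendecompositions
#' of the (desk-scale) G and \eqn{\Omega} kernels.
#'
#' @param markers Dosage matrix from [simulate_nam_genotypes()] (no missing).
#' @param ecs Daily covariate table from [simulate_env_covariates()].
#' @param config The [sim_config()] used to produce both.
#' @return List with `pheno` (long data.frame `genotype, environment, yield`)
#'   and `truth` (class `true_effects`: `mu`, `env_effects`, `genomic_values`,
#'   `ge_values`, `gw_values`, `interaction_values` = their sum,
#'   `marker_effects`, `residuals`).
#' @export
simulate_phenotypes <- function(markers, ecs, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(markers)
  envs <- unique(ecs$environment)
  m <- length(envs)
  if (n != config$n_families * config$family_size || ncol(markers) != config$n_markers) {
    stop("structural error: marker matrix does not match the configuration", call. = FALSE)
  }
  if (m != config$n_environments) {
    stop("structural error: EC table does not match the configuration", call. = FALSE)
  }
  if (anyNA(markers)) stop("structural error: markers must be complete for simulation", call. = FALSE)
  vc <- config$variance_components
  with_seed(derive_seed(config$seed, "phenotypes"), {
    # genomic values from marker effects, rescaled to hit sigma2_g exactly
    g <- numeric(n)
    beta <- numeric(ncol(markers))
    eg <- NULL
    if (vc[["sigma2_g"]] > 0 || vc[["sigma2_gE"]] > 0 || vc[["sigma2_gW"]] > 0) {
      poly <- apply(markers, 2, stats::var) > 0
      if (!any(poly)) stop("structural error: all simulated markers are monomorphic", call. = FALSE)
      Xs <- center_scale(markers[, poly, drop = FALSE])
      if (vc[["sigma2_g"]] > 0) {
        b <- stats::rnorm(ncol(Xs))
        g0 <- drop(Xs %*% b)
        sc <- sqrt(vc[["sigma2_g"]] / stats::var(g0))
        g <- g0 * sc
        beta[poly] <- b * sc
      }
      if (vc[["sigma2_gE"]] > 0 || vc[["sigma2_gW"]] > 0) {
        G <- genomic_relationship(Xs)
        eg <- eigen(G, symmetric = TRUE)
        eg$values <- pmax(eg$values, 0)
      }
    }
    E <- stats::rnorm(m, 0, sqrt(vc[["sigma2_E"]]))
    names(E) <- envs
    gE <- matrix(0, n, m)
    if (vc[["sigma2_gE"]] > 0) {
      Z <- matrix(stats::rnorm(n * m), n, m)
      gE <- sqrt(vc[["sigma2_gE"]]) * (eg$vectors %*% (sqrt(eg$values) * Z))
    }
    gw <- matrix(0, n, m)
    if (vc[["sigma2_gW"]] > 0) {
      Om <- env_kinship(ecs)
      Om <- Om[envs, envs]
      eo <- eigen(Om, symmetric = TRUE)
      eo$values <- pmax(eo$values, 0)
      Z <- matrix(stats::rnorm(n * m), n, m)
      # vec(gw) ~ N(0, (Omega x G) sigma2_gW) through the two factorizations
      gw <- sqrt(vc[["sigma2_gW"]]) *
        (eg$vectors %*% (sqrt(eg$values) * Z) %*% (t(eo$vectors) * sqrt(eo$values)))
    }
    e <- matrix(stats::rnorm(n * m, 0, sqrt(vc[["sigma2_resid"]])), n, m)
    y <- config$mu + matrix(E, n, m, byrow = TRUE) + g + gE + gw + e
    gid <- rownames(markers)
    dimnames(y) <- dimnames(gE) <- dimnames(gw) <- dimnames(e) <- list(gid, envs)
    names(g) <- gid
    pheno <- data.frame(genotype = rep(gid, times = m),
                        environment = rep(envs, each = n),
                        yield = as.vector(y),
                        stringsAsFactors = FALSE)
    truth <- structure(list(mu = config$mu, env_effects = E, genomic_values = g,
                            ge_values = gE, gw_values = gw,
                            interaction_values = gE + gw,
                            marker_effects = beta, residuals = e),
                       class = "true_effects")
    list(pheno = pheno, truth = truth)
  })
}

#' Simulate a complete multi-environment trial
#'
#' Convenience wrapper running the three generators and the kinship builders
#' in one call.
#'
#' @param config A [sim_config()].
#' @return List: `markers`, `ec`, `pheno`, `truth`, `G` (genomic kinship),
#'   `Omega` (environmental kinship), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  markers <- simulate_nam_genotypes(config)
  ec <- simulate_env_covariates(config)
  sim <- simulate_phenotypes(markers, ec, config)
  list(markers = markers, ec = ec, pheno = sim$pheno, truth = sim$truth,
       G = genomic_kinship(markers, max_missing = 1, min_maf = 0),
       Omega = env_kinship(ec), config = config)
}

#' Simulate one replicated single-environment trial
#'
#' The minimal design under which within-environment heritability is
#' identifiable without a kinship: `n_lines` lines with `n_reps` plot
#' replicates each, `y = mu + L_i + e_ir`, line effects and residuals IID
#' normal. Used to study heritability recovery of the variance-component
#' model.
#'
#' @param n_lines,n_reps Design size.
#' @param sigma2_L,sigma2_resid Line and residual variances (yield units^2).
#' @param mu Grand mean.
#' @param environment Environment label stamped on every record.
#' @param seed RNG seed.
#' @return List: `pheno` (long data.frame with repeated genotype rows) and
#'   `truth` (`line_effects`, `H2` = sigma2_L / (sigma2_L + sigma2_resid)).
#' @export
simulate_replicated_env <- function(n_lines = 500L, n_reps = 2L,
                                    sigma2_L = 90000, sigma2_resid = 90000,
                                    mu = 2500, environment = "IA_2013",
                                    seed = 1L) {
  stopifnot(n_lines >= 2, n_reps >= 2, sigma2_L >= 0, sigma2_resid > 0)
  with_seed(seed, {
    L <- stats::rnorm(n_lines, 0, sqrt(sigma2_L))
    ids <- sprintf("L%04d", seq_len(n_lines))
    pheno <- data.frame(
      genotype = rep(ids, each = n_reps),
      environment = environment,
      yield = mu + rep(L, each = n_reps) +
        stats::rnorm(n_lines * n_reps, 0, sqrt(sigma2_resid)),
      stringsAsFactors = FALSE)
    list(pheno = pheno,
         truth = list(line_effects = stats::setNames(L, ids),
                      H2 = sigma2_L / (sigma2_L + sigma2_resid)))
  })
}

#' Mask cells at random to create missing data
#'
#' Masks each cell (marker dosage, or EC value) independently with
#' probability `rate`, re-drawing any column / daily series that would lose
#' all of its values, so every marker column and every
#' (environment, variable) series keeps at least one observation.
#'
#' @param table A dosage matrix or a long EC data.frame with a `value` column.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return Same shape as `table`, with `NA`s injected.
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("configuration error: rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(table)
  with_seed(seed, {
    if (is.matrix(table)) {
      for (j in seq_len(ncol(table))) {
        repeat {
          mask <- stats::runif(nrow(table)) < rate
          if (!all(mask)) break
        }
        table[mask, j] <- NA
      }
      table
    } else if (is.data.frame(table) && "value" %in% names(table)) {
      grp <- interaction(table$environment, table$variable, drop = TRUE)
      for (g in levels(grp)) {
        idx <- which(grp == g)
        repeat {
          mask <- stats::runif(length(idx)) < rate
          if (!all(mask)) break
        }
        table$value[idx[mask]] <- NA
      }
      table
    } else {
      stop("inject_missing: unsupported table type", call. = FALSE)
    }
  })
}
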