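#' Enumerate all non-empty training-environment subsets
#'
#' All `2^m - 1` non-empty subsets of the candidate environments, ordered by
#' size and then lexicographically, so that counts per size follow the
#' binomial coefficients (8 environments give 8, 28, 56, 70, 56, 28, 8, 1).
#'
#' @param envs Character vector of candidate environment labels.
#' @return List of character vectors (each sorted).
#' @export
enumerate_training_subsets <- function(envs) {
  stopifnot(length(envs) >= 1, !anyDuplicated(envs))
  envs <- sort(envs)
  out <- list()
  for (k in seq_along(envs)) {
    cmb <- utils::combn(envs, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Construct a CV00 design
#'
#' CV00 predicts untested genotypes in an untested environment: `n_test`
#' genotypes are drawn as the testing set for the target environment, and a
#' disjoint `n_train` genotypes supply the training phenotypes from the
#' remaining environments. No record from the target environment and no test
#' genotype may enter training.
#'
#' The split is deterministic given `(seed, replicate_id)`; by default the
#' same split is reused across target environments within a replicate (set
#' `resample_per_target = TRUE` to draw a fresh split per target). The child
#' seed follows [derive_seed()].
#'
#' @param pheno Long phenotype table on a complete grid.
#' @param target_env Environment to be treated as unobserved.
#' @param n_test,n_train Testing / training genotype counts (study defaults
#'   200 and 300 out of 500 sampled genotypes).
#' @param replicate_id Replicate number (the study runs 4).
#' @param seed Master seed.
#' @param resample_per_target Include the target label in the seed key.
#' @return Object of class `cv_design`.
#' @export
make_cv00_design <- function(pheno, target_env, n_test = 200L, n_train = 300L,
                             replicate_id = 1L, seed = 1L,
                             resample_per_target = FALSE) {
  genos <- sort(unique(pheno$genotype))
  envs <- unique(pheno$environment)
  if (!target_env %in% envs) stop("unknown target environment: ", target_env, call. = FALSE)
  if (length(genos) < n_test + n_train) {
    stop("insufficient genotypes: need ", n_test + n_train, ", have ",
         length(genos), call. = FALSE)
  }
  key <- if (resample_per_target) target_env else ""
  child <- derive_seed(seed, "cv00-split", replicate_id, key)
  with_seed(child, {
    test <- sort(sample(genos, n_test))
    train <- sort(sample(setdiff(genos, test), n_train))
    structure(list(target_env = target_env,
                   test_genotypes = test, train_genotypes = train,
                   training_envs = sort(setdiff(envs, target_env)),
                   replicate_id = as.integer(replicate_id),
                   seed = as.integer(seed)),
              class = "cv_design")
  })
}

#' Training records for one CV00 cell
#'
#' The exact phenotype records a given training-environment subset
#' contributes: training genotypes crossed with the subset environments.
#' Exposed so that leakage audits can re-derive what entered training.
#'
#' @param design A `cv_design`.
#' @param pheno Long phenotype table.
#' @param subset Character vector of training environments.
#' @return Subset of `pheno` rows.
#' @export
cv00_training_records <- function(design, pheno, subset) {
  stopifnot(inherits(design, "cv_design"))
  if (!all(subset %in% design$training_envs)) {
    stop("subset contains non-candidate environments", call. = FALSE)
  }
  pheno[pheno$genotype %in% design$train_genotypes &
          pheno$environment %in% subset, , drop = FALSE]
}

assert_no_leakage <- function(design, train_records) {
  if (any(train_records$environment == design$target_env)) {
    stop("CV00 leakage: target-environment record in training set", call. = FALSE)
  }
  if (any(train_records$genotype %in% design$test_genotypes)) {
    stop("CV00 leakage: test genotype in training set", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between observed phenotypes and predicted
#' GEBVs; negative accuracies are returned untruncated. A constant vector
#' makes the correlation undefined: `NA` is returned with a warning.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 3).
#' @return Scalar correlation, or `NA` when undefined.
#' @export
accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(observed) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("undefined accuracy: constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' Run the CV00 all-subsets evaluation
#'
#' For every requested model and every training-environment subset, fits the
#' model on the training genotypes' records from the subset environments,
#' predicts the test genotypes in the target environment, and scores the
#' Pearson accuracy against their observed target-environment phenotypes.
#' An automated leakage check (no target-environment record, no test
#' genotype in training) aborts the run on violation.
#'
#' Two fitting modes: `"blup"` (default) holds variance components fixed —
#' either supplied through `vc` or pre-estimated once per model by a Gibbs
#' fit on the full training grid — and solves each subset exactly;
#' `"gibbs"` re-runs the sampler for every subset.
#'
#' @param pheno Long phenotype table on a complete grid.
#' @param G Genomic kinship covering all genotypes.
#' @param Omega Environmental kinship covering all environments (required
#'   when `"M3"` is among the models).
#' @param design A `cv_design` from [make_cv00_design()].
#' @param models Character vector among `"M0"`, `"M1"`, `"M2"`, `"M3"`.
#' @param subsets Optional list of training subsets (defaults to all
#'   non-empty subsets of the candidate environments).
#' @param mode `"blup"` or `"gibbs"`.
#' @param vc Optional named list (per model) of fixed variance vectors for
#'   the BLUP mode; when `NULL` they are pre-estimated by Gibbs.
#' @param chain List of chain settings for Gibbs fits
#'   (`n_iter`, `burn_in`, `thin`).
#' @param seed Master seed for the chains.
#' @return Data.frame of class `cv_result`: one row per
#'   (model, subset) with `replicate_id`, `target_env`, `model_id`,
#'   `training_envs` (";"-joined), `n_training_envs`, `accuracy`,
#'   `runtime_s`.
#' @export
run_cv00 <- function(pheno, G, Omega = NULL, design, models = c("M1", "M2", "M3"),
                     subsets = NULL, mode = c("blup", "gibbs"), vc = NULL,
                     chain = list(n_iter = 3000L, burn_in = 500L, thin = 5L),
                     seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "cv_design"))
  subsets <- subsets %||% enumerate_training_subsets(design$training_envs)
  test_obs <- pheno[pheno$genotype %in% design$test_genotypes &
                      pheno$environment == design$target_env, , drop = FALSE]
  test_obs <- test_obs[order(test_obs$genotype), , drop = FALSE]
  cells <- data.frame(genotype = test_obs$genotype,
                      environment = design$target_env,
                      stringsAsFactors = FALSE)

  fit_one <- function(spec, records, fit_seed, fixed) {
    inc <- build_incidence(records)
    stack <- assemble_kernels(spec, G = G, Omega = Omega, Z_E = inc$Z_E,
                              Z_g = inc$Z_g, response = records$yield,
                              record_index = inc$record_index)
    if (is.null(fixed)) {
      fit_gibbs(stack, n_iter = chain$n_iter, burn_in = chain$burn_in,
                thin = chain$thin, seed = fit_seed)
    } else {
      fit_blup(stack, fixed)
    }
  }

  # pre-estimate variance components once per model on the full training grid
  if (mode == "blup" && is.null(vc)) {
    vc <- list()
    full_train <- cv00_training_records(design, pheno, design$training_envs)
    assert_no_leakage(design, full_train)
    for (mid in models) {
      spec <- model_spec(mid)
      f <- fit_one(spec, full_train, derive_seed(seed, "vc", mid), NULL)
      vc[[mid]] <- stats::setNames(f$vc$post_mean, f$vc$term)
    }
  }

  rows <- vector("list", length(models) * length(subsets))
  r <- 0L
  for (mid in models) {
    spec <- model_spec(mid)
    for (si in seq_along(subsets)) {
      sub <- subsets[[si]]
      t0 <- proc.time()[["elapsed"]]
      train <- cv00_training_records(design, pheno, sub)
      assert_no_leakage(design, train)
      records <- rbind(train,
                       data.frame(genotype = cells$genotype,
                                  environment = cells$environment,
                                  yield = NA_real_, stringsAsFactors = FALSE))
      fixed <- if (mode == "blup") vc[[mid]] else NULL
      fit <- fit_one(spec, records, derive_seed(seed, "cv00-fit", mid, si), fixed)
      pred <- predict_gebv(fit, cells)
      acc <- withCallingHandlers(
        accuracy(test_obs$yield, pred$predicted),
        warning = function(w) invokeRestart("muffleWarning"))
      r <- r + 1L
      rows[[r]] <- data.frame(replicate_id = design$replicate_id,
                              target_env = design$target_env,
                              model_id = mid,
                              training_envs = paste(sub, collapse = ";"),
                              n_training_envs = length(sub),
                              accuracy = acc,
                              runtime_s = proc.time()[["elapsed"]] - t0,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "vc") <- vc
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Summarize a CV00 sweep
#'
#' Per (replicate, target environment, model): the best accuracy over all
#' training subsets, the subset achieving it and its size, the all-environment
#' baseline accuracy, and the relative improvement
#' `100 * (best - baseline) / baseline` (flagged undefined when the baseline
#' is not positive). Also returns the per-size maxima used for
#' accuracy-versus-subset-size curves.
#'
#' @param results A `cv_result` (must include the full-subset row per model).
#' @return List of two data.frames: `summary` and `by_size`.
#' @export
summarize_cv00 <- function(results) {
  stopifnot(all(c("replicate_id", "target_env", "model_id", "training_envs",
                  "n_training_envs", "accuracy") %in% names(results)))
  key <- interaction(results$replicate_id, results$target_env,
                     results$model_id, drop = TRUE)
  m_max <- max(results$n_training_envs)
  summ <- lapply(split(results, key), function(d) {
    base_row <- d[d$n_training_envs == m_max, , drop = FALSE]
    if (nrow(base_row) != 1) {
      stop("results must contain exactly one full-subset (all environments) row ",
           "per (replicate, target, model)", call. = FALSE)
    }
    ok <- !is.na(d$accuracy)
    if (!any(ok)) stop("all accuracies undefined for a group", call. = FALSE)
    ib <- which.max(ifelse(ok, d$accuracy, -Inf))
    baseline <- base_row$accuracy
    data.frame(replicate_id = d$replicate_id[1], target_env = d$target_env[1],
               model_id = d$model_id[1],
               best_accuracy = d$accuracy[ib],
               best_subset = d$training_envs[ib],
               best_size = d$n_training_envs[ib],
               baseline_accuracy = baseline,
               rel_improvement_pct = if (!is.na(baseline) && baseline > 0) {
                 100 * (d$accuracy[ib] - baseline) / baseline
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  by_size <- lapply(split(results, key), function(d) {
    agg <- stats::aggregate(accuracy ~ n_training_envs, data = d,
                            FUN = function(a) suppressWarnings(max(a, na.rm = TRUE)))
    data.frame(replicate_id = d$replicate_id[1], target_env = d$target_env[1],
               model_id = d$model_id[1], n_training_envs = agg$n_training_envs,
               max_accuracy = agg$accuracy, stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       by_size = do.call(rbind, c(by_size, list(make.row.names = FALSE))))
}
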