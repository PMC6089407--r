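# Bootstrap confidence procedures: resample the replicate mesocosms with
# replacement, refit, and summarize.  All resample index sets are drawn up
# front from the master seed, so results do not depend on evaluation order.

bootstrap_indices <- function(n, B, seed) {
  if (is.null(seed)) stop("a seed is mandatory for bootstrap procedures",
                          call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
}

# Refits inside bootstrap resamples start from the full-data estimates
# (single start): the resampled likelihood surface is a perturbation of the
# original, so the original optimum is the natural warm start.
refit <- function(model, data, init) {
  tryCatch(fit_model(model, data, init = init, n_starts = 1),
           error = function(e) NULL)
}

#' Bootstrap 95% confidence set of models
#'
#' Resamples the replicates with replacement `B` times; in each resample all
#' candidate models are refitted and the focal model's delta-AICc relative
#' to the resample's best model is recorded.  The 95th percentile of that
#' distribution is the delta-AICc limit: models whose actual-data delta-AICc
#' does not exceed it form the 95% confidence set.
#'
#' @inheritParams select_models
#' @param B Number of bootstrap resamples (>= 1).
#' @param focal_model Model id whose delta-AICc distribution defines the
#'   limit; defaults to the best model on the actual data.
#' @param seed Master seed (mandatory).
#' @param level Confidence level for the delta-AICc limit (default 0.95).
#'
#' @return List with `limit` (the delta-AICc cut-off), `confidence_set`
#'   (model ids within the limit on the actual data), `delta_focal` (the
#'   bootstrap distribution), `actual` (the actual-data selection), and
#'   `n_failed` (resamples dropped because every fit failed).
#' @export
bootstrap_confidence_set <- function(data, models = candidate_models(),
                                     B = 1000, focal_model = NULL,
                                     seed = NULL, level = 0.95,
                                     n_starts = 5) {
  stopifnot(B >= 1)
  actual <- select_models(data, models, n_starts = n_starts, seed = seed)
  if (is.null(focal_model)) focal_model <- actual$table$model[1]
  if (!focal_model %in% actual$table$model) {
    stop("focal model '", focal_model, "' was not fitted on the actual data",
         call. = FALSE)
  }
  inits <- lapply(actual$fits, function(f) as.list(f$estimates))
  idx <- bootstrap_indices(nrow(data), B, seed)
  delta_focal <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    d <- data[idx[b, ], , drop = FALSE]
    aiccs <- vapply(models, function(m) {
      f <- refit(m, d, inits[[m$id]])
      if (is.null(f) || !f$converged || !is.finite(f$aicc)) NA_real_ else f$aicc
    }, numeric(1))
    names(aiccs) <- vapply(models, `[[`, "", "id")
    if (all(is.na(aiccs)) || is.na(aiccs[[focal_model]])) next
    delta_focal[b] <- aiccs[[focal_model]] - min(aiccs, na.rm = TRUE)
  }
  n_failed <- sum(is.na(delta_focal))
  if (n_failed > 0.01 * B) {
    warning(n_failed, " of ", B, " bootstrap resamples dropped ",
            "(fit failures)", call. = FALSE)
  }
  dist <- delta_focal[!is.na(delta_focal)]
  limit <- unname(stats::quantile(dist, level))
  set <- actual$table$model[actual$table$delta_aicc <= limit]
  list(limit = limit, confidence_set = set, delta_focal = dist,
       actual = actual, focal_model = focal_model, n_failed = n_failed)
}

#' Bootstrap percentile confidence intervals for model parameters
#'
#' Resamples the replicates with replacement `B` times, refits the given
#' model, and returns percentile intervals of each free parameter across
#' resamples.
#'
#' @inheritParams bootstrap_confidence_set
#' @param model One element of [candidate_models()].
#' @param level Interval coverage (default 0.95).
#'
#' @return List with `ci` (matrix: one row per parameter, columns `lower`
#'   and `upper`), `estimates` (actual-data estimates), `samples` (matrix of
#'   resample estimates), and `n_failed`.
#' @export
bootstrap_param_ci <- function(data, model, B = 1000, level = 0.95,
                               seed = NULL, n_starts = 5) {
  stopifnot(B >= 1)
  fit0 <- fit_model(model, data, n_starts = n_starts, seed = seed)
  init <- as.list(fit0$estimates)
  idx <- bootstrap_indices(nrow(data), B, seed)
  samples <- matrix(NA_real_, nrow = B, ncol = length(fit0$estimates),
                    dimnames = list(NULL, names(fit0$estimates)))
  for (b in seq_len(B)) {
    f <- refit(model, data[idx[b, ], , drop = FALSE], init)
    if (!is.null(f) && f$converged) samples[b, ] <- f$estimates
  }
  ok <- stats::complete.cases(samples)
  n_failed <- sum(!ok)
  if (n_failed > 0.01 * B) {
    warning(n_failed, " of ", B, " bootstrap resamples dropped ",
            "(fit failures)", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(samples[ok, , drop = FALSE], 2, stats::quantile,
                probs = probs, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = fit0$estimates,
       samples = samples[ok, , drop = FALSE], n_failed = n_failed)
}
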