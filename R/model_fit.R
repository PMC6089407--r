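# Beta-binomial likelihood of offspring ploidy counts given parental
# frequencies, maximum-likelihood fitting of candidate cost-of-sex models,
# and small-sample AIC model selection.
#
# Each replicate contributes P(k | n, q_hat, theta) where
# q_hat = next_frequency(q_t, c(year)) and the beta-binomial is
# mean-parameterized: alpha = q*theta, beta = (1-q)*theta, so the mean is q
# and extra-binomial variance grows as theta shrinks (theta -> Inf recovers
# the binomial).

# q exactly 0 or 1 (boundary q_t) would zero out the likelihood; epsilon
# truncation keeps degenerate replicates finite without discarding them.
.q_eps <- 1e-9

#' Beta-binomial probability mass
#'
#' Mean/dispersion parameterization: `x` successes in `size` trials with
#' success probability drawn from Beta(`prob * theta`, `(1 - prob) * theta`),
#' so the marginal mean is `prob` and smaller `theta` means more
#' overdispersion.  Computed on the log scale via `lbeta`/`lchoose`; stable
#' for `size` up to at least 1e4.
#'
#' @param x Number of successes (vectorized).
#' @param size Number of trials.
#' @param prob Mean success probability, strictly inside (0, 1).
#' @param theta Dispersion parameter (> 0); `theta -> Inf` converges to
#'   `dbinom(x, size, prob)`.
#' @param log Return the log-probability?
#'
#' @return Numeric vector of (log-)probabilities.
#'
#' @examples
#' dbetabinom(3, 10, 0.4, theta = 7)
#' dbetabinom(1, 1, 0.3, theta = 5)   # single trial: just the mean, 0.3
#' @export
dbetabinom <- function(x, size, prob, theta, log = FALSE) {
  if (any(prob <= 0 | prob >= 1)) {
    stop("prob must be strictly inside (0, 1); truncate boundary means ",
         "upstream", call. = FALSE)
  }
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  if (any(x < 0 | x > size)) stop("x must lie in 0..size", call. = FALSE)
  a <- prob * theta
  b <- (1 - prob) * theta
  lp <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

# Candidate cost models ----------------------------------------------------

#' Candidate cost-of-sex models
#'
#' The four models fitted to paired parent/offspring frequencies, all of the
#' form q_t1 = c q_t / (1 + q_t (c - 1)) with a shared beta-binomial
#' dispersion theta:
#' \describe{
#'   \item{`no_cost`}{c fixed at 1 (free: theta).}
#'   \item{`two_fold`}{c fixed at 2 (free: theta).}
#'   \item{`mle`}{c free (free: theta, c).}
#'   \item{`mle_by_year`}{c varies by year as a baseline cost `c0` for the
#'     first year plus a deviation `d_j` per later year
#'     (free: theta, c0, and one deviation per non-baseline year).}
#' }
#'
#' @param ids Character vector selecting a subset of the four models.
#' @return Named list of model definitions, each with elements `id` and
#'   `cost_fun(cost_pars, year_index)`.
#' @export
candidate_models <- function(ids = c("no_cost", "two_fold", "mle", "mle_by_year")) {
  all <- list(
    no_cost = list(id = "no_cost",
                   cost_fun = function(cp, yi) rep(1, length(yi))),
    two_fold = list(id = "two_fold",
                    cost_fun = function(cp, yi) rep(2, length(yi))),
    mle = list(id = "mle",
               cost_fun = function(cp, yi) rep(cp[["c"]], length(yi))),
    mle_by_year = list(id = "mle_by_year",
                       cost_fun = function(cp, yi) {
                         c0 <- cp[["c0"]]
                         d <- c(0, cp[names(cp) != "c0"])
                         c0 + d[yi]
                       })
  )
  bad <- setdiff(ids, names(all))
  if (length(bad) > 0) {
    stop("unknown model id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  all[ids]
}

# Free-parameter names for a model given the years present in the data.
model_par_names <- function(model, years) {
  switch(model$id,
    no_cost = "theta",
    two_fold = "theta",
    mle = c("theta", "c"),
    mle_by_year = c("theta", "c0",
                    if (length(years) > 1) paste0("d", seq_along(years)[-1]))
  )
}

# Year levels in first-appearance order; baseline is the first.
year_levels <- function(data) unique(data$year)

#' Negative log-likelihood of a candidate model
#'
#' Minus the summed beta-binomial log-probability of the observed offspring
#' triploid counts, with the mean for each replicate given by
#' [next_frequency()] applied to its parental frequency and the model's
#' cost for its year.  Means at exactly 0 or 1 are truncated to
#' `[1e-9, 1 - 1e-9]`.  A parameter vector implying a non-positive cost for
#' any year present yields `+Inf` (optimizer-safe penalty).
#'
#' @param model One element of [candidate_models()].
#' @param params Named numeric vector on the natural scale: `theta` plus
#'   the model's cost parameters (`c`; or `c0` and deviations `d2`, ...).
#' @param data Paired-frequency `data.frame` from [paired_frequencies()]
#'   (columns `q_t`, `offspring_k`, `offspring_n`, `year`).
#'
#' @return Scalar negative log-likelihood (0 for empty data).
#' @export
neg_loglik <- function(model, params, data) {
  if (nrow(data) == 0) return(0)
  theta <- params[["theta"]]
  if (!is.finite(theta) || theta <= 0) return(Inf)
  yl <- year_levels(data)
  yi <- match(data$year, yl)
  cost <- model$cost_fun(params[setdiff(names(params), "theta")], yi)
  if (any(!is.finite(cost)) || any(cost <= 0)) return(Inf)
  q_hat <- next_frequency(data$q_t, cost)
  q_hat <- pmin(pmax(q_hat, .q_eps), 1 - .q_eps)
  -sum(dbetabinom(data$offspring_k, data$offspring_n, q_hat, theta, log = TRUE))
}

# Transform between the optimizer scale and the natural scale.
# theta and c/c0 are optimized on the log scale to enforce positivity;
# year deviations stay on the natural scale (validity is enforced by the
# +Inf penalty in neg_loglik).
to_natural <- function(model, x, par_names) {
  out <- x
  names(out) <- par_names
  out["theta"] <- exp(x[1])
  if (model$id == "mle") out["c"] <- exp(x[2])
  if (model$id == "mle_by_year") out["c0"] <- exp(x[2])
  out
}

to_optim_scale <- function(model, params) {
  x <- params
  x[["theta"]] <- log(params[["theta"]])
  if (model$id == "mle") x[["c"]] <- log(params[["c"]])
  if (model$id == "mle_by_year") x[["c0"]] <- log(params[["c0"]])
  unname(unlist(x))
}

#' Fit one candidate model by maximum likelihood
#'
#' Minimizes [neg_loglik()] over the model's free parameters, with theta and
#' the baseline cost log-transformed for positivity.  One-parameter models
#' are profiled with golden-section search; multi-parameter models use
#' Nelder-Mead followed by a BFGS polish, with `n_starts` jittered starting
#' points (default 5) to guard against local optima; the best optimum wins.
#'
#' @inheritParams neg_loglik
#' @param data Paired-frequency `data.frame`.
#' @param init Optional named starting values on the natural scale.
#' @param n_starts Number of jittered starts (>= 1).
#' @param seed Optional seed for the start jitter (deterministic fits for a
#'   given seed).
#'
#' @return An object of class `sexcost_fit`: list with `model_id`,
#'   `estimates` (named, natural scale), `logL`, `k` (number of free
#'   parameters), `n` (replicates), `aicc`, `converged`, and `message`.
#' @export
fit_model <- function(model, data, init = NULL, n_starts = 5, seed = NULL) {
  yl <- year_levels(data)
  par_names <- model_par_names(model, yl)
  k <- length(par_names)
  if (nrow(data) < k) {
    stop("need at least ", k, " replicates to fit model '", model$id, "'",
         call. = FALSE)
  }
  default_init <- c(theta = 20, c = 1.5, c0 = 1.5)
  init_nat <- sapply(par_names, function(p) {
    if (!is.null(init) && p %in% names(init)) init[[p]]
    else if (p %in% names(default_init)) default_init[[p]]
    else 0  # year deviations
  })
  x0 <- to_optim_scale(model, as.list(init_nat))

  obj <- function(x) {
    v <- neg_loglik(model, to_natural(model, x, par_names), data)
    if (!is.finite(v)) 1e10 else v
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    xs <- if (s == 1) x0 else x0 + stats::rnorm(length(x0), sd = 0.5)
    res <- if (length(xs) == 1) {
      o <- stats::optimize(function(z) obj(z), interval = xs + c(-12, 12),
                           tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0)
    } else {
      nm <- stats::optim(xs, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-10))
      bf <- tryCatch(
        stats::optim(nm$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) nm)
      if (bf$value <= nm$value) bf else nm
    }
    if (is.null(best) || res$value < best$value) best <- res
  }

  est <- to_natural(model, best$par, par_names)
  converged <- best$convergence == 0 && is.finite(best$value) &&
    best$value < 1e9
  logL <- -best$value
  structure(list(
    model_id = model$id,
    estimates = est,
    logL = logL,
    k = k,
    n = nrow(data),
    aicc = if (nrow(data) > k + 1) aicc(logL, k, nrow(data)) else NA_real_,
    converged = converged,
    message = if (converged) "ok" else "optimizer did not converge"
  ), class = "sexcost_fit")
}

#' @export
print.sexcost_fit <- function(x, ...) {
  cat("Model '", x$model_id, "': logL = ", format(x$logL, digits = 6),
      ", k = ", x$k, ", AICc = ", format(x$aicc, digits = 6), "\n", sep = "")
  print(round(x$estimates, 4))
  if (!x$converged) cat("WARNING:", x$message, "\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1), with n the number of
#' replicates (mesocosms), not the number of individuals genotyped.
#'
#' @param logL Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (replicates); must exceed `k + 1`.
#' @return Scalar AICc.
#' @examples
#' aicc(-86.27, 1, 24)
#' @export
aicc <- function(logL, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2): normalized evidence,
#' interpretable as the probability each model is the best of the set.
#' Invariant to adding a constant to all AICc values.
#'
#' @param delta_aicc Numeric vector of AICc differences (all >= 0, at least
#'   one 0 when measured from the best model).
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(29.01, 0, 1.98, 8.93))
#' @export
akaike_weights <- function(delta_aicc) {
  if (length(delta_aicc) == 0) stop("no AICc differences given", call. = FALSE)
  w <- exp(-delta_aicc / 2)
  w / sum(w)
}

#' Fit and rank the candidate models
#'
#' Fits every model on the same data, ranks by AICc, and attaches delta-AICc
#' and Akaike weights.  Models whose fit fails are excluded with a warning.
#'
#' @inheritParams fit_model
#' @param models List of model definitions (default all four of
#'   [candidate_models()]).
#'
#' @return An object of class `sexcost_selection`: list with `table` (a
#'   `data.frame` with columns `model`, `logL`, `k`, `aicc`, `delta_aicc`,
#'   `weight`, sorted by AICc) and `fits` (the named `sexcost_fit` objects).
#'   Printing mirrors the conventional model-selection table.
#' @examples
#' dat <- paired_frequencies(paper_like_dataset(seed = 1))
#' select_models(dat, n_starts = 2, seed = 1)
#' @export
select_models <- function(data, models = candidate_models(), init = NULL,
                          n_starts = 5, seed = NULL) {
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_model(m, data, init = init[[m$id]],
                            n_starts = n_starts, seed = seed),
                  error = function(e) e)
    if (inherits(f, "error") || !f$converged) {
      warning("model '", m$id, "' excluded: ",
              if (inherits(f, "error")) conditionMessage(f) else f$message,
              call. = FALSE)
    } else {
      fits[[m$id]] <- f
    }
  }
  if (length(fits) == 0) stop("all model fits failed", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model_id"),
    logL = vapply(fits, `[[`, 0, "logL"),
    k = vapply(fits, `[[`, 0L, "k"),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    row.names = NULL
  )
  tab <- tab[order(tab$aicc), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$weight <- akaike_weights(tab$delta_aicc)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "sexcost_selection")
}

#' @export
print.sexcost_selection <- function(x, digits = 3, ...) {
  cat("Model selection over", nrow(x$table), "candidate cost-of-sex models\n")
  tab <- x$table
  tab$logL <- round(tab$logL, 2)
  tab$aicc <- round(tab$aicc, 2)
  tab$delta_aicc <- round(tab$delta_aicc, 2)
  tab$weight <- round(tab$weight, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize fit results to JSON
#'
#' @param x A `sexcost_fit` or `sexcost_selection` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  obj <- if (inherits(x, "sexcost_selection")) {
    list(table = x$table,
         estimates = lapply(x$fits, function(f) as.list(f$estimates)))
  } else {
    list(model_id = x$model_id, estimates = as.list(x$estimates),
         logL = x$logL, k = x$k, n = x$n, aicc = x$aicc,
         converged = x$converged)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
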