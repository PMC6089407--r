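# Beta-binomial likelihood, MLE fitting, and information-criterion arithmetic.

test_that("beta-binomial pmf matches an independent integration oracle", {
  # oracle: marginalize the binomial over its Beta prior by quadrature
  bb_oracle <- function(k, n, q, th) {
    stats::integrate(function(p) stats::dbinom(k, n, p) *
                       stats::dbeta(p, q * th, (1 - q) * th),
                     0, 1, rel.tol = 1e-12)$value
  }
  # frozen from the oracle: log P(3 | 10, q = 0.4, theta = 7)
  expect_equal(dbetabinom(3, 10, 0.4, 7, log = TRUE), -1.843781921896,
               tolerance = 1e-9)
  for (case in list(c(0, 5, 0.2, 3), c(12, 20, 0.7, 0.8), c(5, 40, 0.1, 50))) {
    expect_equal(dbetabinom(case[1], case[2], case[3], case[4]),
                 bb_oracle(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-8)
  }
  # single trial: probability is just the mean
  expect_equal(dbetabinom(1, 1, 0.3, 5, log = TRUE), log(0.3))
  expect_equal(dbetabinom(0, 1, 0.3, 5), 0.7)
})

test_that("beta-binomial pmf normalizes and converges to the binomial", {
  for (n in c(1, 7, 50, 200)) {
    for (q in c(0.01, 0.3, 0.99)) {
      for (th in c(0.5, 5, 40, 1000)) {
        expect_equal(sum(dbetabinom(0:n, n, q, th)), 1, tolerance = 1e-10)
      }
    }
  }
  k <- 0:60
  expect_equal(dbetabinom(k, 60, 0.37, 1e8), stats::dbinom(k, 60, 0.37),
               tolerance = 1e-4)
  expect_error(dbetabinom(3, 10, 0, 5), "inside")
  expect_error(dbetabinom(3, 10, 1, 5), "inside")
  expect_error(dbetabinom(3, 10, 0.5, -1), "positive")
  expect_error(dbetabinom(11, 10, 0.5, 5), "0..size")
})

test_that("neg_loglik composes the recursion with the pmf", {
  two_fold <- candidate_models("two_fold")[[1]]
  one <- data.frame(year = 2012, mesocosm_id = 1, q_t = 0.3,
                    offspring_k = 30, offspring_n = 70)
  expect_equal(
    neg_loglik(two_fold, c(theta = 12), one),
    -dbetabinom(30, 70, next_frequency(0.3, 2), 12, log = TRUE)
  )
  expect_equal(neg_loglik(two_fold, c(theta = 12), one[0, ]), 0)
  # invalid costs are an optimizer-safe penalty, not an error
  by_year <- candidate_models("mle_by_year")[[1]]
  dat <- make_paired(seed = 2)
  expect_equal(
    neg_loglik(by_year, c(theta = 10, c0 = 1, d2 = -1.5, d3 = 0, d4 = 0), dat),
    Inf
  )
  expect_equal(neg_loglik(two_fold, c(theta = -1), dat), Inf)
})

test_that("MLE recovers the generating cost from noise-free data", {
  mle <- candidate_models("mle")[[1]]
  fit <- fit_model(mle, noiseless_paired(c_true = 2), seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["c"]], 2, tolerance = 1e-2)

  fit15 <- fit_model(mle, noiseless_paired(c_true = 1.5), seed = 1)
  expect_equal(fit15$estimates[["c"]], 1.5, tolerance = 1e-2)
})

test_that("nesting: freeing parameters never lowers the maximized likelihood", {
  dat <- make_paired(seed = 4)
  models <- candidate_models()
  fits <- lapply(models, fit_model, data = dat, seed = 1)
  expect_gte(fits$mle$logL, fits$two_fold$logL - 1e-6)
  expect_gte(fits$mle$logL, fits$no_cost$logL - 1e-6)
  expect_gte(fits$mle_by_year$logL, fits$mle$logL - 1e-6)
  # under no-cost data the free-cost model gains almost nothing
  null_dat <- paired_frequencies(
    generate_experiment(synthetic_config(true_c = 1, seed = 5))$records
  )
  f_mle <- fit_model(models$mle, null_dat, seed = 1)
  f_null <- fit_model(models$no_cost, null_dat, seed = 1)
  expect_equal(f_mle$estimates[["c"]], 1, tolerance = 0.15)
  expect_lt(f_mle$logL - f_null$logL, 1)
})

test_that("AICc arithmetic matches the published-scale formula", {
  expect_equal(aicc(-86.27, 1, 24), -2 * -86.27 + 2 + 4 / 22)
  # printed-table arithmetic at n = 24 replicates
  expect_equal(round(aicc(-100.78, 1, 24), 2), 203.74)
  expect_equal(round(aicc(-86.07, 2, 24), 2), 176.71)
  expect_equal(round(aicc(-85.16, 5, 24), 2), 183.65)
  # large-n limit is plain AIC
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6), "n > k")
})

test_that("Akaike weights normalize and ignore constant shifts", {
  w <- akaike_weights(c(29.01, 0, 1.98, 8.93))
  expect_equal(sum(w), 1)
  expect_equal(round(w, 2), c(0.00, 0.72, 0.27, 0.01))
  expect_equal(akaike_weights(0), 1)
  expect_equal(akaike_weights(c(3, 3)), c(0.5, 0.5))
  d <- c(0, 1.5, 9)
  expect_equal(akaike_weights(d), akaike_weights(d + 100))
  expect_error(akaike_weights(numeric(0)), "no AICc")
})

test_that("select_models ranks by AICc with weights summing to one", {
  dat <- make_paired(seed = 1)
  sel <- select_models(dat, n_starts = 2, seed = 1)
  expect_s3_class(sel, "sexcost_selection")
  expect_equal(nrow(sel$table), 4)
  expect_true(!is.unsorted(sel$table$aicc))
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_equal(sum(sel$table$weight), 1)
  expect_equal(sel$table$k[match(c("no_cost", "two_fold", "mle", "mle_by_year"),
                                 sel$table$model)],
               c(1L, 1L, 2L, 5L))
  # restricting the candidate set restricts the table
  sel2 <- select_models(dat, candidate_models(c("two_fold", "mle")),
                        n_starts = 2, seed = 1)
  expect_equal(sort(sel2$table$model), c("mle", "two_fold"))
  # serialization smoke
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(sel, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})

test_that("degenerate duplicated data collapse the bootstrap distributions", {
  dat <- make_paired(seed = 6)
  dup <- dat[rep(3, 24), ]
  dup$mesocosm_id <- seq_len(24)
  mle <- candidate_models("mle")[[1]]
  ci <- bootstrap_param_ci(dup, mle, B = 20, seed = 11, n_starts = 2)
  expect_lt(diff(ci$ci["c", ]), 1e-4)
  # every resample is identical, so the focal delta-AICc is constant and
  # the limit equals the actual-data delta
  cs <- bootstrap_confidence_set(dup, candidate_models(c("two_fold", "mle")),
                                 B = 10, seed = 11, n_starts = 2)
  actual_delta <- cs$actual$table$delta_aicc[
    cs$actual$table$model == cs$focal_model]
  expect_equal(cs$limit, actual_delta, tolerance = 1e-6)
  expect_true(cs$focal_model %in% cs$confidence_set)
})

test_that("bootstrap procedures are reproducible and seed-mandatory", {
  dat <- make_paired(seed = 8)
  mle <- candidate_models("mle")[[1]]
  a <- bootstrap_param_ci(dat, mle, B = 15, seed = 42, n_starts = 1)
  b <- bootstrap_param_ci(dat, mle, B = 15, seed = 42, n_starts = 1)
  expect_identical(a$ci, b$ci)
  expect_error(bootstrap_param_ci(dat, mle, B = 15), "seed")
  expect_error(bootstrap_confidence_set(dat, B = 5), "seed")
})
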