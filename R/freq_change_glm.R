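# Binomial logistic test of asexual-frequency change from parent to
# offspring generation, with likelihood-ratio tests per effect and the
# odds-ratio to fold-increase conversion.
#
# The response is (triploid, diploid) counts per replicate-generation;
# predictors are generation (reference: parent), year (reference: first
# level), and optionally their interaction.  IRLS is delegated to
# stats::glm; the LRTs, odds-ratio extraction and fold conversion live here.

#' Long-format count table for the logistic model
#'
#' Expands raw mesocosm records into one row per replicate-generation with
#' integer triploid/diploid counts: infected individuals are excluded and
#' males imputed internally.  Parental diploid counts include the imputed
#' males; since the imputed count is fractional, it is rounded half-to-even
#' for the GLM table (the exact fractional ratio is what the likelihood
#' route uses).
#'
#' @param records Raw mesocosm records.
#' @return A `data.frame` with columns `year` (factor, reference = first
#'   level), `mesocosm_id`, `generation` (factor, reference `"parent"`),
#'   `triploid`, `diploid`.
#' @export
paired_glm_data <- function(records) {
  records <- exclude_infected(records)
  keep <- records$dissected_females > 0 &
    records$parent_flow_triploid + records$parent_flow_diploid > 0 &
    records$offspring_flow_triploid + records$offspring_flow_diploid > 0
  if (!all(keep)) {
    warning(sum(!keep), " degenerate replicate(s) dropped", call. = FALSE)
    records <- records[keep, , drop = FALSE]
  }
  m_hat <- impute_males(
    records$parent_flow_triploid + records$parent_flow_diploid,
    records$dissected_males, records$dissected_females
  )
  parent <- data.frame(
    year = records$year, mesocosm_id = records$mesocosm_id,
    generation = "parent",
    triploid = records$parent_flow_triploid,
    diploid = round(records$parent_flow_diploid + m_hat)
  )
  offspring <- data.frame(
    year = records$year, mesocosm_id = records$mesocosm_id,
    generation = "offspring",
    triploid = records$offspring_flow_triploid,
    diploid = records$offspring_flow_diploid
  )
  out <- rbind(parent, offspring)
  out$generation <- factor(out$generation, levels = c("parent", "offspring"))
  out$year <- factor(out$year)
  out
}

#' Binomial logistic model of triploid frequency
#'
#' Fits `cbind(triploid, diploid) ~ generation [+ year [+ interaction]]`
#' with a logit link.  Complete separation (a fitted cell driving a
#' coefficient towards infinity) is flagged in the `separation` element.
#'
#' @param data Long-format counts from [paired_glm_data()].
#' @param year Include the year main effect?
#' @param interaction Include the generation-by-year interaction (implies
#'   `year`)?
#'
#' @return A `glm` object with extra fields `separation` (logical flag) and
#'   class `sexcost_glm` prepended.
#' @export
fit_logistic <- function(data, year = TRUE, interaction = FALSE) {
  if (length(unique(data$generation)) < 2) {
    stop("need both parent and offspring generations", call. = FALSE)
  }
  rhs <- if (interaction) "generation * year"
         else if (year && length(unique(data$year)) > 1) "generation + year"
         else "generation"
  fit <- stats::glm(stats::as.formula(paste("cbind(triploid, diploid) ~", rhs)),
                    family = stats::binomial(link = "logit"), data = data)
  fit$separation <- !fit$converged || any(abs(stats::coef(fit)) > 10)
  if (fit$separation) {
    warning("possible complete separation: coefficient(s) diverging",
            call. = FALSE)
  }
  class(fit) <- c("sexcost_glm", class(fit))
  fit
}

#' Likelihood-ratio test of nested binomial GLMs
#'
#' D = deviance(reduced) - deviance(full), chi-squared with df equal to the
#' difference in estimated parameters.
#'
#' @param full,reduced Fitted `glm` objects, `reduced` nested in `full`.
#' @return List with `D`, `df`, and `p`.
#' @export
lrt <- function(full, reduced) {
  D <- reduced$deviance - full$deviance
  df <- reduced$df.residual - full$df.residual
  if (df < 0) stop("models are not nested: reduced has more parameters",
                   call. = FALSE)
  if (df == 0 && abs(D) < 1e-8) {
    return(list(D = 0, df = 0, p = 1))
  }
  if (df == 0) stop("models are not nested (same df, different deviance)",
                    call. = FALSE)
  list(D = D, df = df, p = stats::pchisq(D, df, lower.tail = FALSE))
}

#' Likelihood-ratio tests for generation, year, and their interaction
#'
#' Reproduces the conventional sequence: the interaction is tested against
#' the additive model, and each main effect against the additive model with
#' that effect removed.
#'
#' @param data Long-format counts from [paired_glm_data()].
#' @return A `data.frame` with one row per effect and columns `effect`,
#'   `D`, `df`, `p`.
#' @export
test_effects <- function(data) {
  multi_year <- length(unique(data$year)) > 1
  additive <- fit_logistic(data, year = multi_year, interaction = FALSE)
  out <- list()
  if (multi_year) {
    inter <- fit_logistic(data, interaction = TRUE)
    t_int <- lrt(inter, additive)
    out$interaction <- data.frame(effect = "generation:year",
                                  D = t_int$D, df = t_int$df, p = t_int$p)
    no_year <- fit_logistic(data, year = FALSE)
    t_year <- lrt(additive, no_year)
    out$year <- data.frame(effect = "year", D = t_year$D, df = t_year$df,
                           p = t_year$p)
    no_gen <- stats::glm(cbind(triploid, diploid) ~ year,
                         family = stats::binomial, data = data)
  } else {
    no_gen <- stats::glm(cbind(triploid, diploid) ~ 1,
                         family = stats::binomial, data = data)
  }
  t_gen <- lrt(additive, no_gen)
  out$generation <- data.frame(effect = "generation", D = t_gen$D,
                               df = t_gen$df, p = t_gen$p)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Odds ratios with confidence intervals from a logistic fit
#'
#' Exponentiated coefficients with profile-likelihood intervals (the
#' default) or Wald intervals as a fallback (with a warning).
#'
#' @param fit A fitted `sexcost_glm` / `glm` object.
#' @param level Confidence level.
#' @param method `"profile"` (default) or `"wald"`.
#' @return A `data.frame` with columns `term`, `or`, `lower`, `upper`.
#' @export
odds_ratios <- function(fit, level = 0.95, method = c("profile", "wald")) {
  method <- match.arg(method)
  est <- stats::coef(fit)
  if (method == "profile") {
    requireNamespace("MASS", quietly = TRUE)  # registers confint.glm
    ci <- suppressMessages(stats::confint(fit, level = level))
  } else {
    warning("using Wald intervals; profile-likelihood intervals are the ",
            "default and preferred", call. = FALSE)
    se <- sqrt(diag(stats::vcov(fit)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- cbind(est - z * se, est + z * se)
  }
  data.frame(term = names(est), or = exp(est),
             lower = exp(ci[, 1]), upper = exp(ci[, 2]),
             row.names = NULL)
}

#' Convert an odds ratio to a fold increase at a baseline proportion
#'
#' An odds ratio `or_value` applied to baseline proportion `p0` implies new
#' odds `or_value * p0 / (1 - p0)` and hence a proportion-scale fold
#' increase of `[odds1 / (1 + odds1)] / p0`.  As `p0 -> 0` the fold change
#' tends to the odds ratio itself.  A confidence interval for the odds
#' ratio transforms endpoint-wise.
#'
#' @param p0 Baseline proportion, strictly inside (0, 1).
#' @param or_value Odds ratio (> 0); vectorized, so CI endpoints can be
#'   passed directly.
#' @return Fold increase(s) on the proportion scale.
#' @examples
#' fold_change_from_or(0.29, 2.119)  # about 1.60
#' @export
fold_change_from_or <- function(p0, or_value) {
  if (any(p0 <= 0 | p0 >= 1)) {
    stop("baseline proportion must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(or_value <= 0)) stop("odds ratio must be positive", call. = FALSE)
  odds1 <- or_value * p0 / (1 - p0)
  (odds1 / (1 + odds1)) / p0
}

#' Fold increase in asexual frequency with confidence interval
#'
#' Runs the additive logistic model (no interaction), extracts the
#' generation odds ratio and its profile-likelihood interval, and converts
#' both to the proportion scale at the parental baseline frequency.
#'
#' @param records Raw mesocosm records.
#' @param baseline `"pooled"` (default: total parental triploids over total
#'   parental counts) or `"mean_of_means"` (mean of per-mesocosm parental
#'   frequencies).
#' @param level Confidence level.
#' @return List with `fold`, `lower`, `upper`, `baseline_p`, `or`, and the
#'   effect-test table under `tests`.
#' @export
fold_increase_summary <- function(records, baseline = c("pooled", "mean_of_means"),
                                  level = 0.95) {
  baseline <- match.arg(baseline)
  long <- paired_glm_data(records)
  parents <- long[long$generation == "parent", ]
  p0 <- if (baseline == "pooled") {
    sum(parents$triploid) / sum(parents$triploid + parents$diploid)
  } else {
    mean(parents$triploid / (parents$triploid + parents$diploid))
  }
  fit <- fit_logistic(long, year = TRUE, interaction = FALSE)
  ors <- odds_ratios(fit, level = level)
  gen <- ors[grepl("^generation", ors$term), ]
  list(
    fold = fold_change_from_or(p0, gen$or),
    lower = fold_change_from_or(p0, gen$lower),
    upper = fold_change_from_or(p0, gen$upper),
    baseline_p = p0,
    or = gen$or,
    tests = test_effects(long)
  )
}
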