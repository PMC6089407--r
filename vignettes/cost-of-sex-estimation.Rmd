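---
title: "Estimating the net cost of sex from mesocosm experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the net cost of sex from mesocosm experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexcost)
```

## The question and the model

Dioecious sexual reproduction carries a demographic handicap: sexual
females spend resources on sons, asexual females do not.  In a mixed
population the net cost of sex, $c$, is defined so that the sexual
subpopulation's per-capita birth rate is $1/c$ times the asexual rate.
Standard one-locus selection arithmetic then gives the one-generation
recursion for the asexual frequency $q$,

$$q_{t+1} = \frac{c\,q_t}{1 + q_t\,(c-1)},$$

implemented by `next_frequency()`.  Its two consequences drive the whole
analysis.  First, the fold-increase $q_{t+1}/q_t = c/(1 + q_t(c-1))$
(`fold_increase()`) declines from $c$ when asexuals are rare to 1 at
fixation — so common asexuals under a two-fold cost increase only
`r round(fold_increase(0.30, 2), 2)`-fold from $q_t = 0.30$, not two-fold.
Second, the recursion inverts to an odds ratio,
$c = q_{t+1}(1-q_t)\,/\,q_t(1-q_{t+1})$ (`estimate_cost()`), which is
algebraically identical to a logistic-regression generation effect — the
package's two inferential routes (likelihood fit and GLM) are therefore
estimating the same quantity and are cross-checked against each other in
the test suite.

The net cost decomposes as $c = r/s$ (`decompose_cost()`,
`cost_of_males()`): the cost of males $1/s$, with $s$ the primary sex
ratio of sexual broods, times the fecundity-survival ratio $r$, the mean
surviving offspring of asexual relative to sexual females.  $r = 1$ is the
"all else equal" benchmark: the entire cost of sex is then the cost of
males.  $s$ is usually unknown; the tertiary sex ratio of dissected sexual
adults (`tertiary_sex_ratio()`) is the observable proxy, and the
decomposition should be reported for both the Fisherian prior $s = 0.5$
and the observed tertiary ratio.  Sons and daughters are assumed equally
costly; unequal offspring costs are deliberately outside the model.

## From raw counts to paired frequencies

The unit of inference is the replicate mesocosm.  Each contributes one row
of raw counts (`mesocosm_schema()`): a female-only parental flow-cytometry
subsample (triploid/diploid), whole-sample dissection tallies of males and
females with infection marks, and an unsexed offspring flow subsample.
Preprocessing (`paired_frequencies()`) applies three rules:

* **Infected individuals are excluded** (`exclude_infected()`).
  Sterilizing trematode infection castrates the host and would distort the
  birth-rate comparison the experiment exists to make.
* **Males are imputed, fractionally.**  Parental flow cytometry sees only
  females, but $q_t$ is a whole-population frequency, so the diploid
  denominator gains `impute_males(T + D, males, females)` male-equivalents
  from the dissection sex ratio.  The imputed count is kept fractional —
  rounding would perturb the ratio it exists to preserve; it is rounded
  (half-to-even) only where an integer table is required, namely the GLM
  count table (`paired_glm_data()`).
* **Degenerate replicates are dropped, not imputed**, with a warning: a
  replicate with an empty flow subsample or no dissected females carries
  no usable frequency.

Flow-cytometry exclusions (unreadable samples) are treated as a property
of the instrument: the counts tables are assumed to already contain only
scored individuals.

## The likelihood and the candidate models

Offspring triploid counts $k_i$ of $n_i$ genotyped are modelled
beta-binomially (`dbetabinom()`) with mean
$\hat q_i = $ `next_frequency(q_t[i], c(year_i))` and a shared dispersion
$\theta$, parameterized $\alpha = q\theta$, $\beta = (1-q)\theta$ so that
the mean is exactly $q$ and $\theta \to \infty$ recovers the binomial.
(The mapping to the textbook shape parameterization is
$\alpha + \beta = \theta$.)  Extra-binomial scatter between mesocosms —
clone-composition differences, micro-environment, counting error — loads
onto $\theta$ rather than corrupting the cost estimate.

Four candidate models are compared (`candidate_models()`): `no_cost`
($c=1$), `two_fold` ($c=2$), `mle` ($c$ free), and `mle_by_year`
($c = c_0$ in the first year, $c_0 + d_j$ in later year $j$).  The
year-indexed model has $k = 5$ free parameters
($\theta, c_0, d_2, d_3, d_4$) in the four-year design; the small-sample
information criterion is only arithmetically consistent with counting all
five, so that is what the package reports, even though such models are
sometimes tabulated as "4 parameters" by counting only the cost terms.

Model ranking uses AICc with $n$ = the number of replicate mesocosms (24
in the reference design) — the mesocosm, not the snail, is the independent
observation — plus Akaike weights (`akaike_weights()`).  Two bootstrap
procedures, both resampling whole replicates with replacement, give (i)
percentile CIs for parameters (`bootstrap_param_ci()`) and (ii) the 95%
ΔAIC confidence set of models (`bootstrap_confidence_set()`).  The
percentile method is used rather than BCa: it is the simplest defensible
choice and the test suite verifies its coverage by simulation at the
reference design.

### Numerical choices

* Likelihood evaluation is in log space via `lbeta`/`lchoose`; stable to
  $n = 10^4$ at least, and the pmf normalizes to 1 within $10^{-10}$ for
  $n \le 200$ (tested against a quadrature oracle).
* Boundary means ($q_t$ of exactly 0 or 1) are truncated to
  $[10^{-9}, 1-10^{-9}]$ before the pmf, keeping degenerate replicates
  finite instead of discarding them.
* Optimization is on transformed parameters ($\log\theta$, $\log c$ or
  $\log c_0$; deviations $d_j$ untransformed, with any implied
  non-positive cost mapped to a $+\infty$ penalty).  One-parameter models
  use golden-section search; multi-parameter models Nelder-Mead with a
  BFGS polish, objective tolerance $10^{-8}$ or better, and 5 jittered
  starts by default.  Bootstrap refits warm-start from the full-data
  optimum with a single start: the resampled surface is a perturbation of
  the original, and the warm start makes the 10^4-fold refit loop cheap.
* All resample index sets are drawn up front from the master seed, so
  bootstrap results are invariant to evaluation order.
* Ties in AICc produce equal Akaike weights; the ranking is otherwise by
  AICc ascending.

## The GLM significance test

Independently of the likelihood machinery, `fit_logistic()` fits
`cbind(triploid, diploid) ~ generation + year` (logit link, reference
levels: parent generation, first year) through `stats::glm`; effects are
tested by likelihood-ratio tests (`lrt()`, `test_effects()`), odds ratios
get profile-likelihood intervals (`odds_ratios()`, Wald as an explicit
fallback), and `fold_change_from_or()` converts the generation odds ratio
to a proportion-scale fold increase at the parental baseline frequency.
The baseline defaults to the pooled parental proportion; a mean-of-means
variant is exposed because either reading of "the mean parental
proportion" is defensible.  Complete separation is flagged, not silently
reported.  Within-mesocosm autocorrelation is not modelled (a GEE variant
is deliberately out of scope); the mesocosm ID is kept in the tidy table
so exchangeability can be checked externally.

## What the synthetic generator emulates — and what it does not

`generate_experiment()` produces raw records with the reference design's
statistical structure: 4 years × 6 mesocosms; true parental frequencies
drawn from a truncated normal with mean 0.29 and between-mesocosm SD 0.08
(the spread is a modelling default — only the mean is an empirical
anchor); offspring counts beta-binomial with $\theta = 40$ around the
recursion's prediction; 150 dissected parents per mesocosm with sex ratio
$s$ among sexual diploids and independent infection marks at rate 0.0982;
parental flow subsamples of uninfected females (hypergeometric in ploidy,
Poisson-perturbed target of 62 genotyped); flow-exclusion thinning at
0.0601 (parents) and 0.0538 (offspring).  Per-mesocosm substreams are
keyed by (year, mesocosm) under one master seed, so any record is
reproducible in isolation.

Deliberate simplifications: infection is independent of reproductive mode
(an odds-bias switch exists for robustness experiments but is off by
default — the generator tests the exclusion plumbing, not parasite
selection); subsample-size variation is Poisson, a modelling choice since
only means are anchored; there is no clone structure, no density
dependence, no multi-year eco-evolutionary feedback.  Passing recovery
tests therefore certify the estimator against sampling noise,
overdispersion, infection exclusion and male imputation — not against
mode-biased parasitism or shared-environment correlation in real data.

## Problem sizes used in the test suite

The simulation-based checks run 200 synthetic experiments at the reference
design for parameter recovery and bootstrap coverage (B = 200 resamples
per experiment) and 100 experiments for model-selection sanity; these
sizes give Monte-Carlo error comfortably inside the asserted bands while
keeping the suite quick on a single CPU.  Larger choices (e.g. the
conventional B = 10,000 for published CIs) are one argument away.

## Known limitations

* The estimator conditions on the measured parental frequency; its
  sampling error (finite flow subsample plus imputed males) is absorbed
  by $\theta$ rather than modelled as errors-in-variables.  At the
  reference subsample sizes this leaves no detectable bias (median
  recovered $\hat c$ within 0.05 of truth in the suite's 200-experiment
  check), but very small parental subsamples would attenuate estimates.
* One generation, two reproductive modes, no partial asexuality: the
  recursion is not a general mating-system model.
* The ΔAIC confidence-set limit is a bootstrap quantile and is itself
  noisy at small B; treat the set membership, not the limit's third
  decimal, as the result.
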