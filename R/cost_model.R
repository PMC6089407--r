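# One-generation theory of asexual-frequency change under a net cost of sex.
#
# An asexual (clonal, all-female) lineage with per-capita birth rate W_asex
# competes against a dioecious sexual population whose per-capita birth rate
# is W_asex / c, where c > 0 is the net cost of sex.  Standard single-locus
# selection arithmetic, q' = q W_asex / W-bar, then gives the recursion
# implemented by next_frequency(); everything else in this file is algebra
# on that recursion.

#' Asexual frequency after one generation of selection
#'
#' Propagates the frequency of asexuals through one generation under a net
#' cost of sex `c`: the sexual subpopulation's per-capita birth rate is a
#' fraction 1/`c` of the asexual birth rate, so
#' \deqn{q_{t+1} = \frac{c\,q_t}{1 + q_t (c - 1)}.}
#' With `c = 1` the map is the identity (no cost, no change); with `c > 1`
#' iteration from any interior frequency converges monotonically to asexual
#' fixation.
#'
#' @param q_t Numeric vector of parental asexual frequencies in \[0, 1\].
#' @param c Numeric vector of net costs of sex (> 0).  `q_t` and `c` are
#'   recycled to a common length.
#'
#' @return Numeric vector of offspring-generation asexual frequencies.
#'
#' @examples
#' next_frequency(0.30, 2)     # 6/13
#' next_frequency(0.5, 1)      # no cost: unchanged
#' @seealso [fold_increase()], [estimate_cost()]
#' @export
next_frequency <- function(q_t, c) {
  check_frequency(q_t, "q_t")
  check_cost(c)
  c * q_t / (1 + q_t * (c - 1))
}

#' Fold-increase in asexual frequency over one generation
#'
#' The ratio `next_frequency(q_t, c) / q_t`, i.e.
#' \deqn{q_{t+1}/q_t = \frac{c}{1 + q_t (c - 1)}.}
#' For `c > 1` this declines from `c` (the rare-mutant limit: a rare asexual
#' under a two-fold cost doubles in frequency) down to 1 at fixation.  The
#' ratio is undefined at `q_t = 0` and the function raises there, although
#' the limit as `q_t` approaches 0 is `c`.
#'
#' @inheritParams next_frequency
#' @param q_t Numeric vector of parental asexual frequencies in (0, 1\].
#'
#' @return Numeric vector of per-generation fold increases.
#'
#' @examples
#' fold_increase(0.30, 2)   # about 1.54: common asexuals gain far less than 2x
#' fold_increase(1, 2)      # 1 at fixation
#' @export
fold_increase <- function(q_t, c) {
  check_frequency(q_t, "q_t")
  check_cost(c)
  if (any(q_t == 0)) {
    stop("fold_increase() is undefined at q_t = 0 (the limit as q_t -> 0 is c)",
         call. = FALSE)
  }
  c / (1 + q_t * (c - 1))
}

#' Estimate the net cost of sex from one generation of frequency change
#'
#' Inverts the one-generation recursion: given parental and offspring asexual
#' frequencies, the implied net cost of sex is the odds ratio
#' \deqn{c = \frac{q_{t+1} (1 - q_t)}{q_t (1 - q_{t+1})}.}
#' Exact inverse of [next_frequency()] in `c` for interior frequencies.
#'
#' @param q_t Numeric vector of parental asexual frequencies, strictly
#'   inside (0, 1).
#' @param q_t1 Numeric vector of offspring asexual frequencies, strictly
#'   inside (0, 1).
#'
#' @return Numeric vector of point estimates of the net cost of sex.
#'
#' @examples
#' estimate_cost(0.30, next_frequency(0.30, 2))  # recovers 2
#' estimate_cost(0.29, 0.29)                     # no change: cost 1
#' @export
estimate_cost <- function(q_t, q_t1) {
  check_frequency(q_t, "q_t")
  check_frequency(q_t1, "q_t1")
  if (any(q_t == 0 | q_t == 1 | q_t1 == 0 | q_t1 == 1)) {
    stop("estimate_cost() needs frequencies strictly inside (0, 1): ",
         "the odds ratio q_t1(1 - q_t) / (q_t(1 - q_t1)) is undefined ",
         "at 0 or 1", call. = FALSE)
  }
  q_t1 * (1 - q_t) / (q_t * (1 - q_t1))
}

#' Decompose the net cost of sex into its fecundity-survival component
#'
#' The net cost of sex factors as c = r / s: the product of the cost of
#' males (1/s, with s the primary sex ratio of sexual broods) and the
#' fecundity-survival ratio r (mean surviving offspring of asexual females
#' divided by that of sexual females).  Given an estimated `c` and an
#' assumed `s`, returns r = c * s.  A value of r = 1 is the "all else
#' equal" benchmark: the entire net cost is then the cost of males.
#'
#' @param c Numeric vector of net costs of sex (> 0).
#' @param s Numeric vector of primary sex ratios (proportion daughters in
#'   sexual broods), in (0, 1\].
#'
#' @return Numeric vector of fecundity-survival ratios r = c * s.
#'
#' @examples
#' decompose_cost(2, 0.5)      # 1: all-else-equal
#' decompose_cost(2.14, 0.5)   # 1.07
#' decompose_cost(2, 0.61)     # 1.22 under a female-biased tertiary ratio
#' @seealso [cost_of_males()]
#' @export
decompose_cost <- function(c, s) {
  check_cost(c)
  check_sex_ratio(s)
  c * s
}

#' Cost of males for a given primary sex ratio
#'
#' Sexual females allocating a proportion `s` of offspring to daughters pay a
#' demographic cost of 1/`s` relative to all-daughter clonal broods: the
#' classic two-fold cost of males when `s = 0.5`.
#'
#' @param s Numeric vector of primary sex ratios in (0, 1\].
#'
#' @return Numeric vector `1/s`.
#'
#' @examples
#' cost_of_males(0.5)   # 2
#' cost_of_males(1)     # all-daughter broods carry no cost
#' @export
cost_of_males <- function(s) {
  check_sex_ratio(s)
  1 / s
}

# Input validation --------------------------------------------------------
# Frequencies are validated, never clamped: silently truncating an
# out-of-range frequency would mask upstream count errors.

check_frequency <- function(q, name) {
  if (!is.numeric(q) || length(q) == 0 || anyNA(q)) {
    stop(name, " must be numeric and non-missing", call. = FALSE)
  }
  if (any(q < 0 | q > 1)) {
    stop(name, " must lie in [0, 1]; got ",
         paste(format(q[q < 0 | q > 1]), collapse = ", "), call. = FALSE)
  }
  invisible(q)
}

check_cost <- function(c) {
  if (!is.numeric(c) || length(c) == 0 || anyNA(c) || any(c <= 0)) {
    stop("cost of sex c must be a positive number", call. = FALSE)
  }
  invisible(c)
}

check_sex_ratio <- function(s) {
  if (!is.numeric(s) || length(s) == 0 || anyNA(s) || any(s <= 0 | s > 1)) {
    stop("primary sex ratio s must lie in (0, 1]", call. = FALSE)
  }
  invisible(s)
}
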