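# Data model and preprocessing for replicated mesocosm experiments.
#
# One row per (year, mesocosm): flow-cytometry ploidy counts for a female
# parental subsample and an unsexed offspring subsample, plus whole-sample
# dissection tallies used to impute the number of males consistent with the
# female flow subsample.  Males are assumed to be sexual diploids.

.required_cols <- c(
  "year", "mesocosm_id",
  "parent_flow_triploid", "parent_flow_diploid",
  "dissected_males", "dissected_females",
  "offspring_flow_triploid", "offspring_flow_diploid"
)
.optional_cols <- c("infected_males", "infected_females", "infected_offspring")
.count_cols <- setdiff(c(.required_cols, .optional_cols), c("year", "mesocosm_id"))

#' Column schema for mesocosm count tables
#'
#' @return A list with `required` and `optional` character vectors of column
#'   names.  Counts are non-negative integers; `year` and `mesocosm_id`
#'   identify the replicate.  The parental flow columns refer to the female
#'   subsample only; the offspring flow columns cover both sexes (offspring
#'   are genotyped unsexed).  Optional infected tallies default to zero.
#' @export
mesocosm_schema <- function() {
  list(required = .required_cols, optional = .optional_cols)
}

#' Read a mesocosm counts table
#'
#' Reads a CSV or TSV file (delimiter chosen by extension, comma otherwise)
#' with one row per (year, mesocosm) and the columns of [mesocosm_schema()].
#' Missing optional infected columns are filled with zeros.
#'
#' @param path Path to the counts file.
#'
#' @return A `data.frame` of validated mesocosm records.
#'
#' @examples
#' path <- system.file("extdata", "synthetic_mesocosm_counts.csv",
#'                     package = "sexcost")
#' head(read_counts(path))
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  validate_records(raw)
}

#' @rdname read_counts
#' @param records A mesocosm record `data.frame` (e.g. from
#'   [generate_experiment()]); validated and returned with infected columns
#'   filled in.
#' @export
validate_records <- function(records) {
  records <- as.data.frame(records)
  missing <- setdiff(.required_cols, names(records))
  if (length(missing) > 0) {
    stop("counts table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in .optional_cols) {
    if (is.null(records[[col]])) records[[col]] <- 0L
  }
  for (col in .count_cols) {
    v <- suppressWarnings(as.numeric(records[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop("column '", col, "' must hold non-negative integer counts; ",
           "offending row(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    records[[col]] <- as.integer(v)
  }
  records[, c(.required_cols, .optional_cols)]
}

#' Write a mesocosm counts table
#'
#' Inverse of [read_counts()]: writes CSV (or TSV by extension) that
#' round-trips losslessly through [read_counts()].
#'
#' @param records Validated mesocosm records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(records, path) {
  records <- validate_records(records)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Remove infected (castrated) individuals from dissection and offspring tallies
#'
#' Sterilizing trematode infection castrates its host and so distorts the
#' relative birth rates the experiment is trying to measure; infected
#' individuals are excluded before any frequency is computed.  Infected
#' counts are subtracted from the dissection tallies (and any infected
#' offspring from the diploid offspring tally, infected snails being sexual
#' diploids in this system), then zeroed.  The parental flow subsample is
#' assumed to consist of uninfected females already, since the flow input is
#' the heads of dissected uninfected females.
#'
#' @param records Validated mesocosm records.
#' @return Records with infected individuals removed and infected columns
#'   set to zero.
#' @export
exclude_infected <- function(records) {
  records <- validate_records(records)
  bad <- records$infected_males > records$dissected_males |
    records$infected_females > records$dissected_females |
    records$infected_offspring > records$offspring_flow_diploid
  if (any(bad)) {
    stop("infected counts exceed the corresponding totals in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  records$dissected_males <- records$dissected_males - records$infected_males
  records$dissected_females <- records$dissected_females - records$infected_females
  records$offspring_flow_diploid <-
    records$offspring_flow_diploid - records$infected_offspring
  records$infected_males <- 0L
  records$infected_females <- 0L
  records$infected_offspring <- 0L
  records
}

#' Impute the male count matching a female flow subsample
#'
#' Parental flow cytometry is run on females only; the diploid denominator
#' of the parental asexual frequency must also count males.  The number of
#' males consistent with a female subsample of size `n_female_subsample` is
#' imputed from the male:female ratio of the whole-mesocosm dissection
#' sample: `n_female_subsample * males / females`.  The imputed count is
#' kept fractional so the ratio is preserved exactly; round only for
#' integer-table export.
#'
#' @param n_female_subsample Size of the female flow subsample.
#' @param males,females Uninfected dissection tallies for the whole
#'   mesocosm sample.
#'
#' @return Numeric (possibly fractional) male-equivalent count.
#'
#' @examples
#' impute_males(60, 50, 100)  # 30
#' @export
impute_males <- function(n_female_subsample, males, females) {
  if (any(females <= 0)) {
    stop("cannot impute males: dissected female count must be positive ",
         "(sex ratio undefined)", call. = FALSE)
  }
  n_female_subsample * males / females
}

#' Parental asexual frequency from a mesocosm record
#'
#' Computes q_t = T / (T + D + M) where T and D are the triploid and diploid
#' counts of the female flow subsample and M is the imputed male count from
#' [impute_males()].  Call [exclude_infected()] first.
#'
#' @param records Validated mesocosm records with infected individuals
#'   already excluded.
#' @return Numeric vector of parental asexual frequencies.
#' @export
parental_frequency <- function(records) {
  records <- validate_records(records)
  T_ <- records$parent_flow_triploid
  D <- records$parent_flow_diploid
  if (any(T_ + D == 0)) {
    stop("degenerate record: parental flow subsample is empty in row(s) ",
         paste(which(T_ + D == 0), collapse = ", "), call. = FALSE)
  }
  M <- impute_males(T_ + D, records$dissected_males, records$dissected_females)
  T_ / (T_ + D + M)
}

#' Offspring triploid count and genotyped total
#'
#' Offspring are genotyped unsexed, so no male imputation is involved:
#' k is the triploid flow count and n = triploid + diploid.
#'
#' @inheritParams parental_frequency
#' @return A `data.frame` with columns `k` and `n`.
#' @export
offspring_frequency <- function(records) {
  records <- validate_records(records)
  k <- records$offspring_flow_triploid
  n <- k + records$offspring_flow_diploid
  if (any(n == 0)) {
    stop("degenerate record: offspring flow subsample is empty in row(s) ",
         paste(which(n == 0), collapse = ", "), call. = FALSE)
  }
  data.frame(k = k, n = n)
}

#' Tertiary sex ratio of the sexual subpopulation
#'
#' Proportion of females among dissected sexual adults, an observable proxy
#' for the primary sex ratio `s` used in [decompose_cost()].
#'
#' @param males,females Adult tallies (uninfected).
#' @return Proportion female, `females / (males + females)`.
#' @examples
#' tertiary_sex_ratio(39, 61)  # 0.61
#' @export
tertiary_sex_ratio <- function(males, females) {
  if (any(males + females <= 0)) {
    stop("sex ratio undefined: males + females must be positive", call. = FALSE)
  }
  females / (males + females)
}

#' Paired parent/offspring frequencies for the likelihood
#'
#' The full preprocessing pipeline: excludes infected individuals, computes
#' the parental asexual frequency (with male imputation) and the offspring
#' triploid count/total for every replicate.  Replicates degenerate in
#' either generation (empty flow subsample, or no dissected females so the
#' sex ratio is undefined) are dropped with a warning, not imputed.
#'
#' @param records Raw mesocosm records.
#' @param drop_degenerate Drop rows that cannot yield both frequencies
#'   (default `TRUE`); with `FALSE` a degenerate row raises an error.
#'
#' @return A `data.frame` with columns `year`, `mesocosm_id`, `q_t`,
#'   `offspring_k`, `offspring_n`, one row per usable replicate.  The
#'   exclusion/imputation log is attached as attribute `"log"`.
#'
#' @examples
#' rec <- paper_like_dataset(seed = 1)
#' head(paired_frequencies(rec))
#' @export
paired_frequencies <- function(records, drop_degenerate = TRUE) {
  records <- exclude_infected(records)
  degenerate <-
    records$parent_flow_triploid + records$parent_flow_diploid == 0 |
    records$offspring_flow_triploid + records$offspring_flow_diploid == 0 |
    records$dissected_females == 0
  if (any(degenerate)) {
    if (!drop_degenerate) {
      stop("degenerate replicate(s) in row(s): ",
           paste(which(degenerate), collapse = ", "), call. = FALSE)
    }
    warning(sum(degenerate), " degenerate replicate(s) dropped (empty flow ",
            "subsample or zero dissected females)", call. = FALSE)
    records <- records[!degenerate, , drop = FALSE]
  }
  off <- offspring_frequency(records)
  out <- data.frame(
    year = records$year,
    mesocosm_id = records$mesocosm_id,
    q_t = parental_frequency(records),
    offspring_k = off$k,
    offspring_n = off$n
  )
  attr(out, "log") <- list(
    n_input = length(degenerate),
    n_dropped = sum(degenerate),
    imputed_males = impute_males(
      records$parent_flow_triploid + records$parent_flow_diploid,
      records$dissected_males, records$dissected_females
    )
  )
  out
}
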