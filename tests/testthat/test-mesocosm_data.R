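# Count-table I/O and the preprocessing arithmetic.

test_that("read_counts round-trips a well-formed table and fills infected columns", {
  rec <- paper_like_dataset(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(rec, path)
  back <- read_counts(path)
  expect_equal(nrow(back), 24)
  expect_equal(back, rec)
  # TSV round-trip too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(rec, path2)
  expect_equal(read_counts(path2), rec)
  # optional infected columns default to zero
  slim <- rec[, setdiff(names(rec), c("infected_males", "infected_females",
                                      "infected_offspring"))]
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(slim, path3, row.names = FALSE)
  expect_equal(read_counts(path3)$infected_males, rep(0L, 24))
})

test_that("read_counts names missing columns and cites bad rows", {
  rec <- paper_like_dataset(seed = 3)
  broken <- rec[, names(rec) != "offspring_flow_diploid"]
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, path, row.names = FALSE)
  expect_error(read_counts(path), "offspring_flow_diploid")

  rec2 <- rec
  rec2$dissected_females[5] <- -3
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec2, path2, row.names = FALSE)
  expect_error(read_counts(path2), "row.*5")
  expect_error(read_counts(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("exclude_infected subtracts and validates infected tallies", {
  rec <- one_record(dissected_males = 55, dissected_females = 95,
                    infected_males = 5, infected_females = 9)
  out <- exclude_infected(rec)
  expect_equal(out$dissected_males, 50L)
  expect_equal(out$dissected_females, 86L)
  expect_equal(out$infected_males, 0L)
  # all-zero infected is the identity
  expect_equal(exclude_infected(one_record()), one_record())
  expect_error(
    exclude_infected(one_record(dissected_males = 55, infected_males = 60)),
    "exceed"
  )
})

test_that("male imputation is ratio arithmetic and fails on zero females", {
  expect_equal(impute_males(60, 50, 100), 30)
  expect_equal(impute_males(60, 0, 100), 0)
  expect_equal(impute_males(62, 55, 95), 62 * 55 / 95)
  expect_error(impute_males(60, 50, 0), "sex ratio")
})

test_that("parental frequency combines flow counts with imputed males", {
  # default record: 60 females genotyped, 1:1 dissection ratio -> 60 males
  expect_equal(parental_frequency(one_record()), 30 / 120)
  # 1:2 male:female ratio -> 30 imputed males
  expect_equal(
    parental_frequency(one_record(dissected_males = 25,
                                  dissected_females = 50)),
    1 / 3
  )
  expect_equal(
    parental_frequency(one_record(parent_flow_triploid = 28,
                                  parent_flow_diploid = 20,
                                  dissected_males = 40,
                                  dissected_females = 80)),
    28 / 72
  )
  expect_equal(parental_frequency(one_record(parent_flow_triploid = 0)), 0)
  expect_error(
    parental_frequency(one_record(parent_flow_triploid = 0,
                                  parent_flow_diploid = 0)),
    "degenerate"
  )
  # scale-invariant in the dissection tallies
  r1 <- one_record(dissected_males = 40, dissected_females = 80)
  r2 <- one_record(dissected_males = 80, dissected_females = 160)
  expect_equal(parental_frequency(r1), parental_frequency(r2))
  # with no males, reduces to the female-only triploid fraction
  r3 <- one_record(dissected_males = 0)
  expect_equal(parental_frequency(r3), 30 / 60)
})

test_that("offspring frequency needs no imputation", {
  out <- offspring_frequency(one_record())
  expect_equal(out$k, 37L)
  expect_equal(out$n, 74L)
  expect_equal(offspring_frequency(one_record(offspring_flow_triploid = 0,
                                              offspring_flow_diploid = 70)),
               data.frame(k = 0L, n = 70L))
  expect_equal(offspring_frequency(one_record(offspring_flow_triploid = 34,
                                              offspring_flow_diploid = 36))$n,
               70L)
  expect_error(
    offspring_frequency(one_record(offspring_flow_triploid = 0,
                                   offspring_flow_diploid = 0)),
    "degenerate"
  )
})

test_that("tertiary sex ratio is the proportion female", {
  expect_equal(tertiary_sex_ratio(39, 61), 0.61)
  expect_equal(tertiary_sex_ratio(50, 50), 0.5)
  expect_equal(tertiary_sex_ratio(0, 10), 1)
  expect_error(tertiary_sex_ratio(0, 0), "undefined")
})

test_that("paired_frequencies excludes infected, drops degenerate rows, and logs", {
  rec <- paper_like_dataset(seed = 9)
  paired <- paired_frequencies(rec)
  expect_equal(nrow(paired), 24)
  expect_true(all(paired$q_t >= 0 & paired$q_t <= 1))
  expect_true(all(paired$offspring_k <= paired$offspring_n))
  expect_equal(attr(paired, "log")$n_dropped, 0)

  rec$offspring_flow_triploid[3] <- 0L
  rec$offspring_flow_diploid[3] <- 0L
  rec$infected_offspring[3] <- 0L
  expect_warning(p2 <- paired_frequencies(rec), "degenerate")
  expect_equal(nrow(p2), 23)
  expect_error(paired_frequencies(rec, drop_degenerate = FALSE), "degenerate")

  # infected exclusion shifts the parental frequency via the sex ratio
  r <- one_record(dissected_males = 50, dissected_females = 100,
                  infected_males = 30)
  q_raw <- parental_frequency(r)          # uses raw 50:100 tallies
  q_cln <- parental_frequency(exclude_infected(r))  # 20:100
  expect_true(q_cln < 1 && q_raw < q_cln)  # fewer males -> higher q_t
})
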