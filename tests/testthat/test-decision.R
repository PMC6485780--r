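test_that("16S classification follows the 98.65/95 rule with conservative boundaries", {
  expect_equal(classify_16s(96.57)$verdict, "new_species_same_genus")
  expect_equal(classify_16s(100)$verdict, "same_species")
  expect_equal(classify_16s(94)$verdict, "possible_new_genus")
  # boundary equality resolves against novelty
  expect_equal(classify_16s(98.65)$verdict, "same_species")
  expect_equal(classify_16s(95)$verdict, "possible_new_genus")
  expect_error(classify_16s(101), "percentage")
  expect_error(classify_16s(-1), "percentage")
})

test_that("genomic classification applies the 70/95 thresholds and flags conflicts", {
  expect_equal(classify_genomic(list(ddh = 28.67, aai = 50.73))$verdict,
               "new_species_same_genus")
  expect_equal(classify_genomic(list(ddh = 85, aai = 97))$verdict,
               "same_species")
  expect_equal(classify_genomic(list(ddh = 72, aai = 90))$verdict,
               "inconclusive")
  expect_equal(classify_genomic(list(ddh = 30, aai = 97))$verdict,
               "inconclusive")
  # boundary equality is non-novel
  expect_equal(classify_genomic(list(ddh = 70, aai = 95))$verdict,
               "same_species")
})

test_that("the verdict is monotone in the relatedness values", {
  verdict_rank <- c(same_species = 1, inconclusive = 2,
                    new_species_same_genus = 3, possible_new_genus = 4)
  withr::local_seed(83)
  for (rep in 1:50) {
    ddh <- runif(1, 0, 100); aai <- runif(1, 0, 100)
    v1 <- classify_genomic(list(ddh = ddh, aai = aai))$verdict
    v2 <- classify_genomic(list(ddh = min(100, ddh + runif(1, 0, 30)),
                                aai = aai))$verdict
    v3 <- classify_genomic(list(ddh = ddh,
                                aai = min(100, aai + runif(1, 0, 30))))$verdict
    # raising a value never moves the verdict toward greater novelty
    expect_lte(verdict_rank[[v2]], verdict_rank[[v1]])
    expect_lte(verdict_rank[[v3]], verdict_rank[[v1]])
  }
  for (i in seq(0, 100, by = 10)) {
    expect_lte(verdict_rank[[classify_16s(min(i + 10, 100))$verdict]],
               verdict_rank[[classify_16s(i)$verdict]])
  }
})

test_that("evidence rows are recomputable from value, threshold and direction", {
  calls <- list(classify_16s(96.57), classify_16s(99),
                classify_genomic(list(ddh = 20, aai = 60)),
                classify_genomic(list(ddh = 80, aai = 90)))
  for (cl in calls) {
    ev <- tidy(cl)
    recomputed <- mapply(function(v, th, dir) switch(dir,
                                                     "<" = v < th,
                                                     "<=" = v <= th,
                                                     ">" = v > th,
                                                     ">=" = v >= th),
                         ev$value, ev$threshold, ev$direction)
    expect_equal(ev$passed, unname(recomputed))
  }
})

test_that("species report reproduces the published delineation scenario", {
  # 16S 96.57; dDDH and AAI rows of the comparison tables, all below 70/95
  ddh_vals <- c(20.5, 19.8, 21.6, 20.1, 19.1, 21.4, 19.3, 23.6, 28.67)
  aai_vals <- c(68.72, 68.19, 68.18, 67.90, 68.08, 64.69, 64.37, 51.72, 50.73)
  genomic <- purrr::map2(ddh_vals, aai_vals,
                         function(d, a) classify_genomic(list(ddh = d, aai = a)))
  rep <- species_report("Marseille-P2481", classify_16s(96.57), genomic)
  expect_equal(rep$overall, "new_species_same_genus")
  expect_false(rep$provisional)
  expect_equal(nrow(tidy(rep)), 2 + 2 * 9)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("species report handles empty, contradictory and mixed evidence", {
  s16 <- classify_16s(96.57)
  empty <- species_report("s", s16)
  expect_equal(empty$overall, s16$verdict)
  expect_true(empty$provisional)

  contra <- species_report("s", classify_16s(94),
                           list(classify_genomic(list(ddh = 85, aai = 97))))
  expect_equal(contra$overall, "inconclusive")

  mixed <- species_report("s", s16,
                          list(classify_genomic(list(ddh = 20, aai = 60)),
                               classify_genomic(list(ddh = 85, aai = 97))))
  expect_equal(mixed$overall, "inconclusive")
})

test_that("reports serialize deterministically", {
  s16 <- classify_16s(96.57)
  genomic <- list(classify_genomic(list(ddh = 25, aai = 60)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_species_report(species_report("s", s16, genomic), d1)
  f2 <- write_species_report(species_report("s", s16, genomic), d2)
  expect_identical(readLines(f1[["json"]]), readLines(f2[["json"]]))
  expect_identical(readLines(f1[["text"]]), readLines(f2[["text"]]))
  parsed <- jsonlite::read_json(f1[["json"]])
  expect_equal(parsed$overall, "new_species_same_genus")
})

test_that("threshold constructor validates its invariants", {
  expect_error(thresholds(s16_species = 90, s16_genus = 95))
  expect_error(thresholds(ddh_species = 0))
  t <- thresholds(aai_species = 96)
  expect_equal(t$aai_species, 96)
})
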