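test_that("primary scores are exact ones/cardinality fractions", {
  full <- primary_score(c(1, 1, 1, 1, 1, 1))
  expect_equal(as.numeric(full), 1)
  third <- primary_score(c(0, 1, 0))
  expect_equal(as.numeric(third), 1 / 3)
  expect_equal(attr(third, "numerator"), 1L)
  expect_equal(attr(third, "denominator"), 3L)
  expect_equal(round_half_up(as.numeric(third), 2), 0.33)
  expect_equal(as.numeric(primary_score(rep(0, 5))), 0)
  expect_error(primary_score(numeric(0)), class = "pmc_score_error")
  expect_error(primary_score(c(0, 2, 1)), class = "pmc_score_error")
})

test_that("the index sums the nine scored primaries exactly", {
  sch <- default_schema()
  top <- c(X1 = 1, X2 = 1/3, X3 = 1/3, X4 = 1, X5 = 1, X6 = 1, X7 = 1,
           X8 = 1, X9 = 1)
  expect_equal(pmc_index(top, sch), 23 / 3)
  expect_equal(round_half_up(pmc_index(top, sch), 2), 7.67)
  expect_equal(pmc_index(setNames(rep(1, 9), paste0("X", 1:9)), sch), 9)
  expect_error(pmc_index(top[-4], sch), "missing scored",
               class = "pmc_score_error")
})

test_that("indentation is the exact complement on the 0-9 scale", {
  expect_equal(indentation_index(23 / 3), 4 / 3)
  expect_equal(round_half_up(indentation_index(23 / 3), 2), 1.33)
  expect_equal(indentation_index(9), 0)
  expect_equal(round_half_up(indentation_index(7.47), 2), 1.53)
  expect_error(indentation_index(9.5), class = "pmc_score_error")
})

test_that("grade bands are inclusive at their printed boundaries", {
  expect_equal(classify_pmc(c(7.67, 5.78, 8.00, 9, 6.00, 7.99, 4.00,
                              5.99, 3.99, 0)),
               c("Good", "Acceptable", "Excellent", "Excellent", "Good",
                 "Good", "Acceptable", "Acceptable", "Poor", "Poor"))
  expect_equal(classify_indentation(c(0, 1.00, 1.01, 3.00, 3.01, 5.00,
                                      5.01, 9)),
               c("Low depression", "Low depression", "Central depression",
                 "Central depression", "Acceptable level of indentation",
                 "Acceptable level of indentation",
                 "Unacceptable level of indentation",
                 "Unacceptable level of indentation"))
})

test_that("scoring the bundled set reproduces every published cell", {
  fix <- integration_policies()
  sc <- score_policies(fix$coding)
  res <- sc$results
  ref <- fix$reference
  ref <- ref[match(res$code, ref$code), ]
  for (t in paste0("X", 1:9)) {
    expect_equal(res[[t]], round_half_up(ref[[t]], 2),
                 info = paste("primary column", t))
  }
  expect_equal(res$pmc_display, ref$pmc)
  # published ranking order, including the tie at 7.47 resolved by code
  expect_equal(res$code[1:3], c("P22", "P9", "P25"))
  expect_equal(res$code[28], "P26")
  expect_equal(res$pmc_display[res$code == "P26"], 4.40)
  expect_equal(unname(table(res$grade)["Good"]), 22L)
  expect_equal(unname(table(res$grade)["Acceptable"]), 6L)
  # column means
  cm <- round_half_up(sc$column_means, 2)
  expect_equal(unname(cm[paste0("X", 1:9)]),
               c(0.67, 0.33, 0.40, 0.77, 0.86, 0.87, 0.96, 0.85, 0.74))
  expect_equal(unname(cm["pmc"]), 6.47)
  expect_equal(unname(cm["indentation"]), 2.53)
})

test_that("a single all-ones policy scores the maximum", {
  sch <- default_schema()
  ones <- matrix(1L, 1, 39, dimnames = list("P1", secondary_ids(sch)))
  sc <- score_policies(pmc_coding(ones, sch), sch)
  expect_equal(sc$results$pmc, 9)
  expect_equal(sc$results$grade, "Excellent")
  expect_equal(sc$results$indentation_grade, "Low depression")
})

test_that("scoring agrees with the brute-force oracle on random matrices", {
  sch <- default_schema()
  card <- cardinalities(sch)
  for (s in 1:200) {
    coding <- random_coding(10, sch, seed = 5000 + s)
    sc <- score_policies(coding, sch)
    expected <- oracle_pmc(coding$values, card)
    got <- setNames(sc$results$pmc, sc$results$code)
    expect_equal(got[names(expected)], expected, tolerance = 1e-12)
  }
})

test_that("flipping one bit raises the index by exactly 1/cardinality", {
  sch <- default_schema()
  card <- cardinalities(sch)
  coding <- random_coding(4, sch, seed = 99)
  base <- score_policies(coding, sch)
  set.seed(100)
  for (rep in 1:25) {
    code <- sample(rownames(coding$values), 1)
    zeros <- which(coding$values[code, ] == 0L)
    if (!length(zeros)) next
    col <- names(zeros)[sample(length(zeros), 1)]
    prim <- sub(":.*", "", col)
    flipped <- coding
    flipped$values[code, col] <- 1L
    sc2 <- score_policies(flipped, sch)
    d <- sc2$results$pmc[sc2$results$code == code] -
      base$results$pmc[base$results$code == code]
    expect_equal(d, 1 / card[[prim]], tolerance = 1e-12)
    # all other primaries unchanged (exact integer numerators)
    others <- setdiff(names(card), prim)
    expect_identical(sc2$exact$num[code, others],
                     base$exact$num[code, others])
  }
})

test_that("index plus indentation is exactly nine in integer arithmetic", {
  sch <- default_schema()
  for (coding in list(integration_policies()$coding,
                      random_coding(50, sch, seed = 7))) {
    sc <- score_policies(coding, sch)
    L <- sc$exact$common_den
    ind_num <- 9L * L - sc$exact$pmc_num
    expect_true(all(sc$exact$pmc_num + ind_num == 9L * L))
    expect_equal(sc$results$pmc + sc$results$indentation,
                 rep(9, nrow(sc$results)))
    expect_true(all(sc$results$pmc >= 0 & sc$results$pmc <= 9))
    expect_true(all(sc$exact$num >= 0 & sc$exact$num <= sc$exact$den))
  }
})

test_that("results export to CSV and full-precision JSON", {
  sc <- score_policies(integration_policies()$coding)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_scores(sc, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), 28)
  expect_equal(back$Code, sc$results$code)
  expect_equal(back[["PMC Index"]][1], 7.67)

  js <- withr::local_tempfile(fileext = ".json")
  export_scores_json(sc, js)
  full <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(full$results$pmc[1], 23 / 3, tolerance = 1e-12)
})
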