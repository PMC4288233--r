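# Synthetic repository generator

# independent per-patient grade counts straight from the laboratory rows
grade_counts_by_patient <- function(repo, grade,
                                    partitions = default_liver_partitions()) {
  lab <- repo$Laboratory
  val <- ifelse(is.na(lab$Result_Number), lab$Result_String,
                lab$Result_Number)
  g <- mapply(function(item, v) grade_of_value(partitions, item, v),
              lab$Item_Name, val)
  tapply(g == grade, lab$Personal_ID, sum)
}

test_that("cardinalities are exact by construction", {
  repo <- generate_repository(generator_config(10, seed = 5))
  expect_equal(nrow(repo$Diagnosis), 10)
  expect_equal(nrow(repo$Laboratory), 50)
  expect_equal(nrow(repo$Treatment), 10)
  expect_length(repository_patients(repo), 10)
  expect_true(all(repo$Diagnosis$ICD9_Code == "155.0"))
  # exactly one of the two result columns per laboratory row
  expect_true(all(xor(is.na(repo$Laboratory$Result_String),
                      is.na(repo$Laboratory$Result_Number))))
  # one row per patient per item
  expect_equal(unname(table(repo$Laboratory$Item_Name)), rep(10L, 5),
               ignore_attr = TRUE)
})

test_that("identical configurations generate identical repositories", {
  r1 <- generate_repository(generator_config(200, seed = 123))
  r2 <- generate_repository(generator_config(200, seed = 123))
  expect_identical(r1, r2)
  r3 <- generate_repository(generator_config(200, seed = 124))
  expect_false(identical(r1$Laboratory, r3$Laboratory))
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_repository(generator_config(10, seed = 99)))
  expect_identical(runif(1), before)
})

test_that("grade classification partitions each item's value space", {
  p <- default_liver_partitions()
  expect_equal(grade_of_value(p, "ICG", 14.9), "A")
  expect_equal(grade_of_value(p, "ICG", 15.0), "B")   # B is inclusive
  expect_equal(grade_of_value(p, "ICG", 40.0), "B")
  expect_equal(grade_of_value(p, "ICG", 40.1), "C")
  expect_equal(grade_of_value(p, "Prothrombin activity", 85), "A")
  expect_equal(grade_of_value(p, "Serum bilirubin", 1.0), "A")
  expect_equal(grade_of_value(p, "Ascites", "None"), "A")
  # a dense grid classifies into exactly one grade each
  for (item in c("ICG", "Prothrombin activity", "Serum albumin",
                 "Serum bilirubin")) {
    rng <- range(unlist(p[[item]][c("A", "B", "C")]))
    grid <- seq(rng[1], rng[2], length.out = 499)
    grades <- vapply(grid, function(v) grade_of_value(p, item, v),
                     character(1))
    expect_true(all(grades %in% c("A", "B", "C")))
    # brute-force membership: B-range values always classify B
    inb <- grid >= p[[item]]$B[1] & grid <= p[[item]]$B[2]
    expect_true(all(grades[inb] == "B"))
  }
})

test_that("every generated value lies inside its item's graded space", {
  repo <- generate_repository(generator_config(500, seed = 31))
  lab <- repo$Laboratory
  p <- default_liver_partitions()
  for (item in setdiff(names(p), "Ascites")) {
    v <- lab$Result_Number[lab$Item_Name == item]
    rng <- range(unlist(p[[item]][c("A", "B", "C")]))
    expect_true(all(v >= rng[1] & v <= rng[2]))
  }
  expect_true(all(lab$Result_String[lab$Item_Name == "Ascites"] %in%
                    c("None", "Controllable", "Uncontrollable")))
})

test_that("pigeonhole: every patient reaches at-least-2 in some grade", {
  repo <- generate_repository(generator_config(1000, seed = 77))
  best <- pmax(grade_counts_by_patient(repo, "A"),
               grade_counts_by_patient(repo, "B"),
               grade_counts_by_patient(repo, "C"))
  expect_true(all(best >= 2))
})

test_that("per-grade hit rate is consistent with the Binomial(5, 1/3) tail", {
  # P(>= 2 of 5 items in a fixed grade) = 1 - (2/3)^5 - 5*(1/3)*(2/3)^4
  p_tail <- 131 / 243
  expect_equal(p_tail, 1 - pbinom(1, 5, 1 / 3), tolerance = 1e-12)
  n <- 2000
  repo <- generate_repository(generator_config(n, seed = 8))
  for (g in c("A", "B", "C")) {
    hits <- sum(grade_counts_by_patient(repo, g) >= 2)
    expect_lt(abs(hits - n * p_tail), 3 * sqrt(n * p_tail * (1 - p_tail)))
  }
})

test_that("treatments are drawn uniformly over the five options", {
  n <- 2000
  repo <- generate_repository(generator_config(n, seed = 12))
  counts <- table(factor(repo$Treatment$Treatment_Name,
                         levels = liver_treatments()))
  expect_true(all(abs(counts - n / 5) < 3 * sqrt(n * 0.2 * 0.8)))
})

test_that("dropout removes laboratory rows only, at roughly its rate", {
  repo <- generate_repository(generator_config(400, seed = 3, dropout = 0.2))
  expect_equal(nrow(repo$Diagnosis), 400)
  expect_equal(nrow(repo$Treatment), 400)
  expect_lt(abs(nrow(repo$Laboratory) - 2000 * 0.8),
            3 * sqrt(2000 * 0.2 * 0.8))
})

test_that("SQLite and CSV exports carry the tables faithfully", {
  repo <- generate_repository(generator_config(30, seed = 6))
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_repository_db(repo, db)
  con <- repository_connect(db)
  withr::defer(DBI::dbDisconnect(con))
  expect_setequal(DBI::dbListTables(con),
                  c("Diagnosis", "Laboratory", "Treatment"))
  expect_equal(DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM Laboratory")$n, 150)

  dir <- withr::local_tempdir()
  write_repository_csv(repo, dir)
  back <- read_repository_csv(dir)
  expect_equal(back$Diagnosis, repo$Diagnosis)
  expect_equal(back$Treatment, repo$Treatment)
  expect_equal(back$Laboratory$Result_Number, repo$Laboratory$Result_Number)
  expect_equal(back$Laboratory$Result_String, repo$Laboratory$Result_String)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(0), "positive integer")
  expect_error(generator_config(10, grade_probabilities = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(generator_config(10, dropout = 1), "dropout")
})
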