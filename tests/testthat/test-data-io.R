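test_that("prevalent diabetes is excluded at the fasting-glucose threshold", {
  toy <- toy_cohort()
  cohort <- toy$cohort
  cohort$fbg_baseline <- c(126, 90, 125.9)
  res <- apply_exclusions(cohort, toy$intake, 0, 1)
  expect_equal(res$log$id, "a")
  expect_equal(res$log$reason, "prevalent_diabetes")
  expect_setequal(res$cohort$id, c("b", "c"))

  cohort2 <- toy$cohort
  cohort2$on_antidiabetic_meds <- c(FALSE, TRUE, FALSE)
  res2 <- apply_exclusions(cohort2, toy$intake, 0, 1)
  expect_equal(res2$log$reason, "prevalent_diabetes")
  expect_equal(res2$log$id, "b")
})

test_that("energy trimming removes exactly the tail observations", {
  set.seed(99)
  n <- 1000
  energy <- sample(seq(1000, 3000, length.out = n))  # distinct values
  cohort <- tibble::tibble(
    id = sprintf("p%04d", 1:n), education_high = 1, exercise_regular = 0,
    smoking = "never", alcohol = 0, bmi = 24, fbg_baseline = 90,
    on_antidiabetic_meds = FALSE
  )
  intake <- tibble::tibble(id = cohort$id, visit = 1L, energy = energy,
                           food_rice = 1)
  res <- apply_exclusions(cohort, intake)
  # brute-force oracle: sort and count values at/beyond the percentile band
  band <- quantile(energy, c(0.005, 0.995), type = 7, names = FALSE)
  oracle_removed <- sort(cohort$id[energy <= band[1] | energy >= band[2]])
  expect_equal(length(oracle_removed), 10)
  expect_equal(sort(res$log$id), oracle_removed)
  expect_true(all(res$log$reason == "energy_outlier"))
})

test_that("exclusion is idempotent and ordered", {
  toy <- toy_cohort()
  cohort <- toy$cohort
  cohort$fbg_baseline <- c(130, 90, 95)
  cohort$bmi[2] <- NA
  res1 <- apply_exclusions(cohort, toy$intake, 0, 1)
  # meds/FBG outranks missing covariate; missing covariate still logged for b
  expect_equal(res1$log$reason[res1$log$id == "a"], "prevalent_diabetes")
  expect_equal(res1$log$reason[res1$log$id == "b"], "missing_covariate")
  res2 <- apply_exclusions(res1$cohort, toy$intake, 0, 1)
  expect_equal(nrow(res2$log), 0)
  expect_identical(res2$cohort$id, res1$cohort$id)
})

test_that("everything excluded raises an explicit error", {
  toy <- toy_cohort()
  cohort <- toy$cohort
  cohort$on_antidiabetic_meds <- TRUE
  expect_error(apply_exclusions(cohort, toy$intake, 0, 1),
               class = "dccn_empty_cohort_error")
})

test_that("cumulative averages honor the diagnosis cutoff", {
  intake <- tibble::tibble(
    id = rep("a", 3), visit = 1:3, energy = c(1500, 1600, 1700),
    food_rice = c(1, 2, 3)
  )
  no_dx <- tibble::tibble(id = "a", diagnosis_visit = NA_integer_)
  expect_equal(cumulative_average(intake, no_dx, "multi_visit")$food_rice, 2)

  dx3 <- tibble::tibble(id = "a", diagnosis_visit = 3L)
  got <- cumulative_average(
    dplyr::mutate(intake, food_rice = c(1, 2, 4)), dx3, "multi_visit"
  )
  expect_equal(got$food_rice, 1.5)

  two <- intake[1:2, ]
  dx2 <- tibble::tibble(id = "a", diagnosis_visit = 2L)
  expect_equal(
    cumulative_average(two, dx2, "baseline_plus_one")$food_rice, 1
  )
  expect_equal(
    cumulative_average(two, no_dx, "baseline_plus_one")$food_rice, 1.5
  )
})

test_that("cumulative averaging ignores visit order and post-diagnosis visits", {
  set.seed(5)
  intake <- tibble::tibble(
    id = rep("a", 4), visit = 1:4, energy = rnorm(4, 1500, 50),
    food_rice = c(2, 8, 5, 100)
  )
  cohort <- tibble::tibble(id = "a", diagnosis_visit = 4L)
  base <- cumulative_average(intake, cohort, "multi_visit")
  perm <- intake[c(3, 1, 2, 4), ]
  expect_equal(cumulative_average(perm, cohort, "multi_visit"), base)
  expect_equal(base$food_rice, mean(c(2, 8, 5)))
})

test_that("a participant with no eligible visit raises an error", {
  intake <- tibble::tibble(id = "a", visit = 2L, energy = 1500,
                           food_rice = 1)
  cohort <- tibble::tibble(id = "a", diagnosis_visit = 1L)
  expect_error(cumulative_average(intake, cohort, "multi_visit"),
               "eligible", class = "dccn_input_error")
})

test_that("cohort files round-trip and invalid inputs are named", {
  toy <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  full <- dplyr::left_join(toy$intake, toy$cohort, by = "id")
  readr::write_csv(full, path)
  got <- read_cohort(path)
  expect_setequal(got$cohort$id, toy$cohort$id)
  expect_equal(nrow(got$intake), 6)
  expect_setequal(names(got$intake),
                  c("id", "visit", "energy", "food_rice", "food_veg"))

  bad <- full
  bad$food_rice[2] <- -1
  readr::write_csv(bad, path)
  expect_error(read_cohort(path), "food_rice", class = "dccn_io_error")

  dup <- dplyr::bind_rows(full, full[1, ])
  readr::write_csv(dup, path)
  expect_error(read_cohort(path), "Duplicate", class = "dccn_io_error")

  readr::write_csv(full, path)
  expect_error(read_cohort(path, food_cols = c("food_rice", "food_bread")),
               "food_bread", class = "dccn_io_error")
})

test_that("networks round-trip through edge CSV and GraphML", {
  net <- ccn(
    tibble::tibble(
      food_a = c("rice", "veg", "fish"),
      food_b = c("veg", "fish", "meat"),
      weight = c(0.512345678901, -0.33, 0.21),
      sign = c(1L, -1L, 1L),
      n_iterations_significant = c(100L, 100L, 100L)
    ),
    group = "toy"
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, csv, "edge_csv")
  back <- read_network(csv, group = "toy")
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-12)
  expect_setequal(back$nodes, net$nodes)
  expect_equal(
    names(readr::read_csv(csv, show_col_types = FALSE)),
    c("food_a", "food_b", "weight", "sign", "n_iterations_significant")
  )

  big <- ccn(net$edges, nodes = c(net$nodes, sprintf("iso%02d", 1:41)),
             group = "toy45")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(big, gml, "graphml")
  reopened <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reopened), 45)
  back2 <- read_network(gml, format = "graphml")
  expect_setequal(back2$nodes, big$nodes)
  expect_equal(
    dplyr::arrange(back2$edges[, c("food_a", "food_b", "weight")],
                   food_a, food_b),
    dplyr::arrange(big$edges[, c("food_a", "food_b", "weight")],
                   food_a, food_b),
    tolerance = 1e-12
  )
})

test_that("score tables round-trip losslessly", {
  scores <- tibble::tibble(
    id = c("a", "b"), diabetes_score = c(4.073, 0),
    non_diabetes_score = c(3.51, 0), d_ccn = c(0.563, 0)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, path)
  expect_equal(read_scores(path), scores, tolerance = 1e-12)
})
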