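test_that("adaptive cut-points follow the quartile hierarchy", {
  got <- adaptive_cutpoints(data.frame(f = c(1, 2, 3, 4)))
  expect_equal(got$cutpoint, 1.75)  # linear-interpolation Q1
  expect_equal(got$rule, "Q1")

  got2 <- adaptive_cutpoints(data.frame(f = c(0, 0, 0, 2, 3, 4, 5, 6)))
  expect_equal(got2$cutpoint, 2.5)
  expect_equal(got2$rule, "median")

  got3 <- adaptive_cutpoints(data.frame(f = c(rep(0, 6), 1, 2)))
  expect_equal(got3$rule, "Q3")
  expect_equal(got3$cutpoint, pctl(c(rep(0, 6), 1, 2), 0.75))

  got4 <- adaptive_cutpoints(data.frame(f = c(rep(0, 9), 3)))
  expect_equal(got4$rule, "any_positive")
  expect_equal(got4$cutpoint, 0)

  expect_error(adaptive_cutpoints(data.frame(f = numeric(0))),
               class = "dccn_input_error")
})

test_that("binarization is strict at the cut-point and monotone", {
  x <- data.frame(f = c(1, 2, 3, 4))
  cp <- adaptive_cutpoints(x)
  expect_equal(binarize(x, cp)$f, c(0L, 1L, 1L, 1L))
  # value exactly at the cut-point is coded 0
  expect_equal(binarize(data.frame(f = 1.75), cp)$f, 0L)
  # all-zero participant stays all zero
  y <- data.frame(f = c(rep(0, 9), 3))
  expect_equal(binarize(y, adaptive_cutpoints(y))$f, c(rep(0L, 9), 1L))
  # raising one value over the cut-point flips only that cell
  x2 <- x
  x2$f[1] <- 1.76
  expect_equal(binarize(x2, cp)$f, c(1L, 1L, 1L, 1L))
  expect_error(binarize(data.frame(g = 1), cp), "g",
               class = "dccn_input_error")
})

test_that("D_CCN is the weighted-consumption difference", {
  binary <- tibble::tibble(id = "p1", Bread = 1L, Egg = 0L, Cuttlefish = 1L)
  sc <- score_dccn(binary,
                   weights_diabetic = c(Bread = 4.073, Egg = 2.496),
                   weights_nondiabetic = c(Cuttlefish = 3.510))
  expect_equal(sc$diabetes_score, 4.073)
  expect_equal(sc$non_diabetes_score, 3.510)
  expect_equal(sc$d_ccn, 0.563)

  none <- tibble::tibble(id = "p2", Bread = 0L, Egg = 0L, Cuttlefish = 0L)
  sc0 <- score_dccn(none, c(Bread = 4.073), c(Cuttlefish = 3.510))
  expect_equal(unlist(sc0[, -1]), c(diabetes_score = 0,
                                    non_diabetes_score = 0, d_ccn = 0))

  sc2 <- score_dccn(binary, c(Bread = 2 * 4.073, Egg = 2 * 2.496),
                    c(Cuttlefish = 3.510))
  expect_equal(sc2$diabetes_score, 2 * sc$diabetes_score)
  expect_equal(sc2$non_diabetes_score, sc$non_diabetes_score)

  expect_error(score_dccn(binary, c(Unknown = 1), c(Cuttlefish = 1)),
               "Unknown", class = "dccn_input_error")
})

test_that("a food consumed by no one does not move any score", {
  set.seed(4)
  binary <- tibble::tibble(
    id = paste0("p", 1:20),
    a = rbinom(20, 1, 0.5), b = rbinom(20, 1, 0.5), never = 0L
  )
  base <- score_dccn(binary, c(a = 1.2), c(b = 0.7))
  with_never <- score_dccn(binary, c(a = 1.2, never = 9.9), c(b = 0.7))
  expect_equal(with_never$d_ccn, base$d_ccn)
})

test_that("a constant shift through a universally consumed food moves all scores equally", {
  set.seed(8)
  binary <- tibble::tibble(
    id = paste0("p", 1:40),
    everyone = 1L, a = rbinom(40, 1, 0.5), b = rbinom(40, 1, 0.4)
  )
  w_d <- c(everyone = 1.0, a = 2.0)
  w_nd <- c(b = 1.5)
  base <- score_dccn(binary, w_d, w_nd)
  shifted <- score_dccn(binary, w_d + c(everyone = 3, a = 0), w_nd)
  expect_equal(shifted$d_ccn, base$d_ccn + 3)
  expect_equal(assign_quartiles(shifted$d_ccn)$labels,
               assign_quartiles(base$d_ccn)$labels)
})

test_that("scoring is deterministic", {
  cfg <- sim_config(n_per_group = c(non_diabetic = 150, diabetic = 150),
                    n_foods = 10, seed = 31)
  intake <- generate_intake(cfg)[, c("id", sprintf("food_%02d", 1:10))]
  cp <- adaptive_cutpoints(intake)
  b <- binarize(intake, cp)
  tr <- sim_truth(cfg)
  s1 <- score_dccn(b, tr$weights_diabetic, tr$weights_nondiabetic)
  s2 <- score_dccn(binarize(intake, adaptive_cutpoints(intake)),
                   tr$weights_diabetic, tr$weights_nondiabetic)
  expect_identical(s1, s2)
})

test_that("cross-cohort transfer recomputes cut-points but keeps weights", {
  cfg <- sim_config(n_per_group = c(non_diabetic = 400, diabetic = 400),
                    n_foods = 12, seed = 15)
  intake <- generate_intake(cfg)[, c("id", sprintf("food_%02d", 1:12))]
  tr <- sim_truth(cfg)
  w_d <- c(food_01 = 1.3, food_06 = 0.8)
  w_nd <- c(food_02 = 0.9)
  direct <- score_dccn(binarize(intake, adaptive_cutpoints(intake)),
                       w_d, w_nd)
  transferred <- transfer_scores(intake, w_d, w_nd)
  expect_equal(transferred$d_ccn, direct$d_ccn)

  expect_error(
    transfer_scores(intake, c(food_99 = 1), w_nd, policy = "strict"),
    "food_99", class = "dccn_transfer_error"
  )
  expect_warning(
    dropped <- transfer_scores(intake, c(food_01 = 1.3, food_99 = 1),
                               w_nd, policy = "drop_missing"),
    "food_99"
  )
  expect_equal(
    dropped$d_ccn,
    transfer_scores(intake, c(food_01 = 1.3), w_nd)$d_ccn
  )
})

test_that("transferred scores track in-cohort-derived scores on shared structure", {
  # cohort A contributes the weights (here: the truth weights of the shared
  # planted structure); cohort B re-derives its own weights from its own
  # networks. With the same underlying structure the two scores must agree.
  cfg_b <- sim_config(seed = 62)
  tr_a <- sim_truth(sim_config(seed = 61))
  intake_b <- generate_intake(cfg_b)
  nets <- lapply(c("non_diabetic", "diabetic"), function(g) {
    d <- intake_b[intake_b$group == g, ]
    stability_edges(d[, cfg_b$foods], d[, c("energy", "sex")],
                    seed = 62, group = g)
  })
  dn <- differential(nets[[2]], nets[[1]])
  w_b <- lapply(list(dn$exclusive_a, dn$exclusive_b), function(net) {
    ct <- centralities(net)
    ct[, c("food", "integrated_centrality")]
  })
  cols <- c("id", cfg_b$foods)
  bin_b <- binarize(intake_b[, cols], adaptive_cutpoints(intake_b[, cols]))
  in_cohort <- score_dccn(bin_b, w_b[[1]], w_b[[2]])
  transferred <- transfer_scores(intake_b[, cols], tr_a$weights_diabetic,
                                 tr_a$weights_nondiabetic)
  expect_gt(cor(in_cohort$d_ccn, transferred$d_ccn), 0.9)
})
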