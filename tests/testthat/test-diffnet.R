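mk_net <- function(pairs, group, nodes = letters[1:6]) {
  ccn(tibble::tibble(food_a = pairs[[1]], food_b = pairs[[2]], weight = 0.5),
      nodes = nodes, group = group)
}

test_that("exclusive and shared edges partition the edge union", {
  a <- mk_net(list(c("a", "b"), c("b", "c")), "A")
  b <- mk_net(list(c("b", "c"), c("c", "d")), "B")
  dn <- differential(a, b)
  expect_equal(dn$exclusive_a$edges[, c("food_a", "food_b")],
               tibble::tibble(food_a = "a", food_b = "b"))
  expect_equal(dn$exclusive_b$edges[, c("food_a", "food_b")],
               tibble::tibble(food_a = "c", food_b = "d"))
  expect_equal(dn$shared_edges[, c("food_a", "food_b")],
               tibble::tibble(food_a = "b", food_b = "c"))
  # exclusive subgraph nodes are only those touching an exclusive edge
  expect_setequal(dn$exclusive_a$nodes, c("a", "b"))
  # edge-count conservation
  expect_equal(nrow(dn$exclusive_a$edges) + nrow(dn$shared_edges),
               nrow(a$edges))
  expect_equal(nrow(dn$exclusive_b$edges) + nrow(dn$shared_edges),
               nrow(b$edges))
})

test_that("identical networks have empty exclusive sets; swap is antisymmetric", {
  a <- mk_net(list(c("a", "b"), c("b", "c")), "A")
  dn_same <- differential(a, a)
  expect_equal(nrow(dn_same$exclusive_a$edges), 0)
  expect_equal(nrow(dn_same$exclusive_b$edges), 0)

  b <- mk_net(list(c("b", "c"), c("c", "d")), "B")
  fwd <- differential(a, b)
  rev <- differential(b, a)
  expect_equal(fwd$exclusive_a$edges[, 1:3], rev$exclusive_b$edges[, 1:3])
  expect_equal(fwd$exclusive_b$edges[, 1:3], rev$exclusive_a$edges[, 1:3])
})

test_that("edge identity ignores pair order and weights", {
  a <- ccn(tibble::tibble(food_a = "x", food_b = "y", weight = 0.5),
           nodes = c("x", "y", "z"))
  b <- ccn(tibble::tibble(food_a = "y", food_b = "x", weight = -0.9),
           nodes = c("x", "y", "z"))
  dn <- differential(a, b)
  expect_equal(nrow(dn$shared_edges), 1)
  expect_equal(dn$shared_edges$weight_a, 0.5)
  expect_equal(dn$shared_edges$weight_b, -0.9)
})

test_that("mismatched node universes are rejected with the difference named", {
  a <- mk_net(list("a", "b"), "A", nodes = c("a", "b"))
  b <- mk_net(list("a", "b"), "B", nodes = c("a", "b", "zz"))
  expect_error(differential(a, b), "zz", class = "dccn_input_error")
})

test_that("ego networks cover the hop neighborhood", {
  star <- ccn(tibble::tibble(food_a = "hub", food_b = paste0("l", 1:4),
                             weight = 1))
  ego <- ego_network(star, "l1", steps = 2)
  expect_setequal(ego$nodes, c("hub", paste0("l", 1:4)))
  expect_equal(nrow(ego$edges), 4)

  path <- ccn(tibble::tibble(food_a = letters[1:4], food_b = letters[2:5],
                             weight = 1))
  ego2 <- ego_network(path, "a", steps = 2)
  expect_setequal(ego2$nodes, c("a", "b", "c"))
  expect_equal(nrow(ego2$edges), 2)

  ego0 <- ego_network(path, "c", steps = 0)
  expect_equal(ego0$nodes, "c")
  expect_equal(nrow(ego0$edges), 0)

  iso <- ccn(tibble::tibble(food_a = "a", food_b = "b", weight = 1),
             nodes = c("a", "b", "lonely"))
  expect_warning(ego_iso <- ego_network(iso, "lonely"), "isolate")
  expect_equal(ego_iso$nodes, "lonely")

  expect_error(ego_network(path, "nope"), class = "dccn_input_error")
})

test_that("ego at graph diameter returns the whole connected component", {
  path <- ccn(tibble::tibble(food_a = letters[1:4], food_b = letters[2:5],
                             weight = 1),
              nodes = c(letters[1:5], "island"))
  ego <- ego_network(path, "a", steps = 4)
  expect_setequal(ego$nodes, letters[1:5])
})

test_that("graph summaries match closed forms", {
  tri <- ccn(tibble::tibble(food_a = c("a", "a", "b"),
                            food_b = c("b", "c", "c"), weight = 1))
  s <- graph_summary(tri)
  expect_equal(s$density, 1)
  expect_equal(s$clustering, 1)
  expect_equal(s$average_degree, 2)

  star <- ccn(tibble::tibble(food_a = "hub", food_b = paste0("l", 1:4),
                             weight = 1))
  s2 <- graph_summary(star)
  expect_equal(s2$density, 0.4)
  expect_equal(s2$clustering, 0)
  expect_equal(s2$average_degree, 1.6)

  single <- ccn(tibble::tibble(food_a = character(), food_b = character(),
                               weight = numeric()), nodes = "solo")
  s3 <- graph_summary(single)
  expect_true(s3$degenerate)
  expect_equal(s3$density, 0)
})

test_that("ego summaries average across focal foods", {
  net <- ccn(tibble::tibble(
    food_a = c("hub", "hub", "hub", "hub", "p", "q"),
    food_b = c("l1", "l2", "l3", "l4", "q", "r"),
    weight = 1
  ))
  # hand-built egos: hub ego has (5, 4); r ego (steps 2) has (3, 2)
  out <- summarize_egos(net, c("hub", "r"), steps = 2)
  expect_equal(out$per_ego$n_nodes, c(5, 3))
  expect_equal(out$per_ego$n_edges, c(4, 2))
  expect_equal(out$mean$n_nodes, 4)
  expect_equal(out$mean$n_edges, 3)
})
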