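test_that("minimal topology is forced by the connectivity invariants", {
  g <- generate_planted_grn(1, 1, 2, mean_out_degree = 1, seed = 7)
  expect_equal(sum(g$edges$layer_pair == "1->2"), 1)
  expect_equal(sum(g$edges$layer_pair == "2->3"), 2)
})

test_that("study-scale topology has the expected gene and sample counts", {
  g <- generate_planted_grn(11, 19, 158, mean_out_degree = 10, seed = 1)
  expect_length(g$layer1_ids, 11)
  expect_length(g$layer2_ids, 19)
  expect_length(g$layer3_ids, 158)
  em <- simulate_time_course(g, simulation_config(seed = 1))
  expect_equal(dim(em$values), c(188, 21))
})

test_that("generation and simulation are pure functions of the seed", {
  g1 <- generate_planted_grn(4, 6, 30, mean_out_degree = 4, seed = 42)
  g2 <- generate_planted_grn(4, 6, 30, mean_out_degree = 4, seed = 42)
  expect_identical(g1$edges, g2$edges)
  e1 <- simulate_time_course(g1, simulation_config(seed = 9))
  e2 <- simulate_time_course(g2, simulation_config(seed = 9))
  expect_identical(e1$values, e2$values)
  e3 <- simulate_time_course(g1, simulation_config(seed = 10))
  expect_false(identical(e1$values, e3$values))
})

test_that("generated hierarchies satisfy the structural invariants", {
  for (s in 1:8) {
    n1 <- 2 + s %% 4; n2 <- 3 + s %% 5; n3 <- 10 + 3 * s
    g <- generate_planted_grn(n1, n2, n3, mean_out_degree = 3, seed = s)
    # the constructor validates all invariants; additionally re-check the
    # degree conditions independently
    e12 <- g$edges[g$edges$layer_pair == "1->2", ]
    e23 <- g$edges[g$edges$layer_pair == "2->3", ]
    expect_setequal(unique(e12$regulator), g$layer1_ids)
    expect_true(all(g$layer2_ids %in% e12$target))
    expect_true(all(g$layer2_ids %in% e23$regulator))
    expect_setequal(unique(e23$target), g$layer3_ids)
    expect_true(all(g$edges$weight != 0))
    expect_true(all(abs(g$edges$weight) >= 0.5 & abs(g$edges$weight) <= 1.5))
  }
})

test_that("mean out-degree is approximately met and bounds are enforced", {
  g <- generate_planted_grn(5, 10, 60, mean_out_degree = 8, seed = 2)
  expect_equal(nrow(g$edges), round(8 * 15))
  # when the requested density is below the forced-connectivity minimum,
  # the minimum wins
  g2 <- generate_planted_grn(5, 10, 60, mean_out_degree = 5, seed = 2)
  expect_gte(nrow(g2$edges), 10 * min(3, 5) + 60)
  expect_error(generate_planted_grn(2, 2, 4, mean_out_degree = 50, seed = 1),
               "exceeds the maximum")
  expect_error(generate_planted_grn(0, 2, 4, mean_out_degree = 1, seed = 1))
})

test_that("noiseless propagation is exactly linear with unit correlations", {
  # two structural genes sharing their sole parent, opposite weight signs
  g <- planted_grn("a", "u", c("x", "y"),
                   data.frame(regulator = c("a", "u", "u"),
                              target = c("u", "x", "y"),
                              weight = c(1, 0.7, -1.3)))
  em <- simulate_time_course(g, simulation_config(noise_sd = 0, seed = 5))
  v <- em$values
  expect_equal(cor(v["x", ], v["u", ]), 1)
  expect_equal(cor(v["y", ], v["u", ]), -1)
  expect_equal(cor(v["x", ], v["y", ]), -1)
  # replicates are identical at zero noise
  expect_identical(v[, "t0h_r1"], v[, "t0h_r2"], ignore_attr = TRUE)
})

test_that("simulation rejects configs with fewer than 3 time points", {
  expect_error(simulation_config(time_points = c(0, 1)), "3 time points")
})

test_that("pattern drivers produce the three archetype profiles", {
  g <- generate_planted_grn(3, 4, 10, mean_out_degree = 3, seed = 1)
  em <- simulate_time_course(g, simulation_config(noise_sd = 0, seed = 1),
                             pattern_drivers = TRUE)
  v <- em$values[g$layer1_ids, em$sample_meta$replicate == 1]
  # archetype 1 rises early then falls below its start; 2 is its mirror
  expect_equal(unname(v[2, ]), unname(-v[1, ]))
  expect_gt(v[1, 2], v[1, 1])
  expect_lt(v[1, 7], v[1, 1])
})

test_that("recovery scoring does plain set arithmetic with sentinels", {
  g <- generate_planted_grn(2, 3, 10, mean_out_degree = 3, seed = 11)
  as_inferred <- function(edges) {
    hierarchical_grn(g$layer1_ids, g$layer2_ids, g$layer3_ids,
                     data.frame(source = edges$regulator,
                                target = edges$target,
                                layer_pair = edges$layer_pair,
                                n_support = 1L))
  }
  sc <- score_recovery(g, as_inferred(g$edges))
  expect_equal(sc$precision, c(1, 1))
  expect_equal(sc$recall, c(1, 1))
  expect_equal(sc$f1, c(1, 1))

  # drop one 2->3 edge: recall falls by exactly 1/n, precision stays 1
  e23 <- which(g$edges$layer_pair == "2->3")
  keep <- g$edges[-e23[1], ]
  sc2 <- score_recovery(g, as_inferred(keep))
  expect_equal(sc2$precision[2], 1)
  expect_equal(sc2$recall[2], (length(e23) - 1) / length(e23))

  # empty inferred set: NaN precision sentinel, zero recall
  empty <- hierarchical_grn(character(0), character(0), character(0),
                            data.frame(source = character(0),
                                       target = character(0),
                                       layer_pair = character(0),
                                       n_support = integer(0)))
  sc3 <- score_recovery(g, empty)
  expect_true(all(is.nan(sc3$precision)))
  expect_equal(sc3$recall, c(0, 0))
})

test_that("edge recall degrades with noise (20-seed average)", {
  recall_at <- function(noise_sd) {
    mean(vapply(1:20, function(s) {
      g <- generate_planted_grn(5, 8, 40, mean_out_degree = 4, seed = s)
      em <- simulate_time_course(g, simulation_config(noise_sd = noise_sd,
                                                      seed = s))
      grn <- suppressMessages(suppressWarnings(
        assemble_three_layer_grn(em, c(g$layer1_ids, g$layer2_ids),
                                 g$layer3_ids)))
      score_recovery(g, grn)$recall[2]
    }, numeric(1)))
  }
  expect_gte(recall_at(0.05), recall_at(1.0))
})
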