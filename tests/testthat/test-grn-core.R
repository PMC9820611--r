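test_that("pearson_with_p matches the closed-form definitions", {
  x <- as.numeric(1:7)
  expect_equal(pearson_with_p(x, x), list(r = 1, p = 0))
  expect_equal(pearson_with_p(x, -x), list(r = -1, p = 0))

  y <- c(2, 1, 4, 3, 6, 5, 8)
  got <- pearson_with_p(x, y)
  oracle <- pearson_oracle(x, y)
  expect_equal(got$r, oracle$r, tolerance = 1e-12)
  expect_equal(got$p, oracle$p, tolerance = 1e-12)

  expect_error(pearson_with_p(c(1, 1, 1), x[1:3], x_name = "gZ"), "gZ")
  expect_error(pearson_with_p(1:2, 2:3), "n >= 3")
})

test_that("partial correlation follows the first-order formula", {
  expect_equal(partial_correlation(0.64, 0.8, 0.8), 0)
  expect_equal(partial_correlation(0.9, 0, 0), 0.9)
  expect_equal(partial_correlation(0.9, 0.8, 0.7),
               (0.9 - 0.56) / sqrt(0.36 * 0.51), tolerance = 1e-12)
  expect_error(partial_correlation(0.5, 1, 0.2), "degenerate conditioning")
  expect_error(partial_correlation(0.5, 0.2, -1), "degenerate conditioning")
  expect_error(partial_correlation(1.2, 0, 0), "\\[-1, 1\\]")
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
    res_x <- residuals(lm(x ~ z))
    res_y <- residuals(lm(y ~ z))
    expect_equal(partial_correlation(r_xy, r_xz, r_yz), cor(res_x, res_y),
                 tolerance = 1e-10)
    # exchange symmetry of the two conditioning correlations
    expect_equal(partial_correlation(r_xy, r_xz, r_yz),
                 partial_correlation(r_xy, r_yz, r_xz))
  }
})

test_that("co-expressed pair screening honours the >= threshold", {
  set.seed(5)
  base <- rnorm(21)
  v <- rbind(g1 = base, g2 = base, g3 = rnorm(21))
  em <- make_expr(v)
  pairs <- find_coexpressed_pairs(em, c("g1", "g2", "g3"))
  expect_equal(pairs$x, "g1")
  expect_equal(pairs$y, "g2")
  expect_equal(pairs$r_xy, 1)

  # the gate is inclusive: a pair exactly at r_min is returned
  r_13 <- cor(v["g1", ], v["g3", ])
  p_13 <- find_coexpressed_pairs(em, c("g1", "g3"),
                                 grn_params(r_min = abs(r_13) - 1e-12,
                                            p_max = 0.999,
                                            partial_max = 0,
                                            use_absolute_r = TRUE))
  p_13_incl <- find_coexpressed_pairs(em, c("g1", "g3"),
                                      grn_params(r_min = abs(r_13),
                                                 p_max = 0.999,
                                                 partial_max = 0,
                                                 use_absolute_r = TRUE))
  expect_equal(nrow(p_13), 1)
  expect_equal(nrow(p_13_incl), 1)

  expect_error(find_coexpressed_pairs(em, c("g1", "nope")), "nope")
})

test_that("pair screening agrees with a brute-force all-pairs scan", {
  set.seed(8)
  v <- matrix(rnorm(10 * 21), nrow = 10,
              dimnames = list(sprintf("n%02d", 1:10), NULL))
  em <- make_expr(v)
  params <- grn_params(r_min = 0.5, p_max = 0.05, partial_max = 0.3)
  got <- find_coexpressed_pairs(em, rownames(v), params)
  # oracle: exhaustive double loop with the closed-form test
  found <- list()
  ids <- sort(rownames(v))
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    o <- pearson_oracle(v[ids[i], ], v[ids[j], ])
    if (o$r >= params$r_min && o$p < params$p_max) {
      found[[length(found) + 1]] <- c(ids[i], ids[j])
    }
  }
  expect_equal(nrow(got), length(found))
  if (length(found) > 0) {
    expect_equal(got$x, vapply(found, `[`, "", 1))
    expect_equal(got$y, vapply(found, `[`, "", 2))
  }
  # default study thresholds on independent noise: typically empty
  strict <- find_coexpressed_pairs(em, rownames(v), grn_params())
  expect_equal(nrow(strict), 0)
})

test_that("regulator attribution keeps all passing triples and no self-triples", {
  # x, y sole children of z; w independent of everything
  g <- planted_grn("a", "z", c("x", "y"),
                   data.frame(regulator = c("a", "z", "z"),
                              target = c("z", "x", "y"),
                              weight = c(1, 1, 0.9)))
  em0 <- simulate_time_course(g, simulation_config(noise_sd = 0.05, seed = 2))
  set.seed(99)
  v <- rbind(em0$values, w = rnorm(21))
  em <- make_expr(v)
  pairs <- find_coexpressed_pairs(em, c("x", "y"))
  expect_equal(nrow(pairs), 1)
  tr <- attribute_pairs_to_regulators(pairs, c("z", "w", "x"), em)
  expect_false(any(tr$z %in% c("x", "y")))
  # conditioning on the true parent collapses most of the pair correlation;
  # its own measurement noise leaves a residual partial correlation near
  # 1/2 (errors-in-variables floor), far below the raw r_xy
  z_row <- tr[tr$z == "z", ]
  expect_equal(tr$r_xy_given_z[tr$z == "z"],
               partial_correlation(z_row$r_xy, z_row$r_xz, z_row$r_yz))
  expect_lt(abs(z_row$r_xy_given_z), 0.65)
  expect_lt(abs(z_row$r_xy_given_z), z_row$r_xy - 0.3)
  # an independent conditioner leaves the pair correlation untouched
  w_row <- tr[tr$z == "w", ]
  expect_false(w_row$passes)
  expect_equal(w_row$r_xy_given_z, w_row$r_xy, tolerance = 0.35)
  # with the parent observed noise-free, conditioning cancels exactly-ish
  v2 <- v
  v2["z", ] <- rep(colMeans(matrix(v["z", ], nrow = 3)), each = 3)  # denoise
  # replicate mean as a less noisy conditioner shrinks the partial
  em2 <- make_expr(v2)
  tr2 <- attribute_pairs_to_regulators(pairs, "z", em2)
  expect_lt(abs(tr2$r_xy_given_z), abs(z_row$r_xy_given_z) + 0.1)

  expect_equal(nrow(attribute_pairs_to_regulators(pairs, character(0), em)),
               0)
})

test_that("edge materialisation merges duplicates and counts support", {
  triple <- function(x, y, z, pr = 0.1) {
    data.frame(x = x, y = y, z = z, r_xy = 0.9, p_xy = 1e-5, r_xz = 0.9,
               r_yz = 0.9, r_xy_given_z = pr, passes = TRUE,
               stringsAsFactors = FALSE)
  }
  one <- edges_from_triples(triple("x", "y", "z"))
  expect_equal(nrow(one), 2)
  expect_setequal(one$target, c("x", "y"))
  expect_equal(one$source, c("z", "z"))

  two <- edges_from_triples(rbind(triple("x", "y", "z"),
                                  triple("x", "w", "z", pr = 0.05)))
  expect_equal(nrow(two), 3)
  expect_equal(two$n_support[two$target == "x"], 2L)
  expect_equal(two$partial_r[two$target == "x"], 0.05)  # strongest support

  empty <- edges_from_triples(triple("x", "y", "z")[0, ])
  expect_equal(nrow(empty), 0)

  bad <- triple("x", "y", "z"); bad$passes <- FALSE
  expect_error(edges_from_triples(bad), "passing triples only")
})

test_that("the noiseless chain is assembled into the expected layers", {
  g <- chain_grn()
  em <- simulate_time_course(g, simulation_config(noise_sd = 0, seed = 1))
  grn <- suppressMessages(suppressWarnings(
    assemble_three_layer_grn(em, c("z1", "z2"), c("s1", "s2"))))
  expect_true("z2" %in% grn$layer2)
  expect_setequal(grn$layer3, c("s1", "s2"))
  e23 <- grn$edges[grn$edges$layer_pair == "2->3", ]
  expect_true(all(c("s1", "s2") %in% e23$target[e23$source == "z2"]))
})

test_that("independent structural genes yield an empty network", {
  set.seed(21)
  v <- matrix(rnorm(8 * 21), nrow = 8,
              dimnames = list(c(sprintf("s%d", 1:6), "tfA", "tfB"), NULL))
  em <- make_expr(v)
  grn <- suppressMessages(suppressWarnings(
    assemble_three_layer_grn(em, c("tfA", "tfB"), sprintf("s%d", 1:6))))
  expect_equal(nrow(grn$edges), 0)
  expect_length(grn$layer1, 0)
  expect_length(grn$layer2, 0)
  expect_length(grn$layer3, 0)
})

test_that("assembly rejects overlapping TF and structural sets", {
  em <- make_expr(matrix(rnorm(3 * 9), nrow = 3,
                         dimnames = list(c("a", "b", "c"), NULL)),
                  tp = c(0, 1, 3))
  expect_error(assemble_three_layer_grn(em, c("a", "b"), c("b", "c")),
               "disjoint")
})

test_that("assembly is deterministic and invariant to gene input order", {
  g <- generate_planted_grn(4, 6, 30, mean_out_degree = 4, seed = 13)
  em <- simulate_time_course(g, simulation_config(noise_sd = 0.1, seed = 13))
  tfs <- c(g$layer1_ids, g$layer2_ids)
  a <- suppressMessages(suppressWarnings(
    assemble_three_layer_grn(em, tfs, g$layer3_ids)))
  b <- suppressMessages(suppressWarnings(
    assemble_three_layer_grn(em, rev(tfs), sample(g$layer3_ids))))
  expect_identical(a$edges, b$edges)
  expect_identical(a$layer1, b$layer1)
  expect_identical(a$layer2, b$layer2)
})

test_that("relaxing partial_max only adds edges; raising r_min only removes pairs", {
  g <- generate_planted_grn(3, 5, 25, mean_out_degree = 4, seed = 17)
  em <- simulate_time_course(g, simulation_config(noise_sd = 0.3, seed = 17))
  tfs <- c(g$layer1_ids, g$layer2_ids)
  edge_keys <- function(pm) {
    grn <- suppressMessages(suppressWarnings(assemble_three_layer_grn(
      em, tfs, g$layer3_ids, grn_params(partial_max = pm))))
    paste(grn$edges$source, grn$edges$target)
  }
  loose <- edge_keys(0.5)
  tight <- edge_keys(0.2)
  expect_true(all(tight %in% loose))

  pair_count <- function(rm) {
    nrow(find_coexpressed_pairs(em, g$layer3_ids,
                                grn_params(r_min = rm, p_max = 0.01,
                                           partial_max = 0.1)))
  }
  expect_gte(pair_count(0.6), pair_count(0.8))
  expect_gte(pair_count(0.8), pair_count(0.95))
})

test_that("every edge's supporting triples pass and share its source", {
  g <- generate_planted_grn(3, 5, 25, mean_out_degree = 4, seed = 23)
  em <- simulate_time_course(g, simulation_config(noise_sd = 0.1, seed = 23))
  grn <- suppressMessages(suppressWarnings(assemble_three_layer_grn(
    em, c(g$layer1_ids, g$layer2_ids), g$layer3_ids)))
  expect_true(all(grn$triples$passes))
  for (i in seq_len(nrow(grn$edges))) {
    e <- grn$edges[i, ]
    support <- grn$triples[grn$triples$z == e$source &
                             (grn$triples$x == e$target |
                                grn$triples$y == e$target), ]
    expect_gte(nrow(support), 1)
    expect_equal(e$n_support, nrow(support))
  }
  expect_equal(nrow(grn$edges),
               sum(grn$edges$layer_pair == "1->2") +
                 sum(grn$edges$layer_pair == "2->3"))
})

test_that("network summaries do exact bookkeeping with percentage rounding", {
  l2 <- sprintf("m%02d", 1:5)
  l3 <- sprintf("s%03d", 1:158)
  edges <- data.frame(source = rep(l2, length.out = 158), target = l3,
                      layer_pair = "2->3", n_support = 1L)
  grn <- hierarchical_grn(character(0), l2, l3, edges)
  ann <- data.frame(
    gene_id = l3[1:45],
    term_id = rep(c("response to jasmonic acid", "response to ethylene",
                    "ethylene-activated signaling pathway"),
                  length.out = 45))
  s <- summarize_grn(grn, ann,
                     subset_terms = unique(ann$term_id))
  expect_equal(s$n_edges_23, 158)
  expect_equal(s$n_edges_total, 158)
  expect_equal(s$subset_pct, 28.5)   # 45 of 158 bottom-layer genes
  expect_equal(sum(s$go_composition$count), 45)

  empty <- hierarchical_grn(character(0), character(0), character(0),
                            edges[0, ])
  s0 <- summarize_grn(empty, ann, go_terms = unique(ann$term_id),
                      subset_terms = unique(ann$term_id))
  expect_equal(s0$n_edges_total, 0)
  expect_true(is.nan(s0$subset_pct))
})
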