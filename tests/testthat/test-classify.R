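test_that("the PD / T / NPD / OTHER definitions are honoured", {
  map <- two_map()
  expect_equal(classify_interval(c("CY", "CY", "-", "-"), map, c("A", "B")), "PD")
  expect_equal(classify_interval(c("CY", "C", "Y", "-"), map, c("A", "B")), "T")
  expect_equal(classify_interval(c("C", "C", "Y", "Y"), map, c("A", "B")), "NPD")
  # 3:1 segregation is impossible for a true tetrad from a coupling het
  expect_equal(classify_interval(c("CY", "CY", "CY", "-"), map, c("A", "B")), "OTHER")
  expect_equal(classify_interval(c("C", "C", "C", "Y"), map, c("A", "B")), "OTHER")
})

test_that("classification is invariant to grain order and channel letter order", {
  map <- two_map()
  g <- c("CY", "C", "Y", "-")
  set.seed(1)
  for (i in 1:10)
    expect_equal(classify_interval(sample(g), map, c("A", "B")), "T")
  expect_equal(classify_interval(c("YC", "C", "Y", "-"), map, c("A", "B")), "T")
})

test_that("unknown channel labels and bad pairs are rejected", {
  map <- two_map()
  expect_error(classify_interval(c("CX", "C", "Y", "-"), map, c("A", "B")),
               "unknown channel")
  expect_error(classify_interval(c("CY", "C", "Y", "-"), map, c("A", "Z")),
               "unknown markers")
  expect_error(classify_interval(c("CY", "C", "Y"), map, c("A", "B")),
               "4 grains")
})

test_that("tabulation conserves tetrads and partitions exactly by group", {
  map <- two_map()
  td <- tetrads_from_grains(list(
    c("CY", "CY", "-", "-"), c("CY", "C", "Y", "-"), c("CY", "CY", "-", "-"),
    c("C", "C", "Y", "Y"), c("CY", "CY", "CY", "-")), map)
  td$temperature <- c("20C", "20C", "28C", "28C", "28C")
  pooled <- tabulate_tetrads(td, c("A", "B"), group_by = NULL)
  expect_equal(pooled$PD + pooled$T + pooled$NPD + pooled$OTHER, nrow(td))
  expect_equal(pooled$n, pooled$PD + pooled$T + pooled$NPD)
  expect_equal(unname(unlist(pooled[c("PD", "T", "NPD", "OTHER")])),
               c(2L, 1L, 1L, 1L))
  by_temp <- tabulate_tetrads(td, c("A", "B"), group_by = "temperature")
  expect_equal(sum(by_temp$PD), pooled$PD)
  expect_equal(sum(by_temp$n) + sum(by_temp$OTHER), nrow(td))
})

test_that("an empty dataset tabulates to all-zero counts", {
  map <- two_map()
  td <- tetrads_from_grains(list(c("CY", "CY", "-", "-")), map)[0, ]
  class(td) <- c("tetrad_data", "data.frame")
  attr(td, "marker_map") <- map
  tab <- tabulate_tetrads(td, c("A", "B"), group_by = NULL)
  expect_equal(unname(unlist(tab[c("PD", "T", "NPD", "OTHER", "n")])),
               rep(0L, 5))
})

test_that("three-colour projection is consistent across nested intervals", {
  # an NPD tetrad in the outer pair cannot be PD in both inner pairs
  cfg <- sim_config(n_meioses = 3000, interference_shape = 1, seed = 11)
  map <- three_map()
  td <- simulate_tetrad_dataset(cfg, map)
  gm <- as.matrix(td[, paste0("grain", 1:4)])
  outer <- ftlmap:::classify_vec(gm, "C", "R")
  in1 <- ftlmap:::classify_vec(gm, "C", "Y")
  in2 <- ftlmap:::classify_vec(gm, "Y", "R")
  expect_false(any(outer == "NPD" & in1 == "PD" & in2 == "PD"))
})

test_that("adjacent-interval partitioning follows the T/NPD conditioning rule", {
  map <- three_map()
  td <- tetrads_from_grains(list(
    c("CYR", "CYR", "-", "-"),   # PD everywhere -> wo, test PD
    c("CYR", "CY", "R", "-"),    # cond (B,C) T, test (A,B) PD -> wi
    c("CY", "CYR", "R", "-"),    # cond T, test PD -> wi
    c("CYR", "C", "YR", "-"),    # cond PD, test T -> wo
    c("CYR", "CYR", "CYR", "-")  # OTHER in conditioning -> dropped
  ), map)
  part <- partition_by_adjacent(td, c("A", "B"), c("B", "C"))
  expect_equal(part$wo$n, 2L)
  expect_equal(part$wi$n, 2L)
  expect_equal(part$wi$PD, 2L)
  expect_equal(part$wo$T, 1L)
  expect_equal(part$n_dropped, 1L)
  # no conditioning crossover at all -> empty wi partition
  td2 <- td[1, , drop = FALSE]
  class(td2) <- c("tetrad_data", "data.frame")
  attr(td2, "marker_map") <- map
  part2 <- partition_by_adjacent(td2, c("A", "B"), c("B", "C"))
  expect_equal(part2$wi$n, 0L)
  expect_error(partition_by_adjacent(td, c("A", "B"), c("A", "B")), "adjacent")
})

test_that("without interference the conditioned distances agree", {
  cfg <- sim_config(n_meioses = 20000, interference_shape = 1, seed = 12)
  td <- simulate_tetrad_dataset(cfg, three_map())
  fit <- interference_ratio(partition_by_adjacent(td, c("A", "B"), c("B", "C")))
  expect_lt(abs(fit$R - 1), 3 * sqrt(fit$Var_R))
})
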