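test_that("a single discordant pair differing in one box gives one unit edge", {
  dat <- tibble::tibble(
    x1 = c(0L, 1L), x2 = c(0L, 1L),  # box 1 differs: codes 1 and 4
    x3 = c(1L, 1L), x4 = c(0L, 0L),  # box 2 identical
    y = c(0L, 1L)
  )
  g <- conflict_graphs(dat, c(2, 2))
  expect_identical(g[[1]]$W[1, 4], 1L)
  expect_identical(sum(g[[1]]$W), 2L)  # the one edge, both orientations
  expect_identical(sum(g[[2]]$W), 0L)
  expect_identical(total_conflict_mass(g), 1)

  # same rows, equal labels: no conflict anywhere
  dat$y <- c(1L, 1L)
  g2 <- conflict_graphs(dat, c(2, 2))
  expect_identical(total_conflict_mass(g2), 0)
})

test_that("pairs differing in zero or several boxes contribute nothing", {
  # identical features, discordant labels (possible after noise):
  # differ in zero boxes, must be ignored
  dup <- tibble::tibble(x1 = c(1L, 1L), x2 = c(0L, 0L),
                        x3 = c(1L, 1L), x4 = c(1L, 1L), y = c(0L, 1L))
  expect_identical(total_conflict_mass(conflict_graphs(dup, c(2, 2))), 0)
  # both boxes differ: excluded by the exactly-one-box condition
  two <- tibble::tibble(x1 = c(0L, 1L), x2 = c(0L, 0L),
                        x3 = c(0L, 0L), x4 = c(0L, 1L), y = c(0L, 1L))
  expect_identical(total_conflict_mass(conflict_graphs(two, c(2, 2))), 0)
})

test_that("grouped accumulation equals the naive all-pairs scan", {
  st <- fn_structure(c(3, 2, 2))
  # the full worked-example enumeration, clean and noisy
  dat <- enumerate_dataset(example_network())
  for (q in c(0, 0.1)) {
    noisy <- if (q > 0) flip_labels(dat, q, seed = 11) else dat
    fast <- conflict_graphs(noisy, st)
    slow <- naive_conflict_graphs(noisy, st)
    for (m in 1:3) expect_identical(fast[[m]]$W, slow[[m]])
  }
  # random (non-network) datasets of growing size, including S = 512
  for (S in c(16, 64, 200, 512)) {
    dat <- random_binary_dataset(S, 7, seed = S)
    fast <- conflict_graphs(dat, st)
    slow <- naive_conflict_graphs(dat, st)
    for (m in 1:3) expect_identical(fast[[m]]$W, slow[[m]])
    expect_identical(total_conflict_mass(fast),
                     sum(vapply(slow, sum, double(1))) / 2)
  }
})

test_that("weight matrices are symmetric with zero diagonal, always", {
  for (s in 1:5) {
    dat <- random_binary_dataset(100, 6, seed = s)
    for (g in conflict_graphs(dat, c(2, 2, 2))) {
      expect_identical(g$W, t(g$W))
      expect_true(all(diag(g$W) == 0L))
      expect_true(all(g$W >= 0L))
    }
  }
})

test_that("label noise increases the expected conflict mass", {
  dat <- enumerate_dataset(example_network())
  clean_mass <- total_conflict_mass(conflict_graphs(dat, c(3, 2, 2)))
  noisy_masses <- vapply(1:5, function(s) {
    total_conflict_mass(
      conflict_graphs(flip_labels(dat, 0.1, seed = s), c(3, 2, 2))
    )
  }, double(1))
  expect_gt(mean(noisy_masses), clean_mass)
})

test_that("the edge-list dump matches the matrices", {
  dat <- enumerate_dataset(example_network())
  g <- conflict_graphs(dat, c(3, 2, 2))
  edges <- conflict_edges(g)
  expect_true(all(edges$k < edges$l))
  expect_identical(as.numeric(sum(edges$weight)), total_conflict_mass(g))
  one <- edges[edges$box == 1, ][1, ]
  expect_identical(g[[1]]$W[one$k, one$l], as.integer(one$weight))
})

test_that("shape errors are reported", {
  dat <- random_binary_dataset(10, 5, seed = 1)
  expect_error(conflict_graphs(dat, c(3, 3)), "Expected 6 feature columns")
  expect_error(conflict_graphs(dat[0, ], c(3, 2)), "empty")
})
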