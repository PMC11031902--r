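test_that("random structures are valid compositions within the bounds", {
  st <- random_structure(7, 3, 2, 3, seed = 4)
  expect_identical(sum(st$n_input_each_box), 7L)
  expect_true(all(st$n_input_each_box %in% 2:3))

  expect_identical(random_structure(6, 3, 2, 2, seed = 1)$n_input_each_box,
                   c(2L, 2L, 2L))

  for (s in 1:10) {
    st <- random_structure(12, 3, 2, 6, seed = s)
    expect_identical(sum(st$n_input_each_box), 12L)
    expect_true(all(st$n_input_each_box >= 2 & st$n_input_each_box <= 6))
  }

  expect_error(random_structure(20, 3, 2, 6), "No composition")
})

test_that("random networks respect the class-balance window and the seed", {
  st <- random_structure(8, 3, 2, 4, seed = 2)
  for (s in 1:8) {
    fn <- random_network(st, seed = s)
    frac <- mean(enumerate_dataset(fn)$y)
    expect_gte(frac, 0.1875)
    expect_lte(frac, 0.8125)
  }
  expect_identical(random_network(st, seed = 3), random_network(st, seed = 3))
  # a [0, 1] window accepts the very first draw
  fn_any <- random_network(st, balance_window = c(0, 1), seed = 3,
                           max_retries = 1)
  expect_s3_class(fn_any, "functional_network")
  expect_error(random_network(st, balance_window = c(0.0001, 0.0002),
                              seed = 1, max_retries = 2),
               "after 2 draws")
})

test_that("enumerated datasets cover every input code exactly once", {
  for (d in c(6, 8, 10)) {
    st <- random_structure(d, 3, 2, 4, seed = d)
    fn <- random_network(st, seed = d)
    dat <- enumerate_dataset(fn)
    expect_identical(nrow(dat), as.integer(2^d))
    codes <- as.integer(
      1 + as.matrix(dat[paste0("x", 1:d)]) %*% 2^(0:(d - 1))
    )
    expect_identical(sort(codes), seq_len(2^d))
    expect_identical(dat$y, predict(fn, dat))
  }
})

test_that("the benchmark suite has the documented shape", {
  suite <- make_benchmark_suite(seed = 1)
  expect_identical(nrow(suite), 30L)
  expect_identical(sort(unique(suite$d)), 8:12)
  expect_true(all(table(suite$d) == 6))
  sizes <- unlist(suite$n_input_each_box)
  expect_true(all(lengths(suite$n_input_each_box) == 3))
  expect_true(all(sizes >= 2 & sizes <= 6))
  expect_true(all(suite$class1_fraction >= 0.1875 &
                    suite$class1_fraction <= 0.8125))
})

test_that("suite generation is seed-deterministic and seed-sensitive", {
  a <- make_benchmark_suite(seed = 7, dims = 8, structures_per_dim = 2)
  b <- make_benchmark_suite(seed = 7, dims = 8, structures_per_dim = 2)
  c <- make_benchmark_suite(seed = 8, dims = 8, structures_per_dim = 2)
  expect_identical(a, b)
  expect_false(identical(a$data, c$data))
})

test_that("generated networks cover both balanced and imbalanced labels", {
  fracs <- vapply(1:12, function(s) {
    st <- random_structure(8, 3, 2, 4, seed = s)
    mean(enumerate_dataset(random_network(st, seed = s + 100))$y)
  }, double(1))
  expect_true(any(fracs < 0.5))
  expect_true(any(fracs > 0.5))
})

test_that("dataset CSV round-trips through disk", {
  fn <- example_network()
  dat <- flip_labels(enumerate_dataset(fn), 0.1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(dat, path)
  back <- read_dataset_csv(path)
  expect_identical(as.data.frame(back), as.data.frame(dat))
  expect_identical(names(back),
                   c(paste0("x", 1:7), "y", "y_clean", "flipped"))
})
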