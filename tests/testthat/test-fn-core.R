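test_that("decimal encoding follows the least-significant-first convention", {
  expect_identical(decimal_encode(c(0, 0, 0)), 1L)
  expect_identical(decimal_encode(c(0, 1, 0)), 3L)
  expect_identical(decimal_encode(c(1, 1, 1)), 8L)
  expect_identical(decimal_decode(1, 3), c(0L, 0L, 0L))
  expect_identical(decimal_decode(8, 3), c(1L, 1L, 1L))
  expect_identical(decimal_decode(3, 2), c(0L, 1L))
})

test_that("decimal encoding rejects invalid input", {
  expect_error(decimal_encode(integer(0)), "Empty")
  expect_error(decimal_encode(c(0, 2)), "0 or 1")
  expect_error(decimal_decode(0, 3), "1..2\\^n")
  expect_error(decimal_decode(9, 3), "1..2\\^n")
})

test_that("encode/decode is a bijection on every bit vector up to n = 8", {
  for (n in 1:8) {
    codes <- vapply(seq_len(2^n), function(k) {
      decimal_encode(decimal_decode(k, n))
    }, integer(1))
    expect_identical(codes, seq_len(2^n))
  }
})

test_that("structure validation enforces sizes and slicing", {
  st <- fn_structure(c(3, 2, 2))
  expect_identical(st$M, 3L)
  expect_identical(st$N, 7L)
  expect_identical(st$box_slices, list(1:3, 4:5, 6:7))
  expect_error(fn_structure(c(2, 0)), "positive")
  expect_error(functional_network(c(2, 2), list(c(0, 1, 1, 0)), c(0, 1)),
               "one first-layer truth table per box")
  expect_error(
    functional_network(c(2, 2), list(c(0, 1), c(0, 1, 1, 0))[c(2, 2)],
                       c(0, 1)),
    "Output box"
  )
  expect_error(truth_table(c(0, 1, 2, 1)), "in \\{0, 1\\}")
  expect_error(truth_table(c(0, 1, 1)), "power of 2")
})

test_that("the worked-example network evaluates as printed", {
  fn <- example_network()
  ev <- evaluate_fn(fn, c(0, 1, 0, 0, 1, 1, 0))
  expect_identical(ev$first_layer_outputs, c(1L, 1L, 1L))
  expect_identical(ev$label, 0L)
})

test_that("evaluation guards input shape and values", {
  fn <- example_network()
  expect_error(evaluate_fn(fn, c(0, 1)), "does not match N")
  expect_error(evaluate_fn(fn, c(0, 1, 0, 0, 1, 1, 2)), "binary")
  expect_error(predict(fn, matrix(1L, 2, 5)), "feature columns")
})

test_that("a constant-zero output box labels everything 0", {
  fn <- functional_network(
    c(2, 2),
    first_layer = list(c(0, 1, 1, 0), c(1, 0, 0, 1)),
    output_box = c(0, 0, 0, 0)
  )
  X <- matrix(sample(0:1, 40, replace = TRUE), ncol = 4)
  expect_true(all(predict(fn, X) == 0L))
})

test_that("full enumeration of the worked example reproduces the frozen labels", {
  # frozen from a direct table-lookup oracle over all 2^7 inputs
  dat <- enumerate_dataset(example_network())
  expect_identical(nrow(dat), 128L)
  expect_identical(mean(dat$y), 0.625)
  expect_identical(sum(dat$y * seq_along(dat$y)), 5728L)
  expect_identical(dat$y[1:16],
                   c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L,
                     1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L))
})

test_that("network JSON serialization round-trips, including the shipped fixture", {
  path <- withr::local_tempfile(fileext = ".json")
  fn <- example_network()
  write_fn_json(fn, path)
  expect_identical(read_fn_json(path), fn)
  shipped <- system.file("extdata", "example_network.json",
                         package = "noisecut")
  expect_identical(read_fn_json(shipped), fn)
})

test_that("vectorized prediction agrees with single-vector evaluation", {
  fn <- example_network()
  X <- enumerate_dataset(fn)
  labs <- vapply(seq_len(nrow(X)), function(i) {
    evaluate_fn(fn, as.integer(X[i, 1:7]))$label
  }, integer(1))
  expect_identical(predict(fn, X), labs)
})
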