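test_that("a clean, fully covered fit reproduces the generating network", {
  dat <- enumerate_dataset(example_network())
  fit <- noisecut(dat, c(3, 2, 2))
  expect_identical(predict(fit, dat), dat$y)
  # the worked-example input is classified as printed
  expect_identical(predict(fit, matrix(c(0, 1, 0, 0, 1, 1, 0), nrow = 1)),
                   0L)
})

test_that("full-coverage identifiability holds across random networks", {
  # clean full enumerations of 3-box networks with small boxes: the
  # fitted model must reproduce the true labels everywhere
  for (s in 1:20) {
    d <- sample(6:10, 1)
    lo <- 2; hi <- 4
    st <- tryCatch(random_structure(d, 3, lo, hi, seed = s),
                   error = function(e) NULL)
    if (is.null(st)) next
    fn <- random_network(st, balance_window = c(0, 1), seed = s + 500)
    dat <- enumerate_dataset(fn)
    fit <- noisecut(dat, st$n_input_each_box)
    expect_identical(predict(fit, dat), dat$y)
  }
})

test_that("a single training sample yields a constant predictor", {
  dat <- tibble::tibble(x1 = 1L, x2 = 0L, x3 = 1L, x4 = 1L, y = 1L)
  fit <- noisecut(dat, c(2, 2))
  X <- enumerate_dataset(example_network())[, 1:4]
  names(X) <- paste0("x", 1:4)
  expect_true(all(predict(fit, X[1:16, ]) == 1L))
  expect_identical(fit$default_label, 1L)
})

test_that("first-layer orientation is absorbed by the output box", {
  dat <- flip_labels(enumerate_dataset(example_network()), 0.05, seed = 3)
  fit <- noisecut(dat, c(3, 2, 2))
  # complement every first-layer table and remap the output cells by
  # complementing their M-bit codes
  M <- fit$structure$M
  flipped <- fit
  flipped$first_layer <- lapply(fit$first_layer, function(t) {
    truth_table(1L - t$table)
  })
  remap <- vapply(seq_len(2^M), function(v) {
    bits <- decimal_decode(v, M)
    decimal_encode(1L - bits)
  }, integer(1))
  flipped$output_table <- truth_table(fit$output_table$table[remap])
  flipped$output_votes <- fit$output_votes[remap, ]
  expect_identical(predict(flipped, dat), predict(fit, dat))
  expect_identical(predict(flipped, dat, type = "prob"),
                   predict(fit, dat, type = "prob"))
})

test_that("prediction scores are vote fractions with a prior fallback", {
  # craft a model with known votes
  st <- fn_structure(c(1, 1))
  model <- structure(list(
    structure = st,
    first_layer = list(truth_table(c(0, 1)), truth_table(c(0, 1))),
    output_votes = cbind(votes0 = c(0L, 5L, 3L, 0L),
                         votes1 = c(7L, 5L, 0L, 0L)),
    output_table = truth_table(c(1, 0, 0, 0)),
    default_label = 0L,
    prior_1 = 0.4,
    n_train = 20L,
    solver = NULL
  ), class = "noisecut")
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))  # cells 1..4
  expect_equal(predict(model, X, type = "prob"), c(1.0, 0.5, 0.0, 0.4))
})

test_that("fits are deterministic and serialize losslessly", {
  dat <- flip_labels(enumerate_dataset(example_network()), 0.1, seed = 8)
  f1 <- noisecut(dat, c(3, 2, 2))
  f2 <- noisecut(dat, c(3, 2, 2))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_noisecut_json(f1, p1)
  write_noisecut_json(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_noisecut_json(p1)
  expect_identical(predict(back, dat), predict(f1, dat))
  expect_identical(predict(back, dat, type = "prob"),
                   predict(f1, dat, type = "prob"))
})

test_that("tidy and glance summarize the fitted network", {
  dat <- enumerate_dataset(example_network())
  fit <- noisecut(dat, c(3, 2, 2))
  td <- tidy(fit)
  expect_identical(nrow(td), 8L + 4L + 4L + 8L)
  expect_true(all(td$output %in% 0:1))
  out_rows <- td[td$layer == "output", ]
  expect_identical(sum(out_rows$votes0 + out_rows$votes1), 128L)
  gl <- glance(fit)
  expect_identical(gl$n_train, 128L)
  expect_identical(gl$n_boxes, 3L)
  expect_identical(gl$prior_1, 0.625)
})

test_that("the learned network exports as a functional network", {
  dat <- enumerate_dataset(example_network())
  fit <- noisecut(dat, c(3, 2, 2))
  fn <- as_functional_network(fit)
  expect_s3_class(fn, "functional_network")
  expect_identical(predict(fn, dat), predict(fit, dat))
})

test_that("width mismatches fail loudly", {
  dat <- enumerate_dataset(example_network())
  expect_error(noisecut(dat, c(3, 3)), "Expected 6 feature columns")
})
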