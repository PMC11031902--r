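#' Inject label noise by flipping a fraction of labels
#'
#' Flips the labels of exactly `round_half_up(noise * S)` distinct rows,
#' chosen uniformly at random without replacement. The corruption is
#' applied to the dataset as a whole (typically before any train/test
#' split), and provenance columns record which rows were touched.
#'
#' @param data Dataset tibble with columns `x1..xN` and `y`.
#' @param noise Noise intensity `q` in `[0, 1]`: the fraction of samples
#'   whose label is flipped.
#' @param seed Integer seed.
#' @return The input tibble with `y` corrupted and two extra columns:
#'   `y_clean` (original labels) and `flipped` (0/1 flag); the invariant
#'   `y == xor(y_clean, flipped)` always holds.
#' @examples
#' fn <- random_network(random_structure(6, 3, 2, 2, seed = 1), seed = 1)
#' noisy <- flip_labels(enumerate_dataset(fn), noise = 0.1, seed = 7)
#' sum(noisy$flipped) # 6 of 64 rows
#' @export
flip_labels <- function(data, noise, seed = 1L) {
  if (length(noise) != 1L || is.na(noise) || noise < 0 || noise > 1) {
    stop("`noise` must be a single fraction in [0, 1].", call. = FALSE)
  }
  y <- dataset_labels(data)
  S <- length(y)
  k <- floor(noise * S + 0.5)
  withr::local_seed(seed)
  idx <- if (k > 0) sample.int(S, k) else integer(0)
  flipped <- integer(S)
  flipped[idx] <- 1L
  out <- data
  out$y_clean <- y
  out$flipped <- flipped
  out$y <- bitwXor(y, flipped)
  tibble::as_tibble(out)
}

#' Split a dataset into training and test sets
#'
#' Uniform random partition without replacement: the training set holds
#' `round_half_up(train_fraction * S)` rows; the rest form the test set.
#' Provenance columns (`y_clean`, `flipped`) are carried through, so
#' noise injected before the split stays traceable on both sides.
#'
#' @param data Dataset tibble.
#' @param train_fraction Fraction of rows assigned to training,
#'   strictly between 0 and 1 (the benchmark uses 0.7).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test` (disjoint, covering all
#'   rows).
#' @export
split_data <- function(data, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  S <- nrow(data)
  if (S < 2L) stop("Need at least 2 rows to split.", call. = FALSE)
  k <- floor(train_fraction * S + 0.5)
  if (k < 1L || k >= S) {
    stop("Split leaves an empty side (train size ", k, " of ", S, ").",
         call. = FALSE)
  }
  withr::local_seed(seed)
  idx <- sample.int(S, k)
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE])
}
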