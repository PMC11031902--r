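#' Draw a random tree-network structure
#'
#' Samples per-box input counts `[n_1..n_boxes]` uniformly over the
#' compositions of `d` with every part in
#' `[min_box_inputs, max_box_inputs]`, by rejection from uniform parts.
#'
#' @param d Total number of binary input features.
#' @param n_boxes Number of first-layer boxes (default 3, the benchmark
#'   configuration).
#' @param min_box_inputs,max_box_inputs Bounds on the per-box input count
#'   (defaults 2 and 6).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An [fn_structure()].
#' @examples
#' random_structure(10, seed = 1)
#' @export
random_structure <- function(d, n_boxes = 3, min_box_inputs = 2,
                             max_box_inputs = 6, seed = 1L) {
  if (n_boxes * min_box_inputs > d || n_boxes * max_box_inputs < d) {
    stop("No composition of d = ", d, " into ", n_boxes, " parts in [",
         min_box_inputs, ", ", max_box_inputs, "] exists.", call. = FALSE)
  }
  withr::local_seed(seed)
  repeat {
    parts <- sample(seq.int(min_box_inputs, max_box_inputs), n_boxes,
                    replace = TRUE)
    if (sum(parts) == d) return(fn_structure(parts))
  }
}

#' Draw a random functional network with a class-balance guarantee
#'
#' Fills every truth-table entry i.i.d. Bernoulli(0.5), labels the full
#' enumeration of the input space, and accepts the network only if the
#' class-1 fraction of the enumerated labels falls inside
#' `balance_window`; otherwise all tables are redrawn (same random
#' stream), up to `max_retries` times.
#'
#' @param structure An [fn_structure()].
#' @param balance_window Accepted range for the enumerated class-1
#'   fraction. The default `c(0.1875, 0.8125)` spans the benchmark's
#'   balanced-to-imbalanced label-ratio range.
#' @param seed Integer seed.
#' @param max_retries Redraw budget before giving up.
#' @return A [functional_network()] whose enumerated class-1 fraction
#'   lies inside `balance_window`.
#' @export
random_network <- function(structure, balance_window = c(0.1875, 0.8125),
                           seed = 1L, max_retries = 1000L) {
  stopifnot(inherits(structure, "fn_structure"))
  if (balance_window[1] < 0 || balance_window[1] > balance_window[2] ||
      balance_window[2] > 1) {
    stop("`balance_window` must satisfy 0 <= lo <= hi <= 1.", call. = FALSE)
  }
  withr::local_seed(seed)
  X <- enumerate_inputs(structure$N)
  ratio <- NA_real_
  for (try in seq_len(max_retries)) {
    fl <- lapply(structure$n_input_each_box, function(n) {
      truth_table(stats::rbinom(2^n, 1, 0.5))
    })
    ob <- truth_table(stats::rbinom(2^structure$M, 1, 0.5))
    fn <- functional_network(structure, fl, ob)
    ratio <- mean(evaluate_fn_matrix(fn, X))
    if (ratio >= balance_window[1] && ratio <= balance_window[2]) return(fn)
  }
  stop("Could not reach a class-1 fraction in [", balance_window[1], ", ",
       balance_window[2], "] after ", max_retries,
       " draws (last ratio: ", signif(ratio, 4), ").", call. = FALSE)
}

# All 2^n binary vectors as a matrix, row k = decimal_decode(k, n).
enumerate_inputs <- function(n) {
  if (n > 24) stop("Refusing to enumerate 2^", n, " rows (guard: n <= 24).",
                   call. = FALSE)
  codes <- seq_len(2^n) - 1L
  X <- matrix(0L, nrow = length(codes), ncol = n)
  for (i in seq_len(n)) X[, i] <- bitwAnd(codes %/% 2L^(i - 1L), 1L)
  X
}

#' Fully enumerate the labelled dataset of a functional network
#'
#' Generates all `2^N` distinct binary input vectors in decimal-code
#' order and labels each with the network. The benchmark datasets are
#' such full enumerations, so reported class ratios are exact dyadic
#' fractions.
#'
#' @param fn A [functional_network()].
#' @return A tibble with columns `x1..xN` and `y`, `2^N` rows.
#' @examples
#' fn <- random_network(random_structure(6, 3, 2, 2, seed = 1), seed = 1)
#' enumerate_dataset(fn)
#' @export
enumerate_dataset <- function(fn) {
  X <- enumerate_inputs(fn$structure$N)
  y <- evaluate_fn_matrix(fn, X)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(y = y))
}

#' Generate the synthetic benchmark suite
#'
#' Builds `structures_per_dim` random tree networks for each input
#' dimension in `dims`, together with their fully enumerated labelled
#' datasets. The full benchmark uses `dims = 8:12` and six structures
#' per dimension (30 datasets); reduced suites for quick experiments
#' just shrink those two arguments.
#'
#' @param seed Master seed; every network draws a distinct child seed
#'   from it, so the suite is reproducible as a whole.
#' @param dims Input dimensions to cover.
#' @param structures_per_dim Networks per dimension.
#' @param n_boxes,min_box_inputs,max_box_inputs,balance_window Passed to
#'   [random_structure()] and [random_network()].
#' @return A tibble with one row per dataset: `dataset_id`, `d`,
#'   `n_input_each_box` (list-column), `network` (list-column of
#'   [functional_network()]s), `data` (list-column of tibbles) and
#'   `class1_fraction`.
#' @export
make_benchmark_suite <- function(seed = 1L, dims = 8:12,
                                 structures_per_dim = 6,
                                 n_boxes = 3, min_box_inputs = 2,
                                 max_box_inputs = 6,
                                 balance_window = c(0.1875, 0.8125)) {
  grid <- tidyr::expand_grid(d = as.integer(dims),
                             rep = seq_len(structures_per_dim))
  purrr::pmap_dfr(grid, function(d, rep) {
    s_seed <- derive_seed(seed, d, rep, 1L)
    n_seed <- derive_seed(seed, d, rep, 2L)
    st <- random_structure(d, n_boxes, min_box_inputs, max_box_inputs,
                           seed = s_seed)
    fn <- random_network(st, balance_window, seed = n_seed)
    dat <- enumerate_dataset(fn)
    frac <- mean(dat$y)
    tibble::tibble(
      dataset_id = sprintf("d%02d_s%d", d, rep),
      d = d,
      n_input_each_box = list(st$n_input_each_box),
      network = list(fn),
      data = list(dat),
      class1_fraction = frac
    )
  })
}

# Deterministic child seeds from a master seed and an index path.
# Plain modular mixing; all arithmetic stays exact in doubles and the
# result fits a 32-bit integer.
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (k in as.double(c(...))) {
    h <- (h * 48271 + k + 1) %% 2147483647
  }
  as.integer(h)
}

#' Write / read a labelled binary dataset as CSV
#'
#' Plain CSV with header `x1,...,xN,y` and 0/1 values; the optional
#' noise-provenance columns `y_clean` and `flipped` round-trip too.
#'
#' @param data Dataset tibble.
#' @param path File path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_dataset_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_integer()))
}
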