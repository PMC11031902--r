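#' Define the structure of a tree-structured functional network
#'
#' A two-layer tree functional network (FN) routes disjoint, consecutive
#' blocks of binary input features into `M` first-layer boxes; box `m`
#' consumes `n_input_each_box[m]` features. The first `n_1` feature columns
#' feed box 1, the next `n_2` feature columns feed box 2, and so on.
#'
#' @param n_input_each_box Integer vector of per-box input counts
#'   (the sole hyperparameter of the method; prior knowledge of how
#'   features group into sub-processes).
#' @return An object of class `fn_structure` with elements
#'   `n_input_each_box`, `M` (number of first-layer boxes), `N` (total
#'   feature count) and `box_slices` (list of feature-column indices per box).
#' @examples
#' fn_structure(c(3, 2, 2))
#' @export
fn_structure <- function(n_input_each_box) {
  n <- as.integer(n_input_each_box)
  if (length(n) < 1L || anyNA(n) || any(n < 1L)) {
    stop("`n_input_each_box` must be a non-empty vector of positive integers.",
         call. = FALSE)
  }
  ends <- cumsum(n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(
    list(
      n_input_each_box = n,
      M = length(n),
      N = sum(n),
      box_slices = Map(seq.int, starts, ends)
    ),
    class = "fn_structure"
  )
}

#' @export
print.fn_structure <- function(x, ...) {
  cat("<fn_structure> ", x$M, " first-layer boxes over ", x$N,
      " binary features\n", sep = "")
  cat("  inputs per box: ", paste(x$n_input_each_box, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Construct a Boolean truth table
#'
#' A truth table maps the decimal code of an `n`-bit binary input
#' (see [decimal_encode()]) to a binary output. Entry `k` of `values` is
#' the output for code `k`, i.e. for the bit vector `decimal_decode(k, n)`.
#'
#' @param values Vector of `2^n` values in `{0, 1}`, in code order
#'   `1..2^n`.
#' @return An object of class `truth_table` with elements `n_inputs` and
#'   `table` (integer vector of length `2^n_inputs`).
#' @examples
#' truth_table(c(1, 0, 1, 1)) # a 2-input box
#' @export
truth_table <- function(values) {
  v <- as.integer(values)
  if (length(v) < 2L || anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop("A truth table needs >= 2 entries, all in {0, 1}.", call. = FALSE)
  }
  n <- log2(length(v))
  if (n != round(n)) {
    stop("Truth-table length must be a power of 2.", call. = FALSE)
  }
  structure(list(n_inputs = as.integer(n), table = v), class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> ", x$n_inputs, " inputs: [",
      paste(x$table, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Assemble a two-layer tree functional network
#'
#' @param structure An [fn_structure()], or a bare integer vector of
#'   per-box input counts.
#' @param first_layer List of `M` truth tables (or bare 0/1 vectors);
#'   table `m` must have `n_input_each_box[m]` inputs.
#' @param output_box Truth table (or bare 0/1 vector) over the `M`
#'   first-layer outputs.
#' @return An object of class `functional_network`.
#' @examples
#' fn <- functional_network(
#'   c(2, 2),
#'   first_layer = list(c(0, 1, 1, 0), c(1, 0, 0, 1)),
#'   output_box = c(0, 1, 1, 0)
#' )
#' evaluate_fn(fn, c(1, 0, 0, 1))
#' @export
functional_network <- function(structure, first_layer, output_box) {
  if (!inherits(structure, "fn_structure")) structure <- fn_structure(structure)
  as_tt <- function(x) if (inherits(x, "truth_table")) x else truth_table(x)
  first_layer <- lapply(first_layer, as_tt)
  output_box <- as_tt(output_box)
  if (length(first_layer) != structure$M) {
    stop("Need one first-layer truth table per box.", call. = FALSE)
  }
  n_in <- vapply(first_layer, function(t) t$n_inputs, integer(1))
  if (!identical(n_in, structure$n_input_each_box)) {
    stop("First-layer table sizes do not match `n_input_each_box`.",
         call. = FALSE)
  }
  if (output_box$n_inputs != structure$M) {
    stop("Output box must take exactly M = ", structure$M, " inputs.",
         call. = FALSE)
  }
  structure(
    list(structure = structure, first_layer = first_layer,
         output_box = output_box),
    class = "functional_network"
  )
}

#' @export
print.functional_network <- function(x, ...) {
  cat("<functional_network> ", x$structure$M, " boxes (",
      paste(x$structure$n_input_each_box, collapse = ", "), ") over ",
      x$structure$N, " features\n", sep = "")
  invisible(x)
}

#' Decimal code of a binary vector
#'
#' Maps an `n`-bit vector to its code in `1..2^n`:
#' `1 + sum(2^(i-1) * bits[i])`. The first element is the
#' least-significant bit. This is the indexing convention of every truth
#' table in the package.
#'
#' @param bits Vector of values in `{0, 1}`.
#' @return Integer code in `1..2^length(bits)`.
#' @examples
#' decimal_encode(c(0, 1, 0)) # 3
#' @export
decimal_encode <- function(bits) {
  b <- as.integer(bits)
  if (length(b) < 1L) stop("Empty bit vector.", call. = FALSE)
  if (anyNA(b) || !all(b %in% c(0L, 1L))) {
    stop("Bits must all be 0 or 1.", call. = FALSE)
  }
  as.integer(1 + sum(2^(seq_along(b) - 1) * b))
}

#' Binary vector of a decimal code
#'
#' Inverse of [decimal_encode()].
#'
#' @param code Integer in `1..2^n`.
#' @param n Number of bits.
#' @return Integer vector of `n` bits, least-significant first.
#' @examples
#' decimal_decode(3, 2) # c(0, 1)
#' @export
decimal_decode <- function(code, n) {
  n <- as.integer(n)
  code <- as.integer(code)
  if (length(code) != 1L || is.na(code) || code < 1L || code > 2^n) {
    stop("`code` must lie in 1..2^n.", call. = FALSE)
  }
  as.integer(intToBits(code - 1L))[seq_len(n)]
}

# Vectorized per-box decimal codes: X is an S x N 0/1 matrix; returns an
# S x M integer matrix of codes in 1..2^{n_m}.
box_codes <- function(X, structure) {
  if (ncol(X) != structure$N) {
    stop("Feature width ", ncol(X), " does not match structure N = ",
         structure$N, ".", call. = FALSE)
  }
  codes <- matrix(0L, nrow = nrow(X), ncol = structure$M)
  for (m in seq_len(structure$M)) {
    sl <- structure$box_slices[[m]]
    w <- 2^(seq_along(sl) - 1)
    codes[, m] <- as.integer(1 + X[, sl, drop = FALSE] %*% w)
  }
  codes
}

#' Evaluate a functional network on one input vector
#'
#' Slices `x` per box, encodes each slice ([decimal_encode()]), looks up
#' the first-layer tables, encodes the resulting `M` bits, and looks up
#' the output box.
#'
#' @param fn A [functional_network()].
#' @param x Binary vector of length `fn$structure$N`.
#' @return List with `label` (0 or 1) and `first_layer_outputs`
#'   (integer vector of the `M` intermediate bits).
#' @export
evaluate_fn <- function(fn, x) {
  x <- as.integer(x)
  st <- fn$structure
  if (length(x) != st$N) {
    stop("Input length ", length(x), " does not match N = ", st$N, ".",
         call. = FALSE)
  }
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("Input must be binary.", call. = FALSE)
  }
  f <- integer(st$M)
  for (m in seq_len(st$M)) {
    f[m] <- fn$first_layer[[m]]$table[decimal_encode(x[st$box_slices[[m]]])]
  }
  list(label = fn$output_box$table[decimal_encode(f)],
       first_layer_outputs = f)
}

# Vectorized network evaluation over an S x N matrix; returns integer labels.
evaluate_fn_matrix <- function(fn, X) {
  st <- fn$structure
  codes <- box_codes(X, st)
  Fm <- matrix(0L, nrow = nrow(X), ncol = st$M)
  for (m in seq_len(st$M)) {
    Fm[, m] <- fn$first_layer[[m]]$table[codes[, m]]
  }
  out_code <- as.integer(1 + Fm %*% 2^(seq_len(st$M) - 1))
  fn$output_box$table[out_code]
}

#' Predict labels from a functional network
#'
#' @param object A [functional_network()].
#' @param new_data Data frame with binary feature columns `x1..xN`
#'   (a label column `y`, if present, is ignored), or a binary matrix.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per row.
#' @export
predict.functional_network <- function(object, new_data, ...) {
  X <- dataset_features(new_data, object$structure$N)
  evaluate_fn_matrix(object, X)
}

#' Serialize a functional network to JSON
#'
#' Writes `{"n_input_each_box": [...], "first_layer": [[...], ...],
#' "output_box": [...]}` with truth tables as 0/1 arrays in code order.
#'
#' @param fn A [functional_network()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_fn_json <- function(fn, path) {
  obj <- list(
    n_input_each_box = fn$structure$n_input_each_box,
    first_layer = lapply(fn$first_layer, function(t) t$table),
    output_box = fn$output_box$table
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a functional network from JSON
#'
#' @param path File written by [write_fn_json()].
#' @return A [functional_network()].
#' @export
read_fn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- obj$first_layer
  if (is.matrix(fl)) fl <- lapply(seq_len(nrow(fl)), function(i) fl[i, ])
  functional_network(unlist(obj$n_input_each_box), fl,
                     unlist(obj$output_box))
}

# Extract an S x N 0/1 matrix from a dataset tibble (x1..xN [+ y ...])
# or pass a matrix through, validating binarity.
dataset_features <- function(data, expected_n = NULL) {
  if (is.matrix(data)) {
    X <- data
  } else {
    data <- as.data.frame(data)
    xcols <- grep("^x[0-9]+$", names(data), value = TRUE)
    if (length(xcols) == 0L) {
      stop("No feature columns `x1..xN` found.", call. = FALSE)
    }
    xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
    X <- as.matrix(data[xcols])
  }
  storage.mode(X) <- "integer"
  if (anyNA(X) || !all(X %in% c(0L, 1L))) {
    stop("Features must be binary (0/1).", call. = FALSE)
  }
  if (!is.null(expected_n) && ncol(X) != expected_n) {
    stop("Expected ", expected_n, " feature columns, got ", ncol(X), ".",
         call. = FALSE)
  }
  X
}

# Extract the 0/1 label vector from a dataset tibble.
dataset_labels <- function(data) {
  if (!"y" %in% names(data)) stop("No label column `y` found.", call. = FALSE)
  y <- as.integer(data[["y"]])
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("Labels must be binary (0/1).", call. = FALSE)
  }
  y
}
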