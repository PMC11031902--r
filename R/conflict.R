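#' Build the per-box conflict graphs of a training set
#'
#' For every unordered pair of training rows with *different* labels
#' whose per-box decimal codes differ in *exactly one* box `m`, the edge
#' between the pair's two codes in box `m` gains unit weight. Pairs that
#' agree in every box, or differ in two or more boxes, contribute
#' nothing. The result is one symmetric, zero-diagonal, nonnegative
#' integer weight matrix per box; a heavy edge `(k, l)` is strong
#' evidence that the box function assigns different outputs to input
#' codes `k` and `l`.
#'
#' Internally rows are grouped by the joint code of all *other* boxes
#' (the pair's shared context), which reproduces the naive scan over all
#' `choose(S, 2)` pairs exactly but runs in roughly `O(S * M)` plus one
#' small cross-product per context.
#'
#' @param data Training dataset tibble (`x1..xN`, `y`).
#' @param structure An [fn_structure()] (or bare vector of per-box input
#'   counts) describing how features group into boxes.
#' @return A list of `M` objects of class `conflict_graph`, each with
#'   elements `box`, `n_inputs` and `W` (the `2^n_inputs` square weight
#'   matrix).
#' @export
conflict_graphs <- function(data, structure) {
  if (!inherits(structure, "fn_structure")) structure <- fn_structure(structure)
  X <- dataset_features(data, structure$N)
  y <- dataset_labels(data)
  if (nrow(X) == 0L) stop("Training data is empty.", call. = FALSE)
  codes <- box_codes(X, structure)
  M <- structure$M
  lapply(seq_len(M), function(m) {
    n_codes <- 2L^structure$n_input_each_box[m]
    # context = joint code of all boxes except m, mixed-radix packed
    ctx <- rep(0, nrow(X))
    for (j in setdiff(seq_len(M), m)) {
      ctx <- ctx * 2^structure$n_input_each_box[j] + (codes[, j] - 1)
    }
    ctx_id <- match(ctx, unique(ctx))
    n_ctx <- max(ctx_id)
    # counts of label-0 and label-1 rows per (context, code-in-box-m) cell
    N0 <- matrix(0L, n_ctx, n_codes)
    N1 <- matrix(0L, n_ctx, n_codes)
    i0 <- y == 0L
    t0 <- table(factor(ctx_id[i0], levels = seq_len(n_ctx)),
                factor(codes[i0, m], levels = seq_len(n_codes)))
    t1 <- table(factor(ctx_id[!i0], levels = seq_len(n_ctx)),
                factor(codes[!i0, m], levels = seq_len(n_codes)))
    N0[] <- as.integer(t0)
    N1[] <- as.integer(t1)
    W <- crossprod(N0, N1)  # pairs (label 0 at code k, label 1 at code l)
    W <- W + t(W)
    diag(W) <- 0L
    storage.mode(W) <- "integer"
    dimnames(W) <- NULL
    base::structure(
      list(box = m, n_inputs = structure$n_input_each_box[m], W = W),
      class = "conflict_graph"
    )
  })
}

#' @export
print.conflict_graph <- function(x, ...) {
  cat("<conflict_graph> box ", x$box, " (", x$n_inputs, " inputs, ",
      nrow(x$W), " vertices), total edge mass ",
      sum(x$W[upper.tri(x$W)]), "\n", sep = "")
  invisible(x)
}

#' Total conflict mass across a set of conflict graphs
#'
#' The number of unordered label-discordant training pairs that differ
#' in exactly one box: `sum over m, k < l of W_m[k, l]`. A diagnostic
#' that grows with label noise.
#'
#' @param graphs List returned by [conflict_graphs()].
#' @return A single nonnegative integer (as double, to avoid overflow).
#' @export
total_conflict_mass <- function(graphs) {
  sum(vapply(graphs, function(g) sum(g$W[upper.tri(g$W)]), double(1)))
}

#' Dump conflict graphs as an edge-list table
#'
#' @param graphs List returned by [conflict_graphs()].
#' @return Tibble with columns `box`, `k`, `l`, `weight` (1-based codes,
#'   `k < l`, zero-weight edges omitted).
#' @export
conflict_edges <- function(graphs) {
  purrr::map_dfr(graphs, function(g) {
    ut <- which(upper.tri(g$W) & g$W > 0, arr.ind = TRUE)
    tibble::tibble(box = g$box, k = ut[, 1], l = ut[, 2],
                   weight = g$W[ut])
  })
}
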