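# Independent oracles and fixtures shared across tests.

# The worked-example network: three first-layer boxes (3, 2 and 2
# inputs) and the output box, all given as explicit truth tables.
example_network <- function() {
  functional_network(
    c(3, 2, 2),
    first_layer = list(c(0, 0, 1, 1, 1, 0, 1, 0),
                       c(1, 0, 1, 1),
                       c(1, 1, 0, 0)),
    output_box = c(0, 0, 1, 1, 1, 0, 1, 0)
  )
}

# Naive conflict-graph builder: vectorized scan over all S^2 ordered row
# pairs, straight from the definition. Independent of the grouped
# accumulation in conflict_graphs().
naive_conflict_graphs <- function(data, structure) {
  if (!inherits(structure, "fn_structure")) structure <- fn_structure(structure)
  xcols <- paste0("x", seq_len(structure$N))
  X <- as.matrix(data[xcols])
  y <- data$y
  M <- structure$M
  codes <- sapply(seq_len(M), function(m) {
    sl <- structure$box_slices[[m]]
    as.integer(1 + X[, sl, drop = FALSE] %*% 2^(seq_along(sl) - 1))
  })
  codes <- matrix(codes, ncol = M)
  ydiff <- outer(y, y, "!=")
  diffs <- lapply(seq_len(M), function(m) outer(codes[, m], codes[, m], "!="))
  n_diff <- Reduce(`+`, diffs)
  lapply(seq_len(M), function(m) {
    n_codes <- 2L^structure$n_input_each_box[m]
    W <- matrix(0L, n_codes, n_codes)
    sel <- which(ydiff & n_diff == 1L & diffs[[m]], arr.ind = TRUE)
    sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]  # unordered pairs
    for (i in seq_len(nrow(sel))) {
      k <- codes[sel[i, 1], m]
      l <- codes[sel[i, 2], m]
      W[k, l] <- W[k, l] + 1L
      W[l, k] <- W[l, k] + 1L
    }
    W
  })
}

# Random symmetric integer weight matrix with zero diagonal.
random_weights <- function(n, max_w = 20, density = 0.6) {
  W <- matrix(0L, n, n)
  for (u in seq_len(n - 1)) {
    for (v in seq.int(u + 1, n)) {
      if (stats::runif(1) < density) {
        W[u, v] <- W[v, u] <- sample.int(max_w + 1L, 1L) - 1L
      }
    }
  }
  W
}

# A small random labelled binary dataset (not from any network).
random_binary_dataset <- function(S, N, seed) {
  withr::local_seed(seed)
  X <- matrix(sample(0:1, S * N, replace = TRUE), nrow = S)
  colnames(X) <- paste0("x", seq_len(N))
  dplyr::bind_cols(tibble::as_tibble(X),
                   tibble::tibble(y = sample(0:1, S, replace = TRUE)))
}
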