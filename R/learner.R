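#' Fit a noise-tolerant functional-network classifier
#'
#' Learns a two-layer tree functional network from labelled binary data,
#' given only the per-box input counts as prior knowledge:
#'
#' 1. builds one conflict graph per first-layer box
#'    ([conflict_graphs()]) — edge weights count label-discordant sample
#'    pairs that differ only in that box's inputs;
#' 2. solves an exact max-cut on each graph ([solve_maxcut()]); the two
#'    sides of the optimal partition become the box's 0- and 1-output
#'    input codes (the side containing code 1, the all-zeros input, is
#'    labelled 0 — orientation is arbitrary and absorbed by the output
#'    box);
#' 3. routes every training row through the learned first layer and
#'    identifies the output box by majority voting over the labels that
#'    arrive at each of its `2^M` input codes. Unseen or tied cells
#'    default to the majority training class (ties there fall to 0).
#'
#' Maximising the cut keeps the heavily-supported disagreements and
#' discards light, noise-borne edges, which is what makes the fit robust
#' to label noise.
#'
#' @param data Training dataset tibble (`x1..xN`, `y`).
#' @param n_input_each_box Integer vector of per-box input counts; must
#'   sum to the number of feature columns.
#' @param time_limit Per-box max-cut budget in seconds (a solver that
#'   cannot prove optimality in time throws rather than returning a
#'   heuristic cut).
#' @return An object of class `noisecut`: the fitted model, with the
#'   learned first-layer truth tables, output-box vote counts and table,
#'   default label, training prevalence `prior_1` and per-box solver
#'   diagnostics. Supports [predict()][predict.noisecut()],
#'   [tidy()][tidy.noisecut()], [glance()][glance.noisecut()].
#' @examples
#' fn <- random_network(random_structure(6, 3, 2, 2, seed = 1), seed = 1)
#' fit <- noisecut(enumerate_dataset(fn), n_input_each_box = c(2, 2, 2))
#' glance(fit)
#' @export
noisecut <- function(data, n_input_each_box, time_limit = 120) {
  st <- fn_structure(n_input_each_box)
  X <- dataset_features(data, st$N)
  y <- dataset_labels(data)
  graphs <- conflict_graphs(data, st)
  solutions <- lapply(graphs, function(g) {
    tryCatch(
      solve_maxcut(g$W, lex = FALSE, time_limit = time_limit),
      error = function(e) {
        stop("max-cut failed for box ", g$box, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  first_layer <- lapply(solutions, function(s) truth_table(s$assignment))

  # route training rows through the learned first layer, tally votes
  codes <- box_codes(X, st)
  Fm <- matrix(0L, nrow = nrow(X), ncol = st$M)
  for (m in seq_len(st$M)) Fm[, m] <- first_layer[[m]]$table[codes[, m]]
  out_code <- as.integer(1 + Fm %*% 2^(seq_len(st$M) - 1))
  n_cells <- 2L^st$M
  votes0 <- tabulate(out_code[y == 0L], nbins = n_cells)
  votes1 <- tabulate(out_code[y == 1L], nbins = n_cells)

  prior_1 <- mean(y)
  default_label <- if (prior_1 > 0.5) 1L else 0L
  out_table <- ifelse(votes1 > votes0, 1L,
                      ifelse(votes0 > votes1, 0L, default_label))

  base::structure(
    list(
      structure = st,
      first_layer = first_layer,
      output_votes = cbind(votes0 = votes0, votes1 = votes1),
      output_table = truth_table(out_table),
      default_label = default_label,
      prior_1 = prior_1,
      n_train = length(y),
      solver = tibble::tibble(
        box = seq_len(st$M),
        n_vertices = vapply(graphs, function(g) nrow(g$W), integer(1)),
        cut_value = vapply(solutions, function(s) s$cut_value, double(1)),
        conflict_mass = vapply(graphs, function(g)
          sum(g$W[upper.tri(g$W)]), double(1)),
        nodes = vapply(solutions, function(s) as.double(s$nodes), double(1))
      )
    ),
    class = "noisecut"
  )
}

#' @export
print.noisecut <- function(x, ...) {
  cat("<noisecut> fitted on ", x$n_train, " samples; boxes (",
      paste(x$structure$n_input_each_box, collapse = ", "),
      "); training prevalence ", signif(x$prior_1, 3), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted noisecut model
#'
#' @param object A fitted [noisecut()] model.
#' @param new_data Data frame with feature columns `x1..xN`, or a binary
#'   matrix.
#' @param type `"class"` for hard 0/1 labels (the majority-vote output
#'   table) or `"prob"` for the vote fraction
#'   `votes1 / (votes0 + votes1)` at the routed output cell, with the
#'   training prevalence as fallback for cells no training row reached.
#' @param ... Unused.
#' @return Integer labels or numeric scores, one per row.
#' @export
predict.noisecut <- function(object, new_data,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- dataset_features(new_data, object$structure$N)
  codes <- box_codes(X, object$structure)
  M <- object$structure$M
  Fm <- matrix(0L, nrow = nrow(X), ncol = M)
  for (m in seq_len(M)) {
    Fm[, m] <- object$first_layer[[m]]$table[codes[, m]]
  }
  out_code <- as.integer(1 + Fm %*% 2^(seq_len(M) - 1))
  if (type == "class") {
    return(object$output_table$table[out_code])
  }
  v0 <- object$output_votes[, "votes0"][out_code]
  v1 <- object$output_votes[, "votes1"][out_code]
  tot <- v0 + v1
  score <- ifelse(tot > 0, v1 / pmax(tot, 1L), object$prior_1)
  as.numeric(score)
}

#' Turn a fitted model back into a functional network
#'
#' @param model A fitted [noisecut()] model.
#' @return A [functional_network()] with the learned truth tables.
#' @export
as_functional_network <- function(model) {
  functional_network(model$structure, model$first_layer, model$output_table)
}

#' Tidy a fitted noisecut model
#'
#' One row per truth-table entry of the fitted network. First-layer rows
#' carry the learned box output for each input code; output-box rows
#' additionally carry the vote counts behind the majority decision.
#'
#' @param x A fitted [noisecut()] model.
#' @param ... Unused.
#' @return A tibble with columns `layer` (`"first"`/`"output"`), `box`,
#'   `code`, `output`, `votes0`, `votes1`.
#' @export
tidy.noisecut <- function(x, ...) {
  first <- purrr::map_dfr(seq_len(x$structure$M), function(m) {
    tt <- x$first_layer[[m]]
    tibble::tibble(layer = "first", box = m,
                   code = seq_along(tt$table), output = tt$table,
                   votes0 = NA_integer_, votes1 = NA_integer_)
  })
  out <- tibble::tibble(
    layer = "output", box = NA_integer_,
    code = seq_along(x$output_table$table),
    output = x$output_table$table,
    votes0 = x$output_votes[, "votes0"],
    votes1 = x$output_votes[, "votes1"]
  )
  dplyr::bind_rows(first, out)
}

#' One-row summary of a fitted noisecut model
#'
#' @param x A fitted [noisecut()] model.
#' @param ... Unused.
#' @return A tibble with `n_train`, `n_features`, `n_boxes`, `prior_1`,
#'   `default_label`, `conflict_mass` (total conflict-graph edge mass)
#'   and `cut_mass` (total weight cut by the optimal partitions).
#' @export
glance.noisecut <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_features = x$structure$N,
    n_boxes = x$structure$M,
    prior_1 = x$prior_1,
    default_label = x$default_label,
    conflict_mass = sum(x$solver$conflict_mass),
    cut_mass = sum(x$solver$cut_value)
  )
}

#' Serialize a fitted noisecut model to JSON
#'
#' @param model A fitted [noisecut()] model.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_noisecut_json <- function(model, path) {
  obj <- list(
    n_input_each_box = model$structure$n_input_each_box,
    first_layer = lapply(model$first_layer, function(t) t$table),
    output_table = model$output_table$table,
    output_votes0 = unname(model$output_votes[, "votes0"]),
    output_votes1 = unname(model$output_votes[, "votes1"]),
    default_label = model$default_label,
    prior_1 = model$prior_1,
    n_train = model$n_train
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a fitted noisecut model from JSON
#'
#' @param path File written by [write_noisecut_json()].
#' @return A `noisecut` model (without solver diagnostics).
#' @export
read_noisecut_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- obj$first_layer
  if (is.matrix(fl)) fl <- lapply(seq_len(nrow(fl)), function(i) fl[i, ])
  st <- fn_structure(unlist(obj$n_input_each_box))
  base::structure(
    list(
      structure = st,
      first_layer = lapply(fl, truth_table),
      output_votes = cbind(votes0 = as.integer(obj$output_votes0),
                           votes1 = as.integer(obj$output_votes1)),
      output_table = truth_table(unlist(obj$output_table)),
      default_label = as.integer(obj$default_label),
      prior_1 = as.numeric(obj$prior_1),
      n_train = as.integer(obj$n_train),
      solver = NULL
    ),
    class = "noisecut"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
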