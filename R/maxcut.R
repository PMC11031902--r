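#' Solve a max-cut problem exactly
#'
#' Finds a provably optimal partition of the vertices of a weighted
#' undirected graph into two sides, maximising the total weight of
#' crossing edges, by branch-and-bound (see the package vignette for the
#' bounding strategy). Vertex 1 is always placed on side 0 — the two
#' orientations of a cut are equivalent — and with `lex = TRUE` the
#' returned assignment is additionally the lexicographically smallest
#' optimal one, obtained by a sequence of per-vertex decision solves.
#'
#' The solver never returns a non-optimal cut silently: if `time_limit`
#' is exhausted before optimality is proved, it throws.
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal
#'   (e.g. a `conflict_graph$W`).
#' @param lex Lexicographic tie-breaking among optimal cuts (default
#'   `TRUE`). With `FALSE` the solver still fixes vertex 1 to side 0 and
#'   is deterministic, but ties fall to branch order.
#' @param time_limit Per-call budget in seconds.
#' @param use_eigen Enable the eigenvalue bound (only worth disabling
#'   for profiling).
#' @param eigen_min Smallest free-vertex count at which the eigenvalue
#'   bound is evaluated; below it the residual-mass bound alone prunes
#'   well.
#' @param eigen_iters Projected-subgradient refinement steps for the
#'   bound's correcting vector at each search node.
#' @return An object of class `maxcut_solution`: list with `assignment`
#'   (0/1 vector, `assignment[1] == 0`), `cut_value`, `optimal`
#'   (always `TRUE` on return) and `nodes` (search nodes explored).
#' @examples
#' W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 5
#' solve_maxcut(W)
#' @export
solve_maxcut <- function(W, lex = TRUE, time_limit = 120,
                         use_eigen = TRUE, eigen_min = 14L,
                         eigen_iters = 60L) {
  W <- validate_maxcut_weights(W)
  n <- nrow(W)
  if (n == 1L) {
    return(new_maxcut_solution(0L, 0, 0))
  }
  fixed <- c(0L, rep(-1L, n - 1L))
  deadline <- Sys.time() + time_limit
  res <- .maxcut_bb(W, fixed, target = -1, use_eigen = use_eigen,
                    eigen_min = eigen_min, eigen_iters = eigen_iters,
                    time_limit = time_limit)
  if (!res$completed) {
    stop("max-cut search exceeded the time budget of ", time_limit,
         " s (", format(res$nodes, big.mark = ","),
         " nodes); no optimality proof, refusing to return a cut.",
         call. = FALSE)
  }
  assignment <- res$assignment
  opt <- res$cut_value
  if (lex && n > 2L) {
    for (v in 2:(n - 1L)) {
      if (assignment[v] == 0L) { fixed[v] <- 0L; next }
      trial <- fixed
      trial[v] <- 0L
      left <- as.numeric(difftime(deadline, Sys.time(), units = "secs"))
      if (left <= 0) {
        stop("max-cut lexicographic pass exceeded the time budget.",
             call. = FALSE)
      }
      dec <- .maxcut_bb(W, trial, target = opt, use_eigen = use_eigen,
                        eigen_min = eigen_min, eigen_iters = eigen_iters,
                        time_limit = left)
      if (!dec$completed && !dec$found_target) {
        stop("max-cut lexicographic pass exceeded the time budget.",
             call. = FALSE)
      }
      if (dec$found_target) {
        fixed <- trial
        assignment <- dec$assignment
      } else {
        fixed[v] <- 1L
      }
    }
    # last vertex: prefer 0 if it still attains the optimum
    last <- c(fixed[-n], 0L)
    if (cut_value_of(W, last) >= opt) assignment <- last
    else assignment <- c(fixed[-n], 1L)
  }
  new_maxcut_solution(assignment, opt, res$nodes)
}

new_maxcut_solution <- function(assignment, cut_value, nodes) {
  base::structure(
    list(assignment = as.integer(assignment), cut_value = cut_value,
         optimal = TRUE, nodes = nodes),
    class = "maxcut_solution"
  )
}

#' @export
print.maxcut_solution <- function(x, ...) {
  cat("<maxcut_solution> cut value ", x$cut_value, " over ",
      length(x$assignment), " vertices (optimal)\n", sep = "")
  invisible(x)
}

#' Cut value of a given assignment
#'
#' @param W Weight matrix.
#' @param assignment 0/1 vector over the vertices.
#' @return Total weight of edges crossing the partition.
#' @export
cut_value_of <- function(W, assignment) {
  s <- as.integer(assignment)
  diff <- outer(s, s, `!=`)
  as.numeric(sum(W[upper.tri(W) & diff]))
}

#' Exhaustive max-cut (test oracle)
#'
#' Enumerates all `2^(n-1)` partitions with vertex 1 on side 0 and
#' returns the maximum cut, breaking ties toward the lexicographically
#' smallest assignment. Independent of [solve_maxcut()]; intended as an
#' oracle for small graphs.
#'
#' @param W Symmetric nonnegative weight matrix, at most 20 vertices.
#' @return A `maxcut_solution`.
#' @export
brute_force_maxcut <- function(W) {
  W <- validate_maxcut_weights(W)
  n <- nrow(W)
  if (n > 20L) stop("Brute force is limited to n <= 20 vertices.",
                    call. = FALSE)
  if (n == 1L) return(new_maxcut_solution(0L, 0, 1))
  k <- n - 1L
  n_assign <- 2L^k
  # assignment matrix in lexicographic order of (x_2, ..., x_n)
  A <- matrix(0L, nrow = n_assign, ncol = n)
  codes <- seq_len(n_assign) - 1L
  for (j in seq_len(k)) {
    A[, j + 1L] <- bitwAnd(codes %/% 2L^(k - j), 1L)
  }
  cuts <- numeric(n_assign)
  for (u in seq_len(n - 1L)) {
    for (v in seq.int(u + 1L, n)) {
      if (W[u, v] != 0) {
        cuts <- cuts + W[u, v] * (A[, u] != A[, v])
      }
    }
  }
  best <- which.max(cuts)  # first index = lexicographically smallest
  new_maxcut_solution(A[best, ], cuts[best], n_assign)
}

validate_maxcut_weights <- function(W) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (nrow(W) != ncol(W) || anyNA(W)) {
    stop("`W` must be a square numeric matrix without NAs.", call. = FALSE)
  }
  if (any(W < 0)) stop("`W` must be nonnegative.", call. = FALSE)
  if (!isTRUE(all.equal(W, t(W)))) {
    stop("`W` must be symmetric.", call. = FALSE)
  }
  if (any(diag(W) != 0)) stop("`W` must have a zero diagonal.", call. = FALSE)
  W
}
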