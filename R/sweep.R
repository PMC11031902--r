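#' Run a label-noise sweep over the synthetic benchmark
#'
#' The benchmark experiment: for every generated dataset, noise level
#' and repeat, corrupt the *full* dataset ([flip_labels()]), split it
#' 70/30 ([split_data()]), fit the classifier ([noisecut()]) on the
#' training side, and score predictions against the (noisy) test labels.
#' Every run draws its noise and split seeds deterministically from the
#' master seed, so the sweep is reproducible row for row.
#'
#' @param suite Benchmark tibble from [make_benchmark_suite()] (columns
#'   `dataset_id`, `n_input_each_box`, `data` at minimum).
#' @param noise_levels Noise intensities to sweep (fractions).
#' @param train_fraction Training fraction (default 0.7).
#' @param repeats_per_dataset Fresh noise/split realizations per dataset
#'   and noise level.
#' @param seed Master seed.
#' @param time_limit Per-box max-cut budget in seconds.
#' @param progress Print one line per completed run.
#' @return A tibble of class `noisecut_sweep`: one row per run with
#'   `dataset_id`, `noise`, `rep`, the metric columns of
#'   [evaluate_classifier()] (computed with vote-fraction scores), the
#'   hard-label AUC `auc_hard`, `n_train`, `n_test` and `conflict_mass`.
#'   Failed runs are reported as warnings and omitted, never silently
#'   dropped.
#' @export
run_noise_sweep <- function(suite,
                            noise_levels = c(0, 0.025, 0.05, 0.075, 0.1),
                            train_fraction = 0.7,
                            repeats_per_dataset = 5,
                            seed = 1L,
                            time_limit = 120,
                            progress = FALSE) {
  grid <- tidyr::expand_grid(
    ds = seq_len(nrow(suite)),
    noise = noise_levels,
    rep = seq_len(repeats_per_dataset)
  )
  rows <- purrr::pmap(grid, function(ds, noise, rep) {
    id <- suite$dataset_id[ds]
    noise_seed <- derive_seed(seed, ds, round(noise * 1000), rep, 3L)
    split_seed <- derive_seed(seed, ds, round(noise * 1000), rep, 4L)
    res <- tryCatch({
      noisy <- flip_labels(suite$data[[ds]], noise = noise,
                           seed = noise_seed)
      parts <- split_data(noisy, train_fraction = train_fraction,
                          seed = split_seed)
      fit <- noisecut(parts$train, suite$n_input_each_box[[ds]],
                      time_limit = time_limit)
      y_test <- dataset_labels(parts$test)
      pred <- predict(fit, parts$test)
      score <- predict(fit, parts$test, type = "prob")
      met <- evaluate_classifier(y_test, pred, scores = score)
      met$auc_hard <- evaluate_classifier(y_test, pred)$auc_roc
      dplyr::bind_cols(
        tibble::tibble(dataset_id = id, noise = noise, rep = rep),
        met,
        tibble::tibble(n_train = nrow(parts$train),
                       n_test = nrow(parts$test),
                       conflict_mass = sum(fit$solver$conflict_mass))
      )
    }, error = function(e) {
      warning("run (", id, ", noise=", noise, ", rep=", rep, ") failed: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (progress && !is.null(res)) {
      message(sprintf("  %s noise=%.3f rep=%d acc=%.3f",
                      id, noise, rep, res$accuracy))
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("noisecut_sweep", class(out))
  out
}

#' Aggregate a noise sweep into per-noise-level medians
#'
#' @param results A [run_noise_sweep()] tibble.
#' @param metrics Metric columns to aggregate.
#' @param level,n_boot,seed Passed to [median_with_ci()].
#' @return A tibble with one row per (noise, metric): `median`, `lower`,
#'   `upper`, `n`.
#' @export
aggregate_sweep <- function(results,
                            metrics = c("accuracy", "recall", "precision",
                                        "f1", "auc_roc"),
                            level = 0.95, n_boot = 2000L, seed = 1L) {
  long <- tidyr::pivot_longer(
    dplyr::select(results, dplyr::all_of(c("noise", metrics))),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  dplyr::group_modify(
    dplyr::group_by(long, .data$noise, .data$metric),
    function(df, key) median_with_ci(df$value, level = level,
                                     n_boot = n_boot, seed = seed)
  ) |>
    dplyr::ungroup()
}

#' Plot a noise sweep
#'
#' Median test metric against noise intensity with the bootstrap
#' confidence band, one panel per metric.
#'
#' @param object A [run_noise_sweep()] tibble.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noisecut_sweep <- function(object, metrics = "accuracy", ...) {
  agg <- aggregate_sweep(object, metrics = metrics)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$noise, y = .data$median)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "label-noise intensity",
                  y = "median over runs (95% bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
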