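#' Canonical benchmark problem (objective + bounds)
#'
#' Standard search domains: sphere on `[-100, 100]^d`, Rastrigin on
#' `[-5.12, 5.12]^d`, Rosenbrock on `[-5, 10]^d`.
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param d Dimension.
#' @return A list with `objective` and `space`.
#' @export
benchmark_problem <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                              d = 10L) {
  name <- match.arg(name)
  bounds <- switch(name,
    sphere = c(-100, 100),
    rastrigin = c(-5.12, 5.12),
    rosenbrock = c(-5, 10)
  )
  list(objective = make_test_objective(name, d),
       space = search_space(bounds[1], bounds[2], d = d))
}

#' Run a full-factorial SSA/ISSA benchmark
#'
#' Runs every algorithm on every objective for every seed, recording the
#' per-iteration best-so-far curve and the final fitness of each run.
#' Identical inputs reproduce the report exactly.
#'
#' @param objectives Character vector of test-objective names (resolved
#'   by [benchmark_problem()] at dimension `d`) or a named list of
#'   `list(objective =, space =)` pairs.
#' @param algorithms Subset of `c("ssa", "issa")`.
#' @param cfg An [optimizer_config()]; its seed is overridden per run.
#' @param seeds Integer vector of seeds (one run per seed per cell).
#' @param d Dimension used when `objectives` is a character vector.
#' @return A `benchmark_report`: see [tidy.benchmark_report()],
#'   [glance.benchmark_report()], [paired_comparison()].
#' @examples
#' rep <- run_benchmark("sphere", cfg = optimizer_config(max_iter = 50),
#'                      seeds = 1:2, d = 2)
#' glance(rep)
#' @export
run_benchmark <- function(objectives, algorithms = c("ssa", "issa"),
                          cfg = optimizer_config(), seeds = 1:5,
                          d = 10L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (is.character(objectives)) {
    objectives <- stats::setNames(
      lapply(objectives, benchmark_problem, d = d), objectives)
  }
  if (length(objectives) < 1 || length(seeds) < 1) {
    stop("need at least one objective and one seed", call. = FALSE)
  }
  cells <- tidyr::expand_grid(
    objective = names(objectives),
    arm = algorithms,
    seed = as.integer(seeds)
  )
  runs <- purrr::pmap(cells, function(objective, arm, seed) {
    prob <- objectives[[objective]]
    cfg_i <- cfg
    cfg_i$seed <- seed
    res <- if (arm == "issa") run_issa(prob$objective, prob$space, cfg_i)
           else run_ssa(prob$objective, prob$space, cfg_i)
    tibble::tibble(
      objective = objective, arm = arm, seed = seed,
      final_fitness = res$best_fitness,
      n_evaluations = res$n_evaluations,
      history = list(res$history)
    )
  })
  new_benchmark_report(dplyr::bind_rows(runs), kind = "benchmark")
}

#' Ablate the good-point-set initializer
#'
#' Runs ISSA twice per seed — once from the good-point-set start, once
#' from a random start, everything else identical — and reports the
#' paired final-fitness comparison. This isolates the contribution of
#' the low-discrepancy initialization from that of the elite-guided
#' update.
#'
#' @param objective A test-objective name or a
#'   `list(objective =, space =)` pair.
#' @param cfg An [optimizer_config()].
#' @param seeds Integer vector of seeds.
#' @param d Dimension used when `objective` is a name.
#' @return A `benchmark_report` with arms `"issa_gps"` and
#'   `"issa_random"`.
#' @export
ablate_initializer <- function(objective, cfg = optimizer_config(),
                               seeds = 1:5, d = 10L) {
  prob <- if (is.character(objective)) benchmark_problem(objective, d = d)
          else objective
  obj_name <- prob$objective$name
  runs <- purrr::map(as.integer(seeds), function(seed) {
    cfg_i <- cfg
    cfg_i$seed <- seed
    purrr::map(c(issa_gps = "gps", issa_random = "random"), function(ini) {
      res <- run_issa(prob$objective, prob$space, cfg_i, init = ini)
      tibble::tibble(
        objective = obj_name,
        arm = if (ini == "gps") "issa_gps" else "issa_random",
        seed = seed,
        final_fitness = res$best_fitness,
        n_evaluations = res$n_evaluations,
        history = list(res$history)
      )
    }) |> dplyr::bind_rows()
  })
  new_benchmark_report(dplyr::bind_rows(runs), kind = "ablation")
}

new_benchmark_report <- function(runs, kind) {
  structure(list(runs = runs, kind = kind), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> (", x$kind, ") ", nrow(x$runs), " runs\n",
      sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-run records of a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param histories If `TRUE`, unnest the per-iteration best-so-far
#'   curves into long format (`iteration`, `best_fitness`); otherwise
#'   one row per run with the final fitness.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.benchmark_report <- function(x, histories = FALSE, ...) {
  if (!histories) return(dplyr::select(x$runs, -"history"))
  x$runs |>
    dplyr::mutate(iteration = purrr::map(.data$history, seq_along)) |>
    tidyr::unnest(c("history", "iteration")) |>
    dplyr::rename(best_fitness = "history") |>
    dplyr::select("objective", "arm", "seed", "iteration", "best_fitness")
}

#' Aggregate summary of a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return A tibble with one row per objective x arm: number of runs,
#'   median and IQR of the final fitness, and the best run.
#' @export
glance.benchmark_report <- function(x, ...) {
  x$runs |>
    dplyr::group_by(.data$objective, .data$arm) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      median_final = stats::median(.data$final_fitness),
      iqr_final = stats::IQR(.data$final_fitness),
      best_final = min(.data$final_fitness),
      .groups = "drop"
    )
}

#' Paired-seed comparison between two arms
#'
#' For every objective and seed shared by both arms, compares the final
#' fitness and counts wins (arm `a` strictly better, i.e. lower for
#' minimization), losses, and ties. Wins + losses + ties equals the
#' number of shared seeds.
#'
#' @param report A `benchmark_report`.
#' @param a,b Arm labels; default the report's first two arms.
#' @param tol Absolute tie tolerance on the final fitness.
#' @return A tibble with one row per objective: `wins_a`, `losses_a`,
#'   `ties`, `n_pairs`, `median_a`, `median_b`.
#' @export
paired_comparison <- function(report, a = NULL, b = NULL, tol = 0) {
  arms <- unique(report$runs$arm)
  if (is.null(a)) a <- arms[1]
  if (is.null(b)) b <- arms[2]
  wide <- report$runs |>
    dplyr::filter(.data$arm %in% c(a, b)) |>
    dplyr::select("objective", "arm", "seed", "final_fitness") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "final_fitness")
  wide |>
    dplyr::group_by(.data$objective) |>
    dplyr::summarise(
      wins_a = sum(.data[[a]] < .data[[b]] - tol),
      losses_a = sum(.data[[a]] > .data[[b]] + tol),
      ties = sum(abs(.data[[a]] - .data[[b]]) <= tol),
      n_pairs = dplyr::n(),
      median_a = stats::median(.data[[a]]),
      median_b = stats::median(.data[[b]]),
      .groups = "drop"
    )
}

#' Plot benchmark convergence curves
#'
#' Median best-so-far fitness per iteration, one line per arm, faceted
#' by objective, log-scale fitness axis when all values are positive.
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_report <- function(object, ...) {
  df <- tidy(object, histories = TRUE) |>
    dplyr::group_by(.data$objective, .data$arm, .data$iteration) |>
    dplyr::summarise(best_fitness = stats::median(.data$best_fitness),
                     .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                        y = .data$best_fitness,
                                        colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~objective, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = "Median best-so-far fitness",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (all(df$best_fitness > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
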