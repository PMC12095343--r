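#' Define an objective function for the optimizer
#'
#' Wraps an evaluator together with its optimization sense. Internally
#' the optimizers always minimize; a `maximize` objective is negated at
#' this boundary so there is a single code path.
#'
#' @param fn Function mapping a length-`d` numeric position to a finite
#'   scalar.
#' @param sense `"minimize"` (default) or `"maximize"`.
#' @param known_optimum Optional scalar: the objective value at the
#'   global optimum, for test functions.
#' @param name Optional label used in reports.
#' @return An object of class `objective`.
#' @export
objective <- function(fn, sense = c("minimize", "maximize"),
                      known_optimum = NULL, name = "custom") {
  stopifnot(is.function(fn))
  sense <- match.arg(sense)
  structure(
    list(fn = fn, sense = sense, known_optimum = known_optimum, name = name),
    class = "objective"
  )
}

#' @export
print.objective <- function(x, ...) {
  cat("<objective> ", x$name, " (", x$sense, ")\n", sep = "")
  invisible(x)
}

#' Standard benchmark objectives
#'
#' Closed-form test functions with known global minimum 0:
#' * `sphere`: `sum(x^2)`, minimum at the origin;
#' * `rastrigin`: `10 d + sum(x^2 - 10 cos(2 pi x))`, highly multimodal,
#'   minimum at the origin;
#' * `rosenbrock`: `sum(100 (x[j+1] - x[j]^2)^2 + (1 - x[j])^2)`, a
#'   curved valley with minimum at the all-ones vector.
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param d Dimension.
#' @return An `objective` with `known_optimum = 0`.
#' @examples
#' obj <- make_test_objective("sphere", 3)
#' obj$fn(c(0, 0, 0))
#' @export
make_test_objective <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                                d) {
  name <- match.arg(name)
  check_count(d, "d")
  fn <- switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      if (length(x) < 2) return((1 - x[1])^2)
      sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
    }
  )
  objective(fn, sense = "minimize", known_optimum = 0, name = name)
}

#' Rectangular search space
#'
#' @param lb,ub Numeric bound vectors with `ub > lb` elementwise; scalars
#'   are recycled to length `d`.
#' @param d Dimension; defaults to `length(lb)`.
#' @return An object of class `search_space` with fields `d`, `lb`, `ub`.
#' @examples
#' search_space(-100, 100, d = 10)
#' @export
search_space <- function(lb, ub, d = max(length(lb), length(ub))) {
  check_count(d, "d")
  lb <- rep_len(as.numeric(lb), d)
  ub <- rep_len(as.numeric(ub), d)
  if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(ub <= lb)) {
    stop("bounds must be finite with `ub` > `lb` in every dimension",
         call. = FALSE)
  }
  structure(list(d = as.integer(d), lb = lb, ub = ub),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> d =", x$d, "\n")
  invisible(x)
}

#' Optimizer configuration
#'
#' All tunables for [run_ssa()] and [run_issa()].
#'
#' @param pop_size Population size `N` (at least 4).
#' @param max_iter Number of iterations `T`.
#' @param discoverer_fraction Fraction of the population acting as
#'   discoverers (producers), in (0,1).
#' @param scout_fraction Fraction acting as scouts, in (0,1);
#'   `discoverer_fraction + scout_fraction` must be below 1.
#' @param alarm_threshold Alarm threshold `ST` in (0,1): probability of
#'   the cautious multiplicative-decay discoverer move rather than the
#'   normal-step move.
#' @param alpha Learning rate of the elite-guided update (pull strength
#'   toward the best position), positive.
#' @param beta Perturbation scale of the elite-guided update, positive;
#'   multiplied by `(rand - 0.5)` and the per-dimension bound range.
#' @param elite_fraction Fraction `q` in (0,1] of the population kept in
#'   the elite set.
#' @param seed Integer seed controlling every random draw of a run.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 30L, max_iter = 500L,
                             discoverer_fraction = 0.2,
                             scout_fraction = 0.1,
                             alarm_threshold = 0.8,
                             alpha = 0.5, beta = 0.3,
                             elite_fraction = 0.2, seed = 1L) {
  check_count(pop_size, "pop_size")
  check_count(max_iter, "max_iter")
  stopifnot(
    pop_size >= 4,
    discoverer_fraction > 0, discoverer_fraction < 1,
    scout_fraction > 0, scout_fraction < 1,
    alarm_threshold > 0, alarm_threshold <= 1,
    alpha > 0, beta >= 0,
    elite_fraction > 0, elite_fraction <= 1
  )
  if (discoverer_fraction + scout_fraction >= 1) {
    stop("`discoverer_fraction` + `scout_fraction` must be below 1",
         call. = FALSE)
  }
  n_disc <- ceiling(discoverer_fraction * pop_size)
  n_scout <- ceiling(scout_fraction * pop_size)
  if (n_disc + n_scout >= pop_size) {
    stop("role fractions leave no followers: ",
         "ceiling(PD*N) + ceiling(SD*N) must be below N", call. = FALSE)
  }
  structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         discoverer_fraction = discoverer_fraction,
         scout_fraction = scout_fraction,
         alarm_threshold = alarm_threshold,
         alpha = alpha, beta = beta,
         elite_fraction = elite_fraction, seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

#' @export
print.optimizer_config <- function(x, ...) {
  cat("<optimizer_config> N =", x$pop_size, " T =", x$max_iter,
      " PD =", x$discoverer_fraction, " SD =", x$scout_fraction,
      " ST =", x$alarm_threshold, "\n  alpha =", x$alpha,
      " beta =", x$beta, " q =", x$elite_fraction, " seed =", x$seed, "\n")
  invisible(x)
}

#' Read an optimizer configuration from YAML or JSON
#'
#' The file holds a mapping with exactly the [optimizer_config()] field
#' names (any subset; missing fields take the defaults) and optionally an
#' `algorithm` key, `"ssa"` or `"issa"`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `optimizer_config`, with attribute `"algorithm"` if the
#'   file set one.
#' @export
read_optimizer_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  algorithm <- raw$algorithm
  raw$algorithm <- NULL
  known <- names(formals(optimizer_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(optimizer_config, raw)
  if (!is.null(algorithm)) {
    algorithm <- match.arg(algorithm, c("ssa", "issa"))
    attr(cfg, "algorithm") <- algorithm
  }
  cfg
}
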