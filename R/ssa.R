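#' Create a sparrow population
#'
#' Container for the state of one iteration of the sparrow search: the
#' candidate positions, their fitness, role labels, and the best position
#' found so far. Fitness is stored internally in minimize sense
#' (maximize objectives are negated on entry and un-negated in results).
#'
#' @param positions `N` x `d` numeric matrix inside the space bounds.
#' @param space A [search_space()].
#' @param sense `"minimize"` or `"maximize"`; used when reporting.
#' @return An object of class `sparrow_population`.
#' @keywords internal
#' @export
sparrow_population <- function(positions, space,
                               sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == space$d)
  structure(
    list(positions = positions, space = space, sense = sense,
         fitness = rep(NA_real_, nrow(positions)),
         roles = rep(NA_character_, nrow(positions)),
         best_position = NULL, best_fitness = Inf,
         n_evaluations = 0L),
    class = "sparrow_population"
  )
}

#' Random uniform initialization
#'
#' Draws `n` positions independently and uniformly inside the bounds,
#' entry `X[i, j] ~ U(lb_j, ub_j)`.
#'
#' @param space A [search_space()].
#' @param n Number of positions.
#' @param seed Optional integer; if given, the draw is made under this
#'   seed without disturbing the caller's RNG stream. If `NULL`, the
#'   ambient stream is used.
#' @return An `n` x `d` matrix.
#' @export
random_init <- function(space, n, seed = NULL) {
  check_count(n, "n")
  draw <- function() {
    u <- matrix(stats::runif(n * space$d), nrow = n, ncol = space$d)
    map_to_bounds(u, space$lb, space$ub)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Evaluate the fitness of every sparrow
#'
#' Applies the objective to each row, records internal (minimize-sense)
#' fitness, updates the best-so-far position, and increments the
#' evaluation counter by `N`.
#'
#' @param pop A `sparrow_population`.
#' @param obj An [objective()].
#' @return The updated population.
#' @export
evaluate_population <- function(pop, obj) {
  vals <- evaluate_matrix(pop$positions, obj, pop$sense)
  pop$fitness <- vals
  i <- which.min(vals)
  if (vals[i] < pop$best_fitness) {
    pop$best_fitness <- vals[i]
    pop$best_position <- pop$positions[i, ]
  }
  pop$n_evaluations <- pop$n_evaluations + nrow(pop$positions)
  pop
}

evaluate_matrix <- function(positions, obj, sense) {
  vals <- vapply(seq_len(nrow(positions)),
                 function(i) as.numeric(obj$fn(positions[i, ])),
                 numeric(1))
  if (sense == "maximize") vals <- -vals
  bad <- which(!is.finite(vals))
  if (length(bad) > 0) {
    stop("objective returned a non-finite value at position [",
         paste(signif(positions[bad[1], ], 6), collapse = ", "), "]",
         call. = FALSE)
  }
  vals
}

#' Assign discoverer / follower / scout roles
#'
#' The best `ceiling(PD * N)` individuals by fitness become discoverers
#' (ties broken by lowest index); `ceiling(SD * N)` individuals drawn
#' uniformly at random from the remainder become scouts; the rest are
#' followers. Uses the ambient RNG stream for the scout draw.
#'
#' @param pop An evaluated `sparrow_population`.
#' @param cfg An [optimizer_config()].
#' @return The population with `roles` filled.
#' @export
partition_roles <- function(pop, cfg) {
  n <- nrow(pop$positions)
  if (anyNA(pop$fitness)) stop("fitness must be evaluated first", call. = FALSE)
  n_disc <- ceiling(cfg$discoverer_fraction * n)
  n_scout <- ceiling(cfg$scout_fraction * n)
  if (n_disc + n_scout >= n) {
    stop("role fractions exhaust the population", call. = FALSE)
  }
  ord <- order(pop$fitness, seq_len(n))  # ties: lowest index first
  roles <- rep("follower", n)
  disc <- ord[seq_len(n_disc)]
  roles[disc] <- "discoverer"
  rest <- setdiff(seq_len(n), disc)
  scouts <- rest[sample.int(length(rest), n_scout)]
  roles[scouts] <- "scout"
  pop$roles <- roles
  pop
}

#' Discoverer (producer) position update
#'
#' For each discoverer, with probability `ST` (no alarm) the position
#' shrinks multiplicatively, `X * exp(-rank / (u * T))` with
#' `u ~ U(0, 1]` and `rank` the discoverer's fitness rank; otherwise
#' (alarm raised) it takes a common normal step `X + Q` with
#' `Q ~ N(0, 1)` shared across dimensions. Results are clamped to the
#' bounds.
#'
#' @param pop A `sparrow_population` with roles assigned.
#' @param cfg An [optimizer_config()].
#' @param t Current iteration (unused by the formula beyond `T`).
#' @return The population with discoverer rows updated.
#' @export
discoverer_update <- function(pop, cfg, t = 1L) {
  idx <- which(pop$roles == "discoverer")
  if (length(idx) == 0) return(pop)
  # rank discoverers among themselves by fitness (1 = best)
  rk <- rank(pop$fitness[idx], ties.method = "first")
  for (k in seq_along(idx)) {
    i <- idx[k]
    r <- stats::runif(1)
    if (r < cfg$alarm_threshold) {
      u <- 1 - stats::runif(1)  # in (0, 1]
      pop$positions[i, ] <- pop$positions[i, ] *
        exp(-rk[k] / (u * cfg$max_iter))
    } else {
      pop$positions[i, ] <- pop$positions[i, ] + stats::rnorm(1)
    }
  }
  pop$positions[idx, ] <- clamp_rows(pop$positions[idx, , drop = FALSE],
                                     pop$space)
  pop
}

#' Follower (scrounger) position update
#'
#' Followers in the worst half of the population (by overall fitness
#' rank) migrate: `X_new = Q * exp((X_worst - X) / rank^2)` with `Q` a
#' standard-normal scalar. Followers in the better half move next to the
#' best position: `X_new = X_best + |X - X_best| . A` where `A` is a
#' random per-dimension sign vector scaled by `1/d`. Clamped to bounds.
#'
#' @inheritParams discoverer_update
#' @return The population with follower rows updated.
#' @export
follower_update <- function(pop, cfg) {
  idx <- which(pop$roles == "follower")
  if (length(idx) == 0) return(pop)
  n <- nrow(pop$positions)
  d <- ncol(pop$positions)
  overall_rank <- rank(pop$fitness, ties.method = "first")
  worst <- pop$positions[which.max(pop$fitness), ]
  best <- pop$best_position
  for (i in idx) {
    if (overall_rank[i] > n / 2) {
      q <- stats::rnorm(1)
      pop$positions[i, ] <-
        q * exp((worst - pop$positions[i, ]) / overall_rank[i]^2)
    } else {
      signs <- sample(c(-1, 1), d, replace = TRUE)
      pop$positions[i, ] <-
        best + abs(pop$positions[i, ] - best) * signs / d
    }
  }
  pop$positions[idx, ] <- clamp_rows(pop$positions[idx, , drop = FALSE],
                                     pop$space)
  pop
}

#' Scout position update
#'
#' Each scout moves a uniform-random fraction of the way toward the best
#' position: `X_new = X + rand * (X_best - X)`, one `rand ~ U(0,1)` per
#' scout shared across dimensions, so the move stays on the segment
#' between `X` and `X_best`.
#'
#' @inheritParams discoverer_update
#' @return The population with scout rows updated.
#' @export
scout_update <- function(pop, cfg) {
  idx <- which(pop$roles == "scout")
  if (length(idx) == 0) return(pop)
  best <- pop$best_position
  for (i in idx) {
    r <- stats::runif(1)
    pop$positions[i, ] <- pop$positions[i, ] +
      r * (best - pop$positions[i, ])
  }
  pop$positions[idx, ] <- clamp_rows(pop$positions[idx, , drop = FALSE],
                                     pop$space)
  pop
}

clamp_rows <- function(m, space) {
  m <- pmin(pmax(m, matrix(space$lb, nrow(m), ncol(m), byrow = TRUE)),
            matrix(space$ub, nrow(m), ncol(m), byrow = TRUE))
  m
}

#' Run the baseline sparrow search algorithm
#'
#' Random uniform initialization followed by `max_iter` iterations of
#' evaluate, role partition, and discoverer / follower / scout updates.
#' The best-so-far fitness is recorded once per iteration; total
#' objective evaluations equal `N * (T + 1)`. The whole run is
#' reproducible from `cfg$seed`.
#'
#' @param obj An [objective()].
#' @param space A [search_space()].
#' @param cfg An [optimizer_config()].
#' @return A `sparrow_result`; see [tidy.sparrow_result()].
#' @examples
#' sp <- search_space(-100, 100, d = 2)
#' res <- run_ssa(make_test_objective("sphere", 2), sp,
#'                optimizer_config(pop_size = 20, max_iter = 50, seed = 1))
#' res$best_fitness
#' @export
run_ssa <- function(obj, space, cfg = optimizer_config()) {
  run_sparrow_engine(obj, space, cfg, algorithm = "ssa")
}

# Shared SSA/ISSA loop. `init` chooses the starting population;
# `elite_stage` switches the fitness-preserving elite-guided refresh on.
run_sparrow_engine <- function(obj, space, cfg,
                               algorithm = c("ssa", "issa"),
                               init = NULL) {
  algorithm <- match.arg(algorithm)
  elite_stage <- algorithm == "issa"
  if (is.null(init)) {
    init <- if (algorithm == "issa") "gps" else "random"
  }
  withr::with_seed(cfg$seed, {
    X0 <- switch(init,
      random = random_init(space, cfg$pop_size),
      gps = map_to_bounds(good_point_set(cfg$pop_size, space$d),
                          space$lb, space$ub)
    )
    pop <- sparrow_population(X0, space, sense = obj$sense)
    pop <- evaluate_population(pop, obj)
    history <- numeric(cfg$max_iter)
    for (t in seq_len(cfg$max_iter)) {
      pop <- partition_roles(pop, cfg)
      pop <- discoverer_update(pop, cfg, t)
      pop <- follower_update(pop, cfg)
      pop <- scout_update(pop, cfg)
      pop <- evaluate_population(pop, obj)
      if (elite_stage) {
        pop <- elite_stage_update(pop, obj, cfg)
      }
      history[t] <- pop$best_fitness
    }
    new_sparrow_result(pop, history, obj, cfg, algorithm, init)
  })
}

new_sparrow_result <- function(pop, history, obj, cfg, algorithm, init) {
  sgn <- if (obj$sense == "maximize") -1 else 1
  structure(
    list(best_position = pop$best_position,
         best_fitness = sgn * pop$best_fitness,
         history = sgn * history,
         n_evaluations = pop$n_evaluations,
         seed = cfg$seed,
         algorithm = algorithm,
         init = init,
         objective_name = obj$name,
         sense = obj$sense,
         config = cfg),
    class = "sparrow_result"
  )
}

#' @export
print.sparrow_result <- function(x, ...) {
  cat("<sparrow_result> ", toupper(x$algorithm), " on ", x$objective_name,
      " (", x$sense, ")\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness, digits = 6),
      "  evaluations: ", x$n_evaluations, "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Tidy a sparrow search result
#'
#' @param x A `sparrow_result`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`,
#'   `best_fitness` (best-so-far), `algorithm`, `objective`, `seed`.
#' @export
tidy.sparrow_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$history),
    best_fitness = x$history,
    algorithm = x$algorithm,
    objective = x$objective_name,
    seed = x$seed
  )
}

#' One-row summary of a sparrow search result
#'
#' @param x A `sparrow_result`.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, objective, best fitness, gap to
#'   the known optimum (if any), evaluation count, seed.
#' @export
glance.sparrow_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    objective = x$objective_name,
    best_fitness = x$best_fitness,
    n_iterations = length(x$history),
    n_evaluations = x$n_evaluations,
    seed = x$seed
  )
}

#' Plot the convergence curve of a run
#'
#' Best-so-far fitness against iteration, log-scaled where all values
#' are positive.
#'
#' @param object A `sparrow_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sparrow_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                        y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Best-so-far fitness",
                  title = paste(toupper(object$algorithm), "on",
                                object$objective_name)) +
    ggplot2::theme_minimal()
  if (all(df$best_fitness > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
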