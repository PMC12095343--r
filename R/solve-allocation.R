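#' Solve an allocation problem with SSA or ISSA
#'
#' Treats every sparrow as a candidate allocation: positions live in the
#' per-target box, every position is repaired to feasibility
#' ([repair_allocation()]: clamp, project onto the box-constrained
#' simplex, shrink to the variance cap) before its weighted effect is
#' evaluated, and the optimizer maximizes the repaired objective. The
#' returned solution is the repaired best position with its balance
#' score and a constraint-by-constraint feasibility report.
#'
#' @param prob An [allocation_problem()].
#' @param cfg An [optimizer_config()].
#' @param algorithm `"issa"` (default) or `"ssa"`.
#' @return An object of class `allocation_solution` with fields `x`,
#'   `objective_value`, `balance`, `feasible` (named flags), `repaired`,
#'   `problem`, and `result` (the underlying `sparrow_result`).
#' @examples
#' prob <- allocation_problem(data.frame(efficiency = c(2, 1, 1.5)),
#'                            delta_sq = 0.6)
#' sol <- solve_allocation(prob, optimizer_config(max_iter = 100, seed = 1))
#' tidy(sol)
#' @export
solve_allocation <- function(prob, cfg = optimizer_config(),
                             algorithm = c("issa", "ssa")) {
  algorithm <- match.arg(algorithm)
  tg <- prob$targets
  # widen degenerate box dimensions epsilon-wise is unnecessary: the
  # search space requires ub > lb, which validation guarantees except
  # when lb == ub == 1/n (n = 1); handle the trivial case directly
  if (prob$n == 1L) {
    return(new_allocation_solution(1, prob, repaired = FALSE,
                                   result = NULL, algorithm = algorithm))
  }
  lb <- tg$lb
  ub <- tg$ub
  if (any(ub <= lb)) {
    fix <- ub <= lb
    lb[fix] <- pmax(lb[fix] - 1e-9, 0)
    ub[fix] <- pmin(ub[fix] + 1e-9, 1)
  }
  space <- search_space(lb, ub, d = prob$n)
  obj <- objective(
    make_allocation_evaluator(prob),
    sense = "maximize", name = paste0("allocation-", prob$category)
  )
  res <- if (algorithm == "issa") run_issa(obj, space, cfg) else
    run_ssa(obj, space, cfg)
  x <- repair_allocation(res$best_position, prob)
  new_allocation_solution(as.numeric(x), prob,
                          repaired = attr(x, "repaired"),
                          result = res, algorithm = algorithm)
}

# Fast repaired-objective evaluator for the optimizer hot path: same
# mathematics as allocation_objective(repair_allocation(v, prob), prob)
# but with the target table unpacked into plain vectors up front.
make_allocation_evaluator <- function(prob) {
  tg <- prob$targets
  lb <- as.numeric(tg$lb)
  ub <- as.numeric(tg$ub)
  w <- as.numeric(tg$weight)
  E <- as.numeric(tg$efficiency)
  fam <- tg$g_family
  par <- as.numeric(tg$g_param)
  n <- prob$n
  d2 <- prob$delta_sq
  all_linear <- all(fam == "linear")
  wE <- w * E
  uni <- 1 / n
  function(v) {
    x <- pmin(pmax(v, lb), ub)
    x <- project_box_simplex(x, lb, ub)
    ss <- sum(x * x)
    if (ss > d2) {
      t <- sqrt(max(d2 - uni, 0) / (ss - uni))
      x <- uni + t * (x - uni)
    }
    if (all_linear) return(sum(wE * x))
    g <- numeric(n)
    for (a in seq_len(n)) {
      g[a] <- switch(fam[a],
        linear = E[a] * x[a],
        saturating = E[a] * (1 - exp(-par[a] * x[a])),
        power = E[a] * max(x[a], 0)^par[a])
    }
    sum(w * g)
  }
}

new_allocation_solution <- function(x, prob, repaired, result, algorithm) {
  structure(
    list(x = x,
         objective_value = allocation_objective(x, prob),
         balance = jain_balance(x),
         feasible = allocation_feasibility(x, prob),
         repaired = isTRUE(repaired),
         algorithm = algorithm,
         problem = prob,
         result = result),
    class = "allocation_solution"
  )
}

#' @export
print.allocation_solution <- function(x, ...) {
  cat("<allocation_solution> ", toupper(x$algorithm), " on ",
      x$problem$category, " (", x$problem$n, " targets)\n", sep = "")
  cat("  objective: ", format(x$objective_value, digits = 6),
      "   balance: ", format(x$balance, digits = 4),
      "   feasible: ", all(x$feasible), "\n", sep = "")
  invisible(x)
}

#' Tidy an allocation solution
#'
#' @param x An `allocation_solution`.
#' @param ... Unused.
#' @return A tibble with one row per target: `target_id`, `efficiency`,
#'   `weight`, `share`, `effect` (the target's weighted contribution to
#'   the objective).
#' @export
tidy.allocation_solution <- function(x, ...) {
  tg <- x$problem$targets
  share <- x$x
  contrib <- vapply(seq_len(x$problem$n), function(a) {
    xa <- share[a]
    g <- switch(tg$g_family[a],
      linear = tg$efficiency[a] * xa,
      saturating = tg$efficiency[a] * (1 - exp(-tg$g_param[a] * xa)),
      power = tg$efficiency[a] * max(xa, 0)^tg$g_param[a])
    tg$weight[a] * g
  }, numeric(1))
  tibble::tibble(
    target_id = tg$target_id,
    efficiency = tg$efficiency,
    weight = tg$weight,
    share = share,
    effect = contrib
  )
}

#' One-row summary of an allocation solution
#'
#' @param x An `allocation_solution`.
#' @param ... Unused.
#' @return A one-row tibble: objective value, Jain balance, feasibility
#'   flags, number of evaluations, seed.
#' @export
glance.allocation_solution <- function(x, ...) {
  tibble::tibble(
    category = x$problem$category,
    n_targets = x$problem$n,
    delta_sq = x$problem$delta_sq,
    algorithm = x$algorithm,
    objective_value = x$objective_value,
    balance = x$balance,
    feasible = all(x$feasible),
    repaired = x$repaired,
    n_evaluations = if (is.null(x$result)) 0L else x$result$n_evaluations,
    seed = if (is.null(x$result)) NA_integer_ else x$result$seed
  )
}

#' Plot an allocation solution
#'
#' Bar chart of shares per target, annotated with the balance score and
#' the uniform share `1/n` as a reference line.
#'
#' @param object An `allocation_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.allocation_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_id, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / object$problem$n,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Target", y = "Share",
      title = sprintf("%s allocation (balance %.3f)",
                      object$problem$category, object$balance)) +
    ggplot2::theme_minimal()
}
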