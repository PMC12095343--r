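#' Exact optimum of the linear allocation problem (KKT oracle)
#'
#' Maximizes `sum(x * E)` over `{sum(x) = 1, x >= 0, sum(x^2) <= delta_sq}`
#' by enumerating the Karush-Kuhn-Tucker active sets. For a linear
#' objective over this (simplex intersected with an L2 ball) region the
#' support of the optimum is a top-`k` prefix of the targets sorted by
#' efficiency; on the support, stationarity gives
#' `x_a = 1/k + (E_a - mean(E_S)) / (2 mu)` with the ball multiplier
#' `2 mu = sqrt(sum((E_S - mean(E_S))^2) / (delta_sq - 1/k))`. The
#' oracle evaluates every prefix candidate (plus the one-hot vertex,
#' feasible only when `delta_sq >= 1`) and returns the feasible one with
#' the largest objective. Ties in efficiency are broken by lowest index.
#'
#' This serves as the independent ground truth for
#' [solve_allocation()] on linear problems; for `n <= 3` it can itself
#' be checked against [grid_oracle_linear()].
#'
#' @param E Positive efficiency vector.
#' @param delta_sq Second-moment cap in `[1/n, 1]`.
#' @param n Number of targets; defaults to `length(E)`.
#' @return A list: `x` (the maximizer), `value` (the maximum), `support`
#'   (indices of positive shares).
#' @examples
#' kkt_oracle_linear(c(2, 1), 0.625)  # x = (0.75, 0.25), value 1.75
#' @export
kkt_oracle_linear <- function(E, delta_sq, n = length(E)) {
  stopifnot(length(E) == n, all(E > 0))
  if (delta_sq < 1 / n - 1e-12) {
    stop("infeasible variance cap: delta_sq below 1/n", call. = FALSE)
  }
  if (delta_sq > 1 + 1e-12) delta_sq <- 1
  ord <- order(-E, seq_len(n))  # efficiency descending, lowest index first
  best <- NULL
  for (k in seq_len(n)) {
    S <- ord[seq_len(k)]
    Es <- E[S]
    x <- rep(0, n)
    if (delta_sq <= 1 / k + 1e-14) {
      # cap at (or numerically at) its minimum for this support: uniform
      if (delta_sq < 1 / k - 1e-12) next
      x[S] <- 1 / k
    } else {
      s2 <- sum((Es - mean(Es))^2)
      if (s2 == 0) {
        x[S] <- 1 / k
      } else {
        two_mu <- sqrt(s2 / (delta_sq - 1 / k))
        x[S] <- 1 / k + (Es - mean(Es)) / two_mu
      }
    }
    if (any(x < -1e-12)) next
    x <- pmax(x, 0)
    x <- x / sum(x)
    if (sum(x^2) > delta_sq + 1e-9) next
    val <- sum(x * E)
    if (is.null(best) || val > best$value + 1e-15) {
      best <- list(x = x, value = val, support = which(x > 1e-12))
    }
  }
  best
}

#' Dense grid-search oracle for small linear problems
#'
#' Brute-force maximizer of `sum(x * E)` over the constrained simplex by
#' enumerating a regular grid of step `step` (only `n` of 2 or 3 are
#' supported — the grid is exhaustive, which is the point). Used to
#' cross-check [kkt_oracle_linear()].
#'
#' @param E Efficiency vector of length 2 or 3.
#' @param delta_sq Second-moment cap.
#' @param step Grid resolution (default 1e-3).
#' @return A list with `x` and `value`.
#' @export
grid_oracle_linear <- function(E, delta_sq, step = 1e-3) {
  n <- length(E)
  if (!n %in% c(2L, 3L)) {
    stop("the grid oracle supports n = 2 or 3 only", call. = FALSE)
  }
  g <- seq(0, 1, by = step)
  if (n == 2L) {
    x1 <- g
    x2 <- 1 - x1
    ok <- x1^2 + x2^2 <= delta_sq + 1e-12
    vals <- x1 * E[1] + x2 * E[2]
    vals[!ok] <- -Inf
    i <- which.max(vals)
    return(list(x = c(x1[i], x2[i]), value = vals[i]))
  }
  grid <- expand.grid(x1 = g, x2 = g)
  x3 <- 1 - grid$x1 - grid$x2
  ok <- x3 >= -1e-12 & (grid$x1^2 + grid$x2^2 + x3^2) <= delta_sq + 1e-12
  vals <- grid$x1 * E[1] + grid$x2 * E[2] + pmax(x3, 0) * E[3]
  vals[!ok] <- -Inf
  i <- which.max(vals)
  list(x = c(grid$x1[i], grid$x2[i], max(x3[i], 0)), value = vals[i])
}

#' Dense grid-search oracle for general effect curves (n = 2 or 3)
#'
#' Same exhaustive grid as [grid_oracle_linear()] but maximizing the
#' full weighted-effect objective of an [allocation_problem()],
#' including saturating and power effect curves. Slow by design; used in
#' tests of monotone resource response.
#'
#' @param prob An `allocation_problem` with 2 or 3 targets.
#' @param step Grid resolution.
#' @return A list with `x` and `value`.
#' @export
grid_oracle_problem <- function(prob, step = 1e-2) {
  n <- prob$n
  if (!n %in% c(2L, 3L)) {
    stop("the grid oracle supports n = 2 or 3 only", call. = FALSE)
  }
  g <- seq(0, 1, by = step)
  pts <- if (n == 2L) {
    cbind(g, 1 - g)
  } else {
    grid <- as.matrix(expand.grid(g, g))
    cbind(grid, 1 - rowSums(grid))
  }
  pts <- pts[pts[, n] >= -1e-12, , drop = FALSE]
  pts[, n] <- pmax(pts[, n], 0)
  tg <- prob$targets
  ok <- rowSums(pts^2) <= prob$delta_sq + 1e-12
  for (a in seq_len(n)) {
    ok <- ok & pts[, a] >= tg$lb[a] - 1e-12 & pts[, a] <= tg$ub[a] + 1e-12
  }
  pts <- pts[ok, , drop = FALSE]
  vals <- apply(pts, 1, allocation_objective, prob = prob)
  i <- which.max(vals)
  list(x = pts[i, ], value = vals[i])
}
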