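#' Euclidean projection onto the probability simplex
#'
#' Projects `v` onto `{x : x >= 0, sum(x) = 1}` by the sorted-threshold
#' algorithm: sort `v` decreasingly, find the largest `k` with
#' `v_(k) + (1 - sum of top k) / k > 0`, and subtract the resulting
#' threshold, clipping at zero. The projection is idempotent and leaves
#' simplex points unchanged.
#'
#' @param v Numeric vector.
#' @return The closest (in Euclidean norm) point of the simplex.
#' @examples
#' project_to_simplex(c(0.5, 0.5, 1.0))  # (1/6, 1/6, 2/3)
#' @export
project_to_simplex <- function(v) {
  n <- length(v)
  if (n < 1) stop("`v` must be nonempty", call. = FALSE)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(u + (1 - css) / seq_len(n) > 0))
  theta <- (css[k] - 1) / k
  pmax(v - theta, 0)
}

# Euclidean projection onto {sum(x) = 1, lb <= x <= ub}: the solution is
# x = clip(v - theta, lb, ub), where theta solves the piecewise-linear
# equation sum(clip(v - theta, lb, ub)) = 1. The sum is non-increasing
# in theta with breakpoints at v - ub and v - lb, so theta is found
# exactly by sorting the 2n breakpoints and interpolating on the
# bracketing segment. Assumes sum(lb) <= 1 <= sum(ub).
project_box_simplex <- function(v, lb, ub) {
  bp <- sort(c(v - ub, v - lb))
  s_at <- .colSums(pmin(pmax(outer(v, bp, "-"), lb), ub),
                   length(v), length(bp))
  if (s_at[1] <= 1) {
    theta <- bp[1]
  } else if (s_at[length(bp)] >= 1) {
    theta <- bp[length(bp)]
  } else {
    k <- max(which(s_at >= 1))
    s1 <- s_at[k]; s2 <- s_at[k + 1]
    theta <- if (s2 == s1) bp[k] else
      bp[k] + (s1 - 1) * (bp[k + 1] - bp[k]) / (s1 - s2)
  }
  x <- pmin(pmax(v - theta, lb), ub)
  # spread any residual rounding over the interior coordinates
  resid <- 1 - sum(x)
  free <- x > lb + 1e-12 & x < ub - 1e-12
  if (abs(resid) > 0 && any(free)) {
    x[free] <- x[free] + resid / sum(free)
  }
  x
}

#' Shrink an allocation to meet the variance cap
#'
#' If `sum(x^2) > delta_sq`, the allocation is pulled toward the uniform
#' vector `u = 1/n` along the segment joining them:
#' `u + t * (x - u)` with `t = sqrt((delta_sq - 1/n) / (sum(x^2) - 1/n))`,
#' which stays on the simplex, preserves the ranking of the components,
#' and meets `sum(x^2) = delta_sq` exactly. Allocations already under
#' the cap are returned unchanged.
#'
#' @param x Allocation on the simplex.
#' @param delta_sq Second-moment cap, at least `1/length(x)`.
#' @return An allocation on the simplex with `sum(x^2) <= delta_sq`.
#' @examples
#' enforce_variance_cap(c(1, 0), 0.625)  # (0.75, 0.25)
#' @export
enforce_variance_cap <- function(x, delta_sq) {
  n <- length(x)
  if (delta_sq < 1 / n - 1e-12) {
    stop(sprintf("infeasible variance cap: delta_sq = %.4g < 1/n = %.4g",
                 delta_sq, 1 / n), call. = FALSE)
  }
  ss <- sum(x^2)
  if (ss <= delta_sq) return(x)
  u <- 1 / n
  t <- sqrt(max(delta_sq - u, 0) / (ss - u))
  u + t * (x - u)
}

#' Repair an arbitrary vector into a feasible allocation
#'
#' Maps any real vector to a feasible allocation for `prob` in three
#' steps: clamp to the box `[lb, ub]`; project (Euclidean) onto the
#' intersection of the simplex with the box; shrink toward uniform until
#' the variance cap holds. Because the box admits the uniform vector,
#' the shrink (a convex combination with uniform) cannot leave the box,
#' so the result satisfies all constraint families. The repair is
#' idempotent.
#'
#' @param v Any numeric vector of length `n`.
#' @param prob An [allocation_problem()].
#' @return Feasible allocation with attribute `repaired` (`TRUE` if `v`
#'   was moved by more than 1e-9 in any coordinate).
#' @export
repair_allocation <- function(v, prob) {
  tg <- prob$targets
  if (length(v) != prob$n) stop("`v` must have length ", prob$n,
                                call. = FALSE)
  x <- pmin(pmax(v, tg$lb), tg$ub)
  x <- project_box_simplex(x, tg$lb, tg$ub)
  x <- enforce_variance_cap(x, prob$delta_sq)
  attr(x, "repaired") <- max(abs(x - v)) > 1e-9
  x
}

#' Constraint-by-constraint feasibility report
#'
#' @param x Allocation vector.
#' @param prob An [allocation_problem()].
#' @param tol_sum,tol_nonneg,tol_var Tolerances for the simplex sum, the
#'   nonnegativity, and the variance cap.
#' @return A named logical vector with entries `simplex`, `nonneg`,
#'   `variance`, `box`.
#' @export
allocation_feasibility <- function(x, prob, tol_sum = 1e-9,
                                   tol_nonneg = 1e-12, tol_var = 1e-9) {
  tg <- prob$targets
  c(simplex = abs(sum(x) - 1) <= tol_sum,
    nonneg = all(x >= -tol_nonneg),
    variance = sum(x^2) <= prob$delta_sq + tol_var,
    box = all(x >= tg$lb - 1e-9) && all(x <= tg$ub + 1e-9))
}
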