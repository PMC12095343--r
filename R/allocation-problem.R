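#' Define a resource-allocation problem
#'
#' An allocation problem distributes one category of public-health
#' education resource (teaching materials R1, staff R2, facilities R3,
#' IT support R4) as shares `x_a` over `n` targets (regions,
#' institutions or projects). A feasible allocation lies on the
#' probability simplex (`sum(x) = 1`, `x >= 0`), respects per-target box
#' bounds `lb_a <= x_a <= ub_a`, and satisfies a concentration cap on
#' the second moment, `sum(x^2) <= delta_sq`, which limits how unevenly
#' the resource may be spread. The objective maximized is the weighted
#' effect `sum(w_a * g_a(x_a))`, where each target has an efficiency
#' `E_a` and an effect curve `g_a` from:
#' * `linear`: `g(x) = E * x`;
#' * `saturating`: `g(x) = E * (1 - exp(-kappa * x))` (diminishing
#'   returns, rate `kappa` in `g_param`);
#' * `power`: `g(x) = E * x^gamma` (concave for `gamma < 1`, exponent in
#'   `g_param`).
#'
#' @param targets Data frame with one row per target. Required column
#'   `efficiency` (positive). Optional columns: `target_id` (default
#'   `t1..tn`), `weight` (nonnegative, must sum to 1; default uniform),
#'   `g_family` (`"linear"`, `"saturating"`, `"power"`; default linear),
#'   `g_param` (parameter for the chosen family), `lb`, `ub` (box
#'   bounds in `[0, 1]`, defaults 0 and 1).
#' @param delta_sq Second-moment cap in `[1/n, 1]`. The lower end forces
#'   the uniform allocation; the upper end permits full concentration.
#' @param category Resource category label, one of `"R1"` (materials),
#'   `"R2"` (staff), `"R3"` (facilities), `"R4"` (IT).
#' @param shareable Whether the resource can be shared across locations
#'   (materials and IT can; staff and facilities are location-bound).
#'   Defaults by category. Metadata only: it drives scenario
#'   generation, not the mathematics.
#' @return An object of class `allocation_problem`.
#' @details The box bounds must admit the uniform allocation
#'   (`lb_a <= 1/n <= ub_a`): together with `delta_sq >= 1/n` this
#'   guarantees the feasible set is nonempty and that shrinking toward
#'   uniform never leaves the box.
#' @examples
#' prob <- allocation_problem(
#'   data.frame(efficiency = c(2, 1)), delta_sq = 0.625)
#' allocation_objective(c(0.75, 0.25), prob)
#' @export
allocation_problem <- function(targets, delta_sq,
                               category = c("R1", "R2", "R3", "R4"),
                               shareable = NULL) {
  category <- match.arg(category)
  if (is.null(shareable)) shareable <- category %in% c("R1", "R4")
  targets <- tibble::as_tibble(targets)
  n <- nrow(targets)
  if (n < 1) stop("at least one target is required", call. = FALSE)
  if (!"efficiency" %in% names(targets)) {
    stop("`targets` must have an `efficiency` column", call. = FALSE)
  }
  if (any(targets$efficiency <= 0)) {
    stop("efficiencies must be positive", call. = FALSE)
  }
  if (!"target_id" %in% names(targets)) {
    targets$target_id <- paste0("t", seq_len(n))
  }
  if (!"weight" %in% names(targets)) targets$weight <- rep(1 / n, n)
  if (any(targets$weight < 0)) stop("weights must be nonnegative",
                                    call. = FALSE)
  if (abs(sum(targets$weight) - 1) > 1e-9) {
    stop("weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (!"g_family" %in% names(targets)) targets$g_family <- "linear"
  bad <- setdiff(unique(targets$g_family),
                 c("linear", "saturating", "power"))
  if (length(bad) > 0) {
    stop("unknown effect family: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"g_param" %in% names(targets)) targets$g_param <- NA_real_
  needs_param <- targets$g_family != "linear"
  if (any(needs_param & !is.finite(targets$g_param))) {
    stop("saturating/power effect families need a finite `g_param`",
         call. = FALSE)
  }
  if (!"lb" %in% names(targets)) targets$lb <- 0
  if (!"ub" %in% names(targets)) targets$ub <- 1
  if (any(targets$lb < 0) || any(targets$ub > 1) ||
      any(targets$lb > targets$ub)) {
    stop("box bounds must satisfy 0 <= lb <= ub <= 1", call. = FALSE)
  }
  if (sum(targets$lb) > 1 + 1e-12 || sum(targets$ub) < 1 - 1e-12) {
    stop("box bounds are incompatible with the simplex: ",
         "need sum(lb) <= 1 <= sum(ub)", call. = FALSE)
  }
  if (any(targets$lb > 1 / n + 1e-12) || any(targets$ub < 1 / n - 1e-12)) {
    stop("box bounds must admit the uniform allocation ",
         "(lb <= 1/n <= ub per target)", call. = FALSE)
  }
  if (length(delta_sq) != 1 || !is.finite(delta_sq)) {
    stop("`delta_sq` must be a finite scalar", call. = FALSE)
  }
  if (delta_sq < 1 / n - 1e-12) {
    stop(sprintf(paste0("infeasible variance cap: delta_sq = %.4g is ",
                        "below 1/n = %.4g (even the uniform allocation ",
                        "violates it)"), delta_sq, 1 / n), call. = FALSE)
  }
  if (delta_sq > 1 + 1e-12) {
    stop("`delta_sq` above 1 is vacuous on the simplex", call. = FALSE)
  }
  structure(
    list(targets = targets[, c("target_id", "efficiency", "weight",
                               "g_family", "g_param", "lb", "ub")],
         n = n, delta_sq = as.numeric(delta_sq),
         category = category, shareable = shareable),
    class = "allocation_problem"
  )
}

#' @export
print.allocation_problem <- function(x, ...) {
  cat("<allocation_problem> ", x$category,
      if (x$shareable) " (shareable)" else " (location-bound)",
      ": ", x$n, " targets, delta_sq = ", format(x$delta_sq, digits = 4),
      "\n", sep = "")
  print(x$targets, n = 5)
  invisible(x)
}

#' @describeIn allocation_problem the target table as a tibble.
#' @param x An `allocation_problem`.
#' @param ... Unused.
#' @export
as_tibble.allocation_problem <- function(x, ...) x$targets

#' Weighted-effect allocation objective
#'
#' Computes `sum(w_a * g_a(x_a))` for an allocation `x`. With all-linear
#' effects and uniform weights this is `mean(x * E)`, i.e. the classic
#' efficiency-weighted sum up to the constant `1/n`.
#'
#' @param x Allocation vector of length `n` (need not be feasible).
#' @param prob An [allocation_problem()].
#' @return A scalar effect value.
#' @export
allocation_objective <- function(x, prob) {
  tg <- prob$targets
  if (length(x) != prob$n) {
    stop("`x` must have length ", prob$n, call. = FALSE)
  }
  g <- numeric(prob$n)
  for (fam in unique(tg$g_family)) {
    i <- tg$g_family == fam
    g[i] <- switch(fam,
      linear = tg$efficiency[i] * x[i],
      saturating = tg$efficiency[i] * (1 - exp(-tg$g_param[i] * x[i])),
      power = tg$efficiency[i] * pmax(x[i], 0)^tg$g_param[i]
    )
  }
  sum(tg$weight * g)
}

#' Jain's fairness index of an allocation
#'
#' `(sum(x))^2 / (n * sum(x^2))`, a balance score in `(0, 1]`: 1 for the
#' uniform allocation, `1/n` for a one-hot allocation. On the simplex it
#' reduces to `1 / (n * sum(x^2))`, so the variance cap
#' `sum(x^2) <= delta_sq` bounds balance from below by
#' `1 / (n * delta_sq)`.
#'
#' @param x Nonnegative allocation vector with positive sum.
#' @return Scalar in `(0, 1]`.
#' @examples
#' jain_balance(rep(0.25, 4))   # 1
#' jain_balance(c(1, 0, 0, 0))  # 0.25
#' @export
jain_balance <- function(x) {
  if (any(x < 0) || sum(x) <= 0) {
    stop("`x` must be nonnegative with a positive sum", call. = FALSE)
  }
  sum(x)^2 / (length(x) * sum(x^2))
}
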