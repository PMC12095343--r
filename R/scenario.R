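#' Specify a synthetic allocation scenario
#'
#' Describes a family of multi-region allocation problems over the four
#' resource categories (R1 materials, R2 staff, R3 facilities, R4 IT).
#' Per-target efficiencies are drawn log-uniformly on `[0.5, 2]` by
#' default (so a target can be up to four times as efficient as
#' another), weights are uniform or Dirichlet, and the variance cap is
#' drawn uniformly inside `delta_sq_range` (sub-interval of `[1/n, 1]`;
#' values near `1/n` force near-uniform allocations, values near 1
#' permit concentration). Non-shareable categories (staff, facilities)
#' receive a tighter per-target upper bound, encoding that
#' location-bound resources cannot pile up in one place.
#'
#' @param n_regions Number of targets per problem (at least 2).
#' @param categories Character subset of `c("R1","R2","R3","R4")`.
#' @param efficiency_range Range of the log-uniform efficiency law.
#' @param weight_law `"uniform"` or `"dirichlet"`.
#' @param dirichlet_alpha Concentration parameter when
#'   `weight_law = "dirichlet"`.
#' @param delta_sq_range Interval the variance cap is drawn from;
#'   clipped into `[1/n, 1]`. Defaults to the full admissible range.
#' @param g_family Effect family applied to every target (`"linear"`
#'   default, or `"saturating"`, `"power"`).
#' @param g_param Effect-curve parameter for non-linear families.
#' @param ub_shareable,ub_fixed Per-target upper bounds for shareable
#'   (R1, R4) and location-bound (R2, R3) categories.
#' @param seed Integer seed; scenarios are reproducible from it.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_regions = 5L,
                          categories = c("R1", "R2", "R3", "R4"),
                          efficiency_range = c(0.5, 2),
                          weight_law = c("uniform", "dirichlet"),
                          dirichlet_alpha = 5,
                          delta_sq_range = NULL,
                          g_family = c("linear", "saturating", "power"),
                          g_param = 5,
                          ub_shareable = 1, ub_fixed = 0.5,
                          seed = 1L) {
  check_count(n_regions, "n_regions")
  if (n_regions < 2) stop("`n_regions` must be at least 2", call. = FALSE)
  categories <- match.arg(categories, several.ok = TRUE)
  weight_law <- match.arg(weight_law)
  g_family <- match.arg(g_family)
  n <- as.integer(n_regions)
  if (is.null(delta_sq_range)) delta_sq_range <- c(1 / n, 1)
  delta_sq_range <- c(max(delta_sq_range[1], 1 / n),
                      min(delta_sq_range[2], 1))
  if (delta_sq_range[1] > delta_sq_range[2]) {
    stop("empty `delta_sq_range` after clipping into [1/n, 1]",
         call. = FALSE)
  }
  stopifnot(efficiency_range[1] > 0,
            efficiency_range[2] >= efficiency_range[1])
  structure(
    list(n_regions = n, categories = categories,
         efficiency_range = efficiency_range,
         weight_law = weight_law, dirichlet_alpha = dirichlet_alpha,
         delta_sq_range = delta_sq_range,
         g_family = g_family, g_param = g_param,
         ub_shareable = ub_shareable, ub_fixed = ub_fixed,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$n_regions, " regions x {",
      paste(x$categories, collapse = ", "), "}, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic allocation scenario
#'
#' Draws one [allocation_problem()] per requested resource category
#' under the laws of the [scenario_spec()]. Every emitted problem passes
#' full validation (feasible variance cap, box bounds admitting the
#' uniform allocation), and regeneration from the same spec is
#' identical.
#'
#' @param spec A `scenario_spec`.
#' @return A named list of `allocation_problem`s, one per category.
#' @examples
#' sc <- generate_scenario(scenario_spec(n_regions = 4, seed = 7))
#' names(sc)
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_regions
  withr::with_seed(spec$seed, {
    out <- lapply(spec$categories, function(cat) {
      shareable <- cat %in% c("R1", "R4")
      eff <- exp(stats::runif(n, log(spec$efficiency_range[1]),
                              log(spec$efficiency_range[2])))
      w <- if (spec$weight_law == "uniform") rep(1 / n, n) else {
        g <- stats::rgamma(n, shape = spec$dirichlet_alpha, rate = 1)
        g / sum(g)
      }
      d2 <- stats::runif(1, spec$delta_sq_range[1], spec$delta_sq_range[2])
      ub <- if (shareable) spec$ub_shareable else spec$ub_fixed
      ub <- max(ub, 1 / n)  # box must admit the uniform allocation
      targets <- tibble::tibble(
        target_id = paste0("region", seq_len(n)),
        efficiency = eff,
        weight = w,
        g_family = spec$g_family,
        g_param = if (spec$g_family == "linear") NA_real_ else spec$g_param,
        lb = 0,
        ub = ub
      )
      allocation_problem(targets, delta_sq = d2, category = cat,
                         shareable = shareable)
    })
    names(out) <- spec$categories
    out
  })
}

#' Generate a linear problem together with its exact optimum
#'
#' Emits a linear-effect, uniform-weight allocation problem (default
#' box `[0, 1]`, efficiencies log-uniform on `[0.5, 2]`, variance cap
#' uniform on `[1/n, 1]`) together with its exact maximizer from
#' [kkt_oracle_linear()] — a self-checking fixture for
#' parameter-recovery tests.
#'
#' @param n Number of targets (at least 2).
#' @param seed Integer seed.
#' @param delta_sq Optional fixed variance cap; drawn randomly if `NULL`.
#' @return A list: `problem` (an `allocation_problem`), `x_star`,
#'   `f_star`.
#' @examples
#' fx <- generate_with_known_optimum(3, seed = 2)
#' fx$f_star
#' @export
generate_with_known_optimum <- function(n, seed = 1L, delta_sq = NULL) {
  check_count(n, "n")
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    E <- exp(stats::runif(n, log(0.5), log(2)))
    d2 <- if (is.null(delta_sq)) stats::runif(1, 1 / n, 1) else delta_sq
    prob <- allocation_problem(
      tibble::tibble(efficiency = E), delta_sq = d2, category = "R1")
    orc <- kkt_oracle_linear(E, d2)
    # objective uses uniform weights 1/n, so scale the oracle value
    list(problem = prob, x_star = orc$x, f_star = orc$value / n)
  })
}
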