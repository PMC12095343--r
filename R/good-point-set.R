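#' Deterministic good-point-set in the unit cube
#'
#' Constructs the classical good point set of `n` points in `[0,1)^d`:
#' point `k` is `({gamma_1 k}, ..., {gamma_d k})` for `k = 1..n`, where
#' `{.}` is the fractional part and the generators are
#' `gamma_j = frac(2 cos(2 pi j / p))` with `p` the smallest prime
#' `>= 2d + 3`. The construction is deterministic: no seed, and repeated
#' calls with the same `(n, d)` are bit-identical. Good point sets cover
#' the cube more evenly than uniform random draws (lower star
#' discrepancy), which is why they are used to initialize population
#' optimizers.
#'
#' @param n Number of points (positive integer).
#' @param d Dimension (positive integer).
#' @return An object of class `good_point_set`: a list with `points`
#'   (an `n` x `d` matrix with entries in `[0,1)`), `generators`
#'   (length-`d` numeric), `prime`, `n` and `d`.
#' @examples
#' gps <- good_point_set(100, 2)
#' head(gps$points)
#' @export
good_point_set <- function(n, d) {
  check_count(n, "n")
  check_count(d, "d")
  p <- smallest_prime_geq(2L * d + 3L)
  gamma <- (2 * cos(2 * pi * seq_len(d) / p)) %% 1
  k <- seq_len(n)
  pts <- (outer(k, gamma)) %% 1
  dimnames(pts) <- NULL
  structure(
    list(points = pts, generators = gamma, prime = p, n = as.integer(n),
         d = as.integer(d)),
    class = "good_point_set"
  )
}

#' @export
print.good_point_set <- function(x, ...) {
  cat("<good_point_set> ", x$n, " points in [0,1)^", x$d,
      " (p = ", x$prime, ")\n", sep = "")
  invisible(x)
}

#' @describeIn good_point_set points as a tibble with columns
#'   `dim1..dimd`.
#' @param x A `good_point_set`.
#' @param ... Unused.
#' @export
as_tibble.good_point_set <- function(x, ...) {
  colnames(x$points) <- paste0("dim", seq_len(x$d))
  out <- tibble::as_tibble(x$points)
  colnames(x$points) <- NULL
  out
}

#' Affinely map unit-cube points onto search bounds
#'
#' Maps points in `[0,1)^d` onto the box `[lb, ub)` by
#' `lb + pts * (ub - lb)`, dimension by dimension.
#'
#' @param pts A `good_point_set` or a numeric matrix with entries in
#'   `[0,1)`.
#' @param lb,ub Numeric vectors of length `d` (or scalars, recycled) with
#'   `ub > lb` elementwise.
#' @return An `n` x `d` numeric matrix inside `[lb, ub)`.
#' @export
map_to_bounds <- function(pts, lb, ub) {
  m <- if (inherits(pts, "good_point_set")) pts$points else as.matrix(pts)
  d <- ncol(m)
  lb <- rep_len(as.numeric(lb), d)
  ub <- rep_len(as.numeric(ub), d)
  if (any(ub <= lb)) {
    stop("`ub` must exceed `lb` in every dimension", call. = FALSE)
  }
  sweep(sweep(m, 2, ub - lb, "*"), 2, lb, "+")
}

#' Monte-Carlo estimate of the star discrepancy
#'
#' The star discrepancy of a point set is the worst-case absolute
#' difference between the fraction of points falling in an anchored box
#' `[0, a)` and the box's volume. Computing it exactly is NP-hard in the
#' dimension, so it is estimated here by probing `n_probe` random anchor
#' corners `a ~ U(0,1)^d` and taking the maximum deviation. The estimate
#' is a lower bound on the true discrepancy and is deterministic given
#' `seed`.
#'
#' @param points An `n` x `d` matrix with entries in `[0,1)`, or a
#'   `good_point_set`.
#' @param n_probe Number of random probe boxes (default 4096).
#' @param seed Integer seed for the probe draw.
#' @return A nonnegative scalar estimate.
#' @examples
#' gps <- good_point_set(200, 2)
#' estimate_discrepancy(gps, seed = 1)
#' @export
estimate_discrepancy <- function(points, n_probe = 4096, seed = 1L) {
  m <- if (inherits(points, "good_point_set")) points$points else as.matrix(points)
  if (any(m < 0) || any(m >= 1)) {
    stop("`points` must lie in the half-open unit cube [0,1)^d", call. = FALSE)
  }
  check_count(n_probe, "n_probe")
  n <- nrow(m)
  d <- ncol(m)
  withr::with_seed(as.integer(seed), {
    anchors <- matrix(stats::runif(n_probe * d), nrow = n_probe, ncol = d)
    best <- 0
    # process probes in blocks to bound memory at n x block
    block <- max(1L, as.integer(2e6 / max(n, 1L)))
    for (start in seq(1L, n_probe, by = block)) {
      idx <- start:min(start + block - 1L, n_probe)
      a <- anchors[idx, , drop = FALSE]
      # counts[i, j] = how many points fall in box [0, a_j)
      inside <- matrix(TRUE, nrow = n, ncol = length(idx))
      for (j in seq_len(d)) {
        inside <- inside & outer(m[, j], a[, j], "<")
      }
      frac <- colSums(inside) / n
      vol <- apply(a, 1, prod)
      best <- max(best, max(abs(frac - vol)))
    }
    best
  })
}

# smallest prime >= x by trial division; x is tiny (2d + 3)
smallest_prime_geq <- function(x) {
  is_prime <- function(q) {
    if (q < 2L) return(FALSE)
    if (q < 4L) return(TRUE)
    if (q %% 2L == 0L) return(FALSE)
    f <- 3L
    while (f * f <= q) {
      if (q %% f == 0L) return(FALSE)
      f <- f + 2L
    }
    TRUE
  }
  q <- as.integer(x)
  while (!is_prime(q)) q <- q + 1L
  q
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
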