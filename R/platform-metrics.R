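#' Content-push scores and ranking
#'
#' Scores each educational content item by the weighted affinity of its
#' user groups to the push strategy: `C_i = sum_j U_ij * P_j`, where row
#' `i` of the affinity table holds content `i`'s weight for each user
#' group and `P` weights the push strategy across groups. Contents are
#' ranked by descending score, ties broken by lowest row index. Scores
#' are linear in `P`: rescaling all strategy weights by a positive
#' constant rescales every score but leaves the ranking unchanged.
#'
#' @param affinity Data frame or matrix: one row per content item,
#'   one numeric column per user group (an optional `content_id` column
#'   is carried through). Affinities must be nonnegative.
#' @param strategy_weights Nonnegative numeric vector, one entry per
#'   user-group column.
#' @return A tibble with columns `content_id`, `score`, `rank`, ordered
#'   by rank.
#' @examples
#' push_scores(data.frame(g1 = c(1, 0), g2 = c(0, 1)), c(0.9, 0.1))
#' @export
push_scores <- function(affinity, strategy_weights) {
  affinity <- tibble::as_tibble(as.data.frame(affinity))
  ids <- if ("content_id" %in% names(affinity)) {
    as.character(affinity$content_id)
  } else {
    paste0("content", seq_len(nrow(affinity)))
  }
  U <- as.matrix(affinity[setdiff(names(affinity), "content_id")])
  storage.mode(U) <- "double"
  if (ncol(U) != length(strategy_weights)) {
    stop("`strategy_weights` must have one entry per user-group column (",
         ncol(U), ")", call. = FALSE)
  }
  if (any(U < 0) || any(strategy_weights < 0)) {
    stop("affinities and strategy weights must be nonnegative",
         call. = FALSE)
  }
  score <- as.numeric(U %*% strategy_weights)
  rk <- rank(-score, ties.method = "first")
  tibble::tibble(content_id = ids, score = score, rank = as.integer(rk)) |>
    dplyr::arrange(.data$rank)
}

#' User-satisfaction score
#'
#' The weighted mean `S = sum_i Q_i * W_i` of per-service quality
#' ratings `Q` under normalized weights `W` (`sum(W) = 1`). Being a
#' convex combination, `S` always lies between `min(Q)` and `max(Q)`,
#' and is invariant under a joint permutation of `(Q, W)`.
#'
#' @param quality Numeric vector of per-service quality ratings.
#' @param weights Nonnegative weights of the same length summing to 1
#'   (within 1e-9); normalize upstream if needed.
#' @return Scalar satisfaction score.
#' @examples
#' satisfaction_score(c(8, 6), c(0.7, 0.3))  # 7.4
#' @export
satisfaction_score <- function(quality, weights) {
  if (length(quality) != length(weights)) {
    stop("`quality` and `weights` must have equal length", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be nonnegative and sum to 1 (within 1e-9); ",
         "normalize explicitly upstream", call. = FALSE)
  }
  sum(quality * weights)
}
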