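#' Write / read an allocation problem as CSV + JSON header
#'
#' The on-disk format is a pair of files: `<stem>.csv` holding the
#' target table (columns `target_id, efficiency, weight, g_family,
#' g_param, lb, ub`) and `<stem>.json` holding the scalar header
#' (`n`, `delta_sq`, `category`, `shareable`).
#'
#' @param prob An [allocation_problem()].
#' @param stem Path stem; `.csv` and `.json` are appended.
#' @return `write_allocation_problem` returns `stem` invisibly;
#'   `read_allocation_problem` returns the reconstructed problem.
#' @export
write_allocation_problem <- function(prob, stem) {
  utils::write.csv(prob$targets, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n = prob$n, delta_sq = prob$delta_sq, category = prob$category,
         shareable = prob$shareable),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_allocation_problem
#' @export
read_allocation_problem <- function(stem) {
  targets <- utils::read.csv(paste0(stem, ".csv"),
                             stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!is.null(hdr$n) && hdr$n != nrow(targets)) {
    stop("header n (", hdr$n, ") disagrees with the target table (",
         nrow(targets), " rows)", call. = FALSE)
  }
  allocation_problem(targets, delta_sq = hdr$delta_sq,
                     category = hdr$category, shareable = hdr$shareable)
}

#' Write an allocation solution as CSV + JSON summary
#'
#' `<stem>.csv` holds the shares (`target_id, share`); `<stem>.json`
#' holds the summary (objective value, Jain balance, feasibility flags,
#' repaired flag, algorithm, seed). No timestamps or host information
#' are written, so outputs are byte-reproducible.
#'
#' @param sol An `allocation_solution`.
#' @param stem Path stem.
#' @return `stem`, invisibly.
#' @export
write_allocation_solution <- function(sol, stem) {
  utils::write.csv(
    data.frame(target_id = sol$problem$targets$target_id, share = sol$x),
    paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(objective_value = sol$objective_value,
         balance = sol$balance,
         feasible = as.list(sol$feasible),
         repaired = sol$repaired,
         algorithm = sol$algorithm,
         category = sol$problem$category,
         seed = if (is.null(sol$result)) NULL else sol$result$seed),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Write an optimization result as JSON
#'
#' Serializes `best_position`, `best_fitness`, the per-iteration
#' best-so-far `history`, `n_evaluations` and `seed`.
#'
#' @param res A `sparrow_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_optimization_result <- function(res, path) {
  jsonlite::write_json(
    list(algorithm = res$algorithm,
         objective = res$objective_name,
         best_position = res$best_position,
         best_fitness = res$best_fitness,
         history = res$history,
         n_evaluations = res$n_evaluations,
         seed = res$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a good point set as headerless CSV
#'
#' One row per point, one column per dimension, no header.
#'
#' @param pts A `good_point_set` or unit-cube matrix.
#' @param path Output path.
#' @param header Write a `dim1..dimd` header row (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_point_set <- function(pts, path, header = FALSE) {
  m <- if (inherits(pts, "good_point_set")) pts$points else as.matrix(pts)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = if (header) paste0("dim", seq_len(ncol(m)))
                                 else FALSE)
  invisible(path)
}
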